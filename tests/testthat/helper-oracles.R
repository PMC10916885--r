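# Independent reference implementations (plain loops, no shared code paths
# with the package internals) used as oracles.

# Reflect-pad (symmetric, edge included) by p pixels; supports padding wider
# than the matrix by tiling the mirrored sequence.
oracle_pad <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  tile <- function(n) {
    base <- c(seq_len(n), rev(seq_len(n)))   # one full mirror period
    reps <- ceiling((n + 2 * p) / (2 * n)) + 1
    full <- rep(base, reps)
    # align so that the p-th element before the window start mirrors row p
    start <- 2 * n * ceiling(p / (2 * n)) - p + 1
    full[start:(start + n + 2 * p - 1)]
  }
  m[tile(nr), tile(nc)]
}

# Direct sliding-window cross-correlation with an odd kernel.
oracle_filter <- function(m, kern) {
  kh <- (nrow(kern) - 1) / 2
  P <- oracle_pad(m, max(kh, (ncol(kern) - 1) / 2))
  out <- matrix(NA_real_, nrow(m), ncol(m))
  kw <- (ncol(kern) - 1) / 2
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      pi <- i + kh; pj <- j + kw
      out[i, j] <- sum(P[(pi - kh):(pi + kh), (pj - kw):(pj + kw)] * kern)
    }
  }
  out
}

# Quantile with linear interpolation (type 7), written from the definition.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

# Full brute-force re-implementation of the driver/modulator insertion
# algorithm (noise disabled), following the published order of operations.
oracle_insertion <- function(image_edges, object_edges, type,
                             blur_sd = 5, harris_block = 10, harris_k = 0.04,
                             corner_quantile = 0.9, window_diam_frac = 0.8,
                             window_sd_frac = 0.1) {
  if (type == "image_driven") {
    drv <- image_edges; mod <- object_edges
  } else {
    drv <- object_edges; mod <- image_edges
  }
  H <- nrow(drv$magnitude); W <- ncol(drv$magnitude)
  mm <- function(m) (m - min(m)) / (max(m) - min(m))
  M_up <- mm(drv$magnitude)
  M_dn <- if (max(mod$magnitude) - min(mod$magnitude) < 1e-300) {
    matrix(0, H, W)
  } else mm(mod$magnitude)
  half <- ceiling(4 * blur_sd)
  xs <- -half:half
  g1 <- exp(-xs^2 / (2 * blur_sd^2))
  gk <- outer(g1, g1); gk <- gk / sum(gk)
  M_dn <- 1 - oracle_filter(M_dn, gk)
  # Harris: 3x3 Sobel derivatives, 10x10 box sums (offsets -4..+5)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- oracle_filter(M_up, sx)
  gy <- oracle_filter(M_up, t(sx))
  P <- list(xx = oracle_pad(gx * gx, 6), yy = oracle_pad(gy * gy, 6),
            xy = oracle_pad(gx * gy, 6))
  lo <- -(harris_block %/% 2 - 1); hi <- harris_block %/% 2
  R <- matrix(NA_real_, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ri <- (i + 6 + lo):(i + 6 + hi); ci <- (j + 6 + lo):(j + 6 + hi)
      sxx <- sum(P$xx[ri, ci]); syy <- sum(P$yy[ri, ci])
      sxy <- sum(P$xy[ri, ci])
      R[i, j] <- (sxx * syy - sxy^2) - harris_k * (sxx + syy)^2
    }
  }
  thr <- oracle_quantile7(as.vector(R), corner_quantile)
  M_up <- M_up * (R < thr)
  M <- M_up * M_dn
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  r0 <- window_diam_frac * W / 2; sdw <- window_sd_frac * W
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      r <- sqrt((i - cr)^2 + (j - cc)^2)
      if (r > r0) M[i, j] <- M[i, j] * exp(-(r - r0)^2 / (2 * sdw^2))
    }
  }
  cand <- which(M == max(M), arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  list(point = unname(cand[1, ]), M = M)
}

# Dominant spectral orientation of a patch via zero-padded 2-D FFT: the
# orientation (degrees in [0,180), 0 = horizontal stripes) of the strongest
# non-DC frequency component.
oracle_fft_orientation <- function(patch, pad = 128) {
  m <- patch - mean(patch)
  P <- matrix(0, pad, pad)
  P[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  A <- Mod(stats::fft(P))^2
  fr <- c(0:(pad / 2), -((pad / 2 - 1):1)) / pad   # cycles/px per index
  FR <- matrix(fr, pad, pad)        # row frequency (y, downward)
  FC <- matrix(fr, pad, pad, byrow = TRUE)
  A[1, 1] <- 0
  idx <- which.max(A)
  fy <- FR[idx]; fx <- FC[idx]
  # intensity varies along u = x sin(theta) + y cos(theta), so the spectral
  # peak sits at a wavevector proportional to (sin(theta), cos(theta))
  theta <- atan2(fx, fy) * 180 / pi
  ((theta %% 180) + 180) %% 180
}

# Central-difference Sobel oracle: gradients from the kernel definition at
# interior pixels only.
oracle_sobel_interior <- function(m) {
  H <- nrow(m); W <- ncol(m)
  gx <- matrix(NA_real_, H, W); gy <- matrix(NA_real_, H, W)
  for (i in 2:(H - 1)) {
    for (j in 2:(W - 1)) {
      gx[i, j] <- (m[i - 1, j + 1] + 2 * m[i, j + 1] + m[i + 1, j + 1]) -
        (m[i - 1, j - 1] + 2 * m[i, j - 1] + m[i + 1, j - 1])
      gy[i, j] <- (m[i + 1, j - 1] + 2 * m[i + 1, j] + m[i + 1, j + 1]) -
        (m[i - 1, j - 1] + 2 * m[i - 1, j] + m[i - 1, j + 1])
    }
  }
  list(gx = gx, gy = gy)
}

# Full-field grating at stripe orientation theta (degrees), period lambda px.
make_grating <- function(dims, theta, lambda, phase = 0.7, amplitude = 0.45,
                         baseline = 0.5) {
  thr <- theta * pi / 180
  X <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  Y <- matrix(seq_len(dims[1]), dims[1], dims[2])
  baseline + amplitude * cos(2 * pi * (X * sin(thr) + Y * cos(thr)) / lambda +
                               phase)
}

# Random edge-map pair for oracle comparisons.
random_edge_maps <- function(seed, dims = c(20L, 20L)) {
  withr::with_seed(seed, {
    a <- matrix(stats::runif(prod(dims)), dims[1], dims[2])
    b <- matrix(stats::runif(prod(dims)), dims[1], dims[2])
    list(image = sobelEdgeMap(a), object = sobelEdgeMap(b))
  })
}
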