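# Shared numerical utilities: seeded RNG plumbing and FFT-based 2-D filtering
# with reflected borders. All stochastic entry points take an explicit integer
# seed and restore the caller's RNG state on exit.

#' Derive a child seed from a parent seed and an index
#'
#' Deterministic mixing used to hand independent seeds to sub-stages (one per
#' trial, per block, per bootstrap draw) from a single user-facing seed. Kept
#' below 2^31 so the result is always a valid R integer seed.
#'
#' @param seed Parent integer seed.
#' @param k Nonnegative integer index of the sub-stage.
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 48271 + as.numeric(k) * 9973 + 1) %% 2147483647)
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Symmetric-reflection index: position `pos` (may run beyond [1, n] on
# either side) folded into 1..n with period 2n, edge sample included
# (...3,2,1|1,2,3...|3,2,1...). Handles padding wider than the matrix.
reflect_index <- function(pos, n) {
  q <- (pos - 1L) %% (2L * n)
  ifelse(q < n, q + 1L, 2L * n - q)
}

# Reflect-pad a matrix by (pr, pc) pixels on each side (symmetric padding,
# edge pixel included).
pad_reflect <- function(m, pr, pc) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- reflect_index((1L - pr):(nr + pr), nr)
  ci <- reflect_index((1L - pc):(nc + pc), nc)
  m[ri, ci, drop = FALSE]
}

# Smallest 5-smooth (2^a 3^b 5^c) integer >= n: mixed-radix FFTs degrade
# badly on sizes with large prime factors.
next_good_size <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

# Zero-extend a matrix at the bottom/right to the given dimensions.
zero_extend <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  out <- matrix(0, nr, nc)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# 2-D cross-correlation (filter semantics, like a sliding dot product) of an
# image with an odd-sized kernel, reflected borders, computed via FFT at an
# FFT-friendly padded size (the appended zeros sit beyond the cropped
# region, so the wrap-around of the circular convolution never reaches it).
conv2_reflect <- function(img, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L
  kc <- (ncol(kern) - 1L) %/% 2L
  stopifnot(nrow(kern) == 2L * kr + 1L, ncol(kern) == 2L * kc + 1L)
  P <- pad_reflect(img, kr, kc)
  nr <- next_good_size(nrow(P))
  nc <- next_good_size(ncol(P))
  P <- zero_extend(P, nr, nc)
  K <- matrix(0, nr, nc)
  # place the flipped kernel so that circular convolution realizes correlation
  K[seq_len(2L * kr + 1L), seq_len(2L * kc + 1L)] <-
    kern[rev(seq_len(2L * kr + 1L)), rev(seq_len(2L * kc + 1L))]
  full <- Re(stats::fft(stats::fft(P) * stats::fft(K), inverse = TRUE)) /
    length(P)
  full[(2L * kr + 1L):(2L * kr + nrow(img)),
       (2L * kc + 1L):(2L * kc + ncol(img)), drop = FALSE]
}

# Correlate one padded-image FFT against a precomputed kernel FFT. Used by the
# Gabor bank so each map costs one forward transform regardless of channels.
conv2_from_fft <- function(img_fft, kern_fft, dims, kr, kc) {
  full <- Re(stats::fft(img_fft * kern_fft, inverse = TRUE)) /
    length(img_fft)
  full[(2L * kr + 1L):(2L * kr + dims[1L]),
       (2L * kc + 1L):(2L * kc + dims[2L]), drop = FALSE]
}

# Isotropic Gaussian kernel, truncated at 4 SD, normalized to unit sum.
gaussian_kernel <- function(sd, truncate = 4) {
  half <- max(1L, ceiling(truncate * sd))
  xs <- -half:half
  g <- exp(-xs^2 / (2 * sd^2))
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian blur with reflected borders.
gaussian_blur <- function(m, sd, truncate = 4) {
  conv2_reflect(m, gaussian_kernel(sd, truncate))
}

# Fold an angle (degrees) into [0, 180). Guards the floating-point edge
# where `x %% 180` returns exactly 180 for tiny negative x.
fold180 <- function(theta) {
  out <- theta %% 180
  out[out < 0] <- out[out < 0] + 180
  out[out >= 180] <- 0
  out
}

# Argmax over a matrix with deterministic tie-breaking: among tied maxima the
# lowest (row, col) lexicographic index wins.
argmax_rc <- function(m) {
  mx <- max(m)
  idx <- which(m == mx)
  rows <- ((idx - 1L) %% nrow(m)) + 1L
  cols <- ((idx - 1L) %/% nrow(m)) + 1L
  o <- order(rows, cols)[1L]
  c(row = rows[o], col = cols[o])
}

# Soft circular window: 1 inside a centred disc, Gaussian falloff outside.
circular_window <- function(dims, diameter, edge_sd) {
  r0 <- diameter / 2
  cr <- (dims[1L] + 1) / 2
  cc <- (dims[2L] + 1) / 2
  rr <- matrix(seq_len(dims[1L]), dims[1L], dims[2L]) - cr
  cc2 <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE) - cc
  r <- sqrt(rr^2 + cc2^2)
  w <- matrix(1, dims[1L], dims[2L])
  out <- r > r0
  w[out] <- exp(-(r[out] - r0)^2 / (2 * edge_sd^2))
  w
}
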