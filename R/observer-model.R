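# Weighted cue-combination observer model: quadrature Gabor orientation/
# energy maps of the image, depth, and probe-present snapshots; pixel-wise
# circular orientation differences against the probe map; weighted averaging
# of the two differential maps by cue weight w; 3x3 pooling at the probe
# location and a 45-degree decision rule. The weight is fitted by maximizing
# trial-by-trial agreement with observed responses over a w grid, with
# bootstrap resampling of trials.

# Cache of Gabor banks keyed by (dims, sd, lambda), holding kernel FFTs at
# the padded size so each map costs a single forward transform.
.gabor_cache <- new.env(parent = emptyenv())

gabor_bank <- function(dims, sd_px, lambda_px,
                       channels = seq(0, 157.5, by = 22.5)) {
  key <- paste(dims[1], dims[2], signif(sd_px, 10), signif(lambda_px, 10),
               sep = "|")
  if (!is.null(.gabor_cache[[key]])) return(.gabor_cache[[key]])
  half <- max(1L, ceiling(4 * sd_px))
  xs <- -half:half
  n <- length(xs)
  X <- matrix(xs, n, n, byrow = TRUE)   # col offset (x, rightward)
  Y <- matrix(xs, n, n)                 # row offset (y, downward)
  env <- exp(-(X^2 + Y^2) / (2 * sd_px^2))
  pr <- half; pc <- half
  PR <- next_good_size(dims[1] + 2L * pr)
  PC <- next_good_size(dims[2] + 2L * pc)
  embed_fft <- function(kern) {
    K <- matrix(0, PR, PC)
    K[seq_len(2L * pr + 1L), seq_len(2L * pc + 1L)] <-
      kern[rev(seq_len(nrow(kern))), rev(seq_len(ncol(kern)))]
    stats::fft(K)
  }
  kernels <- lapply(channels, function(th) {
    thr <- th * pi / 180
    u <- X * sin(thr) + Y * cos(thr)
    even <- env * cos(2 * pi * u / lambda_px)
    even <- even - mean(even)            # zero DC: constant input -> 0 energy
    odd <- env * sin(2 * pi * u / lambda_px)
    list(even = embed_fft(even), odd = embed_fft(odd))
  })
  bank <- list(channels = channels, kernels = kernels, half = half,
               dims = dims)
  .gabor_cache[[key]] <- bank
  bank
}

#' Orientation/energy map from a quadrature Gabor bank
#'
#' Filters the map with quadrature pairs of Gabor wavelets at eight
#' orientations spanning [0, 180) in 22.5-degree steps. Defaults follow the
#' analysis geometry: carrier wavelength 2% of image width and envelope SD 2%
#' of image width for scene maps (halve `envelope_sd_frac` for the probe
#' map). Per pixel, channel energy is (even response)^2 + (odd response)^2;
#' the map stores the winning channel's orientation and energy. The
#' cosine-phase kernel is mean-subtracted, so constant inputs yield exactly
#' zero energy and undefined (`NA`) orientation. Borders are reflected.
#'
#' @param map2d Numeric matrix (any scale; the channel argmax is invariant to
#'   affine intensity changes).
#' @param envelope_sd_frac Envelope SD as a fraction of image width.
#' @param carrier_wavelength_frac Carrier wavelength as a fraction of image
#'   width.
#' @return A list of class `"orientation_energy_map"` with `orientation`
#'   (degrees in {0, 22.5, ..., 157.5}, `NA` where energy is 0), `energy`
#'   (channel-max energy), and `channels`.
#' @export
gaborOrientationMap <- function(map2d, envelope_sd_frac = 0.02,
                                carrier_wavelength_frac = 0.02) {
  stopifnot(is.matrix(map2d), all(is.finite(map2d)), envelope_sd_frac > 0)
  dims <- dim(map2d)
  W <- dims[2]
  bank <- gabor_bank(dims, sd_px = envelope_sd_frac * W,
                     lambda_px = carrier_wavelength_frac * W)
  P <- zero_extend(pad_reflect(map2d, bank$half, bank$half),
                   nrow(bank$kernels[[1]]$even), ncol(bank$kernels[[1]]$even))
  Pf <- stats::fft(P)
  best_e <- matrix(-Inf, dims[1], dims[2])
  best_i <- matrix(1L, dims[1], dims[2])
  for (i in seq_along(bank$channels)) {
    ev <- conv2_from_fft(Pf, bank$kernels[[i]]$even, dims, bank$half, bank$half)
    od <- conv2_from_fft(Pf, bank$kernels[[i]]$odd, dims, bank$half, bank$half)
    e <- ev^2 + od^2
    upd <- e > best_e
    best_e[upd] <- e[upd]
    best_i[upd] <- i
  }
  best_e[best_e < 0] <- 0
  # clamp FFT round-off so genuinely flat inputs report exactly zero energy
  best_e[best_e < 1e-18 * max(1, max(abs(map2d)))^2] <- 0
  ori <- matrix(bank$channels[best_i], dims[1], dims[2])
  ori[best_e == 0] <- NA_real_
  structure(list(orientation = ori, energy = best_e,
                 channels = bank$channels),
            class = "orientation_energy_map")
}

#' Circular distance between orientations
#'
#' Distance on the 180-degree orientation circle:
#' `min(|a - b| mod 180, 180 - |a - b| mod 180)`, in [0, 90]. Symmetric and
#' vectorized.
#'
#' @param theta_a,theta_b Orientations in degrees.
#' @return Distances in degrees.
#' @export
circularOrientationDistance <- function(theta_a, theta_b) {
  d <- abs(theta_a - theta_b) %% 180
  pmin(d, 180 - d)
}

#' Bundle the three aligned snapshots of one trial for the observer model
#'
#' @param M_image Pre-probe luminance snapshot (matrix).
#' @param M_depth Pre-probe depth snapshot (matrix, same dims).
#' @param M_probe Probe-present luminance snapshot (matrix, same dims).
#' @param probe_point `c(row, col)` probe centre (1-based).
#' @param human_response Optional `"congruent"`/`"incongruent"` observed
#'   response.
#' @return A list of class `"model_trial_input"`.
#' @export
modelTrialInput <- function(M_image, M_depth, M_probe, probe_point,
                            human_response = NULL) {
  stopifnot(is.matrix(M_image),
            all(dim(M_image) == dim(M_depth)),
            all(dim(M_image) == dim(M_probe)),
            length(probe_point) == 2)
  if (!is.null(human_response)) {
    stopifnot(human_response %in% c("congruent", "incongruent"))
  }
  structure(list(M_image = M_image, M_depth = M_depth, M_probe = M_probe,
                 probe_point = as.integer(probe_point),
                 human_response = human_response),
            class = "model_trial_input")
}

# Pool the two differential maps of a trial over the 3x3 box at the probe
# point. Returns c(image = ., object = .) mean circular differences in
# degrees, or NULL if the trial is excluded (some energy map carries no
# energy, or no defined orientation, within the pooling region). The result
# is cached on the trial object's environment-free attribute pathway by
# callers that loop over w.
pooled_cue_diffs <- function(trial,
                             scene_sd_frac = 0.02, probe_sd_frac = 0.01,
                             carrier_wavelength_frac = 0.02,
                             energy_rel_tol = 1e-9) {
  pt <- trial$probe_point
  dims <- dim(trial$M_image)
  if (pt[1] < 2 || pt[2] < 2 || pt[1] > dims[1] - 1 || pt[2] > dims[2] - 1) {
    stop("probe_point 3x3 pooling box exits the map")
  }
  rows <- (pt[1] - 1L):(pt[1] + 1L)
  cols <- (pt[2] - 1L):(pt[2] + 1L)
  om_i <- gaborOrientationMap(trial$M_image, scene_sd_frac,
                              carrier_wavelength_frac)
  om_o <- gaborOrientationMap(trial$M_depth, scene_sd_frac,
                              carrier_wavelength_frac)
  om_p <- gaborOrientationMap(trial$M_probe, probe_sd_frac,
                              carrier_wavelength_frac)
  no_energy <- function(om) {
    e <- om$energy[rows, cols]
    all(e <= energy_rel_tol * max(om$energy))
  }
  if (no_energy(om_i) || no_energy(om_o) || no_energy(om_p)) return(NULL)
  oi <- om_i$orientation[rows, cols]
  oo <- om_o$orientation[rows, cols]
  op <- om_p$orientation[rows, cols]
  # isolated zero-energy pixels have undefined orientation; the pooled mean
  # runs over the pixels where both maps are defined (the region as a whole
  # passed the energy test, so at least one pixel qualifies per map)
  di <- circularOrientationDistance(oi, op)
  do <- circularOrientationDistance(oo, op)
  if (all(is.na(di)) || all(is.na(do))) return(NULL)
  c(image = mean(di, na.rm = TRUE),
    object = mean(do, na.rm = TRUE))
}

#' Model response for one trial at cue weight w
#'
#' Builds image-driven and object-driven orientation maps (envelope SD 2% of
#' width) and the probe orientation map (SD 1%), forms the two differential
#' maps (pixel-wise circular distance against the probe map), combines them
#' as `w * imageDiff + (1 - w) * objectDiff`, pools the mean over the 3x3 box
#' at the probe point, and responds `"incongruent"` if the pooled value
#' exceeds 45 degrees, `"congruent"` otherwise (a pooled value of exactly 45
#' counts as congruent). Returns `"excluded"` when any of the three energy
#' maps carries no energy (relative tolerance `1e-9` of the map maximum) or
#' no defined orientation within the pooling region; exclusion does not
#' depend on `w`.
#'
#' @param trial A [modelTrialInput()].
#' @param w Cue weight in [0, 1] applied to the image-driven differential map.
#' @param diffs Optional precomputed [pooled_cue_diffs] result (internal fast
#'   path).
#' @return `"congruent"`, `"incongruent"`, or `"excluded"`. The pooled value
#'   is attached as attribute `"pooled"` (NA when excluded).
#' @export
modelResponse <- function(trial, w, diffs = NULL) {
  stopifnot(w >= 0, w <= 1)
  if (is.null(diffs)) diffs <- pooled_cue_diffs(trial)
  if (is.null(diffs)) {
    return(structure("excluded", pooled = NA_real_))
  }
  v <- w * diffs[["image"]] + (1 - w) * diffs[["object"]]
  structure(if (v > 45) "incongruent" else "congruent", pooled = v)
}

#' Human-model agreement over a grid of cue weights
#'
#' For each `w` in the grid, the fraction of (non-excluded) trials on which
#' the model's response equals the observed response. Excluded trials are
#' dropped from numerator and denominator; their fraction is reported.
#'
#' @param trials List of [modelTrialInput()]s, each with a `human_response`.
#' @param w_grid Weights in [0, 1] (default 0 to 1 in steps of 0.01).
#' @param diffs Optional precomputed list of [pooled_cue_diffs] results
#'   (internal fast path; `NULL` entries mark excluded trials).
#' @return A list of class `"w_estimate"` with `w_grid`, `agreement`,
#'   `excluded_fraction`, `n_used`.
#' @export
agreementCurve <- function(trials, w_grid = seq(0, 1, by = 0.01),
                           diffs = NULL) {
  stopifnot(length(trials) > 0, all(w_grid >= 0), all(w_grid <= 1))
  if (is.null(diffs)) diffs <- lapply(trials, pooled_cue_diffs)
  resp <- vapply(trials, function(tr) {
    if (is.null(tr$human_response)) {
      stop("every trial must carry a human_response")
    }
    tr$human_response
  }, character(1))
  keep <- !vapply(diffs, is.null, logical(1))
  if (!any(keep)) stop("all trials excluded: no agreement can be computed")
  iD <- vapply(diffs[keep], `[[`, numeric(1), "image")
  oD <- vapply(diffs[keep], `[[`, numeric(1), "object")
  incong <- resp[keep] == "incongruent"
  V <- outer(iD, w_grid) + outer(oD, 1 - w_grid)   # n x length(w_grid)
  match_mat <- (V > 45) == incong
  structure(list(w_grid = w_grid,
                 agreement = colMeans(match_mat),
                 excluded_fraction = mean(!keep),
                 n_used = sum(keep),
                 match_matrix = match_mat),
            class = "w_estimate")
}

#' Fit the cue weight by agreement maximization with bootstrap
#'
#' `w_best` is the grid argmax of the full-data agreement curve (ties
#' resolved at the midpoint of the tied index run). The bootstrap
#' distribution resamples trials with replacement and records the argmax per
#' resample. Deterministic given the seed.
#'
#' @param trials List of [modelTrialInput()]s with responses.
#' @param w_grid Weight grid.
#' @param n_bootstrap Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param diffs Optional precomputed pooled differences (fast path).
#' @return A `"w_estimate"` with `w_best` and `bootstrap_w` added.
#' @export
fitW <- function(trials, w_grid = seq(0, 1, by = 0.01), n_bootstrap = 1000L,
                 seed = 1L, diffs = NULL) {
  stopifnot(n_bootstrap >= 1)
  est <- agreementCurve(trials, w_grid, diffs = diffs)
  est$w_best <- w_grid[argmax_mid(est$agreement)]
  mm <- est$match_matrix
  n <- nrow(mm)
  est$bootstrap_w <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      ii <- sample.int(n, n, replace = TRUE)
      w_grid[argmax_mid(colMeans(mm[ii, , drop = FALSE]))]
    }, numeric(1))
  })
  est$match_matrix <- NULL
  est
}

# Index of the maximum; ties resolved at the midpoint of the tied indices.
argmax_mid <- function(x) {
  idx <- which(x == max(x))
  idx[(length(idx) + 1L) %/% 2L]
}

#' @export
print.w_estimate <- function(x, ...) {
  cat(sprintf("<w_estimate> grid of %d weights, peak agreement %.3f%s, %.0f%% excluded\n",
              length(x$w_grid), max(x$agreement),
              if (!is.null(x$w_best)) sprintf(" at w = %.2f", x$w_best) else "",
              100 * x$excluded_fraction))
  invisible(x)
}
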