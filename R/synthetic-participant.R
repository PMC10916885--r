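# Synthetic participant: a responder whose decisions are generated by the
# cue-combination observer model at a known ground-truth weight, softened by
# logistic decision noise, with lapse and invalid-response rates and a
# fixed-accuracy memory stage. Replaces human observers so that every
# analysis stage can be validated against known parameters.

#' Responder parameters
#'
#' @param w_true Ground-truth cue weight in [0, 1].
#' @param tau Decision noise (degrees): the 45-degree rule is softened to
#'   `P(incongruent) = logistic((v - 45) / tau)`; `tau = 0` recovers the hard
#'   rule. Default 8.
#' @param lapse_rate Probability of answering with a fair coin regardless of
#'   the stimulus.
#' @param invalid_rate Probability of failing to answer within the response
#'   window.
#' @param memory_accuracy Probability of a correct memory-task response.
#' @param w_drift Optional linear weight schedule,
#'   `list(w_start=, w_end=, onset_time=)` (seconds): constant at `w_start`
#'   before `onset_time`, linear to `w_end` at block end. Emulates slow cue
#'   reweighting within a block.
#' @return A list of class `"responder_params"`.
#' @export
responderParams <- function(w_true, tau = 8, lapse_rate = 0,
                            invalid_rate = 0, memory_accuracy = 0.75,
                            w_drift = NULL) {
  stopifnot(w_true >= 0, w_true <= 1, tau >= 0,
            lapse_rate >= 0, lapse_rate <= 1,
            invalid_rate >= 0, invalid_rate <= 1,
            memory_accuracy >= 0, memory_accuracy <= 1)
  if (!is.null(w_drift)) {
    stopifnot(all(c("w_start", "w_end", "onset_time") %in% names(w_drift)))
  }
  structure(list(w_true = w_true, tau = tau, lapse_rate = lapse_rate,
                 invalid_rate = invalid_rate,
                 memory_accuracy = memory_accuracy, w_drift = w_drift),
            class = "responder_params")
}

#' Cue weight at time t under the responder's schedule
#'
#' Constant `w_true` without drift; with drift, `w_start` until `onset_time`,
#' then linear interpolation to `w_end` at `block_end`, clipped to [0, 1].
#'
#' @param t Seconds since block start.
#' @param params A [responderParams()].
#' @param block_end Block duration in seconds (default 300).
#' @return Weight(s) in [0, 1]; vectorized over `t`.
#' @export
wSchedule <- function(t, params, block_end = 300) {
  stopifnot(inherits(params, "responder_params"), all(t >= 0))
  d <- params$w_drift
  if (is.null(d)) return(rep(params$w_true, length(t)))
  frac <- (t - d$onset_time) / max(block_end - d$onset_time, 1e-12)
  frac <- pmin(1, pmax(0, frac))
  pmin(1, pmax(0, d$w_start + frac * (d$w_end - d$w_start)))
}

#' Sensory response of the synthetic participant
#'
#' With probability `invalid_rate` the trial is `"invalid"`; with probability
#' `lapse_rate` the answer is a fair coin; otherwise the pooled incongruency
#' `v` is computed by the observer model at the scheduled weight `w(t)` and
#' the answer is `"incongruent"` with probability `logistic((v - 45) / tau)`
#' (hard 45-degree rule when `tau = 0`, ties answered congruent). Trials the
#' model excludes are answered by a fair coin: an observer always produces a
#' decision even when the model's maps carry no signal. Deterministic given
#' the seed.
#'
#' @param trial A [modelTrialInput()].
#' @param params A [responderParams()].
#' @param t Seconds since block start (drives the weight schedule).
#' @param seed Integer seed.
#' @param block_end Block duration in seconds.
#' @param diffs Optional precomputed [pooled_cue_diffs] result (fast path).
#' @return `"congruent"`, `"incongruent"`, or `"invalid"`.
#' @export
sensoryResponse <- function(trial, params, t = 0, seed = 1L,
                            block_end = 300, diffs = NULL) {
  stopifnot(inherits(params, "responder_params"))
  w <- wSchedule(t, params, block_end)
  if (is.null(diffs)) diffs <- pooled_cue_diffs(trial)
  with_seed(seed, {
    if (stats::runif(1) < params$invalid_rate) return("invalid")
    if (stats::runif(1) < params$lapse_rate) {
      return(if (stats::runif(1) < 0.5) "congruent" else "incongruent")
    }
    if (is.null(diffs)) {
      return(if (stats::runif(1) < 0.5) "congruent" else "incongruent")
    }
    v <- w * diffs[["image"]] + (1 - w) * diffs[["object"]]
    p_incong <- if (params$tau <= 0) as.numeric(v > 45)
                else stats::plogis((v - 45) / params$tau)
    if (stats::runif(1) < p_incong) "incongruent" else "congruent"
  })
}

#' Memory-task response
#'
#' Correct with probability `memory_accuracy`; `memory_accuracy = 0.5` is a
#' uniform-random choice between the two labelled boxes (the chance level of
#' the two-alternative task).
#'
#' @param params A [responderParams()].
#' @param seed Integer seed.
#' @return `"correct"` or `"incorrect"`.
#' @export
memoryResponse <- function(params, seed = 1L) {
  stopifnot(inherits(params, "responder_params"))
  with_seed(seed,
            if (stats::runif(1) < params$memory_accuracy) "correct"
            else "incorrect")
}

# --- synthetic model-trial stimuli ------------------------------------------

# Noisy grating at stripe orientation theta (degrees): baseline + amplitude *
# cos(2 pi u / lambda) + N(0, noise_sd) per pixel, u along the wavevector.
noisy_grating <- function(dims, theta, lambda, amplitude = 0.45,
                          baseline = 0.5, noise_sd = 0.12) {
  thr <- theta * pi / 180
  X <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  Y <- matrix(seq_len(dims[1]), dims[1], dims[2])
  u <- X * sin(thr) + Y * cos(thr)
  g <- baseline + amplitude * cos(2 * pi * u / lambda)
  g + matrix(stats::rnorm(prod(dims), 0, noise_sd), dims[1], dims[2])
}

#' Generate a synthetic model-trial stimulus with controlled cue content
#'
#' Builds one [modelTrialInput()] directly from noisy oriented gratings (no
#' scene rendering): the image snapshot carries orientation `theta_image`,
#' the depth snapshot `theta_object`, and the probe-present snapshot
#' `theta_probe`, all at the analysis carrier wavelength (2% of image width)
#' with per-pixel Gaussian noise so the channelized pooled orientation
#' differences spread continuously rather than snapping to the 22.5-degree
#' channel grid. A cue-conflict trial is one where the image and object
#' orientations disagree, so the model's response depends on `w`.
#'
#' @param seed Integer seed.
#' @param conflict If `TRUE`, `theta_object` is offset from `theta_image` by
#'   a uniform 45-90 degree conflict; otherwise the cues agree.
#' @param dims Map dimensions (default `c(100, 90)`).
#' @param noise_sd Pixel noise SD of the gratings.
#' @return A `"model_trial_input"` with attributes `theta_image`,
#'   `theta_object`, `theta_probe`, `conflict`.
#' @export
makeSyntheticTrial <- function(seed, conflict = TRUE, dims = c(100L, 90L),
                               noise_sd = 0.12) {
  with_seed(seed, {
    theta_i <- stats::runif(1, 0, 180)
    theta_o <- if (conflict) {
      fold180(theta_i + sample(c(-1, 1), 1) * stats::runif(1, 45, 90))
    } else {
      fold180(theta_i + stats::rnorm(1, 0, 3))
    }
    theta_p <- fold180(theta_i + sample(c(0, 90), 1) + stats::rnorm(1, 0, 8))
    lambda <- 0.02 * dims[2]
    M_image <- noisy_grating(dims, theta_i, lambda, noise_sd = noise_sd)
    M_depth <- 2 + 2 * noisy_grating(dims, theta_o, lambda,
                                     noise_sd = noise_sd)
    M_probe <- noisy_grating(dims, theta_p, lambda, noise_sd = noise_sd)
    tr <- modelTrialInput(M_image, M_depth, M_probe,
                          probe_point = c(round(dims[1] / 2),
                                          round(dims[2] / 2)))
    attr(tr, "theta_image") <- theta_i
    attr(tr, "theta_object") <- theta_o
    attr(tr, "theta_probe") <- theta_p
    attr(tr, "conflict") <- conflict
    tr
  })
}

#' Pool of synthetic trials with precomputed cue differences
#'
#' Convenience generator for model-fitting studies: `n` synthetic stimuli
#' with the requested cue-conflict fraction, each carrying its pooled
#' image/object orientation differences so that responder simulation and
#' weight fitting run without re-filtering the maps.
#'
#' @param n Number of stimuli.
#' @param conflict_fraction Fraction of cue-conflict stimuli.
#' @param seed Integer seed.
#' @param dims Map dimensions.
#' @return A list with `trials` (list of `"model_trial_input"`) and `diffs`
#'   (list of pooled difference vectors, `NULL` where excluded).
#' @export
syntheticTrialPool <- function(n, conflict_fraction = 0.5, seed = 1L,
                               dims = c(100L, 90L)) {
  stopifnot(n >= 1, conflict_fraction >= 0, conflict_fraction <= 1)
  n_conf <- round(n * conflict_fraction)
  conflict <- c(rep(TRUE, n_conf), rep(FALSE, n - n_conf))
  trials <- lapply(seq_len(n), function(i) {
    makeSyntheticTrial(deriveSeed(seed, i), conflict = conflict[i],
                       dims = dims)
  })
  list(trials = trials, diffs = lapply(trials, pooled_cue_diffs))
}
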