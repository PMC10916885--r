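# Signal-detection analysis of the trial log: d-prime and criterion from
# hit/false-alarm probabilities, the diagonal shift d' - c, differential
# sensitivity between insertion types, sliding-window time courses,
# early/late splits, and configuration comparison statistics.
#
# Convention: congruent trials are "signal"; a hit is responding congruent
# on a congruent trial, a false alarm is responding congruent on an
# incongruent trial, so a lax criterion (c < 0) is an inclination toward
# reporting congruent. Invalid responses are excluded everywhere.

#' Signal-detection metrics from response counts
#'
#' `d' = qnorm(p_hit) - qnorm(p_fa)` and
#' `c = -(qnorm(p_hit) + qnorm(p_fa)) / 2`, with extreme proportions (0 or 1)
#' corrected by the 1/(2N) rule before the inverse-normal transform. The
#' diagonal shift `d' - c` projects the (bias, sensitivity) point onto the
#' negative diagonal.
#'
#' @param n_hit,n_miss Counts on congruent (signal) trials.
#' @param n_fa,n_cr Counts on incongruent (noise) trials.
#' @return A list of class `"sdt_summary"`: `n_signal`, `n_noise`, `p_hit`,
#'   `p_fa`, `dprime`, `criterion`, `diagonal_shift`.
#' @export
sdtMetrics <- function(n_hit, n_miss, n_fa, n_cr) {
  stopifnot(n_hit >= 0, n_miss >= 0, n_fa >= 0, n_cr >= 0)
  n_signal <- n_hit + n_miss
  n_noise <- n_fa + n_cr
  if (n_signal == 0 || n_noise == 0) {
    stop("sdtMetrics requires at least one signal and one noise trial")
  }
  correct_extreme <- function(p, n) {
    if (p <= 0) 1 / (2 * n) else if (p >= 1) 1 - 1 / (2 * n) else p
  }
  p_hit <- correct_extreme(n_hit / n_signal, n_signal)
  p_fa <- correct_extreme(n_fa / n_noise, n_noise)
  zh <- stats::qnorm(p_hit)
  zf <- stats::qnorm(p_fa)
  structure(list(n_signal = n_signal, n_noise = n_noise,
                 p_hit = p_hit, p_fa = p_fa,
                 dprime = zh - zf,
                 criterion = -(zh + zf) / 2,
                 diagonal_shift = (zh - zf) + (zh + zf) / 2),
            class = "sdt_summary")
}

#' @export
print.sdt_summary <- function(x, ...) {
  cat(sprintf("<sdt_summary> d' = %.3f, c = %.3f, shift = %.3f (N = %d + %d)\n",
              x$dprime, x$criterion, x$diagonal_shift, x$n_signal, x$n_noise))
  invisible(x)
}

# SDT summary from a trial-log subset (valid trials only); NULL if the
# subset lacks signal or noise trials.
sdt_from_trials <- function(trials) {
  tr <- trials[trials$response %in% c("congruent", "incongruent"), ,
               drop = FALSE]
  n_hit <- sum(tr$congruent & tr$response == "congruent")
  n_miss <- sum(tr$congruent & tr$response == "incongruent")
  n_fa <- sum(!tr$congruent & tr$response == "congruent")
  n_cr <- sum(!tr$congruent & tr$response == "incongruent")
  if (n_hit + n_miss == 0 || n_fa + n_cr == 0) return(NULL)
  sdtMetrics(n_hit, n_miss, n_fa, n_cr)
}

# Count of valid trials in a trial-log subset.
n_valid <- function(trials) {
  sum(trials$response %in% c("congruent", "incongruent"))
}

#' Differential sensitivity between insertion types
#'
#' `d'(image-driven) - d'(object-driven)` over the valid trials of a subset.
#' If either insertion type has fewer than `min_trials` valid trials (or
#' lacks one congruency class) an insufficient-data marker is returned
#' rather than an error.
#'
#' @param trials Trial-log data.frame subset.
#' @param min_trials Minimum valid trials per insertion type (default 10).
#' @return A list of class `"delta_sensitivity"`: `delta` (NA when
#'   insufficient), `insufficient`, `dprime_image`, `dprime_object`,
#'   `n_image`, `n_object`.
#' @export
differentialSensitivity <- function(trials, min_trials = 10L) {
  img <- trials[trials$insertion_type == "image_driven", , drop = FALSE]
  obj <- trials[trials$insertion_type == "object_driven", , drop = FALSE]
  ni <- n_valid(img)
  no <- n_valid(obj)
  si <- if (ni >= min_trials) sdt_from_trials(img) else NULL
  so <- if (no >= min_trials) sdt_from_trials(obj) else NULL
  if (is.null(si) || is.null(so)) {
    return(structure(list(delta = NA_real_, insufficient = TRUE,
                          dprime_image = NA_real_, dprime_object = NA_real_,
                          n_image = ni, n_object = no),
                     class = "delta_sensitivity"))
  }
  structure(list(delta = si$dprime - so$dprime, insufficient = FALSE,
                 dprime_image = si$dprime, dprime_object = so$dprime,
                 n_image = ni, n_object = no),
            class = "delta_sensitivity")
}

#' Sliding-window time course of differential sensitivity
#'
#' For each window centre, trials with `t_probe` inside the centred window
#' are pooled within observer (across blocks of the same configuration,
#' which the caller selects), differential sensitivity is computed per
#' observer, and the across-observer mean and SEM are reported. Centres
#' where fewer than two observers contribute are flagged
#' (`sem_uncomputable`), mirroring open plotting symbols for insufficient
#' data.
#'
#' @param trials Trial-log data.frame (one shadow configuration).
#' @param window Window length in seconds (default 120).
#' @param step Centre step in seconds (default 10).
#' @param block_duration Block duration bounding the centres (default 300).
#' @param min_trials Per-type valid-trial threshold passed down.
#' @return A data.frame of class `"time_course"`: `center`,
#'   `delta_sensitivity`, `sem`, `n_observers`, `sem_uncomputable`; window
#'   and step stored as attributes.
#' @export
slidingTimecourse <- function(trials, window = 120, step = 10,
                              block_duration = 300, min_trials = 10L) {
  stopifnot(window > 0, step > 0)
  lo <- window / 2
  hi <- block_duration - window / 2
  centers <- if (hi < lo) block_duration / 2 else seq(lo, hi, by = step)
  observers <- unique(trials$observer_id)
  rows <- lapply(centers, function(ct) {
    sel <- trials$t_probe >= ct - window / 2 & trials$t_probe <= ct + window / 2
    sub <- trials[sel, , drop = FALSE]
    deltas <- vapply(observers, function(obs) {
      d <- differentialSensitivity(sub[sub$observer_id == obs, , drop = FALSE],
                                   min_trials = min_trials)
      d$delta
    }, numeric(1))
    deltas <- deltas[!is.na(deltas)]
    n <- length(deltas)
    data.frame(center = ct,
               delta_sensitivity = if (n) mean(deltas) else NA_real_,
               sem = if (n >= 2) stats::sd(deltas) / sqrt(n) else NA_real_,
               n_observers = n,
               sem_uncomputable = n < 2)
  })
  out <- do.call(rbind, rows)
  attr(out, "window") <- window
  attr(out, "step") <- step
  class(out) <- c("time_course", "data.frame")
  out
}

#' Early/late split of differential sensitivity
#'
#' Splits each observer's trials at the block midpoint, computes
#' differential sensitivity per observer and half, and reports 95%
#' confidence intervals across observers per half.
#'
#' @param trials Trial-log data.frame (one shadow configuration).
#' @param midpoint Split time in seconds (default 150, half of a 5-min
#'   block).
#' @param min_trials Per-type valid-trial threshold.
#' @return A list of class `"split_half"`: `per_observer` (data.frame
#'   observer/half/delta) and `ci` (data.frame half/mean/lower/upper/n).
#' @export
splitHalfSummary <- function(trials, midpoint = 150, min_trials = 10L) {
  observers <- unique(trials$observer_id)
  per <- do.call(rbind, lapply(observers, function(obs) {
    sub <- trials[trials$observer_id == obs, , drop = FALSE]
    early <- differentialSensitivity(
      sub[sub$t_probe < midpoint, , drop = FALSE], min_trials)
    late <- differentialSensitivity(
      sub[sub$t_probe >= midpoint, , drop = FALSE], min_trials)
    data.frame(observer = obs, half = c("early", "late"),
               delta = c(early$delta, late$delta),
               stringsAsFactors = FALSE)
  }))
  ci <- do.call(rbind, lapply(c("early", "late"), function(h) {
    x <- per$delta[per$half == h]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n >= 2) {
      m <- mean(x)
      half_width <- stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
      data.frame(half = h, mean = m, lower = m - half_width,
                 upper = m + half_width, n = n)
    } else {
      data.frame(half = h, mean = if (n) mean(x) else NA_real_,
                 lower = NA_real_, upper = NA_real_, n = n)
    }
  }))
  structure(list(per_observer = per, ci = ci), class = "split_half")
}

#' Per-observer diagonal shifts by configuration and insertion type
#'
#' Convenience extractor feeding [configComparisonStats()]: for every
#' observer x shadow mode x insertion type cell, the diagonal shift
#' `d' - c` of the pooled valid trials.
#'
#' @param trials Master trial-log data.frame.
#' @return A data.frame with `observer`, `config`, `insertion_type`,
#'   `shift`.
#' @export
diagonalShifts <- function(trials) {
  cells <- expand.grid(observer = unique(trials$observer_id),
                       config = unique(trials$shadow_mode),
                       insertion_type = c("image_driven", "object_driven"),
                       stringsAsFactors = FALSE)
  cells$shift <- vapply(seq_len(nrow(cells)), function(i) {
    sub <- trials[trials$observer_id == cells$observer[i] &
                    trials$shadow_mode == cells$config[i] &
                    trials$insertion_type == cells$insertion_type[i], ,
                  drop = FALSE]
    s <- sdt_from_trials(sub)
    if (is.null(s)) NA_real_ else s$diagonal_shift
  }, numeric(1))
  cells
}

#' Configuration comparison statistics
#'
#' Paired Wilcoxon signed-rank tests of image-driven versus object-driven
#' diagonal shifts, separately per shadow configuration, with a 3x
#' Bonferroni correction (capped at 1). A two-way repeated-measures ANOVA
#' (configuration x insertion type, observer as the error stratum) is
#' reported alongside when more than one configuration is present.
#'
#' @param shifts Data.frame as returned by [diagonalShifts()].
#' @param bonferroni Correction factor (default 3, one per shadow
#'   configuration).
#' @return A list of class `"config_comparison"`: `wilcoxon` (data.frame
#'   config/n/statistic/p_raw/p_corrected) and `anova` (summary or NULL).
#' @export
configComparisonStats <- function(shifts, bonferroni = 3) {
  stopifnot(all(c("observer", "config", "insertion_type", "shift") %in%
                  names(shifts)))
  configs <- unique(shifts$config)
  wil <- do.call(rbind, lapply(configs, function(cf) {
    sub <- shifts[shifts$config == cf, , drop = FALSE]
    img <- sub$shift[sub$insertion_type == "image_driven"][
      order(sub$observer[sub$insertion_type == "image_driven"])]
    obj <- sub$shift[sub$insertion_type == "object_driven"][
      order(sub$observer[sub$insertion_type == "object_driven"])]
    ok <- !is.na(img) & !is.na(obj)
    if (sum(ok) < 5) {
      stop("configComparisonStats requires at least 5 paired observers per ",
           "configuration (", cf, " has ", sum(ok), ")")
    }
    d <- img[ok] - obj[ok]
    if (all(d == 0)) {
      # no nonzero differences: the signed-rank statistic is undefined and
      # there is no evidence against the null
      stat <- NA_real_
      p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(img[ok], obj[ok],
                                                paired = TRUE))
      stat <- unname(wt$statistic)
      p <- wt$p.value
    }
    data.frame(config = cf, n = sum(ok), statistic = stat, p_raw = p,
               p_corrected = min(1, bonferroni * p),
               stringsAsFactors = FALSE)
  }))
  anova_fit <- NULL
  if (length(configs) > 1) {
    dat <- shifts[!is.na(shifts$shift), , drop = FALSE]
    dat$observer <- factor(dat$observer)
    dat$config <- factor(dat$config)
    dat$insertion_type <- factor(dat$insertion_type)
    anova_fit <- summary(stats::aov(
      shift ~ config * insertion_type +
        Error(observer / (config * insertion_type)),
      data = dat))
  }
  structure(list(wilcoxon = wil, anova = anova_fit),
            class = "config_comparison")
}

#' @export
print.config_comparison <- function(x, ...) {
  cat("<config_comparison> paired Wilcoxon (image vs object diagonal shift):\n")
  print(x$wilcoxon, row.names = FALSE)
  invisible(x)
}
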