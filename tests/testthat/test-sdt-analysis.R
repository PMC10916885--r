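# Construct synthetic trial-log data frames directly; SDT analysis consumes
# the log, not the simulator.
make_log <- function(observer, type, congruent, response,
                     t_probe = seq_along(congruent) * 3,
                     mode = "reliable") {
  n <- length(congruent)
  data.frame(observer_id = observer, block_id = paste0(observer, "_b1"),
             trial_index = seq_len(n), t_probe = t_probe,
             shadow_mode = mode, light_azimuth = 0,
             insertion_type = rep_len(type, n),
             point_row = 50L, point_col = 45L, local_orientation = 0,
             congruent = congruent, response = response,
             correct = ifelse(response == "invalid", NA,
                              response == ifelse(congruent, "congruent",
                                                 "incongruent")),
             consecutive_errors_after = 0L, scrambled_after = FALSE,
             stringsAsFactors = FALSE)
}

# Binary-mixture log with a target hit/fa structure per insertion type.
mixture_log <- function(observer, n_per_type, p_hit, p_fa, seed,
                        types = c("image_driven", "object_driven")) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_along(types), function(k) {
      congruent <- rep(c(TRUE, FALSE), each = n_per_type / 2)
      p <- ifelse(congruent, p_hit[k], p_fa[k])
      response <- ifelse(stats::runif(n_per_type) < p, "congruent",
                         "incongruent")
      make_log(observer, types[k], congruent, response)
    }))
  })
}

test_that("SDT closed forms match the inverse-normal oracle", {
  s <- sdtMetrics(25, 25, 25, 25)
  expect_equal(s$dprime, 0)
  expect_equal(s$criterion, 0)
  s2 <- sdtMetrics(84, 16, 16, 84)
  expect_equal(s2$dprime, stats::qnorm(0.84) - stats::qnorm(0.16),
               tolerance = 1e-12)
  expect_equal(s2$criterion, 0, tolerance = 1e-12)
  expect_equal(s2$diagonal_shift, s2$dprime - s2$criterion)
  # extreme proportions are corrected by 1/(2N)
  s3 <- sdtMetrics(30, 20, 0, 50)
  expect_equal(s3$p_fa, 0.01)
  s4 <- sdtMetrics(50, 0, 10, 40)
  expect_equal(s4$p_hit, 1 - 1 / 100)
  expect_error(sdtMetrics(0, 0, 5, 5), "signal")
})

test_that("d-prime is antisymmetric and the diagonal shift is linear", {
  a <- sdtMetrics(70, 30, 20, 80)
  # swapping hit and fa proportions flips d' (and leaves c unchanged)
  b <- sdtMetrics(20, 80, 70, 30)
  expect_equal(a$dprime, -b$dprime)
  expect_equal(a$criterion, b$criterion)
  # relabelling the two responses (complementing both proportions) flips
  # both d' and c
  cc <- sdtMetrics(30, 70, 80, 20)
  expect_equal(a$dprime, -cc$dprime)
  expect_equal(a$criterion, -cc$criterion)
  # shift responds linearly: a change (delta_d, delta_c) moves it by
  # delta_d - delta_c
  zh <- stats::qnorm(a$p_hit); zf <- stats::qnorm(a$p_fa)
  delta <- 0.3
  shift_at <- function(zh, zf) (zh - zf) + (zh + zf) / 2
  # d' up by 2*delta, c unchanged -> shift up by 2*delta
  expect_equal(shift_at(zh + delta, zf - delta) - a$diagonal_shift,
               2 * delta, tolerance = 1e-12)
  # d' unchanged, c down by delta -> shift up by delta
  expect_equal(shift_at(zh + delta, zf + delta) - a$diagonal_shift,
               delta, tolerance = 1e-12)
})

test_that("differential sensitivity composes per-type d-primes and flags
          insufficient data", {
  log <- mixture_log("o1", 200, p_hit = c(0.9, 0.75), p_fa = c(0.2, 0.3),
                     seed = 1)
  ds <- differentialSensitivity(log)
  img <- log[log$insertion_type == "image_driven", ]
  obj <- log[log$insertion_type == "object_driven", ]
  d_img <- sdtMetrics(sum(img$congruent & img$response == "congruent"),
                      sum(img$congruent & img$response == "incongruent"),
                      sum(!img$congruent & img$response == "congruent"),
                      sum(!img$congruent & img$response == "incongruent"))
  d_obj <- sdtMetrics(sum(obj$congruent & obj$response == "congruent"),
                      sum(obj$congruent & obj$response == "incongruent"),
                      sum(!obj$congruent & obj$response == "congruent"),
                      sum(!obj$congruent & obj$response == "incongruent"))
  expect_equal(ds$delta, d_img$dprime - d_obj$dprime)
  expect_false(ds$insufficient)
  # identical response statistics across types -> zero difference
  sym <- rbind(make_log("o1", "image_driven", rep(c(TRUE, FALSE), 20),
                        rep(c("congruent", "incongruent"), 20)),
               make_log("o1", "object_driven", rep(c(TRUE, FALSE), 20),
                        rep(c("congruent", "incongruent"), 20)))
  expect_equal(differentialSensitivity(sym)$delta, 0)
  # missing type -> marker, not an error
  only_img <- make_log("o1", "image_driven", rep(c(TRUE, FALSE), 20),
                       rep(c("congruent", "incongruent"), 20))
  m <- differentialSensitivity(only_img)
  expect_true(m$insufficient)
  expect_true(is.na(m$delta))
})

test_that("invalid responses are excluded from every analysis", {
  log <- mixture_log("o1", 200, p_hit = c(0.9, 0.9), p_fa = c(0.1, 0.1),
                     seed = 2)
  ds0 <- differentialSensitivity(log)
  # appending invalid trials changes nothing
  inv <- make_log("o1", "image_driven", rep(c(TRUE, FALSE), 30),
                  rep("invalid", 60))
  expect_equal(differentialSensitivity(rbind(log, inv))$delta, ds0$delta)
  s <- sdt_from_trials <- shadowcue:::sdt_from_trials(rbind(log, inv))
  expect_equal(s$n_signal + s$n_noise, 400)
})

test_that("a stationary responder yields a flat time course and a window
          covering the block reproduces the block-level value", {
  logs <- do.call(rbind, lapply(sprintf("o%02d", 1:8), function(obs) {
    mixture_log(obs, 300, p_hit = c(0.85, 0.85), p_fa = c(0.15, 0.15),
                seed = match(obs, sprintf("o%02d", 1:8)),
                types = c("image_driven", "object_driven"))
  }))
  logs$t_probe <- withr::with_seed(9, stats::runif(nrow(logs), 0, 300))
  tc <- slidingTimecourse(logs, window = 120, step = 30)
  expect_true(all(!tc$sem_uncomputable))
  expect_true(all(abs(tc$delta_sensitivity) < 0.6))
  # degenerate window = one centre carrying the pooled block-level estimate
  tc_all <- slidingTimecourse(logs, window = 600, step = 600,
                              block_duration = 300)
  per_obs <- vapply(unique(logs$observer_id), function(o) {
    differentialSensitivity(logs[logs$observer_id == o, ])$delta
  }, numeric(1))
  expect_equal(nrow(tc_all), 1)
  expect_equal(tc_all$delta_sensitivity, mean(per_obs), tolerance = 1e-12)
  # consistency: step = window reproduces disjoint-bin pooling
  tc_dis <- slidingTimecourse(logs, window = 100, step = 100)
  for (i in seq_len(nrow(tc_dis))) {
    sel <- logs$t_probe >= tc_dis$center[i] - 50 &
      logs$t_probe <= tc_dis$center[i] + 50
    per <- vapply(unique(logs$observer_id), function(o) {
      differentialSensitivity(logs[sel & logs$observer_id == o, ])$delta
    }, numeric(1))
    expect_equal(tc_dis$delta_sensitivity[i], mean(per, na.rm = TRUE))
  }
})

test_that("early/late splits separate a drift with onset after midpoint", {
  # early half balanced, late half image-favouring, several observers
  logs <- do.call(rbind, lapply(1:6, function(k) {
    obs <- sprintf("o%02d", k)
    early <- mixture_log(obs, 200, p_hit = c(0.8, 0.8), p_fa = c(0.2, 0.2),
                         seed = 100 + k)
    early$t_probe <- withr::with_seed(200 + k,
                                      stats::runif(nrow(early), 0, 150))
    late <- mixture_log(obs, 200, p_hit = c(0.95, 0.7), p_fa = c(0.05, 0.3),
                        seed = 300 + k)
    late$t_probe <- withr::with_seed(400 + k,
                                     stats::runif(nrow(late), 150, 300))
    rbind(early, late)
  }))
  sh <- splitHalfSummary(logs, midpoint = 150)
  early_ci <- sh$ci[sh$ci$half == "early", ]
  late_ci <- sh$ci[sh$ci$half == "late", ]
  expect_gt(late_ci$mean, early_ci$mean)
  expect_gt(late_ci$lower, 0)
  expect_true(early_ci$lower < 0 && early_ci$upper > 0)
  expect_equal(nrow(sh$per_observer), 12)
})

test_that("configuration comparisons flag a planted separation and respect
          the Bonferroni cap", {
  observers <- sprintf("o%02d", 1:11)
  shifts_null <- do.call(rbind, lapply(observers, function(o) {
    data.frame(observer = o, config = "reliable",
               insertion_type = c("image_driven", "object_driven"),
               shift = c(1.2, 1.2))
  }))
  res_null <- configComparisonStats(shifts_null, bonferroni = 3)
  expect_equal(res_null$wilcoxon$p_corrected, 1)
  # strong separation: all observers positive
  withr::with_seed(5, {
    shifts_sep <- do.call(rbind, lapply(observers, function(o) {
      base <- stats::rnorm(1, 1, 0.2)
      data.frame(observer = o, config = "unreliable",
                 insertion_type = c("image_driven", "object_driven"),
                 shift = c(base + stats::runif(1, 0.3, 0.8), base))
    }))
  })
  res_sep <- configComparisonStats(shifts_sep, bonferroni = 3)
  expect_lt(res_sep$wilcoxon$p_corrected, 0.05)
  # permuting the type labels destroys the effect
  perm <- shifts_sep
  withr::with_seed(11, {
    for (o in observers) {
      if (stats::runif(1) < 0.5) {
        i <- perm$observer == o
        perm$shift[i] <- rev(perm$shift[i])
      }
    }
  })
  res_perm <- configComparisonStats(perm, bonferroni = 3)
  expect_gt(res_perm$wilcoxon$p_corrected, 0.05)
  # too few observers is an error
  expect_error(configComparisonStats(shifts_sep[1:8, ]), "at least 5")
})

test_that("diagonal shifts table covers every cell and feeds the ANOVA", {
  logs <- do.call(rbind, lapply(sprintf("o%02d", 1:6), function(obs) {
    rbind(mixture_log(obs, 120, p_hit = c(0.9, 0.7), p_fa = c(0.1, 0.25),
                      seed = match(obs, sprintf("o%02d", 1:6))),
          {
            l2 <- mixture_log(obs, 120, p_hit = c(0.8, 0.8),
                              p_fa = c(0.2, 0.2),
                              seed = 50 + match(obs, sprintf("o%02d", 1:6)))
            l2$shadow_mode <- "absent"
            l2
          })
  }))
  sh <- diagonalShifts(logs)
  expect_equal(nrow(sh), 6 * 2 * 2)
  expect_false(anyNA(sh$shift))
  res <- configComparisonStats(sh, bonferroni = 3)
  expect_s3_class(res, "config_comparison")
  expect_false(is.null(res$anova))
  expect_equal(nrow(res$wilcoxon), 2)
})
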