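# Cohort simulation used by the end-to-end acceptance test: a "reliable"
# cohort of stationary responders (w = 0.45) versus an "unreliable" cohort
# whose weight drifts linearly from 0.45 to 0.75 across the block.
simulate_cohorts <- function(n_obs = 11, blocks = 1, seed0 = 400) {
  out <- list()
  for (drift in c(FALSE, TRUE)) {
    rp <- if (drift) {
      responderParams(0.45, tau = 8,
                      w_drift = list(w_start = 0.45, w_end = 0.75,
                                     onset_time = 0))
    } else {
      responderParams(0.45, tau = 8)
    }
    for (o in seq_len(n_obs)) {
      for (b in seq_len(blocks)) {
        cfg <- blockConfig(if (drift) "unreliable" else "reliable",
                           observer_id = sprintf("obs%02d", o),
                           block_id = sprintf("obs%02d_b%d_%d", o, b, drift))
        bl <- runBlock(cfg, rp,
                       deriveSeed(seed0 + o * 17 + b, if (drift) 1 else 2))
        out[[length(out) + 1]] <- bl$trials
      }
    }
  }
  do.call(rbind, out)
}
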