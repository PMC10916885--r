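# Block and session orchestration: trial timing, shadow schedules,
# insertion-type and congruency randomization, probe synthesis/insertion,
# responder queries, the consecutive-error scrambling rule, the end-of-block
# memory displacement, and scoring.

#' Block configuration
#'
#' @param shadow_mode `"reliable"`, `"unreliable"`, or `"absent"`.
#' @param observer_id,block_id Identifiers recorded in the trial log.
#' @param n_trials Sensory trials per block (default 100).
#' @param block_duration Nominal block duration in seconds (default 300;
#'   drives the responder's weight schedule).
#' @param iti_range Inter-trial interval range in seconds (default
#'   `c(2.0, 3.6)`, drawn uniformly).
#' @param res Snapshot resolution `c(rows, cols)`.
#' @param noise_max Driver-map insertion noise bound (see
#'   [selectInsertionPoint()]).
#' @param noise_mean,noise_sd,signal_contrast Probe contrast parameters.
#' @param room_params A [roomParams()] list.
#' @return A list of class `"block_config"`.
#' @export
blockConfig <- function(shadow_mode = c("reliable", "unreliable", "absent"),
                        observer_id = "obs1", block_id = "block1",
                        n_trials = 100L, block_duration = 300,
                        iti_range = c(2.0, 3.6), res = c(100L, 90L),
                        noise_max = 0.2, noise_mean = 0.03, noise_sd = 0.01,
                        signal_contrast = 0.40,
                        room_params = roomParams()) {
  shadow_mode <- match.arg(shadow_mode)
  structure(list(shadow_mode = shadow_mode, observer_id = observer_id,
                 block_id = block_id, n_trials = as.integer(n_trials),
                 block_duration = block_duration, iti_range = iti_range,
                 res = as.integer(res), noise_max = noise_max,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 signal_contrast = signal_contrast,
                 room_params = room_params),
            class = "block_config")
}

#' Block score
#'
#' Each correct sensory discrimination is one point; the total is doubled by
#' a correct memory response and halved by an incorrect one.
#'
#' @param n_correct Number of correct sensory responses.
#' @param memory_correct Logical memory-task outcome.
#' @return The block score (points).
#' @export
blockScore <- function(n_correct, memory_correct) {
  stopifnot(n_correct >= 0)
  if (isTRUE(memory_correct)) n_correct * 2 else n_correct / 2
}

# 8-bit capture emulation for the observer model's depth input: min-max
# normalized and quantized to 256 levels, like a rendered depth image grabbed
# from the display pipeline. The quantization staircase gives smooth depth
# ramps a well-defined bandpass orientation structure (isodepth contours);
# metric depth stays in use everywhere else (geometry, edge maps, file IO).
quantize_capture <- function(depth, levels = 256L) {
  rng <- range(depth)
  if (rng[2] - rng[1] < 1e-12) return(matrix(0, nrow(depth), ncol(depth)))
  round((depth - rng[1]) / (rng[2] - rng[1]) * (levels - 1L)) / (levels - 1L)
}

# Probe patch half-width (px) implied by a block config's geometry; must
# match renderProbe's support so selected points always admit the patch.
patch_half <- function(config, diameter_deg = 3, window_sd_arcmin = 15) {
  px_per_degree <- config$res[2] / 45
  ceiling((diameter_deg / 2 + 4 * window_sd_arcmin / 60) * px_per_degree) + 1L
}

# Zero-row trial-record data.frame with the canonical column set.
empty_trial_df <- function() {
  data.frame(observer_id = character(0), block_id = character(0),
             trial_index = integer(0), t_probe = numeric(0),
             shadow_mode = character(0), light_azimuth = numeric(0),
             insertion_type = character(0), point_row = integer(0),
             point_col = integer(0), local_orientation = numeric(0),
             congruent = logical(0), response = character(0),
             correct = logical(0), consecutive_errors_after = integer(0),
             scrambled_after = logical(0), stringsAsFactors = FALSE)
}

# Displace one randomly selected instantiated box to the spare (first
# non-instantiated) spec's location, preserving its size and rotation.
# Returns list(room, moved_index, target_index).
displace_box <- function(room, seed) {
  inst <- which(vapply(room$boxes, function(b) b$instantiated, logical(1)))
  spare <- which(!vapply(room$boxes, function(b) b$instantiated, logical(1)))
  if (!length(spare)) stop("no spare box specification to displace onto")
  moved <- with_seed(seed, sample(inst, 1))
  target <- spare[1]
  room$boxes[[moved]]$center_xy <- room$boxes[[target]]$center_xy
  list(room = room, moved_index = moved, target_index = target)
}

#' Run one experimental block
#'
#' For each of `n_trials` trials: advance the clock by a uniform inter-trial
#' interval, advance the camera walk, draw the light state for the block's
#' shadow mode (one azimuth per block when reliable, a fresh azimuth before
#' every probe when unreliable), render the aligned image/depth snapshot,
#' compute both Sobel edge maps, draw the insertion type (image/object, p =
#' 0.5) and run the insertion algorithm, draw the congruency label (p =
#' 0.5), synthesize and composite the probe, and query the responder. A
#' correct response resets the consecutive-error counter; four consecutive
#' incorrect/invalid responses scramble the room (all boxes reseated) for
#' the following trial. After the last trial one instantiated box is
#' displaced to the spare specification's location (size and rotation
#' preserved), the memory response is drawn, and the score is computed.
#' Fully deterministic given the seed.
#'
#' @param config A [blockConfig()].
#' @param responder A [responderParams()].
#' @param seed Integer block seed.
#' @return A list of class `"block_log"`: `trials` (data.frame of trial
#'   records), `room_history` (initial room plus each scramble),
#'   `memory_outcome`, `moved_box`, `score`, `config`.
#' @export
runBlock <- function(config, responder, seed) {
  stopifnot(inherits(config, "block_config"),
            inherits(responder, "responder_params"))
  room <- generateRoom(deriveSeed(seed, 1L), config$room_params)
  room_history <- list(room)
  walk_seed <- deriveSeed(seed, 2L)
  light_seed <- deriveSeed(seed, 3L)
  itis <- with_seed(deriveSeed(seed, 4L),
                    stats::runif(config$n_trials, config$iti_range[1],
                                 config$iti_range[2]))
  t_probe <- cumsum(itis)
  rec <- vector("list", config$n_trials)
  consecutive <- 0L
  for (i in seq_len(config$n_trials)) {
    tseed <- deriveSeed(seed, 100L + i)
    t <- t_probe[i]
    light <- lightSchedule(config$shadow_mode, trial_index = i,
                           seed = light_seed)
    draws <- with_seed(deriveSeed(tseed, 1L), stats::runif(2))
    insertion_type <- if (draws[1] < 0.5) "image_driven" else "object_driven"
    congruent <- draws[2] < 0.5
    # A view hugging a featureless surface cannot support insertion; let the
    # walk advance in 0.25 s steps (deterministically) until it can, as a
    # moving observer would.
    ins <- NULL
    for (attempt in 0:11) {
      t <- t_probe[i] + 0.25 * attempt
      ins <- tryCatch({
        pose <- samplePose(room, t, walk_seed)
        snap <- renderSnapshot(room, pose, light, res = config$res)
        image_edges <- sobelEdgeMap(snap$image)
        object_edges <- sobelEdgeMap(snap$depth)
        selectInsertionPoint(image_edges, object_edges, insertion_type,
                             seed = deriveSeed(tseed, 2L),
                             noise_max = config$noise_max,
                             support_margin = patch_half(config),
                             require_defined_orientation = TRUE)
      }, error = function(e) NULL)
      if (!is.null(ins)) break
    }
    if (is.null(ins)) {
      stop("block failure: no insertable view near t = ",
           round(t_probe[i], 1), " s (observer ", config$observer_id,
           ", block ", config$block_id, ")")
    }
    spec <- makeProbeSpec(congruent, ins$local_orientation,
                          noise_mean = config$noise_mean,
                          noise_sd = config$noise_sd,
                          signal_contrast = config$signal_contrast,
                          seed = deriveSeed(tseed, 3L))
    patch <- renderProbe(spec, px_per_degree = config$res[2] / 45)
    M_probe <- compositeProbe(snap$image, patch, ins$point)
    trial <- modelTrialInput(snap$image, quantize_capture(snap$depth),
                             M_probe, ins$point)
    response <- sensoryResponse(trial, responder, t = t,
                                seed = deriveSeed(tseed, 4L),
                                block_end = config$block_duration)
    correct <- if (response == "invalid") NA else {
      response == (if (congruent) "congruent" else "incongruent")
    }
    if (isTRUE(correct)) {
      consecutive <- 0L
    } else {
      consecutive <- consecutive + 1L
    }
    scrambled <- FALSE
    if (consecutive >= 4L && i < config$n_trials) {
      room <- scrambleRoom(room, deriveSeed(tseed, 5L))
      room_history[[length(room_history) + 1L]] <- room
      consecutive <- 0L
      scrambled <- TRUE
    }
    rec[[i]] <- data.frame(
      observer_id = config$observer_id, block_id = config$block_id,
      trial_index = i, t_probe = t, shadow_mode = config$shadow_mode,
      light_azimuth = if (is.na(light$azimuth)) NA_real_ else light$azimuth,
      insertion_type = insertion_type,
      point_row = ins$point[1], point_col = ins$point[2],
      local_orientation = ins$local_orientation,
      congruent = congruent, response = response,
      correct = correct, consecutive_errors_after = consecutive,
      scrambled_after = scrambled,
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rec)
  disp <- displace_box(room, deriveSeed(seed, 5L))
  memory_outcome <- memoryResponse(responder, deriveSeed(seed, 6L))
  n_correct <- sum(trials$correct, na.rm = TRUE)
  structure(list(trials = trials, room_history = room_history,
                 memory_outcome = memory_outcome,
                 moved_box = disp$moved_index,
                 final_room = disp$room,
                 score = blockScore(n_correct, memory_outcome == "correct"),
                 config = config),
            class = "block_log")
}

#' @export
print.block_log <- function(x, ...) {
  cat(sprintf("<block_log> %s/%s: %d trials (%s), %d scrambles, memory %s, score %.1f\n",
              x$config$observer_id, x$config$block_id, nrow(x$trials),
              x$config$shadow_mode, length(x$room_history) - 1L,
              x$memory_outcome, x$score))
  invisible(x)
}

#' Run a memory-only block
#'
#' No sensory probes: the camera walks the room for a short duration
#' (default 30 s, the duration that brings memory performance off ceiling),
#' one box is displaced, and the memory response is drawn. The score
#' degenerates to the memory outcome.
#'
#' @param config A [blockConfig()]; `block_duration` is overridden by
#'   `duration`.
#' @param responder A [responderParams()].
#' @param seed Integer seed.
#' @param duration Block duration in seconds (default 30).
#' @return A `"block_log"` with zero trial records.
#' @export
runMemoryOnlyBlock <- function(config, responder, seed, duration = 30) {
  stopifnot(inherits(config, "block_config"),
            inherits(responder, "responder_params"))
  room <- generateRoom(deriveSeed(seed, 1L), config$room_params)
  disp <- displace_box(room, deriveSeed(seed, 5L))
  memory_outcome <- memoryResponse(responder, deriveSeed(seed, 6L))
  structure(list(trials = empty_trial_df(), room_history = list(room),
                 memory_outcome = memory_outcome,
                 moved_box = disp$moved_index,
                 final_room = disp$room,
                 duration = duration,
                 score = blockScore(0, memory_outcome == "correct"),
                 config = config),
            class = "block_log")
}

#' Run a multi-observer session
#'
#' Each observer runs `blocks_per_mode` blocks of every shadow mode in a
#' seeded pseudo-random (per-observer balanced shuffle) order. Responder
#' parameters may be given per mode. The concatenated trial log is returned
#' and optionally written as CSV.
#'
#' @param observers Character vector of observer ids.
#' @param responders Either one [responderParams()] used everywhere, or a
#'   named list with one entry per shadow mode.
#' @param modes Shadow modes to run.
#' @param blocks_per_mode Blocks per observer per mode.
#' @param seed Integer session seed.
#' @param config_template A [blockConfig()] supplying everything except ids
#'   and mode.
#' @param log_path Optional path for the master trial-log CSV.
#' @return A list of class `"session_log"` with `trials` (master
#'   data.frame), `blocks` (list of `"block_log"`), `block_order`.
#' @export
runSession <- function(observers, responders,
                       modes = c("reliable", "unreliable", "absent"),
                       blocks_per_mode = 1L, seed = 1L,
                       config_template = blockConfig(),
                       log_path = NULL) {
  if (inherits(responders, "responder_params")) {
    responders <- stats::setNames(rep(list(responders), length(modes)), modes)
  }
  stopifnot(all(modes %in% names(responders)))
  blocks <- list()
  order_log <- list()
  for (oi in seq_along(observers)) {
    obs <- observers[oi]
    sched <- rep(modes, each = blocks_per_mode)
    sched <- with_seed(deriveSeed(seed, 1000L + oi), sample(sched))
    order_log[[obs]] <- sched
    for (bi in seq_along(sched)) {
      cfg <- config_template
      cfg$shadow_mode <- sched[bi]
      cfg$observer_id <- obs
      cfg$block_id <- sprintf("%s_b%02d_%s", obs, bi, sched[bi])
      bl <- runBlock(cfg, responders[[sched[bi]]],
                     seed = deriveSeed(seed, 10000L + 100L * oi + bi))
      blocks[[length(blocks) + 1L]] <- bl
    }
  }
  trials <- do.call(rbind, lapply(blocks, `[[`, "trials"))
  rownames(trials) <- NULL
  if (!is.null(log_path)) writeTrialLog(trials, log_path)
  structure(list(trials = trials, blocks = blocks, block_order = order_log),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d blocks, %d trials, %d observers\n",
              length(x$blocks), nrow(x$trials),
              length(unique(x$trials$observer_id))))
  invisible(x)
}
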