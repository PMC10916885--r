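# File formats: the master trial-log CSV (round-trip exact), plain-text PGM
# snapshot maps (8-bit luminance, 16-bit millimetre depth), JSON room/probe
# serialization, and the YAML session configuration with strict key
# checking. Pixel coordinates in all files are 1-based (row, col), matching
# R matrix indexing; orientations are degrees in [0, 180).

trial_log_columns <- c(
  observer_id = "character", block_id = "character",
  trial_index = "integer", t_probe = "double", shadow_mode = "character",
  light_azimuth = "double", insertion_type = "character",
  point_row = "integer", point_col = "integer",
  local_orientation = "double", congruent = "logical",
  response = "character", correct = "logical",
  consecutive_errors_after = "integer", scrambled_after = "logical")

# Full-precision text for doubles so that write -> read is the identity.
fmt_double <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write the master trial log
#'
#' Fixed, documented header (one row per trial record); UTF-8; doubles
#' written at full precision so that [readTrialLog()] reproduces the records
#' exactly.
#'
#' @param records Trial-record data.frame (the `trials` element of a block
#'   or session log).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrialLog <- function(records, path) {
  cols <- names(trial_log_columns)
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("trial log is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- records[, cols, drop = FALSE]
  for (cc in cols) {
    out[[cc]] <- switch(trial_log_columns[[cc]],
                        double = fmt_double(out[[cc]]),
                        as.character(out[[cc]]))
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a master trial log
#'
#' Validates the header (a schema error names the offending column) and the
#' row contents (bad rows are rejected with their line numbers).
#'
#' @param path CSV path written by [writeTrialLog()].
#' @return Trial-record data.frame.
#' @export
readTrialLog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  cols <- names(trial_log_columns)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("trial log schema mismatch: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), cols)
  if (length(extra)) {
    stop("trial log schema mismatch: unknown column(s) ",
         paste(extra, collapse = ", "))
  }
  df <- df[, cols, drop = FALSE]
  if (!nrow(df)) return(empty_trial_df())
  parse_col <- function(x, type) {
    switch(type,
           character = x,
           integer = suppressWarnings(as.integer(x)),
           double = suppressWarnings(as.numeric(ifelse(x == "NA", NA, x))),
           logical = ifelse(x == "NA", NA, x == "TRUE"))
  }
  for (cc in cols) df[[cc]] <- parse_col(df[[cc]], trial_log_columns[[cc]])
  bad <- which(is.na(df$trial_index) |
                 !(df$response %in% c("congruent", "incongruent", "invalid")) |
                 !(df$shadow_mode %in% c("reliable", "unreliable", "absent")) |
                 !(df$insertion_type %in% c("image_driven", "object_driven")))
  if (length(bad)) {
    stop("invalid trial log row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))   # +1 for the header line
  }
  df
}

#' Write a snapshot map as plain-text PGM
#'
#' Luminance maps are stored as 8-bit PGM (P2, maxval 255, values rounded
#' from [0, 1]); depth maps as 16-bit PGM (P2, maxval 65535) holding metric
#' depth in millimetres. Pixel (1,1) is the top-left map entry.
#'
#' @param map Numeric matrix (luminance in [0, 1] or depth in metres).
#' @param path Output path.
#' @param type `"luminance"` or `"depth"`.
#' @return `path`, invisibly.
#' @export
writeMap <- function(map, path, type = c("luminance", "depth")) {
  type <- match.arg(type)
  stopifnot(is.matrix(map))
  if (type == "luminance") {
    stopifnot(all(map >= 0), all(map <= 1))
    vals <- round(map * 255)
    maxval <- 255L
  } else {
    stopifnot(all(map >= 0))
    vals <- round(map * 1000)
    if (any(vals > 65535)) stop("depth exceeds the 65.535 m PGM range")
    maxval <- 65535L
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(map), nrow(map)), as.character(maxval)), con)
  write(t(vals), con, ncolumns = ncol(map))
  invisible(path)
}

#' Read a plain-text PGM snapshot map
#'
#' @param path PGM (P2) path written by [writeMap()].
#' @param type `"luminance"` (rescaled to [0, 1]) or `"depth"` (metres).
#' @return Numeric matrix.
#' @export
readMap <- function(path, type = c("luminance", "depth")) {
  type <- match.arg(type)
  tokens <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(tokens) < 4 || tokens[1] != "P2") {
    stop("malformed PGM: expected plain-text P2 header in ", path)
  }
  w <- as.integer(tokens[2])
  h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  vals <- suppressWarnings(as.numeric(tokens[-(1:4)]))
  if (anyNA(vals) || length(vals) != w * h) {
    stop("malformed PGM: expected ", w * h, " pixel values, found ",
         length(vals), " in ", path)
  }
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (type == "luminance") m / 255 else m / 1000
}

#' Serialize a room specification to JSON
#'
#' @param room A `"room_spec"`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or the JSON string.
#' @export
roomToJson <- function(room, path = NULL) {
  stopifnot(inherits(room, "room_spec"))
  obj <- list(room_dims = room$room_dims,
              boxes = lapply(room$boxes, function(b) {
                list(center_xy = b$center_xy, width = b$width,
                     length = b$length, height = b$height,
                     rotation = b$rotation, instantiated = b$instantiated)
              }),
              params = unclass(room$params))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Deserialize a room specification from JSON
#'
#' @param path JSON path or string produced by [roomToJson()].
#' @return A `"room_spec"`.
#' @export
roomFromJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  params <- do.call(roomParams, obj$params[names(obj$params) %in%
                                             names(formals(roomParams))])
  boxes <- lapply(obj$boxes, function(b) {
    boxSpec(b$center_xy, b$width, b$length, b$height, b$rotation,
            b$instantiated)
  })
  structure(list(room_dims = as.numeric(obj$room_dims), boxes = boxes,
                 params = params),
            class = "room_spec")
}

#' Serialize a fitted weight estimate to JSON
#'
#' @param est A `"w_estimate"` from [fitW()] or [agreementCurve()].
#' @param path Optional output path.
#' @return The path (invisibly) or the JSON string.
#' @export
wEstimateToJson <- function(est, path = NULL) {
  stopifnot(inherits(est, "w_estimate"))
  js <- jsonlite::toJSON(unclass(est), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

session_config_keys <- c("observers", "blocks_per_mode", "modes", "seed",
                         "responders", "n_trials", "block_duration",
                         "noise_max", "noise_mean", "noise_sd",
                         "signal_contrast")

#' Read and validate a session configuration
#'
#' YAML key-value file naming observers, blocks per mode, shadow modes, the
#' session seed, and per-mode responder parameter sets. Unknown keys are
#' rejected; every stochastic stage draws its seed from the single session
#' seed.
#'
#' @param path YAML path.
#' @return A validated list of class `"session_config"`.
#' @export
readSessionConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), session_config_keys)
  if (length(unknown)) {
    stop("unknown session config key(s): ", paste(unknown, collapse = ", "))
  }
  required <- c("observers", "modes", "seed", "responders")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("session config missing key(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(all(cfg$modes %in% c("reliable", "unreliable", "absent")))
  cfg$responders <- lapply(cfg$responders, function(rp) {
    do.call(responderParams, rp)
  })
  if (!all(cfg$modes %in% names(cfg$responders))) {
    stop("session config must name responder parameters for every mode")
  }
  structure(cfg, class = "session_config")
}

#' Run a session from a configuration file
#'
#' @param path YAML session configuration path (see [readSessionConfig()]).
#' @param log_path Optional master trial-log CSV output path.
#' @return A `"session_log"`.
#' @export
runSessionFromConfig <- function(path, log_path = NULL) {
  cfg <- readSessionConfig(path)
  tmpl <- blockConfig(
    n_trials = if (is.null(cfg$n_trials)) 100L else cfg$n_trials,
    block_duration = if (is.null(cfg$block_duration)) 300 else cfg$block_duration,
    noise_max = if (is.null(cfg$noise_max)) 0.2 else cfg$noise_max,
    noise_mean = if (is.null(cfg$noise_mean)) 0.03 else cfg$noise_mean,
    noise_sd = if (is.null(cfg$noise_sd)) 0.01 else cfg$noise_sd,
    signal_contrast = if (is.null(cfg$signal_contrast)) 0.40 else cfg$signal_contrast)
  runSession(observers = cfg$observers, responders = cfg$responders,
             modes = cfg$modes,
             blocks_per_mode = if (is.null(cfg$blocks_per_mode)) 1L
                               else cfg$blocks_per_mode,
             seed = cfg$seed, config_template = tmpl, log_path = log_path)
}
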