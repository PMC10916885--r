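# Probe synthesis and edge-guided insertion. The probe is a disc carrying 16
# superimposed gratings spanning orientation in 11.25-degree steps; the
# insertion point is chosen on Sobel edge maps of the image (luminance) and
# depth snapshots by the driver/modulator algorithm with Harris corner
# suppression.
#
# Orientation convention (shared by all modules): degrees in [0, 180), 0 =
# horizontal edge/stripe, increasing counterclockwise on screen. Maps are R
# matrices indexed [row, col], row 1 at the top; pixel coordinates are
# 1-based (row, col).

#' Probe texture specification
#'
#' Draws the stochastic components of one probe: 16 phases uniform on
#' [0, 360), a noise amplitude vector `n` of i.i.d. Gaussian contrasts
#' (negative draws clipped to zero), and a signal vector `s` that is zero
#' except at the component matching the congruency: component 1 (0 degrees
#' relative to the local reference orientation) for congruent probes,
#' component 9 (+90 degrees) for incongruent. The amplitude vector is
#' `a = n + s`. Component i carries pre-shift orientation `(i - 1) * 11.25`
#' degrees; at render time all orientations are shifted by
#' `reference_orientation`.
#'
#' @param congruent Logical congruency label.
#' @param reference_orientation Local environmental orientation (degrees in
#'   [0, 180)) that anchors the probe.
#' @param noise_mean,noise_sd Gaussian noise contrast parameters (defaults
#'   0.03 and 0.01, i.e. 3% +/- 1% contrast).
#' @param signal_contrast Signal component contrast (default 0.40).
#' @param seed Integer seed.
#' @param frequency Carrier frequency, cycles/degree (default 1.2).
#' @param window_sd_arcmin Gaussian edge SD of the disc window (default 15).
#' @param diameter_deg Disc diameter in degrees (default 3).
#' @return A list of class `"probe_spec"` with `amplitudes`, `phases`,
#'   `noise`, `signal`, `orientations` (pre-shift, degrees), plus the
#'   geometry fields.
#' @export
makeProbeSpec <- function(congruent, reference_orientation,
                          noise_mean = 0.03, noise_sd = 0.01,
                          signal_contrast = 0.40, seed = 1L,
                          frequency = 1.2, window_sd_arcmin = 15,
                          diameter_deg = 3) {
  stopifnot(is.logical(congruent), length(congruent) == 1,
            reference_orientation >= 0, reference_orientation < 180,
            noise_mean >= 0, noise_sd >= 0, signal_contrast >= 0)
  draws <- with_seed(seed, {
    list(phases = stats::runif(16, 0, 360),
         noise = pmax(0, stats::rnorm(16, noise_mean, noise_sd)))
  })
  s <- numeric(16)
  s[if (congruent) 1L else 9L] <- signal_contrast
  structure(list(amplitudes = draws$noise + s,
                 phases = draws$phases,
                 noise = draws$noise,
                 signal = s,
                 orientations = (seq_len(16) - 1) * 11.25,
                 congruent = congruent,
                 reference_orientation = as.numeric(reference_orientation),
                 frequency = frequency,
                 window_sd_arcmin = window_sd_arcmin,
                 diameter_deg = diameter_deg),
            class = "probe_spec")
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("<probe_spec> %s, reference %.1f deg, signal %.2f at component %d\n",
              if (x$congruent) "congruent" else "incongruent",
              x$reference_orientation, max(x$signal), which.max(x$signal)))
  invisible(x)
}

#' Render a probe patch
#'
#' Luminance pattern `0.5 * (1 + sum_i a_i cos(2 pi f u_i + p_i))` where
#' `u_i` is the coordinate along the wavevector of component i at absolute
#' orientation `orientations[i] + reference_orientation`, windowed by a disc
#' with Gaussian edge, clipped to [0, 1].
#'
#' @param spec A `"probe_spec"`.
#' @param px_per_degree Pixels per degree of the target snapshot (default 2,
#'   i.e. 90 px across 45 degrees).
#' @return A list of class `"probe_patch"` with `pattern` (luminance matrix),
#'   `window` (same size, in [0, 1]), and `half` (patch half-width, px).
#' @export
renderProbe <- function(spec, px_per_degree = 2) {
  stopifnot(inherits(spec, "probe_spec"))
  r_disc <- spec$diameter_deg / 2
  sd_deg <- spec$window_sd_arcmin / 60
  half <- ceiling((r_disc + 4 * sd_deg) * px_per_degree)
  xs <- (-half:half) / px_per_degree   # degrees, x rightward
  ys <- (-half:half) / px_per_degree   # degrees, y downward (rows)
  n <- length(xs)
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n)
  pat <- matrix(0.5, n, n)
  th_all <- (spec$orientations + spec$reference_orientation) * pi / 180
  for (i in seq_len(16)) {
    if (spec$amplitudes[i] == 0) next
    u <- X * sin(th_all[i]) + Y * cos(th_all[i])
    pat <- pat + 0.5 * spec$amplitudes[i] *
      cos(2 * pi * spec$frequency * u + spec$phases[i] * pi / 180)
  }
  pat[] <- pmin(1, pmax(0, pat))
  r <- sqrt(X^2 + Y^2)
  win <- ifelse(r <= r_disc, 1, exp(-(r - r_disc)^2 / (2 * sd_deg^2)))
  structure(list(pattern = pat, window = win, half = half),
            class = "probe_patch")
}

#' Composite a probe patch into a snapshot image
#'
#' Window-weighted replacement: within the disc the scene is replaced by the
#' probe pattern, the Gaussian edge blending smoothly back into the scene.
#'
#' @param image Snapshot luminance matrix in [0, 1].
#' @param patch A `"probe_patch"`.
#' @param point `c(row, col)` centre of insertion (1-based).
#' @return The probe-present image matrix.
#' @export
compositeProbe <- function(image, patch, point) {
  stopifnot(inherits(patch, "probe_patch"), length(point) == 2)
  h <- patch$half
  r0 <- point[1] - h; r1 <- point[1] + h
  c0 <- point[2] - h; c1 <- point[2] + h
  if (r0 < 1 || c0 < 1 || r1 > nrow(image) || c1 > ncol(image)) {
    stop("probe patch exceeds snapshot bounds at the requested centre")
  }
  out <- image
  w <- patch$window
  out[r0:r1, c0:c1] <- image[r0:r1, c0:c1] * (1 - w) + patch$pattern * w
  out
}

#' Sobel edge map
#'
#' 3x3 Sobel gradients with reflected borders. `magnitude` is the gradient
#' magnitude; `orientation` is the edge orientation (gradient direction
#' rotated by 90 degrees, folded into [0, 180), 0 = horizontal edge), `NA`
#' where the gradient vanishes.
#'
#' @param map2d Numeric matrix.
#' @return A list of class `"edge_map"` with `magnitude` and `orientation`.
#' @export
sobelEdgeMap <- function(map2d) {
  stopifnot(is.matrix(map2d), all(is.finite(map2d)))
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dcol
  ky <- t(kx)                                                 # d/drow
  gx <- conv2_reflect(map2d, kx)
  gy <- conv2_reflect(map2d, ky)
  mag <- sqrt(gx^2 + gy^2)
  ori <- fold180(atan2(-gy, gx) * 180 / pi + 90)
  ori[mag < 1e-12] <- NA_real_
  structure(list(magnitude = mag, orientation = ori), class = "edge_map")
}

# Min-max normalize a matrix to [0, 1]; NULL when constant.
norm_minmax <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] < 1e-300) return(NULL)
  (m - rng[1]) / (rng[2] - rng[1])
}

# Harris corner response of a map: 3x3 Sobel derivatives, structure tensor
# summed over a `block` x `block` box (anchor at offset -(block/2 - 1), i.e.
# offsets -4..+5 for block 10), R = det - k * trace^2. Borders reflected.
harris_response <- function(m, block = 10L, k = 0.04) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  ky <- t(kx)
  gx <- conv2_reflect(m, kx)
  gy <- conv2_reflect(m, ky)
  lo <- -(block %/% 2L - 1L)
  hi <- block %/% 2L
  # even-sized box sum realized with an odd kernel of zeros on one edge
  size <- 2L * hi + 1L
  box <- matrix(0, size, size)
  box[(lo + hi + 1L):(hi + hi + 1L), (lo + hi + 1L):(hi + hi + 1L)] <- 1
  Sxx <- conv2_reflect(gx * gx, box)
  Syy <- conv2_reflect(gy * gy, box)
  Sxy <- conv2_reflect(gx * gy, box)
  (Sxx * Syy - Sxy^2) - k * (Sxx + Syy)^2
}

#' Select a probe insertion point
#'
#' Implements the driver/modulator algorithm. With `insertion_type =
#' "image_driven"` the image edge map drives and the depth edge map
#' modulates; `"object_driven"` swaps the roles. Steps, in order: (1) min-max
#' normalize both magnitude maps; (2) blur the modulator (Gaussian SD
#' `blur_sd` px) and invert it as `1 - M`; (3) corrupt the driver with
#' per-pixel uniform noise `U(0, noise_max)`; (4) compute the Harris corner
#' response of the (noise-corrupted) driver, zero the top `100 * (1 -
#' corner_quantile)` percent of pixels via a binary mask; (5) multiply driver
#' and modulator; (6) apply a circular window (disc diameter
#' `window_diam_frac` of image width, Gaussian edge SD `window_sd_frac` of
#' image width); (7) take the argmax (ties broken toward the lowest
#' (row, col)). The local orientation is read from the driver's Sobel
#' orientation at the selected pixel.
#'
#' A constant driver raises a degenerate-map error (an uninformative scene).
#' A constant modulator exerts no suppression.
#'
#' @param image_edges,object_edges `"edge_map"`s of the image and depth
#'   snapshots (aligned).
#' @param insertion_type `"image_driven"` or `"object_driven"`.
#' @param seed Integer seed for the driver noise.
#' @param noise_max Upper bound of the driver noise; 0 disables it.
#' @param blur_sd Modulator blur SD in pixels.
#' @param harris_block,harris_k Harris block size and free parameter.
#' @param corner_quantile Quantile above which corner pixels are zeroed;
#'   `1` disables corner suppression.
#' @param window_diam_frac,window_sd_frac Circular window geometry as
#'   fractions of image width.
#' @param support_margin Width (px) of a border band excluded from the
#'   argmax (0 disables). The session layer passes the probe patch
#'   half-width so that every selected point has full patch support; the
#'   soft circular window alone leaves a small tail probability of
#'   near-border selections.
#' @param require_defined_orientation If `TRUE`, pixels whose driver Sobel
#'   orientation is undefined (zero gradient) are excluded from the argmax,
#'   so the probe is always anchored to a real driver edge; the driver
#'   noise would otherwise occasionally peak in a featureless region. The
#'   default `FALSE` keeps the literal argmax and raises the degenerate-map
#'   error at such a point.
#' @return A list of class `"insertion_result"`: `point` (`c(row, col)`),
#'   `local_orientation` (degrees), `insertion_type`, `M` (the final
#'   insertion map).
#' @export
selectInsertionPoint <- function(image_edges, object_edges,
                                 insertion_type = c("image_driven",
                                                    "object_driven"),
                                 seed = 1L, noise_max = 0.2, blur_sd = 5,
                                 harris_block = 10L, harris_k = 0.04,
                                 corner_quantile = 0.9,
                                 window_diam_frac = 0.8,
                                 window_sd_frac = 0.1,
                                 support_margin = 0L,
                                 require_defined_orientation = FALSE) {
  insertion_type <- match.arg(insertion_type)
  stopifnot(inherits(image_edges, "edge_map"),
            inherits(object_edges, "edge_map"),
            all(dim(image_edges$magnitude) == dim(object_edges$magnitude)))
  if (insertion_type == "image_driven") {
    driver <- image_edges; modulator <- object_edges
  } else {
    driver <- object_edges; modulator <- image_edges
  }
  dims <- dim(driver$magnitude)
  M_up <- norm_minmax(driver$magnitude)
  if (is.null(M_up)) {
    stop("degenerate driver map: constant magnitude, normalization undefined")
  }
  M_dn <- norm_minmax(modulator$magnitude)
  if (is.null(M_dn)) M_dn <- matrix(0, dims[1], dims[2])
  M_dn <- 1 - gaussian_blur(M_dn, blur_sd)
  if (noise_max > 0) {
    M_up <- M_up + with_seed(seed, matrix(stats::runif(prod(dims), 0, noise_max),
                                          dims[1], dims[2]))
  }
  if (corner_quantile < 1) {
    R <- harris_response(M_up, block = harris_block, k = harris_k)
    thr <- stats::quantile(R, corner_quantile, names = FALSE, type = 7)
    corner_mask <- ifelse(R >= thr, 0, 1)
  } else {
    corner_mask <- matrix(1, dims[1], dims[2])
  }
  M_up <- M_up * corner_mask
  M <- M_up * M_dn
  win <- circular_window(dims, diameter = window_diam_frac * dims[2],
                         edge_sd = window_sd_frac * dims[2])
  M <- M * win
  if (support_margin > 0) {
    sm <- as.integer(support_margin)
    stopifnot(2L * sm < dims[1], 2L * sm < dims[2])
    keep <- matrix(0, dims[1], dims[2])
    keep[(sm + 1L):(dims[1] - sm), (sm + 1L):(dims[2] - sm)] <- 1
    M <- M * keep
  }
  if (require_defined_orientation) {
    defined <- !is.na(driver$orientation)
    if (!any(defined & M > 0)) {
      stop("degenerate driver map: no pixel with defined edge orientation ",
           "inside the window")
    }
    M <- M * defined
  }
  pt <- argmax_rc(M)
  ori <- driver$orientation[pt[1], pt[2]]
  if (is.na(ori)) {
    stop("degenerate map: no defined edge orientation at the insertion point")
  }
  structure(list(point = pt, local_orientation = ori,
                 insertion_type = insertion_type, M = M,
                 corner_mask = corner_mask),
            class = "insertion_result")
}

#' @export
print.insertion_result <- function(x, ...) {
  cat(sprintf("<insertion_result> %s at (row %d, col %d), orientation %.1f deg\n",
              x$insertion_type, x$point[1], x$point[2], x$local_orientation))
  invisible(x)
}
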