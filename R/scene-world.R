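# Procedural virtual room: box placement by rejection sampling, zigzag wall
# texture, point-light schedules, a smooth random-waypoint camera walk, and a
# pinhole ray-cast renderer producing aligned luminance + depth snapshots.
#
# World frame: x east, y north (floor plane), z up. The room is the interior
# of [0,W] x [0,L] x [0,H] metres. All stochastic functions take explicit
# seeds and are deterministic given them.

#' Room generation parameters
#'
#' Bundles the geometric constants of the virtual room: dimensions, box count,
#' sampling ranges for box size/rotation, clearance constraints, and texture
#' scales. Defaults encode the study conditions: a 6 x 6 x 3 m room holding 10
#' instantiated boxes (an 11th spec is kept spare as the memory-task
#' displacement target), box sides 0.40-1.20 m (height up to 2.40 m), free
#' rotation in [0, 180) degrees, 0.80 m clearance from the room centre and
#' between box centres, ~0.70 m zigzag stripes turning 90 degrees every
#' ~1.5 m, box texture at half the wall scale.
#'
#' @param room_dims Numeric length-3, room width/length/height in metres.
#' @param n_boxes Total box specifications to create (instantiated + spare).
#' @param n_instantiated Number of boxes actually present during a block.
#' @param width_range,length_range,height_range Uniform sampling ranges (m).
#' @param rotation_range Uniform sampling range for rotation (degrees).
#' @param min_center_clearance Minimum box-centre distance from room centre (m).
#' @param min_separation Minimum pairwise box-centre distance (m).
#' @param stripe_width Wall stripe width (m); boxes use `stripe_width / box_texture_scale`.
#' @param zigzag_period Wall zigzag turn period (m).
#' @param box_texture_scale Scale divisor applied to the box texture.
#' @param max_attempts Rejection-sampling attempts per box before failing.
#' @return A list of class `"room_params"`.
#' @export
roomParams <- function(room_dims = c(6, 6, 3),
                       n_boxes = 11L,
                       n_instantiated = 10L,
                       width_range = c(0.4, 1.2),
                       length_range = c(0.4, 1.2),
                       height_range = c(0.4, 2.4),
                       rotation_range = c(0, 180),
                       min_center_clearance = 0.8,
                       min_separation = 0.8,
                       stripe_width = 0.7,
                       zigzag_period = 1.5,
                       box_texture_scale = 2,
                       max_attempts = 5000L) {
  stopifnot(length(room_dims) == 3, all(room_dims > 0),
            n_boxes >= n_instantiated, n_instantiated >= 0)
  structure(list(room_dims = room_dims,
                 n_boxes = as.integer(n_boxes),
                 n_instantiated = as.integer(n_instantiated),
                 width_range = width_range,
                 length_range = length_range,
                 height_range = height_range,
                 rotation_range = rotation_range,
                 min_center_clearance = min_center_clearance,
                 min_separation = min_separation,
                 stripe_width = stripe_width,
                 zigzag_period = zigzag_period,
                 box_texture_scale = box_texture_scale,
                 max_attempts = as.integer(max_attempts)),
            class = "room_params")
}

#' Box specification
#'
#' One axis-rotated box standing on the floor: centre position on the floor
#' plane, footprint width/length, height, and rotation about the vertical
#' axis.
#'
#' @param center_xy Numeric length-2 centre on the floor plane (m).
#' @param width,length,height Box dimensions (m).
#' @param rotation Rotation about the vertical axis, degrees in [0, 180).
#' @param instantiated Logical; spare (memory-target) specs are not rendered.
#' @return A list of class `"box_spec"`.
#' @export
boxSpec <- function(center_xy, width, length, height, rotation,
                    instantiated = TRUE) {
  stopifnot(length(center_xy) == 2, width > 0, length > 0, height > 0)
  structure(list(center_xy = as.numeric(center_xy),
                 width = as.numeric(width),
                 length = as.numeric(length),
                 height = as.numeric(height),
                 rotation = as.numeric(rotation) %% 180,
                 instantiated = isTRUE(instantiated)),
            class = "box_spec")
}

# Footprint corners of a box on the floor plane (4 x 2 matrix).
box_corners <- function(box) {
  hw <- box$width / 2
  hl <- box$length / 2
  phi <- box$rotation * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  local <- rbind(c(-hw, -hl), c(hw, -hl), c(hw, hl), c(-hw, hl))
  sweep(local %*% t(R), 2, box$center_xy, `+`)
}

# Check the placement constraints of a candidate centre against params and
# prior boxes. Only the centre location is constrained (clearance from the
# room centre, pairwise separation); dimensions are drawn independently, so
# accepted boxes keep exactly uniform size/rotation distributions.
box_ok <- function(box, params, placed) {
  ctr <- params$room_dims[1:2] / 2
  if (sqrt(sum((box$center_xy - ctr)^2)) < params$min_center_clearance)
    return(FALSE)
  for (b in placed) {
    if (sqrt(sum((box$center_xy - b$center_xy)^2)) < params$min_separation)
      return(FALSE)
  }
  TRUE
}

#' Generate a room by sequential rejection sampling
#'
#' Boxes are placed one at a time: a candidate centre is drawn uniformly on
#' the floor, then width/length/height/rotation are drawn uniformly from
#' their ranges; the candidate is rejected if it violates the centre
#' clearance, the pairwise separation, or leaves the room footprint. The
#' first `n_instantiated` specs are instantiated; remaining specs are spares.
#'
#' @param seed Integer seed; the result is deterministic given it.
#' @param params A [roomParams()] list.
#' @return A list of class `"room_spec"` with elements `boxes` (list of
#'   [boxSpec()]), `room_dims`, and `params`.
#' @export
generateRoom <- function(seed, params = roomParams()) {
  stopifnot(inherits(params, "room_params"))
  boxes <- with_seed(seed, {
    placed <- list()
    for (i in seq_len(params$n_boxes)) {
      ok <- FALSE
      for (attempt in seq_len(params$max_attempts)) {
        cand <- boxSpec(
          center_xy = c(stats::runif(1, 0, params$room_dims[1]),
                        stats::runif(1, 0, params$room_dims[2])),
          width = stats::runif(1, params$width_range[1], params$width_range[2]),
          length = stats::runif(1, params$length_range[1], params$length_range[2]),
          height = stats::runif(1, params$height_range[1], params$height_range[2]),
          rotation = stats::runif(1, params$rotation_range[1], params$rotation_range[2]),
          instantiated = i <= params$n_instantiated)
        if (box_ok(cand, params, placed)) {
          placed[[i]] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("room placement failure: could not satisfy box constraints ",
             "within max_attempts (box ", i, "); the parameters are ",
             "over-constrained", call. = FALSE)
      }
    }
    placed
  })
  structure(list(room_dims = params$room_dims, boxes = boxes, params = params),
            class = "room_spec")
}

#' @export
print.room_spec <- function(x, ...) {
  n_inst <- sum(vapply(x$boxes, function(b) b$instantiated, logical(1)))
  cat(sprintf("<room_spec> %.1f x %.1f x %.1f m, %d box specs (%d instantiated)\n",
              x$room_dims[1], x$room_dims[2], x$room_dims[3],
              length(x$boxes), n_inst))
  invisible(x)
}

#' Regenerate all box placements ("room scrambling")
#'
#' Produces a fresh room from the same parameters under a new seed; dimensions
#' and texture settings are unchanged. Used when an observer accumulates four
#' consecutive incorrect/invalid responses.
#'
#' @param room A `"room_spec"`.
#' @param seed Integer seed for the regenerated layout.
#' @return A new `"room_spec"`.
#' @export
scrambleRoom <- function(room, seed) {
  stopifnot(inherits(room, "room_spec"))
  generateRoom(seed, room$params)
}

# Unit triangle wave: period 1, range [-1, 1], tri(0) = -1, tri(0.5) = +1.
tri_wave <- function(t) {
  f <- t - floor(t)
  1 - 4 * abs(f - 0.5)
}

#' Zigzag stripe texture
#'
#' Binary black/white stripe pattern whose stripe direction alternates by 90
#' degrees: stripes of width `stripe_width / scale` run at +/-45 degrees to
#' the u axis, the direction flipping every `zigzag_period / scale` along v.
#' Implemented as the parity of `floor((u + A tri(v / P)) / s)` with `A = P/4`
#' so segment slope is exactly +/-1. Total, deterministic, periodic.
#'
#' @param u,v Surface coordinates (m); vectorized.
#' @param scale 1 for walls, 2 for boxes (halves stripe width and period).
#' @param stripe_width,zigzag_period Wall-scale texture constants (m).
#' @return 0/1 pattern values, same length as `u`.
#' @export
zigzagTexture <- function(u, v, scale = 1, stripe_width = 0.7,
                          zigzag_period = 1.5) {
  s <- stripe_width / scale
  P <- zigzag_period / scale
  A <- P / 4
  floor((u + A * tri_wave(v / P)) / s) %% 2
}

#' Light state for one trial
#'
#' `reliable` draws one azimuth per block and holds it; `unreliable` redraws
#' the azimuth before every probe; `absent` has no directional term and
#' doubles the ambient gain. Elevation is fixed at 45 degrees whenever the
#' directional light exists.
#'
#' @param mode One of `"reliable"`, `"unreliable"`, `"absent"`.
#' @param trial_index 1-based trial number within the block.
#' @param seed Block-level integer seed for the light stream.
#' @return A list of class `"light_state"` with `mode`, `azimuth` (degrees,
#'   `NA` when absent), `elevation` (45 or `NA`), `ambient_gain` (2 when
#'   absent, 1 otherwise).
#' @export
lightSchedule <- function(mode = c("reliable", "unreliable", "absent"),
                          trial_index = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "absent") {
    return(structure(list(mode = mode, azimuth = NA_real_,
                          elevation = NA_real_, ambient_gain = 2),
                     class = "light_state"))
  }
  az_seed <- if (mode == "reliable") deriveSeed(seed, 0L)
             else deriveSeed(seed, as.integer(trial_index))
  az <- with_seed(az_seed, stats::runif(1, 0, 360))
  structure(list(mode = mode, azimuth = az, elevation = 45, ambient_gain = 1),
            class = "light_state")
}

#' Camera pose
#'
#' @param position Numeric length-3 (x, y, z) in metres, inside the room.
#' @param yaw Heading in degrees, counterclockwise from +y (north).
#' @param pitch Elevation of gaze in degrees, positive up.
#' @return A list of class `"camera_pose"`.
#' @export
cameraPose <- function(position, yaw = 0, pitch = 0) {
  stopifnot(length(position) == 3)
  structure(list(position = as.numeric(position), yaw = as.numeric(yaw),
                 pitch = as.numeric(pitch)),
            class = "camera_pose")
}

#' Sample the camera pose of a random-waypoint walk
#'
#' Emulates free navigation: waypoints are drawn uniformly inside the room
#' (keeping `margin` from the walls), visited in order at constant speed with
#' piecewise-linear interpolation; yaw follows the walking direction plus a
#' slow sinusoidal wander, pitch is a bounded slow oscillation, eye height is
#' fixed. Deterministic in (seed, t): the whole trajectory is a function of
#' the seed.
#'
#' @param room A `"room_spec"`.
#' @param t Time in seconds since block start.
#' @param seed Integer walk seed.
#' @param speed Walking speed (m/s).
#' @param eye_height Eye height (m).
#' @param pitch_max Pitch bound (degrees).
#' @param margin Wall clearance of waypoints (m).
#' @return A `"camera_pose"`.
#' @export
samplePose <- function(room, t, seed, speed = 0.8, eye_height = 1.6,
                       pitch_max = 30, margin = 0.8) {
  stopifnot(inherits(room, "room_spec"), t >= 0)
  dims <- room$room_dims
  wp <- with_seed(deriveSeed(seed, 101L), {
    n <- 240L
    cbind(stats::runif(n, margin, dims[1] - margin),
          stats::runif(n, margin, dims[2] - margin))
  })
  ph <- with_seed(deriveSeed(seed, 103L), stats::runif(2, 0, 2 * pi))
  seg <- diff(wp)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  dist <- (speed * t) %% cum[length(cum)]
  i <- findInterval(dist, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(seg))
  frac <- (dist - cum[i]) / seg_len[i]
  pos_xy <- wp[i, ] + frac * seg[i, ]
  pos_xy <- push_out_of_boxes(pos_xy, room, eye_height, clearance = 0.4,
                              margin = 0.5)
  heading <- atan2(seg[i, 1], seg[i, 2]) * 180 / pi  # ccw-from-+y convention
  yaw <- heading + 20 * sin(2 * pi * t / 11 + ph[1])
  pitch <- 0.6 * pitch_max * sin(2 * pi * t / 7 + ph[2])
  cameraPose(c(pos_xy, eye_height), yaw = yaw, pitch = pitch)
}

# Deterministically displace a walk position out of any instantiated box
# footprint it penetrates (plus a body-clearance band), along the local axis
# of shallowest penetration; the waypoint walk itself is box-blind. Clamped
# to the room afterwards.
push_out_of_boxes <- function(pos_xy, room, eye_height, clearance = 0.15,
                              margin = 0.2) {
  clamp <- function(p) pmin(pmax(p, margin), room$room_dims[1:2] - margin)
  pos_xy <- clamp(pos_xy)
  for (pass in 1:20) {
    moved <- FALSE
    for (box in room$boxes) {
      if (!box$instantiated) next
      phi <- box$rotation * pi / 180
      dx <- pos_xy[1] - box$center_xy[1]
      dy <- pos_xy[2] - box$center_xy[2]
      lx <- dx * cos(phi) + dy * sin(phi)
      ly <- -dx * sin(phi) + dy * cos(phi)
      hx <- box$width / 2 + clearance
      hy <- box$length / 2 + clearance
      if (abs(lx) < hx && abs(ly) < hy) {
        # exit along the axis needing the smallest displacement
        ex <- hx - abs(lx)
        ey <- hy - abs(ly)
        if (ex <= ey) lx <- sign(lx + 1e-12) * hx else ly <- sign(ly + 1e-12) * hy
        pos_xy <- clamp(c(box$center_xy[1] + lx * cos(phi) - ly * sin(phi),
                          box$center_xy[2] + lx * sin(phi) + ly * cos(phi)))
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  pos_xy
}

# --- ray casting ------------------------------------------------------------

# Direction unit vectors for every pixel of an H x W snapshot covering
# fov = c(horizontal, vertical) degrees. Returns an (H*W) x 3 matrix in
# column-major pixel order (row index fastest), matching R matrix layout.
ray_directions <- function(pose, res = c(100L, 90L), fov = c(45, 50)) {
  H <- res[1L]; W <- res[2L]
  tanx <- tan(fov[1] / 2 * pi / 180)
  tanz <- tan(fov[2] / 2 * pi / 180)
  u <- ((seq_len(W) - 0.5) / W * 2 - 1) * tanx      # rightward
  v <- -(((seq_len(H) - 0.5) / H * 2 - 1)) * tanz   # row 1 = top = up
  U <- matrix(u, H, W, byrow = TRUE)
  V <- matrix(v, H, W)
  d_cam <- cbind(as.vector(U), 1, as.vector(V))
  pr <- pose$pitch * pi / 180
  yr <- pose$yaw * pi / 180
  # pitch about camera x-axis, then yaw about world z (ccw from +y)
  d1 <- cbind(d_cam[, 1],
              d_cam[, 2] * cos(pr) - d_cam[, 3] * sin(pr),
              d_cam[, 2] * sin(pr) + d_cam[, 3] * cos(pr))
  d2 <- cbind(d1[, 1] * cos(yr) + d1[, 2] * sin(yr),
              -d1[, 1] * sin(yr) + d1[, 2] * cos(yr),
              d1[, 3])
  d2 / sqrt(rowSums(d2^2))
}

# Conservative screen-space pixel index range covered by a box, or NULL when
# the box is entirely outside the view. Falls back to all pixels when a
# corner lies at or behind the camera plane.
box_pixel_range <- function(box, pose, res, fov, margin = 2L) {
  H <- res[1L]; W <- res[2L]
  crn <- box_corners(box)
  corners <- rbind(cbind(crn, 0), cbind(crn, box$height))
  rel <- sweep(corners, 2, pose$position)
  yr <- -pose$yaw * pi / 180
  pr <- -pose$pitch * pi / 180
  x1 <- rel[, 1] * cos(yr) + rel[, 2] * sin(yr)
  y1 <- -rel[, 1] * sin(yr) + rel[, 2] * cos(yr)
  z1 <- rel[, 3]
  y2 <- y1 * cos(pr) - z1 * sin(pr)
  z2 <- y1 * sin(pr) + z1 * cos(pr)
  if (any(y2 < 0.05)) return(seq_len(H * W))
  tanx <- tan(fov[1] / 2 * pi / 180)
  tanz <- tan(fov[2] / 2 * pi / 180)
  u <- (x1 / y2) / tanx          # [-1, 1] across columns
  v <- (z2 / y2) / tanz          # [-1, 1], positive up
  cols <- floor((u + 1) / 2 * W + 0.5)
  rows <- floor((1 - v) / 2 * H + 0.5)
  c0 <- max(1L, min(cols) - margin); c1 <- min(W, max(cols) + margin)
  r0 <- max(1L, min(rows) - margin); r1 <- min(H, max(rows) + margin)
  if (c0 > c1 || r0 > r1) return(NULL)
  as.vector(outer(r0:r1, (c0:c1 - 1L) * H, `+`))
}

# Nearest positive intersection of rays with the six interior wall planes.
# Returns list(t, face) where face indexes c(x0,x1,y0,y1,z0,z1).
intersect_walls <- function(p, d, dims) {
  n <- nrow(d)
  tbest <- rep(Inf, n)
  fbest <- rep(NA_integer_, n)
  bounds <- list(c(1, 0), c(1, dims[1]), c(2, 0), c(2, dims[2]),
                 c(3, 0), c(3, dims[3]))
  for (f in seq_along(bounds)) {
    ax <- bounds[[f]][1]; b <- bounds[[f]][2]
    tt <- (b - p[ax]) / d[, ax]
    ok <- is.finite(tt) & tt > 1e-9 & tt < tbest
    if (any(ok)) {
      tbest[ok] <- tt[ok]
      fbest[ok] <- f
    }
  }
  list(t = tbest, face = fbest)
}

# Ray/box slab intersection in the box's local frame. Returns list(t, axis,
# sgn) of entry hits (Inf where missed). p is length-3, d is n x 3.
intersect_box <- function(p, d, box) {
  phi <- box$rotation * pi / 180
  cphi <- cos(phi); sphi <- sin(phi)
  # world -> local (rotate by -phi about z, translate by centre)
  px <- p[1] - box$center_xy[1]
  py <- p[2] - box$center_xy[2]
  pl <- c(px * cphi + py * sphi, -px * sphi + py * cphi, p[3])
  dl1 <- d[, 1] * cphi + d[, 2] * sphi
  dl2 <- -d[, 1] * sphi + d[, 2] * cphi
  dl3 <- d[, 3]
  lo <- c(-box$width / 2, -box$length / 2, 0)
  hi <- c(box$width / 2, box$length / 2, box$height)
  n <- nrow(d)
  tmin <- rep(-Inf, n); tmax <- rep(Inf, n)
  ax_min <- rep(0L, n)
  dls <- list(dl1, dl2, dl3)
  for (ax in 1:3) {
    dd <- dls[[ax]]
    # nudge exactly-parallel rays; the +/-Inf arithmetic of 1/dd then yields
    # correct slab intervals except on a measure-zero boundary set
    dd <- dd + (abs(dd) < 1e-12) * 1e-12
    inv <- 1 / dd
    t1 <- (lo[ax] - pl[ax]) * inv
    t2 <- (hi[ax] - pl[ax]) * inv
    swap <- t2 < t1
    tlo <- t1; tlo[swap] <- t2[swap]
    thi <- t2; thi[swap] <- t1[swap]
    upd <- tlo > tmin
    tmin[upd] <- tlo[upd]
    ax_min[upd] <- ax
    tmax <- pmin(tmax, thi)
  }
  hit <- tmin <= tmax & tmax > 1e-9 & tmin > 1e-9
  t <- ifelse(hit, tmin, Inf)
  # sign of the entry face normal along the hit axis (local frame)
  sgn <- integer(n)
  for (ax in 1:3) {
    sel <- hit & ax_min == ax
    sgn[sel] <- ifelse(dls[[ax]][sel] > 0, -1L, 1L)
  }
  list(t = t, axis = ax_min, sgn = sgn,
       local_p = pl, local_d = cbind(dl1, dl2, dl3))
}

# TRUE if a world point lies strictly inside a box.
point_in_box <- function(pt, box) {
  phi <- box$rotation * pi / 180
  px <- pt[1] - box$center_xy[1]
  py <- pt[2] - box$center_xy[2]
  lx <- px * cos(phi) + py * sin(phi)
  ly <- -px * sin(phi) + py * cos(phi)
  abs(lx) < box$width / 2 && abs(ly) < box$length / 2 &&
    pt[3] > 0 && pt[3] < box$height
}

# Occlusion test: TRUE where the segment from `pts` (n x 3) toward direction
# `ldir` (unit, length 3) is blocked by any instantiated box. Directional
# light: any positive hit occludes. Only rows where `active` is TRUE are
# tested.
shadow_occluded <- function(pts, ldir, boxes, active) {
  n <- nrow(pts)
  occ <- rep(FALSE, n)
  idx <- which(active)
  if (!length(idx)) return(occ)
  # horizontal unit vector toward the light (elevation fixed; a surface
  # point can only be shadowed by a box it passes over at low enough height)
  lh <- sqrt(ldir[1]^2 + ldir[2]^2)
  slope <- ldir[3] / max(lh, 1e-12)      # rise per metre of horizontal travel
  ux <- ldir[1] / max(lh, 1e-12)
  uy <- ldir[2] / max(lh, 1e-12)
  for (box in boxes) {
    if (!box$instantiated) next
    sub <- idx[!occ[idx]]
    if (!length(sub)) break
    # prefilter: the ray from pts[s,] reaches the box footprint (radius r)
    # at altitude pz + slope * dist; it can only hit below the box top
    r <- sqrt(box$width^2 + box$length^2) / 2
    da <- (box$center_xy[1] - pts[sub, 1]) * ux +
      (box$center_xy[2] - pts[sub, 2]) * uy
    dp <- abs((box$center_xy[1] - pts[sub, 1]) * uy -
                (box$center_xy[2] - pts[sub, 2]) * ux)
    reach <- da > -r & dp <= r &
      pts[sub, 3] + slope * pmax(da - r, 0) < box$height
    sub <- sub[reach]
    if (!length(sub)) next
    phi <- box$rotation * pi / 180
    cphi <- cos(phi); sphi <- sin(phi)
    px <- pts[sub, 1] - box$center_xy[1]
    py <- pts[sub, 2] - box$center_xy[2]
    plx <- px * cphi + py * sphi
    ply <- -px * sphi + py * cphi
    plz <- pts[sub, 3]
    dlx <- ldir[1] * cphi + ldir[2] * sphi
    dly <- -ldir[1] * sphi + ldir[2] * cphi
    dlz <- ldir[3]
    lo <- c(-box$width / 2, -box$length / 2, 0)
    hi <- c(box$width / 2, box$length / 2, box$height)
    tmin <- rep(-Inf, length(sub)); tmax <- rep(Inf, length(sub))
    pls <- list(plx, ply, plz); dls <- c(dlx, dly, dlz)
    for (ax in 1:3) {
      dd <- dls[ax]
      if (abs(dd) < 1e-12) {
        out <- pls[[ax]] < lo[ax] | pls[[ax]] > hi[ax]
        tmin[out] <- Inf
      } else {
        t1 <- (lo[ax] - pls[[ax]]) / dd
        t2 <- (hi[ax] - pls[[ax]]) / dd
        if (dd > 0) {
          tmin <- pmax(tmin, t1); tmax <- pmin(tmax, t2)
        } else {
          tmin <- pmax(tmin, t2); tmax <- pmin(tmax, t1)
        }
      }
    }
    blocked <- tmin <= tmax & tmax > 1e-6 & tmin > 1e-6
    occ[sub[blocked]] <- TRUE
  }
  occ
}

#' Render an aligned luminance + depth snapshot
#'
#' Pinhole ray cast at the native analysis resolution (default 100 rows x 90
#' columns covering 50 x 45 degrees of visual field, height x width): each
#' pixel receives the nearest hit among the six walls and all instantiated
#' boxes. Depth is the metric distance to the hit. Luminance is the zigzag
#' albedo times `ambient + diffuse * max(0, n.l) * visibility` under a
#' directional light at the configured azimuth/elevation (hard shadows cast
#' by boxes only), or `2 * ambient` times albedo in absent mode; clipped to
#' [0, 1].
#'
#' @param room A `"room_spec"`.
#' @param pose A `"camera_pose"` inside the room (and outside every box).
#' @param light A `"light_state"`.
#' @param res `c(rows, cols)` of the snapshot.
#' @param fov `c(horizontal, vertical)` field of view in degrees.
#' @param ambient Ambient luminance gain (multiplied by `light$ambient_gain`).
#' @param diffuse Diffuse (Lambertian) gain.
#' @param albedo Length-2 luminance of black/white stripes.
#' @param supersample Rays per pixel side (default 2): the scene is cast at
#'   `supersample`-fold resolution and box-averaged down, emulating the
#'   downsampling of a high-resolution capture. One ray per pixel leaves
#'   binary stripe boundaries as jagged staircases that alias badly at the
#'   fine spatial scales of the edge/orientation analysis.
#' @return A list of class `"scene_snapshot"` with `image` (rows x cols in
#'   [0,1]), `depth` (metres), `pose`, `light`.
#' @export
renderSnapshot <- function(room, pose, light, res = c(100L, 90L),
                           fov = c(45, 50), ambient = 0.25, diffuse = 1,
                           albedo = c(0.1, 0.9), supersample = 2L) {
  stopifnot(inherits(room, "room_spec"), inherits(pose, "camera_pose"),
            inherits(light, "light_state"))
  p <- pose$position
  dims <- room$room_dims
  if (any(p < 0) || any(p > dims)) stop("camera pose outside the room")
  for (b in room$boxes) {
    if (b$instantiated && point_in_box(p, b))
      stop("degenerate viewpoint: camera pose lies inside a box")
  }
  H <- res[1L]; W <- res[2L]
  s <- max(1L, as.integer(supersample))
  Hs <- H * s; Ws <- W * s
  d <- ray_directions(pose, c(Hs, Ws), c(fov[1], fov[2]))
  walls <- intersect_walls(p, d, dims)
  tbest <- walls$t
  # surface bookkeeping: 0 = wall face walls$face, k>0 = box k
  hit_box <- rep(0L, nrow(d))
  box_axis <- rep(0L, nrow(d))
  box_sgn <- rep(0L, nrow(d))
  inst <- which(vapply(room$boxes, function(b) b$instantiated, logical(1)))
  for (k in inst) {
    sub <- box_pixel_range(room$boxes[[k]], pose, c(Hs, Ws), fov)
    if (is.null(sub)) next
    bh <- intersect_box(p, d[sub, , drop = FALSE], room$boxes[[k]])
    upd <- sub[bh$t < tbest[sub]]
    updl <- bh$t < tbest[sub]
    tbest[upd] <- bh$t[updl]
    hit_box[upd] <- k
    box_axis[upd] <- bh$axis[updl]
    box_sgn[upd] <- bh$sgn[updl]
  }
  pts <- cbind(p[1] + tbest * d[, 1],
               p[2] + tbest * d[, 2],
               p[3] + tbest * d[, 3])

  tex <- numeric(nrow(d))
  normal <- matrix(0, nrow(d), 3)
  wsel <- hit_box == 0L
  if (any(wsel)) {
    f <- walls$face[wsel]
    px <- pts[wsel, 1]; py <- pts[wsel, 2]; pz <- pts[wsel, 3]
    uu <- numeric(sum(wsel)); vv <- numeric(sum(wsel))
    # face-local texture coordinates and inward normals
    sel <- f %in% c(1L, 2L); uu[sel] <- py[sel]; vv[sel] <- pz[sel]
    sel <- f %in% c(3L, 4L); uu[sel] <- px[sel]; vv[sel] <- pz[sel]
    sel <- f %in% c(5L, 6L); uu[sel] <- px[sel]; vv[sel] <- py[sel]
    nrm <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
    normal[wsel, ] <- nrm[f, , drop = FALSE]
    tex[wsel] <- zigzagTexture(uu, vv, scale = 1,
                               stripe_width = room$params$stripe_width,
                               zigzag_period = room$params$zigzag_period)
  }
  for (k in inst) {
    bsel <- hit_box == k
    if (!any(bsel)) next
    box <- room$boxes[[k]]
    phi <- box$rotation * pi / 180
    cphi <- cos(phi); sphi <- sin(phi)
    px <- pts[bsel, 1] - box$center_xy[1]
    py <- pts[bsel, 2] - box$center_xy[2]
    lx <- px * cphi + py * sphi
    ly <- -px * sphi + py * cphi
    lz <- pts[bsel, 3]
    ax <- box_axis[bsel]; sg <- box_sgn[bsel]
    uu <- numeric(sum(bsel)); vv <- numeric(sum(bsel))
    sel <- ax == 1L; uu[sel] <- ly[sel] + box$length / 2; vv[sel] <- lz[sel]
    sel <- ax == 2L; uu[sel] <- lx[sel] + box$width / 2; vv[sel] <- lz[sel]
    sel <- ax == 3L
    uu[sel] <- lx[sel] + box$width / 2
    vv[sel] <- ly[sel] + box$length / 2
    tex[bsel] <- zigzagTexture(uu, vv, scale = room$params$box_texture_scale,
                               stripe_width = room$params$stripe_width,
                               zigzag_period = room$params$zigzag_period)
    # local outward normal, rotated back to world
    nl <- matrix(0, sum(bsel), 3)
    nl[cbind(seq_len(sum(bsel)), ax)] <- sg
    normal[bsel, ] <- cbind(nl[, 1] * cphi - nl[, 2] * sphi,
                            nl[, 1] * sphi + nl[, 2] * cphi,
                            nl[, 3])
  }

  alb <- albedo[1] + (albedo[2] - albedo[1]) * tex
  if (light$mode == "absent") {
    lum <- alb * (ambient * light$ambient_gain)
  } else {
    el <- light$elevation * pi / 180
    az <- light$azimuth * pi / 180
    ldir <- c(cos(el) * sin(az), cos(el) * cos(az), sin(el))
    ndotl <- pmax(0, as.vector(normal %*% ldir))
    active <- ndotl > 0
    occ <- shadow_occluded(pts, ldir, room$boxes, active)
    vis <- as.numeric(!occ)
    lum <- alb * (ambient * light$ambient_gain + diffuse * ndotl * vis)
  }
  lum <- pmin(1, pmax(0, lum))
  structure(list(image = downsample_box(matrix(lum, Hs, Ws), s),
                 depth = downsample_box(matrix(tbest, Hs, Ws), s),
                 pose = pose, light = light),
            class = "scene_snapshot")
}

# Box-average downsampling by an integer factor.
downsample_box <- function(m, s) {
  if (s == 1L) return(m)
  H <- nrow(m) %/% s; W <- ncol(m) %/% s
  ri <- rep(seq_len(H), each = s)
  ci <- rep(seq_len(W), each = s)
  rs <- rowsum(m, ri)             # sum over row blocks
  t(rowsum(t(rs), ci)) / s^2      # then column blocks
}

#' @export
print.scene_snapshot <- function(x, ...) {
  cat(sprintf("<scene_snapshot> %d x %d px, light=%s, depth %.2f-%.2f m\n",
              nrow(x$image), ncol(x$image), x$light$mode,
              min(x$depth), max(x$depth)))
  invisible(x)
}
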