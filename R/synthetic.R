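#' Define a synthetic plant scene
#'
#' Describes a single side-view plant used to generate test imagery with
#' known ground truth: a vertical stalk plus straight or mildly curved
#' leaves that leave the stalk at declared angles from vertical, drawn
#' dark (green) on a brighter gray background so the blue channel
#' separates plant from background, as in real greenhouse captures.
#' All coordinates are 0-based pixels, origin top-left.
#'
#' @param width,height Frame size in pixels.
#' @param stalk_col Stalk center column (default: frame middle).
#' @param stalk_width Stalk width in pixels.
#' @param n_leaves Number of leaves, auto-placed bottom-up with
#'   alternating sides (the planar phyllotaxy of maize/sorghum seen from
#'   the side).
#' @param base_angles Per-leaf nominal angles from vertical in degrees,
#'   each in `[5, 85]`; recycled to `n_leaves`.
#' @param leaf_length,leaf_thickness Leaf stroke geometry in pixels
#'   (recycled).
#' @param curvature Per-leaf curvature in `[0, 0.3]` (recycled): the blade
#'   direction turns by `30 * curvature` degrees from base to tip,
#'   emulating the downward bend of a real blade.
#' @param plant_rgb,background_rgb Colors on the `[0, 255]` scale.
#' @param noise_sd Standard deviation of additive Gaussian intensity
#'   noise (per pixel, per channel).
#' @param seed Integer seed; all randomness of rendering flows from it.
#' @return A `synthetic_scene` object with a `leaves` tibble
#'   (leaf_id, junction_row, side, base_angle_deg, length, thickness,
#'   curvature).
#' @export
synthetic_scene <- function(width = 320, height = 240,
                            stalk_col = NULL, stalk_width = 4,
                            n_leaves = 3, base_angles = c(25, 45, 65),
                            leaf_length = 72, leaf_thickness = 5,
                            curvature = 0,
                            plant_rgb = c(45, 85, 40),
                            background_rgb = c(205, 205, 205),
                            noise_sd = 5, seed = 1L) {
  if (is.null(stalk_col)) stalk_col <- round(width / 2)
  stopifnot(width >= 64, height >= 64, stalk_width >= 1, n_leaves >= 1)
  base_angles <- rep_len(base_angles, n_leaves)
  leaf_length <- rep_len(leaf_length, n_leaves)
  leaf_thickness <- rep_len(leaf_thickness, n_leaves)
  curvature <- rep_len(curvature, n_leaves)
  stopifnot(all(base_angles >= 5 & base_angles <= 85),
            all(curvature >= 0 & curvature <= 0.3),
            noise_sd >= 0)
  junction_rows <- height - 50 - (seq_len(n_leaves) - 1L) * 45L
  sides <- rep(c("right", "left"), length.out = n_leaves)
  leaves <- tibble::tibble(
    leaf_id = seq_len(n_leaves),
    junction_row = as.integer(junction_rows),
    side = sides,
    base_angle_deg = base_angles,
    length = leaf_length,
    thickness = leaf_thickness,
    curvature = curvature
  )
  scene <- structure(
    list(width = as.integer(width), height = as.integer(height),
         stalk_col = as.integer(stalk_col),
         stalk_width = as.integer(stalk_width),
         leaves = leaves, plant_rgb = plant_rgb,
         background_rgb = background_rgb,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_scene"
  )
  validate_scene_geometry(scene)
  scene
}

stalk_col_range <- function(scene) {
  half <- (scene$stalk_width - 1L) %/% 2L
  c(scene$stalk_col - half,
    scene$stalk_col - half + scene$stalk_width - 1L)
}

# Leaves must stay inside the frame for every angle a schedule can
# request (5..88 degrees from vertical), so failures surface at scene
# construction, not at render time.
validate_scene_geometry <- function(scene) {
  sc <- stalk_col_range(scene)
  for (i in seq_len(nrow(scene$leaves))) {
    lf <- scene$leaves[i, ]
    reach <- lf$length + lf$thickness
    droop <- ceiling(sin(pmax(0, 88 + 30 * lf$curvature - 90) * pi / 180) *
                       lf$length) + lf$thickness
    ok <- lf$junction_row - reach >= 0 &&
      lf$junction_row + droop < scene$height &&
      (lf$side == "left" || sc[2] + reach < scene$width) &&
      (lf$side == "right" || sc[1] - reach >= 0)
    if (!ok) {
      stop(sprintf("leaf %d geometry would exit the %d x %d frame",
                   lf$leaf_id, scene$height, scene$width))
    }
  }
  invisible(scene)
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d leaf(s), noise sd %.1f, seed %d\n",
              x$height, x$width, nrow(x$leaves), x$noise_sd, x$seed))
  print(x$leaves)
  invisible(x)
}

# Centerline of one leaf at a given angle from vertical: points every
# `dt` px along the blade, turning by 30*curvature degrees base-to-tip.
leaf_centerline <- function(lf, angle_deg, stalk_col, dt = 0.4) {
  ts <- seq(0, lf$length, by = dt)
  phi <- (angle_deg + 30 * lf$curvature * ts / lf$length) * pi / 180
  s <- if (lf$side == "right") 1 else -1
  # cumulative integration of the direction field
  dr <- -cos(phi) * dt
  dc <- s * sin(phi) * dt
  rows <- lf$junction_row + cumsum(dr) - dr[1]
  cols <- stalk_col + cumsum(dc) - dc[1]
  cbind(row = rows, col = cols, t = ts)
}

# Chord angle (degrees from vertical) from the junction to the blade tip;
# for a straight leaf this is exactly the base angle.
chord_angle <- function(cl, junction_row, stalk_col) {
  tip <- cl[nrow(cl), ]
  atan2(abs(tip["col"] - stalk_col), junction_row - tip["row"]) * 180 / pi
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

rasterize_leaf <- function(lf, angle_deg, scene) {
  m <- matrix(0, scene$height, scene$width)
  cl <- leaf_centerline(lf, angle_deg, scene$stalk_col)
  offs <- disk_offsets(lf$thickness / 2)
  r0 <- round(cl[, "row"]) + 1L
  c0 <- round(cl[, "col"]) + 1L
  for (k in seq_len(nrow(offs))) {
    r <- r0 + offs$dr[k]
    c <- c0 + offs$dc[k]
    ok <- r >= 1L & r <= scene$height & c >= 1L & c <= scene$width
    m[cbind(r[ok], c[ok])] <- 1
  }
  list(mask = m, truth = unname(chord_angle(cl, lf$junction_row, scene$stalk_col)))
}

stalk_raster <- function(scene) {
  m <- matrix(0, scene$height, scene$width)
  sc <- stalk_col_range(scene) + 1L
  top <- min(scene$leaves$junction_row) - 15L
  m[max(top, 1L):scene$height, sc[1]:sc[2]] <- 1
  m
}

with_local_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(if (exists(".Random.seed", envir = .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv))
  }
  set.seed(seed)
  expr
}

#' Render one synthetic frame
#'
#' Draws the vertical stalk and each non-occluded leaf at the requested
#' angle from vertical, then adds i.i.d. Gaussian intensity noise (clipped
#' to `[0, 255]` and quantised to integers, as an 8-bit sensor would
#' record). Rendering is deterministic given the scene seed and frame
#' index. Occluded leaves are omitted before noise, emulating a foreign
#' object fully blocking the blade.
#'
#' @param scene A [synthetic_scene()].
#' @param angles Per-leaf angles from vertical in degrees, each in
#'   `[5, 88]` (0 is rejected: an erect blade is indistinguishable from
#'   the stalk).
#' @param frame_index 0-based frame number (seeds the noise stream).
#' @param occluded_leaves Integer leaf ids rendered as absent.
#' @return A list: `frame` (a [plant_frame()]), `plant` (clean binary
#'   raster, pre-noise), `leaves` (named list of per-leaf rasters),
#'   `truth` (named vector of chord ground-truth angles, `NA` for
#'   occluded leaves).
#' @export
render_frame <- function(scene, angles, frame_index = 0L,
                         occluded_leaves = integer(0)) {
  stopifnot(inherits(scene, "synthetic_scene"))
  n <- nrow(scene$leaves)
  angles <- rep_len(angles, n)
  if (any(angles < 5 | angles > 88)) {
    stop("leaf angles must lie in [5, 88] degrees from vertical")
  }
  plant <- stalk_raster(scene)
  leaf_masks <- vector("list", n)
  truth <- rep(NA_real_, n)
  names(leaf_masks) <- names(truth) <- scene$leaves$leaf_id
  for (i in seq_len(n)) {
    rl <- rasterize_leaf(scene$leaves[i, ], angles[i], scene)
    occluded <- scene$leaves$leaf_id[i] %in% occluded_leaves
    leaf_masks[[i]] <- if (occluded) matrix(0, scene$height, scene$width) else rl$mask
    truth[i] <- if (occluded) NA_real_ else rl$truth
    if (!occluded) plant <- pmax(plant, rl$mask)
  }
  px <- array(0, dim = c(scene$height, scene$width, 3L))
  for (ch in 1:3) {
    layer <- matrix(scene$background_rgb[ch], scene$height, scene$width)
    layer[plant > 0] <- scene$plant_rgb[ch]
    px[, , ch] <- layer
  }
  if (scene$noise_sd > 0) {
    noise_seed <- (scene$seed %% 100000L) * 10007L + frame_index
    px <- px + with_local_rng(noise_seed,
      array(stats::rnorm(length(px), 0, scene$noise_sd), dim = dim(px)))
  }
  px <- round(pmin(pmax(px, 0), 255))
  list(
    frame = plant_frame(px, filename = sprintf("frame_%04d.png", frame_index + 1L),
                        index = as.integer(frame_index)),
    plant = plant,
    leaves = leaf_masks,
    truth = truth
  )
}

#' Define a wilting schedule
#'
#' Per-leaf angle trajectories across a series:
#' `angle(t) = base + drift_per_frame * t + jitter_sd * eps_t`, clamped to
#' `[5, 88]` degrees. Drift models wilting (a progressive increase in
#' leaf angle under water deficit); jitter models frame-to-frame wobble
#' such as wind. Occlusions name (frame, leaf) pairs where a leaf is
#' invisible.
#'
#' @param n_frames Number of frames.
#' @param base_angles Per-leaf starting angles (degrees from vertical).
#' @param drift_per_frame Per-leaf drift in degrees per frame (recycled).
#' @param jitter_sd SD of i.i.d. Gaussian angle jitter in degrees.
#' @param occlusions `NULL` or a data frame with columns `frame` (0-based)
#'   and `leaf_id`.
#' @param seed Integer seed for the jitter stream.
#' @return A `wilting_schedule` with an `angles` matrix
#'   (`n_frames x n_leaves`) and the occlusion table.
#' @export
wilting_schedule <- function(n_frames, base_angles, drift_per_frame = 0,
                             jitter_sd = 0.5, occlusions = NULL,
                             seed = 1L) {
  stopifnot(n_frames >= 1, all(base_angles >= 5 & base_angles <= 88),
            jitter_sd >= 0)
  k <- length(base_angles)
  drift <- rep_len(drift_per_frame, k)
  t <- 0:(n_frames - 1)
  angles <- outer(t, drift) + matrix(base_angles, n_frames, k, byrow = TRUE)
  if (jitter_sd > 0) {
    angles <- angles + with_local_rng(seed,
      matrix(stats::rnorm(n_frames * k, 0, jitter_sd), n_frames, k))
  }
  angles <- pmin(pmax(angles, 5), 88)
  if (is.null(occlusions)) {
    occlusions <- tibble::tibble(frame = integer(0), leaf_id = integer(0))
  } else {
    occlusions <- tibble::as_tibble(occlusions)
    stopifnot(all(c("frame", "leaf_id") %in% names(occlusions)),
              all(occlusions$frame >= 0 & occlusions$frame < n_frames))
  }
  structure(
    list(n_frames = as.integer(n_frames), angles = angles,
         occlusions = occlusions, jitter_sd = jitter_sd, seed = as.integer(seed)),
    class = "wilting_schedule"
  )
}

#' Render a full synthetic series to disk
#'
#' Writes `n_frames` PNG images with natural-sortable names
#' (`frame_0001.png`, ...) plus a ground-truth CSV
#' (`frame_index, leaf_id, true_angle_deg`, occluded pairs as `NaN`) in
#' the pipeline's CSV dialect.
#'
#' @param scene A [synthetic_scene()].
#' @param schedule A [wilting_schedule()] whose leaf count matches.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `dir`, `truth` (tibble) and the path of
#'   the truth CSV.
#' @export
render_series <- function(scene, schedule, out_dir) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(schedule, "wilting_schedule"),
            ncol(schedule$angles) == nrow(scene$leaves))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  truth_rows <- vector("list", schedule$n_frames)
  for (t in seq_len(schedule$n_frames) - 1L) {
    occ <- schedule$occlusions$leaf_id[schedule$occlusions$frame == t]
    rf <- render_frame(scene, schedule$angles[t + 1L, ],
                       frame_index = t, occluded_leaves = occ)
    png::writePNG(rf$frame$pixels / 255,
                  file.path(out_dir, rf$frame$filename))
    truth_rows[[t + 1L]] <- tibble::tibble(
      frame_index = t,
      leaf_id = scene$leaves$leaf_id,
      true_angle_deg = unname(rf$truth)
    )
  }
  truth <- dplyr::bind_rows(truth_rows)
  truth_path <- file.path(out_dir, "truth.csv")
  lines <- c("frame_index,leaf_id,true_angle_deg",
             sprintf("%d,%d,%s", truth$frame_index, truth$leaf_id,
                     format_angle(truth$true_angle_deg)))
  writeLines(lines, truth_path, sep = "\n")
  invisible(list(dir = out_dir, truth = truth, truth_csv = truth_path))
}

#' Default ROIs and stalk anchor for a synthetic scene
#'
#' Places, for each leaf, a rectangle beside its junction on the leaf's
#' side, offset from the stalk by `margin` pixels so it never touches
#' stalk pixels, and tall/wide enough to contain the blade at any angle a
#' schedule can produce (5-88 degrees). The anchor sits at the bottom
#' center of the stalk.
#'
#' @param scene A [synthetic_scene()].
#' @param margin Gap in pixels between the stalk edge and the ROI
#'   (>= 1).
#' @return A list with `rois` (list of [leaf_roi()]) and `anchor`
#'   (a [stalk_anchor()]).
#' @export
default_rois <- function(scene, margin = 3L) {
  stopifnot(inherits(scene, "synthetic_scene"), margin >= 1)
  sc <- stalk_col_range(scene)
  rois <- vector("list", nrow(scene$leaves))
  for (i in seq_len(nrow(scene$leaves))) {
    lf <- scene$leaves[i, ]
    reach <- ceiling(lf$length)
    th <- ceiling(lf$thickness)
    top <- lf$junction_row - reach - th
    height <- reach + 2L * th
    if (lf$side == "right") {
      left <- sc[2] + 1L + margin
    } else {
      left <- sc[1] - margin - reach
    }
    if (top < 0 || left < 0 || left + reach > scene$width ||
        top + height > scene$height) {
      stop(sprintf("cannot place an ROI for leaf %d: too close to the frame edge",
                   lf$leaf_id))
    }
    rois[[i]] <- leaf_roi(lf$leaf_id, top = top, left = left,
                          height = height, width = reach)
  }
  list(rois = rois,
       anchor = stalk_anchor(scene$height - 1L, scene$stalk_col))
}
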