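#' Stalk anchor point
#'
#' The user-declared bottom-center of the (assumed vertical) stalk, in
#' 0-based pixel coordinates with the origin at the top-left corner.
#'
#' @param row,col Pixel coordinates (0-based).
#' @return A `stalk_anchor` object.
#' @export
stalk_anchor <- function(row, col) {
  stopifnot(row >= 0, col >= 0)
  structure(list(row = as.integer(row), col = as.integer(col)),
            class = "stalk_anchor")
}

#' Leaf region of interest
#'
#' An axis-aligned rectangle placed close to one leaf-stalk junction,
#' without touching the stalk, inside which that leaf's angle is measured
#' on every frame of the series. Half-open extent
#' `[top, top + height) x [left, left + width)`, 0-based.
#'
#' @param leaf_id Small integer naming the leaf.
#' @param top,left Top-left corner (0-based pixels).
#' @param height,width Extent in pixels (both >= 3).
#' @return A `leaf_roi` object.
#' @export
leaf_roi <- function(leaf_id, top, left, height, width) {
  stopifnot(height >= 3, width >= 3, top >= 0, left >= 0)
  structure(
    list(leaf_id = as.integer(leaf_id), top = as.integer(top),
         left = as.integer(left), height = as.integer(height),
         width = as.integer(width)),
    class = "leaf_roi"
  )
}

roi_in_bounds <- function(roi, nrow, ncol) {
  roi$top >= 0 && roi$left >= 0 &&
    roi$top + roi$height <= nrow && roi$left + roi$width <= ncol
}

#' Moment-matched ellipse of a pixel region
#'
#' Computes the ellipse sharing the region's central second moments, the
#' standard region-properties construction: with a +1/12 per-axis
#' correction for the unit pixel area, orientation is
#' `0.5 * atan2(2 * mu11, mu20 - mu02)` in a y-up frame (image rows
#' negated), reported in degrees in `(-90, 90]` from the horizontal axis.
#' Axis lengths follow from the moment eigenvalues. For an isotropic
#' region (equal axis moments, zero cross moment — a lone pixel or a
#' disk), orientation is undefined and returned as `NA`.
#'
#' @param coords Two-column matrix of (row, col) pixel coordinates.
#' @return An `ellipse_fit` list: `centroid`, `major_axis_len`,
#'   `minor_axis_len`, `orientation_deg` (NA when degenerate), `area`.
#' @export
fit_ellipse <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, nrow(coords) >= 1L)
  n <- nrow(coords)
  x <- coords[, 2]
  y <- -coords[, 1] # y points up
  mx <- mean(x); my <- mean(y)
  mu20 <- mean((x - mx)^2) + 1 / 12
  mu02 <- mean((y - my)^2) + 1 / 12
  mu11 <- mean((x - mx) * (y - my))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  orientation <- if (common < 1e-12) {
    NA_real_
  } else {
    deg <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    if (deg <= -90) deg + 180 else deg # map to (-90, 90]
  }
  structure(
    list(
      centroid = c(row = mean(coords[, 1]), col = mx),
      major_axis_len = 2 * sqrt(2) * sqrt(mu20 + mu02 + common),
      minor_axis_len = 2 * sqrt(2) * sqrt(max(mu20 + mu02 - common, 0)),
      orientation_deg = orientation,
      area = n
    ),
    class = "ellipse_fit"
  )
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "<ellipse_fit> area %d px, axes %.1f x %.1f, orientation %s deg\n",
    x$area, x$major_axis_len, x$minor_axis_len,
    if (is.na(x$orientation_deg)) "NA" else sprintf("%.2f", x$orientation_deg)
  ))
  invisible(x)
}

#' Leaf angle from ellipse orientation
#'
#' Converts the major-axis orientation (degrees from horizontal, y-up) to
#' the leaf angle from vertical: `90 - |orientation|`. 0 = fully erect,
#' 90 = horizontal; left- and right-side leaves give the same angle.
#'
#' @param orientation_deg Orientation in `(-90, 90]`.
#' @return Angle in `[0, 90]` degrees.
#' @export
leaf_angle_from_orientation <- function(orientation_deg) {
  stopifnot(all(orientation_deg > -90 & orientation_deg <= 90, na.rm = TRUE))
  90 - abs(orientation_deg)
}

#' Measure one leaf's angle inside its ROI
#'
#' Crops the (already cleaned) plant mask to the ROI, labels 8-connected
#' components, selects the largest with at least `min_area` pixels (ties
#' break to the lowest label), fits the moment ellipse and converts its
#' orientation to degrees from vertical. When no component qualifies —
#' the leaf is occluded or absent — the measurement is missing (`NA`),
#' which is a value, not an error.
#'
#' @param mask Binary plant mask for the full frame.
#' @param roi A [leaf_roi()].
#' @param min_area Minimum component area in pixels.
#' @return Angle in degrees `[0, 90]`, or `NA_real_`.
#' @export
measure_leaf <- function(mask, roi, min_area = 20L) {
  stopifnot(inherits(roi, "leaf_roi"))
  if (!roi_in_bounds(roi, nrow(mask), ncol(mask))) {
    stop(sprintf("ROI for leaf %d exceeds frame bounds", roi$leaf_id))
  }
  crop <- mask[(roi$top + 1L):(roi$top + roi$height),
               (roi$left + 1L):(roi$left + roi$width), drop = FALSE]
  if (!any(crop > 0)) return(NA_real_)
  lc <- label_components(crop)
  areas <- tabulate(lc$labels[lc$labels > 0L], nbins = lc$n)
  if (max(areas) < min_area) return(NA_real_)
  best <- which.max(areas) # first max = lowest label on ties
  fit <- fit_ellipse(which(lc$labels == best, arr.ind = TRUE))
  if (is.na(fit$orientation_deg)) {
    warning(sprintf(
      "leaf %d: isotropic region, orientation undefined; recording missing",
      roi$leaf_id
    ))
    return(NA_real_)
  }
  leaf_angle_from_orientation(fit$orientation_deg)
}

#' Measure leaf angles across a whole series
#'
#' For every frame, segments the plant, cleans the mask, optionally
#' skeletonizes and prunes it, and measures each declared leaf ROI. ROIs
#' are fixed in pixel coordinates and so propagate unchanged to every
#' frame (the camera and plant pot are assumed static). Exactly
#' `n_frames x n_rois` records are returned, with missing angles as `NA`
#' rather than dropped rows; a frame whose segmentation fails (for
#' example a degenerate, plant-free image) yields missing angles for all
#' its leaves and a warning, not an abort.
#'
#' @param series An `image_series`.
#' @param anchor A [stalk_anchor()]; used to warn when an ROI overlaps the
#'   stalk column band.
#' @param rois List of [leaf_roi()] objects (at least one).
#' @param seg A [seg_params()] object.
#' @param morph A [morph_params()] object.
#' @param min_area Minimum qualifying component area within an ROI.
#' @param use_skeleton If `TRUE`, measure on the pruned skeleton instead of
#'   the full connected-component area (the default uses all leaf pixels,
#'   which is less sensitive to thinning artifacts).
#' @param stalk_halfwidth Half-width (px) of the stalk band around the
#'   anchor column used for the ROI-placement warning.
#' @param progress If `TRUE`, log per-frame progress to stderr.
#' @return A tibble of class `leaf_angle_tbl` with columns `frame_index`
#'   (0-based), `filename`, `leaf_id`, `angle_deg`, sorted by
#'   (frame_index, leaf_id).
#' @export
measure_series <- function(series, anchor, rois,
                           seg = seg_params(), morph = morph_params(),
                           min_area = 20L, use_skeleton = FALSE,
                           stalk_halfwidth = 4L, progress = FALSE) {
  stopifnot(inherits(series, "image_series"), length(rois) >= 1L)
  if (inherits(rois, "leaf_roi")) rois <- list(rois)
  h <- series$frames[[1]]$height
  w <- series$frames[[1]]$width
  for (roi in rois) {
    if (!roi_in_bounds(roi, h, w)) {
      stop(sprintf("ROI for leaf %d exceeds the %d x %d frame",
                   roi$leaf_id, h, w))
    }
    if (!is.null(anchor) &&
        roi$left <= anchor$col + stalk_halfwidth &&
        roi$left + roi$width - 1L >= anchor$col - stalk_halfwidth) {
      warning(sprintf(
        "ROI for leaf %d overlaps the stalk column band (col %d +/- %d); place ROIs beside, not on, the stalk",
        roi$leaf_id, anchor$col, stalk_halfwidth
      ))
    }
  }
  leaf_ids <- vapply(rois, function(r) r$leaf_id, integer(1))
  rows <- vector("list", length(series))
  for (i in seq_len(length(series))) {
    frame <- series$frames[[i]]
    if (progress) {
      message(sprintf("frame %d/%d: %s", i, length(series), frame$filename))
    }
    angles <- rep(NA_real_, length(rois))
    mask <- tryCatch({
      m <- segment_plant(frame, seg)
      m <- clean_mask(m, morph)
      if (use_skeleton) m <- prune_skeleton(skeletonize(m), morph$prune_spur_len)
      m
    }, error = function(e) {
      warning(sprintf("frame %d (%s): segmentation failed (%s); recording missing angles",
                      frame$index, frame$filename, conditionMessage(e)))
      NULL
    })
    if (!is.null(mask)) {
      angles <- purrr::map_dbl(rois, function(r) measure_leaf(mask, r, min_area))
    }
    rows[[i]] <- tibble::tibble(
      frame_index = frame$index,
      filename = frame$filename,
      leaf_id = leaf_ids,
      angle_deg = angles
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows),
                        .data$frame_index, .data$leaf_id)
  class(out) <- c("leaf_angle_tbl", class(out))
  out
}
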