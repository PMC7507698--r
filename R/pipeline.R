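format_angle <- function(x) ifelse(is.na(x), "NaN", sprintf("%.2f", x))

#' Assemble a run configuration
#'
#' Bundles everything a headless run needs: where the frames are, which
#' range to analyse, the stalk anchor, the leaf ROIs, and the
#' segmentation/morphology parameters. This replaces the interactive
#' steps of a GUI workflow (stalk click, ROI drawing, threshold slider)
#' with a reproducible declaration.
#'
#' @param input_dir Directory of frames.
#' @param anchor A [stalk_anchor()].
#' @param rois List of [leaf_roi()] (at least one).
#' @param pattern Filename glob for frames.
#' @param first,last Optional 0-based inclusive frame range.
#' @param seg A [seg_params()].
#' @param morph A [morph_params()].
#' @param min_area Minimum qualifying component area within an ROI (px).
#' @param use_skeleton Measure on the pruned skeleton instead of the full
#'   component area.
#' @param output_csv Path for the angle CSV.
#' @param plot_path Optional path for a PNG trajectory plot.
#' @param log_level `"info"` (per-frame progress plus warnings, to stderr)
#'   or `"quiet"` (warnings only).
#' @return A validated `run_config` object.
#' @export
run_config <- function(input_dir, anchor, rois, pattern = "*",
                       first = NULL, last = NULL,
                       seg = seg_params(), morph = morph_params(),
                       min_area = 20L, use_skeleton = FALSE,
                       output_csv = "leaf_angles.csv", plot_path = NULL,
                       log_level = c("quiet", "info")) {
  cfg <- structure(
    list(input_dir = input_dir, pattern = pattern,
         first = first, last = last, anchor = anchor, rois = rois,
         seg = seg, morph = morph, min_area = as.integer(min_area),
         use_skeleton = isTRUE(use_skeleton),
         output_csv = output_csv, plot_path = plot_path,
         log_level = match.arg(log_level)),
    class = "run_config"
  )
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  problems <- character(0)
  if (!is.character(cfg$input_dir) || !dir.exists(cfg$input_dir)) {
    problems <- c(problems,
                  sprintf("input_dir '%s' does not exist", cfg$input_dir))
  }
  if (!inherits(cfg$anchor, "stalk_anchor")) {
    problems <- c(problems, "anchor must be a stalk_anchor")
  }
  if (length(cfg$rois) < 1L ||
      !all(vapply(cfg$rois, inherits, logical(1), "leaf_roi"))) {
    problems <- c(problems, "at least one leaf_roi is required")
  }
  if (!inherits(cfg$seg, "seg_params")) {
    problems <- c(problems, "seg must be a seg_params object")
  }
  if (!inherits(cfg$morph, "morph_params")) {
    problems <- c(problems, "morph must be a morph_params object")
  }
  if (!is.null(cfg$first) && !is.null(cfg$last) && cfg$first > cfg$last) {
    problems <- c(problems, "first must not exceed last")
  }
  if (length(problems) > 0) {
    stop(paste0("invalid run configuration:\n  - ",
                paste(problems, collapse = "\n  - ")))
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file with the fields of [run_config()]
#'   (`anchor: {row, col}`; `rois:` a list of
#'   `{leaf_id, top, left, height, width}`; `seg:`/`morph:` parameter
#'   maps). Relative paths in the file are resolved against the file's
#'   directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  }
  seg <- do.call(seg_params, y$seg %||% list())
  morph <- do.call(morph_params, y$morph %||% list())
  rois <- lapply(y$rois, function(r) do.call(leaf_roi, r))
  run_config(
    input_dir = resolve(y$input_dir),
    pattern = y$pattern %||% "*",
    first = y$first, last = y$last,
    anchor = stalk_anchor(y$anchor$row, y$anchor$col),
    rois = rois, seg = seg, morph = morph,
    min_area = y$min_area %||% 20L,
    use_skeleton = y$use_skeleton %||% FALSE,
    output_csv = resolve(y$output_csv %||% "leaf_angles.csv"),
    plot_path = resolve(y$plot_path),
    log_level = y$log_level %||% "quiet"
  )
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  y <- list(
    input_dir = cfg$input_dir, pattern = cfg$pattern,
    first = cfg$first, last = cfg$last,
    anchor = list(row = cfg$anchor$row, col = cfg$anchor$col),
    rois = lapply(cfg$rois, function(r) {
      list(leaf_id = r$leaf_id, top = r$top, left = r$left,
           height = r$height, width = r$width)
    }),
    seg = cfg$seg[c("channel", "level", "sharpen_radius",
                    "sharpen_amount", "invert")],
    morph = unclass(cfg$morph),
    min_area = cfg$min_area, use_skeleton = cfg$use_skeleton,
    output_csv = cfg$output_csv, log_level = cfg$log_level
  )
  if (!is.null(cfg$plot_path)) y$plot_path <- cfg$plot_path
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write leaf-angle records as CSV
#'
#' Deterministic dialect: comma separators, UNIX newlines, `.` decimal
#' mark, angles with two decimals, missing values as the literal `NaN`.
#' Rows are sorted by (frame_index, leaf_id). Rerunning the same analysis
#' reproduces the file byte for byte.
#'
#' @param records A `leaf_angle_tbl` from [measure_series()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_angles_csv <- function(records, path) {
  stopifnot(all(c("frame_index", "filename", "leaf_id", "angle_deg")
                %in% names(records)))
  records <- dplyr::arrange(records, .data$frame_index, .data$leaf_id)
  lines <- c(
    "frame_index,filename,leaf_id,angle_deg",
    sprintf("%d,%s,%d,%s", records$frame_index, records$filename,
            records$leaf_id, format_angle(records$angle_deg))
  )
  con <- file(path, open = "wb") # binary mode: UNIX newlines everywhere
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a leaf-angle or ground-truth CSV
#'
#' @param path CSV written by [write_angles_csv()] or [render_series()].
#' @return A tibble; `NaN` angle fields come back as missing values.
#' @export
read_angles_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run the full measurement pipeline
#'
#' Loads the frame series, measures every declared leaf on every frame,
#' writes the angle CSV (and, if configured, a trajectory plot), and logs
#' per-frame warnings to stderr. The output path is checked before any
#' processing starts.
#'
#' @param cfg A [run_config()].
#' @param output_csv Optional override of the configured CSV path.
#' @return The records tibble, invisibly, with attribute `csv` giving the
#'   output path.
#' @export
run_pipeline <- function(cfg, output_csv = NULL) {
  validate_run_config(cfg)
  out <- output_csv %||% cfg$output_csv
  ok <- tryCatch(suppressWarnings({
    con <- file(out, open = "ab"); close(con); TRUE
  }), error = function(e) FALSE)
  if (!ok) stop(sprintf("output path '%s' is not writable", out))
  series <- load_series(cfg$input_dir, cfg$pattern)
  if (!is.null(cfg$first) || !is.null(cfg$last)) {
    series <- select_range(series, cfg$first %||% 0L,
                           cfg$last %||% (length(series) - 1L))
  }
  records <- measure_series(series, cfg$anchor, cfg$rois,
                            seg = cfg$seg, morph = cfg$morph,
                            min_area = cfg$min_area,
                            use_skeleton = cfg$use_skeleton,
                            progress = identical(cfg$log_level, "info"))
  write_angles_csv(records, out)
  message(sprintf("wrote %d records (%d frames x %d leaves) to %s",
                  nrow(records), length(series), length(cfg$rois), out))
  if (!is.null(cfg$plot_path)) {
    ggplot2::ggsave(cfg$plot_path, ggplot2::autoplot(records),
                    width = 7, height = 4, dpi = 150)
  }
  attr(records, "csv") <- out
  invisible(records)
}

#' Validate measured angles against ground truth
#'
#' Joins measured records with a truth table on (frame_index, leaf_id),
#' keeps pairs where both values are present, and reports the sample
#' Pearson correlation, the mean absolute error in degrees, and the pair
#' count — the same summary used to compare automated measurements with
#' manual protractor readings.
#'
#' @param records Tibble with `frame_index`, `leaf_id`, `angle_deg`.
#' @param truth Tibble with `frame_index`, `leaf_id`, `true_angle_deg`
#'   (an `angle_deg` column is also accepted).
#' @return An `angle_validation` object with fields `pearson_r`,
#'   `mean_abs_err_deg`, `n`.
#' @export
validate_against_truth <- function(records, truth) {
  truth <- tibble::as_tibble(truth)
  if (!"true_angle_deg" %in% names(truth) && "angle_deg" %in% names(truth)) {
    truth <- dplyr::rename(truth, true_angle_deg = "angle_deg")
  }
  stopifnot(all(c("frame_index", "leaf_id", "angle_deg") %in% names(records)),
            all(c("frame_index", "leaf_id", "true_angle_deg") %in% names(truth)))
  joined <- dplyr::inner_join(
    records[, c("frame_index", "leaf_id", "angle_deg")],
    truth[, c("frame_index", "leaf_id", "true_angle_deg")],
    by = c("frame_index", "leaf_id")
  )
  joined <- joined[!is.na(joined$angle_deg) & !is.na(joined$true_angle_deg), ]
  if (nrow(joined) < 3L) {
    stop(sprintf("insufficient pairs: %d matched non-missing pair(s), need >= 3",
                 nrow(joined)))
  }
  structure(
    list(
      pearson_r = stats::cor(joined$angle_deg, joined$true_angle_deg),
      mean_abs_err_deg = mean(abs(joined$angle_deg - joined$true_angle_deg)),
      n = nrow(joined)
    ),
    class = "angle_validation"
  )
}

#' @export
print.angle_validation <- function(x, ...) {
  cat(sprintf(
    "<angle_validation> n = %d pairs, Pearson r = %.3f, MAE = %.2f deg\n",
    x$n, x$pearson_r, x$mean_abs_err_deg
  ))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname validate_against_truth
#' @param x An `angle_validation` object.
#' @param ... Unused.
#' @method glance angle_validation
#' @export
glance.angle_validation <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r,
                 mean_abs_err_deg = x$mean_abs_err_deg,
                 n = x$n)
}

#' @rdname validate_against_truth
#' @method tidy angle_validation
#' @export
tidy.angle_validation <- function(x, ...) {
  tibble::tibble(
    statistic = c("pearson_r", "mean_abs_err_deg", "n"),
    value = c(x$pearson_r, x$mean_abs_err_deg, x$n)
  )
}
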