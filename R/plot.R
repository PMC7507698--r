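#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-leaf angle trajectories
#'
#' One line per leaf, angle from vertical against frame index. Missing
#' (occluded) measurements leave gaps rather than interpolating across
#' them.
#'
#' @param object A `leaf_angle_tbl` from [measure_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot leaf_angle_tbl
#' @export
autoplot.leaf_angle_tbl <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$frame_index, y = .data$angle_deg,
                 color = factor(.data$leaf_id), group = .data$leaf_id)
  ) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 90)) +
    ggplot2::labs(x = "frame", y = "leaf angle from vertical (deg)",
                  color = "leaf") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.leaf_angle_tbl
#' @param records A `leaf_angle_tbl`.
#' @export
plot_trajectories <- function(records, ...) autoplot.leaf_angle_tbl(records, ...)

#' Per-leaf summary of a measured series
#'
#' @param x A `leaf_angle_tbl`.
#' @param ... Unused.
#' @return One row per leaf: frame count, missing count, mean/min/max
#'   angle and net change (last minus first non-missing value), the
#'   quantity that flags a wilting leaf.
#' @method glance leaf_angle_tbl
#' @export
glance.leaf_angle_tbl <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$leaf_id),
    n_frames = dplyr::n(),
    n_missing = sum(is.na(.data$angle_deg)),
    mean_angle_deg = mean(.data$angle_deg, na.rm = TRUE),
    min_angle_deg = min(.data$angle_deg, na.rm = TRUE),
    max_angle_deg = max(.data$angle_deg, na.rm = TRUE),
    net_change_deg = {
      v <- .data$angle_deg[!is.na(.data$angle_deg)]
      if (length(v) >= 2) v[length(v)] - v[1] else NA_real_
    },
    .groups = "drop"
  )
}
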