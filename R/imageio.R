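#' Construct a single frame
#'
#' A frame is the in-memory representation of one still image: an
#' `height x width x 3` numeric array with channel intensities on the
#' `[0, 255]` scale (16-bit inputs are rescaled at load so one internal
#' intensity scale serves all thresholds), plus its source filename and its
#' 0-based position in the series.
#'
#' @param pixels `H x W x 3` numeric array, values in `[0, 255]`.
#' @param filename Source filename (basename, no directory).
#' @param index 0-based position of the frame within its series.
#' @return An object of class `plant_frame`.
#' @export
plant_frame <- function(pixels, filename = "<in-memory>", index = 0L) {
  if (length(dim(pixels)) == 2L) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("frame intensities must lie in [0, 255]")
  }
  structure(
    list(
      pixels = pixels,
      filename = filename,
      index = as.integer(index),
      height = dim(pixels)[1],
      width = dim(pixels)[2]
    ),
    class = "plant_frame"
  )
}

#' @export
print.plant_frame <- function(x, ...) {
  cat(sprintf(
    "<plant_frame> %s  [%d x %d px, index %d]\n",
    x$filename, x$height, x$width, x$index
  ))
  invisible(x)
}

new_image_series <- function(frames, source_dir) {
  structure(list(frames = frames, source_dir = source_dir),
            class = "image_series")
}

#' @export
length.image_series <- function(x) length(x$frames)

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %d frame(s) from %s\n",
              length(x), x$source_dir))
  if (length(x) > 0) {
    h <- x$frames[[1]]
    cat(sprintf("  frame size: %d x %d px\n", h$height, h$width))
    cat(sprintf("  first: %s  last: %s\n",
                x$frames[[1]]$filename, x$frames[[length(x)]]$filename))
  }
  invisible(x)
}

#' Retrieve one frame from a series
#'
#' @param series An `image_series`.
#' @param index 0-based frame index.
#' @return The `plant_frame` at that position.
#' @export
get_frame <- function(series, index) {
  stopifnot(inherits(series, "image_series"))
  if (index < 0 || index >= length(series)) {
    stop(sprintf("frame index %d out of range [0, %d]",
                 index, length(series) - 1L))
  }
  series$frames[[index + 1L]]
}

# Natural-sort key: digit runs compare as integers, so img_2 < img_10.
natural_sort_key <- function(x) {
  vapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    parts <- vapply(parts, function(p) {
      if (grepl("^[0-9]+$", p)) sprintf("%020d", as.numeric(p)) else p
    }, character(1))
    paste(parts, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

natural_sort <- function(x) x[order(natural_sort_key(x), x, method = "radix")]

# Decode one image file to an H x W x 3 array on the [0, 255] scale.
read_frame_pixels <- function(path) {
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) stop(sprintf("cannot decode image file '%s': %s",
                                     basename(path), conditionMessage(e)))
  )
  px <- EBImage::imageData(img) # x (col) by y (row) [by channel]
  if (length(dim(px)) == 2L) {
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  } else if (dim(px)[3] > 3L) {
    px <- px[, , 1:3, drop = FALSE] # drop alpha
  } else if (dim(px)[3] == 2L) {    # gray + alpha
    px <- array(rep(px[, , 1], 3L), dim = c(dim(px)[1:2], 3L))
  }
  px <- aperm(px, c(2L, 1L, 3L)) * 255
  px[px < 0] <- 0
  px[px > 255] <- 255
  px
}

#' Load a directory of time-lapse frames as one series
#'
#' All images in a folder that match `pattern` are loaded and ordered by
#' natural filename sort (digit runs compared as integers), which keeps a
#' time-stamped or counter-named capture sequence in shooting order
#' regardless of copy dates. Grayscale inputs are promoted to three
#' identical channels; every frame must share the same pixel dimensions.
#'
#' @param dir Directory containing the frames.
#' @param pattern Filename glob (default `"*"` matches any of the supported
#'   formats: PNG, JPEG, TIFF).
#' @return An `image_series` with 0-based contiguous frame indices.
#' @examples
#' \dontrun{
#' series <- load_series("plant01/", "frame_*.png")
#' }
#' @export
load_series <- function(dir, pattern = "*") {
  if (!dir.exists(dir)) stop(sprintf("directory '%s' does not exist", dir))
  files <- list.files(dir, pattern = utils::glob2rx(pattern))
  files <- files[grepl("\\.(png|jpe?g|tiff?)$", files, ignore.case = TRUE)]
  if (length(files) == 0) {
    stop(sprintf("no frames in '%s' match pattern '%s'", dir, pattern))
  }
  files <- natural_sort(files)
  frames <- vector("list", length(files))
  ref_dim <- NULL
  for (i in seq_along(files)) {
    px <- read_frame_pixels(file.path(dir, files[i]))
    if (is.null(ref_dim)) {
      ref_dim <- dim(px)[1:2]
    } else if (!identical(dim(px)[1:2], ref_dim)) {
      stop(sprintf(
        "inconsistent frame size: '%s' is %d x %d but series is %d x %d",
        files[i], dim(px)[1], dim(px)[2], ref_dim[1], ref_dim[2]
      ))
    }
    frames[[i]] <- plant_frame(px, filename = files[i], index = i - 1L)
  }
  new_image_series(frames, normalizePath(dir))
}

#' Restrict a series to a frame range
#'
#' Selects the sub-series from `first` to `last` (0-based, inclusive), the
#' programmatic equivalent of picking the first and last image of the
#' sequence to analyse. Indices are re-based to `0..(last - first)`;
#' original filenames are preserved.
#'
#' @param series An `image_series`.
#' @param first,last 0-based inclusive bounds, `0 <= first <= last < n`.
#' @return A new `image_series`.
#' @export
select_range <- function(series, first, last) {
  stopifnot(inherits(series, "image_series"))
  n <- length(series)
  if (first < 0 || last >= n || first > last) {
    stop(sprintf(
      "invalid frame range [%d, %d] for a series of %d frame(s)",
      first, last, n
    ))
  }
  frames <- series$frames[(first + 1L):(last + 1L)]
  for (i in seq_along(frames)) frames[[i]]$index <- i - 1L
  new_image_series(frames, series$source_dir)
}
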