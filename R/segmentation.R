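#' Segmentation parameters
#'
#' Controls how a frame is turned into a binary plant mask. The blue
#' channel is the default because chlorophyll-rich tissue reflects little
#' blue light, so a green plant is dark against a brighter background in
#' that channel. Thresholding is always interpreted on the complemented
#' (plant-bright) grayscale; `invert = FALSE` selects the background side
#' of the same threshold instead.
#'
#' @param channel One of `"red"`, `"green"`, `"blue"`, `"luminance"`.
#' @param level Threshold in `[0, 1]` on the complemented grayscale, or
#'   `"otsu"` (default) to pick it per frame by Otsu's method.
#' @param sharpen_radius Gaussian radius (pixels) of the unsharp mask.
#' @param sharpen_amount Unsharp gain; `0` disables sharpening.
#' @param invert If `TRUE` (default) the mask marks the plant (dark pixels);
#'   if `FALSE` it marks the background.
#' @return A `seg_params` list.
#' @export
seg_params <- function(channel = "blue", level = "otsu",
                       sharpen_radius = 1.0, sharpen_amount = 0.8,
                       invert = TRUE) {
  channel <- match.arg(channel, c("red", "green", "blue", "luminance"))
  if (is.character(level)) {
    if (!identical(level, "otsu")) stop("level must be numeric or \"otsu\"")
  } else {
    stopifnot(is.numeric(level), length(level) == 1L, level >= 0, level <= 1)
  }
  stopifnot(sharpen_radius > 0, sharpen_amount >= 0)
  structure(
    list(channel = channel, level = level,
         sharpen_radius = sharpen_radius, sharpen_amount = sharpen_amount,
         invert = isTRUE(invert)),
    class = "seg_params"
  )
}

#' Extract a grayscale image from a frame
#'
#' Returns the chosen channel rescaled to `[0, 1]`; `"luminance"` is the
#' Rec. 601 weighted sum 0.299 R + 0.587 G + 0.114 B.
#'
#' @param frame A `plant_frame`.
#' @param channel `"red"`, `"green"`, `"blue"` or `"luminance"`.
#' @return Numeric matrix in `[0, 1]`.
#' @export
to_gray <- function(frame, channel = "blue") {
  stopifnot(inherits(frame, "plant_frame"))
  channel <- match.arg(channel, c("red", "green", "blue", "luminance"))
  px <- frame$pixels / 255
  switch(channel,
    red = px[, , 1],
    green = px[, , 2],
    blue = px[, , 3],
    luminance = 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  )
}

#' Otsu threshold of a grayscale image
#'
#' Bins intensities into 256 levels (`round(g * 255)`) and finds the bin
#' split maximising the between-class variance `w0 w1 (mu0 - mu1)^2`;
#' ties break to the lowest bin so the result is bit-for-bit
#' reproducible. The returned level is the upper boundary
#' `(k + 0.5)/255` of the maximising bin, so every pixel binned at or
#' below `k` falls strictly below the threshold.
#'
#' @param gray Numeric matrix in `[0, 1]`.
#' @return Threshold level in `[0, 1)`.
#' @export
otsu_threshold <- function(gray) {
  g <- as.numeric(gray)
  stopifnot(all(g >= 0), all(g <= 1))
  bins <- pmin(pmax(round(g * 255), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L) {
    stop("degenerate histogram: image has fewer than 2 distinct intensity levels")
  }
  n <- length(g)
  p <- counts / n
  lev <- 0:255
  w0 <- cumsum(p)
  m0 <- cumsum(p * lev)
  mt <- m0[256]
  # between-class variance for split after bin k (k = 0..254)
  w0k <- w0[1:255]
  w1k <- 1 - w0k
  num <- (mt * w0k - m0[1:255])^2
  sb <- ifelse(w0k > 0 & w1k > 0, num / (w0k * w1k), 0)
  k <- which.max(sb) - 1L # which.max takes the first (lowest) maximising bin
  (k + 0.5) / 255
}

# Normalised 1D Gaussian taps covering +/- 3 sigma; the 2D kernel is
# their outer product (the Gaussian is separable).
gaussian_taps <- function(radius) {
  k <- as.integer(ceiling(3 * radius))
  w <- stats::dnorm(-k:k, sd = radius)
  w / sum(w)
}

# One-dimensional smoothing operator of size n as a banded matrix with
# replicated (clamped) borders; cached per (n, radius) since frame sizes
# repeat across a series.
.blur_cache <- new.env(parent = emptyenv())
smoothing_matrix <- function(n, radius) {
  key <- sprintf("%d_%g", n, radius)
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- gaussian_taps(radius)
  k <- (length(w) - 1L) %/% 2L
  S <- matrix(0, n, n)
  for (o in -k:k) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n) # replicate boundary
    S[cbind(seq_len(n), idx)] <- S[cbind(seq_len(n), idx)] + w[o + k + 1L]
  }
  .blur_cache[[key]] <- S
  S
}

# Separable Gaussian blur with replicated borders: R %*% X %*% t(C).
gaussian_blur <- function(x, radius) {
  smoothing_matrix(nrow(x), radius) %*% x %*%
    t(smoothing_matrix(ncol(x), radius))
}

#' Unsharp-mask sharpening
#'
#' Sharpens by adding back the difference between the image and a
#' Gaussian-blurred copy: `clip(g + amount * (g - blur(g, radius)), 0, 1)`.
#' The blur uses replicated borders so edges are not wrapped.
#'
#' @param gray Numeric matrix in `[0, 1]`.
#' @param radius Gaussian sigma in pixels (> 0).
#' @param amount Gain (>= 0); `0` returns the input unchanged.
#' @return Sharpened matrix in `[0, 1]`.
#' @export
sharpen <- function(gray, radius = 1.0, amount = 0.8) {
  stopifnot(radius > 0, amount >= 0)
  if (amount == 0) return(gray)
  blurred <- gaussian_blur(gray, radius)
  out <- gray + amount * (gray - blurred)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Image complement
#'
#' Subtracts each pixel from the maximum representable intensity
#' (`1 - g` on the unit scale), turning the dark plant into the bright,
#' active object.
#'
#' @param gray Numeric matrix in `[0, 1]`.
#' @return `1 - gray`.
#' @export
complement <- function(gray) {
  stopifnot(min(gray) >= 0, max(gray) <= 1)
  1 - gray
}

#' Binarize a grayscale image
#'
#' Pixels strictly greater than `level` become 1, all others 0.
#'
#' @param gray Numeric matrix in `[0, 1]`.
#' @param level Threshold in `[0, 1]`.
#' @return Binary matrix of 0/1.
#' @export
binarize <- function(gray, level) {
  stopifnot(level >= 0, level <= 1)
  (gray > level) * 1
}

#' Segment a frame into a binary plant mask
#'
#' Runs the full foreground/background separation in order: channel
#' extraction, unsharp sharpening, complement, thresholding. With
#' `level = "otsu"` the threshold is chosen on the complemented image of
#' each frame; a numeric `level` overrides it on the same (plant-bright)
#' scale. `invert = FALSE` returns the exact complement of the plant mask.
#'
#' @param frame A `plant_frame`.
#' @param params A [seg_params()] object.
#' @return Binary matrix, 1 = plant (or background when `invert = FALSE`).
#' @export
segment_plant <- function(frame, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  g <- to_gray(frame, params$channel)
  g <- sharpen(g, params$sharpen_radius, params$sharpen_amount)
  g <- complement(g)
  level <- if (identical(params$level, "otsu")) otsu_threshold(g) else params$level
  m <- binarize(g, level)
  if (!params$invert) m <- 1 - m
  m
}
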