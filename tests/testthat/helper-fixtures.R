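# Programmatic fixtures shared across test files.

# A flat-colored PNG written to `dir`, returning its path.
write_flat_png <- function(dir, name, h = 8, w = 8, rgb = c(0.5, 0.5, 0.5)) {
  px <- array(rep(rgb, each = h * w), dim = c(h, w, 3))
  path <- file.path(dir, name)
  png::writePNG(px, path)
  path
}

# Random blobby binary mask: union of a few thick random strokes plus
# optional speckles; used for skeleton/labeling property tests.
random_blob_mask <- function(n = 48, strokes = 3, speckles = 0) {
  m <- matrix(0, n, n)
  for (s in seq_len(strokes)) {
    r0 <- stats::runif(1, 5, n - 5)
    c0 <- stats::runif(1, 5, n - 5)
    ang <- stats::runif(1, 0, pi)
    len <- stats::runif(1, n / 4, n / 2)
    ts <- seq(0, len, by = 0.5)
    r <- round(r0 + ts * sin(ang))
    c <- round(c0 + ts * cos(ang))
    for (dr in -1:1) {
      for (dc in -1:1) {
        ok <- r + dr >= 1 & r + dr <= n & c + dc >= 1 & c + dc <= n
        m[cbind(r[ok] + dr, c[ok] + dc)] <- 1
      }
    }
  }
  if (speckles > 0) {
    idx <- sample(n * n, speckles)
    m[idx] <- 1
  }
  m
}

# A small synthetic scene used where full realism is not needed.
tiny_scene <- function(..., seed = 7) {
  synthetic_scene(width = 256, height = 220, noise_sd = 0, seed = seed, ...)
}

# Render a scene+schedule into a temp dir and return paths + truth.
render_tmp_series <- function(scene, schedule) {
  dir <- file.path(tempdir(), paste0("series_", as.integer(stats::runif(1, 1, 1e8))))
  rs <- render_series(scene, schedule, dir)
  rs$dir <- dir
  rs
}
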