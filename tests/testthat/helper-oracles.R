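# Independent oracles used by the tests. These deliberately use naive
# implementations (exhaustive scans, nested loops, flood fill, eigen
# decomposition) so they share no code path with the package.

# Exhaustive-scan Otsu: best split bin over all 255 candidate splits of a
# 256-bin histogram, maximising w0*w1*(mu0-mu1)^2, lowest bin on ties.
oracle_otsu_bin <- function(gray) {
  bins <- pmin(pmax(round(as.numeric(gray) * 255), 0), 255)
  n <- length(bins)
  best <- -Inf
  best_k <- NA_integer_
  for (k in 0:254) {
    left <- bins <= k
    n0 <- sum(left)
    n1 <- n - n0
    v <- if (n0 == 0L || n1 == 0L) 0 else {
      (n0 / n) * (n1 / n) * (mean(bins[left]) - mean(bins[!left]))^2
    }
    if (v > best) { # strict: first (lowest) maximising bin wins
      best <- v
      best_k <- k
    }
  }
  best_k
}

# The bin the package's threshold corresponds to (level is the upper
# boundary (k + 0.5)/255 of the maximising bin).
package_otsu_bin <- function(gray) {
  as.integer(round(otsu_threshold(gray) * 255 - 0.5))
}

# Direct nested-loop 2D convolution with replicated borders.
oracle_conv2_replicate <- function(x, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      acc <- 0
      for (a in -kr:kr) {
        for (b in -kc:kc) {
          ii <- min(max(i + a, 1L), nrow(x))
          jj <- min(max(j + b, 1L), ncol(x))
          acc <- acc + x[ii, jj] * kernel[a + kr + 1L, b + kc + 1L]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Principal-eigenvector orientation of a point set's covariance, mapped
# to (-90, 90] degrees from horizontal in a y-up frame.
oracle_orientation <- function(coords) {
  x <- coords[, 2]
  y <- -coords[, 1]
  e <- eigen(stats::cov(cbind(x, y)))
  v <- e$vectors[, 1]
  a <- atan2(v[2], v[1]) * 180 / pi
  if (a <= -90) a <- a + 180
  if (a > 90) a <- a - 180
  a
}

# Smallest absolute difference between two axial (mod 180) angles.
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# Breadth-first flood fill, 8-connected: returns the number of
# components of a binary matrix.
oracle_component_count <- function(mask) {
  m <- mask > 0
  nr <- nrow(m)
  nc <- ncol(m)
  count <- 0L
  while (any(m)) {
    count <- count + 1L
    seed <- which(m)[1]
    queue <- seed
    m[seed] <- FALSE
    while (length(queue) > 0) {
      p <- queue[1]
      queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) {
        for (dc in -1:1) {
          r2 <- r + dr
          c2 <- c + dc
          if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
            q <- (c2 - 1L) * nr + r2
            if (m[q]) {
              m[q] <- FALSE
              queue <- c(queue, q)
            }
          }
        }
      }
    }
  }
  count
}

# Textbook Pearson correlation from first principles.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
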