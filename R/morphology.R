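#' Morphology parameters
#'
#' Knobs for binary-mask cleanup between segmentation and angle
#' measurement. `min_blob_area` is calibrated to frame resolution: the
#' default 50 px suits multi-megapixel captures; proportionally smaller
#' values fit downscaled fixtures.
#'
#' @param thicken_iters How many times to fatten thin (sub-3-px) structures.
#' @param min_blob_area Connected components smaller than this many pixels
#'   are removed as speckle noise.
#' @param bridge Whether to connect 0-pixels whose neighborhoods contain
#'   two mutually non-adjacent foreground pixels (closes 1-px breaks).
#' @param prune_spur_len Iterations of endpoint removal used when a
#'   skeleton is pruned downstream.
#' @return A `morph_params` list.
#' @export
morph_params <- function(thicken_iters = 1L, min_blob_area = 50L,
                         bridge = TRUE, prune_spur_len = 10L) {
  stopifnot(thicken_iters >= 0, min_blob_area >= 0, prune_spur_len >= 0)
  structure(
    list(thicken_iters = as.integer(thicken_iters),
         min_blob_area = as.integer(min_blob_area),
         bridge = isTRUE(bridge),
         prune_spur_len = as.integer(prune_spur_len)),
    class = "morph_params"
  )
}

# Value of the neighbor at offset (dr, dc); pixels outside the image read
# as `pad`.
nbr <- function(m, dr, dc, pad = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc, drop = FALSE]
  out
}

# Ring of 8-neighbor offsets in clockwise order starting north.
RING_OFFSETS <- list(
  c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
  c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L)
)

# 3x3 box dilation/erosion, separable (row pass then column pass) for
# speed on full frames. Erosion with `pad = 0` zeroes the image border
# (outside counts as background); `pad = 1` treats outside as foreground,
# the convention that keeps a closing from shaving objects touching the
# frame edge.
dilate3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m <- pmax(m, m[c(1L, seq_len(nr - 1L)), , drop = FALSE],
            m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE])
  pmax(m, m[, c(1L, seq_len(nc - 1L)), drop = FALSE],
       m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE])
}

erode3 <- function(m, pad = 1) {
  nr <- nrow(m); nc <- ncol(m)
  m <- pmin(m, m[c(1L, seq_len(nr - 1L)), , drop = FALSE],
            m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE])
  m <- pmin(m, m[, c(1L, seq_len(nc - 1L)), drop = FALSE],
            m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE])
  if (pad == 0) {
    m[c(1L, nr), ] <- 0
    m[, c(1L, nc)] <- 0
  }
  m
}

open3 <- function(m) dilate3(erode3(m, pad = 0))
close3 <- function(m) erode3(dilate3(m), pad = 1)

# Fatten structures thinner than 3 px (the parts removed by a 3x3
# opening) by one dilation, leaving already-thick bodies untouched. This
# reaches a fixed point, so repeated cleanup is stable, unlike a plain
# dilation which grows without bound.
thicken_once <- function(m) {
  thin <- m * (1 - open3(m))
  if (!any(thin > 0)) return(m)
  pmax(m, dilate3(thin))
}

# Lookup table over the 256 possible 8-neighborhood patterns: TRUE when
# the foreground neighbors of a background pixel form two or more
# connected groups *within* the neighborhood (adjacency among the ring
# cells themselves: consecutive ring cells touch, and so do the
# orthogonal pairs N-E, E-S, S-W, W-N across a missing diagonal).
# Setting such a pixel to 1 bridges a genuine 1-px break; neighbors that
# already connect through the ring (for example NE and SE through E) do
# not trigger it.
bridge_lut <- local({
  touching <- c(lapply(1:8, function(i) c(i, i %% 8L + 1L)),
                list(c(1L, 3L), c(3L, 5L), c(5L, 7L), c(7L, 1L)))
  lut <- logical(256)
  for (pat in 0:255) {
    present <- which(bitwAnd(pat, bitwShiftL(1L, 0:7)) > 0)
    if (length(present) < 2) next
    comp <- seq_along(present)
    repeat {
      changed <- FALSE
      for (e in touching) {
        i <- match(e[1], present)
        j <- match(e[2], present)
        if (!is.na(i) && !is.na(j) && comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    lut[pat + 1L] <- length(unique(comp)) >= 2
  }
  lut
})

# Set 0-pixels to 1 when their foreground neighbors are not connected
# within the 8-neighborhood (a 1-px break in a line). One pass; only
# background pixels adjacent to foreground can qualify.
bridge_gaps <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  cand <- which(m == 0 & dilate3(m) > 0)
  if (length(cand) == 0) return(m)
  M <- matrix(0, nr + 2, nc + 2)
  M[2:(nr + 1), 2:(nc + 1)] <- m
  r <- ((cand - 1L) %% nr) + 2L
  c <- ((cand - 1L) %/% nr) + 2L
  pat <- integer(length(cand))
  for (i in 1:8) {
    o <- RING_OFFSETS[[i]]
    pat <- pat + bitwShiftL(as.integer(M[cbind(r + o[1], c + o[2])] > 0), i - 1L)
  }
  m[cand[bridge_lut[pat + 1L]]] <- 1
  m
}

#' Clean a binary plant mask
#'
#' Applies, in order: thickening of thin structures (emphasises the stalk
#' and thin blades), bridging of 1-px breaks, a 3x3 morphological closing
#' to fill remaining single-pixel gaps, and removal of 8-connected
#' components smaller than `min_blob_area` (speckle from sensor noise).
#'
#' @param mask Binary matrix (0/1).
#' @param params A [morph_params()] object.
#' @return Cleaned binary matrix.
#' @export
clean_mask <- function(mask, params = morph_params()) {
  m <- (mask > 0) * 1
  for (i in seq_len(params$thicken_iters)) m <- thicken_once(m)
  if (params$bridge) m <- bridge_gaps(m)
  m <- close3(m)
  if (params$min_blob_area > 0 && any(m > 0)) {
    lc <- label_components(m)
    areas <- tabulate(lc$labels[lc$labels > 0L], nbins = lc$n)
    keep <- areas >= params$min_blob_area
    m <- matrix(as.numeric(lc$labels > 0L & keep[pmax(lc$labels, 1L)]),
                nrow(m), ncol(m))
  }
  m
}

# Yokoi connectivity number for 8-connected foreground at padded position
# (r, c); the pixel is "simple" (deletable without changing topology) iff
# the number equals 1.
yokoi_nc8 <- function(M, r, c) {
  x <- c(M[r, c + 1], M[r - 1, c + 1], M[r - 1, c], M[r - 1, c - 1],
         M[r, c - 1], M[r + 1, c - 1], M[r + 1, c], M[r + 1, c + 1])
  xb <- 1 - x
  s <- 0L
  for (k in c(1L, 3L, 5L, 7L)) {
    k1 <- if (k == 7L) 8L else k + 1L
    k2 <- if (k >= 7L) k - 6L else k + 2L
    s <- s + xb[k] - xb[k] * xb[k1] * xb[k2]
  }
  s
}

#' Skeletonize a binary mask
#'
#' Thins the foreground to a ~1-px-wide curve while preserving
#' connectivity. Each round runs four directional subpasses (north,
#' south, east, west border pixels in turn) so objects erode
#' symmetrically from all sides; within a subpass, pixels are deleted
#' sequentially and only when topologically simple (Yokoi connectivity
#' number 1) and not endpoints, which guarantees that the number of
#' 8-connected components never changes and that line ends are not eaten
#' away. Every skeleton pixel lies on the input mask.
#'
#' @param mask Binary matrix (0/1).
#' @return Binary skeleton matrix.
#' @export
skeletonize <- function(mask) {
  m <- (mask > 0) * 1
  nr <- nrow(m); nc <- ncol(m)
  M <- matrix(0, nr + 2, nc + 2)
  M[2:(nr + 1), 2:(nc + 1)] <- m
  dirs <- list(c(-1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, -1L))
  repeat {
    changed <- FALSE
    for (d in dirs) {
      inner <- M[2:(nr + 1), 2:(nc + 1)]
      border <- inner == 1 & nbr(inner, d[1], d[2]) == 0
      idx <- which(border, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      for (i in seq_len(nrow(idx))) {
        r <- idx[i, 1] + 1L; c <- idx[i, 2] + 1L
        if (M[r, c] == 0) next
        B <- M[r - 1, c - 1] + M[r - 1, c] + M[r - 1, c + 1] +
             M[r, c - 1] + M[r, c + 1] +
             M[r + 1, c - 1] + M[r + 1, c] + M[r + 1, c + 1]
        if (B < 2 || B > 7) next # keep endpoints and isolated/interior pixels
        if (yokoi_nc8(M, r, c) == 1L) {
          M[r, c] <- 0
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  M[2:(nr + 1), 2:(nc + 1)]
}

#' Prune skeleton spurs
#'
#' Iteratively deletes endpoint pixels (exactly one 8-neighbor) `spur_len`
#' times, removing short side branches left by thinning. Closed loops have
#' no endpoints and are untouched; an isolated component shorter than
#' `spur_len` disappears entirely.
#'
#' @param skeleton Binary skeleton matrix.
#' @param spur_len Maximum number of endpoint-removal passes.
#' @return Pruned binary matrix.
#' @export
prune_skeleton <- function(skeleton, spur_len = 10L) {
  stopifnot(spur_len >= 0)
  m <- (skeleton > 0) * 1
  for (i in seq_len(spur_len)) {
    nsum <- Reduce(`+`, lapply(RING_OFFSETS, function(o) nbr(m, o[1], o[2])))
    endpoints <- m == 1 & nsum == 1
    if (!any(endpoints)) break
    m[endpoints] <- 0
  }
  m
}

#' Label 8-connected components
#'
#' Assigns a distinct positive integer label to every 8-connected
#' component of foreground pixels (pixels touching by edge or corner
#' belong together); background stays 0. Labels follow raster-scan
#' first-encounter order, so the labelling is deterministic.
#'
#' @param mask Binary matrix (0/1).
#' @return A list with `labels` (integer matrix) and `n` (component count).
#' @export
label_components <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  labels <- matrix(0L, nr, nc)
  fg <- which(m)
  n_fg <- length(fg)
  if (n_fg == 0L) return(list(labels = labels, n = 0L))
  vid <- integer(nr * nc)
  vid[fg] <- seq_len(n_fg)
  rows <- ((fg - 1L) %% nr) + 1L
  cols <- ((fg - 1L) %/% nr) + 1L
  edges <- vector("list", 4L)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    r2 <- rows + o[1]; c2 <- cols + o[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- m[j]
    edges[[k]] <- rbind(vid[fg[ok][keep]], vid[j[keep]])
  }
  edges <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, as.vector(edges))
  memb <- igraph::components(g)$membership
  ord <- order(rows, cols)
  first_seen <- memb[ord][!duplicated(memb[ord])]
  lab <- match(memb, first_seen)
  labels[fg] <- lab
  list(labels = labels, n = max(lab))
}
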