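# Low-level raster helpers shared by all image operations.
#
# Conventions (used package-wide):
#   * images and masks are base R matrices, H x W; row = y (top to bottom),
#     col = x (left to right); R indices are 1-based, exported CSV is 0-based
#   * connectivity is 8 for foreground components and for holes
#   * disk structuring elements are {p : ||p||_2 <= r} on the pixel grid
#   * outside-image pixels act as background (-Inf for max filters,
#     +Inf for min filters), i.e. structuring elements are clipped to the
#     image domain

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1L, 1L + dr):min(H, H + dr)
  cs <- max(1L, 1L + dc):min(W, W + dc)
  if (length(rs) > 0 && length(cs) > 0 && rs[1] <= rs[length(rs)] &&
      cs[1] <= cs[length(cs)])
    out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Integer offsets (dr, dc) of the rasterized disk of radius r.
disk_offsets <- function(r) {
  r <- as.numeric(r)
  s <- floor(r)
  g <- expand.grid(dr = -s:s, dc = -s:s)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# 0/1 kernel matrix for the same disk (odd-sized, centered).
disk_kernel <- function(r) {
  s <- floor(r)
  d <- outer((-s:s)^2, (-s:s)^2, "+")
  (d <= r^2) * 1
}

# --- union-find (small, used to merge diagonal label adjacencies) ----------

uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# 8-connected components of a logical matrix.  Built on EBImage::bwlabel
# (4-connected, compiled) followed by a union-find merge of diagonally
# adjacent label pairs.  Labels are renumbered 1..n in raster-scan order
# (rows top to bottom, columns left to right) of each component's first pixel.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  mode(mask) <- "logical"
  if (!any(mask)) return(matrix(0L, H, W))
  lab4 <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(matrix(as.numeric(mask), H, W)))), H, W)
  n <- max(lab4)
  parent <- seq_len(n)
  for (d in list(c(-1L, -1L), c(-1L, 1L))) {
    nb <- shift_mat(lab4, d[1], d[2], 0L)
    sel <- lab4 > 0L & nb > 0L & nb != lab4
    if (any(sel)) {
      pairs <- unique(cbind(lab4[sel], nb[sel]))
      for (k in seq_len(nrow(pairs))) {
        a <- uf_find(parent, pairs[k, 1]); b <- uf_find(parent, pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  root <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  lab <- matrix(0L, H, W)
  lab[mask] <- root[lab4[mask]]
  relabel_raster_order(lab)
}

# Renumber positive labels 1..n by raster-scan order of each label's first
# pixel; preserves geometry, drops gaps in the id sequence.
relabel_raster_order <- function(lab) {
  w <- which(lab > 0)
  if (length(w) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  labs <- lab[w]
  raster <- (row(lab)[w] - 1L) * ncol(lab) + col(lab)[w]  # row-major position
  o <- order(labs, raster)
  firsts <- raster[o][!duplicated(labs[o])]   # first raster pixel per id
  ids <- labs[o][!duplicated(labs[o])]
  map <- integer(max(ids))
  map[ids[order(firsts)]] <- seq_along(ids)
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[w] <- map[labs]
  out
}

# Per-label Crofton-corrected perimeter: (pi/4) x number of 4-neighbour
# pixel edges between a label and anything that is not that label (the image
# border counts as background).  For a rasterized disk this estimates 2*pi*r
# nearly unbiasedly, so the roundness statistic 4*pi*A/P^2 of a disk is ~1.
label_perimeters <- function(lab) {
  ids <- max(lab)
  if (ids == 0) return(numeric(0))
  edges <- numeric(ids)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- shift_mat(lab, d[1], d[2], 0L)
    sel <- lab > 0L & nb != lab
    if (any(sel)) {
      t <- tabulate(lab[sel], nbins = ids)
      edges <- edges + t
    }
  }
  edges * (pi / 4)
}

# Per-label pixel areas (index = label id).
label_areas <- function(lab) {
  if (max(lab) == 0) return(numeric(0))
  tabulate(lab[lab > 0], nbins = max(lab))
}

# Per-label centroids as a matrix with columns (row, col); NA rows for
# absent ids.
label_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  sel <- lab > 0
  a <- tabulate(lab[sel], nbins = n)
  rs <- rowsum(cbind(row(lab)[sel], col(lab)[sel]), lab[sel])
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  out[as.integer(rownames(rs)), ] <- rs / a[as.integer(rownames(rs))]
  out
}

# Exact Euclidean distance (pixel centers) from every pixel to the nearest
# pixel of `mask` (logical).  Pixels of the mask itself get 0.
distance_to_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(matrix(Inf, nrow(mask), ncol(mask)))
  inv <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  matrix(as.numeric(EBImage::imageData(EBImage::distmap(inv))),
         nrow(mask), ncol(mask))
}

# --- running-extreme filters ----------------------------------------------
# Grayscale max/min filter over the disk {||p|| <= r}, computed by chord
# decomposition: for each row offset dr the disk contributes a centered
# horizontal window of half-width floor(sqrt(r^2 - dr^2)); horizontal window
# extremes are taken with a sparse-table (doubling) scheme so the total cost
# is O(r) elementwise passes instead of O(r^2).

.row_window_extreme <- function(m, h, fun, fill) {
  # centered window of half-width h along columns; m is padded with h
  # fill-columns per side so both sparse-table anchors stay in range
  w <- 2L * h + 1L
  if (h == 0L) return(m)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(fill, H, h)
  tab <- cbind(pad, m, pad)
  len <- 1L
  while (2L * len <= w) {           # tab = extreme over [c, c + len - 1]
    tab <- fun(tab, shift_mat(tab, 0L, -len, fill))
    len <- 2L * len
  }
  # window [c-h, c+h]: union of [c-h, c-h+len-1] and [c+h-len+1, c+h]
  out <- fun(shift_mat(tab, 0L, h, fill),
             shift_mat(tab, 0L, -(h - len + 1L), fill))
  out[, (h + 1L):(h + W), drop = FALSE]
}

disk_extreme_filter <- function(img, r, type = c("max", "min")) {
  type <- match.arg(type)
  fun <- if (type == "max") pmax else pmin
  fill <- if (type == "max") -Inf else Inf
  s <- floor(r)
  out <- matrix(fill, nrow(img), ncol(img))
  # cache row-window results per half-width
  hs <- vapply(-s:s, function(dr) floor(sqrt(r^2 - dr^2)), numeric(1))
  uh <- unique(hs)
  rowres <- lapply(uh, function(h) .row_window_extreme(img, as.integer(h), fun, fill))
  names(rowres) <- as.character(uh)
  for (i in seq_along(-s:s)) {
    dr <- (-s:s)[i]
    out <- fun(out, shift_mat(rowres[[as.character(hs[i])]], dr, 0L, fill))
  }
  out
}

gray_dilate <- function(img, r) disk_extreme_filter(img, r, "max")
gray_erode  <- function(img, r) disk_extreme_filter(img, r, "min")

# --- seeded randomness -----------------------------------------------------

# All generator randomness flows from one top-level integer seed.  Substreams
# (per well, field, timepoint) use an affine split: child = (seed * 48271 +
# 104729 * k) mod (2^31 - 1), documented here and in the methods vignette.
split_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + 104729 * as.numeric(k)) %%
               2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
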