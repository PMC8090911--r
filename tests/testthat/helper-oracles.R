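# Brute-force oracles, independent of the implementation paths they check.
# All use direct per-pixel definitions (O(N*M) scans), affordable at the
# 64x64 scale the oracle suites run at.

# nearest-label assignment within radius n; equidistant ties -> smallest id
oracle_grow <- function(lab, n) {
  H <- nrow(lab); W <- ncol(lab)
  pts <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[pts]
  out <- matrix(0L, H, W)
  for (r in 1:H) for (c in 1:W) {
    if (lab[r, c] > 0) { out[r, c] <- lab[r, c]; next }
    d2 <- (r - pts[, 1])^2 + (c - pts[, 2])^2
    md <- min(d2)
    if (md <= n^2) out[r, c] <- min(ids[d2 == md])
  }
  out
}

# per-label erosion: keep pixel iff all pixels within distance n share label
oracle_shrink <- function(lab, n) {
  H <- nrow(lab); W <- ncol(lab)
  out <- matrix(0L, H, W)
  s <- floor(n)
  for (r in 1:H) for (c in 1:W) {
    l <- lab[r, c]
    if (l == 0) next
    ok <- TRUE
    for (dr in -s:s) for (dc in -s:s) {
      if (dr^2 + dc^2 > n^2) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      if (lab[rr, cc] != l) { ok <- FALSE; break }
    }
    if (ok) out[r, c] <- l
  }
  out
}

# grayscale closing by disk(n) minus image, SE clipped at borders
oracle_bottom_hat <- function(img, n) {
  H <- nrow(img); W <- ncol(img)
  s <- floor(n)
  off <- expand.grid(dr = -s:s, dc = -s:s)
  off <- off[off$dr^2 + off$dc^2 <= n^2, ]
  ext <- function(m, fun, fill) {
    out <- matrix(fill, H, W)
    for (k in seq_len(nrow(off))) {
      dr <- off$dr[k]; dc <- off$dc[k]
      sh <- matrix(fill, H, W)
      rs <- max(1, 1 + dr):min(H, H + dr); cs <- max(1, 1 + dc):min(W, W + dc)
      sh[rs, cs] <- m[rs - dr, cs - dc]
      out <- fun(out, sh)
    }
    out
  }
  ext(ext(img, pmax, -Inf), pmin, Inf) - img
}

# exhaustive Otsu: maximize between-class variance over all 256 bin splits
oracle_otsu <- function(img, n_bins = 256) {
  lo <- min(img); hi <- max(img)
  bin <- pmin(floor((img - lo) / (hi - lo) * n_bins) + 1, n_bins)
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    g0 <- img[bin <= t]; g1 <- img[bin > t]
    if (length(g0) == 0 || length(g1) == 0) next
    w0 <- length(g0) / length(img); w1 <- 1 - w0
    # between-class variance with bin-center means
    c0 <- mean(lo + (bin[bin <= t] - 0.5) * (hi - lo) / n_bins)
    c1 <- mean(lo + (bin[bin > t] - 0.5) * (hi - lo) / n_bins)
    v <- w0 * w1 * (c0 - c1)^2
    if (v > best) { best <- v; best_t <- t }
  }
  lo + best_t * (hi - lo) / n_bins
}

# flood fill from the border over background; unreached background = holes
oracle_fill_holes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  reach <- matrix(FALSE, H, W)
  queue <- which(!mask & (row(mask) %in% c(1, H) | col(mask) %in% c(1, W)))
  reach[queue] <- TRUE
  while (length(queue) > 0) {
    p <- queue[1]; queue <- queue[-1]
    r <- (p - 1) %% H + 1; c <- (p - 1) %/% H + 1
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      q <- (cc - 1) * H + rr
      if (!mask[q] && !reach[q]) { reach[q] <- TRUE; queue <- c(queue, q) }
    }
  }
  mask | (!mask & !reach)
}

# random label mask: k disk/point seeds on an HxW grid
random_label_mask <- function(seed, H = 64, W = 64, k = 5, r_max = 6) {
  set.seed(seed)
  lab <- matrix(0L, H, W)
  for (i in seq_len(k)) {
    r0 <- sample(5:(H - 4), 1); c0 <- sample(5:(W - 4), 1)
    rad <- runif(1, 0, r_max)
    sel <- (row(lab) - r0)^2 + (col(lab) - c0)^2 <= rad^2
    lab[sel & lab == 0L] <- i
  }
  perilyso:::relabel_raster_order(lab)
}

# disk-shaped label centred at (r0, c0)
disk_label <- function(H, W, r0, c0, rad, id = 1L) {
  m <- matrix(0L, H, W)
  m[(row(m) - r0)^2 + (col(m) - c0)^2 <= rad^2] <- id
  m
}
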