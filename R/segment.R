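# Open re-implementations of the segmentation primitives used by commercial
# high-content analysis software: round-object detection, per-label shrink,
# collision-free label growth, border-object removal, puncta detection,
# bottom-hat filtering, Otsu auto-thresholding, binary dilation, hole filling
# and minimum-area filtering.  All operators use 8-connectivity and Euclidean
# disk structuring elements {p : ||p|| <= r}; see `segment_config()`.

#' Segmentation configuration
#'
#' Central record of the conventions shared by all segmentation operators.
#'
#' @param connectivity Pixel connectivity for components and holes (8; fixed).
#' @param roundness_min Minimum roundness 4*pi*A/P^2 for round-object
#'   detection; perimeter P is the Crofton-corrected 4-neighbour edge count,
#'   under which a rasterized disk scores ~1 and a thin line ~0.4.
#' @param puncta_roundness_min Relaxed roundness bound for diffraction-limited
#'   puncta (few-pixel objects quantize coarsely).
#' @param threshold_method Default intensity threshold when none is given:
#'   `"otsu"` (per image/channel).
#' @return A named list.
#' @export
segment_config <- function(connectivity = 8, roundness_min = 0.6,
                           puncta_roundness_min = 0.3,
                           threshold_method = "otsu") {
  stopifnot(connectivity == 8)
  list(connectivity = connectivity, roundness_min = roundness_min,
       puncta_roundness_min = puncta_roundness_min,
       threshold_method = threshold_method)
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  invisible(image)
}

#' Detect round objects by threshold, size band and roundness
#'
#' Thresholds the image, labels 8-connected components and retains those
#' whose equivalent circular diameter 2*sqrt(A/pi) lies in
#' `[diameter_min_px, diameter_max_px]` and whose roundness 4*pi*A/P^2 is at
#' least `roundness_min`.  Labels are numbered sequentially from 1 in
#' raster-scan order of each component's first pixel.
#'
#' @param image 2-D numeric intensity matrix.
#' @param diameter_min_px,diameter_max_px Equivalent-diameter band in pixels.
#' @param intensity_threshold Pixels strictly above this value are
#'   foreground; `NULL` (default) uses the Otsu threshold of the image.
#' @param roundness_min Minimum roundness (default 0.6).
#' @param pixel_size_um Pixel size carried into the result.
#' @return A [label_mask].
#' @export
find_round_objects <- function(image, diameter_min_px, diameter_max_px,
                               intensity_threshold = NULL,
                               roundness_min = 0.6,
                               pixel_size_um = 0.1625) {
  check_image(image)
  if (diameter_min_px >= diameter_max_px)
    stop("diameter_min_px must be smaller than diameter_max_px")
  if (is.null(intensity_threshold))
    intensity_threshold <- otsu_threshold(image)
  mask <- image > intensity_threshold
  lab <- label_components(mask)
  if (max(lab) > 0) {
    areas <- label_areas(lab)
    perim <- label_perimeters(lab)
    diam <- 2 * sqrt(areas / pi)
    round <- 4 * pi * areas / perim^2
    keep <- which(diam >= diameter_min_px & diam <= diameter_max_px &
                    round >= roundness_min)
    lab[!(lab %in% keep)] <- 0L
    lab <- relabel_raster_order(lab)
  }
  label_mask(lab, pixel_size_um)
}

#' Shrink every label by a Euclidean disk
#'
#' Per-label morphological erosion: a pixel keeps its label iff every pixel
#' within Euclidean distance `n_px` carries the same label.  Labels that
#' vanish entirely are dropped and reported in the `dropped_labels`
#' attribute (with a message).
#'
#' @param mask A [label_mask].
#' @param n_px Erosion radius in pixels (>= 0).
#' @return A [label_mask] with attribute `dropped_labels`.
#' @export
shrink_labels <- function(mask, n_px) {
  if (n_px < 0) stop("n_px must be non-negative")
  lab <- unclass_mask(mask)
  if (n_px == 0 || max(lab) == 0) {
    out <- label_mask(lab, pixel_size(mask))
    attr(out, "dropped_labels") <- integer(0)
    return(out)
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  dropped <- integer(0)
  for (l in label_ids(lab)) {
    # distance from each label pixel to the nearest non-label pixel; keep
    # the pixel iff that distance exceeds n_px
    d <- distance_to_nonmask(lab == l)
    keep <- lab == l & d > n_px
    if (!any(keep)) dropped <- c(dropped, l) else out[keep] <- l
  }
  if (length(dropped) > 0)
    message("shrink_labels: labels eroded away entirely: ",
            paste(dropped, collapse = ", "))
  res <- label_mask(out, pixel_size(mask))
  attr(res, "dropped_labels") <- dropped
  res
}

# distance from each pixel to the nearest pixel NOT in `mask` (image border
# does not count); mask pixels deep inside get large values, non-mask get 0
distance_to_nonmask <- function(mask) distance_to_mask(!mask)

#' Grow labels without touching (collision-free Voronoi expansion)
#'
#' Every input pixel keeps its label.  Each background pixel within Euclidean
#' distance `n_px` of at least one labeled pixel receives the label of the
#' nearest labeled pixel; equidistant ties go to the smallest label id.
#' Grown territories therefore never merge.
#'
#' @param mask A [label_mask].
#' @param n_px Growth radius in pixels (>= 0).
#' @return A [label_mask].
#' @export
grow_labels_without_touching <- function(mask, n_px) {
  if (n_px < 0) stop("n_px must be non-negative")
  lab <- unclass_mask(mask)
  if (n_px == 0 || max(lab) == 0) return(label_mask(lab, pixel_size(mask)))
  H <- nrow(lab); W <- ncol(lab)
  best_d <- matrix(Inf, H, W)
  best_l <- matrix(0L, H, W)
  for (l in label_ids(lab)) {   # ascending ids + strict '<' => ties to min id
    d <- distance_to_mask(lab == l)
    upd <- d < best_d & d <= n_px
    best_l[upd] <- l
    best_d[upd] <- d[upd]
  }
  best_l[lab > 0] <- lab[lab > 0]
  label_mask(best_l, pixel_size(mask))
}

#' Remove objects touching the image border
#'
#' Deletes every label having at least one pixel on the first/last row or
#' column.  Remaining ids are preserved.
#'
#' @param mask A [label_mask].
#' @return A [label_mask].
#' @export
remove_border_objects <- function(mask) {
  lab <- unclass_mask(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  lab[lab %in% border] <- 0L
  label_mask(lab, pixel_size(mask))
}

#' Detect diffraction-limited puncta
#'
#' [find_round_objects()] with puncta-scale defaults: a small lower diameter
#' bound, an upper bound wide enough to keep the larger objects formed when
#' tightly clustered puncta merge (the signal the perinuclear mean-area
#' readout relies on), and a relaxed roundness bound (tiny and merged
#' objects quantize coarsely on the pixel grid).  Per-punctum areas and centroids are available via
#' [mask_features()].
#'
#' @inheritParams find_round_objects
#' @return A [label_mask].
#' @export
detect_puncta <- function(image, intensity_threshold = NULL,
                          diameter_min_px = 1, diameter_max_px = 20,
                          roundness_min = 0.2, pixel_size_um = 0.1625) {
  find_round_objects(image, diameter_min_px, diameter_max_px,
                     intensity_threshold, roundness_min, pixel_size_um)
}

#' Morphological bottom-hat transform
#'
#' Closing by the Euclidean disk of radius `radius_px` minus the original
#' image.  Dark structures narrower than the structuring element become
#' bright; flat background maps to ~0.  The structuring element is clipped
#' at image borders.
#'
#' @param image 2-D numeric matrix.
#' @param radius_px Disk radius (>= 1).
#' @return Numeric matrix of the same shape.
#' @export
bottom_hat <- function(image, radius_px) {
  check_image(image)
  if (radius_px < 1) stop("radius_px must be >= 1")
  closing <- gray_erode(gray_dilate(image, radius_px), radius_px)
  closing - image
}

#' Otsu threshold of an image
#'
#' Threshold maximizing the between-class variance of the 256-bin histogram
#' spanning the image's intensity range.  Returns the intensity value at the
#' upper edge of the chosen bin; foreground is `image > threshold`.
#'
#' @param image 2-D numeric matrix with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return Scalar threshold (intensity units).
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  check_image(image)
  lo <- min(image); hi <- max(image)
  if (hi <= lo) stop("otsu_threshold: image is constant, no threshold exists")
  bin <- pmin(floor((image - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  p <- h / sum(h)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, n_bins)
  sb[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  t_bin <- which.max(sb)   # first maximum on ties
  lo + t_bin * (hi - lo) / n_bins
}

#' Automatic (Otsu) binarization
#'
#' @param image 2-D numeric matrix with >= 2 distinct values.
#' @param pixel_size_um Pixel size carried into the result.
#' @return A [binary_mask] with attribute `threshold`.
#' @export
auto_threshold <- function(image, pixel_size_um = 0.1625) {
  thr <- otsu_threshold(image)
  out <- binary_mask(image > thr, pixel_size_um)
  attr(out, "threshold") <- thr
  out
}

#' Dilate a binary mask by a Euclidean disk
#'
#' @param mask A [binary_mask] (or logical matrix).
#' @param n_px Dilation radius (>= 0).
#' @return A [binary_mask].
#' @export
dilate_binary <- function(mask, n_px) {
  if (n_px < 0) stop("n_px must be non-negative")
  m <- unclass_mask(mask)
  mode(m) <- "logical"
  if (n_px == 0 || !any(m)) return(binary_mask(m, pixel_size(mask)))
  d <- distance_to_mask(m)
  binary_mask(d <= n_px, pixel_size(mask))
}

#' Fill holes in a binary mask
#'
#' Background components (8-connected) not connected to the image border
#' become foreground.
#'
#' @param mask A [binary_mask] (or logical matrix).
#' @return A [binary_mask].
#' @export
fill_holes <- function(mask) {
  m <- unclass_mask(mask)
  mode(m) <- "logical"
  bg <- label_components(!m)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  hole <- bg > 0 & !(bg %in% border)
  binary_mask(m | hole, pixel_size(mask))
}

#' Remove small components from a binary mask
#'
#' Deletes 8-connected foreground components with pixel area strictly below
#' `min_area_px`.
#'
#' @param mask A [binary_mask] (or logical matrix).
#' @param min_area_px Minimum area in pixels (>= 0).
#' @return A [binary_mask].
#' @export
filter_min_area <- function(mask, min_area_px) {
  if (min_area_px < 0) stop("min_area_px must be non-negative")
  m <- unclass_mask(mask)
  mode(m) <- "logical"
  if (!any(m) || min_area_px == 0) return(binary_mask(m, pixel_size(mask)))
  lab <- label_components(m)
  areas <- label_areas(lab)
  small <- which(areas < min_area_px)
  m[lab %in% small] <- FALSE
  binary_mask(m, pixel_size(mask))
}
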