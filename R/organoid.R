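# Organoid invasion pipeline for transmitted-light images: bottom-hat
# enhancement of the dark organoid areas, Otsu auto-threshold, dilation to
# close gaps, hole filling and a minimum-area filter; growth is reported as
# percent area change between day 1 and day 3 (100 = doubling, 0 = no
# change).

#' Segment dark organoids in a transmitted-light image
#'
#' Stage order: [bottom_hat()] (radius `bh_radius_px`) to turn dark organoid
#' areas bright, [auto_threshold()], [dilate_binary()] (`dilate_px`) to close
#' gaps, [fill_holes()], [filter_min_area()] (`min_area_px`).  Emits a
#' warning when the image appears to contain bright (not dark) objects,
#' since the bottom-hat stage targets dark structures.
#'
#' @param image Transmitted-light matrix; organoids darker than background.
#' @param bh_radius_px Bottom-hat structuring-element radius (default 50).
#' @param dilate_px Dilation radius (default 3).
#' @param min_area_px Minimum surviving component area (default 500 px^2).
#' @param min_contrast Minimum contrast guard: the Otsu threshold of the
#'   bottom-hat response must exceed its median by this many MADs, otherwise
#'   the image is considered organoid-free and an empty mask is returned
#'   (Otsu always splits a histogram, even pure noise; the guard stops that).
#' @param pixel_size_um Pixel size carried into the result.
#' @param keep_stages Also return every intermediate mask for audit.
#' @return A [binary_mask]; with `keep_stages = TRUE` the attribute `stages`
#'   holds `bottom_hat`, `threshold`, `dilated`, `filled`.
#' @export
segment_organoids <- function(image, bh_radius_px = 50, dilate_px = 3,
                              min_area_px = 500, pixel_size_um = 1.3,
                              min_contrast = 5, keep_stages = FALSE) {
  check_image(image)
  if (mean(image) - stats::median(image) > 0.05 * stats::sd(image))
    warning(paste("image intensity is right-skewed (bright minority):",
                  "organoids are expected dark on a bright background;",
                  "the bottom-hat stage will not enhance bright objects"))
  bh <- bottom_hat(image, bh_radius_px)
  thr <- auto_threshold(bh, pixel_size_um)
  guard <- stats::median(bh) +
    min_contrast * stats::mad(as.numeric(bh), constant = 1.4826)
  if (attr(thr, "threshold") < guard) {
    th0 <- attr(thr, "threshold")
    thr <- binary_mask(matrix(FALSE, nrow(image), ncol(image)),
                       pixel_size_um)
    attr(thr, "threshold") <- th0
  }
  dil <- dilate_binary(thr, dilate_px)
  fil <- fill_holes(dil)
  fin <- filter_min_area(fil, min_area_px)
  if (keep_stages)
    attr(fin, "stages") <- list(bottom_hat = bh, threshold = thr,
                                dilated = dil, filled = fil)
  fin
}

#' Total foreground area of a mask
#'
#' @param mask A [binary_mask] (or logical matrix).
#' @return Foreground pixel count, with attribute `area_um2` (via the
#'   carried pixel size).
#' @export
total_area <- function(mask) {
  m <- unclass_mask(mask)
  mode(m) <- "logical"
  a <- sum(m)
  structure(a, area_um2 = a * pixel_size(mask)^2)
}

#' Percent change between two areas
#'
#' `(area_d3 - area_d1) / area_d1 * 100`: 100 means the area doubled, 0
#' means no change.
#'
#' @param area_d1,area_d3 Areas at day 1 and day 3 (`area_d1 > 0`).
#' @return Scalar percent change.
#' @export
percent_change <- function(area_d1, area_d3) {
  if (any(area_d1 <= 0))
    stop("area_d1 must be positive: percent change undefined")
  (area_d3 - area_d1) / area_d1 * 100
}

#' Measure organoid growth from a day-1 / day-3 image pair
#'
#' Runs [segment_organoids()] with identical parameters on both images (so
#' any dilation-induced area bias applies to both days) and reports the
#' growth record.
#'
#' @param image_d1,image_d3 Transmitted-light matrices or single-channel
#'   `field_image`s.
#' @param well,drug,concentration Optional annotation carried into the
#'   record.
#' @inheritParams segment_organoids
#' @return One-row data frame: `well`, `drug`, `concentration`,
#'   `area_d1_px`, `area_d3_px`, `area_d1_um2`, `area_d3_um2`,
#'   `percent_change`.
#' @export
measure_organoid_growth <- function(image_d1, image_d3, well = NA,
                                    drug = NA, concentration = NA,
                                    bh_radius_px = 50, dilate_px = 3,
                                    min_area_px = 500, pixel_size_um = 1.3) {
  get_mat <- function(x) {
    if (inherits(x, "field_image")) {
      pixel_size_um <<- x$pixel_size_um
      x$channels[[1]]
    } else x
  }
  m1 <- get_mat(image_d1); m3 <- get_mat(image_d3)
  s1 <- segment_organoids(m1, bh_radius_px, dilate_px, min_area_px,
                          pixel_size_um)
  s3 <- segment_organoids(m3, bh_radius_px, dilate_px, min_area_px,
                          pixel_size_um)
  a1 <- total_area(s1); a3 <- total_area(s3)
  data.frame(well = well, drug = drug, concentration = concentration,
             area_d1_px = as.numeric(a1), area_d3_px = as.numeric(a3),
             area_d1_um2 = attr(a1, "area_um2"),
             area_d3_um2 = attr(a3, "area_um2"),
             percent_change = percent_change(as.numeric(a1), as.numeric(a3)))
}
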