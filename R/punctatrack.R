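# Time-course classification: per-cell puncta assignment, LMP positivity
# (galectin-3 puncta), dead-cell detection, per-timepoint readouts and
# tandem-fluorescence autophagy-flux classification.

#' Assign puncta to cells by territory growth
#'
#' Cell territories are the nucleus labels grown without touching up to
#' `max_radius_px`; a punctum is assigned to the territory containing its
#' centroid pixel.  Puncta outside every territory stay unassigned and are
#' counted.
#'
#' @param puncta,nuclei [label_mask]s sharing geometry.
#' @param max_radius_px Maximum territory growth from the nucleus (pixels).
#' @return A `cell_assignment` list: `territories` ([label_mask]),
#'   `assignment` (data frame `punctum`, `cell`, `area_px`; `cell = 0` for
#'   unassigned), `n_unassigned`.
#' @export
assign_puncta_to_cells <- function(puncta, nuclei, max_radius_px = 40) {
  stopifnot(inherits(puncta, "label_mask"), inherits(nuclei, "label_mask"))
  if (!all(dim(puncta) == dim(nuclei)))
    stop("puncta and nuclei have mismatched geometry")
  terr <- grow_labels_without_touching(nuclei, max_radius_px)
  feats <- mask_features(puncta)
  tm <- unclass_mask(terr)
  cell <- integer(nrow(feats))
  if (nrow(feats) > 0) {
    r <- pmin(pmax(round(feats$row), 1), nrow(tm))
    c <- pmin(pmax(round(feats$col), 1), ncol(tm))
    cell <- tm[cbind(r, c)]
  }
  structure(list(territories = terr,
                 assignment = data.frame(punctum = feats$label, cell = cell,
                                         area_px = feats$area_px),
                 n_unassigned = sum(cell == 0)),
            class = "cell_assignment")
}

#' Per-cell puncta counts from an assignment
#'
#' @param assignment A `cell_assignment`.
#' @param nuclei The nucleus [label_mask] (defines the cell id universe).
#' @return Integer vector of puncta counts, one per nucleus label id.
#' @export
puncta_counts_per_cell <- function(assignment, nuclei) {
  ids <- label_ids(nuclei)
  a <- assignment$assignment
  cnt <- integer(length(ids))
  names(cnt) <- ids
  if (nrow(a) > 0) {
    t <- table(factor(a$cell[a$cell > 0], levels = ids))
    cnt[] <- as.integer(t)
  }
  cnt
}

#' LMP positivity of cells from puncta counts
#'
#' A cell is puncta-positive (scored as undergoing lysosomal membrane
#' permeabilization) iff it carries `min_puncta` or more marker puncta.
#'
#' @param counts Integer vector of per-cell puncta counts.
#' @param min_puncta Positivity threshold (default 3, inclusive).
#' @return Logical vector.
#' @export
classify_lmp_positive <- function(counts, min_puncta = 3) {
  if (any(counts < 0)) stop("puncta counts must be non-negative")
  counts >= min_puncta
}

#' Detect dead cells from nuclear morphology and intensity
#'
#' A nucleus is scored dead iff its area is below `area_factor` times the
#' field-median nuclear area AND its mean intensity is above
#' `intensity_factor` times the field-median mean intensity (shrunken,
#' brightly stained nuclei).  Cells not scored dead are live.
#'
#' @param nucleus_image Nucleus-channel intensity matrix.
#' @param nuclei A [label_mask] of nuclei (>= 1 label).
#' @param area_factor,intensity_factor Multipliers against field medians.
#' @return Logical vector (one flag per nucleus label id, in id order).
#' @export
detect_dead_cells <- function(nucleus_image, nuclei, area_factor = 0.5,
                              intensity_factor = 1.5) {
  stopifnot(inherits(nuclei, "label_mask"))
  check_image(nucleus_image)
  ids <- label_ids(nuclei)
  if (length(ids) == 0) stop("empty nucleus mask")
  lab <- unclass_mask(nuclei)
  areas <- label_areas(lab)[ids]
  ints <- vapply(ids, function(l) mean(nucleus_image[lab == l]), numeric(1))
  dead <- areas < area_factor * stats::median(areas) &
    ints > intensity_factor * stats::median(ints)
  names(dead) <- ids
  dead
}

#' Per-timepoint readouts of a time-course series
#'
#' For each timepoint: segments nuclei, flags dead cells, detects marker
#' puncta, assigns them to cell territories, and reports the percentage of
#' puncta-positive cells among live cells (dead cells excluded) and the
#' percentage of dead cells among all detected cells.
#'
#' @param series List of per-timepoint lists with elements `t_h` and `image`
#'   (a `field_image` with channels `nucleus` and `marker`), e.g. from
#'   [simulate_timecourse()].
#' @param config Analysis parameters, see [screen_config()].
#' @return Data frame: `t_h`, `n_cells`, `n_live`, `pct_puncta_positive`
#'   (of live cells), `pct_dead` (of all cells).
#' @export
timecourse_readouts <- function(series, config = screen_config()) {
  if (length(series) == 0) stop("series must contain at least one timepoint")
  rows <- lapply(series, function(tp) {
    img <- tp$image
    nuclei <- find_round_objects(img$channels$nucleus,
                                 config$nucleus_diameter_px[1],
                                 config$nucleus_diameter_px[2],
                                 roundness_min = config$roundness_min,
                                 pixel_size_um = img$pixel_size_um)
    n_cells <- n_labels(nuclei)
    if (n_cells == 0)
      return(data.frame(t_h = tp$t_h, n_cells = 0L, n_live = 0L,
                        pct_puncta_positive = NA_real_,
                        pct_dead = NA_real_))
    dead <- detect_dead_cells(img$channels$nucleus, nuclei,
                              config$dead_area_factor,
                              config$dead_intensity_factor)
    puncta <- detect_puncta(img$channels$marker,
                            intensity_threshold = config$puncta_threshold,
                            diameter_min_px = config$puncta_diameter_px[1],
                            diameter_max_px = config$puncta_diameter_px[2],
                            roundness_min = config$puncta_roundness_min,
                            pixel_size_um = img$pixel_size_um)
    asg <- assign_puncta_to_cells(puncta, nuclei, config$territory_radius_px)
    counts <- puncta_counts_per_cell(asg, nuclei)
    pos <- classify_lmp_positive(counts, config$min_puncta)
    live <- !dead
    data.frame(t_h = tp$t_h, n_cells = n_cells, n_live = sum(live),
               pct_puncta_positive = if (sum(live) > 0)
                 100 * mean(pos[live]) else NA_real_,
               pct_dead = 100 * mean(dead))
  })
  do.call(rbind, rows)
}

#' Classify tandem-fluorescence puncta as yellow or red
#'
#' For each punctum, the mean GFP / mean RFP intensity ratio over the
#' punctum pixels decides its class: red (autolysosome; GFP quenched at
#' acidic pH) iff the ratio is below `ratio_threshold`, yellow
#' (autophagosome) otherwise.  Puncta with non-positive RFP mean are flagged
#' unclassifiable.
#'
#' @param gfp_image,rfp_image Co-registered channel matrices.
#' @param puncta A [label_mask] of puncta.
#' @param ratio_threshold GFP/RFP ratio below which a punctum is red.
#' @return Data frame: `punctum`, `gfp_mean`, `rfp_mean`, `ratio`, `class`
#'   (`"yellow"`, `"red"`, or `NA` for unclassifiable).
#' @export
classify_flux_puncta <- function(gfp_image, rfp_image, puncta,
                                 ratio_threshold = 0.5) {
  stopifnot(inherits(puncta, "label_mask"))
  check_image(gfp_image); check_image(rfp_image)
  if (!all(dim(gfp_image) == dim(puncta)) ||
      !all(dim(rfp_image) == dim(puncta)))
    stop("channels and puncta have mismatched geometry")
  lab <- unclass_mask(puncta)
  ids <- label_ids(lab)
  g <- vapply(ids, function(l) mean(gfp_image[lab == l]), numeric(1))
  r <- vapply(ids, function(l) mean(rfp_image[lab == l]), numeric(1))
  ratio <- ifelse(r > 0, g / r, NA_real_)
  cls <- ifelse(is.na(ratio), NA_character_,
                ifelse(ratio < ratio_threshold, "red", "yellow"))
  data.frame(punctum = ids, gfp_mean = g, rfp_mean = r, ratio = ratio,
             class = cls)
}
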