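# Orchestration: the end-to-end screen (fields -> PNLA -> well aggregation
# -> Z-prime QC -> robust Z -> hits) and the LMP time-course classifier.

#' Analysis configuration
#'
#' Central parameter record.  Defaults follow the screening recipe where one
#' is stated (shrink 2 px, grow 25 px, hit threshold 2 MADs, puncta-positive
#' at >= 3 puncta, plate inclusion at Z' > 0 with acceptable band (0, 0.5));
#' the remaining defaults are documented package choices.
#'
#' @param shrink_px,grow_px Perinuclear ring construction parameters.
#' @param nucleus_diameter_px,puncta_diameter_px Diameter bands for round
#'   object detection (pixels).
#' @param roundness_min,puncta_roundness_min Roundness bounds.
#' @param puncta_threshold Absolute marker-channel intensity threshold for
#'   puncta detection (the "appropriate threshold" of high-content practice,
#'   chosen for the generator's intensity scale: well above background +
#'   noise, well below spot peaks).  `NULL` falls back to per-field Otsu,
#'   which is only reliable when the channel actually contains many spots.
#' @param hit_threshold Robust-Z hit threshold (MAD units).
#' @param qc_band Acceptable Z-prime band for phenotypic assays.
#' @param min_puncta LMP positivity threshold (puncta per cell).
#' @param dead_area_factor,dead_intensity_factor Dead-cell rule multipliers.
#' @param territory_radius_px Maximum cell-territory growth (pixels).
#' @param flux_ratio_threshold GFP/RFP ratio below which a punctum is red.
#' @param membership Ring membership rule for puncta.
#' @param mad_scale MAD multiplier for robust Z (1 = raw).
#' @param lmp_split_h Early/late LMP split time (hours).
#' @param lmp_min_pct,lmp_rise_factor "Evident" puncta formation rule: the
#'   positive-cell percentage must reach `max(lmp_rise_factor * baseline,
#'   lmp_min_pct)`; the 15 % floor requires at least two positive cells in a
#'   typical 8-12 cell field, so one stray positive cell never counts as
#'   evidence.
#' @param organoid Organoid stage parameters (list: `bh_radius_px`,
#'   `dilate_px`, `min_area_px`).
#' @return Named list of parameters.
#' @export
screen_config <- function(shrink_px = 2, grow_px = 25,
                          nucleus_diameter_px = c(6, 40),
                          puncta_diameter_px = c(1, 20),
                          roundness_min = 0.6, puncta_roundness_min = 0.2,
                          puncta_threshold = 600,
                          hit_threshold = 2, qc_band = c(0, 0.5),
                          min_puncta = 3, dead_area_factor = 0.5,
                          dead_intensity_factor = 1.5,
                          territory_radius_px = 40,
                          flux_ratio_threshold = 0.5,
                          membership = "centroid", mad_scale = 1,
                          lmp_split_h = 12, lmp_min_pct = 15,
                          lmp_rise_factor = 2,
                          organoid = list(bh_radius_px = 50, dilate_px = 3,
                                          min_area_px = 500)) {
  as.list(environment())
}

#' PNLA analysis of one field
#'
#' Segments nuclei, builds perinuclear rings, detects puncta and scores the
#' field; the building block of [run_screen()].
#'
#' @param image A `field_image` with channels `nucleus` and `marker`.
#' @param config See [screen_config()].
#' @return A `pnla_result`.
#' @export
score_field <- function(image, config = screen_config()) {
  stopifnot(inherits(image, "field_image"))
  nuclei <- find_round_objects(image$channels$nucleus,
                               config$nucleus_diameter_px[1],
                               config$nucleus_diameter_px[2],
                               roundness_min = config$roundness_min,
                               pixel_size_um = image$pixel_size_um)
  rings <- suppressWarnings(
    build_perinuclear_rings(nuclei, config$shrink_px, config$grow_px))
  puncta <- detect_puncta(image$channels$marker,
                          intensity_threshold = config$puncta_threshold,
                          diameter_min_px = config$puncta_diameter_px[1],
                          diameter_max_px = config$puncta_diameter_px[2],
                          roundness_min = config$puncta_roundness_min,
                          pixel_size_um = image$pixel_size_um)
  pnla_score(puncta, rings, marker_image = image$channels$marker,
             membership = config$membership)
}

#' Run the full screen on a simulated (or assembled) plate
#'
#' Per field: PNLA scoring.  Per well: mean field score.  Plate level:
#' Z-prime from the control wells, inclusion decision, robust Z-scores of
#' the compound wells (controls excluded from the normalization population)
#' and hit calls.
#'
#' @param plate A `plate_sim` from [simulate_plate()], or a compatible list
#'   of wells (each with `well`, `role`, `compound` and `fields`, where each
#'   field has an `image`).
#' @param config See [screen_config()].
#' @return List: `field_table` (per-field readouts), `well_table` (per-well
#'   PNLA), `plate_stats` (control summaries + Z' + QC), `screen`
#'   (`screen_result` with hits).
#' @export
run_screen <- function(plate, config = screen_config()) {
  wells <- if (inherits(plate, "plate_sim")) plate$wells else plate
  roles <- vapply(wells, function(w) w$role, character(1))
  if (sum(roles == "negative_control") < 2 ||
      sum(roles == "positive_control") < 2)
    stop("plate must contain at least 2 negative and 2 positive control wells")
  frows <- list()
  wrows <- list()
  for (w in wells) {
    scores <- numeric(0)
    for (f in seq_along(w$fields)) {
      res <- score_field(w$fields[[f]]$image, config)
      frows[[length(frows) + 1]] <- data.frame(
        well = w$well, field = f, role = w$role,
        compound = if (is.null(w$compound)) NA_character_ else w$compound,
        n_cells = res$n_cells, n_puncta_total = res$n_puncta_total,
        n_puncta_in_rings = res$n_puncta_in_rings,
        pnla_px2 = res$pnla_px2, pnla_um2 = res$pnla_um2,
        perinuclear_fraction = res$perinuclear_fraction,
        ring_mean_intensity = res$ring_mean_intensity,
        flags = paste(res$flags, collapse = ";"))
      scores <- c(scores, res$pnla_px2)
    }
    wrows[[length(wrows) + 1]] <- data.frame(
      well = w$well, role = w$role,
      compound = if (is.null(w$compound)) NA_character_ else w$compound,
      pnla = mean(scores), n_fields = length(scores))
  }
  field_table <- do.call(rbind, frows)
  well_table <- do.call(rbind, wrows)

  pos <- well_table$pnla[well_table$role == "positive_control"]
  neg <- well_table$pnla[well_table$role == "negative_control"]
  zf <- z_factor(pos, neg)
  qc <- plate_qc(zf, config$qc_band)
  plate_stats <- list(mu_pos = mean(pos), sigma_pos = stats::sd(pos),
                      mu_neg = mean(neg), sigma_neg = stats::sd(neg),
                      z_factor = zf, included = qc$included,
                      in_band = qc$in_band, qc_band = config$qc_band)

  cmpd <- well_table[well_table$role == "compound", ]
  screen <- robust_z_scores(data.frame(compound = cmpd$compound,
                                       value = cmpd$pnla),
                            scale = config$mad_scale)
  screen <- call_hits(screen, config$hit_threshold)
  list(field_table = field_table, well_table = well_table,
       plate_stats = plate_stats, screen = screen)
}

#' Classify a time course as early / late / no LMP
#'
#' Puncta formation is "evident" at the first timepoint where the
#' puncta-positive percentage among live cells reaches
#' `max(lmp_rise_factor * baseline, lmp_min_pct)` (baseline = value at the
#' first timepoint).  Classes: `early` if evident strictly before
#' `lmp_split_h` (12 h), `late` if evident at or after it, `none` if never.
#'
#' @param readouts Data frame from [timecourse_readouts()].
#' @param config See [screen_config()].
#' @return List: `class`, `t_evident_h` (NA if never), `threshold_pct`.
#' @export
classify_lmp_timecourse <- function(readouts, config = screen_config()) {
  t <- readouts$t_h
  if (min(t) >= config$lmp_split_h || max(t) < config$lmp_split_h)
    stop("time course must span the ", config$lmp_split_h,
         " h split to classify early vs late LMP")
  pct <- readouts$pct_puncta_positive
  baseline <- pct[which.min(t)]
  thr <- max(config$lmp_rise_factor * baseline, config$lmp_min_pct)
  ev <- which(!is.na(pct) & pct >= thr)
  if (length(ev) == 0)
    return(list(class = "none", t_evident_h = NA_real_,
                threshold_pct = thr))
  t_ev <- min(t[ev])
  list(class = if (t_ev < config$lmp_split_h) "early" else "late",
       t_evident_h = t_ev, threshold_pct = thr)
}

#' Run the LMP time-course analysis for several compounds
#'
#' @param series_by_compound Named list: compound id -> time-course series
#'   (as accepted by [timecourse_readouts()]).
#' @param config See [screen_config()].
#' @return List: `matrix` (compound x timepoint percent-positive, heatmap
#'   ready), `readouts` (long data frame), `classes` (named character
#'   vector).
#' @export
run_lmp_timecourse <- function(series_by_compound,
                               config = screen_config()) {
  stopifnot(length(series_by_compound) >= 1,
            !is.null(names(series_by_compound)))
  longs <- list()
  classes <- character(length(series_by_compound))
  names(classes) <- names(series_by_compound)
  for (cmpd in names(series_by_compound)) {
    ro <- timecourse_readouts(series_by_compound[[cmpd]], config)
    ro$compound <- cmpd
    longs[[cmpd]] <- ro
    classes[cmpd] <- classify_lmp_timecourse(ro, config)$class
  }
  long <- do.call(rbind, longs)
  rownames(long) <- NULL
  tps <- sort(unique(long$t_h))
  mat <- t(vapply(names(series_by_compound), function(cmpd) {
    ro <- longs[[cmpd]]
    ro$pct_puncta_positive[match(tps, ro$t_h)]
  }, numeric(length(tps))))
  colnames(mat) <- tps
  list(matrix = mat, readouts = long, classes = classes)
}
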