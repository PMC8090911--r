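# Perinuclear ring construction and the PNLA (perinuclear lysosome
# accumulation) score.
#
# Ring recipe: each segmented nucleus is reduced by `shrink_px` (default
# 2 px = 0.325 um at 0.1625 um/px), expanded by `grow_px` (default 25 px =
# 4.0625 um) without touching its neighbours, border-touching objects are
# removed, and the shrunken nucleus is subtracted from its expansion.  The
# PNLA score of a field is the mean area of the marker puncta lying within
# any ring.

#' Build perinuclear rings from nucleus labels
#'
#' Pipeline: [shrink_labels()] by `shrink_px`, then
#' [grow_labels_without_touching()] by `grow_px`, then
#' [remove_border_objects()], then per-label set difference (expansion minus
#' shrunken nucleus).  Each ring keeps its nucleus's label id.
#'
#' @param nuclei A [label_mask] of nuclei (e.g. from [find_round_objects()]).
#' @param shrink_px Nucleus reduction in pixels (default 2).
#' @param grow_px Collision-free expansion in pixels (default 25).
#' @return A `ring_set`: list with `ring_labels` ([label_mask]),
#'   `source_nuclei`, `shrunken`, `shrink_px`, `grow_px`.
#' @export
build_perinuclear_rings <- function(nuclei, shrink_px = 2, grow_px = 25) {
  stopifnot(inherits(nuclei, "label_mask"))
  if (n_labels(nuclei) == 0) {
    warning("empty nucleus mask: returning empty ring set")
    empty <- label_mask(matrix(0L, nrow(nuclei), ncol(nuclei)),
                        pixel_size(nuclei))
    return(structure(list(ring_labels = empty, source_nuclei = nuclei,
                          shrunken = empty, shrink_px = shrink_px,
                          grow_px = grow_px), class = "ring_set"))
  }
  shrunk <- shrink_labels(nuclei, shrink_px)
  expanded <- grow_labels_without_touching(shrunk, grow_px)
  expanded <- remove_border_objects(expanded)
  rings <- unclass_mask(expanded)
  rings[unclass_mask(shrunk) > 0] <- 0L
  # drop ring fragments whose expansion was border-removed
  structure(list(ring_labels = label_mask(rings, pixel_size(nuclei)),
                 source_nuclei = nuclei, shrunken = shrunk,
                 shrink_px = shrink_px, grow_px = grow_px),
            class = "ring_set")
}

#' @export
print.ring_set <- function(x, ...) {
  cat(sprintf("<ring_set: %d rings (shrink %d px, grow %d px, %.4f um/px)>\n",
              n_labels(x$ring_labels), x$shrink_px, x$grow_px,
              pixel_size(x$ring_labels)))
  invisible(x)
}

#' Physical width of the ring expansion
#'
#' @param rings A `ring_set`.
#' @return Expansion width `grow_px * pixel_size_um` in micrometres.
#' @export
ring_width_um <- function(rings) {
  stopifnot(inherits(rings, "ring_set"))
  rings$grow_px * pixel_size(rings$ring_labels)
}

# membership of each punctum (by rounded centroid pixel) in any ring
puncta_membership <- function(puncta, rings, rule = c("centroid", "overlap")) {
  rule <- match.arg(rule)
  lab <- unclass_mask(puncta)
  ringm <- unclass_mask(rings$ring_labels)
  if (!all(dim(lab) == dim(ringm)))
    stop("puncta and rings have mismatched geometry")
  feats <- mask_features(puncta)
  if (nrow(feats) == 0) return(cbind(feats, member = logical(0)))
  if (rule == "centroid") {
    r <- pmin(pmax(round(feats$row), 1), nrow(lab))
    c <- pmin(pmax(round(feats$col), 1), ncol(lab))
    feats$member <- ringm[cbind(r, c)] > 0
  } else {
    feats$member <- vapply(feats$label, function(l)
      any(ringm[lab == l] > 0), logical(1))
  }
  feats
}

#' PNLA score of a field
#'
#' The perinuclear lysosome accumulation (PNLA) score is the mean pixel area
#' of the marker puncta lying within any perinuclear ring, pooled over the
#' field.  A punctum is "within" a ring when its centroid pixel lies in the
#' ring (`membership = "centroid"`, default) or when it overlaps any ring
#' pixel (`"overlap"`).  Fields without member puncta score 0 and are
#' flagged rather than dropped, so cytotoxic wells do not bias upward.
#'
#' @param puncta A [label_mask] of detected puncta.
#' @param rings A `ring_set` from [build_perinuclear_rings()].
#' @param marker_image Optional marker-channel matrix for the ring-intensity
#'   companion readout.
#' @param membership Membership rule, `"centroid"` or `"overlap"`.
#' @return A `pnla_result` list: `pnla_px2`, `pnla_um2`,
#'   `n_puncta_in_rings`, `n_puncta_total`, `perinuclear_fraction`,
#'   `ring_mean_intensity`, `n_cells`, `flags`.
#' @export
pnla_score <- function(puncta, rings, marker_image = NULL,
                       membership = c("centroid", "overlap")) {
  stopifnot(inherits(puncta, "label_mask"), inherits(rings, "ring_set"))
  feats <- puncta_membership(puncta, rings, membership)
  n_total <- nrow(feats)
  member <- feats$member
  n_in <- sum(member)
  flags <- character(0)
  if (n_in == 0) flags <- c(flags, "no_ring_puncta")
  px <- pixel_size(puncta)
  score <- if (n_in > 0) mean(feats$area_px[member]) else 0
  ring_int <- if (!is.null(marker_image)) {
    ringm <- unclass_mask(rings$ring_labels)
    if (!all(dim(marker_image) == dim(ringm)))
      stop("marker image and rings have mismatched geometry")
    if (any(ringm > 0)) mean(marker_image[ringm > 0]) else NA_real_
  } else NA_real_
  structure(list(
    pnla_px2 = score, pnla_um2 = score * px^2,
    n_puncta_in_rings = n_in, n_puncta_total = n_total,
    perinuclear_fraction = if (n_total > 0) n_in / n_total else NA_real_,
    ring_mean_intensity = ring_int,
    n_cells = n_labels(rings$ring_labels), flags = flags),
    class = "pnla_result")
}

#' @export
print.pnla_result <- function(x, ...) {
  cat(sprintf(paste0("<pnla_result: score %.2f px^2 (%.4f um^2), ",
                     "%d/%d puncta in rings (fraction %.3f), %d cells%s>\n"),
              x$pnla_px2, x$pnla_um2, x$n_puncta_in_rings, x$n_puncta_total,
              x$perinuclear_fraction, x$n_cells,
              if (length(x$flags)) paste0(", flags: ",
                                          paste(x$flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Fraction of puncta inside the perinuclear rings
#'
#' @inheritParams pnla_score
#' @return Member count / total count; `NA` (with attribute
#'   `flag = "no_puncta"`) when no puncta were detected.
#' @export
perinuclear_fraction <- function(puncta, rings,
                                 membership = c("centroid", "overlap")) {
  feats <- puncta_membership(puncta, rings, membership)
  if (nrow(feats) == 0)
    return(structure(NA_real_, flag = "no_puncta"))
  sum(feats$member) / nrow(feats)
}

#' Mean marker intensity over the perinuclear rings
#'
#' @param marker_image Marker-channel intensity matrix.
#' @param rings A `ring_set`.
#' @return Mean intensity over all ring pixels.
#' @export
ring_intensity <- function(marker_image, rings) {
  stopifnot(inherits(rings, "ring_set"))
  check_image(marker_image)
  ringm <- unclass_mask(rings$ring_labels)
  if (!all(dim(marker_image) == dim(ringm)))
    stop("marker image and rings have mismatched geometry")
  if (!any(ringm > 0)) stop("empty ring set: no ring pixels to average")
  mean(marker_image[ringm > 0])
}
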