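# Disk interfaces: 16-bit per-channel TIFF, ground-truth CSV sidecar
# (0-based (row, col) coordinates, origin top-left) and YAML spec dumps.

#' Write a field as per-channel 16-bit TIFF files
#'
#' One file per channel, named `<prefix>_<channel>.tif`, intensities clamped
#' to [0, 65535].
#'
#' @param image A `field_image`.
#' @param prefix Path prefix (directories must exist).
#' @return Invisibly, the written file paths.
#' @export
write_field_tiff <- function(image, prefix) {
  stopifnot(inherits(image, "field_image"))
  paths <- character(0)
  for (ch in names(image$channels)) {
    p <- paste0(prefix, "_", ch, ".tif")
    m <- pmin(pmax(image$channels[[ch]], 0), 65535) / 65535
    tiff::writeTIFF(m, p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a single-channel TIFF as an intensity matrix
#'
#' @param path TIFF file path.
#' @param scale Multiplier applied to the [0, 1] pixel values (default
#'   65535, inverting [write_field_tiff()]).
#' @return Numeric matrix.
#' @export
read_tiff_matrix <- function(path, scale = 65535) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * scale
}

#' Write a ground-truth sidecar CSV
#'
#' Long table with one row per object: `object_id`, `type`
#' (`nucleus`/`punctum`), `well`, `field`, `x`, `y` (0-based column/row,
#' origin top-left), `area_px`, `class`.
#'
#' @param truth A `ground_truth` from the generator.
#' @param path Output CSV path.
#' @param well,field Optional identifiers embedded in the table.
#' @return Invisibly, the written data frame.
#' @export
write_ground_truth_csv <- function(truth, path, well = NA, field = NA) {
  stopifnot(inherits(truth, "ground_truth"))
  nu <- truth$nuclei
  pu <- truth$puncta
  df <- rbind(
    if (nrow(nu) > 0) data.frame(
      object_id = paste0("nucleus_", nu$cell), type = "nucleus",
      well = well, field = field, x = nu$col - 1, y = nu$row - 1,
      area_px = round(pi * nu$radius_rendered^2, 1),
      class = ifelse(nu$dead, "dead", "live")) else NULL,
    if (nrow(pu) > 0) data.frame(
      object_id = paste0("punctum_", seq_len(nrow(pu))), type = "punctum",
      well = well, field = field, x = pu$col - 1, y = pu$row - 1,
      area_px = pu$area_px, class = pu$radial_class) else NULL)
  if (is.null(df))
    df <- data.frame(object_id = character(0), type = character(0),
                     well = character(0), field = character(0),
                     x = numeric(0), y = numeric(0), area_px = numeric(0),
                     class = character(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a generator spec as YAML
#'
#' @param spec Any generator spec (`field_spec`, `plate_spec`,
#'   `timecourse_spec`, `organoid_spec`).
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_spec_yaml <- function(spec, path) {
  x <- unclass(spec)
  x$spec_class <- class(spec)[1]
  if (is.data.frame(x$roles)) x$roles <- as.list(x$roles)
  if (inherits(x$field, "field_spec")) x$field <- unclass(x$field)
  yaml::write_yaml(x, path)
  invisible(path)
}
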