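# Plate quality control, robust normalization and hit calling.
#
# Z' (Z-prime, Z-factor):  Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos -
# mean_neg|, sample standard deviations.  Plates are included iff Z' > 0;
# the acceptable band for complex phenotypic assays is 0 < Z' < 0.5.
#
# Robust Z-score:  z_i = (x_i - median(X)) / MAD(X) with the raw
# (unscaled) median absolute deviation, exactly as the formula is usually
# printed for screening data; the Gaussian consistency factor 1.4826 is
# opt-in.  Compounds with z >= 2 (two MADs above the sample median) are
# called hits.

#' Z-prime (Z-factor) plate-separation statistic
#'
#' `1 - 3 * (sd(pos) + sd(neg)) / abs(mean(pos) - mean(neg))` with sample
#' (n-1 denominator) standard deviations.
#'
#' @param pos_values,neg_values Readouts of the positive / negative control
#'   wells (>= 2 each).
#' @return Scalar Z' (<= 1; 1 only for zero-spread controls).
#' @export
z_factor <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2)
    stop("need at least 2 values per control arm")
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n)
    stop("control means are equal: Z-prime separation undefined")
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / abs(mu_p - mu_n)
}

#' Plate inclusion decision from Z-prime
#'
#' A plate is included iff its Z' is positive; the result also annotates
#' whether Z' falls inside the acceptable band for complex phenotypic
#' screening assays (default (0, 0.5), exclusive).
#'
#' @param z Scalar Z' value (e.g. from [z_factor()]).
#' @param qc_band Acceptable band, length-2 numeric.
#' @return List with `z_factor`, `included`, `in_band`, `qc_band`.
#' @export
plate_qc <- function(z, qc_band = c(0, 0.5)) {
  list(z_factor = z, included = z > 0,
       in_band = z > qc_band[1] && z < qc_band[2], qc_band = qc_band)
}

#' Robust Z-scores of compound readouts
#'
#' `(x_i - median(X)) / MAD(X)` where `X` is the normalization population
#' (by default all supplied compound values, controls excluded upstream) and
#' MAD is the raw median absolute deviation (`scale = 1`); set
#' `scale = 1.4826` for the Gaussian-consistent variant.
#'
#' @param values Named numeric vector (names = compound ids) or a data frame
#'   with columns `compound` and `value`.
#' @param scale MAD multiplier (default 1, the formula as printed).
#' @return A `screen_result` data frame: `compound`, `value`, `robust_z`,
#'   and (after [call_hits()]) `hit`.
#' @export
robust_z_scores <- function(values, scale = 1) {
  if (is.data.frame(values)) {
    stopifnot(all(c("compound", "value") %in% names(values)))
    df <- values[, c("compound", "value")]
  } else {
    df <- data.frame(compound = if (is.null(names(values)))
      as.character(seq_along(values)) else names(values),
      value = as.numeric(values))
  }
  if (nrow(df) < 3) stop("need at least 3 compound values")
  med <- stats::median(df$value)
  mad_raw <- stats::median(abs(df$value - med)) * scale
  if (mad_raw == 0)
    stop("MAD of the normalization population is zero (degenerate dispersion)")
  df$robust_z <- (df$value - med) / mad_raw
  class(df) <- c("screen_result", "data.frame")
  attr(df, "median") <- med
  attr(df, "mad") <- mad_raw
  df
}

#' Call hits at a robust-Z threshold
#'
#' Flags compounds whose robust Z-score is `threshold` or higher (inclusive
#' boundary: "2 or higher").
#'
#' @param result A `screen_result` from [robust_z_scores()].
#' @param threshold Hit threshold in MAD units (default 2).
#' @return The `screen_result` with logical column `hit` and attribute
#'   `hit_threshold`.
#' @export
call_hits <- function(result, threshold = 2) {
  stopifnot(inherits(result, "screen_result"))
  result$hit <- result$robust_z >= threshold
  attr(result, "hit_threshold") <- threshold
  result
}

#' Two-sample comparison (Student's t-test)
#'
#' Thin wrapper around [stats::t.test()]; the Welch (unequal-variance)
#' variant is the default, the pooled-variance variant is available with
#' `var_equal = TRUE`.
#'
#' @param a_values,b_values Numeric samples (>= 2 each).
#' @param var_equal Use the pooled-variance test.
#' @return List with `statistic`, `p_value`, `df`, `method`.
#' @export
compare_two_conditions <- function(a_values, b_values, var_equal = FALSE) {
  if (length(a_values) < 2 || length(b_values) < 2)
    stop("need at least 2 values per arm")
  if (stats::sd(a_values) == 0 && stats::sd(b_values) == 0)
    stop("degenerate input: both samples are constant")
  tt <- stats::t.test(a_values, b_values, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), method = tt$method)
}
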