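#' Per-endosome log10 intensity ratios
#'
#' Computes `log10(mean_fp / mean_dye)` for each region of a
#' [region_stats()] table. The ratio is oriented fluorescent protein over
#' dye, so it falls as the lumen acidifies. Regions with a non-positive
#' mean in either channel cannot be ratioed and are dropped with a warning.
#'
#' @param region_table data.frame with columns `mean_fp` and `mean_dye`.
#' @return Numeric vector of log10 ratios, one per retained region, with
#'   attribute `n_dropped`.
#' @export
per_endosome_log_ratio <- function(region_table) {
  stopifnot(all(c("mean_fp", "mean_dye") %in% names(region_table)))
  ok <- region_table$mean_dye > 0 & region_table$mean_fp > 0
  if (any(!ok))
    warning(sum(!ok), " region(s) dropped (non-positive channel mean)")
  out <- log10(region_table$mean_fp[ok] / region_table$mean_dye[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Fit a log-linear pH calibration curve
#'
#' Ordinary least squares of the mean log10(fp/dye) ratio at each
#' calibration pH against pH: `log10(ratio) = a * pH + b`. Following the
#' way standard curves are plotted (one averaged point per buffer pH with
#' SD error bars), both the fit and its R-squared are computed on the
#' per-pH means; the per-endosome scatter is retained as per-pH SDs.
#'
#' @param ph numeric vector of pH values, one per observation.
#' @param log_ratio numeric vector of per-endosome log10 ratios, same
#'   length.
#' @return A `CalibrationCurve`: list with `slope`, `intercept`,
#'   `r_squared`, `ph_range` (range of the calibration grid), and `per_ph`
#'   (data.frame `ph, mean_log_ratio, sd_log_ratio, n`).
#' @export
fit_calibration <- function(ph, log_ratio) {
  stopifnot(length(ph) == length(log_ratio))
  grid <- sort(unique(ph))
  if (length(grid) < 3) stop("need at least 3 distinct calibration pH values")
  per_ph <- data.frame(
    ph = grid,
    mean_log_ratio = as.numeric(tapply(log_ratio, factor(ph, grid), mean)),
    sd_log_ratio = as.numeric(tapply(log_ratio, factor(ph, grid), stats::sd)),
    n = as.integer(table(factor(ph, grid))))
  fit <- stats::lm(mean_log_ratio ~ ph, data = per_ph)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((per_ph$mean_log_ratio - mean(per_ph$mean_log_ratio))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 ph_range = range(grid),
                 per_ph = per_ph),
            class = "CalibrationCurve")
}

#' @export
print.CalibrationCurve <- function(x, ...) {
  cat(sprintf(
    "<CalibrationCurve> log10(ratio) = %.4f * pH + %.4f  (R^2 = %.4f, pH %.1f-%.1f)\n",
    x$slope, x$intercept, x$r_squared, x$ph_range[1], x$ph_range[2]))
  invisible(x)
}

#' Invert a calibration curve: log ratio to pH
#'
#' Returns `(log_ratio - intercept) / slope`. Estimates falling outside the
#' curve's calibration range are returned unchanged but flagged, since
#' ratiometric variance grows rapidly outside each probe's optimal pH
#' range and such values should not be trusted quantitatively.
#'
#' @param curve a [fit_calibration()] result.
#' @param log_ratio numeric vector of log10(fp/dye) values.
#' @return Numeric vector of pH estimates with logical attribute
#'   `out_of_range`.
#' @export
invert_calibration <- function(curve, log_ratio) {
  stopifnot(inherits(curve, "CalibrationCurve"))
  if (curve$slope == 0) stop("calibration slope is zero; cannot invert")
  ph <- (log_ratio - curve$intercept) / curve$slope
  attr(ph, "out_of_range") <- ph < curve$ph_range[1] | ph > curve$ph_range[2]
  ph
}

#' Empirical dynamic range from a fitted calibration
#'
#' Fold change of the intensity ratio across a pH interval implied by the
#' fitted slope: `10^(slope * (pH_high - pH_low))`. Both pH values must lie
#' inside the curve's calibration range.
#'
#' @param curve a [fit_calibration()] result.
#' @param ph_high,ph_low pH interval endpoints (`ph_high > ph_low`).
#' @return Fold change.
#' @export
empirical_dynamic_range <- function(curve, ph_high, ph_low) {
  stopifnot(inherits(curve, "CalibrationCurve"))
  if (ph_high <= ph_low) stop("ph_high must exceed ph_low")
  rng <- curve$ph_range
  if (ph_high > rng[2] || ph_low < rng[1])
    stop("pH values outside the calibration range")
  10^(curve$slope * (ph_high - ph_low))
}

#' Write / read a calibration curve as JSON
#'
#' @param curve a `CalibrationCurve`.
#' @param path JSON file path.
#' @param sensor_name optional sensor label stored alongside.
#' @return `write_calibration_json` returns `path` invisibly;
#'   `read_calibration_json` returns a `CalibrationCurve`.
#' @export
write_calibration_json <- function(curve, path, sensor_name = NULL) {
  stopifnot(inherits(curve, "CalibrationCurve"))
  jsonlite::write_json(
    list(sensor = sensor_name, slope = curve$slope,
         intercept = curve$intercept, r_squared = curve$r_squared,
         ph_range = curve$ph_range, per_ph = curve$per_ph),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = j$slope, intercept = j$intercept,
                 r_squared = j$r_squared, ph_range = as.numeric(j$ph_range),
                 per_ph = as.data.frame(j$per_ph)),
            class = "CalibrationCurve")
}

#' Default calibration pH grid for each SRpHi probe
#'
#' The optimal (usable) pH range of each probe, in 0.5-unit steps:
#' SRpHi1/4 pH 5.0-7.0, SRpHi2 pH 4.5-6.5, SRpHi3 pH 5.5-7.5.
#'
#' @param name sensor name.
#' @return Numeric vector of calibration pH values.
#' @export
calibration_grid <- function(name = c("SRpHi1", "SRpHi2", "SRpHi3", "SRpHi4")) {
  name <- match.arg(name)
  rng <- switch(name,
    SRpHi1 = c(5.0, 7.0), SRpHi4 = c(5.0, 7.0),
    SRpHi2 = c(4.5, 6.5), SRpHi3 = c(5.5, 7.5))
  seq(rng[1], rng[2], by = 0.5)
}
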