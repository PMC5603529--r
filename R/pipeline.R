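#' Run configuration for the calibration workflow
#'
#' A serializable bundle of everything [run_calibration_workflow()] needs;
#' re-running an identical configuration reproduces identical outputs.
#'
#' @param sensor_name SRpHi probe name (see [srphi_sensor()]).
#' @param modality optics preset, `"confocal"` or `"STED"`.
#' @param ph_values calibration pH grid; defaults to the probe's optimal
#'   range via [calibration_grid()].
#' @param n_per_ph endosomes simulated per pH.
#' @param seed integer master seed.
#' @param noise apply the detector noise model?
#' @param min_endosomes_per_ph minimum segmented endosomes per pH before a
#'   warning is raised (standard curves conventionally use > 150).
#' @param background_subtract subtract the ROI-estimated background from
#'   each channel before ratioing (off by default; raw ratios are used).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return A `RunConfig` list.
#' @export
run_config <- function(sensor_name = "SRpHi1", modality = "confocal",
                       ph_values = NULL, n_per_ph = 150L, seed = 1L,
                       noise = TRUE, min_endosomes_per_ph = 150L,
                       background_subtract = FALSE, out_dir = NULL) {
  if (is.null(ph_values)) ph_values <- calibration_grid(sensor_name)
  structure(list(sensor_name = sensor_name, modality = modality,
                 ph_values = ph_values, n_per_ph = n_per_ph,
                 seed = as.integer(seed), noise = noise,
                 min_endosomes_per_ph = min_endosomes_per_ph,
                 background_subtract = background_subtract,
                 out_dir = out_dir),
            class = "RunConfig")
}

#' End-to-end ratiometric calibration workflow
#'
#' Simulates (or accepts) a nigericin-style equilibration series, segments
#' each field on the dye channel, computes per-endosome log10(fp/dye)
#' ratios and fits the log-linear calibration curve. When `out_dir` is set
#' the curve (JSON), the per-endosome table (CSV), a standard-curve plot
#' (PNG) and a provenance record (JSON: config, seeds, package versions)
#' are written there.
#'
#' @param config a [run_config()].
#' @param series optional pre-simulated series (as returned by
#'   [simulate_calibration_series()]); simulated from `config` when `NULL`.
#' @return List with `curve` (a `CalibrationCurve`), `table` (per-endosome
#'   data.frame: ph, region stats, log_ratio), `counts` (segmented
#'   endosomes per pH) and `config`.
#' @export
run_calibration_workflow <- function(config, series = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  sens <- srphi_sensor(config$sensor_name)
  optics <- optics_preset(config$modality)
  if (is.null(series)) {
    message("simulating calibration series: pH ",
            paste(config$ph_values, collapse = ", "))
    series <- simulate_calibration_series(config$ph_values, config$n_per_ph,
                                          sens, optics, seed = config$seed,
                                          noise = config$noise)
  }
  rows <- lapply(series, function(entry) {
    regions <- segment_endosomes(entry$pair$dye)
    tab <- region_stats(regions, entry$pair)
    if (config$background_subtract && nrow(tab)) {
      bg <- background_stats(entry$pair, regions, seed = config$seed)
      tab$mean_fp <- tab$mean_fp - bg$fp
      tab$mean_dye <- tab$mean_dye - bg$dye
    }
    if (nrow(tab) < config$min_endosomes_per_ph)
      warning("only ", nrow(tab), " endosomes segmented at pH ", entry$ph,
              " (minimum ", config$min_endosomes_per_ph, ")")
    if (!nrow(tab)) return(NULL)
    lr <- suppressWarnings(per_endosome_log_ratio(tab))
    keep <- tab$mean_dye > 0 & tab$mean_fp > 0
    cbind(ph = entry$ph, tab[keep, , drop = FALSE], log_ratio = as.numeric(lr))
  })
  table <- do.call(rbind, rows)
  message("fitting calibration on ", nrow(table), " endosomes")
  curve <- fit_calibration(table$ph, table$log_ratio)
  counts <- table(table$ph)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_calibration_json(curve, file.path(config$out_dir, "calibration.json"),
                           sensor_name = config$sensor_name)
    utils::write.csv(table, file.path(config$out_dir, "endosomes.csv"),
                     row.names = FALSE)
    plot_calibration(curve, file.path(config$out_dir, "standard_curve.png"))
    write_provenance(config, file.path(config$out_dir, "provenance.json"))
  }
  list(curve = curve, table = table, counts = counts, config = config)
}

# Standard-curve diagnostic plot: per-pH mean log ratios with SD bars and
# the fitted line.
plot_calibration <- function(curve, path) {
  grDevices::png(path, width = 720, height = 540)
  on.exit(grDevices::dev.off())
  pp <- curve$per_ph
  graphics::plot(pp$ph, pp$mean_log_ratio, pch = 19,
                 xlab = "pH", ylab = "log10(FP / dye)",
                 main = sprintf("Standard curve (R^2 = %.3f)", curve$r_squared))
  graphics::arrows(pp$ph, pp$mean_log_ratio - pp$sd_log_ratio,
                   pp$ph, pp$mean_log_ratio + pp$sd_log_ratio,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(curve$intercept, curve$slope, col = "red")
  invisible(path)
}

write_provenance <- function(config, path) {
  jsonlite::write_json(
    list(config = unclass(config),
         r_version = R.version.string,
         package_version = as.character(utils::packageVersion("endopH")),
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Segment an image pair and estimate per-endosome pH
#'
#' Convenience wrapper for the measurement side of the pipeline: segments
#' the dye channel, builds the pH map with the supplied calibration and
#' returns the per-endosome pH table.
#'
#' @param pair an `ImagePair`.
#' @param curve a [fit_calibration()] curve.
#' @param min_size minimum region area in pixels.
#' @return A [per_endosome_ph()] table.
#' @export
analyze_image_pair <- function(pair, curve, min_size = 5L) {
  regions <- segment_endosomes(pair$dye, min_size = min_size)
  map <- build_ph_map(pair, regions, curve)
  per_endosome_ph(map, pair)
}

#' Regression of endosome mean intensity on endosome size
#'
#' Tests whether region brightness scales with region area: ordinary least
#' squares of per-region mean intensity on area in pixels. For
#' well-behaved ratiometric data the two should be essentially unrelated
#' (R-squared near zero); a strong relation would indicate that small
#' endosomes sink toward the noise floor.
#'
#' @param region_table data.frame with `area_px` and an intensity column.
#' @param intensity column name to regress (default `"mean_dye"`).
#' @return List with `slope`, `intercept`, `r_squared` and `n`.
#' @export
size_intensity_regression <- function(region_table, intensity = "mean_dye") {
  stopifnot(intensity %in% names(region_table))
  if (nrow(region_table) < 10) stop("need at least 10 regions")
  if (stats::var(region_table$area_px) == 0)
    stop("degenerate region table: constant area")
  fit <- stats::lm(region_table[[intensity]] ~ region_table$area_px)
  ss_tot <- sum((region_table[[intensity]] - mean(region_table[[intensity]]))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = nrow(region_table))
}

#' Compare two endosome pH populations
#'
#' Group means and SDs, a pooled-variance two-tailed Student's t-test, and
#' pH histograms in 0.5-unit bins (left-closed, right-open, anchored at
#' integer pH).
#'
#' @param ph_a,ph_b numeric vectors of per-endosome pH estimates.
#' @return List with `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `p_value`, `sem_a`, `sem_b`, `breaks` and histogram `counts`
#'   (matrix, one row per group).
#' @export
compare_populations <- function(ph_a, ph_b) {
  if (length(ph_a) < 2 || length(ph_b) < 2)
    stop("need at least 2 values per group")
  lo <- floor(min(ph_a, ph_b))
  hi <- floor(max(ph_a, ph_b) / 0.5) * 0.5 + 0.5   # smallest covering edge
  breaks <- seq(lo, hi, by = 0.5)
  countb <- function(x) {
    as.integer(table(cut(x, breaks, right = FALSE, include.lowest = FALSE)))
  }
  tt <- stats::t.test(ph_a, ph_b, var.equal = TRUE, alternative = "two.sided")
  counts <- rbind(a = countb(ph_a), b = countb(ph_b))
  colnames(counts) <- paste0("[", breaks[-length(breaks)], ",",
                             breaks[-1], ")")
  list(mean_a = mean(ph_a), sd_a = stats::sd(ph_a),
       sem_a = stats::sd(ph_a) / sqrt(length(ph_a)), n_a = length(ph_a),
       mean_b = mean(ph_b), sd_b = stats::sd(ph_b),
       sem_b = stats::sd(ph_b) / sqrt(length(ph_b)), n_b = length(ph_b),
       p_value = tt$p.value, breaks = breaks, counts = counts, test = tt)
}
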