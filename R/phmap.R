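#' Build a per-pixel ratiometric pH map
#'
#' Within the endosome mask, each pixel's pH is obtained by dividing the
#' protein channel by the dye channel, taking log10 and inverting the
#' calibration curve. Pixels outside the mask, pixels with a zero dye
#' value and saturated input pixels carry `NA` in the pH image. The 8-bit
#' display image maps the calibration pH range affinely onto 0-255 (a
#' linear LUT over pH), clipping outside values; background renders as 0.
#'
#' @param pair an `ImagePair`.
#' @param regions a [segment_endosomes()] result for the pair.
#' @param curve a [fit_calibration()] curve.
#' @return A `PHMap`: list with `ph_image` (numeric matrix, `NA` outside
#'   the mask), `display_image` (integer matrix in 0-255), `calibration`
#'   and `regions`.
#' @export
build_ph_map <- function(pair, regions, curve) {
  stopifnot(inherits(pair, "ImagePair"), inherits(regions, "LabeledRegions"),
            inherits(curve, "CalibrationCurve"))
  if (!all(dim(regions$label_map) == dim(pair$fp)))
    stop("label map and images have different dimensions")
  mask <- regions$label_map > 0L & pair$dye > 0 &
    !pair$saturated$fp & !pair$saturated$dye
  if (!any(mask)) warning("empty mask: pH map contains no pixels")
  ph <- matrix(NA_real_, nrow(pair$fp), ncol(pair$fp))
  ph[mask] <- invert_calibration(curve,
                                 log10(pair$fp[mask] / pair$dye[mask]))
  rng <- curve$ph_range
  disp <- matrix(0L, nrow(ph), ncol(ph))
  scaled <- (ph[mask] - rng[1]) / (rng[2] - rng[1]) * 255
  disp[mask] <- as.integer(pmin(pmax(round(scaled), 0), 255))
  structure(list(ph_image = ph, display_image = disp,
                 calibration = curve, regions = regions),
            class = "PHMap")
}

#' @export
print.PHMap <- function(x, ...) {
  cat("<PHMap>", sum(!is.na(x$ph_image)), "in-mask pixels; pH range",
      paste(x$calibration$ph_range, collapse = "-"), "\n")
  invisible(x)
}

#' Per-endosome pH estimates from a pH map
#'
#' For each region, reports both the mean of the per-pixel pH values
#' (`ph_pixel_mean`) and the pH obtained from the ratio of the region's
#' channel mean intensities (`ph_ratio_of_means`). The two agree exactly
#' for a uniform-ratio region and approximately otherwise; both are
#' reported because either convention is defensible.
#'
#' @param map a [build_ph_map()] result.
#' @param pair the `ImagePair` the map was built from.
#' @return Region data.frame with `ph_pixel_mean`, `ph_ratio_of_means` and
#'   `out_of_range` (TRUE when the ratio-of-means estimate leaves the
#'   calibration range) appended.
#' @export
per_endosome_ph <- function(map, pair) {
  stopifnot(inherits(map, "PHMap"), inherits(pair, "ImagePair"))
  regions <- map$regions
  tab <- region_stats(regions, pair)
  if (!nrow(tab)) {
    tab$ph_pixel_mean <- numeric(0)
    tab$ph_ratio_of_means <- numeric(0)
    tab$out_of_range <- logical(0)
    return(tab)
  }
  idx <- which(regions$label_map > 0L & !is.na(map$ph_image))
  l <- regions$label_map[idx]
  px_mean <- tapply(map$ph_image[idx], factor(l, tab$label), mean)
  tab$ph_pixel_mean <- as.numeric(px_mean)
  rom <- invert_calibration(map$calibration,
                            log10(tab$mean_fp / tab$mean_dye))
  tab$ph_ratio_of_means <- as.numeric(rom)
  tab$out_of_range <- as.logical(attr(rom, "out_of_range"))
  tab
}

#' Write a pH map to disk
#'
#' Writes the per-pixel pH image as 32-bit float TIFF (`NA` encoded as
#' `background_code`), the display image as 8-bit TIFF, and the
#' per-endosome pH table as CSV. Float TIFF samples must lie in `[0, 1]`,
#' so pH values are stored divided by 14 (the full pH scale);
#' [read_ph_image()] undoes the scaling.
#'
#' @param map a `PHMap`.
#' @param pair the source `ImagePair`.
#' @param prefix output path prefix.
#' @param background_code value written for out-of-mask pixels in the
#'   float TIFF (in pH units).
#' @return Invisibly, the paths written.
#' @export
write_ph_map <- function(map, pair, prefix, background_code = 0) {
  ph <- map$ph_image
  ph[is.na(ph)] <- background_code
  p1 <- paste0(prefix, "_ph32.tif")
  tiff::writeTIFF(pmin(pmax(ph, 0), 14) / 14, p1, bits.per.sample = 32,
                  reduce = FALSE)
  p2 <- paste0(prefix, "_display.tif")
  tiff::writeTIFF(map$display_image / 255, p2, bits.per.sample = 8)
  p3 <- paste0(prefix, "_endosome_ph.csv")
  utils::write.csv(per_endosome_ph(map, pair), p3, row.names = FALSE)
  invisible(c(ph = p1, display = p2, table = p3))
}

#' @rdname write_ph_map
#' @param path a float TIFF written by `write_ph_map`.
#' @export
read_ph_image <- function(path) {
  tiff::readTIFF(path) * 14
}
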