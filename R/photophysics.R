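#' Single-site protonation occupancy
#'
#' Fraction of fluorophores in the bright (deprotonated) state under a
#' single-site protonation equilibrium, the Henderson-Hasselbalch form
#' `1 / (1 + 10^(pKa - pH))`. This is the quenching model used for
#' acid-sensitive fluorescent proteins such as EYFP: at `pH == pKa` exactly
#' half of the population is bright.
#'
#' @param pH pH value(s), dimensionless.
#' @param pKa protonation midpoint of the fluorophore, pH units.
#' @return Bright fraction in (0, 1), same length as `pH`.
#' @examples
#' protonation_fraction(6.9, 6.9)   # 0.5 at the midpoint
#' protonation_fraction(5.0, 6.9)   # strong quenching two pH units below pKa
#' @export
protonation_fraction <- function(pH, pKa) {
  if (!all(is.finite(pH)) || !all(is.finite(pKa)))
    stop("pH and pKa must be finite")
  1 / (1 + 10^(pKa - pH))
}

#' Construct a fluorophore pH-response model
#'
#' A `FluorophoreModel` describes relative brightness as a function of pH in
#' one of three modes:
#' \describe{
#'   \item{`protonation`}{single-site quenching,
#'     `brightness(pH) = acid_floor + (1 - acid_floor) * protonation_fraction(pH, pKa)`.
#'     The canonical model for GFP-derived proteins.}
#'   \item{`constant`}{pH-independent brightness 1, for acid-stable dyes
#'     (STAR400/410/512).}
#'   \item{`loglinear`}{`brightness(pH) = 10^(slope * (pH - ref_pH))`, an
#'     empirical description for dyes with mild in-solution attenuation.}
#' }
#' Brightness is normalized so the fully deprotonated (alkaline) state has
#' brightness 1; `brightness` scales it as a relative peak amplitude.
#'
#' @param name text label, e.g. `"EYFP"`.
#' @param mode one of `"protonation"`, `"constant"`, `"loglinear"`.
#' @param pKa protonation midpoint (protonation mode), pH units.
#' @param acid_floor residual bright fraction at very low pH, in `[0, 1)`.
#' @param slope log10-brightness change per pH unit (loglinear mode).
#' @param ref_pH anchor pH at which loglinear brightness equals 1.
#' @param brightness relative peak brightness, arbitrary units > 0.
#' @return An object of class `FluorophoreModel`.
#' @examples
#' eyfp <- fluorophore("EYFP", "protonation", pKa = 6.9)
#' star410 <- fluorophore("STAR410", "constant")
#' @export
fluorophore <- function(name, mode = c("protonation", "constant", "loglinear"),
                        pKa = NA_real_, acid_floor = 0,
                        slope = NA_real_, ref_pH = 7.0, brightness = 1) {
  mode <- match.arg(mode)
  if (mode == "protonation") {
    if (!is.finite(pKa)) stop("protonation mode requires a finite pKa")
    if (acid_floor < 0 || acid_floor >= 1)
      stop("acid_floor must be in [0, 1)")
  }
  if (mode == "loglinear" && !is.finite(slope))
    stop("loglinear mode requires a finite slope")
  if (!is.finite(brightness) || brightness <= 0)
    stop("brightness must be > 0")
  structure(
    list(name = name, mode = mode, pKa = pKa, acid_floor = acid_floor,
         slope = slope, ref_pH = ref_pH, brightness = brightness),
    class = "FluorophoreModel")
}

# Absolute model brightness on the normalized scale (1 = deprotonated state,
# respectively the loglinear anchor). Internal; relative_brightness() and
# sensor_ratio() are the public surface.
model_brightness <- function(f, pH) {
  stopifnot(inherits(f, "FluorophoreModel"))
  if (!all(is.finite(pH))) stop("pH must be finite")
  switch(f$mode,
    protonation = f$acid_floor +
      (1 - f$acid_floor) * protonation_fraction(pH, f$pKa),
    constant    = rep(1, length(pH)),
    loglinear   = 10^(f$slope * (pH - f$ref_pH)),
    stop("unknown fluorophore mode: ", f$mode))
}

#' Relative brightness of a fluorophore at one pH versus a reference pH
#'
#' @param f a [fluorophore()] model.
#' @param pH pH at which to evaluate.
#' @param ref_pH reference pH the result is normalized to.
#' @return `brightness(pH) / brightness(ref_pH)`; 1 for constant mode.
#' @examples
#' eyfp <- fluorophore("EYFP", "protonation", pKa = 6.9)
#' relative_brightness(eyfp, 5.0, 7.0)  # ~0.022: strong acid quenching
#' @export
relative_brightness <- function(f, pH, ref_pH) {
  model_brightness(f, pH) / model_brightness(f, ref_pH)
}

#' Construct a two-fluorophore ratiometric sensor model
#'
#' Pairs an acid-sensitive fluorescent protein (numerator channel) with an
#' acid-stable dye (denominator channel). `bleed_through` is the fraction of
#' the protein signal that leaks into the dye detection channel during
#' imaging; it is applied by the image renderer, not by the ideal
#' photophysical ratio.
#'
#' @param fp [fluorophore()] model for the pH-sensitive protein channel.
#' @param dye [fluorophore()] model for the acid-stable dye channel.
#' @param bleed_through fraction in `[0, 0.1]` of fp signal added to the dye
#'   channel.
#' @param label_ratio dye:protein labelling stoichiometry (metadata only).
#' @return An object of class `SensorModel`.
#' @export
sensor <- function(fp, dye, bleed_through = 0.05, label_ratio = 2) {
  stopifnot(inherits(fp, "FluorophoreModel"), inherits(dye, "FluorophoreModel"))
  if (identical(fp, dye)) stop("fp and dye must be distinct models")
  if (bleed_through < 0 || bleed_through > 0.1)
    stop("bleed_through must be in [0, 0.1]")
  structure(list(fp = fp, dye = dye, bleed_through = bleed_through,
                 label_ratio = label_ratio),
            class = "SensorModel")
}

#' Built-in SRpHi sensor models
#'
#' Default registry of the four SRpHi probes. The protein channel uses the
#' protonation model with the probe's pKa (EYFP 6.9, EGFP 5.9,
#' sepHluorin 7.1); dye channels (STAR410/512/400) are modelled as constant,
#' reflecting their acid stability in cells. Pass
#' `star410_loglinear = TRUE` to SRpHi1 to use instead the empirical
#' in-solution STAR410 attenuation (~37% residual at pH 5 vs 7).
#'
#' @param name one of `"SRpHi1"`, `"SRpHi2"`, `"SRpHi3"`, `"SRpHi4"`.
#' @param bleed_through fp-into-dye bleed-through fraction, default 0.05.
#' @param star410_loglinear use the log-linear STAR410 model (SRpHi1 only).
#' @return A [sensor()] model.
#' @examples
#' s <- srphi_sensor("SRpHi1")
#' dynamic_range(s, 7.0, 5.0)
#' @export
srphi_sensor <- function(name = c("SRpHi1", "SRpHi2", "SRpHi3", "SRpHi4"),
                         bleed_through = 0.05, star410_loglinear = FALSE) {
  name <- match.arg(name)
  reg <- list(
    SRpHi1 = list(fp = c("EYFP", 6.9),      dye = "STAR410"),
    SRpHi2 = list(fp = c("EGFP", 5.9),      dye = "STAR512"),
    SRpHi3 = list(fp = c("sepHluorin", 7.1), dye = "STAR512"),
    SRpHi4 = list(fp = c("EYFP", 6.9),      dye = "STAR400"))
  r <- reg[[name]]
  fp <- fluorophore(r$fp[1], "protonation", pKa = as.numeric(r$fp[2]))
  dye <- if (star410_loglinear && name == "SRpHi1") {
    # slope solving 10^(slope * (5 - 7)) = 0.37 (in-solution residual)
    fluorophore("STAR410", "loglinear", slope = log10(0.37) / -2, ref_pH = 7.0)
  } else {
    fluorophore(r$dye, "constant")
  }
  sensor(fp, dye, bleed_through = bleed_through)
}

#' Ideal sensor intensity ratio (FP over dye) at a given pH
#'
#' The photophysical fp/dye brightness ratio on the normalized scale
#' (brightness 1 in the fully deprotonated state). Bleed-through is an
#' imaging effect and is not applied here.
#'
#' @param s a [sensor()] model.
#' @param pH pH value(s).
#' @return Positive ratio value(s).
#' @export
sensor_ratio <- function(s, pH) {
  stopifnot(inherits(s, "SensorModel"))
  model_brightness(s$fp, pH) / model_brightness(s$dye, pH)
}

#' Ratiometric dynamic range of a sensor over a pH interval
#'
#' Fold change of the fp/dye ratio between a high and a low pH,
#' `sensor_ratio(pH_high) / sensor_ratio(pH_low)`. For an acid-quenched
#' numerator over an acid-stable denominator this is >= 1 and grows with the
#' width of the interval around the protein's pKa.
#'
#' @param s a [sensor()] model.
#' @param pH_high upper end of the range (must exceed `pH_low`).
#' @param pH_low lower end of the range.
#' @return Fold change (>= 1 for default sensors).
#' @examples
#' dynamic_range(srphi_sensor("SRpHi2"), 6.5, 4.5)  # > 15-fold
#' @export
dynamic_range <- function(s, pH_high, pH_low) {
  if (!is.finite(pH_high) || !is.finite(pH_low) || pH_high <= pH_low)
    stop("pH_high must be greater than pH_low")
  sensor_ratio(s, pH_high) / sensor_ratio(s, pH_low)
}

#' @export
print.FluorophoreModel <- function(x, ...) {
  cat("<FluorophoreModel>", x$name, "mode:", x$mode)
  if (x$mode == "protonation")
    cat(" pKa:", x$pKa, "acid_floor:", x$acid_floor)
  if (x$mode == "loglinear")
    cat(" slope:", signif(x$slope, 4), "ref_pH:", x$ref_pH)
  cat("\n")
  invisible(x)
}

#' @export
print.SensorModel <- function(x, ...) {
  cat("<SensorModel> fp:", x$fp$name, "/ dye:", x$dye$name,
      "bleed_through:", x$bleed_through, "\n")
  invisible(x)
}

#' Write / read a sensor model as JSON
#'
#' Serializes the fluorophore pair and bleed-through fraction so a sensor
#' configuration can travel with analysis outputs.
#'
#' @param s a [sensor()] model.
#' @param path file path for the JSON document.
#' @return `write_sensor_json` returns `path` invisibly; `read_sensor_json`
#'   returns a [sensor()] model.
#' @export
write_sensor_json <- function(s, path) {
  stopifnot(inherits(s, "SensorModel"))
  flat <- function(f) f[c("name", "mode", "pKa", "acid_floor", "slope",
                          "ref_pH", "brightness")]
  jsonlite::write_json(
    list(fp = flat(s$fp), dye = flat(s$dye),
         bleed_through = s$bleed_through, label_ratio = s$label_ratio),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_sensor_json
#' @export
read_sensor_json <- function(path) {
  j <- jsonlite::read_json(path)
  un <- function(f) {
    num <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
    fluorophore(f$name, f$mode, pKa = num(f$pKa),
                acid_floor = num(f$acid_floor) %|na|% 0,
                slope = num(f$slope), ref_pH = num(f$ref_pH) %|na|% 7,
                brightness = num(f$brightness) %|na|% 1)
  }
  sensor(un(j$fp), un(j$dye), bleed_through = j$bleed_through,
         label_ratio = j$label_ratio)
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a
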