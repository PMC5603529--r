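#' Optical model of the acquisition
#'
#' Bundles the point-spread function, sampling and detector parameters used
#' by the synthetic image renderer. The PSF is an isotropic 2-D Gaussian
#' parameterized by its full width at half maximum
#' (`sigma = psf_fwhm / 2.355`).
#'
#' @param modality `"confocal"` or `"STED"` (label only; the numbers govern).
#' @param psf_fwhm PSF FWHM in nm; length 1, or 2 for per-channel values
#'   (fp, dye).
#' @param pixel_size pixel pitch in nm/pixel; `psf_fwhm >= 2 * pixel_size`
#'   is enforced so the PSF is sampled adequately.
#' @param photon_scale expected detected counts per unit of ideal signal.
#' @param read_noise_sd Gaussian detector read noise, counts.
#' @param bit_depth output quantization, 8 or 16 bits.
#' @param background_level uniform background, counts.
#' @return An object of class `OpticsModel`.
#' @seealso [optics_preset()] for the defaults used throughout.
#' @export
optics_model <- function(modality = c("confocal", "STED"),
                         psf_fwhm, pixel_size,
                         photon_scale = 1, read_noise_sd = 2,
                         bit_depth = 16, background_level = 18) {
  modality <- match.arg(modality)
  if (any(psf_fwhm <= 0) || pixel_size <= 0)
    stop("psf_fwhm and pixel_size must be positive")
  if (min(psf_fwhm) < 2 * pixel_size)
    stop("undersampled PSF: psf_fwhm must be >= 2 * pixel_size")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  structure(list(modality = modality,
                 psf_fwhm = rep(psf_fwhm, length.out = 2),
                 pixel_size = pixel_size, photon_scale = photon_scale,
                 read_noise_sd = read_noise_sd, bit_depth = bit_depth,
                 background_level = background_level),
            class = "OpticsModel")
}

#' Default confocal and STED optics
#'
#' Confocal: 250 nm PSF (the diffraction limit) at 50 nm pixels.
#' STED: 50 nm PSF at 20 nm pixels. Both use 16-bit quantization, a
#' background of 18 counts and 2 counts read noise.
#'
#' @param modality `"confocal"` or `"STED"`.
#' @param ... overrides passed on to [optics_model()].
#' @return An `OpticsModel`.
#' @export
optics_preset <- function(modality = c("confocal", "STED"), ...) {
  modality <- match.arg(modality)
  defaults <- switch(modality,
    confocal = list(psf_fwhm = 250, pixel_size = 50),
    STED     = list(psf_fwhm = 50,  pixel_size = 20))
  args <- utils::modifyList(c(list(modality = modality), defaults), list(...))
  do.call(optics_model, args)
}

#' Place endosomes in a synthetic field of view
#'
#' Draws `n` endosome centres uniformly over the field (respecting a margin
#' and a minimum pairwise separation, by rejection sampling), diameters
#' uniformly over `diameter_range`, and luminal pH values from a normal
#' distribution truncated to pH 3-9. The default amplitude (expected peak
#' signal of an unblurred endosome, counts) is chosen so that segmented
#' endosomes are approximately 9-fold brighter than background under the
#' default confocal optics.
#'
#' @param n number of endosomes (>= 0).
#' @param diameter_range min/max endosome diameter, nm.
#' @param ph_mean,ph_sd mean and SD of the true luminal pH distribution.
#' @param field field size in pixels, `c(rows, cols)` (scalar recycled).
#' @param pixel_size nm per pixel (positions are stored in nm).
#' @param min_separation minimum pairwise centre distance, nm.
#' @param seed integer seed; identical seeds give identical scenes.
#' @param amplitude expected peak signal per endosome, counts.
#' @param margin distance from the field edge reserved free of centres, nm.
#' @return A `Scene`: list with `endosomes` (data.frame `id, x, y,
#'   diameter, true_ph, amplitude`; x/y in nm), `field` (pixels),
#'   `pixel_size` and `seed`.
#' @export
place_endosomes <- function(n, diameter_range = c(100, 500),
                            ph_mean = 6.0, ph_sd = 0.3,
                            field = c(512, 512), pixel_size = 50,
                            min_separation = 1200, seed = 1,
                            amplitude = 350, margin = NULL) {
  stopifnot(n >= 0)
  field <- rep(field, length.out = 2)
  if (is.null(margin)) margin <- max(500, min_separation / 2)
  ext <- field * pixel_size           # field extent in nm (rows, cols)
  if (n > 0 && any(ext - 2 * margin <= 0))
    stop("field too small for the requested margin")
  endo <- withr::with_seed(seed, {
    xs <- ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n) {
      if ((tries <- tries + 1L) > max(1000L, 200L * n))
        stop("could not place ", n, " endosomes at min_separation = ",
             min_separation, " nm in this field (packing infeasible)")
      x <- stats::runif(1, margin, ext[2] - margin)
      y <- stats::runif(1, margin, ext[1] - margin)
      if (length(xs) == 0 ||
          min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_separation) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
    }
    ph <- numeric(0)
    while (length(ph) < n) {          # truncated normal by resampling
      p <- stats::rnorm(n - length(ph), ph_mean, ph_sd)
      ph <- c(ph, p[p >= 3 & p <= 9])
    }
    data.frame(id = seq_len(n), x = xs, y = ys,
               diameter = if (n) stats::runif(n, diameter_range[1],
                                              diameter_range[2]) else numeric(0),
               true_ph = ph, amplitude = rep(amplitude, n))
  })
  structure(list(endosomes = endo, field = field,
                 pixel_size = pixel_size, seed = seed),
            class = "Scene")
}

#' @export
print.Scene <- function(x, ...) {
  cat("<Scene>", nrow(x$endosomes), "endosomes in", x$field[1], "x",
      x$field[2], "px field (", x$pixel_size, "nm/px )\n")
  invisible(x)
}

# Area coverage of a disk over the pixel grid, by subpixel supersampling.
# Returns a list(rows, cols, cov) patch; pixel (i, j) spans
# [(j-1)*px, j*px] x [(i-1)*px, i*px] in nm.
disk_coverage <- function(x, y, diameter, field, pixel_size, super = 8L) {
  r <- diameter / 2
  i0 <- max(1L, floor((y - r) / pixel_size) + 1L)
  i1 <- min(field[1], ceiling((y + r) / pixel_size))
  j0 <- max(1L, floor((x - r) / pixel_size) + 1L)
  j1 <- min(field[2], ceiling((x + r) / pixel_size))
  if (i0 > i1 || j0 > j1) return(NULL)
  off <- (seq_len(super) - 0.5) / super          # subsample offsets in [0,1]
  sx <- as.vector(outer(rep(1, super), off))     # super^2 subsample grid
  sy <- as.vector(outer(off, rep(1, super)))
  rows <- i0:i1; cols <- j0:j1
  cov <- matrix(0, length(rows), length(cols))
  for (a in seq_along(rows)) {
    py <- (rows[a] - 1) * pixel_size
    for (b in seq_along(cols)) {
      px <- (cols[b] - 1) * pixel_size
      dx <- px + sx * pixel_size - x
      dy <- py + sy * pixel_size - y
      cov[a, b] <- mean(dx * dx + dy * dy <= r * r)
    }
  }
  list(rows = rows, cols = cols, cov = cov)
}

# Separable Gaussian blur with a truncated (+-4 sigma), normalized kernel.
# Zero padding outside the field; interior flux is conserved exactly because
# each 1-D kernel sums to one.
blur_gaussian <- function(img, fwhm_nm, pixel_size) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2))) / pixel_size
  if (sigma < 1e-6) return(img)
  h <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (d in -h:h) {
      idx <- seq_len(n - abs(d))
      if (d >= 0) m[cbind(idx + d, idx)] <- k[d + h + 1]
      else        m[cbind(idx, idx - d)] <- k[d + h + 1]
    }
    m
  }
  band(nrow(img)) %*% img %*% t(band(ncol(img)))
}

# Poisson photon noise + Gaussian read noise + round-half-up quantization.
add_detector_noise <- function(ideal, optics) {
  lam <- optics$photon_scale * ideal
  counts <- matrix(stats::rpois(length(lam), lam), nrow(lam)) /
    optics$photon_scale
  counts <- counts + stats::rnorm(length(counts), 0, optics$read_noise_sd)
  maxv <- 2^optics$bit_depth - 1
  q <- pmin(pmax(floor(counts + 0.5), 0), maxv)
  matrix(q, nrow(ideal))
}

#' Render a two-channel image pair from a scene
#'
#' Each endosome contributes a uniform disk whose amplitude in each channel
#' is its `amplitude` times the channel fluorophore's relative brightness at
#' the endosome's true pH (referenced to `ref_ph`, the neutral baseline of
#' nascent vesicles). Disks are convolved with the channel's Gaussian PSF, a
#' uniform background is added, and a `bleed_through` fraction of the ideal
#' protein signal is added to the dye channel. With `noise = TRUE`, Poisson
#' photon noise (on `photon_scale` x ideal), Gaussian read noise and
#' round-half-up quantization to `bit_depth` are applied; with
#' `noise = FALSE` the continuous ideal image is returned unquantized.
#'
#' @param scene a [place_endosomes()] scene.
#' @param sensor a [sensor()] model.
#' @param optics an [optics_model()].
#' @param seed integer seed for the noise draws (ignored when `noise = FALSE`).
#' @param noise apply the detector noise model?
#' @param ref_ph reference pH for relative brightness (default 7.4).
#' @return An `ImagePair`: list with matrices `fp` and `dye`, `pixel_size`,
#'   `bit_depth`, logical saturation masks `saturated`, and the scene's
#'   ground-truth table as `truth`.
#' @export
render_image_pair <- function(scene, sensor, optics, seed = 1,
                              noise = TRUE, ref_ph = 7.4) {
  stopifnot(inherits(scene, "Scene"), inherits(sensor, "SensorModel"),
            inherits(optics, "OpticsModel"))
  if (!isTRUE(all.equal(scene$pixel_size, optics$pixel_size)))
    stop("scene was placed at ", scene$pixel_size, " nm/px but the optics ",
         "sample at ", optics$pixel_size, " nm/px")
  field <- scene$field
  ideal_fp <- matrix(0, field[1], field[2])
  ideal_dye <- matrix(0, field[1], field[2])
  e <- scene$endosomes
  if (nrow(e)) {
    rb_fp <- relative_brightness(sensor$fp, e$true_ph, ref_ph)
    rb_dye <- relative_brightness(sensor$dye, e$true_ph, ref_ph)
    for (i in seq_len(nrow(e))) {
      p <- disk_coverage(e$x[i], e$y[i], e$diameter[i], field,
                         optics$pixel_size)
      if (is.null(p)) next
      ideal_fp[p$rows, p$cols] <- ideal_fp[p$rows, p$cols] +
        e$amplitude[i] * rb_fp[i] * p$cov
      ideal_dye[p$rows, p$cols] <- ideal_dye[p$rows, p$cols] +
        e$amplitude[i] * rb_dye[i] * p$cov
    }
  }
  ideal_fp <- blur_gaussian(ideal_fp, optics$psf_fwhm[1], optics$pixel_size)
  ideal_dye <- blur_gaussian(ideal_dye, optics$psf_fwhm[2], optics$pixel_size)
  ideal_dye <- ideal_dye + sensor$bleed_through * ideal_fp
  ideal_fp <- ideal_fp + optics$background_level
  ideal_dye <- ideal_dye + optics$background_level
  if (noise) {
    fp <- withr::with_seed(seed, add_detector_noise(ideal_fp, optics))
    dye <- withr::with_seed(seed + 1L, add_detector_noise(ideal_dye, optics))
  } else {
    fp <- ideal_fp; dye <- ideal_dye
  }
  maxv <- 2^optics$bit_depth - 1
  sat <- list(fp = fp >= maxv, dye = dye >= maxv)
  if (mean(sat$fp) > 0.5 || mean(sat$dye) > 0.5)
    stop("more than half of the pixels are saturated; ",
         "amplitude/photon_scale misconfigured")
  structure(list(fp = fp, dye = dye, pixel_size = optics$pixel_size,
                 bit_depth = optics$bit_depth, saturated = sat,
                 truth = e),
            class = "ImagePair")
}

#' @export
print.ImagePair <- function(x, ...) {
  cat("<ImagePair>", nrow(x$fp), "x", ncol(x$fp), "px,",
      x$pixel_size, "nm/px,", x$bit_depth, "bit\n")
  invisible(x)
}

#' Simulate a pH calibration image series
#'
#' Emulates the nigericin/KCl equilibration experiment used to build
#' ratiometric standard curves: one field per calibration pH in which every
#' endosome's luminal pH equals the buffer pH exactly.
#'
#' @param ph_values calibration pH grid (all within 3-9).
#' @param n_per_ph endosomes per pH value.
#' @param sensor a [sensor()] model.
#' @param optics an [optics_model()].
#' @param seed integer master seed; per-pH scene and noise seeds are derived
#'   from it.
#' @param noise apply the detector noise model?
#' @param ... further arguments to [place_endosomes()].
#' @return List with one element per pH: `list(ph, pair, scene)`.
#' @export
simulate_calibration_series <- function(ph_values, n_per_ph = 150,
                                        sensor, optics, seed = 1,
                                        noise = TRUE, ...) {
  if (any(ph_values < 3 | ph_values > 9))
    stop("calibration pH values must lie in [3, 9]")
  lapply(seq_along(ph_values), function(k) {
    scene <- place_endosomes(n_per_ph, pixel_size = optics$pixel_size,
                             seed = seed + 101L * k, ...)
    scene$endosomes$true_ph <- rep(ph_values[k], n_per_ph)
    pair <- render_image_pair(scene, sensor, optics,
                              seed = seed + 101L * k + 50L, noise = noise)
    list(ph = ph_values[k], pair = pair, scene = scene)
  })
}

#' Simulate a two-channel punctum pair with known colocalized fraction
#'
#' Generates query puncta (channel 1) and partner puncta (channel 2) such
#' that `round(coloc_fraction * n_query)` queries have a partner centred
#' within `offset_within` nm and the remainder have their nearest channel-2
#' punctum at least `offset_beyond` nm away. Query centres are kept at least
#' `2 * offset_beyond` apart so that a far partner of one query cannot fall
#' within the matching threshold of another.
#'
#' @param n_query number of channel-1 puncta.
#' @param coloc_fraction ground-truth colocalized fraction in `[0, 1]`.
#' @param offset_within centre offset of colocalized partners, nm.
#' @param offset_beyond minimum centre offset of non-colocalized partners, nm.
#' @param optics an [optics_model()].
#' @param seed integer seed.
#' @param punctum_diameter punctum diameter, nm.
#' @param amplitude peak signal per punctum, counts.
#' @param field field size in pixels.
#' @param noise apply the detector noise model?
#' @return List with matrices `ch1`, `ch2`, the ground-truth table `truth`
#'   (`id, x, y, partner_x, partner_y, colocalized`) and `optics`.
#' @export
simulate_coloc_pair <- function(n_query, coloc_fraction,
                                offset_within = 100, offset_beyond = 1000,
                                optics = optics_preset("confocal"), seed = 1,
                                punctum_diameter = 250, amplitude = 350,
                                field = c(768, 768), noise = TRUE) {
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must be in [0, 1]")
  if (offset_within >= offset_beyond)
    stop("offset_within must be smaller than offset_beyond")
  scene <- place_endosomes(n_query, diameter_range = rep(punctum_diameter, 2),
                           field = field, pixel_size = optics$pixel_size,
                           min_separation = 2 * offset_beyond +
                             punctum_diameter,
                           seed = seed, amplitude = amplitude,
                           margin = offset_beyond + 2 * punctum_diameter)
  q <- scene$endosomes
  n_match <- round(coloc_fraction * n_query)
  truth <- withr::with_seed(seed + 7L, {
    ang <- stats::runif(n_query, 0, 2 * pi)
    d <- c(rep(offset_within, n_match),
           rep(offset_beyond, n_query - n_match))
    data.frame(id = q$id, x = q$x, y = q$y,
               partner_x = q$x + d * cos(ang),
               partner_y = q$y + d * sin(ang),
               colocalized = seq_len(n_query) <= n_match)
  })
  render1 <- function(xs, ys, noise_seed) {
    img <- matrix(0, field[1], field[2])
    for (i in seq_along(xs)) {
      p <- disk_coverage(xs[i], ys[i], punctum_diameter, field,
                         optics$pixel_size)
      if (!is.null(p))
        img[p$rows, p$cols] <- img[p$rows, p$cols] + amplitude * p$cov
    }
    img <- blur_gaussian(img, optics$psf_fwhm[1], optics$pixel_size) +
      optics$background_level
    if (noise) withr::with_seed(noise_seed, add_detector_noise(img, optics))
    else img
  }
  list(ch1 = render1(truth$x, truth$y, seed + 11L),
       ch2 = render1(truth$partner_x, truth$partner_y, seed + 13L),
       truth = truth, optics = optics)
}

#' Write an image pair as per-channel grayscale TIFF plus truth CSV
#'
#' Channels are written as 16-bit (or 8-bit) grayscale TIFF files
#' `<prefix>_fp.tif` and `<prefix>_dye.tif`; the ground-truth table, when
#' present, as `<prefix>_truth.csv` with positions in both nm and pixels.
#'
#' @param pair an `ImagePair`.
#' @param prefix output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_image_pair <- function(pair, prefix) {
  stopifnot(inherits(pair, "ImagePair"))
  maxv <- 2^pair$bit_depth - 1
  bps <- pair$bit_depth
  paths <- c(fp = paste0(prefix, "_fp.tif"), dye = paste0(prefix, "_dye.tif"))
  tiff::writeTIFF(pmin(pair$fp, maxv) / maxv, paths["fp"],
                  bits.per.sample = bps)
  tiff::writeTIFF(pmin(pair$dye, maxv) / maxv, paths["dye"],
                  bits.per.sample = bps)
  if (!is.null(pair$truth) && nrow(pair$truth)) {
    tr <- pair$truth
    out <- data.frame(id = tr$id,
                      x_px = tr$x / pair$pixel_size,
                      y_px = tr$y / pair$pixel_size,
                      diameter_nm = tr$diameter, true_ph = tr$true_ph)
    tpath <- paste0(prefix, "_truth.csv")
    utils::write.csv(out, tpath, row.names = FALSE)
    paths <- c(paths, truth = tpath)
  }
  invisible(paths)
}

#' Read a two-channel image pair from grayscale TIFF files
#'
#' @param fp_path,dye_path per-channel TIFF paths.
#' @param pixel_size nm per pixel of the acquisition.
#' @param bit_depth bit depth the files were quantized to.
#' @return An `ImagePair` (no ground truth attached).
#' @export
read_image_pair <- function(fp_path, dye_path, pixel_size, bit_depth = 16) {
  maxv <- 2^bit_depth - 1
  fp <- tiff::readTIFF(fp_path) * maxv
  dye <- tiff::readTIFF(dye_path) * maxv
  if (!all(dim(fp) == dim(dye))) stop("channel dimensions differ")
  structure(list(fp = fp, dye = dye, pixel_size = pixel_size,
                 bit_depth = bit_depth,
                 saturated = list(fp = fp >= maxv, dye = dye >= maxv),
                 truth = NULL),
            class = "ImagePair")
}
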