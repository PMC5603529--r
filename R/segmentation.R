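#' Otsu intensity threshold
#'
#' Computes the global threshold maximizing the between-class variance of
#' the image histogram. The histogram uses `levels` equal-width bins
#' spanning the observed intensity range (bin width = range / levels), so
#' for 16-bit images the computation matches the classic 256-level
#' formulation; for 8-bit-range integer images the bins coincide with
#' integer intensities. The returned threshold is the lower edge of the
#' first foreground bin: pixels with `intensity >= threshold` are
#' foreground (inclusive).
#'
#' @param image numeric matrix, single channel.
#' @param levels number of histogram bins (default 256).
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(image, levels = 256L) {
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || !is.finite(hi) || lo == hi)
    stop("cannot threshold a constant image")
  if (all(v == round(v)) && (hi - lo) < levels) {
    # integer image within the level budget: one bin per integer value, so
    # the histogram is exact and the threshold is an integer
    nb <- as.integer(hi - lo + 1)
    h <- tabulate(v - lo + 1, nbins = nb)
    centers <- lo + seq_len(nb) - 1
    n <- length(v)
    cw <- cumsum(h); cm <- cumsum(h * centers)
    k <- seq_len(nb - 1L)
    w0 <- cw[k] / n; w1 <- 1 - w0
    mu0 <- ifelse(cw[k] > 0, cm[k] / cw[k], 0)
    mu1 <- ifelse(cw[nb] - cw[k] > 0,
                  (cm[nb] - cm[k]) / (cw[nb] - cw[k]), 0)
    bcv <- w0 * w1 * (mu0 - mu1)^2
    return(lo + which.max(bcv))        # smallest foreground intensity
  }
  width <- (hi - lo) / levels
  bin <- pmin(floor((v - lo) / width) + 1L, levels)
  h <- tabulate(bin, nbins = levels)
  n <- length(v)
  centers <- lo + (seq_len(levels) - 0.5) * width
  cw <- cumsum(h)                      # pixels in bins 1..k
  cm <- cumsum(h * centers)            # intensity mass in bins 1..k
  k <- seq_len(levels - 1L)
  w0 <- cw[k] / n
  w1 <- 1 - w0
  mu0 <- ifelse(cw[k] > 0, cm[k] / cw[k], 0)
  mu1 <- ifelse(cw[levels] - cw[k] > 0,
                (cm[levels] - cm[k]) / (cw[levels] - cw[k]), 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  kstar <- which.max(bcv)              # first maximum on ties
  lo + kstar * width                   # lower edge of first foreground bin
}

# 8-connected component labelling of a logical mask by breadth-first
# flood fill over linear indices. Labels are assigned in raster-scan order
# of each component's seed pixel.
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  # neighbour offsets in (row, col) for 8-connectivity
  di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  current <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    lab[seed] <- current
    frontier <- seed
    while (length(frontier)) {
      i <- ((frontier - 1L) %% n) + 1L
      j <- ((frontier - 1L) %/% n) + 1L
      ni <- rep(i, each = 8L) + di
      nj <- rep(j, each = 8L) + dj
      ok <- ni >= 1L & ni <= n & nj >= 1L & nj <= m
      ni <- ni[ok]; nj <- nj[ok]
      nid <- unique((nj - 1L) * n + ni)
      nid <- nid[mask[nid] & lab[nid] == 0L]
      lab[nid] <- current
      frontier <- nid
    }
  }
  lab
}

#' Segment endosomes by Otsu thresholding and connected components
#'
#' Pixels at or above the Otsu threshold of the mask channel form the
#' foreground; 8-connected components are labelled and components smaller
#' than `min_size` pixels are discarded. Surviving labels are renumbered
#' consecutively in raster order.
#'
#' @param mask_channel numeric matrix used to build the mask (conventionally
#'   the acid-stable dye channel, which stays bright at all endosomal pH).
#' @param min_size minimum component area in pixels (default 5).
#' @param threshold optional fixed threshold overriding Otsu.
#' @return A `LabeledRegions` object: `label_map` (integer matrix, 0 =
#'   background), `regions` (data.frame `label, area_px, cx, cy,
#'   eq_diameter_px`), `threshold` and `min_size`. Centroids are unweighted
#'   pixel-centre means in pixel coordinates (`cx` = column, `cy` = row);
#'   `eq_diameter_px = 2 * sqrt(area / pi)`.
#' @export
segment_endosomes <- function(mask_channel, min_size = 5L, threshold = NULL) {
  if (is.null(threshold)) threshold <- otsu_threshold(mask_channel)
  mask <- mask_channel >= threshold
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  if (!length(keep)) {
    warning("no regions of at least ", min_size, " pixels survive")
    return(structure(list(label_map = matrix(0L, nrow(mask), ncol(mask)),
                          regions = data.frame(label = integer(), area_px = integer(),
                                               cx = numeric(), cy = numeric(),
                                               eq_diameter_px = numeric()),
                          threshold = threshold, min_size = min_size),
                     class = "LabeledRegions"))
  }
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  idx <- which(lab > 0L)
  l <- lab[idx]
  i <- ((idx - 1L) %% nrow(lab)) + 1L
  j <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- as.integer(tabulate(l))
  regions <- data.frame(
    label = seq_along(keep),
    area_px = area,
    cx = as.numeric(tapply(j, l, mean)),
    cy = as.numeric(tapply(i, l, mean)),
    eq_diameter_px = 2 * sqrt(area / pi))
  structure(list(label_map = lab, regions = regions,
                 threshold = threshold, min_size = min_size),
            class = "LabeledRegions")
}

#' @export
print.LabeledRegions <- function(x, ...) {
  cat("<LabeledRegions>", nrow(x$regions), "regions (min_size =", x$min_size,
      "px, threshold =", signif(x$threshold, 5), ")\n")
  invisible(x)
}

#' Per-region dual-channel intensity statistics
#'
#' Computes the mean pixel intensity of each labelled region in both
#' channels of an image pair and appends them to the region table.
#'
#' @param regions a [segment_endosomes()] result.
#' @param pair an `ImagePair` congruent with the label map.
#' @return The region data.frame with columns `mean_fp` and `mean_dye`
#'   added.
#' @export
region_stats <- function(regions, pair) {
  stopifnot(inherits(regions, "LabeledRegions"), inherits(pair, "ImagePair"))
  if (!all(dim(regions$label_map) == dim(pair$fp)))
    stop("label map and images have different dimensions")
  tab <- regions$regions
  if (!nrow(tab)) {
    tab$mean_fp <- numeric(0); tab$mean_dye <- numeric(0)
    return(tab)
  }
  idx <- which(regions$label_map > 0L)
  l <- regions$label_map[idx]
  tab$mean_fp <- as.numeric(tapply(pair$fp[idx], l, mean))
  tab$mean_dye <- as.numeric(tapply(pair$dye[idx], l, mean))
  tab
}

# Binary dilation of a mask with a (2r+1) square structuring element.
dilate_mask <- function(mask, r) {
  out <- mask
  n <- nrow(mask); m <- ncol(mask)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    si <- max(1, 1 + di):min(n, n + di)
    ti <- max(1, 1 - di):min(n, n - di)
    sj <- max(1, 1 + dj):min(m, m + dj)
    tj <- max(1, 1 - dj):min(m, m - dj)
    out[ti, tj] <- out[ti, tj] | mask[si, sj]
  }
  out
}

#' Background intensity from randomly placed ROIs
#'
#' Places `n_rois` square regions of interest uniformly at random, entirely
#' outside a dilated exclusion zone around the segmented endosomes, and
#' returns the mean intensity over all ROI pixels per channel. This mirrors
#' the practice of estimating image background from randomly chosen
#' object-free ROIs.
#'
#' @param pair an `ImagePair`.
#' @param regions a [segment_endosomes()] result (may contain 0 regions).
#' @param n_rois number of ROIs (default 30).
#' @param roi_size ROI side length in pixels.
#' @param seed integer seed for ROI placement.
#' @param exclusion_dilate dilation radius (pixels) of the endosome mask.
#' @return List with per-channel means `fp` and `dye`, per-ROI means
#'   `roi_means` (data.frame) and the ROI corner coordinates.
#' @export
background_stats <- function(pair, regions, n_rois = 30L, roi_size = 10L,
                             seed = 1, exclusion_dilate = 3L) {
  stopifnot(inherits(pair, "ImagePair"))
  excl <- dilate_mask(regions$label_map > 0L, exclusion_dilate)
  n <- nrow(excl); m <- ncol(excl)
  if (roi_size > n || roi_size > m) stop("roi_size exceeds image")
  rois <- withr::with_seed(seed, {
    placed <- matrix(0L, 0, 2)
    tries <- 0L
    while (nrow(placed) < n_rois) {
      if ((tries <- tries + 1L) > 500L * n_rois)
        stop("could not place ", n_rois, " background ROIs outside objects")
      i <- sample.int(n - roi_size + 1L, 1L)
      j <- sample.int(m - roi_size + 1L, 1L)
      if (!any(excl[i:(i + roi_size - 1L), j:(j + roi_size - 1L)]))
        placed <- rbind(placed, c(i, j))
    }
    placed
  })
  roi_means <- data.frame(
    roi = seq_len(n_rois), row = rois[, 1], col = rois[, 2],
    mean_fp = apply(rois, 1, function(p)
      mean(pair$fp[p[1]:(p[1] + roi_size - 1L), p[2]:(p[2] + roi_size - 1L)])),
    mean_dye = apply(rois, 1, function(p)
      mean(pair$dye[p[1]:(p[1] + roi_size - 1L), p[2]:(p[2] + roi_size - 1L)])))
  list(fp = mean(roi_means$mean_fp), dye = mean(roi_means$mean_dye),
       roi_means = roi_means)
}

#' Full width at half maximum of a punctum
#'
#' Extracts an intensity profile through the punctum centroid, estimates the
#' local background as the median of the outer 20% of the profile, and
#' locates the two half-maximum crossings by linear interpolation between
#' neighbouring pixels.
#'
#' @param image numeric matrix, single channel.
#' @param centroid `c(cx, cy)` in pixel coordinates (column, row).
#' @param pixel_size nm per pixel.
#' @param axis `"auto"` (the brighter of the x and y profiles), `"x"` or
#'   `"y"`.
#' @param expected_fwhm rough expected FWHM in nm; the profile window is 6
#'   times this value (default window 31 pixels when omitted).
#' @return FWHM in nm.
#' @export
measure_fwhm <- function(image, centroid, pixel_size,
                         axis = c("auto", "x", "y"), expected_fwhm = NULL) {
  axis <- match.arg(axis)
  cx <- round(centroid[1]); cy <- round(centroid[2])
  n <- nrow(image); m <- ncol(image)
  if (cx < 1 || cx > m || cy < 1 || cy > n) stop("centroid outside image")
  win <- if (is.null(expected_fwhm)) 31L
         else max(7L, 2L * floor(3 * expected_fwhm / pixel_size) + 1L)
  h <- (win - 1L) %/% 2L
  prof_x <- image[cy, max(1, cx - h):min(m, cx + h)]
  prof_y <- image[max(1, cy - h):min(n, cy + h), cx]
  prof <- switch(axis,
    x = prof_x, y = prof_y,
    auto = if (max(prof_x) >= max(prof_y)) prof_x else prof_y)
  L <- length(prof)
  tail_n <- max(1L, floor(0.1 * L))
  bg <- stats::median(c(prof[seq_len(tail_n)], prof[(L - tail_n + 1L):L]))
  pk <- which.max(prof)
  half <- bg + (prof[pk] - bg) / 2
  cross <- function(side) {
    ii <- if (side == "left") rev(seq_len(pk - 1L)) else (pk + 1L):L
    if (pk == 1L && side == "left" || pk == L && side == "right")
      stop("profile does not fall below half-maximum (unresolved object)")
    for (i in ii) {
      if (prof[i] < half) {
        j <- if (side == "left") i + 1L else i - 1L   # neighbour above half
        return(j + (half - prof[j]) / (prof[i] - prof[j]) * (i - j))
      }
    }
    stop("profile does not fall below half-maximum (unresolved object)")
  }
  (cross("right") - cross("left")) * pixel_size
}
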