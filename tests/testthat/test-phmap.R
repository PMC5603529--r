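# Shared small fixture: a noise-free field with a matching calibration
# built through the identical image pipeline, so inversion biases cancel.
local_phmap_fixture <- function(true_ph = 5.5, n = 6, noise = FALSE,
                                seed = 50) {
  s <- test_sensor(bleed = 0.05)
  opt <- optics_preset("confocal")
  ser <- simulate_calibration_series(seq(5, 7, 0.5), n_per_ph = 40, s, opt,
                                     seed = seed, noise = noise)
  rows <- lapply(ser, function(e) {
    tab <- region_stats(segment_endosomes(e$pair$dye), e$pair)
    data.frame(ph = e$ph, lr = as.numeric(per_endosome_log_ratio(tab)))
  })
  d <- do.call(rbind, rows)
  curve <- fit_calibration(d$ph, d$lr)
  sc <- place_endosomes(n, seed = seed + 1, field = c(256, 256))
  sc$endosomes$true_ph <- rep(true_ph, n)
  pair <- render_image_pair(sc, s, opt, seed = seed + 2, noise = noise)
  regions <- segment_endosomes(pair$dye)
  list(pair = pair, regions = regions, curve = curve, sensor = s, optics = opt)
}

test_that("pH maps honour the mask and preserve ratio order", {
  fx <- local_phmap_fixture()
  map <- build_ph_map(fx$pair, fx$regions, fx$curve)
  inmask <- fx$regions$label_map > 0
  # mask conservation: pH defined exactly on the (unsaturated) mask pixels
  expect_true(all(is.na(map$ph_image[!inmask])))
  expect_equal(sum(!is.na(map$ph_image)),
               sum(inmask & fx$pair$dye > 0 &
                     !fx$pair$saturated$fp & !fx$pair$saturated$dye))
  # order preservation: higher fp/dye ratio => higher pH
  idx <- which(!is.na(map$ph_image))
  ratio <- fx$pair$fp[idx] / fx$pair$dye[idx]
  expect_true(all(diff(map$ph_image[idx][order(ratio)]) >= 0))
  # display image spans 0..255 and is 0 on the background
  expect_true(all(map$display_image[!inmask] == 0))
  expect_true(all(map$display_image >= 0 & map$display_image <= 255))
})

test_that("uniform-ratio regions give identical pixel-mean and ratio-of-means pH", {
  cal <- fit_calibration(c(5, 6, 7), c(-1, -0.6, -0.2))
  pair <- structure(list(fp = matrix(30, 32, 32), dye = matrix(60, 32, 32),
                         pixel_size = 50, bit_depth = 16,
                         saturated = list(fp = matrix(FALSE, 32, 32),
                                          dye = matrix(FALSE, 32, 32)),
                         truth = NULL), class = "ImagePair")
  lab <- matrix(0L, 32, 32); lab[10:15, 10:15] <- 1L
  regions <- structure(list(label_map = lab,
                            regions = data.frame(label = 1L, area_px = 36L,
                                                 cx = 12.5, cy = 12.5,
                                                 eq_diameter_px = 2 * sqrt(36 / pi)),
                            threshold = 20, min_size = 5L),
                       class = "LabeledRegions")
  map <- build_ph_map(pair, regions, cal)
  tab <- per_endosome_ph(map, pair)
  expect_equal(tab$ph_pixel_mean, tab$ph_ratio_of_means)
  expect_equal(tab$ph_pixel_mean,
               as.numeric(invert_calibration(cal, log10(0.5))))
})

test_that("a noise-free endosome field recovers its true pH via the matched calibration", {
  fx <- local_phmap_fixture(true_ph = 5.5, noise = FALSE)
  map <- build_ph_map(fx$pair, fx$regions, fx$curve)
  tab <- per_endosome_ph(map, fx$pair)
  # noise-free and calibrated through the same pipeline: the remaining
  # deviation is the linear fit's curvature residual, which the calibration
  # itself bounds at max|residual| / slope (~0.13 pH for this curve)
  resid_bound <- max(abs(fx$curve$per_ph$mean_log_ratio -
                           (fx$curve$slope * fx$curve$per_ph$ph +
                              fx$curve$intercept))) / fx$curve$slope
  expect_lt(abs(median(tab$ph_ratio_of_means) - 5.5), resid_bound + 0.05)
  expect_lt(abs(median(tab$ph_pixel_mean) - 5.5), resid_bound + 0.05)
})

test_that("8-bit display rescaling round-trips pH within its quantization step", {
  fx <- local_phmap_fixture()
  map <- build_ph_map(fx$pair, fx$regions, fx$curve)
  rng <- fx$curve$ph_range
  idx <- which(!is.na(map$ph_image) &
                 map$ph_image >= rng[1] & map$ph_image <= rng[2])
  back <- rng[1] + map$display_image[idx] / 255 * (rng[2] - rng[1])
  expect_true(all(abs(back - map$ph_image[idx]) <= (rng[2] - rng[1]) / 255 / 2 + 1e-9))
})

test_that("saturated pixels are excluded from per-endosome pH", {
  fx <- local_phmap_fixture()
  pair <- fx$pair
  # force saturation on a handful of in-mask pixels
  idx <- which(fx$regions$label_map > 0)[1:5]
  pair$saturated$fp[idx] <- TRUE
  map <- build_ph_map(pair, fx$regions, fx$curve)
  expect_true(all(is.na(map$ph_image[idx])))
  tab <- per_endosome_ph(map, pair)
  expect_true(all(is.finite(tab$ph_pixel_mean)))
})

test_that("empty masks warn and pH maps write to disk faithfully", {
  cal <- fit_calibration(c(5, 6, 7), c(-1, -0.6, -0.2))
  pair <- structure(list(fp = matrix(10, 16, 16), dye = matrix(20, 16, 16),
                         pixel_size = 50, bit_depth = 16,
                         saturated = list(fp = matrix(FALSE, 16, 16),
                                          dye = matrix(FALSE, 16, 16)),
                         truth = NULL), class = "ImagePair")
  empty <- structure(list(label_map = matrix(0L, 16, 16),
                          regions = data.frame(label = integer(),
                                               area_px = integer(),
                                               cx = numeric(), cy = numeric(),
                                               eq_diameter_px = numeric()),
                          threshold = 0, min_size = 5L),
                     class = "LabeledRegions")
  expect_warning(map <- build_ph_map(pair, empty, cal), "empty mask")
  fx <- local_phmap_fixture()
  map <- build_ph_map(fx$pair, fx$regions, fx$curve)
  prefix <- file.path(withr::local_tempdir(), "map")
  paths <- write_ph_map(map, fx$pair, prefix)
  ph_back <- read_ph_image(paths["ph"])
  idx <- which(!is.na(map$ph_image))
  expect_equal(ph_back[idx], map$ph_image[idx], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(file.exists(paths["table"]))
})

test_that("two populations 0.3 pH units apart separate by t-test after full recovery", {
  fx <- local_phmap_fixture(noise = TRUE, seed = 70)
  measure <- function(mu, seed) {
    sc <- place_endosomes(150, ph_mean = mu, ph_sd = 0.3, seed = seed)
    pr <- render_image_pair(sc, fx$sensor, fx$optics, seed = seed + 1)
    analyze_image_pair(pr, fx$curve)$ph_ratio_of_means
  }
  a <- measure(6.0, 71)
  b <- measure(5.7, 81)
  cmp <- compare_populations(a, b)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$mean_a, cmp$mean_b)
})
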