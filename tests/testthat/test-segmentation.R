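test_that("Otsu threshold equals the exhaustive-search argmax", {
  # random 8-bit style images: the integer histogram is exact, so the
  # cumulative-statistics implementation must agree with brute force
  # thresholds are compared through the partitions they induce, since any
  # threshold inside the same histogram gap selects the same foreground
  for (k in 1:25) {
    img <- withr::with_seed(k, matrix(sample(0:255, 256, replace = TRUE),
                                      16, 16))
    expect_identical(img >= otsu_threshold(img),
                     img >= brute_force_otsu(img),
                     info = paste("replicate", k))
  }
  # bimodal images too, where the split actually matters
  for (k in 1:10) {
    img <- withr::with_seed(100 + k, matrix(
      c(rpois(200, 20), rpois(56, 180)), 16, 16))
    expect_identical(img >= otsu_threshold(img),
                     img >= brute_force_otsu(img))
  }
})

test_that("Otsu threshold separates two-valued images and shifts with offsets", {
  img <- matrix(c(rep(10, 30), rep(200, 34)), 8, 8)
  th <- otsu_threshold(img)
  expect_gt(th, 10)
  expect_lte(th, 200)
  expect_equal(otsu_threshold(img + 17), th + 17)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "constant")
})

test_that("connected components are 8-connected and min_size filters apply", {
  img <- matrix(0, 16, 16)
  img[2:4, 2:4] <- 100          # 9 px block
  img[8, 8] <- 100; img[9, 9] <- 100; img[10, 10] <- 100  # 3 px diagonal
  img[13:14, 12:14] <- 100      # 6 px block, diagonal-touching tail
  img[12, 11] <- 100
  reg <- segment_endosomes(img, min_size = 5, threshold = 50)
  # diagonal chain is one (3 px) component -> dropped; the diagonal tail
  # joins the 6 px block -> kept as one region of 7 px
  expect_equal(nrow(reg$regions), 2)
  expect_setequal(reg$regions$area_px, c(9, 7))
  # labels consecutive from 1
  expect_setequal(unique(reg$label_map[reg$label_map > 0]),
                  seq_len(nrow(reg$regions)))
})

test_that("no region below min_size survives, exhaustively", {
  for (k in 1:8) {
    img <- withr::with_seed(300 + k,
      matrix(ifelse(runif(32 * 32) < 0.12, 200 + rpois(32 * 32, 20), 10),
             32, 32))
    reg <- segment_endosomes(img, min_size = 5, threshold = 100)
    if (nrow(reg$regions)) {
      expect_true(all(reg$regions$area_px >= 5))
      expect_true(all(tabulate(reg$label_map[reg$label_map > 0]) >= 5))
    }
  }
})

test_that("a single bright square yields one region centred on it", {
  img <- matrix(10, 21, 21)
  img[9:11, 13:15] <- 200
  reg <- segment_endosomes(img)
  expect_equal(nrow(reg$regions), 1)
  expect_equal(reg$regions$cx, 14)
  expect_equal(reg$regions$cy, 10)
  expect_equal(reg$regions$eq_diameter_px, 2 * sqrt(9 / pi))
})

test_that("segmentation is invariant under order-preserving affine intensity maps", {
  # keep the affine image's range under 256 so both use the exact
  # integer histogram
  img <- withr::with_seed(17, matrix(
    c(rpois(900, 15), rpois(124, 80)), 32, 32))
  a <- segment_endosomes(img)
  b <- segment_endosomes(2 * img + 31)
  expect_identical(a$label_map, b$label_map)
})

test_that("segmentation recovers well-separated synthetic endosomes", {
  s <- test_sensor()
  opt <- optics_preset("confocal")
  # equal-diameter endosomes so every object clears the global threshold;
  # detection of *dim small* endosomes is an amplitude question, not a
  # geometry one
  sc <- place_endosomes(12, seed = 31, field = c(256, 256),
                        min_separation = 1500,
                        diameter_range = c(300, 300))
  pr <- render_image_pair(sc, s, opt, noise = FALSE)
  reg <- segment_endosomes(pr$dye)
  expect_equal(nrow(reg$regions), 12)
  # centroid error <= 1 px against ground truth
  for (i in seq_len(12)) {
    e <- sc$endosomes[i, ]
    d <- sqrt((reg$regions$cx - (e$x / 50 + 0.5))^2 +
                (reg$regions$cy - (e$y / 50 + 0.5))^2)
    expect_lt(min(d), 1)
  }
})

test_that("region means equal explicit per-pixel iteration", {
  s <- test_sensor()
  opt <- optics_preset("confocal")
  sc <- place_endosomes(5, seed = 41, field = c(160, 160))
  pr <- render_image_pair(sc, s, opt, seed = 42)
  reg <- segment_endosomes(pr$dye)
  tab <- region_stats(reg, pr)
  for (r in seq_len(nrow(tab))) {
    px <- which(reg$label_map == tab$label[r])
    expect_equal(tab$mean_fp[r], mean(pr$fp[px]))
    expect_equal(tab$mean_dye[r], mean(pr$dye[px]))
  }
  # fp = 2 x dye everywhere gives a ratio of exactly 2
  pr2 <- pr
  pr2$fp <- 2 * pr$dye
  tab2 <- region_stats(reg, pr2)
  expect_equal(tab2$mean_fp / tab2$mean_dye, rep(2, nrow(tab2)))
  pr_bad <- pr
  pr_bad$fp <- pr$fp[1:10, 1:10]
  expect_error(region_stats(reg, pr_bad), "dimensions")
})

test_that("background ROIs avoid endosomes and report the configured contrast", {
  s <- test_sensor()
  opt <- optics_preset("confocal")
  # uniform background with no regions returns the background exactly
  flat <- structure(list(fp = matrix(18, 64, 64), dye = matrix(18, 64, 64),
                         pixel_size = 50, bit_depth = 16,
                         saturated = list(fp = matrix(FALSE, 64, 64),
                                          dye = matrix(FALSE, 64, 64)),
                         truth = NULL), class = "ImagePair")
  noreg <- structure(list(label_map = matrix(0L, 64, 64),
                          regions = data.frame(), threshold = 0,
                          min_size = 5), class = "LabeledRegions")
  bg <- background_stats(flat, noreg, n_rois = 10, seed = 1)
  expect_equal(bg$dye, 18)
  # default synthetic scene: segmented endosomes ~9-fold above background
  sc <- place_endosomes(150, seed = 2)
  sc$endosomes$true_ph <- rep(5.0, 150)
  pr <- render_image_pair(sc, s, opt, seed = 3)
  reg <- segment_endosomes(pr$dye)
  tab <- region_stats(reg, pr)
  bg <- background_stats(pr, reg, n_rois = 30, seed = 4)
  fold <- mean(tab$mean_dye) / bg$dye
  expect_gt(fold, 7)
  expect_lt(fold, 11)
})

test_that("FWHM of a pure Gaussian spot is 2.355 sigma", {
  px <- 20
  sigma <- 50
  grid <- (seq_len(101) - 51) * px
  img <- outer(grid, grid, function(y, x) 100 * exp(-(x^2 + y^2) / (2 * sigma^2)))
  w <- measure_fwhm(img, c(51, 51), pixel_size = px, expected_fwhm = 118)
  expect_equal(w, 2 * sqrt(2 * log(2)) * sigma, tolerance = px / 117.7)
})

test_that("measured FWHM of blurred disks matches a fine-grid convolution oracle", {
  s <- test_sensor()
  render_disk <- function(diam, modality) {
    opt <- optics_preset(modality)
    fld <- if (modality == "confocal") c(64, 64) else c(128, 128)
    sc <- place_endosomes(1, diameter_range = c(diam, diam), field = fld,
                          pixel_size = opt$pixel_size,
                          min_separation = 0, seed = 1, margin = 1000)
    pr <- render_image_pair(sc, s, opt, noise = FALSE)
    reg <- segment_endosomes(pr$dye)
    measure_fwhm(pr$dye, c(reg$regions$cx[1], reg$regions$cy[1]),
                 opt$pixel_size, expected_fwhm = opt$psf_fwhm[1])
  }
  # 40 nm endosome under the 250 nm confocal PSF: the oracle sits near the
  # closed-form 2.355 * sqrt(sigma^2 + r^2/4) ~ 251 nm; the pixel-grid
  # measurement must agree within one 50 nm pixel
  oracle_conf <- disk_psf_fwhm_oracle(40, 250)
  expect_equal(oracle_conf, 2 * sqrt(2 * log(2)) * sqrt((250 / 2.3548)^2 + 20^2 / 4),
               tolerance = 0.01)
  expect_equal(render_disk(40, "confocal"), oracle_conf, tolerance = 50 / 251)
  # same endosome under a 50 nm STED PSF stays below 100 nm
  oracle_sted <- disk_psf_fwhm_oracle(40, 50)
  got_sted <- render_disk(40, "STED")
  expect_equal(got_sted, oracle_sted, tolerance = 20 / 60)
  expect_lt(got_sted, 100)
})

test_that("unresolved profiles fail rather than returning a width", {
  img <- matrix(100, 15, 15)  # flat: never crosses half-max
  expect_error(measure_fwhm(img, c(8, 8), 50), "half-maximum")
  expect_error(measure_fwhm(img, c(99, 8), 50), "outside")
})
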