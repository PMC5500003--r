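test_that("buffer threshold is the mean intensity, with saturation warning", {
  buf <- brightfield_image(matrix(100, 32, 32), pixel_size_um = 0.5,
                           bit_depth = 8)
  expect_equal(buffer_threshold(buf), 100)
  set.seed(1)
  noisy <- matrix(round(rnorm(200 * 200, 2000, 50)), 200, 200)
  bufn <- brightfield_image(noisy, pixel_size_um = 0.5)
  expect_lt(abs(buffer_threshold(bufn) - 2000), 3 * 50 / sqrt(200 * 200) + 1)
  sat <- brightfield_image(matrix(4095, 32, 32), pixel_size_um = 0.5)
  expect_warning(th <- buffer_threshold(sat), "saturated")
  expect_equal(th, 4095)
})

test_that("a rasterized disk is segmented pixel-for-pixel", {
  ell <- data.frame(cx = 250, cy = 250, a = 50, b = 50, angle = 0,
                    depth = 600)
  img <- sim_droplet_image(500, 500, pixel_size_um = 0.5, ellipses = ell,
                           background_sd = 0)
  regions <- segment_droplets(img, threshold = 2000)
  expect_equal(nrow(regions), 1)
  oracle <- oracle_ellipse_pixels(500, 500, 250, 250, 50, 50)
  expect_identical(regions$n_pixels, oracle)
  expect_lt(regions$eccentricity, 0.1)
  expect_false(regions$touches_border)
})

test_that("elongated regions get the analytic eccentricity", {
  ell <- data.frame(cx = 250, cy = 250, a = 40, b = 8, angle = 0.3,
                    depth = 600)
  img <- sim_droplet_image(500, 500, pixel_size_um = 0.5, ellipses = ell,
                           background_sd = 0)
  regions <- segment_droplets(img, threshold = 2000)
  expect_equal(regions$eccentricity, sqrt(1 - (8 / 40)^2), tolerance = 0.01)
})

test_that("blank images yield no regions and zero coverage", {
  img <- brightfield_image(matrix(2000, 64, 64), pixel_size_um = 0.5)
  regions <- filter_droplets(segment_droplets(img, 1500))
  expect_equal(nrow(regions), 0)
  cov <- droplet_coverage(regions, img)
  expect_equal(cov$percent_coverage, 0)
})

test_that("shape filters cut at eccentricity 0.9 and diameter 1 um", {
  # round 10-um droplet kept; 0.98-eccentric streak and sub-um speck cut
  ell <- data.frame(
    cx = c(100, 300, 450), cy = c(100, 300, 450),
    a = c(10, 40, 0.9), b = c(10, 8, 0.9),
    angle = 0, depth = 600
  )
  img <- sim_droplet_image(500, 500, pixel_size_um = 0.5, ellipses = ell,
                           background_sd = 0)
  regions <- filter_droplets(segment_droplets(img, 2000))
  expect_equal(nrow(regions), 3)
  keep <- regions[regions$kept, ]
  drop <- regions[!regions$kept, ]
  expect_equal(nrow(keep), 1)
  expect_equal(keep$equiv_diameter_um, 10, tolerance = 0.1)
  expect_true(any(drop$eccentricity > 0.9))
  expect_true(any(drop$equiv_diameter_um < 1))
  # partition is exhaustive and exclusive
  expect_equal(sum(regions$kept) + sum(!regions$kept), nrow(regions))
})

test_that("coverage equals the pixel-count oracle exactly without noise", {
  ell <- data.frame(cx = c(120, 350), cy = c(150, 300), a = c(30, 20),
                    b = c(28, 20), angle = 0, depth = 600)
  img <- sim_droplet_image(500, 500, pixel_size_um = 0.5, ellipses = ell,
                           background_sd = 0)
  cov <- quantify_droplets(img, threshold = 2000)
  expect_equal(cov$percent_coverage, attr(img, "truth_coverage"),
               tolerance = 1e-12)
  # removing a kept region strictly decreases coverage
  regions <- filter_droplets(segment_droplets(img, 2000))
  partial <- regions[-1, ]
  attr(partial, "image_dim") <- attr(regions, "image_dim")
  expect_lt(droplet_coverage(partial, img)$percent_coverage,
            cov$percent_coverage)
})

test_that("coverage stays within 0.2 points of truth under 2% noise", {
  # noise sd = 2% of the 600-count contrast; threshold from a buffer blank
  # at mean - 3 sd so background speckle stays sub-micrometre
  devs <- purrr::map_dbl(1:5, function(i) {
    ell <- data.frame(cx = c(120, 350), cy = c(150, 300), a = c(30, 20),
                      b = c(28, 20), angle = 0, depth = 600)
    img <- sim_droplet_image(500, 500, pixel_size_um = 0.5, ellipses = ell,
                             background_sd = 12, seed = 300 + i)
    buf <- sim_droplet_image(500, 500, pixel_size_um = 0.5,
                             background_sd = 12, seed = 600 + i)
    cov <- quantify_droplets(img, buffer_image = buf, offset_sd = 3)
    cov$percent_coverage - attr(img, "truth_coverage")
  })
  expect_lt(max(abs(devs)), 0.2)
})

test_that("segmentation is invariant under affine intensity rescaling", {
  ell <- data.frame(cx = 200, cy = 200, a = 25, b = 20, angle = 0.2,
                    depth = 600)
  img <- sim_droplet_image(400, 400, pixel_size_um = 0.5, ellipses = ell,
                           background_sd = 10, seed = 7)
  r1 <- segment_droplets(img, threshold = 1970)
  scaled <- brightfield_image(img$pixels / 2 + 100, img$pixel_size_um,
                              img$bit_depth)
  r2 <- segment_droplets(scaled, threshold = 1970 / 2 + 100)
  expect_equal(r1$n_pixels, r2$n_pixels)
  expect_equal(r1$eccentricity, r2$eccentricity)
})

test_that("tightening the filters never increases coverage", {
  ell <- data.frame(cx = c(100, 250, 380), cy = c(100, 250, 380),
                    a = c(10, 18, 30), b = c(9, 6, 28), angle = 0,
                    depth = 600)
  img <- sim_droplet_image(500, 500, pixel_size_um = 0.5, ellipses = ell,
                           background_sd = 0)
  regions <- segment_droplets(img, 2000)
  cov <- function(ecc, dia) {
    droplet_coverage(filter_droplets(regions, ecc, dia), img)$percent_coverage
  }
  expect_lte(cov(0.8, 1), cov(0.9, 1))
  expect_lte(cov(0.9, 5), cov(0.9, 1))
})

test_that("4-connectivity splits diagonal bridges that 8 merges", {
  px <- matrix(2000, 32, 32)
  px[10, 10] <- 100; px[11, 11] <- 100
  img <- brightfield_image(px, pixel_size_um = 0.5)
  expect_equal(nrow(segment_droplets(img, 1000, connectivity = 8)), 1)
  expect_equal(nrow(segment_droplets(img, 1000, connectivity = 4)), 2)
})

test_that("labelling agrees with an established image-analysis toolkit", {
  skip_if_not_installed("EBImage")
  set.seed(42)
  mask <- matrix(runif(120 * 120) < 0.2, 120, 120)
  img <- brightfield_image(ifelse(mask, 100, 3000), pixel_size_um = 0.5)
  ours <- segment_droplets(img, 1000, connectivity = 4)
  eb <- EBImage::bwlabel(mask * 1)            # EBImage labels 4-connected
  expect_equal(nrow(ours), max(eb))
  expect_equal(sort(ours$n_pixels), sort(as.integer(table(eb[eb > 0]))))
})

test_that("provenance and calibration errors are caught", {
  img <- brightfield_image(matrix(2000, 64, 64), pixel_size_um = 0.5)
  other <- brightfield_image(matrix(2000, 32, 32), pixel_size_um = 0.5)
  regions <- segment_droplets(img, 1500)
  expect_error(droplet_coverage(regions, other), "dimension mismatch")
  expect_error(brightfield_image(matrix(2000, 8, 8), 0.5), "16 x 16")
  expect_error(brightfield_image(matrix(5000, 32, 32), 0.5, bit_depth = 12),
               "bit depth")
})

test_that("TIFF round trip preserves the segmentation", {
  ell <- data.frame(cx = 40, cy = 40, a = 10, b = 10, angle = 0, depth = 600)
  img <- sim_droplet_image(100, 100, pixel_size_um = 0.5, ellipses = ell,
                           background_sd = 0)
  tmp_tif <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(img$pixels / 4095, tmp_tif, bits.per.sample = 16)
  back <- read_brightfield(tmp_tif, pixel_size_um = 0.5, bit_depth = 16)
  # 12-bit data scaled into 16 bits: the mask at a scaled threshold matches
  # (threshold placed mid-contrast so bit rescaling cannot flip a pixel)
  r1 <- segment_droplets(img, 1700)
  r2 <- segment_droplets(back, 1700 / 4095 * 65535)
  expect_equal(r1$n_pixels, r2$n_pixels)
})

test_that("replicate aggregation reports mean, sd and n per condition", {
  covs <- purrr::map(1:3, function(i) {
    ell <- data.frame(cx = 60, cy = 60, a = 15, b = 15, angle = 0,
                      depth = 600)
    img <- sim_droplet_image(128, 128, pixel_size_um = 0.5, ellipses = ell,
                             background_sd = 10, seed = i)
    img$condition <- "no_salt"; img$replicate <- i
    quantify_droplets(img, threshold = 1700)
  })
  agg <- aggregate_coverage(dplyr::bind_rows(covs))
  expect_equal(agg$n, 3)
  expect_gt(agg$mean_coverage, 0)
  expect_gte(agg$sd_coverage, 0)
})
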