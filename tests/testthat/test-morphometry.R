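# Segmentation and area measurement of chromosome images.

noiseless_config <- function(area_um2, elongation = 2, pixel_size_um = 0.1,
                             n_objects = 1, seed = 1, frac = 0.15) {
  chrom_image_sim_config(
    n_objects = n_objects, area_mean_um2 = area_um2, area_sd_um2 = 0,
    pixel_size_um = pixel_size_um, elongation = elongation,
    shape_exponent = 2, boundary_jitter = 0, centromere_area_frac = frac,
    background_level = 0, noise_sd = 0, shot_noise = FALSE,
    cenpa_channel = TRUE, seed = seed)
}

test_that("a noiseless ellipse is one object with the analytic area", {
  # semi-axes 10 px x 5 px at 0.1 um/px: area = pi * 1 * 0.5 um^2
  A <- pi * 1 * 0.5
  sim <- simulate_chromosome_image_set(noiseless_config(A))
  expect_equal(sim$truth$area_um2, A)
  lab <- segment_chromosomes(sim$images[[1]],
                             segmentation_config(min_object_px = 5))
  expect_equal(max(lab), 1)
  measured <- measure_chromosome_area(lab, 0.1)
  expect_equal(unname(measured), A, tolerance = 0.05)
})

test_that("multiple separated bodies give one label each", {
  img <- matrix(0, 60, 60)
  img[5:15, 5:15] <- 1000
  img[30:40, 10:20] <- 1000
  img[45:55, 40:55] <- 1000
  ci <- chromosome_image(img, pixel_size_um = 0.1)
  lab <- segment_chromosomes(ci, segmentation_config(threshold_method = "fixed",
                                                     threshold_value = 500,
                                                     min_object_px = 5,
                                                     exclude_border = FALSE))
  expect_equal(max(lab), 3)
})

test_that("blank images yield zero objects with a warning", {
  ci <- chromosome_image(matrix(0, 20, 20), pixel_size_um = 0.1)
  expect_warning(lab <- segment_chromosomes(ci), "foreground")
  expect_equal(max(lab), 0)
})

test_that("diagonally touching pixels belong to one 8-connected object", {
  img <- matrix(0, 20, 20)
  for (k in 5:12) img[k, k] <- 1000  # a pure diagonal line
  ci <- chromosome_image(img, pixel_size_um = 0.1)
  lab <- segment_chromosomes(ci, segmentation_config(threshold_method = "fixed",
                                                     threshold_value = 500,
                                                     min_object_px = 1))
  expect_equal(max(lab), 1)
})

test_that("area scales with pixel count and the square of pixel size", {
  mask <- matrix(0L, 20, 20)
  mask[1:10, 1:10] <- 1L
  expect_equal(unname(measure_chromosome_area(mask, 0.1)), 1.0)
  expect_equal(unname(measure_chromosome_area(mask, 0.2)),
               4 * unname(measure_chromosome_area(mask, 0.1)))
})

test_that("measured areas recover generator truth with low bias", {
  sim <- simulate_chromosome_image_set(chrom_image_sim_config(
    n_objects = 40, seed = 6))
  meas <- measure_image_set(sim$images)
  expect_equal(nrow(meas), 40)
  m <- merge(meas, sim$truth, by = "image_id")
  rel <- (m$chromosome_area_um2 - m$area_um2) / m$area_um2
  expect_true(all(abs(rel) < 0.05))       # per-object recovery
  expect_lt(abs(mean(rel)), 0.05)          # aggregate bias
})

test_that("isotropic dilation by f scales measured area by f^2", {
  f <- 1.3
  base <- simulate_chromosome_image_set(noiseless_config(10, seed = 3))
  big <- simulate_chromosome_image_set(noiseless_config(10 * f^2, seed = 3))
  cfg <- segmentation_config(min_object_px = 5)
  a1 <- measure_chromosomes(base$images[[1]], cfg)$chromosome_area_um2
  a2 <- measure_chromosomes(big$images[[1]], cfg)$chromosome_area_um2
  expect_equal(a2 / a1, f^2, tolerance = 0.05)
})

test_that("DAPI-high area recovers the planted pericentric fraction", {
  sim <- simulate_chromosome_image_set(chrom_image_sim_config(
    n_objects = 25, centromere_brightness_ratio = 3,
    centromere_area_frac = 0.2, seed = 10))
  meas <- measure_image_set(sim$images)
  m <- merge(meas, sim$truth, by = "image_id")
  rel <- (m$centromere_area_um2.x - m$centromere_area_um2.y) /
    m$centromere_area_um2.y
  expect_lt(abs(mean(rel)), 0.15)
  expect_true(all(m$centromere_area_um2.x <= m$chromosome_area_um2 + 1e-9))
})

test_that("a flat-intensity object has zero DAPI-high area", {
  img <- matrix(0, 30, 30)
  img[10:20, 10:20] <- 5000  # perfectly flat interior
  ci <- chromosome_image(img, pixel_size_um = 0.1)
  obj <- img > 0
  area <- measure_centromere_area(ci, obj)
  expect_equal(as.numeric(area), 0)
})

test_that("centromere containment holds across a random object sweep", {
  set.seed(99)
  for (s in 1:5) {
    sim <- simulate_chromosome_image_set(chrom_image_sim_config(
      n_objects = 20, area_mean_um2 = runif(1, 10, 45),
      centromere_area_frac = runif(1, 0.05, 0.4),
      centromere_brightness_ratio = runif(1, 1.5, 4), seed = s))
    meas <- measure_image_set(sim$images)
    expect_true(all(meas$centromere_area_um2 <=
                      meas$chromosome_area_um2 + 1e-9))
  }
})

test_that("Cenpa spots overlap the DAPI-high domain they mark", {
  sim <- simulate_chromosome_image_set(chrom_image_sim_config(
    n_objects = 10, seed = 12))
  meas <- measure_image_set(sim$images)
  expect_true(all(meas$cenpa_overlap_frac >= 0.9))
})

test_that("displaced or empty Cenpa channels are handled", {
  img <- matrix(0, 40, 80)
  img[15:25, 10:70] <- 10000
  img[15:25, 60:70] <- 30000        # DAPI-high band at the right end
  cenpa <- matrix(100, 40, 80)
  cenpa[18:22, 12:16] <- 20000      # spot at the opposite (left) end
  ci <- chromosome_image(img, pixel_size_um = 0.1, cenpa = cenpa)
  obj <- img > 0
  high <- attr(measure_centromere_area(ci, obj), "mask")
  expect_lt(cenpa_overlap(cenpa, high), 0.05)

  flat <- matrix(100, 40, 80)
  expect_warning(ov <- cenpa_overlap(flat, high), "empty")
  expect_true(is.na(ov))
})

test_that("group comparison matches the textbook Student t", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_sided, 1)

  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  oracle <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(cmp$p_two_sided, oracle$p, tolerance = 1e-12)
  expect_equal(cmp$mean, c(2, 5))
  expect_equal(cmp$sd, c(1, 1))

  expect_error(compare_groups(1, c(2, 3)), "at least 2")
})

test_that("images round-trip through 16-bit TIFF with sidecar metadata", {
  sim <- simulate_chromosome_image_set(chrom_image_sim_config(
    n_objects = 2, seed = 5))
  dir <- tempfile()
  write_chromosome_images(sim$images, dir)
  back <- read_chromosome_images(dir)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$dapi, sim$images[[1]]$dapi)
  expect_equal(back[[2]]$cenpa, sim$images[[2]]$cenpa)
  expect_equal(back[[1]]$pixel_size_um, sim$images[[1]]$pixel_size_um)
})

test_that("image generation is deterministic under a fixed seed", {
  cfg <- chrom_image_sim_config(n_objects = 3, seed = 7)
  a <- simulate_chromosome_image_set(cfg)
  b <- simulate_chromosome_image_set(cfg)
  expect_identical(a$images[[3]]$dapi, b$images[[3]]$dapi)
  expect_identical(a$truth, b$truth)
})

test_that("invalid calibration is rejected", {
  expect_error(chromosome_image(matrix(1, 5, 5), pixel_size_um = 0),
               "pixel_size_um")
  expect_error(chrom_image_sim_config(pixel_size_um = -1), "pixel_size_um")
})
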