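# Synthetic DAPI/Cenpa images of isolated mitotic chromosomes with exact
# ground-truth areas, for parameter-recovery testing of the morphometry
# stage.

# Area of a superellipse |x/a|^n + |y/b|^n <= 1.
.superellipse_area_const <- function(n) 4 * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)

#' Configuration for the chromosome image generator
#'
#' Each generated image holds one elongated chromosome body — a rotated
#' superellipse with mild low-order boundary jitter — with a brighter
#' DAPI-high sub-domain at one end of the major axis (mouse chromosomes are
#' telocentric) and, optionally, a Cenpa spot centred on that sub-domain.
#' True body areas are drawn Normal(`area_mean_um2`, `area_sd_um2`)
#' truncated at zero and recorded analytically in the ground truth, before
#' rasterisation and noise.
#'
#' @param n_objects number of images (one object each).
#' @param area_mean_um2,area_sd_um2 mean and SD of true chromosome area in
#'   square micrometres; defaults match wild-type chromosome 19
#'   (18.4 +/- 3.0).
#' @param pixel_size_um pixel edge length in micrometres (no default
#'   calibration is assumed; 0.05 matches a typical super-resolution
#'   acquisition).
#' @param elongation major/minor aspect ratio of the body (>= 1).
#' @param shape_exponent superellipse exponent (2 = ellipse; slightly
#'   larger values give the blunter outline of a condensed chromatid).
#' @param boundary_jitter SD of the low-order radial boundary modulation
#'   (relative units; keeps the analytic area unbiased to well below 1%).
#' @param centromere_area_frac fraction of the body area occupied by the
#'   DAPI-high domain (< 1).
#' @param centromere_brightness_ratio DAPI intensity ratio of the
#'   DAPI-high domain to the body (> 1).
#' @param foreground_level mean DAPI intensity of the chromosome body
#'   (16-bit scale).
#' @param background_level mean background intensity.
#' @param noise_sd additive Gaussian read-noise SD.
#' @param shot_noise apply Poisson shot noise to the expected intensities.
#' @param cenpa_channel generate a second channel with a Cenpa spot.
#' @param seed integer seed.
#' @return a `chrom_image_sim_config` list.
#' @export
chrom_image_sim_config <- function(n_objects = 100,
                                   area_mean_um2 = 18.4,
                                   area_sd_um2 = 3.0,
                                   pixel_size_um = 0.05,
                                   elongation = 3,
                                   shape_exponent = 2.5,
                                   boundary_jitter = 0.015,
                                   centromere_area_frac = 0.15,
                                   centromere_brightness_ratio = 2.5,
                                   foreground_level = 15000,
                                   background_level = 800,
                                   noise_sd = 200,
                                   shot_noise = TRUE,
                                   cenpa_channel = TRUE,
                                   seed = NULL) {
  errors <- character()
  errors <- check_that(errors, is_count(n_objects), "n_objects must be a positive count")
  errors <- check_that(errors, is_number(area_mean_um2) && area_mean_um2 > 0,
                       "area_mean_um2 must be positive")
  errors <- check_that(errors, is_number(area_sd_um2) && area_sd_um2 >= 0,
                       "area_sd_um2 must be non-negative")
  errors <- check_that(errors, is_number(pixel_size_um) && pixel_size_um > 0,
                       "pixel_size_um must be positive")
  errors <- check_that(errors, is_number(elongation) && elongation >= 1,
                       "elongation must be >= 1")
  errors <- check_that(errors, is_number(shape_exponent) && shape_exponent >= 1,
                       "shape_exponent must be >= 1")
  errors <- check_that(errors,
                       is_proportion(centromere_area_frac) && centromere_area_frac < 1,
                       "centromere_area_frac must be in [0,1)")
  errors <- check_that(errors,
                       is_number(centromere_brightness_ratio) &&
                         centromere_brightness_ratio > 1,
                       "centromere_brightness_ratio must exceed 1")
  errors <- check_that(errors, is_number(background_level) && background_level >= 0,
                       "background_level must be non-negative")
  errors <- check_that(errors, is_number(noise_sd) && noise_sd >= 0,
                       "noise_sd must be non-negative")
  stop_if_errors(errors, "invalid chrom_image_sim_config")
  structure(as.list(environment())[c(
    "n_objects", "area_mean_um2", "area_sd_um2", "pixel_size_um",
    "elongation", "shape_exponent", "boundary_jitter",
    "centromere_area_frac", "centromere_brightness_ratio",
    "foreground_level", "background_level", "noise_sd", "shot_noise",
    "cenpa_channel", "seed")],
    class = "chrom_image_sim_config")
}

# Rasterise one jittered rotated superellipse; returns the body mask, the
# DAPI-high mask (end of the major axis, approximately frac of the body),
# and the centroid of the high domain.
.rasterise_body <- function(area_um2, config, theta, jitter_coef, jitter_phase) {
  n_exp <- config$shape_exponent
  ps <- config$pixel_size_um
  cA <- .superellipse_area_const(n_exp)
  b <- sqrt(area_um2 / (cA * config$elongation))  # semi-minor, um
  a <- config$elongation * b                      # semi-major, um
  half <- a * 1.3
  dim_px <- max(16L, 2L * as.integer(ceiling(half / ps)))
  centre <- (dim_px + 1) / 2
  xy <- (seq_len(dim_px) - centre) * ps
  X <- matrix(xy, dim_px, dim_px)
  Y <- matrix(xy, dim_px, dim_px, byrow = TRUE)
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  r <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  # superellipse boundary radius at angle phi, modulated by smooth jitter
  R <- (abs(cos(phi) / a)^n_exp + abs(sin(phi) / b)^n_exp)^(-1 / n_exp)
  eps <- jitter_coef[1] * cos(2 * phi + jitter_phase[1]) +
    jitter_coef[2] * cos(3 * phi + jitter_phase[2])
  body <- r <= R * (1 + eps)
  # DAPI-high domain: the far end of the major axis holding ~frac of the area
  high <- body & FALSE
  if (config$centromere_area_frac > 0 && any(body)) {
    cut <- stats::quantile(u[body], 1 - config$centromere_area_frac,
                           names = FALSE)
    high <- body & u > cut
  }
  list(body = body, high = high,
       centre_high = if (any(high)) c(mean(X[high]), mean(Y[high])) else c(NA, NA),
       X = X, Y = Y)
}

#' Simulate a set of chromosome images with ground truth
#'
#' Generates `n_objects` single-chromosome images (DAPI channel, optional
#' Cenpa channel) and the analytic ground truth for each object: total
#' body area and DAPI-high (pericentric) area in square micrometres.
#' Identical configurations (including seed) reproduce the images exactly.
#'
#' @param config a [chrom_image_sim_config()].
#' @return list with `images` (list of [chromosome_image()]) and `truth`
#'   (data frame: `image_id`, `area_um2`, `centromere_area_um2`).
#' @export
simulate_chromosome_image_set <- function(config) {
  stopifnot(inherits(config, "chrom_image_sim_config"))
  with_seed(config$seed, {
    n <- config$n_objects
    areas <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        A <- stats::rnorm(1, config$area_mean_um2, config$area_sd_um2)
        if (A > 0) break
      }
      areas[i] <- A
    }
    images <- vector("list", n)
    for (i in seq_len(n)) {
      theta <- stats::runif(1, 0, pi)
      jc <- stats::rnorm(2, 0, config$boundary_jitter)
      jp <- stats::runif(2, 0, 2 * pi)
      geom <- .rasterise_body(areas[i], config, theta, jc, jp)
      expected <- matrix(config$background_level,
                         nrow(geom$body), ncol(geom$body))
      expected[geom$body] <- config$background_level + config$foreground_level
      expected[geom$high] <- config$background_level +
        config$foreground_level * config$centromere_brightness_ratio
      img <- expected
      if (config$shot_noise) {
        img[] <- stats::rpois(length(expected), lambda = expected)
      }
      if (config$noise_sd > 0) {
        img <- img + stats::rnorm(length(img), 0, config$noise_sd)
      }
      img <- matrix(pmin(pmax(round(img), 0), 65535),
                    nrow(expected), ncol(expected))
      cenpa <- NULL
      if (config$cenpa_channel && all(is.finite(geom$centre_high))) {
        spot_sd <- 0.25 * sqrt(config$centromere_area_frac * areas[i])
        d2 <- (geom$X - geom$centre_high[1])^2 + (geom$Y - geom$centre_high[2])^2
        cen_expected <- 200 + 12000 * exp(-d2 / (2 * spot_sd^2))
        cenpa <- cen_expected
        if (config$shot_noise) {
          cenpa[] <- stats::rpois(length(cen_expected), lambda = cen_expected)
        }
        if (config$noise_sd > 0) {
          cenpa <- cenpa + stats::rnorm(length(cenpa), 0, config$noise_sd)
        }
        cenpa <- matrix(pmin(pmax(round(cenpa), 0), 65535),
                        nrow(expected), ncol(expected))
      }
      images[[i]] <- chromosome_image(dapi = img,
                                      pixel_size_um = config$pixel_size_um,
                                      cenpa = cenpa,
                                      image_id = sprintf("sim_%04d", i))
    }
    truth <- data.frame(image_id = vapply(images, `[[`, "", "image_id"),
                        area_um2 = areas,
                        centromere_area_um2 = config$centromere_area_frac * areas,
                        stringsAsFactors = FALSE)
    list(images = images, truth = truth)
  })
}

#' Write chromosome images as 16-bit TIFFs with a metadata sidecar
#'
#' Pixel size is recorded in the sidecar CSV rather than in TIFF tags, for
#' portability across readers.
#'
#' @param images list of [chromosome_image()] objects.
#' @param dir output directory (created if needed).
#' @return path of the metadata CSV, invisibly.
#' @export
write_chromosome_images <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(images, function(img) {
    dapi_file <- paste0(img$image_id, "_dapi.tif")
    tiff::writeTIFF(img$dapi / 65535, file.path(dir, dapi_file),
                    bits.per.sample = 16L)
    cenpa_file <- NA_character_
    if (!is.null(img$cenpa)) {
      cenpa_file <- paste0(img$image_id, "_cenpa.tif")
      tiff::writeTIFF(img$cenpa / 65535, file.path(dir, cenpa_file),
                      bits.per.sample = 16L)
    }
    data.frame(image_id = img$image_id, dapi_file = dapi_file,
               cenpa_file = cenpa_file, pixel_size_um = img$pixel_size_um,
               stringsAsFactors = FALSE)
  }))
  meta_path <- file.path(dir, "images.csv")
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(meta_path)
}

#' Read chromosome images written by [write_chromosome_images()]
#'
#' @param dir directory holding the TIFFs and `images.csv` sidecar.
#' @return list of [chromosome_image()] objects.
#' @export
read_chromosome_images <- function(dir) {
  meta_path <- file.path(dir, "images.csv")
  if (!file.exists(meta_path)) {
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    dapi <- round(tiff::readTIFF(file.path(dir, meta$dapi_file[i])) * 65535)
    cenpa <- NULL
    if (!is.na(meta$cenpa_file[i])) {
      cenpa <- round(tiff::readTIFF(file.path(dir, meta$cenpa_file[i])) * 65535)
    }
    chromosome_image(dapi = dapi, pixel_size_um = meta$pixel_size_um[i],
                     cenpa = cenpa, image_id = meta$image_id[i])
  })
}
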