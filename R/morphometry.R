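#' Calibrated fluorescence image of isolated mitotic chromosomes
#'
#' Wraps one or two intensity channels (DAPI, and optionally Cenpa
#' immunofluorescence) with the pixel calibration needed to report areas
#' in square micrometres.
#'
#' @param dapi numeric matrix of non-negative DAPI intensities.
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @param cenpa optional Cenpa channel, same shape as `dapi`.
#' @param image_id identifier used in measurement tables.
#' @return an object of class `chromosome_image`.
#' @export
chromosome_image <- function(dapi, pixel_size_um, cenpa = NULL,
                             image_id = "image") {
  errors <- character()
  errors <- check_that(errors, is.matrix(dapi) && is.numeric(dapi),
                       "dapi must be a numeric matrix")
  errors <- check_that(errors, all(dapi >= 0, na.rm = TRUE),
                       "dapi intensities must be non-negative")
  errors <- check_that(errors, is_number(pixel_size_um) && pixel_size_um > 0,
                       "pixel_size_um must be positive")
  errors <- check_that(errors,
                       is.null(cenpa) || identical(dim(cenpa), dim(dapi)),
                       "cenpa channel must match the dapi shape")
  stop_if_errors(errors, "invalid chromosome_image")
  structure(list(dapi = dapi, cenpa = cenpa,
                 pixel_size_um = pixel_size_um,
                 image_id = as.character(image_id)),
            class = "chromosome_image")
}

#' @export
print.chromosome_image <- function(x, ...) {
  cat(sprintf("Chromosome image '%s': %d x %d px at %.4g um/px%s\n",
              x$image_id, nrow(x$dapi), ncol(x$dapi), x$pixel_size_um,
              if (is.null(x$cenpa)) "" else " (+ Cenpa channel)"))
  invisible(x)
}

#' Segmentation settings for chromosome morphometry
#'
#' @param threshold_method `"otsu"` (default; parameter-free, robust for
#'   bimodal foreground/background), `"fixed"` (absolute intensity in
#'   `threshold_value`) or `"quantile"` (global intensity quantile in
#'   `threshold_value`).
#' @param threshold_value threshold parameter for the fixed and quantile
#'   methods.
#' @param min_object_px minimum connected-component size in pixels.
#' @param exclude_border drop components touching the image border
#'   (partial objects bias areas down).
#' @param centromere_quantile per-object DAPI intensity quantile defining
#'   the DAPI-high (pericentric) sub-domain, default 0.8.
#' @param cenpa_method threshold method for the Cenpa channel in
#'   [cenpa_overlap()]: `"otsu"` or `"quantile"`.
#' @param cenpa_quantile quantile for `cenpa_method = "quantile"`.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "fixed", "quantile"),
                                threshold_value = NULL,
                                min_object_px = 20L,
                                exclude_border = TRUE,
                                centromere_quantile = 0.8,
                                cenpa_method = c("otsu", "quantile"),
                                cenpa_quantile = 0.99) {
  threshold_method <- match.arg(threshold_method)
  cenpa_method <- match.arg(cenpa_method)
  errors <- character()
  if (threshold_method != "otsu") {
    errors <- check_that(errors, is_number(threshold_value),
                         "threshold_value required for fixed/quantile methods")
    if (threshold_method == "quantile") {
      errors <- check_that(errors,
                           is_number(threshold_value) && threshold_value > 0 &&
                             threshold_value < 1,
                           "quantile threshold_value must be in (0,1)")
    }
  }
  errors <- check_that(errors, is_count(min_object_px),
                       "min_object_px must be >= 1")
  errors <- check_that(errors,
                       is_number(centromere_quantile) &&
                         centromere_quantile > 0 && centromere_quantile < 1,
                       "centromere_quantile must be in (0,1)")
  stop_if_errors(errors, "invalid segmentation_config")
  structure(list(threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 min_object_px = as.integer(min_object_px),
                 exclude_border = isTRUE(exclude_border),
                 centromere_quantile = centromere_quantile,
                 cenpa_method = cenpa_method,
                 cenpa_quantile = cenpa_quantile),
            class = "segmentation_config")
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]     # down-left diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

.threshold_value <- function(dapi, config) {
  switch(config$threshold_method,
         otsu = {
           rng <- range(dapi)
           if (diff(rng) == 0) return(rng[2])  # blank image
           norm <- (dapi - rng[1]) / diff(rng)
           t <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1),
                              levels = 65536L)
           rng[1] + t * diff(rng)
         },
         fixed = config$threshold_value,
         quantile = stats::quantile(dapi, config$threshold_value, names = FALSE))
}

#' Segment chromosomes in a DAPI image
#'
#' Thresholds the DAPI channel, labels 8-connected foreground components,
#' and removes components smaller than `min_object_px` or touching the
#' border (when `exclude_border`).
#'
#' @param image a [chromosome_image()].
#' @param config a [segmentation_config()].
#' @return an integer label matrix (0 = background, 1..K = objects) with
#'   the applied intensity threshold attached as attribute `threshold`.
#'   A blank image yields an all-zero matrix with a warning.
#' @export
segment_chromosomes <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "chromosome_image"),
            inherits(config, "segmentation_config"))
  dapi <- image$dapi
  thr <- .threshold_value(dapi, config)
  mask <- dapi > thr
  if (!any(mask)) {
    warning("no foreground pixels in image '", image$image_id, "'")
    out <- matrix(0L, nrow(dapi), ncol(dapi))
    attr(out, "threshold") <- thr
    return(out)
  }
  lab <- .label8(mask)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < config$min_object_px)
  if (config$exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, border[border > 0])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L
  kept <- sort(unique(lab[lab > 0]))
  if (length(kept)) {
    lab[lab > 0] <- match(lab[lab > 0], kept)
  } else {
    warning("no objects survive size/border filters in image '",
            image$image_id, "'")
  }
  out <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
  attr(out, "threshold") <- thr
  out
}

#' Chromosome area from a labeled mask
#'
#' Area = foreground pixel count times `pixel_size_um^2`.
#'
#' @param mask integer label matrix from [segment_chromosomes()] (or a
#'   logical mask for a single object).
#' @param pixel_size_um pixel edge length in micrometres.
#' @return named numeric vector of areas in square micrometres, one per
#'   object label.
#' @export
measure_chromosome_area <- function(mask, pixel_size_um) {
  stopifnot(is_number(pixel_size_um), pixel_size_um > 0)
  if (is.logical(mask)) mask <- mask * 1L
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) return(stats::setNames(numeric(0), character(0)))
  counts <- tabulate(mask[mask > 0], nbins = max(labs))[labs]
  stats::setNames(counts * pixel_size_um^2, labs)
}

#' DAPI-high (pericentric) area within one chromosome object
#'
#' The DAPI-high domain is defined per object as the pixels whose DAPI
#' intensity strictly exceeds the object's own `centromere_quantile`
#' intensity quantile; the largest 8-connected such component is reported.
#' A flat-intensity object therefore has zero DAPI-high area.
#'
#' @param image a [chromosome_image()].
#' @param object_mask logical matrix selecting one segmented object.
#' @param config a [segmentation_config()].
#' @return the DAPI-high area in square micrometres (0 if none), with the
#'   selected high-intensity mask attached as attribute `mask`.
#' @export
measure_centromere_area <- function(image, object_mask,
                                    config = segmentation_config()) {
  stopifnot(inherits(image, "chromosome_image"), is.logical(object_mask))
  vals <- image$dapi[object_mask]
  if (!length(vals)) return(structure(0, mask = object_mask & FALSE))
  thr <- stats::quantile(vals, config$centromere_quantile, names = FALSE)
  high <- object_mask & image$dapi > thr
  if (!any(high)) return(structure(0, mask = high))
  lab <- .label8(high)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  sel <- lab == best
  structure(sizes[best] * image$pixel_size_um^2, mask = sel)
}

#' Fraction of Cenpa signal inside the DAPI-high domain
#'
#' Thresholds the Cenpa channel (Otsu by default) and reports the fraction
#' of Cenpa-positive pixels that fall inside the DAPI-high mask.
#'
#' @param cenpa_channel numeric matrix of Cenpa intensities.
#' @param dapi_high_mask logical DAPI-high mask (attribute `mask` of
#'   [measure_centromere_area()]).
#' @param config a [segmentation_config()].
#' @return overlap fraction in `[0, 1]`, or `NA` (with a warning) when the
#'   channel contains no positive signal.
#' @export
cenpa_overlap <- function(cenpa_channel, dapi_high_mask,
                          config = segmentation_config()) {
  if (is.null(cenpa_channel)) return(NA_real_)
  rng <- range(cenpa_channel)
  if (diff(rng) == 0) {
    warning("empty Cenpa channel; overlap not defined")
    return(NA_real_)
  }
  thr <- if (config$cenpa_method == "otsu") {
    norm <- (cenpa_channel - rng[1]) / diff(rng)
    rng[1] + EBImage::otsu(EBImage::Image(norm), range = c(0, 1),
                           levels = 65536L) * diff(rng)
  } else {
    stats::quantile(cenpa_channel, config$cenpa_quantile, names = FALSE)
  }
  pos <- cenpa_channel > thr
  if (!any(pos)) {
    warning("no Cenpa-positive pixels above threshold")
    return(NA_real_)
  }
  sum(pos & dapi_high_mask) / sum(pos)
}

#' Measure all chromosomes in one image
#'
#' Runs segmentation and reports, per object, the total chromosome area,
#' the DAPI-high (pericentric) area and, when a Cenpa channel is present,
#' the Cenpa overlap fraction.
#'
#' @param image a [chromosome_image()].
#' @param config a [segmentation_config()].
#' @return data frame with one row per object: `image_id`, `object_label`,
#'   `chromosome_area_um2`, `centromere_area_um2`, `cenpa_overlap_frac`.
#' @export
measure_chromosomes <- function(image, config = segmentation_config()) {
  lab <- segment_chromosomes(image, config)
  labs <- sort(unique(lab[lab > 0]))
  if (!length(labs)) {
    return(data.frame(image_id = character(0), object_label = integer(0),
                      chromosome_area_um2 = numeric(0),
                      centromere_area_um2 = numeric(0),
                      cenpa_overlap_frac = numeric(0)))
  }
  areas <- measure_chromosome_area(lab, image$pixel_size_um)
  cen <- numeric(length(labs))
  overlap <- rep(NA_real_, length(labs))
  for (k in seq_along(labs)) {
    obj <- lab == labs[k]
    ca <- measure_centromere_area(image, obj, config)
    cen[k] <- as.numeric(ca)
    if (!is.null(image$cenpa)) {
      overlap[k] <- suppressWarnings(
        cenpa_overlap(image$cenpa, attr(ca, "mask"), config))
    }
  }
  data.frame(image_id = image$image_id, object_label = labs,
             chromosome_area_um2 = as.numeric(areas),
             centromere_area_um2 = cen,
             cenpa_overlap_frac = overlap,
             stringsAsFactors = FALSE)
}

#' Measure a set of chromosome images
#'
#' @param images list of [chromosome_image()] objects.
#' @param config a [segmentation_config()].
#' @return row-bound data frame of per-object measurements.
#' @export
measure_image_set <- function(images, config = segmentation_config()) {
  do.call(rbind, lapply(images, measure_chromosomes, config = config))
}

#' Unpaired two-tailed Student's t comparison of two measurement groups
#'
#' Pooled-variance (classical Student, not Welch) two-sample t test with
#' per-group mean and sample SD, as used for comparing chromosome or
#' centromere areas between cell lines.
#'
#' @param measurements_a,measurements_b numeric vectors (e.g. areas in
#'   square micrometres), each with at least 2 values.
#' @param group_names length-2 character vector of group labels.
#' @return an object of class `group_comparison` with per-group `n`,
#'   `mean`, `sd`, the pooled `t_statistic`, degrees of freedom and the
#'   two-sided `p_two_sided`.
#' @export
compare_groups <- function(measurements_a, measurements_b,
                           group_names = c("A", "B")) {
  a <- measurements_a[!is.na(measurements_a)]
  b <- measurements_b[!is.na(measurements_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 measurements", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- if (se == 0) {
    if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
  } else {
    (mean(a) - mean(b)) / se
  }
  df <- n1 + n2 - 2
  p <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df)
  structure(list(group_names = group_names,
                 n = c(n1, n2),
                 mean = c(mean(a), mean(b)),
                 sd = c(stats::sd(a), stats::sd(b)),
                 t_statistic = t_stat, df = df, p_two_sided = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Unpaired two-tailed Student's t test (pooled variance)\n")
  for (i in 1:2) {
    cat(sprintf("  %s: n = %d, mean +/- SD = %.3g +/- %.3g\n",
                x$group_names[i], x$n[i], x$mean[i], x$sd[i]))
  }
  cat(sprintf("  t = %.4g (df = %d), two-sided p = %.3g\n",
              x$t_statistic, x$df, x$p_two_sided))
  invisible(x)
}
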