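# Pipeline orchestration: a validated YAML configuration drives the
# simulate / enrich / measure / atac stages and produces a consistent run
# report.

.default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "chromosort_run",
    stages = c("simulate", "enrich", "measure", "atac"),
    simulate = list(
      lfq = list(n_proteins = 1000, frac_enriched = 0.1, frac_depleted = 0.1,
                 effect_log2 = 2, within_sd_log2 = 0.5,
                 base_log2_mean = 25, base_log2_sd = 2,
                 missing = "mnar", missing_quantile = 0.25, missing_rate = 0.6,
                 n_bio = 3, n_tech = 2),
      images = list(n_objects = 50, area_mean_um2 = 18.4, area_sd_um2 = 3.0,
                    pixel_size_um = 0.05),
      atac = list(chrom_length = 2e6, background_rate = 0.005,
                  n_peaks = 20, peak_half_width = 250, peak_fold = 4)
    ),
    enrich = list(table = NULL, column_map = NULL, s0 = 0.1, fdr = 0.01,
                  n_randomizations = 250, min_peptides = 2),
    measure = list(images = NULL, threshold_method = "otsu",
                   min_object_px = 20, centromere_quantile = 0.8),
    atac = list(reads = NULL, chrom_sizes = NULL, summits = NULL,
                window_size = 25000, extend_bp = 25, span_bp = 2000,
                bin_bp = 10)
  )
}

# Recursively overlay user values on the defaults.
.merge_config <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  for (k in names(user)) {
    if (k %in% names(defaults) && is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]])
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML configuration (or an equivalent list), fills in documented
#' defaults, and checks every constraint of the embedded stage
#' configurations. All violations are reported together, each naming the
#' offending key.
#'
#' @param config path to a YAML file, or a named list.
#' @return the validated configuration list (with defaults filled in);
#'   errors aggregate every violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- .merge_config(.default_run_config(), config)
  errors <- character()
  errors <- check_that(errors, is_count(cfg$seed, 0L), "seed: must be a non-negative integer")
  errors <- check_that(errors, all(cfg$stages %in% c("simulate", "enrich", "measure", "atac")),
                       "stages: unknown stage name")
  l <- cfg$simulate$lfq
  errors <- check_that(errors, is_proportion(l$frac_enriched),
                       "simulate.lfq.frac_enriched: must be in [0,1]")
  errors <- check_that(errors, is_proportion(l$frac_depleted),
                       "simulate.lfq.frac_depleted: must be in [0,1]")
  errors <- check_that(errors,
                       is_number(l$frac_enriched) && is_number(l$frac_depleted) &&
                         l$frac_enriched + l$frac_depleted <= 1,
                       "simulate.lfq: frac_enriched + frac_depleted must be <= 1")
  errors <- check_that(errors, is_count(l$n_bio, 2L),
                       "simulate.lfq.n_bio: must be >= 2")
  e <- cfg$enrich
  errors <- check_that(errors, is_number(e$fdr) && e$fdr > 0 && e$fdr < 1,
                       "enrich.fdr: must be in (0,1)")
  errors <- check_that(errors, is_number(e$s0) && e$s0 >= 0,
                       "enrich.s0: must be non-negative")
  errors <- check_that(errors, is_count(e$n_randomizations),
                       "enrich.n_randomizations: must be >= 1")
  m <- cfg$measure
  errors <- check_that(errors,
                       is_number(m$centromere_quantile) &&
                         m$centromere_quantile > 0 && m$centromere_quantile < 1,
                       "measure.centromere_quantile: must be in (0,1)")
  errors <- check_that(errors,
                       is_number(cfg$simulate$images$pixel_size_um) &&
                         cfg$simulate$images$pixel_size_um > 0,
                       "simulate.images.pixel_size_um: must be positive")
  a <- cfg$atac
  errors <- check_that(errors, is_count(a$window_size),
                       "atac.window_size: must be a positive count")
  # input files must resolve before any stage runs
  for (key in c("enrich.table", "enrich.column_map", "measure.images",
                "atac.reads", "atac.chrom_sizes", "atac.summits")) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    if (!is.null(val) && is.character(val) && !file.exists(val)) {
      errors <- c(errors, paste0(key, ": input does not exist: ", val))
    }
  }
  stop_if_errors(errors, "invalid run configuration")
  cfg
}

#' Run the chromosome analysis pipeline
#'
#' Executes the selected stages in dependency order — synthetic-data
#' generation, LFQ enrichment analysis, chromosome morphometry, ATAC
#' accessibility — writing stage outputs and a run report (JSON + text)
#' under `outdir`. Identical configuration and seed reproduce every output
#' file. Stages with no configured input fall back to the simulated data
#' from the `simulate` stage.
#'
#' @param config path to a YAML configuration or a named list
#'   (see [validate_config()]).
#' @param outdir optional output directory override.
#' @param seed optional seed override; propagated to every stochastic
#'   component.
#' @param stages optional character vector restricting the stages to run.
#' @return the run report, invisibly (also written to
#'   `<outdir>/report.json` and `<outdir>/report.txt`).
#' @export
run_pipeline <- function(config = list(), outdir = NULL, seed = NULL,
                         stages = NULL) {
  cfg <- validate_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(stages)) cfg$stages <- stages
  cfg <- validate_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  report <- list(seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("chromosort")),
                 stages = list())
  sim <- NULL

  if ("simulate" %in% cfg$stages) {
    l <- cfg$simulate$lfq
    mm <- switch(l$missing,
                 none = missing_none(),
                 mcar = missing_mcar(l$missing_rate),
                 mnar = missing_mnar(l$missing_quantile, l$missing_rate))
    lfq_cfg <- lfq_sim_config(n_proteins = l$n_proteins,
                              frac_enriched = l$frac_enriched,
                              frac_depleted = l$frac_depleted,
                              effect_log2 = l$effect_log2,
                              within_sd_log2 = l$within_sd_log2,
                              base_log2_mean = l$base_log2_mean,
                              base_log2_sd = l$base_log2_sd,
                              missing_model = mm,
                              n_bio = l$n_bio, n_tech = l$n_tech,
                              seed = cfg$seed)
    sim_lfq <- simulate_lfq_table(lfq_cfg)
    write_protein_group_table(sim_lfq$table,
                              file.path(cfg$outdir, "proteinGroups.txt"),
                              file.path(cfg$outdir, "column_map.csv"))
    utils::write.csv(sim_lfq$truth, file.path(cfg$outdir, "lfq_truth.csv"),
                     row.names = FALSE)

    im <- cfg$simulate$images
    img_cfg <- chrom_image_sim_config(n_objects = im$n_objects,
                                      area_mean_um2 = im$area_mean_um2,
                                      area_sd_um2 = im$area_sd_um2,
                                      pixel_size_um = im$pixel_size_um,
                                      seed = cfg$seed + 1L)
    sim_img <- simulate_chromosome_image_set(img_cfg)
    utils::write.csv(sim_img$truth, file.path(cfg$outdir, "image_truth.csv"),
                     row.names = FALSE)

    at <- cfg$simulate$atac
    chrom_sizes <- c(chrSim = as.integer(at$chrom_length))
    usable <- at$chrom_length - 2 * at$peak_half_width
    summit_pos <- as.integer(at$peak_half_width +
                               round(seq(0.05, 0.95, length.out = at$n_peaks) * usable))
    peaks <- atac_peaks(chrom = rep("chrSim", at$n_peaks),
                        summit = summit_pos,
                        half_width = at$peak_half_width,
                        class = rep(c("retained", "lost"),
                                    length.out = at$n_peaks),
                        fold = at$peak_fold)
    atac_cfg <- atac_sim_config(chrom_sizes = chrom_sizes,
                                background_rate = at$background_rate,
                                peaks = peaks, seed = cfg$seed + 2L)
    sim_atac <- simulate_atac_reads(atac_cfg)
    for (cond in names(sim_atac$reads)) {
      write_bed6(sim_atac$reads[[cond]],
                 file.path(cfg$outdir, paste0("reads_", cond, ".bed")))
    }
    utils::write.table(data.frame(names(chrom_sizes), chrom_sizes),
                       file.path(cfg$outdir, "chrom.sizes"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(peaks$chrom, peaks$summit, peaks$summit + 1L,
                                  peaks$class),
                       file.path(cfg$outdir, "summits.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)

    sim <- list(lfq = sim_lfq, images = sim_img, atac = sim_atac,
                chrom_sizes = chrom_sizes, peaks = peaks)
    report$stages$simulate <- list(
      lfq_rows = nrow(sim_lfq$table$intensities),
      images = length(sim_img$images),
      atac_reads = vapply(sim_atac$reads, nrow, integer(1)))
  }

  if ("enrich" %in% cfg$stages) {
    e <- cfg$enrich
    table <- if (!is.null(e$table)) {
      read_protein_group_table(e$table, e$column_map)
    } else if (!is.null(sim)) {
      sim$lfq$table
    } else {
      stop("enrich stage needs either enrich.table or the simulate stage",
           call. = FALSE)
    }
    fit <- lfq_enrichment(table, s0 = e$s0, fdr = e$fdr,
                          n_randomizations = e$n_randomizations,
                          min_peptides = e$min_peptides, seed = cfg$seed)
    write_enrichment_results(fit, file.path(cfg$outdir, "enrichment_results.csv"))
    counts <- fit$counts
    stopifnot(counts$enriched + counts$depleted + counts$ns +
                counts$not_tested == counts$after_filter)
    report$stages$enrich <- counts
  }

  if ("measure" %in% cfg$stages) {
    m <- cfg$measure
    images <- if (!is.null(m$images)) {
      read_chromosome_images(m$images)
    } else if (!is.null(sim)) {
      sim$images$images
    } else {
      stop("measure stage needs either measure.images or the simulate stage",
           call. = FALSE)
    }
    seg_cfg <- segmentation_config(threshold_method = m$threshold_method,
                                   min_object_px = m$min_object_px,
                                   centromere_quantile = m$centromere_quantile)
    meas <- measure_image_set(images, seg_cfg)
    utils::write.csv(meas, file.path(cfg$outdir, "measurements.csv"),
                     row.names = FALSE)
    report$stages$measure <- list(images = length(images),
                                  objects = nrow(meas),
                                  mean_area_um2 = mean(meas$chromosome_area_um2))
  }

  if ("atac" %in% cfg$stages) {
    a <- cfg$atac
    if (!is.null(a$reads)) {
      reads <- list(input = read_bed6(a$reads))
      chrom_sizes <- read_chrom_sizes(a$chrom_sizes)
      summits <- if (!is.null(a$summits)) read_summits(a$summits) else NULL
    } else if (!is.null(sim)) {
      reads <- sim$atac$reads
      chrom_sizes <- sim$chrom_sizes
      summits <- data.frame(chrom = sim$peaks$chrom, pos = sim$peaks$summit,
                            class = sim$peaks$class, stringsAsFactors = FALSE)
    } else {
      stop("atac stage needs either atac.reads or the simulate stage",
           call. = FALSE)
    }
    atac_report <- list()
    for (cond in names(reads)) {
      sites <- extract_insertion_centers(reads[[cond]], chrom_sizes)
      track <- windowed_log2_enrichment(sites, chrom_sizes,
                                        window_size = a$window_size)
      stopifnot(sum(track$count) == nrow(sites))
      write_bedgraph(track, file.path(cfg$outdir,
                                      paste0("enrichment_", cond, ".bedgraph")))
      if (!is.null(summits)) {
        prof <- summit_trend_profile(sites, summits, extend_bp = a$extend_bp,
                                     span_bp = a$span_bp, bin_bp = a$bin_bp)
        write_trend_profile(prof, file.path(cfg$outdir,
                                            paste0("profile_", cond, ".csv")))
      }
      atac_report[[cond]] <- list(
        reads = nrow(reads[[cond]]),
        sites = nrow(sites),
        dropped_strand = attr(sites, "n_dropped_strand"),
        dropped_bounds = attr(sites, "n_dropped_bounds"))
    }
    report$stages$atac <- atac_report
  }

  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  txt <- utils::capture.output(utils::str(report, give.attr = FALSE))
  writeLines(c(sprintf("chromosort run (seed %d)", cfg$seed), txt),
             file.path(cfg$outdir, "report.txt"))
  invisible(report)
}
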