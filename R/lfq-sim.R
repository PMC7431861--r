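#' Missing-value models for simulated LFQ tables
#'
#' LFQ proteomics data are dominated by left-censored (intensity-dependent)
#' missingness: low-abundance peptides drop below the detection limit.
#' `missing_mnar()` models this by masking, within each run, values that lie
#' below the run's `quantile` intensity quantile, each with probability
#' `rate`. `missing_mcar()` masks values completely at random;
#' `missing_none()` disables missingness.
#'
#' @param rate masking probability in `[0, 1]`.
#' @param quantile intensity quantile in `(0, 1)` below which values are
#'   eligible for MNAR masking.
#' @return a missing-model specification list.
#' @export
missing_none <- function() structure(list(type = "none"), class = "lfq_missing_model")

#' @rdname missing_none
#' @export
missing_mcar <- function(rate) {
  stopifnot(is_proportion(rate))
  structure(list(type = "mcar", rate = rate), class = "lfq_missing_model")
}

#' @rdname missing_none
#' @export
missing_mnar <- function(quantile = 0.25, rate = 0.6) {
  stopifnot(is_proportion(rate), is_number(quantile), quantile > 0, quantile < 1)
  structure(list(type = "mnar", quantile = quantile, rate = rate),
            class = "lfq_missing_model")
}

#' Configuration for the synthetic LFQ table generator
#'
#' Describes a two-condition label-free proteomics experiment
#' (mitotic lysate pellet vs flow-sorted chromosomes) with `n_bio`
#' biological replicates each measured in `n_tech` technical replicates.
#' Per-protein log2 base abundance is drawn
#' Normal(`base_log2_mean`, `base_log2_sd`); planted enriched/depleted
#' proteins shift the sorted-condition mean by +/-`effect_log2`; biological
#' replicate noise is Normal(0, `within_sd_log2`) and technical replicates
#' add Normal(0, `within_sd_log2 / 2`).
#'
#' Defaults mirror a typical MaxQuant LFQ experiment on the log2 scale
#' (base mean 25, base SD 2, within-replicate SD 0.5) with the study design
#' of 3 biological x 2 technical replicates per condition and left-censored
#' missingness.
#'
#' @param n_proteins number of protein groups.
#' @param frac_enriched,frac_depleted proportions of proteins planted as
#'   enriched / depleted on sorted chromosomes; their sum must be <= 1.
#' @param effect_log2 planted absolute log2 fold change (sorted - lysate).
#' @param within_sd_log2 biological replicate SD on the log2 scale.
#' @param base_log2_mean,base_log2_sd mean and SD of per-protein base
#'   abundance on the log2 scale.
#' @param missing_model a [missing_none()], [missing_mcar()] or
#'   [missing_mnar()] specification.
#' @param n_bio biological replicates per condition (>= 2).
#' @param n_tech technical replicates per biological replicate.
#' @param seed integer seed for reproducible generation.
#' @return an `lfq_sim_config` list.
#' @export
lfq_sim_config <- function(n_proteins = 1000,
                           frac_enriched = 0.1,
                           frac_depleted = 0.1,
                           effect_log2 = 2,
                           within_sd_log2 = 0.5,
                           base_log2_mean = 25,
                           base_log2_sd = 2,
                           missing_model = missing_mnar(),
                           n_bio = 3,
                           n_tech = 2,
                           seed = NULL) {
  if (is.character(missing_model) && identical(missing_model, "none")) {
    missing_model <- missing_none()
  }
  errors <- character()
  errors <- check_that(errors, is_count(n_proteins), "n_proteins must be a positive count")
  errors <- check_that(errors, is_proportion(frac_enriched), "frac_enriched must be in [0,1]")
  errors <- check_that(errors, is_proportion(frac_depleted), "frac_depleted must be in [0,1]")
  errors <- check_that(errors,
                       is_number(frac_enriched) && is_number(frac_depleted) &&
                         frac_enriched + frac_depleted <= 1,
                       "frac_enriched + frac_depleted must be <= 1")
  errors <- check_that(errors, is_number(effect_log2) && effect_log2 >= 0,
                       "effect_log2 must be non-negative")
  errors <- check_that(errors, is_number(within_sd_log2) && within_sd_log2 > 0,
                       "within_sd_log2 must be positive")
  errors <- check_that(errors, is_number(base_log2_sd) && base_log2_sd > 0,
                       "base_log2_sd must be positive")
  errors <- check_that(errors, inherits(missing_model, "lfq_missing_model"),
                       "missing_model must be a missing-model specification")
  errors <- check_that(errors, is_count(n_bio, 2L), "n_bio must be >= 2")
  errors <- check_that(errors, is_count(n_tech), "n_tech must be >= 1")
  stop_if_errors(errors, "invalid lfq_sim_config")
  structure(list(n_proteins = as.integer(n_proteins),
                 frac_enriched = frac_enriched, frac_depleted = frac_depleted,
                 effect_log2 = effect_log2, within_sd_log2 = within_sd_log2,
                 base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
                 missing_model = missing_model,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 seed = seed),
            class = "lfq_sim_config")
}

#' Simulate an LFQ protein-group table with planted enrichment
#'
#' Generates a raw-scale [protein_group_table()] for the two-condition
#' sorted-chromosome vs mitotic-lysate comparison, with ground-truth class
#' labels (`enriched`, `depleted`, `null`) for every protein group.
#' Identical configurations (including seed) reproduce the table exactly.
#'
#' @param config an [lfq_sim_config()].
#' @return a list with elements `table` (the [protein_group_table()]) and
#'   `truth` (data frame: `protein_id`, `class`, `planted_log2fc`).
#' @export
simulate_lfq_table <- function(config) {
  stopifnot(inherits(config, "lfq_sim_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    n_enr <- round(config$frac_enriched * n)
    n_dep <- round(config$frac_depleted * n)
    class <- rep("null", n)
    planted <- sample.int(n, n_enr + n_dep)
    class[planted[seq_len(n_enr)]] <- "enriched"
    if (n_dep > 0) class[planted[n_enr + seq_len(n_dep)]] <- "depleted"
    delta <- ifelse(class == "enriched", config$effect_log2,
                    ifelse(class == "depleted", -config$effect_log2, 0))

    base <- stats::rnorm(n, config$base_log2_mean, config$base_log2_sd)
    conditions <- c("lysate", "sorted")
    design <- expand.grid(tech = seq_len(config$n_tech),
                          bio = seq_len(config$n_bio),
                          condition = conditions,
                          stringsAsFactors = FALSE)[, c("condition", "bio", "tech")]
    design$column <- sprintf("LFQ intensity %s_%d_%d",
                             design$condition, design$bio, design$tech)

    m <- matrix(NA_real_, n, nrow(design))
    # biological deviations shared by the technical replicates of a bio rep
    for (cond in conditions) {
      for (b in seq_len(config$n_bio)) {
        bio_dev <- stats::rnorm(n, 0, config$within_sd_log2)
        mu <- base + if (cond == "sorted") delta else 0
        cols <- which(design$condition == cond & design$bio == b)
        for (j in cols) {
          tech_dev <- stats::rnorm(n, 0, config$within_sd_log2 / 2)
          m[, j] <- 2^(mu + bio_dev + tech_dev)
        }
      }
    }

    mm <- config$missing_model
    if (mm$type == "mcar" && mm$rate > 0) {
      m[stats::runif(length(m)) < mm$rate] <- NA_real_
    } else if (mm$type == "mnar" && mm$rate > 0) {
      for (j in seq_len(ncol(m))) {
        thr <- stats::quantile(m[, j], mm$quantile, na.rm = TRUE)
        low <- which(m[, j] < thr)
        mask <- low[stats::runif(length(low)) < mm$rate]
        m[mask, j] <- NA_real_
      }
    }

    ids <- sprintf("P%05d", seq_len(n))
    table <- protein_group_table(
      protein_id = ids,
      intensities = m,
      design = design[, c("column", "condition", "bio", "tech")],
      razor_unique_peptides = 2L + stats::rpois(n, 8)
    )
    truth <- data.frame(protein_id = ids, class = class,
                        planted_log2fc = delta, stringsAsFactors = FALSE)
    list(table = table, truth = truth)
  })
}
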