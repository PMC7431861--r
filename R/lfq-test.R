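# Differential enrichment testing: S0-moderated t statistic with
# permutation-based FDR control, as used for volcano analyses of
# label-free proteomics data.

# Per-row group summaries over a column subset, NA-aware.
.group_stats <- function(m, idx) {
  sub <- m[, idx, drop = FALSE]
  nv <- rowSums(!is.na(sub))
  s <- rowSums(sub, na.rm = TRUE)
  mean <- ifelse(nv > 0, s / nv, NA_real_)
  # two-pass (centred) sum of squares for full double precision
  ss <- rowSums((sub - mean)^2, na.rm = TRUE)
  list(n = nv, mean = mean, ss = ss)
}

# Vectorised moderated statistic for all rows of a log2 matrix.
# Returns NA for rows with fewer than min_valid valid values in a group.
.d_stats <- function(m, idx_sorted, idx_lysate, s0, min_valid = 2L) {
  g1 <- .group_stats(m, idx_sorted)
  g2 <- .group_stats(m, idx_lysate)
  testable <- g1$n >= min_valid & g2$n >= min_valid
  df <- g1$n + g2$n - 2
  sp2 <- ifelse(df > 0, (g1$ss + g2$ss) / df, NA_real_)
  se <- sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  diff <- g1$mean - g2$mean
  denom <- se + s0
  d <- diff / denom
  # zero variance in both groups with s0 = 0: +/-Inf with the sign of the
  # mean difference; 0/0 (identical constant groups) is 0
  degenerate <- testable & !is.na(denom) & denom == 0
  d[degenerate] <- sign(diff[degenerate]) * Inf
  d[degenerate & diff == 0] <- 0
  d[!testable] <- NA_real_
  list(d = d, diff = diff, se = se, df = df, testable = testable)
}

#' S0-moderated two-sample t statistic
#'
#' The SAM-style moderated statistic
#' \eqn{d = (\bar{x}_{sorted} - \bar{x}_{lysate}) / (se + s_0)}, where
#' \eqn{se} is the pooled-variance standard error of the mean difference and
#' \eqn{s_0 \ge 0} damps the significance of low-variance, low-effect
#' features. With `s0 = 0` this is the classical pooled two-sample
#' t statistic. Antisymmetric under swapping the two groups.
#'
#' @param x_sorted,x_lysate numeric vectors of log2 intensities (each with
#'   at least 2 valid values).
#' @param s0 non-negative moderation constant on the log2 scale.
#' @return the moderated statistic (a single number). If both groups have
#'   zero variance and `s0 = 0`, returns `Inf` with the sign of the mean
#'   difference (0 when the means are equal too).
#' @export
moderated_t_statistic <- function(x_sorted, x_lysate, s0 = 0.1) {
  stopifnot(is_number(s0), s0 >= 0)
  x_sorted <- x_sorted[!is.na(x_sorted)]
  x_lysate <- x_lysate[!is.na(x_lysate)]
  if (length(x_sorted) < 2 || length(x_lysate) < 2) {
    stop("each group needs at least 2 valid values", call. = FALSE)
  }
  m <- matrix(c(x_sorted, x_lysate), nrow = 1)
  res <- .d_stats(m, seq_along(x_sorted), length(x_sorted) + seq_along(x_lysate),
                  s0 = s0)
  res$d[1]
}

# All distinct relabelings of the samples into pseudo-groups of the
# original sizes, excluding the identity labeling (which would reproduce
# every observed statistic and put a floor of 1/n_splits on the estimated
# FDR). For equal group sizes a split and its complement give the same
# |d|, so only splits containing the first column are kept.
.enumerate_splits <- function(idx_sorted, idx_lysate) {
  all_cols <- sort(c(idx_sorted, idx_lysate))
  n1 <- length(idx_sorted)
  comb <- utils::combn(all_cols, n1)
  keep <- rep(TRUE, ncol(comb))
  if (n1 == length(idx_lysate)) {
    keep <- comb[1, ] == all_cols[1]
  }
  comb <- comb[, keep, drop = FALSE]
  identity <- vapply(seq_len(ncol(comb)),
                     function(j) setequal(comb[, j], idx_sorted) ||
                       setequal(comb[, j], idx_lysate),
                     logical(1))
  comb[, !identity, drop = FALSE]
}

.sample_splits <- function(idx_sorted, idx_lysate, n_randomizations) {
  all_cols <- sort(c(idx_sorted, idx_lysate))
  n1 <- length(idx_sorted)
  out <- matrix(NA_integer_, n1, n_randomizations)
  for (j in seq_len(n_randomizations)) {
    repeat {
      s <- sort(sample(all_cols, n1))
      if (!setequal(s, idx_sorted) && !setequal(s, idx_lysate)) break
    }
    out[, j] <- s
  }
  out
}

#' Permutation-based FDR significance calls for a log2 LFQ table
#'
#' Computes the S0-moderated statistic for every testable protein and
#' estimates a global significance cutoff on `|d|` from relabelings of the
#' averaged biological-replicate samples into two pseudo-groups. For each
#' candidate cutoff `c` the false-discovery rate is estimated as the mean
#' number of null `|d| >= c` per relabeling divided by the number of
#' observed `|d| >= c`, capped at 1 and made monotone by a running minimum
#' from the least significant cutoff; proteins at or above the smallest
#' cutoff whose estimate is `<= fdr` are called significant.
#'
#' When the number of distinct non-identity relabelings does not exceed
#' `n_randomizations` (always the case for 3 vs 3 samples, which admit 9),
#' mode `"auto"` enumerates them exhaustively; otherwise it samples
#' `n_randomizations` relabelings with replacement, reproducibly under
#' `seed`.
#'
#' @param table a [protein_group_table()], technical replicates averaged and
#'   log2-transformed.
#' @param s0 moderation constant (default 0.1).
#' @param fdr target permutation FDR (default 0.01).
#' @param n_randomizations number of relabelings in sampling mode
#'   (default 250).
#' @param mode `"auto"`, `"exhaustive"` or `"sample"`.
#' @param min_valid_per_group minimum valid values per condition for a
#'   protein to be testable (default 2).
#' @param seed seed for sampling mode.
#' @return data frame with `protein_id`, `d_stat`, `q_value`, `testable`
#'   and `significant`; the `|d|` cutoff is attached as attribute
#'   `threshold` and the number of relabelings as `n_relabelings`.
#' @export
permutation_fdr_calls <- function(table, s0 = 0.1, fdr = 0.01,
                                  n_randomizations = 250,
                                  mode = c("auto", "exhaustive", "sample"),
                                  min_valid_per_group = 2L,
                                  seed = NULL) {
  stopifnot(inherits(table, "protein_group_table"))
  if (!table$log2_scale) stop("table must be log2-transformed", call. = FALSE)
  mode <- match.arg(mode)
  stopifnot(is_number(fdr), fdr > 0, fdr < 1, is_count(n_randomizations))
  idx_sorted <- which(table$design$condition == "sorted")
  idx_lysate <- which(table$design$condition == "lysate")
  if (length(idx_sorted) < 2 || length(idx_lysate) < 2) {
    stop("insufficient replication: need >= 2 samples per condition",
         call. = FALSE)
  }
  m <- table$intensities
  obs <- .d_stats(m, idx_sorted, idx_lysate, s0, min_valid_per_group)

  n_distinct <- choose(length(idx_sorted) + length(idx_lysate), length(idx_sorted))
  if (length(idx_sorted) == length(idx_lysate)) n_distinct <- n_distinct / 2
  n_distinct <- n_distinct - 1  # identity excluded
  use_exhaustive <- switch(mode,
    exhaustive = TRUE,
    sample = FALSE,
    auto = n_distinct <= n_randomizations && n_distinct <= 1e4)
  splits <- if (use_exhaustive) {
    .enumerate_splits(idx_sorted, idx_lysate)
  } else {
    with_seed(seed, .sample_splits(idx_sorted, idx_lysate, n_randomizations))
  }
  n_perm <- ncol(splits)
  all_cols <- sort(c(idx_sorted, idx_lysate))

  null_abs <- vector("list", n_perm)
  for (j in seq_len(n_perm)) {
    pseudo1 <- splits[, j]
    pseudo2 <- setdiff(all_cols, pseudo1)
    dj <- .d_stats(m, pseudo1, pseudo2, s0, min_valid_per_group)$d
    null_abs[[j]] <- abs(dj[!is.na(dj)])
  }
  null_sorted <- sort(unlist(null_abs))
  n_null <- length(null_sorted)

  abs_obs <- abs(obs$d)
  testable_idx <- which(obs$testable & !is.na(abs_obs))
  significant <- rep(FALSE, nrow(m))
  q_value <- rep(NA_real_, nrow(m))
  threshold <- Inf
  if (length(testable_idx)) {
    cutoffs <- sort(unique(abs_obs[testable_idx]), decreasing = TRUE)
    obs_sorted <- sort(abs_obs[testable_idx])
    n_obs <- length(obs_sorted)
    obs_ge <- n_obs - findInterval(cutoffs, obs_sorted, left.open = TRUE)
    null_ge <- n_null - findInterval(cutoffs, null_sorted, left.open = TRUE)
    fdp <- pmin(1, (null_ge / n_perm) / obs_ge)
    q <- rev(cummin(rev(fdp)))  # monotone: stricter cutoff never worse
    ok <- which(q <= fdr)
    if (length(ok)) {
      threshold <- cutoffs[max(ok)]
      significant[testable_idx] <- abs_obs[testable_idx] >= threshold
    }
    # per-protein q: the estimate at the protein's own |d| cutoff
    pos <- match(abs_obs[testable_idx], cutoffs)
    q_value[testable_idx] <- q[pos]
  }

  out <- data.frame(protein_id = table$protein_id,
                    d_stat = obs$d,
                    q_value = q_value,
                    testable = obs$testable,
                    significant = significant,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  attr(out, "n_relabelings") <- n_perm
  attr(out, "exhaustive") <- use_exhaustive
  out
}

#' Log2 fold change between conditions for one protein
#'
#' Mean of the sorted-condition log2 intensities minus the mean of the
#' lysate-condition log2 intensities, i.e. the log2 fold change
#' sorted / lysate.
#'
#' @param table a log2-scale [protein_group_table()].
#' @param protein protein id or row index.
#' @param min_valid_per_group minimum valid values required per condition.
#' @return the log2 fold change, or `NA` if the protein is not testable at
#'   the requested minimum.
#' @export
compute_log2_fc <- function(table, protein, min_valid_per_group = 2L) {
  stopifnot(inherits(table, "protein_group_table"))
  if (!table$log2_scale) stop("table must be log2-transformed", call. = FALSE)
  i <- if (is.character(protein)) match(protein, table$protein_id) else protein
  if (is.na(i)) stop("unknown protein: ", protein, call. = FALSE)
  x <- table$intensities[i, table$design$condition == "sorted"]
  y <- table$intensities[i, table$design$condition == "lysate"]
  if (sum(!is.na(x)) < min_valid_per_group || sum(!is.na(y)) < min_valid_per_group) {
    return(NA_real_)
  }
  mean(x, na.rm = TRUE) - mean(y, na.rm = TRUE)
}

#' Classify proteins from fold change and significance
#'
#' Assigns every protein to exactly one of `enriched` (significant, log2
#' fold change > 0), `depleted` (significant, < 0), `ns` (testable but not
#' significant) or `not_tested`.
#'
#' @param results data frame with columns `log2_fc`, `significant` and
#'   `testable`.
#' @return `results` with a `call` column added.
#' @export
classify_proteins <- function(results) {
  stopifnot(all(c("log2_fc", "significant", "testable") %in% names(results)))
  call <- rep("not_tested", nrow(results))
  call[results$testable] <- "ns"
  call[results$testable & results$significant & results$log2_fc > 0] <- "enriched"
  call[results$testable & results$significant & results$log2_fc < 0] <- "depleted"
  results$call <- factor(call, levels = c("enriched", "depleted", "ns", "not_tested"))
  results
}

#' Differential enrichment analysis of flow-sorted chromosome proteomes
#'
#' Full volcano-style analysis of an LFQ protein-group table comparing
#' flow-sorted mitotic chromosomes against total mitotic lysate pellet:
#' QC filtering (reverse decoys, contaminants, site-only identifications,
#' `>= min_peptides` razor + unique peptides), averaging of technical
#' replicates (mean of valid values), log2 transformation, the
#' S0-moderated t statistic with permutation-based FDR calls, a plain
#' two-sided Student t p-value for plotting, and the
#' enriched / depleted / ns / not_tested classification.
#'
#' @param table a [protein_group_table()]; raw-scale tables are filtered,
#'   averaged and log2-transformed internally, log2 tables are used as-is
#'   (no filtering).
#' @param s0 moderation constant (default 0.1).
#' @param fdr permutation FDR level (default 0.01).
#' @param n_randomizations relabelings for the permutation null
#'   (default 250).
#' @param mode permutation mode, see [permutation_fdr_calls()].
#' @param min_peptides razor + unique peptide filter (default 2).
#' @param min_valid_per_group minimum valid values per condition for
#'   testing (default 2).
#' @param seed seed for sampling-mode permutations.
#' @return an object of class `lfq_enrichment` with components `results`
#'   (per-protein data frame), `threshold` (the `|d|` cutoff), `counts`,
#'   `settings` and the processed log2 `table`. Methods: `print`,
#'   `summary`, `plot` (volcano), `coef` (named log2 fold changes),
#'   `as.data.frame`.
#' @examples
#' sim <- simulate_lfq_table(lfq_sim_config(n_proteins = 200, seed = 1))
#' fit <- lfq_enrichment(sim$table, seed = 1)
#' fit
#' table(as.data.frame(fit)$call)
#' @export
lfq_enrichment <- function(table, s0 = 0.1, fdr = 0.01,
                           n_randomizations = 250,
                           mode = c("auto", "exhaustive", "sample"),
                           min_peptides = 2L,
                           min_valid_per_group = 2L,
                           seed = NULL) {
  stopifnot(inherits(table, "protein_group_table"))
  mode <- match.arg(mode)
  n_input <- length(table$protein_id)
  if (!table$log2_scale) {
    table <- filter_protein_groups(table, min_peptides = min_peptides)
    if (length(table$protein_id) == 0) {
      stop("no protein groups left after filtering", call. = FALSE)
    }
    if (any(!is.na(table$design$tech))) {
      table <- average_technical_replicates(table)
    }
    table <- log2_transform_table(table)
  }
  n_filtered <- length(table$protein_id)

  idx_sorted <- which(table$design$condition == "sorted")
  idx_lysate <- which(table$design$condition == "lysate")
  m <- table$intensities
  obs0 <- .d_stats(m, idx_sorted, idx_lysate, s0 = 0, min_valid_per_group)
  log2_fc <- obs0$diff
  log2_fc[!obs0$testable] <- NA_real_

  # plain Student t (pooled variance) for the volcano y-axis
  t_plain <- obs0$d
  p_raw <- rep(NA_real_, n_filtered)
  ok <- obs0$testable & is.finite(t_plain)
  p_raw[ok] <- 2 * stats::pt(-abs(t_plain[ok]), df = obs0$df[ok])
  p_raw[obs0$testable & is.infinite(t_plain)] <- 0
  p_raw[obs0$testable & !is.finite(t_plain) & !is.infinite(t_plain)] <- NA_real_

  calls <- permutation_fdr_calls(table, s0 = s0, fdr = fdr,
                                 n_randomizations = n_randomizations,
                                 mode = mode,
                                 min_valid_per_group = min_valid_per_group,
                                 seed = seed)

  results <- data.frame(protein_id = table$protein_id,
                        gene_names = table$gene_names,
                        log2_fc = log2_fc,
                        d_stat = calls$d_stat,
                        p_raw = p_raw,
                        minus_log10_p = -log10(p_raw),
                        q_value = calls$q_value,
                        testable = calls$testable,
                        significant = calls$significant,
                        stringsAsFactors = FALSE)
  results <- classify_proteins(results)

  counts <- as.list(table(results$call))
  counts$input <- n_input
  counts$after_filter <- n_filtered
  counts$tested <- sum(results$testable)

  structure(
    list(results = results,
         threshold = attr(calls, "threshold"),
         counts = counts,
         settings = list(s0 = s0, fdr = fdr,
                         n_randomizations = n_randomizations,
                         mode = mode,
                         exhaustive = attr(calls, "exhaustive"),
                         n_relabelings = attr(calls, "n_relabelings"),
                         min_peptides = min_peptides,
                         min_valid_per_group = min_valid_per_group,
                         seed = seed),
         table = table),
    class = "lfq_enrichment")
}

#' @export
print.lfq_enrichment <- function(x, ...) {
  cat("LFQ enrichment analysis: sorted chromosomes vs mitotic lysate\n")
  cat(sprintf("  %d protein groups (%d after QC filter), %d tested\n",
              x$counts$input, x$counts$after_filter, x$counts$tested))
  cat(sprintf("  S0 = %g, permutation FDR <= %g (%d relabelings%s)\n",
              x$settings$s0, x$settings$fdr, x$settings$n_relabelings,
              if (isTRUE(x$settings$exhaustive)) ", exhaustive" else ""))
  cat(sprintf("  calls: %d enriched, %d depleted, %d ns, %d not tested\n",
              x$counts$enriched, x$counts$depleted, x$counts$ns,
              x$counts$not_tested))
  if (is.finite(x$threshold)) {
    cat(sprintf("  |d| cutoff: %.4g\n", x$threshold))
  } else {
    cat("  no |d| cutoff met the FDR target (no calls)\n")
  }
  invisible(x)
}

#' @export
summary.lfq_enrichment <- function(object, ...) {
  out <- list(counts = object$counts,
              threshold = object$threshold,
              settings = object$settings,
              top_enriched = utils::head(
                object$results[order(-object$results$d_stat), ], 10),
              top_depleted = utils::head(
                object$results[order(object$results$d_stat), ], 10))
  class(out) <- "summary.lfq_enrichment"
  out
}

#' @export
print.summary.lfq_enrichment <- function(x, ...) {
  cat(sprintf("Calls: %d enriched, %d depleted, %d ns, %d not tested\n",
              x$counts$enriched, x$counts$depleted, x$counts$ns,
              x$counts$not_tested))
  cat("Top enriched proteins (by d statistic):\n")
  print(x$top_enriched[, c("protein_id", "log2_fc", "d_stat", "call")],
        row.names = FALSE)
  cat("Top depleted proteins:\n")
  print(x$top_depleted[, c("protein_id", "log2_fc", "d_stat", "call")],
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.lfq_enrichment <- function(object, ...) {
  stats::setNames(object$results$log2_fc, object$results$protein_id)
}

#' @export
as.data.frame.lfq_enrichment <- function(x, ...) x$results

#' Volcano plot of an enrichment analysis
#'
#' Log2 fold change (sorted / lysate) against -log10 of the plain Student
#' t p-value, coloured by call (enriched red, depleted blue, ns grey).
#'
#' @param x an [lfq_enrichment()] fit.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lfq_enrichment <- function(x, ...) {
  r <- x$results[x$results$testable, ]
  cols <- c(enriched = "firebrick", depleted = "steelblue",
            ns = "grey50", not_tested = "grey80")
  graphics::plot(r$log2_fc, r$minus_log10_p,
                 col = cols[as.character(r$call)], pch = 16, cex = 0.5,
                 xlab = expression(Log[2] ~ "fold change (sorted / lysate)"),
                 ylab = expression(-Log[10] ~ italic(p)), ...)
  graphics::legend("topleft", legend = c("enriched", "depleted", "ns"),
                   col = cols[1:3], pch = 16, bty = "n")
  invisible(x)
}

#' Write per-protein enrichment results to CSV
#'
#' @param fit an [lfq_enrichment()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_results <- function(fit, path) {
  stopifnot(inherits(fit, "lfq_enrichment"))
  utils::write.csv(fit$results, path, row.names = FALSE)
  invisible(path)
}
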