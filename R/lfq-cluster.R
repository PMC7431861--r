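# Hierarchical clustering of differentially abundant proteins, with the
# k-means row-reduction preprocessing used by common proteomics heatmap
# workflows.

#' Configuration for hierarchical clustering of significant rows
#'
#' Defaults mirror the standard heatmap workflow for LFQ volcano follow-up:
#' rows are prefiltered to those with at least two valid values in at least
#' one condition and a significant plain two-sample t test (permutation FDR
#' 0.05, S0 = 0), z-scored, reduced by k-means (300 clusters, 10
#' iterations, 1 restart) and agglomerated with euclidean distance and
#' average linkage over both rows and columns.
#'
#' @param prefilter_fdr permutation FDR for the prefilter t test.
#' @param prefilter_s0 S0 for the prefilter t test (default 0).
#' @param min_valid_in_one_group minimum valid values required in at least
#'   one condition.
#' @param kmeans_k number of k-means centroids (`NULL` disables the
#'   k-means reduction).
#' @param kmeans_max_iter,kmeans_restarts k-means iteration cap and number
#'   of restarts.
#' @param n_randomizations relabelings for the prefilter permutation FDR.
#' @param seed seed for k-means initialisation and sampling-mode
#'   permutations.
#' @return a `cluster_config` list.
#' @export
cluster_config <- function(prefilter_fdr = 0.05,
                           prefilter_s0 = 0,
                           min_valid_in_one_group = 2L,
                           kmeans_k = 300L,
                           kmeans_max_iter = 10L,
                           kmeans_restarts = 1L,
                           n_randomizations = 250L,
                           seed = NULL) {
  errors <- character()
  errors <- check_that(errors, is_number(prefilter_fdr) &&
                         prefilter_fdr > 0 && prefilter_fdr < 1,
                       "prefilter_fdr must be in (0,1)")
  errors <- check_that(errors, is_number(prefilter_s0) && prefilter_s0 >= 0,
                       "prefilter_s0 must be non-negative")
  errors <- check_that(errors, is.null(kmeans_k) || is_count(kmeans_k, 2L),
                       "kmeans_k must be NULL or >= 2")
  errors <- check_that(errors, is_count(kmeans_max_iter),
                       "kmeans_max_iter must be a positive count")
  errors <- check_that(errors, is_count(kmeans_restarts),
                       "kmeans_restarts must be a positive count")
  stop_if_errors(errors, "invalid cluster_config")
  structure(list(prefilter_fdr = prefilter_fdr, prefilter_s0 = prefilter_s0,
                 min_valid_in_one_group = as.integer(min_valid_in_one_group),
                 kmeans_k = if (is.null(kmeans_k)) NULL else as.integer(kmeans_k),
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 n_randomizations = as.integer(n_randomizations),
                 seed = seed),
            class = "cluster_config")
}

# Z-score a row over its valid values; population (divide-by-n) convention,
# fixed for testability. Constant rows map to 0.
.zscore_row <- function(x) {
  v <- !is.na(x)
  mu <- mean(x[v])
  sd_pop <- sqrt(mean((x[v] - mu)^2))
  if (!is.finite(sd_pop) || sd_pop == 0) {
    x[v] <- 0
  } else {
    x[v] <- (x[v] - mu) / sd_pop
  }
  x
}

#' Cluster differentially abundant rows of a log2 LFQ table
#'
#' Prefilters rows to those with at least `min_valid_in_one_group` valid
#' values in one condition and a significant two-sample t test under
#' permutation FDR (`prefilter_fdr`, `prefilter_s0`), z-scores each
#' retained row (population SD over its valid values; remaining missing
#' values are set to 0, the row mean, for distance computations), reduces
#' rows to at most `kmeans_k` k-means centroids, and builds average-linkage
#' euclidean dendrograms over the (reduced) rows and over the columns.
#'
#' @param table a log2-scale, technical-replicate-averaged
#'   [protein_group_table()].
#' @param config a [cluster_config()].
#' @return a list of class `lfq_hca`: `row_tree` and `col_tree`
#'   ([stats::hclust] objects), `assignments` (data frame mapping each
#'   retained protein to its k-means cluster), `z` (the z-scored matrix)
#'   and `centroids`.
#' @export
cluster_significant_rows <- function(table, config = cluster_config()) {
  stopifnot(inherits(table, "protein_group_table"),
            inherits(config, "cluster_config"))
  if (!table$log2_scale) stop("table must be log2-transformed", call. = FALSE)
  m <- table$intensities
  cond <- table$design$condition
  nv_sorted <- rowSums(!is.na(m[, cond == "sorted", drop = FALSE]))
  nv_lysate <- rowSums(!is.na(m[, cond == "lysate", drop = FALSE]))
  keep <- pmax(nv_sorted, nv_lysate) >= config$min_valid_in_one_group
  sub <- subset_rows(table, which(keep))

  calls <- permutation_fdr_calls(sub, s0 = config$prefilter_s0,
                                 fdr = config$prefilter_fdr,
                                 n_randomizations = config$n_randomizations,
                                 seed = config$seed)
  sig <- subset_rows(sub, which(calls$significant))
  n_sig <- length(sig$protein_id)
  if (n_sig < 2) {
    stop("fewer than 2 rows survive the significance prefilter", call. = FALSE)
  }

  z <- t(apply(sig$intensities, 1, .zscore_row))
  rownames(z) <- sig$protein_id
  z_imp <- z
  z_imp[is.na(z_imp)] <- 0

  if (!is.null(config$kmeans_k) && n_sig > config$kmeans_k) {
    km <- with_seed(config$seed,
                    stats::kmeans(z_imp, centers = config$kmeans_k,
                                  iter.max = config$kmeans_max_iter,
                                  nstart = config$kmeans_restarts))
    centroids <- km$centers
    cluster <- km$cluster
  } else {
    centroids <- z_imp
    cluster <- seq_len(n_sig)
  }
  row_tree <- stats::hclust(stats::dist(centroids, method = "euclidean"),
                            method = "average")
  col_tree <- stats::hclust(stats::dist(t(z_imp), method = "euclidean"),
                            method = "average")

  structure(
    list(row_tree = row_tree, col_tree = col_tree,
         assignments = data.frame(protein_id = sig$protein_id,
                                  cluster = cluster,
                                  stringsAsFactors = FALSE),
         z = z, centroids = centroids,
         n_significant = n_sig, config = config),
    class = "lfq_hca")
}

#' @export
print.lfq_hca <- function(x, ...) {
  cat("Hierarchical clustering of differentially abundant proteins\n")
  cat(sprintf("  %d significant rows, %d row centroids, %d columns\n",
              x$n_significant, nrow(x$centroids), ncol(x$z)))
  invisible(x)
}
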