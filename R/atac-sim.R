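# Synthetic ATAC-seq read sets: uniform background insertions plus peaks
# whose accessibility is retained or lost between conditions, emitted as
# BED6 read records from which the analysis stage must recover the planted
# insertion centres.

#' Peak table for the ATAC simulator
#'
#' Builds the peak specification consumed by [atac_sim_config()]: each peak
#' has a summit, a half-width, a bookmarking class and one fold-accessibility
#' per condition. `retained` peaks keep their fold in the second condition;
#' `lost` peaks revert to background (fold 1).
#'
#' @param chrom chromosome name(s).
#' @param summit summit position(s), 0-based bp.
#' @param half_width peak half-width(s), bp.
#' @param class `"retained"` or `"lost"` per peak.
#' @param fold fold-accessibility over background in the first condition.
#' @param conditions length-2 character vector naming the conditions.
#' @return data frame with one row per peak and `fold.<condition>` columns.
#' @export
atac_peaks <- function(chrom, summit, half_width, class, fold = 4,
                       conditions = c("asynchronous", "mitotic")) {
  stopifnot(all(class %in% c("retained", "lost")), length(conditions) == 2)
  out <- data.frame(chrom = chrom, summit = as.integer(summit),
                    half_width = as.integer(half_width),
                    class = class, stringsAsFactors = FALSE)
  out[[paste0("fold.", conditions[1])]] <- fold
  out[[paste0("fold.", conditions[2])]] <- ifelse(class == "retained", fold, 1)
  out
}

#' Configuration for the ATAC read simulator
#'
#' Background insertion centres are uniform over each chromosome at
#' `background_rate` insertions per bp; peaks add (or, for folds below 1,
#' thin) insertions around their summits with a triangular density over
#' `summit +/- half_width`, scaled so the local density is approximately
#' `fold` times background. Each insertion centre is emitted as one
#' fixed-length read whose 5' end encodes the centre under the Tn5
#' +4/-5 bp offset convention.
#'
#' @param chrom_sizes named integer vector mapping chromosome to length bp.
#' @param background_rate insertions per bp (default 0.005, i.e. an
#'   expected 125 insertions per 25 kb window).
#' @param peaks peak table from [atac_peaks()], or `NULL` for a
#'   background-only simulation.
#' @param read_length read length in bp (default 75).
#' @param frac_minus_strand proportion of reads on the minus strand.
#' @param conditions condition names; must match the peak table's fold
#'   columns.
#' @param seed integer seed.
#' @return an `atac_sim_config` list.
#' @export
atac_sim_config <- function(chrom_sizes,
                            background_rate = 0.005,
                            peaks = NULL,
                            read_length = 75L,
                            frac_minus_strand = 0.5,
                            conditions = c("asynchronous", "mitotic"),
                            seed = NULL) {
  errors <- character()
  errors <- check_that(errors,
                       length(chrom_sizes) > 0 && !is.null(names(chrom_sizes)) &&
                         all(nzchar(names(chrom_sizes))),
                       "chrom_sizes must be a non-empty named vector")
  errors <- check_that(errors, all(chrom_sizes > 0),
                       "chromosome lengths must be positive")
  errors <- check_that(errors, is_number(background_rate) && background_rate >= 0,
                       "background_rate must be non-negative")
  errors <- check_that(errors, is_count(read_length),
                       "read_length must be a positive count")
  errors <- check_that(errors, is_proportion(frac_minus_strand),
                       "frac_minus_strand must be in [0,1]")
  if (!is.null(peaks)) {
    errors <- check_that(errors,
                         all(peaks$chrom %in% names(chrom_sizes)),
                         "peak chromosomes must appear in chrom_sizes")
    fold_cols <- paste0("fold.", conditions)
    errors <- check_that(errors, all(fold_cols %in% names(peaks)),
                         "peaks must carry one fold.<condition> column per condition")
    if (all(peaks$chrom %in% names(chrom_sizes))) {
      len <- chrom_sizes[peaks$chrom]
      errors <- check_that(errors,
                           all(peaks$summit - peaks$half_width >= 0) &&
                             all(peaks$summit + peaks$half_width <= len),
                           "summit +/- half_width must lie within chromosome bounds")
    }
    if (all(fold_cols %in% names(peaks))) {
      errors <- check_that(errors,
                           all(as.matrix(peaks[, fold_cols]) >= 0),
                           "fold-accessibility values must be non-negative")
    }
  }
  stop_if_errors(errors, "invalid atac_sim_config")
  structure(list(chrom_sizes = stats::setNames(as.integer(chrom_sizes),
                                               names(chrom_sizes)),
                 background_rate = background_rate, peaks = peaks,
                 read_length = as.integer(read_length),
                 frac_minus_strand = frac_minus_strand,
                 conditions = conditions, seed = seed),
            class = "atac_sim_config")
}

# Turn insertion centres into BED6 read records under the +4/-5 convention:
# a + read's corrected centre is start + 4, a - read's is (end - 1) - 5.
.centers_to_reads <- function(chrom, centers, config) {
  n <- length(centers)
  if (!n) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  minus <- stats::runif(n) < config$frac_minus_strand
  start <- ifelse(minus, centers + 6L - config$read_length, centers - 4L)
  end <- start + config$read_length
  len <- config$chrom_sizes[[chrom]]
  ok <- start >= 0 & end <= len
  data.frame(chrom = chrom, start = as.integer(start[ok]),
             end = as.integer(end[ok]),
             name = ".", score = 0L,
             strand = ifelse(minus[ok], "-", "+"),
             stringsAsFactors = FALSE)
}

#' Simulate ATAC-seq read sets with planted peaks
#'
#' @param config an [atac_sim_config()].
#' @return list with `reads` (named list of sorted BED6-style data frames,
#'   one per condition) and `truth` (the peak table plus the realised
#'   background rate), reproducible under the configured seed.
#' @export
simulate_atac_reads <- function(config) {
  stopifnot(inherits(config, "atac_sim_config"))
  with_seed(config$seed, {
    reads <- stats::setNames(vector("list", length(config$conditions)),
                             config$conditions)
    for (cond in config$conditions) {
      per_chrom <- lapply(names(config$chrom_sizes), function(chrom) {
        len <- config$chrom_sizes[[chrom]]
        n_bg <- stats::rpois(1, config$background_rate * len)
        centers <- if (n_bg > 0) {
          as.integer(floor(stats::runif(n_bg, 0, len)))
        } else {
          integer(0)
        }
        pk <- config$peaks
        if (!is.null(pk)) {
          pk <- pk[pk$chrom == chrom, , drop = FALSE]
          fold_col <- paste0("fold.", cond)
          for (i in seq_len(nrow(pk))) {
            fold <- pk[[fold_col]][i]
            s <- pk$summit[i]; hw <- pk$half_width[i]
            if (fold < 1) {
              in_peak <- centers >= s - hw & centers < s + hw
              drop <- in_peak & stats::runif(length(centers)) >= fold
              centers <- centers[!drop]
            } else if (fold > 1) {
              lambda <- (fold - 1) * config$background_rate * 2 * hw
              n_extra <- stats::rpois(1, lambda)
              if (n_extra > 0) {
                off <- round(hw * (stats::runif(n_extra) + stats::runif(n_extra) - 1))
                extra <- pmin(pmax(s + off, 0L), len - 1L)
                centers <- c(centers, as.integer(extra))
              }
            }
          }
        }
        .centers_to_reads(chrom, centers, config)
      })
      bed <- do.call(rbind, per_chrom)
      bed <- bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
      if (nrow(bed)) bed$name <- sprintf("read_%07d", seq_len(nrow(bed)))
      rownames(bed) <- NULL
      reads[[cond]] <- bed
    }
    list(reads = reads,
         truth = list(peaks = config$peaks,
                      background_rate = config$background_rate,
                      conditions = config$conditions))
  })
}

#' Read and write BED6 read records and chrom.sizes files
#'
#' Plain-text helpers for the module's interchange formats: 6-column BED
#' (chrom, start, end, name, score, strand; 0-based half-open) and
#' two-column chrom.sizes tables.
#'
#' @param path file path.
#' @return `read_bed6()` returns a data frame with the six BED columns;
#'   `read_chrom_sizes()` a named integer vector.
#' @export
read_bed6 <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end",
                                         "name", "score", "strand"))
  bed$start <- as.integer(bed$start)
  bed$end <- as.integer(bed$end)
  bed
}

#' @rdname read_bed6
#' @param bed data frame with columns chrom, start, end, name, score, strand.
#' @export
write_bed6 <- function(bed, path) {
  utils::write.table(bed[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_bed6
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, stringsAsFactors = FALSE,
                           col.names = c("chrom", "size"))
  stats::setNames(as.integer(tab$size), tab$chrom)
}

#' Read a summit BED file with bookmarking classes
#'
#' Summits are single positions (3-column BED, optionally with the class
#' in the name field, e.g. `"retained"` / `"lost"`).
#'
#' @param path BED file path.
#' @return data frame with `chrom`, `pos` and `class`.
#' @export
read_summits <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  out <- data.frame(chrom = tab[[1]], pos = as.integer(tab[[2]]),
                    stringsAsFactors = FALSE)
  out$class <- if (ncol(tab) >= 4) as.character(tab[[4]]) else "all"
  out
}
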