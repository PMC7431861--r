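# ATAC-seq accessibility transforms: Tn5 insertion-centre extraction,
# windowed log2 enrichment tracks and summit-centred trend profiles.

#' Extract Tn5 insertion centres from aligned reads
#'
#' Applies the standard Tn5 offset correction to the 5' end of every read:
#' plus-strand insertions at `start + 4`, minus-strand insertions at
#' `(end - 1) - 5` (0-based coordinates; the minus-strand 5' end is
#' `end - 1`). Records with unknown strand are skipped with a warning;
#' when `chrom_sizes` is supplied, offset positions falling outside the
#' chromosome are dropped and counted.
#'
#' @param reads data frame with columns `chrom`, `start`, `end`, `strand`
#'   (BED6-style, 0-based half-open).
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   bounds checking.
#' @return data frame of insertion sites (`chrom`, `pos`) with attributes
#'   `n_dropped_strand` and `n_dropped_bounds`.
#' @export
extract_insertion_centers <- function(reads, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  known <- reads$strand %in% c("+", "-")
  n_bad_strand <- sum(!known)
  if (n_bad_strand > 0) {
    warning(n_bad_strand, " read(s) with unknown strand skipped")
  }
  r <- reads[known, , drop = FALSE]
  pos <- ifelse(r$strand == "+", r$start + 4L, (r$end - 1L) - 5L)
  sites <- data.frame(chrom = r$chrom, pos = as.integer(pos),
                      stringsAsFactors = FALSE)
  n_oob <- 0L
  if (!is.null(chrom_sizes)) {
    len <- chrom_sizes[sites$chrom]
    ok <- !is.na(len) & sites$pos >= 0 & sites$pos < len
    n_oob <- sum(!ok)
    sites <- sites[ok, , drop = FALSE]
  } else {
    ok <- sites$pos >= 0
    n_oob <- sum(!ok)
    sites <- sites[ok, , drop = FALSE]
  }
  rownames(sites) <- NULL
  attr(sites, "n_dropped_strand") <- n_bad_strand
  attr(sites, "n_dropped_bounds") <- n_oob
  sites
}

#' Windowed log2 accessibility enrichment track
#'
#' Tiles every chromosome with non-overlapping windows (25 kb by default;
#' the final partial window keeps its true length), counts insertion sites
#' per window, and reports the log2 ratio of the count to the genome-wide
#' expectation (total sites scaled by window length / genome length).
#' Zero-count windows use a pseudocount of 0.5 before the log so the track
#' stays finite; counts themselves are unchanged, so window counts always
#' sum to the number of sites.
#'
#' @param sites insertion sites from [extract_insertion_centers()].
#' @param chrom_sizes named vector of chromosome lengths.
#' @param window_size window width in bp (default 25000).
#' @param pseudocount value replacing zero counts inside the log
#'   (default 0.5).
#' @return data frame of class `enrichment_track` with columns `chrom`,
#'   `start`, `end`, `count`, `expected`, `log2_enrichment`.
#' @export
windowed_log2_enrichment <- function(sites, chrom_sizes,
                                     window_size = 25000L,
                                     pseudocount = 0.5) {
  stopifnot(is_count(window_size), length(chrom_sizes) > 0)
  total_sites <- nrow(sites)
  genome_length <- sum(as.numeric(chrom_sizes))
  if (total_sites == 0) {
    warning("no insertion sites; enrichment track is all-missing")
  }
  out <- lapply(names(chrom_sizes), function(chrom) {
    len <- chrom_sizes[[chrom]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    ends <- pmin(starts + window_size, len)
    pos <- sites$pos[sites$chrom == chrom]
    counts <- tabulate(pos %/% window_size + 1L, nbins = length(starts))
    expected <- total_sites * (ends - starts) / genome_length
    log2e <- ifelse(expected > 0,
                    log2(ifelse(counts == 0, pseudocount, counts) / expected),
                    NA_real_)
    data.frame(chrom = chrom, start = starts, end = ends,
               count = counts, expected = expected,
               log2_enrichment = log2e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "window_size") <- as.integer(window_size)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("enrichment_track", "data.frame")
  out
}

#' Write an enrichment track as bedGraph
#'
#' One line per window carrying the log2 enrichment value; the pseudocount
#' convention is recorded in a track comment line.
#'
#' @param track an [windowed_log2_enrichment()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# log2 insertion-site enrichment; window=%d bp; zero-count pseudocount=%g",
                     attr(track, "window_size"), attr(track, "pseudocount")), con)
  utils::write.table(track[, c("chrom", "start", "end", "log2_enrichment")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summit-centred accessibility trend profiles by peak class
#'
#' Extends every insertion site by `extend_bp` on both sides (the standard
#' +/-25 bp smoothing), accumulates the per-bp coverage of these intervals
#' across a `span_bp` window centred on every summit, averages within
#' summits of the same class, bins the result, and normalises each class
#' profile to a mean relative density of 1.
#'
#' @param sites insertion sites from [extract_insertion_centers()].
#' @param summits data frame with `chrom`, `pos` and `class` (see
#'   [read_summits()]).
#' @param extend_bp half-width of the site extension (default 25).
#' @param span_bp total profile span centred on the summit (default 2000);
#'   must be an even multiple of `bin_bp`.
#' @param bin_bp bin width (default 10).
#' @return data frame of class `trend_profile` with columns `class`,
#'   `offset` (bin centre relative to the summit) and `rel_density`.
#'   Classes with zero summits are absent, with a warning.
#' @export
summit_trend_profile <- function(sites, summits, extend_bp = 25L,
                                 span_bp = 2000L, bin_bp = 10L) {
  stopifnot(all(c("chrom", "pos", "class") %in% names(summits)),
            is_count(extend_bp, 0L), is_count(span_bp), is_count(bin_bp))
  if (span_bp %% (2L * bin_bp) != 0) {
    stop("span_bp must be an even multiple of bin_bp", call. = FALSE)
  }
  half <- span_bp %/% 2L
  n_bins <- span_bp %/% bin_bp

  # per-chromosome sorted site positions for fast range lookup
  by_chrom <- split(sites$pos, sites$chrom)
  by_chrom <- lapply(by_chrom, sort)

  classes <- unique(summits$class)
  profiles <- list()
  for (cl in classes) {
    s <- summits[summits$class == cl, , drop = FALSE]
    if (nrow(s) == 0) {
      warning("no summits for class '", cl, "'")
      next
    }
    cov <- numeric(span_bp)  # coverage at offsets -half .. half-1
    for (i in seq_len(nrow(s))) {
      pos <- by_chrom[[s$chrom[i]]]
      if (is.null(pos)) next
      lo <- s$pos[i] - half - extend_bp
      hi <- s$pos[i] + half + extend_bp
      i0 <- findInterval(lo - 1L, pos) + 1L
      i1 <- findInterval(hi, pos)
      if (i1 < i0) next
      rel <- pos[i0:i1] - s$pos[i]
      a <- pmax(rel - extend_bp, -half) + half + 1L  # 1-based into cov
      b <- pmin(rel + extend_bp, half - 1L) + half + 1L
      ok <- b >= a
      if (!any(ok)) next
      # difference-array accumulation of interval coverage
      d <- numeric(span_bp + 1L)
      for (k in which(ok)) {
        d[a[k]] <- d[a[k]] + 1
        d[b[k] + 1L] <- d[b[k] + 1L] - 1
      }
      cov <- cov + cumsum(d[seq_len(span_bp)])
    }
    cov <- cov / nrow(s)
    binned <- colMeans(matrix(cov, nrow = bin_bp))
    rel_density <- if (mean(binned) > 0) binned / mean(binned) else binned
    offsets <- -half + (seq_len(n_bins) - 0.5) * bin_bp
    profiles[[cl]] <- data.frame(class = cl, offset = offsets,
                                 rel_density = rel_density,
                                 stringsAsFactors = FALSE)
  }
  if (!length(profiles)) {
    stop("no classes with summits", call. = FALSE)
  }
  out <- do.call(rbind, profiles)
  rownames(out) <- NULL
  attr(out, "extend_bp") <- as.integer(extend_bp)
  attr(out, "bin_bp") <- as.integer(bin_bp)
  attr(out, "span_bp") <- as.integer(span_bp)
  class(out) <- c("trend_profile", "data.frame")
  out
}

#' Plot summit-centred trend profiles
#'
#' @param x a [summit_trend_profile()] result.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.trend_profile <- function(x, ...) {
  classes <- unique(x$class)
  offs <- sort(unique(x$offset))
  m <- sapply(classes, function(cl) {
    x$rel_density[x$class == cl][order(x$offset[x$class == cl])]
  })
  graphics::matplot(offs, m, type = "l", lty = 1,
                    xlab = "distance from summit (bp)",
                    ylab = "relative insertion density", ...)
  graphics::legend("topright", legend = classes,
                   col = seq_along(classes), lty = 1, bty = "n")
  invisible(x)
}

#' Write trend profiles as CSV
#'
#' @param profile a [summit_trend_profile()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trend_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
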