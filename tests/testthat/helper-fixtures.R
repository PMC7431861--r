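# Shared fixtures and independent oracles for the test suite.

# Build a log2-scale table directly from a matrix (cols: B lysate then B
# sorted averaged samples) for testing the statistics without the IO layer.
make_log_table <- function(m, n_bio = ncol(m) / 2) {
  design <- data.frame(
    column = c(sprintf("lysate_%d", seq_len(n_bio)),
               sprintf("sorted_%d", seq_len(n_bio))),
    condition = rep(c("lysate", "sorted"), each = n_bio),
    bio = rep(seq_len(n_bio), 2),
    tech = NA_integer_,
    stringsAsFactors = FALSE)
  protein_group_table(
    protein_id = sprintf("P%03d", seq_len(nrow(m))),
    intensities = m, design = design, log2_scale = TRUE)
}

# Swap the condition labels of a table (for antisymmetry checks).
swap_conditions <- function(table) {
  table$design$condition <- ifelse(table$design$condition == "sorted",
                                   "lysate", "sorted")
  table
}

# Textbook pooled-variance two-sample t statistic and two-sided p.
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# Naive O(n^3) average-linkage agglomeration; returns merge heights.
oracle_average_linkage_heights <- function(x) {
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Minimal MaxQuant-dialect fixture file; returns its path.
write_lfq_fixture <- function(dir = tempdir()) {
  path <- file.path(dir, "proteinGroups_fixture.txt")
  header <- paste(c("Protein IDs", "Gene names", "Reverse",
                    "Potential contaminant", "Only identified by site",
                    "Razor + unique peptides",
                    "LFQ intensity lysate_1_1", "LFQ intensity sorted_1_1"),
                  collapse = "\t")
  rows <- c(
    paste(c("P1", "GeneA", "", "", "", "5", "1000", "2000"), collapse = "\t"),
    paste(c("P2", "GeneB", "+", "", "", "3", "1500", "0"), collapse = "\t"),
    paste(c("P3", "GeneC", "", "", "", "1", "0", "800"), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

fixture_column_map <- function() {
  data.frame(column = c("LFQ intensity lysate_1_1", "LFQ intensity sorted_1_1"),
             condition = c("lysate", "sorted"),
             bio = c(1L, 1L), tech = c(1L, 1L),
             stringsAsFactors = FALSE)
}
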