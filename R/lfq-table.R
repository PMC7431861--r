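#' Protein-group intensity tables
#'
#' A `protein_group_table` holds label-free quantification (LFQ) intensities
#' for protein groups across runs of a two-condition design
#' (`lysate` = mitotic lysate pellet, `sorted` = flow-sorted chromosomes),
#' together with the MaxQuant-style quality flags used for filtering.
#' Intensities are stored as a numeric matrix with one column per run and
#' `NA` for missing values; the `design` data frame maps every column to its
#' (condition, biological replicate, technical replicate) coordinates.
#'
#' @param protein_id character vector of unique protein-group identifiers.
#' @param intensities numeric matrix, rows = protein groups, columns = runs;
#'   missing values as `NA`, valid values must be non-negative.
#' @param design data frame with columns `column`, `condition`
#'   (`"lysate"`/`"sorted"`), `bio` and `tech` (integer), one row per
#'   intensity column, in column order. `tech` may be `NA` after technical
#'   replicates have been averaged.
#' @param gene_names optional character vector of gene names.
#' @param is_reverse,is_contaminant,only_identified_by_site logical QC flags,
#'   one per row (reverse decoy hit, potential contaminant, identified only
#'   by a modification site).
#' @param razor_unique_peptides integer count of razor + unique peptides per
#'   protein group.
#' @param log2_scale logical; `TRUE` once intensities are on the log2 scale.
#' @return an object of class `protein_group_table`.
#' @seealso [read_protein_group_table()], [filter_protein_groups()],
#'   [average_technical_replicates()], [log2_transform_table()]
#' @export
protein_group_table <- function(protein_id, intensities, design,
                                gene_names = protein_id,
                                is_reverse = FALSE,
                                is_contaminant = FALSE,
                                only_identified_by_site = FALSE,
                                razor_unique_peptides = NA_integer_,
                                log2_scale = FALSE) {
  n <- length(protein_id)
  intensities <- as.matrix(intensities)
  errors <- character()
  errors <- check_that(errors, n > 0, "table must contain at least one row")
  errors <- check_that(errors, !anyDuplicated(protein_id),
                       "duplicate protein ids")
  errors <- check_that(errors, nrow(intensities) == n,
                       "intensity matrix rows must match protein ids")
  errors <- check_that(errors,
                       all(c("column", "condition", "bio", "tech") %in% names(design)),
                       "design needs columns: column, condition, bio, tech")
  errors <- check_that(errors, nrow(design) == ncol(intensities),
                       "design rows must match intensity columns")
  errors <- check_that(errors, !anyDuplicated(design$column),
                       "duplicated design columns")
  errors <- check_that(errors, all(design$condition %in% c("lysate", "sorted")),
                       "condition must be 'lysate' or 'sorted'")
  if (!log2_scale) {
    errors <- check_that(errors, all(is.na(intensities) | intensities >= 0),
                         "raw intensities must be missing or non-negative")
  }
  stop_if_errors(errors, "invalid protein_group_table")

  recycle <- function(x) {
    if (length(x) == 1L) rep(x, n) else x
  }
  colnames(intensities) <- design$column
  structure(
    list(
      protein_id = as.character(protein_id),
      gene_names = recycle(as.character(gene_names)),
      intensities = intensities,
      design = design,
      is_reverse = recycle(as.logical(is_reverse)),
      is_contaminant = recycle(as.logical(is_contaminant)),
      only_identified_by_site = recycle(as.logical(only_identified_by_site)),
      razor_unique_peptides = recycle(as.integer(razor_unique_peptides)),
      log2_scale = isTRUE(log2_scale)
    ),
    class = "protein_group_table"
  )
}

#' @export
print.protein_group_table <- function(x, ...) {
  cat("Protein-group table:", length(x$protein_id), "protein groups,",
      ncol(x$intensities), "intensity columns\n")
  tab <- table(x$design$condition)
  cat("  columns per condition:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  scale:", if (x$log2_scale) "log2" else "raw intensity", "\n")
  cat("  missing values:", sum(is.na(x$intensities)), "\n")
  invisible(x)
}

#' @export
dim.protein_group_table <- function(x) dim(x$intensities)

# Row subset preserving all parallel fields.
subset_rows <- function(table, keep) {
  table$protein_id <- table$protein_id[keep]
  table$gene_names <- table$gene_names[keep]
  table$intensities <- table$intensities[keep, , drop = FALSE]
  table$is_reverse <- table$is_reverse[keep]
  table$is_contaminant <- table$is_contaminant[keep]
  table$only_identified_by_site <- table$only_identified_by_site[keep]
  table$razor_unique_peptides <- table$razor_unique_peptides[keep]
  table
}

#' Read a MaxQuant-style protein-group table
#'
#' Reads a tab-separated protein-group file (a `proteinGroups.txt`-dialect
#' subset) together with a column map assigning every LFQ intensity column to
#' its (condition, biological replicate, technical replicate) coordinates.
#' Intensity cells equal to zero are converted to missing (`NA`), matching
#' the convention that zero LFQ intensity means "not quantified". QC flag
#' columns use the MaxQuant `"+"` marker convention.
#'
#' @param path path to the tab-separated table. Expected columns:
#'   `Protein IDs`, optionally `Gene names`, `Reverse`,
#'   `Potential contaminant`, `Only identified by site`,
#'   `Razor + unique peptides`, and the intensity columns named in
#'   `column_map`.
#' @param column_map a data frame (or path to a CSV) with columns `column`,
#'   `condition`, `bio`, `tech`.
#' @return a [protein_group_table()].
#' @export
read_protein_group_table <- function(path, column_map) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(column_map)) {
    column_map <- utils::read.csv(column_map, stringsAsFactors = FALSE)
  }
  errors <- character()
  errors <- check_that(errors,
                       all(c("column", "condition", "bio", "tech") %in% names(column_map)),
                       "column map needs columns: column, condition, bio, tech")
  stop_if_errors(errors, "invalid column map")

  raw <- tryCatch(
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse protein-group table: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0L || ncol(raw) == 0L) {
    stop("protein-group table is empty: ", path, call. = FALSE)
  }
  missing_cols <- setdiff(column_map$column, names(raw))
  if (length(missing_cols)) {
    stop("intensity columns in column map not present in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  id_col <- if ("Protein IDs" %in% names(raw)) "Protein IDs" else names(raw)[1]
  ids <- as.character(raw[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids in table", call. = FALSE)
  }

  m <- as.matrix(raw[, column_map$column, drop = FALSE])
  storage.mode(m) <- "double"
  m[m == 0] <- NA_real_  # zero LFQ intensity = not quantified

  flag <- function(name) {
    if (name %in% names(raw)) trimws(as.character(raw[[name]])) == "+" else rep(FALSE, nrow(raw))
  }
  peptides <- if ("Razor + unique peptides" %in% names(raw)) {
    as.integer(raw[["Razor + unique peptides"]])
  } else {
    rep(NA_integer_, nrow(raw))
  }
  genes <- if ("Gene names" %in% names(raw)) as.character(raw[["Gene names"]]) else ids

  protein_group_table(
    protein_id = ids,
    gene_names = genes,
    intensities = m,
    design = data.frame(column = column_map$column,
                        condition = column_map$condition,
                        bio = as.integer(column_map$bio),
                        tech = as.integer(column_map$tech),
                        stringsAsFactors = FALSE),
    is_reverse = flag("Reverse"),
    is_contaminant = flag("Potential contaminant"),
    only_identified_by_site = flag("Only identified by site"),
    razor_unique_peptides = peptides
  )
}

#' Write a protein-group table and its column map to disk
#'
#' Emits the tab-separated dialect read back by
#' [read_protein_group_table()]: missing intensities are written as `0`,
#' flags as `"+"`/empty.
#'
#' @param table a [protein_group_table()] on the raw intensity scale.
#' @param path output path for the tab-separated table.
#' @param column_map_path optional output path for the column-map CSV.
#' @return `path`, invisibly.
#' @export
write_protein_group_table <- function(table, path, column_map_path = NULL) {
  stopifnot(inherits(table, "protein_group_table"))
  if (table$log2_scale) {
    stop("write_protein_group_table expects raw-scale intensities", call. = FALSE)
  }
  m <- table$intensities
  m[is.na(m)] <- 0
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    `Protein IDs` = table$protein_id,
                    `Gene names` = table$gene_names)
  out[["Reverse"]] <- ifelse(table$is_reverse, "+", "")
  out[["Potential contaminant"]] <- ifelse(table$is_contaminant, "+", "")
  out[["Only identified by site"]] <- ifelse(table$only_identified_by_site, "+", "")
  out[["Razor + unique peptides"]] <- table$razor_unique_peptides
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(column_map_path)) {
    utils::write.csv(table$design, column_map_path, row.names = FALSE)
  }
  invisible(path)
}

#' Remove decoy, contaminant, site-only and low-evidence protein groups
#'
#' Drops rows with any QC flag set (reverse decoy hits, potential
#' contaminants, groups only identified by a modification site) and, when
#' `min_peptides > 0`, rows identified by fewer than `min_peptides`
#' razor + unique peptides. Row order is otherwise preserved; an empty
#' result is permitted.
#'
#' @param table a [protein_group_table()].
#' @param min_peptides minimum razor + unique peptide count (default 2);
#'   use 0 to disable the peptide rule.
#' @return the filtered table.
#' @export
filter_protein_groups <- function(table, min_peptides = 2L) {
  stopifnot(inherits(table, "protein_group_table"))
  keep <- !(table$is_reverse | table$is_contaminant | table$only_identified_by_site)
  if (min_peptides > 0) {
    pep_ok <- !is.na(table$razor_unique_peptides) &
      table$razor_unique_peptides >= min_peptides
    keep <- keep & pep_ok
  }
  subset_rows(table, which(keep))
}

#' Average technical replicates within each biological replicate
#'
#' Collapses the intensity matrix to one column per (condition, biological
#' replicate) by taking the mean of valid technical-replicate values; a cell
#' with at least one valid technical value yields their mean, otherwise it
#' stays missing. Averaging operates on the current scale; in the standard
#' workflow it is applied to raw intensities before log2 transformation.
#'
#' @param table a [protein_group_table()].
#' @return a table with `tech = NA` in its design and one column per
#'   (condition, bio).
#' @export
average_technical_replicates <- function(table) {
  stopifnot(inherits(table, "protein_group_table"))
  d <- table$design
  key <- paste(d$condition, d$bio, sep = "_")
  groups <- unique(key)
  m <- table$intensities
  out <- matrix(NA_real_, nrow(m), length(groups))
  for (j in seq_along(groups)) {
    cols <- which(key == groups[j])
    sub <- m[, cols, drop = FALSE]
    n_valid <- rowSums(!is.na(sub))
    s <- rowSums(sub, na.rm = TRUE)
    out[, j] <- ifelse(n_valid >= 1L, s / n_valid, NA_real_)
  }
  first <- match(groups, key)
  design <- data.frame(column = groups,
                       condition = d$condition[first],
                       bio = d$bio[first],
                       tech = NA_integer_,
                       stringsAsFactors = FALSE)
  table$intensities <- out
  colnames(table$intensities) <- groups
  table$design <- design
  table
}

#' Log2-transform a protein-group table
#'
#' Replaces every valid intensity by its log2; missing values stay missing.
#'
#' @param table a [protein_group_table()] on the raw scale.
#' @return the table on the log2 scale.
#' @export
log2_transform_table <- function(table) {
  stopifnot(inherits(table, "protein_group_table"))
  if (table$log2_scale) stop("table is already log2-transformed", call. = FALSE)
  m <- table$intensities
  if (any(m <= 0, na.rm = TRUE)) {
    stop("cannot log2-transform non-positive intensities", call. = FALSE)
  }
  table$intensities <- log2(m)
  table$log2_scale <- TRUE
  table
}
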