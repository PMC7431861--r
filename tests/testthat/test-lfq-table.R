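# IO and preprocessing of protein-group tables.

test_that("fixture file round-trips with flags parsed and zeros as missing", {
  path <- write_lfq_fixture()
  tab <- read_protein_group_table(path, fixture_column_map())
  expect_equal(length(tab$protein_id), 3)
  expect_equal(tab$is_reverse, c(FALSE, TRUE, FALSE))
  # zero LFQ intensity cells become missing
  expect_true(is.na(tab$intensities[2, 2]))
  expect_true(is.na(tab$intensities[3, 1]))
  expect_equal(tab$intensities[1, ], c(`LFQ intensity lysate_1_1` = 1000,
                                       `LFQ intensity sorted_1_1` = 2000))
  expect_equal(tab$razor_unique_peptides, c(5L, 3L, 1L))
})

test_that("reader rejects empty files, unmapped columns and duplicate ids", {
  empty <- tempfile(fileext = ".txt"); file.create(empty)
  expect_error(read_protein_group_table(empty, fixture_column_map()))

  path <- write_lfq_fixture()
  bad_map <- fixture_column_map()
  bad_map$column[2] <- "LFQ intensity nonexistent"
  expect_error(read_protein_group_table(path, bad_map), "not present")

  dup <- tempfile(fileext = ".txt")
  writeLines(c("Protein IDs\tLFQ intensity lysate_1_1\tLFQ intensity sorted_1_1",
               "P1\t10\t20", "P1\t30\t40"), dup)
  expect_error(read_protein_group_table(dup, fixture_column_map()), "duplicate")
})

test_that("written tables read back identically", {
  sim <- simulate_lfq_table(lfq_sim_config(n_proteins = 25, seed = 4))
  dir <- tempfile(); dir.create(dir)
  write_protein_group_table(sim$table, file.path(dir, "pg.txt"),
                            file.path(dir, "map.csv"))
  back <- read_protein_group_table(file.path(dir, "pg.txt"),
                                   file.path(dir, "map.csv"))
  expect_equal(back$protein_id, sim$table$protein_id)
  expect_equal(unname(back$intensities), unname(sim$table$intensities),
               tolerance = 1e-6)
  expect_equal(back$razor_unique_peptides, sim$table$razor_unique_peptides)
})

test_that("QC filter removes flagged and low-peptide rows, preserving order", {
  n <- 10
  tab <- protein_group_table(
    protein_id = sprintf("P%d", 1:n),
    intensities = matrix(1, n, 2),
    design = fixture_column_map(),
    is_reverse = c(TRUE, rep(FALSE, 9)),
    is_contaminant = c(FALSE, TRUE, rep(FALSE, 8)),
    only_identified_by_site = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
    razor_unique_peptides = c(5L, 5L, 5L, 1L, rep(5L, 6)))
  f0 <- filter_protein_groups(tab, min_peptides = 0)
  expect_equal(length(f0$protein_id), 7)
  expect_equal(f0$protein_id, sprintf("P%d", 4:10))

  f2 <- filter_protein_groups(tab, min_peptides = 2)
  expect_false("P4" %in% f2$protein_id)  # one razor/unique peptide only
  expect_equal(length(f2$protein_id), 6)

  clean <- protein_group_table(sprintf("Q%d", 1:3), matrix(1, 3, 2),
                               fixture_column_map())
  expect_equal(filter_protein_groups(clean, min_peptides = 0)$protein_id,
               clean$protein_id)
})

test_that("technical-replicate averaging keeps single valid values", {
  design <- data.frame(
    column = c("l_1_1", "l_1_2", "s_1_1", "s_1_2"),
    condition = c("lysate", "lysate", "sorted", "sorted"),
    bio = 1L, tech = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE)
  m <- rbind(c(4, 6, 5, NA), c(NA, NA, 3, 3))
  tab <- protein_group_table(c("P1", "P2"), m, design)
  avg <- average_technical_replicates(tab)
  expect_equal(ncol(avg$intensities), 2)
  expect_equal(avg$intensities[1, ], c(lysate_1 = 5, sorted_1 = 5))
  expect_true(is.na(avg$intensities[2, "lysate_1"]))
  expect_equal(avg$intensities[2, "sorted_1"], c(sorted_1 = 3))
})

test_that("log2 transform maps values and propagates missing", {
  tab <- protein_group_table(c("P1", "P2"), rbind(c(8, 1), c(NA, 4)),
                             fixture_column_map())
  lg <- log2_transform_table(tab)
  expect_equal(unname(lg$intensities[1, ]), c(3, 0))
  expect_true(is.na(lg$intensities[2, 1]))
  expect_true(lg$log2_scale)
  expect_error(log2_transform_table(lg), "already")

  zero <- protein_group_table("P1", matrix(c(0, 2), 1, 2), fixture_column_map())
  expect_error(log2_transform_table(zero), "non-positive")
})
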