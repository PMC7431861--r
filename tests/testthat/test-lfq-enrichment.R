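# Moderated statistic, permutation FDR and classification.

test_that("log2 fold change is the difference of condition means", {
  tab <- make_log_table(rbind(c(2, 2, 2, 3, 3, 3),
                              c(5, 5, 5, 5, 5, 5),
                              c(1, 2, 3, 4, 5, 6)))
  expect_equal(compute_log2_fc(tab, "P001"), 1.0)
  expect_equal(compute_log2_fc(tab, "P002"), 0.0)
  expect_equal(compute_log2_fc(tab, "P003"), 3.0)
  expect_error(compute_log2_fc(tab, "missing_id"), "unknown")
})

test_that("moderated statistic matches the textbook pooled t at s0 = 0", {
  expect_equal(moderated_t_statistic(c(1, 2, 3), c(1, 2, 3), s0 = 0.5), 0)
  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(moderated_t_statistic(a, b, s0 = 0), oracle_pooled_t(a, b)$t,
                 tolerance = 1e-12)
  }
})

test_that("zero-variance groups reduce the denominator to s0", {
  expect_equal(moderated_t_statistic(c(2, 2, 2), c(0, 0, 0), s0 = 0.1), 20)
  # both variances zero and s0 = 0: infinity with the sign of the difference
  expect_identical(moderated_t_statistic(c(2, 2, 2), c(0, 0, 0), s0 = 0), Inf)
  expect_identical(moderated_t_statistic(c(0, 0), c(1, 1), s0 = 0), -Inf)
})

test_that("the statistic is antisymmetric and |d| non-increasing in s0", {
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(3, 1); b <- rnorm(3)
    expect_equal(moderated_t_statistic(a, b, 0.1),
                 -moderated_t_statistic(b, a, 0.1))
    d_grid <- sapply(c(0, 0.05, 0.1, 0.5, 1, 2),
                     function(s0) abs(moderated_t_statistic(a, b, s0)))
    expect_true(all(diff(d_grid) <= 1e-12))
  }
})

test_that("plain p-values match t.test with pooled variance", {
  sim <- simulate_lfq_table(lfq_sim_config(n_proteins = 30, n_tech = 1,
                                           missing_model = missing_none(),
                                           seed = 5))
  fit <- lfq_enrichment(sim$table)
  m <- fit$table$intensities
  cond <- fit$table$design$condition
  for (i in c(1, 7, 19)) {
    ref <- t.test(m[i, cond == "sorted"], m[i, cond == "lysate"],
                  var.equal = TRUE)
    expect_equal(fit$results$p_raw[i], ref$p.value, tolerance = 1e-12)
    expect_equal(fit$results$log2_fc[i], unname(diff(rev(ref$estimate))),
                 tolerance = 1e-12)
  }
})

test_that("sampled permutation calls converge to the exhaustive oracle", {
  for (s in 1:5) {
    sim <- simulate_lfq_table(lfq_sim_config(
      n_proteins = 20, frac_enriched = 0.2, frac_depleted = 0.2,
      effect_log2 = 4, within_sd_log2 = 0.3, n_tech = 1,
      missing_model = missing_none(), seed = s))
    tab <- log2_transform_table(sim$table)
    ex <- permutation_fdr_calls(tab, mode = "exhaustive")
    sa <- permutation_fdr_calls(tab, mode = "sample", n_randomizations = 250,
                                seed = s + 50)
    expect_identical(sa$significant, ex$significant)
    expect_equal(attr(ex, "n_relabelings"), 9)  # C(6,3)/2 - identity
    # auto mode picks the exhaustive ensemble for 3 vs 3
    au <- permutation_fdr_calls(tab, mode = "auto")
    expect_true(attr(au, "exhaustive"))
    expect_identical(au$significant, ex$significant)
  }
})

test_that("strong planted effects are fully recovered with correct signs", {
  sim <- simulate_lfq_table(lfq_sim_config(
    n_proteins = 1000, frac_enriched = 0.05, frac_depleted = 0.05,
    effect_log2 = 4, within_sd_log2 = 0.3,
    missing_model = missing_none(), seed = 2))
  fit <- lfq_enrichment(sim$table, seed = 2)
  merged <- merge(as.data.frame(fit), sim$truth, by = "protein_id")
  expect_equal(sum(merged$class == "enriched" & merged$call == "enriched"), 50)
  expect_equal(sum(merged$class == "depleted" & merged$call == "depleted"), 50)
  expect_true(all(merged$log2_fc[merged$class == "enriched"] > 0))
})

test_that("proteins with under two valid values per group are not tested", {
  m <- rbind(c(1, 2, 3, 4, 5, 6),
             c(NA, NA, 3, 4, 5, 6),
             c(1, NA, NA, 4, 5, NA))
  tab <- make_log_table(m)
  fit <- lfq_enrichment(tab)
  expect_equal(as.character(fit$results$call[2]), "not_tested")
  expect_equal(as.character(fit$results$call[3]), "not_tested")
  expect_true(fit$results$testable[1])
})

test_that("classification partitions all proteins exhaustively", {
  res <- data.frame(log2_fc = c(2, -1, 0.5, NA),
                    significant = c(TRUE, TRUE, FALSE, FALSE),
                    testable = c(TRUE, TRUE, TRUE, FALSE))
  out <- classify_proteins(res)
  expect_equal(as.character(out$call),
               c("enriched", "depleted", "ns", "not_tested"))
  expect_false(anyNA(out$call))
})

test_that("swapping condition labels negates effects and swaps calls", {
  sim <- simulate_lfq_table(lfq_sim_config(
    n_proteins = 300, frac_enriched = 0.1, frac_depleted = 0.1,
    effect_log2 = 4, within_sd_log2 = 0.3, seed = 8))
  fit <- lfq_enrichment(sim$table, seed = 8)
  swapped <- lfq_enrichment(swap_conditions(fit$table), seed = 8)
  expect_equal(swapped$results$log2_fc, -fit$results$log2_fc)
  expect_equal(swapped$results$d_stat, -fit$results$d_stat)
  expect_equal(sum(swapped$results$call == "enriched"),
               sum(fit$results$call == "depleted"))
  expect_equal(sum(swapped$results$call == "depleted"),
               sum(fit$results$call == "enriched"))
})

test_that("the analysis is reproducible end to end under a fixed seed", {
  sim <- simulate_lfq_table(lfq_sim_config(n_proteins = 150, seed = 13))
  f1 <- lfq_enrichment(sim$table, seed = 13)
  f2 <- lfq_enrichment(sim$table, seed = 13)
  expect_identical(f1$results, f2$results)
  expect_identical(f1$threshold, f2$threshold)
})
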