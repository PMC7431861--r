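# Tn5 insertion-centre extraction, windowed enrichment, trend profiles.

test_that("Tn5 offsets are exact on hand-built reads at both strands", {
  reads <- data.frame(
    chrom = "chr1",
    start = c(100L, 151L, 0L, 995L, 40L),
    end   = c(150L, 201L, 50L, 1000L, 90L),
    name = ".", score = 0L,
    strand = c("+", "-", "+", "-", "*"),
    stringsAsFactors = FALSE)
  expect_warning(sites <- extract_insertion_centers(reads, c(chr1 = 1000L)),
                 "unknown strand")
  # +: start + 4; -: (end - 1) - 5
  expect_equal(sites$pos, c(104L, 195L, 4L, 994L))
  expect_equal(attr(sites, "n_dropped_strand"), 1L)
  expect_equal(attr(sites, "n_dropped_bounds"), 0L)
})

test_that("site counts are conserved: input = retained + dropped", {
  reads <- data.frame(
    chrom = "chr1",
    start = c(0L, 0L, 996L, 500L, 200L, 300L, 700L, 10L, 20L, 30L),
    end   = c(2L, 50L, 1000L, 550L, 250L, 350L, 750L, 60L, 70L, 80L),
    name = ".", score = 0L,
    strand = c("-", "+", "+", "-", "+", "-", "+", "*", "+", "-"),
    stringsAsFactors = FALSE)
  # read 1: minus 5' end at 1, offset to -4 -> out of bounds
  # read 3: plus start 996 -> site 1000 -> out of bounds
  expect_warning(sites <- extract_insertion_centers(reads, c(chr1 = 1000L)))
  expect_equal(nrow(sites) + attr(sites, "n_dropped_strand") +
                 attr(sites, "n_dropped_bounds"), nrow(reads))
  expect_equal(attr(sites, "n_dropped_bounds"), 2L)
  expect_true(all(sites$pos >= 0 & sites$pos < 1000))
})

test_that("empty read sets give empty site lists", {
  reads <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
  sites <- extract_insertion_centers(reads, c(chr1 = 1000L))
  expect_equal(nrow(sites), 0)
})

test_that("a window at exactly twice the average density has log2 = 1", {
  # 4 windows with counts (x, x, x, 3x): window 4 holds twice the
  # genome-wide average count
  x <- 100L
  pos <- c(sample.int(25000L, x) - 1L,
           25000L + sample.int(25000L, x) - 1L,
           50000L + sample.int(25000L, x) - 1L,
           75000L + sample.int(25000L, 3L * x) - 1L)
  sites <- data.frame(chrom = "chr1", pos = sort(pos))
  track <- windowed_log2_enrichment(sites, c(chr1 = 100000L))
  expect_equal(nrow(track), 4)
  expect_equal(track$log2_enrichment[4], 1, tolerance = 1e-12)
  expect_equal(sum(track$count), nrow(sites))
})

test_that("uniform insertions give a null enrichment track", {
  # depth of 1000 expected sites per window keeps every Poisson deviate
  # within +/-0.2 on the log2 scale
  sim <- simulate_atac_reads(atac_sim_config(c(chr1 = 2000000L),
                                             background_rate = 0.04,
                                             seed = 17))
  sites <- extract_insertion_centers(sim$reads[[1]], c(chr1 = 2000000L))
  track <- windowed_log2_enrichment(sites, c(chr1 = 2000000L))
  expect_true(all(track$expected >= 100))
  expect_true(all(abs(track$log2_enrichment) < 0.2))
  expect_lt(abs(mean(track$log2_enrichment)), 0.05)
  expect_equal(sum(track$count), nrow(sites))
})

test_that("uniform window counts are Poisson by a dispersion test", {
  sim <- simulate_atac_reads(atac_sim_config(c(chr1 = 2500000L),
                                             background_rate = 0.004,
                                             seed = 23))
  sites <- extract_insertion_centers(sim$reads[[1]], c(chr1 = 2500000L))
  track <- windowed_log2_enrichment(sites, c(chr1 = 2500000L))
  counts <- track$count
  lambda <- mean(counts)
  stat <- sum((counts - lambda)^2 / lambda)  # ~ chi-square, df = n - 1
  p <- stats::pchisq(stat, df = length(counts) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("a fold-2 peak roughly doubles the local window density", {
  cs <- c(chr1 = 2000000L)
  pk <- atac_peaks("chr1", summit = 1000000L, half_width = 12000L,
                   class = "retained", fold = 2)
  sim <- simulate_atac_reads(atac_sim_config(cs, background_rate = 0.01,
                                             peaks = pk, seed = 31))
  sites <- extract_insertion_centers(sim$reads[[1]], cs)
  track <- windowed_log2_enrichment(sites, cs)
  in_peak <- track$start <= 1000000 & track$end > 1000000
  background <- mean(track$count[!in_peak]) / 25000
  peak_dens <- sum(track$count[track$start >= 975000 & track$end <= 1025000]) /
    50000
  # 24 kb of fold-2 signal inside 50 kb of windows: expected ratio
  # 1 + 24/50 = 1.48 over background
  expect_equal(peak_dens / background, 1.48, tolerance = 0.15)
})

test_that("background_rate 0 with a fold-0 peak yields no reads", {
  cs <- c(chr1 = 100000L)
  pk <- atac_peaks("chr1", summit = 50000L, half_width = 500L,
                   class = "lost", fold = 0)
  pk$fold.asynchronous <- 0
  sim <- simulate_atac_reads(atac_sim_config(cs, background_rate = 0,
                                             peaks = pk, seed = 1))
  expect_equal(nrow(sim$reads[[1]]), 0)
  expect_equal(nrow(sim$reads[[2]]), 0)
})

test_that("empty site sets warn and produce an all-missing track", {
  sites <- data.frame(chrom = character(0), pos = integer(0))
  expect_warning(track <- windowed_log2_enrichment(sites, c(chr1 = 50000L)),
                 "no insertion sites")
  expect_true(all(track$count == 0))
})

test_that("uniform sites give a flat, mean-one trend profile", {
  cs <- c(chr1 = 1000000L)
  sim <- simulate_atac_reads(atac_sim_config(cs, background_rate = 0.3,
                                             seed = 41))
  sites <- extract_insertion_centers(sim$reads[[1]], cs)
  summits <- data.frame(chrom = "chr1",
                        pos = as.integer(seq(20000, 980000, by = 5000)),
                        class = "all")
  prof <- summit_trend_profile(sites, summits)
  expect_equal(mean(prof$rel_density), 1, tolerance = 1e-9)
  expect_true(all(abs(prof$rel_density - 1) < 0.1))
  # bins exactly tile [-1000, 1000)
  expect_equal(min(prof$offset), -995)
  expect_equal(max(prof$offset), 995)
  expect_equal(nrow(prof), 200)
})

test_that("mirror-symmetric input yields a symmetric profile", {
  summit <- 10000L
  offs <- c(-800L, -500L, -120L, -30L, 0L, 30L, 120L, 500L, 800L)
  sites <- data.frame(chrom = "chr1", pos = summit + offs)
  # single-bp bins make the mirror comparison exact: position +r pairs
  # with -r for every r in 1..999
  prof <- summit_trend_profile(sites,
                               data.frame(chrom = "chr1", pos = summit,
                                          class = "all"),
                               bin_bp = 1L)
  d <- prof$rel_density
  r <- 1:999
  expect_equal(d[r + 1001], d[1001 - r], tolerance = 1e-12)
})

test_that("retained peaks keep their summit signal, lost peaks flatten", {
  cs <- c(chr1 = 4000000L)
  pk <- atac_peaks("chr1",
                   summit = as.integer(seq(200000, 3800000, length.out = 12)),
                   half_width = 200L,
                   class = rep(c("retained", "lost"), 6), fold = 4)
  sim <- simulate_atac_reads(atac_sim_config(cs, background_rate = 0.02,
                                             peaks = pk, seed = 51))
  summits <- data.frame(chrom = "chr1", pos = pk$summit, class = pk$class)
  mitotic <- extract_insertion_centers(sim$reads$mitotic, cs)
  prof <- summit_trend_profile(mitotic, summits)
  centre <- abs(prof$offset) < 200
  flank <- abs(prof$offset) > 600
  retained <- prof$class == "retained"
  lost <- prof$class == "lost"
  expect_gt(mean(prof$rel_density[retained & centre]) /
              mean(prof$rel_density[retained & flank]), 2)
  expect_lt(mean(prof$rel_density[lost & centre]) /
              mean(prof$rel_density[lost & flank]), 1.3)

  # in the first condition both classes carry the peak
  async <- extract_insertion_centers(sim$reads$asynchronous, cs)
  prof0 <- summit_trend_profile(async, summits)
  expect_gt(mean(prof0$rel_density[prof0$class == "lost" & centre]) /
              mean(prof0$rel_density[prof0$class == "lost" & flank]), 2)
})

test_that("BED and chrom.sizes round-trip through their writers", {
  sim <- simulate_atac_reads(atac_sim_config(c(chrA = 50000L),
                                             background_rate = 0.01,
                                             seed = 2))
  path <- tempfile(fileext = ".bed")
  write_bed6(sim$reads[[1]], path)
  back <- read_bed6(path)
  expect_equal(back$start, sim$reads[[1]]$start)
  expect_equal(back$strand, sim$reads[[1]]$strand)

  cs_path <- tempfile()
  writeLines("chrA\t50000", cs_path)
  expect_equal(read_chrom_sizes(cs_path), c(chrA = 50000L))
})

test_that("read simulation is deterministic and respects strand fractions", {
  cfg <- atac_sim_config(c(chr1 = 500000L), background_rate = 0.02,
                         frac_minus_strand = 0.3, seed = 77)
  a <- simulate_atac_reads(cfg)
  b <- simulate_atac_reads(cfg)
  expect_identical(a$reads, b$reads)
  frac_minus <- mean(a$reads[[1]]$strand == "-")
  expect_equal(frac_minus, 0.3, tolerance = 0.03)
})

test_that("invalid ATAC configurations are rejected", {
  expect_error(atac_sim_config(integer(0)), "non-empty")
  pk <- atac_peaks("chr1", 100L, 500L, "retained")
  expect_error(atac_sim_config(c(chr1 = 10000L), peaks = pk), "bounds")
})
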