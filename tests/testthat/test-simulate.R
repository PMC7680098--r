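test_that("the default design yields 15 circles x 3 samples = 45", {
  sim <- simulate_population(sim_config(n_sites = 30, seed = 2))
  expect_length(sim$variants$sample_ids, 45L)
  expect_equal(nrow(sim$sheet), 45L)
  expect_equal(nrow(sim$hapcounts), 45L)
  expect_equal(length(unique(sim$sheet$circle_id)), 15L)
  # centres respect the configured minimum spacing
  centers <- unique(sim$sheet[, c("center_x", "center_y")])
  expect_gte(min(dist(centers)), 10)
})

test_that("identical seeds give bit-identical output", {
  cfg <- sim_config(n_circles = 3, n_sites = 200, seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sheet, b$sheet)
  c2 <- simulate_population(sim_config(n_circles = 3, n_sites = 200,
                                       seed = 100))
  expect_false(identical(a$variants$alt_depth, c2$variants$alt_depth))
})

test_that("ramets of one genet share genotype and ploidy", {
  sim <- simulate_population(sim_config(n_circles = 4, clonal_circles = 1,
                                        n_sites = 300, seed = 11))
  for (cid in unique(sim$sheet$circle_id)) {
    ids <- sim$sheet$sample_id[sim$sheet$circle_id == cid]
    expect_length(unique(sim$truth$genet_id[ids]), 1L)
    expect_length(unique(sim$truth$ploidy[ids]), 1L)
    dos <- sim$truth$dosage[, ids, drop = FALSE]
    expect_true(all(dos == dos[, 1L]))
  }
})

test_that("diploid heterozygosity matches Hardy-Weinberg at p = 0.5, F = 0", {
  sim <- simulate_population(sim_config(
    n_circles = 5, samples_per_circle = 2,
    ploidy_mix = c("2" = 1, "4" = 0, "8" = 0),
    allele_freq = 0.5, selfing_F = 0, error_rate = 0,
    n_sites = 10000, seed = 21))
  het <- mean(sim$truth$dosage == 1L)
  n_cells <- length(sim$truth$dosage)
  expect_lt(abs(het - 0.5), 4 * sqrt(0.25 / n_cells))   # 4-sigma binomial band
})

test_that("selfing depresses heterozygosity by the expected factor", {
  base <- sim_config(n_circles = 5, samples_per_circle = 2,
                     ploidy_mix = c("2" = 1, "4" = 0, "8" = 0),
                     allele_freq = 0.5, error_rate = 0,
                     n_sites = 10000, seed = 31)
  cfg_f <- base; cfg_f$selfing_F <- 0.3
  het0 <- mean(simulate_population(base)$truth$dosage == 1L)
  hetf <- mean(simulate_population(cfg_f)$truth$dosage == 1L)
  expect_equal(hetf / het0, 0.7, tolerance = 0.05)
})

test_that("allele balance at single-copy variant sites sits near 1/ploidy", {
  for (k in c(2L, 4L, 8L)) {
    mix <- stats::setNames(as.numeric(c(2, 4, 8) == k), c("2", "4", "8"))
    sim <- simulate_population(sim_config(
      n_circles = 2, samples_per_circle = 2, ploidy_mix = mix,
      fixed_dosage = 1, homoeolog_fixed_fraction = 0, error_rate = 0,
      mean_depth = 50, n_sites = 4000, seed = k))
    f <- sim$variants$alt_depth / (sim$variants$ref_depth +
                                     sim$variants$alt_depth)
    expect_equal(mean(f, na.rm = TRUE), 1 / k, tolerance = 0.01)
  }
})

test_that("homoeologous fixed differences add balanced sites in polyploids", {
  mk <- function(h, seed) {
    sim <- simulate_population(sim_config(
      n_circles = 3, ploidy_mix = c("2" = 0, "4" = 1, "8" = 0),
      homoeolog_fixed_fraction = h, n_sites = 3000, seed = seed))
    f <- sim$variants$alt_depth[, 1] /
      (sim$variants$ref_depth[, 1] + sim$variants$alt_depth[, 1])
    sum(abs(f - 0.5) < 0.1, na.rm = TRUE)
  }
  for (seed in 1:3) expect_gt(mk(0.3, seed), mk(0.02, seed))
})

test_that("infeasible geometry and invalid configs are rejected", {
  expect_error(simulate_population(
    sim_config(n_circles = 100, circle_spacing_m = 10, area_side_m = 100,
               n_sites = 10)), "infeasible")
  expect_error(sim_config(ploidy_mix = c("2" = 0.5, "4" = 0.4, "8" = 0.2)),
               "sum to 1")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(error_rate = 1.5), "rates")
})

test_that("haplotype-count summaries show the polyploid excess", {
  sim <- simulate_population(sim_config(n_circles = 10, n_sites = 20,
                                        seed = 17))
  n3 <- stats::setNames(sim$hapcounts$n_loci_3plus_hap,
                        sim$hapcounts$sample_id)
  poly <- sim$truth$ploidy >= 4L
  expect_true(all(n3[poly] >= 2000))
  expect_true(all(n3[!poly] <= 200))
  tot <- rowSums(sim$hapcounts[, c("n_loci_1hap", "n_loci_2hap",
                                   "n_loci_3plus_hap")])
  expect_true(all(tot == sim$config$total_loci))
})
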