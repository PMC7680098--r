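test_that("within/between minima match the design combinatorics", {
  # 2 circles x 2 samples, hand-built distances
  ids <- c("a1", "a2", "b1", "b2")
  D <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  D["a1", "a2"] <- D["a2", "a1"] <- 0.2
  sheet <- validate_sample_sheet(data.frame(
    sample_id = ids, circle_id = c("A", "A", "B", "B"),
    position_label = rep(c("near_1", "near_2"), 2),
    center_x = c(0, 0, 50, 50), center_y = 0, stringsAsFactors = FALSE))
  mwb <- min_within_between(dist_matrix(D), sheet)
  expect_equal(mwb$within[["A"]], 0.2)
  expect_equal(mwb$within[["B"]], 1)
  expect_equal(nrow(mwb$between), 1L)
  expect_equal(mwb$between$min_dist, 1)
})

test_that("minimum-distance extraction agrees with an exhaustive scan", {
  set.seed(77)
  for (rep in 1:5) {
    n_circ <- 6; spc <- sample(2:4, 1)
    n <- n_circ * spc
    pts <- matrix(rnorm(n * 6), ncol = 6)
    rownames(pts) <- sprintf("s%02d", 1:n)
    D <- as.matrix(dist(pts))
    circle <- rep(sprintf("c%d", 1:n_circ), each = spc)
    sheet <- validate_sample_sheet(data.frame(
      sample_id = rownames(D), circle_id = circle,
      position_label = "near_1",
      center_x = rep(seq(0, 100, length.out = n_circ), each = spc),
      center_y = 0, stringsAsFactors = FALSE))
    got <- min_within_between(dist_matrix(D), sheet)
    ora <- naive_min_within_between(D, circle)
    expect_equal(got$within[names(ora$within)], ora$within)
    expect_equal(got$between, ora$between)
  }
})

test_that("rank-sum test matches hand-computed exact cases", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)    # 2/20 orderings as extreme
  expect_true(res$exact)

  sym <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$p_value, 1)

  expect_warning(flat <- wilcoxon_rank_sum(rep(2, 5), rep(2, 7)),
                 "identical")
  expect_equal(flat$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum p-values match the exhaustive permutation oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:7, 1); m <- sample(3:7, 1)
    repeat {
      x <- round(rnorm(n, 0, 2), 6); y <- round(rnorm(m, 1, 2), 6)
      if (!anyDuplicated(c(x, y))) break
    }
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, perm_wilcox_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum type-I error is calibrated on iid groups", {
  # at the study's group sizes (15 within, 105 between minima)
  set.seed(2024)
  rej <- mean(replicate(400, {
    wilcoxon_rank_sum(rlnorm(15), rlnorm(105))$p_value < 0.05
  }))
  band <- qbinom(c(0.025, 0.975), 400, 0.05) / 400
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("distance decay recovers an exact linear relation", {
  circles <- sprintf("c%d", 1:5)
  sheet <- validate_sample_sheet(data.frame(
    sample_id = paste0(rep(circles, each = 2), "-", 1:2),
    circle_id = rep(circles, each = 2), position_label = "near_1",
    center_x = rep(c(0, 10, 25, 45, 70), each = 2), center_y = 0,
    stringsAsFactors = FALSE))
  pairs <- t(combn(circles, 2))
  cx <- c(0, 10, 25, 45, 70); names(cx) <- circles
  spatial <- abs(cx[pairs[, 1]] - cx[pairs[, 2]])
  between <- data.frame(circle_1 = pairs[, 1], circle_2 = pairs[, 2],
                        min_dist = 2 * spatial + 1,
                        stringsAsFactors = FALSE)
  fit <- distance_decay(between, sheet)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)

  flat <- between; flat$min_dist <- 3
  ffit <- distance_decay(flat, sheet)
  expect_equal(ffit$slope, 0)
  expect_equal(ffit$r, 0)
  expect_true(ffit$degenerate)

  same <- sheet; same$center_x <- 0
  expect_error(distance_decay(between, same), "zero variance")
})

test_that("panmictic simulations give a flat distance decay on average", {
  slopes <- ses <- numeric(10)
  for (seed in 1:10) {
    sim <- simulate_population(sim_config(n_circles = 8, n_sites = 500,
                                          seed = 700 + seed))
    rep <- fc_clonality(sim$variants, sim$sheet)
    slopes[seed] <- rep$decay$slope
    ses[seed] <- summary(lm(genetic_dist ~ spatial_dist,
                            data = rep$decay$data))$coefficients[2, 2]
  }
  expect_lt(abs(mean(slopes)), 2 * mean(ses) / sqrt(10))
})

test_that("a fully homozygous sample has inbreeding coefficient one", {
  set.seed(31)
  vals <- matrix(sample(c(0, 0.5, 1), 300, TRUE), ncol = 6)
  vals[, 1] <- rep(c(0, 1), length.out = 50)   # sample 1: no heterozygosity
  f <- inbreeding_coefficient(make_recoded(vals))
  expect_equal(unname(f$F[1]), 1)
  expect_equal(f$n_samples, 6L)
  expect_error(inbreeding_coefficient(make_recoded(matrix(0, 10, 3))),
               "polymorphic")
})

test_that("inbreeding estimates recover the simulated selfing level", {
  est <- sapply(c(0, 0.2), function(f_true) {
    sim <- simulate_population(sim_config(
      n_circles = 5, samples_per_circle = 2,
      ploidy_mix = c("2" = 1, "4" = 0, "8" = 0),
      selfing_F = f_true, n_sites = 4000, seed = 53))
    m <- recode_genotypes(sim$variants)
    inbreeding_coefficient(m)$mean_F
  })
  expect_lt(abs(est[1] - 0), 0.06)
  expect_lt(abs(est[2] - 0.2), 0.06)
  # bootstrap interval broadly agrees with the t interval
  sim <- simulate_population(sim_config(
    n_circles = 5, samples_per_circle = 2,
    ploidy_mix = c("2" = 1, "4" = 0, "8" = 0), n_sites = 2000, seed = 59))
  m <- recode_genotypes(sim$variants)
  set.seed(1)
  bt <- inbreeding_coefficient(m, ci = "bootstrap", n_boot = 500)
  tt <- inbreeding_coefficient(m, ci = "t")
  expect_lt(abs(bt$ci[1] - tt$ci[1]), 0.05)
  expect_lt(abs(bt$ci[2] - tt$ci[2]), 0.05)
})

test_that("clonal designs give a decisive rank-sum rejection", {
  sim <- simulate_population(sim_config(n_circles = 15, clonal_circles = 1,
                                        mean_depth = 60,
                                        ploidy_mix = c("2" = 1, "4" = 0,
                                                       "8" = 0),
                                        error_rate = 0, n_sites = 1500,
                                        seed = 61))
  rep <- fc_clonality(sim$variants, sim$sheet)
  expect_true(all(rep$within == 0))
  expect_lt(rep$wilcoxon$p_value, 0.01)
  expect_equal(rep$wilcoxon$n_x, 15L)
  expect_equal(rep$wilcoxon$n_y, 105L)
})

test_that("within/between decomposition is invariant to sample order", {
  sim <- simulate_population(sim_config(n_circles = 5, n_sites = 400,
                                        seed = 67))
  rep <- fc_clonality(sim$variants, sim$sheet)
  set.seed(1)
  perm <- sample(sim$variants$sample_ids)
  vt2 <- subset_variant_table(sim$variants, samples = perm)
  sheet2 <- sim$sheet[match(perm, sim$sheet$sample_id), ]
  rep2 <- fc_clonality(vt2, sheet2)
  expect_equal(rep2$within[names(rep$within)], rep$within)
  key <- function(b) paste(pmin(b$circle_1, b$circle_2),
                           pmax(b$circle_1, b$circle_2))
  expect_equal(rep2$between$min_dist[match(key(rep$between),
                                           key(rep2$between))],
               rep$between$min_dist)
})
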