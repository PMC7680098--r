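#' Minimum genetic distances within and between circles
#'
#' The clonality statistics: for each circle (with at least two samples),
#' the smallest genetic distance among its samples; for each unordered
#' pair of circles, the smallest distance between any sample of one and
#' any sample of the other. A clonal circle has within-minimum 0.
#'
#' @param d a [dist_matrix()] over the samples.
#' @param sheet a `sample_sheet` assigning every sample in `d` to a circle.
#' @return list with `within` (named numeric, one per eligible circle) and
#'   `between` (data.frame: `circle_1`, `circle_2`, `min_dist`, one row per
#'   unordered circle pair).
#' @export
min_within_between <- function(d, sheet) {
  stopifnot(inherits(d, "dist_matrix"))
  sheet <- as.data.frame(sheet)
  circ <- sheet$circle_id[match(d$sample_ids, sheet$sample_id)]
  if (anyNA(circ))
    stop("sample(s) without a circle assignment: ",
         paste(d$sample_ids[is.na(circ)], collapse = ", "))
  circles <- unique(circ)
  within <- numeric(0)
  for (c_i in circles) {
    idx <- which(circ == c_i)
    if (length(idx) < 2L) {
      warning("circle ", c_i, " has <2 samples; excluded from ",
              "within-circle distances", call. = FALSE)
      next
    }
    sub <- d$d[idx, idx, drop = FALSE]
    within[c_i] <- min(sub[upper.tri(sub)])
  }
  if (length(circles) < 2L) {
    between <- data.frame(circle_1 = character(0), circle_2 = character(0),
                          min_dist = numeric(0), stringsAsFactors = FALSE)
  } else {
    pairs <- utils::combn(circles, 2L)
    between <- data.frame(
      circle_1 = pairs[1L, ], circle_2 = pairs[2L, ],
      min_dist = apply(pairs, 2L, function(p)
        min(d$d[circ == p[1L], circ == p[2L]])),
      stringsAsFactors = FALSE)
  }
  list(within = within, between = between)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when both groups are small
#' (min(n, m) <= 10) and there are no ties across the pooled values;
#' otherwise the normal approximation with tie and continuity correction.
#' The switch is reported in the result so downstream reports can state
#' which path produced the p-value.
#'
#' @param x,y numeric vectors (e.g. within- and between-circle minimum
#'   distances).
#' @return list with `statistic` (the Mann-Whitney U of `x`), `p_value`,
#'   `n_x`, `n_y`, `exact` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical in both groups; p = 1", call. = FALSE)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                n_x = length(x), n_y = length(y), exact = FALSE))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- !ties && min(length(x), length(y)) <= 10L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_x = length(x), n_y = length(y), exact = exact)
}

#' Genetic-versus-spatial distance decay across circle pairs
#'
#' Ordinary least-squares regression of the minimum between-circle genetic
#' distance on the Euclidean distance between circle centres
#' (isolation-by-distance diagnostic). Only between-circle comparisons
#' enter. With spatially unstructured (panmictic) genotypes the slope is
#' expected to be 0.
#'
#' @param between the `between` data.frame from [min_within_between()].
#' @param sheet a `sample_sheet` carrying the circle centres.
#' @return list with `slope`, `intercept`, `r` (Pearson; 0 with a
#'   `degenerate = TRUE` flag when the genetic distances have zero
#'   variance), `n_pairs`, and `data` (the regression table).
#' @export
distance_decay <- function(between, sheet) {
  if (nrow(between) < 3L) stop("need at least 3 circle pairs")
  sheet <- as.data.frame(sheet)
  centers <- unique(sheet[, c("circle_id", "center_x", "center_y")])
  cx <- stats::setNames(centers$center_x, centers$circle_id)
  cy <- stats::setNames(centers$center_y, centers$circle_id)
  spatial <- sqrt((cx[between$circle_1] - cx[between$circle_2])^2 +
                  (cy[between$circle_1] - cy[between$circle_2])^2)
  if (stats::sd(spatial) == 0)
    stop("zero variance in spatial distances between circle centres")
  fit <- stats::lm(between$min_dist ~ spatial)
  degenerate <- stats::sd(between$min_dist) == 0
  r <- if (degenerate) 0 else stats::cor(spatial, between$min_dist)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = r, degenerate = degenerate, n_pairs = nrow(between),
       data = data.frame(spatial_dist = unname(spatial),
                         genetic_dist = between$min_dist,
                         circle_1 = between$circle_1,
                         circle_2 = between$circle_2,
                         stringsAsFactors = FALSE))
}

#' Method-of-moments inbreeding coefficients from recoded genotypes
#'
#' Per sample, F = (O_hom - E_hom) / (L - E_hom), where O_hom is the
#' number of sites coded homozygous (0 or 1), L the number of polymorphic
#' sites used, and E_hom = sum over sites of 1 - 2*p*q * 2k/(2k - 1) the
#' homozygosity expected under Hardy-Weinberg, with p the sample-set allele
#' frequency (0.5 codes counting half) and 2k/(2k - 1) the small-sample
#' correction on 2k allele copies from k diploid samples. F near 0
#' indicates outbreeding; negative F an excess of heterozygotes; F = 1 a
#' fully homozygous sample. Intended for the diploid subset only — in
#' polyploids the 0.5 codes conflate heterozygosity with homoeologous
#' fixed differences.
#'
#' @param m a `recoded_matrix`.
#' @param samples the diploid samples to use (ids or indices; default all
#'   columns of `m`).
#' @param conf_level confidence level for the interval on the mean F.
#' @param ci `"t"` (default): mean +/- t-quantile * SE over the per-sample
#'   F values; `"bootstrap"`: percentile interval from resampling samples.
#' @param n_boot bootstrap replicates when `ci = "bootstrap"`.
#' @return list with `F` (named per-sample values), `mean_F`, `ci`
#'   (length-2), `n_sites_used`, `n_samples`, `ci_method`.
#' @export
inbreeding_coefficient <- function(m, samples = NULL, conf_level = 0.95,
                                   ci = c("t", "bootstrap"),
                                   n_boot = 1000L) {
  stopifnot(inherits(m, "recoded_matrix"))
  ci <- match.arg(ci)
  values <- m$values
  if (!is.null(samples)) {
    j <- if (is.character(samples)) match(samples, m$sample_ids) else samples
    if (anyNA(j)) stop("unknown sample id")
    values <- values[, j, drop = FALSE]
  }
  k <- ncol(values)
  if (k < 2L) stop("need at least 2 diploid samples")
  p_hat <- rowMeans(values)                 # 0.5 codes count half
  poly <- p_hat > 0 & p_hat < 1
  if (!any(poly))
    stop("no sites polymorphic across the selected samples")
  values <- values[poly, , drop = FALSE]
  p_hat <- p_hat[poly]
  L <- nrow(values)
  corr <- (2 * k) / (2 * k - 1)             # allele-copy small-sample factor
  e_hom <- sum(1 - 2 * p_hat * (1 - p_hat) * corr)
  o_hom <- colSums(values != 0.5)
  f_per_sample <- (o_hom - e_hom) / (L - e_hom)
  mean_f <- mean(f_per_sample)
  alpha <- 1 - conf_level
  if (ci == "t") {
    se <- stats::sd(f_per_sample) / sqrt(k)
    tq <- stats::qt(1 - alpha / 2, df = k - 1L)
    interval <- c(mean_f - tq * se, mean_f + tq * se)
  } else {
    boots <- replicate(n_boot,
                       mean(f_per_sample[sample.int(k, k, replace = TRUE)]))
    interval <- unname(stats::quantile(boots, c(alpha / 2, 1 - alpha / 2)))
  }
  list(F = f_per_sample, mean_F = mean_f, ci = interval,
       n_sites_used = L, n_samples = k, ci_method = ci,
       conf_level = conf_level)
}
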