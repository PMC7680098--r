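#' Configuration for the synthetic-population generator
#'
#' Defaults describe the study design the package targets: 15 circles,
#' three plants sampled per circle (two neighbouring "near" samples on the
#' perimeter plus one on the far side), circle centres at least 10 m apart
#' on roughly one hectare, and a cohort mixing diploids with allotetraploids
#' (and the occasional octoploid) in the proportions seen in a
#' mixed-ploidy grass population.
#'
#' @param n_circles number of circles.
#' @param samples_per_circle samples (plants) per circle.
#' @param ploidy_mix named proportions over ploidies `"2"`, `"4"`, `"8"`;
#'   must sum to 1.
#' @param clonal_circles fraction of circles whose samples are ramets of a
#'   single genet (clonal copies). 0 = every sample its own genet.
#' @param n_sites number of biallelic SNP sites.
#' @param allele_freq per-site population alternative-allele frequency
#'   prior: `"sfs"` (default; rare-skewed site-frequency spectrum with
#'   density proportional to p^-1.5 truncated to (0.05, 0.95), so that
#'   low-dosage variants dominate as in empirical SNP panels), `"neutral"`
#'   (density proportional to 1/p, the standard coalescent shape),
#'   `"uniform"` (Uniform(0.05, 0.95)), a single numeric (all sites share
#'   that frequency), or a `function(n)` returning `n` frequencies.
#' @param homoeolog_fixed_fraction fraction of sites at which allopolyploid
#'   subgenomes carry fixed opposite alleles (half the subgenomes fixed for
#'   ALT), so every polyploid shows an allele balance of 0.5 there.
#' @param cytotype_fixed_fraction fraction of sites at which all subgenomes
#'   of every polyploid are fixed for ALT while diploids segregate at the
#'   (rare-skewed) population frequency: fixed divergence between the
#'   polyploid subgenomes and the diploid gene pool. Such sites have allele
#'   balance near 1 in polyploids (so they never enter the ploidy spectrum,
#'   whose upper bound removes them) but are recoded 1 versus mostly 0 in
#'   diploids, which is what makes cytotypes separate in genotype space.
#' @param mean_depth expected total reads per site and sample.
#' @param depth_model `"nbinom"` (default): negative binomial with mean
#'   `mean_depth` and dispersion `depth_dispersion`, the standard
#'   overdispersed model for RAD-seq coverage — the depth spread also keeps
#'   read-fraction values off a sparse lattice, which a fixed-width
#'   histogram would turn into comb artifacts; `"poisson"`: equidispersed.
#' @param depth_dispersion negative-binomial size parameter (smaller =
#'   more overdispersed); default 5 (coefficient of variation ~0.47 at
#'   depth 30).
#' @param error_rate per-read base miscall probability; each read flips
#'   allele with this probability.
#' @param selfing_F inbreeding coefficient used for the diploid genotype
#'   draw (and for each subgenome of a polyploid):
#'   P(het) = 2p(1-p)(1-F).
#' @param circle_spacing_m minimum distance between circle centres, metres.
#' @param area_side_m side of the square sampling area, metres.
#' @param conserved_fraction fraction of sites flagged as the stringent
#'   conserved subset.
#' @param fixed_dosage `NA` (default: population draw) or an integer d:
#'   every sample carries ALT dosage `min(d, ploidy)` at every site. Used
#'   for spectrum calibration (d = 1 gives purely heterozygous diploids,
#'   simplex tetraploids, 1-of-8 octoploids).
#' @param polyploid_locus_count baseline count of RAD loci with >= 3
#'   haplotypes simulated for polyploids.
#' @param diploid_locus_count upper bound for the (small) diploid count of
#'   loci with >= 3 haplotypes.
#' @param total_loci total RAD loci per sample in the haplotype summary.
#' @param seed integer RNG seed; identical configs give bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_circles = 15L, samples_per_circle = 3L,
                       ploidy_mix = c("2" = 0.600, "4" = 0.375, "8" = 0.025),
                       clonal_circles = 0, n_sites = 5000L,
                       allele_freq = "sfs",
                       homoeolog_fixed_fraction = 0.05,
                       cytotype_fixed_fraction = 0.05,
                       mean_depth = 30, depth_model = c("nbinom", "poisson"),
                       depth_dispersion = 5, error_rate = 0.005,
                       selfing_F = 0,
                       circle_spacing_m = 10, area_side_m = 100,
                       conserved_fraction = 0.25,
                       fixed_dosage = NA,
                       polyploid_locus_count = 2000L,
                       diploid_locus_count = 200L,
                       total_loci = 63000L,
                       seed = 1L) {
  cfg <- list(n_circles = as.integer(n_circles),
              samples_per_circle = as.integer(samples_per_circle),
              ploidy_mix = ploidy_mix,
              clonal_circles = clonal_circles,
              n_sites = as.integer(n_sites),
              allele_freq = allele_freq,
              homoeolog_fixed_fraction = homoeolog_fixed_fraction,
              cytotype_fixed_fraction = cytotype_fixed_fraction,
              mean_depth = mean_depth,
              depth_model = match.arg(depth_model),
              depth_dispersion = depth_dispersion,
              error_rate = error_rate,
              selfing_F = selfing_F,
              circle_spacing_m = circle_spacing_m,
              area_side_m = area_side_m,
              conserved_fraction = conserved_fraction,
              fixed_dosage = fixed_dosage,
              polyploid_locus_count = as.integer(polyploid_locus_count),
              diploid_locus_count = as.integer(diploid_locus_count),
              total_loci = as.integer(total_loci),
              seed = as.integer(seed))
  if (is.null(names(cfg$ploidy_mix)) ||
      !setequal(names(cfg$ploidy_mix), c("2", "4", "8")))
    stop("ploidy_mix must be named with ploidies \"2\", \"4\", \"8\"")
  cfg$ploidy_mix <- cfg$ploidy_mix[c("2", "4", "8")]
  if (abs(sum(cfg$ploidy_mix) - 1) > 1e-8)
    stop("ploidy_mix proportions must sum to 1")
  fracs <- c(cfg$clonal_circles, cfg$homoeolog_fixed_fraction,
             cfg$cytotype_fixed_fraction,
             cfg$conserved_fraction, cfg$error_rate, cfg$selfing_F)
  if (any(fracs < 0 | fracs > 1))
    stop("fractions and rates must lie in [0, 1]")
  if (cfg$mean_depth <= 0) stop("mean_depth must be > 0")
  if (cfg$circle_spacing_m < 0) stop("circle_spacing_m must be >= 0")
  if (cfg$n_circles < 1L || cfg$samples_per_circle < 1L || cfg$n_sites < 1L)
    stop("n_circles, samples_per_circle and n_sites must be positive")
  class(cfg) <- "sim_config"
  cfg
}

draw_allele_freq <- function(n, spec) {
  if (is.function(spec)) return(spec(n))
  if (is.numeric(spec)) {
    if (length(spec) == 1L) return(rep(spec, n))
    stop("numeric allele_freq must be a single frequency")
  }
  u <- stats::runif(n)
  l <- 0.05; h <- 0.95
  switch(match.arg(spec, c("sfs", "neutral", "uniform")),
         # inverse-CDF draws from truncated power-law spectra
         sfs     = (l^-0.5 + u * (h^-0.5 - l^-0.5))^-2,  # density ~ p^-1.5
         neutral = l * (h / l)^u,                        # density ~ 1/p
         uniform = l + u * (h - l))
}

# dosage in {0,1,2} for one subgenome, with inbreeding F
draw_subgenome <- function(p, f_inb) {
  q <- 1 - p
  p0 <- q^2 + f_inb * p * q
  p1 <- 2 * p * q * (1 - f_inb)
  u <- stats::runif(length(p))
  ifelse(u < p0, 0L, ifelse(u < p0 + p1, 1L, 2L))
}

#' Simulate a mixed-ploidy clonality study
#'
#' Generates a full synthetic data set — variant table of per-sample allele
#' depths, sample sheet with circle geometry, per-sample haplotype-count
#' summary — together with the ground truth needed for parameter-recovery
#' tests.
#'
#' The genotype model: per site a population ALT frequency p is drawn from
#' the configured prior. A diploid genet draws dosage in \{0,1,2\} with
#' inbreeding F. An allotetraploid is two independent diploid subgenomes,
#' an octoploid four, except at the homoeolog-fixed sites where half the
#' subgenomes are fixed ALT and half fixed REF (dosage = ploidy/2),
#' mimicking fixed differences between homoeologous loci, and at the
#' cytotype-diagnostic sites where every polyploid subgenome is fixed ALT
#' (fixed divergence of the polyploid lineage from the diploid gene pool). Total read depth
#' per cell follows the configured depth model (overdispersed negative
#' binomial by default); ALT reads are Binomial(depth, q)
#' with q = dosage/ploidy adjusted for the per-read error rate
#' (q' = q(1-e) + (1-q)e, the exact distribution of per-read allele flips).
#' In a clonal circle all samples are ramets: identical genotype and ploidy.
#'
#' @param config a [sim_config()].
#' @return An object of class `fc_sim`: list with elements `variants`
#'   ([variant_table()]), `sheet` (`sample_sheet`), `hapcounts`
#'   (`hap_summary`), `truth` (list: `ploidy`, `genet_id`, `dosage`
#'   site-by-sample matrix, `selfing_F`) and `config`.
#' @examples
#' sim <- simulate_population(sim_config(n_circles = 2, n_sites = 50))
#' sim$variants
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- config$n_circles; spc <- config$samples_per_circle
  n_samples <- nc * spc
  L <- config$n_sites

  # --- geometry: jittered grid respecting the minimum spacing -------------
  k <- ceiling(sqrt(nc))
  pitch <- config$area_side_m / k
  if (0.8 * pitch < config$circle_spacing_m)
    stop("infeasible geometry: ", nc, " circles with spacing ",
         config$circle_spacing_m, " m do not fit in a ",
         config$area_side_m, " m square")
  grid <- expand.grid(gx = seq_len(k), gy = seq_len(k))[seq_len(nc), ]
  center_x <- (grid$gx - 0.5) * pitch + stats::runif(nc, -0.1, 0.1) * pitch
  center_y <- (grid$gy - 0.5) * pitch + stats::runif(nc, -0.1, 0.1) * pitch

  # --- site-level structure ----------------------------------------------
  p <- draw_allele_freq(L, config$allele_freq)
  n_homoeo <- round(config$homoeolog_fixed_fraction * L)
  homoeo_idx <- if (n_homoeo > 0L) sample.int(L, n_homoeo) else integer(0)
  n_cyto <- round(config$cytotype_fixed_fraction * L)
  cyto_idx <- if (n_cyto > 0L)
    sample(setdiff(seq_len(L), homoeo_idx), min(n_cyto, L - n_homoeo))
  else integer(0)
  conserved <- rep(FALSE, L)
  n_cons <- round(config$conserved_fraction * L)
  if (n_cons > 0L) conserved[sample.int(L, n_cons)] <- TRUE

  # --- genets: clonal circles share one genet ----------------------------
  n_clonal <- round(config$clonal_circles * nc)
  clonal_circle <- rep(FALSE, nc)
  if (n_clonal > 0L) clonal_circle[sample.int(nc, n_clonal)] <- TRUE
  circle_of_sample <- rep(seq_len(nc), each = spc)
  genet_of_sample <- integer(n_samples)
  next_genet <- 0L
  for (c_i in seq_len(nc)) {
    idx <- which(circle_of_sample == c_i)
    if (clonal_circle[c_i]) {
      next_genet <- next_genet + 1L
      genet_of_sample[idx] <- next_genet
    } else {
      genet_of_sample[idx] <- next_genet + seq_along(idx)
      next_genet <- next_genet + length(idx)
    }
  }
  n_genets <- next_genet
  genet_ploidy <- sample(c(2L, 4L, 8L), n_genets, replace = TRUE,
                         prob = config$ploidy_mix)

  # --- genotypes (ALT dosage per site) per genet -------------------------
  dosage_genet <- matrix(0L, nrow = L, ncol = n_genets)
  for (g in seq_len(n_genets)) {
    m <- genet_ploidy[g] %/% 2L     # number of diploid subgenomes
    dos <- integer(L)
    for (s in seq_len(m)) dos <- dos + draw_subgenome(p, config$selfing_F)
    if (genet_ploidy[g] >= 4L) {
      if (length(homoeo_idx)) dos[homoeo_idx] <- m  # half the subgenomes ALT
      if (length(cyto_idx)) dos[cyto_idx] <- 2L * m # diverged from diploids
    }
    dosage_genet[, g] <- dos
  }
  if (!is.na(config$fixed_dosage)) {
    for (g in seq_len(n_genets))
      dosage_genet[, g] <- min(as.integer(config$fixed_dosage),
                               genet_ploidy[g])
  }

  sample_ploidy <- genet_ploidy[genet_of_sample]
  dosage <- dosage_genet[, genet_of_sample, drop = FALSE]

  # --- reads --------------------------------------------------------------
  e <- config$error_rate
  q_true <- sweep(dosage, 2L, sample_ploidy, "/")
  q_read <- q_true * (1 - e) + (1 - q_true) * e
  depth <- matrix(
    if (config$depth_model == "poisson")
      stats::rpois(L * n_samples, config$mean_depth)
    else
      stats::rnbinom(L * n_samples, size = config$depth_dispersion,
                     mu = config$mean_depth),
    nrow = L)
  alt <- matrix(stats::rbinom(L * n_samples, as.vector(depth),
                              as.vector(q_read)), nrow = L)
  ref <- depth - alt

  circle_ids <- sprintf("c%02d", seq_len(nc))
  sample_ids <- sprintf("%s-%d", circle_ids[circle_of_sample],
                        sequence(rep(spc, nc)))
  site_ids <- sprintf("chr1:%d", seq_len(L))
  vt <- variant_table(ref, alt, site_ids, sample_ids, conserved)

  pos_label <- function(j) {
    if (j == 1L) "near_1" else if (j == 2L) "near_2"
    else if (j == 3L) "far_3" else sprintf("extra_%d", j)
  }
  sheet <- data.frame(
    sample_id = sample_ids,
    circle_id = circle_ids[circle_of_sample],
    position_label = vapply(sequence(rep(spc, nc)), pos_label, character(1)),
    center_x = center_x[circle_of_sample],
    center_y = center_y[circle_of_sample],
    stringsAsFactors = FALSE)
  sheet <- suppressWarnings(validate_sample_sheet(sheet, vt))

  # --- haplotype-count summary (summary level, not per-locus) ------------
  is_poly <- sample_ploidy >= 4L
  n3 <- integer(n_samples)
  n3[is_poly] <- config$polyploid_locus_count +
    stats::rpois(sum(is_poly), round(0.1 * config$polyploid_locus_count))
  n3[!is_poly] <- stats::rbinom(sum(!is_poly),
                                config$diploid_locus_count, 0.5)
  n2 <- round(0.3 * (config$total_loci - n3))
  hc <- data.frame(sample_id = sample_ids,
                   n_loci_1hap = config$total_loci - n2 - n3,
                   n_loci_2hap = n2,
                   n_loci_3plus_hap = n3,
                   stringsAsFactors = FALSE)
  class(hc) <- c("hap_summary", "data.frame")

  truth <- list(
    ploidy = stats::setNames(sample_ploidy, sample_ids),
    genet_id = stats::setNames(sprintf("g%03d", genet_of_sample), sample_ids),
    dosage = `dimnames<-`(dosage, list(site_ids, sample_ids)),
    selfing_F = config$selfing_F)

  structure(list(variants = vt, sheet = sheet, hapcounts = hc,
                 truth = truth, config = config),
            class = "fc_sim")
}

#' @export
print.fc_sim <- function(x, ...) {
  tab <- table(x$truth$ploidy)
  cat(sprintf("fc_sim: %d samples (%d circles x %d), %d sites\n",
              length(x$truth$ploidy), x$config$n_circles,
              x$config$samples_per_circle, x$config$n_sites))
  cat("  ploidy:", paste(sprintf("%sn=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  genets: %d; clonal circle fraction: %.2f\n",
              length(unique(x$truth$genet_id)), x$config$clonal_circles))
  invisible(x)
}

#' Write a simulated data set to disk
#'
#' Emits the variant table as VCF, the sample sheet and haplotype summary
#' as TSV, and the ground truth as JSON, into `dir`.
#'
#' @param sim an `fc_sim` from [simulate_population()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "fc_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    variants = file.path(dir, "variants.vcf"),
    sheet = file.path(dir, "samples.tsv"),
    hapcounts = file.path(dir, "hapcounts.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_variant_table(sim$variants, paths[["variants"]])
  write_sample_sheet(sim$sheet, paths[["sheet"]])
  write_hapcounts(sim$hapcounts, paths[["hapcounts"]])
  truth <- sim$truth
  truth$dosage <- NULL   # matrix ground truth kept in-memory only
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
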