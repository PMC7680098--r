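#' Recode per-sample genotypes into the ternary code \{0, 0.5, 1\}
#'
#' The recoding that makes diploid and polyploid samples comparable: per
#' cell, with f = alt/(alt+ref), a site is coded 0 when f <= tau (only the
#' reference allele is credibly present), 1 when f >= 1 - tau, and 0.5
#' otherwise (both alleles at more than `tau` of the reads). The
#' heterozygous band is deliberately wide because in an allopolyploid reads
#' are sampled from four (or eight) haplotypes, and fixed homoeologous
#' differences legitimately produce intermediate allele balance.
#'
#' Site filters, applied in order:
#' \enumerate{
#'   \item `conserved_only`: keep only sites flagged as the stringent
#'     conserved subset;
#'   \item depth: keep only sites with total depth >= `min_depth` in
#'     *every* selected sample (full-coverage requirement, so no missing
#'     cells remain);
#'   \item `min_individuals_variant`: keep only sites with a non-reference
#'     code (0.5 or 1) in at least that many samples.
#' }
#'
#' @param vt a [variant_table()].
#' @param samples samples to include (ids or indices; default all).
#' @param min_depth per-cell total-depth threshold (>=, default 11).
#' @param het_threshold tau, the strict band edge for calling 0.5
#'   (default 0.05: a cell is heterozygous only when *more than* 5% of
#'   reads support each allele).
#' @param min_individuals_variant minimum number of samples that must carry
#'   a non-reference code for a site to be kept (default 1; the robustness
#'   setting of 2 excludes singleton artefacts).
#' @param conserved_only restrict to the conserved site subset.
#' @return Object of class `recoded_matrix`: list with `site_ids`,
#'   `sample_ids`, `values` (site x sample matrix over \{0, 0.5, 1\}) and
#'   `provenance` (the filter settings and per-filter drop counts).
#' @examples
#' sim <- simulate_population(sim_config(n_circles = 2, n_sites = 300))
#' m <- recode_genotypes(sim$variants)
#' table(m$values)
#' @export
recode_genotypes <- function(vt, samples = NULL, min_depth = 11,
                             het_threshold = 0.05,
                             min_individuals_variant = 1L,
                             conserved_only = FALSE) {
  stopifnot(inherits(vt, "variant_table"))
  if (het_threshold < 0 || het_threshold >= 0.5)
    stop("het_threshold must lie in [0, 0.5)")
  if (!is.null(samples)) vt <- subset_variant_table(vt, samples = samples)

  drops <- c(conserved = 0L, depth = 0L, min_individuals = 0L)
  if (conserved_only) {
    drops[["conserved"]] <- sum(!vt$conserved_flag)
    if (!any(vt$conserved_flag))
      stop("zero surviving sites: conserved_only removed all sites")
    vt <- subset_variant_table(vt, sites = which(vt$conserved_flag))
  }

  total <- vt$ref_depth + vt$alt_depth
  deep <- rowSums(total >= min_depth) == ncol(total)
  drops[["depth"]] <- sum(!deep)
  if (!any(deep))
    stop("zero surviving sites: all-samples depth filter (min_depth = ",
         min_depth, ") removed all sites")
  vt <- subset_variant_table(vt, sites = which(deep))
  total <- total[deep, , drop = FALSE]

  f <- vt$alt_depth / total
  tau <- het_threshold
  values <- matrix(0.5, nrow = nrow(f), ncol = ncol(f),
                   dimnames = dimnames(f))
  values[f <= tau] <- 0
  values[f >= 1 - tau] <- 1

  if (min_individuals_variant > 0L) {
    n_nonref <- rowSums(values > 0)
    keep <- n_nonref >= min_individuals_variant
    drops[["min_individuals"]] <- sum(!keep)
    if (!any(keep))
      stop("zero surviving sites: min_individuals_variant = ",
           min_individuals_variant, " removed all sites")
    values <- values[keep, , drop = FALSE]
    vt <- subset_variant_table(vt, sites = which(keep))
  }

  structure(list(site_ids = vt$site_ids, sample_ids = vt$sample_ids,
                 values = values,
                 provenance = list(min_depth_all_samples = min_depth,
                                   het_threshold = het_threshold,
                                   min_individuals_variant =
                                     as.integer(min_individuals_variant),
                                   conserved_only = conserved_only,
                                   sites_dropped = drops)),
            class = "recoded_matrix")
}

#' @export
print.recoded_matrix <- function(x, ...) {
  tab <- table(factor(x$values, levels = c(0, 0.5, 1)))
  cat(sprintf("recoded_matrix: %d sites x %d samples (tau = %g%s)\n",
              nrow(x$values), ncol(x$values), x$provenance$het_threshold,
              if (x$provenance$conserved_only) ", conserved subset" else ""))
  cat(sprintf("  codes 0 / 0.5 / 1: %d / %d / %d\n",
              tab[["0"]], tab[["0.5"]], tab[["1"]]))
  invisible(x)
}

#' Write a recoded genotype matrix as TSV (sites as rows)
#' @param m a `recoded_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recoded_matrix <- function(m, path) {
  stopifnot(inherits(m, "recoded_matrix"))
  utils::write.table(m$values, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
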