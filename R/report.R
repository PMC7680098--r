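#' Full clonality analysis of a mixed-ploidy cohort
#'
#' The package's main entry point for the relatedness analysis: recodes
#' genotypes, computes Euclidean genetic distances, clusters the samples,
#' extracts minimum within- and between-circle distances, compares them
#' with a Wilcoxon rank-sum test, fits the genetic-versus-spatial
#' distance-decay regression, and calls clone pairs.
#'
#' If every circle's ring were a single spreading genet (the clonality
#' hypothesis), the within-circle minima would sit at ~0 and far below the
#' between-circle minima; unstructured minima and a flat distance decay
#' argue against clonality.
#'
#' @param vt a [variant_table()].
#' @param sheet a `sample_sheet` covering the same samples.
#' @param min_depth,het_threshold,min_individuals_variant,conserved_only
#'   recoding filters, see [recode_genotypes()].
#' @param linkage clustering linkage, see [hierarchical_cluster()].
#' @param epsilon clone-calling distance threshold (default 0).
#' @param per_site normalise distances by sqrt(site count)?
#' @return Object of class `fc_clonality`: list with `recoded`, `dist`,
#'   `dendrogram`, `within`, `between`, `wilcoxon`, `decay`, `clones`,
#'   `epsilon_recommended` (1st percentile of all between-circle pairwise
#'   distances — reported as a suggestion for noisy data, never applied
#'   silently) and `sheet`.
#' @examples
#' sim <- simulate_population(sim_config(n_circles = 4, n_sites = 500))
#' rep <- fc_clonality(sim$variants, sim$sheet)
#' print(rep)
#' @export
fc_clonality <- function(vt, sheet, min_depth = 11, het_threshold = 0.05,
                         min_individuals_variant = 1L,
                         conserved_only = FALSE,
                         linkage = "complete", epsilon = 0,
                         per_site = FALSE) {
  stopifnot(inherits(vt, "variant_table"))
  m <- recode_genotypes(vt, samples = sheet$sample_id,
                        min_depth = min_depth,
                        het_threshold = het_threshold,
                        min_individuals_variant = min_individuals_variant,
                        conserved_only = conserved_only)
  d <- genetic_distance_matrix(m, per_site = per_site)
  dend <- hierarchical_cluster(d, linkage = linkage)
  mwb <- min_within_between(d, sheet)
  wil <- if (length(mwb$within) && nrow(mwb$between))
    wilcoxon_rank_sum(mwb$within, mwb$between$min_dist) else NULL
  dec <- if (nrow(mwb$between) >= 3L) distance_decay(mwb$between, sheet)
         else NULL
  clones <- call_clones(d, epsilon = epsilon)
  circ <- sheet$circle_id[match(d$sample_ids, sheet$sample_id)]
  cross <- outer(circ, circ, "!=") & upper.tri(d$d)
  eps_rec <- if (any(cross))
    unname(stats::quantile(d$d[cross], 0.01)) else NA_real_
  structure(list(recoded = m, dist = d, dendrogram = dend,
                 within = mwb$within, between = mwb$between,
                 wilcoxon = wil, decay = dec, clones = clones,
                 epsilon_recommended = eps_rec, sheet = sheet),
            class = "fc_clonality")
}

#' @export
print.fc_clonality <- function(x, ...) {
  cat(sprintf("fc_clonality: %d samples, %d circles, %d sites\n",
              length(x$dist$sample_ids),
              length(unique(x$sheet$circle_id)), nrow(x$recoded$values)))
  cat(sprintf("  minimum distances: %d within-circle, %d between-circle\n",
              length(x$within), nrow(x$between)))
  if (!is.null(x$wilcoxon))
    cat(sprintf("  rank-sum within vs between: W = %g, p = %.4g (%s)\n",
                x$wilcoxon$statistic, x$wilcoxon$p_value,
                if (x$wilcoxon$exact) "exact" else "normal approx."))
  if (!is.null(x$decay))
    cat(sprintf("  distance decay: slope = %.4g per m, r = %.3f%s\n",
                x$decay$slope, x$decay$r,
                if (x$decay$degenerate) " [degenerate]" else ""))
  cat(sprintf("  clone pairs at epsilon = %g: %d (suggested epsilon: %.4g)\n",
              attr(x$clones, "epsilon"), nrow(x$clones),
              x$epsilon_recommended))
  invisible(x)
}

#' @export
summary.fc_clonality <- function(object, ...) {
  print(object)
  cat("\nwithin-circle minima:\n")
  print(round(object$within, 4))
  cat("\nbetween-circle minima (first rows):\n")
  print(utils::head(object$between))
  invisible(object)
}

#' @export
plot.fc_clonality <- function(x, which = c("dendrogram", "minima", "decay"),
                              ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- par(mfrow = c(1, length(which)))
  on.exit(par(old))
  if ("dendrogram" %in% which) plot(x$dendrogram)
  if ("minima" %in% which)
    boxplot(list(within = x$within, between = x$between$min_dist),
            ylab = "minimum genetic distance",
            main = "within vs between circles")
  if ("decay" %in% which && !is.null(x$decay)) {
    plot(x$decay$data$spatial_dist, x$decay$data$genetic_dist,
         xlab = "distance between circle centres (m)",
         ylab = "minimum genetic distance", main = "distance decay")
    abline(x$decay$intercept, x$decay$slope, col = "grey40")
  }
  invisible(x)
}

#' Export a clonality report as JSON
#'
#' Writes the scalar results (counts, rank-sum test, decay fit, clone
#' pairs, recommended epsilon) plus the within/between minima.
#'
#' @param x an `fc_clonality`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_clonality_report <- function(x, path) {
  stopifnot(inherits(x, "fc_clonality"))
  out <- list(
    n_samples = length(x$dist$sample_ids),
    n_sites = nrow(x$recoded$values),
    within_min = as.list(x$within),
    between_min = x$between,
    wilcoxon = x$wilcoxon,
    decay = if (is.null(x$decay)) NULL else
      x$decay[c("slope", "intercept", "r", "degenerate", "n_pairs")],
    clone_pairs = as.data.frame(x$clones),
    epsilon = attr(x$clones, "epsilon"),
    epsilon_recommended = x$epsilon_recommended,
    filters = x$recoded$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
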