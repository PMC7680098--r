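#' Labelled symmetric distance matrix
#'
#' @param m square symmetric numeric matrix with matching dimnames.
#' @param metric metric label, e.g. `"euclidean"`.
#' @return Object of class `dist_matrix`: list with `sample_ids`, `d`
#'   (matrix) and `metric`.
#' @export
dist_matrix <- function(m, metric = "euclidean") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m))) stop("distance matrix must be labelled")
  if (any(m < 0)) stop("distances must be non-negative")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix must be symmetric")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(list(sample_ids = rownames(m), d = m, metric = metric),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  off <- x$d[upper.tri(x$d)]
  cat(sprintf("dist_matrix (%s): %d samples; range %.4g..%.4g\n",
              x$metric, nrow(x$d),
              if (length(off)) min(off) else NA, if (length(off)) max(off) else NA))
  invisible(x)
}

#' Euclidean genetic distances between recoded genotype columns
#'
#' d(i, j) = sqrt(sum over sites of (m[s,i] - m[s,j])^2) on the ternary
#' codes. Raw (unnormalised) by default, so the scale grows with the site
#' count; `per_site = TRUE` divides by sqrt(number of sites) for
#' comparisons across filters with different site counts.
#'
#' @param m a `recoded_matrix` (or a plain site-by-sample numeric matrix
#'   with column names).
#' @param per_site normalise by sqrt(n_sites)?
#' @return A [dist_matrix()].
#' @examples
#' g <- matrix(c(0, 0.5, 0.5, 1), 2, dimnames = list(NULL, c("a", "b")))
#' genetic_distance_matrix(g)$d["a", "b"]   # sqrt(0.25 + 0.25)
#' @export
genetic_distance_matrix <- function(m, per_site = FALSE) {
  values <- if (inherits(m, "recoded_matrix")) m$values else as.matrix(m)
  if (ncol(values) < 2L) stop("need at least 2 samples")
  if (nrow(values) < 1L) stop("need at least 1 site")
  d <- as.matrix(stats::dist(t(values), method = "euclidean"))
  if (per_site) d <- d / sqrt(nrow(values))
  dist_matrix(d, metric = if (per_site) "euclidean/site" else "euclidean")
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' A thin, deterministic front end to [stats::hclust()]. Supported
#' linkages: complete (default), average, single. At equal candidate merge
#' heights the pair containing the smallest member index (input order) is
#' merged first, which is `hclust`'s own deterministic rule.
#'
#' @param d a [dist_matrix()].
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return Object of class `dendrogram_fc`: list with `hclust` (the fitted
#'   tree), `linkage`, `leaf_order` (sample ids in dendrogram order).
#' @export
hierarchical_cluster <- function(d, linkage = c("complete", "average",
                                                "single")) {
  stopifnot(inherits(d, "dist_matrix"))
  linkage <- match.arg(linkage)
  if (!all(is.finite(d$d))) stop("non-finite distances")
  hc <- stats::hclust(stats::as.dist(d$d), method = linkage)
  structure(list(hclust = hc, linkage = linkage,
                 leaf_order = d$sample_ids[hc$order]),
            class = "dendrogram_fc")
}

#' @export
print.dendrogram_fc <- function(x, ...) {
  cat(sprintf("dendrogram (%s linkage): %d leaves, height %.4g\n",
              x$linkage, length(x$leaf_order), max(x$hclust$height)))
  invisible(x)
}

#' @export
plot.dendrogram_fc <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "",
       main = sprintf("hierarchical clustering (%s linkage)", x$linkage),
       ...)
  invisible(x)
}

#' Cophenetic distances of a dendrogram
#' @param dend a `dendrogram_fc`.
#' @return labelled symmetric matrix of cophenetic (merge-height) distances.
#' @export
cophenetic_matrix <- function(dend) {
  stopifnot(inherits(dend, "dendrogram_fc"))
  as.matrix(stats::cophenetic(dend$hclust))
}

#' Call clone pairs from a distance matrix
#'
#' All unordered sample pairs at distance `epsilon` or less. With
#' error-free data clones are at distance exactly 0, so the default is
#' `epsilon = 0`; for noisy data choose a small threshold (e.g. the 1st
#' percentile of the between-circle distance distribution, reported by
#' [fc_clonality()]) and pass it explicitly.
#'
#' @param d a [dist_matrix()].
#' @param epsilon maximum distance for a pair to be called clonal (>= 0).
#' @return Object of class `clone_pairs`: data.frame with columns
#'   `sample_1`, `sample_2`, `distance`; attribute `epsilon`.
#' @export
call_clones <- function(d, epsilon = 0) {
  stopifnot(inherits(d, "dist_matrix"))
  if (epsilon < 0) stop("epsilon must be >= 0")
  ut <- which(upper.tri(d$d) & d$d <= epsilon, arr.ind = TRUE)
  pairs <- data.frame(
    sample_1 = d$sample_ids[ut[, 1L]],
    sample_2 = d$sample_ids[ut[, 2L]],
    distance = d$d[ut],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$sample_1, pairs$sample_2), , drop = FALSE]
  rownames(pairs) <- NULL
  attr(pairs, "epsilon") <- epsilon
  class(pairs) <- c("clone_pairs", "data.frame")
  pairs
}

#' @export
print.clone_pairs <- function(x, ...) {
  cat(sprintf("clone_pairs: %d pair(s) at epsilon = %g\n", nrow(x),
              attr(x, "epsilon")))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}
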