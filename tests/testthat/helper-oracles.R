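# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid stats::hclust / stats::wilcox.test internals.

# O(n^3) naive agglomerative clustering; returns the cophenetic matrix.
naive_cophenetic <- function(D, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  cluster_dist <- function(a, b) {
    vals <- D[a, b, drop = FALSE]
    switch(linkage, complete = max(vals), single = min(vals),
           average = mean(vals))
  }
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      h <- cluster_dist(clusters[[i]], clusters[[j]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    coph[clusters[[bi]], clusters[[bj]]] <- best
    coph[clusters[[bj]], clusters[[bi]]] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  coph
}

# Exhaustive two-sided rank-sum p-value by enumerating all C(n+m, n) group
# assignments (tie-free data only).
perm_wilcox_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_of(x, y)
  splits <- utils::combn(length(pooled), n)
  us <- apply(splits, 2L, function(ii) u_of(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Exhaustive per-circle minimum-distance scan (independent of the package's
# vectorised implementation).
naive_min_within_between <- function(D, circle) {
  D <- as.matrix(D)
  ids <- rownames(D)
  circles <- unique(circle)
  within <- c()
  for (ci in circles) {
    idx <- which(circle == ci)
    if (length(idx) < 2L) next
    best <- Inf
    for (a in idx) for (b in idx) if (a < b) best <- min(best, D[a, b])
    within[ci] <- best
  }
  between <- NULL
  for (i in seq_along(circles)) for (j in seq_along(circles)) if (i < j) {
    best <- Inf
    for (a in which(circle == circles[i]))
      for (b in which(circle == circles[j])) best <- min(best, D[a, b])
    between <- rbind(between,
                     data.frame(circle_1 = circles[i], circle_2 = circles[j],
                                min_dist = best, stringsAsFactors = FALSE))
  }
  list(within = within, between = between)
}

# Small hand-built fixtures -------------------------------------------------

make_vt <- function(ref, alt, conserved = NULL) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  variant_table(ref, alt,
                site_ids = sprintf("chr1:%d", seq_len(nrow(ref))),
                sample_ids = sprintf("s%d", seq_len(ncol(ref))),
                conserved_flag = conserved)
}

make_spectrum <- function(freqs, sample_id = "sX") {
  structure(list(sample_id = sample_id, frequencies = freqs,
                 filters = list(min_depth = 11, bounds = c(0.05, 0.95)),
                 n_dropped_depth = 0L, n_dropped_bounds = 0L,
                 low_confidence = length(freqs) < 50L),
            class = "af_spectrum")
}

make_recoded <- function(values) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("chr1:%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  structure(list(site_ids = rownames(values), sample_ids = colnames(values),
                 values = values,
                 provenance = list(min_depth_all_samples = 11,
                                   het_threshold = 0.05,
                                   min_individuals_variant = 1L,
                                   conserved_only = FALSE,
                                   sites_dropped = c(conserved = 0L,
                                                     depth = 0L,
                                                     min_individuals = 0L))),
            class = "recoded_matrix")
}

make_hap_summary <- function(sample_id, n3, total = 60000L) {
  df <- data.frame(sample_id = sample_id,
                   n_loci_1hap = total - 1000L - n3,
                   n_loci_2hap = 1000L,
                   n_loci_3plus_hap = n3,
                   stringsAsFactors = FALSE)
  class(df) <- c("hap_summary", "data.frame")
  df
}
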