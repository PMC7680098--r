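#' Construct a variant table of per-sample allele depths
#'
#' The central input container: for each biallelic SNP site and each sample,
#' the number of reads supporting the reference and the alternative allele.
#' An optional per-site flag marks a "conserved subset" of sites (e.g. loci
#' mappable to a well-annotated related genome) used for stringent re-analysis.
#'
#' @param ref_depth integer matrix, sites x samples, reads supporting REF.
#' @param alt_depth integer matrix, same shape, reads supporting ALT.
#' @param site_ids character vector of unique site identifiers
#'   (conventionally "chrom:pos", 1-based positions).
#' @param sample_ids character vector of unique sample identifiers.
#' @param conserved_flag logical vector, one per site; defaults to all FALSE.
#' @return An object of class `variant_table`: a list with fields
#'   `site_ids`, `sample_ids`, `ref_depth`, `alt_depth`, `conserved_flag`.
#' @examples
#' vt <- variant_table(matrix(10, 3, 2), matrix(0:5, 3, 2),
#'                     site_ids = paste0("chr1:", 1:3),
#'                     sample_ids = c("s1", "s2"))
#' dim(vt)
#' @export
variant_table <- function(ref_depth, alt_depth, site_ids, sample_ids,
                          conserved_flag = NULL) {
  ref_depth <- as.matrix(ref_depth)
  alt_depth <- as.matrix(alt_depth)
  if (!identical(dim(ref_depth), dim(alt_depth)))
    stop("ref_depth and alt_depth must have identical dimensions")
  if (any(ref_depth < 0, na.rm = TRUE) || any(alt_depth < 0, na.rm = TRUE))
    stop("allele depths must be non-negative")
  site_ids <- as.character(site_ids)
  sample_ids <- as.character(sample_ids)
  if (length(site_ids) != nrow(ref_depth))
    stop("length(site_ids) must equal nrow(ref_depth)")
  if (length(sample_ids) != ncol(ref_depth))
    stop("length(sample_ids) must equal ncol(ref_depth)")
  if (anyDuplicated(site_ids)) stop("site_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (is.null(conserved_flag)) conserved_flag <- rep(FALSE, length(site_ids))
  if (length(conserved_flag) != length(site_ids))
    stop("conserved_flag must have one entry per site")
  dimnames(ref_depth) <- dimnames(alt_depth) <- list(site_ids, sample_ids)
  structure(
    list(site_ids = site_ids, sample_ids = sample_ids,
         ref_depth = ref_depth, alt_depth = alt_depth,
         conserved_flag = as.logical(conserved_flag)),
    class = "variant_table")
}

#' @export
dim.variant_table <- function(x) dim(x$ref_depth)

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d biallelic sites x %d samples\n",
              nrow(x$ref_depth), ncol(x$ref_depth)))
  cat(sprintf("  conserved subset: %d sites\n", sum(x$conserved_flag)))
  cat(sprintf("  mean total depth: %.1f\n",
              mean(x$ref_depth + x$alt_depth)))
  invisible(x)
}

#' Subset a variant table
#'
#' @param x a `variant_table`.
#' @param sites site indices, ids or logical mask (default all).
#' @param samples sample indices, ids or logical mask (default all).
#' @return A `variant_table` restricted to the requested sites/samples,
#'   in the requested order.
#' @export
subset_variant_table <- function(x, sites = NULL, samples = NULL) {
  si <- if (is.null(sites)) seq_along(x$site_ids) else sites
  sa <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  if (is.character(si)) si <- match(si, x$site_ids)
  if (is.character(sa)) sa <- match(sa, x$sample_ids)
  if (anyNA(si)) stop("unknown site id in subset")
  if (anyNA(sa)) stop("unknown sample id in subset")
  variant_table(x$ref_depth[si, sa, drop = FALSE],
                x$alt_depth[si, sa, drop = FALSE],
                x$site_ids[si], x$sample_ids[sa],
                x$conserved_flag[si])
}
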