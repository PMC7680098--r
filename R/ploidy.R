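#' Alternative-allele-balance spectrum for one sample
#'
#' For each site, the fraction of reads supporting the alternative allele,
#' f = alt / (alt + ref), retained only when the site's total depth reaches
#' `min_depth` and f lies strictly inside `bounds`. The bounds remove
#' homozygous sites (and sequencing-error tails), so the spectrum is carried
#' by sites where the sample holds both alleles: its peaks sit near
#' dosage/ploidy — 0.5 for a diploid heterozygote, 0.25 for a simplex
#' tetraploid site, 0.125 for a 1-of-8 octoploid site.
#'
#' @param vt a [variant_table()].
#' @param sample sample id (or index).
#' @param min_depth minimum total depth per site (default 11, i.e. >= 11
#'   reads).
#' @param bounds length-2 numeric; frequencies at or outside these bounds
#'   are dropped (default 0.05 and 0.95, strict).
#' @return Object of class `af_spectrum`: list with `sample_id`,
#'   `frequencies`, `filters`, drop counts, and `low_confidence` (TRUE when
#'   fewer than 50 sites survive).
#' @export
allele_frequency_spectrum <- function(vt, sample, min_depth = 11,
                                      bounds = c(0.05, 0.95)) {
  stopifnot(inherits(vt, "variant_table"))
  if (is.character(sample) && !sample %in% vt$sample_ids)
    stop("sample not in variant table: ", sample)
  j <- if (is.character(sample)) match(sample, vt$sample_ids) else sample
  ref <- vt$ref_depth[, j]
  alt <- vt$alt_depth[, j]
  total <- ref + alt
  deep <- total >= min_depth
  f <- alt[deep] / total[deep]
  in_bounds <- f > bounds[1L] & f < bounds[2L]
  freqs <- f[in_bounds]
  spec <- list(sample_id = vt$sample_ids[j],
               frequencies = as.numeric(freqs),
               filters = list(min_depth = min_depth, bounds = bounds),
               n_dropped_depth = sum(!deep),
               n_dropped_bounds = sum(!in_bounds),
               low_confidence = length(freqs) < 50L)
  if (spec$low_confidence)
    warning("only ", length(freqs), " sites retained for ",
            spec$sample_id, "; ploidy calls will be low-confidence",
            call. = FALSE)
  class(spec) <- "af_spectrum"
  spec
}

#' @export
print.af_spectrum <- function(x, ...) {
  cat(sprintf("af_spectrum for %s: %d sites retained (mode %.3f)%s\n",
              x$sample_id, length(x$frequencies),
              if (length(x$frequencies)) spectrum_mode(x) else NA_real_,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Histogram mode of an allele-balance spectrum
#'
#' The spectrum is binned over (0, 1) with fixed-width bins and the centre
#' of the fullest bin is returned. Ties are broken toward the lower bin so
#' a symmetric simplex/triplex tetraploid pair of peaks (0.25 / 0.75)
#' resolves to the sub-0.5 peak.
#'
#' @param spec an `af_spectrum` (or a bare numeric vector of frequencies).
#' @param bin_width histogram bin width (default 0.02).
#' @return the modal bin centre, a single numeric.
#' @export
spectrum_mode <- function(spec, bin_width = 0.02) {
  f <- if (inherits(spec, "af_spectrum")) spec$frequencies else as.numeric(spec)
  if (length(f) == 0L) stop("empty spectrum: no retained frequencies")
  if (any(f <= 0 | f >= 1)) stop("frequencies must lie strictly in (0, 1)")
  n_bins <- ceiling(1 / bin_width)
  bin <- pmin(ceiling(f / bin_width), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  (which.max(counts) - 0.5) * bin_width    # which.max takes the lowest tie
}

#' Call ploidy from a spectrum's modal allele balance
#'
#' The mode is matched to the candidate peaks 1/2, 1/4, 1/8 of the three
#' ploidy classes; the nearest candidate wins. A mode above 0.7, or a mode
#' exactly equidistant between two candidates, is flagged `ambiguous`; in
#' [combine_ploidy_calls()] the haplotype-count evidence then takes
#' precedence.
#'
#' @param spec an `af_spectrum`.
#' @param bin_width passed to [spectrum_mode()].
#' @return A `ploidy_call`: list with `sample_id`, `ploidy`,
#'   `spectrum_mode`, `method = "spectrum"`, `flags`.
#' @export
estimate_ploidy_from_spectrum <- function(spec, bin_width = 0.02) {
  stopifnot(inherits(spec, "af_spectrum"))
  m <- spectrum_mode(spec, bin_width)
  candidates <- c("2" = 0.5, "4" = 0.25, "8" = 0.125)
  dd <- abs(m - candidates)
  ploidy <- as.integer(names(candidates)[which.min(dd)])
  flags <- character(0)
  if (m > 0.7 || sum(dd == min(dd)) > 1L) flags <- c(flags, "ambiguous")
  if (spec$low_confidence) flags <- c(flags, "low_confidence")
  new_ploidy_call(spec$sample_id, ploidy, method = "spectrum",
                  spectrum_mode = m, flags = flags)
}

#' Classify diploid vs polyploid from haplotype counts
#'
#' A RAD locus with three or more distinct haplotypes in one sample cannot
#' come from a diploid (barring error); samples with more than `threshold`
#' such loci are called polyploid. The classifier cannot tell tetraploid
#' from octoploid, so polyploids are reported as ploidy 4 with the flag
#' `polyploid_unresolved`.
#'
#' @param lh a `hap_summary` data.frame (see [read_hapcounts()]) or a
#'   single-row subset of one.
#' @param sample sample id; may be omitted when `lh` has one row.
#' @param threshold count of >= 3-haplotype loci that must be exceeded
#'   (strictly) to call polyploid. Default 1000.
#' @return A `ploidy_call` with `method = "haplotype_counts"`.
#' @export
classify_by_haplotype_counts <- function(lh, sample = NULL, threshold = 1000) {
  df <- as.data.frame(lh)
  if (!is.null(sample)) df <- df[df$sample_id == sample, , drop = FALSE]
  if (nrow(df) != 1L)
    stop("need exactly one haplotype-summary row (got ", nrow(df), ")")
  n3 <- df$n_loci_3plus_hap
  polyploid <- n3 > threshold
  new_ploidy_call(df$sample_id,
                  ploidy = if (polyploid) 4L else 2L,
                  method = "haplotype_counts",
                  n_loci_3plus_hap = n3,
                  flags = if (polyploid) "polyploid_unresolved" else character(0))
}

#' Reconcile spectrum- and haplotype-count-based ploidy calls
#'
#' When the two lines of evidence agree on diploid vs polyploid, the
#' spectrum call (which resolves 4n from 8n) is returned. When they
#' disagree, the spectrum call is kept but flagged `discordant` — unless
#' the spectrum call was itself flagged `ambiguous`, in which case the
#' haplotype-count call takes precedence.
#'
#' @param spectrum_call,haplotype_call `ploidy_call`s for the same sample.
#' @return A combined `ploidy_call` (`method = "combined"`).
#' @export
combine_ploidy_calls <- function(spectrum_call, haplotype_call) {
  stopifnot(inherits(spectrum_call, "ploidy_call"),
            inherits(haplotype_call, "ploidy_call"))
  if (!identical(spectrum_call$sample_id, haplotype_call$sample_id))
    stop("calls are for different samples")
  flags <- union(spectrum_call$flags, haplotype_call$flags)
  if ("ambiguous" %in% spectrum_call$flags) {
    out <- haplotype_call
  } else {
    out <- spectrum_call
    concordant <- (spectrum_call$ploidy >= 4L) == (haplotype_call$ploidy >= 4L)
    if (!concordant) flags <- c(flags, "discordant")
  }
  new_ploidy_call(out$sample_id, out$ploidy, method = "combined",
                  spectrum_mode = spectrum_call$spectrum_mode,
                  n_loci_3plus_hap = haplotype_call$n_loci_3plus_hap,
                  flags = flags)
}

new_ploidy_call <- function(sample_id, ploidy, method,
                            spectrum_mode = NA_real_,
                            n_loci_3plus_hap = NA_integer_,
                            flags = character(0)) {
  structure(list(sample_id = sample_id, ploidy = as.integer(ploidy),
                 spectrum_mode = spectrum_mode,
                 n_loci_3plus_hap = n_loci_3plus_hap,
                 method = method, flags = unique(flags)),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("%s: %dn [%s]%s\n", x$sample_id, x$ploidy, x$method,
              if (length(x$flags)) paste0(" (", paste(x$flags, collapse = ","),
                                          ")") else ""))
  invisible(x)
}

#' Call ploidy for every sample in a cohort
#'
#' Runs the allele-balance spectrum and, when a haplotype-count summary is
#' supplied, the haplotype-count classifier for each sample, and combines
#' the evidence with [combine_ploidy_calls()].
#'
#' @param vt a [variant_table()].
#' @param lh optional `hap_summary` covering the same samples.
#' @param min_depth,bounds spectrum filters, see
#'   [allele_frequency_spectrum()].
#' @param bin_width histogram bin width for the mode.
#' @param hap_threshold polyploidy threshold on loci with >= 3 haplotypes.
#' @return Object of class `fc_ploidy`: list with `calls` (a data.frame:
#'   sample_id, ploidy, spectrum_mode, n_retained, n_loci_3plus_hap,
#'   method, flags) and `spectra` (named list of `af_spectrum`).
#' @examples
#' sim <- simulate_population(sim_config(n_circles = 2, n_sites = 400))
#' fc_ploidy(sim$variants, sim$hapcounts)
#' @export
fc_ploidy <- function(vt, lh = NULL, min_depth = 11, bounds = c(0.05, 0.95),
                      bin_width = 0.02, hap_threshold = 1000) {
  stopifnot(inherits(vt, "variant_table"))
  spectra <- lapply(vt$sample_ids, function(s)
    suppressWarnings(allele_frequency_spectrum(vt, s, min_depth, bounds)))
  names(spectra) <- vt$sample_ids
  calls <- lapply(vt$sample_ids, function(s) {
    sc <- estimate_ploidy_from_spectrum(spectra[[s]], bin_width)
    if (is.null(lh)) return(sc)
    hc <- classify_by_haplotype_counts(lh, s, hap_threshold)
    combine_ploidy_calls(sc, hc)
  })
  df <- data.frame(
    sample_id = vapply(calls, `[[`, character(1), "sample_id"),
    ploidy = vapply(calls, `[[`, integer(1), "ploidy"),
    spectrum_mode = vapply(calls, `[[`, numeric(1), "spectrum_mode"),
    n_retained = vapply(spectra, function(s) length(s$frequencies),
                        integer(1)),
    n_loci_3plus_hap = vapply(calls, `[[`, integer(1), "n_loci_3plus_hap"),
    method = vapply(calls, `[[`, character(1), "method"),
    flags = vapply(calls, function(x) paste(x$flags, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(calls = df, spectra = spectra), class = "fc_ploidy")
}

#' @export
print.fc_ploidy <- function(x, ...) {
  tab <- table(x$calls$ploidy)
  cat(sprintf("fc_ploidy: %d samples — %s\n", nrow(x$calls),
              paste(sprintf("%sn: %d", names(tab), tab), collapse = ", ")))
  flagged <- x$calls$flags != ""
  if (any(flagged))
    cat("  flagged:", paste(sprintf("%s(%s)", x$calls$sample_id[flagged],
                                    x$calls$flags[flagged]),
                            collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.fc_ploidy <- function(object, ...) {
  print(object)
  invisible(object$calls)
}
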