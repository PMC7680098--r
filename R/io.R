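#' Read a variant table from a VCF with per-sample allele depths
#'
#' Parses a VCF whose genotype columns carry the standard `AD` FORMAT field
#' (ref,alt read depths). Only biallelic SNP sites are retained; multi-allelic
#' sites are dropped with a warning giving the count. Sample order follows
#' the file. A site whose INFO field contains the `CONSERVED` flag is marked
#' as part of the stringent conserved subset.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @return A [variant_table()].
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) stop("no variant records in ", path)
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "AD" %in% f, logical(1))))
    stop("per-sample allele-depth annotation (FORMAT field 'AD') is missing")
  bi <- vcfR::is.biallelic(vcf)
  n_dropped <- sum(!bi)
  if (n_dropped > 0L) {
    warning(sprintf("dropped %d multi-allelic site(s); %d biallelic retained",
                    n_dropped, sum(bi)), call. = FALSE)
    vcf <- vcf[bi, ]
  }
  if (nrow(vcf@fix) == 0L) stop("zero usable biallelic sites after filtering")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  ref <- vcfR::masplit(ad, record = 1L, sort = 0, decreasing = 0)
  alt <- vcfR::masplit(ad, record = 2L, sort = 0, decreasing = 0)
  ref[is.na(ref)] <- 0L
  alt[is.na(alt)] <- 0L
  site_ids <- paste(vcf@fix[, "CHROM"], vcf@fix[, "POS"], sep = ":")
  info <- vcf@fix[, "INFO"]
  conserved <- !is.na(info) & grepl("(^|;)CONSERVED($|;|=)", info)
  variant_table(ref, alt, site_ids, colnames(ad), conserved)
}

#' Write a variant table as a minimal VCF
#'
#' Emits a plain-text VCF with a single FORMAT field `AD` and the
#' `CONSERVED` INFO flag on conserved-subset sites. Allele depths round-trip
#' losslessly through [read_variant_table()]. Placeholder REF/ALT bases are
#' written because the container carries depths, not alleles.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  pos_split <- regmatches(vt$site_ids, regexpr(":[0-9]+$", vt$site_ids))
  if (length(pos_split) != length(vt$site_ids))
    stop("site_ids must have the form 'chrom:pos' to be written as VCF")
  pos <- sub(":", "", pos_split, fixed = TRUE)
  chrom <- sub(":[0-9]+$", "", vt$site_ids)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CONSERVED,Number=0,Type=Flag,Description=\"Site in the stringent conserved subset\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$sample_ids), collapse = "\t"))
  cells <- matrix(paste(vt$ref_depth, vt$alt_depth, sep = ","),
                  nrow = nrow(vt$ref_depth))
  body <- paste(chrom, pos, ".", "A", "C", ".", "PASS",
                ifelse(vt$conserved_flag, "CONSERVED", "."), "AD",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sheet is a TSV with columns `sample_id`, `circle_id`,
#' `position_label`, `center_x`, `center_y` (planar metres). Validation:
#' sample ids must be unique; all samples of one circle must share one
#' centre; circles with fewer than two samples trigger a warning (their
#' within-circle distances cannot be computed). If a variant table is
#' supplied, the sheet and the table must contain exactly the same samples.
#'
#' @param path path to the TSV.
#' @param variant_table optional [variant_table()] to cross-check samples.
#' @return A `data.frame` of class `sample_sheet`, rows in file order.
#' @export
read_sample_sheet <- function(path, variant_table = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(df, variant_table)
}

#' @rdname read_sample_sheet
#' @param df a data.frame with the sample-sheet columns, e.g. built in code.
#' @export
validate_sample_sheet <- function(df, variant_table = NULL) {
  required <- c("sample_id", "circle_id", "position_label",
                "center_x", "center_y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$circle_id <- as.character(df$circle_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample_id in sheet: ", dup[1L])
  for (cid in unique(df$circle_id)) {
    rows <- df[df$circle_id == cid, ]
    if (nrow(unique(rows[, c("center_x", "center_y")])) > 1L)
      stop("inconsistent circle centers for circle ", cid)
    if (nrow(rows) < 2L)
      warning("circle ", cid, " has <2 samples; within-circle distances ",
              "will be skipped for it", call. = FALSE)
  }
  centers <- unique(df[, c("circle_id", "center_x", "center_y")])
  if (anyDuplicated(centers[, c("center_x", "center_y")]))
    warning("two circles share a center (spatial distance 0)", call. = FALSE)
  if (!is.null(variant_table)) {
    absent <- setdiff(df$sample_id, variant_table$sample_ids)
    if (length(absent))
      stop("sample(s) in sheet absent from variant table: ",
           paste(absent, collapse = ", "))
    unlisted <- setdiff(variant_table$sample_ids, df$sample_id)
    if (length(unlisted))
      stop("sample(s) in variant table missing from sheet: ",
           paste(unlisted, collapse = ", "))
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet
#' @param sheet a `sample_sheet` (or compatible data.frame).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a per-sample RAD-locus haplotype-count summary
#'
#' TSV with columns `sample_id`, `n_loci_1hap`, `n_loci_2hap`,
#' `n_loci_3plus_hap`: for each sample, how many assembled RAD loci carry
#' exactly one, exactly two, or three or more distinct haplotypes. Loci with
#' three or more haplotypes are the signature of polyploidy.
#'
#' @param path TSV path.
#' @return data.frame of class `hap_summary`.
#' @export
read_hapcounts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "n_loci_1hap", "n_loci_2hap", "n_loci_3plus_hap")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("haplotype summary lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  counts <- as.matrix(df[, required[-1L]])
  if (any(counts < 0)) stop("haplotype-count summaries must be non-negative")
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("hap_summary", "data.frame")
  df
}

#' @rdname read_hapcounts
#' @param hc a `hap_summary` data.frame.
#' @export
write_hapcounts <- function(hc, path) {
  utils::write.table(as.data.frame(hc), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a labelled square distance matrix as TSV
#'
#' @param d a `dist_matrix` (see [genetic_distance_matrix()]) or a labelled
#'   square numeric matrix.
#' @param path TSV path.
#' @return For the writer, `path` invisibly; for the reader, a `dist_matrix`.
#' @export
write_distance_matrix <- function(d, path) {
  m <- if (inherits(d, "dist_matrix")) d$d else as.matrix(d)
  if (length(m) == 0L || nrow(m) == 0L) stop("empty distance matrix")
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  out <- format(m, digits = 17, trim = TRUE, scientific = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("file does not contain a labelled square matrix")
  dist_matrix(m, metric = "euclidean")
}

#' Export a dendrogram to newick
#'
#' Branch lengths are derived from the merge heights of the hierarchical
#' clustering (via [ape::as.phylo()]).
#'
#' @param dend a `dendrogram_fc` from [hierarchical_cluster()] or an `hclust`.
#' @param path output newick path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dend, path) {
  hc <- if (inherits(dend, "dendrogram_fc")) dend$hclust else dend
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
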