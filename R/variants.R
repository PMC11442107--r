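#' Read a VCF into a genotype matrix
#'
#' Loads biallelic SNP records from a VCF (v4.x) file and converts the GT
#' field to alt-allele dosages. Records that are not biallelic SNPs
#' (multi-allelic sites, indels, symbolic alleles) are skipped and their
#' count reported via a message. Missing genotypes (`./.` or `.`) become
#' `NA` dosages.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @return A [genotype_matrix()].
#' @details Input records must be sorted by position within each
#'   chromosome; unsorted input is an error. A GT value outside
#'   `0/0, 0/1, 1/0, 1/1, ./.` (or the phased `|` equivalents, or haploid
#'   `0`/`1`/`.`) raises an error identifying the offending record.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  snp <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0) {
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  }
  if (!any(snp)) stop("no biallelic SNP records in ", path)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  gt <- gt[snp, , drop = FALSE]
  chrom <- chrom[snp]; pos <- pos[snp]; ref <- ref[snp]; alt <- alt[snp]

  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p)) stop("VCF records not sorted by position on ", ch)
  }

  map <- c("0/0" = 0L, "0|0" = 0L, "0" = 0L,
           "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
           "1/1" = 2L, "1|1" = 2L, "1" = 2L)
  dosage <- matrix(map[gt], nrow = nrow(gt), ncol = ncol(gt))
  bad <- !is.na(gt) & gt != "./." & gt != "." & gt != ".|." & is.na(dosage)
  if (any(bad)) {
    rec <- which(rowSums(bad) > 0)[1]
    stop(sprintf("malformed GT field '%s' at record %s:%d",
                 gt[bad][1], chrom[rec], pos[rec]))
  }

  genotype_matrix(
    t(dosage),
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE),
    accessions = colnames(gt)
  )
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a minimal GT-only VCF: dosage 0 as `0/0`, 1 as `0/1`, 2 as `1/1`,
#' missing as `./.`. Round-trips losslessly through [read_vcf()].
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param contig_lengths optional named vector of chromosome lengths for
#'   `##contig` header lines; defaults to the maximum marker position per
#'   chromosome.
#' @param overwrite overwrite an existing file? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, contig_lengths = NULL, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("file exists (use overwrite = TRUE): ", path)
  }
  if (n_markers(g) == 0) stop("refusing to write a VCF with no markers")
  chroms <- unique(g$markers$chrom)
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(
      chroms, function(ch) max(g$markers$pos[g$markers$chrom == ch]), 0L
    )
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chroms,
            as.integer(contig_lengths[chroms])),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$accessions), collapse = "\t")
  )
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_markers(g), ncol = n_accessions(g))
  ok <- !is.na(t(g$dosage))
  gt[ok] <- code[t(g$dosage)[ok] + 1L]
  body <- paste(
    g$markers$chrom, g$markers$pos, marker_ids(g$markers),
    g$markers$ref, g$markers$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Mask heterozygous genotype calls
#'
#' Sets every heterozygous call (dosage 1) to missing, the standard
#' post-filter for panels of fully inbred lines where residual
#' heterozygosity reflects genotyping error or seed admixture. Homozygous
#' calls are untouched.
#'
#' @param g a [genotype_matrix()].
#' @return A `genotype_matrix` with hets set to `NA`; the number of masked
#'   calls is available as `attr(, "n_masked")`.
#' @export
mask_heterozygotes <- function(g) {
  het <- which(g$dosage == 1L)
  d <- g$dosage
  d[het] <- NA_integer_
  out <- genotype_matrix(d, g$markers, g$accessions)
  attr(out, "n_masked") <- length(het)
  out
}

#' Per-marker summary statistics
#'
#' Computes, for every marker, the minor-allele frequency over non-missing
#' calls, the missing-call rate, and the heterozygote rate (useful before
#' [mask_heterozygotes()]).
#'
#' @param g a [genotype_matrix()].
#' @return A data frame with columns `chrom`, `pos`, `maf`, `missing_rate`,
#'   `het_rate`. A marker with zero non-missing calls gets `maf = NA`.
#' @export
marker_stats <- function(g) {
  d <- g$dosage
  n <- nrow(d)
  n_miss <- colSums(is.na(d))
  n_obs <- n - n_miss
  p <- ifelse(n_obs > 0, colSums(d, na.rm = TRUE) / (2 * n_obs), NA_real_)
  data.frame(
    chrom = g$markers$chrom,
    pos = g$markers$pos,
    maf = pmin(p, 1 - p),
    missing_rate = n_miss / n,
    het_rate = colSums(d == 1L, na.rm = TRUE) / n,
    stringsAsFactors = FALSE
  )
}

#' Filter markers on MAF and missingness
#'
#' Retains markers with minor-allele frequency strictly greater than
#' `maf_min` and missing rate less than or equal to `miss_max` — the
#' inequality directions follow the usual "more than x% MAF / at most y%
#' missing" phrasing. Markers with undefined MAF (all calls missing) are
#' removed.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor-allele frequency (exclusive). Default 0.05.
#' @param miss_max maximum missing rate (inclusive). Default 0.20.
#' @param stats optional precomputed [marker_stats()] for `g`.
#' @return The filtered `genotype_matrix`; marker order preserved. Counts
#'   removed per rule are attached as `attr(, "filter_report")`.
#' @export
filter_markers <- function(g, maf_min = 0.05, miss_max = 0.20, stats = NULL) {
  if (is.null(stats)) stats <- marker_stats(g)
  stopifnot(nrow(stats) == n_markers(g))
  fail_maf <- is.na(stats$maf) | stats$maf <= maf_min
  fail_miss <- stats$missing_rate > miss_max
  keep <- !fail_maf & !fail_miss
  out <- subset_markers(g, keep)
  attr(out, "filter_report") <- list(
    n_in = n_markers(g), n_out = sum(keep),
    removed_maf = sum(fail_maf), removed_missing = sum(fail_miss)
  )
  out
}

#' Prune markers to one per genomic window
#'
#' Partitions each chromosome into consecutive non-overlapping windows of
#' `window_bp` base pairs (0-based half-open bins anchored at position 0)
#' and keeps exactly one marker per non-empty bin: the marker with the
#' lowest missing rate, ties broken by lowest position. Reduces marker
#' redundancy before PCA / tree building.
#'
#' @param g a [genotype_matrix()].
#' @param window_bp window length in bp. Default 20000.
#' @return The pruned `genotype_matrix`; marker order preserved.
#' @export
prune_by_window <- function(g, window_bp = 20000) {
  stopifnot(window_bp > 0)
  stats <- marker_stats(g)
  bin <- (g$markers$pos - 1L) %/% as.integer(window_bp)  # pos is 1-based
  key <- paste(g$markers$chrom, bin)
  ord <- order(stats$missing_rate, g$markers$pos)  # best first within bin
  keep_rows <- ord[!duplicated(key[ord])]
  keep <- sort(keep_rows)
  subset_markers(g, keep)
}
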