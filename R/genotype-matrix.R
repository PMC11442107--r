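#' Genotype matrix container
#'
#' A `genotype_matrix` bundles the alt-allele dosage matrix of an inbred
#' diversity panel with its marker map. Dosages are counts of the alternate
#' allele per diploid genotype (0, 1, 2) with `NA` for missing calls; for
#' fully inbred accessions only 0 and 2 are expected, and heterozygous calls
#' are normally masked with [mask_heterozygotes()] before analysis.
#'
#' @param dosage integer/numeric matrix, accessions in rows, markers in
#'   columns; entries in `{0, 1, 2, NA}`.
#' @param markers data frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, one row per marker, sorted by (chrom, pos) with unique
#'   positions per chromosome.
#' @param accessions character vector of accession identifiers, one per row
#'   of `dosage`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `markers`, `accessions`.
#' @export
genotype_matrix <- function(dosage, markers, accessions = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(accessions)) {
    accessions <- paste0("acc", seq_len(nrow(dosage)))
  }
  accessions <- as.character(accessions)
  markers <- as.data.frame(markers)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt") %in% names(markers)),
    nrow(markers) == ncol(dosage),
    length(accessions) == nrow(dosage)
  )
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  rownames(markers) <- NULL
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  # markers must be sorted by (chrom, pos), unique positions per chromosome
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$pos)
  if (!identical(ord, seq_len(nrow(markers)))) {
    stop("markers must be sorted by (chrom, pos)")
  }
  if (anyDuplicated(markers[, c("chrom", "pos")])) {
    stop("duplicate marker positions within a chromosome")
  }
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- accessions
  if (ncol(dosage) > 0) colnames(dosage) <- marker_ids(markers)
  structure(
    list(dosage = dosage, markers = markers, accessions = accessions),
    class = "genotype_matrix"
  )
}

marker_ids <- function(markers) paste0(markers$chrom, ":", markers$pos)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d accessions x %d markers on %d chromosome(s)\n",
    length(x$accessions), nrow(x$markers), length(unique(x$markers$chrom))
  ))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

n_markers <- function(g) nrow(g$markers)
n_accessions <- function(g) length(g$accessions)

#' Subset a genotype matrix by marker index
#'
#' @param g a [genotype_matrix()].
#' @param j integer or logical index over markers.
#' @return A `genotype_matrix` restricted to the selected markers.
#' @export
subset_markers <- function(g, j) {
  genotype_matrix(g$dosage[, j, drop = FALSE], g$markers[j, , drop = FALSE],
                  g$accessions)
}

# Locate marker column indices from "chrom:pos" strings; error on misses.
match_marker_ids <- function(g, ids) {
  idx <- match(ids, marker_ids(g$markers))
  if (anyNA(idx)) {
    stop("markers not found in genotype matrix: ",
         paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

# Per-column mean imputation on the dosage scale; errors on all-missing
# columns unless allow_all_missing (then left as the column mean 0).
impute_dosage <- function(dosage) {
  x <- dosage
  storage.mode(x) <- "double"
  cm <- colMeans(x, na.rm = TRUE)
  if (anyNA(cm)) {
    stop(sum(is.na(cm)), " marker(s) have no non-missing calls; ",
         "filter them before analysis")
  }
  nas <- which(is.na(x))
  if (length(nas)) {
    x[nas] <- cm[(nas - 1L) %/% nrow(x) + 1L]
  }
  x
}
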