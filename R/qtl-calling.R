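#' Call QTL regions from an association scan
#'
#' Applies a dual-threshold, d_LD50-window region definition: a QTL is a
#' genomic window of `window_bp` bp either side of a peak marker that
#' contains at least one marker at or above the significant line and at
#' least two markers (the peak included) at or above the suggestive line.
#' Regions are found greedily per chromosome: take the unclaimed marker
#' with the highest score above the significant line (ties: lower
#' position), collect markers within the window, call the region iff the
#' suggestive count is >= 2, claim the window's markers, repeat.
#' Overlapping candidate windows therefore merge into the stronger peak's
#' region; an isolated significant spike with no suggestive neighbor is
#' rejected. Regions are named `q<trait><chrom>.<index>` with
#' per-chromosome indices in positional order.
#'
#' @param result an `assoc_result` from [association_scan()], sorted by
#'   (chrom, pos).
#' @param window_bp half-window in bp; conventionally the genome-wide
#'   d_LD50 from [ld_decay()].
#' @param sig_line significant threshold in `-log10(p)` units
#'   (`>= sug_line`).
#' @param sug_line suggestive threshold in `-log10(p)` units.
#' @param trait short trait tag used in region names. Default `"TRAIT"`.
#' @return A list of `qtl_region` objects, each with `name`, `chrom`,
#'   `peak` (row of `result`), `window` (`c(lo, hi)` bp), `supporting`
#'   (in-window rows at/above the suggestive line) and `n_significant`.
#' @export
call_qtl_regions <- function(result, window_bp, sig_line, sug_line,
                             trait = "TRAIT") {
  stopifnot(window_bp > 0, sig_line >= sug_line)
  if (nrow(result) == 0) return(list())
  ord <- order(match(result$chrom, unique(result$chrom)), result$pos)
  result <- result[ord, , drop = FALSE]

  regions <- list()
  for (ch in unique(result$chrom)) {
    rows <- result[result$chrom == ch, , drop = FALSE]
    score <- rows$minus_log10_p
    claimed <- rep(FALSE, nrow(rows))
    repeat {
      cand <- which(!claimed & !is.na(score) & score >= sig_line)
      if (length(cand) == 0) break
      peak <- cand[order(-score[cand], rows$pos[cand])][1]
      win <- which(!claimed & abs(rows$pos - rows$pos[peak]) <= window_bp)
      sug <- win[!is.na(score[win]) & score[win] >= sug_line]
      if (length(sug) >= 2) {
        claimed[win] <- TRUE
        regions[[length(regions) + 1]] <- structure(list(
          name = NA_character_,
          chrom = ch,
          peak = rows[peak, , drop = FALSE],
          window = c(lo = rows$pos[peak] - window_bp,
                     hi = rows$pos[peak] + window_bp),
          supporting = rows[sug, , drop = FALSE],
          n_significant = sum(score[win] >= sig_line, na.rm = TRUE)
        ), class = "qtl_region")
      } else {
        claimed[peak] <- TRUE  # reject the isolated spike, keep looking
      }
    }
  }
  # name in positional order with per-chromosome ordinals
  if (length(regions)) {
    chrom_of <- vapply(regions, function(r) r$chrom, "")
    pos_of <- vapply(regions, function(r) r$peak$pos, 0)
    ord <- order(match(chrom_of, unique(result$chrom)), pos_of)
    regions <- regions[ord]
    idx <- stats::ave(seq_along(regions), chrom_of[ord], FUN = seq_along)
    chrom_num <- sub("^chr", "", chrom_of[ord])
    for (i in seq_along(regions)) {
      regions[[i]]$name <- sprintf("q%s%s.%d", trait, chrom_num[i], idx[i])
    }
    for (r in regions) validate_qtl_region(r)
  }
  regions
}

validate_qtl_region <- function(r) {
  stopifnot(
    r$n_significant >= 1,
    nrow(r$supporting) >= 2,
    r$peak$pos >= r$window["lo"], r$peak$pos <= r$window["hi"],
    all(r$supporting$minus_log10_p <= r$peak$minus_log10_p)
  )
  invisible(r)
}

#' @export
print.qtl_region <- function(x, ...) {
  cat(sprintf(
    "%s: %s:%d (-log10 p = %.2f), window [%.0f, %.0f], %d suggestive / %d significant\n",
    x$name, x$chrom, x$peak$pos, x$peak$minus_log10_p,
    x$window["lo"], x$window["hi"], nrow(x$supporting), x$n_significant
  ))
  invisible(x)
}

#' Correlations between QTL peak-marker genotypes
#'
#' Pairwise Pearson correlations between the dosage vectors at the peak
#' markers of the called regions, over accessions non-missing at both
#' peaks. The diagonal is computed as the self-correlation (exactly 1 for
#' any polymorphic marker). A monomorphic peak vector yields an undefined
#' (`NA`) entry with a warning.
#'
#' @param g a [genotype_matrix()] containing the peak markers.
#' @param regions list of `qtl_region`s from [call_qtl_regions()].
#' @return A symmetric correlation matrix named by region.
#' @export
peak_genotype_correlations <- function(g, regions) {
  ids <- vapply(regions, function(r) paste0(r$chrom, ":", r$peak$pos), "")
  idx <- match_marker_ids(g, ids)
  x <- g$dosage[, idx, drop = FALSE]
  storage.mode(x) <- "double"
  k <- length(idx)
  cm <- matrix(NA_real_, k, k,
               dimnames = rep(list(vapply(regions, `[[`, "", "name")), 2))
  for (a in seq_len(k)) {
    for (b in a:k) {
      ok <- !is.na(x[, a]) & !is.na(x[, b])
      va <- stats::var(x[ok, a]); vb <- stats::var(x[ok, b])
      if (sum(ok) >= 2 && va > 0 && vb > 0) {
        cm[a, b] <- cm[b, a] <- stats::cor(x[ok, a], x[ok, b])
      }
    }
  }
  if (anyNA(diag(cm))) warning("monomorphic peak marker: undefined correlation")
  cm
}

#' Local LD matrix around a QTL region
#'
#' Full pairwise r-squared matrix (squared Pearson correlation of dosages
#' over pairwise-complete accessions, as in [pairwise_r2()]) for all
#' markers inside the region window extended by `flank_bp`, for LD heatmap
#' rendering.
#'
#' @param g a [genotype_matrix()].
#' @param region a `qtl_region`.
#' @param flank_bp extension of the window on each side. Default 0.
#' @return A symmetric r-squared matrix with unit diagonal; marker
#'   positions as dimnames and in `attr(, "pos")`.
#' @export
local_ld_matrix <- function(g, region, flank_bp = 0) {
  sel <- which(g$markers$chrom == region$chrom &
                 g$markers$pos >= region$window["lo"] - flank_bp &
                 g$markers$pos <= region$window["hi"] + flank_bp)
  if (length(sel) < 2) stop("fewer than 2 markers in the region window")
  x <- g$dosage[, sel, drop = FALSE]
  storage.mode(x) <- "double"
  r <- stats::cor(x, use = "pairwise.complete.obs")
  r2 <- r^2
  diag(r2) <- 1
  dimnames(r2) <- rep(list(as.character(g$markers$pos[sel])), 2)
  attr(r2, "pos") <- g$markers$pos[sel]
  r2
}

#' Annotated genes inside a QTL region
#'
#' Reads gene features from a GFF3 annotation and returns those whose
#' `[start, end]` span (1-based inclusive) intersects the region window,
#' with each gene's distance from the peak marker (0 if the peak lies
#' inside the gene).
#'
#' @param annotation path to a GFF3 file, or a `GRanges` already imported.
#' @param region a `qtl_region`.
#' @param feature_type GFF3 `type` to report. Default `"gene"`.
#' @return A data frame (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `distance_from_peak`) sorted by distance.
#' @export
genes_in_region <- function(annotation, region, feature_type = "gene") {
  gr <- if (is.character(annotation)) {
    rtracklayer::import(annotation, format = "gff3")
  } else {
    annotation
  }
  gr <- gr[gr$type == feature_type]
  gff_chroms <- as.character(unique(GenomicRanges::seqnames(gr)))
  if (!region$chrom %in% gff_chroms) {
    stop("chromosome name mismatch: region on '", region$chrom,
         "', annotation has {", paste(gff_chroms, collapse = ", "), "}")
  }
  df <- data.frame(
    gene_id = if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df <- df[df$chrom == region$chrom &
             df$end >= region$window["lo"] &
             df$start <= region$window["hi"], , drop = FALSE]
  peak <- region$peak$pos
  df$distance_from_peak <- ifelse(
    peak >= df$start & peak <= df$end, 0L,
    pmin(abs(peak - df$start), abs(peak - df$end))
  )
  df <- df[order(df$distance_from_peak, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
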