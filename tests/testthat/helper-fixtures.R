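# Shared fixture builders and independent oracles for the test suite.

n_markers_of <- function(g) nrow(g$markers)

subset_accessions <- function(g, i) {
  genotype_matrix(g$dosage[i, , drop = FALSE], g$markers, g$accessions[i])
}

match_id <- function(g, id) {
  match(id, paste0(g$markers$chrom, ":", g$markers$pos))
}

# A tiny genotype matrix from a dosage matrix (markers on one chromosome
# at 1 kb spacing unless positions are given).
toy_geno <- function(dosage, pos = NULL, chrom = "chr1") {
  dosage <- as.matrix(dosage)
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 1000L
  genotype_matrix(
    dosage,
    data.frame(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "T",
               stringsAsFactors = FALSE)
  )
}

# A small simulated panel for integration-style tests.
small_panel_config <- function(seed = 1, ...) {
  sim_config(
    n_accessions = 120, n_chromosomes = 2, chrom_length_bp = 8e6,
    n_markers_per_chrom = 600, n_founders = 12,
    major_locus = c(chrom = 1, pos = 4e6),
    modifier_loci = list(c(chrom = 1, pos = 1e6), c(chrom = 2, pos = 6e6)),
    seed = seed, ...
  )
}

# O(m^2) brute-force Benjamini-Hochberg: q_i = min over all tails of
# m * p_(j) / j for ranks j >= rank(i).
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(1, min(m * p[o][rank_i:m] / (rank_i:m)))
  }
  q
}

# From-scratch logistic-regression score test (intercept-only null fitted
# by IRLS, then the efficient score for adding marker x).
logistic_score_p <- function(y, x) {
  # IRLS for the intercept-only model converges to mu = mean(y)
  mu <- mean(y)
  W <- rep(mu * (1 - mu), length(y))
  U <- sum(x * (y - mu))
  V <- sum(W * x^2) - sum(W * x)^2 / sum(W)
  stats::pchisq(U^2 / V, df = 1, lower.tail = FALSE)
}

# -2 restricted log-likelihood of the Gaussian mixed model
# y = X b + u + e, u ~ N(0, tau K), e ~ N(0, s2 I), computed from the
# definition (used as a grid-search oracle for REML fits).
reml_m2ll <- function(tau, s2, y, X, K) {
  V <- tau * K + diag(s2, nrow(K))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(
    determinant(V, logarithm = TRUE)$modulus +
      determinant(t(X) %*% Vi %*% X, logarithm = TRUE)$modulus +
      t(r) %*% Vi %*% r
  )
}

# Write a small VCF file from raw lines, returning its path.
write_vcf_lines <- function(body, samples = c("S1", "S2", "S3"),
                            contigs = "chr1") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=1000000>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}
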