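#' Configuration for the inbred-panel simulator
#'
#' Builds and validates the parameter set for the founder-mosaic genotype
#' simulator and its phenotype/origin generators. Defaults emulate a
#' diversity panel of 250 fully inbred rice accessions with no subpopulation
#' structure, distance-decaying intra-chromosomal LD, a weak
#' genotype-latitude cline, and a binary apiculus-color trait controlled by
#' one major loss-of-function locus plus two complementary modifier loci
#' with near-complete penetrance.
#'
#' @param n_accessions number of inbred accessions. Default 250.
#' @param n_chromosomes number of chromosomes. Default 12.
#' @param chrom_length_bp chromosome length in bp (same for all). Default 30 Mb.
#' @param n_markers_per_chrom markers simulated per chromosome. Default 5000.
#' @param n_founders number of founder haplotypes (>= 2). Default 20.
#' @param switch_rate founder-switch probability per bp along a chromosome;
#'   controls how fast LD decays (larger = faster decay). Default 2e-5.
#' @param founder_ld_rate per-bp decay rate of allele correlation within the
#'   founder pool itself (founder haplotypes share ancestry, so tightly
#'   linked markers carry near-identical founder allele columns and panel
#'   r-squared approaches 1 at short distances). Default 5e-6.
#' @param maf_min minimum simulated minor-allele frequency, in (0, 0.5).
#'   Markers falling below it are redrawn or dropped. Default 0.05.
#' @param missing_rate fraction of genotype calls set missing, in \[0, 1). Default 0.05.
#' @param het_injection_rate fraction of calls emitted heterozygous (before
#'   any downstream masking), emulating residual genotyping error. Default 0.01.
#' @param major_locus `c(chrom, pos)` of the major loss-of-function locus;
#'   the alt allele is the loss allele. Default chromosome 6, 4.87 Mb.
#' @param modifier_loci list of two `c(chrom, pos)` pairs for the
#'   complementary modifier loci. Defaults on chromosomes 8 and 12.
#' @param major_loss_freq target founder frequency of the loss allele at the
#'   major locus. Default 0.72, so roughly 72\% of accessions are
#'   loss-homozygotes.
#' @param modifier_alt_freq target founder frequency of the alt allele at
#'   each modifier locus. Default 0.26, so about 6-7\% of accessions are
#'   alt-homozygous at both modifiers.
#' @param penetrance_major probability that a loss-homozygote is colorless.
#'   Default 159/161.
#' @param leak_rate probability that a functional-allele carrier without the
#'   double-modifier genotype is colorless anyway. Default 0 (the rare
#'   colorless carriers then arise only through the modifier pair).
#' @param geo_effect target correlation between genotype PC1 and latitude.
#'   Default 0.39.
#' @param geo_effect_lon target correlation between PC2 and longitude.
#'   Default 0.22.
#' @param seed master random seed; per-stage streams are derived from it by
#'   fixed offsets so stages can be regenerated independently.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 250,
                       n_chromosomes = 12,
                       chrom_length_bp = 30e6,
                       n_markers_per_chrom = 5000,
                       n_founders = 20,
                       switch_rate = 2e-5,
                       founder_ld_rate = 5e-6,
                       maf_min = 0.05,
                       missing_rate = 0.05,
                       het_injection_rate = 0.01,
                       major_locus = c(chrom = 6, pos = 4866454),
                       modifier_loci = list(c(chrom = 8, pos = 7780702),
                                            c(chrom = 12, pos = 958898)),
                       major_loss_freq = 0.72,
                       modifier_alt_freq = 0.26,
                       penetrance_major = 159 / 161,
                       leak_rate = 0,
                       geo_effect = 0.39,
                       geo_effect_lon = 0.22,
                       seed = 1L) {
  cfg <- list(
    n_accessions = as.integer(n_accessions),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    n_founders = as.integer(n_founders),
    switch_rate = switch_rate,
    founder_ld_rate = founder_ld_rate,
    maf_min = maf_min,
    missing_rate = missing_rate,
    het_injection_rate = het_injection_rate,
    major_locus = major_locus,
    modifier_loci = modifier_loci,
    major_loss_freq = major_loss_freq,
    modifier_alt_freq = modifier_alt_freq,
    penetrance_major = penetrance_major,
    leak_rate = leak_rate,
    geo_effect = geo_effect,
    geo_effect_lon = geo_effect_lon,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_accessions >= 2, cfg$n_chromosomes >= 1,
    cfg$n_markers_per_chrom >= 1, cfg$n_founders >= 2,
    cfg$switch_rate > 0, cfg$founder_ld_rate >= 0,
    cfg$maf_min > 0, cfg$maf_min < 0.5,
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$het_injection_rate >= 0, cfg$het_injection_rate < 1,
    cfg$penetrance_major >= 0, cfg$penetrance_major <= 1,
    cfg$leak_rate >= 0, cfg$leak_rate <= 1,
    abs(cfg$geo_effect) <= 1, abs(cfg$geo_effect_lon) <= 1
  )
  # maf_min must be reachable with founder allele counts k/n_founders
  k <- seq_len(cfg$n_founders - 1L)
  if (!any(k / cfg$n_founders >= cfg$maf_min &
           k / cfg$n_founders <= 1 - cfg$maf_min)) {
    stop("maf_min = ", cfg$maf_min, " is unattainable with ",
         cfg$n_founders, " founder haplotypes")
  }
  for (loc in c(list(cfg$major_locus), cfg$modifier_loci)) {
    if (loc[["chrom"]] > cfg$n_chromosomes || loc[["pos"]] > cfg$chrom_length_bp ||
        loc[["pos"]] < 1) {
      stop("causal locus outside the simulated genome: chrom ",
           loc[["chrom"]], " pos ", loc[["pos"]])
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# Fixed per-stage seed offsets (stages regenerable independently).
stage_seed <- function(cfg, stage) {
  off <- c(genotypes = 11L, phenotype = 23L, origins = 37L)
  (cfg$seed + off[[stage]]) %% .Machine$integer.max
}

#' Simulate inbred-panel genotypes by founder-haplotype mosaics
#'
#' Each accession's chromosome is a hidden-Markov mosaic of `n_founders`
#' founder haplotypes: moving along the marker map, the copied founder
#' switches between adjacent markers with probability
#' `1 - exp(-switch_rate * gap_bp)`, giving geometric segment lengths and a
#' pairwise r-squared that decays with physical distance. Genotypes are
#' fully homozygous (dosage 0 or 2); heterozygous calls are then injected at
#' `het_injection_rate` and calls are set missing at `missing_rate` to
#' exercise downstream masking and filtering. Founder alleles are drawn so
#' every marker's minor-allele frequency is at least `maf_min` (violating
#' markers are redrawn, then dropped). Marker positions include the exact
#' causal loci named in the config, with founder allele frequencies there
#' pinned to `major_loss_freq` / `modifier_alt_freq`.
#'
#' @param config a [sim_config()].
#' @return A [genotype_matrix()]; deterministic given the config (and its
#'   seed).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "genotypes"))
  n <- config$n_accessions
  nf <- config$n_founders
  causal <- c(list(config$major_locus), config$modifier_loci)

  dosage_all <- vector("list", config$n_chromosomes)
  markers_all <- vector("list", config$n_chromosomes)

  for (ch in seq_len(config$n_chromosomes)) {
    chrom_name <- paste0("chr", ch)
    m <- config$n_markers_per_chrom
    pos <- sort(sample.int(config$chrom_length_bp, m))
    # place causal loci at their exact positions
    causal_here <- Filter(function(l) l[["chrom"]] == ch, causal)
    causal_pos <- vapply(causal_here, function(l) as.integer(l[["pos"]]), 0L)
    for (cp in causal_pos) {
      if (!cp %in% pos) pos[which.min(abs(pos - cp))] <- cp
    }
    pos <- sort(unique(pos))
    m <- length(pos)

    # founder mosaic: switch indicator between adjacent markers
    p_switch <- 1 - exp(-config$switch_rate * diff(pos))
    founder <- matrix(0L, n, m)
    founder[, 1] <- sample.int(nf, n, replace = TRUE)
    if (m > 1) {
      sw <- matrix(stats::runif(n * (m - 1)), n, m - 1) <
        matrix(p_switch, n, m - 1, byrow = TRUE)
      new_f <- matrix(sample.int(nf, n * (m - 1), replace = TRUE), n, m - 1)
      for (k in 2:m) {
        founder[, k] <- ifelse(sw[, k - 1], new_f[, k - 1], founder[, k - 1])
      }
    }

    # founder alleles: a Markov chain along the map so founder haplotypes
    # share local ancestry (allele correlation decays at founder_ld_rate);
    # allele counts k/nf constrained to keep panel MAF >= maf_min
    k_ok <- which(seq_len(nf - 1) / nf >= config$maf_min &
                  seq_len(nf - 1) / nf <= 1 - config$maf_min)
    k_min <- min(k_ok); k_max <- max(k_ok)
    draw_col <- function() {
      k <- sample(k_ok, 1)
      sample(c(rep(1L, k), rep(0L, nf - k)))
    }
    force_count <- function(col, k_target) {
      k <- sum(col)
      if (k < k_target) {
        z <- which(col == 0L)
        col[z[sample.int(length(z), k_target - k)]] <- 1L
      } else if (k > k_target) {
        o <- which(col == 1L)
        col[o[sample.int(length(o), k - k_target)]] <- 0L
      }
      col
    }
    clamp_count <- function(col) {
      k <- sum(col)
      if (k < k_min) col <- force_count(col, k_min)
      if (k > k_max) col <- force_count(col, k_max)
      col
    }
    causal_k <- function(ci) {
      freq <- if (identical(causal_here[[ci]], config$major_locus)) {
        config$major_loss_freq
      } else {
        config$modifier_alt_freq
      }
      max(1L, min(nf - 1L, as.integer(round(freq * nf))))
    }
    p_keep <- exp(-config$founder_ld_rate * diff(pos))
    H <- matrix(0L, nf, m)
    H[, 1] <- draw_col()
    if (m > 1) {
      for (j in 2:m) {
        col <- H[, j - 1]
        renew <- stats::runif(nf) >= p_keep[j - 1]
        if (any(renew)) {
          q <- sample(k_ok, 1) / nf
          col[renew] <- stats::rbinom(sum(renew), 1L, q)
        }
        H[, j] <- clamp_count(col)
      }
    }
    for (ci in seq_along(causal_pos)) {
      j <- match(causal_pos[ci], pos)
      H[, j] <- force_count(H[, j], causal_k(ci))
    }

    realized <- function(j) {
      2L * H[cbind(founder[, j], j)]
    }
    dos <- matrix(0L, n, m)
    for (j in seq_len(m)) dos[, j] <- realized(j)

    # enforce realized MAF >= maf_min by nudging the founder allele count
    # toward the interior (preserves local founder ancestry, unlike a
    # full redraw)
    maf_of <- function(x) { p <- mean(x) / 2; min(p, 1 - p) }
    is_causal <- pos %in% causal_pos
    for (j in seq_len(m)) {
      if (is_causal[j]) next
      tries <- 0
      while (maf_of(dos[, j]) < config$maf_min && tries < nf) {
        k <- sum(H[, j])
        k_new <- if (k <= nf / 2) k + 1L else k - 1L
        H[, j] <- force_count(H[, j], k_new)
        dos[, j] <- realized(j)
        tries <- tries + 1
      }
    }
    keep <- is_causal | apply(dos, 2, maf_of) >= config$maf_min
    dos <- dos[, keep, drop = FALSE]
    pos <- pos[keep]

    dosage_all[[ch]] <- dos
    markers_all[[ch]] <- data.frame(
      chrom = chrom_name, pos = pos,
      ref = "A", alt = "T", stringsAsFactors = FALSE
    )
  }

  dosage <- do.call(cbind, dosage_all)
  markers <- do.call(rbind, markers_all)
  mm <- nrow(markers)

  # inject hets, then missing calls, on disjoint random cell sets;
  # causal-locus columns are kept clean of injected hets so the planted
  # architecture stays interpretable (missing calls may still hit them)
  causal_ids <- vapply(causal, function(l) {
    sprintf("chr%d:%d", as.integer(l[["chrom"]]), as.integer(l[["pos"]]))
  }, "")
  causal_cols <- match(causal_ids, paste0(markers$chrom, ":", markers$pos))
  ncell <- length(dosage)
  n_het <- round(config$het_injection_rate * ncell)
  n_miss <- round(config$missing_rate * ncell)
  cells <- sample.int(ncell, n_het + n_miss)
  het_cells <- cells[seq_len(n_het)]
  het_cells <- het_cells[!(((het_cells - 1L) %/% nrow(dosage)) + 1L) %in% causal_cols]
  miss_cells <- cells[seq_len(n_miss) + n_het]
  dosage[het_cells] <- 1L
  dosage[miss_cells] <- NA_integer_

  g <- genotype_matrix(dosage, markers,
                       accessions = sprintf("ACC%03d", seq_len(n)))
  attr(g, "config") <- config
  g
}

#' Simulate a binary apiculus-color phenotype
#'
#' An accession is colorless (coded 1) if it is homozygous for the loss
#' allele (alt) at the major locus — with probability `penetrance_major` —
#' or if it carries the functional allele but is alt-homozygous at *both*
#' complementary modifier loci, or if `leak_rate` noise fires. Accessions
#' with a missing genotype call at any causal locus get a missing phenotype.
#'
#' @param g a [genotype_matrix()] containing the causal loci of `config`.
#' @param config the [sim_config()] used to generate `g`.
#' @return A data frame (`accession_id`, `trait`) with trait coded
#'   colorless = 1, colored = 0, `NA` for missing; deterministic given the
#'   config seed.
#' @export
simulate_phenotype <- function(g, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "phenotype"))
  ml <- config$major_locus
  ids <- c(sprintf("chr%d:%d", as.integer(ml[["chrom"]]), as.integer(ml[["pos"]])),
           vapply(config$modifier_loci, function(l) {
             sprintf("chr%d:%d", as.integer(l[["chrom"]]), as.integer(l[["pos"]]))
           }, ""))
  idx <- match_marker_ids(g, ids)
  major <- g$dosage[, idx[1]]
  mod1 <- g$dosage[, idx[2]]
  mod2 <- g$dosage[, idx[3]]

  n <- n_accessions(g)
  loss_hom <- major == 2L
  double_mod <- mod1 == 2L & mod2 == 2L
  u_pen <- stats::runif(n)
  u_leak <- stats::runif(n)
  colorless <- ifelse(
    loss_hom,
    as.integer(u_pen < config$penetrance_major),
    as.integer(double_mod | u_leak < config$leak_rate)
  )
  colorless[is.na(major) | is.na(mod1) | is.na(mod2)] <- NA_integer_
  data.frame(accession_id = g$accessions, trait = colorless,
             stringsAsFactors = FALSE)
}

# Latitude bands (degrees N) to region labels, south to north; a fixture
# convention for a Myanmar-like cline, not a geographic claim.
.region_bands <- data.frame(
  region = c("DR", "WCR", "ECR", "CDZ", "EMR", "WMR", "NMR"),
  upper = c(14.0, 15.2, 16.2, 17.4, 18.6, 20.0, Inf),
  stringsAsFactors = FALSE
)

#' Simulate geographic origins with a genotype-latitude cline
#'
#' Latitude is generated as a linear function of the panel's first genotype
#' principal component plus Gaussian noise, scaled so that
#' `cor(PC1, latitude)` approaches `geo_effect` for large panels
#' (`geo_effect = 1` with zero noise gives exact correlation 1). Longitude
#' follows PC2 the same way at `geo_effect_lon`. Region labels are assigned
#' by fixed latitude bands.
#'
#' @param g a [genotype_matrix()].
#' @param config the [sim_config()].
#' @return A data frame (`accession_id`, `latitude`, `longitude`, `region`);
#'   deterministic given the config seed.
#' @export
simulate_origins <- function(g, config) {
  stopifnot(inherits(config, "sim_config"))
  if (n_accessions(g) < 2) stop("need at least 2 accessions")
  set.seed(stage_seed(config, "origins"))
  pc <- geno_pca(g, n_components = 2)
  z1 <- as.numeric(scale(pc$scores[, 1]))
  z2 <- if (ncol(pc$scores) >= 2) as.numeric(scale(pc$scores[, 2])) else 0 * z1
  n <- n_accessions(g)

  mix <- function(z, r) {
    if (abs(r) == 1) r * z else r * z + sqrt(1 - r^2) * stats::rnorm(n)
  }
  lat <- 16.5 + 2.0 * mix(z1, config$geo_effect)
  lon <- 96.0 + 1.5 * mix(z2, config$geo_effect_lon)
  region <- .region_bands$region[
    findInterval(lat, c(-Inf, .region_bands$upper), left.open = TRUE)
  ]
  data.frame(accession_id = g$accessions, latitude = lat, longitude = lon,
             region = region, stringsAsFactors = FALSE)
}

#' Write a simulated panel to disk as VCF + TSV fixtures
#'
#' Emits `genotypes.vcf` (VCF v4.2, diploid GT, `./.` for missing, `0/1`
#' for injected hets), `phenotype.tsv` (colorless = 1, colored = 0; coding
#' documented in a header comment) and `origins.tsv`. The VCF round-trips
#' losslessly through [read_vcf()].
#'
#' @param g a [genotype_matrix()].
#' @param pheno a phenotype table from [simulate_phenotype()].
#' @param origins an origin table from [simulate_origins()].
#' @param out_dir output directory (created if absent).
#' @param overwrite overwrite existing files? Default `FALSE`.
#' @return Named character vector of the three file paths.
#' @export
write_fixture <- function(g, pheno, origins, out_dir, overwrite = FALSE) {
  if (n_markers(g) == 0) stop("refusing to write a fixture with no markers")
  stopifnot(identical(g$accessions, pheno$accession_id),
            identical(g$accessions, origins$accession_id))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    pheno = file.path(out_dir, "phenotype.tsv"),
    origins = file.path(out_dir, "origins.tsv")
  )
  clash <- file.exists(paths)
  if (any(clash) && !overwrite) {
    stop("file(s) exist (use overwrite = TRUE): ",
         paste(paths[clash], collapse = ", "))
  }
  write_vcf(g, paths["vcf"], overwrite = overwrite)
  con <- file(paths["pheno"], "w")
  writeLines("# trait: apiculus color; colorless = 1, colored = 0", con)
  utils::write.table(pheno, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  utils::write.table(origins, paths["origins"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Read a phenotype TSV written by [write_fixture()]
#'
#' @param path TSV with columns `accession_id`, `trait`; `#` comment lines
#'   are ignored.
#' @return A data frame (`accession_id`, `trait`).
#' @export
read_phenotype <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = c("character", "integer"))
}

#' Read an origins TSV
#'
#' @param path TSV with columns `accession_id`, `latitude`, `longitude`,
#'   `region`.
#' @return A data frame.
#' @export
read_origins <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
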