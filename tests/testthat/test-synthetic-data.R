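test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_founders = 1), "n_founders")
  expect_error(sim_config(maf_min = 0.6), "maf_min")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(switch_rate = 0), "switch_rate")
  # with 3 founders no allele count k/3 lies in [0.4, 0.6]
  expect_error(sim_config(n_founders = 3, maf_min = 0.4), "unattainable")
  # causal locus off the simulated genome
  expect_error(
    sim_config(n_chromosomes = 2, major_locus = c(chrom = 5, pos = 100)),
    "causal locus"
  )
})

test_that("simulation is deterministic given the config and stages are independent", {
  cfg <- small_panel_config(seed = 9)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$markers, g2$markers)
  expect_identical(simulate_phenotype(g1, cfg), simulate_phenotype(g2, cfg))
  expect_identical(simulate_origins(g1, cfg), simulate_origins(g2, cfg))
})

test_that("genotypes are homozygous mosaics respecting MAF and noise rates", {
  cfg <- small_panel_config(seed = 2, missing_rate = 0.1,
                            het_injection_rate = 0.02)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% c(0L, 1L, 2L) | is.na(g$dosage)))
  expect_lt(abs(mean(is.na(g$dosage)) - 0.1), 0.01)
  het_frac <- sum(g$dosage == 1L, na.rm = TRUE) / length(g$dosage)
  expect_lt(abs(het_frac - 0.02), 0.005)
  # hets are pure injection noise: without injection all calls homozygous
  g0 <- simulate_genotypes(small_panel_config(seed = 2, het_injection_rate = 0))
  expect_false(any(g0$dosage == 1L, na.rm = TRUE))
  st <- marker_stats(g0)
  expect_true(all(st$maf >= cfg$maf_min - 1e-9, na.rm = TRUE))
})

test_that("two founders without switching give perfect LD; free recombination erases it", {
  cfg <- sim_config(n_accessions = 80, n_chromosomes = 1, chrom_length_bp = 1e6,
                    n_markers_per_chrom = 30, n_founders = 2,
                    switch_rate = 1e-15, founder_ld_rate = 0,
                    missing_rate = 0, het_injection_rate = 0,
                    major_locus = c(chrom = 1, pos = 5e5),
                    modifier_loci = list(c(chrom = 1, pos = 2e5),
                                         c(chrom = 1, pos = 8e5)),
                    seed = 3)
  g <- simulate_genotypes(cfg)
  cc <- suppressWarnings(stats::cor(g$dosage))^2
  seg <- apply(g$dosage, 2, stats::var) > 0
  expect_true(all(abs(cc[seg, seg] - 1) < 1e-12))

  # switch at every bp: adjacent r2 indistinguishable from the
  # between-chromosome background
  cfg2 <- sim_config(n_accessions = 200, n_chromosomes = 2,
                     chrom_length_bp = 1e6, n_markers_per_chrom = 150,
                     n_founders = 12, switch_rate = 1, founder_ld_rate = 0,
                     missing_rate = 0, het_injection_rate = 0,
                     major_locus = c(chrom = 1, pos = 5e5),
                     modifier_loci = list(c(chrom = 1, pos = 2e5),
                                          c(chrom = 2, pos = 8e5)),
                     seed = 4)
  g2 <- simulate_genotypes(cfg2)
  d <- g2$dosage; storage.mode(d) <- "double"
  on1 <- g2$markers$chrom == "chr1"
  adj <- vapply(which(on1)[-sum(on1)], function(j) {
    stats::cor(d[, j], d[, j + 1])^2
  }, 0)
  set.seed(1)
  cross <- stats::cor(d[, sample(which(on1), 50)],
                      d[, sample(which(!on1), 50)])^2
  expect_lt(abs(mean(adj) - mean(cross)), 0.01)
})

test_that("mean r2 decays with distance under moderate switching", {
  cfg <- sim_config(n_accessions = 150, n_chromosomes = 1,
                    chrom_length_bp = 10e6, n_markers_per_chrom = 500,
                    switch_rate = 2e-5, missing_rate = 0,
                    het_injection_rate = 0,
                    major_locus = c(chrom = 1, pos = 5e6),
                    modifier_loci = list(c(chrom = 1, pos = 2e6),
                                         c(chrom = 1, pos = 8e6)),
                    seed = 6)
  g <- simulate_genotypes(cfg)
  # brute-force r2 over all pairs in a 50-marker sub-window
  sub <- 101:150
  d <- g$dosage[, sub]; storage.mode(d) <- "double"
  cc <- stats::cor(d)^2
  dist_bp <- abs(outer(g$markers$pos[sub], g$markers$pos[sub], "-"))
  ut <- upper.tri(cc)
  near <- dist_bp[ut] < 10e3 & dist_bp[ut] > 0
  nc <- ncol(g$dosage)
  far_pairs <- stats::cor(d[, 1:10],
                          g$dosage[, (nc - 50):nc] * 1.0)^2  # > 1 Mb away
  expect_gt(mean(cc[ut][near]), mean(far_pairs))

  # binned mean r2 non-increasing with distance (within sampling error)
  pr <- sample_marker_pairs(g, n_pairs = 30000, max_dist = 5e6, seed = 1)
  pr <- pairwise_r2(g, pr)
  bins <- cut(pr$d, c(0, 1e4, 5e4, 2e5, 1e6, 5e6))
  mu <- tapply(pr$r2, bins, mean)
  expect_true(all(diff(mu) < 0.02))
})

test_that("phenotype rules implement major locus, modifiers and penetrance", {
  cfg <- small_panel_config(seed = 5, penetrance_major = 1, leak_rate = 0,
                            missing_rate = 0, het_injection_rate = 0)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  major <- g$dosage[, match_id(g, "chr1:4000000")]
  m1 <- g$dosage[, match_id(g, "chr1:1000000")]
  m2 <- g$dosage[, match_id(g, "chr2:6000000")]
  expected <- as.integer(major == 2L | (m1 == 2L & m2 == 2L))
  expect_identical(ph$trait, expected)

  # missing causal genotype -> missing phenotype
  g_na <- g
  g_na$dosage[3, match_id(g, "chr1:4000000")] <- NA_integer_
  ph_na <- simulate_phenotype(g_na, cfg)
  expect_true(is.na(ph_na$trait[3]))
  expect_identical(ph_na$trait[-3], ph$trait[-3])
})

test_that("penetrance is calibrated: colorless fractions within 3 binomial SD", {
  cfg <- sim_config(n_accessions = 2000, n_chromosomes = 1,
                    chrom_length_bp = 2e6, n_markers_per_chrom = 50,
                    penetrance_major = 0.9, leak_rate = 0,
                    missing_rate = 0, het_injection_rate = 0,
                    major_locus = c(chrom = 1, pos = 1e6),
                    modifier_loci = list(c(chrom = 1, pos = 4e5),
                                         c(chrom = 1, pos = 1.6e6)),
                    seed = 7)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  major <- g$dosage[, match_id(g, "chr1:1000000")]
  loss <- which(major == 2L)
  expect_gt(length(loss), 1000)
  frac <- mean(ph$trait[loss])
  sd3 <- 3 * sqrt(0.9 * 0.1 / length(loss))
  expect_lt(abs(frac - 0.9), sd3)

  # defaults reproduce near-complete penetrance and rare carrier colorless
  cfg2 <- sim_config(n_accessions = 1500, n_chromosomes = 1,
                     chrom_length_bp = 2e6, n_markers_per_chrom = 50,
                     missing_rate = 0, het_injection_rate = 0,
                     major_locus = c(chrom = 1, pos = 1e6),
                     modifier_loci = list(c(chrom = 1, pos = 4e5),
                                          c(chrom = 1, pos = 1.6e6)),
                     seed = 8)
  g2 <- simulate_genotypes(cfg2)
  ph2 <- simulate_phenotype(g2, cfg2)
  major2 <- g2$dosage[, match_id(g2, "chr1:1000000")]
  loss_frac <- mean(ph2$trait[major2 == 2L])
  expect_lt(abs(loss_frac - 159 / 161), 3 * sqrt((159 / 161) * (2 / 161) /
                                                   sum(major2 == 2L)))
  carrier_frac <- mean(ph2$trait[major2 == 0L])
  expect_gt(carrier_frac, 0.005)  # some colorless carriers exist...
  expect_lt(carrier_frac, 0.20)   # ...but they are rare (a few per hundred)
})

test_that("origins reproduce the requested genotype-latitude correlation", {
  base <- list(n_accessions = 1000, n_chromosomes = 1, chrom_length_bp = 2e6,
               n_markers_per_chrom = 60, missing_rate = 0,
               het_injection_rate = 0,
               major_locus = c(chrom = 1, pos = 1e6),
               modifier_loci = list(c(chrom = 1, pos = 4e5),
                                    c(chrom = 1, pos = 1.6e6)))
  for (case in list(c(eff = 0, tol = 0.1), c(eff = 0.39, tol = 0.08))) {
    cfg <- do.call(sim_config, c(base, list(geo_effect = case[["eff"]], seed = 11)))
    g <- simulate_genotypes(cfg)
    org <- simulate_origins(g, cfg)
    pc1 <- geno_pca(g, 1)$scores[, 1]
    expect_lt(abs(abs(stats::cor(pc1, org$latitude)) - abs(case[["eff"]])),
              case[["tol"]])
  }
  # exact correlation at geo_effect = 1 (zero noise)
  cfg1 <- do.call(sim_config, c(base, list(geo_effect = 1, seed = 12)))
  g1 <- simulate_genotypes(cfg1)
  org1 <- simulate_origins(g1, cfg1)
  pc1 <- geno_pca(g1, 1)$scores[, 1]
  expect_equal(abs(stats::cor(pc1, org1$latitude)), 1, tolerance = 1e-12)
  # region labels come from the declared closed set
  expect_true(all(org1$region %in% c("DR", "WCR", "ECR", "CDZ", "EMR",
                                     "WMR", "NMR")))
})

test_that("fixtures round-trip through the VCF reader and refuse overwrites", {
  cfg <- small_panel_config(seed = 13)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g, cfg)
  org <- simulate_origins(g, cfg)
  dir <- tempfile()
  paths <- write_fixture(g, ph, org, dir)
  expect_error(write_fixture(g, ph, org, dir), "exist")
  g2 <- read_vcf(paths[["vcf"]])
  expect_equal(unname(g2$dosage), unname(g$dosage))
  expect_equal(g2$markers[, c("chrom", "pos")], g$markers[, c("chrom", "pos")])
  ph2 <- read_phenotype(paths[["pheno"]])
  expect_equal(ph2$trait, ph$trait)
  org2 <- read_origins(paths[["origins"]])
  expect_equal(org2$region, org$region)

  # byte-identical regeneration from the same config
  dir2 <- tempfile()
  write_fixture(simulate_genotypes(cfg), ph, org, dir2)
  expect_identical(readLines(file.path(dir2, "genotypes.vcf")),
                   readLines(paths[["vcf"]]))

  # a 3-accession, 2-marker fixture with exactly one missing call
  g3 <- toy_geno(matrix(c(0L, 2L, NA, 2L, 0L, 0L), nrow = 3))
  ph3 <- data.frame(accession_id = g3$accessions, trait = c(1L, 0L, 1L))
  or3 <- data.frame(accession_id = g3$accessions, latitude = 1:3,
                    longitude = 4:6, region = "DR")
  p3 <- write_fixture(g3, ph3, or3, tempfile())
  expect_equal(sum(gregexpr("\\./\\.", paste(readLines(p3[["vcf"]]),
                                             collapse = ""))[[1]] > 0), 1)

  # degenerate input: no markers -> error, nothing written
  g0 <- suppressWarnings(subset_markers(g3, integer(0)))
  dir0 <- tempfile()
  expect_error(write_fixture(g0, ph3, or3, dir0), "no markers")
  expect_false(file.exists(file.path(dir0, "genotypes.vcf")))
})
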