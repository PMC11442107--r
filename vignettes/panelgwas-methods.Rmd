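---
title: "Methods: population structure, LD decay and mixed-model GWAS in inbred panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure, LD decay and mixed-model GWAS in inbred panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelgwas)
```

`panelgwas` implements the analysis chain used for genome-wide association
in fully inbred crop diversity panels — collections of a few hundred
seed-bank accessions, each treated as a single homozygous genotype, scored
at millions of biallelic SNPs. This vignette documents the statistical
models, the numerical choices behind them, and the design decisions that
were genuinely open.

## Data model and marker post-filters

Genotypes live in a `genotype_matrix`: an accession × marker matrix of
alt-allele dosages (0, 1, 2, or missing) plus a sorted marker map. Because
the accessions are inbred, true heterozygotes are essentially absent and
residual `0/1` calls reflect genotyping error or seed admixture;
`mask_heterozygotes()` therefore sets every dosage-1 call to missing as an
explicit, testable stage rather than silently inside the reader.

The standard filters follow the conventions of inbred-panel pipelines:

* **MAF filter** — keep markers with minor-allele frequency *strictly
  greater* than the cutoff (default 0.05). The strictness matters at the
  boundary and is asserted by tests.
* **Missingness filter** — keep markers with missing rate *at most* the
  cutoff (0.20 for association scans; structure analyses conventionally use
  a tighter 0.10).
* **Window pruning** — for structure analyses, one marker per 20-kb
  stretch. Positions are 1-based as in VCF; windows are 0-based half-open
  bins anchored at the chromosome start, so positions 19,999 and 20,001
  fall in different 20-kb bins. The kept marker is the one with the lowest
  missing rate (ties: lowest position). Which marker per stretch to keep is
  not dictated by any standard; lowest-missingness is chosen because it
  maximizes information and is deterministic.

## Population structure

PCA mean-imputes missing dosages per marker and centers columns;
variance-scaling is available (`scale. = TRUE`) but off by default, the
usual choice for SNP dosages where scaling would up-weight rare alleles.
Contribution ratios are eigenvalue shares over all computed components.

The phylogeographic summary uses the Euclidean distance between
(mean-imputed) dosage vectors on a random marker subsample — the same
imputation convention as PCA, so distances and PCA see the same matrix — a
neighbor-joining tree (Saitou–Nei, via `ape::nj()`), and the standard
phylogenetic bootstrap that resamples marker columns with replacement
(`ape::boot.phylo()`). NJ recovers tree-additive distance matrices exactly;
the test suite verifies this through the package surface for 4–8 taxa.

Varietal groups are delimited by removing the *k − 1* longest internal
edges of the NJ tree and labelling the connected leaf components VG1..VGk
by decreasing size. No standard defines how to cut an NJ tree into a fixed
number of groups; longest-internal-edge removal was chosen as a
deterministic, parameter-free convention, and is flagged as such here.
Geographic enrichment compares observed group-by-region counts with
contingency-margin expectations (`group total × region total / grand
total`); each group is assigned the region maximizing the
observed/expected ratio, with ties broken by larger observed count and
then lexicographically.

## LD decay and the half-decay distance

Pairwise linkage disequilibrium is the squared Pearson correlation of
dosage vectors over accessions non-missing at both markers (*composite
r²*). For fully homozygous lines with hets masked this equals haplotype
r², so no EM-based phase estimation is needed — a deliberate divergence
from estimators designed for heterozygous data.

Pairs are sampled uniformly without replacement from the implicit space of
same-chromosome pairs separated by at most a distance cap (default 10 Mb,
500,000 pairs), never materializing the full pair set. The expected decay
is modelled by an extended Hill–Weir hyperbola

$$E[r^2] = \frac{r^2_{high} - r^2_{low}}{1 + d\, r_d} + r^2_{low},$$

with $r^2_{high}$, $r^2_{low}$ the maximum and minimum observed r²
asymptotes and $r_d$ the decay rate per bp. The distance at which the
curve falls halfway between its asymptotes is $d_{LD50} = 1/r_d$, an exact
algebraic consequence of the model that `d_ld50()` re-verifies on every
call. The genome-wide $d_{LD50}$ is the arithmetic mean of per-chromosome
values; a pooled single fit exists but is off by default. Pair sampling is
genome-wide with per-chromosome fitting — whether sampling should instead
be stratified per chromosome is ambiguous in common practice; the
genome-wide interpretation was adopted and the per-chromosome pair counts
are reported.

Numerics: the model is fitted with `stats::nls()` (port algorithm) under
box constraints $0 \le r^2_{low}, r^2_{high} \le 1$, $r_d > 0$. Distances
are internally rescaled by their median so the rate parameter is O(1);
starting values take $r^2_{high}$ from the closest 1% of distances,
$r^2_{low}$ from the farthest 1%, and $r_d$ = 1/median distance, with five
jittered restarts and lowest-RSS selection. Port's "singular convergence"
is accepted (it returns a least-squares iterate with a flat direction —
typical when few short-distance pairs constrain $r^2_{high}$). A flat
sample leaves $r_d$ unidentifiable: the fit is flagged `degenerate`, its
$d_{LD50}$ is undefined, and the genome-wide average skips it with a
warning rather than propagating an astronomical distance.

## Mixed-model association

The random-effect covariance is the VanRaden genomic relationship matrix:
markers mean-imputed, standardized as $(x - 2p)/\sqrt{2p(1-p)}$, and
cross-multiplied over the polymorphic markers, $K = ZZ'/m$.

For a **quantitative** response the null model $y = X\beta + u + e$,
$u \sim N(0, \tau K)$, is fitted by REML via the eigendecomposition of
$K$, profiling the restricted likelihood over the variance ratio with a
1-D optimizer (boundary $\tau = 0$ checked explicitly). For a **binary**
response the null is a logistic linear mixed model fitted by penalized
quasi-likelihood: iterate the working response
$z = \eta + (y - \mu)/W$ with weights $W = \mu(1 - \mu)$, re-estimating
$\tau$ by REML on the working covariance $\tau K + W^{-1}$ each step,
until the linear predictor changes by less than 1e-6 (max 100
iterations). Applying the *quantitative* machinery to a 0/1 coding
reproduces the Gaussian-on-binary fallback that practitioners reach for
when the logistic conditional model inflates genome-wide p-values — a
known behavior of binary mixed-model scans with strong fixed-effect
covariates, which is why `conditional_scan()` exposes both responses.

Each marker is tested by a **score test** with variance components held at
their null estimates: $U = g'P y^*$, $\mathrm{Var}(U) = g'Pg$ with $P$ the
null model's projection matrix and $y^*$ the (working) response, giving a
1-df chi-squared statistic. This one-null-fit-per-scan strategy is the
standard fast approximation in mixed-model GWAS; per-marker refitting is
not implemented. At $\tau = 0$ the binary score test reduces exactly to
the classical logistic-regression score test, and with $K = I$ the
quantitative test matches ordinary regression asymptotically — both are
enforced by oracle tests. Missing dosages are mean-imputed per marker so
the sample size is constant across markers. The reported `effect` is the
one-step estimate $U/\mathrm{Var}(U)$. No principal components are
included as fixed effects by default (appropriate for a panel with no
subpopulation structure); covariates can be supplied where needed.

Multiple testing uses Benjamini–Hochberg q-values (`p.adjust`,
`method = "fdr"`; missing p-values are excluded from the marker count).
Threshold lines for Manhattan plots are the BH rejection boundaries
rendered in −log10(p) units at FDR 0.05 ("suggestive") and 0.01
("significant"); when nothing passes, the line is placed just above the
maximum observed score so that zero markers clear it.

## QTL region calling

A QTL region is a window of the genome-wide $d_{LD50}$ either side of a
peak marker that contains (a) at least one marker at or above the
significant line and (b) at least two markers at or above the suggestive
line, *counting the peak itself*. Reading "multiple suggestive markers" as
"the peak is not alone" rejects isolated single-marker spikes — the
evident purpose of the rule — and is recorded here as an interpretation.
Calling is greedy per chromosome: the strongest unclaimed significant
marker seeds a window, in-window markers are claimed, and overlapping
candidate windows therefore merge into the stronger peak's region; ties
break to the lower position, so calling is deterministic and
order-invariant. Regions are named `q<trait><chrom>.<index>` in positional
order.

Peak characterization reports pairwise Pearson correlations between peak
genotypes (complete-case per pair; the self-correlation of any
polymorphic peak is exactly 1), local pairwise-r² matrices for LD heatmap
rendering, and — given a GFF3 annotation — genes whose spans intersect a
region window, ordered by distance from the peak.

## The synthetic panel generator

The generator exists so the whole chain is testable end-to-end without
external data. It emulates a panel of ~250 fully inbred accessions drawn
from a single well-mixed population: no subpopulation clusters, LD that
decays with physical distance, a weak genotype–latitude cline, and a
binary apiculus-color phenotype under major-gene control with
near-complete penetrance.

* **Genotypes** are founder-haplotype mosaics: each accession's chromosome
  copies one of `n_founders` (default 20) founder haplotypes, switching
  founders between adjacent markers with probability
  `1 − exp(−switch_rate · gap)` (default 2e-5/bp), giving geometric
  segment lengths. The founder haplotypes themselves share local ancestry:
  founder allele columns evolve along the map as a Markov chain whose
  correlation decays at `founder_ld_rate` (default 5e-6/bp), so panel r²
  rises toward 1 at short distances instead of being capped near
  1/(n_founders − 1). The mapping from these two rates to the fitted
  $r_d$ is approximate and is always estimated empirically from the
  simulated data, never assumed. At default settings the realized
  genome-wide $d_{LD50}$ is of order 10 kb — smaller than real rice
  panels (which print values near 100 kb) because the simulated marker map
  is ~40× sparser; the decay *shape* and the pipeline behavior, not the
  absolute scale, are what the defaults target.
* **Inbred coding**: genotypes are generated homozygous (dosage 0/2);
  heterozygous calls exist only as injected noise (default 1% of calls),
  and missing calls are inserted at 5%, to exercise the masking and
  filtering stages.
* **MAF control**: founder allele counts are constrained so every marker's
  frequency is attainable above `maf_min`; markers whose realized panel
  MAF still falls short are repaired by nudging the founder allele count
  toward the interior — a repair that preserves local ancestry, unlike a
  redraw. Configurations where no founder allele count can satisfy
  `maf_min` are rejected at construction.
* **Phenotype**: colorless (coded 1) iff loss-homozygous at the major
  locus (alt allele = loss; default founder frequency 0.72, penetrance
  159/161), or functional-allele carrier that is alt-homozygous at *both*
  modifier loci (default modifier frequency 0.26, so roughly 5–7% of
  carriers), or `leak_rate` noise (default 0). These defaults reproduce
  the observed scale of near-complete major-gene penetrance with rare
  colorless carriers explained by complementary modifiers; whether such
  exceptions arise from genetics or scoring error is not decidable from
  counts alone, so both `leak_rate` and the modifier pair are exposed to
  simulate either hypothesis. A missing genotype at any causal locus
  yields a missing phenotype.
* **Origins**: latitude is a linear function of genotype PC1 plus noise,
  scaled so the PC1–latitude correlation approaches `geo_effect`
  (default 0.39; exactly 1 when `geo_effect = 1`); longitude follows PC2
  at 0.22. Seven fixed latitude bands map to the region labels DR, WCR,
  ECR, CDZ, EMR, WMR, NMR (south to north) — purely a fixture convention.
* **Seeds**: one master seed; per-stage streams are derived by fixed
  offsets so genotypes, phenotype and origins can be regenerated
  independently and fixtures are byte-identical across runs.

What the generator does *not* emulate: subpopulation admixture,
genotyping-by-sequencing artifacts, allele-frequency spectra from real
demography, variable marker density, or quantitative traits. Passing tests
therefore demonstrate the correctness and calibration of the machinery
under idealized inbred-panel conditions, not performance on real data.

## Problem sizes used in the tests

The test suite and acceptance script choose sizes that keep each property
informative: oracle equivalences run on 3×2 to 50×20 fixtures; type-I
calibration uses a 200-accession, ~2,500-marker weak-LD panel (so marker
tests are effectively independent and the binomial bound applies);
planted-locus recovery runs 20 replicates of the full default panel (250
accessions × 12 chromosomes × 5,000 markers) with the LD-decay window
re-estimated per replicate from 100,000 pairs capped at 2 Mb — a cap well
above the simulated LD range that concentrates sampling where the decay
curve carries information.

## Known limitations

* PQL is a first-order approximation; for rare binary traits or strong
  polygenic variance its variance components are biased toward zero, a
  known property of the algorithm. The score test inherits the null fit.
* The FDR thresholds are computed over all scanned markers jointly;
  per-chromosome adjustment is not offered.
* `fit_ld_decay()` estimates asymptotes from observed r², so with few
  short-distance pairs $r^2_{high}$ is weakly identified (singular
  convergence); the genome-wide $d_{LD50}$ remains stable because it
  depends on $r_d$.
* The tree-cutting and region-enrichment conventions are reasonable
  defaults, not community standards; both are deterministic and
  documented so results are reproducible and comparable.
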