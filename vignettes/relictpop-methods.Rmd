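---
title: "Models and methods in relictpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in relictpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`relictpop` implements the analysis chain used in conservation-genomics
studies of small, fragmented plant populations, plus a synthetic-data
generator that produces panels with known truth so every stage can be
validated quantitatively. This vignette explains the models, the
parameters that matter, the numerical choices, and what passing the test
suite does and does not demonstrate about real data.

## The coalescent generator

### Demographic model

`demography_config()` describes a caterpillar-shaped multi-lineage
history: lineage 1 diverges at the oldest split, later lineages peel off
toward the present. Time is in generations; the defaults translate a
100 kya and a 40 kya divergence through a 5-year generation time into
splits at 20,000 and 8,000 generations, with mutation rate
μ = 1.25×10⁻⁸ per site per generation. Backward in time the simulator is
an event-driven structured coalescent: within-deme coalescence at rate
k(k−1)/2 / 2Nₑ, migration of single lineages between extant demes, mass
moves at splits, and stepwise deme-size changes at epoch boundaries.

Per-lineage effective sizes are treated as free conditions of the
emulated system, calibrated once so that the simulated panels reproduce
the population-genetic regime of a three-lineage relict fern: per-lineage
π around 1.0–1.4×10⁻³ with the first lineage lowest, pairwise F_ST
roughly between 0.12 and 0.32, and positive Tajima's D after
bottlenecks. The defaults achieving this
are Nₑ = (8000, 10000, 14000) for the extant lineages,
ancestral sizes (20000, 15000), a pre-bottleneck root size of 40,000
older than 36,000 generations, and symmetric migration 2.5×10⁻⁵ per
generation. These are conditions, not estimates; change them freely.

### Recombination approximation

Linkage is modelled as *free between* blocks of `block_bp` (default
5 kb) consecutive bases and *complete within* a block: each block gets
its own genealogy, and infinite-sites mutations fall on it
independently. This is the classical independent-loci approximation. It
reproduces the site-frequency-spectrum statistics (π, Tajima's D, F_ST)
and gives realistic within-block LD, but the LD decay curve has no
structure beyond the block scale, and background homozygosity is
mosaic-like at 5 kb granularity. The ROH detector's length thresholds
(≥ 100 kb ≈ 20 blocks) average over this mosaic.

### Planted truth layers

* **ROH**: `plant_roh()` collapses heterozygotes to homozygotes inside
  sampled tracts (coin-flip allele per site), recording merged tract
  coordinates. Planted F_ROH is exact arithmetic on the truth table.
* **Functional variants**: `inject_functional_variants()` enumerates
  all single-base coding changes over the simulated CDS, verifies each
  label against the standard genetic code, and injects sites with
  per-lineage genotype frequencies. Defaults (synonymous 100, missense
  120 with half radical by Grantham ≥ 150, stop-gained 40; homozygous
  frequency 0.2 in the focal lineage vs 0.1 elsewhere) put the panel in
  the elevated-homozygous-load regime with π₀/π₄ near 0.45–0.51 when
  combined with `purify_zero_fold()` (keep = 0.45), the
  relaxed-purifying-selection regime reported for endangered ferns.
* **Environment**: seven bioclim-like surfaces are smooth functions of
  latitude/longitude, built from coarse regional gradients plus
  fine-scale "topographic" oscillations. Weights are whitened against
  the site covariance and mixed to a target correlation structure — a
  temperature-like and a precipitation-like block (within-block r =
  0.68, across 0.2), all pairs below the |r| < 0.7 pruning ceiling. An
  accept-loop additionally guarantees that at least half of each
  variable's variance lies *within* lineages and that the block
  correlations survive conditioning on lineage, because
  structure-corrected association tests can only find signal there.
* **Adaptive loci**: selected loci (default 120, ~1.4% of segregating
  sites, matching the adaptive fractions reported for range-wide plant
  panels) receive logistic clines, `p = plogis(3·gradient)`. The
  gradient is a 50/50 blend of the assigned variable and its block
  mean: organisms respond to integrated climate syndromes rather than a
  single bioclim summary, and this is precisely the structure that
  makes the "significant for ≥ 3 variables" outlier rule attainable.
  Clines planted on a strictly private variable leave the partner
  variables' signals at the false-discovery margin, and recall of the
  core adaptive set becomes a coin toss — a useful reminder that the
  multi-variable rule implicitly assumes correlated predictors.

### What the generator does not emulate

Gene conversion, structural variation, linked selection, realistic
recombination maps, genotyping error beyond uniform missingness
(default 2%), reference bias, and gametophyte selfing. Tests passing on
these panels show the *estimators* are correct and the *workflow* is
coherent; they do not certify robustness to artifacts real resequencing
data carry.

## Statistical choices

* **π** uses the pixy-style denominator: positions without a variant
  record are assumed invariant and callable at the mean non-missing rate
  of the window's variant sites. Windows with no variants report π = 0;
  windows with no callable genotypes report `NA`.
* **F_ST** is Hudson's estimator as a ratio of sums (the choice pixy
  makes), not Weir–Cockerham; negative per-window values are reported as
  computed. Linearized distances F_ST/(1−F_ST) clamp F_ST at 1−10⁻⁶.
* **Tajima's D** uses the full haplotype count of the sample for its
  constants; the per-site π terms are missing-aware. S = 0 windows are
  `NA`, never 0.
* **Heterozygosity** is het calls over callable sites; with a genome
  size supplied the denominator includes assumed-invariant callable
  positions, putting it on the π scale.
* **ROH** detection is PLINK-like: 50-SNP scanning windows with ≤ 1
  heterozygote and ≤ 5 missing calls, SNP hit-fraction ≥ 0.05, minimum
  segment length 100 kb. Candidate segments must qualify on their own
  *before* gap-merging (merging first welds the background mosaic into
  genome-wide false segments); the merge gap defaults to 100 kb on
  desk-size genomes.
* **Polarization**: an allele is ancestral when more than 50% of
  non-missing individuals are homozygous for it; exact ties and
  majority-less sites are excluded from load metrics. Missing genotypes
  are excluded from the denominator.
* **Load ratio** defaults to 2·hom/(2·hom+het), the fraction of derived
  deleterious alleles carried homozygously, bounded in [0,1]. The
  literal box-plot arithmetic 2·hom/(hom+het) seen in figure captions
  can exceed 1 and is offered as `formula = "literal"`.
* **Latent-factor GEA** replaces MCMC with a deterministic construction:
  the top-K left singular vectors of the scaled genotype matrix enter as
  covariates (K = 3 by default). p-values come from the exact t
  distribution (squared t at n ≈ 20–70 is heavier-tailed than χ²₁),
  are mapped through the normal quantile, and the squared z-scores are
  rescaled by the genomic inflation factor (median-χ² calibration)
  before per-variable Benjamini–Hochberg adjustment.
* **RDA outliers** come from the SVD of the environmental fitted-value
  matrix of centered dosages, with per-axis standardized loadings and a
  ±3.5 SD rule. By default *all* constrained axes are examined: with
  several weakly correlated predictors the leading axes are dominated by
  neutral structure and adaptive signal loads on trailing axes, so a
  fixed "first 3 axes" rule caps recall near 0.6 regardless of effect
  size (`n_axes = 3` restores it).
* **Mantel tests** use one-sided upper-tail permutation p-values
  (positive association is the isolation-by-distance/environment
  hypothesis), permuting rows and columns of the first matrix jointly.
  The partial test correlates residuals after regressing each matrix on
  the control; a constant control degenerates to the plain test and a
  control identical to the second matrix leaves r = 0 by convention.
* **Great-circle distances** use the haversine formula on the WGS84 mean
  radius (6371.0088 km).

## The generalized dissimilarity model

`gdm_fit()` is a from-scratch GDM: each predictor enters through a
monotone function f_p(x) = Σ_k w_pk·I_pk(x) built from three order-2
I-splines with knots at the predictor's min/median/max, the linear
predictor is η = a₀ + Σ_p |f_p(x_i) − f_p(x_j)| (geographic distance, if
included, enters as its own monotone predictor evaluated at the
distance), and the response link is d = 1 − exp(−η). Because every
basis function is non-decreasing, |f_p(x_i) − f_p(x_j)| is linear in the
coefficients, so the fit is a single non-negative least squares solve on
the transformed response η = −ln(1−d) — deterministic, exact in the
noiseless case, and guaranteeing monotone fitted functions and
predictions in [0,1). This replaces the reference implementation's
iteratively reweighted likelihood; for the smooth, low-noise responses
used here the two agree closely, but the NNLS fit does not provide
likelihood-based uncertainty.

The response for offset work is population-pair F_ST/(1−F_ST) on the
adaptive loci, rescaled into [0,1) by the observed maximum times a
`headroom` factor of 1.05. A headroom of 1+10⁻⁶ would pin the largest
pair at η ≈ 13.8 and let a single saturated pair dominate the fit;
1.05 caps η near 3 while preserving the ordering.

Offsets: local = predicted dissimilarity between a cell's current and
future climate; forward/reverse = the minimum over candidate cells of
the current→future (future→current) dissimilarity, with the geographic
term zeroed so offsets measure climate mismatch, not travel cost.
Migration distance is the haversine distance to the nearest cell whose
future climate keeps the predicted offset under τ (0.15 "high", 0.05
"moderate"); a cell that qualifies in place has distance 0, and a cell
with no refuge anywhere is `NA`. RGB channels min-max normalize the
three offsets over the grid. One future scenario is processed per call;
scenario ladders are loops over `shift_scale`.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → filter → stats/roh/load → gea →
offset, writing plain-text artifacts (VCF, FASTA, GFF3, TSV, Newick,
markdown report) to one directory. Per-stage seeds are derived from the
master seed by fixed offsets, so a rerun with the same configuration is
byte-identical. Unknown configuration keys are rejected.

Problem sizes: the bundled demonstration and the acceptance script use
the default panel (68 diploids in three lineages) on a 2-Mb
two-chromosome genome with 40 genes — large enough that windowed
statistics have ~20 windows, ROH tracts span hundreds of SNPs, the
MAF-filtered set holds ~9,000 loci, and the whole run takes well under a
minute. Calibration tests use 30 replicates of a 1-Mb single-population
panel (n = 20) for π and Tajima's D, and ~16,000 unlinked loci for the
association null rates.

## Known limitations

* The independent-blocks coalescent understates long-range LD; LD decay
  beyond 5 kb is flat by construction.
* Heterozygosity and π share a synthetic callable-site model; on real
  data (e.g. folded-SFS heterozygosity from genotype likelihoods) the
  absolute scales differ even when the ranking is preserved.
* The GDM is fitted to as few population pairs as the panel provides
  (dozens); its uncertainty is not quantified.
* The "core adaptive set" intersects two outlier tests but inherits any
  shared confounding between them; on real data its size is sensitive
  to the latent-factor count and the FDR threshold in ways the synthetic
  panels only partially probe.
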