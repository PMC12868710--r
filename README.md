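# relictpop

Conservation genomics for small, fragmented plant populations, end to end
and at desk scale. `relictpop` is aimed at population geneticists who want
a tested, reproducible implementation of the analysis chain that modern
conservation-genomics studies of relict species run on resequencing
panels — from filtered genotypes through diversity, inbreeding, and
genetic load, to genotype–environment association and climate-driven
genetic offsets — together with a coalescent simulator that generates
panels with known truth for validating every step.

## What the package computes

**Synthetic panels with planted truth.** A self-contained structured
coalescent (event-driven coalescence, migration, population splits and
size changes; infinite-sites mutation on independent non-recombining
blocks) simulates multi-lineage demographies. Defaults emulate a
three-lineage relict fern system: divergence at 20,000 and 8,000
generations (100 kya and 40 kya at 5 y/generation), μ = 1.25×10⁻⁸,
post-glacial bottlenecks, and weak migration. On top of the neutral panel
the generator plants: autozygous tracts (known ROH), codon-verified
functional variants (synonymous / missense / stop-gained) with
controllable per-lineage homozygous burdens, purifying-selection thinning
at 0-fold degenerate sites, and logistic allele-frequency clines along
bioclim-like environmental gradients.

**Variant handling.** GATK-style hard filters
(QD < 2, MQ < 40, FS > 60, SOR > 3, MQRankSum < −12.5,
ReadPosRankSum < −8; strict inequalities, absent annotations pass),
core-variant selection (biallelic SNPs, missingness cap), a strict
MAF > 5% filter, and PLINK-style windowed LD pruning.

**Diversity and structure.** Windowed nucleotide diversity with a
pixy-style callable-site denominator

&nbsp;&nbsp;&nbsp;&nbsp;π = Σ_sites 2p̂(1−p̂)·n/(n−1) / callable bp,

Hudson's F_ST as a ratio of sums

&nbsp;&nbsp;&nbsp;&nbsp;F_ST = Σ[(p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1)] / Σ[p₁(1−p₂)+p₂(1−p₁)],

Tajima's D, individual heterozygosity, LD decay, PCA, neighbor-joining
trees, and Mantel / partial-Mantel tests of isolation by distance and by
environment on F_ST/(1−F_ST) matrices.

**Inbreeding.** PLINK-style two-phase ROH detection (50-SNP scanning
windows, het/missing allowances, per-SNP hit fraction, 100-kb minimum
length) and F_ROH by length class (> 100 kb, > 1 Mb).

**Genetic load.** Derived-allele polarization by the majority-homozygote
rule (> 50% of individuals sharing a homozygous genotype), a codon-level
effect classifier against the standard genetic code, the published
Grantham (1974) distance matrix with the GS ≥ 150 deleterious screen,
per-individual load ratios 2·hom/(2·hom+het) for deleterious and
loss-of-function alleles, homozygous-LOF density inside vs outside ROH
(Wilcoxon rank-sum), 0-fold/4-fold degeneracy annotation, and π₀/π₄.

**Genotype–environment association.** Correlation pruning of
environmental variables (|r| < 0.7), a deterministic latent-factor
regression (top-K genotype singular vectors as covariates, K = 3,
genomic-inflation calibration, per-variable BH FDR < 0.05 with the
≥ 3-variables rule), redundancy-analysis outliers (|loading z| > 3.5),
and the core adaptive set as their intersection.

**Genetic offset.** A generalized dissimilarity model written from
scratch: order-2 I-spline basis (3 functions, knots at min/median/max),
negative-exponential link d = 1 − exp(−η), non-negative least squares;
then local, forward and reverse offsets on climate grids, RGB
vulnerability channels, migration distance and bearing to the nearest
climatically tolerable cell at offset thresholds 0.15 and 0.05, and polar
summaries of migration direction.

## Worked example

```r
library(relictpop)

cfg <- demography_config(seed = 7)       # three-lineage defaults
sim <- simulate_genotypes(cfg)
sim
#> Synthetic resequencing panel: 68 diploid samples, 16660 biallelic SNPs
#>   lineages: SC (n=42), VN (n=5), YN (n=21)
#>   genome: 2e+06 bp in 2 chromosome(s)

m <- sim$meta
yn <- m$sample_id[m$lineage == "YN"]; sc <- m$sample_id[m$lineage == "SC"]
mean(window_pi(sim$gm, sim$vt, sim$chrom_lengths, yn)$pi, na.rm = TRUE)
#> [1] 0.00124
hudson_fst(sim$gm, match(yn, m$sample_id), match(sc, m$sample_id))
#> [1] 0.257

sim <- plant_roh(sim, n_tracts = 2, length_range = c(3e5, 5e5),
                 samples = yn[1:5], seed = 8)
seg <- detect_roh(sim$gm, sim$vt)
froh(seg, sum(sim$chrom_lengths), samples = yn[1:5])[1:5, ]
#>   sample  class total_roh_bp genome_bp      froh
#> 1  YN_01 medium       481831     2e+06 0.2409155
#> 2  YN_02 medium       566381     2e+06 0.2831905
#> 3  YN_03 medium       742463     2e+06 0.3712315
#> 4  YN_04 medium       768279     2e+06 0.3841395
#> 5  YN_05 medium       438580     2e+06 0.2192900
mean(roh_recovery_score(seg, sim$truth$planted_roh))
#> [1] 0.991
```

The YN lineage shows the lowest diversity (π ≈ 1.2×10⁻³), lineage
divergence is moderate (F_ST ≈ 0.26), and the detector recovers the
planted autozygous tracts almost perfectly (base-pair Jaccard 0.99) —
the inbred individuals' F_ROH (0.22–0.38) is the fraction of their
genome inside runs of homozygosity longer than 100 kb.

The whole chain — simulation, filtering, statistics, ROH, load, GEA,
offsets, and a markdown report — runs as one call:

```r
run_pipeline(pipeline_config(seed = 11), "out/")
```

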