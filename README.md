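# migrasv

Structural-variant (SV) population genomics for wild migratory birds, built
around the study design used for the Eurasian blackcap (*Sylvia
atricapilla*): a cohort of individually tracked birds, each genotyped for
SVs by several independent callers, with migratory phenotypes derived from
light-level geolocator tracks.

The package covers the full analysis chain as tested, reusable functions:

- **Consensus calling and merging** — SURVIVOR-style breakpoint clustering:
  within an individual, a call is kept when at least two callers place both
  breakpoints within 1 kb of each other *and* agree on the genotype; calls
  shorter than 50 bp or carrying runs of more than 10 N bases are removed;
  per-individual call sets are then merged across the cohort (same rules,
  at least 4 carriers) into a loci-by-individuals dosage matrix, filtered
  at minor allele frequency (MAF) ≥ 0.05.
- **Genome landscape** — SV densities in 200-kb windows, per-window GC
  content, per-type size spectra, and overlap with a repeat annotation.
- **Population genetics** — folded allele-frequency spectra (insertions and
  deletions pooled, since their polarity against the reference is
  arbitrary), Tajima's D, Hudson's FST per locus

  `num = (p1 − p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)`,
  `den = p1(1−p2) + p2(1−p1)`,

  genome-wide FST as the ratio of sums, and the population branch statistic
  for three groups, `PBS_X = (T_XY + T_XZ − T_YZ)/2` with
  `T = −ln(1 − FST)`, plus top-5% outlier genes, linkage disequilibrium
  inside inversions against size-matched colinear controls, and PCA.
- **Migratory traits** — rhumb-line direction and distance between breeding
  and wintering sites, wintering longitude, 50%-route timing and 30–70%
  duration from great-circle route fractions, speed, and NW/SW/SE/S group
  classification (37.5° N latitude rule with 5° E / 20° E longitude
  cutoffs, 0° E south of 37.5° N).
- **GWAS** — a Bayesian sparse linear mixed model (BSLMM):
  `y = 1μ + Xβ + u + ε` with a spike–slab prior on `β` and a kinship random
  effect `u ~ N(0, σ_b²K)`, sampled by MCMC with the random effect
  integrated out analytically. Reports PVE ("chip heritability"),
  per-variant posterior inclusion probabilities (PIP) and model-averaged
  effects, genetic correlations between traits, and polygenic-score
  cross-validation with 25% of phenotypes masked per fold.
- **Synthetic cohorts with known truth** — Balding–Nichols population
  structure, branch-specific selected loci, three noisy emulated callers
  (breakpoint jitter, dropout, genotype error), repeat/gene annotations,
  genotype-driven phenotypes and constant-speed daily migration tracks, so
  every stage is testable end to end without any external data.

## Worked example

Simulate a blackcap-shaped cohort (79 birds in four migratory groups,
~15,000 SV loci, one 710-bp focal deletion on a microchromosome driving
migratory direction) and run the whole chain:

```r
library(migrasv)
report <- run_blackcap_pipeline(seed = 1)
report
#> <blackcap_pipeline>
#>   loci: 15000 truth -> 14960 merged -> 14737 after MAF filter
#>   weighted FST: NW_SW 0.023, NW_SE 0.023, SW_SE 0.022
#>   direction GWAS: PVE 0.94 +/- 0.06, top PIP locus_13376 (1.00)
#>   focal deletion: merged as locus_13376, top-PIP TRUE, PBS_SE percentile 1.000
```

Reading the output: of 15,000 simulated SVs, 14,960 survive multi-caller
consensus and cohort merging and 14,737 pass the MAF filter; genome-wide
weighted FST between migratory groups is ~0.02 (weak structure, as in wild
blackcaps); and the GWAS on geolocator-derived migratory direction assigns
its highest posterior inclusion probability to exactly the merged locus
that corresponds to the simulated focal deletion, which also sits at the
top of the SE-branch PBS distribution — the pipeline recovers the planted
signal through every noisy stage.

Individual stages are plain functions on tibbles:

```r
calls  <- read_sv_vcf("callerA.vcf", caller_label = "A")
cons   <- consensus_individual(list(a = callsA, b = callsB, c = callsC))
cohort <- merge_cohort(per_individual_consensus) |> maf_filter(0.05)
fit    <- bslmm_fit(prepare_trait(direction, sex), cohort, seed = 1)
tidy(fit)      # per-variant PIP and model-averaged effects
glance(fit)    # PVE, PGE, model size
autoplot(fit)  # PIP Manhattan plot
```

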