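---
title: "Models and methods behind migrasv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind migrasv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

migrasv implements the analysis chain used to study structural variants
(SVs) in a wild cohort of migratory songbirds: noisy multi-caller SV call
sets are reduced to a cohort genotype matrix, characterized with
population-genetic statistics, and connected to geolocator-derived
migratory traits with a sparse Bayesian mixed model. This vignette explains
each model, the parameters that matter, the design choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Coordinate conventions

Every interval inside the package is 0-based and half-open, `[start, end)`.
VCF (1-based positions) and GFF3 (1-based closed intervals) are converted
at the reader/writer boundary and nowhere else; BED is passed through
unchanged. Insertions occupy a 1-bp breakpoint interval (`end = start + 1`)
with the inserted length carried separately, which keeps interval overlap
queries well-defined for all five SV types (DEL, INS, DUP, INV, TRA).
Translocations are stored by their source interval only, so interval
analyses always have one locatable span per variant.

## Consensus genotyping and cohort merging

Within an individual, calls from independent callers are clustered
greedily: calls are sorted by start; each unassigned call seeds a cluster
and recruits, per other caller, the nearest unassigned call whose start
*and* end both lie within `max_dist` (default 1,000 bp) of the seed's
breakpoints (distance = the larger of the two breakpoint offsets; ties go
to the smaller start). A cluster becomes a consensus call only when at
least two distinct callers support it with identical (unphased) genotypes;
the representative record is the concordant supporter with the median
start, the lower of the middle pair for even counts, which is robust to
breakpoint jitter. Calls shorter than 50 bp are dropped before clustering
and calls whose alternate sequence contains a run of more than 10 N bases
(scaffolding-gap artifacts) are removed afterwards.

The same clustering, additionally requiring matching SV type, merges
consensus calls across individuals; loci carried by at least 4 individuals
are kept. Individuals without a call at a retained locus are coded as
homozygous reference (dosage 0), not missing: downstream allele-frequency
computations over the merged matrix require this closure, at the cost of
mistaking a few dropped calls for reference genotypes. The seed-anchored
clustering guarantees that two true loci separated by more than
`2 * max_dist` can never fall into one cluster, and the seed order makes
results invariant to caller and individual ordering.

Cohort minor allele frequencies are computed over non-missing dosages, and
the MAF filter keeps loci at or above the threshold (default 0.05: the
boundary survives).

## Population-genetic statistics

**Folded AFS.** Each polymorphic locus contributes its minor-allele copy
count; a locus at frequency exactly 0.5 falls into the highest folded bin.
Insertions and deletions are pooled as INDEL because their polarity
against the reference is arbitrary. Monomorphic loci are excluded and
counted.

**Tajima's D** uses the textbook constants derived from the number of
allele copies; loci with any missing dosage are dropped so the sample size
is uniform across loci.

**Hudson's FST** per locus is
`[(p1−p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)] / [p1(1−p2) + p2(1−p1)]`,
with loci fixed in both populations flagged undefined; genome-wide values
are the ratio of summed numerators to summed denominators (ratio of
averages), without clamping.

**PBS.** For three groups, per-locus pairwise FST values are clamped to
`[0, 1 − 1e−12]`, transformed to branch lengths `T = −ln(1 − FST)`, and
combined as `PBS_X = (T_XY + T_XZ − T_YZ)/2`. Per-locus values are used
directly (no windowing), since the study design reports per-SV PBS points.
Outlier genes are those overlapping (≥ 1 bp) loci at or above each group's
own empirical 95th percentile, ties included, deduplicated. A known
limitation of the branch statistic, visible in our simulations: a locus
under strong selection in one branch leaks into the sister branches
through the `(T_XZ − T_YZ)/2` term, whose spread at such a locus is driven
by the irreducible frequency difference between the two sister groups; a
strongly SE-shifted locus therefore lands above the sister branches' own
95th percentiles in a substantial fraction of replicates even though it is
only selected in SE.

**LD.** Squared Pearson correlations of dosages between all SNP pairs
inside each inversion, binned by pairwise distance (500-bp bins to 10 kb
by default), separately among major- and minor-arrangement homozygotes;
the control stratum uses the same number of size-matched colinear
intervals placed by rejection sampling (at most 10,000 attempts) so they
never overlap an inversion. Pairs involving a SNP monomorphic within a
stratum are skipped.

**PCA** mean-imputes missing dosages per locus, centers and scales loci to
unit variance, and eigendecomposes the individuals-by-individuals
covariance, so the eigenvalue sum equals the number of loci retained.

## Migratory traits

Direction and distance are the rhumb-line (loxodrome) bearing and distance
between breeding and wintering sites, with the earth a sphere of radius
6371.0088 km (the mean radius; fixed for determinism). Route timing
projects each daily position onto the breeding-to-wintering great circle
via the cross-track/along-track construction; fractions are clamped to
[0, 1] and made monotone with a cumulative maximum, because geolocator
noise can move positions backwards and the timing quantiles must be
well-defined. Timing is the first date at or past 50% of the route,
duration the days between first reaching 30% and 70%, and speed the
rhumb-line distance divided by duration (undefined for zero-day
durations).

Group classification follows the wintering-location rule: north of
37.5° N, west of 5° E is SW and east of 20° E is SE; south of 37.5° N the
western cutoff drops to 0° E; boundary longitudes fall into S (the rule
speaks of birds *between* the cutoffs). Birds wintering at or north of
45° N with a northwest-quadrant bearing are screened off first as NW
migrants — the longitude rules alone would label UK-wintering birds SW;
the latitude threshold is configurable.

## The sparse Bayesian linear mixed model

The GWAS model is `y = 1μ + Xβ + u + ε`, with loci standardized to unit
variance, `β_j` zero with probability `1 − π` and otherwise normal with
variance `σ_a²`, `u ~ N(0, σ_b²K)` for the kinship matrix `K = WW'/p`
(centered dosages), and `ε ~ N(0, σ_e²I)`. Hyperpriors are
`h ~ U(0,1)`, `ρ ~ U(0,1)` and `log π ~ U(log 1/p, 0)`, mapped to variances
by `V_g = h/(1−h)·σ_e²`, `σ_a² = ρV_g/(πp)`, `σ_b² = (1−ρ)V_g/κ` with `κ`
the mean diagonal of `K`; `σ_e²` carries a Jeffreys prior.

The sampler works in the eigenbasis of `K` with the random effect
integrated out analytically, so the marginal covariance is diagonal
(`σ_b²d_k + σ_e²` per coordinate) and every update is `O(n)`. This choice
matters: an earlier design that sampled `u` explicitly conditioned the
spike–slab updates on a random effect that had already absorbed each
locus's signal, trapping chains in a fully polygenic mode; evaluating
inclusion odds against the whitened marginal residual removes that
hysteresis. One MCMC step performs a configurable number of spike–slab
locus updates (effect integrated out for the inclusion odds,
Rao–Blackwellized draw when included), a Gibbs update of the intercept,
and one random-walk Metropolis update of each hyperparameter, with step
sizes adapted toward ~30% acceptance during burn-in and frozen afterwards.
Setting a step size to zero pins that hyperparameter, which is how the
test suite forces the model into its two analytic limits (ridge
regression at `π = ρ = 1`; the kinship-only LMM at `ρ = 0`).

Per posterior sample, PVE is the sample variance of the genetic value
`Xβ + u` (with `u` drawn from its exact conditional at recording time)
divided by that variance plus `σ_e²`; PIP is the inclusion fraction across
thinned samples, and the model-averaged effect is the mean of `γ_jβ_j`.
Chains are bit-reproducible given a seed. The desk-scale default schedule
is a burn-in of 10,000 steps and 100,000 sampling steps thinned every 10
across 4 chains; the field-scale schedule (millions of steps) is reachable
through `bslmm_control()` but not the default. An acceptance rate below 1%
for a hyperparameter whose posterior still has spread raises a divergence
error; boundary-pinned posteriors (for example under a noise-free trait)
legitimately stop moving and are not flagged.

Traits are prepared by regressing out sex (ordinary least squares on a sex
indicator) and rank-based normal quantile transformation,
`Φ⁻¹((rank − 0.5)/m)` with average ranks for ties. Direction is treated as
linear degrees: the synthetic cohorts generate bearings within (135°,
335°), so the 0° branch cut is never crossed and circular regression is
unnecessary.

Polygenic-score cross-validation masks each of four random folds (sizes as
equal as possible) in turn, refits the model on the remainder, and
predicts the masked individuals as
`μ̂ + xβ̄ + σ̂_b²K_ct(σ̂_b²K_tt + σ̂_e²I)⁻¹r_t` — the model-averaged fixed
part plus the conditional mean of the random effect given the training
residuals (the random-effect term is included; whether the original
analysis did so is not documented, and omitting it only weakens
prediction). The final correlation and p value come from an ordinary
linear model of observed on predicted values. Genetic correlations between
traits are Pearson correlations of model-averaged effects over the union
of variants with PIP above 0.01 in either trait; pairs with fewer than
three such variants are flagged undefined.

## The synthetic cohort generator

The generator's defaults emulate the blackcap study shape: 79 diploid
birds in groups of 19 NW / 28 SW / 12 SE / 20 S; ~15,000 SV loci dominated
by deletions and insertions with median sizes near 245/265 bp and a
handful of kb-scale inversions; Balding–Nichols group divergence with
`F = 0.025`, matching the reported weighted FST range (0.021–0.031);
three emulated callers with 150-bp breakpoint jitter (shared between start
and end, so lengths stay exact), 20% dropout and 2% genotype error; and a
scaled-down seven-chromosome genome (~85 Mb) that keeps the full chain
desk-runnable in about a minute. Truth loci are placed uniformly with a
2-kb minimum gap so that breakpoint clustering can never confuse two true
loci. Callers only emit variants the individual actually carries, which is
why cohort-level absence-as-reference is the natural closure.

The focal 710-bp deletion sits on the microchromosome and follows a
frequency cline across the migratory divide — 0.9 in NW and SW, 0.5 in S,
0.02 in SE — reflecting the reported pattern (SE migrants nearly fixed for
the reference allele; S birds the most variable group). Its effect on
direction is 14° per allele copy on the absolute bearing scale against a
within-group non-focal scale of 10° (half polygenic, half noise), which
reproduces the reported strength of the genotype–direction association
within the S group (genotype explaining roughly half the within-group
variance). Group mean bearings are pinned to their geographic targets
(NW 296°, SW 233°, S 192°, SE 144°) by absorbing the expected per-group
focal shift into the baselines. A further two dozen branch-specific
selected loci are frequency-shifted toward fixation in their own group;
they are phenotypically neutral and exist to give the PBS scan realistic
outliers. Routes then place each wintering site by rhumb-line travel from
the breeding area (Austria, ±1°) along the bird's direction for a
group-typical distance, daily tracks are constant-speed great-circle
interpolations (speed ~N(60, 8) km/day) with 50-km isotropic position
noise, and group labels are re-derived from the tracks — so a handful of
birds near classification boundaries can change group, exactly as real
intermediate birds would.

What the generator does *not* emulate: sequence-level read evidence (no
FASTA/BAM), linked-read barcoding, reference bias, repeat-mediated caller
artifacts (caller noise is independent of the repeat track), recombination
maps or realistic LD between SV loci (truth loci are independent given
group frequencies), and circularity of bearings. Green tests therefore
demonstrate that the *methods* recover planted truth through the modeled
noise processes, not that any particular biological dataset would behave
identically.

## Numerical choices and degenerate inputs

Problem sizes in the test suite are chosen to keep the full suite within a
few minutes on one core: consensus studies use 5,000 truth loci; FST and
AFS calibrations use 5,000 loci and 50 diploids per group; Tajima's D
neutrality uses 200 replicates of 2,000 loci; BSLMM calibrations use
n = 200 with 1,000–2,000 loci and ten seeds; the end-to-end study runs the
full 79-bird, 15,000-locus profile once. Other fixed choices: lower-median
convention wherever an even-count median is needed (integer-valued,
reproducible); window assignment of an SV by its start coordinate only;
negative per-locus Hudson FST clamped to zero before the branch-length
transform but never in genome-wide ratios; monomorphic loci dropped from
PCA and GWAS design matrices after mean imputation; rejection-sampled LD
control regions error out after 10,000 failed placements rather than
silently overlapping; and the consensus resolver prefers the
best-supported genotype, breaking ties toward the smaller dosage.
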