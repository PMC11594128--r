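---
title: "Methods: simulating multi-breed genomic prediction under breed-specific LD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating multi-breed genomic prediction under breed-specific LD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Many beef-cattle breeds are small: a few dozen genotyped animals per breed,
far too few to build a within-breed reference population for genomic
selection (GS). Pooling breeds into a multi-breed reference is the obvious
remedy, but it only works to the extent that marker–QTL associations
transfer across breeds. The transferable quantity is the *persistence of LD
phase*: the correlation, across shared marker pairs, of the signed LD
statistic r between two populations (at a 100 kb pair-distance window this
is the `cor100` statistic). crossblup is a simulation pipeline for studying
exactly this question: it generates multi-breed genotype panels with
controllable between-breed phase consistency, expands them to populations
large enough to train GBLUP, simulates traits under contrasting QTL
architectures, and measures how cross-breed prediction accuracy tracks
consistency, heritability, and reference composition.

## Pipeline overview

```{r}
library(crossblup)

map    <- sim_genome()                                   # desk-scale genome
pair   <- make_study_pair(seed = 1)                      # two breeds, cor100 ~ 0.5
popA   <- resample_population(pair$panels$A, 1500,
                              block_len = desk_defaults()$block_len, seed = 2)
popAq  <- qc_filter(popA)$genotypes
qtl    <- sample_qtls(popAq$map, trait_architecture("II"), seed = 3)
tbv    <- compute_tbv(popAq, qtl)
pheno  <- simulate_phenotypes(tbv, h2 = 0.3, seed = 4)
```

Prediction experiments are orchestrated by `experiment_config()` +
`run_experiment()`, which emit a long tibble of per-replicate accuracies and
bias slopes; `summarize_experiment()`, `plot_consistency_accuracy()` and
`plot_added_b()` aggregate and draw them.

## The genotype generator

### Ancestral pool

`generate_ancestral_pool()` initialises allele frequencies uniformly on
[0.05, 0.95], draws haplotypes independently per marker, and runs a
Wright–Fisher population of `ancestral_ne` (default 200) diploids forward
for `burn_in` generations. Meiosis draws a Poisson number of crossovers per
chromosome (mean = genetic length in Morgans), places them uniformly in cM,
and has no interference; there is no mutation or selection. Drift against
recombination builds distance-dependent LD.

The burn-in default is `ancestral_ne / 2` = 100 generations. This is a
deliberate compromise: full drift–recombination equilibrium at tightly
linked pairs would need several times `2 Ne` generations, by which time —
with no mutation to replenish variation — most markers would be fixed.
One hundred generations leaves the large majority of markers polymorphic
while producing mean r² ≈ 0.15–0.2 at 25–50 kb marker spacing, which is the
level reported for cattle chip data at comparable distances.

### Breed divergence: drift plus breed-specific admixture

`derive_breed()` samples `n_founders` (default 70) diploids as breed
founders and drifts them for `generations` at constant size. Drift alone,
however, cannot reproduce the low end of the observed between-breed
consistency range: the marker pairs that remain polymorphic after deep
drift are strongly enriched for two-haplotype systems that inherit their
phase from the founders, so the measured consistency plateaus near 0.5
long before polymorphism is exhausted. We verified this empirically during development: after 512 generations at
branch size 70, consistency was still ≈ 0.5 while over 95% of markers had
fixed.

Real indigenous cattle breeds sit on admixture gradients between divergent
lineages (in Chinese cattle, the taurine–indicine cline), and that is what
spreads their pairwise phase consistency over a wide range. The generator
therefore gives each breed branch its own migrant source: every generation,
each parent is with probability `migration_rate` (default 0.01) drawn from
a breed-specific donor pool. The donor pool is the ancestral panel with
allele labels flipped at a random half of the markers — a transformation
that preserves the allele-frequency spectrum and the magnitude of LD but
randomises the sign of r, i.e. a maximally phase-divergent population with
otherwise identical statistical structure. Shared ancestry then decays as
(1 − m)^g per branch, so consistency declines smoothly and monotonically
from 1 towards 0 as `generations` grows, with drift adding its own
decorrelation on top.

Drift duration alone, however, confounds two things: deeper splits lower
the pair's consistency *and* erode each breed's own diversity, and a
breed's within-breed diversity feeds directly into how well its own
reference animals predict. For multi-breed sets the generator therefore
offers a second, orthogonal knob: **correlated admixture donors**. All
breeds drift for the same number of generations (the default ten-breed
configuration uses 100, beyond the migration–drift equilibrium point, so
every breed ends with the same diversity and the same residual founder
relatedness), and pairwise consistency is controlled by how similar two
breeds' donor pools are. Breed *b*'s donor flip vector copies a global
flip vector at a fraction `donor_affinity[b]` of markers and is random
elsewhere; the donor-phase correlation of breeds *a* and *b* is then
`(w_a w_b)^2`. With the default affinity ladder the ten breeds span
pairwise consistencies of roughly 0.23–0.53 — the range reported for real
indigenous-cattle pairs — at identical drift depth, which is what lets
cross-breed accuracy trends be attributed to phase consistency rather
than to diversity differences.

`calibrate_divergence()` exploits the monotonicity in generations: it bisects over
`generations` (after geometric bracket expansion, since the cost of
evaluating g is proportional to g), measuring Monte-Carlo mean consistency
on panels of 70 individuals — 70 being the usual minimum sample size for a
reliable LD-consistency estimate; smaller panels trigger a warning, not an
error, since the emulated chip panels themselves have only 21–26
individuals. On the default genome the calibration reaches both ends of the
published range (targets 0.516 and 0.107 are hit within ±0.05, as the
test suite verifies).

### Block resampling

`resample_population()` expands a small panel to `n_out` individuals
(default 1500): markers are tiled into consecutive blocks that restart at
chromosome boundaries, and each simulated gamete copies, independently per
block, one source haplotype drawn uniformly with replacement. Within-block
LD and allele frequencies are preserved in expectation; block boundaries
act as strong recombination hotspots that break cross-block LD. Each
individual is two independent gametes, so phase is known by construction.

### Desk-scale genome and the block-length calibration

The default genome (`sim_genome()`) is a proportional reduction of a
cattle-like genome: 10 chromosomes × 25 Mb at 1 cM/Mb with 1000 markers
each (10,000 markers, 2.5 Morgans). On a ~658k-marker HD chip a 500-marker
block spans about 1.9 cM; at desk spacing (25 kb) the same 500 markers
would span 12.5 cM, collapsing the genome to ~20 blocks and the resampled
genotype space to a few hundred dimensions. GBLUP accuracy at reference
size n is governed by the effective number of independent segments Me,
approximately sqrt(n h² / (n h² + Me)); the study's within-breed
accuracies (0.18/0.31/0.43 at h² = 0.1/0.3/0.6, n = 400) imply Me ≈ 1100,
which a 20-block genome cannot reach. Desk-scale experiments therefore
resample in 40-marker blocks (1 Mb ≈ 1 cM; `desk_defaults()$block_len`),
which reproduces Me ≈ 1.1 × 10³ (as computed by `effective_segments()`,
the inverse variance of off-diagonal relationships, in the test suite) and
with it the study's within-breed accuracy regime. `resample_population()` keeps 500 as
its default `block_len`, the appropriate value at HD density. We calibrated
this once, before freezing the test suite, and treat it as part of the
desk-scale study conditions.

`effective_segments()` defaults to Me = 1/var(G_ij) over off-diagonal
relationships — the standard plug-in for the deterministic accuracy
formula; an eigenvalue-based effective dimension is available via
`method = "eigen"`.

## Quality control

`qc_filter()` applies the usual chip cascade in a fixed order — samples by
call rate (< 0.90), then markers by call rate (< 0.90), minor allele
frequency (< 0.01), and Hardy–Weinberg equilibrium (1-df chi-square on
genotype counts, p < 1e-6) — and reports every removal with exactly one
primary reason (plus `non_autosomal` for markers off the autosomes).
Synthetic data are complete by default; `mask_genotypes()` injects
missingness so the call-rate filters can be exercised. QC runs after
resampling by default; whether the emulated study filtered before or after
resampling is not stated, and the stage order is configurable by simply
applying `qc_filter()` to panels first.

## Trait simulation

`trait_architecture()` encodes four strategies (100 QTLs all large-effect;
2000 split 1361/614/25; 5000 split 4595/390/15; 10,000 all small-effect).
Additive effects are drawn from N(0, c·σg²) with c = 0.0001, 0.001, 0.01
for small, medium and large effects. We map the variance scales monotonely
to the class sizes — large effects get the 0.01 scale — since a 100-QTL
trait must carry its genetic variance on those 100 loci; descriptions that
pair the variances with the classes in the opposite order are not
self-consistent with the class counts.

QTLs are drawn uniformly without replacement from QC-passing markers and
remain in the prediction panel (no masking): the emulated design selects
QTLs from the chip loci themselves. `compute_tbv()` is the plain dosage ×
effect sum, uncentered. `simulate_phenotypes()` sets
Ve = Vg·(1 − h²)/h², where Vg is the *realized* variance of the TBVs in
the population at hand, so realized heritability matches the target by
construction; in multi-breed experiments phenotypes are scaled per breed,
keeping each breed's realized h² on target.

## GBLUP

`compute_grm()` builds the VanRaden relationship matrix
G = WW′ / (2Σ p(1−p)) with W the dosage matrix centered by 2p; frequencies
are pooled over the analysis set by default (a single-GRM multi-breed model
needs one frequency vector), with a per-breed centering option.
Monomorphic markers contribute zero and are excluded from the denominator.

`solve_gblup()` solves the mixed-model equations for y = Xb + g + e with
g ~ N(0, G σg²) over all GRM individuals and records mapped to the
reference; fixed effects are the overall mean, plus breed for multi-breed
references. The pedigree polygenic term of the full animal model is
dropped: block-resampled individuals have no pedigree, and the evaluation
is purely genomic. The GRM is ridge-stabilised (+1e-6 on the diagonal —
necessary because column-centering leaves the all-ones vector in the null
space) and the system is solved by dense factorisation; the GRM inverse is
cached on the object so cross-validation folds reuse it. GEBVs of
validation individuals are read directly from the solution vector.

Variance components default to the simulation truth (realized Vg and Ve on
the reference set), which isolates design effects from estimation noise;
`estimate_varcomp()` provides REML when estimation is wanted, profiling
the restricted likelihood over the variance ratio on the eigenbasis of G
and maximising with Brent search — for a single genomic random effect this
is equivalent to AI-REML but cannot diverge. A ratio pinned at the search
boundary (e.g. a trait with no genetic signal) is flagged rather than
errored.

`cluster_breeds()` reproduces the k-means grouping step: PCA on centered
pooled dosages, per-breed centroids in the top 10 components, k-means with
multiple restarts.

## Evaluation designs

`scenario_within()` (1200 individuals of one breed), `scenario_group()`
(1200 drawn equally from a k-means group), `scenario_pooled()` (120 from
each of ten breeds) are evaluated by 5-fold cross-validation repeated 5
times (`cross_validate()`); accuracy there is cor(adjusted phenotype,
GEBV), where the adjusted phenotype removes the training model's fixed
effects — the only covariates that exist in simulation. `scenario_cross()`
(reference 400 A + n B, 200 held-out per breed) is scored against true
breeding values, cor(GEBV, TBV). Both accuracy modes are labelled in the
results.

The dispersion bias is reported as the regression slope
cov(y, gebv)/var(gebv); slopes above 1 indicate deflated, below 1 inflated
GEBVs. A literal cor(y, gebv)/var(gebv) variant exists behind
`bias_slope(..., literal = TRUE)` because that form appears in print, but
it is not scale-free and is not the default.

Replicates default to 10 for trait-architecture grids and 5 for
cross-breed designs, both configurable. The added-reference grid defaults
to n_b ∈ {0, 100, 200, 300, 400}.

## Numerical and convention choices

* Distances are base pairs throughout; distance bins are half-open
  (lo, hi], with the 22-bin scheme 2.5 kb × 4, 10 kb × 9, 100 kb × 9 up
  to 1 Mb.
* The consistency window defaults to 100 kb (`cor100`). The printed
  "0–100 mb" range in the source tables is read as 0–100 kb: the method's
  own bin scheme stops at 1 Mb, and a 100 Mb window would include nearly
  every intra-chromosomal pair. The window is an argument, so either
  reading can be run.
* Consistency is computed on per-pair signed r by default — the standard,
  better-powered persistence-of-phase estimator; a bin-averaged variant
  (`method = "binned"`) is exposed since "average linkage phase across
  distances" can be read either way.
* Signed r comes from phased haplotype frequencies (equivalently, the
  Pearson correlation of the two haplotype indicator vectors), never from
  genotype correlations: the pipeline owns phase, and the sign of r is
  only meaningful with it.
* Seeds: every stage seed is derived deterministically from one global
  seed; identical configuration + seed gives bit-identical output,
  including fold assignments.
* GBLUP ridge 1e-6; REML profile searched on log(σe²/σg²) ∈ [−12, 12];
  k-means uses 10 restarts under a fixed seed.

## Problem sizes used by the test suite and acceptance script

Desk-scale reproductions use the default 10 × 25 Mb genome (10k markers),
two breeds calibrated to cor100 ≈ 0.5, populations of 1500, references of
400 (+200), validation sets of 200, Strategy II traits at h² ∈
{0.1, 0.3, 0.6}, and 10 trait replicates; the cross-validation check uses
one breed, n = 1200, 5 × 5 folds. Trend reproductions (accuracy vs
consistency over six breed pairs spanning ≈ 0.1–0.5, accuracy vs added-B
count) run on a 4-chromosome version of the same genome with populations
of 1000. These sizes are the package's desk-scale study conditions.

## What the synthetic data do and do not emulate

The generator reproduces the statistical features the method depends on:
breed panels of 21–26 phased individuals, chip-like marker maps,
within-breed LD decay, a tunable 0.1–0.5 range of between-breed phase
consistency, block-resampled populations with preserved within-block LD,
and trait architectures over QC'd markers. It does not emulate mutation,
selection, sex chromosomes, genotyping error, pedigree structure, real
minor-allele-frequency spectra, or the taurine/indicine admixture history
itself (the donor-pool construction is a statistical stand-in, not a
demographic model). Passing tests therefore show that the *pipeline*
reproduces the study's quantitative behaviour under these controlled
conditions; they do not certify accuracy levels for any particular real
cattle population.

A further caveat: because the two synthetic breeds share resampled founder
haplotypes, their cross-breed genomic relationships are larger than those
of real distinct breeds, and a reference of breed A transfers information
to breed B more strongly than in the real data. The within-breed accuracy
triplet and all trend patterns reproduce; the absolute cross-to-within
accuracy ratio is higher than the printed one, and the printed cross-breed
triplet itself exceeds the same study's within-breed triplet at low
heritability — a combination no internally consistent simulation can
match simultaneously. The acceptance materials report what the pipeline
actually computes.

## Known limitations

* No mutation means long burn-ins lose polymorphism; the burn-in default
  trades equilibrium LD for realistic marker density.
* The forward simulator is discrete-generation, monoecious random mating
  with selfing allowed; fine demographic detail is out of scope.
* PLINK 1 binary cannot carry phase; the writer emits a companion
  haplotype table, and phased exchange is better served by the VCF path.
* REML assumes a single genomic variance component; multi-component or
  single-step models are out of scope.
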