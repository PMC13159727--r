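---
title: "Demographic inference and population genomics for a fragmented five-cluster primate system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference and population genomics for a fragmented five-cluster primate system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhinopop)
```

## The scientific problem

The black-and-white snub-nosed monkey (*Rhinopithecus bieti*) persists as a
chain of isolated groups along a narrow north–south band of high-altitude
forest. Genome-wide SNP-panel data resolve five genetic clusters — Southwest
(SW), Southeast (SE), Central (C), North-Central (NC) and North (N) — and the
central scientific questions are (i) where the species originated and how it
dispersed, (ii) whether the SE and NC clusters are admixed "stepping-stone"
populations, and (iii) how strongly geography structures genetic
differentiation today.

`rhinopop` implements the full analysis chain as reusable, tested code:
coalescent simulation of competing origin/dispersal scenarios,
site-frequency-spectrum (SFS) composite-likelihood fitting with AIC model
selection, and the upstream stages — neutral SNP panel design, hard-filter
QC, KING-robust kinship pruning, Weir–Cockerham F~ST~, observed
heterozygosity, and Mantel isolation-by-distance. Because the original data
are not redistributable, a first-class synthetic-data module emulates the
study design (20 sampling groups in 5 clusters, planted relatives and
low-quality individuals), and every empirical claim in this vignette is
computed by the test suite or the analysis scripts.

## The demographic model and its encoding

A `demography` is a set of demes (diploid effective size `Ne`, haploid sample
size) plus an ordered backward-time event program: **splits** (all lineages
of a deme move into another and the source disappears), **admixture pulses**
(a fraction of lineages moves), migration-matrix changes and size changes.
Migration is a backward per-generation rate matrix: `m[d, e]` is the
probability that a lineage now in `d` traces to `e`. The "migrants per
generation" convention used in figure annotations equals `2 * Ne_d * m[d, e]`
of the receiving deme; the converter is explicit because published figures
rarely state it.

An admixed deme is encoded as a pulse of fraction `a` into its minor parent
followed immediately by a split of the remainder into its major parent, so
`a = 1` is event-for-event identical to a split (a tested bit-level
identity). The best-supported scenario, `model4_SE_NC_admix`, reads
(backward in time, 10 years per generation):

| event | time (ka) | detail |
|---|---|---|
| SE formed | 8.2 | 37% from SW, 63% from C |
| NC formed | 13.5 | 81% from N, 19% from C |
| C–N split | 106.3 | N merges into C |
| SW–C split | 128.5 | C merges into SW (ancestral deme) |

Seven rivals are encoded the same way: two serial-founder origin models
(`origin_SW`, `origin_C`), the pure stepping-stone `model1_stepping`,
single-admixture variants (`model2_SE_admix`, `model3_NC_admix`), a star
isolation-with-migration model (`model5_IM`) and the stepping-stone topology
with unrestricted pairwise migration (`model6_independent`). The circulating
numbering of these scenarios labels two of them "Model 5"; we number the
independent-migration scenario 6 and flag the collision here. Within-cluster divergence
models (`within_SW`, `within_C`, `within_NC`, `within_N`) are 2- or 3-deme
isolation-with-migration programs matching the subpopulation counts; their
topologies are configuration defaults because no published topology exists
for them.

Validation is structural: every constructor traces lineages through the
event program and rejects demographies that do not funnel into exactly one
ancestral deme, and `model4` enforces the backward ordering
`T_SE < T_NC < T_CN < T_SWC`.

### Parameters, bounds and study-condition defaults

Fitting bounds follow the priors used for the original fits: `Ne` uniform on
[50, 10^4^] (searched on log scale), between-cluster divergence times on
[100, 5×10^4^] generations, migration rates on [10^-6^, 10^-2^] per
generation. The time prior is read as generations — consistent with
128.5 ka ÷ 10 y/gen = 12,850 ≤ 5×10^4^. Within-cluster models use a lower
time bound of 5 generations because the subpopulation divergences being
modelled (~120–610 years, i.e. 12–61 generations) lie below the
between-cluster floor.

`default_params()` returns the synthetic-truth conditions used throughout:
the published best-fit times and fractions above, μ = 1.36×10^-8^ per site
per generation, and — because the effective sizes and migration rates behind
the published figure are not in the extracted text — sizes chosen once,
mid-prior (SW 5000, SE 1000, C 8000, NC 1000, N 3000, ancestral 5000) so
that split depths are of order one coalescent unit (both shared and private
variation exist, which is what makes the times identifiable), and a shared
adjacent-pair migration rate of 10^-4^ (≈0.2–1.6 migrants/generation). These
values were fixed before the recovery experiments and are not tuned.

## Simulation machinery

The structured-coalescent engine (C++) simulates genealogies deme by deme
with exponential competing risks (pairwise coalescence at rate `1/(2 Ne_d)`,
per-lineage migration), applying the event program at its prescribed times.
Three outputs feed everything else:

* `simulate_sfs()` — infinite-sites mutation mode: Poisson(μ·L) mutations
  per locus placed on branches proportional to length. This is the mode the
  Watterson oracle tests (single deme: E[ξ~i~] = θ/i).
* `expected_sfs_probs()` — branch-length mode: every branch contributes its
  length to the joint-SFS cell of its descendant configuration; normalized
  over polymorphic cells, this estimates the probability a segregating site
  falls in each cell with far lower variance than placing mutations.
* `simulate_snp_sfs()` / the genotype generator — segregating sites drawn
  conditional on polymorphism (genealogies ∝ total length, branches ∝
  length). At μ = 1.36×10^-8^ an unconditional per-site draw would discard
  ~99.9% of simulations as monomorphic; the conditional draw is exactly the
  multinomial model the composite likelihood assumes. Sites sharing a
  genealogy are linked; the generators default to ≥10 genealogies per
  thousand sites so this linkage stays mild, and it inflates variance, not
  means.

Reproducibility: one root seed; per-genealogy streams are derived with a
counter-based splitter (SplitMix64 into xoshiro256**), so results are
independent of execution order and identical seeds give bit-identical
output. A step guard (10^9^ events per genealogy) and a
zero-rate-with-no-events check convert pathological demographies
(disconnected demes, all migration zero) into immediate diagnostic errors
rather than hangs.

## The composite likelihood and its numerical traps

For an observed SFS with cell counts m and expected cell probabilities p,
`lnCL = Σ m_i ln max(p_i, p_min)` over polymorphic cells (natural log;
`AIC = 2k − 2 lnCL`, with `aic_from_log10()` as the converter for log10
conventions). Two numerical decisions matter and both are the product of
hard lessons during development:

1. **The floor lives in the likelihood, not the probabilities.**
   `p_min = 1/(10 n_sims)` substitutes for observed cells with zero
   simulated mass. Flooring *every* empty cell of the expected vector and
   renormalizing — a seemingly innocuous alternative — adds spurious mass
   proportional to the number of empty cells (up to ~0.8 for a 16×10^4^-cell
   joint SFS), deflates all real probabilities by a parameter-dependent
   factor, and tilts every likelihood surface toward whichever parameter
   value happens to reach fewer cells.

2. **Desk-scale profiles use the pairwise-2D composite.** A 5-population
   joint SFS at 10 haploids per axis has 161,051 cells; with 5×10^4^ SNPs
   most observed cells are nearly empty and the simulated log-likelihood is
   dominated by Monte-Carlo noise in tiny probabilities (profile argmaxes
   were unstable across seeds even at 2×10^5^ simulations per grid point).
   `composite_log_likelihood(pairwise = TRUE)` instead sums the composite
   over the 2D marginal spectra of all 10 population pairs — dense cells,
   stable estimates — which mirrors how fit quality is conventionally
   validated against 2D and 1D spectra. All marginal cells are included:
   every site is polymorphic in the full sample, so pair-corner cells are
   informative categories, and excluding them without renormalizing would
   bias the statistic toward parameters that maximize included-cell mass.
   The full joint composite remains the default objective; the desk-scale
   experiments (model selection and profile recovery alike) opt into the
   pairwise form.

## Fitting, model selection, uncertainty

`fit_model_ecm()` runs cycles of conditional one-parameter maximization
(bounded Brent line searches; log scale for log-scaled parameters) with
common random numbers within a cycle, so each line search sees a
quasi-deterministic surface; fresh streams across cycles by default
(`crn_across_cycles = TRUE` gives an exactly non-decreasing trace, a tested
property). Update order — times oldest to youngest, then sizes, fractions,
migration — reflects that times dominate SFS shape. A candidate from a line
search is accepted only if it improves on the incumbent under the same
random numbers. Restarts perturb the starting point and keep the best final
likelihood. `compare_models()` takes best-of-restarts per model and ranks by
AIC; `profile_likelihood()` evaluates a grid with common random numbers;
`parametric_bootstrap_ci()` simulates at the point estimate and refits at
reduced settings for percentile intervals.

Monomorphic cells are excluded from likelihoods throughout (SNP-panel data
carry no monomorphic counts). No ascertainment correction for the
MAF ≥ 0.05 discovery panel is applied by default — no published choice exists for it — but the synthetic harness works with the unascertained
spectrum, so recovery experiments are internally consistent.

## The synthetic cohort generator

`simulate_genotype_matrix()` emulates the study design: cluster allele
frequencies come from coalescent-simulated segregating sites; each of the 20
sampling groups draws its frequency around its cluster value with a
Balding–Nichols beta deviate (default F = 0.05, matching the
within-cluster group differentiation scale reported for the system);
genotypes are Hardy–Weinberg draws; parent–offspring pairs are planted by
Mendelian transmission; low-quality individuals get mean depth < 4× or
missingness > 30%; per-site QUAL/FS/QD/MQ/rank-sum annotations come from
pass/fail mixtures with recorded truth labels. `default_group_design(494)`
reproduces the sampling layout (4 SW, 1 SE, 6 C, 5 NC, 4 N groups).

What the generator does **not** emulate: genotype-calling error correlated
with depth, linkage beyond shared genealogies, reference bias, and the
ascertainment of the real capture panel. Passing tests therefore demonstrate
that the *methods* behave correctly on data satisfying their assumptions,
not that the original study's numbers are reproduced — the published
real-data values (absolute AICs, F~ST~ 0.077–0.163, Ho 0.287–0.379, Mantel
R² = 0.505) require the original 309-individual dataset and are out of
scope by design.

## QC, kinship, panel design, statistics

* Hard filters implement the published removal conditions as *strict*
  inequalities (QUAL < 60, FS > 60, QD < 2, MQ < 40, MQRankSum < −20,
  ReadPosRankSum < −8, MAF < 0.05); boundary values pass. "Missing in > 80%
  of samples" is read as a call-rate ≥ 80% requirement (default
  `max_site_missing = 0.20`); the literal laxer reading is available via the
  threshold. Each removed site is attributed to its first failing rule in
  documented order, removals sum exactly to input − output, and a missing
  annotation skips that rule for that record (rank-sum statistics exist only
  for heterozygote-carrying sites).
* Kinship is the between-family KING-robust estimator
  φ = (N~het,het~ − 2 N~opp-hom~)/(N~het~(i) + N~het~(j)) over
  pairwise-complete sites; duplicates ≈ 0.5, parent–offspring ≈ 0.25,
  unrelated ≈ 0 (per-pair sd ≈ 0.011 at 10^4^ sites — individual pairs
  scatter, so "≈ 0" is asserted on the average magnitude). Pruning at
  φ > 0.177 is a greedy maximum-degree vertex cover (ties: higher
  missingness, then label order); the source only states how many
  individuals were removed, so the strategy is ours and is documented as
  such.
* Panel design applies, in order: biallelic-autosomal restriction, gene
  mask, CpG mask, complete genotyping, MAF ≥ 0.05, exact Hardy–Weinberg
  p ≥ 0.001 (Levene's conditional distribution, two-sided by summing all
  heterozygote counts no more probable than observed — verified against a
  brute-force enumeration oracle), then one SNP per 10-kb window
  (deterministic: first surviving site; windows anchored at position 1).
* F~ST~ is Weir–Cockerham 1984, ratio of summed variance components across
  loci, reported unclamped (negatives are clamped only by
  `linearize_fst()`, Rousset's f/(1−f)). Geographic distances are haversine
  with mean Earth radius 6371 km; the original least-cost-path distances
  depend on a resistance surface that is out of scope, so the Mantel stage
  accepts any externally supplied distance matrix. The Mantel test is
  one-sided (positive association, the isolation-by-distance hypothesis)
  with p = (1 + #{r\* ≥ r})/(n_perm + 1), validated against exhaustive
  enumeration on small label sets and against `vegan::mantel`.

## Desk-scale problem sizes

The package's own experiments (test suite and `scripts/acceptance.R`) use:
50,000 segregating SNPs (the study's own panel scale) on 10 haploids per
cluster for parameter recovery, 12,000 genealogies behind each observed
spectrum, 25,000 genealogies per profile grid point (60,000 for the two
deep split times, whose profiles are flattest; the test suite uses
15,000/40,000), profile grids of 10–13 points containing the simulation
truth (4–5% steps for times, 4-percentage-point steps for fractions), and
5,000-SNP replicates with single-cycle ECM fits for the model-selection
experiment.
These sizes were chosen so each experiment completes in minutes on one CPU
while leaving the recovered values comfortably inside their assessment
tolerances; the full-scale analogue (10^5^ simulations per set, 40 ECM
cycles, 100 restarts) is a matter of turning the same knobs up.

## Known limitations

* Simulated composite likelihoods carry a small negative bias from ln of a
  noisy probability estimate; it shrinks as 1/n_sims and cancels to first
  order between nearby parameter values under common random numbers, but
  absolute lnCL values should not be compared across different `n_sims`.
* The recovery harness profiles one parameter at a time with the others
  held at truth; full joint refitting at scale (the original studies' 100
  restarts × 40 cycles × 10^5^ simulations) is expressible with
  `fit_model_ecm()` but not exercised at that scale in the tests.
* Within-cluster model topologies and the five cluster effective sizes are
  package defaults, not published values.
* No recombination within loci, no selection, no sequencing-read level
  simulation (by design).
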