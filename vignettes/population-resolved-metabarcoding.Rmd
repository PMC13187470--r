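---
title: "Population-resolved metabarcoding: models, parameters and design choices"
author: "popspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-resolved metabarcoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popspec)
```

# The problem

Genus-level amplicon profiling can miss the ecology entirely: a genus may be
evenly distributed along an environmental gradient while specific sub-genus
populations within it — groups of isolates connected by recent gene flow,
here called main clusters (MCs) — are strongly selected at one end of the
gradient. `popspec` implements a complete, testable inference chain for
detecting such populations and characterizing their genomic correlates:
population-resolving primer design, phylogenetic-placement assignment of
amplicon sequence variants (ASVs) to MCs, ordination-based specialist
classification, phylogenetic comparative tests, and convergent-clade
detection.

This vignette documents the models, the tunable parameters, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the design decisions taken where the procedure was genuinely open.

# Models and procedures

## Primer design

Candidate primers are windows of the degenerate ingroup consensus (minimal
IUPAC cover of the observed bases per column). A window pair qualifies when

1. each window covers at least one *discriminating SNP* — an alignment
   column whose ingroup and outgroup base sets are disjoint after IUPAC
   expansion (gap-containing columns never qualify);
2. each primer is 17–25 bp and the product, measured on the ungapped
   ingroup consensus with both primers included
   (`size = reverse_end − forward_start + 1`), is strictly below 600 bp;
3. the pair shows no cross-complementarity.

"No complementarity" is operationalized as: neither primer's 3'-terminal
4-mer has a reverse-complement match (IUPAC-set intersection at every
offset) anywhere in the other primer. The 3' anchor is the dimer-relevant
case; the window length `k = 4` is exposed as an argument. A degeneracy cap
(default 16, the product of per-base alternative counts) prunes
hyper-degenerate windows; published degenerate primers for this kind of
assay fall well under it. Melting temperature is deliberately **not** a
criterion; a Wallace-rule estimate is available as advisory metadata only
(`wallace_tm()`).

The inclusive product arithmetic is fixed by the primer-naming convention
(forward name = amplicon 5' start, reverse name = amplicon 3' end): it
reproduces 550 bp for a 562F/1111R pair, 522 bp for 668F/1189R and 382 bp
for 514F/895R.

An open design question is whether discriminating SNPs should separate the
genus from outgroups only, or also populations from each other. We implement
genus-level discrimination and report population resolution separately, as
the fraction of MCs that are monophyletic on a marker tree
(`score_population_resolution()`).

## ASV assignment

Queries are aligned to the reference profile (global affine-gap alignment to
the ungapped consensus via `Biostrings::pairwiseAlignment`, then mapped back
into reference columns; query insertions are discarded so the reference
coordinate frame is preserved; queries under 50% identity are excluded and
logged). The joint tree is neighbor-joining on Jukes–Cantor distances,
midpoint-rooted, with rows sorted lexicographically first so the output is
independent of input order. Externally computed maximum-likelihood trees can
be supplied instead.

The assignment rule: take the ASV tip's parent node; among the *reference*
tips it subtends, assign the plurality MC if its fraction **strictly
exceeds 0.80** ("over 80%"). Decisions taken where the rule is silent:

- the denominator counts reference tips only — co-placed query ASVs would
  dilute a rule whose purpose is reference affiliation;
- a parent subtending zero reference tips is ascended minimally until at
  least one reference tip is subtended, and the rule applied exactly once
  there (bounded ascent avoids assigning from the root);
- a plurality tie is unassigned;
- the boundary case 4:1 (fraction exactly 0.8) is **unassigned**.

ASVs matching no MC are kept as an explicit unassigned category, and their
count mass is reported per sample (`aggregate_population_abundance()`),
never silently dropped.

## Specialist classification

Per marker, per-sample MC relative abundances go through Bray–Curtis
dissimilarity and NMDS (k = 2, matching how such data are usually displayed;
stress is reported but not thresholded). Each MC's abundance vector is
fitted onto the ordination (`envfit_vector()`): R² from least squares, P
from permuting the vector across samples, `p = (1 + #{R²_perm >= R²}) /
(1 + n_perm)` with 999 permutations by default.

An MC is *enriched* for a marker when envfit P < 0.05 **and** its mean
relative abundance is higher in western (high-nutrient) than in non-western
samples. The direction condition replaces reading arrow geometry off an
ordination plot: for vector fitting, the arrow points up the abundance
gradient, so the mean comparison is the same quantity made reproducible.

The specialist call requires enrichment in (taxonomic marker 1 **or** 2)
**and** the functional marker, **and** mean western relative abundance above
1% in the taxonomic tables. With two taxonomic markers the abundance is
averaged over the tables that carry the MC; a `max`-over-sites alternative
is available via the screen's columns. Site-group membership (which sites
count as "western") is a configuration input, not inferred from the
ordination.

PERMANOVA (`permanova()`) is implemented one-factor from Anderson's
partition of summed squared distances; multi-factor reports are produced by
running factors separately.

## Phylogenetic comparative tests

*PhylANOVA* (`phylanova()`): observed F is the classical one-way ANOVA
statistic; the null distribution comes from `n_sim` (default 10,000)
Brownian simulations on the tree at the maximum-likelihood rate σ̂²
(GLS mean profiled out), `p = (1 + #{F_sim ≥ F_obs}) / (1 + n_sim)`. We
implement the one-way form on specialist status; a published variant with
population identity as an additional covariate is not operationally defined
and is therefore not reproduced.

*Pagel's λ* (`pagel_lambda_signal()`): profile MVN likelihood with
off-diagonal covariance scaled by λ ∈ [0, 1], LR against λ = 0 on χ²₁.
Binary presence/absence traits are accepted as 0/1 numerics — an
approximation, flagged as such, matching how the screening is done in
practice. Constant traits are *excluded* (the NaN-pattern rule), not
errors.

*binaryPGLMM* (`binary_pglmm()`): logit P(y=1) = Xβ + b with
b ~ N(0, s²C), fitted by iterated working-response penalized
quasi-likelihood: for a candidate s², alternate GLS updates of β and the
random effect until the relative change drops below 1e-6 (max 100
iterations); s² ≥ 0 minimizes the working-model restricted likelihood; Wald
tests on β. C is standardized to unit mean diagonal so the s² scale is
tree-independent. Complete or quasi-complete separation (fitted
probabilities pinned at 0/1) is flagged with a warning; the Wald statistic
collapses there (Hauck–Donner), which is a property of the method, not a
bug, and the flag lets callers treat such genes separately.

*Workflow* (`gene_trait_association_workflow()`): per gene — invariant →
excluded; λ-signal P ≤ 0.05 → PGLMM against specialist status; otherwise
Pearson chi-square on the 2×2 table (no continuity correction by default,
exposed as a flag) plus an ordinary linear-regression coefficient. Raw
P-values are reported; multiplicity correction is left to the caller.

*Median dichotomization* (`median_dichotomize_chisq()`): group A is
strictly above the whole-dataset median — ties go to group B — followed by
a Pearson chi-square of independence against site group. Because the 2×2
statistic is discrete, the null P distribution is conservative rather than
exactly uniform; the tests assert the conservative direction.

## Convergent clades

`detect_specialist_convergent_clade()` scans every internal node of a
(rooted; midpoint-rooted with a warning if not) gene tree: a node witnesses
convergence when its descendant leaves carry genes from at least two
distinct specialist MCs and from no other MC; the largest qualifying clade
is reported. Single leaves never qualify. The prevalence filter
(`filter_ogs()`, keep when ≥ 50% of genomes carry the OG) is inclusive at
the boundary, per its wording. Gene-tree/species-tree reconciliation is
*not* re-implemented: the clade criterion is applied to the supplied gene
trees directly. When the pipeline has no external gene trees it prunes the
species tree to each OG's carriers — a stand-in that cannot show
transfer-induced topology changes; supply reconciled or ML gene trees for
real analyses.

## Pathway genotyping

`classify_pathway()` is a total pure function on the six gene flags:
complete ⟺ (napA ∨ narG) ∧ (nirS ∨ nirK) ∧ norB ∧ nosZ; none ⟺ all absent;
otherwise partial. The test suite checks all 64 combinations against an
independently formulated truth table.

# The synthetic-data generator: a stated world

`sim_config()` fixes the world; one master seed determines everything
(stage-specific streams are derived with `child_seed()`, a Lehmer step, so
stages can be re-run independently). Defaults and their rationale:

- **20 MCs × 4 isolates, 4 specialists** — the scale of the planted
  recovery scenario; every MC keeps ≥ 3 isolates, the minimum for an MC to
  be delineated at all.
- **Tree shape**: pure-birth backbone scaled to depth 1 with internal
  splits compressed below `1 − 3f`, and within-MC subtrees of depth
  `f = 0.04` grafted at the tips. The compression makes
  within-MC < between-MC patristic distance a *construction guarantee*,
  not a statistical accident.
- **Markers**: Jukes–Cantor evolution at 0.1 substitutions/site per unit
  length, giving ~99% within-MC and ~80–97% between-MC identity — the
  nucleotide-identity regime in which sub-genus populations live. Two
  taxonomic markers are universal; the functional marker is carried by
  non-specialist tips with probability 0.8 (specialists always carry it).
  Outgroups evolve over an extra unit branch, and 40 planted diagnostic
  columns are homogenized (ingroup consensus vs a fixed different outgroup
  base) so primer design has true genus-discriminating SNPs to find.
- **Abundances**: per sample, MC proportions are Dirichlet with
  concentration θ·π(site), counts multinomial at depth 20,000.
  `log π` is a lognormal baseline (SD 1) plus `log(10)` for specialist MCs
  at western sites. Specialist baselines are drawn low (around 1% of the
  community) so the 10-fold enrichment lands specialists at roughly 1–10%
  west versus 0.1–2% elsewhere — the regime the method is designed for.
  θ defaults to 200: tight enough that a 10-fold planted effect is the
  dominant systematic axis of the ordination, as it visibly is in real
  surveys of this kind; θ = 50 makes dominant-MC sampling noise swamp the
  gradient, a *different* world in which no envfit-based screen can work.
- **Noise**: sequencing error is optional (`read_noise`, default 0,
  applied once per ASV sequence) because no error model is part of the
  stated procedure; the placement tests use 1% to show robustness.
- **Gene content**: two-state Markov gains/losses (rates 0.5/0.5);
  planted associated genes multiply the gain rate (and divide the loss
  rate) by 8 on branches whose descendants are all specialist tips.
- **Phenotypes**: Brownian motion (σ² = 1) plus an additive specialist
  shift; a log-scale option yields positive rate-like traits.

What a green test does **not** establish: the generator has no chimeras,
no PCR/primer bias, no compositional sequencing artifacts, no host
contamination, no within-MC ecological heterogeneity, and its gene trees
(in the pipeline fallback) are pruned species trees. Recovery of planted
effects under this world shows the inference chain is correct, not that the
biological effect sizes are identifiable in any particular real dataset.

# Numerical choices

- **NMDS**: stress majorization with isotonic disparities; a step that
  fails to decrease stress-1 is reverted and the restart stops, making the
  stress sequence non-increasing by construction. One metric (classical
  scaling) start plus seeded random restarts; scores are rotated to
  principal axes with a deterministic sign convention. On embeddable
  inputs the implementation reaches the same stress as `vegan::metaMDS`
  (checked in tests).
- **Permutation counting**: a permuted statistic equal to the observed one
  must count as an exceedance; equality is taken up to a relative 1e-12 to
  absorb last-ulp BLAS differences between code paths. Exhaustive mode
  enumerates all n! label orders (identity included) and reports
  `#{≥}/n!`; random mode reports `(1 + #{≥})/(1 + B)`, so p never drops
  below its lattice floor.
- **Pagel's λ**: `optimize()` on [0, 1] with boundary evaluations folded
  in, so the reported optimum never falls below λ = 0 or λ = 1
  likelihoods.
- **PGLMM**: fitted probabilities are clamped away from 0/1 (1e-10) inside
  the working response; s² is profiled on [0, 10] after covariance
  standardization, with an explicit s² = 0 comparison so the boundary is
  reachable exactly.
- **Degenerate inputs**: constant traits are errors for phylANOVA (no
  test is possible) but *exclusions* for the λ/PGLMM gene screen (the
  screening convention); samples with zero assigned reads carry NA
  abundances and are flagged, never silently renormalized.

# Known limitations

- Assignment quality inherits everything NJ + midpoint rooting implies;
  for hard cases import an ML tree and keep the placement rule.
- The specialist screen tests each MC marginally; strongly co-varying MCs
  share ordination axes and their envfit P-values are not independent.
- The PGLMM Wald test loses power under separation (flagged); a
  likelihood-ratio or penalized alternative is out of scope.
- The convergence criterion is applied to the trees you supply;
  without reconciliation, a clade that is specialist-exclusive only after
  transfer-aware rearrangement will be missed.
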