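# popspec

Population-resolved amplicon analysis of host-associated bacterial
communities.

Most microbiome surveys stop at the genus. But ecologically decisive
adaptations — such as the hyper-efficient denitrification that lets some
corals persist under chronic nitrate pollution — can be carried by specific
sub-genus *populations* that are invisible at genus-level resolution.
`popspec` implements the full inference chain for finding such populations
from marker-gene amplicons:

1. **Marker design** — enumerate degenerate primer pairs over a labelled
   alignment whose forward and reverse primers each cover at least one
   genus-discriminating SNP, are 17–25 bp long with a product under 600 bp,
   and show no 3'-anchored cross-complementarity.
2. **ASV assignment** — place amplicon sequence variants (ASVs) into a joint
   reference + query tree and assign each ASV to a population ("main
   cluster", MC) when **more than 80%** of the reference tips under its
   parental node belong to that MC.
3. **Specialist classification** — Bray–Curtis NMDS ordination, vector
   fitting with permutation *P*-values, and PERMANOVA; an MC is called a
   *specialist* when it is enriched at high-nutrient (western) sites in a
   taxonomic marker **and** the functional marker, with mean western
   relative abundance **> 1%**.
4. **Phylogenetic comparative tests** — phylogenetic ANOVA (null F
   distribution from Brownian simulation on the tree), Pagel's λ signal
   test, and a binary phylogenetic GLMM (penalized quasi-likelihood) linking
   gene presence/absence to specialist status, with the λ-significance
   branch rule (PGLMM when *P* ≤ 0.05, otherwise chi-square).
5. **Convergence detection** — a gene-tree clade witnesses convergent
   evolution when its leaves carry genes from ≥ 2 distinct specialist MCs
   and none from any other MC.
6. **Pathway genotyping** — a denitrification pathway is *complete* when a
   genome encodes (napA ∨ narG) ∧ (nirS ∨ nirK) ∧ norB ∧ nosZ.

Every stage is exercisable on synthetic data with known ground truth: a
seeded generator produces population-clustered marker sequences, a
west→east nutrient gradient, planted specialist enrichment,
phylogenetically structured gene content, and Brownian phenotypes.

## Core statistics

- Bray–Curtis: d(i,j) = Σ|xᵢ−xⱼ| / Σ(xᵢ+xⱼ); NMDS minimizes Kruskal
  stress-1 by majorization with isotonic regression.
- envfit: R² = 1 − SS_res/SS_tot of the variable regressed on ordination
  scores; p = (1 + #{R²_perm ≥ R²}) / (1 + n_perm).
- PERMANOVA pseudo-F from Anderson's partition of summed squared distances.
- PhylANOVA: p = (1 + #{F_sim ≥ F_obs}) / (1 + n_sim) with F_sim from
  Brownian traits at the ML rate σ̂².
- Pagel's λ: MVN likelihood with off-diagonal covariance scaled by
  λ ∈ [0,1]; LR test against λ = 0 on χ²₁.
- binaryPGLMM: logit P(y=1) = Xβ + b, b ~ N(0, s²C), iterated
  working-response PQL with Wald tests.

## Worked example

```r
library(popspec)

cfg <- sim_config(seed = 42)                 # 20 MCs, 4 planted specialists
pt  <- simulate_population_tree(cfg)
md  <- simulate_sample_metadata(cfg)         # 2 western + 2 eastern sites
aln <- simulate_marker_alignments(pt, cfg)   # ATP5B-, parC-, nirS-like
tab <- simulate_asv_tables(pt, aln, md, cfg)

abund <- lapply(tab, function(tb) {
  aggregate_population_abundance(
    tb, data.frame(asv_id = tb$truth$asv_id, assigned_mc = tb$truth$mc)
  )$abundance
})
scr <- specialist_screen(abund, md$site_group, seed = 7)
scr$calls[scr$calls$call == "specialist", ]
```

prints

```
   mc p_taxonomic_1 p_taxonomic_2 p_functional mean_western_abundance
  MC1         0.001         0.001        0.001                 0.0456
 MC12         0.001         0.001        0.001                 0.0711
 MC17         0.001         0.001        0.001                 0.0674
  MC3         0.001         0.001        0.001                 0.0382
```

exactly the four planted specialist MCs (`pt$specialist_mcs` is
`MC1, MC12, MC17, MC3`): each is enriched at western sites in both marker
classes at the permutation floor p = 1/(999+1) = 0.001 and carries 3.8–7.1%
of the western community, above the 1% specialist floor.

Primer-name arithmetic (forward name = amplicon 5' start, reverse name =
3' end, product inclusive):

```r
product_size(562, 1111)  # 550  (ATP5B 562F/1111R)
product_size(668, 1189)  # 522  (parC 668F/1189R)
product_size(514, 895)   # 382  (nirS-Rue514F/895R)
```

The full chain (placement included) runs with
`run_pipeline(pipeline_config(out_dir = "out", seed = 42))`, which writes
per-stage TSVs and a machine-readable `manifest.json`. A command-line
interface is available via `exec/popspec`
(`popspec simulate | design-primers | assign | classify-specialists |
phylanova | phylo-assoc | convergence | pathway | run`).

## Documentation

The methods vignette
(`vignettes/population-resolved-metabarcoding.Rmd`) describes the models,
the synthetic-data generator's stated world, numerical choices, and known
limitations.
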