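---
title: "Single-step genomic-polygenic association with pathway and network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic-polygenic association with pathway and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssgwaspath)
```

## The analysis in one paragraph

ssgwaspath implements a complete single-step genomic association workflow
for three correlated dairy traits — 305-day milk yield (MY, kg), 305-day
fat yield (FY, kg), and age at first calving (AFC, days) — in an admixed
population with two founder breed pools (H, e.g. Holstein, and O, "other
breeds").  Genotyped and non-genotyped animals are analyzed jointly through
the combined relationship matrix H; variance components come from
multi-trait average-information REML; per-SNP allele-substitution effects
are back-solved from the genomic breeding values and converted to per-SNP
percentages of the genetic variance; SNPs above a variance threshold are
assigned to nearby genes; gene lists feed a hypergeometric pathway
over-representation test with Holm (Bonferroni step-down) correction; and
the enriched-pathway genes form a confidence-filtered protein-protein
interaction network whose degree structure and aggregate variance
contributions are summarized.  A synthetic-data generator reproduces the
population structure, trait architecture, and annotation resources of this
design at desk scale so every stage is testable without any external
database.

## The mixed model

For records on `t = 3` traits the model is

    y = Xb + Zu + e

where the fixed effects per trait are the herd-year-season (HYS)
contemporary group, a breed regression on the animal's expected O fraction,
and a heterosis regression on the expected heterozygosity
`sire_H * dam_O + sire_O * dam_H`.  Random effects are the animal additive
genetic values, `var(u) = H ⊗ V_a` (Kronecker product, animals ordered
animal-major), and residuals, `var(e) = I ⊗ V_e`, with `V_a` and `V_e` the
3×3 additive and residual covariance matrices among MY, FY, and AFC.

### Relationship matrices

* `build_A()` computes Wright's numerator relationship matrix by the
  tabular method with inbreeding (`a_ii = 1 + F_i`,
  `F_i = a(sire, dam)/2`).
* `build_G()` computes the genomic relationship matrix
  `G = ZZ' / (2 Σ p_j (1 − p_j))`, where `z_ij = code_ij − 2 p_j` and
  `p_j` is the observed frequency of the second allele.  Missing genotypes
  are imputed to the column mean `2 p_j` (zero after centering) — the
  conventional choice, neutral to the expectation of G.
* `tune_G_to_A22()` rescales G so that its mean diagonal and mean
  off-diagonal equal those of `A22` (the pedigree relationships among
  genotyped animals), solving a 2×2 linear system for `G* = βG + αJ`.
* `blend_G()` forms `G_b = α_b G* + (1 − α_b) A22`, default
  `α_b = 0.95`, guaranteeing invertibility when G is rank-deficient
  (more animals than markers).
* `build_H_inv()` assembles the single-step inverse
  `H⁻¹ = A⁻¹ + [[0, 0], [0, G_b⁻¹ − A22⁻¹]]` on the (non-genotyped,
  genotyped) partition.  With no genotyped animals this is pedigree BLUP;
  with every animal genotyped and no blending it is exactly GBLUP — both
  limits are verified in the test suite.

### AI-REML

`reml_ai()` maximizes the restricted likelihood over the 12 free
parameters (6 per symmetric 3×3 matrix).  Two code paths compute identical
likelihoods:

* **fast path** (complete records, one record per animal): the
  relationship submatrix K among recorded animals is eigendecomposed once;
  after rotation the covariance is block diagonal with 3×3 blocks
  `V_i = d_i V_a + V_e`, so each iteration costs O(n) small-matrix
  operations.  This is what makes replicated parameter-recovery studies at
  n = 1,500 animals practical on a single core.
* **general path** (arbitrary missing-trait patterns): the dense
  covariance over the observed trait-cells, with each record contributing
  its observed-trait block of `V_e` (record-level residual subsetting).

Updates are average-information (AI) steps with step-halving and
Levenberg-style damping; whenever no damped AI step stays inside the
positive-definite cone and improves the likelihood, an exact EM-REML step
(which provably cannot decrease it) is taken instead.  The restricted
log-likelihood is therefore non-decreasing across accepted iterations, a
property asserted on the iteration trace in the tests.

Numerical choices:

* starting values `V_a = V_e = 0.5 ×` the phenotypic covariance of the
  records (inside the PD cone by construction, nudged if pairwise-complete
  covariances are inconsistent);
* convergence at relative parameter change `< 1e-8` (default), with a
  first-order stop when the scaled score has vanished while parameters
  have stabilized — AI steps cycle in the roundoff plateau of the surface
  otherwise;
* explicit boundary handling: at small n the REML optimum frequently lies
  on the boundary of the parameter space (a genetic correlation at ±1 or a
  variance at zero).  EM approaches such an optimum geometrically slowly,
  so a nearly singular component (relative eigenvalue `< 1e-5`) with
  stabilized parameters is flagged (`boundary = TRUE`, with a warning)
  rather than iterated forever.  Degenerate data (constant records) floor
  the collapsing variance near zero and flag it;
* every constructed covariance/relationship matrix is symmetrized as
  `(M + M')/2`; positive semi-definiteness is checked at tolerance 1e-8.

`solve_mme()` solves Henderson's mixed-model equations for fixed effects
(drop-first-level constraint per trait; estimable contrasts, fitted values
and GEBVs are invariant to the constraint, which is verified by
relabeling) and returns GEBVs for *every* pedigree animal, genotyped or
not.

## SNP effects and variance shares

`backsolve_effects()` implements the standard single-pass back-solution
with identity SNP weights,

    a_hat = Z' G_b⁻¹ u_hat / (2 Σ p_j (1 − p_j)),

expressed per copy of the second allele.  `variance_share()` converts
effects to per-SNP percentages of a trait's genetic variance,

    v_j = 100 · 2 p_j (1 − p_j) a_hat_j² / σ²_a(trait),

with `σ²_a` the REML estimate of the trait's total additive variance (the
denominator choice; the empirical variance of `Z_j a_j` across genotyped
animals is available as an alternative `method`).  Shares are non-negative
but need not sum to 100%: the back-solution projects effects onto the
(at most n-dimensional) row space of Z, so with m ≫ n independent markers
much of the variance is not attributable to any single marker.  A planted
QTL of one genetic SD still ranks first in variance share essentially
always at n = 500, which the acceptance tests verify over 20 replicates.

`gene_predicted_value()` sums the allele-substitution effects of the SNPs
assigned to each gene — the "predicted SNP value" of the gene — and
likewise sums variance shares per gene.

## Gene mapping rules

`qc_genotypes()` removes SNPs with call rate strictly below 0.90 or minor
allele frequency strictly below 0.01 (a SNP exactly at a threshold is
retained).  `filter_by_variance()` keeps SNPs explaining **at least**
0.001% of the genetic variance (boundary inclusive), per trait.
`assign_to_genes()` matches each SNP to every gene on its chromosome whose
interval contains it or whose nearest edge is within 2,500 bp (inclusive);
distances are binned `inside`, `≤2500`, `(2500,5000]`, `(5000,25000]`,
`>25000` by a left-closed convention at the shared edges (the usual verbal
description of such bins, "between 2,500 and 5,000 bp", does not resolve
the edges itself; the convention is configurable).
Only `inside` and `≤2500` assignments feed enrichment.  Multi-gene hits
are kept — no nearest-gene tie-breaking — and coordinates are 1-based
inclusive throughout, with a converter for 0-based half-open BED input.

## Enrichment and the interaction network

`enrich()` tests each pathway by the right-tailed hypergeometric
distribution (via the log-gamma-stable `phyper`) and adjusts across the
tested family by Holm's step-down method (`p.adjust`), calling
significance at adjusted p < 0.05.  Design choices where the upstream
conventions are ambiguous: the universe defaults to genes belonging to at
least one gene set; pathways with zero overlap are reported with p = 1 but
excluded from the adjustment family; and the default query pools the three
per-trait gene lists, since the summary tables pool traits.  All three
choices are configurable.

`filter_ppi_edges()` keeps interaction edges with confidence strictly
greater than 0.7, drops self-loops, merges duplicate unordered pairs at
maximum confidence, and by default excludes isolated query genes from the
node set (a network reported smaller than its gene list is consistent with
dropping unconnected genes).  Degree is the unweighted edge count;
confidence is a filter, not a weight.  `network_gene_summary()` joins each
node's degree, enriched-pathway membership count, variance shares and
predicted values, and reports network totals plus their ratio to the
enriched-pathway union totals — computed, never asserted.

## What the synthetic generator emulates — and what it does not

The generator reproduces, at desk scale, the features of a tropical
multibreed dairy study that the downstream statistics depend on:

* a three-generation pedigree from two founder pools with random
  non-overlapping-generation matings (no selection), breed fractions
  propagating as parent means, and heterozygosity entering the phenotype
  only through the linear covariate actually fitted;
* gene-dropped genotypes (founders drawn from pool-specific allele
  frequencies, Mendelian transmission, loci independent), with
  missing-completely-at-random calls and a small fraction of poorly
  genotyping assays so the QC stage has real work;
* three correlated traits simulated under the fitted model, with
  herd-year-season effects, polygenic values from `N(0, A ⊗ V_a)` and an
  equal-variance QTL architecture: each QTL contributes exactly
  `qtl_var_frac / n_qtl` of every trait's additive variance, with signs
  correlated like `V_a`.  Defaults give heritabilities of about 0.25 (MY),
  0.25 (FY) and 0.15 (AFC) and a strong positive MY-FY genetic
  correlation;
* a gene-dense toy annotation (2,400 non-overlapping genes on two
  chromosomes), 24 pathways in the four categories (cellular processes,
  nervous system, digestive system, environment adaptation), and a
  confidence-scored edge table in which 70% of edges connect members of a
  common pathway — proteins of one pathway interact far more often than
  random pairs, as in curated databases;
* a gene-centric genotyping panel: a fraction of markers is placed inside
  genes and one moderate-frequency tag marker is placed inside each
  QTL-hosting gene, emulating trait-targeted commercial chips.  The QTL
  host genes are members of the largest pathways ("causal pathways"),
  which plants a recoverable over-representation signal: the default
  pipeline run finds exactly the planted pathways significant.

It deliberately does **not** emulate linkage disequilibrium beyond
pedigree cosegregation, selection or assortative mating, sequence-level
variation, or imputation error.  Two consequences matter for
interpretation.  First, without LD the back-solved variance shares scale
with the ratio of genotyped animals to markers, so absolute share values
are much smaller than in dense-LD cattle data; the selection threshold
(0.001%) is meaningful only because panel size and population size are
balanced accordingly.  Second, passing tests demonstrate the correctness
of the machinery under the stated generative model, not the biological
validity of any particular gene list on real data.

AFC is simulated and analyzed in days (the unit is a configurable choice;
no transformation is applied), and the HYS class is an opaque categorical
label with balanced cyclic assignment — no seasonal model is implied.
305-day yields use the test-interval method: interval length times the
mean of adjacent test-day yields, with the first interval projected from
day 0 at the first test's yield and the last projected to day 305 at the
last test's yield (the ICAR convention); test-day fat yield is fat
percentage times milk yield.

## Problem sizes

The default pipeline configuration simulates 550 animals (100 founders,
three generations), 70% genotyped, 2,500 SNPs on two chromosomes, 60 QTL
carrying half the additive variance, 2,400 genes, 24 pathways and 8,000
candidate edges; it completes in well under a minute on one core.  The
test suite uses smaller populations for algebraic oracles and two larger
designs chosen for statistical resolution: 20 replicates of n = 1,500
animals for variance-component recovery (feasible because the fast REML
path reuses one eigendecomposition across replicates) and 20 replicates of
n = 500 genotyped animals × 2,000 SNPs for the QTL-ranking property.

## Known limitations

* Dense linear algebra throughout: population sizes are desk-scale by
  design; sparse inverses (Henderson's rules) and large-scale single-step
  approximations (APY) are out of scope.
* Multi-trait REML at small n (a few hundred records) frequently has its
  optimum on the parameter-space boundary; the fit then converges with a
  `boundary` flag and the affected correlation should be read as ±1 rather
  than as a precise estimate.
* No metafounders or unknown-parent groups; animals with exactly one known
  parent are rejected rather than approximated.
* The hypergeometric test conditions on the realized query size; with a
  query that is a large fraction of the universe the test has little
  power, which constrains how far the toy problem can be scaled down.
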