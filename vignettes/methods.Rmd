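---
title: "Mapping immune cell frequency QTL and classifying cyto-cis / cyto-trans associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping immune cell frequency QTL and classifying cyto-cis / cyto-trans associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccimmune)
```

## The scientific problem

In a panel of recombinant inbred mouse strains descended from eight founder
strains (a Collaborative-Cross-like design), the frequency of each immune
cell type in bone marrow is a heritable quantitative trait. Mapping the
loci that control these frequencies, and then asking whether each
associated gene is *expressed* in the cell type whose abundance it
controls, separates two regulatory modes:

* **cyto-cis** — the gene is expressed in the associated cell type and can
  act cell-intrinsically;
* **cyto-trans** — the gene is silent in the associated cell type, so its
  effect must be relayed through another cell type (ligands, metabolites,
  progenitors).

Because a cyto-trans gene can have no additional function in the cell type
it regulates, such genes are hypothesized to face weaker negative
selection. The package's final stage therefore compares per-gene
evolutionary conservation (PhastCons-style per-site scores averaged over
conserved elements in coding sequence) between the two classes with a
one-sided two-sample Kolmogorov–Smirnov test.

`ccimmune` implements the full inference chain as testable, reusable
stages, together with a synthetic panel generator that produces all inputs
with machine-readable ground truth, so every stage can be exercised,
calibrated and power-tested without any external download.

## The synthetic panel

`panel_config()` fixes the study conditions; `simulate_panel()` draws a
panel:

* 8 homozygous founder strains; 54 recombinant inbred strains split into a
  discovery cohort (30 strains × 2 replicate mice) and a disjoint
  validation cohort (24 strains × 2 replicates);
* per-chromosome founder mosaics with Poisson(`recomb_rate` = 2)
  breakpoints; biallelic observed genotypes;
* nine cell types labelled HSC, NK, CD4, CD8, B, proB, lateB, GN, MO so
  lineage-collapsing rules run against their real names;
* phenotypes generated on the logit scale,
  `logit(freq) = baseline + planted founder effects + strain noise
  (sd 0.15) + replicate noise (sd 0.25)`, then mapped through the logistic
  function so frequencies stay in (0, 1). Baselines are realistic bone
  marrow fractions (e.g. 0.35 for granulocytes, 0.005 for HSC). Analysis
  happens on the raw frequency scale, which is what the assay measures;
  the logit is only the generative device that keeps frequencies bounded.
* four planted QTL by default, additive allele effect 2 on the logit
  scale — a large, clearly detectable effect of the kind that survives a
  5% FDR screen in a 30-strain panel — half of them cyto-trans;
* a two-Gaussian expression reference (silent component mean 20 a.u.,
  expressed component mean 200 a.u., sd 5, thresholds 47/120 a.u.), with
  population maps in which the B and GN subsets deliberately span two
  reference populations each to exercise the "expressed in at least one
  subpopulation" rule;
* per-gene conservation tracks: Beta-distributed site scores with mean 0.7
  for cis-only genes and 0.4 for genes carrying a planted cyto-trans
  association (concentration 10), written as 0-based half-open BED /
  bedGraph structures.

Two design points deserve emphasis. First, founder allele patterns are
correlated *within* a gene (`ld_within_gene` = 0.9): variants in one gene
sit on shared founder haplotypes in real panels, and without this
correlation a biallelic validation test at a gene's lead locus would be
blind to an effect planted at a neighbouring locus of the same gene.
Second, compositionality is deliberately not enforced — each cell type's
frequency is generated independently, matching per-trait scans.

What the generator does **not** emulate: raw cytometry events and gating,
antibody-affinity artefacts, shared-precursor compositional coupling
between traits, genuine genome-wide LD beyond gene-block haplotype
sharing, and polygenic backgrounds beyond the strain-level noise term.
Passing tests therefore demonstrate correctness and calibration of the
*procedure*, not performance on real CyTOF data.

## Haplotype reconstruction and kinship

`reconstruct_haplotypes()` runs a per-strain, per-chromosome
forward–backward pass over a hidden Markov chain whose states are the
eight homozygous founder origins (the panel is inbred, so no heterozygous
states exist). Emission probability is `1 − ε` when the observed allele
matches the founder allele and `ε` otherwise (`ε` = 0.01 by default);
missing genotypes are uninformative. Transitions stay on the same founder
with probability `1 − τ` and switch to each other founder with
`τ/(n_founders − 1)` (`τ` = 0.002). Transition probability is constant per
adjacent-locus interval — no genetic map is used; this is a documented
simplification.

`compute_kinship()` returns `K[i,j]` = mean over loci of the inner product
of the two strains' founder-probability vectors. For the scan itself the
pipeline uses `compute_kinship_loco()`: the kinship recomputed for each
chromosome from all *other* chromosomes. With a single global matrix, a
strong QTL inflates the estimated heritability of its own trait and is
partially absorbed into the polygenic covariance, deflating its LOD
(proximal contamination); leave-one-chromosome-out kinship is the standard
remedy in modern scan packages and measurably restores power here.

## The genome scan

For one trait, `qtl_scan()` fits at every locus

\[
y = \mu + X_\ell \beta + g + e, \qquad
\mathrm{cov}(g) = \sigma^2_g K, \quad \mathrm{cov}(e) = \sigma^2_e I,
\]

where `X_ℓ` holds the founder-dosage columns (haplotype posterior
probabilities, one column dropped against collinearity with the
intercept). The heritability is profiled once per trait under the null
model after a single eigendecomposition of K; the null and all locus
models are then generalized least-squares fits in the rotated space, so a
genome scan costs one QR decomposition per locus.
`LOD = (n/2) log10(RSS₀/RSS₁)` under the profiled Gaussian likelihood.

Replicate mice are averaged to one value per strain before fitting
(`pool_replicates = TRUE`). The strains are inbred, so replicates are
genetically identical; at the sample level the kinship matrix would
contain identical rows per strain, and *any* strain-level variance —
including the tested QTL's — would masquerade as heritability and compress
LOD scores (we observed profiled h² ≈ 0.95 and roughly threefold LOD
shrinkage in that regime). Scanning strain means is the standard treatment
of replicated inbred panels.

**Permutation FDR.** `permutation_threshold()` shuffles strain labels
relative to the genotypes — replicates always move together, which is
automatic for strain means — and recomputes the scan for every shuffle,
re-profiling the heritability per shuffle (snapped to a 0.05 grid, with a
knot at 0.99, so shuffles in the same weighting regime share locus
decompositions). The estimated FDR at a candidate threshold `t` is the
mean permuted count of loci at or above `t` divided by the observed count;
the threshold is the smallest observed LOD with estimated FDR ≤ 5%, or
`+∞` when none qualifies. An exhaustive mode enumerates all label
permutations for small panels and is verified against a brute-force oracle
in the tests.

**Stability.** `loo_stability()` removes each mouse in turn and keeps a
locus only if its LOD stays at or above the full-data threshold in every
refit. `collapse_to_genes()` then reports one lead locus per gene (highest
LOD, ties broken by smallest genomic position).

## Replication and signal propagation

`validate_associations()` re-tests every stage-1 association in the
validation cohort: one-way ANOVA of the trait across the biallelic
genotype classes at the lead locus (each mouse enters individually by
default; pooling to strain means is available behind a flag),
Benjamini–Hochberg correction applied jointly across all tested
associations, and a directionality gate requiring strictly positive
Spearman correlation between the allele-stratified trait means of the two
cohorts. Allele groups with fewer than two samples make an association
untestable rather than failed.

`cluster_genes()` clusters the validated genes' LOD profiles across cell
types with k-means (multiple restarts under a fixed seed); the number of
clusters maximizes the mean silhouette width under Euclidean distance, and
the candidate range is truncated to `[2, n_genes − 1]`. Profiles are not
standardized by default; both choices are configurable because neither is
dictated by the method itself. `propagate()` computes each cluster's
median LOD per cell type and associates the cluster with every cell type
whose median reaches at least 40% of the cluster's top median (`≥`, so
"at least 40%" includes exact equality; the 40% value is a configurable
default, not re-derived here). Every gene in the cluster inherits those
associations; propagation only ever adds, and the rule is scale-free even
though k-means itself is not.

## Classification and conservation

`binarize_expression()` calls a gene expressed at or above 47 a.u. — the
level below which a gene is silent with ≥95% probability under the
two-Gaussian decomposition of microarray intensity histograms. Using this
low bound rather than the 120 a.u. confident-expression bound is
deliberately conservative against over-calling cyto-trans; the boundary
value 47 itself counts as expressed for the same reason. A cell type
mapped to several reference populations counts as expressing the gene if
any one population does; the human lymphocyte composite instead requires
expression in both B and T cells. Genes absent from the reference are
flagged unclassifiable and excluded from tallies and from conservation
grouping, with a logged count.

`gene_conservation_score()` averages per-site scores over the intersection
of conserved elements with coding sequence. Site-weighted averaging is the
default (the finer-grained reading); element-weighted mean-of-means is
available via `weighting = "element"`. A gene whose CDS overlaps no
conserved element has a missing score and is dropped pairwise from
comparisons. `assign_groups()` flags genes with any cyto-trans association
and genes associated with ≥2 cell types after collapsing all B-cell
subtypes into one type and granulocytes+monocytes into another.

`ks_one_sided()` tests whether the focal group is stochastically smaller
(less conserved): `D = sup(ECDF_a − ECDF_b)` over the pooled sample
points, with the one-sided asymptotic tail `p = exp(−2D² n_a n_b/(n_a+n_b))`.
The direction is fixed a priori by the weaker-selection hypothesis. An
exact small-sample p-value (lattice-path counting, valid without ties) is
available with `exact = TRUE`; the asymptotic tail is mildly conservative
at n ≈ 30 per group (empirical null rejection ≈ 0.034 at α = 0.05 versus
0.046 for the exact variant), so the calibration suite exercises the exact
option. `chi2_enrichment()` is the Pearson chi-square with one degree of
freedom, continuity correction off by default, with a `low_expected` flag
when the asymptotic approximation is doubtful.

## Numerical choices and degenerate inputs

* Eigenvalues of kinship matrices are clipped at zero; heritability is
  profiled on (0, 0.99); rank-deficient locus designs (e.g. monomorphic
  posteriors) fall back to the fitted rank and yield LOD 0 with a warning;
  LOD values are clipped at 0 and a constant phenotype yields LOD 0
  everywhere.
* Posterior rows of the haplotype HMM are renormalized per locus; scaled
  forward–backward avoids underflow.
* Exact LOD ties at a gene's lead locus break toward the smallest genomic
  position; k-means falls back to a single cluster when all profiles are
  identical or no valid k remains.
* Empty immune gene sets warn and return an empty locus table rather than
  erroring; empty association lists propagate cleanly to empty tallies
  without division by zero.

## Problem sizes used by the test and acceptance suites

The acceptance suite runs the full pipeline on the default panel (30 + 24
strains, 240 loci, 60 genes, 9 cell types, 200 permutations per trait)
over 50 seeds for recovery, 200 reduced null panels (2 cell types, 60
loci, 20 genes, 60 permutations, stability filter off so that null
survivors exist to validate) for calibration, 100 conservation-shift
panels for KS power, and 1,000 draws for the KS/chi-square null rejection
rates. These sizes give stable rates while keeping a full run of the suite
in the minutes range on one CPU.

## Known limitations

* The HMM transition probability ignores genetic map distance; kinship is
  realized rather than pedigree-based.
* The scan assumes Gaussian residuals on the raw frequency scale; strongly
  skewed traits (very rare cell types) are handled but not transformed.
* The permutation FDR estimator is the empirical tail-count ratio; with
  very few observed loci above threshold it is discrete and conservative.
* Human mode accepts only pre-binarized expression calls; no numeric
  threshold is applied to human data.
* The 40% propagation threshold and the 47 a.u. expression threshold are
  configuration defaults taken from their field-standard values, not
  re-derived from data.
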