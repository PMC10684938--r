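---
title: "Models and methods behind obake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind obake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`obake` analyses population structure, diversity, and interspecific
hybridization in panels of *Oryza longistaminata* (the perennial,
self-incompatible wild rice of sub-Saharan Africa) and its AA-genome
relatives *O. sativa*, *O. barthii* and *O. glaberrima*.  "Obake" is the
field name for spontaneous *O. sativa* x *O. longistaminata* hybrids.  This
vignette explains each model, the tunable parameters, the numerical
choices, and the synthetic-data generator used to validate every stage.

## Genotype filtering

The filter cascade (`filter_sites()`, `filter_individuals()`) follows the
standard post-calling practice for reduced-representation (RAD-seq) rice
genotypes, in a fixed order:

1. multi-allelic records are reduced to their two most common alleles;
   calls carrying any other allele become missing;
2. calls whose total allelic read depth falls outside `[depth_min,
   depth_max]` (default 7–400 reads) are masked — per genotype, not per
   site, so a site with a few bad calls survives;
3. sites are dropped when the heterozygous fraction among remaining calls
   exceeds `max_het_fraction` (default 0.5 — in a panel dominated by
   inbred or partially inbred material, an excess of heterozygous calls
   marks paralog collapse), when the minor allele frequency falls below
   `maf_min` (default 0.01), or when fewer than `site_presence_min`
   (default 66%) of individuals carry a call;
4. individuals missing more than `indiv_missing_max` (default 40%) of
   calls are removed.

Each dropped site is attributed to the *first* rule it fails, producing a
deterministic filter log.  The heterozygosity cap is computed among
non-missing calls only; whether missing calls belong in the denominator is
genuinely ambiguous, and the choice is stated here rather than guessed to
match anything.  MAF and presence are always recomputed when the analysis
subset changes (hence the site count shrinks in pass 2).

## The admixture model

Each of K clusters has its own alt-allele frequency per locus
(`P`, K x L); each individual has ancestry proportions on the K-simplex
(`Q`, N x K).  A dosage `x` at locus `l` for individual `i` is binomial
with success probability `theta_il = sum_k Q_ik P_kl`.

`fit_unsupervised()` is a Gibbs sampler over latent allele-copy origins:
every allele copy is assigned to a cluster with probability proportional
to `Q_ik P(allele|k)`; cluster frequencies are redrawn from
`Beta(lambda + alt count, lambda + ref count)`; ancestry rows from
`Dirichlet(alpha + origin counts)`; the single shared concentration
`alpha` by a Metropolis step (uniform(0, 10) prior, proposal sd 0.05).
The frequency prior is the independent-frequencies model with a symmetric
`lambda = 1`; the correlated-frequencies variant is out of scope — for a
panel of well-diverged species the independent prior is adequate and much
simpler.  Posterior means of `Q` and `P` are taken over post-burn-in
sweeps; the model evidence is estimated by the usual
`mean(lnL) - var(lnL)/2` convention over the post-burn-in trace, so Evanno
inputs are well defined.  Clusters are reported in descending
total-ancestry order; cross-run alignment uses greedy maximum shared-mass
matching (`match_clusters()`).

`fit_supervised()` implements the use-population-information semantics:
flagged individuals are pinned to the indicator ancestry of their
predefined population (a zero migration prior) and are the only ones whose
allele origins update `P`; unlabeled individuals receive admixture-model
ancestry against those frequencies.

A deterministic EM (MAP) counterpart (`method = "em"`) exists for fast
exact-ish unit tests; all stochastic claims are tested with the Gibbs
sampler under stated seeds.  The data log-likelihood is evaluated on a
thinned schedule (`ll_thin`, default every 5th sweep in the reduced
profile) purely to save time; the evidence estimator uses the evaluated
sweeps.

Chain lengths: the full profile is 10,000 burn-in + 50,000 repetitions
with 3 chains at K = 1..9; the reduced profile (1,000 + 5,000) is the
default for synthetic desk-scale panels of a few hundred loci, where
trace inspection shows convergence within a few hundred sweeps.

## Evanno delta-K

`evanno()` takes replicate evidence estimates per K on a contiguous grid
and computes `L(K)` (replicate mean), `L'(K)`, `|L''(K)|` and
`deltaK = |L''(K)|/sd(L(K))`; the optimum maximizes deltaK over interior
K.  When every replicate at some K returns the same evidence the ratio is
undefined and reported missing; if that happens everywhere the function
stops and directs the user to inspect `lnP` directly, because the
statistic carries no information in that case.

## DAPC

`run_pca()` mean-imputes missing dosages per site, centers columns
(no variance scaling) and decomposes by SVD.  `find_clusters()` runs
k-means (`stats::kmeans`, `n_start` restarts — the same convergence device
as the field-standard implementation) for each K and scores
`BIC(K) = n log(WSS_K/n) + K log(n)`, selecting the argmin.  The search
runs on the leading PCs only, by default at most N/3 axes (the usual DAPC
rule of thumb): the between-group signal of a panel at realistic
differentiation lives in a handful of axes, while the remaining axes carry
per-locus sampling noise whose within-cluster volume otherwise rewards
spurious splits.  The N/3 default is a design choice made once; both the
axis count and `n_start` are explicit arguments and logged in results.

`fit_assign()` builds linear discriminant axes from the between/within
scatter of the retained PCs and scores posteriors from Gaussian
class-conditional densities with a shared within-group covariance and
equal priors (so a point equidistant between two identical-covariance
groups scores exactly 0.5/0.5 regardless of group sizes).  A singular
within-scatter matrix receives a logged ridge.

## Spatial PCA

Genotypes are pooled by collection site (exact coordinate equality after
rounding to 4 decimals) and sites are connected by the minimum spanning
tree on great-circle distances (haversine, Earth radius 6371.0088 km),
with ties broken lexicographically by site id.  With the row-normalized
adjacency `W` and its symmetrization `Omega`, `spca()` eigendecomposes
`(1/n) X' Omega X` of the column-centered site-frequency matrix, so each
eigenvalue is exactly the product of the axis score variance and a
Moran-type spatial autocorrelation — large positive eigenvalues are
cline-like global structure.  Lagged scores are `W %*% scores`
(neighborhood-smoothed); two axes are retained by default.  Raster
interpolation of lagged scores is out of scope; per-site lagged scores are
the exported product.

Geographic thinning (`geo_thin()`, default 25 km) greedily keeps
accessions in stable id order, both individuals of an accession together,
because the accession is the sampling unit.  `geo_correlation()` regresses
a coordinate on the K-1 free ancestry components (the full Q matrix is
collinear) and reports r-squared; a per-group simple correlation would be
a different, also defensible, aggregation — the regression definition is
this package's documented choice.

## Diversity statistics

`nei_components()` implements harmonic-mean sample-size-corrected
estimators: with `ntilde` the harmonic mean of per-group sample sizes and
S groups,

```
Ho = mean_s Ho_s
Hs = ntilde/(ntilde-1) * (1 - mean_s sum_a p_sa^2 - Ho/(2 ntilde))
Ht = 1 - sum_a pbar_a^2 + Hs/(ntilde S) - Ho/(2 ntilde S)
```

whence per-locus `F_ST = 1 - Hs/Ht`, `F_IS = 1 - Ho/Hs`, per-group gene
diversity `D = (2n/(2n-1)) (1 - sum p^2)`, per-group `F_ST` against the
pooled total, and pairwise Jost's
`D = ((Ht - Hs)/(1 - Hs)) * S/(S-1)`.  These corrections make `Hs`
unbiased for the parametric gene diversity even under inbreeding, which is
what makes `F_IS` recovery exact in expectation.

Two summaries are reported.  The table-style summary is the mean and
standard error of the per-locus values across loci, with loci excluded per
statistic where it is undefined (`Hs = 0` for F_IS, `Ht = 0` for F_ST,
`Hs = 1` for Jost's D); negative per-locus values from sampling noise are
retained, not clamped.  The `multilocus` summary is the
ratio-of-locus-means (Nei's multi-locus convention), which is the
estimator that recovers the generating divergence without bias: averaging
per-locus ratios is accurate in the weak-differentiation regime
(F_ST of order 0.01–0.05, where the wild-rice subpopulations live) but
biased downward at strong divergence, so parameter-recovery claims at
F = 0.3 are made with the multilocus form.

## Trees and haplotype networks

`ibs_distance()` is the probability that one allele drawn from each of two
individuals differs, `p_i(1-p_j) + (1-p_i)p_j` with `p = dosage/2`,
averaged over shared non-missing loci.  It is a pseudo-metric: symmetric
with zero self-distance, but the triangle inequality is *not* guaranteed
and not asserted.  Neighbor-joining uses the Saitou–Nei agglomeration of
`ape::nj`; negative branch lengths are clamped to zero with the deficit
moved to a sibling branch, which preserves leaf-to-leaf path lengths as
far as the tree allows.  Rooting (`root_at_max_distance()`) places the
root on the pendant edge of the candidate (outgroup) leaf involved in the
globally maximal pairwise distance, ties broken by the lexicographically
smaller id; the alternative reading — the candidate with the maximal row
mean — is available via the distance matrix directly.

Plastid SSR haplotypes are collapsed exactly (`collapse_haplotypes()`,
requiring complete 7-locus profiles, mirroring the no-missing-data rule of
capillary-scored plastid markers).  The haplotype network (`msn()`) is the
union of all minimum spanning trees: an edge of weight w survives iff its
endpoints lie in different components of the strictly-lighter subgraph, so
tied edges at the joining threshold are all retained and the construction
is deterministic.  The default SSR distance counts differing loci; a
stepwise (sum of repeat-size differences) option exists, since the
appropriate mutation model for these markers is not settled.

## Hybrid classification

Thresholds are calibrated from control hybrid material
(`calibrate_thresholds()`): the lower edge is the minimum control
outgroup-admixture (folded onto the nearer simplex corner, since the band
is symmetric), rounded down to 3 decimals minus one grid step so every
control falls inside; the default band without controls is
`[0.044, 0.956]`.  The printed 4.4% definition and the 4.5% narrative
minimum coexist in practice; entries in `[0.044, 0.045)` carry a
borderline flag, and the pass-2 exclusion cutoff defaults to 0.045
independently.

For a wild-labeled entry the outgroup admixture is the *total*
non-conspecific ancestry `1 - Q_longistaminata` (an option restricts to
`Q_sativa` only); entries inside the band are putative hybrids.  Direction
compares the two focal components; generation bands compare the
minority-parent proportion with 0.5 (F1/F2), 0.25 (BC1) and 0.125 (BC2)
at half-width `delta = 0.06`, chosen to contain known F1/F2 controls
whose minority ancestry prints at 0.46–0.49; overlapping bands resolve in
that order.  The maternal parent is read off the plastid haplotype group,
and a cytonuclear consistency flag checks that the maternal species also
contributes nuclear ancestry.

## The synthetic-data generator

`sim_spec()`/`sim_panel()` emulate the study design: one outcrossing wild
species with three geographically structured subpopulations, a
domesticated Asian species with two groups, an African outgroup pair that
behaves as a single cluster, pedigreed interspecific hybrids, maternally
inherited plastid SSR haplotypes, and missing-data/read-depth models, with
complete ground truth.

Allele frequencies follow a Balding–Nichols hierarchy: ancestral
frequencies uniform(0.05, 0.95); each pool a Beta draw around its parent.
Divergence parameters are expressed in units of the *expected measured*
Nei F_ST and converted internally (`bn_coef()`): a naive two-group draw at
coefficient F yields measured F_ST of roughly F/2, so the conversion
`c = S F/(S - 1 + mean(F))` is what makes "simulate at F = 0.022" and
"measure 0.022" the same statement.  Defaults: wild-vs-domesticated split
0.30; outgroup pool 0.35; the two domesticated groups 0.20 (a realistic
subspecies-scale differentiation); the outgroup pair 0.01 (they cluster
together, as observed); subpopulations (0.022, 0.013, 0.023) — the
weak-differentiation regime reported for this species; inbreeding
(0.28, 0.29, 0.44) for the wild subpopulations and 0.95 for the selfing
species.  Wild individuals carry ancestry gradients: subpop weights decay
exponentially with distance to the subpop centers (steepness 0.0015/km,
which leaves near-center individuals ~90% assigned and mid-range
individuals visibly admixed).  An `ancient_admixture` option blends a
small fixed domesticated-ancestry fraction (e.g. 0.037) into every member
of a named subpopulation to emulate old introgression; it is off by
default.

Genotypes are unlinked: each locus draws independently given ancestry
(`sim_individual()`, with inbreeding implemented as allele duplication
with probability `f_is`).  Pedigrees (`sim_pedigree()`) track explicit
haplotypes and per-copy species origins through a crossing grammar (`F1`,
`F2`, `BCn(parent)`, `SELFk`, `RIL = F1 > SELF5`), so true ancestry is the
*realized* fraction of allele copies, and the maternal lineage (hence the
plastid haplotype) follows the mother through the chain — backcrosses take
the hybrid as mother, matching the observed predominance of wild-plastid
field hybrids.  Plastid founders differ at >= 3 of 7 loci between species
and mutate stepwise (+/-1 repeat) within species lineages only.

Because loci are unlinked and frequencies exchangeable, the generator does
not reproduce linkage disequilibrium, allele-frequency spectra under
selection, or realistic demography; passing tests therefore validate the
estimators and decision rules under the model the analyses themselves
assume, not robustness to those violations.

Two focused designs exist for validation: `sim_design_panel()` draws six
discrete, variance-homogeneous clusters (the k-means/BIC contract is about
spherical equal-variance clusters, which the gradient-admixed,
unequal-inbreeding full panel deliberately is not), and
`sim_pedigree_panel()` pairs homogeneous species pools with pedigreed
progeny (reference groups with internal substructure attenuate hybrid
ancestry estimates — visible in real panels too, where F1 controls print
slightly below 0.5 on the domesticated side).

## Problem sizes

Synthetic validation runs at desk scale, chosen once: the Evanno panel is
~116 individuals x 500 loci with 3 chains at K = 1..5 under the reduced
MCMC profile; the DAPC design panel is 180 individuals x 6,000 loci
(resolving ~0.02 differentiation needs a few thousand loci, since cluster
detectability grows like F*sqrt(L)); estimator recovery uses 100
individuals x 2,000 loci; pedigree recovery 103 individuals x 1,000 loci
with 3 supervised chains.

## Known limitations

- The admixture sampler uses a single shared alpha; per-cluster alphas and
  the correlated-frequencies prior are not implemented.
- Supervised ancestry of hybrids leaks a little posterior mass into a
  third, correlated cluster at modest locus counts (the posterior mean of
  a boundary parameter is necessarily positive); at a few hundred loci
  this is visible as ~2–5% phantom ancestry and shrinks with L.
- Per-locus-averaged F_ST is biased downward at strong divergence; use the
  `multilocus` field for parameter-level statements.
- IBS distances can violate the triangle inequality; NJ consumes them
  regardless, as is standard practice.
- The k-means BIC argmin over-splits when cluster variances are strongly
  unequal; the retained-PC rule mitigates but does not remove this.
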