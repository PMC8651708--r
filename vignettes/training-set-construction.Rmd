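---
title: "Training-set construction for genomic prediction in autotetraploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-set construction for genomic prediction in autotetraploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic prediction (GP) regresses phenotypes of a *training set* on
genome-wide markers and predicts the genotypic values of individuals that
have not been phenotyped. When phenotyping is the expensive step, the
practical question is *which* individuals to phenotype: a training set that
covers the genetic space of the prediction targets calibrates the model
where it will be used; a redundant or lopsided one wastes plots and lowers
accuracy. For autotetraploid crops such as cultivated potato the marker data
come as allele dosages — at a biallelic SNP a tetraploid can be AAAA, AAAB,
AABB, ABBB or BBBB, coded 0–4 copies of the alternate allele — and every
step of the workflow (distances, kinship, prediction models) has to respect
that dosage scale rather than collapse it to diploid 0/1/2 calls.

`tetrasel` implements the full comparison workflow: dosage-aware genetic
distance measures, four training-set samplers, three whole-genome regression
models, two cross-validation designs with a factorial ANOVA of accuracies,
and a synthetic panel generator that stands in for a real diversity panel so
the entire pipeline is testable end to end.

## The synthetic panel: what it emulates, and what it does not

`simulate_panel()` emulates a potato diversity panel of about 190 cultivated
tetraploid lines genotyped at about 3,262 biallelic SNPs after marker QC,
organised in three *weakly* separated subpopulations (market-class groups).
Differentiation follows the Balding–Nichols model: marker $j$ has an
ancestral alternate-allele frequency $p_j \sim U(0.05, 0.95)$, stratum $k$
draws $p_{jk} \sim \mathrm{Beta}$ with mean $p_j$ and variance
$F\,p_j(1-p_j)$, and individual dosages are $\mathrm{Binomial}(4, p_{jk})$.
The single knob $F$ (`fst_target`, default 0.012) puts the panel in the
weak-structure regime that motivates the whole study: allele-frequency-based
pairwise Fst between groups of roughly 0.01–0.02, and a leading principal
component explaining well under 10% of the dosage variance.

Two modelling notes that matter when reading the numbers:

* **Dosage AMOVA inflates differentiation by the ploidy.** In an AMOVA on
  squared Euclidean *dosage* distances the four allele copies of an
  individual move together with the group mean, so for
  $\mathrm{Binomial}(q, p_{jk})$ dosages the expected among-group fraction
  is $qF/(1 + (q-1)F)$ — about 4.6% at the default $F = 0.012$ — while an
  allele-frequency estimator (Hudson's, available in
  `pairwise_fst(estimator = "hudson")`) recovers $F$ itself. Real panels
  report among-group fractions and pairwise Fst values from different
  groupings and estimators that a single-$F$ exchangeable model cannot
  reproduce simultaneously; we calibrate to the pairwise Fst scale and
  document the dosage-AMOVA transform instead of chasing both.
* **No linkage disequilibrium, no pedigree.** Markers are independent given
  the stratum frequencies and individuals are unrelated within strata. Real
  diversity panels carry LD blocks and family structure, which raise the
  effective information per marker and hence the absolute prediction
  accuracies. Consequently the *absolute* accuracies here are lower than on
  a real panel at the same sizes; the method *contrasts* (analytical vs
  random samplers, model rankings, size effects) are the quantities the
  generator is designed to support, and what the tests assert. Passing
  tests therefore demonstrate correct algorithms and the expected
  qualitative pattern under weak structure — not accuracy levels
  transferable to field data.

Traits are additive in dosage over `n_qtl` randomly placed QTL (with
optional pairwise multiplicative epistasis); residuals are orthogonalised
against the genetic values and rescaled so the realized variance-ratio
heritability equals the target exactly in every replicate, which makes
heritability-recovery tests sharp rather than approximate. The workflow's
default traits mirror a high-heritability polygenic trait
($h^2 = 0.91$, 50 QTL, tuber-length-like) and two sparser sugar-content
traits ($h^2 = 0.85$ and $0.67$, 10 QTL), following the view that sugar
content is controlled by few loci.

## Distances and similarities on dosages

Four measures are implemented, all over shared non-missing markers
(pairwise deletion with per-pair renormalisation; no imputation):

* **Euclidean** on raw dosages, $D_{XY} = \sqrt{\sum_j (X_j - Y_j)^2}$ — a
  purely geometric measure, converted to similarity by $1 - D/\max(D)$.
* **Nei's distance**, treating each individual's dosage as within-individual
  allele proportions $(d/4,\, 1 - d/4)$ and forming the printed single
  global ratio across loci (not a per-locus average); $-\ln$ of a zero
  ratio is kept as an `Inf` sentinel that maps to similarity 0. Its
  similarity transform $1 - D$ is clamped to $[0,1]$ because the distance
  is unbounded.
* **Jaccard**, $\sum_j \min(X_j, Y_j) / \sum_j \max(X_j, Y_j)$ — an
  intersection-over-union on alternate-allele counts. Although written as a
  "distance" in parts of the literature it is already a similarity in
  $[0,1]$ and is used as such (no further transform); a pair of identical
  reference homozygotes (0/0 denominator) is defined as similarity 1.
* **Kosman–Leonard**, the ploidy-aware allele-sharing fraction
  $\tfrac1r \sum_j (X_j \cap Y_j)/q$ with
  $X_j \cap Y_j = \min(X_j, Y_j) + \min(q - X_j,\, q - Y_j)$; for biallelic
  dosages this equals $1 - \mathrm{Manhattan}/(qr)$, a closed form the
  tests use as a cross-check.

`mantel_correlation()` compares matrices by the Pearson correlation of
lower-triangle entries with a joint row/column permutation test; the
identity permutation is counted so the p-value is never zero, and the test
is two-sided on $|r|$.

## Kinship and the CDmean criterion

`vanraden_A()` builds the additive genomic relationship matrix from the
recoded dosages $W = (d - q/2)/(q/2)$ (so $\{0..4\} \to \{-1, .., 1\}$):
$Q_{ij} = W_{ij} + 1 - 2p_j$ and $A = QQ'/(2\sum_j p_j(1-p_j))$. We take
$p_j$ as the frequency of the *counted* (alternate) allele,
$\bar d_j / q$: that is the unique choice under which $1 - 2p_j$ exactly
centers $W$, giving zero-mean columns of $Q$ and $A\mathbf{1} = 0$ when
frequencies are estimated from the panel itself — the centering identity
the formula exists to provide. Missing dosages are mean-imputed in $W$
(only here; distances use pairwise deletion), which keeps $A$ positive
semidefinite.

The CDmean criterion scores a candidate training set $T$ by the generalized
coefficient of determination of prediction contrasts
$c_t = e_t - \frac{1}{N}\mathbf{1}$ between each unphenotyped target $t$
and the candidate average:

$$ CD(c) = \frac{c'\!\left(A - \lambda (Z'MZ + \lambda A^{-1})^{-1}\right) c}{c'Ac}, $$

with $\lambda = (1-h^2)/h^2$ (default $h^2 = 0.5$, i.e. $\lambda = 1$ — a
deliberately trait-agnostic choice, since training sets are usually chosen
before heritability can be estimated and for several traits at once), $Z$
the incidence of training observations and $M$ the projector orthogonal to
the intercept. `cdmean_select()` maximizes the mean CD by a stall-bounded
stochastic exchange search (default 2,000 consecutive rejections to stop,
3 restarts): swaps are accepted only on strict improvement, so the
objective trajectory is non-decreasing and the result can be checked
against exhaustive enumeration on small instances (the tests do exactly
that on all $\binom{8}{3}$ subsets). In the training-validation setting the
"individuals without phenotypes" are whatever is currently unselected, so
the target set is recomputed after every accepted swap; in the
training-test setting the contrasts target the fixed test set. Internally
the search maintains the inverse of $\lambda A^{-1} + \mathrm{diag}(t)$
under rank-one Sherman–Morrison updates (refreshed every 200 accepted swaps
against numerical drift), so one proposal costs $O(N^2)$ instead of a fresh
$O(N^3)$ factorization; tests verify the fast objective against the dense
formula to $10^{-8}$. A ridge of $10^{-6}$ on the diagonal of $A$ keeps the
inverse well-defined for singular relationship matrices.

## The four samplers

* **SRS** — uniform without replacement.
* **STRAT** — proportional allocation $n_S = (n/N) N_S$ per stratum,
  reconciled to exactly $n$ by largest remainders, then SRS within strata.
* **GD** — radial-exclusion (core-collection) sampling on a similarity
  matrix: pick uniformly, discard everything within distance $r$
  (strictly, so $r = 0$ discards nothing and reduces to SRS; ties at $r$
  survive), repeat until $n$ are chosen. The radius is tied to the sample
  size; since larger $r$ spreads the sample more, `gd_sample()` tunes $r$
  by bisection to the largest radius at which $n$ is still attainable,
  replaying a fixed inner RNG substream per evaluation so the search is
  monotone and reproducible. The realized minimum pairwise distance of the
  sample is always at least the final radius.
* **CDMEAN** — the exchange search above.

All samplers are deterministic under a fixed seed, return exactly `n`
unique candidate ids, and record their tuning diagnostics.

## Prediction models

`gblup_fit_predict()` fits $y = \mathbf{1}\beta + u + \varepsilon$,
$u \sim N(0, A\sigma^2_g)$, by REML on the training block of $A$ using the
spectral decomposition of the projected kernel (exact and fast at panel
sizes of a few hundred; the variance ratio is profiled on a coarse log grid
and refined by golden-section search). Predictions for unphenotyped
individuals are the conditional means under the joint normal — equivalent
to training-set BLUP followed by kernel projection, and checked against a
dense mixed-model-equation solve and against ridge regression on $Q$ with
the matched penalty.

`rkhs_fit_predict()` swaps $A$ for the Gaussian kernel
$K = \exp(-D/\theta)$. The bandwidth grid is fixed to 20 values in
$(0.05, 1]$, which is only meaningful if $D$ is on a stable scale, so $D$
is the squared Euclidean distance on recoded dosages divided by its own
mean off-diagonal entry (the unnormalized and plain-distance options are
flags; squared distances are the default reading of a Gaussian kernel).
$\theta$ is chosen by maximum restricted likelihood over the grid.

`bayesc_fit_predict()` is a Gibbs sampler (Rcpp) for the spike-and-slab
model: $b_j = 0$ with probability $\pi$, else $N(0, \sigma^2_b)$, with
$\pi \sim \mathrm{Beta}(1,1)$ estimated from the data and
scaled-inverse-$\chi^2$ priors on both variances (df 5, scales split at
$R^2 = 0.5$ — conventional defaults of Bayesian whole-genome regression
software, stated here because no reference fixes them). Marker columns are
centered at training means; predictions use posterior-mean effects.
Default chain length is 5,000 with 2,500 burn-in. The $\pi = 0$ limit is
checked against an independent plain-R Bayesian ridge sampler, $\pi = 1$
collapses to the intercept, and chains are bit-reproducible under a seed.

## Evaluation designs and the accuracy ANOVA

The **TV scheme** samples training sets of 50–150 from all 190 and
validates on the complement (100 replicates per size at full scale). The
**TT scheme** first holds out a common test set (40 by default; menus pair
test sets of 40/70 with training sizes 25–100 and a test set of 95 with
30–75), then lets every method sample from the remaining pool, so all
methods predict identical individuals; CDmean uses targeted contrasts
there. Accuracy is the Pearson correlation between predictions and the
held-out phenotypes; `fisher_z()` ($\tfrac12\ln\frac{1+r}{1-r}$)
variance-stabilizes it.

`anova_accuracy()` aggregates to one cell mean per
(method, size, model) — the residual degrees of freedom of the reference
layout (36 for a 4×5×3 grid, 24 for 4×4×3) identify cell means, not
replicate-level records, as the response, and a single degree of freedom
for size identifies it as a numeric covariate — then fits
`z ~ method * size * model` with sequential (Type I) sums of squares in
that term order (Type II behind a flag).

Replicates are seeded by a deterministic counter derived from the base
seed, so any subset of cells reproduces identically regardless of
execution order.

## Problem sizes used in the shipped analyses and tests

The numbered scripts under `analysis/` and the heavier tests run a
desk-scale replication chosen to keep the full pipeline at minutes on one
CPU: 20 TV replicates (sizes 50–150), 10 test sets × 5 sampling replicates
for TT (sizes 25–100), GBLUP + BayesC with 1,000/500 MCMC iterations, and
the CDmean search at `max_stall = 300` with one start. Package defaults
remain at the full design (100 TV reps, 50 × 50 TT, 5,000/2,500 MCMC,
`max_stall = 2000`, 3 starts). At desk scale the qualitative conclusions —
analytical samplers above SRS at small $n$, stratification
indistinguishable from SRS under weak structure, sample size the dominant
ANOVA factor, no method × model interaction — are stable; individual
accuracy estimates carry Monte-Carlo error of a few hundredths.

## Numerical choices and edge cases

* Distances: orthogonal Nei profiles give `Inf` (similarity 0); all-zero
  Jaccard denominators give similarity 1; pairs with no shared markers are
  an error rather than a guess.
* `qc_filter()` applies the boundaries strictly as stated: MAF *below* 5%
  removed (exactly 5% kept), *more than* 30 missing removed (exactly 30
  kept); the missingness threshold is an absolute count tied to a
  190-line panel, with a fractional alternative. First-failure attribution
  orders filters as monomorphic, unmapped, MAF, missingness; the report
  also carries per-filter totals since a marker can fail several.
* Kernel REML adds a $10^{-8}$ jitter before the training-block solve;
  eigenvalues of the projected kernel are clipped at zero and a negative
  spectrum beyond tolerance is an error (non-PSD input).
* The GD bisection runs 40 iterations on $[0, \max D]$; with a
  user-supplied radius an unattainable $n$ (a sampling path that dead-ends)
  is an explicit error naming the shortfall.
* Exchange-search acceptance requires improvement beyond $10^{-12}$ to
  guard against cycling on rank-one roundoff.

## Known limitations

* The generator's lack of LD and relatedness compresses the gains of
  analytical samplers relative to a real panel; at small training sizes
  they remain positive but modest, and assertions on them are sign-based.
* Because the default synthetic traits are purely additive, RKHS has no
  non-additive signal to exploit and performs like GBLUP here, while
  BayesC clearly leads on the sparse traits; on real panels with epistasis
  or dominance RKHS is expected to close that gap (and the generator's
  epistasis option can be used to study exactly that).
* DAPC-style merging of market classes is out of scope — strata are inputs.
* Only biallelic markers are supported; the Kosman–Leonard measure's
  multi-allelic generality is not exercised.
* BayesC posterior summaries are posterior means only; no credible
  intervals are reported.
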