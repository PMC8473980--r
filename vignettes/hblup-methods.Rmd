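---
title: "Single-step genomic evaluation of disconnected tree breeding programs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hblup)
```

## The problem

Industrial tree breeding programs evaluate tens of thousands of progeny
in replicated field trials, but different programs record their
pedigrees independently and share almost no ancestors.  Pedigree-based
evaluation (ABLUP) therefore cannot compare breeding values across
programs, and cannot predict how a parent would perform in a region
where its progeny were never planted.  Single-step genomic BLUP (HBLUP)
solves both problems with a modest genotyping investment: genotyping a
few hundred progeny-tested parents yields realized genomic
relationships that bridge the programs, and the single-step relationship
matrix **H** propagates that information to every ungenotyped relative.

`hblup` implements this workflow end to end for a two-program,
three-region *Eucalyptus*-style setting: pedigree machinery, genomic
relationships, the H matrix and its sparse inverse, a REML engine for
the individual-tree mixed model with regionally correlated additive
effects, the two-stage multi-site analysis flow, a scenario comparator,
and a gene-drop simulator that generates data with the statistical
structure the analysis assumes.

## Relationship matrices

**Pedigree.** `build_A_tabular()` constructs the numerator relationship
matrix A by the tabular method with inbreeding
(`inbreeding_meuwissen_luo()`); the diagonal is $1+F_i$.  Inbreeding is
always carried through to `build_A_inverse()`, which applies
Henderson's rules with Mendelian-sampling variances
$d_i = 0.5 - 0.25(F_s + F_d)$, an unknown parent entering as an
unrelated, non-inbred population draw ($F = -1$ in that formula).  We
keep inbreeding in both A and its inverse so that the two stay exact
inverses of one another; the tests assert
$\lVert A^{-1}A - I\rVert_\infty < 10^{-8}$ on random pedigrees.

**Genomic.** `compute_G_vanraden1()` uses the first VanRaden form
$G = ZZ' / 2\sum_j p_j(1-p_j)$ with $Z = M - 2P$.  Allele frequencies
are computed from the currently genotyped sample, and missing calls are
mean-imputed to $2p_j$ after a minor-allele-frequency filter (default
5%) — the default behaviour of the preprocessing tools used in routine
single-step pipelines.  A consequence worth knowing: with
sample-estimated frequencies, $G$ is centred so that its overall mean
is zero, which shifts it relative to A in structured samples; the
compatibility rescaling below exists precisely to undo this.

**Tuning and blending.** `tune_G()` solves the two-moment system

$$a + b\,\overline{\mathrm{diag}(G)} = \overline{\mathrm{diag}(A_{22})},
\qquad a + b\,\bar G = \bar A_{22}$$

for the intercept and slope of $G_a = a + bG$.  Both overall means
average all $n^2$ entries including the diagonal; this makes the two
equations linearly independent whenever $G$ is non-degenerate and
matches the tuning literature the approach comes from.  `blend_G()`
then forms $G_w = w G_a + (1-w) A_{22}$ with $w = 0.95$ by default, the
standard weight that guarantees invertibility when $A_{22}$ is positive
definite.  Blending is the sole invertibility guard: no eigenvalue
"bending" of H is applied.

**Single-step H.** `build_H()` assembles

$$H = \begin{pmatrix}
A_{11} + A_{12}A_{22}^{-1}(G_w - A_{22})A_{22}^{-1}A_{21} &
A_{12}A_{22}^{-1}G_w \\
G_w A_{22}^{-1}A_{21} & G_w
\end{pmatrix}$$

and re-sorts the result to the pedigree order.  Two algebraically
equivalent assemblies (the form above and the expanded one that
subtracts $A_{12}A_{22}^{-1}A_{21}$ explicitly) are both implemented
and compared in the tests to $10^{-10}$.  The sparse inverse is

$$H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\
0 & G_w^{-1} - A_{22}^{-1} \end{pmatrix},$$

a pedigree-sparse matrix plus one dense block over the genotyped
subset, which is what the mixed-model engine consumes.

**Race genetic groups.** Founders carry race/landrace labels.
`group_fraction_matrix()` propagates expected founder-race fractions
down the pedigree (founder rows are indicators, every other row is the
mean of its parents' rows; an unknown parent contributes to a pseudo
group `UNKNOWN_RACE`).  Races enter the model as fixed fraction
covariates appended to the design matrix — not as modifications of the
relationship inverse — which keeps H construction group-free and
mirrors the practice of fitting races as fixed genetic groups.  The H
built here deliberately knows nothing about races; comparing fits with
and without the covariates is exactly the ABLUP$_{\pm\mathrm{race}}$
contrast the scenario comparator automates.

**Pedigree conflict detection.** `detect_pedigree_conflicts()` compares
the raw (pre-tuning) G against $A_{22}$ and flags pairs, and diagonal
self-comparisons, whose absolute deviation reaches a threshold.  The
default 0.35 sits midway between the half-sib (0.25) and
parent-offspring (0.5) expectations; it is configurable.  Detection
runs on the raw identity-by-state scale because parentage logic lives
there — tuning would shift it.  The correction policy implemented by
`correct_pedigree()` severs the conflicting parent link (sets it
unknown) rather than searching for the true parent; relationship
construction is then re-run on the corrected pedigree.

## The mixed model

The observation model is $y = Xb + Zu + e$.  Fixed effects: overall
mean, replicate-within-trial contrasts, checklot means (unpedigreed
commercial entries are benchmarks, not genetic entries), and optional
race fractions.  Random terms:

* **additive** — one effect per pedigree individual, per region when
  `region_structure = "unstructured"`; covariance
  $\Sigma_a \otimes K$ with $K^{-1}$ supplied as the sparse $A^{-1}$ or
  $H^{-1}$ and $\Sigma_a$ an unstructured region covariance.  Every
  tree is phenotyped in exactly one region, so cross-region information
  flows only through relatives and $\Sigma_a$;
* **family (SCA)** — keyed by the unordered parent pair of control-
  pollinated progeny, with one variance per region by default (a
  trial-group keying is available for settings where the
  family-to-additive ratio differs between groups of trials);
* **OP family** — open-pollinated families are fitted as iid family
  means and their records carry no individual additive effect, so they
  do not contribute to $\hat\sigma^2_a$;
* **incomplete block** and **row plot** — iid within trial with
  trial-specific variances; residuals are also trial-specific.

### REML

`reml_fit()` maximizes the restricted likelihood with
average-information (AI) updates and an EM fallback.  All quantities
come from one sparse Cholesky factorization of the mixed-model
coefficient matrix per parameter value: the likelihood from
$\log|C| + \log|R| + \log|G| + y'Py$, the gradient from trace
identities evaluated on extracted blocks of $C^{-1}$, and the AI matrix
from projected derivative vectors ($\mathrm{AI}_{kl} = \tfrac12 f_k' P
f_l$).  Numerical choices:

* variances are optimized on the log scale and $\Sigma_a$ through a
  log-Cholesky parametrization, so every candidate is positive
  (semi)definite by construction;
* the LL' (not LDL) factorization is used, so a numerically indefinite
  candidate fails loudly and the line search discards it;
* variances are floored at $10^{-8}\,\mathrm{var}(y)$, and additive
  correlations are restrained to $|r| \le 0.995$ — near $\pm1$ the
  covariance is singular and the likelihood is a flat ridge, and the
  restraint (standard in REML software) simply stops iterations from
  crawling along it;
* parameters pinned at a boundary with an outward gradient are frozen
  out of the AI system (an active set), which restores the quadratic
  convergence the boundary would otherwise destroy;
* AI steps are capped and line-searched against the likelihood, with a
  guaranteed-uphill EM update whenever the AI step fails; the first two
  iterations are EM to stabilize poor starting values;
* convergence requires both $|\Delta\log L| < 10^{-6}$ and a maximum
  relative parameter change below $10^{-6}$, with a 200-iteration cap
  and a warning (not an error) on non-convergence.

The gradient is verified against central finite differences in the test
suite, the AI matrix against a numerical Hessian during development,
and the solutions and likelihood against a dense
$V = ZGZ' + R$ oracle.

### Prediction error variance and accuracy

PEV comes from the exact diagonal of the inverted coefficient matrix —
not from the approximation algorithms used by some REML packages at
scale.  Exact PEV is never larger than those approximations, so
accuracies here can differ slightly (upward) from values computed with
approximate PEV.  Accuracy is $r = \sqrt{1 - \mathrm{PEV}/\sigma^2_a}$
per region, clipped to $[0, 1]$ with a warning.  AIC is
$-2\log L + 2k$ with $k$ the number of free variance parameters; REML
likelihoods condition on the fixed-effect design, so AIC is comparable
only across fits with identical fixed effects — the race/no-race
contrasts report it anyway (as is conventional), and this caveat is the
reason the comparison is labelled descriptive.

## The two-stage analysis flow

`single_site_adjust()` fits each trial separately (pedigree NRM; races
as covariates when supplied) and subtracts the replicate effects and
the incomplete-block and row-plot BLUPs from the response.
`standardize_by_trial()` then centres each trial at zero and scales it
by the trial's additive standard deviation, so trials with different
ages and measurement scales become commensurable; trials whose additive
variance collapsed to the floor are excluded with a warning rather than
dividing by ~0.  `fit_multiregion()` fits the standardized data across
regions with the unstructured additive covariance.  The per-trial
adjustment uses A (the stage precedes genotype integration), and the
two stages are literal, inspectable steps with intermediate columns —
a deliberate simplification of the corresponding operational pipelines,
whose single-site internals are tool-specific.

Heritability and dominance proportions follow the variance-ratio
definitions

$$h^2 = \frac{\hat\sigma^2_a}
{\hat\sigma^2_a + \hat\sigma^2_f + \overline{(\hat\sigma^2_{b} +
\hat\sigma^2_{p} + \hat\sigma^2_{e})}},\qquad
d^2 = \frac{4\hat\sigma^2_f}{\text{same denominator}},$$

with the environmental sum averaged over the region's trials
(`mode = "regional"`) or all trials (`mode = "xsite"`, with a
record-weighted mean family variance).  $d^2$ is four times the
family-variance ratio because full-sib family effects capture one
quarter of the dominance variance.  The additive coefficient of
variation $100\,\hat\sigma_a/\bar y$ is reported only when a trait mean
is supplied — it is meaningless on standardized data.

`scenario_compare()` runs ABLUP with race groups (benchmark), ABLUP
without groups, within-program HBLUP, and joint HBLUP on identical
phenotype rows, and summarizes genetic parameters plus mean EBV
accuracy (with standard errors of class means) for five deterministic
classes per target region: parents with progeny evaluated in the
region, parents whose progeny were evaluated only elsewhere ("parents
correlated" — the class joint analysis helps most), genotyped
non-parents with and without pedigree links, and progeny.

## The synthetic-data generator

`simulate_breeding_data()` emulates the study conditions the analysis
assumes: two programs founded on ~10 native races and landraces
(defaults: 112 and 83 founders, four founders shared), a sparse
candidate-gene panel (2,500 markers), a few hundred genotyped parents,
full-sib/half-sib/checklot entries in incomplete-block, row-plot trials
across three regions, low growth heritability (~0.15) with non-trivial
dominance (~0.12) and inter-region additive correlations of 0.7, and
moderate wood-trait heritabilities on a trial subset.

* **Race structure** is Balding–Nichols: race frequency at marker $j$
  is Beta-distributed around an ancestral Uniform(0.1, 0.9) draw with
  variance $p(1-p)F_{st}$ ($F_{st} = 0.1$ by default); landraces can
  be declared as admixtures of source races.
* **Genotypes** are gene-dropped down the true pedigree without
  linkage.  The panel emulates sparse candidate-gene markers, for which
  linkage disequilibrium structure is irrelevant to relationship
  estimation; nothing in the package models LD.
* **Breeding values are polygenic**, generated from the pedigree
  (founders $\sim N(\text{race shift}, \Sigma_a)$; offspring =
  mid-parent + Mendelian deviation scaled by
  $\tfrac12(1 - \bar F_{parents})$), not from the markers: markers
  inform relationships only, mirroring how single-step evaluation uses
  G as a relationship estimator rather than a marker-effect model.
* **Race mean shifts** are drawn $N(0, \sigma^2_{race})$ with
  $\sigma^2_{race} = 0.4$ by default, so removing race groups from the
  model visibly inflates $\hat\sigma^2_a$ — the directional effect the
  scenario comparison checks.
* **Trial layout**: each family fills one `plot_size`-tree contiguous
  row-plot per replicate in each of its trials, and plots are
  randomized into incomplete blocks within replicates.  Parent reuse
  matters: matings draw from a limited parent pool
  (`parents_per_gen`) so each parent appears in several families, as
  in operational factorial mating designs.  This reuse is also what
  statistically separates additive from family (SCA) variance — with
  one family per parent pair and no parent reuse the two are nearly
  confounded, and variance-component estimates at low heritability
  become erratic.  The generator's defaults keep the ratio of families
  to parents in the operational range.
* **Pedigree errors** replace the recorded sire of a random fraction
  of non-founders with a random earlier individual of the same
  program, keeping the pedigree acyclic and logging every swap in the
  truth log.
* All randomness flows from one master seed through stable per-stage
  seeds, so identical configurations reproduce identical datasets
  byte for byte.

What the generator does **not** emulate: marker linkage and LD,
selection across generations (parents are drawn at random, so there is
no selection-induced trend or Bulmer effect), spatial field trend
beyond the block/plot hierarchy, genotype-calling error other than
missingness, age-age and trait-trait genetic correlations (traits are
generated independently), and checklot-specific residual variances.
Passing tests on this generator therefore validate the estimation
machinery under the model's own assumptions and the stated population
structure — they do not certify behaviour under model violations such
as spatial autocorrelation or selection.

## Problem sizes and reproducibility

The test-suite and acceptance runs use deliberately scaled-down
configurations chosen to exercise every code path while keeping the
whole suite fast on a single core: parameter-recovery runs use 20
replicates of a two-region, ~650-record program (36 families from 14
parents), and the scenario comparison uses a two-program, six-trial
dataset of ~600 records with 800 markers and single-trial families, so
that a sizeable "parents correlated" class exists in every run.  The
statistical contrasts these sizes support (bias of variance-ratio
estimates against 3 Monte-Carlo standard errors; the sign of the
race-removal inflation; the joint-vs-within accuracy gain for
cross-region parents; conflict-detection sensitivity at 2,000 markers)
are the package's acceptance properties, recomputed from scratch by
`scripts/acceptance.R`.

Recovery replicates are generated with race mean shifts switched off so
the generative variance components are exactly the quantities the
fitted model estimates; the race-structured generator is used where the
race contrast itself is the property under test.  Headline quantities
from the motivating application — counts of markers passing QC,
cross-program relationship distributions, AIC orderings, accuracy
gains by class — depend on proprietary field and genotype data and are
reproduced here only directionally, on synthetic data, not numerically.

## Known limitations

* One trait at a time; no multi-trait covariance (regions play the
  "trait" role in the multivariate machinery).
* Family cross-region correlations default to independence; the
  unstructured machinery exists but is exercised only for the additive
  term.
* Checklot records share the trial residual variance (no
  checklot-specific extra residual term).
* No spatial (AR1×AR1) residual modelling; no multistem-form effects.
* `build_A_tabular()` materializes the dense A (or the dense recursion
  for a subset), which is fine to a few thousand individuals but is
  not the path to million-tree evaluations; the sparse
  $H^{-1}$-through-MME route is, and is the one the fitting engine
  uses.
* Automatic parentage reassignment is out of scope: conflicts are
  detected and links severed, not reassigned.
* Genetic groups are fixed covariates; group-aware H formulations
  (Quaas–Pollak absorption, metafounders) are not implemented.
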