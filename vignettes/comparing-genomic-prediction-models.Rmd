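---
title: "Comparing genomic prediction models with paired cross validation and equivalence margins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing genomic prediction models with paired cross validation and equivalence margins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcv)
```

## The problem

Genomic prediction relates dense marker genotypes to quantitative phenotypes
so that the genetic merit of unphenotyped selection candidates can be
predicted. Two model families dominate practice. Marker regressions
("Bayesian alphabet") write

$$y = \mu + X\beta + \varepsilon,\qquad \beta_j \sim F(\Theta),$$

and differ only in the prior on marker effects: a common normal (ridge
regression BLUP, BRR), a scaled-t obtained by putting a scaled-inverse-
$\chi^2$ prior on each marker's variance (BayesA), and spike-slab variants
that set a fraction $\pi$ of effects exactly to zero (BayesB with a t slab,
BayesC with a normal slab). Kernel mixed models instead place the marker
information in the covariance of individual genetic values,

$$y = X\beta + \textstyle\sum_i u^{(i)} + \varepsilon,\qquad
u^{(i)} \sim N(0,\, K^{(i)}\sigma^2_{u(i)}),$$

with $K$ an additive GRM (G-BLUP), its Hadamard square (pairwise epistasis),
a categorical marker-match kernel, or a Gaussian RKHS kernel — possibly
several at once. Since all these kernels are defined only up to a
multiplicative constant (absorbed by $\sigma^2_u$), every fitted quantity in
`gpcv` is invariant to kernel rescaling; this is asserted by tests.

Choosing between such models by cross validation sounds straightforward but
has two statistical traps this package is designed around: ignoring that CV
accuracy estimates are strongly correlated between models (which wastes
power), and treating any statistically significant difference as meaningful
(which, at high power, flags differences no breeder would act on).

## Paired cross validation

`make_fold_plan()` draws an r-replicated k-fold partition once, and
`run_paired_cv()` evaluates *every* model on exactly those folds. The
fold-level accuracy difference $d_f = r_{A,f} - r_{B,f}$ then has variance
$\operatorname{Var}(d) = 2\sigma^2_f(1-\rho)$ when the two models' fold
scores share variance $\sigma^2_f$ and correlate at $\rho$; at $\rho = 0.8$
this is a fivefold reduction against the unpaired $2\sigma^2_f$, with the
corresponding gain in power (`power_paired_vs_unpaired()` gives the analytic
noncentral-t curves; `sim_fold_scores()` generates correlated fold scores to
check them by simulation). The pairing is enforced structurally: if any
model fails on a fold (for example, a zero-variance test fold), that fold is
excluded for all models, because silently unbalancing the pairing would
invalidate the variance argument.

Accuracy is the fold-level Pearson correlation between predictions and
observations — invariant to scaling or shifting the predictions, which
affect MSE but not selection rankings. MSE is recorded alongside. The
overall accuracy reported for a model is the unweighted mean of fold
accuracies: fold scores are the unit of the paired analysis, so their mean
(rather than a pooled-prediction correlation) is the natural summary; fold
differences from different replicates are pooled as exchangeable. A
conservative alternative — collapsing each replicate to its mean and using
r − 1 degrees of freedom — can be obtained by summarising per replicate
before calling `paired_stat()`; fold overlap across replicates makes the
pooled version mildly liberal, which users should weigh when r is large.

Phenotype-scale accuracy $r_{ph}$ understates what breeders care about:
accuracy on true genetic values is $r_{ph}/\sqrt{h^2}$
(`rescale_by_heritability()`, which insists on one common heritability
estimate per trait — in this package, REML on the full data with the
additive GRM — because mixing estimates would change model rankings).
Going one step further, under truncation selection of the top fraction $q$
the expected genetic gain in phenotypic standard deviations is
$\Delta G/\sigma_P = i_q\, r_{ph}$ with $i_q$ the selection intensity
(`selection_intensity()`, the mean of the upper-$q$ truncated standard
normal). The map is linear, so paired differences transform by the same
factor — a scale on which an equivalence margin is a domain judgment about
foregone genetic gain.

## Equivalence margins and the four tests

A margin $[-\Delta, \Delta]$ declares which differences are practically
irrelevant. `gpcv` never supplies a default $\Delta$: it is a judgment about
the application (for example, "less than 0.01 phenotypic SD of expected gain
per cycle"), not a statistical constant. Given a margin, `run_tests()`
tests four nulls about the mean difference:

* `sd` — $H_0: d = 0$ (conventional two-sided test);
* `eq` — $H_0: |d| > \Delta$ (equivalence, two one-sided tests);
* `noi` — $H_0: d < -\Delta$ (non-inferiority);
* `sup` — $H_0: d < \Delta$ (superiority).

All four use the same t machinery on the fold differences: `sd` at level
$\alpha$, and the margin tests via the two-sided $(1-2\alpha)$ confidence
interval — equivalence when the interval lies inside $(-\Delta, \Delta)$,
non-inferiority when its lower bound exceeds $-\Delta$, superiority when its
lower bound exceeds $\Delta$. This TOST-via-interval construction is what
guarantees the coherence properties (superiority implies non-inferiority;
equivalence excludes superiority for $\Delta > 0$) that the test suite
verifies by exhaustive grid enumeration. A zero margin makes the equivalence
test undecidable; it is reported as not rejected, with a warning.

For reporting, the default interval attached to a `paired_stat` is a
nonparametric bootstrap percentile interval of the mean fold difference
(resampling folds with replacement, `bootstrap_ci()`), with the t interval
available via `ci = "t"`. The two can disagree slightly at small fold
counts — percentile intervals are somewhat narrow below ~20 folds — which is
why test *decisions* always use the t construction while the bootstrap
interval is descriptive.

## Letters and rankings

Pairwise outcomes across m models are condensed by `compare_models()` into
three label systems:

* **Equivalence letters** — an undirected graph joins two models when their
  equivalence null was rejected; one letter is assigned per maximal clique
  (via igraph), and a model's label is the set of letters of its cliques.
  Sharing a letter therefore *means* pairwise demonstrated equivalence —
  unlike conventional significance letters, which only record a failure to
  detect a difference. Conventional letters are also produced (lowercase,
  from the complement of the `sd` rejection graph) because readers expect
  them.
* **Superiority and non-inferiority rankings** — a digraph with an edge from
  the inferior to the superior model wherever the directed null was
  rejected. The ranking is the consensus of all topological orders,
  computed as ordinal$(v) = 1 +$ length of the longest directed path ending
  at $v$: a model outranks another only when a chain of rejections forces
  it, and models incomparable in every topological order share an ordinal.
  A cyclic rejection pattern is reported as an inconsistency error with the
  offending models; with the coherent interval construction above,
  superiority cycles cannot arise from one dataset. Non-inferiority is a
  weaker relation that routinely holds in both directions (the pair is then
  inside the margin); mutual rejections carry no ordering information, so
  only asymmetric non-inferiority rejections contribute edges. This
  longest-path operationalisation of "consensus ordering" is a design
  choice; any construction consistent with all topological orders yields
  the same layering on the patterns exercised in the tests.

No multiple-testing correction is applied across model pairs by default —
margin-based conclusions are reported per pair, as is usual in equivalence
testing; `compare_models(bonferroni = TRUE)` divides $\alpha$ by the number
of pairs for users who want family-wise control.

Across many prediction tasks (traits × datasets × panel densities),
`summarize_tasks()` reports the fraction of tasks on which each null was
rejected, and `report_tasks()` prints the per-task star matrix with the
proportion rows. A bundled example grid (`gain_task_outcomes()`, a published
multi-species Gaussian-kernel-vs-G-BLUP comparison on the gain scale) shows
the typical pattern: equivalence rejections rise from under 10% of tasks at
low marker density to half at high density, consistent with part of the
apparent epistatic advantage being a low-density artefact.

## Model fitting internals

**REML.** With one kernel, the restricted likelihood is profiled on the
spectrum of the kernel restricted to the orthogonal complement of the fixed
design (error contrasts), leaving a one-dimensional maximisation over the
log variance ratio (bounded search over $e^{\pm 25}$, tolerance 1e-10, with
the boundary values checked so $\hat h^2 = 0$ is attainable). Working in an
explicit orthonormal complement — rather than eigendecomposing the projected
kernel — matters for rank-deficient kernels, whose null space would
otherwise mix with the intercept direction and bias the profile. The
decomposition can be cached on the kernel (`cache_eigen()`) so that many
traits fitted against one kernel pay for a single decomposition. With
several kernels, REML is maximised numerically over log variance components
(Nelder-Mead with a restart, reltol 1e-12); the log parameterisation
enforces nonnegativity. The reported $\hat h^2$ weights each component by
its kernel's mean diagonal — the genetic variance on the observation
scale — making it invariant to the arbitrary kernel constant.

**Gibbs sampling.** The Bayesian-alphabet sampler (compiled, single pass
over markers per iteration with residual updates) uses standard conjugate
full conditionals; the scaled-inverse-$\chi^2$ convention is
$\sigma^2 \sim S/\chi^2_\nu$ (prior mode $S/(\nu+2)$), so the conjugate
update is $(S + SS)/\chi^2_{\nu+m}$. Prior scales are elicited from a
target $R^2_{geno}$ — the proportion of phenotypic variance the markers are
a priori expected to explain: $S = \mathrm{var}(y)\,R^2_{geno}/MS_x\,
(\nu+2)$ with $MS_x$ the summed variance of centered marker columns,
inflated by $1/(1-\pi)$ for spike-slab families so the expected genomic
variance is preserved. Defaults: $R^2_{geno} = 0.5$, $\nu = 5$, $\pi = 0.5$
(fixed, not sampled — it is treated as a tunable hyper-parameter), chains of
12,000 iterations with 2,000 burn-in and thinning 5. A fixed-variance test
mode freezes both variances, in which the BRR posterior mean has the exact
ridge form $(X'X + \lambda I)^{-1}X'y$, $\lambda = \sigma^2_e/\sigma^2_\beta$
— the oracle used to validate the sampler, with Monte-Carlo error assessed
by batch means. The classic identity linking the two families — ridge
predictions with $G = WW'/c$ and $\sigma^2_u = c\,\sigma^2_\beta$ equal
kernel-BLUP predictions exactly — is verified to 1e-6 on a 200×500 panel.

Missing phenotypes are excluded from training, never imputed. Cross
validation slices full-data kernels (`kernel_slice()`) rather than
rebuilding them per fold: rebuilding would change the centering constants
and silently break the train/test geometry.

**Numerical conventions.** Kernels are accepted as PSD when the smallest
eigenvalue is ≥ −1e−8 times the largest; the Gaussian kernel uses a
*negative* exponent, $K_{ij} = \exp(-D_{ij}/h)$ — similarity must decay
with distance for the matrix to be a valid covariance — with the default
multi-kernel bandwidth grid at the 0.2/0.5/0.8 quantiles of the
off-diagonal distances (a spread wide enough to let REML weight local
against global similarity when no single bandwidth is obviously right).
Scaling constants: $G$ divided by $2\sum_j p_j(1-p_j)$ (unit average
diagonal at Hardy-Weinberg proportions), $C_m$ averaged over markers,
$C_e$ exactly $\tfrac12(C_m \odot C_m + C_m)$, Gaussian kernels with
constant 1; scale equivariance makes these choices immaterial to accuracy.
Dosage matching for $C_m$ is exact integer equality (genotypes as
categories, including heterozygotes).

## The synthetic-data generator

`sim_genotypes()` draws per-marker allele frequencies uniformly in a MAF
band and dosages as two independent allele draws at Hardy-Weinberg
proportions, independently across markers. `sim_phenotypes()` builds the
genetic value from standard-normal effects on frequency-centered dosages at
uniformly placed QTL, plus effects on products of centered dosage pairs for
the epistatic share, each component rescaled to its exact target variance
share, with normal noise filling the remainder. The generator deliberately
omits linkage disequilibrium, population structure, dominance and
genotype-by-environment interaction. Two consequences matter for
interpreting test results. First, passing tests demonstrate correctness of
the machinery under a clean exchangeable architecture, not performance on
structured breeding populations. Second, some real-data phenomena invert:
with unrelated lines and independent markers, the Hadamard-square kernel
$G \odot G$ is nearly diagonal (its off-diagonal entries are squares of
already-small relationships) and EG-BLUP captures almost no between-line
signal even for a genuinely epistatic trait — whereas on real panels much
of EG-BLUP's apparent advantage rides on LD and relatedness. The Gaussian
kernel, which spans interaction terms through its exponential expansion,
does recover purely epistatic signal here.

## Problem sizes and demonstration designs

The validation suite uses problem sizes chosen to make each statistical
check sharp at desk scale: the variance-reduction and correlation checks
use 10⁴ simulated fold pairs; heritability recovery uses 50 model-true
traits on a 1000×500 panel (one cached decomposition, three heritability
levels, per-level mean $\hat h^2$ within 0.05 of truth); the
sampler-vs-ridge check runs 50,000 iterations; test calibration uses 2000
null replicates. The epistatic demonstration — a Gaussian kernel shown
*superior* to G-BLUP at margin Δ = 0.01 in a 2×5-fold paired CV — uses a
400-line, 50-marker panel with 50 interacting pairs at $h^2_{epi} = 0.8$:
a deliberately low-dimensional panel, because the pairwise-product feature
space (~p²/2 dimensions) must be learnable from ~320 training lines for
*any* method to expose the contrast; at several hundred markers both models
sit near zero accuracy and the comparison is uninformative.

## Known limitations

Random fold assignment only: partitions by generation, family or
sub-population — appropriate when predictions will cross those boundaries —
are out of scope, as are leave-one-out schemes (suited to conditional
rather than marginal accuracy), multi-trait models, dominance kernels and
$\pi$-learning for BayesB/C. Fold differences pooled across replicates
slightly understate the variance of the mean difference when r is large
(training-set overlap); the replicate-collapsed summary above is the
conservative alternative. The bootstrap percentile interval is descriptive,
not the decision rule. Equivalence letters can proliferate when the
equivalence graph is sparse but not empty — every maximal clique gets a
letter — which is faithful to the construction but visually busy for large
model rosters.
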