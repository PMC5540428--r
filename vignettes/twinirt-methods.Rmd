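---
title: "Methods: nonparametric IRT scale validation and twin modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonparametric IRT scale validation and twin modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinirt)
```

`twinirt` implements a complete validation pipeline for short polytomous
mental-health questionnaires administered in twin-family cohorts: kernel-based
nonparametric item response theory (NIRT) for item screening and latent
scoring, classical psychometrics, twin variance-component models, and
kinship-aware association of the resulting scores with binary diagnoses. This
vignette records the models, the tunable parameters and their defaults, the
numerical choices, and the design decisions taken where the methodology left
room — so that a reader can judge exactly what the package computes and what
its passing test suite does and does not establish.

## The measurement model

Each item $j$ has three ordered response categories $X_j \in \{0, 1, 2\}$
("sometimes/never", "often", "most of the time"). The nonparametric graded
response model only assumes that the two *item response step functions*

$$S_{j x}(\theta) = P(X_j \ge x \mid \theta), \qquad x \in \{1, 2\}$$

are nondecreasing in the latent trait $\theta$ (monotonicity), together with
unidimensionality and conditional independence. No logistic or other
parametric shape is imposed; the step functions are estimated by kernel
regression.

**Latent-trait assignment.** Respondents with complete responses on the scale
are ranked by their sum score; rank $r$ of $N$ maps to
$\theta = \Phi^{-1}((r - 0.5)/N)$. Ties are ubiquitous with 0/1/2 items, so
they are broken by a seeded uniform jitter keyed to `person_id`: the
assignment is reproducible and invariant to row order. This rank metric is
what licenses inference — with more than five items, fewer than five
categories and similarly shaped step functions, the sum score stochastically
orders respondents on the latent trait.

**Kernel estimation.** At each of $Q$ grid points the option curves are
Nadaraya–Watson estimates with a Gaussian kernel,
$\hat p_{jk}(\theta_q) \propto \sum_i K((\theta_q - \theta_i)/h)\,1[x_{ij} = k]$,
and the step functions are their upper cumulative sums. Pointwise 95% bands
use the kernel-weighted binomial approximation
$\hat p \pm 1.96\sqrt{\hat p (1 - \hat p)/n_\mathrm{eff}}$ with
$n_\mathrm{eff} = (\sum_i w_i)^2 / \sum_i w_i^2$; this is deterministic and
fast, and is the input to every band-based decision rule below. A bootstrap
would widen the bands slightly at the grid extremes but would make the
screening protocol stochastic.

Defaults, chosen once: a grid of 51 equally spaced points on $[-3, 3]$ (the
extent makes a respondent who endorses nothing score exactly $-3$, the
boundary value such data sets report), and the classic kernel-IRT bandwidth
$h = 1.1\,N^{-1/5}$ (about $0.28$ at $N = 2000$). Both are overridable.

**Scoring.** The maximum-likelihood score is the grid argmax of
$\sum_j \log \max(\hat p_{j,x_{ij}}(\theta_q), 10^{-6})$; the probability
floor prevents $-\infty$ from smoothing zeros, and ties resolve to the lowest
tied grid point so the all-zero respondent lands on the boundary
deterministically. Item difficulty and discrimination are read off a
centered, unscaled PCA of the items × grid matrix of expected scores; the
first component is oriented so higher = easier, the second so higher = more
discriminant.

## Item screening

`refine_scale()` iterates: fit curves on the current scale, exclude — in one
batch — every item flagged non-monotone, low-endorsement or empty-category,
refit, repeat until clean; then test candidate items singly for admission.
Batch exclusion is deliberate: a flag can be an artifact of poorly correlated
co-items distorting the latent ranking, so the flags are re-evaluated after
each batch rather than trusted item by item.

**Monotonicity** flags a step function that decreases by more than
$\delta = 0.05$ over a run of at least two consecutive decreasing grid steps
*within the central 95% of the latent density* ($[-1.96, 1.96]$) — decreases
confined to the extreme tails affect almost nobody and are only reported —
and additionally requires the decrease to be unambiguous given the pointwise
bands (the run's starting estimate must exceed the end's upper confidence
limit). Without the band condition, kernel noise at $n \approx 1200$
false-flags clean items in roughly one replicate in ten.

**Endorsement** flags an item whose first step function visibly plateaus
below 1: the upper 95% band must fail to reach 0.95 anywhere over the top of
the grid ($\theta \ge 2.5$). Two numerical points matter here. First, the
check uses a *rest-score* ranking (the scale sum excluding the item itself):
ranking by the full sum conditions an item on itself — the top-ranked
respondents have, by construction, endorsed nearly everything, which drags
the top of every estimated curve towards 1 and completely masks genuine
ceilings (we observed items with a true ceiling of 0.3 estimated at 0.94 at
the grid top under full-sum ranking). Monotonicity, by contrast, stays on the
full-sum curves, which are smoother; a genuine dip survives the ranking.
Second, the band is taken as its maximum over the whole top region rather
than at the single endpoint, where the effective sample size is a handful of
respondents.

**Admission** requires a candidate, added singly to the refined scale, to
raise no flag and to be discriminant enough to add information: its
expected-score curve's total variation must exceed the lower quartile of the
scale items'. Total variation is used rather than the raw second
principal-component coordinate because PC2 can be dominated by curve-shape
contrasts and misorder items with clearly different slopes. Candidates
belonging to a sibling scale are refused outright, so shared items cannot
artificially inflate the correlation between two scores.

**Differential item functioning.** Groups (sexes, or each wave against a
benchmark wave) are compared on a common metric: the pooled sample is ranked
once, then curves are fitted per group. The DIF statistic is the
standard-normal-density-weighted root-mean-square distance between the two
groups' step functions (the mean-absolute variant is available as an option;
the density weighting reflects that differences where respondents actually
sit matter most). An item is excluded when its larger per-step DIF exceeds
0.25 *and* the groups' 95% bands are disjoint over a contiguous region
carrying at least 10% of the latent mass — the magnitude threshold encodes
"one group 25% more likely to report the symptom at equal severity", and the
band rule operationalizes "significant as indicated by the confidence
intervals", which the source methodology states only informally.

## The synthetic cohort

No participant data are distributable, so the generator *is* the study
population for every test. It emulates: MZ and DZ twin pairs with an optional
third sibling and singletons; one or two latent traits with an exact A/C/E
variance decomposition (MZ co-twins share A fully; every other sib pair
correlates 0.5 through a mid-parental construction; C is shared by all
children of a family); cross-trait component correlations $r_G$, $r_C$,
$r_E$; sex and age shifts applied after standardization; graded-response
items; a retest administration with
$\theta' = \rho\theta + \sqrt{1-\rho^2}\,\varepsilon$; and binary diagnoses
from a logistic model with a kinship-structured random effect. A single
master seed expands into labelled sub-streams (`substream_seed`), so each
stage is independently reproducible.

Defaults follow the study design the package models: 226 MZ pairs, 408 DZ
pairs, extra-sibling probability 0.13, 28 singletons (the 8–12-year cohort
composition); heritabilities 0.27–0.51 across traits and ages with
$r_G = 0.87$, $r_E = 0.44$ at the youngest bin; retest reliability 0.47; a
diagnosis at ~16% prevalence with an odds ratio of 1.39 per latent-trait
unit. The generating item parameters are nowhere published, so the default
bank was calibrated once from the analytic model and frozen: thresholds
$b_1 \in [0.4, 1.8]$ with discriminations 1.2–2.9 give a zero-score mass of
about 20% for a 14-item scale (population screeners of this kind report
15–25%) while every clean item's first step function reaches $\ge 0.97$ at
$\theta = 3$, clearing the endorsement rule with margin. The pathological
bank makes each failure mode unambiguous at desk sample sizes: dips of depth
0.6 and width 0.6 centered at $\theta = 1$ on easy, discriminating items (a
bump on a hard item is clipped away and a bump where the scale carries no
information is invisible after rank smoothing); ceilings of 0.25 reached
early; an empty top category; threshold shifts of 1.0 for sex-DIF. The
diagnosis generator's polygenic variance defaults to 0.3 — modest familial
clustering consistent with moderate liability heritability; no published
value exists.

What the generator does *not* emulate: item-level missingness beyond optional
MCAR masking, multidimensional traits, age-varying item parameters, and
informative retest attrition. Passing tests therefore certify the estimators
and decision rules under a faithful unidimensional graded-response world, not
robustness to structured missingness or trait drift in real cohorts.

## Classical psychometrics

Cronbach's alpha uses the standard variance-ratio formula on complete cases
(listwise deletion; the data this mirrors had at most 0.6% missingness per
item). Polytomous Loevinger coefficients divide observed inter-item
covariances by their maximum given the marginals — the covariance of the
comonotone (sorted-marginals) coupling — with item and scale coefficients as
ratio aggregates and Mokken classes at the conventional 0.3/0.4/0.5 cutoffs
on $\min_i H_i$; an exhaustive small-sample oracle ships in the test suite.
Test-retest reliability is the two-way consistency ICC — $(MS_R - MS_E)/
(MS_R + MS_E)$ for two occasions — which deliberately ignores systematic
occasion shifts; its 95% CI uses the F-distribution method (the bracket
method was not named in the source, and the F method is the textbook choice
for consistency ICCs). Winsorisation clips at mean ± 3 SD of the *input*
moments; it is not idempotent by construction and is not claimed to be. Sex
differences in scores are tested by a Gaussian mixed model with a pedigree
relatedness covariance (profile ML over the variance ratio, Wald t with
$n - \mathrm{rank}(X)$ degrees of freedom); with an identity relatedness this
reduces exactly to the OLS t-test.

## Pedigree handling

The additive relatedness matrix is expected (pedigree) relatedness: 1 for MZ
co-twins, 0.5 for all other sib pairs, block-diagonal by family — realized
genotype-based relatedness is out of scope for pedigree-only data. Familial
pruning draws one member per family 1000 times and keeps the draw minimizing
$|\Delta\bar{\mathrm{age}}|/\mathrm{sd} + |\mathrm{var\ ratio} - 1| +
|\Delta f_\mathrm{female}|$ — an unweighted sum, since the matching criteria
are named but no composite metric is published; the weights are exposed in
code. Cross-wave selection assigns persons observed in both waves
preferentially to the smaller wave and keeps the most balanced of 100
iterations. Age bins are half-open, left-closed: $[9,13)$, $[13,15)$,
$[15,17)$, $[17,28]$ — where the source's table header ("8 to 12") conflicts
with its methods text ("9 to <13"), the methods wording wins, and ages
outside $[9, 28]$ are dropped with a warning. Family size is restricted to
the twin pair plus one seeded-random extra sibling.

## Twin variance-component models

Univariate ACE/ADE/AE/CE/E models are fitted by full-information maximum
likelihood: each family contributes the multivariate-normal log density of
its *observed* members, with pairwise covariance
$k_A a^2 + c^2$ (ACE) or $k_A a^2 + k_D d^2$ (ADE), $k_A \in \{1, 0.5\}$ and
$k_D \in \{1, 0.25\}$; C carries no finer structure than "shared by all
children" because the design statement gives none. Families with identical
covariance structure are grouped so the likelihood costs a handful of small
Cholesky factorizations per evaluation. Optimization is over unbounded path
coefficients (variances are squares, so non-negativity is automatic and the
sign is resolved to non-negative by convention) with five seeded multi-starts
under BFGS; a non-positive-definite implied covariance returns $-\infty$ and
is simply rejected. Confidence intervals on the standardized proportions are
profile-likelihood based (the brackets such studies print are asymmetric;
delta-method intervals are not). Nested models are compared by LRT with the
naive $\chi^2$ reference, matching common twin-literature practice; the 50:50
boundary mixture correction is available as an option. The omnibus
homogeneity test compares group-specific (zygosity × role) means and
variances against fully equated ones, with within-family covariances free per
pair type in both models so the test is calibrated under relatedness; the
degrees of freedom are reported from the actual parameter count, since the
parameterization that yields exactly 20 df in the source is not specified.
The sex-limitation check LRTs sex-specific A/E paths (opposite-sex pairs
covary through $0.5\,a_F a_M$) against equal paths.

The bivariate model is a Cholesky parameterization per component
($\Sigma_A = L_A L_A^\top$, likewise E and optionally C), giving
$r_G = \Sigma_A[1,2]/\sqrt{\Sigma_A[1,1]\Sigma_A[2,2]}$ and the exact
decomposition $r_\mathrm{phen} = r_G\sqrt{a^2_1 a^2_2} +
r_E\sqrt{e^2_1 e^2_2}$ (+ C term), which the tests verify to $10^{-6}$.
Boundary hypotheses are tested by constrained refits: $r_G = 0$ fixes the
cross path $a_{21} = 0$, $r_G = 1$ fixes $a_{22} = 0$, $r_E = 1$ fixes
$e_{22} = 0$. A constrained $\Sigma_E$ of rank 1 makes an MZ pair's implied
covariance exactly singular, so a ridge of $10^{-8}$ on the diagonal keeps
those boundary refits finitely evaluable; on non-degenerate data the
resulting LRT correctly rejects.

## Kinship-aware logistic association

Binary diagnoses are regressed on scale scores with sex, ages and wave
dummies as covariates and a polygenic random effect
$u \sim N(0, \sigma_g^2 K)$, fitted by penalized quasi-likelihood: iterate
the working linearization of the logit, re-estimate $\sigma_g^2$ each cycle
by maximizing the Gaussian likelihood of the working response (a
one-dimensional profile search over the block-diagonal family structure), and
update the fixed and random effects from the mixed-model equations. PQL is
the quasi-likelihood approach such analyses use; its known attenuation of
$|\beta|$ for binary outcomes with modest cluster sizes is documented here
deliberately — the odds-ratio recovery experiment below lands about 0.03–0.05
below the generating value of 1.39, well inside the experiment's tolerance.
Inference is a Wald t-test with $n - \mathrm{rank}(X)$ degrees of freedom
("Student's t" is all the source states). Non-convergence within 100 cycles
and separation ($|\hat\beta| > 15$) are flagged, never silently accepted.

Multiplicity: the effective number of independent scores uses the Li–Ji
eigenvalue estimator $n_p = \sum_i (1[\lambda_i \ge 1] + (\lambda_i -
\lfloor\lambda_i\rfloor))$ on the pairwise-complete correlation matrix (the
source cites two eigenvalue methods without choosing; Nyholt's is available
behind a flag), and the familywise threshold is $0.05/(n_p \cdot
n_\mathrm{outcomes})$ — $0.05/24 \approx 2.1\times10^{-3}$ at $n_p = 6$ with
four diagnoses.

## Validation experiments and problem sizes

The `experiment_*` functions re-run the pipeline at the published design
points; the acceptance script (`scripts/acceptance.R`) reports their means.
Sizes are chosen to estimate each quantity stably at desk scale: 20
replicates for the heritability (8–12-year composition, generating
$a^2 = 0.41$), bivariate ($600$ twin+sibling families, $r_G = 0.87$,
$r_E = 0.44$) and odds-ratio (~2000 persons, OR 1.39) recoveries; 200
replicates of the 52-pair retest design for the ICC; 50 null comparisons for
the DIF false-positive rate; 200 null replicates for the type-I error of the
kinship logistic model; 20 refinement runs at $n = 1200$ for the screening
protocol's operating characteristics. The test suite runs the same
experiments at these sizes. Recovery experiments fit the simulated trait
values directly: they measure the estimators at the published generating
values, uncontaminated by measurement error, which is the comparison the
recovery tolerances describe.

## Known limitations

* The latent metric is the rank-normal metric of the analyzed sample; scores
  from different samples are comparable only through the shared item curves,
  not as absolute values.
* Kernel curves at the grid extremes rest on a handful of respondents;
  decision rules mitigate this (top-region maxima, band conditions), but
  extreme-tail features of single items should not be over-read.
* Full-sum ranking biases an item's own curve upward at the top; the package
  uses rest-score ranking inside the endorsement check, but exported curve
  fits are full-sum by default and inherit the effect.
* PQL attenuates logistic effects; for strong effects or tiny prevalence a
  full-likelihood mixed model would be preferable.
* The twin machinery covers twin/sibling/singleton families only — no
  parents, no arbitrary pedigrees — and never fits C and D simultaneously,
  which a twin-only design cannot identify.
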