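---
title: "Methods: polytomous Rasch calibration, category diagnostics, and penalized DIF detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polytomous Rasch calibration, category diagnostics, and penalized DIF detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmdif)
```

`pcmdif` implements an item-level psychometric pipeline for short ordinal
rating scales, built around the 15-item Childhood Autism Rating Scale
(first edition, "CARS"): each item is rated 1–4 by a clinician, the total
(15–60) quantifies autistic symptom severity, and the substantive questions
are (i) whether the rating categories function, (ii) whether one latent
severity dimension accounts for the responses, and (iii) whether items behave
differently across demographic groups at equal severity (differential item
functioning, DIF).

This vignette records the models, conventions and numerical choices, so that
every number the package produces is auditable.

## The Partial Credit Model and its calibration

For person $p$ with severity $\theta_p$ (logits) and item $i$ with step
difficulties $\delta_{i1},\dots,\delta_{im_i}$, the Partial Credit Model
(PCM) sets the adjacent-category log-odds to

$$\log\frac{P(X_{pi}=h)}{P(X_{pi}=h-1)} = \theta_p - \delta_{ih},
\qquad h = 1,\dots,m_i,$$

equivalently $P(X_{pi}=h) \propto \exp\sum_{k\le h}(\theta_p-\delta_{ik})$
with the empty sum equal to 0. The $\delta_{ih}$ are Andrich thresholds: the
latent locations where categories $h-1$ and $h$ are equally probable.
Raw categories 1–4 are coded 0–3 internally; all reported tables convert
back to the 1–4 labels. Raw categories that attract no responses are
structurally dropped and the remaining ones renumbered (recorded in the
fit's `category_map`).

`fit_pcm()` maximizes the joint (unconditional) likelihood: alternating
damped Newton updates of all $\theta_p$ and all $\delta_{ih}$, with
step-halving so the joint log-likelihood never decreases, until the largest
absolute parameter change falls below 0.005 logits (tighter than the
2-decimal reporting precision) or 200 iterations. Identification: the mean
item difficulty (the mean of each item's steps, averaged over items) is
re-centred to 0 every iteration. Raw total score is sufficient for
$\theta$, so persons with equal totals on complete data receive equal
measures, and internal computations collapse to the distinct total scores.
Standard errors come from the inverse observed information
($1/\sqrt{\sum_i W_{pi}}$ for persons; the inverse step-information matrix
per item).

**Extreme scores.** All-minimum and all-maximum persons carry no information
about item parameters and have infinite ML measures; they are excluded from
item estimation, then scored against the anchored items after moving their
raw total 0.3 score points inside the boundary, and flagged.

**Finite-test bias.** Joint ML with a fixed number of items is inconsistent:
the incidental person parameters inflate the logit spread of the item
estimates by roughly $I/(I-1)$ for an $I$-item test — about +7–10% here —
and the bias does not shrink as $n$ grows (we verified the theoretical
factor on dichotomous simulations at $n = 20{,}000$). The package therefore
applies the standard correction by default (`bias_correction` in
`run_config()`): centred step difficulties are shrunk by $(I-1)/I$ and
person measures re-solved against the corrected items. Without it, step
recovery stalls at an RMSE floor of roughly $0.1\times$ the generating
spread no matter how many persons are sampled; with it, full-size
simulations recover steps to well under 0.1 logits. The correction is a
deliberate departure from leaving joint-ML output raw, and can be switched
off for strict comparability with uncorrected programs.

## Category diagnostics and rescoring

A functioning 4-point category structure should satisfy three published
conventions, all configurable in `run_config()`:

* every category attracts at least 10 responses (`min_count`);
* thresholds increase with category (no disorder);
* adjacent thresholds are between 1.4 and 5 logits apart
  (`interval_bounds`) — closer and the middle category never usefully
  dominates; wider and one category swallows people of very different
  severity.

The interval bounds are conventions from the applied rating-scale
literature, not derivable quantities; they are configuration, not policy.
`rescore_collapse()` merges each sparse category into an adjacent one — top
merges downward, bottom upward, interior into the smaller neighbour with
ties toward the lower category (the merge direction is our choice; the
practice of collapsing is standard, its direction rarely stated). The map is
total and order-preserving and never increases the number of thresholds.
DIF analysis (below) consumes rescored data, mirroring standard practice of
eliminating under-used options first.

## Fit statistics, separation, reliability

With $E_{pi}$, $W_{pi}$, $C_{pi}$ the conditional mean, variance and fourth
central moment of a response, residuals are $y = x - E$ and standardized
residuals $z = y/\sqrt W$. Per item (and symmetrically per person):

* outfit MNSQ $= \frac1N\sum z^2$ (unweighted, outlier-sensitive);
* infit MNSQ $= \sum y^2 / \sum W$ (information-weighted);
* standardized values via the Wilson–Hilferty cube-root transform
  $Z = (M^{1/3}-1)\,(3/q) + q/3$ with model variance
  $q^2_{\text{outfit}} = [\sum C/W^2 - N]/N^2$ and
  $q^2_{\text{infit}} = \sum(C - W^2)/(\sum W)^2$, reported capped at
  $\pm 9.9$ as conventional.

Acceptance bands default to MNSQ 0.75–1.33 and $|Z| \le 2$. Two behaviours
of these statistics are worth knowing. First, joint ML consumes one degree
of freedom per person, so under the model the mean item mean-square sits
near $(I-1)/I \approx 0.93$, not exactly 1. Second, at several thousand
persons the standardized form detects that small systematic deviation with
high power — so large-sample $Z$ values flag trivial misfit, which is why
the published convention also bounds the mean squares themselves. Our null
property test therefore checks the $\le 10\%$ flag rate at calibration-sized
samples (a few hundred persons, the conventional 250–500 calibration band),
and the full-size check asserts the mean item infit stays in $[0.9, 1.1]$.

Separation and reliability: $RMSE = \sqrt{\mathrm{mean}(SE^2)}$,
true SD $= \sqrt{\max(0, SD_{obs}^2 - RMSE^2)}$, separation
$G = SD_{true}/RMSE$ and reliability $R = G^2/(1+G^2)$ (so $G = 2.57$ gives
$R = 0.87$, and $1 - R$ is the error share of observed variance).
`wright_map()` prints the joint person–item logit axis as fixed-width text.

## Unidimensionality: PCA of standardized residuals

If one dimension drives the responses, the standardized residuals should be
unstructured. `residual_pca()` computes the item-by-item pairwise-complete
correlation matrix of $z$, its eigen-decomposition ("contrasts", in item
units summing to the item count $L$), and the variance decomposition in
eigenvalue units:

$$V_m = L\cdot\frac{\sum_{pi}(E_{pi}-\bar x_i)^2}{\sum_{pi}(x_{pi}-E_{pi})^2},
\qquad
\text{measures\%} = \frac{V_m}{V_m+L},\qquad
\text{contrast}_k\% = \frac{\lambda_k}{V_m+L}.$$

The decomposition convention (modelled scores about item means over residual
sum of squares) is chosen because it reproduces the standard printed
arithmetic of the field's dominant program — e.g. a measure variance of
18.08 units with $L=15$ gives 54.7% explained by measures and a 2.27-unit
first contrast 6.9% — and percentages add to 100 by construction. The
conventional support for unidimensionality is measures% above 40 with the
first contrast eigenvalue below 2 ("less than two items' worth of shared
residual structure"). Loadings at or above 0.4 in absolute value (an
admittedly arbitrary screen) list the items driving a contrast; the second
contrast is screened whenever its eigenvalue reaches 1.8.

Note that measures% is a property of the population as much as of the scale:
it grows with the ratio of person-severity variance to conditional response
noise. The default synthetic population (ability SD 1 against thresholds
spanning ±5 logits) yields measures% near 30; clinical samples whose
severity range matches the item range yield 50%+ — our property test uses
such a population (ability SD 2) when asserting the >40% convention, and the
narrow-population behaviour is expected, not a defect.

## Uniform DIF: lasso-penalized Generalized Partial Credit Model

The DIF model adds an item discrimination $\beta_i$ and a group-specific
difficulty shift:

$$\log\frac{P(Y_{pi}=r)}{P(Y_{pi}=r-1)} =
\beta_i\left(\theta_p - \delta_{ir} - x_p^\top\gamma_i\right),$$

with $x_p$ the reference-coded dummy vector (female; kindergarten, primary,
junior-high; non-autism, severe — the predominant groups male, infant,
mild-to-moderate are the reference and the dummy columns match the
conventional reporting layout). A nonzero $\gamma_{in}$ shifts every step of
item $i$ by $\gamma_{in}$ logits for members of group $n$ — uniform DIF; the
group's item difficulty is the baseline plus $\gamma$. Ability is integrated
out against $\theta \sim N(0, \sigma^2)$ with fixed-node Gauss–Hermite
quadrature (21 nodes by default, configurable), and the penalized criterion

$$\max_{\beta,\delta,\gamma}\;
\ell(\beta,\delta,\gamma) - \lambda\sum_{i,n}|\gamma_{in}|$$

is solved by proximal gradient: smooth gradient steps on $\log\beta$,
$\delta$ (and optionally $\log\sigma$) with backtracking line search, and a
soft-threshold proximal step on $\gamma$ — so zero coefficients are exactly
zero, not small floats. Convergence: relative objective change below 1e-7.
The C++ likelihood kernel exploits that the three covariates span at most
$2\times4\times3 = 24$ distinct dummy patterns, so category probabilities
are computed per (item, pattern, node) regardless of sample size; the
analytic gradient is verified against numerical differentiation and the
quadrature against adaptive integration in the test suite.

**Identification.** In this model $(\beta,\delta,\gamma,\sigma) \mapsto
(\beta/c,\, c\delta,\, c\gamma,\, c\sigma)$ leaves the likelihood invariant,
so the ability SD and free discriminations cannot both be estimated. The
package fixes $\sigma = 1$ and estimates $\beta_i$ on the log scale by
default; `est_beta = FALSE, est_sigma = TRUE` gives the complementary
identification (used internally to check that the marginal estimator
reduces to the joint-ML PCM estimates when the penalty saturates).

**Path and selection.** $\lambda_{max}$ is the largest absolute
$\gamma$-gradient at the no-DIF fit (the Karush–Kuhn–Tucker bound), and the
grid is 50 log-spaced values (configurable) down to $\lambda_{max}/1000$,
warm-started downward. Each model's BIC is $-2\ell + df\log n$ with $df$
the number of nonzero free parameters; the BIC minimizer among converged
fits is selected, and an item is flagged for uniform DIF when any of its
six coefficients is nonzero there. `welch_dif_baseline()` provides the
classical per-item two-group Welch test the penalized model improves upon
(it handles all covariates jointly and shrinks spurious effects to zero).

Non-uniform DIF (group-by-ability interaction) is out of scope by design.

## Scale-level comparisons

`group_comparison()` supplies the conventional companion analysis on total
scores: a Welch unequal-variance t test by gender and a one-way ANOVA
across age groups with Bonferroni-adjusted pairwise pooled-variance t tests
(p times the number of pairs, capped at 1; $N-k$ degrees of freedom). All
tests are two-sided at $\alpha = 0.05$ and are also computable directly
from published (n, mean, SD) summaries, since raw clinical data are often
unavailable.

## The synthetic population: what it emulates and what it does not

No response-level data for the reference study are deposited, so
`design_table1()` fixes a fully stated generating world against which every
pipeline stage is testable:

* **Margins, exact.** 3,348 persons; 2,673 male / 675 female; age groups
  1,416 / 1,506 / 406 / 20 (infant, kindergarten, primary, junior high);
  severity classes 1,635 / 1,114 / 599 (mild-to-moderate, non-autism,
  severe). Covariate levels are assigned by seeded permutation of fixed
  level vectors, not sampled, so the margins are reproduced exactly at the
  default size and by largest-remainder scaling otherwise. The junior-high
  stratum of 20 persons is deliberately kept despite its instability — it
  is a real feature of such referral samples.
* **Items.** Discrimination 1 (a pure PCM). Item locations follow the
  instrument's reported difficulty hierarchy (hardest: adaptation to
  environmental change, +1.53; easiest: consistency of intellectual
  response, −3.89), with common relative steps −3.4 / 0 / +3.4 logits, so
  extreme categories of extreme items attract few responses — reproducing
  the sparse top categories seen in referred samples.
* **Persons.** Ability $\sim N(-1.33, 1)$: the mean is the reported
  person–item offset for this population and yields the instrument's
  typical mean total near 31.7; the SD of 1 is a neutral default (group
  mean shifts default to 0 and are configurable via `ability_shift`).
* **DIF.** An items × dummies matrix of uniform shifts, default zero;
  planted values flow through the same adjacent-categories model the
  detector assumes.

Deliberately not emulated: rater effects and rater disagreement, local
item dependence, non-uniform DIF, missing data mechanisms, and any
correlation between the demographic covariates and ability (independent by
default). A green simulation test therefore establishes internal
correctness of estimation and detection under the stated model — not that
real clinical CARS data satisfy the model.

## Numerical choices, degenerate inputs, limitations

* PCM probabilities use row-wise max-shifted exponentials; probabilities
  and moments match brute-force enumeration to 1e-12.
* JML convergence 0.005 logits / 200 iterations; person-side Newton steps
  clipped to ±1 logit; log-likelihood monotone via step halving.
* Items with fewer than two observed categories, datasets with fewer than
  two non-extreme persons, and collapsing below two categories are errors;
  non-convergence is a flag, not an exception.
* Zero residual variance excludes an item from the residual correlation
  with a warning; zero residual sum of squares makes the variance
  decomposition degenerate and errors.
* Separation is 0 (flagged `degenerate`) when error variance exceeds
  observed variance.
* The DIF optimizer's backtracking guarantees descent of the penalized
  objective; per-$\lambda$ non-convergence excludes that model from BIC
  selection.
* Quadrature with 15–21 nodes is accurate to ~1e-3 in log-likelihood for
  these designs; raise `n_quad` for abilities far outside ±4 SD.
* Known limitations: joint-ML bias correction is the simple multiplicative
  factor (adequate for moderate steps, approximate for extreme ones);
  standardized fit statistics at several-thousand samples flag trivially
  small systematic misfit; the lasso shrinks selected nonzero coefficients
  toward zero, so flagged effects are detected, not unbiasedly estimated —
  refit at a small penalty for magnitudes.
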