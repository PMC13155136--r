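---
title: "Power-law modeling of limiting dilution assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-law modeling of limiting dilution assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powerlda)
```

## The model

A limiting dilution assay (LDA) seeds a geometric series of expected cell
numbers $S$ into $n$ replicate wells and scores each well as showing
clonogenic growth or not. Writing $\mu$ for the probability that a well
*fails* to grow, the number of negative wells at a dilution step is
binomial, $Y \sim \mathrm{Bin}(n, \mu)$.

The classical single-hit Poisson model assumes every seeded cell founds a
colony independently with probability $p$, so the number of active cells
per well is Poisson with mean $\lambda = p\,S$ and
$\mu = P(X = 0) = e^{-pS}$. Colony formation at limiting dilution is,
however, strongly modulated by neighboring cells and their secreted
factors: cells may *cooperate* (clonogenicity per cell rises with density)
or *compete*. powerlda therefore generalizes the mean activity to a power
law,

$$\lambda = p\,S^{b}, \qquad
  \ln(-\ln \mu) = \alpha + b \ln S, \qquad \alpha = \ln p ,$$

where $b$ is the nonlinearity coefficient: $b = 1$ recovers the linear
model, $b > 1$ indicates cooperation and $0 < b < 1$ competition. On the
link scale this is a binomial regression of the failure fraction with a
log–log link and covariate $\ln S$, and the whole analysis inherits the
standard GLM toolbox: likelihood, Fisher information, deviance, nested
tests.

Assumptions worth keeping in mind:

* wells at one dilution step are exchangeable and independent given $S$;
* every well receives the same *expected* cell number (no seeding noise);
* a single dispersion-free binomial law holds per step — inter-replicate
  heterogeneity beyond binomial noise is **not** modeled (see
  "Replicates" below).

## Estimation

`fit_loglog_glm()` maximizes the exact binomial likelihood

$$\ell(\alpha, b) = \sum_i \log\binom{n_i}{Y_i}
  + Y_i \log \mu_i + (n_i - Y_i)\log(1 - \mu_i),
  \qquad \mu_i = e^{-e^{\alpha + b\ln S_i}},$$

by Fisher scoring with step-halving. Convergence requires the score norm
to fall below $10^{-8}$ on the link scale within 100 iterations — ample
for these small, well-conditioned problems. Counts at the boundary
($Y_i = 0$ or $Y_i = n_i$) enter the likelihood as they are; no
continuity correction is applied. Fitted failure probabilities are clamped
to $[10^{-12}, 1-10^{-12}]$ purely to keep logarithms finite.

The reported covariance of $(\hat\alpha, \hat b)$ is the inverse
**expected** Fisher information at the optimum. Observed and expected
information differ for a non-canonical link such as this one; the expected
form is what iteratively reweighted least squares (and hence `stats::glm`)
reports, and its interval coverage is verified by simulation in the test
suite (95% nominal, observed within ±3% at the default study size).

Two degenerate inputs get explicit treatment:

* **all wells negative everywhere** — there is no evidence of clonogenic
  growth at all and no finite maximizer; estimation is *refused* with a
  classed error (batch tables report the group with a `refused_reason`
  instead of dropping it);
* **all wells positive everywhere** — the likelihood climbs toward a
  parameter-space boundary; the fit is returned flagged
  `converged = FALSE` with a warning rather than pretending a point
  estimate.

The fixed-slope variant (`slope_fixed = TRUE`) holds $b = 1$ and refits
$\alpha$ only; it is the linear comparator for `compare_models()`, which
performs the likelihood-ratio test on the deviance difference
($\chi^2_1$) and reports $\Delta\mathrm{AIC}$.

## Clonogenic activity and its interval

The clonogenic activity

$$a = e^{-\alpha/b} = p^{-1/b}$$

is the number of cells to seed so that on average one clonogenic cell
arises per well ($\lambda = 1$), i.e. a fraction $e^{-1} \approx 37\%$ of
wells stay negative. Only under linearity ($b = 1$) does $1/a$ equal a
per-cell frequency; under cooperation or competition the frequency
language is misleading, which is why the convenience readout
`capacity_percent = 100 / a` is documented as frequency-interpretable only
near $b = 1$.

The default interval (`method = "band_inversion"`) inverts the link-scale
confidence band: the bounds are the seeding densities at which the band
around $\hat\eta(x) = \hat\alpha + \hat b x$ ($x = \ln S$) crosses zero.
They solve the Fieller-type quadratic

$$(\hat\alpha + \hat b x)^2 = z^2\big(\mathrm{Var}(\hat\alpha)
  + 2x\,\mathrm{Cov}(\hat\alpha,\hat b) + x^2 \mathrm{Var}(\hat b)\big).$$

The confidence set is $\{x : g(x) \le 0\}$ with $g$ the difference of the
two sides; since $g(\ln \hat a) < 0$ it always contains the estimate. The
case analysis follows the sign of the leading coefficient
$A = \hat b^2 - z^2\mathrm{Var}(\hat b)$:

* $A > 0$: the set is the finite interval between the two roots — the
  usual case;
* $A \le 0$ (the slope is not significantly distinct from zero): the band
  fails to re-cross the 37% line on one side or both, and the affected
  bound is reported as $0$ or $\infty$ with a warning. Geometrically the
  set is a ray (roots both on one side of $\ln\hat a$) or the whole line.

The closed form is exact and fast; a numeric root scan of the band edges
is kept in the test suite as an independent oracle. `method = "delta"`
offers first-order error propagation on $\ln a$,
$\mathrm{Var}(\ln \hat a) = \mathrm{Var}(\hat\alpha)/\hat b^2 +
\hat\alpha^2\mathrm{Var}(\hat b)/\hat b^4 -
2\hat\alpha\,\mathrm{Cov}(\hat\alpha,\hat b)/\hat b^3$; the two methods
agree to within about 2% per bound once wells per dilution reach the
thousands.

## Survival fractions and replicates

The survival fraction of a treated group is the ratio of cell numbers
needed for the same reference activity,

$$\mathrm{SF} = \frac{a_0}{a_t}
  = e^{\alpha_t/b_t - \alpha_0/b_0},$$

with $(\alpha_0, b_0)$ from the untreated reference. Its 95% interval is
assembled from the **83.5%** band-inversion intervals of the two
activities as $(a_{0,\mathrm{lb}}/a_{t,\mathrm{ub}},\;
a_{0,\mathrm{ub}}/a_{t,\mathrm{lb}})$: crossing the component bounds of a
ratio at 83.5% each yields close to 95% joint coverage, which the test
suite confirms by simulation (500 runs, true SF = 0.5, coverage within
±3% of nominal). Both levels are named configuration constants.

Biological replicates are handled in two explicit modes — there is no
automatic switch, because the choice is a judgment about inter-replicate
variability:

* **pooled** — well counts are summed per dilution step across replicates
  before fitting (dilution steps matched on `cells_per_well` rounded to 6
  decimals: dilution series are specified values, not measurements;
  mismatched series raise an error listing the offending values).
  Appropriate when replicate scatter is within the intrinsic binomial
  noise of well counts.
* **per_replicate** — activities and SFs are computed inside each
  replicate against that replicate's own reference, then summarized by
  mean and standard error; the 95% CI uses a Student-$t$ quantile on
  $r - 1$ degrees of freedom, the defensible choice at the 3–4 replicates
  typical of these assays.

`binomial_expectation_range()` quantifies the intrinsic noise to guide
that judgment: for 12 wells failing with probability $1/3$ the central
95% range is 1–7 negative wells, i.e. roughly $-2.5$ to $-0.5$ on the
$\ln\mu$ scale — replicate scatter inside such a band carries no evidence
of extra-binomial variability.

## The simulator

`simulate_lda()` draws data from exactly the generative chain the model
assumes: $\mu = e^{-p_t S^b}$ per dilution, $Y \sim \mathrm{Bin}(n, \mu)$,
with treatment $t$ scaling the activity parameter as $p_t = p\,\mathrm{sf}^b$
so that the generative survival fraction is exact for any $b$. Defaults —
$p = 0.1$, $b = 1$, dilution ladder $2^0 \dots 2^7$, 12 wells per step —
mirror a standard 96-well, eight-step assay in which roughly half the
ladder is informative. The random stream order is fixed (treatment-major,
then replicate, then dilution) so a seed reproduces an experiment
bit-exactly; the session RNG state is restored afterwards. The latent
Poisson colony count is never materialized since $\mu$ depends on
$\lambda$ alone.

What the simulator deliberately does **not** emulate — and hence what
green tests do *not* establish about wet-lab data: Poisson noise in the
number of cells actually seeded, spatial plate and edge-well effects,
medium-volume covariates, inter-replicate heterogeneity and the resulting
overdispersion. Modeling that overdispersion would require a different
likelihood (e.g. beta-binomial or mixed effects) and is out of scope.

`design_grid()` repeats simulate–fit–summarize over a grid of wells per
dilution and dilution-ladder lengths and reports mean CI widths for the
activity and the SF; precision improves monotonically in wells per
dilution, quantifying the return on technical replication.

## Numerical and design choices, problem sizes

* Input tables may report positive or negative wells; the canonical
  internal response is the failure count, on which the likelihood is
  written.
* `cells_per_well` is a positive real, not an integer: fractional expected
  seeding densities (e.g. $2^{-3}$ cells per well) are legitimate designs.
* Validation is strict and names the offending row; pooling conserves
  total well and failure counts by construction.
* The validation studies run by the tests and the acceptance script use
  deliberately desk-scale sizes: 200 simulated experiments for parameter
  recovery and coverage, 1000 for the size of the likelihood-ratio test,
  500 for SF-interval coverage, 8 dilutions at 12–96 wells. These sizes
  give Monte-Carlo standard errors comfortably inside the asserted
  tolerances.

## Known limitations

* The maximum-likelihood estimate of $b$ is biased upward in small
  samples: at 12 wells per dilution on the default ladder the mean
  $\hat b$ at a true $b = 1.5$ is about 1.7–1.8, falling within 0.05 of
  the truth only from roughly 48 wells per dilution upward. Interval
  coverage is nonetheless close to nominal at 12 wells. Studies that
  interpret the *magnitude* of $b$ (not just its direction) should use
  generous well counts or pool replicates.
* Wald-type machinery underlies both interval methods; at very sparse
  designs (few informative dilutions) the band-inversion interval can
  legitimately become one-sided unbounded.
* No overdispersion parameter: if replicate scatter clearly exceeds the
  binomial expectation range, analyze replicates separately rather than
  pooling — the pooled intervals would be too narrow.
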