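---
title: "Estimating nest abundance from repeated drone flyovers"
author: "nestcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nest abundance from repeated drone flyovers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestcr)
```

## The problem

Counting the nests of colonial waterbirds from stitched drone imagery looks
like a census, but it is not: on any one flyover a substantial fraction of
active nests is invisible. A bird may be away foraging, the nest may be
hidden by branches or washed out by luminosity, the bird on it may be
indistinguishable from a co-occurring look-alike species, the image
interpreter may simply miss it, or the nest may fall outside the stitched
panorama altogether. A raw count from one image therefore underestimates the
colony, and by an amount that changes with time of day, season and site, so
raw counts are not comparable across surveys.

`nestcr` treats repeated flyovers of a colony within a short, demographically
closed session as a closed-population capture–recapture study. Each flyover
is a capture occasion; each nest detected at least once gets a binary capture
history (e.g. `101` over three flyovers). The closed models estimate the
per-flyover detection probability $p$ and, from it, the number of nests never
detected at all, giving an abundance estimate with a confidence interval
instead of an uncounted minimum.

## The model

For colony $g$ observed over $T$ occasions, let $n_g$ be the number of nests
detected at least once and $x_{t,g}$ the number detected on occasion $t$.
The model parameterizes the expected number of never-detected nests
$f_{0,g} \ge 0$ on a log link and the detection probabilities on a logit
link, with $N_g = n_g + f_{0,g}$. The full (unconditional) log-likelihood is

$$
\ell = \sum_g \Big[ \ln\Gamma(N_g+1) - \ln\Gamma(f_{0,g}+1)
 + \sum_{t=1}^{T} \big( x_{t,g}\ln p_{t,g} + (N_g - x_{t,g})\ln(1-p_{t,g}) \big) \Big],
$$

with $f_0$ treated as continuous through the gamma function, as in standard
closed-model software, so the surface is smooth and a quasi-Newton optimizer
applies. The model set mirrors standard closed-captures practice for a
multi-colony survey and contains exactly four members:

| model | $p$ structure | colonies |
|---|---|---|
| `p(.)` | constant | equal $p$ |
| `p(.)+colony` | constant | additive logit offset per colony |
| `p(t)` | one $p$ per flyover | equal $p$ |
| `p(t)+colony` | one $p$ per flyover | additive logit offset per colony |

$f_0$ is always colony-specific, so each colony gets its own abundance
estimate under every model. `rank_models()` fits all four and sorts by
$\mathrm{AIC} = -2\ell + 2K$; AIC (not AICc) is the default selection score,
with ties broken by smaller $K$ and then by the canonical order above.
Behavioural-response and individual-heterogeneity models are deliberately
absent: nests are fixed objects that cannot become trap-shy, and the
generator (below) makes the independence assumption exact, so the four-model
set is the intended scope.

Confidence intervals: for $p$, a delta-method interval on the logit scale,
back-transformed, which keeps bounds inside $(0,1)$. For $N$, the standard
closed-captures lognormal interval on $f_0$:
$C = \exp\{z\sqrt{\ln(1 + \mathrm{cv}(f_0)^2)}\}$ with
$\mathrm{cv}(f_0) = \mathrm{SE}(f_0)/f_0$, giving
$[\,n_g + f_{0,g}/C,\; n_g + f_{0,g}\,C\,]$. The lower bound can never fall
below the number of nests actually seen, and a colony whose every nest was
detected gets the degenerate interval $[n_g, n_g]$ — the behaviour a small,
fully-detected colony should produce.

`huggins_fit()` implements the conditional-likelihood alternative (the
likelihood of the observed nests given detection at least once, followed by
a Horvitz–Thompson estimate $\hat N_g = n_g / \hat p^*_g$). It is kept as an
independent cross-check of the full-likelihood route — the two must agree
asymptotically — not as the default estimator.

## Synthetic colonies

`simulate_colony()` generates the latent detection process explicitly rather
than drawing detections from a single Bernoulli rate. At each (nest,
occasion) cell five stages are drawn in sequence, and detection requires all
of them to succeed:

1. **cut** — the nest is lost when the flyover's photos are stitched
   (probability `cut_prob`, redrawn per occasion because each flyover is
   assembled separately);
2. **absence** — no bird is present on the nest (`1 - presence_prob`, which
   may vary by occasion to mimic diurnal attendance; see
   `diurnal_presence()` for a Gaussian-dip profile with a late-morning
   minimum);
3. **occlusion** — the nest is unavailable in the image (luminosity,
   branches; `1 - availability_prob`);
4. **misidentification** — the bird is not distinguishable from the
   look-alike species (`1 - identify_prob`);
5. **observer miss** — the interpreter overlooks it (`1 - observer_prob`).

The implied per-occasion detection probability is the stage product
$p_t = (1-c)\,\pi_t\,a\,q\,o$, and every non-detection carries exactly one
cause label: the first failed stage in the fixed order above. That
first-failed-stage convention mirrors how single causes are assigned when
images are reviewed by hand, and it makes the cause mix analytic
(`analytic_cause_props()`), so the generator can be verified against closed
forms rather than against itself. `calibrate_cause_config()` inverts the
relationship: given a target $p$ and a target cause mix, it solves the stage
probabilities sequentially. The shipped default mix (5% cut, 20% absence,
33% occlusion, 31% misidentification, 11% observer miss, at $p = 0.60$) is
a realistic profile for canopy-breeding colonies surveyed by drone, where
occlusion and misidentification dominate.

Two deliberate design choices. Occlusion is redrawn per occasion by
default, which makes detections independent across flyovers — exactly the
closed models' assumption — so estimator checks are not confounded by
generator heterogeneity. A `persistent_occlusion` switch (off by default)
draws availability once per nest instead, for probing the negative bias
that chronically hidden nests induce. Second, `extract_dataset()` applies
the field definition of the data: only nests detected at least once enter
the capture table, while the true colony size is returned alongside for
recovery checks.

`select_peak_session()` encodes the session-selection rule used with
multi-session campaigns: analyse the session whose single best flyover
counted the most nests (the reproduction peak), ties to the earliest.

## Survey design by simulation

How many flyovers are enough? `power_grid()` answers the question the way a
monitoring program would ask it. For each cell of a (number of flyovers
$T$) × (colony size $N$) grid it simulates `n_sim` surveys with i.i.d.
Bernoulli($p$) detections, drops never-detected nests, fits the constant
one-colony closed model, and summarizes:

* **mean CV** — the mean over converged replicates of
  $\mathrm{SE}(\hat N)/\hat N$. The phrase "mean cv of the abundance
  estimates" is ambiguous between this and the empirical
  $\mathrm{SD}(\hat N)/\mathrm{mean}(\hat N)$ across replicates; both are
  implemented in `mean_cv()`, and the per-replicate form is the default
  because it is what a practitioner obtains from a single real survey, and
  the two converge for an unbiased estimator.
* **decline power** — for each decline $d$ on a grid (default 1–20%), the
  proportion of replicates whose 95% abundance interval excludes
  $N(1-d/100)$. The default exclusion rule is one-sided in the decline
  direction (interval lower bound above the declined value); a two-sided
  option exists, and on the default grid the two rules give identical
  results because the upper-bound exclusion never binds at these declines.
* **minimum detectable decline** — the smallest grid decline with power at
  least 0.80, or `NA` ("none within the grid").

Defaults follow the canonical design question for drone-surveyed heron
colonies: $p = 0.60$, $T \in \{2,\dots,5\}$, $N \in \{50, 100, 150, 200\}$,
100 replicates per cell. The declined value is compared against the true
generating $N$: the question asked is whether the design could distinguish
the current population from one $d\%$ smaller, not whether a second
declined population was estimated.

Replicates whose fit fails (possible in principle at $T = 2$ where boundary
likelihoods arise) are flagged and excluded from summaries rather than
propagating `NaN`; `n_converged` reports how many survived, and a cell with
more than half failed is flagged.

A note on what the mean CV can and cannot be. At $T = 2$, $N = 50$,
$p = 0.60$ the Fisher information of the constant closed model fixes the
achievable precision at $\mathrm{cv} \approx 0.094$
($\mathrm{Var}(\hat N) = N\,[q^{-T} - Tp/q - 1]^{-1}$ with $q = 1 - p$);
the package's simulations agree with this closed form and with the
empirical spread across replicates. Larger CVs reported for comparable
designs elsewhere would imply either a lower effective $p$ or inflated
standard errors; the package reports the information-bound value.

## Numerical choices

* Optimization is multi-start BFGS with analytic gradients. The first
  start is moment-based (pooled detection frequency; implied $f_0$), the
  remaining `n_starts - 1` (default 2 more) jitter it with seeded standard
  normal noise on the link scales.
* Boundary handling: the $f_0 = 0$ boundary is approached only
  geometrically along $\log f_0$, so after BFGS the fitter pins
  near-boundary coordinates at numerical zero, re-optimizes, and runs a
  1-D Brent profile pass per colony followed by a restart — this recovers
  both boundary suprema and the very shallow interior optima (order
  $10^{-6}$ log-likelihood) that a line search can step across. On tiny
  datasets the maximized log-likelihood is verified in the test suite
  against a brute-force $(p, f_0)$ grid to within $10^{-6}$.
* $\hat f_0 < 10^{-6}$ is reported as the boundary value 0 with a
  degenerate interval; $\hat p > 1 - 10^{-6}$ as a saturated occasion.
  Logit predictors are capped at $\pm 35$ and cell probabilities clamped to
  $[10^{-12}, 1-10^{-12}]$, keeping the objective finite for any finite
  parameter vector.
* The variance–covariance matrix comes from the numerical Hessian at the
  optimum, inverted on the block of free (non-boundary) coordinates: a
  colony at the $f_0$ boundary contributes a flat direction that would
  otherwise make the full Hessian singular and poison every colony's
  standard error.
* Convergence is declared from the optimizer's status, backed by an
  analytic-gradient check with a scale-aware tolerance; `converged = FALSE`
  still returns the best point found.
* All randomness descends from one root seed through deterministic
  substreams (`replicate_fits()`, `power_grid()`, `cmd_simulate()`), so any
  single replicate or grid cell can be reproduced in isolation and
  identical configurations give bit-identical results.

## Problem sizes used in the tests

The test suite exercises the estimator at the scales the methods are meant
for while staying quick to run: grid-oracle comparisons use 50 random
datasets of up to 10 nests and 3 occasions; parameter recovery uses 500
replicates at $N = 150$, $T = 3$, $p = 0.6$ (mean $\hat p$ within 0.02,
interval coverage inside [0.91, 0.98]); generator calibration tabulates
over 5000 non-detection events; the design grid runs the full
$4 \times 4 \times 100$ configuration. These sizes were chosen as the
smallest at which the asymptotic checks are meaningful.

## Limitations

* The generator emulates the statistical structure of the detection
  process, not its physics: no spatial nest layout, no image synthesis, no
  correlated occlusion between neighbouring nests, and look-alike species
  enter only through a misidentification probability. Passing recovery
  tests on generated data therefore demonstrates estimator correctness
  under the stated assumptions, not robustness to every field violation of
  them.
* All colonies in one dataset must share the same number of occasions; a
  session with a deviating flyover count must be analysed separately.
* Open-population dynamics, robust designs across sessions, spatial
  capture–recapture and misidentification-aware CR models are out of scope.
* At $T = 2$ the constant model is exactly identified, intervals lean
  heavily on asymptotics, and precision is poor — which is, in fact, the
  design conclusion the power grid is built to expose.
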