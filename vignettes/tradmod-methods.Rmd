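---
title: "Methods: psychometric simulation, covariance-structure estimation and market dynamics in tradmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: psychometric simulation, covariance-structure estimation and market dynamics in tradmod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tradmod)
```

`tradmod` studies a consumer-psychology system in which purchase intention
(PI) for traditional-medicine functional foods is pulled in opposite
directions by cultural identity (CI) and by a categorical
"medicine-vs-food" schema, medicine-food separation cognition (MFSC), with
attitude (ATT) and perceived price (PP) completing the predictor set and
purchase behavior (PB) downstream of intention. The original questionnaire
data are not deposited, so the package is built around a synthetic-survey
generator that reproduces the published statistical structure; every later
stage (measurement diagnostics, SEM, relative importance, the agent-based
market model) is exercised and tested against that generator.

This vignette records the models, the parameter choices, and the design
decisions that were genuinely open, so a maintainer can see why the code is
the way it is.

## 1. The synthetic survey generator

### What it emulates

A `population_spec` holds, for nine constructs (CI, MFSC, ATT, PP, PI, PB,
plus food neophobia FN, health literacy HL, and a method-marker construct
MK):

* the published inter-construct correlations (discriminant-validity tables),
* per-construct standardized loadings chosen as the square root of the
  published AVE (so that AVE is reproduced by construction),
* the urban/rural mix (54.6% urban) and four age-group proportions
  (21.8 / 45.1 / 24.9 / 8.2%),
* a standardized urban-context effect on MFSC of 0.26,
* reverse-keyed items (all three MFSC items; the first FN item), generated
  in reversed orientation and un-reversed at scoring time.

Construct means are mostly unpublished; only the PI composite mean (3.73)
and SD (1.07) are anchored. The other defaults (CI 3.8, MFSC 3.0, ATT 3.7,
PP 3.2, PB 3.1, FN 2.9, HL 3.5, SD 1.0) are plausible mid-scale values for
a consumer sample of this kind and are configurable; nothing downstream is
calibrated against them.

### Two generating regimes

The published tables are mutually inconsistent: the structural coefficients
combined with the printed correlations imply an explained variance for PI
near 0.87 rather than the printed 0.65, and attitude's single predictor
(0.41) cannot produce the printed R² of 0.44. No single generator can match
both the correlation tables and the path table, so the generator offers two
regimes:

* **`model-generated`** (default): exogenous constructs are drawn with the
  published exogenous correlations, and the endogenous constructs are built
  from the structural equations (ATT = 0.41 CI + disturbance; PI = 0.34 CI
  − 0.29 MFSC + 0.44 ATT − 0.27 PP + disturbance; PB = 0.59 PI +
  disturbance; MFSC = 0.26 urban + disturbance, with the MFSC disturbance
  carrying the published MFSC correlations with CI and PP). Refitting the
  structural model to these data recovers the published coefficients; this
  regime backs the parameter-recovery experiments.
* **`corr-matched`**: the latent correlation matrix is calibrated so that
  the *composite* correlations of the discretized items reproduce the
  published tables; this regime backs the measurement and
  relative-importance checks.

### Likert discretization and attenuation calibration

Items are built as `loading × latent z + sqrt(1 − loading²) × noise` and
cut at fixed thresholds into categories 1-5. Thresholds default to the
equal-probability quintile cuts of the standard normal (±0.8416, ±0.2533):
symmetric and parameter-free. A per-construct mean offset is solved (by
`uniroot`) so the expected item mean equals the requested construct mean —
this is what anchors the PI composite at 3.73 without any post-hoc tuning.

Discretization attenuates correlations, and the attenuation is not a single
scalar: writing the step function of the cut in the Hermite polynomial
basis, the covariance of two discretized items with continuous correlation
ρ is `Σ a_n² ρⁿ/n!`, where the coefficients `a_n` depend only on the
threshold positions relative to the construct's mean offset. The generator
uses this expansion (truncated at n = 12, error < 1e-6) in three places:

1. *generating loadings* are solved so that the observed inter-item
   correlations equal the product of the requested standardized loadings —
   hence observed AVE/CR/alpha match the requested reliability structure;
2. in the `corr-matched` regime each latent pair correlation is solved so
   the discretized-composite correlation equals its published target;
3. in the `model-generated` regime each latent pair correlation is solved
   so the correlation recovered *through the factor structure* of the
   discretized items equals the structurally implied one — this removes
   the small (≈0.01-0.03) bias that raw discretization would otherwise
   leave in refitted structural coefficients, and keeps the likelihood-ratio
   statistic essentially central.

The urban shift of MFSC is applied as `0.26/sd(dummy)` added to urban
respondents' latent MFSC (mean-centred), with the Gaussian residual
variance reduced so the marginal moments still match the generating matrix
exactly. The literal reading "shift by effect × SD" would give a
standardized dummy coefficient of about 0.13, half the published 0.26, so
the standardized-coefficient reading is used.

### What the generator does **not** emulate

Response styles (acquiescence, straightlining), missing data, item-specific
method variance, non-normal latent distributions, and any real sampling
design. Tests passing on these data show the *machinery* is correct under
the assumed structure; they say nothing about real consumers.

## 2. Measurement diagnostics

Cronbach's alpha uses raw covariances by default (a standardized option
exists). CR and AVE are the usual functions of standardized loadings; when
estimated from data, one-factor loadings come from the centroid method
(exact under a single common factor, stable at k = 2). Harman's
single-factor share is operationalized as the largest eigenvalue of the
item correlation matrix over the number of items — the most common,
deterministic reading, since no extraction method is published. The
discriminant report replaces the diagonal with √AVE and labels its
correlations as unit-weighted composite correlations, because whether the
published tables are latent or composite correlations is not stated.
Reverse-keyed items are un-reversed before every computation.

## 3. The covariance-structure engine

The model is the standard linear structural system: latent regressions
`η = Bη + Γξ + ζ` and measurement equations `y = Λη + ε`, implemented in an
all-latent form with implied covariance
`Σ(θ) = Λ (I−B)⁻¹ Ψ (I−B)⁻ᵀ Λᵀ + Θ` and, when a mean structure is on,
`μ(θ) = ν + Λ(I−B)⁻¹α`. Estimation minimizes the maximum-likelihood
discrepancy `F = log|Σ| − log|S| + tr(SΣ⁻¹) − p` (plus the mean term), with
`χ² = (n−1)F`.

Numerical choices:

* variances are log-parameterized (positive by construction; a Heywood
  tendency shows up as a variance collapsing toward zero and is flagged);
* gradients are analytic for every matrix block (audited against central
  finite differences in the tests); optimization is quasi-Newton
  (`nlminb`), with optional random multi-starts (`n_starts`) for
  ill-conditioned problems such as the common-latent-factor model;
* standard errors come from the numeric Hessian of the analytic gradient;
* identification fixes the first loading per latent to 1 (or the latent
  variance, with `std_lv`); a single-indicator latent (the urban dummy) is
  fixed at loading 1 with zero measurement error;
* the CFI/TLI baseline is the independence model with free variances (and
  saturated means), the convention of the commercial software the published
  tables came from.

The published t-values are not reproducible — they are inconsistent with
the printed confidence intervals — so t statistics are reported but not
held to any target.

Multi-group estimation minimizes the pooled discrepancy
`Σ_g (n_g−1)/(N−G) F_g` with equality constraints expressed by shared
parameter labels: configural (none), metric (loadings), scalar (loadings +
intercepts, latent means free in non-reference groups). The invariance
sequence applies the |ΔCFI| ≤ 0.01 rule; the configural level is judged by
its own CFI (cutoff 0.90). Invariance is tested on the measurement (CFA)
model, the standard practice. The common-latent-factor check adds one
orthogonal factor with a single shared loading on all indicators; note that
when trait loadings are nearly equal across items this decomposition is
close to unidentified — a known weakness of the technique, visible in the
test design, which varies the trait loadings.

## 4. Relative importance (LMG)

LMG values are computed exactly by the subset-weight formula (up to 12
predictors; `R²` per subset from the correlation-matrix identity), and the
test suite carries an independent brute-force oracle that averages over all
orderings. Input can be a correlation matrix, raw scores, or a survey
(unit-weighted composites, the conventional choice). The published shares
(42.8/28.1/16.5/12.6%) were computed on data we do not have; the pipeline
report prints computed and published shares side by side without asserting
equality, because the two generating regimes cannot reproduce both the
correlation tables and the printed R² at once.

## 5. The agent-based market model

1,000 agents carry (CI, MFSC, ATT, PP) states on the 1-5 scale, initialized
from the population spec (or resampled from a survey), on a Barabási-Albert
network (attachment m = 3, giving hubs — the published topology choice).
Each of 100 synchronous steps:

1. PI is the standardized linear combination of the agent's state z-scores
   (published coefficients 0.34, −0.29, 0.44, −0.27) plus Gaussian noise
   (σ = 0.3 z-units), destandardized by the anchors (mean 3.73, SD 1.07)
   and clipped to [1, 5]. Applying standardized coefficients to raw 1-5
   scores cannot produce the published PI level, so destandardization via
   the published anchors is the minimal consistent reading.
2. Purchase occurs when PI exceeds a stochastic threshold drawn per
   agent-step from N(3.4, 0.5²) — unpublished, chosen mid-scale so baseline
   purchase rates are interior rather than saturated.
3. CI increases by τ times the aggregate of positive neighbour gaps (only
   neighbours with higher CI exert influence). The default aggregation is
   the mean over all neighbours: the literal sum overshoots the maximum
   neighbour gap for hub agents at any realistic τ; `sum` mode is retained
   for fidelity experiments. Both modes clip to [1, 5].

Because influence is upward-gated, per-agent CI is non-decreasing (a
ratchet) and the population drifts toward the ceiling; the rate is governed
by τ. This has two consequences worth stating plainly:

* **The published calibration pattern is not reachable at τ = 0.05.** With
  z-scores anchored at the initial distribution, 100 steps of diffusion at
  τ = 0.05 raise mean CI by roughly a full scale point, which lifts the
  final-window mean PI to about 4.0 and collapses its SD to about 0.73 —
  outside the stated pattern (≈3.7, ≈1.1). The package's own
  pattern-oriented calibration (`calibrate_tau`) therefore selects the
  smallest grid value (τ = 0.01), where drift over 100 steps is mildest.
  The corresponding acceptance check is left failing rather than adjusted,
  and the simulator reports its own honest baseline.
* **Two uplift metrics are needed.** For the targeted CI intervention
  (+0.1 to the 26-55 age groups at t = 0), `uplift_vs_control` compares
  paired runs with identical seeds and isolates the intervention (zero at
  zero dose, monotone in the dose, but *decreasing* in τ because both arms
  saturate at the ceiling), while `uplift_vs_baseline` compares the treated
  run's final window with the pre-intervention level (the published
  "3.20 → 3.83" framing) and *increases* with τ, reproducing the published
  sensitivity ordering. The sensitivity table reports both; each
  qualitative contract is tested on the metric that expresses it.

Determinism: a run consumes a single RNG stream derived from its seed, so
identical parameters give bit-identical results and paired experiments
share networks, initial states and noise.

## 6. Problem sizes used by the tests

The acceptance-style experiments use the study's own sizes: 200 replicate
surveys of n = 1,076 for parameter recovery and for the MFSC-FN
correlation, 30 seeds of the full 1,000-agent / 100-step simulation for the
baseline pattern, and 10 independent networks for the topology-stability
check. Unit tests use smaller models and samples chosen so each statistical
assertion still has comfortable Monte-Carlo margin (e.g. n = 60,000 for a
±0.03 check on a group-mean difference whose sampling SE is below 0.01).

## 7. Known limitations

* Likert items are treated as continuous in ML estimation (the published
  analysis did the same); no ordinal (WLSMV) estimator, no robust
  corrections, no bootstrap intervals.
* The structural system must be recursive; no feedback loops.
* The generator's higher-moment structure is Gaussian-copula-like; only
  first and second moments (and the discretization mapping) are calibrated.
* The ABM's unpublished noise and threshold parameters make the published
  uplift magnitudes under-determined; only orderings and signs are treated
  as contracts.
* Exact LMG enumerates 2^k subsets; beyond 12 predictors a different
  algorithm would be needed.
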