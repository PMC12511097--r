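# tradmod

Psychometric modelling and market simulation for culturally embedded health
products.

## The problem

Consumer acceptance of traditional-medicine functional foods sits at a
tension between two mindsets: **cultural identity (CI)** — affinity for
traditional health philosophy — pulls purchase intention up, while
**medicine-food separation cognition (MFSC)** — the modern categorical
schema "medicine treats illness, food is for meals" — pushes it down, more
strongly in urban, digitally saturated environments. The standard empirical
arc for such questions is: validate the measurement instrument (reliability
and discriminant validity), fit a covariance-based structural equation
model (CB-SEM), decompose the explained variance of purchase intention into
predictor importances (relative importance analysis, RIA), and then embed
the validated coefficients as decision rules in an agent-based market model
(ABM) to explore interventions.

`tradmod` implements that whole arc as a tested, reusable R package for
quantitative consumer researchers and methodologists. Because the original
questionnaire data are not deposited, the package includes a
**synthetic-survey generator** that reproduces the published statistical
structure — inter-construct correlations, reliabilities, demographic mix,
the urban→MFSC effect, and the purchase-intention anchors (mean 3.73,
SD 1.07) — so every stage is verifiable offline.

## The models

**Measurement.** Cronbach's α; composite reliability
CR = (Σλ)² / ((Σλ)² + Σ(1−λ²)) and AVE = mean(λ²) from standardized
loadings λ; Fornell–Larcker discriminant matrix (diagonal √AVE); Harman
single-factor share; marker-variable check.

**CB-SEM.** Latent structure η = Bη + Γξ + ζ with measurement
y = Λη + ε; implied covariance Σ(θ) = Λ(I−B)⁻¹Ψ(I−B)⁻ᵀΛᵀ + Θ; maximum
likelihood F = log|Σ(θ)| − log|S| + tr(SΣ(θ)⁻¹) − p, χ² = (n−1)F; CFI,
TLI, RMSEA, SRMR against the independence baseline; multi-group estimation
and the configural → metric → scalar invariance sequence with the
|ΔCFI| ≤ 0.01 rule; a common-latent-factor method-bias check. The engine is
written in pure R with analytic gradients and log-parameterized variances.

**RIA.** Exact LMG (Shapley) decomposition:
LMG(x) = Σ_{S⊆P∖{x}} |S|!(k−|S|−1)!/k! · (R²(S∪{x}) − R²(S)),
computed by the subset-weight formula and verified in the tests against a
brute-force average over all orderings.

**ABM.** 1,000 agents on a Barabási–Albert network (m = 3); per step,
PI = anchors + Σβ·z(states) + noise (β from the structural model), purchase
when PI exceeds a stochastic threshold, and cultural identity diffuses
upward: CI_i ← CI_i + τ · mean⁺(CI_j − CI_i) over neighbours j with higher
CI. Pattern-oriented calibration of τ, targeted-intervention experiments
(+ΔCI to the 26–55 age groups) and a τ-sensitivity sweep.

## Worked example

```r
library(tradmod)

survey <- generate_survey(n = 1076, seed = 42)
survey
#> <survey_dataset> 1076 respondents, 26 items, 9 constructs
#>   constructs: CI, MFSC, ATT, PP, PI, PB, FN, HL, MK

head(reliability_report(survey), 3)
#>   construct items     alpha        CR       AVE
#> 1        CI     3 0.9029944 0.9031348 0.7566140
#> 2      MFSC     3 0.8853239 0.8853871 0.7203069
#> 3       ATT     3 0.9168260 0.9170144 0.7864991

fit <- fit_ml(sem_data(survey), default_sem_model())
fit
#> <sem_fit> chi-square = 160.02 df = 124  n = 1076
#> Structural paths (standardized):
#>    to from    est    std    se       t
#>   ATT   CI  0.424  0.428 0.032  13.296
#>    PI   CI  0.361  0.337 0.022  16.114
#>    PI MFSC -0.330 -0.321 0.021 -15.659
#>    PI  ATT  0.459  0.423 0.021  21.928
#>    PI   PP -0.247 -0.249 0.018 -13.584
#>    PB   PI  0.596  0.592 0.032  18.735
#>  MFSC  URB  0.525  0.221 0.076   6.947

lmg(survey, outcome = "PI", predictors = c("ATT", "CI", "MFSC", "PP"))
#> LMG decomposition of R^2 = 0.7859 for outcome PI
#>  predictor    lmg share
#>        ATT 0.2352  29.9
#>         CI 0.2356  30.0
#>       MFSC 0.1903  24.2
#>         PP 0.1249  15.9

sim <- run_simulation(simulation_params(tau = 0.05, seed = 42))
sim
#> <simulation_result> 100 steps, tau = 0.05
#>   final-20 mean PI = 3.925 (SD 0.748), mean CI = 4.643, purchase rate = 0.723
```

Reading the numbers: the survey reproduces the intended reliability
structure (AVE near the generating λ², e.g. 0.757 for CI against a target
of 0.778 up to sampling error); the SEM refit recovers the generating
standardized coefficients (0.41, 0.34, −0.29, 0.44, −0.27, 0.59, 0.26)
within sampling error of a single n = 1,076 draw, with χ² close to its 124
degrees of freedom; the LMG shares rank attitude and cultural identity as
the dominant predictors of purchase intention; and the simulation shows the
upward cultural-identity diffusion lifting mean CI while mean purchase
intention stabilizes near the top of its calibrated band (see the methods
vignette for why the final level sits above the 3.73 anchor at τ = 0.05).

`run_pipeline()` chains all five stages and `make_report()` prints the
computed values side by side with the published reference values, labelling
which comparisons are tested contracts and which are informational.

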