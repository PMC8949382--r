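---
title: "Methods: trajectory profiles of accelerometer-measured activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory profiles of accelerometer-measured activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the processing rules, the
synthetic-data design, and the numerical and design choices behind
`patraj`, in the spirit of a model-methods appendix. It states no empirical
result that the test suite does not itself compute.

## 1. The model

For subject $i$ with observation times $t_{i1},\dots,t_{in_i}$ (years) and
$K$ z-scored outcomes, conditional on latent class $g$:

$$ y_{ik} = X_i \beta_{kg} + X_i b_{ik} + \varepsilon_{ik}, \qquad
   X_i = (\mathbf{1}, t_i), \quad
   b_{ik} \sim N_2(0, D_k), \quad
   \varepsilon_{ik} \sim N(0, \sigma^2_k I), $$

with mixing probabilities $\pi_g$, correlated random intercept and slope per
outcome, outcomes conditionally independent given class and their own random
effects, and variance components ($D_k$, $\sigma^2_k$) common across
classes. The observed-data log-likelihood marginalises the random effects:

$$ \ell = \sum_i \log \sum_g \pi_g \prod_k
   \phi\!\left(y_{ik};\, X_i\beta_{kg},\; X_i D_k X_i^\top + \sigma^2_k I\right). $$

Missing waves contribute nothing (their rows are simply absent), which is
valid under missingness at random; the generator produces missing waves
completely at random, consistent with that.

**Why this concrete form.** The analysis this package reproduces names the
method ("latent class mixed model for multivariate longitudinal outcomes,
correlated random effects for time") without printing equations. We fixed
the smallest model consistent with that description: class-specific linear
time trends per outcome, outcome-specific correlated intercept+slope, and
common variance components. The reference R implementation of such models
also offers a shared latent-process formulation with outcome loadings;
whether the original analysis used it is not recoverable, so the separate-
outcome form is the default and the latent-process variant is left as an
extension point behind `lclmm_spec()`. Random effects common (not
class-specific) across classes is likewise the parsimonious default.

Time is coded in years (`wave_month / 12`) so slopes read as z-units per
year; z-scored outcomes make them unit-free.

The parameter count, used for AIC/BIC, is
$(G-1) + 2KG + 4K$: mixing, fixed effects, and per outcome three
random-effect covariance terms plus one residual variance. BIC uses the
number of subjects as $N$.

## 2. Estimation

EM treats both class labels and random effects as missing data. The E-step
yields posterior class probabilities $p_{ig}$ and conditional random-effect
moments $m_{ikg} = S_{ik} X_i^\top (y_{ik} - X_i\beta_{kg})/\sigma^2_k$,
$S_{ik} = (X_i^\top X_i/\sigma^2_k + D_k^{-1})^{-1}$. The CM-steps update,
in order, $\pi$, $\beta$ (posterior-weighted least squares on
$y - X m$), $D_k$ (weighted mean of $m m^\top + S$), and $\sigma^2_k$
(weighted residual sum of squares plus trace correction, using the new
$\beta$). Each block maximises the same expected complete-data objective,
so the observed log-likelihood is monotone non-decreasing — this is
asserted (slack $10^{-8}$) on every fitted dataset in the tests. Subjects
sharing an observed-wave pattern are processed as matrix blocks, so cost
grows with the number of patterns, not subjects.

Numerical choices:

* **Convergence**: relative log-likelihood change $< 10^{-6}$ (default),
  `max_iter` 500.
* **Multistart**: one deterministic start (k-means on per-subject OLS
  intercept/slope summaries) plus `n_starts - 1` seeded random hard
  assignments; best final log-likelihood wins, ties to the lowest start
  index. The caller's RNG state is saved and restored.
* **Label switching**: classes are reported in descending $\pi_g$, ties
  broken on the first outcome's intercept, making output deterministic
  given the seed.
* **Degeneracies**: non-positive-definite $D$ draws a tiny ridge
  ($10^{-8}$); classes with $\pi_g < 1/(2N)$ are flagged; empty classes in
  classification report `NA` mean posteriors and are flagged.
* **Relative entropy**: $1 - \sum_{i,g}(-p_{ig}\log p_{ig}) / (N\log G)$,
  with $0\log 0 := 0$ and the convention $E = 1$ at $G = 1$.

The G = 1 collapse is verified against `lme4::lmer` (ML): the likelihood
function is checked at lme4's estimates to $10^{-6}$, and the EM optimum to
$10^{-3}$ — two optimisers' stopping points cannot meaningfully be compared
at $10^{-6}$ when EM converges linearly in the variance components.

## 3. Class enumeration

`sweep_classes()` fits each candidate $G$ under a shared seed protocol;
`select_classes()` applies the codified rule: among converged candidates
whose smallest class holds at least 5% of subjects (default floor;
prevents degenerate splits from dominating), choose the highest lowest
per-profile mean posterior probability, then the highest entropy, then the
smaller $G$. AIC and BIC are reported but not dispositive — matching the
reproduced analysis, which preferred the 2-profile model on
posterior/entropy despite lower AIC at 3–4 profiles; the tests assert that
this rule applied to the published fit-index table reproduces that choice.
A $G=1$ row is treated as a reference only: posterior and entropy are
identically 1 there, so admitting it to the comparison would make the rule
vacuous. Substantive "meaningfulness" of profiles is a human judgement;
the rule only flags candidates.

## 4. Epoch processing rules

All thresholds are inclusive at their stated boundaries (90, 10, 30,
600 min, 3 days, 150 min/week). Days are processed independently; runs
truncated by the day boundary count if long enough, and no run spans
midnight, because the day is the unit of summary.

* **Non-wear**: a maximal run of zero-count epochs totalling ≥ 90 zero
  minutes, allowed to absorb interior interruptions of ≤ 2 consecutive
  non-zero minutes; absorbed interruption minutes are excluded from wear
  time. This is the plainest reading of the one-line rule in the source
  description. The stricter convention in which an interruption only
  merges runs when flanked by ≥ 30-min zero windows on both sides is
  available as `processing_rules(choi_flank = TRUE)`; which variant the
  original study used is not stated.
* **Bouts** are strictly consecutive (no tolerance minutes), per the
  "consecutive minutes of" wording.
* **Guideline**: mean daily MVPA over included valid days × 7, inclusive
  at 150 min/week.
* **Zero-MVPA imputation**: the source analysis imputed two zero weekly
  MVPA values "based on maximum likelihood estimation" without further
  detail; the method is unrecoverable, so the pipeline default is no
  imputation, and the event (a participant-wave with zero MVPA) simply
  flows through feature computation (affecting the ilr via
  zero-replacement, which is flagged).

Both the non-wear and bout detectors are checked against independently
written brute-force oracles (a regular-expression scanner and an explicit
forward scan) on 1,000 random days in the acceptance suite.

## 5. Time-use features

The 15 variables per participant-wave are computed over valid days only;
SDs use the sample ($n-1$) formula; bout features enter as per-day means so
waves with different day counts are comparable. The ilr pivot coordinates
use $\sqrt{2/3}\,\ln(x/\sqrt{yz})$; they sum to zero and are scale
invariant (both property-tested). Zero parts are replaced by 0.5 min/day
before the transform — standard small-composition practice — and flagged.

**Pooled z-scoring.** One mean/SD per feature pooled over all retained
participant-waves, not per wave. Rationale: per-wave scaling would force
every wave's cross-sectional mean to zero, making within-profile z-value
trajectories flat by construction; profile trajectories that drift across
waves are only expressible under pooled scaling. Whether the original
analysis pooled is not stated; pooled is the default for this reason.

**Pruning.** The Spearman threshold used originally is not stated
(default here: $|\rho| \ge 0.9$), nor is the rule for which member of a
correlated pair was dropped. Two policies are therefore provided: a
`greedy` policy (drop, from the worst pair, the member with the larger
mean absolute correlation; ties to the later canonical position) and the
`paper_list` reproduction default, which excludes the ten variables the
source analysis names and retains
`mean_sb, mean_lipa, mean_mvpa, sd_mvpa, ilr_sb`.

## 6. The synthetic cohort

The generator emulates the measurement design of a two-year activity trial
in prediabetes/type-2 diabetes: waves at months 0, 6, 12, 18, 24; 3–7
monitored days per wave; non-baseline waves missing completely at random
(default 10%); 1440 one-minute epochs per day comprising a contiguous
nocturnal non-wear block, optional daytime non-wear insertions, and waking
minutes whose SB/LIPA/MVPA state follows a semi-Markov process with
geometric dwell times. Counts are drawn inside the cut-point band of the
generating state (SB uniform on [0, 99] with a 0.35 point mass at zero;
LIPA uniform on [100, 1951]; MVPA uniform on [1952, 5724]), so cut-point
classification recovers the state; steps are Poisson per state. Behaviour
totals per day are drawn as class-wave targets plus person-level
intercept/slope offsets plus between-day normal noise, and the state
process fills exactly those totals.

Design choices worth recording:

* **The nocturnal block is the residual** $1440 -$ waking minutes
  $-$ insertions (floor 480 min), rather than an independently drawn
  length. Drawing both the block and the behaviour minutes would
  over-determine the day and destroy marginal calibration of the daily
  means, which the tests require (pooled means within 3 min of targets at
  ~250 days, person heterogeneity off). Targets summing above the 840-min
  nominal waking wear window are rejected with the offending class and
  wave named.
* **Short-wear days** (default probability 0.08) scale a day's behaviour
  minutes to 30–65%, landing below the 10-h validity threshold. This
  exercises the valid-day filter and the wave/participant exclusion paths
  without biasing valid-day means (day invalidity is independent of the
  retained days' values).
* **Epoch length is fixed at 60 s**: the counts-per-minute cut-points of
  the GT1M era imply per-minute epochs.
* Count magnitudes within bands, step rates, dwell means and the daytime
  non-wear insertion law are conventions, not reproductions — the source
  study reports no within-day distributional facts.

What the generator does **not** emulate: triaxial/raw-acceleration
signals, sleep structure, wear-location effects, autocorrelated day-to-day
behaviour, seasonal effects, or informative missingness. A green recovery
test therefore establishes that the estimation machinery recovers planted
class structure under the model's own assumptions — not that the model is
robust to real-world violations of them.

Presets: `paper_like` (22%/78% classes whose trajectory directions,
age/BMI/comorbidity distributions and baseline guideline shares mimic the
reproduced cohort), `high_separation` (equal classes, MVPA slope
difference 25 min/day/yr ≈ > 1 z/yr, for recovery experiments), and
`zero_separation` (identical class profiles).

## 7. Predictors of profile membership

With two profiles, multinomial regression reduces to binary logistic
regression; the binary form is implemented and the multinomial
generalisation is out of scope. The profile with the largest fitted MVPA
slope is labelled "increased" and modelled against the reference, so odds
ratios read as odds of improving. Gender (reference female), age, and
randomisation arm (reference multi-component) are forced; BMI,
hypertension, COPD, other disease and baseline guideline achievement are
candidates for backward elimination on AIC (default; BIC by
configuration — the source description names both without resolving).
Diagnostics follow the three conventions behind the original one-line
checking sentence: Box–Tidwell $x\ln x$ terms for logit linearity (flag at
$p < 0.05$), variance-inflation factors on the linear design (flag > 5),
and approximate Cook's distance (flag > $4/n$). Fits use IRLS via
`stats::glm`; the 2×2 closed form ($ad/bc$, SE
$\sqrt{1/a+1/b+1/c+1/d}$) serves as an independent oracle in the tests.

## 8. Known limitations, and the deliberate red test

* **Entropy does not guard against overextraction.** The acceptance suite
  expects the zero-separation preset (identical class profiles) to yield
  an unconfident 2-class solution, "entropy near 0". It does not, and the
  expectation is left red rather than weakened. Two mechanisms, both
  visible in the diagnostics the tests compute: (i) latent classes absorb
  cross-outcome dependence that the conditional-independence likelihood
  cannot represent — `sd_mvpa` and `ilr_sb` are deterministic functions of
  the same person-level MVPA driver as `mean_mvpa`, and splitting subjects
  on that shared driver raises the likelihood substantially (the 2-class
  solution beats 1 class on BIC, not just AIC); (ii) with 4–5 waves a
  subject's random intercept is well identified, so wherever EM places two
  components within a continuous heterogeneity distribution, each
  subject's posterior is decisive — measured entropy is ~0.8 on the
  pipeline's five outcomes and 0.35–0.64 even on the three conditionally
  independent mean outcomes. The class-recovery facet of the same
  experiment behaves correctly: agreement with the (arbitrary) true labels
  stays at chance (≤ 60%). The practical lesson the red test encodes:
  high entropy is evidence of sharp classification, not of true class
  structure, and class enumeration should weight substantive
  meaningfulness accordingly.
* The latent-process multivariate formulation (shared process with outcome
  loadings) is not implemented.
* No imputation of zero-MVPA values; no penalised (Firth) logistic
  regression for separation; covariate missingness is handled by
  complete-case analysis with a logged count.
* Percentages in characteristic tables round half away from zero; three
  percentage cells printed in the reproduced baseline table are
  inconsistent with their own printed counts under any conventional
  rounding, and the tests assert the arithmetically correct values for
  those cells.
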