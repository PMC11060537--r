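---
title: "Scoring and analysing the Future Thinking IRAP: models and methods"
author: "ftirap package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and analysing the Future Thinking IRAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirap)
```

## The measure

The Future Thinking Implicit Relational Assessment Procedure (FT-IRAP) is a
latency-based implicit measure of future expectancies. On each trial a sample
phrase ("I expect" / "I don't expect") is paired with one of twelve outcome
words (six positive, six negative) and the participant answers *true* or
*false* under block-level instructions that are either **consistent** with an
optimistic disposition (affirm expecting positive outcomes, affirm not
expecting negative ones) or **inconsistent** with it (the converse). A task
administration comprises four 24-trial blocks with strictly alternating
instructions (first-block condition counterbalanced across participants); each
of the four trial types — expect-positive, expect-negative,
don't-expect-positive, don't-expect-negative — occurs six times per block, and
every target word appears twice per block, once under each sample.

The dependent measure is a standardised latency difference per trial type,
the D score. Writing pair 1 for blocks 1–2 and pair 2 for blocks 3–4,

$$
D_{\text{pair}} \;=\; \frac{\bar L_{\text{inconsistent}} -
  \bar L_{\text{consistent}}}{S_{\text{pooled}}},
\qquad
D \;=\; \tfrac12\,(D_{\text{pair 1}} + D_{\text{pair 2}}),
$$

where the cell means are the mean retained latencies of that trial type in
each block of the pair and $S_{\text{pooled}}$ is the sample SD
($n-1$ denominator) of that trial type's raw retained latencies combined
across the two blocks. $D$ is clamped to $[-2, 2]$; positive values indicate
an optimistic orientation (faster responding under optimism-consistent
instructions).

Before scoring, practice trials and trials slower than 10,000 ms are removed.
A participant's entire data set is excluded when more than 10% of their
retained test trials are 300 ms or faster, or when first-response accuracy in
any single test block falls below 80%. Ties are resolved strictly as the
rules are phrased: exactly 10,000 ms is retained, exactly 300 ms counts as
fast, exactly 10% and exactly 80% are retained. All thresholds are
`pipeline_config()` arguments, so sensitivity analyses are possible; the
defaults reproduce the published rules.

Two readings of "the pooled standard deviation of raw RTs in the relevant two
blocks" are possible: the SD of that *trial type's* latencies in the two
blocks (12 values), or of *all* latencies of the two blocks (48 values). The
package defaults to the trial-type-specific reading, which follows the
standard D-algorithm lineage of per-trial-type standardisation; the
alternative is available as `compute_dscores(..., sd_scope = "block_pair")`.

Latency is defined as the time from trial onset to the eventual *correct*
response, so error trials carry the retry delay; first-response accuracy is
used only for the exclusion rule. This is the convention implied by a display
that remains onscreen until the correct key is pressed.

## The synthetic cohort generator

No participant-level data are distributed with the task, so the package
contains a first-class generator whose ground truth is expressed directly on
the D scale. One simulated latency is

$$
L \;=\;
\begin{cases}
U(0,\, 300\,\text{ms}) & \text{with probability } q
  \;(\text{fast guess}),\\[2pt]
X + B\,G & \text{otherwise,}
\end{cases}
$$

with $X$ a floor-truncated Gaussian whose mean is shifted by $\mp\delta/2$
(consistent / inconsistent), $B$ a Bernoulli($p$) indicator of a wrong first
response, and $G$ a Gamma retry delay added to the recorded latency. Defaults
(`rt_params()`): base mean 1800 ms and SD 400 ms (block means sit plausibly
under the 2 s feedback target shown to participants), floor 250 ms, error
rate $p = .03$ (well inside the 80% accuracy rule), Gamma(2, scale 300)
penalties, and fast-guess rate $q = .005$ — enough to exercise the 300 ms
exclusion rule without dominating the data. The absolute latency scale is a
free choice (the task's published analyses report no trial-level RT
summaries); D is scale-invariant, so only the shift-to-SD ratio matters.

**Calibration.** The generator's promise is that the *expected value of the D
estimator itself* — computed from 6-trial cells exactly as `compute_dscores()`
does — equals the requested `true_d`. With equal cell sizes $n_1 = n_2$ and
$n = 2 n_1$, the pair score is an exact monotone transform of the two-sample
$t$ statistic,

$$
D_{\text{pair}} \;=\; c_0\, \frac{t}{\sqrt{\,n - 2 + t^2\,}},
\qquad c_0 = \sqrt{\frac{n(n-1)}{n_1 n_2}},
$$

with $t$ noncentral-$t$ under within-cell normality. `dscore_calibration()`
evaluates $E[D_{\text{pair}}]$ as a function of the noncentrality by
Gauss–Hermite quadrature, inverts it with a monotone spline, and converts the
noncentrality into a millisecond shift using the analytic mean and variance
of the full latency mixture (penalties and fast guesses included; fast
guesses also dilute the mean shift by $1-q$). Because non-normal latencies
inflate the sampling variance of the pooled SD, the pooled sum of squares is
modelled as a moment-matched Gamma whose variance uses the mixture's analytic
excess kurtosis rather than the $\chi^2$ value. Floor truncation is ignored
in these moments; with the defaults the truncated mass is below $10^{-4}$.

Two structural consequences are worth noting. First,
$|D_{\text{pair}}| < c_0 \approx 1.915$ at six trials per cell, so the
$[-2,2]$ clamp can never bind for complete balanced sessions — it matters
only for degraded data with unequal cells — and true values beyond
$\approx 1.9$ are not representable by any latency shift (the calibration
rejects them). Second, the calibration is estimator-specific: the large-sample
standardised mean difference of the latency distributions is *not* `true_d`;
the finite-cell estimator's expectation is. Package tests verify the
generator two ways: the analytic mixture moments against large-sample
simulation, and estimator unbiasedness (to within 3 Monte-Carlo standard
errors over ≥500 cohorts) at several true values in $[-1, 1]$.

Cohort-level defaults mirror the motivating study's conditions: groups of
36 (`pst`) and 37 (`neutral`) participants, three task administrations each,
and a truth grid (`default_truth_grid()`) whose cell values are the study's
published group-mean D scores, including the intervention effect concentrated
on don't-expect-negative trials after positive simulation training.
Participants deviate from their grid cell by a shared Normal(0, 0.3)
individual effect — chosen so that observed cohort SDs (individual spread
plus estimation noise) land in the 0.4–0.5 range typical of such data — and
this deviation is constant across time points, as a stable disposition should
be. Individual true values are clipped to the calibration's representable
range (just under the $c_0$ bound), which matters only for deviations beyond
about four individual-effect SDs. CESD-R totals are drawn from a shifted Gamma matched to mean 19.9, SD
13.0 and skewness 0.73, rounded and clipped to 0–80 (clipping affects ~5% of
draws and lifts the mean by well under one point); item vectors are uniform
compositions of the total over twenty 0–4 items. Mood (VAMS) readings and
vividness/emotionality ratings are truncated Gaussians matched to the
published group summaries.

What the generator does **not** emulate: sequential effects (practice,
fatigue, block-order drift within a session), response-bias strategies,
cognitive-process structure (it is a descriptive mixture, not a
diffusion-style model), and any correlation between depressive symptoms and
task performance (the published correlations were null). Passing recovery
tests therefore demonstrate that the scoring and inference machinery is
correct and calibrated — not that real FT-IRAP data satisfy the generative
assumptions.

## Inference

The analysis stage reproduces the study's statistical machinery.
`splitplot_anova()` fits the split-plot (mixed) ANOVA with one
between-subjects factor (group), one within-subjects factor (trial type or
mood-scale valence), and optionally a continuous covariate — the
square-root-transformed CESD-R total, transformed because the raw totals are
right-skewed (the package's `moment_diagnostics()` reports the
sample-adjusted skewness/kurtosis with their normal-theory standard errors to
justify exactly this step). The decomposition is classical univariate
mixed-model: subject means form the between stratum; orthonormal
within-subject contrasts form the within stratum, where the between-design
intercept carries the within main effect, the group columns the interaction,
and the covariate its interaction with the within factor. Sums of squares are
Type III with sum-to-zero coding and an uncentered covariate; no sphericity
correction is applied. These conventions give the integer error dfs standard
in this literature: $(k-1)(N-2)$ for two groups without covariate and
$(k-1)(N-3)$ with one covariate — e.g. within-effect dfs $(3, 213)$ and
$(3, 210)$ at $N = 73$, and $(3, 207)$ at $N = 72$. The implementation is
cross-checked in the test suite against `car::Anova`'s Type III univariate
repeated-measures tests on random designs.

Post-hoc group comparisons per trial type use pooled-variance $t$ tests on
change scores with Bonferroni correction over the four trial types
(corrected $\alpha = .0125$; adjusted $p = \min(1, 4p)$) and Cohen's $d$ =
mean difference / pooled SD, with no small-sample correction. Marginal means
carry 95% CIs of $\bar x \pm t_{.975,\,N-2}\, s_{\text{pooled}}/\sqrt{n_g}$,
pooling the two groups' variances per within level. Group comparisons of
demographics use the pooled two-sample $t$ (from raw data or printed
summaries) and the Pearson chi-square without continuity correction — the
uncorrected form is what reproduces published values of such statistics from
their printed counts. Change-score post-hoc tests are *not*
covariate-adjusted; where published post-hoc dfs imply a reduced or adjusted
sample, the unadjusted pooled test is the package's documented default.

## Numerical and design choices

* **Randomness.** Every stochastic function draws from a private
  Mersenne-Twister stream derived from its seed; the caller's `.Random.seed`
  is never touched, and cohort seeds are split from one master seed, so runs
  are bit-reproducible end to end.
* **Degenerate inputs.** Zero pooled SD in a pair yields a pair score of 0
  with a warning; an empty latency cell makes that trial type's D `NA` with a
  diagnosable warning naming participant, time point and trial type; a
  participant with no retained trials is excluded with a warning; constant
  covariates, single groups and incomplete within-level data are rejected or
  dropped with explicit messages. In `run_pipeline()` a failed analysis stage
  is recorded and skipped without aborting the rest.
* **Problem sizes in the test suite.** Stochastic checks use 500 simulated
  cohorts for unbiasedness (3 Monte-Carlo-SE tolerance), 1000 null cohorts
  for type-I calibration of the interaction test (tolerance 3 binomial SEs
  around .05), 200 random datasets for brute-force oracle equivalence, and
  80 cohorts for the power-ordering check. These sizes were chosen to keep
  Monte-Carlo error comfortably below each tolerance.
* **Clamping diagnostics.** Raw unclamped D values are retained alongside the
  clamped ones in every panel.
* **Dysphoria flag.** The screening cutoff (total ≥ 16) is the common CESD
  convention for subclinical depressive symptomatology; the instrument's own
  DSM-aligned episode algorithms are out of scope, and the cutoff is
  configurable.

## Known limitations

The generator's practice blocks reuse the 24-trial test-block structure (the
task description gives no practice-block length). The calibration assumes
within-cell normality up to a fourth-moment correction; residual bias from
higher moments is below ~0.01 on the D scale at the default contamination
rates, within the tolerance of the package's own recovery checks but not
exactly zero. The inference layer covers the two-group split-plot family
used by this design; it is not a general mixed-model engine (no more than
one within factor, no sphericity corrections, no missing-data modelling —
incomplete subjects are dropped listwise, matching the complete-case
convention of the original analyses).
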