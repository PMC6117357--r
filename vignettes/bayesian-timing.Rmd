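---
title: "Bayesian observer models of multisensory time estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian observer models of multisensory time estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(bayestime)
library(dplyr)
```

## The problem

Two well-established phenomena shape human interval timing. First, timing
noise is *scalar*: the standard deviation of duration estimates grows in
proportion to the duration itself, so sensitivity is summarized by a
dimensionless Weber fraction (WF). Second, duration estimates show a
*central tendency*: reproductions of a given duration are pulled toward the
mean of the durations experienced recently. Both are captured by a Bayesian
observer that combines a noisy sensory measurement with a Gaussian prior
over durations. When an interval is marked simultaneously in two modalities
(audiovisual stimulation), a third ingredient appears: reliability-weighted
cue combination (maximum-likelihood estimation, MLE), which predicts a
combined estimate more precise than either unisensory estimate.

The open architectural question this package is built around: does the
prior act *within each modality before* the cues are combined (model 1), or
*once, after* combination (model 2)? The two orders make different
quantitative predictions for the audiovisual central tendency, so they can
be told apart from behavior. This package provides (i) a generative
simulator for both architectures, (ii) the standard psychophysical
analyses, (iii) closed-form predictors for both architectures, and (iv) the
resampling statistics used to compare conditions and models.

## The observer model

For a stimulus duration $D$ the sensory measurement is
$m \sim \mathcal{N}(D,\ \sigma_L^2)$ with the scalar likelihood width

$$\sigma_L = \mathrm{WF} \times D .$$

The prior over durations is $\mathcal{N}(\mu_P, \sigma_P^2)$, with $\mu_P$
set to the mean presented duration $\bar D$. The posterior mean, which
drives reproduction, shrinks the measurement toward the prior:

$$\mu_R = w\,m + (1 - w)\,\mu_P, \qquad
  w = \frac{\sigma_P^2}{\sigma_P^2 + \sigma_L^2}.$$

Regressing reproductions on stimulus durations therefore yields a slope
below 1; at a single likelihood width the slope equals $w$ itself
(`ct_slope()`), which is also how the prior width is recovered from data:
$\sigma_P = \sigma_L \sqrt{CT/(1-CT)}$ (`estimate_prior_width()`).

Cue combination weights each modality by its precision:

$$\hat S_{AV} = w_A \hat S_A + w_V \hat S_V,\qquad
  w_A = \frac{\sigma_A^{-2}}{\sigma_A^{-2} + \sigma_V^{-2}},\qquad
  \sigma_{AV}^{-2} = \sigma_A^{-2} + \sigma_V^{-2},$$

which, because widths are proportional to duration, implies a duration-free
combined Weber fraction
$\mathrm{WF}_{AV} = \sqrt{\mathrm{WF}_V^2\mathrm{WF}_A^2 /
(\mathrm{WF}_V^2 + \mathrm{WF}_A^2)} \le \min(\mathrm{WF}_V, \mathrm{WF}_A)$
(`predict_optimal_wf()`).

The two architectures (`predict_model1()`, `predict_model2()`):

* **Model 1 — prior first.** Each modality forms its own posterior, then
  the two (already biased) posteriors are MLE-combined with weights set by
  the posterior widths. The predicted audiovisual slope is obtained by
  regressing the combined posterior means on the stimulus durations.
* **Model 2 — combination first.** The unbiased measurements are
  MLE-combined; a single prior, centered on $\bar D$ with width
  $(\sigma_{P,V} + \sigma_{P,A})/2$, then biases the combined estimate.

Because combination shrinks the likelihood width before the prior applies,
model 2 always predicts a slope at least as large (weaker central
tendency) as model 1 at matched inputs; the package verifies this ordering
over an exhaustive grid. Intuitively, model 1 "locks in" unisensory biases
and can only average them, while model 2 applies the prior to a sharper
likelihood that resists it.

```{r architectures}
d <- make_design()
pri <- gaussian_belief(d$mean_duration_ms, 238)
glance(predict_model1(0.17, 0.17, pri, pri, d$reproduction_levels_ms))
glance(predict_model2(0.17, 0.17, 238, 238, d$reproduction_levels_ms,
                      prior_mean_ms = d$mean_duration_ms))
```

## One approximation worth knowing about

The slope formula $CT = \sigma_P^2 / (\sigma_P^2 + \sigma_L^2)$ uses a
single likelihood width, but under scalar timing $\sigma_L$ differs at
every duration level, so the shrinkage weight $w(D)$ falls with $D$. The
exact expectation of the trial-level OLS slope is the regression of the
per-duration posterior means on the durations; `predict_ct_slope()`
computes it, and it runs 0.01–0.02 *below* the single-width formula
evaluated at $\bar D$ for the parameter range of interest. Simulation tests
use the exact regression form as their oracle; the single-width formula is
retained because it is the standard reporting convention and the inversion
target for `estimate_prior_width()`.

Two small consequences follow and are visible in simulated data:

* A pure-shrinkage observer shows a slightly *negative* overall
  reproduction bias, $\mathrm{mean}_D[w(D)(D - \bar D)] \approx -10$ ms at
  WF 0.17, because far-above-mean durations are shrunk harder than
  far-below-mean ones. With a constant weight the grand mean would be
  untouched.
* Prior widths recovered by inverting the single-width formula at
  $\sigma_L = \mathrm{WF}\,\bar D$ carry a mild downward bias (about 5–8%
  in the simulated regime), which stays comfortably inside the 15%
  recovery tolerance the tests use.

## The synthetic-data generator

`make_design()` encodes the task: a 640-ms standard; comparison and
reproduction durations log-spaced from 450 to 900 ms; 24 presentations per
comparison level and 60 per reproduction level; visual, auditory and
audiovisual conditions with background-noise levels *no/low/high*, the
audiovisual blocks pairing high/high, high/low and low/high visual/auditory
noise. The number of levels per task is not dictated by the task geometry
itself; the default of 7 log-spaced levels over the 2:1 range is standard
psychophysical practice and is configurable.

`observer_params()` holds the generative parameters. Defaults are the
package's reference conditions, fixed once:

| parameter | default | rationale |
|---|---|---|
| WF (no/low/high noise) | 0.13 / 0.17 / 0.22 | sensitivity near 0.17 at low noise in both modalities, rising with noise, falling slightly without it; modalities matched since discrimination sensitivity does not differ reliably between them |
| prior width V / A | 177 / 282 ms | visual timing leans more on the prior than auditory timing at matched sensitivity |
| prior mean | `"auto"` = arithmetic mean of levels (653.5 ms) | the prior centers on the mean stimulus duration; a geometric-mean option exists |
| motor noise CV | 0 | the architectural predictions contain no motor stage; a multiplicative-noise option exists for robustness studies |
| AV architecture | `"model2"` | the architecture the behavioral evidence favors |

Discrimination trials default to a *psychometric mode*: the probability of
judging the comparison longer is
$\Phi\!\left((D_c - D_s)/(\mathrm{WF}\,D_s)\right)$, a Bernoulli draw, so
the analysis model is exactly recoverable by construction. An *estimate
mode* draws a noisy estimate per interval with width
$\mathrm{WF}\,D/\sqrt 2$ (so decision noise at the standard matches the
psychometric mode) and compares them; it exists because a two-interval
noise decomposition is the more mechanistic story, but it is not the
default since the analysis fits only the psychometric function.

Non-positive reproductions are redrawn at the trial level; at realistic
parameters the event has probability below $10^{-8}$, so the induced bias
is immaterial.

What the generator deliberately does **not** emulate: trial-order and
hysteresis effects, feedback-driven learning, practice effects, the
modality-dependent overall over/under-estimation seen in real reproduction
data (its origin is an open question; `overall_bias()` measures it,
nothing models it), lapses in discrimination (a fixed-lapse fit option
exists), and non-Gaussian internal scales (e.g. log-normal). Passing tests
therefore certify the pipeline's statistical machinery on data from this
model family, not the full richness of real timing data.

## Fitting choices

**Psychometric fits** (`fit_cumulative_normal()`) maximize the Bernoulli
likelihood over `(PSE, log sigma)` with Nelder-Mead from a moment start —
PSE from the interpolated 50% crossing, sigma from the 25–75% span — plus
two jittered restarts; a Brent fallback handles the fixed-PSE variant. The
fitted maximum has been checked against a quasi-Newton polish on hundreds
of simulated datasets (no improvement beyond $10^{-8}$ log-likelihood
units). The PSE is free by default; whether to constrain it is genuinely
open, so both modes exist. All-identical response sets raise a
degenerate-data error rather than returning an unidentified sigma. The
just-noticeable difference is identified with the fitted sigma throughout;
no separate 75%-point convention is used.

**Central tendency** (`fit_central_tendency()`) is ordinary least squares
of reproduced on stimulus duration over individual trials (per-trial
pooling rather than level means, matching how such data are usually
plotted and fitted). The outlier rule removes trials more than 3 SD from
the cell mean in a single, non-iterative pass, with means and SDs taken
from the unfiltered data. The cell is condition × stimulus level by
default — the conservative reading that does not conflate level means — and
a per-condition mode is available. Zero-variance cells exclude nothing.

**Prior-width estimation** inverts the slope formula at
$\sigma_L = \mathrm{WF} \times \bar D$ with $\bar D$ the arithmetic mean of
the presented levels (geometric option available). Fitted slopes at or
above 1 mean no detectable central tendency; the pipeline clamps to 0.999,
yielding a finite, very wide prior, rather than failing a whole cohort on
one noisy cell.

## Inference

`bootstrap_paired_test()` resamples paired units (subject × condition
means) with replacement, 10,000 resamples by default, and reports the
two-sided percentile p-value with a +1 continuity correction, Cohen's
$d_z$, and the 95% percentile CI. The plug-in percentile scheme is known to
run slightly liberal in small samples: at 21 pairs its measured type-I
error is ≈ 0.069 at a nominal 0.05 (40,000-replication measurement in the
test suite). Families of condition contrasts are Bonferroni-corrected with
the family size made explicit (`bonferroni(p, m = 3)` for the three
audiovisual noise combinations). `paired_t()` reports the classical paired
t with $d_z$, returning a signed infinite statistic for zero-variance
nonzero differences instead of failing. `regress_pred_vs_meas()` is the
measured-on-predicted OLS with Pearson correlation and a 95% confidence
band, used for model-prediction scatter plots.

## The experiment runner

`run_experiment()` simulates a cohort (default 7 subjects) through all nine
conditions and both tasks, fits every cell, estimates prior widths,
predicts the audiovisual central tendency under both architectures from
each subject's *fitted* unisensory parameters, runs the contrasts, and
writes all artifacts (trial CSVs, fit CSVs, predictions, `stats.json`,
`config.yaml`, `report.md`) into a run directory; `report()` renders the
summary. Between-subject heterogeneity is log-normal — multiplicative
jitter with sdlog 0.10 on Weber fractions and 0.15 on prior widths —
keeping parameters positive with a constant coefficient of variation, a
conventional way to represent individual differences in sensitivity
indices. Model comparison selects the architecture with the smaller mean
absolute error between predicted and measured audiovisual slopes.

Determinism: every random draw derives from the configured seed through a
per-(task, condition, subject) sub-seed, so a saved `config.yaml`
reproduces every CSV byte for byte, and simulating one condition does not
perturb another's stream.

```{r run, eval = FALSE}
cfg <- run_config(n_subjects = 7, seed = 42)
dir <- run_experiment(cfg, "my_run")
cat(report(dir), sep = "\n")
```

## Problem sizes used by the test suite

The suite checks closed forms against a numerical density-product oracle
(1,000 randomized parameter sets), Weber-fraction recovery on ~200
datasets at the study's 7 × 24 trial counts, prior-width recovery at
7 × 600 (600 replicates), generator/theory slope agreement over a
3 × 3 parameter grid with a joint 95% Monte-Carlo interval, the
architecture ordering over an exhaustive 8 × 8 × 5 grid, architecture
identifiability over 100 replicate cohorts per generating architecture,
and the bootstrap's type-I error at 40,000 replications. These sizes give
each stochastic check a comfortably small Monte-Carlo error relative to
its tolerance.

## Known limitations

* Gaussian likelihoods and priors throughout; heavy-tailed or log-scale
  internal representations would need a different machinery (the numerical
  oracle, however, would generalize).
* Prior widths are estimated by moment-style inversion of the slope, not
  by trial-level likelihood maximization; the inversion inherits the
  single-width approximation discussed above.
* The model-2 audiovisual prior width is fixed to the average of the two
  unisensory widths; it is a modeling convention, not an estimate.
* The bootstrap's resampling unit is the subject × condition pair; whether
  trial-level resampling would be preferable is left open, and the
  implemented scheme is the one whose calibration the suite quantifies.
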