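---
title: "Methods: measuring perception-production links for a vowel contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring perception-production links for a vowel contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vowelpp)
```

This vignette is the package's account of its models, parameters, numerical
choices and limitations. It states no empirical result that the test suite
does not itself compute.

## The scientific setting

A long-standing hypothesis in speech research holds that talkers with more
narrowly specified auditory targets for a phonetic contrast should both
categorize that contrast more consistently and produce it more precisely.
`vowelpp` operationalizes both sides for a two-vowel contrast (the American
English "head"/"had" pair, labeled `EH` and `AE`): a perceptual measure from
a forced-choice identification task, three acoustic production measures from
repeated single-word utterances, and a cohort-level rank-correlation
analysis of individual differences.

## Perception: the psychometric model

Identification trials present step $x \in \{1,\dots,11\}$ of a synthesized
continuum and record a binary "head"/"had" label. We model

$$P(\mathrm{HEAD}\mid x) = \frac{1}{1+\exp\!\big((x-x_0)/s\big)},$$

a two-parameter logistic decreasing toward the "had" end. $x_0$ (steps) is
the categorical boundary; the boundary width
$w = 2 s \ln 3$ — the distance between the 25% and 75% points — is the
categorical labeling consistency index. No lapse or guess parameters are
included: the width definition presumes a function spanning 0–100%, and a
lapse rate would change the meaning of the 25/75 crossings.

Estimation choices:

* **Trial-level Bernoulli maximum likelihood**, aggregated to per-step
  binomial counts (identical likelihood up to a constant). ML is
  well-defined for unequal per-step counts, unlike least squares on
  proportions.
* **Box constraints** $s\in[0.01, 50]$, $x_0\in[-5, 17]$ steps, optimized
  by L-BFGS-B (analytic gradient) from three deterministic starts: an
  unconstrained logistic-regression solution when one exists, a
  variance-weighted crossing guess, and the continuum midpoint. Best
  likelihood wins; ties go to the smaller $s$. The fit is therefore fully
  deterministic given the data — no random restarts.
* **Orientation handling.** The model expects HEAD to dominate low steps;
  if the data are oriented the other way the responses are flipped
  internally and flagged. Relabeling the categories or mirroring the step
  axis leaves the width unchanged (tested).
* The x-axis is the step *index*, not Hz: the width is reported in
  continuum steps, and the continuum is deliberately non-uniform in Hz
  (denser near the expected boundary). The synthetic continuum generator
  reproduces that spacing pattern, but the fit never sees Hz.
* A perfect step responder drives $s$ to its lower bound; the fit is
  returned with `at_bound = TRUE` and a width of $2\cdot 0.01\ln 3
  \approx 0.022$ steps rather than an error, since such data are valid
  (maximally consistent) behavior.

## Production measures

All production analysis happens in mel-scaled $(F_1, F_2)$ space. The mel
conversion defaults to $m = 2595\log_{10}(1+f/700)$, the convention most
phonetics tooling uses; the natural-log variant $1127\ln(1+f/700)$ (the
same function up to a ~1.00001 factor) is selectable via
`analysis_config(mel_formula_id=)`. Tokens arrive either window-averaged or
as per-frame tracks; tracks are reduced by averaging mel-converted frames
inside two windows — the initial 0–50 ms, and the middle 50% of token
duration — with closed interval membership at both ends. For tokens shorter
than 200 ms the two windows overlap geometrically ($0.25d < 50$ ms); the
package flags but retains such tokens, and additionally reports a
configurable short-duration flag (default 150 ms) because the two criteria
need not coincide. Tokens whose track leaves a window empty are carried
with `excluded = TRUE`, so exclusion counts remain reportable; excluded
tokens are dropped before every statistic.

**Contrast distance** uses per-vowel *means* of the midpoint window;
**ellipse area** uses the midpoint sample covariance $S$ (denominator
$n-1$, $n \ge 3$) with area $\pi\, q\, \sqrt{\det S}$, where
$q = \chi^2_2(0.95) \approx 5.991$. This is the *coverage* (data) ellipse
of the token distribution, not the standard-error ellipse of the mean: the
measure targets trial-to-trial variability, and a standard-error ellipse
would shrink with $n$ rather than estimate dispersion. The coverage level
is configurable; the alternative reading is one config value away.
**Centering** uses per-formant *medians* as the reference point. The
mean/median asymmetry across measures is deliberate and preserved exactly
as each measure is defined.

Log transforms are natural logs throughout (the base is a scale choice; it
is documented and fixed). A note on units: ellipse areas are mel², so the
log-area measure is log-mel²; descriptive tables label it accordingly.

The centering ratio per vowel is
$1 - \overline{d_\mathrm{mid}}/\overline{d_\mathrm{init}}$, averaged over
the two vowels. It is bounded above by 1 (equality iff every
$d_\mathrm{mid}=0$) but not bounded below; negative values mean outward
drift.

## The synthetic cohort: a stated world

No generative model is inherited from the measurement definitions, so the
generator is the package's own formalization, chosen for minimality:

* **Listeners** respond from the true logistic with parameters
  $(x_{0,\mathrm{true}}, s_\mathrm{true})$, independently across trials;
  11 steps × 20 reps by default.
* **Speakers** draw an onset deviation $\delta \sim N(0,\Sigma_\mathrm{on})$
  per token; onset formants are $\mu + \delta$ and midpoint formants
  $\mu + (1-g)\delta + \varepsilon$, $\varepsilon \sim
  N(0,\Sigma_\mathrm{mid})$, with 45 tokens per vowel. The linear gain
  $g \in [0,1]$ is the simplest mechanism whose population centering ratio
  equals $g$ in the noiseless limit — and in that limit the *sample*
  pipeline recovers $g$ exactly, because medians of onset and midpoint
  deviations cancel in the ratio.
* **Cohort defaults** were fixed once to make the measure distributions
  span published study-scale ranges and were not revisited: boundary width
  truncated-Normal(1.89, 0.56) on [0.5, 3.5] steps; $x_0 \sim N(6, 0.8)$;
  vowel midpoint centroids near (720, 1640) and (860, 1540) mel with
  20-mel per-participant jitter; onset token SD uniform on 16–28 mel;
  midpoint noise SD 8 mel; gain uniform on [0, 0.27] (small net positive
  centering); durations Normal(179, 30) and Normal(237, 30) ms truncated
  at zero, used only by the overlap flag.
* **Coupling.** A Gaussian copula on the latent normals imposes a target
  Spearman correlation between listener width and speaker onset dispersion
  (latent Pearson $r = 2\sin(\pi\rho_S/6)$); `coupling = 0` yields the
  fully independent null world used for type-I-error checks.
* Trajectories are not simulated frame-by-frame; window means are
  generated directly. A separate track expander (piecewise-linear with
  optional frame noise) exists solely to exercise the preprocessing stage.

What a green test does **not** establish: real formant tracks have
measurement error, within-window dynamics, duration-dependent spectral
change and non-Gaussian token distributions, none of which the generator
emulates. Parameter-recovery results certify the *pipeline arithmetic*, not
robustness to real acoustic data.

## Cohort screening and inference

Shapiro–Wilk tests (standard algorithm, 3 ≤ n ≤ 5000) motivate robust
screening. The MAD filter excludes a participant whose value on any
screened measure lies strictly more than $k$ MADs from the cohort median
($k = 2$), with median and MAD computed once on the full pre-screening
cohort (no iteration). Values exactly at the cutoff are retained. The
screened measures default to labeling consistency, log contrast distance
and log ellipse area; the centering ratio is normality-checked but not
screened — an asymmetry preserved from the analysis this package
operationalizes.

The MAD is **raw** by default (no 1.4826 normal-consistency constant).
Worth knowing: for Gaussian-like measures, 2 raw MADs ≈ 1.35 SD, which
excludes roughly 18% of a cohort per measure and ~40% across three — far
more aggressive than 2 *consistent* MADs ≈ 2 SD (~5% per measure, about
2 of 37 participants). Study-scale exclusion counts are better matched by
`mad_consistency_constant = 1.4826`; the raw default is kept because the
screening rule is stated as "two MADs" with no consistency scaling, and
the constant is one config value away.

Spearman's $\rho$ is the Pearson correlation of mid-ranks (average ranks
on ties); the two-sided p-value uses $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on
$n-2$ df. Exactly three planned tests relate labeling consistency to each
production measure; p-values are reported unadjusted with a multiplicity
note in the report. Under the null generator the empirical type-I error of
all three tests is checked to sit at $0.05 \pm 0.02$ (the t approximation
is known to run very slightly liberal at $n \approx 31$; it stays inside
that band).

## Numerical conventions and degenerate inputs

* Window membership closed at both ends; overlap comparison strict
  (duration exactly 200 ms does not flag).
* MAD cutoff strict; exact ties with the cutoff are retained.
* Identical vowel centroids (log of zero distance), singular token
  covariance, constant vectors in correlation or normality tests, all-one-
  category responders, and zero mean initial distance raise typed,
  class-tagged errors (`vpp_*_error`) rather than NA or silent drops.
* Validation is total: malformed tables fail with schema/parse/range
  errors naming the offending column or row; excluded participants and
  tokens always carry recorded reasons.
* All simulation is seed-driven; the same seed and parameters reproduce
  byte-identical datasets.

## Limitations

The package starts from formant values; formant *estimation* (LPC
tracking, alignment, manual correction) is upstream and out of scope. The
identification fit assumes stationary listeners (no lapses, learning or
bias drift). The generator's independence of trials and tokens is an
idealization. The short-duration overlap threshold (150 ms) and the
geometric overlap criterion (200 ms) are both reported because they do not
coincide and the package takes no position on which governs any particular
dataset.
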