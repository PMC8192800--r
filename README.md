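# vowelpp

Perception–production analysis of a two-vowel contrast (American English
/ε/–/æ/, "head"–"had") at the level of individual differences.

The scientific question: do listeners who categorize a synthesized
head–had continuum more *consistently* also produce the two vowels more
*distinctly* and less *variably*? The package implements the full analysis
pipeline for that question — psychometric perception measures, mel-scale
acoustic production measures, cohort screening, and rank correlations —
together with a synthetic-cohort generator with known ground truth, so
every stage is testable without access to raw study recordings.

## The measures

**Categorical labeling consistency.** Each listener labels an 11-step
head–had continuum (20 presentations per step). Trial-level responses are
fit by maximum likelihood to a two-parameter logistic

P(HEAD | step) = 1 / (1 + exp((step − x₀)/s)),

where x₀ is the categorical boundary (the 50% point) and s the logistic
scale, in continuum steps. The boundary width — the distance between the
25% and 75% points, w = 2·s·ln 3 — indexes labeling consistency: smaller
width, more consistent categorization.

**Vowel contrast distance.** Per speaker, the Euclidean distance in mel
(F1, F2) space between the two vowels' mean midpoint formants, then
natural-log-transformed.

**Area of the ellipse.** Per vowel, the area of the 95% coverage ellipse
of the midpoint (F1, F2) token cloud, A = π·q·√det S with S the sample
covariance and q = χ²₂(0.95) ≈ 5.991; the per-speaker measure is the log
of the mean of the two per-vowel areas (trial-to-trial variability).

**Centering ratio.** Within each utterance, d_init is the distance of the
onset (F1, F2) values from the speaker's median onset values, d_mid the
same at mid-vowel; centering = d_init − d_mid. Per vowel the mean
centering is normalized by the mean initial distance
(ratio = 1 − mean d_mid / mean d_init) and the final measure averages the
two vowels: 1 = full correction toward the median by midpoint, 0 = none,
negative = outward drift.

**Cohort stage.** Shapiro–Wilk normality checks; one-shot outlier
screening that excludes a participant whose labeling consistency, log
contrast distance, or log ellipse area lies more than 2 (raw) MADs from
the cohort median; Table-style descriptives; and Spearman rank
correlations (t-approximation p, df = n − 2) of labeling consistency
against each production measure.

## Worked example

```r
library(vowelpp)

truth <- cohort_truth(n_participants = 37, coupling = 0, seed = 1000)
sim   <- simulate_cohort(truth)
analysis <- analyze_cohort(sim$production, sim$identification)
print(analysis)
```

prints (abbreviated):

```
Perception-production cohort analysis
  participants: 37 input, 37 complete, 0 incomplete
  MAD screening: 13 excluded, 24 included (tokens excluded upstream: 0)
    ...
Descriptives (included participants):
  labeling_consistency   mean    1.756  sd   0.430  min    1.060  max    2.415
  log_contrast_distance  mean    5.167  sd   0.098  min    5.012  max    5.354
  log_ellipse_area       mean    8.900  sd   0.329  min    8.309  max    9.439
  centering_ratio        mean    0.065  sd   0.071  min   -0.047  max    0.192

Spearman correlations (unadjusted p; 3 planned tests):
  labeling_consistency ~ log_contrast_distance  rho(22) =  0.069, p = 0.750
  labeling_consistency ~ log_ellipse_area       rho(22) = -0.237, p = 0.264
  labeling_consistency ~ centering_ratio        rho(22) = -0.194, p = 0.364
```

Reading it: 37 simulated participants were analyzed end to end; 13 were
screened out by the 2-MAD rule; over the remaining 24, mean boundary width
was 1.76 continuum steps, mean log contrast distance 5.17 log-mel, mean
log ellipse area 8.90, mean centering ratio 0.065 (slight net
self-correction). The cohort was generated with perception independent of
production (`coupling = 0`), and accordingly none of the three rank
correlations approaches significance.

File-level equivalents (`run_simulate`, `run_analyze`, `run_report`)
write CSV outputs, a text report and a JSON run record with seeds, input
digests and an exclusion audit trail; `inst/cli/vowelpp.R` wraps them as
`simulate` / `analyze` / `report` subcommands.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates a study-scale 37-participant cohort from the given seed, runs
the complete analysis (psychometric fits, production measures, MAD
screening, descriptives, the three-test correlation suite), prints the
report, and writes the results JSON.
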