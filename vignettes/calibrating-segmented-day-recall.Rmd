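---
title: "Calibrating segmented-day activity self-reports against accelerometer MVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating segmented-day activity self-reports against accelerometer MVPA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Youth self-reports of physical activity are cheap and scalable but their raw
ordinal scores are not measurements: a "4" on a recess item has no unit.
Calibration converts such scores into the metric of an objective criterion —
minutes (or percent of window time) of moderate-to-vigorous physical activity
(MVPA) measured by a wearable monitor — by fitting statistical models that
link each item to the matching period of the monitor record.

`yapcal` implements this design end to end for segmented-day instruments in
the Youth Activity Profile (YAP) family: 15 items in three sections, five
tied to school-day windows (transport to school, PE, recess, lunch,
transport from school), five to out-of-school windows (before school, after
school, evening, Saturday, Sunday), and five sedentary items that are scored
but never calibrated against MVPA.

```{r, eval = FALSE}
library(yapcal)
default_instrument()
```

## Segmenting the monitored week

Minute-level monitor records (1-minute epochs with an energy-expenditure
value, an automatic wear flag and an MVPA flag) are mapped onto a weekly
window schedule. School start/end clocks are school-specific; recess, PE and
lunch times are supplied per date and simply absent on dates without them.
Derived bounds: the transport windows are the 30 minutes abutting school
start and end, the before-school window is the 60 minutes before transport,
after-school runs from the end of transport to 18:00, the evening window is
fixed at 18:00--22:00 and each weekend day is a single 07:00--22:00 window.

Numerical conventions worth stating explicitly, because they decide boundary
minutes:

* every interval is half-open `[start, end)` and each minute is labelled by
  its start, so abutting windows never double-count a minute — a property
  the test suite verifies against a brute-force per-minute assignment loop
  on randomized schedules;
* the MVPA flag, when it has to be derived from energy expenditure, uses an
  inclusive `>= 3.0` MET cut (configurable; the conventional moderate cut);
* percent MVPA before screening is computed over worn minutes only.

## Screening and nonwear imputation

A window occurrence is *valid* when worn-plus-imputed minutes cover at least
70% of its scheduled length; "at least" is taken literally, so exactly 70%
passes. A participant enters an item's calibration when the item's window
type has at least 3 valid occurrences in the week, relaxed to 1 for window
types that occur once or twice a week (PE, Saturday, Sunday).

Documented nonwear bouts from a daily activity log are imputed before
validity is assessed: nonwear minutes overlapping a logged bout receive the
activity's compendium MET value and count as MVPA when that value reaches
the MET cut. Imputed minutes count toward *both* the 70% fraction and
percent MVPA — since the point of imputation is to rescue windows (and
participants) that would otherwise be discarded, letting it affect only the
outcome but not validity would defeat its purpose. Worn minutes are never
altered, which the tests assert as a conservation property.

Two screening designs are provided. `item_wise` retention decides per
(participant, window type); `whole_week` — the traditional design — keeps a
participant only when every scheduled window type meets its requirement.
Item-wise retention is therefore a superset of whole-week retention for
every item, which is exactly why the segmented design maximises calibration
sample sizes; the test suite checks the superset relation on every
simulated cohort rather than any particular pair of counts.

## The calibration model

For each activity item, ordinary least squares on the item-wise retained
rows:

\[
\mathrm{MVPA}_{i} = \beta_0 + \beta_1\,\mathrm{age}_i +
\beta_2\,\mathrm{gender}_i + \beta_3\,\mathrm{score}_i + \varepsilon_i,
\]

where the outcome is the participant's percent time in MVPA averaged over
the valid occurrences of the item's window (equal weight per occurrence),
age is continuous years, and gender is coded 0 = female, 1 = male. Working
on the percent scale keeps coefficients comparable across windows of very
different lengths; conversion to minutes happens only at the composite
stage.

Not every item is linearly related to measured activity: for some (PE is
the canonical case) observed MVPA rises across the lower scores and then
plateaus at the top of the scale. The score term can therefore be entered
*categorically* — one effect per observed score level — which fits any
monotone or plateauing shape. `select_encoding()` fits both encodings and
keeps the categorical one only when it lowers the selection criterion.

**Why BIC is the default criterion.** The categorical encoding adds three
parameters on a 5-point scale. Under a truly linear relation the deviance
gain of those parameters is approximately chi-squared with 3 degrees of
freedom, so AIC-family criteria (threshold about 6) wrongly prefer the
categorical encoding in roughly 10% of samples no matter how large n gets.
BIC's threshold grows with `log(n)`, making the choice consistent: at the
package's reference size (n = 500 per item) the false-selection rate under
linearity is far below 1%, while a clear plateau (slope 8%/score to a knot
at 4, residual SD 6) yields a noncentrality near 70, far above BIC's
threshold of about 18.6, so the plateau is still detected essentially
always. `criterion = "aicc"` or `"aic"` remain available.

Fitting floors: 10 rows per estimated coefficient by default. A constant
response leaves the score slope inestimable; the linear encoding then fits
demographics only and pins the slope at zero, and `select_encoding()` falls
back to linear with a warning.

## Composites

Each item's predicted percent MVPA (clipped to [0, 100]; the outcome is not
transformed, a documented simplicity trade-off) is converted to weekly
minutes as `pct/100 x scheduled window minutes x weekly frequency`:
weekday windows count 5 times, weekend windows once, and recess/PE/lunch
their scheduled number of dates. School and out-of-school composites sum
their sections; the weekly total is their sum. A missing item response
contributes the model's prediction at the calibration-sample mean score and
is flagged (or skipped, by option).

## Evaluation

*Agreement.* Individual error for participant *i* is
`(pred_i - obs_i) / mean(obs) x 100`; the group error is the same formula
applied to the two means. Because the group error is the mean of the
individual errors, `|group| <= mean|individual|` is an identity — the
statistical content of "aggregation dilutes error" — and the tests verify
the implementation reproduces it on every simulated cohort.

*Equivalence.* Group-level agreement is tested with two one-sided tests
(TOST): compute the paired differences, form the two one-sided 95%
confidence bounds `mean(d) -/+ t_{0.95, n-1} se`, and declare equivalence
when both lie inside ±10% of the observed (accelerometer) group mean. Note
that the two one-sided 95% bounds *are* the endpoints of the 90% two-sided
interval — the two descriptions sometimes treated as different procedures
are numerically identical, so the package exposes only `alpha`. The region
defaults to 10% and is configurable. With a degenerate zero-variance
difference the verdict comes from the constant difference alone. The TOST
size property — at a true difference pinned exactly on the boundary,
equivalence is declared in about 5% of replicates — is checked by
simulation with the reference held fixed, since a sampled reference would
smear the boundary.

*Power.* Sample-size planning uses the R²-change F test: effect size
`f² = (R²_full - R²_reduced)/(1 - R²_full)`, noncentrality `n f²`,
`df1` = number of tested predictors, `df2 = n - p_full - 1`. With the
defaults (R² 0.35 vs 0.25, three predictors in the full model, one tested,
alpha 0.05, power 0.80) the required n is 54. The reduced model is taken as
age + gender, so one predictor (the item score) is tested; the "random
factors" phrasing sometimes attached to such calculations is not modelled —
only the two R² values enter, so the computation is fixed-effects
R²-change power.

## The synthetic cohort simulator

No public dataset pairs segmented-day responses with minute-level monitor
records, so the package ships a simulator whose defaults encode the study
conditions the pipeline targets:

* cohort of 300 by default, 60/20/20 elementary/middle/high (the age mix of
  the reported nonwear subset), balanced genders, four seasons;
* latent true percent MVPA per (participant, window type) from a normal
  truncated to [0, 100], centred on window-specific means (highest at
  recess/PE, lowest before school), shifted by age (-0.8 %/year), gender
  (+5% male) and season, between-participant SD 12; occurrence-level
  day-to-day SD 8. These magnitudes are chosen for face validity against
  the youth accelerometry literature, not taken from any single study;
* responses: each item's score is a monotone link from the participant's
  window truth plus Gaussian reporting noise (SD 0.6 score units), rounded
  and clipped to the 1--5 scale. The PE item's link plateaus from score 4;
  all other items are linear;
* streams: minute MVPA flags are Bernoulli draws around the occurrence
  truth (plus device noise, SD 3), so worn-minute percent MVPA is an
  unbiased but noisy window estimate;
* nonwear: Poisson bouts per day at rates 0.4/0.8/1.2 for
  elementary/middle/high — nonwear increasing with age is a qualitative
  pattern the generator reproduces and the tests assert — with lognormal
  durations around 45 min, about half documented in the activity log.

Each participant draws from an own sub-seeded RNG stream, so enlarging a
cohort never reshuffles earlier participants, and the whole object is
byte-reproducible from one seed.

Two deliberate simplifications matter for interpreting green tests. First,
all age groups get daily recess in the default schedules so that every item
is estimable within every cohort; real secondary schools often have none,
which in the field simply thins that item's calibration sample. Second, the
generator's reporting process is exactly the monotone-link-plus-noise
structure the calibration model assumes. Passing tests therefore show the
machinery is correct and unbiased *under the assumed error structure*; they
cannot show that real children's recall errors are Gaussian, uncorrelated
with activity, or plateau-free elsewhere — with real data those are
empirical questions for cross-validation.

Two generator modes exist purely for verification. `discretize_scores =
FALSE` keeps continuous latent scores, because exact (1e-8) coefficient
recovery is provably impossible from rounded ordinal scores;
`cohort_truth_summaries()` exposes the latent truth as a perfect-device
window table for the same reason. `simulate_item_data()` draws one item's
calibration rows directly from the regression model — the generator used
for the Monte Carlo bias and encoding-selection studies, where the estimand
must be known exactly. The `detail = "summary"` mode skips minute-level
stream generation and emits window summaries directly (worn minutes minus
bout overlap, binomial MVPA counts); large-n evaluation studies use it, and
its marginal distribution matches the stream path by construction.

## Problem sizes

The test and verification studies use: 50 random schedule/stream pairs for
the segmentation oracle; five 60-participant cohorts for screening
dominance; 150 noiseless participants for exact recovery; 200 replicates of
n = 500 for Monte Carlo coefficient bias; 100 replicates per generator for
encoding selection; 2000 replicates of n = 50 for TOST size; and held-out
cross-validation on 120- vs 1200-participant cohorts for the error-dilution
contrast. These sizes make every Monte Carlo standard error small relative
to its assertion band while keeping a full run inside a few minutes on one
core.

## Known limitations

* OLS ignores error in the criterion itself; no regression-calibration or
  attenuation correction is attempted.
* Predictions are clipped to [0, 100] rather than modelled on a bounded
  scale; with extreme covariates the clipping introduces (documented) bias.
* Season is carried in the simulator but not entered as a model covariate
  by default; the calibration equations use age, gender and score only.
* The bundled item prompts are placeholders, not validated wording, and the
  bundled MET table is a small testing default — studies should supply
  their own compendium excerpt.
* Only 1-minute epochs are supported, and nonwear detection is assumed to
  come from the device (as with multi-sensor armbands), not inferred from
  count patterns.
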