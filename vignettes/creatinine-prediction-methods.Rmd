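---
title: "Predicting one-day creatinine excretion in schoolchildren: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting one-day creatinine excretion in schoolchildren}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crekid)
```

## The problem

Spot-urine concentrations of nutrients and environmental chemicals are
routinely divided by the spot creatinine (Cre) concentration to correct
for urine dilution, and then multiplied by the person's one-day Cre
excretion to obtain a daily excretion estimate. Daily Cre excretion is
roughly constant within an individual but varies strongly with sex,
age, body size and muscle mass, and in children it roughly doubles
between the first and seventh school grades. Collecting true 24-hour
urine from children is burdensome, so a prediction equation from easily
measured covariates is the practical alternative. This package
implements such an equation for children aged 6–12 years, together with
the machinery used to build and judge it: an estimator battery,
Bland–Altman agreement, a trend-bias recalibration operator, a
Lasso-based model-development stage, and a spot-urine sodium estimator
driven by the predicted creatinine.

## The reference equation and its recalibration

The base model is linear in sex (coded boy = 1, girl = 2), age in
integer years, and Mosteller body surface area
$\mathrm{BSA} = \sqrt{\mathrm{BH}\cdot\mathrm{BW}/3600}$ (m²):

$$\widehat{\mathrm{cre}}_{24} = -198.96 - 38.54\,\mathrm{sex}
  + 15.43\,\mathrm{age} + 633.73\,\mathrm{BSA} \quad [\mathrm{mg/day}]$$

Least-squares predictions are under-dispersed relative to the
measurements (their variance is the explained share of the outcome
variance), so a Bland–Altman plot of prediction minus measurement
against the pair mean shows a systematic negative slope: the model
overestimates low excretors and underestimates high ones. The one-step
recalibration

$$e \;\longrightarrow\; (1+t)\,e - c$$

stretches the predictions back toward the measured spread. Two details
matter:

- **Orientation of t.** We define $t$ as the OLS slope of
  *(measured − estimated)* on the pair mean — the negative of the
  conventional Bland–Altman slope, which this package reports with
  differences oriented estimated − measured. Only this orientation
  makes the correction contract: writing $e = a\,m$ for dispersion
  $a$, one step maps $a \mapsto a(3-a)/(1+a)$, which converges toward
  1 for any $a \in (0,3)$; using the estimated − measured slope maps
  $a \mapsto a(1+t_{e-m})$ *away* from 1 and amplifies the bias. With
  $t = 0.15$ the residual trend after one step is about 0.01 — an
  order of magnitude smaller — which is why no iteration is performed.
- **Definition of c.** $c = \overline{(1+t)e - m}$, i.e. the mean
  difference that remains *after* scaling. By construction the
  recalibrated series has mean difference exactly zero on the fitting
  sample (assert-able to machine precision). With a mean difference of
  −26 mg/day, $t = 0.15$ and cohort-scale predictions around
  520 mg/day this gives $c \approx 49$.

Applying (t, c) = (0.15, 49) to the base model multiplies every
coefficient by 1.15 and maps the intercept to
$-198.96 \times 1.15 - 49 = -277.804$:

```{r}
cre_model_1r()
```

The published form of this equation prints the intercept as −277.40;
the constructed value differs by 0.40, which we attribute to rounding
during the original derivation. The constructed value is the default
and the printed one is available via
`cre_model_1r(intercept = "printed")`. The published prose also
describes the sex coding as 1/0; we follow the coefficient table's
boy = 1 / girl = 2 coding throughout, since the 1/0 description
reverses the sex-effect direction and is inconsistent with the ×1.15
construction. The coding is a configurable constant, not hard-wired.

## The estimator battery

Methods A–K map a child (plus optional spot or volume data) to mg/day:
weight-based (A–C), a fixed 800 mg/day value (D, justified by a median
FVU concentration of ~104 mg/dL and a typical 800 mL daily volume),
age+weight+height regressions (E), FVU concentration over specific
gravity minus one (F, G), an external method not reproduced here (H, a
registry hook via `register_method_h()`), volume-based (I),
height-based (J) and height/weight-based (K). Two printed formulas are
implemented verbatim but flagged on every use: method I's volume unit
is ambiguous as printed (with mL it yields non-physiologic 10⁴–10⁵
mg/day; the default interprets the volume in dL and a message notes
the choice), and method K's boys branch is negative for all plausible
heights (likely a typographic truncation in its source), so it emits a
suspect-formula warning rather than a silent fix.

## Bland–Altman agreement

`bland_altman()` reports, for difference $d_i = e_i - m_i$ and mean
$a_i = (e_i + m_i)/2$: the fixed error $\bar d$ with a Student-t CI
(n − 1 df), the conventional 95% limits of agreement
$\bar d \pm 1.96\,\mathrm{SD}(d)$ (normal-quantile multiplier, matching
the common implementations), and the proportional error as the OLS
slope of $d$ on $a$ with a two-sided t-test (n − 2 df). When the pair
means have zero variance the trend is undefined and reported as NA with
a warning. Fewer than 3 pairs is an error.

## Model development

The study design this stage reproduces: 26 candidate features
(demographics, anthropometry, LMS z-scores, spot concentrations,
specific gravities, per-hour and per-SG ratios, optionally muscle
mass), an 80/20 train/validation split, Lasso selection with 20-fold
cross-validated lambda tuning on a 100-point logarithmic grid, and OLS
refits of the surviving feature subsets compared by adjusted R².

**Feature-ranking semantics.** The exact ranking procedure behind such
published feature tables is rarely specified, so this package defines
one and documents it. Features are ordered by the step at which they
first enter the Lasso path as the penalty relaxes; the **rank-1 group**
is the shortest CV-optimal *prefix* of that ordering — for each
candidate number of leading features (including zero), an OLS refit on
the prefix is scored by mean out-of-fold R², and the best-scoring
prefix forms rank 1. This mirrors the natural procedure of examining
how the number of selected features affects cross-validated fit and
picking the count with the best mean score. Later features take ranks
2, 3, … by entry group; features that never enter share the last rank;
exactly duplicated columns always share a rank. We chose the prefix
rule over the more obvious "active set at the tuned lambda" because
the latter is unstable under near-collinearity: height and weight can
jointly substitute for BSA at the CV-tuned penalty, dropping the true
generative feature from the selected set in roughly a third of
synthetic replicates, whereas the entry-order prefix recovers
{sex, age, BSA} in ≈95% of replicates (BSA, the strongest marginal
predictor, enters the path first and cannot be displaced). A
standardized-coefficient ranker remains available
(`ranker = "coef"`).

**Subset search.** `subset_search()` enumerates all subsets of a
candidate list (optionally requiring at least one of a must-keep set),
scores each by k-fold out-of-fold R², and reports alongside it an
adjusted score applying the $1-(1-R^2)(n-1)/(n-p-1)$ penalty with the
fold *training* size (the held-out fold of a 20-fold split is too
small for the penalty to be meaningful). Ordering ties break toward
fewer features, then lexicographic names; the fold assignment is fixed
once per search, so the result is invariant to feature column order.

## Sodium estimation

The spot-urine sodium estimator is the power law
$21.98\,(\mathrm{Na}/(\mathrm{Cre}\cdot 10)\cdot
\widehat{\mathrm{cre}}_{24})^{0.392}$ mEq/day. The printed chain
"A/B/10×C" is parsed left-to-right as $(A/B/10)\cdot C$, matching the
original formulation and yielding physiologic outputs. Because the
exponent is below one, predictions are range-compressed: the ratio of
two predictions is the true ratio raised to 0.392, so high intakes are
systematically pulled toward the centre — the mechanism behind the
negative proportional error seen when comparing spot-based sodium
estimates against measured daily excretion. A salt conversion
(1 mEq Na = 0.0585 g NaCl) is provided as a convenience.

## The synthetic cohort generator

No participant-level data are distributed with studies of this kind,
so the generator recreates the statistical structure the analysis
assumes, with every default tied to a published summary statistic:

- n = 204 children, 113:91 boys:girls; integer ages 6–12 drawn from a
  discretized normal giving mean 8.7, SD 1.5.
- Height and weight from an age- and sex-conditional bivariate normal
  (within-cell correlation 0.8, clamped to 90–180 cm / 12–80 kg);
  growth slopes 5.8 cm and 3.2 kg per year; sex offsets derived from
  the printed boy−girl gaps with a zero sex-weighted mean; within-cell
  SDs back-computed so the marginals hit 131.3 ± 10.9 cm and
  28.6 ± 7.2 kg, which puts the mean Mosteller BSA at 1.02 m².
- True one-day Cre excretion: the base model's coefficients plus
  Gaussian noise with SD 69 mg/day (back-derived from the published
  limits of agreement, (109.3 − (−26.0))/1.96), truncated at
  50 mg/day.
- Daily urine volume: lognormal with median 686 mL and the published
  interquartile spread; 3 + Poisson(1.3) collected voids on day 1
  anchored at 07:00 with a ≥30-min inter-void gap (physiologic, and it
  keeps per-hour features well-scaled), a bedtime void near 21:30, and
  the day-2 first void (FVU) near 06:45 completing the 24-hour
  collection — the day-1 first void is not collected, matching the
  field protocol, so the first record of day 1 is the day's second
  void (SVU).
- Per-void creatinine amounts are proportional to the time since the
  previous void, jittered by a *conserving* excretion-rate noise
  (lognormal, SD 0.25 on the log scale): it perturbs spot
  concentrations realistically while leaving the daily total exact.
  Separate multiplicative assay noise (CV 0.05) applies to every
  reported concentration; only this noise breaks the conservation
  identity, so the reconstructed composite differs from the truth by a
  few percent, as a pooled laboratory composite would. With assay
  noise set to zero the composite equals the truth to machine
  precision — a conservation identity the tests assert.
- The overnight FVU is more concentrated than the daily pool by the
  factor 104/71.87 (the ratio of the published FVU and pooled median
  concentrations), implemented by down-weighting its volume share so
  conservation is untouched.
- Sodium and potassium daily excretions are lognormal with medians
  from the published concentration medians times the median volume;
  specific gravity rises linearly with creatinine concentration
  (2.7×10⁻⁴ per mg/dL, noise SD 0.0015, floor 1.001), giving a median
  SG near 1.020.

**What the generator does not emulate**: diet, circadian concentration
rhythm beyond the overnight factor, puberty-stage body-composition
shifts, skewed weight distributions, or real growth-reference
tables — the shipped LMS table (`synthetic_lms_reference()`) is a
smooth synthetic stand-in, and real national references must be
supplied by the user. Passing tests therefore demonstrate the
*machinery* (identities, calibration, recovery, agreement) on data
with the assumed structure, not the clinical validity of any equation
on real children.

## Eligibility and the pipeline

`apply_eligibility()` mirrors the field exclusions: one-day collected
volume strictly below 254 mL (the boundary value is retained), unknown
age, and unrecorded void times (which make spot designation
impossible), each logged with its reason. `run_pipeline()` chains
simulation → composites/spots/features → battery → per-method
Bland–Altman → model development → recalibration → sodium agreement,
fully seeded; method H remains in the agreement table as an NA row
with a "not configured" note unless a callable is registered, so the
eleven-method table shape is preserved. TVU designation takes the
earliest void at or after 15:00 not already designated (the common
phrase "third urine collected after 3 pm" is ambiguous; this reading
needs no assumption about void counts).

## Numerical choices, sizes and limitations

- Problem sizes in the tests and the acceptance script: cohorts of
  204 (the study scale), 200 replicates for coverage, 100 for ranking
  recovery, 500 for recalibration suppression, 200 random instances
  for the agreement oracle — together they run in about two minutes.
- Tolerances: algebraic identities (conservation, zero post-hoc mean
  difference, model/prediction-space commutation) at 1e−9 or machine
  precision; statistical rates at ±2–3 percentage points of nominal.
- Degenerate inputs: zero total volume, non-positive anthropometry,
  SG = 1 in methods F/G, fewer than 3 pairs, zero variance of pair
  means, and rank-deficient designs all raise named errors rather
  than propagating NaN.
- The adjusted-CV score and the prefix ranking are this package's own
  documented definitions of under-specified published procedures;
  alternative choices (1-SE lambda rule, standardized-coefficient
  ranking) are exposed as options.
- Age enters the models in integer years; months are carried for the
  LMS lookups only.
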