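---
title: "Feed-to-milk iodine transfer: models, fitting machinery and dietary scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feed-to-milk iodine transfer: models, fitting machinery and dietary scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactiodine)
```

## The transfer models

The iodine concentration of herd milk is modelled as a log-linear
polynomial in two feed covariates: the iodine concentration of the ration
(`iodineIn`, mg I/kg dry matter) and one goitrogen measure — either the
glucosinolate intake (`gsl`, mmol/day; model 1) or the inclusion rate of
rapeseed cake/meal (`rapeseed`, g/kg DM; model 2). The response is the
natural logarithm of the milk iodine concentration in µg/kg: milk iodine
is a strictly positive quantity whose residual scatter across feeding
trials grows with its level, which the log transform stabilises; it also
makes the back-transformed model multiplicative, the natural scale for a
transfer efficiency.

```{r}
m2 <- milk_iodine_model("model2")
summary(m2)
```

The modelling unit is the *treatment mean* — the average response of one
dietary treatment group in one feeding trial. Between-animal variation
(reported elsewhere at 7–12% of total variance) and lactation-stage
effects are averaged out at that level, so the models describe herds or
groups of cows, never individual animals.

Both cubics are empirical interpolations of the trials behind them, not
mechanistic saturation curves. That shows at the edges: model 2's positive
`rapeseed²` term makes the prediction turn upward past ≈174 g/kg DM, with
no physiological interpretation, and both models steepen unrealistically
above ≈4 mg I/kg DM feed iodine. The packaged validity limits —
`iodine_in` ∈ [0, 4] mg/kg DM, `gsl` ∈ [0, 14] mmol/day, `rapeseed` ∈
[0, 180] g/kg DM — encode this. Predictions outside them are computed
(the published prediction surfaces themselves extend to 5 mg/kg DM) but
always flagged; `strict = TRUE` turns the flag into an error. The limits
are a `validity_ranges()` object and can be overridden deliberately.

Where the two models can be compared directly — goitrogen-free rations —
they agree within 25% in predicted concentration for feed iodine up to
3 mg/kg DM, which is the region the source trials populate densely. Near
the upper validity bound they diverge (model 2 predicts up to ~1.3× model
1 at 4 mg/kg DM, zero goitrogen); we therefore assert the agreement
property on [0, 3] only and regard both models as equally uncertain
above 3.5 mg/kg DM.

## Inversion

`invert_required_iodine()` answers the formulation question: which feed
iodine concentration gives a target milk concentration at a fixed
goitrogen level? The log-prediction is a cubic in `iodineIn` whose
derivative is strictly positive on [0, 4] for both sets of published
coefficients, so the root is unique. The implementation still verifies
monotonicity at call time by a sign scan of the gridded log-prediction
(step 0.01) — a refitted model need not be monotone — then bisects to an
absolute tolerance of 1e-6 on the log scale (≈0.0001% in concentration).
Targets outside `[predict(0), predict(4)]` raise an error that reports the
achievable interval rather than silently clamping.

## The fitting machinery

`milk_iodine_fit()` reconstructs the pipeline that produced the published
coefficients:

1. **Candidate pool** (`build_candidate_terms()`): all monomials in
   `iodineIn` and one goitrogen covariate up to total degree 3 — ten terms
   for two variables.
2. **Stepwise selection** (`stepwise_select()`): at each move the
   excluded candidate with the smallest partial t-test p-value enters if
   below `p_enter`, then the included term with the largest p-value leaves
   if above `p_remove`. Defaults are `p_enter = p_remove = 0.05`,
   matching the published retention criterion (every printed term has
   p < 0.05); the fitting tool the source work used defaults to a removal
   threshold of 0.10, so both knobs are exposed. Ties break
   deterministically: lower total degree first, then lexicographic
   descriptor. With `hierarchy = TRUE` (default) a pure power may enter
   only while its next lower power is present, and an interaction only
   while its main effects are; this is the weakest hierarchy notion
   consistent with both published models (model 1 contains
   `iodineIn:gsl^2` without `iodineIn^2:gsl`). Selection on an exactly
   interpolating fit is stopped: t-statistics computed from numerically
   zero residuals carry no information.
3. **Inference** (`fit_ols()`): ordinary least squares on the log
   response; standard errors from the unbiased residual variance,
   two-sided t-based p-values, and t-quantile confidence intervals. The
   printed tables do not state their CI level; 95% is assumed (it is the
   cited tool's default and reproduces the printed intervals' widths).
   `rmse = sqrt(SSE/(n − p))` and the usual adjusted R².
4. **Cross-validation** (`loo_rmsecv()`): leave-one-out RMSECV via the
   exact hat-matrix identity `e₋ᵢ = eᵢ/(1 − hᵢᵢ)`; the literal n-refit
   loop is kept as `method = "refit"` and the two agree to 1e-10, which
   the test suite asserts.
5. **Study screen** (`study_effect_screen()`): before covariate
   modelling, `log(milk_iodine) ~ study` as a fixed-effect one-way layout
   (dummy coding, first sorted label as reference — the source does not
   state its contrast scheme), reporting the overall F-test, adjusted R²
   and per-level p-values. The source compilation showed no study effect
   and dropped the factor; the screen reproduces that decision path.

The exact entry/removal order of the original tool's path is not
documented anywhere; ours is stated above and is deterministic, so two
runs on the same data always select the same model.

## The synthetic generator

The 69 treatment means behind the published fits were never released, so
`generate_dataset()` draws datasets with the compilation's reported
statistical structure: 69 rows in 10 contiguous study blocks (block sizes
randomized within 3–12), feed iodine uniform on the validity range
[0, 4] mg/kg DM, glucosinolate intake from a normal(20, 24.1 mmol/day)
truncated at zero (the reported study-level mean ± SD; after truncation
the realised mean/SD are 28.6/18.3, which the tests check against the
closed-form truncated-normal moments), and rapeseed inclusion as a 30%
point mass at zero (rapeseed-free control diets — our invention,
configurable) mixed with a uniform on [0, 236] g/kg DM (the highest
inclusion observed in the source trials). Responses are
`exp(Xβ + study offset + ε)` with β a chosen truth model (default: the
packaged model 2), ε ~ N(0, `noise_sd`) with default 0.382 — the published
residual RMSE of that model — and study offsets defaulting to SD 0 because
the source found no study effect (nonzero values exist to test the
screen's power).

What the generator does *not* emulate: the real joint distribution of
iodine and rapeseed across trials (independence is assumed), unequal
within-study covariate designs, measurement error in the covariates, and
any correlation between study size and treatment levels. Passing recovery
tests therefore show the machinery is correct and well calibrated under
the stated structure — not that the published coefficients would be
recovered from the real literature data.

Under these conditions the fixed true term set refits with residual RMSE
inside the chi-square(63 df) band [0.30, 0.47] and ~95% CI coverage of the
generating coefficients; stepwise selection always finds the intercept and
both main effects, finds `iodineIn²` in >90% of replicates, and admits
spurious terms rarely — but recovers the *exact* published six-term set in
only ≈20% of replicates, because `rapeseed²` (published p = 0.029) sits
near the retention threshold at n = 69. Predictive recovery is much
tighter than term-set recovery: the median absolute relative prediction
error of a selected model against the truth inside the validity region is
≈9%. The test suite asserts the stable aggregate facts (always main
effects, exact set in a non-trivial fraction, median error < 15%) rather
than a majority exact-set rate the data-generating conditions do not
support.

## Dietary scenarios

`dairy_intake_table()` packages the Norwegian consumption profiles
(g/day of milk, flavored milk, yoghurt, cheese, whey cheese and cream
products for men, women, 2-year-olds and pregnant women) with product
iodine concentrations (µg/100 g) representative of the current milk level
of 200 µg/kg. Contributions are
`intake × concentration / 100` at full precision;
percent-of-recommendation uses 150/90/175 µg/day. Reported values are
rounded half-up only at presentation — the unrounded pregnant-women total
is 98.44 µg/day (56.25% of 175), which presentation rounds to 98; the
corresponding printed survey total of 99 appears to carry upstream
rounding of the intake grams, and we reproduce the three totals that are
internally consistent (102, 74, 97) and this unrounded fourth.

How cheese iodine tracks the fluid-milk concentration in a scenario is
not defined anywhere, so `intake_vs_milk_concentration()` exposes the
choice: the default `proportional` rule scales every product with
`conc/200` (totals exactly linear in the milk concentration); `milk-only`
scales only the fluid products and holds the cheeses fixed. Both coincide
with the packaged table at 200 µg/kg.

## Numerical choices

* Natural logarithm throughout: `exp` of the model-2 polynomial at
  (1 mg/kg DM, 0) gives 259.8 ≈ the published 260; base-10 does not.
* Coefficients are stored at their printed precision and never re-rounded.
* Presentation rounding is half-away-from-zero (`round_half_up()`), not
  banker's rounding; internal computation is full precision.
* OLS via QR decomposition; rank deficiency is an error naming the
  collinear terms, never a silent drop.
* Degenerate inputs: leverage-1 rows make leave-one-out undefined and are
  reported by row; empty datasets, non-positive responses and rows with
  neither goitrogen covariate are rejected or excluded with an explicit
  message.

The test suite runs its simulations at deliberately modest sizes — 500
replicates for the calibration bands, 30–100 for selection behaviour,
1000 one-way fits for the null-uniformity check, 10⁵ draws for the
distributional oracles — chosen so the full suite completes in well under
a minute while keeping Monte-Carlo error far from each asserted bound.

## Limitations

* No teat-dip or disinfectant iodine pathway, no lactation-stage,
  seasonality or milk-yield terms, and no individual-cow prediction.
* No mixed-effects treatment of the study factor; the fixed-effect screen
  mirrors the source analysis, which dropped the factor.
* The dietary module covers dairy products only — no fish, supplements or
  iodized salt — and group means only, not intake percentiles.
* Fits to user data inherit none of the published validity limits
  automatically beyond the packaged defaults; refitted models should have
  their own covariate ranges considered before inversion or extrapolation.
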