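---
title: "Estimating lean body mass from anthropometry: models, validation statistics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lean body mass from anthropometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbmpe)
```

## The problem

Lean body mass (LBM) — soft tissue plus muscle, excluding fat and bone —
declines with age, and a low LBM predicts excess toxicity from drugs whose
exposure scales with lean mass (cytotoxic chemotherapy, propofol). The
reference measurement, dual-energy X-ray absorptiometry (DXA), is often out of
reach at the bedside, in rural care, or for frail patients. A regression
equation on routinely available covariates is the practical substitute, and
`lbmpe` implements both the equations themselves and the complete machinery
needed to develop such equations and to judge whether one agrees with DXA
well enough to use.

## The prediction equations

The central estimator is the anthropometric equation (here `pe1`), carried at
full precision:

$$\widehat{\mathrm{LBM}} = 22.932326 + 0.684668\,W - 1.137156\,B
  - 0.009213\,A + 9.940015\,[\mathrm{male}]$$

with weight $W$ in kg, BMI $B = W/H^2$ in kg/m², age $A$ in years. Its
development residual scale (SEE) is 3.61 kg. Three siblings add biochemistry
— creatine kinase (`pe2`), CK + hsCRP (`pe3`), CK + hsCRP + LDH (`pe4`) —
and are carried at the two-decimal precision at which they were published.
We deliberately do not reverse-engineer hidden digits for `pe2`–`pe4`: only
printed values are trustworthy, and the package treats the full-precision
coefficients as canonical only where they were actually published (`pe1`).

Three published fat-free-mass (FFM) comparators are included for
benchmarking: Heitmann (linear body-fat mass, sex-specific weight
coefficient, FFM = weight − fat), Janmahasatian (rational form
$9270 W / (6680 + 216 B)$ for men, $9270 W / (8780 + 244 B)$ for women) and
Deurenberg (linear body-fat percent, FFM = $W(1 - \mathrm{pct}/100)$). FFM
and LBM differ by membrane lipids (roughly 3–5% of body weight) and by the
treatment of bone; the package labels each equation's output (`lbm` or
`ffm`) and never converts between them.

Predictions are **never clamped**. Outputs outside $(0, \mathrm{weight})$, or
a body-fat percentage outside $[0, 100]$, raise a warning and are marked in a
`flags` attribute. This matters in practice: the Heitmann equation yields a
*negative* fat mass for a young, lean, light man (age 18, BMI 18, 40 kg), so
a blanket "all estimators stay within physiological range" assumption is
false and the package surfaces the violation instead of hiding it.

### Units and record validation

Units are fixed at the record boundary (kg, m, years, U/L for CK/LDH/AST,
mg/L for hsCRP, g/L for albumin) and validated, never silently converted.
Sex is a required binary field; records with other or missing sex are
rejected rather than imputed. When both height and BMI are supplied, the
stored BMI wins (it reproduces the input exactly) and a warning is emitted if
it disagrees with $W/H^2$ by more than 0.1 kg/m².

## Equation development

`best_subsets()` re-implements the development engine: exhaustive
ordinary-least-squares over every subset of the candidate predictors (all
$2^k - 1$ of them; the canonical pool of ten candidates — sex, age, weight,
height, BMI, albumin, AST, LDH, CK, hsCRP — costs under a thousand fits, so
no stepwise shortcut is taken), ranked within each size by adjusted $R^2$,

$$R^2_{adj} = 1 - (1 - R^2)\frac{n-1}{n-p-1}, \qquad
  \mathrm{SEE} = \sqrt{\frac{\mathrm{SSE}}{n-p-1}}.$$

Design choices where the procedure was under-specified:

* **Ties** in adjusted $R^2$ are broken by the lexicographic order of the
  sorted predictor names, making rankings deterministic.
* **Sex coding** is male = 1, female = 0 everywhere (matching the "if male"
  offsets and the Deurenberg convention).
* **$R^2$ is reported in percent and both plain and adjusted values are
  kept**: published "R2" figures for equations of this family are ambiguous
  about which was meant, so acceptance of a refit is anchored on SEE
  recovery, which is unambiguous.
* **Rank-deficient subsets** (collinear columns) are skipped with a logged
  warning rather than failing the run.
* Row order does not affect fits beyond floating-point noise (the QR
  factorisation is order-dependent in its last bits); the suite checks
  agreement to $10^{-10}$ rather than bit identity.

## The agreement battery

`evaluate_agreement()` assembles one validation-table row from four
statistics.

**Mean error (bias).** $\mathrm{ME} = \overline{(\hat y - y)}$ — positive
when the equation over-estimates DXA. Its 95% CI uses the normal quantile,
$\mathrm{ME} \pm 1.96\, s_d/\sqrt{n}$ (this reconstructs published intervals
exactly, e.g. $1.88 \pm 1.96 \cdot 4.0/\sqrt{52} = (0.79, 2.97)$, whereas a
$t$ quantile would not); the p-value is the paired two-sided $t$-test.

**RMSE (precision).** $\sqrt{\tfrac1n\sum(\hat y_i - y_i)^2}$, with the CI
formed on the mean-squared-error scale ($\mathrm{MSE} \pm 1.96\,
\mathrm{SE}(d^2)$) and square-rooted, floored at zero. The exact CI
construction used in the original analyses is not stated anywhere and cannot
be reverse-engineered from printed values without raw data; this choice is
ours and is documented as such. The identity
$\mathrm{RMSE}^2 = \mathrm{ME}^2 + \tfrac1n\sum(d_i - \bar d)^2$ holds to
machine precision and is enforced by tests.

**Lin's concordance correlation.** With population ($1/n$) moments, as in
Lin's definition,

$$\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},
 \qquad \rho_c = \rho\, C_b,$$

where $\rho$ is the Pearson correlation (ratio-invariant to the $1/n$ versus
$1/(n-1)$ choice) and $C_b \in (0, 1]$ penalises location/scale shift. The
factorisation is exact in this parameterisation and tested to machine
precision. The CI uses the Fisher $z$-transform with Lin's 1989 asymptotic
standard error (the original analyses cite Lin but not a CI method).
`check_published_consistency()` applies the factorisation to the transcribed
published tables: honestly rounded three-decimal triples can deviate by at
most about 0.002, and the three rows that deviate further (one prints
$C_b$ identical to $R$; one prints a $\rho_c$ equal to its own lower CI
bound) are thereby identified as typographical errors.

**Bland–Altman limits.** $\bar d \pm 1.96\, s_d$ with the sample SD and no
CI around the limits (none were published). Differences default to
**reference − prediction**, the orientation of the published tables — note
that this is opposite in sign to ME, so a +1.88 kg over-estimation appears as
limits centred on −1.88; both orientations are available and the discrepancy
is deliberate, reproducing the tables without hiding the inconsistency.
Percentage limits divide by the mean paired average $(\hat y + y)/2$; the
published percentage denominators were unstated, so this is flagged as an
approximation.

Missing values in either vector are rejected, not silently pairwise-deleted,
unless `drop_missing = TRUE` — silent deletion corrupts $n$.

## Stratification

Published subgroup tables group by sex, age (50–64, 65–79, ≥80 years) and BMI
(<22, 22–<27, 27–<30, ≥30 kg/m²). Bins are half-open $[\ell, u)$: BMI exactly
27 falls in 27–<30 and age exactly 80 in ≥80. The "50–64" label with a 65
lower neighbour implies integer-year boundaries; on continuous ages we
implement $[50, 65)$, so an age of 64.5 belongs to 50–64 (whether the
original analysis rounded or truncated such ages is not stated; the half-open
continuous convention reproduces the printed labels either way). Each
dimension partitions the cohort independently, as in the published tables;
records missing a field or outside the declared range are reported
unassignable, never silently dropped.

Cross-densitometer correction is a user-supplied linear transform
(`machine_correction()`), defaulting to the identity: the numeric factor used
to convert between specific machines was never printed, so it must come from
the user's own cross-calibration.

## The synthetic-cohort generator

Because the original subject-level data were never deposited, the package
ships a generator whose presets carry the printed cohort summaries as their
parameters: `"CASA"` (development cohort, n = 188; age 49.2 [17.0] years on
[18, 83], BMI 26.7 [5.2] kg/m² on [16, 45], CK 114.3 [66.0] U/L, LDH 175.0
[37.4] U/L, albumin 39.1 [3.1] g/L), `"VC"` (n = 52) and `"NWAHS-FAMAS"`
(n = 2287 with 1436 men; age and BMI are size-weighted blends of the two
component studies, 63.96 years and 28.32 kg/m²). Marginals are independent
normals truncated to plausibility bounds, sampled by inverse CDF; weight is
derived as $B H^2$, never sampled, so BMI is consistent by construction.
Reference LBM is the generating equation (default: full-precision `pe1`)
plus $N(0, 3.61^2)$ noise — the development SEE — plus any injected
`nuisance_effects`.

What the generator does **not** emulate, and hence what passing tests do not
show about real data:

* No covariance structure: only means and SDs were published, so age, BMI and
  biochemistry are drawn independently, whereas real anthropometry is
  correlated. Recovery results demonstrate correctness of the machinery, not
  field performance.
* Height (1.70 [0.10] m), hsCRP (2.0 [2.0] mg/L) and AST (24 [8] U/L)
  marginals were never published; these defaults are declared assumptions.
* Biochemistry is pure noise with respect to LBM unless a nuisance effect
  injects a true coefficient — which is exactly what makes the generator
  useful for testing that subset selection excludes uninformative predictors
  and recovers injected ones.
* Residuals are homoscedastic Gaussian; real DXA disagreement can be
  proportional to size.

Each cohort is drawn under its own seed without touching the caller's RNG
stream, and ground truth (seed, generating coefficients, noise SD, exact
truncated-normal marginal means) travels with the cohort as provenance.

## Numerical choices and problem sizes

* Truncated-normal draws use $\Phi^{-1}(p_\ell + U (p_u - p_\ell))$;
  truncation windows carrying essentially zero mass (< 1e-12) are a
  configuration error rather than an infinite loop.
* Degenerate agreement inputs (zero variance, fewer than 2–3 pairs, length
  mismatches) raise classed errors; `pred = ref` short-circuits the CCC
  interval to a point.
* Test and acceptance simulations use n = 5,000 for coefficient/SEE recovery
  (coefficient Monte-Carlo SEs ≈ 0.1 kg for the sex offset, SEE SE ≈ 0.036
  kg, so 5% tolerances are comfortable but not vacuous) and n = 10,000–20,000
  for moment checks — sizes chosen to keep Monte-Carlo error an order of
  magnitude under the assertion tolerances while the whole suite runs in
  seconds.

## Known limitations

* The equations were developed in Caucasian adults; nothing here validates
  them for other ethnicities, children, or clinical populations with altered
  body composition (ascites, renal failure).
* `pe2`–`pe4` coefficients are two-decimal; with CK in the hundreds of U/L,
  the rounding of its 0.01–0.02 coefficient contributes up to a few tenths of
  a kg of quantisation error that cannot be removed.
* The RMSE confidence interval construction is the package's own (see above);
  published RMSE CIs are not exactly reproducible by any construction without
  raw data.
* Percentage limits of agreement depend on an unstated denominator
  convention.
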