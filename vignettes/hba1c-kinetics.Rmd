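---
title: "Interpreting early HbA1c: the two-curve mixture model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting early HbA1c: the two-curve mixture model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hba1ckin)
```

## The model

Glycated hemoglobin (HbA1c) forms continuously, nonenzymatically and
essentially irreversibly over the life of an erythrocyte, at a rate
proportional to the ambient mean plasma glucose (MPG). Erythrocytes live
about 120 days and are replaced at a constant rate, so at any moment the
circulating population is uniformly distributed in age: 1/120 of the
red-cell mass is one day old, 1/120 two days old, and so on. `hba1ckin`
builds everything on three premises:

1. **A linear conversion between steady-state HbA1c and MPG.** The
   package defaults to the DCCT regression
   \(MPG = 35.6 \times HbA1c - 77.3\) (mg/dl); the ADAG anchors are
   available as a tabulated alternative (no closed form is carried for
   ADAG, only lookup and linear interpolation between its anchors).

2. **Linear per-cell accumulation.** A cell of age \(m\) months living at
   glucose sustaining steady-state HbA1c \(H\) carries \(H\,m/2\) percent
   HbA1c — zero at birth, \(2H\) at the end of its 4-month life. With a
   uniform age distribution the population mean is the arithmetic mean of
   the youngest and oldest cells, i.e. exactly \(H\).

3. **A step change in control.** When glycemic control jumps from the
   curve sustaining \(Hb_1\) to the curve sustaining \(Hb_x\), the
   laboratory HbA1c measured \(m\) months later (\(0 < m \le 4\)) mixes
   survivors of the old curve with cells born after the change:

   \[
   Hb_{mix}(m) \;=\; \frac{Hb_x\,(8m - m^2) + Hb_1\,(m^2 - 8m + 16)}{16}.
   \]

   The surviving group contributes its pre-change mean
   \(\Phi_{mean} = Hb_1 (4-m)/4\) plus the glycation it accrued on the
   new curve, \(\Delta\Phi_{mean} = Hb_x\, m/2\); the newborn group
   contributes \(\Phi_2 = Hb_x\, m/4\); the mixture weights are the group
   masses \((4-m)/4\) and \(m/4\). `hb_mix()` exposes the closed form and
   `phi_upper()`, `phi_mean()`, `delta_phi_mean()`, `phi1()`, `phi2()`
   the intermediate cohort statistics.

Because the mixture formula is affine and its coefficients sum to one,
\(Hb_{mix}\) always lies between \(Hb_1\) and \(Hb_x\), approaches
\(Hb_x\) monotonically, and is invertible in closed form:

\[
Hb_x \;=\; \frac{16\,Hb_{mix} - Hb_1\,(m^2 - 8m + 16)}{8m - m^2},
\]

implemented by `invert_hbx()` (and `invert_mpgx()` in glucose space).
This inversion is the package's clinical payload: it recovers the *true*
recent glucose level from an HbA1c drawn before full erythrocyte
turnover, which a naive conversion of \(Hb_{mix}\) misses. The completed
fraction of the total change, \(100\,(8m-m^2)/16\), is independent of
the endpoints (`percent_change()`): 43.75% of the change is done after
one month, 75% after two, 100% only at four — the characteristic prompt
early fall after tightening control.

## Parameters and conventions

* **Time unit.** A "month" is exactly 30 days and the lifespan exactly
  120 days = 4 months; fractional `m` is allowed. `m = 0` is excluded
  from mixture/inversion domains (no measurement is taken zero months
  later); limits at `m -> 0+` are covered by property tests.
* **Intercept modes.** The printed inverse regression uses intercept
  2.17, whereas the true inverse of the forward map has intercept
  \(77.3/35.6 = 2.17135\). Both are available everywhere
  (`intercept_mode = "paper"` / `"exact"`); the default is `"paper"`
  because it reproduces the published tables digit for digit, while
  `"exact"` makes forward∘inverse the identity to 1e−9 and is what the
  self-consistency tests use.
* **MPG-space constants.** The glucose-space mixture and inversion use
  constants \(16 \times 35.6\) and \(16 \times 77.3\); their
  conventionally rounded forms 570 and 1236 are the `"paper"` constant
  mode (default, matching published error tables). The two conventions
  differ in recovered glucose by exactly \((0.4\,Hb_{mix} + 0.8)/(8m -
  m^2)\) mg/dl — under 1.5 mg/dl once a month has elapsed, up to ~1.7
  mg/dl at half a month.
* **Display rounding** is half-away-from-zero (`round_half_out()`), the
  clinical-table convention; no raw operation ever rounds.
* **Units.** HbA1c in percent, glucose in mg/dl (mmol/l anchors are
  stored verbatim in the reference tables; 18.016 mg/dl per mmol/l where
  a conversion is ever needed). IFCC mmol/mol units are out of scope.

## The cohort simulator

`init_steady_state()`, `cohort_step()` and `simulate_cohort()` implement
the model without any closed form: 120 equal-mass daily age cohorts,
each day every survivor gains `steady_hba1c(mpg_today)/60` percent, the
oldest cohort dies and a newborn enters. Design choices:

* **Mid-day convention.** Cohorts are evaluated at ages \(a + 0.5\) days
  (the newborn enters with half a daily increment). This makes the
  discrete steady-state mean equal the continuous arithmetic-mean result
  *exactly* instead of with an \(O(1/120)\) bias, and — at whole-day
  elapsed times — makes the simulated step change agree with the
  closed-form mixture to machine precision when forcing is given in
  HbA1c space. The 0.05-percentage-point tolerance used in the
  oracle-equivalence tests is therefore dominated by intercept-mode
  differences when states are initialized from mg/dl, not by
  discretization.
* **Piecewise-constant forcing**: each day's increment is set by that
  day's glucose alone, the natural discrete reading of the linear-rate
  premise. Arbitrary daily trajectories (CSV columns `day`,
  `mpg_mg_dl`) generalize the two-curve scenario.
* **Determinism.** The model has no stochastic component; the simulator
  takes no seed.

What the simulator does *not* emulate: inter-individual variation in
glycation rate, distributed (rather than fixed) erythrocyte lifespans —
hemoglobinopathies in particular — reticulocyte dynamics, glycation
saturation, and assay noise. Agreement between simulator and closed
forms therefore validates the internal consistency of the model, not its
fidelity to any patient population.

## Error grids and the masking rule

`error_grid()` tabulates, over baseline glucose (columns) and measured
HbA1c (rows), the relative error committed by converting \(Hb_{mix}\)
directly to glucose instead of inverting the mixture:
\(100\,(1 - MPG_{crude}/MPG_x)\). Negative cells mean the crude
conversion overestimates glucose (control recently improved), positive
cells underestimation; magnitudes grow with the baseline/measurement
mismatch and shrink as the interval lengthens.

Published versions of these tables drop extreme cells as "out of
range" without stating a rule. The package masks a cell when (i) the
implied new-curve HbA1c leaves a configurable plausibility envelope
(default 0–20%), (ii) the recovered glucose is non-positive, or (iii)
the absolute error exceeds a configurable cap (default 55%). We adopted
the cap after checking the envelope rule alone against the published
2-month table: every implied \(Hb_x\) on that grid lies between 2% and
18%, so an HbA1c envelope cannot produce the blank corners, whereas the
55% cap reproduces the published blank pattern cell for cell (and
correctly leaves the 3-month table unmasked). Masked cells are still
computed and carried in the object — only display and CSV output blank
them — and non-physiological inversions are flagged, never raised or
clamped, because the grids legitimately tabulate such regimes.

Two caveats inherited from the published account, both handled as
documented discrepancies rather than targets: the printed half-month
inversion value 6.93% does not follow from the inversion formula (which
gives 7.733% for \(Hb_{mix}=11\), \(Hb_1=12\), \(m=0.5\); 6.93
corresponds to \(m \approx 0.417\)), so the package asserts the exact
inverse-identity property instead; and the printed third/fourth-month
change percentages (17%/8%, cumulative 92%) disagree with the model's
own 18.75%/6.25%/93.75%, so only the first-month, second-month and
terminal values are treated as anchors. Individual error-table cells
are likewise irreproducible to the printed digit under either constant
convention (the original rounding path is unrecoverable); tests assert
their sign, masking, near-zero diagonal and monotonicity structure
instead.

## Numerical and testing notes

All closed forms are exact rational arithmetic in doubles; tolerances in
the test suite are 1e−9 to 1e−12 for algebraic identities, 0.05
percentage points for simulator-versus-closed-form equivalence (5×5
endpoint grid on [4, 14]² × five elapsed times, plus a 25-scenario
randomized grid behind `generate_fixtures()`, fixed seed 20100829), and
published-anchor equality at the printed precision. Simulations in the
default suite cover at most 480 days × a few hundred populations and run
in seconds. The `evaluate_fixtures()` bundle tags every expectation
`paper` (printed anchor), `trivial` (holds by construction) or `derived`
(computed by an independent route) so the provenance of each expected
value is explicit.

## Known limitations

The model is a single deterministic step change within one lifespan:
multiple changes inside a 4-month window are handled only by the
simulator, not in closed form. The DCCT regression coefficients are
taken as given, not refitted, and no measurement uncertainty is
propagated through the inversion — recovered \(MPG_x\) is exquisitely
sensitive to \(Hb_{mix}\) at small \(m\) (the denominator \(8m - m^2\)),
which is precisely why early measurements mislead naive conversion in
the first place.
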