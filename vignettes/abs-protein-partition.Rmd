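---
title: "Modelling ionic-liquid aqueous biphasic systems for protein partition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ionic-liquid aqueous biphasic systems for protein partition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filabs)
```

## The workflow this package models

Aqueous biphasic systems (ABS) form when two water-soluble solutes — here
an ionic liquid (IL), possibly fluorinated (FIL), and a salting-out agent
such as K~3~PO~4~, a carbohydrate, or choline dihydrogen phosphate — exceed
threshold concentrations and demix into two water-rich liquid phases.
Proteins partition between those phases, which makes ABS a mild
liquid–liquid extraction platform. A complete characterisation couples:

1. the **phase diagram** (binodal curve and tie-lines),
2. the **partition outcome** (extraction efficiency per phase),
3. **protein quality** in each phase: binding of the phase formers to the
   protein (MST dissociation constants), thermal stability (DSC melting
   temperatures), and enzymatic function (turbidity-decay activity).

`filabs` implements the quantitative core of each step plus seeded
generators that emulate every instrument, so the full analysis is testable
with no measurements on hand.

## Binodal curve

The solubility boundary is described by the empirical three-parameter
Merchuck form

$$Y = A\,\exp\!\left(B X^{0.5} - C X^{3}\right),$$

with $Y$ the IL weight percent and $X$ the weight percent of the second
phase former. A literal polynomial variant $Y = A(BX^{0.5} - CX^3)$ is
retained behind `form = "literal"` for comparison, but it cannot reproduce
sigmoidal binodals and is not the default. Fitting (`fit_binodal()`) is
plain least squares via Levenberg–Marquardt, multi-started from a fixed
deterministic grid of sign/magnitude patterns for $(A, B, C)$ — no random
restarts, so a given data set always yields the same fit. Fitting is done
in wt% coordinates, the coordinates in which cloud-point titrations are
recorded; molality-axis displays are obtained by converting the fitted
curve with `wtpct_to_molality()` (moles of solute per kilogram of *water*,
the ternary-diagram convention), never by refitting.

On noiseless synthetic data the fit recovers the generating parameters to
better than $10^{-6}$ relative; the test suite asserts this together with
consistency as the number of noisy points grows.

```{r}
truth <- binodal_model(80, -0.3, 5e-5)
pts <- gen_binodal(truth, n = 20, noise_sd = 0.3, seed = 1)
fit_binodal(pts)
```

`classify_mixture()` labels a composition monophasic, biphasic, or on the
curve within a 10^-6^ wt% band — purely numerical, far below the ±10^-4^ g
gravimetric resolution of the underlying titrations.

## Tie-lines

A tie-line connects the compositions of the two coexisting phases; any
global mixture on it splits into those phases with mass fractions given by
the lever rule. The gravimetric determination poses four equations: both
endpoints lie on the binodal, and the lever rule holds on each composition
axis, with $\alpha$ the measured IL-rich phase mass over total mass:

$$Y_{IL} = \frac{Y_m}{\alpha} - \frac{1-\alpha}{\alpha} Y_{non},
\qquad
X_{IL} = \frac{X_m}{\alpha} - \frac{1-\alpha}{\alpha} X_{non}.$$

Because the $X$-axis lever rule is linear, the system reduces *exactly* to
one unknown, the non-IL-rich endpoint abscissa $X_{non}$. `solve_tieline()`
brackets that scalar equation on the admissible interval
($X_{non} > X_m$, $X_{IL} \ge 0$, everything inside $[0, 100]$ wt%) and
solves it with Brent's method plus a Newton polish; this is more robust
than a damped 2-D Newton iteration because the bracket guarantees
convergence whenever a physical root exists. Residuals of all four
equations are verified below $10^{-10}$ and forward-constructed cases
(endpoints chosen on a known binodal, mixture built with the lever rule)
are recovered to $10^{-8}$ with mass balance closed to $10^{-10}$ — the
test suite runs 100 random such constructions. The IL-rich endpoint is
identified as the one with larger IL content, matching the IL-rich bottom
phase of these systems; $\alpha$ always denotes the IL-rich (not top)
phase fraction, and the complementary convention is handled by explicit
complementation only.

```{r}
m <- binodal_model(80, -0.3, 5e-5)
tl <- solve_tieline(tieline_problem(m, x_m = 6, y_m = 45, alpha = 0.6))
tl
```

`lever_rule_alpha()` inverts the construction, recovering $\alpha$ per
axis from a mixture and its endpoints and reporting the inter-axis closure
as a consistency diagnostic.

## Composition bookkeeping

`validate_composition()` accepts ternary compositions whose sum deviates
from 100 wt% by at most 0.5 (gravimetric rounding) and rescales them to
close exactly. Published *phase* compositions are a different matter:
measured coexisting-phase rows in the packaged `abs_phase_table()` deviate
from closure by up to ≈3 wt% (water content, IL and non-IL assayed by
independent methods). Those rows are stored exactly as printed; loading
them through the validator requires `normalize = FALSE` with an explicit,
wider envelope, so the closure deviation is flagged rather than silently
repaired.

## Extraction efficiency

Partition is summarised as the percentage of total protein mass in the
IL/FIL-rich phase,

$$EE\% = 100\,\frac{m^{IL\text{-}rp}}{m^{IL\text{-}rp} + m^{non\text{-}IL\text{-}rp}},$$

always relative to the IL-rich phase, so
`extraction_efficiency(a, b) + extraction_efficiency(b, a) = 100` exactly
and enrichment direction is a derived label (`ee >= 50`). Replicate
uncertainty is the SD over replicate-level EE values, matching how
triplicate partition experiments are summarised, not a per-phase error
propagation. `linear_calibration()` provides the supporting
standards-line inversion and refuses extrapolation beyond 10% of the
calibrated range.

## MST binding isotherms

Microscale thermophoresis titrates a constant concentration of
fluorescently labeled protein (0.41 µM here) against a 16-point twofold
serial dilution of ligand and records normalized fluorescence. The
response is modelled with the exact 1:1 mass-action solution

$$f_b = \frac{(L + T + K_d) - \sqrt{(L + T + K_d)^2 - 4LT}}{2T},$$

evaluated in the cancellation-free form $2L/(S + \sqrt{S^2 - 4LT})$. The
exact quadratic is used even though $T \ll K_d$ throughout (it reduces to
the hyperbola $L/(L+K_d)$ in that limit and is correct in all regimes).
`fit_kd()` estimates $(K_d, f_{unbound}, f_{bound})$ by nonlinear least
squares with both plateaus free — normalization fixes neither — and
requires at least 8 points spanning two decades.
`capillary_quality_filter()` reproduces the instrument-software rule of
discarding capillaries above 50 mM ligand (fluorescence inhomogeneity at
high surfactant loadings).

Two decisions merit note:

* **No-binding calls.** A titration is declared "no binding detected"
  when the *realized response swing* — fitted amplitude times the span of
  the fitted fraction-bound curve over the sampled ligand range — is
  below 3× the residual SD. The raw amplitude parameter is the wrong
  statistic: when the fitted curve is flat across the series the plateaus
  are unidentifiable and $|f_{bound} - f_{unbound}|$ can be arbitrarily
  inflated on pure noise.
* **Noise convention.** The generator's default plateaus are 0 and 1, so
  its `noise_sd` is a fraction of the full binding amplitude; "2% noise"
  means `noise_sd = 0.02`. That is the noise level at which the
  parameter-recovery checks are run.

```{r}
ser <- gen_titration(kd = 1.27, start_mM = 34, noise_sd = 0.02, seed = 42)
fit_kd(ser)
```

Recovery behaviour at those conditions: over 200 replicates per affinity,
the median recovered $K_d$ for generating values between 0.5 and 10 mM
stays well inside the published ± intervals (the acceptance script
recomputes exactly this).

## DSC two-state thermograms

Thermal unfolding is modelled as a single folded ⇌ unfolded equilibrium
with van't Hoff enthalpy $\Delta H$ and midpoint $T_m$ (Kelvin
internally, Celsius in all interfaces):

$$K(T) = \exp\!\left[\frac{\Delta H}{R}\left(\frac{1}{T_m} -
\frac{1}{T}\right)\right], \qquad
C_p^{exc}(T) = s\,\frac{\Delta H^2}{R T^2}\,\frac{K}{(1+K)^2}.$$

The single amplitude factor $s$ absorbs instrument units and the
calorimetric/van't Hoff enthalpy ratio; this scaled two-state form is our
reconstruction of the vendor's undocumented "two-state scaled" model and
is flagged as such. The peak area equals $s\,\Delta H$ and the peak
maximum sits at $T_m$ to first order — the $1/T^2$ prefactor shifts the
true maximum about 0.07 °C below $T_m$ at 400 kJ/mol, which matters for
argmax-based initialisation but not for the fit itself. $\Delta S =
\Delta H / T_m$, and the stability curve $\Delta G(T) = \Delta H - T
\Delta S$ vanishes at $T_m$ by construction.

`subtract_baseline()` fits a cubic (configurable) to the signal outside an
exclusion window of ±8 °C around the peak, re-centring the window once on
the corrected argmax. Eight degrees suits transitions of ≳700 kJ/mol;
broader peaks (≈500 kJ/mol, FWHM ≈ 7 °C) leave tails under the baseline
points and benefit from `exclude_halfwidth = 12`. `fit_two_state()` uses
analytic starts (argmax for $T_m$; height/area for $\Delta H$ and $s$) and
recovers noiseless parameters at machine precision; a peak is required to
exceed 3× the off-peak SD before fitting is attempted.

`multi_transition_fit()` fits a sum of $k \le 4$ components jointly,
initialising midpoints at weighted quantiles of the signal mass so that
heavily overlapping peaks (e.g. three transitions spaced ≈3 °C apart in an
aggregating FIL solution) still start near their basins. Components are
reported sorted by $T_m$, with AICc against the $(k-1)$-component refit
for model comparison. Model selection near the noise floor is genuinely
stochastic: on one-component data, a second component occasionally chases
a noise excursion, so parsimony should be judged over replicates, and
non-convergence at large $k$ is itself the "unresolvable peak" diagnostic.

```{r}
tg <- gen_thermogram(74.56, dhs = 500,
                     baseline_coeffs = c(1, 0.01, -1e-4, 5e-7),
                     noise_sd = 0.6, seed = 7)
fit_two_state(subtract_baseline(tg))
```

## Enzymatic activity

Lysozyme activity is read from the linear decrease of A~450~ of a
bacterial-substrate suspension over a fixed 5-minute window sampled every
30 s. `activity_slope()` is an ordinary least-squares slope over the whole
window — no automatic linear-range selection, because the assay protocol
fixes the window — warning when $r^2 < 0.9$. `relative_activity()` maps
the water/buffer reference to 100%, reports the sample/reference slope
ratio, clips non-decaying samples at 0%, and takes replicate SD over
per-replicate relative activities.

## What the generators do and do not emulate

Each generator reproduces the statistical structure the corresponding fit
assumes: Merchuck-curve point clouds with additive Gaussian wt% noise
(log-uniform abscissae, mimicking titration density near the knee),
lever-consistent partitions with multiplicative lognormal concentration
noise, mass-action titrations with Gaussian fnorm noise (and a flat
no-binding mode), two-state peaks on polynomial baselines with Gaussian
cp noise on a 0.1 °C grid, and linear turbidity decays with Gaussian read
noise. Defaults follow the study conditions: 0.41 µM target, 16-point
twofold dilutions, 20–90 °C at 1 °C/min, 2 mg protein in a 2 g system,
triplicates, 2% fnorm noise, 1% peak-height cp noise.

They deliberately do **not** emulate instrument physics: thermophoretic
trace shapes, ligand-induced fluorescence quenching, scan-rate-dependent
(kinetic) unfolding, substrate depletion curvature in the activity assay,
or inter-phase cross-contamination in partition. Passing parameter
recovery on these generators therefore demonstrates correctness of the
estimators under their own noise model, not robustness to every artefact
of real instruments — which is the appropriate scope for a reanalysis
toolkit whose raw data are not deposited.

All generators take an explicit `seed` and restore the caller's RNG
stream, so fixture data are byte-reproducible.

## Numerical choices and problem sizes

* Binodal multi-start grid: $A \in \{y_{max}, 1.5y_{max}\}$, $B \in
  \{-0.02, -0.1, -0.3, -0.8\}$, $C \in \{10^{-6}, 10^{-5}, 10^{-4},
  10^{-3}\}$; best converged RSS wins; ties cannot occur in practice
  (identical optima compare equal).
* Tie-line solver: Brent bracket + Newton polish to residual $< 10^{-10}$;
  non-bracketing cases scanned on a 512-point grid before declaring no
  root; endpoints outside $[0,100]$ wt% rejected as unphysical.
* Kd fit: start at the half-response ligand level (geometric mid-range
  fallback), lower bound $K_d \ge 10^{-9}$ mM.
* DSC: 701-point grids (0.1 °C); multi-transition enthalpies bounded to
  $[1, 10^4]$ kJ/mol.
* Routine test-suite simulation sizes: 200 replicates for Kd recovery and
  no-binding classification, 25–50 for Tm recovery, 40 for binodal bias,
  100 random tie-line constructions — sizes chosen to keep Monte-Carlo
  error an order of magnitude below each asserted tolerance.

## Known limitations

* Single temperature: binodals, tie-lines and partitions are isothermal
  (25 °C data); no temperature dependence is modelled.
* No plait-point estimation or four-parameter binodal variants.
* The two-state DSC model excludes kinetic distortion and absolute heat
  capacity calibration; only $T_m$, $\Delta H$, $\Delta S$, $\Delta G(T)$
  and a relative amplitude are identified.
* MST modelling is 1:1 only; cooperative or multi-site binding of
  surfactant aggregates is summarised by an apparent $K_d$.
* Published phase compositions are reproduced as printed, including their
  closure deviations; no re-closure rule is imposed.
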