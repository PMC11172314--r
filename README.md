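# filabs

Quantitative modelling for protein purification in ionic-liquid **aqueous
biphasic systems** (ABS), including the fluorinated-ionic-liquid (FIL)
systems used to extract and characterise lysozyme.

It is written for bioseparation scientists who need, in one tested
package, the analysis chain behind an ABS partition campaign:

* **Phase diagrams** — fit the Merchuck binodal
  `Y = A·exp(B·X^0.5 − C·X³)` to cloud-point titration data, classify
  mixtures as mono/biphasic, and convert ternary compositions between
  weight percent and molality (mol per kg water).
* **Tie-lines** — solve the gravimetric lever-rule system for the
  coexisting-phase compositions given a mixture point and the measured
  phase-mass fraction α, with tie-line length (TLL) and slope (STL).
* **Partition** — extraction efficiency
  `EE% = 100·m_ILrp / (m_ILrp + m_nonILrp)`, replicate statistics, and
  linear calibration with guarded inverse prediction.
* **Binding (MST)** — 16-point twofold serial dilutions, the exact 1:1
  mass-action isotherm
  `fb = ((L+T+Kd) − sqrt((L+T+Kd)² − 4LT)) / 2T`, capillary quality
  filtering (>50 mM discarded), and nonlinear Kd estimation with a
  principled "no binding detected" call.
* **Thermal stability (DSC)** — polynomial baseline subtraction and
  two-state van't Hoff fitting of excess heat capacity
  `Cp = s·ΔH²/(RT²)·K/(1+K)²` for Tm, ΔH, ΔS and ΔG(T) = ΔH − TΔS,
  including joint fits of up to four overlapping transitions.
* **Enzymatic activity** — turbidity-decay (A450) slopes and relative
  activity against a water/buffer reference (= 100%).
* **Synthetic data** — seeded generators emulating every instrument, so
  the complete pipeline runs and is testable without raw measurements.

Packaged reference tables ship the published phase properties of the
twelve biphasic systems (`abs_phase_table()`), the MST dissociation
constants (`kd_table()`), and the printed melting temperatures
(`tm_table()`).

## Worked example

```r
library(filabs)

## 1. Binodal from (synthetic) cloud-point titration data
truth <- binodal_model(80, -0.3, 5e-5)
pts   <- gen_binodal(truth, n = 20, noise_sd = 0.3, seed = 1)
fit   <- fit_binodal(pts)
fit
#> <binodal model: exponential Merchuck form>
#>   A = 80.0695  B = -0.2998  C = 5.18079e-05
#>   fit: n = 20, RSS = 1.57, max |resid| = 0.7314

## 2. Tie-line for a biphasic mixture (6 wt% salt, 45 wt% IL, alpha = 0.6)
tl <- solve_tieline(tieline_problem(fit, x_m = 6, y_m = 45, alpha = 0.6))
tl
#> <tie-line>
#>   IL-rich endpoint:     (0.9923, 59.3944) wt%
#>   non-IL-rich endpoint: (13.5115, 23.4084) wt%
#>   TLL = 38.1016  STL = -2.8745  alpha = 0.6000  resid = 0.00e+00

## 3. Extraction efficiency of a measured protein mass split
extraction_efficiency(0.9625, 0.0375)
#> [1] 96.25

## 4. Kd from an MST titration (0.41 uM labeled lysozyme)
ser <- gen_titration(kd = 1.27, start_mM = 34, noise_sd = 0.02, seed = 42)
fit_kd(ser)
#> <Kd fit> Kd = 1.249 +/- 0.087 mM (n = 16, RSS = 0.00587)

## 5. Melting temperature from a DSC thermogram
tg <- gen_thermogram(74.56, dhs = 500,
                     baseline_coeffs = c(1, 0.01, -1e-4, 5e-7),
                     noise_sd = 0.6, seed = 7)
fit_two_state(subtract_baseline(tg))
#> <two-state fit> Tm = 74.56 C  dH = 517.0 kJ/mol  dS = 1.4869 kJ/mol/K  scale = 0.921
```

The binodal fit recovers the generating curve from noisy titration points;
the tie-line solver returns the two coexisting-phase compositions whose
lever-rule combination reproduces the mixture exactly (residual at
machine precision); 96.25% is the fraction of protein mass found in the
FIL-rich phase; the Kd and Tm fits recover the generating 1.27 mM and
74.56 °C within their standard errors.

`run_pipeline()` chains binodal → tie-line → partition from a single
(YAML-able) configuration and emits a manifest (package version, seed,
config checksum) for reproducible reports; `write_pipeline_report()`
serialises the result to JSON.

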