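# Seeded synthetic-data generators emulating each instrument in the ABS
# workflow: cloud-point titrations, partition experiments, MST titrations,
# DSC thermograms and turbidity activity traces. Zero-noise outputs lie
# exactly on the generating model; a fixed seed gives identical output.

# Run `expr` under a locally seeded RNG without disturbing the caller's
# stream; seed = NULL uses the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate cloud-point binodal data
#'
#' Samples non-IL abscissae log-uniformly over `x_range` and evaluates the
#' binodal model, adding Gaussian noise in wt%. Negative noisy ordinates
#' are truncated at zero and counted in the `n_truncated` attribute.
#'
#' @param model Generating [binodal_model()].
#' @param n Number of titration points (>= 3; default 20).
#' @param noise_sd Gaussian noise SD on y, wt% (default 0).
#' @param x_range Span of the abscissa, wt% (default `c(0.05, 40)`).
#' @param seed Optional integer seed for reproducibility.
#' @return Data frame with columns `x`, `y`, sorted by `x`, suitable for
#'   [fit_binodal()].
#' @export
gen_binodal <- function(model, n = 20, noise_sd = 0,
                        x_range = c(0.05, 40), seed = NULL) {
  stopifnot(inherits(model, "binodal_model"), n >= 3, noise_sd >= 0,
            x_range[1] > 0, x_range[2] > x_range[1])
  .with_seed(seed, {
    x <- sort(exp(runif(n, log(x_range[1]), log(x_range[2]))))
    y <- evaluate_binodal(model, x) + rnorm(n, 0, noise_sd)
    n_trunc <- sum(y < 0)
    y[y < 0] <- 0
    structure(data.frame(x = x, y = y), n_truncated = n_trunc)
  })
}

#' Generate a synthetic partition experiment
#'
#' Splits a known total protein mass between the phases according to a
#' true extraction efficiency, converts to per-phase concentrations via
#' the phase volumes, and perturbs concentrations with multiplicative
#' lognormal noise at a given coefficient of variation — emulating
#' replicate colorimetric quantification of both phases.
#'
#' @param true_ee True extraction efficiency, percent.
#' @param total_mass Total protein mass, mg (default 2, i.e. 1 mg/mL in a
#'   2 g system).
#' @param v_il,v_non Phase volumes, mL (default 1 each).
#' @param conc_noise_cv Lognormal CV of the concentration measurement
#'   (default 0).
#' @param n_reps Number of replicate experiments (default 3).
#' @param system_id Label for the generated system.
#' @param seed Optional seed.
#' @return Long-format data frame as consumed by [partition_summary()].
#' @export
gen_partition <- function(true_ee, total_mass = 2, v_il = 1, v_non = 1,
                          conc_noise_cv = 0, n_reps = 3,
                          system_id = "SYN#1", seed = NULL) {
  stopifnot(true_ee >= 0, true_ee <= 100, total_mass > 0,
            v_il > 0, v_non > 0, conc_noise_cv >= 0, n_reps >= 1)
  m_il <- total_mass * true_ee / 100
  m_non <- total_mass - m_il
  conc_true <- c(il_rich = m_il / v_il, non_il_rich = m_non / v_non)
  vol <- c(il_rich = v_il, non_il_rich = v_non)
  .with_seed(seed, {
    rows <- lapply(seq_len(n_reps), function(r) {
      noise <- if (conc_noise_cv > 0) {
        sdlog <- sqrt(log(1 + conc_noise_cv^2))
        exp(rnorm(2, -sdlog^2 / 2, sdlog))
      } else c(1, 1)
      data.frame(system_id = system_id, replicate = r,
                 phase = names(conc_true),
                 conc_mg_ml = unname(conc_true * noise),
                 volume_ml = unname(vol),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate an MST titration series
#'
#' Serial-dilution design plus the exact 1:1 mass-action response with
#' Gaussian noise on normalized fluorescence. Defaults put the unbound
#' plateau at 0 and the bound plateau at 1, so `noise_sd` is expressed as
#' a fraction of the full binding amplitude (0.02 = 2% noise). With
#' `flat = TRUE` the amplitude is zero (no-binding control).
#'
#' @param kd Generating dissociation constant, mM (> 0; ignored when
#'   `flat`).
#' @param target_uM Labeled-protein concentration, micromolar
#'   (default 0.41).
#' @param start_mM First-capillary ligand concentration, mM (default 100).
#' @param n,ratio Dilution design, see [serial_dilution()].
#' @param f_unbound,f_bound Response plateaus (defaults 0 and 1).
#' @param noise_sd Gaussian noise SD on fnorm (default 0.02).
#' @param flat Generate a zero-amplitude (no-binding) series.
#' @param replicate_id Replicate label.
#' @param seed Optional seed.
#' @return A [titration_series()].
#' @export
gen_titration <- function(kd, target_uM = 0.41, start_mM = 100, n = 16L,
                          ratio = 2, f_unbound = 0, f_bound = 1,
                          noise_sd = 0.02, flat = FALSE,
                          replicate_id = NA, seed = NULL) {
  stopifnot(noise_sd >= 0)
  L <- serial_dilution(start_mM, n = n, ratio = ratio)
  mu <- if (flat) {
    rep(f_unbound, n)
  } else {
    stopifnot(kd > 0)
    f_unbound + (f_bound - f_unbound) *
      fraction_bound_model(L, target_uM / 1000, kd)
  }
  .with_seed(seed, {
    titration_series(L, mu + rnorm(n, 0, noise_sd),
                     target_uM = target_uM, replicate_id = replicate_id)
  })
}

#' Generate a DSC thermogram
#'
#' Sum of two-state excess heat-capacity components on a polynomial
#' baseline with Gaussian noise, on a regular temperature grid (default
#' 20-90 C in 0.1 C steps, matching a 1 C/min scan sampled every 6 s).
#'
#' @param tms Transition midpoints, degrees C (each inside `t_range`).
#' @param dhs Van't Hoff enthalpies, kJ/mol, same length as `tms`.
#' @param scales Amplitude factors, same length (default all 1).
#' @param baseline_coeffs Polynomial baseline coefficients in increasing
#'   powers of temperature in C (default none).
#' @param noise_sd Gaussian noise SD in cp units (default 0).
#' @param t_range,dt Temperature grid span and step, degrees C.
#' @param seed Optional seed.
#' @return A [thermogram()].
#' @export
gen_thermogram <- function(tms, dhs, scales = rep(1, length(tms)),
                           baseline_coeffs = 0, noise_sd = 0,
                           t_range = c(20, 90), dt = 0.1, seed = NULL) {
  stopifnot(length(tms) == length(dhs), length(tms) == length(scales),
            all(tms > t_range[1]), all(tms < t_range[2]), noise_sd >= 0)
  t <- seq(t_range[1], t_range[2], by = dt)
  mu <- Reduce(`+`, Map(function(tm, dh, s) two_state_excess_cp(t, tm, dh, s),
                        tms, dhs, scales))
  base <- drop(outer(t, seq_along(baseline_coeffs) - 1, `^`) %*%
                 baseline_coeffs)
  .with_seed(seed, {
    thermogram(t, mu + base + rnorm(length(t), 0, noise_sd))
  })
}

#' Generate turbidity-decay activity traces
#'
#' Linear absorbance decays sampled every `interval` seconds over
#' `duration`, with slope `reference_slope * true_relative_pct / 100`
#' and Gaussian read noise — the synthetic counterpart of triplicate
#' lysozyme assays against a Micrococcus substrate.
#'
#' @param true_relative_pct True activity relative to the reference, %.
#' @param reference_slope Reference (100%) slope, absorbance/s; must be
#'   negative (default -1e-3).
#' @param a0 Initial absorbance (default 1.0).
#' @param duration Read window, s (default 300).
#' @param interval Sampling interval, s (default 30).
#' @param noise_sd Gaussian absorbance noise SD (default 0).
#' @param n_reps Number of replicate traces (default 3).
#' @param condition Condition label.
#' @param seed Optional seed.
#' @return Data frame `condition`, `replicate`, `time_s`, `a450`.
#' @export
gen_activity <- function(true_relative_pct, reference_slope = -1e-3,
                         a0 = 1.0, duration = 300, interval = 30,
                         noise_sd = 0, n_reps = 3,
                         condition = "sample", seed = NULL) {
  stopifnot(true_relative_pct >= 0, reference_slope < 0, noise_sd >= 0,
            n_reps >= 1)
  tt <- seq(0, duration, by = interval)
  slope <- reference_slope * true_relative_pct / 100
  .with_seed(seed, {
    rows <- lapply(seq_len(n_reps), function(r) {
      data.frame(condition = condition, replicate = r, time_s = tt,
                 a450 = a0 + slope * tt + rnorm(length(tt), 0, noise_sd),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
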