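# Two-state protein-unfolding calorimetry: excess heat capacity model,
# polynomial baseline subtraction, single- and multi-transition fitting.

# Gas constant, kJ / (mol K)
.R_KJ <- 8.31446261815324e-3

#' Build a thermogram object
#'
#' @param temp_c Temperature grid, degrees Celsius, strictly increasing
#'   (>= 50 points for fitting).
#' @param cp Heat-capacity signal on that grid (instrument units; the
#'   fits are scale-invariant in these units).
#' @param scan_rate Heating rate, C/min (metadata; default 1).
#' @param protein_conc Protein concentration, mg/mL (metadata).
#' @return Object of class `"thermogram"`.
#' @export
thermogram <- function(temp_c, cp, scan_rate = 1, protein_conc = NA_real_) {
  stopifnot(length(temp_c) == length(cp), all(is.finite(temp_c)))
  if (any(diff(temp_c) <= 0)) stop("temperature grid must be strictly increasing")
  structure(
    list(temp_c = as.numeric(temp_c), cp = as.numeric(cp),
         scan_rate = scan_rate, protein_conc = protein_conc),
    class = "thermogram"
  )
}

#' Two-state excess heat capacity
#'
#' Van't Hoff two-state unfolding: the equilibrium constant
#' `K(T) = exp((dh/R) (1/Tm - 1/T))` (temperatures in Kelvin) gives a
#' fraction unfolded `fu = K/(1+K)` and an excess heat capacity
#' \deqn{C_p^{exc}(T) = s \, \frac{\Delta H^2}{R T^2} \frac{K}{(1+K)^2}}
#' with a single amplitude scale `s` absorbing instrument units and
#' calorimetric/van't Hoff enthalpy ratio. The peak sits at `Tm` to first
#' order and the area under the peak equals `s * dh`.
#'
#' @param temp_c Temperature(s), degrees C; vectorized.
#' @param tm Midpoint temperature, degrees C.
#' @param dh Van't Hoff unfolding enthalpy, kJ/mol (> 0).
#' @param scale Amplitude factor (default 1).
#' @return Excess heat capacity, `scale` * kJ/(mol K).
#' @examples
#' two_state_excess_cp(74, tm = 74, dh = 400)
#' @export
two_state_excess_cp <- function(temp_c, tm, dh, scale = 1) {
  if (dh <= 0) stop("'dh' must be positive for unfolding")
  t_k <- temp_c + 273.15
  tm_k <- tm + 273.15
  k_eq <- exp((dh / .R_KJ) * (1 / tm_k - 1 / t_k))
  scale * dh^2 / (.R_KJ * t_k^2) * k_eq / (1 + k_eq)^2
}

#' Fraction of protein unfolded
#'
#' @inheritParams two_state_excess_cp
#' @return `K/(1+K)` in \[0, 1\]; 0.5 at `temp_c == tm`.
#' @export
fraction_unfolded <- function(temp_c, tm, dh) {
  if (dh <= 0) stop("'dh' must be positive for unfolding")
  k_eq <- exp((dh / .R_KJ) * (1 / (tm + 273.15) - 1 / (temp_c + 273.15)))
  k_eq / (1 + k_eq)
}

#' Subtract a polynomial baseline from a thermogram
#'
#' Fits a polynomial (default cubic) to the signal outside an exclusion
#' window around the transition peak and subtracts it everywhere. When no
#' window is supplied, the peak is located at the signal argmax, the
#' baseline is fitted excluding `tm +/- exclude_halfwidth`, and the window
#' is re-centred once on the corrected signal's argmax before the final
#' fit.
#'
#' @param tg A [thermogram()].
#' @param degree Polynomial degree (default 3).
#' @param exclude_halfwidth Half-width of the peak exclusion window,
#'   degrees C (default 8).
#' @param window Optional explicit exclusion interval `c(lo, hi)` in
#'   degrees C, overriding the automatic search.
#' @return A corrected [thermogram()] with attributes `baseline_coeffs`
#'   (increasing powers of `temp_c`) and `window`.
#' @export
subtract_baseline <- function(tg, degree = 3, exclude_halfwidth = 8,
                              window = NULL) {
  stopifnot(inherits(tg, "thermogram"))
  t <- tg$temp_c; y <- tg$cp
  fit_outside <- function(win) {
    out <- t < win[1] | t > win[2]
    if (sum(out) < degree + 1) {
      stop("exclusion window leaves too few points for the baseline fit")
    }
    cf <- coef(lm(y[out] ~ poly(t[out], degree, raw = TRUE)))
    drop(cbind(1, outer(t, seq_len(degree), `^`)) %*% cf)
  }
  if (is.null(window)) {
    tm0 <- t[which.max(y)]
    window <- c(tm0 - exclude_halfwidth, tm0 + exclude_halfwidth)
    corrected <- y - fit_outside(window)
    tm1 <- t[which.max(corrected)]
    window <- c(tm1 - exclude_halfwidth, tm1 + exclude_halfwidth)
  }
  if (window[1] <= min(t) && window[2] >= max(t)) {
    stop("exclusion window covers the whole temperature range")
  }
  base <- fit_outside(window)
  out <- thermogram(t, y - base, scan_rate = tg$scan_rate,
                    protein_conc = tg$protein_conc)
  # store increasing-power coefficients of the fitted polynomial
  cf <- coef(lm(base ~ poly(t, degree, raw = TRUE)))
  attr(out, "baseline_coeffs") <- unname(cf)
  attr(out, "window") <- window
  out
}

# Shared peak-detectability check: peak max against off-peak noise.
.check_peak <- function(t, y, halfwidth = 8, factor = 3) {
  tm0 <- t[which.max(y)]
  off <- abs(t - tm0) > halfwidth
  noise <- if (sum(off) >= 10) sd(y[off]) else sd(y)
  if (!is.finite(noise) || noise == 0) noise <- .Machine$double.eps
  if (max(y) <= factor * noise) {
    stop("no discernible unfolding peak (max signal < ", factor,
         "x off-peak SD)")
  }
  tm0
}

#' Fit a two-state unfolding transition
#'
#' Nonlinear least squares of [two_state_excess_cp()] over `(tm, dh,
#' scale)` on a baseline-corrected thermogram. Starting values are
#' analytic: `tm` at the signal argmax; `dh` from the peak height to area
#' ratio (`dh = 4 R Tm_K^2 * height / area`); `scale = area / dh`.
#' The entropy is `dS = dH / Tm_K`, and the stability curve
#' `dG(T) = dH - T_K * dS` vanishes at `Tm` by construction.
#'
#' @param tg Baseline-corrected [thermogram()] with a discernible peak
#'   (max > 3x off-peak SD).
#' @return Object of class `"two_state_fit"`: `tm` (C), `dh` (kJ/mol),
#'   `ds` (kJ/mol/K), `scale`, `tm_se`, `dh_se`, `fit_rss`, `n_points`
#'   and `dg_fn(temp_c)` returning `dG` in `scale`-free kJ/mol.
#' @examples
#' t <- seq(20, 90, by = 0.1)
#' tg <- thermogram(t, two_state_excess_cp(t, 74.56, 500))
#' fit_two_state(tg)
#' @export
fit_two_state <- function(tg) {
  stopifnot(inherits(tg, "thermogram"))
  t <- tg$temp_c; y <- tg$cp
  if (length(t) < 50) stop("thermogram needs >= 50 points for fitting")
  tm0 <- .check_peak(t, y)
  height <- max(y)
  area <- sum(diff(t) * (head(y, -1) + y[-1]) / 2)
  dh0 <- 4 * .R_KJ * (tm0 + 273.15)^2 * height / max(area, 1e-12)
  dh0 <- min(max(dh0, 50), 5000)
  s0 <- max(area, 1e-12) / dh0

  fit <- minpack.lm::nlsLM(
    y ~ two_state_excess_cp(t, tm, dh, s),
    data = data.frame(t = t, y = y),
    start = list(tm = tm0, dh = dh0, s = s0),
    lower = c(tm = min(t), dh = 1, s = 1e-12),
    upper = c(tm = max(t), dh = Inf, s = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  tm <- cf[["tm"]]; dh <- cf[["dh"]]
  ds <- dh / (tm + 273.15)
  structure(
    list(tm = tm, dh = dh, ds = ds, scale = cf[["s"]],
         tm_se = unname(se[1]), dh_se = unname(se[2]),
         fit_rss = sum(residuals(fit)^2), n_points = length(t),
         dg_fn = function(temp_c) dh - (temp_c + 273.15) * ds),
    class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "<two-state fit> Tm = %.2f C  dH = %.1f kJ/mol  dS = %.4f kJ/mol/K  scale = %.3g\n",
    x$tm, x$dh, x$ds, x$scale))
  invisible(x)
}

# Initial transition positions for k overlapping peaks: weighted quantiles
# of the positive part of the corrected signal, treating it as a density.
.multi_tm_init <- function(t, y, k) {
  w <- pmax(y, 0)
  cw <- cumsum(w) / sum(w)
  probs <- (seq_len(k) - 0.5) / k
  vapply(probs, function(p) t[which.min(abs(cw - p))], numeric(1))
}

#' Fit a sum of two-state transitions
#'
#' Jointly fits `k` two-state components (each with its own `tm`, `dh`
#' and `scale`) to a baseline-corrected thermogram, for proteins showing
#' multiple unfolding transitions (e.g. aggregate species coexisting with
#' the monomer). Components are initialised at weighted quantiles of the
#' signal mass and reported sorted by `tm`. The corrected Akaike
#' criterion (AICc) of the `k`-component model and, for `k > 1`, of the
#' `(k-1)`-component refit are reported for model comparison.
#'
#' @param tg Baseline-corrected [thermogram()].
#' @param k Number of transitions, 1 to 4.
#' @return For `k = 1`, a `"two_state_fit"` (plus `aicc` attribute).
#'   Otherwise a list of class `"multi_transition_fit"` with `components`
#'   (list of per-transition parameter lists, sorted by `tm`), `aicc`,
#'   `aicc_km1`, `fit_rss`, `n_points`.
#' @export
multi_transition_fit <- function(tg, k) {
  stopifnot(inherits(tg, "thermogram"), k %in% 1:4)
  t <- tg$temp_c; y <- tg$cp
  .check_peak(t, y)
  aicc <- function(rss, n, p) {
    n * log(rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
  }
  if (k == 1) {
    fit <- fit_two_state(tg)
    attr(fit, "aicc") <- aicc(fit$fit_rss, fit$n_points, 3)
    return(fit)
  }

  tms0 <- .multi_tm_init(t, y, k)
  area <- sum(diff(t) * (head(y, -1) + y[-1]) / 2)
  dh0 <- rep(800, k)
  s0 <- rep(max(area, 1e-12) / k / 800, k)
  model_k <- function(t, theta) {
    out <- 0
    for (j in seq_len(k)) {
      out <- out + two_state_excess_cp(
        t, theta[j], theta[k + j], theta[2 * k + j])
    }
    out
  }
  theta0 <- c(tms0, dh0, s0)
  names(theta0) <- c(paste0("tm", 1:k), paste0("dh", 1:k), paste0("s", 1:k))
  resid_fn <- function(theta) y - model_k(t, theta)
  nlfit <- minpack.lm::nls.lm(
    par = theta0, fn = resid_fn,
    lower = c(rep(min(t), k), rep(1, k), rep(1e-12, k)),
    upper = c(rep(max(t), k), rep(1e4, k), rep(Inf, k)),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!(nlfit$info %in% 1:4)) {
    stop("multi-transition fit did not converge (k = ", k,
         " may exceed the resolvable number of peaks)")
  }
  th <- nlfit$par
  ord <- order(th[1:k])
  comps <- lapply(ord, function(j) {
    tm <- th[j]; dh <- th[k + j]
    list(tm = unname(tm), dh = unname(dh),
         ds = unname(dh / (tm + 273.15)), scale = unname(th[2 * k + j]))
  })
  rss <- sum(resid_fn(th)^2)
  km1 <- multi_transition_fit(tg, k - 1)
  aicc_km1 <- if (k - 1 == 1) attr(km1, "aicc") else km1$aicc
  structure(
    list(components = comps, k = k,
         aicc = aicc(rss, length(t), 3 * k), aicc_km1 = aicc_km1,
         fit_rss = rss, n_points = length(t)),
    class = "multi_transition_fit")
}

#' @export
print.multi_transition_fit <- function(x, ...) {
  cat(sprintf("<%d-transition fit> AICc = %.1f (k-1: %.1f)\n",
              x$k, x$aicc, x$aicc_km1))
  for (cmp in x$components) {
    cat(sprintf("  Tm = %.2f C  dH = %.1f kJ/mol  scale = %.3g\n",
                cmp$tm, cmp$dh, cmp$scale))
  }
  invisible(x)
}
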