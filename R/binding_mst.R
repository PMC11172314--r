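# Microscale thermophoresis (MST) dose-response analysis: serial-dilution
# designs, the exact 1:1 mass-action binding isotherm, capillary quality
# filtering, and nonlinear least-squares estimation of the dissociation
# constant Kd.

#' Serial-dilution ligand series
#'
#' Concentrations for an n-point serial dilution:
#' `conc_i = start / ratio^(i-1)`. The MST protocol uses 16 twofold (1:1)
#' dilutions, e.g. 100 mM down to 100/2^15 = 3.0518e-3 mM.
#'
#' @param start_conc Highest ligand concentration (first capillary), mM.
#' @param n Number of points (>= 2; default 16).
#' @param ratio Dilution factor between consecutive points (> 1;
#'   default 2).
#' @return Numeric vector of length `n`, strictly decreasing.
#' @examples
#' serial_dilution(100)[16]  # 3.0517578125e-3 mM
#' @export
serial_dilution <- function(start_conc, n = 16L, ratio = 2) {
  stopifnot(is.numeric(start_conc), start_conc > 0, n >= 2)
  if (ratio <= 1) stop("'ratio' must exceed 1 for a dilution series")
  start_conc / ratio^(seq_len(n) - 1)
}

#' Exact 1:1 mass-action fraction bound
#'
#' Fraction of target bound at equilibrium for a 1:1 interaction, from the
#' exact quadratic solution of the mass-action equations:
#' \deqn{f_b = \frac{(L + T + K_d) - \sqrt{(L + T + K_d)^2 - 4 L T}}{2T}}
#' evaluated in the numerically stable equivalent form
#' `2L / (S + sqrt(S^2 - 4LT))` with `S = L + T + Kd`, which avoids
#' catastrophic cancellation when the target concentration is far below
#' Kd (the usual MST regime). Reduces to the hyperbola `L / (L + Kd)` as
#' `T -> 0`.
#'
#' @param ligand Ligand concentration(s), mM; vectorized, >= 0.
#' @param target Labeled-target concentration, mM (> 0).
#' @param kd Dissociation constant, mM (> 0).
#' @return Fraction bound in \[0, 1\].
#' @examples
#' fraction_bound_model(1.27, 4.1e-4, 1.27)  # ~0.5 when L = Kd >> T
#' @export
fraction_bound_model <- function(ligand, target, kd) {
  stopifnot(all(ligand >= 0), target > 0, kd > 0)
  s <- ligand + target + kd
  disc <- s^2 - 4 * ligand * target
  2 * ligand / (s + sqrt(pmax(disc, 0)))
}

#' Assemble an MST titration series
#'
#' @param ligand_mM Ligand concentrations, mM.
#' @param fnorm Normalized fluorescence readings, same length.
#' @param target_uM Labeled-protein concentration, micromolar (constant
#'   across capillaries; default 0.41).
#' @param replicate_id Optional replicate label.
#' @return Object of class `"titration_series"`.
#' @export
titration_series <- function(ligand_mM, fnorm, target_uM = 0.41,
                             replicate_id = NA) {
  stopifnot(length(ligand_mM) == length(fnorm), all(ligand_mM >= 0),
            target_uM > 0)
  structure(
    list(data = data.frame(ligand_mM = ligand_mM, fnorm = fnorm),
         target_uM = target_uM, replicate_id = replicate_id),
    class = "titration_series"
  )
}

#' Drop capillaries above a ligand-concentration cutoff
#'
#' MST quality control discards capillaries whose ligand concentration
#' exceeds a cutoff (default 50 mM) because of fluorescence inhomogeneity
#' at high surfactant-like ligand loadings. Removed capillaries are
#' counted in the `n_removed` attribute; a warning is raised when fewer
#' than 8 points remain (the Kd fit precondition).
#'
#' @param series A [titration_series()].
#' @param max_conc Cutoff, mM (default 50).
#' @return The filtered series with attribute `n_removed`.
#' @export
capillary_quality_filter <- function(series, max_conc = 50) {
  stopifnot(inherits(series, "titration_series"))
  keep <- series$data$ligand_mM <= max_conc
  n_removed <- sum(!keep)
  series$data <- series$data[keep, , drop = FALSE]
  rownames(series$data) <- NULL
  attr(series, "n_removed") <- n_removed
  if (nrow(series$data) < 8) {
    warning("only ", nrow(series$data),
            " capillaries remain after filtering; Kd fitting needs >= 8")
  }
  series
}

#' Fit a 1:1 binding isotherm to an MST titration
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `fnorm = f_unbound + (f_bound - f_unbound) * fb(L, T, Kd)` with the
#' exact quadratic [fraction_bound_model()]. The unbound and bound
#' plateaus are free parameters rather than being pinned to the extreme
#' capillaries. Binding is flagged as undetected when the realized
#' response swing over the sampled ligand range (fitted amplitude times
#' the span of the fitted fraction-bound curve) is below `amp_factor`
#' times the residual standard deviation, or when the fit does not
#' converge; in that case `kd` is `NA`.
#'
#' @param series A [titration_series()] with at least 8 points spanning
#'   at least 2 decades of ligand concentration.
#' @param amp_factor Detection threshold on amplitude / residual SD
#'   (default 3).
#' @return Object of class `"titration_fit"`: `kd` and `kd_se` (mM, from
#'   the Jacobian), `f_unbound`, `f_bound`, `fraction_bound` (per point),
#'   `binding_detected`, `converged`, `rss`, `n_points`.
#' @examples
#' L <- serial_dilution(34)
#' fn <- fraction_bound_model(L, 4.1e-4, kd = 1.27)
#' fit_kd(titration_series(L, fn))
#' @export
fit_kd <- function(series, amp_factor = 3) {
  stopifnot(inherits(series, "titration_series"))
  d <- series$data[series$data$ligand_mM > 0, , drop = FALSE]
  if (nrow(d) < 8) stop("need at least 8 usable titration points")
  span <- log10(max(d$ligand_mM) / min(d$ligand_mM))
  if (span < 2) stop("titration must span at least 2 decades of ligand")
  target_mM <- series$target_uM / 1000

  ord <- order(d$ligand_mM)
  L <- d$ligand_mM[ord]; fn <- d$fnorm[ord]
  f0_init <- mean(fn[seq_len(3)])
  f1_init <- mean(fn[seq.int(length(fn) - 2, length(fn))])
  amp_init <- f1_init - f0_init
  # Kd start: ligand level at half response, else geometric mid of range.
  kd_init <- if (abs(amp_init) > 1e-12) {
    half <- f0_init + amp_init / 2
    i <- which(diff(sign(fn - half)) != 0)
    if (length(i)) sqrt(L[i[1]] * L[i[1] + 1]) else sqrt(min(L) * max(L))
  } else sqrt(min(L) * max(L))

  no_binding <- function(converged) {
    structure(
      list(kd = NA_real_, kd_se = NA_real_,
           f_unbound = mean(fn), f_bound = mean(fn),
           fraction_bound = rep(NA_real_, length(fn)),
           binding_detected = FALSE, converged = converged,
           rss = sum((fn - mean(fn))^2), n_points = length(fn)),
      class = "titration_fit")
  }

  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      fn ~ f0 + (f1 - f0) * fraction_bound_model(L, target_mM, kd),
      data = data.frame(L = L, fn = fn),
      start = list(kd = kd_init, f0 = f0_init, f1 = f1_init),
      lower = c(kd = 1e-9, f0 = -Inf, f1 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300))),
    error = function(e) NULL)
  if (is.null(fit)) return(no_binding(FALSE))

  cf <- coef(fit)
  resid_sd <- sqrt(sum(residuals(fit)^2) / max(1, length(fn) - 3))
  amp <- cf[["f1"]] - cf[["f0"]]
  # Detection uses the realized response swing over the sampled ligand
  # range, not the raw amplitude parameter: when the fitted curve is flat
  # across the series the plateaus are unidentifiable and |f1 - f0| alone
  # can be arbitrarily inflated.
  fbv <- fraction_bound_model(L, target_mM, cf[["kd"]])
  swing <- abs(amp) * (max(fbv) - min(fbv))
  detected <- is.finite(swing) && swing >= amp_factor * resid_sd
  if (!detected) return(no_binding(TRUE))

  se <- tryCatch(summary(fit)$coefficients["kd", "Std. Error"],
                 error = function(e) NA_real_)
  structure(
    list(kd = cf[["kd"]], kd_se = se,
         f_unbound = cf[["f0"]], f_bound = cf[["f1"]],
         fraction_bound = (fn - cf[["f0"]]) / amp,
         binding_detected = TRUE, converged = TRUE,
         rss = sum(residuals(fit)^2), n_points = length(fn)),
    class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  if (x$binding_detected) {
    cat(sprintf("<Kd fit> Kd = %.4g +/- %.2g mM (n = %d, RSS = %.3g)\n",
                x$kd, x$kd_se, x$n_points, x$rss))
  } else {
    cat("<Kd fit> no binding detected\n")
  }
  invisible(x)
}
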