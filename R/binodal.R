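# Merchuck binodal (solubility) curve: fitting, evaluation, classification.

#' Construct a Merchuck binodal model
#'
#' The binodal of an aqueous biphasic system is described by the empirical
#' three-parameter Merchuck form
#' \deqn{Y = A \exp(B X^{0.5} - C X^3)}
#' where `Y` is the ionic-liquid weight percent and `X` the weight percent
#' of the second phase former. The literal polynomial variant
#' \eqn{Y = A (B X^{0.5} - C X^3)} is retained behind `form = "literal"`
#' for comparison; it cannot reproduce sigmoidal binodals and is not the
#' default.
#'
#' @param a,b,c Model parameters.
#' @param form `"exponential"` (default) or `"literal"`.
#' @param fit_rss Residual sum of squares of the fit (0 for a model stated
#'   rather than fitted).
#' @param n_points Number of points behind the fit.
#' @param stderr Optional named vector of parameter standard errors.
#' @param max_resid Optional maximum absolute fit residual.
#' @return Object of class `"binodal_model"`.
#' @examples
#' m <- binodal_model(80, -0.3, 5e-5)
#' evaluate_binodal(m, c(0, 5, 25))
#' @export
binodal_model <- function(a, b, c, form = c("exponential", "literal"),
                          fit_rss = 0, n_points = NA_integer_,
                          stderr = NULL, max_resid = NA_real_) {
  form <- match.arg(form)
  stopifnot(is.finite(a), is.finite(b), is.finite(c), fit_rss >= 0)
  structure(
    list(a = a, b = b, c = c, form = form, fit_rss = fit_rss,
         n_points = n_points, stderr = stderr, max_resid = max_resid),
    class = "binodal_model"
  )
}

#' @export
print.binodal_model <- function(x, ...) {
  cat(sprintf("<binodal model: %s Merchuck form>\n", x$form))
  cat(sprintf("  A = %.6g  B = %.6g  C = %.6g\n", x$a, x$b, x$c))
  if (!is.na(x$n_points)) {
    cat(sprintf("  fit: n = %d, RSS = %.4g, max |resid| = %.4g\n",
                x$n_points, x$fit_rss, x$max_resid))
  }
  invisible(x)
}

#' Evaluate a binodal model
#'
#' @param model A [binodal_model()].
#' @param x Weight percent of the non-IL phase former; vectorized,
#'   all values must be non-negative.
#' @return Predicted IL weight percent, same length as `x`.
#' @export
evaluate_binodal <- function(model, x) {
  stopifnot(inherits(model, "binodal_model"), is.numeric(x))
  if (any(!is.finite(x)) || any(x < 0)) stop("'x' must be finite and >= 0")
  core <- model$b * sqrt(x) - model$c * x^3
  switch(model$form,
         exponential = model$a * exp(core),
         literal = model$a * core)
}

# Deterministic multi-start grid used by fit_binodal (no RNG involved).
.binodal_start_grid <- function(y, form) {
  a0 <- if (form == "exponential") max(y) else c(max(y), -max(y))
  expand.grid(
    a = c(a0 * 1.0, a0 * 1.5),
    b = c(-0.02, -0.1, -0.3, -0.8),
    c = c(1e-6, 1e-5, 1e-4, 1e-3),
    KEEP.OUT.ATTRS = FALSE
  )
}

#' Fit the Merchuck binodal by least squares
#'
#' Levenberg-Marquardt least squares over a fixed, deterministic grid of
#' starting values (no randomness): every start is tried, the converged
#' candidate with the lowest residual sum of squares wins.
#'
#' @param points Data frame with columns `x` (non-IL wt%) and `y` (IL wt%),
#'   one row per cloud-point titration point. At least 3 distinct `x`
#'   values are required; the exponential form additionally requires all
#'   `y > 0`.
#' @param form Functional form, see [binodal_model()].
#' @return A fitted [binodal_model()] with `fit_rss`, `stderr` and
#'   `max_resid` filled in.
#' @examples
#' truth <- binodal_model(80, -0.3, 5e-5)
#' pts <- data.frame(x = seq(0.5, 30, length.out = 20))
#' pts$y <- evaluate_binodal(truth, pts$x)
#' fit_binodal(pts)
#' @export
fit_binodal <- function(points, form = c("exponential", "literal")) {
  form <- match.arg(form)
  stopifnot(is.data.frame(points), all(c("x", "y") %in% names(points)))
  x <- as.numeric(points$x); y <- as.numeric(points$y)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0)) {
    stop("binodal points must be finite with x >= 0")
  }
  if (length(unique(x)) < 3L) {
    stop("need at least 3 points with distinct x to fit a 3-parameter curve")
  }
  if (form == "exponential" && any(y <= 0)) {
    stop("exponential form requires all y > 0")
  }

  fml <- if (form == "exponential") {
    y ~ a * exp(b * sqrt(x) - c * x^3)
  } else {
    y ~ a * (b * sqrt(x) - c * x^3)
  }
  dat <- data.frame(x = x, y = y)
  starts <- .binodal_start_grid(y, form)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fml, data = dat, start = as.list(starts[i, ]),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("binodal fit failed to converge from any start in the grid")
  }
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  binodal_model(cf[["a"]], cf[["b"]], cf[["c"]], form = form,
                fit_rss = best$rss, n_points = length(x),
                stderr = setNames(as.numeric(se), names(cf)),
                max_resid = max(abs(residuals(best$fit))))
}

#' Classify a mixture against a binodal
#'
#' Phase separation occurs for mixtures lying above the binodal: a mixture
#' is biphasic when its IL content exceeds the curve at its non-IL content.
#'
#' @param model A [binodal_model()].
#' @param comp A `"ternary_composition"` (the `w_non`/`w_il` coordinates
#'   are compared against the curve).
#' @param tol Half-width of the `"on_curve"` band in wt% (default 1e-6,
#'   purely numerical, far below gravimetric resolution).
#' @return One of `"monophasic"`, `"biphasic"`, `"on_curve"`.
#' @export
classify_mixture <- function(model, comp, tol = 1e-6) {
  stopifnot(inherits(comp, "ternary_composition"))
  y_curve <- evaluate_binodal(model, comp$w_non)
  d <- comp$w_il - y_curve
  if (abs(d) <= tol) "on_curve" else if (d > 0) "biphasic" else "monophasic"
}
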