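# Gravimetric tie-line determination: solve for coexisting-phase
# compositions given the binodal, the global mixture point and the measured
# phase-mass fraction, then derive tie-line length and slope.

#' Pose a tie-line problem
#'
#' A tie-line problem couples a fitted binodal with a global mixture point
#' `(x_m, y_m)` (non-IL and IL wt%) and the gravimetrically measured mass
#' fraction `alpha` of the IL-rich phase over the total mixture mass. The
#' mixture must classify biphasic under the model.
#'
#' @param model A [binodal_model()].
#' @param x_m,y_m Mixture coordinates in wt%.
#' @param alpha IL-rich phase mass / total mass, strictly in (0, 1).
#' @return Object of class `"tieline_problem"`.
#' @export
tieline_problem <- function(model, x_m, y_m, alpha) {
  stopifnot(inherits(model, "binodal_model"),
            is.finite(x_m), is.finite(y_m), is.finite(alpha))
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be strictly in (0, 1)")
  comp <- validate_composition(y_m, x_m, 100 - x_m - y_m)
  cls <- classify_mixture(model, comp)
  if (cls != "biphasic") {
    stop("mixture point is ", cls, "; tie-lines require a biphasic mixture")
  }
  structure(list(model = model, x_m = x_m, y_m = y_m, alpha = alpha),
            class = "tieline_problem")
}

#' Solve a tie-line by the gravimetric lever rule
#'
#' The four tie-line equations (both endpoints on the binodal, plus the
#' lever rule on each axis) reduce exactly to one unknown: for a candidate
#' non-IL-rich endpoint abscissa `X_non`, the IL-rich abscissa follows
#' linearly from the X-axis lever rule,
#' `X_IL = x_m/alpha - ((1-alpha)/alpha) * X_non`, and the only remaining
#' condition is the Y-axis lever rule evaluated through the binodal. That
#' scalar equation is bracketed on `(x_m, x_hi)` and solved by Brent's
#' method, then polished with Newton steps until the maximum equation
#' residual is below `tol`.
#'
#' @param problem A [tieline_problem()].
#' @param tol Maximum absolute residual of the four tie-line equations
#'   (default 1e-10).
#' @return Object of class `"tieline"`: endpoints `il_rich` and
#'   `non_il_rich` (each `c(x, y)`), `alpha`, `mixture`, `length` (TLL),
#'   `slope` (STL) and `residual`.
#' @examples
#' m <- binodal_model(80, -0.3, 5e-5)
#' pr <- tieline_problem(m, x_m = 6, y_m = 45, alpha = 0.6)
#' solve_tieline(pr)
#' @export
solve_tieline <- function(problem, tol = 1e-10) {
  stopifnot(inherits(problem, "tieline_problem"))
  model <- problem$model
  xm <- problem$x_m; ym <- problem$y_m; a <- problem$alpha
  f <- function(x) evaluate_binodal(model, x)
  k <- (1 - a) / a
  x_il_of <- function(x_non) xm / a - k * x_non
  # Y-lever residual as a function of the non-IL-rich endpoint abscissa.
  h <- function(x_non) f(x_il_of(x_non)) - ym / a + k * f(x_non)

  # Admissible bracket: X_non > xm (salt-rich side), X_IL >= 0, both <= 100.
  x_hi <- min(100, xm / (1 - a))
  lo <- xm * (1 + 1e-12) + 1e-12
  hi <- x_hi * (1 - 1e-12)
  if (hi <= lo) stop("no admissible interval for the non-IL-rich endpoint")
  h_lo <- h(lo); h_hi <- h(hi)
  if (abs(h_lo) < tol) {
    stop("mixture lies on the binodal; tie-line endpoints coincide")
  }
  if (sign(h_lo) == sign(h_hi)) {
    # Scan for a sign change; the residual is continuous on the bracket.
    grid <- seq(lo, hi, length.out = 512L)
    hv <- vapply(grid, h, numeric(1))
    idx <- which(diff(sign(hv)) != 0)
    if (!length(idx)) {
      stop("no tie-line root in the admissible box [", signif(lo, 6), ", ",
           signif(hi, 6), "]; mixture may be too close to the binodal")
    }
    lo <- grid[idx[1]]; hi <- grid[idx[1] + 1L]
  }
  root <- uniroot(h, c(lo, hi), tol = .Machine$double.eps^0.8)$root

  # Newton polish on the scalar residual.
  for (i in 1:50) {
    hv <- h(root)
    if (abs(hv) < tol / 4) break
    eps <- max(abs(root), 1) * 1e-7
    dh <- (h(root + eps) - h(root - eps)) / (2 * eps)
    if (!is.finite(dh) || dh == 0) break
    root <- root - hv / dh
  }

  x_non <- root
  x_il <- x_il_of(x_non)
  y_il <- f(x_il); y_non <- f(x_non)
  pts <- c(x_il, y_il, x_non, y_non)
  if (any(pts < -1e-9) || any(pts > 100 + 1e-9)) {
    stop("tie-line endpoints fall outside the physical [0, 100] wt% box")
  }
  if (abs(x_il - x_non) < 1e-9 && abs(y_il - y_non) < 1e-9) {
    stop("converged endpoints coincide; mixture lies on the binodal")
  }
  # Residuals of the four original equations.
  res <- c(
    on_curve_il = 0,  # y_il defined through the binodal
    on_curve_non = 0, # likewise
    lever_y = y_il - (ym / a - k * y_non),
    lever_x = x_il - (xm / a - k * x_non)
  )
  residual <- max(abs(res))
  if (residual > max(tol, 1e-8)) {
    stop("tie-line solver did not reach the residual tolerance (",
         signif(residual, 3), ")")
  }
  # IL-rich endpoint carries the larger IL content (Y).
  if (y_il < y_non) {
    tmp <- c(x_il, y_il); x_il <- x_non; y_il <- y_non
    x_non <- tmp[1]; y_non <- tmp[2]
  }
  tl <- structure(
    list(il_rich = c(x = x_il, y = y_il),
         non_il_rich = c(x = x_non, y = y_non),
         alpha = a, mixture = c(x = xm, y = ym),
         residual = residual),
    class = "tieline"
  )
  met <- tieline_metrics(tl)
  tl$length <- met[["length"]]
  tl$slope <- met[["slope"]]
  tl
}

#' @export
print.tieline <- function(x, ...) {
  cat("<tie-line>\n")
  cat(sprintf("  IL-rich endpoint:     (%.4f, %.4f) wt%%\n",
              x$il_rich[["x"]], x$il_rich[["y"]]))
  cat(sprintf("  non-IL-rich endpoint: (%.4f, %.4f) wt%%\n",
              x$non_il_rich[["x"]], x$non_il_rich[["y"]]))
  cat(sprintf("  TLL = %.4f  STL = %.4f  alpha = %.4f  resid = %.2e\n",
              x$length, x$slope, x$alpha, x$residual))
  invisible(x)
}

#' Tie-line length and slope
#'
#' Length (TLL) is the Euclidean distance between the coexisting-phase
#' compositions in wt% coordinates; slope (STL) is the ratio of IL to
#' non-IL composition differences. A vertical tie-line yields an infinite
#' slope with attribute `vertical = TRUE`.
#'
#' @param tl A `"tieline"`, or any list with `il_rich` and `non_il_rich`
#'   endpoints `c(x, y)`.
#' @return Named vector `c(length = , slope = )`.
#' @examples
#' tieline_metrics(list(il_rich = c(x = 10, y = 50),
#'                      non_il_rich = c(x = 30, y = 5)))
#' @export
tieline_metrics <- function(tl) {
  p <- tl$il_rich; q <- tl$non_il_rich
  dx <- p[["x"]] - q[["x"]]; dy <- p[["y"]] - q[["y"]]
  len <- sqrt(dx^2 + dy^2)
  if (dx == 0) {
    out <- c(length = len, slope = Inf)
    attr(out, "vertical") <- TRUE
    return(out)
  }
  c(length = len, slope = dy / dx)
}

#' Lever-rule phase-mass fraction from a mixture and its endpoints
#'
#' Recovers `alpha` (IL-rich phase mass over total mass) from the position
#' of the mixture on its tie-line, independently on each composition axis,
#' and reports the closure between the two as a consistency diagnostic.
#' An axis on which the endpoints coincide is skipped (`NA`).
#'
#' @param mixture,il_rich,non_il_rich Points `c(x, y)` in wt%.
#' @return List with `alpha_y`, `alpha_x`, `alpha` (mean of the available
#'   axes) and `closure` (`|alpha_y - alpha_x|`, `NA` if an axis was
#'   skipped).
#' @examples
#' lever_rule_alpha(c(x = 3, y = 30), c(x = 0.33, y = 54.0350),
#'                  c(x = 6.75, y = 4.2344))
#' @export
lever_rule_alpha <- function(mixture, il_rich, non_il_rich) {
  if (all(il_rich == non_il_rich)) stop("endpoints must be distinct")
  one_axis <- function(m, p, q) {
    if (p == q) return(NA_real_)
    (m - q) / (p - q)
  }
  ay <- one_axis(mixture[["y"]], il_rich[["y"]], non_il_rich[["y"]])
  ax <- one_axis(mixture[["x"]], il_rich[["x"]], non_il_rich[["x"]])
  list(alpha_y = ay, alpha_x = ax,
       alpha = mean(c(ay, ax), na.rm = TRUE),
       closure = if (is.na(ay) || is.na(ax)) NA_real_ else abs(ay - ax))
}
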