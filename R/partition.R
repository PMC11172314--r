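# Protein partition bookkeeping: extraction efficiency, per-phase masses,
# replicate statistics and linear calibration for quantification assays.

#' Extraction efficiency
#'
#' Percentage of total protein mass recovered in the ionic-liquid-rich
#' phase: `EE% = 100 * m_il_rp / (m_il_rp + m_non_rp)`. The efficiency is
#' always expressed relative to the IL-rich phase regardless of which
#' phase is protein-enriched; `extraction_efficiency(m1, m2) +
#' extraction_efficiency(m2, m1) == 100` by construction.
#'
#' @param m_il_rp Protein mass in the IL/FIL-rich phase (mg); vectorized.
#' @param m_non_rp Protein mass in the non-IL-rich phase (mg).
#' @return Extraction efficiency in percent, in \[0, 100\].
#' @examples
#' extraction_efficiency(0.9625, 0.0375)  # 96.25
#' @export
extraction_efficiency <- function(m_il_rp, m_non_rp) {
  if (any(!is.finite(m_il_rp)) || any(!is.finite(m_non_rp))) {
    stop("masses must be finite")
  }
  if (any(m_il_rp < 0) || any(m_non_rp < 0)) stop("masses must be >= 0")
  total <- m_il_rp + m_non_rp
  if (any(total == 0)) stop("both phase masses are zero; EE undefined")
  100 * m_il_rp / total
}

#' Protein mass from concentration and phase volume
#'
#' @param conc Concentration in mg/mL; vectorized.
#' @param volume Phase volume in mL.
#' @return Mass in mg.
#' @export
mass_from_concentration <- function(conc, volume) {
  if (any(conc < 0) || any(volume < 0)) {
    stop("concentration and volume must be >= 0")
  }
  conc * volume
}

#' Replicate summary of extraction efficiencies
#'
#' Mean and standard deviation over replicate-level EE values. The SD is
#' reported only for two or more replicates (flagged `NA` otherwise),
#' mirroring how replicate partition experiments are summarised.
#'
#' @param ee Numeric vector of per-replicate extraction efficiencies (%).
#' @return List with `mean`, `sd` and `n`.
#' @examples
#' replicate_stats(c(96, 97, 95))
#' @export
replicate_stats <- function(ee) {
  stopifnot(is.numeric(ee), length(ee) >= 1)
  list(mean = mean(ee),
       sd = if (length(ee) >= 2) sd(ee) else NA_real_,
       n = length(ee))
}

#' Per-system extraction efficiency from a partition table
#'
#' Aggregates a long-format partition table (one row per system, replicate
#' and phase, with measured concentration and phase volume) into
#' replicate-level and system-level extraction efficiencies. EE is
#' computed per replicate from masses (`conc * volume`) and then
#' summarised with [replicate_stats()].
#'
#' @param data Data frame with columns `system_id`, `replicate`,
#'   `phase` (`"il_rich"` or `"non_il_rich"`), `conc_mg_ml`, `volume_ml`.
#' @return Data frame with one row per system: `system_id`, `ee_pct`,
#'   `replicate_sd`, `n_replicates`, `enriched_phase`.
#' @export
partition_summary <- function(data) {
  need <- c("system_id", "replicate", "phase", "conc_mg_ml", "volume_ml")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  if (!all(data$phase %in% c("il_rich", "non_il_rich"))) {
    stop("'phase' must be 'il_rich' or 'non_il_rich'")
  }
  out <- lapply(split(data, data$system_id), function(d) {
    reps <- split(d, d$replicate)
    ee <- vapply(reps, function(r) {
      m_il <- sum(mass_from_concentration(
        r$conc_mg_ml[r$phase == "il_rich"], r$volume_ml[r$phase == "il_rich"]))
      m_non <- sum(mass_from_concentration(
        r$conc_mg_ml[r$phase == "non_il_rich"],
        r$volume_ml[r$phase == "non_il_rich"]))
      extraction_efficiency(m_il, m_non)
    }, numeric(1))
    st <- replicate_stats(ee)
    data.frame(system_id = d$system_id[1], ee_pct = st$mean,
               replicate_sd = st$sd, n_replicates = st$n,
               enriched_phase = if (st$mean >= 50) "il_rich" else "non_il_rich",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Linear calibration curve with inverse prediction
#'
#' Ordinary least squares line through calibration standards
#' (absorbance vs. concentration), with inverse prediction of unknown
#' concentrations. Inverse prediction refuses absorbances whose implied
#' concentration lies more than 10% of the calibrated range outside it
#' (no silent extrapolation).
#'
#' @param conc Standard concentrations (>= 2 distinct values).
#' @param absorbance Measured responses for the standards.
#' @return Object of class `"linear_calibration"` with `slope`,
#'   `intercept`, `r_squared`, `residuals`, and a `predict_conc(a)`
#'   closure.
#' @examples
#' cal <- linear_calibration(c(0, 0.5, 1), c(0.01, 0.52, 1.01))
#' cal$predict_conc(0.25)
#' @export
linear_calibration <- function(conc, absorbance) {
  stopifnot(length(conc) == length(absorbance), length(conc) >= 2)
  if (length(unique(conc)) < 2) stop("standards need >= 2 distinct concentrations")
  fit <- lm(absorbance ~ conc)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope == 0) stop("singular calibration: zero slope")
  rng <- range(conc)
  margin <- 0.10 * diff(rng)
  predict_conc <- function(a) {
    est <- (a - intercept) / slope
    bad <- est < rng[1] - margin | est > rng[2] + margin
    if (any(bad)) {
      stop("absorbance implies concentration outside the calibrated range ",
           sprintf("[%g, %g] (+/- 10%%)", rng[1], rng[2]))
    }
    est
  }
  structure(
    list(slope = slope, intercept = intercept,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         residuals = unname(residuals(fit)),
         predict_conc = predict_conc),
    class = "linear_calibration"
  )
}
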