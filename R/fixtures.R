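# Packaged reference datasets: measured phase properties of the twelve
# biphasic systems, the MST dissociation-constant table, and the printed
# melting temperatures. Stored as plain CSV with the published digits.

.filabs_extdata <- function(file) {
  system.file("extdata", file, package = "filabs", mustWork = TRUE)
}

#' Phase properties of the twelve biphasic systems
#'
#' Volume ratio (IL-rich over non-IL-rich phase volume), pH and ternary
#' composition (wt% water, IL, non-IL) of both coexisting phases for the
#' twelve studied biphasic points (BP#1-BP#12), at 25 C. Values carry the
#' published digits; phase compositions need not close exactly to 100 wt%
#' (measured quantities), which [validate_composition()] tolerates up to
#' 0.5 wt%.
#'
#' @return Data frame, one row per biphasic system.
#' @examples
#' abs_phase_table()[abs_phase_table()$system_id == "BP#3", ]
#' @export
abs_phase_table <- function() {
  read.csv(.filabs_extdata("abs_phase_properties.csv"),
           check.names = TRUE, stringsAsFactors = FALSE)
}

#' MST dissociation constants of lysozyme with ABS phase formers
#'
#' Kd of FITC-labeled lysozyme with the fluorinated ionic liquids (per
#' aggregation regime of the ligand), the fluoro-containing ionic liquid
#' and the stabilizer. `binding_detected == FALSE` rows correspond to
#' monomer-regime titrations where no binding was observed; their `kd_mM`
#' is `NA`.
#'
#' @return Data frame, one row per ligand/concentration-range entry.
#' @export
kd_table <- function() {
  read.csv(.filabs_extdata("kd_table.csv"),
           check.names = TRUE, stringsAsFactors = FALSE)
}

#' Published melting temperatures
#'
#' Lysozyme (and BSA) melting temperatures in water, in aqueous
#' fluorinated-IL solution (including the three-transition case above the
#' first critical aggregation concentration) and in ABS phases, with the
#' printed uncertainties.
#'
#' @return Data frame, one row per reported transition.
#' @export
tm_table <- function() {
  read.csv(.filabs_extdata("tm_table.csv"),
           check.names = TRUE, stringsAsFactors = FALSE)
}
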