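#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm median poly residuals rnorm runif sd setNames
#'   uniroot
#' @importFrom utils head read.csv
NULL

# Roles a phase-forming species can play in an ABS formulation.
.component_roles <- c(
  "fluorinated_IL", "fluoro_containing_IL", "conventional_IL",
  "inorganic_salt", "carbohydrate", "stabilizer", "water", "protein"
)

#' Define a chemical component
#'
#' A component couples a unique name with its molar mass and its role in an
#' aqueous-biphasic-system formulation (ionic liquid, salting-out agent,
#' water, protein, ...). Molar masses feed the weight-percent to molality
#' conversion used for phase-diagram axes.
#'
#' @param name Character identifier, e.g. `"[C2C1Im][C4F9SO3]"`. Must be
#'   unique within a registry.
#' @param molar_mass Molar mass in g/mol; must be positive.
#' @param role One of `"fluorinated_IL"`, `"fluoro_containing_IL"`,
#'   `"conventional_IL"`, `"inorganic_salt"`, `"carbohydrate"`,
#'   `"stabilizer"`, `"water"`, `"protein"`.
#' @return An object of class `"abs_component"`.
#' @examples
#' component("glucose", 180.16, "carbohydrate")
#' @export
component <- function(name, molar_mass, role) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L ||
      !is.finite(molar_mass) || molar_mass <= 0) {
    stop("'molar_mass' must be a single positive number (g/mol)")
  }
  role <- match.arg(role, .component_roles)
  structure(
    list(name = name, molar_mass = as.numeric(molar_mass), role = role),
    class = "abs_component"
  )
}

#' @export
print.abs_component <- function(x, ...) {
  cat(sprintf("<component> %s  M = %.2f g/mol  role = %s\n",
              x$name, x$molar_mass, x$role))
  invisible(x)
}

#' Load a component registry
#'
#' Reads a YAML registry of components (name, molar mass, role). The
#' packaged default covers the phase formers used throughout this toolkit:
#' the perfluorobutanesulfonate fluorinated ionic liquids, the
#' trifluoromethanesulfonate fluoro-containing ionic liquids, potassium
#' phosphate, glucose, sucrose, choline dihydrogen phosphate, water and the
#' model proteins. Molar masses were computed from standard atomic weights;
#' they are not measured quantities.
#'
#' @param path Path to a `components.yaml` file; `NULL` (default) loads the
#'   packaged registry.
#' @return A named list of [component()] objects, class `"abs_registry"`.
#' @examples
#' reg <- component_registry()
#' reg[["glucose"]]
#' @export
component_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "components.yaml", package = "filabs",
                        mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)$components
  if (is.null(raw)) stop("registry file has no 'components' key: ", path)
  comps <- lapply(raw, function(r) {
    component(r$name, r$molar_mass_g_mol, r$role)
  })
  nms <- vapply(comps, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate component names in registry: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  structure(setNames(comps, nms), class = "abs_registry")
}

# Resolve a component argument: either an abs_component or a name looked up
# in the registry.
.resolve_component <- function(x, registry) {
  if (inherits(x, "abs_component")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (is.null(registry)) registry <- component_registry()
    comp <- registry[[x]]
    if (is.null(comp)) stop("component not found in registry: '", x, "'")
    return(comp)
  }
  stop("component must be an 'abs_component' or a registry name")
}

#' Validate and normalize a ternary composition
#'
#' A ternary composition holds the weight percent of the ionic-liquid
#' component, the non-ionic-liquid phase former, and water. Gravimetric
#' phase compositions rarely sum to exactly 100; sums within
#' `closure_tol` (default 0.5 wt%) of 100 are accepted and, by default,
#' rescaled to close exactly. Larger deviations are rejected as data errors.
#'
#' @param w_il Weight percent of the ionic-liquid component.
#' @param w_non Weight percent of the non-IL phase former (salt,
#'   carbohydrate or stabilizer).
#' @param w_water Weight percent of water.
#' @param normalize Rescale the three fractions to sum to exactly 100
#'   (default `TRUE`). When `FALSE` the values are stored as given and the
#'   closure deviation is only flagged.
#' @param closure_tol Maximum allowed |sum - 100| before rejection,
#'   in wt% (default 0.5, the gravimetric rounding envelope).
#' @return An object of class `"ternary_composition"` with fields `w_il`,
#'   `w_non`, `w_water` and attribute `closure_dev` (raw sum minus 100).
#' @examples
#' validate_composition(54.0350, 0.3349, 43.6779)  # an IL-rich phase
#' validate_composition(0, 0, 100)                 # pure water
#' @export
validate_composition <- function(w_il, w_non, w_water, normalize = TRUE,
                                 closure_tol = 0.5) {
  w <- c(w_il = w_il, w_non = w_non, w_water = w_water)
  if (!all(is.finite(w))) stop("composition contains non-finite values")
  if (any(w < 0)) {
    stop("negative weight fraction: ",
         paste(names(w)[w < 0], collapse = ", "))
  }
  total <- sum(w)
  dev <- total - 100
  if (abs(dev) > closure_tol) {
    stop(sprintf(
      "composition sums to %.4f wt%%; deviates from 100 by more than %g",
      total, closure_tol))
  }
  if (normalize && total > 0) w <- w * (100 / total)
  structure(
    list(w_il = unname(w[["w_il"]]), w_non = unname(w[["w_non"]]),
         w_water = unname(w[["w_water"]])),
    closure_dev = dev,
    class = "ternary_composition"
  )
}

#' @export
print.ternary_composition <- function(x, ...) {
  cat(sprintf(
    "<ternary composition> IL %.4f / non-IL %.4f / water %.4f wt%% (closure %+0.4f)\n",
    x$w_il, x$w_non, x$w_water, attr(x, "closure_dev")))
  invisible(x)
}

#' Convert a ternary composition from weight percent to molality
#'
#' Molality here is moles of solute per kilogram of water (not of mixed
#' solvent), the convention used for aqueous-two-phase ternary diagrams:
#' `b_i = (w_i / M_i) / (w_water / 1000)`.
#'
#' @param comp A [validate_composition()] result.
#' @param il,non_il The solute components: [component()] objects or registry
#'   names.
#' @param registry Registry used to resolve names; default packaged
#'   registry.
#' @return Named numeric vector `c(il = , non_il = )` in mol/kg water.
#' @examples
#' comp <- validate_composition(0, 25, 75)
#' wtpct_to_molality(comp, "[C2C1Im][C4F9SO3]", "glucose")
#' @seealso [molality_to_wtpct()] for the inverse.
#' @export
wtpct_to_molality <- function(comp, il, non_il, registry = NULL) {
  stopifnot(inherits(comp, "ternary_composition"))
  if (comp$w_water <= 0) {
    stop("molality is undefined at zero water content")
  }
  il <- .resolve_component(il, registry)
  non_il <- .resolve_component(non_il, registry)
  kg_water <- comp$w_water / 1000  # per 100 g of mixture
  c(il = (comp$w_il / il$molar_mass) / kg_water,
    non_il = (comp$w_non / non_il$molar_mass) / kg_water)
}

#' Convert molalities back to a weight-percent ternary composition
#'
#' Inverse of [wtpct_to_molality()]: given solute molalities (mol per kg
#' water), reconstructs the wt% composition that closes to 100.
#'
#' @param b_il,b_non Molalities of the IL and non-IL solutes, mol/kg water.
#' @inheritParams wtpct_to_molality
#' @return A `"ternary_composition"`.
#' @export
molality_to_wtpct <- function(b_il, b_non, il, non_il, registry = NULL) {
  stopifnot(is.numeric(b_il), is.numeric(b_non), b_il >= 0, b_non >= 0)
  il <- .resolve_component(il, registry)
  non_il <- .resolve_component(non_il, registry)
  # grams of solute per gram of water
  r_il <- b_il * il$molar_mass / 1000
  r_non <- b_non * non_il$molar_mass / 1000
  w_water <- 100 / (1 + r_il + r_non)
  validate_composition(r_il * w_water, r_non * w_water, w_water)
}
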