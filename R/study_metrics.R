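#' Component masses of a fixed-ratio three-compound formulation
#'
#' Splits a total mass across compounds in proportion to their ratio parts
#' and rounds each to the nearest increment, e.g. a berberine : baicalin :
#' geniposide ratio of 5.05 : 4.02 : 2.70 over 1000 mg with a 10 mg
#' increment gives 430 / 340 / 230 mg.
#'
#' @param parts Named numeric vector of ratio parts, all > 0.
#' @param total_mass Total mass to split, > 0 (any mass unit).
#' @param rounding_increment Rounding grain in the same unit, > 0.
#' @return Named numeric vector of rounded per-compound masses.
#' @export
component_masses <- function(parts, total_mass, rounding_increment = 1) {
  if (any(parts <= 0)) stop("ratio parts must be positive", call. = FALSE)
  if (total_mass <= 0) stop("total_mass must be positive", call. = FALSE)
  if (rounding_increment <= 0) stop("rounding_increment must be positive", call. = FALSE)
  raw <- total_mass * parts / sum(parts)
  round(raw / rounding_increment) * rounding_increment
}

#' Parent-formula dose equivalent to a component dose
#'
#' When the measured compounds make up `summed_fraction_percent` of the
#' parent decoction, the parent dose delivering a given total component dose
#' is `dose / (fraction / 100)`, reported to 3 significant figures.
#'
#' @param component_dose_total Combined dose of the measured compounds.
#' @param summed_fraction_percent Their summed mass fraction in the parent,
#'   in (0, 100].
#' @return Parent dose in the same unit as the input, 3 significant figures.
#' @export
parent_equivalent_dose <- function(component_dose_total, summed_fraction_percent) {
  if (summed_fraction_percent <= 0 || summed_fraction_percent > 100) {
    stop("summed_fraction_percent must lie in (0, 100]", call. = FALSE)
  }
  signif(component_dose_total / (summed_fraction_percent / 100), 3)
}

#' Extraction yield percentage
#'
#' `100 * extract_mass / input_mass`, two decimals. An extract heavier than
#' the input is physically suspicious: still computed, but flagged via the
#' `"suspicious"` attribute.
#'
#' @param extract_mass Mass of the extract, >= 0.
#' @param input_mass Mass of the starting material, > 0.
#' @return Yield percent (2 decimals) with attribute `suspicious`.
#' @export
extraction_yield <- function(extract_mass, input_mass) {
  if (input_mass <= 0) stop("input_mass must be positive", call. = FALSE)
  suspicious <- extract_mass > input_mass
  if (suspicious) warning("extract mass exceeds input mass")
  out <- round(100 * extract_mass / input_mass, 2)
  attr(out, "suspicious") <- suspicious
  out
}

#' Infarct volume percentage
#'
#' `I% = (Vc - Vi) / Vc * 100`, where `Vc` is the non-infarcted volume of
#' the contralateral (left) hemisphere and `Vi` that of the ipsilateral
#' (right) hemisphere, in any common unit.
#'
#' @param Vc Contralateral non-infarcted volume, > 0.
#' @param Vi Ipsilateral non-infarcted volume, >= 0.
#' @return Infarct percentage.
#' @export
infarct_percent <- function(Vc, Vi) {
  if (Vc <= 0) stop("Vc must be positive", call. = FALSE)
  if (Vi < 0) stop("Vi must be >= 0", call. = FALSE)
  (Vc - Vi) / Vc * 100
}

#' Mortality rate percentage
#'
#' @param deaths Number of deaths, `0 <= deaths <= total`.
#' @param total Number of animals, > 0.
#' @return `100 * deaths / total`.
#' @export
mortality_rate <- function(deaths, total) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (deaths < 0 || deaths > total) {
    stop("deaths must lie between 0 and total", call. = FALSE)
  }
  100 * deaths / total
}

#' Validate a neurological deficit score
#'
#' Five-point neurological scale: 0 normal, 1 cannot extend the
#' contralateral forelimb, 2 circles to the contralateral side, 3 falls to
#' the contralateral side, 4 loss of consciousness.
#'
#' @param value Integer in `0:4`.
#' @return The validated integer score (class `neuro_score`).
#' @export
neuro_score <- function(value) {
  if (length(value) != 1L || is.na(value) || value != as.integer(value) ||
      !value %in% 0:4) {
    stop("neurological score must be an integer in 0..4", call. = FALSE)
  }
  structure(as.integer(value), class = "neuro_score")
}

#' Echo study-arithmetic computations as JSON
#'
#' Convenience wrapper bundling the formulation, dose and yield arithmetic
#' for a given ratio/total into one JSON-serializable list.
#'
#' @param parts Named ratio parts (also read as percent content in the
#'   parent formula).
#' @param total_mass Total formulation mass.
#' @param rounding_increment Rounding grain for component masses.
#' @param path Optional JSON output path.
#' @return List with `component_masses` and `parent_equivalent_dose`.
#' @export
study_metrics_json <- function(parts, total_mass, rounding_increment = 1,
                               path = NULL) {
  out <- list(
    ratio_parts = as.list(parts),
    total_mass = total_mass,
    component_masses = as.list(component_masses(parts, total_mass, rounding_increment)),
    parent_equivalent_dose = parent_equivalent_dose(total_mass, sum(parts))
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
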