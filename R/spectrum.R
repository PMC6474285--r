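#' Construct a spectrum
#'
#' A spectrum is a chemical-shift axis (ppm, stored strictly ascending) with
#' one intensity per grid point and a sample identifier. All downstream
#' preprocessing operates on this container.
#'
#' @param ppm Numeric vector of chemical shifts (ppm), strictly increasing.
#' @param intensity Numeric vector of the same length; finite values only.
#' @param sample_id Single character sample identifier.
#' @return An object of class `nmr_spectrum` with fields `ppm`, `intensity`
#'   and `sample_id`.
#' @examples
#' sp <- new_spectrum(seq(0, 10, by = 0.01), rep(0, 1001), "blank")
#' sp
#' @export
new_spectrum <- function(ppm, intensity, sample_id = "sample") {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity)) {
    stop("ppm and intensity must have equal length", call. = FALSE)
  }
  if (length(ppm) < 2L) stop("a spectrum needs at least 2 points", call. = FALSE)
  if (any(!is.finite(ppm)) || any(!is.finite(intensity))) {
    stop("ppm and intensity must be finite", call. = FALSE)
  }
  if (any(diff(ppm) <= 0)) stop("ppm must be strictly increasing", call. = FALSE)
  structure(
    list(ppm = ppm, intensity = intensity, sample_id = as.character(sample_id)[1]),
    class = "nmr_spectrum"
  )
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf(
    "<nmr_spectrum> %s: %d points, %.4f to %.4f ppm\n",
    x$sample_id, length(x$ppm), min(x$ppm), max(x$ppm)
  ))
  invisible(x)
}

#' Construct a spectrum set
#'
#' Bundles spectra with their group labels and, for simulated cohorts, the
#' per-sample ground truth (true concentrations and dilution factors) that
#' parameter-recovery tests rely on.
#'
#' @param spectra List of [new_spectrum()] objects with unique sample ids.
#' @param labels Named character vector mapping sample id to group.
#' @param truth Optional list with elements `concentrations` (samples x
#'   metabolites matrix) and `dilution` (named numeric); present iff the set
#'   was simulated.
#' @return An object of class `nmr_spectrum_set`.
#' @export
new_spectrum_set <- function(spectra, labels, truth = NULL) {
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("sample ids must be unique", call. = FALSE)
  if (!all(ids %in% names(labels))) {
    stop("every spectrum needs a group label", call. = FALSE)
  }
  labels <- labels[ids]
  structure(
    list(spectra = spectra, labels = labels, truth = truth),
    class = "nmr_spectrum_set"
  )
}

#' @export
print.nmr_spectrum_set <- function(x, ...) {
  cat(sprintf(
    "<nmr_spectrum_set> %d spectra, groups: %s%s\n",
    length(x$spectra),
    paste(sprintf("%s(%d)", names(table(x$labels)), table(x$labels)), collapse = ", "),
    if (is.null(x$truth)) "" else " [with ground truth]"
  ))
  invisible(x)
}

#' @export
length.nmr_spectrum_set <- function(x) length(x$spectra)

# shared ppm grid or error; used by alignment and bucketing
common_grid <- function(set) {
  grid <- set$spectra[[1]]$ppm
  for (s in set$spectra[-1]) {
    if (length(s$ppm) != length(grid) || max(abs(s$ppm - grid)) > 1e-9) {
      stop("spectra are on differing ppm grids; align/interpolate first", call. = FALSE)
    }
  }
  grid
}
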