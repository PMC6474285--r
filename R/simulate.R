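#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. Defaults define the
#' study conditions emulated throughout the package: n = 8 animals per group,
#' a 0-10 ppm grid fine enough for 0.0025 ppm buckets, multiplicative
#' (log-normal) biological variation, sample-specific dilution, small
#' chemical-shift jitter, smooth baseline drift and additive noise.
#'
#' @param n_per_group Samples per group (>= 3).
#' @param ppm_grid `c(min, max, points)` for the shared chemical-shift axis.
#' @param noise_sd SD of additive Gaussian noise, intensity units.
#' @param conc_sd SD of per-sample Gaussian variation on the natural-log
#'   concentration scale (log-normal concentrations).
#' @param dilution_range `c(low, high)` for the uniform per-sample dilution
#'   factor; both > 0, low <= high.
#' @param shift_jitter_sd SD of per-metabolite, per-sample peak position
#'   jitter, ppm.
#' @param baseline_amplitude Scale of the smooth baseline drift, intensity
#'   units (0 disables it).
#' @param tsp_height Height of the TSP reference singlet at 0 ppm.
#' @param water_amplitude Height of the broad residual-water hump
#'   (Lorentzian, half-width 0.1 ppm, centered at 4.95 ppm).
#' @param seed Integer RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = 8,
                       ppm_grid = c(0, 10, 20001),
                       noise_sd = 0.005,
                       conc_sd = 0.15,
                       dilution_range = c(0.5, 2),
                       shift_jitter_sd = 0.001,
                       baseline_amplitude = 0.05,
                       tsp_height = 1,
                       water_amplitude = 5,
                       seed = 1L) {
  if (n_per_group < 3) stop("n_per_group must be >= 3", call. = FALSE)
  if (length(ppm_grid) != 3L || ppm_grid[2] <= ppm_grid[1] || ppm_grid[3] < 16) {
    stop("ppm_grid must be c(min, max, points) with max > min", call. = FALSE)
  }
  if (noise_sd < 0 || conc_sd < 0 || shift_jitter_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (any(dilution_range <= 0) || dilution_range[1] > dilution_range[2]) {
    stop("dilution_range must be positive with low <= high", call. = FALSE)
  }
  structure(
    list(n_per_group = as.integer(n_per_group), ppm_grid = ppm_grid,
         noise_sd = noise_sd, conc_sd = conc_sd,
         dilution_range = dilution_range, shift_jitter_sd = shift_jitter_sd,
         baseline_amplitude = baseline_amplitude, tsp_height = tsp_height,
         water_amplitude = water_amplitude, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Group effect specification
#'
#' Describes how one cohort group deviates from the reference metabolite
#' levels: signed log2 effects per metabolite, attenuated by a recovery
#' fraction (1 = full return to reference, 0 = full effect expressed).
#' Metabolites not named carry effect 0.
#'
#' @param group Group name.
#' @param log2_effect Named numeric vector, metabolite -> signed log2 shift.
#' @param recovery_fraction Scalar in \[0, 1\].
#' @return A `group_effect` object.
#' @export
group_effect <- function(group, log2_effect = numeric(0), recovery_fraction = 0) {
  if (length(log2_effect) && is.null(names(log2_effect))) {
    stop("log2_effect must be a named vector", call. = FALSE)
  }
  if (recovery_fraction < 0 || recovery_fraction > 1) {
    stop("recovery_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(group = as.character(group), log2_effect = log2_effect,
         recovery_fraction = recovery_fraction),
    class = "group_effect"
  )
}

# metabolite direction lists for the packaged stroke-study design:
# signs follow the reported serum and brain concentration changes
# (model vs sham); magnitude is a single log2 effect size.
study_directions <- function(tissue) {
  if (tissue == "serum") {
    c("Leucine" = 1, "Valine" = 1, "Isoleucine" = 1, "Glucose" = 1,
      "3-Hydroxybutyrate" = -1, "Alanine" = -1,
      "Gamma-aminobutyric acid" = -1, "Acetate" = -1, "Succinate" = -1,
      "Glutamine" = -1, "Glycine" = -1)
  } else {
    c("Leucine" = 1, "Valine" = 1, "Isoleucine" = 1, "3-Hydroxybutyrate" = 1,
      "Alanine" = 1, "Lysine" = 1, "Glutamate" = 1, "Citrate" = 1,
      "Methionine" = 1, "Trimethylamine-N-oxide" = 1, "Glucose" = 1,
      "Glycine" = 1, "Glycerol" = 1, "Threonine" = 1, "Serine" = 1,
      "Lactate" = 1, "O-phosphocholine" = 1, "Guanosine" = 1,
      "Acetate" = -1, "N-Acetylaspartate" = -1, "N-Acetylglutamate" = -1,
      "Glutathione" = -1, "Aspartate" = -1, "Trimethylamine" = -1,
      "Creatine/Creatine phosphate" = -1, "Malonate" = -1, "Inosine" = -1,
      "UDP-glucose" = -1, "ADP" = -1, "Nicotinurate" = -1, "Xanthine" = -1,
      "Hypoxanthine" = -1, "Oxypurinol" = -1, "Adenosine" = -1)
  }
}

#' Default six-group study design
#'
#' Sham reference, a disease model group expressing the full signed
#' metabolite effects, and four treatment-delay groups whose recovery
#' fractions (1.0, 0.9, 0.75, 0.1) reproduce an "effective early, ineffective
#' late" therapeutic-window pattern.
#'
#' @param tissue `"serum"` or `"brain"` (chooses the signed direction list).
#' @param effect_size log2 magnitude of each perturbed metabolite (default 1).
#' @return List of [group_effect()] objects.
#' @export
default_study_design <- function(tissue = "serum", effect_size = 1) {
  dirs <- study_directions(match.arg(tissue, c("serum", "brain"))) * effect_size
  list(
    group_effect("Sham"),
    group_effect("Model", dirs, recovery_fraction = 0),
    group_effect("T0.5", dirs, recovery_fraction = 1.0),
    group_effect("T3",   dirs, recovery_fraction = 0.9),
    group_effect("T5",   dirs, recovery_fraction = 0.75),
    group_effect("T7",   dirs, recovery_fraction = 0.1)
  )
}

lorentzian <- function(x, center, gamma) gamma^2 / ((x - center)^2 + gamma^2)

# deterministic fixed-shape contributions present in every spectrum
fixed_signals <- function(ppm, config) {
  config$tsp_height * lorentzian(ppm, 0, 0.0015) +
    config$water_amplitude * lorentzian(ppm, 4.95, 0.1)
}

#' Simulate one absorption-mode spectrum
#'
#' Renders the sum of Lorentzian peaks for the given concentrations, a TSP
#' reference singlet at 0 ppm, a broad residual-water hump inside the
#' 4.65-5.25 ppm exclusion window, smooth baseline drift and additive noise:
#' `I(d) = dilution * sum_m c_m sum_k h_mk g^2 / ((d - (mu_mk + e_m))^2 + g^2)
#' + baseline(d) + noise(d)`.
#'
#' @param concentrations Named numeric vector (metabolite -> amount >= 0);
#'   every name must exist in `templates`.
#' @param templates Library from [build_library()].
#' @param config [sim_config()].
#' @param dilution Per-sample dilution factor multiplying the metabolite
#'   signal (not TSP/water/baseline/noise).
#' @param sample_id Sample identifier.
#' @param seed Optional seed; when given, jitter/baseline/noise draws are
#'   reproduced bit-for-bit.
#' @return An [new_spectrum()] object.
#' @export
simulate_spectrum <- function(concentrations, templates, config = sim_config(),
                              dilution = 1, sample_id = "sample", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  unknown <- setdiff(names(concentrations), names(templates))
  if (length(unknown)) {
    stop("concentration given for unknown metabolite: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(concentrations < 0)) stop("amounts must be >= 0", call. = FALSE)
  ppm <- seq(config$ppm_grid[1], config$ppm_grid[2], length.out = config$ppm_grid[3])
  jitter <- stats::rnorm(length(concentrations), 0, config$shift_jitter_sd)
  names(jitter) <- names(concentrations)
  signal <- numeric(length(ppm))
  for (nm in names(concentrations)) {
    c_m <- concentrations[[nm]]
    if (c_m == 0) next
    tp <- templates[[nm]]
    for (k in seq_len(nrow(tp$peaks))) {
      signal <- signal + c_m * tp$peaks$height[k] *
        lorentzian(ppm, tp$peaks$center[k] + jitter[[nm]], tp$linewidth)
    }
  }
  base <- if (config$baseline_amplitude > 0) {
    co <- stats::runif(3)
    config$baseline_amplitude *
      (co[1] + co[2] * ppm / max(ppm) + co[3] * sin(pi * ppm / max(ppm)))
  } else 0
  noise <- if (config$noise_sd > 0) stats::rnorm(length(ppm), 0, config$noise_sd) else 0
  new_spectrum(ppm, dilution * signal + fixed_signals(ppm, config) + base + noise,
               sample_id)
}

# draw the ground-truth concentration matrix, dilutions and labels for a
# design; shared by simulate_cohort() and simulate_quantities()
draw_truth <- function(design, templates, config) {
  groups <- vapply(design, function(g) g$group, character(1))
  if (anyDuplicated(groups)) stop("group names must be unique", call. = FALSE)
  if (!length(design)) stop("design must be non-empty", call. = FALSE)
  if (config$n_per_group < 3) stop("n_per_group must be >= 3", call. = FALSE)
  mets <- names(templates)
  ref_log <- log(vapply(templates, function(tp) tp$ref_conc, numeric(1)))
  n <- config$n_per_group
  ids <- character(0); labels <- character(0)
  conc <- NULL; dil <- numeric(0)
  for (g in design) {
    eff <- numeric(length(mets)); names(eff) <- mets
    known <- intersect(names(g$log2_effect), mets)
    eff[known] <- g$log2_effect[known]
    shift <- (1 - g$recovery_fraction) * eff * log(2)
    for (i in seq_len(n)) {
      id <- sprintf("%s_%02d", g$group, i)
      lc <- ref_log + shift + stats::rnorm(length(mets), 0, config$conc_sd)
      conc <- rbind(conc, exp(lc))
      dil <- c(dil, stats::runif(1, config$dilution_range[1], config$dilution_range[2]))
      ids <- c(ids, id); labels <- c(labels, g$group)
    }
  }
  rownames(conc) <- ids; colnames(conc) <- mets
  names(dil) <- ids; names(labels) <- ids
  list(concentrations = conc, dilution = dil, labels = labels)
}

#' Simulate a labeled cohort of spectra with ground truth
#'
#' Per sample, natural-log concentrations are the template reference level
#' plus `(1 - recovery_fraction) * log2_effect * ln 2` plus individual
#' Gaussian variation; the dilution factor is drawn uniformly from the
#' configured range and recorded in the truth slot. The same seed reproduces
#' the cohort exactly.
#'
#' @inheritParams simulate_spectrum
#' @param design List of [group_effect()] with unique group names.
#' @return An [new_spectrum_set()] with `truth` filled in.
#' @export
simulate_cohort <- function(design, templates, config = sim_config()) {
  set.seed(config$seed)
  tr <- draw_truth(design, templates, config)
  spectra <- lapply(rownames(tr$concentrations), function(id) {
    simulate_spectrum(tr$concentrations[id, ], templates, config,
                      dilution = tr$dilution[[id]], sample_id = id)
  })
  new_spectrum_set(spectra, tr$labels,
                   truth = list(concentrations = tr$concentrations,
                                dilution = tr$dilution))
}

#' Simulate quantity-level cohorts (no spectral rendering)
#'
#' Draws the same ground-truth concentration matrix as [simulate_cohort()]
#' but skips rendering spectra. Useful for statistical power/recovery studies
#' where the spectral stage is not under test.
#'
#' @inheritParams simulate_cohort
#' @return List with `quantities` (samples x metabolites), `labels`,
#'   `dilution`.
#' @export
simulate_quantities <- function(design, templates, config = sim_config()) {
  set.seed(config$seed)
  tr <- draw_truth(design, templates, config)
  list(quantities = tr$concentrations, labels = tr$labels, dilution = tr$dilution)
}

#' Write / read a spectrum set as plain text
#'
#' One two-column tab-separated file (ppm, intensity) per sample plus a
#' `labels.csv` (sample_id, group); simulated truth goes to
#' `truth_concentrations.csv` and `truth_dilution.csv`.
#'
#' @param set [new_spectrum_set()].
#' @param dir Output directory (created if absent).
#' @return `write_spectrum_set`: the directory, invisibly;
#'   `read_spectrum_set`: the reconstructed set.
#' @export
write_spectrum_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in set$spectra) {
    utils::write.table(
      data.frame(ppm = s$ppm, intensity = s$intensity),
      file.path(dir, paste0(s$sample_id, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  utils::write.csv(
    data.frame(sample_id = names(set$labels), group = unname(set$labels)),
    file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE
  )
  if (!is.null(set$truth)) {
    utils::write.csv(
      data.frame(sample_id = rownames(set$truth$concentrations),
                 set$truth$concentrations, check.names = FALSE),
      file.path(dir, "truth_concentrations.csv"), row.names = FALSE
    )
    utils::write.csv(
      data.frame(sample_id = names(set$truth$dilution),
                 dilution = unname(set$truth$dilution)),
      file.path(dir, "truth_dilution.csv"), row.names = FALSE, quote = FALSE
    )
  }
  invisible(dir)
}

#' @rdname write_spectrum_set
#' @export
read_spectrum_set <- function(dir) {
  labels_df <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  labels <- stats::setNames(labels_df$group, labels_df$sample_id)
  spectra <- lapply(labels_df$sample_id, function(id) {
    d <- utils::read.delim(file.path(dir, paste0(id, ".tsv")))
    new_spectrum(d$ppm, d$intensity, id)
  })
  truth <- NULL
  cfile <- file.path(dir, "truth_concentrations.csv")
  if (file.exists(cfile)) {
    cd <- utils::read.csv(cfile, check.names = FALSE, stringsAsFactors = FALSE)
    conc <- as.matrix(cd[, -1, drop = FALSE])
    rownames(conc) <- cd$sample_id
    dd <- utils::read.csv(file.path(dir, "truth_dilution.csv"), stringsAsFactors = FALSE)
    truth <- list(concentrations = conc,
                  dilution = stats::setNames(dd$dilution, dd$sample_id))
  }
  new_spectrum_set(spectra, labels, truth)
}
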