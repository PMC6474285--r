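# Shared helpers: small synthetic panels and cohorts built in code.

# uniform-abundance panel of k single-peak metabolites (M1..Mk), peaks spread
# over 0.5..k/2 ppm
uniform_panel <- function(k) {
  tps <- lapply(seq_len(k), function(i) {
    new_metabolite_template(paste0("M", i),
                            data.frame(center = i / 2, height = 1),
                            linewidth = 0.0015, ref_conc = 1)
  })
  names(tps) <- paste0("M", seq_len(k))
  tps
}

# Pareto-scale a plain quantity matrix (center, divide by sqrt(sd))
pareto_mat <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  out <- sweep(sweep(X, 2, mu), 2, sqrt(pmax(sdv, 1e-12)), "/")
  out[, sdv < 1e-12] <- 0
  out
}

# quantity-level two-model SUS scenario: treatment A reverses shared+unique,
# treatment B only shared, both against the same reference group
fit_sus_pair <- function(quantities, labels, groups = c("A", "B"),
                         reference = "Model", n_orthogonal = 1) {
  fits <- lapply(groups, function(g) {
    sel <- labels %in% c(g, reference)
    X <- pareto_mat(quantities[sel, , drop = FALSE])
    list(model = fit_oplsda(X, labels[sel], n_orthogonal, positive_class = g),
         X = X)
  })
  names(fits) <- groups
  fits
}

# flat two-point-per-bucket spectrum set on a bucketing-friendly grid
flat_set <- function(n_samples = 2, points = 4001, value = 0) {
  ppm <- seq(0, 10, length.out = points)
  spectra <- lapply(seq_len(n_samples), function(i) {
    new_spectrum(ppm, rep(value, points), sprintf("s%02d", i))
  })
  labels <- stats::setNames(rep("G", n_samples), sprintf("s%02d", seq_len(n_samples)))
  new_spectrum_set(spectra, labels)
}
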