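#' Shared-and-unique-structure (SUS) comparison of two OPLS-DA models
#'
#' Compares two models that discriminate different treatments against the
#' same reference class. Each variable gets the S-plot correlation from both
#' models and is classified: `shared_positive` near the +1 diagonal,
#' `shared_negative` near the -1 diagonal, `unique_A`/`unique_B` when only
#' one model shows correlation and that model's VIP exceeds 1, else
#' `neither`.
#'
#' @param model_A,model_B `oplsda_model`s sharing the reference (-1 coded)
#'   class.
#' @param X_A,X_B The corresponding training matrices (pre-deflation),
#'   identical variable sets.
#' @param tau_diag Diagonal band half-width on `|corr_A -/+ corr_B|`
#'   (default 0.2).
#' @param tau_corr Minimum absolute correlation to count as an effect
#'   (default 0.3).
#' @return data.frame of class `sus_data`: `variable`, `corr_A`, `corr_B`,
#'   `VIP_A`, `VIP_B`, `classification`.
#' @export
sus_plot <- function(model_A, model_B, X_A, X_B, tau_diag = 0.2, tau_corr = 0.3) {
  ref_A <- names(model_A$class_coding)[model_A$class_coding == -1]
  ref_B <- names(model_B$class_coding)[model_B$class_coding == -1]
  if (!identical(ref_A, ref_B)) {
    stop("models must share the same reference class", call. = FALSE)
  }
  if (!identical(model_A$variables, model_B$variables)) {
    stop("variable sets differ between the two models", call. = FALSE)
  }
  sa <- s_plot(model_A, X_A)
  sb <- s_plot(model_B, X_B)
  va <- vip(model_A)
  vb <- vip(model_B)
  ca <- sa$correlation
  cb <- sb$correlation
  cls <- character(length(ca))
  for (j in seq_along(ca)) {
    min_abs <- min(abs(ca[j]), abs(cb[j]))
    cls[j] <- if (abs(ca[j] - cb[j]) <= tau_diag && min_abs >= tau_corr) {
      "shared_positive"
    } else if (abs(ca[j] + cb[j]) <= tau_diag && min_abs >= tau_corr) {
      "shared_negative"
    } else if (abs(ca[j]) >= tau_corr && abs(cb[j]) < tau_corr && va[j] > 1) {
      "unique_A"
    } else if (abs(cb[j]) >= tau_corr && abs(ca[j]) < tau_corr && vb[j] > 1) {
      "unique_B"
    } else "neither"
  }
  out <- data.frame(variable = sa$variable, corr_A = ca, corr_B = cb,
                    VIP_A = unname(va), VIP_B = unname(vb),
                    classification = cls, row.names = NULL)
  class(out) <- c("sus_data", "data.frame")
  out
}

#' Sample-size-aware SUS correlation threshold
#'
#' The S-plot correlation of a truly unaffected variable is a sample
#' correlation against an (essentially fixed) score vector, so its null
#' spread is about `1/sqrt(n - 1)` for `n` samples in the two-group model.
#' A fixed cutoff like 0.3 only separates signal from noise when that
#' spread is small (n of 45 or more at 95% confidence); for small cohorts
#' the cutoff should be the corresponding null quantile. This helper
#' returns `z_{(1+conf)/2} / sqrt(n - 1)`.
#'
#' @param n Number of samples in each two-class model (both groups).
#' @param conf Two-sided confidence level (default 0.99).
#' @return Correlation threshold suitable for `tau_corr` in [sus_plot()].
#' @examples
#' sus_tau_corr(16)   # ~0.67: 8 + 8 samples
#' sus_tau_corr(100)  # ~0.26: large cohort
#' @export
sus_tau_corr <- function(n, conf = 0.99) {
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  stats::qnorm((1 + conf) / 2) / sqrt(n - 1)
}

#' Venn partition of 2-4 named sets
#'
#' Enumerates every membership region (all `2^k - 1` non-empty label
#' combinations) with contents and counts. Regions are disjoint and their
#' union reconstructs the input union.
#'
#' @param named_sets Named list of 2-4 character vectors.
#' @return List of class `venn_partition`: `regions` (named list, labels
#'   joined by `&`), `counts`, `sets` (deduplicated inputs).
#' @export
venn_partition <- function(named_sets) {
  k <- length(named_sets)
  if (k < 2 || k > 4) stop("venn_partition supports 2-4 sets", call. = FALSE)
  if (is.null(names(named_sets)) || any(names(named_sets) == "")) {
    stop("sets must be named", call. = FALSE)
  }
  named_sets <- lapply(named_sets, unique)
  universe <- unique(unlist(named_sets))
  labels <- names(named_sets)
  regions <- list()
  for (mask in seq_len(2^k - 1)) {
    inside <- labels[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    outside <- setdiff(labels, inside)
    members <- universe
    for (lb in inside) members <- intersect(members, named_sets[[lb]])
    for (lb in outside) members <- setdiff(members, named_sets[[lb]])
    regions[[paste(inside, collapse = "&")]] <- members
  }
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 sets = named_sets),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("<venn_partition>\n")
  for (nm in names(x$regions)) {
    cat(sprintf("  %-12s %d\n", nm, length(x$regions[[nm]])))
  }
  invisible(x)
}
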