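#' Bucket table container
#'
#' Samples x buckets matrix of integrated spectral intensities with bucket
#' edges, group labels and provenance flags. Produced by [bucket()], modified
#' by [pqn_normalize()] and [pareto_scale()].
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids).
#' @param edges data.frame with columns `lo`, `hi` (half-open \[lo, hi) ppm),
#'   ascending, non-overlapping, one row per column of `values`.
#' @param labels Named character vector, sample id -> group.
#' @param provenance Character vector of applied steps (`"raw"`, `"pqn"`,
#'   `"pareto"`).
#' @return A `bucket_table` object.
#' @export
new_bucket_table <- function(values, edges, labels, provenance = "raw") {
  stopifnot(is.matrix(values), nrow(edges) == ncol(values))
  if (any(diff(edges$lo) <= 0)) stop("bucket edges must ascend", call. = FALSE)
  if (any(edges$hi[-nrow(edges)] > edges$lo[-1] + 1e-12)) {
    stop("bucket edges must not overlap", call. = FALSE)
  }
  labels <- labels[rownames(values)]
  structure(list(values = values, edges = edges, labels = labels,
                 provenance = provenance),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table> %d samples x %d buckets [%s]\n",
              nrow(x$values), ncol(x$values), paste(x$provenance, collapse = "+")))
  invisible(x)
}

#' @export
dim.bucket_table <- function(x) dim(x$values)

#' Reference a spectrum to the TSP singlet at 0 ppm
#'
#' Shifts the chemical-shift axis so the maximum inside the search window
#' sits at exactly 0 ppm; intensities are untouched. The peak must rise above
#' five times the median absolute intensity in the window to count as TSP.
#'
#' @param spectrum [new_spectrum()].
#' @param search_window ppm interval to search, default `c(-0.2, 0.2)`.
#' @return The re-referenced spectrum.
#' @export
reference_to_tsp <- function(spectrum, search_window = c(-0.2, 0.2)) {
  idx <- which(spectrum$ppm >= search_window[1] & spectrum$ppm <= search_window[2])
  if (!length(idx)) stop("search window does not overlap the ppm axis", call. = FALSE)
  win <- spectrum$intensity[idx]
  if (max(win) <= 5 * stats::median(abs(win))) {
    stop("no TSP peak in search window", call. = FALSE)
  }
  apex <- spectrum$ppm[idx[which.max(win)]]
  new_spectrum(spectrum$ppm - apex, spectrum$intensity, spectrum$sample_id)
}

#' Asymmetric least squares baseline correction
#'
#' Estimates a slowly varying baseline by iteratively reweighted penalized
#' least squares (second-difference penalty; points above the current
#' baseline get weight `asymmetry`, points below get `1 - asymmetry`) and
#' subtracts it. Narrow peaks are barely attenuated while drifts and offsets
#' are removed.
#'
#' @param spectrum [new_spectrum()] with at least 10 points.
#' @param smoothness Penalty weight lambda (> 0); larger = stiffer baseline.
#' @param asymmetry Weight p in (0, 1) for points above the baseline.
#' @param n_iter Reweighting iterations.
#' @return Baseline-subtracted spectrum; the estimated baseline is attached
#'   as attribute `"baseline"`.
#' @export
baseline_correct <- function(spectrum, smoothness = 1e6, asymmetry = 0.001,
                             n_iter = 10) {
  if (length(spectrum$ppm) < 10L) stop("need at least 10 points", call. = FALSE)
  if (smoothness <= 0) stop("smoothness must be positive", call. = FALSE)
  if (asymmetry <= 0 || asymmetry >= 1) stop("asymmetry must lie in (0, 1)", call. = FALSE)
  y <- spectrum$intensity
  n <- length(y)
  D <- Matrix::diff(Matrix::Diagonal(n), differences = 2)
  P <- smoothness * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(n_iter)) {
    A <- Matrix::forceSymmetric(Matrix::Diagonal(x = w) + P)
    z <- as.numeric(Matrix::solve(Matrix::Cholesky(A), w * y))
    w_new <- ifelse(y > z, asymmetry, 1 - asymmetry)
    if (all(w_new == w) && i > 1L) break
    w <- w_new
  }
  out <- new_spectrum(spectrum$ppm, y - z, spectrum$sample_id)
  attr(out, "baseline") <- z
  out
}

shift_vector <- function(v, s) {
  n <- length(v)
  if (s == 0) return(v)
  if (s > 0) c(rep(v[1], s), v[seq_len(n - s)])
  else c(v[(1 - s):n], rep(v[n], -s))
}

#' Segment-wise cross-correlation alignment
#'
#' Splits the common axis into fixed-width segments and, per sample and
#' segment, applies the integer-point shift (clamped to `max_shift`) that
#' maximizes cross-correlation with the corresponding segment of the
#' cohort-median spectrum; gaps are filled with edge values.
#'
#' @param set [new_spectrum_set()] on a common grid.
#' @param segment_width Segment width in ppm (default 0.02).
#' @param max_shift Maximum shift in grid points (default 5).
#' @return Aligned spectrum set; the applied shifts (samples x segments) are
#'   attached as attribute `"shifts"`.
#' @export
align_segments <- function(set, segment_width = 0.02, max_shift = 5) {
  if (max_shift < 0) stop("max_shift must be >= 0", call. = FALSE)
  grid <- common_grid(set)
  dx <- grid[2] - grid[1]
  seg_len <- max(1L, round(segment_width / dx))
  if (seg_len < 3L) stop("segment_width smaller than 3 grid points", call. = FALSE)
  n <- length(grid)
  starts <- seq(1L, n, by = seg_len)
  mat <- do.call(rbind, lapply(set$spectra, function(s) s$intensity))
  med <- apply(mat, 2, stats::median)
  shifts <- matrix(0L, nrow(mat), length(starts))
  for (j in seq_along(starts)) {
    idx <- starts[j]:min(starts[j] + seg_len - 1L, n)
    if (length(idx) < 3L) next
    ref <- med[idx]
    candidates <- (-max_shift):max_shift
    candidates <- candidates[order(abs(candidates))]  # ties favor no shift
    for (i in seq_len(nrow(mat))) {
      seg <- mat[i, idx]
      best <- 0L; best_score <- -Inf
      for (s in candidates) {
        sv <- shift_vector(seg, s)
        nrm <- sqrt(sum(sv^2))
        score <- if (nrm > 0) sum(sv * ref) / nrm else 0  # normalized CC:
        # edge filling must not be able to inflate the match
        if (score > best_score + 1e-12) { best_score <- score; best <- s }
      }
      if (best != 0L) mat[i, idx] <- shift_vector(seg, best)
      shifts[i, j] <- best
    }
  }
  spectra <- lapply(seq_len(nrow(mat)), function(i) {
    new_spectrum(grid, mat[i, ], set$spectra[[i]]$sample_id)
  })
  out <- new_spectrum_set(spectra, set$labels, set$truth)
  rownames(shifts) <- names(set$labels)
  attr(out, "shifts") <- shifts
  out
}

# exact trapezoidal integral of the piecewise-linear spectrum over [a, b],
# evaluated for many intervals at once via an edge-augmented cumulative sum
bucket_integrals <- function(ppm, intensity, lo, hi) {
  edges <- sort(unique(c(lo, hi)))
  aug <- sort(unique(c(ppm, edges[edges >= ppm[1] & edges <= ppm[length(ppm)]])))
  vals <- stats::approx(ppm, intensity, xout = aug)$y
  ct <- c(0, cumsum(diff(aug) * (vals[-length(vals)] + vals[-1]) / 2))
  ct_at <- function(x) {
    x <- pmin(pmax(x, aug[1]), aug[length(aug)])
    ct[match(x, aug)]
  }
  ct_at(hi) - ct_at(lo)
}

#' Bucket spectra into fixed-width integrated bins
#'
#' Segments the axis into half-open `[lo, lo + width)` buckets over `range`,
#' drops every bucket whose interval intersects the open water-exclusion
#' interval, and fills each kept bucket with the trapezoidal integral of
#' intensity over the bucket. With the defaults (0.0025 ppm over 0-10 ppm,
#' excluding 4.65-5.25 ppm) exactly 3760 of 4000 buckets are retained.
#'
#' @param set [new_spectrum_set()] on a common grid.
#' @param width Bucket width in ppm, default 0.0025; must divide the range
#'   and the exclusion boundaries to within 1e-9 ppm.
#' @param range ppm range, default `c(0, 10)`.
#' @param exclude Water window, default `c(4.65, 5.25)`; `NULL` disables.
#' @return A [new_bucket_table()].
#' @export
bucket <- function(set, width = 0.0025, range = c(0, 10), exclude = c(4.65, 5.25)) {
  grid <- common_grid(set)
  divisible <- function(x) {
    r <- (x - range[1]) / width
    abs(r - round(r)) * width < 1e-9
  }
  if (!divisible(range[2]) || (!is.null(exclude) && !all(divisible(exclude)))) {
    stop("width must divide the range and exclusion boundaries", call. = FALSE)
  }
  n_buckets <- round((range[2] - range[1]) / width)
  lo <- range[1] + width * (seq_len(n_buckets) - 1)
  hi <- lo + width
  keep <- rep(TRUE, n_buckets)
  if (!is.null(exclude)) keep <- !(hi > exclude[1] + 1e-12 & lo < exclude[2] - 1e-12)
  lo <- lo[keep]; hi <- hi[keep]
  vals <- t(vapply(set$spectra, function(s) {
    bucket_integrals(s$ppm, s$intensity, lo, hi)
  }, numeric(length(lo))))
  rownames(vals) <- names(set$labels)
  colnames(vals) <- sprintf("ppm_%.4f", lo)
  new_bucket_table(vals, data.frame(lo = lo, hi = hi), set$labels, "raw")
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution: each sample is first scaled to unit total
#' integral, the per-bucket median over samples forms the reference spectrum,
#' the per-sample quotient vector is taken over signal-carrying buckets
#' (reference above the `signal_quantile` reference quantile and above a
#' small absolute floor), and the sample is divided by the median quotient.
#' Restricting quotients to signal buckets keeps noise-only and
#' residual-background buckets -- which do not scale with dilution -- from
#' dominating the quotient median in sparse spectra.
#' The reported dilution factor combines the total-integral factor with the
#' quotient and is normalized to cohort median 1 (factors are identifiable
#' only up to a cohort-wide constant). Negative bucket values are floored at
#' 0 first.
#'
#' @param table [new_bucket_table()] with >= 2 samples.
#' @param eps Absolute reference floor below which buckets are always
#'   ignored in quotients.
#' @param signal_quantile Reference quantile defining signal buckets for the
#'   quotient median (default 0.95); set to 0 to use every bucket above
#'   `eps` (the textbook all-variable variant).
#' @return List of class `pqn_result`: `table` (normalized bucket table),
#'   `dilution_factors` (named, median 1), `reference_spectrum`.
#' @export
pqn_normalize <- function(table, eps = 1e-12, signal_quantile = 0.95) {
  X <- pmax(table$values, 0)
  if (nrow(X) < 2L) stop("PQN needs at least 2 samples", call. = FALSE)
  totals <- rowSums(X)
  if (any(totals <= 0)) {
    stop("sample(s) with non-positive total integral: ",
         paste(rownames(X)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  X1 <- X / totals
  ref <- apply(X1, 2, stats::median)
  sel <- ref > max(eps, stats::quantile(ref, signal_quantile))
  if (!any(sel)) sel <- ref > eps
  q <- apply(X1[, sel, drop = FALSE], 1, function(row) stats::median(row / ref[sel]))
  factors <- (totals / stats::median(totals)) * q
  factors <- factors / stats::median(factors)
  out <- table$values / factors
  res <- list(
    table = new_bucket_table(out, table$edges, table$labels,
                             c(table$provenance, "pqn")),
    dilution_factors = factors,
    reference_spectrum = ref
  )
  class(res) <- "pqn_result"
  res
}

#' @export
print.pqn_result <- function(x, ...) {
  cat(sprintf("<pqn_result> %d samples, dilution factors %.3f-%.3f\n",
              length(x$dilution_factors),
              min(x$dilution_factors), max(x$dilution_factors)))
  invisible(x)
}

#' Pareto scaling
#'
#' Centers each bucket and divides by the square root of its sample standard
#' deviation (ddof = 1) -- intermediate between no scaling and unit-variance
#' scaling, damping the dominance of intense buckets without blowing up
#' noise. Near-constant buckets (SD below `eps`) are set to 0 and flagged.
#'
#' @param table [new_bucket_table()] with >= 2 samples.
#' @param eps SD threshold below which a bucket counts as constant.
#' @return Scaled [new_bucket_table()]; flagged column indices in attribute
#'   `"constant_buckets"`, column means/SDs in `"center"`/`"scale_sd"`.
#' @export
pareto_scale <- function(table, eps = 1e-12) {
  X <- table$values
  if (nrow(X) < 2L) stop("Pareto scaling needs at least 2 samples", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  flagged <- which(sdv < eps)
  sc <- sqrt(pmax(sdv, eps))
  out <- sweep(sweep(X, 2, mu), 2, sc, "/")
  if (length(flagged)) out[, flagged] <- 0
  res <- new_bucket_table(out, table$edges, table$labels,
                          c(table$provenance, "pareto"))
  attr(res, "constant_buckets") <- flagged
  attr(res, "center") <- mu
  attr(res, "scale_sd") <- sdv
  res
}

#' Integrate bucket values into metabolite quantities
#'
#' Sums bucket values over the ppm interval(s) assigned to each metabolite.
#' A bucket contributes to an interval when the two intervals overlap.
#'
#' @param table [new_bucket_table()] (typically PQN-normalized, unscaled).
#' @param assignments Named list, metabolite -> data.frame(lo, hi) of ppm
#'   intervals inside the bucketed range and outside the water window, e.g.
#'   from [default_assignments()].
#' @param exclude Water window the assignments must avoid.
#' @return data.frame with `sample_id`, `group` and one column per
#'   metabolite.
#' @export
integrate_metabolites <- function(table, assignments, exclude = c(4.65, 5.25)) {
  edges <- table$edges
  rng <- c(min(edges$lo), max(edges$hi))
  qmat <- matrix(0, nrow(table$values), length(assignments),
                 dimnames = list(rownames(table$values), names(assignments)))
  for (nm in names(assignments)) {
    iv <- assignments[[nm]]
    if (!nrow(iv)) {
      warning("no assignment intervals for ", nm, "; quantity set to 0")
      next
    }
    if (any(iv$lo < rng[1] - 1e-9 | iv$hi > rng[2] + 1e-9)) {
      stop("assignment for ", nm, " outside the bucketed range", call. = FALSE)
    }
    if (!is.null(exclude) && any(iv$hi > exclude[1] + 1e-12 & iv$lo < exclude[2] - 1e-12)) {
      stop("assignment for ", nm, " overlaps the excluded water region", call. = FALSE)
    }
    cols <- rep(FALSE, nrow(edges))
    for (k in seq_len(nrow(iv))) {
      cols <- cols | (edges$hi > iv$lo[k] + 1e-12 & edges$lo < iv$hi[k] - 1e-12)
    }
    qmat[, nm] <- rowSums(table$values[, cols, drop = FALSE])
  }
  data.frame(sample_id = rownames(table$values),
             group = unname(table$labels[rownames(table$values)]),
             qmat, check.names = FALSE, row.names = NULL)
}

#' Write a bucket table as CSV with a JSON provenance sidecar
#'
#' @param table [new_bucket_table()].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param params Extra parameters to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_bucket_table <- function(table, path, params = list()) {
  df <- data.frame(sample_id = rownames(table$values),
                   group = unname(table$labels[rownames(table$values)]),
                   table$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- c(list(provenance = table$provenance,
                    n_buckets = ncol(table$values),
                    bucket_integration = "trapezoid",
                    edges_ppm = range(c(table$edges$lo, table$edges$hi))),
               params)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
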