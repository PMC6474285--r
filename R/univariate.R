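#' Per-metabolite fold change between two groups
#'
#' `FC = mean(numerator group) / mean(denominator group)` on raw
#' (normalized, unscaled) quantities. The numerator is the non-reference
#' group, the denominator the comparison baseline. Rows with non-positive
#' denominator mean are flagged and left `NA` rather than crashing.
#'
#' @param quantities data.frame from [integrate_metabolites()] (or any
#'   `sample_id`, `group`, metabolite... layout).
#' @param group_num,group_den Group names (numerator / denominator), each
#'   with >= 2 samples.
#' @return data.frame: `metabolite`, `FC`, `log2FC`, `flagged`.
#' @export
fold_change <- function(quantities, group_num, group_den) {
  mets <- setdiff(names(quantities), c("sample_id", "group"))
  a <- quantities[quantities$group == group_num, mets, drop = FALSE]
  b <- quantities[quantities$group == group_den, mets, drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  mu_a <- colMeans(a)
  mu_b <- colMeans(b)
  flagged <- mu_b <= 0
  fc <- ifelse(flagged, NA_real_, mu_a / mu_b)
  data.frame(metabolite = mets, FC = unname(fc), log2FC = unname(log2(fc)),
             flagged = unname(flagged), row.names = NULL)
}

#' Choose a two-group test by per-group normality
#'
#' Shapiro-Wilk on each group; when both p-values reach the normality alpha,
#' a two-sided Welch t-test is used, otherwise a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test.
#'
#' @param group_a,group_b Numeric vectors, each with >= 3 values.
#' @param alpha_normality Shapiro-Wilk alpha (default 0.05).
#' @return `"t"` or `"mann_whitney"`.
#' @export
choose_test <- function(group_a, group_b, alpha_normality = 0.05) {
  if (length(group_a) < 3L || length(group_b) < 3L) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  shapiro_p <- function(x) {
    if (stats::sd(x) == 0) return(0)  # degenerate: not plausibly Gaussian
    stats::shapiro.test(x)$p.value
  }
  if (shapiro_p(group_a) >= alpha_normality && shapiro_p(group_b) >= alpha_normality) {
    "t"
  } else {
    "mann_whitney"
  }
}

two_group_p <- function(a, b, test) {
  if (test == "t") {
    stats::t.test(a, b, var.equal = FALSE)$p.value
  } else {
    stats::wilcox.test(a, b, exact = FALSE)$p.value
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-implemented step-up procedure: sort p-values ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clip to 1 and return in the input
#' order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(ranked)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Fold-change table over multiple comparisons
#'
#' For each comparison (numerator vs denominator group) computes per
#' metabolite the fold change, the test chosen by [choose_test()], its raw
#' p-value and the BH-adjusted p-value (adjusted within the comparison).
#'
#' @inheritParams fold_change
#' @param comparisons List of `c(numerator, denominator)` group pairs.
#' @param alpha_normality Passed to [choose_test()].
#' @return Long-format data.frame of class `fold_change_table`:
#'   `comparison`, `metabolite`, `FC`, `log2FC`, `raw_p`, `adjusted_p`,
#'   `test_used`, `flagged`.
#' @export
fc_table <- function(quantities, comparisons, alpha_normality = 0.05) {
  rows <- list()
  for (cmp in comparisons) {
    num <- cmp[1]; den <- cmp[2]
    fc <- fold_change(quantities, num, den)
    mets <- fc$metabolite
    tests <- character(length(mets)); pvals <- numeric(length(mets))
    for (i in seq_along(mets)) {
      a <- quantities[quantities$group == num, mets[i]]
      b <- quantities[quantities$group == den, mets[i]]
      tests[i] <- choose_test(a, b, alpha_normality)
      pvals[i] <- two_group_p(a, b, tests[i])
    }
    rows[[paste(num, "vs", den)]] <- data.frame(
      comparison = paste(num, "vs", den), metabolite = mets,
      FC = fc$FC, log2FC = fc$log2FC, raw_p = pvals,
      adjusted_p = bh_adjust(pvals), test_used = tests, flagged = fc$flagged,
      row.names = NULL
    )
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "fc_statistic") <- "mean"
  class(out) <- c("fold_change_table", "data.frame")
  out
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

fc_color <- function(log2fc, limit) {
  pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(255)
  x <- pmax(pmin(log2fc, limit), -limit)
  idx <- round((x + limit) / (2 * limit) * 254) + 1
  ifelse(is.na(log2fc), "#BBBBBB", pal[idx])
}

#' Render a colored fold-change table
#'
#' Maps log2 fold changes onto a symmetric blue-white-red diverging scale
#' (FC = 1 is the neutral white midpoint; FC = 2 and FC = 0.5 mirror each
#' other) and attaches significance stars at adjusted-p thresholds
#' 0.05/0.01/0.001. The CSV written for a fixed input is byte-identical
#' across runs.
#'
#' @param table [fc_table()] output.
#' @param path Optional CSV path for the deterministic artifact.
#' @param limit Symmetric |log2FC| color saturation limit (default 2).
#' @return data.frame with added `color` (hex) and `stars` columns.
#' @export
render_fc_table <- function(table, path = NULL, limit = 2) {
  out <- as.data.frame(table)
  out$color <- fc_color(out$log2FC, limit)
  out$stars <- significance_stars(out$adjusted_p)
  if (!is.null(path)) {
    fmt <- out
    for (col in c("FC", "log2FC", "raw_p", "adjusted_p")) {
      fmt[[col]] <- sprintf("%.6g", fmt[[col]])
    }
    utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  }
  out
}

#' Heatmap figure of a fold-change table
#'
#' @param table [fc_table()] output.
#' @param limit Symmetric |log2FC| color limit.
#' @return A ggplot object (metabolites x comparisons, tiles colored by
#'   log2FC, stars overlaid).
#' @export
plot_fc_table <- function(table, limit = 2) {
  df <- as.data.frame(table)
  df$stars <- significance_stars(df$adjusted_p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$metabolite,
                                   fill = .data$log2FC)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#FFFFFF",
                                  high = "#B2182B", limits = c(-limit, limit),
                                  oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 FC") +
    ggplot2::theme_minimal()
}

# minimal squish to avoid depending on the scales package surface directly
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
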