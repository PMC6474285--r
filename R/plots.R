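#' OPLS-DA / PCA score plot
#'
#' Predictive vs first orthogonal score (OPLS-DA) or the first two principal
#' components (PCA), colored by group.
#'
#' @param model `oplsda_model` or `pca_model`.
#' @param labels Named group vector (required for `pca_model`; taken from
#'   the model for OPLS-DA).
#' @return A ggplot object.
#' @export
plot_scores <- function(model, labels = NULL) {
  if (inherits(model, "oplsda_model")) {
    t2 <- if (model$n_orthogonal > 0) model$orthogonal[[1]]$t_o else
      seq_along(model$predictive$t) * 0
    df <- data.frame(t1 = model$predictive$t, t2 = t2, group = model$y)
    xl <- "t[pred]"; yl <- if (model$n_orthogonal > 0) "t[ortho 1]" else ""
  } else {
    df <- data.frame(t1 = model$scores[, 1],
                     t2 = if (ncol(model$scores) > 1) model$scores[, 2] else 0,
                     group = labels[rownames(model$scores)])
    xl <- "PC1"; yl <- "PC2"
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$t1, .data$t2, color = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::stat_ellipse(level = 0.95, linewidth = 0.3) +
    ggplot2::labs(x = xl, y = yl) +
    ggplot2::theme_classic()
}

#' S-plot figure
#'
#' Covariance vs correlation with the predictive scores; high-|correlation|,
#' high-|covariance| extremes are the reliable discriminators.
#'
#' @param splot [s_plot()] output.
#' @param vip_scores Optional VIP vector; points with VIP > 1 are
#'   highlighted.
#' @return A ggplot object.
#' @export
plot_s_plot <- function(splot, vip_scores = NULL) {
  df <- as.data.frame(splot)
  df$important <- if (!is.null(vip_scores)) vip_scores > 1 else FALSE
  ggplot2::ggplot(df, ggplot2::aes(.data$covariance, .data$correlation,
                                   color = .data$important)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_color_manual(values = c("FALSE" = "grey50", "TRUE" = "#B2182B"),
                                guide = "none") +
    ggplot2::labs(x = "cov(t, x)", y = "corr(t, x)") +
    ggplot2::theme_classic()
}

#' SUS-plot figure
#'
#' Correlation from model A vs model B with the +/- diagonals and the
#' classification coloring.
#'
#' @param sus [sus_plot()] output.
#' @return A ggplot object.
#' @export
plot_sus <- function(sus) {
  df <- as.data.frame(sus)
  ggplot2::ggplot(df, ggplot2::aes(.data$corr_A, .data$corr_B,
                                   color = .data$classification)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "#B2182B",
                         linetype = 2, linewidth = 0.3) +
    ggplot2::geom_abline(slope = -1, intercept = 0, color = "#1B7837",
                         linetype = 2, linewidth = 0.3) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_cartesian(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "corr (model A)", y = "corr (model B)") +
    ggplot2::theme_classic()
}
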