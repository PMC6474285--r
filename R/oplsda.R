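#' Two-class OPLS-DA
#'
#' Orthogonal projections to latent structures discriminant analysis for two
#' classes, NIPALS-style. The class vector is coded -1/+1 and centered. Each
#' orthogonal round computes `w = X'y/|X'y|`, `t = Xw`, `p = X't/(t't)`,
#' splits off the y-orthogonal part of the loading `w_o = p - (w'p)w`
#' (normalized), forms `t_o = X w_o`, `p_o = X't_o/(t_o't_o)` and deflates
#' `X <- X - t_o p_o'`. The predictive component is then fit on the deflated
#' matrix. Component signs are fixed so the largest-magnitude predictive
#' weight is positive.
#'
#' @param X Scaled numeric matrix (samples x variables), e.g. Pareto-scaled
#'   buckets or metabolite quantities.
#' @param y Two-class vector (character/factor), length `nrow(X)`; each class
#'   needs >= 2 samples.
#' @param n_orthogonal Number of orthogonal components to extract (>= 0).
#'   Extraction stops early when the orthogonal weight norm collapses; the
#'   actual count is recorded.
#' @param positive_class Class coded +1; default: the later of the two sorted
#'   class names. The other (reference) class is coded -1.
#' @return List of class `oplsda_model` with elements `predictive` (`w`, `t`,
#'   `p`, `q`), `orthogonal` (list of `w_o`, `t_o`, `p_o`), `n_orthogonal`,
#'   `R2X`, `R2Y`, `class_coding`, `y`, `y_centered`, `y_mean`, `variables`.
#' @export
fit_oplsda <- function(X, y, n_orthogonal = 1, positive_class = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("y must contain exactly two classes", call. = FALSE)
  if (any(table(y) < 2L)) stop("each class needs >= 2 samples", call. = FALSE)
  if (n_orthogonal < 0) stop("n_orthogonal must be >= 0", call. = FALSE)
  if (is.null(positive_class)) positive_class <- classes[2]
  if (!positive_class %in% classes) stop("positive_class not present in y", call. = FALSE)
  coding <- stats::setNames(ifelse(classes == positive_class, 1, -1), classes)
  y_raw <- unname(coding[y])
  y_mean <- mean(y_raw)
  yc <- y_raw - y_mean
  if (all(yc == 0)) stop("one class empty after coding", call. = FALSE)

  X0 <- X
  Xd <- X
  ortho <- list()
  for (k in seq_len(n_orthogonal)) {
    w <- crossprod(Xd, yc)
    w <- w / sqrt(sum(w^2))
    t_p <- Xd %*% w
    p <- crossprod(Xd, t_p) / sum(t_p^2)
    w_o <- p - c(crossprod(w, p)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-10) break
    w_o <- w_o / nrm
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    if (w_o[which.max(abs(w_o))] < 0) { w_o <- -w_o; t_o <- -t_o; p_o <- -p_o }
    Xd <- Xd - tcrossprod(t_o, p_o)
    ortho[[k]] <- list(w_o = drop(w_o), t_o = drop(t_o), p_o = drop(p_o))
  }

  w <- crossprod(Xd, yc)
  w <- w / sqrt(sum(w^2))
  t_p <- Xd %*% w
  p <- crossprod(Xd, t_p) / sum(t_p^2)
  q <- sum(yc * t_p) / sum(t_p^2)
  if (w[which.max(abs(w))] < 0) { w <- -w; t_p <- -t_p; p <- -p; q <- -q }

  ss_y <- sum(yc^2)
  R2Y <- 1 - sum((yc - q * t_p)^2) / ss_y
  ss_x <- sum(X0^2)
  explained_x <- sum(t_p^2) * sum(p^2) +
    if (length(ortho)) sum(vapply(ortho, function(o) sum(o$t_o^2) * sum(o$p_o^2),
                                  numeric(1))) else 0
  structure(
    list(predictive = list(w = drop(w), t = drop(t_p), p = drop(p), q = q),
         orthogonal = ortho, n_orthogonal = length(ortho),
         R2X = explained_x / ss_x, R2Y = R2Y,
         class_coding = coding, y = y, y_centered = yc, y_mean = y_mean,
         variables = colnames(X)),
    class = "oplsda_model"
  )
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf(
    "<oplsda_model> %s (+1) vs %s (-1): 1 predictive + %d orthogonal; R2X = %.3f, R2Y = %.3f\n",
    names(x$class_coding)[x$class_coding == 1],
    names(x$class_coding)[x$class_coding == -1],
    x$n_orthogonal, x$R2X, x$R2Y))
  invisible(x)
}

#' Project new samples through a fitted OPLS-DA model
#'
#' Applies the stored orthogonal filtering (score, deflate) and predictive
#' component to new rows on the same variable set and scaling as the
#' training matrix.
#'
#' @param object `oplsda_model`.
#' @param newdata Numeric matrix with the training variable count.
#' @param ... Unused.
#' @return List: `t` (predictive scores), `y_hat` (continuous class
#'   prediction on the -1/+1 scale), `class` (predicted labels).
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != length(object$predictive$w)) {
    stop("newdata column count does not match the model", call. = FALSE)
  }
  for (o in object$orthogonal) {
    t_o <- Xn %*% o$w_o
    Xn <- Xn - tcrossprod(t_o, o$p_o)
  }
  t_p <- drop(Xn %*% object$predictive$w)
  y_hat <- t_p * object$predictive$q + object$y_mean
  lab <- names(object$class_coding)
  list(t = t_p, y_hat = y_hat,
       class = ifelse(y_hat >= 0, lab[object$class_coding == 1],
                      lab[object$class_coding == -1]))
}

# deterministic stratified fold assignment: per class, shuffle then deal
# round-robin
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated R2Y and Q2Y
#'
#' Stratified k-fold cross-validation in which every fold refits the full
#' OPLS-DA model -- orthogonal filtering included -- on the training split
#' only. `Q2Y = 1 - PRESS / SS_tot` with PRESS accumulated over folds on the
#' -1/+1 coded labels; `R2Y` comes from the fit on all samples.
#'
#' @inheritParams fit_oplsda
#' @param folds Number of folds (default 7), at most `nrow(X)`.
#' @param seed Integer seed fixing the fold assignment.
#' @return List with `R2Y`, `Q2Y`, `folds`, `n_orthogonal`.
#' @export
cross_validate <- function(X, y, n_orthogonal = 1, folds = 7, seed = 1,
                           positive_class = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (folds > nrow(X)) stop("folds must not exceed the sample count", call. = FALSE)
  if (folds < 2) stop("need at least 2 folds", call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("y must contain exactly two classes", call. = FALSE)
  if (is.null(positive_class)) positive_class <- classes[2]
  coding <- stats::setNames(ifelse(classes == positive_class, 1, -1), classes)
  y_num <- unname(coding[y])

  assign <- stratified_folds(y, folds, seed)
  press <- 0
  for (f in seq_len(folds)) {
    test <- which(assign == f)
    train <- which(assign != f)
    if (length(unique(y[train])) < 2L) {
      stop("fold ", f, " loses a class in its training split", call. = FALSE)
    }
    if (!length(test)) next
    m <- fit_oplsda(X[train, , drop = FALSE], y[train], n_orthogonal,
                    positive_class = positive_class)
    pr <- predict(m, X[test, , drop = FALSE])
    press <- press + sum((y_num[test] - pr$y_hat)^2)
  }
  ss_tot <- sum((y_num - mean(y_num))^2)
  full <- fit_oplsda(X, y, n_orthogonal, positive_class = positive_class)
  list(R2Y = full$R2Y, Q2Y = 1 - press / ss_tot,
       folds = folds, n_orthogonal = full$n_orthogonal)
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Adds orthogonal components while each one improves Q2Y by at least
#' `min_gain`; returns the smallest count beyond which the gain drops below
#' that threshold, capped at `max_components`.
#'
#' @inheritParams cross_validate
#' @param max_components Cap on the orthogonal component count (>= 0).
#' @param min_gain Minimum Q2Y improvement to accept another component.
#' @return Integer component count.
#' @export
auto_orthogonal <- function(X, y, max_components = 3, folds = 7, seed = 1,
                            min_gain = 0.01, positive_class = NULL) {
  if (max_components < 0) stop("max_components must be >= 0", call. = FALSE)
  if (max_components == 0) return(0L)
  q_prev <- cross_validate(X, y, 0, folds, seed, positive_class)$Q2Y
  for (k in seq_len(max_components)) {
    q_k <- cross_validate(X, y, k, folds, seed, positive_class)$Q2Y
    if (q_k - q_prev < min_gain) return(k - 1L)
    q_prev <- q_k
  }
  as.integer(max_components)
}

#' S-plot coordinates
#'
#' For each variable, the covariance and correlation of the (training,
#' pre-deflation) data column with the predictive score vector. Extreme
#' points combine high model contribution (covariance) with high reliability
#' (correlation).
#'
#' @param model `oplsda_model`.
#' @param X The training matrix the model was fit on (before deflation);
#'   column count must match.
#' @param eps SD floor; near-constant columns get correlation 0 and a flag.
#' @return data.frame of class `s_plot_data`: `variable`, `covariance`,
#'   `correlation`, `flagged_constant`.
#' @export
s_plot <- function(model, X, eps = 1e-12) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$predictive$w)) {
    stop("X column count does not match the model", call. = FALSE)
  }
  t_p <- model$predictive$t
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  tc <- t_p - mean(t_p)
  covs <- drop(crossprod(Xc, tc)) / (n - 1)
  sds <- apply(X, 2, stats::sd)
  flag <- sds < eps
  corr <- ifelse(flag, 0, covs / (stats::sd(t_p) * pmax(sds, eps)))
  out <- data.frame(
    variable = if (is.null(colnames(X))) paste0("V", seq_len(ncol(X))) else colnames(X),
    covariance = covs, correlation = corr, flagged_constant = flag,
    row.names = NULL
  )
  class(out) <- c("s_plot_data", "data.frame")
  out
}

#' Variable influence on projection (VIP)
#'
#' Single-component VIP on the predictive component:
#' `VIP_j = sqrt(p * w_j^2)` with normalized weights, so the mean squared
#' VIP is exactly 1 and VIP > 1 marks variables contributing more than
#' average to the class separation.
#'
#' @param model `oplsda_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  w <- model$predictive$w
  v <- sqrt(length(w) * w^2)
  names(v) <- model$variables %||% paste0("V", seq_along(w))
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
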