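test_that("PCA reproduces the covariance eigenstructure", {
  set.seed(17)
  # rank-1 data: all variance along one direction
  v <- c(1, 2, -1, 0.5)
  X1 <- outer(stats::rnorm(6), v)
  p1 <- fit_pca(X1, 1)
  expect_equal(p1$explained_variance_fraction[1], 1, tolerance = 1e-10)

  # oracle: eigendecomposition of the covariance matrix, up to column sign
  X <- matrix(stats::rnorm(20), 5, 4)
  pc <- fit_pca(X, 3)
  ev <- eigen(stats::cov(X))
  Xc <- sweep(X, 2, colMeans(X))
  for (j in 1:3) {
    oracle <- Xc %*% ev$vectors[, j]
    d <- min(max(abs(pc$scores[, j] - oracle)), max(abs(pc$scores[, j] + oracle)))
    expect_lt(d, 1e-8)
  }
  # loadings orthonormal; full-rank reconstruction
  expect_equal(crossprod(pc$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  pfull <- fit_pca(X, 4)
  rec <- sweep(pfull$scores %*% t(pfull$loadings), 2, -pfull$center)
  expect_lt(max(abs(rec - X)), 1e-8)
  expect_error(fit_pca(X, 5), "n_components")
  X[1, 1] <- NA
  expect_error(fit_pca(X, 1), "finite")
})

test_that("zero-orthogonal OPLS-DA equals the NIPALS PLS1 first component", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(stats::rnorm(20 * 50), 20, 50)
    y <- rep(c("A", "B"), each = 10)
    m <- fit_oplsda(X, y, 0)
    yc <- ifelse(y == "B", 1, -1); yc <- yc - mean(yc)
    w <- crossprod(X, yc); w <- w / sqrt(sum(w^2))
    t_oracle <- drop(X %*% w)
    d <- min(max(abs(m$predictive$t - t_oracle)),
             max(abs(m$predictive$t + t_oracle)))
    expect_lt(d, 1e-8)
    expect_equal(m$n_orthogonal, 0)
  }
})

test_that("orthogonal filtering isolates the class axis in a constructed case", {
  y <- rep(c("A", "B"), each = 8)
  yv <- ifelse(y == "B", 1, -1)
  set.seed(3)
  v2 <- stats::rnorm(16, 0, 3)
  v2 <- v2 - mean(v2)
  v2 <- v2 - yv * sum(yv * v2) / sum(yv^2)  # exactly class-orthogonal
  X <- cbind(yv, v2)
  m <- fit_oplsda(X, y, 1)
  expect_gt(abs(m$predictive$p[1]) / sqrt(sum(m$predictive$p^2)), 0.99)
  expect_gt(m$R2Y, 0.99)
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  set.seed(11)
  X <- matrix(stats::rnorm(18 * 40), 18, 40)
  y <- rep(c("A", "B"), each = 9)
  m <- fit_oplsda(X, y, 3)
  for (o in m$orthogonal) {
    expect_lt(abs(sum(m$predictive$t * o$t_o)), 1e-8)
  }
})

test_that("class coding direction does not change model quality", {
  set.seed(21)
  X <- matrix(stats::rnorm(16 * 25), 16, 25)
  y <- rep(c("A", "B"), each = 8)
  X[y == "B", 1:4] <- X[y == "B", 1:4] + 2
  Xs <- scale(X)
  m1 <- fit_oplsda(Xs, y, 1, positive_class = "B")
  m2 <- fit_oplsda(Xs, y, 1, positive_class = "A")
  expect_equal(m1$R2Y, m2$R2Y, tolerance = 1e-10)
  expect_equal(vip(m1), vip(m2), tolerance = 1e-10)
  cv1 <- cross_validate(Xs, y, 1, 7, 5, positive_class = "B")
  cv2 <- cross_validate(Xs, y, 1, 7, 5, positive_class = "A")
  expect_equal(cv1$Q2Y, cv2$Q2Y, tolerance = 1e-10)
  # predictions map to the same labels either way
  p1 <- predict(m1, Xs)
  p2 <- predict(m2, Xs)
  expect_identical(p1$class, p2$class)
})

test_that("cross-validation separates real effects from permuted labels", {
  set.seed(7)
  X <- matrix(stats::rnorm(16 * 30), 16, 30)
  y <- rep(c("A", "B"), each = 8)
  X[y == "B", 1:5] <- X[y == "B", 1:5] + 4  # 4 SD effect
  Xs <- scale(X)
  cv <- cross_validate(Xs, y, 1, folds = 7, seed = 3)
  expect_gt(cv$Q2Y, 0.9)
  q2perm <- vapply(1:20, function(i) {
    set.seed(100 + i)
    cross_validate(Xs, sample(y), 1, folds = 7, seed = 3)$Q2Y
  }, numeric(1))
  expect_lt(mean(q2perm), 0)
  expect_error(cross_validate(Xs, y, 1, folds = 20, seed = 1), "folds")
})

test_that("auto_orthogonal counts planted orthogonal structure", {
  set.seed(5)
  n <- 16; p <- 40
  y <- rep(c("A", "B"), each = 8)
  yv <- rep(c(-1, 1), each = 8)
  a <- stats::rnorm(p); b <- stats::rnorm(p)
  X0 <- outer(yv, a) + matrix(stats::rnorm(n * p, 0, 0.5), n, p)
  expect_equal(auto_orthogonal(scale(X0), y, 3, 7, 2), 0L)
  g <- stats::rnorm(n, 0, 3); g <- g - mean(g)
  g <- g - yv * sum(yv * g) / sum(yv^2)
  X1 <- outer(yv, a) + outer(g, b) + matrix(stats::rnorm(n * p, 0, 0.5), n, p)
  expect_equal(auto_orthogonal(scale(X1), y, 3, 7, 2), 1L)
  expect_equal(auto_orthogonal(scale(X1), y, 0, 7, 2), 0L)
})

test_that("S-plot ranks a planted effect first and bounds correlations", {
  set.seed(13)
  n <- 20; p <- 15
  y <- rep(c("A", "B"), each = 10)
  X <- matrix(stats::rnorm(n * p), n, p)
  X[y == "B", 1] <- X[y == "B", 1] + 5
  colnames(X) <- paste0("V", seq_len(p))
  Xs <- scale(X)
  m <- fit_oplsda(Xs, y, 0)
  sp <- s_plot(m, Xs)
  expect_true(all(abs(sp$correlation) <= 1 + 1e-12))
  expect_equal(which.max(abs(sp$correlation)), 1L)
  expect_equal(which.max(abs(sp$covariance)), 1L)
  # variable constructed orthogonal to t has near-zero correlation
  t_p <- m$predictive$t
  ortho <- stats::rnorm(n)
  ortho <- ortho - mean(ortho)
  ortho <- ortho - t_p * sum(t_p * ortho) / sum(t_p^2)
  X2 <- cbind(Xs, ortho)
  m2w <- c(m$predictive$w, 0)
  sp2 <- s_plot(structure(list(predictive = list(w = m2w, t = t_p),
                               variables = colnames(X2)),
                          class = "oplsda_model"), X2)
  expect_lt(abs(sp2$correlation[p + 1]), 0.05)
  expect_error(s_plot(m, Xs[, 1:3]), "column count")
})

test_that("VIP normalization and planted-effect ordering hold", {
  set.seed(19)
  X <- matrix(stats::rnorm(16 * 10), 16, 10)
  y <- rep(c("A", "B"), each = 8)
  X[y == "B", 4] <- X[y == "B", 4] + 5
  Xs <- scale(X)
  m <- fit_oplsda(Xs, y, 1)
  v <- vip(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-8)
  expect_equal(which.max(v), 4L, ignore_attr = TRUE)
  expect_gt(max(v), 1)
  # identical columns share the weight: all VIP = 1
  col <- stats::rnorm(16)
  Xeq <- matrix(rep(col, 6), 16, 6)
  meq <- fit_oplsda(Xeq, y, 0)
  expect_equal(unname(vip(meq)), rep(1, 6), tolerance = 1e-8)
})

test_that("VIP > 1 recovers planted effects with high sensitivity", {
  tps <- uniform_panel(20)
  planted <- paste0("M", 1:10)
  eff <- stats::setNames(rep(c(1, -1), 5), planted)
  sens <- fpr <- numeric(20)
  for (seed in 1:20) {
    q <- simulate_quantities(list(group_effect("Sham"), group_effect("Model", eff)),
                             tps, sim_config(n_per_group = 8, seed = seed))
    Xs <- pareto_mat(q$quantities)
    m <- fit_oplsda(Xs, q$labels, 1, positive_class = "Model")
    hits <- names(vip(m))[vip(m) > 1]
    sens[seed] <- length(intersect(hits, planted)) / length(planted)
    fpr[seed] <- length(setdiff(hits, planted)) / (20 - length(planted))
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fpr), 0.1)
})
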