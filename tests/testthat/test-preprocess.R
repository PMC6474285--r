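lorentz <- function(x, mu, g) g^2 / ((x - mu)^2 + g^2)

test_that("TSP referencing shifts the apex to exactly 0 ppm", {
  ppm <- seq(-0.5, 9.5, by = 0.0025)
  clean <- new_spectrum(ppm, lorentz(ppm, 0, 0.002) + lorentz(ppm, 3, 0.002), "a")
  expect_equal(reference_to_tsp(clean)$ppm, clean$ppm)

  shifted <- new_spectrum(ppm, lorentz(ppm, 0.010, 0.002) + lorentz(ppm, 3, 0.002), "b")
  out <- reference_to_tsp(shifted)
  expect_equal(out$ppm, shifted$ppm - 0.010, tolerance = 1e-12)
  win <- which(out$ppm >= -0.2 & out$ppm <= 0.2)
  expect_equal(out$ppm[win][which.max(out$intensity[win])], 0)

  flat <- new_spectrum(ppm, rep(1, length(ppm)), "c")
  expect_error(reference_to_tsp(flat), "no TSP peak")
})

test_that("baseline correction removes drift while preserving peaks", {
  ppm <- seq(0, 10, by = 0.0025)
  clean <- 2 * lorentz(ppm, 2, 0.002) + lorentz(ppm, 5.5, 0.002) +
    1.5 * lorentz(ppm, 8, 0.002)
  ramp <- 0.1 * ppm
  out <- baseline_correct(new_spectrum(ppm, clean + ramp, "s"))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(out$intensity - clean), rms(ramp) / 20)
  # apex heights preserved within 5%
  for (mu in c(2, 5.5, 8)) {
    i <- which.min(abs(ppm - mu))
    expect_lt(abs(out$intensity[i] - clean[i]) / clean[i], 0.05)
  }
  # constant offset: corrected minimum near zero
  off <- baseline_correct(new_spectrum(ppm, clean + 3, "s"))
  expect_lt(abs(min(off$intensity)), 0.05 * 3)
  # nothing to remove: output close to input
  none <- baseline_correct(new_spectrum(ppm, clean, "s"))
  expect_lt(rms(none$intensity - clean), 0.01 * max(clean))
  expect_error(baseline_correct(new_spectrum(1:5, rep(1, 5), "s")), "10 points")
})

test_that("segment alignment recovers planted integer shifts and clamps", {
  ppm <- seq(0, 2, by = 0.002)
  base <- lorentz(ppm, 0.5, 0.004) + lorentz(ppm, 1.5, 0.004)
  mk <- function(int, id) new_spectrum(ppm, int, id)
  ids <- sprintf("s%d", 1:4)
  labels <- stats::setNames(rep("G", 4), ids)

  same <- new_spectrum_set(lapply(ids, mk, int = base), labels)
  out <- align_segments(same, segment_width = 0.05, max_shift = 5)
  expect_true(all(attr(out, "shifts") == 0))

  # segment starting at 1.5 spans 1.5-1.548; plant a peak mid-segment and
  # shift it by +3 grid points in one sample only
  base2 <- lorentz(ppm, 0.5, 0.004) + lorentz(ppm, 1.524, 0.004)
  shifted <- lorentz(ppm, 0.5, 0.004) + lorentz(ppm, 1.524 + 3 * 0.002, 0.004)
  plant <- new_spectrum_set(c(lapply(ids[1:3], mk, int = base2),
                              list(mk(shifted, "s4"))), labels)
  out <- align_segments(plant, segment_width = 0.05, max_shift = 5)
  sh <- attr(out, "shifts")["s4", ]
  expect_true(any(sh == -3))
  expect_true(all(abs(sh) <= 5))

  far <- lorentz(ppm, 0.5, 0.004) + lorentz(ppm, 1.524 + 10 * 0.002, 0.004)
  clamped <- new_spectrum_set(c(lapply(ids[1:3], mk, int = base2),
                                list(mk(far, "s4"))), labels)
  outc <- align_segments(clamped, segment_width = 0.05, max_shift = 5)
  expect_equal(min(attr(outc, "shifts")["s4", ]), -5)

  expect_error(align_segments(same, segment_width = 0.003, max_shift = 5),
               "3 grid points")
})

test_that("default bucketing keeps exactly 3760 buckets around the water gap", {
  bt <- bucket(flat_set())
  expect_equal(ncol(bt$values), 3760)
  expect_true(all(bt$values == 0))
  # no kept bucket intersects the open water interval
  expect_false(any(bt$edges$hi > 4.65 + 1e-12 & bt$edges$lo < 5.25 - 1e-12))
  # boundary buckets on both sides of the gap survive
  expect_true(any(abs(bt$edges$hi - 4.65) < 1e-9))
  expect_true(any(abs(bt$edges$lo - 5.25) < 1e-9))
  expect_equal(nrow(bt$edges), ncol(bt$values))
})

test_that("an impulse lands its full mass in the containing bucket", {
  ppm <- seq(0, 2, by = 0.00025)
  int <- rep(0, length(ppm))
  i <- which.min(abs(ppm - 1.00125))
  dx <- 0.00025
  int[i] <- 1 / dx  # unit trapezoid area
  set <- new_spectrum_set(list(new_spectrum(ppm, int, "s1"),
                               new_spectrum(ppm, int, "s2")),
                          c(s1 = "G", s2 = "G"))
  bt <- bucket(set, width = 0.0025, range = c(0, 2), exclude = NULL)
  target <- which(abs(bt$edges$lo - 1.0000) < 1e-9)
  expect_equal(unname(bt$values[1, target]), 1, tolerance = 1e-9)
  expect_equal(sum(bt$values[1, -target]), 0, tolerance = 1e-12)
})

test_that("bucketing rejects incompatible grids and widths", {
  ppm1 <- seq(0, 10, by = 0.0025)
  ppm2 <- seq(0, 10, by = 0.005)
  set <- new_spectrum_set(list(new_spectrum(ppm1, rep(0, length(ppm1)), "a"),
                               new_spectrum(ppm2, rep(0, length(ppm2)), "b")),
                          c(a = "G", b = "G"))
  expect_error(bucket(set), "differing ppm grids")
  expect_error(bucket(flat_set(), width = 0.003), "divide")
})

test_that("PQN identifies pure dilution exactly", {
  pattern <- c(rep(0.01, 60), seq(1, 4, length.out = 40))  # 40 signal buckets
  vals <- rbind(s1 = pattern, s2 = 2 * pattern, s3 = 0.5 * pattern)
  edges <- data.frame(lo = (0:99) * 0.0025, hi = (1:100) * 0.0025)
  bt <- new_bucket_table(vals, edges, c(s1 = "G", s2 = "G", s3 = "G"))
  res <- pqn_normalize(bt)
  expect_equal(unname(res$dilution_factors), c(1, 2, 0.5), tolerance = 1e-10)
  for (i in 1:3) expect_equal(unname(res$table$values[i, ]), pattern,
                              tolerance = 1e-10)
})

test_that("PQN recovers dilution factors from perturbed cohorts", {
  set.seed(31)
  n <- 48; p <- 120
  pattern <- c(rep(0.005, 70), seq(0.5, 3, length.out = 50))
  dil <- stats::runif(n, 0.5, 2)
  vals <- t(vapply(seq_len(n), function(i) {
    dil[i] * pattern * exp(stats::rnorm(p, 0, 0.05))  # 5% peak perturbation
  }, numeric(p)))
  rownames(vals) <- sprintf("s%02d", seq_len(n))
  edges <- data.frame(lo = (seq_len(p) - 1) * 0.0025, hi = seq_len(p) * 0.0025)
  bt <- new_bucket_table(vals, edges,
                         stats::setNames(rep("G", n), rownames(vals)))
  res <- pqn_normalize(bt)
  true_rel <- dil / stats::median(dil)
  expect_gt(stats::cor(res$dilution_factors, true_rel), 0.95)
  expect_lt(stats::median(abs(res$dilution_factors - true_rel) / true_rel), 0.05)
})

test_that("PQN rejects degenerate samples", {
  vals <- rbind(s1 = c(1, 2), s2 = c(0, 0))
  edges <- data.frame(lo = c(0, 0.0025), hi = c(0.0025, 0.005))
  bt <- new_bucket_table(vals, edges, c(s1 = "G", s2 = "G"))
  expect_error(pqn_normalize(bt), "s2")
})

test_that("Pareto scaling matches its closed form and flags constants", {
  vals <- cbind(a = c(0, 2), b = c(5, 5), c = c(1, 3))
  rownames(vals) <- c("s1", "s2")
  edges <- data.frame(lo = c(0, 0.0025, 0.005), hi = c(0.0025, 0.005, 0.0075))
  bt <- new_bucket_table(vals, edges, c(s1 = "G", s2 = "G"))
  out <- pareto_scale(bt)
  expect_equal(max(abs(colMeans(out$values))), 0, tolerance = 1e-10)
  # column [0, 2]: centered +/-1 divided by sqrt(sd) = 2^(1/4)
  expect_equal(unname(out$values[, "a"]), c(-1, 1) / 2^(1/4), tolerance = 1e-12)
  # scaled sample variance equals the original column SD
  expect_equal(stats::var(out$values[, "a"]), stats::sd(vals[, "a"]),
               tolerance = 1e-12)
  expect_equal(unname(out$values[, "b"]), c(0, 0))
  expect_equal(names(attr(out, "constant_buckets")), "b")
  one <- new_bucket_table(vals[1, , drop = FALSE], edges, c(s1 = "G"))
  expect_error(pareto_scale(one), "2 samples")
})

test_that("metabolite integration is complete, linear and guarded", {
  tps <- uniform_panel(2)
  cfg <- sim_config(ppm_grid = c(0, 2, 2001), noise_sd = 0, shift_jitter_sd = 0,
                    baseline_amplitude = 0, tsp_height = 0, water_amplitude = 0)
  s1 <- simulate_spectrum(c(M1 = 1, M2 = 0), tps, cfg, sample_id = "a", seed = 1)
  s2 <- simulate_spectrum(c(M1 = 2, M2 = 0), tps, cfg, sample_id = "b", seed = 1)
  set <- new_spectrum_set(list(s1, s2), c(a = "G1", b = "G2"))
  bt <- bucket(set, width = 0.0025, range = c(0, 2), exclude = NULL)

  all_in <- list(All = data.frame(lo = 0, hi = 2))
  q <- integrate_metabolites(bt, all_in, exclude = NULL)
  expect_equal(q$All, unname(rowSums(bt$values)), tolerance = 1e-12)

  asn <- list(M1 = data.frame(lo = 0.49, hi = 0.51))
  q2 <- integrate_metabolites(bt, asn, exclude = NULL)
  expect_equal(q2$M1[2] / q2$M1[1], 2, tolerance = 0.02)

  expect_warning(
    q3 <- integrate_metabolites(bt, list(Empty = data.frame(lo = numeric(0),
                                                            hi = numeric(0))),
                                exclude = NULL),
    "Empty")
  expect_equal(q3$Empty, c(0, 0))
  expect_error(
    integrate_metabolites(bt, list(Bad = data.frame(lo = 4.7, hi = 4.8))),
    "bucketed range|water")
})
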