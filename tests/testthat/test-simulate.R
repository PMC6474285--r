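quiet_cfg <- function(...) {
  sim_config(ppm_grid = c(0, 10, 2001), noise_sd = 0, shift_jitter_sd = 0,
             baseline_amplitude = 0, ...)
}

test_that("zero concentrations leave only the TSP and water contributions", {
  cfg <- quiet_cfg()
  tps <- uniform_panel(3)
  sp <- simulate_spectrum(stats::setNames(rep(0, 3), names(tps)), tps, cfg, seed = 1)
  expected <- cfg$tsp_height * 0.0015^2 / (sp$ppm^2 + 0.0015^2) +
    cfg$water_amplitude * 0.1^2 / ((sp$ppm - 4.95)^2 + 0.1^2)
  expect_equal(sp$intensity, expected, tolerance = 1e-12)
})

test_that("metabolite-attributable intensity is linear in concentration and dilution", {
  cfg <- quiet_cfg()
  tps <- uniform_panel(4)
  conc <- stats::setNames(c(0.5, 1, 2, 0.3), names(tps))
  base <- simulate_spectrum(stats::setNames(rep(0, 4), names(tps)), tps, cfg, seed = 1)
  s1 <- simulate_spectrum(conc, tps, cfg, seed = 1)
  s2 <- simulate_spectrum(2 * conc, tps, cfg, seed = 1)
  expect_equal(s2$intensity - base$intensity,
               2 * (s1$intensity - base$intensity), tolerance = 1e-10)
  sd2 <- simulate_spectrum(conc, tps, cfg, dilution = 2, seed = 1)
  expect_equal(sd2$intensity - base$intensity,
               2 * (s1$intensity - base$intensity), tolerance = 1e-10)
})

test_that("a lone narrow peak has its apex at the template center", {
  cfg <- sim_config(ppm_grid = c(0, 2, 4001), noise_sd = 0, shift_jitter_sd = 0,
                    baseline_amplitude = 0, tsp_height = 0, water_amplitude = 0)
  tp <- list(One = new_metabolite_template("One", data.frame(center = 1, height = 1),
                                           linewidth = 0.001))
  sp <- simulate_spectrum(c(One = 1), tp, cfg, seed = 1)
  expect_lt(abs(sp$ppm[which.max(sp$intensity)] - 1), 0.01)
})

test_that("simulation rejects unknown metabolites and bad cohort sizes", {
  tps <- uniform_panel(2)
  expect_error(simulate_spectrum(c(Nope = 1), tps, quiet_cfg()), "unknown metabolite")
  expect_error(simulate_spectrum(c(M1 = -1), tps, quiet_cfg()), ">= 0")
  expect_error(sim_config(n_per_group = 2), "n_per_group")
  expect_error(simulate_cohort(list(group_effect("A"), group_effect("A")),
                               tps, quiet_cfg()), "unique")
})

test_that("the same seed reproduces a cohort exactly", {
  tps <- uniform_panel(3)
  cfg <- sim_config(n_per_group = 3, ppm_grid = c(0, 10, 801), seed = 9)
  a <- simulate_cohort(list(group_effect("G1"), group_effect("G2")), tps, cfg)
  b <- simulate_cohort(list(group_effect("G1"), group_effect("G2")), tps, cfg)
  expect_identical(a, b)
})

test_that("null designs give exchangeable groups on truth concentrations", {
  tps <- uniform_panel(4)
  nonsig <- 0
  for (seed in 1:50) {
    q <- simulate_quantities(list(group_effect("A"), group_effect("B")), tps,
                             sim_config(n_per_group = 8, seed = seed))
    p <- stats::t.test(q$quantities[q$labels == "A", "M1"],
                       q$quantities[q$labels == "B", "M1"])$p.value
    if (p >= 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 48)
})

test_that("a +1 log2 effect at recovery 0 doubles the mean truth level", {
  tps <- uniform_panel(3)
  q <- simulate_quantities(
    list(group_effect("Ref"), group_effect("Up", c(M2 = 1), recovery_fraction = 0)),
    tps, sim_config(n_per_group = 50, seed = 4))
  ratio <- mean(q$quantities[q$labels == "Up", "M2"]) /
    mean(q$quantities[q$labels == "Ref", "M2"])
  expect_lt(abs(ratio - 2) / 2, 0.10)
})

test_that("recovery fraction 1 returns the group to reference levels", {
  tps <- uniform_panel(3)
  q <- simulate_quantities(
    list(group_effect("Ref"),
         group_effect("Treated", c(M1 = 2), recovery_fraction = 1)),
    tps, sim_config(n_per_group = 50, seed = 6))
  ratio <- mean(q$quantities[q$labels == "Treated", "M1"]) /
    mean(q$quantities[q$labels == "Ref", "M1"])
  expect_lt(abs(ratio - 1), 0.15)
})

test_that("spectrum sets round-trip through the text formats", {
  tps <- uniform_panel(3)
  cfg <- sim_config(n_per_group = 3, ppm_grid = c(0, 10, 401), seed = 2)
  set <- simulate_cohort(list(group_effect("A"), group_effect("B")), tps, cfg)
  dir <- withr::local_tempdir()
  write_spectrum_set(set, dir)
  back <- read_spectrum_set(dir)
  expect_identical(names(back$labels), names(set$labels))
  expect_identical(unname(back$labels), unname(set$labels))
  expect_equal(back$spectra[[1]]$intensity, set$spectra[[1]]$intensity,
               tolerance = 1e-9)
  expect_equal(back$truth$dilution, set$truth$dilution, tolerance = 1e-9)
  expect_equal(back$truth$concentrations, set$truth$concentrations,
               tolerance = 1e-9)
})
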