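test_that("crank_profile matches the high-order series oracle", {
  # frozen DERIVED value: 1000-term oracle at the MeTHF parameters, 60 min
  # past t0 (computed once with oracle_crank_x and frozen here)
  p <- list(deff = 0.122e-10, rd = 1e-3, x_inf = 0.4596, x0 = 0.100, t0 = 0)
  ours <- crank_profile(60, p$deff, p$rd, p$x_inf, p$x0, p$t0)
  oracle <- oracle_crank_x(60, p$deff, p$rd, p$x_inf, p$x0, p$t0)
  expect_equal(ours, oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 6), 0.307729)

  # tau >= 1e-4 sweep against the 1000-term oracle
  taus <- 10^seq(-4, 0, length.out = 12)
  t_min <- taus * p$rd^2 / (p$deff * 60)
  expect_lt(max(abs(crank_profile(t_min, p$deff, p$rd, p$x_inf, p$x0) -
                    oracle_crank_x(t_min, p$deff, p$rd, p$x_inf, p$x0, 0))),
            1e-10)
})

test_that("crank_profile limits and domain", {
  expect_equal(crank_profile(5, 1e-11, 1e-3, 0.46, 0.1, t0 = 5), 0.1)
  expect_equal(crank_profile(1e6, 1e-10, 1e-3, 0.46, 0.1, t0 = 5), 0.46,
               tolerance = 1e-9)
  x <- crank_profile(seq(5, 120, by = 5), 1e-11, 1e-3, 0.46, 0.1, t0 = 5)
  expect_true(all(diff(x) > 0))
  expect_error(crank_profile(4, 1e-11, 1e-3, 0.46, 0.1, t0 = 5),
               "t >= t0")
  expect_error(crank_profile(10, 1e-11, 1e-3, 0.46, 0.5, t0 = 5),
               "x0 must be < x_inf")
})

test_that("log-linear fit recovers a pure single exponential exactly", {
  k_true <- 8e-4  # s^-1
  rd <- 1e-3; x_inf <- 0.46; x0 <- 0.1; t0 <- 5
  t_min <- c(10, 15, 20, 30, 60, 90, 120)
  x <- x_inf - (x_inf - x0) * exp(-k_true * (t_min - t0) * 60)
  ds <- kinetic_dataset(t_min, x, rd = rd, x_inf_hint = x_inf)
  fit <- fit_crank(ds, t0 = t0, x0 = x0, method = "loglinear")
  expect_equal(fit$k, k_true, tolerance = 1e-12)
  expect_equal(fit$deff, k_true * rd^2 / pi^2, tolerance = 1e-12)
})

test_that("series fit recovers Crank parameters over a seeded grid", {
  x_inf <- 0.4596
  for (deff in c(0.01e-10, 0.034e-10, 0.122e-10, 0.5e-10, 1e-10)) {
    for (x0 in c(0, 0.1 * x_inf, 0.3 * x_inf)) {
      sim <- gen_kinetics(kinetic_gen_spec(deff = deff, x_inf = x_inf,
                                           x0 = x0))
      fit <- fit_crank(sim$dataset)
      expect_lt(abs(fit$deff / deff - 1), 0.05)
      expect_lt(abs(fit$x0 - x0), 0.02 * x_inf)
    }
  }
})

test_that("series fit tolerates 2% multiplicative noise (50 replicates)", {
  errs <- vapply(1:50, function(i) {
    sim <- gen_kinetics(kinetic_gen_spec(deff = 0.122e-10, seed = 42 + i,
                                         noise_model = "multiplicative",
                                         cv = 0.02))
    suppressWarnings(fit_crank(sim$dataset)$deff / 0.122e-10 - 1)
  }, numeric(1))
  # recovery within 15% in aggregate: mean absolute error and the 90th
  # percentile (individual replicates can stray further on 10 points)
  expect_lt(mean(abs(errs)), 0.15)
  expect_lt(stats::quantile(abs(errs), 0.9), 0.15)
  expect_lt(abs(mean(errs)), 0.10)
})

test_that("deff_from_k applies the sphere eigenvalue relation", {
  expect_equal(deff_from_k(pi^2, 1), 1)
  expect_equal(deff_from_k(1.204e-4, 1e-3), 1.204e-10 / pi^2)
  expect_equal(round(deff_from_k(1.204e-4, 1e-3), 13), 1.22e-11)
  expect_equal(deff_from_k(1e-4, 2e-3), 4 * deff_from_k(1e-4, 1e-3))
  expect_error(deff_from_k(-1, 1e-3), "k")
  expect_error(deff_from_k(1e-4, 0), "rd")
})

test_that("starting accessibility is recovered and expressed vs total oil", {
  sim <- gen_kinetics(kinetic_gen_spec(deff = 0.122e-10, x0 = 0.100))
  sa <- starting_accessibility(sim$dataset, total_oil_content = 0.4634)
  expect_lt(abs(sa$x0 / 0.100 - 1), 0.02)
  expect_equal(sa$fraction_pct, 100 * sa$x0 / 0.4634)
  expect_equal(round(100 * 0.100 / 0.4634, 1), 21.6)

  sim0 <- gen_kinetics(kinetic_gen_spec(deff = 0.122e-10, x0 = 0))
  sa0 <- starting_accessibility(sim0$dataset)
  expect_lt(abs(sa0$x0), 1e-3)
  expect_true(is.na(starting_accessibility(sim$dataset)$fraction_pct))
})

test_that("sampling correction inverts the withdrawal bookkeeping", {
  spec <- kinetic_gen_spec(deff = 0.122e-10, withdrawal_mass = 1,
                           solvent_mass = 128, dm_mass = 27.66)
  sim <- gen_kinetics(spec)
  corr <- correct_for_sampling(sim$withdrawals$sample_mass_g,
                               sim$withdrawals$extract_fraction,
                               solvent_mass_initial = 128,
                               dry_matter_mass = 27.66,
                               times = sim$withdrawals$time_min)
  expect_equal(corr$x, sim$dataset$x, tolerance = 0.005)
  expect_equal(corr$x, sim$dataset$x, tolerance = 1e-9)  # exact inversion

  # zero-mass draws equal the naive conversion
  w <- sim$withdrawals$extract_fraction
  naive <- w * 128 / (1 - w) / 27.66
  corr0 <- correct_for_sampling(rep(0, length(w)), w, 128, 27.66,
                                times = sim$withdrawals$time_min)
  expect_equal(corr0$x, naive)

  expect_error(correct_for_sampling(c(200, 200), c(0.1, 0.1), 128, 27.66,
                                    times = c(1, 2)),
               "mass-balance")
})

test_that("residual-oil extrapolation scales by the pilot improvement", {
  r <- extrapolate_residual(16.5, 1.8, 0.8)
  expect_equal(round_half_up(r$projected_kg_per_t, 1), 7.3)
  expect_equal(round_half_up(r$gain_kg_per_t, 1), 9.2)
  expect_equal(extrapolate_residual(16.5, 1.8, 1.8)$gain_kg_per_t, 0)
  expect_equal(extrapolate_residual(16.5, 1.8, 0)$gain_kg_per_t, 16.5)
  expect_error(extrapolate_residual(16.5, 0, 1), "positive|> 0")
})

test_that("kinetic CSV io round-trips", {
  ds <- kinetic_dataset(c(10, 20, 30), c(0.2, 0.3, 0.35), rd = 1e-3,
                        temperature = 55, solvent = "MeTHF")
  f <- tempfile(fileext = ".csv")
  write_kinetics_csv(ds, f)
  back <- read_kinetics_csv(f)
  expect_equal(back$x, ds$x)
  expect_equal(back$rd, ds$rd)
  expect_equal(back$solvent, "MeTHF")
})
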