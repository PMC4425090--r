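test_that("elementary duty calculations", {
  expect_equal(sensible_heat(550, 1.9, 55, 105), 52.25)
  expect_equal(round_half_up(sensible_heat(550, 1.9, 55, 105)), 52)
  expect_equal(sensible_heat(100, 2, 60, 60), 0)
  expect_equal(sensible_heat(1000, 2.0, 69, 110), 82)
  expect_error(sensible_heat(550, 1.9, 105, 55), "t_to")

  expect_equal(vaporization_heat(29.5, 2257), 66.5815)
  expect_equal(round_half_up(vaporization_heat(29.5, 2257)), 67)
  expect_equal(vaporization_heat(0, 2257), 0)
  expect_equal(vaporization_heat(228.7, 328), 75.0136)

  st <- steam_properties(total_enthalpy_sparged = 2800)
  sp <- sparged_steam(228.7, 0.12, st)
  expect_equal(sp$steam_kg_per_t, 27.444)
  expect_equal(sp$heat_MJ_per_t, 27.444 * 2.8)
  expect_equal(sparged_steam(228.7, 0, st)$heat_MJ_per_t, 0)
  expect_equal(sparged_steam(108 / 0.375, 0.14, st)$steam_kg_per_t, 40.32)

  expect_equal(heat_recovery(139.0), -104.25)
  expect_equal(round_half_up(heat_recovery(139.0), 1), -104.3)
  expect_equal(heat_recovery(168.9), -126.675)
  expect_equal(heat_recovery(100, 0), 0)
  expect_error(heat_recovery(100, 1.2), "fraction")
})

test_that("steam_from_heat converts by steam class", {
  st <- steam_properties(latent_heat_6bar = 2093, latent_heat_10bar = 1992)
  expect_equal(steam_from_heat(270, "6bar", st), 270000 / 2093)
  expect_equal(round_half_up(steam_from_heat(270, "6bar", st), 1), 129)
  expect_equal(round_half_up(steam_from_heat(52, "10bar", st), 1), 26.1)
  expect_equal(steam_from_heat(0, "6bar", st), 0)
  expect_error(steam_from_heat(10, "3bar", st))
  expect_error(steam_from_heat(-1, "6bar", st), "heat")
  # monotone in the heat within a class
  h <- seq(0, 300, by = 25)
  expect_true(all(diff(sapply(h, steam_from_heat, "10bar", st)) > 0))
})

test_that("ledger additivity and structural invariants", {
  for (sv in c("hexane", "methf")) {
    lg <- build_ledger(default_process_scenario(sv))
    r <- lg$rows
    by_cat <- function(cat, col) sum(r[r$category == cat, col])
    for (cat in c("preparation", "desolventization", "distillation",
                  "recovery", "losses")) {
      nm <- if (cat == "losses") "losses" else cat
      expect_equal(by_cat(cat, "heat_MJ_per_t"),
                   unname(lg$subtotals[[nm]]["heat"]), tolerance = 0.05)
    }
    expect_equal(unname(lg$totals["heat"]), sum(r$heat_MJ_per_t),
                 tolerance = 0.05)
    expect_equal(unname(lg$totals["steam"]), sum(r$steam_kg_per_t),
                 tolerance = 0.05)
    # recovery credit never exceeds the distillation subtotal
    expect_lte(abs(lg$subtotals$recovery["heat"]),
               lg$subtotals$distillation["heat"])
    expect_lte(unname(lg$subtotals$recovery["heat"]), 0)
    # extraction = desolventization + distillation + recovery
    expect_equal(lg$subtotals$extraction,
                 lg$subtotals$desolventization + lg$subtotals$distillation +
                   lg$subtotals$recovery)
  }
})

test_that("zero-mass scenario passes through the preparation constants", {
  sv <- solvent_record("x", hansen(15, 2, 3), cp = 2, t_boil = 70,
                       dh_vap = 300)
  sc <- process_scenario(sv, meal_mass = 0, sparged_steam_ratio = 0,
                         retained_solvent = 0, oil_to_distillation = 0,
                         solvent_to_distillation = 0, miscella_heat = 0,
                         condensed_steam_heat = 0)
  lg <- build_ledger(sc)
  expect_equal(unname(lg$subtotals$preparation["heat"]), 269)
  expect_equal(unname(lg$subtotals$desolventization["heat"]), 0)
  expect_equal(unname(lg$subtotals$distillation["heat"]), 0)
  expect_equal(unname(lg$totals["heat"]), 269 * 1.05)
})

test_that("scenario comparison and structure checks", {
  a <- build_ledger(default_process_scenario("hexane"))
  b <- build_ledger(default_process_scenario("methf"))
  self <- compare_scenarios(a, a)
  expect_true(all(self$rows$delta_heat_MJ_per_t == 0))
  expect_equal(unname(self$total_delta), c(0, 0))
  cmp <- compare_scenarios(a, b)
  expect_equal(unname(cmp$total_delta["heat"]),
               unname(b$totals["heat"] - a$totals["heat"]))
  # structure mismatch is reported with the unmatched rows
  b2 <- b; b2$rows <- b2$rows[-3, ]
  expect_error(compare_scenarios(a, b2), "unmatched")
})

test_that("scenario configs load from JSON with named missing-field errors", {
  f <- tempfile(fileext = ".json")
  cfg <- list(solvent = list(name = "n-hexane", hansen = c(14, 0, 0),
                             cp = 2.27, t_boil = 69, dh_vap = 328),
              sparged_steam_ratio = 0.12, retained_solvent = 75 / 0.328,
              miscella_heat = 8,
              solvent_to_distillation = (139 - 8 - 10.004) / 0.328)
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  sc <- read_process_scenario(f)
  lg <- build_ledger(sc)
  ref <- build_ledger(default_process_scenario("hexane"))
  expect_equal(lg$totals, ref$totals, tolerance = 1e-10)

  cfg$sparged_steam_ratio <- NULL
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_process_scenario(f), "sparged_steam_ratio")
})

test_that("steam properties are validated", {
  expect_error(steam_properties(total_enthalpy_sparged = 1000),
               "latent heats")
})
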