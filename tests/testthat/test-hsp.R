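test_that("total parameter and Hansen distance match hand evaluation", {
  expect_equal(total_parameter(hansen(14, 0, 0)), 14)
  expect_equal(total_parameter(hansen(16.4, 4.7, 4.6)), sqrt(312.21))
  expect_equal(round(total_parameter(hansen(16.4, 4.7, 4.6)), 2), 17.67)
  expect_equal(total_parameter(hansen(0, 0, 0)), 0)
  expect_error(hansen(-1, 0, 0), "Hansen components")

  a <- hansen(14, 0, 0); b <- hansen(16.4, 4.7, 4.6)
  expect_equal(hansen_distance(a, a), 0)
  expect_equal(hansen_distance(a, b), hansen_distance(b, a))
  expect_equal(hansen_distance(a, b), sqrt(4 * 2.4^2 + 4.7^2 + 4.6^2))
  expect_equal(round(hansen_distance(a, b), 2), 8.14)
  expect_equal(hansen_distance(a, b, dispersion_weight = 1),
               sqrt(2.4^2 + 4.7^2 + 4.6^2))
})

test_that("hansen_distance is a metric on the rescaled space", {
  set.seed(7)
  for (i in 1:50) {
    a <- random_hansen(); b <- random_hansen(); c <- random_hansen()
    expect_lte(hansen_distance(a, b),
               hansen_distance(a, c) + hansen_distance(c, b) + 1e-12)
    expect_gte(hansen_distance(a, b), 0)
  }
})

test_that("RED evaluates and classifies", {
  sph <- solute_sphere(hansen(16, 3, 4), radius_r0 = 4, label = "TAG")
  expect_equal(red(hansen(16, 3, 4), sph), 0)
  # a point exactly on the sphere surface: RED = 1
  on_surface <- hansen(16, 3 + 4, 4)
  expect_equal(red(on_surface, sph), 1)
  expect_equal(as.character(red_class(red(on_surface, sph))), "borderline")
  expect_equal(as.character(red_class(0.83)), "good")
  expect_equal(as.character(red_class(1.15)), "poor")
  expect_error(solute_sphere(hansen(16, 3, 4), radius_r0 = 0), "radius_r0")
})

test_that("RED is scale-consistent in the radius", {
  set.seed(11)
  center <- random_hansen()
  for (i in 1:20) {
    s1 <- solute_sphere(center, radius_r0 = runif(1, 1, 8))
    s2 <- solute_sphere(center, radius_r0 = 2 * s1$radius_r0)
    p <- random_hansen()
    expect_equal(red(p, s2), red(p, s1) / 2)
  }
})

test_that("sphere inversion round-trips noise-free panels", {
  sol <- panel_solvents()
  set.seed(42)
  for (w in c(4, 1)) for (rep in 1:3) {
    truth <- solute_sphere(random_hansen(), radius_r0 = runif(1, 2, 6),
                           label = "X", dispersion_weight = w)
    pan <- gen_red_panel(truth, sol, decimals = Inf)
    fit <- fit_solute_sphere(pan, sol, dispersion_weight = w)
    expect_lt(max(abs(fit$center - truth$center)), 1e-6)
    expect_lt(abs(fit$radius_r0 - truth$radius_r0), 1e-6)
  }
})

test_that("sphere inversion rejects degenerate designs", {
  sol <- panel_solvents()
  expect_error(fit_solute_sphere(gx_red_panel()[1:3, ], sol),
               "fit-degenerate")
  coplanar <- data.frame(name = letters[1:5], delta_d = 15:19,
                         delta_p = c(2, 4, 6, 8, 10), delta_h = 0)
  obs <- data.frame(solvent = coplanar$name, red = c(1, 2, 1, 2, 3))
  expect_error(fit_solute_sphere(obs, coplanar), "coplanar")
})

test_that("the published TAG3 column refits within the rounding budget", {
  fit <- fit_solute_sphere(gx_red_panel(), panel_solvents(),
                           solute = "TAG3", dispersion_weight = 1)
  expect_lte(fit$rms, 0.05)
  expect_equal(unname(fit$fitted), unname(red_matrix()[, "TAG3"]),
               tolerance = 0.1)
})

test_that("evaporation energy follows cp (Tb - Tref) + dHvap", {
  hex <- solvent_record("hexane", hansen(14, 0, 0), cp = 2.27, t_boil = 69,
                        dh_vap = 328)
  met <- solvent_record("methf", hansen(16.4, 4.7, 4.6), cp = 1.758,
                        t_boil = 80, dh_vap = 375)
  expect_equal(evaporation_energy(hex), 2.27 * 44 + 328)  # 427.88
  expect_equal(evaporation_energy(met), 1.758 * 55 + 375) # 471.69
  expect_equal(evaporation_energy(hex, t_ref = 69), 328)
  expect_warning(e <- evaporation_energy(hex, t_ref = 100), "clamped")
  expect_equal(e, 328)
})

test_that("screening report ranks, flags and normalizes", {
  sol <- gx_solvents()
  panel <- gx_red_panel()
  spheres <- lapply(c("TAG1", "W"), function(s)
    fit_solute_sphere(panel, panel_solvents(), solute = s,
                      dispersion_weight = 1))
  rep <- screening_report(sol, spheres, desirable = "TAG1",
                          undesirable = "W", reference = "n-hexane")
  expect_equal(nrow(rep), 9)
  hex <- rep[rep$solvent == "n-hexane", ]
  expect_equal(hex$ratio_evaporation_energy_kJ_kg, 1)
  expect_equal(hex$ratio_t_boil_C, 1)
  met <- rep[rep$solvent == "MeTHF", ]
  expect_equal(met$n_desirable_good, 1)
  expect_false(met$undesirable_flag)   # wax avoided
  expect_true(hex$undesirable_flag)    # hexane extracts the wax
  # a solvent with missing properties is kept, columns absent
  expect_true("ethanol" %in% rep$solvent)
  expect_true(is.na(rep$evaporation_energy_kJ_kg[rep$solvent == "ethanol"]))
  # single solvent, single sphere: one-row table
  one <- screening_report(sol[["MeTHF"]], spheres[[1]])
  expect_equal(nrow(one), 1)
})
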