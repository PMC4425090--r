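#' Saturated-steam properties used by the crushing-process ledger
#'
#' Desolventization uses 10-bar saturated steam (indirect) plus live
#' (sparged) steam injected into the meal bed; distillation of the
#' miscella uses 6-bar saturated steam. Heats in MJ/t are converted to
#' steam in kg/t with the class latent heat; sparged steam is accounted at
#' its total enthalpy because the condensate leaves with the meal.
#'
#' Defaults are calibrated against the reference hexane crushing ledger
#' this model reproduces (see the vignette): 6-bar latent heat 2085
#' kJ/kg, 10-bar 1992 kJ/kg, sparged total enthalpy 2778 kJ/kg (10-bar
#' saturated vapor), steam price 30 EUR/t.
#'
#' @param latent_heat_6bar,latent_heat_10bar latent heats (kJ/kg).
#' @param total_enthalpy_sparged total enthalpy of live steam (kJ/kg);
#'   must exceed both latent heats.
#' @param price EUR per tonne of steam.
#' @return object of class `steam_properties`.
#' @export
steam_properties <- function(latent_heat_6bar = 2085,
                             latent_heat_10bar = 1992,
                             total_enthalpy_sparged = 2778,
                             price = 30) {
  if (!(total_enthalpy_sparged > latent_heat_6bar &&
        total_enthalpy_sparged > latent_heat_10bar &&
        latent_heat_6bar > 0 && latent_heat_10bar > 0))
    stop_domain("need total_enthalpy_sparged > latent heats > 0")
  structure(list(latent_heat_6bar = latent_heat_6bar,
                 latent_heat_10bar = latent_heat_10bar,
                 total_enthalpy_sparged = total_enthalpy_sparged,
                 price = price),
            class = "steam_properties")
}

#' Sensible heat duty
#'
#' `mass * cp * (t_to - t_from) / 1000`, in MJ per tonne of seeds.
#'
#' @param mass mass flow (kg per tonne of seeds).
#' @param cp specific heat (kJ/(degC kg)).
#' @param t_from,t_to temperatures (degC), `t_to >= t_from`.
#' @return heat in MJ/t.
#' @export
#' @examples
#' sensible_heat(550, 1.9, 55, 105)  # 52.25 MJ/t (meal through the DT)
sensible_heat <- function(mass, cp, t_from, t_to) {
  assert_scalar_num(mass, "mass", nonneg = TRUE)
  assert_scalar_num(cp, "cp", positive = TRUE)
  if (t_to < t_from) stop_domain("t_to must be >= t_from")
  mass * cp * (t_to - t_from) / 1000
}

#' Vaporization heat duty
#'
#' `mass * dh_vap / 1000`, in MJ per tonne of seeds.
#' @param mass mass vaporized (kg/t).
#' @param dh_vap latent heat (kJ/kg).
#' @return heat in MJ/t.
#' @export
vaporization_heat <- function(mass, dh_vap) {
  assert_scalar_num(mass, "mass", nonneg = TRUE)
  assert_scalar_num(dh_vap, "dh_vap", positive = TRUE)
  mass * dh_vap / 1000
}

#' Sparged (live) steam demand of the desolventizer
#'
#' Live steam strips residual solvent from the meal at a fixed ratio per
#' kilogram of solvent vaporized; its heat is accounted at the total
#' enthalpy since the condensate is lost to the meal.
#'
#' @param solvent_mass solvent vaporized in the desolventizer (kg/t).
#' @param ratio kg steam per kg solvent (> 0; 0 allowed for the no-steam
#'   limit).
#' @param steam a [steam_properties()].
#' @return list with `steam_kg_per_t` and `heat_MJ_per_t`.
#' @export
sparged_steam <- function(solvent_mass, ratio, steam = steam_properties()) {
  assert_scalar_num(solvent_mass, "solvent_mass", nonneg = TRUE)
  assert_scalar_num(ratio, "ratio", nonneg = TRUE)
  s <- solvent_mass * ratio
  list(steam_kg_per_t = s,
       heat_MJ_per_t = s * steam$total_enthalpy_sparged / 1000)
}

#' Desolventizer-to-distillation heat recovery credit
#'
#' Vapors leaving the desolventizer condense against the miscella and
#' supply a fraction (75% by default) of the distillation duty.
#'
#' @param distillation_total distillation heat subtotal (MJ/t).
#' @param fraction recovered fraction in `[0, 1]`.
#' @return negative credit in MJ/t.
#' @export
heat_recovery <- function(distillation_total, fraction = 0.75) {
  if (fraction < 0 || fraction > 1) stop_domain("fraction must be in [0, 1]")
  -fraction * distillation_total
}

#' Convert a heat duty to a steam mass
#'
#' @param heat heat duty (MJ/t), >= 0.
#' @param class steam class: `"6bar"`, `"10bar"` (latent heat) or
#'   `"sparged"` (total enthalpy).
#' @param steam a [steam_properties()].
#' @return steam in kg/t.
#' @export
steam_from_heat <- function(heat, class = c("6bar", "10bar", "sparged"),
                            steam = steam_properties()) {
  assert_scalar_num(heat, "heat", nonneg = TRUE)
  class <- match.arg(class)
  h <- switch(class, "6bar" = steam$latent_heat_6bar,
              "10bar" = steam$latent_heat_10bar,
              "sparged" = steam$total_enthalpy_sparged)
  heat * 1000 / h
}

#' Process scenario for the crushing-energy ledger
#'
#' Every solvent-independent preparation entry is a fixed constant (heat
#' and steam), inherited from the reference seed-preparation line-up; the
#' solvent-dependent desolventization and distillation entries are
#' computed from the masses, specific heats and temperatures below.
#'
#' @param solvent a [solvent_record()] with `cp`, `t_boil`, `dh_vap` set.
#' @param prep_steps data.frame `step`, `material`, `change`,
#'   `heat_MJ_per_t`, `steam_kg_per_t` of fixed preparation entries.
#' @param meal_mass meal mass (kg per tonne of seeds).
#' @param meal_cp,oil_cp specific heats (kJ/(degC kg)).
#' @param extraction_T extraction temperature (degC).
#' @param desolventizer_exit_T meal temperature leaving the desolventizer.
#' @param sparged_steam_ratio kg live steam per kg solvent stripped.
#' @param retained_solvent solvent held by the extracted meal entering the
#'   desolventizer (kg/t).
#' @param oil_to_distillation oil leaving with the miscella (kg/t).
#' @param solvent_to_distillation solvent evaporated from the miscella
#'   (kg/t); when `NULL`, derived from `oil_to_distillation` and
#'   `miscella_oil_fraction`.
#' @param miscella_oil_fraction oil mass fraction of the miscella (used
#'   only when `solvent_to_distillation` is `NULL`).
#' @param miscella_heat fixed miscella-heating duty (MJ/t).
#' @param oil_final_T oil temperature after distillation (degC).
#' @param condensed_steam_heat enthalpy of the condensed live steam lost
#'   to meal drying (MJ/t).
#' @param heat_recovery_fraction see [heat_recovery()].
#' @param loss_fraction unrecovered losses applied to preparation +
#'   extraction.
#' @return object of class `process_scenario`.
#' @export
process_scenario <- function(solvent,
                             prep_steps = default_prep_steps(),
                             meal_mass = 550, meal_cp = 1.9, oil_cp = 2.0,
                             extraction_T = 55, desolventizer_exit_T = 105,
                             sparged_steam_ratio,
                             retained_solvent,
                             oil_to_distillation = 122,
                             solvent_to_distillation = NULL,
                             miscella_oil_fraction = 0.25,
                             miscella_heat,
                             oil_final_T = 110,
                             condensed_steam_heat = 38,
                             heat_recovery_fraction = 0.75,
                             loss_fraction = 0.05) {
  if (!inherits(solvent, "solvent_record"))
    stop_domain("configuration error: 'solvent' must be a solvent_record")
  for (nm in c("cp", "t_boil", "dh_vap"))
    if (is.na(solvent[[nm]]))
      stop_domain("configuration error: solvent record lacks '", nm, "'")
  for (nm in c("meal_mass", "meal_cp", "oil_cp", "sparged_steam_ratio",
               "retained_solvent", "oil_to_distillation", "miscella_heat",
               "condensed_steam_heat"))
    assert_scalar_num(get(nm), nm, nonneg = TRUE)
  if (loss_fraction < 0 || loss_fraction > 1 ||
      heat_recovery_fraction < 0 || heat_recovery_fraction > 1)
    stop_domain("fractions must be in [0, 1]")
  if (is.null(solvent_to_distillation))
    solvent_to_distillation <- oil_to_distillation *
      (1 - miscella_oil_fraction) / miscella_oil_fraction
  structure(list(solvent = solvent, prep_steps = prep_steps,
                 meal_mass = meal_mass, meal_cp = meal_cp, oil_cp = oil_cp,
                 extraction_T = extraction_T,
                 desolventizer_exit_T = desolventizer_exit_T,
                 sparged_steam_ratio = sparged_steam_ratio,
                 retained_solvent = retained_solvent,
                 oil_to_distillation = oil_to_distillation,
                 solvent_to_distillation = solvent_to_distillation,
                 miscella_oil_fraction = miscella_oil_fraction,
                 miscella_heat = miscella_heat, oil_final_T = oil_final_T,
                 condensed_steam_heat = condensed_steam_heat,
                 heat_recovery_fraction = heat_recovery_fraction,
                 loss_fraction = loss_fraction),
            class = "process_scenario")
}

#' Fixed preparation entries of the reference crushing line
#'
#' Conditioning, cooking, flake-water vaporization and drying air. These
#' are constants, not recomputed from specific heats: the reference values
#' are not reproducible from the printed specific heats alone (e.g. the
#' conditioning entry is below `1.9 * 45 * 1000 / 1000` MJ/t), so fidelity
#' to the reference line-up is preferred over an unverifiable derivation.
#'
#' @return data.frame of preparation rows.
#' @export
default_prep_steps <- function() {
  data.frame(
    step = c("Conditioning", "Cooking", "Cooking", "Cooking"),
    material = c("Seeds", "Flakes", "Water", "Air (dry)"),
    change = c("T: 15 => 60 C", "T: 55 => 105 C",
               "Vaporization of 30 kg of water", "T: 20 => 100 C (drying)"),
    heat_MJ_per_t = c(78, 110, 66, 15),
    steam_kg_per_t = c(36.6, 53.4, 32.2, 7.2))
}

#' Packaged default scenarios for hexane and MeTHF
#'
#' Mass-flow defaults are back-derived from the reference ledger of the
#' hexane rapeseed crushing process and its MeTHF counterpart: retained
#' solvent 228.66 / 288.0 kg/t (the desolventizer vaporization duties at
#' the respective latent heats), solvent distilled from the miscella
#' 368.89 / 372.21 kg/t (calibrated so the distillation subtotal matches
#' the reference 139.0 / 168.9 MJ/t), 122 kg/t oil through distillation,
#' live-steam ratios 0.12 / 0.14 kg per kg solvent, and fixed
#' miscella-heating duties 8 / 22 MJ/t.
#'
#' @param solvent `"hexane"` or `"methf"`.
#' @return a [process_scenario()].
#' @export
default_process_scenario <- function(solvent = c("hexane", "methf")) {
  solvent <- match.arg(solvent)
  if (solvent == "hexane") {
    sr <- solvent_record("n-hexane", hansen(14, 0, 0), cp = 2.27,
                         t_boil = 69, dh_vap = 328, density = 0.675,
                         t_melt = -95, viscosity = 0.31, price = 0.9)
    process_scenario(sr, sparged_steam_ratio = 0.12,
                     retained_solvent = 75 / 0.328,
                     solvent_to_distillation = (139.0 - 8 - 10.004) / 0.328,
                     miscella_heat = 8)
  } else {
    sr <- solvent_record("MeTHF", hansen(16.4, 4.7, 4.6), cp = 1.758,
                         t_boil = 80, dh_vap = 375, density = 0.855,
                         t_melt = -136, viscosity = 0.60, price = 5)
    process_scenario(sr, sparged_steam_ratio = 0.14,
                     retained_solvent = 108 / 0.375,
                     solvent_to_distillation = (168.9 - 22 - 7.32) / 0.375,
                     miscella_heat = 22)
  }
}

ledger_row <- function(step, material, change, heat, steam, category) {
  data.frame(step = step, material = material, change = change,
             heat_MJ_per_t = heat, steam_kg_per_t = steam,
             category = category)
}

#' Build the crushing-process energy and steam ledger
#'
#' Assembles, per tonne of seeds, the ordered heat/steam entries of seed
#' preparation, desolventization (meal sensible heat, solvent sensible
#' heat to its boiling point, solvent vaporization, sparged steam,
#' condensed-steam loss), miscella distillation (miscella heating, oil
#' heating from the boiling point to its exit temperature, solvent
#' vaporization), the desolventizer heat-recovery credit (a fraction of
#' the distillation subtotal, applied to both the heat and the steam
#' column), and proportional losses on preparation + extraction.
#'
#' Steam-column conventions follow the reference ledger: preparation rows
#' are fixed constants; desolventization duties convert at the 10-bar
#' latent heat; sparged steam is a mass; condensed steam and the
#' distillation sensible duties convert at the live-steam total enthalpy;
#' the distillation vaporization duty converts at the 6-bar latent heat.
#'
#' @param sc a [process_scenario()].
#' @param steam a [steam_properties()].
#' @return object of class `energy_ledger`: `rows` (data.frame),
#'   `subtotals` (preparation, desolventization, distillation, recovery,
#'   extraction, losses) and `totals`, each a `c(heat, steam)` pair.
#' @export
build_ledger <- function(sc, steam = steam_properties()) {
  if (!inherits(sc, "process_scenario"))
    stop_domain("'sc' must be a process_scenario")
  s <- sc$solvent
  prep <- ledger_row(sc$prep_steps$step, sc$prep_steps$material,
                     sc$prep_steps$change, sc$prep_steps$heat_MJ_per_t,
                     sc$prep_steps$steam_kg_per_t, "preparation")

  meal_heat <- sensible_heat(sc$meal_mass, sc$meal_cp, sc$extraction_T,
                             sc$desolventizer_exit_T)
  solv_sens <- sensible_heat(sc$retained_solvent, s$cp, sc$extraction_T,
                             s$t_boil)
  solv_vap <- vaporization_heat(sc$retained_solvent, s$dh_vap)
  sparge <- sparged_steam(sc$retained_solvent, sc$sparged_steam_ratio, steam)
  desolv <- rbind(
    ledger_row("Desolventization", "Meal",
               sprintf("T: %g => %g C", sc$extraction_T, sc$desolventizer_exit_T),
               meal_heat, steam_from_heat(meal_heat, "10bar", steam),
               "desolventization"),
    ledger_row("Desolventization", "Solvent",
               sprintf("T: %g => Bp", sc$extraction_T),
               solv_sens, steam_from_heat(solv_sens, "10bar", steam),
               "desolventization"),
    ledger_row("Desolventization", "Solvent", "Vaporization",
               solv_vap, steam_from_heat(solv_vap, "10bar", steam),
               "desolventization"),
    ledger_row("Desolventization", "Steam", "Sparged",
               sparge$heat_MJ_per_t, sparge$steam_kg_per_t,
               "desolventization"),
    ledger_row("Desolventization", "Steam", "Condensed",
               sc$condensed_steam_heat,
               steam_from_heat(sc$condensed_steam_heat, "sparged", steam),
               "desolventization"))

  oil_heat <- sensible_heat(sc$oil_to_distillation, sc$oil_cp, s$t_boil,
                            sc$oil_final_T)
  dist_vap <- vaporization_heat(sc$solvent_to_distillation, s$dh_vap)
  dist <- rbind(
    ledger_row("Distillation", "Miscella",
               sprintf("T: %g => Bp", sc$extraction_T),
               sc$miscella_heat,
               steam_from_heat(sc$miscella_heat, "sparged", steam),
               "distillation"),
    ledger_row("Distillation", "Oil",
               sprintf("T: Bp => %g C", sc$oil_final_T),
               oil_heat, steam_from_heat(oil_heat, "sparged", steam),
               "distillation"),
    ledger_row("Distillation", "Solvent", "Vaporization",
               dist_vap, steam_from_heat(dist_vap, "6bar", steam),
               "distillation"))

  dist_sub <- c(heat = sum(dist$heat_MJ_per_t),
                steam = sum(dist$steam_kg_per_t))
  recov <- ledger_row("Recovery", "Gas from DT", "Heat recovered",
                      heat_recovery(dist_sub["heat"], sc$heat_recovery_fraction),
                      heat_recovery(dist_sub["steam"], sc$heat_recovery_fraction),
                      "recovery")

  prep_sub <- c(heat = sum(prep$heat_MJ_per_t), steam = sum(prep$steam_kg_per_t))
  desolv_sub <- c(heat = sum(desolv$heat_MJ_per_t),
                  steam = sum(desolv$steam_kg_per_t))
  extraction <- desolv_sub + dist_sub +
    c(recov$heat_MJ_per_t, recov$steam_kg_per_t)
  losses_v <- sc$loss_fraction * (prep_sub + extraction)
  losses <- ledger_row("Losses", "", sprintf("%g%% of prep + extraction",
                                             100 * sc$loss_fraction),
                       losses_v["heat"], losses_v["steam"], "losses")
  totals <- prep_sub + extraction + losses_v
  rows <- rbind(prep, desolv, dist, recov, losses)
  rownames(rows) <- NULL
  structure(list(rows = rows, solvent = s$name,
                 subtotals = list(preparation = prep_sub,
                                  desolventization = desolv_sub,
                                  distillation = dist_sub,
                                  recovery = c(heat = recov$heat_MJ_per_t,
                                               steam = recov$steam_kg_per_t),
                                  extraction = extraction,
                                  losses = losses_v),
                 totals = totals),
            class = "energy_ledger")
}

#' @export
print.energy_ledger <- function(x, digits = 1, ...) {
  cat(sprintf("Energy ledger: %s (per tonne of seeds)\n", x$solvent))
  r <- x$rows
  r$heat_MJ_per_t <- round_half_up(r$heat_MJ_per_t, digits)
  r$steam_kg_per_t <- round_half_up(r$steam_kg_per_t, digits)
  print(r, row.names = FALSE)
  st <- x$subtotals
  for (nm in names(st))
    cat(sprintf("  %-18s %8.1f MJ/t  %7.1f kg/t\n", nm,
                round_half_up(st[[nm]]["heat"], 1),
                round_half_up(st[[nm]]["steam"], 1)))
  cat(sprintf("  %-18s %8.1f MJ/t  %7.1f kg/t\n", "TOTAL",
              round_half_up(x$totals["heat"], 1),
              round_half_up(x$totals["steam"], 1)))
  invisible(x)
}

#' Compare two process ledgers
#'
#' @param a,b [build_ledger()] results with identical row structure
#'   (same steps/materials/changes up to the solvent-specific temperature
#'   labels).
#' @return list with `rows` (per-row heat/steam deltas `b - a`),
#'   `subtotals`, `total_delta`, and `pct_increase` (heat and steam totals,
#'   half-up rounded to the nearest integer percent).
#' @export
compare_scenarios <- function(a, b) {
  if (!inherits(a, "energy_ledger") || !inherits(b, "energy_ledger"))
    stop_domain("both arguments must be energy ledgers")
  key <- function(l) paste(l$rows$step, l$rows$material, l$rows$category)
  if (!identical(key(a), key(b))) {
    mism <- union(setdiff(key(a), key(b)), setdiff(key(b), key(a)))
    stop_domain("ledger structures differ; unmatched rows: ",
                paste(mism, collapse = "; "))
  }
  rows <- data.frame(step = a$rows$step, material = a$rows$material,
                     category = a$rows$category,
                     delta_heat_MJ_per_t = b$rows$heat_MJ_per_t - a$rows$heat_MJ_per_t,
                     delta_steam_kg_per_t = b$rows$steam_kg_per_t - a$rows$steam_kg_per_t)
  subs <- lapply(names(a$subtotals),
                 function(nm) b$subtotals[[nm]] - a$subtotals[[nm]])
  names(subs) <- names(a$subtotals)
  list(rows = rows, subtotals = subs,
       total_delta = b$totals - a$totals,
       pct_increase = c(
         heat = round_half_up(100 * unname(b$totals["heat"] / a$totals["heat"]) - 100),
         steam = round_half_up(100 * unname(b$totals["steam"] / a$totals["steam"]) - 100)))
}

#' Write a ledger to CSV
#' @param ledger an `energy_ledger`.
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_ledger_csv <- function(ledger, file) {
  utils::write.csv(ledger$rows, file, row.names = FALSE)
  invisible(file)
}

#' Load a process scenario from a JSON config
#'
#' Field names mirror the arguments of [process_scenario()]; the solvent
#' is given as an object with `name`, `hansen` (array of 3), `cp`,
#' `t_boil`, `dh_vap` and optional extras.
#'
#' @param file path to a JSON file.
#' @return a [process_scenario()].
#' @export
read_process_scenario <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(cfg$solvent))
    stop_domain("configuration error: missing field 'solvent'")
  sv <- cfg$solvent
  sr <- solvent_record(sv$name, hansen(sv$hansen[1], sv$hansen[2], sv$hansen[3]),
                       cp = sv$cp %||% NA_real_, t_boil = sv$t_boil %||% NA_real_,
                       dh_vap = sv$dh_vap %||% NA_real_,
                       density = sv$density %||% NA_real_)
  args <- cfg[setdiff(names(cfg), "solvent")]
  req <- c("sparged_steam_ratio", "retained_solvent", "miscella_heat")
  for (nm in req) if (is.null(args[[nm]]))
    stop_domain("configuration error: missing field '", nm, "'")
  do.call(process_scenario, c(list(solvent = sr), args))
}
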