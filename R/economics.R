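#' Economic assumptions for a solvent substitution
#'
#' Prices and consumptions entering the per-tonne cost-benefit balance of
#' replacing the reference solvent by the alternative. Defaults reflect a
#' hexane-to-MeTHF substitution in rapeseed crushing: solvent prices 5 vs
#' 0.9 EUR/kg, 0.75 kg/t solvent make-up, 37 kg/t additional steam at 30
#' EUR/t, 10 kg/t extra oil gross of which 60% is valued (the extra oil
#' displaces an equal mass of meal), oil 900 and meal 350 EUR/t, and a
#' 0.8 EUR/t fixed-cost reduction from a ~5% extractor capacity gain.
#'
#' @param solvent_price_alt,solvent_price_ref EUR/kg.
#' @param solvent_consumption solvent make-up (kg per tonne of seeds).
#' @param extra_steam additional steam demand (kg/t).
#' @param steam_price EUR per tonne of steam.
#' @param extra_oil_gross additional oil recovered (kg/t), gross.
#' @param oil_recovery_value_fraction fraction of the gross extra oil
#'   carrying full oil value.
#' @param oil_price,cake_price EUR/t.
#' @param capacity_gain_fraction extractor capacity gain (informational).
#' @param fixed_cost_reduction EUR/t credit from the capacity gain.
#' @return object of class `econ_assumptions`.
#' @export
economic_assumptions <- function(solvent_price_alt = 5,
                                 solvent_price_ref = 0.9,
                                 solvent_consumption = 0.75,
                                 extra_steam = 37, steam_price = 30,
                                 extra_oil_gross = 10,
                                 oil_recovery_value_fraction = 0.60,
                                 oil_price = 900, cake_price = 350,
                                 capacity_gain_fraction = 0.05,
                                 fixed_cost_reduction = 0.8) {
  for (nm in c("solvent_price_alt", "solvent_price_ref", "steam_price",
               "oil_price", "cake_price"))
    assert_scalar_num(get(nm), nm, nonneg = TRUE)
  if (oil_recovery_value_fraction < 0 || oil_recovery_value_fraction > 1 ||
      capacity_gain_fraction < 0 || capacity_gain_fraction > 1)
    stop_domain("fractions must be in [0, 1]")
  structure(list(solvent_price_alt = solvent_price_alt,
                 solvent_price_ref = solvent_price_ref,
                 solvent_consumption = solvent_consumption,
                 extra_steam = extra_steam, steam_price = steam_price,
                 extra_oil_gross = extra_oil_gross,
                 oil_recovery_value_fraction = oil_recovery_value_fraction,
                 oil_price = oil_price, cake_price = cake_price,
                 capacity_gain_fraction = capacity_gain_fraction,
                 fixed_cost_reduction = fixed_cost_reduction),
            class = "econ_assumptions")
}

#' Solvent make-up cost increment
#'
#' `consumption * (price_alt - price_ref)` EUR per tonne of seeds.
#' @param a an [economic_assumptions()].
#' @return EUR/t (can be negative if the alternative is cheaper).
#' @export
solvent_makeup_cost <- function(a) {
  assert_scalar_num(a$solvent_consumption, "solvent_consumption",
                    positive = TRUE)
  a$solvent_consumption * (a$solvent_price_alt - a$solvent_price_ref)
}

#' Additional steam cost
#'
#' `extra_steam * steam_price / 1000` EUR per tonne of seeds.
#' @param extra_steam kg steam per tonne of seeds.
#' @param steam_price EUR per tonne of steam.
#' @return EUR/t.
#' @export
steam_cost <- function(extra_steam, steam_price) {
  extra_steam * steam_price / 1000
}

#' Value of shifting mass from meal to oil
#'
#' Extra oil recovered from the meal displaces an equal mass of meal, so
#' it is valued at the oil/meal price differential:
#' `net_oil * (oil_price - cake_price) / 1000` EUR per tonne of seeds.
#'
#' @param a an [economic_assumptions()].
#' @param net_oil_kg_per_t net valued extra oil (kg/t), >= 0; defaults to
#'   `extra_oil_gross * oil_recovery_value_fraction`.
#' @return EUR/t.
#' @export
#' @examples
#' oil_shift_benefit(economic_assumptions())  # 6 kg * 0.55 EUR/kg = 3.30
oil_shift_benefit <- function(a, net_oil_kg_per_t = NULL) {
  net <- net_oil_kg_per_t %||%
    (a$extra_oil_gross * a$oil_recovery_value_fraction)
  assert_scalar_num(net, "net_oil_kg_per_t", nonneg = TRUE)
  net * (a$oil_price - a$cake_price) / 1000
}

#' Cost-benefit balance of the substitution
#'
#' Costs: solvent make-up and extra steam. Benefits: the valued extra oil
#' and the fixed-cost reduction from the capacity gain. Each line carries
#' a reporting precision matching the granularity at which such figures
#' are conventionally quoted (make-up cost to the euro, the rest to 0.1
#' EUR/t); reported totals sum the rounded lines while `net` keeps full
#' precision.
#'
#' @param a an [economic_assumptions()].
#' @return object of class `econ_balance`: `lines` (data.frame with
#'   `label`, `eur_per_t`, `reported`, `sign`), `total_costs`,
#'   `total_benefits`, `net` (all full precision), and
#'   `total_costs_reported` / `total_benefits_reported` /
#'   `net_reported` from the rounded lines.
#' @export
balance <- function(a) {
  if (!inherits(a, "econ_assumptions"))
    stop_domain("configuration error: 'a' must be economic_assumptions")
  lines <- data.frame(
    label = c("solvent make-up", "additional steam",
              "extra oil value", "fixed-cost reduction"),
    eur_per_t = c(solvent_makeup_cost(a),
                  steam_cost(a$extra_steam, a$steam_price),
                  oil_shift_benefit(a),
                  a$fixed_cost_reduction),
    digits = c(0, 1, 2, 1),
    sign = c(-1, -1, 1, 1))
  lines$reported <- round_half_up(lines$eur_per_t, lines$digits)
  costs <- lines$sign < 0
  structure(list(
    lines = lines,
    total_costs = sum(lines$eur_per_t[costs]),
    total_benefits = sum(lines$eur_per_t[!costs]),
    net = sum(lines$sign * lines$eur_per_t),
    total_costs_reported = round_half_up(sum(lines$reported[costs]), 1),
    total_benefits_reported = round_half_up(sum(lines$reported[!costs]), 1),
    net_reported = round_half_up(sum(lines$reported[!costs]) -
                                   sum(lines$reported[costs]), 1)),
    class = "econ_balance")
}

#' @export
print.econ_balance <- function(x, ...) {
  cat("Solvent-substitution balance (EUR per tonne of seeds)\n")
  for (i in seq_len(nrow(x$lines)))
    cat(sprintf("  %-22s %s%.2f\n", x$lines$label[i],
                if (x$lines$sign[i] < 0) "-" else "+", x$lines$eur_per_t[i]))
  cat(sprintf("  costs %.1f vs benefits %.1f  (net %+.1f reported, %+.2f exact)\n",
              x$total_costs_reported, x$total_benefits_reported,
              x$net_reported, x$net))
  invisible(x)
}

#' Load economic assumptions from a JSON config
#' @param file path; keys mirror [economic_assumptions()] arguments.
#' @return an [economic_assumptions()].
#' @export
read_economic_assumptions <- function(file) {
  cfg <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(economic_assumptions, cfg)
}
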