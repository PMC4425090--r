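#' Solvent property record
#'
#' Physical and economic properties of a candidate extraction solvent, as
#' used for technical screening and for the crushing-process energy model.
#' Missing optional properties may be `NA`; the screening report keeps the
#' solvent and marks the column absent.
#'
#' @param name solvent name.
#' @param hansen Hansen parameters ([hansen()]).
#' @param cp specific heat (kJ/(degC kg)).
#' @param t_boil boiling point (degC).
#' @param dh_vap latent heat of vaporization (kJ/kg), > 0.
#' @param density density at 25 degC (g/cm^3).
#' @param t_melt melting point (degC); must be below `t_boil`.
#' @param viscosity dynamic viscosity at 25 degC (cP).
#' @param price optional price (EUR/kg).
#' @return object of class `solvent_record`.
#' @export
solvent_record <- function(name, hansen, cp = NA_real_, t_boil = NA_real_,
                           dh_vap = NA_real_, density = NA_real_,
                           t_melt = NA_real_, viscosity = NA_real_,
                           price = NA_real_) {
  hansen <- as_hansen(hansen)
  if (!is.na(dh_vap) && dh_vap <= 0) stop_domain("dh_vap must be > 0")
  if (!is.na(t_boil) && !is.na(t_melt) && t_boil <= t_melt)
    stop_domain("t_boil must exceed t_melt")
  structure(list(name = name, hansen = hansen, cp = cp, t_boil = t_boil,
                 dh_vap = dh_vap, density = density, t_melt = t_melt,
                 viscosity = viscosity, price = price),
            class = "solvent_record")
}

#' Read a solvent property table
#'
#' CSV with header `name,delta_d,delta_p,delta_h,cp,t_boil,dh_vap,density,
#' t_melt,viscosity,price`; missing optional cells may be empty.
#'
#' @param file path to the CSV.
#' @return list of [solvent_record()] objects, named by solvent.
#' @export
read_solvent_table <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "delta_d", "delta_p", "delta_h")
  if (!all(need %in% names(d)))
    stop_domain("solvent table must have columns ", paste(need, collapse = ","))
  opt <- function(col, i) if (col %in% names(d)) d[[col]][i] else NA_real_
  out <- lapply(seq_len(nrow(d)), function(i)
    solvent_record(d$name[i], hansen(d$delta_d[i], d$delta_p[i], d$delta_h[i]),
                   cp = opt("cp", i), t_boil = opt("t_boil", i),
                   dh_vap = opt("dh_vap", i), density = opt("density", i),
                   t_melt = opt("t_melt", i), viscosity = opt("viscosity", i),
                   price = opt("price", i)))
  stats::setNames(out, d$name)
}

#' Read a RED observation panel
#'
#' Long-format CSV `solvent,solute,red`.
#' @param file path to the CSV.
#' @return data.frame with those three columns.
#' @export
read_red_panel <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("solvent", "solute", "red") %in% names(d)))
    stop_domain("RED panel must have columns solvent,solute,red")
  if (any(d$red < 0)) stop_domain("RED values must be >= 0")
  d
}

#' Rank candidate solvents against solute spheres
#'
#' Combines solubility predictions (RED per solute sphere) with technical
#' properties: for each solvent the count of desirable solutes predicted
#' soluble (RED < 1), a flag when any undesirable solute is also predicted
#' soluble, the evaporation energy, and melting point / boiling point /
#' viscosity, each also expressed relative to a reference solvent
#' (reference = 1).
#'
#' @param solvents list of [solvent_record()] (as from
#'   [read_solvent_table()]).
#' @param spheres list of [solute_sphere()] objects (fitted or supplied).
#' @param desirable labels of solutes one wants to extract (e.g.
#'   triglycerides).
#' @param undesirable labels of solutes to avoid (e.g. waxes).
#' @param reference name of the reference solvent for the ratio columns.
#' @return data.frame, one row per solvent, ordered by decreasing
#'   `n_desirable_good` then increasing evaporation energy.
#' @export
screening_report <- function(solvents, spheres,
                             desirable = character(), undesirable = character(),
                             reference = NULL) {
  if (inherits(solvents, "solvent_record")) solvents <- list(solvents)
  if (inherits(spheres, "solute_sphere")) spheres <- list(spheres)
  labels <- vapply(spheres, function(s) as.character(s$label), character(1))
  if (anyDuplicated(labels)) stop_domain("duplicate sphere labels")
  rows <- lapply(solvents, function(s) {
    reds <- vapply(spheres, function(sp) red(s$hansen, sp), numeric(1))
    names(reds) <- paste0("RED_", labels)
    good <- labels[reds < 1]
    data.frame(solvent = s$name, t(reds),
               n_desirable_good = sum(desirable %in% good),
               undesirable_flag = any(undesirable %in% good),
               evaporation_energy_kJ_kg =
                 if (is.na(s$cp) || is.na(s$t_boil) || is.na(s$dh_vap))
                   NA_real_ else evaporation_energy(s),
               t_melt_C = s$t_melt, t_boil_C = s$t_boil,
               viscosity_cP = s$viscosity,
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(reference)) {
    if (!reference %in% out$solvent)
      stop_domain("reference solvent '", reference, "' not in table")
    ref <- out[out$solvent == reference, ]
    for (col in c("evaporation_energy_kJ_kg", "t_boil_C", "viscosity_cP")) {
      out[[paste0("ratio_", col)]] <-
        if (is.na(ref[[col]]) || ref[[col]] == 0) NA_real_ else out[[col]] / ref[[col]]
    }
  }
  out[order(-out$n_desirable_good, out$evaporation_energy_kJ_kg), ]
}
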