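#' End-to-end solvent substitution report
#'
#' Chains the four stages of the screening pipeline on the packaged
#' fixtures and synthetic data: (1) solubility-sphere inversion of the
#' RED panel and solvent screening, (2) extraction kinetics fitted on
#' synthetic curves generated at the reference diffusivities plus the
#' multi-wash simulation, (3) the hexane-vs-alternative energy/steam
#' ledgers, (4) the economic balance, and (5) the lipid-composition
#' equivalence summary. Writes per-stage CSVs and a combined markdown
#' report; all randomness flows from `seed`.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for the synthetic kinetics stage.
#' @param config optional list (or JSON path) overriding stage inputs:
#'   `red_panel`, `solvents` (CSV paths), `assumptions` (JSON path).
#' @return invisibly, a list with the per-stage results and the report
#'   path.
#' @export
run_full_report <- function(out_dir = ".", seed = 1, config = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  config <- config %||% list()
  for (f in unlist(config[c("red_panel", "solvents", "assumptions")]))
    if (!file.exists(f)) stop_domain("config file does not exist: ", f)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)

  # 1 -- HSP screening
  panel <- if (!is.null(config$red_panel)) read_red_panel(config$red_panel)
           else gx_red_panel()
  solvent_csv <- config$solvents %||% gx_extdata("solvents_panel.csv")
  solvent_tab <- utils::read.csv(solvent_csv)
  solvents <- read_solvent_table(solvent_csv)
  spheres <- lapply(unique(panel$solute), function(sl)
    fit_solute_sphere(panel, solvent_tab, solute = sl,
                      dispersion_weight = 1))
  names(spheres) <- unique(panel$solute)
  screen <- screening_report(solvents, spheres,
                             desirable = c("TAG1", "TAG2", "TAG3", "TAG4"),
                             undesirable = "W", reference = "n-hexane")
  utils::write.csv(screen, out("screening.csv"), row.names = FALSE)

  # 2 -- kinetics on synthetic curves at the reference diffusivities
  fits <- lapply(c(hexane = 0.034e-10, methf = 0.122e-10), function(d) {
    sim <- gen_kinetics(kinetic_gen_spec(deff = d, seed = seed,
                                         noise_model = "multiplicative"))
    fit_crank(sim$dataset)
  })
  deff_ratio <- fits$methf$deff / fits$hexane$deff
  kin <- data.frame(solvent = names(fits),
                    deff_m2_s = vapply(fits, `[[`, numeric(1), "deff"),
                    x0_g_gDM = vapply(fits, `[[`, numeric(1), "x0"),
                    r2 = vapply(fits, `[[`, numeric(1), "r2"))
  utils::write.csv(kin, out("kinetics.csv"), row.names = FALSE)
  washes <- lapply(c(hexane = "hexane", methf = "methf"), function(s)
    simulate_washes(default_washing_scenario(s)))
  utils::write.csv(do.call(rbind, Map(cbind, solvent = names(washes),
                                      washes)),
                   out("washes.csv"), row.names = FALSE)

  # 3 -- energy ledger
  lg_h <- build_ledger(default_process_scenario("hexane"))
  lg_m <- build_ledger(default_process_scenario("methf"))
  cmp <- compare_scenarios(lg_h, lg_m)
  write_ledger_csv(lg_h, out("ledger_hexane.csv"))
  write_ledger_csv(lg_m, out("ledger_methf.csv"))

  # 4 -- economics
  assum <- if (!is.null(config$assumptions))
    read_economic_assumptions(config$assumptions) else economic_assumptions()
  bal <- balance(assum)
  utils::write.csv(bal$lines, out("balance.csv"), row.names = FALSE)
  resid <- extrapolate_residual(16.5, 1.8, 0.8)

  # 5 -- composition
  compo <- compare_profiles(gx_fatty_acids("hexane"), gx_fatty_acids("methf"))
  utils::write.csv(compo, out("composition_comparison.csv"),
                   row.names = FALSE)

  methf_row <- screen[screen$solvent == "MeTHF", ]
  report <- c(
    "# Solvent substitution report", "",
    "## Solubility screening",
    sprintf("- spheres fitted to %d solutes; worst column RMS %.3f",
            length(spheres), max(vapply(spheres, `[[`, numeric(1), "rms"))),
    sprintf("- MeTHF: %d/4 triglycerides predicted soluble (RED < 1); wax avoided: %s",
            methf_row$n_desirable_good, !methf_row$undesirable_flag),
    "", "## Extraction kinetics",
    sprintf("- fitted Deff: hexane %.3e, alternative %.3e m2/s",
            fits$hexane$deff, fits$methf$deff),
    sprintf("- Deff ratio %.2f (>= 3.5 expected for MeTHF vs hexane)",
            deff_ratio),
    sprintf("- washes to reach 95%% recovery: hexane %s, alternative %s",
            match(TRUE, washes$hexane$cumulative_recovery_pct >= 95),
            match(TRUE, washes$methf$cumulative_recovery_pct >= 95)),
    "", "## Energy",
    sprintf("- heat totals: %.0f vs %.0f MJ/t (delta %.0f)",
            lg_h$totals["heat"], lg_m$totals["heat"],
            cmp$total_delta["heat"]),
    sprintf("- steam totals: %.0f vs %.0f kg/t (increase %d%%)",
            round_half_up(lg_h$totals["steam"]),
            round_half_up(lg_m$totals["steam"]),
            as.integer(cmp$pct_increase["steam"])),
    "", "## Economics",
    sprintf("- costs %.1f vs benefits %.1f EUR/t (net %+.1f)",
            bal$total_costs_reported, bal$total_benefits_reported,
            bal$net_reported),
    sprintf("- residual-oil projection: %.1f kg/t left, %.1f kg/t gained",
            round_half_up(resid$projected_kg_per_t, 1),
            round_half_up(resid$gain_kg_per_t, 1)),
    "", "## Composition",
    sprintf("- %d of %d comparable fatty acids differ at alpha = 0.05",
            attr(compo, "n_significant"), sum(compo$comparable)))
  writeLines(report, out("report.md"))
  invisible(list(spheres = spheres, screening = screen, fits = fits,
                 deff_ratio = deff_ratio, washes = washes,
                 ledgers = list(hexane = lg_h, methf = lg_m),
                 comparison = cmp, balance = bal, residual = resid,
                 composition = compo, report = out("report.md")))
}

#' Command-line entry point
#'
#' Thin dispatcher over the package's stages, callable as
#' `Rscript -e 'greenextract::greenextract_cli()' <subcommand> ...` or
#' through the shipped launcher `inst/cli/greenextract.R`. Subcommands:
#' `report`, `hsp-fit-sphere`, `kinetics-fit`, `energy`, `econ`,
#' `compo-summarize`, `synth-kinetics`, `--version`.
#'
#' @param args character vector of CLI arguments (defaults to the
#'   command line).
#' @return exit status (0 on success), invisibly.
#' @export
greenextract_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: greenextract <cmd> [options]",
    "  report          --out-dir D [--seed N] [--config F]",
    "  hsp-fit-sphere  --red-table F --solvents F [--solute S] [--weight W]",
    "  kinetics-fit    --input F [--t0 N]",
    "  energy          [--scenario F ...] [--compare]",
    "  econ            [--assumptions F]",
    "  compo-summarize --input F",
    "  synth-kinetics  --deff D --seed N --out F", sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i)) return(default)
    if (i == length(args)) stop_domain("missing value for ", flag)
    args[i + 1]
  }
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  log_msg <- function(...) message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                                   ...)
  status <- 0L
  switch(cmd,
    "--version" = cat("greenextract",
                      as.character(utils::packageVersion("greenextract")),
                      "\n"),
    "report" = {
      log_msg("running full report")
      run_full_report(out_dir = opt("--out-dir", "."),
                      seed = as.integer(opt("--seed", "1")),
                      config = opt("--config"))
    },
    "hsp-fit-sphere" = {
      panel <- read_red_panel(opt("--red-table"))
      sol <- utils::read.csv(opt("--solvents"))
      sph <- fit_solute_sphere(panel, sol, solute = opt("--solute"),
                               dispersion_weight =
                                 as.numeric(opt("--weight", "4")))
      print(sph)
      cat(sprintf("RMS %.4f\n", sph$rms))
    },
    "kinetics-fit" = {
      ds <- read_kinetics_csv(opt("--input"))
      print(fit_crank(ds, t0 = as.numeric(opt("--t0", "5"))))
    },
    "energy" = {
      files <- args[which(args == "--scenario") + 1]
      scens <- if (length(files)) lapply(files, read_process_scenario)
               else list(default_process_scenario("hexane"),
                         default_process_scenario("methf"))
      ledgers <- lapply(scens, build_ledger)
      lapply(ledgers, print)
      if ("--compare" %in% args && length(ledgers) >= 2) {
        cmp <- compare_scenarios(ledgers[[1]], ledgers[[2]])
        cat(sprintf("steam increase: %d%%\n",
                    as.integer(cmp$pct_increase["steam"])))
      }
    },
    "econ" = {
      a <- if (!is.null(opt("--assumptions")))
        read_economic_assumptions(opt("--assumptions"))
      else economic_assumptions()
      print(balance(a))
    },
    "compo-summarize" = {
      d <- read_composition(opt("--input"))
      d <- d[d$analyte != "yield", ]
      # reporting path: tolerate mildly inconsistent published tables
      p <- fa_profile(d$analyte, d$mean, d$sd, d$n, max_total = 105)
      print(round(class_sums(p), 2))
    },
    "synth-kinetics" = {
      spec <- kinetic_gen_spec(deff = as.numeric(opt("--deff")),
                               seed = as.integer(opt("--seed", "1")),
                               noise_model = "multiplicative")
      sim <- gen_kinetics(spec)
      write_kinetics_csv(sim$dataset, opt("--out"))
      log_msg("wrote ", opt("--out"))
    },
    { message("unknown subcommand: ", cmd); message(usage); status <- 1L })
  invisible(status)
}
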