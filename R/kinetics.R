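#' Fraction of solute remaining in a sphere (Crank series)
#'
#' `E(tau) = sum_{i>=1} 6/(i^2 pi^2) exp(-i^2 pi^2 tau)` with dimensionless
#' time `tau = Deff (t - t0) / rd^2`. E(0) = 1; E decreases to 0.
#' @noRd
crank_remaining <- function(tau, n_terms = 200) {
  stopifnot(n_terms >= 1)
  i <- seq_len(n_terms)
  vapply(tau, function(tt) {
    if (tt < 0) stop_domain("crank series undefined for t < t0")
    if (tt == 0) return(1)
    sum(6 / (i^2 * pi^2) * exp(-i^2 * pi^2 * tt))
  }, numeric(1))
}

#' Forward Crank sphere extraction profile
#'
#' Analytic solution for Fickian diffusion out of a sphere of radius `rd`
#' under a perfect-sink boundary, shifted so that the curve passes through
#' the starting accessibility `x0` at the reference time `t0`:
#' `x(t) = x_inf - (x_inf - x0) * E(Deff (t - t0) / rd^2)` with the series
#' `E` of [deff_from_k()]'s model. Nondecreasing in `t`, tends to `x_inf`.
#'
#' @param times times in minutes since solvent contact; all must be >= `t0`
#'   (the model is not defined before the reference time).
#' @param deff effective diffusivity (m^2/s).
#' @param rd particle radius (m).
#' @param x_inf plateau yield (g extract / g dry matter).
#' @param x0 starting accessibility (g/g DM), `0 <= x0 < x_inf`.
#' @param t0 reference time (minutes), default 0.
#' @param n_terms number of series terms (200 is ample for
#'   `tau >= 1e-4`; agreement with a 1000-term sum is ~1e-12).
#' @return extract yield x(t) in g/g DM, same length as `times`.
#' @export
#' @examples
#' crank_profile(c(5, 10, 30), deff = 0.122e-10, rd = 1e-3,
#'               x_inf = 0.4596, x0 = 0.100, t0 = 5)
crank_profile <- function(times, deff, rd, x_inf, x0 = 0, t0 = 0,
                          n_terms = 200) {
  assert_scalar_num(deff, "deff", nonneg = TRUE)
  assert_scalar_num(rd, "rd", positive = TRUE)
  assert_scalar_num(x_inf, "x_inf", positive = TRUE)
  assert_scalar_num(x0, "x0", nonneg = TRUE)
  if (x0 >= x_inf) stop_domain("x0 must be < x_inf")
  if (any(times < t0)) stop_domain("crank_profile is defined for t >= t0 only")
  tau <- deff * (times - t0) * 60 / rd^2
  x_inf - (x_inf - x0) * crank_remaining(tau, n_terms)
}

#' Kinetic dataset of extract yield versus time
#'
#' @param times sampling times (minutes), strictly increasing, >= 0.
#' @param x extract yield at each time (g extract / g dry matter).
#' @param rd particle radius (m).
#' @param temperature extraction temperature (degC).
#' @param solvent solvent name.
#' @param x_inf_hint optional known plateau yield (g/g DM); observed values
#'   may not exceed it by more than 10%.
#' @return object of class `kinetic_dataset`.
#' @export
kinetic_dataset <- function(times, x, rd, temperature = NA_real_,
                            solvent = NA_character_, x_inf_hint = NULL) {
  if (length(times) != length(x)) stop_domain("times and x lengths differ")
  if (any(times < 0) || any(diff(times) <= 0))
    stop_domain("times must be strictly increasing and >= 0")
  if (any(x < 0)) stop_domain("yields must be >= 0")
  if (!is.null(x_inf_hint) && any(x > x_inf_hint * 1.1))
    stop_domain("yield exceeds x_inf_hint by more than 10%")
  assert_scalar_num(rd, "rd", positive = TRUE)
  structure(list(times = times, x = x, rd = rd, temperature = temperature,
                 solvent = solvent, x_inf_hint = x_inf_hint),
            class = "kinetic_dataset")
}

#' @export
print.kinetic_dataset <- function(x, ...) {
  cat(sprintf("Kinetic dataset: %d points, %.0f-%.0f min, rd = %g m, solvent = %s\n",
              length(x$times), min(x$times), max(x$times), x$rd, x$solvent))
  invisible(x)
}

plateau_x_inf <- function(ds) {
  # plateau: relative change over the last two samples < 1%
  n <- length(ds$x)
  if (!is.null(ds$x_inf_hint)) return(ds$x_inf_hint)
  if (n >= 2 && ds$x[n - 1] > 0 &&
      abs(ds$x[n] - ds$x[n - 1]) / ds$x[n - 1] < 0.01)
    return(mean(ds$x[(n - 1):n]))
  warning("no plateau detected; using max(x) as x_inf estimate")
  max(ds$x)
}

#' Fit the Crank sphere model to extraction kinetics
#'
#' Estimates the effective diffusivity and starting accessibility from a
#' yield-versus-time series, using data at `t > t0` only (early points are
#' dominated by surface washing, not diffusion).
#'
#' Two routes are provided. `method = "series"` (default) fits the full
#' Crank series by nonlinear least squares in `(log deff, x0)`,
#' initialized from the log-linear route. `method = "loglinear"` is the
#' classical single-term linearization: a least-squares line of
#' `ln((x_inf - x)/(x_inf - x0))` against `t - t0`, through the origin
#' when `x0` is supplied, otherwise jointly estimating `x0` from the free
#' intercept. The log-linear estimator is strongly biased when the
#' dimensionless time `deff * t / rd^2` of the data is below ~0.1 (several
#' series terms still alive), which is precisely the regime of slow
#' oilseed extraction -- hence the series default; see the vignette.
#'
#' @param ds a [kinetic_dataset()].
#' @param t0 reference time (minutes), default 5.
#' @param x_inf plateau yield; default taken from the dataset hint, else
#'   the mean of the last two points when they differ by < 1% (plateau),
#'   else `max(x)` with a warning.
#' @param x0 starting accessibility if known; estimated otherwise.
#' @param method `"series"` or `"loglinear"`.
#' @param origin for `"loglinear"` with known `x0`: force the regression
#'   through the origin (the model form has no intercept); `FALSE` keeps a
#'   free intercept as a diagnostic.
#' @return object of class `crank_fit`: `x_inf`, `x0`, `t0`, `k` (s^-1),
#'   `deff` (m^2/s, `= k rd^2 / pi^2` exactly), `r2` (on the log scale for
#'   the points used), `n_points_used`, `method`.
#' @export
fit_crank <- function(ds, t0 = 5, x_inf = NULL, x0 = NULL,
                      method = c("series", "loglinear"), origin = TRUE) {
  if (!inherits(ds, "kinetic_dataset")) stop_domain("'ds' must be a kinetic_dataset")
  method <- match.arg(method)
  x_inf <- x_inf %||% plateau_x_inf(ds)
  sel <- ds$times > t0
  t_min <- ds$times[sel]; x <- ds$x[sel]
  bad <- x >= x_inf
  if (any(bad)) {
    warning(sum(bad), " point(s) at or above x_inf dropped from fit")
    t_min <- t_min[!bad]; x <- x[!bad]
  }
  if (length(x) < 3) stop_domain("unfittable: fewer than 3 usable points beyond t0")
  ts <- (t_min - t0) * 60   # seconds, so k is in s^-1 and deff in m^2/s

  loglin <- function(x0_fix) {
    if (is.null(x0_fix)) {
      f <- stats::lm(log(x_inf - x) ~ ts)
      k <- -unname(stats::coef(f)[2])
      x0_hat <- x_inf - exp(unname(stats::coef(f)[1]))
      list(k = k, x0 = max(0, min(x0_hat, 0.999 * x_inf)),
           r2 = summary(f)$r.squared)
    } else {
      y <- log((x_inf - x) / (x_inf - x0_fix))
      if (origin) {
        k <- -sum(y * ts) / sum(ts^2)
        ss_res <- sum((y + k * ts)^2)
        list(k = k, x0 = x0_fix, r2 = 1 - ss_res / sum(y^2))
      } else {
        f <- stats::lm(y ~ ts)
        list(k = -unname(stats::coef(f)[2]), x0 = x0_fix,
             r2 = summary(f)$r.squared)
      }
    }
  }

  init <- loglin(x0)
  if (method == "loglinear") {
    k <- init$k
    if (k <= 0) stop_domain("unfittable: nonpositive slope")
    fit <- init
  } else {
    k0 <- max(init$k, 1e-12)
    obj <- function(p) {
      deff <- exp(p[1])
      x0v <- if (is.null(x0)) p[2] else x0
      if (x0v < 0 || x0v >= x_inf) return(1e10)
      tau <- deff * ts / ds$rd^2
      sum((x_inf - (x_inf - x0v) * crank_remaining(tau) - x)^2)
    }
    p0 <- c(log(k0 * ds$rd^2 / pi^2), if (is.null(x0)) init$x0)
    o <- stats::optim(p0, obj, method = if (is.null(x0)) "Nelder-Mead" else "Brent",
                      lower = if (!is.null(x0)) log(1e-20) else -Inf,
                      upper = if (!is.null(x0)) log(1e-4) else Inf,
                      control = list(maxit = 5000, reltol = 1e-14))
    deff <- exp(o$par[1])
    x0v <- if (is.null(x0)) o$par[2] else x0
    fitted_x <- x_inf - (x_inf - x0v) * crank_remaining(deff * ts / ds$rd^2)
    fit <- list(k = deff * pi^2 / ds$rd^2, x0 = x0v,
                r2 = 1 - sum((x - fitted_x)^2) / sum((x - mean(x))^2))
  }
  deff <- deff_from_k(fit$k, ds$rd)
  structure(list(x_inf = x_inf, x0 = fit$x0, t0 = t0, k = fit$k,
                 deff = deff, r2 = fit$r2, n_points_used = length(x),
                 method = method, solvent = ds$solvent, rd = ds$rd),
            class = "crank_fit")
}

#' @export
print.crank_fit <- function(x, ...) {
  cat(sprintf("Crank fit (%s, %s): Deff = %.4g m2/s, X0 = %.4f g/g DM, Xinf = %.4f, k = %.4g s-1, R2 = %.4f (%d points, t0 = %g min)\n",
              x$method, x$solvent, x$deff, x$x0, x$x_inf, x$k, x$r2,
              x$n_points_used, x$t0))
  invisible(x)
}

#' Effective diffusivity from the first-order transfer coefficient
#'
#' `Deff = k rd^2 / pi^2`, the leading-eigenvalue relation of the Crank
#' sphere series.
#'
#' @param k transfer coefficient (s^-1), > 0.
#' @param rd particle radius (m), > 0.
#' @return effective diffusivity (m^2/s).
#' @export
deff_from_k <- function(k, rd) {
  assert_scalar_num(k, "k", positive = TRUE)
  assert_scalar_num(rd, "rd", positive = TRUE)
  k * rd^2 / pi^2
}

#' Starting accessibility of an extraction
#'
#' The extract fraction already available at the particle surface,
#' obtained by extrapolating the diffusion model fitted for `t > t0` back
#' to time zero (the model value at `t0` maps to `t = 0` by construction:
#' the surface wash happens before diffusion control sets in).
#'
#' @param ds a [kinetic_dataset()].
#' @param t0 reference time (minutes).
#' @param total_oil_content optional total oil content of the matrix
#'   (g/g DM) to express the accessibility as a percentage of total oil.
#' @param ... passed to [fit_crank()].
#' @return list with `x0` (g/g DM), `fraction_pct` (percent of total oil,
#'   `NA` when `total_oil_content` is absent) and the underlying `fit`.
#' @export
starting_accessibility <- function(ds, t0 = 5, total_oil_content = NULL, ...) {
  fit <- fit_crank(ds, t0 = t0, ...)
  frac <- if (is.null(total_oil_content)) NA_real_ else
    100 * fit$x0 / total_oil_content
  list(x0 = fit$x0, fraction_pct = frac, fit = fit)
}

#' Reconstruct a kinetic series from miscella samples
#'
#' Batch maceration kinetics are followed by repeatedly withdrawing small
#' miscella samples and weighing their extract after evaporating the
#' solvent. Each draw removes both solvent and dissolved extract, so the
#' naive concentration-to-yield conversion drifts; this routine propagates
#' the withdrawal bookkeeping. At draw i the solvent remaining is the
#' initial mass minus the solvent removed by all previous draws; the
#' measured extract mass fraction of the sample then gives the extract
#' dissolved in the batch, and the cumulative extracted amount adds back
#' the extract carried away by earlier draws.
#'
#' @param sample_mass mass of each withdrawn sample (g), in time order.
#' @param extract_fraction extract mass fraction of each sample
#'   (g extract / g sample), in `[0, 1)`.
#' @param solvent_mass_initial initial solvent mass in the batch (g).
#' @param dry_matter_mass dry matter mass of the solids (g).
#' @param times sampling times (minutes).
#' @param rd,temperature,solvent passed to [kinetic_dataset()].
#' @return a [kinetic_dataset()] of cumulative extract yield (g/g DM).
#' @export
correct_for_sampling <- function(sample_mass, extract_fraction,
                                 solvent_mass_initial, dry_matter_mass,
                                 times, rd = 1e-3, temperature = NA_real_,
                                 solvent = NA_character_) {
  n <- length(sample_mass)
  if (length(extract_fraction) != n || length(times) != n)
    stop_domain("sample_mass, extract_fraction and times lengths differ")
  if (any(extract_fraction < 0 | extract_fraction >= 1))
    stop_domain("extract fractions must be in [0, 1)")
  assert_scalar_num(solvent_mass_initial, "solvent_mass_initial", positive = TRUE)
  assert_scalar_num(dry_matter_mass, "dry_matter_mass", positive = TRUE)
  solvent_left <- solvent_mass_initial
  extract_removed <- 0
  x <- numeric(n)
  for (i in seq_len(n)) {
    w <- extract_fraction[i]
    extract_in_batch <- w * solvent_left / (1 - w)
    x[i] <- (extract_in_batch + extract_removed) / dry_matter_mass
    solv_out <- sample_mass[i] * (1 - w)
    if (solv_out > solvent_left + 1e-12 ||
        sample_mass[i] > solvent_left + extract_in_batch + 1e-12)
      stop_domain("mass-balance error: withdrawals exceed batch contents")
    solvent_left <- solvent_left - solv_out
    extract_removed <- extract_removed + sample_mass[i] * w
  }
  kinetic_dataset(times, x, rd = rd, temperature = temperature,
                  solvent = solvent)
}

#' Project industrial residual oil under a solvent change
#'
#' Scales the industry-average residual oil by the improvement ratio seen
#' at pilot scale: `projected = industry * alt / ref`, and the oil gain is
#' the difference.
#'
#' @param industry_residual_kg_per_t industry residual oil (kg per tonne of
#'   seeds).
#' @param pilot_residual_ref_pct pilot residual oil with the reference
#'   solvent (percent in meal), > 0.
#' @param pilot_residual_alt_pct pilot residual with the alternative.
#' @return list with `projected_kg_per_t` and `gain_kg_per_t`.
#' @export
#' @examples
#' extrapolate_residual(16.5, 1.8, 0.8)  # 7.33 kg/t left, 9.17 kg/t gained
extrapolate_residual <- function(industry_residual_kg_per_t,
                                 pilot_residual_ref_pct,
                                 pilot_residual_alt_pct) {
  assert_scalar_num(pilot_residual_ref_pct, "pilot_residual_ref_pct",
                    positive = TRUE)
  assert_scalar_num(pilot_residual_alt_pct, "pilot_residual_alt_pct",
                    nonneg = TRUE)
  projected <- industry_residual_kg_per_t *
    pilot_residual_alt_pct / pilot_residual_ref_pct
  list(projected_kg_per_t = projected,
       gain_kg_per_t = industry_residual_kg_per_t - projected)
}

#' Read a kinetic CSV
#'
#' Format: comment header lines `# rd_m=...`, `# solvent=...`,
#' `# temperature_C=...`, then columns `time_min,x_g_per_gDM`.
#' @param file path.
#' @return a [kinetic_dataset()].
#' @export
read_kinetics_csv <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", l), "=")[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  d <- utils::read.csv(text = paste(grep("^#", lines, invert = TRUE,
                                         value = TRUE), collapse = "\n"))
  kinetic_dataset(d$time_min, d$x_g_per_gDM,
                  rd = as.numeric(meta$rd_m %||% 1e-3),
                  temperature = as.numeric(meta$temperature_C %||% NA),
                  solvent = meta$solvent %||% NA_character_)
}

#' Write a kinetic CSV in the dialect of [read_kinetics_csv()]
#' @param ds a [kinetic_dataset()].
#' @param file path.
#' @return `file`, invisibly.
#' @export
write_kinetics_csv <- function(ds, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rd_m=%g", ds$rd),
               sprintf("# solvent=%s", ds$solvent),
               sprintf("# temperature_C=%g", ds$temperature),
               "time_min,x_g_per_gDM"), con)
  utils::write.table(data.frame(ds$times, ds$x), con, sep = ",",
                     col.names = FALSE, row.names = FALSE)
  invisible(file)
}
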