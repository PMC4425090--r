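#' Specification for a synthetic extraction-kinetics experiment
#'
#' Emulates a bench maceration: solids batch-extracted while ~1 g
#' miscella samples are drawn on a fixed grid (1, 3, 5, 10, 15, 20, 30
#' min, then every 30 min to 2 h), each draw removing solvent and
#' dissolved extract. Defaults match 30 g of flaked rapeseed (7.8%
#' moisture) in 150 mL of solvent at 55 degC with the plateau yield of
#' the rapeseed oil content.
#'
#' @param deff effective diffusivity (m^2/s).
#' @param rd particle radius (m).
#' @param x_inf plateau yield (g/g DM).
#' @param x0 starting accessibility (g/g DM).
#' @param t0 reference time (min); sampled points before `t0` follow a
#'   linear surface-washing ramp from 0 to `x0` and are flagged `pre_t0`
#'   (the diffusion model is undefined there).
#' @param noise_model `"none"`, `"additive"` (SD `sigma` g/g DM) or
#'   `"multiplicative"` (coefficient of variation `cv`).
#' @param sigma,cv noise magnitudes.
#' @param grid sampling times (minutes).
#' @param seed RNG seed; mandatory when noise is on.
#' @param withdrawal_mass mass of each sample (g); 0 disables withdrawal
#'   bookkeeping.
#' @param solvent_mass initial solvent mass in the batch (g).
#' @param dm_mass dry matter mass (g).
#' @param solvent solvent name carried into the dataset.
#' @return object of class `kinetic_gen_spec`.
#' @export
kinetic_gen_spec <- function(deff, rd = 1e-3, x_inf = 0.4596, x0 = 0.100,
                             t0 = 5,
                             noise_model = c("none", "additive",
                                             "multiplicative"),
                             sigma = 0.005, cv = 0.02,
                             grid = c(1, 3, 5, 10, 15, 20, 30, 60, 90, 120),
                             seed = NULL, withdrawal_mass = 1,
                             solvent_mass = 128, dm_mass = 27.66,
                             solvent = NA_character_) {
  noise_model <- match.arg(noise_model)
  if (noise_model != "none" && is.null(seed))
    stop_domain("seed is mandatory when noise is on")
  assert_scalar_num(deff, "deff", nonneg = TRUE)
  assert_scalar_num(x_inf, "x_inf", positive = TRUE)
  if (x0 < 0 || x0 >= x_inf) stop_domain("x0 must be in [0, x_inf)")
  if (any(diff(grid) <= 0) || any(grid < 0))
    stop_domain("grid must be strictly increasing, >= 0")
  structure(list(deff = deff, rd = rd, x_inf = x_inf, x0 = x0, t0 = t0,
                 noise_model = noise_model, sigma = sigma, cv = cv,
                 grid = grid, seed = seed,
                 withdrawal_mass = withdrawal_mass,
                 solvent_mass = solvent_mass, dm_mass = dm_mass,
                 solvent = solvent),
            class = "kinetic_gen_spec")
}

#' Generate a synthetic kinetic dataset with withdrawal bookkeeping
#'
#' Forward-simulates the Crank sphere profile, applies measurement noise,
#' and simulates the per-draw removal of solvent and extract so that
#' [correct_for_sampling()] can be exercised end-to-end. Deterministic
#' for a fixed seed; the caller's RNG state is untouched.
#'
#' @param spec a [kinetic_gen_spec()].
#' @return list with `dataset` (a [kinetic_dataset()] of the true noisy
#'   yields, with attribute `pre_t0` flagging pre-reference points),
#'   `withdrawals` (data.frame `time_min`, `sample_mass_g`,
#'   `extract_fraction`, `solvent_in_batch_g`, `extract_in_batch_g`,
#'   `extract_in_samples_g`) and `solvent_mass_initial`.
#' @export
gen_kinetics <- function(spec) {
  if (!inherits(spec, "kinetic_gen_spec")) stop_domain("'spec' must be a kinetic_gen_spec")
  g <- spec$grid
  pre <- g < spec$t0
  x_true <- numeric(length(g))
  x_true[!pre] <- crank_profile(g[!pre], spec$deff, spec$rd, spec$x_inf,
                                spec$x0, spec$t0)
  x_true[pre] <- spec$x0 * g[pre] / spec$t0   # surface-washing ramp
  x_obs <- with_seed(spec$seed, switch(
    spec$noise_model,
    none = x_true,
    additive = pmax(0, x_true + stats::rnorm(length(g), 0, spec$sigma)),
    multiplicative = pmax(0, x_true *
                            (1 + stats::rnorm(length(g), 0, spec$cv)))))
  # withdrawal bookkeeping on the (noisy) yield actually observed
  solvent_left <- spec$solvent_mass
  extract_removed <- 0
  wd <- vector("list", length(g))
  for (i in seq_along(g)) {
    extract_in_batch <- x_obs[i] * spec$dm_mass - extract_removed
    if (extract_in_batch < 0) extract_in_batch <- 0
    w <- extract_in_batch / (extract_in_batch + solvent_left)
    draw <- spec$withdrawal_mass
    if (draw > extract_in_batch + solvent_left)
      stop_domain("mass-balance error: withdrawal exceeds batch")
    solvent_left <- solvent_left - draw * (1 - w)
    extract_removed <- extract_removed + draw * w
    wd[[i]] <- data.frame(time_min = g[i], sample_mass_g = draw,
                          extract_fraction = w,
                          solvent_in_batch_g = solvent_left,
                          extract_in_batch_g = extract_in_batch - draw * w,
                          extract_in_samples_g = extract_removed)
  }
  ds <- kinetic_dataset(g, x_obs, rd = spec$rd, temperature = 55,
                        solvent = spec$solvent,
                        x_inf_hint = spec$x_inf)
  attr(ds, "pre_t0") <- pre
  list(dataset = ds, withdrawals = do.call(rbind, wd),
       solvent_mass_initial = spec$solvent_mass)
}

#' Generate replicate composition tables
#'
#' Gaussian replicates around the specified means (truncated at zero);
#' replicate sets whose total exceeds 100% are scaled back to 100%.
#'
#' @param mean named numeric vector of analyte means (percent), >= 0.
#' @param sd SDs (recycled).
#' @param n number of replicates.
#' @param seed RNG seed.
#' @param renormalize cap each replicate's total at 100%.
#' @return matrix `n x length(mean)` of replicates (columns named).
#' @export
gen_composition <- function(mean, sd, n = 3, seed = NULL,
                            renormalize = TRUE) {
  if (any(mean < 0)) stop_domain("means must be >= 0")
  sd <- rep_len(sd, length(mean))
  reps <- with_seed(seed, {
    m <- matrix(stats::rnorm(n * length(mean), rep(mean, each = n),
                             rep(sd, each = n)), nrow = n)
    pmax(m, 0)
  })
  colnames(reps) <- names(mean)
  if (renormalize) {
    tot <- rowSums(reps)
    over <- tot > 100
    reps[over, ] <- reps[over, , drop = FALSE] * (100 / tot[over])
  }
  reps
}

#' Generate a RED observation panel from a known sphere
#'
#' Computes exact REDs for the given solvents, optionally jitters them,
#' then rounds to the table's precision. Used to exercise
#' [fit_solute_sphere()] round trips.
#'
#' @param sphere a [solute_sphere()].
#' @param solvents data.frame `name`, `delta_d`, `delta_p`, `delta_h`
#'   with >= 4 rows.
#' @param decimals rounding of the printed REDs (`Inf` for none).
#' @param jitter_sd SD of additive Gaussian jitter before rounding.
#' @param seed RNG seed for the jitter.
#' @return data.frame `solvent`, `solute`, `red`.
#' @export
gen_red_panel <- function(sphere, solvents, decimals = 2, jitter_sd = 0,
                          seed = NULL) {
  if (nrow(solvents) < 4) stop_domain("need >= 4 solvents")
  reds <- vapply(seq_len(nrow(solvents)), function(i)
    red(hansen(solvents$delta_d[i], solvents$delta_p[i], solvents$delta_h[i]),
        sphere), numeric(1))
  if (jitter_sd > 0)
    reds <- pmax(0, reds + with_seed(seed, stats::rnorm(length(reds), 0,
                                                        jitter_sd)))
  if (is.finite(decimals)) reds <- round(reds, decimals)
  data.frame(solvent = solvents$name, solute = sphere$label, red = reds)
}
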