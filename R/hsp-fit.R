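#' Fit a solubility sphere to a RED observation panel
#'
#' Inverts a panel of published RED values: given >= 4 solvents with known
#' Hansen parameters and their RED against one solute, recovers the solute
#' sphere (center and interaction radius R0) by least squares on
#' `sum((Ra_i / R0 - red_i)^2)`. For a fixed center the optimal `1/R0` is
#' closed-form, so only the three center coordinates are searched, by
#' multi-start local optimization (Nelder-Mead then BFGS) seeded at the
#' solvent centroid, at every solvent, and at `n_starts` random points in
#' the bounding box (randomized starts use a private RNG seed).
#'
#' @param obs data.frame with columns `solvent` and `red` (one solute), or
#'   columns `solvent`, `solute`, `red` from which a single solute is taken
#'   (specify `solute` if several are present).
#' @param solvents data.frame with columns `name`, `delta_d`, `delta_p`,
#'   `delta_h` covering every solvent in `obs`.
#' @param solute optional solute label to select from `obs`.
#' @param dispersion_weight distance convention (see [hansen_distance()]).
#' @param n_starts number of extra randomized starts.
#' @param seed RNG seed for the randomized starts.
#' @return a [solute_sphere()] with extra fields `residuals` (per-solvent,
#'   fitted minus observed), `rms`, `fitted`, `observed`, `converged`.
#' @export
fit_solute_sphere <- function(obs, solvents, solute = NULL,
                              dispersion_weight = 4, n_starts = 25,
                              seed = 1729) {
  if (!is.data.frame(obs) || !all(c("solvent", "red") %in% names(obs)))
    stop_domain("'obs' must have columns 'solvent' and 'red'")
  if ("solute" %in% names(obs)) {
    solute <- solute %||% unique(obs$solute)
    if (length(solute) != 1L)
      stop_domain("'obs' contains several solutes; pass 'solute'")
    obs <- obs[obs$solute == solute, , drop = FALSE]
  }
  if (any(obs$red < 0)) stop_domain("RED observations must be >= 0")
  idx <- match(obs$solvent, solvents$name)
  if (anyNA(idx))
    stop_domain("unknown solvent(s): ",
                paste(obs$solvent[is.na(idx)], collapse = ", "))
  m <- as.matrix(solvents[idx, c("delta_d", "delta_p", "delta_h")])
  r <- as.numeric(obs$red)
  if (nrow(unique(m)) < 4L)
    stop_domain("fit-degenerate: need >= 4 distinct solvents, got ",
                nrow(unique(m)))
  # degenerate geometry: solvents must affinely span 3 dimensions, else the
  # center has a mirror ambiguity across their common plane
  if (qr(sweep(m, 2, colMeans(m)))$rank < 3L)
    stop_domain("fit-degenerate: solvent set is coplanar in Hansen space")

  w <- dispersion_weight
  ra_fun <- function(c3) sqrt(w * (m[, 1] - c3[1])^2 + (m[, 2] - c3[2])^2 +
                                (m[, 3] - c3[3])^2)
  obj <- function(c3) {
    ra <- ra_fun(c3)
    u <- sum(r * ra) / sum(ra^2)   # optimal 1/R0 for this center
    sum((u * ra - r)^2)
  }
  lo <- apply(m, 2, min) - 10; hi <- apply(m, 2, max) + 10
  starts <- rbind(colMeans(m), m)
  if (n_starts > 0) {
    rand <- with_seed(seed, matrix(stats::runif(3L * n_starts, rep(lo, each = n_starts),
                                                rep(hi, each = n_starts)),
                                   ncol = 3L))
    starts <- rbind(starts, rand)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch({
      o1 <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-14))
      stats::optim(o1$par, obj, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14))
    }, error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    stop_domain("fit_solute_sphere failed to converge from any start")
  ra <- ra_fun(best$par)
  u <- sum(r * ra) / sum(ra^2)
  fitted <- u * ra
  sph <- solute_sphere(hansen(max(best$par[1], 0), max(best$par[2], 0),
                              max(best$par[3], 0)),
                       radius_r0 = 1 / u,
                       label = solute %||% NA_character_,
                       dispersion_weight = w)
  sph$observed <- stats::setNames(r, obs$solvent)
  sph$fitted <- stats::setNames(fitted, obs$solvent)
  sph$residuals <- sph$fitted - sph$observed
  sph$rms <- sqrt(mean(sph$residuals^2))
  sph$converged <- isTRUE(best$convergence == 0)
  sph
}
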