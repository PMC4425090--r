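#' Hansen solubility parameters of a molecule
#'
#' A point in Hansen space: the cohesive energy density split into a
#' dispersion (`delta_d`), polar (`delta_p`) and hydrogen-bonding
#' (`delta_h`) component, all in MPa^0.5.
#'
#' @param delta_d,delta_p,delta_h non-negative finite components (MPa^0.5).
#' @return an object of class `hansen_par` (named numeric length 3).
#' @export
#' @examples
#' hansen(16.4, 4.7, 4.6)  # 2-methyltetrahydrofuran
hansen <- function(delta_d, delta_p, delta_h) {
  p <- c(delta_d = delta_d, delta_p = delta_p, delta_h = delta_h)
  if (!is.numeric(p) || length(p) != 3L || any(!is.finite(p)) || any(p < 0))
    stop_domain("Hansen components must be finite and >= 0")
  structure(p, class = "hansen_par")
}

as_hansen <- function(x) {
  if (inherits(x, "hansen_par")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(hansen(x[[1]], x[[2]], x[[3]]))
  stop_domain("cannot interpret object as Hansen parameters")
}

#' @export
print.hansen_par <- function(x, ...) {
  cat(sprintf("Hansen parameters (MPa^0.5): dD=%.2f dP=%.2f dH=%.2f (total %.2f)\n",
              x[1], x[2], x[3], total_parameter(x)))
  invisible(x)
}

#' Total (Hildebrand-like) solubility parameter
#'
#' `sqrt(delta_d^2 + delta_p^2 + delta_h^2)`.
#'
#' @param p Hansen parameters ([hansen()] or numeric length 3).
#' @return total parameter in MPa^0.5.
#' @export
total_parameter <- function(p) {
  p <- as_hansen(p)
  sqrt(sum(p^2))
}

#' Hansen distance Ra between two points
#'
#' By the field convention the dispersion axis is weighted by a factor 4:
#' `Ra^2 = 4 (dD_a - dD_b)^2 + (dP_a - dP_b)^2 + (dH_a - dH_b)^2`.
#' `dispersion_weight` exposes the weighting because published RED panels
#' are not always consistent with the factor-4 form; the packaged rapeseed
#' panel, for instance, is reproduced markedly better with weight 1 (see
#' the methods vignette).
#'
#' @param a,b Hansen parameters.
#' @param dispersion_weight multiplier on the squared dispersion difference
#'   (4 = standard Hansen convention, 1 = plain Euclidean).
#' @return distance in MPa^0.5; symmetric, zero iff `a == b`.
#' @export
#' @examples
#' hansen_distance(hansen(14, 0, 0), hansen(16.4, 4.7, 4.6))  # 8.14
hansen_distance <- function(a, b, dispersion_weight = 4) {
  a <- as_hansen(a); b <- as_hansen(b)
  assert_scalar_num(dispersion_weight, "dispersion_weight", positive = TRUE)
  d <- a - b
  sqrt(dispersion_weight * d[[1]]^2 + d[[2]]^2 + d[[3]]^2)
}

#' Solubility sphere of a solute
#'
#' Region of Hansen space whose interior (distance from `center` below the
#' interaction radius `radius_r0`) contains the good solvents for the
#' solute.
#'
#' @param center Hansen parameters of the solute.
#' @param radius_r0 interaction radius R0 (MPa^0.5), > 0.
#' @param label solute identifier (e.g. `"TAG1"`).
#' @param dispersion_weight distance convention the sphere was defined or
#'   fitted under; [red()] reuses it.
#' @return object of class `solute_sphere`.
#' @export
solute_sphere <- function(center, radius_r0, label = NA_character_,
                          dispersion_weight = 4) {
  center <- as_hansen(center)
  assert_scalar_num(radius_r0, "radius_r0", positive = TRUE)
  structure(list(center = center, radius_r0 = radius_r0, label = label,
                 dispersion_weight = dispersion_weight),
            class = "solute_sphere")
}

#' @export
print.solute_sphere <- function(x, ...) {
  cat(sprintf("Solubility sphere '%s': center (%.2f, %.2f, %.2f), R0 = %.3f MPa^0.5 (w_d = %g)\n",
              x$label, x$center[1], x$center[2], x$center[3],
              x$radius_r0, x$dispersion_weight))
  invisible(x)
}

#' Relative energy difference (RED)
#'
#' `RED = Ra(solvent, center) / R0`. RED < 1 predicts a good solvent for
#' the solute, RED > 1 a poor one; exactly 1 lies on the sphere surface.
#'
#' @param solvent Hansen parameters of the solvent.
#' @param sphere a [solute_sphere()].
#' @return dimensionless RED (>= 0).
#' @seealso [red_class()]
#' @export
red <- function(solvent, sphere) {
  if (!inherits(sphere, "solute_sphere"))
    stop_domain("'sphere' must be a solute_sphere")
  if (!is.finite(sphere$radius_r0) || sphere$radius_r0 <= 0)
    stop_domain("invalid sphere: radius_r0 must be > 0")
  hansen_distance(solvent, sphere$center,
                  dispersion_weight = sphere$dispersion_weight) /
    sphere$radius_r0
}

#' Classify a RED value
#'
#' @param x RED value(s).
#' @param tol half-width of the borderline band around 1 (values rounded to
#'   two decimals make an exact 1.00 meaningful).
#' @return factor with levels `good`, `borderline`, `poor`.
#' @export
red_class <- function(x, tol = 0) {
  cls <- ifelse(x < 1 - tol, "good", ifelse(x > 1 + tol, "poor", "borderline"))
  factor(cls, levels = c("good", "borderline", "poor"))
}

#' Energy to evaporate one kilogram of solvent
#'
#' Sensible heat from `t_ref` to the boiling point plus the latent heat:
#' `cp * (t_boil - t_ref) + dh_vap`. A key technical screening property:
#' distillation and solvent recovery dominate the thermal budget of
#' solvent extraction.
#'
#' @param s a [solvent_record()].
#' @param t_ref reference temperature (degrees C), default 25.
#' @return energy in kJ/kg.
#' @export
#' @examples
#' evaporation_energy(solvent_record("n-hexane", hansen(14, 0, 0),
#'   cp = 2.27, t_boil = 69, dh_vap = 328))  # 427.9
evaporation_energy <- function(s, t_ref = 25) {
  if (!inherits(s, "solvent_record")) stop_domain("'s' must be a solvent_record")
  dT <- s$t_boil - t_ref
  if (dT < 0) {
    warning("t_boil below t_ref; sensible term clamped at 0")
    dT <- 0
  }
  s$cp * dT + s$dh_vap
}
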