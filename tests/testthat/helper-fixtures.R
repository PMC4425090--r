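# Shared helpers: independent oracles and small builders.

# Independent Crank-series oracle: straightforward 1000-term partial sum,
# written without reference to the package internals.
oracle_crank_x <- function(t_min, deff, rd, x_inf, x0, t0, n_terms = 1000) {
  i <- seq_len(n_terms)
  vapply(t_min, function(tt) {
    tau <- deff * (tt - t0) * 60 / rd^2
    x_inf - (x_inf - x0) * sum(6 / (i^2 * pi^2) * exp(-i^2 * pi^2 * tau))
  }, numeric(1))
}

# Welch two-sample t from summary statistics (independent of the package).
oracle_welch_p <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  tt <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * pt(-abs(tt), df)
}

panel_solvents <- function() {
  utils::read.csv(gx_extdata("solvents_panel.csv"))
}

# printed RED panel as a matrix for column-wise assertions
red_matrix <- function() {
  p <- gx_red_panel()
  m <- tapply(p$red, list(p$solvent, p$solute), identity)
  m[unique(p$solvent), unique(p$solute)]
}

random_hansen <- function() hansen(runif(1, 12, 20), runif(1, 0, 10),
                                   runif(1, 0, 15))
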