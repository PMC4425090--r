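#' Parse a fatty-acid shorthand label
#'
#' Accepts the GC-table notation `C<carbons>[:<double bonds>][ n-<omega>]`
#' after normalizing typographic variants (Unicode minus, stray spaces,
#' italic markers), e.g. `"C18:1 n - 9"`, `"C16"`, `"C18:3 n-3"`.
#'
#' @param label character label.
#' @return object of class `fatty_acid`: `shorthand` (canonical form),
#'   `carbons`, `double_bonds`, `omega` (or `NA`), `class` (`"SFA"`,
#'   `"MUFA"` or `"PUFA"`).
#' @export
#' @examples
#' parse_fatty_acid("C18:3 n - 3")$class  # "PUFA"
parse_fatty_acid <- function(label) {
  raw <- label
  x <- gsub("−|–|—", "-", label)  # unicode minus/dashes
  x <- gsub("\\*", "", x)                        # italic markers
  x <- gsub("\\s+", "", x)
  m <- regmatches(x, regexec("^C([0-9]+)(?::([0-9]+))?(?:n-([0-9]+))?$", x))[[1]]
  if (length(m) == 0 || m[1] != x)
    stop_domain("cannot parse fatty-acid label: '", raw, "'")
  carbons <- as.integer(m[2])
  db <- if (m[3] == "") 0L else as.integer(m[3])
  omega <- if (m[4] == "") NA_integer_ else as.integer(m[4])
  if (carbons < 4L || carbons %% 2L != 0L)
    stop_domain("implausible fatty acid (carbons must be even, >= 4): '",
                raw, "'")
  structure(list(shorthand = render_fatty_acid(carbons, db, omega),
                 carbons = carbons, double_bonds = db, omega = omega,
                 class = if (db == 0L) "SFA" else if (db == 1L) "MUFA" else "PUFA"),
            class = "fatty_acid")
}

#' Canonical rendering of a fatty acid
#' @param carbons,double_bonds,omega integers (`omega` may be `NA`).
#' @return canonical label, e.g. `"C18:1 n-9"`; `parse_fatty_acid()` of
#'   the result round-trips.
#' @export
render_fatty_acid <- function(carbons, double_bonds = 0L, omega = NA) {
  out <- paste0("C", carbons)
  if (double_bonds > 0) out <- paste0(out, ":", double_bonds)
  if (!is.na(omega)) out <- paste0(out, " n-", omega)
  out
}

#' Fatty-acid profile (relative composition with replicate statistics)
#'
#' @param analyte fatty-acid labels (parseable by [parse_fatty_acid()]).
#' @param mean,sd percent of total fatty acids (mean and SD over
#'   replicates).
#' @param n number of replicates per analyte.
#' @param yield optional extraction yield, `c(mean, sd)` in g/100 g DM.
#' @param max_total upper bound on the sum of the means (percent). The
#'   default 100.5 allows rounding slack only; published tables are
#'   occasionally internally inconsistent beyond that (the packaged MeTHF
#'   profile sums to 101.08%) and need an explicit, documented allowance.
#' @return object of class `fa_profile`: data.frame `entries` plus
#'   `yield`.
#' @export
fa_profile <- function(analyte, mean, sd = NA_real_, n = NA_integer_,
                       yield = NULL, max_total = 100.5) {
  if (any(mean < 0)) stop_domain("means must be >= 0")
  if (sum(mean) > max_total)
    stop_domain(sprintf("composition sums to %.2f%%, more than %.1f%%",
                        sum(mean), max_total))
  fas <- lapply(analyte, parse_fatty_acid)
  entries <- data.frame(
    analyte = vapply(fas, `[[`, character(1), "shorthand"),
    carbons = vapply(fas, `[[`, integer(1), "carbons"),
    double_bonds = vapply(fas, `[[`, integer(1), "double_bonds"),
    class = vapply(fas, `[[`, character(1), "class"),
    mean = mean, sd = rep_len(sd, length(mean)), n = rep_len(n, length(mean)))
  structure(list(entries = entries, yield = yield), class = "fa_profile")
}

#' Sum a fatty-acid profile by saturation class
#'
#' @param p an [fa_profile()].
#' @return named numeric `c(SFA =, MUFA =, PUFA =)` in percent of total
#'   fatty acids (0 for an absent class).
#' @export
class_sums <- function(p) {
  if (!inherits(p, "fa_profile")) stop_domain("'p' must be an fa_profile")
  out <- c(SFA = 0, MUFA = 0, PUFA = 0)
  if (nrow(p$entries)) {
    s <- tapply(p$entries$mean, p$entries$class, sum)
    out[names(s)] <- s
  }
  out
}

#' Tocopherol / tocotrienol panel
#'
#' Contents in mg per kg fat. Values below the quantification limit are
#' entered as censored: `censored = TRUE` rows carry the limit in `mean`
#' and are excluded from sums and equivalents (contributing 0, flagged).
#'
#' @param compound names such as `"alpha"`, `"beta"`, `"gamma"`,
#'   `"delta"`, `"acetate"`, `"alpha_tocotrienol"`, ...
#' @param mean,sd contents (mg/kg fat).
#' @param censored logical, below-quantification-limit flags.
#' @return object of class `toco_panel` (data.frame).
#' @export
tocopherol_panel <- function(compound, mean, sd = NA_real_,
                             censored = FALSE) {
  if (any(mean < 0)) stop_domain("contents must be >= 0")
  structure(data.frame(compound = compound, mean = mean,
                       sd = rep_len(sd, length(mean)),
                       censored = rep_len(censored, length(mean))),
            class = c("toco_panel", "data.frame"))
}

#' Vitamin E activity in alpha-tocopherol equivalents
#'
#' Weights the four tocopherols by the conventional potency factors
#' alpha 1, beta 0.5, gamma 0.1, delta 0.03 and converts mg/kg fat to
#' alpha-TE per 100 g fat (divide by 10). Censored (below-limit) entries
#' contribute 0; the result then carries attribute `censored_dropped`.
#'
#' @param t a [tocopherol_panel()].
#' @return alpha-TE per 100 g fat (numeric scalar).
#' @export
#' @examples
#' p <- tocopherol_panel(c("alpha", "beta", "gamma", "delta"),
#'                       c(277, 3.5, 443, 13.3))
#' vitamin_e_equivalents(p)  # 32.34 -> reported 32.3
vitamin_e_equivalents <- function(t) {
  if (!inherits(t, "toco_panel")) stop_domain("'t' must be a tocopherol_panel")
  factors <- c(alpha = 1, beta = 0.5, gamma = 0.1, delta = 0.03)
  total <- 0
  dropped <- character()
  for (nm in names(factors)) {
    row <- t[t$compound == nm, , drop = FALSE]
    if (nrow(row) == 0) next
    if (any(row$censored)) { dropped <- c(dropped, nm); next }
    total <- total + factors[[nm]] * sum(row$mean)
  }
  structure(total / 10, censored_dropped = dropped)
}

#' Gravimetric extraction yield
#'
#' `100 * extract_mass / dry_seed_mass`, percent of dry matter.
#' @param extract_mass extract mass (g), >= 0.
#' @param dry_seed_mass dry matter mass (g), > 0.
#' @return percent.
#' @export
compute_yield <- function(extract_mass, dry_seed_mass) {
  assert_scalar_num(extract_mass, "extract_mass", nonneg = TRUE)
  assert_scalar_num(dry_seed_mass, "dry_seed_mass", positive = TRUE)
  100 * extract_mass / dry_seed_mass
}

#' Per-analyte equivalence comparison of two profiles
#'
#' Welch two-sample t statistics reconstructed from the summary
#' statistics (mean, SD, n) of each replicate set, with
#' Welch-Satterthwaite degrees of freedom and two-sided p values. A
#' solvent is deemed non-selective when no analyte differs at the chosen
#' level.
#'
#' @param a,b [fa_profile()] objects with `sd` and `n >= 2` set.
#' @param alpha significance level for the flag.
#' @return data.frame per analyte: means, `t`, `df`, `p`, `significant`,
#'   `comparable` (FALSE when an analyte is missing on one side, with
#'   `NA` statistics); attribute `n_significant`.
#' @export
compare_profiles <- function(a, b, alpha = 0.05) {
  ea <- a$entries; eb <- b$entries
  if (any(ea$n < 2, na.rm = TRUE) || any(eb$n < 2, na.rm = TRUE) ||
      anyNA(ea$n) || anyNA(eb$n))
    stop_domain("both profiles need n >= 2 replicates per analyte")
  analytes <- union(ea$analyte, eb$analyte)
  rows <- lapply(analytes, function(an) {
    ia <- match(an, ea$analyte); ib <- match(an, eb$analyte)
    if (is.na(ia) || is.na(ib))
      return(data.frame(analyte = an, mean_a = if (is.na(ia)) NA else ea$mean[ia],
                        mean_b = if (is.na(ib)) NA else eb$mean[ib],
                        t = NA, df = NA, p = NA, significant = NA,
                        comparable = FALSE))
    se2a <- ea$sd[ia]^2 / ea$n[ia]; se2b <- eb$sd[ib]^2 / eb$n[ib]
    se <- sqrt(se2a + se2b)
    tt <- (ea$mean[ia] - eb$mean[ib]) / se
    df <- (se2a + se2b)^2 /
      (se2a^2 / (ea$n[ia] - 1) + se2b^2 / (eb$n[ib] - 1))
    p <- 2 * stats::pt(-abs(tt), df)
    data.frame(analyte = an, mean_a = ea$mean[ia], mean_b = eb$mean[ib],
               t = tt, df = df, p = p, significant = p < alpha,
               comparable = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_significant") <- sum(out$significant, na.rm = TRUE)
  out
}

#' Read a composition CSV
#'
#' Dialect `analyte,mean,sd,n,unit`; a leading `<` in `mean` marks a
#' value below the quantification limit (stored as the limit with a
#' censored flag).
#'
#' @param file path.
#' @return data.frame `analyte`, `mean`, `sd`, `n`, `unit`, `censored`.
#' @export
read_composition <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = c(mean = "character"))
  if (!all(c("analyte", "mean") %in% names(d)))
    stop_domain("composition CSV needs columns analyte,mean[,sd,n,unit]")
  cens <- grepl("^\\s*<", d$mean)
  d$censored <- cens
  d$mean <- as.numeric(sub("^\\s*<\\s*", "", d$mean))
  if (!"sd" %in% names(d)) d$sd <- NA_real_
  if (!"n" %in% names(d)) d$n <- NA_integer_
  if (!"unit" %in% names(d)) d$unit <- NA_character_
  d
}
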