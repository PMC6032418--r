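# The paramagnetic distance chain.
#
# For a ligand in fast exchange with a paramagnetic (ferric, S > 0) heme
# protein, the observed proton relaxation rate is the population-weighted
# average over bound and free states. Subtracting the diamagnetic
# reference rate (ferrous-CO complex) isolates the paramagnetic part T1P;
# dividing out the bound fraction alpha_m and the electron spin factor
# S(S+1) leaves the r^-6 dipolar term of the Solomon-Bloembergen
# relationship, so
#
#   r = [9.78e16 * T1P * alpha_m * S(S+1) * tau_c]^(1/6)   (Angstroms)
#
# with the constant carrying implicit units A^6 s^-2 (seconds in, A out).

.sb_constant <- 9.78e16

#' Paramagnetic relaxation time T1P from a ferric/ferrous-CO T1 pair
#'
#' \code{1/T1P = 1/T1(ferric) - 1/T1(ferrous-CO)}: the ferrous-CO complex
#' is diamagnetic, so its rate is the full diamagnetic contribution and
#' the difference of rates is purely paramagnetic. Requires
#' \code{t1_ferric < t1_ferrous_co} (the paramagnetic state must relax
#' faster); equality or reversal means no detectable paramagnetic effect.
#'
#' The standard error is first-order propagation assuming independent
#' errors on the two T1 values:
#' \code{var(1/T1P) = (se_f/t1_f^2)^2 + (se_d/t1_d^2)^2}, then
#' \code{se(T1P) = T1P^2 * sd(1/T1P)}.
#'
#' @param t1_ferric,t1_ferrous_co T1 in seconds for the ferric and
#'   ferrous-CO states.
#' @param se_ferric,se_ferrous_co their standard errors (seconds).
#' @param proton_label label used in error messages.
#' @return List with \code{t1p} (seconds), \code{se} and
#'   \code{rel_se} (= se/t1p).
#' @examples
#' t1p_from_pair(1.54, 1.85)$t1p  # 9.19 s
#' @export
t1p_from_pair <- function(t1_ferric, t1_ferrous_co,
                          se_ferric = 0, se_ferrous_co = 0,
                          proton_label = "proton") {
  check_positive(t1_ferric, "t1_ferric")
  check_positive(t1_ferrous_co, "t1_ferrous_co")
  if (t1_ferric >= t1_ferrous_co) {
    stop_input("proton '", proton_label, "': no paramagnetic effect ",
               "(T1 ferric ", t1_ferric, " s >= T1 ferrous-CO ",
               t1_ferrous_co, " s)")
  }
  t1p <- 1 / (1 / t1_ferric - 1 / t1_ferrous_co)
  var_rate <- (se_ferric / t1_ferric^2)^2 + (se_ferrous_co / t1_ferrous_co^2)^2
  se <- t1p^2 * sqrt(var_rate)
  list(t1p = t1p, se = se, rel_se = se / t1p)
}

#' Fraction of ligand bound to enzyme under fast exchange
#'
#' \code{alpha_m = [P450] / (Ks + [S])}: with the enzyme far below the
#' substrate concentration and exchange fast on the relaxation timescale,
#' this is the fraction of ligand molecules experiencing the paramagnetic
#' center at any instant. Units cancel, so any consistent concentration
#' unit works; the package uses uM throughout.
#'
#' @param p450_conc enzyme concentration (uM, > 0).
#' @param substrate_conc substrate concentration (uM, > 0).
#' @param ks spectral binding constant (uM, > 0).
#' @param warn_threshold emit a warning when alpha_m exceeds this value
#'   (default 0.1): a large bound fraction strains the dilute-enzyme
#'   fast-exchange assumption.
#' @return The dimensionless bound fraction, in (0, 1).
#' @examples
#' alpha_m(0.017, 171, 17.1)  # 9.04e-5
#' @export
alpha_m <- function(p450_conc, substrate_conc, ks, warn_threshold = 0.1) {
  check_positive(p450_conc, "p450_conc")
  check_positive(substrate_conc, "substrate_conc")
  check_positive(ks, "ks")
  am <- p450_conc / (ks + substrate_conc)
  if (am >= 1) {
    stop_input("alpha_m = ", signif(am, 3),
               " is not a fraction; check concentration units")
  }
  if (am > warn_threshold) {
    warning(sprintf(
      "alpha_m = %.3g exceeds %.3g: the dilute-enzyme fast-exchange
  assumption may be strained", am, warn_threshold), call. = FALSE)
  }
  am
}

#' Proton-iron distance from the Solomon-Bloembergen sixth root
#'
#' \code{r = (9.78e16 * t1p * am * ss1 * tau_c)^(1/6)} in Angstroms.
#' The numerical constant collects the physical prefactors of the
#' dipolar electron-nucleus interaction at the proton Larmor frequency
#' and carries implicit units of A^6 s^-2, so that all time arguments are
#' in seconds and the result in Angstroms.
#'
#' @param t1p paramagnetic relaxation time (seconds, > 0).
#' @param am bound-ligand fraction alpha_m (dimensionless, > 0).
#' @param ss1 effective spin factor S(S+1) (dimensionless, > 0); see
#'   \code{\link{spin_factor}}.
#' @param tau_c correlation time of the electron-nuclear dipolar
#'   interaction (seconds, > 0).
#' @return Distance in Angstroms.
#' @examples
#' iron_distance(9.19, 9.038e-5, 2.91, 3.38e-10)  # 6.55 A
#' @export
iron_distance <- function(t1p, am, ss1, tau_c) {
  check_positive(t1p, "t1p")
  check_positive(am, "am")
  check_positive(ss1, "ss1")
  check_positive(tau_c, "tau_c")
  (.sb_constant * t1p * am * ss1 * tau_c)^(1 / 6)
}

#' First-order standard error of a paramagnetic distance
#'
#' Propagates the T1 fitting errors through the distance chain. Because
#' \code{r} is proportional to \code{T1P^(1/6)},
#' \code{se(r) = (r / 6) * se(T1P) / T1P}, with \code{se(T1P)} from
#' independent-error quadrature on the two relaxation rates (see
#' \code{\link{t1p_from_pair}}). Uncertainty in Ks, spin fractions and
#' tau_c is not propagated: the dominant, quantified errors are those of
#' the T1 fits.
#'
#' @param t1_ferric,t1_ferrous_co the T1 pair (seconds).
#' @param se_ferric,se_ferrous_co their standard errors (seconds).
#' @param r the distance (Angstroms) computed from this pair.
#' @return Standard error of \code{r} in Angstroms (0 when both T1
#'   standard errors are 0).
#' @examples
#' distance_se(1.54, 1.85, 0.15, 0.18, r = 6.55)  # ~0.83 A
#' @export
distance_se <- function(t1_ferric, t1_ferrous_co, se_ferric, se_ferrous_co,
                        r) {
  check_positive(r, "r")
  p <- t1p_from_pair(t1_ferric, t1_ferrous_co, se_ferric, se_ferrous_co)
  (r / 6) * p$rel_se
}

#' Fast-exchange temperature diagnostic
#'
#' In fast exchange the observed paramagnetic rate is exchange-limited
#' from below, so 1/T1P decreases as temperature drops: a double
#' reciprocal plot of 1/T1P against 1/T has positive slope. The
#' diagnostic fits an ordinary least-squares line of \code{1/t1p} on
#' \code{1/temperature} and passes when the slope is positive and
#' R-squared is at least \code{r2_min}.
#'
#' @param temperatures at least 3 distinct temperatures (kelvin).
#' @param t1p_values T1P at those temperatures (seconds, > 0).
#' @param r2_min minimum R-squared for a pass (default 0.95).
#' @return Object of class \code{"exchange_check"}: list with
#'   \code{slope}, \code{intercept}, \code{r_squared}, \code{pass}, and
#'   the fitted \code{lm} object.
#' @examples
#' fast_exchange_check(c(283, 298, 310), c(8.1, 9.2, 10.4))
#' @export
fast_exchange_check <- function(temperatures, t1p_values, r2_min = 0.95) {
  if (length(temperatures) != length(t1p_values)) {
    stop_input("temperatures and t1p_values must have equal length")
  }
  if (length(unique(temperatures)) < 3) {
    stop_input("at least 3 distinct temperatures are required")
  }
  check_positive(temperatures, "temperatures")
  check_positive(t1p_values, "t1p_values")
  inv_t <- 1 / temperatures
  inv_t1p <- 1 / t1p_values
  fit <- lm(inv_t1p ~ inv_t)
  slope <- unname(coef(fit)[2])
  # computed directly: summary.lm warns on an exactly collinear fit
  r2 <- 1 - sum(residuals(fit)^2) / sum((inv_t1p - mean(inv_t1p))^2)
  structure(list(
    slope = slope, intercept = unname(coef(fit)[1]),
    r_squared = r2, pass = (slope > 0 && r2 >= r2_min),
    r2_min = r2_min, lm = fit,
    data = data.frame(temperature_K = temperatures, t1p_s = t1p_values)
  ), class = "exchange_check")
}

#' @export
print.exchange_check <- function(x, ...) {
  cat("Fast-exchange diagnostic (1/T1P vs 1/T):\n")
  cat(sprintf("  slope = %.4g, R^2 = %.4f (threshold %.2f) -> %s\n",
              x$slope, x$r_squared, x$r2_min,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
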