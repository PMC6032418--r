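# Spectral binding: one-site isotherm and difference-spectrum typing.
#
# Substrate binding displaces the axial water of the heme iron; the
# resulting low-spin -> high-spin shift shows as a type I difference
# spectrum (peak ~390 nm, trough ~420 nm). The amplitude of that
# difference tracks occupancy, giving the hyperbolic isotherm
# dA = Bmax * [S] / (Ks + [S]).

#' Fit the one-site spectral binding isotherm
#'
#' Unweighted least-squares fit of \code{dA = Bmax * [S] / (Ks + [S])} to a
#' difference-absorbance titration. \code{Ks} is the substrate
#' concentration at half-maximal absorbance change (the spectral binding
#' constant); \code{Bmax} the absorbance change at saturation.
#'
#' @param substrate_conc substrate concentrations (uM, >= 0, strictly
#'   increasing, at least 5 points).
#' @param delta_A absorbance differences at those concentrations (AU).
#' @param enzyme_label label carried into the result.
#'
#' @return Object of class \code{"binding_fit"}: list with \code{ks},
#'   \code{ks_se}, \code{bmax}, \code{bmax_se} (all > 0), \code{rss},
#'   \code{n_points}, \code{warnings} (character; e.g. when the fitted Ks
#'   exceeds ten times the largest titrated concentration, or when no
#'   concentration reaches the fitted Ks). Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{residuals},
#'   \code{plot}.
#'
#' @examples
#' s <- c(1, 3, 10, 17.1, 30, 60, 120, 200)
#' fit <- fit_binding_isotherm(s, 0.05 * s / (17.1 + s))
#' coef(fit)  # Ks = 17.1 uM, Bmax = 0.05
#' @export
fit_binding_isotherm <- function(substrate_conc, delta_A,
                                 enzyme_label = "enzyme") {
  if (length(substrate_conc) != length(delta_A)) {
    stop_input("substrate_conc and delta_A must have equal length")
  }
  if (length(substrate_conc) < 5) {
    stop_input("at least 5 titration points are required")
  }
  if (any(!is.finite(substrate_conc)) || any(substrate_conc < 0)) {
    stop_input("substrate concentrations must be finite and >= 0")
  }
  if (any(diff(substrate_conc) <= 0)) {
    stop_input("substrate concentrations must be strictly increasing")
  }

  dat <- data.frame(s = substrate_conc, da = delta_A)
  bmax0 <- max(delta_A)
  if (bmax0 <= 0) stop_fit("titration has no positive absorbance change")
  ks0 <- substrate_conc[which.min(abs(delta_A - bmax0 / 2))]
  if (ks0 <= 0) ks0 <- median(substrate_conc[substrate_conc > 0])

  fit <- tryCatch(
    minpack.lm::nlsLM(da ~ bmax * s / (ks + s), data = dat,
                      start = list(bmax = bmax0, ks = ks0),
                      lower = c(bmax = 1e-12, ks = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop_fit("binding isotherm fit failed for '", enzyme_label, "'")
  }
  cf <- summary(fit)$coefficients
  ks <- unname(cf["ks", "Estimate"])
  bmax <- unname(cf["bmax", "Estimate"])
  if (ks <= 0 || bmax <= 0) {
    stop_fit("non-positive parameter estimate for '", enzyme_label, "'")
  }

  warn <- character()
  if (ks > 10 * max(substrate_conc)) {
    warn <- c(warn, sprintf(
      "fitted Ks (%.3g uM) exceeds 10x the largest titrated concentration",
      ks))
  }
  if (max(substrate_conc) < ks) {
    warn <- c(warn, "no titrated concentration reaches the fitted Ks")
  }

  structure(list(
    enzyme_label = enzyme_label,
    ks = ks, ks_se = unname(cf["ks", "Std. Error"]),
    bmax = bmax, bmax_se = unname(cf["bmax", "Std. Error"]),
    rss = sum(residuals(fit)^2), n_points = nrow(dat),
    warnings = warn, nls = fit, data = dat
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Spectral binding fit: %s\n", x$enzyme_label))
  cat(sprintf("  Ks   = %.4g +/- %.2g uM\n", x$ks, x$ks_se))
  cat(sprintf("  Bmax = %.4g +/- %.2g AU  (n = %d, RSS = %.3g)\n",
              x$bmax, x$bmax_se, x$n_points, x$rss))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(ks = object$ks, bmax = object$bmax)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (is.numeric(newdata)) newdata <- data.frame(s = newdata)
  predict(object$nls, newdata = newdata)
}

#' @export
residuals.binding_fit <- function(object, ...) {
  as.numeric(residuals(object$nls))
}

#' @export
plot.binding_fit <- function(x, ...) {
  plot(x$data$s, x$data$da, xlab = "[S] (uM)", ylab = "delta A (AU)",
       main = sprintf("%s: Ks = %.3g uM", x$enzyme_label, x$ks), ...)
  s <- seq(0, max(x$data$s), length.out = 200)
  lines(s, x$bmax * s / (x$ks + s))
  abline(v = x$ks, h = x$bmax / 2, lty = 3)
  invisible(x)
}

#' Classify a difference spectrum as type I or type II
#'
#' A type I spectrum (substrate displacing the axial water, low-to-high
#' spin shift) has its global maximum in 385-400 nm and minimum in
#' 415-425 nm; a type II spectrum (nitrogen ligation to the iron) has the
#' maximum in 425-440 nm and the minimum in 390-410 nm. Anything else,
#' including a flat spectrum, is \code{"indeterminate"}.
#'
#' @param wavelengths ascending wavelengths in nm (within 350-500, at
#'   least 20 points).
#' @param delta_absorbance absorbance differences (AU), same length.
#' @param noise_floor minimum max-minus-min amplitude (AU) below which the
#'   spectrum is considered flat.
#' @return List with \code{type} (\code{"type I"}, \code{"type II"} or
#'   \code{"indeterminate"}), \code{lambda_max} and \code{lambda_min} (nm),
#'   and \code{amplitude} (AU).
#' @export
classify_difference_spectrum <- function(wavelengths, delta_absorbance,
                                         noise_floor = 1e-4) {
  if (length(wavelengths) != length(delta_absorbance)) {
    stop_input("wavelengths and delta_absorbance must have equal length")
  }
  if (length(wavelengths) < 20) {
    stop_input("at least 20 spectral points are required")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop_input("wavelengths must be strictly ascending")
  }
  lam_max <- wavelengths[which.max(delta_absorbance)]
  lam_min <- wavelengths[which.min(delta_absorbance)]
  amp <- max(delta_absorbance) - min(delta_absorbance)
  type <- if (amp < noise_floor) {
    "indeterminate"
  } else if (lam_max >= 385 && lam_max <= 400 &&
             lam_min >= 415 && lam_min <= 425) {
    "type I"
  } else if (lam_max >= 425 && lam_max <= 440 &&
             lam_min >= 390 && lam_min <= 410) {
    "type II"
  } else {
    "indeterminate"
  }
  list(type = type, lambda_max = lam_max, lambda_min = lam_min,
       amplitude = amp)
}
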