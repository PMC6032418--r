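# Inversion-recovery T1 estimation.
#
# The observable is the peak height H of one proton resonance as a function
# of the recovery delay d2 in a d1-180-d2-90 sequence. Real 180-degree
# pulses are imperfect, so the model carries an inversion-efficiency factor
# B in (0.4, 1.1]:
#
#   H(d2) = Hinf * (1 - 2 * B * exp(-d2 / T1))
#
# B = 1 is a perfect inversion (H(0) = -Hinf); B = 0.5 is saturation.

#' Fit an inversion-recovery series to estimate T1
#'
#' Estimates the longitudinal relaxation time T1 of one proton by bounded
#' nonlinear least squares on the three-parameter recovery model
#' \code{H(d2) = Hinf * (1 - 2 * B * exp(-d2 / T1))}, where \code{B} is the
#' inversion-efficiency factor (bounded to (0.4, 1.1]) absorbing imperfect
#' 180-degree pulses. The standard error of T1 comes from the fit
#' covariance.
#'
#' Starting values are \code{Hinf = max(heights)}, \code{B = 1}, and
#' \code{T1 = t0 / log(2)} where \code{t0} is the delay at which the heights
#' change sign (the null point of an ideal recovery), falling back to the
#' median delay when no sign change is present. On non-convergence the fit
#' is restarted up to five times with the T1 start scaled by 0.3, 0.5, 2, 3
#' and 5 before failing.
#'
#' @param delays numeric vector of recovery delays d2 in seconds (>= 0);
#'   at least 4 distinct values.
#' @param heights numeric vector of signal peak heights (arbitrary units),
#'   same length as \code{delays}.
#' @param proton_label label of the resonance, carried into the result.
#' @param enzyme_state one of \code{"ferric"}, \code{"ferrous_CO"},
#'   \code{"free_ligand"}.
#' @param temperature sample temperature in kelvin (metadata only).
#'
#' @return An object of class \code{"t1_fit"}: a list with \code{t1} and
#'   \code{se} (seconds), the full coefficient table, \code{rss},
#'   \code{n_points}, and the input series. Supports \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{residuals} and
#'   \code{plot}.
#'
#' @examples
#' d <- seq(0, 15, length.out = 10)
#' h <- 100 * (1 - 2 * exp(-d / 1.54))
#' fit <- fit_inversion_recovery(d, h, proton_label = "-OCH2-")
#' coef(fit)
#' @export
fit_inversion_recovery <- function(delays, heights, proton_label = "proton",
                                   enzyme_state = c("ferric", "ferrous_CO",
                                                    "free_ligand"),
                                   temperature = 298) {
  enzyme_state <- match.arg(enzyme_state)
  if (length(delays) != length(heights)) {
    stop_input("delays and heights must have equal length")
  }
  if (any(!is.finite(delays)) || any(delays < 0)) {
    stop_input("delays must be finite and non-negative")
  }
  if (length(unique(delays)) < 4) {
    stop_input("proton '", proton_label,
               "': at least 4 distinct recovery delays are required")
  }

  h_inf0 <- max(heights)
  if (h_inf0 <= 0) h_inf0 <- max(abs(heights))
  # null point of the ideal recovery: H = 0 at d2 = T1 * ln 2
  sgn <- sign(heights)
  flip <- which(sgn[-1] != sgn[-length(sgn)] & sgn[-1] != 0)
  t0 <- if (length(flip)) delays[order(delays)][flip[1] + 1] else median(delays)
  t1_0 <- max(t0 / log(2), .Machine$double.eps * 100)

  dat <- data.frame(d2 = delays, h = heights)
  lower <- c(h_inf = -Inf, b = 0.4 + 1e-8, t1 = 1e-8)
  upper <- c(h_inf = Inf, b = 1.1, t1 = Inf)

  fit <- NULL
  for (scale in c(1, 0.3, 0.5, 2, 3, 5)) {
    start <- list(h_inf = h_inf0, b = 1, t1 = t1_0 * scale)
    fit <- tryCatch(
      minpack.lm::nlsLM(h ~ h_inf * (1 - 2 * b * exp(-d2 / t1)),
                        data = dat, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && coef(fit)[["t1"]] > 0) break
    fit <- NULL
  }
  if (is.null(fit)) {
    stop_fit("inversion-recovery fit failed to converge for proton '",
             proton_label, "' after restarts")
  }

  cf <- summary(fit)$coefficients
  structure(list(
    proton_label = proton_label,
    enzyme_state = enzyme_state,
    temperature = temperature,
    t1 = unname(cf["t1", "Estimate"]),
    se = unname(cf["t1", "Std. Error"]),
    coefficients = cf,
    rss = sum(residuals(fit)^2),
    n_points = nrow(dat),
    nls = fit,
    data = dat
  ), class = "t1_fit")
}

#' @export
print.t1_fit <- function(x, ...) {
  cat(sprintf("Inversion-recovery T1 fit: %s (%s)\n",
              x$proton_label, x$enzyme_state))
  cat(sprintf("  T1 = %.4g +/- %.2g s  (n = %d, RSS = %.3g)\n",
              x$t1, x$se, x$n_points, x$rss))
  invisible(x)
}

#' @export
summary.t1_fit <- function(object, ...) {
  print(object)
  cat("\nCoefficients:\n")
  print(object$coefficients)
  invisible(object)
}

#' @export
coef.t1_fit <- function(object, ...) {
  setNames(object$coefficients[, "Estimate"],
           rownames(object$coefficients))
}

#' @export
predict.t1_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  if (is.numeric(newdata)) newdata <- data.frame(d2 = newdata)
  predict(object$nls, newdata = newdata)
}

#' @export
residuals.t1_fit <- function(object, ...) {
  as.numeric(residuals(object$nls))
}

#' @export
plot.t1_fit <- function(x, ...) {
  plot(x$data$d2, x$data$h, xlab = "recovery delay d2 (s)",
       ylab = "peak height (a.u.)",
       main = sprintf("%s (%s): T1 = %.3g s", x$proton_label,
                      x$enzyme_state, x$t1), ...)
  d <- seq(min(x$data$d2), max(x$data$d2), length.out = 200)
  lines(d, predict(x, d))
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Pair ferric and ferrous-CO T1 estimates by proton label
#'
#' Assembles per-proton pairs of T1 in the paramagnetic ferric state and
#' the diamagnetic ferrous-CO reference state, the input to the
#' paramagnetic relaxation time \code{\link{t1p_from_pair}}. Labels present
#' in only one state are reported as unpaired, not silently dropped.
#'
#' @param ferric,ferrous_co lists of \code{"t1_fit"} objects (or data
#'   frames with columns \code{proton_label}, \code{t1}, \code{se}).
#' @return A list with \code{pairs} (data frame: \code{proton_label},
#'   \code{t1_ferric}, \code{se_ferric}, \code{t1_ferrous_co},
#'   \code{se_ferrous_co}) and \code{unpaired} (character vector of labels
#'   found in only one state).
#' @export
pair_states <- function(ferric, ferrous_co) {
  as_tab <- function(x, which) {
    if (is.data.frame(x)) return(x)
    if (!length(x)) return(data.frame(proton_label = character(),
                                      t1 = numeric(), se = numeric()))
    do.call(rbind, lapply(x, function(f) {
      data.frame(proton_label = f$proton_label, t1 = f$t1, se = f$se,
                 stringsAsFactors = FALSE)
    }))
  }
  fe3 <- as_tab(ferric)
  fe2 <- as_tab(ferrous_co)
  shared <- intersect(fe3$proton_label, fe2$proton_label)
  if (!length(shared)) {
    stop_input("no proton labels shared between ferric and ferrous-CO sets")
  }
  i3 <- match(shared, fe3$proton_label)
  i2 <- match(shared, fe2$proton_label)
  pairs <- data.frame(
    proton_label = shared,
    t1_ferric = fe3$t1[i3], se_ferric = fe3$se[i3],
    t1_ferrous_co = fe2$t1[i2], se_ferrous_co = fe2$se[i2],
    stringsAsFactors = FALSE)
  unpaired <- c(setdiff(fe3$proton_label, shared),
                setdiff(fe2$proton_label, shared))
  list(pairs = pairs, unpaired = unpaired)
}

#' Read inversion-recovery series from a long-format CSV
#'
#' Expects columns \code{proton_label}, \code{enzyme_state},
#' \code{temperature_K}, \code{delay_s}, \code{peak_height}, one row per
#' acquired point. Returns one list entry per (proton, state) combination.
#'
#' @param path CSV file path.
#' @return Named list of lists with fields \code{delays}, \code{heights},
#'   \code{proton_label}, \code{enzyme_state}, \code{temperature}, suitable
#'   for \code{do.call(fit_inversion_recovery, .)}.
#' @export
read_inversion_recovery_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("proton_label", "enzyme_state", "temperature_K",
            "delay_s", "peak_height")
  if (!all(need %in% names(df))) {
    stop_input("CSV must have columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(df$proton_label, df$enzyme_state, drop = TRUE)
  lapply(split(df, key), function(g) {
    list(delays = g$delay_s, heights = g$peak_height,
         proton_label = g$proton_label[1],
         enzyme_state = g$enzyme_state[1],
         temperature = g$temperature_K[1])
  })
}

#' Tabulate T1 fits
#'
#' @param fits list of \code{"t1_fit"} objects.
#' @return Data frame with \code{proton_label}, \code{enzyme_state},
#'   \code{t1_s}, \code{se_s}, \code{rss}, \code{n_points}.
#' @export
t1_fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(proton_label = f$proton_label, enzyme_state = f$enzyme_state,
               t1_s = f$t1, se_s = f$se, rss = f$rss, n_points = f$n_points,
               stringsAsFactors = FALSE)
  }))
}
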