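# Synthetic-data generators. Every input modality of the workflow can be
# generated with known ground truth, so the full chain is testable
# end-to-end without external data. Noise is additive i.i.d. Gaussian
# throughout; each generator is deterministic given its seed and carries
# its generating parameters in a ground_truth field.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

#' Simulate an inversion-recovery series
#'
#' Heights follow \code{h_inf * (1 - 2 * b * exp(-d / t1))} plus additive
#' Gaussian noise of standard deviation \code{noise_sd} (same units as
#' the heights).
#'
#' @param t1 generating relaxation time (seconds, > 0).
#' @param h_inf equilibrium height (arbitrary units).
#' @param b inversion-efficiency factor.
#' @param delays recovery delays (seconds); default 12 points spanning
#'   0 to 5 * t1.
#' @param noise_sd additive noise SD (height units).
#' @param seed RNG seed (NULL leaves the RNG state alone).
#' @param proton_label,enzyme_state,temperature series metadata.
#' @return List with \code{delays}, \code{heights}, the metadata fields,
#'   and \code{ground_truth} (t1, h_inf, b, noise_sd).
#' @export
sim_inversion_recovery <- function(t1, h_inf = 100, b = 1,
                                   delays = seq(0, 5 * t1,
                                                length.out = 12),
                                   noise_sd = 0, seed = NULL,
                                   proton_label = "sim",
                                   enzyme_state = "ferric",
                                   temperature = 298) {
  check_positive(t1, "t1")
  if (!length(delays)) stop_input("delays must be non-empty")
  clean <- h_inf * (1 - 2 * b * exp(-delays / t1))
  heights <- with_seed(seed, clean + rnorm(length(delays), 0, noise_sd))
  list(delays = delays, heights = heights, proton_label = proton_label,
       enzyme_state = enzyme_state, temperature = temperature,
       ground_truth = list(t1 = t1, h_inf = h_inf, b = b,
                           noise_sd = noise_sd))
}

#' Simulate a one-site binding isotherm
#'
#' \code{dA = bmax * s / (ks + s)} plus additive Gaussian noise.
#'
#' @param ks,bmax generating parameters (> 0).
#' @param concentrations substrate concentrations (uM, ascending).
#' @param noise_sd additive noise SD (AU).
#' @param seed RNG seed.
#' @return List with \code{substrate_conc}, \code{delta_A} and
#'   \code{ground_truth}.
#' @export
sim_isotherm <- function(ks, bmax,
                         concentrations = c(1, 3, 10, 30, 60, 120, 200),
                         noise_sd = 0, seed = NULL) {
  check_positive(ks, "ks")
  check_positive(bmax, "bmax")
  clean <- bmax * concentrations / (ks + concentrations)
  da <- with_seed(seed, clean + rnorm(length(concentrations), 0, noise_sd))
  list(substrate_conc = concentrations, delta_A = da,
       ground_truth = list(ks = ks, bmax = bmax, noise_sd = noise_sd))
}

#' Simulate a Soret-region absorbance spectrum
#'
#' Sum of three Gaussian bands — low spin, high spin and the broad delta
#' band — with the high- and low-spin areas in ratio
#' \code{f_high : (1 - f_high)}, plus additive Gaussian noise.
#'
#' @param f_high generating high-spin fraction in [0, 1].
#' @param total_area summed area of the two Soret bands (AU * nm).
#' @param centers named numeric: band centers (nm) for \code{delta},
#'   \code{high_spin}, \code{low_spin}.
#' @param widths named numeric: Gaussian SD widths (nm).
#' @param delta_area area of the delta band (AU * nm).
#' @param wavelengths sampling grid (nm).
#' @param noise_sd additive noise SD (AU).
#' @param seed RNG seed.
#' @return List with \code{wavelengths}, \code{absorbance} and
#'   \code{ground_truth}.
#' @export
sim_soret_spectrum <- function(f_high, total_area = 100,
                               centers = c(delta = 360, high_spin = 392,
                                           low_spin = 417),
                               widths = c(delta = 18, high_spin = 14,
                                          low_spin = 12),
                               delta_area = 0.3 * total_area,
                               wavelengths = seq(320, 500, by = 1),
                               noise_sd = 0, seed = NULL) {
  if (f_high < 0 || f_high > 1) stop_input("f_high must lie in [0, 1]")
  check_positive(total_area, "total_area")
  gauss <- function(area, center, width) {
    amp <- area / (width * sqrt(2 * pi))
    amp * exp(-(wavelengths - center)^2 / (2 * width^2))
  }
  clean <- gauss(delta_area, centers[["delta"]], widths[["delta"]]) +
    gauss(total_area * f_high, centers[["high_spin"]],
          widths[["high_spin"]]) +
    gauss(total_area * (1 - f_high), centers[["low_spin"]],
          widths[["low_spin"]])
  a <- with_seed(seed, clean + rnorm(length(wavelengths), 0, noise_sd))
  list(wavelengths = wavelengths, absorbance = a,
       ground_truth = list(f_high = f_high, total_area = total_area,
                           centers = centers, widths = widths,
                           delta_area = delta_area, noise_sd = noise_sd))
}

#' Simulate an enzyme study from target distances
#'
#' Inverts the distance chain: for each target distance r the implied
#' paramagnetic relaxation time is
#' \code{T1P = r^6 / (9.78e16 * alpha_m * S(S+1) * tau_c)}; a diamagnetic
#' T1 (ferrous-CO) is drawn uniformly from \code{t1_dia_range} and the
#' ferric T1 set to \code{1/(1/T1P + 1/T1_dia)}. Multiplicative Gaussian
#' noise of relative standard deviation \code{noise_sd} is then applied
#' to both T1 values, emulating fitting scatter.
#'
#' @param target_r named numeric vector of target distances (Angstroms),
#'   names are proton labels.
#' @param p450_uM,substrate_uM,ks_uM,f_high,tau_c_s study parameters.
#' @param t1_dia_range range (seconds) for the diamagnetic T1 draw.
#' @param noise_sd relative noise on the T1 values (e.g. 0.01 for 1%).
#' @param seed RNG seed.
#' @param enzyme_label label for the generated study.
#' @return An \code{"enzyme_study"} with an extra \code{ground_truth}
#'   field (the targets and noise-free T1 pairs).
#' @examples
#' st <- sim_study_from_distances(c("-OCH2-" = 6.55, "H2,6" = 6.76),
#'                                p450_uM = 0.017, substrate_uM = 171,
#'                                ks_uM = 17.1, f_high = 0.27,
#'                                tau_c_s = 3.38e-10, seed = 1)
#' run_study(st)$tables[[1]]$r_A  # recovers the targets (zero noise)
#' @export
sim_study_from_distances <- function(target_r, p450_uM, substrate_uM,
                                     ks_uM, f_high, tau_c_s,
                                     t1_dia_range = c(1, 5),
                                     noise_sd = 0, seed = NULL,
                                     enzyme_label = "simulated") {
  check_positive(target_r, "target_r")
  if (is.null(names(target_r))) {
    names(target_r) <- paste0("H", seq_along(target_r))
  }
  am <- alpha_m(p450_uM, substrate_uM, ks_uM)
  ss1 <- spin_factor(f_high)
  t1p <- target_r^6 / (.sb_constant * am * ss1 * tau_c_s)
  study <- with_seed(seed, {
    t1_dia <- runif(length(target_r), t1_dia_range[1], t1_dia_range[2])
    t1_fe3 <- 1 / (1 / t1p + 1 / t1_dia)
    noisy_fe3 <- t1_fe3 * (1 + rnorm(length(t1_fe3), 0, noise_sd))
    noisy_dia <- t1_dia * (1 + rnorm(length(t1_dia), 0, noise_sd))
    pairs <- data.frame(
      proton_label = names(target_r),
      t1_ferric = noisy_fe3, se_ferric = noise_sd * t1_fe3,
      t1_ferrous_co = noisy_dia, se_ferrous_co = noise_sd * t1_dia,
      stringsAsFactors = FALSE)
    st <- enzyme_study(enzyme_label, p450_uM, substrate_uM, ks_uM,
                       f_high = f_high, tau_c_s = tau_c_s,
                       t1_pairs = pairs)
    st$ground_truth <- list(target_r = target_r, t1p = t1p,
                            t1_ferric = t1_fe3, t1_ferrous_co = t1_dia,
                            noise_sd = noise_sd)
    st
  })
  study
}
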