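test_that("noiseless inversion recovery returns the generating T1 exactly", {
  d <- seq(0, 15, length.out = 10)
  h <- 100 * (1 - 2 * exp(-d / 1.54))
  fit <- fit_inversion_recovery(d, h, proton_label = "-OCH2-")
  expect_s3_class(fit, "t1_fit")
  expect_lt(abs(fit$t1 - 1.54) / 1.54, 1e-6)
  expect_lt(fit$rss, 1e-10)
  expect_equal(fit$n_points, 10)
  expect_gte(fit$se, 0)
  expect_named(coef(fit), c("h_inf", "b", "t1"))
})

test_that("fit recovers T1 across the parameter space (noiseless)", {
  for (h_inf in c(20, 100)) {
    for (b in c(0.5, 0.75, 1)) {
      for (t1 in c(0.1, 1.3, 7, 50)) {
        d <- seq(0, 5 * t1, length.out = 8)
        h <- h_inf * (1 - 2 * b * exp(-d / t1))
        fit <- fit_inversion_recovery(d, h)
        expect_lt(abs(fit$t1 - t1) / t1, 1e-4,
                  label = sprintf("rel err at h_inf=%g b=%g t1=%g",
                                  h_inf, b, t1))
      }
    }
  }
})

test_that("fitted T1 is invariant to a common height rescaling", {
  d <- seq(0, 8, length.out = 12)
  h <- 50 * (1 - 2 * 0.9 * exp(-d / 2.2))
  f1 <- fit_inversion_recovery(d, h)
  f2 <- fit_inversion_recovery(d, 7.3 * h)
  expect_equal(f1$t1, f2$t1, tolerance = 1e-8)
})

test_that("invalid series are rejected with input errors", {
  expect_error(fit_inversion_recovery(c(0, 1, 2), c(-1, 0, 1)),
               class = "predist_input_error")
  expect_error(fit_inversion_recovery(c(0, 1, 1, 0), c(-1, 0, 0, -1)),
               "distinct")
  expect_error(fit_inversion_recovery(c(0, 1, 2, 3), c(1, 2, 3)),
               "equal length")
  expect_error(fit_inversion_recovery(c(-1, 1, 2, 3), c(1, 2, 3, 4)),
               "non-negative")
})

test_that("noisy series recover T1 within 3 standard errors", {
  s <- sim_inversion_recovery(t1 = 1.54, h_inf = 100, b = 1,
                              delays = seq(0, 15, length.out = 10),
                              noise_sd = 1, seed = 42)
  fit <- fit_inversion_recovery(s$delays, s$heights)
  expect_lt(abs(fit$t1 - 1.54), 3 * fit$se)
})

test_that("pair_states joins on labels and reports unpaired protons", {
  mk <- function(lab, t1, state) {
    s <- sim_inversion_recovery(t1, proton_label = lab,
                                enzyme_state = state)
    fit_inversion_recovery(s$delays, s$heights, proton_label = lab,
                           enzyme_state = state)
  }
  fe3 <- list(mk("a", 1.5, "ferric"), mk("b", 2.0, "ferric"))
  fe2 <- list(mk("b", 2.5, "ferrous_CO"), mk("c", 3.0, "ferrous_CO"))
  out <- pair_states(fe3, fe2)
  expect_equal(nrow(out$pairs), 1)
  expect_equal(out$pairs$proton_label, "b")
  expect_setequal(out$unpaired, c("a", "c"))
  expect_lt(out$pairs$t1_ferric, out$pairs$t1_ferrous_co)

  both <- pair_states(c(fe3, list(mk("c", 1.2, "ferric"))), fe2)
  expect_equal(nrow(both$pairs), 2)
  expect_error(pair_states(fe3, list()), class = "predist_input_error")
  expect_error(pair_states(list(mk("x", 1, "ferric")), fe2),
               class = "predist_input_error")
})

test_that("long-format CSV round-trips into fits", {
  s1 <- sim_inversion_recovery(1.2, proton_label = "H2,6", seed = 1)
  s2 <- sim_inversion_recovery(2.4, proton_label = "H3,5", seed = 2,
                               enzyme_state = "ferrous_CO")
  df <- rbind(
    data.frame(proton_label = s1$proton_label, enzyme_state = "ferric",
               temperature_K = 298, delay_s = s1$delays,
               peak_height = s1$heights),
    data.frame(proton_label = s2$proton_label, enzyme_state = "ferrous_CO",
               temperature_K = 298, delay_s = s2$delays,
               peak_height = s2$heights))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  series <- read_inversion_recovery_csv(path)
  expect_length(series, 2)
  fits <- lapply(series, function(x) do.call(fit_inversion_recovery, x))
  tab <- t1_fit_table(fits)
  expect_setequal(tab$proton_label, c("H2,6", "H3,5"))
  expect_equal(sort(tab$t1_s), c(1.2, 2.4), tolerance = 1e-4)
})
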