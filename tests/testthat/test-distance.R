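test_that("T1P is the reciprocal rate difference of the state pair", {
  # rate-difference oracle computed by hand:
  # 1/(1/1.54 - 1/1.85) = 9.1903, 1/(1/2.43 - 1/4.10) = 5.9659
  expect_equal(t1p_from_pair(1.54, 1.85)$t1p, 9.1903, tolerance = 1e-4)
  expect_equal(t1p_from_pair(2.43, 4.10)$t1p, 5.9659, tolerance = 1e-4)
  expect_error(t1p_from_pair(2.0, 2.0, proton_label = "-CH3"),
               "-CH3.*no paramagnetic effect")
  expect_error(t1p_from_pair(3.0, 2.0), class = "predist_input_error")
})

test_that("alpha_m is the enzyme over (Ks + substrate) ratio", {
  expect_equal(alpha_m(0.017, 171, 17.1), 9.038e-5, tolerance = 1e-3)
  expect_equal(alpha_m(0.011, 102, 10.2), 9.804e-5, tolerance = 1e-3)
  # vanishing enzyme concentration drives the bound fraction to zero
  expect_lt(alpha_m(1e-12, 100, 10), 1e-13)
  expect_warning(alpha_m(50, 100, 10), "strained")
  expect_error(alpha_m(-1, 100, 10), class = "predist_input_error")
  expect_error(alpha_m(0, 100, 10), class = "predist_input_error")
})

test_that("the sixth-root distance matches the measured benchmark", {
  r <- iron_distance(9.19, 9.038e-5, 2.91, 3.38e-10)
  expect_equal(r, 6.55, tolerance = 0.1 / 6.55)
  # N312L -OCH2- chain from its own occupancy and spin inputs
  t1p <- t1p_from_pair(1.62, 1.69)$t1p
  r2 <- iron_distance(t1p, alpha_m(0.011, 102, 10.2), spin_factor(0.14),
                      3.38e-10)
  expect_equal(r2, 7.84, tolerance = 0.1 / 7.84)
})

test_that("distance scales as the sixth root of every factor", {
  base <- list(t1p = 9.19, am = 9.038e-5, ss1 = 2.91, tau_c = 3.38e-10)
  r0 <- do.call(iron_distance, base)
  expect_equal(iron_distance(64 * base$t1p, base$am, base$ss1, base$tau_c),
               2 * r0, tolerance = 1e-12)
  for (arg in names(base)) {
    scaled <- base
    scaled[[arg]] <- 3 * scaled[[arg]]
    expect_equal(do.call(iron_distance, scaled), 3^(1 / 6) * r0,
                 tolerance = 1e-12, label = paste("scaling in", arg))
  }
  # strictly increasing in each argument
  set.seed(2)
  for (i in 1:25) {
    x <- list(t1p = runif(1, 1, 50), am = runif(1, 1e-5, 1e-3),
              ss1 = runif(1, 0.75, 8.75), tau_c = runif(1, 1e-10, 1e-9))
    for (arg in names(x)) {
      up <- x
      up[[arg]] <- up[[arg]] * 1.1
      expect_gt(do.call(iron_distance, up), do.call(iron_distance, x))
    }
  }
})

test_that("analytic distance error agrees with Monte-Carlo resampling", {
  # pairs whose rate difference is well resolved by the quoted SEs; the
  # first-order propagation is only trustworthy in that regime
  cases <- list(c(2.22, 2.78, 0.11, 0.05),
                c(2.43, 4.10, 0.18, 0.07),
                c(1.98, 2.90, 0.12, 0.09))
  for (cs in cases) {
    t1f <- cs[1]; t1d <- cs[2]; sef <- cs[3]; sed <- cs[4]
    r <- iron_distance(t1p_from_pair(t1f, t1d)$t1p, 9.038e-5, 2.91,
                       3.38e-10)
    se_analytic <- distance_se(t1f, t1d, sef, sed, r)

    set.seed(314)
    n <- 10000
    draws_f <- rnorm(n, t1f, sef)
    draws_d <- rnorm(n, t1d, sed)
    ok <- draws_f > 0 & draws_d > draws_f
    t1p_mc <- 1 / (1 / draws_f[ok] - 1 / draws_d[ok])
    r_mc <- (9.78e16 * t1p_mc * 9.038e-5 * 2.91 * 3.38e-10)^(1 / 6)
    expect_lt(abs(se_analytic - sd(r_mc)) / sd(r_mc), 0.15,
              label = sprintf("analytic vs MC for pair (%g, %g)",
                              t1f, t1d))
  }
})

test_that("distance error propagation is first-order linear in the SEs", {
  r <- 6.55
  s1 <- distance_se(1.54, 1.85, 0.15, 0.18, r)
  s2 <- distance_se(1.54, 1.85, 0.30, 0.36, r)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_equal(distance_se(1.54, 1.85, 0, 0, r), 0)
})

test_that("fast-exchange diagnostic matches a closed-form OLS oracle", {
  temps <- c(283, 298, 310)
  # positive slope of 1/T1P on 1/T, exact line
  inv_t1p <- 0.02 + 25 * (1 / temps)
  chk <- fast_exchange_check(temps, 1 / inv_t1p)
  expect_true(chk$pass)
  expect_equal(chk$r_squared, 1, tolerance = 1e-12)

  oracle <- ols_oracle(1 / temps, inv_t1p)
  expect_equal(chk$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(chk$intercept, oracle$intercept, tolerance = 1e-10)

  # negative slope fails regardless of linearity
  neg <- fast_exchange_check(temps, 1 / (0.2 - 30 * (1 / temps)))
  expect_false(neg$pass)
  expect_lt(neg$slope, 0)

  # positive slope but scatter pushing R^2 below the threshold
  set.seed(8)
  temps6 <- c(278, 283, 290, 298, 304, 310)
  y <- 0.02 + 25 * (1 / temps6) + rnorm(6, 0, 2e-3)
  noisy <- fast_exchange_check(temps6, 1 / y)
  oracle6 <- ols_oracle(1 / temps6, y)
  expect_equal(noisy$slope, oracle6$slope, tolerance = 1e-10)
  expect_equal(noisy$r_squared, oracle6$r_squared, tolerance = 1e-10)
  expect_gt(noisy$slope, 0)
  expect_lt(noisy$r_squared, 0.95)
  expect_false(noisy$pass)

  expect_error(fast_exchange_check(c(283, 298), c(1, 2)),
               "at least 3")
})
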