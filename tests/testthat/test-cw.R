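# Freely dissolved concentration estimation and the linear-uptake ratio.

test_that("cw_from_uptake matches the hand-evaluated full model", {
  # 10 ng, logKsw 4.5, m = 30 g, Rs = 1 L/d, t = 91 d
  est <- cw_from_uptake(10, sampling_rate = 1, duration = 91,
                        log_ksw = 4.5, sampler_mass = 0.030)
  oracle <- 10 / (10^4.5 * 0.030 * (1 - exp(-1 * 91 / (10^4.5 * 0.030))))
  expect_equal(est$c_w, oracle, tolerance = 1e-12)
  expect_equal(est$c_w, 0.1152, tolerance = 1e-3)
  expect_equal(est$regime, "transitional")
})

test_that("the full model reduces to its linear and equilibrium limits", {
  # linear limit: deq < 0.002 -> Cw ~ n/(Rs t) within 0.1%
  lin <- cw_from_uptake(5, sampling_rate = 0.01, duration = 50,
                        log_ksw = 4.5, sampler_mass = 0.030)
  expect_lt(lin$deq, 0.002)
  expect_equal(lin$c_w, 5 / (0.01 * 50), tolerance = 1e-3)
  expect_equal(lin$regime, "linear")

  # equilibrium limit: deq > 0.999 -> Cw ~ n/(Ksw m) within 0.1%
  eq <- cw_from_uptake(5, sampling_rate = 80, duration = 91,
                       log_ksw = 3.0, sampler_mass = 0.030)
  expect_gt(eq$deq, 0.999)
  expect_equal(eq$c_w, 5 / (10^3 * 0.030), tolerance = 1e-3)
  expect_equal(eq$regime, "near_equilibrium")

  # vanishing exponent handled by the series limit, no 0/0
  tiny <- cw_from_uptake(5, sampling_rate = 1e-12, duration = 1,
                         log_ksw = 5, sampler_mass = 0.030)
  expect_equal(tiny$c_w, 5 / 1e-12, tolerance = 1e-6)
})

test_that("cw_from_uptake is linear in the accumulated mass", {
  base <- cw_from_uptake(2, 5, 91, 4.5, 0.030)
  scaled <- cw_from_uptake(2 * 7, 5, 91, 4.5, 0.030)
  expect_equal(scaled$c_w, 7 * base$c_w, tolerance = 1e-12)
})

test_that("degree of equilibrium reproduces the winter-end value and identities", {
  expect_equal(degree_of_equilibrium(1, 91, 4.5, 0.030), 0.0915,
               tolerance = 1e-3)
  expect_lt(degree_of_equilibrium(1, 91, 4.5, 0.030), 0.1)
  expect_equal(degree_of_equilibrium(1, 0, 4.5, 0.030), 0)
  # Rs t / (Ksw m) = ln 2 -> DEQ = 1/2
  ksw_m <- 10^4.5 * 0.030
  expect_equal(degree_of_equilibrium(log(2) * ksw_m / 91, 91, 4.5, 0.030),
               0.5, tolerance = 1e-12)
  # monotone in Rs and t
  expect_true(all(diff(degree_of_equilibrium(c(1, 5, 20, 50), 91, 4.5,
                                             0.030)) > 0))
})

test_that("censored uptakes propagate as flags, not zeros", {
  est <- cw_from_uptake(c(10, 0.001), sampling_rate = 1, duration = 91,
                        log_ksw = 4.5, sampler_mass = 0.030,
                        below_loq = c(FALSE, TRUE))
  expect_false(est$censored[1])
  expect_true(est$censored[2])
  expect_true(is.na(est$c_w[2]))
})

test_that("linear_ratio corrects by the Ksw exponent factor", {
  # logKsw difference of 1 -> corrected/raw differ by 10^0.08
  rs_a <- sampling_rate(100, 5.0)
  rs_b <- sampling_rate(100, 4.0)
  lr <- linear_ratio(10, 5, rs_a, rs_b, deq_a = 0.01, deq_b = 0.01)
  expect_equal(lr$raw_ratio, 2)
  expect_equal(lr$discrepancy, 10^0.08, tolerance = 1e-12)
  # identical compounds: corrected == raw
  same <- linear_ratio(10, 5, rs_a, rs_a, deq_a = 0.01, deq_b = 0.01)
  expect_equal(same$corrected_ratio, same$raw_ratio)
  expect_error(linear_ratio(10, 0, 1, 1), "positive")
  expect_warning(linear_ratio(10, 5, rs_a, rs_b, deq_a = 0.5, deq_b = 0.01),
                 "linear")
})

test_that("linear uptake pair round-trips the true Cw ratio", {
  cw_a <- 0.4; cw_b <- 0.1
  beta <- 3
  lka <- 5.0; lkb <- 4.5
  t <- 30; m <- 0.030
  rs_a <- sampling_rate(beta, lka); rs_b <- sampling_rate(beta, lkb)
  # masses generated by the linear model invert exactly
  lr_lin <- linear_ratio(cw_a * rs_a * t, cw_b * rs_b * t, rs_a, rs_b)
  expect_equal(lr_lin$corrected_ratio, cw_a / cw_b, tolerance = 1e-6)
  # masses from the full model deviate only by the residual curvature
  n_a <- cw_a * 10^lka * m * (1 - exp(-rs_a * t / (10^lka * m)))
  n_b <- cw_b * 10^lkb * m * (1 - exp(-rs_b * t / (10^lkb * m)))
  expect_lt(degree_of_equilibrium(rs_a, t, lka, m), 0.05)
  lr <- linear_ratio(n_a, n_b, rs_a, rs_b)
  expect_equal(lr$corrected_ratio, cw_a / cw_b, tolerance = 2e-2)
})

test_that("estimate_cw round-trips a noise-free scenario to 1e-6", {
  sc <- generate_scenario(scenario_config(seed = 5, n_sites = 10,
                                          cv_noise = 0, measurement_cv = 0))
  fits <- fit_beta_by_deployment(sc$prc_observations, sc$deployments)
  cw <- estimate_cw(sc$uptakes, sc$deployments, fits)
  joined <- dplyr::inner_join(
    cw, sc$truth, by = c("deployment_id", "site_id", "compound")
  )
  expect_equal(nrow(joined), nrow(sc$uptakes))
  expect_true(all(abs(joined$c_w / joined$cw_true - 1) < 1e-6))
})

test_that("Cw re-estimation is unbiased under multiplicative measurement noise", {
  set.seed(99)
  reps <- 40
  rel <- replicate(reps, {
    seed <- sample.int(1e6, 1)
    sc <- generate_scenario(scenario_config(seed = seed, n_sites = 6,
                                            cv_noise = 0,
                                            measurement_cv = 0.115))
    fits <- fit_beta_by_deployment(sc$prc_observations, sc$deployments)
    cw <- estimate_cw(sc$uptakes, sc$deployments, fits)
    joined <- dplyr::inner_join(cw, sc$truth,
                                by = c("deployment_id", "site_id",
                                       "compound"))
    mean(joined$c_w / joined$cw_true, na.rm = TRUE)
  })
  expect_equal(mean(rel), 1.0, tolerance = 0.03)
})
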