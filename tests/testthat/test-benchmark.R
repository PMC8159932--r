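# Ratio screening, outlier limits, regression and benchmarking.

test_that("paired ratios drop pairs with a censored member and count them", {
  tab <- make_cw_table(c(4.1, 3.8, 4.4))
  tab$censored[tab$deployment_id == "d02" & tab$compound == "PeCB"] <- TRUE
  r <- paired_ratios(tab)
  expect_equal(nrow(r), 2L)
  expect_equal(attr(r, "n_dropped"), 1L)
  expect_equal(r$ratio, c(4.1, 4.4))
  expect_warning(paired_ratios(make_cw_table(numeric(0))), "no complete")
})

test_that("IQR limits with inversion match the brute-force 5-element oracle", {
  lim <- iqr_outlier_limits(c(2, 3, 4, 5, 6))
  expect_equal(lim$upper, 8)                 # 5 + 1.5 * 2
  # inverted set {1/2..1/6}: Q3' = 1/3, IQR' = 1/3 - 1/5
  expect_equal(lim$lower, 1 / (1 / 3 + 1.5 * (1 / 3 - 1 / 5)),
               tolerance = 1e-12)
  expect_equal(lim$method, "iqr_inversion")
  expect_false(lim$degenerate)
})

test_that("IQR limits handle degeneracy and are scale-equivariant", {
  deg <- iqr_outlier_limits(rep(4.59, 10))
  expect_true(deg$degenerate)
  expect_equal(deg$lower, 4.59)
  expect_equal(deg$upper, 4.59)

  set.seed(7)
  for (i in 1:5) {
    x <- stats::rlnorm(25, log(4.59), 0.3)
    c0 <- stats::runif(1, 0.1, 10)
    lim1 <- iqr_outlier_limits(x)
    lim2 <- iqr_outlier_limits(c0 * x)
    expect_equal(lim2$lower, c0 * lim1$lower, tolerance = 1e-12)
    expect_equal(lim2$upper, c0 * lim1$upper, tolerance = 1e-12)
  }
  expect_error(iqr_outlier_limits(c(1, 2, 3)), "at least 4")
  expect_error(iqr_outlier_limits(c(-1, 2, 3, 4)), "positive")
})

test_that("IQR limits bracket the bulk of a background ratio distribution", {
  # closed-form oracle for lognormal(sdlog = 0.3): upper limit at
  # z = (log(Q3 + 1.5 IQR) - mu)/0.3 = 2.025 on each side, so the band
  # holds 1 - 2 * pnorm(-2.025) = 95.7% of the mass
  set.seed(123)
  x <- stats::rlnorm(1e4, log(4.59), 0.3)
  lim <- iqr_outlier_limits(x)
  inside <- mean(x > lim$lower & x < lim$upper)
  expect_equal(inside, 1 - 2 * stats::pnorm(-2.025), tolerance = 0.01)
  expect_lt(lim$lower, 4.59)
  expect_gt(lim$upper, 4.59)
  # for a (near-)normal ratio sample the upper tail beyond Q3 + 1.5 IQR is
  # 0.35%; the inversion-based lower limit is tighter than the symmetric
  # rule, so overall coverage settles near 98%
  y <- stats::rnorm(1e4, 4.59, 0.5)
  limy <- iqr_outlier_limits(y)
  expect_lt(mean(y > limy$upper), 0.01)
  expect_gt(mean(y > limy$lower & y < limy$upper), 0.97)
})

test_that("air limits scale to water by the 15-degree Henry ratio", {
  air <- fixed_limits(2.4, 7.9)
  water <- scale_air_limits_to_water(air, 288.15)
  expect_equal(water$upper, 7.0, tolerance = 0.005)     # 7.03 before rounding
  expect_equal(water$lower, 2.4 * 0.8901669, tolerance = 1e-6)
  expect_equal(water$provenance$henry_ratio,
               henry_ratio("PeCB", "HCB", 288.15))
  # equal Henry constants leave limits untouched
  same <- scale_air_limits_to_water(air, 288.15, "HCB", "HCB")
  expect_equal(same$lower, air$lower)
  expect_equal(same$upper, air$upper)
})

test_that("normal-band limits recover sigma and collapse at k = 0", {
  set.seed(11)
  x <- stats::rnorm(1e5, 2.76, 0.11)
  lim <- normal_band_limits(x)
  expect_equal(lim$provenance$sigma, 0.11, tolerance = 0.02)
  expect_equal(lim$lower, 2.76 - 3 * 0.11, tolerance = 0.02)
  expect_equal(lim$upper, 2.76 + 3 * 0.11, tolerance = 0.02)

  lim0 <- normal_band_limits(x, k = 0)
  expect_equal(lim0$lower, lim0$upper)
  expect_equal(lim0$lower, stats::median(x))

  # symmetric input gives limits symmetric about the median
  xs <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  ls <- normal_band_limits(xs, k = 2)
  expect_equal(ls$upper - stats::median(xs), stats::median(xs) - ls$lower)
})

test_that("classification partitions records against the freshwater band", {
  lim <- default_ratio_limits("freshwater")
  expect_equal(classify_site(9.5, lim), "hcb_elevated")   # Pechenga-like
  expect_equal(classify_site(4.1, lim), "background")
  expect_equal(classify_site(1.0, lim), "pecb_elevated")  # Danube-drop-like
  expect_equal(classify_site(4.1, lim, censored = TRUE), "indeterminate")
  cls <- classify_site(c(0.5, 3, 10, NA), lim)
  expect_false(any(cls == "hcb_elevated" & cls == "pecb_elevated"))
  expect_setequal(unique(cls),
                  c("pecb_elevated", "background", "hcb_elevated",
                    "indeterminate"))
})

test_that("screen_ratios picks per-matrix default limits", {
  recs <- tibble::tibble(
    site_id = c("f", "m"), deployment_id = c("d1", "d2"),
    matrix = c("freshwater", "marine"), ratio = c(3.5, 3.5)
  )
  out <- screen_ratios(recs)
  # 3.5 is background in freshwater but above the tight marine band
  expect_equal(out$classification, c("background", "hcb_elevated"))
})

test_that("through-origin regression is exact on proportional data", {
  x <- c(1, 2, 3, 5)
  # exact data makes summary.lm warn about a perfect fit; that is the point
  fit <- suppressWarnings(regression_through_origin(x, 4 * x))
  expect_equal(fit$slope, 4)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$se, 0, tolerance = 1e-12)
  fit2 <- suppressWarnings(
    regression_through_origin(c(1, 2, 3), c(2.76, 5.52, 8.28))
  )
  expect_equal(fit2$slope, 2.76, tolerance = 1e-12)
  expect_error(regression_through_origin(1:2, 1:2), "at least 3")
  # free-intercept variant
  fit3 <- suppressWarnings(
    regression_through_origin(x, 4 * x + 1, intercept = TRUE)
  )
  expect_equal(fit3$slope, 4, tolerance = 1e-12)
  expect_equal(fit3$intercept, 1, tolerance = 1e-12)
})

test_that("through-origin slope matches the closed form on noisy data", {
  set.seed(21)
  x <- stats::rlnorm(30, log(0.1), 0.5)
  y <- 4.1 * x * stats::rlnorm(30, 0, 0.2)
  fit <- regression_through_origin(x, y)
  expect_equal(fit$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
})

test_that("benchmarking ranks the injected site first with the right span", {
  inj <- tibble::tibble(site_id = "site_03", compound = "CB28", fold = 80)
  sc <- generate_scenario(scenario_config(seed = 17, n_sites = 12,
                                          injections = inj))
  res <- run_pipeline(sc)
  cb28_hcb <- res$benchmarks |>
    dplyr::filter(target == "CB28", benchmark == "HCB")
  expect_equal(cb28_hcb$site_id[cb28_hcb$rank == 1], "site_03")
  span <- attr(res$benchmarks, "span")
  expect_gt(span$span[span$target == "CB28" & span$benchmark == "HCB"], 20)
})

test_that("benchmark ranking is invariant to scaling all target concentrations", {
  tab <- make_cw_table(c(4, 4.2, 3.9, 4.3))
  cb <- tibble::tibble(
    site_id = unique(tab$site_id),
    deployment_id = unique(tab$deployment_id),
    matrix = "freshwater", compound = "CB28",
    c_w = c(0.5, 0.1, 0.9, 0.3), censored = FALSE
  )
  b1 <- benchmark_targets(dplyr::bind_rows(tab, cb), targets = "CB28")
  cb2 <- dplyr::mutate(cb, c_w = c_w * 13)
  b2 <- benchmark_targets(dplyr::bind_rows(tab, cb2), targets = "CB28")
  expect_equal(b1$rank, b2$rank)
  expect_equal(attr(b1, "span"), attr(b2, "span"))
  # identical sites tie with span 1
  cb3 <- dplyr::mutate(cb, c_w = 0.5)
  tab3 <- make_cw_table(rep(4, 4))
  b3 <- benchmark_targets(dplyr::bind_rows(tab3, cb3), targets = "CB28")
  expect_true(all(b3$rank == 1))
  expect_equal(attr(b3, "span")$span, c(1, 1))
})

test_that("an HCB-contaminated site suppresses target/HCB but not target/PeCB", {
  inj <- tibble::tibble(site_id = "site_02", compound = "HCB", fold = 5)
  sc <- generate_scenario(scenario_config(seed = 23, n_sites = 10,
                                          cv_noise = 0, measurement_cv = 0,
                                          cw_sdlog = 0, target_sdlog = 0,
                                          injections = inj))
  res <- run_pipeline(sc)
  b <- res$benchmarks
  hcb_r <- b$ratio[b$site_id == "site_02" & b$target == "CB28" &
                     b$benchmark == "HCB"]
  hcb_bg <- b$ratio[b$site_id == "site_01" & b$target == "CB28" &
                      b$benchmark == "HCB"]
  pecb_r <- b$ratio[b$site_id == "site_02" & b$target == "CB28" &
                      b$benchmark == "PeCB"]
  pecb_bg <- b$ratio[b$site_id == "site_01" & b$target == "CB28" &
                       b$benchmark == "PeCB"]
  expect_equal(hcb_r, hcb_bg / 5, tolerance = 1e-6)
  expect_equal(pecb_r, pecb_bg, tolerance = 1e-6)
})

test_that("moving average smooths without inventing amplitude", {
  d <- as.Date("2015-01-01") + 0:59
  const <- moving_average(d, rep(4.59, 60))
  expect_equal(const$smoothed, rep(4.59, 60))
  single <- moving_average(d[1], 3.3)
  expect_equal(single$smoothed, 3.3)
  air <- generate_air_series(seed = 2, n_days = 730)
  sm <- moving_average(air$date, air$ratio)
  expect_lt(diff(range(sm$smoothed)), diff(range(air$ratio)))
  expect_equal(nrow(moving_average(as.Date(character()), numeric(0))), 0L)
})
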