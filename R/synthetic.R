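# Synthetic deployment-data generator: multi-site paired HCB/PeCB/PCB
# scenarios with PRC panels, contamination injections and seasonal
# air-ratio series.

#' Configuration for a synthetic monitoring scenario
#'
#' Defines the statistical structure of a simulated multi-site passive
#' sampling campaign. Defaults encode background European conditions:
#' freshwater HCB/PeCB ratio 4.1 and marine ratio 2.76, each compound's
#' concentration varying independently with a multiplicative CV in the
#' 15-20% band (0.175), sampler geometry of 30 g deployed for a quarterly
#' 91-day exposure, and per-deployment transfer factors spanning sampling
#' rates from below 1 L/d (winter) to about 50 L/d (summer).
#'
#' @param seed Integer seed; identical configurations generate identical
#'   datasets.
#' @param n_sites Number of sites (one deployment each). Default 48.
#' @param matrix `"freshwater"`, `"marine"`, or a vector recycled over
#'   sites.
#' @param background_ratio_freshwater True background Cw(HCB)/Cw(PeCB) in
#'   freshwater. Default 4.1.
#' @param background_ratio_marine Marine counterpart. Default 2.76.
#' @param cv_noise Multiplicative CV applied independently to each
#'   compound's true Cw. Default 0.175.
#' @param measurement_cv Analytical RSD applied to every measured mass
#'   (analyte and PRC). Default 0.115, a typical inter-batch figure.
#' @param cw_meanlog,cw_sdlog Lognormal parameters of the true Cw(PeCB)
#'   level across sites, ng/L. Defaults log(0.02) and 0.55 (central 95% of
#'   site levels spanning roughly an order of magnitude around 20 pg/L).
#'   Set `cw_sdlog = 0` for a single-mean scenario in which concentrations
#'   only fluctuate around a common level.
#' @param target_meanlog Named numeric: lognormal meanlog of each target
#'   compound's background Cw (ng/L). Default
#'   `c(CB28 = log(0.005), CB52 = log(0.003))`.
#' @param target_sdlog Spread of target levels across sites. Default 0.6.
#' @param injections Data frame with columns `site_id`, `compound`, `fold`
#'   (> 0): multiplies the named compound's true Cw at that site.
#' @param duration Exposure time, days. Default 91.
#' @param sampler_mass Sampler mass, kg. Default 0.030.
#' @param beta_range Range of the per-deployment transfer factor
#'   (log-uniform draw), L^1.08 kg^0.08 / d. Default `c(2, 120)`.
#' @param prc_log_ksw PRC panel log10 Ksw values. Default
#'   `c(3.0, 3.5, 4.0, 4.5, 5.0, 5.5)`.
#' @param prc_n0 Spiked PRC amount, ng. Default 100.
#' @param loq_ng Fixed mass threshold below which an analyte measurement
#'   is reported censored. Default 0.01 ng.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(seed = 1L, n_sites = 48L,
                            matrix = "freshwater",
                            background_ratio_freshwater = 4.1,
                            background_ratio_marine = 2.76,
                            cv_noise = 0.175,
                            measurement_cv = 0.115,
                            cw_meanlog = log(0.02), cw_sdlog = 0.55,
                            target_meanlog = c(CB28 = log(0.005),
                                               CB52 = log(0.003)),
                            target_sdlog = 0.6,
                            injections = NULL,
                            duration = 91, sampler_mass = 0.030,
                            beta_range = c(2, 120),
                            prc_log_ksw = c(3.0, 3.5, 4.0, 4.5, 5.0, 5.5),
                            prc_n0 = 100,
                            loq_ng = 0.01) {
  stopifnot(n_sites >= 1, cv_noise >= 0, cv_noise < 1,
            measurement_cv >= 0, duration > 0, sampler_mass > 0,
            length(beta_range) == 2L, all(beta_range > 0),
            beta_range[1] <= beta_range[2])
  if (!is.null(injections)) {
    stopifnot(is.data.frame(injections),
              all(c("site_id", "compound", "fold") %in% names(injections)))
    if (any(injections$fold <= 0)) {
      stop("injection fold-changes must be positive", call. = FALSE)
    }
  }
  structure(
    list(seed = as.integer(seed), n_sites = as.integer(n_sites),
         matrix = matrix,
         background_ratio_freshwater = background_ratio_freshwater,
         background_ratio_marine = background_ratio_marine,
         cv_noise = cv_noise, measurement_cv = measurement_cv,
         cw_meanlog = cw_meanlog, cw_sdlog = cw_sdlog,
         target_meanlog = target_meanlog, target_sdlog = target_sdlog,
         injections = injections,
         duration = duration, sampler_mass = sampler_mass,
         beta_range = beta_range, prc_log_ksw = prc_log_ksw,
         prc_n0 = prc_n0, loq_ng = loq_ng),
    class = "scenario_config"
  )
}

# mean-one multiplicative lognormal noise factor with the given CV
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a full synthetic input bundle
#'
#' Draws true freely dissolved concentrations per site, applies
#' contamination injections, forward-simulates PRC retention and analyte
#' accumulation through the sampler uptake model, adds measurement noise
#' and censors masses below the LOQ. The result is everything the
#' pipeline consumes, plus the ground truth for validation.
#'
#' Per site: Cw(PeCB) is drawn lognormal; Cw(HCB) is the background ratio
#' times Cw(PeCB); each compound's Cw is then perturbed independently by a
#' mean-one lognormal factor with CV `cv_noise`; injections multiply the
#' true Cw; the transfer factor beta is drawn log-uniform over
#' `beta_range`; PRC fractions follow the retention model and accumulated
#' masses the inverse of the uptake model, each with multiplicative
#' measurement noise of CV `measurement_cv`.
#'
#' @param config A [scenario_config()].
#' @param compounds Compound table. Default [default_compounds()].
#' @return A list of class `"scenario"`: tibbles `deployments`,
#'   `prc_observations`, `uptakes`, `truth` (per site/compound true Cw,
#'   beta, injection label) and the `config`.
#' @examples
#' sc <- generate_scenario(scenario_config(seed = 7, n_sites = 6))
#' sc$deployments
#' @export
generate_scenario <- function(config, compounds = default_compounds()) {
  stopifnot(inherits(config, "scenario_config"))
  cmp_names <- c("HCB", "PeCB", names(config$target_meanlog))
  missing_cmp <- setdiff(cmp_names, compounds$name)
  if (length(missing_cmp)) {
    stop("compound table lacks: ", paste(missing_cmp, collapse = ", "),
         call. = FALSE)
  }
  site_ids <- sprintf("site_%02d", seq_len(config$n_sites))
  if (!is.null(config$injections)) {
    bad <- setdiff(config$injections$site_id, site_ids)
    if (length(bad)) {
      stop("injection at unknown site(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    bad_cmp <- setdiff(config$injections$compound, cmp_names)
    if (length(bad_cmp)) {
      stop("injection for unknown compound(s): ",
           paste(bad_cmp, collapse = ", "), call. = FALSE)
    }
  }
  set.seed(config$seed)

  matrix <- rep_len(config$matrix, config$n_sites)
  deployments <- tibble::tibble(
    deployment_id = sprintf("dep_%02d", seq_len(config$n_sites)),
    site_id = site_ids,
    matrix = matrix,
    duration = config$duration,
    sampler_mass = config$sampler_mass,
    water_temperature = stats::runif(config$n_sites, 0, 20),
    beta_true = exp(stats::runif(config$n_sites,
                                 log(config$beta_range[1]),
                                 log(config$beta_range[2])))
  )

  ratio <- ifelse(matrix == "marine",
                  config$background_ratio_marine,
                  config$background_ratio_freshwater)
  cw_pecb <- stats::rlnorm(config$n_sites, config$cw_meanlog, config$cw_sdlog)
  truth <- tibble::tibble(
    site_id = rep(site_ids, times = length(cmp_names)),
    deployment_id = rep(deployments$deployment_id,
                        times = length(cmp_names)),
    compound = rep(cmp_names, each = config$n_sites)
  )
  cw_true <- numeric(nrow(truth))
  for (cmp in cmp_names) {
    idx <- truth$compound == cmp
    base <- switch(cmp,
      PeCB = cw_pecb,
      HCB = ratio * cw_pecb,
      stats::rlnorm(config$n_sites, config$target_meanlog[[cmp]],
                    config$target_sdlog)
    )
    cw_true[idx] <- base * lognormal_factor(config$n_sites, config$cv_noise)
  }
  truth$cw_true <- cw_true
  truth$injected <- FALSE
  truth$fold <- 1
  if (!is.null(config$injections)) {
    for (i in seq_len(nrow(config$injections))) {
      inj <- config$injections[i, ]
      idx <- truth$site_id == inj$site_id & truth$compound == inj$compound
      truth$cw_true[idx] <- truth$cw_true[idx] * inj$fold
      truth$injected[idx] <- TRUE
      truth$fold[idx] <- inj$fold
    }
  }
  truth <- dplyr::left_join(
    truth,
    dplyr::select(deployments, "deployment_id", "beta_true"),
    by = "deployment_id"
  )

  # PRC panel: forward retention model + measurement noise on nt
  prc_grid <- tidyr::expand_grid(
    deployment_id = deployments$deployment_id,
    log_ksw = config$prc_log_ksw
  ) |>
    dplyr::left_join(dplyr::select(deployments, "deployment_id",
                                   "beta_true"),
                     by = "deployment_id")
  f_true <- prc_fraction(prc_grid$beta_true, prc_grid$log_ksw,
                         config$duration, config$sampler_mass)
  nt <- config$prc_n0 * f_true *
    lognormal_factor(nrow(prc_grid), config$measurement_cv)
  prc_observations <- tibble::tibble(
    deployment_id = prc_grid$deployment_id,
    prc_name = sprintf("PRC_k%.1f", prc_grid$log_ksw),
    log_ksw = prc_grid$log_ksw,
    n0 = config$prc_n0,
    nt = nt,
    fraction = nt / config$prc_n0,
    below_loq = nt < config$loq_ng
  )

  # analyte masses: inverse of the uptake model + measurement noise
  up <- truth |>
    dplyr::left_join(
      dplyr::select(compounds, compound = "name", "log_ksw"),
      by = "compound"
    )
  rs <- sampling_rate(up$beta_true, up$log_ksw)
  ksw_m <- 10^up$log_ksw * config$sampler_mass
  n_true <- up$cw_true * ksw_m *
    (1 - exp(-rs * config$duration / ksw_m))
  n_meas <- n_true * lognormal_factor(nrow(up), config$measurement_cv)
  uptakes <- tibble::tibble(
    deployment_id = up$deployment_id,
    compound = up$compound,
    n_acc = n_meas,
    below_loq = n_meas < config$loq_ng
  )

  structure(
    list(deployments = deployments, prc_observations = prc_observations,
         uptakes = uptakes, truth = truth, config = config),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$config$n_sites, "sites, seed", x$config$seed, "\n")
  cat("  deployments:", nrow(x$deployments),
      " PRC obs:", nrow(x$prc_observations),
      " uptakes:", nrow(x$uptakes), "\n")
  invisible(x)
}

#' Generate a seasonal air-ratio time series
#'
#' Daily HCB/PeCB air concentration ratios with a sinusoidal seasonal
#' cycle in log space: the seasonal median interpolates between the winter
#' level (minimum on 15 January) and the summer level (maximum half a year
#' later), with multiplicative lognormal noise on top. With `noise_cv = 0`
#' mid-January values equal `winter_median` exactly and mid-July values
#' the summer level.
#'
#' @param seed Integer seed.
#' @param n_days Series length in days (>= 14).
#' @param start_date First day. Default `"2012-01-01"`.
#' @param winter_median Winter (Nov-Feb) median ratio. Default 3.98.
#' @param summer_median Summer (May-Sep) median ratio. Default 5.30.
#' @param noise_cv Multiplicative CV of the day-to-day noise. Default 0.25.
#' @return A tibble `date`, `ratio`.
#' @examples
#' air <- generate_air_series(seed = 1, n_days = 365, noise_cv = 0)
#' range(air$ratio)
#' @export
generate_air_series <- function(seed = 1L, n_days,
                                start_date = as.Date("2012-01-01"),
                                winter_median = 3.98, summer_median = 5.30,
                                noise_cv = 0.25) {
  stopifnot(n_days >= 14, winter_median > 0, summer_median > 0,
            noise_cv >= 0)
  set.seed(as.integer(seed))
  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  doy <- as.numeric(format(dates, "%j"))
  period <- 365.25
  mid <- (log(winter_median) + log(summer_median)) / 2
  amp <- (log(summer_median) - log(winter_median)) / 2
  # minimum of the cycle pinned to day-of-year 15 (mid-January)
  log_median <- mid - amp * cos(2 * pi * (doy - 15) / period)
  ratio <- exp(log_median) * lognormal_factor(n_days, noise_cv)
  tibble::tibble(date = dates, ratio = ratio)
}
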