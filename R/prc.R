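# PRC dissipation kinetics: forward retention model and nonlinear
# least-squares estimation of the exposure-specific transfer factor beta.

# Exponent of the Ksw dependence of the sampling rate under water
# boundary-layer control: Rs = beta * Ksw^(-KSW_EXPONENT).
KSW_EXPONENT <- 0.08

#' Expected PRC retained fraction
#'
#' Fraction of a performance reference compound remaining in a silicone
#' sampler after exposure, under first-order water boundary-layer-controlled
#' exchange:
#' \deqn{f = \exp(-R_s t / (m K_{sw})), \quad R_s = \beta K_{sw}^{-0.08}}
#' so that \eqn{f = \exp(-\beta t / (m K_{sw}^{1.08}))}.
#'
#' @param beta Exposure-specific transfer factor, L^1.08 kg^0.08 / d.
#' @param log_ksw log10 polymer-water partition coefficient of the PRC, L/kg.
#' @param duration Exposure time, days.
#' @param sampler_mass Sampler mass, kg.
#' @param ksw_exponent Exponent of the Ksw dependence of Rs; default 0.08.
#' @return Retained fraction in (0, 1].
#' @examples
#' prc_fraction(beta = 10, log_ksw = 4.5, duration = 91, sampler_mass = 0.030)
#' @export
prc_fraction <- function(beta, log_ksw, duration, sampler_mass,
                         ksw_exponent = KSW_EXPONENT) {
  stopifnot(all(beta >= 0), all(duration > 0), all(sampler_mass > 0))
  ksw <- 10^log_ksw
  exp(-beta * duration / (sampler_mass * ksw^(1 + ksw_exponent)))
}

#' Sampling rate from the transfer factor
#'
#' \deqn{R_s = \beta K_{sw}^{-0.08}}
#'
#' @param beta Transfer factor, L^1.08 kg^0.08 / d.
#' @param compound Compound record/name, or a numeric log10 Ksw.
#' @inheritParams prc_fraction
#' @return Sampling rate, L/d.
#' @examples
#' sampling_rate(100, 5)         # 39.81 L/d
#' sampling_rate(50, "HCB")
#' @export
sampling_rate <- function(beta, compound, ksw_exponent = KSW_EXPONENT) {
  log_ksw <- if (is.numeric(compound)) compound else as_compound(compound)$log_ksw
  if (any(!is.finite(log_ksw))) {
    stop("log Ksw must be finite to compute a sampling rate", call. = FALSE)
  }
  stopifnot(all(beta >= 0))
  beta * (10^log_ksw)^(-ksw_exponent)
}

#' Fit the transfer factor beta to PRC dissipation data
#'
#' Estimates the exposure-specific transfer factor by nonlinear least
#' squares on the retained fractions of a PRC panel spanning a range of
#' Ksw, treating the fraction as a continuous function of the sampling
#' rate. The objective
#' \deqn{\sum_i (f_i^{obs} - f(\beta, K_{sw,i}))^2}
#' is minimised over log10(beta) on a fixed bracket by deterministic
#' one-dimensional bounded search, so repeated fits on identical data are
#' bit-identical.
#'
#' Observed fractions above 1 (analytical noise) are clipped to 1 for the
#' fit; the raw values are kept in the returned observation table. PRCs
#' flagged below the limit of quantification enter with fraction 0 unless
#' `exclude_below_loq = TRUE`.
#'
#' @param observations Data frame with columns `log_ksw` and either
#'   `fraction` or both `n0` and `nt` (amounts spiked/remaining, any common
#'   unit); optional logical column `below_loq`.
#' @param duration Exposure time, days.
#' @param sampler_mass Sampler mass, kg.
#' @param exclude_below_loq Drop below-LOQ PRCs instead of scoring them as
#'   fully dissipated. Default `FALSE`.
#' @param weighted Weight residuals by 1/(f(1-f)) (binomial-style variance);
#'   default `FALSE`, the canonical unweighted fit.
#' @param log10_beta_bounds Search bracket for log10(beta). Default
#'   `c(-3, 6)`.
#' @param tol Convergence tolerance of the bounded search. Default 1e-10.
#' @inheritParams prc_fraction
#' @return An object of class `"prc_fit"`: a list with `beta_sil`,
#'   `beta_se`, `rss`, `n_used`, `converged`, `flag` (`"ok"`,
#'   `"uninformative_lower"` or `"uninformative_upper"`), and
#'   `observations`, the input table augmented with fitted fractions.
#' @examples
#' obs <- tibble::tibble(
#'   log_ksw  = c(3.5, 4.0, 4.5, 5.0),
#'   fraction = prc_fraction(20, c(3.5, 4.0, 4.5, 5.0), 91, 0.030)
#' )
#' fit_beta(obs, duration = 91, sampler_mass = 0.030)
#' @export
fit_beta <- function(observations, duration, sampler_mass,
                     exclude_below_loq = FALSE, weighted = FALSE,
                     log10_beta_bounds = c(-3, 6), tol = 1e-10,
                     ksw_exponent = KSW_EXPONENT) {
  stopifnot(is.data.frame(observations), duration > 0, sampler_mass > 0)
  obs <- tibble::as_tibble(observations)
  if (!"log_ksw" %in% names(obs)) {
    stop("`observations` needs a `log_ksw` column", call. = FALSE)
  }
  if (!"fraction" %in% names(obs)) {
    if (!all(c("n0", "nt") %in% names(obs))) {
      stop("`observations` needs `fraction` or both `n0` and `nt`",
           call. = FALSE)
    }
    if (any(obs$n0 <= 0, na.rm = TRUE)) {
      stop("spiked amounts `n0` must be positive", call. = FALSE)
    }
    obs$fraction <- obs$nt / obs$n0
  }
  if (!"below_loq" %in% names(obs)) obs$below_loq <- FALSE
  obs$below_loq[is.na(obs$below_loq)] <- FALSE

  obs$fraction_raw <- obs$fraction
  obs$fraction_fit <- pmin(pmax(obs$fraction, 0), 1)
  obs$fraction_fit[obs$below_loq] <- 0

  use <- is.finite(obs$fraction_fit) & is.finite(obs$log_ksw)
  if (exclude_below_loq) use <- use & !obs$below_loq
  obs$used <- use
  f_obs <- obs$fraction_fit[use]
  lk <- obs$log_ksw[use]
  n_used <- length(f_obs)
  if (n_used < 1L) stop("no usable PRC observations", call. = FALSE)

  w <- if (weighted) 1 / pmax(f_obs * (1 - f_obs), 1e-4) else rep(1, n_used)

  make_fit <- function(beta, converged, flag) {
    f_hat <- prc_fraction(beta, lk, duration, sampler_mass, ksw_exponent)
    resid <- f_obs - f_hat
    rss <- sum(w * resid^2)
    # asymptotic SE from the Gauss-Newton approximation
    grad <- -duration / (sampler_mass * (10^lk)^(1 + ksw_exponent)) * f_hat
    denom <- sum(w * grad^2)
    sigma2 <- rss / max(n_used - 1L, 1L)
    se <- if (denom > 0 && flag == "ok") sqrt(sigma2 / denom) else NA_real_
    obs$fitted_fraction <- prc_fraction(beta, obs$log_ksw, duration,
                                        sampler_mass, ksw_exponent)
    structure(
      list(beta_sil = beta, beta_se = se, rss = rss, n_used = n_used,
           converged = converged, flag = flag,
           duration = duration, sampler_mass = sampler_mass,
           ksw_exponent = ksw_exponent, observations = obs),
      class = "prc_fit"
    )
  }

  if (all(f_obs >= 0.99)) {
    return(make_fit(0, FALSE, "uninformative_lower"))
  }
  if (all(f_obs <= 1e-6)) {
    return(make_fit(10^log10_beta_bounds[2], FALSE, "uninformative_upper"))
  }

  objective <- function(log10_beta) {
    f_hat <- prc_fraction(10^log10_beta, lk, duration, sampler_mass,
                          ksw_exponent)
    sum(w * (f_obs - f_hat)^2)
  }
  opt <- stats::optimize(objective, interval = log10_beta_bounds, tol = tol)
  beta_hat <- 10^opt$minimum
  at_edge <- opt$minimum <= log10_beta_bounds[1] + 1e-6 ||
    opt$minimum >= log10_beta_bounds[2] - 1e-6
  if (at_edge) {
    warning("beta estimate at the edge of the search bracket; ",
            "fit may be uninformative", call. = FALSE)
  }
  make_fit(beta_hat, !at_edge, "ok")
}

#' @export
print.prc_fit <- function(x, ...) {
  cat("<prc_fit>", x$n_used, "PRCs,", sprintf("t = %g d, m = %g kg\n",
                                              x$duration, x$sampler_mass))
  cat(sprintf("  beta_sil = %.4g (se %.3g) L^1.08 kg^0.08 d^-1, flag: %s\n",
              x$beta_sil, x$beta_se, x$flag))
  invisible(x)
}

#' Fit beta for every deployment in a PRC table
#'
#' Convenience wrapper applying [fit_beta()] per `deployment_id`.
#'
#' @param prc_table Data frame with `deployment_id` plus the columns
#'   [fit_beta()] expects.
#' @param deployments Data frame with `deployment_id`, `duration`
#'   (days) and `sampler_mass` (kg).
#' @param ... Passed to [fit_beta()].
#' @return A tibble with one row per deployment: `deployment_id`,
#'   `beta_sil`, `beta_se`, `rss`, `n_used`, `converged`, `flag`.
#' @export
fit_beta_by_deployment <- function(prc_table, deployments, ...) {
  stopifnot(is.data.frame(prc_table), is.data.frame(deployments))
  ids <- unique(prc_table$deployment_id)
  rows <- lapply(ids, function(id) {
    dep <- deployments[deployments$deployment_id == id, , drop = FALSE]
    if (nrow(dep) != 1L) {
      stop("deployment '", id, "' missing (or duplicated) in `deployments`",
           call. = FALSE)
    }
    fit <- fit_beta(prc_table[prc_table$deployment_id == id, , drop = FALSE],
                    duration = dep$duration, sampler_mass = dep$sampler_mass,
                    ...)
    tibble::tibble(
      deployment_id = id, beta_sil = fit$beta_sil, beta_se = fit$beta_se,
      rss = fit$rss, n_used = fit$n_used, converged = fit$converged,
      flag = fit$flag
    )
  })
  dplyr::bind_rows(rows)
}
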