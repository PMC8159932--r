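# Freely dissolved concentrations from accumulated masses, degree of
# equilibrium, and the linear-uptake mass-ratio approximation.

#' Degree of equilibrium reached by a sampler
#'
#' Fraction of the equilibrium amount a compound attains during an
#' exposure:
#' \deqn{DEQ = 1 - \exp(-R_s t / (K_{sw} m))}
#'
#' @param sampling_rate Sampling rate Rs, L/d.
#' @param duration Exposure time, days.
#' @param log_ksw log10 polymer-water partition coefficient, L/kg (or a
#'   compound record/name).
#' @param sampler_mass Sampler mass, kg.
#' @return DEQ in [0, 1); strictly increasing in `sampling_rate` and
#'   `duration`.
#' @examples
#' # winter-end model compound: quarterly exposure at Rs = 1 L/d
#' degree_of_equilibrium(1, 91, 4.5, 0.030)
#' @export
degree_of_equilibrium <- function(sampling_rate, duration, log_ksw,
                                  sampler_mass) {
  if (!is.numeric(log_ksw)) log_ksw <- as_compound(log_ksw)$log_ksw
  stopifnot(all(sampling_rate >= 0), all(duration >= 0),
            all(sampler_mass > 0))
  1 - exp(-sampling_rate * duration / (10^log_ksw * sampler_mass))
}

#' Freely dissolved concentration from the accumulated mass
#'
#' Full uptake model covering linear, transitional and near-equilibrium
#' sampling:
#' \deqn{C_w = n_{acc} / (K_{sw} m (1 - e^{-R_s t/(K_{sw} m)}))}
#' In the linear limit (DEQ near 0) this reduces to \eqn{n_{acc}/(R_s t)}
#' and at equilibrium to \eqn{n_{acc}/(K_{sw} m)}. When the exponent drops
#' below 1e-12 the linear closed form is used directly to avoid 0/0.
#'
#' Unit contract: mass in ng, Ksw in L/kg, sampler mass in kg, Rs in L/d,
#' time in days; the result is then in ng/L.
#'
#' @param n_acc Accumulated (blank-corrected) mass, ng.
#' @param sampling_rate Rs, L/d.
#' @param duration Exposure time, days.
#' @param log_ksw log10 Ksw, L/kg (or compound record/name).
#' @param sampler_mass Sampler mass, kg.
#' @param below_loq Logical; censored observations give `c_w = NA` with
#'   `censored = TRUE` rather than zero.
#' @param regime_cutoffs Length-2 numeric: DEQ below the first value is
#'   `"linear"`, above the second `"near_equilibrium"`, otherwise
#'   `"transitional"`. Default `c(0.05, 0.95)`.
#' @return A tibble with columns `c_w` (ng/L), `sampling_rate`, `deq`,
#'   `regime`, `censored`. Vectorised over its numeric arguments.
#' @examples
#' cw_from_uptake(10, sampling_rate = 1, duration = 91,
#'                log_ksw = 4.5, sampler_mass = 0.030)
#' @export
cw_from_uptake <- function(n_acc, sampling_rate, duration, log_ksw,
                           sampler_mass, below_loq = FALSE,
                           regime_cutoffs = c(0.05, 0.95)) {
  if (!is.numeric(log_ksw)) log_ksw <- as_compound(log_ksw)$log_ksw
  stopifnot(all(n_acc >= 0, na.rm = TRUE), all(sampling_rate >= 0),
            all(duration > 0), all(sampler_mass > 0),
            length(regime_cutoffs) == 2L,
            regime_cutoffs[1] < regime_cutoffs[2])
  n <- max(length(n_acc), length(sampling_rate), length(duration),
           length(log_ksw), length(sampler_mass))
  n_acc <- rep_len(n_acc, n)
  sampling_rate <- rep_len(sampling_rate, n)
  duration <- rep_len(duration, n)
  log_ksw <- rep_len(log_ksw, n)
  sampler_mass <- rep_len(sampler_mass, n)
  ksw_m <- 10^log_ksw * sampler_mass
  x <- sampling_rate * duration / ksw_m
  deq <- 1 - exp(-x)
  c_w <- ifelse(x < 1e-12,
                n_acc / (sampling_rate * duration),
                n_acc / (ksw_m * deq))
  regime <- dplyr::case_when(
    deq < regime_cutoffs[1] ~ "linear",
    deq > regime_cutoffs[2] ~ "near_equilibrium",
    TRUE ~ "transitional"
  )
  censored <- rep_len(as.logical(below_loq), length(c_w))
  c_w[censored] <- NA_real_
  tibble::tibble(
    c_w = c_w,
    sampling_rate = rep_len(sampling_rate, length(c_w)),
    deq = rep_len(deq, length(c_w)),
    regime = rep_len(regime, length(c_w)),
    censored = censored
  )
}

#' Estimate freely dissolved concentrations for an uptake table
#'
#' Joins accumulated-mass records with their deployments, per-deployment
#' PRC fits and compound properties, then applies [cw_from_uptake()]
#' row-wise with compound-specific sampling rates from [sampling_rate()].
#'
#' @param uptakes Data frame: `deployment_id`, `compound`, `n_acc` (ng),
#'   optional logical `below_loq`.
#' @param deployments Data frame: `deployment_id`, `site_id`, `duration`,
#'   `sampler_mass`, `matrix`.
#' @param prc_fits Data frame as from [fit_beta_by_deployment()]:
#'   `deployment_id`, `beta_sil`.
#' @param compounds Compound table; default [default_compounds()].
#' @inheritParams cw_from_uptake
#' @return A tibble: one row per uptake with `site_id`, `matrix`,
#'   `deployment_id`, `compound`, `n_acc`, `c_w`, `sampling_rate`, `deq`,
#'   `regime`, `censored`.
#' @export
estimate_cw <- function(uptakes, deployments, prc_fits,
                        compounds = default_compounds(),
                        regime_cutoffs = c(0.05, 0.95)) {
  stopifnot(is.data.frame(uptakes), is.data.frame(deployments),
            is.data.frame(prc_fits))
  if (!"below_loq" %in% names(uptakes)) uptakes$below_loq <- FALSE
  tab <- uptakes |>
    dplyr::inner_join(
      dplyr::select(deployments, dplyr::any_of(c(
        "deployment_id", "site_id", "duration", "sampler_mass", "matrix"
      ))),
      by = "deployment_id"
    ) |>
    dplyr::inner_join(
      dplyr::select(compounds, compound = "name", "log_ksw"),
      by = "compound"
    ) |>
    dplyr::inner_join(
      dplyr::select(prc_fits, "deployment_id", "beta_sil"),
      by = "deployment_id"
    )
  if (nrow(tab) == 0L) {
    warning("no uptake records could be joined to deployments/fits/compounds",
            call. = FALSE)
  }
  est <- cw_from_uptake(
    n_acc = tab$n_acc,
    sampling_rate = sampling_rate(tab$beta_sil, tab$log_ksw),
    duration = tab$duration,
    log_ksw = tab$log_ksw,
    sampler_mass = tab$sampler_mass,
    below_loq = tab$below_loq,
    regime_cutoffs = regime_cutoffs
  )
  dplyr::bind_cols(
    dplyr::select(tab, dplyr::any_of(c(
      "site_id", "matrix", "deployment_id", "compound", "n_acc"
    ))),
    est
  )
}

#' Concentration ratio of two compounds under linear uptake
#'
#' Under linear uptake the accumulated-mass ratio of two compounds
#' approximates their freely dissolved concentration ratio, because the
#' exposure time cancels and the sampling rates differ only through the
#' weak Ksw dependence:
#' \deqn{C_{w,a}/C_{w,b} = (n_a/(R_{s,a} t)) / (n_b/(R_{s,b} t))
#'   \approx n_a/n_b}
#' The relative discrepancy between the Rs-corrected ratio and the raw mass
#' ratio equals \eqn{(K_{sw,b}/K_{sw,a})^{0.08}}.
#'
#' @param n_acc_a,n_acc_b Accumulated masses of compounds a and b, ng.
#' @param rs_a,rs_b Their sampling rates, L/d.
#' @param deq_a,deq_b Optional degrees of equilibrium; a warning is issued
#'   when either exceeds `linear_cutoff` (the approximation then degrades).
#' @param linear_cutoff DEQ limit of the linear regime. Default 0.05.
#' @return A list: `corrected_ratio` (Rs-corrected), `raw_ratio` (mass
#'   ratio), `discrepancy` (corrected/raw).
#' @export
linear_ratio <- function(n_acc_a, n_acc_b, rs_a, rs_b,
                         deq_a = NULL, deq_b = NULL, linear_cutoff = 0.05) {
  if (any(n_acc_b <= 0)) {
    stop("denominator mass must be positive for a ratio", call. = FALSE)
  }
  deqs <- c(deq_a, deq_b)
  if (length(deqs) && any(deqs >= linear_cutoff)) {
    warning("degree of equilibrium exceeds the linear-regime cut-off (",
            linear_cutoff, "); the mass-ratio approximation is biased",
            call. = FALSE)
  }
  corrected <- (n_acc_a / rs_a) / (n_acc_b / rs_b)
  raw <- n_acc_a / n_acc_b
  list(corrected_ratio = corrected, raw_ratio = raw,
       discrepancy = corrected / raw)
}
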