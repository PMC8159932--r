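# End-to-end pipeline: PRC fits -> Cw estimation -> ratio screening ->
# benchmarking.

#' Run the full passive-sampling inference chain
#'
#' Executes the stages in order: per-deployment PRC fits, freely dissolved
#' concentration estimation, HCB/PeCB ratio screening against outlier
#' limits, and benchmarking of target compounds. Concentration-based
#' ratios (from PRC-calibrated sampling rates) are preferred; when no PRC
#' table is supplied the pipeline falls back to accumulated-mass ratios,
#' which are valid only under linear uptake, and says so in a message.
#'
#' @param inputs A list with `deployments`, `uptakes`, and optionally
#'   `prc_observations` — e.g. a [generate_scenario()] result or a
#'   [read_input_bundle()] result.
#' @param compounds Compound table. Default [default_compounds()];
#'   an `inputs$compounds` entry overrides it.
#' @param limits An `outlier_limits` object, or `NULL` (default) to use
#'   the fixed per-matrix screening bands of [default_ratio_limits()].
#' @param targets Benchmark target compounds present in the uptake table.
#'   Default intersects `c("CB28", "CB52")` with what is there.
#' @param regime_cutoffs DEQ regime cut-offs for [estimate_cw()].
#' @return A list of class `"sr_pipeline"`: `prc_fits`, `cw`, `ratios`,
#'   `screen`, `benchmarks`, `regression` (through-origin fit of Cw(HCB)
#'   on Cw(PeCB), `NULL` when under 3 pairs), and `mode` (`"cw"` or
#'   `"mass_ratio"`).
#' @examples
#' sc <- generate_scenario(scenario_config(seed = 3, n_sites = 8))
#' res <- run_pipeline(sc)
#' res$regression$slope
#' @export
run_pipeline <- function(inputs, compounds = default_compounds(),
                         limits = NULL, targets = NULL,
                         regime_cutoffs = c(0.05, 0.95)) {
  stopifnot(is.list(inputs),
            is.data.frame(inputs$deployments),
            is.data.frame(inputs$uptakes))
  if (!is.null(inputs$compounds)) compounds <- inputs$compounds
  deployments <- inputs$deployments
  uptakes <- inputs$uptakes
  prc <- inputs$prc_observations

  if (nrow(uptakes) == 0L) {
    warning("empty uptake table: returning empty outputs", call. = FALSE)
  }
  if (is.null(targets)) {
    targets <- intersect(c("CB28", "CB52"), unique(uptakes$compound))
  }

  have_prc <- !is.null(prc) && nrow(prc) > 0L
  if (have_prc) {
    mode <- "cw"
    prc_fits <- fit_beta_by_deployment(prc, deployments)
    cw <- estimate_cw(uptakes, deployments, prc_fits,
                      compounds = compounds,
                      regime_cutoffs = regime_cutoffs)
  } else {
    mode <- "mass_ratio"
    message("no PRC observations: using accumulated-mass ratios ",
            "(valid under linear uptake only)")
    prc_fits <- tibble::tibble(deployment_id = character(),
                               beta_sil = numeric())
    # masses stand in for concentrations; ratios are what is screened
    if (!"below_loq" %in% names(uptakes)) uptakes$below_loq <- FALSE
    cw <- uptakes |>
      dplyr::inner_join(
        dplyr::select(deployments, dplyr::any_of(c(
          "deployment_id", "site_id", "matrix"
        ))),
        by = "deployment_id"
      ) |>
      dplyr::mutate(c_w = .data$n_acc, censored = .data$below_loq,
                    deq = NA_real_, regime = NA_character_,
                    sampling_rate = NA_real_)
  }

  if (nrow(cw) == 0L) {
    empty <- tibble::tibble()
    return(structure(list(prc_fits = prc_fits, cw = cw, ratios = empty,
                          screen = empty, benchmarks = empty,
                          regression = NULL, mode = mode),
                     class = "sr_pipeline"))
  }

  ratios <- paired_ratios(cw, "HCB", "PeCB")
  screen <- if (nrow(ratios)) screen_ratios(ratios, limits) else ratios

  regression <- NULL
  hcb <- cw[cw$compound == "HCB" & !cw$censored, ]
  pecb <- cw[cw$compound == "PeCB" & !cw$censored, ]
  pairs <- dplyr::inner_join(
    dplyr::select(hcb, "deployment_id", y = "c_w"),
    dplyr::select(pecb, "deployment_id", x = "c_w"),
    by = "deployment_id"
  )
  if (nrow(pairs) >= 3L) {
    regression <- regression_through_origin(pairs$x, pairs$y)
  }

  benchmarks <- if (length(targets)) {
    benchmark_targets(cw, targets = targets)
  } else {
    tibble::tibble()
  }

  structure(
    list(prc_fits = prc_fits, cw = cw, ratios = ratios, screen = screen,
         benchmarks = benchmarks, regression = regression, mode = mode),
    class = "sr_pipeline"
  )
}

#' @export
print.sr_pipeline <- function(x, ...) {
  cat("<sr_pipeline> mode:", x$mode, "\n")
  cat("  deployments fitted:", nrow(x$prc_fits),
      " Cw rows:", nrow(x$cw), " ratios:", nrow(x$ratios), "\n")
  if (!is.null(x$regression)) {
    cat(sprintf("  Cw(HCB) = %.3f (se %.3f) x Cw(PeCB), R2 = %.3f, n = %d\n",
                x$regression$slope, x$regression$se,
                x$regression$r_squared, x$regression$n))
  }
  if (nrow(x$screen)) {
    cat("  classification:",
        paste(names(table(x$screen$classification)),
              table(x$screen$classification), collapse = ", "), "\n")
  }
  invisible(x)
}
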