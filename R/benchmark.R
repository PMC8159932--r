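# Diagnostic-ratio screening and benchmarking: paired HCB/PeCB ratios,
# outlier limits, contamination classification, through-origin regression,
# target-compound benchmarking and air-series smoothing.

#' Default indicative outlier limits for the HCB/PeCB water ratio
#'
#' Fixed screening bands: freshwater (2.2, 7.0), derived from European
#' background air ratios scaled by the PeCB/HCB Henry ratio at 15 degrees
#' C, and marine (2.44, 3.08) from the normal-band construction on marine
#' ratios. Recomputation from user data is always available via
#' [iqr_outlier_limits()] and [normal_band_limits()].
#'
#' @param matrix `"freshwater"` or `"marine"`.
#' @return An `outlier_limits` object.
#' @examples
#' default_ratio_limits("freshwater")
#' @export
default_ratio_limits <- function(matrix = c("freshwater", "marine")) {
  matrix <- match.arg(matrix)
  lim <- switch(matrix,
    freshwater = c(2.2, 7.0),
    marine = c(2.44, 3.08)
  )
  new_outlier_limits(lim[1], lim[2], method = "fixed",
                     provenance = list(matrix = matrix))
}

#' Construct a fixed outlier-limits object
#'
#' Wraps externally supplied screening limits (e.g. published air-ratio
#' limits) so they can be scaled, printed and used for classification like
#' limits estimated from data.
#'
#' @param lower,upper Positive limits, `lower <= upper`.
#' @param provenance Optional named list recording where the limits came
#'   from.
#' @return An `outlier_limits` object with `method = "fixed"`.
#' @examples
#' fixed_limits(2.4, 7.9)  # published background air-ratio limits
#' @export
fixed_limits <- function(lower, upper, provenance = list()) {
  stopifnot(lower > 0)
  new_outlier_limits(lower, upper, method = "fixed",
                     provenance = provenance)
}

new_outlier_limits <- function(lower, upper, method, provenance = list(),
                               degenerate = FALSE) {
  stopifnot(lower <= upper)
  structure(
    list(lower = lower, upper = upper, method = method,
         degenerate = degenerate, provenance = provenance),
    class = "outlier_limits"
  )
}

#' @export
print.outlier_limits <- function(x, ...) {
  cat(sprintf("<outlier_limits> (%.3g, %.3g) method: %s%s\n",
              x$lower, x$upper, x$method,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Paired concentration ratios from a Cw (or Ca) table
#'
#' Computes the per-deployment ratio of two compounds' concentrations.
#' Pairs in which either member is censored (below LOQ) are dropped, and
#' the number dropped is recorded in the `n_dropped` attribute — mirroring
#' the screening rule that a ratio with a censored member is uninformative.
#'
#' @param cw_table Data frame with `deployment_id`, `compound`, `c_w` and
#'   optionally `site_id`, `matrix`, `censored`.
#' @param compound_a,compound_b Names of numerator and denominator
#'   compounds. Defaults `"HCB"` and `"PeCB"`.
#' @return A tibble of ratio records (`site_id`, `deployment_id`, `matrix`,
#'   `ratio`) with attribute `n_dropped`; empty (with a warning) when no
#'   complete pair exists.
#' @export
paired_ratios <- function(cw_table, compound_a = "HCB", compound_b = "PeCB") {
  stopifnot(is.data.frame(cw_table),
            all(c("deployment_id", "compound", "c_w") %in% names(cw_table)))
  tab <- tibble::as_tibble(cw_table)
  if (!"censored" %in% names(tab)) tab$censored <- is.na(tab$c_w)
  if (!"site_id" %in% names(tab)) tab$site_id <- tab$deployment_id
  if (!"matrix" %in% names(tab)) tab$matrix <- NA_character_

  pick <- function(cmp) {
    tab |>
      dplyr::filter(.data$compound == cmp) |>
      dplyr::select("site_id", "deployment_id", "matrix", "c_w", "censored")
  }
  a <- pick(compound_a)
  b <- pick(compound_b)
  pairs <- dplyr::inner_join(a, b, by = c("site_id", "deployment_id", "matrix"),
                             suffix = c("_a", "_b"))
  complete <- !pairs$censored_a & !pairs$censored_b &
    is.finite(pairs$c_w_a) & is.finite(pairs$c_w_b) & pairs$c_w_b > 0
  n_dropped <- sum(!complete)
  out <- pairs |>
    dplyr::filter(complete) |>
    dplyr::mutate(ratio = .data$c_w_a / .data$c_w_b) |>
    dplyr::select("site_id", "deployment_id", "matrix", "ratio")
  if (nrow(out) == 0L) {
    warning("no complete ", compound_a, "/", compound_b, " pairs",
            call. = FALSE)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' IQR outlier limits with lower-limit inversion
#'
#' Upper limit: Q3 + k * IQR of the ratios. Because the same construction
#' on the lower side can produce a negative limit for a positive-valued
#' ratio, the lower limit is built on the inverted ratios instead: the
#' upper limit of 1/ratio is computed the same way and back-transformed,
#' lower = 1 / (Q3' + k * IQR'). Quartiles use linear interpolation
#' (R's default type 7), recorded in the provenance.
#'
#' This construction is scale-equivariant: multiplying all ratios by c > 0
#' multiplies both limits by c.
#'
#' @param ratios Positive numeric vector, length >= 4 (shorter input is an
#'   error except the degenerate all-equal case).
#' @param k IQR multiplier, default 1.5.
#' @param quantile_type Quartile rule passed to [stats::quantile()];
#'   default 7.
#' @return An `outlier_limits` object (`method = "iqr_inversion"`); when
#'   all ratios are equal both limits collapse to that value and
#'   `degenerate` is `TRUE`.
#' @examples
#' iqr_outlier_limits(c(2, 3, 4, 5, 6))  # upper = 5 + 1.5 * 2 = 8
#' @export
iqr_outlier_limits <- function(ratios, k = 1.5, quantile_type = 7) {
  ratios <- ratios[is.finite(ratios)]
  if (any(ratios <= 0)) stop("ratios must be positive", call. = FALSE)
  if (length(unique(ratios)) == 1L) {
    v <- ratios[1]
    return(new_outlier_limits(v, v, "iqr_inversion",
                              provenance = list(k = k, n = length(ratios)),
                              degenerate = TRUE))
  }
  if (length(ratios) < 4L) {
    stop("need at least 4 ratios for quartile-based limits", call. = FALSE)
  }
  q <- stats::quantile(ratios, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  upper <- q[2] + k * (q[2] - q[1])
  inv <- 1 / ratios
  qi <- stats::quantile(inv, c(0.25, 0.75), type = quantile_type,
                        names = FALSE)
  lower <- 1 / (qi[2] + k * (qi[2] - qi[1]))
  new_outlier_limits(
    lower, upper, "iqr_inversion",
    provenance = list(
      q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
      inv_q1 = qi[1], inv_q3 = qi[2], inv_iqr = qi[2] - qi[1],
      k = k, quantile_type = quantile_type, n = length(ratios)
    )
  )
}

#' Scale air-ratio outlier limits to water
#'
#' Air-phase HCB/PeCB limits map to water-phase limits by the Henry ratio
#' of the pair at the chosen temperature (the same factor as in
#' [expected_water_ratio()]). The printed air limits (2.4, 7.9) scaled at
#' 15 degrees C give the water screening band of about (2.1, 7.0).
#'
#' @param air_limits An `outlier_limits` object for the air ratio.
#' @param temperature Temperature, K. Default 288.15 (15 degrees C).
#' @param numerator,denominator The compounds of the ratio (numerator /
#'   denominator), defaults HCB over PeCB.
#' @return An `outlier_limits` object for the water ratio, with the
#'   temperature and Henry ratio recorded in the provenance.
#' @export
scale_air_limits_to_water <- function(air_limits, temperature = 288.15,
                                      numerator = "HCB",
                                      denominator = "PeCB") {
  stopifnot(inherits(air_limits, "outlier_limits"),
            air_limits$lower > 0)
  hr <- henry_ratio(denominator, numerator, temperature)
  prov <- air_limits$provenance
  prov$scaled_from_air <- c(air_limits$lower, air_limits$upper)
  prov$temperature_k <- temperature
  prov$henry_ratio <- hr
  new_outlier_limits(air_limits$lower * hr, air_limits$upper * hr,
                     method = air_limits$method, provenance = prov,
                     degenerate = air_limits$degenerate)
}

#' Parametric (normal-band) outlier limits
#'
#' For approximately normal ratios the IQR spans about 1.35 standard
#' deviations, so sigma is estimated as IQR/1.35 and the limits placed at
#' median +/- k * sigma (k = 3 by default).
#'
#' @param ratios Numeric vector; at least 8 values recommended.
#' @param k Sigma multiplier, default 3.
#' @inheritParams iqr_outlier_limits
#' @return An `outlier_limits` object (`method = "normal_sigma"`); zero
#'   spread collapses both limits to the median with `degenerate = TRUE`.
#' @export
normal_band_limits <- function(ratios, k = 3, quantile_type = 7) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2L) stop("need at least 2 ratios", call. = FALSE)
  if (length(ratios) < 8L) {
    warning("fewer than 8 ratios: sigma from IQR/1.35 is unstable",
            call. = FALSE)
  }
  med <- stats::median(ratios)
  q <- stats::quantile(ratios, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  sigma <- (q[2] - q[1]) / 1.35
  degenerate <- sigma == 0
  new_outlier_limits(
    med - k * sigma, med + k * sigma, "normal_sigma",
    provenance = list(median = med, q1 = q[1], q3 = q[2], sigma = sigma,
                      k = k, quantile_type = quantile_type,
                      n = length(ratios)),
    degenerate = degenerate
  )
}

#' Classify a diagnostic ratio against outlier limits
#'
#' A ratio above the upper limit indicates relative enrichment of the
#' numerator compound (for HCB/PeCB: `"hcb_elevated"`); below the lower
#' limit, enrichment of the denominator (`"pecb_elevated"`); in between,
#' `"background"`. Censored records are `"indeterminate"`.
#'
#' @param ratio Numeric vector of ratios (HCB/PeCB by convention).
#' @param limits An `outlier_limits` object.
#' @param censored Logical vector (recycled).
#' @return Character vector of classifications.
#' @examples
#' classify_site(c(9.5, 4.1, 1.0), default_ratio_limits("freshwater"))
#' @export
classify_site <- function(ratio, limits, censored = FALSE) {
  stopifnot(inherits(limits, "outlier_limits"))
  censored <- rep_len(as.logical(censored), length(ratio))
  out <- dplyr::case_when(
    censored | is.na(ratio) ~ "indeterminate",
    ratio > limits$upper ~ "hcb_elevated",
    ratio < limits$lower ~ "pecb_elevated",
    TRUE ~ "background"
  )
  out
}

#' Screen a ratio table against outlier limits
#'
#' @param ratio_records Tibble from [paired_ratios()] (needs a `ratio`
#'   column; an optional `censored` column is honoured).
#' @param limits An `outlier_limits` object, or `NULL` to pick
#'   [default_ratio_limits()] per record from a `matrix` column.
#' @return The input with a `classification` column appended.
#' @export
screen_ratios <- function(ratio_records, limits = NULL) {
  stopifnot(is.data.frame(ratio_records), "ratio" %in% names(ratio_records))
  out <- tibble::as_tibble(ratio_records)
  cens <- if ("censored" %in% names(out)) out$censored else FALSE
  if (is.null(limits)) {
    if (!"matrix" %in% names(out)) {
      stop("supply `limits` or a `matrix` column", call. = FALSE)
    }
    out$classification <- NA_character_
    for (m in unique(out$matrix)) {
      idx <- out$matrix == m
      lim <- default_ratio_limits(m)
      out$classification[idx] <-
        classify_site(out$ratio[idx], lim, rep_len(cens, nrow(out))[idx])
    }
  } else {
    out$classification <- classify_site(out$ratio, limits, cens)
  }
  out
}

#' Least-squares regression of one compound's Cw on another's
#'
#' Fits `y = slope * x` through the origin (default) or with a free
#' intercept, via [stats::lm()]. The through-origin slope is the natural
#' estimate of a constant concentration ratio across sites.
#'
#' @param x,y Paired concentrations (denominator and numerator compound).
#' @param intercept Fit a free intercept. Default `FALSE`.
#' @return A list: `slope`, `se`, `r_squared`, `p_value`, `intercept`
#'   (0 when through-origin), `n`, and the underlying `lm` fit.
#' @examples
#' regression_through_origin(c(1, 2, 3), c(4.1, 8.0, 12.5))
#' @export
regression_through_origin <- function(x, y, intercept = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 complete pairs for a regression", call. = FALSE)
  }
  if (any(x <= 0) || any(y <= 0)) {
    warning("non-positive concentrations in regression input", call. = FALSE)
  }
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x + 0)
  co <- summary(fit)$coefficients
  slope_row <- if (intercept) 2L else 1L
  list(
    slope = unname(co[slope_row, "Estimate"]),
    se = unname(co[slope_row, "Std. Error"]),
    r_squared = summary(fit)$r.squared,
    p_value = unname(co[slope_row, "Pr(>|t|)"]),
    intercept = if (intercept) unname(co[1L, "Estimate"]) else 0,
    n = length(x),
    fit = fit
  )
}

#' Benchmark target compounds against the diagnostic pair
#'
#' Expresses each target compound's freely dissolved concentration relative
#' to the HCB and PeCB concentrations of the same deployment, aggregates to
#' site medians, ranks sites by descending ratio and reports the
#' max/min span across sites. When `c_w` is unavailable for a deployment
#' but all involved compounds sampled in the linear regime, the
#' accumulated-mass ratio is used instead (the linear-uptake
#' approximation).
#'
#' @param cw_table Data frame with `deployment_id`, `compound`, `c_w`, and
#'   optionally `site_id`, `n_acc`, `deq`, `censored`.
#' @param targets Target compound names. Default `c("CB28", "CB52")`.
#' @param benchmarks Benchmark compound names. Default `c("HCB", "PeCB")`.
#' @param linear_cutoff DEQ limit under which the mass-ratio fallback is
#'   allowed. Default 0.05.
#' @return A tibble: `site_id`, `target`, `benchmark`, `ratio` (site
#'   median), `n`, `rank` (1 = highest ratio within target x benchmark),
#'   `basis` (`"cw"` or `"mass"`). Attribute `span`: a tibble of max/min
#'   ratio spans per target x benchmark.
#' @export
benchmark_targets <- function(cw_table, targets = c("CB28", "CB52"),
                              benchmarks = c("HCB", "PeCB"),
                              linear_cutoff = 0.05) {
  stopifnot(is.data.frame(cw_table),
            all(c("deployment_id", "compound", "c_w") %in% names(cw_table)))
  tab <- tibble::as_tibble(cw_table)
  if (!"site_id" %in% names(tab)) tab$site_id <- tab$deployment_id
  if (!"censored" %in% names(tab)) tab$censored <- is.na(tab$c_w)
  if (!"deq" %in% names(tab)) tab$deq <- NA_real_
  if (!"n_acc" %in% names(tab)) tab$n_acc <- NA_real_

  grab <- function(cmp, suffix) {
    tab |>
      dplyr::filter(.data$compound == cmp) |>
      dplyr::select("site_id", "deployment_id", "c_w", "n_acc", "deq",
                    "censored") |>
      dplyr::rename_with(\(x) paste0(x, suffix),
                         c("c_w", "n_acc", "deq", "censored"))
  }

  records <- list()
  for (tg in targets) {
    t_tab <- grab(tg, "_t")
    if (nrow(t_tab) == 0L) {
      warning("target '", tg, "' absent from the table", call. = FALSE)
      next
    }
    for (bm in benchmarks) {
      b_tab <- grab(bm, "_b")
      pairs <- dplyr::inner_join(t_tab, b_tab,
                                 by = c("site_id", "deployment_id"))
      if (nrow(pairs) == 0L) next
      pairs <- pairs |>
        dplyr::mutate(
          cw_ok = !.data$censored_t & !.data$censored_b &
            is.finite(.data$c_w_t) & is.finite(.data$c_w_b) &
            .data$c_w_b > 0,
          mass_ok = !.data$cw_ok &
            is.finite(.data$n_acc_t) & is.finite(.data$n_acc_b) &
            .data$n_acc_b > 0 &
            !.data$censored_t & !.data$censored_b &
            is.finite(.data$deq_t) & is.finite(.data$deq_b) &
            .data$deq_t < linear_cutoff & .data$deq_b < linear_cutoff,
          ratio = dplyr::case_when(
            .data$cw_ok ~ .data$c_w_t / .data$c_w_b,
            .data$mass_ok ~ .data$n_acc_t / .data$n_acc_b,
            TRUE ~ NA_real_
          ),
          basis = dplyr::case_when(
            .data$cw_ok ~ "cw", .data$mass_ok ~ "mass",
            TRUE ~ NA_character_
          )
        ) |>
        dplyr::filter(!is.na(.data$ratio))
      if (nrow(pairs) == 0L) next
      site <- pairs |>
        dplyr::summarise(
          ratio = stats::median(.data$ratio),
          n = dplyr::n(),
          basis = if (all(.data$basis == "cw")) "cw" else
            if (all(.data$basis == "mass")) "mass" else "mixed",
          .by = "site_id"
        ) |>
        dplyr::mutate(
          target = tg, benchmark = bm,
          rank = rank(-.data$ratio, ties.method = "min")
        )
      records[[paste(tg, bm)]] <- site
    }
  }
  if (length(records) == 0L) {
    warning("no benchmark ratios could be formed", call. = FALSE)
    out <- tibble::tibble(site_id = character(), target = character(),
                          benchmark = character(), ratio = numeric(),
                          n = integer(), basis = character(),
                          rank = integer())
    attr(out, "span") <- tibble::tibble(target = character(),
                                        benchmark = character(),
                                        span = numeric())
    return(out)
  }
  out <- dplyr::bind_rows(records) |>
    dplyr::select("site_id", "target", "benchmark", "ratio", "n", "rank",
                  "basis")
  span <- out |>
    dplyr::summarise(span = max(.data$ratio) / min(.data$ratio),
                     .by = c("target", "benchmark"))
  attr(out, "span") <- span
  out
}

#' Centred moving average of a timestamped series
#'
#' Mean over a centred time window: each point is replaced by the mean of
#' all observations within half a window of it, so the window shrinks
#' naturally at the series edges and across gaps.
#'
#' @param dates Date (or numeric time) vector.
#' @param values Numeric vector, same length.
#' @param window Window width in the units of `dates` (days for Dates).
#'   Default 7.
#' @return A tibble `date`, `value`, `smoothed`, ordered by date.
#' @export
moving_average <- function(dates, values, window = 7) {
  stopifnot(length(dates) == length(values), window > 0)
  if (length(dates) == 0L) {
    return(tibble::tibble(date = dates, value = values,
                          smoothed = numeric(0)))
  }
  ord <- order(dates)
  d <- as.numeric(dates[ord])
  v <- values[ord]
  half <- window / 2
  smoothed <- vapply(d, function(t0) {
    mean(v[abs(d - t0) <= half], na.rm = TRUE)
  }, numeric(1))
  tibble::tibble(date = dates[ord], value = v, smoothed = smoothed)
}
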