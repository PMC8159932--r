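# CSV readers/writers for the pipeline's interchange tables.
#
# All tables are plain RFC-4180 CSV, UTF-8, '.' decimal, ISO-8601 dates.
# Readers validate headers (a missing mandatory column is an error naming
# the column) and collect malformed rows into an error report attached as
# the "problems" attribute instead of silently dropping them.

table_schemas <- list(
  compounds = list(
    required = c("name", "molecular_weight"),
    optional = c("cas", "henry_ref", "t_ref", "vant_hoff_slope",
                 "log_ksw", "log_kdoc")
  ),
  deployments = list(
    required = c("deployment_id", "site_id", "duration", "sampler_mass"),
    optional = c("start_date", "end_date", "surface_area",
                 "water_temperature", "matrix")
  ),
  prc_observations = list(
    required = c("deployment_id", "log_ksw"),
    optional = c("prc_name", "n0", "nt", "fraction", "below_loq")
  ),
  uptakes = list(
    required = c("deployment_id", "compound", "n_acc"),
    optional = c("below_loq")
  )
)

validate_rows <- function(df, kind) {
  bad <- rep(FALSE, nrow(df))
  reason <- character(nrow(df))
  flag <- function(idx, why) {
    idx <- which(idx)
    idx <- idx[!bad[idx]]
    bad[idx] <<- TRUE
    reason[idx] <<- why
  }
  if (kind == "deployments") {
    flag(!is.finite(df$duration) | df$duration <= 0,
         "non-positive duration")
    flag(!is.finite(df$sampler_mass) | df$sampler_mass <= 0,
         "non-positive sampler_mass")
  }
  if (kind == "prc_observations") {
    if ("n0" %in% names(df)) flag(is.finite(df$n0) & df$n0 <= 0,
                                  "non-positive n0")
    flag(!is.finite(df$log_ksw), "missing log_ksw")
  }
  if (kind == "uptakes") {
    flag(!is.finite(df$n_acc) | df$n_acc < 0, "negative or missing n_acc")
  }
  if (kind == "compounds") {
    flag(!is.finite(df$molecular_weight) | df$molecular_weight <= 0,
         "non-positive molecular_weight")
  }
  list(ok = df[!bad, , drop = FALSE],
       problems = if (any(bad)) {
         tibble::tibble(row = which(bad), reason = reason[bad])
       } else {
         tibble::tibble(row = integer(), reason = character())
       })
}

#' Read a pipeline input table from CSV
#'
#' Schema-validated CSV reader for the four input table kinds. Missing
#' mandatory columns raise an error naming the column; rows failing
#' row-level validation (e.g. a deployment with negative sampler mass) are
#' removed, reported in a warning, and returned in the `"problems"`
#' attribute.
#'
#' @param path CSV file path.
#' @param kind One of `"compounds"`, `"deployments"`, `"prc_observations"`,
#'   `"uptakes"`.
#' @return A tibble of valid records with attribute `problems` (a tibble
#'   of row numbers and reasons).
#' @export
read_input_table <- function(path, kind = names(table_schemas)) {
  kind <- match.arg(kind)
  schema <- table_schemas[[kind]]
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(schema$required, names(df))
  if (length(missing)) {
    stop("'", path, "' (", kind, ") is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  checked <- validate_rows(df, kind)
  if (nrow(checked$problems) > 0L) {
    warning(nrow(checked$problems), " malformed row(s) removed from '",
            path, "': ",
            paste(unique(checked$problems$reason), collapse = "; "),
            call. = FALSE)
  }
  out <- tibble::as_tibble(checked$ok)
  attr(out, "problems") <- checked$problems
  out
}

#' Write a pipeline table to CSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_output_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Read a full input bundle from a directory
#'
#' Expects `deployments.csv` and `uptakes.csv`, plus optionally
#' `prc_observations.csv` and `compounds.csv`, in `dir`.
#'
#' @param dir Directory path.
#' @return A list with elements `deployments`, `uptakes`,
#'   `prc_observations` (`NULL` when absent) and `compounds` (`NULL` when
#'   absent).
#' @export
read_input_bundle <- function(dir) {
  need <- function(name, kind, required = TRUE) {
    p <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(p)) {
      if (required) stop("missing input file: ", p, call. = FALSE)
      return(NULL)
    }
    read_input_table(p, kind)
  }
  list(
    deployments = need("deployments", "deployments"),
    uptakes = need("uptakes", "uptakes"),
    prc_observations = need("prc_observations", "prc_observations",
                            required = FALSE),
    compounds = need("compounds", "compounds", required = FALSE)
  )
}

#' Write a scenario's input bundle to a directory
#'
#' Writes the tables of a [generate_scenario()] result (plus the truth
#' labels) as the CSV files [read_input_bundle()] expects.
#'
#' @param scenario A `"scenario"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_output_table(scenario$deployments,
                     file.path(dir, "deployments.csv"))
  write_output_table(scenario$prc_observations,
                     file.path(dir, "prc_observations.csv"))
  write_output_table(scenario$uptakes, file.path(dir, "uptakes.csv"))
  write_output_table(scenario$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
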