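# Compound property records and the default physico-chemical table.

#' Universal gas constant (Pa m3 mol-1 K-1)
#'
#' @format Length-one numeric.
#' @export
R_GAS <- 8.314

#' Create a compound property record
#'
#' A compound record carries the physico-chemical constants the sampler and
#' air-water exchange calculations need: molecular weight, a dimensionless
#' Henry's law constant at a reference temperature together with its van 't
#' Hoff slope, the log10 silicone (polymer)-water partition coefficient, and
#' optionally a log10 DOC-water partition coefficient.
#'
#' @param name Compound identifier, e.g. `"HCB"`.
#' @param molecular_weight Molecular weight, g/mol. Must be positive.
#' @param henry_ref Dimensionless Henry's law constant at `t_ref`. Positive.
#' @param t_ref Reference temperature for `henry_ref`, K. Default 293.15 K
#'   (20 degrees C), the temperature the shipped chlorobenzene constants
#'   refer to.
#' @param vant_hoff_slope Temperature slope d(ln H)/d(1/T), K. Applied
#'   literally as a positive coefficient; see [henry_at_temperature()].
#' @param log_ksw log10 polymer-water partition coefficient, L/kg. May be
#'   `NA` for compounds that never enter sampler calculations.
#' @param log_kdoc Optional log10 DOC-water partition coefficient, L/kg.
#' @param cas Optional CAS registry number.
#'
#' @return A list of class `"sr_compound"`.
#' @examples
#' hcb <- compound("HCB", 284.8, henry_ref = 0.015,
#'                 vant_hoff_slope = 6000, log_ksw = 4.51, log_kdoc = 4.4)
#' @export
compound <- function(name, molecular_weight, henry_ref = NA_real_,
                     t_ref = 293.15, vant_hoff_slope = NA_real_,
                     log_ksw = NA_real_, log_kdoc = NA_real_,
                     cas = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.na(molecular_weight) && molecular_weight <= 0) {
    stop("`molecular_weight` must be positive for ", name, call. = FALSE)
  }
  if (!is.na(henry_ref) && henry_ref <= 0) {
    stop("`henry_ref` must be positive for ", name, call. = FALSE)
  }
  if (t_ref <= 0) stop("`t_ref` must be positive (kelvin)", call. = FALSE)
  structure(
    list(
      name = name, cas = cas,
      molecular_weight = as.numeric(molecular_weight),
      henry_ref = as.numeric(henry_ref),
      t_ref = as.numeric(t_ref),
      vant_hoff_slope = as.numeric(vant_hoff_slope),
      log_ksw = as.numeric(log_ksw),
      log_kdoc = as.numeric(log_kdoc)
    ),
    class = "sr_compound"
  )
}

#' @export
print.sr_compound <- function(x, ...) {
  cat("<compound>", x$name,
      sprintf("MW %.1f g/mol", x$molecular_weight), "\n")
  cat(sprintf("  H = %.4g (dimensionless) at %.2f K, dlnH/d(1/T) = %.0f K\n",
              x$henry_ref, x$t_ref, x$vant_hoff_slope))
  cat(sprintf("  logKsw = %.2f L/kg, logKdoc = %.2f L/kg\n",
              x$log_ksw, x$log_kdoc))
  invisible(x)
}

#' Coerce to a compound record
#'
#' Accepts an `sr_compound`, a one-row data frame with the compound-table
#' columns, or a compound name to be looked up in `table`.
#'
#' @param x Compound record, one-row data frame, or name.
#' @param table Compound table used when `x` is a name; defaults to
#'   [default_compounds()].
#' @return An `sr_compound`.
#' @export
as_compound <- function(x, table = default_compounds()) {
  if (inherits(x, "sr_compound")) return(x)
  if (is.character(x) && length(x) == 1L) {
    hit <- table[table$name == x, , drop = FALSE]
    if (nrow(hit) != 1L) {
      stop("compound '", x, "' not found (or not unique) in compound table",
           call. = FALSE)
    }
    x <- hit
  }
  if (is.data.frame(x) && nrow(x) == 1L) {
    return(compound(
      name = x$name,
      molecular_weight = x$molecular_weight,
      henry_ref = if ("henry_ref" %in% names(x)) x$henry_ref else NA_real_,
      t_ref = if ("t_ref" %in% names(x)) x$t_ref else 293.15,
      vant_hoff_slope = if ("vant_hoff_slope" %in% names(x)) x$vant_hoff_slope else NA_real_,
      log_ksw = if ("log_ksw" %in% names(x)) x$log_ksw else NA_real_,
      log_kdoc = if ("log_kdoc" %in% names(x)) x$log_kdoc else NA_real_,
      cas = if ("cas" %in% names(x)) as.character(x$cas) else NA_character_
    ))
  }
  stop("cannot interpret `x` as a compound", call. = FALSE)
}

#' Default compound property table
#'
#' Ships the two diagnostic chlorobenzenes and the two benchmarked PCB
#' congeners. Dimensionless Henry's law constants are 0.015 (HCB) and 0.014
#' (PeCB) at 20 degrees C with van 't Hoff slopes of 6000 K and 5200 K.
#' The log Ksw values are representative AlteSil silicone-water partition
#' coefficients; they are inputs, not constants of nature, and can be
#' overridden by supplying a user table to any function that takes one.
#'
#' @return A tibble with columns `name`, `cas`, `molecular_weight`,
#'   `henry_ref`, `t_ref`, `vant_hoff_slope`, `log_ksw`, `log_kdoc`.
#' @examples
#' default_compounds()
#' @export
default_compounds <- function() {
  tibble::tibble(
    name = c("HCB", "PeCB", "CB28", "CB52"),
    cas = c("118-74-1", "608-93-5", "7012-37-5", "35693-99-3"),
    molecular_weight = c(284.8, 250.3, 257.5, 292.0),
    henry_ref = c(0.015, 0.014, NA, NA),
    t_ref = c(293.15, 293.15, 293.15, 293.15),
    vant_hoff_slope = c(6000, 5200, NA, NA),
    log_ksw = c(4.51, 4.17, 5.07, 5.42),
    log_kdoc = c(4.4, NA, NA, NA)
  )
}

#' Convert degrees Celsius to kelvin
#'
#' @param celsius Temperature in degrees C.
#' @return Temperature in K.
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15
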