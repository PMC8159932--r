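# Temperature-dependent Henry's law constants, air-water fugacity ratios and
# expected water-phase concentration ratios.

#' Henry's law constant at a given temperature
#'
#' Extrapolates a compound's dimensionless Henry's law constant from its
#' reference temperature using the van 't Hoff slope d(ln H)/d(1/T):
#' \deqn{H(T) = H_{ref} \exp(s \cdot (1/T - 1/T_{ref}))}
#'
#' By default the slope is applied literally as printed in the compound
#' table (`sign_convention = "literal"`). With the shipped chlorobenzene
#' constants this convention yields a PeCB/HCB Henry ratio of 0.76 at 0
#' degrees C rising to 1.02 at 30 degrees C. The thermodynamically
#' conventional reading of a positive d(ln H)/d(1/T) slope would make H
#' decrease with temperature; `sign_convention = "thermodynamic"` flips the
#' sign for users whose slope tables follow that convention.
#'
#' @param compound A compound record (see [as_compound()]) with `henry_ref`,
#'   `t_ref` and `vant_hoff_slope` set.
#' @param temperature Water/air temperature in K. Values outside 263-313 K
#'   trigger a warning; non-positive values are an error.
#' @param sign_convention `"literal"` (default) applies the slope with a
#'   positive sign; `"thermodynamic"` negates it.
#' @return Dimensionless Henry's law constant at `temperature`.
#' @examples
#' hcb <- as_compound("HCB")
#' henry_at_temperature(hcb, 293.15)  # 0.015, the reference value
#' henry_at_temperature(hcb, 273.15)
#' @export
henry_at_temperature <- function(compound, temperature,
                                 sign_convention = c("literal", "thermodynamic")) {
  compound <- as_compound(compound)
  sign_convention <- match.arg(sign_convention)
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  }
  if (any(temperature < 263 | temperature > 313)) {
    warning("temperature outside 263-313 K: van 't Hoff extrapolation is ",
            "far from the calibrated range", call. = FALSE)
  }
  if (is.na(compound$henry_ref) || is.na(compound$vant_hoff_slope)) {
    stop("compound '", compound$name,
         "' lacks `henry_ref` or `vant_hoff_slope`", call. = FALSE)
  }
  s <- compound$vant_hoff_slope
  if (sign_convention == "thermodynamic") s <- -s
  compound$henry_ref * exp(s * (1 / temperature - 1 / compound$t_ref))
}

#' Ratio of two compounds' Henry's law constants
#'
#' @param numerator,denominator Compound records or names.
#' @param temperature Temperature in K.
#' @inheritParams henry_at_temperature
#' @return Dimensionless ratio H(numerator) / H(denominator).
#' @examples
#' henry_ratio("PeCB", "HCB", 288.15)  # about 0.89 at 15 degrees C
#' @export
henry_ratio <- function(numerator, denominator, temperature,
                        sign_convention = c("literal", "thermodynamic")) {
  sign_convention <- match.arg(sign_convention)
  henry_at_temperature(numerator, temperature, sign_convention) /
    henry_at_temperature(denominator, temperature, sign_convention)
}

#' Water/air fugacity ratio
#'
#' Ratio of a chemical's fugacity in water to its fugacity in air,
#' \deqn{f_w / f_a = C_w H / (C_a R T)}
#' where H is the Henry's law constant in Pa m3/mol and R the universal gas
#' constant. Because the compound table stores the dimensionless H, it is
#' converted internally via H_Pa = H_dimensionless * R * T. A value of 1
#' indicates air-water phase equilibrium; above 1 the net flux is
#' volatilisation, below 1 net deposition.
#'
#' Concentrations must be on a molar basis (mol/m3) or on a mass basis with
#' identical units in numerator and denominator (the molecular weight then
#' cancels).
#'
#' @param c_water Freely dissolved concentration in water.
#' @param c_air Vapour-phase concentration in air (same units as `c_water`).
#' @param compound Compound record or name.
#' @param temperature Temperature, K.
#' @inheritParams henry_at_temperature
#' @return Dimensionless fugacity ratio.
#' @export
fugacity_ratio <- function(c_water, c_air, compound, temperature,
                           sign_convention = c("literal", "thermodynamic")) {
  sign_convention <- match.arg(sign_convention)
  if (any(c_water <= 0) || any(c_air <= 0)) {
    stop("`c_water` and `c_air` must be positive", call. = FALSE)
  }
  h_dimless <- henry_at_temperature(compound, temperature, sign_convention)
  h_pa <- h_dimless * R_GAS * temperature
  (c_water * h_pa) / (c_air * R_GAS * temperature)
}

#' Expected water-phase concentration ratio from an air-phase ratio
#'
#' Under air-water phase equilibrium for both members of a compound pair,
#' the water concentration ratio follows from the air ratio and the two
#' Henry's law constants:
#' \deqn{C_{w,a}/C_{w,b} = (C_{air,a}/C_{air,b}) \cdot H_b / H_a}
#'
#' Molecular-weight conversions between mass and molar concentrations apply
#' to both phases and cancel, so a mass-basis air ratio maps to a mass-basis
#' water ratio with the same factor; the MW ratio itself is available from
#' [molecular_weight_factor()] for reporting.
#'
#' @param air_ratio Air-phase concentration ratio a/b (positive).
#' @param temperature Temperature, K.
#' @param numerator,denominator Compounds of the ratio's numerator (a) and
#'   denominator (b).
#' @inheritParams henry_at_temperature
#' @return Expected water-phase ratio a/b.
#' @examples
#' # median European air HCB/PeCB ratio mapped to water at 20 degrees C
#' expected_water_ratio(4.59, 293.15, "HCB", "PeCB")
#' @export
expected_water_ratio <- function(air_ratio, temperature,
                                 numerator = "HCB", denominator = "PeCB",
                                 sign_convention = c("literal", "thermodynamic")) {
  sign_convention <- match.arg(sign_convention)
  if (any(air_ratio <= 0)) stop("`air_ratio` must be positive", call. = FALSE)
  air_ratio * henry_ratio(denominator, numerator, temperature, sign_convention)
}

#' Molecular-weight ratio of a compound pair
#'
#' The factor converting between molar and mass concentration ratios of two
#' compounds; for HCB/PeCB it is 284.8/250.3 = 1.138.
#'
#' @param numerator,denominator Compound records or names.
#' @return Dimensionless MW ratio.
#' @export
molecular_weight_factor <- function(numerator = "HCB", denominator = "PeCB") {
  as_compound(numerator)$molecular_weight /
    as_compound(denominator)$molecular_weight
}
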