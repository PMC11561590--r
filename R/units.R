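#' Temperature unit conversion
#'
#' All internal computation in this package is in kelvin; user-facing
#' interfaces (configs, traces, reports) speak Celsius. These two helpers are
#' the only conversion path, so sign conventions cannot drift.
#'
#' @param t_c,t_k temperature in degrees Celsius / kelvin (vectorised)
#' @return numeric vector in the other unit
#' @export
celsius_to_kelvin <- function(t_c) t_c + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(t_k) t_k - 273.15

# latent heat of fusion of pure water, J/kg
.L_WATER <- 333.55e3

`%||%` <- function(a, b) if (is.null(a)) b else a

# cryoscopic constant of water, K kg/mol
.KF_WATER <- 1.853
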