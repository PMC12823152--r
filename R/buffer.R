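# Density and viscosity of H2O/D2O (PBS) mixtures at run temperature.
#
# Reference tables (0-40 C in 5 C steps) for light and heavy water:
#   - H2O density: CRC Handbook of Chemistry and Physics, g/mL.
#   - H2O viscosity: IAPWS-consistent handbook values, poise.
#   - D2O density: CRC Handbook (Kell), g/mL; the 0 C entry is a short
#     extrapolation below the D2O melting point (3.8 C), only reachable for
#     supercooled mixtures.
#   - D2O/H2O viscosity ratio: Hardy & Cottington-type handbook values.
# Mixtures are modeled by linear interpolation in D2O volume fraction; salt
# content enters as a constant density increment plus a viscosity
# multiplier. Explicit (rho, eta) overrides bypass the tables entirely.

.BUFFER_T_C <- seq(0, 40, by = 5)
.H2O_RHO <- c(0.99987, 0.99999, 0.99973, 0.99913, 0.99823,
              0.99707, 0.99567, 0.99406, 0.99224)
.H2O_ETA <- c(1.7916, 1.5192, 1.3069, 1.1382, 1.0016,
              0.8937, 0.8007, 0.7225, 0.6560) / 100
.D2O_RHO <- c(1.10469, 1.10562, 1.10599, 1.10587, 1.10534,
              1.10445, 1.10323, 1.10173, 1.09996)
.D2O_ETA_RATIO <- c(1.289, 1.276, 1.265, 1.254, 1.244,
                    1.233, 1.224, 1.215, 1.207)

interp_table <- function(y, t_celsius) {
  stats::spline(.BUFFER_T_C, y, xout = t_celsius, method = "fmm")$y
}

#' Describe an H2O/D2O buffer
#'
#' @param d2o_fraction D2O volume fraction, between 0 and 1.
#' @param density_increment Additional solvent density contributed by salts,
#'   g/mL. The default 0.0046 corresponds to 1x phosphate-buffered saline;
#'   because the salt is reconstituted in D2O as well, the increment applies
#'   at every D2O fraction. Use 0 for pure water mixtures.
#' @param viscosity_multiplier Multiplier on the mixture viscosity for salt
#'   effects (default 1).
#' @param temperature Absolute temperature, K. Must lie within the tabulated
#'   0-40 C range.
#' @param rho_override,eta_override Optional explicit solvent density (g/mL)
#'   and viscosity (poise); when given they bypass the reference tables.
#' @return An object of class `buffer_spec`.
#' @export
#' @examples
#' buffer_state(buffer_spec(0, density_increment = 0))      # water at 20 C
#' buffer_state(buffer_spec(0.15))                          # 15% D2O in PBS
buffer_spec <- function(d2o_fraction = 0, density_increment = 0.0046,
                        viscosity_multiplier = 1, temperature = 293.15,
                        rho_override = NULL, eta_override = NULL) {
  if (d2o_fraction < 0 || d2o_fraction > 1)
    stop("d2o_fraction must be within [0, 1]")
  if (temperature <= 0) stop("temperature must be positive (kelvin)")
  structure(list(d2o_fraction = d2o_fraction,
                 density_increment = density_increment,
                 viscosity_multiplier = viscosity_multiplier,
                 temperature = temperature,
                 rho_override = rho_override,
                 eta_override = eta_override),
            class = "buffer_spec")
}

#' @export
print.buffer_spec <- function(x, ...) {
  st <- buffer_state(x)
  cat(sprintf(paste0("<buffer_spec> %.0f%% D2O, increment %.4f g/mL, ",
                     "T = %.2f K -> rho = %.5f g/mL, eta = %.6f poise\n"),
              100 * x$d2o_fraction, x$density_increment, x$temperature,
              st$rho, st$eta))
  invisible(x)
}

#' Realize solvent density and viscosity from a buffer description
#'
#' Density is the linear volume-fraction interpolation between the H2O and
#' D2O reference densities at the run temperature, plus the salt density
#' increment. Viscosity applies the interpolated D2O/H2O viscosity ratio to
#' the H2O viscosity at temperature, times the salt viscosity multiplier.
#' Explicit overrides win over the tables.
#'
#' @param spec A [buffer_spec()] (a `buffer_state` passes through).
#' @return A [solvent_state()] object.
#' @export
buffer_state <- function(spec) {
  if (inherits(spec, "buffer_state")) return(spec)
  if (!inherits(spec, "buffer_spec")) stop("expected a buffer_spec")
  t_c <- spec$temperature - 273.15
  if (t_c < 0 || t_c > 40)
    stop(sprintf("temperature %.2f C outside the tabulated 0-40 C range", t_c))
  f <- spec$d2o_fraction
  rho <- if (!is.null(spec$rho_override)) spec$rho_override else {
    h2o <- interp_table(.H2O_RHO, t_c)
    d2o <- interp_table(.D2O_RHO, t_c)
    (1 - f) * h2o + f * d2o + spec$density_increment
  }
  eta <- if (!is.null(spec$eta_override)) spec$eta_override else {
    eta_h2o <- interp_table(.H2O_ETA, t_c)
    ratio <- interp_table(.D2O_ETA_RATIO, t_c)
    eta_h2o * ((1 - f) + f * ratio) * spec$viscosity_multiplier
  }
  solvent_state(rho, eta, spec$temperature)
}
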