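# Hydrodynamic relations connecting molar mass, partial specific volume,
# frictional ratio, sedimentation and diffusion coefficients. All internal
# quantities are CGS: cm, g, s, poise, erg; sedimentation coefficients are
# stored in seconds (1 Svedberg = 1e-13 s) and only converted for display.

#' Construct a solvent state (density, viscosity, temperature)
#'
#' Low-level container consumed by every hydrodynamic conversion. Most users
#' will build it from a buffer description via [buffer_state()] instead.
#'
#' @param rho Solvent density, g/mL.
#' @param eta Solvent viscosity, poise.
#' @param temperature Absolute temperature, K.
#' @return An object of class `buffer_state`.
#' @export
#' @examples
#' water20 <- solvent_state(0.99823, 0.010016, 293.15)
solvent_state <- function(rho, eta, temperature) {
  stopifnot(is.numeric(rho), is.numeric(eta), is.numeric(temperature),
            length(rho) == 1, length(eta) == 1, length(temperature) == 1)
  if (rho <= 0) stop("solvent density must be positive")
  if (eta <= 0) stop("solvent viscosity must be positive")
  if (temperature <= 0) stop("temperature must be positive (kelvin)")
  structure(list(rho = rho, eta = eta, temperature = temperature),
            class = "buffer_state")
}

#' @export
print.buffer_state <- function(x, ...) {
  cat(sprintf("<buffer_state> rho = %.5f g/mL, eta = %.6f poise, T = %.2f K\n",
              x$rho, x$eta, x$temperature))
  invisible(x)
}

as_buffer_state <- function(x) {
  if (inherits(x, "buffer_state")) return(x)
  if (inherits(x, "buffer_spec")) return(buffer_state(x))
  if (is.list(x) && all(c("rho", "eta", "temperature") %in% names(x)))
    return(solvent_state(x$rho, x$eta, x$temperature))
  stop("expected a buffer_state, buffer_spec, or list(rho, eta, temperature)")
}

#' Buoyancy term 1 - vbar * rho
#'
#' The sign of the buoyancy term decides the direction of radial transport:
#' positive means sedimentation toward the cell bottom, negative means
#' flotation toward the meniscus, and zero is the density-match point where
#' only diffusion transport remains.
#'
#' @param vbar Partial specific volume, mL/g (apparent value of the whole
#'   particle, including hydration and bound ions).
#' @param rho Solvent density, g/mL.
#' @return Dimensionless buoyancy term, vectorized over its arguments.
#' @export
#' @examples
#' buoyancy(0.98, 0.99823)   #  0.0217 -> sediments
#' buoyancy(1.02, 1.02)      #  negative -> floats
buoyancy <- function(vbar, rho) {
  if (any(vbar <= 0)) stop("vbar must be positive")
  if (any(rho <= 0)) stop("rho must be positive")
  1 - vbar * rho
}

check_buoyancy_exclusion <- function(vbar, rho, exclusion = .BUOYANCY_EXCLUSION) {
  bad <- abs(buoyancy(vbar, rho)) < exclusion
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(paste0("buoyancy exclusion: |1 - vbar*rho| < %g at vbar = %g, ",
                        "rho = %g (%d point(s)); too close to the density ",
                        "match point for a parameterized conversion"),
                 exclusion, vbar[min(i, length(vbar))],
                 rho[min(i, length(rho))], sum(bad)))
  }
  invisible(TRUE)
}

#' Derive all hydrodynamic quantities of a solute from (M, vbar, alpha)
#'
#' Applies the forward chain: particle volume `V = M vbar / N`, minimal
#' sphere radius `R0 = (3V / 4 pi)^(1/3)`, minimal frictional coefficient
#' `f0 = 6 pi eta R0`, actual frictional coefficient `f = alpha f0`,
#' diffusion coefficient `D = R T / (N f)` and sedimentation coefficient
#' `s = M (1 - vbar rho) / (N f)` (the Svedberg relation). The hydrodynamic
#' radius is `Rh = f / (6 pi eta) = alpha R0`.
#'
#' @param M Molar mass, g/mol. Vectorized.
#' @param vbar Partial specific volume, mL/g. Vectorized.
#' @param alpha Frictional ratio f/f0 (>= 1). Vectorized.
#' @param buffer A [solvent_state()] / [buffer_spec()].
#' @return A data frame with one row per solute and columns
#'   `M, vbar, alpha, s` (seconds), `D` (cm^2/s), `f` (g/s), `V` (cm^3),
#'   `R0` (cm), `f0` (g/s), `Rh` (cm).
#' @export
#' @examples
#' w <- solvent_state(0.99823, 0.010016, 293.15)
#' sol <- solute_from_mass(1e8, 0.98, 1.1, w)
#' sol$s / 1e-13   # sedimentation coefficient in Svedberg (about 51 S)
#' sol$Rh * 1e7    # hydrodynamic radius in nm (about 37 nm)
solute_from_mass <- function(M, vbar, alpha, buffer) {
  buffer <- as_buffer_state(buffer)
  n <- max(length(M), length(vbar), length(alpha))
  M <- rep_len(M, n); vbar <- rep_len(vbar, n); alpha <- rep_len(alpha, n)
  if (any(M <= 0)) stop("molar mass must be positive")
  if (any(vbar <= 0)) stop("vbar must be positive")
  if (any(alpha < 1)) stop("frictional ratio alpha must be >= 1")
  V <- M * vbar / .NAVO
  R0 <- (3 * V / (4 * pi))^(1 / 3)
  f0 <- 6 * pi * buffer$eta * R0
  f <- alpha * f0
  D <- .RGAS * buffer$temperature / (.NAVO * f)
  s <- M * buoyancy(vbar, buffer$rho) / (.NAVO * f)
  data.frame(M = M, vbar = vbar, alpha = alpha, s = s, D = D, f = f,
             V = V, R0 = R0, f0 = f0, Rh = alpha * R0)
}

#' Diffusion coefficient from (s, alpha, vbar) at fixed frictional ratio
#'
#' The grid parameterization: with the frictional ratio held fixed, D is a
#' closed-form function of the sedimentation coefficient, the partial
#' specific volume, and the solvent,
#' `D = R T / (N 18 pi (alpha eta)^(3/2) sqrt(s vbar / (2 (1 - vbar rho))))`.
#' Valid on either side of the density match point as long as the sign of s
#' is consistent with the sign of the buoyancy term.
#'
#' @param s Sedimentation coefficient, seconds (negative for flotation).
#' @param alpha Frictional ratio (>= 1).
#' @param vbar Partial specific volume, mL/g.
#' @param buffer A [solvent_state()] / [buffer_spec()].
#' @param exclusion Buoyancy exclusion threshold on `|1 - vbar rho|`.
#' @return Diffusion coefficient(s), cm^2/s.
#' @export
D_from_s_alpha_vbar <- function(s, alpha, vbar, buffer,
                                exclusion = .BUOYANCY_EXCLUSION) {
  buffer <- as_buffer_state(buffer)
  n <- max(length(s), length(alpha), length(vbar))
  s <- rep_len(s, n); alpha <- rep_len(alpha, n); vbar <- rep_len(vbar, n)
  if (any(alpha < 1)) stop("frictional ratio alpha must be >= 1")
  check_buoyancy_exclusion(vbar, buffer$rho, exclusion)
  b <- buoyancy(vbar, buffer$rho)
  radicand <- s * vbar / (2 * b)
  if (any(radicand <= 0))
    stop(paste0("buoyancy exclusion: sign of s inconsistent with sign of ",
                "1 - vbar*rho (radicand s*vbar/(2(1-vbar*rho)) <= 0)"))
  .RGAS * buffer$temperature /
    (.NAVO * 18 * pi * (alpha * buffer$eta)^1.5 * sqrt(radicand))
}

#' Molar mass from the Svedberg equation
#'
#' `M = s R T / (D (1 - vbar rho))`; the inverse of [solute_from_mass()].
#'
#' @inheritParams D_from_s_alpha_vbar
#' @param D Diffusion coefficient, cm^2/s.
#' @return Molar mass, g/mol.
#' @export
mass_from_sD <- function(s, D, vbar, buffer, exclusion = .BUOYANCY_EXCLUSION) {
  buffer <- as_buffer_state(buffer)
  if (any(D <= 0)) stop("diffusion coefficient must be positive")
  check_buoyancy_exclusion(vbar, buffer$rho, exclusion)
  b <- buoyancy(vbar, buffer$rho)
  if (any(sign(s) * sign(b) < 0))
    stop("sign of s inconsistent with sign of the buoyancy term")
  s * .RGAS * buffer$temperature / (D * b)
}

#' Full solute description from (s, vbar) coordinates at fixed alpha
#'
#' The grid-coordinate conversion: D via the fixed-alpha parameterization
#' ([D_from_s_alpha_vbar()]), then M, f and Rh via the Svedberg and
#' Stokes-Einstein relations. Vectorized over `s` and `vbar`.
#'
#' @inheritParams D_from_s_alpha_vbar
#' @return A solute data frame in the same layout as [solute_from_mass()].
#' @export
solute_from_s_vbar <- function(s, vbar, alpha, buffer,
                               exclusion = .BUOYANCY_EXCLUSION) {
  buffer <- as_buffer_state(buffer)
  n <- max(length(s), length(vbar))
  s <- rep_len(s, n); vbar <- rep_len(vbar, n)
  D <- D_from_s_alpha_vbar(s, alpha, vbar, buffer, exclusion)
  M <- mass_from_sD(s, D, vbar, buffer, exclusion)
  f <- .RGAS * buffer$temperature / (.NAVO * D)
  Rh <- f / (6 * pi * buffer$eta)
  data.frame(M = M, vbar = vbar, alpha = alpha, s = s, D = D, f = f,
             V = M * vbar / .NAVO, R0 = Rh / alpha, f0 = f / alpha, Rh = Rh)
}

#' Convert sedimentation coefficients between seconds and Svedberg
#'
#' @param s Value(s) in seconds.
#' @return Value(s) in Svedberg (1 S = 1e-13 s).
#' @export
to_svedberg <- function(s) s / .SVEDBERG

#' @rdname to_svedberg
#' @param S Value(s) in Svedberg.
#' @export
from_svedberg <- function(S) S * .SVEDBERG
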