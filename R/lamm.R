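# R surface of the finite-volume Lamm equation solver. The transport PDE
#   dC/dt = -(1/r) d/dr [ s w^2 r^2 C - D r dC/dr ],   m < r < b
# is solved on a fixed uniform radial grid with a conservative
# Scharfetter-Gummel (exponential fitting) flux and adaptive backward-Euler
# time stepping (see src/lamm.cpp). Flotation (s < 0) uses the same
# discretization; no reflection tricks.

#' Sector-cell geometry
#'
#' @param meniscus Meniscus radius, cm.
#' @param bottom Cell bottom radius, cm.
#' @param sector_angle Sector angle in radians (metadata only).
#' @param pathlength Optical pathlength, cm (metadata only).
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(meniscus, bottom, sector_angle = 2.5 * pi / 180,
                          pathlength = 1.2) {
  if (!(meniscus > 0)) stop("meniscus must be positive")
  if (!(bottom > meniscus)) stop("bottom must exceed meniscus")
  structure(list(meniscus = meniscus, bottom = bottom,
                 sector_angle = sector_angle, pathlength = pathlength),
            class = "cell_geometry")
}

#' Assemble a sedimentation-velocity scan set
#'
#' A scan set holds the geometry, rotor speed, solvent description and the
#' time-ordered radial signal profiles of one experiment. All scans share a
#' common, strictly increasing radius vector.
#'
#' @param geometry A [cell_geometry()].
#' @param buffer A [buffer_spec()] or [solvent_state()].
#' @param omega Rotor angular velocity, rad/s (see [rpm_to_omega()]).
#' @param times Seconds since the start of sedimentation, strictly increasing.
#' @param radii Common radius vector, cm, strictly increasing.
#' @param signal Matrix of signal values, `length(times)` rows by
#'   `length(radii)` columns.
#' @param temperature Absolute temperature, K.
#' @param wavelength Detection wavelength, nm (metadata).
#' @return An object of class `scan_set`.
#' @export
scan_set <- function(geometry, buffer, omega, times, radii, signal,
                     temperature = 293.15, wavelength = NA_real_) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (any(diff(times) <= 0)) stop("scan times must be strictly increasing")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  signal <- as.matrix(signal)
  if (nrow(signal) != length(times) || ncol(signal) != length(radii))
    stop("signal must be a length(times) x length(radii) matrix")
  if (any(!is.finite(signal))) stop("signal must be finite")
  structure(list(geometry = geometry, buffer = buffer, omega = omega,
                 times = times, radii = radii, signal = signal,
                 temperature = temperature, wavelength = wavelength),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf(paste0("<scan_set> %d scans x %d radii, t = %.0f..%.0f s, ",
                     "omega = %.0f rad/s, column [%.3f, %.3f] cm\n"),
              length(x$times), length(x$radii), min(x$times), max(x$times),
              x$omega, x$geometry$meniscus, x$geometry$bottom))
  invisible(x)
}

#' Convert rotor speed in revolutions per minute to rad/s
#' @param rpm Rotor speed, revolutions per minute.
#' @return Angular velocity, rad/s.
#' @export
rpm_to_omega <- function(rpm) rpm * 2 * pi / 60

# Solve for one (s, D) pair on the solver's uniform node grid, then
# (optionally) interpolate to a requested radius vector; radii outside the
# solution column read zero signal (air above the meniscus, below-bottom).
lamm_profiles <- function(s, D, geometry, omega, times, loading = 1,
                          radii = NULL, n_radii = 600, tol = 1e-6,
                          max_steps = 500000L) {
  m <- geometry$meniscus; b <- geometry$bottom
  raw <- .lamm_solve_cpp(s, D, m, b, omega, as.numeric(times), loading,
                         as.integer(n_radii), tol, as.integer(max_steps))
  attr(raw, "radii_step") <- NULL
  attr(raw, "n_steps") <- NULL
  nodes <- seq(m, b, length.out = n_radii)
  if (is.null(radii)) {
    return(list(radii = nodes, signal = raw))
  }
  out <- matrix(0, nrow = length(times), ncol = length(radii))
  inside <- radii >= m & radii <= b
  if (any(inside)) {
    for (k in seq_along(times))
      out[k, inside] <- approx(nodes, raw[k, ], xout = radii[inside])$y
  }
  list(radii = radii, signal = out)
}

#' Simulate sedimentation of a single solute
#'
#' Produces a mass-conserving numerical solution of the Lamm equation with
#' zero-flux conditions at the meniscus and bottom, starting from a uniform
#' loading concentration. Works identically for sedimenting (s > 0) and
#' floating (s < 0) solutes.
#'
#' @param solute A one-row data frame with columns `s` (seconds) and `D`
#'   (cm^2/s), e.g. from [solute_from_mass()], or a list with those fields.
#' @param geometry A [cell_geometry()].
#' @param omega Rotor angular velocity, rad/s.
#' @param times Output times, seconds, non-decreasing.
#' @param loading_conc Initial uniform concentration, signal units.
#' @param radii Optional radius vector to report on; defaults to the
#'   solver's own node grid. Radii outside the column read zero.
#' @param n_radii Number of solver nodes across the column (default 600).
#' @param tol Local time-stepping error tolerance, relative to loading.
#' @param max_steps Step budget before the solver reports a step-control
#'   failure.
#' @param buffer,temperature,wavelength Metadata attached to the result.
#' @return A [scan_set()].
#' @export
#' @examples
#' w <- solvent_state(0.99823, 0.010016, 293.15)
#' sol <- solute_from_mass(5e7, 0.97, 1.1, w)
#' sim <- simulate_solute(sol, cell_geometry(5.9, 7.2),
#'                        rpm_to_omega(30000), times = c(600, 1800),
#'                        n_radii = 120)
simulate_solute <- function(solute, geometry, omega, times, loading_conc = 1,
                            radii = NULL, n_radii = 600, tol = 1e-6,
                            max_steps = 500000L, buffer = NULL,
                            temperature = 293.15, wavelength = NA_real_) {
  if (!is.finite(solute$s[1])) stop("solute s must be finite")
  if (!(solute$D[1] > 0)) stop("solute D must be positive")
  if (any(times < 0)) stop("times must be non-negative")
  pr <- lamm_profiles(solute$s[1], solute$D[1], geometry, omega, times,
                      loading_conc, radii, n_radii, tol, max_steps)
  scan_set(geometry, buffer, omega, times, pr$radii, pr$signal,
           temperature = temperature, wavelength = wavelength)
}

#' Simulate a mixture of solutes by superposition
#'
#' The Lamm equation is linear in concentration, so a mixture is the
#' amplitude-weighted sum of single-solute solutions.
#'
#' @param solutes Data frame with columns `s` and `D`, one row per species.
#' @param amplitudes Non-negative loading amplitude per species, signal units.
#' @inheritParams simulate_solute
#' @return A [scan_set()].
#' @export
simulate_mixture <- function(solutes, amplitudes, geometry, omega, times,
                             radii = NULL, n_radii = 600, tol = 1e-6,
                             buffer = NULL, temperature = 293.15,
                             wavelength = NA_real_) {
  if (nrow(as.data.frame(solutes)) != length(amplitudes))
    stop("one amplitude per solute required")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  nodes <- if (is.null(radii))
    seq(geometry$meniscus, geometry$bottom, length.out = n_radii) else radii
  total <- matrix(0, nrow = length(times), ncol = length(nodes))
  for (i in seq_along(amplitudes)) {
    if (amplitudes[i] == 0) next
    pr <- lamm_profiles(solutes$s[i], solutes$D[i], geometry, omega, times,
                        1, nodes, n_radii, tol)
    total <- total + amplitudes[i] * pr$signal
  }
  scan_set(geometry, buffer, omega, times, nodes, total,
           temperature = temperature, wavelength = wavelength)
}

#' Total mass in the cell per scan
#'
#' Trapezoidal integral of `C r dr` over the radius vector, per scan; with
#' zero-flux boundaries this is conserved over time.
#'
#' @param scans A [scan_set()].
#' @return Numeric vector, one value per scan.
#' @export
scan_mass <- function(scans) {
  r <- scans$radii
  wts <- diff(r)
  apply(scans$signal, 1, function(ci) {
    f <- ci * r
    sum(0.5 * (f[-1] + f[-length(f)]) * wts)
  })
}
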