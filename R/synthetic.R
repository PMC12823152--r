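# Synthetic LNP-like experiments: lognormal size / normal density
# populations, simulated across a D2O density series with seeded TI/RI and
# Gaussian noise, with the generating ground truth carried alongside so
# every downstream module can be tested for recovery without downloads.

#' One population component
#'
#' Sizes are drawn lognormal in the hydrodynamic radius (`mean_rh_nm` is
#' the geometric mean / median), densities normal in vbar; both are
#' truncated at `trunc_sd` standard deviations so a component's draws stay
#' inside a well-defined window. Size and density are drawn independently.
#'
#' @param mean_rh_nm Geometric mean hydrodynamic radius, nm.
#' @param rh_lnsd Log-standard deviation of Rh.
#' @param mean_vbar Mean partial specific volume, mL/g.
#' @param vbar_sd Standard deviation of vbar, mL/g.
#' @param alpha Frictional ratio (default 1.1, near-spherical particles).
#' @param signal Total signal (e.g. OD) carried by the component.
#' @param trunc_sd Truncation half-width in standard deviations.
#' @return A list of class `population_component`.
#' @export
population_component <- function(mean_rh_nm, rh_lnsd, mean_vbar, vbar_sd,
                                 alpha = 1.1, signal = 0.8, trunc_sd = 2) {
  stopifnot(mean_rh_nm > 0, rh_lnsd >= 0, mean_vbar > 0, vbar_sd >= 0,
            alpha >= 1, signal >= 0, trunc_sd > 0)
  structure(list(mean_rh_nm = mean_rh_nm, rh_lnsd = rh_lnsd,
                 mean_vbar = mean_vbar, vbar_sd = vbar_sd, alpha = alpha,
                 signal = signal, trunc_sd = trunc_sd),
            class = "population_component")
}

#' Population specification
#'
#' @param components List of [population_component()]s (a single component
#'   may be passed bare).
#' @param n_draws Number of particles drawn per component.
#' @param seed Default seed used by [sample_population()].
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(components, n_draws = 30, seed = 42) {
  if (inherits(components, "population_component"))
    components <- list(components)
  stopifnot(length(components) >= 1, n_draws >= 1)
  structure(list(components = components, n_draws = as.integer(n_draws),
                 seed = seed),
            class = "population_spec")
}

rtrunc_norm <- function(n, mean, sd, trunc_sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(-trunc_sd); hi <- stats::pnorm(trunc_sd)
  mean + sd * stats::qnorm(lo + (hi - lo) * runif(n))
}

#' Draw a particle population
#'
#' Each draw gets an Rh (lognormal, truncated), a vbar (normal, truncated)
#' and an equal share of its component's signal; the molar mass follows by
#' inverting the minimal-sphere relations: `R0 = Rh/alpha`,
#' `V = 4/3 pi R0^3`, `M = V N / vbar`. Deterministic for a given seed.
#'
#' @param spec A [population_spec()].
#' @param seed Seed; defaults to the spec's.
#' @return Data frame with columns `component, M, vbar, alpha, Rh`
#'   (cm), `Rh_nm`, `amplitude`.
#' @export
sample_population <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    pieces <- lapply(seq_along(spec$components), function(i) {
      cp <- spec$components[[i]]
      z <- rtrunc_norm(spec$n_draws, 0, 1, cp$trunc_sd)
      rh_nm <- cp$mean_rh_nm * exp(cp$rh_lnsd * z)
      vbar <- rtrunc_norm(spec$n_draws, cp$mean_vbar, cp$vbar_sd, cp$trunc_sd)
      rh <- rh_nm * 1e-7
      r0 <- rh / cp$alpha
      M <- (4 / 3) * pi * r0^3 * .NAVO / vbar
      data.frame(component = i, M = M, vbar = vbar, alpha = cp$alpha,
                 Rh = rh, Rh_nm = rh_nm,
                 amplitude = cp$signal / spec$n_draws)
    })
    do.call(rbind, pieces)
  })
}

#' Lipid-nanoparticle population presets
#'
#' Four formulation archetypes spanning the characteristic density and
#' size windows of empty, protein-conjugated, mRNA-loaded, and
#' protein-conjugated mRNA-loaded LNPs. Densities are narrow (empty LNPs
#' near 0.991 mL/g, cargo-loaded formulations denser, near 0.978-0.983
#' mL/g); sizes are broad for empty LNPs and tighten with cargo or
#' conjugation. All presets use a near-spherical frictional ratio of 1.1.
#'
#' @param n_draws Draws per component.
#' @return Named list of [population_spec()]s:
#'   `empty`, `LNP-P`, `LNP-mRNA`, `LNP-P-mRNA`.
#' @export
#' @examples
#' pop <- sample_population(lnp_presets()[["LNP-mRNA"]])
#' range(pop$vbar)
lnp_presets <- function(n_draws = 30) {
  list(
    "empty" = population_spec(
      population_component(25.0, 0.225, 0.991, 0.0005, signal = 0.58),
      n_draws = n_draws, seed = 101),
    "LNP-P" = population_spec(
      population_component(20.1, 0.188, 0.985, 0.0025, signal = 0.83),
      n_draws = n_draws, seed = 102),
    "LNP-mRNA" = population_spec(
      population_component(24.9, 0.165, 0.9825, 0.00125, signal = 0.83),
      n_draws = n_draws, seed = 103),
    "LNP-P-mRNA" = population_spec(
      population_component(12.0, 0.40, 0.9785, 0.00325, signal = 0.83),
      n_draws = n_draws, seed = 104))
}

# Smooth time-invariant artifact: a Gaussian bump over radius whose
# center/width are drawn from the seed, mimicking a window scratch.
ti_bump <- function(radii, amplitude) {
  center <- runif(1, min(radii), max(radii))
  width <- diff(range(radii)) * runif(1, 0.05, 0.15)
  amplitude * exp(-(radii - center)^2 / (2 * width^2))
}

#' Simulate a D2O density-matching series with ground truth
#'
#' For each D2O fraction the population's (s, D) are recomputed in that
#' solvent from the fixed (M, vbar, alpha) via the Svedberg chain, the
#' mixture is simulated, and seeded noise is added: a time-invariant
#' Gaussian bump over radius, zero-mean per-scan offsets, and i.i.d.
#' Gaussian noise. The generating population and the per-density solute
#' tables are returned alongside the scan sets; there is no hidden
#' randomness.
#'
#' @param population A [population_spec()] or a data frame from
#'   [sample_population()].
#' @param d2o_fractions Vector of D2O volume fractions.
#' @param geometry A [cell_geometry()].
#' @param omega Rotor speed, rad/s.
#' @param times Scan times, seconds.
#' @param radii Optional radius vector for the scans. The default trims
#'   `radius_trim` cm off each end of the column, emulating the usual
#'   practice of excluding the meniscus and back-of-cell regions (where
#'   floating or pelleting material piles into thin, poorly measurable
#'   layers) from the analyzed range.
#' @param radius_trim Trim width, cm, used when `radii` is NULL.
#' @param n_obs_radii Number of observation radii used when `radii` is NULL.
#' @param noise List with `sigma` (i.i.d. Gaussian sd, signal units),
#'   `ti_amplitude` (bump height), `ri_amplitude` (per-scan offset sd).
#' @param density_increment,viscosity_multiplier,temperature Passed to
#'   [buffer_spec()] for each fraction.
#' @param n_radii Solver nodes.
#' @param seed Master seed; per-fraction seeds are derived from it.
#' @return A list of class `density_series`: `scans` (named list of
#'   [scan_set()]s), `truth` (population data frame), `solutes_by_density`
#'   (list of per-buffer solute tables), `buffers`, `noise`, `seed`.
#' @export
make_density_series <- function(population,
                                d2o_fractions = c(0, 0.10, 0.15, 0.20),
                                geometry = cell_geometry(5.9, 7.2),
                                omega = rpm_to_omega(30000),
                                times = seq(1200, 36000, length.out = 25),
                                radii = NULL, radius_trim = 0.03,
                                n_obs_radii = 180,
                                noise = list(sigma = 0.003,
                                             ti_amplitude = 0.01,
                                             ri_amplitude = 0.002),
                                density_increment = 0.0046,
                                viscosity_multiplier = 1,
                                temperature = 293.15,
                                n_radii = 300, seed = 42) {
  pop <- if (inherits(population, "population_spec"))
    sample_population(population, seed = seed) else population
  if (is.null(radii))
    radii <- seq(geometry$meniscus + radius_trim,
                 geometry$bottom - radius_trim, length.out = n_obs_radii)
  noise <- modifyList(list(sigma = 0.003, ti_amplitude = 0.01,
                           ri_amplitude = 0.002), as.list(noise))
  scans <- list(); sols <- list(); buffers <- list()
  for (k in seq_along(d2o_fractions)) {
    spec_k <- buffer_spec(d2o_fractions[k], density_increment,
                          viscosity_multiplier, temperature)
    bst <- buffer_state(spec_k)
    sol <- solute_from_mass(pop$M, pop$vbar, pop$alpha, bst)
    sim <- simulate_mixture(sol, pop$amplitude, geometry, omega, times,
                            radii = radii, n_radii = n_radii, buffer = spec_k,
                            temperature = temperature)
    sim$signal <- sim$signal + with_seed(seed + 1000 + k, {
      nt <- length(times); nr <- length(sim$radii)
      ti <- ti_bump(sim$radii, noise$ti_amplitude)
      ri <- if (noise$ri_amplitude > 0 && nt > 1) {
        v <- rnorm(nt, sd = noise$ri_amplitude); v - mean(v)
      } else numeric(nt)
      matrix(ti, nt, nr, byrow = TRUE) + ri +
        matrix(rnorm(nt * nr, sd = noise$sigma), nt, nr)
    })
    nm <- sprintf("d2o_%02.0f", 100 * d2o_fractions[k])
    scans[[nm]] <- sim
    sols[[nm]] <- sol
    buffers[[nm]] <- spec_k
  }
  structure(list(scans = scans, truth = pop, solutes_by_density = sols,
                 buffers = buffers, d2o_fractions = d2o_fractions,
                 noise = noise, seed = seed),
            class = "density_series")
}

#' @export
print.density_series <- function(x, ...) {
  cat(sprintf(paste0("<density_series> %d densities (%s%% D2O), %d truth ",
                     "species, sigma = %g\n"),
              length(x$scans),
              paste(100 * x$d2o_fractions, collapse = "/"),
              nrow(x$truth), x$noise$sigma))
  invisible(x)
}

#' Ground-truth boundary-fraction table
#'
#' Applies the same cumulative-signal quantile slicing as
#' [boundary_fractions()] to the generating population (ordered by its true
#' s at the reference density), yielding the per-fraction true vbar, molar
#' mass and hydrodynamic radius that a density-matching analysis of the
#' series should recover.
#'
#' @param series A [make_density_series()] result.
#' @param n_fractions,tail_exclusion As in [boundary_fractions()].
#' @param reference Index or name of the reference density (default: the
#'   least dense condition).
#' @return Data frame with `fraction`, `quantile`, `weight`, true `s`
#'   (seconds), `vbar`, `M`, `Rh_nm`.
#' @export
truth_fractions <- function(series, n_fractions = 20, tail_exclusion = 0.02,
                            reference = NULL) {
  rhos <- vapply(series$buffers,
                 function(b) buffer_state(b)$rho, 1.0)
  if (is.null(reference)) reference <- which.min(rhos)
  sol <- series$solutes_by_density[[reference]]
  dist <- data.frame(s = sol$s, vbar = sol$vbar, M = sol$M,
                     Rh_nm = sol$Rh * 1e7,
                     weight = series$truth$amplitude)
  fraction_averages(dist, c("s", "vbar", "M", "Rh_nm"),
                    n_fractions, tail_exclusion)
}

#' Ground-truth sedimentation distribution at one density
#'
#' @param series A [make_density_series()] result.
#' @param which Name or index of the density condition.
#' @return Data frame with the true solutes' `s` (seconds), `vbar`, `M`,
#'   `Rh`, `weight`.
#' @export
truth_distribution <- function(series, which = 1) {
  sol <- series$solutes_by_density[[which]]
  data.frame(s = sol$s, vbar = sol$vbar, M = sol$M, Rh = sol$Rh,
             weight = series$truth$amplitude)
}
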