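# Shared fixtures: a water reference solvent, a standard cell, and a small
# builder for exactly-representable mixtures (data simulated with the same
# solver settings as the fitting basis, so grid-point species are
# reproduced identically).

water20 <- function() solvent_state(0.99823, 0.010016, 293.15)

std_cell <- function() cell_geometry(5.9, 7.2)

std_omega <- function() rpm_to_omega(30000)

# Small combined grid plus data simulated from selected grid rows.
# Truth species are picked by (s [S], vbar) closest match among the
# sedimenting block.
exact_mixture <- function(truth_coords, amplitudes,
                          s_limits = c(1, 20), n_s = 20, n_vbar = 8,
                          vbar_sed = c(0.95, 0.995),
                          vbar_float = c(1.004, 1.04),
                          times = seq(1200, 36000, length.out = 15),
                          radii = seq(5.9, 7.2, length.out = 150),
                          noise_sd = 0, seed = 1) {
  spec <- buffer_spec(0, density_increment = 0)
  bst <- buffer_state(spec)
  grid <- lnp_grid(bst, s_limits = s_limits, n_s = n_s, n_vbar = n_vbar,
                   vbar_sed = vbar_sed, vbar_float = vbar_float)
  sed <- grid$solutes[grid$solutes$s > 0, ]
  idx <- vapply(truth_coords, function(co) {
    which.min(abs(to_svedberg(sed$s) - co[1]) + abs(sed$vbar - co[2]))
  }, 1L)
  truth <- sed[idx, ]
  data <- simulate_mixture(truth, amplitudes, std_cell(), std_omega(),
                           times, radii = radii, n_radii = 240, tol = 1e-5,
                           buffer = spec)
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      data$signal <- data$signal +
        matrix(rnorm(length(data$signal), sd = noise_sd),
               nrow(data$signal))
    })
  }
  list(grid = grid, truth = truth, amplitudes = amplitudes, data = data,
       buffer = spec)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual / expected - 1)), rel_tol)
}
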