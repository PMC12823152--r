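# Density matching: viscosity-only correction, boundary fractions, and
# the extrapolation of corrected s to the zero-sedimentation crossing.

test_that("viscosity correction scales s linearly and preserves signs", {
  ref <- water20()
  dist <- data.frame(s = from_svedberg(c(-5, 2, 10)), weight = c(1, 2, 3))
  same <- viscosity_correct(dist, ref, ref)
  expect_identical(same$s, dist$s)
  hot <- solvent_state(ref$rho, ref$eta * 1.1, ref$temperature)
  corr <- viscosity_correct(dist, hot, ref)
  expect_equal(corr$s, dist$s * 1.1)
  expect_identical(sign(corr$s), sign(dist$s))
})

test_that("viscosity-corrected s of an ideal species is linear in solvent density", {
  specs <- lapply(c(0, 0.10, 0.15, 0.20), buffer_spec)
  states <- lapply(specs, buffer_state)
  ref <- states[[1]]
  s_corr <- vapply(states, function(st) {
    sol <- solute_from_mass(5e7, 0.9825, 1.1, st)
    sol$s * st$eta / ref$eta
  }, 1.0)
  rho <- vapply(states, `[[`, 1.0, "rho")
  fit <- lm(s_corr ~ rho)
  expect_lt(max(abs(residuals(fit))) / abs(s_corr[1]), 1e-6)
  # the zero crossing is the reciprocal of the generating vbar
  expect_equal(-coef(fit)[[1]] / coef(fit)[[2]], 1 / 0.9825,
               tolerance = 1e-6)
})

test_that("boundary fractions slice the cumulative signal correctly", {
  one <- data.frame(s = from_svedberg(7), weight = 2)
  bf <- boundary_fractions(one, n_fractions = 5, tail_exclusion = 0)
  expect_true(all(abs(bf$mean_s - from_svedberg(7)) < 1e-25))
  two <- data.frame(s = from_svedberg(c(10, 50)), weight = c(1, 1))
  bf2 <- boundary_fractions(two, n_fractions = 2, tail_exclusion = 0)
  expect_equal(to_svedberg(bf2$mean_s), c(10, 50))
  expect_equal(bf2$weight, c(1, 1))
  # fraction means are non-decreasing and weights sum to the central mass
  set.seed(8)
  many <- data.frame(s = from_svedberg(sort(runif(40, -20, 30))),
                     weight = runif(40))
  bf3 <- boundary_fractions(many, n_fractions = 10, tail_exclusion = 0.02)
  expect_true(all(diff(bf3$mean_s) >= 0))
  expect_equal(sum(bf3$weight), 0.96 * sum(many$weight))
  expect_error(boundary_fractions(many[0, ], 5), "empty")
})

test_that("two-point extrapolation reproduces the closed-form vbar exactly", {
  st1 <- buffer_state(buffer_spec(0))
  st2 <- buffer_state(buffer_spec(0.20))
  vbar_true <- 0.981
  s1 <- solute_from_mass(4e7, vbar_true, 1.1, st1)$s * st1$eta / st1$eta
  s2 <- solute_from_mass(4e7, vbar_true, 1.1, st2)$s * st2$eta / st1$eta
  ex <- extrapolate_vbar(data.frame(rho = c(st1$rho, st2$rho),
                                    s = c(s1, s2)))
  expect_true(ex$ok)
  closed <- (s1 - s2) / (s1 * st2$rho - s2 * st1$rho)
  expect_equal(ex$vbar, closed, tolerance = 1e-12)
  expect_equal(ex$vbar, vbar_true, tolerance = 1e-10)
})

test_that("degenerate or unphysical extrapolations are flagged", {
  expect_error(extrapolate_vbar(data.frame(rho = c(1, 1), s = c(1, 2))),
               "two distinct")
  up <- extrapolate_vbar(data.frame(rho = c(0.998, 1.02),
                                    s = from_svedberg(c(5, 6))))
  expect_false(up$ok)
  expect_match(up$reason, "slope")
  far <- extrapolate_vbar(data.frame(rho = c(0.998, 1.02),
                                     s = from_svedberg(c(100, 99))))
  expect_false(far$ok)
  expect_match(far$reason, "outside")
})

test_that("ideal per-density distributions are matched to machine accuracy", {
  # three sizes sharing one vbar (so the s rank order is preserved exactly
  # across densities); exact s at each density, no fitting step: the
  # viscosity-corrected linear extrapolation must be exact per fraction
  specs <- lapply(c(0, 0.10, 0.15, 0.20), buffer_spec)
  states <- lapply(specs, buffer_state)
  ref <- states[[1]]
  M <- c(2e7, 4e7, 8e7); vbar_true <- 0.982
  # equal weights align the three equal-signal fractions with the species;
  # the sample floats at 20% D2O, exercising the orientation-aware pairing
  dists <- lapply(states, function(st) {
    sol <- solute_from_mass(M, vbar_true, 1.1, st)
    data.frame(s = sol$s, weight = rep(1 / 3, 3), alpha = 1.1)
  })
  res <- density_match(dists, specs, n_fractions = 3, tail_exclusion = 0)
  ok <- res$fractions
  expect_true(all(ok$ok))
  expect_equal(ok$vbar, rep(vbar_true, 3), tolerance = 1e-9)
  expect_equal(ok$M, M, tolerance = 1e-7)
  rh_true <- solute_from_mass(M, vbar_true, 1.1, ref)$Rh * 1e7
  expect_equal(ok$Rh_nm, rh_true, tolerance = 1e-7)
  expect_equal(sum(ok$weight), 1)
})

test_that("density matching is invariant to the order of conditions", {
  specs <- lapply(c(0, 0.10, 0.15, 0.20), buffer_spec)
  states <- lapply(specs, buffer_state)
  dists <- lapply(states, function(st) {
    sol <- solute_from_mass(c(2e7, 6e7), c(0.980, 0.984), 1.1, st)
    data.frame(s = sol$s, weight = c(0.5, 0.5), alpha = 1.1)
  })
  r1 <- density_match(dists, specs, n_fractions = 4, tail_exclusion = 0)
  perm <- c(3, 1, 4, 2)
  r2 <- density_match(dists[perm], specs[perm], n_fractions = 4,
                      tail_exclusion = 0)
  expect_equal(r1$fractions$vbar, r2$fractions$vbar, tolerance = 1e-12)
  expect_equal(r1$fractions$M, r2$fractions$M, tolerance = 1e-10)
})

test_that("fractions at the reference exclusion band are skipped and counted", {
  # a species exactly density-matched at the reference condition: the
  # extrapolated vbar hits 1/rho_ref, so no mass can be derived there
  specs <- lapply(c(0, 0.20), buffer_spec)
  states <- lapply(specs, buffer_state)
  vbar <- 1 / states[[1]]$rho
  dists <- lapply(states, function(st) {
    data.frame(s = solute_from_mass(4e7, vbar, 1.1, st)$s,
               weight = 1, alpha = 1.1)
  })
  res <- density_match(dists, specs, n_fractions = 2, tail_exclusion = 0)
  expect_equal(res$n_skipped_exclusion, 2)
  expect_equal(sum(res$fractions$ok), 0)
  expect_equal(res$fractions$vbar, rep(vbar, 2), tolerance = 1e-6)
})

test_that("a rank-stable 3-species mixture is recovered through the full pipeline", {
  # all species sediment at every density (the zero crossing is
  # extrapolated, not bracketed), so the s rank order is the same at every
  # condition and quantile-rank fraction pairing is exact
  pop <- do.call(rbind, lapply(list(
    c(rh = 14, vbar = 0.972), c(rh = 18, vbar = 0.9735),
    c(rh = 23, vbar = 0.975)), function(cp) {
      sample_population(population_spec(population_component(
        cp["rh"], 0, cp["vbar"], 0, signal = 0.83 / 3), n_draws = 1))
    }))
  series <- make_density_series(pop, d2o_fractions = c(0, 0.05, 0.10, 0.15),
                                times = seq(1200, 36000, length.out = 20),
                                n_radii = 240, seed = 23)
  fits <- lapply(series$scans, function(data) {
    grid <- lnp_grid(buffer_state(data$buffer), s_limits = c(1, 40),
                     n_s = 64, n_vbar = 8, s_spacing = "logarithmic",
                     vbar_sed = c(0.955, 0.999), vbar_float = c(0.97, 1.005))
    fit <- iterative_refine(data, grid, n_partitions = 4,
                            fit_ti = TRUE, fit_ri = TRUE)
    on.exit(clear_basis_cache())
    monte_carlo(data, fit, n_iterations = 20, seed = 5)
  })
  res <- density_match(fits, series$buffers, n_fractions = 3,
                       tail_exclusion = 0.02)
  tf <- truth_fractions(series, n_fractions = 3, tail_exclusion = 0.02)
  fr <- res$fractions
  expect_true(all(fr$ok))
  expect_lt(max(abs(fr$vbar - tf$vbar)), 0.005)
  expect_lt(max(abs(fr$M / tf$M - 1)), 0.15)
  expect_lt(max(abs(fr$Rh_nm / tf$Rh_nm - 1)), 0.10)
})

test_that("histograms are signal-weighted and ignore zero-weight fractions", {
  fr <- data.frame(fraction = 1:4, quantile = c(.2, .4, .6, .8),
                   rho_m = 1.02, vbar = c(0.98, 0.98, 0.985, 0.985),
                   M = c(1e7, 1e7, 4e7, 4e7),
                   Rh_nm = c(20, 20, 30, 30),
                   weight = c(0.25, 0.25, 0.5, 0),
                   ok = c(TRUE, TRUE, TRUE, TRUE), reason = "")
  res <- structure(list(fractions = fr), class = "density_match_result")
  h <- match_histograms(res, n_bins = 2)
  expect_equal(sum(h$vbar$weight), 1)
  expect_equal(h$vbar$weight, c(0.5, 0.5))
  expect_equal(h$Rh_nm$weight, c(0.5, 0.5))
})
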