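# Fitting-layer tests. Data sets are simulated with the same solver
# settings as the fitting basis, so grid-point species are exactly
# representable and recovery can be checked to machine precision.

test_that("the NNLS engine agrees with the reference Lawson-Hanson solver", {
  set.seed(1)
  for (trial in 1:10) {
    m <- 50; n <- 20
    A <- matrix(rnorm(m * n), m, n)
    xtrue <- abs(rnorm(n)) * rbinom(n, 1, 0.3)
    b <- as.numeric(A %*% xtrue + 0.05 * rnorm(m))
    mine <- as.numeric(sedgrid:::.nnls_lh_cpp(A, b, 1e-12, 1000L, NULL)$x)
    ref <- suppressWarnings(pracma::lsqnonneg(A, b)$x)
    expect_lt(max(abs(mine - ref)), 1e-8)
  }
})

test_that("noise-free grid-point mixtures are recovered exactly", {
  fx <- exact_mixture(list(c(3, 0.96), c(6, 0.9757), c(9, 0.9886)),
                      c(0.3, 0.4, 0.2))
  fit <- nnls_fit(fx$data, fx$grid)
  expect_lt(fit$rmsd, 1e-8)
  rec <- fit$solutes
  for (i in 1:3) {
    j <- which(abs(rec$s - fx$truth$s[i]) < 1e-25 &
                 abs(rec$vbar - fx$truth$vbar[i]) < 1e-12)
    expect_equal(rec$amplitude[j], fx$amplitudes[i], tolerance = 1e-6)
  }
  # total fitted signal matches total loading
  expect_equal(sum(rec$amplitude), sum(fx$amplitudes), tolerance = 2e-2)
})

test_that("with Gaussian noise the rmsd estimates sigma and peaks stay on grid", {
  fx <- exact_mixture(list(c(3, 0.96), c(8, 0.983)), c(0.5, 0.3),
                      noise_sd = 0.005, seed = 21)
  fit <- nnls_fit(fx$data, fx$grid)
  expect_lt(abs(fit$rmsd / 0.005 - 1), 0.05)
  d <- solute_distribution(fit)
  s_step <- diff(sort(unique(fx$grid$solutes$s[fx$grid$solutes$s > 0])))[1]
  for (i in 1:2) {
    near <- abs(d$s - fx$truth$s[i]) <= 1.5 * s_step
    expect_gt(sum(d$weight[near]), 0.7 * fx$amplitudes[i])
  }
})

test_that("enlarging the candidate grid never increases the rmsd", {
  fx <- exact_mixture(list(c(4, 0.965), c(9, 0.985)), c(0.4, 0.3),
                      noise_sd = 0.004, seed = 5)
  sol <- fx$grid$solutes
  half <- sol[seq(1, nrow(sol), by = 2), ]
  fit_half <- nnls_fit(fx$data, half)
  fit_full <- nnls_fit(fx$data, sol)
  expect_lte(fit_full$rmsd, fit_half$rmsd + 1e-12)
})

test_that("injected TI and RI noise vectors are recovered", {
  # conditions sized so the estimator noise floor (sigma/sqrt(n_scans) for
  # TI, sigma/sqrt(n_radii) for RI) sits below the 2% recovery target
  times <- seq(1200, 36000, length.out = 25)
  radii <- seq(5.9, 7.2, length.out = 200)
  fx <- exact_mixture(list(c(5, 0.962), c(12, 0.982)), c(0.5, 0.3),
                      times = times, radii = radii)
  ti_true <- 0.05 * exp(-(radii - 6.5)^2 / (2 * 0.05^2))
  ri_true <- withr::with_seed(3, rnorm(25, sd = 0.02))
  ri_true <- ri_true - mean(ri_true)
  noisy <- fx$data
  noisy$signal <- noisy$signal +
    matrix(ti_true, 25, 200, byrow = TRUE) + ri_true +
    withr::with_seed(4, matrix(rnorm(25 * 200, sd = 0.003), 25, 200))
  fit <- fit_noise(noisy, fx$grid)
  expect_lt(sqrt(mean((fit$ti_noise - ti_true)^2)) / 0.05, 0.02)
  expect_lt(sqrt(mean((fit$ri_noise - ri_true)^2)) /
              sqrt(mean(ri_true^2)), 0.05)
  expect_lt(abs(mean(fit$ri_noise)), 1e-12)     # identifiability constraint
  # noise-free input: vectors vanish and rmsd equals the plain fit
  clean <- fit_noise(fx$data, fx$grid)
  plain <- nnls_fit(fx$data, fx$grid)
  expect_lt(max(abs(clean$ti_noise)), 1e-10)
  expect_lt(max(abs(clean$ri_noise)), 1e-10)
  expect_equal(clean$rmsd, plain$rmsd, tolerance = 1e-6)
})

test_that("RI estimation requires at least 3 scans", {
  fx <- exact_mixture(list(c(5, 0.97)), 0.5,
                      times = c(3600, 7200),
                      radii = seq(5.9, 7.2, length.out = 60))
  expect_error(fit_noise(fx$data, fx$grid, fit_ti = FALSE, fit_ri = TRUE),
               "3 scans")
})

test_that("iterative refinement reaches the full-grid solution", {
  fx <- exact_mixture(list(c(4, 0.966), c(10, 0.988)), c(0.45, 0.25),
                      noise_sd = 0.003, seed = 9)
  oracle <- nnls_fit(fx$data, fx$grid)
  refined <- iterative_refine(fx$data, fx$grid, n_partitions = 4)
  expect_equal(refined$rmsd, oracle$rmsd, tolerance = 1e-4)
  # the refined nonzero set contains grid points adjacent to both species
  d <- solute_distribution(refined)
  s_step <- diff(sort(unique(fx$grid$solutes$s[fx$grid$solutes$s > 0])))[1]
  for (i in 1:2)
    expect_gt(sum(d$weight[abs(d$s - fx$truth$s[i]) <= 1.5 * s_step]),
              0.5 * fx$amplitudes[i])
  # single partition is identical to a direct fit
  direct <- iterative_refine(fx$data, fx$grid, n_partitions = 1)
  expect_equal(direct$rmsd, oracle$rmsd, tolerance = 1e-12)
  # rmsd is non-increasing along the merge schedule
  hist <- refined$provenance$rmsd_history
  expect_true(all(diff(hist) <= 1e-10))
  expect_lte(refined$rmsd, min(vapply(
    partition_for_refinement(fx$grid, 4),
    function(p) nnls_fit(fx$data, p)$rmsd, 1.0)) + 1e-12)
})

test_that("meniscus search recovers the true position", {
  radii <- seq(5.85, 7.2, length.out = 160)   # includes pre-meniscus air
  fx <- exact_mixture(list(c(4, 0.96), c(9, 0.985)), c(0.5, 0.3),
                      s_limits = c(1, 15), n_s = 12, n_vbar = 6,
                      radii = radii, noise_sd = 0.003, seed = 11)
  shifted <- fx$data
  shifted$geometry <- cell_geometry(5.88, 7.2)
  fit <- fit_boundary_positions(shifted, fx$grid,
                                meniscus_range = c(5.87, 5.93),
                                n_candidates = 5)
  spacing <- diff(c(5.87, 5.93)) / 4
  expect_lt(abs(fit$meniscus - 5.9), spacing)
  expect_true(fit$provenance$bracketed)
  # rmsd profile is unimodal around the optimum in the search table
  prof <- fit$provenance$boundary_search
  i0 <- which.min(prof$rmsd)
  expect_true(all(diff(prof$rmsd[seq_len(i0)]) <= 0))
  expect_true(all(diff(prof$rmsd[i0:nrow(prof)]) >= 0))
  # a range that does not bracket the optimum is flagged
  expect_warning(
    fit_boundary_positions(shifted, fx$grid,
                           meniscus_range = c(5.905, 5.95),
                           n_candidates = 3),
    "not bracketed")
})

test_that("Monte Carlo ensembles are seeded, unbiased, and noise-scaled", {
  fx <- exact_mixture(list(c(6, 0.975)), 0.6, s_limits = c(1, 15),
                      n_s = 12, n_vbar = 6, noise_sd = 0.004, seed = 13)
  fit <- nnls_fit(fx$data, fx$grid)
  ens1 <- monte_carlo(fx$data, fit, n_iterations = 12, seed = 99)
  ens2 <- monte_carlo(fx$data, fit, n_iterations = 12, seed = 99)
  amp <- function(e) t(vapply(e$models,
                              function(m) m$solutes$amplitude,
                              numeric(nrow(fit$solutes))))
  expect_identical(amp(ens1), amp(ens2))
  # ensemble mean s is within 2 ensemble sd of the truth
  ms <- vapply(ens1$models, function(m) {
    d <- m$solutes[m$solutes$amplitude > 0, ]
    sum(d$s * d$amplitude) / sum(d$amplitude)
  }, 1.0)
  expect_lt(abs(mean(ms) - fx$truth$s), 2 * sd(ms) + 1e-16)
  # amplitude scatter scales with the injected noise level
  fit_big <- fit; fit_big$rmsd <- fit$rmsd * 3
  ens_big <- monte_carlo(fx$data, fit_big, n_iterations = 12, seed = 99)
  sd_small <- mean(apply(amp(ens1), 2, sd))
  sd_big <- mean(apply(amp(ens_big), 2, sd))
  expect_gt(sd_big / sd_small, 1.8)
  expect_error(monte_carlo(fx$data, fit, n_iterations = 1), ">= 2")
})

test_that("residuals of a correct noisy fit pass the runs sanity check", {
  fx <- exact_mixture(list(c(4, 0.968), c(8, 0.986)), c(0.4, 0.35),
                      noise_sd = 0.004, seed = 17)
  fit <- nnls_fit(fx$data, fx$grid)
  z <- apply(fit_residuals(fit, fx$data), 1, runs_zscore)
  expect_lt(mean(abs(z)), 3)
  clear_basis_cache()
})
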