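test_that("axis specs validate and realize linear and logarithmic spacing", {
  expect_equal(axis_points <- sedgrid:::axis_points(
    grid_axis("s", 1, 100, 3, "logarithmic")), c(1, 10, 100))
  expect_equal(sedgrid:::axis_points(grid_axis("vbar", 0.94, 0.96, 3)),
               c(0.94, 0.95, 0.96))
  expect_error(grid_axis("s", -10, -1, 5, "logarithmic"), "positive")
  expect_error(grid_axis("s", 5, 1, 3), "min < max")
  expect_error(grid_axis("zeta", 1, 2, 2), "arg")
})

test_that("a subgrid is the Cartesian product with full hydrodynamic conversion", {
  w <- water20()
  g <- build_subgrid(grid_axis("s", 2, 10, 5), grid_axis("vbar", 0.95, 0.98, 4),
                     fixed = list(alpha = 1.1), buffer = w)
  expect_equal(nrow(g), 20)
  # conversions are mutually consistent with the closed relations
  expect_equal(g$D, D_from_s_alpha_vbar(g$s, 1.1, g$vbar, w))
  expect_equal(g$M, mass_from_sD(g$s, g$D, g$vbar, w))
  expect_equal(g$Rh, g$alpha * g$R0)
  # single-point axes give exactly one solute
  one <- build_subgrid(grid_axis("s", 5, 5.00001, 1),
                       grid_axis("vbar", 0.97, 0.98, 1),
                       fixed = list(alpha = 1.1), buffer = w)
  expect_equal(nrow(one), 1)
  expect_equal(to_svedberg(one$s), 5)
  expect_equal(one$vbar, 0.97)
})

test_that("buoyancy-violating grid points are rejected with coordinates", {
  w <- water20()
  expect_error(
    build_subgrid(grid_axis("s", 1, 10, 3), grid_axis("vbar", 1.01, 1.05, 3),
                  fixed = list(alpha = 1.1), buffer = w),
    "rejected at s = 1")
  expect_error(
    build_subgrid(grid_axis("s", -10, -1, 3),
                  grid_axis("vbar", 0.95, 0.97, 3),
                  fixed = list(alpha = 1.1), buffer = w),
    "sign-inconsistent")
})

test_that("alternative axis pairs (s, ff0) and (s, M) are supported", {
  w <- water20()
  gf <- build_subgrid(grid_axis("s", 2, 10, 4), grid_axis("ff0", 1, 2, 3),
                      fixed = list(vbar = 0.97), buffer = w)
  expect_equal(nrow(gf), 12)
  expect_equal(gf$D, D_from_s_alpha_vbar(gf$s, gf$alpha, 0.97, w))
  gm <- build_subgrid(grid_axis("s", 2, 10, 4),
                      grid_axis("M", 1e6, 1e8, 5, "logarithmic"),
                      fixed = list(vbar = 0.97), buffer = w)
  expect_equal(nrow(gm), 20)
  expect_equal(mass_from_sD(gm$s, gm$D, 0.97, w), gm$M)
})

test_that("the full LNP configuration realizes 24000 solutes in two blocks", {
  w <- water20()
  g <- lnp_grid(w, s_limits = c(1, 100), vbar_sed = c(0.94, 0.999),
                vbar_float = c(1.003, 1.05), n_s = 200, n_vbar = 120)
  expect_equal(nrow(g$solutes), 24000)
  expect_equal(length(g$subgrids), 2)
  expect_equal(sum(g$solutes$s < 0), 12000)
  expect_equal(range(to_svedberg(g$solutes$s)), c(-100, 100))
  expect_equal(max(g$solutes$vbar[g$solutes$s > 0]), 0.999)
  expect_equal(min(g$solutes$vbar[g$solutes$s < 0]), 1.003)
  # every solute is sign-consistent and outside the exclusion band
  b <- buoyancy(g$solutes$vbar, buffer_state(g$buffer)$rho)
  expect_true(all(sign(b) == sign(g$solutes$s)))
  expect_true(all(abs(b) >= 1e-4))
  expect_true(all(g$solutes$D > 0 & is.finite(g$solutes$D)))
  expect_true(all(g$solutes$M > 0 & is.finite(g$solutes$M)))
})

test_that("combining grids is idempotent and additive for disjoint blocks", {
  w <- water20()
  a <- build_subgrid(grid_axis("s", 2, 10, 4), grid_axis("vbar", 0.95, 0.97, 3),
                     fixed = list(alpha = 1.1), buffer = w)
  b <- build_subgrid(grid_axis("s", -10, -2, 4),
                     grid_axis("vbar", 1.01, 1.04, 3),
                     fixed = list(alpha = 1.1), buffer = w)
  self <- combine_grids(a, a, buffer = w)
  expect_equal(nrow(self$solutes), nrow(a))
  both <- combine_grids(a, b, buffer = w)
  expect_equal(nrow(both$solutes), nrow(a) + nrow(b))
  # conflicting fixed parameters are rejected
  c2 <- build_subgrid(grid_axis("s", 2, 10, 4),
                      grid_axis("vbar", 0.95, 0.97, 3),
                      fixed = list(alpha = 1.5), buffer = w)
  expect_error(combine_grids(a, c2, buffer = w), "frictional ratio")
})

test_that("refinement partitions tile the grid in near-equal strided samples", {
  w <- water20()
  g <- lnp_grid(w, n_s = 40, n_vbar = 12)
  n <- nrow(g$solutes)
  parts <- partition_for_refinement(g, 7)
  sizes <- vapply(parts, nrow, 1L)
  expect_equal(sum(sizes), n)
  expect_lte(diff(range(sizes)), 1)
  idx <- sort(unlist(lapply(parts, attr, "indices")))
  expect_equal(idx, seq_len(n))          # disjoint union = full grid
  full_s <- range(g$solutes$s); full_v <- range(g$solutes$vbar)
  for (p in parts) {
    # every partition spans (nearly) the full parameter ranges
    expect_lt(abs(min(p$s) - full_s[1]) / diff(full_s), 0.1)
    expect_lt(abs(max(p$s) - full_s[2]) / diff(full_s), 0.1)
    expect_lt(abs(min(p$vbar) - full_v[1]) / diff(full_v), 0.1)
    expect_lt(abs(max(p$vbar) - full_v[2]) / diff(full_v), 0.1)
  }
  expect_error(partition_for_refinement(g, n + 1), "more partitions")
  expect_equal(nrow(partition_for_refinement(g, 1)[[1]]), n)
})

test_that("the 82-way partition of the full grid balances near 293 solutes", {
  w <- water20()
  g <- lnp_grid(w, n_s = 200, n_vbar = 120)
  parts <- partition_for_refinement(g, 82)
  sizes <- vapply(parts, nrow, 1L)
  expect_equal(sum(sizes), 24000)
  expect_true(all(sizes %in% c(292L, 293L)))
})

test_that("grid construction is deterministic and exportable", {
  w <- water20()
  g1 <- lnp_grid(w, n_s = 10, n_vbar = 4)
  g2 <- lnp_grid(w, n_s = 10, n_vbar = 4)
  expect_identical(g1$solutes, g2$solutes)
  path <- withr::local_tempfile(fileext = ".csv")
  export_grid(g1, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), nrow(g1$solutes))
  expect_named(tab, c("s_svedberg", "vbar", "alpha", "D", "M", "Rh_nm"))
  expect_equal(tab$s_svedberg, to_svedberg(g1$solutes$s), tolerance = 1e-10)
})
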