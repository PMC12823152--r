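# Custom combined-grid construction: Cartesian subgrids of basis solutes
# over (s, vbar) at fixed frictional ratio (or alternative axis pairs),
# merged into one grid spanning sedimenting and floating species and
# partitioned into coarse interleaved subgrids for iterative refinement.

#' Specify one grid axis
#'
#' @param parameter One of `"s"` (Svedberg), `"vbar"` (mL/g), `"ff0"`
#'   (frictional ratio), `"M"` (g/mol).
#' @param min,max Axis range; `min < max`. For `"s"` the units are Svedberg
#'   and negative values denote flotation.
#' @param n_points Number of points (>= 1; with 1 point the axis is `min`).
#' @param spacing `"linear"` or `"logarithmic"` (positive ranges only).
#' @return An object of class `grid_axis`.
#' @export
#' @examples
#' grid_axis("s", 1, 100, 40, "logarithmic")
grid_axis <- function(parameter, min, max, n_points, spacing = "linear") {
  parameter <- match.arg(parameter, c("s", "vbar", "ff0", "M"))
  spacing <- match.arg(spacing, c("linear", "logarithmic"))
  if (n_points < 1) stop("n_points must be >= 1")
  if (n_points > 1 && !(min < max)) stop("axis requires min < max")
  if (spacing == "logarithmic" && min <= 0)
    stop("logarithmic spacing requires a positive range")
  structure(list(parameter = parameter, min = min, max = max,
                 n_points = as.integer(n_points), spacing = spacing),
            class = "grid_axis")
}

axis_points <- function(axis) {
  if (axis$n_points == 1) return(axis$min)
  if (axis$spacing == "logarithmic")
    exp(seq(log(axis$min), log(axis$max), length.out = axis$n_points))
  else seq(axis$min, axis$max, length.out = axis$n_points)
}

#' Build one Cartesian subgrid of basis solutes
#'
#' Forms the Cartesian product of an s axis (Svedberg) with a second axis
#' and converts every point to a full solute description. With a `vbar`
#' second axis the frictional ratio is fixed and D follows the fixed-alpha
#' parameterization ([D_from_s_alpha_vbar()]); with an `ff0` or `M` second
#' axis the partial specific volume is fixed. Every point must satisfy sign
#' consistency, `sign(s) = sign(1 - vbar rho)`, and the buoyancy exclusion
#' band; violating points raise an error naming the first offending
#' coordinates.
#'
#' @param s_axis A [grid_axis()] with parameter `"s"`, units Svedberg.
#' @param second_axis A [grid_axis()] with parameter `"vbar"`, `"ff0"` or
#'   `"M"`.
#' @param fixed Named list supplying the held-fixed parameter: `alpha` for a
#'   `vbar` axis, `vbar` for an `ff0` or `M` axis (plus `alpha` for `M`,
#'   used only for reporting R0).
#' @param buffer A [buffer_spec()] or [solvent_state()].
#' @param exclusion Buoyancy exclusion threshold.
#' @return A solute table (data frame) with attribute `axes`.
#' @export
build_subgrid <- function(s_axis, second_axis, fixed = list(alpha = 1.1),
                          buffer, exclusion = .BUOYANCY_EXCLUSION) {
  stopifnot(inherits(s_axis, "grid_axis"), inherits(second_axis, "grid_axis"))
  if (s_axis$parameter != "s") stop("first axis must be the s axis")
  bst <- as_buffer_state(buffer)
  s_sv <- axis_points(s_axis)
  p2 <- axis_points(second_axis)
  grid <- expand.grid(s_sv = s_sv, p2 = p2, KEEP.OUT.ATTRS = FALSE)
  s <- from_svedberg(grid$s_sv)
  sol <- switch(second_axis$parameter,
    vbar = {
      if (is.null(fixed$alpha)) stop("fixed$alpha required for a vbar axis")
      check_grid_signs(s, grid$p2, bst, exclusion)
      solute_from_s_vbar(s, grid$p2, fixed$alpha, bst, exclusion)
    },
    ff0 = {
      if (is.null(fixed$vbar)) stop("fixed$vbar required for an ff0 axis")
      check_grid_signs(s, fixed$vbar, bst, exclusion)
      if (any(grid$p2 < 1)) stop("frictional ratio axis must be >= 1")
      D <- D_from_s_alpha_vbar(s, grid$p2, fixed$vbar, bst, exclusion)
      out <- solute_from_s_vbar(s, fixed$vbar, 1, bst, exclusion)
      out$alpha <- grid$p2; out$D <- D
      out$M <- mass_from_sD(s, D, fixed$vbar, bst, exclusion)
      out$f <- .RGAS * bst$temperature / (.NAVO * D)
      out$Rh <- out$f / (6 * pi * bst$eta)
      out$R0 <- out$Rh / out$alpha; out$f0 <- out$f / out$alpha
      out$V <- out$M * fixed$vbar / .NAVO
      out
    },
    M = {
      if (is.null(fixed$vbar)) stop("fixed$vbar required for an M axis")
      check_grid_signs(s, fixed$vbar, bst, exclusion)
      b <- buoyancy(fixed$vbar, bst$rho)
      D <- s * .RGAS * bst$temperature / (grid$p2 * b)
      if (any(D <= 0)) stop("M axis produced non-positive D; check signs")
      f <- .RGAS * bst$temperature / (.NAVO * D)
      alpha_rep <- if (is.null(fixed$alpha)) NA_real_ else fixed$alpha
      data.frame(M = grid$p2, vbar = fixed$vbar, alpha = alpha_rep, s = s,
                 D = D, f = f, V = grid$p2 * fixed$vbar / .NAVO,
                 R0 = NA_real_, f0 = NA_real_, Rh = f / (6 * pi * bst$eta))
    })
  attr(sol, "axes") <- list(s = s_axis, second = second_axis, fixed = fixed)
  sol
}

check_grid_signs <- function(s, vbar, bst, exclusion) {
  b <- buoyancy(vbar, bst$rho)
  bad <- sign(s) * sign(rep_len(b, length(s))) <= 0 |
    abs(rep_len(b, length(s))) < exclusion
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(paste0("grid point rejected at s = %.4g S, vbar = %.5g ",
                        "mL/g (rho = %.5f): sign-inconsistent or inside the ",
                        "buoyancy exclusion band"),
                 to_svedberg(s[i]), rep_len(vbar, length(s))[i], bst$rho))
  }
  invisible(TRUE)
}

#' Combine subgrids into one custom grid
#'
#' Merges any number of subgrids (from [build_subgrid()]) that share the
#' same buffer and fixed frictional ratio into a single combined grid;
#' duplicate (s, vbar) coordinates are removed, and the provenance of every
#' subgrid is retained for partitioning.
#'
#' @param ... Subgrid solute tables.
#' @param buffer The shared [buffer_spec()] / [solvent_state()].
#' @return An object of class `combined_grid` with fields `solutes`
#'   (solute table), `subgrids` (index vectors into `solutes`), `specs`
#'   (per-subgrid axis provenance), `alpha`, `buffer`.
#' @export
combine_grids <- function(..., buffer) {
  subs <- list(...)
  if (length(subs) == 1 && is.list(subs[[1]]) && !is.data.frame(subs[[1]]))
    subs <- subs[[1]]
  if (!length(subs)) stop("at least one subgrid required")
  alphas <- unique(unlist(lapply(subs, function(g) unique(round(g$alpha, 12)))))
  alphas <- alphas[!is.na(alphas)]
  if (length(alphas) > 1)
    stop("subgrids disagree on the fixed frictional ratio")
  specs <- lapply(subs, attr, "axes")
  all_sol <- do.call(rbind, subs)
  key <- paste(signif(all_sol$s, 12), signif(all_sol$vbar, 12))
  keep <- !duplicated(key)
  sol <- all_sol[keep, , drop = FALSE]
  rownames(sol) <- NULL
  # map each subgrid to row indices in the deduplicated table
  lut <- setNames(seq_len(nrow(sol)),
                  paste(signif(sol$s, 12), signif(sol$vbar, 12)))
  offsets <- cumsum(c(0, vapply(subs, nrow, 1L)))
  subgrids <- lapply(seq_along(subs), function(i) {
    k <- key[(offsets[i] + 1):offsets[i + 1]]
    unname(lut[k])
  })
  structure(list(solutes = sol, subgrids = subgrids, specs = specs,
                 alpha = if (length(alphas)) alphas else NA_real_,
                 buffer = as_buffer_state(buffer)),
            class = "combined_grid")
}

#' @export
print.combined_grid <- function(x, ...) {
  cat(sprintf(paste0("<combined_grid> %d solutes in %d subgrid(s); s in ",
                     "[%.3g, %.3g] S, vbar in [%.4g, %.4g] mL/g, alpha = %s\n"),
              nrow(x$solutes), length(x$subgrids),
              to_svedberg(min(x$solutes$s)), to_svedberg(max(x$solutes$s)),
              min(x$solutes$vbar), max(x$solutes$vbar),
              format(x$alpha)))
  invisible(x)
}

#' Partition a combined grid into coarse interleaved subgrids
#'
#' Splits the full solute list into `n_partitions` strided samples, each
#' spanning the full s and vbar ranges, whose disjoint union is exactly the
#' full grid and whose sizes differ by at most one solute. These partitions
#' are the work units of [iterative_refine()].
#'
#' @param grid A [combine_grids()] result.
#' @param n_partitions Number of partitions (>= 1, <= number of solutes).
#' @return List of solute tables; each carries an `indices` attribute into
#'   `grid$solutes`.
#' @export
partition_for_refinement <- function(grid, n_partitions) {
  stopifnot(inherits(grid, "combined_grid"))
  n <- nrow(grid$solutes)
  if (n_partitions < 1) stop("n_partitions must be >= 1")
  if (n_partitions > n) stop("more partitions than grid solutes")
  ord <- order(grid$solutes$vbar, grid$solutes$s)
  lapply(seq_len(n_partitions), function(k) {
    idx <- ord[seq(k, n, by = n_partitions)]
    out <- grid$solutes[idx, , drop = FALSE]
    attr(out, "indices") <- idx
    out
  })
}

#' Two-block (sedimenting + floating) LNP grid
#'
#' Convenience constructor for the default lipid-nanoparticle custom grid:
#' a sedimenting block (positive s, vbar below 1/rho) and a floating block
#' (negative s, vbar above 1/rho) sharing one frictional ratio. The total
#' s-point budget is split between the blocks proportionally to their
#' spans; the vbar budget applies to each block's own range. Block vbar
#' limits are clipped to the buoyancy-valid region of the supplied buffer,
#' so the same grid specification can be realized for every solvent density
#' of a density-matching series.
#'
#' @param buffer A [buffer_spec()] / [solvent_state()].
#' @param s_limits Positive magnitudes, Svedberg: the sedimenting block
#'   spans `[s_limits[1], s_limits[2]]`, the floating block the mirrored
#'   negative range.
#' @param vbar_sed,vbar_float vbar ranges (mL/g) of the two blocks before
#'   clipping.
#' @param n_s Total number of s points across both blocks.
#' @param n_vbar Number of vbar points in each block.
#' @param alpha Fixed frictional ratio.
#' @param s_spacing `"linear"` or `"logarithmic"` (applied to |s|).
#' @param margin Half-width (in units of |1 - vbar rho|) kept clear of the
#'   density-match point when clipping.
#' @return A [combine_grids()] result.
#' @export
#' @examples
#' g <- lnp_grid(buffer_spec(0, density_increment = 0), n_s = 20, n_vbar = 6)
#' nrow(g$solutes)
lnp_grid <- function(buffer, s_limits = c(1, 100),
                     vbar_sed = c(0.94, 0.999), vbar_float = c(1.003, 1.05),
                     n_s = 200, n_vbar = 120, alpha = 1.1,
                     s_spacing = "linear", margin = .BUOYANCY_EXCLUSION) {
  bst <- as_buffer_state(buffer)
  marg <- margin * 1.001   # keep clipped bounds strictly outside the band
  sed_hi <- min(vbar_sed[2], (1 - marg) / bst$rho)
  flo_lo <- max(vbar_float[1], (1 + marg) / bst$rho)
  if (!(vbar_sed[1] < sed_hi))
    stop("sedimenting vbar range empty after buoyancy clipping")
  if (!(flo_lo < vbar_float[2]))
    stop("floating vbar range empty after buoyancy clipping")
  span_neg <- diff(s_limits); span_pos <- diff(s_limits)
  n_neg <- max(1L, round(n_s * span_neg / (span_neg + span_pos)))
  n_pos <- max(1L, n_s - n_neg)
  sed <- build_subgrid(
    grid_axis("s", s_limits[1], s_limits[2], n_pos, s_spacing),
    grid_axis("vbar", vbar_sed[1], sed_hi, n_vbar),
    fixed = list(alpha = alpha), buffer = bst)
  neg_axis <- grid_axis("s", s_limits[1], s_limits[2], n_neg, s_spacing)
  neg_pts <- -rev(axis_points(neg_axis))
  flo <- build_subgrid(
    grid_axis("s", neg_pts[1], neg_pts[length(neg_pts)],
              n_neg, "linear"),
    grid_axis("vbar", flo_lo, vbar_float[2], n_vbar),
    fixed = list(alpha = alpha), buffer = bst)
  # for logarithmic |s| spacing rebuild the floating block point-by-point
  if (s_spacing == "logarithmic") {
    flo <- do.call(rbind, lapply(neg_pts, function(sv) {
      build_subgrid(grid_axis("s", sv, sv + abs(sv) * 1e-9, 1),
                    grid_axis("vbar", flo_lo, vbar_float[2], n_vbar),
                    fixed = list(alpha = alpha), buffer = bst)
    }))
    attr(flo, "axes") <- list(
      s = grid_axis("s", min(neg_pts), max(neg_pts), n_neg),
      second = grid_axis("vbar", flo_lo, vbar_float[2], n_vbar),
      fixed = list(alpha = alpha))
  }
  combine_grids(flo, sed, buffer = bst)
}

#' Export a grid as a columnar text table
#'
#' One solute per row: `s_svedberg, vbar, alpha, D, M, Rh_nm`.
#'
#' @param grid A [combine_grids()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_grid <- function(grid, path) {
  sol <- grid$solutes
  out <- data.frame(s_svedberg = to_svedberg(sol$s), vbar = sol$vbar,
                    alpha = sol$alpha, D = sol$D, M = sol$M,
                    Rh_nm = sol$Rh * 1e7)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
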