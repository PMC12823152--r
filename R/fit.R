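# Two-dimensional spectrum fitting: a scan set is modeled as a
# non-negative linear combination of grid-solute Lamm solutions, optionally
# plus a time-invariant (per-radius) and a radially-invariant (per-scan)
# systematic noise vector. Basis solutions are simulated on demand and
# cached keyed by (solute, geometry, rotor speed, times, radii), so
# alternation rounds, refinement passes and Monte Carlo iterations reuse
# one simulation per solute.

.basis_cache <- new.env(parent = emptyenv())

#' Empty the Lamm basis cache
#'
#' Basis solutions are memoized per (solute, experiment signature). Long
#' multi-experiment pipelines may call this between experiments to bound
#' memory.
#' @return Invisibly, the number of cached experiments dropped.
#' @export
clear_basis_cache <- function() {
  n <- length(ls(.basis_cache))
  rm(list = ls(.basis_cache), envir = .basis_cache)
  invisible(n)
}

data_signature <- function(data, n_radii, tol) {
  paste(paste(format(c(data$geometry$meniscus, data$geometry$bottom,
                       data$omega, n_radii, tol), digits = 15),
              collapse = ","),
        paste(format(data$times, digits = 12), collapse = ","),
        length(data$radii),
        format(data$radii[1], digits = 12),
        format(data$radii[length(data$radii)], digits = 12),
        sep = "|")
}

# Design matrix: one column per solute, the unit-amplitude simulated scan
# set flattened column-major (scans fastest).
basis_matrix <- function(solutes, data, n_radii = 240, tol = 1e-5,
                         use_cache = TRUE) {
  sig <- data_signature(data, n_radii, tol)
  store <- NULL
  if (use_cache) {
    store <- .basis_cache[[sig]]
    if (is.null(store)) {
      store <- new.env(parent = emptyenv())
      .basis_cache[[sig]] <- store
    }
  }
  npts <- length(data$times) * length(data$radii)
  A <- matrix(0, nrow = npts, ncol = nrow(solutes))
  for (i in seq_len(nrow(solutes))) {
    key <- paste(format(solutes$s[i], digits = 15),
                 format(solutes$D[i], digits = 15))
    col <- if (!is.null(store)) store[[key]] else NULL
    if (is.null(col)) {
      pr <- lamm_profiles(solutes$s[i], solutes$D[i], data$geometry,
                          data$omega, data$times, loading = 1,
                          radii = data$radii, n_radii = n_radii, tol = tol)
      col <- as.vector(pr$signal)
      if (!is.null(store)) store[[key]] <- col
    }
    A[, i] <- col
  }
  A
}

rms <- function(x) sqrt(mean(x^2))

solute_key <- function(sol) paste(signif(sol$s, 12), signif(sol$vbar, 12),
                                  signif(sol$D, 12))

as_solute_table <- function(grid) {
  if (inherits(grid, "combined_grid")) grid$solutes
  else as.data.frame(grid)
}

# Remove the TI/RI-reachable subspace from a flattened scan-set vector or
# from every column of a design matrix. With both components this is the
# balanced two-way (scan x radius) additive-model projector: subtract the
# per-radius mean over scans and the per-scan mean over radii, add back the
# grand mean. Grouping is done with rowsum() so large design matrices stay
# cheap.
project_out_noise <- function(M, nt, nr, fit_ti, fit_ri) {
  M <- as.matrix(M)
  radius_idx <- rep(seq_len(nr), each = nt)
  scan_idx <- rep(seq_len(nt), times = nr)
  out <- M
  if (fit_ti) {
    rm_ <- rowsum(M, radius_idx, reorder = TRUE) / nt
    out <- out - rm_[radius_idx, , drop = FALSE]
  }
  if (fit_ri) {
    sm_ <- rowsum(M, scan_idx, reorder = TRUE) / nr
    out <- out - sm_[scan_idx, , drop = FALSE]
  }
  if (fit_ti && fit_ri)
    out <- out + rep(colMeans(M), each = nrow(M))
  out
}

# Shared core: NNLS on a fixed candidate solute set, with the TI/RI noise
# subspace projected out of both the data and the basis so the solute
# amplitudes and the noise vectors solve the joint least-squares problem
# in one pass (the exact fixed point of the classic alternating scheme:
# NNLS on noise-corrected data, TI = per-radius residual mean, RI =
# per-scan residual mean after TI removal). The RI vector is re-centered
# to zero mean, with the offset absorbed into TI.
fit_core <- function(data, solutes, fit_ti = FALSE, fit_ri = FALSE,
                     n_radii = 240, tol = 1e-5, use_cache = TRUE,
                     warm_start = NULL) {
  solutes <- as_solute_table(grid = solutes)
  if (!nrow(solutes)) stop("empty candidate solute set")
  if (fit_ri && length(data$times) < 3)
    stop("radially-invariant noise requires at least 3 scans")
  nt <- length(data$times); nr <- length(data$radii)
  A <- basis_matrix(solutes, data, n_radii, tol, use_cache)
  b0 <- as.vector(data$signal)
  if (fit_ti || fit_ri) {
    Ap <- project_out_noise(A, nt, nr, fit_ti, fit_ri)
    bp <- as.vector(project_out_noise(b0, nt, nr, fit_ti, fit_ri))
  } else {
    Ap <- A; bp <- b0
  }
  fit <- .nnls_lh_cpp(Ap, bp, 1e-12, 10000L, warm_start)
  if (!fit$converged)
    warning(sprintf("NNLS did not reach the KKT tolerance in %d iterations",
                    fit$iterations))
  x <- as.numeric(fit$x)
  resid <- matrix(b0 - as.vector(A %*% x), nt, nr)
  ti <- NULL; ri <- NULL
  if (fit_ti) {
    ti <- colMeans(resid)
    resid <- resid - matrix(ti, nt, nr, byrow = TRUE)
  }
  if (fit_ri) {
    ri <- rowMeans(resid)
    resid <- resid - ri
    if (fit_ti) {
      # zero-mean identifiability convention; offset moves into TI
      off <- mean(ri)
      ri <- ri - off
      ti <- ti + off
    }
  }
  rmsd <- rms(resid)
  sol <- solutes
  sol$amplitude <- x
  structure(list(solutes = sol,
                 ti_noise = ti,
                 ri_noise = ri,
                 rmsd = rmsd,
                 meniscus = data$geometry$meniscus,
                 bottom = data$geometry$bottom,
                 provenance = list(fit_ti = fit_ti, fit_ri = fit_ri,
                                   n_radii = n_radii, tol = tol,
                                   nnls_iterations = fit$iterations)),
            class = "fit_model")
}

#' @export
print.fit_model <- function(x, ...) {
  nz <- sum(x$solutes$amplitude > 0)
  cat(sprintf(paste0("<fit_model> rmsd = %.6g, %d/%d solutes with nonzero ",
                     "amplitude, total signal %.4g\n"),
              x$rmsd, nz, nrow(x$solutes), sum(x$solutes$amplitude)))
  invisible(x)
}

#' Non-negative least squares fit of a scan set over a solute grid
#'
#' Finds amplitudes `c_i >= 0` minimizing the L2 misfit between the data
#' and the linear combination of grid-solute Lamm solutions. The rmsd is
#' the root-mean-square residual over all (scan, radius) points.
#'
#' @param data A [scan_set()].
#' @param grid A [combine_grids()] result or a solute table with columns
#'   `s`, `D` (and `vbar` etc. for downstream interpretation).
#' @param fit_ti,fit_ri Also estimate time-invariant / radially-invariant
#'   noise vectors (see [fit_noise()]).
#' @param n_radii Solver nodes used when simulating basis solutions.
#' @param tol Lamm solver local error tolerance.
#' @param use_cache Reuse memoized basis solutions.
#' @return A `fit_model`: the candidate solute table with an `amplitude`
#'   column, optional `ti_noise` / `ri_noise` vectors, `rmsd`, and fit
#'   provenance.
#' @export
nnls_fit <- function(data, grid, fit_ti = FALSE, fit_ri = FALSE,
                     n_radii = 240, tol = 1e-5, use_cache = TRUE) {
  fit_core(data, grid, fit_ti, fit_ri, n_radii, tol, use_cache = use_cache)
}

#' Fit with time-invariant and radially-invariant noise decomposition
#'
#' Systematic offsets of absorbance optics decompose into a per-radius
#' (time-invariant, TI) vector and a per-scan (radially-invariant, RI)
#' vector estimated jointly with the sedimentation model: the noise
#' subspace is projected out of data and basis before the NNLS solve, which
#' lands directly on the fixed point of the classical alternating scheme
#' (NNLS on noise-corrected data / per-radius residual means / per-scan
#' residual means). The RI vector is constrained to zero mean — the
#' identifiability convention that resolves the TI/RI/baseline degeneracy;
#' the absorbed offset moves into the TI vector.
#'
#' @inheritParams nnls_fit
#' @param fit_ti,fit_ri Which noise components to estimate.
#' @return A `fit_model` (see [nnls_fit()]).
#' @export
fit_noise <- function(data, grid, fit_ti = TRUE, fit_ri = TRUE,
                      n_radii = 240, tol = 1e-5, use_cache = TRUE) {
  fit_core(data, grid, fit_ti, fit_ri, n_radii, tol, use_cache = use_cache)
}

#' Iterative refinement across grid partitions
#'
#' Fits each coarse partition in turn, carrying the nonzero solutes forward
#' and refitting them together with the next partition, and repeats full
#' passes until the nonzero solute set is unchanged between passes (or
#' `max_iterations` passes). Because every refit's candidate set contains
#' the previous nonzero set, the rmsd is non-increasing along the schedule
#' and the final rmsd is bounded by every single-partition rmsd.
#'
#' @inheritParams nnls_fit
#' @param n_partitions Number of interleaved partitions (see
#'   [partition_for_refinement()]).
#' @param max_iterations Maximum number of full passes.
#' @return A `fit_model`; `provenance$rmsd_history` records the rmsd after
#'   every merge step.
#' @export
iterative_refine <- function(data, grid, n_partitions = 8,
                             max_iterations = 10, fit_ti = FALSE,
                             fit_ri = FALSE, n_radii = 240, tol = 1e-5,
                             use_cache = TRUE) {
  stopifnot(inherits(grid, "combined_grid"))
  parts <- partition_for_refinement(grid, n_partitions)
  carried <- NULL
  history <- numeric(0)
  model <- NULL
  prev_keys <- NULL
  for (pass in seq_len(max_iterations)) {
    for (p in parts) {
      cand <- if (is.null(carried)) p else {
        merged <- rbind(carried[, names(p), drop = FALSE], p)
        merged[!duplicated(solute_key(merged)), , drop = FALSE]
      }
      # carried solutes (rows 1..k of cand) seed the active set
      warm <- if (is.null(carried)) NULL else seq_len(nrow(carried))
      model <- fit_core(data, cand, fit_ti, fit_ri, n_radii, tol,
                        use_cache = use_cache, warm_start = warm)
      history <- c(history, model$rmsd)
      carried <- model$solutes[model$solutes$amplitude > 0,
                               setdiff(names(model$solutes), "amplitude"),
                               drop = FALSE]
    }
    keys <- sort(solute_key(carried))
    if (!is.null(prev_keys) && identical(keys, prev_keys)) break
    prev_keys <- keys
  }
  model$provenance$rmsd_history <- history
  model$provenance$passes <- pass
  model$provenance$n_partitions <- n_partitions
  model
}

#' Refine meniscus (and optionally bottom) by grid search
#'
#' Performs a full fit at each candidate boundary position, then refines
#' the discrete rmsd minimum along each axis by parabolic interpolation
#' through the bracketing candidates and refits at the interpolated
#' optimum. A minimum on the edge of the search range is flagged as not
#' bracketed (`provenance$bracketed`).
#'
#' @inheritParams nnls_fit
#' @param meniscus_range Length-2 numeric range, cm.
#' @param n_candidates Candidates per axis.
#' @param bottom_range Optional length-2 range for the cell bottom, cm.
#' @return A `fit_model` with fields `meniscus`/`bottom` set to the fitted
#'   positions and `provenance$boundary_search` holding the rmsd profile.
#' @export
fit_boundary_positions <- function(data, grid, meniscus_range,
                                   n_candidates = 5, bottom_range = NULL,
                                   fit_ti = FALSE, fit_ri = FALSE,
                                   n_radii = 240, tol = 1e-5,
                                   use_cache = TRUE) {
  rspan <- range(data$radii)
  if (meniscus_range[1] < rspan[1] || meniscus_range[2] > rspan[2])
    stop("meniscus_range must lie within the data's radial span")
  if (!is.null(bottom_range) &&
      (bottom_range[1] < rspan[1] || bottom_range[2] > rspan[2]))
    stop("bottom_range must lie within the data's radial span")
  men <- seq(meniscus_range[1], meniscus_range[2], length.out = n_candidates)
  bot <- if (is.null(bottom_range)) data$geometry$bottom else
    seq(bottom_range[1], bottom_range[2], length.out = n_candidates)
  fit_at <- function(m, b) {
    d <- data
    d$geometry <- cell_geometry(m, b, data$geometry$sector_angle,
                                data$geometry$pathlength)
    fit_core(d, grid, fit_ti, fit_ri, n_radii, tol, use_cache = use_cache)
  }
  prof <- expand.grid(meniscus = men, bottom = bot, KEEP.OUT.ATTRS = FALSE)
  prof$rmsd <- mapply(function(m, b) fit_at(m, b)$rmsd,
                      prof$meniscus, prof$bottom)
  best <- which.min(prof$rmsd)
  parab <- function(xs, ys, i) {
    if (i == 1 || i == length(xs)) return(list(x = xs[i], edge = TRUE))
    x <- xs[(i - 1):(i + 1)]; y <- ys[(i - 1):(i + 1)]
    denom <- (x[1] - x[2]) * (x[1] - x[3]) * (x[2] - x[3])
    a <- (x[3] * (y[2] - y[1]) + x[2] * (y[1] - y[3]) +
            x[1] * (y[3] - y[2])) / denom
    bq <- (x[3]^2 * (y[1] - y[2]) + x[2]^2 * (y[3] - y[1]) +
             x[1]^2 * (y[2] - y[3])) / denom
    if (a <= 0) return(list(x = x[2], edge = FALSE))
    list(x = max(min(-bq / (2 * a), x[3]), x[1]), edge = FALSE)
  }
  im <- which(men == prof$meniscus[best])
  mcurve <- vapply(men, function(m)
    min(prof$rmsd[prof$meniscus == m]), 1.0)
  pm <- parab(men, mcurve, im)
  bracketed <- !pm$edge
  m_hat <- pm$x
  b_hat <- prof$bottom[best]
  if (!is.null(bottom_range)) {
    ib <- which(bot == prof$bottom[best])
    bcurve <- vapply(bot, function(b)
      min(prof$rmsd[prof$bottom == b]), 1.0)
    pb <- parab(bot, bcurve, ib)
    bracketed <- bracketed && !pb$edge
    b_hat <- pb$x
  }
  if (!bracketed)
    warning("boundary-position minimum lies on the search range edge; ",
            "not bracketed")
  model <- fit_at(m_hat, b_hat)
  model$meniscus <- m_hat
  model$bottom <- b_hat
  model$provenance$boundary_search <- prof
  model$provenance$bracketed <- bracketed
  model
}

#' Model prediction on the data's (scan, radius) lattice
#'
#' @param object A `fit_model`.
#' @param data The [scan_set()] it was fitted to.
#' @param include_noise Add the fitted TI/RI noise vectors.
#' @param ... Unused.
#' @return Matrix of predicted signal, scans by radii.
#' @export
predict.fit_model <- function(object, data, include_noise = TRUE, ...) {
  nt <- length(data$times); nr <- length(data$radii)
  keep <- object$solutes$amplitude > 0
  d <- data
  d$geometry <- cell_geometry(object$meniscus, object$bottom,
                              data$geometry$sector_angle,
                              data$geometry$pathlength)
  pred <- matrix(0, nt, nr)
  if (any(keep)) {
    A <- basis_matrix(object$solutes[keep, , drop = FALSE], d,
                      object$provenance$n_radii, object$provenance$tol)
    pred <- matrix(as.vector(A %*% object$solutes$amplitude[keep]), nt, nr)
  }
  if (include_noise) {
    if (!is.null(object$ti_noise))
      pred <- pred + matrix(object$ti_noise, nt, nr, byrow = TRUE)
    if (!is.null(object$ri_noise)) pred <- pred + object$ri_noise
  }
  pred
}

#' Residual matrix of a fit
#' @inheritParams predict.fit_model
#' @param model A `fit_model`.
#' @return Matrix of residuals, scans by radii.
#' @export
fit_residuals <- function(model, data) {
  data$signal - predict(model, data)
}

#' Wald-Wolfowitz runs z-score of a residual vector
#'
#' A symmetric sanity check for systematic misfit: long same-sign stretches
#' (stripes) drive the z-score strongly negative, alternation drives it
#' positive; white residuals give |z| of order 1.
#'
#' @param x Residual vector.
#' @return z-score (0 when all residuals share one sign).
#' @export
runs_zscore <- function(x) {
  sgn <- sign(x)
  sgn <- sgn[sgn != 0]
  n1 <- sum(sgn > 0); n2 <- sum(sgn < 0)
  if (n1 == 0 || n2 == 0) return(0)
  runs <- 1 + sum(diff(sgn) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  (runs - mu) / sqrt(v)
}

#' Monte Carlo error analysis of a converged fit
#'
#' Generates `n_iterations` synthetic data sets as the model prediction
#' plus noise (by default homoscedastic Gaussian with sigma equal to the
#' fit rmsd; optionally resampled fit residuals), refits each over the
#' model's candidate solute set, and returns the ensemble. Each iteration
#' uses a seed derived from `seed`, so the ensemble is identical regardless
#' of execution order.
#'
#' @param data The fitted [scan_set()].
#' @param model A converged `fit_model` of `data`.
#' @param n_iterations Number of iterations (>= 2).
#' @param seed Integer seed.
#' @param noise `"gaussian"` or `"residual"`.
#' @return An object of class `mc_ensemble`: list of `fit_model`s plus the
#'   parent model.
#' @export
monte_carlo <- function(data, model, n_iterations = 100, seed = 1,
                        noise = c("gaussian", "residual")) {
  noise <- match.arg(noise)
  if (n_iterations < 2) stop("n_iterations must be >= 2")
  pred <- predict(model, data, include_noise = TRUE)
  resid <- as.vector(data$signal - pred)
  cand <- model$solutes[, setdiff(names(model$solutes), "amplitude"),
                        drop = FALSE]
  d <- data
  d$geometry <- cell_geometry(model$meniscus, model$bottom,
                              data$geometry$sector_angle,
                              data$geometry$pathlength)
  models <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    eps <- with_seed(seed + i, {
      if (noise == "gaussian")
        rnorm(length(pred), sd = model$rmsd)
      else sample(resid, length(pred), replace = TRUE)
    })
    d$signal <- pred + matrix(eps, nrow(pred), ncol(pred))
    models[[i]] <- fit_core(d, cand,
                            fit_ti = !is.null(model$ti_noise),
                            fit_ri = !is.null(model$ri_noise),
                            n_radii = model$provenance$n_radii,
                            tol = model$provenance$tol)
  }
  structure(list(models = models, parent = model, seed = seed,
                 noise = noise),
            class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  r <- vapply(x$models, function(m) m$rmsd, 1.0)
  cat(sprintf("<mc_ensemble> %d iterations, rmsd %.3g +/- %.2g (seed %s)\n",
              length(x$models), mean(r), sd(r), format(x$seed)))
  invisible(x)
}

#' Merged solute distribution of a fit or Monte Carlo ensemble
#'
#' For an ensemble, every iteration's nonzero solutes enter with weight
#' `amplitude / n_iterations`; for a single model the amplitudes are used
#' directly.
#'
#' @param x A `fit_model`, `mc_ensemble`, or a distribution data frame
#'   (passed through unchanged).
#' @return Data frame with the solute columns plus `weight` (signal units).
#' @export
solute_distribution <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("s", "weight") %in% names(x)))
      stop("distribution data frame needs columns s and weight")
    return(x)
  }
  if (inherits(x, "fit_model")) {
    out <- x$solutes[x$solutes$amplitude > 0, , drop = FALSE]
    out$weight <- out$amplitude
    out$amplitude <- NULL
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(x, "mc_ensemble"))
  n <- length(x$models)
  pieces <- lapply(x$models, function(m) {
    d <- m$solutes[m$solutes$amplitude > 0, , drop = FALSE]
    d$weight <- d$amplitude / n
    d$amplitude <- NULL
    d
  })
  out <- do.call(rbind, pieces)
  agg <- stats::aggregate(weight ~ s + vbar + D + M + Rh + alpha, data = out,
                          FUN = sum)
  agg <- agg[order(agg$s), ]
  rownames(agg) <- NULL
  agg
}
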