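# Parametrically constrained spectrum analysis with a straight-line
# vbar(s) family: the basis is restricted to solutes lying on a candidate
# line in the (s, vbar) plane at fixed frictional ratio; the line with the
# lowest NNLS rmsd wins, followed by one refinement pass on a finer
# endpoint grid around the winner.

#' Straight-line PCSA family specification
#'
#' Candidate lines are parameterized by their vbar values at the two ends
#' of the s range; the K x K Cartesian product of endpoint grids defines
#' the family.
#'
#' @param s_range Length-2 s range, Svedberg.
#' @param vbar_start_range,vbar_end_range Length-2 vbar ranges (mL/g) at
#'   `s_range[1]` and `s_range[2]`.
#' @param K Endpoint grid resolution per axis (>= 2).
#' @param L Solutes per candidate line (>= 2).
#' @param alpha Fixed frictional ratio.
#' @return An object of class `line_family_spec`.
#' @export
line_family_spec <- function(s_range, vbar_start_range, vbar_end_range,
                             K = 8, L = 30, alpha = 1.1) {
  if (K < 2 || L < 2) stop("K and L must be >= 2")
  if (!(s_range[1] < s_range[2])) stop("s_range must be increasing")
  structure(list(s_range = s_range, vbar_start_range = vbar_start_range,
                 vbar_end_range = vbar_end_range, K = as.integer(K),
                 L = as.integer(L), alpha = alpha),
            class = "line_family_spec")
}

line_solutes <- function(family, v1, v2, buffer,
                         exclusion = .BUOYANCY_EXCLUSION) {
  s_sv <- seq(family$s_range[1], family$s_range[2],
              length.out = family$L)
  vb <- v1 + (v2 - v1) * (s_sv - family$s_range[1]) /
    diff(family$s_range)
  s <- from_svedberg(s_sv)
  b <- buoyancy(pmax(vb, 1e-6), buffer$rho)
  ok <- vb > 0 & sign(s) * sign(b) > 0 & abs(b) >= exclusion & s != 0
  if (sum(ok) < 2) return(NULL)
  solute_from_s_vbar(s[ok], vb[ok], family$alpha, buffer, exclusion)
}

#' Fit a scan set with the straight-line PCSA
#'
#' Every candidate line is realized as `L` solutes along `vbar(s)` (points
#' violating the buoyancy exclusion or sign consistency are dropped; a line
#' with fewer than two valid solutes is skipped) and NNLS-fitted; the line
#' with minimal rmsd wins, with ties broken by smallest `|slope|`, then
#' smallest intercept. A second pass repeats the search on a K x K endpoint
#' neighborhood one grid spacing wide around the winner.
#'
#' @param data A [scan_set()].
#' @param family A [line_family_spec()].
#' @param refine Run the second, finer pass (default TRUE).
#' @param fit_ti,fit_ri Estimate TI/RI noise during each line fit.
#' @inheritParams nnls_fit
#' @return A list of class `pcsa_fit`: `model` (the winning `fit_model`),
#'   `intercept` (vbar at s = 0), `slope` (mL/g per Svedberg), `endpoints`
#'   (winning vbar values at the s range ends), `rmsd`, and the first-pass
#'   search table `search`.
#' @export
pcsa_fit <- function(data, family, refine = TRUE, fit_ti = FALSE,
                     fit_ri = FALSE, n_radii = 240, tol = 1e-5,
                     use_cache = TRUE) {
  bst <- as_buffer_state(data$buffer)
  run_pass <- function(v1s, v2s) {
    cand <- expand.grid(v1 = v1s, v2 = v2s, KEEP.OUT.ATTRS = FALSE)
    cand$rmsd <- NA_real_
    models <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      sol <- line_solutes(family, cand$v1[i], cand$v2[i], bst)
      if (is.null(sol)) next
      models[[i]] <- fit_core(data, sol, fit_ti, fit_ri, n_radii, tol,
                              use_cache = use_cache)
      cand$rmsd[i] <- models[[i]]$rmsd
    }
    if (all(is.na(cand$rmsd)))
      stop("no valid candidate line (all violate the buoyancy exclusion)")
    slope <- (cand$v2 - cand$v1) / diff(family$s_range)
    intercept <- cand$v1 - slope * family$s_range[1]
    ord <- order(cand$rmsd, abs(slope), intercept)
    best <- ord[1]
    list(cand = cand, best = best, model = models[[best]],
         slope = slope[best], intercept = intercept[best])
  }
  v1s <- seq(family$vbar_start_range[1], family$vbar_start_range[2],
             length.out = family$K)
  v2s <- seq(family$vbar_end_range[1], family$vbar_end_range[2],
             length.out = family$K)
  pass1 <- run_pass(v1s, v2s)
  result <- pass1
  if (refine) {
    h1 <- diff(family$vbar_start_range) / (family$K - 1)
    h2 <- diff(family$vbar_end_range) / (family$K - 1)
    w1 <- pass1$cand$v1[pass1$best]; w2 <- pass1$cand$v2[pass1$best]
    pass2 <- run_pass(seq(w1 - h1, w1 + h1, length.out = family$K),
                      seq(w2 - h2, w2 + h2, length.out = family$K))
    if (pass2$cand$rmsd[pass2$best] <= pass1$cand$rmsd[pass1$best])
      result <- pass2
  }
  structure(list(model = result$model,
                 intercept = result$intercept, slope = result$slope,
                 endpoints = c(result$cand$v1[result$best],
                               result$cand$v2[result$best]),
                 rmsd = result$model$rmsd,
                 search = pass1$cand, family = family),
            class = "pcsa_fit")
}

#' @export
print.pcsa_fit <- function(x, ...) {
  cat(sprintf(paste0("<pcsa_fit> vbar(s) = %.5f %+.3g * s_S, rmsd = %.6g\n"),
              x$intercept, x$slope, x$rmsd))
  invisible(x)
}

# Average vertical distance between the cumulative (signal-weighted) s
# distributions of two models, in signal units: the L1 distance between
# the two cumulative amplitude curves divided by the shared s span.
# Zero for identical distributions; insensitive to sub-grid peak shifts.
sdist_cdf_distance <- function(d1, d2) {
  s_all <- sort(unique(c(d1$s, d2$s)))
  if (length(s_all) < 2) return(0)
  F1 <- vapply(s_all, function(z) sum(d1$weight[d1$s <= z]), 1.0)
  F2 <- vapply(s_all, function(z) sum(d2$weight[d2$s <= z]), 1.0)
  dx <- diff(s_all)
  sum(abs(F1 - F2)[-length(s_all)] * dx) / (max(s_all) - min(s_all))
}

#' Compare a custom-grid model with a PCSA model on the same data
#'
#' @param cg_model A `fit_model` from the unconstrained combined-grid fit.
#' @param pcsa_model A `pcsa_fit` or `fit_model` from the constrained fit.
#' @return A list of class `model_comparison`: `rmsd` (both values and
#'   their ratio CG/PCSA), `distribution_distance` (average discrepancy of
#'   the cumulative s-distributions, signal units), `total_signal`,
#'   `overlay` (long data frame of s in Svedberg, weight, method) and
#'   `scatter` ((s, vbar, weight) points of both models).
#' @export
compare_models <- function(cg_model, pcsa_model) {
  if (inherits(pcsa_model, "pcsa_fit")) pcsa_model <- pcsa_model$model
  stopifnot(inherits(cg_model, "fit_model"), inherits(pcsa_model, "fit_model"))
  if (abs(cg_model$meniscus - pcsa_model$meniscus) > 1e-9 ||
      abs(cg_model$bottom - pcsa_model$bottom) > 1e-9)
    stop("models were fitted to different data (geometry mismatch)")
  d1 <- solute_distribution(cg_model)
  d2 <- solute_distribution(pcsa_model)
  overlay <- rbind(
    data.frame(s_svedberg = to_svedberg(d1$s), weight = d1$weight,
               method = "custom_grid"),
    data.frame(s_svedberg = to_svedberg(d2$s), weight = d2$weight,
               method = "pcsa"))
  scatter <- rbind(
    data.frame(s_svedberg = to_svedberg(d1$s), vbar = d1$vbar,
               weight = d1$weight, method = "custom_grid"),
    data.frame(s_svedberg = to_svedberg(d2$s), vbar = d2$vbar,
               weight = d2$weight, method = "pcsa"))
  structure(list(rmsd = c(custom_grid = cg_model$rmsd,
                          pcsa = pcsa_model$rmsd,
                          ratio = cg_model$rmsd / pcsa_model$rmsd),
                 distribution_distance = sdist_cdf_distance(d1, d2),
                 total_signal = c(custom_grid = sum(d1$weight),
                                  pcsa = sum(d2$weight)),
                 overlay = overlay, scatter = scatter),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(paste0("<model_comparison> rmsd CG %.6g vs PCSA %.6g ",
                     "(ratio %.3f); s-distribution distance %.4g ",
                     "(total signal %.4g)\n"),
              x$rmsd["custom_grid"], x$rmsd["pcsa"], x$rmsd["ratio"],
              x$distribution_distance, x$total_signal["custom_grid"]))
  invisible(x)
}
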