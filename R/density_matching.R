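# Density matching: sedimentation distributions fitted at several D2O
# fractions are divided into boundary fractions (cumulative-signal
# quantile slices), the viscosity-corrected mean s of each fraction is
# regressed on solvent density, and the zero-sedimentation crossing gives
# the matching density, hence the partial specific volume, of that
# fraction. Molar mass and hydrodynamic radius follow from the Svedberg
# and Stokes-Einstein relations at a reference solvent condition.

#' Viscosity-only correction of a sedimentation distribution
#'
#' Multiplies every s by `eta_buffer / eta_reference`, preserving signs.
#' After this correction an ideal species' s is exactly linear in solvent
#' density (the frictional coefficient's viscosity dependence is divided
#' out), which is what makes the linear extrapolation to zero sedimentation
#' exact.
#'
#' @param distribution Data frame with columns `s` (seconds) and `weight`.
#' @param buffer The solvent the distribution was measured in.
#' @param reference The reference solvent.
#' @return The distribution with corrected `s`.
#' @export
viscosity_correct <- function(distribution, buffer, reference) {
  buffer <- as_buffer_state(buffer); reference <- as_buffer_state(reference)
  distribution$s <- distribution$s * buffer$eta / reference$eta
  distribution
}

#' Signal-weighted mean s per boundary fraction
#'
#' Solutes are ordered by s (most negative first), the cumulative signal is
#' formed, the outer `tail_exclusion` mass is dropped on each side, and the
#' remaining central mass is divided into `n_fractions` equal-signal
#' slices. Point masses straddling a slice edge are split proportionally.
#'
#' @param x A `fit_model`, `mc_ensemble`, or distribution data frame with
#'   columns `s` and `weight`.
#' @param n_fractions Number of boundary fractions (>= 1).
#' @param tail_exclusion Fraction of total signal excluded from each tail.
#' @return Data frame with `fraction`, `quantile` (cumulative-signal
#'   midpoint, as a fraction of total), `mean_s` (seconds), `weight`.
#' @export
boundary_fractions <- function(x, n_fractions = 100, tail_exclusion = 0.02) {
  dist <- if (is.data.frame(x)) x else solute_distribution(x)
  out <- fraction_averages(dist, "s", n_fractions, tail_exclusion)
  names(out)[names(out) == "s"] <- "mean_s"
  out
}

# Quantile-slice machinery shared by boundary_fractions and the synthetic
# ground-truth helper: slice the s-ordered cumulative signal and return the
# signal-weighted mean of each requested column per slice; point masses
# straddling an edge are split proportionally.
fraction_averages <- function(dist, cols, n_fractions, tail_exclusion) {
  dist <- dist[dist$weight > 0, , drop = FALSE]
  if (!nrow(dist)) stop("empty sedimentation distribution")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  dist <- dist[order(dist$s), , drop = FALSE]
  w <- dist$weight
  total <- sum(w)
  hi_cum <- cumsum(w); lo_cum <- hi_cum - w
  edges <- seq(tail_exclusion * total, (1 - tail_exclusion) * total,
               length.out = n_fractions + 1)
  out <- data.frame(fraction = seq_len(n_fractions),
                    quantile = (head(edges, -1) + tail(edges, -1)) /
                      (2 * total))
  out$weight <- NA_real_
  for (cl in cols) out[[cl]] <- NA_real_
  for (j in seq_len(n_fractions)) {
    ov <- pmin(hi_cum, edges[j + 1]) - pmax(lo_cum, edges[j])
    ov[ov < 0] <- 0
    out$weight[j] <- sum(ov)
    if (out$weight[j] > 0)
      for (cl in cols)
        out[[cl]][j] <- sum(ov * dist[[cl]]) / out$weight[j]
  }
  out
}

#' Extrapolate one boundary fraction's s(rho) series to zero sedimentation
#'
#' Ordinary least squares of the viscosity-corrected mean s on solvent
#' density. The zero crossing `rho_m = -intercept/slope` is the matching
#' density and `vbar = 1/rho_m`. A non-negative slope, or a crossing
#' outside (0.9, 1.3) g/mL, marks the fraction unmatchable.
#'
#' @param series Data frame with columns `rho` (g/mL) and `s` (corrected,
#'   seconds), one row per solvent density; at least two distinct
#'   densities.
#' @return List with `rho_m`, `vbar`, `slope`, `intercept`, `ok`, `reason`.
#' @export
extrapolate_vbar <- function(series) {
  if (length(unique(series$rho)) < 2)
    stop("at least two distinct solvent densities required")
  fit <- lm(s ~ rho, data = series)
  intercept <- coef(fit)[[1]]; slope <- coef(fit)[[2]]
  out <- list(rho_m = NA_real_, vbar = NA_real_, slope = slope,
              intercept = intercept, ok = FALSE, reason = "")
  if (!is.finite(slope) || slope >= 0) {
    out$reason <- "non-negative slope: s does not decrease with density"
    return(out)
  }
  rho_m <- -intercept / slope
  if (rho_m <= 0.9 || rho_m >= 1.3) {
    out$rho_m <- rho_m
    out$reason <- sprintf("matching density %.4f g/mL outside (0.9, 1.3)",
                          rho_m)
    return(out)
  }
  out$rho_m <- rho_m; out$vbar <- 1 / rho_m; out$ok <- TRUE
  out
}

#' Density matching across solvent densities
#'
#' Combines fits (or Monte Carlo ensembles) obtained at two or more D2O
#' fractions: each distribution is viscosity-corrected to the reference
#' solvent, divided into boundary fractions, fractions are paired across
#' densities by cumulative-signal quantile rank — taken in the direction of
#' each condition's dominant transport, so a condition in which the sample
#' as a whole has crossed the density-match point pairs its fractions in
#' reversed order — and each fraction's s(rho) series is extrapolated to
#' zero sedimentation. Molar mass and
#' hydrodynamic radius are then derived at the reference condition from
#' the fraction's extrapolated vbar and its reference-condition s via the
#' fixed-frictional-ratio parameterization.
#'
#' @param fits List of `fit_model` / `mc_ensemble` (or plain distribution
#'   data frames with columns `s`, `weight`), one per solvent.
#' @param buffers List of [buffer_spec()] / [solvent_state()], same order.
#' @param n_fractions Number of boundary fractions.
#' @param tail_exclusion Signal fraction excluded per tail.
#' @param reference Index of the reference solvent; defaults to the least
#'   dense (0% D2O) condition, which carries the largest |s| signal.
#' @param alpha Fixed frictional ratio; defaults to the one stored in the
#'   first fit's solute table.
#' @param exclusion Buoyancy exclusion threshold for the mass derivation;
#'   fractions whose `|1 - vbar rho_ref|` falls below it are skipped and
#'   counted.
#' @return An object of class `density_match_result`: data frame `fractions`
#'   with `fraction, quantile, rho_m, vbar, M, Rh_nm, weight, ok, reason`,
#'   plus `series` (the per-fraction corrected s at each density),
#'   `n_skipped_exclusion`, and the settings used.
#' @export
density_match <- function(fits, buffers, n_fractions = 100,
                          tail_exclusion = 0.02, reference = NULL,
                          alpha = NULL, exclusion = .BUOYANCY_EXCLUSION) {
  stopifnot(length(fits) == length(buffers), length(fits) >= 2)
  states <- lapply(buffers, as_buffer_state)
  rhos <- vapply(states, function(b) b$rho, 1.0)
  if (is.null(reference)) reference <- which.min(rhos)
  ref <- states[[reference]]
  if (is.null(alpha)) {
    first <- fits[[1]]
    alpha <- if (inherits(first, "mc_ensemble"))
      first$parent$solutes$alpha[1]
    else if (inherits(first, "fit_model")) first$solutes$alpha[1]
    else if (is.data.frame(first) && "alpha" %in% names(first))
      first$alpha[1]
    else stop("supply alpha explicitly for plain distribution input")
  }
  # Fractions are paired across densities by quantile rank in the
  # direction of each condition's dominant transport: for a condition whose
  # signal-weighted mean s is opposite in sign to the reference's, the
  # fraction order is reversed. Without this, a condition in which the
  # whole sample has crossed the density-match point (e.g. all floating)
  # would pair its fastest species with the reference's slowest, and the
  # exactness of the extrapolation for shared-vbar mixtures would be lost.
  orient_ref <- NULL
  fracs <- lapply(seq_along(fits), function(d) {
    dist <- solute_distribution(fits[[d]])
    dist <- viscosity_correct(dist, states[[d]], ref)
    fr <- boundary_fractions(dist, n_fractions, tail_exclusion)
    sgn <- sign(sum(dist$s * dist$weight))
    if (sgn == 0) sgn <- 1
    attr(fr, "transport_sign") <- sgn
    fr
  })
  orient_ref <- attr(fracs[[reference]], "transport_sign")
  fracs <- lapply(fracs, function(fr) {
    if (attr(fr, "transport_sign") * orient_ref < 0) {
      fr <- fr[rev(seq_len(nrow(fr))), , drop = FALSE]
      fr$fraction <- seq_len(nrow(fr))
      fr$quantile <- 1 - fr$quantile
      rownames(fr) <- NULL
    }
    fr
  })
  series <- do.call(rbind, lapply(seq_along(fracs), function(d) {
    data.frame(density_index = d, rho = rhos[d],
               fraction = as.integer(fracs[[d]]$fraction),
               s = as.numeric(fracs[[d]]$mean_s), row.names = NULL)
  }))
  ref_frac <- fracs[[reference]]
  rows <- lapply(seq_len(n_fractions), function(j) {
    ser <- series[series$fraction == j & is.finite(series$s), ]
    base <- data.frame(fraction = j, quantile = ref_frac$quantile[j],
                       rho_m = NA_real_, vbar = NA_real_, M = NA_real_,
                       Rh_nm = NA_real_, weight = ref_frac$weight[j],
                       ok = FALSE, reason = "", stringsAsFactors = FALSE)
    if (length(unique(ser$rho)) < 2) {
      base$reason <- "fewer than two densities with signal"
      return(base)
    }
    ex <- extrapolate_vbar(ser)
    base$rho_m <- ex$rho_m; base$vbar <- ex$vbar
    base$ok <- ex$ok; base$reason <- ex$reason
    if (!ex$ok) return(base)
    s_ref <- ref_frac$mean_s[j]
    b <- 1 - ex$vbar * ref$rho
    if (abs(b) < exclusion || sign(s_ref) * sign(b) <= 0) {
      base$ok <- FALSE
      base$reason <- "reference-condition buoyancy inside exclusion band"
      return(base)
    }
    D <- D_from_s_alpha_vbar(s_ref, alpha, ex$vbar, ref, exclusion)
    base$M <- mass_from_sD(s_ref, D, ex$vbar, ref, exclusion)
    f <- .RGAS * ref$temperature / (.NAVO * D)
    base$Rh_nm <- f / (6 * pi * ref$eta) * 1e7
    base
  })
  fractions <- do.call(rbind, rows)
  structure(list(fractions = fractions, series = series,
                 n_skipped_exclusion = sum(
                   fractions$reason ==
                     "reference-condition buoyancy inside exclusion band"),
                 reference = reference, alpha = alpha,
                 n_fractions = n_fractions, tail_exclusion = tail_exclusion),
            class = "density_match_result")
}

#' @export
print.density_match_result <- function(x, ...) {
  ok <- x$fractions[x$fractions$ok, ]
  cat(sprintf(paste0("<density_match_result> %d/%d fractions matched; ",
                     "vbar %.4f-%.4f mL/g, M %.3g-%.3g Da, Rh %.1f-%.1f nm\n"),
              nrow(ok), nrow(x$fractions),
              min(ok$vbar), max(ok$vbar), min(ok$M), max(ok$M),
              min(ok$Rh_nm), max(ok$Rh_nm)))
  invisible(x)
}

#' Signal-weighted histograms of the matched vbar / M / Rh values
#'
#' @param result A [density_match()] result.
#' @param n_bins Number of histogram bins.
#' @return Named list of data frames (`vbar`, `M`, `Rh_nm`), each with bin
#'   `mid` and summed `weight`; zero-weight fractions contribute nothing.
#' @export
match_histograms <- function(result, n_bins = 30) {
  ok <- result$fractions[result$fractions$ok & result$fractions$weight > 0, ]
  hist_of <- function(v, w, log_scale = FALSE) {
    if (log_scale) v <- log10(v)
    rng <- range(v)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(abs(rng) * 1e-3, 1e-9)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    idx <- pmin(findInterval(v, breaks, rightmost.closed = TRUE), n_bins)
    mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
    if (log_scale) mids <- 10^mids
    data.frame(mid = mids,
               weight = vapply(seq_len(n_bins),
                               function(k) sum(w[idx == k]), 1.0))
  }
  list(vbar = hist_of(ok$vbar, ok$weight),
       M = hist_of(ok$M, ok$weight, log_scale = TRUE),
       Rh_nm = hist_of(ok$Rh_nm, ok$weight))
}

#' Write a density-matching result as columnar text
#'
#' @param result A [density_match()] result.
#' @param path Output file path (CSV: fraction, quantile, rho_m, vbar,
#'   M_Da, Rh_nm, weight, ok).
#' @return The path, invisibly.
#' @export
write_density_match <- function(result, path) {
  fr <- result$fractions
  out <- data.frame(fraction = fr$fraction, quantile = fr$quantile,
                    rho_m = fr$rho_m, vbar = fr$vbar, M_Da = fr$M,
                    Rh_nm = fr$Rh_nm, weight = fr$weight, ok = fr$ok)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
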