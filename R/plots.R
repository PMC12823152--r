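# Diagnostic figures: sedimentation-distribution overlays across
# conditions or methods, residual bitmaps, and density-matching histograms.

#' Overlay sedimentation coefficient distributions
#'
#' @param distributions Named list of distribution data frames (columns `s`
#'   in seconds and `weight`), e.g. from [solute_distribution()]; names
#'   label the conditions.
#' @param smooth_sd Gaussian kernel width (Svedberg) used to render the
#'   discrete amplitudes as continuous curves.
#' @return A ggplot object.
#' @export
plot_s_distributions <- function(distributions, smooth_sd = 1) {
  long <- do.call(rbind, lapply(names(distributions), function(nm) {
    d <- distributions[[nm]]
    data.frame(condition = nm, s_svedberg = to_svedberg(d$s),
               weight = d$weight)
  }))
  rng <- range(long$s_svedberg)
  grid <- seq(rng[1] - 3 * smooth_sd, rng[2] + 3 * smooth_sd,
              length.out = 400)
  curves <- do.call(rbind, lapply(split(long, long$condition), function(d) {
    dens <- vapply(grid, function(x)
      sum(d$weight * stats::dnorm(x, d$s_svedberg, smooth_sd)), 1.0)
    data.frame(condition = d$condition[1], s_svedberg = grid,
               signal = dens)
  }))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$s_svedberg, y = .data$signal,
                               color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sedimentation coefficient (S)",
                  y = "signal density", color = NULL) +
    ggplot2::theme_minimal()
}

#' Residual bitmap of a fit
#'
#' A well-specified fit shows a random, grainy pattern without stripes.
#'
#' @param model A `fit_model`.
#' @param data The [scan_set()] it was fitted to.
#' @return A ggplot object.
#' @export
plot_residual_bitmap <- function(model, data) {
  res <- fit_residuals(model, data)
  df <- expand.grid(scan = seq_along(data$times), radius = data$radii)
  df$residual <- as.vector(res)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radius, y = .data$scan,
                                   fill = .data$residual)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "radius (cm)", y = "scan") +
    ggplot2::theme_minimal()
}

#' Histograms of matched vbar, molar mass, and hydrodynamic radius
#'
#' @param result A [density_match()] result.
#' @param n_bins Bins per histogram.
#' @return A named list of ggplot objects (`vbar`, `M`, `Rh_nm`).
#' @export
plot_match_histograms <- function(result, n_bins = 30) {
  h <- match_histograms(result, n_bins)
  bar <- function(d, xlab, logx = FALSE) {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$weight)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = xlab, y = "signal") +
      ggplot2::theme_minimal()
    if (logx) p <- p + ggplot2::scale_x_log10()
    p
  }
  list(vbar = bar(h$vbar, "partial specific volume (mL/g)"),
       M = bar(h$M, "molar mass (Da)", logx = TRUE),
       Rh_nm = bar(h$Rh_nm, "hydrodynamic radius (nm)"))
}
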