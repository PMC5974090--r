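#' Plot a fitted titration or displacement curve
#'
#' For a direct fit, plots the per-well fractional saturation against the
#' depletion-corrected free-site concentration together with the fitted
#' single-site isotherm.  For a competition fit, plots measured anisotropy
#' against the competitor concentration (log scale) with the anisotropy
#' predicted from the exact competitive equilibrium at the fitted Kd.
#'
#' @param object An `fa_fit` from [fit_direct_kd()] or
#'   [fit_competition_kd()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' p <- probe_params(0.016, 0.245, R = 3.1, kd_nM = 6.8)
#' fit <- fit_direct_kd(simulate_direct_titration(p, kd_nM = 6.8, seed = 1))
#' ggplot2::autoplot(fit)
#' @export
autoplot.fa_fit <- function(object, ...) {
  if (object$mode == "direct") plot_direct_fit(object) else plot_competition_fit(object)
}

#' @rdname autoplot.fa_fit
#' @param x An `fa_fit` object.
#' @param y Unused.
#' @export
plot.fa_fit <- function(x, y, ...) print(autoplot.fa_fit(x, ...))

plot_direct_fit <- function(fit) {
  probe <- fit$probe
  d <- add_saturation(fit$data, probe)
  d$free_sites_nM <- pmax(d$sites_nM - d$nu_b * d$probe_nM, 0)
  kd <- fit$kd_mean_nM
  xmax <- max(d$free_sites_nM)
  curve <- tibble::tibble(free_sites_nM = c(0, lseq(max(xmax * 1e-3, 1e-3),
                                                    max(xmax, 1e-2), 200)))
  curve$nu_b <- curve$free_sites_nM / (kd + curve$free_sites_nM)
  ggplot2::ggplot(d, ggplot2::aes(.data$free_sites_nM, .data$nu_b_raw)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$nu_b),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$replicate)),
                        alpha = 0.8) +
    ggplot2::labs(x = "Free sites (nM)", y = "Fraction of probe bound",
                  shape = "Replicate",
                  title = sprintf("Direct titration fit: Kd = %.3g nM", kd)) +
    ggplot2::theme_minimal()
}

plot_competition_fit <- function(fit) {
  d <- fit$data
  d <- d[d$ligand_nM > 0, ]
  kd <- fit$kd_mean_nM
  lig <- lseq(min(d$ligand_nM), max(d$ligand_nM), 200)
  pred <- solve_competition(d$sites_nM[1], d$probe_nM[1], fit$probe_kd_nM,
                            lig, kd)
  curve <- tibble::tibble(
    ligand_nM = lig,
    anisotropy = anisotropy_from_saturation(pred$nu_b, fit$probe)$anisotropy)
  ggplot2::ggplot(d, ggplot2::aes(.data$ligand_nM, .data$anisotropy)) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$replicate)),
                        alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Competitor (nM)", y = "Anisotropy",
                  shape = "Replicate",
                  title = sprintf("Displacement fit: Kd = %.3g nM", kd)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
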