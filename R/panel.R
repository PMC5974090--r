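#' Reference maytansine-site ligand panel
#'
#' Study conditions bundled with the package: the calibrated endpoint
#' parameters of the fluorescein-maytansinoid probe (rf = 0.016,
#' rb = 0.245, R = 3.1, Kd = 6.8 nM against tubulin) and the reported
#' affinities of the unlabelled maytansine-site ligands measured against it
#' by displacement (ansamitocin P3, PM060184, the two diastereoisomers of
#' the DM1-lysine conjugate, spongistatin-1 and disorazole Z).  These are
#' the defaults used by the synthetic generator and by the end-to-end
#' recovery panel.
#'
#' @return A tibble with columns `compound`, `mode` (`"direct"` or
#'   `"competition"`) and `kd_nM` (reference dissociation constant).
#' @examples
#' reference_panel()
#' @export
reference_panel <- function() {
  tibble::tribble(
    ~compound,              ~mode,          ~kd_nM,
    "FcMaytansine (probe)", "direct",          6.8,
    "ansamitocin P3",       "competition",    15.0,
    "PM060184",             "competition",   111,
    "M9A (DM1-Lys)",        "competition",    12.6,
    "M9B (DM1-Lys)",        "competition",    17.5,
    "spongistatin-1",       "competition",     9.5,
    "disorazole Z",         "competition",   576
  )
}

#' Default probe parameters of the reference assay
#'
#' @param kd_nM Probe dissociation constant to attach (default 6.8 nM).
#' @return A [probe_params()] object with rf = 0.016, rb = 0.245, R = 3.1.
#' @examples
#' reference_probe()
#' @export
reference_probe <- function(kd_nM = 6.8) {
  probe_params(rf = 0.016, rb = 0.245, R = 3.1, kd_nM = kd_nM,
               rf_sd = 0.001, rb_sd = 0.005, R_sd = 0.05)
}

#' End-to-end noiseless recovery panel
#'
#' For every entry of [reference_panel()], generates a noiseless synthetic
#' titration at that entry's reference Kd (direct titration for the probe,
#' displacement series for the competitors), runs the corresponding fitting
#' pipeline, and tabulates recovered against generating values.  This
#' closes the loop generator -> observation model -> equilibrium solver ->
#' fit: with no noise, the fitted Kd must return the generating Kd.
#'
#' @param tol Relative tolerance for the `pass` column (default 0.01).
#' @return A tibble with columns `compound`, `mode`, `kd_true_nM`,
#'   `kd_fit_nM`, `rel_err`, `pass`.
#' @examples
#' run_recovery_panel()
#' @export
run_recovery_panel <- function(tol = 0.01) {
  panel <- reference_panel()
  probe_kd <- panel$kd_nM[panel$mode == "direct"][1]
  probe <- reference_probe(kd_nM = probe_kd)
  fits <- purrr::pmap_dbl(panel, function(compound, mode, kd_nM) {
    if (mode == "direct") {
      d <- simulate_direct_titration(probe, kd_nM = kd_nM,
                                     n_replicates = 1, sigma_r = 0,
                                     sigma_i_rel = 0)
      fit_direct_kd(d)$kd_mean_nM
    } else {
      d <- simulate_displacement(probe, ligand_kd_nM = kd_nM,
                                 n_replicates = 1, sigma_r = 0,
                                 sigma_i_rel = 0)
      fit_competition_kd(d)$kd_mean_nM
    }
  })
  out <- dplyr::mutate(
    dplyr::rename(panel, kd_true_nM = "kd_nM"),
    kd_fit_nM = fits,
    rel_err = abs(.data$kd_fit_nM - .data$kd_true_nM) / .data$kd_true_nM,
    pass = .data$rel_err < tol)
  out
}
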