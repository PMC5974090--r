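#' Photophysical parameters of a fluorescent probe
#'
#' Bundles the endpoint parameters of a labelled tracer needed to convert a
#' measured anisotropy into a fractional saturation: the anisotropy of the
#' free probe (`rf`), the anisotropy of the fully bound probe (`rb`), and the
#' bound-to-free fluorescence intensity ratio (`R = Ib/If`).  The intensity of
#' the free probe is fixed at 1 arbitrary unit, so `Ib = R`; only the ratio
#' enters the saturation formula.  Optionally carries the probe's own
#' dissociation constant once calibrated by [fit_direct_kd()].
#'
#' Anisotropies are stored dimensionless.  Instrument exports often report
#' milli-anisotropy (mA = r x 1000); [read_plate_csv()] converts such files on
#' input, and `probe_params()` accepts `unit = "mA"` to do the same here.
#'
#' @param rf Anisotropy of the free probe (dimensionless unless `unit = "mA"`).
#' @param rb Anisotropy of the bound probe; must exceed `rf`.
#' @param R Bound-to-free fluorescence intensity ratio (`Ib/If`, > 0).
#'   May be `NA` when intensities were not recorded; the quantum-yield
#'   corrected saturation is then unavailable (see [add_saturation()]).
#' @param kd_nM Optional probe dissociation constant in nM (> 0).
#' @param rf_sd,rb_sd,R_sd Optional standard deviations of the endpoint
#'   estimates, as propagated by [estimate_probe_params()].
#' @param unit Unit of `rf`/`rb` (and their SDs): `"anisotropy"`
#'   (dimensionless, default) or `"mA"` (milli-anisotropy, divided by 1000 on
#'   input).
#'
#' @return An object of class `probe_params`: a list with elements `rf`,
#'   `rb`, `R`, `kd_nM`, `rf_sd`, `rb_sd`, `R_sd`.
#' @examples
#' probe_params(rf = 0.016, rb = 0.245, R = 3.1)
#' probe_params(rf = 16, rb = 245, R = 3.1, unit = "mA")
#' @export
probe_params <- function(rf, rb, R = NA_real_, kd_nM = NULL,
                         rf_sd = NA_real_, rb_sd = NA_real_, R_sd = NA_real_,
                         unit = c("anisotropy", "mA")) {
  unit <- match.arg(unit)
  if (unit == "mA") {
    rf <- rf / 1000
    rb <- rb / 1000
    rf_sd <- rf_sd / 1000
    rb_sd <- rb_sd / 1000
  }
  stopifnot(is.numeric(rf), length(rf) == 1L, is.finite(rf),
            is.numeric(rb), length(rb) == 1L, is.finite(rb))
  if (rb <= rf) {
    stop("`rb` (", rb, ") must exceed `rf` (", rf,
         "): a bound probe must be less mobile than a free one.")
  }
  if (!is.na(R) && R <= 0) stop("`R` (bound/free intensity ratio) must be > 0.")
  if (!is.null(kd_nM)) {
    stopifnot(is.numeric(kd_nM), length(kd_nM) == 1L)
    if (!is.finite(kd_nM) || kd_nM <= 0) stop("`kd_nM` must be a positive number.")
  }
  structure(
    list(rf = rf, rb = rb, R = as.numeric(R), kd_nM = kd_nM,
         rf_sd = rf_sd, rb_sd = rb_sd, R_sd = R_sd),
    class = "probe_params"
  )
}

#' @export
print.probe_params <- function(x, ...) {
  fmt_pm <- function(v, s) {
    if (is.na(s)) format(v, digits = 4) else
      paste0(format(v, digits = 4), " ± ", format(s, digits = 3))
  }
  cat("<probe_params>\n")
  cat("  rf (free anisotropy):  ", fmt_pm(x$rf, x$rf_sd), "\n", sep = "")
  cat("  rb (bound anisotropy): ", fmt_pm(x$rb, x$rb_sd), "\n", sep = "")
  cat("  R  (Ib/If ratio):      ",
      if (is.na(x$R)) "not recorded" else fmt_pm(x$R, x$R_sd), "\n", sep = "")
  if (!is.null(x$kd_nM)) {
    cat("  Kd (probe):            ", format(x$kd_nM, digits = 4), " nM  (Ka = ",
        format(1 / x$kd_nM, digits = 4), " nM^-1)\n", sep = "")
  }
  invisible(x)
}

# internal: error early when an operation needs the intensity ratio
check_probe_R <- function(probe, what = "the quantum-yield corrected saturation") {
  if (is.na(probe$R)) {
    stop("Probe intensity ratio R is not available (no intensities recorded); ",
         what, " cannot be computed. Use method = \"simple\" or supply R.",
         call. = FALSE)
  }
  invisible(probe)
}

is_probe_params <- function(x) inherits(x, "probe_params")
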