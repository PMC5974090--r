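#' Predict anisotropy and intensity from fractional saturation
#'
#' Forward observation model of a two-state (free/bound) fluorescent probe.
#' The measured anisotropy is the intensity-weighted average of the free and
#' bound endpoint anisotropies,
#' \deqn{r = (I_f \nu_f r_f + I_b \nu_b r_b) / I_t, \qquad
#'       I_t = I_f \nu_f + I_b \nu_b,}
#' with the free-state intensity fixed at \eqn{I_f = 1} and \eqn{I_b = R}.
#' When the bound probe is brighter (`R > 1`) the bound species contributes
#' disproportionately to the signal; this is exactly the bias the
#' quantum-yield corrected inversion in [add_saturation()] removes.
#'
#' @param nu_b Fractional saturation of the probe, in \[0, 1\]. Vectorised.
#' @param probe A [probe_params()] object with `R` available.
#'
#' @return A tibble with one row per `nu_b`, columns `nu_b`, `anisotropy`,
#'   `intensity` (total intensity in units of the free-probe intensity).
#' @examples
#' p <- probe_params(0.016, 0.245, R = 3.1)
#' anisotropy_from_saturation(c(0, 0.5, 1), p)
#' @seealso [add_saturation()] for the inverse.
#' @export
anisotropy_from_saturation <- function(nu_b, probe) {
  stopifnot(is_probe_params(probe), is.numeric(nu_b))
  check_probe_R(probe, "the forward anisotropy model")
  if (any(!is.finite(nu_b)) || any(nu_b < 0 | nu_b > 1)) {
    stop("`nu_b` must lie in [0, 1]; got values outside that range.")
  }
  nu_f <- 1 - nu_b
  It <- nu_f + probe$R * nu_b
  r <- (nu_f * probe$rf + probe$R * nu_b * probe$rb) / It
  tibble::tibble(nu_b = nu_b, anisotropy = r, intensity = It)
}

# internal vectorised inversions (anisotropy -> saturation), unclamped
nu_from_r_qy <- function(r, rf, rb, R) (r - rf) / ((r - rf) + R * (rb - r))
nu_from_r_simple <- function(r, rf, rb) (r - rf) / (rb - rf)

#' Convert measured anisotropy to fractional saturation
#'
#' Adds fractional-saturation columns to a table of anisotropy measurements.
#' Two inversions are available:
#' \describe{
#'   \item{`"quantum_yield"` (default)}{
#'     \eqn{\nu_b = (r - r_f) / [(r - r_f) + R(r_b - r)]}, which corrects for
#'     the change in fluorescence intensity upon binding. Requires `probe$R`.}
#'   \item{`"simple"`}{\eqn{\nu_b = (r - r_f)/(r_b - r_f)}, valid only when
#'     bound and free probe are equally bright (`R = 1`). For `R != 1` this
#'     equals the *fluorescence* fraction bound, not the molar fraction.}
#' }
#' Measurement noise can push `r` slightly outside `[rf, rb]`. The algebraic
#' (unclamped) value is always kept in `nu_b_raw`; `nu_b` is clamped to
#' \[0, 1\] and such wells are flagged in `saturation_clamped`. Fitting
#' routines use the unclamped values (or work in anisotropy space) so that
#' clamping never biases estimates near the endpoints.
#'
#' @param data A data frame with an anisotropy column (and any other columns,
#'   which are preserved).
#' @param probe A [probe_params()] object.
#' @param method `"quantum_yield"` or `"simple"` (see Details).
#' @param anisotropy Name of the anisotropy column (tidy-eval; default
#'   `anisotropy`).
#'
#' @return The input data frame as a tibble with added columns `nu_b`
#'   (clamped to \[0,1\]), `nu_b_raw` (algebraic value),
#'   `fluor_fraction_bound` (fraction of total intensity emitted by the bound
#'   species), and `saturation_clamped` (logical flag).
#' @examples
#' p <- probe_params(0.016, 0.245, R = 3.1)
#' df <- tibble::tibble(anisotropy = c(0.016, 0.12095, 0.245))
#' add_saturation(df, p)
#' @export
add_saturation <- function(data, probe,
                           method = c("quantum_yield", "simple"),
                           anisotropy = anisotropy) {
  stopifnot(is.data.frame(data), is_probe_params(probe))
  method <- match.arg(method)
  r <- dplyr::pull(data, {{ anisotropy }})
  nu_raw <- switch(method,
    quantum_yield = {
      check_probe_R(probe)
      nu_from_r_qy(r, probe$rf, probe$rb, probe$R)
    },
    simple = nu_from_r_simple(r, probe$rf, probe$rb)
  )
  out <- tibble::as_tibble(data)
  out$nu_b_raw <- nu_raw
  out$nu_b <- pmin(pmax(nu_raw, 0), 1)
  out$fluor_fraction_bound <- nu_from_r_simple(r, probe$rf, probe$rb)
  out$saturation_clamped <- nu_raw < 0 | nu_raw > 1
  out
}
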