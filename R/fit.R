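#' Estimate probe endpoint parameters from control wells
#'
#' Calibrates the photophysical endpoints of the probe from two groups of
#' control wells: probe alone (free state) and probe with saturating sites
#' (bound state).  `rf` and `rb` are the group means of the measured
#' anisotropy, `R` is the ratio of the group mean intensities, and the group
#' standard deviations are carried along as endpoint uncertainties.
#'
#' If either group lacks intensities, `R` is left unset; downstream analyses
#' can then only use the uncorrected (`method = "simple"`) saturation, and
#' requesting the quantum-yield correction raises an error.
#'
#' @param free,bound Data frames of control wells with an `anisotropy`
#'   column and optionally an `intensity` column.
#' @return A [probe_params()] object.
#' @examples
#' free  <- tibble::tibble(anisotropy = c(0.016, 0.016), intensity = 1)
#' bound <- tibble::tibble(anisotropy = c(0.245, 0.245), intensity = 3.1)
#' estimate_probe_params(free, bound)
#' @export
estimate_probe_params <- function(free, bound) {
  stopifnot(is.data.frame(free), is.data.frame(bound),
            nrow(free) > 0, nrow(bound) > 0)
  rf <- mean(free$anisotropy)
  rb <- mean(bound$anisotropy)
  if (rb <= rf) {
    stop("Bound-control anisotropy does not exceed free-control anisotropy; ",
         "cannot define endpoints (rb <= rf).")
  }
  sdz <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
  R <- R_sd <- NA_real_
  has_int <- function(d) "intensity" %in% names(d) && !anyNA(d$intensity)
  if (has_int(free) && has_int(bound)) {
    mf <- mean(free$intensity)
    mb <- mean(bound$intensity)
    R <- mb / mf
    # first-order propagation of the two group SDs through the ratio
    rel <- sqrt(sum(c(sdz(bound$intensity) / mb, sdz(free$intensity) / mf)^2,
                    na.rm = TRUE))
    R_sd <- if (rel > 0) R * rel else NA_real_
  }
  probe_params(rf = rf, rb = rb, R = R,
               rf_sd = sdz(free$anisotropy), rb_sd = sdz(bound$anisotropy),
               R_sd = R_sd)
}

#' Fit the probe dissociation constant from a direct titration
#'
#' Per replicate: (1) each well's anisotropy is converted to fractional
#' saturation with the quantum-yield correction; (2) the free-site
#' concentration is obtained by depleting the total by the bound probe
#' (`free = sites_total - nu_b * probe_total`, 1:1 stoichiometry); (3) the
#' single-site isotherm \eqn{\nu_b = x/(K_d + x)} is fitted to
#' \eqn{(x, \nu_b)} by least squares over \eqn{\log_{10} K_d \in [-2, 7]}
#' (nM).  Replicate estimates are aggregated as mean +/- SEM.
#'
#' The unclamped saturation values are used as the response so that noise at
#' the endpoints is not rectified into bias; the depletion correction uses
#' the clamped value (a physical concentration) and free-site values are
#' floored at zero.
#'
#' @param data A titration table with columns `sites_nM`, `probe_nM`,
#'   `anisotropy` and optionally `replicate` (defaults to a single
#'   replicate), e.g. from [simulate_direct_titration()] or
#'   [read_plate_csv()].
#' @param probe A [probe_params()] object; defaults to the `probe` attribute
#'   attached by the simulators and the CSV reader.
#' @return An object of class `fa_fit` with elements `kd_mean_nM`,
#'   `kd_sem_nM`, `n_replicates`, `replicates` (per-replicate tibble),
#'   `rss`, `converged`, `mode = "direct"`, and diagnostics.  Methods:
#'   [tidy()], [glance()], `print()`, [ggplot2::autoplot()].
#' @examples
#' p <- probe_params(0.016, 0.245, R = 3.1)
#' d <- simulate_direct_titration(p, kd_nM = 6.8, sigma_r = 0)
#' fit_direct_kd(d)
#' @export
fit_direct_kd <- function(data, probe = NULL) {
  probe <- resolve_probe(data, probe)
  check_probe_R(probe, "the direct-titration fit")
  data <- check_series(data, c("sites_nM", "probe_nM", "anisotropy"))

  reps <- split(data, data$replicate)
  rows <- purrr::map(reps, function(d) {
    nu_raw <- nu_from_r_qy(d$anisotropy, probe$rf, probe$rb, probe$R)
    nu_cl <- pmin(pmax(nu_raw, 0), 1)
    x <- pmax(d$sites_nM - nu_cl * d$probe_nM, 0)
    if (length(unique(d$sites_nM)) < 4) {
      stop("Need >= 4 distinct site concentrations per replicate to fit.")
    }
    if (diff(range(nu_raw)) < 1e-3 || max(nu_raw) < 0.02) {
      return(tibble::tibble(replicate = d$replicate[1], kd_nM = NA_real_,
                            rss = NA_real_, n_points = nrow(d),
                            converged = FALSE, flag = "no_binding"))
    }
    rss_fun <- function(lk) {
      kd <- 10^lk
      sum((nu_raw - x / (kd + x))^2)
    }
    opt <- stats::optimize(rss_fun, interval = c(-2, 7), tol = 1e-9)
    at_edge <- min(abs(opt$minimum - c(-2, 7))) < 0.01
    tibble::tibble(replicate = d$replicate[1], kd_nM = 10^opt$minimum,
                   rss = opt$objective, n_points = nrow(d),
                   converged = !at_edge,
                   flag = if (at_edge) "boundary" else NA_character_)
  })
  new_fa_fit(dplyr::bind_rows(rows), mode = "direct", probe = probe,
             data = data)
}

#' Fit a competitor dissociation constant from a displacement series
#'
#' Per replicate, the competitor's Kd is estimated by minimising the sum of
#' squared residuals *in anisotropy space* between the measured anisotropy
#' and the model prediction: for each well the full competitive mass-action
#' equilibrium is solved exactly ([solve_competition()], with ligand
#' depletion) and the predicted probe saturation is mapped to an anisotropy
#' through the forward observation model.  The search is over
#' \eqn{\log_{10} K_d \in [-2, 7]} (nM).  Residuals are taken on the
#' measured anisotropy because the additive instrument noise lives on that
#' scale; inverting to saturation first would distort errors near the
#' endpoints.
#'
#' A series that shows no displacement (anisotropy drop below 0.005 at the
#' highest competitor concentration) cannot yield a point estimate; such
#' replicates are flagged `"no_displacement"` and a lower bound on the Kd —
#' the weakest affinity that would still have produced a detectable drop —
#' is reported instead.
#'
#' @param data A displacement table with columns `sites_nM`, `probe_nM`,
#'   `ligand_nM`, `anisotropy` and optionally `replicate`.
#' @param probe A [probe_params()] object (defaulting to the series
#'   attribute); its `R` is required.
#' @param probe_kd_nM The calibrated probe dissociation constant (nM),
#'   normally from [fit_direct_kd()]; defaults to `probe$kd_nM`.
#' @return An `fa_fit` object (see [fit_direct_kd()]) with
#'   `mode = "competition"`; non-displacing replicates carry `kd_lower_nM`.
#' @examples
#' p <- probe_params(0.016, 0.245, R = 3.1, kd_nM = 6.8)
#' d <- simulate_displacement(p, ligand_kd_nM = 15, sigma_r = 0)
#' fit_competition_kd(d)
#' @export
fit_competition_kd <- function(data, probe = NULL, probe_kd_nM = NULL) {
  probe <- resolve_probe(data, probe)
  check_probe_R(probe, "the competition fit")
  if (is.null(probe_kd_nM)) probe_kd_nM <- probe$kd_nM
  if (is.null(probe_kd_nM)) {
    stop("`probe_kd_nM` is required (calibrate the probe with fit_direct_kd()).")
  }
  data <- check_series(data, c("sites_nM", "probe_nM", "ligand_nM", "anisotropy"))

  reps <- split(data, data$replicate)
  rows <- purrr::map(reps, function(d) {
    if (length(unique(d$ligand_nM)) < 4) {
      stop("Need >= 4 distinct competitor concentrations per replicate to fit.")
    }
    pred_r <- function(kd_l) {
      st <- solve_competition(d$sites_nM, d$probe_nM, probe_kd_nM,
                              d$ligand_nM, kd_l)
      anisotropy_from_saturation(st$nu_b, probe)$anisotropy
    }
    lo_L <- d$anisotropy[which.min(d$ligand_nM)]
    hi_L <- d$anisotropy[which.max(d$ligand_nM)]
    if ((lo_L - hi_L) < 0.005) {
      return(tibble::tibble(
        replicate = d$replicate[1], kd_nM = NA_real_,
        kd_lower_nM = kd_detection_bound(d, probe, probe_kd_nM),
        rss = NA_real_, n_points = nrow(d), converged = FALSE,
        flag = "no_displacement"))
    }
    rss_fun <- function(lk) sum((d$anisotropy - pred_r(10^lk))^2)
    opt <- stats::optimize(rss_fun, interval = c(-2, 7), tol = 1e-9)
    at_edge <- min(abs(opt$minimum - c(-2, 7))) < 0.01
    tibble::tibble(replicate = d$replicate[1], kd_nM = 10^opt$minimum,
                   kd_lower_nM = NA_real_,
                   rss = opt$objective, n_points = nrow(d),
                   converged = !at_edge,
                   flag = if (at_edge) "boundary" else NA_character_)
  })
  new_fa_fit(dplyr::bind_rows(rows), mode = "competition", probe = probe,
             data = data, probe_kd_nM = probe_kd_nM)
}

# Weakest competitor Kd whose predicted anisotropy drop at the highest
# tested concentration still reaches the 0.005 detection threshold.
kd_detection_bound <- function(d, probe, probe_kd_nM, drop = 0.005) {
  Lmax <- max(d$ligand_nM)
  i <- which.max(d$ligand_nM)
  r0 <- anisotropy_from_saturation(
    solve_binary(d$sites_nM[i], d$probe_nM[i], probe_kd_nM)$nu_b,
    probe)$anisotropy
  f <- function(lk) {
    st <- solve_competition(d$sites_nM[i], d$probe_nM[i], probe_kd_nM,
                            Lmax, 10^lk)
    r0 - anisotropy_from_saturation(st$nu_b, probe)$anisotropy - drop
  }
  if (f(12) > 0) return(Inf)   # even a 1e12 nM binder would displace
  if (f(-2) < 0) return(NA_real_)
  10^stats::uniroot(f, c(-2, 12), tol = 1e-6)$root
}

#' Aggregate per-replicate estimates as mean and SEM
#'
#' @param kd_nM Numeric vector of per-replicate estimates (nM).
#' @return A one-row tibble with `kd_mean_nM`, `kd_sem_nM` (sample SD /
#'   sqrt(n); `NA` when n < 2) and `n_replicates`.
#' @examples
#' aggregate_replicates(c(12, 15, 18))
#' @export
aggregate_replicates <- function(kd_nM) {
  kd_nM <- kd_nM[!is.na(kd_nM)]
  if (length(kd_nM) == 0) stop("No replicate estimates to aggregate.")
  n <- length(kd_nM)
  tibble::tibble(
    kd_mean_nM = mean(kd_nM),
    kd_sem_nM = if (n >= 2) stats::sd(kd_nM) / sqrt(n) else NA_real_,
    n_replicates = n
  )
}

#' Z-factor assay quality score
#'
#' Screening-window statistic
#' \deqn{Z = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|}
#' comparing positive (probe fully bound) and negative (probe free) control
#' wells; values near 1 indicate an excellent assay window.  Sample SDs are
#' used.  Z is invariant under positive affine rescaling of the signal, so
#' it does not matter whether anisotropies are dimensionless or in mA.
#'
#' @param positive,negative Anisotropy values of the two control groups:
#'   numeric vectors, or data frames with an `anisotropy` column.  At least
#'   3 wells per group.
#' @return An object of class `fa_zfactor`: list with `z`, group means, SDs
#'   and sizes.  `glance()` returns it as a one-row tibble.
#' @examples
#' zfactor(positive = c(0.244, 0.245, 0.246), negative = c(0.015, 0.016, 0.017))
#' @export
zfactor <- function(positive, negative) {
  grab <- function(x) if (is.data.frame(x)) x$anisotropy else as.numeric(x)
  p <- grab(positive)
  n <- grab(negative)
  if (length(p) < 3 || length(n) < 3) {
    stop("Z-factor requires at least 3 wells in each control group.")
  }
  mp <- mean(p); mn <- mean(n)
  if (mp == mn) stop("Control groups have equal means; Z-factor is undefined.")
  sp <- stats::sd(p); sn <- stats::sd(n)
  structure(
    list(z = 1 - 3 * (sp + sn) / abs(mp - mn),
         mean_positive = mp, sd_positive = sp, n_positive = length(p),
         mean_negative = mn, sd_negative = sn, n_negative = length(n)),
    class = "fa_zfactor"
  )
}

#' @export
print.fa_zfactor <- function(x, ...) {
  cat("<fa_zfactor>  Z =", format(x$z, digits = 3), "\n")
  cat(sprintf("  positive: mean %.4g, sd %.3g (n = %d)\n",
              x$mean_positive, x$sd_positive, x$n_positive))
  cat(sprintf("  negative: mean %.4g, sd %.3g (n = %d)\n",
              x$mean_negative, x$sd_negative, x$n_negative))
  invisible(x)
}

#' @export
glance.fa_zfactor <- function(x, ...) {
  tibble::tibble(z = x$z,
                 mean_positive = x$mean_positive, sd_positive = x$sd_positive,
                 mean_negative = x$mean_negative, sd_negative = x$sd_negative,
                 n_positive = x$n_positive, n_negative = x$n_negative)
}

# ---- fa_fit object -----------------------------------------------------

new_fa_fit <- function(replicates, mode, probe, data, probe_kd_nM = NULL) {
  ok <- !is.na(replicates$kd_nM)
  agg <- if (any(ok)) aggregate_replicates(replicates$kd_nM) else
    tibble::tibble(kd_mean_nM = NA_real_, kd_sem_nM = NA_real_,
                   n_replicates = 0L)
  structure(
    list(mode = mode,
         kd_mean_nM = agg$kd_mean_nM,
         kd_sem_nM = agg$kd_sem_nM,
         n_replicates = nrow(replicates),
         replicates = replicates,
         rss = if (all(is.na(replicates$rss))) NA_real_ else
           sum(replicates$rss, na.rm = TRUE),
         converged = all(replicates$converged),
         probe = probe, probe_kd_nM = probe_kd_nM,
         data = data),
    class = "fa_fit"
  )
}

#' @export
print.fa_fit <- function(x, ...) {
  cat("<fa_fit>  mode:", x$mode, "\n")
  if (is.na(x$kd_mean_nM)) {
    cat("  Kd: not estimable")
    lb <- suppressWarnings(min(x$replicates$kd_lower_nM, na.rm = TRUE))
    if (is.finite(lb)) cat(" (lower bound ~", format(lb, digits = 3), "nM)")
    cat("\n")
  } else {
    cat("  Kd:", format(x$kd_mean_nM, digits = 4), "nM",
        if (!is.na(x$kd_sem_nM))
          paste0("± ", format(x$kd_sem_nM, digits = 3), " (SEM)") else "",
        " [n =", x$n_replicates, "replicates]\n")
  }
  if (!x$converged) {
    cat("  flags:", paste(unique(stats::na.omit(x$replicates$flag)),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy per-replicate fit results
#'
#' @param x An `fa_fit` object.
#' @param ... Unused.
#' @return `tidy()`: one row per replicate with its Kd estimate, residual
#'   sum of squares and convergence flag. `glance()`: a one-row summary
#'   (Kd mean, SEM, replicate count, total RSS, convergence).
#' @export
tidy.fa_fit <- function(x, ...) x$replicates

#' @rdname tidy.fa_fit
#' @export
glance.fa_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, kd_mean_nM = x$kd_mean_nM,
                 kd_sem_nM = x$kd_sem_nM, ka_per_M = 1e9 / x$kd_mean_nM,
                 n_replicates = x$n_replicates, rss = x$rss,
                 converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# ---- shared helpers ----------------------------------------------------

resolve_probe <- function(data, probe) {
  if (is.null(probe)) probe <- attr(data, "probe")
  if (!is_probe_params(probe)) {
    stop("No probe parameters: pass `probe = probe_params(...)` or use a ",
         "series that carries them (simulators, read_plate_csv()).")
  }
  probe
}

check_series <- function(data, cols) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("Series is missing column(s): ", paste(missing, collapse = ", "))
  }
  data <- tibble::as_tibble(data)
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  data
}
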