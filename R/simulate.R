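#' Simulate a direct probe-vs-sites titration plate
#'
#' Generates plate-style data for a direct titration: a fixed probe
#' concentration titrated with increasing site (protein) concentrations.
#' Each well is produced by the exact forward model — 1:1 mass-action
#' equilibrium ([solve_binary()]), then the intensity-weighted anisotropy
#' observation model ([anisotropy_from_saturation()]) — with additive
#' Gaussian noise on the anisotropy (`sigma_r`) and multiplicative Gaussian
#' noise on the intensity (`sigma_i_rel`), applied independently per well.
#'
#' Defaults mirror a typical high-affinity assay design: 10 nM probe,
#' sites from 0 to 400 nM (zero plus 12 log-spaced points), three replicate
#' series, anisotropy SD 0.001 and 1.6% relative intensity SD.
#'
#' @param probe A [probe_params()] object (its `R` is required).
#' @param kd_nM Ground-truth probe dissociation constant (nM, > 0).
#' @param sites_nM Site total concentrations (nM); default
#'   `c(0, lseq(0.5, 400, 12))`.
#' @param probe_nM Probe total concentration (nM).
#' @param n_replicates Number of replicate series.
#' @param sigma_r Additive anisotropy noise SD (dimensionless).
#' @param sigma_i_rel Relative intensity noise SD.
#' @param seed Optional integer seed; the same seed reproduces the series
#'   exactly and the global RNG state is left untouched.
#'
#' @return A tibble (class `fa_series`) with columns `well`, `replicate`,
#'   `sites_nM`, `probe_nM`, `ligand_nM` (all `NA` for direct mode),
#'   `anisotropy`, `intensity`, carrying attributes `mode`, `probe` and
#'   `truth` (the generating parameters).
#' @examples
#' p <- probe_params(0.016, 0.245, R = 3.1)
#' simulate_direct_titration(p, kd_nM = 6.8, seed = 1)
#' @export
simulate_direct_titration <- function(probe, kd_nM,
                                      sites_nM = c(0, lseq(0.5, 400, 12)),
                                      probe_nM = 10, n_replicates = 3,
                                      sigma_r = 0.001, sigma_i_rel = 0.016,
                                      seed = NULL) {
  stopifnot(is_probe_params(probe), kd_nM > 0, probe_nM > 0,
            sigma_r >= 0, sigma_i_rel >= 0, n_replicates >= 1)
  check_probe_R(probe, "simulation")
  clean <- solve_binary(sites_nM, probe_nM, kd_nM)
  obs <- anisotropy_from_saturation(clean$nu_b, probe)
  df <- noisy_wells(obs, n_replicates, sigma_r, sigma_i_rel, seed)
  df <- dplyr::mutate(df, sites_nM = rep(sites_nM, n_replicates),
                      probe_nM = probe_nM, ligand_nM = NA_real_,
                      .after = "replicate")
  new_fa_series(df, mode = "direct", probe = probe,
                truth = list(kd_nM = kd_nM, sigma_r = sigma_r,
                             sigma_i_rel = sigma_i_rel, seed = seed))
}

#' Simulate a competition (displacement) titration plate
#'
#' Generates plate-style data for a displacement experiment: fixed probe and
#' site concentrations pre-equilibrated, then titrated with an unlabelled
#' competitor.  Each well is produced by the exact competitive equilibrium
#' ([solve_competition()], full ligand depletion) followed by the anisotropy
#' observation model and the same noise model as
#' [simulate_direct_titration()].  The noiseless anisotropy is strictly
#' decreasing along an ascending competitor series.
#'
#' Defaults mirror the displacement design of a calibrated high-affinity
#' probe: 10 nM probe, 4 nM sites, and 12 log-spaced competitor
#' concentrations spanning 0.1x to 1000x the competitor's own Kd.
#'
#' @inheritParams simulate_direct_titration
#' @param probe_kd_nM Probe dissociation constant used by the generator;
#'   defaults to `probe$kd_nM`.
#' @param ligand_kd_nM Ground-truth competitor dissociation constant (nM).
#' @param ligand_nM Competitor total concentrations (nM); default 12
#'   log-spaced points from `0.1 * ligand_kd_nM` to `1000 * ligand_kd_nM`.
#' @param sites_nM Site total concentration (nM), a scalar in this design.
#' @return An `fa_series` tibble as in [simulate_direct_titration()], with
#'   `mode = "competition"` and the competitor truth in the `truth`
#'   attribute.
#' @examples
#' p <- probe_params(0.016, 0.245, R = 3.1, kd_nM = 6.8)
#' simulate_displacement(p, ligand_kd_nM = 15, seed = 1)
#' @export
simulate_displacement <- function(probe, ligand_kd_nM, probe_kd_nM = probe$kd_nM,
                                  ligand_nM = lseq(0.1 * ligand_kd_nM,
                                                   1000 * ligand_kd_nM, 12),
                                  sites_nM = 4, probe_nM = 10,
                                  n_replicates = 3,
                                  sigma_r = 0.001, sigma_i_rel = 0.016,
                                  seed = NULL) {
  stopifnot(is_probe_params(probe), ligand_kd_nM > 0,
            length(sites_nM) == 1L, sigma_r >= 0, sigma_i_rel >= 0)
  check_probe_R(probe, "simulation")
  if (is.null(probe_kd_nM)) {
    stop("`probe_kd_nM` is required (set it or store it in the probe).")
  }
  clean <- solve_competition(sites_nM, probe_nM, probe_kd_nM,
                             ligand_nM, ligand_kd_nM)
  obs <- anisotropy_from_saturation(clean$nu_b, probe)
  df <- noisy_wells(obs, n_replicates, sigma_r, sigma_i_rel, seed)
  df <- dplyr::mutate(df, sites_nM = sites_nM, probe_nM = probe_nM,
                      ligand_nM = rep(ligand_nM, n_replicates),
                      .after = "replicate")
  new_fa_series(df, mode = "competition", probe = probe,
                truth = list(ligand_kd_nM = ligand_kd_nM,
                             probe_kd_nM = probe_kd_nM, sigma_r = sigma_r,
                             sigma_i_rel = sigma_i_rel, seed = seed))
}

#' Log-spaced sequence
#'
#' @param from,to Positive endpoints.
#' @param length.out Number of points.
#' @return Numeric vector log-uniformly spaced between `from` and `to`.
#' @examples
#' lseq(1, 1000, 4)
#' @export
lseq <- function(from, to, length.out) {
  stopifnot(from > 0, to > 0)
  10^seq(log10(from), log10(to), length.out = length.out)
}

noisy_wells <- function(obs, n_replicates, sigma_r, sigma_i_rel, seed) {
  gen <- function() {
    purrr::map_dfr(seq_len(n_replicates), function(rep_i) {
      n <- nrow(obs)
      tibble::tibble(
        well = sprintf("%s%02d", LETTERS[(rep_i - 1) %% 26 + 1], seq_len(n)),
        replicate = rep_i,
        anisotropy = obs$anisotropy + stats::rnorm(n, 0, sigma_r),
        intensity = obs$intensity * (1 + stats::rnorm(n, 0, sigma_i_rel))
      )
    })
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

new_fa_series <- function(df, mode, probe, truth) {
  df <- tibble::as_tibble(df[, c("well", "replicate", "sites_nM", "probe_nM",
                                 "ligand_nM", "anisotropy", "intensity")])
  structure(df, mode = mode, probe = probe, truth = truth,
            class = c("fa_series", class(df)))
}

#' @export
print.fa_series <- function(x, ...) {
  cat("<fa_series>  mode:", attr(x, "mode"), "\n")
  tr <- attr(x, "truth")
  if (!is.null(tr)) {
    kd <- tr$kd_nM %||% tr$ligand_kd_nM
    cat("  synthetic truth: Kd =", format(kd, digits = 4), "nM",
        "(sigma_r =", tr$sigma_r, ")\n")
  }
  NextMethod()
}

# ---- plate CSV dialect -------------------------------------------------
#
# Self-describing flat file: '#'-prefixed "key=value" metadata lines
# (probe endpoints, mode, units, synthetic truth), then a CSV table with
# columns well, replicate, sites_nM, probe_nM, ligand_nM, anisotropy,
# intensity.  No standard plate format records per-well chemistry, so the
# dialect keeps the whole pipeline inspectable with a text editor.

#' Write / read a titration series as an annotated plate CSV
#'
#' The file stores `#`-prefixed `key=value` header lines (probe endpoint
#' parameters, mode, anisotropy unit, synthetic ground truth when present)
#' followed by a plain CSV table with columns `well`, `replicate`,
#' `sites_nM`, `probe_nM`, `ligand_nM`, `anisotropy`, `intensity`.  The
#' round trip `read_plate_csv(write_plate_csv(x))` is lossless, including
#' the probe and truth metadata.
#'
#' Files whose header declares `anisotropy_unit=mA` are converted to
#' dimensionless anisotropy on input (divided by 1000) and flagged via the
#' returned series' `unit_converted` attribute.  A missing `intensity`
#' column loads as all-`NA`; quantum-yield corrected analyses will then
#' refuse to run unless the probe's `R` is supplied independently.
#' Malformed headers and duplicate `(well, replicate)` pairs raise parse
#' errors naming the offending line.
#'
#' @param series An `fa_series` (or compatible data frame with the columns
#'   above plus a `probe` attribute).
#' @param path File path.
#' @param unit Unit in which anisotropies are written: `"anisotropy"`
#'   (dimensionless, default) or `"mA"`.
#' @return `write_plate_csv()` returns `path` invisibly; `read_plate_csv()`
#'   returns an `fa_series` tibble.
#' @examples
#' p <- probe_params(0.016, 0.245, R = 3.1)
#' d <- simulate_direct_titration(p, kd_nM = 6.8, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_plate_csv(d, f)
#' read_plate_csv(f)
#' @export
write_plate_csv <- function(series, path, unit = c("anisotropy", "mA")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(series))
  probe <- attr(series, "probe")
  truth <- attr(series, "truth")
  meta <- c(format_version = "fabind_plate_csv/1",
            mode = attr(series, "mode") %||% "unknown",
            anisotropy_unit = unit)
  if (is_probe_params(probe)) {
    meta <- c(meta, probe_rf = probe$rf, probe_rb = probe$rb,
              probe_R = probe$R,
              if (!is.null(probe$kd_nM)) c(probe_kd_nM = probe$kd_nM))
  }
  if (!is.null(truth)) {
    tn <- names(truth)[!vapply(truth, is.null, logical(1))]
    meta <- c(meta, stats::setNames(
      vapply(truth[tn], as.character, character(1)), paste0("truth_", tn)))
  }
  scale <- if (unit == "mA") 1000 else 1
  out <- dplyr::mutate(tibble::as_tibble(series),
                       anisotropy = .data$anisotropy * scale)
  header <- paste0("# ", names(meta), "=", unname(meta))
  readr::write_lines(header, path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  lines <- readr::read_lines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(diff(hdr_idx) != 1)) {
    stop("Malformed plate CSV: metadata '#' lines must be contiguous at the ",
         "top (stray header at line ", hdr_idx[which(diff(hdr_idx) != 1)[1] + 1],
         ").")
  }
  meta <- list()
  for (i in hdr_idx) {
    kv <- sub("^#\\s*", "", lines[i])
    if (!grepl("=", kv, fixed = TRUE)) {
      stop("Malformed plate CSV header at line ", i, ": expected key=value, got '",
           kv, "'.")
    }
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  df <- readr::read_csv(I(lines[setdiff(seq_along(lines), hdr_idx)]),
                        col_types = readr::cols(
                          well = "c", replicate = "i",
                          .default = readr::col_double()),
                        na = "NA", progress = FALSE)
  req <- c("well", "replicate", "sites_nM", "probe_nM", "anisotropy")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("Plate CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"ligand_nM" %in% names(df)) df$ligand_nM <- NA_real_
  if (!"intensity" %in% names(df)) df$intensity <- NA_real_
  dup <- duplicated(df[c("well", "replicate")])
  if (any(dup)) {
    stop("Duplicate (well, replicate) entries in plate CSV at data row(s) ",
         paste(which(dup), collapse = ", "), " (line ",
         which(dup)[1] + length(hdr_idx) + 1, " of file).")
  }
  unit <- meta$anisotropy_unit %||% "anisotropy"
  if (!unit %in% c("anisotropy", "mA")) {
    stop("Unknown anisotropy_unit '", unit, "' in plate CSV header.")
  }
  converted <- unit == "mA"
  if (converted) df$anisotropy <- df$anisotropy / 1000

  probe <- NULL
  if (!is.null(meta$probe_rf) && !is.null(meta$probe_rb)) {
    probe <- probe_params(
      rf = as.numeric(meta$probe_rf), rb = as.numeric(meta$probe_rb),
      R = if (is.null(meta$probe_R)) NA_real_ else as.numeric(meta$probe_R),
      kd_nM = if (is.null(meta$probe_kd_nM)) NULL else
        as.numeric(meta$probe_kd_nM))
  }
  truth_keys <- grep("^truth_", names(meta), value = TRUE)
  truth <- if (length(truth_keys)) {
    vals <- lapply(meta[truth_keys], function(v) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num) && !identical(v, "NA")) v else num
    })
    stats::setNames(vals, sub("^truth_", "", truth_keys))
  }
  out <- new_fa_series(df, mode = meta$mode %||% "unknown", probe = probe,
                       truth = truth)
  attr(out, "unit_converted") <- converted
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
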