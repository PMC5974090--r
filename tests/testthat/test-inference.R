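test_that("endpoint calibration recovers probe parameters from control wells", {
  free <- tibble::tibble(anisotropy = c(0.016, 0.016), intensity = c(1, 1))
  bound <- tibble::tibble(anisotropy = c(0.245, 0.245), intensity = c(3.1, 3.1))
  p <- estimate_probe_params(free, bound)
  expect_equal(c(p$rf, p$rb, p$R), c(0.016, 0.245, 3.1))

  # group scatter propagates into endpoint SDs
  free2 <- tibble::tibble(anisotropy = c(0.015, 0.017), intensity = c(0.98, 1.02))
  p2 <- estimate_probe_params(free2, bound)
  expect_equal(p2$rf_sd, stats::sd(free2$anisotropy))

  # indistinguishable groups cannot define endpoints
  expect_error(estimate_probe_params(bound, bound), "rb <= rf")

  # no intensities: R stays unset, quantum-yield analysis refuses downstream
  p3 <- estimate_probe_params(tibble::tibble(anisotropy = c(0.016, 0.017)),
                              tibble::tibble(anisotropy = c(0.24, 0.25)))
  expect_true(is.na(p3$R))
  expect_error(add_saturation(tibble::tibble(anisotropy = 0.1), p3),
               "R is not available")
  # equal intensities in both states -> R = 1
  p4 <- estimate_probe_params(
    tibble::tibble(anisotropy = c(0.016, 0.016), intensity = c(1, 1)),
    tibble::tibble(anisotropy = c(0.245, 0.245), intensity = c(1, 1)))
  expect_equal(p4$R, 1)
})

test_that("replicate aggregation follows the mean +/- SEM convention", {
  expect_equal(aggregate_replicates(c(10, 10, 10)),
               tibble::tibble(kd_mean_nM = 10, kd_sem_nM = 0, n_replicates = 3L))
  agg <- aggregate_replicates(c(12, 15, 18))
  expect_equal(agg$kd_mean_nM, 15)
  expect_equal(agg$kd_sem_nM, 3 / sqrt(3), tolerance = 1e-12)  # sample SD = 3
  single <- aggregate_replicates(7)
  expect_equal(single$kd_mean_nM, 7)
  expect_true(is.na(single$kd_sem_nM))
  expect_error(aggregate_replicates(numeric()), "No replicate")
})

test_that("direct fit recovers the generating Kd from noiseless data", {
  p <- ref_probe()
  for (kd in c(2, 6.8, 55)) {
    d <- simulate_direct_titration(p, kd_nM = kd, n_replicates = 2,
                                   sigma_r = 0, sigma_i_rel = 0)
    fit <- fit_direct_kd(d)
    expect_s3_class(fit, "fa_fit")
    expect_true(fit$converged)
    expect_equal(fit$kd_mean_nM, kd, tolerance = 1e-5)
    expect_equal(nrow(tidy(fit)), 2)
    expect_equal(glance(fit)$kd_mean_nM, fit$kd_mean_nM)
  }
})

test_that("a flat direct series is flagged, not given a Kd", {
  p <- ref_probe()
  d <- tibble::tibble(sites_nM = c(0, 10, 50, 400), probe_nM = 10,
                      anisotropy = rep(0.016, 4), replicate = 1L)
  fit <- fit_direct_kd(d, probe = p)
  expect_false(fit$converged)
  expect_true(is.na(fit$kd_mean_nM))
  expect_identical(tidy(fit)$flag, "no_binding")
})

test_that("direct fit demands enough distinct concentrations", {
  p <- ref_probe()
  d <- tibble::tibble(sites_nM = c(0, 10, 10), probe_nM = 10,
                      anisotropy = c(0.016, 0.1, 0.1), replicate = 1L)
  expect_error(fit_direct_kd(d, probe = p), ">= 4 distinct")
})

test_that("competition fit recovers the generating Kd, including the probe's own", {
  p <- ref_probe(kd_nM = 6.8)
  for (kd in c(9.5, 120)) {
    d <- simulate_displacement(p, ligand_kd_nM = kd, n_replicates = 2,
                               sigma_r = 0, sigma_i_rel = 0)
    fit <- fit_competition_kd(d)
    expect_true(fit$converged)
    expect_equal(fit$kd_mean_nM, kd, tolerance = 1e-5)
  }
  # self-consistency: a competitor identical to the probe's unlabelled
  # parent must return the probe's own Kd
  d_self <- simulate_displacement(p, ligand_kd_nM = 6.8, n_replicates = 1,
                                  sigma_r = 0, sigma_i_rel = 0)
  expect_equal(fit_competition_kd(d_self)$kd_mean_nM, 6.8, tolerance = 1e-5)
})

test_that("a non-displacing competitor yields a lower bound, not a point estimate", {
  p <- ref_probe(kd_nM = 6.8)
  lig <- lseq(1, 1e4, 12)
  r0 <- anisotropy_from_saturation(solve_binary(4, 10, 6.8)$nu_b, p)$anisotropy
  d <- tibble::tibble(sites_nM = 4, probe_nM = 10, ligand_nM = lig,
                      anisotropy = r0, replicate = 1L)
  fit <- fit_competition_kd(d, probe = p)
  expect_false(fit$converged)
  expect_true(is.na(fit$kd_mean_nM))
  expect_identical(tidy(fit)$flag, "no_displacement")
  lb <- tidy(fit)$kd_lower_nM
  expect_gt(lb, max(lig))  # any binder at least this tight would have shown
})

test_that("noisy replicate fits land near the truth with honest SEMs", {
  p <- ref_probe(kd_nM = 6.8)
  d <- simulate_displacement(p, ligand_kd_nM = 15, n_replicates = 5,
                             sigma_r = 0.002, seed = 101)
  fit <- fit_competition_kd(d)
  expect_true(fit$converged)
  expect_equal(fit$n_replicates, 5)
  expect_lt(abs(fit$kd_mean_nM - 15) / 15, 0.25)
  expect_gt(fit$kd_sem_nM, 0)
})

test_that("Z-factor matches its defining algebra and edge cases", {
  # noiseless controls: Z = 1 exactly
  z0 <- zfactor(rep(0.245, 3), rep(0.016, 3))
  expect_equal(z0$z, 1)

  # constructed SDs: sd(c(m-s, m, m+s)) = s, so sigma_p = sigma_n = 0.001145
  # gives Z = 1 - 3*(2*0.001145)/0.229 = 0.97
  s <- 0.001145
  z <- zfactor(0.245 + c(-s, 0, s), 0.016 + c(-s, 0, s))
  expect_equal(z$z, 0.97, tolerance = 1e-12)

  # noise swamping the window makes Z negative
  zbad <- zfactor(c(0.1, 0.245, 0.39), c(-0.2, 0.016, 0.23))
  expect_lt(zbad$z, 0)

  expect_error(zfactor(c(0.2, 0.3), c(0.01, 0.02, 0.03)), "at least 3")
  expect_error(zfactor(rep(0.1, 3), rep(0.1, 3)), "undefined")
})

test_that("Z-factor is invariant under positive affine rescaling", {
  set.seed(7)
  pos <- stats::rnorm(8, 0.245, 0.002)
  neg <- stats::rnorm(8, 0.016, 0.001)
  z1 <- zfactor(pos, neg)$z
  z2 <- zfactor(1000 * pos + 5, 1000 * neg + 5)$z  # e.g. mA with an offset
  expect_equal(z1, z2, tolerance = 1e-12)
  expect_lte(z1, 1)
  expect_equal(glance(zfactor(pos, neg))$z, z1)
})

test_that("fits refuse to run without the intensity-ratio calibration", {
  p_noR <- probe_params(0.016, 0.245)
  d <- tibble::tibble(sites_nM = c(0, 5, 20, 400), probe_nM = 10,
                      anisotropy = c(0.016, 0.08, 0.15, 0.24))
  expect_error(fit_direct_kd(d, probe = p_noR), "R is not available")
})
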