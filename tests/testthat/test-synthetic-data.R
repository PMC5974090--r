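test_that("noiseless direct simulation hits the physical endpoints", {
  p <- ref_probe()
  d <- simulate_direct_titration(p, kd_nM = 6.8, sites_nM = c(0, 50, 400),
                                 n_replicates = 1, sigma_r = 0, sigma_i_rel = 0)
  expect_equal(d$anisotropy[d$sites_nM == 0], 0.016)  # free probe exactly
  # near-saturation at 400 nM sites: nu_b ~ 0.983, r within 0.004 of rb
  expect_lt(0.245 - d$anisotropy[d$sites_nM == 400], 0.004)
  expect_equal(d$intensity[d$sites_nM == 0], 1)
})

test_that("simulation is reproducible under a fixed seed and leaves the RNG alone", {
  p <- ref_probe(kd_nM = 6.8)
  a <- simulate_direct_titration(p, kd_nM = 6.8, seed = 11)
  b <- simulate_direct_titration(p, kd_nM = 6.8, seed = 11)
  expect_identical(a, b)
  c_ <- simulate_direct_titration(p, kd_nM = 6.8, seed = 12)
  expect_false(identical(a$anisotropy, c_$anisotropy))

  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(simulate_displacement(p, 15, seed = 3))
  expect_identical(stats::runif(1), before)
})

test_that("noiseless displacement curves are monotone and reach the free endpoint", {
  p <- ref_probe(kd_nM = 6.8)
  d <- simulate_displacement(p, ligand_kd_nM = 9.5,
                             ligand_nM = c(lseq(1, 1e4, 11), 1e5),
                             n_replicates = 1, sigma_r = 0, sigma_i_rel = 0)
  expect_true(all(diff(d$anisotropy) < 0))
  expect_lt(d$anisotropy[nrow(d)] - 0.016, 0.005)  # full displacement

  # zero-competitor well equals the direct-titration well at the same sites
  d0 <- simulate_displacement(p, ligand_kd_nM = 15, ligand_nM = c(0, 10, 100, 1000),
                              n_replicates = 1, sigma_r = 0, sigma_i_rel = 0)
  direct <- simulate_direct_titration(p, kd_nM = 6.8, sites_nM = 4,
                                      n_replicates = 1, sigma_r = 0,
                                      sigma_i_rel = 0)
  expect_equal(d0$anisotropy[d0$ligand_nM == 0], direct$anisotropy,
               tolerance = 1e-12)
})

test_that("simulated noise is symmetric about the truth", {
  p <- ref_probe()
  d <- simulate_direct_titration(p, kd_nM = 6.8, sites_nM = rep(0, 100),
                                 n_replicates = 100, sigma_r = 0.001,
                                 seed = 2024)
  resid <- d$anisotropy - 0.016
  expect_equal(length(resid), 10000)
  expect_lt(abs(skewness(resid)), 0.1)
  expect_equal(stats::sd(resid), 0.001, tolerance = 0.05)
})

test_that("plate CSV round-trips data, probe and truth metadata losslessly", {
  p <- ref_probe(kd_nM = 6.8)
  d <- simulate_displacement(p, ligand_kd_nM = 15, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(d, f)
  d2 <- read_plate_csv(f)
  expect_identical(names(d2), names(d))
  for (col in names(d)) expect_equal(d2[[col]], d[[col]], tolerance = 1e-12)
  expect_identical(attr(d2, "mode"), "competition")
  p2 <- attr(d2, "probe")
  expect_equal(c(p2$rf, p2$rb, p2$R, p2$kd_nM), c(0.016, 0.245, 3.1, 6.8))
  expect_equal(attr(d2, "truth")$ligand_kd_nM, 15)
  expect_false(attr(d2, "unit_converted"))
})

test_that("mA plate files are converted to dimensionless anisotropy on input", {
  p <- ref_probe(kd_nM = 6.8)
  d <- simulate_direct_titration(p, kd_nM = 6.8, n_replicates = 1, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(d, f, unit = "mA")
  raw <- readLines(f)
  expect_true(any(grepl("anisotropy_unit=mA", raw)))
  d2 <- read_plate_csv(f)
  expect_true(attr(d2, "unit_converted"))
  expect_equal(d2$anisotropy, d$anisotropy, tolerance = 1e-12)
})

test_that("a plate file without intensities loads but blocks corrected analysis", {
  p <- ref_probe(kd_nM = 6.8)
  d <- simulate_direct_titration(p, kd_nM = 6.8, n_replicates = 1, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(d, f)
  lines <- readLines(f)
  i <- grep("^well,", lines)
  lines[-seq_len(i - 1)] <- sub(",[^,]*$", "", lines[-seq_len(i - 1)])
  lines <- lines[!grepl("probe_R", lines)]
  writeLines(lines, f)
  d2 <- read_plate_csv(f)
  expect_true(all(is.na(d2$intensity)))
  expect_error(fit_direct_kd(d2), "R is not available")
})

test_that("malformed plate files raise parse errors naming the location", {
  p <- ref_probe(kd_nM = 6.8)
  d <- simulate_direct_titration(p, kd_nM = 6.8, n_replicates = 1, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")

  write_plate_csv(d, f)
  lines <- readLines(f)
  writeLines(c(lines, lines[grep("^A01", lines)]), f)  # duplicate well A01
  expect_error(read_plate_csv(f), "Duplicate \\(well, replicate\\)")

  write_plate_csv(d, f)
  lines <- readLines(f)
  writeLines(c("# no equals sign here", lines), f)
  expect_error(read_plate_csv(f), "line 1")

  write_plate_csv(d, f)
  lines <- readLines(f)
  lines <- sub("anisotropy_unit=anisotropy", "anisotropy_unit=furlongs", lines)
  writeLines(lines, f)
  expect_error(read_plate_csv(f), "Unknown anisotropy_unit")
})

test_that("noiseless simulated data re-fit returns the generating Kd", {
  p <- ref_probe(kd_nM = 6.8)
  d <- simulate_direct_titration(p, kd_nM = 42, n_replicates = 1,
                                 sigma_r = 0, sigma_i_rel = 0)
  expect_equal(fit_direct_kd(d)$kd_mean_nM, 42, tolerance = 1e-5)
  dd <- simulate_displacement(p, ligand_kd_nM = 230, n_replicates = 1,
                              sigma_r = 0, sigma_i_rel = 0)
  expect_equal(fit_competition_kd(dd)$kd_mean_nM, 230, tolerance = 1e-5)
})
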