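gauss_run <- function(mz, apex, rt0, sigma, rt = seq(0, 4, by = 0.005),
                      iso = NULL) {
  peaks <- lapply(rt, function(t) {
    h <- apex * exp(-(t - rt0)^2 / (2 * sigma^2))
    if (is.null(iso)) {
      cbind(mz = mz, intensity = h)
    } else {
      cbind(mz = iso$mz, intensity = h * iso$ab)
    }
  })
  spectrum_run(rt, peaks)
}

test_that("XIC extraction sums centroids inside the ppm window only", {
  run <- spectrum_run(
    rt = c(1, 2, 3),
    peaks = list(cbind(1000.0, 500), cbind(1000.0 * (1 + 20e-6), 800),
                 matrix(numeric(0), ncol = 2))
  )
  xic <- extract_xic(run, 1000.0, tolerance_ppm = 10)
  expect_equal(xic$intensity, c(500, 0, 0))
  expect_identical(nrow(xic), 3L)   # one point per spectrum, zero-filled
  # the 20-ppm-offset centroid enters once the tolerance covers it
  expect_equal(extract_xic(run, 1000.0, 25)$intensity, c(500, 800, 0))
  expect_error(extract_xic(run, 1000, tolerance_ppm = 0), "positive")
})

test_that("scaling a run scales the XIC linearly", {
  run <- gauss_run(800, 1e6, 2, 0.05)
  k <- 3.7
  run_k <- spectrum_run(run$rt, lapply(run$peaks, function(p) {
    p[, 2] <- p[, 2] * k
    p
  }))
  x1 <- extract_xic(run, 800)
  x2 <- extract_xic(run_k, 800)
  expect_equal(x2$intensity, k * x1$intensity, tolerance = 1e-12)
})

test_that("widening the tolerance never reduces XIC intensity", {
  set.seed(3)
  rt <- seq(0, 1, by = 0.01)
  peaks <- lapply(rt, function(t)
    cbind(mz = 900 * (1 + rnorm(5, 0, 8e-6)), intensity = runif(5, 0, 1e4)))
  run <- spectrum_run(rt, peaks)
  narrow <- extract_xic(run, 900, 5)$intensity
  wide <- extract_xic(run, 900, 15)$intensity
  expect_true(all(wide >= narrow))
})

test_that("peak detection finds Gaussian peaks at their apex", {
  flat <- tibble::tibble(rt = seq(0, 2, 0.01), intensity = 0)
  expect_identical(nrow(detect_peaks(flat)), 0L)

  run <- gauss_run(800, 1e6, 2, 0.05)
  xic <- extract_xic(run, 800)
  pk <- detect_peaks(xic, min_height = 100)
  expect_identical(nrow(pk), 1L)
  expect_lte(abs(pk$apex_rt - 2), 0.005)  # within one scan interval
  expect_equal(pk$height, 1e6, tolerance = 1e-6)

  # two baseline-resolved Gaussians 1 min apart
  rt <- seq(0, 6, by = 0.005)
  two <- spectrum_run(rt, lapply(rt, function(t) {
    h <- 1e6 * exp(-(t - 2)^2 / (2 * 0.05^2)) +
      5e5 * exp(-(t - 3)^2 / (2 * 0.05^2))
    cbind(mz = 800, intensity = h)
  }))
  pk2 <- detect_peaks(extract_xic(two, 800), min_height = 100)
  expect_identical(nrow(pk2), 2L)
  expect_lte(abs(pk2$apex_rt[1] - 2), 0.005)
  expect_lte(abs(pk2$apex_rt[2] - 3), 0.005)
  expect_true(pk2$right_rt[1] <= pk2$left_rt[2])  # non-overlapping
})

test_that("trapezoidal integration matches analytic areas", {
  # triangle of height h over width w
  tri <- tibble::tibble(rt = c(0, 0.5, 1), intensity = c(0, 1000, 0))
  expect_equal(integrate_peak(tri, 0, 1), 1000 * 1 / 2)

  # dense Gaussian: area apex * sigma * sqrt(2 pi) within 1%
  sigma <- 0.05
  run <- gauss_run(800, 1e6, 2, sigma, rt = seq(0, 4, by = sigma / 10))
  xic <- extract_xic(run, 800)
  expect_equal(integrate_peak(xic, 2 - 6 * sigma, 2 + 6 * sigma),
               1e6 * sigma * sqrt(2 * pi), tolerance = 0.01)

  zero <- tibble::tibble(rt = seq(0, 1, 0.1), intensity = 0)
  expect_identical(integrate_peak(zero, 0, 1), 0)
  expect_error(integrate_peak(tri, 1, 0), "less than")
})

test_that("isotope scores are cosines against the theoretical envelope", {
  tg <- targets_from_species("GM3(d18:1_18:0)", "-H")
  ab <- c(tg$iso_ab_1, tg$iso_ab_2, tg$iso_ab_3)
  iso <- list(mz = c(tg$iso_mz_1, tg$iso_mz_2, tg$iso_mz_3), ab = ab)

  # observed envelope proportional to theory scores 1
  run <- gauss_run(tg$theoretical_mz, 1e6, 2, 0.05, iso = iso)
  expect_equal(isotope_score(run, tg, 2), 1, tolerance = 1e-9)

  # only the monoisotopic peak present: score = ab1 / ||ab||
  mono <- gauss_run(tg$theoretical_mz, 1e6, 2, 0.05)
  expect_equal(isotope_score(mono, tg, 2), ab[1] / sqrt(sum(ab^2)),
               tolerance = 1e-9)

  # signal only at A+1: score = ab2 / ||ab||
  a1 <- gauss_run(iso$mz[2], 1e6, 2, 0.05)
  expect_equal(isotope_score(a1, tg, 2), ab[2] / sqrt(sum(ab^2)),
               tolerance = 1e-9)

  # no signal at all scores 0
  expect_equal(isotope_score(gauss_run(700, 1e3, 2, 0.05), tg, 2), 0)
})

test_that("profile-mode mzML input is rejected", {
  path <- withr::local_tempfile(fileext = ".mzML")
  sim <- simulate_run(sim_config(
    species = default_sim_panel()[3, ], run_length = 1,
    scan_interval = 0.05, seed = 1))
  run <- sim$run
  run$peaks[[1]] <- cbind(mz = 1000, intensity = 10)  # ensure non-empty
  # write with a profile-mode header
  n <- length(run$rt)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 0L, peaksCount = vapply(run$peaks, nrow, 1L),
    totIonCurrent = 0, retentionTime = run$rt * 60, basePeakMZ = 0,
    basePeakIntensity = 0, collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = 0, highMZ = 0, precursorScanNum = 0L, precursorMZ = 0,
    precursorCharge = 0L, precursorIntensity = 0, mergedScan = 0L,
    mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_, spectrumId = paste0("scan=", seq_len(n)),
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(unname(run$peaks), path, header = hdr)
  expect_error(read_mzml(path), "profile")
})

test_that("fixture truth areas are recovered end to end on a clean run", {
  sim <- simulate_run(sim_config(
    species = default_sim_panel()[c(3, 8, 9), ], run_length = 14,
    scan_interval = 0.005, seed = 5))
  truth <- sim$truth
  targets <- targets_from_species(truth$name, truth$adduct,
                                  rt_center = truth$true_rt,
                                  rt_halfwidth = 0.5)
  got <- quantify_targets(sim$run, targets, min_height = 1000)
  expect_equal(nrow(got), 3L)
  expect_true(all(abs(got$apex_rt - truth$true_rt) <= 0.005))
  expect_true(all(abs(got$area - truth$true_area) / truth$true_area <= 0.02))
  expect_true(all(got$isotope_score > 0.99))
})
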