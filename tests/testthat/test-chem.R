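test_that("monoisotopic mass sums the bundled atomic masses", {
  expect_identical(monoisotopic_mass(comp()), 0)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-7)
  expect_equal(monoisotopic_mass("C6H10O5"), 162.052824, tolerance = 1e-8)
  expect_equal(monoisotopic_mass(comp(C = 11, H = 17, N = 1, O = 8)),
               291.095417, tolerance = 1e-8)
  expect_equal(monoisotopic_mass("C6H10O5"),
               mass_of(C = 6, H = 10, O = 5), tolerance = 1e-12)
  expect_error(monoisotopic_mass(comp(Xx = 1)), "Xx")
})

test_that("mass is additive over composition arithmetic", {
  set.seed(42)
  for (i in 1:25) {
    a <- comp(C = sample(0:40, 1), H = sample(0:80, 1), N = sample(0:5, 1),
              O = sample(0:20, 1), S = sample(0:2, 1))
    b <- comp(C = sample(0:40, 1), H = sample(0:80, 1), P = sample(0:2, 1))
    expect_equal(monoisotopic_mass(comp_add(a, b)),
                 monoisotopic_mass(a) + monoisotopic_mass(b),
                 tolerance = 1e-12)
    expect_identical(comp_add(a, b), comp_add(b, a))
  }
  expect_equal(monoisotopic_mass(comp_scale(comp(C = 2, H = 4), 3)),
               3 * monoisotopic_mass(comp(C = 2, H = 4)))
  expect_error(comp(C = -1), "non-negative")
})

test_that("deprotonated m/z follows the charge-carrier arithmetic", {
  expect_equal(adduct_mz(1000, "-H"), 998.99272354, tolerance = 1e-8)
  expect_equal(adduct_mz(1000, "-H", convention = "hydrogen"),
               1000 - 1.00782503207, tolerance = 1e-8)
  # doubly deprotonated: (M - 2 mp) / 2
  expect_equal(adduct_mz(1674.919259, "-2H"),
               (1674.919259 - 2 * 1.00727646) / 2, tolerance = 1e-9)
  # a "neutral mass" at the mass of the removed protons is unphysical
  expect_error(adduct_mz(2.014552, "-2H"), "exceed")
  expect_error(adduct_mz(-5, "-H"), "exceed")
  expect_error(adduct("-0H"), ">= 1")
  expect_error(adduct("+H"), "unrecognized")
  # for fixed M, m/z strictly decreases with the number of protons removed
  mzs <- vapply(c("-H", "-2H", "-3H"), function(a) adduct_mz(2000, a), 0)
  expect_true(all(diff(mzs) < 0))
})

test_that("ppm error matches the printed mass-accuracy arithmetic", {
  expect_equal(round(ppm_error(1516.8375, 1516.8451), 1), 5.0)
  expect_equal(ppm_error(903.4628, 903.4628), 0)
  expect_equal(round(ppm_error(903.4628, 903.4687), 2), 6.53)
  # absolute value: the sign of the deviation is dropped
  expect_equal(ppm_error(1000, 999), ppm_error(1000, 1001))
  expect_error(ppm_error(0, 1), "positive")
})

test_that("isotope patterns match closed forms on simple formulas", {
  p <- isotope_pattern("C1")
  expect_equal(p$mz, c(12, 13.003355), tolerance = 1e-6)
  expect_equal(p$abundance, c(1, 0.0107 / 0.9893), tolerance = 1e-6)

  # heavy isotopologues of water fall below a 0.5 threshold
  w <- isotope_pattern("H2O", threshold = 0.5)
  expect_identical(nrow(w), 1L)
  expect_equal(w$mz, 18.010565, tolerance = 1e-6)

  # A+1/A0 of C100 equals the binomial expectation 100 * r
  c100 <- isotope_pattern("C100")
  expect_equal(c100$prob[c100$shift == 1] / c100$prob[c100$shift == 0],
               100 * 0.0107 / 0.9893, tolerance = 1e-9)

  expect_error(isotope_pattern("C6", threshold = 0), "0, 1")
  expect_error(isotope_pattern("C6", threshold = 1.2), "0, 1")
  expect_error(isotope_pattern(comp()), "non-empty")
})

test_that("pre-truncation isotopologue probabilities sum to one", {
  for (f in c("C6H12O6", "C20H40N4O8S1", "C100H200N20O50")) {
    expect_equal(attr(isotope_pattern(f, 1e-8), "prob_sum"), 1,
                 tolerance = 1e-9)
  }
})

test_that("convolution agrees with brute-force enumeration on small formulas", {
  for (f in list(comp(C = 3, H = 6, O = 2), comp(C = 2, H = 4, N = 2, S = 1),
                 comp(O = 6, S = 2), comp(C = 6, H = 6))) {
    got <- isotope_pattern(f, threshold = 1e-9)
    want <- brute_force_pattern(f)
    merged <- merge(as.data.frame(got), want, by = "shift",
                    suffixes = c("_got", "_want"))
    expect_gt(nrow(merged), 1)
    expect_equal(merged$prob_got, merged$prob_want, tolerance = 1e-9)
    expect_equal(merged$mz_got, merged$mz_want, tolerance = 1e-7)
  }
})

test_that("ion-space patterns use charge-scaled isotope spacing", {
  cmp <- parse_species("GD2(d18:1_18:0)")$composition
  p2 <- isotope_pattern_mz(cmp, "-2H")
  expect_equal(p2$mz[2] - p2$mz[1], 1.00336 / 2, tolerance = 1e-3)
  p1 <- isotope_pattern_mz(cmp, "-H")
  expect_equal(p1$mz[2] - p1$mz[1], 1.00336, tolerance = 1e-3)
})
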