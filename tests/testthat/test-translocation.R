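test_that("resting density solves the normalized baseline equation", {
  rest <- canonicalResting()
  expect_equal(restingDensity(rest), 0.0783, tolerance = 1e-3)
  # closed form agrees with the numeric root-find oracle
  expect_equal(restingDensity(rest),
               oracleRestingDensity(canonicalGrid()), tolerance = 1e-10)
  # uniform illumination: m = 1/N
  uni <- suppressWarnings(illuminationProfile(0, nLayers = 50))
  expect_equal(restingDensity(solveRestingDensity(uni)), 0.02)
  # single layer: everything at the membrane
  one <- suppressWarnings(illuminationProfile(0.008, nLayers = 1))
  expect_equal(restingDensity(solveRestingDensity(one)), 1)
})

test_that("delta-m inversion matches the root-find oracle in both
           scenarios", {
  rest <- canonicalResting()
  for (sc in c("fixed_total", "fixed_cytosol")) {
    for (F in c(1, 1.2, 1.54, 2.5)) {
      expect_equal(solveDeltaM(F, rest, sc),
                   oracleDeltaM(F, rest, sc), tolerance = 1e-10)
    }
  }
  expect_equal(solveDeltaM(1.54, rest, "fixed_total"), 0.7252,
               tolerance = 1e-4)
  expect_equal(solveDeltaM(1.54, rest, "fixed_cytosol"), 0.54,
               tolerance = 1e-10)
  expect_identical(solveDeltaM(1, rest, "fixed_total"), 0)
  expect_identical(solveDeltaM(1, rest, "fixed_cytosol"), 0)
})

test_that("out-of-range fold-changes are rejected with clear errors", {
  rest <- canonicalResting()
  expect_error(solveDeltaM(0.88, rest, "fixed_total"),
               "depletion not modeled")
  expect_warning(dm <- solveDeltaM(0.88, rest, "fixed_total",
                                   allowDepletion = TRUE),
                 "depletion")
  expect_lt(dm, 0)
  # fixed_total maximum: all molecules at the membrane
  Fmax <- nLayers(canonicalGrid()) * restingDensity(rest) *
    illumination(canonicalGrid())[1]
  expect_error(solveDeltaM(Fmax + 0.01, rest, "fixed_total"),
               "negative cytosolic density")
  expect_silent(solveDeltaM(Fmax - 1e-9, rest, "fixed_total"))
  # a uniform grid makes fixed_total F independent of delta-m
  uni <- solveRestingDensity(suppressWarnings(illuminationProfile(0)))
  expect_error(solveDeltaM(1.5, uni, "fixed_total"), "degenerate")
})

test_that("the worked example inverts to a 10-fold and 8-fold membrane
           enrichment", {
  rest <- canonicalResting()
  rmTotal <- membraneRatio(rest, solveDeltaM(1.54, rest, "fixed_total"))
  rmCyto <- membraneRatio(rest, solveDeltaM(1.54, rest, "fixed_cytosol"))
  expect_equal(round(rmTotal), 10)
  expect_equal(round(rmCyto), 8)
  expect_equal(membraneRatio(rest, 0), 1)
  # the two scenarios agree to within 25 percent here
  expect_lt(abs(rmTotal - rmCyto) / rmTotal, 0.25)
})

test_that("forward and inverse fold-change maps are exact inverses", {
  rest <- canonicalResting()
  Fmax <- nLayers(canonicalGrid()) * restingDensity(rest)
  Fgrid <- seq(1, 1 + 0.99 * (Fmax - 1), length.out = 25)
  for (sc in c("fixed_total", "fixed_cytosol")) {
    back <- forwardFoldChange(rest, solveDeltaM(Fgrid, rest, sc), sc)
    expect_equal(back, Fgrid, tolerance = 1e-10)
  }
  expect_identical(forwardFoldChange(rest, 0, "fixed_total"), 1)
  # F is affine and increasing in delta-m
  dms <- seq(0, 1, 0.1)
  Fs <- forwardFoldChange(rest, dms, "fixed_total")
  expect_true(all(diff(Fs) > 0))
  expect_equal(diff(Fs), rep(diff(Fs)[1], 10), tolerance = 1e-12)
})

test_that("membrane ratio grows with fold-change and the fixed-cytosol
           reading never exceeds the fixed-total one", {
  rest <- canonicalResting()
  Fgrid <- seq(1, 3, length.out = 40)
  rmT <- membraneRatio(rest, solveDeltaM(Fgrid, rest, "fixed_total"))
  rmC <- membraneRatio(rest, solveDeltaM(Fgrid, rest, "fixed_cytosol"))
  expect_equal(rmT[1], 1)
  expect_true(all(diff(rmT) > 0))
  expect_true(all(rmC <= rmT + 1e-12))
})

test_that("fixed-total keeps the cytosolic density non-negative over the
           accepted range", {
  rest <- canonicalResting()
  m <- restingDensity(rest)
  N <- nLayers(canonicalGrid())
  Fmax <- N * m # I0 = 1
  Fgrid <- seq(1, Fmax, length.out = 50)
  dm <- solveDeltaM(Fgrid, rest, "fixed_total")
  expect_true(all(m - dm / N >= -1e-12))
})

test_that("estimateTranslocation wraps the chain and tabulates", {
  rest <- canonicalResting()
  est <- estimateTranslocation(c(1, 1.2, 1.54), rest, "fixed_total")
  expect_s4_class(est, "TranslocationEstimate")
  df <- as.data.frame(est)
  expect_named(df, c("fold_change", "delta_m", "membrane_ratio",
                     "scenario"))
  expect_equal(df$membrane_ratio[1], 1)
  expect_equal(foldChange(est), c(1, 1.2, 1.54))
  expect_identical(scenario(est), "fixed_total")
  expect_equal(membraneRatio(est),
               1 + deltaM(est) / restingDensity(rest))
})
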