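test_that("recruitment curves are delayed, bounded and shaped by the
           plateau fraction", {
  kp <- kineticParams(2, delay = 30, riseTau = 40, decayTau = 200,
                      plateauFraction = 0.6)
  tm <- seq(-60, 2000, 5)
  dm <- recruitmentCurve(kp, tm)
  expect_true(all(dm[tm < 30] == 0))
  expect_true(all(dm >= 0) && all(dm <= 2))
  # long-time limit: amplitude * plateauFraction
  expect_equal(recruitmentCurve(kp, 1e6), 2 * 0.6, tolerance = 1e-9)
  # partial relaxation: the peak exceeds the late value
  expect_gt(max(dm), dm[length(dm)] * 1.05)

  mono <- recruitmentCurve(kineticParams(2, plateauFraction = 1), tm)
  expect_true(all(diff(mono) >= 0))
  expect_error(kineticParams(-1), "amplitude")
  expect_error(kineticParams(1, riseTau = 0), "riseTau")
})

test_that("rendering is bit-identical under a fixed seed", {
  rest <- canonicalResting()
  tm <- seq(-60, 120, 10)
  a <- renderStack(kineticParams(0.5), rest, tm, seed = 77)
  b <- renderStack(kineticParams(0.5), rest, tm, seed = 77)
  expect_identical(frames(a$stack), frames(b$stack))
  c <- renderStack(kineticParams(0.5), rest, tm, seed = 78)
  expect_false(identical(frames(a$stack), frames(c$stack)))
})

test_that("a noiseless, amplitude-zero render normalizes to exactly 1", {
  rs <- renderStack(kineticParams(0), canonicalResting(),
                    seq(-120, 480, 10), noise = NULL)
  tr <- footprintTrace(rs$stack, rs$rois, 0)
  expect_equal(tr@normalized, rep(1, length(tr@time)), tolerance = 1e-12)
})

test_that("a noiseless render of the worked example reads back a 1.54
           window summary", {
  rs <- noiselessRender(1.54)
  tr <- footprintTrace(rs$stack, rs$rois, 0)
  expect_equal(windowSummary(tr, "biosensor_late"), 1.54,
               tolerance = 1e-9)
})

test_that("render rejects impossible geometry and noise", {
  rest <- canonicalResting()
  tm <- seq(-60, 60, 10)
  big <- renderGeometry(dim = c(32L, 32L), center = c(16, 16),
                        radii = c(30, 30))
  expect_error(renderStack(kineticParams(0), rest, tm, geometry = big),
               "geometry larger than frame")
  expect_error(cameraNoise(photonsPerUnit = -1), ">= 0")
  expect_error(cameraNoise(readSd = -0.5), ">= 0")
})

test_that("condition templates reproduce the expected cohort
           structure", {
  sim <- generateCohorts(defaultExperiment(60, 20, 30), seed = 202)
  s <- sim$summaries
  resp <- s$summary_value[s$condition == "responder"]
  veh <- s$summary_value[s$condition == "vehicle"]
  inh <- s$summary_value[s$condition == "inhibitor"]

  expect_equal(mean(veh), 1, tolerance = 0.01)
  expect_lt(mean(inh), 1)
  expect_gt(mean(resp), 1.3)
  # right-skewed responder amplitudes propagate to the summaries
  skew <- mean(((resp - mean(resp)) / sd(resp))^3)
  expect_gt(skew, 0)
  # ground truth is coherent with the forward model
  tr <- sim$truth[sim$truth$condition == "responder", ]
  expect_true(all(tr$true_membrane_ratio > 1))
  expect_equal(
    membraneRatio(sim$resting,
                  solveDeltaM(tr$true_fold_change, sim$resting)),
    tr$true_membrane_ratio, tolerance = 1e-10)
})

test_that("cohort generation is deterministic given spec and seed", {
  a <- generateCohorts(cohortSpec("responder", 10, "responder"),
                       seed = 33)
  b <- generateCohorts(cohortSpec("responder", 10, "responder"),
                       seed = 33)
  expect_identical(a$summaries, b$summaries)
  expect_identical(a$truth, b$truth)
})

test_that("responder and vehicle cohorts separate decisively at the
           default sizes", {
  set.seed(71)
  reject <- vapply(1:20, function(i) {
    sim <- generateCohorts(defaultExperiment(100, 20, 1)[1:2],
                           seed = 1000 + i)
    s <- sim$summaries
    rankSumTest(s$summary_value[s$condition == "responder"],
                s$summary_value[s$condition == "vehicle"])$p.value < 0.001
  }, logical(1))
  expect_true(all(reject))
})

test_that("trace and render paths agree on the cohort mean", {
  spec <- cohortSpec("responder", 25, "responder")
  fast <- generateCohorts(spec, seed = 88)
  full <- generateCohorts(spec, method = "render", seed = 88)
  expect_equal(mean(fast$summaries$summary_value),
               mean(full$summaries$summary_value), tolerance = 0.05)
  # same seed draws the same amplitudes on both paths
  expect_equal(fast$truth$amplitude, full$truth$amplitude)
})
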