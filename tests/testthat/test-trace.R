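makeStack <- function(values, dim = c(4L, 4L)) {
  # one constant frame per value
  arr <- array(rep(values, each = prod(dim)), dim = c(dim, length(values)))
  tirfStack(arr, frameInterval = 10, startTime = 0)
}

test_that("ROI extraction is the per-frame arithmetic mean", {
  st <- makeStack(rep(5, 4))
  mask <- matrix(TRUE, 4, 4)
  expect_equal(extractTrace(st, mask), rep(5, 4))

  arr <- array(0, dim = c(2, 2, 2))
  arr[1, 1, ] <- 2
  arr[2, 1, ] <- 4
  st2 <- tirfStack(arr)
  mask2 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(extractTrace(st2, mask2), c(3, 3))

  expect_error(extractTrace(st, matrix(FALSE, 4, 4)), "empty mask")
  expect_error(extractTrace(st, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("background subtraction is elementwise and flags non-positive
           output without clipping", {
  expect_equal(backgroundSubtract(rep(5, 3), rep(2, 3)), rep(3, 3))
  expect_warning(z <- backgroundSubtract(rep(2, 3), rep(2, 3)),
                 "non-positive")
  expect_equal(z, rep(0, 3)) # kept, not clipped
  expect_equal(backgroundSubtract(c(1, 2), c(0, 0)), c(1, 2))
  expect_error(backgroundSubtract(1:3, 1:2), "equal length")
})

test_that("baseline normalization divides by the pre-application mean", {
  time <- seq(-60, 60, 10)
  trace <- ifelse(time < 0, 2, 3)
  norm <- normalizeBaseline(trace, time)
  expect_equal(norm[time >= 0], rep(1.5, sum(time >= 0)))
  expect_equal(mean(norm[time >= -60 & time < 0]), 1)

  expect_equal(normalizeBaseline(rep(7, 13), time), rep(1, 13))
  expect_error(normalizeBaseline(1:5, seq(10, 50, 10)), "baseline window")
  expect_error(normalizeBaseline(rep(-1, 13), time), "non-positive")
})

test_that("normalization is idempotent", {
  time <- seq(-120, 300, 10)
  trace <- 100 + 20 * sin(time / 80)
  once <- normalizeBaseline(trace, time)
  expect_equal(normalizeBaseline(once, time), once, tolerance = 1e-14)
})

test_that("window summaries are half-open means on frame timestamps", {
  tm <- seq(0, 600, 10)
  expect_equal(windowSummary(rep(1, 61), "biosensor_late", time = tm), 1)
  step <- ifelse(tm < 120, 1, 1.5)
  expect_equal(windowSummary(step, treatmentWindow(6, 8), time = tm), 1.5)
  # linear ramp 1 -> 2 over 0-10 min, sampled every 10 s
  ramp <- 1 + tm / 600
  expect_equal(windowSummary(ramp, treatmentWindow(6, 8), time = tm),
               mean(1 + seq(360, 470, 10) / 600))
  # the sample exactly at the window end is excluded
  spike <- rep(1, 61)
  spike[tm == 480] <- 100
  expect_equal(windowSummary(spike, treatmentWindow(6, 8), time = tm), 1)
  expect_error(windowSummary(ramp, treatmentWindow(11, 12), time = tm),
               "no samples")
  expect_error(treatmentWindow(8, 6), "start < end")
  expect_error(windowSummary(ramp, "no_such_preset", time = tm),
               "unknown window preset")
})

test_that("window presets cover both channels at both conventions", {
  p <- windowPresets()
  expect_named(p, c("biosensor_early", "biosensor_late",
                    "channel_early", "channel_late"))
  expect_equal(p$biosensor_early@start, 4)
  expect_equal(p$channel_late@end, 12)
})

test_that("the pipeline is invariant to camera gain and offset", {
  rs <- renderStack(kineticParams(0.5), canonicalResting(),
                    seq(-120, 480, 10), seed = 301)
  ref <- footprintTrace(rs$stack, rs$rois, 0)

  gain <- tirfStack(frames(rs$stack) * 3.7,
                    frameInterval = frameInterval(rs$stack),
                    startTime = frameTimes(rs$stack)[1])
  offs <- tirfStack(frames(rs$stack) + 57,
                    frameInterval = frameInterval(rs$stack),
                    startTime = frameTimes(rs$stack)[1])
  expect_equal(footprintTrace(gain, rs$rois, 0)@normalized,
               ref@normalized, tolerance = 1e-12)
  expect_equal(footprintTrace(offs, rs$rois, 0)@normalized,
               ref@normalized, tolerance = 1e-12)
})

test_that("the pipeline recovers the generator's noiseless truth
           exactly", {
  rest <- canonicalResting()
  kp <- kineticParams(0.6, delay = 30, riseTau = 45, decayTau = 200,
                      plateauFraction = 0.8)
  rs <- renderStack(kp, rest, seq(-120, 480, 10), noise = NULL)
  # raw ROI mean equals offset + baseline * F(t) by construction
  raw <- extractTrace(rs$stack, cellMask(rs$rois))
  expect_equal(raw, 20 + 100 * rs$truth$foldChange, tolerance = 1e-12)
  tr <- footprintTrace(rs$stack, rs$rois, 0)
  expect_equal(tr@normalized, rs$truth$foldChange, tolerance = 1e-9)
})
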