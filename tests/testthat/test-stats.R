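test_that("cohort summaries report mean, SEM and n", {
  expect_equal(summarizeCohort(cohort("a", c(1, 1, 1))),
               list(mean = 1, sem = 0, n = 3L))
  s <- summarizeCohort(cohort("a", c(1, 2, 3)))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_warning(s1 <- summarizeCohort(cohort("a", 5)), "SEM undefined")
  expect_equal(s1$mean, 5)
  expect_true(is.na(s1$sem))

  tab <- summarizeCohorts(list(cohort("a", 1:5), cohort("b", 2:9)))
  expect_equal(tab$condition, c("a", "b"))
  expect_equal(tab$n, c(5L, 8L))
})

test_that("rank-sum p matches exact enumeration and handles the
           symmetric null", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p.value, 0.1, tolerance = 1e-12)
  expect_equal(r$p.value, oracleRankSumP(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(r$statistic, 0)
  # identical multisets: p = 1
  expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(rankSumTest(numeric(0), 1:3), "non-empty")

  # a couple more exact cases against the enumeration oracle
  set.seed(17)
  for (i in 1:5) {
    a <- sample(100, 5)
    b <- sample(200, 6) + 0.5
    expect_equal(rankSumTest(a, b)$p.value, oracleRankSumP(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum p is invariant under monotone transforms", {
  set.seed(21)
  a <- rlnorm(14)
  b <- rlnorm(17) * 1.5
  p0 <- rankSumTest(a, b)$p.value
  expect_equal(rankSumTest(log(a), log(b))$p.value, p0)
  expect_equal(rankSumTest(a^3, b^3)$p.value, p0)
  expect_equal(rankSumTest(-1 / a, -1 / b)$p.value, p0)
})

test_that("exact and approximate rank-sum p agree for moderate
           tie-free samples", {
  set.seed(31)
  for (i in 1:50) {
    a <- rnorm(15)
    b <- rnorm(18)
    d <- abs(rankSumTest(a, b, exact = TRUE)$p.value -
               rankSumTest(a, b, exact = FALSE)$p.value)
    expect_lt(d, 0.01)
  }
})

test_that("a one-sd shift between cohorts of 50 is detected almost
           always", {
  set.seed(41)
  hits <- mean(replicate(200, {
    rankSumTest(rnorm(50), rnorm(50) + 1)$p.value < 0.01
  }))
  expect_gte(hits, 0.95)
})

test_that("Holm step-down arithmetic and degenerate cases", {
  expect_equal(holmBonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holmBonferroni(0.3), 0.3)
  expect_equal(holmBonferroni(c(0.01, 0.011)), c(0.02, 0.02))
  expect_equal(holmBonferroni(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(holmBonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(holmBonferroni(c(-0.1, 0.2)), "\\[0, 1\\]")
})

test_that("Holm adjustment dominates raw p, is capped by Bonferroni and
           preserves order", {
  set.seed(51)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holmBonferroni(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, p * length(p)) + 1e-15))
    expect_equal(order(adj[order(p)]), seq_along(p)) # order-preserving
    expect_true(all(adj <= 1))
  }
})

test_that("paired t test matches the closed form and flags degenerate
           input", {
  r <- pairedTTest(c(2, 4, 6), c(1, 2, 3)) # differences 1, 2, 3
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$p.value, 2 * pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-12)
  expect_equal(pairedTTest(1:4, 1:4), list(statistic = 0, p.value = 1))
  expect_error(pairedTTest(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_error(pairedTTest(1:3, 1:4), "equal length")
})

test_that("blot normalization removes exposure gain and loading
           differences", {
  grid <- cbind(phospho = c(2, 4), panAkt = c(3, 3))
  out <- normalizeBlot(grid)
  expect_equal(unname(out[, "phospho"]), c(2 / 3, 4 / 3))

  same <- cbind(phospho = c(5, 5), panAkt = c(2, 2))
  expect_equal(unname(normalizeBlot(same)[, 1]), c(1, 1))

  # doubling one blot's exposure changes nothing
  out2 <- normalizeBlot(cbind(phospho = 2 * c(2, 4), panAkt = c(3, 3)))
  expect_equal(out2, out)
  out3 <- normalizeBlot(cbind(phospho = c(2, 4), panAkt = 5 * c(3, 3)))
  expect_equal(out3, out)

  expect_error(normalizeBlot(cbind(a = c(1, 2), b = c(1, 1))),
               "pan-reference")
  expect_error(normalizeBlot(grid - 2), "strictly positive")
})

test_that("cohort comparisons share one explicit adjustment family", {
  set.seed(61)
  chs <- list(cohort("responder", rnorm(40, 1.5, 0.3)),
              cohort("vehicle", rnorm(20, 1, 0.05)),
              cohort("inhibitor", rnorm(30, 0.9, 0.05)))
  tab <- compareCohorts(chs, family = list(
    c("responder", "vehicle"), c("responder", "inhibitor"),
    c("vehicle", "inhibitor")))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_adjusted >= tab$p_raw))
  expect_equal(tab$p_adjusted, holmBonferroni(tab$p_raw))
  raw <- compareCohorts(chs, adjust = FALSE)
  expect_false("p_adjusted" %in% names(raw))
  expect_error(compareCohorts(chs, family = list(c("responder", "x"))),
               "unknown condition")
})
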