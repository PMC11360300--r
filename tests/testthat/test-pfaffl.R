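test_that("efficiency fitting inverts the slope law", {
  mk <- function(slope, intercept = 20, logc = 0:-4)
    data.frame(log10_concentration = logc, ct = intercept + slope * logc)
  est <- fitPrimerEfficiency(mk(-1 / log10(2)))
  expect_equal(est$E, 2, tolerance = 1e-9)
  expect_equal(est$percent, 100, tolerance = 1e-6)
  est <- fitPrimerEfficiency(mk(-3.45))
  expect_equal(est$E, 10^(1 / 3.45), tolerance = 1e-12)
  expect_error(fitPrimerEfficiency(mk(0.5)), "implausible-series")
  expect_error(fitPrimerEfficiency(mk(-3.3)[1:2, ]), "3 points")
})

test_that("noiseless simulate -> fit round trip recovers E exactly", {
  for (E in c(1.95, 1.96, 1.98, 2.0)) {
    s <- simulateDilutionSeries(qpcrSimConfig(efficiency = E,
                                              ctNoiseSd = 0))
    expect_equal(fitPrimerEfficiency(s)$E, E, tolerance = 1e-6)
  }
})

test_that("noisy efficiency recovery is unbiased (Monte-Carlo)", {
  E <- 1.96
  est <- vapply(1:100, function(s)
    fitPrimerEfficiency(simulateDilutionSeries(
      qpcrSimConfig(efficiency = E, ctNoiseSd = 0.1, seed = s)))$E,
    numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - E), 2 * se + 1e-12)
})

test_that("relative expression follows the efficiency-corrected ratio", {
  m <- expressionMeasurement("VII", "B2M", 2, 2, 20, 20)
  expect_equal(relativeExpression(m), 1)
  m <- expressionMeasurement("VII", "B2M", 2, 2, 19, 20)
  expect_equal(relativeExpression(m), 2)
  ## mixed efficiencies against a hand-computed oracle
  m <- expressionMeasurement("VII", "B2M", 1.95, 1.98, 24.1, 18.7)
  expect_equal(relativeExpression(m), 1.98^18.7 / 1.95^24.1,
               tolerance = 1e-12)
  expect_error(expressionMeasurement("VII", "B2M", 2.3, 2, 20, 20),
               "invalid-efficiency")
})

test_that("relative expression is monotone in the CTs", {
  r <- vapply(c(20, 21, 22), function(ct)
    relativeExpression(expressionMeasurement("g", "h", 1.95, 1.98, ct,
                                             20)), numeric(1))
  expect_true(all(diff(r) < 0))          # decreasing in GOI CT
  r <- vapply(c(20, 21, 22), function(ct)
    relativeExpression(expressionMeasurement("g", "h", 1.95, 1.98, 20,
                                             ct)), numeric(1))
  expect_true(all(diff(r) > 0))          # increasing in HKG CT
})

test_that("comparative expression matches its Delta-CT form", {
  m1 <- expressionMeasurement("VII", "B2M", 2, 2, 18, 20)
  expect_equal(comparativeExpression(m1, m1), 1)
  m2 <- expressionMeasurement("VII", "B2M", 2, 2, 20, 20)
  expect_equal(comparativeExpression(m1, m2), 4)    # GOI dCT -2, HKG 0
  a <- expressionMeasurement("VII", "B2M", 1.95, 1.98, 22.4, 19.1)
  b <- expressionMeasurement("VII", "B2M", 1.95, 1.98, 24.0, 18.6)
  expect_equal(comparativeExpression(a, b),
               1.95^(-(22.4 - 24.0)) / 1.98^(-(19.1 - 18.6)),
               tolerance = 1e-12)
  other <- expressionMeasurement("I", "B2M", 1.95, 1.98, 20, 20)
  expect_error(comparativeExpression(a, other), "comparison error")
})

test_that("equal efficiencies reduce comparative expression to 2^-ddCT", {
  set.seed(17)
  for (i in 1:25) {
    ct <- round(runif(4, 15, 30), 2)
    m1 <- expressionMeasurement("g", "h", 2, 2, ct[1], ct[2])
    m2 <- expressionMeasurement("g", "h", 2, 2, ct[3], ct[4])
    ddct <- (ct[1] - ct[3]) - (ct[2] - ct[4])
    expect_equal(comparativeExpression(m1, m2), 2^-ddct,
                 tolerance = 1e-12)
  }
})

test_that("undetected targets propagate as missing, never as zero", {
  m <- expressionMeasurement("IV", "B2M", 1.95, 1.98, c(NA, NA, NA),
                             c(18, 18.1, 17.9))
  expect_true(m$undetected)
  r <- relativeExpression(m)
  expect_true(is.na(r))
  expect_true(attr(r, "undetected"))
  tab <- data.frame(sample = "mono",
                    primer_pair = rep(c("B2M", "IV", "VII"), each = 3),
                    replicate = rep(1:3, 3),
                    ct = c(18, 18.1, 17.9, NA, NA, NA, 22, 22.1, 21.9))
  out <- relativeExpressionTable(tab, c(B2M = 1.98, IV = 1.95,
                                        VII = 1.96))
  expect_true(out$undetected[out$primer_pair == "IV"])
  expect_true(is.na(out$ratio[out$primer_pair == "IV"]))
  expect_false(out$undetected[out$primer_pair == "VII"])
})
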