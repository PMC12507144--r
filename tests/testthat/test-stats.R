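test_that("mean arterial pressure follows (2 DBP + SBP) / 3", {
  expect_equal(meanArterialPressure(114, 66), 82)
  expect_equal(meanArterialPressure(117, 67), 83 + 2 / 3)
  expect_equal(aortaflow:::roundHalfUp(meanArterialPressure(117, 67)), 84)
  expect_error(meanArterialPressure(120, 120), "exceed")
  expect_error(meanArterialPressure(120, -5), "positive")
})

test_that("paired t handles degenerate differences and covers the truth", {
  x <- c(1, 2, 3, 4)
  r <- pairedT(x, x)
  expect_true(r$undefined)
  expect_equal(r$change, 0)
  expect_true(is.na(r$p))
  r2 <- pairedT(c(0, 1, 2, 3), c(1, 2, 3, 4))  # differences all 1
  expect_true(r2$undefined)
  expect_equal(r2$change, 1)
  # CI coverage ~ 95% for N(0.5, 1) differences at n = 20
  set.seed(123)
  cover <- vapply(1:1000, function(i) {
    before <- rnorm(20)
    after <- before + rnorm(20, 0.5, 1)
    ci <- pairedT(before, after)$ci
    ci[1] <= 0.5 && 0.5 <= ci[2]
  }, TRUE)
  expect_gt(mean(cover), 0.93)
  expect_lt(mean(cover), 0.97)
})

test_that("pooled-variance t reproduces printed group differences", {
  # samples constructed to exact means: the point estimate is exact
  mkSample <- function(n, mean, sd, seed) {
    set.seed(seed)
    x <- rnorm(n, 0, sd)
    x - mean(x) + mean
  }
  a <- mkSample(26, 29.2, 2.6, 1)
  b <- mkSample(20, 31.8, 2.4, 2)
  r <- unpairedT(a, b)
  expect_equal(r$difference, 2.6, tolerance = 1e-12)
  expect_true(r$ci[1] < 2.6 && 2.6 < r$ci[2])
  # identical groups: difference 0, p = 1
  set.seed(3); g <- rnorm(10)
  r0 <- unpairedT(g, g)
  expect_equal(r0$difference, 0)
  expect_equal(r0$p, 1)
  expect_error(unpairedT(rep(1, 5), rep(1, 5)), "variance")
  # power ~ 0.99 for N(0,1) vs N(1,1) at n = 50
  set.seed(11)
  rej <- vapply(1:500, function(i)
    unpairedT(rnorm(50), rnorm(50, 1))$p < 0.05, TRUE)
  expect_gt(mean(rej), 0.97)
})

test_that("Fisher exact agrees with hypergeometric enumeration", {
  expect_lt(fisherExact(18, 8, 5, 15), 0.05)  # Table-1-style sex imbalance
  expect_equal(fisherExact(5, 5, 5, 5), 1)
  expect_equal(fisherExact(10, 0, 0, 10), fisherBruteForce(10, 0, 0, 10),
               tolerance = 1e-12)
  expect_equal(fisherBruteForce(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # sweep of tables at a few totals
  for (tot in c(5, 12, 23)) {
    for (r1 in 0:tot) {
      for (c1 in 0:tot) {
        for (a in max(0, r1 + c1 - tot):min(r1, c1)) {
          b <- r1 - a; c <- c1 - a; d <- tot - a - b - c
          if (a + b + c + d == 0) next
          expect_equal(fisherExact(a, b, c, d),
                       fisherBruteForce(a, b, c, d), tolerance = 1e-9)
        }
      }
    }
  }
  expect_error(fisherExact(0, 0, 0, 0), "zero")
  expect_error(fisherExact(-1, 2, 3, 4), "non-negative")
})

test_that("exact McNemar follows the binomial convention", {
  expect_true(is.na(mcnemarExact(0, 0)))
  expect_equal(mcnemarExact(1, 0), 1.0)
  expect_equal(mcnemarExact(8, 1), 2 * pbinom(1, 9, 0.5), tolerance = 1e-12)
  expect_equal(mcnemarExact(8, 1), 0.0390625, tolerance = 1e-9)
  # b = c gives p = 1
  for (k in c(1, 3, 7)) expect_equal(mcnemarExact(k, k), 1)
  # agreement with enumeration
  for (b in 0:6) for (c in 0:6) {
    if (b + c == 0) next
    expect_equal(mcnemarExact(b, c), mcnemarBruteForce(b, c),
                 tolerance = 1e-9)
  }
})

test_that("Pearson r handles exact and sampled relationships", {
  x <- 1:10
  expect_equal(pearsonR(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonR(x, -x)$r, -1)
  expect_error(pearsonR(x, rep(1, 10)), "variance")
  expect_error(pearsonR(1:2, 1:2), "3 complete")
  # bivariate normal rho = 0.59, n = 19 (the PWV-age analysis shape)
  set.seed(42)
  rhat <- vapply(1:1000, function(i) {
    x <- rnorm(19)
    y <- 0.59 * x + sqrt(1 - 0.59^2) * rnorm(19)
    pearsonR(x, y)$r
  }, 1)
  expect_lt(abs(mean(rhat) - 0.59), 0.05)
})

test_that("ICC(2,1) absolute agreement matches its constructions", {
  set.seed(8)
  s <- rnorm(30, 10, 1)
  # duplicated ratings: exactly 1
  r1 <- iccAbsoluteAgreement(cbind(s, s))
  expect_equal(r1$icc, 1)
  # large independent noise: near 0
  r2 <- iccAbsoluteAgreement(cbind(s, s + rnorm(30, 0, 10)))
  expect_lt(r2$icc, 0.2)
  # subject SD 1, error SD 0.17: ICC ~ 1 / (1 + 0.17^2)
  set.seed(9)
  subj <- rnorm(200, 0, 1)
  ratings <- cbind(subj + rnorm(200, 0, 0.17), subj + rnorm(200, 0, 0.17))
  r3 <- iccAbsoluteAgreement(ratings)
  expect_lt(abs(r3$icc - 1 / (1 + 0.17^2)), 0.01)
  expect_true(r3$ci[1] < r3$icc && r3$icc < r3$ci[2])
  # absolute agreement: a constant offset on ONE rater lowers the ICC
  r4 <- iccAbsoluteAgreement(cbind(subj, subj + 0.5))
  expect_lt(r4$icc, 1)
  r5 <- iccAbsoluteAgreement(cbind(subj, subj + 1.5))
  expect_lt(r5$icc, r4$icc)
  expect_error(iccAbsoluteAgreement(cbind(rep(1, 10), rep(1, 10))),
               "between-subject")
})

test_that("paired t keeps its nominal type-I error", {
  set.seed(2024)
  p <- vapply(1:2000, function(i) {
    x <- rnorm(20); y <- x + rnorm(20)
    pairedT(x, y)$p
  }, 1)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("report cells format as printed", {
  expect_identical(formatCount(12, 26), "12 (46%)")
  expect_identical(formatCount(20, 20), "20 (100%)")
  expect_identical(formatCount(0, 26), "0 (0%)")
  expect_identical(formatP(0.0004), "<0.001")
  expect_identical(formatP(NA_real_), "NA")
  expect_identical(formatP(0.4534), "0.453")
  expect_identical(formatMeanSD(c(1, 2, 3), 1), "2.0 ± 1.0")
})
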