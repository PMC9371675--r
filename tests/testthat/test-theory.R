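test_that("the resistance sigmoid and its contour invert each other", {
  expect_equal(pResistance(0, 1e4), 0)
  expect_equal(pResistance(1e4, 1e4), 1 - exp(-1))
  expect_equal(pResistance(1e4 * log(20), 1e4), 0.95)
  expect_equal(contourN(0.05, 1e5), 1e5 * log(20 / 19))
  expect_equal(contourN(1 - exp(-1), 123), 123)
  expect_equal(pResistance(contourN(0.37, 777), 777), 0.37)
  expect_error(pResistance(10, 0), "positive")
  expect_error(contourN(1.2, 10), "strictly in")
})

test_that("critical population sizes evaluate the closed forms", {
  consts <- theoryConstants()
  p1 <- driveParams(m = 1, K = 1, beta = 1, sigma = 0.01)
  expect_equal(criticalNNhej(p1, consts), 1 / (4 * 0.2 * 0.0475),
               tolerance = 1e-12)
  # population-level NHEJ rate at N = N*_n is 1 / (2 gammaN) = 2.5
  for (m in 1:4) {
    pm <- driveParams(m = m, K = 1, beta = 0.37, sigma = 0.01)
    rate <- 0.95 * 0.05 * 0.37
    expect_equal(2 * criticalNNhej(pm, consts) * rate^m, 2.5)
  }
  # de novo population-level rates 1 / (2 gammaM) = {0.658, 0.083, 0.009}
  got <- sapply(1:3, function(m) {
    pm <- driveParams(m = m, K = 1, xi = 1)
    2 * criticalNDenovo(pm, consts) * (5.4e-8)^m
  })
  expect_equal(got, 1 / (2 * c(0.76, 6, 55)))
  expect_equal(round(got, 3), c(0.658, 0.083, 0.009))
  # gammaM from sB tau^m reproduces the fitted table within 10%
  sb <- consts@sBDenovo; tau <- consts@tau
  expect_equal(sb * tau^(1:3), c(0.76, 6, 55), tolerance = 0.1)
  # zero rates give infinite critical sizes
  expect_equal(criticalNNhej(driveParams(m = 1, K = 1, beta = 0)), Inf)
  expect_equal(criticalNDenovo(driveParams(m = 1, K = 1, xi = 0)), Inf)
})

test_that("standing-variation critical size matches direct evaluation", {
  consts <- theoryConstants()
  # m = 1 single-site soft-sweep form
  p1 <- driveParams(m = 1, K = 1, xi = 1, sigma = 1e-4)
  expect_equal(criticalNStanding(p1, consts),
               1 / (4 * 5.4e-8 * log(1 + 0.5 / 1e-4)))
  # m = 2 at sigma = 1e-4: about 2.7e8
  p2 <- driveParams(m = 2, K = 1, xi = 1, sigma = 1e-4)
  expect_equal(criticalNStanding(p2, consts), 2.74e8, tolerance = 0.01)
  # exact power-law scaling in sigma once the log factor is divided out
  for (m in 2:3) {
    r <- sapply(c(1e-4, 1e-3), function(sg)
      criticalNStanding(driveParams(m = m, K = 1, xi = 1, sigma = sg),
                        consts) * log(1 + 0.5 / (m * sg)))
    expect_equal(log10(r[2] / r[1]), m - 1, tolerance = 1e-10)
  }
  expect_error(criticalNStanding(driveParams(m = 1, K = 1, sigma = 0)),
               "sigma > 0")
})

test_that("combined critical size is the harmonic combination", {
  consts <- theoryConstants()
  set.seed(501)
  for (rep in 1:20) {
    p <- driveParams(m = sample(1:3, 1), K = 1,
                     beta = 10^stats::runif(1, -4, 0), xi = 1,
                     sigma = 10^stats::runif(1, -6, -2))
    nn <- criticalNNhej(p, consts)
    ns <- criticalNStanding(p, consts)
    nc <- criticalNCombined(p, consts)
    expect_equal(1 / nc, 1 / nn + 1 / ns)
    expect_lte(nc, min(nn, ns))
  }
  # beta -> 0 limit: the standing-variation route dominates
  p0 <- driveParams(m = 2, K = 1, beta = 0, xi = 1, sigma = 1e-4)
  expect_equal(criticalNCombined(p0, consts),
               criticalNStanding(p0, consts))
})

test_that("minimal gRNA numbers reproduce the published scenarios", {
  consts <- theoryConstants()
  pb <- function(beta) driveParams(m = 1, K = 1, beta = beta)
  expect_equal(as.integer(minGuidesNhej(1e6, 0.05, pb(1), consts)), 6L)
  expect_equal(as.integer(minGuidesNhej(1e6, 0.05, pb(0.01), consts)), 3L)
  expect_equal(sapply(c(1, 0.01, 1e-4), function(b)
    as.integer(minGuidesNhej(1e9, 0.05, pb(b), consts))), c(8L, 4L, 2L))
  ps <- function(sg) driveParams(m = 1, K = 1, xi = 1, sigma = sg)
  expect_equal(as.integer(minGuidesStanding(1e6, 0.05, ps(1e-6), consts)),
               4L)
  expect_equal(as.integer(minGuidesStanding(1e6, 0.05, ps(1e-4), consts)),
               2L)
  expect_equal(sapply(c(1e-6, 1e-4, 1e-2), function(sg)
    as.integer(minGuidesStanding(1e9, 0.05, ps(sg), consts))),
    c(7L, 3L, 2L))
})

test_that("closed forms agree with brute-force minimal-m search", {
  consts <- theoryConstants()
  for (N in c(1e3, 1e6, 1e9, 1e12)) {
    for (beta in c(1, 1e-2, 1e-4)) {
      p <- driveParams(m = 1, K = 1, beta = beta)
      g <- minGuidesNhej(N, 0.05, p, consts)
      expect_equal(attr(g, "closedForm"), as.integer(g))
    }
    for (sg in c(1e-6, 1e-4, 1e-2)) for (xi in c(1, 0.01)) {
      p <- driveParams(m = 1, K = 1, xi = xi, sigma = sg)
      g <- minGuidesStanding(N, 0.05, p, consts)
      cf <- attr(g, "closedForm")
      if (!is.na(cf))  # Lambert approximation: within boundary rounding
        expect_lte(abs(cf - as.integer(g)), 1)
    }
  }
})

test_that("amplification ratio matches the published values", {
  consts <- theoryConstants()
  expect_equal(sapply(1:3, amplificationRatio, sigma = 0.01),
               c(5, 217, 6266), tolerance = 0.04)
  expect_equal(sapply(1:3, amplificationRatio, sigma = 1e-4),
               c(11, 5.2e4, 1.6e8), tolerance = 0.04)
  # m = 1 has no sigma power law, only the logarithm
  expect_equal(amplificationRatio(1, 0.01, consts),
               log(1 + 0.5 / 0.01) / 0.76)
  # monotone decreasing in sigma for m >= 2
  for (m in 2:3) {
    v <- sapply(c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2), amplificationRatio,
                m = m)
    expect_true(all(diff(v) < 0))
  }
})

test_that("sigmoid fitting recovers a known critical size", {
  set.seed(502)
  NStar <- 1e5
  N <- round(10^seq(4.3, 5.8, length.out = 8))
  n <- 500
  k <- stats::rbinom(length(N), n, pResistance(N, NStar))
  fit <- fitSigmoid(data.frame(N = N, nResistance = k, nReps = n))
  expect_equal(fit@NStar, NStar, tolerance = 0.1)
  expect_true(fit@ci[1] < NStar && NStar < fit@ci[2])
  expect_equal(fit@boundary, "none")
  # single N observed exactly at p = 1 - e^-1 inverts to N* = N
  f1 <- fitSigmoid(data.frame(N = 1234, nResistance = 632, nReps = 1000))
  expect_equal(f1@NStar, 1234, tolerance = 0.01)
  # all-zero outcomes only bound N* from below
  f0 <- fitSigmoid(data.frame(N = c(100, 200), nResistance = c(0, 0),
                              nReps = c(50, 50)))
  expect_equal(f0@boundary, "upper")
  expect_error(fitSigmoid(data.frame(N = 1)), "columns")
})

test_that("implied fit constants invert the critical-size forms", {
  consts <- theoryConstants()
  p <- driveParams(m = 2, K = 1, beta = 0.01, xi = 1)
  expect_equal(impliedGamma(criticalNNhej(p, consts), p, "nhej"), 0.2)
  expect_equal(impliedGamma(criticalNDenovo(p, consts), p, "denovo"), 6)
})
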