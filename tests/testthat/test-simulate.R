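test_that("burn-in without mutation leaves the population wild type", {
  set.seed(601)
  p <- driveParams(m = 1, K = 500, mu = 0, sigma = 0.05, burnIn = TRUE)
  s <- burnIn(p)
  f <- haplotypeFrequencies(s)
  expect_equal(unname(f["W"]), 1)
  expect_equal(s@generation, 0L)
  expect_error(burnIn(driveParams(m = 1, K = 100, sigma = 0)),
               "sigma > 0")
})

test_that("burn-in equilibrium matches the model's diffusion prediction", {
  # Mutation-selection-drift balance for the R haplotype at m = 1.
  # Selection acts on female survival only, so an autosomal R allele
  # experiences an effective per-generation cost of sigma / 2 (males
  # shelter half the copies). The stationary frequency distribution is
  # then Gamma(shape = 4 N xi mu, rate = 4 N sigma / 2): mean
  # 2 xi mu / sigma. The effective relaxation time is 2 / sigma, so run
  # 10 / sigma generations (five relaxation times) from wild type.
  set.seed(602)
  p <- driveParams(m = 1, K = 1e7, xi = 1, sigma = 0.01,
                   burnIn = TRUE, burnInMultiplier = 10)
  nRep <- 100
  fr <- vapply(seq_len(nRep), function(r) {
    set.seed(deriveSeed(602, 1, r))
    unname(haplotypeFrequencies(burnIn(p))["R"])
  }, numeric(1))
  theta <- 4 * p@K * p@xi * p@mu     # 2.16
  rateEff <- 2 * p@K * p@sigma       # sex-limited selection: 2 N sigma
  meanPred <- theta / rateEff        # = 2 xi mu / sigma
  se <- sqrt(theta) / rateEff / sqrt(nRep)
  expect_lt(abs(mean(fr) - meanPred), 3.5 * se)
  ks <- suppressWarnings(
    stats::ks.test(fr, stats::pgamma, shape = theta, rate = rateEff))
  expect_gt(ks$p.value, 0.01)
})

test_that("drive release converts the requested male allele fraction", {
  p <- driveParams(m = 1, K = 1e4, releaseFreq = 0.1)
  s <- introduceDrive(wildTypeState(p), p)
  geno <- enumerateGenotypes(1)
  maleChrom <- 2 * sum(s@counts["male", ])
  dd <- which(geno$label == "D/D")
  expect_equal(2 * s@counts["male", dd] / maleChrom, 0.1, tolerance = 1e-3,
               ignore_attr = TRUE)
  # all released drive is carried by D/D males; females untouched
  expect_equal(sum(s@counts["female", -1]), 0)
  expect_equal(sum(s@counts), 1e4)
  # releaseFreq = 0 leaves the state unchanged
  p0 <- driveParams(m = 1, K = 1e4, releaseFreq = 0)
  s0 <- wildTypeState(p0)
  expect_identical(introduceDrive(s0, p0)@counts, s0@counts)
  # release samples proportionally across male genotypes
  p2 <- driveParams(m = 1, K = 1e4, releaseFreq = 0.5)
  sv <- wildTypeState(p2)
  sv@counts["male", ] <- 0
  sv@counts["male", c(1, 2)] <- c(3000, 2000)  # W/W and W/R males
  sr <- introduceDrive(sv, p2)
  expect_equal(unname(sr@counts["male", dd]), 2500)
  expect_equal(unname(sr@counts["male", c(1, 2)]), c(1500, 1000))
  expect_error(driveParams(m = 1, K = 10, releaseFreq = 1), "releaseFreq")
})

test_that("no functional-resistance source means no resistance outcome", {
  # beta = 0 and mu = 0: R alleles can never arise
  p <- driveParams(m = 1, K = 500, beta = 0, mu = 0, sigma = 0.01)
  for (seed in 1:5) {
    o <- runReplicate(p, seed = seed)
    expect_true(o@outcome %in% c("elimination", "censored"))
    expect_equal(unname(o@finalFreqs["R"]), 0)
  }
})

test_that("resistance fraction is near one far above N* and near zero far below", {
  p <- driveParams(m = 1, K = 1, beta = 0.01, mu = 0, sigma = 0.01)
  # N*_n = 2632; N = 1e5 gives p = 1 - exp(-38), N = 100 gives p = 0.037
  hi <- resistanceProbability(p, 1e5, nReps = 40, baseSeed = 603)
  expect_gte(hi$pHat, 0.95)
  lo <- resistanceProbability(p, 100, nReps = 40, baseSeed = 604)
  expect_lt(lo$pHat, 0.2)
})

test_that("replicate batches are deterministic given the base seed", {
  p <- driveParams(m = 1, K = 1000, beta = 0.01, mu = 0, sigma = 0.01)
  a <- resistanceProbability(p, c(500, 1000), nReps = 3, baseSeed = 11)
  b <- resistanceProbability(p, c(500, 1000), nReps = 3, baseSeed = 11)
  expect_identical(attr(a, "outcomes"), attr(b, "outcomes"))
  c2 <- resistanceProbability(p, c(500, 1000), nReps = 3, baseSeed = 12)
  expect_false(identical(attr(a, "outcomes")$seed,
                         attr(c2, "outcomes")$seed))
  # n_reps = 1 gives a degenerate estimate
  one <- resistanceProbability(p, 1000, nReps = 1, baseSeed = 5)
  expect_true(one$pHat %in% c(0, 1))
})

test_that("trajectories record the sweep and the rescue", {
  p <- driveParams(m = 1, K = 1e5, beta = 0.01, mu = 0, sigma = 0.01)
  o <- runReplicate(p, seed = 7, keepTrajectory = TRUE)
  expect_equal(o@outcome, "resistance")
  tr <- o@trajectory
  expect_true(all(c("generation", "total", "resistantFreq", "D")
                  %in% colnames(tr)))
  # drive rises above its release frequency before resistance fixes
  expect_gt(max(tr[, "D"]), 0.3)
  # resistant frequency is non-decreasing to threshold at the end
  expect_gte(tr[nrow(tr), "resistantFreq"], p@resistanceThreshold)
  # population dips well below K during the sweep
  expect_lt(min(tr[, "total"]), 0.8 * p@K)
})

test_that("conditional resistance time is consistent across the grid", {
  # Well above N* the wait for establishment is negligible (many R
  # copies arise during the sweep), so the conditional time to the 0.95
  # criterion is set by the drive sweep plus the R-vs-D replacement and
  # is nearly flat in N and beta; every grid cell sits in the same
  # 45-65 generation band.
  grid <- list(list(N = 3e4, beta = 0.01), list(N = 3e6, beta = 0.01),
               list(N = 3e6, beta = 1))
  for (k in seq_along(grid)) {
    p <- driveParams(m = 1, K = 1, beta = grid[[k]]$beta, mu = 0,
                     sigma = 0.01)
    tt <- resistanceTimes(
      resistanceProbability(p, grid[[k]]$N, nReps = 40,
                            baseSeed = 605 + k))
    expect_gt(length(tt), 30)
    expect_gte(mean(tt), 45)
    expect_lte(mean(tt), 65)
  }
})

test_that("pre-release one-short haplotype frequency has the balance scale", {
  # m = 2: haplotypes one R short of full resistance (WR) segregate at
  # a frequency of order 2 * (xi mu / sigma_eff) before release
  set.seed(608)
  p <- driveParams(m = 2, K = 1e7, xi = 1, sigma = 0.01,
                   burnIn = TRUE, burnInMultiplier = 5)
  fr <- vapply(1:15, function(r) {
    set.seed(deriveSeed(608, 1, r))
    unname(haplotypeFrequencies(burnIn(p))["WR"])
  }, numeric(1))
  pred <- 2 * (p@xi * p@mu) / (p@sigma / 2)
  ratio <- mean(fr) / pred
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 10)
})
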