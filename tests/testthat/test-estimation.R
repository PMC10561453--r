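test_that("perfect genotype separation yields heritability one", {
  # constant within genotype, distinct between: all variance is genetic
  y <- rep(c(1, 2, 5), each = 4)
  at <- AbundanceTable(matrix(y, 1), genotype = rep(c("a", "b", "c"), each = 4))
  expect_warning(fit <- fitVarianceComponents(at, 1, method = "anova"),
                 "zero residual")
  expect_equal(fit$h2_hat, 1)
  expect_equal(fit$v_e_hat, 0)
})

test_that("anova and REML agree on balanced data; LRT matches lme4 ML", {
  cp <- correlatedPair(h2 = 0.4, rG = 0.2, rE = 0.1)
  for (seed in c(11, 12, 13)) {
    at <- toRelative(simulatePopulation(cp, 40, 8, seed = seed))
    anv <- fitVarianceComponents(at, 1, method = "anova")
    reml <- fitVarianceComponents(at, 1, method = "reml")
    if (anv$v_g_hat > 0)  # interior optimum: estimators coincide
      expect_lt(abs(anv$h2_hat - reml$h2_hat), 1e-6)
    # independent ML route for the LRT statistic
    y <- abundances(at)[1, ]
    g <- factor(genotypes(at))
    full <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | g), REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))
    lrtOracle <- max(0, 2 * (as.numeric(logLik(full)) -
                               as.numeric(logLik(lm(y ~ 1)))))
    expect_equal(unname(lrtGenotypeEffect(at, 1)["lrt_stat"]), lrtOracle,
                 tolerance = 1e-6)
  }
})

test_that("unbalanced designs require REML and are fit consistently", {
  set.seed(21)
  g <- rep(c("a", "b", "c", "d"), times = c(3, 5, 7, 9))
  y <- rnorm(length(g), mean = rep(c(0, 1, 2, 3), times = c(3, 5, 7, 9)),
             sd = 0.5)
  at <- AbundanceTable(matrix(y, 1), genotype = g)
  expect_error(fitVarianceComponents(at, 1, method = "anova"), "reml")
  fit <- fitVarianceComponents(at, 1, method = "reml")
  expect_gt(fit$h2_hat, 0.5)
  expect_lt(fit$p, 0.01)
})

test_that("permuting genotype labels destroys the heritability estimate", {
  cp <- correlatedPair(h2 = 0.6)
  at <- simulatePopulation(cp, 100, 50, seed = 99)
  y <- abundances(at)[1, , drop = FALSE]
  set.seed(100)
  h2perm <- vapply(1:200, function(k) {
    perm <- AbundanceTable(y, genotype = sample(genotypes(at)))
    fitVarianceComponents(perm, 1, method = "anova")$h2_hat
  }, numeric(1))
  expect_lt(mean(h2perm), 0.02)
})

test_that("LRT is location invariant and explodes under strong signal", {
  cp <- correlatedPair(h2 = 0.5)
  at <- simulatePopulation(cp, 30, 10, seed = 17)
  base <- lrtGenotypeEffect(at, 1)
  shifted <- AbundanceTable(abundances(at) + 50, genotype = genotypes(at))
  expect_equal(unname(lrtGenotypeEffect(shifted, 1)["lrt_stat"]),
               unname(base["lrt_stat"]), tolerance = 1e-8)

  # genotype effect inflated far beyond the residual scale
  gm <- as.numeric(factor(genotypes(at))) * 100
  loud <- AbundanceTable(sweep(abundances(at), 2, gm, `+`),
                         genotype = genotypes(at))
  res <- lrtGenotypeEffect(loud, 1)
  expect_gt(res["lrt_stat"], 100)
  expect_lt(res["p_value"], 1e-10)
})

test_that("the chi-squared(1) reference is conservative under the null", {
  # single taxon, no genetic variance, no background: a true null
  cp <- CommunityParams(alpha = 1, vG = 0, vE = (1 / 6)^2)
  set.seed(55)
  rej <- vapply(1:1000, function(k) {
    sim <- simulatePopulation(cp, 25, 5)
    unname(lrtGenotypeEffect(sim, 1)["p_value"]) < 0.05
  }, logical(1))
  rate <- mean(rej)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
  # boundary mixture rejects even less often than alpha/2-ish inflation
  expect_gt(rate, 0)
})

test_that("estimates on absolute data are nearly unbiased across h2 values", {
  for (h2 in c(0, 0.25, 0.5, 0.75, 1)) {
    cp <- CommunityParams(alpha = c(1, 1), vG = c(h2, 0.3) * (1 / 6)^2,
                          vE = c(1 - h2, 0.7) * (1 / 6)^2)
    est <- vapply(1:10, function(k)
      suppressWarnings(  # h2 = 1 draws have exactly zero residual variance
        fitVarianceComponents(simulatePopulation(cp, 150, 20,
                                                 seed = 1000 * h2 + k),
                              1, method = "anova")$h2_hat), numeric(1))
    expect_lt(abs(mean(est) - h2), 0.02)
  }
})

test_that("mixed-model estimates on relative data track analytic phi-squared", {
  # the central cross-check: simulation-based estimates against Eq. 9
  scenarios <- list(
    focalBackground(alpha = 5, focalH2 = 0.2, backgroundH2 = 0.8,
                    vP = 5 * (1 / 6)^2),
    focalBackground(alpha = 20, focalH2 = 0.2, backgroundH2 = 0,
                    vP = 20 * (1 / 6)^2),
    correlatedPair(h2 = 0.5, rG = 0.6),
    correlatedPair(h2 = 0.5, rE = 0.6)
  )
  seed <- 300
  for (cp in scenarios) {
    phi <- unname(phiSquared(cp, 1))
    est <- vapply(1:12, function(k) {
      seed <<- seed + 1
      rel <- toRelative(simulatePopulation(cp, 200, 50, seed = seed))
      fitVarianceComponents(rel, 1, method = "anova")$h2_hat
    }, numeric(1))
    mcse <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - phi), 3 * mcse + 0.002)
  }
})

test_that("community scan applies BH step-up adjustment across taxa", {
  cp <- CommunityParams(alpha = rep(1, 6),
                        vG = c(0.5, 0.5, 0, 0, 0, 0) * (1 / 6)^2,
                        vE = c(0.5, 0.5, 1, 1, 1, 1) * (1 / 6)^2)
  rel <- toRelative(simulatePopulation(cp, 60, 10, seed = 71))
  scan <- scanCommunity(rel, alphaLevel = 0.05, adjust = "bh")
  expect_identical(nrow(scan), 6L)
  expect_equal(scan$p_adjusted, p.adjust(scan$p, "BH"))
  expect_true(all(scan$p_adjusted >= scan$p))
  expect_identical(attr(scan, "nSignificant"),
                   sum(scan$p_adjusted < 0.05))
  # step-up definition by hand on a known vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # equal p-values pass through unchanged
  expect_equal(p.adjust(rep(0.2, 5), "BH"), rep(0.2, 5))

  # auto method falls back to REML when unbalanced and flags failures
  # as missing rather than failing the scan
  unb <- AbundanceTable(abundances(rel)[, -1], genotype = genotypes(rel)[-1])
  scanU <- scanCommunity(unb)
  expect_identical(nrow(scanU), 6L)
  expect_true(all(is.finite(scanU$p) | is.na(scanU$p)))
})

test_that("a null community keeps its false-positive rate near alpha", {
  cp <- CommunityParams(alpha = rep(1, 20), vG = 0, vE = (1 / 6)^2)
  at <- simulatePopulation(cp, 50, 10, seed = 123)
  scan <- scanCommunity(at, alphaLevel = 0.05, adjust = "none")
  m <- nrow(scan)
  expect_lte(attr(scan, "nSignificant") / m,
             0.05 + 3 * sqrt(0.05 * 0.95 / m))
})
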