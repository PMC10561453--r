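# Brute-force oracles: explicit loops over the full covariance structure,
# independent of the vectorized implementation they check.

bruteCommunityVariance <- function(alpha, v, corr) {
  v <- unname(v)
  m <- length(alpha)
  total <- sum(v)
  for (j in seq_len(m)) for (k in seq_len(m)) if (j < k)
    total <- total + 2 * corr[j, k] * sqrt(v[j] * v[k])
  total
}

bruteAggregates <- function(cp, i) {
  m <- nTaxa(cp)
  alpha <- meanAbundance(cp); vG <- geneticVariance(cp)
  vE <- environmentalVariance(cp)
  rG <- geneticCorrelation(cp); rE <- environmentalCorrelation(cp)
  bg <- setdiff(seq_len(m), i)
  gamma <- eps <- kappa <- nu <- 0
  for (j in bg) {
    gamma <- gamma + rG[i, j] * sqrt(vG[i] * vG[j])
    eps <- eps + rE[i, j] * sqrt(vE[i] * vE[j])
  }
  for (j in bg) for (k in bg) if (j < k) {
    kappa <- kappa + rG[j, k] * sqrt(vG[j] * vG[k])
    nu <- nu + rE[j, k] * sqrt(vE[j] * vE[k])
  }
  list(A = sum(alpha[bg]), omega = sum(vG[bg]), z = sum(vG[bg] + vE[bg]),
       gamma = unname(gamma), epsilon = unname(eps), kappa = unname(kappa),
       nu = unname(nu))
}

test_that("community moments match explicit covariance summation", {
  v <- 0.04
  cp <- CommunityParams(alpha = c(1, 1), vG = c(v / 2, v / 2),
                        vE = c(v / 2, v / 2))
  mom <- communityMoments(cp, "phenotypic")
  expect_equal(mom$mean, 2)
  expect_equal(mom$variance, 2 * v)

  # perfectly genetically correlated pair: var of sum is 4g
  g <- 0.01
  cp2 <- CommunityParams(alpha = c(1, 1), vG = c(g, g), vE = c(0.01, 0.01),
                         rG = 1)
  expect_equal(communityMoments(cp2, "genetic")$variance, 4 * g)

  set.seed(31)
  m <- 100
  cp3 <- CommunityParams(alpha = runif(m, 0.5, 2), vG = runif(m, 0, 0.03),
                         vE = runif(m, 0.01, 0.03), rG = 0.3, rE = 0.3)
  for (component in c("phenotypic", "genetic")) {
    vv <- if (component == "genetic") geneticVariance(cp3)
          else phenotypicVariance(cp3)
    corr <- if (component == "genetic") geneticCorrelation(cp3) else NULL
    expected <- if (component == "genetic")
      bruteCommunityVariance(meanAbundance(cp3), vv, corr)
    else  # phenotypic covariance = genetic + environmental covariance
      bruteCommunityVariance(meanAbundance(cp3), geneticVariance(cp3),
                             geneticCorrelation(cp3)) +
      bruteCommunityVariance(meanAbundance(cp3), environmentalVariance(cp3),
                             environmentalCorrelation(cp3)) -
      sum(geneticVariance(cp3)) - sum(environmentalVariance(cp3)) +
      sum(phenotypicVariance(cp3))
    expect_equal(communityMoments(cp3, component)$variance, expected,
                 tolerance = 1e-12)
  }
})

test_that("background aggregates match brute-force pair sums", {
  # no correlations: all cross terms vanish
  cp <- CommunityParams(alpha = c(1, 2, 3), vG = c(0.1, 0.2, 0.3),
                        vE = 0.1)
  ag <- backgroundAggregates(cp, 2)
  expect_equal(ag[c("gamma", "epsilon", "kappa", "nu")],
               list(gamma = 0, epsilon = 0, kappa = 0, nu = 0))
  expect_equal(ag$A, 4)
  expect_equal(ag$omega, 0.4)

  # two taxa: no background pairs, kappa must be 0 even at rG = 1
  g <- 0.02
  cp2 <- CommunityParams(alpha = c(1, 1), vG = c(g, g), vE = 0.01, rG = 1)
  ag2 <- backgroundAggregates(cp2, 1)
  expect_equal(ag2$gamma, g)
  expect_equal(ag2$kappa, 0)

  # equicorrelated five-taxon community vs explicit loops
  set.seed(7)
  cp3 <- CommunityParams(alpha = runif(5, 0.5, 2), vG = runif(5, 0, 0.05),
                         vE = runif(5, 0.01, 0.05), rG = 0.5, rE = 0.2)
  for (i in 1:5) {
    got <- backgroundAggregates(cp3, i)
    expect_equal(got[c("A", "omega", "z", "gamma", "epsilon", "kappa", "nu")],
                 bruteAggregates(cp3, i), tolerance = 1e-12)
  }

  expect_error(backgroundAggregates(
    CommunityParams(alpha = 1, vG = 0.1, vE = 0.1), 1), "two taxa")
})

test_that("delta-method ratio variance: closed cases and Monte-Carlo oracle", {
  # X identical to Y: the ratio is constant
  expect_equal(ratioVarianceDelta(2, 0.3, 2, 0.3, 0.3), 0)
  # constant denominator: var(X)/muY^2
  expect_equal(ratioVarianceDelta(1, 0.04, 5, 0, 0), 0.04 / 25)
  expect_error(ratioVarianceDelta(1, 0.1, 0, 0.1, 0), "non-zero")

  # taxon-over-community ratio at the worked parameterization
  muX <- 1; vX <- (1 / 6)^2; muY <- 101; vY <- 101 * (1 / 6)^2; cXY <- (1 / 6)^2
  approx <- ratioVarianceDelta(muX, vX, muY, vY, cXY)
  set.seed(2024)
  n <- 1e6
  z1 <- rnorm(n)
  rho <- cXY / sqrt(vX * vY)
  y <- muY + sqrt(vY) * z1
  x <- muX + sqrt(vX) * (rho * z1 + sqrt(1 - rho^2) * rnorm(n))
  mc <- var(x / y)
  mcSE <- mc * sqrt(2 / n)  # sampling SD of a variance estimate
  expect_lt(abs(approx - mc), 3 * mcSE)
})

test_that("phi-squared reproduces the worked two-taxon and rare-focal cases", {
  # equal abundance, h2 = 1 and h2 = 0: both estimates collapse to 0.5
  expect_equal(unname(phiSquared(twoTaxonProblem1())), c(0.5, 0.5))

  # non-heritable rare focal in a heritable background (V_G = 0 numerator)
  cp <- focalBackground(alpha = 1, focalH2 = 0, backgroundH2 = 0.25)
  expect_equal(unname(phiSquared(cp, "focal")), 25 / 10100,
               tolerance = 1e-12)

  # fully non-heritable community
  cp0 <- CommunityParams(alpha = c(1, 2, 3), vG = 0, vE = 0.01)
  expect_equal(unname(phiSquared(cp0)), c(0, 0, 0))

  # perfect genetic correlation wipes out the genotype-level signal
  expect_equal(unname(phiSquared(correlatedPair(h2 = 0.5, rG = 1))),
               c(0, 0))
  # perfect environmental correlation removes within-genotype variation
  expect_equal(unname(phiSquared(correlatedPair(h2 = 0.5, rE = 1))),
               c(1, 1))
})

test_that("phi-squared equals the ratio of delta-method variances", {
  set.seed(99)
  for (k in 1:20) {
    m <- sample(2:10, 1)
    cp <- CommunityParams(alpha = runif(m, 0.5, 3),
                          vG = runif(m, 0, 0.05), vE = runif(m, 0.01, 0.05),
                          rG = runif(1, -1 / (2 * m), 0.7),
                          rE = runif(1, -1 / (2 * m), 0.7))
    i <- sample(m, 1)
    ag <- backgroundAggregates(cp, i)
    gm <- communityMoments(cp, "genetic")
    pm <- communityMoments(cp, "phenotypic")
    a <- meanAbundance(cp)[[i]]
    vg <- geneticVariance(cp)[[i]]
    vp <- phenotypicVariance(cp)[[i]]
    varFG <- ratioVarianceDelta(a, vg, gm$mean, gm$variance, vg + ag$gamma)
    varFP <- ratioVarianceDelta(a, vp, pm$mean, pm$variance,
                                vp + ag$gamma + ag$epsilon)
    expect_equal(unname(phiSquared(cp, i)), varFG / varFP,
                 tolerance = 1e-12)
  }
})

test_that("phi-squared stays in [0, 1] for any valid correlation structure", {
  # both numerator and denominator of the approximation are second-order
  # delta variances, nonnegative whenever the pairwise correlations are
  # bounded by one, so the ratio cannot leave [0, 1] (up to rounding)
  set.seed(404)
  for (k in 1:50) {
    m <- sample(2:8, 1)
    cp <- CommunityParams(alpha = runif(m, 0.2, 5),
                          vG = runif(m, 0, 0.1), vE = runif(m, 0.001, 0.1),
                          rG = runif(1, -1 / m, 0.95),
                          rE = runif(1, -1 / m, 0.95))
    ph <- suppressWarnings(phiSquared(cp))  # rounding can graze 1 + eps
    expect_true(all(ph >= -1e-12 & ph <= 1 + 1e-12))
  }
  # extreme antagonistic/mutualistic mix still lands on the boundary
  v <- 0.02
  cp <- CommunityParams(alpha = c(1, 1), vG = c(v / 2, v / 2),
                        vE = c(v / 2, v / 2), rG = -1, rE = 1)
  expect_equal(unname(suppressWarnings(phiSquared(cp, 1))), 1)
})

test_that("degenerate covariance structures raise an informative error", {
  # identical fully correlated taxa: relative abundances are constant
  v <- 0.02
  cp <- CommunityParams(alpha = c(1, 1), vG = c(v / 2, v / 2),
                        vE = c(v / 2, v / 2), rG = 1, rE = 1)
  expect_error(phiSquared(cp, 1), "degenerate")
})

test_that("rare and dominant limits bracket the approximation", {
  cp <- focalBackground(alpha = 1, focalH2 = 0.2, backgroundH2 = 0.6)
  lim <- phiLimits(cp, "focal")
  expect_equal(unname(lim), c(0.2, 0.6))

  # numerical convergence of the full expression to both limits
  rare <- focalBackground(alpha = 1e-6 * 100, focalH2 = 0.2,
                          backgroundH2 = 0.6, vP = 1e-6 * (1 / 6)^2)
  expect_lt(abs(phiSquared(rare, "focal") - 0.2), 1e-3)
  dominant <- focalBackground(alpha = 1e6 * 100, focalH2 = 0.2,
                              backgroundH2 = 0.6, vP = 1e6 * (1 / 6)^2)
  expect_lt(abs(phiSquared(dominant, "focal") - 0.6), 1e-3)
})

test_that("the compositional error vanishes as the focal taxon becomes rare", {
  # focal h2 0.2, V_P proportional to alpha, heritable background
  alphas <- 100 / 10^(1:6)
  err <- vapply(alphas, function(a) {
    cp <- focalBackground(alpha = a, focalH2 = 0.2, backgroundH2 = 0.8,
                          vP = a * (1 / 6)^2)
    abs(phiSquared(cp, "focal") - 0.2)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[length(err)], 1e-6)
})
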