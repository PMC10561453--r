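#' Monte-Carlo power curve for the genotype likelihood-ratio test
#'
#' For each total sample size, repeatedly simulates a host population from
#' \code{params}, closes it to relative abundances, applies the genotype
#' likelihood-ratio test to the focal taxon and records the fraction of
#' simulations rejecting at \code{alphaLevel}. When the focal taxon has no
#' genetic variance this fraction is the probability that a non-heritable
#' microbe wrongly appears heritable — which grows with sample size
#' whenever the background community is heritable, because the relative
#' abundance of the focal taxon then genuinely carries a genetic signal.
#'
#' @param params a \linkS4class{CommunityParams} object.
#' @param focal focal taxon index or name.
#' @param sampleSizes total host counts, each divisible by
#'   \code{replicatesPerGenotype}.
#' @param replicatesPerGenotype replicate hosts per genotype.
#' @param nSim Monte-Carlo replicates per sample size.
#' @param alphaLevel rejection threshold for the LRT p-value.
#' @param seed integer seed.
#' @param scenarioTag label copied into the output, for assembling multi-
#'   scenario tables.
#' @return \code{data.frame} with columns \code{sample_size},
#'   \code{rejection_rate}, \code{mc_se} (binomial standard error
#'   \eqn{\sqrt{p(1-p)/n_{sim}}}) and \code{scenario_tag}.
#' @export
powerCurve <- function(params, focal, sampleSizes,
                       replicatesPerGenotype = 10, nSim = 200,
                       alphaLevel = 0.05, seed = NULL, scenarioTag = "") {
  stopifnot(nSim >= 1)
  if (any(sampleSizes %% replicatesPerGenotype != 0))
    stop("every sample size must be divisible by replicatesPerGenotype")
  i <- .resolveTaxon(params, focal)
  .withSeed(seed, {
    rows <- lapply(sampleSizes, function(n) {
      nGen <- n / replicatesPerGenotype
      rej <- vapply(seq_len(nSim), function(s) {
        sim <- .simulateMatrix(params, nGen, replicatesPerGenotype)
        rel <- sweep(sim$mat, 2, colSums(sim$mat), `/`)
        ss <- .balancedSS(rel[i, , drop = FALSE], factor(sim$genotype))
        .lrtP(.mlLRTBalanced(ss)) < alphaLevel
      }, logical(1))
      p <- mean(rej)
      data.frame(sample_size = n, rejection_rate = p,
                 mc_se = sqrt(p * (1 - p) / nSim), scenario_tag = scenarioTag)
    })
    do.call(rbind, rows)
  })
}

#' Community-scale false-discovery experiment
#'
#' Simulates full communities in which only the taxa flagged by
#' \code{heritableTaxa} carry genetic variance, scans every taxon with the
#' genotype LRT, applies Benjamini-Hochberg adjustment across taxa, and
#' reports — per sample size, averaged over simulations — the proportion of
#' taxa called significant, split into true positives (among heritable
#' taxa) and false positives (among taxa with zero genetic variance).
#' Because the relative abundances of non-heritable taxa genuinely carry
#' the community's genetic signal, the called proportion rises with sample
#' size and eventually overshoots the true heritable proportion; this is
#' not a multiple-testing artefact and BH cannot remove it.
#'
#' @param params a \linkS4class{CommunityParams} object.
#' @param heritableTaxa logical mask (length M) marking taxa with true
#'   genetic variance; defaults to \code{geneticVariance(params) > 0}.
#' @param sampleSizes total host counts.
#' @param replicatesPerGenotype replicate hosts per genotype.
#' @param nSim Monte-Carlo replicates per sample size.
#' @param alphaLevel significance threshold on BH-adjusted p-values.
#' @param seed integer seed.
#' @return \code{data.frame} with columns \code{sample_size},
#'   \code{prop_significant}, \code{true_positive_rate},
#'   \code{false_positive_rate}, \code{mc_se} (standard error of
#'   \code{prop_significant} over simulations) and \code{true_proportion}.
#' @export
communityFalseDiscovery <- function(params, heritableTaxa = NULL,
                                    sampleSizes, replicatesPerGenotype = 10,
                                    nSim = 100, alphaLevel = 0.05,
                                    seed = NULL) {
  m <- nTaxa(params)
  if (is.null(heritableTaxa)) heritableTaxa <- geneticVariance(params) > 0
  stopifnot(length(heritableTaxa) == m)
  if (any(sampleSizes %% replicatesPerGenotype != 0))
    stop("every sample size must be divisible by replicatesPerGenotype")
  if (any(heritableTaxa != (geneticVariance(params) > 0)))
    warning("heritableTaxa mask disagrees with geneticVariance(params) > 0")
  .withSeed(seed, {
    rows <- lapply(sampleSizes, function(n) {
      nGen <- n / replicatesPerGenotype
      props <- matrix(NA_real_, nSim, 3)
      for (s in seq_len(nSim)) {
        sim <- .simulateMatrix(params, nGen, replicatesPerGenotype)
        rel <- sweep(sim$mat, 2, colSums(sim$mat), `/`)
        ss <- .balancedSS(rel, factor(sim$genotype))
        p <- .lrtP(.mlLRTBalanced(ss))
        sig <- p.adjust(p, "BH") < alphaLevel
        props[s, ] <- c(mean(sig), mean(sig[heritableTaxa]),
                        mean(sig[!heritableTaxa]))
      }
      data.frame(sample_size = n,
                 prop_significant = mean(props[, 1]),
                 true_positive_rate = mean(props[, 2]),
                 false_positive_rate = mean(props[, 3]),
                 mc_se = sd(props[, 1]) / sqrt(nSim),
                 true_proportion = mean(heritableTaxa))
    })
    do.call(rbind, rows)
  })
}
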