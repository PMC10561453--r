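# Shared scenario builders. Communities follow the convention used across
# the analyses: per-taxon coefficient of variation sigma/mu = 1/6 unless a
# scenario states otherwise.

# Two equally abundant taxa, one fully heritable, one not (the canonical
# interdependency example).
twoTaxonProblem1 <- function(v = (1 / 6)^2) {
  CommunityParams(alpha = c(1, 1), vG = c(v, 0), vE = c(0, v),
                  taxa = c("heritable", "nonheritable"))
}

# Focal taxon plus an aggregated background taxon. The focal taxon's
# relative abundance only depends on the background through its summed
# mean (A), genetic variance (omega) and phenotypic variance (z), so a
# single background taxon with those totals is an exact stand-in for a
# many-taxon uncorrelated background.
focalBackground <- function(alpha = 1, focalH2 = 0, backgroundH2 = 0,
                            A = 100, z = 100 * (1 / 6)^2,
                            vP = (1 / 6)^2) {
  CommunityParams(
    alpha = c(alpha, A),
    vG = c(focalH2 * vP, backgroundH2 * z),
    vE = c((1 - focalH2) * vP, (1 - backgroundH2) * z),
    taxa = c("focal", "background")
  )
}

# Two correlated taxa with equal means and variances (the co-abundance
# examples).
correlatedPair <- function(h2 = 0.5, rG = 0, rE = 0, v = (1 / 6)^2) {
  CommunityParams(alpha = c(1, 1), vG = c(h2, h2) * v,
                  vE = c(1 - h2, 1 - h2) * v, rG = rG, rE = rE)
}

# Community for normalization-recovery runs: five taxa spanning a range of
# heritabilities plus a constant reference taxon (no genetic, no
# environmental variance).
recoveryCommunity <- function() {
  a <- rep(10, 5)
  vP <- (a / 6)^2
  h2 <- c(0, 0.2, 0.4, 0.6, 0.8)
  CommunityParams(
    alpha = c(a, 50),
    vG = c(h2 * vP, 0),
    vE = c((1 - h2) * vP, 0),
    taxa = c(paste0("taxon", 1:5), "reference")
  )
}
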