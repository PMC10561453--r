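## ---- closed-form machinery for balanced one-way (genotype) designs ----
##
## For a balanced design with a genotypes and r replicates the Gaussian
## random-intercept model has exact ANOVA/REML estimators and an exact
## profile maximum likelihood, so no iterative fit is needed. These paths
## are cross-checked against lme4 in the test suite.

.designInfo <- function(genotype) {
  g <- factor(genotype)
  counts <- tabulate(g)
  list(g = g, a = nlevels(g), counts = counts,
       balanced = length(unique(counts)) == 1, r = counts[1])
}

## Per-taxon sums of squares for all rows of mat (taxa x hosts) at once.
.balancedSS <- function(mat, g) {
  a <- nlevels(g)
  n <- ncol(mat)
  r <- n / a
  groupMean <- rowsum(t(mat), g) / r            # a x M
  grand <- colMeans(groupMean)
  ssb <- r * colSums(sweep(groupMean, 2, grand)^2)
  ssw <- rowSums(mat^2) - r * colSums(groupMean^2)
  list(ssb = ssb, ssw = pmax(ssw, 0), a = a, r = r, n = n)
}

.anovaComponents <- function(ss) {
  msb <- ss$ssb / (ss$a - 1)
  msw <- ss$ssw / (ss$n - ss$a)
  vG <- pmax((msb - msw) / ss$r, 0)
  list(vG = vG, vE = msw)
}

## Exact ML likelihood-ratio statistic for H0: vG = 0, balanced design.
## Full model: profile over mu (= grand mean), vE and lambda = vE + r*vG
## subject to lambda >= vE; null model: iid Gaussian.
.mlLRTBalanced <- function(ss) {
  n <- ss$n; a <- ss$a
  veHat <- ss$ssw / (n - a)
  lamHat <- ss$ssb / a
  atBoundary <- lamHat <= veHat | veHat == 0
  ve <- ifelse(atBoundary, (ss$ssw + ss$ssb) / n, veHat)
  lam <- ifelse(atBoundary, ve, lamHat)
  logLikFull <- -0.5 * ((n - a) * log(ve) + a * log(lam) +
                          ss$ssw / ve + ss$ssb / lam + n * log(2 * pi))
  s2 <- (ss$ssw + ss$ssb) / n
  logLikNull <- -0.5 * (n * log(s2) + n + n * log(2 * pi))
  pmax(2 * (logLikFull - logLikNull), 0)
}

.lrtP <- function(stat, mixture = FALSE) {
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- ifelse(stat <= 0, 1, 0.5 * p)
  p
}

## Full per-taxon scan on a matrix, closed form (balanced designs only).
.balancedScan <- function(mat, genotype, mixture = FALSE) {
  info <- .designInfo(genotype)
  stopifnot(info$balanced)
  ss <- .balancedSS(mat, info$g)
  vc <- .anovaComponents(ss)
  lrt <- .mlLRTBalanced(ss)
  tot <- vc$vG + vc$vE
  data.frame(
    taxon = rownames(mat) %||% paste0("taxon", seq_len(nrow(mat))),
    v_g_hat = vc$vG, v_e_hat = vc$vE,
    h2_hat = ifelse(tot > 0, vc$vG / tot, NA_real_),
    lrt = lrt, p = .lrtP(lrt, mixture),
    row.names = NULL
  )
}

.taxonVector <- function(x, taxon) {
  a <- abundances(x)
  if (is.character(taxon)) {
    if (!taxon %in% rownames(a)) stop("unknown taxon: ", taxon)
    a[taxon, ]
  } else a[as.integer(taxon), ]
}

## ---- exported estimation surface ----

#' Estimate per-taxon variance components and heritability
#'
#' Fits the one-way random-intercept model
#' \eqn{y_{jk} = \mu + g_j + e_{jk}} to a taxon's abundances with host
#' genotype as the random effect and returns the estimated genetic and
#' residual variances and their ratio, the heritability estimate. On
#' absolute-abundance data this estimates \eqn{h^2}; applied to relative
#' abundances it estimates the compositional analogue \eqn{\varphi^2}.
#'
#' \code{method = "anova"} (balanced designs only) uses the exact
#' mean-square estimator: \eqn{\hat V_G = \max(0, (MSB - MSW)/r)},
#' \eqn{\hat V_E = MSW}. \code{method = "reml"} maximizes the restricted
#' likelihood via \code{lme4::lmer} and also handles unbalanced designs;
#' on balanced data with an interior optimum the two coincide.
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param taxon taxon name or index.
#' @param method \code{"reml"} (default) or \code{"anova"}.
#' @param mixture if \code{TRUE}, the LRT p-value uses the 50:50
#'   chi-squared 0/1 boundary mixture instead of the plain (conservative)
#'   chi-squared with 1 df.
#' @return one-row \code{data.frame} with columns \code{taxon},
#'   \code{v_g_hat}, \code{v_e_hat}, \code{h2_hat}, \code{lrt}, \code{p},
#'   \code{method}.
#' @examples
#' cp <- CommunityParams(alpha = c(1, 1), vG = c(0.5, 0) / 36,
#'                       vE = c(0.5, 1) / 36)
#' at <- simulatePopulation(cp, 50, 10, seed = 1)
#' fitVarianceComponents(at, "taxon1", method = "anova")
#' @export
fitVarianceComponents <- function(x, taxon, method = c("reml", "anova"),
                                  mixture = FALSE) {
  method <- match.arg(method)
  info <- .designInfo(genotypes(x))
  if (info$a < 2) stop("at least two genotypes are required")
  if (max(info$counts) < 2)
    stop("at least one genotype needs replicate hosts")
  y <- .taxonVector(x, taxon)
  taxonId <- if (is.character(taxon)) taxon else rownames(x)[taxon]
  if (method == "anova") {
    if (!info$balanced)
      stop("method = 'anova' requires a balanced design; use method = 'reml'")
    ss <- .balancedSS(matrix(y, 1), info$g)
    vc <- .anovaComponents(ss)
    lrt <- .mlLRTBalanced(ss)
    vG <- vc$vG; vE <- vc$vE
  } else {
    fit <- .remlFit(y, info$g)
    vG <- fit$vG; vE <- fit$vE
    lrt <- .mlLRTGeneral(y, info)
  }
  tot <- vG + vE
  if (tot <= 0) stop("zero total variance: heritability undefined")
  h2 <- vG / tot
  if (vE <= 1e-12 * tot && vG > 0) {
    warning("zero residual variance; heritability estimate is 1")
    h2 <- 1
  }
  data.frame(taxon = taxonId, v_g_hat = unname(vG), v_e_hat = unname(vE),
             h2_hat = unname(h2), lrt = unname(lrt),
             p = .lrtP(lrt, mixture), method = method)
}

.remlFit <- function(y, g) {
  if (sd(y) == 0) return(list(vG = 0, vE = 0))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | g), REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(vG = vc$vcov[vc$grp == "g"], vE = vc$vcov[vc$grp == "Residual"])
}

.mlLRTGeneral <- function(y, info) {
  if (info$balanced)
    return(.mlLRTBalanced(.balancedSS(matrix(y, 1), info$g)))
  full <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ 1 + (1 | g), REML = FALSE, data = list(y = y, g = info$g),
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  ))
  null <- lm(y ~ 1)
  max(2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))), 0)
}

#' Likelihood-ratio test for a host-genotype effect
#'
#' Compares, by maximum likelihood (not REML, so that the two models'
#' likelihoods are comparable), the Gaussian random-intercept model with
#' host genotype against the model without it. The statistic is
#' \eqn{2(\ell_{full} - \ell_{null})}, floored at zero, referred to a
#' chi-squared distribution with 1 df; because the null value of the
#' variance lies on the boundary this reference is conservative, and the
#' 50:50 chi-squared 0/1 mixture is available via \code{mixture = TRUE}.
#'
#' @inheritParams fitVarianceComponents
#' @return named numeric vector \code{c(lrt_stat = , p_value = )}.
#' @export
lrtGenotypeEffect <- function(x, taxon, mixture = FALSE) {
  info <- .designInfo(genotypes(x))
  if (info$a < 2) stop("at least two genotypes are required")
  y <- .taxonVector(x, taxon)
  stat <- .mlLRTGeneral(y, info)
  c(lrt_stat = unname(stat), p_value = unname(.lrtP(stat, mixture)))
}

#' Scan every taxon of a community for heritable variation
#'
#' Per-taxon variance-component fit and genotype likelihood-ratio test,
#' with optional Benjamini-Hochberg step-up adjustment of the p-values
#' across the M taxa. Taxa whose fit fails are kept as rows of missing
#' values rather than failing the scan.
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param alphaLevel significance threshold applied to the (adjusted)
#'   p-values.
#' @param adjust \code{"bh"} (Benjamini-Hochberg, default) or
#'   \code{"none"}.
#' @param method passed to \code{\link{fitVarianceComponents}}; the default
#'   \code{"auto"} uses the exact balanced-design path when the design is
#'   balanced and REML otherwise.
#' @param mixture see \code{\link{fitVarianceComponents}}.
#' @return \code{data.frame} with one row per taxon (columns \code{taxon},
#'   \code{v_g_hat}, \code{v_e_hat}, \code{h2_hat}, \code{lrt}, \code{p},
#'   \code{p_adjusted}, \code{significant}) and attribute
#'   \code{nSignificant}.
#' @export
scanCommunity <- function(x, alphaLevel = 0.05, adjust = c("bh", "none"),
                          method = c("auto", "anova", "reml"),
                          mixture = FALSE) {
  adjust <- match.arg(adjust)
  method <- match.arg(method)
  info <- .designInfo(genotypes(x))
  if (method == "auto") method <- if (info$balanced) "anova" else "reml"
  if (method == "anova") {
    res <- .balancedScan(abundances(x), genotypes(x), mixture)
    tot <- res$v_g_hat + res$v_e_hat
    res$h2_hat[tot <= 0] <- NA_real_
  } else {
    rows <- lapply(seq_len(nrow(x)), function(i) {
      tryCatch(fitVarianceComponents(x, i, method = method,
                                     mixture = mixture)[
        , c("taxon", "v_g_hat", "v_e_hat", "h2_hat", "lrt", "p")],
        error = function(e)
          data.frame(taxon = rownames(x)[i], v_g_hat = NA_real_,
                     v_e_hat = NA_real_, h2_hat = NA_real_,
                     lrt = NA_real_, p = NA_real_))
    })
    res <- do.call(rbind, rows)
  }
  res$p_adjusted <- if (adjust == "bh") p.adjust(res$p, "BH") else res$p
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alphaLevel
  attr(res, "nSignificant") <- sum(res$significant)
  attr(res, "alphaLevel") <- alphaLevel
  res
}
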