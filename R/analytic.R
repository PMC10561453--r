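#' Heritability of absolute abundance
#'
#' The heritability of taxon i is the proportion of the phenotypic variance
#' of its absolute abundance attributable to host genetic variation,
#' \eqn{h^2_i = V_{G_i} / V_{P_i}} with \eqn{V_{P_i} = V_{G_i} + V_{E_i}}.
#'
#' @param params a \linkS4class{CommunityParams} object.
#' @param taxon taxon indices or names; defaults to all taxa.
#' @return named numeric vector of heritabilities in [0, 1].
#' @export
h2Absolute <- function(params, taxon = seq_len(nTaxa(params))) {
  idx <- .resolveTaxon(params, taxon)
  vp <- params@vG[idx] + params@vE[idx]
  if (any(vp <= 0))
    stop("heritability undefined: zero total variance for taxon ",
         paste(taxonNames(params)[idx[vp <= 0]], collapse = ", "))
  params@vG[idx] / vp
}

#' Gaussian moments of total community abundance
#'
#' The total community abundance C is the sum of the M per-taxon absolute
#' abundances and is itself normal. Its mean is the sum of the per-taxon
#' means; its variance is the sum of the per-taxon variances plus twice the
#' sum of all pairwise covariances, using either the phenotypic components
#' (V_P, cov_P) or the genetic components (V_G, cov_G).
#'
#' @param params a \linkS4class{CommunityParams} object.
#' @param component \code{"phenotypic"} or \code{"genetic"}.
#' @return list with elements \code{mean} and \code{variance}.
#' @export
communityMoments <- function(params,
                             component = c("phenotypic", "genetic")) {
  component <- match.arg(component)
  covmat <- if (component == "genetic") .covG(params) else .covP(params)
  list(mean = sum(params@alpha), variance = sum(covmat))
}

#' Background-community aggregates for a focal taxon
#'
#' Summaries of the community excluding the focal taxon i, the quantities
#' entering the phi-squared approximation: \code{A} the summed mean
#' abundance of the background; \code{omega} and \code{z} its summed genetic
#' and phenotypic variances; \code{gamma} and \code{epsilon} the summed
#' genetic and environmental covariances between the focal taxon and each
#' background member; \code{kappa} and \code{nu} the summed genetic and
#' environmental covariances between each pair of background members.
#'
#' @param params a \linkS4class{CommunityParams} object with at least two
#'   taxa.
#' @param focal focal taxon index or name.
#' @return named list with elements \code{focal}, \code{A}, \code{omega},
#'   \code{z}, \code{gamma}, \code{epsilon}, \code{kappa}, \code{nu}.
#' @export
backgroundAggregates <- function(params, focal) {
  if (nTaxa(params) < 2)
    stop("a background community requires at least two taxa")
  i <- .resolveTaxon(params, focal)
  if (length(i) != 1) stop("'focal' must identify a single taxon")
  bg <- setdiff(seq_len(nTaxa(params)), i)
  cg <- .covG(params)
  ce <- .covE(params)
  cgBG <- cg[bg, bg, drop = FALSE]
  ceBG <- ce[bg, bg, drop = FALSE]
  list(
    focal = i,
    A = sum(params@alpha[bg]),
    omega = sum(params@vG[bg]),
    z = sum(params@vG[bg] + params@vE[bg]),
    gamma = sum(cg[i, bg]),
    epsilon = sum(ce[i, bg]),
    kappa = sum(cgBG[upper.tri(cgBG)]),
    nu = sum(ceBG[upper.tri(ceBG)])
  )
}

#' Second-order delta-method variance of a ratio of correlated normals
#'
#' For X ~ Normal(muNum, varNum), Y ~ Normal(muDen, varDen) with
#' cov(X, Y) = covariance, approximates var(X / Y) by the second-order
#' Taylor expansion
#' \deqn{(\mu_X/\mu_Y)^2 (\sigma_X^2/\mu_X^2
#'   - 2\,cov/(\mu_X \mu_Y) + \sigma_Y^2/\mu_Y^2).}
#'
#' The approximation is accurate when the denominator's coefficient of
#' variation is small, the regime of taxon-over-community-total ratios where
#' the denominator aggregates many taxa; the exact ratio of normals has no
#' finite variance, so this is a working approximation, not a bound.
#'
#' @param muNum,varNum mean and variance of the numerator.
#' @param muDen,varDen mean and variance of the denominator
#'   (\code{muDen != 0}).
#' @param covariance covariance between numerator and denominator.
#' @return approximate variance of the ratio (>= 0 in well-posed regimes).
#' @export
ratioVarianceDelta <- function(muNum, varNum, muDen, varDen, covariance) {
  if (any(muDen == 0)) stop("denominator mean must be non-zero")
  (muNum / muDen)^2 *
    (varNum / muNum^2 - 2 * covariance / (muNum * muDen) + varDen / muDen^2)
}

.phiComponents <- function(params, i) {
  ag <- backgroundAggregates(params, i)
  a <- params@alpha[[i]]
  vg <- params@vG[[i]]
  vp <- vg + params@vE[[i]]
  num <- ag$A^2 * vg + a^2 * ag$omega - 2 * a * (ag$A * ag$gamma - a * ag$kappa)
  den <- ag$A^2 * vp + a^2 * ag$z -
    2 * a * (ag$A * (ag$gamma + ag$epsilon) - a * (ag$nu + ag$kappa))
  list(num = num, den = den, scaleRef = ag$A^2 * vp)
}

#' Heritability obtained from relative abundances (phi-squared)
#'
#' The delta-method approximation of the heritability one obtains when the
#' analyzed trait is the taxon's relative, not absolute, abundance:
#' \deqn{\varphi^2 \approx \frac{A^2 V_G + \alpha^2\omega
#'   - 2\alpha(A\gamma - \alpha\kappa)}{A^2 V_P + \alpha^2 z
#'   - 2\alpha(A(\gamma+\epsilon) - \alpha(\nu+\kappa))}}
#' where the background aggregates are those of
#' \code{\link{backgroundAggregates}}. Unlike \eqn{h^2}, the value depends
#' on the focal taxon's mean abundance and on the whole background
#' community. With all covariances zero it reduces to
#' \eqn{(\alpha^2\omega + A^2 V_G) / (\alpha^2 z + A^2 V_P)}; with
#' additionally \eqn{V_G = 0} the numerator keeps only
#' \eqn{\alpha^2\omega}, which is positive whenever the background carries
#' any genetic variance — a non-heritable taxon genuinely inherits a
#' genetic signal from the community it is normalized against.
#'
#' Because both numerator and denominator are second-order delta-method
#' variances, the ratio stays in [0, 1] for any valid (positive
#' semi-definite, correlation-bounded) parameterization; should rounding
#' ever push a value outside that range it is returned as-is with a
#' warning rather than clamped.
#'
#' @param params a \linkS4class{CommunityParams} object with at least two
#'   taxa.
#' @param focal focal taxon indices or names; defaults to all taxa.
#' @return named numeric vector of phi-squared values.
#' @export
phiSquared <- function(params, focal = seq_len(nTaxa(params))) {
  idx <- .resolveTaxon(params, focal)
  out <- vapply(idx, function(i) {
    pc <- .phiComponents(params, i)
    if (pc$den <= 1e-12 * pc$scaleRef)
      stop("phi-squared denominator is not positive for taxon '",
           taxonNames(params)[i], "': the community covariance structure ",
           "removes essentially all variance from its relative abundance ",
           "(degenerate parameter combination)")
    pc$num / pc$den
  }, numeric(1))
  names(out) <- taxonNames(params)[idx]
  if (any(out < 0 | out > 1))
    warning("phi-squared outside [0, 1] for taxa: ",
            paste(names(out)[out < 0 | out > 1], collapse = ", "),
            " (extreme covariance structure; values returned unclamped)")
  out
}

#' Rare- and dominant-taxon limits of phi-squared
#'
#' As the focal taxon becomes rare relative to the background
#' (\eqn{\alpha/A \to 0}), phi-squared approaches the taxon's own
#' heritability \eqn{V_G/V_P}; as it becomes dominant
#' (\eqn{\alpha/A \to \infty}), it approaches the heritability of the
#' background community \eqn{\omega/z}, and is no longer shaped by the
#' focal taxon at all.
#'
#' @param params a \linkS4class{CommunityParams} object with at least two
#'   taxa.
#' @param focal focal taxon index or name.
#' @return named numeric vector \code{c(rare = , dominant = )}.
#' @export
phiLimits <- function(params, focal) {
  i <- .resolveTaxon(params, focal)
  if (length(i) != 1) stop("'focal' must identify a single taxon")
  ag <- backgroundAggregates(params, i)
  vp <- params@vG[[i]] + params@vE[[i]]
  if (vp <= 0) stop("focal taxon has zero phenotypic variance")
  if (ag$z <= 0) stop("background community has zero phenotypic variance")
  c(rare = params@vG[[i]] / vp, dominant = ag$omega / ag$z)
}
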