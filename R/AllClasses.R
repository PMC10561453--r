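#' @import methods
#' @importFrom stats rnorm rbinom pchisq p.adjust qnorm runif var cor sd
#'   logLik lm glm binomial coef anova setNames complete.cases quantile
#'   median
NULL

#' Quantitative-genetic parameterization of a microbial community
#'
#' A \code{CommunityParams} object stores, for each of M taxa, the mean
#' absolute abundance \eqn{\alpha_i}, the host genetic variance
#' \eqn{V_{G_i}} and the environmental (residual) variance \eqn{V_{E_i}} of
#' absolute abundance, together with the M-by-M genetic and environmental
#' correlation matrices that induce co-abundances between taxa. Under the
#' model, the absolute abundance of taxon i in host j is
#' \eqn{P_{ij} = \alpha_i + G_{ij} + E_{ij}}, with breeding values G shared
#' by all hosts of a genotype and residuals E drawn independently per host.
#'
#' Covariances between taxa are parameterized through correlations:
#' \eqn{cov_G(j,k) = r_{G_{jk}} \sqrt{V_{G_j} V_{G_k}}} and likewise for the
#' environmental component. A pair in which one member has zero genetic
#' variance therefore has zero genetic covariance regardless of the stated
#' correlation.
#'
#' @slot alpha numeric vector of mean absolute abundances (all > 0).
#' @slot vG numeric vector of genetic variances (all >= 0).
#' @slot vE numeric vector of environmental variances (all >= 0).
#' @slot corrG genetic correlation matrix (symmetric, unit diagonal, PSD).
#' @slot corrE environmental correlation matrix (symmetric, unit diagonal,
#'   PSD).
#'
#' @seealso \code{\link{CommunityParams}} (constructor),
#'   \code{\link{phiSquared}}, \code{\link{simulatePopulation}}
#' @exportClass CommunityParams
setClass("CommunityParams",
  representation(
    alpha = "numeric",
    vG = "numeric",
    vE = "numeric",
    corrG = "matrix",
    corrE = "matrix"
  )
)

.checkCorr <- function(mat, what, m) {
  if (!is.numeric(mat) || nrow(mat) != m || ncol(mat) != m)
    return(sprintf("%s must be a %d x %d numeric matrix", what, m, m))
  if (any(!is.finite(mat)))
    return(sprintf("%s contains non-finite entries", what))
  if (max(abs(mat - t(mat))) > 1e-8)
    return(sprintf("%s must be symmetric", what))
  if (max(abs(diag(mat) - 1)) > 1e-8)
    return(sprintf("%s must have unit diagonal", what))
  if (any(mat < -1 - 1e-8) || any(mat > 1 + 1e-8))
    return(sprintf("%s entries must lie in [-1, 1]", what))
  ev <- eigen(mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    return(sprintf("%s must be positive semi-definite", what))
  NULL
}

setValidity("CommunityParams", function(object) {
  m <- length(object@alpha)
  msg <- character()
  if (m < 1) msg <- c(msg, "at least one taxon is required")
  if (any(!is.finite(object@alpha)) || any(object@alpha <= 0))
    msg <- c(msg, "all mean abundances (alpha) must be positive and finite")
  if (length(object@vG) != m || length(object@vE) != m)
    msg <- c(msg, "alpha, vG and vE must have equal length")
  if (any(!is.finite(object@vG)) || any(object@vG < 0))
    msg <- c(msg, "genetic variances must be non-negative")
  if (any(!is.finite(object@vE)) || any(object@vE < 0))
    msg <- c(msg, "environmental variances must be non-negative")
  if (length(msg) == 0) {
    cg <- .checkCorr(object@corrG, "genetic correlation matrix", m)
    ce <- .checkCorr(object@corrE, "environmental correlation matrix", m)
    msg <- c(msg, cg, ce)
  }
  if (length(msg)) msg else TRUE
})

#' Host-by-taxon abundance table
#'
#' \code{AbundanceTable} extends \linkS4class{SummarizedExperiment}: taxa are
#' rows, hosts are columns, the single assay \code{"abundance"} holds the
#' abundance matrix, \code{colData} carries the per-host \code{genotype}
#' label, and the measurement scale is one of \code{"absolute"} (abundance
#' units), \code{"relative"} (per-host proportions summing to 1),
#' \code{"counts"} (non-negative integer sequencing counts) or
#' \code{"transformed"} (output of a log-ratio or related transformation,
#' on which row-sum constraints no longer apply).
#'
#' @slot scale character scalar, the measurement scale.
#' @seealso \code{\link{AbundanceTable}} (constructor),
#'   \code{\link{toRelative}}, \code{\link{normalizeAbundance}}
#' @exportClass AbundanceTable
#' @import SummarizedExperiment
setClass("AbundanceTable",
  contains = "SummarizedExperiment",
  representation(scale = "character")
)

.abundanceScales <- c("absolute", "relative", "counts", "transformed")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (length(object@scale) != 1 || !object@scale %in% .abundanceScales)
    msg <- c(msg, sprintf("scale must be one of %s",
                          paste(.abundanceScales, collapse = ", ")))
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  if (!"genotype" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'genotype' column")
  if (length(msg) == 0) {
    a <- SummarizedExperiment::assay(object, "abundance")
    if (identical(object@scale, "relative") && ncol(a) > 0) {
      cs <- colSums(a)
      if (any(abs(cs - 1) > 1e-9))
        msg <- c(msg, "relative abundances must sum to 1 (+/- 1e-9) per host")
    }
    if (identical(object@scale, "counts") && length(a) > 0) {
      if (any(a < 0) || any(a != round(a)))
        msg <- c(msg, "counts must be non-negative integers")
    }
  }
  if (length(msg)) msg else TRUE
})
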