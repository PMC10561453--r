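#' Construct a CommunityParams object
#'
#' @param alpha numeric vector of mean absolute abundances (arbitrary
#'   abundance units), one per taxon; all must be positive.
#' @param vG numeric vector of genetic variances of absolute abundance
#'   (abundance units squared). Recycled if scalar.
#' @param vE numeric vector of environmental variances. Recycled if scalar.
#' @param rG genetic correlation between taxa: either a scalar (every pair
#'   shares the same correlation, the equicorrelated structure used
#'   throughout the co-abundance analyses) or a full M-by-M correlation
#'   matrix.
#' @param rE environmental correlation, same conventions as \code{rG}.
#' @param taxa optional character vector of taxon names.
#'
#' @return A validated \linkS4class{CommunityParams} object.
#' @examples
#' ## two equally abundant taxa, one fully heritable, one not
#' cp <- CommunityParams(alpha = c(1, 1), vG = c(1, 0) / 36, vE = c(0, 1) / 36)
#' h2Absolute(cp)
#' @export
CommunityParams <- function(alpha, vG, vE, rG = 0, rE = 0, taxa = NULL) {
  m <- length(alpha)
  vG <- rep_len(as.numeric(vG), m)
  vE <- rep_len(as.numeric(vE), m)
  if (is.null(taxa)) taxa <- paste0("taxon", seq_len(m))
  if (length(taxa) != m) stop("'taxa' must name every taxon")
  corrG <- if (is.matrix(rG)) rG else equicorrelation(m, rG)
  corrE <- if (is.matrix(rE)) rE else equicorrelation(m, rE)
  dimnames(corrG) <- dimnames(corrE) <- list(taxa, taxa)
  new("CommunityParams", alpha = setNames(as.numeric(alpha), taxa),
      vG = setNames(vG, taxa), vE = setNames(vE, taxa),
      corrG = corrG, corrE = corrE)
}

#' Equicorrelated correlation matrix
#'
#' Unit-diagonal matrix with a common off-diagonal correlation \code{rho};
#' positive semi-definite for \code{rho} in \code{[-1/(m-1), 1]}.
#'
#' @param m dimension.
#' @param rho common pairwise correlation.
#' @return an \code{m} by \code{m} matrix.
#' @export
equicorrelation <- function(m, rho) {
  mat <- matrix(rho, m, m)
  diag(mat) <- 1
  mat
}

#' Read community parameters from a YAML or JSON file
#'
#' The file must provide \code{alpha}, \code{v_g} and \code{v_e} vectors and
#' may give either scalar \code{r_g} / \code{r_e} (equicorrelated) or full
#' matrices \code{corr_g} / \code{corr_e} (list of rows). Optional
#' \code{taxa} names.
#'
#' @param file path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A \linkS4class{CommunityParams} object.
#' @export
readCommunityParams <- function(file) {
  cfg <- .readConfig(file)
  for (f in c("alpha", "v_g", "v_e"))
    if (is.null(cfg[[f]])) stop("config field '", f, "' is required")
  asMat <- function(x) if (is.list(x)) do.call(rbind, lapply(x, unlist)) else x
  rG <- if (!is.null(cfg$corr_g)) asMat(cfg$corr_g) else cfg$r_g %||% 0
  rE <- if (!is.null(cfg$corr_e)) asMat(cfg$corr_e) else cfg$r_e %||% 0
  CommunityParams(unlist(cfg$alpha), unlist(cfg$v_g), unlist(cfg$v_e),
                  rG = rG, rE = rE, taxa = cfg$taxa)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.readConfig <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::fromJSON(file, simplifyVector = TRUE)
  else
    yaml::read_yaml(file)
}

#' @describeIn CommunityParams-accessors number of taxa
#' @export
nTaxa <- function(params) length(params@alpha)

#' Accessors for CommunityParams
#'
#' @param params a \linkS4class{CommunityParams} object.
#' @name CommunityParams-accessors
#' @return numeric vectors (per taxon) or matrices.
NULL

#' @describeIn CommunityParams-accessors taxon names
#' @export
taxonNames <- function(params) names(params@alpha)

#' @describeIn CommunityParams-accessors mean absolute abundances
#' @export
meanAbundance <- function(params) params@alpha

#' @describeIn CommunityParams-accessors genetic variances
#' @export
geneticVariance <- function(params) params@vG

#' @describeIn CommunityParams-accessors environmental variances
#' @export
environmentalVariance <- function(params) params@vE

#' @describeIn CommunityParams-accessors phenotypic variances (vG + vE)
#' @export
phenotypicVariance <- function(params) params@vG + params@vE

#' @describeIn CommunityParams-accessors genetic correlation matrix
#' @export
geneticCorrelation <- function(params) params@corrG

#' @describeIn CommunityParams-accessors environmental correlation matrix
#' @export
environmentalCorrelation <- function(params) params@corrE

## pairwise covariance matrices implied by the correlation parameterization
.covG <- function(params) {
  s <- sqrt(params@vG)
  params@corrG * tcrossprod(s)
}

.covE <- function(params) {
  s <- sqrt(params@vE)
  params@corrE * tcrossprod(s)
}

.covP <- function(params) .covG(params) + .covE(params)

.resolveTaxon <- function(params, taxon) {
  if (is.character(taxon)) {
    idx <- match(taxon, taxonNames(params))
    if (any(is.na(idx))) stop("unknown taxon: ",
                              paste(taxon[is.na(idx)], collapse = ", "))
    idx
  } else {
    taxon <- as.integer(taxon)
    if (any(taxon < 1 | taxon > nTaxa(params)))
      stop("taxon index out of range")
    taxon
  }
}

setMethod("show", "CommunityParams", function(object) {
  m <- nTaxa(object)
  cat("CommunityParams with", m, "taxa\n")
  h2 <- ifelse(object@vG + object@vE > 0,
               object@vG / (object@vG + object@vE), NA_real_)
  cat("  mean abundance: ", .fmtRange(object@alpha), "\n", sep = "")
  cat("  h2 (absolute):  ", .fmtRange(h2), "\n", sep = "")
  offG <- object@corrG[upper.tri(object@corrG)]
  offE <- object@corrE[upper.tri(object@corrE)]
  cat("  correlations:   rG ", .fmtRange(offG),
      "; rE ", .fmtRange(offE), "\n", sep = "")
})

.fmtRange <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return("none")
  if (length(unique(signif(x, 6))) == 1) return(format(signif(x[1], 4)))
  paste0("[", format(signif(min(x), 4)), ", ", format(signif(max(x), 4)), "]")
}
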