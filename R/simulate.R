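## Matrix square root of a covariance matrix via symmetric eigendecomposition;
## tolerates semi-definite structure (e.g. perfectly correlated taxa).
.mvnFactor <- function(sigma) {
  if (all(sigma[lower.tri(sigma)] == 0, sigma[upper.tri(sigma)] == 0))
    return(diag(sqrt(diag(sigma)), nrow(sigma)))
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("covariance matrix is not positive semi-definite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

## Draw n rows from MVN(0, sigma) given a precomputed factor L = sigma^(1/2)
.mvnDraw <- function(n, L) {
  m <- ncol(L)
  z <- matrix(rnorm(n * m), n, m)
  if (all(L[lower.tri(L)] == 0, L[upper.tri(L)] == 0))
    z * rep(diag(L), each = n)   # independent taxa: skip the matrix product
  else
    z %*% L
}

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

## Core simulator: returns list(mat = taxa x hosts, genotype = labels).
## Draw order is fixed (all breeding values, then all residuals) so a given
## seed fully determines the table.
.simulateMatrix <- function(params, nGenotypes, nReplicates,
                            negativePolicy = "truncate") {
  m <- nTaxa(params)
  LG <- .mvnFactor(.covG(params))
  LE <- .mvnFactor(.covE(params))
  G <- .mvnDraw(nGenotypes, LG)                     # one vector per genotype
  E <- .mvnDraw(nGenotypes * nReplicates, LE)       # one vector per host
  gid <- rep(seq_len(nGenotypes), each = nReplicates)
  P <- sweep(G[gid, , drop = FALSE] + E, 2, params@alpha, `+`)
  nNeg <- sum(P < 0)
  if (nNeg > 0) {
    frac <- nNeg / length(P)
    if (negativePolicy == "error")
      stop(sprintf("simulation produced %d negative abundances (%.3f%% of cells)",
                   nNeg, 100 * frac))
    if (negativePolicy == "truncate") {
      if (frac > 0.001)
        warning(sprintf("truncated %.2f%% of cells at zero; the Gaussian model is a poor fit at this noise level", 100 * frac))
      P[P < 0] <- 0
    }
  }
  list(mat = t(P), genotype = paste0("g", gid))
}

#' Simulate a host population with microbial communities
#'
#' Generates absolute abundances under the quantitative-genetic model
#' \eqn{P_{ij} = \alpha_i + G_{ij} + E_{ij}}: for each genotype one
#' breeding-value vector is drawn from MVN(0, Sigma_G) and shared exactly
#' by its replicate hosts (a clonal, broad-sense design); each host
#' additionally receives an independent residual vector from
#' MVN(0, Sigma_E). The covariance matrices are built from the per-taxon
#' variances and the correlation matrices of \code{params}.
#'
#' The Gaussian model admits negative abundances; at the coefficients of
#' variation used throughout (sigma/mu = 1/6) they are vanishingly rare.
#' \code{negativePolicy} controls what happens otherwise: \code{"truncate"}
#' (default) sets them to zero and warns when more than 0.1\% of cells are
#' affected, \code{"error"} aborts listing the affected fraction,
#' \code{"allow"} keeps them.
#'
#' @param params a \linkS4class{CommunityParams} object.
#' @param nGenotypes number of host genotypes (>= 2 for any heritability
#'   estimation).
#' @param nReplicates number of replicate hosts per genotype.
#' @param seed integer seed; the same seed, design and parameters yield a
#'   bit-identical table. \code{NULL} uses the session RNG stream.
#' @param negativePolicy \code{"truncate"}, \code{"error"} or
#'   \code{"allow"}.
#' @return an \linkS4class{AbundanceTable} on the absolute scale.
#' @examples
#' cp <- CommunityParams(alpha = c(1, 1), vG = c(1, 0) / 72,
#'                       vE = c(1, 2) / 72)
#' simulatePopulation(cp, nGenotypes = 10, nReplicates = 5, seed = 1)
#' @export
simulatePopulation <- function(params, nGenotypes, nReplicates, seed = NULL,
                               negativePolicy = c("truncate", "error",
                                                  "allow")) {
  negativePolicy <- match.arg(negativePolicy)
  stopifnot(nGenotypes >= 1, nReplicates >= 1)
  sim <- .withSeed(seed,
    .simulateMatrix(params, nGenotypes, nReplicates, negativePolicy))
  AbundanceTable(sim$mat, genotype = sim$genotype, scale = "absolute",
                 taxa = taxonNames(params))
}

#' Close an abundance table to relative abundances
#'
#' Divides each host's abundances by their total, the total-sum-scaling
#' closure that produces compositional data: every host's relative
#' abundances sum to 1. Idempotent.
#'
#' @param x an \linkS4class{AbundanceTable} on the absolute, counts or
#'   relative scale.
#' @return an \linkS4class{AbundanceTable} on the relative scale.
#' @export
toRelative <- function(x) {
  if (!abundanceScale(x) %in% c("absolute", "counts", "relative"))
    stop("relative closure requires absolute, count or relative data")
  a <- abundances(x)
  tot <- colSums(a)
  if (any(tot <= 0))
    stop("non-positive total abundance for host(s) ",
         paste(which(tot <= 0), collapse = ", "))
  AbundanceTable(sweep(a, 2, tot, `/`), genotype = genotypes(x),
                 scale = "relative", taxa = rownames(a))
}

## Vectorized multinomial sampling across hosts with per-host sizes,
## via the conditional-binomial decomposition (taxon by taxon).
.rmultinomHosts <- function(depths, prob) {
  m <- nrow(prob)
  n <- ncol(prob)
  counts <- matrix(0L, m, n)
  remaining <- as.integer(depths)
  pLeft <- colSums(prob)
  for (i in seq_len(m - 1)) {
    p <- ifelse(pLeft > 0, pmin(prob[i, ] / pLeft, 1), 0)
    draw <- rbinom(n, remaining, p)
    counts[i, ] <- draw
    remaining <- remaining - draw
    pLeft <- pLeft - prob[i, ]
  }
  counts[m, ] <- remaining
  counts
}

#' Thin absolute abundances to sequencing read counts
#'
#' Emulates sequencing: each host's reads are a multinomial draw of its
#' depth with per-taxon probabilities proportional to its absolute
#' abundances. Used to study normalizations under sample-coverage
#' (depth) differences.
#'
#' @param x an \linkS4class{AbundanceTable} on the absolute scale.
#' @param depths per-host sequencing depths (positive integers; recycled if
#'   scalar).
#' @param seed integer seed or \code{NULL}.
#' @return an \linkS4class{AbundanceTable} on the counts scale; each host's
#'   counts sum exactly to its depth.
#' @export
simulateReadCounts <- function(x, depths, seed = NULL) {
  if (abundanceScale(x) != "absolute")
    stop("read-count thinning requires absolute abundances")
  a <- abundances(x)
  depths <- rep_len(as.integer(depths), ncol(a))
  if (any(depths < 1)) stop("depths must be positive integers")
  if (any(colSums(a) <= 0))
    stop("zero-probability abundance vector for host(s) ",
         paste(which(colSums(a) <= 0), collapse = ", "))
  counts <- .withSeed(seed, .rmultinomHosts(depths, pmax(a, 0)))
  AbundanceTable(counts, genotype = genotypes(x), scale = "counts",
                 taxa = rownames(a))
}
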