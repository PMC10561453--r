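#' Compositional normalizations and transformations
#'
#' Applies one of the normalization/transformation schemes used in
#' microbiome studies to an abundance table:
#' \describe{
#'   \item{tss}{total-sum scaling: each host divided by its total; equal to
#'     \code{\link{toRelative}}.}
#'   \item{alr}{additive log-ratio against a designated reference taxon:
#'     \code{log(x_i / x_ref)} for every non-reference taxon. If the
#'     reference has constant absolute abundance across hosts, this turns
#'     relative or count data back into (log) abundances comparable across
#'     hosts.}
#'   \item{clr}{centered log-ratio: \code{log(x_i / gm(x))} with the
#'     per-host geometric mean; each host's transformed values sum to 0.}
#'   \item{css}{cumulative-sum scaling: each host's counts divided by the
#'     sum of its counts at or below its \code{cssQuantile} quantile,
#'     rescaled by the across-host median of these factors.}
#'   \item{log}{\code{log(x + logOffset)}; the offset is arbitrary and must
#'     be chosen by the analyst (default 0, requiring positive data).}
#'   \item{asinsqrt}{arcsine square root of relative abundances.}
#'   \item{rankinverse}{per-taxon rank-based inverse-normal transform.}
#' }
#' Log-based methods require strictly positive values; zeros raise an error
#' naming the offending cells unless \code{pseudocount} is given, in which
#' case it is added first (and a message records that choice, since any
#' pseudocount is arbitrary).
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param method one of \code{"tss"}, \code{"alr"}, \code{"clr"},
#'   \code{"css"}, \code{"log"}, \code{"asinsqrt"}, \code{"rankinverse"}.
#' @param reference reference taxon (name or index) for \code{"alr"}.
#' @param pseudocount value added before log-based methods when zeros are
#'   present; default \code{NULL} (error on zeros).
#' @param cssQuantile quantile defining the CSS scaling factor (default
#'   0.5, the median).
#' @param logOffset offset for \code{method = "log"}.
#' @return an \linkS4class{AbundanceTable}; scale \code{"relative"} for
#'   tss, \code{"transformed"} otherwise. ALR output drops the reference
#'   row (M - 1 taxa).
#' @export
normalizeAbundance <- function(x, method = c("tss", "alr", "clr", "css",
                                             "log", "asinsqrt",
                                             "rankinverse"),
                               reference = NULL, pseudocount = NULL,
                               cssQuantile = 0.5, logOffset = 0) {
  method <- match.arg(method)
  a <- abundances(x)
  g <- genotypes(x)
  if (method == "tss") return(toRelative(x))
  if (method %in% c("alr", "clr", "log")) {
    if (!is.null(pseudocount)) {
      if (any(a == 0))
        message("adding pseudocount ", pseudocount,
                " to zero cells before log transform (arbitrary choice)")
      a <- a + pseudocount
    }
    if (any(a <= 0)) {
      bad <- which(a <= 0, arr.ind = TRUE)
      stop("non-positive values are incompatible with log-based methods ",
           "(e.g. taxon ", rownames(a)[bad[1, 1]], ", host ", bad[1, 2],
           "); supply a pseudocount")
    }
  }
  out <- switch(method,
    alr = {
      if (is.null(reference)) stop("'alr' requires a reference taxon")
      ref <- if (is.character(reference)) {
        if (!reference %in% rownames(a))
          stop("reference taxon '", reference, "' not found")
        match(reference, rownames(a))
      } else as.integer(reference)
      sweep(log(a[-ref, , drop = FALSE]), 2, log(a[ref, ]), `-`)
    },
    clr = {
      la <- log(a)
      sweep(la, 2, colMeans(la), `-`)
    },
    css = {
      if (abundanceScale(x) != "counts")
        stop("cumulative-sum scaling is defined for count data")
      fac <- apply(a, 2, function(col) {
        q <- quantile(col, cssQuantile, names = FALSE, type = 7)
        sum(col[col <= q])
      })
      if (any(fac <= 0)) stop("zero CSS scaling factor for host(s) ",
                              paste(which(fac <= 0), collapse = ", "))
      sweep(a, 2, fac, `/`) * median(fac)
    },
    log = log(a + logOffset),
    asinsqrt = {
      rel <- if (abundanceScale(x) == "relative") a
             else sweep(a, 2, colSums(a), `/`)
      asin(sqrt(rel))
    },
    rankinverse = t(apply(a, 1, function(row)
      qnorm((rank(row) - 0.5) / length(row))))
  )
  AbundanceTable(out, genotype = g, scale = "transformed",
                 taxa = rownames(out))
}

#' Can a normalization recover true heritabilities from count data?
#'
#' Simulates the full measurement chain — absolute abundances, multinomial
#' thinning to sequencing counts at host-specific depths, normalization,
#' per-taxon variance-component estimation — and pairs each taxon's true
#' heritability with the mean recovered estimate. With a constant-abundance
#' reference taxon, the additive log-ratio transform restores abundances
#' comparable across hosts and recovers the true values; total-sum scaling
#' on the same data instead yields the compositional estimates, reproducing
#' the interdependency bias.
#'
#' @param params a \linkS4class{CommunityParams} object. For
#'   \code{method = "alr"} it should contain a constant reference taxon
#'   (zero genetic and environmental variance).
#' @param method passed to \code{\link{normalizeAbundance}}.
#' @param nGenotypes,nReplicates simulated design.
#' @param depthRange range of per-host sequencing depths; depths are drawn
#'   log-uniformly, so \code{c(1e4, 1e5)} gives 10-fold coverage variation.
#'   Set both ends equal for constant depth.
#' @param nSim number of simulated datasets averaged over.
#' @param seed integer seed.
#' @param reference reference taxon for \code{method = "alr"}.
#' @param pseudocount passed to \code{\link{normalizeAbundance}} (count
#'   zeros; default 0.5).
#' @return \code{data.frame} with columns \code{taxon}, \code{true_h2},
#'   \code{recovered_h2} (mean over simulations; \code{NA} for the ALR
#'   reference taxon) and \code{mc_se}.
#' @export
recoveryExperiment <- function(params, method, nGenotypes = 200,
                               nReplicates = 100, depthRange = c(1e4, 1e5),
                               nSim = 5, seed = NULL, reference = NULL,
                               pseudocount = 0.5) {
  m <- nTaxa(params)
  taxa <- taxonNames(params)
  vp <- phenotypicVariance(params)
  trueH2 <- ifelse(vp > 0, geneticVariance(params) / vp, NA_real_)
  .withSeed(seed, {
    est <- matrix(NA_real_, nSim, m, dimnames = list(NULL, taxa))
    for (s in seq_len(nSim)) {
      sim <- simulatePopulation(params, nGenotypes, nReplicates)
      depths <- round(exp(runif(ncol(sim), log(depthRange[1]),
                                log(depthRange[2]))))
      counts <- simulateReadCounts(sim, depths)
      norm <- suppressMessages(
        normalizeAbundance(counts, method, reference = reference,
                           pseudocount = pseudocount))
      scan <- .balancedScan(abundances(norm), genotypes(norm))
      est[s, scan$taxon] <- scan$h2_hat
    }
    data.frame(taxon = taxa, true_h2 = unname(trueH2),
               recovered_h2 = colMeans(est),
               mc_se = apply(est, 2, sd) / sqrt(nSim), row.names = NULL)
  })
}
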