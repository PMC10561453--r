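#' Construct an AbundanceTable
#'
#' @param values numeric matrix, taxa as rows and hosts as columns.
#' @param genotype per-host genotype labels (length \code{ncol(values)}).
#' @param scale one of \code{"absolute"}, \code{"relative"},
#'   \code{"counts"}, \code{"transformed"}.
#' @param taxa optional taxon names (rownames of \code{values} by default).
#' @return an \linkS4class{AbundanceTable}.
#' @examples
#' at <- AbundanceTable(matrix(1:6, 2, 3), genotype = c("g1", "g1", "g2"),
#'                      scale = "absolute")
#' toRelative(at)
#' @export
AbundanceTable <- function(values, genotype, scale = "absolute",
                           taxa = NULL) {
  values <- as.matrix(values)
  if (!is.null(taxa)) rownames(values) <- taxa
  if (is.null(rownames(values)))
    rownames(values) <- paste0("taxon", seq_len(nrow(values)))
  if (length(genotype) != ncol(values))
    stop("'genotype' must label every host (column)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    colData = S4Vectors::DataFrame(genotype = as.character(genotype))
  )
  new("AbundanceTable", se, scale = scale)
}

#' Accessors for AbundanceTable
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @name AbundanceTable-accessors
#' @return \code{abundances}: the taxa-by-hosts matrix; \code{genotypes}:
#'   the per-host genotype labels; \code{abundanceScale}: the scale string.
NULL

#' @describeIn AbundanceTable-accessors abundance matrix (taxa x hosts)
#' @export
abundances <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn AbundanceTable-accessors per-host genotype labels
#' @export
genotypes <- function(x) SummarizedExperiment::colData(x)$genotype

#' @describeIn AbundanceTable-accessors measurement scale
#' @export
abundanceScale <- function(x) x@scale

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable (", object@scale, "): ", nrow(object), " taxa x ",
      ncol(object), " hosts, ",
      length(unique(genotypes(object))), " genotypes\n", sep = "")
})

#' Read / write abundance tables as TSV
#'
#' The on-disk layout follows the field convention for host-by-taxon
#' tables: hosts as rows, first column \code{genotype}, remaining columns
#' one per taxon.
#'
#' @param file path to a tab-separated file.
#' @param scale measurement scale of the stored values.
#' @return \code{readAbundanceTable}: an \linkS4class{AbundanceTable};
#'   \code{writeAbundanceTable}: the file path, invisibly.
#' @export
readAbundanceTable <- function(file, scale = "absolute") {
  df <- utils::read.delim(file, check.names = FALSE)
  if (!"genotype" %in% colnames(df))
    stop("first column 'genotype' is required")
  g <- as.character(df$genotype)
  mat <- t(as.matrix(df[setdiff(colnames(df), "genotype")]))
  colnames(mat) <- NULL
  AbundanceTable(mat, genotype = g, scale = scale)
}

#' @rdname readAbundanceTable
#' @param x an \linkS4class{AbundanceTable} to write.
#' @export
writeAbundanceTable <- function(x, file) {
  df <- data.frame(genotype = genotypes(x), t(abundances(x)),
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
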