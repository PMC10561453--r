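#' Run a named analysis stage from a config file
#'
#' Thin reproducible-workflow layer over the package's functions: reads a
#' YAML or JSON config, executes one stage, writes its outputs as TSV files
#' into \code{outDir} together with a \code{run_manifest.json} recording
#' the seed, the config digest, the package version and the files written.
#' Re-running the same config and seed produces byte-identical outputs.
#'
#' Stages and their config fields:
#' \describe{
#'   \item{phi2}{either \code{community} (fields of
#'     \code{\link{readCommunityParams}}) for per-taxon phi-squared, or
#'     \code{grid} with fields \code{focal_h2}, \code{cv} (sigma/mu of the
#'     focal taxon), \code{A}, \code{z}, \code{alpha} (vector),
#'     \code{background_h2} (vector) for a focal-vs-background sweep.}
#'   \item{simulate}{\code{community}, \code{n_genotypes},
#'     \code{n_replicates}, \code{seed}, optional \code{relative: true} or
#'     \code{depths} (thin to counts).}
#'   \item{estimate}{\code{input} (abundance TSV, hosts as rows, first
#'     column genotype), optional \code{scale}, \code{method},
#'     \code{alpha_level}.}
#'   \item{power}{\code{community}, \code{focal}, \code{sample_sizes},
#'     \code{replicates_per_genotype}, \code{n_sim}, \code{alpha_level},
#'     \code{seed}.}
#'   \item{fdr}{as \code{power} minus \code{focal}.}
#'   \item{transform}{\code{input}, \code{scale}, \code{method}, optional
#'     \code{reference}, \code{pseudocount}.}
#'   \item{meta}{no fields; writes the study-table summary and both
#'     regressions.}
#' }
#'
#' @param command stage name.
#' @param configPath path to the YAML/JSON config.
#' @param outDir output directory (created if needed).
#' @return invisibly, the paths of the files written.
#' @export
runWorkflow <- function(command = c("phi2", "simulate", "estimate", "power",
                                    "fdr", "transform", "meta"),
                        configPath = NULL, outDir = ".") {
  command <- match.arg(command)
  cfg <- if (command == "meta" && is.null(configPath)) list()
         else .readConfig(configPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  need <- function(field) {
    if (is.null(cfg[[field]]))
      stop("config for '", command, "' requires field '", field, "'")
    cfg[[field]]
  }
  community <- function() {
    cc <- need("community")
    asMat <- function(x) if (is.list(x)) do.call(rbind, lapply(x, unlist)) else x
    CommunityParams(unlist(cc$alpha), unlist(cc$v_g), unlist(cc$v_e),
                    rG = if (!is.null(cc$corr_g)) asMat(cc$corr_g)
                         else cc$r_g %||% 0,
                    rE = if (!is.null(cc$corr_e)) asMat(cc$corr_e)
                         else cc$r_e %||% 0,
                    taxa = cc$taxa)
  }
  files <- character()
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, path)
  }

  if (command == "phi2") {
    if (!is.null(cfg$grid)) {
      gr <- cfg$grid
      cv <- gr$cv %||% (1 / 6)
      combos <- expand.grid(alpha = unlist(need("grid")$alpha),
                            background_h2 = unlist(gr$background_h2))
      rows <- lapply(seq_len(nrow(combos)), function(k) {
        a <- combos$alpha[k]; bh2 <- combos$background_h2[k]
        vp <- a * cv^2
        cp <- CommunityParams(
          alpha = c(a, gr$A),
          vG = c(gr$focal_h2 * vp, bh2 * gr$z),
          vE = c((1 - gr$focal_h2) * vp, (1 - bh2) * gr$z))
        data.frame(alpha = a, rel_abundance = a / (a + gr$A),
                   h2_focal = gr$focal_h2, h2_background = bh2,
                   phi2 = unname(phiSquared(cp, 1)),
                   abs_error = abs(unname(phiSquared(cp, 1)) - gr$focal_h2))
      })
      emit(do.call(rbind, rows), "phi2_grid.tsv")
    } else {
      cp <- community()
      lim <- t(vapply(seq_len(nTaxa(cp)), function(i) phiLimits(cp, i),
                      numeric(2)))
      emit(data.frame(taxon = taxonNames(cp),
                      alpha = unname(meanAbundance(cp)),
                      rel_abundance = meanAbundance(cp) / sum(meanAbundance(cp)),
                      h2 = unname(h2Absolute(cp)),
                      phi2 = unname(phiSquared(cp)),
                      rare_limit = lim[, "rare"],
                      dominant_limit = lim[, "dominant"]),
           "phi2.tsv")
    }
  } else if (command == "simulate") {
    at <- simulatePopulation(community(), need("n_genotypes"),
                             need("n_replicates"), seed = cfg$seed)
    if (!is.null(cfg$depths))
      at <- simulateReadCounts(at, unlist(cfg$depths),
                               seed = (cfg$seed %||% 0) + 1)
    if (isTRUE(cfg$relative)) at <- toRelative(at)
    emit(data.frame(genotype = genotypes(at), t(abundances(at)),
                    check.names = FALSE), "abundance.tsv")
  } else if (command == "estimate") {
    at <- readAbundanceTable(need("input"), scale = cfg$scale %||% "absolute")
    scan <- scanCommunity(at, alphaLevel = cfg$alpha_level %||% 0.05,
                          method = cfg$method %||% "auto")
    emit(scan, "estimates.tsv")
  } else if (command == "power") {
    pw <- powerCurve(community(), focal = need("focal"),
                     sampleSizes = unlist(need("sample_sizes")),
                     replicatesPerGenotype =
                       cfg$replicates_per_genotype %||% 10,
                     nSim = cfg$n_sim %||% 200,
                     alphaLevel = cfg$alpha_level %||% 0.05,
                     seed = need("seed"))
    emit(pw, "power.tsv")
  } else if (command == "fdr") {
    fd <- communityFalseDiscovery(community(),
                                  sampleSizes = unlist(need("sample_sizes")),
                                  replicatesPerGenotype =
                                    cfg$replicates_per_genotype %||% 10,
                                  nSim = cfg$n_sim %||% 100,
                                  alphaLevel = cfg$alpha_level %||% 0.05,
                                  seed = need("seed"))
    emit(fd, "fdr.tsv")
  } else if (command == "transform") {
    at <- readAbundanceTable(need("input"), scale = cfg$scale %||% "counts")
    tr <- suppressMessages(
      normalizeAbundance(at, need("method"), reference = cfg$reference,
                         pseudocount = cfg$pseudocount))
    emit(data.frame(genotype = genotypes(tr), t(abundances(tr)),
                    check.names = FALSE), "transformed.tsv")
  } else if (command == "meta") {
    records <- loadTable1()
    s <- summarizeTable1(records)
    emit(data.frame(statistic = c("avg_h2_min", "avg_h2_max",
                                  "avg_h2_mean_across_studies",
                                  "n_taxa_min", "n_taxa_max",
                                  "n_taxa_median"),
                    value = c(s$avg_h2_min, s$avg_h2_max,
                              s$avg_h2_mean_across_studies,
                              s$n_taxa_range, s$n_taxa_median)),
         "meta_summary.tsv")
    emit(s$prop_heritable_by_study, "meta_prop_heritable.tsv")
    rb <- regressProportionHeritable(records)
    rl <- regressAverageHeritability(records)
    emit(data.frame(
      model = c("binomial_prop_heritable", "linear_avg_h2"),
      predictor = "log10_n_samples",
      slope = c(rb$slope, rl$slope),
      slope_se = c(rb$slope_se, rl$slope_se),
      p_value = c(rb$p_value, rl$p_value),
      fit_r2 = c(rb$pseudo_r2, rl$r_squared),
      r2_definition = c(rb$pseudo_r2_definition, "OLS R-squared"),
      n_rows = c(rb$n_rows, rl$n_rows)), "meta_regressions.tsv")
  }

  manifest <- list(
    command = command,
    seed = cfg$seed %||% NA,
    config_digest = if (is.null(configPath)) NA
                    else unname(tools::md5sum(configPath)),
    package_version = as.character(utils::packageVersion("compherit")),
    files = basename(files)
  )
  manifestPath <- file.path(outDir, "run_manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(files, manifestPath))
}
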