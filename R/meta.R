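.TABLE1_MD5 <- "149506aa55755a878f3443d2a80fdc2d"

#' Load the packaged compilation of microbiome-heritability studies
#'
#' Returns the literature compilation shipped with the package: 30 rows
#' across 23 published studies of per-taxon microbiome heritability, each
#' row one study (or one season / ancestry / breed / timepoint / field-year
#' sub-analysis) with its host system, sample size, number of taxa
#' analysed, number called significantly heritable, average non-zero
#' heritability, the basis of the host-relatedness estimate (pedigree,
#' SNPs, lineage, twins) and the normalization applied. Studies providing
#' no significance measure (their average uses all estimates, not only
#' significant ones) and studies without per-taxon estimates are flagged.
#'
#' The packaged TSV is checksummed at load time; a mismatch signals a
#' corrupted installation.
#'
#' @param excludeUnvalidated if \code{TRUE}, drop rows flagged as having no
#'   significance measure (sensitivity toggle).
#' @return \code{data.frame} with columns \code{study_number},
#'   \code{host_system}, \code{sub_row}, \code{n_samples}, \code{n_taxa},
#'   \code{n_heritable}, \code{avg_nonzero_h2}, \code{relatedness_basis},
#'   \code{normalization}, \code{no_significance_measure},
#'   \code{per_taxon_estimates_missing}, \code{reference_key}.
#' @export
loadTable1 <- function(excludeUnvalidated = FALSE) {
  path <- system.file("extdata", "table1_studies.tsv", package = "compherit",
                      mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), .TABLE1_MD5))
    stop("packaged study table fails its checksum; reinstall the package")
  df <- utils::read.delim(path, na.strings = "NA", check.names = FALSE)
  bad <- with(df, !is.na(n_heritable) & n_heritable > n_taxa)
  if (any(bad)) stop("invalid study table: more heritable taxa than taxa")
  if (excludeUnvalidated) df <- df[!df$no_significance_measure, ]
  df
}

#' Summary statistics of the study compilation
#'
#' Descriptive summaries of the published heritability estimates: the range
#' of the per-row average non-zero heritability, its mean across studies
#' (rows of multi-row studies are averaged within study first; studies
#' without a value are excluded — the rule is recorded in the output), the
#' range and median of the number of taxa analysed, and the per-study
#' proportion of taxa called heritable.
#'
#' The min/max are invariant to the multi-row averaging rule; the
#' cross-study mean is not, which is why the rule travels with the result.
#'
#' @param records study table from \code{\link{loadTable1}}.
#' @return list with elements \code{avg_h2_min}, \code{avg_h2_max},
#'   \code{avg_h2_mean_across_studies}, \code{averaging_rule},
#'   \code{n_taxa_range}, \code{n_taxa_median},
#'   \code{prop_heritable_by_study} (data.frame).
#' @export
summarizeTable1 <- function(records = loadTable1()) {
  h2 <- records$avg_nonzero_h2
  byStudy <- tapply(h2, records$study_number,
                    function(v) if (all(is.na(v))) NA_real_
                                else mean(v, na.rm = TRUE))
  prop <- do.call(rbind, lapply(split(records, records$study_number),
    function(d) {
      ok <- !is.na(d$n_heritable)
      data.frame(study_number = d$study_number[1],
                 host_system = d$host_system[1],
                 prop_heritable = if (any(ok))
                   sum(d$n_heritable[ok]) / sum(d$n_taxa[ok]) else NA_real_)
    }))
  rownames(prop) <- NULL
  list(
    avg_h2_min = min(h2, na.rm = TRUE),
    avg_h2_max = max(h2, na.rm = TRUE),
    avg_h2_mean_across_studies = mean(byStudy, na.rm = TRUE),
    averaging_rule = "within-study rows averaged first; studies without a value excluded",
    n_taxa_range = range(records$n_taxa),
    n_taxa_median = median(records$n_taxa),
    prop_heritable_by_study = prop
  )
}

#' Does the reported proportion of heritable taxa grow with sample size?
#'
#' Binomial (logistic-link) regression of the number of heritable taxa out
#' of the number analysed on log10 sample size, one trial set per study
#' row, fit by maximum likelihood. A positive slope means larger studies
#' report a larger fraction of their taxa as heritable — the pattern
#' expected when statistical power, not biology, drives the calls.
#'
#' @param records study table from \code{\link{loadTable1}}; rows lacking
#'   either count are dropped.
#' @return list with \code{slope}, \code{slope_se}, \code{p_value},
#'   \code{pseudo_r2} (McFadden, 1 - logLik(model)/logLik(null);
#'   the definition is attached as \code{pseudo_r2_definition}),
#'   \code{n_rows} and the fitted \code{model}.
#' @export
regressProportionHeritable <- function(records = loadTable1()) {
  d <- records[!is.na(records$n_heritable) & !is.na(records$n_taxa), ]
  d$log10_n <- log10(d$n_samples)
  fit <- glm(cbind(n_heritable, n_taxa - n_heritable) ~ log10_n,
             family = binomial(), data = d)
  null <- glm(cbind(n_heritable, n_taxa - n_heritable) ~ 1,
              family = binomial(), data = d)
  co <- summary(fit)$coefficients
  list(slope = co["log10_n", "Estimate"],
       slope_se = co["log10_n", "Std. Error"],
       p_value = co["log10_n", "Pr(>|z|)"],
       pseudo_r2 = 1 - as.numeric(logLik(fit)) / as.numeric(logLik(null)),
       pseudo_r2_definition = "McFadden: 1 - logLik(model)/logLik(null)",
       n_rows = nrow(d), model = fit)
}

#' Does the average reported heritability shrink with sample size?
#'
#' Ordinary least squares of the per-row average non-zero heritability on
#' log10 sample size. A negative slope means larger studies report lower
#' average heritabilities — consistent with publication bias in small
#' studies and/or with large studies sweeping in many weakly (or
#' spuriously) heritable taxa.
#'
#' @param records study table from \code{\link{loadTable1}}; rows lacking
#'   the average are dropped.
#' @return list with \code{slope}, \code{slope_se}, \code{p_value},
#'   \code{r_squared}, \code{n_rows} and the fitted \code{model}.
#' @export
regressAverageHeritability <- function(records = loadTable1()) {
  d <- records[!is.na(records$avg_nonzero_h2), ]
  d$log10_n <- log10(d$n_samples)
  fit <- lm(avg_nonzero_h2 ~ log10_n, data = d)
  co <- summary(fit)$coefficients
  r2 <- summary(fit)$r.squared
  # constant response: nothing to explain (guard against 0/0 round-off)
  if (!is.finite(r2) || var(d$avg_nonzero_h2) < 1e-14) r2 <- 0
  list(slope = co["log10_n", "Estimate"],
       slope_se = co["log10_n", "Std. Error"],
       p_value = co["log10_n", "Pr(>|t|)"],
       r_squared = r2,
       n_rows = nrow(d), model = fit)
}
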