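#' Classify loci as conserved by coefficient of variation
#'
#' A locus is conserved when the total-population coefficient of variation
#' of allele length (population SD divided by mean) is at most
#' `cov_threshold` (inclusive). The default 0.075 deliberately isolates
#' only the least variable loci.
#'
#' @param total_stats baseline rows (any subset with a `cov` column); TOTAL
#'   rows are the intended input.
#' @param cov_threshold inclusive cutoff (default 0.075).
#' @param min_n minimum allele count for the classification to be
#'   meaningful (default 10).
#' @return logical vector, one per row: TRUE when conserved; NA when the
#'   mean is 0 (cov undefined) or the count guard fails.
#' @export
classify_conserved <- function(total_stats, cov_threshold = 0.075, min_n = 10L) {
  ok <- total_stats$n >= min_n & !is.na(total_stats$cov)
  ifelse(ok, total_stats$cov <= cov_threshold, NA)
}

#' Flag outlier expansions at conserved loci
#'
#' Two-stage screen over probands at conserved loci. Stage 1 flags alleles
#' more than `sd_mult` population standard deviations above the total mean
#' (strict). Stage 2 additionally requires the allele to be at least
#' `ratio_min` times the mean (inclusive). Both stage outputs are returned;
#' the `flagged` column marks hits passing both stages. When the locus SD
#' is 0 the z statistic is undefined and the decision falls to the ratio
#' criterion alone.
#'
#' @param proband_calls filter-passing proband calls.
#' @param baseline baseline stats data.frame; TOTAL rows define mean/sd/cov.
#' @param cov_threshold conserved-locus cutoff (see [classify_conserved()]).
#' @param sd_mult standard-deviation multiple for stage 1 (default 3).
#' @param ratio_min allele/mean ratio for stage 2 (default 2.5, i.e. 250%
#'   of the mean).
#' @param min_n minimum allele count per locus.
#' @return data.frame with one row per proband x conserved locus:
#'   chrom, pos, unit, sample, allele_bp (longest), total_mean_bp,
#'   total_sd_bp, cov, z_individual, ratio, stage1 (z criterion), flagged
#'   (both criteria).
#' @export
screen_conserved_outliers <- function(proband_calls, baseline,
                                      cov_threshold = 0.075, sd_mult = 3,
                                      ratio_min = 2.5, min_n = 10L) {
  tot <- baseline[baseline$group == "TOTAL", , drop = FALSE]
  cons <- classify_conserved(tot, cov_threshold, min_n)
  tot <- tot[!is.na(cons) & cons, , drop = FALSE]
  dt <- data.table::as.data.table(proband_calls)
  dt <- dt[!(missing) & !is.na(a1_bp)]
  dt[, allele_bp := pmax(a1_bp, a2_bp)]
  mg <- merge(dt[, .(chrom, pos, unit, sample, allele_bp)],
              data.table::as.data.table(tot[, c("chrom", "pos", "unit",
                                                "mean", "sd", "cov")]),
              by = c("chrom", "pos", "unit"))
  if (nrow(mg) == 0)
    return(data.frame(chrom = character(), pos = integer(), unit = character(),
                      sample = character(), allele_bp = integer(),
                      total_mean_bp = numeric(), total_sd_bp = numeric(),
                      cov = numeric(), z_individual = numeric(),
                      ratio = numeric(), stage1 = logical(), flagged = logical()))
  mg[, z_individual := data.table::fifelse(sd > 0, (allele_bp - mean) / sd, NA_real_)]
  mg[, ratio := allele_bp / mean]
  # sd = 0: z undefined, stage 1 decided by the ratio criterion alone
  mg[, stage1 := data.table::fifelse(sd > 0, allele_bp > mean + sd_mult * sd,
                                     ratio >= ratio_min)]
  mg[, flagged := stage1 & ratio >= ratio_min]
  out <- as.data.frame(mg[, .(chrom, pos, unit, sample, allele_bp,
                              total_mean_bp = mean, total_sd_bp = sd, cov,
                              z_individual, ratio, stage1, flagged)])
  out[order(out$chrom, out$pos, out$sample), , drop = FALSE]
}

#' Evaluate the conserved-outlier criteria on given summary values
#'
#' Direct evaluation of both the conservation and outlier criteria from a
#' locus's printed summary (mean, coefficient of variation) and one
#' individual's longest allele — useful for auditing published rows where
#' the raw calls are unavailable.
#'
#' @param allele_bp longest allele length (bp).
#' @param mean_bp total-population mean allele length (bp).
#' @param cov coefficient of variation (sd/mean).
#' @param cov_threshold,sd_mult,ratio_min as in
#'   [screen_conserved_outliers()].
#' @param interpretation `"ratio"` (default): at least `ratio_min` x mean;
#'   `"difference"`: (allele - mean)/mean >= `ratio_min`.
#' @return data.frame: conserved, z_individual, ratio, stage1, flagged.
#' @export
evaluate_conserved_criteria <- function(allele_bp, mean_bp, cov,
                                        cov_threshold = 0.075, sd_mult = 3,
                                        ratio_min = 2.5,
                                        interpretation = c("ratio", "difference")) {
  interpretation <- match.arg(interpretation)
  sd_bp <- cov * mean_bp
  z <- ifelse(sd_bp > 0, (allele_bp - mean_bp) / sd_bp, NA_real_)
  ratio <- allele_bp / mean_bp
  size_crit <- if (interpretation == "ratio") ratio >= ratio_min
               else (allele_bp - mean_bp) / mean_bp >= ratio_min
  stage1 <- ifelse(is.na(z), size_crit, allele_bp > mean_bp + sd_mult * sd_bp)
  data.frame(conserved = cov <= cov_threshold, z_individual = z, ratio = ratio,
             stage1 = stage1, flagged = stage1 & size_crit)
}
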