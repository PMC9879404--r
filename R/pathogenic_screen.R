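#' Screen probands at catalogued pathogenic STR loci
#'
#' For each proband and each catalog locus, the longest proband allele is
#' compared with the total-population mean allele length at that locus. A
#' hit is *divergent* when allele / mean >= `ratio_threshold` (inclusive)
#' and *exceeds-pathogenic* when the allele is strictly longer than the
#' locus's published pathogenic length. The two flags are independent: an
#' allele can exceed the pathogenic cutoff without meeting the ratio when
#' the population mean is already high, and vice versa.
#'
#' @param proband_calls filter-passing calls restricted to probands.
#' @param catalog pathogenic-locus catalog from
#'   [read_pathogenic_catalog()].
#' @param baseline baseline stats data.frame; only TOTAL rows are used.
#' @param ratio_threshold divergence cutoff on allele/mean (default 1.5,
#'   i.e. 150% of the mean; 2.5 selects the stricter 250% reading).
#' @param alleles `"longest"` (default) screens the longer allele per call;
#'   `"both"` screens each allele separately.
#' @param assignment optional named primary-ancestry vector for the
#'   ancestry column of the hits.
#' @return data.frame of hits (one row per proband x catalog locus with a
#'   non-missing call): sample, gene, chrom, pos, unit, allele_bp,
#'   total_mean_bp, ratio, divergent, pathogenic_bp, exceeds_pathogenic,
#'   ancestry. Catalog loci absent from the baseline are skipped with a
#'   warning.
#' @export
screen_pathogenic <- function(proband_calls, catalog, baseline,
                              ratio_threshold = 1.5,
                              alleles = c("longest", "both"),
                              assignment = NULL) {
  alleles <- match.arg(alleles)
  tot <- baseline[baseline$group == "TOTAL", , drop = FALSE]
  tot_key <- locus_key(tot$chrom, tot$pos, tot$unit)
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    rec <- catalog[i, ]
    kidx <- match(locus_key(rec$chrom, rec$pos, rec$unit), tot_key)
    if (is.na(kidx)) {
      warnf("catalog locus %s (%s) absent from baseline; skipped",
            rec$gene, locus_key(rec$chrom, rec$pos, rec$unit))
      next
    }
    m <- tot$mean[kidx]
    sub <- proband_calls[proband_calls$chrom == rec$chrom &
                           proband_calls$pos == rec$pos &
                           proband_calls$unit == rec$unit &
                           !proband_calls$missing, , drop = FALSE]
    if (nrow(sub) == 0) next
    if (alleles == "longest") {
      al <- pmax(sub$a1_bp, sub$a2_bp)
      ids <- sub$sample
    } else {
      al <- c(sub$a1_bp, sub$a2_bp)
      ids <- rep(sub$sample, 2)
    }
    out[[length(out) + 1L]] <- data.frame(
      sample = ids, gene = rec$gene, chrom = rec$chrom, pos = rec$pos,
      unit = rec$unit, allele_bp = al, total_mean_bp = m,
      ratio = al / m, divergent = al / m >= ratio_threshold,
      pathogenic_bp = rec$pathogenic_bp,
      exceeds_pathogenic = al > rec$pathogenic_bp,
      ancestry = if (is.null(assignment)) NA_character_ else
        unname(assignment[ids]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(), gene = character(), chrom = character(),
               pos = integer(), unit = character(), allele_bp = integer(),
               total_mean_bp = numeric(), ratio = numeric(),
               divergent = logical(), pathogenic_bp = integer(),
               exceeds_pathogenic = logical(), ancestry = character())
  row.names(out) <- NULL
  out
}

#' Per-gene summary of pathogenic-screen hits
#'
#' Counts divergent hits and pathogenic exceedances per gene, with the
#' ancestry breakdown AMR : EUR : Other, where AMR pools Admixed and
#' Non-admixed Americans and Other pools the remaining groups.
#'
#' @param hits output of [screen_pathogenic()].
#' @return data.frame: gene, n_divergent, n_exceeds_pathogenic, n_AMR,
#'   n_EUR, n_Other, breakdown ("AMR:EUR:Other" over divergent hits).
#' @export
summarize_pathogenic_by_gene <- function(hits) {
  genes <- unique(hits$gene)
  rows <- lapply(genes, function(g) {
    h <- hits[hits$gene == g & hits$divergent, , drop = FALSE]
    amr <- sum(h$ancestry %in% c("AdmixedAMR", "NonadmixedAMR"), na.rm = TRUE)
    eur <- sum(h$ancestry == "EUR", na.rm = TRUE)
    oth <- nrow(h) - amr - eur
    data.frame(gene = g,
               n_divergent = nrow(h),
               n_exceeds_pathogenic = sum(hits$gene == g & hits$divergent &
                                            hits$exceeds_pathogenic),
               n_AMR = amr, n_EUR = eur, n_Other = oth,
               breakdown = paste(amr, eur, oth, sep = ":"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), n_divergent = integer(),
                      n_exceeds_pathogenic = integer(), n_AMR = integer(),
                      n_EUR = integer(), n_Other = integer(),
                      breakdown = character())
  row.names(out) <- NULL
  out
}

#' Ancestral mean allele length at pathogenic loci
#'
#' @param baseline baseline stats data.frame.
#' @param catalog pathogenic catalog.
#' @return data.frame: gene x ancestry group mean allele length (bp); one
#'   row per (gene, group) present in the baseline at that locus.
#' @export
pathogenic_ancestral_means <- function(baseline, catalog) {
  bkey <- locus_key(baseline$chrom, baseline$pos, baseline$unit)
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    rec <- catalog[i, ]
    sub <- baseline[bkey == locus_key(rec$chrom, rec$pos, rec$unit) &
                      baseline$group != "TOTAL", , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    data.frame(gene = rec$gene, group = sub$group, n = sub$n,
               mean_bp = sub$mean, se_bp = sub$se, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), group = character(), n = integer(),
                      mean_bp = numeric(), se_bp = numeric())
  row.names(out) <- NULL
  out
}
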