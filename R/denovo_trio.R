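#' Detect candidate de novo STR events in one trio at one locus
#'
#' An *expansion* is emitted when the proband's longest allele is strictly
#' greater than twice the longest allele across both parents; a
#' *contraction* when the proband's shortest allele is strictly less than
#' half the shortest allele across both parents. Both can co-occur at one
#' locus. Small stepwise mutations (a single repeat unit) are by design
#' invisible to this rule.
#'
#' @param proband,mother,father one-row calls for the three members at one
#'   locus; all must be non-missing (the caller is expected to have applied
#'   call filters to all three).
#' @return data.frame of 0-2 events: type ("expansion"/"contraction"),
#'   proband_allele_bp, parental_extreme_bp, fold (proband/parental for
#'   expansions, parental/proband for contractions).
#' @export
detect_denovo <- function(proband, mother, father) {
  stopifnot(nrow(proband) == 1, nrow(mother) == 1, nrow(father) == 1)
  if (any(c(proband$missing, mother$missing, father$missing)))
    stopf("detect_denovo requires non-missing calls for all trio members")
  par_alleles <- c(mother$a1_bp, mother$a2_bp, father$a1_bp, father$a2_bp)
  pro_max <- max(proband$a1_bp, proband$a2_bp)
  pro_min <- min(proband$a1_bp, proband$a2_bp)
  par_max <- max(par_alleles); par_min <- min(par_alleles)
  out <- list()
  if (pro_max > 2 * par_max)
    out[[length(out) + 1L]] <- data.frame(type = "expansion",
                                          proband_allele_bp = pro_max,
                                          parental_extreme_bp = par_max,
                                          fold = pro_max / par_max)
  if (pro_min < 0.5 * par_min)
    out[[length(out) + 1L]] <- data.frame(type = "contraction",
                                          proband_allele_bp = pro_min,
                                          parental_extreme_bp = par_min,
                                          fold = par_min / pro_min)
  if (length(out)) do.call(rbind, out) else
    data.frame(type = character(), proband_allele_bp = integer(),
               parental_extreme_bp = integer(), fold = numeric())
}

#' Scan all trios for de novo STR events
#'
#' Vectorised genome-wide application of the trio rule: a locus contributes
#' for a family only when all three members have filter-passing,
#' non-missing calls there; incomplete loci are counted, not errors.
#'
#' @param calls filter-passing calls for the whole cohort.
#' @param trios complete-trio table from [trio_table()].
#' @return list with `events` (data.frame: family, proband, chrom, pos,
#'   unit, type, proband_allele_bp, parental_extreme_bp, fold),
#'   `per_proband` (family, proband, n_expansions, n_contractions),
#'   `summary` (n_events, n_expansions, n_contractions, mean/min/max
#'   expansions per proband, n_incomplete_locus_family pairs skipped).
#' @export
scan_trios <- function(calls, trios) {
  dt <- data.table::as.data.table(calls)
  dt <- dt[!(missing) & !is.na(a1_bp)]
  dt[, `:=`(amax = pmax(a1_bp, a2_bp), amin = pmin(a1_bp, a2_bp))]
  slim <- dt[, .(chrom, pos, unit, sample, amax, amin)]

  ev <- list(); skipped <- 0L
  per <- data.frame(family = trios$family, proband = trios$proband,
                    n_expansions = 0L, n_contractions = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(trios))) {
    tr <- trios[i, ]
    pro <- slim[sample == tr$proband]
    mo <- slim[sample == tr$mother]
    fa <- slim[sample == tr$father]
    j <- merge(merge(pro, mo, by = c("chrom", "pos", "unit"),
                     suffixes = c("_p", "_m")),
               fa, by = c("chrom", "pos", "unit"))
    n_union <- length(unique(c(locus_key(pro$chrom, pro$pos, pro$unit),
                               locus_key(mo$chrom, mo$pos, mo$unit),
                               locus_key(fa$chrom, fa$pos, fa$unit))))
    skipped <- skipped + n_union - nrow(j)
    if (nrow(j) == 0) next
    par_max <- pmax(j$amax_m, j$amax)
    par_min <- pmin(j$amin_m, j$amin)
    exp_hit <- j$amax_p > 2 * par_max
    con_hit <- j$amin_p < 0.5 * par_min
    if (any(exp_hit))
      ev[[length(ev) + 1L]] <- data.frame(
        family = tr$family, proband = tr$proband,
        chrom = j$chrom[exp_hit], pos = j$pos[exp_hit], unit = j$unit[exp_hit],
        type = "expansion", proband_allele_bp = j$amax_p[exp_hit],
        parental_extreme_bp = par_max[exp_hit],
        fold = j$amax_p[exp_hit] / par_max[exp_hit], stringsAsFactors = FALSE)
    if (any(con_hit))
      ev[[length(ev) + 1L]] <- data.frame(
        family = tr$family, proband = tr$proband,
        chrom = j$chrom[con_hit], pos = j$pos[con_hit], unit = j$unit[con_hit],
        type = "contraction", proband_allele_bp = j$amin_p[con_hit],
        parental_extreme_bp = par_min[con_hit],
        fold = par_min[con_hit] / j$amin_p[con_hit], stringsAsFactors = FALSE)
    per$n_expansions[i] <- sum(exp_hit)
    per$n_contractions[i] <- sum(con_hit)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(family = character(), proband = character(), chrom = character(),
               pos = integer(), unit = character(), type = character(),
               proband_allele_bp = integer(), parental_extreme_bp = integer(),
               fold = numeric())
  events <- events[order(events$chrom, events$pos, events$family), , drop = FALSE]
  row.names(events) <- NULL
  exp_counts <- per$n_expansions
  list(events = events, per_proband = per,
       summary = list(n_events = nrow(events),
                      n_expansions = sum(per$n_expansions),
                      n_contractions = sum(per$n_contractions),
                      mean_expansions_per_proband = mean(exp_counts),
                      min_expansions_per_proband = if (length(exp_counts)) min(exp_counts) else NA,
                      max_expansions_per_proband = if (length(exp_counts)) max(exp_counts) else NA,
                      n_incomplete_locus_family = skipped))
}

#' Correlation of per-proband de novo counts with parental age
#'
#' Pearson correlation of the number of de novo expansions per proband
#' against maternal and paternal age.
#'
#' @param per_proband per-proband count table from [scan_trios()].
#' @param ages data.frame with columns proband, mother_age, father_age.
#' @param count_col which count column to correlate
#'   (default "n_expansions").
#' @return data.frame with one row per parent: parent, n, r, p_value;
#'   r is NA (reported as undefined) when fewer than 3 complete pairs exist
#'   or a variable has zero variance.
#' @export
parental_age_summary <- function(per_proband, ages, count_col = "n_expansions") {
  m <- merge(per_proband, ages, by = "proband")
  one <- function(parent, age) {
    ok <- is.finite(m[[count_col]]) & is.finite(age)
    n <- sum(ok)
    if (n < 3 || sd(m[[count_col]][ok]) == 0 || sd(age[ok]) == 0)
      return(data.frame(parent = parent, n = n, r = NA_real_, p_value = NA_real_))
    ct <- cor.test(m[[count_col]][ok], age[ok])
    data.frame(parent = parent, n = n, r = unname(ct$estimate),
               p_value = ct$p.value)
  }
  out <- rbind(one("mother", m$mother_age), one("father", m$father_age))
  row.names(out) <- NULL
  out
}
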