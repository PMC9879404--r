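#' Divergence of a group's mean allele length from the European mean
#'
#' The screen statistic is z = (mean_group - mean_EUR) / sd_EUR: the number
#' of European standard deviations separating the group mean from the
#' European mean at a locus. The companion normalisation is the relative
#' difference pct = |mean_group - mean_EUR| / mean_EUR. A locus is divergent
#' when |z| > `z_threshold` AND pct > `pct_threshold` (both strict).
#'
#' @param group_stats one-row baseline record (n, mean, sd) for the
#'   non-European group at a locus.
#' @param eur_stats one-row baseline record for EUR at the same locus.
#' @param z_threshold absolute z cutoff (default 5).
#' @param pct_threshold relative-difference cutoff as a fraction
#'   (default 0.20).
#' @param min_n minimum allele count required in each group (default 10);
#'   loci failing the guard return NA flags.
#' @return data.frame row: z, pct_diff, mean_group, mean_eur, divergent.
#'   With sd_EUR = 0 and unequal means, z is +/-Inf and divergence is
#'   decided by the pct criterion alone; with mean_EUR = 0 the locus is
#'   undefined (NA).
#' @export
divergence_test <- function(group_stats, eur_stats, z_threshold = 5,
                            pct_threshold = 0.20, min_n = 10L) {
  m_g <- group_stats$mean; m_e <- eur_stats$mean; s_e <- eur_stats$sd
  if (group_stats$n < min_n || eur_stats$n < min_n || m_e == 0) {
    return(data.frame(z = NA_real_, pct_diff = NA_real_, mean_group = m_g,
                      mean_eur = m_e, divergent = NA))
  }
  z <- (m_g - m_e) / s_e            # Inf when sd_EUR = 0 and means differ
  if (s_e == 0 && m_g == m_e) z <- 0
  pct <- abs(m_g - m_e) / m_e
  div <- if (is.infinite(z)) pct > pct_threshold
         else abs(z) > z_threshold && pct > pct_threshold
  data.frame(z = z, pct_diff = pct, mean_group = m_g, mean_eur = m_e,
             divergent = div)
}

#' Screen all loci of a baseline for ancestry divergence
#'
#' @param baseline baseline stats data.frame (see
#'   [build_population_baseline()]).
#' @param group target ancestry group (must not be EUR).
#' @param two_sample use a two-sample z with combined standard errors,
#'   z = (mean_g - mean_e) / sqrt(se_g^2 + se_e^2), instead of the default
#'   European-SD denominator.
#' @inheritParams divergence_test
#' @return list with `divergent` (records meeting both criteria),
#'   `scatter` (per-locus table of mean_eur vs mean_group with z and
#'   pct_diff, for plotting), and `n_tested`.
#' @export
screen_divergence <- function(baseline, group, z_threshold = 5,
                              pct_threshold = 0.20, min_n = 10L,
                              two_sample = FALSE) {
  if (group == "EUR") stopf("divergence against EUR itself is undefined")
  target_group <- group
  dt <- data.table::as.data.table(baseline)
  g <- dt[dt$group == target_group]
  e <- dt[dt$group == "EUR"]
  mg <- merge(g, e, by = c("chrom", "pos", "unit"), suffixes = c("_g", "_e"))
  mg <- mg[n_g >= min_n & n_e >= min_n & mean_e > 0]
  if (two_sample) {
    mg[, z := (mean_g - mean_e) / sqrt(se_g^2 + se_e^2)]
  } else {
    mg[, z := data.table::fifelse(sd_e == 0 & mean_g == mean_e, 0,
                                  (mean_g - mean_e) / sd_e)]
  }
  mg[, pct_diff := abs(mean_g - mean_e) / mean_e]
  mg[, divergent := data.table::fifelse(is.infinite(z), pct_diff > pct_threshold,
                                        abs(z) > z_threshold & pct_diff > pct_threshold)]
  scatter <- as.data.frame(mg[, .(chrom, pos, unit, group = target_group,
                                  mean_eur = mean_e, mean_group = mean_g,
                                  z, pct_diff, divergent)])
  list(divergent = scatter[scatter$divergent, , drop = FALSE],
       scatter = scatter, n_tested = nrow(scatter))
}

#' Top divergent loci by absolute z
#'
#' @param records divergent records from [screen_divergence()].
#' @param k number of loci to keep (default 20).
#' @return the k highest-|z| records, ties broken by pct_diff (descending)
#'   then locus key (ascending), so the ranking is deterministic.
#' @export
top_divergent <- function(records, k = 20L) {
  if (nrow(records) == 0) return(records)
  ord <- order(-abs(records$z), -records$pct_diff,
               locus_key(records$chrom, records$pos, records$unit))
  out <- records[ord, , drop = FALSE][seq_len(min(k, nrow(records))), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Loci shared between per-group top-divergent lists
#'
#' @param top_lists named list of per-group record data.frames (each with
#'   chrom, pos, unit).
#' @return data.frame: locus key columns, `groups` (comma-separated groups
#'   sharing the locus), `n_groups`; only loci present in >= 2 lists.
#' @export
shared_loci <- function(top_lists) {
  stopifnot(length(top_lists) >= 2)
  keyed <- lapply(names(top_lists), function(g) {
    r <- top_lists[[g]]
    if (nrow(r) == 0) return(NULL)
    data.frame(key = locus_key(r$chrom, r$pos, r$unit), chrom = r$chrom,
               pos = r$pos, unit = r$unit, group = g, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, keyed)
  if (is.null(all))
    return(data.frame(chrom = character(), pos = integer(), unit = character(),
                      groups = character(), n_groups = integer()))
  sp <- split(all, all$key)
  out <- do.call(rbind, lapply(sp, function(s) {
    if (length(unique(s$group)) < 2) return(NULL)
    data.frame(chrom = s$chrom[1], pos = s$pos[1], unit = s$unit[1],
               groups = paste(sort(unique(s$group)), collapse = ","),
               n_groups = length(unique(s$group)), stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(), unit = character(),
                      groups = character(), n_groups = integer())
  row.names(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}
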