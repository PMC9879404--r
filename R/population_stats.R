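#' Per-locus allele-length statistics per ancestry group
#'
#' Pools both alleles of every filter-passing call (the pooled-allele
#' convention; a longest-allele-only mode is available) and computes, for
#' each locus and each ancestry group plus the pooled TOTAL: allele count,
#' mean length, population standard deviation (divisor n), coefficient of
#' variation sd/mean, and standard error sd/sqrt(n).
#'
#' @param calls filter-passing calls data.frame (see [filter_cohort()]).
#' @param assignment named character vector mapping sample id to primary
#'   ancestry group. Every sample present in `calls` must be assigned.
#' @param alleles `"both"` (default) pools the two alleles per call;
#'   `"longest"` uses only the longer allele.
#' @return data.frame with one row per (locus, group) and per (locus,
#'   TOTAL): chrom, pos, unit, group, n, mean, sd, cov, se. Groups with no
#'   alleles at a locus are omitted; `cov` is NA when the mean is 0.
#' @examples
#' # alleles 8 and 12 at one locus: mean 10, population sd 2, cov 0.2
#' @export
compute_group_stats <- function(calls, assignment, alleles = c("both", "longest")) {
  alleles <- match.arg(alleles)
  unknown <- setdiff(unique(calls$sample), names(assignment))
  if (length(unknown))
    stopf("sample(s) without ancestry assignment: %s", unknown[1])
  long <- .allele_long(calls, alleles)
  long[, group := assignment[sample]]
  per_group <- .agg_stats(long, by_group = TRUE)
  total <- .agg_stats(long, by_group = FALSE)
  out <- rbind(per_group, total)
  data.table::setorder(out, chrom, pos, unit, group)
  as.data.frame(out)
}

# long table of single alleles: one row per contributing allele
.allele_long <- function(calls, alleles = "both") {
  dt <- data.table::as.data.table(calls)
  dt <- dt[!(missing) & !is.na(a1_bp) & !is.na(a2_bp)]
  if (alleles == "both") {
    long <- rbind(dt[, .(chrom, pos, unit, sample, len = a1_bp)],
                  dt[, .(chrom, pos, unit, sample, len = a2_bp)])
  } else {
    long <- dt[, .(chrom, pos, unit, sample, len = pmax(a1_bp, a2_bp))]
  }
  long
}

.agg_stats <- function(long, by_group) {
  by <- if (by_group) c("chrom", "pos", "unit", "group") else c("chrom", "pos", "unit")
  st <- long[, {
    n <- .N
    m <- mean(len)
    s <- sqrt(sum((len - m)^2) / n)   # population SD, divisor n
    .(n = n, mean = m, sd = s,
      cov = if (m > 0) s / m else NA_real_,
      se = s / sqrt(n))
  }, by = by]
  if (!by_group) st[, group := "TOTAL"]
  data.table::setcolorder(st, c("chrom", "pos", "unit", "group", "n", "mean", "sd", "cov", "se"))
  st
}

#' Allele tally at one locus
#'
#' @param calls calls at a single locus.
#' @param alleles pooling convention as in [compute_group_stats()].
#' @return table of allele length (bp) to count.
#' @export
allele_tally <- function(calls, alleles = "both") {
  long <- .allele_long(calls, match.arg(alleles, c("both", "longest")))
  table(long$len)
}

#' Population-cohort membership
#'
#' The population cohort comprises all parents plus only those probands
#' whose parents are absent from the data set; siblings are excluded.
#'
#' @param ped pedigree data.frame from [read_pedigree()].
#' @return character vector of sample ids in the population cohort.
#' @export
population_cohort <- function(ped) {
  parents <- ped$sample[ped$role %in% c("mother", "father")]
  pro <- ped[ped$role == "proband", , drop = FALSE]
  orphan <- !(pro$mother %in% ped$sample) & !(pro$father %in% ped$sample)
  c(parents, pro$sample[orphan])
}

#' Build the per-locus per-group baseline from a cohort
#'
#' Applies the population-cohort membership rule, restricts calls to that
#' cohort, and computes [compute_group_stats()] over it. This baseline is
#' the comparative metric for every downstream screen.
#'
#' @param calls filter-passing calls for the whole data set.
#' @param ped pedigree data.frame.
#' @param assignment named primary-ancestry vector (sample -> group).
#' @param alleles pooling convention.
#' @return list with `stats` (the baseline data.frame) and `members`
#'   (the population-cohort sample ids actually present in `calls`).
#' @export
build_population_baseline <- function(calls, ped, assignment, alleles = "both") {
  members <- intersect(population_cohort(ped), unique(calls$sample))
  if (length(members) == 0) stopf("population cohort is empty")
  sub <- calls[calls$sample %in% members, , drop = FALSE]
  list(stats = compute_group_stats(sub, assignment, alleles = alleles),
       members = members)
}

#' Read / write a baseline statistics store
#'
#' TSV keyed by locus x group with columns chrom, pos, unit, group, n,
#' mean, sd, cov, se.
#'
#' @param stats baseline data.frame.
#' @param path TSV path.
#' @export
write_baseline <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
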