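#' Call-level filter parameters
#'
#' Defaults mirror the dumpSTR-style parameter set used for STR call-level
#' quality control: depth within \[50, 1000\], genotype quality at least
#' 0.90, supporting (length-bounding) reads required, and the
#' maximum-likelihood genotype required to fall inside its 95% bootstrap
#' confidence interval. All keep-side inequalities are inclusive.
#'
#' @param min_depth minimum call depth (keep when depth >= this).
#' @param max_depth maximum call depth (keep when depth <= this).
#' @param min_quality minimum genotype quality, in \[0,1\].
#' @param require_supported_reads drop calls whose evidence consists only of
#'   spanning/flanking reads, i.e. with zero enclosing and zero
#'   fully-repetitive reads. The read classes counted as "supporting" can be
#'   changed via `supporting_classes`.
#' @param require_ml_in_ci drop calls where either allele's length falls
#'   outside its own 95% bootstrap confidence interval.
#' @param supporting_classes read-class columns that bound allele length.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(min_depth = 50L, max_depth = 1000L, min_quality = 0.90,
                          require_supported_reads = TRUE, require_ml_in_ci = TRUE,
                          supporting_classes = c("n_enclosing", "n_frr")) {
  stopifnot(min_depth >= 0, min_depth <= max_depth,
            min_quality >= 0, min_quality <= 1)
  structure(list(min_depth = as.integer(min_depth),
                 max_depth = as.integer(max_depth),
                 min_quality = min_quality,
                 require_supported_reads = isTRUE(require_supported_reads),
                 require_ml_in_ci = isTRUE(require_ml_in_ci),
                 supporting_classes = supporting_classes),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat("STR call filters: depth in [", x$min_depth, ",", x$max_depth,
      "], quality >=", x$min_quality,
      if (x$require_supported_reads) ", supporting reads required" else "",
      if (x$require_ml_in_ci) ", ML genotype within 95% CI" else "", "\n")
  invisible(x)
}

# vectorised evaluation of every sub-filter; returns a logical matrix of
# failures (rows = calls) so that `reasons` can list all of them, not just
# the first
.filter_matrix <- function(calls, params) {
  n <- nrow(calls)
  fail <- cbind(
    missing = calls$missing | is.na(calls$a1_bp) | is.na(calls$a2_bp),
    min_depth = !is.na(calls$depth) & calls$depth < params$min_depth,
    max_depth = !is.na(calls$depth) & calls$depth > params$max_depth,
    min_quality = !is.na(calls$quality) & calls$quality < params$min_quality,
    no_supporting_reads = rep(FALSE, n),
    ml_outside_ci = rep(FALSE, n)
  )
  if (params$require_supported_reads) {
    supp <- Reduce(`+`, lapply(params$supporting_classes, function(cl) {
      v <- calls[[cl]]
      ifelse(is.na(v), 0L, v)
    }))
    fail[, "no_supporting_reads"] <- !fail[, "missing"] & supp == 0L
  }
  if (params$require_ml_in_ci) {
    out1 <- calls$a1_bp < calls$ci1_lo_bp | calls$a1_bp > calls$ci1_hi_bp
    out2 <- calls$a2_bp < calls$ci2_lo_bp | calls$a2_bp > calls$ci2_hi_bp
    bad <- (out1 | out2)
    bad[is.na(bad)] <- FALSE
    fail[, "ml_outside_ci"] <- !fail[, "missing"] & bad
  }
  fail
}

#' Apply call-level filters to one call
#'
#' @param call a one-row calls data.frame (see [read_str_vcf()]).
#' @param params a [filter_params()] object.
#' @return list with `keep` (logical) and `reasons` (character vector of all
#'   failed sub-filters; empty when kept). Missing genotypes are always
#'   dropped with reason `"missing"`.
#' @export
filter_call <- function(call, params = filter_params()) {
  fail <- .filter_matrix(call, params)
  list(keep = !any(fail[1, ]), reasons = colnames(fail)[fail[1, ]])
}

#' Vectorised filter over a calls table
#'
#' @param calls calls data.frame.
#' @param params a [filter_params()] object.
#' @return `calls` with columns `keep` (logical) and `reasons`
#'   (comma-separated failed sub-filters, `""` when kept) appended.
#' @export
filter_calls <- function(calls, params = filter_params()) {
  fail <- .filter_matrix(calls, params)
  calls$keep <- rowSums(fail) == 0L
  reasons <- character(nrow(calls))
  bad <- which(!calls$keep)
  if (length(bad))
    reasons[bad] <- apply(fail[bad, , drop = FALSE], 1L,
                          function(r) paste(colnames(fail)[r], collapse = ","))
  calls$reasons <- reasons
  calls
}

#' Filter a multi-sample call set and summarise drop reasons
#'
#' @param calls calls data.frame (any number of loci and samples).
#' @param params a [filter_params()] object.
#' @return list with `kept` (the surviving calls, original columns),
#'   `dropped` (the removed calls with their `reasons`), and `summary`
#'   (data.frame of per-reason drop counts; a call failing several
#'   sub-filters counts once under each). `n_input = n_kept + n_dropped`
#'   always holds.
#' @export
filter_cohort <- function(calls, params = filter_params()) {
  fail <- .filter_matrix(calls, params)
  keep <- rowSums(fail) == 0L
  kept <- calls[keep, , drop = FALSE]
  dropped <- calls[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    dfail <- fail[!keep, , drop = FALSE]
    dropped$reasons <- apply(dfail, 1L,
                             function(r) paste(colnames(fail)[r], collapse = ","))
  } else dropped$reasons <- character(0)
  row.names(kept) <- row.names(dropped) <- NULL
  summary <- data.frame(reason = colnames(fail),
                        n = colSums(fail[!keep, , drop = FALSE]),
                        row.names = NULL)
  list(kept = kept, dropped = dropped, summary = summary,
       n_input = nrow(calls), n_kept = nrow(kept), n_dropped = nrow(dropped))
}
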