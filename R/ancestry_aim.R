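#' Estimate 4-way genetic admixture from AIM SNP genotypes
#'
#' Supervised maximum-likelihood admixture estimation under the standard
#' binomial-mixture model: each of an individual's two allele copies at
#' marker i carries the alternate allele with probability
#' p_i = sum_k q_k f_ki, where f_ki is the alternate-allele frequency of
#' reference superpopulation k (AFR, EUR, EAS, AMR) and q is the admixture
#' vector on the 3-simplex. The log-likelihood
#' sum_i \[ g_i log p_i + (2 - g_i) log(1 - p_i) \] is maximised by EM from a
#' fixed uniform initialisation, so the result is deterministic for fixed
#' input. Panel frequencies are clamped away from 0 and 1 to keep the
#' likelihood finite at fixed alleles.
#'
#' @param genotypes numeric vector of alternate-allele dosages in
#'   \{0, 1, 2\} (NA = missing), one per panel marker, in panel order.
#' @param panel an `aim_panel` (see [read_aim_panel()]): a markers x 4
#'   frequency matrix with columns AFR, EUR, EAS, AMR.
#' @param eps frequency clamp; frequencies are confined to \[eps, 1 - eps\].
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return an object of class `admixture_fit` with elements `q` (named
#'   4-vector, non-negative, summing to 1), `loglik`, `n_markers_used`,
#'   `n_iter`, `converged`, and `identifiable` (FALSE when the panel carries
#'   no frequency contrast, in which case `q` is uniform).
#' @examples
#' f <- matrix(runif(40, 0.05, 0.95), 10, 4, dimnames = list(NULL, c("AFR","EUR","EAS","AMR")))
#' g <- rbinom(10, 2, f[, "AFR"])
#' estimate_admixture(g, f)
#' @export
estimate_admixture <- function(genotypes, panel, eps = 1e-3, tol = 1e-12,
                               max_iter = 2000L) {
  f <- if (inherits(panel, "aim_panel")) panel$freqs else panel
  f <- as.matrix(f)
  if (ncol(f) != 4) stopf("panel must have four population columns, got %d", ncol(f))
  if (is.null(colnames(f))) colnames(f) <- AIM_POPS
  if (length(genotypes) != nrow(f))
    stopf("genotype vector length (%d) != panel size (%d)", length(genotypes), nrow(f))
  use <- !is.na(genotypes)
  if (!any(use)) stopf("no non-missing genotypes overlap the panel")
  g <- as.numeric(genotypes[use])
  if (any(g < 0 | g > 2)) stopf("dosages must lie in {0,1,2}")
  f <- clamp(f[use, , drop = FALSE], eps, 1 - eps)
  m <- nrow(f)

  identifiable <- max(apply(f, 1L, function(r) diff(range(r)))) > 1e-12

  q <- rep(1 / 4, 4)
  ll_old <- -Inf; it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    p <- as.vector(f %*% q)
    ll <- sum(g * log(p) + (2 - g) * log1p(-p))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (it > max_iter) break
    ll_old <- ll
    # E-step responsibilities per allele copy, M-step in one pass
    r_alt <- sweep(f, 2L, q, `*`) / p
    r_ref <- sweep(1 - f, 2L, q, `*`) / (1 - p)
    q <- (colSums(g * r_alt) + colSums((2 - g) * r_ref)) / (2 * m)
    q <- q / sum(q)
  }
  names(q) <- colnames(f)
  structure(list(q = q, loglik = ll, n_markers_used = m, n_iter = it,
                 converged = converged, identifiable = identifiable),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, digits = 3, ...) {
  cat("Supervised admixture fit (", x$n_markers_used, " markers, ",
      x$n_iter, " EM iterations)\n", sep = "")
  print(round(x$q, digits))
  cat("log-likelihood:", format(x$loglik, digits = 8),
      if (!x$identifiable) " [non-identifiable panel: uniform q]" else "", "\n")
  invisible(x)
}

#' @export
coef.admixture_fit <- function(object, ...) object$q

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$loglik, df = 3, class = "logLik")
}

#' Assign primary and secondary ancestry from an admixture vector
#'
#' Rules, applied in order: (1) Pacific Islander self-report takes
#' precedence (PAC is assigned from self-reported ethnicity, not markers);
#' (2) AMR fraction > 0.75 gives NonadmixedAMR; (3) a component > 0.60 is
#' the primary ancestry (AMR maps to AdmixedAMR); (4) a maximum in
#' \[0.50, 0.60\] gives that primary plus the second-largest component as
#' secondary ancestry; (5) otherwise unassigned. Argmax ties break in the
#' fixed order AFR, EUR, EAS, AMR.
#'
#' @param q an `admixture_fit`, or a named/ordered numeric 4-vector
#'   (AFR, EUR, EAS, AMR) summing to 1.
#' @param self_report optional self-reported ancestry label; only
#'   `"PAC"`/`"Pacific Islander"` affects assignment.
#' @return list with `primary` (one of AFR, EUR, EAS, AdmixedAMR,
#'   NonadmixedAMR, PAC, unassigned) and `secondary` (label or NA).
#' @export
assign_ancestry <- function(q, self_report = NA) {
  if (inherits(q, "admixture_fit")) q <- q$q
  stopifnot(length(q) == 4)
  if (is.null(names(q))) names(q) <- AIM_POPS
  q <- q[AIM_POPS]
  lab <- function(p) if (p == "AMR") "AdmixedAMR" else p
  if (!is.na(self_report) && self_report %in% c("PAC", "Pacific Islander"))
    return(list(primary = "PAC", secondary = NA_character_))
  if (q[["AMR"]] > 0.75)
    return(list(primary = "NonadmixedAMR", secondary = NA_character_))
  ord <- order(-q, match(names(q), AIM_POPS))
  top <- q[ord[1]]
  if (top > 0.60)
    return(list(primary = lab(names(top)), secondary = NA_character_))
  if (top >= 0.50)
    return(list(primary = lab(names(top)), secondary = lab(names(q)[ord[2]])))
  list(primary = "unassigned", secondary = NA_character_)
}

#' Estimate admixture and assign ancestry for a cohort
#'
#' @param genotypes samples x markers dosage matrix (rownames = sample ids).
#' @param panel an `aim_panel` or frequency matrix.
#' @param self_report optional named character vector of self-reported
#'   ancestry labels, indexed by sample id.
#' @param ... passed to [estimate_admixture()].
#' @return data.frame with one row per sample: sample, q_AFR..q_AMR,
#'   primary, secondary, loglik, n_markers_used.
#' @export
assign_cohort_ancestry <- function(genotypes, panel, self_report = NULL, ...) {
  ids <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    fit <- estimate_admixture(genotypes[i, ], panel, ...)
    a <- assign_ancestry(fit, self_report = self_report[ids[i]] %||% NA)
    data.frame(sample = ids[i], q_AFR = fit$q[["AFR"]], q_EUR = fit$q[["EUR"]],
               q_EAS = fit$q[["EAS"]], q_AMR = fit$q[["AMR"]],
               primary = a$primary, secondary = a$secondary,
               loglik = fit$loglik, n_markers_used = fit$n_markers_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Curate a labelled reference panel by iterative eviction and downsampling
#'
#' Starting from reference individuals labelled with one of the four
#' superpopulations, iterate: estimate per-population allele frequencies
#' from current members; estimate every member's admixture against those
#' frequencies; evict members whose own-label admixture fraction falls
#' below `own_fraction_threshold`. Repeat to a fixed point (or `max_iter`),
#' then downsample each population to at most `max_per_pop` members
#' (seeded), and return the frequencies of the survivors.
#'
#' @param genotypes individuals x markers dosage matrix (rownames = ids).
#' @param labels character vector of population labels (AFR/EUR/EAS/AMR),
#'   one per row of `genotypes`.
#' @param max_per_pop downsampling cap per population (default 300).
#' @param own_fraction_threshold eviction threshold on the own-label
#'   admixture fraction (default 0.75; the threshold is a curation choice,
#'   not a published constant).
#' @param seed integer seed for the downsampling draw.
#' @param eps frequency clamp passed through to the panel.
#' @param max_iter maximum eviction iterations.
#' @return an object of class `aim_panel`: list with `freqs` (markers x 4
#'   matrix), `members` (surviving ids per population), `evicted`
#'   (ids evicted, with their own-label fractions), `n_iter`.
#' @export
prune_reference_panel <- function(genotypes, labels, max_per_pop = 300L,
                                  own_fraction_threshold = 0.75, seed = 1L,
                                  eps = 1e-3, max_iter = 20L) {
  stopifnot(nrow(genotypes) == length(labels))
  if (!all(labels %in% AIM_POPS))
    stopf("labels must be among %s", paste(AIM_POPS, collapse = ", "))
  ids <- rownames(genotypes) %||% paste0("R", seq_len(nrow(genotypes)))
  rownames(genotypes) <- ids
  active <- rep(TRUE, nrow(genotypes))
  evicted <- data.frame(sample = character(), pop = character(),
                        own_fraction = numeric())
  it <- 0L
  repeat {
    it <- it + 1L
    freqs <- .panel_freqs(genotypes[active, , drop = FALSE], labels[active], eps)
    own <- vapply(which(active), function(i) {
      estimate_admixture(genotypes[i, ], freqs, eps = eps)$q[[labels[i]]]
    }, numeric(1))
    out <- which(active)[own < own_fraction_threshold]
    if (length(out) == 0 || it >= max_iter) break
    evicted <- rbind(evicted, data.frame(sample = ids[out], pop = labels[out],
                                         own_fraction = own[match(out, which(active))]))
    active[out] <- FALSE
    emptied <- setdiff(AIM_POPS, unique(labels[active]))
    if (length(emptied))
      stopf("reference curation emptied population %s", emptied[1])
  }
  members <- split(ids[active], factor(labels[active], levels = AIM_POPS))
  members <- with_seed(seed, lapply(members, function(m)
    if (length(m) > max_per_pop) sort(sample(m, max_per_pop)) else m))
  keep_ids <- unlist(members, use.names = FALSE)
  sel <- ids %in% keep_ids
  freqs <- .panel_freqs(genotypes[sel, , drop = FALSE], labels[sel], eps)
  structure(list(freqs = freqs, members = members, evicted = evicted,
                 n_iter = it),
            class = "aim_panel")
}

.panel_freqs <- function(genotypes, labels, eps = 1e-3) {
  f <- vapply(AIM_POPS, function(p) {
    rows <- labels == p
    if (!any(rows)) stopf("population %s has no members", p)
    colMeans(genotypes[rows, , drop = FALSE], na.rm = TRUE) / 2
  }, numeric(ncol(genotypes)))
  clamp(f, eps, 1 - eps)
}

#' @export
print.aim_panel <- function(x, ...) {
  cat("AIM reference panel:", nrow(x$freqs), "markers;",
      paste(sprintf("%s=%d", AIM_POPS, lengths(x$members[AIM_POPS])), collapse = " "),
      "\n")
  invisible(x)
}

#' Read / write an AIM frequency panel
#'
#' TSV with columns `marker`, `f_AFR`, `f_EUR`, `f_EAS`, `f_AMR`.
#'
#' @param path panel TSV path.
#' @return an `aim_panel` with `freqs` only.
#' @export
read_aim_panel <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", paste0("f_", AIM_POPS))
  if (!all(need %in% names(df)))
    stopf("panel must have columns: %s", paste(need, collapse = ", "))
  f <- as.matrix(df[paste0("f_", AIM_POPS)])
  colnames(f) <- AIM_POPS
  rownames(f) <- df$marker
  structure(list(freqs = f, members = NULL, evicted = NULL, n_iter = 0L),
            class = "aim_panel")
}

#' @rdname read_aim_panel
#' @param panel an `aim_panel` or frequency matrix.
#' @export
write_aim_panel <- function(panel, path) {
  f <- if (inherits(panel, "aim_panel")) panel$freqs else panel
  df <- data.frame(marker = rownames(f) %||% paste0("M", seq_len(nrow(f))),
                   f_AFR = f[, "AFR"], f_EUR = f[, "EUR"],
                   f_EAS = f[, "EAS"], f_AMR = f[, "AMR"])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write AIM genotype dosages
#'
#' TSV with a `sample` column followed by one column per marker holding
#' alternate-allele dosages in \{0,1,2\} (NA = missing).
#'
#' @param path genotype TSV path.
#' @return samples x markers numeric matrix with sample rownames.
#' @export
read_aim_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_aim_genotypes
#' @param genotypes samples x markers dosage matrix.
#' @export
write_aim_genotypes <- function(genotypes, path) {
  df <- data.frame(sample = rownames(genotypes), genotypes, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
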