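# in-code fixtures and independent oracles used across the suite

# one synthetic call with sensible defaults, overridable per test
make_call <- function(a1_bp = 30L, a2_bp = 60L, depth = 100L, quality = 0.99,
                      ci1 = c(a1_bp, a1_bp), ci2 = c(a2_bp, a2_bp),
                      enclosing = 25L, spanning = 25L, frr = 25L, flanking = 25L,
                      missing = FALSE, sample = "S1", chrom = "chr1",
                      pos = 1000L, unit = "CTG") {
  data.frame(chrom = chrom, pos = pos, unit = unit, period = nchar(unit),
             sample = sample, a1_bp = a1_bp, a2_bp = a2_bp,
             ci1_lo_bp = ci1[1], ci1_hi_bp = ci1[2],
             ci2_lo_bp = ci2[1], ci2_hi_bp = ci2[2],
             depth = depth, quality = quality,
             n_enclosing = enclosing, n_spanning = spanning,
             n_frr = frr, n_flanking = flanking,
             missing = missing, stringsAsFactors = FALSE)
}

# many random calls for property tests (valid by construction unless asked)
random_calls <- function(n, seed = 42L) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    a1 <- 3L * sample(5:40, 1); a2 <- 3L * sample(5:40, 1)
    w1 <- sample(0:6, 1); w2 <- sample(0:6, 1)
    make_call(a1, a2,
              depth = sample(1:1200, 1),
              quality = round(runif(1, 0.5, 1), 3),
              ci1 = sort(a1 + 3L * c(-w1, sample(-w1:w1, 1))),
              ci2 = sort(a2 + 3L * c(-w2, sample(-w2:w2, 1))),
              enclosing = sample(0:40, 1), frr = sample(0:40, 1),
              missing = runif(1) < 0.05,
              sample = paste0("S", i), pos = 1000L + i)
  }))
}

# one-row baseline record
stat_row <- function(group, n, mean, sd, chrom = "chr1", pos = 1000L,
                     unit = "CTG") {
  data.frame(chrom = chrom, pos = pos, unit = unit, group = group, n = n,
             mean = mean, sd = sd, cov = if (mean > 0) sd / mean else NA_real_,
             se = sd / sqrt(n), stringsAsFactors = FALSE)
}

# naive two-pass per-(locus, group) statistics: the brute-force oracle for
# compute_group_stats
naive_group_stats <- function(calls, assignment) {
  calls <- calls[!calls$missing & !is.na(calls$a1_bp), , drop = FALSE]
  out <- list()
  keys <- unique(calls[c("chrom", "pos", "unit")])
  for (i in seq_len(nrow(keys))) {
    sub <- calls[calls$chrom == keys$chrom[i] & calls$pos == keys$pos[i] &
                   calls$unit == keys$unit[i], , drop = FALSE]
    grp <- assignment[sub$sample]
    for (g in c(unique(grp), "TOTAL")) {
      x <- if (g == "TOTAL") c(sub$a1_bp, sub$a2_bp) else
        c(sub$a1_bp[grp == g], sub$a2_bp[grp == g])
      m <- mean(x)
      s <- sqrt(mean((x - m)^2))
      out[[length(out) + 1L]] <- data.frame(
        chrom = keys$chrom[i], pos = keys$pos[i], unit = keys$unit[i],
        group = g, n = length(x), mean = m, sd = s,
        cov = if (m > 0) s / m else NA_real_, se = s / sqrt(length(x)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out[order(out$chrom, out$pos, out$unit, out$group), , drop = FALSE]
}

# exhaustive grid search over the 3-simplex at the given resolution:
# the independent oracle for the admixture EM
grid_admixture_oracle <- function(genotypes, freqs, step = 0.01, eps = 1e-3) {
  use <- !is.na(genotypes)
  g <- genotypes[use]
  f <- pmin(pmax(freqs[use, , drop = FALSE], eps), 1 - eps)
  k <- round(1 / step)
  gr <- expand.grid(i = 0:k, j = 0:k, l = 0:k)
  gr <- gr[gr$i + gr$j + gr$l <= k, ]
  Q <- cbind(gr$i, gr$j, gr$l, k - gr$i - gr$j - gr$l) / k
  P <- Q %*% t(f)                      # grid x markers
  ll <- as.vector(log(P) %*% g + log(1 - P) %*% (2 - g))
  list(loglik = max(ll), q = Q[which.max(ll), ])
}

# brute-force per-locus trio scan: oracle for scan_trios
brute_denovo <- function(calls, trios) {
  calls <- calls[!calls$missing, , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(trios))) {
    tr <- trios[i, ]
    keys <- unique(calls[c("chrom", "pos", "unit")])
    for (j in seq_len(nrow(keys))) {
      at <- calls$chrom == keys$chrom[j] & calls$pos == keys$pos[j] &
        calls$unit == keys$unit[j]
      p <- calls[at & calls$sample == tr$proband, ]
      m <- calls[at & calls$sample == tr$mother, ]
      f <- calls[at & calls$sample == tr$father, ]
      if (nrow(p) != 1 || nrow(m) != 1 || nrow(f) != 1) next
      ev <- strscreen::detect_denovo(p, m, f)
      if (nrow(ev))
        hits[[length(hits) + 1L]] <- cbind(family = tr$family,
                                           keys[j, , drop = FALSE], ev)
    }
  }
  if (length(hits)) do.call(rbind, hits) else NULL
}

# small cohort simulation used by several tests
quick_sim <- function(seed = 11L, ...) {
  simulate_cohort(sim_config(
    seed = seed, n_loci = 60, n_trios = 4,
    groups = c(AFR = 8, EUR = 15, EAS = 5, AdmixedAMR = 6,
               NonadmixedAMR = 4, PAC = 2), ...))
}

truth_assignment <- function(sim) setNames(sim$samples$group, sim$samples$sample)
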