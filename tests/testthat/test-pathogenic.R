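# a minimal baseline with TOTAL rows at two catalog loci (AR, TCF4)
catalog_baseline <- function() {
  cat_df <- read_pathogenic_catalog()
  ar <- cat_df[cat_df$gene == "AR", ]; tcf4 <- cat_df[cat_df$gene == "TCF4", ]
  rbind(stat_row("TOTAL", 400, 66, 3, chrom = ar$chrom, pos = ar$pos, unit = ar$unit),
        stat_row("TOTAL", 400, 45, 3, chrom = tcf4$chrom, pos = tcf4$pos,
                 unit = tcf4$unit))
}

catalog_call <- function(gene, allele_bp, sample = "P1") {
  cat_df <- read_pathogenic_catalog()
  rec <- cat_df[cat_df$gene == gene, ]
  make_call(rec$ref_bp %/% nchar(rec$unit) * nchar(rec$unit), allele_bp,
            sample = sample, chrom = rec$chrom, pos = rec$pos, unit = rec$unit)
}

test_that("divergence and pathogenic exceedance are independent flags", {
  bl <- catalog_baseline()
  cat_df <- read_pathogenic_catalog()
  calls <- rbind(catalog_call("AR", 110L, "P1"), catalog_call("TCF4", 151L, "P2"))
  hits <- screen_pathogenic(calls, cat_df[cat_df$gene %in% c("AR", "TCF4"), ], bl)
  ar <- hits[hits$gene == "AR", ]; tcf4 <- hits[hits$gene == "TCF4", ]
  # AR at 110 bp: 1.67x the 66 bp mean but under the 114 bp pathogenic length
  expect_true(ar$divergent)
  expect_false(ar$exceeds_pathogenic)
  # TCF4 at 151 bp: strictly past the 150 bp pathogenic length
  expect_true(tcf4$exceeds_pathogenic)
  expect_true(tcf4$divergent)
})

test_that("the ratio threshold is inclusive and exceedance strict", {
  bl <- catalog_baseline()
  cat_df <- read_pathogenic_catalog()
  cat_df <- cat_df[cat_df$gene == "AR", ]
  hits <- screen_pathogenic(catalog_call("AR", 99L), cat_df, bl)   # 1.5 x 66
  expect_true(hits$divergent)
  hits <- screen_pathogenic(catalog_call("AR", 114L), cat_df, bl)  # == cutoff
  expect_false(hits$exceeds_pathogenic)
  hits <- screen_pathogenic(catalog_call("AR", 115L), cat_df, bl)
  expect_true(hits$exceeds_pathogenic)
})

test_that("raising the ratio threshold never adds divergent hits", {
  bl <- catalog_baseline()
  cat_df <- read_pathogenic_catalog()
  set.seed(12)
  calls <- do.call(rbind, lapply(1:30, function(i)
    catalog_call("AR", 3L * sample(20:60, 1), paste0("P", i))))
  n_hits <- vapply(c(1.5, 2.0, 2.5), function(th)
    sum(suppressWarnings(
      screen_pathogenic(calls, cat_df, bl, ratio_threshold = th))$divergent),
    numeric(1))
  expect_true(all(diff(n_hits) <= 0))
})

test_that("per-gene summaries report the AMR:EUR:Other breakdown", {
  expect_equal(nrow(summarize_pathogenic_by_gene(
    suppressWarnings(screen_pathogenic(make_call()[0, ],
                                       read_pathogenic_catalog()[0, ],
                                       catalog_baseline())))), 0L)

  bl <- catalog_baseline()
  cat_df <- read_pathogenic_catalog()
  calls <- rbind(catalog_call("TCF4", 150L, "P1"), catalog_call("TCF4", 150L, "P2"),
                 catalog_call("TCF4", 150L, "P3"))
  anc <- c(P1 = "AdmixedAMR", P2 = "EUR", P3 = "EAS")
  hits <- suppressWarnings(screen_pathogenic(calls, cat_df, bl, assignment = anc))
  sm <- summarize_pathogenic_by_gene(hits)
  expect_equal(sm$breakdown[sm$gene == "TCF4"], "1:1:1")
  expect_equal(sm$n_divergent[sm$gene == "TCF4"], 3L)
})

test_that("injected expansions reproduce their ancestry breakdown", {
  sim <- quick_sim(seed = 29, pathogenic = data.frame(
    gene = "TCF4", n_carriers = 3, allele_bp = 153L))
  filt <- filter_cohort(sim$calls)
  anc <- truth_assignment(sim)
  ped <- sim$samples
  bl <- build_population_baseline(filt$kept, ped, anc)
  pro <- filt$kept[filt$kept$sample %in% ped$sample[ped$role == "proband"], ]
  hits <- suppressWarnings(screen_pathogenic(pro, read_pathogenic_catalog(),
                                             bl$stats, assignment = anc))
  carriers <- sim$truth$pathogenic$sample
  expect_setequal(hits$sample[hits$exceeds_pathogenic], carriers)
  sm <- summarize_pathogenic_by_gene(hits)
  truth_amr <- sum(anc[carriers] %in% c("AdmixedAMR", "NonadmixedAMR"))
  expect_equal(sm$n_AMR[sm$gene == "TCF4"], truth_amr)
})

test_that("ancestral mean tables cover catalog x present groups", {
  sim <- quick_sim(seed = 37, pathogenic = data.frame(
    gene = "DMPK", n_carriers = 1, allele_bp = 153L))
  filt <- filter_cohort(sim$calls)
  bl <- build_population_baseline(filt$kept, sim$samples, truth_assignment(sim))
  tab <- pathogenic_ancestral_means(bl$stats, read_pathogenic_catalog())
  expect_true(all(tab$group != "TOTAL"))
  per_gene <- table(tab$gene)
  groups_present <- length(unique(bl$stats$group)) - 1L   # minus TOTAL
  expect_true(all(per_gene <= groups_present))
  # means at a shared-distribution locus agree across groups within 2 se
  dmpk <- tab[tab$gene == "DMPK" & tab$n >= 10, ]
  if (nrow(dmpk) >= 2) {
    spread <- max(dmpk$mean_bp) - min(dmpk$mean_bp)
    expect_lte(spread, 2 * (max(dmpk$se_bp) + max(dmpk$se_bp)))
  }
})

test_that("catalog loci absent from the baseline are skipped with a warning", {
  bl <- catalog_baseline()
  cat_df <- read_pathogenic_catalog()
  ws <- testthat::capture_warnings(
    hits <- screen_pathogenic(catalog_call("AR", 110L), cat_df, bl))
  expect_true(any(grepl("absent from baseline", ws)))
  expect_equal(nrow(hits), 1L)   # only the AR locus is present in the baseline
})
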