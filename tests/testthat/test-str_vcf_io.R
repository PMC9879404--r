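gangstr_vcf_lines <- function(records, samples = "S1") {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=RU,Number=1,Type=String,Description=\"Repeat unit\">",
    "##INFO=<ID=PERIOD,Number=1,Type=Integer,Description=\"Period\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=Q,Number=1,Type=Float,Description=\"Q\">",
    "##FORMAT=<ID=REPCN,Number=1,Type=String,Description=\"CN\">",
    "##FORMAT=<ID=REPCI,Number=1,Type=String,Description=\"CI\">",
    "##FORMAT=<ID=RC,Number=1,Type=String,Description=\"RC\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("copy numbers convert to base pairs as copies x period", {
  rec <- paste(c("chr1", "100", ".", strrep("CTG", 17), strrep("CTG", 50), ".",
                 ".", "RU=CTG;PERIOD=3", "GT:DP:Q:REPCN:REPCI:RC",
                 "0/1:80:0.95:17,50:15-19,45-55:20,20,20,20"), collapse = "\t")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(gangstr_vcf_lines(rec), f)
  out <- read_str_vcf(f)
  expect_equal(out$calls$a1_bp, 51L)
  expect_equal(out$calls$a2_bp, 150L)
  expect_equal(out$calls$ci1_lo_bp, 45L)
  expect_equal(out$calls$ci2_hi_bp, 165L)
  expect_false(out$calls$missing)
  expect_identical(out$loci$ref_bp, 51L)
  # copies mode leaves lengths in repeat units
  expect_equal(read_str_vcf(f, unit = "copies")$calls$a1_bp, 17L)
})

test_that("uncalled genotypes become missing-flagged calls", {
  rec <- paste(c("chr1", "100", ".", "CTGCTG", ".", ".", ".",
                 "RU=CTG;PERIOD=3", "GT:DP:Q:REPCN:REPCI:RC",
                 "./.:.:.:.:.:."), collapse = "\t")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(gangstr_vcf_lines(rec), f)
  out <- read_str_vcf(f)
  expect_true(out$calls$missing)
  expect_true(is.na(out$calls$a1_bp))
})

test_that("loci with period outside 1-6 are skipped with a warning", {
  recs <- c(
    paste(c("chr1", "100", ".", "CTGCTG", ".", ".", ".", "RU=CTG;PERIOD=3",
            "GT:DP:Q:REPCN:REPCI:RC", "0/0:80:0.95:2,2:2-2,2-2:20,20,20,20"),
          collapse = "\t"),
    paste(c("chr1", "200", ".", strrep("CTGCTGA", 2), ".", ".", ".",
            "RU=CTGCTGA;PERIOD=7", "GT:DP:Q:REPCN:REPCI:RC",
            "0/0:80:0.95:2,2:2-2,2-2:20,20,20,20"), collapse = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(gangstr_vcf_lines(recs), f)
  expect_warning(out <- read_str_vcf(f), "skipped")
  expect_equal(nrow(out$loci), 1L)
})

test_that("a malformed VCF body line raises a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(gangstr_vcf_lines(character(0)), "chr1\t100\tbroken"), f)
  expect_error(read_str_vcf(f), "line 11")
})

test_that("simulator output round-trips exactly through VCF write/read", {
  sim <- simulate_cohort(sim_config(seed = 5, n_loci = 100, n_trios = 0,
                                    groups = c(EUR = 6, AFR = 4)))
  d <- withr::local_tempdir()
  sim_write(sim, d)
  rt <- read_str_vcfs(list.files(file.path(d, "vcf"), full.names = TRUE))
  expect_identical(rt$loci, sim$loci)
  a <- sim$calls[order(sim$calls$sample, sim$calls$chrom, sim$calls$pos), ]
  b <- rt$calls[order(rt$calls$sample, rt$calls$chrom, rt$calls$pos), names(a)]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("pedigree parsing validates structure and counts trios", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family\tsample\tfather\tmother\trole",
               "F1\tP1\tD1\tM1\tproband",
               "F1\tM1\t0\t0\tmother",
               "F1\tD1\t0\t0\tfather"), f)
  ped <- read_pedigree(f)
  expect_equal(nrow(attr(ped, "trios")), 1L)

  writeLines(c("family\tsample\tfather\tmother\trole",
               "F1\tP1\t0\t0\tproband"), f)
  ped <- read_pedigree(f)
  expect_equal(nrow(attr(ped, "trios")), 0L)
  expect_equal(sum(ped$role == "proband"), 1L)

  writeLines(c("family\tsample\tfather\tmother\trole",
               "F1\tP1\tP1\tM1\tproband"), f)
  expect_error(read_pedigree(f), "own parent")

  writeLines(c("family\tsample\tfather\tmother\trole",
               "F1\tP1\t0\t0\tchild"), f)
  expect_error(read_pedigree(f), "role")

  writeLines(c("family\tsample\tfather\tmother\trole",
               "F1\tP1\t0\t0\tproband",
               "F2\tP1\t0\t0\tproband"), f)
  expect_error(read_pedigree(f), "duplicate")
})

test_that("a simulated trio cohort yields one complete trio per family", {
  sim <- simulate_cohort(sim_config(seed = 2, n_loci = 1, n_trios = 184,
                                    groups = c(EUR = 2)))
  expect_equal(nrow(trio_table(sim$samples)), 184L)
})

test_that("the packaged pathogenic catalog carries the six printed loci", {
  cat_df <- read_pathogenic_catalog()
  expect_setequal(cat_df$gene, c("AR", "TCF4", "DMPK", "DIP2B", "ATXN10", "RFC1"))
  expect_equal(cat_df$pathogenic_bp[cat_df$gene == "AR"], 114L)
  expect_equal(cat_df$pathogenic_bp[cat_df$gene == "DIP2B"], 600L)
  expect_equal(cat_df$pathogenic_bp[cat_df$gene == "TCF4"], 150L)
})

test_that("catalog validation rejects non-positive lengths, warns on empty", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tchrom\tpos\tunit\tref_bp\tpathogenic_bp",
               "X1\tchr1\t100\tCAG\t30\t-5"), f)
  expect_error(read_pathogenic_catalog(f), "non-positive")
  writeLines("gene\tchrom\tpos\tunit\tref_bp\tpathogenic_bp", f)
  expect_warning(out <- read_pathogenic_catalog(f), "empty")
  expect_equal(nrow(out), 0L)
})

test_that("results TSV writes deterministically ordered rows and round-trips", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(chrom = character(), pos = integer(), sample = character())
  write_results_tsv(empty, f)
  expect_length(readLines(f), 1L)

  recs <- data.frame(chrom = c("chr2", "chr1"), pos = c(5L, 9L),
                     sample = c("B", "A"), fold = c(2.5, 3.0))
  write_results_tsv(recs, f)
  expect_length(readLines(f), 3L)
  back <- read_results_tsv(f)
  expect_equal(back$chrom, c("chr1", "chr2"))  # sorted on write
  expect_equal(back$fold, c(3.0, 2.5))
})
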