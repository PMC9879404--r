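trio_calls <- function(pro, mo, fa) {
  list(proband = make_call(pro[1], pro[2], sample = "P"),
       mother = make_call(mo[1], mo[2], sample = "M"),
       father = make_call(fa[1], fa[2], sample = "F"))
}

test_that("expansions need the proband allele to exceed twice the parental max", {
  tc <- trio_calls(c(20L, 41L), c(20L, 20L), c(18L, 19L))
  ev <- detect_denovo(tc$proband, tc$mother, tc$father)
  expect_equal(ev$type, "expansion")
  expect_equal(ev$fold, 41 / 20)

  # exactly twice: strict inequality, no event
  tc <- trio_calls(c(20L, 40L), c(20L, 20L), c(18L, 19L))
  expect_equal(nrow(detect_denovo(tc$proband, tc$mother, tc$father)), 0L)
})

test_that("contractions compare against the shortest allele of both parents", {
  tc <- trio_calls(c(4L, 12L), c(11L, 12L), c(10L, 12L))
  ev <- detect_denovo(tc$proband, tc$mother, tc$father)
  expect_equal(ev$type, "contraction")
  expect_equal(ev$parental_extreme_bp, 10L)

  # exactly half: strict, no event
  tc <- trio_calls(c(5L, 12L), c(11L, 12L), c(10L, 12L))
  expect_equal(nrow(detect_denovo(tc$proband, tc$mother, tc$father)), 0L)
})

test_that("both event types can co-occur and parent labels are symmetric", {
  tc <- trio_calls(c(4L, 41L), c(20L, 12L), c(10L, 18L))
  ev <- detect_denovo(tc$proband, tc$mother, tc$father)
  expect_setequal(ev$type, c("expansion", "contraction"))
  ev_swap <- detect_denovo(tc$proband, tc$father, tc$mother)
  expect_equal(ev, ev_swap)
})

test_that("enlarging a parental allele can only remove expansion events", {
  tc <- trio_calls(c(20L, 41L), c(20L, 20L), c(18L, 19L))
  before <- nrow(detect_denovo(tc$proband, tc$mother, tc$father))
  tc$mother$a2_bp <- 30L
  after <- nrow(detect_denovo(tc$proband, tc$mother, tc$father))
  expect_lte(after, before)
})

test_that("pure Mendelian transmission yields zero events", {
  sim <- simulate_cohort(sim_config(seed = 43, n_loci = 300, n_trios = 15,
                                    groups = c(EUR = 4)))
  expect_equal(nrow(sim$truth$denovo), 0L)
  scan <- scan_trios(filter_cohort(sim$calls)$kept, trio_table(sim$samples))
  expect_equal(nrow(scan$events), 0L)
})

test_that("injected jumps are recovered exactly, with count conservation", {
  sim <- simulate_cohort(sim_config(
    seed = 47, n_loci = 500, n_trios = 15, groups = c(EUR = 4),
    denovo = list(expansion_rate = 5e-3, contraction_rate = 1e-3, factor = 2.5)))
  truth <- sim$truth$denovo
  expect_gt(nrow(truth), 0L)
  scan <- scan_trios(filter_cohort(sim$calls)$kept, trio_table(sim$samples))
  expect_setequal(paste(scan$events$family, scan$events$pos, scan$events$type),
                  paste(truth$family, truth$pos, truth$type))
  expect_equal(sum(scan$per_proband$n_expansions) +
                 sum(scan$per_proband$n_contractions), nrow(scan$events))
})

test_that("single-repeat stepwise mutations are invisible to the 2x rule", {
  sim <- simulate_cohort(sim_config(
    seed = 53, n_loci = 400, n_trios = 10, groups = c(EUR = 4),
    denovo = list(expansion_rate = 0.01, model = "stepwise")))
  expect_gt(nrow(sim$truth$stepwise), 0L)
  scan <- scan_trios(filter_cohort(sim$calls)$kept, trio_table(sim$samples))
  expect_equal(nrow(scan$events), 0L)
})

test_that("the genome-wide scan agrees with the brute-force oracle", {
  sim <- simulate_cohort(sim_config(
    seed = 59, n_loci = 40, n_trios = 5, groups = c(EUR = 2),
    denovo = list(expansion_rate = 0.02, contraction_rate = 0.005, factor = 2.5)))
  kept <- filter_cohort(sim$calls)$kept
  trios <- trio_table(sim$samples)
  scan <- scan_trios(kept, trios)
  brute <- brute_denovo(kept, trios)
  if (is.null(brute)) {
    expect_equal(nrow(scan$events), 0L)
  } else {
    expect_setequal(paste(scan$events$family, scan$events$pos, scan$events$type),
                    paste(brute$family, brute$pos, brute$type))
  }
})

test_that("parental-age correlations handle degenerate inputs", {
  per <- data.frame(family = paste0("T", 1:6), proband = paste0("P", 1:6),
                    n_expansions = c(3L, 3L, 3L, 3L, 3L, 3L),
                    n_contractions = 0L)
  ages <- data.frame(proband = paste0("P", 1:6),
                     mother_age = c(25, 30, 35, 28, 41, 33),
                     father_age = c(27, 31, 39, 30, 44, 35))
  res <- parental_age_summary(per, ages)
  expect_true(all(is.na(res$r)))            # zero count variance: undefined

  per$n_expansions <- as.integer(ages$mother_age)   # perfect dependence
  res <- parental_age_summary(per, ages)
  expect_equal(res$r[res$parent == "mother"], 1, tolerance = 1e-12)

  res <- parental_age_summary(per[1:2, ], ages[1:2, ])
  expect_true(all(is.na(res$r)))            # fewer than 3 pairs
})

test_that("independent ages show no spurious correlation", {
  set.seed(61)
  n <- 60
  per <- data.frame(family = paste0("T", 1:n), proband = paste0("P", 1:n),
                    n_expansions = rpois(n, 17), n_contractions = 0L)
  ages <- data.frame(proband = paste0("P", 1:n),
                     mother_age = round(runif(n, 20, 45)),
                     father_age = round(runif(n, 20, 55)))
  res <- parental_age_summary(per, ages)
  expect_true(all(abs(res$r) < 0.4))
  expect_true(all(res$p_value > 0.001))
})
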