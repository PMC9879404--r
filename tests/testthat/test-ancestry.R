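random_panel <- function(m, seed) {
  set.seed(seed)
  f <- matrix(runif(4 * m, 0.05, 0.95), m, 4,
              dimnames = list(NULL, c("AFR", "EUR", "EAS", "AMR")))
  f
}

test_that("EM matches the exhaustive simplex grid search on small panels", {
  for (seed in 1:4) {
    f <- random_panel(30, seed)
    set.seed(seed + 100)
    q_true <- c(0.5, 0.3, 0.2, 0)[sample(4)]
    g <- rbinom(30, 2, as.vector(f %*% q_true))
    fit <- estimate_admixture(g, f)
    oracle <- grid_admixture_oracle(g, f, step = 0.01)
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
    expect_equal(sum(fit$q), 1, tolerance = 1e-9)
    expect_true(all(fit$q >= 0))
  }
})

test_that("a panel without frequency contrast yields uniform q and a flag", {
  f <- matrix(0.4, 50, 4, dimnames = list(NULL, c("AFR", "EUR", "EAS", "AMR")))
  g <- rep(1L, 50)
  fit <- estimate_admixture(g, f)
  expect_false(fit$identifiable)
  expect_equal(unname(fit$q), rep(0.25, 4), tolerance = 1e-9)
})

test_that("genotypes drawn from one population recover that population", {
  sim <- simulate_cohort(sim_config(seed = 21, n_loci = 1, n_trios = 0,
                                    groups = c(AFR = 5)))
  qs <- vapply(seq_len(5), function(i)
    estimate_admixture(sim$aim$genotypes[i, ], sim$aim$panel)$q[["AFR"]],
    numeric(1))
  expect_gte(median(qs), 0.95)
})

test_that("a 50/50 EUR-EAS admixture is recovered to within 0.15", {
  f <- random_panel(250, 7)
  set.seed(77)
  errs <- replicate(20, {
    g <- rbinom(250, 2, as.vector(f %*% c(0, 0.5, 0.5, 0)))
    q <- estimate_admixture(g, f)$q
    max(abs(q[["EUR"]] - 0.5), abs(q[["EAS"]] - 0.5))
  })
  expect_lte(median(errs), 0.15)
})

test_that("permuting the population columns permutes q identically", {
  f <- random_panel(60, 3)
  set.seed(3); g <- rbinom(60, 2, as.vector(f %*% c(0.6, 0.2, 0.1, 0.1)))
  fit <- estimate_admixture(g, f)
  perm <- c(3, 1, 4, 2)
  fit_p <- estimate_admixture(g, f[, perm])
  expect_equal(unname(fit_p$q), unname(fit$q[perm]), tolerance = 1e-8)
})

test_that("admixture error shrinks as the marker count grows", {
  f <- random_panel(250, 9)
  set.seed(9)
  mae <- function(m) {
    mean(replicate(30, {
      q_true <- c(0.4, 0.3, 0.2, 0.1)
      g <- rbinom(m, 2, as.vector(f[seq_len(m), ] %*% q_true))
      mean(abs(estimate_admixture(g, f[seq_len(m), ])$q - q_true))
    }))
  }
  expect_lt(mae(250), mae(50))
})

test_that("ancestry assignment applies the rules in order", {
  # clear majority
  a <- assign_ancestry(c(AFR = 0.1, EUR = 0.8, EAS = 0.05, AMR = 0.05))
  expect_equal(a$primary, "EUR"); expect_true(is.na(a$secondary))
  # AMR above the non-admixed cutoff
  a <- assign_ancestry(c(AFR = 0.1, EUR = 0.1, EAS = 0.04, AMR = 0.76))
  expect_equal(a$primary, "NonadmixedAMR")
  # AMR majority below the cutoff is Admixed American
  a <- assign_ancestry(c(AFR = 0.1, EUR = 0.2, EAS = 0.05, AMR = 0.65))
  expect_equal(a$primary, "AdmixedAMR")
  # 50-60% window sets a secondary ancestry
  a <- assign_ancestry(c(AFR = 0.55, EUR = 0.40, EAS = 0.03, AMR = 0.02))
  expect_equal(a$primary, "AFR"); expect_equal(a$secondary, "EUR")
  # exactly 0.60 falls in the secondary window (primary rule is strict >)
  a <- assign_ancestry(c(AFR = 0.60, EUR = 0.30, EAS = 0.05, AMR = 0.05))
  expect_equal(a$primary, "AFR"); expect_equal(a$secondary, "EUR")
  # no majority
  a <- assign_ancestry(c(AFR = 0.4, EUR = 0.3, EAS = 0.2, AMR = 0.1))
  expect_equal(a$primary, "unassigned")
  # self-reported Pacific Islander overrides markers
  a <- assign_ancestry(c(AFR = 0.0, EUR = 0.9, EAS = 0.1, AMR = 0.0),
                       self_report = "PAC")
  expect_equal(a$primary, "PAC")
})

test_that("panel curation evicts admixed members and downsamples evenly", {
  set.seed(15)
  m <- 150
  f_true <- random_panel(m, 15)
  draw <- function(q, n) t(replicate(n, rbinom(m, 2, as.vector(f_true %*% q))))
  pure <- rbind(draw(c(1, 0, 0, 0), 30), draw(c(0, 1, 0, 0), 50),
                draw(c(0, 0, 1, 0), 30), draw(c(0, 0, 0, 1), 30))
  labels <- rep(c("AFR", "EUR", "EAS", "AMR"), c(30, 50, 30, 30))
  rownames(pure) <- paste0("R", seq_len(nrow(pure)))

  # clean panel at a lenient threshold: fixed point immediately, no evictions
  pan <- prune_reference_panel(pure, labels, own_fraction_threshold = 0.5)
  expect_equal(nrow(pan$evicted), 0L)
  expect_equal(pan$n_iter, 1L)

  # oversized population is downsampled to the cap
  pan <- prune_reference_panel(pure, labels, max_per_pop = 40L,
                               own_fraction_threshold = 0.5, seed = 4)
  expect_equal(length(pan$members$EUR), 40L)
  expect_equal(length(pan$members$AFR), 30L)

  # half-EUR half-AMR members labelled EUR are evicted; pure members are not
  for (seed in 1:3) {
    set.seed(seed + 50)
    admixed <- draw(c(0, 0.5, 0, 0.5), 4)
    rownames(admixed) <- paste0("X", 1:4)
    geno <- rbind(pure, admixed)
    labs <- c(labels, rep("EUR", 4))
    pan <- prune_reference_panel(geno, labs, own_fraction_threshold = 0.75,
                                 seed = seed)
    expect_true(all(grepl("^X", pan$evicted$sample)))  # no pure member evicted
    expect_gte(nrow(pan$evicted), 3L)                  # admixed members caught
  }
})

test_that("cohort-level assignment recovers simulated group labels", {
  sim <- quick_sim(seed = 31)
  sr <- setNames(sim$samples$self_report, sim$samples$sample)
  anc <- assign_cohort_ancestry(sim$aim$genotypes, sim$aim$panel,
                                self_report = sr)
  truth <- truth_assignment(sim)
  expect_gte(mean(anc$primary == truth[anc$sample]), 0.9)
})
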