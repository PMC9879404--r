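#' Configuration for the synthetic STR cohort generator
#'
#' The generator emulates the statistical structure the screens assume:
#' ancestry-structured allele-length distributions per locus, Mendelian
#' trio transmission with injected de novo jumps, low-variance conserved
#' loci, pathogenic expansions at catalog loci, and AIM SNP genotypes drawn
#' from admixture-weighted, Balding-Nichols-diverged panel frequencies.
#' Allele lengths are discretised normals over repeat copy number (floored
#' at one copy); lengths in the emitted files are exact integers.
#'
#' @param seed integer seed; every draw derives from it.
#' @param n_loci number of background STR loci.
#' @param groups named integer vector of unrelated (singleton-proband)
#'   sample counts per ancestry group.
#' @param n_trios number of complete trio families; each family is
#'   assigned a group with probability proportional to `groups`.
#' @param copies_mean_range,copies_sd_range uniform ranges for each
#'   background locus's mean and SD of repeat copy number.
#' @param divergent list: `n` loci shifted in one group, `group`, `z_mult`
#'   (shift in locus-SD units) and `pct` (minimum relative shift); the
#'   applied shift is `max(z_mult * sd, pct * mean)` copies.
#' @param conserved list: `n` extra low-variance loci, target `cov`
#'   (coefficient of variation), `expansion_factor` and `n_carriers`
#'   (probands per conserved locus given an expanded allele;
#'   trio probands are used first so the population baseline stays clean).
#' @param pathogenic optional data.frame (gene, n_carriers, allele_bp)
#'   injecting expansions at catalog loci; `catalog` supplies the loci.
#' @param catalog pathogenic-locus catalog (used when `pathogenic` given).
#' @param denovo list: `expansion_rate`, `contraction_rate` (per child per
#'   locus), `model` ("jump" or "stepwise"), `factor` (jump multiplier,
#'   > 1). The stepwise model perturbs one inherited allele by a single
#'   repeat unit — deliberately invisible to the >2x trio rule.
#' @param noise list: `enabled` plus `depth_mean`, `depth_sd`,
#'   `low_depth_rate`, `low_quality_rate`, `bad_ci_rate`,
#'   `spanbound_only_rate`, `missing_rate` for the genotyping-noise model.
#'   Disabled by default so truth-recovery is exact.
#' @param aim list: `n_markers`, `fst` (Balding-Nichols divergence of the
#'   four superpopulation frequencies from a shared ancestral frequency),
#'   `anc_range` for the ancestral frequencies.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 1000L,
                       groups = c(AFR = 30L, EUR = 100L, EAS = 20L,
                                  AdmixedAMR = 40L, NonadmixedAMR = 15L, PAC = 5L),
                       n_trios = 20L,
                       copies_mean_range = c(8, 30),
                       copies_sd_range = c(0.5, 2.5),
                       divergent = list(n = 0L, group = "AFR", z_mult = 8, pct = 0.30),
                       conserved = list(n = 0L, cov = 0.03, expansion_factor = 3,
                                        n_carriers = 1L),
                       pathogenic = NULL,
                       catalog = NULL,
                       denovo = list(expansion_rate = 0, contraction_rate = 0,
                                     model = "jump", factor = 2.5),
                       noise = list(enabled = FALSE, depth_mean = 100, depth_sd = 10,
                                    low_depth_rate = 0, low_quality_rate = 0,
                                    bad_ci_rate = 0, spanbound_only_rate = 0,
                                    missing_rate = 0),
                       aim = list(n_markers = 250L, fst = 0.3,
                                  anc_range = c(0.05, 0.95))) {
  defaults <- formals(sim_config)
  divergent <- modifyList(eval(defaults$divergent), divergent)
  conserved <- modifyList(eval(defaults$conserved), conserved)
  denovo <- modifyList(eval(defaults$denovo), denovo)
  noise <- modifyList(eval(defaults$noise), noise)
  aim <- modifyList(eval(defaults$aim), aim)
  if (!all(names(groups) %in% ANCESTRY_GROUPS))
    stopf("group names must be among %s", paste(ANCESTRY_GROUPS, collapse = ", "))
  rates <- c(denovo$expansion_rate, denovo$contraction_rate, noise$low_depth_rate,
             noise$low_quality_rate, noise$bad_ci_rate, noise$spanbound_only_rate,
             noise$missing_rate)
  if (any(rates < 0 | rates > 1)) stopf("all rates must lie in [0,1]")
  if (denovo$model == "jump" && denovo$factor <= 1)
    stopf("de novo jump factor must exceed 1")
  if (conserved$n > 0) {
    # an integer-copy locus cannot realise a small target cov if too short
    min_mean <- 10
    if (conserved$cov * min_mean <= 0 || conserved$cov >= 0.5)
      stopf("infeasible conserved cov target %.3f", conserved$cov)
  }
  if (!is.null(pathogenic) && is.null(catalog))
    catalog <- read_pathogenic_catalog()
  structure(list(seed = as.integer(seed), n_loci = as.integer(n_loci),
                 groups = groups, n_trios = as.integer(n_trios),
                 copies_mean_range = copies_mean_range,
                 copies_sd_range = copies_sd_range,
                 divergent = divergent, conserved = conserved,
                 pathogenic = pathogenic, catalog = catalog,
                 denovo = denovo, noise = noise, aim = aim),
            class = "sim_config")
}

# true admixture per group (AFR, EUR, EAS, AMR); PAC is an EUR/EAS mixture
# identified by self-report
.group_q <- function(group) {
  switch(group,
         AFR = c(1, 0, 0, 0),
         EUR = c(0, 1, 0, 0),
         EAS = c(0, 0, 1, 0),
         AdmixedAMR = c(0.05, 0.25, 0.05, 0.65),
         NonadmixedAMR = c(0.02, 0.05, 0.03, 0.90),
         PAC = c(0, 0.45, 0.55, 0))
}

.random_unit <- function(period) {
  vapply(period, function(p)
    paste(sample(c("A", "C", "G", "T"), p, replace = TRUE), collapse = ""),
    character(1))
}

#' Simulate AIM genotypes for one individual
#'
#' Per marker, the alternate-allele dosage is Binomial(2, sum_k q_k f_k):
#' two allele copies drawn from the admixture-weighted panel frequency.
#'
#' @param q admixture 4-vector on the simplex (AFR, EUR, EAS, AMR order).
#' @param panel `aim_panel` or markers x 4 frequency matrix.
#' @return integer dosage vector, one per marker.
#' @export
simulate_aim_individual <- function(q, panel) {
  f <- if (inherits(panel, "aim_panel")) panel$freqs else panel
  stopifnot(length(q) == 4, abs(sum(q) - 1) < 1e-9, all(q >= 0))
  p <- as.vector(f %*% q)
  rbinom(nrow(f), 2L, p)
}

#' Generate a synthetic STR cohort with ground truth
#'
#' @param config a [sim_config()].
#' @return object of class `str_sim`: list with `loci`, `samples` (sample,
#'   family, role, group, self_report, mother_age, father_age), `calls`
#'   (GangSTR-dialect call table as from [read_str_vcf()]), `aim` (list:
#'   `panel`, `genotypes`, `q_true`), `truth` (injected divergent loci,
#'   conserved loci and carriers, pathogenic carriers, de novo events,
#'   stepwise events), and `config`. Fully reproducible from
#'   `config$seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  grps <- names(cfg$groups)

  ## ---- loci ----------------------------------------------------------
  L0 <- cfg$n_loci
  period <- sample(1:6, L0, replace = TRUE,
                   prob = c(0.35, 0.25, 0.20, 0.10, 0.06, 0.04))
  base_mean <- runif(L0, cfg$copies_mean_range[1], cfg$copies_mean_range[2])
  base_sd <- runif(L0, cfg$copies_sd_range[1], cfg$copies_sd_range[2])

  nc <- cfg$conserved$n
  if (nc > 0) {
    cper <- sample(1:4, nc, replace = TRUE)
    cmean <- runif(nc, 10, 20)
    period <- c(period, cper)
    base_mean <- c(base_mean, cmean)
    base_sd <- c(base_sd, cfg$conserved$cov * cmean)
  }

  cat_df <- NULL
  if (!is.null(cfg$pathogenic)) {
    cat_df <- cfg$catalog
    period <- c(period, nchar(cat_df$unit))
    base_mean <- c(base_mean, cat_df$ref_bp / nchar(cat_df$unit))
    base_sd <- c(base_sd, rep(1, nrow(cat_df)))
  }
  L <- length(period)

  chrom <- paste0("chr", rep_len(1:22, L))
  pos <- 10000L + 1000L * seq_len(L)
  unit <- .random_unit(period)
  if (!is.null(cat_df)) {
    ii <- (L - nrow(cat_df) + 1L):L
    chrom[ii] <- cat_df$chrom; pos[ii] <- cat_df$pos; unit[ii] <- cat_df$unit
  }
  ref_copies <- pmax(1L, as.integer(round(base_mean)))
  loci <- data.frame(chrom = chrom, pos = pos, unit = unit,
                     period = as.integer(period),
                     ref_bp = as.integer(ref_copies * period),
                     stringsAsFactors = FALSE)

  # per-group mean copies, with divergent-locus shifts in one group
  mean_mat <- matrix(rep(base_mean, length(grps)), ncol = length(grps),
                     dimnames = list(NULL, grps))
  div_truth <- NULL
  if (cfg$divergent$n > 0) {
    di <- sort(sample(seq_len(L0), cfg$divergent$n))
    shift <- pmax(cfg$divergent$z_mult * base_sd[di],
                  cfg$divergent$pct * base_mean[di])
    mean_mat[di, cfg$divergent$group] <- base_mean[di] + shift
    div_truth <- data.frame(chrom = chrom[di], pos = pos[di], unit = unit[di],
                            group = cfg$divergent$group,
                            shift_copies = shift, stringsAsFactors = FALSE)
  }

  ## ---- samples -------------------------------------------------------
  singles <- do.call(rbind, lapply(grps, function(g) {
    n <- cfg$groups[[g]]
    if (n == 0) return(NULL)
    id <- sprintf("%s_%03d", g, seq_len(n))
    data.frame(sample = id, family = paste0("F_", id), role = "proband",
               group = g, father = "0", mother = "0", stringsAsFactors = FALSE)
  }))
  trios <- NULL
  if (cfg$n_trios > 0) {
    tg <- sample(grps, cfg$n_trios, replace = TRUE,
                 prob = cfg$groups / sum(cfg$groups))
    fam <- sprintf("T%03d", seq_len(cfg$n_trios))
    trios <- data.frame(family = fam, group = tg,
                        proband = paste0(fam, "_P"), mother = paste0(fam, "_M"),
                        father = paste0(fam, "_F"), stringsAsFactors = FALSE)
  }
  tri_rows <- if (!is.null(trios)) do.call(rbind, lapply(seq_len(nrow(trios)), function(i) {
    t <- trios[i, ]
    data.frame(sample = c(t$proband, t$mother, t$father), family = t$family,
               role = c("proband", "mother", "father"), group = t$group,
               father = c(t$father, "0", "0"), mother = c(t$mother, "0", "0"),
               stringsAsFactors = FALSE)
  })) else NULL
  samples <- rbind(singles, tri_rows)
  samples$self_report <- ifelse(samples$group == "PAC", "PAC", NA_character_)
  samples$mother_age <- ifelse(samples$role == "proband",
                               round(runif(nrow(samples), 20, 45)), NA_real_)
  samples$father_age <- ifelse(samples$role == "proband",
                               round(runif(nrow(samples), 20, 55)), NA_real_)

  ## ---- allele copies (L x S matrices) --------------------------------
  S <- nrow(samples)
  draw_group <- function(g, n) {
    m <- matrix(pmax(1, round(rnorm(L * n, mean = rep(mean_mat[, g], n),
                                    sd = rep(base_sd, n)))), nrow = L)
    m
  }
  a1 <- matrix(0L, L, S, dimnames = list(NULL, samples$sample))
  a2 <- a1
  founders <- samples$role != "proband" | samples$family %in% (singles$family %||% character())
  is_child <- !founders
  for (g in grps) {
    cols <- which(founders & samples$group == g)
    if (length(cols)) {
      a1[, cols] <- draw_group(g, length(cols))
      a2[, cols] <- draw_group(g, length(cols))
    }
  }

  ## ---- Mendelian transmission + de novo ------------------------------
  dn_truth <- list(); sw_truth <- list()
  if (!is.null(trios)) for (i in seq_len(nrow(trios))) {
    t <- trios[i, ]
    mo1 <- a1[, t$mother]; mo2 <- a2[, t$mother]
    fa1 <- a1[, t$father]; fa2 <- a2[, t$father]
    pick_m <- runif(L) < 0.5
    pick_f <- runif(L) < 0.5
    c1 <- ifelse(pick_m, mo1, mo2)     # maternal allele
    c2 <- ifelse(pick_f, fa1, fa2)     # paternal allele
    dn <- cfg$denovo
    u <- runif(L)
    if (dn$model == "jump" && (dn$expansion_rate > 0 || dn$contraction_rate > 0)) {
      par_max <- pmax(mo1, mo2, fa1, fa2)
      par_min <- pmin(mo1, mo2, fa1, fa2)
      exp_at <- which(u < dn$expansion_rate)
      con_at <- which(u >= dn$expansion_rate &
                        u < dn$expansion_rate + dn$contraction_rate)
      con_at <- con_at[floor(par_min[con_at] / dn$factor) >= 1]  # infeasible skipped
      if (length(exp_at)) {
        new <- as.integer(ceiling(dn$factor * par_max[exp_at]))
        side <- runif(length(exp_at)) < 0.5
        c1[exp_at[side]] <- new[side]; c2[exp_at[!side]] <- new[!side]
        dn_truth[[length(dn_truth) + 1L]] <- data.frame(
          family = t$family, proband = t$proband, chrom = chrom[exp_at],
          pos = pos[exp_at], unit = unit[exp_at], type = "expansion",
          allele_copies = new, stringsAsFactors = FALSE)
      }
      if (length(con_at)) {
        new <- as.integer(floor(par_min[con_at] / dn$factor))
        side <- runif(length(con_at)) < 0.5
        c1[con_at[side]] <- new[side]; c2[con_at[!side]] <- new[!side]
        dn_truth[[length(dn_truth) + 1L]] <- data.frame(
          family = t$family, proband = t$proband, chrom = chrom[con_at],
          pos = pos[con_at], unit = unit[con_at], type = "contraction",
          allele_copies = new, stringsAsFactors = FALSE)
      }
    } else if (dn$model == "stepwise" && dn$expansion_rate > 0) {
      at <- which(u < dn$expansion_rate)
      if (length(at)) {
        step <- sample(c(-1L, 1L), length(at), replace = TRUE)
        c1[at] <- pmax(1L, c1[at] + step)
        sw_truth[[length(sw_truth) + 1L]] <- data.frame(
          family = t$family, proband = t$proband, chrom = chrom[at],
          pos = pos[at], unit = unit[at], step = step, stringsAsFactors = FALSE)
      }
    }
    a1[, t$proband] <- c1
    a2[, t$proband] <- c2
  }

  ## ---- conserved-locus and pathogenic carrier injections --------------
  carrier_pool <- c(if (!is.null(trios)) trios$proband,
                    singles$sample %||% character())
  cons_truth <- NULL
  if (nc > 0) {
    ci <- L0 + seq_len(nc)
    rows <- list()
    for (k in seq_along(ci)) {
      n_car <- min(cfg$conserved$n_carriers, length(carrier_pool))
      car <- carrier_pool[((k - 1L) * n_car) %% length(carrier_pool) + seq_len(n_car)]
      newc <- as.integer(ceiling(cfg$conserved$expansion_factor * base_mean[ci[k]]))
      a1[ci[k], car] <- newc
      rows[[k]] <- data.frame(chrom = chrom[ci[k]], pos = pos[ci[k]],
                              unit = unit[ci[k]], target_cov = cfg$conserved$cov,
                              sample = car, allele_copies = newc,
                              stringsAsFactors = FALSE)
    }
    cons_truth <- do.call(rbind, rows)
  }
  path_truth <- NULL
  if (!is.null(cfg$pathogenic)) {
    rows <- list()
    for (k in seq_len(nrow(cfg$pathogenic))) {
      inj <- cfg$pathogenic[k, ]
      li <- which(loci$chrom == cat_df$chrom[cat_df$gene == inj$gene] &
                    loci$pos == cat_df$pos[cat_df$gene == inj$gene])
      per <- loci$period[li]
      if (inj$allele_bp %% per != 0)
        stopf("pathogenic injection for %s: %d bp is not a multiple of period %d",
              inj$gene, inj$allele_bp, per)
      n_car <- min(inj$n_carriers, length(carrier_pool))
      car <- carrier_pool[seq_len(n_car) + (k - 1L)]
      a1[li, car] <- inj$allele_bp %/% per
      rows[[k]] <- data.frame(gene = inj$gene, chrom = loci$chrom[li],
                              pos = loci$pos[li], unit = loci$unit[li],
                              sample = car, allele_bp = inj$allele_bp,
                              stringsAsFactors = FALSE)
    }
    path_truth <- do.call(rbind, rows)
  }

  ## ---- call table with genotyping model ------------------------------
  nz <- cfg$noise
  N <- L * S
  per_v <- rep(loci$period, S)
  a1v <- as.vector(a1) * per_v   # bp
  a2v <- as.vector(a2) * per_v
  lo1 <- a1v; hi1 <- a1v; lo2 <- a2v; hi2 <- a2v
  depth <- rep.int(as.integer(nz$depth_mean), N)
  qual <- rep.int(0.99, N)
  if (isTRUE(nz$enabled)) {
    depth <- pmax(1L, as.integer(round(rnorm(N, nz$depth_mean, nz$depth_sd))))
    qual <- round(runif(N, 0.90, 1), 3)
    ld <- runif(N) < nz$low_depth_rate
    depth[ld] <- sample(10:49, sum(ld), replace = TRUE)
    lq <- runif(N) < nz$low_quality_rate
    qual[lq] <- round(runif(sum(lq), 0.5, 0.89), 3)
    bc <- runif(N) < nz$bad_ci_rate
    lo1[bc] <- a1v[bc] + per_v[bc]; hi1[bc] <- a1v[bc] + 3L * per_v[bc]
  }
  enc <- depth %/% 4L; spa <- depth %/% 4L; frr <- depth %/% 4L
  fla <- depth - 3L * (depth %/% 4L)
  if (isTRUE(nz$enabled) && nz$spanbound_only_rate > 0) {
    sb <- runif(N) < nz$spanbound_only_rate
    spa[sb] <- spa[sb] + enc[sb] + frr[sb]
    enc[sb] <- 0L; frr[sb] <- 0L
  }
  miss <- rep(FALSE, N)
  if (isTRUE(nz$enabled) && nz$missing_rate > 0)
    miss <- runif(N) < nz$missing_rate
  calls <- data.frame(
    chrom = rep(loci$chrom, S), pos = rep(loci$pos, S),
    unit = rep(loci$unit, S), period = per_v,
    sample = rep(samples$sample, each = L),
    a1_bp = ifelse(miss, NA_integer_, a1v),
    a2_bp = ifelse(miss, NA_integer_, a2v),
    ci1_lo_bp = ifelse(miss, NA_integer_, lo1),
    ci1_hi_bp = ifelse(miss, NA_integer_, hi1),
    ci2_lo_bp = ifelse(miss, NA_integer_, lo2),
    ci2_hi_bp = ifelse(miss, NA_integer_, hi2),
    depth = ifelse(miss, NA_integer_, depth),
    quality = ifelse(miss, NA_real_, qual),
    n_enclosing = ifelse(miss, NA_integer_, enc),
    n_spanning = ifelse(miss, NA_integer_, spa),
    n_frr = ifelse(miss, NA_integer_, frr),
    n_flanking = ifelse(miss, NA_integer_, fla),
    missing = miss, stringsAsFactors = FALSE)

  ## ---- AIM panel and genotypes ---------------------------------------
  m <- cfg$aim$n_markers
  p_anc <- runif(m, cfg$aim$anc_range[1], cfg$aim$anc_range[2])
  Fst <- cfg$aim$fst
  a_sh <- p_anc * (1 - Fst) / Fst
  b_sh <- (1 - p_anc) * (1 - Fst) / Fst
  freqs <- vapply(AIM_POPS, function(p) clamp(rbeta(m, a_sh, b_sh), 0.02, 0.98),
                  numeric(m))
  rownames(freqs) <- sprintf("M%04d", seq_len(m))
  panel <- structure(list(freqs = freqs, members = NULL, evicted = NULL,
                          n_iter = 0L), class = "aim_panel")
  q_true <- t(vapply(samples$group, .group_q, numeric(4)))
  colnames(q_true) <- AIM_POPS
  rownames(q_true) <- samples$sample
  geno <- t(vapply(seq_len(S), function(i)
    simulate_aim_individual(q_true[i, ], panel), integer(m)))
  rownames(geno) <- samples$sample
  colnames(geno) <- rownames(freqs)

  truth <- list(
    divergent_loci = div_truth %||% data.frame(),
    conserved = cons_truth %||% data.frame(),
    pathogenic = path_truth %||% data.frame(),
    denovo = if (length(dn_truth)) do.call(rbind, dn_truth) else data.frame(),
    stepwise = if (length(sw_truth)) do.call(rbind, sw_truth) else data.frame(),
    q_true = q_true)

  structure(list(loci = loci, samples = samples, calls = calls,
                 aim = list(panel = panel, genotypes = geno, q_true = q_true),
                 truth = truth, config = cfg),
            class = "str_sim")
}

#' @export
print.str_sim <- function(x, ...) {
  cat("Synthetic STR cohort:", nrow(x$samples), "samples x", nrow(x$loci),
      "loci (seed", x$config$seed, ")\n")
  cat("  trios:", sum(x$samples$role == "mother"),
      " injected: ", nrow(x$truth$divergent_loci), "divergent loci,",
      nrow(x$truth$denovo), "de novo events,",
      nrow(x$truth$pathogenic), "pathogenic carriers\n")
  invisible(x)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits per-sample GangSTR-dialect VCFs (`vcf/<sample>.vcf`), a pedigree
#' TSV, AIM genotype and panel TSVs, and a ground-truth JSON.
#'
#' @param sim an `str_sim` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
sim_write <- function(sim, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  for (s in sim$samples$sample) {
    sub <- sim$calls[sim$calls$sample == s, , drop = FALSE]
    write_str_vcf(sub, sim$loci, file.path(dir, "vcf", paste0(s, ".vcf")),
                  samples = s)
  }
  ped <- sim$samples[, c("family", "sample", "father", "mother", "role",
                         "self_report", "mother_age", "father_age", "group")]
  write.table(ped, file.path(dir, "pedigree.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_aim_genotypes(sim$aim$genotypes, file.path(dir, "aim_genotypes.tsv"))
  write_aim_panel(sim$aim$panel, file.path(dir, "aim_panel.tsv"))
  truth <- sim$truth
  truth$q_true <- as.data.frame(truth$q_true)
  truth$q_true$sample <- rownames(sim$truth$q_true)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), dataframe = "rows",
                       digits = NA, na = "null")
  invisible(dir)
}
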