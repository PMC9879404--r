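#' Split a pedigree into the three study cohorts
#'
#' Population cohort: all parents plus probands whose parents are absent
#' from the data set. Proband cohort: all probands. Trio cohort: complete
#' trios. The cohorts overlap by construction; siblings are parsed but
#' belong to none of them.
#'
#' @param ped pedigree data.frame from [read_pedigree()].
#' @return list with `population` (sample ids), `probands` (sample ids),
#'   `trios` (complete-trio table).
#' @export
split_cohorts <- function(ped) {
  list(population = population_cohort(ped),
       probands = ped$sample[ped$role == "proband"],
       trios = trio_table(ped))
}

#' Annotate screen hits with overlapping genomic features
#'
#' Interval input is BED-style: 0-based, half-open on disk, converted to
#' 1-based closed internally so that a feature starting at BED position k
#' covers 1-based positions k+1 .. end. A hit position at the first base of
#' a feature is included.
#'
#' @param hits data.frame with `chrom` and `pos` (1-based) columns.
#' @param intervals path to a BED-like TSV (chrom, start, end, name) or an
#'   equivalent data.frame; must be sorted by chrom then start.
#' @return `hits` with a `region` column: comma-separated names of
#'   overlapping features, `"N/A"` when none overlap.
#' @export
annotate_intervals <- function(hits, intervals) {
  iv <- if (is.character(intervals))
    read.delim(intervals, header = FALSE,
               col.names = c("chrom", "start", "end", "name")) else intervals
  if (nrow(iv) > 1) {
    o <- order(iv$chrom, iv$start)
    if (!identical(o, seq_len(nrow(iv))))
      stopf("interval file is not sorted by chrom,start; sort it first")
  }
  hits$region <- "N/A"
  if (nrow(hits) == 0 || nrow(iv) == 0) return(hits)
  for (ch in unique(hits$chrom)) {
    hi <- which(hits$chrom == ch)
    ii <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(ii) == 0) next
    ir <- IRanges::IRanges(start = ii$start + 1L, end = ii$end)  # BED -> 1-based
    hr <- IRanges::IRanges(start = hits$pos[hi], width = 1L)
    ov <- IRanges::findOverlaps(hr, ir)
    if (length(ov) == 0) next
    lab <- tapply(ii$name[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), paste, collapse = ",")
    hits$region[hi[as.integer(names(lab))]] <- unname(lab)
  }
  hits
}

#' Pipeline configuration
#'
#' @param vcf_dir directory of GangSTR-dialect VCFs (all `.vcf` files read).
#' @param pedigree path to the pedigree TSV.
#' @param catalog path to the pathogenic catalog (default: packaged).
#' @param aim_panel path to the AIM frequency panel TSV.
#' @param aim_genotypes path to the AIM dosage TSV.
#' @param out_dir output directory for result TSVs and the manifest.
#' @param filter a [filter_params()] object.
#' @param z_threshold,pct_threshold,min_n divergence-screen settings.
#' @param ratio_threshold pathogenic-screen divergence cutoff.
#' @param cov_threshold,sd_mult,ratio_min conserved-screen settings.
#' @param intervals optional BED-like feature file for region annotation.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed covers any seeded upstream steps).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf_dir, pedigree, catalog = default_pathogenic_catalog(),
                            aim_panel = NULL, aim_genotypes = NULL,
                            out_dir = "strscreen_out",
                            filter = filter_params(),
                            z_threshold = 5, pct_threshold = 0.20, min_n = 10L,
                            ratio_threshold = 1.5,
                            cov_threshold = 0.075, sd_mult = 3, ratio_min = 2.5,
                            intervals = NULL, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Stages: (1) read VCFs, (2) call-level filters, (3) ancestry assignment
#' from AIM genotypes (or a `group` column in the pedigree when no AIM
#' inputs are given), (4) cohort split, (5) population baseline, (6)
#' divergence screen per non-European group, (7) pathogenic + conserved +
#' de novo screens. Writes one TSV per output plus `manifest.json`
#' recording stage counts, thresholds, seed, and md5 digests of inputs and
#' outputs; rerunning an identical configuration reproduces identical
#' digests.
#'
#' @param config a [pipeline_config()].
#' @return list of in-memory results (invisibly written to
#'   `config$out_dir`): baseline, ancestry, divergence (per group),
#'   pathogenic hits and gene summary, conserved hits, de novo scan,
#'   manifest.
#' @export
run_pipeline <- function(config) {
  cf <- config
  dir.create(cf$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  vcfs <- list.files(cf$vcf_dir, pattern = "\\.vcf$", full.names = TRUE)
  if (length(vcfs) == 0) stopf("pipeline stage 'read_vcfs' failed: no VCFs in %s", cf$vcf_dir)
  inp <- stage("read_vcfs", read_str_vcfs(vcfs))
  ped <- stage("read_pedigree", read_pedigree(cf$pedigree))
  catalog <- stage("read_catalog", read_pathogenic_catalog(cf$catalog))

  filt <- stage("call_filters", filter_cohort(inp$calls, cf$filter))

  ancestry <- stage("ancestry", {
    if (!is.null(cf$aim_genotypes) && !is.null(cf$aim_panel)) {
      geno <- read_aim_genotypes(cf$aim_genotypes)
      panel <- read_aim_panel(cf$aim_panel)
      sr <- setNames(ped$self_report %||% rep(NA, nrow(ped)), ped$sample)
      assign_cohort_ancestry(geno, panel, self_report = sr)
    } else if (!is.null(ped$group)) {
      data.frame(sample = ped$sample, primary = ped$group,
                 secondary = NA_character_, stringsAsFactors = FALSE)
    } else stopf("no AIM inputs and no group column in the pedigree")
  })
  assignment <- setNames(ancestry$primary, ancestry$sample)

  cohorts <- stage("split_cohorts", split_cohorts(ped))

  baseline <- stage("baseline",
                    build_population_baseline(filt$kept, ped, assignment))
  if (!any(baseline$stats$group == "EUR"))
    stopf("pipeline stage 'baseline' failed: no EUR samples; divergence screen needs a European baseline")

  groups_present <- setdiff(intersect(unique(assignment), ANCESTRY_GROUPS), "EUR")
  divergence <- stage("divergence", {
    out <- lapply(groups_present, function(g)
      screen_divergence(baseline$stats, g, cf$z_threshold, cf$pct_threshold, cf$min_n))
    names(out) <- groups_present
    out
  })

  pro_calls <- filt$kept[filt$kept$sample %in% cohorts$probands, , drop = FALSE]
  pathogenic <- stage("pathogenic", {
    hits <- screen_pathogenic(pro_calls, catalog, baseline$stats,
                              cf$ratio_threshold, assignment = assignment)
    list(hits = hits, by_gene = summarize_pathogenic_by_gene(hits),
         ancestral_means = pathogenic_ancestral_means(baseline$stats, catalog))
  })

  conserved <- stage("conserved",
                     screen_conserved_outliers(pro_calls, baseline$stats,
                                               cf$cov_threshold, cf$sd_mult,
                                               cf$ratio_min, cf$min_n))
  denovo <- stage("denovo", scan_trios(filt$kept, cohorts$trios))

  if (!is.null(cf$intervals)) {
    conserved <- annotate_intervals(conserved, cf$intervals)
    denovo$events <- annotate_intervals(denovo$events, cf$intervals)
  }

  ## ---- write outputs + manifest --------------------------------------
  out <- function(df, name) {
    write_results_tsv(df, file.path(cf$out_dir, name))
  }
  out(baseline$stats, "baseline.tsv")
  out(ancestry, "ancestry.tsv")
  for (g in names(divergence)) {
    out(divergence[[g]]$divergent, sprintf("divergent_%s.tsv", g))
    out(divergence[[g]]$scatter, sprintf("scatter_%s.tsv", g))
  }
  out(pathogenic$hits, "pathogenic_hits.tsv")
  out(pathogenic$by_gene, "pathogenic_by_gene.tsv")
  out(pathogenic$ancestral_means, "pathogenic_ancestral_means.tsv")
  out(conserved, "conserved_hits.tsv")
  out(denovo$events, "denovo_events.tsv")
  out(denovo$per_proband, "denovo_per_proband.tsv")

  outputs <- list.files(cf$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("strscreen")),
    seed = cf$seed,
    stages_completed = c("read_vcfs", "call_filters", "ancestry",
                         "split_cohorts", "baseline", "divergence", "screens"),
    thresholds = list(filter = unclass(cf$filter), z = cf$z_threshold,
                      pct = cf$pct_threshold, ratio = cf$ratio_threshold,
                      cov = cf$cov_threshold, sd_mult = cf$sd_mult,
                      ratio_min = cf$ratio_min, min_n = cf$min_n),
    counts = list(n_samples = length(unique(inp$calls$sample)),
                  n_loci = nrow(inp$loci),
                  n_calls_kept = filt$n_kept, n_calls_dropped = filt$n_dropped,
                  n_trios = nrow(cohorts$trios),
                  n_denovo_events = nrow(denovo$events)),
    input_digests = as.list(tools::md5sum(sort(c(vcfs, cf$pedigree, cf$catalog)))),
    output_digests = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(cf$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(baseline = baseline, ancestry = ancestry,
                 divergence = divergence, pathogenic = pathogenic,
                 conserved = conserved, denovo = denovo,
                 filter_summary = filt$summary, manifest = manifest))
}
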