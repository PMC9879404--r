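#' Read an STR genotype VCF in the GangSTR dialect
#'
#' Parses a (possibly multi-sample) VCF whose records carry the repeat unit
#' and period in INFO and, per sample, the repeat copy-number genotype with
#' bootstrap confidence intervals, depth, quality and read-class counts in
#' FORMAT. Copy numbers are converted to allele lengths in base pairs
#' (copies x period) at parse time, by exact integer arithmetic.
#'
#' @param path path to an uncompressed or bgzipped VCF file.
#' @param unit unit for allele lengths in the returned calls: `"bp"`
#'   (default; copies x period) or `"copies"`.
#' @param format_keys named list overriding the GangSTR default FORMAT key
#'   names: `copy_number` ("REPCN"), `ci` ("REPCI"), `depth` ("DP"),
#'   `quality` ("Q"), `read_counts` ("RC").
#' @return a list with elements `loci` (data.frame: chrom, pos, unit, period,
#'   ref_bp, in file order) and `calls` (data.frame with one row per locus x
#'   sample: chrom, pos, unit, period, sample, a1_bp, a2_bp, ci1_lo_bp,
#'   ci1_hi_bp, ci2_lo_bp, ci2_hi_bp, depth, quality, n_enclosing,
#'   n_spanning, n_frr, n_flanking, missing). Uncalled genotypes yield rows
#'   flagged `missing = TRUE` with NA lengths.
#' @details Records whose repeat period falls outside 1-6 bp are skipped with
#'   a warning. A file that cannot be framed as VCF raises a parse error
#'   naming the offending line; a record lacking the dialect's INFO/FORMAT
#'   keys raises a dialect error.
#' @seealso [write_str_vcf()] for the inverse operation.
#' @export
read_str_vcf <- function(path, unit = c("bp", "copies"), format_keys = list()) {
  unit <- match.arg(unit)
  keys <- modifyList(list(copy_number = "REPCN", ci = "REPCI", depth = "DP",
                          quality = "Q", read_counts = "RC"), format_keys)
  if (!file.exists(path)) stopf("VCF file not found: %s", path)

  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)),
    error = function(e) .vcf_parse_error(path, conditionMessage(e))
  )
  if (nrow(v@fix) == 0) .vcf_parse_error(path, "no data records")

  fix <- v@fix
  ru <- vcfR::extract.info(v, "RU")
  period <- suppressWarnings(as.integer(vcfR::extract.info(v, "PERIOD")))
  if (all(is.na(ru)) || all(is.na(period)))
    stopf("VCF dialect error in %s: INFO keys RU and PERIOD are required", path)

  keep <- !is.na(period) & period >= 1L & period <= 6L & !is.na(ru)
  if (!all(keep)) {
    bad <- which(!keep)
    warnf("%d locus/loci skipped (repeat period outside [1,6] or missing RU), e.g. %s:%s",
          length(bad), fix[bad[1], "CHROM"], fix[bad[1], "POS"])
  }

  samples <- colnames(v@gt)[-1]
  if (is.null(samples) || length(samples) == 0)
    stopf("VCF dialect error in %s: no sample columns", path)

  ext <- function(key) {
    m <- tryCatch(vcfR::extract.gt(v, element = key),
                  error = function(e) NULL)
    if (is.null(m)) stopf("VCF dialect error in %s: FORMAT key %s absent", path, key)
    m
  }
  repcn <- ext(keys$copy_number)
  repci <- ext(keys$ci)
  dp <- ext(keys$depth)
  qual <- ext(keys$quality)
  rc <- ext(keys$read_counts)

  idx <- which(keep)
  L <- length(idx); S <- length(samples)
  loci <- data.frame(
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    unit = ru[idx],
    period = period[idx],
    ref_bp = nchar(fix[idx, "REF"]),
    stringsAsFactors = FALSE, row.names = NULL
  )

  # stack loci x samples column-major (all loci of sample 1, then sample 2 ...)
  flat <- function(m) as.vector(m[idx, , drop = FALSE])
  cn <- flat(repcn); ci <- flat(repci); rcv <- flat(rc)
  per <- rep(loci$period, times = S)

  miss <- is.na(cn) | cn == "." | cn == ""
  cn_sp <- data.table::tstrsplit(ifelse(miss, "NA,NA", cn), ",", fixed = TRUE)
  if (length(cn_sp) != 2)
    stopf("VCF dialect error in %s: %s is not a pair of copy numbers", path, keys$copy_number)
  a1 <- suppressWarnings(as.integer(cn_sp[[1]])); a2 <- suppressWarnings(as.integer(cn_sp[[2]]))
  bad_cn <- !miss & (is.na(a1) | is.na(a2))
  if (any(bad_cn))
    stopf("VCF parse error in %s: malformed %s value '%s'", path, keys$copy_number,
          cn[which(bad_cn)[1]])

  ci_sp <- data.table::tstrsplit(ifelse(is.na(ci) | ci == ".", "NA-NA,NA-NA", ci),
                                 "[,-]")
  if (length(ci_sp) < 4) ci_sp <- c(ci_sp, rep(list(NA_character_), 4 - length(ci_sp)))
  ci1l <- suppressWarnings(as.integer(ci_sp[[1]])); ci1h <- suppressWarnings(as.integer(ci_sp[[2]]))
  ci2l <- suppressWarnings(as.integer(ci_sp[[3]])); ci2h <- suppressWarnings(as.integer(ci_sp[[4]]))

  rc_sp <- data.table::tstrsplit(ifelse(is.na(rcv) | rcv == ".", "NA,NA,NA,NA", rcv),
                                 ",", fixed = TRUE)
  if (length(rc_sp) < 4) rc_sp <- c(rc_sp, rep(list(NA_character_), 4 - length(rc_sp)))
  rcm <- lapply(rc_sp[1:4], function(x) suppressWarnings(as.integer(x)))

  mult <- if (unit == "bp") per else 1L
  calls <- data.frame(
    chrom = rep(loci$chrom, times = S),
    pos = rep(loci$pos, times = S),
    unit = rep(loci$unit, times = S),
    period = per,
    sample = rep(samples, each = L),
    a1_bp = a1 * mult, a2_bp = a2 * mult,
    ci1_lo_bp = ci1l * mult, ci1_hi_bp = ci1h * mult,
    ci2_lo_bp = ci2l * mult, ci2_hi_bp = ci2h * mult,
    depth = suppressWarnings(as.integer(flat(dp))),
    quality = suppressWarnings(as.numeric(flat(qual))),
    n_enclosing = rcm[[1]], n_spanning = rcm[[2]],
    n_frr = rcm[[3]], n_flanking = rcm[[4]],
    missing = miss,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(loci = loci, calls = calls)
}

# locate the first line that does not frame as VCF, for a useful message
.vcf_parse_error <- function(path, why) {
  ln <- tryCatch({
    lines <- readLines(path, warn = FALSE)
    body <- which(!startsWith(lines, "#"))
    nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
    if (length(body) && any(nf < 10)) body[which(nf < 10)[1]] else NA_integer_
  }, error = function(e) NA_integer_)
  if (!is.na(ln))
    stopf("VCF parse error in %s at line %d: fewer than 10 tab-separated fields", path, ln)
  stopf("VCF parse error in %s: %s", path, why)
}

#' Read and merge several single- or multi-sample STR VCFs
#'
#' Loci are merged by the key chrom:pos:repeat-unit; a locus absent from one
#' file is treated as missing calls for that file's samples, not an error.
#'
#' @param paths character vector of VCF paths.
#' @inheritParams read_str_vcf
#' @return as [read_str_vcf()], with loci in first-seen order.
#' @export
read_str_vcfs <- function(paths, unit = "bp", format_keys = list()) {
  parts <- lapply(paths, read_str_vcf, unit = unit, format_keys = format_keys)
  loci <- do.call(rbind, lapply(parts, `[[`, "loci"))
  loci <- loci[!duplicated(locus_key(loci$chrom, loci$pos, loci$unit)), , drop = FALSE]
  row.names(loci) <- NULL
  calls <- do.call(rbind, lapply(parts, `[[`, "calls"))
  row.names(calls) <- NULL
  list(loci = loci, calls = calls)
}

#' Write STR calls as a GangSTR-dialect VCF
#'
#' Inverse of [read_str_vcf()]: emits one record per locus with REF/ALT
#' repeat sequences, `RU` and `PERIOD` in INFO, and per-sample
#' `GT:DP:Q:REPCN:REPCI:RC` fields. Allele lengths must be exact multiples
#' of the repeat period (they are stored as copies in the file).
#'
#' @param calls calls data.frame as returned by [read_str_vcf()].
#' @param loci loci data.frame as returned by [read_str_vcf()].
#' @param path output file path.
#' @param samples optional sample order; defaults to first-seen order.
#' @return `path`, invisibly.
#' @export
write_str_vcf <- function(calls, loci, path, samples = NULL) {
  if (is.null(samples)) samples <- unique(calls$sample)
  dt <- data.table::as.data.table(calls)
  dt[, key := locus_key(chrom, pos, unit)]
  lk <- locus_key(loci$chrom, loci$pos, loci$unit)

  rep_seq <- function(unitv, bp) {
    full <- strrep(unitv, ceiling(bp / nchar(unitv)))
    substr(full, 1L, bp)
  }

  fmt_sample <- function(row, per, ref_bp, alt_bp) {
    if (is.na(row$a1_bp) || isTRUE(row$missing)) return("./.:.:.:.:.:.")
    gt_idx <- function(bp) if (bp == ref_bp) 0L else match(bp, alt_bp)
    g <- paste0(gt_idx(row$a1_bp), "/", gt_idx(row$a2_bp))
    repcn <- paste0(row$a1_bp %/% per, ",", row$a2_bp %/% per)
    repci <- paste0(row$ci1_lo_bp %/% per, "-", row$ci1_hi_bp %/% per, ",",
                    row$ci2_lo_bp %/% per, "-", row$ci2_hi_bp %/% per)
    rc <- paste(row$n_enclosing, row$n_spanning, row$n_frr, row$n_flanking, sep = ",")
    paste(g, row$depth, format(row$quality, digits = 15, scientific = FALSE),
          repcn, repci, rc, sep = ":")
  }

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=strscreen",
    "##INFO=<ID=RU,Number=1,Type=String,Description=\"Repeat unit\">",
    "##INFO=<ID=PERIOD,Number=1,Type=Integer,Description=\"Repeat unit length (bp)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=Q,Number=1,Type=Float,Description=\"Genotype quality (0-1)\">",
    "##FORMAT=<ID=REPCN,Number=1,Type=String,Description=\"Allele repeat copy numbers\">",
    "##FORMAT=<ID=REPCI,Number=1,Type=String,Description=\"95% bootstrap CIs on copy numbers\">",
    "##FORMAT=<ID=RC,Number=1,Type=String,Description=\"Read class counts: enclosing,spanning,FRR,flanking\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t")
  )

  bad <- dt[!(missing) & (a1_bp %% period != 0L | a2_bp %% period != 0L)]
  if (nrow(bad) > 0)
    stopf("allele length not a multiple of the repeat period at %s", bad$key[1])

  recs <- vapply(seq_len(nrow(loci)), function(i) {
    li <- loci[i, ]
    sub <- dt[key == lk[i]]
    sub <- sub[match(samples, sub$sample)]
    lens <- c(sub$a1_bp, sub$a2_bp)
    alt_bp <- sort(setdiff(lens[!is.na(lens)], li$ref_bp))
    alt <- if (length(alt_bp) == 0) "." else
      paste(rep_seq(li$unit, alt_bp), collapse = ",")
    cells <- vapply(seq_len(nrow(sub)), function(j)
      fmt_sample(sub[j], li$period, li$ref_bp, alt_bp), character(1))
    paste(c(li$chrom, li$pos, ".", rep_seq(li$unit, li$ref_bp), alt, ".", ".",
            sprintf("RU=%s;PERIOD=%d", li$unit, li$period),
            "GT:DP:Q:REPCN:REPCI:RC", cells), collapse = "\t")
  }, character(1))

  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read a pedigree file
#'
#' Tab-separated with columns `family`, `sample`, `father`, `mother`, `role`
#' (role one of proband, mother, father, sibling); extra columns such as
#' `self_report`, `mother_age`, `father_age` are carried through. A trio is
#' one proband plus one mother and one father sharing a family id.
#'
#' @param path pedigree TSV path.
#' @return data.frame of samples, with attribute `"trios"` holding the
#'   complete-trio table from [trio_table()].
#' @export
read_pedigree <- function(path) {
  ped <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family", "sample", "father", "mother", "role")
  if (!all(need %in% names(ped)))
    stopf("pedigree must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(ped$sample))
    stopf("duplicate sample id in pedigree: %s", ped$sample[duplicated(ped$sample)][1])
  own <- ped$sample == ped$father | ped$sample == ped$mother
  own[is.na(own)] <- FALSE
  if (any(own)) stopf("sample listed as its own parent: %s", ped$sample[own][1])
  okroles <- c("proband", "mother", "father", "sibling")
  if (!all(ped$role %in% okroles))
    stopf("unknown role '%s' (expected %s)", setdiff(ped$role, okroles)[1],
          paste(okroles, collapse = "/"))
  attr(ped, "trios") <- trio_table(ped)
  ped
}

#' Complete trios in a pedigree
#'
#' @param ped pedigree data.frame from [read_pedigree()].
#' @return data.frame with one row per complete trio: family, proband,
#'   mother, father.
#' @export
trio_table <- function(ped) {
  out <- lapply(split(ped, ped$family), function(f) {
    pro <- f$sample[f$role == "proband"]
    mo <- f$sample[f$role == "mother"]
    fa <- f$sample[f$role == "father"]
    if (length(pro) >= 1 && length(mo) == 1 && length(fa) == 1)
      data.frame(family = f$family[1], proband = pro[1], mother = mo, father = fa,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(family = character(), proband = character(),
                      mother = character(), father = character())
  row.names(out) <- NULL
  out
}

#' Read a pathogenic STR locus catalog
#'
#' TSV with columns `gene`, `chrom`, `pos`, `unit`, `ref_bp`,
#' `pathogenic_bp` (published pathogenic allele-length threshold in base
#' pairs). The packaged default catalog covers six well-characterised
#' disease loci (AR, TCF4, DMPK, DIP2B, ATXN10, RFC1).
#'
#' @param path catalog path; defaults to the packaged catalog.
#' @return data.frame of catalog records, keyed by locus.
#' @export
read_pathogenic_catalog <- function(path = default_pathogenic_catalog()) {
  cat_df <- tryCatch(read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
                     error = function(e) NULL)
  if (is.null(cat_df) || nrow(cat_df) == 0) {
    warnf("empty pathogenic catalog: %s", path)
    return(data.frame(gene = character(), chrom = character(), pos = integer(),
                      unit = character(), ref_bp = integer(),
                      pathogenic_bp = integer()))
  }
  need <- c("gene", "chrom", "pos", "unit", "pathogenic_bp")
  if (!all(need %in% names(cat_df)))
    stopf("catalog must have columns: %s", paste(need, collapse = ", "))
  if (any(cat_df$pathogenic_bp <= 0))
    stopf("non-positive pathogenic length for gene %s",
          cat_df$gene[cat_df$pathogenic_bp <= 0][1])
  cat_df
}

#' Path to the packaged six-gene pathogenic catalog
#' @return file path of the default catalog TSV.
#' @export
default_pathogenic_catalog <- function() {
  system.file("extdata", "pathogenic_catalog.tsv", package = "strscreen",
              mustWork = TRUE)
}

#' Write screen results as TSV
#'
#' Deterministic row order: by chrom, pos, then sample where those columns
#' exist; an empty record set yields a header-only file.
#'
#' @param records data.frame of screen output records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(records, path) {
  ord <- intersect(c("chrom", "pos", "sample"), names(records))
  if (length(ord) && nrow(records))
    records <- records[do.call(order, records[ord]), , drop = FALSE]
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
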