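Package: strscreen
Title: Genome-Wide Short Tandem Repeat Screening Across Ancestral Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-scale analysis of short tandem repeat (STR)
    genotypes called from sequencing data. Reads STR genotype VCFs in the
    GangSTR dialect, applies call-level quality filters, estimates four-way
    genetic admixture from ancestry-informative marker (AIM) SNPs by maximum
    likelihood, computes per-locus allele-length statistics per ancestry
    group, and runs four screens: ancestry divergence of mean allele length,
    expansion at known pathogenic loci, outlier expansions at conserved
    (low coefficient-of-variation) loci, and trio-based de novo expansion
    and contraction detection. Includes a seeded synthetic-cohort generator
    emitting the pipeline's input formats together with ground-truth tables,
    and an end-to-end pipeline driver with deterministic manifests.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    vcfR,
    jsonlite,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
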