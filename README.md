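# strscreen

Genome-wide screening of short tandem repeat (STR) allele lengths across
ancestral groups, from GangSTR-dialect genotype VCFs to four screen
reports.

## The problem

STRs — tandem repeats of 1–6 bp motifs — underlie dozens of expansion
disorders, yet most cohort-scale surveys of STR length variation have been
Europe-centric. Given STR genotype calls for a clinical cohort (probands,
parents, trios), `strscreen`:

1. **filters calls** with the standard dumpSTR-style criteria
   (depth in [50, 1000], genotype quality ≥ 0.90, length-bounding read
   support, maximum-likelihood genotype inside its 95% bootstrap CI);
2. **assigns 4-way genetic admixture** (AFR, EUR, EAS, AMR) from a panel of
   ancestry-informative biallelic SNPs (AIMs) by maximum likelihood, and
   derives primary/secondary ancestry labels (> 60% primary; 50–60% adds a
   secondary; AMR > 75% is "non-admixed American"; Pacific Islanders by
   self-report);
3. **computes per-locus baselines** — allele tally, mean, population SD
   (divisor *n*), coefficient of variation, standard error — per ancestry
   group and for the pooled total; and
4. **runs four screens**:
   - *ancestry divergence*: a locus is divergent in group *g* when
     `z = (mean_g − mean_EUR) / sd_EUR` satisfies |z| > 5 **and** the
     relative difference `|mean_g − mean_EUR| / mean_EUR` exceeds 20%;
   - *pathogenic loci*: longest proband allele ≥ 1.5 × the population mean
     is divergent; strictly above the published pathogenic length
     (e.g. 150 bp at TCF4/DMPK) is an exceedance — the flags are
     independent;
   - *conserved-region outliers*: at loci with coefficient of variation
     ≤ 0.075, flag proband alleles > 3 SD above **and** ≥ 2.5 × the mean;
   - *trio de novo events*: proband longest allele strictly > 2 × the
     longest parental allele (expansion), or shortest allele strictly
     < 0.5 × the shortest parental allele (contraction).

A seeded synthetic-cohort generator (`sim_config()` / `simulate_cohort()`)
emits all input formats with ground-truth tables, so every screen is
validated by truth recovery rather than by fixtures.

## Worked example

```r
library(strscreen)

cfg <- sim_config(seed = 7, n_loci = 100, n_trios = 5,
                  groups = c(AFR = 10, EUR = 20, EAS = 5, AdmixedAMR = 8,
                             NonadmixedAMR = 4, PAC = 3),
                  divergent = list(n = 5),
                  denovo = list(expansion_rate = 1e-2, contraction_rate = 1e-3))
sim  <- simulate_cohort(cfg)
filt <- filter_cohort(sim$calls)
anc  <- setNames(sim$samples$group, sim$samples$sample)
bl   <- build_population_baseline(filt$kept, sim$samples, anc)
scr  <- screen_divergence(bl$stats, "AFR")
nrow(scr$divergent)
#> [1] 5                      # all five injected shifts, nothing else
dn <- scan_trios(filt$kept, trio_table(sim$samples))
nrow(dn$events); nrow(sim$truth$denovo)
#> [1] 4
#> [1] 4                      # every injected de novo jump, no extras

fit <- estimate_admixture(sim$aim$genotypes[1, ], sim$aim$panel)
fit
#> Supervised admixture fit (250 markers, 734 EM iterations)
#> AFR EUR EAS AMR
#>   1   0   0   0
#> log-likelihood: -190.23462
assign_ancestry(fit)$primary
#> [1] "AFR"
```

The divergent count is the number of loci passing both the |z| > 5 and
> 20% criteria against the European baseline; the de novo counts show the
trio rule recovering exactly the injected 2.5× jumps; the admixture fit
shows a pure-AFR individual recovered from its AIM genotypes.

A full run over files on disk goes through `run_pipeline(pipeline_config(...))`
or the thin CLI in `inst/cli/strscreen.R`; both write one TSV per screen
plus a `manifest.json` with input/output digests.

## Limitations

The simulator draws allele lengths as discretised normals over repeat
copy number, not from a full stepwise-mutation process, and its default
genotyping-noise model is off; real call sets carry stutter, dropout and
reference bias that these screens inherit from their inputs. Screens
apply no multiple-testing correction, by design. See the methods vignette
(`vignettes/str-screening-methods.Rmd`) for the model details and the
reasoning behind each threshold interpretation.
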