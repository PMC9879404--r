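---
title: "Methods: cohort-scale STR screening across ancestral groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-scale STR screening across ancestral groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strscreen)
```

`strscreen` turns short tandem repeat (STR) genotype calls into four
screen reports: ancestry divergence of mean allele length, expansions at
known pathogenic loci, outlier expansions at conserved loci, and trio de
novo events. This vignette documents the models and conventions behind
each stage, the parameters that matter, what the synthetic-cohort
generator does and does not emulate, and the design choices made where
more than one reading of the procedure was defensible.

## Data model and units

Allele lengths are stored in **base pairs** throughout: the GangSTR VCF
dialect reports repeat copy numbers, and the reader converts them at parse
time as `copies x period` by exact integer arithmetic. The reason is that
every published decision threshold in this problem — pathogenic cutoffs of
114, 150, 600 and 4000 bp, conserved-region tables — is quoted in base
pairs. Positions are 1-based (VCF convention); BED-style interval inputs
are 0-based half-open on disk and converted on read, so a feature starting
at BED coordinate `k` covers 1-based positions `k+1..end`.

Cohorts follow the three-group design used in trio-based clinical
sequencing. The *population cohort* — all parents plus only those probands
whose parents are absent from the data set — supplies every baseline
statistic, so that probands screened against the baseline do not dominate
it. The *proband cohort* is all probands; the *trio cohort* is complete
mother–father–proband triples. Siblings are parsed but excluded from all
three.

## Call-level filters

`filter_params()` mirrors the dumpSTR parameter set: depth within
\[50, 1000\], genotype quality at least 0.90, rejection of calls whose
read evidence is only spanning/flanking (no enclosing or fully-repetitive
reads — the two classes that actually bound allele length), and rejection
of calls where either allele's maximum-likelihood length falls outside its
own 95% bootstrap confidence interval. The printed thresholds carry no
strictness annotation; we take keep-side inequalities as inclusive
(depth = 50 is kept), which the boundary tests pin down. Failed calls
record *every* failed sub-filter, not just the first, so filter summaries
are interpretable. Filtering is idempotent and monotone in each
threshold, and exclusion is per locus: an individual failing the filter
at one locus still contributes everywhere else.

## Admixture from ancestry-informative markers

Ancestry is estimated under the standard supervised binomial-mixture
admixture model. With panel alternate-allele frequencies $f_{ki}$ for
superpopulations $k \in \{AFR, EUR, EAS, AMR\}$ and dosages
$g_i \in \{0,1,2\}$, the admixture vector $q$ on the 3-simplex maximises

$$\ell(q) = \sum_i \left[ g_i \log p_i + (2-g_i)\log(1-p_i) \right],
\qquad p_i = \sum_k q_k f_{ki}.$$

No inference algorithm is prescribed by the procedure we reimplement, so
we chose EM from a fixed uniform initialisation: it is deterministic,
monotone in the log-likelihood, and the concavity of $\ell$ in $p$ along
the simplex makes the optimum effectively unique; a test verifies the EM
optimum against an exhaustive grid search at 0.01 resolution. Panel
frequencies are clamped to $[10^{-3}, 1-10^{-3}]$ so fixed alleles cannot
produce infinite log-likelihoods. A panel with no frequency contrast is
flagged non-identifiable and returns the uniform vector.

Label assignment applies, in order: Pacific Islander self-report (PAC is a
self-reported label, its members carrying mostly EUR/EAS markers);
AMR > 0.75 as non-admixed American; a component > 0.60 as primary; a
maximum in \[0.50, 0.60\] as primary plus the runner-up as secondary;
otherwise unassigned. Argmax ties break in the fixed order AFR, EUR, EAS,
AMR.

Reference-panel curation (`prune_reference_panel()`) iterates
frequency-estimation / member-classification / eviction of members whose
own-label fraction falls below a threshold, then downsamples each
population to at most 300 members. The eviction threshold is not a
published constant; the default 0.75 is our curation choice, exposed as an
argument and recorded in the returned object.

## Per-locus baselines

`compute_group_stats()` pools **both alleles** of every filter-passing
call (a longest-allele-only mode exists because allele-level conventions
differ between studies), and reports count, mean, *population* standard
deviation (divisor $n$, following the procedure's explicit wording),
coefficient of variation $\mathrm{cov} = s/\bar{x}$, and standard error.
Aggregation is single-pass over a long allele table; a test requires exact
tally agreement and $10^{-9}$ relative agreement of moments with a naive
two-pass recomputation. Hemizygous calls contribute the alleles present in
the genotype — no special-casing of male X loci, a documented
simplification.

## The four screens

**Ancestry divergence.** For each non-European group,
$z = (\bar{x}_g - \bar{x}_{EUR})/s_{EUR}$ and
$\mathrm{pct} = |\bar{x}_g - \bar{x}_{EUR}|/\bar{x}_{EUR}$; a locus is
divergent when $|z| > 5$ and $\mathrm{pct} > 0.20$, both strict. The
denominator is the European SD — the screen asks how many *European*
standard deviations a group mean has moved; a two-sample z using combined
standard errors is available behind a switch. The 20% criterion is
relative to the European mean (the natural reference given the screen's
framing); zero European SD with unequal means yields an infinite z and the
percentage criterion decides, logged. A minimum of 10 alleles per group
(configurable) guards against unstable means in small groups. No
multiple-testing correction is applied — the screen reproduces a
threshold rule, not a calibrated test. Top-divergent lists rank by |z|
with pct then locus-key tie-breaks, so rankings are reproducible.

**Pathogenic loci.** The longest proband allele at each catalog locus is
compared with the total-population mean. The source procedure states the
divergence cutoff inconsistently (150% in the results that generated the
published per-gene table; 250% in the methods summary). We default to
`ratio_threshold = 1.5` — the value consistent with the published
counts — and expose 2.5 as an argument. "Difference" is read as the
allele-to-mean **ratio** (see the conserved screen for why), inclusive at
the threshold; pathogenic exceedance is strict (`allele > pathogenic_bp`).
The two flags are deliberately independent: an allele can exceed a
pathogenic length without tripling a high population mean, and vice
versa. The packaged catalog ships the six printed loci (AR, TCF4, DMPK,
DIP2B, ATXN10, RFC1) with literature hg19 coordinates; its schema is a
plain TSV users can extend.

**Conserved-region outliers.** "Covariance" in the source is read as the
coefficient of variation: the printed per-locus values (0.035–0.070) are
dimensionless and equal sd/mean at the printed means, whereas a
single-variable covariance would be a variance in bp². Conservation is
$\mathrm{cov} \le 0.075$, inclusive per the printed "< =". The outlier
rule is two-stage — allele > mean + 3 SD, then allele ≥ 2.5 × mean — and
both stage outputs are reported. "At least 250% larger than the mean" is
read as the **ratio** `allele >= 2.5 * mean`: under the alternative
`(allele-mean)/mean >= 2.5` reading, the five published example rows fail
their own table (their percent differences are 175%–237%), so the ratio
reading is the only one consistent with the published data. Both readings
are implemented; ratio is the default.

**Trio de novo events.** An expansion requires the proband's longest
allele to strictly exceed twice the longest allele across both parents; a
contraction requires the shortest proband allele strictly below half the
shortest parental allele. All three members must pass call filters at the
locus — un-filtered parental calls would inflate candidate counts, and
orthogonal validation of this class of candidate is known to prune most of
them. Single-repeat stepwise mutations are, by construction, invisible to
a 2× rule; the simulator includes a stepwise mode precisely to verify they
are not flagged. Per-proband counts, their mean/range, and Pearson
correlations against parental age (undefined below 3 pairs or at zero
variance, and reported as such) summarise the scan.

## The synthetic-cohort generator

`simulate_cohort()` emulates the statistical structure the screens
assume, not the biology of replication slippage:

- **Allele lengths** are discretised normals over repeat copy number
  (floored at one copy), with per-locus mean copies uniform on \[8, 30\]
  and SD on \[0.5, 2.5\] — spans typical of polymorphic genomic STRs.
  A full stepwise-mutation chain is deliberately not simulated: the
  screens consume only per-locus means and SDs, and the discretised
  normal parameterises those directly.
- **Divergent loci** shift one group's mean by
  `max(z_mult * sd, pct * mean)` copies (defaults 8 SD / 30%) — large
  enough that the |z| > 5 and 20% criteria are achievable at desk-scale
  allele counts.
- **Conserved loci** target cov = 0.03 with injected `3 x mean` carrier
  alleles; carriers are drawn from trio probands first so the population
  baseline stays clean, mirroring the population/proband cohort split.
- **Trios** transmit one allele per parent uniformly; de novo jumps set a
  child allele to `ceiling(factor x parental extreme)` so an injected
  event always crosses the detection boundary; infeasible contractions
  (below one copy) are skipped and excluded from truth.
- **AIM genotypes** are Binomial(2, q·f) draws from Balding–Nichols
  frequencies: per marker an ancestral frequency uniform on
  \[0.05, 0.95\] and per-population frequencies Beta-distributed around it
  with F = 0.3. AIM panels are *selected* for informativeness, so a high
  divergence parameter is the realistic choice; pure-population
  individuals are then recovered with q ≥ 0.95 and cohort-wide mean
  absolute error is well under 0.05 at 250 markers.
- **Genotyping noise** (depth/quality jitter, bad CIs, spanning-only
  support, missingness) is off by default so truth-recovery tests are
  exact; enabling it exercises the call filters.

Everything derives from a single integer seed; two runs from the same
configuration are byte-identical through VCF emission. What passing these
tests shows is that the screens implement their rules exactly and recover
planted structure under the model's assumptions; what they cannot show is
robustness to real-data artefacts — stutter, allele dropout, reference
bias, length-dependent call failure — which enter upstream of this
package.

## Numerical choices and problem sizes

EM stops when the log-likelihood improves by less than $10^{-12}$ or at
2000 iterations; near-boundary optima converge slowly in steps but the
attained log-likelihood matches the grid oracle to well under $10^{-6}$.
Statistics use double precision with exact integer tallies. Validation
problem sizes were chosen to exercise the asymptotics the screens rely on
while keeping the full suite in minutes on one CPU: 5,000 loci × six
groups of 100 individuals for divergence recovery, 100 trios × 1,000 loci
for de novo recovery, 100 individuals × 250 markers for admixture
accuracy, with an exhaustive simplex grid at 0.01 resolution as the
estimator oracle on 40-marker instances.

## Known limitations

Published counts from the clinical cohort this design follows (total
divergent loci per ancestry, genome-wide de novo totals) are functions of
restricted patient data and are not reproducible from synthetic cohorts;
validation is therefore property-based. The source text also reports
mutually inconsistent counts for its conserved-region stages (35 vs 43 vs
80 positions); we emit both stage outputs and reconcile nothing. X-linked
loci receive no hemizygosity-aware treatment, and expansions beyond the
read-length regime (≫150 bp) are screenable here only insofar as the
upstream genotyper could call them.
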