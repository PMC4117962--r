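---
title: "Mapping a lethal recessive defect: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a lethal recessive defect: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recmapr)
```

## The problem

A recessive lethal that recently arose on a common haplotype shows a
characteristic signature in a livestock population: a handful of affected
animals that are all autozygous — homozygous identical-by-descent — for
the same chromosomal segment; a low-frequency carrier haplotype in the
wider population; and excess mortality among calves from matings in which
both the sire and the maternal grandsire carry the allele. `recmapr`
implements the full desk-side analysis chain for this situation:

1. **Marker QC** on SNP-array genotypes (chromosome class, call rate, MAF).
2. **Mixed-model GWAS** of affection status with a genomic relationship
   matrix absorbing population structure.
3. **Autozygosity mapping**: per-case runs of homozygosity (ROH),
   intersected into the shared disease segment.
4. **Haplotype statistics**: carrier frequency, Hardy–Weinberg tests, the
   concordance-discounted defect-allele frequency, exact risk-mating
   probabilities and the expected case load.
5. **Recessive-compatibility filtering** of sequence variants in the
   segment, plus stop-gain consequence annotation of a candidate CDS
   substitution.
6. **Survival contrast** of risk versus non-risk matings by Kaplan–Meier
   estimation and the log-rank test.

Because raw cohorts of this kind are rarely deposited, the package ships a
first-class synthetic-cohort simulator whose defaults encode the scenario
above, so every stage can be exercised and validated against planted truth.

## Models and estimators

### Genomic relationship matrix

`compute_grm()` uses the first VanRaden formulation,
$G = ZZ'/(2\sum_j p_j(1-p_j))$ with $Z_{ij} = g_{ij} - 2p_j$, from
autosomal markers only. Allele frequencies are estimated from the pooled
sample (cases plus controls) because no external reference population is
assumed; the counted allele is the alternate allele. Missing calls are
mean-imputed ($g \to 2p_j$), which contributes a zero entry of $Z$.
An optional diagonal ridge (default off) is available for downstream
eigen-stability.

### Linear mixed model

`fit_lmm_gwas()` fits, for each SNP,
$y = \mu + x b + u + e$, $u \sim N(0, \sigma_a^2 G)$,
$e \sim N(0, \sigma_e^2 I)$, treating case/control status as a
quantitative trait (any affine coding — 1/2 or 0/1 — gives identical
tests). The implementation is the exact-LMM strategy popularised by
eigendecomposition-based tools: $G = UDU'$ is computed once, $y$ and the
design are rotated by $U'$, and the REML profile likelihood is maximised
per SNP over $\delta = \sigma_e^2/\sigma_a^2$ by Brent search on
$\log_{10}\delta \in [-5, 5]$, with the endpoints checked against the
interior optimum. The Wald statistic for $b = 0$ is referred to
$F(1, n-2)$, so with $G = 0$ the scan reduces *exactly* to the OLS
t-test — a property the test suite asserts at $10^{-8}$. A `null_delta`
mode estimates $\delta$ once under the intercept-only model and reuses it
(the usual fast approximation for large scans). The incidence matrix
linking records to animals is the identity since the design has one record
per genotyped animal.

`significance_threshold()` is plain Bonferroni, $\alpha/n_{tests}$. With
$\alpha = 0.05$ and 644,450 tests this gives $7.76\times10^{-8}$; a
published analysis of that size quotes $7.88\times10^{-8}$, which plain
Bonferroni cannot produce from the stated inputs (the divisor actually
used is not recoverable). We implement the textbook rule and note the
discrepancy here rather than chase an unstated constant.

### Runs of homozygosity and the shared segment

No canonical parameterisation exists for ROH calling, so `detect_roh()`
exposes everything and defaults conservatively for a high-density array:
at least 20 markers and 500 kb, no heterozygous call, at most 2 missing
calls, and runs may neither start nor end on a het/missing call. Maximal
runs are found by a two-pointer scan and verified in the tests against a
brute-force enumeration of all windows. With `max_het > 0` maximal runs
can overlap; all are reported.

`intersect_case_segments()` returns the *longest interval contained in at
least one segment of every case* — not the intersection of per-case
unions, which would be wrong when a case has overlapping segments. The
search places candidate left endpoints at segment starts and takes, per
case, the furthest covering end; a brute-force oracle over all endpoint
pairs backs this in the tests. Coordinates are 1-based inclusive
throughout and segment length is `end − start + 1` (a segment printed as
70,550,045–71,573,501 is 1,023,457 bp ≈ 1,023 kb). Allele-identity across
cases is checked separately (`call_haplotype_carriers()`), since interval
intersection alone does not establish identity by descent.

### Haplotype statistics

* `haplotype_frequency()`: $(n_{het} + 2n_{hom}) / (2n)$.
* `hwe_exact_test()`: the exact conditional test (sum of probabilities of
  all heterozygote counts no more probable than the observed one, given
  the minor-allele count), standard rather than mid-p. Note that when the
  observed count *is* the conditional mode the exact p-value is 1 — which
  happens for, e.g., 380 het + 3 hom among 10,355 animals. A chi-square
  companion (`hwe_chisq_test()`) is provided because published
  haplotype-distribution p-values are often chi-square (those counts give
  0.75 there).
* `carrier_concordance()`: animal-level (mutation carriers over
  haplotype-heterozygous animals, e.g. 100/169 = 59.2%) and copy-level
  (mutation copies over carrier copies, e.g. 102/175 = 58.3%) definitions
  are both available; a published rounding to 59.5% matches neither
  exactly, so both are reported and neither is tuned.
* `risk_mating_homozygote_prob()`: exact transmission probability; a
  carrier sire transmits with probability 1/2, the dam's paternal allele
  comes from the maternal grandsire (1/2 if carrier) and her maternal
  allele from the granddam side at the population frequency `pop_freq`.
  With both men carriers and `pop_freq = 0` this is
  $\tfrac12 \times \tfrac12 \times \tfrac12 = 12.5\%$. The closed form is
  tested against an exhaustive transmission-tree enumeration and Monte
  Carlo.
* `expected_affected_per_year()`: the Hardy–Weinberg projection
  $q^2 \times \text{births}$.

### Recessive-compatibility filter and consequence annotation

`recessive_filter()` retains a variant iff every affected sample is
homozygous-alternate (`case_mode = "hom_alt"`, default), every unaffected
*haplotype-homozygous* animal — which must carry the ancestral,
mutation-free haplotype version — is het or hom-ref, and every plain
control is hom-ref. The `"segregating"` case mode (cases het *or*
hom-alt) exists because low-coverage sequencing can miscall a homozygote
as het; the strict mode is the default because it is the pattern a fully
penetrant recessive must show and it reproduces the worked four-record
example. Missing genotypes make a variant incompatible under the default
`"strict"` policy; `"permissive"` ignores them.

`annotate_consequence()` does the codon arithmetic on a supplied CDS
(genomic-to-CDS mapping is out of scope): codon index
$\lceil pos/3 \rceil$, substitution at offset $(pos-1) \bmod 3$,
classification by the standard genetic code; a stop-gain at codon $k$
truncates the protein to $k-1$ residues. `synthetic_pld4_cds()` builds a
*synthetic* stand-in CDS — the real gene sequence is not bundled —
constrained only to the published facts (ATG start, TGG at codon 215,
487-residue wild-type protein), so the c.G645A example yields codon 215,
TGG→TGA, a 214-residue product and 273 residues lost.

### Survival

`kaplan_meier()` is the product-limit estimator with Greenwood standard
errors and the deaths-before-censorings convention at tied times; it is
tested for exact equality with empirical survival under no censoring and
against the reference implementation in the `survival` package.
`logrank_test()` is the standard unweighted log-rank with hypergeometric
variances; p-values below the double-precision floor are reported as the
floor, never 0. `mortality_table()` evaluates the right-continuous step
function on the registry day grid (6, 10, 20, 50, 102, 202, 300).

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` defaults are the stated world of the target scenario, fixed
up front:

| parameter | default | why |
|---|---|---|
| `n_samples`, `n_cases` | 1,347 / 8 | cohort of the motivating design (8 affected calves + 1,339 controls) |
| `haplotype_freq` | 0.0186 | carrier-haplotype frequency estimated from 10,355 animals |
| `mutation_on_haplotype` | 0.595 | fraction of haplotype copies bearing the nonsense allele |
| `segment` | chr21:70,550,045–71,573,501 | printed coordinates, so fixtures match printed numbers |
| `seq_region_n_snps` / `_indels` | 7,086 / 574 | in-segment variant counts (7,660 polymorphic sites) |
| `array_missing_rate` | 0.01 | typical high-density array missingness; only aggregate QC counts are published, so a round per-call rate was chosen once |
| `maf_floor`, `maf_range` | 0.05, 0.40 | post-QC array MAF spectrum stand-in |
| `hazard_base` | $-\ln(0.903)/300$ | solved from the non-risk 300-day survival 0.903 |
| `hazard_hom_multiplier` | ≈10.26 | solved from $0.834 = 0.875 \times 0.903 + 0.125\, S_{hom}(300)$ |
| `n_risk_matings` / `n_nonrisk_matings` | 1,213 / 2,552 | published group sizes |
| `censor_day` | 300 | administrative censoring; registry censoring rules are unpublished |

Design choices where the design was genuinely open:

* **No multi-generation pedigree.** Founder-haplotype copies are dropped
  onto samples i.i.d. at the configured frequency; exactly `n_cases`
  samples are planted as mutant homozygotes and a non-case sample that
  becomes mutant-homozygous by chance has one copy demoted to the
  wild-type haplotype version (array-identical, so genotypes are
  untouched; the induced frequency bias is $O(10^{-4})$ and is accounted
  for in the recovery test's tolerance). Sire/MGS carrier labels are drawn
  consistently with ½-per-meiosis transmission. The analysis consumes
  carrier states, not pedigrees, so simulating genealogy would add noise
  without adding coverage.
* **Edge erosion.** Each founder copy extends beyond the core segment
  into a 15-marker flank, eroded at each edge by a geometric length with
  mean 5 markers and clamped so the *core* is never eroded. Case ROH
  therefore overhang the core by varying amounts and their intersection
  has a well-defined common part containing the core — the mosaic a real
  case panel shows. Outside the core, haplotype homozygotes are *not*
  guaranteed allele-identical, which is why carrier calling and
  control-screening restrict to the core (use `region_hint`).
* **The true population process is unknowable** from printed summaries;
  any forward model is a stand-in. This one reproduces the *statistics
  the pipeline consumes* (carrier frequency, case autozygosity, variant
  counts, survival contrast), not coalescent realism: there is no
  background LD, no allele-frequency spectrum from a demographic model,
  and no genotyping-intensity simulation. A green end-to-end test
  therefore establishes that the pipeline recovers planted truth with the
  right statistical behaviour — not that it would be similarly powered on
  any real cohort.

The mating/survival simulator draws exponential ages with a
genotype-dependent hazard; risk-mating calves are mutant-homozygous with
the exact probability 1/8. With the default calibration the expected
300-day survivals are 0.903 and 0.834 by construction, and simulated
curves land within Greenwood error of those values.

## Numerical choices

* QC thresholds are strict inequalities (missing fraction **>** 5% fails;
  MAF **<** 0.5% fails), since inclusive-vs-strict is typically left
  unstated; the boundary cases are pinned in tests. Fail flags for the
  three criteria are computed independently on the input and the union is
  removed, because published per-filter counts generally overlap and do
  not sum to the total — per-filter and union counts are both reported.
* The GRM eigendecomposition clamps eigenvalues at 0 and refuses matrices
  with eigenvalues below $-10^{-8}\,\mathrm{tr}(G)/n$, suggesting the
  ridge instead of silently repairing.
* The HWE exact test compares probabilities with a relative
  $1+10^{-12}$ slack, the usual guard against ties lost to rounding.
* Monomorphic SNPs reaching the LMM (a QC leak) are flagged and given
  p = 1 rather than an error, so a scan never dies mid-way.
* JSON summaries are written with fixed precision so identical seeds give
  byte-identical reruns.

## Known limitations

* Phasing is not re-implemented; carrier calling consumes phased input
  (from the simulator, or an external phaser on real data). An
  EM/pedigree-based carrier heuristic for unphased data is explicitly out
  of scope.
* The VCF layer handles biallelic GT-only records; multi-allelic records
  are dropped or rejected, not split.
* No covariates beyond the intercept, no X-dosage model, no permutation
  thresholds in the GWAS; no Cox/frailty models in the survival module.
* `read_plink_text()` loads everything into memory; it is meant for
  cohort-scale text fixtures, not biobank data.
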