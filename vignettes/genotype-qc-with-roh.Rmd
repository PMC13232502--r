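---
title: "Runs of homozygosity as a genotype-quality diagnostic: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runs of homozygosity as a genotype-quality diagnostic: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohqc)
```

## The diagnostic in one paragraph

Runs of homozygosity (ROH) are contiguous stretches of homozygous genotype
calls, interpreted as autozygosity: both haplotypes inherited from a common
ancestor. A genotyping artifact that miscalls true homozygotes as
heterozygous cannot *create* ROH — it can only fragment or erase them. F1
outcrosses between two breeds carry minimal autozygosity by construction,
so the smallest N_ROH observed among F1 samples is a biological floor: any
purebred below it is more plausibly a genotyping casualty than a genuinely
outbred animal. `rohqc` implements this flagging logic together with the
corroborating evidence streams (replicate concordance, call-pattern SNP
classification) and a simulator that generates data with known truth to
validate the whole chain.

## ROH detection

### Presets

Three standard equine parameter regimes are built in (`get_preset()`):

| preset  | min length | min hom SNPs | density     | max gap | het | miss |
|---------|-----------:|-------------:|------------:|--------:|----:|-----:|
| strict  | 500 kb     | > 80         | 50 kb/SNP   | 100 kb  | 1   | 1    |
| medium  | 300 kb     | > 50         | 50 kb/SNP   | 100 kb  | 1   | 2    |
| relaxed | 300 kb     | > 30         | 50 kb/SNP   | 150 kb  | 2   | 4    |

A segment is emitted only if it satisfies all four final constraints:
length at or above the minimum (1-based inclusive,
`length_kb = (end − start + 1)/1000`), *strictly more* than the minimum
number of homozygous SNPs (heterozygous and missing calls inside a segment
never count towards `n_snps`), average spacing at most the density limit
(evaluated on the final trimmed segment), and no internal inter-SNP gap
above the maximum. The gap rule only ever splits runs; it never merges
across a gap.

### Two readings of the het/missing allowance

Published setting descriptions phrase the allowances per segment ("up to
one heterozygous and one missing SNP per segment"), while the
overlapping-window implementations they evoke apply them per scanning
window. The two readings behave very differently, so both are implemented
(`allowance_scope`):

* **window** (default; PLINK-compatible): a window of `window_snps`
  (default 50) consecutive SNPs is homozygous when it holds at most
  `max_het` heterozygous and `max_miss` missing calls; a SNP joins a
  candidate run when at least `window_threshold` (default 0.05) of the
  windows covering it are homozygous; runs are split at over-wide gaps and
  trimmed to homozygous endpoints. The window size and hit threshold are
  tool defaults, not part of the published regimes. Emitted window-scope
  segments can contain more heterozygous calls than `max_het` in total —
  the allowance is a window property.
* **segment**: every maximal run whose total het/missing content stays
  within the allowances, found exactly. When two maximal candidate runs
  overlap (each spending the allowance differently), the leftmost is kept,
  so reported segments never overlap. This scan is cross-checked against
  an exhaustive interval enumerator on hundreds of random chromosomes in
  the test suite.

The sensitivity of each reading is governed by the expected number of
corrupted calls per decision unit. With per-call corruption rate
$\varepsilon$ and $n$ SNPs per unit, a unit survives roughly with
probability $P(\mathrm{Pois}(\varepsilon n) \le \texttt{max\_het})$. A
50-SNP window tolerates per-call error up to several percent before its
hit fraction drops below 5%, whereas a 500-SNP minimum-length segment
under a one-het allowance is destroyed already at $\varepsilon \approx
0.01$–$0.02$. The pipeline therefore uses **window scope by default** for
flagging — robust to sparse batch-wide noise, so it isolates genuinely
degraded samples — while the mechanism experiments in the test suite use
segment scope, where moderate inflation rates (0.005–0.02) produce the
full erosion curve.

### Monotonicity caveat

Loosening the emission thresholds (smaller minimum length, smaller minimum
SNP count) can only add segments, and this is asserted as a property test.
Loosening the *allowances* or the gap limit is not monotone in N_ROH: a
larger allowance can merge two adjacent runs into one, decreasing the
count while increasing S_ROH. Comparisons of N_ROH across settings should
keep this in mind.

## Sample-level QC

* **Call rate**: fraction of non-missing calls; the acceptance threshold
  defaults to 0.97, applied inclusively (a sample at exactly 0.97 passes).
* **F1 threshold**: the *minimum* N_ROH among F1 samples, per setting. The
  captions that motivate the rule report observed F1 values without an
  aggregator; the minimum is the conservative choice (fewest false
  flags), and adding an F1 sample can only lower or preserve it. A
  threshold of zero (an F1 with no ROH) is reported with a warning and
  disables the below-threshold reason.
* **Heterozygosity outliers**: a sample is flagged when its het rate
  exceeds its breed's mean by more than `k` (default 3) standard
  deviations, with the outlier included in the moments. This rule has an
  intrinsic power limit: in a group of $n$ samples the largest attainable
  z-score is $(n-1)/\sqrt{n}$, so at $n = 12$ *no* sample can exceed 3 SD
  regardless of how inflated it is. Groups below 5 samples are skipped
  with a warning, and detection is only reliable for groups of ~20 and
  panels dense enough that per-sample rate noise is small — the simulation
  tests use 20 samples × 20,000 SNPs.
* **Flag reasons** are a union: `zero_roh`, `below_f1_threshold` (strict
  inequality, matching the published "N_ROH < threshold" convention),
  `low_call_rate`, `excess_het`.

## SNP performance classification

`classify_snps()` reuses the familiar category names but derives them from
the call matrix alone — cluster/intensity geometry is not available from
calls, so this is explicitly a proxy, and the intrinsically
intensity-based OffTargetVariant category does not exist here. Priority
order: call rate below threshold → `CallRateBelowThreshold`; Hardy–
Weinberg heterozygote-excess z above `het_excess_z` (default 4) →
`Other`; monomorphic → `MonoHighResolution`; no minor homozygote →
`NoMinorHom`; otherwise `PolyHighResolution`. The z statistic compares the
observed heterozygote count with its binomial expectation at the estimated
allele frequency. A cutoff of 4 is deliberately conservative: moderate
inflation (for example a 30% het-flip rate at MAF 0.1 with 200 samples)
yields an expected z near 2.5 and is *not* classified as `Other`; the
category reacts to strong systematic inflation, while milder batch
problems are usually caught through the call-rate criterion instead. The
`recommended` subset is the union of the first three categories.

`recall_after_exclusion()` re-runs classification (and threshold
derivation) with flagged samples removed. Genotypes cannot be re-called
from text files, so this emulates the best-practice re-calling loop at the
analysis level. Second-pass concordance keeps every replicate pair —
exclusion applies to the inputs of the SNP set, not to the comparisons —
so improvements reflect the cleaner SNP set.

## Concordance

`pairwise_concordance()` uses shared-non-missing-call semantics: variants
missing on either side are excluded entirely, never counted as discordant,
and no call-rate or frequency filter is applied beforehand. Panels are
matched by chromosome and position; allele-swapped codings are reconciled
(calls remapped 0↔2 on one side) and strand-ambiguous A/T and C/G variants
are excluded from comparison, since a strand flip cannot be distinguished
from an allele swap. Self-concordance is exactly 1; for technical
replicates that differ only by independent het-inflation $\varepsilon$ on
a truth with homozygous fraction $h$, the expected rate is
$1 - 2\varepsilon h(1-\varepsilon)$, which the test suite verifies at
100,000 variants within three binomial standard errors.

## The synthetic-data generator

The generator produces exactly the structure the analysis consumes, with
full truth records (true calls, planted segments, per-call error masks
that replay deterministically).

* **Frequencies.** Balding–Nichols: ancestral frequency per variant from
  `Beta(1, 1)`, breed frequencies from the conditional Beta with breed
  F_ST (default 0.1). An ascertainment option resamples variants whose
  discovery-breed MAF falls below a floor, reproducing the inflated
  homozygosity seen when a panel is applied to populations absent from its
  discovery set.
* **Monomorphic tracts.** A configurable number of runs of consecutive
  SNPs fixed for the same allele in every breed (default two per
  chromosome, 800 SNPs each). With independent sites and no linkage, F1
  outcrosses would otherwise have N_ROH identically zero and the F1
  threshold would be degenerate; real panels contain low-diversity
  stretches that give even outcrosses a floor of homozygous-by-state runs
  (observed equine F1 values are in the dozens to hundreds). Tracts are
  the minimal structure that restores this feature. Planted IBD segments
  avoid tracts by default, because autozygosity inside a monomorphic tract
  is unobservable and would corrupt recovery bookkeeping.
* **Individuals.** Purebreds are IBD mosaics: gamma-distributed segment
  lengths (default mean 1.5 Mb, CV 0.2) are placed uniformly into the free
  genome until the planted total reaches `f_true` of the genome exactly
  (the last segment is truncated); inside segments one allele is drawn and
  doubled, outside genotypes are Hardy–Weinberg draws. F1s draw one
  haplotype from each breed. Parameter-recovery experiments use
  tract-free configurations so that the planted `f_true` *is* the truth
  being recovered.
* **Error model.** Per call, in order: homozygote → heterozygote with the
  batch's `het_inflation` (the artifact under study); heterozygote →
  random homozygote with `dropout` (the ascertainment-like direction);
  any call → missing with `missing`. A batch may declare a fraction of
  *failing samples* (`sample_fail_frac`) that carry the full inflation
  while the rest get a background rate, and a set of batch-wide *bad
  variants* with systematic miscalls and elevated missingness — the two
  distinct phenomena a bad processing batch exhibits. Masks record every
  changed call disjointly; replaying them on the truth reproduces the
  observed matrix exactly.
* **Geometry.** Default: two 25-Mb chromosomes with 25,000 SNPs each
  (1 SNP/kb, sorted uniform positions). The density is chosen at the high
  end of array-like panels so that minimum-length segments contain enough
  SNPs for per-call error rates in the 0.5–2% range to be informative;
  the spacing is configurable down to 50K-like densities for cross-array
  comparisons (the bundled study thins to 1 SNP/20 kb for its second
  array).
* **The default study** (`simulate_study()`): 2 breeds × 15 purebreds
  (f_true uniform on 0.05–0.25), 6 F1s, a clean batch and an artifact
  batch holding 25% of purebreds (60% of whose samples fail with
  ε = 0.15), technical replicates feeding same-batch, cross-batch,
  cross-array and versus-WGS comparisons. Under the default window-scope
  presets this produces the expected phenomenology: concordance ordered
  same-batch > cross-array > WGS > cross-batch, failing samples (and only
  those) flagged, and recommended-subset filtering improving cross-batch
  concordance.

## Numerical and representational choices

* Coordinates are 1-based inclusive throughout; lengths in kb.
* Chromosome labels are strings; numeric-like labels sort numerically
  first. Duplicate (chromosome, position) records keep the first
  occurrence with a warning.
* Calls are stored as B-allele counts (0/1/2, NA missing). Allele labels
  are canonicalised to what PLINK text can represent: alphabetical order,
  and labels never observed in any call are dropped to the missing code
  "0" (a variant observed only for its B allele is re-coded onto A). PED
  files cannot store an unobserved allele, so this canonical form is what
  a write-then-read cycle recovers — making the round trip an exact
  identity on the call matrix.
* Half-missing PED genotypes ("A 0") are treated as missing with a
  warning; a third allele at a variant is an error.
* All TSV output uses fixed formatting, so identical inputs give
  byte-identical files; every stage of the pipeline exchanges plain text
  and can be re-run or inspected independently.
* Simulation problem sizes in the test suite (50,000-variant genomes,
  20–66 samples per experiment, 100 random chromosomes for the
  enumerator cross-check) keep the full suite under about a minute while
  leaving the statistical assertions comfortable margins.

## Limitations

* **No linkage model.** Sites are independent given the IBD mosaic. ROH
  detection and call-level error propagation — what this package analyses —
  do not depend on LD, but the simulator cannot reproduce LD-driven
  phenomena (haplotype sharing, realistic N_ROH size spectra at fine
  scale), so passing tests say nothing about, for example, imputation or
  haplotype-based methods.
* **The SNP classifier is a proxy.** It reuses category names from
  cluster-based classifiers but sees only calls; membership of the
  `Other` category in particular is not expected to match an
  intensity-based classifier's.
* **Re-calling is emulated.** The second pass re-analyses existing calls
  after excluding flagged samples; it cannot reproduce the improvement
  that true intensity-level re-calling provides, so second-pass gains are
  conservative.
* **Dish QC and other intensity-level metrics are out of scope**, as are
  liftover, multi-allelic variants and binary PLINK/VCF input.
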