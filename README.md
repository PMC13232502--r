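# rohqc — genotype quality control with runs of homozygosity

SNP-array genotypes are only as good as the calling that produced them, and
one of the more insidious failure modes is **heterozygous-call inflation**: a
processing problem that turns true homozygotes into heterozygous calls. The
damage is invisible to ordinary per-sample call-rate checks, but it has a
distinctive genomic signature — it fragments and erases **runs of
homozygosity (ROH)**, the long stretches of homozygous calls that reflect
autozygosity (both haplotypes identical by descent). A purebred animal with
*fewer* ROH than a first-generation outcross between two breeds is therefore
more plausibly a genotyping casualty than a genuinely outbred individual.

`rohqc` turns that observation into a reusable QC pipeline for diploid
biallelic SNP data (developed around equine 670K-array practice, but
species-agnostic):

* **ROH detection** per sample and chromosome, with the PLINK-compatible
  overlapping-window scan or an exact per-segment allowance scan, under
  three standard presets (*strict*, *medium*, *relaxed*), summarised into
  the canonical statistics

  N_ROH (segment count), S_ROH (summed length),
  L_ROH (mean length), and the genomic inbreeding coefficient
  **F_ROH = S_ROH / L_AUTO**,

  with L_AUTO = 2,280.92 Mb for the horse autosomes
  (`horse_l_auto_kb()`).
* **F1-anchored sample flagging**: the minimum N_ROH observed among F1
  outcrosses is a biological lower bound; purebreds below it, samples with
  zero ROH, low call rate (< 97%), or breed-wise heterozygosity outliers
  (mean + 3 SD) are flagged.
* **Replicate concordance** with shared-non-missing-call semantics (PLINK
  merge-mode 6): only variants called in both members of a replicate pair
  are compared, across same-batch, cross-batch, cross-array and
  versus-WGS scenarios, with allele-swap reconciliation and exclusion of
  strand-ambiguous (A/T, C/G) variants.
* **SNP performance classification** from call patterns (call rate,
  Hardy–Weinberg heterozygote excess, monomorphism, missing minor
  homozygote) into PolyHighResolution / NoMinorHom / MonoHighResolution /
  CallRateBelowThreshold / Other, with the first three forming the
  *recommended* subset — a deliberately intensity-free proxy for
  cluster-based array classifiers.
* **A second pass after exclusion**: classification and thresholds are
  re-derived with flagged samples removed, emulating best-practice
  re-calling at the analysis level.
* **A synthetic-data generator** with breed-structured allele frequencies
  (Balding–Nichols), planted IBD segments with exact autozygosity targets,
  F1 crosses, monomorphic tracts, batch-specific error models and complete
  truth records — every pipeline claim is validated against known truth.

## Worked example

One chromosome with 100 homozygous SNPs every 10 kb from 10,000 to
1,000,000 bp:

```r
library(rohqc)

pos <- seq(10000L, 1000000L, by = 10000L)
v <- data.frame(variant_id = paste0("snp", seq_along(pos)), chromosome = "1",
                position_bp = pos, allele_a = "A", allele_b = "G")
panel <- genotype_panel(v, "horse1", matrix(0L, 1, length(pos)))

seg <- detect_roh(panel, get_preset("strict"))
seg
#>   sample_id chromosome start_bp  end_bp length_kb n_snps n_het n_miss
#> 1    horse1          1    10000 1000000   990.001    100     0      0

summarize_roh(seg, l_auto_kb = horse_l_auto_kb())
#>        sample_id n_roh s_roh_kb l_roh_kb        f_roh
#> horse1    horse1     1  990.001  990.001 0.0004340358
```

The single run spans 990.001 kb ((1,000,000 − 10,000 + 1)/1000, 1-based
inclusive), contains 100 homozygous SNPs (strictly more than the strict
preset's 80), has one SNP per 9.9 kb (well under the 50 kb/SNP limit), and
covers 0.043% of the horse autosomal genome.

An end-to-end simulated study — two array batches (one carrying
heterozygous-call inflation in a subset of its samples plus a set of
systematically miscalled variants), F1 outcrosses, replicates across
batches and platforms — runs with:

```r
cfg <- run_config(out_dir = "qc_run", sim = sim_config(seed = 1))
res <- run_workflow(cfg)
```

and writes ROH segment/summary tables per preset, F1 thresholds, sample
flags, SNP classification, and two-pass concordance reports as plain TSV
into `qc_run/`. The same stages are available from the shell via
`inst/scripts/rohqc.R` (subcommands `simulate | roh | qc | concord |
report`).

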