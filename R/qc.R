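#' Per-sample call rate
#'
#' Fraction of non-missing calls per sample. The conventional acceptance
#' threshold for array QC is a call rate of at least 0.97.
#'
#' @param panel a [genotype_panel()]
#' @return named numeric vector (by sample id)
#' @export
sample_call_rate <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (n_variants(panel) == 0L) stop_data("panel has no variants")
  1 - rowMeans(is.na(panel$calls))
}

#' Per-sample heterozygosity rate
#'
#' Fraction of heterozygous calls among called (non-missing) genotypes.
#'
#' @param panel a [genotype_panel()]
#' @return named numeric vector (by sample id); NA for all-missing samples
#' @export
sample_het_rate <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  het <- rowSums(panel$calls == 1L, na.rm = TRUE)
  called <- rowSums(!is.na(panel$calls))
  ifelse(called > 0L, het / called, NA_real_)
}

#' Flag heterozygosity outliers within groups
#'
#' A sample is flagged when its heterozygosity rate exceeds its group's mean
#' by more than `k` group standard deviations. Groups are typically breeds;
#' groups with fewer than `min_group` samples are skipped with a warning,
#' since mean/SD outlier detection is meaningless at tiny n.
#'
#' @param rates named numeric vector from [sample_het_rate()]
#' @param groups character vector of group labels, parallel to `rates`
#' @param k number of standard deviations (default 3)
#' @param min_group minimum group size for the rule to apply (default 5)
#' @return logical vector, TRUE = excess heterozygosity, named by sample id
#' @export
flag_excess_het <- function(rates, groups, k = 3, min_group = 5L) {
  stopifnot(length(rates) == length(groups))
  flags <- rep(FALSE, length(rates))
  names(flags) <- names(rates)
  for (g in unique(groups)) {
    in_g <- which(groups == g & !is.na(rates))
    if (length(in_g) < min_group) {
      warning("group '", g, "' has ", length(in_g),
              " usable sample(s); heterozygosity-outlier rule skipped")
      next
    }
    mu <- mean(rates[in_g])
    sdev <- stats::sd(rates[in_g])
    if (is.na(sdev) || sdev == 0) next
    flags[in_g] <- rates[in_g] > mu + k * sdev
  }
  flags
}

#' F1-anchored lower bound on N_ROH
#'
#' First-generation outcrosses between breeds are expected to carry minimal
#' autozygosity, so the smallest N_ROH observed among F1 samples is a
#' biologically meaningful lower bound: a purebred below it is more plausibly
#' affected by heterozygous-call inflation than genuinely outbred. The
#' minimum (rather than a mean) is the conservative aggregator — it flags the
#' fewest samples.
#'
#' @param summaries per-sample summary data frame from [summarize_roh()]
#' @param sample_records sample manifest data frame with `sample_id` and
#'   `is_f1` columns (see [read_sample_manifest()])
#' @param setting_name label stored in the result (e.g. the preset name)
#' @return list with `setting`, `threshold_n_roh` and `n_f1`
#' @export
derive_f1_threshold <- function(summaries, sample_records, setting_name = "") {
  f1_ids <- sample_records$sample_id[isTRUE_vec(sample_records$is_f1)]
  f1 <- summaries[summaries$sample_id %in% f1_ids, , drop = FALSE]
  if (!nrow(f1)) {
    stop_config("no F1 samples with an ROH summary; supply a manual ",
                "threshold instead of deriving one")
  }
  thr <- min(f1$n_roh)
  if (thr == 0L) {
    warning("an F1 sample has N_ROH = 0; the derived threshold is degenerate")
  }
  list(setting = setting_name, threshold_n_roh = as.integer(thr),
       n_f1 = nrow(f1))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Combine sample-level QC evidence into flags
#'
#' Produces one row per flagged sample with the union of applicable reasons:
#' `zero_roh` (no ROH at all; implies `below_f1_threshold` whenever the
#' threshold is positive), `below_f1_threshold` (N_ROH strictly below the
#' F1-derived bound), `low_call_rate`, and `excess_het`.
#'
#' @param summaries per-sample summaries from [summarize_roh()]
#' @param threshold result of [derive_f1_threshold()] (or a list with
#'   `threshold_n_roh`); NULL disables the ROH-based reasons
#' @param call_rates named vector from [sample_call_rate()]; NULL disables
#' @param cr_threshold minimum acceptable call rate (default 0.97)
#' @param het_flags named logical vector from [flag_excess_het()]; NULL
#'   disables
#' @return data frame with sample_id and comma-separated `reasons`, one row
#'   per flagged sample (zero rows when nothing is flagged)
#' @export
flag_samples <- function(summaries, threshold = NULL, call_rates = NULL,
                         cr_threshold = 0.97, het_flags = NULL) {
  ids <- summaries$sample_id
  reasons <- stats::setNames(vector("list", length(ids)), ids)
  if (!is.null(threshold)) {
    thr <- threshold$threshold_n_roh
    for (i in seq_along(ids)) {
      r <- character()
      if (summaries$n_roh[i] == 0L) r <- c(r, "zero_roh")
      if (summaries$n_roh[i] < thr) r <- c(r, "below_f1_threshold")
      reasons[[i]] <- r
    }
  }
  if (!is.null(call_rates)) {
    low <- names(call_rates)[call_rates < cr_threshold]
    for (id in intersect(low, ids)) {
      reasons[[id]] <- c(reasons[[id]], "low_call_rate")
    }
  }
  if (!is.null(het_flags)) {
    hot <- names(het_flags)[isTRUE_vec(het_flags)]
    for (id in intersect(hot, ids)) {
      reasons[[id]] <- c(reasons[[id]], "excess_het")
    }
  }
  flagged <- vapply(reasons, length, integer(1)) > 0L
  data.frame(
    sample_id = ids[flagged],
    reasons = vapply(reasons[flagged], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

#' Classify SNP performance from genotype calls
#'
#' A call-pattern proxy for array performance classification. True array
#' classifiers work on cluster/intensity geometry, which genotype calls do
#' not carry; this classifier reuses the category names but derives them
#' from the call matrix only, and has no OffTargetVariant category (that one
#' is intrinsically intensity-based). Assignment is by priority:
#' \enumerate{
#'   \item call rate below `cr_threshold` -> `CallRateBelowThreshold`
#'   \item heterozygote excess over the Hardy-Weinberg expectation with
#'     z-score above `het_excess_z` -> `Other`
#'   \item monomorphic among called genotypes -> `MonoHighResolution`
#'   \item polymorphic but lacking a minor homozygote -> `NoMinorHom`
#'   \item otherwise -> `PolyHighResolution`
#' }
#' Every variant receives exactly one category. The het-excess z uses the
#' binomial standard error of the expected heterozygote count at the
#' estimated allele frequency.
#'
#' @param panel a [genotype_panel()]
#' @param cr_threshold per-variant call-rate threshold (default 0.97)
#' @param het_excess_z z-score cutoff for heterozygote excess (default 4)
#' @return data frame with variant_id, call_rate, n_homA, n_het, n_homB,
#'   n_missing, maf, het_z, category
#' @seealso [recommended_subset()]
#' @export
classify_snps <- function(panel, cr_threshold = 0.97, het_excess_z = 4) {
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  ns <- nrow(calls)
  if (ns == 0L) stop_data("panel has no samples")
  n_homA <- colSums(calls == 0L, na.rm = TRUE)
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  n_homB <- colSums(calls == 2L, na.rm = TRUE)
  n_missing <- ns - (n_homA + n_het + n_homB)
  n_called <- ns - n_missing
  call_rate <- n_called / ns

  p <- ifelse(n_called > 0L, (2 * n_homB + n_het) / (2 * n_called), NA_real_)
  maf <- pmin(p, 1 - p)
  exp_het <- 2 * p * (1 - p) * n_called
  var_het <- exp_het * (1 - 2 * p * (1 - p))
  het_z <- ifelse(!is.na(var_het) & var_het > 0,
                  (n_het - exp_het) / sqrt(var_het), 0)

  category <- rep("PolyHighResolution", ncol(calls))
  category[n_homA == 0L | n_homB == 0L] <- "NoMinorHom"
  category[!is.na(maf) & maf == 0] <- "MonoHighResolution"
  category[het_z > het_excess_z] <- "Other"
  category[call_rate < cr_threshold | n_called == 0L] <- "CallRateBelowThreshold"

  data.frame(
    variant_id = panel$variants$variant_id,
    call_rate = call_rate,
    n_homA = as.integer(n_homA), n_het = as.integer(n_het),
    n_homB = as.integer(n_homB), n_missing = as.integer(n_missing),
    maf = maf, het_z = het_z,
    category = category,
    stringsAsFactors = FALSE
  )
}

#' Recommended variant subset
#'
#' Variants in the high-quality categories `PolyHighResolution`, `NoMinorHom`
#' and `MonoHighResolution`; `CallRateBelowThreshold` and `Other` variants
#' are excluded.
#'
#' @param records data frame from [classify_snps()]
#' @return character vector of variant ids
#' @export
recommended_subset <- function(records) {
  keep <- records$category %in%
    c("PolyHighResolution", "NoMinorHom", "MonoHighResolution")
  records$variant_id[keep]
}

#' Re-run classification and thresholds after excluding flagged samples
#'
#' Emulates the best-practice re-call loop at the analysis level: genotype
#' intensities cannot be re-clustered from calls, so the second pass re-runs
#' SNP classification (and, when ROH summaries and a manifest are supplied,
#' the F1 threshold derivation) on the panel with flagged samples removed,
#' and returns both passes side by side.
#'
#' @param panel a [genotype_panel()]
#' @param flags data frame from [flag_samples()]
#' @param cr_threshold,het_excess_z passed to [classify_snps()]
#' @param summaries optional ROH summaries (first pass) for threshold
#'   re-derivation
#' @param sample_records optional sample manifest (needed with `summaries`)
#' @param setting_name label for the re-derived threshold
#' @return list with `first` and `second`, each containing `snp_records`,
#'   `recommended` and (when derivable) `f1_threshold`; plus
#'   `excluded_samples`
#' @export
recall_after_exclusion <- function(panel, flags, cr_threshold = 0.97,
                                   het_excess_z = 4, summaries = NULL,
                                   sample_records = NULL, setting_name = "") {
  stopifnot(inherits(panel, "genotype_panel"))
  excluded <- intersect(flags$sample_id, panel$samples)
  keep <- setdiff(panel$samples, excluded)
  if (!length(keep)) stop_data("all samples are flagged; nothing left to re-analyse")

  run_pass <- function(p, summ) {
    rec <- classify_snps(p, cr_threshold = cr_threshold, het_excess_z = het_excess_z)
    out <- list(snp_records = rec, recommended = recommended_subset(rec))
    if (!is.null(summ) && !is.null(sample_records)) {
      summ <- summ[summ$sample_id %in% p$samples, , drop = FALSE]
      f1_present <- any(sample_records$sample_id[isTRUE_vec(sample_records$is_f1)]
                        %in% summ$sample_id)
      if (f1_present) {
        out$f1_threshold <- derive_f1_threshold(summ, sample_records, setting_name)
      }
    }
    out
  }
  first <- run_pass(panel, summaries)
  second <- run_pass(subset_panel(panel, samples = keep), summaries)
  list(first = first, second = second, excluded_samples = excluded)
}
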