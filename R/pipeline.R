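#' Pipeline run configuration
#'
#' Parameters of the end-to-end workflow. Input is either a simulation
#' ([sim_config()] + [study_design()]) or a set of existing files in the
#' output directory (PED/MAP panels plus manifests laid out as
#' [stage_simulate()] writes them).
#'
#' @param out_dir output directory (created if absent); every stage reads
#'   and writes plain TSV/PED/MAP/YAML files there, so each step is
#'   independently inspectable
#' @param sim a [sim_config()], or NULL to analyse existing files in
#'   `out_dir`
#' @param design a [study_design()] (simulation input only)
#' @param presets character vector of ROH preset names to run
#' @param preset_scope allowance scope used for the QC presets. The default
#'   `"window"` is the PLINK-compatible reading (allowances per scanning
#'   window), which tolerates sparse batch-wide artifacts and therefore
#'   flags only genuinely degraded samples; `"segment"` applies the
#'   allowances per emitted segment and reacts to much smaller per-call
#'   error rates (see the vignette)
#' @param l_auto_kb autosomal genome length for F_ROH; NULL derives it from
#'   the simulation config, and the horse constant [horse_l_auto_kb()]
#'   applies to real equine panels
#' @param cr_threshold sample and variant call-rate threshold
#' @param het_outlier_k group SD multiplier for heterozygosity outliers
#' @param het_excess_z Hardy-Weinberg het-excess z cutoff for SNP
#'   classification
#' @param autosomes admissible chromosome labels; NULL keeps every
#'   chromosome (simulated genomes are all-autosomal by construction)
#' @return object of class `run_config`
#' @export
run_config <- function(out_dir, sim = sim_config(), design = study_design(),
                       presets = c("strict", "medium", "relaxed"),
                       preset_scope = "window",
                       l_auto_kb = NULL, cr_threshold = 0.97,
                       het_outlier_k = 3, het_excess_z = 4,
                       autosomes = NULL) {
  stopifnot(length(presets) >= 1L)
  if (is.null(l_auto_kb)) {
    if (is.null(sim)) stop_config("l_auto_kb is required when not simulating")
    l_auto_kb <- sim_l_auto_kb(sim)
  }
  if (l_auto_kb <= 0) stop_config("l_auto_kb must be positive")
  structure(list(
    out_dir = out_dir, sim = sim, design = design,
    presets = tolower(presets), preset_scope = preset_scope,
    l_auto_kb = as.numeric(l_auto_kb),
    cr_threshold = as.numeric(cr_threshold),
    het_outlier_k = as.numeric(het_outlier_k),
    het_excess_z = as.numeric(het_excess_z),
    autosomes = autosomes
  ), class = "run_config")
}

panel_paths <- function(out_dir, name) {
  c(ped = file.path(out_dir, paste0("panel_", name, ".ped")),
    map = file.path(out_dir, paste0("panel_", name, ".map")))
}

read_stage_panels <- function(out_dir) {
  maps <- list.files(out_dir, pattern = "^panel_.*\\.map$")
  names <- sub("^panel_(.*)\\.map$", "\\1", maps)
  panels <- list()
  for (nm in names) {
    pp <- panel_paths(out_dir, nm)
    panels[[nm]] <- read_ped_map(pp["ped"], pp["map"])
  }
  if (!length(panels)) {
    stop_data("no panel_*.ped/.map files in ", out_dir,
              "; run the simulate stage (or provide input panels) first")
  }
  panels
}

#' Pipeline stage: simulate and write the study inputs
#'
#' Runs [simulate_study()] and writes panels (PED/MAP), the sample and pair
#' manifests, the truth records (planted segments, error masks) and the
#' simulation parameters (`sim.yaml`) into the output directory.
#'
#' @param config a [run_config()] with a non-NULL `sim`
#' @return invisibly, the study object
#' @export
stage_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$sim)) stop_config("stage_simulate needs a simulation config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config$sim, config$design)
  for (nm in names(study$panels)) {
    pp <- panel_paths(config$out_dir, nm)
    write_ped_map(study$panels[[nm]], pp["ped"], pp["map"])
  }
  write_tsv_file(study$manifest, file.path(config$out_dir, "samples.tsv"))
  write_tsv_file(study$pairs, file.path(config$out_dir, "pairs.tsv"))
  write_tsv_file(study$truth$segments,
                 file.path(config$out_dir, "truth_segments.tsv"))
  write_tsv_file(study$truth$masks, file.path(config$out_dir, "truth_masks.tsv"))
  sim_meta <- unclass(config$sim)
  sim_meta$l_auto_kb <- sim_l_auto_kb(config$sim)
  yaml::write_yaml(sim_meta, file.path(config$out_dir, "sim.yaml"))
  invisible(study)
}

#' Pipeline stage: ROH detection and per-sample summaries
#'
#' Reads the main panel (`panel_axiom`), applies the autosome filter, and
#' for each configured preset writes the detected segments
#' (`roh_segments_<preset>.tsv`) and per-sample summaries
#' (`roh_summary_<preset>.tsv`).
#'
#' @param config a [run_config()]
#' @return invisibly, a named list of summary data frames by preset
#' @export
stage_roh <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pp <- panel_paths(config$out_dir, "axiom")
  panel <- read_ped_map(pp["ped"], pp["map"])
  if (!is.null(config$autosomes)) panel <- filter_autosomes(panel, config$autosomes)
  out <- list()
  for (preset in config$presets) {
    st <- get_preset(preset, allowance_scope = config$preset_scope)
    segs <- detect_roh(panel, st)
    summ <- summarize_roh(segs, config$l_auto_kb, samples = panel$samples)
    write_tsv_file(segs, file.path(config$out_dir,
                                   paste0("roh_segments_", preset, ".tsv")))
    write_tsv_file(summ, file.path(config$out_dir,
                                   paste0("roh_summary_", preset, ".tsv")))
    out[[preset]] <- summ
  }
  invisible(out)
}

#' Pipeline stage: sample QC and SNP classification (first pass)
#'
#' Derives F1-anchored N_ROH thresholds per preset, sample call rates,
#' breed-wise heterozygosity outliers and the combined sample flags; then
#' classifies SNP performance on the main panel and writes the recommended
#' variant list. Outputs: `f1_thresholds.tsv`, `call_rates.tsv`,
#' `sample_flags.tsv`, `snp_classification.tsv`, `snp_category_counts.tsv`,
#' `recommended_variants.txt`.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with thresholds, flags and SNP records
#' @export
stage_qc <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  pp <- panel_paths(out_dir, "axiom")
  panel <- read_ped_map(pp["ped"], pp["map"])
  manifest <- read_sample_manifest(file.path(out_dir, "samples.tsv"))

  call_rates <- sample_call_rate(panel)
  het_rates <- sample_het_rate(panel)
  groups <- manifest$breed[match(panel$samples, manifest$sample_id)]
  het_flags <- suppressWarnings(
    flag_excess_het(het_rates, groups, k = config$het_outlier_k)
  )
  write_tsv_file(
    data.frame(sample_id = panel$samples, call_rate = call_rates,
               het_rate = het_rates, excess_het = het_flags,
               stringsAsFactors = FALSE),
    file.path(out_dir, "call_rates.tsv")
  )

  thresholds <- list()
  flag_frames <- list()
  for (preset in config$presets) {
    summ <- read_tsv_file(file.path(out_dir, paste0("roh_summary_", preset, ".tsv")))
    thr <- derive_f1_threshold(summ, manifest, preset)
    thresholds[[preset]] <- thr
    fl <- flag_samples(summ, threshold = thr, call_rates = call_rates,
                       cr_threshold = config$cr_threshold, het_flags = het_flags)
    if (nrow(fl)) fl$setting <- preset
    flag_frames[[preset]] <- fl
  }
  write_tsv_file(
    data.frame(setting = names(thresholds),
               threshold_n_roh = vapply(thresholds, `[[`, integer(1), "threshold_n_roh"),
               n_f1 = vapply(thresholds, `[[`, integer(1), "n_f1"),
               stringsAsFactors = FALSE),
    file.path(out_dir, "f1_thresholds.tsv")
  )
  flags <- do.call(rbind, flag_frames[vapply(flag_frames, nrow, integer(1)) > 0])
  if (is.null(flags)) {
    flags <- data.frame(sample_id = character(), reasons = character(),
                        setting = character(), stringsAsFactors = FALSE)
  }
  rownames(flags) <- NULL
  write_tsv_file(flags, file.path(out_dir, "sample_flags.tsv"))

  snp_records <- classify_snps(panel, cr_threshold = config$cr_threshold,
                               het_excess_z = config$het_excess_z)
  write_tsv_file(snp_records, file.path(out_dir, "snp_classification.tsv"))
  counts <- as.data.frame(table(category = snp_records$category),
                          stringsAsFactors = FALSE)
  names(counts) <- c("category", "n_snps")
  write_tsv_file(counts, file.path(out_dir, "snp_category_counts.tsv"))
  writeLines(recommended_subset(snp_records),
             file.path(out_dir, "recommended_variants.txt"))

  invisible(list(thresholds = thresholds, flags = flags,
                 snp_records = snp_records))
}

#' Pipeline stage: replicate concordance (first pass)
#'
#' Computes concordance for every pair in the pair manifest on the full
#' shared variant set and on the recommended subset, ordered by each
#' sample's first-preset N_ROH. Outputs `concordance_pass1.tsv` and the
#' per-variant `variant_discordance.tsv` diagnostic.
#'
#' @param config a [run_config()]
#' @return invisibly, the concordance data frame
#' @export
stage_concord <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  panels <- read_stage_panels(out_dir)
  pairs <- read_pair_manifest(file.path(out_dir, "pairs.tsv"))
  recommended <- readLines(file.path(out_dir, "recommended_variants.txt"))
  summ <- read_tsv_file(file.path(out_dir,
                                  paste0("roh_summary_", config$presets[1], ".tsv")))
  order_by <- stats::setNames(summ$n_roh, summ$sample_id)
  conc <- concordance_report(panels, pairs, snp_subset = recommended,
                             order_by = order_by)
  write_tsv_file(conc, file.path(out_dir, "concordance_pass1.tsv"))
  write_tsv_file(variant_discordance(panels, pairs),
                 file.path(out_dir, "variant_discordance.tsv"))
  invisible(conc)
}

#' Pipeline stage: second pass after sample exclusion, and the run log
#'
#' Re-runs SNP classification and F1 threshold derivation with flagged
#' samples removed ([recall_after_exclusion()]), recomputes concordance for
#' every replicate pair on the second-pass recommended subset, and writes
#' the consolidated run log with every parameter. Outputs
#' `snp_classification_pass2.tsv`, `recommended_variants_pass2.txt`,
#' `f1_thresholds_pass2.tsv`, `concordance_pass2.tsv`, `run_log.yaml`.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with the second-pass objects
#' @export
stage_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  panels <- read_stage_panels(out_dir)
  manifest <- read_sample_manifest(file.path(out_dir, "samples.tsv"))
  pairs <- read_pair_manifest(file.path(out_dir, "pairs.tsv"))
  flags <- read_tsv_file(file.path(out_dir, "sample_flags.tsv"))
  flagged <- unique(flags$sample_id)

  thresholds2 <- list()
  for (preset in config$presets) {
    summ <- read_tsv_file(file.path(out_dir, paste0("roh_summary_", preset, ".tsv")))
    summ2 <- summ[!summ$sample_id %in% flagged, , drop = FALSE]
    thresholds2[[preset]] <- derive_f1_threshold(summ2, manifest, preset)
  }
  write_tsv_file(
    data.frame(setting = names(thresholds2),
               threshold_n_roh = vapply(thresholds2, `[[`, integer(1), "threshold_n_roh"),
               n_f1 = vapply(thresholds2, `[[`, integer(1), "n_f1"),
               stringsAsFactors = FALSE),
    file.path(out_dir, "f1_thresholds_pass2.tsv")
  )

  rec <- recall_after_exclusion(
    panels$axiom, flags,
    cr_threshold = config$cr_threshold, het_excess_z = config$het_excess_z
  )
  write_tsv_file(rec$second$snp_records,
                 file.path(out_dir, "snp_classification_pass2.tsv"))
  writeLines(rec$second$recommended,
             file.path(out_dir, "recommended_variants_pass2.txt"))

  ## pass-2 concordance keeps every replicate pair: flagged samples are
  ## excluded from classification and threshold derivation (the inputs of
  ## the SNP set), but their replicate comparisons remain reportable on the
  ## improved SNP set
  summ <- read_tsv_file(file.path(out_dir,
                                  paste0("roh_summary_", config$presets[1], ".tsv")))
  conc2 <- concordance_report(panels, pairs,
                              snp_subset = rec$second$recommended,
                              order_by = stats::setNames(summ$n_roh, summ$sample_id))
  write_tsv_file(conc2, file.path(out_dir, "concordance_pass2.tsv"))

  log <- list(
    presets = config$presets,
    preset_scope = config$preset_scope,
    l_auto_kb = config$l_auto_kb,
    cr_threshold = config$cr_threshold,
    het_outlier_k = config$het_outlier_k,
    het_excess_z = config$het_excess_z,
    n_flagged_samples = length(flagged),
    flagged_samples = as.list(flagged),
    excluded_from_pass2 = as.list(rec$excluded_samples),
    preset_parameters = lapply(config$presets, function(p) {
      unclass(get_preset(p, allowance_scope = config$preset_scope))
    })
  )
  if (!is.null(config$sim)) log$simulation <- unclass(config$sim)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))

  invisible(list(thresholds = thresholds2, recall = rec, concordance = conc2))
}

#' Run the complete QC workflow
#'
#' Executes the pipeline stages in order — simulate (when a simulation
#' config is present), ROH detection under every preset, sample QC and SNP
#' classification, first-pass concordance, and the post-exclusion second
#' pass with the consolidated run log. All interchange is plain TSV/PED/MAP
#' in `config$out_dir`; a stage-wise run via the individual `stage_*`
#' functions produces identical files. Deterministic given the simulation
#' seed.
#'
#' @param config a [run_config()]
#' @return invisibly, a list with the per-stage results
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  study <- if (!is.null(config$sim)) stage_simulate(config) else NULL
  roh <- stage_roh(config)
  qc <- stage_qc(config)
  conc <- stage_concord(config)
  rep <- stage_report(config)
  invisible(list(study = study, roh = roh, qc = qc,
                 concordance_pass1 = conc, report = rep))
}
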