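#' Study design for a simulated QC experiment
#'
#' Describes who is genotyped and how, on top of a [sim_config()] genome:
#' purebred counts and their true autozygosity range, F1 outcrosses, the
#' fraction of samples processed in the artifact-affected batch, and the
#' technical replicates that feed the four concordance comparisons.
#'
#' @param n_per_breed purebred individuals per breed
#' @param f_true_range range of per-individual true autozygous fractions
#'   (drawn uniformly)
#' @param n_f1 F1 outcrosses between breeds 1 and 2
#' @param artifact_frac fraction of purebreds processed in the `artifact`
#'   batch (the rest, and all F1s, are in `clean`)
#' @param n_rep_same,n_rep_cross,n_rep_wgs,n_rep_array number of replicate
#'   pairs for the same-batch, cross-batch, versus-WGS and cross-array
#'   comparisons
#' @param array_thin keep every `array_thin`-th variant on the lower-density
#'   second array
#' @return object of class `study_design`
#' @export
study_design <- function(n_per_breed = 15L, f_true_range = c(0.05, 0.25),
                         n_f1 = 6L, artifact_frac = 0.25,
                         n_rep_same = 6L, n_rep_cross = 6L,
                         n_rep_wgs = 4L, n_rep_array = 5L,
                         array_thin = 20L) {
  stopifnot(n_per_breed >= 0, length(f_true_range) == 2L,
            all(f_true_range >= 0), all(f_true_range < 1),
            artifact_frac >= 0, artifact_frac <= 1, array_thin >= 1)
  structure(list(
    n_per_breed = as.integer(n_per_breed),
    f_true_range = as.numeric(f_true_range),
    n_f1 = as.integer(n_f1),
    artifact_frac = as.numeric(artifact_frac),
    n_rep_same = as.integer(n_rep_same),
    n_rep_cross = as.integer(n_rep_cross),
    n_rep_wgs = as.integer(n_rep_wgs),
    n_rep_array = as.integer(n_rep_array),
    array_thin = as.integer(array_thin)
  ), class = "study_design")
}

#' Simulate a complete genotyping study with truth records
#'
#' Builds the full synthetic experiment: breed frequencies and variant map,
#' purebred individuals as IBD mosaics, F1 outcrosses, batch assignment,
#' per-batch error layers, technical replicates across batches and
#' platforms, and the manifests that drive the pipeline. All randomness
#' derives from `config$seed` (set once at entry; every sub-draw consumes
#' the same stream in a fixed order).
#'
#' @param config a [sim_config()]
#' @param design a [study_design()]
#' @return list with
#'   \item{panels}{named list of observed [genotype_panel()]s: `axiom` (main
#'     array, including replicate samples), `wgs`, `array50k`}
#'   \item{manifest}{sample manifest across all panels (sample_id, breed,
#'     batch, replicate_group, is_f1, panel)}
#'   \item{pairs}{replicate-pair manifest for [concordance_report()]}
#'   \item{truth}{true call matrix (individuals x variants), planted
#'     segments, error masks per panel sample, bad-variant sets per batch,
#'     frequencies and tract map}
#'   \item{config, design}{the inputs}
#' @export
simulate_study <- function(config = sim_config(), design = study_design()) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "study_design"))
  set.seed(config$seed)
  fs <- simulate_frequencies(config)
  nv <- nrow(fs$variants)

  ## --- individuals ------------------------------------------------------
  breeds <- paste0("breed", seq_len(config$n_breeds))
  ind <- data.frame(individual_id = character(), breed = character(),
                    is_f1 = logical(), f_true = numeric(),
                    stringsAsFactors = FALSE)
  for (b in seq_len(config$n_breeds)) {
    if (design$n_per_breed == 0L) break
    ids <- sprintf("%s_%02d", breeds[b], seq_len(design$n_per_breed))
    ind <- rbind(ind, data.frame(
      individual_id = ids, breed = breeds[b], is_f1 = FALSE,
      f_true = stats::runif(length(ids), design$f_true_range[1],
                            design$f_true_range[2]),
      stringsAsFactors = FALSE))
  }
  if (design$n_f1 > 0L) {
    if (config$n_breeds < 2L) stop_config("F1 outcrosses need at least 2 breeds")
    ids <- sprintf("f1_%02d", seq_len(design$n_f1))
    ind <- rbind(ind, data.frame(
      individual_id = ids, breed = paste0(breeds[1], "x", breeds[2]),
      is_f1 = TRUE, f_true = 0, stringsAsFactors = FALSE))
  }
  n_ind <- nrow(ind)

  true_calls <- matrix(NA_integer_, nrow = n_ind, ncol = nv,
                       dimnames = list(ind$individual_id, fs$variants$variant_id))
  seg_list <- list()
  for (i in seq_len(n_ind)) {
    if (ind$is_f1[i]) {
      true_calls[i, ] <- simulate_f1(fs, 1L, 2L)
    } else {
      r <- simulate_individual(fs, match(ind$breed[i], breeds), ind$f_true[i], config)
      true_calls[i, ] <- r$calls
      if (nrow(r$segments)) {
        r$segments$individual_id <- ind$individual_id[i]
        seg_list[[length(seg_list) + 1L]] <- r$segments
      }
    }
  }
  truth_segments <- if (length(seg_list)) {
    do.call(rbind, seg_list)[, c("individual_id", "chromosome", "start_bp",
                                 "end_bp", "length_kb")]
  } else {
    data.frame(individual_id = character(), chromosome = character(),
               start_bp = numeric(), end_bp = numeric(), length_kb = numeric(),
               stringsAsFactors = FALSE)
  }

  ## --- batches and bad-variant sets ------------------------------------
  purebred <- which(!ind$is_f1)
  batch <- rep("clean", n_ind)
  n_artifact <- round(design$artifact_frac * length(purebred))
  if (n_artifact > 0L) {
    batch[sample(purebred, n_artifact)] <- "artifact"
  }
  bad_sets <- list()
  for (bn in names(config$batches)) {
    frac <- config$batches[[bn]]$bad_variant_frac %||% 0
    if (frac > 0) bad_sets[[bn]] <- sort(sample.int(nv, round(frac * nv)))
  }

  ## --- replicate selection (clean-batch purebreds, no double duty) ------
  pool <- ind$individual_id[purebred][batch[purebred] == "clean"]
  need <- design$n_rep_same + design$n_rep_cross + design$n_rep_wgs + design$n_rep_array
  if (need > length(pool)) {
    stop_config("replicate design needs ", need, " clean purebreds but only ",
                length(pool), " are available")
  }
  pool <- sample(pool)   # randomise which individuals get replicated
  take <- function(k) {
    if (k == 0L) return(character(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  rep_same <- take(design$n_rep_same)
  rep_cross <- take(design$n_rep_cross)
  rep_wgs <- take(design$n_rep_wgs)
  rep_array <- take(design$n_rep_array)

  ## --- observed panels --------------------------------------------------
  failing_samples <- character(0)
  observe <- function(individual, batch_name, sample_id) {
    frac <- config$batches[[batch_name]]$sample_fail_frac %||% 1
    failing <- frac >= 1 || stats::runif(1) < frac
    if (failing && frac < 1) failing_samples <<- c(failing_samples, sample_id)
    apply_error_model(true_calls[individual, ], batch_name, config,
                      bad_sets[[batch_name]] %||% integer(0),
                      failing = failing)
  }
  masks <- list()
  add_mask <- function(panel, sample_id, mask) {
    if (nrow(mask)) {
      mask$panel <- panel; mask$sample_id <- sample_id
      masks[[length(masks) + 1L]] <<- mask
    }
  }

  ax_samples <- character(0)
  ax_calls <- list()
  ax_rows <- list()
  add_axiom <- function(sample_id, individual, batch_name, rep_group) {
    o <- observe(individual, batch_name, sample_id)
    ax_samples <<- c(ax_samples, sample_id)
    ax_calls[[length(ax_calls) + 1L]] <<- o$calls
    i <- match(individual, ind$individual_id)
    ax_rows[[length(ax_rows) + 1L]] <<- data.frame(
      sample_id = sample_id, breed = ind$breed[i], batch = batch_name,
      replicate_group = rep_group, is_f1 = ind$is_f1[i], panel = "axiom",
      stringsAsFactors = FALSE)
    add_mask("axiom", sample_id, o$mask)
  }

  replicated <- c(rep_same, rep_cross, rep_wgs, rep_array)
  for (i in seq_len(n_ind)) {
    id <- ind$individual_id[i]
    add_axiom(id, id, batch[i], if (id %in% replicated) id else "")
  }
  for (id in rep_same) add_axiom(paste0(id, ".r1"), id, "clean", id)
  for (id in rep_cross) add_axiom(paste0(id, ".r2"), id, "artifact", id)

  panel_axiom <- genotype_panel(fs$variants, ax_samples,
                                do.call(rbind, ax_calls))

  other_rows <- list()
  make_side_panel <- function(ids, suffix, batch_name, panel_name, variant_idx) {
    if (!length(ids)) return(NULL)
    calls <- list(); snames <- character(0)
    for (id in ids) {
      o <- observe(id, batch_name, paste0(id, suffix))
      snames <- c(snames, paste0(id, suffix))
      calls[[length(calls) + 1L]] <- o$calls[variant_idx]
      m <- o$mask[o$mask$variant_idx %in% variant_idx, , drop = FALSE]
      add_mask(panel_name, paste0(id, suffix), m)
      i <- match(id, ind$individual_id)
      other_rows[[length(other_rows) + 1L]] <<- data.frame(
        sample_id = paste0(id, suffix), breed = ind$breed[i],
        batch = batch_name, replicate_group = id, is_f1 = ind$is_f1[i],
        panel = panel_name, stringsAsFactors = FALSE)
    }
    genotype_panel(fs$variants[variant_idx, , drop = FALSE], snames,
                   do.call(rbind, calls))
  }
  panel_wgs <- make_side_panel(rep_wgs, ".wgs", "wgs", "wgs", seq_len(nv))
  thin_idx <- seq(1L, nv, by = design$array_thin)
  panel_ld <- make_side_panel(rep_array, ".ld", "array50k", "array50k", thin_idx)

  manifest <- do.call(rbind, c(ax_rows, other_rows))
  rownames(manifest) <- NULL

  ## --- pair manifest ----------------------------------------------------
  mk_pairs <- function(ids, suffix, panel_b, scenario) {
    if (!length(ids)) return(NULL)
    data.frame(sample_id_a = ids, panel_a = "axiom",
               sample_id_b = paste0(ids, suffix), panel_b = panel_b,
               scenario = scenario, stringsAsFactors = FALSE)
  }
  pairs <- rbind(
    mk_pairs(rep_same, ".r1", "axiom", "same_batch"),
    mk_pairs(rep_cross, ".r2", "axiom", "cross_batch"),
    mk_pairs(rep_array, ".ld", "array50k", "cross_array"),
    mk_pairs(rep_wgs, ".wgs", "wgs", "vs_wgs")
  )

  panels <- list(axiom = panel_axiom)
  if (!is.null(panel_wgs)) panels$wgs <- panel_wgs
  if (!is.null(panel_ld)) panels$array50k <- panel_ld

  masks <- if (length(masks)) do.call(rbind, masks) else
    data.frame(variant_idx = integer(), kind = character(),
               observed_call = integer(), panel = character(),
               sample_id = character(), stringsAsFactors = FALSE)

  list(
    panels = panels,
    manifest = manifest,
    pairs = pairs,
    truth = list(individuals = ind, true_calls = true_calls,
                 segments = truth_segments, masks = masks,
                 bad_variants = bad_sets, failing_samples = failing_samples,
                 freqs = fs$freqs, variants = fs$variants,
                 tracts = fs$tracts),
    config = config,
    design = design
  )
}
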