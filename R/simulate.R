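#' Simulation configuration
#'
#' Parameters of the synthetic genotype generator. The generator emulates the
#' statistical structure the QC analysis consumes — breed-structured allele
#' frequencies, within-individual autozygosity as a mosaic of planted
#' identity-by-descent (IBD) segments, F1 outcrosses, batch-specific
#' heterozygous-call inflation, allele dropout and missingness — with full
#' truth records. Sites are independent given the IBD mosaic (no linkage
#' model); see the package vignette for what that does and does not emulate.
#'
#' Breed allele frequencies follow a Balding-Nichols model: an ancestral
#' frequency is drawn from `Beta(ancestral_beta[1], ancestral_beta[2])` per
#' variant, and each breed's frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst`. A configurable number of
#' monomorphic tracts — runs of consecutive SNPs fixed for the same allele in
#' every breed — emulates the low-diversity stretches of real panels that
#' give even F1 outcrosses a floor of homozygous-by-state runs.
#'
#' @param seed integer seed; every draw of a study derives from it
#' @param n_chromosomes,chrom_length_bp,snps_per_chrom genome geometry; SNP
#'   positions are sorted uniform draws per chromosome. The default is a
#'   high-density regime (1 SNP/kb) in which per-segment SNP counts carry
#'   information about call errors.
#' @param n_breeds number of breeds
#' @param ancestral_beta length-2 shape parameters of the ancestral
#'   frequency distribution
#' @param fst breed differentiation; scalar or one value per breed
#' @param n_tracts_per_chrom,tract_snps monomorphic tracts per chromosome and
#'   their size in SNPs (0 tracts disables them)
#' @param ascertainment_maf_floor when > 0, variants whose MAF in the
#'   discovery breed falls below the floor are resampled (array
#'   ascertainment); tracts are exempt
#' @param discovery_breed breed index used for ascertainment
#' @param ibd_mean_kb,ibd_cv mean and coefficient of variation of planted
#'   IBD-segment lengths (gamma distributed)
#' @param avoid_tracts keep planted segments clear of monomorphic tracts,
#'   where autozygosity is unobservable (default TRUE)
#' @param batches named list of per-batch error models, each a list with
#'   `het_inflation` (P(hom -> het)), `dropout` (P(het -> random hom)),
#'   `missing` (P(call -> missing), applied last), and optionally
#'   `sample_fail_frac` / `pass_het_inflation` (fraction of the batch's
#'   samples that fail processing and carry the full `het_inflation`; the
#'   remainder get `pass_het_inflation`) and `bad_variant_frac` /
#'   `bad_variant_het` / `bad_variant_missing` describing a set of
#'   batch-specific systematically miscalled variants (hom -> het, and
#'   elevated missingness, at those variants, for every sample in the batch)
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 25e6,
                       snps_per_chrom = 25000L,
                       n_breeds = 2L,
                       ancestral_beta = c(1, 1),
                       fst = 0.1,
                       n_tracts_per_chrom = 2L,
                       tract_snps = 800L,
                       ascertainment_maf_floor = 0,
                       discovery_breed = 1L,
                       ibd_mean_kb = 1500,
                       ibd_cv = 0.2,
                       avoid_tracts = TRUE,
                       batches = default_batches()) {
  stopifnot(length(ancestral_beta) == 2L, all(ancestral_beta > 0),
            n_chromosomes >= 1L, snps_per_chrom >= 1L, chrom_length_bp > 0,
            n_breeds >= 1L, all(fst > 0), all(fst < 1),
            ibd_mean_kb > 0, ibd_cv > 0,
            ascertainment_maf_floor >= 0, ascertainment_maf_floor < 0.5)
  for (b in batches) {
    rates <- c(b$het_inflation %||% 0, b$dropout %||% 0, b$missing %||% 0,
               b$sample_fail_frac %||% 1, b$pass_het_inflation %||% 0,
               b$bad_variant_frac %||% 0, b$bad_variant_het %||% 0,
               b$bad_variant_missing %||% 0)
    if (any(rates < 0 | rates > 1)) stop_config("batch rates must lie in [0, 1]")
  }
  fst <- rep_len(fst, n_breeds)
  structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    snps_per_chrom = as.integer(snps_per_chrom),
    n_breeds = as.integer(n_breeds),
    ancestral_beta = as.numeric(ancestral_beta),
    fst = as.numeric(fst),
    n_tracts_per_chrom = as.integer(n_tracts_per_chrom),
    tract_snps = as.integer(tract_snps),
    ascertainment_maf_floor = as.numeric(ascertainment_maf_floor),
    discovery_breed = as.integer(discovery_breed),
    ibd_mean_kb = as.numeric(ibd_mean_kb),
    ibd_cv = as.numeric(ibd_cv),
    avoid_tracts = isTRUE(avoid_tracts),
    batches = batches
  ), class = "sim_config")
}

#' Default batch error models
#'
#' Two array batches (a clean one and one affected by heterozygous-call
#' inflation plus a set of systematically miscalled variants), a WGS-like
#' profile and a lower-density second-array profile.
#' @return named list of batch error models
#' @export
default_batches <- function() {
  list(
    clean = list(het_inflation = 5e-4, dropout = 0.001, missing = 0.001),
    artifact = list(het_inflation = 0.15, dropout = 0.001, missing = 0.002,
                    sample_fail_frac = 0.6, pass_het_inflation = 0.001,
                    bad_variant_frac = 0.02, bad_variant_het = 0.25,
                    bad_variant_missing = 0.5),
    wgs = list(het_inflation = 0.004, dropout = 0.02, missing = 0.03),
    array50k = list(het_inflation = 0.004, dropout = 0.001, missing = 0.002)
  )
}

#' Simulated autosome length in kb
#' @param config a [sim_config()]
#' @return numeric scalar
#' @export
sim_l_auto_kb <- function(config) {
  config$n_chromosomes * config$chrom_length_bp / 1000
}

#' Draw breed-structured allele frequencies and the variant map
#'
#' Draws SNP positions (sorted uniforms per chromosome), allele pairs (from
#' the four strand-unambiguous pairs, as arrays are designed), monomorphic
#' tract placements and per-breed B-allele frequencies under the
#' Balding-Nichols model described in [sim_config()]. Uses the current RNG
#' state; seed upstream (as [simulate_study()] does) for reproducibility.
#'
#' @param config a [sim_config()]
#' @return list with `variants` (data frame), `freqs` (variants x breeds
#'   matrix of B-allele frequencies), `tracts` (data frame of monomorphic
#'   tract regions) and `in_tract` (logical per variant)
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nc <- config$n_chromosomes
  ns <- config$snps_per_chrom
  n <- nc * ns

  chrom <- rep(as.character(seq_len(nc)), each = ns)
  pos <- unlist(lapply(seq_len(nc), function(i) {
    p <- sort(sample.int(config$chrom_length_bp, ns))
    p
  }), use.names = FALSE)

  ## strand-unambiguous pairs, already in canonical (alphabetical) order
  pairs <- matrix(c("A", "C", "A", "G", "C", "T", "G", "T"), ncol = 2, byrow = TRUE)
  pick <- sample.int(4L, n, replace = TRUE)
  variants <- data.frame(
    variant_id = paste0("snp", seq_len(n)),
    chromosome = chrom, position_bp = pos,
    allele_a = pairs[pick, 1], allele_b = pairs[pick, 2],
    stringsAsFactors = FALSE
  )

  ## monomorphic tracts: non-overlapping blocks of consecutive SNP indices
  in_tract <- logical(n)
  tracts <- NULL
  if (config$n_tracts_per_chrom > 0L && config$tract_snps > 0L) {
    tl <- list()
    for (ci in seq_len(nc)) {
      offset <- (ci - 1L) * ns
      width <- config$tract_snps
      slots <- max(0L, ns - width + 1L)
      if (slots < 1L) next
      placed <- integer(0)
      attempts <- 0L
      while (length(placed) < config$n_tracts_per_chrom && attempts < 1000L) {
        attempts <- attempts + 1L
        st <- sample.int(slots, 1L)
        ## require clear separation from already-placed tracts
        if (!length(placed) || all(abs(st - placed) > 2L * width)) {
          placed <- c(placed, st)
        }
      }
      for (st in sort(placed)) {
        idx <- offset + st:(st + width - 1L)
        in_tract[idx] <- TRUE
        tl[[length(tl) + 1L]] <- data.frame(
          chromosome = as.character(ci),
          start_bp = pos[idx[1]], end_bp = pos[idx[length(idx)]],
          start_idx = idx[1], end_idx = idx[length(idx)],
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(tl)) tracts <- do.call(rbind, tl)
  }
  if (is.null(tracts)) {
    tracts <- data.frame(chromosome = character(), start_bp = integer(),
                         end_bp = integer(), start_idx = integer(),
                         end_idx = integer(), stringsAsFactors = FALSE)
  }

  draw_freqs <- function(k) {
    anc <- stats::rbeta(k, config$ancestral_beta[1], config$ancestral_beta[2])
    f <- sapply(seq_len(config$n_breeds), function(b) {
      Fst <- config$fst[b]
      c1 <- anc * (1 - Fst) / Fst
      c2 <- (1 - anc) * (1 - Fst) / Fst
      stats::rbeta(k, pmax(c1, 1e-8), pmax(c2, 1e-8))
    })
    matrix(f, nrow = k)
  }
  freqs <- draw_freqs(n)

  floor <- config$ascertainment_maf_floor
  if (floor > 0) {
    disc <- config$discovery_breed
    for (round in seq_len(100L)) {
      maf <- pmin(freqs[, disc], 1 - freqs[, disc])
      bad <- which(maf < floor & !in_tract)
      if (!length(bad)) break
      freqs[bad, ] <- draw_freqs(length(bad))
    }
    maf <- pmin(freqs[, disc], 1 - freqs[, disc])
    still <- maf < floor & !in_tract
    if (any(still)) {
      ## force the stragglers by reflecting into the admissible range
      freqs[still, disc] <- floor + (0.5 - floor) * stats::runif(sum(still))
    }
  }
  freqs[in_tract, ] <- 0

  list(variants = variants, freqs = freqs, tracts = tracts, in_tract = in_tract)
}

#' Simulate one purebred individual as an IBD mosaic
#'
#' Plants non-overlapping IBD segments (gamma-distributed lengths) until
#' their total length reaches `f_true` of the genome, truncating the last
#' segment so the planted total is exact. Inside a segment one allele is
#' drawn from the breed frequency and doubled (forced homozygous); outside,
#' the two alleles are drawn independently (Hardy-Weinberg). Uses the
#' current RNG state.
#'
#' @param freq_set result of [simulate_frequencies()]
#' @param breed breed index (column of `freq_set$freqs`)
#' @param f_true target autozygous genome fraction in `[0, 1)`
#' @param config a [sim_config()]
#' @return list with `calls` (integer vector over variants) and `segments`
#'   (data frame chromosome/start_bp/end_bp/length_kb of planted segments)
#' @export
simulate_individual <- function(freq_set, breed, f_true, config) {
  stopifnot(f_true >= 0, f_true < 1)
  p <- freq_set$freqs[, breed]
  n <- length(p)
  v <- freq_set$variants
  genome_bp <- config$n_chromosomes * config$chrom_length_bp
  target_bp <- f_true * genome_bp

  segs <- data.frame(chromosome = character(), start_bp = numeric(),
                     end_bp = numeric(), length_kb = numeric(),
                     stringsAsFactors = FALSE)
  in_ibd <- logical(n)
  if (target_bp > 0) {
    ## free-space bookkeeping: segments are placed uniformly into the gaps
    ## that remain, so they never overlap each other (or, optionally, the
    ## monomorphic tracts) and the placed total hits the target exactly
    free <- data.frame(chromosome = as.character(seq_len(config$n_chromosomes)),
                       start = 1, end = config$chrom_length_bp,
                       stringsAsFactors = FALSE)
    if (config$avoid_tracts && nrow(freq_set$tracts)) {
      for (t in seq_len(nrow(freq_set$tracts))) {
        tr <- freq_set$tracts[t, ]
        hit <- which(free$chromosome == tr$chromosome &
                       free$start <= tr$end_bp & free$end >= tr$start_bp)
        for (k in hit) {
          pieces <- data.frame(
            chromosome = tr$chromosome,
            start = c(free$start[k], tr$end_bp + 1),
            end = c(tr$start_bp - 1, free$end[k]),
            stringsAsFactors = FALSE)
          free <- rbind(free[-k, , drop = FALSE],
                        pieces[pieces$end >= pieces$start, , drop = FALSE])
        }
      }
    }
    placed_bp <- 0
    shape <- 1 / config$ibd_cv^2
    while (placed_bp < target_bp - 0.5) {
      if (!nrow(free)) {
        stop_data("could not place IBD segments totalling f_true = ", f_true,
                  ": no free genome left (tracts too crowded?)")
      }
      len <- stats::rgamma(1, shape = shape, rate = shape / (config$ibd_mean_kb * 1000))
      len <- max(round(len), 1e4)
      if (placed_bp + len > target_bp) len <- round(target_bp - placed_bp)  # truncate last
      width <- free$end - free$start + 1
      fits <- which(width >= len)
      if (length(fits)) {
        k <- if (length(fits) == 1L) fits else
          sample(fits, 1L, prob = width[fits] - len + 1)
        st <- free$start[k] + floor(stats::runif(1) * (width[k] - len + 1))
      } else {
        k <- which.max(width)       # fill the largest remaining gap entirely
        len <- width[k]
        st <- free$start[k]
      }
      en <- st + len - 1
      chl <- free$chromosome[k]
      pieces <- data.frame(chromosome = chl,
                           start = c(free$start[k], en + 1),
                           end = c(st - 1, free$end[k]),
                           stringsAsFactors = FALSE)
      free <- rbind(free[-k, , drop = FALSE],
                    pieces[pieces$end >= pieces$start, , drop = FALSE])
      segs <- rbind(segs, data.frame(chromosome = chl, start_bp = st,
                                     end_bp = en, length_kb = (en - st + 1) / 1000,
                                     stringsAsFactors = FALSE))
      placed_bp <- placed_bp + len
      idx <- which(v$chromosome == chl & v$position_bp >= st & v$position_bp <= en)
      in_ibd[idx] <- TRUE
    }
  }

  calls <- integer(n)
  out <- !in_ibd
  calls[out] <- stats::rbinom(sum(out), 2L, p[out])
  calls[in_ibd] <- 2L * stats::rbinom(sum(in_ibd), 1L, p[in_ibd])
  segs <- segs[order(match(segs$chromosome, as.character(seq_len(config$n_chromosomes))),
                     segs$start_bp), , drop = FALSE]
  rownames(segs) <- NULL
  list(calls = calls, segments = segs)
}

#' Simulate an F1 outcross between two breeds
#'
#' One haplotype drawn from each breed's frequencies; no planted segments.
#' Uses the current RNG state.
#'
#' @param freq_set result of [simulate_frequencies()]
#' @param breed1,breed2 breed column indices
#' @return integer call vector
#' @export
simulate_f1 <- function(freq_set, breed1, breed2) {
  p1 <- freq_set$freqs[, breed1]
  p2 <- freq_set$freqs[, breed2]
  stats::rbinom(length(p1), 1L, p1) + stats::rbinom(length(p2), 1L, p2)
}

#' Apply a batch error model to true calls
#'
#' Independently per call: a homozygote becomes heterozygous with probability
#' `het_inflation` (at batch-specific bad variants, with probability
#' `bad_variant_het` instead); a heterozygote becomes a random homozygote
#' with probability `dropout`; any call is set missing with probability
#' `missing`, applied last. The returned mask records every call whose
#' observed value differs from truth — one row per changed call, so replaying
#' the mask on the true vector reproduces the observed vector exactly.
#'
#' @param true_calls integer call vector
#' @param batch batch name, looked up in `config$batches`
#' @param config a [sim_config()]
#' @param bad_variants integer indices of this batch's systematically
#'   miscalled variants (drawn once per batch by [simulate_study()])
#' @param failing whether this genotyping instance is one of the batch's
#'   failing samples: failing samples experience the batch's `het_inflation`,
#'   passing samples its `pass_het_inflation` (default 0). [simulate_study()]
#'   draws the failing status per sample from the batch's
#'   `sample_fail_frac`.
#' @return list with `calls` (observed) and `mask` (data frame variant_idx,
#'   kind, observed_call)
#' @export
apply_error_model <- function(true_calls, batch, config, bad_variants = integer(0),
                              failing = TRUE) {
  rates <- config$batches[[batch]]
  if (is.null(rates)) stop_config("unknown batch '", batch, "'; config defines: ",
                                  paste(names(config$batches), collapse = ", "))
  eps <- if (failing) rates$het_inflation %||% 0 else rates$pass_het_inflation %||% 0
  delta <- rates$dropout %||% 0
  miss <- rates$missing %||% 0
  bad_het <- rates$bad_variant_het %||% 0
  bad_miss <- rates$bad_variant_missing %||% 0

  n <- length(true_calls)
  obs <- true_calls
  kind <- character(n)

  hom <- which(!is.na(obs) & obs != 1L)
  if (eps > 0 && length(hom)) {
    flip <- hom[stats::runif(length(hom)) < eps]
    obs[flip] <- 1L
    kind[flip] <- "het_inflated"
  }
  if (bad_het > 0 && length(bad_variants)) {
    bh <- bad_variants[!is.na(obs[bad_variants]) & obs[bad_variants] != 1L &
                         kind[bad_variants] == ""]
    flip <- bh[stats::runif(length(bh)) < bad_het]
    obs[flip] <- 1L
    kind[flip] <- "bad_variant"
  }
  het <- which(!is.na(obs) & obs == 1L & kind == "")
  if (delta > 0 && length(het)) {
    drop <- het[stats::runif(length(het)) < delta]
    obs[drop] <- 2L * stats::rbinom(length(drop), 1L, 0.5)
    kind[drop] <- "dropout"
  }
  pmiss <- rep(miss, n)
  if (bad_miss > 0 && length(bad_variants)) {
    pmiss[bad_variants] <- pmax(pmiss[bad_variants], bad_miss)
  }
  if (any(pmiss > 0)) {
    gone <- which(stats::runif(n) < pmiss & !is.na(obs))
    obs[gone] <- NA_integer_
    kind[gone] <- "missing"   # overrides earlier kinds: masks stay disjoint
  }

  changed <- which(kind != "" & (is.na(obs) | is.na(true_calls) | obs != true_calls))
  mask <- data.frame(variant_idx = changed, kind = kind[changed],
                     observed_call = obs[changed], stringsAsFactors = FALSE)
  list(calls = obs, mask = mask)
}

#' Generate technical replicates of one true genotype vector
#'
#' Each replicate applies an independent error layer to the same true calls;
#' the batch label of each replicate selects its error model.
#'
#' @param true_calls integer call vector
#' @param batches character vector of batch names, one per replicate (length
#'   >= 2)
#' @param config a [sim_config()]
#' @param bad_sets named list (by batch) of bad-variant index vectors
#' @return list of [apply_error_model()] results, one per replicate
#' @export
make_replicates <- function(true_calls, batches, config, bad_sets = list()) {
  if (length(batches) < 2L) stop_config("need at least 2 replicates")
  lapply(batches, function(b) {
    apply_error_model(true_calls, b, config, bad_sets[[b]] %||% integer(0))
  })
}
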