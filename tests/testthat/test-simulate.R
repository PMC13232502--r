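small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chromosomes = 1L, chrom_length_bp = 4e6,
             snps_per_chrom = 4000L, n_tracts_per_chrom = 0L, ...)
}

test_that("frequency draws are reproducible and match their Beta mean", {
  cfg <- small_cfg(seed = 51)
  set.seed(cfg$seed); a <- simulate_frequencies(cfg)
  set.seed(cfg$seed); b <- simulate_frequencies(cfg)
  expect_identical(a, b)
  ## Beta(1,1) ancestral with symmetric drift: overall mean frequency ~ 0.5
  expect_lt(abs(mean(a$freqs) - 0.5), 3 * sqrt(1 / 12 / length(a$freqs)) * 2)
  expect_true(all(a$freqs >= 0 & a$freqs <= 1))
  expect_true(all(diff(a$variants$position_bp) > 0))
})

test_that("ascertainment enforces the discovery-breed MAF floor", {
  cfg <- sim_config(seed = 52, n_chromosomes = 1L, chrom_length_bp = 2e6,
                    snps_per_chrom = 2000L, n_tracts_per_chrom = 0L,
                    n_breeds = 2L, ascertainment_maf_floor = 0.1)
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  maf <- pmin(fs$freqs[, 1], 1 - fs$freqs[, 1])
  expect_true(all(maf >= 0.1))
  ## the non-discovery breed is left unconstrained
  maf2 <- pmin(fs$freqs[, 2], 1 - fs$freqs[, 2])
  expect_true(any(maf2 < 0.1))
})

test_that("monomorphic tracts are fixed in every breed and placed apart", {
  cfg <- sim_config(seed = 53, n_chromosomes = 2L, chrom_length_bp = 5e6,
                    snps_per_chrom = 5000L, n_tracts_per_chrom = 2L,
                    tract_snps = 400L)
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  expect_true(all(fs$freqs[fs$in_tract, ] == 0))
  expect_equal(sum(fs$in_tract), nrow(fs$tracts) * 400L)
  by_chrom <- split(fs$tracts, fs$tracts$chromosome)
  for (tt in by_chrom) {
    if (nrow(tt) > 1) {
      tt <- tt[order(tt$start_idx), ]
      expect_true(all(tt$start_idx[-1] > tt$end_idx[-nrow(tt)]))
    }
  }
})

test_that("an outbred individual has no segments and Hardy-Weinberg het levels", {
  cfg <- small_cfg(seed = 54)
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  ind <- simulate_individual(fs, 1, 0, cfg)
  expect_equal(nrow(ind$segments), 0L)
  p <- fs$freqs[, 1]
  expect_lt(abs(mean(ind$calls == 1L) - mean(2 * p * (1 - p))), 0.02)
})

test_that("planted segment totals hit the autozygosity target exactly", {
  cfg <- small_cfg(seed = 55)
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  for (f in c(0.1, 0.3, 0.7)) {
    ind <- simulate_individual(fs, 1, f, cfg)
    total_bp <- sum(ind$segments$end_bp - ind$segments$start_bp + 1)
    expect_equal(total_bp / (cfg$n_chromosomes * cfg$chrom_length_bp), f,
                 tolerance = 1e-6)
    ## non-overlapping per chromosome
    for (ch in unique(ind$segments$chromosome)) {
      s <- ind$segments[ind$segments$chromosome == ch, ]
      s <- s[order(s$start_bp), ]
      if (nrow(s) > 1) expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
    }
    ## calls inside segments are homozygous
    idx <- rep(FALSE, length(ind$calls))
    for (r in seq_len(nrow(ind$segments))) {
      idx <- idx | (fs$variants$chromosome == ind$segments$chromosome[r] &
                      fs$variants$position_bp >= ind$segments$start_bp[r] &
                      fs$variants$position_bp <= ind$segments$end_bp[r])
    }
    expect_true(all(ind$calls[idx] != 1L))
  }
})

test_that("a nearly complete autozygous target approaches genome-wide homozygosity", {
  cfg <- sim_config(seed = 56, n_chromosomes = 1L, chrom_length_bp = 2e6,
                    snps_per_chrom = 1000L, n_tracts_per_chrom = 0L,
                    ibd_mean_kb = 400)
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  ind <- simulate_individual(fs, 1, 0.95, cfg)
  expect_gt(mean(ind$calls != 1L), 0.9)
})

test_that("planted segments avoid monomorphic tracts when asked", {
  cfg <- sim_config(seed = 57, n_chromosomes = 1L, chrom_length_bp = 6e6,
                    snps_per_chrom = 6000L, n_tracts_per_chrom = 2L,
                    tract_snps = 500L, avoid_tracts = TRUE)
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  ind <- simulate_individual(fs, 1, 0.3, cfg)
  for (t in seq_len(nrow(fs$tracts))) {
    tr <- fs$tracts[t, ]
    overlap <- ind$segments$chromosome == tr$chromosome &
      ind$segments$start_bp <= tr$end_bp & ind$segments$end_bp >= tr$start_bp
    expect_false(any(overlap))
  }
})

test_that("F1 heterozygosity matches the cross-breed expectation", {
  cfg <- small_cfg(seed = 58, n_breeds = 2L)
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  g <- simulate_f1(fs, 1, 2)
  p1 <- fs$freqs[, 1]; p2 <- fs$freqs[, 2]
  expected <- mean(p1 * (1 - p2) + p2 * (1 - p1))
  expect_lt(abs(mean(g == 1L) - expected), 0.02)
})

test_that("error model limits behave as designed", {
  cfg <- small_cfg(seed = 59, batches = list(
    none = list(),
    all_het = list(het_inflation = 1),
    some = list(het_inflation = 0.05)))
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  truth <- simulate_individual(fs, 1, 0.2, cfg)$calls

  o0 <- apply_error_model(truth, "none", cfg)
  expect_identical(o0$calls, truth)
  expect_equal(nrow(o0$mask), 0L)

  o1 <- apply_error_model(truth, "all_het", cfg)
  expect_true(all(o1$calls == 1L))

  o2 <- apply_error_model(truth, "some", cfg)
  hom <- truth != 1L
  frac <- mean(o2$calls[hom] == 1L)
  se <- sqrt(0.05 * 0.95 / sum(hom))
  expect_lt(abs(frac - 0.05), 3 * se)

  expect_error(apply_error_model(truth, "ghost", cfg), "unknown batch")
})

test_that("error masks exactly reconcile truth with observation", {
  cfg <- small_cfg(seed = 60, batches = list(
    messy = list(het_inflation = 0.05, dropout = 0.1, missing = 0.05,
                 bad_variant_frac = 0.05, bad_variant_het = 0.5,
                 bad_variant_missing = 0.3)))
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  truth <- simulate_individual(fs, 1, 0.2, cfg)$calls
  bad <- sort(sample.int(length(truth), 200L))
  o <- apply_error_model(truth, "messy", cfg, bad_variants = bad)
  expect_false(any(duplicated(o$mask$variant_idx)))   # masks are disjoint
  replay <- truth
  replay[o$mask$variant_idx] <- o$mask$observed_call
  expect_identical(replay, o$calls)
  ## untouched positions agree with truth
  untouched <- setdiff(seq_along(truth), o$mask$variant_idx)
  expect_identical(o$calls[untouched], truth[untouched])
})

test_that("replicates of one truth are identical without error and diverge with it", {
  cfg <- small_cfg(seed = 61, batches = list(
    none = list(), eps = list(het_inflation = 0.02)))
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  truth <- simulate_individual(fs, 1, 0.1, cfg)$calls
  clean <- make_replicates(truth, c("none", "none"), cfg)
  expect_identical(clean[[1]]$calls, clean[[2]]$calls)

  for (r in 1:5) {
    mixed <- make_replicates(truth, c("none", "eps", "eps"), cfg)
    d_clean_eps <- mean(mixed[[1]]$calls != mixed[[2]]$calls)
    expect_gt(d_clean_eps, 0)
  }
  expect_error(make_replicates(truth, "none", cfg), "at least 2")
})

test_that("genotype counts are Hardy-Weinberg consistent without planted segments", {
  cfg <- sim_config(seed = 62, n_chromosomes = 1L, chrom_length_bp = 1e6,
                    snps_per_chrom = 400L, n_tracts_per_chrom = 0L)
  set.seed(cfg$seed)
  fs <- simulate_frequencies(cfg)
  n_ind <- 150
  calls <- t(sapply(seq_len(n_ind), function(i) simulate_individual(fs, 1, 0, cfg)$calls))
  p <- fs$freqs[, 1]
  pass <- logical(ncol(calls))
  for (j in seq_len(ncol(calls))) {
    probs <- c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
    obs <- tabulate(calls[, j] + 1L, nbins = 3L)
    keep <- probs > 0
    if (sum(keep) < 2) { pass[j] <- TRUE; next }
    pv <- suppressWarnings(stats::chisq.test(obs[keep], p = probs[keep])$p.value)
    pass[j] <- is.na(pv) || pv > 0.01
  }
  expect_gte(mean(pass), 0.95)
})

test_that("a full study is deterministic and internally consistent", {
  cfg <- sim_config(seed = 63, n_chromosomes = 1L, chrom_length_bp = 3e6,
                    snps_per_chrom = 3000L, n_tracts_per_chrom = 1L,
                    tract_snps = 300L)
  des <- study_design(n_per_breed = 6L, n_f1 = 2L, n_rep_same = 2L,
                      n_rep_cross = 2L, n_rep_wgs = 1L, n_rep_array = 1L)
  s1 <- simulate_study(cfg, des)
  s2 <- simulate_study(cfg, des)
  expect_identical(s1$panels$axiom$calls, s2$panels$axiom$calls)
  expect_identical(s1$truth$segments, s2$truth$segments)

  ## manifest covers every panel sample exactly once
  for (nm in names(s1$panels)) {
    in_manifest <- s1$manifest$sample_id[s1$manifest$panel == nm]
    expect_setequal(in_manifest, s1$panels[[nm]]$samples)
  }
  ## every pair resolves, and scenarios are as designed
  expect_equal(sum(s1$pairs$scenario == "same_batch"), 2L)
  expect_equal(sum(s1$pairs$scenario == "cross_batch"), 2L)
  expect_equal(sum(s1$pairs$scenario == "vs_wgs"), 1L)
  expect_equal(sum(s1$pairs$scenario == "cross_array"), 1L)

  ## masks replay truth into the observed axiom panel; columns where the
  ## panel kept only a data-supported allele label are compared after
  ## applying the same canonical re-coding
  ax <- s1$panels$axiom
  flip <- ax$variants$allele_a == s1$truth$variants$allele_b
  for (sid in sample(ax$samples, 5)) {
    ind_id <- s1$manifest$replicate_group[s1$manifest$sample_id == sid]
    if (ind_id == "") ind_id <- sid
    truth_row <- s1$truth$true_calls[ind_id, ]
    m <- s1$truth$masks
    m <- m[m$panel == "axiom" & m$sample_id == sid, ]
    replay <- truth_row
    replay[m$variant_idx] <- m$observed_call
    replay[flip] <- 2L - replay[flip]
    expect_identical(unname(replay), unname(ax$calls[sid, ]))
  }
})
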