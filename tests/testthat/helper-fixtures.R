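# Fixture builders and the independent brute-force ROH enumerator used to
# cross-check the segment-scope scan.

# Panel with one chromosome and explicit calls; positions default to an even
# 10-kb grid.
make_panel <- function(calls, pos = NULL, chrom = "1",
                       allele_a = "A", allele_b = "G") {
  if (!is.matrix(calls)) calls <- matrix(as.integer(calls), nrow = 1)
  nv <- ncol(calls)
  if (is.null(pos)) pos <- seq(10000L, by = 10000L, length.out = nv)
  v <- data.frame(variant_id = paste0("v", seq_len(nv)),
                  chromosome = chrom, position_bp = pos,
                  allele_a = allele_a, allele_b = allele_b,
                  stringsAsFactors = FALSE)
  genotype_panel(v, paste0("s", seq_len(nrow(calls))), calls)
}

# Random multi-chromosome panel with missing calls, for round-trip and
# property tests. Caller controls the RNG seed.
random_panel <- function(n_samples = 5, n_variants = 50, n_chrom = 2,
                         miss_rate = 0.05) {
  chrom <- sort(sample(as.character(seq_len(n_chrom)), n_variants, replace = TRUE))
  pos <- integer(n_variants)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- sort(sample.int(1e7, k))
  }
  pairs <- matrix(c("A", "C", "A", "G", "T", "C", "T", "G", "A", "T", "C", "G"),
                  ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), n_variants, replace = TRUE)
  calls <- matrix(sample(c(0:2, NA), n_samples * n_variants, replace = TRUE,
                         prob = c(0.4, 0.2, 0.35, miss_rate)),
                  nrow = n_samples)
  v <- data.frame(variant_id = paste0("rv", seq_len(n_variants)),
                  chromosome = chrom, position_bp = pos,
                  allele_a = pairs[pick, 1], allele_b = pairs[pick, 2],
                  stringsAsFactors = FALSE)
  genotype_panel(v, paste0("smp", seq_len(n_samples)), calls)
}

# Random single-chromosome genotype vector mixing homozygosity regimes, used
# for the enumerator cross-checks.
random_roh_instance <- function(n = 250) {
  hom_p <- sample(c(0.55, 0.8, 0.97), 1)
  spacing <- sample(c(2000, 8000, 40000), 1)
  pos <- cumsum(1 + stats::rgeom(n, 1 / spacing))
  g <- sample(c(0L, 2L, 1L, NA), n, replace = TRUE,
              prob = c(hom_p / 2, hom_p / 2, (1 - hom_p) * 0.8, (1 - hom_p) * 0.2))
  list(g = g, pos = as.integer(pos))
}

# Exhaustive reference enumerator for segment-scope ROH: lists every
# qualifying interval, keeps the maximal ones (not strictly contained in
# another qualifying interval), then resolves overlaps leftmost-first.
# Deliberately naive: O(n^2) interval enumeration.
oracle_segments <- function(g, pos, s) {
  n <- length(g)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  ch <- c(0L, cumsum(het)); cm <- c(0L, cumsum(mis)); co <- c(0L, cumsum(hom))
  gaps_bad <- c(which(diff(pos) > s$max_gap_kb * 1000), n)  # gap after index k

  ivs <- list()
  for (i in seq_len(n)) {
    if (!hom[i]) next
    jmax <- min(gaps_bad[gaps_bad >= i])   # cannot cross a bad gap
    j <- i:jmax
    nh <- co[j + 1L] - co[i]
    nhet <- ch[j + 1L] - ch[i]
    nmis <- cm[j + 1L] - cm[i]
    len_kb <- (pos[j] - pos[i] + 1) / 1000
    ok <- hom[j] & nhet <= s$max_het & nmis <= s$max_miss &
      len_kb >= s$min_length_kb & nh > s$min_snps &
      len_kb / nh <= s$max_density_kb_per_snp
    for (jj in j[ok]) ivs[[length(ivs) + 1L]] <- c(i, jj)
  }
  if (!length(ivs)) {
    return(data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(), n_miss = integer()))
  }
  m <- do.call(rbind, ivs)
  ## keep one interval per start (the widest), then drop intervals whose end
  ## is covered by an earlier, wider start: exactly the non-contained ones
  m <- m[order(m[, 1], -m[, 2]), , drop = FALSE]
  m <- m[!duplicated(m[, 1]), , drop = FALSE]
  run_max <- cummax(c(-1L, m[-nrow(m), 2]))
  m <- m[m[, 2] > run_max, , drop = FALSE]
  ## greedy leftmost-first non-overlap
  kept <- list(); last_end <- 0L
  for (r in seq_len(nrow(m))) {
    if (m[r, 1] > last_end) { kept[[length(kept) + 1L]] <- m[r, ]; last_end <- m[r, 2] }
  }
  m <- do.call(rbind, kept)
  data.frame(start_bp = pos[m[, 1]], end_bp = pos[m[, 2]],
             n_snps = co[m[, 2] + 1L] - co[m[, 1]],
             n_het = ch[m[, 2] + 1L] - ch[m[, 1]],
             n_miss = cm[m[, 2] + 1L] - cm[m[, 1]])
}

# Compare detect_roh (segment scope) with the enumerator on one instance.
expect_matches_oracle <- function(g, pos, settings, info = NULL) {
  p <- make_panel(matrix(g, nrow = 1), pos = pos)
  got <- detect_roh(p, settings)
  want <- oracle_segments(g, pos, settings)
  expect_equal(nrow(got), nrow(want), info = info)
  if (nrow(want)) {
    expect_equal(got$start_bp, want$start_bp, info = info)
    expect_equal(got$end_bp, want$end_bp, info = info)
    expect_equal(got$n_snps, want$n_snps, info = info)
    expect_equal(got$n_het, want$n_het, info = info)
    expect_equal(got$n_miss, want$n_miss, info = info)
  }
}
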