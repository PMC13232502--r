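test_that("minimal PED/MAP pair parses to a single homozygous call", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines("1\tsnp1\t0\t1000", map)
  writeLines("F1 S1 0 0 0 -9 A A", ped)
  p <- read_ped_map(ped, map)
  expect_equal(p$samples, "S1")
  expect_equal(unname(p$calls[1, 1]), 0L)
  expect_equal(p$variants$allele_a, "A")
  expect_equal(p$variants$allele_b, "0")  # second allele never observed
})

test_that("heterozygote parsing is allele-order insensitive", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\tsnp1\t0\t1000"), map)
  writeLines(c("F1 S1 0 0 0 -9 G A",
               "F1 S2 0 0 0 -9 A G",
               "F1 S3 0 0 0 -9 G G"), ped)
  p <- read_ped_map(ped, map)
  expect_equal(unname(p$calls[, 1]), c(1L, 1L, 2L))  # alleles normalised A < G
})

test_that("half-missing genotypes become missing with a warning", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines("1\tsnp1\t0\t1000", map)
  writeLines(c("F1 S1 0 0 0 -9 A 0", "F1 S2 0 0 0 -9 A A"), ped)
  expect_warning(p <- read_ped_map(ped, map), "half-missing")
  expect_true(is.na(p$calls["S1", 1]))
  expect_equal(unname(p$calls["S2", 1]), 0L)
})

test_that("malformed files raise parse/data errors naming the offender", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1\tsnp1\t0\t1000", "1\tsnp2\t0\t2000"), map)
  writeLines("F1 S1 0 0 0 -9 A A", ped)   # one variant short
  expect_error(read_ped_map(ped, map), "PED line 1")

  writeLines("1\tsnp1\t0", map)           # 3 columns
  expect_error(read_ped_map(ped, map), "MAP line 1")

  writeLines("1\tsnp1\t0\t1000", map)
  writeLines(c("F1 S1 0 0 0 -9 A A", "F1 S2 0 0 0 -9 C G"), ped)
  expect_error(read_ped_map(ped, map), "snp1")  # three distinct alleles
})

test_that("write-then-read is the identity on the call matrix", {
  set.seed(11)
  for (trial in 1:5) {
    p <- random_panel(n_samples = sample(2:8, 1), n_variants = sample(20:80, 1))
    ped <- withr::local_tempfile(fileext = ".ped")
    map <- withr::local_tempfile(fileext = ".map")
    write_ped_map(p, ped, map)
    q <- read_ped_map(ped, map)
    expect_identical(q$samples, p$samples)
    expect_identical(q$variants$chromosome, p$variants$chromosome)
    expect_identical(q$variants$position_bp, p$variants$position_bp)
    expect_identical(unname(q$calls), unname(p$calls))
  }
})

test_that("round-trip preserves a larger simulated panel exactly", {
  set.seed(12)
  cfg <- sim_config(seed = 12, n_chromosomes = 2L, chrom_length_bp = 2e6,
                    snps_per_chrom = 500L, n_tracts_per_chrom = 0L)
  fs <- simulate_frequencies(cfg)
  calls <- t(replicate(50, simulate_individual(fs, 1, 0.1, cfg)$calls))
  p <- genotype_panel(fs$variants, sprintf("id%02d", 1:50), calls)
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(p, ped, map)
  expect_identical(unname(read_ped_map(ped, map)$calls), unname(p$calls))
})

test_that("an all-missing sample round-trips as a row of 0 0 pairs", {
  p <- make_panel(matrix(c(0L, 1L, NA, NA, NA, NA), nrow = 2, byrow = TRUE))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(p, ped, map)
  line2 <- readLines(ped)[2]
  expect_match(line2, "-9( 0 0){3}$")
  q <- read_ped_map(ped, map)
  expect_true(all(is.na(q$calls[2, ])))
})

test_that("an empty panel writes a valid MAP and an empty PED body", {
  v <- data.frame(variant_id = "x", chromosome = "1", position_bp = 5L,
                  allele_a = "A", allele_b = "C")
  p <- genotype_panel(v, character(0), matrix(integer(0), nrow = 0, ncol = 1))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(p, ped, map)
  expect_length(readLines(map), 1L)
  expect_length(readLines(ped), 0L)
  q <- read_ped_map(ped, map)
  expect_equal(n_samples(q), 0L)
  expect_equal(n_variants(q), 1L)
})

test_that("autosome filtering removes sex/unplaced variants and is idempotent", {
  chrom <- c("1", "1", "2", "X", "0", "31", "32")
  v <- data.frame(variant_id = paste0("v", 1:7), chromosome = chrom,
                  position_bp = c(100L, 200L, 100L, 100L, 100L, 100L, 100L),
                  allele_a = "A", allele_b = "G")
  p <- genotype_panel(v, "s1", matrix(0L, 1, 7))
  f <- filter_autosomes(p)
  expect_setequal(f$variants$chromosome, c("1", "2", "31"))
  expect_equal(n_variants(f), 4L)
  expect_identical(filter_autosomes(f)$variants, f$variants)
})

test_that("a panel with a fixed fraction off-autosome filters to the exact count", {
  set.seed(13)
  n <- 200
  chrom <- rep("1", n)
  chrom[sample.int(n, n / 10)] <- sample(c("X", "0"), n / 10, replace = TRUE)
  v <- data.frame(variant_id = paste0("v", 1:n), chromosome = chrom,
                  position_bp = seq_len(n) * 100L, allele_a = "A", allele_b = "G")
  p <- genotype_panel(v, "s1", matrix(1L, 1, n))
  expect_equal(n_variants(filter_autosomes(p)), as.integer(0.9 * n))
})

test_that("panel construction normalises allele order and rejects bad input", {
  v <- data.frame(variant_id = "v1", chromosome = "1", position_bp = 100L,
                  allele_a = "G", allele_b = "A")
  p <- genotype_panel(v, c("a", "b"), matrix(c(0L, 2L), 2, 1))
  expect_equal(p$variants$allele_a, "A")
  expect_equal(unname(p$calls[, 1]), c(2L, 0L))   # calls flipped with alleles

  expect_error(genotype_panel(v, c("a", "a"), matrix(0L, 2, 1)), "duplicate")
  expect_error(genotype_panel(v, "a", matrix(3L, 1, 1)), "call codes")
  v2 <- v; v2$position_bp <- 0L
  expect_error(genotype_panel(v2, "a", matrix(0L, 1, 1)), "position_bp")
})

test_that("duplicate positions are dropped keeping the first, with a warning", {
  v <- data.frame(variant_id = c("v1", "v2"), chromosome = "1",
                  position_bp = c(100L, 100L), allele_a = "A", allele_b = "G")
  expect_warning(p <- genotype_panel(v, "s", matrix(c(0L, 2L), 1, 2)),
                 "duplicated positions")
  expect_equal(p$variants$variant_id, "v1")
})

test_that("identical panels intersect fully; disjoint positions do not", {
  set.seed(14)
  p <- random_panel(n_samples = 2, n_variants = 30)
  sh <- intersect_panels(p, p)
  expect_equal(nrow(sh$map), 30L)
  expect_true(all(sh$map$orientation == "same" | !sh$map$compared))

  q <- p
  q$variants$position_bp <- q$variants$position_bp + 1L
  q <- genotype_panel(q$variants, q$samples, q$calls)
  expect_equal(nrow(intersect_panels(p, q)$map), 0L)
})

test_that("strand-ambiguous variants are excluded from comparison", {
  v <- data.frame(variant_id = c("v1", "v2"), chromosome = "1",
                  position_bp = c(100L, 200L),
                  allele_a = c("A", "A"), allele_b = c("T", "G"))
  p <- genotype_panel(v, "s1", matrix(1L, 1, 2))  # hets: both alleles observed
  sh <- intersect_panels(p, p)
  expect_equal(sh$map$orientation, c("ambiguous", "same"))
  expect_equal(sum(sh$map$compared), 1L)
})

test_that("a panel coded with swapped alleles compares identically", {
  set.seed(15)
  p <- random_panel(n_samples = 3, n_variants = 40, miss_rate = 0)
  ## same genotypes expressed with A/B roles swapped at every variant
  v2 <- p$variants
  names(v2)[names(v2) == "allele_a"] <- "tmp"
  names(v2)[names(v2) == "allele_b"] <- "allele_a"
  names(v2)[names(v2) == "tmp"] <- "allele_b"
  q <- genotype_panel(v2, p$samples, 2L - p$calls)
  sh <- intersect_panels(p, q)
  for (s in p$samples) {
    r <- pairwise_concordance(sh, s, s)
    expect_equal(r$rate, 1)
  }
})

test_that("monomorphic records reconcile against polymorphic ones", {
  v1 <- data.frame(variant_id = "v1", chromosome = "1", position_bp = 100L,
                   allele_a = "A", allele_b = "G")
  p1 <- genotype_panel(v1, c("x", "y"), matrix(c(1L, 2L), 2, 1))  # A/G, G/G
  v2 <- v1; v2$allele_a <- "G"; v2$allele_b <- "0"                # only G seen
  p2 <- genotype_panel(v2, c("x", "y"), matrix(c(0L, 0L), 2, 1))
  sh <- intersect_panels(p1, p2)
  expect_equal(sh$map$orientation, "swapped")
  expect_equal(pairwise_concordance(sh, "y", "y")$rate, 1)  # G/G both sides
  expect_equal(pairwise_concordance(sh, "x", "x")$rate, 0)  # A/G vs G/G
})

test_that("construction keeps only data-supported allele labels", {
  v <- data.frame(variant_id = c("v1", "v2", "v3"), chromosome = "1",
                  position_bp = c(100L, 200L, 300L),
                  allele_a = "C", allele_b = "G")
  calls <- rbind(c(2L, 0L, NA), c(2L, 0L, NA))  # only G seen; only C; nothing
  p <- genotype_panel(v, c("a", "b"), calls)
  expect_equal(p$variants$allele_a, c("G", "C", "0"))
  expect_equal(p$variants$allele_b, c("0", "0", "0"))
  expect_equal(unname(p$calls[, 1]), c(0L, 0L))  # re-coded onto allele_a
})

test_that("manifest readers validate their schemas", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tbreed\tbatch\treplicate_group\tis_f1",
               "s1\tFM\tb1\t\tFALSE", "s2\tFM\tb1\tg1\tTRUE"), f)
  m <- read_sample_manifest(f)
  expect_equal(m$replicate_group, c("", "g1"))
  expect_equal(m$is_f1, c(FALSE, TRUE))

  writeLines(c("sample_id\tbreed", "s1\tFM"), f)
  expect_error(read_sample_manifest(f), "missing column")

  writeLines(c("sample_id_a\tpanel_a\tsample_id_b\tpanel_b\tscenario",
               "s1\taxiom\ts2\taxiom\tbad_label"), f)
  expect_error(read_pair_manifest(f), "unknown scenario")
})
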