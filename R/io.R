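#' Read a PLINK text PED/MAP pair
#'
#' Parses a whitespace-separated MAP (chromosome, variant id, cM, bp) and PED
#' (six leading columns, then two allele columns per variant). Allele codes
#' may be A/C/G/T or 1/2; `0` is the missing-allele code. Per variant the two
#' observed alleles become `allele_a`/`allele_b` (alphabetical order), and
#' each sample's allele pair is mapped to a call: both `allele_a` -> 0, both
#' `allele_b` -> 2, one of each -> 1 (order-insensitive), `0 0` -> NA.
#' Half-missing pairs (e.g. `A 0`) are treated as missing with a warning.
#' A third allele at a variant is an error naming the variant.
#'
#' @param ped_path path to the PED file
#' @param map_path path to the MAP file
#' @return a [genotype_panel()]; variants re-sorted by (chromosome, position)
#' @seealso [write_ped_map()]
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (length(nf) && any(nf != 4L)) {
    stop_parse("MAP line ", which(nf != 4L)[1], " has ", nf[nf != 4L][1],
               " columns; expected 4")
  }
  m <- if (length(map_fields)) do.call(rbind, map_fields) else
    matrix(character(), 0, 4)
  variants <- data.frame(
    variant_id = m[, 2], chromosome = m[, 1],
    position_bp = as.integer(m[, 4]),
    allele_a = "0", allele_b = "0",
    stringsAsFactors = FALSE
  )
  nv <- nrow(variants)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ns <- length(ped_lines)
  samples <- character(ns)
  a1 <- matrix("0", nrow = ns, ncol = nv)
  a2 <- matrix("0", nrow = ns, ncol = nv)
  for (i in seq_len(ns)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * nv) {
      stop_parse("PED line ", i, " has ", length(f), " fields; expected ",
                 6L + 2L * nv, " for ", nv, " variants")
    }
    samples[i] <- f[2]
    if (nv) {
      g <- f[-(1:6)]
      a1[i, ] <- g[seq(1L, 2L * nv, by = 2L)]
      a2[i, ] <- g[seq(2L, 2L * nv, by = 2L)]
    }
  }

  calls <- matrix(NA_integer_, nrow = ns, ncol = nv)
  half_missing <- 0L
  for (j in seq_len(nv)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    half <- xor(x1 == "0", x2 == "0")
    if (any(half)) {
      half_missing <- half_missing + sum(half)
      x1[half] <- "0"; x2[half] <- "0"
    }
    obs <- sort(unique(c(x1, x2)))
    obs <- obs[obs != "0"]
    if (length(obs) > 2L) {
      stop_data("variant ", variants$variant_id[j], " has ", length(obs),
                " distinct alleles (", paste(obs, collapse = ","), ")")
    }
    if (length(obs) >= 1L) variants$allele_a[j] <- obs[1]
    if (length(obs) == 2L) variants$allele_b[j] <- obs[2]
    called <- x1 != "0"
    calls[called, j] <- (x1[called] == variants$allele_b[j]) +
                        (x2[called] == variants$allele_b[j])
  }
  if (half_missing > 0L) {
    warning(half_missing, " half-missing genotype(s) treated as missing")
  }
  genotype_panel(variants, samples, calls)
}

#' Write a panel as a PLINK text PED/MAP pair
#'
#' The MAP carries (chromosome, variant id, 0 cM, bp); the PED uses the sample
#' id for both family and individual id, `0` for parents/sex and `-9` for the
#' phenotype. Missing calls are written `0 0`; heterozygotes as
#' `allele_a allele_b`. Files are re-readable by [read_ped_map()] with an
#' identical call matrix.
#'
#' @param panel a [genotype_panel()]
#' @param ped_path,map_path output paths
#' @return invisibly, the two paths
#' @export
write_ped_map <- function(panel, ped_path, map_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  v <- panel$variants
  map <- paste(v$chromosome, v$variant_id, 0L, v$position_bp, sep = "\t")
  writeLines(map, map_path)

  nv <- nrow(v)
  con <- file(ped_path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(panel$samples)) {
    g <- panel$calls[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2L, v$allele_b, v$allele_a))
    x2 <- ifelse(is.na(g), "0", ifelse(g == 0L, v$allele_a, v$allele_b))
    line <- paste(c(panel$samples[i], panel$samples[i], "0", "0", "0", "-9",
                    as.vector(rbind(x1, x2))), collapse = " ")
    writeLines(line, con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Keep only variants on admissible autosomes
#'
#' Drops variants on sex chromosomes, unplaced contigs, or any label not in
#' `autosome_labels` (SNPs without a known chromosomal position conventionally
#' carry chromosome "0"). Order of retained variants is preserved.
#'
#' @param panel a [genotype_panel()]
#' @param autosome_labels character vector of admissible chromosome labels;
#'   defaults to the horse autosomes "1".."31"
#' @return a filtered `genotype_panel`
#' @export
filter_autosomes <- function(panel, autosome_labels = horse_autosomes()) {
  stopifnot(inherits(panel, "genotype_panel"))
  keep <- panel$variants$chromosome %in% as.character(autosome_labels) &
    panel$variants$position_bp >= 1L
  if (!any(keep)) warning("no variants remain after autosome filtering")
  subset_panel(panel, variants = keep)
}

#' Read a sample manifest
#'
#' Headered TSV with columns `sample_id`, `breed`, `batch`,
#' `replicate_group` (empty string when the sample is not replicated) and
#' `is_f1` (TRUE/FALSE). Samples sharing a `replicate_group` are technical
#' replicates of one individual.
#'
#' @param path TSV path
#' @return data frame
#' @export
read_sample_manifest <- function(path) {
  m <- read_tsv_file(path)
  need <- c("sample_id", "breed", "batch", "replicate_group", "is_f1")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop_parse("sample manifest is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(m$sample_id)) stop_data("duplicate sample_id in manifest")
  m$sample_id <- as.character(m$sample_id)
  m$replicate_group[is.na(m$replicate_group)] <- ""
  m$is_f1 <- as.logical(m$is_f1)
  m
}

#' Read a replicate-pair manifest
#'
#' Headered TSV with columns `sample_id_a`, `panel_a`, `sample_id_b`,
#' `panel_b`, `scenario`; scenario is one of `same_batch`, `cross_batch`,
#' `cross_array`, `vs_wgs`.
#'
#' @param path TSV path
#' @return data frame
#' @export
read_pair_manifest <- function(path) {
  m <- read_tsv_file(path)
  need <- c("sample_id_a", "panel_a", "sample_id_b", "panel_b", "scenario")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop_parse("pair manifest is missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  ok <- m$scenario %in% c("same_batch", "cross_batch", "cross_array", "vs_wgs")
  if (!all(ok)) {
    stop_data("unknown scenario label(s): ",
              paste(unique(m$scenario[!ok]), collapse = ", "))
  }
  m
}
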