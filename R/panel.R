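#' Genotype panel
#'
#' The central container of the package: variant metadata plus a samples x
#' variants matrix of diploid biallelic genotype calls. Calls are stored as
#' the count of the B allele: `0` = homozygous A/A, `1` = heterozygous,
#' `2` = homozygous B/B, `NA` = missing. Variants are kept sorted by
#' (chromosome, position) with strictly increasing positions within each
#' chromosome, which the ROH scan relies on.
#'
#' Allele labels are normalised to what PLINK text files can represent:
#' `allele_a` sorts before `allele_b` alphabetically, and an allele label
#' never observed in any call is dropped to the missing code `"0"` (a
#' variant observed only for its B allele is re-coded onto A, flipping its
#' calls). A/B assignment in PED files is arbitrary and unobserved alleles
#' cannot be written, so this canonical form is exactly what
#' [read_ped_map()] recovers — making write-then-read an identity on the
#' call matrix for every valid panel.
#'
#' @param variants data frame with columns `variant_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`
#' @param samples character vector of unique sample ids
#' @param calls integer matrix, `length(samples)` rows x `nrow(variants)`
#'   columns, entries in `{0, 1, 2, NA}`
#' @return an object of class `genotype_panel`
#' @examples
#' v <- data.frame(variant_id = "snp1", chromosome = "1", position_bp = 1000L,
#'                 allele_a = "A", allele_b = "G")
#' p <- genotype_panel(v, "s1", matrix(2L, 1, 1))
#' n_variants(p)
#' @export
genotype_panel <- function(variants, samples, calls) {
  required <- c("variant_id", "chromosome", "position_bp", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop_data("variants is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  variants <- as.data.frame(variants)[required]
  variants$variant_id <- as.character(variants$variant_id)
  variants$chromosome <- as.character(variants$chromosome)
  variants$position_bp <- as.integer(variants$position_bp)
  variants$allele_a <- as.character(variants$allele_a)
  variants$allele_b <- as.character(variants$allele_b)
  samples <- as.character(samples)
  if (!is.matrix(calls)) calls <- matrix(as.integer(calls), nrow = length(samples))
  storage.mode(calls) <- "integer"

  if (anyDuplicated(samples)) stop_data("duplicate sample ids in panel")
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(variants)) {
    stop_data("call matrix is ", nrow(calls), " x ", ncol(calls),
              " but panel has ", length(samples), " samples and ",
              nrow(variants), " variants")
  }
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) stop_data("call codes must be 0, 1, 2 or NA")
  if (any(variants$position_bp < 1L, na.rm = TRUE)) {
    stop_data("position_bp must be >= 1")
  }

  ## normalise allele order: allele_a < allele_b; "0" sorts to allele_b
  a <- variants$allele_a
  b <- variants$allele_b
  flip <- (a == "0" & b != "0") | (b != "0" & a != "0" & a > b)
  if (any(flip)) {
    tmp <- a[flip]; variants$allele_a[flip] <- b[flip]; variants$allele_b[flip] <- tmp
    calls[, flip] <- 2L - calls[, flip]
  }
  same <- variants$allele_a == variants$allele_b & variants$allele_a != "0"
  if (any(same)) {
    stop_data("allele_a equals allele_b at variant ",
              variants$variant_id[which(same)[1]])
  }

  ## sort by chromosome then position, permuting calls consistently
  ord <- chrom_order(variants$chromosome)
  ord <- ord[order(match(variants$chromosome[ord], unique(variants$chromosome[ord])),
                   variants$position_bp[ord])]
  if (!identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  dup <- duplicated(paste(variants$chromosome, variants$position_bp))
  if (any(dup)) {
    warning("dropping ", sum(dup), " variant(s) at duplicated positions (keeping first)")
    variants <- variants[!dup, , drop = FALSE]
    calls <- calls[, !dup, drop = FALSE]
  }

  ## keep only data-supported allele labels, mirroring what PLINK text files
  ## can represent: an allele never observed in any call is dropped to "0",
  ## and a variant observed for allele_b alone is re-coded onto allele_a
  if (nrow(calls) > 0L) {
    seen_a <- colSums(calls == 0L | calls == 1L, na.rm = TRUE) > 0L
    seen_b <- colSums(calls == 2L | calls == 1L, na.rm = TRUE) > 0L
  } else {
    seen_a <- seen_b <- rep(FALSE, ncol(calls))
  }
  sw <- !seen_a & seen_b
  if (any(sw)) {
    variants$allele_a[sw] <- variants$allele_b[sw]
    calls[, sw] <- 2L - calls[, sw]
  }
  variants$allele_b[!seen_b | sw] <- "0"
  variants$allele_a[!seen_a & !seen_b] <- "0"
  rownames(variants) <- NULL
  dimnames(calls) <- list(samples, variants$variant_id)

  structure(list(variants = variants, samples = samples, calls = calls),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel: ", length(x$samples), " samples x ",
      nrow(x$variants), " variants on ",
      length(unique(x$variants$chromosome)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call fraction: %.4f\n", miss))
  invisible(x)
}

#' Number of samples / variants in a panel
#' @param panel a `genotype_panel`
#' @return integer count
#' @export
n_samples <- function(panel) length(panel$samples)

#' @rdname n_samples
#' @export
n_variants <- function(panel) nrow(panel$variants)

#' Subset a panel by samples and/or variants
#'
#' @param panel a `genotype_panel`
#' @param samples character vector of sample ids to keep (default all)
#' @param variants character vector of variant ids, or logical/integer index
#'   over variant columns (default all)
#' @return a `genotype_panel`
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- seq_along(panel$samples)
  if (!is.null(samples)) {
    si <- match(samples, panel$samples)
    if (anyNA(si)) stop_data("unknown sample id(s): ",
                             paste(samples[is.na(si)], collapse = ", "))
  }
  vi <- seq_len(n_variants(panel))
  if (!is.null(variants)) {
    if (is.character(variants)) {
      vi <- which(panel$variants$variant_id %in% variants)
    } else {
      vi <- seq_len(n_variants(panel))[variants]
    }
  }
  genotype_panel(panel$variants[vi, , drop = FALSE],
                 panel$samples[si],
                 panel$calls[si, vi, drop = FALSE])
}

#' Default horse autosome labels
#'
#' Chromosome labels "1" through "31" (Equus caballus autosomes).
#' @return character vector
#' @export
horse_autosomes <- function() as.character(1:31)
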