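#' Intersect two genotype panels by genomic position
#'
#' Matches variants across platforms by (chromosome, position_bp) and records
#' how the allele pairs line up:
#' \describe{
#'   \item{same}{allele_a/allele_b identical (up to missing "0" codes)}
#'   \item{swapped}{A/B assignment reversed between the panels; calls on side
#'     b must be remapped `0 <-> 2` before comparison}
#'   \item{ambiguous}{strand-ambiguous A/T or C/G variant; a strand flip is
#'     indistinguishable from an allele swap, so these are excluded from
#'     comparison by default}
#'   \item{incompatible}{allele sets cannot be reconciled}
#' }
#' Only `same` and `swapped` pairs enter downstream concordance
#' (`compared = TRUE`).
#'
#' @param panel_a,panel_b [genotype_panel()] objects
#' @return object of class `shared_panel`: a list with the two panels and a
#'   `map` data frame (idx_a, idx_b, chromosome, position_bp, orientation,
#'   compared)
#' @export
intersect_panels <- function(panel_a, panel_b) {
  stopifnot(inherits(panel_a, "genotype_panel"), inherits(panel_b, "genotype_panel"))
  key_a <- paste(panel_a$variants$chromosome, panel_a$variants$position_bp)
  key_b <- paste(panel_b$variants$chromosome, panel_b$variants$position_bp)
  idx_b <- match(key_a, key_b)
  idx_a <- which(!is.na(idx_b))
  idx_b <- idx_b[idx_a]

  va <- panel_a$variants[idx_a, , drop = FALSE]
  vb <- panel_b$variants[idx_b, , drop = FALSE]

  ## Alleles are normalised within each panel (allele_a < allele_b, "0" last),
  ## so a pair of fully-known biallelic records is either same-order or
  ## incompatible: an A/B swap in the source files was already folded into the
  ## call codes at construction. "swapped" arises when one side is monomorphic
  ## and its single observed allele is the other side's allele_b.
  orientation <- rep("incompatible", length(idx_a))
  aA <- va$allele_a; aB <- va$allele_b
  bA <- vb$allele_a; bB <- vb$allele_b
  full <- aB != "0" & bB != "0"
  orientation[full & aA == bA & aB == bB] <- "same"
  mono_b <- aB != "0" & bB == "0" & bA != "0"
  orientation[mono_b & bA == aA] <- "same"
  orientation[mono_b & bA == aB] <- "swapped"
  mono_a <- aB == "0" & bB != "0" & aA != "0"
  orientation[mono_a & aA == bA] <- "same"
  orientation[mono_a & aA == bB] <- "swapped"
  both_mono <- aB == "0" & bB == "0"
  orientation[both_mono & (aA == bA | aA == "0" | bA == "0")] <- "same"

  pair_at <- function(v) paste0(pmin(v$allele_a, v$allele_b), pmax(v$allele_a, v$allele_b))
  amb <- pair_at(va) %in% c("AT", "CG") & orientation %in% c("same", "swapped")
  orientation[amb] <- "ambiguous"

  map <- data.frame(
    variant_id_a = va$variant_id, variant_id_b = vb$variant_id,
    idx_a = idx_a, idx_b = idx_b,
    chromosome = va$chromosome, position_bp = va$position_bp,
    orientation = orientation,
    compared = orientation %in% c("same", "swapped"),
    stringsAsFactors = FALSE
  )
  structure(list(panel_a = panel_a, panel_b = panel_b, map = map),
            class = "shared_panel")
}

#' @export
print.shared_panel <- function(x, ...) {
  cat("shared_panel: ", nrow(x$map), " position-matched variants (",
      sum(x$map$compared), " comparable)\n", sep = "")
  print(table(x$map$orientation))
  invisible(x)
}

#' Reconciled call vectors for one sample from each side of a shared panel
#'
#' Returns the two call vectors over the comparable variants, with side-b
#' calls of swapped pairs remapped `0 <-> 2` so that codes refer to the same
#' allele on both sides.
#'
#' @param shared a `shared_panel`
#' @param sample_a,sample_b sample ids in panel_a / panel_b
#' @return list with integer vectors `a` and `b`
#' @keywords internal
reconciled_calls <- function(shared, sample_a, sample_b) {
  ia <- match(sample_a, shared$panel_a$samples)
  ib <- match(sample_b, shared$panel_b$samples)
  if (is.na(ia)) stop_data("unknown sample id in panel_a: ", sample_a)
  if (is.na(ib)) stop_data("unknown sample id in panel_b: ", sample_b)
  m <- shared$map[shared$map$compared, , drop = FALSE]
  a <- shared$panel_a$calls[ia, m$idx_a]
  b <- shared$panel_b$calls[ib, m$idx_b]
  sw <- m$orientation == "swapped"
  b[sw] <- 2L - b[sw]
  list(a = a, b = b)
}
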