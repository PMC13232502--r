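#' ROH detection settings
#'
#' Bundles the parameters of the run-of-homozygosity scan. A detected segment
#' must satisfy all four final constraints: `length_kb >= min_length_kb`,
#' homozygous-SNP count strictly greater than `min_snps`, average spacing
#' `length_kb / n_snps <= max_density_kb_per_snp`, and no internal inter-SNP
#' gap above `max_gap_kb`. The heterozygous/missing allowances `max_het` /
#' `max_miss` apply either per scanning window (`allowance_scope = "window"`,
#' the PLINK-compatible reading and the default) or per emitted segment
#' (`"segment"`, the reading under which the allowances literally cap the
#' het/missing content of each run).
#'
#' @param name label for reports
#' @param min_length_kb minimum segment length in kb
#' @param min_snps segment must contain strictly more than this many
#'   homozygous SNPs
#' @param max_density_kb_per_snp maximum kb per homozygous SNP in a segment
#' @param max_gap_kb maximum gap between consecutive SNPs inside a segment
#' @param max_het maximum heterozygous calls allowed (per window or segment)
#' @param max_miss maximum missing calls allowed (per window or segment)
#' @param allowance_scope `"window"` or `"segment"`
#' @param window_snps scanning-window size in SNPs (window scope only)
#' @param window_threshold minimum fraction of homozygous windows covering a
#'   SNP for it to enter a candidate run, in (0, 1]
#' @return object of class `roh_settings`
#' @seealso [get_preset()] for the strict/medium/relaxed presets
#' @export
roh_settings <- function(name, min_length_kb, min_snps, max_density_kb_per_snp,
                         max_gap_kb, max_het, max_miss,
                         allowance_scope = c("window", "segment"),
                         window_snps = 50L, window_threshold = 0.05) {
  allowance_scope <- match.arg(allowance_scope)
  stopifnot(min_length_kb > 0, min_snps > 0, max_density_kb_per_snp > 0,
            max_gap_kb > 0, max_het >= 0, max_miss >= 0, window_snps >= 1,
            window_threshold > 0, window_threshold <= 1)
  structure(list(
    name = as.character(name),
    min_length_kb = as.numeric(min_length_kb),
    min_snps = as.integer(min_snps),
    max_density_kb_per_snp = as.numeric(max_density_kb_per_snp),
    max_gap_kb = as.numeric(max_gap_kb),
    max_het = as.integer(max_het),
    max_miss = as.integer(max_miss),
    allowance_scope = allowance_scope,
    window_snps = as.integer(window_snps),
    window_threshold = as.numeric(window_threshold)
  ), class = "roh_settings")
}

#' @export
print.roh_settings <- function(x, ...) {
  cat(sprintf(
    "roh_settings '%s': >=%g kb, >%d hom SNPs, <=%g kb/SNP, gap <=%g kb, het <=%d, miss <=%d (%s scope",
    x$name, x$min_length_kb, x$min_snps, x$max_density_kb_per_snp,
    x$max_gap_kb, x$max_het, x$max_miss, x$allowance_scope))
  if (x$allowance_scope == "window") {
    cat(sprintf(", window %d SNPs, threshold %g", x$window_snps, x$window_threshold))
  }
  cat(")\n")
  invisible(x)
}

.roh_presets <- list(
  strict  = list(min_length_kb = 500, min_snps = 80L,
                 max_density_kb_per_snp = 50, max_gap_kb = 100,
                 max_het = 1L, max_miss = 1L),
  medium  = list(min_length_kb = 300, min_snps = 50L,
                 max_density_kb_per_snp = 50, max_gap_kb = 100,
                 max_het = 1L, max_miss = 2L),
  relaxed = list(min_length_kb = 300, min_snps = 30L,
                 max_density_kb_per_snp = 50, max_gap_kb = 150,
                 max_het = 2L, max_miss = 4L)
)

#' Standard ROH setting presets
#'
#' Three widely used equine parameter regimes:
#' \describe{
#'   \item{strict}{500 kb minimum length, more than 80 homozygous SNPs, one
#'     SNP per 50 kb density, 100 kb gap, up to 1 het and 1 missing call}
#'   \item{medium}{300 kb, more than 50 SNPs, 50 kb/SNP, 100 kb gap, 1 het,
#'     2 missing}
#'   \item{relaxed}{300 kb, more than 30 SNPs, 50 kb/SNP, 150 kb gap, 2 het,
#'     4 missing}
#' }
#' The name is matched case-insensitively. The window size (50 SNPs) and hit
#' threshold (0.05) are the PLINK defaults and are not part of the published
#' regimes; override them here if needed.
#'
#' @param name one of `"strict"`, `"medium"`, `"relaxed"` (any case)
#' @inheritParams roh_settings
#' @return an [roh_settings()] object
#' @examples
#' get_preset("strict")
#' get_preset("Relaxed", allowance_scope = "segment")
#' @export
get_preset <- function(name, allowance_scope = c("window", "segment"),
                       window_snps = 50L, window_threshold = 0.05) {
  key <- tolower(as.character(name))
  if (length(key) != 1L || !key %in% names(.roh_presets)) {
    stop_config("unknown ROH preset '", name, "'; valid names: ",
                paste(names(.roh_presets), collapse = ", "))
  }
  p <- .roh_presets[[key]]
  roh_settings(name = key, min_length_kb = p$min_length_kb,
               min_snps = p$min_snps,
               max_density_kb_per_snp = p$max_density_kb_per_snp,
               max_gap_kb = p$max_gap_kb, max_het = p$max_het,
               max_miss = p$max_miss,
               allowance_scope = match.arg(allowance_scope),
               window_snps = window_snps, window_threshold = window_threshold)
}
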