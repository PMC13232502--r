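#' Per-sample ROH summary statistics
#'
#' Collapses detected segments into the four standard per-sample statistics:
#' `n_roh` (segment count), `s_roh_kb` (summed length), `l_roh_kb` (mean
#' length, 0 when there are no segments) and the genomic inbreeding
#' coefficient `f_roh = s_roh_kb / l_auto_kb`, where `l_auto_kb` is the
#' length of the autosomal genome covered by the panel.
#'
#' @param segments segment data frame from [detect_roh()]
#' @param l_auto_kb autosomal genome length in kb; the horse value is
#'   `horse_l_auto_kb()` (2,280.92 Mb), simulated genomes carry their own
#' @param samples optional character vector of sample ids that must appear in
#'   the summary; samples without segments get an all-zero row. Defaults to
#'   the samples present in `segments`.
#' @return data frame with sample_id, n_roh, s_roh_kb, l_roh_kb, f_roh
#' @export
summarize_roh <- function(segments, l_auto_kb, samples = NULL) {
  if (!is.numeric(l_auto_kb) || length(l_auto_kb) != 1L || l_auto_kb <= 0) {
    stop_config("l_auto_kb must be a single positive number")
  }
  if (is.null(samples)) samples <- unique(segments$sample_id)
  n_roh <- integer(length(samples))
  s_roh <- numeric(length(samples))
  if (nrow(segments)) {
    tab <- table(factor(segments$sample_id, levels = samples))
    n_roh <- as.integer(tab)
    s <- tapply(segments$length_kb, factor(segments$sample_id, levels = samples), sum)
    s_roh <- ifelse(is.na(s), 0, as.numeric(s))
  }
  f_roh <- s_roh / l_auto_kb
  if (any(f_roh > 1)) {
    stop_data("f_roh > 1 for sample(s) ",
              paste(samples[f_roh > 1], collapse = ", "),
              ": segments exceed the stated genome length")
  }
  data.frame(
    sample_id = as.character(samples),
    n_roh = n_roh,
    s_roh_kb = s_roh,
    l_roh_kb = ifelse(n_roh > 0L, s_roh / pmax(n_roh, 1L), 0),
    f_roh = f_roh,
    stringsAsFactors = FALSE
  )
}

#' Horse autosomal genome length in kb
#'
#' The EquCab3.0 autosomal genome length, 2,280.92 Mb, expressed in kb — the
#' denominator of F_ROH for equine array data.
#' @return numeric scalar (2,280,920 kb)
#' @export
horse_l_auto_kb <- function() 2280920
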