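#' Detect runs of homozygosity
#'
#' Scans each sample's autosomal calls chromosome by chromosome and returns
#' homozygous segments under the given [roh_settings()].
#'
#' With `allowance_scope = "window"` (PLINK-compatible overlapping-window
#' scan): a window of `window_snps` consecutive SNPs is homozygous when it
#' contains at most `max_het` heterozygous and `max_miss` missing calls; each
#' SNP's hit fraction is the proportion of homozygous windows among the
#' windows covering it; SNPs at or above `window_threshold` form candidate
#' runs, runs are split wherever the inter-SNP gap exceeds `max_gap_kb`, and
#' each run is trimmed to start and end on a homozygous call. On a chromosome
#' with fewer SNPs than `window_snps` the whole chromosome acts as the single
#' window. Emitted window-scope segments may contain more than `max_het`
#' heterozygous calls in total — the allowance is a window property, which is
#' the behaviour of the PLINK flags this mode mirrors.
#'
#' With `allowance_scope = "segment"` the het/missing allowances cap each
#' emitted segment: the scan finds every maximal run whose het and missing
#' counts stay within the allowances and whose internal gaps stay within
#' `max_gap_kb`; when two maximal candidate runs overlap (each spending the
#' allowance differently), the leftmost is kept, so reported segments never
#' overlap.
#'
#' In both modes a run is emitted only if `length_kb >= min_length_kb`, it
#' contains strictly more than `min_snps` homozygous SNPs (heterozygous and
#' missing calls never count towards `n_snps`), and
#' `length_kb / n_snps <= max_density_kb_per_snp` evaluated on the final
#' trimmed segment. Lengths are 1-based inclusive:
#' `length_kb = (end_bp - start_bp + 1) / 1000`.
#'
#' @param panel an autosome-filtered, position-sorted [genotype_panel()]
#' @param settings an [roh_settings()] object (see [get_preset()])
#' @param samples sample ids to scan (default: all samples in the panel)
#' @return data frame of segments: sample_id, chromosome, start_bp, end_bp,
#'   length_kb, n_snps, n_het, n_miss; zero rows when no segment qualifies
#' @examples
#' pos <- seq(10000L, 1000000L, by = 10000L)
#' v <- data.frame(variant_id = paste0("snp", seq_along(pos)), chromosome = "1",
#'                 position_bp = pos, allele_a = "A", allele_b = "G")
#' p <- genotype_panel(v, "s1", matrix(0L, 1, length(pos)))
#' detect_roh(p, get_preset("strict"))  # one 990.001-kb segment of 100 SNPs
#' @export
detect_roh <- function(panel, settings, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(settings, "roh_settings"))
  if (is.null(samples)) samples <- panel$samples
  idx <- match(samples, panel$samples)
  if (anyNA(idx)) stop_data("unknown sample id(s): ",
                            paste(samples[is.na(idx)], collapse = ", "))
  chrom <- panel$variants$chromosome
  pos <- panel$variants$position_bp
  chrom_runs <- rle(chrom)
  ends <- cumsum(chrom_runs$lengths)
  starts <- ends - chrom_runs$lengths + 1L

  out <- list()
  for (s in seq_along(idx)) {
    g_all <- panel$calls[idx[s], ]
    for (ci in seq_along(starts)) {
      rng <- starts[ci]:ends[ci]
      segs <- if (settings$allowance_scope == "window") {
        roh_scan_window(g_all[rng], pos[rng], settings)
      } else {
        roh_scan_segment(g_all[rng], pos[rng], settings)
      }
      if (!is.null(segs) && nrow(segs)) {
        segs$sample_id <- samples[s]
        segs$chromosome <- chrom_runs$values[ci]
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  cols <- c("sample_id", "chromosome", "start_bp", "end_bp", "length_kb",
            "n_snps", "n_het", "n_miss")
  if (!length(out)) {
    return(data.frame(sample_id = character(), chromosome = character(),
                      start_bp = integer(), end_bp = integer(),
                      length_kb = numeric(), n_snps = integer(),
                      n_het = integer(), n_miss = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)[, cols]
  rownames(res) <- NULL
  res
}

## Shared final filter + segment assembly from index bounds (i, j inclusive).
roh_emit <- function(bounds, g, pos, settings) {
  if (!length(bounds)) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  chom <- cumsum(hom); chet <- cumsum(het); cmis <- cumsum(mis)
  cs <- function(cum, i, j) cum[j] - if (i > 1L) cum[i - 1L] else 0L
  rows <- lapply(bounds, function(b) {
    i <- b[1]; j <- b[2]
    len_kb <- (pos[j] - pos[i] + 1) / 1000
    nh <- cs(chom, i, j)
    if (len_kb < settings$min_length_kb) return(NULL)
    if (nh <= settings$min_snps) return(NULL)
    if (len_kb / nh > settings$max_density_kb_per_snp) return(NULL)
    data.frame(start_bp = pos[i], end_bp = pos[j], length_kb = len_kb,
               n_snps = nh, n_het = cs(chet, i, j), n_miss = cs(cmis, i, j),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

## Window-scope scan of one sample-chromosome. Returns segment rows or NULL.
roh_scan_window <- function(g, pos, settings) {
  n <- length(g)
  if (n == 0L) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  w <- min(settings$window_snps, n)
  nwin <- n - w + 1L
  chet <- c(0L, cumsum(het)); cmis <- c(0L, cumsum(mis))
  wi <- seq_len(nwin)
  hom_win <- (chet[wi + w] - chet[wi]) <= settings$max_het &
             (cmis[wi + w] - cmis[wi]) <= settings$max_miss
  chw <- c(0L, cumsum(hom_win))
  k <- seq_len(n)
  lo <- pmax(1L, k - w + 1L)
  hi <- pmin(nwin, k)
  frac <- (chw[hi + 1L] - chw[lo]) / (hi - lo + 1L)
  cand <- frac >= settings$window_threshold

  ci <- which(cand)
  if (!length(ci)) return(NULL)
  gap_bp <- settings$max_gap_kb * 1000
  ## new run when candidate indices are non-consecutive or the gap is too wide
  brk <- c(TRUE, diff(ci) > 1L | (pos[ci[-1]] - pos[ci[-length(ci)]]) > gap_bp)
  run_id <- cumsum(brk)
  bounds <- lapply(split(ci, run_id), function(kk) {
    hh <- kk[hom[kk]]
    if (!length(hh)) return(NULL)
    c(hh[1], hh[length(hh)])
  })
  bounds <- bounds[!vapply(bounds, is.null, logical(1))]
  roh_emit(bounds, g, pos, settings)
}

## Segment-scope scan of one sample-chromosome: maximal runs within the
## het/miss allowances, leftmost-first on overlap. Returns rows or NULL.
roh_scan_segment <- function(g, pos, settings) {
  n <- length(g)
  if (n == 0L) return(NULL)
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  hom <- !het & !mis
  gap_bp <- settings$max_gap_kb * 1000
  min_bp <- settings$min_length_kb * 1000
  chom <- c(0L, cumsum(hom))

  ## blocks delimited by over-wide gaps; no segment may span a block boundary
  blk_start <- c(1L, which(diff(pos) > gap_bp) + 1L)
  blk_end <- c(blk_start[-1L] - 1L, n)

  ## farthest right end J[i] staying within the allowances and the gap block:
  ## cumulative het/miss counts are nondecreasing, so the allowance frontier
  ## is a findInterval lookup rather than a pointer walk
  chet <- c(0L, cumsum(het)); cmis <- c(0L, cumsum(mis))
  i_all <- seq_len(n)
  j_het <- findInterval(chet[i_all] + settings$max_het, chet[-1L])
  j_mis <- findInterval(cmis[i_all] + settings$max_miss, cmis[-1L])
  J <- pmin(j_het, j_mis, blk_end[findInterval(i_all, blk_start)])

  ## only starts whose reachable span can meet the length minimum matter
  starts <- which(hom & J >= i_all & (pos[pmax(J, 1L)] - pos + 1) >= min_bp)
  hpos <- which(hom)
  hrank <- cumsum(hom)   # hrank[x] = number of hom calls at or before x

  bounds <- list()
  best_end <- 0L
  for (i in starts) {
    ji <- J[i]
    if (ji <= best_end) next                  # contained in an earlier maximal run
    k <- hrank[ji]                            # scan hom ends right-to-left
    while (k >= hrank[i]) {
      j <- hpos[k]
      if (j < i || pos[j] - pos[i] + 1 < min_bp) break  # shrinking only shortens
      nh <- chom[j + 1L] - chom[i]
      if (nh > settings$min_snps &&
          (pos[j] - pos[i] + 1) / 1000 / nh <= settings$max_density_kb_per_snp) {
        ## j is the largest qualifying end for start i; unless it pushes past
        ## the frontier the interval is contained in an earlier maximal run
        if (j > best_end) {
          bounds[[length(bounds) + 1L]] <- c(i, j)
          best_end <- j
        }
        break
      }
      k <- k - 1L
    }
  }
  if (!length(bounds)) return(NULL)
  ## greedy non-overlap: keep the leftmost of any overlapping maximal runs
  kept <- list(); last_end <- 0L
  for (bd in bounds) {
    if (bd[1] > last_end) { kept[[length(kept) + 1L]] <- bd; last_end <- bd[2] }
  }
  roh_emit(kept, g, pos, settings)
}
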