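#' Replicate-pair genotype concordance
#'
#' Compares the genotype calls of two samples over the comparable variants of
#' a shared panel, restricted to calls present (non-missing) in both — the
#' semantics of PLINK's merge-mode 6. Disagreements where one side is missing
#' are excluded entirely, not counted as discordant. No call-rate or allele
#' frequency filter is applied here; variant-set filtering enters only through
#' [concordance_report()]'s `snp_subset`.
#'
#' @param shared a `shared_panel` from [intersect_panels()] (a panel compared
#'   against itself is the common same-platform case)
#' @param sample_a sample id in `shared$panel_a`
#' @param sample_b sample id in `shared$panel_b`
#' @return data frame with one row: `n_shared_variants` (comparable variants),
#'   `n_both_called`, `n_concordant` and `rate` = n_concordant / n_both_called
#'   (`NA` when nothing is called on both sides)
#' @export
pairwise_concordance <- function(shared, sample_a, sample_b) {
  stopifnot(inherits(shared, "shared_panel"))
  cc <- reconciled_calls(shared, sample_a, sample_b)
  n_shared <- length(cc$a)
  both <- !is.na(cc$a) & !is.na(cc$b)
  n_both <- sum(both)
  n_conc <- sum(cc$a[both] == cc$b[both])
  if (n_shared == 0L) warning("no comparable variants shared by the two panels")
  data.frame(
    sample_id_a = sample_a, sample_id_b = sample_b,
    n_shared_variants = n_shared,
    n_both_called = n_both,
    n_concordant = n_conc,
    rate = if (n_both > 0L) n_conc / n_both else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Concordance report over a pair manifest
#'
#' Computes [pairwise_concordance()] for every pair in the manifest, once on
#' the full shared variant set and, if `snp_subset` is given, once restricted
#' to that variant-id set (e.g. the recommended subset from [classify_snps()]).
#' Rows are ordered by `order_by` (typically each sample's strict-setting
#' N_ROH) and pairs referencing absent samples are skipped with a warning.
#'
#' @param panels named list of [genotype_panel()] objects; names must cover
#'   the `panel_a` / `panel_b` labels of the manifest
#' @param pairs pair manifest data frame (see [read_pair_manifest()])
#' @param snp_subset optional character vector of variant ids defining the
#'   filtered condition
#' @param order_by optional named numeric vector (by sample id) used to sort
#'   rows increasingly, mirroring an N_ROH-ordered presentation
#' @return data frame with columns pair_id, scenario, snp_set
#'   ("full"/"filtered"), the count columns of [pairwise_concordance()] and
#'   `rate`
#' @export
concordance_report <- function(panels, pairs, snp_subset = NULL,
                               order_by = NULL) {
  stopifnot(is.list(panels), !is.null(names(panels)))
  conditions <- list(full = NULL)
  if (!is.null(snp_subset)) conditions$filtered <- snp_subset

  shared_cache <- list()
  get_shared <- function(la, lb, subset) {
    key <- paste(la, lb, if (is.null(subset)) "full" else "filtered", sep = "\r")
    if (!is.null(shared_cache[[key]])) return(shared_cache[[key]])
    pa <- panels[[la]]; pb <- panels[[lb]]
    if (is.null(pa) || is.null(pb)) return(NULL)
    if (!is.null(subset)) {
      pa <- subset_panel(pa, variants = intersect(pa$variants$variant_id, subset))
      pb <- subset_panel(pb, variants = intersect(pb$variants$variant_id, subset))
    }
    sh <- intersect_panels(pa, pb)
    shared_cache[[key]] <<- sh
    sh
  }

  out <- list()
  for (cond in names(conditions)) {
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      sh <- get_shared(p$panel_a, p$panel_b, conditions[[cond]])
      if (is.null(sh)) {
        warning("pair ", i, ": unknown panel label; skipped")
        next
      }
      if (!(p$sample_id_a %in% sh$panel_a$samples) ||
          !(p$sample_id_b %in% sh$panel_b$samples)) {
        warning("pair ", p$sample_id_a, "/", p$sample_id_b,
                ": sample absent from panel; skipped")
        next
      }
      r <- pairwise_concordance(sh, p$sample_id_a, p$sample_id_b)
      r <- cbind(
        data.frame(pair_id = paste(p$sample_id_a, p$sample_id_b, sep = ":"),
                   scenario = p$scenario, snp_set = cond,
                   stringsAsFactors = FALSE),
        r
      )
      out[[length(out) + 1L]] <- r
    }
  }
  if (!length(out)) {
    return(data.frame(pair_id = character(), scenario = character(),
                      snp_set = character(), sample_id_a = character(),
                      sample_id_b = character(),
                      n_shared_variants = integer(), n_both_called = integer(),
                      n_concordant = integer(), rate = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(order_by)) {
    key <- order_by[res$sample_id_a]
    key[is.na(key)] <- Inf
    res <- res[order(res$snp_set, res$scenario, key, res$pair_id), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

#' Per-variant discordance counts for a set of pairs (diagnostic)
#'
#' For each comparable variant, counts across all resolvable pairs how often
#' the two calls were both present and how often they disagreed.
#'
#' @inheritParams concordance_report
#' @return data frame with variant_id, n_both_called, n_discordant
#' @export
variant_discordance <- function(panels, pairs) {
  parts <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    pa <- panels[[p$panel_a]]; pb <- panels[[p$panel_b]]
    if (is.null(pa) || is.null(pb)) next
    if (!(p$sample_id_a %in% pa$samples) || !(p$sample_id_b %in% pb$samples)) next
    sh <- intersect_panels(pa, pb)
    cc <- reconciled_calls(sh, p$sample_id_a, p$sample_id_b)
    both <- !is.na(cc$a) & !is.na(cc$b)
    parts[[length(parts) + 1L]] <- data.frame(
      variant_id = sh$map$variant_id_a[sh$map$compared],
      both = as.integer(both),
      disc = as.integer(both & cc$a != cc$b),
      stringsAsFactors = FALSE
    )
  }
  if (!length(parts)) {
    return(data.frame(variant_id = character(), n_both_called = integer(),
                      n_discordant = integer(), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, parts)
  agg <- rowsum(all[c("both", "disc")], group = all$variant_id)
  data.frame(variant_id = rownames(agg),
             n_both_called = as.integer(agg$both),
             n_discordant = as.integer(agg$disc),
             stringsAsFactors = FALSE)
}
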