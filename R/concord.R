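#' Pair differentially expressed piRNAs with the DE genes they map to
#'
#' Emits one pair per (significant piRNA, significant gene) where the
#' piRNA's genic assignment targets that gene; by default only antisense
#' piRNAs are paired. Gene ids present in assignments but absent from the
#' gene table are skipped and tallied in the `skipped_genes` attribute.
#'
#' @param pirna_de piRNA DE table (`feature_id`, `log2fc`, `direction`).
#' @param assignments table from [assign_categories()] (genic rows used).
#' @param gene_de gene DE table (`gene_id`, `log2fc`, `q`, and a
#'   `direction` column whose value `"ns"` marks non-significant genes).
#' @param sense_filter `"antisense"` (default), `"sense"` or `"both"`.
#' @param collapse_targets when `TRUE`, keep only one pair per piRNA (its
#'   largest-|gene log2fc| target) instead of one per target gene.
#' @return a `data.table` of pairs: `pirna_id`, `gene_id`, `pirna_log2fc`,
#'   `gene_log2fc`, `pirna_sense`, deterministically ordered.
#' @export
antisense_pairs <- function(pirna_de, assignments, gene_de,
                            sense_filter = c("antisense", "sense", "both"),
                            collapse_targets = FALSE) {
  sense_filter <- match.arg(sense_filter)
  pe <- as.data.table(pirna_de)
  ge <- as.data.table(gene_de)
  as_ <- as.data.table(assignments)[category == "genic" & !is.na(target_id)]
  if (sense_filter != "both") as_ <- as_[sense == sense_filter]
  sig_p <- pe[direction != "ns"]
  sig_g <- ge[direction != "ns"]
  cand <- merge(as_[, .(pirna_id = read_id, gene_id = target_id,
                        pirna_sense = sense)],
                sig_p[, .(pirna_id = feature_id, pirna_log2fc = log2fc)],
                by = "pirna_id")
  known <- cand$gene_id %in% ge$gene_id
  skipped <- sum(!known)
  if (skipped > 0) {
    message("antisense_pairs: skipped ", skipped,
            " pair(s) whose gene id is absent from the gene DE table")
  }
  cand <- cand[known]
  pairs <- merge(cand, sig_g[, .(gene_id, gene_log2fc = log2fc)],
                 by = "gene_id")
  setcolorder(pairs, c("pirna_id", "gene_id", "pirna_log2fc", "gene_log2fc",
                       "pirna_sense"))
  setorder(pairs, pirna_id, gene_id)
  if (collapse_targets && nrow(pairs) > 0L) {
    setorder(pairs, pirna_id, -abs(gene_log2fc), gene_id)
    pairs <- pairs[, .SD[1L], by = pirna_id]
    setorder(pairs, pirna_id, gene_id)
  }
  setattr(pairs, "skipped_genes", skipped)
  pairs[]
}

#' Quadrant counts and the headline concordance fraction
#'
#' Classifies each pair by the signs of the gene and piRNA fold changes and
#' reports, among piRNA-down pairs, the share whose gene is upregulated,
#' with an exact binomial confidence interval. Pairs with a zero fold
#' change on either axis are excluded and tallied.
#'
#' @param pairs table from [antisense_pairs()].
#' @param conf_level confidence level for the exact interval.
#' @return a list: `quadrants` (one-row table `n_uu`, `n_ud`, `n_du`,
#'   `n_dd`; gene direction first, piRNA direction second), `n_zero`,
#'   `headline` (fraction, CI bounds and pair count).
#' @export
quadrant_counts <- function(pairs, conf_level = 0.95) {
  p <- as.data.table(pairs)
  if (nrow(p) == 0L) stop("no pairs to classify", call. = FALSE)
  nz <- p[gene_log2fc != 0 & pirna_log2fc != 0]
  n_zero <- nrow(p) - nrow(nz)
  quad <- data.table(
    n_uu = nz[gene_log2fc > 0 & pirna_log2fc > 0, .N],
    n_ud = nz[gene_log2fc > 0 & pirna_log2fc < 0, .N],
    n_du = nz[gene_log2fc < 0 & pirna_log2fc > 0, .N],
    n_dd = nz[gene_log2fc < 0 & pirna_log2fc < 0, .N]
  )
  n_down <- quad$n_ud + quad$n_dd
  if (n_down > 0) {
    bt <- binom.test(quad$n_ud, n_down, conf.level = conf_level)
    headline <- data.frame(fraction_gene_up = quad$n_ud / n_down,
                           ci_lo = bt$conf.int[1], ci_hi = bt$conf.int[2],
                           n_pirna_down_pairs = n_down)
  } else {
    headline <- data.frame(fraction_gene_up = NA_real_, ci_lo = NA_real_,
                           ci_hi = NA_real_, n_pirna_down_pairs = 0L)
  }
  list(quadrants = quad[], n_zero = n_zero, headline = headline)
}
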