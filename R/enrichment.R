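# Per-motif yes/no enrichment of binding-site occurrences: occurrence counts
# in the promoters of upregulated ("yes") genes versus background ("no")
# genes, the pseudocounted occurrences-per-promoter ratio, and an exact
# binomial tail p-value under a length-proportional null.

#' Per-motif enrichment of site occurrences in yes vs no promoters
#'
#' For each motif, with `k = occ_yes` occurrences among `n = occ_yes +
#' occ_no` total and null success probability `p0` (the yes share of
#' scannable positions, or of promoters under the per-promoter null),
#' computes the upper binomial tail `P[Bin(n, p0) >= k]` by exact summation,
#' the Haldane-Anscombe-pseudocounted occurrences-per-promoter ratio, and a
#' BH adjustment across motifs.
#'
#' @param hits A `hit_table` from [scan_all()] (its `offsets` attribute
#'   supplies scannable-position totals).
#' @param yes_genes,no_genes Disjoint character vectors of gene ids; both
#'   must intersect the scanned promoter universe.
#' @param null_model `"length"` (default): occurrences split between yes and
#'   no proportionally to scannable length; `"promoter"`: proportionally to
#'   promoter counts.
#' @return data.frame of class `enrichment_result`, one row per motif,
#'   sorted by `p_binom` then decreasing ratio: columns `motif_id`,
#'   `tf_name`, `occ_yes`, `occ_no`, `n_yes`, `n_no`, `L_yes`, `L_no`,
#'   `ratio`, `p_binom`, `p_adj`.
#' @export
enrich_motifs <- function(hits, yes_genes, no_genes, null_model = c("length", "promoter")) {
  null_model <- match.arg(null_model)
  if (!length(yes_genes)) uk_precondition_error("yes set is empty")
  if (length(intersect(yes_genes, no_genes)))
    uk_precondition_error("yes and no gene sets must be disjoint")
  off <- attr(hits, "offsets")
  if (is.null(off)) uk_precondition_error("hit table lacks scannable-offset counts")
  universe <- unique(off$gene_id)
  yes_genes <- intersect(yes_genes, universe)
  no_genes <- intersect(no_genes, universe)
  if (!length(yes_genes) || !length(no_genes))
    uk_precondition_error("both gene sets must have scanned promoters")

  motifs <- sort(unique(off$motif_id))
  tf_of <- if (nrow(hits)) {
    stats::setNames(hits$tf_name, hits$motif_id)
  } else stats::setNames(motifs, motifs)
  n_yes <- length(yes_genes); n_no <- length(no_genes)

  rows <- lapply(motifs, function(m) {
    hm <- hits[hits$motif_id == m, , drop = FALSE]
    occ_yes <- sum(hm$gene_id %in% yes_genes)
    occ_no <- sum(hm$gene_id %in% no_genes)
    om <- off[off$motif_id == m, , drop = FALSE]
    L_yes <- sum(om$n_offsets[om$gene_id %in% yes_genes])
    L_no <- sum(om$n_offsets[om$gene_id %in% no_genes])
    p0 <- if (null_model == "length") L_yes / (L_yes + L_no)
          else n_yes / (n_yes + n_no)
    k <- occ_yes; n <- occ_yes + occ_no
    tf <- unname(tf_of[m])
    if (is.null(tf) || is.na(tf)) tf <- m
    data.frame(motif_id = m,
               tf_name = tf,
               occ_yes = occ_yes, occ_no = occ_no,
               n_yes = n_yes, n_no = n_no, L_yes = L_yes, L_no = L_no,
               ratio = ((occ_yes + 0.5) / n_yes) / ((occ_no + 0.5) / n_no),
               p_binom = binom_upper_tail(k, n, p0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_binom)
  out <- out[order(out$p_binom, -out$ratio, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Exact upper binomial tail P[Bin(n, p0) >= k]
#'
#' Direct summation of the binomial probability mass from `k` to `n`;
#' `k = 0` (an empty strict lower tail) returns 1.
#'
#' @param k,n Non-negative integers, `k <= n`.
#' @param p0 Null success probability in (0, 1).
#' @return Probability in (0, 1].
#' @export
binom_upper_tail <- function(k, n, p0) {
  stopifnot(k >= 0, n >= k, p0 > 0, p0 < 1)
  if (k == 0) return(1)
  if (n == 0) return(1)
  min(1, sum(stats::dbinom(k:n, n, p0)))
}

#' @export
print.enrichment_result <- function(x, n = 6, ...) {
  cat(sprintf("enrichment_result: %d motifs; %d with adjusted p < 0.05\n",
              nrow(x), sum(x$p_adj < 0.05)))
  print.data.frame(utils::head(x, n), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Select candidate TFs from an enrichment result
#'
#' TFs whose motifs pass `p_adj < p_cut` and `ratio > ratio_cut`, ordered by
#' `p_binom` with ties broken by larger ratio then lexicographic motif id.
#' This list seeds the composite-module motif pool.
#'
#' @param records An `enrichment_result`.
#' @param p_cut Adjusted-p threshold (default 0.05).
#' @param ratio_cut Yes/no ratio threshold (default 1.0).
#' @return data.frame of passing records (possibly empty, with a warning).
#' @export
rank_tfs <- function(records, p_cut = 0.05, ratio_cut = 1.0) {
  stopifnot(inherits(records, "enrichment_result"))
  keep <- records[records$p_adj < p_cut & records$ratio > ratio_cut, , drop = FALSE]
  keep <- keep[order(keep$p_binom, -keep$ratio, keep$motif_id), , drop = FALSE]
  rownames(keep) <- NULL
  if (!nrow(keep))
    uk_warn("no motif passes the enrichment thresholds; candidate TF list is empty",
            class = "upstreamkit_empty_enrichment")
  keep
}
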