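# Master-regulator search: breadth-first reachability from the module TFs
# over the reversed signaling graph, distance-discounted scoring, detection
# of positive feedback loops closed by TF -> regulator-gene transcription,
# and the three-component (log2FC, regulatory score, network score) ranking.

#' Find candidate master regulators upstream of a TF set
#'
#' A candidate is any network node from which at least `m_min` of the module
#' TFs are reachable through directed SIGNALING edges within radius `r`
#' (shortest-path distances). Its network score is the distance-discounted
#' coverage
#' `mr_score = sum_{t reached} ((r - d(c,t) + 1) / r) / |tf_set|`,
#' which lies in (0, 1] and is 1 only when every TF sits at distance 1.
#' A pure-coverage alternative (`|reached| / |tf_set|`) is available via
#' `score = "coverage"`.
#'
#' @param network A [signaling_network()].
#' @param tf_set Character vector of TF node ids present in the network.
#' @param r Search radius in edges (default 4).
#' @param m_min Minimum number of TFs reached (default 2).
#' @param score `"discounted"` (default) or `"coverage"`.
#' @return data.frame of class `mr_candidates`, ordered by decreasing
#'   `mr_score` then node id: columns `node_id`, `gene_id`, `mr_score`,
#'   `n_tfs_reached`, plus a list-column `reached` of per-candidate named
#'   distance vectors.
#' @export
find_mr_candidates <- function(network, tf_set, r = 4L, m_min = 2L,
                               score = c("discounted", "coverage")) {
  score <- match.arg(score)
  stopifnot(inherits(network, "signaling_network"))
  if (r < 1) uk_precondition_error("radius r must be >= 1")
  if (!length(tf_set)) uk_precondition_error("tf_set must be non-empty")
  missing <- setdiff(tf_set, network$nodes$id)
  if (length(missing))
    uk_precondition_error(sprintf("TF node(s) not in network: %s",
                                  paste(missing, collapse = ", ")))
  g <- network_igraph(network, kinds = "SIGNALING")
  # rows = TFs, columns = all nodes; mode "in" follows edges backwards, so
  # entry [t, c] is the directed distance c -> t.
  dmat <- igraph::distances(g, v = tf_set, mode = "in")
  nodes <- colnames(dmat)
  rows <- list()
  for (ci in seq_along(nodes)) {
    c_id <- nodes[ci]
    if (c_id %in% tf_set) next   # a module TF is not its own upstream regulator
    d <- stats::setNames(dmat[, ci], rownames(dmat))
    reached <- d[is.finite(d) & d <= r & d >= 1]
    if (length(reached) < m_min) next
    sc <- if (score == "discounted")
      sum((r - reached + 1) / r) / length(tf_set)
    else length(reached) / length(tf_set)
    rows[[length(rows) + 1L]] <- list(node_id = c_id,
                                      gene_id = network$nodes[c_id, "gene"],
                                      mr_score = sc,
                                      n_tfs_reached = length(reached),
                                      reached = reached)
  }
  if (!length(rows)) {
    uk_warn("no master-regulator candidate reaches enough module TFs",
            class = "upstreamkit_no_candidates")
    out <- data.frame(node_id = character(), gene_id = character(),
                      mr_score = double(), n_tfs_reached = integer(),
                      stringsAsFactors = FALSE)
    out$reached <- list()
    return(structure(out, class = c("mr_candidates", "data.frame"),
                     tf_set = tf_set, r = as.integer(r)))
  }
  out <- data.frame(node_id = vapply(rows, `[[`, "", "node_id"),
                    gene_id = vapply(rows, `[[`, "", "gene_id"),
                    mr_score = vapply(rows, `[[`, 0, "mr_score"),
                    n_tfs_reached = vapply(rows, `[[`, 0L, "n_tfs_reached"),
                    stringsAsFactors = FALSE)
  out$reached <- lapply(rows, `[[`, "reached")
  out <- out[order(-out$mr_score, out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mr_candidates", "data.frame"),
            tf_set = tf_set, r = as.integer(r))
}

#' @export
print.mr_candidates <- function(x, n = 8, ...) {
  cat(sprintf("mr_candidates: %d candidate(s) for %d TFs at radius %d\n",
              nrow(x), length(attr(x, "tf_set")), attr(x, "r")))
  print.data.frame(utils::head(x[, c("node_id", "gene_id", "mr_score",
                                     "n_tfs_reached")], n),
                   digits = 4, row.names = FALSE)
  invisible(x)
}

#' Detect positive feedback loops through candidate master regulators
#'
#' A loop is recorded for a candidate `c` and module TF `t` when `t` is
#' reachable from `c` within the search radius AND the circuit closes back
#' transcriptionally: either the network carries a TRANSCRIPTION edge from
#' `t` onto a node encoding `c`'s gene (`NETWORK_EDGE` evidence), or `t`'s
#' motif has a module-passing site in `c`'s gene promoter (`PROMOTER_SITE`
#' evidence). A loop is labeled positive when the product of signaling-edge
#' signs along the shortest path is +1; negative-product loops are kept but
#' flagged.
#'
#' @param network A [signaling_network()].
#' @param candidates An `mr_candidates` table.
#' @param module Optional [composite_module()] whose motif thresholds define
#'   "module-passing" promoter sites; with `hits` supplies the
#'   `PROMOTER_SITE` evidence. The mapping motif -> TF node uses `tf_map`.
#' @param hits Optional hit table over the candidate genes' promoters.
#' @param tf_map Named character vector mapping motif ids to TF node ids
#'   (defaults to the hit table's `tf_name`).
#' @return The candidates table with a `loops` list-column (one data.frame
#'   per candidate: `tf_node`, `path`, `evidence`, `sign_product`,
#'   `positive`) and an `n_loops` column.
#' @export
detect_feedback_loops <- function(network, candidates, module = NULL,
                                  hits = NULL, tf_map = NULL) {
  stopifnot(inherits(candidates, "mr_candidates"))
  g <- network_igraph(network, kinds = "SIGNALING")
  tr <- network$edges[network$edges$kind == "TRANSCRIPTION", , drop = FALSE]
  gene_of <- stats::setNames(network$nodes$gene, network$nodes$id)

  # promoter-site evidence: motif -> tf-node map plus per-gene passing sites
  site_tfs_of_gene <- function(gene) character(0)
  if (!is.null(module) && !is.null(hits) && nrow(hits)) {
    if (is.null(tf_map))
      tf_map <- stats::setNames(hits$tf_name, hits$motif_id)
    tf_map <- tf_map[!duplicated(names(tf_map))]
    mm <- module$motifs
    site_tfs_of_gene <- function(gene) {
      hg <- hits[hits$gene_id %in% gene & hits$motif_id %in% mm$motif_id, ,
                 drop = FALSE]
      if (!nrow(hg)) return(character(0))
      pass <- hg$mss > mm$theta[match(hg$motif_id, mm$motif_id)]
      unique(unname(tf_map[hg$motif_id[pass]]))
    }
  }

  loops <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    c_id <- candidates$node_id[i]
    c_gene <- candidates$gene_id[i]
    reached <- candidates$reached[[i]]
    recs <- list()
    if (!is.na(c_gene)) {
      targets_of <- function(tf)
        tr$to[tr$from == tf]
      site_tfs <- site_tfs_of_gene(c_gene)
      for (tf in names(reached)) {
        ev <- character(0)
        tgt_genes <- gene_of[targets_of(tf)]
        if (any(!is.na(tgt_genes) & tgt_genes == c_gene))
          ev <- c(ev, "NETWORK_EDGE")
        if (tf %in% site_tfs) ev <- c(ev, "PROMOTER_SITE")
        if (!length(ev)) next
        sp <- igraph::shortest_paths(g, from = c_id, to = tf,
                                     mode = "out", output = "both")
        path_nodes <- names(sp$vpath[[1]])
        sgn <- prod(igraph::edge_attr(g, "sign", sp$epath[[1]]))
        recs[[length(recs) + 1L]] <- data.frame(
          tf_node = tf, path = paste(path_nodes, collapse = "->"),
          evidence = paste(ev, collapse = "+"),
          sign_product = sgn, positive = sgn > 0,
          stringsAsFactors = FALSE)
      }
    }
    loops[[i]] <- if (length(recs)) do.call(rbind, recs) else
      data.frame(tf_node = character(), path = character(),
                 evidence = character(), sign_product = double(),
                 positive = logical(), stringsAsFactors = FALSE)
  }
  candidates$loops <- loops
  candidates$n_loops <- vapply(loops, nrow, 0L)
  candidates
}

#' Rank master-regulator candidates by three components
#'
#' Components, each ranked descending: (a) the log2 fold change of the
#' candidate's encoding gene, (b) its regulatory (CMA) score, (c) its
#' network `mr_score`. The combined rank is the average of the three
#' component ranks; ties break by node id. Candidates without an encoding
#' gene take log2FC = 0 and regulatory score = 0.
#'
#' @param candidates An `mr_candidates` table (optionally loop-annotated).
#' @param de_results A `de_result` (for component a).
#' @param reg_scores data.frame `gene_id`/`score` from [regulatory_scores()]
#'   (for component b).
#' @return data.frame of class `mr_ranking`, ordered by `combined_rank`:
#'   node, gene, the three components and their ranks, the number of TFs
#'   reached through the network and (when loops were annotated) supported
#'   by promoter sites, and loop counts.
#' @export
rank_master_regulators <- function(candidates, de_results, reg_scores) {
  stopifnot(inherits(candidates, "mr_candidates"))
  if (!nrow(candidates)) uk_precondition_error("no candidates to rank")
  lfc <- stats::setNames(de_results$log2FC, de_results$gene_id)
  rsc <- stats::setNames(reg_scores$score, reg_scores$gene_id)
  tab <- candidates
  tab$lfc <- ifelse(is.na(tab$gene_id), 0,
                    ifelse(is.na(lfc[tab$gene_id]), 0, lfc[tab$gene_id]))
  tab$reg_score <- ifelse(is.na(tab$gene_id), 0,
                          ifelse(is.na(rsc[tab$gene_id]), 0, rsc[tab$gene_id]))
  rk <- function(x) rank(-x, ties.method = "average")  # midranks for ties
  tab$rank_lfc <- rk(tab$lfc)
  tab$rank_reg <- rk(tab$reg_score)
  tab$rank_mr <- rk(tab$mr_score)
  tab$combined_rank <- (tab$rank_lfc + tab$rank_reg + tab$rank_mr) / 3
  ord <- order(tab$combined_rank, tab$node_id)
  tab <- tab[ord, , drop = FALSE]
  tab$final_rank <- seq_len(nrow(tab))
  if (!"n_loops" %in% names(tab)) tab$n_loops <- NA_integer_
  rownames(tab) <- NULL
  structure(tab, class = c("mr_ranking", class(candidates)))
}

#' @export
print.mr_ranking <- function(x, n = 8, ...) {
  cat(sprintf("mr_ranking: %d candidate(s); combined rank = mean of log2FC, regulatory-score and network-score ranks\n",
              nrow(x)))
  cols <- intersect(c("final_rank", "node_id", "gene_id", "lfc", "reg_score",
                      "mr_score", "n_tfs_reached", "n_loops"), names(x))
  print.data.frame(utils::head(as.data.frame(x)[, cols], n), digits = 4,
                   row.names = FALSE)
  invisible(x)
}
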