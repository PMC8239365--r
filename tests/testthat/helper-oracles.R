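# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately naive (brute force / closed form) and never call
# the code paths they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed GA seed per study seed, kept apart from the generator streams
derive_seed_t <- function(seed) 10000L + 37L * seed

# --- fixtures ---------------------------------------------------------------

toy_motif <- function(consensus, id = "MX", tf = id, strength = 20,
                      mss_cutoff = 0.75, css_cutoff = 0.70) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  counts <- matrix(1, L, 4, dimnames = list(NULL, bases))
  idx <- match(strsplit(consensus, "")[[1]], bases)
  counts[cbind(seq_len(L), idx)] <- strength
  motif_model(counts, id, tf, mss_cutoff = mss_cutoff,
              css_cutoff = css_cutoff)
}

random_promoter <- function(gene_id, length = 300, seed = 1,
                            window_end = 0L) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  promoter_record(gene_id, seq, window_end - length, window_end)
}

implant_site <- function(promoter, site, at_coord) {
  # at_coord: TSS-relative start of the site
  pos <- at_coord - promoter$window_start + 1L
  seq <- promoter$sequence
  substr(seq, pos, pos + nchar(site) - 1L) <- site
  promoter_record(promoter$gene_id, seq, promoter$window_start,
                  promoter$window_end)
}

# a small chain/star network builder
edges_df <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], sign = as.integer(m[, 3]),
             kind = m[, 4], stringsAsFactors = FALSE)
}

# a hit table built directly (bypassing scanning) for enrichment/module tests
manual_hits <- function(gene, motif, start, mss, tf = motif,
                        strand = "+", offsets = NULL) {
  h <- data.frame(gene_id = gene, motif_id = motif,
                  tf_name = rep_len(tf, length(gene)),
                  start = as.integer(rep_len(start, length(gene))),
                  strand = rep_len(strand, length(gene)),
                  mss = rep_len(mss, length(gene)),
                  css = rep_len(mss, length(gene)), stringsAsFactors = FALSE)
  structure(h, offsets = offsets, class = c("hit_table", "data.frame"))
}

uniform_offsets <- function(genes, motifs, n_offsets) {
  d <- expand.grid(gene_id = genes, motif_id = motifs,
                   stringsAsFactors = FALSE)
  d$n_offsets <- n_offsets
  d
}

# --- oracles ----------------------------------------------------------------

# brute-force best-window module score: every integer window start
brute_module_score <- function(hits_one_gene, module, start_range = NULL) {
  mm <- module$motifs
  w <- mm$weight / sum(mm$weight)
  if (!nrow(hits_one_gene)) return(0)
  if (is.null(start_range))
    start_range <- (min(hits_one_gene$start) - module$window_W):
                   (max(hits_one_gene$start) + 1L)
  best <- 0
  for (s in start_range) {
    v <- 0
    for (m in seq_len(nrow(mm))) {
      hm <- hits_one_gene[hits_one_gene$motif_id == mm$motif_id[m] &
                          hits_one_gene$start >= s &
                          hits_one_gene$start < s + module$window_W, ,
                          drop = FALSE]
      if (nrow(hm) && max(hm$mss) > mm$theta[m])
        v <- v + w[m] * (max(hm$mss) - mm$theta[m])
    }
    best <- max(best, v)
  }
  best
}

# naive MATCH similarity of one window (direct formula)
naive_mss <- function(motif, window_seq) {
  bases <- c("A", "C", "G", "T")
  f <- motif$freqs; I <- motif$info
  idx <- match(strsplit(window_seq, "")[[1]], bases)
  cur <- sum(I * f[cbind(seq_along(idx), idx)])
  lo <- sum(I * apply(f, 1, min))
  hi <- sum(I * apply(f, 1, max))
  (cur - lo) / (hi - lo)
}

# Floyd-Warshall all-pairs shortest paths on a signaling_network's
# SIGNALING edges (unit edge lengths)
floyd_warshall <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  e <- network$edges[network$edges$kind == "SIGNALING", , drop = FALSE]
  for (i in seq_len(nrow(e))) d[e$from[i], e$to[i]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# exhaustive enumeration of qualifying feedback (candidate, tf) pairs
brute_feedback_pairs <- function(network, candidates, r) {
  d <- floyd_warshall(network)
  tr <- network$edges[network$edges$kind == "TRANSCRIPTION", , drop = FALSE]
  gene_of <- stats::setNames(network$nodes$gene, network$nodes$id)
  out <- list()
  for (i in seq_len(nrow(candidates))) {
    c_id <- candidates$node_id[i]
    c_gene <- candidates$gene_id[i]
    if (is.na(c_gene)) next
    for (tf in names(candidates$reached[[i]])) {
      ok <- any(tr$from == tf &
                !is.na(gene_of[tr$to]) & gene_of[tr$to] == c_gene)
      if (ok) out[[length(out) + 1L]] <- c(c_id, tf)
    }
  }
  out
}

# exhaustive composite-module search over the theta/W grids with uniform
# weights, for a fixed motif set
exhaustive_module_fitness <- function(hits, yes, no, motif_ids, lambda = 0.1,
                                      theta_grid = seq(0.70, 0.95, 0.05),
                                      W_grid = seq(100L, 600L, 50L)) {
  k <- length(motif_ids)
  grid <- do.call(expand.grid, c(rep(list(theta_grid), k), list(W_grid)))
  best <- -Inf
  for (i in seq_len(nrow(grid))) {
    mod <- composite_module(
      data.frame(motif_id = motif_ids,
                 theta = as.numeric(grid[i, seq_len(k)]),
                 weight = rep(1, k), stringsAsFactors = FALSE),
      window_W = grid[i, k + 1])
    f <- module_fitness(mod, hits, yes, no, lambda = lambda)
    if (f > best) best <- f
  }
  best
}

# small planted two-motif study used by GA-vs-exhaustive checks
tiny_cma_instance <- function(seed, n_yes = 12, n_no = 24) {
  motifs <- gen_motifs(n = 2, length_range = c(10L, 12L),
                       seed = seed + 500)
  yes_ids <- sprintf("y%02d", seq_len(n_yes))
  no_ids <- sprintf("n%02d", seq_len(n_no))
  prom <- gen_promoters(motifs, yes_ids, no_ids, length = 600,
                        module_motifs = names(motifs), pi_implant = 1,
                        W = 200L, decoy_rate = 0.2, seed = seed)
  hits <- scan_all(prom$promoters, motifs)
  list(hits = hits, yes = yes_ids, no = no_ids, motifs = motifs,
       promoters = prom$promoters)
}
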