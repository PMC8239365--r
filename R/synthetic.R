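# Synthetic study generator with a planted-truth manifest: two-group
# expression with planted log2FC effects, promoter sequences carrying
# planted clusters of motif sites, a Dirichlet motif library, and a
# signaling network with a planted regulator upstream of the module TFs
# plus transcriptional feedback edges. Every generator is deterministic
# under its seed and uses an independent stream, so regenerating one
# artifact leaves the others bit-identical.

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Simulate a two-group log2 expression matrix with planted effects
#'
#' Per-gene baselines are N(7, 1); planted genes shift the YES group by a
#' per-gene effect drawn uniformly from `effect_range` (positive for up,
#' negative for down); all samples add Gaussian noise with sd `sigma`.
#'
#' @param n_genes,n_yes,n_no Matrix dimensions (defaults 2000, 20, 20).
#' @param n_up,n_down Planted up/down gene counts (defaults 150, 100).
#' @param effect_range Uniform range of planted |log2FC| (default
#'   `c(0.6, 1.5)`).
#' @param sigma Noise sd (default 0.5).
#' @param seed Integer seed.
#' @return List with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frames of planted up/down genes with effects, plus the seed).
#' @export
gen_expression <- function(n_genes = 2000, n_yes = 20, n_no = 20,
                           n_up = 150, n_down = 100,
                           effect_range = c(0.6, 1.5), sigma = 0.5,
                           seed = 1L) {
  stopifnot(n_up + n_down <= n_genes)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- c(sprintf("yes_%02d", seq_len(n_yes)),
                 sprintf("no_%02d", seq_len(n_no)))
    groups <- stats::setNames(rep(c("YES", "NO"), c(n_yes, n_no)), samples)
    base <- stats::rnorm(n_genes, 7, 1)
    vals <- matrix(stats::rnorm(n_genes * (n_yes + n_no), 0, sigma),
                   n_genes, n_yes + n_no, dimnames = list(genes, samples))
    vals <- vals + base
    up_idx <- seq_len(n_up)
    down_idx <- n_up + seq_len(n_down)
    eff_up <- if (n_up) sort(stats::runif(n_up, effect_range[1], effect_range[2]),
                             decreasing = TRUE) else numeric(0)
    eff_down <- if (n_down) stats::runif(n_down, effect_range[1], effect_range[2])
                else numeric(0)
    if (n_up)
      vals[up_idx, seq_len(n_yes)] <- vals[up_idx, seq_len(n_yes)] + eff_up
    if (n_down)
      vals[down_idx, seq_len(n_yes)] <- vals[down_idx, seq_len(n_yes)] - eff_down
    list(matrix = expression_matrix(vals, groups),
         truth = list(up = data.frame(gene_id = genes[up_idx], effect = eff_up,
                                      stringsAsFactors = FALSE),
                      down = data.frame(gene_id = genes[down_idx],
                                        effect = -eff_down,
                                        stringsAsFactors = FALSE),
                      sigma = sigma, seed = as.integer(seed)))
  })
}

#' Generate a synthetic motif library
#'
#' Position frequency columns are Dirichlet-sampled and tempered (raised to
#' a power and renormalized) until the mean information content per position
#' is within `info_tol` of `target_info` bits.
#'
#' @param n Number of motifs (default 20).
#' @param length_range Motif lengths drawn uniformly from this integer range
#'   (default 8..14).
#' @param target_info Mean bits per position (default 1.2).
#' @param info_tol Tolerance around `target_info` (default 0.2).
#' @param seed Integer seed.
#' @return A `motif_library` of [motif_model()]s with ids `M01..` and TF
#'   names `TF01..`.
#' @export
gen_motifs <- function(n = 20, length_range = c(8L, 14L), target_info = 1.2,
                       info_tol = 0.2, seed = 1L) {
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      Ls <- length_range[1]:length_range[2]
      L <- Ls[sample.int(length(Ls), 1)]
      f <- t(vapply(seq_len(L), function(j) {
        x <- stats::rgamma(4, shape = 0.5)
        x / sum(x)
      }, numeric(4)))
      f <- temper_to_info(f, target_info)
      out[[i]] <- motif_model(f, sprintf("M%02d", i), sprintf("TF%02d", i))
    }
    names(out) <- vapply(out, `[[`, "", "motif_id")
    structure(out, class = c("motif_library", "list"))
  })
}

# Bisection on the tempering exponent g (columns f^g, renormalized) to reach
# a mean information content of `target` bits per position.
temper_to_info <- function(f, target) {
  info_bits <- function(m) mean(information_vector(m, pseudocount = 0.001)) / log(2)
  apply_g <- function(g) {
    m <- f^g
    m / rowSums(m)
  }
  lo <- 1e-3; hi <- 60
  for (i in 1:60) {
    mid <- sqrt(lo * hi)
    if (info_bits(apply_g(mid)) < target) lo <- mid else hi <- mid
  }
  apply_g(sqrt(lo * hi))
}

#' Most informative motifs of a library
#'
#' Orders motifs by total information content (sum of the per-position
#' information vector) and returns the top `n` ids. Used as the default
#' planted-module choice: high-information motifs have low background hit
#' rates, so a planted site cluster is identifiable at the default scanning
#' stringency — mirroring the specificity of real composite-module TFs.
#'
#' @param motifs A `motif_library`.
#' @param n Number of motifs (default 3).
#' @return Character vector of motif ids.
#' @export
top_info_motifs <- function(motifs, n = 3) {
  tot <- vapply(motifs, function(m) sum(m$info), 0)
  names(sort(tot, decreasing = TRUE))[seq_len(min(n, length(tot)))]
}

# Sample one site from a PFM, rejecting draws whose MSS falls below
# `min_mss`: models a strong functional site that a scanner at that cutoff
# is guaranteed to rediscover.
sample_site <- function(motif, min_mss = 0.9, max_tries = 200) {
  f <- motif$freqs
  w <- motif$info * f
  wmin <- apply(w, 1, min); wmax <- apply(w, 1, max)
  den <- sum(wmax) - sum(wmin)
  for (try in seq_len(max_tries)) {
    b <- vapply(seq_len(nrow(f)), function(i) sample.int(4, 1, prob = f[i, ]), 0L)
    cur <- sum(w[cbind(seq_len(nrow(f)), b)])
    if ((cur - sum(wmin)) / den >= min_mss)
      return(paste(BASES[b], collapse = ""))
  }
  consensus_sequence(motif)
}

#' Generate synthetic promoter sets with a planted composite module
#'
#' Yes promoters carry, with probability `pi_implant`, one sampled site per
#' module motif placed non-overlapping inside a random window of width `W`;
#' no promoters are background plus Poisson-distributed decoy singleton
#' sites of randomly chosen library motifs.
#'
#' @param motifs A `motif_library`.
#' @param yes_gene_ids,no_gene_ids Gene ids to attach to the promoters.
#' @param length Promoter length in bp (default 1100, window `[-1000, 100)`).
#' @param gc Background GC content (default 0.5).
#' @param module_motifs Motif ids planted as the module (default: the 3
#'   most informative library motifs, see [top_info_motifs()]).
#' @param pi_implant Implant probability per yes promoter (default 0.9).
#' @param W Cluster window width in bp (default 300).
#' @param decoy_rate Poisson mean of decoy sites per no promoter
#'   (default 0.5).
#' @param min_site_mss Minimum MSS of sampled sites (default 0.9, see
#'   details in the package vignette).
#' @param force_implant Gene ids among `yes_gene_ids` whose promoters always
#'   receive the full module cluster regardless of `pi_implant`.
#' @param seed Integer seed.
#' @return List with `promoters` (a `promoter_set`, yes then no) and `truth`
#'   (module motifs, window, per-promoter implant table with coordinates).
#' @export
gen_promoters <- function(motifs, yes_gene_ids, no_gene_ids, length = 1100L,
                          gc = 0.5, module_motifs = top_info_motifs(motifs, 3),
                          pi_implant = 0.9, W = 300L, decoy_rate = 0.5,
                          min_site_mss = 0.9, force_implant = character(0),
                          seed = 1L) {
  window_start <- -(length - 100L)
  window_end <- 100L
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  with_seed(seed, {
    rand_seq <- function()
      paste(sample(BASES, length, replace = TRUE, prob = base_prob),
            collapse = "")
    implant <- function(seq, site, at) {   # at: 1-based position
      paste0(substr(seq, 1, at - 1), site,
             substr(seq, at + nchar(site), nchar(seq)))
    }
    place_cluster <- function(seq, gene) {
      win0 <- sample.int(length - W + 1L, 1)   # 1-based window start
      placed <- list()
      occupied <- integer(0)
      for (m in module_motifs) {
        site <- sample_site(motifs[[m]], min_site_mss)
        for (try in 1:100) {
          at <- win0 + sample.int(W - nchar(site) + 1L, 1) - 1L
          span <- at:(at + nchar(site) - 1L)
          if (!length(intersect(span, occupied))) break
        }
        occupied <- c(occupied, span)
        seq <- implant(seq, site, at)
        placed[[m]] <- data.frame(gene_id = gene, motif_id = m,
                                  start = window_start + at - 1L,
                                  site = site, stringsAsFactors = FALSE)
      }
      list(seq = seq, placed = do.call(rbind, placed))
    }

    promoters <- list()
    implants <- list()
    for (g in yes_gene_ids) {
      seq <- rand_seq()
      if (g %in% force_implant || stats::runif(1) < pi_implant) {
        pc <- place_cluster(seq, g)
        seq <- pc$seq
        implants[[g]] <- pc$placed
      }
      promoters[[g]] <- promoter_record(g, seq, window_start, window_end)
    }
    for (g in no_gene_ids) {
      seq <- rand_seq()
      nd <- stats::rpois(1, decoy_rate)
      for (d in seq_len(nd)) {
        m <- sample(names(motifs), 1)
        site <- sample_site(motifs[[m]], min_site_mss)
        at <- sample.int(length - nchar(site) + 1L, 1)
        seq <- implant(seq, site, at)
      }
      promoters[[g]] <- promoter_record(g, seq, window_start, window_end)
    }
    list(promoters = structure(promoters, class = c("promoter_set", "list")),
         truth = list(module_motifs = module_motifs, pi = pi_implant, W = W,
                      implants = if (length(implants))
                        do.call(rbind, c(implants, list(make.row.names = FALSE)))
                      else NULL,
                      seed = as.integer(seed)))
  })
}

#' Generate a signaling network with a planted master regulator
#'
#' Background nodes form a sparse random digraph among themselves. The
#' planted regulator is wired to every module TF through activating
#' SIGNALING paths of length at most `d_max`; distractor hubs connect to at
#' most half of the TFs; TRANSCRIPTION feedback edges run from each module
#' TF to the planted regulator (whose node carries its encoding gene).
#'
#' @param tf_nodes Character vector of module TF node ids.
#' @param regulator_gene Gene id encoding the planted regulator.
#' @param n_nodes Background node count (default 300).
#' @param mean_out_degree Background edge density (default 2.5).
#' @param d_max Maximum planted wiring distance to a TF (default 3).
#' @param n_distractors Distractor hub count (default 5).
#' @param seed Integer seed.
#' @return List with `network` (a [signaling_network()]) and `truth`
#'   (regulator node id, wiring distances, distractor ids, seed).
#' @export
gen_network <- function(tf_nodes, regulator_gene, n_nodes = 300,
                        mean_out_degree = 2.5, d_max = 3L,
                        n_distractors = 5L, seed = 1L) {
  with_seed(seed, {
    bg <- sprintf("P%03d", seq_len(n_nodes))
    reg <- "REG1"
    distractors <- sprintf("DIS%d", seq_len(n_distractors))
    n_edges <- stats::rpois(1, mean_out_degree * n_nodes)
    edges <- data.frame(from = sample(bg, n_edges, replace = TRUE),
                        to = sample(bg, n_edges, replace = TRUE),
                        sign = sample(c(1L, -1L), n_edges, replace = TRUE,
                                      prob = c(0.8, 0.2)),
                        kind = "SIGNALING", stringsAsFactors = FALSE)
    edges <- edges[edges$from != edges$to, , drop = FALSE]

    # planted activating paths REG1 -> (intermediates) -> TF, length <= d_max
    wiring <- data.frame(tf = tf_nodes, distance = NA_integer_,
                         stringsAsFactors = FALSE)
    inter_i <- 0L
    for (ti in seq_along(tf_nodes)) {
      d <- sample.int(d_max, 1)
      prev <- reg
      if (d > 1) for (s in seq_len(d - 1L)) {
        inter_i <- inter_i + 1L
        node <- sprintf("INT%02d", inter_i)
        edges <- rbind(edges, data.frame(from = prev, to = node, sign = 1L,
                                         kind = "SIGNALING",
                                         stringsAsFactors = FALSE))
        prev <- node
      }
      edges <- rbind(edges, data.frame(from = prev, to = tf_nodes[ti],
                                       sign = 1L, kind = "SIGNALING",
                                       stringsAsFactors = FALSE))
      wiring$distance[ti] <- d
    }
    # distractor hubs reach at most half the TFs
    k_dis <- max(1L, ceiling(length(tf_nodes) / 2))
    for (dd in distractors) {
      reach <- sample(tf_nodes, sample.int(k_dis, 1))
      edges <- rbind(edges, data.frame(from = dd, to = reach, sign = 1L,
                                       kind = "SIGNALING",
                                       stringsAsFactors = FALSE))
    }
    # transcriptional feedback: every module TF transcribes the regulator gene
    edges <- rbind(edges, data.frame(from = tf_nodes, to = reg, sign = 1L,
                                     kind = "TRANSCRIPTION",
                                     stringsAsFactors = FALSE))
    nodes <- data.frame(
      id = c(bg, reg, distractors, tf_nodes,
             if (inter_i) sprintf("INT%02d", seq_len(inter_i))),
      kind = c(rep("PROTEIN", n_nodes), "PROTEIN",
               rep("PROTEIN", n_distractors), rep("TF", length(tf_nodes)),
               rep("PROTEIN", inter_i)),
      gene = NA_character_, stringsAsFactors = FALSE)
    nodes$gene[nodes$id == reg] <- regulator_gene
    net <- signaling_network(edges, nodes)
    list(network = net,
         truth = list(regulator_node = reg, regulator_gene = regulator_gene,
                      wiring = wiring, distractors = distractors,
                      seed = as.integer(seed)))
  })
}

#' Generate a complete synthetic study with cross-referenced planted truth
#'
#' Gene ids are consistent across artifacts: the promoter "yes" universe is
#' the strongest planted up-regulated genes, the planted module targets are
#' a subset of the planted up genes, and the planted regulator's encoding
#' gene is the planted up gene with the largest effect and always carries
#' the module cluster in its promoter — encoding the positive-feedback
#' premise as generative structure.
#'
#' @param seed Integer master seed; each artifact derives an independent
#'   sub-seed from it.
#' @param n_promoter_yes,n_promoter_no Promoter universe sizes (defaults
#'   50, 200).
#' @param ... Passed on to [gen_expression()].
#' @return List of class `synthetic_study` with `expression`, `promoters`,
#'   `motifs`, `network` and a `truth` manifest.
#' @export
gen_study <- function(seed = 1L, n_promoter_yes = 50L, n_promoter_no = 200L,
                      ...) {
  expr <- gen_expression(seed = derive_seed(seed, 1L), ...)
  motifs <- gen_motifs(seed = derive_seed(seed, 2L))
  up <- expr$truth$up        # sorted by decreasing effect
  regulator_gene <- up$gene_id[1]
  yes_ids <- up$gene_id[seq_len(min(n_promoter_yes, nrow(up)))]
  null_genes <- setdiff(rownames(expr$matrix$values),
                        c(up$gene_id, expr$truth$down$gene_id))
  no_ids <- with_seed(derive_seed(seed, 5L),
                      sort(sample(null_genes, n_promoter_no)))
  prom <- gen_promoters(motifs, yes_ids, no_ids,
                        force_implant = regulator_gene,
                        seed = derive_seed(seed, 3L))
  tf_nodes <- vapply(prom$truth$module_motifs,
                     function(m) motifs[[m]]$tf_name, "")
  net <- gen_network(tf_nodes = unname(tf_nodes),
                     regulator_gene = regulator_gene,
                     seed = derive_seed(seed, 4L))
  truth <- list(seed = as.integer(seed),
                expression = expr$truth,
                module = prom$truth,
                network = net$truth,
                tf_of_motif = as.list(stats::setNames(unname(tf_nodes),
                                                      prom$truth$module_motifs)))
  structure(list(expression = expr$matrix, promoters = prom$promoters,
                 motifs = motifs, network = net$network, truth = truth),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study (seed %d): %d genes x %d samples, %d promoters, %d motifs, %d network nodes\n",
              x$truth$seed, nrow(x$expression$values), ncol(x$expression$values),
              length(x$promoters), length(x$motifs), nrow(x$network$nodes)))
  cat(sprintf("planted: %d up / %d down genes; module %s; regulator %s (gene %s)\n",
              nrow(x$truth$expression$up), nrow(x$truth$expression$down),
              paste(x$truth$module$module_motifs, collapse = "+"),
              x$truth$network$regulator_node, x$truth$network$regulator_gene))
  invisible(x)
}

#' Write a synthetic study's input files and truth manifest to a directory
#'
#' Emits `expression.tsv`, `groups.tsv`, `promoters.fa`, `motifs.transfac`,
#' `network.tsv`, `nodes.tsv` and `truth.json`.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(study$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "groups.tsv"))
  write_promoters(study$promoters, file.path(dir, "promoters.fa"))
  write_motifs(study$motifs, file.path(dir, "motifs.transfac"))
  write_network(study$network, file.path(dir, "network.tsv"),
                file.path(dir, "nodes.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(dir)
}

#' Read back a truth manifest written by [write_study()]
#' @param path Path to `truth.json`.
#' @return The manifest list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
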