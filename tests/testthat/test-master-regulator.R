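star_network <- function(n_tf = 5) {
  tfs <- sprintf("T%d", seq_len(n_tf))
  ed <- do.call(edges_df, as.list(t(cbind("c", tfs, 1, "SIGNALING"))))
  nodes <- data.frame(id = c("c", tfs), kind = c("PROTEIN", rep("TF", n_tf)),
                      gene = c("gc", rep(NA, n_tf)), stringsAsFactors = FALSE)
  signaling_network(ed, nodes)
}

test_that("mr_score closed forms hold on star and chain graphs", {
  net <- star_network(5)
  cand <- find_mr_candidates(net, sprintf("T%d", 1:5), r = 4, m_min = 2)
  expect_equal(cand$node_id, "c")
  expect_equal(cand$mr_score, 1.0)

  # chain c -> a -> t: not a candidate at r = 1, score 0.5 at r = 2
  ed <- edges_df("c", "a", 1, "SIGNALING", "a", "t", 1, "SIGNALING")
  nodes <- data.frame(id = c("c", "a", "t"),
                      kind = c("PROTEIN", "PROTEIN", "TF"),
                      gene = NA_character_, stringsAsFactors = FALSE)
  chain <- signaling_network(ed, nodes)
  c1 <- find_mr_candidates(chain, "t", r = 1, m_min = 1)
  expect_false("c" %in% c1$node_id)      # only "a" is within radius 1
  c2 <- find_mr_candidates(chain, "t", r = 2, m_min = 1)
  cc <- c2[c2$node_id == "c", ]
  expect_equal(unname(cc$reached[[1]]["t"]), 2)
  expect_equal(cc$mr_score, ((2 - 2 + 1) / 2) / 1)  # = 0.5
})

test_that("coverage scoring and candidate preconditions behave", {
  net <- star_network(4)
  cand <- find_mr_candidates(net, sprintf("T%d", 1:4), r = 4, m_min = 2,
                             score = "coverage")
  expect_equal(cand$mr_score, 1.0)
  expect_error(find_mr_candidates(net, "missing_tf"),
               class = "upstreamkit_precondition_error")
  expect_error(find_mr_candidates(net, "T1", r = 0),
               class = "upstreamkit_precondition_error")
})

test_that("reachability distances equal Floyd-Warshall on random graphs", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(10:40, 1)
    ids <- sprintf("v%02d", seq_len(n))
    ne <- sample(n:(3 * n), 1)
    ed <- data.frame(from = sample(ids, ne, TRUE), to = sample(ids, ne, TRUE),
                     sign = 1L, kind = "SIGNALING", stringsAsFactors = FALSE)
    ed <- ed[ed$from != ed$to, , drop = FALSE]
    tfs <- sample(ids, 3)
    nodes <- data.frame(id = ids,
                        kind = ifelse(ids %in% tfs, "TF", "PROTEIN"),
                        gene = NA_character_, stringsAsFactors = FALSE)
    net <- signaling_network(ed, nodes)
    d <- floyd_warshall(net)
    r <- 4
    cand <- suppressWarnings(find_mr_candidates(net, tfs, r = r, m_min = 1))
    for (i in seq_len(nrow(cand))) {
      reached <- cand$reached[[i]]
      expect_equal(unname(reached),
                   unname(d[cand$node_id[i], names(reached)]))
    }
    # every non-TF node within radius of >= 1 TF must be reported
    expected <- setdiff(
      rownames(d)[apply(d[, tfs, drop = FALSE], 1,
                        function(x) any(x >= 1 & x <= r))], tfs)
    expect_setequal(cand$node_id, expected)
  }
})

test_that("candidate sets are monotone in radius and in added edges", {
  set.seed(99)
  ids <- sprintf("v%02d", 1:20)
  ed <- data.frame(from = sample(ids, 35, TRUE), to = sample(ids, 35, TRUE),
                   sign = 1L, kind = "SIGNALING", stringsAsFactors = FALSE)
  ed <- ed[ed$from != ed$to, ]
  tfs <- c("v01", "v02")
  nodes <- data.frame(id = ids, kind = ifelse(ids %in% tfs, "TF", "PROTEIN"),
                      gene = NA_character_, stringsAsFactors = FALSE)
  net <- signaling_network(ed, nodes)
  c3 <- suppressWarnings(find_mr_candidates(net, tfs, r = 3, m_min = 1))
  c4 <- suppressWarnings(find_mr_candidates(net, tfs, r = 4, m_min = 1))
  expect_true(all(c3$node_id %in% c4$node_id))

  # adding one edge never decreases any candidate's score
  extra <- data.frame(from = "v10", to = "v01", sign = 1L,
                      kind = "SIGNALING", stringsAsFactors = FALSE)
  net2 <- signaling_network(rbind(ed, extra), nodes)
  c4b <- suppressWarnings(find_mr_candidates(net2, tfs, r = 4, m_min = 1))
  common <- intersect(c4$node_id, c4b$node_id)
  expect_true(all(c4$node_id %in% c4b$node_id))
  s1 <- setNames(c4$mr_score, c4$node_id)
  s2 <- setNames(c4b$mr_score, c4b$node_id)
  expect_true(all(s2[common] >= s1[common] - 1e-12))
})

test_that("feedback loops require both reachability and transcription closure", {
  # c -> t signaling, t -> c transcription (c carries a gene): one loop
  ed <- edges_df("c", "t", 1, "SIGNALING", "t", "c", 1, "TRANSCRIPTION")
  nodes <- data.frame(id = c("c", "t"), kind = c("PROTEIN", "TF"),
                      gene = c("gc", NA), stringsAsFactors = FALSE)
  net <- signaling_network(ed, nodes)
  cand <- find_mr_candidates(net, "t", r = 2, m_min = 1)
  ann <- detect_feedback_loops(net, cand)
  expect_equal(ann$n_loops[ann$node_id == "c"], 1L)
  lp <- ann$loops[[which(ann$node_id == "c")]]
  expect_equal(lp$evidence, "NETWORK_EDGE")
  expect_equal(lp$path, "c->t")
  expect_true(lp$positive)

  # no transcription edge and no promoter site: zero loops
  ed2 <- edges_df("c", "t", 1, "SIGNALING")
  net2 <- signaling_network(ed2, nodes)
  cand2 <- find_mr_candidates(net2, "t", r = 2, m_min = 1)
  ann2 <- detect_feedback_loops(net2, cand2)
  expect_equal(ann2$n_loops[ann2$node_id == "c"], 0L)

  # candidate without an encoding gene: no loops, no error
  nodes3 <- nodes; nodes3$gene <- NA_character_
  net3 <- signaling_network(edges_df("c", "t", 1, "SIGNALING"), nodes3)
  ann3 <- detect_feedback_loops(net3,
                                find_mr_candidates(net3, "t", r = 2, m_min = 1))
  expect_equal(ann3$n_loops, 0L)

  # a net-negative signaling path is reported but flagged non-positive
  ed4 <- edges_df("c", "a", -1, "SIGNALING", "a", "t", 1, "SIGNALING",
                  "t", "c", 1, "TRANSCRIPTION")
  nodes4 <- data.frame(id = c("c", "a", "t"),
                       kind = c("PROTEIN", "PROTEIN", "TF"),
                       gene = c("gc", NA, NA), stringsAsFactors = FALSE)
  net4 <- signaling_network(ed4, nodes4)
  ann4 <- detect_feedback_loops(net4,
                                find_mr_candidates(net4, "t", r = 3, m_min = 1))
  lp4 <- ann4$loops[[which(ann4$node_id == "c")]]
  expect_false(lp4$positive)
  expect_equal(lp4$sign_product, -1)
})

test_that("loop detection equals exhaustive (candidate, tf) enumeration", {
  net <- gen_network(tf_nodes = c("TA", "TB", "TC"),
                     regulator_gene = "gr", n_nodes = 40,
                     n_distractors = 3, seed = 17)$network
  cand <- suppressWarnings(
    find_mr_candidates(net, c("TA", "TB", "TC"), r = 4, m_min = 1))
  ann <- detect_feedback_loops(net, cand)
  got <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i)
    if (nrow(ann$loops[[i]]))
      cbind(ann$node_id[i], ann$loops[[i]]$tf_node)))
  want <- do.call(rbind, brute_feedback_pairs(net, cand, r = 4))
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
})

test_that("ranking averages the three component ranks with dominance respected", {
  mk_cand <- function(df) {
    df$reached <- replicate(nrow(df), c(t = 1), simplify = FALSE)
    structure(df, class = c("mr_candidates", "data.frame"),
              tf_set = "t", r = 4L)
  }
  de <- structure(data.frame(gene_id = c("gA", "gB"), log2FC = c(1, 2),
                             t_mod = 1, df = 10, p = 0.01, p_adj = 0.02,
                             direction = "UP", stringsAsFactors = FALSE),
                  class = c("de_result", "data.frame"))
  reg <- data.frame(gene_id = c("gA", "gB"), score = c(0.2, 0.4))

  single <- mk_cand(data.frame(node_id = "A", gene_id = "gA",
                               mr_score = 0.5, n_tfs_reached = 1L,
                               stringsAsFactors = FALSE))
  expect_equal(rank_master_regulators(single, de, reg)$final_rank, 1L)

  # all 8 dominance patterns: B dominates A whenever all its components win
  for (pat in 0:7) {
    lfcs <- c(1, 2); regs <- c(0.2, 0.4); mrs <- c(0.5, 0.9)
    if (bitwAnd(pat, 1)) lfcs <- rev(lfcs)
    if (bitwAnd(pat, 2)) regs <- rev(regs)
    if (bitwAnd(pat, 4)) mrs <- rev(mrs)
    de_i <- de; de_i$log2FC <- lfcs
    reg_i <- reg; reg_i$score <- regs
    cand <- mk_cand(data.frame(node_id = c("A", "B"), gene_id = c("gA", "gB"),
                               mr_score = mrs, n_tfs_reached = 1L,
                               stringsAsFactors = FALSE))
    rk <- rank_master_regulators(cand, de_i, reg_i)
    dominant <- if (lfcs[1] > lfcs[2] && regs[1] > regs[2] && mrs[1] > mrs[2])
      "A" else if (lfcs[1] < lfcs[2] && regs[1] < regs[2] && mrs[1] < mrs[2])
      "B" else NA
    if (!is.na(dominant)) expect_equal(rk$node_id[1], dominant)
  }

  expect_error(rank_master_regulators(single[0, ], de, reg),
               class = "upstreamkit_precondition_error")
})
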