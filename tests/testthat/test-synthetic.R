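test_that("expression generator plants effects deterministically", {
  g1 <- gen_expression(n_genes = 300, n_up = 30, n_down = 10, seed = 5)
  g2 <- gen_expression(n_genes = 300, n_up = 30, n_down = 10, seed = 5)
  expect_identical(g1$matrix$values, g2$matrix$values)
  expect_equal(dim(g1$matrix), c(300L, 40L))
  expect_equal(nrow(g1$truth$up), 30)
  expect_true(all(g1$truth$up$effect >= 0.6 & g1$truth$up$effect <= 1.5))
  # effects actually present: planted-up group difference near the effect
  m <- g1$matrix$values
  d <- rowMeans(m[, g1$matrix$groups == "YES"]) -
       rowMeans(m[, g1$matrix$groups == "NO"])
  expect_equal(mean(d[g1$truth$up$gene_id] - g1$truth$up$effect), 0,
               tolerance = 0.1)
  g3 <- gen_expression(n_genes = 300, n_up = 30, n_down = 10, seed = 6)
  expect_false(identical(g1$matrix$values, g3$matrix$values))
})

test_that("motif generator hits the target information content and round-trips", {
  lib <- gen_motifs(n = 8, seed = 3)
  bits <- vapply(lib, function(m) mean(m$info) / log(2), 0)
  expect_true(all(abs(bits - 1.2) <= 0.2))
  expect_true(all(vapply(lib, length, 0L) >= 8))
  lib2 <- gen_motifs(n = 8, seed = 4)
  expect_false(identical(lib[[1]]$freqs, lib2[[1]]$freqs))

  path <- withr::local_tempfile(fileext = ".transfac")
  write_motifs(lib, path)
  back <- read_motifs(path)
  expect_equal(lapply(back, `[[`, "freqs"), lapply(lib, `[[`, "freqs"),
               tolerance = 1e-9)
})

test_that("promoter generator implants rediscoverable sites and respects GC", {
  lib <- gen_motifs(n = 5, seed = 11)
  yes <- sprintf("y%02d", 1:12); no <- sprintf("n%02d", 1:20)
  gp <- gen_promoters(lib, yes, no, module_motifs = names(lib)[1:2],
                      pi_implant = 1, decoy_rate = 0, seed = 8)
  expect_length(gp$promoters, 32)
  expect_equal(gp$promoters[[1]]$window_start, -1000L)
  expect_equal(nchar(gp$promoters[[1]]$sequence), 1100L)

  # every recorded implant is recovered by scanning at cutoff 0.9
  imp <- gp$truth$implants
  hits <- scan_all(gp$promoters[yes], lib[names(lib)[1:2]],
                   mss_cutoff = 0.9, css_cutoff = 0)
  coords <- unique(as.data.frame(hits)[, c("gene_id", "motif_id", "start")])
  found <- merge(imp, coords, by = c("gene_id", "motif_id", "start"))
  expect_equal(nrow(found), nrow(imp))
  # implanted cluster fits inside the declared window width
  spread <- tapply(imp$start, imp$gene_id, function(s) diff(range(s)))
  expect_true(all(spread <= gp$truth$W))

  # pi = 0: no implants recorded
  gp0 <- gen_promoters(lib, yes, no, pi_implant = 0, decoy_rate = 0, seed = 9)
  expect_null(gp0$truth$implants)

  # GC content of background-only promoters within 2% of the request
  gp3 <- gen_promoters(lib, character(0), no, gc = 0.6, pi_implant = 0,
                       decoy_rate = 0, seed = 10)
  gc_obs <- mean(vapply(gp3$promoters, function(p) {
    s <- strsplit(p$sequence, "")[[1]]
    mean(s %in% c("G", "C"))
  }, 0))
  expect_equal(gc_obs, 0.6, tolerance = 0.02)
})

test_that("network generator wiring is verified by graph search", {
  tfs <- c("TA", "TB", "TC", "TD")
  gn <- gen_network(tf_nodes = tfs, regulator_gene = "g0001", seed = 13)
  net <- gn$network
  g <- igraph::graph_from_data_frame(
    net$edges[net$edges$kind == "SIGNALING", 1:2], directed = TRUE,
    vertices = net$nodes$id)
  d <- igraph::distances(g, v = "REG1", to = tfs, mode = "out")
  expect_true(all(is.finite(d) & d <= 3))
  expect_equal(as.numeric(d[1, gn$truth$wiring$tf]), gn$truth$wiring$distance)
  # transcription feedback edges from every TF onto the regulator node
  tr <- net$edges[net$edges$kind == "TRANSCRIPTION", ]
  expect_setequal(tr$from, tfs)
  expect_true(all(tr$to == "REG1"))
  expect_equal(net$nodes["REG1", "gene"], "g0001")

  # distractors reach at most ceiling(|TF|/2) TFs
  for (dd in gn$truth$distractors) {
    reach <- sum(is.finite(igraph::distances(g, v = dd, to = tfs,
                                             mode = "out")))
    expect_lte(reach, ceiling(length(tfs) / 2))
  }

  # with no distractors the planted node is the unique full-coverage candidate
  gn0 <- gen_network(tf_nodes = tfs, regulator_gene = "g0001",
                     n_distractors = 0, seed = 14)
  cand <- find_mr_candidates(gn0$network, tfs, r = 4, m_min = 2)
  full <- cand$node_id[cand$n_tfs_reached == length(tfs)]
  expect_identical(full, "REG1")
})

test_that("gen_study is seed-deterministic with independent artifact streams", {
  s1 <- gen_study(seed = 2, n_genes = 400, n_up = 40, n_down = 10)
  s2 <- gen_study(seed = 2, n_genes = 400, n_up = 40, n_down = 10)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(lapply(s1$promoters, `[[`, "sequence"),
                   lapply(s2$promoters, `[[`, "sequence"))
  expect_identical(s1$network$edges, s2$network$edges)

  # artifacts come from independent streams: the expression sub-seed alone
  # reproduces the expression matrix
  e <- gen_expression(seed = upstreamkit:::derive_seed(2, 1L),
                      n_genes = 400, n_up = 40, n_down = 10)
  expect_identical(e$matrix$values, s1$expression$values)
})

test_that("the planted truth is cross-referentially consistent and serializes", {
  study <- gen_study(seed = 4, n_genes = 500, n_up = 60, n_down = 20,
                     n_promoter_yes = 30, n_promoter_no = 60)
  up <- study$truth$expression$up$gene_id
  # module target genes are planted up genes; regulator gene is the
  # strongest planted up gene and carries the module cluster
  yes_prom <- names(study$promoters)[1:30]
  expect_true(all(yes_prom %in% up))
  reg_gene <- study$truth$network$regulator_gene
  expect_identical(reg_gene, up[1])
  expect_true(reg_gene %in% study$truth$module$implants$gene_id)
  # module TFs exist as TF nodes in the network
  tfs <- unlist(study$truth$tf_of_motif)
  expect_true(all(tfs %in%
                  study$network$nodes$id[study$network$nodes$kind == "TF"]))

  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_true(all(file.exists(file.path(dir,
    c("expression.tsv", "groups.tsv", "promoters.fa", "motifs.transfac",
      "network.tsv", "nodes.tsv", "truth.json")))))
  tr <- read_truth(file.path(dir, "truth.json"))
  expect_equal(tr$seed, 4)
  expect_equal(tr$network$regulator_node, "REG1")
  expect_equal(sort(tr$module$module_motifs),
               sort(study$truth$module$module_motifs))
  expect_equal(tr$expression$up$gene_id, study$truth$expression$up$gene_id)

  # round trip of the generated inputs themselves
  m2 <- read_expression(file.path(dir, "expression.tsv"),
                        file.path(dir, "groups.tsv"))
  expect_equal(m2$values, study$expression$values, tolerance = 1e-12)
  p2 <- read_promoters(file.path(dir, "promoters.fa"))
  expect_identical(lapply(p2, `[[`, "sequence"),
                   lapply(study$promoters, `[[`, "sequence"))
})
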