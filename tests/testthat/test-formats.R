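test_that("expression TSV round-trips and validates", {
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  groups <- setNames(c("YES", "YES", "NO", "NO"), colnames(vals))
  x <- expression_matrix(vals, groups)
  expect_equal(dim(x), c(3L, 4L))

  mp <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, mp, gp)
  y <- read_expression(mp, gp)
  expect_equal(y$values, x$values, tolerance = 1e-12)
  expect_identical(y$groups, x$groups)

  # missing sample in groups names the sample
  g2 <- groups[-2]
  gp2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(names(g2), g2), gp2, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_expression(mp, gp2), "s2",
               class = "upstreamkit_format_error")

  # non-numeric cell reported with coordinates
  bad <- read.table(mp, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  bad[2, 3] <- "oops"
  mp2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, mp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(mp2, gp), "row 2.*g2",
               class = "upstreamkit_format_error")

  # duplicate gene ids rejected
  dup <- rbind(bad[1, ], bad[1, ])
  mp3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(dup, mp3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(mp3, gp), "duplicate",
               class = "upstreamkit_format_error")
})

test_that("JASPAR and TRANSFAC motif dialects parse and round-trip", {
  jp <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">MA0001.1 TFA",
               "A [ 10  0  5  2 ]",
               "C [  0 12  5  2 ]",
               "G [  2  0  1  8 ]",
               "T [  0  0  1  0 ]",
               ">MA0002.1 TFB",
               "A 1 2 3 4 5",
               "C 4 3 2 1 0",
               "G 0 0 0 0 0",
               "T 7 7 7 7 7"), jp)
  lib <- read_motifs(jp)
  expect_length(lib, 2)
  expect_equal(length(lib[["MA0001.1"]]), 4L)
  expect_equal(length(lib[["MA0002.1"]]), 5L)
  expect_equal(lib[["MA0002.1"]]$tf_name, "TFB")

  tf <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("AC  M001", "NA  TFC", "P0      A      C      G      T",
               "01 12 0 0 0", "02 0 12 0 0", "03 0 0 12 0", "04 0 0 0 12",
               "//"), tf)
  lib2 <- read_motifs(tf)
  expect_length(lib2, 1)
  # counts (12,0,0,0) normalize to ~(1,0,0,0) up to the pseudocount
  expect_equal(unname(lib2[["M001"]]$freqs[1, "A"]), 1.001 / 1.004,
               tolerance = 1e-9)

  # write/read round trip preserves frequencies
  out <- withr::local_tempfile(fileext = ".transfac")
  write_motifs(lib, out)
  lib3 <- read_motifs(out)
  expect_equal(lib3[["MA0001.1"]]$freqs, lib[["MA0001.1"]]$freqs,
               tolerance = 1e-9)
  expect_equal(lib3[["MA0002.1"]]$info, lib[["MA0002.1"]]$info,
               tolerance = 1e-9)

  writeLines(c("just", "noise"), out)
  expect_error(read_motifs(out), class = "upstreamkit_format_error")
  tf_zero <- withr::local_tempfile()
  writeLines(c("AC  M002", "P0 A C G T", "01 1 1 1 1", "02 0 0 0 0",
               "03 1 1 1 1", "04 1 1 1 1", "//"), tf_zero)
  expect_error(read_motifs(tf_zero), "zero-sum",
               class = "upstreamkit_format_error")
})

test_that("promoter coordinates are TSS-relative half-open windows", {
  p <- promoter_record("g1", strrep("ACGT", 275), -1000L, 100L)
  expect_equal(nchar(p$sequence), 1100L)
  expect_error(promoter_record("g1", "ACGT", -3L, 2L),
               class = "upstreamkit_format_error")    # length mismatch
  expect_error(promoter_record("g1", strrep("A", 10), 0L, 10L),
               class = "upstreamkit_format_error")    # start must be < 0

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 -1000 100", p$sequence, ">g2", "ACGTACGTAC"), fa)
  ps <- read_promoters(fa)
  expect_equal(ps$g1$window_start, -1000L)
  expect_equal(ps$g1$window_end, 100L)
  # plain header: window defaults to [-length, 0)
  expect_equal(ps$g2$window_start, -10L)
  expect_equal(ps$g2$window_end, 0L)

  out <- withr::local_tempfile(fileext = ".fa")
  write_promoters(ps, out)
  ps2 <- read_promoters(out)
  expect_identical(lapply(ps2, unclass), lapply(ps, unclass))
})

test_that("network edge lists round-trip with typed nodes and defaults", {
  ed <- edges_df("a", "b", 1, "SIGNALING",
                 "b", "c", -1, "SIGNALING",
                 "t", "r", 1, "TRANSCRIPTION",
                 "c", "t", 1, "SIGNALING",
                 "a", "t", 1, "SIGNALING")
  nodes <- data.frame(id = c("t", "r"), kind = c("TF", "PROTEIN"),
                      gene = c(NA, "g9"), stringsAsFactors = FALSE)
  net <- signaling_network(ed, nodes)
  expect_equal(nrow(net$edges), 5)
  # undeclared endpoints auto-created as PROTEIN
  expect_equal(net$nodes["a", "kind"], "PROTEIN")

  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, ep, np)
  net2 <- read_network(ep, np)
  expect_equal(net2$edges[order(net2$edges$from, net2$edges$to), ],
               net$edges[order(net$edges$from, net$edges$to), ],
               ignore_attr = TRUE)
  expect_equal(sort(net2$nodes$id), sort(net$nodes$id))

  expect_error(signaling_network(edges_df("a", "b", 1, "WEIRD")),
               "unknown edge kind", class = "upstreamkit_format_error")
  # transcription edge must have TF source and gene-bearing target
  expect_error(signaling_network(edges_df("a", "b", 1, "TRANSCRIPTION")),
               class = "upstreamkit_format_error")
})
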