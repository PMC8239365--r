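test_that("module_score matches brute-force window enumeration exactly", {
  set.seed(31)
  mod <- composite_module(
    data.frame(motif_id = c("MA", "MB", "MC"),
               theta = c(0.75, 0.80, 0.70), weight = c(1, 2, 1)),
    window_W = 120L)
  for (rep in 1:25) {
    n <- sample(0:14, 1)
    hits <- manual_hits(gene = rep("g1", n),
                        motif = sample(c("MA", "MB", "MC", "MD"), n, TRUE),
                        start = sample(-900:90, max(n, 1))[seq_len(n)],
                        mss = runif(n, 0.5, 1))
    expect_equal(module_score(hits, mod),
                 brute_module_score(hits, mod, start_range = -1050:100),
                 tolerance = 1e-12)
  }
})

test_that("module_score base cases and window monotonicity", {
  mod <- composite_module(
    data.frame(motif_id = c("MA", "MB"), theta = c(0.75, 0.75),
               weight = c(1, 1)),
    window_W = 300L)
  expect_equal(module_score(manual_hits(character(0), character(0),
                                        integer(0), double(0)), mod), 0)

  # single passing hit: w * (mss - theta); the other motif contributes 0
  one <- manual_hits("g1", "MA", -500L, 0.85)
  expect_equal(module_score(one, mod), 0.5 * 0.1, tolerance = 1e-12)

  # two hits 600 bp apart: W = 300 counts only the better single window;
  # widening to 700 joins them and cannot decrease the score
  two <- manual_hits(c("g1", "g1"), c("MA", "MB"), c(-800L, -200L),
                     c(0.85, 0.95))
  s300 <- module_score(two, mod)
  mod700 <- composite_module(mod$motifs, window_W = 700L)
  s700 <- module_score(two, mod700)
  expect_equal(s300, 0.5 * 0.2, tolerance = 1e-12)
  expect_equal(s700, 0.5 * 0.1 + 0.5 * 0.2, tolerance = 1e-12)
  expect_gte(s700, s300)
})

test_that("fitness is the Welch t of module scores minus the complexity penalty", {
  mod <- composite_module(
    data.frame(motif_id = c("MA", "MB"), theta = c(0.75, 0.75),
               weight = c(1, 1)),
    window_W = 300L)
  yes <- sprintf("y%02d", 1:20); no <- sprintf("n%02d", 1:20)
  # identical degenerate score distributions -> fitness = -lambda * k
  none <- manual_hits(character(0), character(0), integer(0), double(0))
  expect_equal(module_fitness(mod, none, yes, no, lambda = 0.1), -0.2)

  # perfect separation: yes scores all 0.125, no scores all 0
  hits <- manual_hits(gene = yes, motif = "MA", start = -100L, mss = 1.0)
  t_hand <- (0.125 - 0) / sqrt(1e-12 / 20 + 1e-12 / 20)
  expect_equal(module_fitness(mod, hits, yes, no, lambda = 0.1),
               t_hand - 0.2, tolerance = 1e-6)
})

test_that("the GA is seed-deterministic with non-decreasing elite fitness", {
  inst <- tiny_cma_instance(seed = 101)
  f1 <- run_cma(inst$hits, inst$yes, inst$no, pool = names(inst$motifs),
                k_max = 2, n_modules = 1, pop = 30, gens = 12, n_perm = 0,
                seed = 77)
  f2 <- run_cma(inst$hits, inst$yes, inst$no, pool = names(inst$motifs),
                k_max = 2, n_modules = 1, pop = 30, gens = 12, n_perm = 0,
                seed = 77)
  expect_identical(f1$modules, f2$modules)
  expect_identical(f1$scores, f2$scores)
  expect_true(all(diff(f1$trace) >= 0))
  f3 <- run_cma(inst$hits, inst$yes, inst$no, pool = names(inst$motifs),
                k_max = 2, n_modules = 1, pop = 30, gens = 12, n_perm = 0,
                seed = 78)
  expect_false(identical(f1$seed, f3$seed))

  expect_error(run_cma(inst$hits, inst$yes, inst$no, pool = "M01", seed = 1),
               class = "upstreamkit_precondition_error")
})

test_that("GA reaches the exhaustive-search optimum on two-motif instances", {
  wins <- 0L
  for (seed in 1:5) {
    inst <- tiny_cma_instance(seed = seed)
    ex <- exhaustive_module_fitness(inst$hits, inst$yes, inst$no,
                                    names(inst$motifs))
    ga <- run_cma(inst$hits, inst$yes, inst$no, pool = names(inst$motifs),
                  k_max = 2, n_modules = 1, pop = 40, gens = 25, n_perm = 0,
                  seed = seed * 13)
    if (ga$modules[[1]]$fitness >= 0.99 * ex) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("adding an irrelevant motif does not raise fitness in expectation", {
  diffs <- vapply(1:10, function(seed) {
    inst <- tiny_cma_instance(seed = 200 + seed)
    decoy <- gen_motifs(n = 1, length_range = c(10L, 10L), seed = 900 + seed)
    decoy[[1]]$motif_id <- "DEC"
    dec_hits <- scan_all(inst$promoters, decoy)
    all_hits <- rbind(as.data.frame(inst$hits), as.data.frame(dec_hits))
    base <- composite_module(
      data.frame(motif_id = names(inst$motifs), theta = 0.8, weight = 1),
      window_W = 300L)
    plus <- composite_module(
      rbind(base$motifs,
            data.frame(motif_id = "DEC", theta = 0.8, weight = 1 / 2)),
      window_W = 300L)
    module_fitness(plus, all_hits, inst$yes, inst$no) -
      module_fitness(base, all_hits, inst$yes, inst$no)
  }, 0)
  expect_lte(mean(diffs), 0)
})

test_that("permutation significance is exact for a perfectly separating module", {
  yes <- sprintf("y%02d", 1:15); no <- sprintf("n%02d", 1:15)
  hits <- manual_hits(gene = yes, motif = rep(c("MA", "MB"), length.out = 15),
                      start = -150L, mss = 1.0)
  mod <- composite_module(
    data.frame(motif_id = c("MA", "MB"), theta = c(0.70, 0.70),
               weight = c(1, 1)),
    window_W = 300L)
  p <- permutation_significance(mod, hits, yes, no, n_perm = 199, seed = 4)
  expect_equal(p, 1 / 200)
  expect_error(permutation_significance(mod, hits, yes, no, n_perm = 10),
               class = "upstreamkit_precondition_error")
})

test_that("regulatory scores are the per-gene maximum over modules", {
  m1 <- composite_module(data.frame(motif_id = c("MA", "MB"), theta = 0.75,
                                    weight = 1), window_W = 300L)
  m2 <- composite_module(data.frame(motif_id = c("MC", "MD"), theta = 0.75,
                                    weight = 1), window_W = 300L)
  hits <- manual_hits(c("g1", "g2"), c("MA", "MC"), c(-100L, -200L),
                      c(0.95, 0.85))
  rs <- regulatory_scores(list(m1, m2), hits, c("g1", "g2", "g3"))
  expect_equal(rs$score, c(0.5 * 0.2, 0.5 * 0.1, 0), tolerance = 1e-12)
  # matches module_score applied per gene
  expect_equal(rs$score[1],
               max(module_score(hits[hits$gene_id == "g1", ], m1),
                   module_score(hits[hits$gene_id == "g1", ], m2)))
})
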