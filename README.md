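# upstreamkit

Upstream regulatory analysis for two-group expression studies: from
differential expression to candidate master regulators.

Given (a) a log2 expression matrix with a two-group annotation (condition
"yes" vs background "no", e.g. short- vs long-term survivors in a tumor
cohort), (b) promoter sequences, (c) a motif library (TRANSFAC or JASPAR
format), and (d) a directed, signed signaling network, the pipeline asks the
question *what sits upstream of the observed dysregulation*:

1. **Differential expression** — empirical-Bayes moderated t. Per-gene
   pooled variances `s_g^2` (on `d_g` df) are shrunk toward a prior
   `s_0^2` with prior df `d_0` estimated by trigamma-inversion method of
   moments: `s~_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)`, with
   `t = log2FC / (s~_g sqrt(1/n1 + 1/n2))` on `d_0 + d_g` df and
   Benjamini–Hochberg FDR control. Significantly upregulated genes
   (adjusted p < 0.05, log2FC > 0.5) form the "yes" promoter set;
   expression-matched non-significant genes the "no" set.
2. **Promoter scanning** — MATCH-style scoring of every offset, both
   strands, in TSS-relative windows (default [−1000, +100)):
   `MSS = (Current − Min)/(Max − Min)` with
   `Current = Σ_i I(i) f(i, s_i)`, `I(i) = Σ_b f(i,b) ln 4f(i,b)`, and the
   core similarity CSS computed the same way on the 5 most informative
   consecutive positions.
3. **Site enrichment** — per motif, the pseudocounted occurrences-per-
   promoter yes/no ratio and an exact binomial tail p-value under a
   length-proportional null, BH-adjusted across motifs.
4. **Composite modules** — a genetic algorithm searches for small sets of
   weighted, thresholded motifs whose sites co-occur within a bounded
   promoter window and jointly discriminate yes from no promoters
   (Welch-t fitness minus a complexity penalty), with label-permutation
   significance and a per-gene regulatory score.
5. **Master regulators** — breadth-first search over the reversed
   signaling graph finds nodes reaching the module TFs within a radius,
   scores them by distance-discounted coverage, detects positive feedback
   loops closed by TF→gene transcription evidence, and ranks candidates by
   the average of three component ranks (log2FC, regulatory score, network
   score).

A synthetic-study generator (`gen_study()`) plants ground truth at every
level — effect sizes, promoter site clusters, an upstream regulator wired
to the module TFs with transcriptional feedback — so the whole chain is
testable without any external download.

## Worked example

```r
library(upstreamkit)

study <- gen_study(seed = 1)
#> synthetic_study (seed 1): 2000 genes x 40 samples, 250 promoters, 20 motifs, 309 network nodes
#> planted: 150 up / 100 down genes; module M10+M03+M19; regulator REG1 (gene g0001)

de <- moderated_de(study$expression)
de
#> de_result: 2000 genes (148 UP, 97 DOWN); log2FC = YES - NO
#> prior: d0 = 2240.28, s0^2 = 0.2481
#>  gene_id log2FC  t_mod   df         p     p_adj direction
#>    g0018  1.761  11.18 2278 2.704e-28 5.407e-25        UP
#>    g0012  1.717  10.91 2278 4.692e-27 4.692e-24        UP
#>    g0010  1.699  10.82 2278 1.268e-26 6.568e-24        UP

sets <- select_degs(de)
hits <- scan_all(study$promoters, study$motifs)
yes  <- intersect(sets$yes_genes, names(study$promoters))
no   <- intersect(sets$no_genes,  names(study$promoters))

enr <- enrich_motifs(hits, yes, no)
head(as.data.frame(enr), 4)
#>   motif_id tf_name occ_yes occ_no    ratio      p_binom        p_adj
#> 1      M19    TF19      81     72 2.338207 1.371393e-07 2.742786e-06
#> 2      M10    TF10      79    101 1.629163 8.888836e-04 8.888836e-03
#> 3      M03    TF03     108    161 1.397399 4.839861e-03 3.226574e-02
#> 4      M15    TF15     759   1510 1.045852 1.640335e-01 7.544707e-01

fit <- run_cma(hits, yes, no, pool = rank_tfs(enr)$motif_id, seed = 42)
fit
#> cma_fit: 1 module(s) over a 3-motif pool (seed 42)
#>   module 1: M03 + M19 | W = 300 bp, fitness = 17.154, p_perm = 0.005

cand <- find_mr_candidates(study$network,
          unique(hits$tf_name[hits$motif_id %in% coef(fit)$motif_id]))
cand <- detect_feedback_loops(study$network, cand, fit$modules[[1]], hits = hits)
rank_master_regulators(cand, de,
                       regulatory_scores(fit, hits, names(study$promoters)))
#> mr_ranking: 3 candidate(s); combined rank = mean of log2FC, regulatory-score and network-score ranks
#>  final_rank node_id gene_id   lfc reg_score mr_score n_tfs_reached n_loops
#>           1    REG1   g0001 1.399     0.174        1             2       2
#>           2    DIS1    <NA> 0.000     0.000        1             2       0
#>           3    DIS3    <NA> 0.000     0.000        1             2       0
```

The three enriched motifs are exactly the planted module (M19/M10/M03); the
fitted composite module separates yes from no promoters (permutation
p = 0.005); and the planted regulator REG1 — reaching both module TFs, the
most upregulated encoding gene, two positive feedback loops — ranks first,
ahead of the distractor hubs, which have network support but no expression
or promoter evidence.

The same stages run from a single YAML config and an output directory:

```r
run_pipeline("study.yaml", "out/")   # writes de.tsv, enrich.tsv,
                                     # module.json, mr.json, report.md
```

or from the shell via the thin wrapper `inst/scripts/upstreamkit.R`
(subcommands `simulate`, `de`, `scan`, `enrich`, `cma`, `mr`, `run`).

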