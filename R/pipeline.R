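# End-to-end orchestration: a single validated configuration drives the five
# stages (DE -> scan -> enrichment -> composite modules -> master
# regulators), writing plain TSV/JSON intermediates so any stage can be run
# or replaced standalone. Every output embeds the config hash and seeds.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with every tunable at its default.
#' Unknown keys in a user configuration are rejected by
#' [validate_config()].
#'
#' @param ... Top-level overrides (partial nested lists are merged).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    inputs = list(expression = NULL, groups = NULL, promoters = NULL,
                  motifs = NULL, network = NULL, nodes = NULL),
    de = list(alpha = 0.05, lfc = 0.5, ns_lfc = 0.1, cap_ratio = 10),
    scan = list(mss_cutoff = 0.75, css_cutoff = 0.70),
    enrich = list(p_cut = 0.05, ratio_cut = 1.0, null_model = "length"),
    cma = list(k_max = 6, n_modules = 2, pop = 200, gens = 100,
               p_cross = 0.7, p_mut = 0.3, lambda = 0.1, n_perm = 199,
               objective = "welch"),
    mr = list(radius = 4, m_min = 2, score = "discounted"),
    stages = list(de = TRUE, scan = TRUE, enrich = TRUE, cma = TRUE,
                  mr = TRUE),
    seed = 1L)
  user <- list(...)
  merge_cfg <- function(base, upd, path = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        uk_format_error(sprintf("unknown config key: %s%s", path, nm))
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- merge_cfg(base[[nm]], upd[[nm]],
                                paste0(path, nm, "."))
      } else base[[nm]] <- upd[[nm]]
    }
    base
  }
  structure(merge_cfg(cfg, user), class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#' @param cfg A `pipeline_config`.
#' @return The config, invisibly; errors on invalid values.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    uk_format_error("config seed must be a single integer")
  with(cfg$de, {
    if (alpha <= 0 || alpha >= 1) uk_format_error("de.alpha must be in (0,1)")
    if (lfc < 0) uk_format_error("de.lfc must be >= 0")
  })
  with(cfg$scan, {
    if (mss_cutoff < 0 || mss_cutoff > 1 || css_cutoff < 0 || css_cutoff > 1)
      uk_format_error("scan cutoffs must lie in [0,1]")
  })
  if (cfg$mr$radius < 1) uk_format_error("mr.radius must be >= 1")
  invisible(cfg)
}

config_hash <- function(cfg) {
  fnv1a_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"))
}

uk_log <- function(fmt, ...) {
  message(sprintf(paste0("[upstreamkit] ", fmt), ...))
}

write_tsv_stamped <- function(df, path, hash, seed, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# config_hash=%s seed=%d", hash, as.integer(seed)),
               extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full upstream-analysis pipeline
#'
#' Executes the stages in order from a validated configuration: moderated
#' differential expression and yes/no set selection, promoter scanning,
#' motif enrichment, composite-module discovery, and master-regulator
#' search with feedback-loop detection and ranking. Writes `de.tsv`,
#' `enrich.tsv`, `module.json`, `mr.json` and `report.md` into `out_dir`;
#' a rerun with an identical configuration and seed is byte-identical.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param out_dir Output directory.
#' @return An object of class `pipeline_result` collecting every stage's
#'   in-memory result plus the ranked master-regulator table.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- as.integer(config$seed)
  t_all <- proc.time()[3]

  stage_input <- function(key) {
    p <- config$inputs[[key]]
    if (is.null(p) || !file.exists(p))
      uk_error(sprintf("stage input missing: %s (%s)", key, p %||% "unset"),
               class = "upstreamkit_stage_error")
    p
  }

  # stage 0/1: differential expression
  if (!isTRUE(config$stages$de))
    uk_error("stage de is required", class = "upstreamkit_stage_error")
  t0 <- proc.time()[3]
  mat <- read_expression(stage_input("expression"), stage_input("groups"))
  de <- moderated_de(mat, alpha = config$de$alpha, lfc = config$de$lfc)
  sets <- select_degs(de, alpha = config$de$alpha, lfc = config$de$lfc,
                      ns_lfc = config$de$ns_lfc,
                      cap_ratio = config$de$cap_ratio,
                      seed = derive_seed(seed, 11L))
  write_tsv_stamped(as.data.frame(de), file.path(out_dir, "de.tsv"), hash, seed,
                    "# log2FC = YES (condition) - NO (background)")
  uk_log("de: %d genes, %d up / %d down [%.1fs]", nrow(de),
         length(sets$yes_genes), length(sets$down_genes),
         proc.time()[3] - t0)
  if (!length(sets$yes_genes)) {
    report <- c("# Upstream analysis report", "",
                sprintf("config_hash: %s, seed: %d", hash, seed), "",
                "No significantly upregulated genes at the configured",
                "thresholds; downstream stages were not run.")
    writeLines(report, file.path(out_dir, "report.md"))
    return(structure(list(de = de, sets = sets, hits = NULL, enrich = NULL,
                          cma = NULL, mr = NULL, config = config,
                          hash = hash, out_dir = out_dir),
                     class = "pipeline_result"))
  }

  # stage 2: promoter scanning
  if (!isTRUE(config$stages$scan))
    uk_error("stage scan disabled but required downstream",
             class = "upstreamkit_stage_error")
  t0 <- proc.time()[3]
  promoters <- read_promoters(stage_input("promoters"))
  motifs <- read_motifs(stage_input("motifs"),
                        mss_cutoff = config$scan$mss_cutoff,
                        css_cutoff = config$scan$css_cutoff)
  yes_scan <- intersect(sets$yes_genes, names(promoters))
  no_scan <- intersect(sets$no_genes, names(promoters))
  if (!length(yes_scan))
    uk_error("no promoter sequence available for any yes gene",
             class = "upstreamkit_stage_error")
  hits <- scan_all(promoters[c(yes_scan, no_scan)], motifs)
  uk_log("scan: %d hits over %d promoters x %d motifs [%.1fs]", nrow(hits),
         length(yes_scan) + length(no_scan), length(motifs),
         proc.time()[3] - t0)

  # stage 3: enrichment
  if (!isTRUE(config$stages$enrich))
    uk_error("stage enrich disabled but required downstream",
             class = "upstreamkit_stage_error")
  t0 <- proc.time()[3]
  enr <- enrich_motifs(hits, yes_scan, no_scan,
                       null_model = config$enrich$null_model)
  pool_tab <- rank_tfs(enr, p_cut = config$enrich$p_cut,
                       ratio_cut = config$enrich$ratio_cut)
  write_tsv_stamped(as.data.frame(enr), file.path(out_dir, "enrich.tsv"),
                    hash, seed)
  uk_log("enrich: %d motifs, %d in candidate pool [%.1fs]", nrow(enr),
         nrow(pool_tab), proc.time()[3] - t0)

  # stage 4: composite modules
  module_path <- file.path(out_dir, "module.json")
  if (!isTRUE(config$stages$cma)) {
    cma <- NULL
  } else {
    t0 <- proc.time()[3]
    cma <- run_cma(hits, yes_scan, no_scan, pool = pool_tab$motif_id,
                   k_max = config$cma$k_max, n_modules = config$cma$n_modules,
                   pop = config$cma$pop, gens = config$cma$gens,
                   p_cross = config$cma$p_cross, p_mut = config$cma$p_mut,
                   lambda = config$cma$lambda,
                   objective = config$cma$objective,
                   n_perm = config$cma$n_perm, seed = derive_seed(seed, 12L))
    write_module_json(cma, module_path, hash, seed)
    uk_log("cma: %d module(s), best fitness %.3f [%.1fs]",
           length(cma$modules), max(vapply(cma$modules, `[[`, 0, "fitness")),
           proc.time()[3] - t0)
  }

  # stage 5: master regulators
  mr_ranked <- NULL
  if (isTRUE(config$stages$mr)) {
    if (is.null(cma) || !file.exists(module_path))
      uk_error("stage mr requires the cma stage: missing module.json",
               class = "upstreamkit_stage_error")
    t0 <- proc.time()[3]
    network <- read_network(stage_input("network"),
                            nodes_path = config$inputs$nodes)
    tf_map <- stats::setNames(hits$tf_name, hits$motif_id)
    tf_map <- tf_map[!duplicated(names(tf_map))]
    module_tfs <- unique(unname(
      tf_map[unlist(lapply(cma$modules, function(m) m$motifs$motif_id))]))
    module_tfs <- intersect(module_tfs, network$nodes$id)
    if (length(module_tfs) < config$mr$m_min)
      uk_error("too few module TFs present in the network",
               class = "upstreamkit_stage_error")
    cand <- find_mr_candidates(network, module_tfs, r = config$mr$radius,
                               m_min = config$mr$m_min,
                               score = config$mr$score)
    if (nrow(cand)) {
      cand_genes <- unique(stats::na.omit(cand$gene_id))
      reg <- regulatory_scores(cma, hits,
                               genes = union(cand_genes, names(promoters)))
      cand <- detect_feedback_loops(network, cand, cma$modules[[1]],
                                    hits = scan_all(
                                      promoters[intersect(cand_genes,
                                                          names(promoters))],
                                      motifs),
                                    tf_map = tf_map)
      mr_ranked <- rank_master_regulators(cand, de, reg)
      write_mr_json(mr_ranked, file.path(out_dir, "mr.json"), hash, seed)
      mr_tsv <- as.data.frame(mr_ranked)[, c("final_rank", "node_id",
                                             "gene_id", "lfc", "reg_score",
                                             "mr_score", "n_tfs_reached",
                                             "n_loops")]
      write_tsv_stamped(mr_tsv, file.path(out_dir, "mr.tsv"), hash, seed)
    }
    uk_log("mr: %d candidate(s) [%.1fs]",
           if (is.null(mr_ranked)) 0L else nrow(mr_ranked),
           proc.time()[3] - t0)
  }

  write_report(out_dir, hash, seed, de, sets, enr, cma, mr_ranked)
  uk_log("pipeline complete [%.1fs total]", proc.time()[3] - t_all)
  structure(list(de = de, sets = sets, hits = hits, enrich = enr,
                 pool = pool_tab, cma = cma, mr = mr_ranked,
                 config = config, hash = hash, out_dir = out_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (config %s): outputs in %s\n", x$hash, x$out_dir))
  cat(sprintf("  de: %d up / %d down of %d genes\n", length(x$sets$yes_genes),
              length(x$sets$down_genes), nrow(x$de)))
  if (!is.null(x$cma)) print(x$cma)
  if (!is.null(x$mr)) print(x$mr, n = 5)
  invisible(x)
}

write_module_json <- function(cma, path, hash, seed) {
  obj <- list(config_hash = hash, seed = as.integer(seed),
              cma_seed = cma$seed, objective = cma$objective,
              lambda = cma$lambda, pool = cma$pool,
              modules = lapply(cma$modules, function(m)
                list(motifs = m$motifs, window_W = m$window_W,
                     fitness = m$fitness, p_perm = m$p_perm)),
              scores = cma$scores)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read a composite-module JSON written by the pipeline
#' @param path Path to `module.json`.
#' @return A `cma_fit`-like list with `modules` and `scores`.
#' @export
read_module_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  modules <- lapply(obj$modules, function(m)
    composite_module(
      data.frame(motif_id = unlist(m$motifs$motif_id),
                 theta = unlist(m$motifs$theta),
                 weight = unlist(m$motifs$weight),
                 stringsAsFactors = FALSE),
      window_W = m$window_W, fitness = m$fitness,
      p_perm = if (is.null(m$p_perm)) NA_real_ else m$p_perm))
  scores <- as.data.frame(lapply(obj$scores, unlist),
                          stringsAsFactors = FALSE)
  list(modules = modules, scores = scores,
       pool = unlist(obj$pool), seed = obj$cma_seed)
}

write_mr_json <- function(mr, path, hash, seed) {
  cand <- lapply(seq_len(nrow(mr)), function(i) {
    list(node_id = mr$node_id[i], gene_id = mr$gene_id[i],
         lfc = mr$lfc[i], reg_score = mr$reg_score[i],
         mr_score = mr$mr_score[i],
         n_tfs_reached = mr$n_tfs_reached[i],
         reached = as.list(mr$reached[[i]]),
         combined_rank = mr$combined_rank[i], final_rank = mr$final_rank[i],
         loops = mr$loops[[i]])
  })
  jsonlite::write_json(list(config_hash = hash, seed = as.integer(seed),
                            candidates = cand),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(path)
}

write_report <- function(out_dir, hash, seed, de, sets, enr, cma, mr) {
  fmt_tab <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) fmt_num(x, 4))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "), "|"))
    c(header, sep, rows)
  }
  lines <- c("# Upstream analysis report", "",
             sprintf("config_hash: %s, seed: %d", hash, as.integer(seed)),
             "", "## Differential expression",
             sprintf("%d genes tested; %d upregulated, %d downregulated (log2FC = YES - NO).",
                     nrow(de), length(sets$yes_genes), length(sets$down_genes)),
             "", "Top upregulated genes:", "")
  top_up <- de[de$direction == "UP", , drop = FALSE]
  top_up <- top_up[order(-top_up$log2FC), , drop = FALSE]
  lines <- c(lines, fmt_tab(utils::head(
    top_up[, c("gene_id", "log2FC", "p", "p_adj")], 5)))
  lines <- c(lines, "", "Top downregulated genes:", "")
  top_dn <- de[de$direction == "DOWN", , drop = FALSE]
  top_dn <- top_dn[order(top_dn$log2FC), , drop = FALSE]
  lines <- c(lines, fmt_tab(utils::head(
    top_dn[, c("gene_id", "log2FC", "p", "p_adj")], 5)))
  if (!is.null(enr)) {
    lines <- c(lines, "", "## Motif enrichment (yes vs no promoters)", "",
               fmt_tab(utils::head(as.data.frame(enr)[, c(
                 "motif_id", "tf_name", "occ_yes", "occ_no", "ratio",
                 "p_binom", "p_adj")], 8)))
  }
  if (!is.null(cma)) {
    lines <- c(lines, "", "## Composite modules", "")
    for (i in seq_along(cma$modules)) {
      m <- cma$modules[[i]]
      lines <- c(lines,
                 sprintf("Module %d (window %d bp, fitness %s, p_perm %s):",
                         i, m$window_W, fmt_num(m$fitness, 4),
                         fmt_num(m$p_perm, 4)), "",
                 fmt_tab(m$motifs), "")
    }
  }
  if (!is.null(mr)) {
    lines <- c(lines, "## Master regulators", "",
               fmt_tab(utils::head(as.data.frame(mr)[, c(
                 "final_rank", "node_id", "gene_id", "lfc", "reg_score",
                 "mr_score", "n_tfs_reached", "n_loops")], 8)))
  }
  writeLines(lines, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
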