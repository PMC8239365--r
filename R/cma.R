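# Composite-module discovery: sets of weighted, thresholded motifs whose
# clustered binding sites discriminate yes from no promoters, optimized by a
# seeded genetic algorithm; plus the per-gene regulatory score used by the
# master-regulator ranking.

# ---------------------------------------------------------------------------
# Module objects and scoring

#' Construct a composite module
#'
#' A composite module is a set of 2..k motifs, each with a similarity
#' threshold `theta` in `[0.5, 1]` and a positive weight (normalized to sum
#' to 1), plus a window width in bp. A promoter's module score is the best
#' window placement of width `window_W`:
#' `max_s sum_m w_m * max(0, best mss of motif m in [s, s+W) - theta_m)`.
#'
#' @param motifs data.frame with columns `motif_id`, `theta`, `weight`.
#' @param window_W Window width in bp.
#' @param fitness,p_perm Optional fit statistics.
#' @return An object of class `composite_module`.
#' @export
composite_module <- function(motifs, window_W, fitness = NA_real_,
                             p_perm = NA_real_) {
  motifs <- as.data.frame(motifs, stringsAsFactors = FALSE)
  stopifnot(all(c("motif_id", "theta", "weight") %in% names(motifs)))
  if (nrow(motifs) < 2) uk_precondition_error("a composite module needs >= 2 motifs")
  if (anyDuplicated(motifs$motif_id))
    uk_precondition_error("duplicate motif in module")
  if (any(motifs$theta < 0.5 | motifs$theta > 1))
    uk_precondition_error("module thresholds must lie in [0.5, 1]")
  if (any(motifs$weight <= 0))
    uk_precondition_error("module weights must be positive")
  motifs$weight <- motifs$weight / sum(motifs$weight)
  structure(list(motifs = motifs, window_W = as.integer(window_W),
                 fitness = fitness, p_perm = p_perm),
            class = "composite_module")
}

#' @export
print.composite_module <- function(x, ...) {
  cat(sprintf("composite_module: %d motifs, window %d bp, fitness %.4g, p_perm %s\n",
              nrow(x$motifs), x$window_W, x$fitness,
              ifelse(is.na(x$p_perm), "NA", fmt_num(x$p_perm))))
  print.data.frame(x$motifs, digits = 3, row.names = FALSE)
  invisible(x)
}

# Flat hit index over a fixed promoter universe and motif pool: hits sorted
# by start within each promoter, with a 0-based slice pointer per promoter.
build_hit_index <- function(hits, gene_ids, pool) {
  h <- hits[hits$gene_id %in% gene_ids & hits$motif_id %in% pool, , drop = FALSE]
  h$mot <- match(h$motif_id, pool)
  h$g <- match(h$gene_id, gene_ids)
  h <- h[order(h$g, h$start), , drop = FALSE]
  counts <- tabulate(h$g, nbins = length(gene_ids))
  list(start = as.integer(h$start), mss = as.numeric(h$mss),
       mot = as.integer(h$mot), ptr = as.integer(c(0L, cumsum(counts))),
       genes = gene_ids, pool = pool)
}

index_scores <- function(index, motif_ids, theta, weight, W) {
  slot_of <- integer(length(index$pool))
  slot_of[match(motif_ids, index$pool)] <- seq_along(motif_ids)
  cpp_module_scores(index$start, index$mss, index$mot, index$ptr,
                    slot_of, as.numeric(theta),
                    as.numeric(weight / sum(weight)), as.integer(W))
}

#' Score one promoter's hits under a composite module
#'
#' @param promoter_hits Hit table rows for a single promoter (as produced by
#'   [scan_promoter()] or a [scan_all()] subset).
#' @param module A [composite_module()].
#' @return The best-window module score (non-negative scalar; 0 when no
#'   module motif passes its threshold anywhere).
#' @export
module_score <- function(promoter_hits, module) {
  g <- unique(promoter_hits$gene_id)
  if (length(g) > 1) uk_precondition_error("hits must belong to one promoter")
  if (!length(g)) return(0)
  idx <- build_hit_index(promoter_hits, g, module$motifs$motif_id)
  as.numeric(index_scores(idx, module$motifs$motif_id, module$motifs$theta,
                          module$motifs$weight, module$window_W))
}

#' Module scores for a whole promoter universe
#'
#' @param hits A hit table.
#' @param genes Character vector of gene ids (genes without hits score 0).
#' @param module A [composite_module()].
#' @return Named numeric vector of scores.
#' @export
module_scores <- function(hits, genes, module) {
  idx <- build_hit_index(hits, genes, module$motifs$motif_id)
  stats::setNames(index_scores(idx, module$motifs$motif_id,
                               module$motifs$theta, module$motifs$weight,
                               module$window_W), genes)
}

# ---------------------------------------------------------------------------
# Fitness

welch_t <- function(x, y, var_floor = 1e-12) {
  vx <- max(stats::var(x), var_floor)
  vy <- max(stats::var(y), var_floor)
  (mean(x) - mean(y)) / sqrt(vx / length(x) + vy / length(y))
}

wilcoxon_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  # tie-corrected normal approximation of the Mann-Whitney U
  nt <- table(r)
  tie <- sum(nt^3 - nt)
  sd_u <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie / ((n1 + n2) * (n1 + n2 - 1))))
  if (sd_u == 0) return(0)
  (u - n1 * n2 / 2) / sd_u
}

#' Discrimination fitness of a composite module
#'
#' Welch t-statistic (default) or tie-corrected Mann-Whitney z of the module
#' scores in yes vs no promoters, minus a complexity penalty `lambda * k`.
#'
#' @param module A [composite_module()].
#' @param hits Hit table covering both promoter sets.
#' @param yes_genes,no_genes Non-empty gene-id vectors.
#' @param lambda Complexity penalty per motif (default 0.1).
#' @param objective `"welch"` or `"wilcoxon"`.
#' @return Scalar fitness; higher is better.
#' @export
module_fitness <- function(module, hits, yes_genes, no_genes, lambda = 0.1,
                           objective = c("welch", "wilcoxon")) {
  objective <- match.arg(objective)
  if (!length(yes_genes) || !length(no_genes))
    uk_precondition_error("both promoter sets must be non-empty")
  sc <- module_scores(hits, c(yes_genes, no_genes), module)
  score_fitness(sc[seq_along(yes_genes)],
                sc[-seq_along(yes_genes)],
                nrow(module$motifs), lambda, objective)
}

score_fitness <- function(sy, sn, k, lambda, objective) {
  stat <- if (objective == "welch") welch_t(sy, sn) else wilcoxon_z(sy, sn)
  stat - lambda * k
}

# ---------------------------------------------------------------------------
# Genetic algorithm

#' Discover composite modules by a seeded genetic algorithm
#'
#' Chromosomes hold up to `k_max` motif slots (each slot a pool motif with a
#' threshold from `theta_grid` and a positive weight) plus a window width
#' from `W_grid`. Search uses tournament selection (size 3), uniform
#' crossover on motif slots, mutation (motif swap or slot toggle, theta
#' jitter of one grid step, weight jitter x U(0.8, 1.25), window jitter of
#' one grid step) and elitism, so the best fitness is non-decreasing over
#' generations and a fixed seed gives a bit-identical result.
#'
#' @param hits Hit table from [scan_all()].
#' @param yes_genes,no_genes Promoter universes of the two classes.
#' @param pool Character vector of candidate motif ids (>= 2), typically the
#'   `motif_id` column of [rank_tfs()].
#' @param k_max Maximum motifs per module (default 6).
#' @param n_modules Number of motif-disjoint modules to report (default 2).
#' @param pop,gens Population size and generation count (defaults 200, 100).
#' @param p_cross,p_mut Crossover and mutation probabilities.
#' @param lambda Complexity penalty (default 0.1).
#' @param theta_grid,W_grid,W_init Threshold and window search grids.
#' @param objective Fitness statistic, see [module_fitness()].
#' @param n_perm Label permutations for per-module significance (>= 19;
#'   default 199). `0` skips the permutation test.
#' @param seed Integer seed (required for reproducibility).
#' @return An object of class `cma_fit`: fitted `modules` (list of
#'   [composite_module()]), per-promoter `scores` (per module and summed),
#'   the fitness `trace`, pool and configuration.
#' @export
run_cma <- function(hits, yes_genes, no_genes, pool = NULL, k_max = 6,
                    n_modules = 2, pop = 200, gens = 100, p_cross = 0.7,
                    p_mut = 0.3, lambda = 0.1,
                    theta_grid = seq(0.70, 0.95, by = 0.05),
                    W_grid = seq(100L, 600L, by = 50L), W_init = 300L,
                    objective = c("welch", "wilcoxon"), n_perm = 199L,
                    seed = 1L) {
  objective <- match.arg(objective)
  if (is.null(pool)) pool <- sort(unique(hits$motif_id))
  pool <- as.character(pool)
  if (length(pool) < 2)
    uk_precondition_error("motif pool must contain at least 2 motifs")
  if (!length(yes_genes) || !length(no_genes))
    uk_precondition_error("both promoter sets must be non-empty")
  npool <- length(pool)
  k_max <- min(k_max, npool)
  genes <- c(yes_genes, no_genes)
  is_yes <- seq_along(genes) <= length(yes_genes)
  index <- build_hit_index(hits, genes, pool)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  eval_chrom <- function(ch) {
    act <- which(ch$slots > 0L)
    if (length(act) < 2) return(list(fit = -Inf, scores = NULL))
    slot_of <- integer(npool)
    slot_of[ch$slots[act]] <- seq_along(act)
    w <- ch$w[act] / sum(ch$w[act])
    sc <- cpp_module_scores(index$start, index$mss, index$mot, index$ptr,
                            slot_of, ch$theta[act], w, as.integer(ch$W))
    list(fit = score_fitness(sc[is_yes], sc[!is_yes], length(act), lambda,
                             objective),
         scores = sc)
  }

  random_chrom <- function() {
    ks <- 2:k_max
    k <- ks[sample.int(length(ks), 1)]
    slots <- integer(k_max)
    slots[sample.int(k_max, k)] <- sample.int(npool, k)
    list(slots = slots,
         theta = sample(theta_grid, k_max, replace = TRUE),
         w = stats::runif(k_max, 0.5, 2),
         W = as.integer(W_init))
  }

  repair <- function(ch) {
    act <- which(ch$slots > 0L)
    dup <- act[duplicated(ch$slots[act])]
    ch$slots[dup] <- 0L
    act <- which(ch$slots > 0L)
    while (length(act) < 2) {
      free <- setdiff(seq_len(npool), ch$slots[act])
      slot <- which(ch$slots == 0L)[1]
      ch$slots[slot] <- free[sample.int(length(free), 1)]
      act <- which(ch$slots > 0L)
    }
    ch
  }

  mutate <- function(ch) {
    op <- sample.int(4L, 1)
    if (op == 1L) {          # motif swap / slot toggle
      slot <- sample.int(k_max, 1)
      act <- which(ch$slots > 0L)
      if (ch$slots[slot] == 0L) {
        free <- setdiff(seq_len(npool), ch$slots[act])
        if (length(free)) {
          ch$slots[slot] <- free[sample.int(length(free), 1)]
          ch$theta[slot] <- sample(theta_grid, 1)
          ch$w[slot] <- 1
        }
      } else if (length(act) > 2 && stats::runif(1) < 0.5) {
        ch$slots[slot] <- 0L
      } else {
        free <- setdiff(seq_len(npool), ch$slots[act])
        if (length(free)) ch$slots[slot] <- free[sample.int(length(free), 1)]
      }
    } else if (op == 2L) {   # theta jitter +/- one grid step
      slot <- sample.int(k_max, 1)
      step <- sample(c(-0.05, 0.05), 1)
      ch$theta[slot] <- min(max(ch$theta[slot] + step, min(theta_grid)),
                            max(theta_grid))
    } else if (op == 3L) {   # weight jitter
      slot <- sample.int(k_max, 1)
      ch$w[slot] <- min(max(ch$w[slot] * stats::runif(1, 0.8, 1.25), 0.05), 20)
    } else {                 # window jitter +/- one grid step
      step <- sample(c(-50L, 50L), 1)
      ch$W <- min(max(ch$W + step, min(W_grid)), max(W_grid))
    }
    repair(ch)
  }

  crossover <- function(a, b) {
    take_b <- stats::runif(k_max) < 0.5
    ch <- a
    ch$slots[take_b] <- b$slots[take_b]
    ch$theta[take_b] <- b$theta[take_b]
    ch$w[take_b] <- b$w[take_b]
    if (stats::runif(1) < 0.5) ch$W <- b$W
    repair(ch)
  }

  population <- replicate(pop, repair(random_chrom()), simplify = FALSE)
  fits <- vapply(population, function(ch) eval_chrom(ch)$fit, 0)
  hof <- new.env(parent = emptyenv())
  note_hof <- function(ch, fit) {
    key <- paste(sort(ch$slots[ch$slots > 0L]), collapse = ",")
    cur <- hof[[key]]
    if (is.null(cur) || fit > cur$fit) hof[[key]] <- list(ch = ch, fit = fit)
  }
  for (i in seq_along(population)) note_hof(population[[i]], fits[i])

  tournament <- function() {
    cand <- sample.int(pop, 3L)
    cand[which.max(fits[cand])]
  }

  trace <- numeric(gens)
  for (g in seq_len(gens)) {
    elite <- which.max(fits)
    nxt <- vector("list", pop)
    nxt[[1]] <- population[[elite]]
    nfits <- c(fits[elite], numeric(pop - 1L))
    for (i in 2:pop) {
      pa <- population[[tournament()]]
      child <- if (stats::runif(1) < p_cross)
        crossover(pa, population[[tournament()]]) else pa
      if (stats::runif(1) < p_mut) child <- mutate(child)
      nxt[[i]] <- child
      nfits[i] <- eval_chrom(child)$fit
      note_hof(child, nfits[i])
    }
    population <- nxt
    fits <- nfits
    trace[g] <- max(fits)
  }

  # best motif-disjoint modules from the hall of fame (ordered by fitness,
  # ties by motif-set key so the result is reproducible)
  entries <- as.list(hof)
  entries <- entries[order(names(entries))]
  ord <- order(-vapply(entries, `[[`, 0, "fit"), names(entries))
  chosen <- list()
  used <- integer(0)
  for (i in ord) {
    ch <- entries[[i]]$ch
    act <- which(ch$slots > 0L)
    if (length(intersect(ch$slots[act], used))) next
    chosen[[length(chosen) + 1L]] <- entries[[i]]
    used <- c(used, ch$slots[act])
    if (length(chosen) >= n_modules) break
  }
  if (length(chosen) < n_modules)
    uk_warn(sprintf("only %d motif-disjoint module(s) found (requested %d)",
                    length(chosen), n_modules),
            class = "upstreamkit_fewer_modules")

  modules <- lapply(chosen, function(e) {
    act <- which(e$ch$slots > 0L)
    ordm <- act[order(pool[e$ch$slots[act]])]
    composite_module(
      data.frame(motif_id = pool[e$ch$slots[ordm]],
                 theta = e$ch$theta[ordm],
                 weight = e$ch$w[ordm] / sum(e$ch$w[ordm]),
                 stringsAsFactors = FALSE),
      window_W = e$ch$W, fitness = e$fit)
  })

  if (n_perm > 0) {
    perm_seeds <- derive_seed(seed, seq_along(modules) + 100L)
    for (i in seq_along(modules)) {
      modules[[i]]$p_perm <- permutation_significance(
        modules[[i]], hits, yes_genes, no_genes, n_perm = n_perm,
        lambda = lambda, objective = objective, seed = perm_seeds[i])
    }
  }

  score_tab <- data.frame(gene_id = genes,
                          group = ifelse(is_yes, "YES", "NO"),
                          stringsAsFactors = FALSE)
  for (i in seq_along(modules)) {
    score_tab[[paste0("module", i)]] <-
      as.numeric(module_scores(hits, genes, modules[[i]]))
  }
  mod_cols <- grep("^module", names(score_tab))
  score_tab$combined <- rowSums(score_tab[, mod_cols, drop = FALSE])

  structure(list(modules = modules, scores = score_tab, trace = trace,
                 pool = pool, lambda = lambda, objective = objective,
                 config = list(k_max = k_max, n_modules = n_modules,
                               pop = pop, gens = gens, p_cross = p_cross,
                               p_mut = p_mut, theta_grid = theta_grid,
                               W_grid = W_grid, W_init = W_init,
                               n_perm = n_perm),
                 seed = as.integer(seed)),
            class = "cma_fit")
}

#' @export
print.cma_fit <- function(x, ...) {
  cat(sprintf("cma_fit: %d module(s) over a %d-motif pool (seed %d)\n",
              length(x$modules), length(x$pool), x$seed))
  for (i in seq_along(x$modules)) {
    m <- x$modules[[i]]
    cat(sprintf("  module %d: %s | W = %d bp, fitness = %.3f, p_perm = %s\n",
                i, paste(m$motifs$motif_id, collapse = " + "), m$window_W,
                m$fitness, ifelse(is.na(m$p_perm), "NA", fmt_num(m$p_perm))))
  }
  invisible(x)
}

#' @method summary cma_fit
#' @export
summary.cma_fit <- function(object, ...) {
  print(object)
  sy <- object$scores$combined[object$scores$group == "YES"]
  sn <- object$scores$combined[object$scores$group == "NO"]
  cat(sprintf("combined score: yes mean %.3f (n=%d), no mean %.3f (n=%d)\n",
              mean(sy), length(sy), mean(sn), length(sn)))
  cat(sprintf("GA best fitness: start %.3f, end %.3f over %d generations\n",
              object$trace[1], object$trace[length(object$trace)],
              length(object$trace)))
  invisible(object)
}

#' @method coef cma_fit
#' @export
coef.cma_fit <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$modules), function(i) {
    m <- object$modules[[i]]
    cbind(module = i, m$motifs, window_W = m$window_W)
  }))
}

#' @export
predict.cma_fit <- function(object, hits, genes = NULL, ...) {
  if (is.null(genes)) genes <- unique(hits$gene_id)
  regulatory_scores(object, hits, genes)
}

#' @method plot cma_fit
#' @export
plot.cma_fit <- function(x, ...) {
  sy <- x$scores$combined[x$scores$group == "YES"]
  sn <- x$scores$combined[x$scores$group == "NO"]
  br <- pretty(range(c(sy, sn)), 30)
  hy <- graphics::hist(sy, breaks = br, plot = FALSE)
  hn <- graphics::hist(sn, breaks = br, plot = FALSE)
  ylim <- c(0, max(hy$density, hn$density))
  graphics::plot(hy, freq = FALSE, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, ylim = ylim, main = "Composite-module scores",
                 xlab = "combined module score", ...)
  graphics::plot(hn, freq = FALSE, col = grDevices::adjustcolor("grey40", 0.5),
                 border = NA, add = TRUE)
  graphics::legend("topright", fill = grDevices::adjustcolor(c("firebrick", "grey40"), 0.5),
                   legend = c("yes promoters", "no promoters"), bty = "n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Permutation significance

# Deterministic threshold/weight/window refit for a fixed motif set: one
# pass of coordinate ascent over the theta grid, the window grid and
# per-motif weight scalings. Used identically for the observed labels and
# for every permutation, so the permutation p-value is exchangeable under
# the null.
refit_fitness <- function(index, motif_ids, is_yes, W0, lambda, objective,
                          theta_grid = seq(0.70, 0.95, by = 0.05),
                          W_grid = seq(100L, 600L, by = 50L)) {
  k <- length(motif_ids)
  slot_of <- integer(length(index$pool))
  slot_of[match(motif_ids, index$pool)] <- seq_len(k)
  n_yes <- sum(is_yes)
  evalf <- function(theta, w, W) {
    sc <- cpp_module_scores(index$start, index$mss, index$mot, index$ptr,
                            slot_of, theta, w / sum(w), as.integer(W))
    score_fitness(sc[is_yes], sc[!is_yes], k, lambda, objective)
  }
  theta <- rep(theta_grid[2], k)
  w <- rep(1, k)
  W <- as.integer(W0)
  best <- evalf(theta, w, W)
  for (m in seq_len(k)) {
    for (th in theta_grid) {
      cand <- theta; cand[m] <- th
      f <- evalf(cand, w, W)
      if (f > best) { best <- f; theta <- cand }
    }
  }
  for (Wc in W_grid) {
    f <- evalf(theta, w, Wc)
    if (f > best) { best <- f; W <- as.integer(Wc) }
  }
  for (m in seq_len(k)) {
    for (fac in c(0.5, 2)) {
      cand <- w; cand[m] <- w[m] * fac
      f <- evalf(theta, cand, W)
      if (f > best) { best <- f; w <- cand }
    }
  }
  best
}

#' Permutation significance of a composite module
#'
#' Permutes the yes/no promoter labels, refits the module's thresholds,
#' weights and window (composition fixed) for the observed and for every
#' permuted labelling with the same deterministic procedure, and reports
#' `p_perm = (1 + #{permuted fitness >= observed}) / (n_perm + 1)`.
#'
#' @param module A [composite_module()].
#' @param hits Hit table covering both promoter sets.
#' @param yes_genes,no_genes Promoter label sets.
#' @param n_perm Number of permutations, >= 19 (default 199).
#' @param lambda,objective Fitness settings, as in [module_fitness()].
#' @param seed Integer seed for the permutations.
#' @return Permutation p-value in (0, 1].
#' @export
permutation_significance <- function(module, hits, yes_genes, no_genes,
                                     n_perm = 199L, lambda = 0.1,
                                     objective = c("welch", "wilcoxon"),
                                     seed = 1L) {
  objective <- match.arg(objective)
  if (n_perm < 19) uk_precondition_error("n_perm must be >= 19")
  genes <- c(yes_genes, no_genes)
  is_yes <- seq_along(genes) <= length(yes_genes)
  index <- build_hit_index(hits, genes, module$motifs$motif_id)
  obs <- refit_fitness(index, module$motifs$motif_id, is_yes,
                       module$window_W, lambda, objective)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(is_yes)
    f <- refit_fitness(index, module$motifs$motif_id, perm,
                       module$window_W, lambda, objective)
    if (f >= obs) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_perm + 1)
}

# ---------------------------------------------------------------------------
# Regulatory scores

#' Per-gene regulatory (CMA) scores under a fitted module set
#'
#' For each gene, the maximum over fitted modules of the best-window module
#' score of its promoter: the evidence that the module TFs target that
#' gene's promoter.
#'
#' @param fit A `cma_fit` (or list of [composite_module()]s).
#' @param hits Hit table covering the promoters of interest.
#' @param genes Gene ids to score.
#' @return data.frame with columns `gene_id`, `score`.
#' @export
regulatory_scores <- function(fit, hits, genes) {
  modules <- if (inherits(fit, "cma_fit")) fit$modules else fit
  sc <- vapply(modules, function(m) as.numeric(module_scores(hits, genes, m)),
               numeric(length(genes)))
  sc <- matrix(sc, nrow = length(genes))
  data.frame(gene_id = genes, score = apply(sc, 1, max),
             stringsAsFactors = FALSE)
}
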