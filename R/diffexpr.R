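# Two-group moderated differential expression.
#
# The moderated t follows the standard empirical-Bayes construction: per-gene
# residual variances s_g^2 (pooled within the two groups, d_g = n1+n2-2 df)
# are shrunk toward a common prior s_0^2 with prior df d_0,
#   s~_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),
# and (d_0, s_0^2) are estimated by method of moments on log s_g^2 using
# trigamma inversion. p-values come from a t distribution on d_0 + d_g df.

#' Moderated two-group differential expression
#'
#' Computes, per gene, the YES-minus-NO log2 fold change, an empirical-Bayes
#' moderated t-statistic, raw and Benjamini-Hochberg adjusted p-values, and a
#' direction call (`UP`/`DOWN`/`NS`) at the supplied thresholds.
#'
#' @param matrix An [expression_matrix()]; each group needs at least 2 samples.
#' @param alpha Adjusted-p threshold for the direction call (default 0.05).
#' @param lfc Absolute log2FC threshold for the direction call (default 0.5).
#' @param d0_override Optional prior degrees of freedom: `0` reproduces the
#'   ordinary per-gene t, `Inf` the pooled common-variance t. `NULL` (default)
#'   estimates d0 from the data.
#' @return A data.frame of class `de_result` with columns `gene_id`, `log2FC`,
#'   `t_mod`, `df`, `p`, `p_adj`, `direction`, ordered as the input genes.
#'   Attributes `d0` and `s0_2` carry the fitted prior.
#' @export
moderated_de <- function(matrix, alpha = 0.05, lfc = 0.5, d0_override = NULL) {
  stopifnot(inherits(matrix, "expression_matrix"))
  yes <- matrix$values[, matrix$groups == "YES", drop = FALSE]
  no <- matrix$values[, matrix$groups == "NO", drop = FALSE]
  n1 <- ncol(yes); n2 <- ncol(no)
  if (n1 < 2 || n2 < 2)
    uk_precondition_error("each group needs at least 2 samples")
  m1 <- rowMeans(yes); m2 <- rowMeans(no)
  log2fc <- m1 - m2
  dg <- n1 + n2 - 2
  ss <- rowSums((yes - m1)^2) + rowSums((no - m2)^2)
  s2 <- ss / dg

  if (is.null(d0_override)) {
    prior <- fit_variance_prior(s2, dg)
  } else {
    s0 <- if (is.finite(d0_override) && d0_override > 0)
      prior_s0_given_d0(s2, dg, d0_override) else mean(s2)
    prior <- list(d0 = d0_override, s0_2 = s0)
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2

  if (is.infinite(d0)) {
    s2_mod <- rep(s0_2, length(s2))
    df_tot <- rep(Inf, length(s2))
  } else {
    s2_mod <- (d0 * s0_2 + dg * s2) / (d0 + dg)
    df_tot <- rep(d0 + dg, length(s2))
  }
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tt <- log2fc / se
  tt[se == 0] <- 0   # all-constant degenerate gene: no evidence either way
  p <- 2 * stats::pt(abs(tt), df = df_tot, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p_adj <- bh_adjust(p)
  direction <- rep("NS", length(p))
  direction[p_adj < alpha & log2fc > lfc] <- "UP"
  direction[p_adj < alpha & log2fc < -lfc] <- "DOWN"

  out <- data.frame(gene_id = rownames(matrix$values), log2FC = log2fc,
                    t_mod = tt, df = df_tot, p = p, p_adj = p_adj,
                    direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("de_result", "data.frame"),
            d0 = d0, s0_2 = s0_2, alpha = alpha, lfc = lfc,
            n_yes = n1, n_no = n2)
}

#' @export
print.de_result <- function(x, n = 6, ...) {
  cat(sprintf("de_result: %d genes (%d UP, %d DOWN); log2FC = YES - NO\n",
              nrow(x), sum(x$direction == "UP"), sum(x$direction == "DOWN")))
  cat(sprintf("prior: d0 = %s, s0^2 = %.4g\n",
              fmt_num(attr(x, "d0")), attr(x, "s0_2")))
  print.data.frame(utils::head(x[order(x$p), ], n), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @method summary de_result
#' @export
summary.de_result <- function(object, ...) {
  cat(sprintf("Moderated two-group DE: %d genes, %d + %d samples\n",
              nrow(object), attr(object, "n_yes"), attr(object, "n_no")))
  cat(sprintf("  thresholds: adjusted p < %.3g, |log2FC| > %.3g\n",
              attr(object, "alpha"), attr(object, "lfc")))
  cat(sprintf("  UP %d, DOWN %d, NS %d\n", sum(object$direction == "UP"),
              sum(object$direction == "DOWN"), sum(object$direction == "NS")))
  invisible(object)
}

# Method-of-moments fit of the scaled inverse-chi-square variance prior on
# z = log s_g^2: var(z) = trigamma(dg/2) + trigamma(d0/2), solved for d0 by
# Newton inversion of the trigamma function. No finite root (observed spread
# below the chi-square floor) falls back to d0 = 4.
fit_variance_prior <- function(s2, dg) {
  pos <- s2 > 0
  if (sum(pos) < 2) return(list(d0 = 4, s0_2 = max(mean(s2), 1e-12)))
  z <- log(s2[pos])
  ev <- stats::var(z) - trigamma(dg / 2)
  if (!is.finite(ev) || ev <= 1e-8) {
    d0 <- 4
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    if (!is.finite(d0) || d0 <= 0) d0 <- 4
  }
  list(d0 = d0, s0_2 = prior_s0_given_d0(s2, dg, d0))
}

prior_s0_given_d0 <- function(s2, dg, d0) {
  z <- log(s2[s2 > 0])
  if (!length(z)) return(1e-12)
  if (is.infinite(d0)) return(exp(mean(z) - digamma(dg / 2) + log(dg / 2)))
  exp(mean(z) - digamma(dg / 2) + log(dg / 2) + digamma(d0 / 2) - log(d0 / 2))
}

# Newton solve of trigamma(y) = x for y > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around the standard step-up FDR adjustment: output is
#' monotone-preserving, at least the input, and capped at 1.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, aligned with the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || !length(p))
    uk_precondition_error("p must be a non-empty numeric vector")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    uk_precondition_error("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select yes/no gene sets from a DE result
#'
#' The "yes set" is the significantly upregulated genes (the promoters whose
#' motif content the downstream stages interrogate). The "no set" is an
#' expression-matched background: non-significant genes with
#' `|log2FC| < ns_lfc`, size-capped at `cap_ratio` times the yes set by seeded
#' subsampling.
#'
#' @param results A `de_result`.
#' @param alpha,lfc Selection thresholds (defaults 0.05 and 0.5).
#' @param ns_lfc Background band: NS genes with `|log2FC|` below this value
#'   (default 0.1).
#' @param cap_ratio Maximum no-set size as a multiple of the yes set
#'   (default 10).
#' @param seed Seed for the subsampling of an over-sized no set.
#' @return List with `yes_genes`, `no_genes` (disjoint character vectors) and
#'   `down_genes` (the significantly downregulated genes, for reporting).
#' @export
select_degs <- function(results, alpha = 0.05, lfc = 0.5, ns_lfc = 0.1,
                        cap_ratio = 10, seed = 1L) {
  stopifnot(inherits(results, "de_result"), nrow(results) > 0)
  up <- results$gene_id[results$p_adj < alpha & results$log2FC > lfc]
  down <- results$gene_id[results$p_adj < alpha & results$log2FC < -lfc]
  ns <- results$p_adj >= alpha | abs(results$log2FC) <= lfc
  no <- results$gene_id[ns & abs(results$log2FC) < ns_lfc]
  no <- setdiff(no, up)
  if (!length(up))
    uk_warn("no significantly upregulated genes at these thresholds; yes set is empty",
            class = "upstreamkit_empty_yes_set")
  cap <- max(1L, ceiling(cap_ratio * length(up)))
  if (length(up) && length(no) > cap) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(seed)
    no <- sort(sample(no, cap))
  }
  list(yes_genes = up, no_genes = no, down_genes = down)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
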