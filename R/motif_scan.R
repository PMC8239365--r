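# MATCH-style promoter scanning: information-weighted, min-max normalized
# matrix similarity (MSS) over the whole matrix and core similarity (CSS)
# over the 5 most informative consecutive positions, both strands.

BASES <- c("A", "C", "G", "T")

#' Construct a motif model from a count or frequency matrix
#'
#' Counts are normalized per position, regularized with a pseudocount
#' (added after normalization, then renormalized, so scoring is invariant to
#' scaling all counts by a constant), and annotated with the information
#' vector `I(i) = sum_b f(i,b) ln(4 f(i,b))` and the 5-position core (the
#' consecutive positions maximizing summed information; leftmost on ties).
#'
#' @param counts L x 4 non-negative matrix (columns A, C, G, T), L >= 4,
#'   every row summing to a positive value.
#' @param motif_id,tf_name Identifiers (TF name defaults to the motif id).
#' @param mss_cutoff,css_cutoff Similarity cutoffs in `[0, 1]` used by
#'   [scan_promoter()].
#' @param pseudocount Regularization added to frequencies (default 0.001).
#' @return An object of class `motif_model` with fields `freqs`, `info`,
#'   `core_start`, `core_len`.
#' @export
motif_model <- function(counts, motif_id, tf_name = motif_id,
                        mss_cutoff = 0.75, css_cutoff = 0.70,
                        pseudocount = 0.001) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4) uk_format_error("motif matrix must have 4 base columns")
  if (nrow(counts) < 4)
    uk_format_error(sprintf("motif %s: matrix needs >= 4 positions", motif_id))
  if (any(counts < 0))
    uk_format_error(sprintf("motif %s: negative counts", motif_id))
  rs <- rowSums(counts)
  if (any(rs <= 0))
    uk_format_error(sprintf("motif %s: zero-sum position %d", motif_id,
                            which(rs <= 0)[1]))
  if (any(!c(mss_cutoff, css_cutoff) >= 0) || any(c(mss_cutoff, css_cutoff) > 1))
    uk_format_error("cutoffs must lie in [0, 1]")
  f <- counts / rs
  f <- (f + pseudocount) / (1 + 4 * pseudocount)
  colnames(f) <- BASES
  rownames(f) <- NULL
  info <- information_vector(f, pseudocount = 0)
  core <- core_window(info)
  structure(list(motif_id = motif_id, tf_name = tf_name, freqs = f,
                 counts = counts, info = info,
                 core_start = core$start, core_len = core$len,
                 mss_cutoff = mss_cutoff, css_cutoff = css_cutoff),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model %s (%s): %d positions, core %d..%d, cutoffs mss %.2f css %.2f\n",
              x$motif_id, x$tf_name, nrow(x$freqs), x$core_start,
              x$core_start + x$core_len - 1L, x$mss_cutoff, x$css_cutoff))
  cat(sprintf("consensus %s, information %.2f bits/position\n",
              consensus_sequence(x), mean(x$info) / log(2)))
  invisible(x)
}

#' @export
length.motif_model <- function(x) nrow(x$freqs)

#' Per-position information vector of a frequency matrix
#'
#' `I(i) = sum_b f(i,b) ln(4 f(i,b))` (natural log), computed after adding a
#' pseudocount and renormalizing; lies in `[0, ln 4]` per position.
#'
#' @param freqs L x 4 frequency matrix with rows summing to 1.
#' @param pseudocount Regularization (default 0.001; pass 0 for an
#'   already-regularized matrix).
#' @return Numeric vector of length L.
#' @export
information_vector <- function(freqs, pseudocount = 0.001) {
  f <- freqs / rowSums(freqs)
  if (pseudocount > 0) f <- (f + pseudocount) / (1 + 4 * pseudocount)
  rowSums(ifelse(f > 0, f * log(4 * f), 0))
}

core_window <- function(info, width = 5L) {
  L <- length(info)
  if (L <= width) return(list(start = 1L, len = L))
  sums <- vapply(seq_len(L - width + 1L),
                 function(i) sum(info[i:(i + width - 1L)]), 0)
  list(start = which.max(sums), len = width)   # which.max: leftmost on ties
}

#' Consensus sequence of a motif (per-position maximum-frequency base)
#' @param motif A [motif_model()].
#' @return Character scalar.
#' @export
consensus_sequence <- function(motif) {
  paste(BASES[apply(motif$freqs, 1, which.max)], collapse = "")
}

encode_dna <- function(sequence) {
  m <- match(strsplit(sequence, "")[[1]], BASES)
  m[is.na(m)] <- 0L  # N and friends
  as.integer(m)
}

# reverse-complemented motif view: reversed positions, complemented columns.
revcomp_freqs <- function(f) f[rev(seq_len(nrow(f))), 4:1, drop = FALSE]

# core scan of one encoded sequence with one motif: returns bare vectors
# (start offsets are 1-based sequence positions; caller adds window_start-1)
scan_core <- function(s, motif, mss_cut, css_cut) {
  L <- nrow(motif$freqs)
  if (length(s) < L)
    return(list(pos = integer(0), strand = character(0), mss = double(0),
                css = double(0), n_offsets = 0L))
  wf <- motif$info * motif$freqs
  fwd <- cpp_scan(s, wf, motif$core_start, motif$core_len)
  # reverse strand: score the forward sequence with the reverse-complemented
  # matrix; offset o then corresponds to the same forward window.
  rcf <- revcomp_freqs(motif$freqs)
  rc_core <- L - (motif$core_start + motif$core_len - 1L) + 1L
  rev_ <- cpp_scan(s, rev(motif$info) * rcf, rc_core, motif$core_len)
  kf <- which(!is.na(fwd$mss) & fwd$mss >= mss_cut & fwd$css >= css_cut)
  kr <- which(!is.na(rev_$mss) & rev_$mss >= mss_cut & rev_$css >= css_cut)
  list(pos = c(kf, kr),
       strand = rep(c("+", "-"), c(length(kf), length(kr))),
       mss = c(fwd$mss[kf], rev_$mss[kr]),
       css = c(fwd$css[kf], rev_$css[kr]),
       n_offsets = 2L * sum(!is.na(fwd$mss)))
}

#' Scan one promoter with one motif
#'
#' Scores every offset on both strands with the MATCH similarity
#' `MSS = (Current - Min) / (Max - Min)` where
#' `Current = sum_i I(i) f(i, s_i)` and Min/Max use the per-position
#' minimum/maximum frequency, and analogously `CSS` on the core positions.
#' Hits are offsets passing both cutoffs; windows overlapping an N are
#' skipped. Reverse-strand matches are reported in forward coordinates
#' (`start` = TSS-relative coordinate of the leftmost matched base).
#'
#' @param promoter A [promoter_record()].
#' @param motif A [motif_model()].
#' @param mss_cutoff,css_cutoff Optional overrides of the motif's cutoffs.
#' @return data.frame with columns `gene_id`, `motif_id`, `tf_name`, `start`,
#'   `strand`, `mss`, `css`, ordered by (start, strand). Attribute
#'   `n_offsets` carries the number of scorable (N-free) offsets summed over
#'   both strands, used by the enrichment null model.
#' @export
scan_promoter <- function(promoter, motif, mss_cutoff = NULL, css_cutoff = NULL) {
  stopifnot(inherits(promoter, "promoter_record"), inherits(motif, "motif_model"))
  sc <- scan_core(encode_dna(promoter$sequence), motif,
                  mss_cutoff %||% motif$mss_cutoff,
                  css_cutoff %||% motif$css_cutoff)
  hits <- data.frame(gene_id = rep(promoter$gene_id, length(sc$pos)),
                     motif_id = rep(motif$motif_id, length(sc$pos)),
                     tf_name = rep(motif$tf_name, length(sc$pos)),
                     start = promoter$window_start + sc$pos - 1L,
                     strand = sc$strand, mss = sc$mss, css = sc$css,
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  structure(hits, n_offsets = sc$n_offsets)
}

#' Scan a promoter set with a motif library
#'
#' @param promoters A `promoter_set` (named list of [promoter_record()]s).
#' @param motifs A `motif_library` (named list of [motif_model()]s).
#' @param mss_cutoff,css_cutoff Optional global cutoff overrides.
#' @return A `hit_table`: data.frame of all passing hits in deterministic
#'   (gene, motif, start, strand) order, with attribute `offsets`, a
#'   data.frame of scannable-offset counts per (gene, motif).
#' @export
scan_all <- function(promoters, motifs, mss_cutoff = NULL, css_cutoff = NULL) {
  np <- length(promoters); nm <- length(motifs)
  acc <- vector("list", np * nm)
  n_off <- integer(np * nm)
  gene_v <- character(np * nm); motif_v <- character(np * nm)
  idx <- 0L
  for (p in promoters) {
    s <- encode_dna(p$sequence)
    for (m in motifs) {
      idx <- idx + 1L
      sc <- scan_core(s, m, mss_cutoff %||% m$mss_cutoff,
                      css_cutoff %||% m$css_cutoff)
      gene_v[idx] <- p$gene_id; motif_v[idx] <- m$motif_id
      n_off[idx] <- sc$n_offsets
      if (length(sc$pos))
        acc[[idx]] <- list(gene_id = p$gene_id, motif_id = m$motif_id,
                           tf_name = m$tf_name,
                           start = p$window_start + sc$pos - 1L,
                           strand = sc$strand, mss = sc$mss, css = sc$css)
    }
  }
  acc <- acc[!vapply(acc, is.null, TRUE)]
  cat_field <- function(fld, proto)
    unlist(lapply(acc, function(a) rep_len(a[[fld]], length(a$start))),
           use.names = FALSE) %||% proto
  hits <- data.frame(gene_id = cat_field("gene_id", character(0)),
                     motif_id = cat_field("motif_id", character(0)),
                     tf_name = cat_field("tf_name", character(0)),
                     start = cat_field("start", integer(0)),
                     strand = cat_field("strand", character(0)),
                     mss = cat_field("mss", double(0)),
                     css = cat_field("css", double(0)),
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$gene_id, hits$motif_id, hits$start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  structure(hits,
            offsets = data.frame(gene_id = gene_v, motif_id = motif_v,
                                 n_offsets = n_off, stringsAsFactors = FALSE),
            class = c("hit_table", "data.frame"))
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("hit_table: %d hits, %d genes, %d motifs\n", nrow(x),
              length(unique(x$gene_id)), length(unique(x$motif_id))))
  print.data.frame(utils::head(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write / read a hit table as TSV
#' @param hits A `hit_table`.
#' @param path TSV path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  off <- attr(hits, "offsets")
  if (!is.null(off))
    utils::write.table(off, paste0(path, ".offsets"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  offp <- paste0(path, ".offsets")
  off <- if (file.exists(offp))
    utils::read.table(offp, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  structure(h, offsets = off, class = c("hit_table", "data.frame"))
}
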