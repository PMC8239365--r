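# Readers and writers for every external format the pipeline touches:
# expression TSV + group labels, promoter FASTA, TRANSFAC/JASPAR motif
# libraries, signaling-network edge lists, and JSON/YAML artifacts.
# All downstream stages consume only the domain objects built here.

# ---------------------------------------------------------------------------
# ExpressionMatrix

#' Construct an expression matrix with two-group sample labels
#'
#' The container used by the differential-expression stage: a genes x samples
#' matrix of log2 expression values together with a YES/NO group label per
#' sample (YES = the condition of interest, e.g. short-term survivors; NO =
#' the comparison group).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers and must be unique.
#' @param groups Named character vector mapping every sample id to
#'   `"YES"` or `"NO"` (case-insensitive; `"yes"`/`"no"` accepted).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    uk_format_error("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    uk_format_error("values must have gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    uk_format_error(sprintf("duplicate gene id: %s",
                            rownames(values)[duplicated(rownames(values))][1]))
  if (anyDuplicated(colnames(values)))
    uk_format_error(sprintf("duplicate sample id: %s",
                            colnames(values)[duplicated(colnames(values))][1]))
  if (!all(is.finite(values)))
    uk_format_error("expression values must all be finite")
  groups <- toupper(groups)
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    uk_format_error(sprintf("sample(s) missing from groups: %s",
                            paste(missing, collapse = ", ")))
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("YES", "NO")))
    uk_format_error("group labels must be YES or NO")
  if (!all(c("YES", "NO") %in% groups))
    uk_format_error("both YES and NO groups must be non-empty")
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d YES, %d NO)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "YES"), sum(x$groups == "NO")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix and its group labels from TSV files
#'
#' @param path TSV with a header row of sample ids; first column gene ids.
#' @param groups_path Two-column TSV (`sample`, `group`) mapping every sample
#'   to yes/no.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, groups_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) uk_format_error("expression TSV needs gene ids plus >=1 sample")
  gene_ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    uk_format_error(sprintf("non-numeric expression value at row %d (gene %s), column %d (sample %s)",
                            bad[1], gene_ids[bad[1]], bad[2], colnames(vals)[bad[2]]))
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  g <- utils::read.table(groups_path, header = FALSE, sep = "\t",
                         col.names = c("sample", "group"),
                         colClasses = "character", comment.char = "#",
                         quote = "", stringsAsFactors = FALSE)
  if (nrow(g) && tolower(g$sample[1]) == "sample") g <- g[-1, , drop = FALSE]
  groups <- stats::setNames(g$group, g$sample)
  expression_matrix(num, groups)
}

#' Write an expression matrix (and optionally its group labels) to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output TSV path.
#' @param groups_path Optional path for the two-column group file.
#' @export
write_expression <- function(x, path, groups_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- data.frame(gene = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    utils::write.table(data.frame(names(x$groups), unname(x$groups)),
                       groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Promoters

#' Construct a promoter record
#'
#' Coordinates are TSS-relative, 0-based and half-open `[start, end)`: the TSS
#' (first transcribed base) is position 0, negative positions are upstream.
#' Sequence position `i` (1-based in R) maps to coordinate `window_start+i-1`.
#'
#' @param gene_id Gene identifier.
#' @param sequence Character scalar over A/C/G/T/N.
#' @param window_start,window_end Integers with
#'   `window_start < 0 <= window_end` and
#'   `nchar(sequence) == window_end - window_start`.
#' @return A `promoter_record`.
#' @export
promoter_record <- function(gene_id, sequence, window_start = -1000L,
                            window_end = window_start + nchar(sequence)) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    uk_format_error(sprintf("promoter %s: sequence contains letters outside ACGTN", gene_id))
  window_start <- as.integer(window_start)
  window_end <- as.integer(window_end)
  if (nchar(sequence) != window_end - window_start)
    uk_format_error(sprintf("promoter %s: sequence length %d != window [%d,%d)",
                            gene_id, nchar(sequence), window_start, window_end))
  if (!(window_start < 0 && window_end >= 0))
    uk_format_error(sprintf("promoter %s: window must satisfy start < 0 <= end", gene_id))
  structure(list(gene_id = gene_id, sequence = sequence,
                 window_start = window_start, window_end = window_end),
            class = "promoter_record")
}

#' Read promoter sequences from FASTA
#'
#' Headers of the form `gene_id window_start window_end` carry the TSS-relative
#' window; plain headers default to a window ending at the TSS
#' (`[-length, 0)`).
#'
#' @param path FASTA file.
#' @return A named list of [promoter_record()]s (class `promoter_set`).
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- vector("list", length(seqs))
  ids <- character(length(seqs))
  for (i in seq_along(seqs)) {
    hdr <- strsplit(names(seqs)[i], "\\s+")[[1]]
    s <- as.character(seqs[[i]])
    if (length(hdr) >= 3 && !is.na(suppressWarnings(as.integer(hdr[2])))) {
      rec <- promoter_record(hdr[1], s, as.integer(hdr[2]), as.integer(hdr[3]))
    } else {
      rec <- promoter_record(hdr[1], s, -nchar(s), 0L)
    }
    out[[i]] <- rec
    ids[i] <- rec$gene_id
  }
  if (anyDuplicated(ids))
    uk_format_error(sprintf("duplicate promoter id: %s", ids[duplicated(ids)][1]))
  names(out) <- ids
  structure(out, class = c("promoter_set", "list"))
}

#' Write promoters to FASTA with coordinate-bearing headers
#'
#' @param promoters A `promoter_set` or list of [promoter_record()]s.
#' @param path Output FASTA path.
#' @export
write_promoters <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(vapply(promoters, `[[`, "", "sequence"))
  names(seqs) <- vapply(promoters, function(p)
    sprintf("%s %d %d", p$gene_id, p$window_start, p$window_end), "")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Motif libraries (TRANSFAC and JASPAR dialects)

#' Read a motif library in TRANSFAC or JASPAR format
#'
#' The dialect is auto-detected: JASPAR files start records with `>`,
#' TRANSFAC files carry `AC`/`P0` blocks terminated by `//`. Counts are
#' normalized to frequencies and regularized with a pseudocount (see
#' [motif_model()]).
#'
#' @param path Motif file.
#' @param mss_cutoff,css_cutoff Default matrix/core similarity cutoffs
#'   attached to each motif (overridable downstream).
#' @return A named list of [motif_model()]s (class `motif_library`).
#' @export
read_motifs <- function(path, mss_cutoff = 0.75, css_cutoff = 0.70) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (!length(lines)) uk_format_error("empty motif file")
  if (any(grepl("^>", lines))) {
    mats <- parse_jaspar(lines)
  } else if (any(grepl("^(AC|P0|PO)\\b", lines))) {
    mats <- parse_transfac(lines)
  } else {
    uk_format_error("motif file is neither JASPAR (> headers) nor TRANSFAC (AC/P0 blocks)")
  }
  out <- lapply(mats, function(m)
    motif_model(m$counts, m$id, m$tf, mss_cutoff = mss_cutoff, css_cutoff = css_cutoff))
  names(out) <- vapply(out, `[[`, "", "motif_id")
  if (anyDuplicated(names(out)))
    uk_format_error("duplicate motif ids in library")
  structure(out, class = c("motif_library", "list"))
}

parse_jaspar <- function(lines) {
  starts <- grep("^>", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    id <- toks[1]
    tf <- if (length(toks) > 1) toks[2] else toks[1]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) < 4) uk_format_error(sprintf("JASPAR record %s: expected 4 base rows", id))
    rows <- lapply(body[1:4], function(l) {
      l2 <- gsub("^[ACGTacgt]\\s*", "", l)
      l2 <- gsub("[][]", " ", l2)
      as.numeric(strsplit(trimws(l2), "\\s+")[[1]])
    })
    labels <- toupper(substr(trimws(body[1:4]), 1, 1))
    counts <- do.call(cbind, rows)      # positions x 4 after transpose below
    if (all(labels %in% c("A", "C", "G", "T"))) {
      counts <- counts[, match(c("A", "C", "G", "T"), labels), drop = FALSE]
    }
    if (anyNA(counts)) uk_format_error(sprintf("JASPAR record %s: non-numeric count", id))
    colnames(counts) <- c("A", "C", "G", "T")
    list(id = id, tf = tf, counts = counts)
  })
}

parse_transfac <- function(lines) {
  blocks <- split(lines, cumsum(c(0, head(grepl("^//", lines), -1))))
  mats <- list()
  for (blk in blocks) {
    blk <- blk[!grepl("^//", blk)]
    if (!length(blk)) next
    ac <- sub("^AC\\s+", "", grep("^AC\\b", blk, value = TRUE)[1])
    nm <- grep("^(NA|ID)\\b", blk, value = TRUE)
    tf <- if (length(nm)) sub("^(NA|ID)\\s+", "", nm[1]) else ac
    rows <- grep("^\\d+\\s", blk, value = TRUE)
    if (is.na(ac) || !length(rows)) next
    counts <- t(vapply(rows, function(r) {
      toks <- strsplit(trimws(r), "\\s+")[[1]]
      as.numeric(toks[2:5])
    }, numeric(4)))
    if (anyNA(counts)) uk_format_error(sprintf("TRANSFAC record %s: non-numeric count", ac))
    dimnames(counts) <- list(NULL, c("A", "C", "G", "T"))
    mats[[length(mats) + 1L]] <- list(id = ac, tf = tf, counts = counts)
  }
  if (!length(mats)) uk_format_error("no TRANSFAC matrix blocks found")
  mats
}

#' Write a motif library in TRANSFAC format
#'
#' The raw (pre-pseudocount) count matrix is written at full precision, so a
#' write/read round trip reconstructs identical frequencies.
#'
#' @param motifs A `motif_library` or list of [motif_model()]s.
#' @param path Output path.
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(c(sprintf("AC  %s", m$motif_id),
                 sprintf("NA  %s", m$tf_name),
                 "P0      A      C      G      T"), con)
    cnt <- m$counts %||% m$freqs
    for (i in seq_len(nrow(cnt))) {
      writeLines(sprintf("%02d  %s", i,
                         paste(sprintf("%.12g", cnt[i, ]), collapse = "  ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Signaling network

#' Construct a typed, signed signaling network
#'
#' @param edges data.frame with columns `from`, `to`, `sign` (+1/-1) and
#'   `kind` (`"SIGNALING"` or `"TRANSCRIPTION"`).
#' @param nodes Optional data.frame with columns `id`, `kind`
#'   (`PROTEIN`/`COMPLEX`/`TF`) and `gene` (NA when the molecule has no
#'   associated encoding gene). Endpoints absent from `nodes` are created as
#'   `PROTEIN` with no gene.
#' @return A `signaling_network`.
#' @export
signaling_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("from", "to", "sign", "kind")
  if (!all(need %in% names(edges)))
    uk_format_error("edges need columns from, to, sign, kind")
  edges$sign <- as.integer(edges$sign)
  if (!all(edges$sign %in% c(1L, -1L)))
    uk_format_error("edge sign must be +1 or -1")
  edges$kind <- toupper(edges$kind)
  if (!all(edges$kind %in% c("SIGNALING", "TRANSCRIPTION")))
    uk_format_error(sprintf("unknown edge kind: %s",
                            setdiff(edges$kind, c("SIGNALING", "TRANSCRIPTION"))[1]))
  if (is.null(nodes)) {
    nodes <- data.frame(id = character(), kind = character(), gene = character(),
                        stringsAsFactors = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"kind" %in% names(nodes)) nodes$kind <- "PROTEIN"
  if (!"gene" %in% names(nodes)) nodes$gene <- NA_character_
  nodes$kind <- toupper(nodes$kind)
  if (!all(nodes$kind %in% c("PROTEIN", "COMPLEX", "TF")))
    uk_format_error(sprintf("unknown node kind: %s",
                            setdiff(nodes$kind, c("PROTEIN", "COMPLEX", "TF"))[1]))
  extra <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(extra)) {
    nodes <- rbind(nodes, data.frame(id = extra, kind = "PROTEIN",
                                     gene = NA_character_,
                                     stringsAsFactors = FALSE))
  }
  if (anyDuplicated(nodes$id)) uk_format_error("duplicate node ids")
  rownames(nodes) <- nodes$id
  tr <- edges$kind == "TRANSCRIPTION"
  if (any(tr)) {
    src_tf <- nodes[edges$from[tr], "kind"] == "TF"
    tgt_gene <- !is.na(nodes[edges$to[tr], "gene"])
    if (!all(src_tf))
      uk_format_error("TRANSCRIPTION edge with non-TF source")
    if (!all(tgt_gene))
      uk_format_error("TRANSCRIPTION edge target carries no encoding gene")
  }
  structure(list(nodes = nodes, edges = edges), class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf("signaling_network: %d nodes (%d TF), %d edges (%d transcription)\n",
              nrow(x$nodes), sum(x$nodes$kind == "TF"), nrow(x$edges),
              sum(x$edges$kind == "TRANSCRIPTION")))
  invisible(x)
}

#' Read a signaling network from a tabular edge list
#'
#' @param path TSV with columns `source`, `target`, `sign` (one of `+`, `-`,
#'   `+1`, `-1`) and `kind` (`SIGNALING`/`TRANSCRIPTION`); a header row is
#'   detected and skipped.
#' @param nodes_path Optional TSV with columns `id`, `kind`, `gene`.
#' @return A [signaling_network()].
#' @export
read_network <- function(path, nodes_path = NULL) {
  e <- utils::read.table(path, header = FALSE, sep = "\t",
                         colClasses = "character", comment.char = "#",
                         quote = "", stringsAsFactors = FALSE)
  if (ncol(e) < 4) uk_format_error("edge list needs 4 tab-separated columns")
  names(e)[1:4] <- c("from", "to", "sign", "kind")
  if (nrow(e) && tolower(e$from[1]) %in% c("source", "from"))
    e <- e[-1, , drop = FALSE]
  sign_map <- c("+" = 1L, "-" = -1L, "+1" = 1L, "-1" = -1L, "1" = 1L)
  if (!all(e$sign %in% names(sign_map)))
    uk_format_error(sprintf("unknown sign token: %s",
                            setdiff(e$sign, names(sign_map))[1]))
  e$sign <- unname(sign_map[e$sign])
  nodes <- NULL
  if (!is.null(nodes_path)) {
    nodes <- utils::read.table(nodes_path, header = FALSE, sep = "\t",
                               colClasses = "character", comment.char = "#",
                               quote = "", stringsAsFactors = FALSE,
                               fill = TRUE, na.strings = c("NA", ""))
    names(nodes)[1:min(3, ncol(nodes))] <- c("id", "kind", "gene")[1:min(3, ncol(nodes))]
    if (nrow(nodes) && tolower(nodes$id[1]) == "id") nodes <- nodes[-1, , drop = FALSE]
  }
  signaling_network(e, nodes)
}

#' Write a signaling network as edge-list plus node-table TSVs
#'
#' @param network A [signaling_network()].
#' @param path Edge-list output path.
#' @param nodes_path Optional node-table output path.
#' @export
write_network <- function(network, path, nodes_path = NULL) {
  e <- network$edges
  e$sign <- ifelse(e$sign > 0, "+", "-")
  utils::write.table(e[, c("from", "to", "sign", "kind")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(nodes_path)) {
    utils::write.table(network$nodes[, c("id", "kind", "gene")], nodes_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, na = "NA")
  }
  invisible(path)
}

# igraph view of the SIGNALING subgraph (directed), used by the MR stage.
network_igraph <- function(network, kinds = "SIGNALING") {
  e <- network$edges[network$edges$kind %in% kinds, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to", "sign")], directed = TRUE,
    vertices = network$nodes[, c("id", "kind", "gene")])
  g
}
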