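#' Normalize a replicate-averaged expression matrix for network building
#'
#' log2(x + 1), then quantile normalization across columns (every column
#' shares the identical sorted value vector; ties averaged), then row
#' mean-centering. Constant rows survive normalization but are flagged:
#' their correlation with anything is undefined downstream.
#'
#' @param mat numeric matrix, features x conditions (replicate-averaged
#'   FPKM).
#' @return matrix with attribute `constant_rows` (character vector).
#' @export
preprocess_expression <- function(mat) {
  # constancy is judged on the input: quantile normalization reassigns a
  # flat row the column-wise reference quantiles, hiding its flatness
  const <- apply(mat, 1L, function(v) all(abs(v - v[1L]) < 1e-12))
  x <- log2(mat + 1)
  x <- limma::normalizeQuantiles(x, ties = TRUE)
  x <- x - rowMeans(x)
  dimnames(x) <- dimnames(mat)
  attr(x, "constant_rows") <- rownames(mat)[const]
  x
}

#' Per-method co-expression candidate edges
#'
#' Three methods vote: `PCC` (|Pearson r| >= `pcc_min`), `SPEARMAN`
#' (|rho| >= `rho_min`) and `LM` (linear model of one feature on the other
#' plus time-point indicator covariates; adjusted R^2 >= `r2_min`).
#' Constant features are excluded from the correlation methods.
#'
#' @param norm normalized matrix from [preprocess_expression].
#' @param covariates factor of time-point labels, one per column.
#' @param pairs two-column matrix/data.frame of feature id pairs to test;
#'   default: all unordered pairs.
#' @param pcc_min,rho_min,r2_min method thresholds (defaults 0.55, 0.55,
#'   0.9).
#' @return named list of data.frames (`PCC`, `SPEARMAN`, `LM`), each with
#'   `node_a`, `node_b` and the method statistic.
#' @export
method_edges <- function(norm, covariates, pairs = NULL,
                         pcc_min = 0.55, rho_min = 0.55, r2_min = 0.9) {
  if (ncol(norm) < 6L) stop("need at least 6 samples/conditions")
  ids <- rownames(norm)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2L))
  }
  pairs <- as.matrix(pairs)
  const <- attr(norm, "constant_rows") %||% character(0)
  ok <- !(pairs[, 1L] %in% const) & !(pairs[, 2L] %in% const)
  cp <- pairs[ok, , drop = FALSE]
  canon <- function(df) { rownames(df) <- NULL; df }
  pear <- stats::cor(t(norm))
  spear <- stats::cor(t(norm), method = "spearman")
  r_p <- pear[cbind(cp[, 1L], cp[, 2L])]
  r_s <- spear[cbind(cp[, 1L], cp[, 2L])]
  pcc <- canon(data.frame(node_a = cp[, 1L], node_b = cp[, 2L], pcc = r_p,
                          stringsAsFactors = FALSE)[abs(r_p) >= pcc_min, ])
  sp <- canon(data.frame(node_a = cp[, 1L], node_b = cp[, 2L],
                         spearman = r_s,
                         stringsAsFactors = FALSE)[abs(r_s) >= rho_min, ])
  cov <- as.factor(covariates)
  lm_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    y <- norm[pairs[i, 1L], ]; x <- norm[pairs[i, 2L], ]
    fit <- stats::lm(y ~ x + cov)
    # a perfect y = x fit triggers a harmless precision warning
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (!is.na(r2) && r2 >= r2_min)
      lm_rows[[length(lm_rows) + 1L]] <- data.frame(
        node_a = pairs[i, 1L], node_b = pairs[i, 2L], adj_r2 = r2,
        stringsAsFactors = FALSE)
  }
  lm_df <- if (length(lm_rows)) do.call(rbind, lm_rows) else
    data.frame(node_a = character(0), node_b = character(0),
               adj_r2 = numeric(0))
  list(PCC = pcc, SPEARMAN = sp, LM = canon(lm_df))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Consensus network from per-method candidate sets
#'
#' An edge is consensus iff supported by at least two methods. Edges are
#' undirected and deduplicated; full support provenance is kept.
#'
#' @param method_sets named list of data.frames with `node_a`, `node_b`
#'   (and optional statistic columns), as from [method_edges].
#' @return data.frame: `node_a`, `node_b` (lexicographic order),
#'   statistic columns where available, `support`
#'   (comma-separated methods), `n_support`, `consensus`.
#' @export
consensus_network <- function(method_sets) {
  if (length(method_sets) < 2L) stop("need at least 2 method sets")
  all_edges <- list()
  for (m in names(method_sets)) {
    df <- method_sets[[m]]
    if (!nrow(df)) next
    key <- edge_key(df$node_a, df$node_b)
    stat_cols <- setdiff(names(df), c("node_a", "node_b"))
    for (i in seq_len(nrow(df))) {
      k <- key[i]
      e <- all_edges[[k]] %||% list(node_a = pmin(df$node_a[i], df$node_b[i]),
                                    node_b = pmax(df$node_a[i], df$node_b[i]),
                                    support = character(0))
      e$support <- union(e$support, m)
      for (sc in stat_cols) e[[sc]] <- df[[sc]][i]
      all_edges[[k]] <- e
    }
  }
  if (!length(all_edges))
    return(data.frame(node_a = character(0), node_b = character(0),
                      support = character(0), n_support = integer(0),
                      consensus = logical(0)))
  stat_names <- unique(unlist(lapply(all_edges, function(e)
    setdiff(names(e), c("node_a", "node_b", "support")))))
  rows <- lapply(all_edges, function(e) {
    r <- data.frame(node_a = e$node_a, node_b = e$node_b,
                    stringsAsFactors = FALSE)
    for (sn in stat_names) r[[sn]] <- e[[sn]] %||% NA_real_
    r$support <- paste(sort(e$support), collapse = ",")
    r$n_support <- length(e$support)
    r$consensus <- length(e$support) >= 2L
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label gene-TE edges as cis or trans
#'
#' A gene-TE edge is cis iff both features are on the same chromosome and
#' the edge-to-edge gap between them is at most `window` bp (inclusive
#' boundary; overlap counts as gap 0); otherwise trans. Edges with a
#' missing position are labelled `unknown`.
#'
#' @param edges data.frame with `node_a`, `node_b`.
#' @param positions data.frame with `id`, `seq_id`, `start`, `end`.
#' @param window cis window in bp (default 100000).
#' @return `edges` with an added `cis_trans` column.
#' @export
classify_cis_trans <- function(edges, positions, window = 100000L) {
  pos <- positions[match(c(edges$node_a, edges$node_b), positions$id), ]
  n <- nrow(edges)
  a <- pos[seq_len(n), ]; b <- pos[n + seq_len(n), ]
  gap <- pmax(pmax(a$start, b$start) - pmin(a$end, b$end), 0L)
  lab <- ifelse(is.na(a$seq_id) | is.na(b$seq_id), "unknown",
         ifelse(a$seq_id == b$seq_id & gap <= window, "cis", "trans"))
  edges$cis_trans <- lab
  edges
}

#' Longest open reading frame (forward frames)
#'
#' Scans the three forward frames for ATG...stop ORFs; an ORF without an
#' in-frame stop runs to the last complete codon. Length is in amino
#' acids, including the initial Met, excluding the stop.
#'
#' @param sequence nucleotide string (ACGTN).
#' @param both_strands also scan the reverse complement (for unstranded
#'   input; default FALSE, since assembled transcripts are oriented).
#' @return integer (aa).
#' @export
longest_orf_aa <- function(sequence, both_strands = FALSE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence with non-ACGTN characters")
  strands <- if (both_strands) c(sequence, revcomp(sequence)) else sequence
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (s in strands) {
    n <- nchar(s)
    for (frame in 0:2) {
      codons <- substring(s, seq(frame + 1L, n - 2L, by = 3L),
                          seq(frame + 3L, n, by = 3L))
      if (!length(codons)) next
      open_at <- NA_integer_
      for (ci in seq_along(codons)) {
        if (is.na(open_at)) {
          if (codons[ci] == "ATG") open_at <- ci
        } else if (codons[ci] %in% stops) {
          best <- max(best, ci - open_at)
          open_at <- NA_integer_
        }
      }
      if (!is.na(open_at)) best <- max(best, length(codons) - open_at + 1L)
    }
  }
  as.integer(best)
}

#' Filter transcripts to TE-derived lncRNA candidates
#'
#' A candidate is at least `min_len` nt long, has a longest forward-frame
#' ORF of at most `max_orf_aa` amino acids, and overlaps a TE annotation.
#'
#' @param transcripts data.frame with `transcript_id`, `sequence` and
#'   either a logical `te_overlap` column or genomic columns `seq_id`,
#'   `start`, `end` to be intersected with `te_annotations`.
#' @param te_annotations data.frame of TE intervals (ignored when
#'   `te_overlap` supplied).
#' @param min_len,max_orf_aa the lncRNA gates (defaults 200 nt, 120 aa).
#' @return `transcripts` with added `length`, `longest_orf_aa`,
#'   `te_overlap`, `candidate` columns.
#' @export
lncrna_filter <- function(transcripts, te_annotations = NULL,
                          min_len = 200L, max_orf_aa = 120L) {
  tr <- transcripts
  tr$length <- nchar(tr$sequence)
  tr$longest_orf_aa <- vapply(tr$sequence, longest_orf_aa, 0L)
  if (!"te_overlap" %in% names(tr)) {
    if (is.null(te_annotations))
      stop("need either a te_overlap column or te_annotations")
    tr$te_overlap <- vapply(seq_len(nrow(tr)), function(i) {
      te <- te_annotations[te_annotations$seq_id == tr$seq_id[i], ,
                           drop = FALSE]
      any(te$start < tr$end[i] & te$end > tr$start[i])
    }, TRUE)
  }
  tr$candidate <- tr$length >= min_len & tr$longest_orf_aa <= max_orf_aa &
    tr$te_overlap
  rownames(tr) <- NULL
  tr
}
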