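#' Read a FASTA file into a named character vector
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' sequences are uppercased. Input order is preserved.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(character(0))
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1L])
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# Parse the 9th GFF3 column into a named character vector.
parse_gff3_attrs <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  kv <- regmatches(parts, regexpr("=", parts, fixed = TRUE), invert = TRUE)
  vals <- vapply(kv, function(p) if (length(p) == 2L) p[2L] else "", "")
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals <- vals[nzchar(names(vals))]
  # GFF3 percent-encoding of the reserved characters
  vapply(vals, utils::URLdecode, "")
}

#' Read GFF3 gene models and TE annotations
#'
#' Coordinates are converted from GFF3's 1-based inclusive convention to the
#' package-internal 0-based half-open one. `gene`/`mRNA`/`exon` features are
#' resolved through their `Parent` attributes into a [gene_set]; features
#' carrying the classification attribute (superfamily label, e.g.
#' `Classification=LTR/Gypsy`) are returned as TE annotation intervals.
#'
#' @param path GFF3 file.
#' @param classification_attr attribute key holding the TE superfamily
#'   (default `"Classification"`; the key used by TE annotation GFF3 dialects
#'   varies, so it is configurable).
#' @return list with elements `genes` (a [gene_set] or `NULL`) and
#'   `te` (data.frame of TE intervals with `superfamily`, or `NULL`).
#' @export
read_gff3 <- function(path, classification_attr = "Classification") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list(genes = NULL, te = NULL))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("malformed GFF3: expected 9 columns")
  f <- do.call(rbind, f)
  start1 <- as.integer(f[, 4L]); end1 <- as.integer(f[, 5L])
  if (any(end1 < start1)) stop("GFF3 feature with end < start")
  attrs <- lapply(f[, 9L], parse_gff3_attrs)
  feat <- data.frame(seq_id = f[, 1L], type = f[, 3L],
                     start = start1 - 1L, end = end1,   # internal convention
                     score = f[, 6L], strand = f[, 7L],
                     stringsAsFactors = FALSE)
  feat$strand[!feat$strand %in% c("+", "-")] <- "."
  attr_get <- function(a, k) if (k %in% names(a)) a[[k]] else NA_character_
  feat$id <- vapply(attrs, attr_get, "", k = "ID")
  feat$parent <- vapply(attrs, attr_get, "", k = "Parent")
  feat$superfamily <- vapply(attrs, attr_get, "", k = classification_attr)

  te <- feat[!is.na(feat$superfamily), c("seq_id", "start", "end", "strand",
                                         "superfamily", "id")]
  is_gene <- feat$type == "gene"
  gs <- NULL
  if (any(is_gene)) {
    genes <- feat[is_gene, c("seq_id", "start", "end", "strand", "id")]
    names(genes)[names(genes) == "id"] <- "gene_id"
    if (any(is.na(genes$gene_id))) stop("gene feature without ID attribute")
    # mRNA Parent -> gene; exon Parent -> mRNA or gene
    mrna2gene <- feat$id[feat$type == "mRNA"]
    names(mrna2gene) <- mrna2gene
    mrna2gene[] <- feat$parent[feat$type == "mRNA"]
    ex <- feat[feat$type == "exon", , drop = FALSE]
    if (nrow(ex)) {
      parent <- ex$parent
      via_mrna <- parent %in% names(mrna2gene)
      parent[via_mrna] <- mrna2gene[parent[via_mrna]]
      if (any(is.na(parent)) || !all(parent %in% genes$gene_id))
        stop("exon without parent gene")
      exons <- data.frame(gene_id = parent, seq_id = ex$seq_id,
                          start = ex$start, end = ex$end, strand = ex$strand,
                          stringsAsFactors = FALSE)
      # collapse identical exons shared by isoforms
      exons <- unique(exons)
    } else {
      # genes without annotated exons are modelled as single-exon genes
      exons <- data.frame(gene_id = genes$gene_id, seq_id = genes$seq_id,
                          start = genes$start, end = genes$end,
                          strand = genes$strand, stringsAsFactors = FALSE)
    }
    gs <- gene_set(genes, exons)
  }
  list(genes = gs, te = if (nrow(te)) te else NULL)
}

#' Write gene models and/or TE annotations to GFF3
#'
#' @param genes a [gene_set] or `NULL`.
#' @param te data.frame of TE intervals with `superfamily` column, or `NULL`.
#' @param path output file.
#' @param classification_attr attribute key for the TE superfamily.
#' @export
write_gff3 <- function(path, genes = NULL, te = NULL,
                       classification_attr = "Classification") {
  out <- "##gff-version 3"
  if (!is.null(genes)) {
    g <- genes$genes
    out <- c(out, sprintf("%s\ttipscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          g$seq_id, g$start + 1L, g$end, g$strand, g$gene_id))
    e <- genes$exons
    out <- c(out, sprintf(
      "%s\ttipscape\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      e$seq_id, e$start + 1L, e$end, e$strand,
      paste0(e$gene_id, ".exon", stats::ave(seq_len(nrow(e)), e$gene_id,
                                            FUN = seq_along)),
      e$gene_id))
  }
  if (!is.null(te) && nrow(te)) {
    id <- if ("id" %in% names(te) && !any(is.na(te$id))) te$id
          else sprintf("TE%05d", seq_len(nrow(te)))
    score <- if ("score" %in% names(te)) te$score else "."
    out <- c(out, sprintf("%s\ttipscape\ttransposable_element\t%d\t%d\t%s\t%s\t.\tID=%s;%s=%s",
                          te$seq_id, te$start + 1L, te$end, score,
                          te$strand %||% ".", id, classification_attr,
                          te$superfamily))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' BED output is 0-based half-open. Rows are sorted by (seq_id, start, end).
#'
#' @param intervals data.frame with `seq_id`, `start`, `end` and optional
#'   `name` column.
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[order(intervals$seq_id, intervals$start, intervals$end), ,
                  drop = FALSE]
  cols <- cbind(df$seq_id, df$start, df$end)
  if ("name" %in% names(df)) cols <- cbind(cols, df$name)
  writeLines(apply(cols, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED file (first three columns chrom/start/end; an optional
#'   fourth column is kept as `name`).
#' @return data.frame of internal intervals.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  df <- data.frame(seq_id = as.character(tb[[1L]]), start = as.integer(tb[[2L]]),
                   end = as.integer(tb[[3L]]), strand = ".",
                   stringsAsFactors = FALSE)
  if (ncol(tb) >= 4L) df$name <- as.character(tb[[4L]])
  validate_intervals(df)
  df
}

#' Write / read a TSV table with header row
#'
#' @param table data.frame.
#' @param path file path.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
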