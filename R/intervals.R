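#' Construct a table of genomic intervals
#'
#' All coordinates inside the package are 0-based, half-open `[start, end)`.
#' Conversion to 1-based inclusive (GFF3, VCF) happens only at I/O
#' boundaries.
#'
#' @param seq_id character vector of sequence names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @return a `data.frame` with columns `seq_id`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(seq_id, start, end, strand = ".") {
  df <- data.frame(seq_id = as.character(seq_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$seq_id)) || any(!nzchar(df$seq_id)))
    stop("interval with empty seq_id")
  if (any(df$start < 0L)) stop("interval with negative start")
  if (any(df$end <= df$start)) stop("interval with end <= start")
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

# IRanges on the 1-based closed scale used by Bioconductor; internal 0-based
# half-open [s, e) maps to IRanges(s + 1, e).
as_iranges <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)

# Total length of the union of a set of internal intervals (single seq_id).
union_width <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts + 1L, ends))))
}

#' Construct a gene set
#'
#' A gene set couples gene-body intervals with their exon structure. Introns
#' are the gaps between consecutive exons; they are implied, never stored.
#'
#' @param genes data.frame with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand` (internal 0-based half-open coordinates).
#' @param exons data.frame with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand`; every exon must lie within its gene body, exons of one gene
#'   must not overlap.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(genes, exons) {
  validate_intervals(genes)
  validate_intervals(exons)
  stopifnot("gene_id" %in% names(genes), "gene_id" %in% names(exons))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene table")
  bad <- setdiff(exons$gene_id, genes$gene_id)
  if (length(bad)) stop("exon without parent gene: ", bad[1L])
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  for (g in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == g, ]
    gi <- genes[genes$gene_id == g, ]
    if (any(ex$start < gi$start) || any(ex$end > gi$end))
      stop("exon outside gene body for gene ", g)
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
      stop("overlapping exons for gene ", g)
  }
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon)) stop("gene without exons: ", no_exon[1L])
  structure(list(genes = genes, exons = exons), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$seq_id)), "sequence(s)\n")
  invisible(x)
}
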