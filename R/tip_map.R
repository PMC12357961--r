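#' Classify TIP-gene co-occurrence events
#'
#' One event per (TIP, gene) pair whose anchor lies within
#' `[gene.start - window, gene.end + window)`. Anchors inside the gene body
#' are classed `exon` if they fall in an exon, `intron` otherwise; anchors
#' outside are `upstream2k` or `downstream2k` oriented by gene strand
#' ("upstream" is 5' of the gene on its own strand). A TIP near two genes
#' yields two events; a gene with two TIPs yields two events. The anchor of
#' an insertion-type TIP is its breakpoint; of a deletion-type TIP, the
#' midpoint of the deleted span.
#'
#' @param tips data.frame with `sv_id`, `seq_id`, `anchor` (the `tips`
#'   element of a `tip_set`).
#' @param genes a [gene_set].
#' @param window flanking window in bp (default 2000).
#' @return data.frame of events: `tip_id`, `gene_id`, `location_class`,
#'   `distance_to_gene` (bp; 0 inside the gene body).
#' @export
classify_events <- function(tips, genes, window = 2000L) {
  g <- genes$genes; ex <- genes$exons
  out <- list()
  for (k in seq_len(nrow(g))) {
    sel <- tips$seq_id == g$seq_id[k] &
      tips$anchor >= g$start[k] - window & tips$anchor < g$end[k] + window
    if (!any(sel)) next
    t <- tips[sel, , drop = FALSE]
    minus <- g$strand[k] == "-"
    cls <- character(nrow(t)); dist <- integer(nrow(t))
    inside <- t$anchor >= g$start[k] & t$anchor < g$end[k]
    if (any(inside)) {
      exk <- ex[ex$gene_id == g$gene_id[k], , drop = FALSE]
      in_exon <- vapply(t$anchor[inside], function(a)
        any(a >= exk$start & a < exk$end), TRUE)
      cls[inside] <- ifelse(in_exon, "exon", "intron")
      dist[inside] <- 0L
    }
    left <- t$anchor < g$start[k]
    right <- t$anchor >= g$end[k]
    cls[left] <- if (minus) "downstream2k" else "upstream2k"
    cls[right] <- if (minus) "upstream2k" else "downstream2k"
    dist[left] <- g$start[k] - t$anchor[left]
    dist[right] <- t$anchor[right] - g$end[k] + 1L
    out[[length(out) + 1L]] <- data.frame(
      tip_id = t$sv_id, gene_id = g$gene_id[k], location_class = cls,
      distance_to_gene = dist, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tip_id = character(0), gene_id = character(0),
                      location_class = character(0),
                      distance_to_gene = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' TIP genes and per-class unique-insertion gene sets
#'
#' `tip_genes()` returns every gene with at least one event. The
#' unique-insertion sets contain, per location class, genes having exactly
#' one event overall with that event in the class — the genes whose
#' expression contrast can be attributed to a single insertion.
#'
#' @param events data.frame from [classify_events].
#' @return `tip_genes()`: character vector; `unique_insertion_genes()`:
#'   named list of character vectors (`upstream2k`, `exon`, `intron`,
#'   `downstream2k`).
#' @export
tip_genes <- function(events) sort(unique(events$gene_id))

#' @rdname tip_genes
#' @export
unique_insertion_genes <- function(events) {
  n_ev <- table(events$gene_id)
  single <- names(n_ev)[n_ev == 1L]
  ev1 <- events[events$gene_id %in% single, , drop = FALSE]
  lapply(stats::setNames(nm = c("upstream2k", "exon", "intron",
                                "downstream2k")),
         function(cl) sort(ev1$gene_id[ev1$location_class == cl]))
}

#' Insertion-density profile around gene bodies
#'
#' Metagene profile of TIP anchors over `[-flank, gene body, +flank]`,
#' strand-oriented; the gene body is length-normalized. Bins are split
#' equally between the upstream flank, the body and the downstream flank.
#' Densities sum to 1.
#'
#' @param tips data.frame with `seq_id`, `anchor`.
#' @param genes a [gene_set].
#' @param flank flank size in bp.
#' @param n_bins total number of bins (multiple of 3).
#' @return data.frame: `bin`, `region` (upstream/body/downstream),
#'   `rel_pos` (bin midpoint on the -1..2 metagene axis), `count`,
#'   `density`.
#' @export
insertion_density_profile <- function(tips, genes, flank = 2000L,
                                      n_bins = 60L) {
  if (nrow(genes$genes) == 0L) stop("empty gene set")
  stopifnot(n_bins %% 3L == 0L)
  per <- n_bins / 3L
  counts <- numeric(n_bins)
  g <- genes$genes
  for (k in seq_len(nrow(g))) {
    sel <- tips$seq_id == g$seq_id[k] &
      tips$anchor >= g$start[k] - flank & tips$anchor < g$end[k] + flank
    if (!any(sel)) next
    a <- tips$anchor[sel]
    glen <- g$end[k] - g$start[k]
    # metagene coordinate: [-1,0) upstream, [0,1) body, [1,2) downstream
    rel <- ifelse(a < g$start[k], (a - g$start[k]) / flank,
           ifelse(a < g$end[k], (a - g$start[k]) / glen,
                  1 + (a - g$end[k]) / flank))
    if (g$strand[k] == "-") rel <- 1 - rel
    bin <- pmin(pmax(floor((rel + 1) * per) + 1L, 1L), n_bins)
    for (b in bin) counts[b] <- counts[b] + 1
  }
  region <- rep(c("upstream", "body", "downstream"), each = per)
  mid <- (seq_len(n_bins) - 0.5) / per - 1
  data.frame(bin = seq_len(n_bins), region = region, rel_pos = mid,
             count = counts,
             density = if (sum(counts)) counts / sum(counts) else counts)
}

#' Subspecies-conservation flags for TIP sites
#'
#' Per TIP: `fixed_differential` if every non-missing accession of one
#' group carries the TE and every non-missing accession of the other does
#' not; `group_private` if the locus segregates in exactly one group;
#' `shared_polymorphic` otherwise. Heterozygous accessions count as
#' carriers.
#'
#' @param presence matrix (tips x accessions) with entries
#'   present/absent/heterozygous/missing, as in a `tip_set`.
#' @param group_labels named vector accession -> group (two groups).
#' @return named character vector tip_id -> flag.
#' @export
conservation_flags <- function(presence, group_labels) {
  labs <- group_labels[colnames(presence)]
  groups <- unique(stats::na.omit(as.character(labs)))
  if (length(groups) < 2L) stop("need two groups")
  a <- which(labs == groups[1L]); b <- which(labs == groups[2L])
  flag_one <- function(row) {
    carrier <- function(x) x %in% c("present", "heterozygous")
    fa <- carrier(row[a])[row[a] != "missing"]
    fb <- carrier(row[b])[row[b] != "missing"]
    if (!length(fa) || !length(fb)) return("shared_polymorphic")
    seg_a <- any(fa) && !all(fa); seg_b <- any(fb) && !all(fb)
    if (!seg_a && !seg_b && all(fa) != all(fb)) return("fixed_differential")
    if (xor(seg_a, seg_b)) return("group_private")
    "shared_polymorphic"
  }
  out <- apply(presence, 1L, flag_one)
  names(out) <- rownames(presence)
  out
}
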