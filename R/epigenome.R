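#' Partition a genome into pTE / cTE / non-TE space
#'
#' Base-resolution labelling: TE-annotated bases that fall inside any TIP
#' interval are polymorphic-TE (pTE) space; remaining TE-annotated bases
#' are consensus-TE (cTE) space; everything else is non-TE. The three
#' labels are disjoint and cover the genome exactly (pTE wins over cTE at
#' overlaps by construction). A whole-feature mode labels every base of a
#' TE feature pTE as soon as the feature touches a TIP.
#'
#' @param te_annotations data.frame of reference-coordinate TE intervals
#'   (`seq_id`, `start`, `end`).
#' @param tip_intervals data.frame of TIP reference intervals.
#' @param genome_lengths named integer vector: seq_id -> length (bp).
#' @param mode `"base"` (default) or `"feature"`.
#' @return object of class `category_map`: data.frame (`seq_id`, `start`,
#'   `end`, `label`) with `genome_lengths` attribute.
#' @export
build_category_map <- function(te_annotations, tip_intervals, genome_lengths,
                               mode = c("base", "feature")) {
  mode <- match.arg(mode)
  bad <- setdiff(unique(c(te_annotations$seq_id, tip_intervals$seq_id)),
                 names(genome_lengths))
  if (length(bad))
    stop("coordinate system mismatch: unknown sequence ", bad[1L])
  out <- list()
  for (chr in names(genome_lengths)) {
    L <- genome_lengths[[chr]]
    whole <- IRanges::IRanges(1L, L)
    te <- te_annotations[te_annotations$seq_id == chr, , drop = FALSE]
    tp <- tip_intervals[tip_intervals$seq_id == chr, , drop = FALSE]
    te_r <- IRanges::reduce(as_iranges(te))
    tip_r <- IRanges::reduce(as_iranges(tp))
    if (mode == "base") {
      pte <- IRanges::intersect(te_r, tip_r)
    } else {
      hit <- IRanges::overlapsAny(te_r, tip_r)
      pte <- te_r[hit]
    }
    cte <- IRanges::setdiff(te_r, pte)
    nonte <- IRanges::setdiff(whole, te_r)
    add <- function(r, label) if (length(r))
      data.frame(seq_id = chr, start = IRanges::start(r) - 1L,
                 end = IRanges::end(r), label = label,
                 stringsAsFactors = FALSE) else NULL
    out[[chr]] <- rbind(add(pte, "pTE"), add(cte, "cTE"),
                        add(nonte, "nonTE"))
  }
  cm <- do.call(rbind, out)
  cm <- cm[order(cm$seq_id, cm$start), , drop = FALSE]
  rownames(cm) <- NULL
  structure(cm, class = c("category_map", "data.frame"),
            genome_lengths = genome_lengths)
}

#' Per-label bp totals of a category map
#' @param cmap a `category_map`.
#' @export
category_totals <- function(cmap) {
  out <- c(pTE = 0L, cTE = 0L, nonTE = 0L)
  got <- tapply(cmap$end - cmap$start, cmap$label, sum)
  out[names(got)] <- got
  out
}

# restrict a category map to a scope space (list of internal intervals)
restrict_map <- function(cmap, space) {
  out <- list()
  for (chr in unique(cmap$seq_id)) {
    cm <- cmap[cmap$seq_id == chr, , drop = FALSE]
    sp <- space[space$seq_id == chr, , drop = FALSE]
    if (!nrow(sp)) next
    spr <- IRanges::reduce(as_iranges(sp))
    for (lab in unique(cm$label)) {
      r <- IRanges::intersect(as_iranges(cm[cm$label == lab, ]), spr)
      if (length(r))
        out[[length(out) + 1L]] <- data.frame(
          seq_id = chr, start = IRanges::start(r) - 1L, end = IRanges::end(r),
          label = lab, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(cmap[0, , drop = FALSE])
  do.call(rbind, out)
}

#' Quantify peak coverage per genome category
#'
#' For each (mark, condition, label): the bp of the label overlapped by
#' peaks, the proportion of the label's bp that is marked, and the number
#' of peaks touching the label (>= 1 bp). Scope `"WGS"` uses the whole
#' genome; `"GFS"` restricts both labels and peaks to gene bodies +/-
#' `flank`.
#'
#' @param cmap a `category_map`.
#' @param peaks data.frame with `mark`, `condition`, `seq_id`, `start`,
#'   `end`.
#' @param scope `"WGS"` or `"GFS"`.
#' @param genes a [gene_set]; required for GFS.
#' @param flank GFS flank in bp.
#' @return data.frame: `mark`, `condition`, `label`, `bp_total`,
#'   `bp_marked`, `proportion` (`NA` for an empty category), `peak_count`.
#' @export
quantify_marks <- function(cmap, peaks, scope = c("WGS", "GFS"),
                           genes = NULL, flank = 2000L) {
  scope <- match.arg(scope)
  if (scope == "GFS") {
    if (is.null(genes)) stop("GFS scope requires genes")
    g <- genes$genes
    space <- data.frame(seq_id = g$seq_id,
                        start = pmax(g$start - flank, 0L),
                        end = g$end + flank, stringsAsFactors = FALSE)
    cmap <- restrict_map(cmap, space)
  }
  labels <- c("pTE", "cTE", "nonTE")
  out <- list()
  for (mk in unique(peaks$mark)) for (cond in unique(
    peaks$condition[peaks$mark == mk])) {
    pk <- peaks[peaks$mark == mk & peaks$condition == cond, , drop = FALSE]
    for (lab in labels) {
      cm <- cmap[cmap$label == lab, , drop = FALSE]
      bp_total <- sum(cm$end - cm$start)
      bp_marked <- 0L; pk_hit <- logical(nrow(pk))
      for (chr in unique(cm$seq_id)) {
        cr <- as_iranges(cm[cm$seq_id == chr, ])
        sel <- pk$seq_id == chr
        if (!any(sel)) next
        pr <- as_iranges(pk[sel, ])
        bp_marked <- bp_marked +
          sum(IRanges::width(IRanges::intersect(IRanges::reduce(pr), cr)))
        pk_hit[sel] <- pk_hit[sel] | IRanges::overlapsAny(pr, cr)
      }
      out[[length(out) + 1L]] <- data.frame(
        mark = mk, condition = cond, label = lab, bp_total = bp_total,
        bp_marked = bp_marked,
        proportion = if (bp_total > 0L) bp_marked / bp_total else NA_real_,
        peak_count = sum(pk_hit), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean methylation per genome category
#'
#' Weighted (per-cytosine) mean methylation level per label and condition,
#' with a per-context (CG/CHG/CHH) breakdown; cytosines outside every label
#' are ignored and counted. When two conditions are present, the
#' per-interval mean levels are contrasted with a two-tailed Wilcoxon test
#' per label.
#'
#' @param cmap a `category_map`.
#' @param meth data.frame: `seq_id`, `pos` (0-based), `context`, `level`
#'   (in `[0,1]`), `condition`.
#' @return list with `by_label` (label x condition means and n),
#'   `by_context`, `tests` (per-label Wilcoxon p for condition pairs) and
#'   `n_outside`.
#' @export
methylation_by_category <- function(cmap, meth) {
  stopifnot(all(meth$level >= 0 & meth$level <= 1))
  meth$label <- NA_character_
  meth$interval <- NA_integer_
  for (chr in unique(meth$seq_id)) {
    cm_idx <- which(cmap$seq_id == chr)
    if (!length(cm_idx)) next
    sel <- which(meth$seq_id == chr)
    q <- IRanges::IRanges(meth$pos[sel] + 1L, width = 1L)
    hits <- IRanges::findOverlaps(q, as_iranges(cmap[cm_idx, ]))
    meth$label[sel[S4Vectors::queryHits(hits)]] <-
      cmap$label[cm_idx[S4Vectors::subjectHits(hits)]]
    meth$interval[sel[S4Vectors::queryHits(hits)]] <-
      cm_idx[S4Vectors::subjectHits(hits)]
  }
  n_outside <- sum(is.na(meth$label))
  m <- meth[!is.na(meth$label), , drop = FALSE]
  agg <- function(keys) stats::aggregate(m$level, by = keys,
    FUN = function(v) c(mean = mean(v), n = length(v)))
  by_label <- stats::aggregate(level ~ label + condition, data = m, mean)
  by_label$n <- stats::aggregate(level ~ label + condition, data = m,
                                 length)$level
  by_context <- stats::aggregate(level ~ label + condition + context,
                                 data = m, mean)
  tests <- NULL
  conds <- unique(m$condition)
  if (length(conds) >= 2L) {
    pairs <- utils::combn(conds, 2L)
    rows <- list()
    for (p in seq_len(ncol(pairs))) for (lab in unique(m$label)) {
      iv_mean <- function(cond) {
        mm <- m[m$condition == cond & m$label == lab, ]
        if (!nrow(mm)) return(numeric(0))
        tapply(mm$level, mm$interval, mean)
      }
      va <- iv_mean(pairs[1L, p]); vb <- iv_mean(pairs[2L, p])
      if (length(va) >= 2L && length(vb) >= 2L) {
        pv <- suppressWarnings(
          stats::wilcox.test(va, vb, alternative = "two.sided")$p.value)
        rows[[length(rows) + 1L]] <- data.frame(
          label = lab, cond_a = pairs[1L, p], cond_b = pairs[2L, p],
          mean_a = mean(va), mean_b = mean(vb), p_value = pv,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) tests <- do.call(rbind, rows)
  }
  list(by_label = by_label, by_context = by_context, tests = tests,
       n_outside = n_outside)
}
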