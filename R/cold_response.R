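#' Construct an expression set
#'
#' @param values non-negative abundance matrix (features x samples; TPM or
#'   FPKM).
#' @param samples data.frame with one row per column of `values`:
#'   `sample`, `accession`, `time_point` (one of `"0h"`, `"24h"`, `"72h"`),
#'   `replicate`.
#' @param feature_kind character vector (`"gene"`/`"TE"`), one per row.
#' @param unit `"FPKM"` or `"TPM"`.
#' @return object of class `expr_set`.
#' @export
expr_set <- function(values, samples, feature_kind, unit = "FPKM") {
  stopifnot(ncol(values) == nrow(samples),
            nrow(values) == length(feature_kind),
            all(c("sample", "accession", "time_point", "replicate") %in%
                  names(samples)))
  if (any(values < 0)) stop("negative abundance values")
  if (any(is.na(samples$accession)) || any(is.na(samples$time_point)))
    stop("every sample needs accession and time_point")
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples,
                 feature_kind = feature_kind, unit = unit),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$values), "features x", ncol(x$values), "samples (",
      x$unit, ")\n")
  invisible(x)
}

welch_t <- function(x, y) {
  # Welch two-sample t on rows of two matrices (features x replicates)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1); v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & m1 == m2] <- 1         # identical constant groups
  list(t = t, df = df, p = p, m1 = m1, m2 = m2)
}

#' Differential expression for one contrast
#'
#' log2 fold change is computed on group means with a pseudocount of 1,
#' log2FC = log2((mean_b + 1) / (mean_a + 1)); the p-value is a Welch
#' two-sample t-test on log2(value + 1), Benjamini-Hochberg adjusted across
#' features. A feature is responsive iff |log2FC| >= `lfc_min` and
#' FDR < `fdr_max`.
#'
#' @param es an [expr_set].
#' @param accession accession to test within.
#' @param time_point treatment time point, contrasted against `ref`.
#' @param ref reference time point (default `"0h"`).
#' @param lfc_min,fdr_max the responsiveness gates (defaults 1 and 0.05).
#' @return data.frame: `feature_id`, `kind`, `contrast`, `log2fc`,
#'   `p_value`, `fdr`, `responsive`, `direction`.
#' @export
call_de <- function(es, accession, time_point, ref = "0h",
                    lfc_min = 1, fdr_max = 0.05) {
  s <- es$samples
  ia <- which(s$accession == accession & s$time_point == ref)
  ib <- which(s$accession == accession & s$time_point == time_point)
  if (length(ia) < 2L) stop("fewer than 2 replicates in group: ", accession,
                            " ", ref)
  if (length(ib) < 2L) stop("fewer than 2 replicates in group: ", accession,
                            " ", time_point)
  xa <- es$values[, ia, drop = FALSE]; xb <- es$values[, ib, drop = FALSE]
  lfc <- log2((rowMeans(xb) + 1) / (rowMeans(xa) + 1))
  wt <- welch_t(log2(xa + 1), log2(xb + 1))
  fdr <- stats::p.adjust(wt$p, method = "BH")
  data.frame(feature_id = rownames(es$values), kind = es$feature_kind,
             contrast = paste0(time_point, "_vs_", ref, "@", accession),
             time_point = time_point, accession = accession,
             log2fc = lfc, p_value = wt$p, fdr = fdr,
             responsive = abs(lfc) >= lfc_min & fdr < fdr_max,
             direction = ifelse(lfc >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cold-responsive features across all contrasts
#'
#' Runs [call_de] for every (accession, treatment time point) pair against
#' 0 h. A feature is cold-responsive if it is responsive in any contrast.
#'
#' @param es an [expr_set].
#' @param time_points treatment time points (default the non-0h levels).
#' @param ... gates forwarded to [call_de].
#' @return list with `de` (all per-contrast rows) and `cold_responsive`
#'   (data.frame `feature_id`, `kind`, `responsive`).
#' @export
cold_responsive <- function(es, time_points = NULL, ...) {
  s <- es$samples
  if (is.null(time_points))
    time_points <- setdiff(unique(s$time_point), "0h")
  res <- list()
  for (acc in unique(s$accession)) for (tp in time_points) {
    if (!any(s$accession == acc & s$time_point == tp)) next
    res[[length(res) + 1L]] <- call_de(es, acc, tp, ...)
  }
  de <- do.call(rbind, res)
  resp <- tapply(de$responsive, de$feature_id, any)
  cr <- data.frame(feature_id = names(resp),
                   kind = es$feature_kind[match(names(resp),
                                                rownames(es$values))],
                   responsive = as.logical(resp), stringsAsFactors = FALSE)
  list(de = de, cold_responsive = cr)
}

#' Up/down counts of responsive features per kind and time point
#'
#' @param de per-contrast results from [call_de]/[cold_responsive].
#' @return data.frame: `kind`, `time_point`, `direction`, `n` (a feature
#'   responsive at a time point in several accessions is counted once per
#'   time point).
#' @export
updown_summary <- function(de) {
  r <- de[de$responsive, , drop = FALSE]
  if (!nrow(r))
    return(data.frame(kind = character(0), time_point = character(0),
                      direction = character(0), n = integer(0)))
  key <- unique(r[, c("feature_id", "kind", "time_point", "direction")])
  out <- stats::aggregate(feature_id ~ kind + time_point + direction,
                          data = key, FUN = length)
  names(out)[names(out) == "feature_id"] <- "n"
  out
}

#' +TE vs -TE expression contrast per location class
#'
#' For genes with a unique TIP insertion, accessions are split by TIP
#' presence; the per-accession mean log2(expression + 1) values are pooled
#' across the genes of a location class and contrasted with a two-tailed
#' Wilcoxon rank-sum test per class and time point.
#'
#' @param events data.frame from [classify_events], restricted to
#'   unique-insertion genes by the caller or here (`unique_only = TRUE`).
#' @param es an [expr_set].
#' @param presence tips x accessions presence matrix (from a `tip_set`).
#' @param time_point time point to test.
#' @param unique_only restrict to unique-insertion genes (default TRUE).
#' @return data.frame per class: `location_class`, `n_genes`, `p_value`,
#'   `median_plus`, `median_minus`, `underpowered` (fewer than 3 genes).
#' @export
te_presence_contrast <- function(events, es, presence, time_point,
                                 unique_only = TRUE) {
  if (unique_only) {
    n_ev <- table(events$gene_id)
    events <- events[events$gene_id %in% names(n_ev)[n_ev == 1L], ,
                     drop = FALSE]
  }
  s <- es$samples
  sel <- s$time_point == time_point
  out <- list()
  for (cl in c("upstream2k", "exon", "intron", "downstream2k")) {
    ev <- events[events$location_class == cl, , drop = FALSE]
    plus <- numeric(0); minus <- numeric(0); n_genes <- 0L
    for (i in seq_len(nrow(ev))) {
      gid <- ev$gene_id[i]; tid <- ev$tip_id[i]
      if (!gid %in% rownames(es$values) || !tid %in% rownames(presence)) next
      pres <- presence[tid, ]
      accs <- unique(s$accession[sel])
      val <- vapply(accs, function(a) {
        cols <- sel & s$accession == a
        mean(log2(es$values[gid, cols] + 1))
      }, 0)
      carrier <- pres[accs] %in% c("present", "heterozygous")
      noncar <- pres[accs] == "absent"
      if (!any(carrier) || !any(noncar)) next
      n_genes <- n_genes + 1L
      plus <- c(plus, val[carrier]); minus <- c(minus, val[noncar])
    }
    p <- if (length(plus) && length(minus))
      suppressWarnings(stats::wilcox.test(plus, minus,
                                          alternative = "two.sided")$p.value)
    else NA_real_
    out[[length(out) + 1L]] <- data.frame(
      location_class = cl, n_genes = n_genes, p_value = p,
      median_plus = if (length(plus)) stats::median(plus) else NA_real_,
      median_minus = if (length(minus)) stats::median(minus) else NA_real_,
      underpowered = n_genes < 3L, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' TIP-expression association (cis eQTL-style scan)
#'
#' For every (TIP, gene) pair with the gene body within `max_distance` of
#' the TIP anchor, per-accession mean expression at each time point is
#' contrasted by TIP presence with a two-tailed Wilcoxon test;
#' Benjamini-Hochberg adjustment is applied across all tested pairs.
#' Monomorphic or all-missing TIPs are skipped with a reason.
#'
#' @param events data.frame from [classify_events] (pairs to test).
#' @param es an [expr_set].
#' @param presence tips x accessions presence matrix.
#' @param fdr_max significance gate on the adjusted p.
#' @return list with `results` (tested pairs: `tip_id`, `gene_id`,
#'   `time_point`, `n_plus`, `n_minus`, `delta_log2`, `p_value`, `fdr`,
#'   `significant`, `direction`) and `skipped` (pair, reason).
#' @export
tip_expression_assoc <- function(events, es, presence, fdr_max = 0.05) {
  s <- es$samples
  pairs <- unique(events[, c("tip_id", "gene_id")])
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(pairs))) {
    tid <- pairs$tip_id[i]; gid <- pairs$gene_id[i]
    if (!tid %in% rownames(presence) || !gid %in% rownames(es$values)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        tip_id = tid, gene_id = gid, reason = "not in data"); next
    }
    pres <- presence[tid, ]
    if (all(pres == "missing")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        tip_id = tid, gene_id = gid, reason = "all genotypes missing"); next
    }
    carrier_acc <- names(pres)[pres %in% c("present", "heterozygous")]
    noncar_acc <- names(pres)[pres == "absent"]
    if (!length(carrier_acc) || !length(noncar_acc)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        tip_id = tid, gene_id = gid, reason = "monomorphic"); next
    }
    for (tp in unique(s$time_point)) {
      acc_mean <- function(accs) vapply(accs, function(a) {
        cols <- s$time_point == tp & s$accession == a
        if (!any(cols)) return(NA_real_)
        mean(log2(es$values[gid, cols] + 1))
      }, 0)
      vp <- stats::na.omit(acc_mean(carrier_acc))
      vm <- stats::na.omit(acc_mean(noncar_acc))
      if (length(vp) < 2L || length(vm) < 2L) next
      p <- suppressWarnings(
        stats::wilcox.test(vp, vm, alternative = "two.sided")$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        tip_id = tid, gene_id = gid, time_point = tp,
        n_plus = length(vp), n_minus = length(vm),
        delta_log2 = mean(vp) - mean(vm), p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tip_id = character(0), gene_id = character(0),
               time_point = character(0), n_plus = integer(0),
               n_minus = integer(0), delta_log2 = numeric(0),
               p_value = numeric(0))
  if (nrow(results)) {
    results$fdr <- stats::p.adjust(results$p_value, method = "BH")
    results$significant <- results$fdr < fdr_max
    results$direction <- ifelse(results$delta_log2 >= 0, "up", "down")
  }
  list(results = results,
       skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
}
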