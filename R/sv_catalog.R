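#' Classify a structural variant as insertion, deletion or allelic
#'
#' A biallelic site whose ALT is at least `min_sv_len` bp longer than REF is
#' an insertion; at least `min_sv_len` bp shorter, a deletion. A site with
#' two or more ALT alleles is an allelic variation, as is a biallelic site
#' whose length change is below `min_sv_len` but whose replaced segment
#' (the shorter of REF and ALT) is at least `min_sv_len` bp — a
#' length-neutral sequence replacement. Sites below `min_sv_len` in every
#' respect are not structural variants and classify as `NA`.
#'
#' Classes are relative to the designated reference path of the pangenome
#' graph; swapping REF and ALT of a biallelic site swaps insertion and
#' deletion.
#'
#' @param ref REF allele sequence.
#' @param alts character vector of ALT allele sequences (at least one).
#' @param min_sv_len minimum structural-variant length in bp (default 50,
#'   the conventional SV size floor).
#' @return `"insertion"`, `"deletion"`, `"allelic"` or `NA_character_`.
#' @export
classify_sv <- function(ref, alts, min_sv_len = 50L) {
  if (length(alts) == 0L) stop("record with zero ALT alleles")
  rl <- nchar(ref); al <- nchar(alts)
  qualifies <- abs(al - rl) >= min_sv_len | pmin(al, rl) >= min_sv_len
  if (!any(qualifies)) return(NA_character_)
  if (length(alts) >= 2L) return("allelic")
  d <- al - rl
  if (d >= min_sv_len) "insertion"
  else if (d <= -min_sv_len) "deletion"
  else "allelic"
}

#' Summarize a classified SV catalog
#'
#' @param svs an `sv_set` from [read_sv_vcf] or the simulator.
#' @param min_sv_len passed to [classify_sv].
#' @return object of class `sv_catalog_summary`: per-class counts, the
#'   allele-count histogram, the biallelic count and fraction (percent,
#'   reported to 0.1), total affected bp and the number of dropped
#'   (sub-threshold) records.
#' @export
summarize_catalog <- function(svs, min_sv_len = 50L) {
  n <- nrow(svs$sites)
  cls <- character(n)
  for (i in seq_len(n))
    cls[i] <- classify_sv(svs$sites$ref[i], svs$alts[[i]], min_sv_len)
  keep <- !is.na(cls)
  allele_count <- 1L + lengths(svs$alts)
  counts <- c(insertion = sum(cls == "insertion", na.rm = TRUE),
              deletion = sum(cls == "deletion", na.rm = TRUE),
              allelic = sum(cls == "allelic", na.rm = TRUE))
  total <- sum(keep)
  biallelic <- sum(allele_count[keep] == 2L)
  tot_bp <- sum(vapply(which(keep), function(i)
    max(nchar(svs$sites$ref[i]), nchar(svs$alts[[i]])), 0))
  structure(list(
    class_counts = counts, total = total,
    allele_count_hist = table(allele_count[keep]),
    biallelic = biallelic,
    biallelic_fraction_pct = if (total) round(100 * biallelic / total, 1) else NA_real_,
    total_bp = tot_bp, dropped = n - total,
    classes = stats::setNames(cls, svs$sites$sv_id)),
    class = "sv_catalog_summary")
}

#' @export
print.sv_catalog_summary <- function(x, ...) {
  cat("SV catalog:", x$total, "sites (", x$dropped, "below size threshold )\n")
  cat(sprintf("  insertions %d, deletions %d, allelic %d\n",
              x$class_counts["insertion"], x$class_counts["deletion"],
              x$class_counts["allelic"]))
  cat(sprintf("  biallelic %d (%.1f%%), total %.3g bp affected\n",
              x$biallelic, x$biallelic_fraction_pct, x$total_bp))
  invisible(x)
}

#' Structural variants fixed-differential between two groups
#'
#' Returns SV ids where every non-missing accession of one group is
#' homozygous for one allele and every non-missing accession of the other
#' group is homozygous for a different allele — the operational reading of
#' variants conserved between two subspecies.
#'
#' @param svs an `sv_set` with genotypes.
#' @param group_labels named character/factor vector: accession -> group;
#'   exactly two groups required among genotyped accessions.
#' @return character vector of sv_ids.
#' @export
subspecies_shared_svs <- function(svs, group_labels) {
  if (is.null(svs$gt)) stop("sv_set has no genotypes")
  acc <- colnames(svs$gt)
  labs <- group_labels[acc]
  groups <- unique(stats::na.omit(as.character(labs)))
  if (length(groups) < 2L) stop("fewer than 2 groups among genotyped accessions")
  if (length(groups) > 2L) stop("more than 2 groups; provide a two-group labelling")
  a_idx <- which(labs == groups[1L]); b_idx <- which(labs == groups[2L])
  fixed_allele <- function(gts) {
    # the single allele all non-missing members are homozygous for, else NA
    sets <- lapply(gts, parse_gt)
    sets <- sets[!vapply(sets, is.null, TRUE)]
    if (!length(sets)) return(NA_integer_)
    u <- unique(unlist(sets))
    if (length(u) == 1L) u else NA_integer_
  }
  hit <- vapply(seq_len(nrow(svs$sites)), function(i) {
    fa <- fixed_allele(svs$gt[i, a_idx])
    fb <- fixed_allele(svs$gt[i, b_idx])
    !is.na(fa) && !is.na(fb) && fa != fb
  }, TRUE)
  svs$sites$sv_id[hit]
}
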