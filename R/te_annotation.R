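#' Map a TE superfamily label to its structural group
#'
#' The structural group drives the overlap-resolution priority
#' (LTR > TIR > SINE/LINE > Helitron > other). MITEs and the classic cut-and-
#' paste superfamilies (Mutator, PIF-Harbinger, Tc1-Mariner, hAT, CACTA,
#' Tourist, Stowaway) are terminal-inverted-repeat elements and fall in the
#' TIR group; Helitrons form their own group.
#'
#' @param superfamily character vector, e.g. `"LTR/Gypsy"`, `"MITE/Tourist"`,
#'   `"DNA/Helitron"`.
#' @return character vector in `{"LTR","TIR","SINE_LINE","Helitron","other"}`.
#' @export
structural_group <- function(superfamily) {
  out <- rep("other", length(superfamily))
  out[grepl("^LTR", superfamily, ignore.case = TRUE)] <- "LTR"
  out[grepl("Helitron", superfamily, ignore.case = TRUE)] <- "Helitron"
  out[grepl("^(LINE|SINE)|/(LINE|SINE|L1|RTE)", superfamily,
            ignore.case = TRUE)] <- "SINE_LINE"
  tir <- grepl("^(MITE|TIR)|Mutator|Harbinger|Mariner|hAT|CACTA|Tourist|Stowaway|^DNAnona|^DNAauto",
               superfamily, ignore.case = TRUE) &
    !grepl("Helitron", superfamily, ignore.case = TRUE)
  out[tir] <- "TIR"
  out
}

#' @rdname structural_group
#' @return for `te_class()`: `"retrotransposon"` or `"DNA"`.
#' @export
te_class <- function(superfamily) {
  ifelse(structural_group(superfamily) %in% c("LTR", "SINE_LINE"),
         "retrotransposon", "DNA")
}

#' Construct a TE library
#'
#' @param family_id character vector of family names.
#' @param superfamily character vector of superfamily labels.
#' @param sequence character vector of consensus sequences (>= 80 bp).
#' @return data.frame of class `te_library`.
#' @export
te_library <- function(family_id, superfamily, sequence) {
  if (any(nchar(sequence) < 80L))
    stop("TE library entries must be at least 80 bp")
  if (anyDuplicated(family_id)) stop("duplicate family_id in library")
  structure(data.frame(family_id = family_id, superfamily = superfamily,
                       te_class = te_class(superfamily),
                       structural_group = structural_group(superfamily),
                       sequence = toupper(sequence), stringsAsFactors = FALSE),
            class = c("te_library", "data.frame"))
}

#' Read a pan-TE library FASTA with `>family_id#superfamily` headers
#'
#' @param path FASTA file.
#' @export
read_te_library <- function(path) {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), "#", fixed = TRUE)
  fam <- vapply(parts, `[[`, "", 1L)
  sup <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "Unknown", "")
  te_library(fam, sup, unname(seqs))
}

#' Write a TE library as FASTA with `>family_id#superfamily` headers
#'
#' @param lib a [te_library].
#' @param path output file.
#' @export
write_te_library <- function(lib, path) {
  seqs <- lib$sequence
  names(seqs) <- paste0(lib$family_id, "#", lib$superfamily)
  write_fasta(seqs, path)
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Match a sequence against a TE library under the 80-80 rule
#'
#' Seed-and-extend local alignment: shared 15-mers between the query and a
#' library entry define a diagonal band, which is extended with a banded
#' affine-gap local alignment (match +1, mismatch -1, gap open -2, gap
#' extend -1). A hit is reported iff alignment identity >= `min_identity`,
#' aligned length >= `min_len` bp and aligned length >=
#' `min_coverage` x the coverage denominator. Both strands are searched;
#' hits are reported in query coordinates. The best hit per (family,
#' strand) is kept.
#'
#' @param query sequence (>= 80 bp; shorter queries return an empty result
#'   with a warning).
#' @param library a [te_library].
#' @param target_id label stored in the output (e.g. the SV allele id).
#' @param min_identity,min_coverage,min_len the 80-80 thresholds.
#' @param coverage_denominator `"shorter"` (default: the shorter of query
#'   and library entry — the permissive reading), `"query"` or `"library"`.
#' @param seed_k seed k-mer size.
#' @param band_slack extra diagonals allowed either side of the seed band.
#' @return data.frame of annotation intervals: `target_id`, `start`, `end`
#'   (query coordinates, 0-based half-open), `strand`, `family_id`,
#'   `superfamily`, `structural_group`, `score`, `identity`, `coverage`.
#' @export
match_80_80 <- function(query, library, target_id = "query",
                        min_identity = 0.8, min_coverage = 0.8,
                        min_len = 80L, coverage_denominator = "shorter",
                        seed_k = 15L, band_slack = 30L) {
  empty <- data.frame(target_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      family_id = character(0), superfamily = character(0),
                      structural_group = character(0), score = numeric(0),
                      identity = numeric(0), coverage = numeric(0),
                      stringsAsFactors = FALSE)
  query <- toupper(query)
  if (nchar(query) < min_len) {
    warning("query shorter than ", min_len, " bp; no annotation attempted")
    return(empty)
  }
  rows <- vector("list", 2L * nrow(library))
  ri <- 0L
  for (e in seq_len(nrow(library))) {
    for (strand in c("+", "-")) {
      subj <- library$sequence[e]
      if (strand == "-") subj <- revcomp(subj)
      seeds <- kmer_seeds(query, subj, seed_k)
      if (nrow(seeds) == 0L) next
      diags <- seeds[, 2L] - seeds[, 1L]
      hit <- band_align(query, subj, min(diags) - band_slack,
                        max(diags) + band_slack)
      if (hit$columns < min_len) next
      identity <- hit$matches / hit$columns
      denom <- switch(coverage_denominator,
                      shorter = min(nchar(query), nchar(library$sequence[e])),
                      query = nchar(query),
                      library = nchar(library$sequence[e]),
                      stop("unknown coverage_denominator"))
      coverage <- hit$columns / denom
      if (identity < min_identity || coverage < min_coverage) next
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        target_id = target_id, start = hit$q_start, end = hit$q_end,
        strand = strand, family_id = library$family_id[e],
        superfamily = library$superfamily[e],
        structural_group = library$structural_group[e],
        score = hit$score, identity = identity, coverage = coverage,
        stringsAsFactors = FALSE)
    }
  }
  if (ri == 0L) return(empty)
  do.call(rbind, rows[seq_len(ri)])
}

#' Remove redundant entries from a TE library under the 80-80 rule
#'
#' Greedy non-redundancy: entries are visited longest first (ties broken by
#' family_id) and an entry is retained iff it has no 80-80 match to any
#' already-retained entry.
#'
#' @param library a [te_library].
#' @param ... thresholds forwarded to [match_80_80].
#' @return list with `retained` (a [te_library]) and `collapsed`
#'   (data.frame member -> representative provenance).
#' @export
deduplicate_library <- function(library, ...) {
  ord <- order(-nchar(library$sequence), library$family_id)
  lib <- library[ord, , drop = FALSE]
  keep <- logical(nrow(lib))
  rep_of <- character(0); member <- character(0)
  for (i in seq_len(nrow(lib))) {
    ret <- lib[keep, , drop = FALSE]
    if (nrow(ret) == 0L) { keep[i] <- TRUE; next }
    hits <- suppressWarnings(
      match_80_80(lib$sequence[i], ret, target_id = lib$family_id[i], ...))
    if (nrow(hits) == 0L) keep[i] <- TRUE
    else {
      member <- c(member, lib$family_id[i])
      rep_of <- c(rep_of, hits$family_id[which.max(hits$score)])
    }
  }
  retained <- lib[keep, , drop = FALSE]
  class(retained) <- c("te_library", "data.frame")
  list(retained = retained,
       collapsed = data.frame(member = member, representative = rep_of,
                              stringsAsFactors = FALSE))
}

# whitelisted fully-nested (inner, outer) structural-group pairs
NESTING_WHITELIST <- matrix(c("LTR", "Helitron",
                              "Helitron", "LTR",
                              "TIR", "LTR",
                              "LTR", "TIR"), ncol = 2L, byrow = TRUE)
STRUCT_PRIORITY <- c(LTR = 1L, TIR = 2L, SINE_LINE = 3L, Helitron = 4L,
                     other = 5L)

nesting_ok <- function(inner_group, outer_group) {
  any(NESTING_WHITELIST[, 1L] == inner_group &
      NESTING_WHITELIST[, 2L] == outer_group)
}

# TRUE if row a loses to row b under score -> length -> leftmost
loses_to <- function(ann, a, b) {
  if (ann$score[a] != ann$score[b]) return(ann$score[a] < ann$score[b])
  la <- ann$end[a] - ann$start[a]; lb <- ann$end[b] - ann$start[b]
  if (la != lb) return(la < lb)
  if (ann$start[a] != ann$start[b]) return(ann$start[a] > ann$start[b])
  a > b   # final deterministic tie-break on input order
}

#' Resolve overlapping TE annotations on one target
#'
#' The retention cascade: (1) overlapping annotations of the same
#' superfamily keep the higher score (ties: longer, then leftmost);
#' (2) annotations of different structural groups where one is fully nested
#' in the other are both kept when the (inner, outer) pair is a known
#' nesting configuration (LTR in Helitron, Helitron in LTR, TIR in LTR,
#' LTR in TIR); (3) all remaining boundary-crossing overlaps keep the
#' annotation of higher structural priority (LTR > TIR > SINE/LINE >
#' Helitron > other), equal priority falling back to score/length/leftmost.
#' The cascade is run to a fixed point and is idempotent; the output is
#' always a subset of the input.
#'
#' @param ann data.frame of annotations on a single target (as returned by
#'   [match_80_80]).
#' @return filtered data.frame.
#' @export
resolve_overlaps <- function(ann) {
  if (nrow(ann) <= 1L) return(ann)
  if (length(unique(ann$target_id)) > 1L)
    stop("annotations on mixed targets; resolve one target at a time")
  alive <- rep(TRUE, nrow(ann))
  repeat {
    idx <- which(alive)
    idx <- idx[order(ann$start[idx], ann$end[idx])]
    dropped <- FALSE
    for (ai in seq_along(idx)) {
      a <- idx[ai]
      for (bi in seq_along(idx)) {
        if (bi <= ai) next
        b <- idx[bi]
        if (ann$start[b] >= ann$end[a]) break   # sorted by start
        # a and b overlap
        if (ann$superfamily[a] == ann$superfamily[b]) {
          loser <- if (loses_to(ann, a, b)) a else b
          alive[loser] <- FALSE; dropped <- TRUE; break
        }
        ga <- ann$structural_group[a]; gb <- ann$structural_group[b]
        if (ga != gb) {
          a_in_b <- ann$start[a] >= ann$start[b] && ann$end[a] <= ann$end[b]
          b_in_a <- ann$start[b] >= ann$start[a] && ann$end[b] <= ann$end[a]
          if ((a_in_b && nesting_ok(ga, gb)) ||
              (b_in_a && nesting_ok(gb, ga))) next   # whitelisted nesting
          pa <- STRUCT_PRIORITY[[ga]]; pb <- STRUCT_PRIORITY[[gb]]
          loser <- if (pa != pb) { if (pa > pb) a else b }
                   else if (loses_to(ann, a, b)) a else b
          alive[loser] <- FALSE; dropped <- TRUE; break
        }
        # same structural group, different superfamily: no whitelist entry
        # applies; fall back to score/length/leftmost
        loser <- if (loses_to(ann, a, b)) a else b
        alive[loser] <- FALSE; dropped <- TRUE; break
      }
      if (dropped) break
    }
    if (!dropped) break
  }
  out <- ann[alive, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promote an SV to a TIP site
#'
#' An SV becomes a TIP site iff the fraction of its focal allele covered by
#' resolved TE annotations is at least `min_te_fraction`. The focal allele
#' is the longest non-reference-matching allele (the inserted sequence for
#' insertions; the deleted reference segment for deletions). The dominant
#' superfamily is the one with the greatest summed annotated length (ties:
#' longer single annotation, then lexicographic). Presence genotypes map
#' each accession's allele calls onto the TE-carrying allele.
#'
#' @param sv_id SV identifier.
#' @param allele_length length (bp) of the focal allele.
#' @param resolved data.frame of resolved annotations on the focal allele.
#' @param genotypes optional character vector (accession -> GT string).
#' @param te_allele_index allele index (0 = REF) that carries the TE.
#' @param min_te_fraction TIP-calling threshold on the TE-covered fraction
#'   (default 0.8, configurable; reported in the result).
#' @return a list of class `tip_site`, or `NULL` if below threshold.
#' @export
call_tip <- function(sv_id, allele_length, resolved, genotypes = NULL,
                     te_allele_index = 1L, min_te_fraction = 0.8) {
  if (nrow(resolved) == 0L) return(NULL)
  frac <- union_width(resolved$start, resolved$end) / allele_length
  if (frac < min_te_fraction) return(NULL)
  lens <- resolved$end - resolved$start
  by_sup <- tapply(lens, resolved$superfamily, sum)
  cand <- names(by_sup)[by_sup == max(by_sup)]
  if (length(cand) > 1L) {
    longest <- tapply(lens, resolved$superfamily, max)[cand]
    cand <- cand[longest == max(longest)]
    cand <- sort(cand)[1L]
  }
  presence <- NULL
  if (!is.null(genotypes)) {
    presence <- vapply(genotypes, function(g) {
      al <- parse_gt(g)
      if (is.null(al)) return("missing")
      carries <- al == te_allele_index
      if (all(carries)) "present" else if (any(carries)) "heterozygous"
      else "absent"
    }, "")
    names(presence) <- names(genotypes)
  }
  structure(list(sv_id = sv_id, dominant_superfamily = cand[1L],
                 te_covered_fraction = frac, annotations = resolved,
                 presence_genotypes = presence,
                 min_te_fraction = min_te_fraction),
            class = "tip_site")
}

#' @export
print.tip_site <- function(x, ...) {
  cat(sprintf("TIP %s: %s, %.2f of allele covered by %d annotation(s)\n",
              x$sv_id, x$dominant_superfamily, x$te_covered_fraction,
              nrow(x$annotations)))
  invisible(x)
}

#' Annotate an SV catalog against a TE library and call TIP sites
#'
#' For each SV, every non-reference allele (or the deleted reference
#' segment for deletions) of at least `min_len` bp is matched against the
#' library under the 80-80 rule, overlaps are resolved, and the site is
#' promoted to a TIP if any allele passes the TE-covered-fraction
#' threshold.
#'
#' @param svs an `sv_set`.
#' @param library a [te_library] (ideally deduplicated).
#' @param min_te_fraction TIP-calling threshold.
#' @param min_sv_len SV size floor for classification.
#' @param ... thresholds forwarded to [match_80_80].
#' @return object of class `tip_set`: list with `tips` (data.frame:
#'   `sv_id`, `seq_id`, `start`, `end`, `sv_class`, `dominant_superfamily`,
#'   `te_covered_fraction`, `anchor` — the reference-coordinate anchor
#'   position), `sites` (list of `tip_site`), `n_te_containing` (SVs with
#'   any 80-80 hit) and `presence` (matrix tips x accessions of
#'   present/absent/heterozygous/missing).
#' @export
annotate_sv_catalog <- function(svs, library, min_te_fraction = 0.8,
                                min_sv_len = 50L, ...) {
  sites <- list(); rows <- list(); n_te <- 0L
  for (i in seq_len(nrow(svs$sites))) {
    ref <- svs$sites$ref[i]; alts <- svs$alts[[i]]
    cls <- classify_sv(ref, alts, min_sv_len)
    if (is.na(cls)) next
    # candidate focal sequences: each non-reference allele; plus the
    # replaced reference segment for deletion/allelic records
    cand_seq <- alts; cand_idx <- seq_along(alts)
    if (cls %in% c("deletion", "allelic") && nchar(ref) >= 80L) {
      cand_seq <- c(cand_seq, ref); cand_idx <- c(cand_idx, 0L)
    }
    ord <- order(-nchar(cand_seq))
    any_hit <- FALSE; site <- NULL
    for (ci in ord) {
      if (nchar(cand_seq[ci]) < 80L) next
      hits <- match_80_80(cand_seq[ci], library,
                          target_id = svs$sites$sv_id[i], ...)
      if (nrow(hits) == 0L) next
      any_hit <- TRUE
      resolved <- resolve_overlaps(hits)
      gts <- if (!is.null(svs$gt)) {
        g <- svs$gt[i, ]; names(g) <- colnames(svs$gt); g
      } else NULL
      cand_site <- call_tip(svs$sites$sv_id[i], nchar(cand_seq[ci]), resolved,
                            genotypes = gts, te_allele_index = cand_idx[ci],
                            min_te_fraction = min_te_fraction)
      if (!is.null(cand_site)) { site <- cand_site; break }
    }
    if (any_hit) n_te <- n_te + 1L
    if (is.null(site)) next
    anchor <- if (cls == "insertion") svs$sites$start[i] + 1L
              else (svs$sites$start[i] + svs$sites$end[i]) %/% 2L
    sites[[length(sites) + 1L]] <- site
    rows[[length(rows) + 1L]] <- data.frame(
      sv_id = svs$sites$sv_id[i], seq_id = svs$sites$seq_id[i],
      start = svs$sites$start[i], end = svs$sites$end[i], sv_class = cls,
      dominant_superfamily = site$dominant_superfamily,
      te_covered_fraction = site$te_covered_fraction, anchor = anchor,
      stringsAsFactors = FALSE)
  }
  tips <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sv_id = character(0), seq_id = character(0),
               start = integer(0), end = integer(0), sv_class = character(0),
               dominant_superfamily = character(0),
               te_covered_fraction = numeric(0), anchor = integer(0))
  presence <- NULL
  if (length(sites) && !is.null(sites[[1L]]$presence_genotypes)) {
    presence <- do.call(rbind, lapply(sites, `[[`, "presence_genotypes"))
    rownames(presence) <- tips$sv_id
  }
  structure(list(tips = tips, sites = sites, n_te_containing = n_te,
                 presence = presence, min_te_fraction = min_te_fraction),
            class = "tip_set")
}

#' @export
print.tip_set <- function(x, ...) {
  cat("tip_set:", nrow(x$tips), "TIP sites (",
      x$n_te_containing, "TE-containing SVs; threshold",
      x$min_te_fraction, ")\n")
  invisible(x)
}
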