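# Shared fixtures, computed lazily once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# default toy pangenome (the study conditions: 2 subspecies x 5 haplotypes,
# 200 planted TE insertions, seed 42)
toy_sim <- function() fixture("sim", function() simulate_pangenome(sim_config()))

# deduplicated library + annotated TIP set for the toy pangenome
toy_tips <- function() fixture("tips", function() {
  sim <- toy_sim()
  dedup <- deduplicate_library(sim$library)
  annotate_sv_catalog(sim$svs, dedup$retained)
})

toy_events <- function() fixture("events", function()
  classify_events(toy_tips()$tips, toy_sim()$genes))

# small random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# reverse complement without touching package internals
rc <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

# Independent 80-80 hit decision via Biostrings Smith-Waterman.
# Gap of length L costs 2 + (L - 1) under the package scoring; Biostrings
# charges gapOpening + L * gapExtension, so gapOpening = 1, gapExtension = 1.
oracle_80_80_hit <- function(query, subject, min_identity = 0.8,
                             min_coverage = 0.8, min_len = 80L) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (s in c(subject, rc(subject))) {
    pa <- Biostrings::pairwiseAlignment(query, s, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 1, gapExtension = 1)
    if (Biostrings::score(pa) <= 0) next
    cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
    ident <- Biostrings::nmatch(pa) / cols
    denom <- min(nchar(query), nchar(subject))
    if (ident >= min_identity && cols >= min_len &&
        cols >= min_coverage * denom) return(TRUE)
  }
  FALSE
}

# Independent overlap-resolution oracle: same retention rules, different
# algorithm (IRanges overlap detection, explicit violating-pair queue).
oracle_resolve <- function(ann) {
  priority <- c(LTR = 1L, TIR = 2L, SINE_LINE = 3L, Helitron = 4L,
                other = 5L)
  whitelist <- list(c("LTR", "Helitron"), c("Helitron", "LTR"),
                    c("TIR", "LTR"), c("LTR", "TIR"))
  nested_ok <- function(gi, go) any(vapply(whitelist, function(w)
    w[1] == gi && w[2] == go, TRUE))
  beats <- function(a, b) {  # TRUE if a wins the score/length/left tie chain
    if (ann$score[a] != ann$score[b]) return(ann$score[a] > ann$score[b])
    la <- ann$end[a] - ann$start[a]; lb <- ann$end[b] - ann$start[b]
    if (la != lb) return(la > lb)
    if (ann$start[a] != ann$start[b]) return(ann$start[a] < ann$start[b])
    a < b
  }
  alive <- seq_len(nrow(ann))
  repeat {
    if (length(alive) <= 1L) break
    ir <- IRanges::IRanges(ann$start[alive] + 1L, ann$end[alive])
    ov <- as.data.frame(IRanges::findOverlaps(ir, ir))
    ov <- ov[ov$queryHits < ov$subjectHits, , drop = FALSE]
    if (!nrow(ov)) break
    # order pairs the way the cascade scans: by leftmost member
    key <- pmin(ann$start[alive[ov$queryHits]], ann$start[alive[ov$subjectHits]])
    key2 <- pmax(ann$start[alive[ov$queryHits]], ann$start[alive[ov$subjectHits]])
    ov <- ov[order(key, key2), , drop = FALSE]
    removed <- FALSE
    for (r in seq_len(nrow(ov))) {
      a <- alive[ov$queryHits[r]]; b <- alive[ov$subjectHits[r]]
      if (ann$superfamily[a] == ann$superfamily[b]) {
        loser <- if (beats(a, b)) b else a
      } else if (ann$structural_group[a] != ann$structural_group[b]) {
        a_in_b <- ann$start[a] >= ann$start[b] && ann$end[a] <= ann$end[b]
        b_in_a <- ann$start[b] >= ann$start[a] && ann$end[b] <= ann$end[a]
        if ((a_in_b && nested_ok(ann$structural_group[a],
                                 ann$structural_group[b])) ||
            (b_in_a && nested_ok(ann$structural_group[b],
                                 ann$structural_group[a]))) next
        pa <- priority[[ann$structural_group[a]]]
        pb <- priority[[ann$structural_group[b]]]
        loser <- if (pa != pb) { if (pa > pb) a else b }
                 else if (beats(a, b)) b else a
      } else {
        loser <- if (beats(a, b)) b else a
      }
      alive <- setdiff(alive, loser)
      removed <- TRUE
      break
    }
    if (!removed) break
  }
  sort(alive)
}

# random annotation instance on one target
rand_annotations <- function(n, target_len = 2000L) {
  sups <- c("LTR/Gypsy", "LTR/Copia", "MITE/Tourist", "DNA/Helitron",
            "LINE/L1", "Unknown")
  start <- sample.int(target_len - 200L, n, replace = TRUE)
  width <- sample(80:600, n, replace = TRUE)
  sup <- sample(sups, n, replace = TRUE)
  data.frame(target_id = "t", start = start,
             end = pmin(start + width, target_len), strand = "+",
             family_id = sprintf("F%02d", seq_len(n)), superfamily = sup,
             structural_group = structural_group(sup),
             score = sample(50:300, n, replace = TRUE),
             identity = 0.9, coverage = 0.9, stringsAsFactors = FALSE)
}

# Brute-force longest forward-frame ORF: enumerate every ATG, walk to the
# first in-frame stop (or the last complete codon).
oracle_orf <- function(seq) {
  seq <- toupper(seq); n <- nchar(seq)
  best <- 0L
  atg <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
  if (atg[1L] == -1L) return(0L)
  for (p in atg) {
    len <- 0L; i <- p
    repeat {
      if (i + 2L > n) break
      codon <- substr(seq, i, i + 2L)
      if (len > 0L && codon %in% c("TAA", "TAG", "TGA")) break
      len <- len + 1L
      i <- i + 3L
    }
    best <- max(best, len)
  }
  best
}
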