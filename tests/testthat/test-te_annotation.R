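test_that("superfamily labels map to structural groups and classes", {
  expect_equal(structural_group(c("LTR/Gypsy", "MITE/Tourist", "LINE/L1",
                                  "DNA/Helitron", "Unknown", "DNAnona/Mutator")),
               c("LTR", "TIR", "SINE_LINE", "Helitron", "other", "TIR"))
  expect_equal(te_class(c("LTR/Copia", "DNA/Mutator", "SINE/tRNA")),
               c("retrotransposon", "DNA", "retrotransposon"))
})

test_that("an exact library copy matches with identity and coverage 1", {
  set.seed(11)
  lib <- te_library("famA", "LTR/Gypsy", rand_dna(500))
  hits <- match_80_80(lib$sequence[1], lib)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$coverage, 1.0)
  expect_equal(hits$strand, "+")
  expect_equal(c(hits$start, hits$end), c(0L, 500L))
})

test_that("a reverse-complement copy is found on the minus strand", {
  set.seed(12)
  lib <- te_library("famA", "LTR/Gypsy", rand_dna(400))
  hits <- match_80_80(rc(lib$sequence[1]), lib)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$identity, 1.0)
})

test_that("identity below 80% yields no hit; short queries warn", {
  set.seed(13)
  s <- rand_dna(400)
  lib <- te_library("famA", "LTR/Gypsy", s)
  chars <- strsplit(s, "")[[1]]
  mut <- sample(400, 100)  # 25% mutated
  for (p in mut) chars[p] <- sample(setdiff(c("A","C","G","T"), chars[p]), 1)
  hits <- match_80_80(paste(chars, collapse = ""), lib)
  expect_equal(nrow(hits), 0L)
  expect_warning(h2 <- match_80_80(rand_dna(60), lib), "80")
  expect_equal(nrow(h2), 0L)
})

test_that("seed-and-extend hit decisions equal the full Smith-Waterman oracle", {
  set.seed(21)
  lib_seqs <- vapply(1:10, function(i) rand_dna(sample(150:600, 1)), "")
  lib <- te_library(sprintf("F%02d", 1:10),
                    rep(c("LTR/Gypsy", "MITE/Tourist"), 5), lib_seqs)
  mutate <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    k <- rbinom(1, length(ch), rate)
    if (k > 0) for (p in sample(length(ch), k))
      ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  queries <- character(20)
  for (i in 1:20) {
    queries[i] <- if (i <= 6) rand_dna(300)             # random decoys
    else if (i <= 12) mutate(lib_seqs[i - 6], 0.05)     # clear family members
    else if (i <= 16) mutate(lib_seqs[i - 12], 0.15)    # borderline
    else rc(mutate(lib_seqs[i - 16], 0.05))             # minus strand
  }
  for (q in queries) {
    got <- suppressWarnings(match_80_80(q, lib))
    for (e in seq_len(nrow(lib))) {
      expect_equal(lib$family_id[e] %in% got$family_id,
                   oracle_80_80_hit(q, lib$sequence[e]),
                   info = paste("query", which(queries == q), "entry", e))
    }
  }
})

test_that("library deduplication keeps one representative per 80-80 cluster", {
  set.seed(31)
  base <- vapply(1:10, function(i) rand_dna(sample(200:500, 1)), "")
  mutate5 <- function(s) {
    ch <- strsplit(s, "")[[1]]
    for (p in sample(length(ch), round(0.05 * length(ch))))
      ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  dup_of <- sample(1:10, 10, replace = TRUE)
  seqs <- c(base, vapply(dup_of, function(i) mutate5(base[i]), ""))
  lib <- te_library(sprintf("F%02d", 1:20), rep("LTR/Gypsy", 20), seqs)
  dd <- deduplicate_library(lib)

  # oracle: connected components of the all-vs-all 80-80 graph
  parent <- 1:20
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:19) for (j in (i + 1):20)
    if (oracle_80_80_hit(seqs[i], seqs[j]))
      parent[find(j)] <- find(i)
  n_comp <- length(unique(vapply(1:20, find, 1L)))
  expect_equal(nrow(dd$retained), n_comp)
  expect_equal(nrow(dd$collapsed), 20L - n_comp)

  # identical entries collapse; 70%-identity entries both survive
  two <- te_library(c("a", "b"), c("LTR/Gypsy", "LTR/Gypsy"),
                    rep(rand_dna(300), 2))
  expect_equal(nrow(deduplicate_library(two)$retained), 1L)
  s1 <- rand_dna(300)
  ch <- strsplit(s1, "")[[1]]
  for (p in sample(300, 90)) ch[p] <- sample(setdiff(c("A","C","G","T"),
                                                     ch[p]), 1)
  far <- te_library(c("a", "b"), c("LTR/Gypsy", "LTR/Gypsy"),
                    c(s1, paste(ch, collapse = "")))
  expect_equal(nrow(deduplicate_library(far)$retained), 2L)
})

ann_row <- function(start, end, superfamily, score, fam = "f") {
  data.frame(target_id = "t", start = start, end = end, strand = "+",
             family_id = fam, superfamily = superfamily,
             structural_group = structural_group(superfamily), score = score,
             identity = 0.9, coverage = 0.9, stringsAsFactors = FALSE)
}

test_that("overlap cascade: same superfamily keeps the higher score", {
  ann <- rbind(ann_row(0, 500, "LTR/Gypsy", 100),
               ann_row(300, 800, "LTR/Gypsy", 90))
  out <- resolve_overlaps(ann)
  expect_equal(nrow(out), 1L)
  expect_equal(out$score, 100)
})

test_that("overlap cascade: whitelisted full nesting keeps both copies", {
  ann <- rbind(ann_row(0, 1000, "LTR/Gypsy", 100),
               ann_row(200, 500, "DNA/Helitron", 80))
  expect_equal(nrow(resolve_overlaps(ann)), 2L)
  # non-whitelisted nesting (LINE inside LTR) resolves by priority
  ann2 <- rbind(ann_row(0, 1000, "LTR/Gypsy", 100),
                ann_row(200, 500, "LINE/L1", 80))
  out2 <- resolve_overlaps(ann2)
  expect_equal(out2$superfamily, "LTR/Gypsy")
})

test_that("overlap cascade: boundary overlaps resolve by structural priority", {
  ann <- rbind(ann_row(0, 600, "LTR/Gypsy", 50),
               ann_row(400, 900, "DNA/Helitron", 200))
  out <- resolve_overlaps(ann)
  expect_equal(out$superfamily, "LTR/Gypsy")   # LTR outranks Helitron
})

test_that("overlap cascade equals the independent oracle and is idempotent", {
  set.seed(41)
  for (rep in 1:40) {
    ann <- rand_annotations(sample(2:12, 1))
    out <- resolve_overlaps(ann)
    keep <- oracle_resolve(ann)
    expect_equal(sort(paste(out$start, out$end, out$superfamily)),
                 sort(paste(ann$start[keep], ann$end[keep],
                            ann$superfamily[keep])), info = paste("rep", rep))
    # idempotence and subset
    expect_equal(resolve_overlaps(out), out)
    expect_lte(sum(out$end - out$start), sum(ann$end - ann$start))
  }
  expect_error(resolve_overlaps(rbind(ann_row(0, 100, "LTR/Gypsy", 10),
                                      within(ann_row(0, 100, "LTR/Gypsy", 10),
                                             target_id <- "u"))),
               "mixed targets")
})

test_that("call_tip applies the covered-fraction threshold and dominance", {
  ann <- ann_row(0, 300, "MITE/Tourist", 100)
  tip <- call_tip("sv1", 300L, ann)
  expect_s3_class(tip, "tip_site")
  expect_equal(tip$dominant_superfamily, "MITE/Tourist")
  expect_equal(tip$te_covered_fraction, 1.0)

  expect_null(call_tip("sv2", 1000L, ann))   # 0.3 < 0.8

  # one site carrying several TE annotations stays a single TIP
  ann3 <- rbind(ann_row(0, 400, "DNAnona/Mutator", 90),
                ann_row(400, 700, "DNA/Helitron", 80),
                ann_row(700, 1000, "DNAauto/Mutator", 95))
  tip3 <- call_tip("sv3", 1000L, ann3)
  expect_equal(nrow(tip3$annotations), 3L)
  expect_equal(tip3$te_covered_fraction, 1.0)

  # dominance: greatest summed length, ties by longest single annotation
  ann4 <- rbind(ann_row(0, 300, "LTR/Gypsy", 10),
                ann_row(300, 450, "DNA/Helitron", 10),
                ann_row(450, 600, "DNA/Helitron", 10))
  expect_equal(call_tip("sv4", 600L, ann4)$dominant_superfamily, "LTR/Gypsy")
})

test_that("presence genotypes map allele calls onto the TE-carrying allele", {
  gts <- c(a = "1/1", b = "0/0", c = "0/1", d = ".")
  tip <- call_tip("sv", 300L, ann_row(0, 300, "LTR/Gypsy", 10),
                  genotypes = gts, te_allele_index = 1L)
  expect_equal(unname(tip$presence_genotypes),
               c("present", "absent", "heterozygous", "missing"))
  # deletion-type site: the REF allele carries the TE
  tip2 <- call_tip("sv", 300L, ann_row(0, 300, "LTR/Gypsy", 10),
                   genotypes = gts, te_allele_index = 0L)
  expect_equal(unname(tip2$presence_genotypes),
               c("absent", "present", "heterozygous", "missing"))
})
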