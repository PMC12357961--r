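# independent quantile-normalization oracle (rank average for ties)
oracle_qnorm <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    out[, j] <- approx(seq_len(nrow(x)), ref, xout = r)$y
  }
  out
}

test_that("preprocessing normalizes columns identically and centers rows", {
  set.seed(51)
  m <- matrix(2^rnorm(200, 5, 2), nrow = 20,
              dimnames = list(sprintf("f%d", 1:20), sprintf("s%d", 1:10)))
  norm <- preprocess_expression(m)
  # identical column empirical distributions
  sorted <- apply(norm + rowMeans(log2(m + 1)) * 0, 2, sort)  # on centered
  pre_center <- limma::normalizeQuantiles(log2(m + 1), ties = TRUE)
  expect_true(all(apply(apply(pre_center, 2, sort), 1,
                        function(r) max(r) - min(r)) < 1e-9))
  # every row mean is 0
  expect_lt(max(abs(rowMeans(norm))), 1e-12)
  # constant rows flagged
  m2 <- rbind(m, const = rep(7, 10))
  expect_equal(attr(preprocess_expression(m2), "constant_rows"), "const")
})

test_that("a small matrix matches the step-by-step oracle", {
  set.seed(52)
  m <- matrix(round(2^rnorm(20, 4, 1), 2), nrow = 5,
              dimnames = list(letters[1:5], sprintf("s%d", 1:4)))
  norm <- preprocess_expression(m)
  manual <- oracle_qnorm(log2(m + 1))
  manual <- manual - rowMeans(manual)
  expect_equal(unname(norm), unname(manual), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("method thresholds fire exactly at the documented cutoffs", {
  set.seed(53)
  n <- 12L
  x <- rnorm(n)
  make_with_r <- function(r) r * x + sqrt(1 - r^2) * rnorm(n)
  # scale to give a known empirical correlation by construction check
  y_hi <- x                           # r = 1: all methods fire
  m <- rbind(g1 = x, g2 = y_hi)
  m <- m - rowMeans(m)
  attr(m, "constant_rows") <- character(0)
  me <- method_edges(m, rep(c("0h", "24h", "72h"), each = 4))
  expect_equal(nrow(me$PCC), 1L)
  expect_equal(nrow(me$SPEARMAN), 1L)
  expect_equal(nrow(me$LM), 1L)

  # empirical |r| just below 0.55 does not fire the PCC method
  repeat {
    y <- make_with_r(0.45)
    if (abs(cor(x, y)) < 0.5 && abs(cor(x, y)) > 0.3) break
  }
  m2 <- rbind(g1 = x, g2 = y)
  m2 <- m2 - rowMeans(m2)
  attr(m2, "constant_rows") <- character(0)
  me2 <- method_edges(m2, rep(c("0h", "24h", "72h"), each = 4))
  expect_equal(nrow(me2$PCC), 0L)
  expect_error(method_edges(m2[, 1:5], rep("0h", 5)), "at least 6")
})

test_that("PCC candidates equal the direct correlation oracle with planted pairs", {
  set.seed(54)
  n_cond <- 12L
  n_pairs <- 30L
  feats <- list(); ids <- character(0)
  for (i in seq_len(n_pairs)) {   # planted r ~ 0.9 pairs
    a <- rnorm(n_cond)
    b <- 0.9 * scale(a)[, 1] + sqrt(1 - 0.81) * rnorm(n_cond)
    feats[[length(feats) + 1]] <- a; ids <- c(ids, sprintf("p%da", i))
    feats[[length(feats) + 1]] <- b; ids <- c(ids, sprintf("p%db", i))
  }
  for (i in 1:140) {              # nulls
    feats[[length(feats) + 1]] <- rnorm(n_cond)
    ids <- c(ids, sprintf("n%d", i))
  }
  m <- do.call(rbind, feats); rownames(m) <- ids
  m <- m - rowMeans(m)
  attr(m, "constant_rows") <- character(0)
  me <- method_edges(m, rep(c("a", "b", "c"), each = 4))
  # oracle: direct correlation over all pairs at the same threshold
  cm <- cor(t(m))
  idx <- which(abs(cm) >= 0.55 & upper.tri(cm), arr.ind = TRUE)
  oracle <- sort(paste(pmin(ids[idx[, 1]], ids[idx[, 2]]),
                       pmax(ids[idx[, 1]], ids[idx[, 2]])))
  got <- sort(paste(pmin(me$PCC$node_a, me$PCC$node_b),
                    pmax(me$PCC$node_a, me$PCC$node_b)))
  expect_equal(got, oracle)
  # planted recovery >= 28/30
  planted <- sprintf("p%da p%db", 1:n_pairs, 1:n_pairs)
  planted <- sort(paste(sprintf("p%da", 1:n_pairs), sprintf("p%db", 1:n_pairs)))
  expect_gte(sum(planted %in% got), 28L)
})

test_that("consensus requires support from at least two methods", {
  pcc <- data.frame(node_a = c("g1", "g2"), node_b = c("t1", "t2"),
                    pcc = c(0.9, 0.6), stringsAsFactors = FALSE)
  lm_df <- data.frame(node_a = "t1", node_b = "g1", adj_r2 = 0.95,
                      stringsAsFactors = FALSE)  # reversed order: same edge
  sp <- data.frame(node_a = character(0), node_b = character(0),
                   spearman = numeric(0))
  net <- consensus_network(list(PCC = pcc, SPEARMAN = sp, LM = lm_df))
  expect_equal(nrow(net), 2L)
  e1 <- net[net$node_a == "g1", ]
  expect_true(e1$consensus)
  expect_equal(e1$support, "LM,PCC")
  expect_false(net$consensus[net$node_a == "g2"])
  # |consensus| equals the pairs with >= 2 supports, exactly
  expect_equal(sum(net$consensus), 1L)
  expect_error(consensus_network(list(PCC = pcc)), "at least 2")
})

test_that("cis/trans classification uses the inclusive 100 kb edge gap", {
  pos <- data.frame(id = c("g1", "t1", "t2", "t3", "t4"),
                    seq_id = c("chr1", "chr1", "chr1", "chr2", "chr1"),
                    start = c(0L, 51000L, 101500L, 500L, 101000L),
                    end = c(1000L, 52000L, 102500L, 900L, 101500L),
                    stringsAsFactors = FALSE)
  edges <- data.frame(node_a = c("g1", "g1", "g1", "g1"),
                      node_b = c("t1", "t2", "t3", "t4"),
                      stringsAsFactors = FALSE)
  out <- classify_cis_trans(edges, pos)
  expect_equal(out$cis_trans, c("cis", "trans", "trans", "cis"))
  # t4 gap is exactly 100000: inclusive boundary keeps it cis
  # unknown position -> unknown label
  out2 <- classify_cis_trans(data.frame(node_a = "g1", node_b = "zz"), pos)
  expect_equal(out2$cis_trans, "unknown")
})

test_that("cis labels are invariant under chromosome renaming", {
  pos <- data.frame(id = c("g1", "t1"), seq_id = "chrA",
                    start = c(0L, 5000L), end = c(1000L, 6000L),
                    stringsAsFactors = FALSE)
  e <- data.frame(node_a = "g1", node_b = "t1", stringsAsFactors = FALSE)
  l1 <- classify_cis_trans(e, pos)$cis_trans
  pos$seq_id <- "renamed"
  expect_equal(classify_cis_trans(e, pos)$cis_trans, l1)
})

test_that("lncRNA gates: length, ORF and TE overlap", {
  set.seed(55)
  no_atg <- paste(rep("C", 600), collapse = "")
  long_orf <- paste0("ATG", strrep("GCA", 200), "TAA")  # 200-codon ORF
  short_orf <- paste0(strrep("C", 100), "ATG", strrep("GCT", 39), "TGA",
                      strrep("C", 380))
  tr <- data.frame(
    transcript_id = c("short", "coding", "good", "no_te"),
    sequence = c(strrep("A", 150), long_orf, short_orf, short_orf),
    te_overlap = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  out <- lncrna_filter(tr)
  expect_equal(out$candidate, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$longest_orf_aa[out$transcript_id == "good"], 40L)
  expect_error(lncrna_filter(data.frame(transcript_id = "x",
                                        sequence = "ACGTX",
                                        te_overlap = TRUE)), "non-ACGTN")
})

test_that("longest ORF equals the brute-force 3-frame oracle", {
  set.seed(56)
  for (i in 1:40) {
    s <- rand_dna(sample(100:500, 1))
    expect_equal(longest_orf_aa(s), oracle_orf(s), info = paste("seq", i))
  }
  # overlap computed from intervals when no te_overlap column is given
  tr <- data.frame(transcript_id = "x", sequence = strrep("C", 250),
                   seq_id = "chr1", start = 100L, end = 350L,
                   stringsAsFactors = FALSE)
  te <- data.frame(seq_id = "chr1", start = 300L, end = 700L)
  expect_true(lncrna_filter(tr, te)$candidate)
  te2 <- data.frame(seq_id = "chr1", start = 400L, end = 700L)
  expect_false(lncrna_filter(tr, te2)$candidate)
})
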