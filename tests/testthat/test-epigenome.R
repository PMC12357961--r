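test_that("category map partitions the genome at base resolution", {
  te <- data.frame(seq_id = "chr1", start = 2000L, end = 3000L)
  tip <- data.frame(seq_id = "chr1", start = 1500L, end = 3500L)
  cm <- build_category_map(te, tip, c(chr1 = 10000L))
  tot <- category_totals(cm)
  expect_equal(unname(tot), c(1000L, 0L, 9000L))      # pTE, cTE, nonTE
  expect_equal(sum(tot, na.rm = TRUE), 10000L)

  # partial overlap: only the overlapping bases become pTE
  tip2 <- data.frame(seq_id = "chr1", start = 2500L, end = 3500L)
  cm2 <- build_category_map(te, tip2, c(chr1 = 10000L))
  tot2 <- category_totals(cm2)
  expect_equal(unname(tot2), c(500L, 500L, 9000L))

  # whole-feature mode labels the full TE copy
  cm3 <- build_category_map(te, tip2, c(chr1 = 10000L), mode = "feature")
  expect_equal(unname(category_totals(cm3)), c(1000L, 0L, 9000L))

  expect_error(build_category_map(te, data.frame(seq_id = "chrX",
                                                 start = 1L, end = 2L),
                                  c(chr1 = 10000L)), "mismatch")
})

test_that("category totals always cover the genome without overlap", {
  sim <- toy_sim()
  te_ref <- rbind(sim$truth$deletions[, c("seq_id", "start", "end")],
                  sim$truth$cte[, c("seq_id", "start", "end")])
  tip_ref <- sim$truth$deletions[, c("seq_id", "start", "end")]
  cm <- build_category_map(te_ref, tip_ref, sim$truth$genome_lengths)
  expect_equal(sum(cm$end - cm$start),
               sum(sim$truth$genome_lengths))
  # disjointness: no two intervals on a chromosome overlap
  for (chr in unique(cm$seq_id)) {
    x <- cm[cm$seq_id == chr, ]
    x <- x[order(x$start), ]
    expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
  # planted deletion spans are exactly the pTE space
  expect_equal(unname(category_totals(cm)["pTE"]),
               sum(sim$truth$deletions$end - sim$truth$deletions$start))
})

test_that("peaks covering exactly the pTE space give proportion 1/0/0", {
  te <- data.frame(seq_id = "chr1", start = c(1000L, 5000L),
                   end = c(2000L, 6000L))
  tip <- data.frame(seq_id = "chr1", start = 1000L, end = 2000L)
  cm <- build_category_map(te, tip, c(chr1 = 10000L))
  peaks <- data.frame(mark = "H3K9me2", condition = "0h",
                      seq_id = "chr1", start = 1000L, end = 2000L)
  qm <- quantify_marks(cm, peaks)
  expect_equal(qm$proportion[qm$label == "pTE"], 1.0)
  expect_equal(qm$proportion[qm$label == "cTE"], 0.0)
  expect_equal(qm$proportion[qm$label == "nonTE"], 0.0)
  expect_equal(qm$peak_count[qm$label == "pTE"], 1L)
})

test_that("an empty category reports an undefined proportion, not zero", {
  te <- data.frame(seq_id = "chr1", start = 1000L, end = 2000L)
  tip <- data.frame(seq_id = "chr1", start = 1000L, end = 2000L)  # no cTE
  cm <- build_category_map(te, tip, c(chr1 = 4000L))
  peaks <- data.frame(mark = "m", condition = "c", seq_id = "chr1",
                      start = 1L, end = 2L)
  qm <- quantify_marks(cm, peaks)
  expect_true(is.na(qm$proportion[qm$label == "cTE"]))
})

test_that("planted peak probabilities are recovered within binomial error", {
  # larger genome so the per-category interval counts support a CI
  cfg <- sim_config(seed = 7L, n_genes = 60L, n_deletions = 30L,
                    n_cte = 28L, n_insertions = 20L,
                    n_nonte_insertions = 0L,
                    peak_prob_pTE = c("0h" = 0.46),
                    peak_prob_cTE = c("0h" = 0.27))
  sim <- simulate_pangenome(cfg)
  epi <- simulate_epigenome(sim, cfg)
  te_ref <- rbind(sim$truth$deletions[, c("seq_id", "start", "end")],
                  sim$truth$cte[, c("seq_id", "start", "end")])
  tip_ref <- sim$truth$deletions[, c("seq_id", "start", "end")]
  cm <- build_category_map(te_ref, tip_ref, sim$truth$genome_lengths)
  qm <- quantify_marks(cm, epi$peaks)
  # peak-count-based marked fraction per category against planted probability
  n_pte <- nrow(sim$truth$deletions); n_cte <- nrow(sim$truth$cte)
  phat_pte <- qm$peak_count[qm$label == "pTE"] / n_pte
  phat_cte <- qm$peak_count[qm$label == "cTE"] / n_cte
  expect_lt(abs(phat_pte - 0.46), 2 * sqrt(0.46 * 0.54 / n_pte) + 1e-9)
  expect_lt(abs(phat_cte - 0.27), 2 * sqrt(0.27 * 0.73 / n_cte) + 1e-9)
})

test_that("a planted peak-count increase on pTEs is detected across conditions", {
  sim <- toy_sim()
  epi <- fixture("epi", function() simulate_epigenome(toy_sim()))
  te_ref <- rbind(sim$truth$deletions[, c("seq_id", "start", "end")],
                  sim$truth$cte[, c("seq_id", "start", "end")])
  tip_ref <- sim$truth$deletions[, c("seq_id", "start", "end")]
  cm <- build_category_map(te_ref, tip_ref, sim$truth$genome_lengths)
  qm <- quantify_marks(cm, epi$peaks)
  d_pte <- diff(qm$peak_count[qm$label == "pTE"])   # 72h - 0h
  d_cte <- diff(qm$peak_count[qm$label == "cTE"])
  expect_gte(d_pte, d_cte)   # planted 0.46->0.66 vs 0.27->0.30
})

test_that("GFS scope restricts quantification to gene-flanking space", {
  sim <- toy_sim()
  te_ref <- rbind(sim$truth$deletions[, c("seq_id", "start", "end")],
                  sim$truth$cte[, c("seq_id", "start", "end")])
  tip_ref <- sim$truth$deletions[, c("seq_id", "start", "end")]
  cm <- build_category_map(te_ref, tip_ref, sim$truth$genome_lengths)
  peaks <- data.frame(mark = "m", condition = "c", seq_id = "chr1",
                      start = 0L, end = 1000L)
  wgs <- quantify_marks(cm, peaks, scope = "WGS")
  gfs <- quantify_marks(cm, peaks, scope = "GFS", genes = sim$genes)
  # GFS space is smaller than WGS space for every label present
  for (lab in c("pTE", "cTE", "nonTE")) {
    expect_lte(gfs$bp_total[gfs$label == lab], wgs$bp_total[wgs$label == lab])
  }
  expect_error(quantify_marks(cm, peaks, scope = "GFS"), "requires genes")
})

test_that("methylation means and the zero case behave per category", {
  te <- data.frame(seq_id = "chr1", start = c(0L, 2000L),
                   end = c(1000L, 3000L))
  tip <- data.frame(seq_id = "chr1", start = 0L, end = 1000L)
  cm <- build_category_map(te, tip, c(chr1 = 4000L))
  meth <- data.frame(seq_id = "chr1",
                     pos = c(10L, 500L, 2500L, 3500L),
                     context = "CG",
                     level = c(0, 0, 0, 0), condition = "0h")
  mb <- methylation_by_category(cm, meth)
  expect_true(all(mb$by_label$level == 0))
  expect_equal(mb$n_outside, 0L)
  # a cytosine outside every labelled chromosome is counted, not dropped
  meth2 <- rbind(meth, data.frame(seq_id = "chrX", pos = 1L, context = "CG",
                                  level = 0.5, condition = "0h"))
  expect_equal(methylation_by_category(cm, meth2)$n_outside, 1L)
})

test_that("simulated Beta methylation contrasts are recovered per label", {
  sim <- toy_sim()
  epi <- fixture("epi", function() simulate_epigenome(toy_sim()))
  te_ref <- rbind(sim$truth$deletions[, c("seq_id", "start", "end")],
                  sim$truth$cte[, c("seq_id", "start", "end")])
  tip_ref <- sim$truth$deletions[, c("seq_id", "start", "end")]
  cm <- build_category_map(te_ref, tip_ref, sim$truth$genome_lengths)
  mb <- methylation_by_category(cm, epi$meth)
  bl <- mb$by_label[mb$by_label$condition == "0h", ]
  expect_lt(abs(bl$level[bl$label == "pTE"] - 0.8), 0.05)  # Beta(8,2)
  expect_lt(abs(bl$level[bl$label == "cTE"] - 0.2), 0.05)  # Beta(2,8)
  expect_gt(bl$level[bl$label == "pTE"] - bl$level[bl$label == "cTE"], 0.5)
})
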