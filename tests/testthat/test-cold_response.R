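make_es <- function(values, accession = "acc1", tps = c("0h", "24h"),
                    reps = 3L, kind = NULL) {
  samples <- expand.grid(replicate = seq_len(reps), time_point = tps,
                         accession = accession, stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_r%d", samples$accession,
                            samples$time_point, samples$replicate)
  samples <- samples[, c("sample", "accession", "time_point", "replicate")]
  if (is.null(kind)) kind <- rep("gene", nrow(values))
  expr_set(values, samples, kind)
}

test_that("identical groups give log2FC 0 and no response", {
  v <- matrix(rep(c(4, 4, 4, 4, 4, 4), each = 3), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  es <- make_es(v)
  de <- call_de(es, "acc1", "24h")
  expect_equal(de$log2fc, rep(0, 3))
  expect_false(any(de$responsive))
})

test_that("call_de requires two replicates per group and flags direction", {
  v <- matrix(1, nrow = 2, ncol = 6,
              dimnames = list(c("g1", "g2"), NULL))
  es <- make_es(v, tps = c("0h", "24h"), reps = 3L)
  es$samples$time_point <- c(rep("0h", 5), "24h")
  expect_error(call_de(es, "acc1", "24h"), "fewer than 2 replicates")

  set.seed(3)
  up <- 2^(rnorm(6, c(rep(2, 3), rep(6, 3)), 0.2))
  down <- 2^(rnorm(6, c(rep(6, 3), rep(2, 3)), 0.2))
  v2 <- rbind(g_up = up, g_dn = down)
  de <- call_de(make_es(v2), "acc1", "24h")
  expect_equal(de$direction, c("up", "down"))
  expect_true(all(de$responsive))
})

test_that("DE type-I error stays at the nominal level on null data", {
  set.seed(17)
  n_feat <- 2000L
  fp <- replicate(10, {
    v <- matrix(2^rnorm(n_feat * 6, mean = 5, sd = 0.5), nrow = n_feat,
                dimnames = list(sprintf("g%d", 1:n_feat), NULL))
    de <- call_de(make_es(v), "acc1", "24h")
    mean(de$responsive)
  })
  # responsive requires FDR < 0.05 on null data: essentially nothing passes
  expect_lte(mean(fp), 0.05 + 2 * sd(fp) / sqrt(length(fp)) + 1e-9)
})

test_that("DE power reaches 0.9 for planted 3-log2FC effects", {
  set.seed(18)
  n_feat <- 400L
  planted <- sprintf("g%d", 1:100)
  pow <- replicate(5, {
    base <- rnorm(n_feat, 5, 1)
    v0 <- 2^(matrix(rnorm(n_feat * 6, base, 0.5), nrow = n_feat) )
    shift <- ifelse(seq_len(n_feat) <= 100, 3, 0)
    v1 <- 2^(matrix(rnorm(n_feat * 6, base + shift, 0.5), nrow = n_feat))
    v <- cbind(v0, v1)
    rownames(v) <- sprintf("g%d", 1:n_feat)
    es <- make_es(v, reps = 6L)
    de <- call_de(es, "acc1", "24h")
    mean(de$responsive[de$feature_id %in% planted])
  })
  expect_gte(mean(pow), 0.9)
})

test_that("call_de is invariant to sample column order", {
  set.seed(19)
  v <- matrix(2^rnorm(50 * 6, 5, 0.5), nrow = 50,
              dimnames = list(sprintf("g%d", 1:50), NULL))
  es <- make_es(v)
  perm <- sample(ncol(v))
  es2 <- expr_set(es$values[, perm], es$samples[perm, ], es$feature_kind)
  d1 <- call_de(es, "acc1", "24h"); d2 <- call_de(es2, "acc1", "24h")
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$log2fc, d2$log2fc)
})

test_that("BH adjustment is monotone after step-up enforcement", {
  set.seed(20)
  v <- matrix(2^rnorm(200 * 6, 5, 1), nrow = 200,
              dimnames = list(sprintf("g%d", 1:200), NULL))
  de <- call_de(make_es(v), "acc1", "24h")
  o <- order(de$p_value)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))
  expect_true(all(de$fdr >= de$p_value - 1e-12))
})

test_that("cold-responsive means responsive in any contrast; up/down summary", {
  set.seed(21)
  # g1 responds at 24h only, g2 at 72h only (down), g3 never; t1 (TE) up
  mk <- function(mu) 2^rnorm(3, mu, 0.1)
  v <- rbind(g1 = c(mk(3), mk(6), mk(3)),
             g2 = c(mk(6), mk(6), mk(3)),
             g3 = c(mk(4), mk(4), mk(4)),
             t1 = c(mk(2), mk(5), mk(5)))
  es <- make_es(v, tps = c("0h", "24h", "72h"),
                kind = c("gene", "gene", "gene", "TE"))
  cr <- cold_responsive(es)
  resp <- cr$cold_responsive
  expect_setequal(resp$feature_id[resp$responsive], c("g1", "g2", "t1"))
  ud <- updown_summary(cr$de)
  expect_equal(ud$n[ud$kind == "gene" & ud$time_point == "24h" &
                      ud$direction == "up"], 1L)
  expect_equal(ud$n[ud$kind == "gene" & ud$time_point == "72h" &
                      ud$direction == "down"], 1L)
  expect_equal(sum(ud$n[ud$kind == "TE"]), 2L)  # t1 up at both time points
  expect_equal(nrow(updown_summary(cr$de[cr$de$responsive == FALSE, ])), 0L)
})

test_that("the planted gene-down/TE-up skew is reproduced on the toy data", {
  ex <- fixture("expr", function() simulate_expression(toy_sim()))
  cr <- cold_responsive(ex$es)
  ud <- updown_summary(cr$de)
  gene_down <- sum(ud$n[ud$kind == "gene" & ud$direction == "down"])
  gene_up <- sum(ud$n[ud$kind == "gene" & ud$direction == "up"])
  expect_gte(gene_down, gene_up)   # planted 70% down for genes
})

test_that("+TE/-TE contrast recovers a planted upstream effect", {
  cfg <- sim_config(seed = 5L, n_insertions = 36L, expression_effect = 2,
                    n_nonte_insertions = 0L)
  sim <- simulate_pangenome(cfg)
  dedup <- deduplicate_library(sim$library)
  tips <- annotate_sv_catalog(sim$svs, dedup$retained)
  ev <- classify_events(tips$tips, sim$genes)
  ex <- simulate_expression(sim, cfg)
  tc <- te_presence_contrast(ev, ex$es, tips$presence, "0h")
  up <- tc[tc$location_class == "upstream2k", ]
  expect_gt(up$n_genes, 0)
  expect_lt(up$p_value, 0.001)
  expect_lt(up$median_plus, up$median_minus)
  # exon insertions are expression-neutral in the simulation
  exon <- tc[tc$location_class == "exon", ]
  if (!exon$underpowered) expect_gt(exon$p_value, 0.01)
})

test_that("a single gene's +TE/-TE ordering matches the exact Wilcoxon", {
  # all +TE values below all -TE values: p equals the exact enumeration
  plus <- 1:7; minus <- 11:17
  p_pkg <- wilcox.test(plus, minus, alternative = "two.sided",
                       exact = TRUE)$p.value
  # enumeration oracle: rank-sum distribution over all assignments
  pool <- c(plus, minus)
  combs <- combn(14, 7)
  w_obs <- sum(rank(pool)[1:7]) - 7 * 8 / 2
  w_all <- apply(combs, 2, function(ix) sum(rank(pool)[ix]) - 7 * 8 / 2)
  p_exact <- mean(w_all <= w_obs | w_all >= (7 * 7 - w_obs))
  expect_equal(p_pkg, p_exact)
})

test_that("eQTL scan finds planted pairs and respects the null", {
  sim <- toy_sim()
  tips <- toy_tips()
  ev <- toy_events()
  ex <- fixture("expr", function() simulate_expression(toy_sim()))
  ea <- tip_expression_assoc(ev, ex$es, tips$presence)
  aff <- ex$truth$affected_genes
  hits <- ea$results[ea$results$significant, ]
  planted_pairs <- paste(aff$tip_id, aff$gene_id)
  found <- paste(hits$tip_id, hits$gene_id) %in% planted_pairs
  # a planted causal pair is reported significant with the right direction
  expect_gt(sum(found), 0)
  expect_true(all(hits$direction[found] == "down"))
  # permuted presence: the significant fraction collapses
  set.seed(33)
  perm <- tips$presence[, sample(ncol(tips$presence))]
  colnames(perm) <- colnames(tips$presence)
  ea_p <- tip_expression_assoc(ev, ex$es, perm)
  expect_lte(mean(ea_p$results$significant), 0.05)
  # monomorphic TIPs are skipped with a reason
  mono <- tips$presence
  mono[1, ] <- "present"
  ea_m <- tip_expression_assoc(ev[ev$tip_id == rownames(mono)[1], ],
                               ex$es, mono)
  expect_equal(ea_m$skipped$reason, "monomorphic")
})
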