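#' Simulation configuration
#'
#' Defaults define the package's toy study conditions: a two-subspecies,
#' ten-haplotype miniature pangenome with 200 planted TE insertions whose
#' gene-relative placement follows the upstream:exon:intron:downstream
#' proportions 9131:3201:4358:7686 observed in real TIP maps, plus
#' reference TE copies that are deleted in some haplotypes (deletion-type
#' TIPs) or in none (consensus TEs).
#'
#' @param seed master seed; every sub-generator derives its own stream
#'   from it by a fixed offset, so a fixed seed gives byte-identical
#'   outputs.
#' @param n_chromosomes,n_genes genome layout (genes are placed in
#'   fixed-geometry slots; chromosome length is emergent unless
#'   `chrom_length` is given, in which case the tail is padded to reach it
#'   and an error is raised if it cannot).
#' @param te_superfamilies data.frame (`superfamily`, `min_len`,
#'   `max_len`) of simulated superfamilies.
#' @param n_library_families TE families in the simulated library.
#' @param n_haplotypes_per_subspecies haplotypes per subspecies (two
#'   subspecies, `A` and `B`).
#' @param n_insertions planted insertion-type TIP loci.
#' @param n_nonte_insertions planted insertions of random (non-TE)
#'   sequence — structural variants that must not be called TIPs.
#' @param n_deletions reference TE copies deleted in some haplotypes.
#' @param n_cte reference TE copies present in every haplotype.
#' @param shared_fraction fraction of insertions fixed within one
#'   subspecies and absent from the other (fixed-differential).
#' @param location_weights unnormalized placement weights for
#'   upstream2k/exon/intron/downstream2k.
#' @param mutation_rate per-base substitution rate applied to each planted
#'   TE copy (<= 5 percent keeps copies within the 80-80 family rule).
#' @param tsd_max maximum target-site-duplication length (bp).
#' @param expression_effect log2 expression shift (downward) for carriers
#'   of upstream/intron insertions.
#' @param expr_noise_sd replicate noise SD on the log2 scale.
#' @param n_replicates expression replicates per time point.
#' @param cold_fraction fraction of features given a true cold response.
#' @param peak_prob_pTE,peak_prob_cTE per-condition peak probabilities
#'   (named vectors over conditions).
#' @param meth_beta list of Beta(a, b) parameters per category.
#' @param n_accessions genotype-panel size (two subpopulations).
#' @param causal_effect phenotype shift (survival percentage points) for
#'   homozygous carriers of the causal TIP.
#' @param noise_sd phenotype residual SD.
#' @param chrom_length optional minimum chromosome length (bp).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_chromosomes = 2L,
                       n_genes = 40L,
                       te_superfamilies = NULL,
                       n_library_families = 12L,
                       n_haplotypes_per_subspecies = 5L,
                       n_insertions = 200L,
                       n_nonte_insertions = 10L,
                       n_deletions = 16L,
                       n_cte = 20L,
                       shared_fraction = 0.3,
                       location_weights = c(upstream2k = 9131, exon = 3201,
                                            intron = 4358,
                                            downstream2k = 7686),
                       mutation_rate = 0.02,
                       tsd_max = 10L,
                       expression_effect = 2,
                       expr_noise_sd = 0.5,
                       n_replicates = 3L,
                       cold_fraction = 0.3,
                       peak_prob_pTE = c("0h" = 0.46, "72h" = 0.66),
                       peak_prob_cTE = c("0h" = 0.27, "72h" = 0.30),
                       meth_beta = list(pTE = c(8, 2), cTE = c(2, 8),
                                        nonTE = c(1, 9)),
                       n_accessions = 200L,
                       causal_effect = 40,
                       noise_sd = 10,
                       chrom_length = NULL) {
  if (is.null(te_superfamilies))
    te_superfamilies <- data.frame(
      superfamily = c("LTR/Gypsy", "LTR/Copia", "MITE/Tourist",
                      "DNA/Mutator", "DNA/Helitron", "LINE/L1"),
      min_len = c(800L, 700L, 150L, 300L, 500L, 600L),
      max_len = c(1500L, 1200L, 450L, 800L, 1000L, 1200L),
      stringsAsFactors = FALSE)
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            all(peak_prob_pTE >= 0 & peak_prob_pTE <= 1),
            all(peak_prob_cTE >= 0 & peak_prob_cTE <= 1),
            n_genes %% n_chromosomes == 0L)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  s <- strsplit(seq, "")[[1L]]
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}

# partition `total` into n parts each >= minw
rand_partition <- function(total, n, minw) {
  extra <- total - n * minw
  if (extra < 0L) stop("cannot partition")
  if (n == 1L) return(total)
  cuts <- sort(sample.int(extra + 1L, n - 1L, replace = TRUE) - 1L)
  minw + diff(c(0L, cuts, extra))
}

#' Simulate a miniature pangenome with planted TE polymorphisms
#'
#' Builds a reference genome with genes and reference TE copies, a TE
#' library, and per-haplotype genomes equal to the reference with planted
#' TE insertions (library copies with point mutations and a 5' target-site
#' duplication) and deletions of reference TE copies. The emitted VCF
#' encodes exactly the planted variants; the truth table is a complete
#' account of every one.
#'
#' @param config a [sim_config].
#' @param outdir optional directory; when given, writes `reference.fa`,
#'   per-haplotype FASTAs, `genes.gff3`, `te_library.fa`, `svs.vcf` and
#'   truth TSVs.
#' @return list of class `sim_pangenome`: `reference`, `haplotypes`,
#'   `genes` (a [gene_set]), `library` (a [te_library]), `svs` (an
#'   `sv_set`), `truth` (list: `insertions`, `deletions`, `cte`,
#'   `genome_lengths`, `accessions`, `subspecies`).
#' @export
simulate_pangenome <- function(config = sim_config(), outdir = NULL) {
  set.seed(config$seed)
  sf <- config$te_superfamilies
  n_fam <- config$n_library_families
  fam_sup <- sf$superfamily[rep_len(seq_len(nrow(sf)), n_fam)]
  fam_len <- integer(n_fam)
  fam_seq <- character(n_fam)
  for (i in seq_len(n_fam)) {
    r <- sf[sf$superfamily == fam_sup[i], ][1L, ]
    fam_len[i] <- sample(r$min_len:r$max_len, 1L)
    fam_seq[i] <- random_dna(fam_len[i])
  }
  lib <- te_library(sprintf("FAM%02d", seq_len(n_fam)), fam_sup, fam_seq)

  n_per <- config$n_genes %/% config$n_chromosomes
  n_slots <- config$n_genes
  # assign reference TE copies (cTE + deletion-source) to distinct slots
  if (config$n_cte + config$n_deletions > n_slots)
    stop("chromosome too short to host requested genes and TE copies; ",
         "reduce n_cte + n_deletions or raise n_genes")
  copy_slots <- sample.int(n_slots, config$n_cte + config$n_deletions)
  del_slots <- copy_slots[seq_len(config$n_deletions)]
  cte_slots <- copy_slots[-seq_len(config$n_deletions)]

  reference <- character(config$n_chromosomes)
  names(reference) <- sprintf("chr%d", seq_len(config$n_chromosomes))
  genes_df <- list(); exons_df <- list(); copies <- list()
  slot_id <- 0L
  for (ch in seq_len(config$n_chromosomes)) {
    pieces <- character(0); cur <- 0L
    for (k in seq_len(n_per)) {
      slot_id <- slot_id + 1L
      gid <- sprintf("gene%03d", slot_id)
      # slot layout (final coordinates):
      #   200 rand | TE copy (optional) | 2100 rand | 2000 upstream zone |
      #   gene | 2000 downstream zone | 800 tail
      pieces <- c(pieces, random_dna(200L)); cur <- cur + 200L
      if (slot_id %in% copy_slots) {
        fam <- sample.int(n_fam, 1L)
        cseq <- mutate_seq(fam_seq[fam], config$mutation_rate)
        copies[[length(copies) + 1L]] <- data.frame(
          event_id = sprintf("REFTE%03d", slot_id),
          seq_id = names(reference)[ch], start = cur,
          end = cur + nchar(cseq), family_id = lib$family_id[fam],
          superfamily = fam_sup[fam],
          role = if (slot_id %in% del_slots) "deletion_source" else "cte",
          stringsAsFactors = FALSE)
        pieces <- c(pieces, cseq); cur <- cur + nchar(cseq)
      }
      pieces <- c(pieces, random_dna(2100L + 2000L)); cur <- cur + 4100L
      # gene: 2-4 exons, exon/intron widths >= 150
      glen <- sample(1200:2000, 1L)
      n_ex <- sample(2:4, 1L)
      widths <- rand_partition(glen, 2L * n_ex - 1L, 150L)
      strand <- sample(c("+", "-"), 1L)
      gstart <- cur
      genes_df[[slot_id]] <- data.frame(
        gene_id = gid, seq_id = names(reference)[ch], start = gstart,
        end = gstart + glen, strand = strand, stringsAsFactors = FALSE)
      off <- gstart + cumsum(c(0L, widths))[seq_len(2L * n_ex - 1L)]
      exi <- seq(1L, 2L * n_ex - 1L, by = 2L)
      exons_df[[slot_id]] <- data.frame(
        gene_id = gid, seq_id = names(reference)[ch], start = off[exi],
        end = off[exi] + widths[exi], strand = strand,
        stringsAsFactors = FALSE)
      pieces <- c(pieces, random_dna(glen)); cur <- cur + glen
      pieces <- c(pieces, random_dna(2000L + 800L)); cur <- cur + 2800L
    }
    if (!is.null(config$chrom_length)) {
      if (cur > config$chrom_length)
        stop("chromosome too short to host requested genes/insertions: ",
             "need at least ", cur, " bp")
      if (cur < config$chrom_length)
        pieces <- c(pieces, random_dna(config$chrom_length - cur))
      cur <- max(cur, config$chrom_length)
    }
    reference[ch] <- paste(pieces, collapse = "")
  }
  genes <- gene_set(do.call(rbind, genes_df), do.call(rbind, exons_df))
  copies <- if (length(copies)) do.call(rbind, copies) else
    data.frame(event_id = character(0), seq_id = character(0),
               start = integer(0), end = integer(0),
               family_id = character(0), superfamily = character(0),
               role = character(0))

  n_hap <- 2L * config$n_haplotypes_per_subspecies
  accessions <- sprintf("hap%02d", seq_len(n_hap))
  subspecies <- stats::setNames(
    rep(c("A", "B"), each = config$n_haplotypes_per_subspecies), accessions)

  draw_carriers <- function(fixed) {
    if (fixed) {
      grp <- sample(c("A", "B"), 1L)
      return(accessions[subspecies == grp])
    }
    repeat {
      car <- accessions[stats::runif(n_hap) < 0.5]
      if (length(car) > 0L) return(car)
    }
  }

  # planted insertion events
  cls_prob <- config$location_weights / sum(config$location_weights)
  g <- genes$genes; ex <- genes$exons
  used_pos <- new.env(hash = TRUE)
  ins <- list()
  n_fixed <- round(config$shared_fraction * config$n_insertions)
  for (i in seq_len(config$n_insertions)) {
    for (attempt in 1:100) {
      gi <- sample.int(nrow(g), 1L)
      cls <- sample(names(cls_prob), 1L, prob = cls_prob)
      minus <- g$strand[gi] == "-"
      b <- switch(cls,
        upstream2k = if (!minus) g$start[gi] - sample.int(2000L, 1L)
                     else g$end[gi] + sample.int(2000L, 1L) - 1L,
        downstream2k = if (!minus) g$end[gi] + sample.int(2000L, 1L) - 1L
                       else g$start[gi] - sample.int(2000L, 1L),
        exon = {
          exk <- ex[ex$gene_id == g$gene_id[gi], , drop = FALSE]
          e <- exk[sample.int(nrow(exk), 1L), ]
          e$start + sample.int(e$end - e$start, 1L) - 1L
        },
        intron = {
          exk <- ex[ex$gene_id == g$gene_id[gi], , drop = FALSE]
          ii <- sample.int(nrow(exk) - 1L, 1L)
          s0 <- exk$end[ii]; e0 <- exk$start[ii + 1L]
          s0 + sample.int(e0 - s0, 1L) - 1L
        })
      key <- paste(g$seq_id[gi], b)
      if (b < 10L || !is.null(used_pos[[key]])) next
      used_pos[[key]] <- TRUE
      fam <- sample.int(n_fam, 1L)
      tsd <- sample(0:config$tsd_max, 1L)
      ins[[i]] <- data.frame(
        event_id = sprintf("INS%04d", i), seq_id = g$seq_id[gi],
        breakpoint = b, gene_id = g$gene_id[gi], location_class = cls,
        family_id = lib$family_id[fam], superfamily = fam_sup[fam],
        tsd = tsd, fixed_differential = i <= n_fixed,
        sequence = mutate_seq(fam_seq[fam], config$mutation_rate),
        carriers = paste(draw_carriers(i <= n_fixed), collapse = ";"),
        stringsAsFactors = FALSE)
      break
    }
    if (is.null(ins[[i]])) stop("could not place insertion ", i,
                                "; chromosome too short/crowded")
  }
  ins <- if (config$n_insertions > 0L) do.call(rbind, ins) else
    data.frame(event_id = character(0), seq_id = character(0),
               breakpoint = integer(0), gene_id = character(0),
               location_class = character(0), family_id = character(0),
               superfamily = character(0), tsd = integer(0),
               fixed_differential = logical(0), sequence = character(0),
               carriers = character(0))

  # non-TE insertions: random sequence, must never be called a TIP
  nonte <- vector("list", config$n_nonte_insertions)
  for (i in seq_len(config$n_nonte_insertions)) {
    for (attempt in 1:100) {
      gi <- sample.int(nrow(g), 1L)
      side <- sample(c(-1L, 1L), 1L)
      b <- if (side < 0L) g$start[gi] - sample.int(2000L, 1L)
           else g$end[gi] + sample.int(2000L, 1L) - 1L
      key <- paste(g$seq_id[gi], b)
      if (b < 10L || !is.null(used_pos[[key]])) next
      used_pos[[key]] <- TRUE
      nonte[[i]] <- data.frame(
        event_id = sprintf("NTE%04d", i), seq_id = g$seq_id[gi],
        breakpoint = b, tsd = sample(0:config$tsd_max, 1L),
        sequence = random_dna(sample(300:800, 1L)),
        carriers = paste(draw_carriers(FALSE), collapse = ";"),
        stringsAsFactors = FALSE)
      break
    }
    if (is.null(nonte[[i]])) stop("could not place non-TE insertion ", i)
  }
  nonte <- if (config$n_nonte_insertions > 0L) do.call(rbind, nonte) else
    data.frame(event_id = character(0), seq_id = character(0),
               breakpoint = integer(0), tsd = integer(0),
               sequence = character(0), carriers = character(0))

  dels <- copies[copies$role == "deletion_source", , drop = FALSE]
  if (nrow(dels)) {
    dels$event_id <- sprintf("DEL%04d", seq_len(nrow(dels)))
    dels$carriers <- vapply(seq_len(nrow(dels)), function(i)
      paste(draw_carriers(FALSE), collapse = ";"), "")
  }
  cte <- copies[copies$role == "cte", , drop = FALSE]

  # haplotype sequences: apply carried events right to left
  haplotypes <- stats::setNames(vector("list", n_hap), accessions)
  for (h in accessions) {
    hap <- reference
    for (ch in names(reference)) {
      evs <- list()
      ii <- rbind(ins[ins$seq_id == ch,
                      c("breakpoint", "tsd", "sequence", "carriers")],
                  nonte[nonte$seq_id == ch,
                        c("breakpoint", "tsd", "sequence", "carriers")])
      for (r in seq_len(nrow(ii)))
        if (h %in% strsplit(ii$carriers[r], ";")[[1L]])
          evs[[length(evs) + 1L]] <- list(type = "ins", pos = ii$breakpoint[r],
                                          row = ii[r, ])
      dd <- dels[dels$seq_id == ch, , drop = FALSE]
      for (r in seq_len(nrow(dd)))
        if (h %in% strsplit(dd$carriers[r], ";")[[1L]])
          evs[[length(evs) + 1L]] <- list(type = "del", pos = dd$start[r],
                                          row = dd[r, ])
      if (!length(evs)) next
      ord <- order(-vapply(evs, `[[`, 0, "pos"))
      s <- hap[[ch]]
      for (e in evs[ord]) {
        if (e$type == "ins") {
          b <- e$pos; t <- e$row$tsd
          tsd_seq <- if (t > 0L) substr(s, b - t + 1L, b) else ""
          s <- paste0(substr(s, 1L, b), tsd_seq, e$row$sequence,
                      substr(s, b + 1L, nchar(s)))
        } else {
          s <- paste0(substr(s, 1L, e$row$start),
                      substr(s, e$row$end + 1L, nchar(s)))
        }
      }
      hap[[ch]] <- s
    }
    haplotypes[[h]] <- hap
  }

  # VCF records for every planted event
  gt_row <- function(carriers) {
    gt <- rep("0/0", n_hap)
    gt[accessions %in% strsplit(carriers, ";")[[1L]]] <- "1/1"
    gt
  }
  rec <- list()
  all_ins <- rbind(ins[, c("event_id", "seq_id", "breakpoint", "tsd",
                           "sequence", "carriers")],
                   nonte[, c("event_id", "seq_id", "breakpoint", "tsd",
                             "sequence", "carriers")])
  for (r in seq_len(nrow(all_ins))) {
    b <- all_ins$breakpoint[r]; chr <- all_ins$seq_id[r]
    ref_base <- substr(reference[[chr]], b, b)        # 0-based b-1
    tsd_seq <- if (all_ins$tsd[r] > 0L)
      substr(reference[[chr]], b - all_ins$tsd[r] + 1L, b) else ""
    rec[[length(rec) + 1L]] <- list(
      chrom = chr, pos1 = b, id = all_ins$event_id[r], ref = ref_base,
      alt = paste0(ref_base, tsd_seq, all_ins$sequence[r]),
      gt = gt_row(all_ins$carriers[r]))
  }
  for (r in seq_len(nrow(dels))) {
    chr <- dels$seq_id[r]; s0 <- dels$start[r]; e0 <- dels$end[r]
    ref_seq <- substr(reference[[chr]], s0, e0)       # 0-based s0-1 .. e0-1
    rec[[length(rec) + 1L]] <- list(
      chrom = chr, pos1 = s0, id = dels$event_id[r], ref = ref_seq,
      alt = substr(reference[[chr]], s0, s0), gt = gt_row(dels$carriers[r]))
  }
  ord <- order(vapply(rec, `[[`, "", "chrom"),
               vapply(rec, `[[`, 0, "pos1"))
  rec <- rec[ord]
  sites <- data.frame(
    sv_id = vapply(rec, `[[`, "", "id"),
    seq_id = vapply(rec, `[[`, "", "chrom"),
    start = vapply(rec, `[[`, 0, "pos1") - 1L,
    end = vapply(rec, `[[`, 0, "pos1") - 1L +
      nchar(vapply(rec, `[[`, "", "ref")),
    ref = vapply(rec, `[[`, "", "ref"), stringsAsFactors = FALSE)
  gt <- if (length(rec)) do.call(rbind, lapply(rec, `[[`, "gt")) else
    matrix(character(0), 0L, n_hap)
  colnames(gt) <- accessions; rownames(gt) <- sites$sv_id
  svs <- structure(list(sites = sites,
                        alts = as.list(vapply(rec, `[[`, "", "alt")),
                        gt = gt), class = "sv_set")

  truth <- list(insertions = ins, nonte_insertions = nonte,
                deletions = dels, cte = cte,
                genome_lengths = vapply(reference, nchar, 0L),
                accessions = accessions, subspecies = subspecies)
  out <- structure(list(reference = reference, haplotypes = haplotypes,
                        genes = genes, library = lib, svs = svs,
                        truth = truth, config = config),
                   class = "sim_pangenome")
  if (!is.null(outdir)) write_sim_pangenome(out, outdir)
  out
}

#' @export
print.sim_pangenome <- function(x, ...) {
  cat("sim_pangenome:", length(x$reference), "chromosomes,",
      nrow(x$genes$genes), "genes,", length(x$haplotypes), "haplotypes,",
      nrow(x$truth$insertions), "planted insertions,",
      nrow(x$truth$deletions), "planted deletions\n")
  invisible(x)
}

write_sim_pangenome <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$reference, file.path(outdir, "reference.fa"))
  for (h in names(sim$haplotypes))
    write_fasta(sim$haplotypes[[h]], file.path(outdir, paste0(h, ".fa")))
  write_gff3(file.path(outdir, "genes.gff3"), genes = sim$genes)
  write_te_library(sim$library, file.path(outdir, "te_library.fa"))
  write_sv_vcf(sim$svs, file.path(outdir, "svs.vcf"))
  write_tsv(sim$truth$insertions, file.path(outdir, "truth_insertions.tsv"))
  write_tsv(sim$truth$nonte_insertions,
            file.path(outdir, "truth_nonte_insertions.tsv"))
  write_tsv(sim$truth$deletions, file.path(outdir, "truth_deletions.tsv"))
  write_tsv(data.frame(accession = sim$truth$accessions,
                       subspecies = unname(sim$truth$subspecies)),
            file.path(outdir, "subspecies.tsv"))
  invisible(outdir)
}

#' Simulate expression matrices with planted pTE and cold effects
#'
#' Log-normal baselines; carriers of upstream/intron insertions are
#' shifted down by `expression_effect` log2 units at every time point
#' (polymorphic TEs near promoters and in introns associate with lower
#' expression); a seeded fraction of genes and TE families receives a true
#' cold response at 24 h and 72 h (genes mostly down, TEs mostly up);
#' replicate noise is i.i.d. normal on the log2 scale.
#'
#' @param sim a `sim_pangenome`.
#' @param config the [sim_config] (defaults to the one inside `sim`).
#' @return list: `es` (an [expr_set]) and `truth` (`affected_genes`,
#'   `cold_responders`).
#' @export
simulate_expression <- function(sim, config = sim$config) {
  set.seed(config$seed + 1000L)
  genes <- sim$genes$genes$gene_id
  tes <- sim$library$family_id
  feats <- c(genes, tes)
  kind <- c(rep("gene", length(genes)), rep("TE", length(tes)))
  acc <- sim$truth$accessions
  tps <- c("0h", "24h", "72h")
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         time_point = tps, accession = acc,
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_r%d", samples$accession,
                            samples$time_point, samples$replicate)
  samples <- samples[, c("sample", "accession", "time_point", "replicate")]

  base <- stats::rnorm(length(feats), mean = 5, sd = 1)
  names(base) <- feats

  # pTE expression effect: carriers of any upstream/intron insertion
  ins <- sim$truth$insertions
  aff <- ins[ins$location_class %in% c("upstream2k", "intron"), ,
             drop = FALSE]
  affected <- list()
  eff_mat <- matrix(0, nrow = length(feats), ncol = length(acc),
                    dimnames = list(feats, acc))
  for (gid in unique(aff$gene_id)) {
    # one causal TIP per gene: the first upstream/intron event planted at
    # it; additional TIPs near the same gene stay expression-neutral, so
    # each affected gene has a clean carrier/non-carrier contrast
    row <- aff[aff$gene_id == gid, , drop = FALSE][1L, ]
    carriers <- strsplit(row$carriers, ";")[[1L]]
    if (length(carriers) == 0L ||
        length(carriers) == length(acc)) next      # no contrast possible
    eff_mat[gid, carriers] <- -config$expression_effect
    affected[[length(affected) + 1L]] <- data.frame(
      gene_id = gid, tip_id = row$event_id,
      effect = -config$expression_effect, stringsAsFactors = FALSE)
  }
  affected <- if (length(affected)) do.call(rbind, affected) else NULL

  # cold responders
  n_resp <- round(config$cold_fraction * length(feats))
  resp_idx <- sample.int(length(feats), n_resp)
  direction <- ifelse(kind[resp_idx] == "gene",
                      ifelse(stats::runif(n_resp) < 0.7, -1, 1),
                      ifelse(stats::runif(n_resp) < 0.7, 1, -1))
  lfc24 <- stats::runif(n_resp, 1.5, 3) * direction
  cold <- data.frame(feature_id = feats[resp_idx], kind = kind[resp_idx],
                     lfc_24h = lfc24, lfc_72h = 1.2 * lfc24,
                     stringsAsFactors = FALSE)

  vals <- matrix(0, nrow = length(feats), ncol = nrow(samples),
                 dimnames = list(feats, samples$sample))
  cold_shift <- matrix(0, nrow = length(feats), ncol = 3L,
                       dimnames = list(feats, tps))
  cold_shift[resp_idx, "24h"] <- lfc24
  cold_shift[resp_idx, "72h"] <- 1.2 * lfc24
  for (j in seq_len(nrow(samples))) {
    mu <- base + eff_mat[, samples$accession[j]] +
      cold_shift[, samples$time_point[j]]
    vals[, j] <- 2^(mu + stats::rnorm(length(feats),
                                      sd = config$expr_noise_sd))
  }
  list(es = expr_set(vals, samples, kind, unit = "FPKM"),
       truth = list(affected_genes = affected, cold_responders = cold))
}

#' Simulate peak and methylation data enriched on polymorphic TEs
#'
#' Every pTE interval (deletion-source TE span on the reference) carries a
#' peak with the condition-dependent probability `peak_prob_pTE`, every
#' cTE with `peak_prob_cTE`; per-cytosine methylation levels are drawn
#' from category-specific Beta distributions.
#'
#' @param sim a `sim_pangenome`.
#' @param config the [sim_config].
#' @param mark mark name recorded in the peak set.
#' @param meth_sites_per_kb cytosines simulated per kb of each category.
#' @return list: `peaks` (data.frame `mark`, `condition`, `seq_id`,
#'   `start`, `end`) and `meth` (data.frame `seq_id`, `pos`, `context`,
#'   `level`, `condition`).
#' @export
simulate_epigenome <- function(sim, config = sim$config, mark = "H3K9me2",
                               meth_sites_per_kb = 20) {
  set.seed(config$seed + 2000L)
  pte <- sim$truth$deletions
  cte <- sim$truth$cte
  conds <- names(config$peak_prob_pTE)
  peaks <- list(); meth <- list()
  # one latent uniform per interval shared across conditions: a peak
  # present at a low-probability condition persists at a higher one, so a
  # planted probability increase always yields a peak-count increase
  u_pte <- if (nrow(pte)) stats::runif(nrow(pte)) else numeric(0)
  u_cte <- if (nrow(cte)) stats::runif(nrow(cte)) else numeric(0)
  draw_peaks <- function(iv, u, prob, cond) {
    if (!nrow(iv) || prob <= 0) return(NULL)
    hit <- u < prob
    if (!any(hit)) return(NULL)
    data.frame(mark = mark, condition = cond,
               seq_id = iv$seq_id[hit],
               start = pmax(iv$start[hit] - 50L, 0L),
               end = iv$end[hit] + 50L, stringsAsFactors = FALSE)
  }
  glen <- sim$truth$genome_lengths
  occupied <- rbind(pte[, c("seq_id", "start", "end")],
                    cte[, c("seq_id", "start", "end")])
  draw_meth <- function(iv, ab, cond) {
    if (!nrow(iv)) return(NULL)
    n_per <- pmax(1L, round((iv$end - iv$start) / 1000 * meth_sites_per_kb))
    pos <- unlist(lapply(seq_len(nrow(iv)), function(i)
      iv$start[i] + sort(sample.int(iv$end[i] - iv$start[i], n_per[i]) - 1L)))
    chr <- rep(iv$seq_id, n_per)
    data.frame(seq_id = chr, pos = pos,
               context = sample(c("CG", "CHG", "CHH"), length(pos),
                                replace = TRUE),
               level = stats::rbeta(length(pos), ab[1L], ab[2L]),
               condition = cond, stringsAsFactors = FALSE)
  }
  # non-TE sampling space: a random set of windows outside TE copies
  nonte_iv <- do.call(rbind, lapply(names(glen), function(chr) {
    occ <- occupied[occupied$seq_id == chr, , drop = FALSE]
    cand_start <- sample.int(glen[[chr]] - 1000L, 20L)
    keep <- vapply(cand_start, function(s)
      !any(occ$start < s + 1000L & occ$end > s), TRUE)
    data.frame(seq_id = chr, start = cand_start[keep],
               end = cand_start[keep] + 1000L, stringsAsFactors = FALSE)
  }))
  for (cond in conds) {
    peaks[[cond]] <- rbind(
      draw_peaks(pte, u_pte, config$peak_prob_pTE[[cond]], cond),
      draw_peaks(cte, u_cte, config$peak_prob_cTE[[cond]], cond))
    meth[[cond]] <- rbind(
      draw_meth(pte, config$meth_beta$pTE, cond),
      draw_meth(cte, config$meth_beta$cTE, cond),
      draw_meth(nonte_iv, config$meth_beta$nonTE, cond))
  }
  list(peaks = do.call(rbind, peaks), meth = do.call(rbind, meth))
}

#' Simulate a two-subpopulation genotype panel and survival phenotype
#'
#' TIP allele frequencies are differentiated between two subpopulations;
#' the phenotype is mu + causal_effect x (dosage / 2) + a small polygenic
#' term from background TIPs + Normal(0, noise_sd), truncated to
#' `[0, 100]`.
#'
#' @param sim a `sim_pangenome`.
#' @param config the [sim_config].
#' @param causal_freqs carrier allele frequency of the causal TIP in the
#'   two subpopulations.
#' @param pheno_mean baseline survival percentage.
#' @param polygenic_sd SD of the total polygenic contribution.
#' @return list: `panel` (a [genotype_panel]), `phenotype` (named vector),
#'   `causal_tip_id`, `subpop` (named vector).
#' @export
simulate_population <- function(sim, config = sim$config,
                                causal_freqs = c(0.7, 0.3),
                                pheno_mean = 50, polygenic_sd = 3) {
  set.seed(config$seed + 3000L)
  ins <- sim$truth$insertions
  dels <- sim$truth$deletions
  variants <- data.frame(
    variant_id = c(ins$event_id, dels$event_id),
    seq_id = c(ins$seq_id, dels$seq_id),
    pos = c(ins$breakpoint, dels$start), stringsAsFactors = FALSE)
  m <- nrow(variants)
  n <- config$n_accessions
  acc <- sprintf("acc%03d", seq_len(n))
  subpop <- stats::setNames(rep(c("P1", "P2"), length.out = n), acc)
  # causal TIP: first upstream-class insertion
  up <- ins$event_id[ins$location_class == "upstream2k"]
  causal <- if (length(up)) up[1L] else variants$variant_id[1L]
  f_base <- stats::rbeta(m, 2, 2)
  delta <- stats::rnorm(m, 0, 0.15)
  f1 <- pmin(pmax(f_base + delta, 0.02), 0.98)
  f2 <- pmin(pmax(f_base - delta, 0.02), 0.98)
  ci <- match(causal, variants$variant_id)
  f1[ci] <- causal_freqs[1L]; f2[ci] <- causal_freqs[2L]
  calls <- matrix(NA_integer_, n, m, dimnames = list(acc, NULL))
  p1 <- subpop == "P1"
  for (j in seq_len(m)) {
    calls[p1, j] <- stats::rbinom(sum(p1), 2L, f1[j])
    calls[!p1, j] <- stats::rbinom(sum(!p1), 2L, f2[j])
  }
  panel <- genotype_panel(calls, variants, subpop)
  bg <- setdiff(seq_len(m), ci)
  b <- stats::rnorm(length(bg), 0, polygenic_sd / sqrt(length(bg)))
  Zc <- sweep(calls[, bg, drop = FALSE], 2L, colMeans(calls[, bg,
                                                            drop = FALSE]))
  pheno <- pheno_mean + config$causal_effect * calls[, ci] / 2 +
    as.vector(Zc %*% b) + stats::rnorm(n, 0, config$noise_sd)
  pheno <- pmin(pmax(pheno, 0), 100)
  names(pheno) <- acc
  list(panel = panel, phenotype = pheno, causal_tip_id = causal,
       subpop = subpop)
}
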