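#' Run the TIP-map pipeline end-to-end on a simulated pangenome
#'
#' Stages, in dependency order: simulate the pangenome; deduplicate the TE
#' library; annotate SV alleles under the 80-80 rule and call TIP sites;
#' classify TIP-gene events and conservation flags; build the pTE/cTE/
#' non-TE category map and quantify simulated peaks and methylation; call
#' cold-responsive features; build the consensus co-expression network;
#' filter and scan the genotype panel and compare haplotype survival.
#' All tabular outputs are written as TSV together with a reproducibility
#' manifest (configuration, seed, package version, file checksums).
#'
#' @param config a [sim_config].
#' @param outdir output directory (created; must not already contain a
#'   manifest — outputs are write-once per run directory).
#' @param stages character vector of stage names to run (dependencies are
#'   not re-derived; upstream stages must be included).
#' @return invisible list with the in-memory stage results.
#' @export
run_tip_pipeline <- function(config = sim_config(), outdir,
                             stages = c("simulate", "annotate", "map",
                                        "epimark", "de", "coexpress",
                                        "assoc")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(outdir, "manifest.tsv")))
    stop("output directory already holds a run; outputs are write-once")
  res <- list(config = config)

  need <- function(stage, dep) {
    if (is.null(res[[dep]]))
      stop("stage '", stage, "' needs output of stage '", dep,
           "' which did not run")
  }

  if ("simulate" %in% stages) {
    res$sim <- simulate_pangenome(config, outdir = file.path(outdir, "sim"))
  }
  if ("annotate" %in% stages) {
    need("annotate", "sim")
    dedup <- deduplicate_library(res$sim$library)
    res$tips <- annotate_sv_catalog(res$sim$svs, dedup$retained,
                                    min_te_fraction = 0.8)
    res$catalog <- summarize_catalog(res$sim$svs)
    write_tsv(res$tips$tips, file.path(outdir, "tip_map.tsv"))
    write_gff3(file.path(outdir, "tip_annotations.gff3"),
               te = do.call(rbind, lapply(res$tips$sites, function(s) {
                 a <- s$annotations
                 data.frame(seq_id = a$target_id, start = a$start,
                            end = a$end, strand = a$strand,
                            superfamily = a$superfamily, score = a$score,
                            id = paste0(s$sv_id, "_",
                                        seq_len(nrow(a))),
                            stringsAsFactors = FALSE)
               })))
  }
  if ("map" %in% stages) {
    need("map", "tips")
    res$events <- classify_events(res$tips$tips, res$sim$genes)
    res$flags <- conservation_flags(res$tips$presence,
                                    res$sim$truth$subspecies)
    res$profile <- insertion_density_profile(res$tips$tips, res$sim$genes)
    write_tsv(res$events, file.path(outdir, "events.tsv"))
    write_tsv(res$profile, file.path(outdir, "insertion_density.tsv"))
    write_tsv(data.frame(tip_id = names(res$flags),
                         flag = unname(res$flags)),
              file.path(outdir, "conservation_flags.tsv"))
  }
  if ("epimark" %in% stages) {
    need("epimark", "tips")
    te_ref <- rbind(res$sim$truth$deletions[, c("seq_id", "start", "end")],
                    res$sim$truth$cte[, c("seq_id", "start", "end")])
    tip_ref <- res$tips$tips[res$tips$tips$sv_class == "deletion",
                             c("seq_id", "start", "end")]
    res$cmap <- build_category_map(te_ref, tip_ref,
                                   res$sim$truth$genome_lengths)
    epi <- simulate_epigenome(res$sim, config)
    res$marks <- quantify_marks(res$cmap, epi$peaks, scope = "WGS")
    res$meth <- methylation_by_category(res$cmap, epi$meth)
    write_bed(res$cmap[, c("seq_id", "start", "end")],
              file.path(outdir, "category_map.bed"))
    write_tsv(res$marks, file.path(outdir, "mark_proportions.tsv"))
    write_tsv(res$meth$by_label, file.path(outdir, "methylation.tsv"))
  }
  if ("de" %in% stages) {
    need("de", "sim")
    expr <- simulate_expression(res$sim, config)
    res$expr <- expr
    cr <- cold_responsive(expr$es)
    res$de <- cr
    write_tsv(cr$de, file.path(outdir, "de_results.tsv"))
    write_tsv(updown_summary(cr$de), file.path(outdir, "updown_summary.tsv"))
  }
  if ("coexpress" %in% stages) {
    need("coexpress", "expr")
    es <- res$expr$es
    s <- es$samples
    key <- paste(s$accession, s$time_point)
    agg <- t(apply(es$values, 1L, function(v) tapply(v, key, mean)))
    cond_tp <- sub("^\\S+ ", "", colnames(agg))
    norm <- preprocess_expression(agg)
    gene_ids <- rownames(norm)[es$feature_kind == "gene"]
    te_ids <- rownames(norm)[es$feature_kind == "TE"]
    pairs <- expand.grid(node_a = gene_ids, node_b = te_ids,
                         stringsAsFactors = FALSE)
    me <- method_edges(norm, cond_tp, pairs = pairs)
    res$network <- consensus_network(me)
    write_tsv(res$network, file.path(outdir, "network.tsv"))
  }
  if ("assoc" %in% stages) {
    need("assoc", "sim")
    pop <- simulate_population(res$sim, config)
    filt <- filter_panel(pop$panel)
    scan <- association_scan(filt$panel, pop$phenotype, model = "lm")
    res$assoc <- list(pop = pop, scan = scan)
    top <- scan$variant_id[which.min(scan$p_value)]
    res$haplo <- haplotype_survival(top, filt$panel, pop$phenotype)
    write_tsv(as.data.frame(scan), file.path(outdir, "association.tsv"))
    write_tsv(res$haplo$groups, file.path(outdir, "haplotype_survival.tsv"))
  }

  # reproducibility manifest
  cfg_flat <- vapply(config, function(v)
    paste(format(unlist(v)), collapse = ","), "")
  files <- setdiff(list.files(outdir, recursive = TRUE, full.names = TRUE),
                   file.path(outdir, "manifest.tsv"))
  manifest <- rbind(
    data.frame(key = paste0("config.", names(cfg_flat)),
               value = unname(cfg_flat), stringsAsFactors = FALSE),
    data.frame(key = "package_version",
               value = as.character(utils::packageVersion("tipscape")),
               stringsAsFactors = FALSE),
    data.frame(key = paste0("md5.", basename(files)),
               value = unname(tools::md5sum(files)),
               stringsAsFactors = FALSE))
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(res)
}
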