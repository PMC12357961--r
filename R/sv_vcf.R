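#' Read a sequence-resolved structural-variant VCF
#'
#' Reads the VCF dialect produced by pangenome-graph deconstruction: every
#' REF and ALT allele is a literal sequence. Symbolic ALT alleles
#' (`<INS>`, `<DEL>`, breakends) are rejected because downstream TE
#' annotation needs the inserted sequence itself. Genotypes, when present,
#' are kept as allele-index strings (`"0/1"`, `"1|1"`, ...; `"."` treated
#' as missing).
#'
#' @param path VCF file (plain text or gzip).
#' @return object of class `sv_set`: list with `sites` (data.frame:
#'   `sv_id`, `seq_id`, `start` (0-based position of the REF allele),
#'   `end`, `ref`), `alts` (list of character vectors, one per site) and
#'   `gt` (character matrix sites x accessions, or `NULL`).
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt_raw <- fix[, "ALT"]
  if (any(grepl("[][<>]", alt_raw)))
    stop("symbolic ALT alleles found; provide a sequence-resolved VCF ",
         "(full REF/ALT sequences, as emitted by graph deconstruction)")
  alts <- strsplit(toupper(alt_raw), ",", fixed = TRUE)
  ref <- toupper(fix[, "REF"])
  pos <- as.integer(fix[, "POS"])
  ids <- fix[, "ID"]
  if (all(is.na(ids)) || is.null(ids)) ids <- rep(NA_character_, length(pos))
  ids[is.na(ids) | ids == "."] <-
    paste0("sv", seq_along(pos))[is.na(ids) | ids == "."]
  sites <- data.frame(sv_id = ids, seq_id = as.character(fix[, "CHROM"]),
                      start = pos - 1L, end = pos - 1L + nchar(ref),
                      ref = ref, stringsAsFactors = FALSE)
  gt <- NULL
  if (ncol(v@gt) > 1L) {
    gt <- vcfR::extract.gt(v, element = "GT")
    rownames(gt) <- ids
  }
  structure(list(sites = sites, alts = alts, gt = gt), class = "sv_set")
}

#' @export
print.sv_set <- function(x, ...) {
  cat("sv_set:", nrow(x$sites), "sites")
  if (!is.null(x$gt)) cat(",", ncol(x$gt), "accessions")
  cat("\n")
  invisible(x)
}

#' Write an `sv_set` as a VCF 4.2 file
#'
#' @param svs an `sv_set`.
#' @param path output file.
#' @export
write_sv_vcf <- function(svs, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=.,Number=0,Type=Flag,Description=\"none\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- !is.null(svs$gt)
  if (has_gt) cols <- c(cols, "FORMAT", colnames(svs$gt))
  s <- svs$sites
  body <- paste(s$seq_id, s$start + 1L, s$sv_id, s$ref,
                vapply(svs$alts, paste, "", collapse = ","),
                ".", "PASS", ".", sep = "\t")
  if (has_gt) {
    gtm <- svs$gt
    gtm[is.na(gtm)] <- "."
    body <- paste(body, "GT", apply(gtm, 1L, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

# Parse one GT string into an integer vector of allele indices, or NULL for
# missing. "0/1" -> c(0L, 1L); "." / "./." -> NULL.
parse_gt <- function(gt) {
  if (is.na(gt)) return(NULL)
  a <- strsplit(gt, "[/|]")[[1L]]
  if (any(a == "." | !nzchar(a))) return(NULL)
  as.integer(a)
}
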