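#' Construct a genotype panel
#'
#' @param calls integer matrix, accessions x variants, values 0/1/2 copies
#'   of the alternate (TE-presence) allele, `NA` missing.
#' @param variants data.frame with `variant_id`, `seq_id`, `pos`.
#' @param subpop optional named vector accession -> subpopulation.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(calls, variants, subpop = NULL) {
  stopifnot(ncol(calls) == nrow(variants))
  colnames(calls) <- variants$variant_id
  structure(list(calls = calls, variants = variants, subpop = subpop),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$calls), "accessions x", ncol(x$calls),
      "variants\n")
  invisible(x)
}

panel_maf <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Filter a genotype panel on MAF and missingness
#'
#' Removes variants with minor-allele frequency below `maf_min` or a
#' missing-call fraction above `max_missing`, and reports removals by
#' reason. Idempotent.
#'
#' @param panel a [genotype_panel].
#' @param maf_min MAF floor (default 0.05).
#' @param max_missing maximum missing fraction (default 0.1).
#' @return list with `panel` (filtered) and `removed` (data.frame
#'   `variant_id`, `reason`).
#' @export
filter_panel <- function(panel, maf_min = 0.05, max_missing = 0.1) {
  maf <- panel_maf(panel$calls)
  miss <- colMeans(is.na(panel$calls))
  drop_maf <- maf < maf_min
  drop_miss <- miss > max_missing
  keep <- !(drop_maf | drop_miss)
  if (!any(keep))
    stop("all variants removed; relax maf_min/max_missing")
  removed <- data.frame(
    variant_id = colnames(panel$calls)[!keep],
    reason = ifelse(drop_miss[!keep], "missingness",
                    "maf")[seq_len(sum(!keep))],
    stringsAsFactors = FALSE)
  out <- genotype_panel(panel$calls[, keep, drop = FALSE],
                        panel$variants[keep, , drop = FALSE], panel$subpop)
  list(panel = out, removed = removed)
}

# mean-imputed, column-centered dosage matrix
imputed_dosage <- function(calls) {
  Z <- calls
  mu <- colMeans(Z, na.rm = TRUE)
  for (j in seq_len(ncol(Z))) Z[is.na(Z[, j]), j] <- mu[j]
  sweep(Z, 2L, mu)
}

#' Realized genotype relationship (kinship) matrix
#'
#' Centered genotype cross-product scaled by the variant count:
#' K = Z Z' / m with Z the mean-imputed, column-centered dosage matrix.
#'
#' @param panel a [genotype_panel].
#' @export
kinship_matrix <- function(panel) {
  Z <- imputed_dosage(panel$calls)
  tcrossprod(Z) / ncol(Z)
}

#' Per-variant association scan against a quantitative phenotype
#'
#' `model = "lm"`: ordinary least squares of phenotype on allele dosage
#' plus the top `n_pcs` genotype principal components.
#' `model = "lmm"`: the same fixed effects plus a random effect with
#' covariance proportional to the realized relationship matrix; the
#' heritability is estimated once on the null model by profiling the
#' likelihood over a grid (0-0.99, step 0.01) on the eigendecomposed
#' kinship, then reused for every variant (EMMAX-style approximation via
#' generalized least squares in the rotated space).
#'
#' @param panel a [genotype_panel].
#' @param phenotype named numeric vector accession -> value (survival %).
#' @param n_pcs number of genotype PCs as fixed covariates (default 3).
#' @param model `"lm"` or `"lmm"`.
#' @param min_n minimum phenotyped accessions (default 30).
#' @return data.frame of class `assoc_scan`: `variant_id`, `beta`, `se`,
#'   `p_value`, `maf`, `n_used`; attribute `lambda_gc` holds the genomic
#'   inflation factor.
#' @export
association_scan <- function(panel, phenotype, n_pcs = 3L,
                             model = c("lm", "lmm"), min_n = 30L) {
  model <- match.arg(model)
  acc <- rownames(panel$calls)
  y <- phenotype[acc]
  use <- !is.na(y)
  if (sum(use) < min_n) stop("phenotype present for fewer than ", min_n,
                             " accessions")
  calls <- panel$calls[use, , drop = FALSE]
  y <- y[use]
  n <- nrow(calls); m <- ncol(calls)
  Z <- imputed_dosage(calls)
  covar <- matrix(1, n, 1L)
  if (n_pcs > 0L) {
    pcs <- stats::prcomp(Z, center = FALSE)$x[, seq_len(min(n_pcs, n - 1L)),
                                              drop = FALSE]
    covar <- cbind(covar, pcs)
  }
  if (model == "lmm") {
    K <- tcrossprod(Z) / m
    eig <- eigen(K, symmetric = TRUE)
    U <- eig$vectors; lam <- pmax(eig$values, 0)
    yr <- crossprod(U, y); Xr <- crossprod(U, covar)
    loglik <- function(h2) {
      d <- h2 * lam + (1 - h2)
      w <- 1 / d
      # profile ML: GLS fit of covariates, then sigma^2 profiled out
      XtWX <- crossprod(Xr, Xr * w)
      beta <- solve(XtWX, crossprod(Xr, yr * w))
      r <- yr - Xr %*% beta
      rss <- sum(w * r^2)
      -0.5 * (n * log(rss / n) + sum(log(d)))
    }
    h2_grid <- seq(0, 0.99, by = 0.01)
    ll <- vapply(h2_grid, loglik, 0)
    h2 <- h2_grid[which.max(ll)]
    d <- h2 * lam + (1 - h2)
    sw <- 1 / sqrt(d)
    # rotate and whiten once; per-variant fits are then ordinary OLS
    y_t <- as.vector(crossprod(U, y)) * sw
    covar_t <- crossprod(U, covar) * sw
    Z_t <- crossprod(U, Z) * sw
  } else {
    y_t <- y; covar_t <- covar; Z_t <- Z
  }
  # residualize phenotype and dosages on covariates (Frisch-Waugh)
  qr_c <- qr(covar_t)
  ry <- stats::resid(stats::lm.fit(covar_t, y_t))
  p_cov <- qr_c$rank
  res <- data.frame(variant_id = colnames(calls), beta = NA_real_,
                    se = NA_real_, p_value = NA_real_,
                    maf = panel_maf(calls), n_used = NA_integer_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    g <- Z_t[, j]
    if (stats::var(calls[, j], na.rm = TRUE) %in% c(0, NA)) next  # monomorphic
    rg <- stats::resid(stats::lm.fit(covar_t, g))
    sxx <- sum(rg^2)
    if (sxx < 1e-12) next
    beta <- sum(rg * ry) / sxx
    df <- n - p_cov - 1L
    rss <- sum((ry - beta * rg)^2)
    se <- sqrt(rss / df / sxx)
    tstat <- beta / se
    res$beta[j] <- beta; res$se[j] <- se
    res$p_value[j] <- 2 * stats::pt(-abs(tstat), df)
    res$n_used[j] <- sum(!is.na(calls[, j]))
  }
  pv <- res$p_value[!is.na(res$p_value)]
  lambda <- if (length(pv))
    stats::median(stats::qchisq(1 - pv, df = 1)) / stats::qchisq(0.5, df = 1)
  else NA_real_
  structure(res, class = c("assoc_scan", "data.frame"), lambda_gc = lambda,
            model = model)
}

#' Haplotype survival comparison at one variant
#'
#' Accessions are grouped into hapA (reference-homozygous), hapB
#' (alternate-homozygous) and heterozygous; missing calls are excluded.
#' hapA and hapB phenotypes are contrasted with a two-tailed Wilcoxon
#' rank-sum test; per-group subpopulation composition is reported.
#'
#' @param variant_id variant to inspect.
#' @param panel a [genotype_panel].
#' @param phenotype named numeric vector accession -> value.
#' @return list with `groups` (data.frame `group`, `n`, `median`),
#'   `p_value` (hapA vs hapB; `NA` with a `skipped` note if a group is
#'   empty) and `subpop_composition`.
#' @export
haplotype_survival <- function(variant_id, panel, phenotype) {
  g <- panel$calls[, variant_id]
  y <- phenotype[rownames(panel$calls)]
  grp <- ifelse(is.na(g), NA, ifelse(g == 0L, "hapA",
                                     ifelse(g == 2L, "hapB", "Hetero")))
  keep <- !is.na(grp) & !is.na(y)
  grp <- grp[keep]; y <- y[keep]
  lv <- c("hapA", "hapB", "Hetero")
  groups <- data.frame(
    group = lv, n = vapply(lv, function(l) sum(grp == l), 0L),
    median = vapply(lv, function(l)
      if (any(grp == l)) stats::median(y[grp == l]) else NA_real_, 0),
    stringsAsFactors = FALSE)
  skipped <- NULL; p <- NA_real_
  if (any(grp == "hapA") && any(grp == "hapB")) {
    p <- suppressWarnings(stats::wilcox.test(
      y[grp == "hapA"], y[grp == "hapB"],
      alternative = "two.sided")$p.value)
  } else skipped <- "a haplotype group is empty; comparison skipped"
  comp <- NULL
  if (!is.null(panel$subpop)) {
    sp <- panel$subpop[rownames(panel$calls)][keep]
    comp <- as.data.frame(table(group = grp, subpop = sp),
                          stringsAsFactors = FALSE)
  }
  list(groups = groups, p_value = p, skipped = skipped,
       subpop_composition = comp)
}
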