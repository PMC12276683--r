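#' EigenGWAS: single-marker association against a leading PC
#'
#' Regresses the pseudo-phenotype (typically PC1 of the genotype matrix for
#' the two populations being contrasted) on each marker's dosage by
#' ordinary least squares with an intercept, excluding missing dosages
#' pairwise. Test statistics are chi-square with 1 df; genomic control
#' deflates them by `lambda_gc = median(chisq) / 0.4549364` (the chi-square
#' 1-df median) before p-values are taken from the upper tail; following
#' standard genomic-control practice, lambda below 1 never inflates
#' statistics (the reported `lambda_gc` stays uncapped). Markers with
#' fewer than 2 minor-allele copies among non-missing samples are skipped
#' (their slope standard error is not usable) and counted.
#'
#' @param gm output of [genotype_matrix()] or a bare samples-by-variants
#'   dosage matrix.
#' @param pc1 per-sample phenotype values (length = number of samples).
#' @return an `EigenScanResult` list: `table` (per-marker beta, se, chisq,
#'   chisq_adj, p_adj plus marker metadata), `lambda_gc`, `n_tested`,
#'   `n_skipped`.
#' @export
eigengwas_scan <- function(gm, pc1) {
  G <- if (is.list(gm)) gm$G else gm
  meta <- if (is.list(gm)) gm$meta else NULL
  if (length(pc1) != nrow(G)) stop("pc1 length must equal the number of samples")
  if (stats::sd(pc1) == 0) stop("pc1 is constant")
  M <- ncol(G)
  beta <- se <- rep(NA_real_, M)
  mac <- vapply(seq_len(M), function(j) {
    g <- G[, j]; g <- g[!is.na(g)]
    min(sum(g), 2 * length(g) - sum(g))
  }, numeric(1))
  testable <- mac >= 2
  if (!any(testable)) stop("all markers monomorphic or near-monomorphic")
  for (j in which(testable)) {
    g <- G[, j]
    ok <- !is.na(g)
    gg <- g[ok]; yy <- pc1[ok]
    n <- length(gg)
    vg <- stats::var(gg)
    if (is.na(vg) || vg == 0 || n < 3) { testable[j] <- FALSE; next }
    b <- stats::cov(gg, yy) / vg
    a <- mean(yy) - b * mean(gg)
    rss <- sum((yy - a - b * gg)^2)
    s2 <- rss / (n - 2)
    beta[j] <- b
    se[j] <- sqrt(s2 / ((n - 1) * vg))
  }
  chisq <- (beta / se)^2
  lambda <- stats::median(chisq[testable], na.rm = TRUE) / 0.4549364
  # standard genomic-control convention: never inflate when lambda < 1
  chisq_adj <- chisq / max(lambda, 1)
  p_adj <- stats::pchisq(chisq_adj, df = 1, lower.tail = FALSE)
  tab <- data.frame(beta = beta, se = se, chisq = chisq,
                    chisq_adj = chisq_adj, p_adj = p_adj,
                    tested = testable)
  if (!is.null(meta)) tab <- cbind(meta, tab)
  structure(list(table = tab, lambda_gc = lambda,
                 n_tested = sum(testable), n_skipped = sum(!testable)),
            class = "EigenScanResult")
}

#' @export
print.EigenScanResult <- function(x, ...) {
  cat(sprintf("EigenGWAS: %d markers tested (%d skipped), lambda_GC = %.3f\n",
              x$n_tested, x$n_skipped, x$lambda_gc))
  invisible(x)
}

#' Bonferroni-significant loci with flank annotation
#'
#' A marker is significant when its genomic-control-adjusted p-value is
#' strictly below `alpha / n`, with `n` the number of tested markers in the
#' scan. Each significant marker is annotated with every gene overlapping
#' the interval `[pos - flank, pos + flank]`, clipped at chromosome bounds.
#'
#' @param res an `EigenScanResult` whose table carries `chrom`/`start`
#'   metadata.
#' @param alpha family-wise error target (default 0.05).
#' @param gene_models list of `GeneModel`s (optional).
#' @param flank annotation flank in bp (default 100 kb).
#' @param chrom_lengths optional named lengths for clipping.
#' @return list: `loci` (significant rows with a `genes` list-column),
#'   `genes` (deduplicated annotated gene ids), `threshold` (= alpha / n).
#' @export
significant_loci <- function(res, alpha = 0.05, gene_models = NULL,
                             flank = 1e5, chrom_lengths = NULL) {
  tab <- res$table
  thr <- alpha / res$n_tested
  sig <- which(tab$tested & !is.na(tab$p_adj) & tab$p_adj < thr)
  loci <- tab[sig, , drop = FALSE]
  gene_sets <- vector("list", length(sig))
  if (!is.null(gene_models) && length(sig) && !is.null(loci$chrom)) {
    gtab <- data.frame(
      chrom = vapply(gene_models, `[[`, "", "chrom"),
      start = vapply(gene_models, `[[`, 0, "start"),
      end = vapply(gene_models, `[[`, 0, "end"),
      name = vapply(gene_models, `[[`, "", "gene_id"),
      stringsAsFactors = FALSE)
    for (i in seq_along(sig)) {
      lo <- max(0, loci$start[i] - flank)
      hi <- loci$start[i] + flank
      if (!is.null(chrom_lengths)) hi <- min(hi, chrom_lengths[[loci$chrom[i]]])
      hit <- gtab$chrom == loci$chrom[i] & gtab$start <= hi & gtab$end > lo
      gene_sets[[i]] <- gtab$name[hit]
    }
  }
  loci$genes <- gene_sets
  list(loci = loci, genes = unique(unlist(gene_sets)), threshold = thr)
}
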