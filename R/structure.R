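#' Extract an analysis-ready genotype matrix
#'
#' Samples-by-variants dosage matrix with per-column metadata, the input to
#' PCA, admixture estimation and EigenGWAS.
#'
#' @param vs a `VariantSet`.
#' @param vtype optional variant types to keep.
#' @param drop_all_missing drop columns with no non-missing call?
#' @return list with `G` (n_samples x n_variants dosage matrix, `NA` =
#'   missing) and `meta` (data.frame: chrom, start, ref, alt, vtype).
#' @export
genotype_matrix <- function(vs, vtype = NULL, drop_all_missing = TRUE) {
  keep <- if (is.null(vtype)) seq_len(n_sites(vs)) else which(vs$sites$vtype %in% vtype)
  G <- t(vs$geno[keep, , drop = FALSE])
  meta <- vs$sites[keep, c("chrom", "start", "ref", "alt", "vtype"), drop = FALSE]
  if (drop_all_missing) {
    ok <- colSums(!is.na(G)) > 0
    G <- G[, ok, drop = FALSE]
    meta <- meta[ok, , drop = FALSE]
  }
  rownames(meta) <- NULL
  list(G = G, meta = meta)
}

#' Principal component analysis of genotype dosages
#'
#' Missing dosages are mean-imputed per variant; columns are centered by
#' `2p` and, by default, scaled by `sqrt(2p(1-p))` (Patterson scaling),
#' where `p` is the observed alt-allele frequency. Monomorphic columns are
#' dropped. Eigendecomposition of the sample covariance yields PCs; each
#' PC's sign is fixed so the sample score of largest magnitude is positive.
#'
#' @param gm output of [genotype_matrix()], or a bare samples-by-variants
#'   matrix.
#' @param n_pc number of components to return.
#' @param scale apply Patterson scaling? (unscaled PCA when `FALSE`).
#' @return a `StructureResult` list: `scores` (samples x n_pc),
#'   `explained` (percent variance per PC, non-increasing), `n_variants`.
#' @export
genotype_pca <- function(gm, n_pc = 10, scale = TRUE) {
  G <- if (is.list(gm)) gm$G else gm
  if (nrow(G) < 2) stop("PCA needs at least 2 samples")
  p <- colMeans(G, na.rm = TRUE) / 2
  v <- apply(G, 2, stats::var, na.rm = TRUE)
  poly <- !is.na(p) & p > 0 & p < 1 & !is.na(v) & v > 0
  if (sum(poly) < 2) stop("fewer than 2 polymorphic variants")
  G <- G[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(G, 2, 2 * p)
  X[is.na(X)] <- 0  # mean imputation after centering
  if (scale) X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  C <- tcrossprod(X) / ncol(X)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  n_pc <- min(n_pc, ncol(eig$vectors))
  scores <- eig$vectors[, seq_len(n_pc), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_pc)]), n_pc)
  for (j in seq_len(n_pc)) {
    i_max <- which.max(abs(scores[, j]))
    if (scores[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  structure(list(scores = scores,
                 explained = 100 * vals[seq_len(n_pc)] / sum(vals),
                 n_variants = ncol(X)),
            class = "StructureResult")
}

#' @export
print.StructureResult <- function(x, ...) {
  if (!is.null(x$scores)) {
    cat(sprintf("PCA on %d variants: PC1 %.1f%%, PC2 %.1f%% of variance\n",
                x$n_variants, x$explained[1],
                if (length(x$explained) > 1) x$explained[2] else 0))
  }
  if (!is.null(x$Q)) {
    cat(sprintf("Admixture K=%d, log-likelihood %.2f (%d EM iterations, best of %d restarts)\n",
                ncol(x$Q), x$loglik[length(x$loglik)], length(x$loglik),
                x$restarts))
  }
  invisible(x)
}

#' Model-based admixture estimation (binomial-mixture EM)
#'
#' Fits the standard unsupervised admixture model: the alt-allele dosage of
#' sample i at variant j is Binomial(2, sum_k q_ik f_kj). EM alternates
#' responsibilities for alt and ref allele copies with closed-form updates
#' of the ancestry matrix Q and component frequencies F. The log-likelihood
#' is non-decreasing; iteration stops when the gain drops below `tol`.
#' Missing dosages are excluded from all sums. The best of `restarts`
#' seeded random initializations is returned.
#'
#' @param gm output of [genotype_matrix()] or a bare dosage matrix.
#' @param K number of ancestral components.
#' @param seed integer seed for the restarts.
#' @param max_iter,tol EM stopping rule.
#' @param restarts number of random restarts.
#' @return a `StructureResult` list: `Q` (samples x K, rows sum to 1), `F`
#'   (K x variants), `loglik` (trace of the best run), `restarts`.
#' @export
admixture_em <- function(gm, K = 2, seed = 1, max_iter = 500, tol = 1e-4,
                         restarts = 5) {
  G <- if (is.list(gm)) gm$G else gm
  N <- nrow(G); M <- ncol(G)
  if (K < 1) stop("K must be at least 1")
  if (K > N) stop("K cannot exceed the number of samples")
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0
  m_i <- rowSums(obs)  # non-missing variant count per sample
  p_hat <- colSums(G0) / (2 * pmax(colSums(obs), 1))

  if (K == 1) {
    f <- clamp01(p_hat)
    ll <- loglik_admix(G, obs, matrix(1, N, 1), matrix(f, 1, M))
    return(structure(list(Q = matrix(1, N, 1), F = matrix(f, 1, M),
                          loglik = ll, restarts = 1),
                     class = "StructureResult"))
  }

  set.seed(substream_seed(seed, "admixture"))
  best <- NULL
  for (r in seq_len(restarts)) {
    Q <- matrix(stats::rgamma(N * K, 1), N, K)
    Q <- Q / rowSums(Q)
    F_ <- t(vapply(seq_len(K), function(k) {
      clamp01(p_hat + stats::runif(M, -0.1, 0.1))
    }, numeric(M)))
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      # responsibilities: alt copies ~ q_ik f_kj, ref copies ~ q_ik (1-f_kj)
      PA <- Q %*% F_        # N x M: P(alt copy)
      PR <- Q %*% (1 - F_)  # = 1 - PA
      num_q <- matrix(0, N, K)
      num_f <- matrix(0, K, M)
      den_f <- matrix(0, K, M)
      for (k in seq_len(K)) {
        wa <- (Q[, k] %o% F_[k, ]) / PA        # a_ijk
        wr <- (Q[, k] %o% (1 - F_[k, ])) / PR  # b_ijk
        ta <- G0 * wa; tr <- (2 - G0) * wr
        ta[!obs] <- 0; tr[!obs] <- 0
        num_q[, k] <- rowSums(ta + tr)
        num_f[k, ] <- colSums(ta)
        den_f[k, ] <- colSums(ta + tr)
      }
      Q <- num_q / (2 * m_i)
      Q <- Q / rowSums(Q)  # guard rounding
      F_ <- clamp01(num_f / pmax(den_f, 1e-300))
      ll <- loglik_admix(G, obs, Q, F_)
      if (!is.finite(ll)) stop("non-finite admixture likelihood at iteration ", it)
      ll_trace <- c(ll_trace, ll)
      if (ll - ll_prev < tol && it > 1) break
      ll_prev <- ll
    }
    if (is.null(best) || ll_trace[length(ll_trace)] > best$loglik[length(best$loglik)]) {
      best <- list(Q = Q, F = F_, loglik = ll_trace, restarts = restarts)
    }
  }
  rownames(best$Q) <- rownames(G)
  structure(best, class = "StructureResult")
}

clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

loglik_admix <- function(G, obs, Q, F_) {
  PA <- Q %*% F_
  ll <- G * log(PA) + (2 - G) * log1p(-PA)
  sum(ll[obs])
}

#' Align admixture components to breed labels
#'
#' Resolves the label-switching ambiguity: component 1 is the one
#' maximizing mean ancestry among the reference breed's samples.
#'
#' @param Q samples x K ancestry matrix with rownames.
#' @param popmap named population vector.
#' @param ref_pop breed label anchoring component 1.
#' @return `Q` with columns permuted.
#' @export
align_components <- function(Q, popmap, ref_pop) {
  idx <- which(popmap[rownames(Q)] == ref_pop)
  lead <- which.max(colMeans(Q[idx, , drop = FALSE]))
  Q[, c(lead, setdiff(seq_len(ncol(Q)), lead)), drop = FALSE]
}
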