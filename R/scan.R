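#' Sliding windows over chromosomes
#'
#' Windows start at 0 and advance by `step`; a final partial window is
#' emitted when the chromosome end is not otherwise covered. Coordinates
#' are 0-based half-open.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param size window size (default 50 kb).
#' @param step step size (default 25 kb); must satisfy `size >= step > 0`.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, size = 50000, step = 25000) {
  if (step <= 0 || size < step) stop("need size >= step > 0")
  if (any(chrom_lengths <= 0)) stop("non-positive chromosome length")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len, by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + size, len)
    # a trailing partial window adds nothing when a full-size window
    # already covers it; partial windows extending past every full one stay
    keep <- logical(length(starts))
    max_full_end <- -Inf
    for (i in seq_along(starts)) {
      keep[i] <- ends[i] > max_full_end
      if (ends[i] - starts[i] == size) max_full_end <- max(max_full_end, ends[i])
    }
    data.frame(chrom = ch, start = starts[keep], end = ends[keep])
  })
  do.call(rbind, out)
}

#' Weir-Cockerham per-site variance components (two populations)
#'
#' Returns the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components of the WC84 estimator for
#' one biallelic site, computed from per-population genotype counts. The
#' per-site estimate is `a / (a + b + c)` when the denominator is positive.
#'
#' @param counts1,counts2 integer vectors `c(n_hom_ref, n_het, n_hom_alt)`
#'   of non-missing genotype counts in each population.
#' @return named numeric vector `c(a, b, c, theta)`; `theta` is `NA` when
#'   the denominator is zero.
#' @export
fst_components <- function(counts1, counts2) {
  n1 <- sum(counts1); n2 <- sum(counts2)
  if (n1 < 1 || n2 < 1) stop("each population needs at least one non-missing genotype")
  r <- 2
  n_i <- c(n1, n2)
  p_i <- c((2 * counts1[3] + counts1[2]) / (2 * n1),
           (2 * counts2[3] + counts2[2]) / (2 * n2))
  h_i <- c(counts1[2] / n1, counts2[2] / n2)
  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  if (n_bar <= 1 || n_c <= 0) {
    return(c(a = NA_real_, b = NA_real_, c = h_bar / 2, theta = NA_real_))
  }
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  c(a = a, b = b, c = cc, theta = if (denom > 0) a / denom else NA_real_)
}

# Per-site components for every record of a VariantSet between two
# populations. Sites where either population has zero non-missing calls are
# skipped (NA row).
site_fst_table <- function(vs, popmap, pop1, pop2) {
  g <- vs$geno
  s1 <- which(popmap[vs$samples] == pop1)
  s2 <- which(popmap[vs$samples] == pop2)
  if (!length(s1) || !length(s2)) stop("population label absent from cohort")
  comp <- t(vapply(seq_len(nrow(g)), function(i) {
    g1 <- g[i, s1]; g2 <- g[i, s2]
    c1 <- c(sum(g1 == 0, na.rm = TRUE), sum(g1 == 1, na.rm = TRUE),
            sum(g1 == 2, na.rm = TRUE))
    c2 <- c(sum(g2 == 0, na.rm = TRUE), sum(g2 == 1, na.rm = TRUE),
            sum(g2 == 2, na.rm = TRUE))
    if (sum(c1) == 0 || sum(c2) == 0) {
      return(c(a = NA_real_, b = NA_real_, c = NA_real_, theta = NA_real_))
    }
    fst_components(c1, c2)
  }, numeric(4)))
  cbind(vs$sites[, c("chrom", "start", "vtype")], as.data.frame(comp))
}

#' Windowed Weir-Cockerham Fst scan
#'
#' Per-site WC84 components are aggregated per window as a ratio of sums:
#' `sum(a) / sum(a + b + c)` ("weighted Fst"). Windows with no usable site
#' or a non-positive denominator are unscored (dropped). A per-site mean of
#' site-level estimates is available with `weighting = "mean"`.
#'
#' @param vs a `VariantSet`.
#' @param popmap named population vector.
#' @param pop1,pop2 population labels to contrast.
#' @param windows data.frame from [make_windows()]; built from
#'   `chrom_lengths` when omitted.
#' @param chrom_lengths named lengths (needed when `windows` is missing).
#' @param size,step window geometry for the default tiling.
#' @param weighting `"ratio"` (ratio of sums) or `"mean"`.
#' @return data.frame of scored windows: `chrom`, `start`, `end`,
#'   `n_sites`, `score`, `sum_a`, `sum_abc`.
#' @export
windowed_fst <- function(vs, popmap, pop1, pop2, windows = NULL,
                         chrom_lengths = NULL, size = 50000, step = 25000,
                         weighting = c("ratio", "mean")) {
  weighting <- match.arg(weighting)
  if (is.null(windows)) {
    if (is.null(chrom_lengths)) stop("supply windows or chrom_lengths")
    windows <- make_windows(chrom_lengths, size, step)
  }
  sites <- site_fst_table(vs, popmap, pop1, pop2)
  score_windows(sites, windows, weighting)
}

score_windows <- function(sites, windows, weighting = "ratio") {
  usable <- stats::complete.cases(sites[, c("a", "b", "c")])
  sites <- sites[usable, , drop = FALSE]
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sel <- sites$chrom == w$chrom & sites$start >= w$start & sites$start < w$end
    if (!any(sel)) return(NULL)
    a <- sites$a[sel]; abc <- sites$a[sel] + sites$b[sel] + sites$c[sel]
    if (weighting == "ratio") {
      if (sum(abc) <= 0) return(NULL)
      score <- sum(a) / sum(abc)
    } else {
      th <- sites$theta[sel]
      if (!any(!is.na(th))) return(NULL)
      score <- mean(th, na.rm = TRUE)
    }
    data.frame(chrom = w$chrom, start = w$start, end = w$end,
               n_sites = sum(sel), score = score,
               sum_a = sum(a), sum_abc = sum(abc))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_sites = integer(), score = numeric(),
                      sum_a = numeric(), sum_abc = numeric())
  }
  out
}

#' Top-quantile outlier windows
#'
#' The threshold is the empirical quantile of the scores (linear
#' interpolation, the default `quantile` type); windows scoring at or above
#' the threshold are returned, so ties at the threshold are all included.
#'
#' @param scores data.frame of scored windows with a `score` column.
#' @param quantile score quantile defining outliers (default 0.95: the top
#'   5% of windows).
#' @return the outlier rows, with the threshold attached as attribute
#'   `threshold`.
#' @export
outlier_windows <- function(scores, quantile = 0.95) {
  if (!nrow(scores)) stop("no scored windows")
  thr <- stats::quantile(scores$score, quantile, names = FALSE)
  if (min(scores$score) == max(scores$score)) {
    warning("all window scores are equal; every window is at the threshold")
  }
  out <- scores[scores$score >= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Annotate windows with overlapping features
#'
#' A feature (gene model or BED interval) annotates a window when their
#' intervals overlap by at least 1 bp (half-open arithmetic: a feature
#' starting exactly at the window end does not overlap).
#'
#' @param windows data.frame with `chrom`, `start`, `end`.
#' @param features list of `GeneModel`s, or a data.frame with `chrom`,
#'   `start`, `end` and a `name` (or `trait`) column.
#' @return list with `per_window` (feature names per window), `features`
#'   (deduplicated annotated feature names) and `tally` (per-name counts of
#'   hit windows).
#' @export
annotate_windows <- function(windows, features) {
  if (is.list(features) && !is.data.frame(features) &&
      length(features) && inherits(features[[1]], "GeneModel")) {
    features <- data.frame(
      chrom = vapply(features, `[[`, "", "chrom"),
      start = vapply(features, `[[`, 0, "start"),
      end = vapply(features, `[[`, 0, "end"),
      name = vapply(features, `[[`, "", "gene_id"),
      stringsAsFactors = FALSE)
  }
  if (is.null(features$name)) features$name <- features$trait
  miss_chr <- setdiff(unique(features$chrom), unique(windows$chrom))
  if (length(miss_chr)) {
    warning("feature chromosomes absent from windows: ",
            paste(miss_chr, collapse = ", "))
  }
  per_window <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    hit <- features$chrom == w$chrom & features$start < w$end & features$end > w$start
    unique(features$name[hit])
  })
  all_feats <- unique(unlist(per_window))
  tally <- sort(table(unlist(per_window)), decreasing = TRUE)
  list(per_window = per_window, features = all_feats, tally = tally)
}

#' Percentage overlap between two gene sets
#'
#' The overlap denominator is ambiguous in common usage, so all three
#' conventions are reported: relative to set A, relative to set B, and the
#' Jaccard index, each as a percentage.
#'
#' @param set_a,set_b character vectors of gene identifiers.
#' @return named numeric vector `c(pct_of_a, pct_of_b, jaccard)`, all `NA`
#'   when both sets are empty.
#' @export
gene_overlap_percent <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) && !length(set_b)) {
    return(c(pct_of_a = NA_real_, pct_of_b = NA_real_, jaccard = NA_real_))
  }
  inter <- length(intersect(set_a, set_b))
  uni <- length(union(set_a, set_b))
  c(pct_of_a = if (length(set_a)) 100 * inter / length(set_a) else NA_real_,
    pct_of_b = if (length(set_b)) 100 * inter / length(set_b) else NA_real_,
    jaccard = 100 * inter / uni)
}
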