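#' Classify a biallelic variant by allele length
#'
#' Single-base substitution -> `SNP`; length difference 1-49 bp -> `INDEL`;
#' length difference of 50 bp or more -> `SV`. The 50 bp boundary is assigned
#' to the SV class, the conventional structural-variant cutoff.
#'
#' @param ref,alt allele strings (A/C/G/T only). Vectorized.
#' @return character vector in `{"SNP", "INDEL", "SV"}`.
#' @export
classify_variant <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt))) {
    stop("alleles must be non-empty A/C/G/T strings")
  }
  size <- abs(nchar(alt) - nchar(ref))
  ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
         ifelse(size >= 50, "SV", "INDEL"))
}

#' Fraction of missing genotype calls at a site
#' @param genotypes dosage vector (0/1/2/NA).
#' @return fraction in \[0, 1\].
#' @export
site_missingness <- function(genotypes) {
  if (!length(genotypes)) stop("empty genotype vector")
  mean(is.na(genotypes))
}

#' Minor allele frequency over non-missing calls
#' @param genotypes dosage vector (0/1/2/NA).
#' @return `min(p, 1 - p)` where `p` is the alt-allele frequency among
#'   non-missing calls.
#' @export
minor_allele_freq <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (!length(g)) stop("all genotypes missing: MAF undefined")
  p <- sum(g) / (2 * length(g))
  min(p, 1 - p)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact conditional test: given the sample size and minor-allele
#' count, the p-value is the sum of the conditional probabilities of every
#' heterozygote count whose probability does not exceed that of the observed
#' count. Monomorphic sites return p = 1. Probabilities are computed by the
#' standard recurrence from the modal heterozygote count, which is stable for
#' the cohort sizes this pipeline sees.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact two-sided p-value in (0, 1\].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("negative genotype counts")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  n_alt <- 2 * n_hom_alt + n_het
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1.0)

  # possible het counts share the parity of the minor-allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- numeric(length(hets))
  # start at the modal het count and fill outward by the ratio recurrence:
  # P(h+2)/P(h) = 4 * n_aa(h) * n_bb(h) / ((h+2) * (h+1))
  # where n_aa, n_bb are the homozygote counts implied by h.
  mode_h <- hets[which.min(abs(hets - n_minor * (2 * n - n_minor) / (2 * n)))]
  mi <- match(mode_h, hets)
  probs[mi] <- 1
  h <- mode_h
  if (mi < length(hets)) {
    for (i in (mi + 1):length(hets)) {
      h <- hets[i - 1]
      haa <- (n_minor - h) / 2; hbb <- n - haa - h
      probs[i] <- probs[i - 1] * 4 * haa * hbb / ((h + 2) * (h + 1))
    }
  }
  if (mi > 1) {
    for (i in (mi - 1):1) {
      h <- hets[i + 1]
      haa <- (n_minor - h) / 2; hbb <- n - haa - h
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (haa + 1) * (hbb + 1))
    }
  }
  probs <- probs / sum(probs)
  n_het_minor <- n_het  # het count is the same whichever allele is minor
  obs <- probs[match(n_het_minor, hets)]
  if (is.na(obs)) stop("observed het count incompatible with allele counts")
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

#' QC thresholds
#'
#' Defaults follow the pipeline's site-level filters: remove sites with a
#' missing-genotype proportion strictly greater than 10%, minor allele
#' frequency strictly lower than 5%, or an exact HWE p-value strictly below
#' 1e-6 (SNPs and INDELs only; SVs are exempt from the HWE filter).
#'
#' @param max_missing maximum tolerated missingness (strictly greater is
#'   removed).
#' @param min_maf minimum tolerated MAF (strictly lower is removed).
#' @param hwe_alpha HWE significance threshold (strictly below is removed).
#' @param sv_min_len minimum length difference for the SV class (bp).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_missing = 0.10, min_maf = 0.05,
                          hwe_alpha = 1e-6, sv_min_len = 50) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5,
            hwe_alpha > 0, hwe_alpha < 1, sv_min_len >= 1)
  structure(list(max_missing = max_missing, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, sv_min_len = sv_min_len),
            class = "qc_thresholds")
}

#' Apply site-level QC filters
#'
#' Filters are applied with a fixed order of attribution: missingness, then
#' MAF, then HWE. A site failing an earlier filter is counted only under that
#' filter. The HWE filter applies to the variant types in `hwe_types` only
#' (default SNPs and INDELs; SVs are retained regardless of their genotype
#' pattern). Monomorphic sites fall under the MAF filter (MAF 0 < min_maf).
#'
#' @param vs a `VariantSet`.
#' @param th a [qc_thresholds()] object.
#' @param hwe_types variant types subject to the HWE filter.
#' @return list with `vs` (filtered `VariantSet`) and `report` (a
#'   `QCReport`: per-filter removal counts and per-type before/after counts).
#' @export
apply_qc_filters <- function(vs, th = qc_thresholds(),
                             hwe_types = c("SNP", "INDEL")) {
  g <- vs$geno
  n <- ncol(g)
  miss <- rowMeans(is.na(g))
  nonmiss <- n - rowSums(is.na(g))
  fail_miss <- miss > th$max_missing
  p <- rowSums(g, na.rm = TRUE) / (2 * pmax(nonmiss, 1L))
  maf <- pmin(p, 1 - p)
  maf[nonmiss == 0] <- 0
  fail_maf <- !fail_miss & (maf < th$min_maf)

  fail_hwe <- rep(FALSE, nrow(g))
  candidates <- which(!fail_miss & !fail_maf & vs$sites$vtype %in% hwe_types)
  if (length(candidates)) {
    pvals <- vapply(candidates, function(i) {
      gi <- g[i, ]
      hwe_exact_p(sum(gi == 0, na.rm = TRUE), sum(gi == 1, na.rm = TRUE),
                  sum(gi == 2, na.rm = TRUE))
    }, numeric(1))
    fail_hwe[candidates] <- pvals < th$hwe_alpha
  }

  keep <- !(fail_miss | fail_maf | fail_hwe)
  before <- table(factor(vs$sites$vtype, levels = c("SNP", "INDEL", "SV")))
  after <- table(factor(vs$sites$vtype[keep], levels = c("SNP", "INDEL", "SV")))
  report <- structure(list(
    n_input = nrow(g), n_output = sum(keep),
    removed = c(missingness = sum(fail_miss), maf = sum(fail_maf),
                hwe = sum(fail_hwe)),
    by_type_before = as.integer(before), by_type_after = as.integer(after),
    types = c("SNP", "INDEL", "SV"),
    thresholds = th), class = "QCReport")
  stopifnot(report$n_output + sum(report$removed) == report$n_input)
  list(vs = vs_subset(vs, which(keep)), report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QC: %d sites in, %d retained (removed: missingness=%d, MAF=%d, HWE=%d)\n",
              x$n_input, x$n_output, x$removed["missingness"],
              x$removed["maf"], x$removed["hwe"]))
  tab <- rbind(before = x$by_type_before, after = x$by_type_after)
  colnames(tab) <- x$types
  print(tab)
  invisible(x)
}
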