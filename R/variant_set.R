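#' Construct a VariantSet
#'
#' A `VariantSet` is the common currency of the pipeline: an ordered table of
#' biallelic variant records with a per-sample genotype matrix. Coordinates
#' are stored 0-based half-open internally (`start` is the 0-based position of
#' the first reference base; the record spans `[start, start + nchar(ref))`);
#' VCF I/O converts to/from the 1-based VCF convention at the boundary.
#'
#' Genotypes are integer dosages of the alternate allele: 0 (hom-ref),
#' 1 (het), 2 (hom-alt), `NA` (missing).
#'
#' @param samples character vector of cohort sample names, in genotype-column
#'   order.
#' @param sites data.frame with columns `chrom`, `start` (0-based), `ref`,
#'   `alt`, and optionally `vtype` (recomputed when absent) and `id`.
#' @param geno integer matrix, `nrow(sites)` x `length(samples)`, entries in
#'   `{0, 1, 2, NA}`.
#' @param source provenance label, one of `"SR"`, `"Pan"`, `"Merged"`,
#'   `"Truth"`.
#' @param sort sort records by (chrom, start, ref, alt)? Records must be
#'   sorted for merging; constructors from simulation already emit sorted
#'   sets.
#' @return an object of class `VariantSet`.
#' @export
variant_set <- function(samples, sites, geno, source = "Truth", sort = TRUE) {
  stopifnot(is.character(samples), is.data.frame(sites))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(sites) != nrow(geno)) {
    stop("sites and genotype matrix have different numbers of records")
  }
  if (ncol(geno) != length(samples)) {
    stop("genotype matrix has ", ncol(geno), " columns but ", length(samples),
         " samples were given")
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  sites$chrom <- as.character(sites$chrom)
  sites$ref <- toupper(as.character(sites$ref))
  sites$alt <- toupper(as.character(sites$alt))
  if (any(sites$start < 0)) stop("negative start coordinate")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  if (is.null(sites$vtype)) {
    sites$vtype <- classify_variant(sites$ref, sites$alt)
  }
  if (sort && nrow(sites)) {
    ord <- order(sites$chrom, sites$start, sites$ref, sites$alt)
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
  }
  rownames(sites) <- NULL
  dimnames(geno) <- list(NULL, samples)
  key <- variant_keys(sites)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, start, ref, alt) keys in VariantSet")
  }
  structure(list(samples = samples, sites = sites, geno = geno,
                 source = source),
            class = "VariantSet")
}

variant_keys <- function(sites) {
  paste(sites$chrom, sites$start, sites$ref, sites$alt, sep = ":")
}

#' Number of variant records in a VariantSet
#' @param vs a `VariantSet`.
#' @return integer count of records.
#' @export
n_sites <- function(vs) nrow(vs$sites)

#' @export
print.VariantSet <- function(x, ...) {
  tab <- table(factor(x$sites$vtype, levels = c("SNP", "INDEL", "SV")))
  cat(sprintf("VariantSet [%s]: %d records x %d samples (%s)\n",
              x$source, n_sites(x), length(x$samples),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
summary.VariantSet <- function(object, ...) {
  g <- object$geno
  cat(sprintf("VariantSet source=%s, %d records, %d samples\n",
              object$source, n_sites(object), length(object$samples)))
  cat(sprintf("  missing call rate: %.4f\n", mean(is.na(g))))
  print(genotype_class_frequencies(object, by_type = TRUE))
  invisible(object)
}

# Subset a VariantSet by record index (internal helper).
vs_subset <- function(vs, idx, source = vs$source) {
  variant_set(vs$samples, vs$sites[idx, , drop = FALSE],
              vs$geno[idx, , drop = FALSE], source = source, sort = FALSE)
}

check_sorted <- function(vs) {
  s <- vs$sites
  if (nrow(s) < 2) return(invisible(TRUE))
  ord <- order(s$chrom, s$start, s$ref, s$alt)
  if (!identical(ord, seq_len(nrow(s)))) stop("VariantSet is not sorted")
  invisible(TRUE)
}
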