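#' Normalize variant representations
#'
#' Trims the shared suffix, then the shared prefix (advancing `start`), of
#' each record's REF/ALT pair, always keeping at least one base of each.
#' When a reference sequence is supplied, records are additionally
#' left-aligned: while REF and ALT end in the same base and can be extended
#' one base leftward from the reference, the record is shifted left. Records
#' that normalize to the same key are collapsed when their genotypes agree
#' and raise an error otherwise.
#'
#' @param vs a `VariantSet`.
#' @param ref_seq optional named character vector of chromosome sequences;
#'   REF alleles are checked against it.
#' @return a normalized, sorted `VariantSet`.
#' @export
normalize_variants <- function(vs, ref_seq = NULL) {
  s <- vs$sites
  for (i in seq_len(nrow(s))) {
    nv <- normalize_one(s$chrom[i], s$start[i], s$ref[i], s$alt[i], ref_seq)
    s$start[i] <- nv$start; s$ref[i] <- nv$ref; s$alt[i] <- nv$alt
  }
  s$vtype <- classify_variant(s$ref, s$alt)
  key <- variant_keys(s)
  if (anyDuplicated(key)) {
    geno <- vs$geno
    keep <- !duplicated(key)
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      base <- geno[rows[1], ]
      for (r in rows[-1]) {
        conflict <- !is.na(base) & !is.na(geno[r, ]) & base != geno[r, ]
        if (any(conflict)) {
          stop("records normalize to the same key ", k,
               " with conflicting genotypes")
        }
        base <- ifelse(is.na(base), geno[r, ], base)
      }
      geno[rows[1], ] <- base
    }
    return(variant_set(vs$samples, s[keep, , drop = FALSE],
                       geno[keep, , drop = FALSE], source = vs$source))
  }
  variant_set(vs$samples, s, vs$geno, source = vs$source)
}

normalize_one <- function(chrom, start, ref, alt, ref_seq = NULL) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  if (!is.null(ref_seq)) {
    chromseq <- ref_seq[[chrom]]
    obs <- substr(chromseq, start + 1, start + length(r))
    if (!identical(obs, paste(r, collapse = ""))) {
      stop(sprintf("REF allele mismatch at %s:%d (VCF pos %d): have %s, reference shows %s",
                   chrom, start, start + 1, paste(r, collapse = ""), obs))
    }
  }
  repeat {
    # trim shared suffix
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    # left-align: extend from the reference when still right-anchored
    if (!is.null(ref_seq) && r[length(r)] == a[length(a)] && start > 0) {
      prev <- substr(ref_seq[[chrom]], start, start)
      r <- c(prev, r[-length(r)]); a <- c(prev, a[-length(a)])
      start <- start - 1
      next
    }
    break
  }
  # trim shared prefix
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; start <- start + 1
  }
  list(start = start, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Genotype concordance between two call vectors
#'
#' Agreements divided by comparisons, where a comparison is counted only
#' when both calls are non-missing. With zero comparable pairs the
#' concordance is undefined and `NA` is returned.
#'
#' @param g_a,g_b dosage vectors of equal length, same sample order.
#' @return fraction in \[0, 1\], or `NA` when no pair is comparable.
#' @export
genotype_concordance <- function(g_a, g_b) {
  if (length(g_a) != length(g_b)) stop("genotype vectors differ in length")
  ok <- !is.na(g_a) & !is.na(g_b)
  if (!any(ok)) return(NA_real_)
  mean(g_a[ok] == g_b[ok])
}

#' Merge parameters
#' @param min_concordance retention bar for overlapping sites; sites are
#'   retained only when concordance is strictly greater.
#' @param genotype_priority which source's genotypes survive at retained
#'   overlapping sites, `"SR"` or `"Pan"`.
#' @return a `merge_params` list.
#' @export
merge_params <- function(min_concordance = 0.90, genotype_priority = c("SR", "Pan")) {
  stopifnot(min_concordance >= 0, min_concordance <= 1)
  genotype_priority <- match.arg(genotype_priority)
  structure(list(min_concordance = min_concordance,
                 genotype_priority = genotype_priority),
            class = "merge_params")
}

#' Integrate the single-reference and panel call sets
#'
#' Sites present in only one source pass through with their genotypes.
#' Overlapping sites (same chrom, position, REF, ALT) are retained once when
#' their genotype concordance strictly exceeds `min_concordance`, keeping
#' the priority source's genotypes; discordant overlaps are discarded.
#' Overlapping sites with no comparable genotype pair are discarded and
#' counted separately.
#'
#' @param sr,pan `VariantSet`s over the same cohort (same samples, same
#'   order), each sorted.
#' @param params a [merge_params()].
#' @return list with `vs` (merged `VariantSet`) and `report` (a
#'   `MergeReport`).
#' @export
merge_callsets <- function(sr, pan, params = merge_params()) {
  if (!identical(sr$samples, pan$samples)) {
    stop("the two call sets cover different sample lists")
  }
  check_sorted(sr); check_sorted(pan)
  key_sr <- variant_keys(sr$sites)
  key_pan <- variant_keys(pan$sites)
  in_both <- intersect(key_sr, key_pan)
  sr_only <- which(!key_sr %in% in_both)
  pan_only <- which(!key_pan %in% in_both)

  i_sr <- match(in_both, key_sr)
  i_pan <- match(in_both, key_pan)
  conc <- vapply(seq_along(in_both), function(j) {
    genotype_concordance(sr$geno[i_sr[j], ], pan$geno[i_pan[j], ])
  }, numeric(1))
  no_pair <- is.na(conc)
  retained <- !no_pair & conc > params$min_concordance

  keep_sr <- sort(c(sr_only, if (params$genotype_priority == "SR") i_sr[retained]))
  keep_pan <- sort(c(pan_only, if (params$genotype_priority == "Pan") i_pan[retained]))
  sites <- rbind(sr$sites[keep_sr, , drop = FALSE],
                 pan$sites[keep_pan, , drop = FALSE])
  geno <- rbind(sr$geno[keep_sr, , drop = FALSE],
                pan$geno[keep_pan, , drop = FALSE])
  merged <- variant_set(sr$samples, sites, geno, source = "Merged", sort = TRUE)

  types <- c("SNP", "INDEL", "SV")
  count_by_type <- function(vt) as.integer(table(factor(vt, levels = types)))
  n_sr_t <- count_by_type(sr$sites$vtype)
  n_merged_t <- count_by_type(merged$sites$vtype)
  gains <- ifelse(n_sr_t > 0, 100 * (n_merged_t - n_sr_t) / n_sr_t, NA_real_)
  report <- structure(list(
    n_sr = n_sites(sr), n_pan = n_sites(pan),
    n_sr_only = length(sr_only), n_pan_only = length(pan_only),
    n_overlap_retained = sum(retained),
    n_overlap_discarded = sum(!retained & !no_pair),
    n_overlap_no_comparison = sum(no_pair),
    n_merged = n_sites(merged),
    types = types, n_sr_by_type = n_sr_t, n_merged_by_type = n_merged_t,
    gain_pct_by_type = gains,
    params = params), class = "MergeReport")
  stopifnot(report$n_merged ==
              report$n_sr_only + report$n_pan_only + report$n_overlap_retained)
  list(vs = merged, report = report)
}

#' @export
print.MergeReport <- function(x, ...) {
  cat(sprintf("Merge: SR=%d, Pan=%d -> merged=%d (SR-only=%d, Pan-only=%d, overlap retained=%d, discarded=%d, incomparable=%d)\n",
              x$n_sr, x$n_pan, x$n_merged, x$n_sr_only, x$n_pan_only,
              x$n_overlap_retained, x$n_overlap_discarded,
              x$n_overlap_no_comparison))
  tab <- rbind(SR = x$n_sr_by_type, merged = x$n_merged_by_type,
               gain_pct = round(x$gain_pct_by_type, 2))
  colnames(tab) <- x$types
  print(tab)
  invisible(x)
}

#' Genotype-class frequency table
#'
#' Proportions of hom-ref / het / hom-alt / missing calls over all
#' sample-by-site cells, optionally per variant type. Rows sum to 1.
#'
#' @param vs a non-empty `VariantSet`.
#' @param by_type split by variant type?
#' @return matrix of proportions with columns `hom_ref`, `het`, `hom_alt`,
#'   `missing`.
#' @export
genotype_class_frequencies <- function(vs, by_type = TRUE) {
  if (!n_sites(vs)) stop("empty VariantSet")
  one <- function(g) {
    n <- length(g)
    c(hom_ref = sum(g == 0L, na.rm = TRUE), het = sum(g == 1L, na.rm = TRUE),
      hom_alt = sum(g == 2L, na.rm = TRUE), missing = sum(is.na(g))) / n
  }
  if (!by_type) return(t(as.matrix(one(vs$geno))))
  types <- intersect(c("SNP", "INDEL", "SV"), unique(vs$sites$vtype))
  out <- t(vapply(types, function(tt) one(vs$geno[vs$sites$vtype == tt, , drop = FALSE]),
                  numeric(4)))
  rownames(out) <- types
  out
}

#' Per-window variant counts on a fixed tiling
#'
#' Non-overlapping windows of `window_size` bp tile each chromosome; the
#' final partial window is kept. Counts include every record whose start
#' falls in the window.
#'
#' @param vs a `VariantSet`.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window_size tile width in bp (default 500 kb).
#' @param vtype optional variant type to count (default: all).
#' @return data.frame with `chrom`, `start`, `end`, `count`.
#' @export
window_density <- function(vs, chrom_lengths, window_size = 5e5, vtype = NULL) {
  if (window_size <= 0) stop("window_size must be positive")
  s <- vs$sites
  if (!is.null(vtype)) s <- s[s$vtype %in% vtype, , drop = FALSE]
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    pos <- s$start[s$chrom == ch]
    count <- vapply(seq_along(starts), function(i) {
      sum(pos >= starts[i] & pos < ends[i])
    }, numeric(1))
    data.frame(chrom = ch, start = starts, end = ends, count = count)
  })
  do.call(rbind, out)
}

#' Coefficient of variation of window counts
#'
#' Population standard deviation divided by the mean; `NA` when the mean is
#' zero (undefined).
#'
#' @param counts numeric vector of per-window counts.
#' @return CV as a single number.
#' @export
uniformity_cv <- function(counts) {
  m <- mean(counts)
  if (m == 0) return(NA_real_)
  sqrt(mean((counts - m)^2)) / m
}
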