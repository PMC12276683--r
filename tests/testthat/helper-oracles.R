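# Independent oracles used across test files. Each is deliberately written
# against the formulas from first principles, not by calling package code.

# Exact HWE test by direct enumeration with log-factorial probabilities:
# P(n_het | n, n_minor) = 2^h * n! / (n_aa! h! n_bb!) * n_minor! n_major! / (2n)!
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1.0)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_minor - h) / 2
    nbb <- n - naa - h
    h * log(2) + lfactorial(n) - lfactorial(naa) - lfactorial(h) -
      lfactorial(nbb) + lfactorial(n_minor) + lfactorial(2 * n - n_minor) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  # same tie convention as the implementation: include probabilities equal
  # to the observed one up to floating-point noise
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# Weir & Cockerham (1984) variance components, written as the general
# r-population formulas evaluated at r = 2 (spreadsheet style).
wc_oracle <- function(counts1, counts2) {
  n <- c(sum(counts1), sum(counts2))
  p <- c((2 * counts1[3] + counts1[2]) / (2 * n[1]),
         (2 * counts2[3] + counts2[2]) / (2 * n[2]))
  h <- c(counts1[2] / n[1], counts2[2] / n[2])
  r <- 2
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc,
    theta = if (a + b + cc > 0) a / (a + b + cc) else NA_real_)
}

# Full-transcript translation oracle: splice the CDS out of the reference,
# translate with Biostrings, repeat with the substituted base, and compare
# the two protein sequences.
consequence_oracle <- function(chrom, start, ref, alt, gm, ref_seq) {
  chromseq <- ref_seq[[chrom]]
  splice <- function(seqstr) {
    parts <- vapply(seq_len(nrow(gm$cds)), function(i) {
      substr(seqstr, gm$cds[i, 1] + 1, gm$cds[i, 2])
    }, character(1))
    cds <- paste(parts, collapse = "")
    if (gm$strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    } else cds
  }
  mutated <- chromseq
  substr(mutated, start + 1, start + 1) <- alt
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(splice(chromseq)),
                                               no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(splice(mutated)),
                                               no.init.codon = TRUE))
  if (aa_ref == aa_alt) return("synonymous")
  d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])[1]
  a1 <- substr(aa_ref, d, d); a2 <- substr(aa_alt, d, d)
  if (a2 == "*") "stop_gained" else if (a1 == "*") "stop_lost" else "missense"
}

# Brute-force variant normalizer: apply the variant to a sequence context,
# then search every (pos, ref, alt) pair that reproduces the same mutated
# sequence and return the one with minimal allele lengths at the leftmost
# position.
normalize_oracle <- function(chrom, start, ref, alt, ref_seq) {
  chromseq <- ref_seq[[chrom]]
  n <- nchar(chromseq)
  mutated <- paste0(substr(chromseq, 1, start),
                    alt,
                    substr(chromseq, start + nchar(ref) + 1, n))
  best <- NULL
  for (pos in 0:(n - 1)) {
    for (rl in 1:min(12, n - pos)) {
      rr <- substr(chromseq, pos + 1, pos + rl)
      for (al in 1:12) {
        # candidate alt must reconstruct `mutated`
        prefix <- substr(chromseq, 1, pos)
        suffix <- substr(chromseq, pos + rl + 1, n)
        need <- nchar(mutated) - nchar(prefix) - nchar(suffix)
        if (need != al) next
        aa <- substr(mutated, pos + 1, pos + al)
        if (paste0(prefix, aa, suffix) != mutated) next
        if (rr == aa) next
        # minimality: no shared first or last base unless length-1
        r1 <- substr(rr, 1, 1); a1 <- substr(aa, 1, 1)
        re <- substr(rr, rl, rl); ae <- substr(aa, al, al)
        if (rl > 1 && al > 1 && (r1 == a1 || re == ae)) next
        if (is.null(best) || pos < best$start ||
            (pos == best$start && rl + al < nchar(best$ref) + nchar(best$alt))) {
          best <- list(start = pos, ref = rr, alt = aa)
        }
      }
    }
  }
  best
}

# mean silhouette score on a score matrix given integer labels
silhouette_mean <- function(X, labels) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
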