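# Standard genetic code, codon -> one-letter amino acid ("*" = stop).
GENETIC_CODE_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Intersect selection-evidence gene sets with a DEG list
#'
#' Exact set algebra over named evidence sets (e.g. Fst genes, sweep-scan
#' genes, EigenGWAS genes, per variant type) and a differentially-expressed
#' gene list. Joint candidates are genes in the DEG set that appear in at
#' least `min_evidence` evidence sets. Upset-style intersection counts are
#' reported for every combination of membership flags.
#'
#' @param evidence named list of character vectors of gene ids.
#' @param deg character vector of DE gene ids (or a data.frame with columns
#'   `gene_id` and `is_DE`).
#' @param min_evidence minimum number of evidence sets a joint candidate
#'   must appear in (default 1).
#' @return a `CandidateTable` list: `table` (gene x flag membership),
#'   `joint_candidates`, `upset` (counts per flag combination).
#' @export
intersect_candidates <- function(evidence, deg, min_evidence = 1) {
  if (is.data.frame(deg)) deg <- deg$gene_id[as.logical(deg$is_DE)]
  deg <- unique(deg)
  if (!length(deg)) warning("empty DEG set: no joint candidates possible")
  if (is.null(names(evidence)) || any(names(evidence) == "")) {
    names(evidence) <- paste0("evidence", seq_along(evidence))
  }
  genes <- unique(c(unlist(evidence), deg))
  flags <- vapply(evidence, function(s) genes %in% s, logical(length(genes)))
  flags <- matrix(flags, nrow = length(genes),
                  dimnames = list(genes, names(evidence)))
  de_flag <- genes %in% deg
  tab <- data.frame(gene_id = genes, flags, DE = de_flag,
                    n_evidence = rowSums(flags), row.names = NULL,
                    check.names = FALSE)
  joint <- tab$gene_id[tab$DE & tab$n_evidence >= min_evidence]
  combo <- apply(cbind(flags, DE = de_flag), 1, paste, collapse = "")
  upset <- table(combo)
  stopifnot(sum(upset) == length(genes))
  structure(list(table = tab, joint_candidates = joint, upset = upset,
                 min_evidence = min_evidence),
            class = "CandidateTable")
}

#' @export
print.CandidateTable <- function(x, ...) {
  cat(sprintf("CandidateTable: %d genes across %d evidence sets + DEG; %d joint candidate(s) (>= %d evidence sets)\n",
              nrow(x$table), ncol(x$table) - 3, length(x$joint_candidates),
              x$min_evidence))
  if (length(x$joint_candidates)) {
    cat("  joint:", paste(x$joint_candidates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coding consequence of a variant against one gene model
#'
#' Positional classes: `upstream`/`downstream` (within `flank` bp of the
#' transcript span on the strand-appropriate side), `intergenic` (farther),
#' `intronic` (inside the span, outside exons), `exonic_noncoding` (exonic,
#' outside the CDS). For SNPs inside the CDS the affected codon is rebuilt
#' from the reference sequence honoring strand and frame, the alternate
#' base substituted (reverse-complemented on the minus strand), and both
#' codons translated with the standard genetic code: `synonymous`,
#' `missense`, `stop_gained` or `stop_lost`. INDELs and SVs inside the CDS
#' are reported as `coding_indel_unclassified` (no frame analysis).
#'
#' @param chrom,start,ref,alt variant record (0-based start).
#' @param gm a `GeneModel`.
#' @param ref_seq named character vector of chromosome sequences.
#' @param flank upstream/downstream window (default 5 kb).
#' @return a `ConsequenceCall` list: `gene`, `class`, `codon_change`,
#'   `aa_change`.
#' @export
coding_consequence <- function(chrom, start, ref, alt, gm, ref_seq,
                               flank = 5000) {
  call <- function(class, codon = NA_character_, aa = NA_character_) {
    structure(list(gene = gm$gene_id, class = class,
                   codon_change = codon, aa_change = aa),
              class = "ConsequenceCall")
  }
  if (chrom != gm$chrom) return(call("intergenic"))
  if (start < gm$start || start >= gm$end) {
    before <- start < gm$start
    dist <- if (before) gm$start - start else start - gm$end + 1
    if (dist > flank) return(call("intergenic"))
    # upstream = 5' side of the transcript, which depends on strand
    side_up <- if (gm$strand == "+") before else !before
    return(call(if (side_up) "upstream" else "downstream"))
  }
  in_exon <- any(gm$exons[, 1] <= start & start < gm$exons[, 2])
  if (!in_exon) return(call("intronic"))
  if (is.null(gm$cds)) return(call("exonic_noncoding"))
  in_cds <- any(gm$cds[, 1] <= start & start < gm$cds[, 2])
  if (!in_cds) return(call("exonic_noncoding"))
  if (nchar(ref) != 1 || nchar(alt) != 1) return(call("coding_indel_unclassified"))

  chromseq <- ref_seq[[chrom]]
  obs <- substr(chromseq, start + 1, start + 1)
  if (obs != ref) {
    stop(sprintf("REF mismatch at %s:%d: record has %s, reference shows %s",
                 chrom, start + 1, ref, obs))
  }
  # genomic CDS coordinates in transcription order
  cds_pos <- unlist(lapply(seq_len(nrow(gm$cds)), function(i) {
    seq(gm$cds[i, 1], gm$cds[i, 2] - 1)
  }))
  if (gm$strand == "-") cds_pos <- rev(cds_pos)
  idx <- match(start, cds_pos)            # 1-based position within the CDS
  codon_i <- (idx - 1) %/% 3
  codon_genomic <- cds_pos[codon_i * 3 + 1:3]
  base_at <- function(p) substr(chromseq, p + 1, p + 1)
  codon_bases <- vapply(codon_genomic, base_at, "")
  if (gm$strand == "-") codon_bases <- chartr("ACGT", "TGCA", codon_bases)
  ref_codon <- paste(codon_bases, collapse = "")
  within <- (idx - 1) %% 3 + 1
  alt_base <- if (gm$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  alt_codon_bases <- codon_bases
  alt_codon_bases[within] <- alt_base
  alt_codon <- paste(alt_codon_bases, collapse = "")
  aa_ref <- GENETIC_CODE_TABLE[[ref_codon]]
  aa_alt <- GENETIC_CODE_TABLE[[alt_codon]]
  cls <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gained"
    else if (aa_ref == "*") "stop_lost"
    else "missense"
  call(cls, paste0(ref_codon, ">", alt_codon), paste0(aa_ref, ">", aa_alt))
}

#' @export
print.ConsequenceCall <- function(x, ...) {
  cat(sprintf("%s: %s%s\n", x$gene, x$class,
              if (!is.na(x$aa_change)) paste0(" (", x$codon_change, ", ",
                                              x$aa_change, ")") else ""))
  invisible(x)
}

#' Per-population genotype-class percentages at one site
#'
#' @param vs a `VariantSet`.
#' @param chrom,start,ref,alt the site key (0-based start).
#' @param popmap named population vector.
#' @return data.frame per population: raw counts and percentages of
#'   hom-ref, het, hom-alt and missing calls (percentages of that
#'   population's sample count, unrounded).
#' @export
population_genotype_report <- function(vs, chrom, start, ref, alt, popmap) {
  key <- paste(chrom, start, ref, alt, sep = ":")
  i <- match(key, variant_keys(vs$sites))
  if (is.na(i)) stop("site not present in the call set: ", key)
  g <- vs$geno[i, ]
  pops <- unique(popmap[vs$samples])
  out <- lapply(pops, function(p) {
    gp <- g[popmap[vs$samples] == p]
    n <- length(gp)
    counts <- c(hom_ref = sum(gp == 0, na.rm = TRUE),
                het = sum(gp == 1, na.rm = TRUE),
                hom_alt = sum(gp == 2, na.rm = TRUE),
                missing = sum(is.na(gp)))
    data.frame(population = p, n = n, t(counts),
               t(stats::setNames(100 * counts / n, paste0("pct_", names(counts)))))
  })
  do.call(rbind, out)
}

#' Dosage matrix for a genomic region, grouped by population
#'
#' Sites inside `[start, end)` (half-open) in positional order; rows are
#' samples grouped by population label. The dosage encoding (0/1/2, `NA`
#' missing) stands in for phased haplotypes, which this pipeline never
#' infers.
#'
#' @param vs a `VariantSet`.
#' @param chrom,start,end region (0-based half-open).
#' @param popmap named population vector.
#' @return samples-by-sites integer matrix with an attribute `positions`;
#'   zero columns (with a warning) when the region is empty.
#' @export
haplotype_matrix <- function(vs, chrom, start, end, popmap) {
  if (end <= start) stop("empty region")
  sel <- which(vs$sites$chrom == chrom & vs$sites$start >= start &
                 vs$sites$start < end)
  ord <- order(popmap[vs$samples], vs$samples)
  m <- t(vs$geno[sel, ord, drop = FALSE])
  rownames(m) <- vs$samples[ord]
  colnames(m) <- vs$sites$start[sel]
  if (!length(sel)) warning("no sites in region ", chrom, ":", start, "-", end)
  attr(m, "positions") <- vs$sites$start[sel]
  attr(m, "population") <- popmap[vs$samples][ord]
  m
}
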