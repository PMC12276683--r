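#' Read a VCF file into a VariantSet
#'
#' Reads a VCF (4.x, plain text or gzipped) keeping only biallelic records
#' with a concrete ALT allele. Multi-allelic records, symbolic/missing ALT
#' alleles (`<DEL>`, `.`) and spanning-deletion records (ALT `*`) are dropped
#' and counted. Phased separators (`|`) are accepted and collapsed to
#' unphased dosages; half-missing calls (`./1`) are treated as missing.
#'
#' @param path VCF file path.
#' @param expected_samples optional character vector; if given, the VCF
#'   sample header must match it exactly (same names, same order) or an
#'   error is raised.
#' @param source provenance label to attach (`"SR"`, `"Pan"`, ...). Defaults
#'   to the `##source=` header value when present, else `"SR"`.
#' @return a `VariantSet` with attribute `drop_report`, a named integer
#'   vector of dropped-record counts (`multiallelic`, `symbolic`,
#'   `spanning_deletion`).
#' @export
read_variant_table <- function(path, expected_samples = NULL, source = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  span <- !is.na(alt) & !multi &
    (alt == "*" | grepl("*", alt, fixed = TRUE))
  symb <- is.na(alt) | alt == "." | grepl("[<>\\[\\]]", alt)
  symb <- symb & !multi & !span
  keep <- !(multi | span | symb)
  drop_report <- c(multiallelic = sum(multi), symbolic = sum(symb),
                   spanning_deletion = sum(span))

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  vcf_samples <- colnames(v@gt)[-1]
  if (!is.null(expected_samples) &&
      !identical(as.character(vcf_samples), as.character(expected_samples))) {
    stop("VCF sample header does not match the expected sample list")
  }
  geno <- parse_gt_codes(gt[keep, , drop = FALSE])
  if (is.null(source)) {
    src_line <- grep("^##source=", v@meta, value = TRUE)
    source <- if (length(src_line)) sub("^##source=", "", src_line[1]) else "SR"
    source <- if (source %in% c("SR", "Pan", "Merged", "Truth")) source else "SR"
  }
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      start = as.integer(fix[keep, "POS"]) - 1L,
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  vs <- variant_set(vcf_samples, sites, geno, source = source, sort = TRUE)
  attr(vs, "drop_report") <- drop_report
  vs
}

# "0/0", "0|1", "1/1", "./.", "./1" (with or without trailing FORMAT fields)
# -> dosage codes 0/1/2/NA. Any missing allele makes the call missing.
parse_gt_codes <- function(gt) {
  dim0 <- dim(gt)
  x <- sub(":.*$", "", as.character(gt))
  a1 <- substr(x, 1, 1)
  a2 <- substr(x, 3, 3)
  single <- !is.na(x) & nchar(x) == 1
  a2[single] <- a1[single]
  miss <- is.na(x) | a1 == "." | a2 == "." | a1 == "" | a2 == ""
  d <- suppressWarnings(as.integer(a1) + as.integer(a2))
  d[miss] <- NA_integer_
  if (any(!is.na(d) & d > 2L)) stop("allele index > 1 in a biallelic VCF")
  matrix(d, nrow = dim0[1], ncol = dim0[2])
}

#' Write a VariantSet as a VCF 4.2 file
#'
#' Emits a minimal GT-only VCF. The header records the record source and the
#' package version; contig lines are written when `chrom_lengths` is given.
#'
#' @param vs a `VariantSet`.
#' @param path output path (plain text).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vs, path, chrom_lengths = NULL) {
  ver <- as.character(utils::packageVersion("panhybrid"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=", vs$source),
           paste0("##panhybridVersion=", ver),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", vs$samples),
                      collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n_sites(vs)) {
    gt_strings <- matrix(c("0/0", "0/1", "1/1")[vs$geno + 1L],
                         nrow = n_sites(vs))
    gt_strings[is.na(vs$geno)] <- "./."
    body <- paste(vs$sites$chrom, vs$sites$start + 1L, ".",
                  vs$sites$ref, vs$sites$alt, ".", "PASS", ".", "GT",
                  apply(gt_strings, 1, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a sample-to-population map
#'
#' @param path TSV with columns `sample` and `population` (header optional;
#'   a headerless two-column file is accepted).
#' @param samples optional cohort sample list; when given, every sample must
#'   be present exactly once in the map.
#' @return named character vector: population label per sample.
#' @export
read_popmap <- function(path, samples = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, col.names = c("sample", "population"))
  if (identical(tolower(df$sample[1]), "sample")) df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df$sample)) stop("duplicate sample in population map")
  pm <- stats::setNames(as.character(df$population), df$sample)
  if (!is.null(samples)) {
    missing <- setdiff(samples, names(pm))
    if (length(missing)) {
      stop("samples absent from population map: ", paste(missing, collapse = ", "))
    }
    pm <- pm[samples]
  }
  pm
}

#' Write a population map TSV
#' @param popmap named character vector (names = samples).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(data.frame(sample = names(popmap), population = popmap),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Construct a gene model
#'
#' All coordinates 0-based half-open. Exons must be disjoint; CDS intervals
#' must lie within exons; when a protein is declared (`coding = TRUE`) the
#' total CDS length must be divisible by 3.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end), 0-based half-open.
#' @param cds optional two-column matrix of coding intervals.
#' @param coding is a protein product declared?
#' @return an object of class `GeneModel`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL,
                       coding = !is.null(cds)) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.numeric(exons), ncol = 2)
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1])) stop("empty or inverted exon interval")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("overlapping exons in gene ", gene_id)
  }
  if (!is.null(cds)) {
    cds <- matrix(as.numeric(cds), ncol = 2)
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
    }, logical(1))
    if (!all(inside)) stop("CDS interval outside exons in gene ", gene_id)
    if (coding && sum(cds[, 2] - cds[, 1]) %% 3 != 0) {
      stop("CDS length of gene ", gene_id, " not divisible by 3")
    }
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = min(exons[, 1]), end = max(exons[, 2]),
                 exons = exons, cds = cds, coding = coding),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s %s:%d-%d(%s), %d exon(s)%s\n", x$gene_id,
              x$chrom, x$start, x$end, x$strand, nrow(x$exons),
              if (x$coding) sprintf(", CDS %d bp", sum(x$cds[, 2] - x$cds[, 1]))
              else ""))
  invisible(x)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention. For genes with several transcripts the transcript
#' with the longest CDS (then longest span) is kept.
#'
#' @param path GFF3 (`.gff/.gff3`) or BED12 (`.bed`) file.
#' @return list of `GeneModel` objects.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    return(read_gene_models_bed12(path))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  tx_types <- c("mRNA", "transcript")
  tx <- df[df$type %in% tx_types, , drop = FALSE]
  genes <- df[df$type == "gene", , drop = FALSE]
  first_chr <- function(x) if (length(x)) as.character(x)[1] else NA_character_
  parent_of <- vapply(tx$Parent, first_chr, character(1))
  models <- list()
  use_tx <- nrow(tx) > 0
  units <- if (use_tx) tx else genes
  unit_gene <- if (use_tx) ifelse(is.na(parent_of), tx$ID, parent_of) else genes$ID
  children_parent <- vapply(df$Parent, first_chr, character(1))
  for (i in seq_len(nrow(units))) {
    uid <- units$ID[i]
    kids <- df[!is.na(children_parent) & children_parent == uid, , drop = FALSE]
    ex <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    cd <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(ex) == 0) ex <- units[i, c("start", "end"), drop = FALSE]
    exons <- cbind(ex$start - 1, ex$end)       # GFF3 1-based incl -> 0-based half-open
    cds <- if (nrow(cd)) cbind(cd$start - 1, cd$end) else NULL
    gid <- unit_gene[i]
    if (is.na(gid) || !length(gid)) gid <- uid
    gm <- gene_model(gid, as.character(units$seqnames[i]),
                     as.character(units$strand[i]), exons, cds)
    prev <- models[[gid]]
    if (is.null(prev) || cds_len(gm) > cds_len(prev) ||
        (cds_len(gm) == cds_len(prev) && (gm$end - gm$start) > (prev$end - prev$start))) {
      models[[gid]] <- gm
    }
  }
  unname(models)
}

cds_len <- function(gm) if (is.null(gm$cds)) 0 else sum(gm$cds[, 2] - gm$cds[, 1])

read_gene_models_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  lapply(seq_len(nrow(df)), function(i) {
    start0 <- df$start[i] - 1              # rtracklayer re-bases BED to 1-based
    blocks <- df$blocks[[i]]
    if (!is.null(blocks) && length(blocks)) {
      b <- as.data.frame(blocks)
      exons <- cbind(start0 + b$start - 1, start0 + b$end)
    } else {
      exons <- cbind(start0, df$end[i])
    }
    cds <- NULL
    if (!is.null(df$thick.start) && !is.na(df$thick.start[i]) &&
        df$thick.end[i] > df$thick.start[i] - 1) {
      ts <- df$thick.start[i] - 1; te <- df$thick.end[i]
      cds <- clip_to_intervals(exons, ts, te)
    }
    gene_model(as.character(df$name[i]), as.character(df$seqnames[i]),
               as.character(df$strand[i]), exons, cds,
               coding = !is.null(cds))
  })
}

clip_to_intervals <- function(iv, lo, hi) {
  s <- pmax(iv[, 1], lo); e <- pmin(iv[, 2], hi)
  keep <- e > s
  if (!any(keep)) return(NULL)
  cbind(s[keep], e[keep])
}

#' Write gene models as GFF3
#' @param models list of `GeneModel` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (gm in models) {
    g1 <- gm$start + 1; g2 <- gm$end                # back to 1-based inclusive
    gid <- gm$gene_id; tid <- paste0(gid, ".t1")
    lines <- c(lines,
      sprintf("%s\tpanhybrid\tgene\t%d\t%d\t.\t%s\t.\tID=%s", gm$chrom, g1, g2, gm$strand, gid),
      sprintf("%s\tpanhybrid\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              gm$chrom, g1, g2, gm$strand, tid, gid),
      sprintf("%s\tpanhybrid\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              gm$chrom, gm$exons[, 1] + 1, gm$exons[, 2], gm$strand, tid))
    if (!is.null(gm$cds)) {
      lines <- c(lines, sprintf("%s\tpanhybrid\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                                gm$chrom, gm$cds[, 1] + 1, gm$cds[, 2], gm$strand, tid, tid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a reference sequence as FASTA
#' @param seqs named character vector (chromosome name -> sequence).
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA reference into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[(hdr[i] + 1):ends[i]], collapse = "")
  }, character(1))
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  toupper(seqs)
}
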