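#' Simulation configuration for a two-breed hybrid cohort
#'
#' The generator models the breeding design behind the cohort this pipeline
#' targets: two diverged founder breeds, an F1 cross between them, and
#' random intra-cohort mating to F5, from which the hybrid samples are drawn.
#' Founder divergence follows the Balding-Nichols model with a single
#' parameter `divergence`. Two imperfect call sets are then emulated on the
#' sampled cohort: a single-reference set with reference-bias errors
#' (het-to-hom-ref miscalls near SVs, whole-site dropout of
#' reference-unrepresentable "private" loci, random missingness) and a
#' parental-panel set restricted to the variants carried by one sampled
#' diploid per breed, with a symmetric genotype error.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length (bp); must be at least 10 windows of
#'   the 50 kb scan window.
#' @param n_snp,n_indel,n_sv variant counts per type (genome-wide).
#' @param divergence Balding-Nichols divergence F between the founder
#'   breeds, in (0, 1).
#' @param n_founders_a,n_founders_b diploid founder population sizes.
#' @param cohort_size individuals per intercross generation.
#' @param n_generations hybrid generations (5 = F1 through F5).
#' @param n_a_out,n_b_out,n_hybrid_out samples drawn for the cohort
#'   (defaults 31, 40, 37: maternal breed, paternal breed, F5 hybrids).
#' @param pop_labels labels for (maternal breed, paternal breed, hybrids).
#' @param recomb_rate crossovers per bp per meiosis. The default 5e-7 gives
#'   each synthetic chromosome ~2.5 crossovers per meiosis, the per-
#'   chromosome crossover count of a real chromosome-scale map compressed
#'   to the desk-scale chromosome length, so ancestry blocks localize at
#'   sub-Mb scale as they do in a real intercross.
#' @param sweep_loci data.frame with columns `chrom`, `pos`, `s`: loci under
#'   selection during the intercross; parents are drawn with probability
#'   proportional to the product of `1 + s * dosage / 2`. Each sweep locus
#'   is planted at the nearest SNP as a breed-differentiated variant
#'   (alt frequency 0.95 in the maternal breed, 0.03 in the paternal
#'   breed, the pattern of a breed-private selected allele), so selection drags
#'   local maternal-breed ancestry and leaves a spatially localized
#'   signature. `NULL` for neutrality.
#' @param sweep_halo radius (bp) of the diverged haplotype block around each
#'   sweep locus.
#' @param halo_frac fraction of halo sites given strongly divergent breed
#'   frequencies (alt common in the maternal breed, rare in the paternal
#'   breed).
#' @param pi_priv fraction of loci unrepresentable on the single reference
#'   (dropped from the SR call set) outside bias regions.
#' @param pi_priv_bias the same fraction inside bias regions: mapping near
#'   SVs fails more often, so dropout is elevated there.
#' @param indel_bias_frac fraction of INDELs placed inside bias regions.
#' @param bias_halfwidth half-width (bp) of the reference-bias region around
#'   each SV.
#' @param eps_base,eps_bias probability that the SR caller turns a true het
#'   into hom-ref outside / inside bias regions.
#' @param mu_miss per-call missingness probability in the SR set.
#' @param eps_pan symmetric per-call genotype error in the panel set.
#' @param n_genes number of simulated gene models.
#' @param deg_frac fraction of background genes flagged as differentially
#'   expressed (sweep-overlapping genes are always flagged).
#' @param seed integer seed; every stochastic stage derives a named
#'   substream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chrom = 2, chrom_len = 5e6,
                       n_snp = 4000, n_indel = 800, n_sv = 60,
                       divergence = 0.2,
                       n_founders_a = 50, n_founders_b = 50,
                       cohort_size = 200, n_generations = 5,
                       n_a_out = 31, n_b_out = 40, n_hybrid_out = 37,
                       pop_labels = c("GZB", "DLW", "QCB"),
                       recomb_rate = 5e-7,
                       sweep_loci = data.frame(chrom = "chr1", pos = 2.5e6, s = 12),
                       sweep_halo = 1e5, halo_frac = 0.7,
                       pi_priv = 0.08, pi_priv_bias = 0.5,
                       indel_bias_frac = 0.7, bias_halfwidth = 10000,
                       eps_base = 0.01, eps_bias = 0.15, mu_miss = 0.03,
                       eps_pan = 0.01,
                       n_genes = 60, deg_frac = 0.1, seed = 1) {
  rates <- c(pi_priv, pi_priv_bias, indel_bias_frac, eps_base, eps_bias,
             mu_miss, eps_pan, deg_frac, halo_frac)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (divergence <= 0 || divergence >= 1) stop("divergence must lie in (0, 1)")
  if (chrom_len < 10 * 50000) stop("chrom_len must be at least 10 scan windows (500 kb)")
  if (cohort_size < 2) stop("cohort_size must be at least 2")
  if (!is.null(sweep_loci) && nrow(sweep_loci)) {
    if (any(sweep_loci$pos < 0 | sweep_loci$pos > chrom_len)) {
      stop("sweep locus outside chromosome bounds")
    }
    if (any(!sweep_loci$chrom %in% paste0("chr", seq_len(n_chrom)))) {
      stop("sweep locus on unknown chromosome")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

# Named substream: deterministic 31-bit seed derived from (seed, stage name),
# so any stage can be pinned independently of the others.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_len(nchar(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483629) + 1L
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate diverged founder breeds
#'
#' Draws loci along the genome, Balding-Nichols breed allele frequencies,
#' and founder haplotypes. Per locus, the ancestral frequency p0 is
#' Uniform(0.05, 0.95) and each breed's frequency is an independent
#' Beta(p0(1-F)/F, (1-p0)(1-F)/F) draw. SV positions define "bias regions"
#' (+/- `bias_halfwidth`); a configurable fraction of INDELs is placed inside
#' them, and loci there receive the elevated private probability
#' `pi_priv_bias`.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_founders` list: `loci` (site table, 0-based starts),
#'   breed frequencies `p_a`/`p_b`, haplotype matrices `hap_a`/`hap_b`
#'   (2N x L), `private` flags, `bias` intervals, `chrom_lengths`.
#' @export
simulate_founders <- function(cfg) {
  set.seed(substream_seed(cfg$seed, "founders"))
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  chrom_lengths <- stats::setNames(rep(cfg$chrom_len, cfg$n_chrom), chroms)
  max_pos <- cfg$chrom_len - 500  # leave room for long ref alleles

  draw_pos <- function(n) {
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = sample.int(max_pos, n, replace = TRUE) - 1L,
               stringsAsFactors = FALSE)
  }

  # SVs first: their positions define the bias regions
  sv <- draw_pos(cfg$n_sv)
  sv_len <- sample(50:300, cfg$n_sv, replace = TRUE)
  sv_ins <- stats::runif(cfg$n_sv) < 0.5
  sv$ref <- ifelse(sv_ins, vapply(seq_len(cfg$n_sv), function(i) random_bases(1), ""),
                   vapply(sv_len + 1, random_bases, ""))
  sv$alt <- ifelse(sv_ins, vapply(sv_len + 1, random_bases, ""),
                   substr(sv$ref, 1, 1))
  bias <- data.frame(chrom = sv$chrom,
                     start = pmax(0, sv$start - cfg$bias_halfwidth),
                     end = pmin(cfg$chrom_len, sv$start + cfg$bias_halfwidth))

  # INDELs: a fraction inside bias regions, the rest uniform
  n_in_bias <- round(cfg$n_indel * cfg$indel_bias_frac)
  n_in_bias <- min(n_in_bias, cfg$n_indel)
  host <- if (nrow(bias)) sample.int(nrow(bias), n_in_bias, replace = TRUE) else integer(0)
  ind_b <- data.frame(
    chrom = bias$chrom[host],
    start = as.integer(floor(stats::runif(length(host), bias$start[host],
                                          pmin(bias$end[host], max_pos)))),
    stringsAsFactors = FALSE)
  ind_u <- draw_pos(cfg$n_indel - length(host))
  ind <- rbind(ind_b, ind_u)
  ind_len <- sample(1:49, cfg$n_indel, replace = TRUE)
  ind_ins <- stats::runif(cfg$n_indel) < 0.5
  ind$ref <- ifelse(ind_ins, vapply(seq_len(cfg$n_indel), function(i) random_bases(1), ""),
                    vapply(ind_len + 1, random_bases, ""))
  ind$alt <- ifelse(ind_ins, vapply(ind_len + 1, random_bases, ""),
                    substr(ind$ref, 1, 1))

  snp <- draw_pos(cfg$n_snp)
  bases <- c("A", "C", "G", "T")
  snp$ref <- sample(bases, cfg$n_snp, replace = TRUE)
  snp$alt <- vapply(snp$ref, function(r) sample(setdiff(bases, r), 1), "")

  loci <- rbind(snp, ind, sv)
  loci$vtype <- rep(c("SNP", "INDEL", "SV"), c(cfg$n_snp, cfg$n_indel, cfg$n_sv))
  # keep (chrom, start) unique so site keys are unique
  while (any(dup <- duplicated(paste(loci$chrom, loci$start)))) {
    loci$start[dup] <- (loci$start[dup] + 1L) %% max_pos
  }
  ord <- order(loci$chrom, loci$start, loci$ref, loci$alt)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  L <- nrow(loci)

  p0 <- stats::runif(L, 0.05, 0.95)
  fdiv <- cfg$divergence
  shape <- (1 - fdiv) / fdiv
  p_a <- stats::rbeta(L, p0 * shape, (1 - p0) * shape)
  p_b <- stats::rbeta(L, p0 * shape, (1 - p0) * shape)
  # plant each sweep locus on a breed-differentiated haplotype block: the
  # selected SNP and a fraction of its neighbours get strongly divergent
  # breed frequencies, so fixing local maternal ancestry in the hybrids
  # leaves the classic near-fixation sweep signature around the locus
  si <- sweep_site_indices(loci, cfg$sweep_loci)
  for (k in seq_along(si)) {
    ds <- abs(loci$start - loci$start[si[k]])
    halo <- which(loci$chrom == loci$chrom[si[k]] & ds <= cfg$sweep_halo)
    # LD decays outward from the selected site: the core of the selected
    # haplotype is fully differentiated, the outer halo partially
    core <- ds[halo] <= cfg$sweep_halo * 0.3
    pick <- halo[stats::runif(length(halo)) < ifelse(core, 1, cfg$halo_frac)]
    p_a[pick] <- stats::runif(length(pick), 0.95, 0.995)
    p_b[pick] <- stats::runif(length(pick), 0.30, 0.50)
  }
  p_a[si] <- 0.95
  p_b[si] <- 0.03

  hap_a <- matrix(stats::rbinom(2 * cfg$n_founders_a * L, 1,
                                rep(p_a, each = 2 * cfg$n_founders_a)),
                  nrow = 2 * cfg$n_founders_a)
  hap_b <- matrix(stats::rbinom(2 * cfg$n_founders_b * L, 1,
                                rep(p_b, each = 2 * cfg$n_founders_b)),
                  nrow = 2 * cfg$n_founders_b)

  in_bias <- in_intervals(loci$chrom, loci$start, bias)
  private <- stats::runif(L) < ifelse(in_bias, cfg$pi_priv_bias, cfg$pi_priv)

  structure(list(loci = loci, p0 = p0, p_a = p_a, p_b = p_b,
                 hap_a = hap_a, hap_b = hap_b, private = private,
                 in_bias = in_bias, bias = bias,
                 chrom_lengths = chrom_lengths, cfg = cfg),
            class = "sim_founders")
}

# nearest SNP to each configured sweep position (one index per sweep row)
sweep_site_indices <- function(loci, sweep_loci) {
  if (is.null(sweep_loci) || !nrow(sweep_loci)) return(integer(0))
  vapply(seq_len(nrow(sweep_loci)), function(k) {
    d <- abs(loci$start - sweep_loci$pos[k])
    d[loci$chrom != sweep_loci$chrom[k] | loci$vtype != "SNP"] <- Inf
    which.min(d)
  }, integer(1))
}

# logical: is (chrom, pos) inside any interval of df(chrom, start, end)?
in_intervals <- function(chrom, pos, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (ch in unique(iv$chrom)) {
    sel <- chrom == ch
    if (!any(sel)) next
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(ivc))) {
      out[sel] <- out[sel] | (pos[sel] >= ivc$start[j] & pos[sel] < ivc$end[j])
    }
  }
  out
}

# One gamete: Poisson crossovers per chromosome, mosaic of the parent's two
# haplotypes. h1/h2 are 0/1 vectors over all loci; loci_chrom/loci_pos give
# positions; chrom_lengths named lengths.
make_gamete <- function(h1, h2, loci_chrom, loci_pos, chrom_lengths, rate) {
  gam <- integer(length(h1))
  for (ch in names(chrom_lengths)) {
    idx <- which(loci_chrom == ch)
    if (!length(idx)) next
    n_co <- stats::rpois(1, rate * chrom_lengths[[ch]])
    xo <- sort(stats::runif(n_co, 0, chrom_lengths[[ch]]))
    seg <- findInterval(loci_pos[idx], xo)
    use_h1 <- (seg + stats::rbinom(1, 1, 0.5)) %% 2 == 0
    gam[idx] <- ifelse(use_h1, h1[idx], h2[idx])
  }
  gam
}

#' Simulate the hybrid pedigree and assemble ground truth
#'
#' F1 individuals are dam(A) x sire(B) crosses of random founders; later
#' generations mate randomly within the previous cohort with Poisson-
#' crossover recombination. When sweep loci are configured, each parent of
#' generations F2 onward is drawn with probability proportional to the
#' product over sweep loci of `1 + s * dosage / 2`. Samples drawn from the
#' founder breeds and the final hybrid generation form the cohort; their
#' full genotypes, the panel membership flags (variants carried by one
#' sampled diploid per breed, mirroring one assembly per parent), the bias
#' intervals, gene models and a DEG table constitute the `TruthBundle`.
#'
#' @param founders output of [simulate_founders()].
#' @param cfg the same [sim_config()].
#' @return a `TruthBundle` list: `truth` (`VariantSet` with no missing
#'   calls), `popmap`, `panel`/`private` flags, `bias` intervals,
#'   `sweep_loci`, `gene_models`, `deg`, `chrom_lengths`, breed frequencies.
#' @export
simulate_pedigree <- function(founders, cfg = founders$cfg) {
  set.seed(substream_seed(cfg$seed, "pedigree"))
  loci <- founders$loci
  L <- nrow(loci)
  cl <- founders$chrom_lengths

  pair_rows <- function(hap, i) list(hap[2 * i - 1, ], hap[2 * i, ])
  sweep_idx <- sweep_site_indices(loci, cfg$sweep_loci)
  sweep_s <- if (length(sweep_idx)) cfg$sweep_loci$s else numeric(0)
  sel_weights <- function(hap1, hap2) {
    if (!length(sweep_idx)) return(rep(1, length(hap1)))
    w <- rep(1, length(hap1))
    for (k in seq_along(sweep_idx)) {
      dos <- vapply(seq_along(hap1), function(i) {
        hap1[[i]][sweep_idx[k]] + hap2[[i]][sweep_idx[k]]
      }, numeric(1))
      w <- w * (1 + sweep_s[k] * dos / 2)
    }
    w
  }

  # F1: A dams x B sires
  cohort1 <- vector("list", cfg$cohort_size)
  cohort2 <- vector("list", cfg$cohort_size)
  for (i in seq_len(cfg$cohort_size)) {
    dam <- pair_rows(founders$hap_a, sample.int(cfg$n_founders_a, 1))
    sire <- pair_rows(founders$hap_b, sample.int(cfg$n_founders_b, 1))
    cohort1[[i]] <- make_gamete(dam[[1]], dam[[2]], loci$chrom, loci$start, cl, cfg$recomb_rate)
    cohort2[[i]] <- make_gamete(sire[[1]], sire[[2]], loci$chrom, loci$start, cl, cfg$recomb_rate)
  }
  gen <- 1
  while (gen < cfg$n_generations) {
    w <- sel_weights(cohort1, cohort2)
    new1 <- vector("list", cfg$cohort_size)
    new2 <- vector("list", cfg$cohort_size)
    for (i in seq_len(cfg$cohort_size)) {
      parents <- sample.int(cfg$cohort_size, 2, prob = w)
      new1[[i]] <- make_gamete(cohort1[[parents[1]]], cohort2[[parents[1]]],
                               loci$chrom, loci$start, cl, cfg$recomb_rate)
      new2[[i]] <- make_gamete(cohort1[[parents[2]]], cohort2[[parents[2]]],
                               loci$chrom, loci$start, cl, cfg$recomb_rate)
    }
    cohort1 <- new1; cohort2 <- new2
    gen <- gen + 1
  }

  # ancestry bookkeeping for tests: fraction of each hybrid genome from breed A
  # is recoverable from allele frequencies; store the final haplotypes instead.
  a_pick <- sample.int(cfg$n_founders_a, cfg$n_a_out)
  b_pick <- sample.int(cfg$n_founders_b, cfg$n_b_out)
  h_pick <- sample.int(cfg$cohort_size, cfg$n_hybrid_out)

  dos_a <- t(vapply(a_pick, function(i) {
    founders$hap_a[2 * i - 1, ] + founders$hap_a[2 * i, ]
  }, numeric(L)))
  dos_b <- t(vapply(b_pick, function(i) {
    founders$hap_b[2 * i - 1, ] + founders$hap_b[2 * i, ]
  }, numeric(L)))
  dos_h <- t(vapply(h_pick, function(i) cohort1[[i]] + cohort2[[i]], numeric(L)))

  lab <- cfg$pop_labels
  samples <- c(sprintf("%s_%02d", lab[1], seq_len(cfg$n_a_out)),
               sprintf("%s_%02d", lab[2], seq_len(cfg$n_b_out)),
               sprintf("%s_%02d", lab[3], seq_len(cfg$n_hybrid_out)))
  popmap <- stats::setNames(rep(lab, c(cfg$n_a_out, cfg$n_b_out, cfg$n_hybrid_out)),
                            samples)
  geno <- t(rbind(dos_a, dos_b, dos_h))  # sites x samples
  truth <- variant_set(samples, loci, geno, source = "Truth", sort = FALSE)

  # panel: one diploid per breed ("one assembly per parent")
  pa <- sample.int(cfg$n_founders_a, 1)
  pb <- sample.int(cfg$n_founders_b, 1)
  carry_a <- founders$hap_a[2 * pa - 1, ] + founders$hap_a[2 * pa, ] >= 1
  carry_b <- founders$hap_b[2 * pb - 1, ] + founders$hap_b[2 * pb, ] >= 1
  panel <- carry_a | carry_b

  gm <- simulate_gene_models(cfg, loci, sweep_idx)

  structure(list(truth = truth, popmap = popmap, panel = panel,
                 private = founders$private, in_bias = founders$in_bias,
                 bias = founders$bias,
                 sweep_loci = cfg$sweep_loci, sweep_site_idx = sweep_idx,
                 gene_models = gm$models, deg = gm$deg,
                 p_a = founders$p_a, p_b = founders$p_b,
                 chrom_lengths = founders$chrom_lengths, cfg = cfg),
            class = "TruthBundle")
}

# Random gene models plus a DEG table; genes overlapping a sweep locus
# (+/- 50 kb) are guaranteed to exist and are flagged DE.
simulate_gene_models <- function(cfg, loci, sweep_idx) {
  set.seed(substream_seed(cfg$seed, "genes"))
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  models <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    if (i <= length(sweep_idx)) {
      ch <- loci$chrom[sweep_idx[i]]
      center <- loci$start[sweep_idx[i]]
      start <- max(0, center - sample(1000:20000, 1))
    } else {
      ch <- sample(chroms, 1)
      start <- sample.int(cfg$chrom_len - 40000, 1)
    }
    n_ex <- sample(1:3, 1)
    ex_len <- sample(150:900, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1) sample(200:3000, n_ex - 1, replace = TRUE) else integer(0)
    s <- start
    exons <- matrix(0, n_ex, 2)
    for (e in seq_len(n_ex)) {
      exons[e, ] <- c(s, s + ex_len[e])
      s <- s + ex_len[e] + if (e < n_ex) gaps[e] else 0
    }
    total <- sum(ex_len)
    trim <- total %% 3
    if (trim) exons[n_ex, 2] <- exons[n_ex, 2] - trim
    models[[i]] <- gene_model(sprintf("gene%03d", i), ch,
                              sample(c("+", "-"), 1), exons, cds = exons,
                              coding = TRUE)
  }
  ids <- vapply(models, `[[`, "", "gene_id")
  is_sweep_gene <- seq_len(cfg$n_genes) <= length(sweep_idx)
  de <- is_sweep_gene | stats::runif(cfg$n_genes) < cfg$deg_frac
  list(models = models,
       deg = data.frame(gene_id = ids, is_DE = de, stringsAsFactors = FALSE))
}

#' Emulate the two imperfect call sets from ground truth
#'
#' The single-reference (SR) set drops private loci, then miscalls true hets
#' as hom-ref with probability `eps_bias` inside bias regions and `eps_base`
#' elsewhere, then sets each call missing with probability `mu_miss`. The
#' panel (Pan) set is the truth restricted to panel loci with a symmetric
#' genotype error `eps_pan` (an erroneous call is one of the two other
#' classes, equiprobably). Both keep the truth site keys.
#'
#' @param tb a `TruthBundle`.
#' @param cfg the same [sim_config()].
#' @return list with `sr` and `pan` `VariantSet`s.
#' @export
emulate_callsets <- function(tb, cfg = tb$cfg) {
  set.seed(substream_seed(cfg$seed, "callsets"))
  truth <- tb$truth
  g <- truth$geno

  sr_keep <- which(!tb$private)
  sr_g <- g[sr_keep, , drop = FALSE]
  pbias <- ifelse(tb$in_bias[sr_keep], cfg$eps_bias, cfg$eps_base)
  het <- sr_g == 1L
  flip <- het & (matrix(stats::runif(length(sr_g)), nrow(sr_g)) <
                   matrix(pbias, nrow(sr_g), ncol(sr_g)))
  sr_g[flip] <- 0L
  miss <- matrix(stats::runif(length(sr_g)), nrow(sr_g)) < cfg$mu_miss
  sr_g[miss] <- NA_integer_
  sr <- variant_set(truth$samples, truth$sites[sr_keep, , drop = FALSE],
                    sr_g, source = "SR", sort = FALSE)

  pan_keep <- which(tb$panel)
  pan_g <- g[pan_keep, , drop = FALSE]
  err <- matrix(stats::runif(length(pan_g)), nrow(pan_g)) < cfg$eps_pan
  if (any(err)) {
    idx <- which(err)
    cur <- pan_g[idx]
    shift <- sample(1:2, length(idx), replace = TRUE)
    pan_g[idx] <- (cur + shift) %% 3L
  }
  pan <- variant_set(truth$samples, truth$sites[pan_keep, , drop = FALSE],
                     pan_g, source = "Pan", sort = FALSE)

  list(sr = sr, pan = pan)
}

#' Simulate a full cohort: founders, pedigree, and both call sets
#'
#' @param cfg a [sim_config()].
#' @return list with `truth` (a `TruthBundle`), `sr` and `pan`
#'   (`VariantSet`s).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  founders <- simulate_founders(cfg)
  tb <- simulate_pedigree(founders, cfg)
  cs <- emulate_callsets(tb, cfg)
  list(truth = tb, sr = cs$sr, pan = cs$pan)
}

#' Build a reference sequence consistent with the truth ref alleles
#'
#' Random chromosome sequences with every variant's REF allele written at
#' its position, so codon-level consequence calls on simulated data are
#' self-consistent.
#'
#' @param tb a `TruthBundle`.
#' @return named character vector of chromosome sequences.
#' @export
sim_reference <- function(tb) {
  set.seed(substream_seed(tb$cfg$seed, "reference"))
  seqs <- lapply(tb$chrom_lengths, function(len) {
    sample(c("A", "C", "G", "T"), len, replace = TRUE)
  })
  s <- tb$truth$sites
  for (i in seq_len(nrow(s))) {
    bases <- strsplit(s$ref[i], "")[[1]]
    seqs[[s$chrom[i]]][s$start[i] + seq_along(bases)] <- bases
  }
  vapply(seqs, paste, character(1), collapse = "")
}

#' Write all simulator outputs to a directory
#'
#' Emits `truth.vcf`, `sr.vcf`, `pan.vcf`, `popmap.tsv`, `genes.gff3`,
#' `ref.fa`, `deg.tsv` and `truth.json` (sweep loci, panel/private flags,
#' bias intervals).
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param with_reference also write `ref.fa` (slow for long genomes).
#' @return `dir`, invisibly.
#' @export
write_sim_outputs <- function(sim, dir, with_reference = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- sim$truth
  cl <- tb$chrom_lengths
  write_variant_table(tb$truth, file.path(dir, "truth.vcf"), cl)
  write_variant_table(sim$sr, file.path(dir, "sr.vcf"), cl)
  write_variant_table(sim$pan, file.path(dir, "pan.vcf"), cl)
  write_popmap(tb$popmap, file.path(dir, "popmap.tsv"))
  write_gene_models(tb$gene_models, file.path(dir, "genes.gff3"))
  utils::write.table(tb$deg, file.path(dir, "deg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (with_reference) write_fasta(sim_reference(tb), file.path(dir, "ref.fa"))
  truth_meta <- list(
    sweep_loci = tb$sweep_loci,
    panel_keys = variant_keys(tb$truth$sites)[tb$panel],
    private_keys = variant_keys(tb$truth$sites)[tb$private],
    bias_intervals = tb$bias,
    chrom_lengths = as.list(cl))
  jsonlite::write_json(truth_meta, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
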