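# Shared simulation products, cached so expensive replicates are computed
# once per test run regardless of which files use them.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) assign(key, fn(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# a small neutral cohort for structural checks
small_cfg <- function(seed = 101, ...) {
  defaults <- list(n_chrom = 1, chrom_len = 1e6, n_snp = 500, n_indel = 100,
                   n_sv = 10, n_founders_a = 20, n_founders_b = 20,
                   cohort_size = 60, n_a_out = 12, n_b_out = 12,
                   n_hybrid_out = 14, sweep_loci = NULL, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# one full-pipeline replicate at the generator's default study conditions;
# returns the scalar summaries every downstream claim is judged on
pipeline_rep <- function(seed) {
  cached(paste0("rep", seed), function() {
    cfg <- sim_config(seed = seed)
    sim <- simulate_cohort(cfg)
    tb <- sim$truth
    mres <- merge_callsets(sim$sr, sim$pan)
    q <- apply_qc_filters(mres$vs)$vs
    cl <- tb$chrom_lengths
    pm <- tb$popmap
    sp <- cfg$sweep_loci$pos[1]
    sp_chrom <- cfg$sweep_loci$chrom[1]
    in_sweep <- function(sc) sc$chrom == sp_chrom & sc$start <= sp & sc$end > sp
    fst <- windowed_fst(q, pm, "QCB", "DLW", chrom_lengths = cl)
    xp <- xpclr_scan(q, pm, "QCB", "DLW", chrom_lengths = cl,
                     grid = sweep_grid(recomb_cM_per_Mb = cfg$recomb_rate * 1e8))
    fo <- outlier_windows(fst)
    xo <- outlier_windows(xp)
    fst_genes <- suppressWarnings(annotate_windows(fo, tb$gene_models)$features)
    xp_genes <- suppressWarnings(annotate_windows(xo, tb$gene_models)$features)
    ct <- intersect_candidates(list(fst = fst_genes, xpclr = xp_genes), tb$deg)
    sweep_de_genes <- tb$deg$gene_id[seq_len(nrow(cfg$sweep_loci))]
    list(
      report = mres$report,
      hom_alt_sr = genotype_class_frequencies(sim$sr, by_type = FALSE)[, "hom_alt"],
      hom_alt_merged = genotype_class_frequencies(mres$vs, by_type = FALSE)[, "hom_alt"],
      cv_sr = uniformity_cv(window_density(sim$sr, cl, vtype = "SNP")$count),
      cv_merged = uniformity_cv(window_density(mres$vs, cl, vtype = "SNP")$count),
      fst_hit = any(in_sweep(fo)),
      xp_hit = any(in_sweep(xo)),
      sweep_de_recovered = all(sweep_de_genes %in% ct$joint_candidates),
      qc_sites = n_sites(q))
  })
}

crit4_seeds <- 901:920

# founder-level weighted WC Fst straight from simulated haplotypes
founder_fst <- function(f, n_loci = NULL) {
  L <- if (is.null(n_loci)) nrow(f$loci) else min(n_loci, nrow(f$loci))
  dos_a <- f$hap_a[seq(1, nrow(f$hap_a), 2), 1:L, drop = FALSE] +
    f$hap_a[seq(2, nrow(f$hap_a), 2), 1:L, drop = FALSE]
  dos_b <- f$hap_b[seq(1, nrow(f$hap_b), 2), 1:L, drop = FALSE] +
    f$hap_b[seq(2, nrow(f$hap_b), 2), 1:L, drop = FALSE]
  comp <- vapply(1:L, function(j) {
    c1 <- tabulate(dos_a[, j] + 1, 3)
    c2 <- tabulate(dos_b[, j] + 1, 3)
    fst_components(c1, c2)[c("a", "b", "c")]
  }, numeric(3))
  sum(comp["a", ], na.rm = TRUE) / sum(colSums(comp), na.rm = TRUE)
}
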