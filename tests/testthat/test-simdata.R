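test_that("Balding-Nichols founders recover the configured divergence", {
  cfg <- sim_config(n_chrom = 1, chrom_len = 2e6, n_snp = 2000, n_indel = 0,
                    n_sv = 0, n_founders_a = 60, n_founders_b = 60,
                    divergence = 0.2, sweep_loci = NULL, seed = 1)
  f <- simulate_founders(cfg)
  # conditional variance of breed frequencies: E[(p_a - p0)^2] = F p0 (1 - p0)
  expect_equal(mean((f$p_a - f$p0)^2 / (f$p0 * (1 - f$p0))), 0.2,
               tolerance = 0.25)
  # realized weighted WC Fst between the two founder samples
  expect_equal(founder_fst(f), 0.2, tolerance = 0.05)
})

test_that("founder divergence vanishes as F approaches zero and rises with F", {
  fst_at <- function(fv) {
    cached(paste0("fstF", fv), function() {
      cfg <- sim_config(n_chrom = 1, chrom_len = 1e6, n_snp = 1200, n_indel = 0,
                        n_sv = 0, n_founders_a = 50, n_founders_b = 50,
                        divergence = fv, sweep_loci = NULL, seed = 7)
      founder_fst(simulate_founders(cfg))
    })
  }
  small <- fst_at(0.01)
  expect_lt(small, 0.04)
  grid <- vapply(c(0.05, 0.1, 0.2, 0.3), fst_at, numeric(1))
  expect_true(all(diff(grid) > 0))
  expect_equal(grid, c(0.05, 0.1, 0.2, 0.3), tolerance = 0.05)
})

test_that("F1 offspring are heterozygous wherever the breeds are fixed different", {
  cfg <- sim_config(n_chrom = 1, chrom_len = 6e5, n_snp = 400, n_indel = 50,
                    n_sv = 5, n_founders_a = 8, n_founders_b = 8,
                    divergence = 0.6, cohort_size = 30, n_generations = 1,
                    n_a_out = 5, n_b_out = 5, n_hybrid_out = 20,
                    sweep_loci = NULL, seed = 31)
  f <- simulate_founders(cfg)
  tb <- simulate_pedigree(f, cfg)
  fixed_diff <- (colMeans(f$hap_a) == 1 & colMeans(f$hap_b) == 0) |
    (colMeans(f$hap_a) == 0 & colMeans(f$hap_b) == 1)
  expect_gt(sum(fixed_diff), 0)
  hyb <- tb$popmap[tb$truth$samples] == "QCB"
  expect_true(all(tb$truth$geno[fixed_diff, hyb] == 1L))
})

test_that("neutral F5 hybrids carry about half of each breed's ancestry", {
  cfg <- small_cfg(seed = 55)
  f <- simulate_founders(cfg)
  tb <- simulate_pedigree(f, cfg)
  hyb <- tb$popmap[tb$truth$samples] == "QCB"
  p_h <- rowMeans(tb$truth$geno[, hyb]) / 2
  d <- tb$p_a - tb$p_b
  # regression estimate of maternal-breed ancestry from frequency shifts
  anc <- sum((p_h - tb$p_b) * d) / sum(d^2)
  expect_equal(anc, 0.5, tolerance = 0.05)
})

test_that("selection raises the sweep-allele frequency above its F1 value", {
  rises <- vapply(1:20, function(s) {
    cfg <- sim_config(n_chrom = 1, chrom_len = 1e6, n_snp = 400, n_indel = 0,
                      n_sv = 0, n_founders_a = 15, n_founders_b = 15,
                      cohort_size = 60, n_a_out = 10, n_b_out = 10,
                      n_hybrid_out = 15,
                      sweep_loci = data.frame(chrom = "chr1", pos = 5e5, s = 2),
                      seed = 400 + s)
    f <- simulate_founders(cfg)
    tb <- simulate_pedigree(f, cfg)
    hyb <- tb$popmap[tb$truth$samples] == "QCB"
    f1_freq <- (tb$p_a[tb$sweep_site_idx] + tb$p_b[tb$sweep_site_idx]) / 2
    mean(tb$truth$geno[tb$sweep_site_idx, hyb]) / 2 > f1_freq
  }, logical(1))
  expect_gte(mean(rises), 0.95)
})

test_that("zero-noise call sets equal the truth on their respective loci", {
  cfg <- small_cfg(seed = 77, eps_base = 0, eps_bias = 0, mu_miss = 0,
                   eps_pan = 0)
  sim <- simulate_cohort(cfg)
  tb <- sim$truth
  keyt <- panhybrid:::variant_keys(tb$truth$sites)
  isr <- match(panhybrid:::variant_keys(sim$sr$sites), keyt)
  expect_equal(unname(sim$sr$geno), unname(tb$truth$geno[isr, ]))
  ipan <- match(panhybrid:::variant_keys(sim$pan$sites), keyt)
  expect_equal(unname(sim$pan$geno), unname(tb$truth$geno[ipan, ]))
  expect_setequal(which(tb$panel), ipan)
})

test_that("single-reference dropout follows the private-locus fraction", {
  cfg <- small_cfg(seed = 78, n_snp = 2000, n_indel = 0, n_sv = 0,
                   pi_priv = 0.1, pi_priv_bias = 0.1)
  sim <- simulate_cohort(cfg)
  L <- n_sites(sim$truth$truth)
  expect_equal(n_sites(sim$sr), L - sum(sim$truth$private))
  # binomial count check: dropped ~ Binom(L, 0.1), +/- 3 sd
  expect_lt(abs(sum(sim$truth$private) - 0.1 * L), 3 * sqrt(L * 0.1 * 0.9))
  # private loci carried by the panel individuals appear in Pan, never SR
  pp <- which(sim$truth$private & sim$truth$panel)
  expect_gt(length(pp), 0)
  keyt <- panhybrid:::variant_keys(sim$truth$truth$sites)
  expect_true(all(keyt[pp] %in% panhybrid:::variant_keys(sim$pan$sites)))
  expect_false(any(keyt[pp] %in% panhybrid:::variant_keys(sim$sr$sites)))
})

test_that("truth bundles satisfy their structural invariants", {
  sim <- cached("small_sim", function() simulate_cohort(small_cfg()))
  tb <- sim$truth
  expect_false(anyNA(tb$truth$geno))
  sv <- tb$truth$sites$vtype == "SV"
  expect_true(all(abs(nchar(tb$truth$sites$alt[sv]) -
                        nchar(tb$truth$sites$ref[sv])) >= 50))
  expect_equal(length(tb$panel), n_sites(tb$truth))
  expect_equal(sort(unique(tb$popmap)), c("DLW", "GZB", "QCB"))
  expect_equal(as.vector(table(tb$popmap)[c("GZB", "DLW", "QCB")]),
               c(12, 12, 14))
  # DEG table covers all genes; sweep genes (none here) need not exist
  expect_equal(nrow(tb$deg), length(tb$gene_models))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(divergence = 0), "divergence")
  expect_error(sim_config(divergence = 1), "divergence")
  expect_error(sim_config(eps_base = 1.2), "rates")
  expect_error(sim_config(chrom_len = 1e5), "500 kb")
  expect_error(sim_config(cohort_size = 1), "cohort_size")
  expect_error(sim_config(sweep_loci = data.frame(chrom = "chr9", pos = 1e5, s = 1)),
               "chromosome")
  expect_error(sim_config(sweep_loci = data.frame(chrom = "chr1", pos = 9e9, s = 1)),
               "bounds")
})

test_that("simulator outputs write a complete, readable file bundle", {
  sim <- cached("small_sim", function() simulate_cohort(small_cfg()))
  dir <- file.path(tempdir(), "simout")
  write_sim_outputs(sim, dir, with_reference = TRUE)
  expect_true(all(file.exists(file.path(dir,
    c("truth.vcf", "sr.vcf", "pan.vcf", "popmap.tsv", "genes.gff3",
      "ref.fa", "deg.tsv", "truth.json")))))
  back <- read_variant_table(file.path(dir, "sr.vcf"))
  expect_equal(n_sites(back), n_sites(sim$sr))
  pm <- read_popmap(file.path(dir, "popmap.tsv"), samples = sim$sr$samples)
  expect_equal(unname(pm), unname(sim$truth$popmap))
  # the written reference carries every REF allele at its position
  ref <- read_fasta(file.path(dir, "ref.fa"))
  s <- sim$truth$truth$sites[sim$truth$truth$sites$vtype == "SNP", ][1:20, ]
  expect_true(all(unname(substr(ref[s$chrom], s$start + 1, s$start + 1)) ==
                    s$ref))
})
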