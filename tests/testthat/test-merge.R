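mk_vs <- function(starts, geno, samples = letters[1:ncol(geno)],
                  source = "SR", chrom = "chr1") {
  sites <- data.frame(chrom = chrom, start = starts,
                      ref = "A", alt = "G")
  variant_set(samples, sites, geno, source = source)
}

test_that("genotype concordance uses pairwise-complete comparisons", {
  expect_equal(genotype_concordance(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(genotype_concordance(c(rep(0, 9), 1), c(rep(0, 9), 2)), 0.9)
  g1 <- c(rep(0, 9), NA); g2 <- c(rep(0, 9), 1)
  expect_equal(genotype_concordance(g1, g2), 1)       # 9/9, missing pair excluded
  expect_true(is.na(genotype_concordance(c(NA, NA), c(1, NA))))
  expect_error(genotype_concordance(1:3, 1:4), "length")
})

test_that("disjoint call sets merge to their union", {
  set.seed(1)
  g1 <- matrix(sample(0:2, 100 * 4, TRUE), 100)
  g2 <- matrix(sample(0:2, 40 * 4, TRUE), 40)
  sr <- mk_vs(seq(0, 990, by = 10), g1)
  pan <- mk_vs(seq(5000, 5390, by = 10), g2, source = "Pan")
  res <- merge_callsets(sr, pan)
  expect_equal(res$report$n_merged, 140)
  expect_equal(res$report$n_overlap_retained, 0)
  expect_equal(res$report$n_overlap_discarded, 0)
})

test_that("concordant overlaps are retained once with priority-source genotypes", {
  g <- matrix(rep(c(0L, 1L, 2L, 1L), 10), 10, byrow = TRUE)
  sr <- mk_vs(1:10 * 100, g)
  pan <- mk_vs(1:10 * 100, g, source = "Pan")
  res <- merge_callsets(sr, pan)
  expect_equal(res$report$n_overlap_retained, 10)
  expect_equal(res$report$n_overlap_discarded, 0)
  expect_equal(res$report$n_merged, 10)
  expect_equal(res$vs$source, "Merged")
})

test_that("the 90% concordance bar is strict", {
  # 10 samples, 9 agree, 1 disagrees -> concordance exactly 0.9 -> discarded
  g_sr <- matrix(c(rep(0L, 9), 1L), 1)
  g_pan <- matrix(c(rep(0L, 9), 2L), 1)
  sr <- mk_vs(100, g_sr, samples = sprintf("s%d", 1:10))
  pan <- mk_vs(100, g_pan, samples = sprintf("s%d", 1:10), source = "Pan")
  res <- merge_callsets(sr, pan)
  expect_equal(res$report$n_overlap_discarded, 1)
  expect_equal(res$report$n_merged, 0)
  # one disagreement among 11 comparable -> 10/11 > 0.9 -> retained
  sr2 <- mk_vs(100, matrix(c(rep(0L, 10), 1L), 1), samples = sprintf("s%d", 1:11))
  pan2 <- mk_vs(100, matrix(c(rep(0L, 10), 2L), 1), samples = sprintf("s%d", 1:11),
                source = "Pan")
  expect_equal(merge_callsets(sr2, pan2)$report$n_overlap_retained, 1)
})

test_that("merge count identity holds and key set is label-symmetric", {
  cfg <- sim_config(n_chrom = 1, chrom_len = 1e6, n_snp = 400, n_indel = 80,
                    n_sv = 8, n_founders_a = 15, n_founders_b = 15,
                    cohort_size = 40, n_a_out = 8, n_b_out = 8, n_hybrid_out = 10,
                    sweep_loci = NULL, seed = 21)
  sim <- simulate_cohort(cfg)
  res <- merge_callsets(sim$sr, sim$pan)
  r <- res$report
  expect_equal(r$n_merged, r$n_sr_only + r$n_pan_only + r$n_overlap_retained)
  swapped <- merge_callsets(sim$pan, sim$sr)
  keys <- function(x) panhybrid:::variant_keys(x$vs$sites)
  expect_setequal(keys(res), keys(swapped))
  # fully concordant inputs: merged = union exactly
  res0 <- merge_callsets(sim$sr, sim$sr)
  expect_equal(res0$report$n_merged, n_sites(sim$sr))
})

test_that("mismatched cohorts and unsorted sets are rejected", {
  g <- matrix(0L, 1, 3)
  sr <- mk_vs(1, g, samples = c("a", "b", "c"))
  pan <- mk_vs(1, g, samples = c("a", "b", "x"), source = "Pan")
  expect_error(merge_callsets(sr, pan), "sample")
})

test_that("variant normalization trims, left-aligns and collapses duplicates", {
  # ("AT" -> "AAT") at VCF pos 101: shared suffix T trimmed -> A -> AA
  sites <- data.frame(chrom = "chr1", start = 100, ref = "AT", alt = "AAT")
  vs <- variant_set(c("x", "y"), sites, matrix(c(1L, 0L), 1))
  nv <- normalize_variants(vs)
  expect_equal(nv$sites$ref, "A")
  expect_equal(nv$sites$alt, "AA")
  expect_equal(nv$sites$start, 100)
  # minimal SNP unchanged; idempotence
  snp <- variant_set("x", data.frame(chrom = "chr1", start = 5, ref = "C",
                                     alt = "T"), matrix(1L))
  expect_equal(normalize_variants(snp)$sites, snp$sites)
  # duplicates with identical genotypes collapse to one record
  dup <- variant_set(c("x", "y"),
                     data.frame(chrom = "chr1", start = c(100, 100),
                                ref = c("AT", "ATT"), alt = c("AAT", "AATT")),
                     rbind(c(1L, 0L), c(1L, 0L)))
  expect_equal(n_sites(normalize_variants(dup)), 1)
  # conflicting genotypes raise an error
  dup2 <- variant_set(c("x", "y"),
                      data.frame(chrom = "chr1", start = c(100, 100),
                                 ref = c("AT", "ATT"), alt = c("AAT", "AATT")),
                      rbind(c(1L, 0L), c(2L, 0L)))
  expect_error(normalize_variants(dup2), "conflicting")
})

test_that("normalization against a reference matches the brute-force oracle", {
  set.seed(7)
  ref_seq <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = ""))
  n_checked <- 0
  for (i in 1:40) {
    pos <- sample(8:25, 1)
    rl <- sample(1:4, 1)
    ref <- substr(ref_seq[["chr1"]], pos + 1, pos + rl)
    alt <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1), TRUE), collapse = "")
    if (alt == ref) next
    got <- panhybrid:::normalize_one("chr1", pos, ref, alt, ref_seq)
    want <- normalize_oracle("chr1", pos, ref, alt, ref_seq)
    # both must describe the same edit; oracle returns the leftmost-minimal form
    expect_equal(got[c("start", "ref", "alt")],
                 want[c("start", "ref", "alt")],
                 info = sprintf("pos=%d ref=%s alt=%s", pos, ref, alt))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 30)
})

test_that("REF alleles disagreeing with the reference are reported", {
  ref_seq <- c(chr1 = "ACGTACGTAC")
  vs <- variant_set("x", data.frame(chrom = "chr1", start = 2, ref = "T",
                                    alt = "A"), matrix(1L))
  expect_error(normalize_variants(vs, ref_seq), "mismatch")
})

test_that("genotype class frequencies are proportions that sum to one", {
  sites <- data.frame(chrom = "chr1", start = 1, ref = "A", alt = "G")
  vs <- variant_set(c("a", "b", "c", "d"), sites,
                    matrix(c(0L, 1L, 2L, NA), 1))
  f <- genotype_class_frequencies(vs, by_type = FALSE)
  expect_equal(unname(f[1, ]), rep(0.25, 4))
  vs2 <- variant_set(c("a", "b"), data.frame(chrom = "chr1", start = 1:3,
                                             ref = "A", alt = "G"),
                     matrix(0L, 3, 2))
  f2 <- genotype_class_frequencies(vs2, by_type = TRUE)
  expect_equal(unname(f2["SNP", "hom_ref"]), 1)
  expect_equal(unname(rowSums(f2)), rep(1, nrow(f2)))
  expect_error(genotype_class_frequencies(vs_empty <- variant_set("a",
    sites[0, ], matrix(integer(0), 0, 1))), "empty")
})

test_that("window density tiles chromosomes and the CV follows sd/mean", {
  expect_equal(uniformity_cv(c(10, 10, 10, 10)), 0)
  expect_equal(uniformity_cv(c(0, 20)), 1)          # population sd / mean
  expect_true(is.na(uniformity_cv(c(0, 0))))
  sites <- data.frame(chrom = "chr1", start = c(0, 100, 600, 1100),
                      ref = "A", alt = "G")
  vs <- variant_set("x", sites, matrix(0L, 4, 1))
  wd <- window_density(vs, c(chr1 = 1500), window_size = 500)
  expect_equal(wd$count, c(2, 1, 1))
  expect_equal(wd$end, c(500, 1000, 1500))
  expect_error(window_density(vs, c(chr1 = 1500), window_size = 0), "positive")
})
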