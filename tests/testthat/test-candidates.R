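test_that("candidate intersection performs exact set algebra", {
  ct <- intersect_candidates(list(sel = c("A", "B", "C")), c("B", "C", "D"))
  expect_setequal(ct$joint_candidates, c("B", "C"))
  expect_equal(nrow(ct$table), 4)
  expect_warning(ct0 <- intersect_candidates(list(sel = c("A")), character(0)),
                 "empty DEG")
  expect_length(ct0$joint_candidates, 0)
  disj <- intersect_candidates(list(e1 = "A", e2 = "B"), "C")
  expect_length(disj$joint_candidates, 0)
  expect_equal(sum(disj$upset), 3)
  # minimum-evidence rule
  ct2 <- intersect_candidates(list(e1 = c("A", "B"), e2 = c("B")), c("A", "B"),
                              min_evidence = 2)
  expect_equal(ct2$joint_candidates, "B")
})

test_that("upset counts equal brute-force powerset enumeration", {
  set.seed(30)
  genes <- sprintf("g%02d", 1:40)
  ev <- lapply(1:5, function(i) sample(genes, sample(5:20, 1)))
  names(ev) <- paste0("e", 1:5)
  deg <- sample(genes, 12)
  ct <- intersect_candidates(ev, deg)
  universe <- unique(c(unlist(ev), deg))
  flags <- cbind(vapply(ev, function(s) universe %in% s, logical(length(universe))),
                 DE = universe %in% deg)
  pat <- apply(flags, 1, paste, collapse = "")
  for (p in unique(pat)) {
    expect_equal(unname(ct$upset[p]), sum(pat == p))
  }
  expect_equal(sum(ct$upset), length(universe))
})

test_that("positional consequence classes follow gene anatomy", {
  ref <- c(chr1 = paste(rep("ACGT", 2500), collapse = ""))
  gm <- gene_model("g1", "chr1", "+", exons = rbind(c(1000, 1300), c(2000, 2300)),
                   cds = rbind(c(1000, 1300), c(2000, 2300)))
  cc <- function(pos, r, a, model = gm) {
    coding_consequence("chr1", pos, r, a, model, ref)$class
  }
  base_at <- function(pos) substr(ref[["chr1"]], pos + 1, pos + 1)
  p <- 1500
  expect_equal(cc(p, base_at(p), "A"), "intronic")
  p <- 900
  expect_equal(cc(p, base_at(p), "C"), "upstream")
  p <- 2500
  expect_equal(cc(p, base_at(p), "C"), "downstream")
  p <- 100                                       # 900 bp before the span
  expect_equal(cc(p, base_at(p), "C"), "upstream")
  # more than 5 kb away -> intergenic
  gm_far <- gene_model("g2", "chr1", "+", exons = cbind(9000, 9300),
                       cds = cbind(9000, 9300))
  expect_equal(coding_consequence("chr1", 100, base_at(100), "C", gm_far,
                                  ref)$class, "intergenic")
  # minus strand flips upstream/downstream
  gmm <- gene_model("g3", "chr1", "-", exons = cbind(1000, 1300),
                    cds = cbind(1000, 1300))
  expect_equal(cc(900, base_at(900), "C", gmm), "downstream")
  expect_equal(cc(1400, base_at(1400), "C", gmm), "upstream")
  # INDEL in CDS gets no frame analysis
  expect_equal(cc(1005, paste0(base_at(1005), base_at(1006)), base_at(1005)),
               "coding_indel_unclassified")
  # REF mismatch is a data error
  wrong <- setdiff(c("A", "C", "G", "T"), base_at(1005))[1]
  expect_error(cc(1005, wrong, base_at(1005)), "mismatch")
})

test_that("codon-level calls classify known substitutions", {
  # plus-strand gene whose first codons are GGA ATG ...
  seqstr <- paste0(paste(rep("T", 100), collapse = ""), "GGAATGTAA",
                   paste(rep("T", 100), collapse = ""))
  ref <- c(chrX = seqstr)
  gm <- gene_model("gX", "chrX", "+", exons = cbind(100, 109),
                   cds = cbind(100, 109))
  # GGA -> GGG at codon position 3: Gly -> Gly
  r1 <- coding_consequence("chrX", 102, "A", "G", gm, ref)
  expect_equal(r1$class, "synonymous")
  expect_equal(r1$aa_change, "G>G")
  # ATG -> ATA: Met -> Ile
  r2 <- coding_consequence("chrX", 105, "G", "A", gm, ref)
  expect_equal(r2$class, "missense")
  expect_equal(r2$aa_change, "M>I")
  # TAA stop lost: TAA -> CAA (Gln)
  r3 <- coding_consequence("chrX", 106, "T", "C", gm, ref)
  expect_equal(r3$class, "stop_lost")
})

test_that("codon calls agree with the full-transcript translation oracle", {
  set.seed(33)
  for (i in 1:100) {
    L <- 600
    chromseq <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    ref <- c(chr1 = chromseq)
    n_ex <- sample(1:3, 1)
    len <- 3 * sample(4:20, n_ex, TRUE)
    gaps <- if (n_ex > 1) sample(10:40, n_ex - 1, TRUE) else integer(0)
    s0 <- sample(10:60, 1)
    exons <- matrix(0, n_ex, 2)
    s <- s0
    for (e in seq_len(n_ex)) {
      exons[e, ] <- c(s, s + len[e])
      s <- s + len[e] + if (e < n_ex) gaps[e] else 0
    }
    strand <- sample(c("+", "-"), 1)
    gm <- gene_model(sprintf("r%03d", i), "chr1", strand, exons, cds = exons)
    cds_pos <- unlist(apply(exons, 1, function(x) seq(x[1], x[2] - 1),
                            simplify = FALSE))
    pos <- sample(cds_pos, 1)
    rb <- substr(chromseq, pos + 1, pos + 1)
    ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    got <- coding_consequence("chr1", pos, rb, ab, gm, ref)$class
    want <- consequence_oracle("chr1", pos, rb, ab, gm, ref)
    expect_equal(got, want,
                 info = sprintf("case %d strand %s pos %d %s>%s", i, strand,
                                pos, rb, ab))
  }
})

test_that("per-population genotype reports match the printed-percentage idiom", {
  n <- 77
  geno <- matrix(c(rep(0L, 40), rep(0L, 21), rep(1L, 15), rep(2L, 1)), 1)
  samples <- c(sprintf("D%02d", 1:40), sprintf("Q%02d", 1:37))
  pm <- setNames(rep(c("DLW", "QCB"), c(40, 37)), samples)
  vs <- variant_set(samples, data.frame(chrom = "chr8", start = 43738940,
                                        ref = "C", alt = "T"), geno)
  rep_ <- population_genotype_report(vs, "chr8", 43738940, "C", "T", pm)
  dlw <- rep_[rep_$population == "DLW", ]
  qcb <- rep_[rep_$population == "QCB", ]
  expect_equal(dlw$pct_hom_ref, 100)
  expect_equal(qcb$pct_hom_ref, 100 * 21 / 37, tolerance = 1e-12)
  expect_equal(qcb$pct_het, 100 * 15 / 37, tolerance = 1e-12)
  expect_equal(round(c(qcb$pct_hom_ref, qcb$pct_het, qcb$pct_hom_alt), 1),
               c(56.8, 40.5, 2.7))
  sums <- rowSums(rep_[, c("pct_hom_ref", "pct_het", "pct_hom_alt", "pct_missing")])
  expect_equal(unname(sums), c(100, 100), tolerance = 1e-9)
  expect_error(population_genotype_report(vs, "chr8", 1, "C", "T", pm),
               "not present")
})

test_that("region matrices are half-open, ordered and population-grouped", {
  sites <- data.frame(chrom = "chr1", start = seq(100, 1000, by = 100),
                      ref = "A", alt = "G")
  geno <- matrix(rep(0:2, length.out = 40), 10, 4)
  pm <- c(w = "P2", x = "P1", y = "P2", z = "P1")
  vs <- variant_set(c("w", "x", "y", "z"), sites, geno)
  m <- haplotype_matrix(vs, "chr1", 100, 400, pm)
  expect_equal(ncol(m), 3)                       # site at 400 excluded
  expect_equal(attr(m, "positions"), c(100, 200, 300))
  expect_equal(rownames(m), c("x", "z", "w", "y"))
  expect_warning(haplotype_matrix(vs, "chr2", 0, 100, pm), "no sites")
})

test_that("swept regions lose heterozygosity relative to matched controls", {
  rep1 <- pipeline_rep(crit4_seeds[1])
  sim <- cached(paste0("repsim", crit4_seeds[1]), function() {
    simulate_cohort(sim_config(seed = crit4_seeds[1]))
  })
  tb <- sim$truth
  m_sweep <- haplotype_matrix(tb$truth, "chr1", 2.4e6, 2.6e6, tb$popmap)
  m_ctrl <- haplotype_matrix(tb$truth, "chr2", 2.4e6, 2.6e6, tb$popmap)
  hyb <- attr(m_sweep, "population") == "QCB"
  het <- function(m, rows) mean(m[rows, ] == 1, na.rm = TRUE)
  expect_lt(het(m_sweep, hyb), het(m_ctrl, attr(m_ctrl, "population") == "QCB"))
})
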