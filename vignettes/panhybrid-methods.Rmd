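---
title: "Models and methods behind panhybrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panhybrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`panhybrid` integrates two genotype call sets over a two-breed hybrid
cohort — one from mapping to a single linear reference, one from
genotyping against a parental variant panel — and runs the downstream
population-genomic comparisons. This vignette documents the models, the
parameters that matter, the simulator's assumptions, and the numerical
choices, in the package's own terms.

## The integration rule

Both call sets are reduced to biallelic records with GT-only genotypes;
multi-allelic records, symbolic alternates and spanning-deletion records
(`*`) are dropped on read and counted. Records are normalized (shared
suffix then prefix trimmed, left-aligned against the reference when one
is supplied) so that "the same variant" means the same (chromosome,
position, REF, ALT) key. Sites present in only one source pass through.
Overlapping sites are retained once when genotype concordance — the
fraction of agreeing calls among sample pairs where both calls are
non-missing — strictly exceeds 0.90; others are discarded. Which source's
genotypes survive at retained overlaps is a parameter (`genotype_priority`,
default the single-reference set, whose calls derive from per-sample
reads). Sites with zero comparable pairs are discarded and counted
separately, since concordance is undefined for them. An internal assertion
enforces the count identity
`n_merged = n_SR_only + n_Pan_only + n_overlap_retained` on every merge.

Site-level QC runs *after* merging, in a fixed order with per-filter
attribution: missingness > 10%, then minor allele frequency < 5% (computed
over non-missing calls), then an exact Hardy-Weinberg test at P < 1e-6.
All inequalities are strict, so boundary sites are retained. The HWE
filter applies to SNPs and INDELs only; structural variants are exempt.
The exact test enumerates every heterozygote count compatible with the
conditional minor-allele count, computes probabilities by the standard
mode-anchored recurrence, and sums those not exceeding the observed
count's probability (two-sided). At cohort sizes around one hundred a
chi-square approximation is unreliable at P ~ 1e-6, which is why the test
is exact. Note one consequence that matters downstream: pooling three
differentiated populations creates a Wahlund heterozygote deficit, so the
*most* extremely breed-differentiated sites are removed by this filter —
selection scans then rely on moderately differentiated sites, exactly as
they would on real data processed the same way.

Variant classes follow allele lengths: single-base substitutions are SNPs;
otherwise the length difference classifies the record, 1-49 bp as INDEL
and >= 50 bp as SV. The conventional 50 bp boundary is assigned to the SV
class.

## Windowed statistics

Scans use 50 kb windows advancing by 25 kb. Windows start at 0; a trailing
partial window is kept unless an earlier full-size window already covers
it. Per-site Weir-Cockerham variance components (a, b, c) are computed
from per-population genotype counts and aggregated per window as
`sum(a) / sum(a+b+c)` — the ratio-of-sums ("weighted") convention;
negative per-site estimates are not clamped, only the aggregation bounds
the window score. A per-site mean is available behind a flag. The top 5%
of scored windows (empirical quantile with linear interpolation; ties at
the threshold all included) are outliers, and genes or QTL intervals
annotate a window on >= 1 bp overlap in half-open arithmetic.

The sweep scan is a composite-likelihood reimplementation of the
cross-population XP-CLR design — drift null, distance-decaying escape
probability, maximization over a selection grid — not a numerical clone of
any existing program. Under the null, the object population's frequency at
a site is a censored normal centred on the reference population's
frequency `p` with variance `omega * p(1-p)`; `omega` is estimated
genome-wide by the method of moments, with frequencies clamped to
[0.01, 0.99]. The site likelihood integrates the binomial likelihood of
the observed allele count over that density with a fixed 512-point
midpoint quadrature plus the censored boundary masses at 0 and 1. Under a
sweep of strength `s`, a site at distance `d` from the window centre
escapes with probability `c = 1 - exp(-r d / s)` (recombination `r` in
Morgans/bp); a non-escaping site's frequency follows a two-component
mixture with mass `p` centred at `1 - c(1-p)` and mass `1-p` centred at
`c p`, each with variance `c * omega * p(1-p)` floored at 1e-6 (both null
and sweep variances share the floor so the `s = 0` identity is exact).
The window score is `2 max_s sum_sites [L(s) - L0]`, floored at 0, over the
grid `{0} union logspace(1e-5, 1e-1, 15)`. Because the grid contains 0 and
`c -> 1` recovers the null exactly, the score is identically 0 when no
sweep model improves on drift.

EigenGWAS regresses the leading principal component (computed from the two
populations being contrasted) on each marker's dosage by OLS with
pairwise-complete handling of missing calls; markers with minor-allele
count < 2 are skipped. Chi-square statistics are deflated by
`lambda_GC = median(chisq) / 0.4549364` before Bonferroni thresholding at
`0.05 / n_tested` (strict); per standard genomic-control practice a lambda
below 1 is never used to inflate statistics (the reported lambda stays
uncapped). One calibration fact worth knowing: when the
pseudo-phenotype is PC1 of the *same* marker matrix, the null expectation
of `lambda_GC` is not 1 but the top-eigenvalue edge `(1 + sqrt(n/M))^2` of
the null covariance spectrum — about 1.30 for 100 samples and 5,000
markers, and approaching 1 only when markers vastly outnumber samples as
in real whole-genome panels. The package's null tests assert agreement
with that prediction rather than with 1.

PCA centres dosages by `2p` and scales by `sqrt(2p(1-p))` (Patterson
scaling; unscaled available), mean-imputes missing dosages after
centring, and fixes each PC's sign so its largest-magnitude score is
positive. The admixture estimator is the standard binomial-mixture EM with
frequencies clamped to [1e-6, 1-1e-6], seeded Dirichlet initialization and
5 restarts by default; the log-likelihood is non-decreasing by
construction and checked in tests. Component labels are aligned by
anchoring component 1 to the breed with the highest mean ancestry.

## The synthetic cohort generator

The generator emulates the breeding design the pipeline targets: two
founder breeds diverged under a Balding-Nichols model (ancestral frequency
`p0 ~ Uniform(0.05, 0.95)`, breed frequencies Beta-distributed around it
with divergence `F`, default 0.2), an F1 of dam x sire crosses, then
random mating within cohorts of 200 to F5 with Poisson-crossover
recombination. Defaults mirror the target design's cohort: 31 maternal-breed,
40 paternal-breed and 37 F5 hybrid samples. The desk-scale genome is two
5 Mb chromosomes carrying 4,000 SNPs, 800 INDELs and 60 SVs; the
recombination rate (5e-7 /bp/meiosis, ~2.5 crossovers per chromosome per
meiosis) gives each synthetic chromosome a realistic per-chromosome map
length so ancestry blocks localize at sub-Mb scale.

Two error processes emulate the call sets. The single-reference set drops
"private" loci (unrepresentable on the reference; probability 0.08,
elevated to 0.5 inside +/-10 kb bias regions around SVs, where mapping
fails most), miscalls true hets as hom-ref with probability 0.15 inside
bias regions (0.01 outside), and erases calls at random with probability
0.03. The panel set contains exactly the variants carried by one sampled
diploid per breed — mirroring one assembly per parent — with a symmetric
0.01 genotype error. Placing 70% of INDELs inside bias regions makes the
INDEL dropout, and hence the post-merge INDEL gain, exceed the SNP gain;
because this also clusters true INDELs near SVs, density uniformity is
compared on per-type (SNP) window counts, matching how per-type density
tracks are normally displayed.

Selection during the intercross draws each parent with probability
proportional to `prod(1 + s * dosage/2)` over configured sweep loci. A
sweep locus is planted at the nearest SNP with breed frequencies
0.95/0.03 and sits on a breed-differentiated haplotype block: all sites
within a 30 kb core and 70% of sites out to 100 kb receive maternal-breed
frequencies in (0.95, 0.995) against paternal frequencies in (0.30, 0.50).
This is the structure of a regionally selected, anciently diverged
haplotype — the situation the scans target — and it is what makes a
top-5% window call reproducible: fixing local maternal ancestry drives
hybrid frequencies near fixation against a moderate reference frequency,
which both the Fst and the composite-likelihood statistics reward. The
paternal frequencies are deliberately moderate; fully private haplotypes
would be stripped by the pooled-cohort HWE filter before the scans ever
saw them. The default selection weight (s = 12) represents intense
single-trait artificial selection and reliably fixes local ancestry within
four generations of intercrossing.

Every stochastic stage draws its own named substream from the single
configured seed, so any stage can be re-run or pinned independently.

What the generator does *not* model: background linkage disequilibrium
within the founder breeds (founder haplotypes are in linkage equilibrium,
so sweeps must be planted as diverged blocks rather than emerging from
hitchhiking alone), sequence-level read errors and genotype likelihoods,
gene conversion, overlapping variant representation beyond simple
left-alignment, and realistic gene structure (genes are random 1-3-exon
models). Passing tests on this cohort therefore demonstrate the
pipeline's logic and its estimators' calibration, not performance on the
error structure of any particular sequencing technology.

## Numerical and convention choices

- Internal coordinates are 0-based half-open everywhere; VCF and GFF3 I/O
  convert at the boundary. "Spanning-deletion" records are the records
  whose ALT is the `*` allele; half-missing genotypes (`./1`) are treated
  as missing.
- Simulation problem sizes in the test-suite are scaled to the desk: the
  acceptance replicates use the default two-chromosome, 4,860-site genome;
  module tests use a 1 Mb, ~600-site genome. Tolerances on stochastic
  recovery checks (founder `F` within +/-0.05; hybrid ancestry 0.5 +/-
  0.1; drift variance within 20%) reflect the sampling noise at those
  sizes.
- The merge keeps the site on first encounter when duplicate keys carry
  identical genotypes and errors on conflict rather than guessing.
- `coding_consequence` reports `exonic_noncoding` for exonic sites outside
  the CDS rather than folding them into UTR-side classes, and
  `coding_indel_unclassified` for non-SNPs in coding sequence (no frame
  analysis). Upstream/downstream use a 5 kb window, configurable.
- The haplotype display for a focal region uses genotype dosages, not
  phased haplotypes: the pipeline never phases, and the regional pattern
  (reduced heterozygosity, consistent dosage blocks) is visible at dosage
  level.
- The "joint candidate" rule is a configurable minimum-evidence
  intersection (default: in the DEG list and in at least one
  selection-evidence set), since different studies combine scan evidence
  differently.

## Known limitations

The sweep scan's composite-likelihood model shares the structure, not the
numerics, of the original cross-population CLR programs; scores are
comparable within a run, not across tools. The admixture EM is the plain
algorithm without quasi-Newton acceleration and is intended for the
desk-scale marker counts used here (hundreds to a few thousand markers;
subsample for speed). Cross-validation for choosing K is out of scope — K
is a parameter. The generic interval annotator stands in for curated QTL
databases: it annotates whatever intervals it is given and knows nothing
about trait ontology.
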