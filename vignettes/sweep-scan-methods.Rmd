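---
title: "Methods: permutation-normalized selective-sweep scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-normalized selective-sweep scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Artificial selection leaves two complementary footprints in population
genomes: allele frequencies at the selected locus (and linked sites)
diverge between the selected population and its relatives, and diversity
within the selected population collapses. `dsscan` scans a two-group
comparison for both signals at once: sliding-window Weir–Cockerham F_ST
and the absolute difference in windowed nucleotide diversity, |Δπ|. Both
raw statistics have comparison-specific scales — they depend on sample
sizes, SNP density and background divergence — so neither has a universal
significance threshold. The package therefore normalizes each against an
empirical permutation null built from the comparison's own data, and calls
windows on the resulting Z-scores.

## Statistics

**Per-site summaries.** For each group at each bi-allelic SNP we record the
number of called diploids `n`, the alt-allele frequency among called
alleles `p`, the observed heterozygote fraction `h`, and the per-site
nucleotide diversity `π = 2·c_ref·c_alt / (m(m−1))` over the `m = 2n`
called alleles (the unbiased mean pairwise difference). Missing genotypes
simply reduce `n`; nothing is imputed.

**Weir–Cockerham F_ST.** Per site we compute the 1984 variance components
`a` (among populations), `b` (among individuals within populations) and
`c` (within individuals) for `r = 2` populations from `(n, p, h)` of the
two groups; the window estimate is the weighted ratio of sums
`Σa / Σ(a+b+c)` over the sites in the window. The ratio-of-sums form
weights informative sites properly and is the standard windowed estimator.
Negative window values are retained: flooring at zero would distort the
null distribution that the Z-transform relies on.

**Windowed π and |Δπ|.** Window π is the sum of per-site π divided by the
window length in bp (truncated terminal windows use their true length), so
values are per-bp and comparable across windows; |Δπ| is the absolute
difference between the two groups' window values. A group with no usable
sites in a window contributes π = 0 — absence of diversity is signal for
this statistic, not missing data — but windows containing no scan sites at
all are dropped from scoring entirely.

**Windows.** 40 kb windows advanced in 20 kb steps (both configurable),
starting at 0 on every chromosome and truncated at the chromosome end.
Truncation (rather than letting windows overhang) keeps the per-bp π
normalization exact; overhang would silently deflate terminal windows.

## The permutation null

The null model asks: what do the window statistics look like when per-site
records are scattered at random over the same genomic positions? Each
replicate reassigns the complete per-site payload — both groups' `(n, p,
h, π)` jointly as one tuple — to the fixed positions by a uniform
permutation over all sites genome-wide. Shuffling the tuple jointly keeps
every site internally consistent (`h` and `π` are functions of the same
genotypes as `p`); only the spatial clustering that windows detect is
destroyed. Shuffling is genome-wide rather than per-chromosome because a
single global null mean and SD are used for all windows. Both choices are
interpretations of an under-specified step, made once and fixed.

With K replicates (default 100; the calibration analyses here use K = 20)
all scored windows of all replicates are pooled, and `μ_Null`, `σ_Null`
are the pooled mean and sample SD (N−1) per statistic. Observed windows
are scored as `Z = (x − μ_Null)/σ_Null`. If `σ_Null = 0` every permuted
window was identical — the input carries no usable signal — and the scan
aborts rather than emit infinite Z-scores.

**Cutoffs.** A window is a putative sweep when `ZF_ST > 6` or `Z|Δπ| >
3.09`. The |Δπ| cutoff is the one-sided standard-normal quantile at P =
0.001 (`qnorm(0.999) = 3.0902`, rounded); the F_ST statistic produces a
heavier upper tail under the null, so its cutoff is raised to 6. Both
comparisons are strict: a window exactly at a cutoff is not called.

**DSS merging.** Significant windows overlapping by ≥ 1 bp merge
transitively into discrete selective sweeps (DSSs); abutting half-open
intervals (end = start) do not merge. The final call set is the interval
union of the F_ST-derived and |Δπ|-derived DSS lists, re-merged under the
same rule, with per-DSS method flags (`fst`, `dpi`, `both`) and window
counts retained — the two statistics overlap only partially, which is why
the union is taken rather than the intersection.

## Hard filters and site selection

Upstream of the scan, sites are hard-filtered on the caller INFO metrics
with the standard GATK-style thresholds — SNPs removed when QD < 2,
FS > 60, MQ < 40, SOR > 3, MQRankSum < −12.5 or ReadPosRankSum < −8;
indels when QD < 2, FS > 200, SOR > 10, InbreedingCoeff < −0.8 or
ReadPosRankSum < −20. All inequalities are strict (boundary values pass)
and an absent metric never removes a site: callers emit the rank-sum
metrics only where they are defined, and treating absence as failure would
discard valid sites. The scan then keeps bi-allelic SNPs that are
polymorphic across the pooled groups; multi-allelic sites are excluded
outright rather than decomposed.

## The synthetic-data generator

The generator exists so every downstream stage can be validated without
any external data, and its defaults are the fixed study conditions used by
the calibration and recovery analyses: one 10 Mb chromosome, expected SNP
density 0.005/bp (~50,000 sites), two groups of 25 diploids, background
divergence F = 0.05, ancestral frequencies Uniform(0.05, 0.95).

Per site, each group's frequency is a Balding–Nichols draw
`Beta(p(1−F)/F, (1−p)(1−F)/F)` around the ancestral `p` — mean `p`,
variance `F·p(1−p)` — independent across groups and sites. `F = 0` is
accepted as the exact no-drift limit (every group frequency equals `p`),
which the neutrality tests use. Genotypes are independent `Binomial(2,
p_g)` dosages. A sweep interval redraws the target group's frequency with
a larger divergence `F_sweep` and then pushes it deterministically toward
the nearer boundary (`p → p(1−s)` below 0.5, `p → p + s(1−p)` above);
the redraw inflates between-group differentiation and the push removes
within-group heterozygosity, producing both of the scan's signals with two
interpretable knobs. The recovery analyses plant five 200 kb sweeps
(`F_sweep = 0.6`, `s = 0.9`) spaced across the chromosome.

What the generator deliberately does not emulate: linkage (sites are
independent, so LD decays immediately and the permutation null is, if
anything, conservative relative to real linked data, where block
permutations would be needed for exact calibration), recombination maps,
demographic history, and sex-chromosome ploidy. Passing calibration and
recovery on these data therefore shows the machinery is correct and
calibrated for independent sites, not that real-genome FDR equals the
nominal rate. Monomorphic sites that arise in sampling are still written
to the VCF so the selection path is exercised; the VCF also carries
all-passing INFO constants, with a configurable fraction of sites given
exactly one failing metric to exercise the filters.

## Annotation and summaries

SNPs are placed into exclusive location categories with the fixed
precedence coding = splicing > ncRNA > 5'UTR > 3'UTR > intronic >
up/downstream > intergenic (up/downstream = within 1 kb of a transcript
end, splicing = within 2 bp of an intron boundary). Exclusive percentages
require some precedence; this order resolves multi-annotation sites in
favour of the functionally more specific category, matching common
annotator conventions. Coding SNPs are subtyped by strand-aware codon
translation (synonymous / nonsynonymous / stop-gain / stop-loss), with the
most severe call returned when transcripts disagree. Group-specific SNPs
are sites whose alt allele is present in the focal group and absent among
called alleles everywhere else, with a strict p > 0.9 "nearly fixed"
subset.

LD decay is computed as composite r² — the squared Pearson correlation of
unphased dosage vectors — because the package's inputs are unphased;
haplotype-EM r² would require phase the data do not carry. The decay rate
is the midpoint of the first distance bin (default 100 bp bins to 300 kb)
whose mean r² is ≤ 0.2, undefined if never reached. The MAF spectrum
folds frequencies to min(p, 1−p) and uses the three-part partition
[0, 0.005), [0.005, 0.01], (0.01, 0.5]; the middle bin is closed on both
sides so that the rare/common thresholds partition [0, 0.5] exactly.

## Numerical and degenerate-input conventions

All internal intervals are 0-based half-open; VCF positions are converted
on read, BED files pass through unchanged, and GRanges conversion adds 1
to starts. Sites where either group has fewer than two called diploids
are unusable for F_ST and skipped; windows whose component denominator
sums to zero (e.g. all-monomorphic) are undefined and excluded from both
the observed scores and the null pool. Determinism is part of the
contract: every stochastic step (simulation, genotype sampling, INFO
failures, each permutation replicate) derives its seed from the
user-supplied one, and identical inputs plus seeds reproduce outputs
byte-for-byte.

## Problem sizes used in the validation analyses

The packaged calibration and recovery analyses run the full pipeline —
VCF emission, parsing, filtering, scan — on the generator defaults above
with K = 20 permutation replicates and three fixed seeds. At these sizes a
single comparison scores 500 windows from ~50,000 sites and pools 10,000
null windows per statistic, which is ample for stable null moments: the
pooled SD estimate has relative error ~1%, well under the 2% the
calibration bounds assume. The observed false-positive fractions are
around the nominal 0.001 level for Z|Δπ| > 3.09 and zero for ZF_ST > 6,
with neutral DSS genome fractions ~1–2%, and all five planted sweeps are
recovered in each seed.

## Known limitations

- The permutation null assumes exchangeable sites; strong LD in real data
  makes the effective number of independent sites per window smaller than
  the count, so real-data Z-scores are mildly anti-conservative at a given
  cutoff. The high F_ST cutoff absorbs some of this in practice.
- Window π uses SNP-based per-site π over the window length, i.e. it
  assumes invariant sites are truly invariant rather than uncalled.
- The F_ST estimator requires observed heterozygote fractions; on haploid
  or inbred data `h` should be supplied as 0 and the `b`/`c` components
  interpreted accordingly.
- Multi-allelic sites are dropped, not decomposed; comparisons of groups
  with very different sample sizes rely on the estimator's sample-size
  corrections rather than any resampling.
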