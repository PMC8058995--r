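---
title: "Methods: small-RNA miRNA discovery, expression and target validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA miRNA discovery, expression and target validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `mirdevel`, the
choices made where the design was genuinely open, and what the synthetic
data can and cannot demonstrate about real libraries.

## Study design and scope

The package implements the desk-scale analysis of a developmental
small-RNA study: five stages (vegetative juvenile through flower
differentiation), three replicate libraries per stage, a reference
transcriptome carrying the miRNA precursors, a miRBase-style catalogue,
and one pooled degradome library. All computation runs on synthetic data
with recorded ground truth; no external database is contacted.

## Read triage

A raw read is `insert + 3' adapter + read-through`, 50 nt. Trimming
removes the suffix starting at the leftmost match of an adapter prefix of
at least `adapter_min_overlap = 6` nt with at most one mismatch; partial
overlaps at the read's 3' end are allowed down to the same minimum. Reads
whose adapter starts at position 1 are adapter dimers ("adapter only").
The paper trail for the remaining thresholds is thin in this field's
methods sections, so they are explicit parameters: poly-N junk means an
N-fraction above 10% of the insert; low quality means a mean Phred below
20; valid tags are 18–25 nt. Each read receives exactly one label, and the
per-library statistics table asserts that the labels partition the raw
total on every run.

ncRNA/repeat annotation is exact substring matching on both strands
against the contaminant references, with a fixed precedence
(rRNA > tRNA > snoRNA > snRNA > other, then repeats). Exact matching is
bit-reproducible and adequate at desk scale; an aligner with mismatch
tolerance would be the natural replacement at survey scale.

## Hairpin criteria for novel miRNAs

Candidates are excised as ±150 nt windows around transcriptome hits of
unannotated valid tags (the longest plant pre-miRNAs reported in
comparable surveys are just under 200 nt, so 150 + 25 + 150 covers them),
merged when they overlap, folded at their minimum free energy (ViennaRNA
`RNAfold`, 37 °C), and measured on the helix that carries the mature:

* number of base pairs in the stem (≥ 16),
* largest contiguous unpaired run in a single stem bulge (≤ 12 nt),
* largest unpaired run inside the mature region (≤ 4 nt),
* unpaired mature positions, "errors" (≤ 2),
* asymmetric unpaired nucleotides within a single mature-region internal
  loop, "biased errors" (≤ 2),
* the mature must not span the terminal loop.

The stem is traced from the terminal loop outward while pairs remain
directly nested, stopping at multiloop branches and at a 250 nt span so
that long-range pairings of flanking window sequence are not mistaken for
precursor stem. The criterion wording for "biased errors" is ambiguous in
the field's usual phrasing; the reading above (asymmetry of a single
internal loop touching the mature) is isolated in one function so it can
be revised without touching anything else. Two consequences of the
criteria's structure are worth noting: a mature-region bulge larger than
4 nt necessarily also unpairs more than 2 mature positions, and with a
mature of ≥ 18 nt the 16-pair stem minimum cannot be violated in
isolation — so "single-violation" decoys exist only for the stem-bulge and
mature-error criteria, and the mature-bulge decoys carry their inherent
error/bias cascade.

Candidates cut from wide windows are evaluated in two stages: the helix
traced in the window fold is excised with a 10 nt pad and refolded in
isolation, and the verdict is taken from the refold. This follows the
usual excise-and-refold practice and removes most artifacts of flanking
sequence pairing into (or away from) the stem. It does not remove all of
them: occasionally the transcript context genuinely changes the minimum
free-energy structure — flanks can absorb a designed defect into a clean
hairpin, or append a bulged helix to a clean stem — so in-context recovery
of planted hairpins is near, but not always exactly, perfect, while the
same hairpins evaluated as bare precursors are classified perfectly.

## Normalization and differential expression

The reference profile is the per-sequence median copy number over the
"common" sequences (nonzero in every sample). Each library is regressed,
`Log2(sample) = a + b·Log2(reference)`, over the common sequences whose
Log2 difference from the reference lies within 2 units **of the median
difference**, and corrected by inverting the line:
`expected Log2(copy#) = (Log2(obs) − a)/b`. Centering the subset window on
the median difference is a deliberate choice: it makes the rule
scale-invariant, so a library that is a uniform multiple of the reference
fits on its full common set (a 4× library yields exactly a = 2, b = 1 and
recovers the reference), and only sequences deviating from the bulk shift
are excluded. An uncentered window would empty the subset for any global
shift of 2 Log2 units or more. The simpler mean-offset correction (slope
fixed at 1) is available behind `method = "offset"`. Zeros are floored at
a pseudocount of 1 inside the log; positive counts are logged exactly.

Differential expression is the classic fixed-effects one-way ANOVA per
miRNA on the expected Log2 scale, computed by vectorized sums of squares
(thousands of miRNAs per call) and cross-checked in the tests against
`stats::oneway.test(var.equal = TRUE)` to 1e-10. Significance follows the
raw p ≤ 0.05 rule; BH-adjusted q-values are reported alongside but do not
drive the flag. Rows with zero between- and within-group variance get
p = 1 by convention. The omnibus ANOVA is used rather than per-pair
post-hoc tests; with five ordered stages the omnibus question ("does this
miRNA change during development?") is the one the downstream clustering
and network stages consume.

Normalization assumes the majority of sequences are not stage-dependent —
the same assumption every global-scaling method makes. The synthetic
catalogue therefore keeps most miRNAs flat (the ageing-pathway families
miR156/miR166 trend down and miR172/miR159 up, everything else is
overwhelmingly stable); when the DE fraction is pushed far above
realistic levels the per-stage regression tilts and null profiles drift,
which is a property of the method, not of the implementation.

## Degradome categories and duplex scoring

Binding sites are scored with the classic plant penalty scheme: mismatch
1, G:U wobble 0.5, single-nucleotide gap 1, every penalty doubled at
miRNA positions 2–13, sites kept at penalty ≤ 4. At most one gap is
allowed: plant miRNA:target duplexes tolerate a lone bulged nucleotide,
not register shifts — and an unbounded gap budget would let two seed
mismatches be bypassed for less than their intended penalty. Scoring is a
gap-budgeted dynamic program; a brute-force alignment enumerator lives in
the tests as its independent twin.

The expected cleavage position is the transcript nucleotide opposite
miRNA position 10 (from the miRNA 5' end); evidence within ±1 nt
validates a site. Categories follow the standard degradome convention:
4 = exactly one read; 0 = unique transcript maximum; 1 = tied maximum;
2 = above the median of nonzero positions but below the maximum;
3 = more than one read, at or below that median. The nonzero-position
median (zeros excluded) is the documented choice; assignment is total and
exclusive, verified exhaustively against an independent oracle over all
profiles of length ≤ 6 with counts ≤ 3.

## Coexpression network

The network is unsigned, `a_ij = |cor(x_i, x_j)|^β` with β = 12 — unsigned
matches an "undirected weighted" network and is the conventional default.
One consequence is scientific, not numerical: profiles that fall and
profiles that rise across development are perfectly anti-correlated and
therefore share a module in an unsigned network; the synthetic truth
tables record module membership accordingly ("monotone" rather than
separate up/down modules). The topological overlap is
`TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
connectivity `k` the off-diagonal row sums, checked against a triple-loop
oracle to 1e-12. Modules come from average-linkage clustering of
`1 − TOM` with a static cut (height 0.99) and a 10-gene minimum — a static
cut is simpler and reproducible at desk scale, where the dynamic hybrid
cutter's advantages do not bind — followed by merging of modules whose
eigengenes (first principal component of the standardized module
expression, signed to follow the mean profile) correlate above 0.75.
Module colours follow the conventional size-ordered palette (turquoise,
blue, brown, ...). Soft-threshold selection fits `log10 p(k)` against
`log10 k` over 10 connectivity bins and picks the smallest candidate power
reaching R² ≥ 0.8 with negative slope; a near point-mass connectivity
distribution makes that fit vacuous and is treated as trivially
qualifying, and when nothing qualifies the default 12 is returned with a
warning. Enrichment is the upper-tail hypergeometric test against a local
annotation table with BH correction.

## The synthetic-data generator

The generator is first-class, tested code. It emulates: the 5 × 3 library
design; library composition (adapter dimers 1%, poly-N junk 2%,
ncRNA contaminants 10%, low-quality reads 2%, remainder miRNA-derived);
mature lengths concentrated at 21–24 nt with the mode at 24 nt
(enforced abundance-weighted in every stage, after 3' isomiR trimming of
0–2 nt at 80/15/5%); stage trajectories (8-fold geometric decrease or
increase, a mid-peak, or flat); negative-binomial-like overdispersion
(dispersion 0.1) implemented as gamma-weight perturbation followed by a
multinomial over the library's miRNA read total, which keeps composition
fractions exact while the marginals stay overdispersed; hairpin
precursors built as perfect-complement stems with short A/C loops,
embedded verbatim in transcripts and *verified with the package's own
evaluator* before acceptance (decoys are redrawn until exactly the
designed criterion — plus its inherent cascades — is violated); planted
cleavage sites as perfect reverse-complement insertions with degradome
tag abundances arranged to produce each intended category (dominant
peaks, ties, sparse or dense backgrounds); and a Ct table following
`Ct = baseline − log2(expression) + noise` with flat reference genes.

What it does **not** emulate: sequencing error profiles, genomic (versus
transcriptomic) context, isomiR diversity beyond 3' trimming, family
members sharing near-identical matures, partial-complement target sites,
and the compositional complexity of a real degradome. Passing tests on
this generator therefore demonstrate the correctness of the computations
and the recoverability of planted signal under the stated noise — not
performance on real libraries.

Default problem sizes, chosen as comfortable desk-scale conditions: 120
transcripts (0.6–1.5 kb), 40 catalogued miRNAs, 10 planted novel and 10
decoy hairpins, 20,000 reads per library, 12 planted target sites; the
test fixtures use smaller versions of the same design (down to 60
transcripts and 1,500–5,000 reads) and the calibration tests use 2,000
null and 300–500 planted profiles.

## Numerical and degenerate-input conventions

Zero-depth libraries warn and return empty; candidates shorter than the
mature plus a minimal loop are rejected with a reason, not an error; a
normalization fit with fewer than 2 usable points or zero reference
variance falls back to the identity with a warning, and subsets under 10
sequences are flagged; ANOVA rows with no variance at all get p = 1;
correlation distance treats constant profiles as distance 1; module
detection reports unassigned genes as grey.

One degeneracy deserves emphasis because it shapes the tests: at exactly
zero replicate noise, the within-stage variance is zero and the omnibus F
flags *any* systematic residual — rounding, compositional coupling through
the shared library total — as infinitely significant. The zero-noise
round-trip therefore asserts perfect sensitivity plus a clean separation
of planted effect sizes from null drift, while false-positive *rates* are
calibrated where they are meaningful, under noise (type-I error within
[0.035, 0.065] at 2,000 null profiles; power ≥ 0.9 for 4-fold effects at
σ = 0.2). For the same reason null profiles only behave like unassigned
network nodes under noise, and that is where the grey-module behaviour is
asserted.

## Known limitations

Exact-substring matching throughout (catalogue, transcriptome, degradome)
stands in for the BLAST-tier alignment a survey-scale study would use;
multi-mapping tags are counted once per locus (a fractional mode exists);
the static tree cut can split very close modules that the dynamic cutter
would keep; and the hairpin criteria are applied to the single MFE
structure — suboptimal-ensemble evidence is not consulted.
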