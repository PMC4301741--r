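---
title: "Auditing gene-targeted plant lines: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing gene-targeted plant lines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtaudit)
```

# The problem

Gene targeting (GT) modifies an endogenous plant gene by homologous
recombination. Whether a GT line is "clean" is then a molecular question with
three parts: (i) does the genome carry any unintended vector-backbone or
*Agrobacterium*-derived sequence, (ii) how many incidental somaclonal
mutations did tissue culture and regeneration introduce, and (iii) what might
those mutations do to genes. `gtaudit` implements the corresponding analysis
chain — CAPS genotyping of the targeted locus, read-based screening for
exogenous sequence, tiling-array CGH, depth/quality variant auditing with a
Mendelian back-estimation of the T0 mutation load, mutation-spectrum
summaries, and snpEff-style effect classification — together with a seeded
synthetic-data generator that reproduces the statistical structure of the
study design, so every stage is testable without any external data.

The package follows the design of a four-line study: two T2 sibling lines
descended from one regenerated T0 plant (one carrying a randomly integrated
GT vector homozygously, one heterozygously) and two independent, clean T3
lines.

# The selfing fixation model and the T0 estimator

A somaclonal mutation arises in the regenerated T0 plant as a heterozygous
site. Under self-fertilization each heterozygous site segregates per
generation as 1/4 homozygous mutant : 1/2 heterozygous : 1/4 homozygous wild
type, with the homozygous states absorbing. After $g$ generations

$$p_\text{hom}(g) = \frac{1 - 2^{-g}}{2}, \qquad p_\text{het}(g) = 2^{-g},$$

so a T3 plant ($g = 3$) retains 43.75% of its T0 mutations as homozygous and
12.5% as heterozygous sites. Heterozygous calls at modest sequencing depth
are unreliable (both alleles must be sampled and pass thresholds), so the
load estimate is anchored on homozygous calls only:

$$\hat N_{T0} = \frac{\text{raw homozygous count}}
{f \cdot p_\text{hom}(g)},$$

where $f$ is the fraction of the genome callable in *all* compared lines at
the chosen stringency — homozygous variants outside that region are
invisible, and dividing by $f$ undoes the thinning. Inside the
shared-callable region a homozygous variant passes the same filter that
defined the region, so the estimator is unbiased by construction; the
round-trip property tests verify recovery of a planted load within 2% on
average.

Two arithmetic conventions matter for reproducing published tables and are
therefore fixed in code:

* all intermediate arithmetic is unrounded; rounding (half away from zero)
  happens once, at presentation. Totals are sums of unrounded per-class
  estimates — rounding per class first and summing gives visibly different
  totals (e.g. 224 + 75 = 299 where the unrounded total rounds to 298);
* sibling lines estimate the same T0 quantity, so their unrounded estimates
  are averaged and rounded once.

Uncertainty is reported as a parametric bootstrap: the observed homozygous
count is re-drawn Poisson 200 times and re-inverted, giving a percentile
interval. A nonparametric resample of the called variants cannot vary a
plain count, which is why the Poisson model of the count is used.

# Variant audit

Calls carry the supporting-read count as depth and a quality score. Two
named filter profiles mirror common stringencies: `DP2Q10` (depth ≥ 2,
quality ≥ 10) and `DP4Q20` (depth ≥ 4, quality ≥ 20). Filtering is monotone:
the stricter profile's survivors are always a subset.

Background polymorphisms — differences between the laboratory stock and the
reference assembly — are present in every line, so a variant carried by two
or more lines whose carrier set is not confined to one sibling group is
subtracted as a polymorphism. The carrier threshold reads "two or more":
under the alternative reading ("more than two") the sibling-pair exception
would be vacuous, since any variant in exactly the two siblings would
already survive. Sibling lines inherit the same T0 mutations, so variants
confined to one sibling group remain candidates. The threshold is an
argument (`min_carriers`, default 2).

Whether to subtract shared variants before or after restricting to the
shared-callable region is not dictated by the method; this package subtracts
first and restricts second (`subtract_first = TRUE`), because a polymorphism
is evidence of common origin wherever it was seen. The converse order is one
flag away and, on noise-free synthetic data, yields the same line-specific
sets.

Substitutions are collapsed onto six strand-symmetric classes (AT→GC, GC→AT,
AT→CG, AT→TA, GC→CG, GC→TA); the first two are transitions. Ti/Tv is
reported per line to two decimals, and the cross-line average is the mean of
the *pre-rounded* per-line ratios, reported to three decimals — averaging
unrounded ratios differs in the third decimal (1.114 vs 1.115 on the
reference worked example), and the pre-rounding convention is the one that
reproduces published averages of published two-decimal ratios.

# Effect classification

Variants are classified against single-transcript gene models into sixteen
categories, one record per variant × nearby transcript (records can exceed
variants; percentages are of records, to two decimals). Within a transcript
the precedence is splice site (within 2 bp of an intron boundary) → CDS →
UTR → intron → exon. CDS SNPs are translated codon-locally with the standard
code: a damaged initiator ATG is `START_LOST`, a new stop `STOP_GAINED`,
otherwise synonymous/non-synonymous. CDS indels are `FRAME_SHIFT` unless
their length is a multiple of three; in-frame deletions become
`CODON_CHANGE_PLUS_CODON_DELETION`; in-frame insertions are not a
represented category and are tallied as `EXON` with a warning. A 5'UTR SNP
creating a new ATG upstream of the annotated start (within the UTR interval)
is `START_GAINED`. The upstream/downstream windows default to 5,000 bp, the
conventional annotation-tool default. Eight categories (frameshift through
splice donor) count as "protein-affecting".

The test suite checks this classifier position-by-position against an
independently written oracle that mutates the genome, re-extracts the whole
CDS or UTR, and compares full translated proteins — a deliberately different
route to the same answer — and asserts strand symmetry: reverse-complementing
genome, models and variants leaves every category call unchanged.

# Exogenous-sequence screen

Read mapping is replaced, at desk scale, by exact matching of unique
k-mers: a read hits a reference if it shares, on either strand, a 31-mer
that occurs in that reference and nowhere in the host genome (uniqueness
standing in for a mapping-quality filter). Coverage accumulates over the
reference spans of matched k-mers. The verdict is "present" when hit reads
≥ 3 and covered fraction ≥ 1%. Reads are first quality-trimmed at both ends
and discarded below 20 bp, mirroring standard short-read QC. The generator
guarantees the vector shares no 31-mer with the host, so the specificity
property (0 false detections in 100 host-only simulations at error rate
0.001) holds by construction plus the astronomically small chance of an
error-created unique 31-mer; sensitivity at 10× coverage of a heterozygous
carrier is 100/100 simulations.

# Tiling-array CGH

Probes are 60-mers: host tiles every 60 bp on one strand, vector tiles every
5 bp on both strands, plus 13 control probes. The signal model is linear in
copy number with a small additive background $b$ (default 0.02 of one copy)
and multiplicative log-normal noise ($\sigma = 0.1$):
$I = a\,(c + b)\,e^{\varepsilon}$. The background keeps zero-copy ratios
finite and makes a homozygous insertion double a heterozygous one on the
ratio scale: $(2+b)/(1+b) \approx 1.98$.

Normalization divides each channel by its control-probe median and then
re-centers log2 ratios on the median of the copy-neutral host probes
(centralization). The second step matters: thirteen control probes leave a
residual channel-gain offset of a few percent that does not average out with
more probes and would blur the homozygous-vs-heterozygous comparison; the
host-probe bulk pins the neutral level far more precisely.

Smoothing is a centered moving average over 1/5/10/20 probes (60 bp – 1.2 kb)
with windows truncated at the track ends. Note that no row-stochastic
centered smoother with truncated edge windows can conserve the track mean
exactly (edge columns of the weight matrix do not sum to one); mean
conservation holds exactly for constant tracks and for tracks supported away
from the edges, and the property tests assert those plus equality with a
brute-force reimplementation.

Aberrant intervals are maximal same-sign runs above a fuzzy-zero floor
(default 0.3 log2 units) with at least 5 probes and an interval score
$|\bar x|\sqrt{n} / \mathrm{MAD}(\text{track}) \ge 4$ — a fully specified
stand-in for proprietary segmentation software, chosen because it reproduces
the qualitative carrier/non-carrier separation. The floor default is 0.3: a
floor of 3 log2 units would exceed the amplitude of any one-copy event and
is accepted only as an explicit override. Host-genome copy states follow the
standard log2 reading (+0.6 one-copy gain, ≥ +1 two-copy gain, −1 one-copy
loss, ≤ −2 two-copy loss, ±0.2 bands); vector-probe zygosity is called from
the log2 difference between two carrier lines (1.0 ± 0.3 → homozygous vs
heterozygous).

# CAPS genotyping

The targeted-locus assay is modeled exactly: exact-match primers extract a
2,287 bp amplicon; MfeI (C^AATTG, palindromic) cuts after the leading C; the
GT allele carries two codon edits (TGG→TTG and AGT→ATT) that each create one
recognition site, resolving the amplicon into 1,751 + 299 + 237 bp, while
the wild-type amplicon is uncut. A diploid sample shows the union of its two
allelic patterns (cut-only, uncut-only, or both → homozygous GT, WT,
heterozygous). The real locus sequence is not distributed; the fixture
generator is labelled synthetic and places the edits so the published
fragment lengths emerge, with the fragment *multiset* (not orientation) as
the asserted quantity.

# Ranked partial validation

When only part of a quality-ranked candidate list is re-sequenced, the
estimate of truly existing variants is taken from the confirmed/failed
boundary: with failures present, every candidate from the lowest-ranked
failure down is discounted (estimate = lowest failed rank − 1); if outcomes
are rank-inconsistent the boundary falls back to the lowest-ranked
confirmation; with no failures the full list stands. This single rule
reproduces both canonical worked cases (39 of 45 homozygous candidates with
the bottom 6 of 12 validated failing; 13 of 121 heterozygous candidates with
35 of the 48 validated failing) and is monotone in the number of bottom-block
failures, bounded by [confirmed count, n].

# The synthetic generator: what it emulates, and what it does not

Defaults are the study conditions: four lines as above, 500 induced
mutations per T0 plant, 300 background polymorphisms (homozygous-alternate
in all lines), GC content 0.44, 76-base reads, per-line depth means 8/4/6/10
(the per-line depth-distribution peaks), spectrum weights from the pooled
observed homozygous-SNP spectrum with a 34% indel fraction, CGH background
fraction 0.02 and noise 0.1. The host genome is scaled to 100 kb with 20
gene models — the package's chosen desk-scale problem size; on it the full
pipeline runs in seconds while every estimator sees hundreds of variants.
The resulting mutation density (~5 × 10⁻³/bp) is therefore about 5,000-fold
the real per-base rate; nothing in the analysis depends on density except
through counts, which are matched.

Per-call quality is `round(3 × supporting reads)` capped at 60 — a monotone
proxy, sufficient because the audit only thresholds at 10/20. One visible
consequence: "quality ≥ 20" translates to ≥ 7 supporting reads, so at depth
peaks of 4–10× the DP4Q20-consistent shared-callable fraction collapses to a
few percent of the genome and DP4Q20 estimates on the simulation are noisy
(real callers' quality scores do not scale this sharply with depth, and the
published DP4Q20 shared fraction was 46%). The DP2Q10 route is the one used
for parameter-recovery claims. Also not emulated: mapping ambiguity,
realistic base-error profiles, structural variants beyond one clean vector
insertion, and multi-allelic sites. Passing tests therefore demonstrate the
correctness of the estimators and decision rules under the stated model, not
the behavior of any particular caller on real reads.

Callable masks are profile-aware: a position is callable when its depth
would let a homozygous call pass the profile
(`depth ≥ max(min_depth, ceiling(min_quality/3))`, with plain depth ≥ 1 as
the profile-free default). This keeps the coverage correction consistent
with the filter — the property the estimator's unbiasedness rests on — and
mirrors the fact that stricter filters shrink the shared-callable region.

# Numerical and interface conventions

* Intervals are 1-based and closed in memory (the IRanges convention);
  files follow their own contracts — VCF and GFF3 1-based, BED 0-based
  half-open — via Biostrings, vcfR and rtracklayer.
* Rounding is half away from zero everywhere a table value is presented;
  no true .5 ties arise from the ratios involved, but the rule is fixed.
* Every generator and the pipeline draw all randomness from explicit seeds;
  a repeated run is byte-identical. Degenerate inputs fail loudly: zero
  control medians, empty reference panels, g = 0 back-estimation (no
  information in homozygous counts), infeasible gene packing.
* Zero transversions make Ti/Tv undefined (NA), never infinite.

# Reproducing the analysis

The `analysis/` directory holds six numbered drivers (simulate, CAPS,
screen, CGH, variant audit, mutation load) that run the full chain on the
default synthetic study and write TSV tables under `results/`;
`scripts/acceptance.R` recomputes the headline closed-form quantities and
writes them as JSON. Both operate on the installed package and a single
`--seed`.
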