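---
title: "Methods and design notes for camtakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for camtakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtakit)
```

This vignette documents the models behind each stage of `camtakit`, the
tunable parameters and their defaults, what the synthetic-data generators do
and do not emulate, and the design choices made where the methodology was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## Domain scanning and family classification

CAMTA proteins are recognised from five sequence features. Two patterns are
the field's published consensus motifs: the IQ motif `IQXXXRGXXXR` and the
cotton calmodulin-binding domain
`WXVX(2)[LVI]XKX(2)[L][R][W][R]X[KR]X(3)[FL][R]X`, in the standard compact
notation (`X` any residue, `[...]` a residue class, `(k)` a repeat of the
preceding element). The CG-1, TIG and ankyrin detectors are *bundled seed
patterns in the same notation*, standing in for the Pfam profile HMMs that a
genome-scale study would use: profile databases and HMMER are outside this
package's scope, and deterministic consensus patterns are fully
oracle-checkable. The seeds were designed so that the synthetic generator's
planted domains are found with zero false negatives; they are **not**
calibrated for sensitivity on real proteomes, and a user scanning real
sequences should treat CG-1/TIG/ANK hits as provisional. The bipartite NLS
rule — two clusters of ≥ 2 basic residues (K/R) separated by a 9–12 residue
linker — is an approximation the package states as such; the CG-1 seed embeds
a compatible cluster pair so the rule can be exercised inside a CG-1 span.

Classification: a protein `is_camta` when it has a CG-1 hit plus at least one
calmodulin-binding feature (IQ or CaMBD); a CAMTA without a TIG hit is
`non-TIG`. Scanning is non-overlapping left-to-right; hit coordinates are
1-based inclusive and always equal the reported matched text.

Protein properties use one bundled average-residue-mass table (plus one
water, 18.015 Da) and one bundled pKa set (N/C termini 8.6/3.6; K 10.8,
R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1). The isoelectric point is the
bisection root of the Henderson–Hasselbalch net charge, to |charge| < 1e-4;
the charge is strictly decreasing in pH, so the root is unique. Different
servers bundle different pKa sets, so digit-level agreement with any
particular published pI column is *not* promised — correctness is defined by
the charge-root condition, which the tests verify directly.

The hydrophobic moment is μH = |Σₙ hₙ·e^{inδ}|/N on the Eisenberg consensus
scale with δ = 100° per residue (α-helix) and an 18-residue default window,
matching the length of the calmodulin-binding helix analysed in cotton
CAMTAs. A window is called amphipathic at μH ≥ 0.2; the literature gives no
universal cutoff and 0.2 separates the package's planted helices from
homopolymer controls.

## Alignment, paralogy and Ka/Ks

Global alignment is Needleman–Wunsch under BLOSUM62 with affine gaps
(open 10, extend 0.5; a gap of length L costs open + L·extend), provided by
Biostrings behind the package's interface and verified against a brute-force
enumeration oracle on short sequences. Three statistics are defined on the
alignment: *coverage* = both-aligned columns as % of the longer input,
*identity* = % of both-aligned columns identical, and *similarity* = % of
both-aligned columns with a positive BLOSUM62 score. Paralogs require
coverage > 70 **and** similarity > 70 (strict inequalities, per the published
rule); "similarity" has no published formula, so the positive-score
definition is the package's documented choice, switchable to identity.
Ortholog detection is reciprocal-best-hit by alignment score, with ties
yielding no pair (recorded rather than silently resolved).

Ka/Ks is the Nei–Gojobori (1986) counting method:

* synonymous site fractions per codon position, computed per sequence and
  averaged over the two sequences; mutations *to* stop codons count as
  non-synonymous;
* codons differing at > 1 position average their difference counts over all
  orderings of the changes, excluding pathways through stop intermediates and
  re-weighting the remainder equally (all orderings are used if every pathway
  is blocked);
* Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)p) applied to pn and ps
  separately; p ≥ 3/4 makes that rate undefined (never silently clamped).

N + S = 3 × codons holds to 1e-9 on every input, and the whole estimator is
checked codon-by-codon against an independent enumeration oracle. Selection
labels use a ±0.05 neutral band around Ka/Ks = 1, since exact equality never
occurs in floating point. Duplication dates are T = Ks/(2λ) with
λ = 1.5×10⁻⁸ synonymous substitutions/site/year (the cotton clock),
reported in MYA and rounded to 2 decimals in reports. Two published dates
(15.03, 13.04) appear truncated rather than rounded (0.4511 and 0.3914 give
15.037 and 13.047); the package rounds half-up and documents the 0.01
discrepancy instead of guessing the original rule. Duplication typing:
tandem requires same chromosome and an inter-gene gap ≤ 100 kb
(configurable); different chromosomes are always segmental — the direction
the published analysis actually uses, which is window-independent.

The distance tree is standard neighbor joining (exact on additive matrices,
which the tests exploit over random 4–8-taxon trees), with negative branch
estimates clamped to zero and flagged, and bootstrap support from resampling
alignment columns of p-distances. It is a desk-scale stand-in for ML
phylogenetics, adequate for family grouping but not for publication trees.

## Co-expression networks

Expression is log2(FPKM + 1) transformed (pseudocount 1 so zero FPKM maps to
zero; configurable) before Pearson correlation of every gene with a focal
gene across developmental stages. Thresholds are inclusive: r ≥ 0.95 joins
the positive set, r ≤ −0.95 the negative set. Zero-variance genes have
undefined correlation and are excluded and logged. With only five stages,
|r| ≥ 0.95 is a weak statistical filter — the chance rate for an unrelated
gene is about 1.3% — so the package reports n and leaves significance to the
user. Stage summaries are medians and quartiles with the
linear-interpolation percentile convention (R type 7); the published figures
name quartiles without a convention.

## Promoter motif enrichment

Promoters are the 1000 bases immediately upstream of the gene start
(plus strand) or the reverse complement of the 1000 bases immediately
downstream of the gene end (minus strand), truncated and flagged at
chromosome edges. IUPAC motifs (defaults `MCGCGB`, `MCGTGT`) are scanned
with all overlapping positions counted, on both strands by default
(cis-elements are double-stranded; the source analysis is silent), with
coordinates hit by several motifs deduplicated and `N` never matching.

The enrichment statistic is the *fraction of promoters with ≥ 1 match*
(presence/absence). The published frequencies 0.29–0.41 are consistent with
fractions but the statistic is never defined there — this is the package's
largest judgment call, and a matches-per-promoter mode is provided behind a
flag. Significance is a two-sided Fisher's exact test (hypergeometric
summation, verified exhaustively against a `choose()`-based enumeration
oracle for all tables with row margins ≤ 30) against a seeded uniform random
control of 700 genes drawn from the non-co-expressed complement. The sample
odds ratio adds 0.5 to all cells only when some cell is zero.

## qRT-PCR and trait correlation

2^−ΔΔCt quantification averages technical replicates on the Ct scale before
the exponential transform (the replicate structure is published, the
averaging order is not; biological replicates are summarised after
transformation). The 1/ΔCt expression proxy is implemented literally,
including its sign flip for negative ΔCt, which triggers a warning — fidelity
to the published axis definition over numerical niceness. Trait scans report
Pearson r with two-sided p from t = r·√((n−2)/(1−r²)), pairwise-complete per
trait with n reported, and no multiplicity correction across the six traits
(matching the source analysis; Benjamini–Hochberg is available but off).

## What the synthetic generators emulate — and what they do not

All generators are deterministic given (config, seed) and never touch the
global RNG state.

* **Genomes** place multi-exon genes (11–14 exons, matching the 10–15 intron
  range of real cotton CAMTAs) on one chromosome with 1000-bp clean flanks;
  planted proteins concatenate sampled consensus instances in the canonical
  CG-1–TIG–ANK–IQ–CaMBD order with non-basic linkers. CDS are uniform
  synonymous reverse translations, so translation round-trips exactly. Not
  emulated: repeats/transposons, codon-usage bias, UTRs, alternative splicing.
* **Codon-pair divergence** gives each of two descendant lineages half the
  target divergence as per-position Poisson event counts at the ancestor's
  NG86 site fractions, with jump-chain moves inside the synonymous or
  non-synonymous (non-stop) alternative sets; stop-creating proposals are
  rejected and redrawn. Freezing site classes on the ancestor causes a small
  downward bias at extreme rates (codon context drifts); at the tested
  Ka = 0.1 / Ks = 0.4 over 30-kb ancestors the mean estimates land within
  ~1% of target, well inside the ±10% acceptance band. With `target_ka = 0`
  every event preserves the amino acid, so descendant translations equal the
  ancestor's exactly.
* **Promoter sets** plant exactly `round(n · planted_fraction)` single motif
  instances into i.i.d. background with a symmetric GC split; labels record
  planting, not total matches. Note that i.i.d. background at a realistic
  genomic GC of 0.35 produces ~0.7 expected chance presence per kilobase —
  far more than real promoters show (the published control frequency is 0.29
  per kilobase) because real sequence is not i.i.d. The Fisher power
  analysis therefore uses the alphabet-exclusion background (gc = 0; both
  motifs require G/C), making observed presence frequencies equal the
  planted 0.41 vs 0.29 — the published contrast. A green power test
  establishes the test machinery's sensitivity at that contrast, not that
  real cotton promoters would reproduce it.
* **Expression matrices** plant modules as affine transforms of the focal
  profile *on the log2(FPKM+1) scale* — the scale the network is built on —
  so noise-free module correlations are exactly ±1 through the full
  pipeline. Module recovery (F1 ≥ 0.9) is assessed as a mean over replicate
  seeds because the 5-stage chance-hit rate makes single-run F1 noisy. The
  affine-module model is an assumption; no distributional description of
  fiber-stage FPKM is available, and background genes are simply independent
  log-normals.
* **Trait tables** draw ΔCt from a truncated Normal(8, 1.5) (≥ 2) and blend
  the standardized 1/ΔCt proxy with independent noise to hit the target
  population correlation (0.63 by default, the published fiber-strength
  effect size), scaled to fiber-strength-like units. At |r| = 1 the sample
  correlation is exactly ±1; otherwise it converges at the usual √n rate.

## Numerical conventions

Rounding in reports: Ka/Ks ratios to 4 decimals, dates to 2 — the published
precision. Degenerate inputs: empty sequences, zero-variance profiles,
zero-total Fisher tables, missing chromosomes and infeasible genome packing
all raise explicit errors naming the offender; saturated Jukes–Cantor
proportions return NA with selection `undefined`. Ties in reciprocal-best-hit
scoring (within 1e-9) produce no pair. NJ ties in the Q matrix resolve to
the first minimum, making topologies deterministic. All derived seeds stay
below 2³¹.

## Known limitations

No profile-HMM or PWM scanning; no ML phylogenetics or codon-model (codeml)
Ka/Ks; no genome-wide synteny, so segmental calls rest on the
different-chromosome criterion alone; the NLS rule and CG-1/TIG/ANK seeds are
package constructs; enrichment assumes promoter independence; and published
headline counts that require the cotton genome assemblies, SRA expression
data and unpublished phenotype tables are out of reach at desk scale — the
test suite substitutes planted-truth recovery at the published effect sizes.
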