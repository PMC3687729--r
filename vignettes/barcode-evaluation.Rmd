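---
title: "Evaluating ITS2 and psbA-trnH barcodes for Flos Lonicerae Japonicae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ITS2 and psbA-trnH barcodes for Flos Lonicerae Japonicae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lonibarcode)
```

## The problem

Flos Lonicerae Japonicae — the dried flower bud of *Lonicera japonica*
— is routinely adulterated with the flowers of six congeners that look
alike after drying but differ in price and pharmacopoeial status.
Distance-based DNA barcoding identifies a specimen by comparing a short
standardized sequence (here the nuclear ribosomal ITS2 spacer or the
chloroplast *psbA-trnH* spacer) against a reference panel. A barcode
works when conspecific divergence is small, heterospecific divergence is
larger, and the two distributions do not overlap (the *barcoding gap*);
identification then reduces to assigning each query the species of its
best-scoring hit.

This package implements that evaluation end to end and ships a
synthetic-panel generator so the whole pipeline is testable without any
sequence downloads.

## The synthetic panels

The generator does not attempt to reconstruct the deposited nucleotide
strings; it reproduces the *summary structure* the evaluation actually
consumes, which is fully determined by the voucher tables:

* **ITS2**: 53 records, 7 species. *L. japonica* contributes 32 records
  in two haplotypes (A1×4, A2×28, of which 8 are public-database
  records realized as ordinary A2 members) that differ only by a C/T
  transition at base 27. The six congeners carry one haplotype each
  (B1×5, B2×5, B3×2, B4×2, B5×5, B6×2). The ancestor is 228 bp at GC
  75.4%; 14 distinct positions are substituted across all haplotypes
  and one haplotype carries a 1-bp insertion, so lengths are 228–229 bp.
* ***psbA-trnH***: 45 records, 7 species; *L. japonica* is a single
  invariant 339 bp haplotype (24 records), 10 positions vary among all
  taxa, and per-haplotype indels spread realized lengths over
  332–356 bp. Ancestor GC is 29.5%.

Choices the voucher tables do not pin down are fixed once and
documented here:

* **Positions of the interspecific variable sites.** ITS2 uses 13
  evenly spread positions (40, 55, …, 220) besides base 27; *psbA-trnH*
  uses 10 (30, 55, …, 255). Spreading them keeps each site in a
  distinct alignment column even near the indels.
* **Per-haplotype substitution subsets.** Each congener substitutes a
  subset of those positions, chosen so the focal interspecific K2P
  distance averages ≈ 0.029 (realistic for congeneric ITS2 and close to
  the published 0.0331) while the closest heterospecific pair (B3 vs
  B4) differs at 2 sites — still above the maximal conspecific
  divergence of 1 site, so the barcoding gap survives. For
  *psbA-trnH* the minimal heterospecific pair likewise differs at 2
  sites (≈ 0.0060 in K2P terms).
* **All substitutions are transitions.** The ancestor base at every
  edited position is pinned (by composition-preserving swaps) to the
  transition partner of the target base, so `Q = 0` in every pairwise
  comparison and small-distance arithmetic is exact and predictable.
* **Indel carriers.** The tables do not say which taxon carries the
  229 bp ITS2 variant; it is assigned to *L. acuminata* (B6). The
  *psbA-trnH* per-species lengths within 332–356 bp are likewise
  unstated; the defaults use one indel per congener (−7, −3, +5, −1,
  +10, +17 bp) placed downstream of all substituted sites.
* **Seeds.** A spec carries one master seed; the ancestor draw uses it
  directly and indel fill bases use master + 1, so a spec realizes to a
  byte-identical panel every time and the RNG state of the calling
  session is never disturbed.

What the generator deliberately does *not* emulate: sequencing noise,
ambiguity codes, intragenomic ITS2 copy variants, alignment-hostile
repeat regions, and real ITS2 secondary-structure constraints. Tests
that pass on these panels therefore demonstrate the correctness of the
*computations* under the study's structure, not robustness of barcoding
to messy field data.

## Alignment

Panels this homogeneous (divergence ≤ ~5%, at most one indel event per
sequence pair) are aligned by a *star* strategy: every sequence is
globally aligned to the longest sequence (affine gap penalties; match
+2, mismatch −3, gap open −5, gap extend −2, configurable) and the
pairwise alignments are merged on reference coordinates, padding where
other rows inserted ("once a gap, always a gap"). Each row's induced
pairwise alignment to the reference is score-optimal — an invariant the
test suite checks directly — and the merge is deterministic. Optimal
pairwise alignments themselves are computed by `Biostrings`
(`pairwiseAlignment`), whose traceback is deterministic; tie-breaking
among co-optimal paths follows that implementation. A general
progressive aligner would be required for divergent inputs, which are
out of scope.

A column counts as *variable* when at least two distinct unambiguous
bases occur among the chosen rows; gap-only disagreement does not
count, and indel events are reported separately. Applied to the default
panels this recovers exactly 14 + 1 (ITS2: sites + indel) and 10
(*psbA-trnH*), matching how the published counts separate substitutions
from the insertion/deletion event.

## Distances

The Kimura 2-parameter distance is

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q), $$

with $P$ and $Q$ the transition (A↔G, C↔T) and transversion proportions
over compared sites. Sites where either sequence has a gap or an IUPAC
ambiguity code are excluded pair by pair (*pairwise deletion*), the
usual choice for barcode panels where a single indel would otherwise
discard a column for everyone. Saturation ($1-2P-Q \le 0$ or
$1-2Q \le 0$) raises an error naming the pair rather than returning
`NaN`. The matrix implementation is a vectorized indicator-matrix
formulation; tests verify it against per-pair recomputation and against
`ape::dist.dna(model = "K80", pairwise.deletion = TRUE)` as an
independent implementation.

One transition among 228 compared sites gives
$d = -\tfrac12\ln(1 - 2/228) = 0.0044$ — the maximal conspecific ITS2
distance — and averaging over the $4 \times 28 = 112$ cross-haplotype
pairs among $\binom{32}{2} = 496$ conspecific pairs gives
$112 \cdot 0.0044 / 496 = 0.0010$, reproducing the published
intraspecific mean exactly.

## Divergence metrics and conventions

`six_metrics()` reports, each as mean ± sample SD of the listed values:
all intra- and all interspecific distance, theta (per-species mean
conspecific distance, averaged over species), coalescent depth
(per-species *maximum* conspecific distance, averaged), theta prime
(per-species-pair mean heterospecific distance, averaged), and the
minimum interspecific distance (per-species minimum to any
heterospecific record, averaged).

Two conventions are genuinely open and both are implemented:

* The *all intra* / *all inter* rows default to the **focal-species
  convention** (focal = *L. japonica*), i.e. conspecific pairs of the
  focal species and focal-vs-other pairs. This is the reading under
  which the published intraspecific means (0.0010 ITS2 / 0.0000
  *psbA-trnH*) are reproduced exactly, and it matches framing the
  divergence question as "the focal medicinal species against its
  adulterants". A `convention = "global"` mode pools all species
  instead.
* The *minimum interspecific distance* defaults to the mean of
  per-species minima — a single global minimum would have zero spread,
  whereas a nonzero spread is meaningful only when averaging over
  species. `gap_exists()` always uses the global extremes, since the
  gap criterion compares distributions.

Theta and coalescent depth computed under the standard definitions
above give ≈ 0.0001 and ≈ 0.0006 on the default ITS2 panel; these
definitions cannot be reconciled with every published summary cell
under any averaging we tried, so the package states its definitions
precisely and makes no further claim for those two quantities. Species
with a single record have undefined conspecific divergence and are
excluded from theta/coalescent depth with a warning.

`gap_histogram()` bins conspecific and heterospecific distances into
half-open classes $[kw, (k+1)w)$ of width $w = 0.010$ by default, the
class width conventional in barcoding-gap figures.

## Identification

`loo_efficiency()` is the BLAST1 assignment rule in a closed reference
set: each record is removed, queried against the rest, and assigned the
species of its top-ranked hit. Ranking uses Smith–Waterman local
alignment scores (same scheme as above) — raw scores suffice in a
closed set, so no E-values are computed and no external search binary
is involved. A top-score tie spanning more than one species is counted
as a failure: a conservative policy, and the only one consistent with a
reported 100% efficiency. A `mode = "k2p"` nearest-neighbor variant is
provided; tests require both modes to agree on the default panels.
Records of species with a lone member cannot be identified correctly by
construction and are excluded from the denominator with a warning.

When a barcoding gap exists, every query's nearest neighbor is
conspecific, so efficiency is necessarily 100% in k2p mode — a
cross-module invariant the tests assert.

## Trees

`nj()` is classic neighbor joining: at each step the pair minimizing
$Q_{ij} = (m-2)d_{ij} - r_i - r_j$ is joined, with the standard
branch-length and distance-update formulas. Ties in $Q$ (common here,
where many sequences are identical) are broken deterministically by the
first minimal pair in column-major scan order. Negative branch lengths,
a known artifact of NJ on non-additive data, are clamped to zero with
the deficit transferred to the sister branch so the pair's total length
decomposition is preserved. Trees are returned as unrooted `ape::phylo`
objects with an arbitrary basal trifurcation; display rooting is
presentation, not inference, and is left to the user. On additive
matrices NJ is exact, which the tests exploit: distances generated from
random trees (n ≤ 8) are recovered with identical topology and path
lengths, and the topology agrees with `ape::nj()` as an independent
implementation.

`bootstrap_support()` resamples alignment *columns* with replacement
(gap columns like any other), rebuilds the K2P matrix and NJ tree per
replicate, and scores each original bipartition by the percentage of
replicates containing it (tallied with `ape::prop.clades`,
bipartition-wise). Supports below the conventional 50% display cutoff
are retained in `node.label`, not blanked — filtering is a display
decision. `is_monophyletic()` tests whether some edge bipartition
isolates exactly one species' leaves; single-leaf species are
monophyletic by convention.

## Problem sizes and numerical choices

The default panels (53 and 45 records, ≤ 371 alignment columns) run the
full pipeline in seconds; the test suite uses 10–100 bootstrap
replicates and the worked examples 1000, a tree-figure convention.
Distances are kept at full double precision internally and rounded to
four decimals only in reports; GC is reported to one decimal percent.
The histogram uses half-open bins so boundary values are counted once.
Metadata is TSV rather than CSV so locality strings may contain commas.
IUPAC ambiguity codes are accepted on input and excluded from distance
and variable-site computations; the alignment scorer itself requires
plain A/C/G/T, which the generator always produces.

## Limitations

* The star alignment assumes near-identical panels; it is not a general
  MSA and is not suitable for divergent loci.
* Only the K2P model is provided, matching the evaluation it
  implements; no JC69/HKY/GTR, no maximum-likelihood or Bayesian trees.
* The synthetic panels encode the published haplotype structure, not
  the real deposited sequences; quantities that depend on the actual
  nucleotide strings of the congeners (e.g. the exact interspecific
  means) are emulated only to realistic magnitude.
* BLAST1 is re-implemented as an assignment rule; word-size heuristics
  and E-value statistics of a database search are intentionally absent.
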