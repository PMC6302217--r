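---
title: "Methods: CRISPR mining, binning and phage comparison in thermavir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRISPR mining, binning and phage comparison in thermavir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermavir)
```

## Scope and model

thermavir reconstructs the virus-facing layer of a hot-spring
metagenome analysis from assembled contigs: CRISPR repeat–spacer
arrays (the molecular record of past phage infection), genome bins for
candidate phage hosts, taxonomy and best-hit screens over homology
tables, and comparative genomics of reconstructed phage genomes.
Because the real deposited metagenomes are far beyond desk scale, the
package pairs every stage with a synthetic-community generator that
plants known features and writes a ground-truth manifest; all recovery
claims made by the test suite are claims about those synthetic
conditions.

## CRISPR array detection

A CRISPR array is modelled as `copies` near-identical direct repeats
of one length, separated by independent spacers. Two detectors are run
independently and only loci they agree on are retained, mirroring the
two-predictor consensus design used in environmental CRISPR surveys:

* **Seed-and-extend** (`detect_arrays_seed`): exact 8-mers recurring at
  an offset compatible with one repeat plus one spacer (41–108 nt under
  the defaults) seed an X-drop extension (+1 match, −2 mismatch,
  drop-off 4) to a maximal repeat unit; further copies are chained in
  both directions by gapless identity (≥ 0.7) within the spacer-length
  window.
* **Periodic self-similarity** (`detect_arrays_periodic`): for each lag
  in the period range, the sequence is compared against its own
  translate; windowed match fractions (window 70 nt) above 0.5 call
  candidate regions, and matching runs at the best lag locate copies.
  Homopolymers and short tandems would score highly at *every* lag, so
  regions with ≥ 0.6 self-match at any lag below the minimum period are
  rejected.

Both detectors share a refinement stage that the naive copy calls
need: candidate starts are realigned gaplessly to a medoid reference
copy and then to the running consensus (slack ±20 nt, deliberately
below the minimum array period so a copy cannot snap onto its
neighbour); repeat boundaries are the maximal run of columns whose
majority-base agreement reaches 0.6; copies below 0.7 identity to the
consensus are dropped as spurious flanking runs; and gaps of roughly
*k* periods are probed at interpolated lattice positions so a copy
whose run was broken by mutations is not lost. Arrays are split
wherever an implied spacer leaves the 20–60 nt bracket, and chains
shorter than `min_copies = 3` are discarded.

Consensus retention (`consensus_arrays`) keeps a seed-detector locus
iff a periodic-detector locus on the same contig overlaps it
reciprocally by ≥ 0.5 of each interval; the retained record keeps the
seed detector's repeat starts and widens the interval to the union.
Reciprocal overlap is our operationalization of "consistent between
two predictors", which published pipelines leave unquantified.

Repeat consensus is the gapless per-column majority with ties broken
A<C<G<T. Copies are aligned by position only; indel-containing copies
are truncated or padded to the modal length — a documented limitation.
Repeat **types** are single-linkage clusters of arrays at ≥ 0.9
global-alignment identity of their consensus repeats, best of forward
and reverse complement (exact-match typing would shatter types under
sequencing noise). Motif assignment scores a type's representative
against a motif-consensus database (a *synthetic* 33-entry database
ships in `extdata`; real analyses supply their own) and assigns the
arg-max motif at ≥ 0.8 identity, else "novel".

Defaults: repeats 21–48 nt, spacers 20–60 nt, `min_copies` 3, seed
k = 8. These bracket the ~35 nt repeat / ~34 nt spacer geometry the
detectors are built around; all are `crispr_params()` arguments.
Coordinates are 0-based half-open internally; GFF3 output converts to
1-based inclusive.

## Contig binning and completeness

Contigs ≥ 10 kb are clustered by average-linkage hierarchical
clustering on a weighted Euclidean distance over three feature blocks:
the 256-dimensional tetranucleotide frequency (TNF) profile, the
standardized `log10(coverage + 1)`, and GC fraction. Coverage enters
on a log scale because abundances span orders of magnitude, and is
standardized across the dataset because no absolute scale is
meaningful. The tree is cut at an explicit `k`, or `k = "auto"`
maximizes the mean silhouette width over k ∈ 2..10 — the bin count
selection rule is ours, since upstream descriptions leave it open.

4-mers are counted on the given strand only, with no
reverse-complement canonicalization: this keeps the 256-length
contract and the counting oracle trivial; users wanting canonical
counts can pre-canonicalize their sequences. Windows containing `N`
are skipped. Pearson (not rank) correlation is used wherever TNF
profiles are compared.

Bin completeness is the fraction of a 107-entry essential-gene list
recovered (distinct markers only; duplicates are reported separately),
alongside a 31-entry single-copy list. The shipped lists are synthetic
placeholder ids that exercise the counting logic — the published
marker sets are deliberately not reproduced. Note one upstream
inconsistency we inherited and resolved: a recovery of 106/107
essential genes is sometimes described as "99.9% completeness", but
106/107 = 99.07%; completeness here is strictly
`essential_found / list length`.

## Homology-hit classification

Hits arrive as 12-column blast-tabular rows plus a subject→lineage
map. Ranking is total: bit score descending, E-value ascending,
subject id lexicographic. The voting rule assigns a **phylum** iff the
top min(10, n) hits carry one identical non-missing phylum; **class,
family and genus** each require a single taxon to *strictly* exceed
half of the top min(30, n) hits ("majority" is interpreted as > 50%,
and the order rank is deliberately not votable because the rule
enumerates class, family and genus only). Queries with fewer than 10
hits are unassigned; the threshold is configurable. The deepest
assignable rank is reported.

The best-hit screen filters to query coverage ≥ 80% (coverage is
100·span/query length when computed internally) and takes the ranked
top; bit score is the primary key with E-value tiebreak, one
consistent reading of ranking "based on E-value, bit score".
Per-reference summaries report query counts and the unweighted mean
percent identity rounded to integer.

## Phage comparative genomics

* **Dot plots**: all exact shared words of size 10 (configurable ≥ 4),
  both orientations, as 0-based coordinate pairs.
* **Pairwise identity**: global Needleman–Wunsch with affine gaps
  (match +1, mismatch −1, open −5, extend −1), identity =
  100·matches/columns. Group similarity is the mean ± sd of pairwise
  identities within a group. This deliberately *re-defines* the
  whole-genome similarity statistic — the aligner-suite score it
  replaces has no published formula — so absolute values are not
  comparable to scores from other tools.
* **TNF network**: nodes are genomes, edges are Pearson correlations of
  TNF profiles at ≥ 0.5 (configurable; 0 emits the complete graph),
  node weight = sum of incident edge weights.
* **RSD orthologs**: reciprocal smallest distance with an internal
  Smith–Waterman (BLOSUM62, gap open 11 / extend 1) and a fixed
  Karlin–Altschul parameterization (λ = 0.267, K = 0.041) for
  E-values — the screen needs a consistent threshold, not
  database-calibrated significance. Distance is 1 − fractional
  identity of the local alignment (a documented simplification of the
  maximum-likelihood distance in the original algorithm); defaults
  E ≤ 1e-15 and distance ≤ 0.5 in both directions.
* **Shared cores**: single-linkage components of pooled RSD pairs; a
  component is core iff it touches every genome.
* **Welch tests**: per-category unequal-variance t-tests
  (Welch–Satterthwaite df, two-sided) between two genome groups.
  P-values are reported raw (a Benjamini–Hochberg column is optional)
  and the significance flag follows the raw 0.05 threshold, matching
  the uncorrected convention of the analyses this reproduces.
  Zero-variance-in-both-groups categories are flagged degenerate:
  non-significant when means agree, p = 0 when they differ.
* **Proteome tree**: genome distance 1 − shared pairs / smaller
  proteome size, neighbor-joining, negative branch lengths clamped
  to 0. NJ on shared-ortholog distance is our choice for the proteome
  phylogeny; nothing deeper is implied by branch lengths.

## The synthetic-community generator

The generator emulates exactly what the analysis assumes and no more:
i.i.d. bases at a target GC (no higher-order Markov structure — enough
to give bins distinct TNF centroids while keeping counting oracles
trivial); planted arrays with independently mutated repeat copies and
i.i.d. uniform spacers (real spacers are phage-derived, but detection
depends only on repeat periodicity); truncated-normal coverage with
genome-specific means (composition+coverage binning presumes coverage
separates organisms) and within-genome dispersion around 15% of the
mean, typical of uniform shotgun coverage; phage genome lengths
uniform over 24–200 kb; and ranked hit tables with strictly decreasing
bit scores whose lineages are resampled from a decoy pool at a
configurable noise rate. Arrays are planted by overwriting a segment
in place, so genome length and downstream fragment coordinates are
unaffected.

What it does **not** model: sequencing error and read-level artifacts,
assembly chimerism, strain microdiversity, repeat-induced assembly
fragmentation, real spacer content, and compositional biases beyond
GC. Passing recovery tests therefore demonstrate algorithmic
correctness under the stated statistical structure, not field
performance on real assemblies.

Randomness follows one master seed; each stage derives its own
generator via a stable labelled hash (`derive_seed`), so adding a
stage never perturbs earlier draws, and identical configuration gives
byte-identical FASTA/TSV/manifest outputs.

## Numerical and design choices

* Ties: consensus bases A<C<G<T; motif ties to the lowest motif id;
  hit-ranking ties to E-value then subject id; silhouette ties resolve
  to the smaller k via `which.max`.
* Degenerate inputs: all-`N` sequences raise composition errors;
  constant TNF profiles raise a degeneracy error naming the genome;
  sub-`min_copies` tandems are never emitted; empty motif databases and
  empty proteomes are parameter errors.
* Problem sizes in the shipped tests were chosen so the whole suite
  exercises every stage on one CPU in well under a minute of detector
  time: planted-array batteries use 100 contigs of 8 kb; recovery of
  high-copy geometry uses single 100–200 kb genomes; binning
  communities use three 120 kb genomes fragmented at ~14 kb.

## Known limitations

Gapless repeat-copy alignment misestimates consensus around
indel-carrying copies; detection sensitivity degrades above ~10%
per-copy repeat divergence (by design — the consensus stage exists to
arbitrate exactly those cases); the group-similarity statistic is not
comparable to whole-genome aligner scores; and the family-level
(1–40) repeat characterization of the motif framework is not
implemented because its criteria are not public — only motif-level
(1–33) assignment is.
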