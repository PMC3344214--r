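---
title: "Microsatellite decomposition and flanking-region phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite decomposition and flanking-region phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatphylo)
```

## The problem

Dinucleotide microsatellites (SSRs) are tandem arrays such as
`(TG)_n` whose repeat number mutates orders of magnitude faster than the
surrounding unique sequence. When the same locus can be amplified and cloned
across several congeneric species — here four freshwater eels of the genus
*Anguilla*, coded J (*A. japonica*), A (*A. anguilla*), M (*A. marmorata*)
and B (*A. bicolor pacifica*) at six conserved loci — the cloned alleles
carry two very different signals:

* the **major region** (the repeat tract), which varies by whole repeat
  units through replication slippage and occasionally acquires an
  interrupting point substitution, turning `(TG)_19` into patterns like
  `(TG)_8AG(TG)_10`;
* the **flanking regions**, unique sequence on either side of the tract,
  which accumulate ordinary point substitutions and rare 1–2 nt indels and
  therefore behave like any slowly evolving nuclear marker, usable for
  phylogeny.

msatphylo implements the full chain: decompose every allele into
5' flank / major region / 3' flank, classify its repeat architecture,
summarize the per-locus allele diversity, build intraspecific IUPAC
consensus flanks, concatenate them across loci, census the interspecific
variation, compute Kimura two-parameter (K2P) distances, and infer a
Neighbor-joining (NJ) tree with bootstrap support. A forward-time simulator
generates datasets with the same statistical structure for validation.

## Repeat-region notation

Survey tables describe allele pools compactly: subscripts are counts
(`(TG)_8`), `~` denotes a range of alleles (`(TG)_7~13`), and comma lists
enumerate alternatives (`(TG)_14~18, 20`). `parse_repeat_notation()` expands
a notation string into the set of concrete decompositions it denotes.

Two semantics exist when several subscripts in one pattern are lists. For
`(TG)_3, 8CG(TG)_1, 4` the table's authorship could mean position-wise
pairing (alleles 3+1 and 8+4) or a Cartesian product (four alleles). The
package defaults to pairing whenever all multi-count subscripts have equal
length and to the Cartesian product otherwise, which reproduces the printed
allele counts (e.g. `(TG)_12~18TA(TG)_0, 2` denotes 7 × 2 = 14 alleles);
`list_mode = "cartesian"` forces crossing. Zero counts are legal in notation
(`(TG)_0, 2`) and zero-count runs are dropped during canonicalization, so
those alleles end in the bare literal `TA`.

Canonical form guarantees: no zero-count runs, no adjacent runs of the same
motif, no adjacent literals, and single foreign units written as 2-nt
literals (so `(AG)_1` and `AG` are the same interruption). Serialization of
a canonical decomposition re-parses to itself; the test suite checks this
for every entry of the bundled survey table.

## Major-region detection

`decompose_major_region()` finds every maximal exact tandem array of the
locus motif in *both phases* (TG and GT — cloned inserts can present either
phase, and interrupted patterns such as `(TG)_3CG(GT)_10` genuinely switch
phase at the interruption). Overlapping phase-shifted duplicates are pruned
(longest first, declared phase preferred, then leftmost). Arrays are chained
across a junction when the junction is a 1–2 nt literal, or a single extra
foreign dinucleotide unit (a 4-nt tandem such as `AGAG`, giving `(AG)_2`
interruptions) provided both neighboring arrays have at least three units —
without that guard, a stray duplet in the flank two bases away from the
tract would be absorbed into the major region. A chain qualifies if it
contains an array of at least `min_seed_units` (default 3) units; among
qualifying chains the longest expanded region wins, leftmost on ties. The
tie-break is arbitrary but deterministic; the notation never states one.

Classification follows the usual three-way scheme: **perfect** (one
uninterrupted run), **interrupted** (runs of the locus motif separated by
short literals or a foreign run of ≤ 2 units), **compound** (adjacent runs
of ≥ 3 units of two different motifs). Classification is invariant under
reversal of the element list.

## Alignment and consensus

Intraspecific flanks at one locus are nearly identical, so a simple global
aligner suffices: Needleman–Wunsch with linear gap penalties
(match +1, mismatch −1, gap −2; all exposed as parameters) and a
deterministic traceback (diagonal, then gap-in-second, then gap-in-first on
ties), extended to multiple sequences by center-star progressive alignment
(center = maximal summed pairwise score; "once a gap, always a gap"). The
original study aligned flanks in an interactive editor without reporting
parameters; for near-identical sequences any sane global aligner agrees,
which is why the defaults are ordinary textbook scores rather than tuned
values. The 5' and 3' flanks of each allele are joined (the major region
removed) before alignment, with the junction index recorded.

`build_consensus()` emits one residue per column. Columns where gaps are the
majority are dropped from the intraspecific consensus (they represent
within-species indel polymorphism, not a species character); minority gaps
are ignored. With the default `ambiguity_threshold = NULL` the plurality
residue wins and only genuine ties produce IUPAC codes — a G/T tie yields
`K`, the code observed in the real consensus data. Setting a numeric
threshold switches to frequency filtering (all residues with frequency at or
above the threshold are coded), which is the conventional WebLogo-style
alternative; with `{A, A, G}` a threshold of 0.3 gives `R` where the default
gives `A`. The two regimes are intentionally distinct: no single rule
reproduces both behaviours.

Per-species consensus sequences are concatenated in the configured locus
order (junction positions recorded; positions are reported 1-based per
locus) and the four concatenations are aligned with the same center-star
aligner. `census_variation()` then classifies each column: an **indel
site** if any species has a gap, otherwise a **substitution site** if the
column holds incompatible residues — IUPAC letters are compared as base
sets, and overlapping sets (e.g. `K` vs `T`) are compatible, so consensus
ambiguity is never double-counted as fixed difference. Indel sites are
split into monomorphic (non-gap residues all compatible) and polymorphic.
Percentages are over variable sites and base composition over unambiguous
residues. When the published counts — 44 substitution and 27 indel sites —
are fed through this census the percentages are 61.97% and 38.03%.

## Distances and the tree

`count_site_differences()` uses pairwise complete deletion: a column is
excluded for a pair when either sequence has a gap *or* an ambiguity code
there. Exclusion rather than probabilistic resolution is conservative and
deterministic, and pairwise (not global) deletion is deliberate: the
published per-pair difference counts imply different effective lengths for
different pairs, which only pairwise deletion produces. Transitions are
A↔G and C↔T; everything else is a transversion.

The K2P distance is
$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)$
with $P = \mathrm{Ts}/L$ and $Q = \mathrm{Tv}/L$; its standard error is the
analytic delta-method estimate (the estimator behind the published standard
errors is unstated, so the SE is reported but never treated as a precision
claim). Saturated pairs ($1-2P-Q \le 0$ or $1-2Q \le 0$) raise an explicit
"distance undefined" error. With the printed Ts = 8, Tv = 12 over 469 sites
the distance is 0.0439 → 0.044, the published minimum.

`neighbor_joining()` is canonical NJ: join the pair minimizing
$Q(i,j) = (n-2)\,d(i,j) - r_i - r_j$, with ties broken on the
lexicographically smallest sorted label pair (within $10^{-12}$) and
negative branch lengths clamped to zero with the deficit recorded. On the
published 4 × 4 distance matrix the two candidate joins tie exactly and
both yield the same unrooted split {M, B} | {J, A} — the tie-break cannot
affect the biological conclusion. With four taxa and no outgroup only this
unrooted split is inferable; the package never roots the tree.

`bootstrap_support()` resamples alignment columns with replacement,
recomputes distances and NJ per replicate, and reports each split's support
as a percentage. The seed is mandatory; replicates with undefined distances
are dropped and counted, with a warning above 10%.

## The simulator

`simulate_msat_dataset()` is a forward-time generator whose defaults *are*
the study design being emulated, not free dials:

| parameter | default | why |
|---|---|---|
| tree | split {M,B} \| {J,A}; external edges 0.025/0.028/0.020/0.024 (J/A/M/B), internal 0.006 subs/site | reproduces pairwise flank divergences of 0.044–0.058, inside the published 0.044–0.061 band; the internal edge is what the published distance matrix itself implies via the four-point condition |
| loci | six dinucleotide loci (five TG, one GA), flanks totalling 463 bp | published concatenated consensus lengths are 458–469 bp |
| allele depths | the survey's per-locus, per-species clone counts (274 total) | mirrors the real sampling design |
| `slip_rate` | 0.005 per generation per direction | stepwise mutation model rate in the middle of the literature's 10⁻⁵–10⁻² per-generation band |
| `generations_per_branch` 20000, `allele_generations` 400 | maps branch lengths to slippage generations so within-species repeat-count spreads match the survey's (about 4–7 units per locus) |
| `kappa` | 1.4 | realized Ts:Tv under K2P is κ:2; the published pairwise counts (Ts 8–11 vs Tv 12–16) give Ts/Tv ≈ 0.7 |
| `flank_indel_rate` | 0.3 indel events/site/unit branch, lengths 1–2 nt | yields tens of interspecific indel sites per dataset, matching the published 27 |
| `interruption_rate` | 0.05 events/repeat-nt/unit branch | a handful of interrupted patterns per dataset, as in the survey table |

Slippage is a symmetric ±1-unit walk reflecting at one unit, applied to the
longest run; interruptions substitute one interior unit of a run, producing
`(TG)_nXG(TG)_m`-style patterns; indels never touch the major region —
`validate_simulation()` asserts on every dataset that no tract literal has
odd length, the in-model counterpart of the empirical observation that
single-nucleotide indels do not occur inside repeat tracts. Within-species
structure is a star of short branches (`allele_branch` 0.002): allele pools
from population samples carry no recorded pedigree, so nothing deeper than
a star can be identified anyway. A two-phase (multi-unit jump) slippage
mode was considered and left out: single-unit slippage is the mechanism the
data support, and nothing downstream distinguishes the two at these depths.

What the simulator does *not* emulate: coalescent genealogy within species,
recombination inside flanks, unequal crossing-over as a mechanism distinct
from slippage (observationally indistinguishable here), mutation-rate
heterogeneity among loci, and cloning/PCR artifacts. Passing recovery tests
on simulated data therefore shows the pipeline is correct and well-calibrated
for data of this shape — it does not certify behaviour on pathological real
data (e.g. paralogous amplification).

## Numerical and degenerate-input choices

* Alignment traceback preference (diagonal > up > left) fixes a unique
  optimal alignment among co-optima.
* All-gap columns are dropped with a logged warning; an alignment of
  identical rows produces zero variable sites and the census sets a
  `no_variation` flag instead of emitting 0/0 percentages.
* NJ clamps negative branch lengths at zero (recording the deficit) —
  estimated distance matrices are never exactly additive.
* An allele in which no seed array exists raises "no major region"; the
  pipeline can either abort or drop-and-record such alleles
  (`on_error = "drop"`), so every input is accounted for in the report.
* The published site census self-reports both "68 point mutation sites" and
  44 + 27 = 71 sites; the percentages match 44/71 and 38.03 = 27/71, so the
  census reports the component counts and percentages and makes no attempt
  to reconcile the 68.

## Problem sizes used in validation

The shipped test suite runs the slippage-moment check at 10,000 replicates
of 100 generations, the bootstrap-against-oracle comparison at 2,000
replicates, and the end-to-end topology recovery on 100 simulated datasets
at the default configuration (seeds 1–100, fixed); these sizes give the
stated statistical tolerances comfortable margins while keeping the suite
runnable on a laptop. Every empirical number quoted in this vignette is
recomputed by the tests or by `scripts/acceptance.R`; none is asserted from
memory.

## Known limitations

* Center-star alignment can place gaps inconsistently between non-center
  pairs around real indels; with the short, near-identical flanks involved
  this occasionally costs a few sites of signal but never creates spurious
  shared characters in the consensus (gap columns are excluded pairwise
  from distances).
* Only dinucleotide motifs are supported; motif discovery is out of scope
  (motifs are declared per locus).
* The aligner is linear-gap; affine penalties were unnecessary for flanks
  of this length and identity.
* Sequences are analysed in cloned orientation only; the locus
  configuration records orientation notes but the pipeline never
  reverse-complements.
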