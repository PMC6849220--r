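---
title: "Methods: MUM-based progenitor inference for allopolyploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MUM-based progenitor inference for allopolyploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

An allotetraploid genome contains two complete subgenomes, each inherited
from a different parental lineage. Given an assembly of such a genome and a
panel of candidate relative genomes, we want to nominate the pair of
candidates most likely to represent the two progenitor lineages. The signal
used here is exact-match synteny: a candidate closely related to one
subgenome shares many long exact substrings with the target, and the *pair*
of candidates that together cover the largest fraction of the target genome
is the natural progenitor nomination — each true progenitor explains one
subgenome, so the two footprints are largely complementary.

The package implements the whole chain: maximal unique match (MUM)
detection, one-to-one filtering, coverage statistics, and pair ranking,
plus a k-mer spectrum genome-size estimator and two small phenotype
formulas that belong to the same study design. A synthetic allotetraploid
simulator with known ground truth makes every step testable end to end.

# Maximal unique matches

A MUM between target $T$ and candidate $C$ is an exact match of length at
least `min_length` that (i) cannot be extended in either direction and
(ii) is unique: the matched string occurs exactly once in $T$ and — with
`uniqueness = "both"`, the default — exactly once in $C$, counting both
strands of $C$. Uniqueness in both genomes is the classical MUM
definition and matches the statistic's name; because some aligners
default to reference-side uniqueness only, that variant is available as
`uniqueness = "reference_only"`.

`find_mums()` builds one generalized suffix array (prefix-doubling
construction with counting sort, then Kasai's LCP array) over
$T$, $C$, and the reverse complement of $C$. Every record boundary and
every `N` receives its own unique sentinel code, so a match can never
cross a record or include an `N`. With both-sided uniqueness, a MUM is
exactly an adjacent suffix pair spanning the two genomes whose common
prefix is longer than the LCP with both outer neighbours (the matched
string then occurs exactly twice in the combined text) and whose
preceding characters differ (left-maximality). A consequence worth
knowing: a reverse-complement-palindromic string occurs on both strands
of the candidate at the same locus, counts twice, and is therefore never
a MUM under `"both"`.

Minus-strand matches report `qry_start` on the candidate's *forward*
strand (leftmost matched base), so interval arithmetic never needs
strand-specific coordinate flattening. All coordinates in the package are
0-based half-open.

`min_length` defaults to 20 bases, the customary anchor length for
whole-genome alignment at the divergences involved; at desk scale the
tests also exercise 5 and 10.

`find_mums_naive()` is a permanent second implementation used as the test
oracle: run-length enumeration of equality runs along all diagonals of
every record pair (both strands), followed by explicit occurrence counting
with overlap-aware string search. It shares no code or algorithmic idea
with the suffix-array path and refuses inputs beyond a 20 kb guard.

# One-to-one filtering

Raw MUM sets still allow one region of either genome to be matched twice
(e.g. by a forward and a minus-strand match, or across different record
pairs). The filter retains a subset in which no two matches overlap on the
target axis or on the candidate axis and matches sharing
(`ref_id`, `qry_id`, `strand`) are mutually collinear (consistently
ordered, non-crossing), maximizing total matched bases.

Two paths, both deterministic:

* **Exact** (inputs up to `exact_limit = 20` matches): branch-and-bound
  over the pairwise conflict graph, pruned by remaining weight. All
  constraints here are pairwise (overlap, or crossing within a group), so
  subset feasibility is a pairwise check. Ties resolve toward retaining
  the earliest matches in (`ref_id`, `ref_start`, `qry_id`, `qry_start`)
  order. The exact path was chosen because a purely greedy resolution
  provably misses the optimum on configurations as small as three
  matches — a heavy match that blocks two lighter, mutually compatible
  ones — and the filter's contract is stated as an optimum.
* **Heuristic** (larger inputs): per-group maximum-weight collinear
  chaining (quadratic dynamic program, equal-weight ties resolved toward
  the chain whose first match starts earliest), then greedy cross-chain
  resolution in descending chain weight, dropping any match that
  conflicts with an already retained one. This is the classical
  chain-and-filter strategy of whole-genome aligners; at genome scale the
  exact optimum is not computable and the difference is second order.

A conflicting match is dropped whole — no partial trimming — so every
retained match still satisfies the exact-match invariant. The filter is
idempotent on both paths.

# Coverage statistics and pair ranking

`merge_to_intervals()` unions the retained matches' target footprints per
sequence (adjacent intervals coalesce; interval algebra is delegated to
IRanges). The per-candidate statistic is

$$\text{percent} = 100 \cdot \frac{\text{covered bases}}{\text{target length}},$$

and the pair statistic is the percentage covered by the **union** of the
two candidates' interval sets. Union rather than sum is deliberate: the
two progenitors' footprints overlap wherever ancestral sequence is still
recognizable from both lineages, a sum would double-count exactly those
regions and could exceed 100%. The plain sum is retained in the
`pair_coverage` object (`sum_percent`) for transparency. From the union
definition two invariants follow and are tested on every simulated panel:
the pair value dominates each single value, and never exceeds
`min(100, single_i + single_j)`.

Coverage is computed on the one-to-one filtered set by default;
`use_raw_mums = TRUE` exposes the unfiltered variant since either set is
a defensible basis for the statistic. `rank_pairs()` sorts all unordered
pairs by percentage (ties lexicographic by name); the top pair is the
nomination. Reports round percentages to two decimals; all comparisons
internally use full precision.

# k-mer genome size

For `N` reads of length `L`, each read contributes `L - K + 1` k-mer
windows. With `B` the number of k-mer *instances* in low-frequency bins
(multiplicity below the cutoff of 4, attributed to sequencing error) and
`D` the sequencing depth, the genome size is

$$G = \frac{N (L - K + 1) - B}{D}.$$

Choices that need stating:

* **`D` is the spectrum mode at or above the cutoff** (ties toward the
  smaller multiplicity). No mixture model is fitted; heterozygosity and
  repeat shoulders are out of scope. Because the mode is an integer, the
  estimate carries a discretization error of order $1/D$ — at depth 30
  and $L=100$, $k=21$, the per-window depth is $30 \cdot 0.8 = 24$ and the
  estimate lands within a few percent of truth.
* **`B` counts instances** (multiplicity times bin count), not distinct
  k-mers, because it is subtracted from the instance total
  $N(L-K+1)$. The distinct-k-mer reading is available with a warning.
* **No canonical strand collapsing**: k-mers are counted as read, so the
  window count and the instance total agree exactly. Windows containing
  `N` are skipped.
* `k` defaults to 21 for desk-scale data; with real short-read data
  larger odd values (41 and up) are the usual choice and are fully
  supported.

# The simulator

`make_scenario()` emulates the study design: an ancestor genome evolves
along independent lineages (a star phylogeny — the simplest structure
that makes the ranking non-trivial through a divergence gradient), two
lineages hybridize, and both subgenomes accumulate further divergence.

Default study conditions, chosen once as a realistic desk-scale setting:

| parameter | default | why |
|---|---|---|
| ancestor length | 200 kb, 2 chromosomes | large enough for stable coverage statistics, small enough for minutes-scale runs |
| GC | 0.36 | typical crucifer genome composition |
| panel divergences | 0.05 (both progenitors), 0.03, 0.075, 0.12, 0.20 subs/site | spans close sister lineages to distant relatives; nearest decoy at 1.5x the progenitor divergence |
| post-hybrid divergence | 0.02 subs/site | progenitor relatives are close but not identical to the subgenomes |
| indels | rate 5e-4/site, length 1-10 | realistic small-indel load; shifts coordinates without dominating divergence |
| inversions | 2 per lineage, 0.5-5 kb | rearrangement before/after hybridization; exercises minus-strand chaining |
| substitution model | uniform base replacement | MUM statistics depend only on exact-run lengths, not on transition bias |

Reads are single-end, uniformly placed on the forward strand with a
uniform per-base error rate; mate-pair structure and quality profiles are
irrelevant to every statistic computed here and are not emulated.

Everything is bit-reproducible from integer seeds (`withr::with_seed`,
so the caller's RNG state is never disturbed).

What passing the simulated recovery test does *not* show: real
assemblies are fragmented, repeat-rich and partially masked, real panels
are unevenly sampled, and real lineages share ancestry in nested clades
rather than a star. The simulation validates the statistical machinery
and its implementation, not the biological difficulty of any particular
panel.

# Phenotype formulas

From absorbances of a chlorophyll extract at 664 and 649 nm:

* chlorophyll a = 13.36 A664 − 5.19 A649
* chlorophyll b = 27.43 A649 − 8.12 A664
* total = 5.24 A664 + 22.24 A649 (identically a + b; asserted in tests)

Values are reported in formula units (concentration in the extract);
multiplying by extract volume and dividing by the leaf area used for
extraction gives an amount per cm². Negative components trigger a
warning — they indicate absorbance ratios outside the formula's validity —
but are not errors.

Relative expression fold change is
`(target_treated / reference_treated) / (target_control / reference_control)`
on linear-scale quantities; it is invariant under common rescaling of
either pair. No Cq-to-quantity conversion is implemented: inputs are
assumed to be already on a linear scale relative to reference-gene
amplification.

# Numerical and testing choices

* Determinism everywhere: fully specified sort orders, explicit
  tie-breaks (documented per function), no time- or locale-dependent
  output; rerunning any pipeline on identical inputs yields byte-identical
  report files.
* Degenerate inputs fail loudly with named records/stages: empty FASTA,
  duplicate ids, mismatched FASTQ qualities, zero-length targets,
  spectra entirely below the cutoff, single-candidate panels.
* Problem sizes in the test suite: oracle equivalence on 200 random
  genome pairs (50–2000 bp, `min_length` 5/10/20); filter optimality
  against full enumeration on 100 random sets of up to 12 matches;
  coverage vs a position-bitmap oracle up to 10 kb; 20 end-to-end
  scenario seeds at the default conditions; genome-size recovery at
  depth 30 on a 100 kb genome with and without 1% read error.
* Known limitations: the heuristic filter path is not guaranteed optimal
  (by construction); the k-mer counter is in-memory and intended for
  desk-scale read sets; no gapped alignment, no repeat masking, no
  nested-clade simulation (a structured-tree option is a natural
  extension).
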