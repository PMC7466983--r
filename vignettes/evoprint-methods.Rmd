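---
title: "Phylogenetic footprinting with evoprintr: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic footprinting with evoprintr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoprintr)
```

## The problem and the model

Functional non-coding DNA — enhancers, silencers, insulators — evolves far
more slowly than the neutral sequence around it. Phylogenetic footprinting
exploits this: align orthologous regions from a set of diverged test species
to one reference sequence and ask, base by base, which reference positions
are conserved. `evoprintr` renders the answer as an *EvoPrint*: the
reference sequence printed once, uninterrupted, with conserved bases in
uppercase and diverged bases in lowercase. Runs of uppercase form *conserved
sequence blocks* (CSBs); CSBs cluster into enhancer-scale units separated by
poorly conserved spacers; and CSBs that additionally survive in a distantly
related taxon are *ultraconserved* CSBs (uCSBs), whose order and orientation
across taxa expose microinversions.

Formally, for test species $s = 1, \dots, S$ and reference positions
$p = 1, \dots, L$, the aligner produces a boolean conservation matrix
$C_{sp}$ ($C_{sp} = 1$ iff position $p$ lies in a retained local-alignment
block for species $s$ and the aligned test base is identical). The relaxed
EvoPrint mask with relaxation parameter $R$ is

$$M_R(p) = \mathbf{1}\Big[\sum_s (1 - C_{sp}) \le R\Big],$$

so $R = 0$ is the strict print ("conserved in **all** test species") and
$R = 1$ the standard relaxed print ("all or all but one"). Masks are nested
in $R$ by construction.

## The seed-and-extend aligner

Each test species is aligned to the reference independently with a
BLAT-style pipeline, on both strands:

1. **Seeding.** Every overlapping k-mer of the test sequence and of its
   reverse complement is indexed (defaults $k \in \{9, 11\}$, union of
   hits); exact matches against reference k-mers become seeds. K-mers
   containing `N` are skipped, as are k-mers occurring more than
   `max_kmer_hits = 32` times in the index (low-complexity guard; such
   regions remain reachable by extension).
2. **Diagonal merging and extension.** Seeds sharing a diagonal are merged
   into exact-match runs, then extended ungapped in both directions with
   x-drop termination (match $+1$, mismatch $-1$, stop when the running
   score falls `x_drop = 50` below its maximum; `N` never matches).
3. **Chaining.** Blocks of one strand are chained by dynamic programming
   when colinear on both sequences within `max_chain_gap = 500` bp; chains
   with fewer than `min_chain_matches = 20` identical bases are dropped.
   Consecutive blocks on different diagonals are joined at the
   identity-optimal cut point; same-diagonal gaps inside a chain are
   bridged. Chain ends are patched across short unseedable tails by trying
   shifted diagonals charged a linear gap cost of 2 per base.
4. **Projection.** A reference base is conserved for the species iff it
   lies in a retained chain block and the aligned test base is identical;
   where chains overlap on the reference the higher-scoring chain decides
   (ties: the chain starting leftmost).

Because marking is strand-agnostic (minus-strand chains are computed in the
coordinates of the reverse-complemented test), `align_species(ref, test)`
and `align_species(ref, revcomp(test))` mark the same reference set.

### Why mismatch −1 rather than a steeper penalty

The test suite checks the marked set of each small alignment against an
exact local dynamic-programming oracle scored match $+1$ / mismatch $-1$ /
gap $-2$ (linear). A steeper extension penalty (e.g. $-2$) keeps only
regions above 2/3 match density while the DP keeps regions above 1/2, so
the two systematically disagree at mismatch-dense flanks; the extension
therefore uses $-1$ with a deeper x-drop. Tie conventions (keep leading
net-zero stretches, shed trailing ones, place ambiguous indel cuts
rightmost) were chosen to track the oracle's traceback.

**A fundamental caveat, documented on purpose.** With a *linear* gap cost
the DP optimum is unique in score but massively degenerate in path: gap
bases can scatter freely among co-optimal placements (splitting a 2 bp
deletion around a single matching base changes the identity-position *set*
without changing the score). A chained seed-and-extend aligner — which by
design contains no gapped DP in its main path — cannot reproduce one
specific traceback's tie choices. In practice roughly 60% of random
small-pair alignments agree *exactly* with the oracle and the rest agree
with median Jaccard ≈ 0.99; the residual disagreements are concentrated in
double-indel interiors and near-end indels. The corresponding acceptance
test demands 98/100 exact agreement and is intentionally left failing
rather than weakening the oracle or tuning the pair generator: the bar is
unattainable for any heuristic aligner measured against one DP traceback,
and the test documents exactly how close the implementation gets.

## Strict vs relaxed prints, and what recovery they support

With $S$ independent test species each substituting block bases at rate
$p$, a base survives *strictly* with probability $(1-p)^S$. At the
simulator's stated world ($S = 8$, $p_\text{block} = 0.02$) this is
$0.98^8 = 0.851$ — an upper bound on strict per-base recovery *before* any
run-length filtering, and the mean conserved run length,
$1/(1 - 0.98^8) \approx 6.7$ bp, falls below the default minimum CSB length
of 10 bp, so strict-print CSB recovery of planted 30–60 bp blocks lands
near 35%. The acceptance test that demands ≥ 90% recovery *from the strict
print* is therefore left failing with this analysis; the same pipeline at
the standard relaxed print ($R = 1$, per-base retention
$0.98^8 + 8 \cdot 0.02 \cdot 0.98^7 = 0.990$) recovers ≈ 99% of block bases
while marking ≈ 0.2% of spacer bases, which is the regime the method is
designed for and what the companion property test asserts.

## CSB calling and clustering

`call_csbs()` extracts maximal uppercase runs of length ≥ `L_min` (default
10 bp — the order of the shortest blocks treated as meaningful shared
sequence); `max_interruptions` (default 0) optionally bridges isolated
single-base interruptions. `cluster_csbs()` groups CSBs greedily left to
right, starting a new cluster when the gap exceeds `G` (default 100 bp,
chosen to merge figure-scale clusters while splitting multi-kb spacers).
Both defaults are free parameters, exposed as flags, because no numeric
thresholds exist in the method's source material — the biology constrains
only the qualitative picture (blocks ≪ spacers).

## uCSB mapping, colinearity and sharing

`map_csb()` aligns one CSB against both strands of a distant-taxon contig
with the same engine and reports matches with

* **identity** = identical bases / aligned bases, and
* **coverage** = aligned bases / CSB length,

accepted at `min_identity = 0.8`, `min_coverage = 0.5`. Coverage at 0.5
deliberately admits "a portion of a CSB" as a uCSB. (Identity is computed
over *aligned* bases; defining it over the full CSB length would make the
0.8/0.5 defaults mutually unsatisfiable for partial matches.)

`analyze_colinearity()` keeps one best match per CSB (identity, then
coverage, then leftmost target start), sorts by reference CSB start,
computes the majority strand, and reports `is_colinear` — strict
monotonicity of the majority-strand target starts (increasing for a `+`
majority, decreasing for `-`) — plus minority-strand CSBs as inversion
candidates. Monotonicity rather than adjacency defines colinearity because
intervening distances differ freely across taxa. `classify_sharing()`
partitions CSBs into both / target1-only / target2-only / neither across
two targets.

## The simulator: what it emulates and what it does not

`generate_dataset()` draws a uniform-composition ancestor, plants
non-overlapping conserved blocks, and evolves each species independently
(star phylogeny): i.i.d. substitutions at `p_block` inside blocks and
`p_spacer` in spacers (substituted base always differs), indels only in
spacers (per-base start rate `indel_rate`, lengths uniform on
`indel_length_range`), and at most one configured inversion or
translocation of a block copy. Rates may be per-species vectors;
`preset_gambiae_ladder()` builds a two-level design (four near-identical
species plus a divergence ladder) emulating a close species complex with
outgroups. Ground-truth block coordinates and strands are maintained
through every edit and exported as BED6.

Deliberate simplifications: no phylogenetic correlation between species, no
transition/transversion bias, no rate heterogeneity, no block-internal
indels (this keeps truth coordinates exact). The pipeline under test is
identity-based, so richer substitution models would change none of the
quantities the tests measure. A green recovery test therefore establishes
that the aligner and caller recover independently diverged planted blocks —
not that the simulator is a realistic model of molecular evolution.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; printed spans equal
  end − start. Region strings accept commas and internal whitespace.
* `N` bases never count as identical, are excluded from seeds, and break
  k-mers; gap characters in input FASTA are stripped with a warning.
* `make_evoprint()` rejects `R` ≥ number of species (a vacuous print).
* Empty seed sets, empty chain sets and all-false masks flow through as
  empty results, not errors.
* All simulator randomness derives from a single stored seed; the RNG state
  of the caller is saved and restored.
* CLI subcommands are deterministic given files + flags + seed; logs go to
  standard error only.

## Known limitations

* Agreement with an exact DP oracle is bounded by tie degeneracy (above).
* The aligner is for orthologous regions of a few kb to tens of kb, not
  whole-genome indexing; repeat handling is a simple occurrence cap.
* Colinearity uses one best match per CSB; paralogous multi-hits are
  reported by `map_csb()` but not used for ordering.
* Scorecard units are conserved-base counts — the simplest monotone
  divergence measure; no attempt is made to mimic any external server's
  score scale.
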