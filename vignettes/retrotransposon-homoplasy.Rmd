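---
title: "Quantifying homoplasy in retrotransposon presence/absence markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying homoplasy in retrotransposon presence/absence markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrohom)
```

## The problem

SINE retrotransposons spread by copy-and-paste: once a copy integrates at a
genomic site it is essentially never excised cleanly, and independent
integration at exactly the same site in two genomes is rare. A shared
insertion at orthologous positions in two species is therefore strong
evidence of common ancestry, which makes presence/absence patterns of
SINEs nearly homoplasy-free phylogenetic markers. "Nearly" is the operative
word: rare parallel insertions into the same target site, rare precise
deletions that restore the pre-insertion site, and incomplete lineage
sorting (ILS) of insertion polymorphisms all create patterns that conflict
with the species tree. `retrohom` implements the full analysis chain needed
to find, classify, and quantify these events in toothed-whale CHR2 SINE
data or in any comparable presence/absence marker system, plus a simulator
that generates loci with known event labels so every stage can be validated
against ground truth.

## Locus screening

Candidate elements come from a distilled RepeatMasker-style annotation
table. Two filters select usable loci:

* **Completeness** — the element must miss at most 10 nt of its family
  consensus. Truncated copies make breakpoint (and hence TSD-shift)
  assessment unreliable.
* **TE-free flanks** — at least 85% of the 500-nt flank on *each* side must
  be free of other transposable elements, so that downstream flank-signal
  analysis has single-copy sequence to work with. The criterion is applied
  per side (the wording of the underlying protocol is ambiguous between a
  per-side and a joint evaluation; per-side is the stricter and safer
  reading). Flanks shorter than 100 nt (contig edges) are rejected
  outright: the fraction would be evaluated on too little sequence, and
  such loci cannot support flank analysis anyway.

## Orthology and the TSD shift

When the same site carries an insertion in two species, three features
decide whether one ancestral event or two independent events are
responsible:

* **TSD shift** — the maximum displacement of the two breakpoints in the
  locus alignment frame, after discarding columns gapped in both species.
  Shift ≤ 1 nt is *precise*, 2–3 nt *nearly precise*, > 3 nt *unrelated*
  (different sites). Requiring *both* breakpoints to agree is the
  conservative operationalization of "identical target site duplications":
  a shift definition based on one breakpoint only would conflate co-located
  but staggered insertions. The 3-nt allowance absorbs the mutable
  low-complexity sequence that typically flanks SINEs.
* **Family and orientation** — independent insertions of different element
  families, or in opposite orientations, are immediately recognizable as
  non-homoplasious parallel insertions even when the shift is 0.
* **Tail divergence** — same-family, same-orientation co-located insertions
  can still be independent; clearly different 3′ low-complexity tails
  reveal this. We use normalized Levenshtein distance with a default
  threshold of 0.3. No published cutoff exists for this criterion, so the
  verdict records a `tail_heuristic` flag whenever the threshold decided
  the category.

TSD sequence identity is reported (`tsd_identical`) but never vetoes
orthology on its own, because TSDs accumulate point mutations like any
neutral sequence.

## Pattern assignment on the reference tree

Each locus's presence/absence vector is compared with the clades of a dated
reference topology (the 14-taxon whale tree shipped as `whale_tree()`, or
any user tree). Categories:

* **diagnostic** — the presence set equals a clade (restricted to species
  with data). Singleton presence sets are lineage autapomorphies; they form
  the denominators of the frequency estimators.
* **precise_deletion** — exactly one species lacks an otherwise clade-wide
  insertion, i.e. presence ∪ {that species} is a clade. One loss is more
  parsimonious than many parallel gains. The screening reference species is
  excluded (its presence is predefined by the extraction procedure, so
  deletions in it are invisible), as are species on the exclusion list.
  A deletion in the clade's outermost lineage leaves a clean sub-clade
  pattern and is unavoidably read as diagnostic — a known blind spot of the
  marker system itself, not of the implementation.
* **conflict_parallel_candidate / conflict_ils_candidate** — two-lineage
  patterns that violate the topology. The discriminator is the longest
  internal branch whose bipartition the pattern conflicts with: a
  hemiplasious (ILS) explanation requires the insertion polymorphism to
  survive that branch, and the expected survival time is of order the
  fixation time 4Ne generations (~1 MY for the whale parameters Ne =
  13,000, generation time 21.1 y). With the default 10-MY window, a
  Tursiops+Physeter pattern (conflicting with the 11.7-MY Physeteroidea
  stem) is a parallel-insertion candidate, while a Delphinida+Platanista
  pattern (conflicting only with the sub-MY radiation branch of Synrhina)
  is an ILS candidate. The window is configurable (`ils_window_my`).
* **ambiguous** — outgroup presence (insertion predates the root of
  interest), no present ingroup species, or patterns requiring three or
  more independent gains (complex multi-event scenarios). We deliberately
  emit a single catch-all category rather than inventing sub-rules for
  multi-event loci.

## Flank signal versus insertion signal

A conflicting pattern can reflect true homoplasy (two independent
insertions) or a genuine but non-treelike shared ancestry (ILS or
introgression). The two are separated by the flanking sequence: within a
recombination unit the flanks share the genealogy of the locus, so

* ILS/introgression ⇒ flanks support the *same discordant* clade as the
  insertion pattern;
* true homoplasy ⇒ flanks follow the species tree and *contradict* the
  insertion pattern.

`extract_flanks()` takes a configurable window (default 200 nt per side,
extended mode 1000 nt) upstream of the left TSD and downstream of the right
TSD, for carriers and non-carriers alike; repeat-masked columns are
removed, and species with fewer than 50 usable nt per side are dropped.
Subsets of ≥ 3 loci can be concatenated. Distances are Kimura 2-parameter
with pairwise gap deletion (JC69 available), trees are neighbor joining
with negative branch lengths clamped to zero, and clade support is the
percentage of bootstrap (site-resampling) replicate trees containing each
bipartition of the point tree. The original protocol read clade supports
off neighbor-net networks; NJ bootstrap bipartition support is used here as
a method substitution because the support percentage for a bipartition is
the only quantity the verdict consumes. Support thresholds default to 90%
for concatenated subsets and 80% for single loci, mirroring the reported
cutoffs; both are configurable.

## Parsimony on the presence/absence matrix

Insertions are asymmetric characters, so the matrix is scored under two
criteria:

* **Dollo** — one gain (at the MRCA of the carriers), unlimited losses;
  score = number of maximal carrier-free subtrees under the gain node.
* **Irreversible (Camin–Sokal)** — no losses; score = minimum number of
  independent gains = number of maximal carrier-only subtrees.

`?` states are compatible with either state and never force an event. Both
scorers are validated in the test suite against an exhaustive oracle that
enumerates every ancestral-state assignment on trees of up to 10 taxa.
Note that neither score dominates the other in general: a character present
in two distant leaves needs 2 irreversible gains but may need many Dollo
losses.

`parsimony_search()` hill-climbs through NNI rearrangements from a
neighbor-joining starting tree on Hamming distances of the matrix rows (the
original analysis used PAUP*'s heuristic search, which does not document
its starting tree; NJ is a standard, deterministic choice). Bootstrap
support resamples characters with replacement and repeats the search.
Bipartitions with equal support are ordered lexicographically by leaf set
for stable output. All searches are bit-reproducible for a fixed seed.

`directional_marker_test()` is a one-sided sign test — the upper binomial
tail of the supporting-marker count at p = 0.5. It deliberately is **not**
the KKSC insertion significance test (which models the insertion process
itself); it is a conservative screening statistic provided as plumbing.

## Frequency estimators

For a lineage pair, the parallel-insertion frequency is
100 · n_par / (n_autapomorphies_A + n_autapomorphies_B + n_par); the
precise-deletion rate is deletions per screened lineage, and the deletion
frequency is 100 · rate / (substrate + deletions). Estimates carry both
full precision and printed-style rounding (half-up; 2 decimals for
insertion frequencies and the rate, 3 for the deletion frequency), so that
published values are reproduced exactly while downstream computation keeps
numeric fidelity. Ratio comparisons against another clade's frequencies are
reported as a min/max/midpoint table (`frequency_ratio_table()`) against
user-supplied comparator values; no comparator values are hard-coded
because their published derivation is not fully specified.

## The simulator

`simulate_dataset()` emulates the study design, not any particular genome:

* Flanks evolve by JC69 along the dated tree at 0.002 subs/site/MY (a
  typical neutral mammalian rate; the inference side uses K2P — a
  deliberate slight model misspecification that keeps the validation
  honest). TSDs are drawn uniformly at 8–16 nt, typical for
  LINE1-mobilized SINEs.
* Diagnostic insertions land on branches proportionally to branch length;
  all leaves below the branch carry the element with one shared TSD.
* Parallel insertions place two independent copies at the same hot site on
  two lineages, with breakpoint jitter 0–1 nt (precise) or 2–3 nt (nearly
  precise); non-homoplasious variants differ in family, orientation, or
  carry a tail ≥ 0.35 diverged from the family consensus tail. Co-located
  copies share one alignment block with both TSD boundaries anchored, as an
  aligner would place them; family length differences are padded inside
  the element region. The finite hot-site pool idea (smaller genomes, fewer
  usable integration sites) is what the `hotspot_fraction` parameter
  operationalizes.
* Precise deletions remove the element plus exactly one TSD copy from one
  nested species, restoring the pre-insertion site byte-for-byte.
* ILS loci draw a genealogy mechanistically: the two sister lineages
  entering the short internal branch coalesce within it with probability
  1 − exp(−T/2Ne); failing that, one of three pairings is drawn uniformly.
  Discordant draws paint *both* the insertion and the flanks on the
  discordant genealogy (the moved lineage reattaches near the host clade's
  crown, reflecting deep coalescence); concordant draws are relabelled
  diagnostic. The closed form (2/3)·exp(−T/2Ne) is exposed as
  `ils_discordance_probability()` and checked empirically in the tests.

What the simulator does **not** model: insertion-site sequence preferences
(endonuclease motifs), indel evolution in flanks, assembly error,
alignment error beyond the breakpoint jitter, and recombination within a
locus. Passing the validation suite therefore demonstrates correctness of
the analysis logic under clean alignments, not robustness to upstream
alignment artifacts.

## Problem sizes and numerical choices

The validation suite uses: 1000 random characters on trees of 5–10 taxa for
the parsimony oracles; 10,000 loci at a true parallel frequency of 0.2%
for frequency recovery (acceptance band: the exact binomial 95% CI of the
count); 20 parallel-insertion loci and ~90 ILS-process draws with 1000-nt
flanks and 100 bootstrap replicates for the concordance checks; and 10,000
coalescent draws at three branch lengths for the discordance calibration.
Bootstrap replicates default to 1000 in the API; tests use 100–200, which
keeps supports at integer-percent granularity.

Degenerate inputs are handled explicitly: all-absent characters are a
scoring error (no gain exists); saturated K2P pairs are clamped to a
configurable ceiling with a warning; NJ ties resolve deterministically;
empty verdict tables and all-zero summaries round-trip cleanly. All
coordinates are 0-based half-open throughout; `to_one_based()` /
`to_zero_based()` are exact inverses.

## Known limitations

* Precise deletions of a clade's outermost lineage are undetectable in
  principle (see above).
* The ILS-window rule uses a single branch-length threshold; a full
  hemiplasy risk model would integrate over Ne along the conflicting path.
* The per-locus flank verdict depends on bootstrap support reaching a
  threshold; loci with little informative flank sequence return
  `uninformative` rather than a forced call.
* Bayesian tree inference and split networks are out of scope; the
  parsimony surface plus NJ bootstrap covers the quantities the analysis
  consumes.
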