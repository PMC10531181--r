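# retrohom

Quantifying homoplasy in retrotransposon presence/absence phylogenetic
markers.

SINE retrotransposon insertions are close to ideal phylogenetic markers: a
shared insertion at an orthologous genomic site almost always means shared
ancestry. *Almost* — rare parallel insertions into the same target site,
rare precise deletions that restore the pre-insertion site, and incomplete
lineage sorting (ILS) of insertion polymorphisms all produce conflicting
presence/absence patterns. `retrohom` is an R package for measuring how
often this happens, built around the toothed-whale CHR2 SINE marker system
but applicable to any comparable dataset. It is aimed at molecular
phylogeneticists working with presence/absence markers who need to
classify conflicting loci and put numbers on marker reliability.

The package provides:

* **Locus screening** — completeness (≤ 10 nt missing) and TE-free-flank
  (≥ 85% per 500-nt side) filters over a RepeatMasker-style annotation
  table.
* **Orthology classification** of co-located insertions by target site
  duplication (TSD) shift — `shift = max(|Δstart|, |Δend|)` in alignment
  columns, with bands ≤ 1 (precise), 2–3 (nearly precise), > 3 (unrelated)
  — plus element family, orientation and 3′-tail divergence.
* **Pattern assignment** of each locus onto a dated reference tree:
  diagnostic, precise deletion, parallel-insertion candidate versus ILS
  candidate (split by whether the longest topology-conflicting internal
  branch exceeds a 10-MY window), or ambiguous.
* **Flank-signal concordance** — K2P/NJ bootstrap bipartition support for
  the flanking sequence, which follows the species tree for true homoplasy
  but tracks the discordant insertion pattern for ILS/introgression.
* **Dollo and irreversible (Camin–Sokal) parsimony** scoring and NNI tree
  search with character-bootstrap support over the 0/1/? matrix.
* **Frequency estimators** — parallel-insertion frequency
  `100·n_par/(auta_A + auta_B + n_par)`, per-lineage deletion rate,
  deletion frequency `100·rate/(substrate + deletions)`, and the
  `4·Ne·generation-time` marker fixation time.
* **A simulator** that generates loci on a dated 14-taxon whale tree with
  known diagnostic/parallel/deletion/ILS event labels, so the whole
  pipeline is testable end to end without any genome downloads.

## Worked example

Feeding the estimators the marker counts from the whale n-way screens:

```r
library(retrohom)

parallel_insertion_frequency(14, 7782, 36)   # Tursiops vs Physeter
#> parallel_insertion frequency: 0.18% (14/7832 x 100%)
parallel_insertion_frequency(23, 7782, 94)   # Tursiops vs Kogia
#> parallel_insertion frequency: 0.29% (23/7899 x 100%)
rate <- deletion_rate(5, 13)                 # 5 deletions over 13 lineages
deletion_frequency(rate$printed, 11164, 5)
#> precise_deletion frequency: 0.003% (0.38/11169 x 100%)
fixation_time(13000, 21.1)                   # Ne = 13,000, 21.1 y/generation
#> [1] 1097200
```

So roughly 2–3 of every 1000 insertion events on these lineage pairs are
parallel insertions, precise deletions are an order of magnitude rarer
still, and a neutral insertion polymorphism needs about one million years
to fix — which is why only sub-MY radiations leave appreciable ILS signal
in this marker system.

An end-to-end simulated run:

```r
cfg <- pipeline_config(outgroup_species = c("Bos_taurus", "Hippopotamus_amphibius"),
                       reference_species = "Tursiops_truncatus", seed = 1)
p <- sim_params(n_loci = 200, seed = 1, hotspot_fraction = 0.05,
                p_deletion = 0.05, flank_len = 80)
simulate_dataset(p, out_dir = "sim")
run_pipeline(cfg, "sim", "out",
             lineage_pairs = list(c("Tursiops_truncatus", "Physeter_macrocephalus")))
```

`out/summary.tsv` then tallies the categories the pipeline assigned:

```
category	count
diagnostic	187
conflict_parallel_candidate	7
conflict_ils_candidate	0
precise_deletion	6
ambiguous	0
```

and `out/summary.json` carries the per-pair frequency estimate computed
from those classifications (here 7 parallel loci against 8 + 14
autapomorphies, i.e. a deliberately exaggerated simulated rate). A thin
command-line wrapper for the simulate/run/screen steps is installed at
`inst/scripts/retrohom.R`.

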