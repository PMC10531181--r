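Package: retrohom
Title: Homoplasy Analysis of Retrotransposon Presence/Absence Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying homoplasy in retrotransposon (SINE)
    presence/absence phylogenetic markers. Classifies co-located insertions
    across species into orthologous, parallel (precise and nearly precise),
    and unrelated categories using target site duplication (TSD) shift,
    element family, orientation and tail divergence; maps presence/absence
    patterns onto a dated reference species tree to separate diagnostic
    markers from parallel-insertion candidates, incomplete-lineage-sorting
    candidates and precise deletions; compares the phylogenetic signal of
    locus flanking sequences against the insertion signal to distinguish
    true homoplasy from lineage sorting or introgression; scores and
    searches trees under Dollo and irreversible (Camin-Sokal) parsimony with
    bootstrap bipartition support; and computes insertion- and
    deletion-homoplasy frequency estimators. A coalescent-aware simulator
    generates locus datasets with known event rates on a dated toothed-whale
    tree so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
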