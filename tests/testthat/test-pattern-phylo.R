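wt <- whale_tree()
cfg <- whale_config()

states_on <- function(present, missing = character(0)) {
  s <- setNames(rep("0", length(wt$tip.label)), wt$tip.label)
  s[present] <- "1"
  s[missing] <- "?"
  s
}

test_that("clade-matching patterns are diagnostic", {
  a <- assign_pattern(states_on(c("Physeter_macrocephalus",
                                  "Kogia_breviceps")), wt, cfg)
  expect_identical(a$category, "diagnostic")
  expect_setequal(a$matched_clade,
                  c("Physeter_macrocephalus", "Kogia_breviceps"))
  # a single present species is a lineage-diagnostic autapomorphy
  a <- assign_pattern(states_on("Tursiops_truncatus"), wt, cfg)
  expect_identical(a$category, "diagnostic")
  # clade match is evaluated on observed species only; the smallest
  # compatible clade is reported
  a <- assign_pattern(states_on("Physeter_macrocephalus",
                                missing = "Kogia_breviceps"), wt, cfg)
  expect_identical(a$category, "diagnostic")
  expect_true("Physeter_macrocephalus" %in% a$matched_clade)
})

test_that("conflicts split into parallel and ILS candidates by branch depth", {
  # Tursiops + Physeter conflicts across the 11.7-MY Physeteroidea stem
  a <- assign_pattern(states_on(c("Tursiops_truncatus",
                                  "Physeter_macrocephalus")), wt, cfg)
  expect_identical(a$category, "conflict_parallel_candidate")
  expect_gt(a$max_conflict_branch_my, 10)
  # Delphinida + Platanista conflicts only across the 0.8-MY radiation branch
  delphinida <- c("Lipotes_vexillifer", "Inia_geoffrensis",
                  "Pontoporia_blainvillei", "Tursiops_truncatus",
                  "Phocoena_phocoena", "Delphinapterus_leucas")
  a <- assign_pattern(states_on(c(delphinida, "Platanista_minor")), wt, cfg)
  expect_identical(a$category, "conflict_ils_candidate")
  expect_lt(a$max_conflict_branch_my, 1)
})

test_that("single nested absences are precise deletions; messier ones are not", {
  synrhina <- c("Platanista_minor", "Ziphius_cavirostris", "Mesoplodon_bidens",
                "Lipotes_vexillifer", "Inia_geoffrensis",
                "Pontoporia_blainvillei", "Tursiops_truncatus",
                "Phocoena_phocoena", "Delphinapterus_leucas")
  a <- assign_pattern(states_on(setdiff(synrhina, "Lipotes_vexillifer")),
                      wt, cfg)
  expect_identical(a$category, "precise_deletion")
  expect_identical(a$deletion_species, "Lipotes_vexillifer")
  # two nested absent species: ambiguous, not a deletion
  a <- assign_pattern(states_on(setdiff(synrhina, c("Lipotes_vexillifer",
                                                    "Ziphius_cavirostris"))),
                      wt, cfg)
  expect_identical(a$category, "ambiguous")
  # outgroup presence renders the locus ambiguous
  a <- assign_pattern(states_on(c("Bos_taurus", "Tursiops_truncatus")),
                      wt, cfg)
  expect_identical(a$category, "ambiguous")
})

test_that("deletion inference skips the reference and excluded species", {
  synrhina <- c("Platanista_minor", "Ziphius_cavirostris", "Mesoplodon_bidens",
                "Lipotes_vexillifer", "Inia_geoffrensis",
                "Pontoporia_blainvillei", "Tursiops_truncatus",
                "Phocoena_phocoena", "Delphinapterus_leucas")
  mk <- function(id, absent) {
    a <- assign_pattern(states_on(setdiff(synrhina, absent)), wt, cfg)
    a$locus_id <- id
    a
  }
  asg <- list(mk("l1", "Mesoplodon_bidens"), mk("l2", "Mesoplodon_bidens"),
              mk("l3", "Mesoplodon_bidens"), mk("l4", "Ziphius_cavirostris"),
              mk("l5", "Pontoporia_blainvillei"))
  del <- infer_precise_deletions(asg, wt,
                                 reference_species = "Tursiops_truncatus",
                                 excluded = "Pontoporia_blainvillei")
  expect_equal(sum(del$species == "Mesoplodon_bidens"), 3L)
  expect_false("Pontoporia_blainvillei" %in% del$species)
  expect_false("Tursiops_truncatus" %in% del$species)
  expect_equal(nrow(del), 4L)
})

test_that("Dollo score handles clade-wide presence, nested loss and missing data", {
  all_present <- setNames(rep("1", 14), wt$tip.label)
  expect_equal(dollo_score(wt, all_present)$score, 0)
  synrhina_minus_one <- states_on(
    setdiff(c("Platanista_minor", "Ziphius_cavirostris", "Mesoplodon_bidens",
              "Lipotes_vexillifer", "Inia_geoffrensis",
              "Pontoporia_blainvillei", "Tursiops_truncatus",
              "Phocoena_phocoena", "Delphinapterus_leucas"),
            "Lipotes_vexillifer"))
  expect_equal(dollo_score(wt, synrhina_minus_one)$score, 1)
  # "?" taxa never force a loss
  s <- synrhina_minus_one
  s["Lipotes_vexillifer"] <- "?"
  expect_equal(dollo_score(wt, s)$score, 0)
  expect_error(dollo_score(wt, setNames(rep("0", 14), wt$tip.label)),
               "all-absent")
})

test_that("irreversible score counts maximal present-only subtrees", {
  expect_equal(as.integer(irreversible_score(
    wt, states_on(c("Physeter_macrocephalus", "Kogia_breviceps")))), 1L)
  expect_equal(as.integer(irreversible_score(
    wt, states_on(c("Tursiops_truncatus", "Physeter_macrocephalus")))), 2L)
})

test_that("parsimony scores match the exhaustive state-assignment oracle", {
  set.seed(23)
  for (rep in 1:60) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    st <- random_binary_states(tr)
    expect_equal(dollo_score(tr, st)$score,
                 oracle_parsimony(tr, st, "dollo"),
                 info = paste("dollo rep", rep))
    expect_equal(as.integer(irreversible_score(tr, st)),
                 oracle_parsimony(tr, st, "irreversible"),
                 info = paste("irrev rep", rep))
  }
})

test_that("parsimony search recovers the generating topology with full support", {
  set.seed(5)
  gen <- read_newick(text = "((A:1,B:1):1,((C:1,D:1):1,(E:1,F:1):1):1);")
  sets <- Filter(function(s) length(s) >= 2 && length(s) <= 4 &&
                   !"A" %in% s, retrohom:::clade_leafsets(gen))
  taxa <- gen$tip.label
  m <- sapply(sample(seq_along(sets), 50, replace = TRUE), function(i) {
    ifelse(taxa %in% sets[[i]], "1", "0")
  })
  rownames(m) <- taxa
  res <- parsimony_search(pa_matrix(m), "dollo", n_bootstrap = 100, seed = 9,
                          outgroup = "A")
  expect_equal(res$score, 0)
  expect_equal(ape::dist.topo(ape::unroot(res$tree), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
  expect_true(all(res$support$support == 100))

  # one conflicting character costs extra steps but not the topology
  m2 <- cbind(m, ifelse(taxa %in% c("B", "F"), "1", "0"))
  res2 <- parsimony_search(pa_matrix(m2), "dollo", n_bootstrap = 100, seed = 9,
                           outgroup = "A")
  expect_equal(ape::dist.topo(ape::unroot(res2$tree), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
  expect_gte(res2$score, 1)
  expect_true(all(res2$support$support >= 0 & res2$support$support <= 100))

  # determinism under a fixed seed
  res3 <- parsimony_search(pa_matrix(m2), "dollo", n_bootstrap = 100, seed = 9,
                           outgroup = "A")
  expect_identical(res3$support, res2$support)
  expect_identical(ape::write.tree(res3$tree), ape::write.tree(res2$tree))
  expect_error(parsimony_search(pa_matrix(m[1:3, ]), "dollo"), "4 taxa")
})

test_that("directional marker test gives exact binomial tail probabilities", {
  expect_equal(directional_marker_test(0, 0), 1)
  expect_equal(directional_marker_test(10, 0), 2^-10)
  expect_equal(directional_marker_test(5, 5), 0.623046875)
  expect_equal(directional_marker_test(0, 5), 1)
  expect_error(directional_marker_test(-1, 2), ">= 0")
  # the paper-scale asymmetry is overwhelmingly significant
  expect_lt(directional_marker_test(529, 39), 1e-100)
})
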