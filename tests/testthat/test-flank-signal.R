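test_that("flank extraction returns width columns per side for all species", {
  lc <- make_toy_locus(flank = 60, present = c("A", "B"), absent = "C")
  fl <- extract_flanks(lc, width = 50)
  expect_setequal(names(fl), c("A", "B", "C"))
  expect_true(all(nchar(fl) == 100))
  expect_false(any(grepl("-", fl)))
  # present and absent species share the homologous flank columns
  expect_identical(fl[["A"]], fl[["C"]])

  # repeat-masked columns vanish from every species
  fl2 <- extract_flanks(lc, width = 50, repeat_mask = 10:19, min_per_side = 30)
  expect_length(fl2, 3)
  expect_true(all(nchar(fl2) == 90))

  # truncated flanks drop every species, each with its own warning
  w <- capture_warnings(fl3 <- extract_flanks(lc, width = 50,
                                              min_per_side = 200))
  expect_length(w, 3)
  expect_match(w, "below", all = TRUE)
  expect_length(fl3, 0)
})

test_that("subset concatenation needs 3 loci and shared species", {
  loci <- lapply(1:3, function(i) {
    make_toy_locus(locus_id = paste0("l", i), flank = 60, seed = 100 + i)
  })
  ds <- concatenate_subset(loci, width = 50, min_per_side = 10)
  expect_s3_class(ds, "flank_dataset")
  expect_true(all(nchar(ds$alignment) == 300))
  expect_error(concatenate_subset(loci[1:2]), "fewer than 3")
  disjoint <- c(loci[1:2], list(make_toy_locus(
    locus_id = "l4", present = c("X", "Y"), absent = "Z", seed = 104)))
  expect_error(concatenate_subset(disjoint, width = 50, min_per_side = 10),
               "shared")
})

test_that("K2P distances match the closed form and are symmetric", {
  # 1000 sites, transitions at exactly 10% of them, no transversions
  base <- strrep("ACGT", 250)
  # transition-flip (A<->G, C<->T) the first 100 positions only
  s2 <- paste0(chartr("ACGT", "GTAC", substr(base, 1, 100)),
               substr(base, 101, 1000))
  aln <- c(a = base, b = s2)
  d <- k2p_distance_matrix(aln)
  expect_equal(d["a", "b"], k2p_closed_form(P = 0.1, Q = 0), tolerance = 1e-12)
  expect_equal(d["a", "b"], d["b", "a"])
  expect_equal(unname(diag(d)), c(0, 0))
  # identical rows are at distance zero
  expect_equal(k2p_distance_matrix(c(x = base, y = base))["x", "y"], 0)
  # random alignments give symmetric matrices
  set.seed(3)
  rnd <- setNames(replicate(5, paste(sample(c("A", "C", "G", "T"), 400,
                                            replace = TRUE), collapse = "")),
                  letters[1:5])
  dr <- suppressWarnings(k2p_distance_matrix(rnd, ceiling = 5))
  expect_equal(dr, t(dr), tolerance = 1e-12)
})

test_that("NJ reconstructs additive and ultrametric distances", {
  gen <- read_newick(text = "((A:2,B:3):1,(C:1.5,D:2.5):2);")
  d <- cophenetic(gen)
  tr <- nj_tree(d)
  expect_equal(ape::dist.topo(tr, ape::unroot(gen)), 0, ignore_attr = TRUE)
  # additive distances are reproduced exactly by the NJ tree
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # ultrametric distances: same topology as average-linkage clustering
  um <- read_newick(text = "((A:1,B:1):2,(C:2,D:2):1);")
  du <- cophenetic(um)
  upgma <- ape::as.phylo(stats::hclust(as.dist(du), method = "average"))
  expect_equal(ape::dist.topo(nj_tree(du), ape::unroot(upgma)), 0,
               ignore_attr = TRUE)
  # ties resolve deterministically
  deq <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(deq) <- 0
  expect_identical(ape::write.tree(nj_tree(deq)), ape::write.tree(nj_tree(deq)))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("bootstrap support is deterministic and permutation-invariant", {
  set.seed(8)
  p <- sim_params(n_loci = 1, seed = 21, flank_len = 300)
  lc <- simulate_dataset(p)$loci[[1]]
  fl <- extract_flanks(lc, width = 250)
  b1 <- bootstrap_bipartition_support(fl, n_reps = 100, seed = 4)
  b2 <- bootstrap_bipartition_support(fl, n_reps = 100, seed = 4)
  expect_identical(b1$support, b2$support)
  # permuting the input rows does not change the supports
  b3 <- bootstrap_bipartition_support(fl[rev(seq_along(fl))], n_reps = 100,
                                      seed = 4)
  expect_identical(b3$support[order(b3$support$clade), ],
                   b1$support[order(b1$support$clade), ],
                   ignore_attr = TRUE)
  expect_true(all(b1$support$support >= 0 & b1$support$support <= 100))
  expect_error(bootstrap_bipartition_support(fl, n_reps = 10), ">= 100")
})

test_that("concordance verdicts separate homoplasy from lineage sorting", {
  cfg <- whale_config()
  taxa <- letters[1:6]
  sup <- data.frame(clade = c("a,b", "c,d", "a,b,c,d"),
                    support = c(100, 95, 60))
  # flanks back the reference clade, insertions conflict with it: homoplasy
  v <- concordance_verdict(retro_clade = c("a", "c"), sup,
                           reference_clade = c("a", "b"), taxa, cfg,
                           mode = "concatenated")
  expect_identical(v$verdict, "true_homoplasy")
  # flanks back the same discordant clade as the insertions: ILS/introgression
  v <- concordance_verdict(retro_clade = c("c", "d"), sup,
                           reference_clade = c("a", "b", "e"), taxa, cfg,
                           mode = "concatenated")
  expect_identical(v$verdict, "ils_or_introgression")
  # per-locus mode accepts 85% under its 80% threshold
  sup2 <- data.frame(clade = "a,b", support = 85)
  v <- concordance_verdict(c("a", "c"), sup2, c("a", "b"), taxa, cfg,
                           mode = "per_locus")
  expect_identical(v$verdict, "true_homoplasy")
  # the same support is insufficient for concatenated mode
  v <- concordance_verdict(c("a", "c"), sup2, c("a", "b"), taxa, cfg,
                           mode = "concatenated")
  expect_identical(v$verdict, "uninformative")
  # complements of a bipartition count as the same split
  sup3 <- data.frame(clade = "c,d,e,f", support = 97)
  v <- concordance_verdict(c("a", "c"), sup3, c("a", "b"), taxa, cfg,
                           mode = "concatenated")
  expect_identical(v$verdict, "true_homoplasy")
})
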