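test_that("simulation is byte-identical under a fixed seed", {
  p <- sim_params(n_loci = 6, seed = 77, hotspot_fraction = 0.3,
                  p_deletion = 0.2, p_ils = 0.2, flank_len = 80)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(p, out_dir = d1)
  simulate_dataset(p, out_dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("all-zero event rates give purely diagnostic loci and 0% homoplasy", {
  wt <- whale_tree()
  cfg <- whale_config()
  p <- sim_params(n_loci = 50, seed = 13, flank_len = 60)
  d <- simulate_dataset(p)
  expect_true(all(d$truth$event == "diagnostic"))
  asg <- lapply(d$loci, assign_pattern, tree = wt, config = cfg)
  verd <- do.call(rbind, lapply(d$loci, classify_locus, config = cfg))
  est <- estimate_parallel_frequency(asg, verd, "Tursiops_truncatus",
                                     "Physeter_macrocephalus")
  expect_equal(est$value, 0)
})

test_that("deletion restores the pre-insertion site exactly", {
  p <- sim_params(n_loci = 30, seed = 19, p_deletion = 1, flank_len = 60)
  d <- simulate_dataset(p)
  for (i in seq_along(d$loci)) {
    lc <- d$loci[[i]]
    del_sp <- d$truth$detail[i]
    del_seq <- gsub("-", "", lc$alignment[[del_sp]])
    # re-inserting the element at the same site reproduces a carrier-style
    # sequence: the deleted species' ungapped sequence equals what any
    # never-inserted species looks like (flank + single TSD + flank)
    out_seq <- gsub("-", "", lc$alignment[["Bos_taurus"]])
    expect_equal(nchar(del_seq), nchar(out_seq))
    expect_identical(lc$calls[[del_sp]]$state, "absent")
    # and splicing a carrier's inserted block into the deleted species at the
    # breakpoints reconstructs a full-length carrier sequence
    carrier <- Filter(function(c) c$state == "present", lc$calls)[[1]]
    block <- substr(lc$alignment[[carrier$species]], carrier$start + 1,
                    carrier$end)
    rebuilt <- paste0(substr(lc$alignment[[del_sp]], 1, carrier$start),
                      block,
                      substr(lc$alignment[[del_sp]], carrier$end + 1,
                             nchar(lc$alignment[[del_sp]])))
    expect_equal(nchar(gsub("-", "", rebuilt)),
                 nchar(gsub("-", "", lc$alignment[[carrier$species]])))
  }
})

test_that("discordance probability matches the coalescent closed form", {
  expect_equal(ils_discordance_probability(0, 13000), 2 / 3)
  expect_equal(ils_discordance_probability(2 * 13000, 13000),
               (2 / 3) * exp(-1))
  expect_lt(ils_discordance_probability(1e9, 13000), 1e-10)
  # empirical draw frequency agrees within 3 standard errors
  set.seed(41)
  for (t_gen in c(5000, 26000, 60000)) {
    n <- 12000
    draws <- replicate(n, retrohom:::draw_genealogy(t_gen, 13000))
    p_hat <- mean(draws != "concordant")
    p_true <- ils_discordance_probability(t_gen, 13000)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(p_hat - p_true), 3 * se)
  }
})

test_that("ILS loci carry a discordant genealogy painted on both signals", {
  p <- sim_params(n_loci = 60, seed = 55, p_ils = 1, flank_len = 200)
  d <- simulate_dataset(p)
  ils <- which(d$truth$event == "ils")
  expect_gt(length(ils), 3)
  for (i in head(ils, 4)) {
    pres <- strsplit(d$truth$presence[i], ",")[[1]]
    expect_true("Platanista_minor" %in% pres)
    # the presence set is the moving lineage plus exactly one host clade
    expect_gt(length(pres), 1)
  }
})

test_that("benchmark suite emits parseable datasets with 1:1 truth joins", {
  out <- tempfile()
  dirs <- make_benchmark_suite(out, seed = 3, n_loci = 4)
  expect_gte(length(dirs), 6)
  expect_setequal(names(dirs),
                  c("diagnostic", "parallel_precise",
                    "parallel_nearly_precise", "parallel_non_homoplasious",
                    "deletion", "ils"))
  for (nm in names(dirs)) {
    ds <- read_dataset(dirs[[nm]])
    expect_length(ds$loci, 4)
    ids <- vapply(ds$loci, function(l) l$locus_id, character(1))
    expect_setequal(ids, ds$truth$locus_id)
    expect_false(anyDuplicated(ds$truth$locus_id) > 0)
  }
})

test_that("end-to-end category confusion matrix is diagonally dominant", {
  wt <- whale_tree()
  cfg <- whale_config()
  p <- sim_params(n_loci = 150, seed = 7, hotspot_fraction = 0.3,
                  parallel_mix = c(precise = 0.4, nearly_precise = 0.3,
                                   non_homoplasious = 0.3),
                  p_deletion = 0.15, p_ils = 0.3, flank_len = 60)
  d <- simulate_dataset(p)
  asg <- lapply(d$loci, assign_pattern, tree = wt, config = cfg)
  pred <- vapply(asg, function(a) a$category, character(1))
  verd <- do.call(rbind, lapply(d$loci, classify_locus, config = cfg))

  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  truth <- d$truth$event
  expect_identical(modal(pred[truth == "diagnostic"]), "diagnostic")
  expect_identical(modal(pred[truth == "deletion"]), "precise_deletion")
  if (any(truth == "ils")) {
    expect_identical(modal(pred[truth == "ils"]), "conflict_ils_candidate")
  }
  for (ev in c("parallel_precise", "parallel_nearly_precise")) {
    expect_identical(modal(pred[truth == ev]), "conflict_parallel_candidate")
  }
  # classification of pair verdicts: precision/recall of orthologous_* vs
  # non-homoplasious calls on co-located pairs
  vt <- merge(verd, d$truth, by = "locus_id")
  is_orth_truth <- vt$event %in% c("parallel_precise",
                                   "parallel_nearly_precise", "diagnostic",
                                   "deletion", "ils")
  is_orth_pred <- vt$category %in% c("orthologous_precise",
                                     "orthologous_nearly_precise")
  tp <- sum(is_orth_truth & is_orth_pred)
  precision <- tp / sum(is_orth_pred)
  recall <- tp / sum(is_orth_truth)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})
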