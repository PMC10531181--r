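# Independent oracles and fixture builders used across the suite.

# Exhaustive parsimony oracle: enumerate every ancestral-state assignment
# (free nodes = internal nodes plus "?" leaves) and minimize the relevant
# event count. A gain is a 0->1 edge, or the root being in state 1 (the
# character arose on the stem); a loss is a 1->0 edge.
oracle_parsimony <- function(tree, states, mode = c("dollo", "irreversible")) {
  mode <- match.arg(mode)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  fixed <- rep(NA_integer_, n_node)
  s <- states[tree$tip.label]
  fixed[seq_len(n_tip)][s == "1"] <- 1L
  fixed[seq_len(n_tip)][s == "0"] <- 0L
  free <- which(is.na(fixed))
  k <- length(free)
  n_masks <- 2^k
  asg <- matrix(rep(fixed, each = n_masks), n_masks, n_node)
  if (k > 0) {
    bits <- sapply(seq_len(k), function(j) bitwAnd(seq_len(n_masks) - 1,
                                                   2^(j - 1)) > 0)
    asg[, free] <- bits + 0L
  }
  pa <- asg[, tree$edge[, 1], drop = FALSE]
  ch <- asg[, tree$edge[, 2], drop = FALSE]
  gains <- rowSums(pa == 0 & ch == 1) + (asg[, root] == 1)
  losses <- rowSums(pa == 1 & ch == 0)
  if (mode == "dollo") {
    ok <- gains == 1
    if (!any(ok)) return(Inf)
    min(losses[ok])
  } else {
    ok <- losses == 0
    if (!any(ok)) return(Inf)
    min(gains[ok])
  }
}

random_binary_states <- function(tree, p_missing = 0.15) {
  repeat {
    s <- sample(c("0", "1", "?"), length(tree$tip.label), replace = TRUE,
                prob = c((1 - p_missing) / 2, (1 - p_missing) / 2, p_missing))
    if (any(s == "1") && any(s == "0")) break
  }
  setNames(s, tree$tip.label)
}

# closed-form Kimura 2-parameter distance
k2p_closed_form <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# hand-built 3-species locus: flank | TSD | element | tail | TSD | flank
make_toy_locus <- function(locus_id = "toy", flank = 60, tsd = "ACGTACGTAC",
                           elem = strrep("GATTACA", 10), tail = "AAAAAAAAAA",
                           present = c("A", "B"), absent = "C",
                           missing = character(0), seed = 99) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed); on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    code
  }
  withr_seed({
    left <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                  collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                   collapse = "")
    block <- paste0(elem, tail, tsd)
    start <- flank + nchar(tsd)
    end <- start + nchar(block)
    species <- c(present, absent, missing)
    aln <- setNames(vapply(species, function(sp) {
      if (sp %in% present) paste0(left, tsd, block, right)
      else paste0(left, tsd, strrep("-", nchar(block)), right)
    }, character(1)), species)
    calls <- lapply(species, function(sp) {
      if (sp %in% present) {
        insertion_call(sp, "present", family = "CHR2", orientation = "+",
                       start = start, end = end, tsd_left = tsd,
                       tsd_right = tsd, tail = tail)
      } else if (sp %in% absent) {
        insertion_call(sp, "absent")
      } else {
        insertion_call(sp, "missing")
      }
    })
    locus_record(locus_id, aln, calls, flank_width = flank)
  })
}

whale_outgroups <- c("Bos_taurus", "Hippopotamus_amphibius")

whale_config <- function(...) {
  pipeline_config(outgroup_species = whale_outgroups,
                  reference_species = "Tursiops_truncatus", ...)
}
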