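# Mapping presence/absence patterns onto a reference topology and scoring
# binary characters under Dollo (single gain, unlimited losses) and
# irreversible/Camin-Sokal (gains only) parsimony. Retrotransposon insertions
# are effectively irreversible characters: a shared insertion is near-certain
# evidence of common ancestry, so any conflicting pattern is explained by
# parallel insertion, precise deletion, or incomplete lineage sorting.

# --- small rooted-tree helpers ------------------------------------------------

tree_index <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  parent <- integer(n_node)
  children <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c <- tree$edge[i, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  depth <- integer(n_node)
  # preorder depths
  ord <- root
  i <- 1L
  while (i <= length(ord)) {
    nd <- ord[i]
    for (ch in children[[nd]]) {
      depth[ch] <- depth[nd] + 1L
      ord <- c(ord, ch)
    }
    i <- i + 1L
  }
  list(n_tip = n_tip, n_node = n_node, parent = parent, children = children,
       root = root, preorder = ord)
}

mrca_of <- function(idx, nodes) {
  cur <- nodes[1]
  for (nd in nodes[-1]) {
    a <- cur; b <- nd
    while (a != b) {
      # walk the deeper one up
      da <- node_depth_(idx, a); db <- node_depth_(idx, b)
      if (da >= db) a <- idx$parent[a] else b <- idx$parent[b]
    }
    cur <- a
  }
  cur
}

node_depth_ <- function(idx, node) {
  d <- 0L
  while (node != idx$root) { node <- idx$parent[node]; d <- d + 1L }
  d
}

# per-node flags: does the clade contain a present (1) / absent (0) tip?
node_flags <- function(idx, tip_state) {
  has_p <- logical(idx$n_node); has_a <- logical(idx$n_node)
  has_p[seq_len(idx$n_tip)] <- tip_state == "1"
  has_a[seq_len(idx$n_tip)] <- tip_state == "0"
  for (nd in rev(idx$preorder)) {
    for (ch in idx$children[[nd]]) {
      has_p[nd] <- has_p[nd] || has_p[ch]
      has_a[nd] <- has_a[nd] || has_a[ch]
    }
  }
  list(has_present = has_p, has_absent = has_a)
}

states_for_tree <- function(tree, states) {
  if (is.null(names(states))) stop("states must be named by species", call. = FALSE)
  s <- states[tree$tip.label]
  s[is.na(s)] <- "?"
  if (!all(s %in% c("0", "1", "?"))) {
    stop("states must be 0, 1 or ?", call. = FALSE)
  }
  unname(s)
}

#' Dollo parsimony score of a binary character on a rooted tree
#'
#' Under Dollo parsimony a character (here: a retrotransposon insertion) is
#' gained exactly once and may be lost any number of times. The gain is placed
#' on the most recent common ancestor of the taxa carrying the insertion; the
#' score is the number of losses, i.e. the number of maximal subtrees under
#' the gain node whose (non-missing) leaves all lack the insertion. `?` taxa
#' are compatible with either state and never force a loss.
#'
#' @param tree Rooted `phylo` tree.
#' @param states Named vector over tip labels with values `"0"`, `"1"`, `"?"`.
#' @return List with `score` (number of losses), `gain` (node id of the
#'   single gain), `losses` (node ids of the loss subtree roots).
#' @export
dollo_score <- function(tree, states) {
  idx <- tree_index(tree)
  s <- states_for_tree(tree, states)
  present <- which(s == "1")
  if (length(present) == 0L) {
    stop("all-absent character has no Dollo gain", call. = FALSE)
  }
  gain <- if (length(present) == 1L) present else mrca_of(idx, present)
  fl <- node_flags(idx, s)
  losses <- integer(0)
  visit <- function(node) {
    if (!fl$has_absent[node]) return(invisible(NULL))
    if (!fl$has_present[node]) {
      losses <<- c(losses, node)
      return(invisible(NULL))
    }
    for (ch in idx$children[[node]]) visit(ch)
  }
  if (gain > idx$n_tip) for (ch in idx$children[[gain]]) visit(ch)
  list(score = length(losses), gain = gain, losses = losses)
}

#' Irreversible (Camin-Sokal) parsimony score of a binary character
#'
#' Losses are forbidden: the score is the minimum number of independent
#' 0 to 1 gains, i.e. the number of maximal subtrees containing only
#' insertion-bearing (or `?`) leaves needed to cover all present taxa.
#'
#' @inheritParams dollo_score
#' @return Integer score, with attribute `gains` giving the gain node ids.
#' @export
irreversible_score <- function(tree, states) {
  idx <- tree_index(tree)
  s <- states_for_tree(tree, states)
  present <- which(s == "1")
  if (length(present) == 0L) {
    stop("all-absent character has no gain", call. = FALSE)
  }
  fl <- node_flags(idx, s)
  gains <- integer(0)
  for (tp in present) {
    cur <- tp
    while (cur != idx$root && !fl$has_absent[idx$parent[cur]]) {
      cur <- idx$parent[cur]
    }
    if (cur == idx$root || !fl$has_absent[cur]) {
      # can only happen when no absent leaf exists at all
    }
    gains <- c(gains, cur)
  }
  gains <- unique(gains)
  structure(length(gains), gains = gains)
}

# --- pattern assignment -------------------------------------------------------

locus_states <- function(locus, config = pipeline_config()) {
  st <- vapply(locus$calls, function(c) c$state, character(1))
  out <- ifelse(st == "present", "1", ifelse(st == "absent", "0", "?"))
  names(out) <- names(locus$calls)
  out[names(out) %in% config$excluded_species] <- "?"
  out
}

clade_leafsets <- function(tree) {
  idx <- tree_index(tree)
  sets <- vector("list", idx$n_node)
  sets[seq_len(idx$n_tip)] <- as.list(tree$tip.label)
  for (nd in rev(idx$preorder)) {
    for (ch in idx$children[[nd]]) {
      sets[[nd]] <- c(sets[[nd]], sets[[ch]])
    }
  }
  sets
}

#' Assign a locus's presence/absence pattern to a phylogenetic category
#'
#' Compares the set of insertion-bearing species against the clades of the
#' reference species tree (restricted to species with data):
#' \itemize{
#'   \item presence set equals a clade: `diagnostic` marker for that clade;
#'   \item exactly one ingroup species lacks an otherwise clade-wide
#'     insertion: `precise_deletion` (one loss is more parsimonious than many
#'     parallel gains);
#'   \item presence set conflicts with the topology: `conflict_parallel_candidate`
#'     when the longest conflicting internal branch exceeds the ILS window
#'     (polymorphism cannot plausibly persist that long),
#'     otherwise `conflict_ils_candidate`;
#'   \item outgroup presence, no present ingroup species, or no applicable
#'     rule: `ambiguous`.
#' }
#'
#' @param locus A [locus_record()], or a named states vector
#'   (`"0"/"1"/"?"`) over species.
#' @param tree Rooted reference `phylo` with branch lengths in million years.
#' @param config A [pipeline_config()]; uses `outgroup_species`,
#'   `excluded_species`, `reference_species` and `ils_window_my`.
#' @return A `pattern_assignment`: list with `locus_id`, `presence`,
#'   `absence`, `missing`, `matched_clade` (leaf labels or NULL), `category`,
#'   `deletion_species` (or NA), `max_conflict_branch_my` (or NA).
#' @export
assign_pattern <- function(locus, tree, config = pipeline_config()) {
  if (inherits(locus, "locus_record")) {
    states <- locus_states(locus, config)
    locus_id <- locus$locus_id
  } else {
    states <- locus
    states[names(states) %in% config$excluded_species] <- "?"
    locus_id <- NA_character_
  }
  sp <- intersect(tree$tip.label, names(states))
  states <- states[sp]
  outg <- intersect(config$outgroup_species, sp)
  ingroup <- setdiff(sp, outg)
  presence <- sp[states == "1"]
  absence <- sp[states == "0"]
  missing <- sp[states == "?"]

  res <- list(locus_id = locus_id, presence = presence, absence = absence,
              missing = missing, matched_clade = NULL,
              category = "ambiguous", deletion_species = NA_character_,
              max_conflict_branch_my = NA_real_)
  class(res) <- "pattern_assignment"

  if (any(presence %in% outg) || length(presence) == 0L) return(res)

  nonmiss <- setdiff(sp, missing)
  sets <- clade_leafsets(tree)
  restrict <- function(leaves) sort(intersect(leaves, nonmiss))
  p_sorted <- sort(presence)
  # diagnostic: presence set equals some clade, restricted to observed species
  for (s in sets) {
    if (identical(restrict(s), p_sorted) && !any(s %in% outg)) {
      res$matched_clade <- s
      res$category <- "diagnostic"
      return(res)
    }
  }
  # precise deletion: presence plus exactly one absent species forms a clade
  # (one loss inside that clade is cheaper than many parallel gains)
  ingroup_absent <- intersect(absence, ingroup)
  candidates <- list()
  for (a in ingroup_absent) {
    target <- sort(c(p_sorted, a))
    for (s in sets) {
      if (identical(restrict(s), target) && !any(s %in% outg)) {
        candidates[[a]] <- s
        break
      }
    }
  }
  if (length(candidates) == 1L) {
    res$matched_clade <- candidates[[1]]
    res$category <- "precise_deletion"
    res$deletion_species <- names(candidates)
    return(res)
  }
  # conflict: a two-lineage shared-insertion pattern violating the topology.
  # Classified by the longest internal branch whose bipartition the pattern
  # violates: hemiplasy requires the insertion polymorphism to survive that
  # branch, implausible beyond the ILS window. Patterns needing three or
  # more independent gains are complex scenarios and stay ambiguous.
  states_vec <- setNames(rep("?", length(sp)), sp)
  states_vec[presence] <- "1"
  states_vec[setdiff(sp, c(presence, missing))] <- "0"
  n_lineages <- as.integer(irreversible_score(tree, states_vec))
  conf <- conflicting_branch_lengths(tree, presence,
                                     setdiff(nonmiss, presence))
  if (n_lineages == 2L && length(conf)) {
    res$max_conflict_branch_my <- max(conf)
    res$category <- if (max(conf) > config$ils_window_my) {
      "conflict_parallel_candidate"
    } else {
      "conflict_ils_candidate"
    }
  }
  res
}

# lengths of internal branches whose induced bipartition X|Y has presence and
# absence on both sides (the four-point conflict condition)
conflicting_branch_lengths <- function(tree, presence, absence) {
  sets <- clade_leafsets(tree)
  n_tip <- length(tree$tip.label)
  out <- numeric(0)
  for (i in seq_len(nrow(tree$edge))) {
    child <- tree$edge[i, 2]
    if (child <= n_tip) next
    x <- sets[[child]]
    y <- setdiff(tree$tip.label, x)
    if (any(presence %in% x) && any(presence %in% y) &&
        any(absence %in% x) && any(absence %in% y)) {
      out <- c(out, if (is.null(tree$edge.length)) NA_real_
               else tree$edge.length[i])
    }
  }
  out
}

#' Collect precise-deletion events from pattern assignments
#'
#' Keeps one (locus, species) pair per `precise_deletion` assignment,
#' excluding the screening reference species (its presence is predefined, so
#' deletions in it are invisible by construction) and any excluded species.
#'
#' @param assignments List of [assign_pattern()] results.
#' @param tree Reference tree (used only for validation).
#' @param reference_species Reference species name (or NULL).
#' @param excluded Character vector of excluded species.
#' @return Data frame with columns `locus_id`, `species`.
#' @export
infer_precise_deletions <- function(assignments, tree,
                                    reference_species = NULL,
                                    excluded = character(0)) {
  rows <- lapply(assignments, function(a) {
    if (a$category != "precise_deletion") return(NULL)
    sp <- a$deletion_species
    if (!is.na(sp) && !sp %in% c(reference_species, excluded) &&
        sp %in% tree$tip.label) {
      data.frame(locus_id = a$locus_id, species = sp)
    } else NULL
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(data.frame(locus_id = character(0),
                                       species = character(0)))
  do.call(rbind, rows)
}

# --- parsimony tree search ----------------------------------------------------

hamming_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] != "?" & mat[j, ] != "?"
      d[i, j] <- d[j, i] <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0.5
    }
  }
  as.dist(d)
}

score_matrix <- function(rooted, mat, mode) {
  total <- 0
  for (k in seq_len(ncol(mat))) {
    states <- setNames(mat[, k], rownames(mat))
    total <- total + if (mode == "dollo") {
      dollo_score(rooted, states)$score
    } else {
      as.integer(irreversible_score(rooted, states))
    }
  }
  total
}

root_for_scoring <- function(tree, outgroup) {
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

nni_hillclimb <- function(start, mat, mode, outgroup) {
  best <- start
  best_score <- score_matrix(root_for_scoring(best, outgroup), mat, mode)
  repeat {
    nbrs <- phangorn::nni(best)
    scores <- vapply(nbrs, function(t) {
      score_matrix(root_for_scoring(t, outgroup), mat, mode)
    }, numeric(1))
    if (min(scores) < best_score) {
      best <- nbrs[[which.min(scores)]]
      best_score <- min(scores)
    } else break
  }
  list(tree = best, score = best_score)
}

#' Heuristic parsimony tree search with bootstrap support
#'
#' Searches tree space by NNI hill-climbing from a neighbor-joining starting
#' tree (Hamming distances between the species' presence/absence rows),
#' scoring trees under Dollo or irreversible parsimony. Bootstrap support is
#' computed by resampling characters with replacement, repeating the search,
#' and recording the percentage of replicate trees containing each
#' bipartition of the point-estimate tree. Deterministic for a fixed seed.
#'
#' @param matrix A [pa_matrix()] (species x characters).
#' @param mode `"dollo"` or `"irreversible"`.
#' @param n_bootstrap Number of bootstrap replicates. Default 1000.
#' @param seed Integer random seed.
#' @param outgroup Species used to root the tree for scoring; default the
#'   first row.
#' @return A `parsimony_result`: list with `tree` (rooted `phylo`), `score`,
#'   `per_character` (data frame of per-character scores, gain and loss
#'   nodes), `support` (data frame of bipartitions with bootstrap %), `mode`.
#' @export
parsimony_search <- function(matrix, mode = c("dollo", "irreversible"),
                             n_bootstrap = 1000L, seed = 1L,
                             outgroup = NULL) {
  mode <- match.arg(mode)
  if (!inherits(matrix, "pa_matrix")) matrix <- pa_matrix(matrix)
  if (nrow(matrix) < 4L) stop("need at least 4 taxa", call. = FALSE)
  if (is.null(outgroup)) outgroup <- rownames(matrix)[1]

  with_seed(seed, {
    start <- nj_tree(hamming_dist(matrix))
    fit <- nni_hillclimb(start, matrix, mode, outgroup)
    point <- fit$tree

    boot_trees <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      cols <- sample.int(ncol(matrix), replace = TRUE)
      bmat <- matrix[, cols, drop = FALSE]
      keep <- apply(bmat, 2, function(col) any(col == "1") && any(col == "0"))
      bmat <- bmat[, keep, drop = FALSE]
      boot_trees[[b]] <- if (ncol(bmat) == 0L) start else {
        nni_hillclimb(nj_tree(hamming_dist(bmat)), bmat, mode, outgroup)$tree
      }
    }
    class(boot_trees) <- "multiPhylo"
    support <- bipartition_support_table(point, boot_trees, n_bootstrap)

    rooted <- root_for_scoring(point, outgroup)
    per_char <- do.call(rbind, lapply(seq_len(ncol(matrix)), function(k) {
      states <- setNames(matrix[, k], rownames(matrix))
      ds <- dollo_score(rooted, states)
      is_ <- irreversible_score(rooted, states)
      data.frame(character = k,
                 dollo_losses = ds$score, gain_node = ds$gain,
                 irreversible_gains = as.integer(is_))
    }))
    structure(
      list(tree = rooted, score = fit$score, per_character = per_char,
           support = support, mode = mode, n_bootstrap = n_bootstrap),
      class = "parsimony_result")
  })
}

# run code with a locally-set RNG state, restoring the caller's state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Directional binomial test for marker-count asymmetry
#'
#' Upper-tail binomial probability of observing at least `n_support` markers
#' for the focal grouping among `n_support + n_conflict` informative markers
#' under an even-odds null: `P(X >= n_support | n, p = 0.5)`. This is a
#' simple directional sign test, documented as NOT the KKSC insertion
#' significance model (which accounts for the insertion process itself);
#' it serves as a conservative screening statistic.
#'
#' @param n_support Markers supporting the grouping.
#' @param n_conflict Markers conflicting with it.
#' @return p-value in (0, 1]; 1 when both counts are zero.
#' @export
directional_marker_test <- function(n_support, n_conflict) {
  if (n_support < 0 || n_conflict < 0) stop("counts must be >= 0", call. = FALSE)
  n <- n_support + n_conflict
  if (n == 0L) return(1)
  pbinom(n_support - 1, n, 0.5, lower.tail = FALSE)
}
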