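# Locus simulator: generates presence/absence loci with known ground truth on
# a dated species tree. Flanks evolve by a Jukes-Cantor process along the
# locus genealogy (the species tree, or a discordant gene tree for ILS loci);
# insertions are painted on branches as diagnostic events, on two lineages as
# parallel events with breakpoint jitter, or removed again as precise
# deletions that restore the pre-insertion site.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# JC69: per-site substitution probability over time t at rate mu (subs/site/t)
jc69_mutate <- function(chars, t, rate) {
  p <- 0.75 * (1 - exp(-4 / 3 * rate * t))
  hit <- which(runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(BASES, chars[i]), 1)
  }
  chars
}

# evolve a root sequence down every branch; returns named character vector of
# leaf sequences
evolve_alignment <- function(tree, root_seq, rate) {
  idx <- tree_index(tree)
  seqs <- vector("list", idx$n_node)
  seqs[[idx$root]] <- strsplit(root_seq, "")[[1]]
  edge_len <- setNames(tree$edge.length, tree$edge[, 2])
  for (nd in idx$preorder) {
    if (nd == idx$root) next
    seqs[[nd]] <- jc69_mutate(seqs[[idx$parent[nd]]],
                              edge_len[[as.character(nd)]], rate)
  }
  out <- vapply(seq_len(idx$n_tip), function(i) paste(seqs[[i]], collapse = ""),
                character(1))
  names(out) <- tree$tip.label
  out
}

#' Probability of genealogical discordance across a short internal branch
#'
#' For three lineages separated by an internal branch of `T` generations in a
#' population of effective size `Ne`, the probability that the gene genealogy
#' is discordant with the species tree is `(2/3) * exp(-T / (2 * Ne))`: the
#' two sister lineages fail to coalesce within the branch with probability
#' `exp(-T/(2Ne))`, after which two of the three possible pairings are
#' discordant.
#'
#' @param branch_length_generations Internal branch length in generations.
#' @param Ne Effective population size (individuals).
#' @return Probability in [0, 2/3].
#' @export
ils_discordance_probability <- function(branch_length_generations, Ne) {
  (2 / 3) * exp(-branch_length_generations / (2 * Ne))
}

# mechanistic draw of the genealogy of a triplet across an internal branch:
# exponential coalescence within the branch, otherwise random pairing
draw_genealogy <- function(branch_length_generations, Ne) {
  t_coal <- stats::rexp(1, rate = 1 / (2 * Ne))
  if (t_coal < branch_length_generations) return("concordant")
  sample(c("concordant", "discordant_a", "discordant_b"), 1)
}

# regraft `moving_tip` onto the stem edge of the clade defined by
# `target_tips`, at `attach_frac` of that edge's length above the clade crown
gene_tree_discordant <- function(tree, moving_tip, target_tips,
                                 attach_frac = 0.1) {
  pruned <- ape::drop.tip(tree, moving_tip)
  node <- if (length(target_tips) == 1L) {
    which(pruned$tip.label == target_tips)
  } else {
    ape::getMRCA(pruned, target_tips)
  }
  stem_edge <- which(pruned$edge[, 2] == node)
  stem_len <- pruned$edge.length[stem_edge]
  pos <- attach_frac * stem_len
  heights <- ape::node.depth.edgelength(pruned)
  tip_height <- max(heights)
  attach_height <- heights[node] - pos
  tip_tree <- structure(
    list(edge = matrix(c(2L, 1L), 1, 2), tip.label = moving_tip,
         edge.length = tip_height - attach_height, Nnode = 1L),
    class = "phylo")
  ape::bind.tree(pruned, tip_tree, where = node, position = pos)
}

#' Dated toothed-whale reference tree
#'
#' A 14-taxon tree of toothed whales plus a baleen-whale and two terrestrial
#' outgroups, with branch lengths in million years (MY) following published
#' cetacean timetrees: Odontoceti crown at 34.1 MYA, an 11.7-MY Physeteroidea
#' stem, and a sub-MY radiation of Platanistidae, Ziphiidae and Delphinida
#' within Synrhina.
#'
#' @return Rooted ultrametric `phylo` tree.
#' @export
whale_tree <- function() {
  txt <- paste0(
    "(Bos_taurus:56,(Hippopotamus_amphibius:53,(Balaenoptera_acutorostrata:",
    "36.7,((Physeter_macrocephalus:22.4,Kogia_breviceps:22.4):11.7,",
    "(Platanista_minor:29.6,((Ziphius_cavirostris:16,Mesoplodon_bidens:16):",
    "12.8,((Lipotes_vexillifer:23,(Inia_geoffrensis:14,Pontoporia_blainvillei",
    ":14):9):1.5,(Tursiops_truncatus:19,(Phocoena_phocoena:15,",
    "Delphinapterus_leucas:15):4):5.5):4.3):0.8):4.5):2.6):16.3):3);")
  read_newick(text = txt)
}

#' Simulation parameters
#'
#' The event mix is controlled by per-locus probabilities: with probability
#' `hotspot_fraction` a locus receives two independent insertions at the same
#' hot site on the two `parallel_pair` lineages (split into precise, nearly
#' precise and non-homoplasious sub-types by `parallel_mix`); with
#' `p_deletion` a clade-wide insertion is precisely deleted in one nested
#' species; with `p_ils` an insertion arises across the configured short
#' internal branch and segregates through it (only genealogically discordant
#' outcomes are labelled `ils`); the remainder are diagnostic insertions
#' placed on a branch drawn proportionally to branch length.
#'
#' @param tree Dated species tree (`phylo`, branch lengths in MY). Default
#'   [whale_tree()].
#' @param n_loci Number of loci to simulate.
#' @param seed Integer random seed (mandatory).
#' @param hotspot_fraction Probability a locus is a parallel-insertion event.
#' @param parallel_mix Probabilities (summing to 1) of the
#'   `precise`, `nearly_precise`, `non_homoplasious` parallel sub-types.
#' @param p_deletion Probability a locus is a precise-deletion event.
#' @param p_ils Probability a locus is drawn from the ILS process.
#' @param parallel_pair Two species receiving parallel insertions.
#' @param deletion_clade_tips Two species whose MRCA defines the clade whose
#'   stem carries deletion-substrate insertions.
#' @param ils_moving_tip,ils_clade_a,ils_clade_b ILS triplet: the lineage
#'   that may sort discordantly, and two species defining each alternative
#'   host clade (single species name = that clade's representative pair).
#' @param Ne Effective population size for the ILS branch (individuals).
#' @param generation_time Generation time in years.
#' @param flank_len Flank length per side (nt).
#' @param subst_rate Flank substitution rate (subs/site/MY).
#' @param tsd_range TSD length range (nt), drawn uniformly.
#' @param families Named list of element family consensus lengths.
#' @param tail_len Element tail length (nt).
#' @param outgroups Species never receiving insertions (always absent).
#' @param reference_species Species with predefined presence; never chosen as
#'   a deletion lineage.
#' @param diagnostic_branches Optional character vector of species names;
#'   when given, diagnostic insertions are placed only on those terminal
#'   branches (length-weighted), emulating a lineage-restricted n-way screen.
#'   Default NULL: any all-ingroup branch.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(tree = whale_tree(), n_loci = 100L, seed,
                       hotspot_fraction = 0,
                       parallel_mix = c(precise = 1, nearly_precise = 0,
                                        non_homoplasious = 0),
                       p_deletion = 0, p_ils = 0,
                       parallel_pair = c("Tursiops_truncatus",
                                         "Physeter_macrocephalus"),
                       deletion_clade_tips = c("Platanista_minor",
                                               "Tursiops_truncatus"),
                       ils_moving_tip = "Platanista_minor",
                       ils_clade_a = c("Tursiops_truncatus",
                                       "Lipotes_vexillifer"),
                       ils_clade_b = c("Ziphius_cavirostris",
                                       "Mesoplodon_bidens"),
                       Ne = 13000, generation_time = 21.1,
                       flank_len = 200L, subst_rate = 0.002,
                       tsd_range = c(8L, 16L),
                       families = list(CHR2 = 300L, CHR2B = 260L),
                       tail_len = 20L,
                       outgroups = c("Bos_taurus", "Hippopotamus_amphibius"),
                       reference_species = "Tursiops_truncatus",
                       diagnostic_branches = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(hotspot_fraction, p_deletion, p_ils)
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1) {
    stop("event probabilities must be in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  if (n_loci <= 0) stop("n_loci must be > 0", call. = FALSE)
  if (abs(sum(parallel_mix) - 1) > 1e-9) {
    stop("parallel_mix must sum to 1", call. = FALSE)
  }
  sp <- tree$tip.label
  need <- c(parallel_pair, deletion_clade_tips, outgroups)
  if (!all(need %in% sp)) {
    stop("species missing from tree: ",
         paste(setdiff(need, sp), collapse = ", "), call. = FALSE)
  }
  structure(as.list(environment()), class = "sim_params")
}

# descendants (tip labels) of each edge's child node
edge_tipsets <- function(tree) {
  sets <- clade_leafsets(tree)
  lapply(tree$edge[, 2], function(nd) sets[[nd]])
}

#' Simulate a locus dataset with known event truth
#'
#' @param params A [sim_params()] object.
#' @param out_dir Optional directory; when given, writes one FASTA + sidecar
#'   per locus, the tree (`tree.nwk`) and the truth table (`truth.tsv`).
#' @return List with `loci` (list of [locus_record()]), `truth` (data frame:
#'   `locus_id`, `event`, `presence`, `detail`), `tree`, `params`.
#' @export
simulate_dataset <- function(params, out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, simulate_dataset_(params, out_dir))
}

simulate_dataset_ <- function(p, out_dir) {
  tree <- p$tree
  ingroup_sp <- setdiff(tree$tip.label, p$outgroups)
  fam_names <- names(p$families)
  # fixed per-dataset family consensus sequences and consensus tails; every
  # copy of a family carries a lightly mutated copy of the consensus tail
  consensus <- lapply(p$families, function(len) random_seq(len))
  consensus_tail <- lapply(p$families, function(len) random_tail(p$tail_len))
  copy_tail <- function(family) {
    paste(jc69_mutate(strsplit(consensus_tail[[family]], "")[[1]], 1, 0.05),
          collapse = "")
  }
  divergent_tail <- function(family) {
    repeat {
      cand <- random_tail(p$tail_len)
      if (tail_divergence(cand, consensus_tail[[family]]) >= 0.35) return(cand)
    }
  }

  # branches available for diagnostic insertions: all-ingroup clades
  tipsets <- edge_tipsets(tree)
  ok_edge <- vapply(tipsets, function(s) all(s %in% ingroup_sp), logical(1))
  if (!is.null(p$diagnostic_branches)) {
    ok_edge <- ok_edge & vapply(tipsets, function(s) {
      length(s) == 1L && s %in% p$diagnostic_branches
    }, logical(1))
  }
  edge_w <- tree$edge.length * ok_edge
  del_clade <- clade_leafsets(tree)[[ape::getMRCA(tree, p$deletion_clade_tips)]]

  # ILS geometry: the branch between MRCA(moving, a, b) and MRCA(a, b)
  ils_ab <- c(p$ils_clade_a[1], p$ils_clade_b[1])
  node_ab <- ape::getMRCA(tree, ils_ab)
  ils_T_my <- tree$edge.length[which(tree$edge[, 2] == node_ab)]
  ils_T_gen <- ils_T_my * 1e6 / p$generation_time
  sets <- clade_leafsets(tree)
  clade_a <- sets[[mrca_or_tip(tree, p$ils_clade_a)]]
  clade_b <- sets[[mrca_or_tip(tree, p$ils_clade_b)]]

  loci <- vector("list", p$n_loci)
  truth <- vector("list", p$n_loci)
  for (i in seq_len(p$n_loci)) {
    locus_id <- sprintf("L%05d", i)
    u <- runif(1)
    kind <- if (u < p$hotspot_fraction) {
      sub <- sample(names(p$parallel_mix), 1, prob = p$parallel_mix)
      paste0("parallel_", sub)
    } else if (u < p$hotspot_fraction + p$p_deletion) {
      "deletion"
    } else if (u < p$hotspot_fraction + p$p_deletion + p$p_ils) {
      "ils_draw"
    } else {
      "diagnostic"
    }

    tsd_len <- sample(seq.int(p$tsd_range[1], p$tsd_range[2]), 1)
    genealogy <- tree
    deletion_species <- NA_character_
    events <- list()

    if (kind == "diagnostic") {
      e <- sample.int(nrow(tree$edge), 1, prob = edge_w)
      carriers <- tipsets[[e]]
      events <- list(list(species = carriers, family = fam_names[1],
                          orientation = "+", jitter = 0L,
                          tail = copy_tail(fam_names[1])))
      event_label <- "diagnostic"
    } else if (startsWith(kind, "parallel")) {
      jit2 <- switch(sub, precise = sample(0:1, 1),
                     nearly_precise = sample(2:3, 1),
                     non_homoplasious = sample(0:1, 1))
      fam2 <- fam_names[1]; ori2 <- "+"
      tail2 <- copy_tail(fam2)
      if (sub == "non_homoplasious") {
        # independent insertions distinguishable by family, orientation, or
        # a clearly divergent tail
        mode_nh <- sample(if (length(fam_names) > 1) 1:3 else 2:3, 1)
        if (mode_nh == 1L) {
          fam2 <- fam_names[2]
          tail2 <- copy_tail(fam2)
        } else if (mode_nh == 2L) {
          ori2 <- "-"
        } else {
          tail2 <- divergent_tail(fam2)
        }
      }
      events <- list(
        list(species = p$parallel_pair[1], family = fam_names[1],
             orientation = "+", jitter = 0L, tail = copy_tail(fam_names[1])),
        list(species = p$parallel_pair[2], family = fam2,
             orientation = ori2, jitter = jit2, tail = tail2))
      event_label <- kind
    } else if (kind == "deletion") {
      deletion_species <- sample(setdiff(del_clade, p$reference_species), 1)
      events <- list(list(species = setdiff(del_clade, deletion_species),
                          family = fam_names[1], orientation = "+",
                          jitter = 0L, tail = copy_tail(fam_names[1])))
      event_label <- "deletion"
    } else { # ils_draw
      draw <- draw_genealogy(ils_T_gen, p$Ne)
      if (draw == "concordant") {
        carriers <- sort(union(clade_a, clade_b))
        events <- list(list(species = carriers, family = fam_names[1],
                            orientation = "+", jitter = 0L,
                            tail = copy_tail(fam_names[1])))
        event_label <- "diagnostic"
      } else {
        host <- if (draw == "discordant_a") clade_a else clade_b
        carriers <- sort(union(host, p$ils_moving_tip))
        genealogy <- gene_tree_discordant(tree, p$ils_moving_tip, host)
        events <- list(list(species = carriers, family = fam_names[1],
                            orientation = "+", jitter = 0L,
                            tail = copy_tail(fam_names[1])))
        event_label <- "ils"
      }
    }

    loci[[i]] <- build_locus(locus_id, genealogy, events, deletion_species,
                             consensus, tsd_len, p)
    carriers_all <- sort(setdiff(unique(unlist(lapply(events, `[[`, "species"))),
                                 deletion_species))
    truth[[i]] <- data.frame(
      locus_id = locus_id, event = event_label,
      presence = paste(carriers_all, collapse = ","),
      detail = if (!is.na(deletion_species)) deletion_species else "")
  }
  out <- list(loci = loci, truth = do.call(rbind, truth), tree = tree,
              params = p)
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

mrca_or_tip <- function(tree, tips) {
  if (length(tips) == 1L) which(tree$tip.label == tips) else
    ape::getMRCA(tree, tips)
}

random_tail <- function(n) {
  paste(sample(BASES, n, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
        collapse = "")
}

# assemble the locus alignment: left flank | site (future left TSD) | element
# block | right flank, with the element block shared by all co-located events
build_locus <- function(locus_id, genealogy, events, deletion_species,
                        consensus, tsd_len, p) {
  flank <- p$flank_len
  backbone_len <- 2L * flank + tsd_len
  root_seq <- random_seq(backbone_len)
  backbone <- evolve_alignment(genealogy, root_seq, p$subst_rate)

  elem_len <- max(vapply(events, function(e) nchar(consensus[[e$family]]),
                         integer(1)))
  block_w <- elem_len + p$tail_len + tsd_len + 3L
  block_at <- flank + tsd_len  # 0-based column where the block starts

  species <- names(backbone)
  aln <- character(length(species)); names(aln) <- species
  calls <- vector("list", length(species))
  names(calls) <- species

  carrier_event <- list()
  for (e in events) {
    for (sp in setdiff(e$species, deletion_species)) carrier_event[[sp]] <- e
  }

  for (sp in species) {
    bb <- backbone[[sp]]
    left <- substr(bb, 1, flank + tsd_len)
    right <- substr(bb, flank + tsd_len + 1, backbone_len)
    site <- substr(bb, flank + 1, flank + tsd_len)
    e <- carrier_event[[sp]]
    if (is.null(e)) {
      block <- strrep("-", block_w)
      calls[[sp]] <- insertion_call(sp, "absent")
    } else {
      # pad shorter families internally so that both TSD boundaries stay
      # anchored in homologous columns, as an aligner would place them
      body <- paste0(consensus[[e$family]],
                     strrep("-", elem_len - nchar(consensus[[e$family]])),
                     e$tail, site)
      block <- paste0(strrep("-", e$jitter), body,
                      strrep("-", block_w - e$jitter - nchar(body)))
      start <- block_at + e$jitter
      end <- start + nchar(body)
      calls[[sp]] <- insertion_call(sp, "present", family = e$family,
                                    orientation = e$orientation,
                                    start = start, end = end,
                                    tsd_left = site, tsd_right = site,
                                    tail = e$tail)
    }
    aln[sp] <- paste0(left, block, right)
  }
  locus_record(locus_id, aln, unname(calls), flank_width = flank)
}

write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(dataset$tree, file.path(out_dir, "tree.nwk"))
  for (lc in dataset$loci) {
    write_locus_fasta(lc, file.path(out_dir, paste0(lc$locus_id, ".fa")),
                      file.path(out_dir, paste0(lc$locus_id, ".tsv")))
  }
  write.table(dataset$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Read back a simulated (or similarly laid out) dataset directory
#'
#' @param dir Directory holding `tree.nwk`, `L*.fa` + `L*.tsv` locus files
#'   and optionally `truth.tsv`.
#' @return List with `loci`, `tree`, and `truth` (NULL when absent).
#' @export
read_dataset <- function(dir) {
  tree <- read_newick(file.path(dir, "tree.nwk"))
  fastas <- sort(list.files(dir, pattern = "\\.fa$", full.names = TRUE))
  loci <- lapply(fastas, function(f) {
    read_locus_fasta(f, sub("\\.fa$", ".tsv", f))
  })
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    read.delim(truth_path, colClasses = "character")
  } else NULL
  list(loci = loci, tree = tree, truth = truth)
}

#' Write a small benchmark suite, one dataset per event category
#'
#' Emits the dated whale tree plus six canned datasets (diagnostic, precise
#' parallel, nearly precise parallel, non-homoplasious parallel, precise
#' deletion, ILS), each with its truth table, under `out_dir`. Used by the
#' test suite and as a quick-start example.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_loci Loci per dataset. Default 8.
#' @return Named character vector of dataset directories.
#' @export
make_benchmark_suite <- function(out_dir, seed, n_loci = 8L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(whale_tree(), file.path(out_dir, "tree.nwk"))
  mixes <- list(
    diagnostic = list(),
    parallel_precise = list(hotspot_fraction = 1,
                            parallel_mix = c(precise = 1, nearly_precise = 0,
                                             non_homoplasious = 0)),
    parallel_nearly_precise = list(hotspot_fraction = 1,
                                   parallel_mix = c(precise = 0,
                                                    nearly_precise = 1,
                                                    non_homoplasious = 0)),
    parallel_non_homoplasious = list(hotspot_fraction = 1,
                                     parallel_mix = c(precise = 0,
                                                      nearly_precise = 0,
                                                      non_homoplasious = 1)),
    deletion = list(p_deletion = 1),
    ils = list(p_ils = 1))
  dirs <- character(0)
  for (nm in names(mixes)) {
    args <- c(list(n_loci = n_loci, seed = seed + match(nm, names(mixes))),
              mixes[[nm]])
    ds <- simulate_dataset(do.call(sim_params, args),
                           out_dir = file.path(out_dir, nm))
    dirs[nm] <- file.path(out_dir, nm)
  }
  dirs
}
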