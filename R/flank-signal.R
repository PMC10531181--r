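# Flank-signal analysis: the nucleotide sequence flanking a retrotransposon
# locus records the locus's own genealogy. If an insertion pattern conflicts
# with the species tree because of incomplete lineage sorting (ILS) or
# introgression, the flanks share that discordant genealogy; if the pattern
# arose by independent parallel insertions, the flanks follow the species
# tree. Comparing bootstrap support for the competing clades separates the
# two explanations.

#' Extract flanking sequence columns for every species at a locus
#'
#' Takes `width` alignment columns upstream of the left TSD and `width`
#' columns downstream of the right TSD (element-free sequence shared by
#' present and absent species). Columns covered by `repeat_mask` are removed.
#' Species whose usable (non-gap) flank falls below `min_per_side` on either
#' side are dropped with a warning.
#'
#' @param locus A [locus_record()].
#' @param width Flank width per side in alignment columns. Default the
#'   locus's recorded flank width.
#' @param repeat_mask Optional integer vector of 0-based alignment columns
#'   covered by other repeats; removed from the output in every species.
#' @param min_per_side Minimum usable nt per side. Default 50.
#' @return Named character vector of concatenated (left + right) flank
#'   sequences.
#' @export
extract_flanks <- function(locus, width = locus$flank_width,
                           repeat_mask = NULL, min_per_side = 50L) {
  if (width <= 0) stop("width must be > 0", call. = FALSE)
  present <- Filter(function(c) c$state == "present", locus$calls)
  if (length(present) == 0L) {
    stop("locus has no present call to anchor flanks", call. = FALSE)
  }
  anchor <- present[[1]]
  tsd_len <- nchar(anchor$tsd_left)
  aln_len <- nchar(locus$alignment[[1]])
  left_cols <- seq.int(max(0L, anchor$start - tsd_len - width),
                       anchor$start - tsd_len - 1L)
  right_cols <- seq.int(anchor$end, min(aln_len, anchor$end + width) - 1L)
  if (!is.null(repeat_mask)) {
    left_cols <- setdiff(left_cols, repeat_mask)
    right_cols <- setdiff(right_cols, repeat_mask)
  }
  chars <- function(sp, cols) {
    substring(locus$alignment[[sp]], cols + 1L, cols + 1L)
  }
  out <- character(0)
  for (sp in names(locus$alignment)) {
    l <- chars(sp, left_cols); r <- chars(sp, right_cols)
    if (sum(l != "-") < min_per_side || sum(r != "-") < min_per_side) {
      warning("species ", sp, " dropped at locus ", locus$locus_id,
              ": flank below ", min_per_side, " nt", call. = FALSE)
      next
    }
    out[sp] <- paste0(paste(l, collapse = ""), paste(r, collapse = ""))
  }
  out
}

#' Concatenate the flanks of a subset of loci into one alignment
#'
#' Column-wise concatenation over the union of species; species lacking a
#' locus are gap-filled for that locus's columns. Subsets with fewer than
#' three loci are rejected (too little signal for a tree).
#'
#' @param loci List of [locus_record()]s.
#' @param width Flank width per side.
#' @param subset_id Identifier carried through to outputs.
#' @param ... Passed to [extract_flanks()].
#' @return A `flank_dataset`: list with `id`, `alignment` (named character
#'   vector), `loci` (ids), `width`, `mode = "concatenated"`.
#' @export
concatenate_subset <- function(loci, width = NULL, subset_id = "subset", ...) {
  if (length(loci) < 3L) {
    stop("subset rejected: fewer than 3 loci", call. = FALSE)
  }
  flanks <- lapply(loci, function(lc) {
    extract_flanks(lc, width = if (is.null(width)) lc$flank_width else width,
                   ...)
  })
  shared <- Reduce(intersect, lapply(flanks, names))
  if (length(shared) == 0L) {
    stop("no species shared across subset loci", call. = FALSE)
  }
  species <- Reduce(union, lapply(flanks, names))
  parts <- lapply(flanks, function(f) {
    len <- nchar(f[[1]])
    vapply(species, function(sp) {
      if (sp %in% names(f)) f[[sp]] else strrep("-", len)
    }, character(1))
  })
  aln <- do.call(function(...) paste0(...), parts)
  names(aln) <- species
  structure(
    list(id = subset_id, alignment = aln,
         loci = vapply(loci, function(l) l$locus_id, character(1)),
         width = width, mode = "concatenated"),
    class = "flank_dataset")
}

alignment_to_DNAbin <- function(aln) {
  m <- do.call(rbind, strsplit(tolower(aln), ""))
  rownames(m) <- names(aln)
  ape::as.DNAbin(m)
}

#' Pairwise distance matrix for a flank alignment
#'
#' Kimura 2-parameter (default) or Jukes-Cantor distances with pairwise gap
#' deletion. Saturated pairs (undefined distance) are set to `ceiling` with a
#' warning; pairs sharing fewer than `min_sites` gap-free positions trigger a
#' warning.
#'
#' @param dataset A `flank_dataset` or a named character vector alignment.
#' @param model `"K80"` (Kimura 2-parameter) or `"JC69"`.
#' @param ceiling Distance assigned to saturated pairs. Default 5.
#' @param min_sites Minimum pairwise-complete positions. Default 100.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
k2p_distance_matrix <- function(dataset, model = c("K80", "JC69"),
                                ceiling = 5, min_sites = 100L) {
  model <- match.arg(model)
  aln <- if (inherits(dataset, "flank_dataset")) dataset$alignment else dataset
  if (length(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  bin <- alignment_to_DNAbin(aln)
  d <- as.matrix(ape::dist.dna(bin, model = model, pairwise.deletion = TRUE))
  chars <- strsplit(toupper(aln), "")
  ok <- vapply(chars, function(x) x %in% c("A", "C", "G", "T"),
               logical(length(chars[[1]])))
  n <- length(aln)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- sum(ok[, i] & ok[, j])
      if (shared < min_sites) {
        warning("pair ", names(aln)[i], "-", names(aln)[j], " shares only ",
                shared, " complete sites", call. = FALSE)
      }
    }
  }
  if (any(!is.finite(d))) {
    warning("saturated pairs set to ceiling distance ", ceiling, call. = FALSE)
    d[!is.finite(d)] <- ceiling
  }
  diag(d) <- 0
  d
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Standard neighbor-joining agglomeration; negative branch lengths produced
#' by the algorithm are clamped to zero.
#'
#' @param d A `dist` object or symmetric distance matrix (>= 4 taxa).
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (is.matrix(d)) {
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
      stop("distance matrix is not symmetric", call. = FALSE)
    }
    d <- as.dist(d)
  }
  if (attr(d, "Size") < 4L) stop("need at least 4 taxa", call. = FALSE)
  tree <- ape::nj(d)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Bootstrap bipartition support for a flank alignment
#'
#' Resamples alignment columns with replacement, rebuilds a neighbor-joining
#' tree per replicate, and reports for each bipartition of the point-estimate
#' tree the percentage of replicate trees containing it. Deterministic for a
#' fixed seed.
#'
#' @param dataset A `flank_dataset` or named character vector alignment.
#' @param n_reps Bootstrap replicates (>= 100). Default 1000.
#' @param seed Integer seed.
#' @param model Distance model, see [k2p_distance_matrix()].
#' @return List with `tree` (point-estimate NJ tree) and `support`
#'   (data frame: `clade` label, `support` %).
#' @export
bootstrap_bipartition_support <- function(dataset, n_reps = 1000L, seed = 1L,
                                          model = "K80") {
  if (n_reps < 100L) stop("n_reps must be >= 100", call. = FALSE)
  aln <- if (inherits(dataset, "flank_dataset")) dataset$alignment else dataset
  chars <- do.call(rbind, strsplit(aln, ""))
  rownames(chars) <- names(aln)
  point <- nj_tree(suppressWarnings(k2p_distance_matrix(aln, model = model,
                                                        min_sites = 0L)))
  with_seed(seed, {
    boot <- vector("list", n_reps)
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(chars), replace = TRUE)
      rep_aln <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      boot[[b]] <- nj_tree(suppressWarnings(
        k2p_distance_matrix(rep_aln, model = model, min_sites = 0L)))
    }
    class(boot) <- "multiPhylo"
    list(tree = point, support = bipartition_support_table(point, boot, n_reps))
  })
}

# % of replicate trees containing each non-trivial bipartition of the point
# tree; equal-frequency bipartitions are ordered lexicographically by leaf set
bipartition_support_table <- function(point, boot_trees, n_reps) {
  counts <- ape::prop.clades(point, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  sets <- clade_leafsets(point)
  n_tip <- length(point$tip.label)
  internal <- (n_tip + 1):(n_tip + point$Nnode)
  support <- data.frame(
    clade = vapply(sets[internal], function(s) paste(sort(s), collapse = ","),
                   character(1)),
    support = 100 * counts / n_reps)
  sizes <- lengths(sets[internal])
  support <- support[sizes >= 2 & sizes <= n_tip - 2, , drop = FALSE]
  support <- support[order(-support$support, support$clade), , drop = FALSE]
  rownames(support) <- NULL
  support
}

# support (%) for a clade in a bipartition table, matching the clade or its
# complement (bipartitions are unrooted)
support_for_clade <- function(support, clade, all_taxa) {
  key1 <- paste(sort(clade), collapse = ",")
  key2 <- paste(sort(setdiff(all_taxa, clade)), collapse = ",")
  hit <- support$support[support$clade %in% c(key1, key2)]
  if (length(hit)) max(hit) else 0
}

#' Per-locus flank concordance analysis
#'
#' Convenience wrapper: extracts the flanks of one locus, bootstraps NJ
#' bipartition support, and issues the concordance verdict for the locus's
#' insertion pattern against a reference clade.
#'
#' @param locus A [locus_record()].
#' @param retro_clade Species grouped by the insertion pattern.
#' @param reference_clade Competing species-tree clade.
#' @param config A [pipeline_config()].
#' @param n_reps,seed Bootstrap settings.
#' @param width Flank width per side; default the locus's recorded width.
#' @return A `concordance_verdict`.
#' @export
locus_flank_concordance <- function(locus, retro_clade, reference_clade,
                                    config = pipeline_config(),
                                    n_reps = 1000L, seed = 1L,
                                    width = locus$flank_width) {
  fl <- extract_flanks(locus, width = width, min_per_side = config$min_flank)
  bs <- bootstrap_bipartition_support(fl, n_reps = n_reps, seed = seed)
  concordance_verdict(retro_clade, bs, reference_clade, names(fl),
                      config = config, mode = "per_locus", id = locus$locus_id)
}

#' Concordance verdict: true homoplasy versus ILS/introgression
#'
#' A conflicting retrotransposon pattern is true homoplasy when the flanks
#' support the reference (species-tree) clade while the insertion pattern
#' contradicts it; it is ILS or introgression when the flanks support the
#' same discordant clade as the insertion. Concatenated subsets use the high
#' support threshold (default 90%), per-locus analyses the low one (default
#' 80%).
#'
#' @param retro_clade Species grouped by the insertion pattern.
#' @param flank_supports Support table from
#'   [bootstrap_bipartition_support()] (the `support` data frame), or the
#'   full result list.
#' @param reference_clade Species-tree clade competing with `retro_clade`.
#' @param all_taxa All taxa in the flank tree.
#' @param config A [pipeline_config()].
#' @param mode `"concatenated"` or `"per_locus"`.
#' @param id Subset or locus identifier.
#' @return A `concordance_verdict`: list with `id`, `retro_clade`,
#'   `flank_clade`, `retro_clade_support`, `reference_clade_support`,
#'   `verdict`.
#' @export
concordance_verdict <- function(retro_clade, flank_supports, reference_clade,
                                all_taxa, config = pipeline_config(),
                                mode = c("concatenated", "per_locus"),
                                id = NA_character_) {
  mode <- match.arg(mode)
  if (is.list(flank_supports) && !is.data.frame(flank_supports)) {
    flank_supports <- flank_supports$support
  }
  thr <- if (mode == "concatenated") config$support_high else config$support_low
  ref_sup <- support_for_clade(flank_supports, reference_clade, all_taxa)
  retro_sup <- support_for_clade(flank_supports, retro_clade, all_taxa)
  same <- setequal(retro_clade, reference_clade)
  verdict <- if (!same && ref_sup >= thr) {
    "true_homoplasy"
  } else if (retro_sup >= thr) {
    "ils_or_introgression"
  } else {
    "uninformative"
  }
  structure(
    list(id = id, retro_clade = retro_clade,
         flank_clade = if (ref_sup >= retro_sup) reference_clade else retro_clade,
         retro_clade_support = retro_sup, reference_clade_support = ref_sup,
         verdict = verdict),
    class = "concordance_verdict")
}
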