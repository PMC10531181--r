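#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames pbinom runif rbinom qbinom sd as.dist cophenetic
#' @importFrom utils read.delim write.table adist head tail packageVersion
NULL

VALID_STATES <- c("present", "absent", "missing")

#' Create an insertion call for one species at one locus
#'
#' An insertion call records whether a retrotransposon (typically a CHR2-family
#' SINE) is present at a locus in a given species and, when present, where its
#' breakpoints fall in the locus alignment and what its target site
#' duplications (TSDs) look like. Coordinates are 0-based, half-open alignment
#' columns.
#'
#' @param species Species identifier (must match a FASTA record id).
#' @param state One of `"present"`, `"absent"`, `"missing"`.
#' @param family Element family name (e.g. `"CHR2"`), required when present.
#' @param orientation `"+"` or `"-"`, relative to the locus forward strand.
#' @param start,end Element breakpoints in alignment columns (0-based,
#'   half-open); required when present, must satisfy `start < end`.
#' @param tsd_left,tsd_right TSD sequences (non-empty when present).
#' @param tail 3' low-complexity tail sequence of the element copy.
#' @return An object of class `insertion_call`.
#' @export
insertion_call <- function(species, state, family = NA_character_,
                           orientation = NA_character_,
                           start = NA_integer_, end = NA_integer_,
                           tsd_left = NA_character_, tsd_right = NA_character_,
                           tail = NA_character_) {
  if (!state %in% VALID_STATES) {
    stop("unknown state token: '", state, "'", call. = FALSE)
  }
  if (state == "present") {
    start <- as.integer(start); end <- as.integer(end)
    if (is.na(start) || is.na(end) || start >= end) {
      stop("present call needs coordinates with start < end", call. = FALSE)
    }
    if (is.na(tsd_left) || is.na(tsd_right) ||
        !nzchar(tsd_left) || !nzchar(tsd_right)) {
      stop("present call needs non-empty TSD sequences", call. = FALSE)
    }
  } else {
    if (!is.na(start) || !is.na(end)) {
      stop("state '", state, "' carries no coordinates", call. = FALSE)
    }
  }
  structure(
    list(species = species, state = state, family = family,
         orientation = orientation, start = if (state == "present") start else NA_integer_,
         end = if (state == "present") end else NA_integer_,
         tsd_left = tsd_left, tsd_right = tsd_right, tail = tail),
    class = "insertion_call")
}

#' Create a locus record
#'
#' A locus record bundles the multi-species alignment of one genomic locus
#' with the per-species insertion calls for the element it harbours.
#'
#' @param locus_id Locus identifier.
#' @param alignment Named character vector of aligned sequences (gaps as
#'   `"-"`); all the same length.
#' @param calls List of [insertion_call()] objects; every call's species must
#'   appear in the alignment.
#' @param flank_width Flank window width (nt) used when the locus was
#'   extracted.
#' @return An object of class `locus_record`.
#' @export
locus_record <- function(locus_id, alignment, calls, flank_width = 200L) {
  if (is.null(names(alignment)) || anyDuplicated(names(alignment))) {
    stop("alignment must be a uniquely named character vector", call. = FALSE)
  }
  if (length(unique(nchar(alignment))) != 1L) {
    stop("aligned sequences differ in length", call. = FALSE)
  }
  sp <- vapply(calls, function(x) x$species, character(1))
  if (!all(sp %in% names(alignment))) {
    stop("insertion call species missing from alignment: ",
         paste(setdiff(sp, names(alignment)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sp)) stop("duplicate species in calls", call. = FALSE)
  structure(
    list(locus_id = locus_id, alignment = toupper(alignment),
         calls = setNames(calls, sp), flank_width = as.integer(flank_width)),
    class = "locus_record")
}

#' @export
print.locus_record <- function(x, ...) {
  states <- vapply(x$calls, function(c) c$state, character(1))
  cat("Locus ", x$locus_id, ": ", length(x$alignment), " species x ",
      nchar(x$alignment[[1]]), " columns (",
      sum(states == "present"), " present, ",
      sum(states == "absent"), " absent, ",
      sum(states == "missing"), " missing)\n", sep = "")
  invisible(x)
}

#' Pipeline configuration
#'
#' Thresholds and settings shared across the pipeline stages. The TSD-shift
#' bands follow the strict orthology definition for presence/absence markers:
#' shift of at most 1 nt is "precise", 2-3 nt is "nearly precise", anything
#' beyond 3 nt is treated as unrelated insertions.
#'
#' @param precise_shift Upper bound (nt) of the precise band. Default 1.
#' @param orthology_shift Upper bound (nt) for co-located insertions to be
#'   considered at the same genomic site at all. Default 3.
#' @param tail_divergence_threshold Normalized edit distance above which two
#'   same-family tails are considered independent copies. Default 0.3
#'   (heuristic stand-in; no published cutoff exists).
#' @param flank_width Flank window per side in nt (default 200; extended
#'   analyses use 1000).
#' @param min_flank Minimum usable flank nt per side before a species is
#'   dropped from flank analyses. Default 50.
#' @param ils_window_my Internal-branch length (million years, MY) above which
#'   a conflicting pattern cannot plausibly be explained by incomplete lineage
#'   sorting. Default 10 MY.
#' @param bootstrap_reps Bootstrap replicates for tree support. Default 1000.
#' @param support_high,support_low Bootstrap support thresholds (%) for
#'   concatenated and per-locus flank analyses. Defaults 90 and 80.
#' @param reference_species Species with predefined "presence" (screening
#'   reference); never reported as a deletion lineage.
#' @param excluded_species Species excluded from pattern classification
#'   (e.g. low assembly quality).
#' @param outgroup_species Outgroup species that must show absence for a locus
#'   to be informative.
#' @param seed Random seed used by stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(precise_shift = 1L, orthology_shift = 3L,
                            tail_divergence_threshold = 0.3,
                            flank_width = 200L, min_flank = 50L,
                            ils_window_my = 10,
                            bootstrap_reps = 1000L,
                            support_high = 90, support_low = 80,
                            reference_species = NULL,
                            excluded_species = character(0),
                            outgroup_species = character(0),
                            seed = 1L) {
  if (!(0 <= precise_shift && precise_shift < orthology_shift)) {
    stop("need 0 <= precise_shift < orthology_shift", call. = FALSE)
  }
  if (flank_width <= 0) stop("flank_width must be > 0", call. = FALSE)
  structure(
    list(precise_shift = as.integer(precise_shift),
         orthology_shift = as.integer(orthology_shift),
         tail_divergence_threshold = tail_divergence_threshold,
         flank_width = as.integer(flank_width),
         min_flank = as.integer(min_flank),
         ils_window_my = ils_window_my,
         bootstrap_reps = as.integer(bootstrap_reps),
         support_high = support_high, support_low = support_low,
         reference_species = reference_species,
         excluded_species = excluded_species,
         outgroup_species = outgroup_species,
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Presence/absence matrix constructor
#'
#' @param x Character matrix with entries in `{"0","1","?"}`, species as rows
#'   and loci/characters as columns.
#' @param drop_uninformative Drop characters without at least one `1` and one
#'   `0` (required for parsimony scoring). Default TRUE.
#' @return A character matrix of class `pa_matrix`.
#' @export
pa_matrix <- function(x, drop_uninformative = TRUE) {
  if (!is.matrix(x) || is.null(rownames(x))) {
    stop("x must be a matrix with species rownames", call. = FALSE)
  }
  mode(x) <- "character"
  if (!all(x %in% c("0", "1", "?"))) {
    stop("matrix cells must be 0, 1 or ?", call. = FALSE)
  }
  if (drop_uninformative) {
    keep <- apply(x, 2, function(col) any(col == "1") && any(col == "0"))
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("matrix has no retained characters", call. = FALSE)
  class(x) <- c("pa_matrix", class(x))
  x
}

# --- coordinate conventions ---------------------------------------------------

#' Convert 0-based half-open coordinates to 1-based closed, and back
#'
#' All coordinates in the package are 0-based half-open. These helpers convert
#' to and from the 1-based closed convention used by most alignment viewers;
#' the two are mutually inverse.
#'
#' @param start,end Interval bounds.
#' @return A list with `start` and `end`.
#' @export
to_one_based <- function(start, end) list(start = start + 1L, end = end)

#' @rdname to_one_based
#' @export
to_zero_based <- function(start, end) list(start = start - 1L, end = end)

# --- I/O ----------------------------------------------------------------------

SIDECAR_COLS <- c("locus_id", "species", "state", "family", "orientation",
                  "start", "end", "tsd_left", "tsd_right", "tail")

#' Read one locus from a FASTA alignment plus a TSV sidecar
#'
#' The sidecar carries the per-species insertion annotations (state, family,
#' orientation, breakpoints, TSDs, tail). Species present in the FASTA but
#' absent from the sidecar are recorded with state `"missing"` (locus could
#' not be evaluated in that assembly).
#'
#' @param path FASTA file with one aligned record per species.
#' @param sidecar_path TSV with columns
#'   `locus_id, species, state, family, orientation, start, end, tsd_left,
#'   tsd_right, tail`.
#' @param flank_width Flank width (nt) recorded on the locus.
#' @return A [locus_record()].
#' @export
read_locus_fasta <- function(path, sidecar_path, flank_width = 200L) {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences differ in length in ", path, call. = FALSE)
  }
  aln <- toupper(vapply(as.character(seqs), paste, character(1), collapse = ""))
  names(aln) <- names(seqs)

  tab <- read.delim(sidecar_path, colClasses = "character")
  miss <- setdiff(SIDECAR_COLS, names(tab))
  if (length(miss)) {
    stop("sidecar missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(tab$species %in% names(aln))) {
    stop("sidecar species not in FASTA: ",
         paste(setdiff(tab$species, names(aln)), collapse = ", "), call. = FALSE)
  }
  calls <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    insertion_call(
      species = r$species, state = r$state,
      family = if (nzchar(r$family)) r$family else NA_character_,
      orientation = if (nzchar(r$orientation)) r$orientation else NA_character_,
      start = if (nzchar(r$start)) as.integer(r$start) else NA_integer_,
      end = if (nzchar(r$end)) as.integer(r$end) else NA_integer_,
      tsd_left = if (nzchar(r$tsd_left)) r$tsd_left else NA_character_,
      tsd_right = if (nzchar(r$tsd_right)) r$tsd_right else NA_character_,
      tail = if (nzchar(r$tail)) r$tail else NA_character_)
  })
  for (sp in setdiff(names(aln), tab$species)) {
    calls <- c(calls, list(insertion_call(sp, "missing")))
  }
  locus_id <- if (nrow(tab)) tab$locus_id[1] else
    sub("\\.fa(sta)?$", "", basename(path))
  locus_record(locus_id, aln, calls, flank_width)
}

#' Write one locus to FASTA plus sidecar TSV
#'
#' Inverse of [read_locus_fasta()]: missing-state calls are omitted from the
#' sidecar (they are re-created on read).
#'
#' @param record A [locus_record()].
#' @param path,sidecar_path Output file paths.
#' @return Invisibly, `record`.
#' @export
write_locus_fasta <- function(record, path, sidecar_path) {
  seqs <- ape::as.DNAbin(strsplit(tolower(record$alignment), ""))
  names(seqs) <- names(record$alignment)
  ape::write.FASTA(seqs, path)
  keep <- Filter(function(c) c$state != "missing", record$calls)
  rows <- lapply(keep, function(c) {
    data.frame(locus_id = record$locus_id, species = c$species, state = c$state,
               family = blank_na(c$family), orientation = blank_na(c$orientation),
               start = blank_na(c$start), end = blank_na(c$end),
               tsd_left = blank_na(c$tsd_left), tsd_right = blank_na(c$tsd_right),
               tail = blank_na(c$tail))
  })
  tab <- do.call(rbind, rows)
  write.table(tab, sidecar_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(record)
}

blank_na <- function(x) if (is.na(x)) "" else as.character(x)

#' Write and read a presence/absence matrix in NEXUS format
#'
#' The matrix is stored as a standard-datatype DATA block with symbols `0 1`
#' and missing `?`; `write_nexus_matrix()` and `read_nexus_matrix()` are
#' mutually inverse.
#'
#' @param matrix A [pa_matrix()] (or coercible character matrix).
#' @param path Output path.
#' @return Invisibly, the matrix.
#' @export
write_nexus_matrix <- function(matrix, path) {
  if (!inherits(matrix, "pa_matrix")) matrix <- pa_matrix(matrix)
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("empty matrix", call. = FALSE)
  }
  rows <- setNames(
    lapply(seq_len(nrow(matrix)), function(i) unname(matrix[i, ])),
    rownames(matrix))
  ape::write.nexus.data(rows, path, format = "standard", interleaved = FALSE)
  invisible(matrix)
}

#' @rdname write_nexus_matrix
#' @export
read_nexus_matrix <- function(path) {
  rows <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(rows, as.character))
  rownames(m) <- names(rows)
  pa_matrix(m, drop_uninformative = FALSE)
}

#' Read a species tree from a Newick file
#'
#' Wraps [ape::read.tree()] with the package's validity checks: unique leaf
#' labels, non-negative branch lengths, a single root. Polytomies are allowed.
#'
#' @param path Newick file (or a Newick string via `text`).
#' @param text Optional literal Newick string instead of a file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  validate_species_tree(tree)
}

validate_species_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree", call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths in tree", call. = FALSE)
  }
  tree
}
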