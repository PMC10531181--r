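# Orthology classification of co-located insertions. Two insertions at the
# same genomic site are orthologous (one ancestral event) when they share
# element family and orientation and their breakpoints coincide within a small
# TSD shift; otherwise they are independent (parallel) copies.

#' TSD shift between two present insertion calls
#'
#' The shift is the maximum displacement of the two breakpoints, measured in
#' alignment columns after discarding columns gapped in both species (those
#' columns carry no positional information for the pair). Both boundaries must
#' nearly coincide for a small shift, matching the "identical TSD" reading of
#' insertion orthology.
#'
#' @param call_a,call_b Present [insertion_call()]s in the same locus
#'   alignment frame.
#' @param alignment Optional named character vector of aligned sequences; when
#'   supplied, columns gapped in both species are removed before comparing
#'   coordinates. When omitted, coordinates are compared directly.
#' @return Integer shift in nt (>= 0).
#' @export
tsd_shift <- function(call_a, call_b, alignment = NULL) {
  if (call_a$state != "present" || call_b$state != "present") {
    stop("tsd_shift requires two present calls", call. = FALSE)
  }
  sa <- call_a$start; ea <- call_a$end
  sb <- call_b$start; eb <- call_b$end
  if (!is.null(alignment)) {
    ga <- strsplit(alignment[[call_a$species]], "")[[1]] == "-"
    gb <- strsplit(alignment[[call_b$species]], "")[[1]] == "-"
    both <- ga & gb
    # map a column index to its rank among retained columns
    shiftmap <- cumsum(!both)
    remap <- function(col) if (col == 0L) 0L else shiftmap[col]
    sa <- remap(sa); sb <- remap(sb)
    ea <- remap(ea); eb <- remap(eb)
  }
  as.integer(max(abs(sa - sb), abs(ea - eb)))
}

#' Normalized tail divergence between two element copies
#'
#' Edit (Levenshtein) distance between the 3' tail sequences, normalized by
#' the longer tail length, in [0, 1]. Independent insertions of the same
#' family typically carry clearly different low-complexity tails, so a high
#' divergence flags a parallel insertion even when family and orientation
#' agree.
#'
#' @param tail_a,tail_b Non-empty tail sequences.
#' @return Numeric in [0, 1].
#' @export
tail_divergence <- function(tail_a, tail_b) {
  if (is.na(tail_a) || is.na(tail_b) || !nzchar(tail_a) || !nzchar(tail_b)) {
    stop("empty tail sequence", call. = FALSE)
  }
  d <- adist(toupper(tail_a), toupper(tail_b))[1, 1]
  d / max(nchar(tail_a), nchar(tail_b))
}

#' Classify a pair of co-located insertions
#'
#' Applies the TSD-shift bands and identity requirements:
#' \itemize{
#'   \item shift <= 1, same family, same orientation, tails not clearly
#'     divergent: `orthologous_precise`;
#'   \item shift 2-3 under the same conditions: `orthologous_nearly_precise`;
#'   \item shift <= 3 but different family, opposite orientation, or tail
#'     divergence above the threshold: `non_homoplasious_parallel`
#'     (independent insertions distinguishable without flank analysis);
#'   \item shift > 3: `unrelated`.
#' }
#' The three shift bands partition all non-negative shifts, so no pair is
#' doubly classified. The verdict is symmetric in its two calls.
#'
#' @param call_a,call_b Present [insertion_call()]s.
#' @param config A [pipeline_config()].
#' @param alignment Optional alignment passed to [tsd_shift()].
#' @return An `orthology_verdict`: list with `species`, `shift`,
#'   `same_family`, `same_orientation`, `tsd_identical`, `tail_divergence`,
#'   `category`, and `tail_heuristic` (TRUE when the tail-divergence cutoff,
#'   which has no published value, decided the category).
#' @export
classify_insertion_pair <- function(call_a, call_b, config = pipeline_config(),
                                    alignment = NULL) {
  shift <- tsd_shift(call_a, call_b, alignment)
  same_family <- identical(call_a$family, call_b$family)
  same_orientation <- identical(call_a$orientation, call_b$orientation)
  tsd_identical <-
    identical(toupper(call_a$tsd_left), toupper(call_b$tsd_left)) &&
    identical(toupper(call_a$tsd_right), toupper(call_b$tsd_right))
  tdiv <- if (!is.na(call_a$tail) && !is.na(call_b$tail) &&
              nzchar(call_a$tail) && nzchar(call_b$tail)) {
    tail_divergence(call_a$tail, call_b$tail)
  } else NA_real_
  tails_diverged <- !is.na(tdiv) && tdiv > config$tail_divergence_threshold

  category <- if (shift > config$orthology_shift) {
    "unrelated"
  } else if (!same_family || !same_orientation || tails_diverged) {
    "non_homoplasious_parallel"
  } else if (shift <= config$precise_shift) {
    "orthologous_precise"
  } else {
    "orthologous_nearly_precise"
  }
  structure(
    list(species = c(call_a$species, call_b$species), shift = shift,
         same_family = same_family, same_orientation = same_orientation,
         tsd_identical = tsd_identical, tail_divergence = tdiv,
         category = category,
         tail_heuristic = tails_diverged && same_family && same_orientation &&
           shift <= config$orthology_shift),
    class = "orthology_verdict")
}

#' Classify all present-call pairs of a locus
#'
#' @param locus A [locus_record()].
#' @param config A [pipeline_config()].
#' @return Data frame with one row per species pair and the verdict fields.
#' @export
classify_locus <- function(locus, config = pipeline_config()) {
  present <- Filter(function(c) c$state == "present", locus$calls)
  if (length(present) < 2L) {
    return(data.frame(locus_id = character(0), species_a = character(0),
                      species_b = character(0), shift = integer(0),
                      same_family = logical(0), same_orientation = logical(0),
                      tsd_identical = logical(0), tail_divergence = numeric(0),
                      category = character(0), tail_heuristic = logical(0)))
  }
  pairs <- utils::combn(names(present), 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    v <- classify_insertion_pair(present[[p[1]]], present[[p[2]]], config,
                                 locus$alignment)
    data.frame(locus_id = locus$locus_id, species_a = p[1], species_b = p[2],
               shift = v$shift, same_family = v$same_family,
               same_orientation = v$same_orientation,
               tsd_identical = v$tsd_identical,
               tail_divergence = v$tail_divergence,
               category = v$category, tail_heuristic = v$tail_heuristic)
  })
  do.call(rbind, rows)
}
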