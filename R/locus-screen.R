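# Candidate-locus screening: keep near-full-length elements whose flanks are
# mostly free of other transposable elements, so that downstream flank analyses
# have usable single-copy sequence.

#' Completeness filter for an element annotation
#'
#' An element passes when it misses at most `max_missing` nucleotides relative
#' to its family consensus (default 10 nt, the "almost full-length" rule).
#'
#' @param ann One annotation row (list or 1-row data.frame) with
#'   `consensus_length` and `matched_length`.
#' @param max_missing Maximum missing nt. Default 10.
#' @return Logical.
#' @export
passes_completeness <- function(ann, max_missing = 10L) {
  cl <- as.numeric(ann$consensus_length)
  ml <- as.numeric(ann$matched_length)
  if (is.na(cl) || is.na(ml) || cl < 0 || ml < 0) {
    stop("negative or missing lengths", call. = FALSE)
  }
  if (cl == 0) stop("consensus length must be > 0", call. = FALSE)
  if (ml > cl) stop("matched length exceeds consensus length", call. = FALSE)
  (cl - ml) <= max_missing
}

#' TE-free flank filter for an element annotation
#'
#' Each flank (up to 500 nt per side) must be at least `min_free_frac`
#' TE-free, evaluated separately on the left and the right flank. Flanks
#' shorter than `min_flank_len` (contig edge) fail outright: they cannot
#' support flank-signal analysis.
#'
#' @param ann Annotation with `left_mask` and `right_mask`: logical/0-1
#'   vectors, TRUE (1) where the flank position overlaps another TE.
#' @param min_free_frac Minimum TE-free fraction per flank. Default 0.85.
#' @param min_flank_len Minimum flank length to evaluate. Default 100.
#' @return Logical.
#' @export
passes_flank_clearance <- function(ann, min_free_frac = 0.85,
                                   min_flank_len = 100L) {
  lm <- ann$left_mask; rm_ <- ann$right_mask
  if (is.null(lm) || is.null(rm_)) stop("missing flank mask", call. = FALSE)
  free_ok <- function(mask) {
    mask <- as.logical(mask)
    if (length(mask) < min_flank_len) return(FALSE)
    mean(!mask) >= min_free_frac
  }
  free_ok(lm) && free_ok(rm_)
}

#' Screen an element annotation table
#'
#' Applies [passes_completeness()] and [passes_flank_clearance()] to every
#' row and keeps those passing both, preserving input order.
#'
#' @param table List of annotation rows (each a list with `element_id`,
#'   `family`, `consensus_length`, `matched_length`, `left_mask`,
#'   `right_mask`, ...), or the result of [read_annotation_table()].
#' @param max_missing,min_free_frac,min_flank_len Filter thresholds, see the
#'   individual filters.
#' @return A list with `selected` (the retained rows, same representation as
#'   the input) and `summary` (counts in, failing each filter, retained).
#' @export
screen_annotations <- function(table, max_missing = 10L, min_free_frac = 0.85,
                               min_flank_len = 100L) {
  n <- length(table)
  if (n == 0L) {
    return(list(selected = table,
                summary = c(n_in = 0L, n_fail_completeness = 0L,
                            n_fail_flanks = 0L, n_retained = 0L)))
  }
  comp <- vapply(table, passes_completeness, logical(1),
                 max_missing = max_missing)
  flank <- vapply(table, passes_flank_clearance, logical(1),
                  min_free_frac = min_free_frac, min_flank_len = min_flank_len)
  keep <- comp & flank
  list(selected = table[keep],
       summary = c(n_in = n,
                   n_fail_completeness = sum(!comp),
                   n_fail_flanks = sum(comp & !flank),
                   n_retained = sum(keep)))
}

#' Read a minimal element-annotation TSV
#'
#' A distilled RepeatMasker-style table: one row per element with columns
#' `element_id, family, contig, start, end, strand, consensus_length,
#' matched_length, left_mask, right_mask`. Masks are strings of `0`/`1`
#' characters (1 = position covered by another TE), one character per flank
#' position.
#'
#' @param path TSV path.
#' @return List of annotation rows suitable for [screen_annotations()].
#' @export
read_annotation_table <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  need <- c("element_id", "family", "contig", "start", "end", "strand",
            "consensus_length", "matched_length", "left_mask", "right_mask")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("annotation table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    list(element_id = r$element_id, family = r$family, contig = r$contig,
         start = as.integer(r$start), end = as.integer(r$end),
         strand = r$strand,
         consensus_length = as.integer(r$consensus_length),
         matched_length = as.integer(r$matched_length),
         left_mask = as.integer(strsplit(r$left_mask, "")[[1]]),
         right_mask = as.integer(strsplit(r$right_mask, "")[[1]]))
  })
}
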