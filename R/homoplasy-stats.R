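# Homoplasy frequency estimators. Parallel-insertion frequency relates the
# number of shared (parallel) insertions between two lineages to all
# insertion events observed on those lineages; precise-deletion frequency
# relates the per-lineage deletion rate to the substrate of insertions
# available for deletion.

#' Round half-up to a fixed number of decimals
#'
#' Unlike [base::round()] (banker's rounding), ties go away from zero, which
#' matches how the frequency estimates are conventionally printed.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Parallel-insertion homoplasy frequency for a lineage pair
#'
#' `100 * n_parallel / (n_auta_a + n_auta_b + n_parallel)`: shared parallel
#' insertions as a percentage of all insertion events on the two lineages
#' (their autapomorphic insertions plus the shared ones).
#'
#' @param n_parallel Number of precise parallel insertions shared by the two
#'   lineages.
#' @param n_auta_a,n_auta_b Autapomorphic insertion counts on each lineage.
#' @return A `frequency_estimate`: list with `kind`, `numerator`,
#'   `denominator`, `value` (full precision, %), `printed` (2 decimals,
#'   half-up).
#' @export
parallel_insertion_frequency <- function(n_parallel, n_auta_a, n_auta_b) {
  if (any(c(n_parallel, n_auta_a, n_auta_b) < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  den <- n_auta_a + n_auta_b + n_parallel
  if (den == 0) stop("zero denominator", call. = FALSE)
  value <- 100 * n_parallel / den
  structure(list(kind = "parallel_insertion", numerator = n_parallel,
                 denominator = den, value = value,
                 printed = round_half_up(value, 2)),
            class = "frequency_estimate")
}

#' Average precise-deletion rate per lineage
#'
#' @param n_deletions Total precise deletions detected.
#' @param n_lineages Number of lineages screened.
#' @return List with `value` (full precision) and `printed` (2 decimals).
#' @export
deletion_rate <- function(n_deletions, n_lineages) {
  if (n_lineages <= 0) stop("n_lineages must be > 0", call. = FALSE)
  if (n_deletions < 0) stop("counts must be >= 0", call. = FALSE)
  value <- n_deletions / n_lineages
  list(value = value, printed = round_half_up(value, 2))
}

#' Precise-deletion homoplasy frequency
#'
#' `100 * rate / (n_substrate + n_deletions)`: the per-lineage deletion rate
#' as a percentage of the insertions that were available to be deleted.
#'
#' @param rate Per-lineage deletion rate (use the printed 2-decimal value to
#'   reproduce published numbers).
#' @param n_substrate Insertions comprising the deletion substrate.
#' @param n_deletions Deletions detected.
#' @return A `frequency_estimate` with `printed` at 3 decimals.
#' @export
deletion_frequency <- function(rate, n_substrate, n_deletions) {
  den <- n_substrate + n_deletions
  if (den <= 0) stop("zero denominator", call. = FALSE)
  value <- 100 * rate / den
  structure(list(kind = "precise_deletion", numerator = rate,
                 denominator = den, value = value,
                 printed = round_half_up(value, 3)),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(x$kind, " frequency: ", x$printed, "% (", x$numerator, "/",
      x$denominator, " x 100%)\n", sep = "")
  invisible(x)
}

#' Expected marker fixation time
#'
#' Time for a neutral insertion polymorphism to fix in a population:
#' 4 Ne generations, converted to years.
#'
#' @param effective_population_size Effective population size Ne
#'   (individuals).
#' @param generation_time_years Generation time (years).
#' @return Fixation time in years.
#' @export
fixation_time <- function(effective_population_size, generation_time_years) {
  if (effective_population_size <= 0 || generation_time_years <= 0) {
    stop("inputs must be > 0", call. = FALSE)
  }
  4 * effective_population_size * generation_time_years
}

#' Ratio table against comparator homoplasy frequencies
#'
#' Reports min, max and midpoint ratios of this study's frequency range to a
#' comparator range (e.g. published frequencies from another clade).
#'
#' @param own Numeric range (length-2) of frequencies (%).
#' @param comparator Numeric range (length-2) of comparator frequencies (%).
#' @return Data frame with `ratio_min`, `ratio_max`, `ratio_midpoint`.
#' @export
frequency_ratio_table <- function(own, comparator) {
  own <- range(own); comparator <- range(comparator)
  data.frame(ratio_min = own[1] / comparator[2],
             ratio_max = own[2] / comparator[1],
             ratio_midpoint = mean(own) / mean(comparator))
}

# --- run-level bookkeeping ----------------------------------------------------

presence_key <- function(a) paste(sort(a$presence), collapse = ",")

#' Estimate the parallel-insertion frequency for a lineage pair from
#' classified loci
#'
#' Counts loci whose presence set is exactly the pair and whose co-located
#' insertions are classified `orthologous_precise` (shift <= 1, same family
#' and orientation) as parallel insertions, and singleton-presence loci on
#' either lineage as autapomorphies, then applies
#' [parallel_insertion_frequency()].
#'
#' @param assignments List of [assign_pattern()] results.
#' @param verdict_table Row-bound output of [classify_locus()] over the same
#'   loci.
#' @param species_a,species_b The lineage pair.
#' @return A `frequency_estimate` with the counts in `numerator`/`counts`.
#' @export
estimate_parallel_frequency <- function(assignments, verdict_table,
                                        species_a, species_b) {
  keys <- vapply(assignments, presence_key, character(1))
  pair_key <- paste(sort(c(species_a, species_b)), collapse = ",")
  pair_loci <- vapply(assignments, function(a) a$locus_id, character(1))[
    keys == pair_key]
  precise <- verdict_table$locus_id[
    verdict_table$category == "orthologous_precise" &
      verdict_table$locus_id %in% pair_loci]
  n_par <- length(unique(precise))
  n_a <- sum(keys == species_a)
  n_b <- sum(keys == species_b)
  est <- parallel_insertion_frequency(n_par, n_a, n_b)
  est$counts <- c(n_parallel = n_par, n_auta_a = n_a, n_auta_b = n_b)
  est
}

#' Summarize a full run: category tallies and frequency estimates
#'
#' @param assignments List of [assign_pattern()] results.
#' @param verdict_table Row-bound [classify_locus()] output (may have 0 rows).
#' @param config A [pipeline_config()].
#' @param lineage_pairs Optional list of 2-vectors of species; a parallel
#'   frequency estimate is produced for each.
#' @param deletion_lineages Number of lineages screened for deletions
#'   (denominator of the deletion rate); default the count of distinct
#'   deletion-eligible species seen in the assignments' trees is not known
#'   here, so callers supply it.
#' @param deletion_substrate Number of substrate insertions for the deletion
#'   frequency.
#' @return List with `tallies` (named counts per category), `n_loci`,
#'   `parallel` (list of estimates), `deletions` (data frame),
#'   `deletion_rate`, `deletion_frequency`.
#' @export
summarize_run <- function(assignments, verdict_table = NULL,
                          config = pipeline_config(),
                          lineage_pairs = NULL,
                          deletion_lineages = NULL,
                          deletion_substrate = NULL) {
  cats <- vapply(assignments, function(a) a$category, character(1))
  levels_ <- c("diagnostic", "conflict_parallel_candidate",
               "conflict_ils_candidate", "precise_deletion", "ambiguous")
  tallies <- vapply(levels_, function(l) sum(cats == l), integer(1))
  del <- data.frame(
    locus_id = vapply(assignments[cats == "precise_deletion"],
                      function(a) a$locus_id, character(1)),
    species = vapply(assignments[cats == "precise_deletion"],
                     function(a) a$deletion_species, character(1)))
  parallel <- list()
  if (!is.null(lineage_pairs) && !is.null(verdict_table)) {
    for (pr in lineage_pairs) {
      parallel[[paste(pr, collapse = "-")]] <-
        estimate_parallel_frequency(assignments, verdict_table, pr[1], pr[2])
    }
  }
  dr <- df <- NULL
  if (!is.null(deletion_lineages)) {
    dr <- deletion_rate(nrow(del), deletion_lineages)
    if (!is.null(deletion_substrate)) {
      df <- deletion_frequency(dr$printed, deletion_substrate, nrow(del))
    }
  }
  list(tallies = tallies, n_loci = length(assignments), parallel = parallel,
       deletions = del, deletion_rate = dr, deletion_frequency = df)
}

#' Write a run summary as JSON and TSV
#'
#' @param summary Output of [summarize_run()].
#' @param json_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, `summary`.
#' @export
write_summary <- function(summary, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(tallies = as.list(summary$tallies), n_loci = summary$n_loci,
           parallel = lapply(summary$parallel, function(e) {
             list(value = e$value, printed = e$printed,
                  counts = as.list(e$counts))
           }),
           deletions = summary$deletions,
           deletion_rate = summary$deletion_rate,
           deletion_frequency = if (!is.null(summary$deletion_frequency)) {
             list(value = summary$deletion_frequency$value,
                  printed = summary$deletion_frequency$printed)
           }),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (!is.null(tsv_path)) {
    tab <- data.frame(category = names(summary$tallies),
                      count = as.integer(summary$tallies))
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(summary)
}
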