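# End-to-end orchestration: classify -> patterns -> deletions -> stats over a
# dataset directory, with a reproducibility manifest. Stages communicate via
# files so each is independently invokable.

#' Run the full analysis pipeline over a dataset directory
#'
#' Expects `input_dir` to hold `tree.nwk` plus one FASTA (`*.fa`) and sidecar
#' (`*.tsv`) per locus (the layout written by [simulate_dataset()]). Executes
#' the orthology classification, pattern assignment, precise-deletion
#' inference and summary stages in order, writing per-stage TSV outputs and a
#' JSON manifest to `out_dir`. A stage failure aborts with a stage-tagged
#' error. The manifest contains no wall-clock fields, so identical inputs and
#' configuration reproduce an identical manifest.
#'
#' @param config A [pipeline_config()].
#' @param input_dir Dataset directory.
#' @param out_dir Output directory (created if needed).
#' @param lineage_pairs Optional list of species pairs for parallel-frequency
#'   estimates.
#' @return The manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config, input_dir, out_dir, lineage_pairs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  dataset <- stage("read", read_dataset(input_dir))
  tree <- dataset$tree

  verdicts <- stage("classify", {
    v <- do.call(rbind, lapply(dataset$loci, classify_locus, config = config))
    write.table(v, file.path(out_dir, "verdicts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    v
  })

  assignments <- stage("patterns", {
    a <- lapply(dataset$loci, assign_pattern, tree = tree, config = config)
    tab <- data.frame(
      locus_id = vapply(a, function(x) x$locus_id, character(1)),
      category = vapply(a, function(x) x$category, character(1)),
      presence = vapply(a, presence_key, character(1)),
      deletion_species = vapply(a, function(x) x$deletion_species,
                                character(1)))
    write.table(tab, file.path(out_dir, "patterns.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    a
  })

  deletions <- stage("deletions", {
    d <- infer_precise_deletions(assignments, tree,
                                 reference_species = config$reference_species,
                                 excluded = config$excluded_species)
    write.table(d, file.path(out_dir, "deletions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    d
  })

  summary <- stage("stats", {
    s <- summarize_run(assignments, verdicts, config,
                       lineage_pairs = lineage_pairs)
    write_summary(s, json_path = file.path(out_dir, "summary.json"),
                  tsv_path = file.path(out_dir, "summary.tsv"))
    s
  })

  inputs <- sort(list.files(input_dir, full.names = TRUE))
  manifest <- list(
    tool = "retrohom",
    version = as.character(packageVersion("retrohom")),
    seed = config$seed,
    config = config[setdiff(names(config), "seed")],
    input_hashes = as.list(tools::md5sum(inputs)),
    stage_rows = list(loci = length(dataset$loci),
                      verdicts = nrow(verdicts),
                      patterns = length(assignments),
                      deletions = nrow(deletions)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
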