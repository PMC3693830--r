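#' Run the full analysis on in-memory objects
#'
#' Executes the stages in order: virtual targets, chemical drug
#' de-redundancy, target merging, minimum-support filtering, enrichment
#' testing, metabolizing-enzyme flagging, co-binding clustering, independent
#' benchmarking (when a knockout reference is present) and drug-side-effect
#' explanation. A per-stage count log is kept.
#'
#' @param network a [study_network()] as returned by [read_network_tables()]
#'   or [simulate_world()].
#' @param fingerprints fingerprint tibble or `NULL` (skips de-redundancy).
#' @param annotations an [annotation_bundle()].
#' @param tanimoto_cutoff chemical redundancy cutoff (default 0.7).
#' @param min_support minimum active drugs per target / side effect
#'   (default 5).
#' @param q_cutoff significance cutoff (default 0.01).
#' @param cobinding_threshold cluster linking threshold (default 0.5).
#' @param fdr_method passed to [estimate_qvalues()].
#' @param n_permutations,seed benchmark permutation settings.
#' @return An object of class `adr_study`: list with `network` (processed),
#'   `merge_map`, `predictions`, `clusters`, `benchmark` (or `NULL`),
#'   `explanation`, `log` (per-stage counts).
#' @export
run_study <- function(network, fingerprints = NULL,
                      annotations = annotation_bundle(),
                      tanimoto_cutoff = 0.7, min_support = 5,
                      q_cutoff = 0.01, cobinding_threshold = 0.5,
                      fdr_method = "storey-smoother",
                      n_permutations = 1e5, seed = NULL) {
  log <- list()
  note <- function(stage, net) {
    log[[length(log) + 1]] <<- mutate(network_counts(net), stage = stage,
                                      .before = 1)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e))))
  }

  note("input", network)
  network <- run_stage("virtual_targets", build_virtual_targets(network))
  note("virtual_targets", network)
  network <- run_stage("drug_deredundancy",
                       apply_drug_deredundancy(network, fingerprints,
                                               tanimoto_cutoff))
  note("drug_deredundancy", network)
  merged <- run_stage("merge_targets", merge_equivalent_targets(network))
  network <- merged$network
  note("merge_targets", network)
  network <- run_stage("min_support",
                       filter_min_support(network, min_support))
  note("min_support", network)

  predictions <- run_stage("enrichment",
                           run_enrichment(network, fdr_method = fdr_method))
  predictions <- run_stage(
    "metabolizing_exclusion",
    flag_metabolizing_exclusions(predictions, network,
                                 annotations$metabolizing))
  clustered <- run_stage(
    "clustering",
    cluster_predictions(predictions, network,
                        known_causal = annotations$known_causal,
                        q_cutoff = q_cutoff,
                        threshold = cobinding_threshold))
  predictions <- clustered$predictions
  clusters <- clustered$clusters

  benchmark <- NULL
  if (nrow(annotations$ko_reference) > 0) {
    reference <- run_stage(
      "benchmark",
      map_ko_phenotypes(annotations$ko_reference,
                        annotations$phenotype_synonyms))
    benchmark <- run_stage(
      "benchmark",
      run_benchmark(predictions, network, reference, q_cutoff = q_cutoff,
                    cobinding_threshold = cobinding_threshold,
                    n_permutations = n_permutations, seed = seed))
  }

  explanation <- run_stage(
    "explanation",
    summarize_explained_fractions(network, predictions, annotations,
                                  q_cutoff = q_cutoff))

  structure(list(network = network, merge_map = merged$merge_map,
                 predictions = predictions, clusters = clusters,
                 benchmark = benchmark, explanation = explanation,
                 log = bind_rows(log), q_cutoff = q_cutoff),
            class = "adr_study")
}

#' @export
print.adr_study <- function(x, ...) {
  cat("<adr_study>\n")
  print(x$network)
  n_sig <- nrow(select_significant(x$predictions, x$q_cutoff))
  cat(sprintf("  tested pairs: %d  significant at q < %g: %d  clusters: %d\n",
              nrow(x$predictions), x$q_cutoff, n_sig, nrow(x$clusters)))
  if (!is.null(x$benchmark)) print(x$benchmark)
  invisible(x)
}

#' Run the pipeline from flat files
#'
#' Thin orchestration over the file readers and [run_study()]. The config is
#' a named list (or a YAML file path) with entries:
#'
#' * `paths`: `drug_target`, `drug_se` (required); `fingerprints`,
#'   `main_targets`, `family_counts`, `metabolizing`, `known_causal`,
#'   `ko_reference`, `phenotype_synonyms` (optional).
#' * `cutoffs`: `confidence` (0.5), `tanimoto` (0.7), `min_support` (5),
#'   `q_significant` (0.01), `q_confident` (1e-5), `cobinding` (0.5).
#' * `seed`: governs benchmark permutations.
#' * `n_permutations` (1e5), `fdr_method` ("storey-smoother").
#' * `out_dir`: when set, predictions, clusters, merge map, benchmark report,
#'   explanation summary and the stage log are written there as TSV.
#'
#' @param config named list or path to a YAML file.
#' @return The `adr_study` object (invisibly when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  paths <- config$paths %||% abort("pipeline stage 'read' failed: config lacks 'paths'")
  for (required in c("drug_target", "drug_se")) {
    if (is.null(paths[[required]]))
      abort(sprintf("pipeline stage 'read' failed: config lacks input path '%s'",
                    required))
  }
  cut <- modifyList(list(confidence = 0.5, tanimoto = 0.7, min_support = 5,
                         q_significant = 0.01, q_confident = 1e-5,
                         cobinding = 0.5),
                    config$cutoffs %||% list())

  network <- read_network_tables(paths$drug_target, paths$drug_se,
                                 confidence_cutoff = cut$confidence)
  fingerprints <- if (!is.null(paths$fingerprints))
    read_fingerprints(paths$fingerprints) else NULL
  annotations <- read_annotations(
    main_targets_path = paths$main_targets,
    family_counts_path = paths$family_counts,
    metabolizing_path = paths$metabolizing,
    known_causal_path = paths$known_causal,
    ko_reference_path = paths$ko_reference,
    phenotype_synonyms_path = paths$phenotype_synonyms)

  study <- run_study(
    network, fingerprints = fingerprints, annotations = annotations,
    tanimoto_cutoff = cut$tanimoto, min_support = cut$min_support,
    q_cutoff = cut$q_significant, cobinding_threshold = cut$cobinding,
    fdr_method = config$fdr_method %||% "storey-smoother",
    n_permutations = config$n_permutations %||% 1e5,
    seed = config$seed)

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_predictions(study$predictions, file.path(dir, "predictions.tsv"))
    readr::write_tsv(cluster_table(study$clusters),
                     file.path(dir, "clusters.tsv"))
    readr::write_tsv(study$merge_map, file.path(dir, "merge_map.tsv"))
    readr::write_tsv(study$log, file.path(dir, "stage_log.tsv"))
    if (!is.null(study$benchmark))
      readr::write_tsv(tidy(study$benchmark),
                       file.path(dir, "benchmark.tsv"))
    readr::write_tsv(study$explanation$by_category,
                     file.path(dir, "explained_by_category.tsv"))
    readr::write_tsv(study$explanation$by_family,
                     file.path(dir, "explained_by_family.tsv"))
    return(invisible(study))
  }
  study
}

# flat cluster table for TSV output
cluster_table <- function(clusters) {
  if (nrow(clusters) == 0)
    return(tibble(se_id = character(), cluster_id = character(),
                  members = character(), proteins = character(),
                  seed = character(), q = numeric(), n_members = integer()))
  mutate(clusters,
         members = purrr::map_chr(.data$members, paste, collapse = ","),
         proteins = purrr::map_chr(.data$proteins, paste, collapse = ","))
}
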