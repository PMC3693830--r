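#' Read the drug-target and drug-side-effect tables
#'
#' Both inputs are headered TSV files (comment lines start with `#`), the
#' dialect of SIDER/STITCH-style flat downloads. The drug-target file needs
#' `drug_id` and `protein_id` columns and may carry `confidence` (0-1 link
#' score) and `mode` (agonist/antagonist/activation/inhibition, normalised to
#' activation/inhibition). The drug-side-effect file needs `drug_id` and
#' `se_id` and may carry `frequency`, which is preserved but unused by the
#' statistics.
#'
#' @param drug_target_path path to the drug-target TSV.
#' @param drug_se_path path to the drug-side-effect TSV.
#' @param confidence_cutoff edges with confidence strictly below this are
#'   dropped (default 0.5, the usual confidence threshold for curated
#'   interaction scores). Rows without a confidence column always pass.
#'
#' @return A [study_network()] with plain (binding-mode) target nodes, mode
#'   annotations stored for [build_virtual_targets()], and all drugs active.
#' @export
read_network_tables <- function(drug_target_path, drug_se_path,
                                confidence_cutoff = 0.5) {
  dt <- read_tsv_quiet(drug_target_path)
  require_columns(dt, c("drug_id", "protein_id"), drug_target_path)
  se <- read_tsv_quiet(drug_se_path)
  require_columns(se, c("drug_id", "se_id"), drug_se_path)

  dt <- mutate(dt, drug_id = as.character(.data$drug_id),
               protein_id = as.character(.data$protein_id))
  se <- mutate(se, drug_id = as.character(.data$drug_id),
               se_id = as.character(.data$se_id))

  if ("confidence" %in% names(dt)) {
    n0 <- nrow(dt)
    dt <- filter(dt, is.na(.data$confidence) |
                   .data$confidence >= confidence_cutoff)
    dropped <- n0 - nrow(dt)
    if (dropped > 0)
      inform(sprintf("dropped %d drug-target edge(s) below confidence %.3g",
                     dropped, confidence_cutoff))
  }

  modes <- tibble(drug_id = character(), protein_id = character(),
                  mode = character())
  if ("mode" %in% names(dt)) {
    modes <- dt |>
      filter(!is.na(.data$mode), nzchar(.data$mode)) |>
      mutate(mode = normalize_mode(.data$mode)) |>
      filter(.data$mode != "binding") |>
      distinct(.data$drug_id, .data$protein_id, .data$mode)
  }

  dt_edges <- distinct(dt, .data$drug_id, .data$protein_id)
  dup_dt <- nrow(dt) - nrow(dt_edges)
  if (dup_dt > 0)
    inform(sprintf("deduplicated %d drug-target row(s)", dup_dt))
  se_edges <- distinct(se, .data$drug_id, .data$se_id, .keep_all = TRUE)
  n_dup <- (nrow(se) - nrow(se_edges))
  if (n_dup > 0) inform(sprintf("deduplicated %d drug-side-effect edge(s)", n_dup))

  drugs <- tibble(drug_id = sort(unique(c(dt_edges$drug_id, se_edges$drug_id))))
  targets <- plain_targets(dt_edges$protein_id)
  sides <- tibble(se_id = sort(unique(se_edges$se_id)))

  study_network(
    drugs = drugs, targets = targets, side_effects = sides,
    drug_target_edges = rename(dt_edges, target_id = "protein_id"),
    drug_se_edges = se_edges,
    mode_annotations = modes
  )
}

read_tsv_quiet <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort(sprintf("parse error in %s: missing required column(s) %s",
                  path, paste(missing, collapse = ", ")))
  invisible(df)
}

#' Read a drug fingerprint table
#'
#' One row per drug: `drug_id` and `bits`, the 2D chemical fingerprint either
#' as a 0/1 string or as hexadecimal (used when any non-binary hex digit
#' occurs in the column). The leftmost character encodes the lowest-index
#' bits; within a hex digit, bit order is little-endian. All fingerprints in
#' one table must have the same length.
#'
#' @param path TSV with columns `drug_id`, `bits`.
#' @return A tibble with `drug_id` and a `bits` list-column of logical
#'   vectors, of class `fingerprint_tbl`.
#' @export
read_fingerprints <- function(path) {
  df <- read_tsv_quiet(path)
  require_columns(df, c("drug_id", "bits"), path)
  raw <- as.character(df$bits)
  if (any(is.na(raw)) || any(!nzchar(raw)))
    abort("fingerprint table contains empty bit strings")
  chars <- unique(strsplit(paste(tolower(raw), collapse = ""), "")[[1]])
  bad <- setdiff(chars, c(0:9, letters[1:6]))
  if (length(bad))
    abort(paste0("unknown fingerprint character(s): ", paste(bad, collapse = " ")))
  hex <- length(setdiff(chars, c("0", "1"))) > 0
  bits <- lapply(tolower(raw), if (hex) hex_to_bits else binary_to_bits)
  lens <- lengths(bits)
  if (length(unique(lens)) > 1)
    abort(sprintf("fingerprint length mismatch: found lengths %s",
                  paste(sort(unique(lens)), collapse = ", ")))
  fingerprint_tbl(tibble(drug_id = as.character(df$drug_id), bits = bits))
}

binary_to_bits <- function(s) strsplit(s, "")[[1]] == "1"

hex_to_bits <- function(s) {
  vals <- strtoi(strsplit(s, "")[[1]], base = 16L)
  as.vector(vapply(vals, function(v) as.logical(bitwAnd(v, c(1L, 2L, 4L, 8L))),
                   logical(4)))
}

fingerprint_tbl <- function(df) {
  df <- as_tibble(df)
  if (anyDuplicated(df$drug_id)) abort("duplicate drug_id in fingerprint table")
  class(df) <- c("fingerprint_tbl", class(df))
  df
}

# logical matrix, rows = drugs
fingerprint_matrix <- function(fps) {
  m <- do.call(rbind, fps$bits)
  rownames(m) <- fps$drug_id
  m
}

#' Write a fingerprint table
#'
#' @param fps fingerprint tibble as returned by [read_fingerprints()].
#' @param path output TSV path.
#' @export
write_fingerprints <- function(fps, path) {
  out <- tibble(drug_id = fps$drug_id,
                bits = vapply(fps$bits,
                              function(b) paste(as.integer(b), collapse = ""),
                              character(1)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read the optional annotation tables
#'
#' Every table is optional; a `NULL` path yields an empty component. Rows
#' with missing fields are skipped with a warning that reports the count.
#' The phenotype synonym map is stored verbatim here and applied only in the
#' benchmark stage ([map_ko_phenotypes()]).
#'
#' @param main_targets_path TSV `drug_id`, `protein_id`.
#' @param family_counts_path TSV `protein_id`, `family`, `count`.
#' @param metabolizing_path TSV `protein_id`.
#' @param known_causal_path TSV `protein_id`, `se_id`.
#' @param ko_reference_path TSV `protein_id`, `phenotype`.
#' @param phenotype_synonyms_path TSV `phenotype`, `se_id`.
#'
#' @return An [annotation_bundle()].
#' @export
read_annotations <- function(main_targets_path = NULL,
                             family_counts_path = NULL,
                             metabolizing_path = NULL,
                             known_causal_path = NULL,
                             ko_reference_path = NULL,
                             phenotype_synonyms_path = NULL) {
  rd <- function(path, cols) {
    if (is.null(path)) return(NULL)
    df <- read_tsv_quiet(path)
    require_columns(df, cols, path)
    df <- mutate(df, across(all_of(cols), as.character))
    ok <- stats::complete.cases(df[, cols])
    if (any(!ok))
      warn(sprintf("%s: skipped %d malformed row(s)", path, sum(!ok)))
    df[ok, ]
  }
  fam <- rd(family_counts_path, c("protein_id", "family"))
  if (!is.null(fam)) fam <- mutate(fam, count = as.integer(.data$count))
  annotation_bundle(
    main_targets = rd(main_targets_path, c("drug_id", "protein_id")),
    family_counts = fam,
    metabolizing = rd(metabolizing_path, "protein_id")$protein_id,
    known_causal = rd(known_causal_path, c("protein_id", "se_id")),
    ko_reference = rd(ko_reference_path, c("protein_id", "phenotype")),
    phenotype_synonyms = rd(phenotype_synonyms_path, c("phenotype", "se_id"))
  )
}

prediction_columns <- c("target_id", "protein_id", "mode", "se_id",
                        "a", "b", "c", "d", "p", "q", "excluded", "cluster_id")

#' Write / read a prediction table
#'
#' Predictions round-trip through TSV with full numeric precision; columns
#' beyond the canonical set are ignored on read (with a message).
#'
#' @param predictions prediction tibble from [run_enrichment()].
#' @param path TSV path.
#' @return `write_predictions()` returns the path invisibly;
#'   `read_predictions()` returns the prediction tibble.
#' @export
write_predictions <- function(predictions, path) {
  cols <- intersect(prediction_columns, names(predictions))
  out <- predictions[, cols]
  # 17 significant digits round-trip IEEE doubles exactly through strtod
  for (col in intersect(c("p", "q"), cols))
    out[[col]] <- sprintf("%.17g", out[[col]])
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  require_columns(df, c("target_id", "se_id", "a", "b", "c", "d", "p", "q"),
                  path)
  extra <- setdiff(names(df), prediction_columns)
  if (length(extra)) {
    inform(paste0("ignoring extra column(s): ", paste(extra, collapse = ", ")))
    df <- df[, setdiff(names(df), extra)]
  }
  df <- df |>
    mutate(across(all_of(intersect(c("a", "b", "c", "d"), names(df))),
                  as.integer),
           # base strtod is correctly rounded, preserving serialized doubles
           across(all_of(c("p", "q")), as.numeric))
  if ("excluded" %in% names(df)) df$excluded <- as.logical(df$excluded)
  else df$excluded <- FALSE
  if (!"cluster_id" %in% names(df)) df$cluster_id <- NA_character_
  as_tibble(df)
}

#' Write the network edge tables
#'
#' Inverse of [read_network_tables()]: emits the drug-target table (with mode
#' annotations re-attached) and the drug-side-effect table.
#'
#' @param network a [study_network()] with plain protein target nodes.
#' @param drug_target_path,drug_se_path output TSV paths.
#' @export
write_network_tables <- function(network, drug_target_path, drug_se_path) {
  dt <- network$drug_target_edges |>
    rename(protein_id = "target_id") |>
    left_join(network$mode_annotations, by = c("drug_id", "protein_id"))
  readr::write_tsv(dt, drug_target_path)
  readr::write_tsv(network$drug_se_edges, drug_se_path)
  invisible(network)
}
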