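#' Study network container
#'
#' A `study_network` holds the two bipartite edge sets of a side-effect study
#' — drugs to target nodes and drugs to side-effect terms — together with the
#' node tables and the *active drug set*, the subset of drugs used for
#' enrichment counting (all drugs until chemical de-redundancy shrinks it).
#'
#' Target nodes carry an action mode: every bound protein has a generic
#' `binding` node and, where agonist/antagonist information exists, an
#' additional virtual `activation` or `inhibition` node (see
#' [build_virtual_targets()]). After [merge_equivalent_targets()] a node may
#' represent several indistinguishable (protein, mode) members, listed in its
#' `members` list-column.
#'
#' @param drugs tibble with `drug_id` (unique, non-empty) and optional `name`.
#' @param targets tibble with `target_id`, `protein_id`, `mode` and a
#'   `members` list-column of tibbles (`protein_id`, `mode`).
#' @param side_effects tibble with `se_id` and optional `label`.
#' @param drug_target_edges tibble with `drug_id`, `target_id`.
#' @param drug_se_edges tibble with `drug_id`, `se_id` and optional
#'   `frequency` (preserved, unused by the statistics).
#' @param mode_annotations tibble with `drug_id`, `protein_id`, `mode`
#'   (`activation`/`inhibition`), consumed by [build_virtual_targets()].
#' @param active_drugs character vector of drug ids used for enrichment.
#'
#' @return An object of class `study_network`.
#' @export
study_network <- function(drugs, targets, side_effects,
                          drug_target_edges, drug_se_edges,
                          mode_annotations = NULL, active_drugs = NULL) {
  drugs <- as_tibble(drugs)
  side_effects <- as_tibble(side_effects)
  targets <- as_tibble(targets)
  drug_target_edges <- distinct(as_tibble(drug_target_edges))
  drug_se_edges <- distinct(as_tibble(drug_se_edges), .data$drug_id,
                            .data$se_id, .keep_all = TRUE)
  if (is.null(mode_annotations)) {
    mode_annotations <- tibble(drug_id = character(), protein_id = character(),
                               mode = character())
  }
  if (is.null(active_drugs)) active_drugs <- drugs$drug_id
  net <- structure(
    list(drugs = drugs, targets = targets, side_effects = side_effects,
         drug_target_edges = drug_target_edges, drug_se_edges = drug_se_edges,
         mode_annotations = as_tibble(mode_annotations),
         active_drugs = active_drugs),
    class = "study_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  stopifnot(inherits(net, "study_network"))
  if (anyDuplicated(net$drugs$drug_id)) abort("duplicate drug_id in drugs table")
  if (any(!nzchar(net$drugs$drug_id))) abort("empty drug_id in drugs table")
  if (anyDuplicated(net$targets$target_id)) abort("duplicate target_id")
  if (anyDuplicated(net$side_effects$se_id)) abort("duplicate se_id")
  miss_d <- setdiff(net$drug_target_edges$drug_id, net$drugs$drug_id)
  miss_t <- setdiff(net$drug_target_edges$target_id, net$targets$target_id)
  miss_s <- setdiff(net$drug_se_edges$se_id, net$side_effects$se_id)
  miss_d2 <- setdiff(net$drug_se_edges$drug_id, net$drugs$drug_id)
  if (length(c(miss_d, miss_d2)))
    abort(paste0("edge references unknown drug(s): ",
                 paste(head(unique(c(miss_d, miss_d2)), 5), collapse = ", ")))
  if (length(miss_t))
    abort(paste0("edge references unknown target(s): ",
                 paste(head(miss_t, 5), collapse = ", ")))
  if (length(miss_s))
    abort(paste0("edge references unknown side effect(s): ",
                 paste(head(miss_s, 5), collapse = ", ")))
  if (length(setdiff(net$active_drugs, net$drugs$drug_id)))
    abort("active_drugs is not a subset of the drug table")
  invisible(net)
}

make_target_id <- function(protein_id, mode) {
  if_else(mode == "binding", protein_id, paste(protein_id, mode, sep = ":"))
}

# one-member target table for plain protein ids (pre virtual-target stage)
plain_targets <- function(protein_ids) {
  protein_ids <- sort(unique(protein_ids))
  tibble(
    target_id = protein_ids,
    protein_id = protein_ids,
    mode = "binding",
    members = purrr::map(protein_ids,
                         ~ tibble(protein_id = .x, mode = "binding"))
  )
}

#' @export
print.study_network <- function(x, ...) {
  cat("<study_network>\n")
  cat(sprintf("  drugs: %d (%d active)  targets: %d  side effects: %d\n",
              nrow(x$drugs), length(x$active_drugs), nrow(x$targets),
              nrow(x$side_effects)))
  cat(sprintf("  drug-target edges: %d  drug-side-effect edges: %d\n",
              nrow(x$drug_target_edges), nrow(x$drug_se_edges)))
  invisible(x)
}

# per-stage node/edge counts used by the pipeline log
network_counts <- function(net) {
  tibble(drugs = nrow(net$drugs), active_drugs = length(net$active_drugs),
         targets = nrow(net$targets), side_effects = nrow(net$side_effects),
         drug_target_edges = nrow(net$drug_target_edges),
         drug_se_edges = nrow(net$drug_se_edges))
}

# edges restricted to the active drug set
active_target_edges <- function(net) {
  filter(net$drug_target_edges, .data$drug_id %in% net$active_drugs)
}

active_se_edges <- function(net) {
  filter(net$drug_se_edges, .data$drug_id %in% net$active_drugs)
}

# named list: target_id -> character vector of active drugs binding it
target_drug_sets <- function(net, target_ids = NULL) {
  edges <- active_target_edges(net)
  if (!is.null(target_ids)) edges <- filter(edges, .data$target_id %in% target_ids)
  split(edges$drug_id, factor(edges$target_id,
                              levels = unique(c(target_ids, edges$target_id))))
}

# expand a target node to the base proteins it represents
target_member_proteins <- function(net) {
  net$targets |>
    select("target_id", "members") |>
    tidyr::unnest("members") |>
    distinct(.data$target_id, .data$protein_id)
}

#' Annotation bundle
#'
#' Collects the optional side tables of a study: literature main targets,
#' GO-style protein family term counts, metabolizing-enzyme flags, known
#' causal protein-side-effect pairs, a mouse-knockout gene-phenotype
#' reference and the phenotype-to-side-effect synonym map.
#'
#' @param main_targets tibble `drug_id`, `protein_id`.
#' @param family_counts tibble `protein_id`, `family`, `count`.
#' @param metabolizing character vector of protein ids.
#' @param known_causal tibble `protein_id`, `se_id`.
#' @param ko_reference tibble `protein_id`, `phenotype`.
#' @param phenotype_synonyms tibble `phenotype`, `se_id`.
#'
#' @return An object of class `annotation_bundle`; missing pieces are empty.
#' @export
annotation_bundle <- function(main_targets = NULL, family_counts = NULL,
                              metabolizing = NULL, known_causal = NULL,
                              ko_reference = NULL, phenotype_synonyms = NULL) {
  tb <- function(x, proto) {
    if (is.null(x)) return(proto)
    out <- distinct(as_tibble(x)[, names(proto)])
    if ("count" %in% names(out)) {
      if (any(out$count < 0 | out$count != floor(out$count)))
        abort("family counts must be non-negative integers")
    }
    out
  }
  structure(list(
    main_targets = tb(main_targets,
                      tibble(drug_id = character(), protein_id = character())),
    family_counts = tb(family_counts,
                       tibble(protein_id = character(), family = character(),
                              count = integer())),
    metabolizing = unique(as.character(metabolizing %||% character())),
    known_causal = tb(known_causal,
                      tibble(protein_id = character(), se_id = character())),
    ko_reference = tb(ko_reference,
                      tibble(protein_id = character(), phenotype = character())),
    phenotype_synonyms = tb(phenotype_synonyms,
                            tibble(phenotype = character(), se_id = character()))
  ), class = "annotation_bundle")
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat("<annotation_bundle>\n")
  cat(sprintf(
    "  main targets: %d  family counts: %d  metabolizing: %d\n",
    nrow(x$main_targets), nrow(x$family_counts), length(x$metabolizing)))
  cat(sprintf(
    "  known causal pairs: %d  KO reference pairs: %d  synonyms: %d\n",
    nrow(x$known_causal), nrow(x$ko_reference), nrow(x$phenotype_synonyms)))
  invisible(x)
}
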