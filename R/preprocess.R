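#' Build action-mode virtual target nodes
#'
#' Every drug-protein binding edge is kept as an edge to the generic
#' `(protein, binding)` node. Where the drug's action mode on the protein is
#' known (agonist/activator or antagonist/inhibitor), an additional edge to a
#' virtual `(protein, activation)` or `(protein, inhibition)` node is added,
#' so that a beta blocker, for example, also targets the inhibited
#' beta-adrenergic receptor node. The two node kinds are tested
#' independently downstream.
#'
#' @param network a [study_network()] with plain protein target nodes.
#' @param mode_annotations tibble `drug_id`, `protein_id`, `mode`; defaults to
#'   the annotations stored on the network by [read_network_tables()]. Modes
#'   for drug-protein pairs without a binding edge are ignored with a warning.
#' @return The network with virtual target nodes and edges added.
#' @export
build_virtual_targets <- function(network,
                                  mode_annotations = network$mode_annotations) {
  stopifnot(all(network$targets$mode == "binding"))
  modes <- mode_annotations |>
    as_tibble() |>
    mutate(mode = normalize_mode(.data$mode)) |>
    filter(.data$mode != "binding") |>
    distinct(.data$drug_id, .data$protein_id, .data$mode)

  known <- semi_join(modes, network$drug_target_edges,
                     by = c(drug_id = "drug_id", protein_id = "target_id"))
  n_orphan <- nrow(modes) - nrow(known)
  if (n_orphan > 0)
    warn(sprintf("%d mode annotation(s) without a binding edge ignored",
                 n_orphan))

  virt_edges <- known |>
    mutate(target_id = make_target_id(.data$protein_id, .data$mode)) |>
    select("drug_id", "target_id")
  virt_nodes <- known |>
    distinct(.data$protein_id, .data$mode) |>
    mutate(target_id = make_target_id(.data$protein_id, .data$mode),
           members = purrr::map2(.data$protein_id, .data$mode,
                                 ~ tibble(protein_id = .x, mode = .y))) |>
    select("target_id", "protein_id", "mode", "members")

  study_network(
    drugs = network$drugs,
    targets = bind_rows(network$targets, virt_nodes) |>
      arrange(.data$target_id),
    side_effects = network$side_effects,
    drug_target_edges = bind_rows(network$drug_target_edges, virt_edges),
    drug_se_edges = network$drug_se_edges,
    mode_annotations = modes,
    active_drugs = network$active_drugs
  )
}

#' Merge targets with identical drug profiles
#'
#' Target nodes bound by exactly the same set of *active* drugs cannot be
#' distinguished by the drug-target data and are merged into one
#' non-redundant node whose `members` column lists all original
#' (protein, mode) members. Edges are relabelled to the merged node (and
#' deduplicated where a drug bound several members).
#'
#' @param network a [study_network()], typically after
#'   [build_virtual_targets()] and drug de-redundancy.
#' @return A list with elements `network` (merged) and `merge_map`, a tibble
#'   `target_id` (original) -> `merged_id`.
#' @export
merge_equivalent_targets <- function(network) {
  sets <- target_drug_sets(network)
  keys <- vapply(network$targets$target_id, function(t)
    paste(sort(sets[[t]] %||% character()), collapse = "\r"), character(1))
  groups <- split(network$targets$target_id, keys)

  merge_map <- purrr::map_dfr(groups, function(ids) {
    ids <- sort(ids)
    tibble(target_id = ids,
           merged_id = if (length(ids) == 1) ids else paste(ids, collapse = "+"))
  })

  targets <- network$targets |>
    left_join(merge_map, by = "target_id") |>
    group_by(.data$merged_id) |>
    summarise(
      protein_id = first(.data$protein_id[order(.data$target_id)]),
      mode = first(.data$mode[order(.data$target_id)]),
      members = list(distinct(bind_rows(.data$members))),
      .groups = "drop") |>
    rename(target_id = "merged_id") |>
    arrange(.data$target_id)

  edges <- network$drug_target_edges |>
    left_join(merge_map, by = "target_id") |>
    select(drug_id = "drug_id", target_id = "merged_id") |>
    distinct()

  net <- study_network(
    drugs = network$drugs, targets = targets,
    side_effects = network$side_effects,
    drug_target_edges = edges, drug_se_edges = network$drug_se_edges,
    mode_annotations = network$mode_annotations,
    active_drugs = network$active_drugs
  )
  list(network = net, merge_map = merge_map)
}

#' Tanimoto similarity of two fingerprints
#'
#' The standard 2D chemical similarity |A intersect B| / |A union B| over set
#' bits. Two all-zero fingerprints have similarity 0.
#'
#' @param fp_a,fp_b logical vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    abort("fingerprint length mismatch")
  u <- sum(fp_a | fp_b)
  if (u == 0) return(0)
  sum(fp_a & fp_b) / u
}

# full pairwise Tanimoto matrix via bit-matrix crossproduct
tanimoto_matrix <- function(fps) {
  m <- fingerprint_matrix(fps) * 1L
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  diag(sim) <- 1
  sim
}

#' Hobohm redundancy removal (algorithm 2)
#'
#' Greedy de-redundancy: repeatedly remove the drug with the most neighbours
#' above the similarity cutoff until no similar pair remains. Ties are broken
#' by removing the lexicographically greatest drug id, so the result is
#' deterministic. Drugs without a fingerprint are kept unconditionally (with
#' a warning).
#'
#' @param drugs character vector of drug ids to consider.
#' @param fingerprints fingerprint tibble ([read_fingerprints()]).
#' @param cutoff similarity above which two drugs count as redundant
#'   (default 0.7, the usual 2D Tanimoto redundancy threshold).
#' @return Character vector of kept drug ids (in input order). The kept set
#'   contains no pair with similarity > cutoff; this post-condition is
#'   asserted on every run.
#' @export
hobohm_reduce <- function(drugs, fingerprints, cutoff = 0.7) {
  drugs <- unique(as.character(drugs))
  have <- drugs[drugs %in% fingerprints$drug_id]
  missing <- setdiff(drugs, have)
  if (length(missing))
    warn(sprintf("%d drug(s) without fingerprints kept unconditionally",
                 length(missing)))
  if (length(have) < 2) return(drugs)

  fps <- fingerprints[match(have, fingerprints$drug_id), ]
  adj <- tanimoto_matrix(fps) > cutoff
  diag(adj) <- FALSE
  alive <- setNames(rep(TRUE, length(have)), have)
  deg <- rowSums(adj)
  while (any(deg[alive] > 0)) {
    cand <- names(deg)[alive & deg == max(deg[alive])]
    victim <- max(cand) # lexicographically greatest id removed on ties
    alive[victim] <- FALSE
    nb <- adj[victim, ] & alive
    deg[nb] <- deg[nb] - 1
    deg[victim] <- 0
    adj[victim, ] <- FALSE
    adj[, victim] <- FALSE
  }
  kept_fp <- names(alive)[alive]
  # post-condition: no kept pair above the cutoff
  if (length(kept_fp) > 1) {
    sub <- tanimoto_matrix(fps[match(kept_fp, fps$drug_id), ])
    diag(sub) <- 0
    stopifnot(all(sub <= cutoff))
  }
  drugs[drugs %in% c(kept_fp, missing)]
}

#' Restrict the active drug set by chemical de-redundancy
#'
#' Applies [hobohm_reduce()] to the network's active drugs. Removed drugs
#' stay in the network (they are still used when explaining observed
#' drug-side-effect pairs); only the active set used for enrichment counting
#' shrinks.
#'
#' @param network a [study_network()].
#' @param fingerprints fingerprint tibble, or `NULL` to skip.
#' @param cutoff Tanimoto cutoff (default 0.7).
#' @return The network with `active_drugs` reduced.
#' @export
apply_drug_deredundancy <- function(network, fingerprints, cutoff = 0.7) {
  if (is.null(fingerprints)) return(network)
  kept <- hobohm_reduce(network$active_drugs, fingerprints, cutoff)
  network$active_drugs <- kept
  validate_network(network)
  network
}

#' Drop weakly supported targets and side effects
#'
#' Target nodes and side-effect terms associated with fewer than `min_drugs`
#' active drugs carry too little signal for confident enrichment and are
#' removed (default 5). Drugs themselves are never removed, so the filter is
#' a single pass: removals cannot cascade.
#'
#' @param network a [study_network()] with the active drug set finalised.
#' @param min_drugs minimum number of active drugs (default 5).
#' @return The filtered network.
#' @export
filter_min_support <- function(network, min_drugs = 5) {
  t_counts <- active_target_edges(network) |> count(.data$target_id)
  keep_t <- t_counts$target_id[t_counts$n >= min_drugs]
  s_counts <- active_se_edges(network) |> count(.data$se_id)
  keep_s <- s_counts$se_id[s_counts$n >= min_drugs]

  study_network(
    drugs = network$drugs,
    targets = filter(network$targets, .data$target_id %in% keep_t),
    side_effects = filter(network$side_effects, .data$se_id %in% keep_s),
    drug_target_edges = filter(network$drug_target_edges,
                               .data$target_id %in% keep_t),
    drug_se_edges = filter(network$drug_se_edges, .data$se_id %in% keep_s),
    mode_annotations = network$mode_annotations,
    active_drugs = network$active_drugs
  )
}

#' Flag predictions for metabolizing enzymes
#'
#' Metabolizing enzymes (e.g. cytochromes) can associate with many side
#' effects indirectly, through shared metabolites, so their predictions are
#' flagged after testing and excluded from significance counting, clustering
#' and explanation — but retained in the output table. A merged node is
#' flagged if *any* member protein is metabolizing.
#'
#' @param predictions prediction tibble from [run_enrichment()].
#' @param network the tested [study_network()] (supplies merged members).
#' @param metabolizing character vector of metabolizing protein ids.
#' @return The predictions with the `excluded` flag set.
#' @export
flag_metabolizing_exclusions <- function(predictions, network, metabolizing) {
  if (length(metabolizing) == 0) {
    predictions$excluded <- FALSE
    return(predictions)
  }
  flagged <- target_member_proteins(network) |>
    filter(.data$protein_id %in% metabolizing) |>
    pull("target_id")
  mutate(predictions, excluded = .data$target_id %in% flagged)
}
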