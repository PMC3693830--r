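#' Directional co-binding fraction
#'
#' The fraction of active drugs binding `t1` that also bind `t2`. Used to
#' decide whether two predicted causal targets of the same side effect are
#' pharmacologically indistinguishable (family members, complex subunits)
#' because drugs that hit one usually hit the other.
#'
#' @param t1,t2 target node ids.
#' @param network a preprocessed [study_network()].
#' @return Fraction in \[0, 1\]; directional (`t1 -> t2`).
#' @export
cobinding_fraction <- function(t1, t2, network) {
  sets <- target_drug_sets(network, c(t1, t2))
  d1 <- sets[[t1]]
  d2 <- sets[[t2]]
  if (length(d1) == 0) abort(paste0("target has no active drugs: ", t1))
  length(intersect(d1, d2)) / length(d1)
}

#' Cluster the predicted causal targets of one side effect
#'
#' Builds an undirected graph over the significant target nodes of a side
#' effect, connecting two nodes when at least `threshold` of the drugs
#' binding one also bind the other (either direction qualifies), and returns
#' the connected components as clusters. When a cluster contains proteins
#' known to cause the side effect, the one attached to the smallest q becomes
#' the cluster seed.
#'
#' @param se_id side-effect term id.
#' @param significant_targets prediction rows for this side effect that
#'   passed [select_significant()].
#' @param network the tested [study_network()].
#' @param known_causal tibble `protein_id`, `se_id` of known causal pairs
#'   (optional).
#' @param threshold co-binding fraction at or above which two targets are
#'   linked (default 0.5, "at least half of the drugs").
#' @return A tibble with one row per cluster: `se_id`, `cluster_id`,
#'   `members` (list of target ids), `proteins` (list of base protein ids),
#'   `seed`, `q` (minimum member q), `n_members`.
#' @export
build_side_effect_clusters <- function(se_id, significant_targets, network,
                                       known_causal = NULL, threshold = 0.5) {
  stopifnot(all(significant_targets$se_id == se_id))
  ids <- significant_targets$target_id
  if (length(ids) == 0) return(empty_cluster_tbl())

  sets <- target_drug_sets(network, ids)
  sizes <- lengths(sets[ids])
  if (any(sizes == 0))
    abort("significant target with no active drugs cannot be clustered")

  comp <- if (length(ids) == 1) {
    setNames(1L, ids)
  } else {
    # incidence matrix: active drugs x targets; co-binding via crossprod
    drugs <- unique(unlist(sets))
    m <- vapply(ids, function(t) drugs %in% sets[[t]], logical(length(drugs)))
    m <- matrix(m, nrow = length(drugs), dimnames = list(NULL, ids))
    inter <- crossprod(m * 1L)
    frac <- inter / sizes[ids] # row i: |i & j| / |i|
    linked <- (frac >= threshold) | (t(frac) >= threshold)
    diag(linked) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
    igraph::components(g)$membership[ids]
  }

  member_proteins <- target_member_proteins(network)
  qs <- setNames(significant_targets$q, significant_targets$target_id)
  kc <- if (is.null(known_causal)) character() else
    known_causal$protein_id[known_causal$se_id == se_id]

  purrr::map_dfr(split(ids, comp), function(members) {
    members <- sort(members)
    prots <- member_proteins |>
      filter(.data$target_id %in% members) |>
      pull("protein_id") |>
      unique()
    seed <- NA_character_
    seeds <- intersect(prots, kc)
    if (length(seeds)) {
      # among known causal proteins, pick the one whose best node q is lowest
      best <- member_proteins |>
        filter(.data$protein_id %in% seeds, .data$target_id %in% members) |>
        mutate(q = qs[.data$target_id]) |>
        arrange(.data$q, .data$protein_id)
      seed <- best$protein_id[1]
      if (length(seeds) > 1)
        inform(sprintf("side effect %s: cluster holds %d known causal proteins",
                       se_id, length(seeds)))
    }
    best_q <- min(qs[members])
    n_members <- length(members)
    tibble(se_id = se_id, members = list(members),
           proteins = list(sort(prots)), seed = seed, q = best_q,
           n_members = n_members)
  })
}

empty_cluster_tbl <- function() {
  tibble(se_id = character(), cluster_id = character(), members = list(),
         proteins = list(), seed = character(), q = numeric(),
         n_members = integer())
}

#' Cluster predictions for every side effect
#'
#' Applies [build_side_effect_clusters()] to each side effect with at least
#' one qualifying prediction and writes cluster ids back into the prediction
#' table.
#'
#' @param predictions prediction tibble from [run_enrichment()] (optionally
#'   flagged by [flag_metabolizing_exclusions()]).
#' @param network the tested [study_network()].
#' @param known_causal optional tibble `protein_id`, `se_id`.
#' @param q_cutoff q-value cutoff defining the clustered prediction set
#'   (default 0.01); use `Inf` to cluster all tested pairs (the benchmark
#'   background).
#' @param threshold co-binding threshold (default 0.5).
#' @return A list with `clusters` (tibble, one row per cluster, `cluster_id`
#'   assigned) and `predictions` (input with `cluster_id` filled in).
#' @export
cluster_predictions <- function(predictions, network, known_causal = NULL,
                                q_cutoff = 0.01, threshold = 0.5) {
  sig <- if (is.finite(q_cutoff)) select_significant(predictions, q_cutoff)
         else filter(predictions, !.data$excluded)
  if (nrow(sig) == 0) {
    return(list(clusters = empty_cluster_tbl(), predictions = predictions))
  }
  clusters <- sig |>
    group_by(.data$se_id) |>
    dplyr::group_map(~ build_side_effect_clusters(
      .y$se_id, mutate(.x, se_id = .y$se_id), network,
      known_causal = known_causal, threshold = threshold)) |>
    bind_rows() |>
    arrange(.data$se_id, .data$q) |>
    group_by(.data$se_id) |>
    mutate(cluster_id = paste0(.data$se_id, ":", row_number())) |>
    ungroup() |>
    select("se_id", "cluster_id", "members", "proteins", "seed", "q",
           "n_members")

  cl_by_target <- clusters |>
    select("se_id", "cluster_id", "members") |>
    tidyr::unnest_longer("members", values_to = "target_id")
  predictions <- predictions |>
    select(-"cluster_id") |>
    left_join(select(cl_by_target, "se_id", "target_id", "cluster_id"),
              by = c("se_id", "target_id"))
  list(clusters = clusters, predictions = predictions)
}

#' Count clusters per side effect and in total
#'
#' Clusters are the counting unit of the knockout-phenotype benchmark: a
#' verified prediction for one member explains the whole cluster.
#'
#' @param clusters cluster tibble from [cluster_predictions()].
#' @return A list with `per_side_effect` (tibble `se_id`, `n_clusters`) and
#'   `total`.
#' @export
count_clusters <- function(clusters) {
  per_se <- count(clusters, .data$se_id, name = "n_clusters")
  list(per_side_effect = per_se, total = nrow(clusters))
}
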