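#' Classify proteins into target families
#'
#' Assigns each protein the family term with the highest annotation count
#' (GPCR, nuclear receptor, ion channel, kinase, enzyme); ties are broken by
#' that fixed precedence, and proteins without counts fall into `other`.
#'
#' @param protein_ids character vector.
#' @param family_counts tibble `protein_id`, `family`, `count`.
#' @return Character vector of family labels, one per input protein.
#' @export
classify_family <- function(protein_ids, family_counts) {
  if (nrow(family_counts) == 0) return(rep("other", length(protein_ids)))
  bad <- setdiff(unique(family_counts$family), FAMILY_LEVELS)
  if (length(bad))
    abort(paste0("unknown family term(s): ", paste(bad, collapse = ", ")))
  best <- family_counts |>
    mutate(rank = match(.data$family, FAMILY_LEVELS)) |>
    group_by(.data$protein_id) |>
    arrange(dplyr::desc(.data$count), .data$rank) |>
    summarise(family = first(.data$family), .groups = "drop")
  out <- best$family[match(protein_ids, best$protein_id)]
  out[is.na(out)] <- "other"
  out
}

#' Resolve the main targets of each drug
#'
#' Main targets are the proteins credited with a drug's therapeutic
#' mechanism. Whole-family annotations are uninformative, so candidate main
#' targets belonging to a family with `max_family_size` or more members
#' *within the drug's own candidate list* are removed — a kinase inhibitor
#' does not get every kinase as its main target.
#'
#' @param annotations an [annotation_bundle()] carrying `main_targets` and
#'   `family_counts`.
#' @param drug_id optional single drug id; default resolves all drugs.
#' @param max_family_size family size at or above which candidates are
#'   dropped (default 10).
#' @return A tibble `drug_id`, `protein_id`, `family`.
#' @export
resolve_main_targets <- function(annotations, drug_id = NULL,
                                 max_family_size = 10) {
  mt <- annotations$main_targets
  if (!is.null(drug_id)) mt <- filter(mt, .data$drug_id %in% !!drug_id)
  if (nrow(mt) == 0)
    return(tibble(drug_id = character(), protein_id = character(),
                  family = character()))
  mt |>
    mutate(family = classify_family(.data$protein_id,
                                    annotations$family_counts)) |>
    group_by(.data$drug_id, .data$family) |>
    filter(n() < max_family_size) |>
    ungroup()
}

#' Explain one observed drug / side-effect pair
#'
#' Looks for significant causal target nodes of the side effect among the
#' drug's own targets. Mode compatibility is encoded in the network: a drug
#' has an edge to a `(protein, inhibition)` node only if it is annotated to
#' inhibit the protein, while generic binding nodes match any binder. The
#' record is categorised against the drug's resolved main targets as
#' `main_only`, `both`, `off_only` or `unexplained`.
#'
#' @param drug_id,se_id an observed drug-side-effect edge.
#' @param significant_predictions output of [select_significant()].
#' @param network the tested [study_network()] (full drug set; drugs removed
#'   by chemical de-redundancy are still explained).
#' @param main_targets tibble `drug_id`, `protein_id` from
#'   [resolve_main_targets()].
#' @param family_counts tibble for [classify_family()] (optional).
#' @return One-row tibble: `drug_id`, `se_id`, `explaining` (list of target
#'   ids), `proteins` (list), `category`, `families` (list).
#' @export
explain_pair <- function(drug_id, se_id, significant_predictions, network,
                         main_targets,
                         family_counts = tibble(protein_id = character(),
                                                family = character(),
                                                count = integer())) {
  if (!drug_id %in% network$drugs$drug_id)
    abort(paste0("unknown drug: ", drug_id))
  if (!se_id %in% network$side_effects$se_id)
    abort(paste0("unknown side effect: ", se_id))
  did <- drug_id
  sid <- se_id
  edge <- filter(network$drug_se_edges, .data$drug_id == did,
                 .data$se_id == sid)
  if (nrow(edge) == 0)
    abort(sprintf("(%s, %s) is not an observed drug-side-effect pair",
                  did, sid))
  records <- explain_records(
    filter(network$drug_se_edges, .data$drug_id == did, .data$se_id == sid),
    significant_predictions, network, main_targets, family_counts)
  records
}

# vectorised core: one explanation record per observed drug-SE edge supplied
explain_records <- function(observed_edges, significant_predictions, network,
                            main_targets, family_counts) {
  mp <- target_member_proteins(network)
  sig <- significant_predictions |>
    select("target_id", "se_id") |>
    inner_join(mp, by = "target_id", relationship = "many-to-many")

  hits <- observed_edges |>
    select("drug_id", "se_id") |>
    inner_join(network$drug_target_edges, by = "drug_id",
               relationship = "many-to-many") |>
    inner_join(sig, by = c("se_id", "target_id"),
               relationship = "many-to-many")

  main_key <- paste(main_targets$drug_id, main_targets$protein_id)
  fam_of <- function(p) classify_family(p, family_counts)

  agg <- hits |>
    group_by(.data$drug_id, .data$se_id) |>
    summarise(
      explaining = list(sort(unique(.data$target_id))),
      proteins = list(sort(unique(.data$protein_id))),
      .groups = "drop")

  out <- observed_edges |>
    select("drug_id", "se_id") |>
    left_join(agg, by = c("drug_id", "se_id"))

  out$explaining <- purrr::map(out$explaining, ~ .x %||% character())
  out$proteins <- purrr::map(out$proteins, ~ .x %||% character())
  out$category <- purrr::map2_chr(out$proteins, out$drug_id, function(p, d) {
    if (length(p) == 0) return("unexplained")
    main <- paste(d, p) %in% main_key
    if (all(main)) "main_only" else if (any(main)) "both" else "off_only"
  })
  out$families <- purrr::map(out$proteins, function(p) {
    if (length(p) == 0) character() else sort(unique(fam_of(p)))
  })
  select(out, "drug_id", "se_id", "explaining", "proteins", "category",
         "families")
}

#' Summarise explained drug / side-effect fractions
#'
#' Explains every observed drug-side-effect pair whose side effect has at
#' least one significant causal prediction, then reports (i) the category
#' split main-only / both / off-only / unexplained over drugs with known main
#' targets, (ii) the fraction of pairs explainable through each protein
#' family, and (iii) per drug's most prevalent main-target family, the
#' fraction explained by any target and by that family's proteins.
#'
#' @param network the tested [study_network()].
#' @param predictions prediction tibble (flags applied).
#' @param annotations an [annotation_bundle()].
#' @param q_cutoff significance cutoff (default 0.01).
#' @param max_family_size passed to [resolve_main_targets()].
#' @return An object of class `adr_explanation`: list with `records`,
#'   `by_category`, `by_family`, `by_main_family`.
#' @export
summarize_explained_fractions <- function(network, predictions, annotations,
                                          q_cutoff = 0.01,
                                          max_family_size = 10) {
  sig <- select_significant(predictions, q_cutoff)
  main <- resolve_main_targets(annotations, max_family_size = max_family_size)
  considered <- filter(network$drug_se_edges, .data$se_id %in% sig$se_id)
  records <- explain_records(considered, sig, network, main,
                             annotations$family_counts)

  # (i) category split, over drugs with a non-empty resolved main-target set
  with_main <- filter(records, .data$drug_id %in% main$drug_id)
  by_category <- with_main |>
    count(category = factor(.data$category,
                            levels = c("main_only", "both", "off_only",
                                       "unexplained")),
          .drop = FALSE, name = "n") |>
    mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else
      NA_real_,
      denominator = sum(.data$n))

  # (ii) fraction of all considered pairs explainable through each family
  by_family <- purrr::map_dfr(c(FAMILY_LEVELS, "any"), function(f) {
    hit <- purrr::map_lgl(records$families, function(fs)
      if (f == "any") length(fs) > 0 else f %in% fs)
    tibble(family = f, n_explained = sum(hit), denominator = nrow(records),
           fraction = if (nrow(records) > 0) mean(hit) else NA_real_)
  })

  # (iii) drugs grouped by their most prevalent main-target family
  main_family <- main |>
    group_by(.data$drug_id) |>
    summarise(main_family = {
      tab <- table(factor(.data$family, levels = FAMILY_LEVELS))
      names(tab)[which.max(tab)] # which.max honours precedence order on ties
    }, .groups = "drop")
  by_main_family <- with_main |>
    inner_join(main_family, by = "drug_id") |>
    group_by(.data$main_family) |>
    summarise(
      n_pairs = n(),
      explained_any = mean(.data$category != "unexplained"),
      explained_by_family = mean(purrr::map2_lgl(
        .data$families, .data$main_family, ~ .y %in% .x)),
      .groups = "drop")

  structure(list(records = records, by_category = by_category,
                 by_family = by_family, by_main_family = by_main_family,
                 q_cutoff = q_cutoff),
            class = "adr_explanation")
}

#' @export
print.adr_explanation <- function(x, ...) {
  cat("<adr_explanation>  pairs considered:", nrow(x$records), "\n")
  fr <- x$by_category
  cat(sprintf("  main-only %.1f%%  both %.1f%%  off-only %.1f%%  unexplained %.1f%%  (n = %d)\n",
              100 * fr$fraction[1], 100 * fr$fraction[2],
              100 * fr$fraction[3], 100 * fr$fraction[4],
              fr$denominator[1]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.adr_explanation <- function(x, ...) x$by_category

#' @exportS3Method generics::glance
glance.adr_explanation <- function(x, ...) {
  fr <- setNames(x$by_category$fraction, x$by_category$category)
  tibble(n_pairs = nrow(x$records),
         n_pairs_with_main = x$by_category$denominator[1],
         main_only = fr[["main_only"]], both = fr[["both"]],
         off_only = fr[["off_only"]], unexplained = fr[["unexplained"]],
         q_cutoff = x$q_cutoff)
}
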