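#' Map knockout phenotypes to side-effect terms
#'
#' Translates a mouse gene-phenotype reference into protein / side-effect
#' pairs by strict synonym matching: only phenotypes with an entry in the
#' synonym map contribute; everything else is skipped (count reported).
#'
#' @param ko_reference tibble `protein_id`, `phenotype`.
#' @param phenotype_synonyms tibble `phenotype`, `se_id`.
#' @return A deduplicated tibble `protein_id`, `se_id` with attribute
#'   `n_unmapped`.
#' @export
map_ko_phenotypes <- function(ko_reference, phenotype_synonyms) {
  ko <- distinct(as_tibble(ko_reference), .data$protein_id, .data$phenotype)
  syn <- distinct(as_tibble(phenotype_synonyms), .data$phenotype, .data$se_id)
  mapped <- inner_join(ko, syn, by = "phenotype",
                       relationship = "many-to-many") |>
    distinct(.data$protein_id, .data$se_id)
  n_unmapped <- nrow(anti_join(ko, syn, by = "phenotype"))
  if (n_unmapped > 0)
    inform(sprintf("%d knockout phenotype(s) without a synonym skipped",
                   n_unmapped))
  structure(mapped, n_unmapped = n_unmapped)
}

#' Best q-value per base protein / side effect
#'
#' Collapses action-mode variants and merged members to base protein ids and
#' keeps, for each protein / side-effect pair, the smallest q over all its
#' target-node variants — the benchmark works at the mode-agnostic protein
#' level.
#'
#' @param predictions prediction tibble.
#' @param network the tested [study_network()] (supplies merged members).
#' @return A tibble `protein_id`, `se_id`, `q` (and `p`, the p attached to
#'   the best-q node).
#' @export
collapse_best_q <- function(predictions, network) {
  predictions |>
    select("target_id", "se_id", "p", "q") |>
    inner_join(target_member_proteins(network), by = "target_id",
               relationship = "many-to-many") |>
    group_by(.data$protein_id, .data$se_id) |>
    arrange(.data$q, .data$p) |>
    summarise(p = first(.data$p), q = first(.data$q), .groups = "drop")
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the reference sample is stochastically smaller than the
#' background (its empirical CDF lies above): D+ = sup over x of
#' F_ref(x) - F_bg(x). The permutation p-value is primary; when all
#' choose(m+n, m) label splits are enumerable within `n_permutations` the
#' enumeration is exact, otherwise `n_permutations` random label shuffles are
#' drawn (govern with `seed`). The asymptotic tail bound
#' exp(-2 D+^2 mn/(m+n)) is reported alongside.
#'
#' @param reference_qs,background_qs numeric samples (e.g. q-values of
#'   reference pairs vs all other tested pairs).
#' @param n_permutations permutation budget (default 1e5).
#' @param seed optional integer seed for the permutation draw.
#' @return A list: `d_plus`, `p_perm`, `p_asymptotic`, `exact` (logical:
#'   enumeration used), `m`, `n`.
#' @export
ks_one_sided <- function(reference_qs, background_qs, n_permutations = 1e5,
                         seed = NULL) {
  m <- length(reference_qs)
  n <- length(background_qs)
  if (m == 0 || n == 0) abort("both KS samples must be non-empty")
  pooled <- c(reference_qs, background_qs)
  o <- order(pooled)
  sorted <- pooled[o]
  is_ref <- o <= m
  step <- c(sorted[-length(sorted)] != sorted[-1], TRUE)
  d_obs <- .ks_dplus_sorted(is_ref, step, m, n)

  n_splits <- suppressWarnings(choose(m + n, m))
  if (is.finite(n_splits) && n_splits <= n_permutations) {
    splits <- combn(m + n, m)
    d_perm <- apply(splits, 2, function(ix) {
      lab <- logical(m + n)
      lab[ix] <- TRUE
      .ks_dplus_sorted(lab, step, m, n)
    })
    p_perm <- mean(d_perm >= d_obs - 1e-12)
    exact <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    d_perm <- .ks_dplus_perm(step, m, n, as.integer(n_permutations))
    p_perm <- (1 + sum(d_perm >= d_obs - 1e-12)) / (n_permutations + 1)
    exact <- FALSE
  }
  p_asym <- min(1, exp(-2 * d_obs^2 * m * n / (m + n)))
  list(d_plus = d_obs, p_perm = p_perm, p_asymptotic = p_asym, exact = exact,
       m = m, n = n)
}

#' Cluster match-rate enrichment against a reference
#'
#' A cluster "matches" the reference when any member protein forms a
#' reference pair with the cluster's side effect. The significant clusters
#' are tested for enrichment of matches over all clusters with a one-sided
#' Fisher test on the 2x2 table (matched/unmatched x significant/other).
#'
#' @param clusters_at_cutoff cluster tibble for the significant predictions.
#' @param all_clusters cluster tibble for all tested pairs (the background);
#'   must include at least as many clusters as `clusters_at_cutoff`.
#' @param reference tibble `protein_id`, `se_id`.
#' @return A list: `table` (tibble a, b, c, d), `p`, `matched_significant`,
#'   `n_significant`, `matched_total`, `n_total`, `rate_significant`,
#'   `rate_total`.
#' @export
match_rate_fisher <- function(clusters_at_cutoff, all_clusters, reference) {
  matched <- function(cl) {
    if (nrow(cl) == 0) return(logical())
    purrr::map2_lgl(cl$proteins, cl$se_id, function(prots, se) {
      any(reference$se_id == se & reference$protein_id %in% prots)
    })
  }
  m_sig <- matched(clusters_at_cutoff)
  m_all <- matched(all_clusters)
  n_sig <- length(m_sig)
  n_all <- length(m_all)
  if (n_all < n_sig) abort("background cluster set smaller than significant set")
  a <- sum(m_sig)
  b <- n_sig - a
  cc <- sum(m_all) - a
  d <- (n_all - n_sig) - cc
  p <- if (n_sig == 0) 1 else fisher_greater(a, b, cc, d)
  list(table = tibble(a = a, b = b, c = cc, d = d), p = p,
       matched_significant = a, n_significant = n_sig,
       matched_total = sum(m_all), n_total = n_all,
       rate_significant = if (n_sig > 0) a / n_sig else NA_real_,
       rate_total = if (n_all > 0) sum(m_all) / n_all else NA_real_)
}

#' Benchmark predictions against an independent reference
#'
#' Combines the two validation views: (i) the q-value distribution of
#' reference pairs versus all other tested pairs (one-sided KS, permutation
#' p-value) after [collapse_best_q()]; (ii) cluster-level match-rate
#' enrichment ([match_rate_fisher()]). Set `unit = "pair"` for the
#' no-clustering variant in which every prediction is its own counting unit.
#'
#' @param predictions prediction tibble (flags applied).
#' @param network the tested [study_network()].
#' @param reference tibble `protein_id`, `se_id` (e.g. from
#'   [map_ko_phenotypes()]).
#' @param q_cutoff significance cutoff (default 0.01).
#' @param cobinding_threshold cluster linking threshold (default 0.5).
#' @param unit `"cluster"` (default) or `"pair"`.
#' @param n_permutations,seed passed to [ks_one_sided()].
#' @return An object of class `adr_benchmark`: list with `ks`, `match`,
#'   `reference_size`, `unit`.
#' @export
run_benchmark <- function(predictions, network, reference, q_cutoff = 0.01,
                          cobinding_threshold = 0.5,
                          unit = c("cluster", "pair"),
                          n_permutations = 1e5, seed = NULL) {
  unit <- arg_match(unit)
  collapsed <- collapse_best_q(filter(predictions, !.data$excluded), network)
  in_ref <- paste(collapsed$protein_id, collapsed$se_id) %in%
    paste(reference$protein_id, reference$se_id)
  ks <- if (any(in_ref) && any(!in_ref)) {
    ks_one_sided(collapsed$q[in_ref], collapsed$q[!in_ref],
                 n_permutations = n_permutations, seed = seed)
  } else NULL

  if (unit == "cluster") {
    sig_cl <- cluster_predictions(predictions, network, q_cutoff = q_cutoff,
                                  threshold = cobinding_threshold)$clusters
    all_cl <- cluster_predictions(predictions, network, q_cutoff = Inf,
                                  threshold = cobinding_threshold)$clusters
  } else {
    as_cl <- function(df) {
      mp <- target_member_proteins(network)
      df |>
        inner_join(mp, by = "target_id", relationship = "many-to-many") |>
        group_by(.data$target_id, .data$se_id) |>
        summarise(proteins = list(unique(.data$protein_id)),
                  q = first(.data$q), .groups = "drop")
    }
    preds <- filter(predictions, !.data$excluded)
    sig_cl <- as_cl(filter(preds, .data$q < q_cutoff))
    all_cl <- as_cl(preds)
  }
  match <- match_rate_fisher(sig_cl, all_cl, reference)

  structure(list(ks = ks, match = match, reference_size = nrow(reference),
                 unit = unit, q_cutoff = q_cutoff),
            class = "adr_benchmark")
}

#' @export
print.adr_benchmark <- function(x, ...) {
  cat("<adr_benchmark>  unit:", x$unit, "\n")
  if (!is.null(x$ks))
    cat(sprintf("  KS D+ = %.3f  (perm p = %.3g, asymptotic p = %.3g)\n",
                x$ks$d_plus, x$ks$p_perm, x$ks$p_asymptotic))
  m <- x$match
  cat(sprintf("  match rate: %d/%d significant (%.1f%%) vs %d/%d overall (%.1f%%), Fisher p = %.3g\n",
              m$matched_significant, m$n_significant,
              100 * (m$rate_significant %||% NA), m$matched_total, m$n_total,
              100 * (m$rate_total %||% NA), m$p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.adr_benchmark <- function(x, ...) {
  tibble(
    statistic = c("ks_d_plus", "ks_p_perm", "ks_p_asymptotic",
                  "match_p", "rate_significant", "rate_total"),
    value = c(x$ks$d_plus %||% NA_real_, x$ks$p_perm %||% NA_real_,
              x$ks$p_asymptotic %||% NA_real_, x$match$p,
              x$match$rate_significant, x$match$rate_total)
  )
}

#' @exportS3Method generics::glance
glance.adr_benchmark <- function(x, ...) {
  tibble(
    d_plus = x$ks$d_plus %||% NA_real_,
    ks_p_perm = x$ks$p_perm %||% NA_real_,
    match_p = x$match$p,
    matched_significant = x$match$matched_significant,
    n_significant = x$match$n_significant,
    matched_total = x$match$matched_total,
    n_total = x$match$n_total,
    reference_size = x$reference_size,
    unit = x$unit
  )
}
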