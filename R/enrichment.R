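#' Contingency table for one target / side-effect pair
#'
#' Counts, over the active drug set, the drugs that bind the target and
#' elicit the side effect (`a`), that bind but do not elicit (`b`), that
#' elicit without binding (`c`), and that do neither (`d`).
#'
#' @param target_id target node id present in the network.
#' @param se_id side-effect term id present in the network.
#' @param network a preprocessed [study_network()].
#' @return A one-row tibble with columns `a`, `b`, `c`, `d`.
#' @export
contingency_table <- function(target_id, se_id, network) {
  if (!target_id %in% network$targets$target_id)
    abort(paste0("unknown target: ", target_id))
  if (!se_id %in% network$side_effects$se_id)
    abort(paste0("unknown side effect: ", se_id))
  tid <- target_id
  sid <- se_id
  binders <- active_target_edges(network) |>
    filter(.data$target_id == tid) |> pull("drug_id")
  elicitors <- active_se_edges(network) |>
    filter(.data$se_id == sid) |> pull("drug_id")
  n <- length(network$active_drugs)
  a <- length(intersect(binders, elicitors))
  tibble(a = a, b = length(binders) - a, c = length(elicitors) - a,
         d = n - length(binders) - length(elicitors) + a)
}

#' One-sided Fisher exact test for overrepresentation
#'
#' Exact hypergeometric upper tail P(X >= a) with all margins fixed,
#' vectorised over tables. Computed through the log-space hypergeometric
#' distribution function, so very small p-values keep full accuracy. An
#' empty overlap (`a = 0`) gives p = 1.
#'
#' @param a,b,c,d table counts as in [contingency_table()] (vectorised).
#' @return Numeric vector of one-sided p-values.
#' @export
fisher_greater <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("negative contingency counts")
  # P(X >= a) for X ~ Hypergeom(m = a+b binders, n = c+d rest, k = a+c)
  exp(phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE, log.p = TRUE))
}

# two-sided variant (sum of tables at most as probable), offered behind the
# `alternative` flag of run_enrichment(); one-sided is the study default
fisher_two_sided <- function(a, b, c, d) {
  purrr::pmap_dbl(list(a, b, c, d), function(a, b, c, d)
    stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value)
}

#' Estimate q-values from a set of p-values
#'
#' The q-value of a test is the minimal false discovery rate at which it
#' would be called significant. `method = "storey-smoother"` estimates the
#' true-null proportion pi0 by evaluating pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda)) on the grid lambda = 0, 0.05, ..., 0.90 and smoothing it
#' with a natural cubic smoothing spline (df = 3), taking the value at the
#' largest lambda, clipped to (0, 1]. The estimator falls back to the
#' conservative pi0 = 1 (which reduces to Benjamini-Hochberg) whenever its
#' own assumptions have no support in the data: fewer than 100 p-values,
#' a p-value tail above the largest lambda holding under a quarter of the
#' mass a uniform null would put there (typical for strongly discrete
#' one-sided p-value sets), or a non-positive smoothed estimate.
#' `method = "bh"` forces pi0 = 1.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param method `"storey-smoother"` (default) or `"bh"`.
#' @return A list with `qvalues` (same order as input, each the running
#'   minimum of pi0 * m * p / rank, clipped to \[0, 1\]) and `pi0`.
#' @export
estimate_qvalues <- function(pvalues, method = c("storey-smoother", "bh")) {
  method <- arg_match(method)
  m <- length(pvalues)
  if (m == 0) abort("empty p-value vector")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    abort("p-values must lie in [0, 1]")

  pi0 <- 1
  lambda_max <- 0.90
  if (method == "storey-smoother" && m >= 100) {
    # The smoother reads the true-null proportion off the tail of the
    # p-value distribution, so it needs the uniform-null tail to exist:
    # any mixture with a sizeable null fraction puts ~pi0 * (1 - lambda_max)
    # of its mass above lambda_max. Discrete one-sided tests restricted to
    # pairs with a >= 1 can have (almost) no mass there, in which case the
    # spline extrapolates noise towards 0; fall back to the conservative
    # pi0 = 1 when the observed tail is under a quarter of the uniform one.
    tail_ok <- mean(pvalues > lambda_max) >= (1 - lambda_max) / 4
    if (!tail_ok) {
      inform("p-value tail too sparse for the pi0 smoother; using pi0 = 1")
    } else {
      lambda <- seq(0, lambda_max, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l),
                      numeric(1))
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- predict(fit, x = lambda_max)$y
      pi0 <- min(pi0, 1)
      if (pi0 <= 0) {
        inform("pi0 estimate non-positive; falling back to pi0 = 1")
        pi0 <- 1
      }
    }
  }

  o <- order(pvalues)
  q_sorted <- pi0 * (m / seq_len(m)) * pvalues[o]
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  list(qvalues = q, pi0 = pi0)
}

#' Test all protein-node / side-effect pairs for overrepresentation
#'
#' Runs [fisher_greater()] on every (target node, side effect) pair with at
#' least one co-annotated active drug — pairs with `a = 0` are untestable
#' for overrepresentation and are excluded from the universe — and estimates
#' q-values jointly over all tested pairs.
#'
#' @param network a preprocessed [study_network()].
#' @param fdr_method passed to [estimate_qvalues()].
#' @param alternative `"greater"` (overrepresentation, the study design) or
#'   `"two.sided"`.
#' @return A tibble of class `adr_predictions`, sorted by q then p, with
#'   columns `target_id`, `protein_id`, `mode`, `se_id`, `a`, `b`, `c`, `d`,
#'   `p`, `q`, `excluded`, `cluster_id`, and attributes `pi0`, `n_active`,
#'   `n_tested`.
#' @export
run_enrichment <- function(network, fdr_method = "storey-smoother",
                           alternative = c("greater", "two.sided")) {
  alternative <- arg_match(alternative)
  n_active <- length(network$active_drugs)
  dt <- active_target_edges(network)
  se <- active_se_edges(network)

  n_binders <- count(dt, .data$target_id, name = "n_binders")
  n_elicit <- count(se, .data$se_id, name = "n_elicit")

  pairs <- inner_join(dt, select(se, "drug_id", "se_id"), by = "drug_id",
                      relationship = "many-to-many") |>
    count(.data$target_id, .data$se_id, name = "a")
  if (nrow(pairs) == 0) abort("no testable target/side-effect pairs")

  recs <- pairs |>
    left_join(n_binders, by = "target_id") |>
    left_join(n_elicit, by = "se_id") |>
    mutate(b = .data$n_binders - .data$a,
           c = .data$n_elicit - .data$a,
           d = n_active - .data$n_binders - .data$c) |>
    select(-"n_binders", -"n_elicit")

  recs$p <- if (alternative == "greater") {
    fisher_greater(recs$a, recs$b, recs$c, recs$d)
  } else {
    fisher_two_sided(recs$a, recs$b, recs$c, recs$d)
  }
  fdr <- estimate_qvalues(recs$p, method = fdr_method)
  recs$q <- fdr$qvalues

  recs <- recs |>
    left_join(select(network$targets, "target_id", "protein_id", "mode"),
              by = "target_id") |>
    mutate(excluded = FALSE, cluster_id = NA_character_) |>
    select(all_of(prediction_columns)) |>
    arrange(.data$q, .data$p, .data$target_id, .data$se_id)

  structure(recs, class = c("adr_predictions", class(recs)),
            pi0 = fdr$pi0, n_active = n_active, n_tested = nrow(recs),
            fdr_method = fdr_method)
}

#' Select significant, non-excluded predictions
#'
#' @param predictions prediction tibble.
#' @param q_cutoff strict upper bound on q (default 0.01).
#' @return Rows with `q < q_cutoff` and `excluded == FALSE`.
#' @export
select_significant <- function(predictions, q_cutoff = 0.01) {
  filter(predictions, .data$q < q_cutoff, !.data$excluded)
}

#' @exportS3Method generics::tidy
tidy.adr_predictions <- function(x, ...) {
  as_tibble(unclass_predictions(x))
}

#' @exportS3Method generics::glance
glance.adr_predictions <- function(x, q_cutoff = 0.01, ...) {
  tibble(
    n_tested = attr(x, "n_tested") %||% nrow(x),
    n_active_drugs = attr(x, "n_active") %||% NA_integer_,
    pi0 = attr(x, "pi0") %||% NA_real_,
    n_significant = nrow(select_significant(x, q_cutoff)),
    n_excluded = sum(x$excluded),
    q_cutoff = q_cutoff
  )
}

unclass_predictions <- function(x) {
  class(x) <- setdiff(class(x), "adr_predictions")
  x
}
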