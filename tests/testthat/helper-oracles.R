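# Independent oracles, deliberately implemented apart from the package paths.

# Brute-force one-sided Fisher tail: enumerate every table sharing the
# margins of (a, b, c, d) and sum the exact probabilities of tables whose
# top-left count is >= a.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0, k - n2)
  hi <- min(k, m)
  x <- lo:hi
  probs <- exp(lchoose(m, x) + lchoose(n2, k - x) - lchoose(m + n2, k))
  sum(probs[x >= a])
}

# Naive one-sided KS statistic D+ = sup_x [F_ref(x) - F_bg(x)], evaluated at
# every pooled data point.
dplus_naive <- function(ref, bg) {
  xs <- sort(unique(c(ref, bg)))
  max(vapply(xs, function(x) mean(ref <= x) - mean(bg <= x), numeric(1)))
}

# Exhaustive permutation p-value for D+ over all label splits.
ks_perm_oracle <- function(ref, bg) {
  pooled <- c(ref, bg)
  m <- length(ref)
  splits <- combn(length(pooled), m)
  d_obs <- dplus_naive(ref, bg)
  d_all <- apply(splits, 2, function(ix)
    dplus_naive(pooled[ix], pooled[-ix]))
  mean(d_all >= d_obs - 1e-12)
}

# tiny hand-buildable study network: drugs x (proteins, modes, side effects)
toy_network <- function(dt_edges, se_edges, modes = NULL) {
  drugs <- sort(unique(c(dt_edges$drug_id, se_edges$drug_id)))
  study_network(
    drugs = tibble::tibble(drug_id = drugs),
    targets = adrtarget:::plain_targets(dt_edges$target_id),
    side_effects = tibble::tibble(se_id = sort(unique(se_edges$se_id))),
    drug_target_edges = dt_edges,
    drug_se_edges = se_edges,
    mode_annotations = modes
  )
}

edge_tbl <- function(...) tibble::tibble(...)
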