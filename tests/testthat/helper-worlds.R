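# Shared synthetic-world runs, computed once per test session. Each run
# executes the preprocessing + enrichment + clustering stages at default
# generator settings for one seed; the knockout benchmark is derived on
# demand (the permutation KS is cheap, the all-pair background clustering is
# not, so tests request only what they score).
.world_runs <- new.env(parent = emptyenv())

default_world_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.world_runs[[key]])) return(.world_runs[[key]])
  w <- simulate_world(generator_params(seed = seed))
  net <- suppressMessages(build_virtual_targets(w$network))
  net <- suppressWarnings(apply_drug_deredundancy(net, w$fingerprints, 0.7))
  net <- merge_equivalent_targets(net)$network
  net <- filter_min_support(net, 5)
  preds <- suppressMessages(run_enrichment(net))
  preds <- flag_metabolizing_exclusions(preds, net,
                                        w$annotations$metabolizing)
  cl <- suppressMessages(
    cluster_predictions(preds, net, w$annotations$known_causal,
                        q_cutoff = 0.01))
  run <- list(world = w, network = net, predictions = cl$predictions,
              clusters = cl$clusters)
  .world_runs[[key]] <- run
  run
}

# enrichment-only run on a background-only (global null) world
null_world_significant_fraction <- function(seed) {
  w <- simulate_world(generator_params(seed = seed, n_causal = 0))
  net <- suppressMessages(build_virtual_targets(w$network))
  net <- suppressWarnings(apply_drug_deredundancy(net, w$fingerprints, 0.7))
  net <- merge_equivalent_targets(net)$network
  net <- filter_min_support(net, 5)
  preds <- suppressMessages(run_enrichment(net))
  nrow(select_significant(preds, 0.01)) / nrow(preds)
}
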