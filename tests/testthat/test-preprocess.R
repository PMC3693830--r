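test_that("virtual target nodes are added per known action mode", {
  dt <- edge_tbl(drug_id = c("d1", "d2", "d3"),
                 target_id = c("P1", "P1", "P1"))
  se <- edge_tbl(drug_id = "d1", se_id = "SE1")
  modes <- edge_tbl(drug_id = c("d1", "d2"), protein_id = c("P1", "P1"),
                    mode = c("inhibition", "activation"))
  net <- build_virtual_targets(toy_network(dt, se), modes)

  # one generic node plus one node per observed mode
  expect_setequal(net$targets$target_id,
                  c("P1", "P1:activation", "P1:inhibition"))
  expect_setequal(
    paste(net$drug_target_edges$drug_id, net$drug_target_edges$target_id),
    c("d1 P1", "d2 P1", "d3 P1", "d1 P1:inhibition", "d2 P1:activation"))
})

test_that("mode annotations without a binding edge are ignored with warning", {
  dt <- edge_tbl(drug_id = "d1", target_id = "P1")
  se <- edge_tbl(drug_id = "d1", se_id = "SE1")
  modes <- edge_tbl(drug_id = "d1", protein_id = "P9", mode = "inhibition")
  expect_warning(net <- build_virtual_targets(toy_network(dt, se), modes),
                 "without a binding edge")
  expect_equal(net$targets$target_id, "P1")
})

test_that("targets with identical active-drug sets merge into one node", {
  dt <- edge_tbl(drug_id = c("d1", "d2", "d3", "d1", "d2", "d3", "d1", "d3"),
                 target_id = c("P1", "P1", "P1", "P2", "P2", "P2", "P3", "P3"))
  se <- edge_tbl(drug_id = "d1", se_id = "SE1")
  net <- toy_network(dt, se)
  res <- merge_equivalent_targets(net)

  expect_setequal(res$network$targets$target_id, c("P1+P2", "P3"))
  merged <- dplyr::filter(res$network$targets, target_id == "P1+P2")
  expect_setequal(merged$members[[1]]$protein_id, c("P1", "P2"))

  # merge map is a partition of the original nodes
  expect_setequal(res$merge_map$target_id, c("P1", "P2", "P3"))
  expect_equal(anyDuplicated(res$merge_map$target_id), 0)

  # P1 {d1,d2} vs P2 {d1,d3} stay unmerged
  dt2 <- edge_tbl(drug_id = c("d1", "d2", "d1", "d3"),
                  target_id = c("P1", "P1", "P2", "P2"))
  res2 <- merge_equivalent_targets(toy_network(dt2, se))
  expect_setequal(res2$network$targets$target_id, c("P1", "P2"))
})

test_that("unmerging reproduces the original active-drug edge multiset", {
  run_seed <- 11
  w <- simulate_world(generator_params(seed = run_seed, n_drugs = 60,
                                       n_proteins = 30, n_families = 6,
                                       n_side_effects = 10, n_causal = 5,
                                       n_near_clones = 0))
  net <- suppressMessages(build_virtual_targets(w$network))
  res <- merge_equivalent_targets(net)
  # expand merged edges back to member target ids
  expanded <- res$network$drug_target_edges |>
    dplyr::inner_join(res$merge_map, by = c(target_id = "merged_id"),
                      relationship = "many-to-many") |>
    dplyr::transmute(drug_id, target_id = target_id.y)
  orig <- net$drug_target_edges
  active <- net$active_drugs
  expect_setequal(
    paste(expanded$drug_id[expanded$drug_id %in% active], expanded$target_id[expanded$drug_id %in% active]),
    paste(orig$drug_id[orig$drug_id %in% active], orig$target_id[orig$drug_id %in% active]))
})

test_that("tanimoto matches |intersection| / |union|", {
  expect_equal(tanimoto(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE)), 1)
  expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  # bits {1,2} vs {1,3}: intersection 1, union 3
  expect_equal(tanimoto(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE)), 1 / 3)
  expect_equal(tanimoto(logical(4), logical(4)), 0)
  expect_error(tanimoto(logical(4), logical(5)), "length mismatch")
})

make_fps <- function(bits) {
  fingerprints <- tibble::tibble(drug_id = names(bits), bits = unname(bits))
  adrtarget:::fingerprint_tbl(fingerprints)
}

test_that("hobohm removes the most connected drug first", {
  # A ~ B, A ~ C, B !~ C: removing hub A clears all edges
  fps <- make_fps(list(
    A = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    B = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),   # sim(A,B) = 4/5
    C = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))) # sim(A,C) = 3/5, sim(B,C)=3/6
  kept <- hobohm_reduce(c("A", "B", "C"), fps, cutoff = 0.55)
  expect_setequal(kept, c("B", "C"))

  # clique of three mutually similar drugs leaves exactly one
  fps2 <- make_fps(list(A = rep(TRUE, 8),
                        B = c(rep(TRUE, 7), FALSE),
                        C = c(FALSE, rep(TRUE, 7))))
  expect_length(hobohm_reduce(c("A", "B", "C"), fps2, cutoff = 0.7), 1)

  # nothing above the cutoff: all kept
  fps3 <- make_fps(list(A = c(TRUE, FALSE, FALSE, FALSE),
                        B = c(FALSE, TRUE, FALSE, FALSE),
                        C = c(FALSE, FALSE, TRUE, FALSE)))
  expect_setequal(hobohm_reduce(c("A", "B", "C"), fps3, 0.7), c("A", "B", "C"))
})

test_that("hobohm is deterministic, tie-broken lexicographically, and keeps fingerprint-less drugs", {
  # two disjoint similar pairs: equal degrees, greatest id of each pair goes
  fps <- make_fps(list(A = c(TRUE, TRUE, TRUE, FALSE),
                       B = c(TRUE, TRUE, TRUE, TRUE),
                       X = c(FALSE, FALSE, TRUE, TRUE),
                       Y = c(FALSE, TRUE, TRUE, TRUE)))
  kept <- hobohm_reduce(c("A", "B", "X", "Y"), fps, cutoff = 0.6)
  expect_setequal(kept, c("A", "X"))

  expect_warning(kept2 <- hobohm_reduce(c("A", "B", "Z"), fps, cutoff = 0.6),
                 "without fingerprints")
  expect_true("Z" %in% kept2)
})

test_that("hobohm post-condition holds on random fingerprint sets", {
  withr::local_seed(99)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    bits <- lapply(seq_len(n), function(i) runif(24) < 0.5)
    names(bits) <- sprintf("d%02d", seq_len(n))
    fps <- make_fps(bits)
    kept <- hobohm_reduce(names(bits), fps, cutoff = 0.6)
    if (length(kept) > 1) {
      pairs <- combn(kept, 2)
      sims <- apply(pairs, 2, function(p)
        tanimoto(bits[[p[1]]], bits[[p[2]]]))
      expect_true(all(sims <= 0.6))
    }
    expect_identical(kept, hobohm_reduce(names(bits), fps, cutoff = 0.6))
  }
})

test_that("min-support filter drops weak targets and side effects, never drugs", {
  dt <- edge_tbl(drug_id = c(sprintf("d%d", 1:5), sprintf("d%d", 1:4)),
                 target_id = c(rep("P1", 5), rep("P2", 4)))
  se <- edge_tbl(drug_id = c(sprintf("d%d", 1:5), "d6"),
                 se_id = c(rep("SE1", 5), "SE2"))
  net <- filter_min_support(toy_network(dt, se), min_drugs = 5)
  expect_equal(net$targets$target_id, "P1")   # P2 has 4 < 5
  expect_equal(net$side_effects$se_id, "SE1") # SE2 has 1
  expect_equal(nrow(net$drugs), 6)            # drugs retained

  # boundary: exactly 5 kept
  expect_true("P1" %in% net$targets$target_id)
})

test_that("metabolizing flag uses any merged member and spares the rest", {
  run <- default_world_run(1)
  preds <- run$predictions
  # empty set flags nothing
  p0 <- flag_metabolizing_exclusions(preds, run$network, character())
  expect_false(any(p0$excluded))

  met <- run$world$annotations$metabolizing
  flagged <- dplyr::filter(preds, excluded)
  if (nrow(flagged) > 0) {
    mp <- adrtarget:::target_member_proteins(run$network)
    members <- dplyr::filter(mp, target_id %in% flagged$target_id)
    expect_true(all(tapply(members$protein_id, members$target_id,
                           function(p) any(p %in% met))))
  }
  # a merged node containing one metabolizing member is flagged
  dt <- edge_tbl(drug_id = c("d1", "d2", "d1", "d2"),
                 target_id = c("CYP", "CYP", "P1", "P1"))
  se <- edge_tbl(drug_id = c("d1", "d2"), se_id = c("SE1", "SE1"))
  mnet <- merge_equivalent_targets(toy_network(dt, se))$network
  fake_preds <- tibble::tibble(target_id = mnet$targets$target_id,
                               se_id = "SE1", excluded = FALSE)
  out <- flag_metabolizing_exclusions(fake_preds, mnet, "CYP")
  expect_true(all(out$excluded)) # CYP and P1 merged into one flagged node
})
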