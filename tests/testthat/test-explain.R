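fam_counts <- function(...) {
  df <- tibble::tribble(...)
  names(df) <- c("protein_id", "family", "count")
  df
}

test_that("classify_family takes the argmax with fixed tie precedence", {
  fc <- fam_counts(
    ~p, ~f, ~n,
    "P1", "GPCR", 5L, "P1", "ion channel", 2L,
    "P2", "GPCR", 3L, "P2", "ion channel", 3L,
    "P3", "kinase", 1L)
  expect_equal(classify_family(c("P1", "P2", "P3", "P4"), fc),
               c("GPCR", "GPCR", "kinase", "other"))
  expect_error(classify_family("P1", fam_counts(~p, ~f, ~n, "P1", "GPCRx", 1L)),
               "unknown family")
})

test_that("resolve_main_targets removes whole-family annotations", {
  fc <- dplyr::bind_rows(
    tibble::tibble(protein_id = sprintf("K%02d", 1:12), family = "kinase",
                   count = 3L),
    tibble::tibble(protein_id = "G1", family = "GPCR", count = 3L))
  ann <- annotation_bundle(
    main_targets = tibble::tibble(drug_id = "d1",
                                  protein_id = c(sprintf("K%02d", 1:12), "G1")),
    family_counts = fc)
  out <- resolve_main_targets(ann)
  expect_equal(out$protein_id, "G1") # 12 kinases >= 10 dropped

  # boundary: exactly 10 family members are removed
  ann10 <- annotation_bundle(
    main_targets = tibble::tibble(drug_id = "d1",
                                  protein_id = sprintf("K%02d", 1:10)),
    family_counts = fc)
  expect_equal(nrow(resolve_main_targets(ann10)), 0)

  # small candidate lists survive untouched
  ann3 <- annotation_bundle(
    main_targets = tibble::tibble(drug_id = "d1",
                                  protein_id = sprintf("K%02d", 1:3)),
    family_counts = fc)
  expect_equal(nrow(resolve_main_targets(ann3)), 3)
})

explain_fixture <- function() {
  # d1 inhibits MAIN (its main target) and binds OFF; d2 binds OFF only
  dt <- edge_tbl(drug_id = c("d1", "d1", "d2"),
                 target_id = c("MAIN", "OFF", "OFF"))
  se <- edge_tbl(drug_id = c("d1", "d2"), se_id = c("SE1", "SE1"))
  modes <- edge_tbl(drug_id = "d1", protein_id = "MAIN", mode = "inhibition")
  net <- build_virtual_targets(toy_network(dt, se), modes)
  list(net = net,
       main = tibble::tibble(drug_id = "d1", protein_id = "MAIN"))
}

test_that("explain_pair categorises main/off-target explanations", {
  fx <- explain_fixture()
  sig_main <- tibble::tibble(target_id = "MAIN:inhibition", se_id = "SE1",
                             q = 1e-4, excluded = FALSE)
  rec <- explain_pair("d1", "SE1", sig_main, fx$net, fx$main)
  expect_equal(rec$category, "main_only")
  expect_equal(rec$explaining[[1]], "MAIN:inhibition")

  sig_both <- dplyr::bind_rows(
    sig_main, tibble::tibble(target_id = "OFF", se_id = "SE1", q = 1e-3,
                             excluded = FALSE))
  expect_equal(explain_pair("d1", "SE1", sig_both, fx$net, fx$main)$category,
               "both")
  # d2 binds OFF only: off_only
  expect_equal(explain_pair("d2", "SE1", sig_both, fx$net, fx$main)$category,
               "off_only")
  # no significant target among the drug's targets
  none <- sig_main[0, ]
  expect_equal(explain_pair("d1", "SE1", none, fx$net, fx$main)$category,
               "unexplained")
  expect_error(explain_pair("dX", "SE1", sig_main, fx$net, fx$main),
               "unknown drug")
  expect_error(explain_pair("d2", "SE9", sig_main, fx$net, fx$main),
               "unknown side effect")
})

test_that("mode-specific significance does not explain a mode-less binder", {
  # d2 binds MAIN without a known mode; only (MAIN, inhibition) is significant
  dt <- edge_tbl(drug_id = c("d1", "d2"), target_id = c("MAIN", "MAIN"))
  se <- edge_tbl(drug_id = c("d1", "d2"), se_id = c("SE1", "SE1"))
  modes <- edge_tbl(drug_id = "d1", protein_id = "MAIN", mode = "inhibition")
  net <- build_virtual_targets(toy_network(dt, se), modes)
  sig <- tibble::tibble(target_id = "MAIN:inhibition", se_id = "SE1",
                        q = 1e-4, excluded = FALSE)
  main <- tibble::tibble(drug_id = character(), protein_id = character())
  expect_equal(explain_pair("d1", "SE1", sig, net, main)$category, "off_only")
  expect_equal(explain_pair("d2", "SE1", sig, net, main)$category,
               "unexplained")
})

test_that("explanation fractions partition and respect family filters", {
  run <- default_world_run(2)
  expl <- summarize_explained_fractions(run$network, run$predictions,
                                        run$world$annotations)
  bc <- expl$by_category
  expect_equal(sum(bc$fraction), 1)
  expect_equal(sum(bc$n), bc$denominator[1])

  # family-filtered explained fractions are bounded by the any-target one
  bf <- expl$by_family
  any_frac <- bf$fraction[bf$family == "any"]
  expect_true(all(bf$fraction <= any_frac + 1e-12))
  # and "any" equals the union over the six families
  hit_any <- purrr::map_lgl(expl$records$families, ~ length(.x) > 0)
  expect_equal(any_frac, mean(hit_any))

  # categories match a manual recomputation on the records
  main <- resolve_main_targets(run$world$annotations)
  rec <- expl$records[expl$records$drug_id %in% main$drug_id, ]
  man <- purrr::map2_chr(rec$proteins, rec$drug_id, function(p, d) {
    if (length(p) == 0) return("unexplained")
    inmain <- p %in% main$protein_id[main$drug_id == d]
    if (all(inmain)) "main_only" else if (any(inmain)) "both" else "off_only"
  })
  tab <- table(factor(man, levels = as.character(bc$category)))
  expect_equal(as.integer(tab), bc$n)
})

test_that("explanation considers all observed pairs of predicted side effects", {
  run <- default_world_run(2)
  expl <- summarize_explained_fractions(run$network, run$predictions,
                                        run$world$annotations)
  sig_se <- unique(select_significant(run$predictions, 0.01)$se_id)
  considered <- run$network$drug_se_edges
  considered <- considered[considered$se_id %in% sig_se, ]
  expect_equal(nrow(expl$records), nrow(considered))
  # de-redundancy removals are still explained (full drug set)
  removed <- setdiff(run$network$drugs$drug_id, run$network$active_drugs)
  if (length(removed) > 0 && any(considered$drug_id %in% removed)) {
    expect_true(any(expl$records$drug_id %in% removed))
  }
})
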