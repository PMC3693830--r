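write_lines <- function(lines, file) writeLines(lines, file)

test_that("read_network_tables applies the confidence cutoff", {
  dt <- withr::local_tempfile(fileext = ".tsv")
  se <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("drug_id\tprotein_id\tconfidence",
                "d1\tP1\t0.9", "d2\tP1\t0.9", "d3\tP2\t0.9"), dt)
  write_lines(c("drug_id\tse_id", "d1\tSE1", "d2\tSE1"), se)
  net <- read_network_tables(dt, se, confidence_cutoff = 0.5)
  expect_equal(nrow(net$drug_target_edges), 3)
  expect_setequal(net$active_drugs, c("d1", "d2", "d3"))

  write_lines(c("drug_id\tprotein_id\tconfidence",
                "d1\tP1\t0.9", "d2\tP1\t0.4"), dt)
  net <- suppressMessages(read_network_tables(dt, se, confidence_cutoff = 0.5))
  expect_equal(net$drug_target_edges$drug_id, "d1")
})

test_that("read_network_tables reports missing columns and deduplicates", {
  dt <- withr::local_tempfile(fileext = ".tsv")
  se <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("chemical\tprotein_id", "d1\tP1"), dt)
  write_lines(c("drug_id\tse_id", "d1\tSE1"), se)
  expect_error(read_network_tables(dt, se), "drug_id")

  write_lines(c("drug_id\tprotein_id", "d1\tP1", "d1\tP1", "d2\tP1"), dt)
  write_lines(c("drug_id\tse_id", "d1\tSE1", "d1\tSE1"), se)
  expect_message(expect_message(net <- read_network_tables(dt, se),
                                "deduplicated"), "deduplicated")
  expect_equal(nrow(net$drug_target_edges), 2)
  expect_equal(nrow(net$drug_se_edges), 1)
})

test_that("mode annotations are normalised and preserved for virtual targets", {
  dt <- withr::local_tempfile(fileext = ".tsv")
  se <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("drug_id\tprotein_id\tconfidence\tmode",
                "d1\tP1\t0.9\tantagonist", "d2\tP1\t0.9\t",
                "d3\tP2\t0.8\tagonist"), dt)
  write_lines(c("drug_id\tse_id", "d1\tSE1", "d2\tSE1", "d3\tSE1",
                "d4\tSE1"), se)
  net <- read_network_tables(dt, se)
  expect_equal(sort(net$mode_annotations$mode), c("activation", "inhibition"))
  expect_true(all(net$targets$mode == "binding"))
})

test_that("fingerprints parse hex and binary with uniform length", {
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("drug_id\tbits", "d1\tff", "d2\t00"), fp)
  fps <- read_fingerprints(fp)
  expect_equal(sum(fps$bits[[1]]), 8)
  expect_equal(sum(fps$bits[[2]]), 0)
  expect_equal(lengths(fps$bits), c(8L, 8L))

  write_lines(c("drug_id\tbits", "d1\t0000", "d2\t0110"), fp)
  fps <- read_fingerprints(fp)
  expect_equal(sum(fps$bits[[1]]), 0)
  expect_equal(lengths(fps$bits), c(4L, 4L)) # binary, not hex

  write_lines(c("drug_id\tbits", "d1\t0000000000000000", "d2\t00000000"), fp)
  expect_error(read_fingerprints(fp), "length mismatch")

  write_lines(c("drug_id\tbits", "d1\t00z0"), fp)
  expect_error(read_fingerprints(fp), "unknown fingerprint character")
})

test_that("annotation reader tolerates missing files and malformed rows", {
  ann <- read_annotations()
  expect_s3_class(ann, "annotation_bundle")
  expect_equal(nrow(ann$main_targets), 0)
  expect_length(ann$metabolizing, 0)

  mt <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("drug_id\tprotein_id", "d1\tP1", "d2\tP2"), mt)
  ko <- withr::local_tempfile(fileext = ".tsv")
  write_lines(c("protein_id\tphenotype", "P1\tMP:1", "P1\tMP:1", "P2\t"), ko)
  expect_warning(
    ann <- read_annotations(main_targets_path = mt, ko_reference_path = ko),
    "malformed")
  expect_equal(nrow(ann$main_targets), 2)
  expect_equal(nrow(ann$ko_reference), 1) # duplicate collapsed, NA skipped
})

test_that("prediction tables round-trip exactly, extras ignored", {
  run <- default_world_run(1)
  preds <- head(run$predictions, 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(preds, path)
  back <- read_predictions(path)
  numify <- function(df) {
    as.data.frame(lapply(df, function(x)
      if (is.numeric(x)) as.numeric(x) else x))
  }
  expect_equal(numify(back), numify(preds[, names(back)]))

  empty <- preds[0, ]
  write_predictions(empty, path)
  expect_equal(nrow(read_predictions(path)), 0)

  lines <- readLines(path)
  writeLines(c(paste0(lines[1], "\tnote"),
               "T1\tP1\tbinding\tSE1\t1\t2\t3\t4\t0.5\t0.6\tFALSE\tNA\thello"),
             path)
  expect_message(back <- read_predictions(path), "extra column")
  expect_false("note" %in% names(back))
})

test_that("network edge tables round-trip through write_network_tables", {
  w <- simulate_world(generator_params(seed = 7, n_drugs = 40, n_proteins = 20,
                                       n_families = 4, n_side_effects = 10,
                                       n_causal = 5, n_near_clones = 2))
  dir <- withr::local_tempdir()
  dt <- file.path(dir, "dt.tsv")
  se <- file.path(dir, "se.tsv")
  write_network_tables(w$network, dt, se)
  back <- read_network_tables(dt, se, confidence_cutoff = 0)
  expect_setequal(
    paste(back$drug_target_edges$drug_id, back$drug_target_edges$target_id),
    paste(w$network$drug_target_edges$drug_id,
          w$network$drug_target_edges$target_id))
  expect_setequal(
    paste(back$drug_se_edges$drug_id, back$drug_se_edges$se_id),
    paste(w$network$drug_se_edges$drug_id, w$network$drug_se_edges$se_id))
  expect_setequal(
    paste(back$mode_annotations$drug_id, back$mode_annotations$protein_id,
          back$mode_annotations$mode),
    paste(w$network$mode_annotations$drug_id,
          w$network$mode_annotations$protein_id,
          w$network$mode_annotations$mode))
})
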