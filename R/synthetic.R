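#' Parameters for the synthetic study generator
#'
#' Defaults describe a desk-scale pharmacology study: 100 proteins in 20
#' families of 5, 300 drugs each centred on one family (binding its members
#' with probability `beta` = 0.8 and everything else with `epsilon` = 0.02),
#' 50 side effects, and 30 planted causal (protein, mode, side effect)
#' relations with penetrance `penetrance` = 0.8 over a background eliciting
#' rate `background_rate` = 0.05 per drug and side effect, combined by
#' noisy-OR. Each protein has a canonical pharmacology direction; an edge's
#' mode is annotated with probability `mode_prob` and then agrees with the
#' canonical direction with probability `canonical_fidelity` (drugs binding a
#' given receptor overwhelmingly share their action mode). Planted relations
#' use the protein's canonical mode, so they exercise the virtual-target
#' machinery. Fingerprints are family prototypes mutated per drug;
#' `n_near_clones` extra drugs duplicate an existing drug's pharmacology with
#' a lightly mutated fingerprint (Tanimoto above the 0.7 redundancy cutoff).
#' The knockout reference contains each planted pair with probability
#' `ko_sensitivity` plus `n_ko_decoys` random decoy pairs.
#'
#' @param n_proteins,n_families,family_sizes protein universe; `family_sizes`
#'   defaults to an even split and must sum to `n_proteins`.
#' @param n_drugs number of primary drugs (clones come on top).
#' @param beta,epsilon in-family / off-family binding probabilities.
#' @param n_side_effects number of side-effect terms.
#' @param n_causal,penetrance planted causal pairs and their penetrance.
#' @param background_rate per-drug background eliciting probability.
#' @param mode_prob,canonical_fidelity action-mode annotation coverage and
#'   agreement with the protein's canonical direction.
#' @param fingerprint_length,fingerprint_mutation,n_near_clones,clone_mutation
#'   fingerprint model.
#' @param ko_sensitivity,n_ko_decoys knockout reference model.
#' @param n_metabolizing proteins flagged as metabolizing enzymes.
#' @param main_targets_per_drug maximum main targets sampled per drug.
#' @param known_causal_fraction fraction of planted pairs entering the
#'   known-causal annotation (cluster seeds).
#' @param seed integer seed; the world is reproducible from (params, seed).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_proteins = 100, n_families = 20,
                             family_sizes = NULL, n_drugs = 300,
                             beta = 0.8, epsilon = 0.02,
                             n_side_effects = 50, n_causal = 30,
                             penetrance = 0.8, background_rate = 0.05,
                             mode_prob = 0.8, canonical_fidelity = 0.95,
                             fingerprint_length = 256,
                             fingerprint_mutation = 0.2,
                             n_near_clones = 10, clone_mutation = 0.02,
                             ko_sensitivity = 0.8, n_ko_decoys = 30,
                             n_metabolizing = 5, main_targets_per_drug = 2,
                             known_causal_fraction = 0.5, seed = 1) {
  if (is.null(family_sizes)) {
    base <- n_proteins %/% n_families
    family_sizes <- rep(base, n_families)
    extra <- n_proteins - sum(family_sizes)
    if (extra > 0) family_sizes[seq_len(extra)] <- family_sizes[seq_len(extra)] + 1
  }
  p <- list(n_proteins = n_proteins, n_families = n_families,
            family_sizes = family_sizes, n_drugs = n_drugs, beta = beta,
            epsilon = epsilon, n_side_effects = n_side_effects,
            n_causal = n_causal, penetrance = penetrance,
            background_rate = background_rate, mode_prob = mode_prob,
            canonical_fidelity = canonical_fidelity,
            fingerprint_length = fingerprint_length,
            fingerprint_mutation = fingerprint_mutation,
            n_near_clones = n_near_clones, clone_mutation = clone_mutation,
            ko_sensitivity = ko_sensitivity, n_ko_decoys = n_ko_decoys,
            n_metabolizing = n_metabolizing,
            main_targets_per_drug = main_targets_per_drug,
            known_causal_fraction = known_causal_fraction,
            seed = as.integer(seed))
  probs <- c(p$beta, p$epsilon, p$penetrance, p$background_rate, p$mode_prob,
             p$canonical_fidelity, p$fingerprint_mutation, p$clone_mutation,
             p$ko_sensitivity, p$known_causal_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  counts <- c(p$n_proteins, p$n_families, p$n_drugs, p$n_side_effects,
              p$fingerprint_length)
  if (any(counts <= 0)) abort("counts must be positive")
  if (sum(p$family_sizes) != p$n_proteins)
    abort("family sizes must sum to n_proteins")
  if (p$n_causal > p$n_proteins)
    abort("more planted causal pairs than proteins")
  structure(p, class = "generator_params")
}

#' Simulate a synthetic study world
#'
#' Generates a [study_network()], fingerprints, an [annotation_bundle()] and
#' the planted ground truth under the model described in
#' [generator_params()]. Fully deterministic given the params (which include
#' the seed).
#'
#' @param params a [generator_params()] list.
#' @return A list of class `synthetic_world`: `network`, `fingerprints`,
#'   `annotations`, `truth` (tibble `protein_id`, `mode`, `se_id`,
#'   `penetrance`), `params`.
#' @export
simulate_world <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(params$seed)

  proteins <- sprintf("P%03d", seq_len(params$n_proteins))
  family <- rep(seq_len(params$n_families), times = params$family_sizes)
  canonical <- sample(c("activation", "inhibition"), params$n_proteins,
                      replace = TRUE)
  # each protein family gets one dominant target class
  fam_class <- sample(FAMILY_LEVELS, params$n_families, replace = TRUE,
                      prob = c(0.30, 0.10, 0.15, 0.15, 0.20, 0.10))
  protein_class <- fam_class[family]

  drugs <- sprintf("D%03d", seq_len(params$n_drugs))
  primary <- sample(seq_len(params$n_families), params$n_drugs, replace = TRUE)

  # binding matrix drugs x proteins
  prob <- matrix(params$epsilon, params$n_drugs, params$n_proteins)
  in_fam <- outer(primary, family, "==")
  prob[in_fam] <- params$beta
  binds <- matrix(runif(length(prob)) < prob, nrow = params$n_drugs)

  # mode annotations per bound edge
  idx <- which(binds, arr.ind = TRUE)
  has_mode <- runif(nrow(idx)) < params$mode_prob
  agrees <- runif(nrow(idx)) < params$canonical_fidelity
  edge_mode <- ifelse(agrees, canonical[idx[, 2]],
                      ifelse(canonical[idx[, 2]] == "activation",
                             "inhibition", "activation"))
  mode_tbl <- tibble(drug_id = drugs[idx[, 1]],
                     protein_id = proteins[idx[, 2]],
                     mode = edge_mode)[has_mode, ]

  # planted causal relations: protein's canonical mode
  se_ids <- sprintf("SE%03d", seq_len(params$n_side_effects))
  truth <- if (params$n_causal > 0) {
    causal_p <- sample(seq_len(params$n_proteins), params$n_causal)
    tibble(protein_id = proteins[causal_p], mode = canonical[causal_p],
           se_id = sample(se_ids, params$n_causal, replace = TRUE),
           penetrance = params$penetrance)
  } else {
    tibble(protein_id = character(), mode = character(), se_id = character(),
           penetrance = numeric())
  }

  # fingerprints: family prototype + per-drug mutation
  L <- params$fingerprint_length
  protos <- matrix(runif(params$n_families * L) < 0.5, params$n_families, L)
  fp <- protos[primary, , drop = FALSE]
  flips <- matrix(runif(params$n_drugs * L) < params$fingerprint_mutation,
                  params$n_drugs, L)
  fp <- xor(fp, flips)

  # near-clone drugs: duplicate pharmacology, lightly mutated fingerprint
  clone_of <- character()
  if (params$n_near_clones > 0) {
    n_cl <- min(params$n_near_clones, params$n_drugs)
    originals <- sample(seq_len(params$n_drugs), n_cl)
    clone_ids <- sprintf("D%03dc", originals)
    clone_of <- setNames(drugs[originals], clone_ids)
    binds <- rbind(binds, binds[originals, , drop = FALSE])
    clone_fp <- xor(fp[originals, , drop = FALSE],
                    matrix(runif(n_cl * L) < params$clone_mutation, n_cl, L))
    fp <- rbind(fp, clone_fp)
    primary <- c(primary, primary[originals])
    clone_modes <- mode_tbl |>
      filter(.data$drug_id %in% drugs[originals]) |>
      mutate(drug_id = names(clone_of)[match(.data$drug_id, clone_of)])
    mode_tbl <- bind_rows(mode_tbl, clone_modes)
    drugs <- c(drugs, clone_ids)
  }
  n_all <- length(drugs)

  # side effects by noisy-OR of background and matched planted relations
  mode_key <- paste(mode_tbl$drug_id, mode_tbl$protein_id, mode_tbl$mode)
  p_elicit <- matrix(params$background_rate, n_all, params$n_side_effects,
                     dimnames = list(drugs, se_ids))
  if (nrow(truth) > 0) {
    for (r in seq_len(nrow(truth))) {
      hit <- paste(drugs, truth$protein_id[r], truth$mode[r]) %in% mode_key
      j <- match(truth$se_id[r], se_ids)
      p_elicit[hit, j] <- 1 - (1 - p_elicit[hit, j]) * (1 - truth$penetrance[r])
    }
  }
  elicits <- matrix(runif(length(p_elicit)) < p_elicit, nrow = n_all)
  se_idx <- which(elicits, arr.ind = TRUE)
  se_edges <- tibble(drug_id = drugs[se_idx[, 1]], se_id = se_ids[se_idx[, 2]])

  dt_idx <- which(binds, arr.ind = TRUE)
  dt_edges <- tibble(drug_id = drugs[dt_idx[, 1]],
                     target_id = proteins[dt_idx[, 2]])

  network <- study_network(
    drugs = tibble(drug_id = drugs),
    targets = plain_targets(proteins),
    side_effects = tibble(se_id = se_ids),
    drug_target_edges = dt_edges,
    drug_se_edges = se_edges,
    mode_annotations = mode_tbl
  )

  fingerprints <- fingerprint_tbl(tibble(
    drug_id = drugs,
    bits = lapply(seq_len(n_all), function(i) fp[i, ])))

  # annotations
  main_targets <- purrr::map_dfr(seq_len(n_all), function(i) {
    cand <- which(binds[i, ] & family == primary[i])
    if (length(cand) == 0) return(NULL)
    take <- head(sample(cand, length(cand)), params$main_targets_per_drug)
    tibble(drug_id = drugs[i], protein_id = proteins[take])
  })
  family_counts <- tibble(protein_id = proteins, family = protein_class,
                          count = sample(3:6, params$n_proteins,
                                         replace = TRUE))
  noisy <- runif(params$n_proteins) < 0.2
  if (any(noisy)) {
    family_counts <- bind_rows(
      family_counts,
      tibble(protein_id = proteins[noisy],
             family = sample(FAMILY_LEVELS, sum(noisy), replace = TRUE),
             count = sample(1:2, sum(noisy), replace = TRUE)))
  }
  non_causal <- setdiff(proteins, truth$protein_id)
  metabolizing <- sample(non_causal, min(params$n_metabolizing,
                                         length(non_causal)))
  known_causal <- truth[runif(nrow(truth)) < params$known_causal_fraction,
                        c("protein_id", "se_id")]
  ko_true <- truth[runif(nrow(truth)) < params$ko_sensitivity,
                   c("protein_id", "se_id")]
  decoys <- tibble(protein_id = sample(proteins, params$n_ko_decoys,
                                       replace = TRUE),
                   se_id = sample(se_ids, params$n_ko_decoys,
                                  replace = TRUE)) |>
    anti_join(truth, by = c("protein_id", "se_id"))
  ko_pairs <- distinct(bind_rows(ko_true, decoys))
  ko_reference <- tibble(protein_id = ko_pairs$protein_id,
                         phenotype = paste0("MP:", ko_pairs$se_id))
  phenotype_synonyms <- tibble(phenotype = paste0("MP:", se_ids),
                               se_id = se_ids)

  annotations <- annotation_bundle(
    main_targets = main_targets, family_counts = family_counts,
    metabolizing = metabolizing, known_causal = known_causal,
    ko_reference = ko_reference, phenotype_synonyms = phenotype_synonyms)

  structure(list(network = network, fingerprints = fingerprints,
                 annotations = annotations,
                 truth = select(truth, "protein_id", "mode", "se_id",
                                "penetrance"),
                 clone_of = clone_of, params = params),
            class = "synthetic_world")
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world>  seed:", x$params$seed, "\n")
  print(x$network)
  cat(sprintf("  planted causal relations: %d\n", nrow(x$truth)))
  invisible(x)
}

#' The worked bradycardia-like example network
#'
#' A fixed 550-drug network holding the textbook configuration: one
#' beta-blocker-like target inhibited by 12 drugs, 11 of which are annotated
#' with the bradycardia-like side effect that 184 drugs elicit overall. Its
#' contingency table is (a, b, c, d) = (11, 1, 173, 365) and the one-sided
#' Fisher p-value is 4e-05 to one significant figure. Inert padding targets
#' and side effects keep every pipeline filter non-trivial.
#'
#' @return A [study_network()].
#' @export
worked_example_fixture <- function() {
  drugs <- sprintf("D%03d", 1:550)
  binders <- drugs[1:12]
  elicitors <- c(drugs[1:11], drugs[13:185]) # 11 binders + 173 others = 184

  dt <- bind_rows(
    tibble(drug_id = binders, target_id = "ADRB1"),
    tibble(drug_id = drugs[201:230], target_id = "PAD1"),
    tibble(drug_id = drugs[221:245], target_id = "PAD2"))
  se <- bind_rows(
    tibble(drug_id = elicitors, se_id = "bradycardia"),
    tibble(drug_id = drugs[301:340], se_id = "padding_se"))
  # every drug appears in at least one edge, so the drug universe survives a
  # round trip through the flat-file tables
  uncovered <- setdiff(drugs, c(dt$drug_id, se$drug_id))
  dt <- bind_rows(dt, tibble(drug_id = uncovered, target_id = "PAD3"))
  modes <- tibble(drug_id = binders, protein_id = "ADRB1",
                  mode = "inhibition")

  study_network(
    drugs = tibble(drug_id = drugs),
    targets = plain_targets(c("ADRB1", "PAD1", "PAD2", "PAD3")),
    side_effects = tibble(se_id = c("bradycardia", "padding_se")),
    drug_target_edges = dt,
    drug_se_edges = se,
    mode_annotations = modes
  )
}

#' Score recovery of planted causal relations
#'
#' A planted relation counts as recovered when some significant cluster for
#' its side effect contains its protein (cluster-level credit). The empirical
#' false discovery rate is the fraction of significant clusters containing no
#' planted protein for their side effect.
#'
#' @param predictions prediction tibble (unused beyond sanity checks; the
#'   clusters carry the decision).
#' @param clusters cluster tibble built at `q_cutoff`.
#' @param truth tibble `protein_id`, `se_id` of planted relations.
#' @param q_cutoff cutoff the clusters were built at (recorded).
#' @return A one-row tibble: `recall`, `precision`, `empirical_fdr`,
#'   `n_recovered`, `n_truth`, `n_clusters`. With no truth, recall is `NA`;
#'   with no clusters, the FDR is `NA` (0/0) and recall 0.
#' @export
recovery_report <- function(predictions, clusters, truth, q_cutoff = 0.01) {
  truth <- distinct(as_tibble(truth), .data$protein_id, .data$se_id)
  if (nrow(truth) == 0) {
    return(tibble(recall = NA_real_, precision = NA_real_,
                  empirical_fdr = if (nrow(clusters) > 0) 1 else NA_real_,
                  n_recovered = 0L, n_truth = 0L,
                  n_clusters = nrow(clusters), q_cutoff = q_cutoff))
  }
  cluster_hit <- function(se, prot) {
    rows <- clusters$se_id == se
    any(purrr::map_lgl(clusters$proteins[rows], ~ prot %in% .x))
  }
  recovered <- purrr::map2_lgl(truth$se_id, truth$protein_id, cluster_hit)
  matched_cluster <- purrr::map2_lgl(clusters$proteins, clusters$se_id,
                                     function(prots, se)
                                       any(truth$se_id == se &
                                             truth$protein_id %in% prots))
  n_cl <- nrow(clusters)
  tibble(
    recall = mean(recovered),
    precision = if (n_cl > 0) mean(matched_cluster) else NA_real_,
    empirical_fdr = if (n_cl > 0) mean(!matched_cluster) else NA_real_,
    n_recovered = sum(recovered), n_truth = nrow(truth),
    n_clusters = n_cl, q_cutoff = q_cutoff)
}

#' Write a synthetic world as flat input tables
#'
#' Emits the full TSV input set consumed by [run_pipeline()]: drug-target
#' (with confidence and mode columns), drug-side-effect, fingerprints and all
#' annotation tables, plus the ground truth for scoring.
#'
#' @param world a [simulate_world()] result.
#' @param dir output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(dir, f)
  net <- world$network
  dt <- net$drug_target_edges |>
    rename(protein_id = "target_id") |>
    left_join(net$mode_annotations, by = c("drug_id", "protein_id")) |>
    mutate(confidence = round(0.5 + 0.5 * runif(n()), 3))
  readr::write_tsv(dt, pth("drug_target.tsv"))
  readr::write_tsv(net$drug_se_edges, pth("drug_se.tsv"))
  write_fingerprints(world$fingerprints, pth("fingerprints.tsv"))
  ann <- world$annotations
  readr::write_tsv(ann$main_targets, pth("main_targets.tsv"))
  readr::write_tsv(ann$family_counts, pth("family_counts.tsv"))
  readr::write_tsv(tibble(protein_id = ann$metabolizing),
                   pth("metabolizing.tsv"))
  readr::write_tsv(ann$known_causal, pth("known_causal.tsv"))
  readr::write_tsv(ann$ko_reference, pth("ko_reference.tsv"))
  readr::write_tsv(ann$phenotype_synonyms, pth("phenotype_synonyms.tsv"))
  readr::write_tsv(world$truth, pth("truth.tsv"))
  invisible(setNames(
    as.list(file.path(dir, c("drug_target.tsv", "drug_se.tsv",
                             "fingerprints.tsv", "main_targets.tsv",
                             "family_counts.tsv", "metabolizing.tsv",
                             "known_causal.tsv", "ko_reference.tsv",
                             "phenotype_synonyms.tsv", "truth.tsv"))),
    c("drug_target", "drug_se", "fingerprints", "main_targets",
      "family_counts", "metabolizing", "known_causal", "ko_reference",
      "phenotype_synonyms", "truth")))
}
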