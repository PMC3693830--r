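Package: adrtarget
Title: Attribution of Drug Side Effects to Protein Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein targets that cause drug side effects by
    overrepresentation testing of protein-side-effect pairs across a
    drug-target and drug-side-effect network. Resolves agonist/antagonist
    action modes as virtual target nodes, merges indistinguishable targets,
    removes chemically redundant drugs (Tanimoto/Hobohm), tests each
    protein-side-effect pair with a one-sided Fisher exact test under
    Storey q-value FDR control, groups predictions into co-binding clusters,
    benchmarks them against mouse-knockout phenotype references, and
    attributes observed drug-side-effect pairs to main targets, off-targets
    and protein families. Ships a synthetic-network generator with planted
    causal pairs for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
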