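Package: dagsynth
Title: Building Causal Directed Acyclic Graphs from Reviewed Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A systematic, auditable workflow for constructing causal
    directed acyclic graphs (DAGs) from a body of reviewed studies. Each
    study's conclusions are mapped into a saturated implied graph; every
    candidate edge is resolved in both directions through sequential
    causal criteria (temporality, face validity, recourse to theory, a
    counterfactual thought experiment) with a complete decision log;
    retained edges are indexed with provenance and synthesised into an
    integrated DAG, with detection of newly possible edges and
    recombination of equivalent nodes. The resulting graphs are analysed
    with d-separation, backdoor path enumeration, minimal sufficient
    adjustment sets, and covariate role classification to direct
    adjustment strategy. Graphs interoperate with the DAGitty model text
    format and Graphviz DOT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
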