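two_node_dag <- function(tail = "x", head = "y") {
  g <- mixed_graph(c(tail, head))
  g <- add_edge(g, tail, head, status = "retained")
  set_graph_stage(g, "translated")
}

test_that("indexing a translated DAG records provenance and is idempotent", {
  ex <- alcohol_example()
  dag <- translate_graph(map_study(ex$studies$hypothetical),
                         ex$assessments$hypothetical)$graph
  idx <- index_edges(dag, "hypothetical")
  expect_equal(nrow(idx$records), 5)
  expect_true(all(purrr::map_lgl(idx$records$provenance,
                                 function(p) "hypothetical" %in% prov_studies(p))))
  merged <- merge_indices(idx, index_edges(dag, "hypothetical"))
  expect_equal(tidy(merged), tidy(idx))
  expect_error(index_edges(map_study(ex$studies$hypothetical), "x"),
               "translated")
})

test_that("conflicting directions across studies are flagged, not merged", {
  ia <- index_edges(two_node_dag("x", "y"), "study_a")
  ib <- index_edges(two_node_dag("y", "x"), "study_b")
  m <- merge_indices(ia, ib)
  expect_equal(nrow(m$records), 1)
  expect_true(m$records$conflict)
  expect_error(synthesise(m, focal = c("x", "y")), "conflict")
  r <- resolve_index_conflict(m, "x", "y", direction = c("x", "y"),
                              rationale = "later measurement wave settles order")
  expect_false(r$records$conflict)
  expect_silent(synthesise(r, focal = c("x", "y")))
})

test_that("index merge is commutative, associative and idempotent on provenance", {
  set.seed(1)
  ixs <- lapply(1:3, function(i) {
    index_edges(random_dag(5, 0.5, seed = i), sprintf("s%d", i))
  })
  ab <- merge_indices(ixs[[1]], ixs[[2]])
  ba <- merge_indices(ixs[[2]], ixs[[1]])
  expect_equal(dplyr::arrange(tidy(ab), tail, head),
               dplyr::arrange(tidy(ba), tail, head))
  abc1 <- merge_indices(merge_indices(ixs[[1]], ixs[[2]]), ixs[[3]])
  abc2 <- merge_indices(ixs[[1]], merge_indices(ixs[[2]], ixs[[3]]))
  expect_equal(dplyr::arrange(tidy(abc1), tail, head),
               dplyr::arrange(tidy(abc2), tail, head))
  expect_equal(tidy(merge_indices(ab, ab)), tidy(ab))
})

test_that("synthesis unions indexed edges and accounts for every pair", {
  # base case: one record, no pending pairs
  idx <- index_edges(two_node_dag(), "s")
  syn <- synthesise(idx)
  expect_equal(nrow(syn$idag$edges), 1)
  expect_equal(nrow(syn$pending), 0)

  ex <- alcohol_example()
  dags <- purrr::map2(purrr::map(ex$studies, map_study),
                      ex$assessments[c("hypothetical", "seljamo")],
                      function(ig, a) translate_graph(ig, a)$graph)
  idx <- merge_indices(index_edges(dags$hypothetical, "hypothetical"),
                       index_edges(dags$seljamo, "seljamo"))
  syn <- synthesise(idx, focal = c("parental_alc_hist", "adol_alc"))
  pend <- pair_key(syn$pending$a, syn$pending$b)
  expect_true(pair_key("family_structure", "adol_sex") %in% pend)
  expect_true(pair_key("alc_initiation", "adol_substance") %in% pend)

  # saturation accounting: pending + indexed + deleted = all pairs
  n <- nrow(syn$idag$nodes)
  expect_equal(nrow(syn$pending) + nrow(syn$idag$edges) +
                 nrow(syn$idag$deletions), choose(n, 2))

  res <- resolve_pending(syn$idag, idx, ex$idag_assessments)
  e <- res$idag$edges
  expect_true(any(e$tail == "alc_initiation" & e$head == "adol_substance"))
  expect_false(pair_key("family_structure", "adol_sex") %in%
                 pair_key(e$tail, e$head))
  n2 <- nrow(res$idag$nodes)
  expect_equal(nrow(pending_pairs(res$idag)), 0)
  expect_equal(nrow(res$idag$edges) + nrow(res$idag$deletions), choose(n2, 2))
  # the final index now carries the I-DAG deletions
  expect_true(pair_key("family_structure", "adol_sex") %in%
                pair_key(res$index$deletions$a, res$index$deletions$b))
})

test_that("synthesis is invariant to insertion order", {
  for (seed in 1:25) {
    idx <- random_edge_index(n_nodes = 6, n_edges = 9, seed = seed)
    base <- synthesise(idx)$idag
    for (perm in 1:5) {
      shuffled <- idx
      ord <- withr::with_seed(seed * 100L + perm,
                              sample(nrow(shuffled$records)))
      shuffled$records <- shuffled$records[ord, ]
      expect_equal(graph_signature(synthesise(shuffled)$idag),
                   graph_signature(base))
    }
  }
})

test_that("reviewer-added nodes create pending pairs and warn when isolated", {
  idx <- random_edge_index(n_nodes = 5, n_edges = 8, seed = 3)
  syn <- synthesise(idx)
  idag <- add_pending_candidates(syn$idag)
  # resolve existing pending pairs by deleting them so the graph is clean
  del_all <- function(pairs, study = "idag") {
    dplyr::bind_rows(purrr::map2(pairs$a, pairs$b, function(a, b) {
      bind_directions(
        direction_assessments(study, a, b, c("yes", "no")),
        direction_assessments(study, b, a, c("yes", "no")))
    }))
  }
  if (nrow(syn$pending) > 0) {
    idag <- translate_graph(idag, del_all(syn$pending))$graph
  }
  n_before <- nrow(idag$nodes)
  rv <- add_reviewer_node(idag, "zz")
  expect_equal(nrow(rv$pending), n_before)
  expect_equal(roles_of(rv$idag, "zz"), "reviewer_added")
  expect_error(add_reviewer_node(rv$idag, "zz"), "already present")

  # deleting every pair leaves the reviewer node isolated, which violates
  # the inclusion rule and warns
  g <- add_pending_candidates(rv$idag, rv$pending)
  expect_warning(tr <- translate_graph(g, del_all(rv$pending)), "isolated")
  expect_equal(graph_signature(tr$graph)$edges,
               graph_signature(idag)$edges)
})

test_that("recombination candidates require identical io and non-adjacency", {
  # two controls sending to exactly {exposure, outcome}
  g <- mixed_graph(c("x", "y", "c1", "c2"))
  for (cv in c("c1", "c2")) {
    g <- add_edge(g, cv, "x", status = "retained")
    g <- add_edge(g, cv, "y", status = "retained")
  }
  g <- add_edge(g, "x", "y", status = "retained")
  g <- set_graph_stage(g, "integrated")
  cands <- recombination_candidates(g)
  expect_equal(nrow(cands), 1)
  expect_equal(c(cands$a, cands$b), c("c1", "c2"))
  expect_equal(cands$evidence, "identical_io")

  # connected nodes are never candidates even with a theory flag
  cands2 <- recombination_candidates(g, theory_pairs = tibble::tibble(
    a = "x", b = "y"))
  expect_false(pair_key("x", "y") %in% pair_key(cands2$a, cands2$b))
  expect_equal(nrow(recombination_candidates(mixed_graph())), 0)
})

test_that("recombining identical-io nodes preserves reachability", {
  g <- mixed_graph(c("x", "y", "c1", "c2", "u"))
  g <- add_edge(g, "u", "c1", status = "retained")
  g <- add_edge(g, "u", "c2", status = "retained")
  for (cv in c("c1", "c2")) {
    g <- add_edge(g, cv, "x", status = "retained")
    g <- add_edge(g, cv, "y", status = "retained")
  }
  g <- add_edge(g, "x", "y", status = "retained")
  g <- set_graph_stage(g, "integrated")
  rc <- recombine(g, c("c1", "c2"), "cmb",
                  justification = "both are categories of one construct")
  merged <- rc$graph
  expect_equal(nrow(merged$nodes), 4)
  expect_true(is_acyclic(merged))
  expect_true(all(c("c1", "c2") %in% merged$nodes$aliases[[
    match("cmb", merged$nodes$id)]]))
  # reachability among untouched nodes is unchanged
  reach <- function(gr, from, to) to %in% descendants(gr, from)
  for (from in c("u", "x")) {
    for (to in c("x", "y")) {
      if (from == to) next
      expect_equal(reach(merged, from, to), reach(g, from, to))
    }
  }
  expect_equal(rc$log$stage, "recombination")
})

test_that("recombination refuses adjacent pairs and cycle-making merges", {
  g <- mixed_graph(c("a", "b", "c"))
  g <- add_edge(g, "a", "b", status = "retained")
  g <- set_graph_stage(g, "translated")
  expect_error(recombine(g, c("a", "b"), "m", justification = "no"),
               "connected by an edge")

  # a -> x -> b: merging a and b would create a 2-cycle through x
  h <- mixed_graph(c("a", "x", "b"))
  h <- add_edge(h, "a", "x", status = "retained")
  h <- add_edge(h, "x", "b", status = "retained")
  h <- set_graph_stage(h, "translated")
  expect_error(recombine(h, c("a", "b"), "m", force = TRUE,
                         justification = "force"), "cycle")
})

test_that("merged edges inherit worst-case confidence", {
  g <- mixed_graph(c("x", "c1", "c2"))
  g <- add_edge(g, "c1", "x", status = "retained", confidence = "low")
  g <- add_edge(g, "c2", "x", status = "retained", confidence = "normal")
  g <- set_graph_stage(g, "translated")
  rc <- recombine(g, c("c1", "c2"), "cmb", justification = "same construct")
  expect_equal(rc$graph$edges$confidence, "low")
})
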