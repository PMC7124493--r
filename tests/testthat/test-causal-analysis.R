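chain3 <- function() analysis_graph_from_edges(
  c("a", "b", "c"), data.frame(tail = c("a", "b"), head = c("b", "c")))

collider3 <- function() analysis_graph_from_edges(
  c("a", "b", "c"), data.frame(tail = c("a", "c"), head = c("b", "b")))

triangle <- function() analysis_graph_from_edges(
  c("x", "y", "z"),
  data.frame(tail = c("z", "z", "x"), head = c("x", "y", "y")))

test_that("d-separation handles chains, forks and colliders", {
  expect_true(d_separated(chain3(), "a", "c", "b"))
  expect_false(d_separated(chain3(), "a", "c"))
  expect_true(d_separated(collider3(), "a", "c"))
  expect_false(d_separated(collider3(), "a", "c", "b"))
  # conditioning on a collider's descendant also opens it
  g <- analysis_graph_from_edges(c("a", "b", "c", "d"),
    data.frame(tail = c("a", "c", "b"), head = c("b", "b", "d")))
  expect_false(d_separated(g, "a", "c", "d"))
  expect_error(d_separated(chain3(), "a", "c", "a"), "must not be in Z")
})

test_that("d-separation agrees with the path-enumeration oracle on random DAGs", {
  for (seed in 1:60) {
    n <- 3 + (seed %% 5)  # 3..7 nodes
    g <- analysis_graph(random_dag(n, p_edge = 0.5, seed = seed))
    edges <- as.data.frame(g$edges)
    ids <- g$nodes$id
    xy <- withr::with_seed(seed, sample(ids, 2))
    rest <- setdiff(ids, xy)
    subsets <- c(list(character()), unlist(lapply(seq_along(rest), function(k) {
      cmb <- utils::combn(rest, k)
      lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
    }), recursive = FALSE))
    for (Z in subsets) {
      expect_equal(d_separated(g, xy[1], xy[2], Z),
                   oracle_d_sep(edges, ids, xy[1], xy[2], Z),
                   info = sprintf("seed %d Z={%s}", seed,
                                  paste(Z, collapse = ",")))
    }
  }
})

test_that("backdoor paths start with an edge into the exposure", {
  bp <- backdoor_paths(triangle(), "x", "y")
  expect_equal(nrow(bp), 1)
  expect_equal(bp$path, "x <- z -> y")
  expect_true(bp$open)
  # no edges into x: no backdoor paths
  g <- analysis_graph_from_edges(c("x", "y"),
                                 data.frame(tail = "x", head = "y"))
  expect_equal(nrow(backdoor_paths(g, "x", "y")), 0)
})

test_that("minimal adjustment sets match subset enumeration on random DAGs", {
  for (seed in 1:40) {
    n <- 4 + (seed %% 4)  # 4..7 nodes
    g <- analysis_graph(random_dag(n, p_edge = 0.5, seed = 1000 + seed))
    ids <- g$nodes$id
    xy <- withr::with_seed(seed, sample(ids, 2))
    got <- minimal_adjustment_sets(g, xy[1], xy[2])
    want <- oracle_min_adjust(as.data.frame(g$edges), ids,
                              rep(TRUE, length(ids)), xy[1], xy[2])
    expect_same_sets(got$set, want)
  }
})

test_that("every returned set satisfies the backdoor criterion minimally", {
  for (seed in c(7, 21, 33)) {
    g <- analysis_graph(random_dag(6, p_edge = 0.6, seed = seed))
    ids <- g$nodes$id
    xy <- withr::with_seed(seed, sample(ids, 2))
    x <- xy[1]; y <- xy[2]
    gx <- g
    gx$edges <- gx$edges[gx$edges$tail != x, , drop = FALSE]
    mas <- minimal_adjustment_sets(g, x, y)
    for (Z in mas$set) {
      expect_true(length(intersect(Z, descendants(g, x))) == 0)
      expect_true(d_separated(gx, x, y, Z))
      for (v in Z) {
        expect_false(d_separated(gx, x, y, setdiff(Z, v)))
      }
    }
  }
})

test_that("bidirectional edges analyse as latent common causes, never adjustable", {
  g <- mixed_graph(c("x", "y"))
  g <- add_edge(g, "x", "y", orientation = "bidirectional",
                status = "retained")
  g <- set_graph_stage(g, "translated")
  ag <- analysis_graph(g)
  expect_equal(nrow(ag$nodes), 3)
  lat <- ag$nodes$id[ag$nodes$latent]
  expect_length(lat, 1)
  expect_false(ag$nodes$measured[ag$nodes$latent])
  # the latent node confounds x and y but can never be in a returned set
  mas <- minimal_adjustment_sets(ag, "x", "y")
  expect_equal(nrow(mas), 0)  # unblockable confounding by latent cause
})

test_that("covariate roles are classified as the worked example states", {
  res <- alcohol_pipeline()
  dag <- res$dags$hypothetical
  expect_equal(
    classify_covariate(dag, "parental_alc_hist", "adol_alc",
                       "adol_substance")$role[1], "mediator")
  expect_equal(
    classify_covariate(dag, "parental_alc_hist", "adol_alc",
                       "adol_sex")$role, "risk_factor_only")
  expect_equal(classify_covariate(triangle(), "x", "y", "z")$role,
               "confounder")
  # instrument and disconnected fallbacks
  g <- analysis_graph_from_edges(c("i", "x", "y", "q"),
    data.frame(tail = c("i", "x"), head = c("x", "y")))
  expect_equal(classify_covariate(g, "x", "y", "i")$role, "instrument_like")
  expect_equal(classify_covariate(g, "x", "y", "q")$role, "disconnected")
})

test_that("mediator classification implies descendant-of-x and ancestor-of-y", {
  for (seed in 1:20) {
    g <- analysis_graph(random_dag(6, p_edge = 0.5, seed = 500 + seed))
    ids <- g$nodes$id
    xy <- withr::with_seed(seed, sample(ids, 2))
    for (v in setdiff(ids, xy)) {
      cl <- classify_covariate(g, xy[1], xy[2], v)
      if ("mediator" %in% cl$role) {
        expect_true(v %in% descendants(g, xy[1]))
        expect_true(v %in% ancestors(g, xy[2]))
      }
    }
  }
})

test_that("adjustment consequences report over-control and collider bias", {
  res <- alcohol_pipeline()
  rep <- adjustment_consequences(res$dags$hypothetical, "parental_alc_hist",
                                 "adol_alc", "adol_substance")
  expect_equal(rep$blocked_causal$path,
               "parental_alc_hist -> adol_substance -> adol_alc")
  expect_equal(nrow(rep$opened), 1)
  expect_match(rep$opened$path,
               "parental_alc_hist -> adol_substance <- adol_sex",
               fixed = TRUE)
  expect_equal(rep$opened$colliders, "adol_substance")

  # empty set: empty report
  rep0 <- adjustment_consequences(res$dags$hypothetical, "parental_alc_hist",
                                  "adol_alc", character())
  expect_equal(nrow(rep0$blocked_causal) + nrow(rep0$opened), 0)

  # chain: adjusting the mediator blocks the only causal path, opens none
  repc <- adjustment_consequences(chain3(), "a", "c", "b")
  expect_equal(repc$blocked_causal$path, "a -> b -> c")
  expect_equal(nrow(repc$opened), 0)
})

test_that("oversized enumeration is refused with a clear message", {
  ids <- sprintf("v%02d", 1:23)
  g <- analysis_graph_from_edges(ids, data.frame(tail = "v01", head = "v23"))
  expect_error(minimal_adjustment_sets(g, "v01", "v23"),
               "exceed the exhaustive-enumeration cap")
})
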