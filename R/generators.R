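#' Generate a random DAG
#'
#' Nodes `n1..nk`; a random topological order is drawn and each unordered
#' pair is included, oriented along that order, with probability
#' `p_edge`. Edges are directed and retained, so the result is a valid
#' translated-stage graph. Deterministic for a given seed.
#'
#' @param n_nodes number of nodes (2 to 12).
#' @param p_edge inclusion probability per pair.
#' @param seed integer seed.
#' @param stage stage flag of the result (default `"translated"`).
#' @return a `mixed_graph`.
#' @export
random_dag <- function(n_nodes, p_edge = 0.4, seed = 1, stage = "translated") {
  if (n_nodes < 2 || n_nodes > 12) abort("n_nodes must be between 2 and 12")
  ids <- sprintf("n%d", seq_len(n_nodes))
  g <- withr::with_seed(seed, {
    order <- sample(ids)
    g <- mixed_graph(ids, stage = "implied")
    pairs <- utils::combn(n_nodes, 2)
    for (j in seq_len(ncol(pairs))) {
      if (stats::runif(1) <= p_edge) {
        g <- add_edge(g, order[pairs[1, j]], order[pairs[2, j]],
                      orientation = "directed", status = "retained",
                      provenance = make_prov("random", "generator"))
      }
    }
    g
  })
  set_stage(g, stage)
}

#' Generate a random saturated implied graph
#'
#' A random study-like IG: a random DAG's edges become directed
#' candidates, then the graph is saturated.
#'
#' @inheritParams random_dag
#' @return a `mixed_graph` at stage `"implied"`.
#' @export
random_ig <- function(n_nodes, p_edge = 0.4, seed = 1) {
  g <- random_dag(n_nodes, p_edge, seed, stage = "implied")
  g$edges$status <- rep("candidate", nrow(g$edges))
  saturate(g)
}

#' Generate a complete random assessment set for an implied graph
#'
#' Draws verdicts for both directions of every candidate edge, honouring
#' the sequential-stop structure (no verdicts are generated after an
#' early failure). Each draw posits a hidden temporal order of the
#' variables: directions running against that order fail the temporality
#' criterion, except with probability `p_theory_unknown` the ordering is
#' treated as ambiguous (verdict `unknown`), which is how bidirectional
#' resolutions arise. Draws that would still translate into a cyclic
#' graph are rejected and redrawn; the number of redraws is recorded in
#' the `redraws` attribute.
#'
#' @param ig a `mixed_graph` with candidate edges.
#' @param seed integer seed.
#' @param p_yes probability that any single criterion verdict is `yes`.
#' @param p_theory_unknown probability that an inherently ambiguous
#'   verdict (`unknown`) is drawn where the protocol permits one.
#' @param max_tries redraw budget before giving up.
#' @return an assessment tibble guaranteed translatable, with attribute
#'   `redraws`.
#' @export
random_assessments <- function(ig, seed = 1, p_yes = 0.8,
                               p_theory_unknown = 0.2, max_tries = 100) {
  stopifnot(inherits(ig, "mixed_graph"))
  cand <- ig$edges[ig$edges$status == "candidate", , drop = FALSE]
  draw_direction <- function(tl, hd, consistent) {
    v_temp <- if (consistent) {
      if (stats::runif(1) <= p_yes) "yes" else "no"
    } else {
      if (stats::runif(1) <= p_theory_unknown) "unknown" else "no"
    }
    if (v_temp == "no") {
      return(direction_assessments("random", tl, hd, "no"))
    }
    v_fv <- if (stats::runif(1) <= p_yes) "yes" else "no"
    if (v_fv == "no") {
      return(direction_assessments("random", tl, hd, c(v_temp, "no")))
    }
    v_rt <- if (stats::runif(1) <= p_theory_unknown) "unknown"
            else if (stats::runif(1) <= p_yes) "yes" else "no"
    v_cf <- if (stats::runif(1) <= p_yes) "yes" else "no"
    direction_assessments("random", tl, hd, c(v_temp, "yes", v_rt, v_cf))
  }
  redraws <- 0L
  out <- NULL
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      ord <- sample(ig$nodes$id)
      a <- bind_rows(map(seq_len(nrow(cand)), function(i) {
        tl <- cand$tail[i]
        hd <- cand$head[i]
        forward <- match(tl, ord) < match(hd, ord)
        bind_rows(draw_direction(tl, hd, consistent = forward),
                  draw_direction(hd, tl, consistent = !forward))
      }))
      ok <- tryCatch({
        suppressWarnings(translate_graph(ig, a))
        TRUE
      }, error = function(e) FALSE)
      if (ok) {
        out <- a
        break
      }
      redraws <- redraws + 1L
    }
  })
  if (is.null(out)) {
    abort(sprintf("no translatable assessment set found in %d draws", max_tries))
  }
  attr(out, "redraws") <- redraws
  out
}

#' Generate a random directed edge index
#'
#' @param n_nodes node-pool size.
#' @param n_edges number of records (at most `choose(n_nodes, 2)`).
#' @param seed integer seed.
#' @param p_bidir probability a record is bidirectional.
#' @return an `edge_index` whose records form an acyclic union.
#' @export
random_edge_index <- function(n_nodes = 8, n_edges = 10, seed = 1,
                              p_bidir = 0.1) {
  dag <- random_dag(n_nodes, p_edge = 1, seed = seed)
  idx <- index_edges(dag, "random")
  withr::with_seed(seed + 1L, {
    keep <- sample(nrow(idx$records), min(n_edges, nrow(idx$records)))
    idx$records <- idx$records[sort(keep), , drop = FALSE]
    flip <- stats::runif(nrow(idx$records)) <= p_bidir
    idx$records$bidirectional[flip] <- TRUE
  })
  idx
}
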