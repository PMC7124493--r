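#' Convert a mixed graph to a purely directed analysis graph
#'
#' Graphical identification works on directed edges. Each bidirectional
#' edge `u <-> v` is expanded to a latent (unmeasured) common cause
#' `u <- .l_u_v -> v` — the standard reading of a bidirected edge — and
#' latent nodes are never eligible for adjustment.
#'
#' @param graph a translated or integrated `mixed_graph`, or an
#'   `analysis_graph` (returned unchanged).
#' @return an `analysis_graph`: nodes (with `measured` and `latent`
#'   flags) and directed edges only.
#' @export
analysis_graph <- function(graph) {
  if (inherits(graph, "analysis_graph")) return(graph)
  stopifnot(inherits(graph, "mixed_graph"))
  if (graph$stage == "implied") {
    abort("implied graphs cannot be analysed; translate first")
  }
  if (any(graph$edges$status == "candidate")) {
    abort("candidate edges remain; resolve them before analysis")
  }
  nodes <- tibble(id = graph$nodes$id, measured = graph$nodes$measured,
                  latent = FALSE)
  dir_e <- graph$edges[graph$edges$orientation == "directed",
                       c("tail", "head"), drop = FALSE]
  bi <- graph$edges[graph$edges$orientation == "bidirectional", , drop = FALSE]
  for (i in seq_len(nrow(bi))) {
    a <- pmin(bi$tail[i], bi$head[i]); b <- pmax(bi$tail[i], bi$head[i])
    lid <- paste0(".l_", a, "_", b)
    nodes <- bind_rows(nodes, tibble(id = lid, measured = FALSE, latent = TRUE))
    dir_e <- bind_rows(dir_e, tibble(tail = lid, head = c(a, b)))
  }
  g <- structure(list(nodes = nodes, edges = dir_e), class = "analysis_graph")
  if (!igraph::is_dag(ag_igraph(g))) abort("analysis graph must be acyclic")
  g
}

ag_igraph <- function(g) {
  igraph::graph_from_data_frame(as.data.frame(g$edges), directed = TRUE,
                                vertices = data.frame(name = g$nodes$id))
}

#' @export
print.analysis_graph <- function(x, ...) {
  cat(sprintf("<analysis_graph> %d nodes (%d latent), %d directed edges\n",
              nrow(x$nodes), sum(x$nodes$latent), nrow(x$edges)))
  invisible(x)
}

check_nodes <- function(g, ids) {
  missing <- setdiff(ids, g$nodes$id)
  if (length(missing) > 0) {
    abort(sprintf("unknown node(s): %s", paste(missing, collapse = ", ")))
  }
}

relatives <- function(g, ids, mode, inclusive = FALSE) {
  if (length(ids) == 0) return(character())
  ig <- ag_igraph(g)
  res <- unique(unlist(lapply(ids, function(v) {
    names(igraph::subcomponent(ig, v, mode = mode))
  })))
  if (!inclusive) res <- setdiff(res, ids)
  res
}

#' Ancestors and descendants
#'
#' @param g an `analysis_graph` (or a graph accepted by
#'   [analysis_graph()]).
#' @param id node id (or several).
#' @return character vector of strict ancestors / descendants.
#' @export
ancestors <- function(g, id) {
  g <- analysis_graph(g); check_nodes(g, id)
  relatives(g, id, "in")
}

#' @rdname ancestors
#' @export
descendants <- function(g, id) {
  g <- analysis_graph(g); check_nodes(g, id)
  relatives(g, id, "out")
}

#' Test d-separation
#'
#' Are `x` and `y` d-separated given the conditioning set `Z`? Uses the
#' moralized ancestral graph construction: restrict to the ancestors of
#' `x`, `y` and `Z`, marry the parents of every node, drop directions,
#' remove `Z`, and test connectivity. Equivalent to the path-wise rules
#' (chains and forks blocked when the middle node is conditioned on;
#' colliders open only when the collider or a descendant is conditioned
#' on).
#'
#' @param g an `analysis_graph` (or coercible).
#' @param x,y node ids, not in `Z`.
#' @param Z character vector of conditioning node ids.
#' @return `TRUE` if every path between `x` and `y` is blocked given `Z`.
#' @examples
#' g <- analysis_graph_from_edges(c("a", "b", "c"),
#'   data.frame(tail = c("a", "b"), head = c("b", "c")))
#' d_separated(g, "a", "c", "b")
#' @export
d_separated <- function(g, x, y, Z = character()) {
  g <- analysis_graph(g)
  check_nodes(g, c(x, y, Z))
  if (x %in% Z || y %in% Z) abort("x and y must not be in Z")
  keep <- unique(c(relatives(g, c(x, y, Z), "in", inclusive = TRUE)))
  e <- g$edges[g$edges$tail %in% keep & g$edges$head %in% keep, , drop = FALSE]
  moral <- e[, c("tail", "head")]
  # marry parents
  for (v in keep) {
    pa <- e$tail[e$head == v]
    if (length(pa) > 1) {
      comb <- utils::combn(pa, 2)
      moral <- bind_rows(moral, tibble(tail = comb[1, ], head = comb[2, ]))
    }
  }
  keep2 <- setdiff(keep, Z)
  moral <- moral[moral$tail %in% keep2 & moral$head %in% keep2, , drop = FALSE]
  if (!x %in% keep2 || !y %in% keep2) return(TRUE)
  ug <- igraph::graph_from_data_frame(as.data.frame(moral), directed = FALSE,
                                      vertices = data.frame(name = keep2))
  comp <- igraph::components(ug)$membership
  comp[[x]] != comp[[y]]
}

# all simple paths between x and y in the undirected skeleton, as node
# sequences
skeleton_paths <- function(g, x, y) {
  ug <- igraph::as_undirected(ag_igraph(g), mode = "collapse")
  ps <- igraph::all_simple_paths(ug, from = x, to = y)
  lapply(ps, function(p) igraph::V(ug)$name[p])
}

has_edge <- function(g, tail, head) {
  any(g$edges$tail == tail & g$edges$head == head)
}

path_arrows <- function(g, p) {
  vapply(seq_len(length(p) - 1), function(i) {
    if (has_edge(g, p[i], p[i + 1])) "->" else "<-"
  }, character(1))
}

format_path <- function(p, arrows) {
  out <- p[1]
  for (i in seq_along(arrows)) out <- paste(out, arrows[i], p[i + 1])
  out
}

path_colliders <- function(p, arrows) {
  if (length(p) < 3) return(character())
  p[1 + which(arrows[-length(arrows)] == "->" & arrows[-1] == "<-")]
}

# path-wise open/blocked status given Z
path_open <- function(g, p, arrows, Z) {
  if (length(p) < 3) return(TRUE)
  colliders <- path_colliders(p, arrows)
  interior <- p[-c(1, length(p))]
  noncol <- setdiff(interior, colliders)
  if (any(noncol %in% Z)) return(FALSE)
  for (cv in colliders) {
    if (!cv %in% Z && !any(descendants(g, cv) %in% Z)) return(FALSE)
  }
  TRUE
}

#' Enumerate backdoor paths
#'
#' All acyclic paths from the exposure to the outcome whose first edge
#' points into the exposure; an open backdoor path induces confounding.
#'
#' @param g an `analysis_graph` (or coercible).
#' @param x exposure id; `y` outcome id.
#' @param y outcome id.
#' @param Z conditioning set against which openness is evaluated
#'   (default empty).
#' @return tibble with columns `path` (arrow notation), `kind`
#'   (`"backdoor"`), `open` (given `Z`), `length`.
#' @export
backdoor_paths <- function(g, x, y, Z = character()) {
  g <- analysis_graph(g)
  check_nodes(g, c(x, y, Z))
  if (x == y) abort("x and y must differ")
  out <- tibble(path = character(), kind = character(), open = logical(),
                length = integer())
  for (p in skeleton_paths(g, x, y)) {
    arrows <- path_arrows(g, p)
    if (arrows[1] != "<-") next
    out <- bind_rows(out, tibble(
      path = format_path(p, arrows), kind = "backdoor",
      open = path_open(g, p, arrows, Z), length = length(p) - 1L))
  }
  arrange(out, .data$length, .data$path)
}

#' Minimal sufficient adjustment sets
#'
#' Every inclusion-minimal set of measured nodes satisfying the backdoor
#' criterion for the effect of `x` on `y`: the set contains no descendant
#' of `x` and blocks every backdoor path. Validity of a candidate set is
#' checked by d-separation of `x` and `y` in the graph with the edges out
#' of `x` removed; candidate sets are enumerated exhaustively, which is
#' ample at review scale (capped at `max_nodes` eligible nodes).
#'
#' @param g an `analysis_graph` (or coercible).
#' @param x,y exposure and outcome ids.
#' @param max_nodes refuse enumeration beyond this many eligible nodes.
#' @return tibble with list-column `set` (character vectors, possibly
#'   empty) and `size`; one row per minimal set.
#' @export
minimal_adjustment_sets <- function(g, x, y, max_nodes = 20) {
  g <- analysis_graph(g)
  check_nodes(g, c(x, y))
  if (x == y) abort("x and y must differ")
  eligible <- g$nodes$id[g$nodes$measured & !g$nodes$latent]
  eligible <- setdiff(eligible, c(x, y, descendants(g, x)))
  if (length(eligible) > max_nodes) {
    abort(sprintf(
      "%d eligible adjustment nodes exceed the exhaustive-enumeration cap of %d; a branch-and-bound search is needed at this scale",
      length(eligible), max_nodes))
  }
  gx <- g
  gx$edges <- gx$edges[gx$edges$tail != x, , drop = FALSE]
  valid <- function(Z) d_separated(gx, x, y, Z)
  minimal <- list()
  for (k in 0:length(eligible)) {
    sets <- if (k == 0) list(character()) else
      apply(utils::combn(eligible, k), 2, identity, simplify = FALSE)
    for (Z in sets) {
      if (any(map_lgl(minimal, function(m) all(m %in% Z)))) next
      if (valid(Z)) minimal[[length(minimal) + 1]] <- sort(Z)
    }
  }
  tibble(set = minimal, size = lengths(minimal))
}

#' Classify the role a covariate plays for an exposure-outcome pair
#'
#' Reports every applicable role in a fixed order: `mediator` (on a
#' directed path from `x` to `y`, so adjusting controls away part of the
#' effect), `confounder` (a non-collider on an open backdoor path, so
#' adjusting removes bias), `collider_on_path` (a collider on some
#' path, so adjusting can induce bias), then `risk_factor_only` (causes
#' the outcome on another pathway — adjustment may improve precision but
#' removes no bias), `instrument_like` (causes the exposure with no
#' other route to the outcome), or `disconnected`.
#'
#' @param g an `analysis_graph` (or coercible).
#' @param x,y exposure and outcome ids.
#' @param v the covariate, distinct from `x` and `y`.
#' @return tibble with columns `node` and `role`, one row per applicable
#'   role.
#' @export
classify_covariate <- function(g, x, y, v) {
  g <- analysis_graph(g)
  check_nodes(g, c(x, y, v))
  if (v %in% c(x, y)) abort("v must differ from x and y")
  an_x <- ancestors(g, x); an_y <- ancestors(g, y)
  de_x <- descendants(g, x)
  roles <- character()
  if (v %in% de_x && y %in% descendants(g, v)) roles <- c(roles, "mediator")
  is_conf <- FALSE
  is_coll <- FALSE
  for (p in skeleton_paths(g, x, y)) {
    arrows <- path_arrows(g, p)
    colliders <- path_colliders(p, arrows)
    interior <- p[-c(1, length(p))]
    if (v %in% colliders) is_coll <- TRUE
    if (arrows[1] == "<-" && v %in% setdiff(interior, colliders) &&
        path_open(g, p, arrows, character())) {
      is_conf <- TRUE
    }
  }
  if (is_conf) roles <- c(roles, "confounder")
  if (is_coll) roles <- c(roles, "collider_on_path")
  if (length(roles) == 0) {
    if (v %in% an_y && !v %in% an_x) {
      roles <- "risk_factor_only"
    } else if (v %in% an_x) {
      # instrument-like: every route to the outcome passes through x
      gx <- g
      gx$edges <- gx$edges[gx$edges$tail != x, , drop = FALSE]
      if (!y %in% descendants(gx, v)) roles <- "instrument_like"
    }
  }
  if (length(roles) == 0) roles <- "disconnected"
  order <- c("mediator", "confounder", "collider_on_path", "risk_factor_only",
             "instrument_like", "disconnected")
  tibble(node = v, role = order[order %in% roles])
}

#' Consequences of a proposed adjustment set
#'
#' Reports the harm an adjustment set would do: causal paths from `x` to
#' `y` it blocks (over-control of the effect under study) and paths it
#' opens by conditioning on a collider or a collider's descendant
#' (induced collider bias).
#'
#' @param g an `analysis_graph` (or coercible).
#' @param x,y exposure and outcome ids.
#' @param Z proposed adjustment set (excluding `x`, `y`).
#' @return an `adjustment_consequences` object: list of tibbles
#'   `blocked_causal` (`path`) and `opened` (`path`, `colliders` — the
#'   conditioned colliders that open it, comma-joined).
#' @export
adjustment_consequences <- function(g, x, y, Z) {
  g <- analysis_graph(g)
  check_nodes(g, c(x, y, Z))
  if (any(c(x, y) %in% Z)) abort("Z must exclude x and y")
  blocked <- tibble(path = character())
  opened <- tibble(path = character(), colliders = character())
  for (p in skeleton_paths(g, x, y)) {
    arrows <- path_arrows(g, p)
    if (all(arrows == "->")) {
      if (any(p[-c(1, length(p))] %in% Z)) {
        blocked <- bind_rows(blocked, tibble(path = format_path(p, arrows)))
      }
      next
    }
    was_open <- path_open(g, p, arrows, character())
    now_open <- path_open(g, p, arrows, Z)
    if (!was_open && now_open) {
      cols <- path_colliders(p, arrows)
      active <- cols[map_lgl(cols, function(cv)
        cv %in% Z || any(descendants(g, cv) %in% Z))]
      opened <- bind_rows(opened, tibble(
        path = format_path(p, arrows),
        colliders = paste(active, collapse = ",")))
    }
  }
  structure(list(blocked_causal = blocked, opened = opened, x = x, y = y,
                 Z = Z),
            class = "adjustment_consequences")
}

#' @export
print.adjustment_consequences <- function(x, ...) {
  cat(sprintf("<adjustment_consequences> %s -> %s given {%s}\n",
              x$x, x$y, paste(x$Z, collapse = ", ")))
  if (nrow(x$blocked_causal) > 0) {
    cat("  blocked causal paths (over-control):\n")
    cat(paste0("    ", x$blocked_causal$path, collapse = "\n"), "\n")
  }
  if (nrow(x$opened) > 0) {
    cat("  opened paths (collider bias):\n")
    cat(paste0("    ", x$opened$path, "  [collider: ", x$opened$colliders, "]",
               collapse = "\n"), "\n")
  }
  if (nrow(x$blocked_causal) == 0 && nrow(x$opened) == 0) {
    cat("  no over-control, no induced collider bias\n")
  }
  invisible(x)
}

#' Build an analysis graph directly from an edge table
#'
#' Mostly useful in examples and tests.
#'
#' @param nodes character vector of node ids.
#' @param edges data frame with columns `tail`, `head`.
#' @param measured logical vector parallel to `nodes` (default all).
#' @return an `analysis_graph`.
#' @export
analysis_graph_from_edges <- function(nodes, edges, measured = TRUE) {
  nodes <- tibble(id = nodes, measured = rep_len(measured, length(nodes)),
                  latent = FALSE)
  g <- structure(list(nodes = nodes,
                      edges = as_tibble(edges)[, c("tail", "head")]),
                 class = "analysis_graph")
  if (!igraph::is_dag(ag_igraph(g))) abort("edges contain a directed cycle")
  g
}
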