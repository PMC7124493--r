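#' Create a mixed causal graph
#'
#' The shared container for every stage of the evidence-synthesis workflow.
#' A mixed graph holds nodes and at most one edge per unordered node pair;
#' each edge is directed, unassigned (orientation not yet decided) or
#' bidirectional, and is either a `candidate` awaiting assessment or
#' `retained` after assessment. Graphs carry a stage flag: `implied` (a
#' study's saturated implied graph, where direction does not yet matter),
#' `translated` (every candidate resolved through the causal criteria) or
#' `integrated` (synthesised across studies). Acyclicity of the directed
#' part is a hard invariant at the translated and integrated stages.
#'
#' @param nodes character vector of node ids, or a tibble with columns
#'   `id`, and optionally `label`, `measured`, `aliases` (list), `roles`
#'   (list), `notes`.
#' @param stage one of `"implied"`, `"translated"`, `"integrated"`.
#' @return a `mixed_graph` object.
#' @examples
#' g <- mixed_graph(c("x", "y", "z"))
#' g <- add_edge(g, "x", "y")
#' glance(g)
#' @export
mixed_graph <- function(nodes = character(), stage = "implied") {
  stage <- match_arg1(stage, STAGES, "stage")
  if (is.character(nodes)) {
    nodes <- tibble(id = nodes)
  }
  nodes <- as_tibble(nodes)
  if (nrow(nodes) > 0) check_token(nodes$id)
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  if (!"measured" %in% names(nodes)) nodes$measured <- TRUE
  if (!"aliases" %in% names(nodes)) nodes$aliases <- rep(list(character()), nrow(nodes))
  if (!"roles" %in% names(nodes)) nodes$roles <- rep(list(character()), nrow(nodes))
  if (!"notes" %in% names(nodes)) nodes$notes <- rep("", nrow(nodes))
  nodes <- nodes[, c("id", "label", "measured", "aliases", "roles", "notes")]
  g <- structure(
    list(nodes = nodes, edges = empty_edges(), deletions = empty_deletions(),
         stage = stage),
    class = "mixed_graph"
  )
  validate_mixed_graph(g)
}

empty_edges <- function() {
  tibble(tail = character(), head = character(),
         orientation = character(), status = character(),
         confidence = character(), provenance = list())
}

empty_deletions <- function() {
  tibble(a = character(), b = character(), provenance = list(),
         rationale = character())
}

validate_mixed_graph <- function(g) {
  nodes <- g$nodes
  edges <- g$edges
  if (anyDuplicated(nodes$id)) {
    abort(sprintf("duplicate node id: %s",
                  paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")))
  }
  all_alias <- unlist(nodes$aliases)
  if (anyDuplicated(all_alias)) {
    abort("alias collision: alias sets of distinct nodes must be disjoint")
  }
  if (any(all_alias %in% nodes$id)) {
    # an alias naming another node's id is an implicit collision too
    clash <- intersect(all_alias, nodes$id)
    own <- unlist(purrr::map2(nodes$id, nodes$aliases, function(i, a) {
      if (i %in% a) i else character()
    }))
    clash <- setdiff(clash, own)
    if (length(clash) > 0) {
      abort(sprintf("alias collision with node id(s): %s",
                    paste(clash, collapse = ", ")))
    }
  }
  if (nrow(edges) > 0) {
    missing <- setdiff(c(edges$tail, edges$head), nodes$id)
    if (length(missing) > 0) {
      abort(sprintf("unknown node id in edges: %s", paste(missing, collapse = ", ")))
    }
    if (any(edges$tail == edges$head)) abort("self-loops are not permitted")
    if (anyDuplicated(pair_key(edges$tail, edges$head))) {
      abort("two edges on one unordered node pair")
    }
    bad <- edges$orientation == "unassigned" & edges$status != "candidate"
    if (any(bad)) abort("unassigned edges must have candidate status")
  }
  if (g$stage %in% c("translated", "integrated")) {
    if (!is_acyclic(g)) abort(sprintf("%s graph must be acyclic", g$stage))
  }
  g
}

#' Add a node to a mixed graph
#'
#' @param graph a `mixed_graph`.
#' @param id canonical node id (lowercase, no whitespace).
#' @param label human-readable name; defaults to the id.
#' @param measured logical; unmeasured nodes are never eligible for
#'   adjustment.
#' @param aliases character vector of study-specific variable names mapped
#'   to this node.
#' @param roles character vector drawn from the recognised role set
#'   (exposure, outcome, control, mediator, instrument, reviewer_added).
#' @return the updated `mixed_graph`.
#' @export
add_node <- function(graph, id, label = id, measured = TRUE,
                     aliases = character(), roles = character()) {
  stopifnot(inherits(graph, "mixed_graph"))
  check_token(id)
  if (id %in% graph$nodes$id) abort(sprintf("node id already present: %s", id))
  if (length(roles) > 0 && !all(roles %in% NODE_ROLES)) {
    abort(sprintf("unknown role(s): %s",
                  paste(setdiff(roles, NODE_ROLES), collapse = ", ")))
  }
  graph$nodes <- bind_rows(
    graph$nodes,
    tibble(id = id, label = label, measured = measured,
           aliases = list(aliases), roles = list(roles), notes = "")
  )
  validate_mixed_graph(graph)
}

#' Add or replace an edge
#'
#' At most one edge may occupy an unordered node pair: the posited
#' direction and its reverse are states of a single edge. Inserting onto
#' an occupied pair replaces the existing edge only while that edge is
#' still a candidate; retained edges must be removed through assessment,
#' never overwritten.
#'
#' @param graph a `mixed_graph`.
#' @param tail,head node ids; for bidirectional or unassigned edges the
#'   order is not meaningful.
#' @param orientation `"directed"`, `"unassigned"` or `"bidirectional"`.
#' @param status `"candidate"` or `"retained"`.
#' @param confidence `"normal"` or `"low"`.
#' @param provenance character vector of `"study@stage"` provenance tokens.
#' @return the updated `mixed_graph`.
#' @export
add_edge <- function(graph, tail, head, orientation = "directed",
                     status = "candidate", confidence = "normal",
                     provenance = character()) {
  stopifnot(inherits(graph, "mixed_graph"))
  orientation <- match_arg1(orientation, ORIENTATIONS, "orientation")
  status <- match_arg1(status, setdiff(STATUSES, "deleted"), "status")
  confidence <- match_arg1(confidence, CONFIDENCES, "confidence")
  if (!tail %in% graph$nodes$id) abort(sprintf("unknown node id: %s", tail))
  if (!head %in% graph$nodes$id) abort(sprintf("unknown node id: %s", head))
  if (tail == head) abort("self-loops are not permitted")
  key <- pair_key(tail, head)
  existing <- pair_key(graph$edges$tail, graph$edges$head) == key
  if (any(existing)) {
    if (any(graph$edges$status[existing] == "retained")) {
      abort(sprintf("pair %s is occupied by a retained edge",
                    pair_label(tail, head)))
    }
    graph$edges <- graph$edges[!existing, ]
  }
  graph$edges <- bind_rows(
    graph$edges,
    tibble(tail = tail, head = head, orientation = orientation,
           status = status, confidence = confidence,
           provenance = list(provenance))
  )
  validate_mixed_graph(graph)
}

# igraph view of the directed part (non-deleted directed edges by default)
directed_igraph <- function(graph, edges = NULL) {
  if (is.null(edges)) {
    edges <- graph$edges[graph$edges$orientation == "directed", , drop = FALSE]
  }
  igraph::graph_from_data_frame(
    d = as.data.frame(edges[, c("tail", "head")]),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$id)
  )
}

#' Is the directed part of a graph acyclic?
#'
#' Only directed edges are considered; unassigned and bidirectional edges
#' cannot form directed cycles and are ignored (a bidirectional edge is
#' read as a latent common cause, not a 2-cycle).
#'
#' @param graph a `mixed_graph`.
#' @return `TRUE` if the directed edges contain no directed cycle.
#' @export
is_acyclic <- function(graph) {
  stopifnot(inherits(graph, "mixed_graph"))
  igraph::is_dag(directed_igraph(graph))
}

# minimal directed cycles, for error reporting: one shortest cycle per
# non-trivial strongly connected component
find_cycles <- function(graph) {
  ig <- directed_igraph(graph)
  comp <- igraph::components(ig, mode = "strong")
  cyc <- list()
  for (k in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == k]
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(ig, members)
    v0 <- igraph::V(sub)[1]
    best <- NULL
    for (w in igraph::neighbors(sub, v0, mode = "out")) {
      p <- igraph::shortest_paths(sub, from = w, to = v0, mode = "out")$vpath[[1]]
      if (length(p) > 0) {
        cand <- c(igraph::V(sub)$name[v0], igraph::V(sub)$name[p])
        if (is.null(best) || length(cand) < length(best)) best <- cand
      }
    }
    if (!is.null(best)) cyc[[length(cyc) + 1]] <- best
  }
  cyc
}

cycle_message <- function(cycles) {
  paste(vapply(cycles, function(cy) paste(c(cy, cy[1]), collapse = " -> "),
               character(1)), collapse = "; ")
}

#' Saturate a graph
#'
#' Ensures every unordered node pair carries exactly one edge, because the
#' absence of an edge is the stronger causal claim: omitted connections
#' must be deleted deliberately, not forgotten. Pairs without an edge gain
#' an unassigned candidate edge; existing edges are untouched, so the
#' operation is idempotent.
#'
#' @param graph a `mixed_graph`.
#' @return the saturated `mixed_graph`.
#' @export
saturate <- function(graph) {
  stopifnot(inherits(graph, "mixed_graph"))
  ids <- sort(graph$nodes$id)
  if (length(ids) < 2) return(graph)
  pairs <- utils::combn(ids, 2)
  have <- pair_key(graph$edges$tail, graph$edges$head)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (!pair_key(a, b) %in% have) {
      graph <- add_edge(graph, a, b, orientation = "unassigned",
                        status = "candidate")
    }
  }
  graph
}

#' Look up the recorded roles of a node
#'
#' @param graph a `mixed_graph`.
#' @param id node id.
#' @return character vector of roles.
#' @export
roles_of <- function(graph, id) {
  stopifnot(inherits(graph, "mixed_graph"))
  i <- match(id, graph$nodes$id)
  if (is.na(i)) abort(sprintf("unknown node id: %s", id))
  graph$nodes$roles[[i]]
}

#' Stage of a graph
#' @param graph a `mixed_graph`.
#' @return `"implied"`, `"translated"` or `"integrated"`.
#' @export
graph_stage <- function(graph) {
  stopifnot(inherits(graph, "mixed_graph"))
  graph$stage
}

set_stage <- function(graph, stage) {
  stage <- match_arg1(stage, STAGES, "stage")
  if (stage %in% c("translated", "integrated")) {
    if (any(graph$edges$status == "candidate")) {
      abort(sprintf("cannot mark graph %s: unresolved candidate edges remain",
                    stage))
    }
    if (!is_acyclic(graph)) {
      abort(sprintf("cannot mark graph %s: directed cycle present (%s)",
                    stage, cycle_message(find_cycles(graph))))
    }
  }
  graph$stage <- stage
  graph
}

#' @export
print.mixed_graph <- function(x, ...) {
  counts <- table(factor(x$edges$orientation, levels = ORIENTATIONS))
  cat(sprintf("<mixed_graph> stage=%s: %d nodes, %d edges (%d directed, %d unassigned, %d bidirectional), %d recorded deletions\n",
              x$stage, nrow(x$nodes), nrow(x$edges),
              counts[["directed"]], counts[["unassigned"]],
              counts[["bidirectional"]], nrow(x$deletions)))
  if (nrow(x$edges) > 0) {
    arrows <- c(directed = "->", unassigned = "--", bidirectional = "<->")
    e <- arrange(x$edges, .data$tail, .data$head)
    cat(paste0("  ", e$tail, " ", arrows[e$orientation], " ", e$head,
               ifelse(e$status == "candidate", " [candidate]", ""),
               ifelse(e$confidence == "low", " [low confidence]", ""),
               collapse = "\n"), "\n")
  }
  invisible(x)
}
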