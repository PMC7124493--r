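#' Export a graph in DAGitty model text
#'
#' Emits the textual `dag { ... }` model dialect understood by DAGitty:
#' one node declaration per line with role annotations
#' (`[exposure]`, `[outcome]`, `[latent]` for unmeasured nodes; other
#' recorded roles are emitted as annotations too so that a round trip is
#' lossless), then one edge per line (`->` directed, `<->`
#' bidirectional). Output ordering is lexicographic, so identical graphs
#' serialise byte-identically. Layout coordinates are presentation, not
#' structure, and are never emitted.
#'
#' @param g a translated or integrated `mixed_graph` (implied graphs hold
#'   unassigned edges, which the format cannot represent).
#' @return a single character string.
#' @examples
#' g <- mixed_graph(c("x", "y"), stage = "implied")
#' g <- add_edge(g, "x", "y", status = "retained")
#' cat(export_dagitty(set_graph_stage(g, "translated")))
#' @export
export_dagitty <- function(g) {
  stopifnot(inherits(g, "mixed_graph"))
  if (g$stage == "implied" || any(g$edges$orientation == "unassigned")) {
    abort("unassigned edges cannot be represented in DAGitty model text; translate first")
  }
  nodes <- arrange(g$nodes, .data$id)
  node_lines <- map_chr(seq_len(nrow(nodes)), function(i) {
    ann <- intersect(c("exposure", "outcome"), nodes$roles[[i]])
    ann <- c(ann, setdiff(nodes$roles[[i]], c("exposure", "outcome")))
    if (!nodes$measured[i]) ann <- c(ann, "latent")
    if (length(ann) == 0) nodes$id[i]
    else paste0(nodes$id[i], " [", paste(ann, collapse = ","), "]")
  })
  e <- g$edges
  edge_lines <- character()
  if (nrow(e) > 0) {
    a <- ifelse(e$orientation == "bidirectional", pmin(e$tail, e$head), e$tail)
    b <- ifelse(e$orientation == "bidirectional", pmax(e$tail, e$head), e$head)
    op <- ifelse(e$orientation == "bidirectional", "<->", "->")
    edge_lines <- sort(paste(a, op, b))
  }
  paste0(paste(c("dag {", node_lines, edge_lines, "}"), collapse = "\n"), "\n")
}

#' Import DAGitty model text
#'
#' Parses the `dag { ... }` dialect: node declarations with bracketed
#' annotations and `->` / `<->` / `<-` edge statements. Recognised
#' annotations become roles (`exposure`, `outcome`, and the package's
#' role vocabulary) or the measured flag (`latent`/`unobserved`);
#' position annotations (`pos=...`) are dropped with a notice; anything
#' else is preserved in the node's notes.
#'
#' @param text DAGitty model text (single string or lines).
#' @param stage stage flag for the resulting graph (default
#'   `"translated"`).
#' @return a `mixed_graph` with all edges retained.
#' @export
import_dagitty <- function(text, stage = "translated") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  n_open <- grep("\\{", lines)
  n_close <- grep("\\}", lines)
  if (length(n_open) == 0 || length(n_close) == 0) {
    abort("not DAGitty model text: missing 'dag {' ... '}'")
  }
  header <- paste(lines[seq_len(n_open[1])], collapse = " ")
  if (!grepl("^\\s*dag\\b", header)) {
    abort(sprintf("line %d: expected model text to open with 'dag'", n_open[1]))
  }
  body_idx <- seq(n_open[1], n_close[length(n_close)])
  body <- lines
  body[n_open[1]] <- sub("^.*\\{", "", body[n_open[1]])
  body[n_close[length(n_close)]] <-
    sub("\\}[^}]*$", "", body[n_close[length(n_close)]])
  body[-body_idx] <- ""

  node_tbl <- tibble(id = character(), measured = logical(),
                     roles = list(), notes = character())
  edge_tbl <- tibble(tail = character(), head = character(),
                     orientation = character())
  dropped_pos <- FALSE
  known_roles <- NODE_ROLES

  declare <- function(id, measured = TRUE, roles = character(), notes = "") {
    i <- match(id, node_tbl$id)
    if (is.na(i)) {
      node_tbl <<- bind_rows(node_tbl, tibble(
        id = id, measured = measured, roles = list(roles), notes = notes))
    } else {
      node_tbl$measured[i] <<- node_tbl$measured[i] && measured
      node_tbl$roles[[i]] <<- union(node_tbl$roles[[i]], roles)
      if (nzchar(notes)) {
        node_tbl$notes[i] <<- paste(c(node_tbl$notes[i][nzchar(node_tbl$notes[i])],
                                      notes), collapse = "; ")
      }
    }
  }

  tok_re <- "[A-Za-z0-9_.]+"
  for (ln in seq_along(body)) {
    stmts <- unlist(strsplit(body[ln], ";", fixed = TRUE))
    for (stmt in stmts) {
      s <- trimws(stmt)
      if (s == "") next
      if (grepl("<->|->|<-", s)) {
        m <- regmatches(s, regexec(
          sprintf("^(%s)\\s*(<->|->|<-)\\s*(%s)$", tok_re, tok_re), s))[[1]]
        if (length(m) == 0) {
          abort(sprintf("line %d: malformed edge statement '%s'", ln, s))
        }
        a <- tolower(m[2]); op <- m[3]; b <- tolower(m[4])
        declare(a); declare(b)
        edge_tbl <- bind_rows(edge_tbl, tibble(
          tail = if (op == "<-") b else a,
          head = if (op == "<-") a else b,
          orientation = if (op == "<->") "bidirectional" else "directed"))
      } else {
        m <- regmatches(s, regexec(
          sprintf("^(%s)\\s*(\\[([^]]*)\\])?$", tok_re), s))[[1]]
        if (length(m) == 0) {
          abort(sprintf("line %d: cannot parse statement '%s'", ln, s))
        }
        id <- tolower(m[2])
        anns <- if (is.na(m[4]) || m[4] == "") character() else
          trimws(unlist(strsplit(m[4], ",", fixed = TRUE)))
        measured <- TRUE; roles <- character(); notes <- character()
        for (ann in anns) {
          key <- sub("=.*$", "", ann)
          if (key %in% c("latent", "unobserved")) measured <- FALSE
          else if (key %in% known_roles) roles <- c(roles, key)
          else if (key == "pos") dropped_pos <- TRUE
          else notes <- c(notes, ann)
        }
        declare(id, measured, roles, paste(notes, collapse = "; "))
      }
    }
  }
  if (dropped_pos) {
    inform("layout coordinates (pos=...) accepted on import but dropped")
  }
  g <- mixed_graph(node_tbl, stage = "implied")
  for (i in seq_len(nrow(edge_tbl))) {
    g <- add_edge(g, edge_tbl$tail[i], edge_tbl$head[i],
                  orientation = edge_tbl$orientation[i], status = "retained")
  }
  set_graph_stage(g, stage)
}

#' Set the stage flag of a graph
#'
#' Promoting to `translated` or `integrated` enforces the hard
#' invariants: no candidate edges and an acyclic directed part.
#'
#' @param graph a `mixed_graph`.
#' @param stage one of `"implied"`, `"translated"`, `"integrated"`.
#' @return the updated graph.
#' @export
set_graph_stage <- function(graph, stage) {
  stopifnot(inherits(graph, "mixed_graph"))
  set_stage(graph, stage)
}

#' Export a graph as Graphviz DOT
#'
#' Bidirectional edges render with `dir=both`, unassigned candidate edges
#' with `dir=none`; exposure and outcome nodes are boxed. Ordering is
#' lexicographic for byte-stable output.
#'
#' @param g a `mixed_graph`.
#' @return DOT digraph text.
#' @export
export_dot <- function(g) {
  stopifnot(inherits(g, "mixed_graph"))
  nodes <- arrange(g$nodes, .data$id)
  node_lines <- map_chr(seq_len(nrow(nodes)), function(i) {
    attrs <- sprintf("label=\"%s\"", nodes$label[i])
    if (any(c("exposure", "outcome") %in% nodes$roles[[i]])) {
      attrs <- paste0(attrs, ", shape=box")
    }
    if (!nodes$measured[i]) attrs <- paste0(attrs, ", style=dashed")
    sprintf("  \"%s\" [%s];", nodes$id[i], attrs)
  })
  e <- g$edges
  edge_lines <- character()
  if (nrow(e) > 0) {
    a <- ifelse(e$orientation == "directed", e$tail, pmin(e$tail, e$head))
    b <- ifelse(e$orientation == "directed", e$head, pmax(e$tail, e$head))
    attr <- map_chr(seq_len(nrow(e)), function(i) {
      toks <- character()
      if (e$orientation[i] == "bidirectional") toks <- c(toks, "dir=both")
      if (e$orientation[i] == "unassigned") toks <- c(toks, "dir=none")
      if (e$status[i] == "candidate") toks <- c(toks, "style=dotted")
      if (length(toks) == 0) "" else
        paste0(" [", paste(toks, collapse = ", "), "]")
    })
    edge_lines <- sort(sprintf("  \"%s\" -> \"%s\"%s;", a, b, attr))
  }
  paste0(paste(c("digraph {", node_lines, edge_lines, "}"), collapse = "\n"),
         "\n")
}
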