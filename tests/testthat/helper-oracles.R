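# Independent brute-force oracles, deliberately built on path enumeration
# and the per-path blocking rules (chain/fork blocked iff middle node
# conditioned on; collider open iff it or a descendant is conditioned on),
# in base R, so they share no machinery with the package implementations.

# edges: data.frame(tail, head) of a DAG
oracle_adj <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$tail[i]]] <- c(adj[[edges$tail[i]]], edges$head[i])
    adj[[edges$head[i]]] <- c(adj[[edges$head[i]]], edges$tail[i])
  }
  lapply(adj, unique)
}

# all simple paths x..y in the undirected skeleton (node sequences)
oracle_all_paths <- function(edges, nodes, x, y) {
  adj <- oracle_adj(edges, nodes)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (!w %in% path) walk(c(path, w))
    }
  }
  walk(x)
  out
}

# descendant sets via reflexive-transitive closure (matrix powers)
oracle_descendants <- function(edges, nodes) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) A[edges$tail[i], edges$head[i]] <- TRUE
  R <- A | diag(TRUE, n)
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  lapply(stats::setNames(nodes, nodes), function(v) nodes[R[v, ]])
}

oracle_has_edge <- function(edges, a, b) {
  any(edges$tail == a & edges$head == b)
}

# is one path open given Z, by the path-wise rules?
oracle_path_open <- function(edges, path, Z, desc) {
  if (length(path) < 3) return(TRUE)
  for (k in 2:(length(path) - 1)) {
    prev <- path[k - 1]; v <- path[k]; nxt <- path[k + 1]
    is_collider <- oracle_has_edge(edges, prev, v) &&
      oracle_has_edge(edges, nxt, v)
    if (is_collider) {
      if (!any(desc[[v]] %in% Z)) return(FALSE)
    } else {
      if (v %in% Z) return(FALSE)
    }
  }
  TRUE
}

oracle_d_sep <- function(edges, nodes, x, y, Z) {
  desc <- oracle_descendants(edges, nodes)
  paths <- oracle_all_paths(edges, nodes, x, y)
  !any(vapply(paths, oracle_path_open, logical(1),
              edges = edges, Z = Z, desc = desc))
}

# backdoor-criterion minimal sets by full subset enumeration over the
# path-wise rules: Z must contain no descendant of x and block every
# path whose first edge points into x; causal (front-door) paths are
# never blocked by an eligible Z since eligible nodes are non-descendants
oracle_min_adjust <- function(edges, nodes, measured, x, y) {
  desc <- oracle_descendants(edges, nodes)
  eligible <- setdiff(nodes[measured], c(x, y, setdiff(desc[[x]], x)))
  paths <- oracle_all_paths(edges, nodes, x, y)
  backdoor <- Filter(function(p) oracle_has_edge(edges, p[2], p[1]), paths)
  valid <- function(Z) {
    !any(vapply(backdoor, oracle_path_open, logical(1),
                edges = edges, Z = Z, desc = desc))
  }
  sets <- list(character())
  for (k in seq_along(eligible)) {
    cmb <- utils::combn(eligible, k)
    sets <- c(sets, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  valids <- Filter(valid, sets)
  minimal <- Filter(function(Z) {
    !any(vapply(valids, function(W)
      length(W) < length(Z) && all(W %in% Z), logical(1)))
  }, valids)
  lapply(minimal, sort)
}

# directed-cycle detection by exhaustive DFS
oracle_acyclic <- function(edges, nodes) {
  state <- stats::setNames(rep(0L, length(nodes)), nodes)
  ok <- TRUE
  visit <- function(v) {
    if (!ok) return(invisible())
    state[v] <<- 1L
    for (w in edges$head[edges$tail == v]) {
      if (state[w] == 1L) ok <<- FALSE
      else if (state[w] == 0L) visit(w)
    }
    state[v] <<- 2L
  }
  for (v in nodes) if (state[v] == 0L) visit(v)
  ok
}

# canonical signature of a mixed graph for equality-as-labelled-sets
graph_signature <- function(g) {
  e <- g$edges
  a <- ifelse(e$orientation == "directed", e$tail, pmin(e$tail, e$head))
  b <- ifelse(e$orientation == "directed", e$head, pmax(e$tail, e$head))
  list(nodes = sort(g$nodes$id),
       roles = lapply(g$nodes$roles[order(g$nodes$id)], sort),
       edges = sort(paste(a, e$orientation, b, e$status)))
}

# minimal adjustment sets as a canonical sorted list for comparison
mas_canonical <- function(mas_tbl) {
  sets <- lapply(mas_tbl$set, sort)
  sets[order(vapply(sets, paste, character(1), collapse = "|"))]
}

expect_same_sets <- function(got, want) {
  expect_equal(mas_canonical(tibble::tibble(set = got)),
               mas_canonical(tibble::tibble(set = want)))
}
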