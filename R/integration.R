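#' Create a directed edge index
#'
#' The provenance-bearing registry of retained edges across studies. Each
#' record is one unordered node pair with its resolved direction (or a
#' bidirectional flag), worst-case confidence, and the set of contributing
#' studies. Deletion records mark pairs assessed and rejected in the
#' context of the integrated DAG, so that synthesis can distinguish
#' "assessed and rejected" from "never assessed".
#'
#' @param records tibble with columns `tail`, `head`, `bidirectional`,
#'   `confidence`, `provenance` (list of character), `notes`, `conflict`.
#' @param deletions tibble with columns `a`, `b`, `provenance`, `notes`.
#' @return an `edge_index` object.
#' @export
edge_index <- function(records = empty_index_records(),
                       deletions = empty_index_deletions()) {
  records <- as_tibble(records)
  deletions <- as_tibble(deletions)
  if (!"conflict" %in% names(records)) records$conflict <- rep(FALSE, nrow(records))
  if (!"notes" %in% names(records)) records$notes <- rep("", nrow(records))
  if (nrow(records) > 0 && any(lengths(records$provenance) == 0)) {
    abort("every index record needs non-empty provenance")
  }
  if (anyDuplicated(pair_key(records$tail, records$head))) {
    abort("edge index holds at most one record per unordered pair")
  }
  overlap <- intersect(pair_key(records$tail, records$head),
                       pair_key(deletions$a, deletions$b))
  if (length(overlap) > 0) {
    abort("a pair cannot be both retained and deleted in the index")
  }
  structure(list(records = records, deletions = deletions),
            class = "edge_index")
}

empty_index_records <- function() {
  tibble(tail = character(), head = character(), bidirectional = logical(),
         confidence = character(), provenance = list(), notes = character(),
         conflict = logical())
}

empty_index_deletions <- function() {
  tibble(a = character(), b = character(), provenance = list(),
         notes = character())
}

#' @export
print.edge_index <- function(x, ...) {
  cat(sprintf("<edge_index> %d records (%d bidirectional, %d conflicts), %d deletion records\n",
              nrow(x$records), sum(x$records$bidirectional),
              sum(x$records$conflict), nrow(x$deletions)))
  if (nrow(x$records) > 0) {
    r <- arrange(x$records, .data$tail, .data$head)
    cat(paste0("  ", r$tail, ifelse(r$bidirectional, " <-> ", " -> "), r$head,
               " [", map_chr(r$provenance, function(p)
                 paste(prov_studies(p), collapse = ";")), "]",
               ifelse(r$conflict, " [CONFLICT]", ""), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Index the retained edges of a translated DAG
#'
#' Enters every retained edge of a study's translated DAG into a (new)
#' directed edge index with the study as provenance. Matching the review
#' protocol, only retained edges are indexed here: a pair deleted in one
#' study's context is a study-level verdict and is re-assessed in the
#' context of the integrated DAG, where it resurfaces as a pending pair.
#'
#' @param dag a translated (or integrated) acyclic `mixed_graph`.
#' @param study_id provenance token for this study.
#' @return an `edge_index` holding this study's retained edges.
#' @export
index_edges <- function(dag, study_id) {
  stopifnot(inherits(dag, "mixed_graph"))
  if (dag$stage == "implied") {
    abort("only translated (or integrated) graphs can be indexed")
  }
  e <- dag$edges[dag$edges$status == "retained", , drop = FALSE]
  recs <- tibble(
    tail = e$tail, head = e$head,
    bidirectional = e$orientation == "bidirectional",
    confidence = e$confidence,
    provenance = map(e$provenance, function(p)
      merge_prov(p, make_prov(study_id, "index"))),
    notes = "", conflict = FALSE)
  edge_index(records = recs)
}

#' Merge edge indices
#'
#' Commutative, associative and idempotent on provenance. Records on the
#' same unordered pair with agreeing direction (or both bidirectional)
#' merge: provenance is unioned and confidence takes the worst case.
#' Disagreeing directions across studies are never silently merged and
#' never auto-promoted to bidirectional — bidirectionality is a
#' substantive claim — so the pair is flagged for reviewer re-assessment
#' (see [resolve_index_conflict()]).
#'
#' @param ... `edge_index` objects.
#' @return the merged `edge_index`.
#' @export
merge_indices <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1, all(map_lgl(xs, inherits, "edge_index")))
  recs <- bind_rows(map(xs, "records"))
  dels <- bind_rows(map(xs, "deletions"))
  out <- empty_index_records()
  if (nrow(recs) > 0) {
    recs$.key <- pair_key(recs$tail, recs$head)
    for (key in unique(recs$.key)) {
      grp <- recs[recs$.key == key, , drop = FALSE]
      dirs <- unique(paste(grp$tail, grp$head, grp$bidirectional))
      prov <- Reduce(merge_prov, grp$provenance)
      notes <- paste(unique(grp$notes[grp$notes != ""]), collapse = "; ")
      if (length(dirs) == 1) {
        out <- bind_rows(out, tibble(
          tail = grp$tail[1], head = grp$head[1],
          bidirectional = grp$bidirectional[1],
          confidence = do.call(min_confidence, as.list(grp$confidence)),
          provenance = list(prov), notes = notes,
          conflict = any(grp$conflict)))
      } else {
        out <- bind_rows(out, tibble(
          tail = grp$tail[1], head = grp$head[1],
          bidirectional = any(grp$bidirectional),
          confidence = "low",
          provenance = list(prov),
          notes = paste0("direction conflict: ",
                         paste(unique(ifelse(grp$bidirectional,
                                             paste(grp$tail, "<->", grp$head),
                                             paste(grp$tail, "->", grp$head))),
                               collapse = " vs "),
                         if (notes != "") paste0("; ", notes) else ""),
          conflict = TRUE))
      }
    }
  }
  dout <- empty_index_deletions()
  if (nrow(dels) > 0) {
    dels$.key <- pair_key(dels$a, dels$b)
    for (key in unique(dels$.key)) {
      grp <- dels[dels$.key == key, , drop = FALSE]
      dout <- bind_rows(dout, tibble(
        a = grp$a[1], b = grp$b[1],
        provenance = list(Reduce(merge_prov, grp$provenance)),
        notes = paste(unique(grp$notes[grp$notes != ""]), collapse = "; ")))
    }
  }
  # a pair retained by any study wins over an I-DAG-stage deletion record:
  # re-assessment superseded the deletion
  if (nrow(dout) > 0 && nrow(out) > 0) {
    dout <- dout[!pair_key(dout$a, dout$b) %in% pair_key(out$tail, out$head), ,
                 drop = FALSE]
  }
  edge_index(records = out, deletions = dout)
}

#' Resolve a flagged direction conflict
#'
#' @param index an `edge_index` with a flagged pair.
#' @param a,b the unordered pair to resolve.
#' @param direction resolved direction: `c(tail, head)`, or
#'   `"bidirectional"`.
#' @param rationale reviewer justification, stored in the record notes.
#' @return the updated `edge_index`.
#' @export
resolve_index_conflict <- function(index, a, b, direction, rationale = "") {
  stopifnot(inherits(index, "edge_index"))
  i <- which(pair_key(index$records$tail, index$records$head) == pair_key(a, b))
  if (length(i) != 1 || !index$records$conflict[i]) {
    abort(sprintf("pair %s has no flagged conflict", pair_label(a, b)))
  }
  if (identical(direction, "bidirectional")) {
    index$records$bidirectional[i] <- TRUE
  } else {
    stopifnot(setequal(direction, c(a, b)))
    index$records$tail[i] <- direction[1]
    index$records$head[i] <- direction[2]
    index$records$bidirectional[i] <- FALSE
  }
  index$records$conflict[i] <- FALSE
  index$records$notes[i] <- paste0("conflict resolved: ", rationale)
  index
}

#' Record I-DAG-stage deletions in the index
#'
#' @param index an `edge_index`.
#' @param deletions tibble with columns `a`, `b` and optionally
#'   `provenance`, `notes` (e.g. the `deletions` element of a translated
#'   I-DAG).
#' @return the updated `edge_index`.
#' @export
record_deletions <- function(index, deletions) {
  stopifnot(inherits(index, "edge_index"))
  d <- as_tibble(deletions)
  if (nrow(d) == 0) return(index)
  if (!"provenance" %in% names(d)) {
    d$provenance <- rep(list("session@synthesis"), nrow(d))
  }
  if (!"notes" %in% names(d)) {
    d$notes <- if ("rationale" %in% names(d)) d$rationale else ""
  }
  merge_indices(index, edge_index(deletions = d[, c("a", "b", "provenance", "notes")]))
}

#' Synthesise an edge index into an integrated DAG
#'
#' Adds each indexed directed edge and its nodes to a blank DAG until the
#' index is exhausted; insertion order is immaterial, the I-DAG is the
#' edge-set union. With each node the index brings in, node pairs that no
#' study ever assessed become possible: these are returned as `pending`
#' and must be routed back through translation in the context of the
#' I-DAG. The accounting is exact: pending, indexed and deleted pairs
#' partition all unordered pairs of the I-DAG node set.
#'
#' @param index a conflict-free `edge_index`.
#' @param focal length-2 character vector `c(exposure, outcome)`; the
#'   focal nodes are added (and role-tagged) even if no record mentions
#'   them.
#' @return a list with `idag` (a `mixed_graph`, stage `integrated`) and
#'   `pending` (tibble of unordered pairs `a`, `b`).
#' @export
synthesise <- function(index, focal = NULL) {
  stopifnot(inherits(index, "edge_index"))
  if (nrow(index$records) == 0 && is.null(focal)) {
    abort("cannot synthesise an empty index without focal nodes")
  }
  if (any(index$records$conflict)) {
    bad <- index$records[index$records$conflict, ]
    abort(sprintf("unresolved direction conflict(s): %s; resolve before synthesis",
                  paste(pair_label(bad$tail, bad$head), collapse = ", ")))
  }
  ids <- sort(unique(c(index$records$tail, index$records$head, focal)))
  g <- mixed_graph(ids, stage = "implied")
  if (!is.null(focal)) {
    stopifnot(length(focal) == 2)
    g$nodes$roles[[match(focal[1], g$nodes$id)]] <- "exposure"
    g$nodes$roles[[match(focal[2], g$nodes$id)]] <- "outcome"
  }
  r <- index$records
  # index invariants already guarantee pair-uniqueness and valid
  # endpoints, so the edge table can be built in one shot; the final
  # validate_mixed_graph() still checks every graph invariant
  g$edges <- tibble(
    tail = r$tail, head = r$head,
    orientation = ifelse(r$bidirectional, "bidirectional", "directed"),
    status = rep("retained", nrow(r)),
    confidence = r$confidence,
    provenance = r$provenance)
  g$edges <- arrange(g$edges, .data$tail, .data$head)
  if (!is_acyclic(g)) {
    abort(sprintf("indexed edges form a directed cycle: %s",
                  cycle_message(find_cycles(g))))
  }
  g$deletions <- tibble(a = index$deletions$a, b = index$deletions$b,
                        provenance = index$deletions$provenance,
                        rationale = index$deletions$notes)
  g$stage <- "integrated"
  g <- validate_mixed_graph(g)
  list(idag = g, pending = pending_pairs(g))
}

#' Unordered node pairs neither indexed nor assessed-and-deleted
#'
#' @param idag an integrated `mixed_graph`.
#' @return tibble of pairs `a`, `b` (with `a < b`), each of which must be
#'   assessed through translation in the context of the I-DAG.
#' @export
pending_pairs <- function(idag) {
  stopifnot(inherits(idag, "mixed_graph"))
  ids <- sort(idag$nodes$id)
  if (length(ids) < 2) return(tibble(a = character(), b = character()))
  pairs <- utils::combn(ids, 2)
  all_p <- tibble(a = pairs[1, ], b = pairs[2, ])
  have <- c(pair_key(idag$edges$tail, idag$edges$head),
            pair_key(idag$deletions$a, idag$deletions$b))
  all_p[!pair_key(all_p$a, all_p$b) %in% have, , drop = FALSE]
}

#' Enter pending pairs as candidates for I-DAG-context translation
#'
#' @param idag an integrated `mixed_graph`.
#' @param pending tibble of pairs (defaults to [pending_pairs()]).
#' @return the graph with one unassigned candidate edge per pending pair.
#' @export
add_pending_candidates <- function(idag, pending = pending_pairs(idag)) {
  for (i in seq_len(nrow(pending))) {
    idag <- add_edge(idag, pending$a[i], pending$b[i],
                     orientation = "unassigned", status = "candidate")
  }
  idag
}

#' Resolve an I-DAG's pending pairs and update the index
#'
#' Convenience wrapper: enters the pending pairs as candidates, translates
#' them in the context of the I-DAG, then writes retained edges and
#' deletions back into the index.
#'
#' @param idag integrated `mixed_graph` from [synthesise()].
#' @param index the `edge_index` it was synthesised from.
#' @param assessments assessment tibble covering both directions of every
#'   pending pair.
#' @param study_id provenance token for the synthesis session.
#' @return list with updated `idag`, `index`, and the translation `log`.
#' @export
resolve_pending <- function(idag, index, assessments, study_id = "idag") {
  g <- add_pending_candidates(idag)
  tr <- translate_graph(g, assessments, study_id = study_id)
  new_dels <- tr$graph$deletions
  new_dels <- new_dels[!pair_key(new_dels$a, new_dels$b) %in%
                         pair_key(idag$deletions$a, idag$deletions$b), ,
                       drop = FALSE]
  idx <- index_edges(tr$graph, study_id)
  idx <- merge_indices(index, idx)
  if (nrow(new_dels) > 0) {
    idx <- record_deletions(idx, tibble(
      a = new_dels$a, b = new_dels$b, provenance = new_dels$provenance,
      notes = new_dels$rationale))
  }
  list(idag = tr$graph, index = idx, log = tr$log)
}

#' Add a reviewer-proposed node to an I-DAG
#'
#' Once the index is exhausted, variables the reviewers believe important
#' but that no reviewed study measured are added as new nodes; every pair
#' they form with existing nodes is returned as pending and assessed in
#' the context of the I-DAG rather than a fresh implied graph.
#'
#' @param idag an integrated `mixed_graph`.
#' @param id fresh node id.
#' @param label,measured,aliases as in [add_node()].
#' @return list with `idag` (node added, role `reviewer_added`) and
#'   `pending` (tibble of new pairs).
#' @export
add_reviewer_node <- function(idag, id, label = id, measured = TRUE,
                              aliases = character()) {
  stopifnot(inherits(idag, "mixed_graph"))
  existing <- idag$nodes$id
  idag <- add_node(idag, id, label = label, measured = measured,
                   aliases = aliases, roles = "reviewer_added")
  pending <- tibble(a = pmin(existing, id), b = pmax(existing, id))
  list(idag = idag, pending = arrange(pending, a, b))
}

# in/out neighbour sets over non-deleted edges; a bidirectional edge
# contributes to both sets of both endpoints
neighbour_sets <- function(graph, id) {
  e <- graph$edges
  dir_in <- e$tail[e$orientation == "directed" & e$head == id]
  dir_out <- e$head[e$orientation == "directed" & e$tail == id]
  bi <- c(e$head[e$orientation == "bidirectional" & e$tail == id],
          e$tail[e$orientation == "bidirectional" & e$head == id])
  list(inn = sort(unique(c(dir_in, bi))), out = sort(unique(c(dir_out, bi))))
}

#' Find node pairs that are candidates for recombination
#'
#' Two indications support merging nodes that different studies
#' conceptualised similarly: reviewer-flagged theoretical support (e.g.
#' both are categories of one concept), and identical directed-edge input
#' and output — they receive from and send to the same nodes. Pairs
#' connected by an edge are never candidates: merging a cause with its
#' effect would create a self-loop.
#'
#' @param idag an integrated (or implied) `mixed_graph`.
#' @param theory_pairs optional tibble (`a`, `b`) of reviewer-flagged
#'   pairs.
#' @return tibble with columns `a`, `b`, `evidence` (`identical_io`,
#'   `theory_flagged`, or both comma-joined).
#' @export
recombination_candidates <- function(idag, theory_pairs = NULL) {
  stopifnot(inherits(idag, "mixed_graph"))
  ids <- sort(idag$nodes$id)
  out <- tibble(a = character(), b = character(), evidence = character())
  if (length(ids) < 2) return(out)
  adjacent <- pair_key(idag$edges$tail, idag$edges$head)
  sets <- lapply(ids, function(i) neighbour_sets(idag, i))
  names(sets) <- ids
  pairs <- utils::combn(ids, 2)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (pair_key(a, b) %in% adjacent) next
    ev <- character()
    sa <- sets[[a]]; sb <- sets[[b]]
    if (setequal(setdiff(sa$inn, b), setdiff(sb$inn, a)) &&
        setequal(setdiff(sa$out, b), setdiff(sb$out, a))) {
      ev <- c(ev, "identical_io")
    }
    if (!is.null(theory_pairs) &&
        pair_key(a, b) %in% pair_key(theory_pairs$a, theory_pairs$b)) {
      ev <- c(ev, "theory_flagged")
    }
    if (length(ev) > 0) {
      out <- bind_rows(out, tibble(a = a, b = b,
                                   evidence = paste(ev, collapse = ",")))
    }
  }
  out
}

#' Recombine two equivalent nodes into one
#'
#' Merges a candidate pair into a single node: the merged node's edges are
#' the union of the pair's, aliases and provenance are unioned, and the
#' pair's ids become aliases of the merged node. Merged edge confidence
#' takes the worst case of the constituents. The merge must preserve
#' acyclicity, and requires a logged justification.
#'
#' @param idag an integrated (or implied) `mixed_graph`.
#' @param pair length-2 character vector of node ids.
#' @param merged_id fresh id for the merged node.
#' @param justification reviewer rationale (required).
#' @param merged_label human-readable name.
#' @param force merge a pair that is not a current candidate (logged).
#' @param theory_pairs passed to [recombination_candidates()].
#' @return list with `graph` and `log` (one recombination entry).
#' @export
recombine <- function(idag, pair, merged_id, justification,
                      merged_label = merged_id, force = FALSE,
                      theory_pairs = NULL) {
  stopifnot(inherits(idag, "mixed_graph"), length(pair) == 2)
  a <- pair[1]; b <- pair[2]
  if (!all(pair %in% idag$nodes$id)) abort("unknown node id in pair")
  check_token(merged_id)
  if (merged_id %in% setdiff(idag$nodes$id, pair)) {
    abort(sprintf("merged id already present: %s", merged_id))
  }
  if (missing(justification) || !nzchar(justification)) {
    abort("recombination requires a justification")
  }
  if (pair_key(a, b) %in% pair_key(idag$edges$tail, idag$edges$head)) {
    abort(sprintf("pair %s is connected by an edge and cannot be recombined",
                  pair_label(a, b)))
  }
  cands <- recombination_candidates(idag, theory_pairs = theory_pairs)
  is_cand <- pair_key(a, b) %in% pair_key(cands$a, cands$b)
  if (!is_cand && !force) {
    abort(sprintf("pair %s is not a recombination candidate (use force = TRUE with justification)",
                  pair_label(a, b)))
  }

  ia <- match(a, idag$nodes$id); ib <- match(b, idag$nodes$id)
  aliases <- sort(unique(c(idag$nodes$aliases[[ia]], idag$nodes$aliases[[ib]],
                           a, b)))
  roles <- sort(unique(c(idag$nodes$roles[[ia]], idag$nodes$roles[[ib]])))
  measured <- idag$nodes$measured[ia] && idag$nodes$measured[ib]

  e <- idag$edges
  e$tail[e$tail %in% pair] <- merged_id
  e$head[e$head %in% pair] <- merged_id
  # collapse duplicate pairs created by the merge
  out_e <- empty_edges()
  for (key in unique(pair_key(e$tail, e$head))) {
    grp <- e[pair_key(e$tail, e$head) == key, , drop = FALSE]
    if (nrow(grp) == 1) {
      out_e <- bind_rows(out_e, grp)
    } else {
      same_dir <- length(unique(paste(grp$tail, grp$head))) == 1
      orient <- unique(grp$orientation)
      if (length(orient) == 1 && orient == "directed" && !same_dir) {
        abort(sprintf("merge of %s would create a cycle through %s",
                      pair_label(a, b),
                      setdiff(c(grp$tail, grp$head), merged_id)[1]))
      }
      merged_or <- if (all(orient == "unassigned")) "unassigned"
                   else if (any(orient == "bidirectional") || !same_dir) "bidirectional"
                   else "directed"
      out_e <- bind_rows(out_e, tibble(
        tail = grp$tail[1], head = grp$head[1], orientation = merged_or,
        status = if (any(grp$status == "retained")) "retained" else "candidate",
        confidence = do.call(min_confidence, as.list(grp$confidence)),
        provenance = list(Reduce(merge_prov, grp$provenance))))
    }
  }

  g <- idag
  g$nodes <- g$nodes[-c(ia, ib), , drop = FALSE]
  g$nodes <- bind_rows(g$nodes, tibble(
    id = merged_id, label = merged_label, measured = measured,
    aliases = list(setdiff(aliases, merged_id)), roles = list(roles),
    notes = ""))
  g$edges <- out_e
  g$deletions$a[g$deletions$a %in% pair] <- merged_id
  g$deletions$b[g$deletions$b %in% pair] <- merged_id
  swap <- g$deletions$a > g$deletions$b
  tmp <- g$deletions$a[swap]
  g$deletions$a[swap] <- g$deletions$b[swap]
  g$deletions$b[swap] <- tmp
  g$deletions <- g$deletions[g$deletions$a != g$deletions$b, , drop = FALSE]
  if (!is_acyclic(g)) {
    abort(sprintf("merge of %s would create a cycle: %s", pair_label(a, b),
                  cycle_message(find_cycles(g))))
  }
  g <- validate_mixed_graph(g)
  entry <- log_append(decision_log(), log_entry(
    "recombination", pair_label(a, b),
    if (is_cand) "recombine" else "recombine (forced)",
    verdicts = merged_id, rationale = justification))
  list(graph = g, log = entry)
}
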