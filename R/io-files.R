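#' Read a study record from a key-value document
#'
#' One YAML document per study, validated against the schema shipped at
#' `system.file("extdata/schemas/study-schema.json", package = "dagsynth")`.
#'
#' @param path path to a study YAML file.
#' @return a [study_record()].
#' @export
read_study <- function(path) {
  doc <- yaml::read_yaml(path)
  validate_study_document(doc, source = path)
  mediators <- map(doc$mediators %||% list(), function(m) {
    unlist(c(m$tail %||% m[[1]], m$head %||% m[[2]]))
  })
  instruments <- character()
  if (!is.null(doc$instruments)) {
    instruments <- unlist(doc$instruments)
  }
  study_record(
    study_id = doc$study_id,
    citation = doc$citation %||% "",
    exposures = unlist(doc$exposures),
    outcomes = unlist(doc$outcomes),
    controls = unlist(doc$controls %||% character()),
    mediators = mediators,
    instruments = instruments
  )
}

#' Write a study record as a key-value document
#' @param record a [study_record()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_study <- function(record, path) {
  stopifnot(inherits(record, "study_record"))
  doc <- list(study_id = record$study_id, citation = record$citation,
              exposures = as.list(record$exposures),
              outcomes = as.list(record$outcomes))
  if (length(record$controls) > 0) doc$controls <- as.list(record$controls)
  if (length(record$mediators) > 0) {
    doc$mediators <- map(record$mediators,
                         function(m) list(tail = m[1], head = m[2]))
  }
  if (length(record$instruments) > 0) {
    doc$instruments <- as.list(record$instruments)
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

# lightweight structural validation against the shipped JSON schema:
# required keys, types, and no unknown top-level keys
validate_study_document <- function(doc, source = "study document") {
  schema_path <- system.file("extdata", "schemas", "study-schema.json",
                             package = "dagsynth")
  schema <- jsonlite::read_json(schema_path)
  props <- names(schema$properties)
  required <- unlist(schema$required)
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required field(s): %s", source,
                  paste(missing, collapse = ", ")))
  }
  unknown <- setdiff(names(doc), props)
  if (length(unknown) > 0) {
    abort(sprintf("%s: unknown field(s): %s", source,
                  paste(unknown, collapse = ", ")))
  }
  for (key in intersect(names(doc), props)) {
    type <- schema$properties[[key]]$type
    val <- doc[[key]]
    ok <- switch(type,
      string = is.character(val) && length(val) == 1,
      array = is.list(val) || is.character(val),
      object = is.list(val),
      TRUE)
    if (!ok) {
      abort(sprintf("%s: field '%s' must be of type %s", source, key, type))
    }
  }
  invisible(doc)
}

ASSESSMENT_COLS <- c("study_id", "tail", "head", "criterion", "verdict",
                     "rationale", "reference", "reviewer", "confidence",
                     "timestamp")

#' Read / write criteria assessments as CSV
#'
#' Tabular records with columns exactly: study_id, tail, head, criterion,
#' verdict, rationale, reference, reviewer, confidence, timestamp.
#'
#' @param path CSV path.
#' @return assessment tibble.
#' @export
read_assessments <- function(path) {
  a <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!identical(names(a), ASSESSMENT_COLS)) {
    abort(sprintf("assessment file must have columns exactly: %s",
                  paste(ASSESSMENT_COLS, collapse = ", ")))
  }
  for (col in c("rationale", "reference", "reviewer", "timestamp")) {
    a[[col]][is.na(a[[col]])] <- ""
  }
  bad <- !a$verdict %in% VERDICTS
  if (any(bad)) abort(sprintf("invalid verdict(s): %s",
                              paste(unique(a$verdict[bad]), collapse = ", ")))
  bad <- !a$criterion %in% CRITERIA
  if (any(bad)) abort(sprintf("invalid criterion(s): %s",
                              paste(unique(a$criterion[bad]), collapse = ", ")))
  a
}

#' @rdname read_assessments
#' @param assessments assessment tibble.
#' @export
write_assessments <- function(assessments, path) {
  a <- as_tibble(assessments)[, ASSESSMENT_COLS]
  readr::write_csv(a, path)
  invisible(path)
}

#' Read / write a directed edge index as CSV
#'
#' Records serialise with columns tail, head, bidirectional, confidence,
#' provenance (semicolon-joined study ids), notes; deletion records in a
#' parallel table with columns a, b, provenance, notes.
#'
#' @param records_path CSV path for retained-edge records.
#' @param deletions_path optional CSV path for deletion records.
#' @return an `edge_index`.
#' @export
read_edge_index <- function(records_path, deletions_path = NULL) {
  r <- readr::read_csv(records_path,
                       col_types = readr::cols(.default = readr::col_character()))
  recs <- tibble(
    tail = r$tail, head = r$head,
    bidirectional = tolower(r$bidirectional) %in% c("true", "1", "yes"),
    confidence = r$confidence,
    provenance = map(strsplit(r$provenance, ";", fixed = TRUE),
                     function(p) make_prov(trimws(p), "index")),
    notes = ifelse(is.na(r$notes), "", r$notes),
    conflict = FALSE)
  dels <- empty_index_deletions()
  if (!is.null(deletions_path) && file.exists(deletions_path)) {
    d <- readr::read_csv(deletions_path,
                         col_types = readr::cols(.default = readr::col_character()))
    dels <- tibble(
      a = d$a, b = d$b,
      provenance = map(strsplit(d$provenance, ";", fixed = TRUE),
                       function(p) make_prov(trimws(p), "index")),
      notes = ifelse(is.na(d$notes), "", d$notes))
  }
  edge_index(records = recs, deletions = dels)
}

#' @rdname read_edge_index
#' @param index an `edge_index`.
#' @export
write_edge_index <- function(index, records_path, deletions_path = NULL) {
  stopifnot(inherits(index, "edge_index"))
  r <- index$records
  readr::write_csv(tibble(
    tail = r$tail, head = r$head, bidirectional = r$bidirectional,
    confidence = r$confidence,
    provenance = map_chr(r$provenance,
                         function(p) paste(prov_studies(p), collapse = ";")),
    notes = r$notes), records_path)
  if (!is.null(deletions_path)) {
    d <- index$deletions
    readr::write_csv(tibble(
      a = d$a, b = d$b,
      provenance = map_chr(d$provenance,
                           function(p) paste(prov_studies(p), collapse = ";")),
      notes = d$notes), deletions_path)
  }
  invisible(records_path)
}

#' Append decision-log entries to a newline-delimited JSON file
#'
#' The session log is stored as one JSON object per line, an append-only
#' format that never rewrites earlier entries; [log_to_csv()] derives a
#' CSV export from it. Sequence numbers are renumbered to continue the
#' file's existing sequence, so logs from successive pipeline steps can
#' share one session file.
#'
#' @param log decision-log tibble.
#' @param path NDJSON path; created if absent, appended to otherwise.
#' @return `path`, invisibly.
#' @export
append_log_file <- function(log, path) {
  last <- 0L
  if (file.exists(path)) {
    existing <- readLines(path, encoding = "UTF-8")
    existing <- existing[nzchar(existing)]
    if (length(existing) > 0) {
      last <- as.integer(jsonlite::fromJSON(existing[length(existing)])$seq)
    }
  }
  log$seq <- last + seq_len(nrow(log))
  lines <- map_chr(seq_len(nrow(log)), function(i) {
    jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE)
  })
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a decision log from a newline-delimited JSON file
#' @param path NDJSON path.
#' @return decision-log tibble.
#' @export
read_log_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(decision_log())
  rows <- map(lines, function(l) as_tibble(jsonlite::fromJSON(l)))
  out <- bind_rows(rows)
  out$seq <- as.integer(out$seq)
  if (is.unsorted(out$seq, strictly = TRUE)) {
    abort("decision log is corrupt: sequence numbers are not strictly increasing")
  }
  out
}

#' Export a decision log as CSV
#' @param log decision-log tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
log_to_csv <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

#' Replay a session's resolutions onto its input graph
#'
#' Re-applies the `resolution` entries of a decision log to the graph
#' they were produced from, reconstructing the translated graph without
#' the assessment tables. Used to audit that a log fully determines the
#' session's output.
#'
#' @param ig the session's input `mixed_graph` (candidate edges intact).
#' @param log the session's decision log.
#' @return the reconstructed `mixed_graph`.
#' @export
replay_translation <- function(ig, log) {
  stopifnot(inherits(ig, "mixed_graph"))
  res <- log[log$action == "resolution", , drop = FALSE]
  g <- ig
  cand_idx <- which(g$edges$status == "candidate")
  cand <- g$edges[cand_idx, , drop = FALSE]
  keep <- g$edges[setdiff(seq_len(nrow(g$edges)), cand_idx), , drop = FALSE]
  g$edges <- keep
  for (i in seq_len(nrow(cand))) {
    subject <- pair_label(cand$tail[i], cand$head[i])
    j <- which(res$subject == subject)
    if (length(j) == 0) {
      abort(sprintf("log has no resolution for pair %s", subject))
    }
    action <- res$verdicts[j[length(j)]]
    tl <- cand$tail[i]; hd <- cand$head[i]
    # direction-specific confidence is not recorded in the resolution
    # row; replay reconstructs structure, carrying the edge's own flag
    conf <- cand$confidence[i]
    if (action == "delete") {
      g$deletions <- bind_rows(g$deletions, tibble(
        a = pmin(tl, hd), b = pmax(tl, hd),
        provenance = list(character()), rationale = "replayed"))
    } else if (action == "retain_posited") {
      g$edges <- bind_rows(g$edges, tibble(
        tail = tl, head = hd, orientation = "directed", status = "retained",
        confidence = conf, provenance = cand$provenance[i]))
    } else if (action == "reverse") {
      g$edges <- bind_rows(g$edges, tibble(
        tail = hd, head = tl, orientation = "directed", status = "retained",
        confidence = conf, provenance = cand$provenance[i]))
    } else if (action == "bidirectional") {
      g$edges <- bind_rows(g$edges, tibble(
        tail = tl, head = hd, orientation = "bidirectional",
        status = "retained", confidence = conf,
        provenance = cand$provenance[i]))
    } else {
      abort(sprintf("unknown resolution action '%s'", action))
    }
  }
  if (g$stage == "implied") g$stage <- "translated"
  validate_mixed_graph(g)
}

#' Serialise a mixed graph to JSON (full fidelity)
#'
#' The session file format used by the command-line interface: preserves
#' stage, roles, aliases, edge status and provenance, and recorded
#' deletions.
#'
#' @param g a `mixed_graph`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(g, path) {
  stopifnot(inherits(g, "mixed_graph"))
  doc <- list(
    stage = g$stage,
    nodes = map(seq_len(nrow(g$nodes)), function(i) list(
      id = g$nodes$id[i], label = g$nodes$label[i],
      measured = g$nodes$measured[i],
      aliases = as.list(g$nodes$aliases[[i]]),
      roles = as.list(g$nodes$roles[[i]]),
      notes = g$nodes$notes[i])),
    edges = map(seq_len(nrow(g$edges)), function(i) list(
      tail = g$edges$tail[i], head = g$edges$head[i],
      orientation = g$edges$orientation[i], status = g$edges$status[i],
      confidence = g$edges$confidence[i],
      provenance = as.list(g$edges$provenance[[i]]))),
    deletions = map(seq_len(nrow(g$deletions)), function(i) list(
      a = g$deletions$a[i], b = g$deletions$b[i],
      provenance = as.list(g$deletions$provenance[[i]]),
      rationale = g$deletions$rationale[i])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path)
  nodes <- tibble(
    id = map_chr(doc$nodes, "id"),
    label = map_chr(doc$nodes, "label"),
    measured = map_lgl(doc$nodes, "measured"),
    aliases = map(doc$nodes, function(n) as.character(unlist(n$aliases))),
    roles = map(doc$nodes, function(n) as.character(unlist(n$roles))),
    notes = map_chr(doc$nodes, "notes"))
  g <- mixed_graph(nodes, stage = "implied")
  for (e in doc$edges) {
    g <- add_edge(g, e$tail, e$head, orientation = e$orientation,
                  status = e$status, confidence = e$confidence,
                  provenance = as.character(unlist(e$provenance)))
  }
  g$deletions <- bind_rows(empty_deletions(), bind_rows(map(doc$deletions,
    function(d) tibble(a = d$a, b = d$b,
                       provenance = list(as.character(unlist(d$provenance))),
                       rationale = d$rationale %||% ""))))
  set_stage(g, doc$stage)
}
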