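CRITERIA <- c("temporality", "face_validity", "recourse_to_theory",
              "counterfactual")
VERDICTS <- c("yes", "no", "unknown")
OUTCOMES <- c("retained", "failed_temporality", "failed_face_validity",
              "failed_counterfactual")
RESOLUTIONS <- c("retain_posited", "reverse", "bidirectional", "delete")

#' Record one criterion verdict for one edge direction
#'
#' Translation assesses each candidate edge, in both directions, under
#' sequential causal criteria: temporality (can the posited cause precede
#' the effect?), face validity (is the relationship plausible given the
#' temporal ordering?), recourse to theory (is there formal theoretical
#' support? — never terminal, since absence of theory does not equate to
#' absence of effect), and finally a counterfactual thought experiment
#' contrasting potential outcomes under the counterfactual exposures. The
#' verdicts themselves are reviewer judgements; the package records and
#' resolves them, it does not make them.
#'
#' @param study_id study (or session) the verdict belongs to.
#' @param tail,head the direction being assessed (tail causes head).
#' @param criterion one of `"temporality"`, `"face_validity"`,
#'   `"recourse_to_theory"`, `"counterfactual"`.
#' @param verdict `"yes"`, `"no"`, or `"unknown"` (`unknown` is permitted
#'   only for recourse to theory and for temporality, where it marks
#'   contemporaneous measurement and downgrades confidence).
#' @param rationale,reference free text; `reference` is the theory
#'   citation slot.
#' @param reviewer token identifying the assessor.
#' @param confidence `"normal"` or `"low"`.
#' @param timestamp character timestamp (stored verbatim).
#' @return a one-row assessment tibble.
#' @export
assessment <- function(study_id, tail, head, criterion, verdict,
                       rationale = "", reference = "", reviewer = "",
                       confidence = "normal", timestamp = "") {
  criterion <- match_arg1(criterion, CRITERIA, "criterion")
  verdict <- match_arg1(verdict, VERDICTS, "verdict")
  confidence <- match_arg1(confidence, CONFIDENCES, "confidence")
  if (verdict == "unknown" &&
      !criterion %in% c("recourse_to_theory", "temporality")) {
    abort(sprintf("verdict 'unknown' is not permitted for %s", criterion))
  }
  tibble(study_id = study_id, tail = tail, head = head,
         criterion = criterion, verdict = verdict, rationale = rationale,
         reference = reference, reviewer = reviewer,
         confidence = confidence, timestamp = timestamp)
}

#' Resolve the verdicts for a single edge direction
#'
#' Applies the sequential logic: a `no` on temporality or face validity
#' stops the assessment and fails the direction; recourse to theory never
#' terminates; the direction is retained only when the counterfactual
#' verdict is `yes`. A temporality verdict of `unknown` (contemporaneous
#' measurement) passes but forces low confidence, since deleting on
#' ambiguity would be a stronger claim than keeping the edge.
#'
#' @param assessments assessment tibble rows for exactly one direction,
#'   covering the criteria in order (later criteria may be absent after an
#'   early failure).
#' @return a one-row tibble with columns `tail`, `head`, `outcome`
#'   (`retained`, `failed_temporality`, `failed_face_validity` or
#'   `failed_counterfactual`) and `confidence`.
#' @export
assess_direction <- function(assessments) {
  a <- as_tibble(assessments)
  if (nrow(a) == 0) abort("no assessments supplied")
  if (length(unique(a$tail)) != 1 || length(unique(a$head)) != 1) {
    abort("assessments must cover exactly one direction")
  }
  tail <- a$tail[1]; head <- a$head[1]
  if (anyDuplicated(a$criterion)) {
    abort(sprintf("duplicate criterion for direction %s -> %s", tail, head))
  }
  ord <- match(a$criterion, CRITERIA)
  if (any(is.na(ord))) abort("unknown criterion")
  if (is.unsorted(ord, strictly = TRUE)) {
    abort(sprintf("out-of-order assessments for direction %s -> %s", tail, head))
  }
  low <- any(a$confidence == "low")
  verdict_of <- function(criterion) {
    i <- which(a$criterion == criterion)
    if (length(i) == 0) NA_character_ else a$verdict[i]
  }
  need <- function(criterion) {
    v <- verdict_of(criterion)
    if (is.na(v)) {
      abort(sprintf("missing required criterion '%s' for direction %s -> %s",
                    criterion, tail, head))
    }
    v
  }
  result <- function(outcome, extra_low = FALSE) {
    tibble(tail = tail, head = head, outcome = outcome,
           confidence = if (low || extra_low) "low" else "normal")
  }
  temp <- need("temporality")
  if (temp == "no") {
    if (nrow(a) > 1) {
      abort(sprintf("assessments after failed temporality for %s -> %s", tail, head))
    }
    return(result("failed_temporality"))
  }
  low <- low || temp == "unknown"
  fv <- need("face_validity")
  if (fv == "no") {
    if (nrow(a) > 2) {
      abort(sprintf("assessments after failed face validity for %s -> %s", tail, head))
    }
    return(result("failed_face_validity"))
  }
  need("recourse_to_theory")  # any verdict proceeds
  cf <- need("counterfactual")
  if (cf == "yes") result("retained") else result("failed_counterfactual")
}

#' Combine the two directional results for one edge
#'
#' Both the posited direction and its reverse are always assessed; an edge
#' may be retained as posited, reversed, kept as bidirectional (both
#' directions survive), or deleted (neither survives).
#'
#' @param posited,reverse one-row results from [assess_direction()], for a
#'   direction and its reverse.
#' @return one of `"retain_posited"`, `"reverse"`, `"bidirectional"`,
#'   `"delete"`.
#' @export
resolve_edge <- function(posited, reverse) {
  for (r in list(posited, reverse)) {
    if (!is.data.frame(r) || nrow(r) != 1 || !all(c("outcome") %in% names(r))) {
      abort("both direction results are required")
    }
  }
  if (!is.na(posited$tail[1]) && !is.na(reverse$tail[1]) &&
      !(posited$tail[1] == reverse$head[1] && posited$head[1] == reverse$tail[1])) {
    abort("reverse result must assess the reversed direction")
  }
  p <- posited$outcome == "retained"
  r <- reverse$outcome == "retained"
  if (p && r) "bidirectional"
  else if (p) "retain_posited"
  else if (r) "reverse"
  else "delete"
}

# assemble per-criterion decision-log entries for one direction, including
# explicit "not assessed" markers for criteria skipped after an early stop
direction_log_entries <- function(a, res, stage) {
  subject <- paste(a$tail[1], "->", a$head[1])
  out <- tibble(seq = NA_integer_, stage = stage, subject = subject,
                action = paste0("criterion:", a$criterion),
                verdicts = a$verdict, rationale = a$rationale,
                reference = a$reference, reviewer = a$reviewer,
                timestamp = a$timestamp)
  skipped <- setdiff(CRITERIA, a$criterion)
  if (res$outcome != "retained" && length(skipped) > 0) {
    out <- bind_rows(out, tibble(
      seq = NA_integer_, stage = stage, subject = subject,
      action = paste0("criterion:", skipped),
      verdicts = "not assessed - earlier criterion failed",
      rationale = "", reference = "",
      reviewer = a$reviewer[nrow(a)], timestamp = a$timestamp[nrow(a)]))
  }
  out
}

#' Translate a graph: resolve every candidate edge through the criteria
#'
#' Works through each candidate edge of an implied (or integrated) graph:
#' both directions are resolved with [assess_direction()], combined with
#' [resolve_edge()], and the graph is mutated accordingly — deleted edges
#' are removed (and recorded as deletions), reversed edges flipped,
#' surviving edges marked retained. The result must be acyclic: if the
#' reviewer's independently resolved edges jointly form a directed cycle,
#' the cycle is reported as an error and nothing is auto-deleted. Every
#' verdict and every resolution produces a decision-log entry.
#'
#' @param ig a `mixed_graph` with candidate edges (stage `implied`, or
#'   `integrated` when resolving newly possible pairs on an I-DAG).
#' @param assessments assessment tibble covering both directions of every
#'   candidate edge.
#' @param study_id provenance token; defaults to the assessments' study id.
#' @return a list with elements `graph` (stage `translated`, or unchanged
#'   `integrated`) and `log` (decision-log tibble).
#' @examples
#' ig <- map_study(study_record("s1", exposures = "x", outcomes = "y"))
#' al <- bind_directions(
#'   direction_assessments("s1", "x", "y", c("yes", "yes", "yes", "yes")),
#'   direction_assessments("s1", "y", "x", "no"))
#' translate_graph(ig, al)$graph
#' @export
translate_graph <- function(ig, assessments, study_id = NULL) {
  stopifnot(inherits(ig, "mixed_graph"))
  a <- as_tibble(assessments)
  if (is.null(study_id)) {
    study_id <- if (nrow(a) > 0) a$study_id[1] else "session"
  }
  cand <- ig$edges[ig$edges$status == "candidate", , drop = FALSE]
  kept <- ig$edges[ig$edges$status != "candidate", , drop = FALSE]
  log <- decision_log()
  stage_tag <- if (ig$stage == "integrated") "synthesis" else "translation"
  out <- ig
  out$edges <- kept
  akey <- if (nrow(a) > 0) paste(a$tail, a$head) else character()

  for (i in seq_len(nrow(cand))) {
    tl <- cand$tail[i]; hd <- cand$head[i]
    ap <- a[akey == paste(tl, hd), , drop = FALSE]
    ar <- a[akey == paste(hd, tl), , drop = FALSE]
    if (nrow(ap) == 0 || nrow(ar) == 0) {
      abort(sprintf("unresolved candidate edge %s: both directions must be assessed",
                    pair_label(tl, hd)))
    }
    rp <- assess_direction(ap)
    rr <- assess_direction(ar)
    res <- resolve_edge(rp, rr)
    log <- log_append(log, direction_log_entries(ap, rp, stage_tag))
    log <- log_append(log, direction_log_entries(ar, rr, stage_tag))
    prov <- merge_prov(cand$provenance[[i]], make_prov(study_id, stage_tag))
    ts <- max(c(ap$timestamp, ar$timestamp))
    reviewer <- ap$reviewer[1]
    if (res == "delete") {
      out$deletions <- bind_rows(out$deletions,
        tibble(a = pmin(tl, hd), b = pmax(tl, hd), provenance = list(prov),
               rationale = sprintf("%s / %s", rp$outcome, rr$outcome)))
    } else {
      edge <- switch(res,
        retain_posited = tibble(tail = tl, head = hd, orientation = "directed",
                                confidence = rp$confidence),
        reverse = tibble(tail = hd, head = tl, orientation = "directed",
                         confidence = rr$confidence),
        bidirectional = tibble(tail = tl, head = hd,
                               orientation = "bidirectional",
                               confidence = min_confidence(rp$confidence,
                                                           rr$confidence)))
      edge$status <- "retained"
      edge$provenance <- list(prov)
      out$edges <- bind_rows(out$edges, edge)
    }
    log <- log_append(log, log_entry(
      stage_tag, pair_label(tl, hd), "resolution", res,
      rationale = sprintf("posited %s -> %s: %s; reverse: %s",
                          tl, hd, rp$outcome, rr$outcome),
      reviewer = reviewer, timestamp = ts))
  }

  if (!is_acyclic(out)) {
    abort(sprintf("resolved edges induce a directed cycle: %s",
                  cycle_message(find_cycles(out))))
  }
  if (out$stage == "implied") out$stage <- "translated"
  out <- validate_mixed_graph(out)
  isolated <- setdiff(out$nodes$id, c(out$edges$tail, out$edges$head))
  if (length(isolated) > 0 && nrow(out$nodes) > 1) {
    warn(sprintf(
      "isolated node(s) after translation: %s (a DAG node should influence at least two others or be removed)",
      paste(isolated, collapse = ", ")))
  }
  list(graph = out, log = log)
}

#' Build a full assessment set for one direction in one call
#'
#' Convenience constructor: supplies verdicts for the criteria in order,
#' stopping where the sequential logic stops.
#'
#' @param study_id,tail,head as in [assessment()].
#' @param verdicts character vector of verdicts in criterion order; supply
#'   only as many as were assessed (e.g. a single `"no"` for a temporality
#'   failure).
#' @param rationale,reference,reviewer,confidence,timestamp recycled over
#'   the criteria.
#' @return an assessment tibble.
#' @export
direction_assessments <- function(study_id, tail, head, verdicts,
                                  rationale = "", reference = "",
                                  reviewer = "reviewer", confidence = "normal",
                                  timestamp = "") {
  if (length(verdicts) > length(CRITERIA)) abort("too many verdicts")
  bind_rows(purrr::map2(CRITERIA[seq_along(verdicts)], verdicts,
    function(cr, v) assessment(study_id, tail, head, cr, v,
                               rationale = rationale, reference = reference,
                               reviewer = reviewer, confidence = confidence,
                               timestamp = timestamp)))
}

#' Combine direction assessment tibbles
#' @param ... assessment tibbles.
#' @return a single assessment tibble.
#' @export
bind_directions <- function(...) bind_rows(...)
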