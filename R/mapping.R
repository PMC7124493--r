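#' Describe one reviewed study
#'
#' A study record captures the causal structure a reviewed study concluded
#' (accurately or otherwise): its exposure(s) and outcome(s), the
#' variables it controlled for, and any mediator or instrumental-variable
#' structure its authors asserted. The record is the input to [map_study()].
#'
#' @param study_id token identifying the study.
#' @param exposures,outcomes non-empty, disjoint character vectors of node
#'   ids.
#' @param controls character vector of node ids, disjoint from exposures
#'   and outcomes.
#' @param mediators list of length-2 character vectors `c(tail, head)`
#'   giving mediating path segments as concluded by the study.
#' @param instruments named character vector: names are instrument node
#'   ids, values the target exposure each instruments.
#' @param citation free-text citation.
#' @return a `study_record` object.
#' @examples
#' study_record("hypothetical",
#'   exposures = "parental_alc_hist", outcomes = "adol_alc",
#'   controls = c("adol_sex", "adol_substance"))
#' @export
study_record <- function(study_id, exposures, outcomes,
                         controls = character(), mediators = list(),
                         instruments = character(), citation = "") {
  check_token(study_id, "study id")
  check_token(exposures)
  check_token(outcomes)
  if (length(controls) > 0) check_token(controls)
  if (length(exposures) == 0 || length(outcomes) == 0) {
    abort("exposures and outcomes must be non-empty")
  }
  if (length(intersect(exposures, outcomes)) > 0) {
    abort("exposures and outcomes must be disjoint")
  }
  if (length(intersect(controls, c(exposures, outcomes))) > 0) {
    abort("controls must be disjoint from exposures and outcomes")
  }
  if (length(mediators) > 0) {
    ok <- vapply(mediators, function(m) is.character(m) && length(m) == 2,
                 logical(1))
    if (!all(ok)) abort("each mediator entry must be c(tail, head)")
  }
  if (length(instruments) > 0) {
    if (is.null(names(instruments)) || any(names(instruments) == "")) {
      abort("instruments must be a named vector: instrument id -> target exposure")
    }
    if (!all(instruments %in% exposures)) {
      abort("each instrument must target a declared exposure")
    }
  }
  structure(
    list(study_id = study_id, citation = citation,
         exposures = exposures, outcomes = outcomes, controls = controls,
         mediators = mediators, instruments = instruments),
    class = "study_record"
  )
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record> %s\n  exposures: %s\n  outcomes:  %s\n  controls:  %s\n",
              x$study_id,
              paste(x$exposures, collapse = ", "),
              paste(x$outcomes, collapse = ", "),
              if (length(x$controls)) paste(x$controls, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Map a study record into its saturated implied graph
#'
#' Builds the study's implied graph (IG): a directed candidate edge from
#' each exposure to each outcome; each control entered as a mutual cause
#' of exposure and outcome — a confounder, the simplest structure that
#' opens a backdoor path and hence justifies controlling for it; mediator
#' and instrument edges as the study concluded them; then saturation, so
#' that every remaining node pair (notably control-control pairs) carries
#' an unassigned candidate edge whose direction is decided at translation.
#'
#' @param record a [study_record()].
#' @return a `mixed_graph` at stage `"implied"`, saturated.
#' @examples
#' rec <- study_record("hypothetical",
#'   exposures = "parental_alc_hist", outcomes = "adol_alc",
#'   controls = c("adol_sex", "adol_substance"))
#' ig <- map_study(rec)
#' glance(ig)
#' @export
map_study <- function(record) {
  stopifnot(inherits(record, "study_record"))
  instr_ids <- names(record$instruments)
  med_nodes <- unique(unlist(record$mediators))
  ids <- unique(c(record$exposures, record$outcomes, record$controls,
                  instr_ids, med_nodes))
  g <- mixed_graph(stage = "implied")
  for (id in ids) {
    roles <- character()
    if (id %in% record$exposures) roles <- c(roles, "exposure")
    if (id %in% record$outcomes) roles <- c(roles, "outcome")
    if (id %in% record$controls) roles <- c(roles, "control")
    if (id %in% instr_ids) roles <- c(roles, "instrument")
    if (id %in% med_nodes && length(roles) == 0) roles <- "mediator"
    g <- add_node(g, id, roles = roles)
  }
  prov <- make_prov(record$study_id, "mapping")
  put <- function(g, tail, head) {
    # the study may assert the same segment twice (e.g. exposure->outcome
    # also listed as a mediator path end); keep the first
    key <- pair_key(tail, head)
    if (key %in% pair_key(g$edges$tail, g$edges$head)) return(g)
    add_edge(g, tail, head, orientation = "directed", status = "candidate",
             provenance = prov)
  }
  for (x in record$exposures) for (y in record$outcomes) g <- put(g, x, y)
  for (cv in record$controls) {
    for (x in record$exposures) g <- put(g, cv, x)
    for (y in record$outcomes) g <- put(g, cv, y)
  }
  for (m in record$mediators) g <- put(g, m[1], m[2])
  for (iv in instr_ids) g <- put(g, iv, record$instruments[[iv]])
  saturate(g)
}
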