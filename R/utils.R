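# internal helpers shared across stages

ORIENTATIONS <- c("directed", "unassigned", "bidirectional")
STATUSES <- c("candidate", "retained", "deleted")
CONFIDENCES <- c("normal", "low")
STAGES <- c("implied", "translated", "integrated")
NODE_ROLES <- c("exposure", "outcome", "control", "mediator", "instrument",
                "reviewer_added")

# canonical key for an unordered node pair
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

pair_label <- function(a, b) {
  paste0("{", pmin(a, b), ", ", pmax(a, b), "}")
}

# provenance entries are "study_id@stage" tokens; sets are character vectors
make_prov <- function(study_id, stage) {
  paste0(study_id, "@", stage)
}

prov_studies <- function(prov) {
  sort(unique(sub("@.*$", "", prov)))
}

merge_prov <- function(a, b) {
  sort(unique(c(a, b)))
}

# worst-case merge of confidence flags
min_confidence <- function(...) {
  flags <- c(...)
  if (any(flags == "low")) "low" else "normal"
}

check_token <- function(id, what = "node id") {
  ok <- is.character(id) & nchar(id) > 0 & !grepl("\\s", id) & id == tolower(id)
  if (!all(ok)) {
    abort(sprintf("invalid %s: '%s' (must be non-empty, lowercase, no whitespace)",
                  what, paste(id[!ok], collapse = "', '")))
  }
  invisible(id)
}

match_arg1 <- function(x, choices, what) {
  if (!is.character(x) || length(x) != 1 || !x %in% choices) {
    abort(sprintf("%s must be one of: %s", what, paste(choices, collapse = ", ")))
  }
  x
}
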