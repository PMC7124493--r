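#' Create an empty decision log
#'
#' Every graph mutation in a review session is recorded in an append-only
#' decision log — the audit trail that makes the workflow transparent and
#' replayable. Entries carry a strictly increasing sequence number.
#'
#' @return a zero-row decision-log tibble.
#' @export
decision_log <- function() {
  tibble(seq = integer(), stage = character(), subject = character(),
         action = character(), verdicts = character(),
         rationale = character(), reference = character(),
         reviewer = character(), timestamp = character())
}

log_entry <- function(stage, subject, action, verdicts = "",
                      rationale = "", reference = "", reviewer = "",
                      timestamp = "") {
  tibble(seq = NA_integer_, stage = stage, subject = subject,
         action = action, verdicts = verdicts,
         rationale = rationale %||% "", reference = reference %||% "",
         reviewer = reviewer %||% "", timestamp = timestamp %||% "")
}

#' Append entries to a decision log
#'
#' @param log an existing decision-log tibble (see [decision_log()]).
#' @param entries tibble of new entries; sequence numbers are assigned.
#' @return the extended log.
#' @export
log_append <- function(log, entries) {
  if (nrow(entries) == 0) return(log)
  start <- if (nrow(log) == 0) 0L else max(log$seq)
  entries$seq <- start + seq_len(nrow(entries))
  bind_rows(log, entries)
}
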