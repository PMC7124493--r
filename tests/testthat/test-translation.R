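test_that("sequential criteria stop where the protocol stops", {
  # temporality failure ends the assessment
  r <- assess_direction(direction_assessments(
    "s", "adol_substance", "parental_alc_hist", "no"))
  expect_equal(r$outcome, "failed_temporality")

  # face-validity failure after temporal ordering holds
  r <- assess_direction(direction_assessments(
    "s", "parental_alc_hist", "adol_sex", c("yes", "no")))
  expect_equal(r$outcome, "failed_face_validity")

  # absence of theory is never terminal
  r <- assess_direction(direction_assessments(
    "s", "adol_sex", "adol_alc", c("yes", "yes", "unknown", "yes")))
  expect_equal(r$outcome, "retained")
  expect_equal(r$confidence, "normal")

  r <- assess_direction(direction_assessments(
    "s", "a", "b", c("yes", "yes", "no", "no")))
  expect_equal(r$outcome, "failed_counterfactual")
})

test_that("ambiguous temporality passes with low confidence", {
  r <- assess_direction(direction_assessments(
    "s", "a", "b", c("unknown", "yes", "yes", "yes")))
  expect_equal(r$outcome, "retained")
  expect_equal(r$confidence, "low")
})

test_that("malformed assessment sets are rejected", {
  a <- direction_assessments("s", "a", "b", c("yes", "yes"))
  expect_error(assess_direction(a), "missing required criterion")
  a2 <- a[2:1, ]
  expect_error(assess_direction(a2), "out-of-order")
  expect_error(assessment("s", "a", "b", "face_validity", "unknown"),
               "not permitted")
  expect_error(assess_direction(direction_assessments("s", "a", "b",
                                                      c("no", "yes"))),
               "after failed temporality")
})

test_that("edge resolution matches the retain/reverse/bidirectional/delete rules", {
  mk <- function(outcome, tail = "a", head = "b") {
    tibble::tibble(tail = tail, head = head, outcome = outcome,
                   confidence = "normal")
  }
  fails <- c("failed_temporality", "failed_face_validity",
             "failed_counterfactual")
  # all 16 combinations of the four direction outcomes
  for (p in c("retained", fails)) {
    for (r in c("retained", fails)) {
      got <- resolve_edge(mk(p), mk(r, "b", "a"))
      want <- if (p == "retained" && r == "retained") "bidirectional"
        else if (p == "retained") "retain_posited"
        else if (r == "retained") "reverse"
        else "delete"
      expect_equal(got, want)
    }
  }
})

test_that("resolution is symmetric under swapping posited and reverse", {
  mk <- function(outcome, tail, head) {
    tibble::tibble(tail = tail, head = head, outcome = outcome,
                   confidence = "normal")
  }
  swap <- c(retain_posited = "reverse", reverse = "retain_posited",
            bidirectional = "bidirectional", delete = "delete")
  for (p in c("retained", "failed_counterfactual")) {
    for (r in c("retained", "failed_temporality")) {
      ab <- resolve_edge(mk(p, "a", "b"), mk(r, "b", "a"))
      ba <- resolve_edge(mk(r, "b", "a"), mk(p, "a", "b"))
      expect_equal(unname(swap[ab]), ba)
    }
  }
})

test_that("translating the worked example retains and deletes the stated edges", {
  ex <- alcohol_example()
  ig <- map_study(ex$studies$hypothetical)
  tr <- translate_graph(ig, ex$assessments$hypothetical)
  dag <- tr$graph
  expect_equal(graph_stage(dag), "translated")
  expect_true(is_acyclic(dag))
  got <- sort(paste(dag$edges$tail, dag$edges$head))
  expect_equal(got, sort(c(
    "parental_alc_hist adol_alc", "adol_sex adol_alc",
    "adol_sex adol_substance", "parental_alc_hist adol_substance",
    "adol_substance adol_alc")))
  # the sex-exposure pair is deleted: sex is a risk factor, not a confounder
  expect_equal(nrow(dag$deletions), 1)
  expect_setequal(c(dag$deletions$a, dag$deletions$b),
                  c("adol_sex", "parental_alc_hist"))
})

test_that("translation demands complete assessment and reports cycles", {
  ig <- map_study(study_record("s", exposures = "x", outcomes = "y",
                               controls = "c1"))
  a <- bind_directions(
    direction_assessments("s", "x", "y", c("yes", "yes", "yes", "yes")),
    direction_assessments("s", "y", "x", "no"))
  expect_error(translate_graph(ig, a), "unresolved candidate")

  # a graph with no candidates translates vacuously with an empty log
  g <- mixed_graph(c("x", "y"))
  g <- add_edge(g, "x", "y", status = "retained")
  tr <- translate_graph(g, direction_assessments("s", "x", "y", "no")[0, ])
  expect_equal(nrow(tr$log), 0)

  # independently retained edges that close a cycle are an error, with
  # the cycle named
  ig3 <- saturate(mixed_graph(c("a", "b", "c")))
  yes <- c("yes", "yes", "yes", "yes")
  a3 <- bind_directions(
    direction_assessments("s", "a", "b", yes),
    direction_assessments("s", "b", "a", "no"),
    direction_assessments("s", "b", "c", yes),
    direction_assessments("s", "c", "b", "no"),
    direction_assessments("s", "c", "a", yes),
    direction_assessments("s", "a", "c", "no"))
  expect_error(translate_graph(ig3, a3), "cycle")
})

test_that("every resolution leaves a complete audit trail that replays", {
  ex <- alcohol_example()
  ig <- map_study(ex$studies$hypothetical)
  tr <- translate_graph(ig, ex$assessments$hypothetical)
  # one resolution entry per pair, criterion entries for all four criteria
  res_entries <- tr$log[tr$log$action == "resolution", ]
  expect_equal(nrow(res_entries), 6)
  per_pair <- table(tr$log$subject[grepl("^criterion:", tr$log$action)])
  expect_true(all(per_pair >= 1))
  skipped <- tr$log$verdicts == "not assessed - earlier criterion failed"
  expect_true(any(skipped))
  expect_true(!is.unsorted(tr$log$seq, strictly = TRUE))

  replayed <- replay_translation(ig, tr$log)
  expect_equal(graph_signature(replayed), graph_signature(tr$graph))
})

test_that("bidirectional resolutions carry worst-case confidence", {
  ig <- map_study(study_record("s", exposures = "x", outcomes = "y"))
  a <- bind_directions(
    direction_assessments("s", "x", "y", c("unknown", "yes", "yes", "yes")),
    direction_assessments("s", "y", "x", c("yes", "yes", "yes", "yes")))
  tr <- translate_graph(ig, a)
  expect_equal(tr$graph$edges$orientation, "bidirectional")
  expect_equal(tr$graph$edges$confidence, "low")
})

test_that("translation warns when a node ends up influencing nothing", {
  ig <- map_study(study_record("s", exposures = "x", outcomes = "y",
                               controls = "c1"))
  del <- function(tl, hd) bind_directions(
    direction_assessments("s", tl, hd, c("yes", "no")),
    direction_assessments("s", hd, tl, c("yes", "no")))
  a <- bind_directions(
    direction_assessments("s", "x", "y", c("yes", "yes", "yes", "yes")),
    direction_assessments("s", "y", "x", "no"),
    del("c1", "x"), del("c1", "y"))
  expect_warning(translate_graph(ig, a), "isolated")
})
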