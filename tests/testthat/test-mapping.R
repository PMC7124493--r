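hyp_record <- function() {
  study_record("hypothetical",
               exposures = "parental_alc_hist", outcomes = "adol_alc",
               controls = c("adol_sex", "adol_substance"))
}

test_that("study records validate their structural invariants", {
  expect_error(study_record("s", exposures = "x", outcomes = "x"), "disjoint")
  expect_error(study_record("s", exposures = "x", outcomes = "y",
                            controls = "x"), "disjoint")
  expect_error(study_record("s", exposures = character(), outcomes = "y"))
  expect_error(study_record("s", exposures = "x", outcomes = "y",
                            instruments = c(z = "q")), "declared exposure")
})

test_that("mapping the worked example gives the expected implied graph", {
  ig <- map_study(hyp_record())
  expect_equal(graph_stage(ig), "implied")
  expect_equal(nrow(ig$nodes), 4)
  expect_equal(nrow(ig$edges), 6)  # C(4,2) after saturation

  directed <- ig$edges[ig$edges$orientation == "directed", ]
  got <- sort(paste(directed$tail, directed$head))
  expect_equal(got, sort(c(
    "parental_alc_hist adol_alc",
    "adol_sex parental_alc_hist", "adol_sex adol_alc",
    "adol_substance parental_alc_hist", "adol_substance adol_alc")))

  una <- ig$edges[ig$edges$orientation == "unassigned", ]
  expect_equal(nrow(una), 1)
  expect_setequal(c(una$tail, una$head), c("adol_sex", "adol_substance"))
  expect_true(all(ig$edges$status == "candidate"))
})

test_that("role lookup reflects the record", {
  ig <- map_study(hyp_record())
  expect_equal(roles_of(ig, "adol_sex"), "control")
  expect_equal(roles_of(ig, "parental_alc_hist"), "exposure")
  expect_equal(roles_of(ig, "adol_alc"), "outcome")
  expect_error(roles_of(ig, "nope"), "unknown node")
})

test_that("directed-edge count is 1 + 2k for a k-control single-pair study", {
  for (k in 0:4) {
    controls <- if (k > 0) sprintf("c%d", seq_len(k)) else character()
    rec <- study_record("s", exposures = "x", outcomes = "y",
                        controls = controls)
    ig <- map_study(rec)
    expect_equal(sum(ig$edges$orientation == "directed"), 1 + 2 * k)
    expect_equal(nrow(ig$edges), choose(k + 2, 2))
  }
})

test_that("a minimal study maps to a single directed edge", {
  ig <- map_study(study_record("s", exposures = "x", outcomes = "y"))
  expect_equal(nrow(ig$edges), 1)
  expect_equal(ig$edges$orientation, "directed")
  expect_equal(c(ig$edges$tail, ig$edges$head), c("x", "y"))
})

test_that("mediators and instruments are mapped as the study concluded", {
  rec <- study_record("s", exposures = "x", outcomes = "y",
                      controls = "c1",
                      mediators = list(c("x", "m"), c("m", "y")),
                      instruments = c(iv = "x"))
  ig <- map_study(rec)
  d <- ig$edges[ig$edges$orientation == "directed", ]
  pairs <- paste(d$tail, d$head)
  expect_true(all(c("x m", "m y", "iv x") %in% pairs))
  expect_equal(roles_of(ig, "m"), "mediator")
  expect_equal(roles_of(ig, "iv"), "instrument")
  # instrument-outcome and other unstated pairs default to unassigned
  una <- ig$edges[ig$edges$orientation == "unassigned", ]
  expect_true(pair_key("iv", "y") %in% pair_key(una$tail, una$head))
})

test_that("multi-exposure studies connect controls to every focal node", {
  rec <- study_record("s", exposures = c("x1", "x2"), outcomes = "y",
                      controls = "c1")
  ig <- map_study(rec)
  d <- ig$edges[ig$edges$orientation == "directed", ]
  pairs <- paste(d$tail, d$head)
  expect_true(all(c("x1 y", "x2 y", "c1 x1", "c1 x2", "c1 y") %in% pairs))
  # exposure-exposure pair stays unassigned
  una <- ig$edges[ig$edges$orientation == "unassigned", ]
  expect_true(pair_key("x1", "x2") %in% pair_key(una$tail, una$head))
})
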