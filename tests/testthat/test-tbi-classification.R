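test_that("term extraction finds pathology mentions with their sentences", {
  h <- extract_term_hits("Large acute subdural haematoma evacuated.", the_lexicon)
  expect_true(all(h$pathology_code == "SDH"))
  expect_true(all(h$sentence == "Large acute subdural haematoma evacuated"))
  expect_true(all(mapply(grepl, h$matched_text, h$sentence, fixed = TRUE)))

  h2 <- extract_term_hits("CT: SDH and traumatic SAH.", the_lexicon)
  expect_setequal(h2$pathology_code, c("SDH", "SAH"))
  # colon does not split sentences: both hits share the full sentence
  expect_true(all(h2$sentence == "CT: SDH and traumatic SAH"))

  expect_equal(nrow(extract_term_hits("", the_lexicon)), 0)
  expect_equal(nrow(extract_term_hits("Fracture of the femur.", the_lexicon)), 0)
})

test_that("matching is case-insensitive and word-bounded", {
  h <- extract_term_hits("SUBDURAL HAEMATOMA noted; sah suspected.", the_lexicon)
  expect_setequal(h$pathology_code, c("SDH", "SAH"))
  # no partial-word acronym matches
  expect_equal(nrow(extract_term_hits("crash dashboard", the_lexicon)), 0)
})

test_that("negation filtering removes cue-preceded hits within the window", {
  f <- function(text) {
    h <- extract_term_hits(text, the_lexicon)
    filter_false_positives(h, the_lexicon)
  }
  expect_equal(nrow(f("No subdural haematoma seen.")), 0)
  # semicolon splits clauses: SDH retained, fracture negated
  out <- f("Subdural haematoma; no skull fracture.")
  expect_setequal(out$pathology_code, "SDH")
  # cue out of scope across a colon: hit retained
  out2 <- f("Not obviously related: subarachnoid haemorrhage present.")
  expect_true("SAH" %in% out2$pathology_code)
  # cue further than 3 tokens back: retained
  out3 <- f("No injury to the chest but subdural haematoma present.")
  expect_true("SDH" %in% out3$pathology_code)
  # audit mode keeps the flagged rows
  all_rows <- filter_false_positives(
    extract_term_hits("No subdural haematoma seen.", the_lexicon),
    the_lexicon, keep_negated = TRUE)
  expect_true(all(all_rows$negated))
})

test_that("profiles union surviving hits and carry fracture subtype", {
  f <- function(text) filter_false_positives(extract_term_hits(text, the_lexicon),
                                             the_lexicon)
  p <- build_tbi_profile(f("Acute subdural haematoma."))
  expect_true(p$SDH)
  expect_false(any(p$SAH, p$EDH, p$focal, p$DAI, p$skull_fracture))

  p2 <- build_tbi_profile(f("Basilar skull fracture on CT."))
  expect_true(p2$skull_fracture)
  expect_equal(p2$fracture_subtype, "basilar")

  p3 <- build_tbi_profile(f("Patient reported headache."),
                          clinical = list(gcs = 15))
  expect_true(p3$symptoms[["headache"]])
  expect_false(p3$SDH)

  mixed <- rbind(transform(f("SDH."), subject_id = "a"),
                 transform(f("SAH."), subject_id = "b"))
  expect_error(build_tbi_profile(mixed), "multiple subjects")
})

test_that("Mayo classification follows the rule table", {
  base <- build_tbi_profile(empty_hits_for_test(), subject_id = "x")
  cls <- function(mod) {
    p <- utils::modifyList(base, mod)
    class(p) <- "tbi_profile"
    classify_mayo(p)
  }
  expect_equal(cls(list(SDH = TRUE)), "moderate_severe")          # GCS missing
  expect_equal(cls(list(DAI = TRUE)), "moderate_severe")
  expect_equal(cls(list(loc_minutes = 45)), "moderate_severe")
  expect_equal(cls(list(pta_hours = 24)), "moderate_severe")
  expect_equal(cls(list(gcs_worst = 12)), "moderate_severe")
  expect_equal(cls(list(death_due_to_tbi = TRUE)), "moderate_severe")
  expect_equal(cls(list(loc_minutes = 10)), "mild_probable")
  expect_equal(cls(list(pta_hours = 2)), "mild_probable")
  expect_equal(cls(list(skull_fracture = TRUE)), "mild_probable")
  expect_equal(cls(list(skull_fracture = TRUE, SAH = TRUE)), "moderate_severe")
  sym <- base$symptoms; sym[["headache"]] <- TRUE
  expect_equal(cls(list(symptoms = sym)), "symptomatic_possible")
  expect_equal(cls(list()), "none")
  # missing fields never satisfy a criterion
  expect_equal(cls(list(gcs_worst = NA_real_, loc_minutes = NA_real_)), "none")
})

test_that("adding a pathology never decreases Mayo severity", {
  set.seed(31)
  sev_rank <- function(s) match(s, c("none", "symptomatic_possible",
                                     "mild_probable", "moderate_severe"))
  base <- build_tbi_profile(empty_hits_for_test(), subject_id = "x")
  paths <- c("SDH", "SAH", "EDH", "focal", "DAI", "skull_fracture")
  for (rep in 1:50) {
    p <- base
    p$loc_minutes <- sample(c(NA, 0, 10, 45), 1)
    p$pta_hours <- sample(c(NA, 0, 5, 30), 1)
    p$gcs_worst <- sample(c(NA, 9, 14, 15), 1)
    on_flags <- sample(paths, sample(0:3, 1))
    for (f in on_flags) p[[f]] <- TRUE
    class(p) <- "tbi_profile"
    before <- sev_rank(classify_mayo(p))
    extra <- sample(setdiff(paths, on_flags), 1)
    p[[extra]] <- TRUE
    expect_gte(sev_rank(classify_mayo(p)), before)
  }
})

test_that("a corpus of purely negated mentions yields zero pathology flags", {
  terms <- unique(the_lexicon$patterns$pattern[
    the_lexicon$patterns$category == "pathology" &
      the_lexicon$patterns$pattern_type == "canonical"])
  corpus <- data.frame(subject_id = as.character(seq_along(terms)),
                       narrative = paste0("No ", terms, " identified."))
  res <- classify_subjects(corpus, the_lexicon)
  expect_false(any(res$profiles$SDH | res$profiles$SAH | res$profiles$EDH |
                     res$profiles$focal | res$profiles$DAI |
                     res$profiles$skull_fracture))
  expect_true(all(res$profiles$mayo_severity == "none"))
})
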