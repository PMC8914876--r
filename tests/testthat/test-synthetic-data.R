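test_that("equal seeds give identical cohorts", {
  a <- small_cohort(seed = 9, n_national = 500, n_indepth = 100)
  b <- small_cohort(seed = 9, n_national = 500, n_indepth = 100)
  expect_identical(a$national, b$national)
  expect_identical(a$indepth, b$indepth)
  expect_identical(a$truth_indepth, b$truth_indepth)
  c <- small_cohort(seed = 10, n_national = 500, n_indepth = 100)
  expect_false(identical(a$indepth, c$indepth))
})

test_that("cohort serialisation round-trips byte-identically under one seed", {
  dir1 <- tempfile(); dir2 <- tempfile()
  write_cohort(small_cohort(seed = 4, n_national = 300, n_indepth = 80), dir1)
  write_cohort(small_cohort(seed = 4, n_national = 300, n_indepth = 80), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                     readBin(file.path(dir2, f), "raw", 1e6))
  }
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(generator_config(road_user_mix = c(pedestrian = 1)),
               "road_user_mix")
  mix <- c(pedestrian = 0.2, cyclist = 0.2, motorcyclist = 0.2,
           car_occupant = 0.2, van_occupant = 0.1, hgv_occupant = 0.2)
  expect_error(generator_config(road_user_mix = mix), "sum to 1")
  dv <- default_deltav_distribution()
  dv$cyclist$scale <- -1
  expect_error(generator_config(deltav_distribution = dv),
               "deltav_distribution")
  expect_error(generator_config(severity_oversampling = c(fatal = 0, serious = 1,
                                                          slight = 1, uninjured = 1)),
               "severity_oversampling")
  thr <- default_pathology_thresholds()
  thr$pedestrian[["SDH"]] <- -2
  expect_error(generator_config(pathology_thresholds = thr),
               "pathology_thresholds")
})

test_that("generated marginals match the configuration within 3 standard errors", {
  cfg <- generator_config(n_national = 20000, n_indepth = 10, seed = 2)
  coh <- generate_cohort(cfg, narratives = FALSE)
  mix <- cfg$road_user_mix
  obs <- table(factor(coh$national$road_user, levels = names(mix))) / 20000
  se <- sqrt(mix * (1 - mix) / 20000)
  expect_true(all(abs(obs - mix) <= 3 * se))
  # delta-V mean for car occupants vs configured gamma mean
  tr <- coh$truth_national[coh$national$road_user == "car_occupant", ]
  spec <- cfg$deltav_distribution$car_occupant
  mu <- spec$shape * spec$scale
  sdv <- sqrt(spec$shape) * spec$scale
  expect_lt(abs(mean(tr$true_total_dv) - mu), 3 * sdv / sqrt(nrow(tr)))
})

test_that("key pathologies never occur below the delta-V thresholds", {
  coh <- generate_cohort(generator_config(n_national = 20000, n_indepth = 2000,
                                          seed = 3), narratives = FALSE)
  for (side in c("national", "indepth")) {
    tr <- coh[[paste0("truth_", side)]]
    users <- if (side == "national") coh$national$road_user else coh$indepth$road_user
    any_path <- tr$SDH | tr$SAH | tr$EDH | tr$DAI | tr$skull_fracture
    car <- users %in% c("car_occupant", "van_occupant", "hgv_occupant")
    expect_equal(sum(any_path & car & tr$true_total_dv < 19), 0)
    expect_equal(sum(tr$focal & car & tr$true_total_dv < 28), 0)
    expect_equal(sum(any_path & !car & tr$true_total_dv < 8), 0)
    expect_equal(sum(tr$focal & !car & tr$true_total_dv < 16), 0)
  }
})

test_that("uniform oversampling gives an unbiased in-depth severity mix", {
  cfg <- generator_config(n_national = 50000, n_indepth = 5000, seed = 6,
                          severity_oversampling = c(fatal = 1, serious = 1,
                                                    slight = 1, uninjured = 1))
  coh <- generate_cohort(cfg, narratives = FALSE)
  for (s in c("fatal", "serious", "slight", "uninjured")) {
    p1 <- mean(coh$national$overall_severity == s)
    p2 <- mean(coh$indepth$overall_severity == s)
    se <- sqrt(p1 * (1 - p1) / 50000 + p2 * (1 - p2) / 5000)
    expect_lt(abs(p1 - p2), 4 * se)
  }
  # and the default multipliers do oversample serious collisions
  coh2 <- small_cohort(seed = 6, n_national = 5000, n_indepth = 1000)
  expect_gt(mean(coh2$indepth$overall_severity %in% c("fatal", "serious")),
            mean(coh2$national$overall_severity %in% c("fatal", "serious")))
})

test_that("narratives always carry a matchable term per true pathology", {
  prof <- list(flags = c(SDH = TRUE, SAH = FALSE, EDH = FALSE, focal = FALSE,
                         DAI = FALSE, skull_fracture = FALSE),
               fracture_subtype = "none",
               symptoms = setNames(rep(FALSE, 7),
                                   c("headache", "confusion", "dizziness", "nausea",
                                     "blurred vision", "dazed", "focal neurological signs")),
               loc_minutes = 0)
  set.seed(1)
  txt <- render_narrative(prof, zero_noise, the_lexicon)
  expect_match(txt, "subdural haematoma")
  txt_acr <- render_narrative(prof, c(misspelling = 0, acronym = 1, negation = 0),
                              the_lexicon)
  expect_match(txt_acr, "\\bSDH\\b")
  # empty profile with certain negation: one negated mention, no true flag
  prof0 <- prof; prof0$flags[] <- FALSE
  txt_neg <- render_narrative(prof0, c(misspelling = 0, acronym = 0, negation = 1),
                              the_lexicon)
  expect_match(txt_neg, "^.*No ")
  res <- classify_subjects(data.frame(subject_id = "s", narrative = txt_neg),
                           the_lexicon)
  expect_true(all(res$profiles$mayo_severity == "none"))
})

test_that("uninjured subjects have empty narratives", {
  coh <- small_cohort(seed = 13, n_national = 200, n_indepth = 400)
  un <- coh$indepth$overall_severity == "uninjured"
  expect_true(any(un))
  expect_true(all(coh$indepth$narrative[un] == ""))
  expect_true(all(nzchar(coh$indepth$narrative[!un])))
})

test_that("the ground-truth risk function matches its logistic definition", {
  p0 <- list(lateral_dominant_logodds = 0.5,
             outcomes = list(moderate_severe = list(car_occupant = c(intercept = 0, slope = 0))),
             pathology_given_modsev = list(car_occupant = c(SDH = 0.4)))
  expect_equal(true_risk(57, "car_occupant", params = p0), 0.5)
  p1 <- p0
  p1$outcomes$moderate_severe$car_occupant <- c(intercept = -4, slope = 0.1)
  expect_equal(true_risk(40, "car_occupant", params = p1), 0.5)
  expect_equal(true_risk(40, "car_occupant", TRUE, params = p1), plogis(0.5))
  # thresholded pathology risk is exactly zero below the threshold
  expect_equal(true_risk(10, "car_occupant", outcome = "SDH"), 0)
  expect_gt(true_risk(25, "car_occupant", outcome = "SDH"), 0)
  expect_error(true_risk(10, "horse_rider"), "unknown road user")
  expect_error(true_risk(-5, "cyclist"), ">= 0")
})
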