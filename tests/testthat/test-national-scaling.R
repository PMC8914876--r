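make_tables <- function(n = 1000, seed = 1) {
  with_seed_test(seed, {
    nat <- data.frame(
      road_user = sample(c("car", "ped"), n, TRUE, c(0.5, 0.5)),
      age_band = sample(c("young", "old"), n, TRUE),
      overall_severity = sample(c("serious", "slight"), n, TRUE, c(0.2, 0.8)))
    ind <- data.frame(
      road_user = sample(c("car", "ped"), n, TRUE, c(0.9, 0.1)),
      age_band = sample(c("young", "old"), n, TRUE),
      overall_severity = sample(c("serious", "slight"), n, TRUE, c(0.6, 0.4)))
    list(nat = nat, ind = ind)
  })
}

test_that("field divergence tests flag distributional differences per field", {
  tb <- make_tables()
  same <- data.frame(f = rep(c("a", "b"), each = 100))
  out <- field_divergence_tests(same, same, "f")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)

  out2 <- field_divergence_tests(tb$ind, tb$nat,
                                 c("road_user", "age_band", "overall_severity"))
  expect_equal(nrow(out2), 3)
  expect_lt(out2$p_value[out2$field == "road_user"], 1e-10)
  expect_error(field_divergence_tests(tb$ind, tb$nat, "lighting"),
               "lighting")
})

test_that("field selection recovers the severity-predictive clustering", {
  with_seed_test(42, {
    n <- 3000
    d <- data.frame(
      road_user = sample(c("car", "ped", "cyc"), n, TRUE),
      age_band = sample(c("young", "old"), n, TRUE),
      lighting = sample(c("day", "dark"), n, TRUE))
    # severity driven purely by road user
    d$overall_severity <- ifelse(d$road_user == "ped",
                                 sample(c("serious", "slight"), n, TRUE, c(0.9, 0.1)),
                                 sample(c("serious", "slight"), n, TRUE, c(0.1, 0.9)))
    sel <- select_scaling_fields(d, c("road_user", "age_band", "lighting"))
    expect_equal(sel, "road_user", ignore_attr = TRUE)

    # severity from a road_user x age_band interaction: the pair wins
    d2 <- d
    hi <- (d2$road_user == "ped") == (d2$age_band == "old")
    d2$overall_severity <- ifelse(hi,
                                  sample(c("serious", "slight"), n, TRUE, c(0.9, 0.1)),
                                  sample(c("serious", "slight"), n, TRUE, c(0.1, 0.9)))
    sel2 <- select_scaling_fields(d2, c("road_user", "age_band", "lighting"))
    expect_equal(sel2, c("age_band", "road_user"), ignore_attr = TRUE)
  })
})

test_that("field selection tie-breaks deterministically when nothing predicts", {
  with_seed_test(7, {
    n <- 2000
    d <- data.frame(
      zeta = sample(c("a", "b"), n, TRUE),
      alpha = sample(c("x", "y"), n, TRUE),
      overall_severity = sample(c("serious", "slight"), n, TRUE, c(0.3, 0.7)))
    sel <- select_scaling_fields(d, c("zeta", "alpha"))
    scores <- attr(sel, "scores")
    # independence: every candidate scores near the majority-class baseline
    expect_true(all(abs(scores$cv_error - 0.3) < 0.05))
    expect_equal(length(sel), 1)
  })
  expect_error(select_scaling_fields(data.frame(overall_severity = "s"),
                                     character(0)), "no candidate")
})

test_that("weights are national over in-depth cluster proportions", {
  ind <- data.frame(g = rep(c("a", "b"), c(25, 75)))
  nat <- data.frame(g = rep(c("a", "b"), c(500, 500)))
  w <- compute_weights(ind, nat, "g")
  expect_equal(sum(w$p_national), 1, tolerance = 1e-12)
  expect_equal(sum(w$p_indepth), 1, tolerance = 1e-12)
  expect_equal(w$weight[w$g == "a"], 2)
  expect_equal(w$weight[w$g == "b"], 2 / 3, tolerance = 1e-12)
  # identical proportions: all weights one
  w1 <- compute_weights(nat, nat, "g")
  expect_true(all(w1$weight == 1))
})

test_that("sparse clusters merge; unmergeable empty clusters are flagged", {
  # single field: below-floor level merges into the big neighbour
  ind <- data.frame(g = rep(c("a", "b"), c(97, 3)))
  nat <- data.frame(g = rep(c("a", "b"), c(50, 50)))
  w <- compute_weights(ind, nat, "g", min_count = 5)
  expect_equal(nrow(w), 1)
  expect_equal(w$weight, 1)

  # two fields: a national-only cluster differing in both fields cannot
  # merge and is flagged with an undefined weight
  ind2 <- data.frame(f1 = rep(c("a", "b"), each = 10), f2 = rep(c("x", "y"), each = 10))
  nat2 <- data.frame(f1 = c(rep(c("a", "b"), each = 10), "c"),
                     f2 = c(rep(c("x", "y"), each = 10), "z"))
  w2 <- compute_weights(ind2, nat2, c("f1", "f2"), min_count = 5)
  bad <- w2[w2$f1 == "c", ]
  expect_equal(nrow(bad), 1)
  expect_true(is.na(bad$weight))
  expect_equal(bad$n_indepth, 0)
})

test_that("self-scaling is the identity and margins are recovered", {
  coh <- small_cohort(seed = 17, n_national = 3000, n_indepth = 800)
  ind <- coh$indepth
  ind$tbi <- coh$truth_indepth$tbi
  w <- compute_weights(ind, ind, c("overall_severity", "road_user"))
  expect_true(all(abs(w$weight - 1) < 1e-12))
  est <- scale_estimates(ind, w, "tbi", nrow(ind))
  expect_equal(est$scaled_count, sum(ind$tbi), tolerance = 1e-9)

  # margin recovery against the national table
  w2 <- compute_weights(ind, coh$national, c("overall_severity", "road_user"))
  ok <- !is.na(w2$weight)
  expect_equal(w2$p_indepth[ok] * w2$weight[ok], w2$p_national[ok],
               tolerance = 1e-12)
})

test_that("weighting corrects the severity-oversampling bias", {
  coh <- generate_cohort(generator_config(n_national = 20000, n_indepth = 2000,
                                          seed = 23), narratives = FALSE)
  ind <- coh$indepth
  ind$tbi <- coh$truth_indepth$tbi
  truth <- mean(coh$truth_national$tbi)
  w <- compute_weights(ind, coh$national, c("overall_severity", "road_user"))
  est <- scale_estimates(ind, w, "tbi", nrow(coh$national))
  expect_gt(est$indepth_rate, truth + 0.05)       # raw rate biased upwards
  expect_lt(abs(est$weighted_rate - truth), 3 * est$se / nrow(coh$national))
})

test_that("unmapped records above 5% are a coverage failure", {
  ind <- data.frame(g = rep(c("a", "b"), c(50, 50)), y = TRUE)
  w <- compute_weights(ind, ind, "g")
  new <- data.frame(g = rep(c("a", "b", "zzz"), c(40, 40, 20)), y = TRUE)
  expect_error(scale_estimates(new, w, "y", 1000), "coverage failure")
  ok <- data.frame(g = rep(c("a", "b", "zzz"), c(49, 49, 2)), y = TRUE)
  expect_silent(scale_estimates(ok, w, "y", 1000))
})

test_that("annualisation divides the scaled count by the period", {
  toy <- data.frame(g = rep("all", 10), casualty = TRUE)
  w <- compute_weights(toy, toy, "g", min_count = 1)
  est <- scale_estimates(toy, w, "casualty", 1190717, period_years = 6.75)
  expect_equal(est$scaled_count, 1190717)
  expect_equal(est$annual_count, 1190717 / 6.75)
  expect_equal(round(est$annual_count / 1000) * 1000, 176000)
})
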