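#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the configuration driving [generate_cohort()]. The
#' defaults encode the study conditions the generator emulates: a national
#' casualty table with only broad shared fields, and a smaller in-depth
#' sample that oversamples serious collisions, carries collision dynamics
#' and clinical narratives, and whose TBI outcomes follow a logistic
#' dependence on delta-V with road-user-specific odds and delta-V
#' thresholds below which key pathologies do not occur. See the methods
#' vignette for how each default was calibrated.
#'
#' @param n_national,n_indepth table sizes.
#' @param road_user_mix named probabilities over the six road-user types
#'   (must sum to 1).
#' @param deltav_distribution per-road-user positive continuous
#'   distribution spec: list with `family` (`"gamma"`, `"lognormal"` or
#'   `"weibull"`), `shape` and `scale` (km/h scale).
#' @param true_risk_params logistic ground truth: per-outcome, per-road-user
#'   `intercept` and `slope` (log-odds per km/h) plus
#'   `lateral_dominant_logodds`, and the conditional pathology
#'   probabilities given moderate-severe TBI.
#' @param pathology_thresholds per-road-user named vector: minimum total
#'   delta-V (km/h) below which each key pathology has probability zero.
#' @param severity_model proportional-odds link of overall severity on
#'   delta-V (`slope`, cutpoints `slight`, `serious`, `fatal`).
#' @param severity_oversampling named positive acceptance-odds multipliers
#'   per overall-severity stratum for the in-depth subsample.
#' @param narrative_noise rates for the narrative generator: `misspelling`,
#'   `acronym`, `negation`.
#' @param helmet_protection multiplier (< 1 protective) on skull-fracture
#'   and SDH probabilities for helmeted cyclists.
#' @param missing_dynamics_rate probability that a record's observed
#'   dynamics fields are masked as missing.
#' @param seed integer seed; all generator randomness flows from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_national = 10000,
                             n_indepth = 1000,
                             road_user_mix = c(pedestrian = 0.12, cyclist = 0.08,
                                               motorcyclist = 0.09, car_occupant = 0.60,
                                               van_occupant = 0.07, hgv_occupant = 0.04),
                             deltav_distribution = default_deltav_distribution(),
                             true_risk_params = default_true_risk_params(),
                             pathology_thresholds = default_pathology_thresholds(),
                             severity_model = list(slope = 0.05, slight = 0.5,
                                                   serious = 3.2, fatal = 6.0),
                             severity_oversampling = c(fatal = 30, serious = 10,
                                                       slight = 2, uninjured = 1),
                             narrative_noise = c(misspelling = 0.1, acronym = 0.3,
                                                 negation = 0.25),
                             helmet_protection = 0.2,
                             missing_dynamics_rate = 0.05,
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' Default per-road-user delta-V distributions
#'
#' Gamma distributions (non-negative, right-skewed like crash severity
#' data) with km/h scale parameters per road-user type; see the methods
#' vignette for the calibration.
#'
#' @return Named list of distribution specs (`family`, `shape`, `scale`).
#' @export
default_deltav_distribution <- function() {
  list(pedestrian = list(family = "gamma", shape = 2, scale = 15),
       cyclist = list(family = "gamma", shape = 2, scale = 14),
       motorcyclist = list(family = "gamma", shape = 2, scale = 14),
       car_occupant = list(family = "gamma", shape = 2, scale = 10),
       van_occupant = list(family = "gamma", shape = 2, scale = 10),
       hgv_occupant = list(family = "gamma", shape = 2, scale = 8))
}

#' Default ground-truth risk parameters
#'
#' Moderate-severe intercept/slope pass through published VRU risk points
#' (26% at 32 km/h, 39% at 48 km/h); car-like occupants sit a VRU-vs-car
#' odds ratio of 6.84 below at matched delta-V; dominant-lateral impacts
#' add log-odds ln(2.19). Conditional pathology probabilities given
#' moderate-severe TBI follow published group counts.
#'
#' @return Parameter list consumed by [true_risk()] and
#'   [generator_config()].
#' @export
default_true_risk_params <- function() {
  vru_ms <- c(intercept = -2.244, slope = 0.0374)
  car_ms <- c(intercept = -2.244 - log(6.84), slope = 0.0374)
  per_user <- function(vru, car) {
    list(pedestrian = vru, cyclist = vru, motorcyclist = vru,
         car_occupant = car, van_occupant = car, hgv_occupant = car)
  }
  list(
    lateral_dominant_logodds = log(2.19),
    outcomes = list(
      moderate_severe = per_user(vru_ms, car_ms),
      mild_probable = per_user(c(intercept = -2.6, slope = 0.02),
                               c(intercept = -3.6, slope = 0.02)),
      symptomatic_possible = per_user(c(intercept = -2.2, slope = 0.015),
                                      c(intercept = -2.8, slope = 0.015))),
    pathology_given_modsev = per_user(
      c(SDH = 0.21, SAH = 0.45, EDH = 0.05, focal = 0.50, DAI = 0.08,
        skull_fracture = 0.60),
      c(SDH = 0.36, SAH = 0.62, EDH = 0.05, focal = 0.49, DAI = 0.08,
        skull_fracture = 0.36)),
    skull_fracture_given_mild = 0.15)
}

#' Default delta-V thresholds below which key pathologies do not occur
#'
#' 19 km/h for car-like occupants and 8 km/h for vulnerable road users,
#' with higher focal-injury thresholds (28 and 16 km/h).
#'
#' @return Named list of per-road-user threshold vectors (km/h).
#' @export
default_pathology_thresholds <- function() {
  vru <- c(SDH = 8, SAH = 8, EDH = 8, focal = 16, DAI = 8, skull_fracture = 8)
  car <- c(SDH = 19, SAH = 19, EDH = 19, focal = 28, DAI = 19, skull_fracture = 19)
  list(pedestrian = vru, cyclist = vru, motorcyclist = vru,
       car_occupant = car, van_occupant = car, hgv_occupant = car)
}

validate_generator_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid generator config: ", field, " ", msg)
  if (!is.numeric(cfg$n_national) || cfg$n_national < 1) fail("n_national", "must be >= 1")
  if (!is.numeric(cfg$n_indepth) || cfg$n_indepth < 1) fail("n_indepth", "must be >= 1")
  mix <- cfg$road_user_mix
  if (!setequal(names(mix), road_user_levels)) fail("road_user_mix", "must name all six road-user types")
  if (any(mix < 0)) fail("road_user_mix", "must be non-negative")
  if (abs(sum(mix) - 1) > 1e-9) fail("road_user_mix", "must sum to 1 within 1e-9")
  for (u in road_user_levels) {
    d <- cfg$deltav_distribution[[u]]
    if (is.null(d)) fail("deltav_distribution", paste("missing road user", u))
    if (!d$family %in% c("gamma", "lognormal", "weibull"))
      fail("deltav_distribution", paste("unknown family", d$family))
    if (d$scale <= 0) fail("deltav_distribution", paste("scale must be > 0 for", u))
    thr <- cfg$pathology_thresholds[[u]]
    if (is.null(thr) || any(thr < 0)) fail("pathology_thresholds", paste("must be >= 0 for", u))
  }
  if (any(cfg$severity_oversampling <= 0)) fail("severity_oversampling", "multipliers must be > 0")
  if (!setequal(names(cfg$severity_oversampling), c("fatal", "serious", "slight", "uninjured")))
    fail("severity_oversampling", "must name every severity stratum")
  nn <- cfg$narrative_noise
  if (any(nn < 0 | nn > 1)) fail("narrative_noise", "rates must lie in [0, 1]")
  if (!all(c("misspelling", "acronym", "negation") %in% names(nn)))
    fail("narrative_noise", "must name misspelling, acronym and negation rates")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator config: n_national =", x$n_national,
      ", n_indepth =", x$n_indepth, ", seed =", x$seed, "\n")
  invisible(x)
}

#' Ground-truth injury risk
#'
#' The generative logistic risk used by the synthetic cohort:
#' `plogis(intercept + slope * delta_v + lateral_dominant_logodds)` for the
#' severity outcomes, with road-user-specific coefficients. For a key
#' pathology the risk is the moderate-severe risk times the conditional
#' pathology probability, and exactly zero below that pathology's delta-V
#' threshold.
#'
#' @param delta_v total delta-V, km/h (vectorised, >= 0).
#' @param road_user one of the six road-user types.
#' @param lateral_dominant logical flag (vehicle occupants).
#' @param params `true_risk_params` list (default
#'   [default_true_risk_params()]).
#' @param outcome `"moderate_severe"` (default), `"mild_probable"`,
#'   `"symptomatic_possible"`, or a pathology code (`"SDH"`, `"SAH"`,
#'   `"EDH"`, `"focal"`, `"DAI"`, `"skull_fracture"`).
#' @param thresholds per-road-user pathology thresholds (default
#'   [default_pathology_thresholds()]).
#' @return Probability (vector over `delta_v`).
#' @examples
#' true_risk(32, "pedestrian")   # ~0.26
#' true_risk(10, "car_occupant", outcome = "SDH")  # 0: below threshold
#' @export
true_risk <- function(delta_v, road_user, lateral_dominant = FALSE,
                      params = default_true_risk_params(),
                      outcome = "moderate_severe",
                      thresholds = default_pathology_thresholds()) {
  if (any(delta_v < 0)) stop("delta_v must be >= 0")
  if (!road_user %in% road_user_levels)
    stop("unknown road user: ", road_user)
  ms <- params$outcomes$moderate_severe[[road_user]]
  dom <- ifelse(lateral_dominant, params$lateral_dominant_logodds, 0)
  if (outcome %in% names(params$outcomes)) {
    cf <- params$outcomes[[outcome]][[road_user]]
    return(plogis(cf[["intercept"]] + cf[["slope"]] * delta_v + dom))
  }
  if (outcome %in% pathology_codes) {
    p_ms <- plogis(ms[["intercept"]] + ms[["slope"]] * delta_v + dom)
    pi_k <- params$pathology_given_modsev[[road_user]][[outcome]]
    thr <- thresholds[[road_user]][[outcome]]
    return(ifelse(delta_v < thr, 0, p_ms * pi_k))
  }
  stop("unknown outcome: ", outcome)
}

# categorical marginals for the non-dynamics shared fields
shared_field_levels <- function() {
  list(age_band = c("0-15" = 0.08, "16-64" = 0.79, "65+" = 0.13),
       lighting = c(daylight = 0.70, dark_lit = 0.20, dark_unlit = 0.10),
       speed_limit = c("20" = 0.05, "30" = 0.45, "40" = 0.10, "50" = 0.05,
                       "60" = 0.20, "70" = 0.15),
       road_class = c(A = 0.45, B = 0.15, minor = 0.30, motorway = 0.10),
       vehicle_age_band = c("0-3" = 0.30, "4-7" = 0.30, "8+" = 0.40))
}

draw_deltav <- function(n, spec) {
  switch(spec$family,
         gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
         lognormal = rlnorm(n, meanlog = log(spec$scale), sdlog = spec$shape),
         weibull = rweibull(n, shape = spec$shape, scale = spec$scale))
}

# Draw one population of n subjects with full ground truth. Uses the
# current RNG stream (caller controls the seed).
gen_population <- function(n, cfg, narratives = TRUE, lexicon = NULL,
                           id_prefix = "S") {
  road_user <- sample(road_user_levels, n, replace = TRUE,
                      prob = cfg$road_user_mix[road_user_levels])
  lat <- lon <- tot <- impact_speed <- vru_speed <- par_frac <- rep(NA_real_, n)
  runover <- rep(FALSE, n)
  dominance <- rep("n/a", n)
  carlike <- road_user %in% c("car_occupant", "van_occupant", "hgv_occupant")
  for (u in road_user_levels) {
    i <- which(road_user == u)
    if (!length(i)) next
    dv <- draw_deltav(length(i), cfg$deltav_distribution[[u]])
    if (u %in% c("car_occupant", "van_occupant", "hgv_occupant")) {
      comp <- sample(c("long", "lat", "both"), length(i), replace = TRUE,
                     prob = c(0.55, 0.08, 0.37))
      theta <- ifelse(comp == "long", 0,
                      ifelse(comp == "lat", pi / 2, runif(length(i), 0, pi / 2)))
      lat[i] <- dv * sin(theta)
      lon[i] <- dv * cos(theta)
      tot[i] <- dv
      dominance[i] <- dominant_component(lat[i], lon[i])
    } else if (u == "pedestrian") {
      impact_speed[i] <- dv
      vru_speed[i] <- rgamma(length(i), 2, scale = 2.5)
      par_frac[i] <- 0
      tot[i] <- vru_delta_v("pedestrian", dv)
      runover[i] <- runif(length(i)) < 0.03
    } else if (u == "cyclist") {
      impact_speed[i] <- dv
      vru_speed[i] <- rgamma(length(i), 4, scale = 4)
      par_frac[i] <- runif(length(i), -1, 1)
      tot[i] <- vru_delta_v(rep("cyclist", length(i)), dv, vru_speed[i], par_frac[i])
      runover[i] <- runif(length(i)) < 0.02
    } else {  # motorcyclist: overall delta-V directly, components unknown
      tot[i] <- dv
    }
  }
  lat_dom <- !is.na(dominance) & dominance == "lateral"
  impact_count <- ifelse(carlike,
                         sample(1:3, n, replace = TRUE, prob = c(0.8, 0.15, 0.05)), 1L)
  phase_known <- ifelse(impact_count > 1, runif(n) < 0.8, TRUE)

  # helmets: cyclists mixed, motorcyclists near-universal
  helmet <- rep("unknown", n)
  cyc <- road_user == "cyclist"
  helmet[cyc] <- sample(c("yes", "no", "unknown"), sum(cyc), replace = TRUE,
                        prob = c(0.45, 0.45, 0.10))
  mc <- road_user == "motorcyclist"
  helmet[mc] <- sample(c("yes", "no", "unknown"), sum(mc), replace = TRUE,
                       prob = c(0.95, 0.02, 0.03))

  # ground-truth TBI outcomes from the logistic truth on total delta-V
  p_ms <- p_mild <- p_sym <- numeric(n)
  for (u in road_user_levels) {
    i <- which(road_user == u)
    if (!length(i)) next
    p_ms[i] <- true_risk(tot[i], u, lat_dom[i], cfg$true_risk_params, "moderate_severe")
    p_mild[i] <- true_risk(tot[i], u, lat_dom[i], cfg$true_risk_params, "mild_probable")
    p_sym[i] <- true_risk(tot[i], u, lat_dom[i], cfg$true_risk_params, "symptomatic_possible")
  }
  ms <- runif(n) < p_ms
  mild <- !ms & runif(n) < p_mild
  sym <- !ms & !mild & runif(n) < p_sym

  # pathologies: only above the per-road-user thresholds
  flags <- matrix(FALSE, n, length(pathology_codes),
                  dimnames = list(NULL, pathology_codes))
  for (u in road_user_levels) {
    i <- which(road_user == u & ms)
    thr <- cfg$pathology_thresholds[[u]]
    pis <- cfg$true_risk_params$pathology_given_modsev[[u]]
    for (k in pathology_codes) {
      if (!length(i)) break
      pk <- rep(pis[[k]], length(i))
      if (k %in% c("skull_fracture", "SDH") && u == "cyclist")
        pk[helmet[i] == "yes"] <- pk[helmet[i] == "yes"] * cfg$helmet_protection
      flags[i, k] <- tot[i] >= thr[[k]] & runif(length(i)) < pk
    }
    # mild cases may carry an isolated skull fracture
    j <- which(road_user == u & mild)
    if (length(j)) {
      pk <- rep(cfg$true_risk_params$skull_fracture_given_mild, length(j))
      if (u == "cyclist") pk[helmet[j] == "yes"] <- pk[helmet[j] == "yes"] * cfg$helmet_protection
      flags[j, "skull_fracture"] <- tot[j] >= thr[["skull_fracture"]] & runif(length(j)) < pk
    }
  }
  intracranial <- rowSums(flags[, c("SDH", "SAH", "EDH", "focal", "DAI"), drop = FALSE]) > 0

  fracture_subtype <- rep("none", n)
  fr <- which(flags[, "skull_fracture"])
  fracture_subtype[fr] <- sample(c("unspecified", "basilar", "depressed", "linear"),
                                 length(fr), replace = TRUE,
                                 prob = c(0.4, 0.2, 0.2, 0.2))

  # clinical fields consistent with the intended Mayo class
  gcs <- rep(15, n); loc <- rep(0, n); pta <- rep(0, n)
  i <- which(ms)
  gcs[i] <- ifelse(runif(length(i)) < 0.7, sample(3:12, length(i), TRUE),
                   sample(13:15, length(i), TRUE))
  loc[i] <- ifelse(runif(length(i)) < 0.6, runif(length(i), 30, 240),
                   runif(length(i), 0, 20))
  # guarantee a moderate-severe criterion when no intracranial pathology
  need <- i[!intracranial[i] & !(gcs[i] < 13) & !(loc[i] >= 30)]
  loc[need] <- runif(length(need), 30, 240)
  pta[i] <- ifelse(runif(length(i)) < 0.3, runif(length(i), 24, 96), 0)
  j <- which(mild)
  gcs[j] <- sample(13:15, length(j), TRUE)
  loc[j] <- ifelse(flags[j, "skull_fracture"] & runif(length(j)) < 0.5,
                   0, runif(length(j), 1, 29))
  needm <- j[!flags[j, "skull_fracture"] & loc[j] == 0]
  loc[needm] <- runif(length(needm), 1, 29)
  pta[j] <- ifelse(runif(length(j)) < 0.4, runif(length(j), 0.5, 23), 0)

  # symptoms: all symptomatic cases, plus most higher-severity cases
  sym_flags <- matrix(FALSE, n, length(symptom_terms),
                      dimnames = list(NULL, symptom_terms))
  has_sym <- sym | ((ms | mild) & runif(n) < 0.6)
  s <- which(has_sym)
  if (length(s)) {
    n_sym <- sample(1:2, length(s), TRUE)
    for (a in seq_along(s)) {
      sym_flags[s[a], sample(length(symptom_terms), n_sym[a])] <- TRUE
    }
  }

  # overall severity: proportional-odds on delta-V, floored for TBI cases
  sm <- cfg$severity_model
  eta <- sm$slope * tot
  u1 <- runif(n)
  severity <- rep("uninjured", n)
  severity[u1 < plogis(eta - sm$slight)] <- "slight"
  severity[u1 < plogis(eta - sm$serious)] <- "serious"
  severity[u1 < plogis(eta - sm$fatal)] <- "fatal"
  severity[ms & !severity %in% c("serious", "fatal")] <- "serious"
  severity[(mild | sym) & severity == "uninjured"] <- "slight"
  death_tbi <- ms & severity == "fatal"

  mayo <- rep("none", n)
  mayo[sym] <- "symptomatic_possible"
  mayo[mild] <- "mild_probable"
  mayo[ms] <- "moderate_severe"

  fields <- shared_field_levels()
  cat_draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)

  subject_id <- sprintf("%s%06d", id_prefix, seq_len(n))
  collision_id <- sprintf("%sC%06d", id_prefix, cumsum(runif(n) < 0.45))

  miss <- runif(n) < cfg$missing_dynamics_rate
  obs <- function(x) ifelse(miss, NA_real_, x)

  subjects <- data.frame(
    subject_id = subject_id, collision_id = collision_id,
    road_user = road_user,
    age_band = cat_draw(fields$age_band),
    lighting = cat_draw(fields$lighting),
    speed_limit = cat_draw(fields$speed_limit),
    road_class = cat_draw(fields$road_class),
    vehicle_age_band = cat_draw(fields$vehicle_age_band),
    overall_severity = severity,
    gcs = gcs, loc_minutes = loc, pta_hours = pta,
    death_due_to_tbi = death_tbi,
    helmet_worn = helmet,
    lateral_dv = obs(lat), longitudinal_dv = obs(lon), total_dv = obs(tot),
    vehicle_impact_speed = obs(impact_speed), vru_speed = obs(vru_speed),
    vru_parallel_fraction = par_frac,
    impact_count = impact_count,
    injury_causing_phase_known = phase_known,
    runover = runover,
    dominance = dominance,
    stringsAsFactors = FALSE)

  truth <- data.frame(subject_id = subject_id, flags,
                      fracture_subtype = fracture_subtype,
                      sym_flags, check.names = FALSE,
                      tbi = ms | mild | sym,
                      moderate_severe = ms,
                      mayo_severity = mayo,
                      true_total_dv = tot,
                      stringsAsFactors = FALSE)

  if (narratives) {
    if (is.null(lexicon)) lexicon <- read_lexicon()
    subjects$narrative <- vapply(seq_len(n), function(a) {
      if (severity[a] == "uninjured") return("")
      render_narrative(
        list(flags = flags[a, ], fracture_subtype = fracture_subtype[a],
             symptoms = sym_flags[a, ], loc_minutes = loc[a]),
        cfg$narrative_noise, lexicon)
    }, character(1))
  } else {
    subjects$narrative <- ""
  }
  list(subjects = subjects, truth = truth)
}

#' Render a synthetic clinical narrative
#'
#' Inverse of the free-text extraction: writes a short clinical note that
#' contains at least one lexicon-matchable term for every true pathology
#' flag and symptom. With probability `acronym` the term is rendered as its
#' acronym, else with probability `misspelling` as an entry from the
#' lexicon's fixed misspelling-variant table (so extraction stays
#' decidable); a named fracture subtype is always written out in full to
#' preserve it. With probability `negation`, a negated mention of an absent
#' pathology ("No <term> seen.") is added. Draws from the current RNG
#' stream.
#'
#' @param profile list with logical `flags` (named by pathology code),
#'   `fracture_subtype`, logical `symptoms` (named by symptom term) and
#'   `loc_minutes`.
#' @param noise named rates `misspelling`, `acronym`, `negation`.
#' @param lexicon a [read_lexicon()] object.
#' @return A single narrative string.
#' @export
render_narrative <- function(profile, noise, lexicon = read_lexicon()) {
  pats <- lexicon$patterns
  pick_form <- function(code) {
    e <- pats[pats$pathology_code == code, , drop = FALSE]
    acr <- e$pattern[e$pattern_type == "acronym"]
    mis <- e$pattern[e$pattern_type == "misspelling"]
    can <- e$pattern[e$pattern_type == "canonical"][1]
    if (length(acr) && runif(1) < noise[["acronym"]]) return(sample(acr, 1))
    if (length(mis) && runif(1) < noise[["misspelling"]]) return(sample(mis, 1))
    can
  }
  sent <- character(0)
  flags <- profile$flags
  for (code in names(flags)[flags %in% TRUE]) {
    if (code == "skull_fracture" &&
        !profile$fracture_subtype %in% c("none", "unspecified")) {
      term <- switch(profile$fracture_subtype,
                     basilar = "basilar skull fracture",
                     depressed = "depressed skull fracture",
                     linear = "linear skull fracture")
    } else term <- pick_form(code)
    sent <- c(sent, paste0("CT head showed ", term, "."))
  }
  syms <- profile$symptoms
  for (s in names(syms)[syms %in% TRUE]) {
    sent <- c(sent, paste0("Patient reported ", s, "."))
  }
  if (isTRUE(profile$loc_minutes > 0))
    sent <- c(sent, "Loss of consciousness at scene.")
  absent <- names(flags)[!flags %in% TRUE]
  if (length(absent) && runif(1) < noise[["negation"]]) {
    e <- pats[pats$pathology_code == sample(absent, 1) &
                pats$pattern_type == "canonical", , drop = FALSE]
    sent <- c(sent, paste0("No ", e$pattern[1], " seen."))
  }
  if (!length(sent)) sent <- "Minor soft tissue injuries only."
  paste(sent, collapse = " ")
}

#' Generate matched national and in-depth synthetic cohorts
#'
#' Draws a national casualty table of `n_national` subjects from the
#' configured marginals, and an in-depth table of `n_indepth` subjects as a
#' severity-biased subsample of an independently drawn population:
#' acceptance sampling with per-stratum odds multipliers reproduces the
#' in-depth database's bias towards serious collisions. The in-depth table
#' additionally carries collision dynamics and clinical narratives. Hidden
#' ground-truth labels for both tables are returned separately so
#' downstream stages can be validated by parameter recovery. Identical
#' seeds give identical output.
#'
#' @param config a [generator_config()].
#' @param narratives generate free-text narratives for the in-depth table
#'   (default `TRUE`; disable for large statistical simulations that do not
#'   exercise the text pipeline).
#' @param lexicon lexicon for narrative rendering (default the packaged
#'   one).
#' @return A `synthetic_cohort` list: `national`, `indepth` (subject data
#'   frames), `truth_national`, `truth_indepth` (ground-truth sidecars
#'   keyed by `subject_id`) and `config`.
#' @export
generate_cohort <- function(config, narratives = TRUE, lexicon = NULL) {
  validate_generator_config(config)
  if (narratives && is.null(lexicon)) lexicon <- read_lexicon()
  with_seed(config$seed, {
    nat <- gen_population(config$n_national, config, narratives = FALSE,
                          id_prefix = "N")
    # national table: only the seven shared fields (no dynamics, no text)
    national <- nat$subjects[, c("subject_id", "collision_id", "road_user",
                                 "age_band", "lighting", "speed_limit",
                                 "road_class", "vehicle_age_band",
                                 "overall_severity")]
    mult <- config$severity_oversampling
    p_acc <- mult / max(mult)
    acc <- list(); acc_truth <- list(); got <- 0L
    rate <- NA_real_
    while (got < config$n_indepth) {
      need <- config$n_indepth - got
      m <- if (is.na(rate)) max(200L, ceiling(need / 0.08))
           else ceiling(1.3 * need / max(rate, 0.01))
      pop <- gen_population(m, config, narratives = narratives,
                            lexicon = lexicon, id_prefix = "D")
      keep <- runif(m) < p_acc[pop$subjects$overall_severity]
      rate <- max(mean(keep), 0.005)
      acc[[length(acc) + 1L]] <- pop$subjects[keep, , drop = FALSE]
      acc_truth[[length(acc_truth) + 1L]] <- pop$truth[keep, , drop = FALSE]
      got <- got + sum(keep)
    }
    indepth <- do.call(rbind, acc)[seq_len(config$n_indepth), ]
    truth_indepth <- do.call(rbind, acc_truth)[seq_len(config$n_indepth), ]
    indepth$subject_id <- sprintf("D%06d", seq_len(config$n_indepth))
    truth_indepth$subject_id <- indepth$subject_id
    rownames(indepth) <- rownames(truth_indepth) <- NULL
    structure(list(national = national, indepth = indepth,
                   truth_national = nat$truth, truth_indepth = truth_indepth,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: national n =", nrow(x$national),
      "| in-depth n =", nrow(x$indepth), "| seed", x$config$seed, "\n")
  cat("In-depth severity mix:\n")
  print(round(prop.table(table(x$indepth$overall_severity)), 3))
  invisible(x)
}

#' Write a synthetic cohort to CSV
#'
#' Writes the national and in-depth tables, their ground-truth sidecars
#' (keyed by `subject_id`) and the generator configuration as JSON into a
#' directory.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(national = file.path(dir, "national.csv"),
             indepth = file.path(dir, "indepth.csv"),
             truth_national = file.path(dir, "truth_national.csv"),
             truth_indepth = file.path(dir, "truth_indepth.csv"),
             config = file.path(dir, "generator_config.json"))
  write.csv(cohort$national, paths["national"], row.names = FALSE)
  write.csv(cohort$indepth, paths["indepth"], row.names = FALSE)
  write.csv(cohort$truth_national, paths["truth_national"], row.names = FALSE)
  write.csv(cohort$truth_indepth, paths["truth_indepth"], row.names = FALSE)
  jsonlite::write_json(unclass(cohort$config), paths["config"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
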