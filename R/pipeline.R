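#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Exactly
#' one data source must be supplied: either paths to existing subject and
#' national CSV tables, or a [generator_config()] to simulate them.
#'
#' @param generator optional [generator_config()].
#' @param subject_csv,national_csv optional input CSV paths.
#' @param lexicon_path lexicon JSON (default the packaged one).
#' @param scaling_candidates candidate fields for scaling-field selection.
#' @param national_total national casualty total to scale to (default: the
#'   national table's row count).
#' @param period_years observation window for annualisation.
#' @param risk list of risk-model settings: `k`, `repeats`, `grid`,
#'   `n_boot`, `seed`.
#' @param output_dir directory for stage outputs (`NULL`: nothing written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = NULL, subject_csv = NULL,
                            national_csv = NULL,
                            lexicon_path = system.file("extdata", "tbi_lexicon.json",
                                                       package = "roadtbi"),
                            scaling_candidates = c("road_user", "age_band",
                                                   "lighting", "speed_limit",
                                                   "road_class", "vehicle_age_band",
                                                   "overall_severity"),
                            national_total = NULL, period_years = 1,
                            risk = list(k = 5, repeats = 200, grid = 0:100,
                                        n_boot = 10000, seed = 1L),
                            output_dir = NULL) {
  from_files <- !is.null(subject_csv) || !is.null(national_csv)
  if (is.null(generator) == !from_files)
    stop("supply exactly one of: a generator config, or subject/national CSV paths")
  if (from_files && (is.null(subject_csv) || is.null(national_csv)))
    stop("both subject_csv and national_csv are required in file mode")
  risk <- utils::modifyList(list(k = 5, repeats = 200, grid = 0:100,
                                 n_boot = 10000, seed = 1L), risk)
  structure(list(generator = generator, subject_csv = subject_csv,
                 national_csv = national_csv, lexicon_path = lexicon_path,
                 scaling_candidates = scaling_candidates,
                 national_total = national_total, period_years = period_years,
                 risk = risk, output_dir = output_dir),
            class = "pipeline_config")
}

required_subject_columns <- c("subject_id", "road_user", "overall_severity",
                              "narrative", "gcs", "loc_minutes", "pta_hours")

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: free-text TBI classification,
#' dynamics eligibility, prevalence and relative-risk tables, national
#' scaling, bootstrapped cumulative delta-V distributions, and
#' cross-validated injury-risk curves, with a run manifest recording seeds
#' and row counts at every stage. Stage outputs are returned as a bundle
#' and, when `output_dir` is set, written as CSV/JSON.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_bundle` list: `classification`, `dynamics`,
#'   `prevalence`, `relative_risk`, `divergence`, `scaling_fields`,
#'   `weights`, `national_estimates`, `cumulative_curves`, `risk_curves`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "load"
  tryCatch({
    lexicon <- read_lexicon(config$lexicon_path)
    if (!is.null(config$generator)) {
      cohort <- generate_cohort(config$generator, lexicon = lexicon)
      indepth <- cohort$indepth
      national <- cohort$national
    } else {
      indepth <- read.csv(config$subject_csv, stringsAsFactors = FALSE)
      national <- read.csv(config$national_csv, stringsAsFactors = FALSE)
    }
    missing_cols <- setdiff(required_subject_columns, names(indepth))
    if (length(missing_cols))
      stop("subject table is missing required column(s): ",
           paste(missing_cols, collapse = ", "))

    stage <- "classification"
    cls <- classify_subjects(indepth, lexicon)
    profiles <- cls$profiles
    profiles$tbi <- profiles$mayo_severity != "none"
    profiles$modsev <- profiles$mayo_severity == "moderate_severe"

    stage <- "dynamics"
    if (!"total_dv" %in% names(indepth) &&
        all(c("lateral_dv", "longitudinal_dv") %in% names(indepth)))
      indepth$total_dv <- total_delta_v(indepth$lateral_dv, indepth$longitudinal_dv)
    elig <- eligibility(indepth)
    dynamics <- cbind(indepth[, intersect(c("subject_id", "road_user", "lateral_dv",
                                            "longitudinal_dv", "total_dv",
                                            "dominance"), names(indepth))], elig)

    stage <- "cohort_stats"
    dat <- cbind(indepth, profiles[match(indepth$subject_id, profiles$subject_id),
                                   c("tbi", "modsev", "SDH", "SAH", "EDH", "focal",
                                     "DAI", "skull_fracture")])
    prevalence <- list(
      tbi_by_road_user = prevalence_table(dat, "tbi", "road_user"),
      modsev_by_road_user = prevalence_table(dat, "modsev", "road_user"))
    vru <- dat$road_user %in% vru_users
    rr <- relative_risk(sum(dat$modsev & vru), sum(vru),
                        sum(dat$modsev & !vru), sum(!vru))
    chisq <- chi_square_independence(table(dat$road_user, dat$tbi))

    stage <- "national_scaling"
    cand <- intersect(config$scaling_candidates, intersect(names(dat), names(national)))
    divergence <- field_divergence_tests(dat, national, cand)
    sel <- select_scaling_fields(dat, setdiff(cand, "overall_severity"))
    # weight within severity strata when severity is not itself selected
    wfields <- unique(c("overall_severity", sel))
    weights <- compute_weights(dat, national, wfields)
    ntot <- config$national_total %||% nrow(national)
    estimates <- scale_estimates(dat, weights, c("tbi", "modsev"), ntot,
                                 config$period_years)

    stage <- "cumulative_curves"
    rs <- config$risk
    ok <- elig$include & !is.na(dat$total_dv)
    curves <- list()
    grp <- function(sel) dat$total_dv[ok & sel]
    pairs <- list(car_modsev = ok & !vru & dat$modsev,
                  car_no_tbi = ok & !vru & !dat$tbi,
                  vru_modsev = ok & vru & dat$modsev,
                  vru_no_tbi = ok & vru & !dat$tbi)
    for (nm in names(pairs)) {
      v <- dat$total_dv[pairs[[nm]]]
      if (length(v) >= 5)
        curves[[nm]] <- cumulative_distribution_with_ci(v, n_boot = rs$n_boot,
                                                        seed = rs$seed)
    }

    stage <- "risk_curves"
    risk_curves <- list()
    for (g in c("car", "vru")) {
      sub <- dat[ok & (if (g == "vru") vru else !vru), ]
      if (nrow(sub) >= 50 && length(unique(sub$modsev)) == 2)
        risk_curves[[g]] <- cross_validated_risk_curve(
          sub, "total_dv", "modsev", k = rs$k, repeats = rs$repeats,
          grid = rs$grid, base_seed = rs$seed)
    }

    manifest <- list(
      package_version = as.character(utils::packageVersion("roadtbi")),
      seed = config$generator$seed %||% NA,
      risk_seed = rs$seed,
      rows = list(indepth = nrow(indepth), national = nrow(national),
                  hits = nrow(cls$hits), eligible = sum(elig$include)),
      exclusions = as.list(table(elig$reason)))

    bundle <- structure(list(classification = cls, dynamics = dynamics,
                             prevalence = prevalence, relative_risk = rr,
                             chi_square = chisq, divergence = divergence,
                             scaling_fields = sel, weights = weights,
                             national_estimates = estimates,
                             cumulative_curves = curves,
                             risk_curves = risk_curves,
                             manifest = manifest),
                        class = "pipeline_bundle")
    if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
    bundle
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$classification$hits, file.path(dir, "classification_audit.csv"),
            row.names = FALSE)
  write.csv(bundle$classification$profiles, file.path(dir, "profiles.csv"),
            row.names = FALSE)
  write.csv(bundle$dynamics, file.path(dir, "dynamics_eligibility.csv"),
            row.names = FALSE)
  write.csv(bundle$prevalence$modsev_by_road_user,
            file.path(dir, "prevalence_modsev.csv"), row.names = FALSE)
  write.csv(as.data.frame(bundle$weights), file.path(dir, "weight_table.csv"),
            row.names = FALSE)
  write.csv(bundle$national_estimates, file.path(dir, "national_estimates.csv"),
            row.names = FALSE)
  for (nm in names(bundle$cumulative_curves)) {
    cc <- bundle$cumulative_curves[[nm]]
    write.csv(data.frame(grid = cc$grid, proportion = cc$proportion,
                         band_low = cc$band_low, band_high = cc$band_high),
              file.path(dir, paste0("cdf_", nm, ".csv")), row.names = FALSE)
  }
  for (nm in names(bundle$risk_curves)) {
    rc <- bundle$risk_curves[[nm]]
    write.csv(data.frame(grid = rc$grid, risk_median = rc$risk_median,
                         risk_low = rc$risk_low, risk_high = rc$risk_high),
              file.path(dir, paste0("risk_curve_", nm, ".csv")), row.names = FALSE)
    jsonlite::write_json(list(n = rc$fit$n, k = rc$k, repeats = rc$repeats,
                              base_seed = rc$base_seed, auc_mean = rc$auc_mean,
                              auc_ci = rc$auc_ci),
                         file.path(dir, paste0("risk_curve_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("Pipeline bundle\n")
  cat("  subjects:", x$manifest$rows$indepth, "in-depth,",
      x$manifest$rows$national, "national\n")
  cat("  eligible dynamics records:", x$manifest$rows$eligible, "\n")
  cat("  scaling fields:", paste(x$scaling_fields, collapse = ", "), "\n")
  for (nm in names(x$risk_curves))
    cat(sprintf("  %s risk model AUC %.3f\n", nm, x$risk_curves[[nm]]$auc_mean))
  invisible(x)
}

#' Read the packaged printed-count fixture
#'
#' Named count tables transcribed from the published study report: road-user
#' group sizes, TBI severity and pathology counts, the cyclist helmet 2x2
#' tables and national casualty totals. These drive
#' [reproduce_paper_tables()] without any access to the restricted source
#' databases.
#'
#' @param path fixture CSV (default the packaged copy).
#' @return Named numeric vector of counts.
#' @export
read_paper_fixture <- function(path = system.file("extdata", "paper_counts.csv",
                                                  package = "roadtbi")) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  fx <- setNames(d$value, d$item)
  stopifnot(fx[["tbi_total"]] <= fx[["casualties_total"]],
            fx[["casualties_total"]] <= fx[["subjects_total"]],
            all(fx[c("sah_total", "focal_total", "skull_fracture_total",
                     "sdh_total", "dai_total")] <= fx[["tbi_total"]]))
  fx
}

#' Recompute the published summary quantities from the count fixture
#'
#' Recomputes every printed percentage and the annualised national casualty
#' figure from the raw fixture counts, through the same prevalence and
#' scaling operations the pipeline uses, and compares against the printed
#' values at their printed rounding precision.
#'
#' @param fixture a [read_paper_fixture()] vector.
#' @return Data frame with `claim`, `computed`, `printed`, `match`.
#' @examples
#' reproduce_paper_tables()
#' @export
reproduce_paper_tables <- function(fixture = read_paper_fixture()) {
  fx <- as.list(fixture)
  groups <- c("pedestrian", "cyclist", "motorcyclist", "car_occupant",
              "van_occupant", "hgv_occupant")
  gsize <- unlist(fx[paste0("n_", sub("_occupant", "_occupant", groups))])
  names(gsize) <- groups
  gms <- unlist(fx[paste0("modsev_", groups)])
  # expand counts to a subject table and run the standard prevalence op
  subj <- data.frame(road_user = rep(groups, gsize))
  subj$modsev <- unlist(lapply(groups, function(g)
    rep(c(TRUE, FALSE), c(gms[[paste0("modsev_", g)]],
                          gsize[[g]] - gms[[paste0("modsev_", g)]]))))
  prev <- prevalence_table(subj, "modsev", "road_user")
  pct <- function(a, n) round(100 * a / n, 1)

  # annualised national casualties through the identity-scaling path
  toy <- data.frame(stratum = rep("all", 10), casualty = TRUE)
  w1 <- compute_weights(toy, toy, "stratum", min_count = 1)
  est <- scale_estimates(toy, w1, "casualty", fx$national_casualties,
                         fx$period_years)

  claims <- list(
    list("tbi_prevalence_pct", pct(fx$tbi_total, fx$casualties_total), 20.2, 1),
    list("modsev_share_pct", pct(fx$tbi_moderate_severe, fx$tbi_total), 52.9, 1),
    list("mild_share_pct", pct(fx$tbi_mild_probable, fx$tbi_total), 22.4, 1),
    list("symptomatic_share_pct", pct(fx$tbi_symptomatic_possible, fx$tbi_total), 24.4, 1),
    list("sah_subject_pct", pct(fx$sah_total, fx$subjects_total), 3.2, 1),
    list("skull_fracture_subject_pct", pct(fx$skull_fracture_total, fx$subjects_total), 3.3, 1),
    list("sdh_subject_pct", pct(fx$sdh_total, fx$subjects_total), 1.8, 1),
    list("focal_subject_pct", pct(fx$focal_total, fx$subjects_total), 3.1, 1),
    list("dai_subject_pct", pct(fx$dai_total, fx$subjects_total), 0.5, 1),
    list("dai_tbi_share_pct", pct(fx$dai_total, fx$tbi_total), 4.4, 1),
    list("modsev_pedestrian_pct", prev$percent[prev$group == "pedestrian"], 36.1, 1),
    list("modsev_cyclist_pct", prev$percent[prev$group == "cyclist"], 25.9, 1),
    list("modsev_motorcyclist_pct", prev$percent[prev$group == "motorcyclist"], 17.2, 1),
    list("modsev_car_occupant_pct", prev$percent[prev$group == "car_occupant"], 4.2, 1),
    list("modsev_van_occupant_pct", prev$percent[prev$group == "van_occupant"], 4.1, 1),
    list("modsev_hgv_occupant_pct", prev$percent[prev$group == "hgv_occupant"], 2.7, 1),
    list("skull_fracture_pedestrian_pct",
         pct(fx$skull_fracture_pedestrian, fx$n_pedestrian), 23.6, 1),
    list("annual_casualties", est$annual_count, 176000, -3))
  out <- do.call(rbind, lapply(claims, function(cl) {
    computed <- as.numeric(cl[[2]])
    digits <- cl[[4]]
    data.frame(claim = cl[[1]], computed = computed, printed = cl[[3]],
               match = round(computed, digits) == cl[[3]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Helmet-protection tests from the printed cyclist counts
#'
#' Rebuilds the helmeted/non-helmeted 2x2 tables for skull fracture and SDH
#' from the fixture counts and runs Fisher's exact test and the relative
#' risk calculation on them.
#'
#' @param fixture a [read_paper_fixture()] vector.
#' @return List with `skull_fracture` and `sdh`, each holding `table`,
#'   `fisher` (a `test_result`) and `rr` (an `rr_result`).
#' @export
helmet_analysis <- function(fixture = read_paper_fixture()) {
  fx <- as.list(fixture)
  build <- function(h_events, nh_events) {
    tab <- matrix(c(h_events, fx$helmeted_n - h_events,
                    nh_events, fx$nonhelmeted_n - nh_events),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("helmeted", "non_helmeted"),
                                  c("event", "no_event")))
    list(table = tab,
         fisher = fisher_exact(tab),
         rr = relative_risk(nh_events, fx$nonhelmeted_n, h_events, fx$helmeted_n))
  }
  list(skull_fracture = build(fx$helmeted_skull_fracture, fx$nonhelmeted_skull_fracture),
       sdh = build(fx$helmeted_sdh, fx$nonhelmeted_sdh))
}
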