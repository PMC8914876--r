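#' Per-field divergence tests between in-depth and national tables
#'
#' For each shared categorical field, tests whether the level distribution
#' differs between the in-depth sample and the national table with a
#' Pearson chi-square test on the dataset-by-level contingency table. A
#' significant divergence on a field is the motivation for re-weighting on
#' it.
#'
#' @param indepth,national data frames sharing the candidate fields.
#' @param fields character vector of field names.
#' @return Data frame with one row per field: `field`, `statistic`, `df`,
#'   `p_value`.
#' @export
field_divergence_tests <- function(indepth, national, fields) {
  for (f in fields) {
    if (!f %in% names(indepth)) stop("field missing in in-depth table: ", f)
    if (!f %in% names(national)) stop("field missing in national table: ", f)
  }
  rows <- lapply(fields, function(f) {
    levs <- sort(unique(c(as.character(indepth[[f]]), as.character(national[[f]]))))
    tab <- rbind(indepth = table(factor(indepth[[f]], levels = levs)),
                 national = table(factor(national[[f]], levels = levs)))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    tr <- chi_square_independence(tab)
    data.frame(field = f, statistic = tr$statistic, df = tr$df,
               p_value = tr$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the scaling fields that best predict overall injury severity
#'
#' Exhaustive search over all single fields and unordered field pairs,
#' scoring each candidate cluster definition by the cross-validated
#' misclassification rate of a majority-class-per-cluster predictor of
#' `overall_severity`. With a handful of candidate fields the search space
#' is tiny, fully deterministic and auditable, which a recursive
#' partitioning fit is not. Ties break towards fewer fields, then
#' lexicographic field order.
#'
#' @param indepth data frame with `overall_severity` and the candidates.
#' @param candidate_fields character vector of categorical candidates.
#' @param max_fields maximum fields to select (1 or 2; default 2).
#' @param k cross-validation folds (default 5).
#' @param seed seed for the deterministic fold assignment.
#' @return Character vector of selected field names; scores for every
#'   candidate set in `attr(, "scores")`.
#' @export
select_scaling_fields <- function(indepth, candidate_fields, max_fields = 2,
                                  k = 5, seed = 1L) {
  if (length(candidate_fields) == 0) stop("no candidate fields supplied")
  stopifnot("overall_severity" %in% names(indepth), max_fields >= 1)
  sets <- lapply(candidate_fields, function(f) f)
  if (max_fields >= 2 && length(candidate_fields) >= 2) {
    prs <- combn(sort(candidate_fields), 2, simplify = FALSE)
    sets <- c(sets, prs)
  }
  n <- nrow(indepth)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  y <- as.character(indepth$overall_severity)
  score_set <- function(fields) {
    key <- do.call(paste, c(lapply(fields, function(f) as.character(indepth[[f]])),
                            sep = "\r"))
    errs <- vapply(seq_len(k), function(fold) {
      tr <- folds != fold
      maj_all <- names(which.max(table(y[tr])))
      maj <- tapply(y[tr], key[tr], function(v) names(which.max(table(v))))
      pred <- maj[key[!tr]]
      pred[is.na(pred)] <- maj_all
      mean(pred != y[!tr])
    }, numeric(1))
    mean(errs)
  }
  scores <- vapply(sets, score_set, numeric(1))
  labels <- vapply(sets, function(s) paste(sort(s), collapse = "+"), character(1))
  ord <- order(scores, lengths(sets), labels)
  best <- sets[[ord[1]]]
  structure(sort(best),
            scores = data.frame(fields = labels, n_fields = lengths(sets),
                                cv_error = scores, stringsAsFactors = FALSE))
}

cluster_key <- function(df, fields, sep = "\r") {
  do.call(paste, c(lapply(fields, function(f) as.character(df[[f]])), sep = sep))
}

#' Post-stratification weight table
#'
#' Clusters both tables by the Cartesian levels of the selected fields and
#' maps each cluster's national proportion onto its in-depth proportion;
#' the weight is the ratio `p_national / p_indepth`. Sparse in-depth
#' clusters (below `min_count`) are first merged into the nearest cluster
#' sharing all but one field level (the neighbour with the largest in-depth
#' count, lexicographic tie-break) so that unbounded weights cannot arise
#' from sampling noise. A cluster with national mass but no in-depth
#' members even after merging is flagged with an undefined weight and
#' excluded from estimates (reported, not dropped silently).
#'
#' @param indepth,national data frames sharing `fields`.
#' @param fields character vector of cluster-defining fields.
#' @param min_count in-depth count floor below which clusters merge
#'   (default 5).
#' @return A `weight_table` data frame: one row per (merged) cluster with
#'   the field levels, `n_indepth`, `n_national`, `p_indepth`, `p_national`
#'   and `weight` (`NA` when undefined). The record-level cluster
#'   assignment map is in `attr(, "assignment")`.
#' @export
compute_weights <- function(indepth, national, fields, min_count = 5) {
  for (f in fields) {
    if (!f %in% names(indepth)) stop("field missing in in-depth table: ", f)
    if (!f %in% names(national)) stop("field missing in national table: ", f)
  }
  sep <- "\r"
  key_i <- cluster_key(indepth, fields, sep)
  key_n <- cluster_key(national, fields, sep)
  keys <- sort(unique(c(key_i, key_n)))
  n_i <- table(factor(key_i, levels = keys))
  n_n <- table(factor(key_n, levels = keys))
  # merge sparse clusters into the largest neighbour differing in one field
  assign_to <- setNames(keys, keys)
  counts <- as.numeric(n_i); names(counts) <- keys
  parts <- strsplit(keys, sep, fixed = TRUE)
  sev_idx <- match("overall_severity", fields)
  # a mergeable neighbour differs in exactly one field level; merging never
  # crosses overall-severity strata (severity is the axis the in-depth
  # sampling distorts, so mixing strata would re-introduce the bias)
  neighbour <- function(a, b) {
    pa <- parts[[match(a, keys)]]; pb <- parts[[match(b, keys)]]
    if (!is.na(sev_idx) && length(pa) > 1 && pa[sev_idx] != pb[sev_idx])
      return(FALSE)
    sum(pa != pb) == 1 || length(pa) == 1
  }
  frozen <- character(0)  # sparse clusters with no mergeable neighbour
  repeat {
    eff <- tapply(counts, assign_to[names(counts)], sum)
    small <- setdiff(names(eff)[eff < min_count], frozen)
    if (length(small) == 0 || length(eff) == 1) break
    # smallest first, lexicographic tie-break
    small <- small[order(eff[small], small)]
    s <- small[1]
    cands <- setdiff(names(eff), s)
    cands <- cands[vapply(cands, function(c) neighbour(s, c), logical(1))]
    if (length(cands) == 0) { frozen <- c(frozen, s); next }
    target <- cands[order(-eff[cands], cands)][1]
    assign_to[assign_to == s] <- target
  }
  final <- sort(unique(assign_to))
  n_i_m <- vapply(final, function(fk) sum(n_i[assign_to == fk]), numeric(1))
  n_n_m <- vapply(final, function(fk) sum(n_n[assign_to == fk]), numeric(1))
  p_i <- n_i_m / sum(n_i_m)
  p_n <- n_n_m / sum(n_n_m)
  weight <- ifelse(p_i > 0, p_n / p_i, NA_real_)
  lev <- do.call(rbind, strsplit(final, sep, fixed = TRUE))
  colnames(lev) <- fields
  wt <- data.frame(lev, n_indepth = n_i_m, n_national = n_n_m,
                   p_indepth = p_i, p_national = p_n, weight = weight,
                   row.names = NULL, stringsAsFactors = FALSE)
  class(wt) <- c("weight_table", "data.frame")
  attr(wt, "fields") <- fields
  attr(wt, "assignment") <- assign_to
  attr(wt, "sep") <- sep
  wt
}

#' @export
print.weight_table <- function(x, ...) {
  cat("Post-stratification weight table over",
      paste(attr(x, "fields"), collapse = " x "), "\n")
  print.data.frame(x, digits = 4)
  und <- sum(is.na(x$weight))
  if (und) cat(und, "cluster(s) with undefined weight (no in-depth members)\n")
  invisible(x)
}

#' Scale in-depth outcome rates to national estimates
#'
#' The scaled national count for an outcome is the national total times the
#' weighted outcome rate `sum_c p_national(c) * rate_c`, where `rate_c` is
#' the outcome rate among in-depth members of cluster `c` — i.e. in-depth
#' rates post-stratified to the national cluster composition. The standard
#' error treats cluster rates as independent binomials. Records falling in
#' clusters with undefined weights are a coverage failure when they exceed
#' 5% of the sample.
#'
#' @param indepth data frame of in-depth records carrying the weight-table
#'   fields plus logical outcome columns.
#' @param weights a [compute_weights()] table.
#' @param outcomes character vector of logical outcome column names.
#' @param national_total national casualty total to scale to.
#' @param period_years observation window for annualisation.
#' @return Data frame with one row per outcome: `outcome`, `indepth_rate`
#'   (unweighted), `weighted_rate`, `scaled_count`, `annual_count`, `se`;
#'   unmapped-record fraction in `attr(, "unmapped")`.
#' @export
scale_estimates <- function(indepth, weights, outcomes, national_total,
                            period_years = 1) {
  fields <- attr(weights, "fields")
  sep <- attr(weights, "sep")
  assign_to <- attr(weights, "assignment")
  key <- cluster_key(indepth, fields, sep)
  final <- assign_to[key]
  wt_key <- cluster_key(weights, fields, sep)
  idx <- match(final, wt_key)
  mapped <- !is.na(idx) & !is.na(weights$weight[idx])
  unmapped <- mean(!mapped)
  if (unmapped > 0.05)
    stop(sprintf("coverage failure: %.1f%% of in-depth records map to no weighted cluster",
                 100 * unmapped))
  rows <- lapply(outcomes, function(oc) {
    y <- as.logical(indepth[[oc]])
    rate_c <- tapply(y[mapped], idx[mapped], mean)
    n_c <- tapply(y[mapped], idx[mapped], length)
    p_n <- weights$p_national[as.integer(names(rate_c))]
    p_n <- p_n / sum(p_n)  # renormalise over covered clusters
    wrate <- sum(p_n * rate_c)
    se_rate <- sqrt(sum(p_n^2 * rate_c * (1 - rate_c) / n_c))
    data.frame(outcome = oc,
               indepth_rate = mean(y),
               weighted_rate = wrate,
               scaled_count = national_total * wrate,
               annual_count = national_total * wrate / period_years,
               se = national_total * se_rate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "unmapped") <- unmapped
  out
}
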