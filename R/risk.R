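#' Empirical cumulative delta-V distribution with bootstrap bands
#'
#' Normalised cumulative frequency distribution of a delta-V sample on the
#' grid of its distinct values, with pointwise percentile confidence bands
#' from bootstrap resamples with replacement. Resampling is implemented by
#' drawing multinomial counts over the distinct values, which is
#' distributionally identical to resampling the raw values and lets the
#' full band computation stay vectorised.
#'
#' @param values non-empty numeric sample (km/h).
#' @param n_boot bootstrap resamples (default 10000).
#' @param conf band coverage (default 0.95: 2.5th/97.5th percentiles).
#' @param seed optional integer seed; bands are reproducible given a seed.
#' @return A `cumulative_curve` list: `grid` (sorted distinct values),
#'   `proportion` (ECDF at each grid point), `band_low`, `band_high`, `n`,
#'   `n_boot`.
#' @export
cumulative_distribution_with_ci <- function(values, n_boot = 10000,
                                            conf = 0.95, seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("empty sample")
  n <- length(values)
  tab <- table(values)
  grid <- as.numeric(names(tab))
  prop <- cumsum(as.numeric(tab)) / n
  draw <- function() {
    cnt <- rmultinom(n_boot, n, prob = as.numeric(tab) / n)
    ecdfs <- apply(cnt, 2, cumsum) / n            # grid x n_boot
    if (is.null(dim(ecdfs))) ecdfs <- matrix(ecdfs, nrow = 1)
    alpha <- (1 - conf) / 2
    t(apply(ecdfs, 1, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  }
  bands <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(grid = grid, proportion = prop,
                 band_low = pmin(bands[, 1], prop),
                 band_high = pmax(bands[, 2], prop),
                 n = n, n_boot = n_boot, conf = conf),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("Cumulative distribution: n = %d, %d grid points, %d bootstrap resamples (%.0f%% bands)\n",
              x$n, length(x$grid), x$n_boot, 100 * x$conf))
  invisible(x)
}

#' Unpenalized maximum-likelihood logistic fit
#'
#' Binary logistic regression by unpenalized maximum likelihood, with the
#' coefficient covariance from the inverse observed information. Complete
#' (or quasi-complete) separation is reported via `converged = FALSE`
#' rather than silently returning divergent coefficients: it is detected
#' when every fitted probability has collapsed to the 0/1 boundary.
#'
#' @param design data frame or matrix of predictors (at least one column).
#' @param outcome binary vector (0/1 or logical); both classes required.
#' @return A `logistic_fit` list: `coefficients`, `covariance`,
#'   `converged`, `n`, `predictors`, and the underlying `glm` object.
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.data.frame(design)
  stopifnot(ncol(design) >= 1)
  y <- as.integer(as.logical(outcome))
  if (length(unique(y)) < 2)
    stop("outcome has a single class; logistic fit undefined")
  dat <- cbind(.y = y, design)
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 500)))
  eps <- 1e-8
  separated <- all(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  structure(list(coefficients = coef(fit),
                 covariance = vcov(fit),
                 converged = fit$converged && !separated,
                 n = length(y),
                 predictors = names(design),
                 glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit on n =", x$n, if (x$converged) "(converged)" else "(NOT converged)", "\n")
  se <- sqrt(diag(x$covariance))
  print(data.frame(coef = x$coefficients, se = se,
                   or = exp(x$coefficients)), digits = 4)
  invisible(x)
}

#' Predicted risk from a logistic fit on a delta-V grid
#'
#' @param fit a `logistic_fit` or `glm` object.
#' @param grid numeric vector for the first predictor (delta-V, km/h).
#' @param at named list fixing the remaining predictors (default 0 /
#'   reference).
#' @return Vector of predicted probabilities on the grid.
#' @export
predict_risk <- function(fit, grid, at = list()) {
  g <- if (inherits(fit, "logistic_fit")) fit$glm else fit
  vars <- attr(g$terms, "term.labels")
  nd <- data.frame(grid)
  names(nd) <- vars[1]
  for (v in vars[-1]) nd[[v]] <- at[[v]] %||% 0
  as.numeric(predict(g, newdata = nd, type = "response"))
}

#' ROC area under the curve
#'
#' Computed as the Mann-Whitney probability of concordance: the chance a
#' randomly chosen positive outscores a randomly chosen negative, with
#' ties counting one half.
#'
#' @param scores numeric predictions.
#' @param labels binary outcomes (both classes required).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both outcome classes required for AUC")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Minimum sample size for a logistic risk model
#'
#' Events-per-variable style guideline `N = 10 k / p`, where `k` is the
#' number of covariates and `p` the smallest of the positive/negative case
#' proportions; rounded up.
#'
#' @param k number of covariate predictors (>= 1).
#' @param p smallest class proportion, in (0, 0.5].
#' @return Required N (integer).
#' @examples
#' sample_size_check(1, 0.1)  # 100
#' @export
sample_size_check <- function(k, p) {
  stopifnot(k >= 1)
  if (!is.numeric(p) || p <= 0) stop("smallest class proportion p must be > 0")
  if (p > 0.5) stop("p is the smallest class proportion and cannot exceed 0.5")
  as.integer(ceiling(10 * k / p))
}

# outcome-stratified fold assignment; returns NULL when any held-out fold
# lacks one of the classes (caller reshuffles with the next seed)
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  for (f in seq_len(k)) {
    if (length(unique(y[fold == f])) < 2 || length(unique(y[fold != f])) < 2)
      return(NULL)
  }
  fold
}

#' Cross-validated logistic injury-risk curve
#'
#' Repeated, outcome-stratified k-fold cross-validation of a logistic risk
#' model. For every repeat the data are shuffled with a prespecified seed
#' (`base_seed + repeat`) and split into `k` outcome-stratified folds; one
#' model is fitted per training split, giving `k * repeats` fold-models.
#' Each fold-model's predicted risk is evaluated on the delta-V grid, and
#' the pointwise median and 2.5th/97.5th percentiles of those curves form
#' the reported risk curve and band. ROC AUC is computed on each held-out
#' fold and summarised by its mean and percentile interval. A repeat whose
#' folds do not contain both classes is reshuffled with the next seed (and
#' logged in the result).
#'
#' @param data data frame containing predictors and outcome.
#' @param predictors character vector of predictor columns; the first is
#'   the delta-V axis of the curve.
#' @param outcome name of the binary outcome column.
#' @param k folds (default 5).
#' @param repeats shuffle repeats (default 200).
#' @param grid delta-V grid, km/h (default 0-100 in 1 km/h steps).
#' @param base_seed seed policy: repeat r uses `base_seed + r`.
#' @param conf band coverage (default 0.95).
#' @return A `risk_curve` list: `grid`, `risk_median`, `risk_low`,
#'   `risk_high`, `auc_mean`, `auc_ci`, `aucs`, `k`, `repeats`,
#'   `iterations` (= k * repeats), `curves` (iterations x grid matrix),
#'   `fit` (full-data fit for odds ratios), `reshuffled` (count).
#' @export
cross_validated_risk_curve <- function(data, predictors, outcome, k = 5,
                                       repeats = 200, grid = 0:100,
                                       base_seed = 1L, conf = 0.95) {
  stopifnot(all(predictors %in% names(data)), outcome %in% names(data))
  y <- as.integer(as.logical(data[[outcome]]))
  if (length(unique(y)) < 2) stop("both outcome classes required")
  p_min <- min(mean(y), 1 - mean(y))
  n_req <- sample_size_check(length(predictors), p_min)
  if (nrow(data) < n_req)
    warning(sprintf("sample size %d below the N = 10k/p guideline (%d)",
                    nrow(data), n_req))
  design <- data[, predictors, drop = FALSE]
  curves <- matrix(NA_real_, nrow = k * repeats, ncol = length(grid))
  aucs <- numeric(k * repeats)
  reshuffled <- 0L
  seed <- base_seed
  for (r in seq_len(repeats)) {
    folds <- NULL
    while (is.null(folds)) {
      seed <- seed + 1L
      folds <- with_seed(seed, stratified_folds(y, k))
      if (is.null(folds)) reshuffled <- reshuffled + 1L
    }
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fit_logistic(design[tr, , drop = FALSE], y[tr])
      i <- (r - 1L) * k + f
      curves[i, ] <- predict_risk(fit, grid)
      te_scores <- predict(fit$glm, newdata = design[!tr, , drop = FALSE],
                           type = "response")
      aucs[i] <- roc_auc(te_scores, y[!tr])
    }
  }
  alpha <- (1 - conf) / 2
  qs <- apply(curves, 2, quantile, probs = c(alpha, 0.5, 1 - alpha),
              names = FALSE)
  structure(list(grid = grid,
                 risk_median = qs[2, ], risk_low = qs[1, ], risk_high = qs[3, ],
                 auc_mean = mean(aucs),
                 auc_ci = unname(quantile(aucs, c(alpha, 1 - alpha))),
                 aucs = aucs, k = k, repeats = repeats,
                 iterations = k * repeats, curves = curves,
                 fit = fit_logistic(design, y),
                 reshuffled = reshuffled, base_seed = base_seed),
            class = "risk_curve")
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("Injury risk curve: %d fold-models (k = %d x %d repeats), grid %g-%g km/h\n",
              x$iterations, x$k, x$repeats, min(x$grid), max(x$grid)))
  cat(sprintf("ROC AUC %.3f (%.3f-%.3f)\n", x$auc_mean, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Odds ratio from a logistic fit coefficient
#'
#' @param fit a converged `logistic_fit`.
#' @param predictor coefficient name.
#' @param conf confidence level (default 0.95).
#' @return List with `or`, `ci` (length-2), `z`, `z_p` (two-sided normal
#'   p-value of the coefficient).
#' @export
odds_ratio_from_fit <- function(fit, predictor, conf = 0.95) {
  if (!fit$converged) stop("odds ratios undefined: fit did not converge")
  if (!predictor %in% names(fit$coefficients))
    stop("predictor not in fit: ", predictor)
  b <- fit$coefficients[[predictor]]
  se <- sqrt(diag(fit$covariance))[[predictor]]
  z <- if (se > 0) b / se else sign(b) * Inf
  zq <- qnorm(1 - (1 - conf) / 2)
  list(or = exp(b), ci = exp(b + c(-1, 1) * zq * se),
       z = z, z_p = 2 * pnorm(abs(z), lower.tail = FALSE))
}
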