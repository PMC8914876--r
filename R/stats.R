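#' Prevalence of an outcome by group
#'
#' Tabulates how many subjects in each group sustained an outcome and the
#' corresponding percentage. The exact proportion is retained alongside the
#' display percentage, which is rounded to one decimal place as the
#' conventional reporting precision.
#'
#' @param subjects data frame.
#' @param outcome_flag name of a logical column (or a logical vector of
#'   length `nrow(subjects)`).
#' @param group_field name of a categorical column.
#' @return Data frame with `group`, `n_group`, `n_outcome`, `proportion`
#'   (exact) and `percent` (1 d.p.; `NA` for empty groups).
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), c(144, 100)),
#'                 y = rep(c(TRUE, FALSE, FALSE), c(34, 110, 100)))
#' prevalence_table(d, "y", "g")
#' @export
prevalence_table <- function(subjects, outcome_flag, group_field) {
  y <- if (is.character(outcome_flag) && length(outcome_flag) == 1)
    subjects[[outcome_flag]] else outcome_flag
  stopifnot(is.logical(y), length(y) == nrow(subjects))
  g <- as.character(subjects[[group_field]])
  levs <- if (is.factor(subjects[[group_field]])) levels(subjects[[group_field]]) else sort(unique(g))
  n_group <- vapply(levs, function(l) sum(g == l), integer(1))
  n_outcome <- vapply(levs, function(l) sum(y & g == l, na.rm = TRUE), integer(1))
  proportion <- ifelse(n_group > 0, n_outcome / n_group, NA_real_)
  data.frame(group = levs, n_group = n_group, n_outcome = n_outcome,
             proportion = proportion,
             percent = round(100 * proportion, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative risk with log-scale confidence interval
#'
#' Relative risk of an outcome between an exposed group (`a` events among
#' `A`) and a comparison group (`b` events among `B`):
#' `RR = (a/A) / (b/B)`, with standard error of `log(RR)` equal to
#' `sqrt(1/a + 1/b - 1/A - 1/B)` and the usual asymmetric interval
#' `exp(log(RR) +/- z * SE)`. No continuity correction is applied by
#' default; when `a` or `b` is zero the point estimate is computed where
#' defined and the interval is flagged undefined.
#'
#' @param a,A events and total in the exposed group.
#' @param b,B events and total in the comparison group.
#' @param conf confidence level (default 0.95).
#' @param correction add 0.5 to every cell before computing (off by default).
#' @return An `rr_result` list: `a`, `A`, `b`, `B`, `rr`, `se_log_rr`,
#'   `ci_low`, `ci_high`, `conf`, `ci_defined`.
#' @examples
#' relative_risk(12, 48, 2, 46)  # RR 5.75 (1.36-24.3)
#' @export
relative_risk <- function(a, A, b, B, conf = 0.95, correction = FALSE) {
  stopifnot(A > 0, B > 0, a >= 0, b >= 0, a <= A, b <= B)
  if (correction) { a <- a + 0.5; b <- b + 0.5; A <- A + 0.5; B <- B + 0.5 }
  rr <- (a / A) / (b / B)
  ci_defined <- a > 0 && b > 0
  if (ci_defined) {
    se <- sqrt(1 / a + 1 / b - 1 / A - 1 / B)
    z <- qnorm(1 - (1 - conf) / 2)
    ci <- exp(log(rr) + c(-1, 1) * z * se)
  } else {
    se <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(a = a, A = A, b = b, B = B, rr = rr, se_log_rr = se,
                 ci_low = ci[1], ci_high = ci[2], conf = conf,
                 ci_defined = ci_defined), class = "rr_result")
}

#' @export
print.rr_result <- function(x, ...) {
  cat(sprintf("RR = %.2f", x$rr))
  if (x$ci_defined)
    cat(sprintf(" (%.0f%% CI %.2f-%.2f)", 100 * x$conf, x$ci_low, x$ci_high))
  else cat(" (CI undefined: zero events in a group)")
  cat(sprintf("  [%d/%d vs %d/%d]\n", x$a, x$A, x$b, x$B))
  invisible(x)
}

test_result <- function(statistic, df, p_value, alternative, method) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(statistic = unname(statistic), df = df,
                 p_value = min(1, unname(p_value)),
                 alternative = alternative, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!is.na(x$df %||% NA)) paste0(", df = ", x$df) else "",
      ", p = ", format.pval(x$p_value, digits = 3),
      " (", x$alternative, ")\n", sep = "")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction, with
#' `df = (r - 1)(c - 1)` and the chi-square reference distribution.
#'
#' @param table matrix of non-negative counts, at least 2x2.
#' @return A `test_result` (`statistic`, `df`, `p_value`).
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square test undefined: a row or column marginal is zero")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  test_result(ct$statistic, unname(ct$parameter), ct$p.value,
              "two_sided", "Pearson chi-square")
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities
#' of all tables with fixed margins no more probable than the observed one.
#'
#' @param table 2x2 matrix of counts.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return A `test_result` with `df = NA`.
#' @examples
#' fisher_exact(matrix(c(2, 12, 44, 36), 2))  # helmet vs skull fracture
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, ncol(table) == 2)
  ft <- fisher.test(table, alternative = sub("two_sided", "two.sided", alternative))
  test_result(unname(ft$estimate), NA_integer_, ft$p.value, alternative,
              "Fisher exact")
}

#' One-sided Mann-Whitney U test
#'
#' U statistic for `x` relative to `y` with ties handled by midranks. For
#' small samples (total size at most 20) the p-value is computed by exact
#' enumeration over all assignments of the pooled ranks to the two groups
#' (the randomisation p-value, so the observed arrangement is included); for
#' larger samples the normal approximation with tie correction is used, with
#' no continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"greater"` tests whether `x` is stochastically larger
#'   than `y`; also `"less"` and `"two_sided"`.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   `NULL` (default) chooses by sample size.
#' @return A `test_result` whose statistic is U for `x`.
#' @examples
#' mann_whitney_one_sided(c(4, 5, 6), c(1, 2, 3), "greater")  # U = 9, p = 0.05
#' @export
mann_whitney_one_sided <- function(x, y,
                                   alternative = c("greater", "less", "two_sided"),
                                   exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (is.null(exact)) exact <- N <= 20
  if (exact) {
    idx <- combn(N, nx)
    Us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p_ge <- mean(Us >= U - eps)
    p_le <- mean(Us <= U + eps)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    mu <- nx * ny / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
    z <- (U - mu) / sqrt(sigma2)
    p <- switch(alternative,
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z),
                two_sided = 2 * pnorm(abs(z), lower.tail = FALSE))
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  test_result(U, NA_integer_, p, alternative, method)
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with tie correction and the chi-square approximation with
#' `df = number of groups - 1`.
#'
#' @param groups list of two or more non-empty numeric samples.
#' @return A `test_result`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("kruskal_wallis requires at least 2 groups")
  if (any(lengths(groups) == 0)) stop("all groups must be non-empty")
  kt <- kruskal.test(groups)
  test_result(kt$statistic, unname(kt$parameter), kt$p.value,
              "two_sided", "Kruskal-Wallis")
}

#' Shapiro-Wilk normality test
#'
#' Used as a gate to justify nonparametric methods for skewed delta-V
#' distributions; valid for sample sizes 3 to 5000.
#'
#' @param x numeric sample.
#' @return A `test_result` whose statistic is W.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(x) == 0) stop("Shapiro-Wilk undefined for a constant sample")
  st <- shapiro.test(x)
  test_result(st$statistic, NA_integer_, st$p.value, "two_sided", "Shapiro-Wilk")
}
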