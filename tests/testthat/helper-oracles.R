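# Independent brute-force oracles used to freeze expected values.
# These deliberately use different computational routes than the package.

# Fisher two-sided p by direct enumeration of all tables with the observed
# margins, table probability from binomial coefficients.
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  prob <- function(x) exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, prob, numeric(1))
  sum(ps[ps <= prob(a) * (1 + 1e-7)])
}

# U by pair counting (ties count one half) -- independent of midranks
oracle_mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact p over all assignments of pooled values to the two groups
oracle_mw_exact_p <- function(x, y, alternative = "greater") {
  pool <- c(x, y); nx <- length(x)
  idx <- combn(length(pool), nx)
  Us <- apply(idx, 2, function(i) oracle_mw_u(pool[i], pool[-i]))
  U <- oracle_mw_u(x, y)
  p_ge <- mean(Us >= U - 1e-9)
  p_le <- mean(Us <= U + 1e-9)
  switch(alternative, greater = p_ge, less = p_le,
         two_sided = min(1, 2 * min(p_ge, p_le)))
}

# Kruskal-Wallis H from the rank-sum formula with tie correction
oracle_kw_h <- function(groups) {
  pool <- unlist(groups)
  N <- length(pool)
  r <- rank(pool)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (N * (N + 1)) * sum(vapply(splits, function(ri)
    sum(ri)^2 / length(ri), numeric(1))) - 3 * (N + 1)
  ties <- table(pool)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# AUC by averaging over all positive-negative pairs
oracle_auc <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]; neg <- scores[!y]
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}

# Pearson chi-square by direct sum over cells
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# direct arithmetic for the relative-risk formulas
oracle_rr <- function(a, A, b, B) {
  rr <- (a / A) / (b / B)
  se <- sqrt(1 / a + 1 / b - 1 / A - 1 / B)
  list(rr = rr, se = se,
       ci = exp(log(rr) + c(-1, 1) * qnorm(0.975) * se))
}
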