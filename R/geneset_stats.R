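# Statistical kernel: permutation gene-set test, Fisher exact, Wilcoxon
# rank-sum, two-sample KS, and Benjamini-Hochberg adjustment. These are
# authored here (rather than delegated) because each carries an
# exhaustive-enumeration oracle in the test suite; base R equivalents are
# used there as independent cross-checks.

new_test_result <- function(method, statistic, p, alternative,
                            n_perm = NA_integer_, seed = NA_integer_,
                            extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   p = min(max(p, 0), 1), alternative = alternative,
                   n_perm = n_perm, seed = seed), extra),
            class = "prime_test")
}

#' @export
print.prime_test <- function(x, ...) {
  cat("<", x$method, "> statistic = ", signif(x$statistic, 5),
      ", p = ", signif(x$p, 4), " (", x$alternative, ")", sep = "")
  if (!is.na(x$n_perm)) cat(" [", x$n_perm, "permutations ]")
  cat("\n")
  invisible(x)
}

#' K-sample (two-group) permutation test on gene-set signal
#'
#' Compares a gene set's per-gene signal against the signal of all remaining
#' genes by permuting set membership over the pooled values. The statistic is
#' the difference in group means. P values are estimated with the add-one
#' rule `p = (1 + #extreme) / (n_perm + 1)` so a resampled p is never exactly
#' zero; when the number of distinct assignments `choose(n, n1)` is at most
#' `exact_limit`, the full enumeration is used instead and the p value is
#' exact.
#'
#' @param values_set per-gene signal for the gene set.
#' @param values_rest signal for all other genes.
#' @param n_perm number of random permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`,
#'   referring to `mean(values_set) - mean(values_rest)`.
#' @param exact_limit enumerate all assignments when `choose(n, n1)` is at
#'   most this.
#' @return a `prime_test` result.
#' @export
permutation_oneway_test <- function(values_set, values_rest, n_perm = 10000L,
                                    seed = 1L,
                                    alternative = c("two_sided", "greater", "less"),
                                    exact_limit = 20000L) {
  alternative <- match.arg(alternative)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  n_dropped <- sum(!is.finite(values_set)) + sum(!is.finite(values_rest))
  values_set <- values_set[is.finite(values_set)]
  values_rest <- values_rest[is.finite(values_rest)]
  n1 <- length(values_set); n2 <- length(values_rest)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pool <- c(values_set, values_rest)
  n <- n1 + n2
  obs <- mean(values_set) - mean(values_rest)
  tol <- 1e-12 * max(1, abs(obs))

  extremity <- function(stat) switch(alternative,
    two_sided = abs(stat) >= abs(obs) - tol,
    greater   = stat >= obs - tol,
    less      = stat <= obs + tol)

  tot <- sum(pool)
  stat_from_sum <- function(s1) s1 / n1 - (tot - s1) / n2

  if (choose(n, n1) <= exact_limit) {
    sums <- combn(pool, n1, sum)
    stats <- stat_from_sum(sums)
    p <- mean(extremity(stats))
    return(new_test_result("permutation_oneway", obs, p, alternative,
                           n_perm = length(stats), seed = NA_integer_,
                           extra = list(exact = TRUE, n_dropped = n_dropped)))
  }
  set.seed(seed)
  sums <- vapply(seq_len(n_perm),
                 function(i) sum(pool[sample.int(n, n1)]), numeric(1))
  stats <- stat_from_sum(sums)
  p <- (1 + sum(extremity(stats))) / (n_perm + 1)
  new_test_result("permutation_oneway", obs, p, alternative,
                  n_perm = n_perm, seed = seed,
                  extra = list(exact = FALSE, n_dropped = n_dropped))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p value by summing, over the hypergeometric support at the
#' observed margins, every table probability not exceeding the observed
#' table's probability (with a small relative tolerance, as in base R). A
#' table with an empty margin has p = 1 by convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (on the first
#'   cell).
#' @return a `prime_test` with the sample odds ratio in `$odds_ratio`.
#' @export
fisher_2x2 <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + c; n_ <- b + d; k <- a + b
  or <- (a * d) / (b * c)
  if (m == 0 || n_ == 0 || k == 0 || (c + d) == 0)
    return(new_test_result("fisher_2x2", or, 1, alternative))
  lo <- max(0, k - n_); hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  p <- switch(alternative,
    two_sided = sum(dens[dens <= p_obs * (1 + 1e-7)]),
    greater   = sum(dens[support >= a]),
    less      = sum(dens[support <= a]))
  new_test_result("fisher_2x2", or, p, alternative,
                  extra = list(odds_ratio = or))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties. Exact p by full enumeration of group assignments when
#' the combined sample size is at most `exact_limit`; otherwise a normal
#' approximation with continuity and tie correction. The branch used is
#' recorded in the result.
#'
#' @param x,y the two samples.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (x shifted
#'   relative to y).
#' @param exact_limit combined-size threshold for the exact branch.
#' @return a `prime_test`; the statistic is the Mann-Whitney U for `x`.
#' @export
wilcoxon_ranksum <- function(x, y,
                             alternative = c("two_sided", "greater", "less"),
                             exact_limit = 12L) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("each sample must have >= 1 observation")
  n <- n1 + n2
  r <- rank(c(x, y))
  u_of <- function(rx) sum(rx) - n1 * (n1 + 1) / 2
  u <- u_of(r[seq_len(n1)])
  mu <- n1 * n2 / 2

  if (n <= exact_limit) {
    idx <- combn(n, n1)
    us <- apply(idx, 2L, function(i) u_of(r[i]))
    tol <- 1e-9
    p <- switch(alternative,
      two_sided = mean(abs(us - mu) >= abs(u - mu) - tol),
      greater   = mean(us >= u - tol),
      less      = mean(us <= u + tol))
    return(new_test_result("wilcoxon_ranksum", u, p, alternative,
                           extra = list(exact = TRUE)))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  sigma <- sqrt(sigma2)
  cc <- 0.5
  z <- switch(alternative,
    two_sided = (u - mu - sign(u - mu) * cc) / sigma,
    greater   = (u - mu - cc) / sigma,
    less      = (u - mu + cc) / sigma)
  p <- switch(alternative,
    two_sided = 2 * pnorm(-abs(z)),
    greater   = pnorm(z, lower.tail = FALSE),
    less      = pnorm(z))
  new_test_result("wilcoxon_ranksum", u, min(p, 1), alternative,
                  extra = list(exact = FALSE))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` by a sweep over the pooled order statistics.
#' The p value uses the asymptotic KS distribution with the
#' Stephens small-sample correction of the effective sample size; a
#' permutation p is available for small samples.
#'
#' @param x,y the two samples.
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm,seed permutation settings when `method = "permutation"`.
#' @return a `prime_test`; the statistic is D.
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "permutation"),
                          n_perm = 2000L, seed = 1L) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("each sample must have >= 1 observation")
  d <- ks_d_statistic(x, y)
  if (method == "permutation") {
    set.seed(seed)
    pool <- c(x, y)
    ds <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n1 + n2, n1)
      ks_d_statistic(pool[idx], pool[-idx])
    }, numeric(1))
    p <- (1 + sum(ds >= d - 1e-12)) / (n_perm + 1)
    return(new_test_result("ks_two_sample", d, p, "two_sided",
                           n_perm = n_perm, seed = seed,
                           extra = list(p_method = "permutation")))
  }
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  p <- ks_q_function(lambda)
  new_test_result("ks_two_sample", d, p, "two_sided",
                  extra = list(p_method = "asymptotic"))
}

# sup |ECDF_x - ECDF_y| over the pooled points
ks_d_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# Kolmogorov Q function: 2 sum_{k>=1} (-1)^{k-1} exp(-2 k^2 lambda^2)
ks_q_function <- function(lambda, terms = 100L) {
  if (lambda <= 0) return(1)
  k <- seq_len(terms)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up q values `q_(i) = min_{j >= i} min(1, p_(j) * m / j)` on the
#' sorted p values, returned in the input order. Ties share a q value by
#' construction.
#'
#' @param pvals numeric vector of p values in `[0, 1]` (NA passed through).
#' @return q values in the input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(pvals))
  if (m > 0L) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    qs <- pmin(1, cummin(p[o] * m / (m - seq_len(m) + 1L)))[ro]
    q[ok] <- qs
  }
  q
}

#' @importFrom stats dhyper pnorm
#' @importFrom utils combn
NULL
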