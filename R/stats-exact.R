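#' Exact two-tailed Mann-Whitney rank-sum test
#'
#' Computes the Mann-Whitney U statistic by rank summation (midranks for
#' ties) and a two-sided p-value. For tie-free samples small enough that the
#' full set of group assignments can be enumerated (`choose(n1 + n2, n1) <=
#' max_enumeration`), the p-value is exact: every assignment of the pooled
#' ranks to the two groups is enumerated and the two-sided p is twice the
#' smaller tail probability, capped at 1. Otherwise (ties, or larger
#' samples) a seeded Monte-Carlo permutation test with the same two-sided
#' rule is used.
#'
#' For tie-free complete separation the exact two-sided p-value equals
#' `2 / choose(n1 + n2, n1)` - e.g. 2/70 = 0.0286 for two groups of four and
#' 2/924 = 0.0022 for two groups of six.
#'
#' @param a,b numeric vectors of observations (each non-empty).
#' @param n_permutations number of Monte-Carlo draws when enumeration is not
#'   used.
#' @param seed RNG seed for the Monte-Carlo path.
#' @param max_enumeration largest number of group assignments that will be
#'   enumerated exactly.
#' @param two_sided_rule `"double_tail"` (default) doubles the smaller exact
#'   tail and caps at 1; `"u_distance"` sums the probability of all outcomes
#'   at least as far from the null mean of U as the observed one.
#' @return an object of class `mw_result`: a list with `u_statistic`, `n1`,
#'   `n2`, `p_two_sided`, `method` (`"exact_enumeration"` or
#'   `"permutation_mc"`), and for the Monte-Carlo path `n_permutations` and
#'   `seed`.
#' @examples
#' mann_whitney_exact(c(1, 2, 3, 4), c(5, 6, 7, 8))$p_two_sided  # 2/70
#' @export
mann_whitney_exact <- function(a, b, n_permutations = 1e5, seed = 1L,
                               max_enumeration = 2e5,
                               two_sided_rule = c("double_tail", "u_distance")) {
  two_sided_rule <- match.arg(two_sided_rule)
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 1L || length(b) < 1L ||
      anyNA(a) || anyNA(b)) {
    stop_input("both groups must be non-empty numeric vectors without NA")
  }
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)  # midranks for ties
  r1 <- sum(rk[seq_len(n1)])
  u_obs <- r1 - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L

  if (!ties && choose(n1 + n2, n1) <= max_enumeration) {
    u_all <- enumerate_u(rk, n1)
    p <- two_sided_p(u_all, u_obs, n1, n2, two_sided_rule)
    res <- list(u_statistic = u_obs, n1 = n1, n2 = n2, p_two_sided = p,
                method = "exact_enumeration")
  } else {
    # canonicalize the group order so that p(a, b) == p(b, a) exactly even
    # under Monte-Carlo sampling (the permutation stream must not depend on
    # which group came first)
    swap <- n1 > n2 ||
      (n1 == n2 && paste(sort(a), collapse = ",") >
                     paste(sort(b), collapse = ","))
    nc <- if (swap) n2 else n1
    uc_obs <- if (swap) n1 * n2 - u_obs else u_obs
    rks <- sort(rk)  # sampling from sorted ranks keeps the stream
                     # invariant to the order the groups were supplied in
    u_perm <- with_seed(seed, {
      N <- n1 + n2
      vapply(seq_len(n_permutations), function(i) {
        idx <- sample.int(N, nc)
        sum(rks[idx]) - nc * (nc + 1) / 2
      }, numeric(1))
    })
    # include the observed statistic among the draws so p > 0
    u_all <- c(u_perm, uc_obs)
    p <- two_sided_p(u_all, uc_obs, nc, n1 + n2 - nc, two_sided_rule)
    res <- list(u_statistic = u_obs, n1 = n1, n2 = n2, p_two_sided = p,
                method = "permutation_mc", n_permutations = n_permutations,
                seed = seed)
  }
  structure(res, class = "mw_result")
}

# U statistic of group 1 for every assignment of n1 of the pooled ranks.
enumerate_u <- function(rk, n1) {
  idx <- utils::combn(length(rk), n1)
  colSums(matrix(rk[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

two_sided_p <- function(u_all, u_obs, n1, n2, rule) {
  m <- length(u_all)
  eps <- 1e-9
  if (rule == "double_tail") {
    p_lo <- sum(u_all <= u_obs + eps) / m
    p_hi <- sum(u_all >= u_obs - eps) / m
    min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n1 * n2 / 2
    sum(abs(u_all - mu) >= abs(u_obs - mu) - eps) / m
  }
}

#' @export
print.mw_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum test (%s)\n", x$method))
  cat(sprintf("  U = %g (n1 = %d, n2 = %d), two-sided p = %.4g\n",
              x$u_statistic, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' Descriptive summary statistics
#'
#' Quantiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7). For a single observation the dispersion
#' measures (`sd`, `sem`) are reported as `NA` rather than 0.
#'
#' @param values numeric vector, length >= 1.
#' @return a one-row data.frame with columns `n`, `min`, `q25`, `median`,
#'   `q75`, `max`, `mean`, `sd` (sample, n-1) and `sem` (`sd / sqrt(n)`).
#' @examples
#' summary_stats(c(1, 2, 3))
#' @export
summary_stats <- function(values) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values)) {
    stop_input("`values` must be a non-empty numeric vector without NA")
  }
  n <- length(values)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  s <- if (n >= 2L) stats::sd(values) else NA_real_
  data.frame(n = n, min = min(values), q25 = q[1], median = q[2], q75 = q[3],
             max = max(values), mean = mean(values), sd = s,
             sem = s / sqrt(n))
}
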