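#' Exact Mann-Whitney U test (two-sided)
#'
#' Rank-sum test implemented from first principles. The U statistic of the
#' first sample is computed from midranks (average ranks for ties):
#' `U = R1 - n1 (n1 + 1) / 2` with `R1` the rank sum of `a`. The exact
#' two-sided p-value is obtained by full enumeration of all
#' `choose(n1 + n2, n1)` group assignments of the pooled values:
#' `p = P(|U* - mu| >= |U - mu|)` where `mu = n1 n2 / 2` is the permutation
#' mean of U. With midranks the permutation distribution is symmetric about
#' `mu` for tie-free data, where this definition coincides with the doubled
#' smaller tail. Above `enum_limit` pooled observations a seeded Monte-Carlo
#' permutation p-value is reported together with its binomial standard
#' error.
#'
#' @param a,b numeric samples (each length >= 1).
#' @param enum_limit maximum pooled size for full enumeration (default 14;
#'   `choose(14, 7) = 3432` assignments).
#' @param n_mc number of Monte-Carlo permutations beyond the limit.
#' @param seed integer seed scoping the Monte-Carlo draw (ignored for the
#'   enumerated path).
#' @return A list of class `exact_test`: `statistic` (U of `a`), `p.value`,
#'   `method` (`"enumeration"` or `"monte-carlo"`), `mc_se` (`NA` for the
#'   enumerated path).
#' @examples
#' mann_whitney_exact(c(1, 2), c(3, 4)) # U = 0, p = 2/6
#' @export
mann_whitney_exact <- function(a, b, enum_limit = 14, n_mc = 10000,
                               seed = 1L) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  if (any(is.na(a)) || any(is.na(b))) stop("missing values are not allowed")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)                      # midranks
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  dev_obs <- abs(u_obs - mu)
  eps <- 1e-9
  if (length(unique(pooled)) == 1) {
    p <- 1; method <- "enumeration"; se <- NA_real_
  } else if (n <= enum_limit) {
    combos <- utils::combn(n, n1)
    rank_sums <- colSums(matrix(r[combos], nrow = n1))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= dev_obs - eps)
    method <- "enumeration"; se <- NA_real_
  } else {
    extreme <- with_seed(seed, {
      sum(vapply(seq_len(n_mc), function(i) {
        u <- sum(r[sample.int(n, n1)]) - n1 * (n1 + 1) / 2
        abs(u - mu) >= dev_obs - eps
      }, logical(1)))
    })
    p <- (1 + extreme) / (n_mc + 1)      # add-one: observed is a permutation
    method <- "monte-carlo"
    se <- sqrt(p * (1 - p) / n_mc)
  }
  structure(list(statistic = u_obs, p.value = p, method = method,
                 mc_se = se, n = c(n1 = n1, n2 = n2)),
            class = "exact_test")
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Conditional on both margins, the first cell follows a hypergeometric
#' distribution whose probabilities are computed here directly from
#' log-binomial coefficients. The two-sided p-value sums the probabilities
#' of all tables whose probability does not exceed that of the observed
#' table (with a 1e-7 relative tolerance for floating-point ties, the usual
#' convention).
#'
#' @param x a 2x2 matrix of non-negative integer counts.
#' @return A list of class `exact_test` with `p.value` and the observed
#'   table. An empty margin gives `p = 1` (no association assessable).
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)) # 2/252
#' @export
fisher_exact_2x2 <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2))) stop("x must be a 2x2 table")
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  r1 <- sum(x[1, ]); c1 <- sum(x[, 1]); N <- sum(x)
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) {
    p <- 1
  } else {
    support <- max(0, r1 + c1 - N):min(r1, c1)
    logp <- lchoose(c1, support) + lchoose(N - c1, r1 - support) -
      lchoose(N, r1)
    prob <- exp(logp)
    obs <- prob[support == x[1, 1]]
    p <- min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
  }
  structure(list(statistic = x[1, 1], p.value = p, table = x,
                 method = "hypergeometric enumeration"),
            class = "exact_test")
}

#' Exact chi-square test for r x c tables
#'
#' For contingency tables with more than two categories: the Pearson
#' chi-square statistic is referred to its exact conditional distribution
#' given both margins. When the number of tables compatible with the
#' margins is small the distribution is fully enumerated (each table
#' weighted by its multivariate hypergeometric probability); otherwise a
#' seeded Monte-Carlo sample of fixed-margin tables (via
#' [stats::r2dtable()]) estimates the p-value with its standard error.
#'
#' @param x an r x c matrix of non-negative integer counts.
#' @param enum_limit maximum number of tables for full enumeration.
#' @param n_mc Monte-Carlo sample size.
#' @param seed integer seed for the Monte-Carlo path.
#' @return A list of class `exact_test`: `statistic` (Pearson chi-square),
#'   `p.value`, `method`, `mc_se`.
#' @export
chisq_exact <- function(x, enum_limit = 1e5, n_mc = 10000, seed = 1L) {
  x <- as.matrix(x)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  rs <- rowSums(x); cs <- colSums(x); N <- sum(x)
  if (N == 0) stop("empty table")
  expected <- outer(rs, cs) / N
  stat_of <- function(tab) {
    ok <- expected > 0
    sum((tab[ok] - expected[ok])^2 / expected[ok])
  }
  obs <- stat_of(x)
  eps <- 1e-9

  tabs <- enumerate_margin_tables(rs, cs, enum_limit)
  if (!is.null(tabs)) {
    # exact conditional distribution: P(T) = prod r_i! prod c_j! / (N! prod n_ij!)
    base <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N)
    p <- 0
    for (tab in tabs) {
      if (stat_of(tab) >= obs - eps) {
        p <- p + exp(base - sum(lfactorial(tab)))
      }
    }
    structure(list(statistic = obs, p.value = min(1, p),
                   method = "enumeration", mc_se = NA_real_),
              class = "exact_test")
  } else {
    extreme <- with_seed(seed, {
      sims <- stats::r2dtable(n_mc, rs, cs)
      sum(vapply(sims, stat_of, numeric(1)) >= obs - eps)
    })
    p <- (1 + extreme) / (n_mc + 1)
    structure(list(statistic = obs, p.value = p, method = "monte-carlo",
                   mc_se = sqrt(p * (1 - p) / n_mc)),
              class = "exact_test")
  }
}

# enumerate all non-negative integer tables with the given margins;
# returns NULL if there are more than `limit`
enumerate_margin_tables <- function(rs, cs, limit) {
  out <- vector("list", 0)
  count <- 0
  nr <- length(rs); nc <- length(cs)
  overflow <- FALSE
  rec_row <- function(rows_done, cs_left) {
    if (overflow) return()
    if (rows_done == nr - 1) {
      # last row forced by remaining column margins
      tab <- rbind(do.call(rbind, rows_acc[seq_len(rows_done)]), cs_left)
      count <<- count + 1
      if (count > limit) { overflow <<- TRUE; return() }
      out[[count]] <<- unname(tab)
      return()
    }
    # enumerate compositions of rs[rows_done+1] into nc cells <= cs_left
    target <- rs[rows_done + 1]
    comp <- integer(nc)
    rec_cell <- function(j, remaining) {
      if (overflow) return()
      if (j == nc) {
        if (remaining <= cs_left[nc]) {
          comp[nc] <<- remaining
          rows_acc[[rows_done + 1]] <<- comp
          rec_row(rows_done + 1, cs_left - comp)
        }
        return()
      }
      for (v in 0:min(remaining, cs_left[j])) {
        comp[j] <<- v
        rec_cell(j + 1, remaining - v)
        if (overflow) return()
      }
    }
    rec_cell(1, target)
  }
  rows_acc <- vector("list", nr)
  if (nr == 1) return(list(matrix(cs, 1)))
  rec_row(0, cs)
  if (overflow) NULL else out
}

#' Spearman's rank correlation
#'
#' Pearson correlation of midranks (ties get average ranks).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\]; error when either rank vector has zero
#'   variance.
#' @examples
#' spearman_rho(c(1, 2, 3), c(3, 1, 2)) # -0.5
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("at least 3 pairs are required")
  if (any(is.na(x)) || any(is.na(y))) stop("missing values are not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("rank correlation undefined: zero rank variance")
  }
  stats::cor(rx, ry)
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("Exact test (%s): statistic = %.4g, p = %.5g",
              x$method, x$statistic, x$p.value))
  if (!is.na(x$mc_se %||% NA)) cat(sprintf(" (MC se %.2g)", x$mc_se))
  cat("\n")
  invisible(x)
}
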