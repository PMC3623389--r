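# Independent brute-force oracles. These deliberately avoid the package's
# computation path: U is counted pairwise (not via rank sums), and the
# hypergeometric probabilities come from plain factorial ratios.

# pairwise-count U statistic of sample `a` against sample `b`
oracle_u <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

# exact two-sided Mann-Whitney p by enumerating every group assignment
oracle_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  mu <- n1 * n2 / 2
  dev_obs <- abs(oracle_u(a, b) - mu)
  combos <- combn(n1 + n2, n1)
  devs <- apply(combos, 2, function(idx) {
    abs(oracle_u(pooled[idx], pooled[-idx]) - mu)
  })
  mean(devs >= dev_obs - 1e-9)
}

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities as factorial ratios
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); N <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, r1 - c2):min(r1, c1)
  prob <- vapply(support, function(i) {
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(N) - lfactorial(i) - lfactorial(r1 - i) -
          lfactorial(c1 - i) - lfactorial(c2 - r1 + i))
  }, numeric(1))
  obs <- prob[support == tab[1, 1]]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# direct region logic for the Thomas quadrants (truth table, no reuse of
# the classifier's branching)
oracle_quadrant <- function(ratio, cutoff, chr) {
  id_side <- ratio > cutoff
  low_chr <- chr < 28
  if (!id_side && !low_chr) "Q1_ACD"
  else if (id_side && !low_chr) "Q2_LATENT_ID"
  else if (id_side && low_chr) "Q3_MANIFEST_ID"
  else "Q4_FUNCTIONAL_ID_ACD"
}

expected_quadrant_of_etiology <- c(
  ACD = "Q1_ACD", latent_ID = "Q2_LATENT_ID",
  manifest_ID = "Q3_MANIFEST_ID", functional_ID_ACD = "Q4_FUNCTIONAL_ID_ACD")
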