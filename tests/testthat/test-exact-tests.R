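test_that("Mann-Whitney U and exact p match hand-enumerated cases", {
  res <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 2 / 6)          # 2 of the C(4,2) assignments
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(mann_whitney_exact(1, 2)$p.value, 1)
  expect_equal(mann_whitney_exact(rep(2, 3), rep(2, 4))$p.value, 1)
})

test_that("enumerated Mann-Whitney agrees with the pairwise-count oracle", {
  set.seed(21)
  for (n1 in 1:5) {
    for (n2 in n1:(10 - n1)) {
      if (n2 < 1) next
      # distinct values
      v <- sample(seq_len(n1 + n2))
      a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
      res <- mann_whitney_exact(a, b)
      expect_equal(res$statistic, oracle_u(a, b))
      expect_equal(res$p.value, oracle_mw_p(a, b))
      # heavy ties
      av <- sample(1:3, n1, replace = TRUE)
      bv <- sample(1:3, n2, replace = TRUE)
      res_t <- mann_whitney_exact(av, bv)
      expect_equal(res_t$statistic, oracle_u(av, bv))
      expect_equal(res_t$p.value, oracle_mw_p(av, bv))
    }
  }
})

test_that("tie-free enumerated p agrees with the classical exact distribution", {
  set.seed(22)
  for (i in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- rnorm(n1); b <- rnorm(n2)
    ours <- mann_whitney_exact(a, b)$p.value
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney falls back to seeded Monte-Carlo", {
  set.seed(23)
  a <- rnorm(12); b <- rnorm(12, 1)
  res <- mann_whitney_exact(a, b, seed = 99)
  expect_equal(res$method, "monte-carlo")
  expect_false(is.na(res$mc_se))
  # reproducible under the same seed, close to the asymptotic reference
  expect_equal(res$p.value, mann_whitney_exact(a, b, seed = 99)$p.value)
  ref <- stats::wilcox.test(a, b, exact = FALSE)$p.value
  expect_lt(abs(res$p.value - ref), 4 * res$mc_se + 0.02)
})

test_that("Fisher exact p matches hand-enumerated tables", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p.value, 2 / 252)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p.value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p.value, 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2))$p.value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
})

test_that("Fisher exact agrees with the factorial oracle and stats::fisher.test", {
  set.seed(24)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:6, 1)), 2)
    ours <- fisher_exact_2x2(tab)$p.value
    expect_equal(ours, oracle_fisher_p(tab), tolerance = 1e-9)
    expect_equal(ours, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("exact chi-square enumeration matches chisq statistic and MC path is seeded", {
  tab <- matrix(c(8, 2, 3, 1, 4, 6), 2)
  res <- chisq_exact(tab)
  expect_equal(res$method, "enumeration")
  expect_equal(res$statistic,
               unname(suppressWarnings(stats::chisq.test(tab)$statistic)))
  # enumerated exact p close to a large simulated reference
  ref <- suppressWarnings(stats::chisq.test(tab, simulate.p.value = TRUE,
                                            B = 20000))$p.value
  expect_lt(abs(res$p.value - ref), 0.02)

  big <- matrix(rpois(12, 40) + 10, 3)
  mc <- chisq_exact(big, enum_limit = 10, seed = 7)
  expect_equal(mc$method, "monte-carlo")
  expect_equal(mc$p.value, chisq_exact(big, enum_limit = 10, seed = 7)$p.value)
})

test_that("enumerated chi-square p sums table probabilities to 1", {
  # sanity on the conditional distribution: a statistic threshold of 0
  # captures every table, so p = 1
  tab <- matrix(c(3, 1, 2, 2), 2)
  res <- chisq_exact(tab)
  expect_lte(res$p.value, 1)
  zero_stat <- matrix(c(2, 2, 2, 2), 2)    # observed = expected
  expect_equal(chisq_exact(zero_stat)$p.value, 1)
})

test_that("Spearman's rho is the Pearson correlation of midranks", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 7, 10)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  set.seed(25)
  x <- rnorm(20); y <- sample(x + rnorm(20))
  expect_equal(spearman_rho(x, y),
               stats::cor(x, y, method = "spearman"))
  expect_error(spearman_rho(rep(1, 4), 1:4), "zero rank variance")
})
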