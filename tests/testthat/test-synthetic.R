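test_that("the same seed and design give byte-identical cohorts", {
  d <- cohort_design(n_group1 = 40, n_group2 = 60, seed = 123)
  expect_identical(generate_cohort(d), generate_cohort(d))
  # and the generator does not disturb the caller's RNG
  set.seed(99); before <- .Random.seed
  invisible(generate_cohort(d))
  expect_identical(before, .Random.seed)
  # different seeds differ
  d2 <- cohort_design(n_group1 = 40, n_group2 = 60, seed = 124)
  expect_false(identical(generate_cohort(d)$hb1, generate_cohort(d2)$hb1))
})

test_that("invalid designs fail before any sampling", {
  expect_error(cohort_design(etiology_mix = list(
    I = c(no_anemia = 0.5, ACD = 0.2, latent_ID = 0.2,
          manifest_ID = 0.2, functional_ID_ACD = 0),
    II = c(no_anemia = 0.6, ACD = 0.2, latent_ID = 0.1,
           manifest_ID = 0.1, functional_ID_ACD = 0))), "sum to 1")
  expect_error(cohort_design(margin = 0.6), "margin")
  expect_error(cohort_design(poct_error = list(
    offset = 0, sd = -1, operator_sd = 0, n_operators = 2)), "SD")
})

test_that("labels are recovered perfectly at positive margin", {
  mix <- c(no_anemia = 0, ACD = 0.3, latent_ID = 0.3,
           manifest_ID = 0.3, functional_ID_ACD = 0.1)
  d <- cohort_design(n_group1 = 0, n_group2 = 800,
                     etiology_mix = list(I = mix, II = mix), seed = 55)
  coh <- generate_cohort(d)
  got <- as.character(classify_thomas(coh)$quadrant)
  expect_identical(got, unname(expected_quadrant_of_etiology[coh$etiology]))
})

test_that("a single-etiology design lands every record in its quadrant", {
  mix <- c(no_anemia = 0, ACD = 0, latent_ID = 0,
           manifest_ID = 1, functional_ID_ACD = 0)
  d <- cohort_design(n_group1 = 0, n_group2 = 150,
                     etiology_mix = list(I = mix, II = mix), seed = 56)
  coh <- generate_cohort(d)
  expect_true(all(classify_thomas(coh)$quadrant == "Q3_MANIFEST_ID"))
  # manifest ID drawn microcytic
  expect_true(all(anemia_flags(coh)$morphology == "microcytic"))
})

test_that("generated Hb per etiology matches its design distribution", {
  # KS self-test against the truncated normal the generator samples from
  d <- cohort_design(n_group1 = 0, n_group2 = 10000, seed = 57)
  coh <- generate_cohort(d)
  p <- d$hb_distributions$no_anemia
  v <- coh$hb1[coh$etiology == "no_anemia"]
  lo <- 13.05; hi <- 17.5
  plo <- pnorm(lo, p[1], p[2]); phi <- pnorm(hi, p[1], p[2])
  cdf <- function(q) (pnorm(q, p[1], p[2]) - plo) / (phi - plo)
  ks <- suppressWarnings(stats::ks.test(v, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("treated group II anemic records carry the therapy arms and doses", {
  coh <- generate_cohort(cohort_design(seed = 58))
  treated <- coh$group == "II" & coh$etiology != "no_anemia"
  expect_true(all(coh$arm[treated] != "NONE"))
  expect_true(all(coh$arm[!treated] == "NONE"))
  expect_true(all(coh$iron_mg[!treated] == 0 & coh$esa_iu[!treated] == 0))
  acd <- treated & coh$etiology == "ACD"
  expect_true(all(coh$iron_mg[acd] == 200 & coh$esa_iu[acd] == 40000))
  id <- treated & coh$etiology %in% c("latent_ID", "manifest_ID")
  expect_true(all(coh$iron_mg[id] == 1000 & coh$esa_iu[id] == 10000))
  # all generated records pass the eligibility filters
  expect_true(all(check_eligibility(coh)$included))
})

test_that("POCT pairing implements reference + offset + operator + noise", {
  coh <- generate_cohort(cohort_design(n_group1 = 50, n_group2 = 0, seed = 59))
  clean <- paired_poct(coh, list(offset = 0, sd = 0, operator_sd = 0,
                                 n_operators = 3), seed = 1)
  expect_equal(clean$poct, clean$reference)
  shift <- paired_poct(coh, list(offset = 0.3, sd = 0, operator_sd = 0,
                                 n_operators = 3), seed = 1)
  expect_equal(shift$poct - shift$reference, rep(0.3, nrow(coh)))
  expect_equal(bland_altman(shift$reference, shift$poct)$bias, -0.3)
  # seeded reproducibility with noise
  noisy1 <- paired_poct(coh, seed = 4)
  noisy2 <- paired_poct(coh, seed = 4)
  expect_identical(noisy1, noisy2)
})

test_that("noise-only pairing recovers the designed limits of agreement", {
  d <- cohort_design(n_group1 = 233, n_group2 = 0, seed = 60)
  coh <- generate_cohort(d)
  halves <- vapply(1:40, function(i) {
    p <- paired_poct(coh, list(offset = 0, sd = 0.5, operator_sd = 0,
                               n_operators = 4), seed = 100 + i)
    ba <- bland_altman(p$reference, p$poct)
    (ba$loa_high - ba$loa_low) / 2
  }, numeric(1))
  expect_lt(abs(mean(halves) - 0.98), 3 * sd(halves) / sqrt(length(halves)) + 0.01)
})
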