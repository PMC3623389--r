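test_that("the decision rule maps (Hb, quadrant) to the published arms", {
  plan <- recommend_therapy(c(13.4, 12.0, 11.0, 12.9, 12.9),
                            c(NA, "Q1_ACD", "Q3_MANIFEST_ID",
                              "Q2_LATENT_ID", "Q4_FUNCTIONAL_ID_ACD"))
  expect_equal(as.character(plan$arm),
               c("NONE", "ACD_ARM", "ID_ARM", "ID_ARM", "ID_ARM"))
  expect_equal(plan$iron_mg, c(0, 200, 1000, 1000, 1000))
  expect_equal(plan$esa_iu, c(0, 40000, 10000, 10000, 10000))
  expect_equal(plan$scheduled_day, rep(20, 5))
})

test_that("Hb exactly at the 13 g/dL threshold has no therapeutic consequence", {
  plan <- recommend_therapy(13.0, "Q3_MANIFEST_ID")
  expect_equal(as.character(plan$arm), "NONE")
  expect_equal(plan$iron_mg + plan$esa_iu, 0)
})

test_that("therapy below threshold requires a classification", {
  expect_error(recommend_therapy(12.0, NA), "classification required")
  expect_error(recommend_therapy(12.0, "Q9"), "unknown")
})

test_that("arms partition the input space and never mix dose pairs", {
  set.seed(31)
  hb <- runif(300, 8.6, 16)
  quad <- sample(c("Q1_ACD", "Q2_LATENT_ID", "Q3_MANIFEST_ID",
                   "Q4_FUNCTIONAL_ID_ACD"), 300, replace = TRUE)
  plan <- recommend_therapy(hb, quad)
  expect_false(anyNA(plan$arm))
  legal <- list(NONE = c(0, 0), ACD_ARM = c(200, 40000),
                ID_ARM = c(1000, 10000))
  for (i in seq_len(300)) {
    expect_equal(c(plan$iron_mg[i], plan$esa_iu[i]),
                 legal[[as.character(plan$arm[i])]])
  }
  # deterministic / idempotent
  expect_identical(plan, recommend_therapy(hb, quad))
})

eligible_record <- function(n = 1) {
  data.frame(hb1 = rep(12, n), hb1_day = -30, hb2 = 12, hb2_day = -1,
             hb3 = 10, hb3_day = 1, hb4 = 9.5, hb4_day = 4,
             therapy_day = NA_real_, arm = "NONE", iron_mg = 0, esa_iu = 0,
             surgery_cancelled = FALSE)
}

test_that("well-formed records are included; each filter excludes", {
  ok <- check_eligibility(eligible_record())
  expect_true(ok$included)
  expect_equal(as.character(ok$reason), "ok")

  r <- eligible_record(); r$hb2 <- NA
  expect_equal(as.character(check_eligibility(r)$reason),
               "missing_hb_timepoint")
  r <- eligible_record(); r$hb1_day <- -120
  expect_equal(as.character(check_eligibility(r)$reason),
               "missing_hb_timepoint")
  r <- eligible_record(); r$hb3 <- NA; r$hb4 <- NA
  expect_equal(as.character(check_eligibility(r)$reason),
               "missing_hb_timepoint")

  r <- eligible_record()
  r$arm <- "ID_ARM"; r$iron_mg <- 1000; r$esa_iu <- 10000; r$therapy_day <- -5
  expect_equal(as.character(check_eligibility(r)$reason),
               "therapy_within_7_days")
  r$therapy_day <- -7   # day -7 itself is inside the window
  expect_equal(as.character(check_eligibility(r)$reason),
               "therapy_within_7_days")
  r$therapy_day <- -8
  expect_true(check_eligibility(r)$included)

  r <- eligible_record()
  r$arm <- "ACD_ARM"; r$iron_mg <- 500; r$esa_iu <- 40000; r$therapy_day <- -20
  expect_equal(as.character(check_eligibility(r)$reason), "dosage_deviation")

  r <- eligible_record(); r$surgery_cancelled <- TRUE
  expect_equal(as.character(check_eligibility(r)$reason), "surgery_cancelled")
})

test_that("multiple violations report the first reason in the fixed order", {
  r <- eligible_record()
  r$hb2 <- NA; r$surgery_cancelled <- TRUE
  expect_equal(as.character(check_eligibility(r)$reason),
               "missing_hb_timepoint")
})

test_that("a 370-record cohort with 35 violations keeps 335", {
  coh <- eligible_record(370)
  coh$hb2[1:12] <- NA                       # missing timepoint
  coh$arm[13:24] <- "ID_ARM"                # late therapy
  coh$iron_mg[13:24] <- 1000; coh$esa_iu[13:24] <- 10000
  coh$therapy_day[13:24] <- -4
  coh$arm[25:30] <- "ACD_ARM"               # dose deviation
  coh$iron_mg[25:30] <- 200; coh$esa_iu[25:30] <- 20000
  coh$therapy_day[25:30] <- -20
  coh$surgery_cancelled[31:35] <- TRUE
  res <- check_eligibility(coh)
  expect_equal(sum(res$included), 335)
  expect_equal(unname(as.vector(table(res$reason)[c(
    "missing_hb_timepoint", "therapy_within_7_days",
    "dosage_deviation", "surgery_cancelled")])), c(12, 12, 6, 5))
  # order independence: included set is invariant under row permutation
  set.seed(9)
  perm <- sample(nrow(coh))
  expect_equal(check_eligibility(coh[perm, ])$included, res$included[perm])
})
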