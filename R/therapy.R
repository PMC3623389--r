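#' Therapy arms of the management algorithm
#'
#' Three mutually exclusive arms cover the (Hb, Thomas-quadrant) space:
#' `NONE` (no substitution), `ACD_ARM` (200 mg iron i.v. + 40000 I.U. ESA,
#' for anemia of chronic disease without functional iron deficiency) and
#' `ID_ARM` (1000 mg iron i.v. + 10000 I.U. ESA, for any form of iron
#' deficiency including combined functional ID/ACD).
#' @keywords internal
therapy_arms <- c("NONE", "ACD_ARM", "ID_ARM")

arm_doses <- function(arm) {
  iron <- c(NONE = 0, ACD_ARM = 200, ID_ARM = 1000)
  esa <- c(NONE = 0, ACD_ARM = 40000, ID_ARM = 10000)
  list(iron_mg = unname(iron[arm]), esa_iu = unname(esa[arm]))
}

#' Recommend iron/ESA therapy from Hb and Thomas-plot quadrant
#'
#' The decision rule of the preoperative algorithm: hemoglobin at or above
#' the 13 g/dL threshold has no therapeutic consequence; below it, the
#' Thomas-plot quadrant selects the arm. ACD without functional iron
#' deficiency (Q1) receives 200 mg iron i.v. plus 40000 I.U. ESA; every
#' iron-deficient constellation (Q2 latent, Q3 manifest, Q4 functional
#' ID + ACD) receives 1000 mg iron i.v. plus 10000 I.U. ESA. Therapy is
#' scheduled by default 20 days before surgery. The ESA route (s.c. or
#' i.v.) is recorded but never affects classification, cost or eligibility.
#'
#' @param hb hemoglobin in g/dL.
#' @param quadrant Thomas-plot quadrant (character or factor, levels as in
#'   [classify_thomas()]); may be `NA` where `hb >= 13` since it is not
#'   consulted there, but must be present whenever `hb < 13`.
#' @param esa_route `"s.c."` or `"i.v."`.
#' @param config a [pbm_config()].
#' @return A `data.frame` of class `therapy_plan` with columns `arm`,
#'   `iron_mg`, `esa_iu`, `esa_route`, `scheduled_day` (days before
#'   surgery).
#' @examples
#' recommend_therapy(c(13.4, 12.0, 11.0),
#'                   c(NA, "Q1_ACD", "Q3_MANIFEST_ID"))
#' @export
recommend_therapy <- function(hb, quadrant = NA_character_,
                              esa_route = "s.c.", config = pbm_config()) {
  if (any(is.na(hb))) stop("hb is required for a therapy recommendation")
  quadrant <- rep_len(as.character(quadrant), length(hb))
  if (!all(esa_route %in% c("s.c.", "i.v."))) {
    stop("esa_route must be 's.c.' or 'i.v.'")
  }
  anemic <- hb < config$hb_cutoff
  if (any(anemic & is.na(quadrant))) {
    stop("classification required before therapy: Hb below threshold ",
         "with missing Thomas-plot quadrant")
  }
  known <- !is.na(quadrant)
  if (any(known & !quadrant %in% thomas_quadrants)) {
    stop("unknown Thomas-plot quadrant label")
  }
  arm <- ifelse(!anemic, "NONE",
                ifelse(quadrant == "Q1_ACD", "ACD_ARM", "ID_ARM"))
  doses <- arm_doses(arm)
  out <- data.frame(
    arm = factor(arm, levels = therapy_arms),
    iron_mg = doses$iron_mg,
    esa_iu = doses$esa_iu,
    esa_route = rep_len(esa_route, length(hb)),
    scheduled_day = config$scheduled_day
  )
  class(out) <- c("therapy_plan", class(out))
  out
}

#' Eligibility reasons, in reporting priority order
#' @keywords internal
eligibility_reasons <- c("ok", "missing_hb_timepoint", "therapy_within_7_days",
                         "dosage_deviation", "surgery_cancelled")

#' Apply the study's inclusion/exclusion filters to a cohort
#'
#' A record is included when all of the following hold, and excluded
#' otherwise with the first failing reason in this fixed order (so multiple
#' violations report reproducibly):
#'
#' 1. `missing_hb_timepoint` — requires a first preoperative Hb (`hb1`)
#'    measured within 90 days before surgery, a second preoperative Hb
#'    (`hb2`) at 0-3 days before surgery, and at least one postoperative Hb
#'    (`hb3` or `hb4`) within the first 7 postoperative days.
#' 2. `therapy_within_7_days` — therapy administered within 7 days before
#'    surgery (therapy day in \[-7, 0), day -7 inclusive) leaves no time for
#'    an erythropoietic response and excludes the record.
#' 3. `dosage_deviation` — administered doses differ from the recommended
#'    arm's fixed iron/ESA pair.
#' 4. `surgery_cancelled` — surgery postponed or cancelled.
#'
#' @param cohort a cohort `data.frame` (see [generate_cohort()] for the
#'   schema): columns `hb1`..`hb4`, `hb1_day`..`hb4_day`, `therapy_day`
#'   (`NA` when untreated), `arm`, `iron_mg`, `esa_iu`, `surgery_cancelled`.
#'   Missing bookkeeping columns are treated as "no violation".
#' @param config a [pbm_config()].
#' @return A `data.frame` with logical `included` and factor `reason`;
#'   `included` is `TRUE` iff `reason == "ok"`.
#' @export
check_eligibility <- function(cohort, config = pbm_config()) {
  n <- nrow(cohort)
  col <- function(nm, default) {
    if (nm %in% names(cohort)) cohort[[nm]] else rep(default, n)
  }
  hb1 <- col("hb1", NA_real_); hb1_day <- col("hb1_day", -30)
  hb2 <- col("hb2", NA_real_); hb2_day <- col("hb2_day", -1)
  hb3 <- col("hb3", NA_real_); hb3_day <- col("hb3_day", 1)
  hb4 <- col("hb4", NA_real_); hb4_day <- col("hb4_day", 4)
  ok1 <- !is.na(hb1) & !is.na(hb1_day) & hb1_day >= -90 & hb1_day < 0
  ok2 <- !is.na(hb2) & !is.na(hb2_day) & hb2_day >= -3 & hb2_day <= 0
  ok3 <- (!is.na(hb3) & !is.na(hb3_day) & hb3_day >= 0 & hb3_day <= 7) |
         (!is.na(hb4) & !is.na(hb4_day) & hb4_day >= 0 & hb4_day <= 7)
  missing_tp <- !(ok1 & ok2 & ok3)

  therapy_day <- col("therapy_day", NA_real_)
  late_therapy <- !is.na(therapy_day) &
    therapy_day >= -config$therapy_window_days & therapy_day < 0

  arm <- as.character(col("arm", "NONE"))
  planned <- arm_doses(ifelse(is.na(arm), "NONE", arm))
  deviation <- (col("iron_mg", 0) != planned$iron_mg) |
               (col("esa_iu", 0) != planned$esa_iu)
  deviation[is.na(deviation)] <- TRUE

  cancelled <- isTRUE_vec(col("surgery_cancelled", FALSE))

  reason <- rep("ok", n)
  reason[cancelled] <- "surgery_cancelled"
  reason[deviation] <- "dosage_deviation"
  reason[late_therapy] <- "therapy_within_7_days"
  reason[missing_tp] <- "missing_hb_timepoint"
  data.frame(included = reason == "ok",
             reason = factor(reason, levels = eligibility_reasons))
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
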