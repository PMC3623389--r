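#' Preoperative anemia prevalence
#'
#' Fraction of a reviewed cohort that is anemic at the first preoperative
#' measurement (`hb1`), under either definition:
#' * `"UNIFIED"` — Hb < 13 g/dL for both sexes (the algorithm's therapeutic
#'   threshold);
#' * `"WHO"` — Hb < 13 g/dL for men, < 12 g/dL for women.
#'
#' The denominator is every reviewed record, not only included ones.
#'
#' @param cohort cohort `data.frame` with columns `hb1` and `sex`.
#' @param definition `"UNIFIED"` or `"WHO"`.
#' @param config a [pbm_config()].
#' @return A list: `n`, `n_anemic`, `percent` (unrounded),
#'   `percent_rounded` (one decimal, half-up), `by_sex` (anemic counts).
#' @examples
#' coh <- data.frame(hb1 = c(11, 12.5, 14), sex = c("female", "female", "male"))
#' prevalence(coh, "WHO")$n_anemic # 1
#' @export
prevalence <- function(cohort, definition = c("UNIFIED", "WHO"),
                       config = pbm_config()) {
  definition <- match.arg(definition)
  if (nrow(cohort) == 0) stop("empty cohort")
  stop_if_missing_cols(cohort, "hb1", "cohort")
  if (any(is.na(cohort$hb1))) stop("hb1 must be present for every record")
  flags <- anemia_flags(data.frame(hb = cohort$hb1, sex = cohort$sex),
                        config = config)
  anemic <- if (definition == "UNIFIED") flags$anemic_unified else flags$anemic_who
  if (any(is.na(anemic))) stop("sex required for the WHO definition")
  n <- nrow(cohort)
  pct <- 100 * sum(anemic) / n
  list(n = n, n_anemic = sum(anemic),
       percent = pct, percent_rounded = round_half_up(pct, 1),
       by_sex = table(sex = cohort$sex[anemic]))
}

#' Transfusion accounting for a cohort or its anemic subset
#'
#' @param cohort cohort `data.frame` with `rbc_units` (and `hb1` when
#'   subsetting to anemic records).
#' @param subset `"all"` or `"anemic"` (anemic = `hb1` below the unified
#'   threshold).
#' @param config a [pbm_config()].
#' @return A list: `n`, `transfused_patients`, `rate_pct` (integer percent,
#'   half-up), `rate` (unrounded), `total_rbc_units`, `units_per_patient`
#'   (unrounded).
#' @examples
#' coh <- data.frame(hb1 = rep(12, 4), sex = "female",
#'                   rbc_units = c(0, 0, 2, 1))
#' transfusion_summary(coh)$rate_pct # 50
#' @export
transfusion_summary <- function(cohort, subset = c("all", "anemic"),
                                config = pbm_config()) {
  subset <- match.arg(subset)
  stop_if_missing_cols(cohort, "rbc_units", "cohort")
  if (subset == "anemic") {
    stop_if_missing_cols(cohort, "hb1", "cohort")
    cohort <- cohort[cohort$hb1 < config$hb_cutoff, , drop = FALSE]
  }
  u <- cohort$rbc_units
  if (any(is.na(u)) || any(u < 0) || any(u != round(u))) {
    stop("rbc_units must be non-negative integers")
  }
  n <- nrow(cohort)
  transfused <- sum(u > 0)
  rate <- if (n > 0) 100 * transfused / n else NA_real_
  list(n = n, transfused_patients = transfused,
       rate = rate, rate_pct = round_half_up(rate),
       total_rbc_units = sum(u),
       units_per_patient = if (n > 0) sum(u) / n else NA_real_)
}

#' Relative reduction in transfused units per patient
#'
#' `100 * (1 - new / ref)` comparing units-per-patient before and after an
#' intervention; positive values mean fewer units under `new`.
#'
#' @param ref reference units per patient (`> 0`).
#' @param new comparison units per patient (`>= 0`).
#' @return A list with `pct` (unrounded) and `pct_rounded` (nearest integer,
#'   half-up).
#' @examples
#' reduction_pct(27 / 101, 35 / 234)$pct_rounded # 44
#' @export
reduction_pct <- function(ref, new) {
  if (is.na(ref) || ref <= 0) stop("reference units per patient must be > 0")
  if (new < 0) stop("new units per patient must be >= 0")
  pct <- 100 * (1 - new / ref)
  list(pct = pct, pct_rounded = round_half_up(pct))
}

#' Therapy and transfusion cost report
#'
#' Sums, over a cohort, transfused RBC units, administered i.v. iron and
#' chargeable ESA doses at the given unit prices:
#' `total = units x rbc_price + sum(iron_mg)/100 x iron_price +
#'  sum(chargeable esa_iu)/1000 x esa_price`, where ESA doses of exactly
#' 40000 I.U. cost nothing when the free-of-charge rule applies. Totals and
#' the per-patient figure are rounded half-up to cents.
#'
#' @param cohort cohort `data.frame` with `rbc_units`, `iron_mg`, `esa_iu`
#'   (missing therapy columns are treated as zero doses).
#' @param prices a [price_table()].
#' @return A list: `n`, `cost_rbc`, `cost_iron`, `cost_esa`, `cost_total`,
#'   `cost_per_patient` (all EUR).
#' @examples
#' coh <- data.frame(rbc_units = c(2, 0), iron_mg = c(0, 1000),
#'                   esa_iu = c(0, 10000))
#' cost_report(coh)$cost_total
#' @export
cost_report <- function(cohort, prices = price_table()) {
  n <- nrow(cohort)
  if (n == 0) {
    return(list(n = 0, cost_rbc = 0, cost_iron = 0, cost_esa = 0,
                cost_total = 0, cost_per_patient = NA_real_))
  }
  col <- function(nm) {
    v <- if (nm %in% names(cohort)) cohort[[nm]] else rep(0, n)
    v[is.na(v)] <- 0
    if (any(v < 0)) stop("negative quantities in '", nm, "'")
    v
  }
  rbc <- col("rbc_units"); iron <- col("iron_mg"); esa <- col("esa_iu")
  chargeable <- if (prices$esa_40000_free) ifelse(esa == 40000, 0, esa) else esa
  cost_rbc <- sum(rbc) * prices$rbc_eur_per_unit
  cost_iron <- sum(iron) / 100 * prices$iron_eur_per_100mg
  cost_esa <- sum(chargeable) / 1000 * prices$esa_eur_per_1000iu
  total <- round_half_up(cost_rbc + cost_iron + cost_esa, 2)
  list(n = n,
       cost_rbc = round_half_up(cost_rbc, 2),
       cost_iron = round_half_up(cost_iron, 2),
       cost_esa = round_half_up(cost_esa, 2),
       cost_total = total,
       cost_per_patient = round_half_up(total / n, 2))
}

#' Hemoglobin course summaries per timepoint
#'
#' Median (mean-of-middle-two convention for even n, i.e. [stats::median()]),
#' minimum and maximum of each requested Hb timepoint; records missing a
#' timepoint are dropped from that timepoint's summary with the dropped
#' count reported. Optional seeded bootstrap percentile confidence
#' intervals for the medians.
#'
#' @param cohort cohort `data.frame` with `hb1`..`hb4` (and `hb1` if
#'   subsetting).
#' @param subset `"all"` or `"anemic"`.
#' @param timepoints which Hb columns to summarise.
#' @param ci logical; compute bootstrap percentile 95% CIs for the medians.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param config a [pbm_config()].
#' @return A `data.frame` with one row per timepoint: `timepoint`, `n`,
#'   `n_missing`, `median`, `min`, `max` (and `ci_low`/`ci_high` when
#'   `ci = TRUE`).
#' @export
hb_course <- function(cohort, subset = c("all", "anemic"),
                      timepoints = c("hb1", "hb2", "hb3", "hb4"),
                      ci = FALSE, n_boot = 1000, seed = 1L,
                      config = pbm_config()) {
  subset <- match.arg(subset)
  if (subset == "anemic") {
    stop_if_missing_cols(cohort, "hb1", "cohort")
    cohort <- cohort[!is.na(cohort$hb1) & cohort$hb1 < config$hb_cutoff, ,
                     drop = FALSE]
  }
  stop_if_missing_cols(cohort, timepoints, "cohort")
  rows <- lapply(seq_along(timepoints), function(i) {
    tp <- timepoints[i]
    v <- cohort[[tp]]
    keep <- !is.na(v)
    v <- v[keep]
    row <- data.frame(timepoint = tp, n = length(v),
                      n_missing = sum(!keep),
                      median = if (length(v)) stats::median(v) else NA_real_,
                      min = if (length(v)) min(v) else NA_real_,
                      max = if (length(v)) max(v) else NA_real_)
    if (ci && length(v) >= 2) {
      meds <- with_seed(seed + i, {
        vapply(seq_len(n_boot), function(b) {
          stats::median(sample(v, replace = TRUE))
        }, numeric(1))
      })
      q <- stats::quantile(meds, c(0.025, 0.975), names = FALSE)
      row$ci_low <- q[1]; row$ci_high <- q[2]
    } else if (ci) {
      row$ci_low <- NA_real_; row$ci_high <- NA_real_
    }
    row
  })
  do.call(rbind, rows)
}
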