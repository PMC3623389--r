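#' Synthetic-cohort design
#'
#' Parameterises the seeded generator of before/after cohorts used to
#' exercise the whole pipeline without patient data. The defaults emulate
#' the structure of the study the algorithm was evaluated on: a
#' conventional-care group (`I`, n = 101, no substitution) and an
#' algorithm-managed group (`II`, n = 234), with roughly 24/101 and 32/234
#' anemic records whose etiologies split 40:11:5:0 over ACD, latent ID,
#' manifest ID and combined functional ID/ACD.
#'
#' Laboratory values for each etiology are drawn uniformly inside
#' configurable boxes placed strictly inside the corresponding Thomas-plot
#' region; a safety margin (default 5% of each box span, applied by
#' shrinking the box) keeps every draw away from the cut-off lines so the
#' generating label is unambiguous ground truth. Gaussian lab values would
#' leak across the cut-offs; uniform boxes with margins do not.
#'
#' Hemoglobin courses: `hb1` per-etiology truncated normal (anemic records
#' truncated below the 13 g/dL threshold, non-anemic above);
#' `hb2 = hb1 + drift (+ therapy effect for treated records)`;
#' `hb3 = hb2 - surgical drop`; `hb4 = hb3 - postoperative drift`. Treated
#' records are the anemic members of group II; their additive `hb2` gain is
#' `therapy_effect`. Transfusion is Bernoulli with probability a decreasing
#' step function of `hb2` (the study used no strict transfusion rule, so
#' this is configuration, not a published fact), with 1-3 units per
#' transfused patient.
#'
#' @param n_group1,n_group2 group sizes.
#' @param etiology_mix list with elements `I` and `II`, each a named
#'   probability vector over
#'   `no_anemia, ACD, latent_ID, manifest_ID, functional_ID_ACD`
#'   summing to 1.
#' @param hb_distributions named list per etiology: `c(mean, sd)` of `hb1`
#'   in g/dL.
#' @param lab_region_params named list per etiology of `c(lo, hi)` ranges
#'   for `stfr`, `ferritin`, `crp`, `chr`, `transferrin`, `iron`, `mcv`,
#'   `mch`.
#' @param margin safety margin as a fraction of each box span.
#' @param poct_error list: `offset` (systematic POCT - reference shift,
#'   g/dL), `sd` (analytic noise SD), `operator_sd` (between-operator
#'   offset SD), `n_operators`.
#' @param transfusion_model list: `breaks` (ascending `hb2` cut-points),
#'   `probs` (length `length(breaks) + 1`, transfusion probability per
#'   `hb2` band, decreasing), `units_probs` (distribution of 1, 2, 3 units).
#' @param therapy_effect `c(mean, sd)` of the additive `hb2` gain (g/dL)
#'   in treated records.
#' @param hb_drift,hb_drop3,hb_drop4 `c(mean, sd)` of the preoperative
#'   drift, the operative Hb drop and the later postoperative change.
#' @param p_female probability a record is female.
#' @param seed integer; the single seed governing all randomness.
#' @return A validated list of class `cohort_design`.
#' @export
cohort_design <- function(
    n_group1 = 101,
    n_group2 = 234,
    etiology_mix = NULL,
    hb_distributions = list(
      no_anemia = c(14.2, 0.9), ACD = c(12.2, 0.7),
      latent_ID = c(12.3, 0.6), manifest_ID = c(11.3, 0.9),
      functional_ID_ACD = c(11.5, 0.8)),
    lab_region_params = default_lab_regions(),
    margin = 0.05,
    poct_error = list(offset = 0.2, sd = 0.5, operator_sd = 0.3,
                      n_operators = 5),
    transfusion_model = list(breaks = c(10, 11, 12, 13),
                             probs = c(0.50, 0.30, 0.18, 0.08, 0.05),
                             units_probs = c(0.45, 0.45, 0.10)),
    therapy_effect = c(0.75, 0.35),
    hb_drift = c(-0.2, 0.3),
    hb_drop3 = c(2.5, 0.6),
    hb_drop4 = c(0.75, 0.35),
    p_female = 0.619,
    seed = 20131L) {
  if (is.null(etiology_mix)) {
    anemic_split <- c(ACD = 40, latent_ID = 11, manifest_ID = 5,
                      functional_ID_ACD = 0) / 56
    mix_for <- function(frac) c(no_anemia = 1 - frac, frac * anemic_split)
    etiology_mix <- list(I = mix_for(24 / 101), II = mix_for(32 / 234))
  }
  design <- list(n_group1 = n_group1, n_group2 = n_group2,
                 etiology_mix = etiology_mix,
                 hb_distributions = hb_distributions,
                 lab_region_params = lab_region_params, margin = margin,
                 poct_error = poct_error,
                 transfusion_model = transfusion_model,
                 therapy_effect = therapy_effect, hb_drift = hb_drift,
                 hb_drop3 = hb_drop3, hb_drop4 = hb_drop4,
                 p_female = p_female, seed = as.integer(seed))
  validate_cohort_design(design)
}

etiologies <- c("no_anemia", "ACD", "latent_ID", "manifest_ID",
                "functional_ID_ACD")

etiology_quadrant <- c(ACD = "Q1_ACD", latent_ID = "Q2_LATENT_ID",
                       manifest_ID = "Q3_MANIFEST_ID",
                       functional_ID_ACD = "Q4_FUNCTIONAL_ID_ACD")

#' Default per-etiology laboratory sampling boxes
#'
#' Uniform-sampling ranges per analyte, sited inside the Thomas-plot region
#' of each etiology (CRP kept below the acute-phase boundary so the 1.5
#' cut-off applies; the 0.8 branch is exercised directly in tests).
#' Manifest iron deficiency is drawn microcytic; all other etiologies
#' normocytic, matching the predominance of normocytic anemia in
#' preoperative cohorts.
#'
#' @return Named list per etiology of `c(lo, hi)` ranges.
#' @keywords internal
#' @export
default_lab_regions <- function() {
  list(
    no_anemia = list(stfr = c(0.8, 1.5), ferritin = c(60, 300),
                     crp = c(0, 4), chr = c(29, 35),
                     transferrin = c(240, 340), iron = c(60, 160),
                     mcv = c(82, 97), mch = c(27.5, 33)),
    ACD = list(stfr = c(0.8, 1.4), ferritin = c(120, 350),
               crp = c(0, 4), chr = c(28.6, 34.5),
               transferrin = c(240, 340), iron = c(40, 110),
               mcv = c(82, 96), mch = c(27, 32)),
    latent_ID = list(stfr = c(2.3, 3.6), ferritin = c(12, 27),
                     crp = c(0, 4), chr = c(28.6, 33),
                     transferrin = c(280, 360), iron = c(30, 80),
                     mcv = c(80.5, 95), mch = c(26.5, 31)),
    manifest_ID = list(stfr = c(2.6, 4.8), ferritin = c(4, 22),
                       crp = c(0, 4), chr = c(22, 27.4),
                       transferrin = c(280, 360), iron = c(20, 60),
                       mcv = c(74, 79.5), mch = c(23.5, 27.5)),
    functional_ID_ACD = list(stfr = c(0.8, 1.3), ferritin = c(130, 330),
                             crp = c(0, 4), chr = c(23, 27.4),
                             transferrin = c(240, 340), iron = c(30, 80),
                             mcv = c(80.5, 92), mch = c(26.5, 30))
  )
}

validate_cohort_design <- function(design) {
  stopifnot(design$n_group1 >= 0, design$n_group2 >= 0)
  for (g in c("I", "II")) {
    mix <- design$etiology_mix[[g]]
    if (is.null(mix) || !setequal(names(mix), etiologies)) {
      stop("etiology_mix$", g, " must be named over: ",
           paste(etiologies, collapse = ", "))
    }
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
      stop("etiology_mix$", g, " must be non-negative and sum to 1")
    }
  }
  if (design$margin < 0 || design$margin >= 0.5) {
    stop("margin must lie in [0, 0.5)")
  }
  sds <- c(design$poct_error$sd, design$poct_error$operator_sd,
           design$therapy_effect[2], design$hb_drift[2],
           design$hb_drop3[2], design$hb_drop4[2],
           vapply(design$hb_distributions, `[`, numeric(1), 2))
  if (any(sds < 0)) stop("all SDs must be >= 0")
  tm <- design$transfusion_model
  if (length(tm$probs) != length(tm$breaks) + 1 ||
      any(tm$probs < 0 | tm$probs > 1)) {
    stop("transfusion_model$probs must be probabilities of length breaks+1")
  }
  structure(design, class = "cohort_design")
}

# inverse-CDF truncated normal: one uniform draw per value, fully
# deterministic under the scoped seed
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

runif_box <- function(n, range, margin) {
  span <- range[2] - range[1]
  stats::runif(n, range[1] + margin * span, range[2] - margin * span)
}

#' Generate a synthetic before/after cohort
#'
#' Draws a reproducible cohort under a [cohort_design()]: group membership,
#' sex, surgery type, ground-truth etiology, laboratory panels inside the
#' etiology's Thomas-plot region, the four-timepoint Hb course with therapy
#' effect for treated (group II anemic) records, transfusion counts, and
#' eligibility bookkeeping (all generated records are eligible; tests and
#' callers mutate records to exercise the exclusion filters).
#'
#' The same design and seed always produce the identical cohort; all
#' randomness is scoped to `design$seed` without touching the caller's RNG
#' state.
#'
#' @param design a [cohort_design()].
#' @param config a [pbm_config()] (used for the therapy recommendation of
#'   treated records).
#' @return A `data.frame` of class `pbm_cohort`, one row per patient, with
#'   the columns described in [check_eligibility()], [classify_thomas()]
#'   and [cost_report()]. The generating etiology is kept in `etiology`.
#' @examples
#' coh <- generate_cohort(cohort_design(n_group1 = 20, n_group2 = 30, seed = 7))
#' table(coh$group, coh$etiology != "no_anemia")
#' @export
generate_cohort <- function(design = cohort_design(), config = pbm_config()) {
  design <- validate_cohort_design(design)
  with_seed(design$seed, {
    n <- design$n_group1 + design$n_group2
    group <- rep(c("I", "II"), c(design$n_group1, design$n_group2))
    etiology <- character(n)
    for (g in c("I", "II")) {
      idx <- which(group == g)
      mix <- design$etiology_mix[[g]][etiologies]
      etiology[idx] <- sample(etiologies, length(idx), replace = TRUE,
                              prob = mix)
    }
    sex <- ifelse(stats::runif(n) < design$p_female, "female", "male")
    surgery <- sample(c("hip", "knee"), n, replace = TRUE)

    # hb1 truncated on the correct side of the therapeutic threshold
    hb1 <- numeric(n)
    thr <- config$hb_cutoff
    for (e in etiologies) {
      idx <- which(etiology == e)
      if (!length(idx)) next
      p <- design$hb_distributions[[e]]
      if (e == "no_anemia") {
        hb1[idx] <- rtrunc_norm(length(idx), p[1], p[2], thr + 0.05, 17.5)
      } else {
        hb1[idx] <- rtrunc_norm(length(idx), p[1], p[2], 8.6, thr - 0.05)
      }
    }

    # labs drawn uniformly inside the etiology's (shrunken) region box
    labs <- c("stfr", "ferritin", "crp", "chr", "transferrin", "iron",
              "mcv", "mch")
    lab <- matrix(NA_real_, n, length(labs), dimnames = list(NULL, labs))
    for (e in etiologies) {
      idx <- which(etiology == e)
      if (!length(idx)) next
      box <- design$lab_region_params[[e]]
      for (a in labs) {
        lab[idx, a] <- runif_box(length(idx), box[[a]], design$margin)
      }
    }
    vitb12 <- ifelse(stats::runif(n) < 0.03,
                     stats::runif(n, 150, 250), stats::runif(n, 260, 900))
    folate <- ifelse(stats::runif(n) < 0.028,
                     stats::runif(n, 1.8, 3.0), stats::runif(n, 3.3, 15))

    anemic <- etiology != "no_anemia"
    treated <- anemic & group == "II"
    quadrant <- ifelse(anemic, unname(etiology_quadrant[etiology]),
                       NA_character_)
    plan <- recommend_therapy(hb1, quadrant, config = config)
    plan[!treated, c("iron_mg", "esa_iu")] <- 0
    plan$arm[!treated] <- "NONE"

    hb2 <- hb1 + stats::rnorm(n, design$hb_drift[1], design$hb_drift[2]) +
      ifelse(treated,
             stats::rnorm(n, design$therapy_effect[1],
                          design$therapy_effect[2]), 0)
    hb3 <- hb2 - stats::rnorm(n, design$hb_drop3[1], design$hb_drop3[2])
    hb4 <- hb3 - stats::rnorm(n, design$hb_drop4[1], design$hb_drop4[2])
    hb2 <- pmax(hb2, 4); hb3 <- pmax(hb3, 3.5); hb4 <- pmax(hb4, 3.5)

    tm <- design$transfusion_model
    p_tx <- tm$probs[findInterval(hb2, tm$breaks) + 1]
    transfused <- stats::runif(n) < p_tx
    rbc_units <- ifelse(transfused,
                        sample(seq_along(tm$units_probs), n, replace = TRUE,
                               prob = tm$units_probs), 0L)

    therapy_day <- ifelse(treated,
                          pmin(-8, round(-config$scheduled_day +
                                           stats::rnorm(n, 0, 4))),
                          NA_real_)

    out <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      group = group, sex = sex, surgery = surgery, etiology = etiology,
      hb = hb1,                      # panel hb = first preoperative Hb
      hb1 = hb1, hb1_day = sample(-60:-14, n, replace = TRUE),
      hb2 = hb2, hb2_day = sample(-3:0, n, replace = TRUE),
      hb3 = hb3, hb3_day = 1L,
      hb4 = hb4, hb4_day = sample(2:6, n, replace = TRUE),
      timepoint_day = -30L,
      stringsAsFactors = FALSE
    )
    for (a in labs) out[[a]] <- lab[, a]
    out$vitb12 <- vitb12
    out$folate <- folate
    out$arm <- as.character(plan$arm)
    out$iron_mg <- plan$iron_mg
    out$esa_iu <- plan$esa_iu
    out$esa_route <- plan$esa_route
    out$scheduled_day <- plan$scheduled_day
    out$therapy_day <- therapy_day
    out$rbc_units <- as.integer(rbc_units)
    out$surgery_cancelled <- FALSE
    class(out) <- c("pbm_cohort", class(out))
    out
  })
}

#' Paired POCT vs reference Hb measurements
#'
#' Emulates measuring the first preoperative hemoglobin with both the
#' laboratory reference method and a handheld point-of-care device:
#' `poct = reference + offset + operator_offset + noise`, where the
#' operator offset is drawn once per (randomly assigned) operator — the
#' user-related component of POCT error — and the noise is Gaussian.
#'
#' @param cohort a cohort with column `hb1`.
#' @param poct_error list with `offset`, `sd`, `operator_sd`,
#'   `n_operators` (see [cohort_design()]).
#' @param seed integer seed.
#' @return A `data.frame` with `reference`, `poct`, `operator`.
#' @export
paired_poct <- function(cohort,
                        poct_error = cohort_design()$poct_error,
                        seed = 1L) {
  stop_if_missing_cols(cohort, "hb1", "cohort")
  if (any(is.na(cohort$hb1))) stop("hb1 must be present")
  with_seed(seed, {
    n <- nrow(cohort)
    op_off <- stats::rnorm(poct_error$n_operators, 0, poct_error$operator_sd)
    op <- sample.int(poct_error$n_operators, n, replace = TRUE)
    poct <- cohort$hb1 + poct_error$offset + op_off[op] +
      stats::rnorm(n, 0, poct_error$sd)
    data.frame(reference = cohort$hb1, poct = poct, operator = op)
  })
}
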