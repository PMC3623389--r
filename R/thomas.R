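#' Thomas-plot quadrant labels
#' @keywords internal
thomas_quadrants <- c("Q1_ACD", "Q2_LATENT_ID", "Q3_MANIFEST_ID",
                      "Q4_FUNCTIONAL_ID_ACD")

#' Classify lab panels into Thomas-plot quadrants
#'
#' The Thomas plot crosses the sTfR/log10(ferritin) index (x-axis, cut-off
#' 1.5 or 0.8 depending on CRP) with reticulocyte hemoglobin content CHr
#' (y-axis, cut-off 28 pg). The four quadrants are:
#'
#' * `Q1_ACD` — index <= cut-off, CHr >= 28: anemia of chronic disease
#'   without functional iron deficiency (iron stores adequate, erythropoiesis
#'   not yet iron-restricted).
#' * `Q2_LATENT_ID` — index > cut-off, CHr >= 28: latent iron deficiency
#'   (stores depleted, erythropoiesis still normal).
#' * `Q3_MANIFEST_ID` — index > cut-off, CHr < 28: manifest iron-deficient
#'   erythropoiesis.
#' * `Q4_FUNCTIONAL_ID_ACD` — index <= cut-off, CHr < 28: functional iron
#'   deficiency combined with ACD.
#'
#' Ties: an index exactly equal to its cut-off falls on the ACD side
#' (Q1/Q4), and CHr exactly 28 is not functional iron deficiency — both
#' conventions follow the strict inequalities of the published definitions
#' ("index elevated", "CHr < 28 pg"). Ferritin at or below 1 ng/mL makes the
#' index undefined; such rows are assigned `Q3_MANIFEST_ID` with
#' `ratio_undefined = TRUE` and a warning, since ferritin that low is
#' unambiguous iron-store depletion.
#'
#' @param panels a `lab_panel` data.frame (or anything with columns `stfr`,
#'   `ferritin`, `crp`, `chr`). All four analytes must be present in every
#'   row; the classifier refuses to classify on missing inputs rather than
#'   imputing.
#' @param config a [pbm_config()].
#' @return A `data.frame` of class `thomas_result` with columns `ratio`,
#'   `ratio_cutoff`, `chr`, `functional_id`, `ratio_undefined` and `quadrant`
#'   (factor over the four quadrant labels).
#' @examples
#' p <- lab_panel(hb = c(12, 11), stfr = c(1, 4), ferritin = c(100, 10),
#'                crp = c(1, 1), chr = c(30, 25))
#' classify_thomas(p)$quadrant
#' @export
classify_thomas <- function(panels, config = pbm_config()) {
  stop_if_missing_cols(panels, c("stfr", "ferritin", "crp", "chr"),
                       "thomas classification input")
  need <- c("stfr", "ferritin", "crp", "chr")
  miss <- vapply(need, function(a) any(is.na(panels[[a]])), logical(1))
  if (any(miss)) {
    stop("cannot classify: missing ",
         paste(need[miss], collapse = ", "),
         " in ", sum(Reduce(`|`, lapply(need, function(a) is.na(panels[[a]])))),
         " row(s); classification refuses to impute")
  }
  cutoff <- ratio_cutoff(panels$crp, config)
  ratio <- stfr_ratio(panels$stfr, panels$ferritin)
  undefined <- !stfr_ratio_defined(panels$stfr, panels$ferritin)
  if (any(undefined)) {
    warning(sum(undefined), " row(s) have ferritin <= 1 ng/mL: ",
            "sTfR/log ferritin undefined; assigned Q3_MANIFEST_ID ",
            "(manifest iron depletion)")
  }
  fid <- panels$chr < config$chr_cutoff
  elevated <- !undefined & ratio > cutoff
  quadrant <- ifelse(
    undefined, "Q3_MANIFEST_ID",
    ifelse(elevated,
           ifelse(fid, "Q3_MANIFEST_ID", "Q2_LATENT_ID"),
           ifelse(fid, "Q4_FUNCTIONAL_ID_ACD", "Q1_ACD")))
  out <- data.frame(
    ratio = ratio,
    ratio_cutoff = cutoff,
    chr = panels$chr,
    functional_id = fid,
    ratio_undefined = undefined,
    quadrant = factor(quadrant, levels = thomas_quadrants)
  )
  class(out) <- c("thomas_result", class(out))
  out
}

#' Anemia, red-cell morphology and vitamin-deficiency flags
#'
#' Two anemia definitions are carried side by side: the unified surgical
#' threshold (Hb < 13 g/dL for both sexes) and the WHO definition
#' (Hb < 13 g/dL for men, < 12 g/dL for women; strict inequalities).
#' Morphology is assigned from MCV alone against the 80-99 fL reference
#' range (microcytic below, macrocytic above); MCH is carried in the panel
#' and reported but not used for assignment. Vitamin deficiencies use the
#' lower reference-range limits: B12 < 254 pg/mL, folate < 3.1 ng/mL.
#' Missing vitamins or MCV leave the corresponding flag `NA` (undefined),
#' never `FALSE`.
#'
#' @inheritParams classify_thomas
#' @return A `data.frame` with logical columns `anemic_unified`,
#'   `anemic_who`, `b12_deficient`, `folate_deficient` and factor
#'   `morphology` in `{microcytic, normocytic, macrocytic}`.
#' @examples
#' anemia_flags(lab_panel(hb = 12.5, sex = "female", mcv = 88))
#' @export
anemia_flags <- function(panels, config = pbm_config()) {
  stop_if_missing_cols(panels, "hb", "anemia flag input")
  if (any(is.na(panels$hb))) stop("hb is required for anemia flags")
  hb <- panels$hb
  sex <- if ("sex" %in% names(panels)) panels$sex else NA_character_
  anemic_unified <- hb < config$hb_cutoff
  anemic_who <- ifelse(is.na(sex), NA,
                       ifelse(sex == "male", hb < config$hb_cutoff,
                              hb < config$hb_who_female))
  mcv <- if ("mcv" %in% names(panels)) panels$mcv else NA_real_
  morphology <- factor(
    ifelse(is.na(mcv), NA_character_,
           ifelse(mcv < config$mcv_low, "microcytic",
                  ifelse(mcv > config$mcv_high, "macrocytic", "normocytic"))),
    levels = c("microcytic", "normocytic", "macrocytic"))
  b12 <- if ("vitb12" %in% names(panels)) panels$vitb12 else NA_real_
  fol <- if ("folate" %in% names(panels)) panels$folate else NA_real_
  data.frame(
    anemic_unified = anemic_unified,
    anemic_who = anemic_who,
    morphology = morphology,
    b12_deficient = ifelse(is.na(b12), NA, b12 < config$vitb12_low),
    folate_deficient = ifelse(is.na(fol), NA, fol < config$folate_low)
  )
}
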