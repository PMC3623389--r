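#' Transferrin saturation (TSAT)
#'
#' TSAT (\%) = serum iron (ug/dL) x 70.9 / transferrin (mg/dL), unrounded.
#' Missing inputs propagate as `NA` (never silently treated as zero).
#'
#' @param iron serum iron in ug/dL (`>= 0`).
#' @param transferrin transferrin in mg/dL (`> 0`).
#' @return Numeric vector of saturations in percent.
#' @examples
#' compute_tsat(100, 354.5) # 20
#' @export
compute_tsat <- function(iron, transferrin) {
  if (length(iron) != length(transferrin)) {
    if (length(iron) == 1) iron <- rep(iron, length(transferrin))
    else if (length(transferrin) == 1) transferrin <- rep(transferrin, length(iron))
    else stop("iron and transferrin must have the same length")
  }
  ok <- !is.na(iron) & !is.na(transferrin)
  if (any(transferrin[ok] <= 0)) stop("transferrin must be > 0")
  if (any(iron[ok] < 0)) stop("iron must be >= 0")
  iron * 70.9 / transferrin
}

#' sTfR / log ferritin index
#'
#' The discriminating index of the Thomas plot: soluble transferrin receptor
#' divided by the base-10 logarithm of ferritin. Base 10 follows the
#' convention of the Thomas-plot literature (the base is an assumption of
#' this implementation, documented, since several conventions circulate).
#' Ferritin at or below 1 ng/mL makes the logarithm non-positive; the index
#' is then returned as `NA` with attribute handling left to the caller —
#' downstream classification routes such panels to manifest iron deficiency,
#' because ferritin that low is itself unambiguous store depletion. Use
#' `stfr_ratio_defined()` to test definedness explicitly.
#'
#' @param stfr soluble transferrin receptor in mg/L (`> 0`).
#' @param ferritin ferritin in ng/mL (numerically identical to ug/L).
#' @return Numeric vector; `NA` where ferritin `<= 1` or any input missing.
#' @examples
#' stfr_ratio(3.0, 100) # 1.5
#' @export
stfr_ratio <- function(stfr, ferritin) {
  if (length(stfr) != length(ferritin)) {
    if (length(stfr) == 1) stfr <- rep(stfr, length(ferritin))
    else if (length(ferritin) == 1) ferritin <- rep(ferritin, length(stfr))
    else stop("stfr and ferritin must have the same length")
  }
  ok <- !is.na(stfr) & !is.na(ferritin)
  if (any(stfr[ok] <= 0)) stop("stfr must be > 0")
  if (any(ferritin[ok] <= 0)) stop("ferritin must be > 0")
  out <- rep(NA_real_, length(stfr))
  def <- ok & ferritin > 1
  out[def] <- stfr[def] / log10(ferritin[def])
  out
}

#' @rdname stfr_ratio
#' @export
stfr_ratio_defined <- function(stfr, ferritin) {
  !is.na(stfr) & !is.na(ferritin) & ferritin > 1
}

#' CRP-dependent cut-off for the sTfR/log ferritin index
#'
#' Without an acute-phase reaction (CRP <= 5 mg/L) the cut-off is 1.5; with
#' one (CRP > 5 mg/L) it drops to 0.8, because ferritin rises and the index
#' falls under inflammation.
#'
#' @param crp C-reactive protein in mg/L (`>= 0`); must be present.
#' @param config a [pbm_config()].
#' @return Numeric vector of cut-offs.
#' @examples
#' ratio_cutoff(c(0, 5, 5.01)) # 1.5 1.5 0.8
#' @export
ratio_cutoff <- function(crp, config = pbm_config()) {
  if (any(is.na(crp))) stop("cut-off selection requires CRP")
  if (any(crp < 0)) stop("CRP must be >= 0")
  ifelse(crp <= config$crp_boundary,
         config$ratio_cutoff_low_crp,
         config$ratio_cutoff_high_crp)
}

# ---- laboratory panel table -------------------------------------------------

panel_analytes <- c("hb", "ferritin", "stfr", "crp", "chr", "transferrin",
                    "iron", "mcv", "mch", "vitb12", "folate")

#' Construct and validate a laboratory panel table
#'
#' A panel table holds one row per patient measurement with fixed units:
#' `hb` (g/dL), `ferritin` (ng/mL), `stfr` (mg/L), `crp` (mg/L), `chr` (pg),
#' `transferrin` (mg/dL), `iron` (ug/dL), `mcv` (fL), `mch` (pg),
#' `vitb12` (pg/mL), `folate` (ng/mL), plus `sex` (`"male"`/`"female"`) and
#' `timepoint_day` (integer days relative to surgery, negative =
#' preoperative). Every analyte except `hb` may be missing; absence is an
#' explicit `NA`, never 0. Validation enforces positivity (CRP may be 0), an
#' Hb plausibility window of (2, 25) g/dL, and `timepoint_day` in [-90, 7].
#'
#' @param hb hemoglobin in g/dL (required).
#' @param sex `"male"` or `"female"` (may be `NA`).
#' @param timepoint_day integer days relative to surgery.
#' @param ... optional analytes from the schema above, recycled to length.
#' @return A `data.frame` of class `lab_panel`.
#' @examples
#' lab_panel(hb = 11.5, sex = "female", ferritin = 20, stfr = 2.8,
#'           crp = 1, chr = 27)
#' @export
lab_panel <- function(hb, sex = NA_character_, timepoint_day = -30L, ...) {
  extra <- list(...)
  bad <- setdiff(names(extra), panel_analytes)
  if (length(bad)) stop("unknown analyte(s): ", paste(bad, collapse = ", "))
  n <- length(hb)
  df <- data.frame(hb = as.numeric(hb),
                   sex = rep_len(as.character(sex), n),
                   timepoint_day = rep_len(as.integer(timepoint_day), n))
  for (a in setdiff(panel_analytes, "hb")) {
    df[[a]] <- if (a %in% names(extra)) rep_len(as.numeric(extra[[a]]), n)
               else NA_real_
  }
  validate_lab_panel(df)
}

#' @rdname lab_panel
#' @param x a data.frame with the panel schema columns.
#' @export
validate_lab_panel <- function(x) {
  stop_if_missing_cols(x, c("hb", "sex", "timepoint_day"), "lab panel")
  if (any(is.na(x$hb))) stop("hb is required for every panel row")
  if (any(x$hb <= 2 | x$hb >= 25)) {
    stop("hb outside the (2, 25) g/dL plausibility window")
  }
  if (any(!is.na(x$sex) & !x$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (any(!is.na(x$timepoint_day) &
          (x$timepoint_day < -90 | x$timepoint_day > 7))) {
    stop("timepoint_day must lie in [-90, 7]")
  }
  for (a in setdiff(panel_analytes, c("hb", "crp"))) {
    if (a %in% names(x) && any(!is.na(x[[a]]) & x[[a]] <= 0)) {
      stop("analyte '", a, "' must be > 0 when present")
    }
  }
  if ("crp" %in% names(x) && any(!is.na(x$crp) & x$crp < 0)) {
    stop("crp must be >= 0 when present")
  }
  class(x) <- unique(c("lab_panel", class(x)))
  x
}

#' Read / write laboratory panel tables as CSV
#'
#' Plain UTF-8 CSV with "." as decimal separator and the documented column
#' schema (see [lab_panel()]); empty cells are missing values.
#'
#' @param path file path.
#' @return `read_panels()` returns a validated `lab_panel` data.frame;
#'   `write_panels()` returns `path` invisibly.
#' @export
read_panels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (a in intersect(panel_analytes, names(df))) {
    df[[a]] <- as.numeric(df[[a]])   # all-missing columns parse as logical
  }
  validate_lab_panel(df)
}

#' @rdname read_panels
#' @param x a `lab_panel` data.frame.
#' @export
write_panels <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
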