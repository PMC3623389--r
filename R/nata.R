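#' NATA-grid anemia categories
#' @keywords internal
nata_categories <- c("ID", "ACD", "ID_AND_OR_ACD",
                     "UNCLASS_HIGH_FERR_LOW_TSAT",
                     "UNCLASS_MID_FERR_HIGH_TSAT")

#' Classify anemia by the NATA ferritin / TSAT grid
#'
#' The comparator scheme uses only ferritin and transferrin saturation.
#' The published band definitions ("and/or") overlap as written; the grid
#' implemented here is the disambiguation forced by the scheme's two
#' explicitly unclassifiable cells:
#'
#' * ferritin < 30 ng/mL (any TSAT) -> `ID` — depleted stores define iron
#'   deficiency regardless of saturation;
#' * ferritin > 100 & TSAT >= 20 -> `ACD`;
#' * ferritin in \[30, 100\] & TSAT < 20 -> `ID_AND_OR_ACD`;
#' * ferritin > 100 & TSAT < 20 -> `UNCLASS_HIGH_FERR_LOW_TSAT`;
#' * ferritin in \[30, 100\] & TSAT >= 20 -> `UNCLASS_MID_FERR_HIGH_TSAT`.
#'
#' The "30-100" band is closed on both ends; the outer bands are strict.
#' The five cells partition the (ferritin, TSAT) plane for ferritin > 0.
#'
#' @param ferritin ferritin in ng/mL (`> 0`, no missing values).
#' @param tsat_pct transferrin saturation in percent (`>= 0`), e.g. from
#'   [compute_tsat()].
#' @param config a [pbm_config()].
#' @return A `data.frame` of class `nata_result` with columns `ferritin`,
#'   `tsat_pct` and `category` (factor over the five cells).
#' @examples
#' classify_nata(c(10, 150, 65), c(15, 15, 25))$category
#' @export
classify_nata <- function(ferritin, tsat_pct, config = pbm_config()) {
  if (length(ferritin) != length(tsat_pct)) {
    stop("ferritin and tsat_pct must have the same length")
  }
  if (any(is.na(ferritin)) || any(is.na(tsat_pct))) {
    stop("cannot classify: ferritin and TSAT must both be present")
  }
  if (any(ferritin <= 0)) stop("ferritin must be > 0")
  if (any(tsat_pct < 0)) stop("tsat_pct must be >= 0")
  lo <- config$ferritin_low
  hi <- config$ferritin_high
  ts <- config$tsat_cutoff
  category <- ifelse(
    ferritin < lo, "ID",
    ifelse(ferritin > hi,
           ifelse(tsat_pct >= ts, "ACD", "UNCLASS_HIGH_FERR_LOW_TSAT"),
           ifelse(tsat_pct < ts, "ID_AND_OR_ACD",
                  "UNCLASS_MID_FERR_HIGH_TSAT")))
  out <- data.frame(ferritin = ferritin, tsat_pct = tsat_pct,
                    category = factor(category, levels = nata_categories))
  class(out) <- c("nata_result", class(out))
  out
}

#' Cross-tabulate Thomas-plot quadrants against NATA categories
#'
#' Builds the patient-aligned contingency table of the two classification
#' schemes and the fraction of patients the NATA grid leaves unclassifiable
#' (the two cells outside its three named categories).
#'
#' @param thomas a [classify_thomas()] result (or factor of quadrants).
#' @param nata a [classify_nata()] result (or factor of categories), aligned
#'   with `thomas` patient by patient.
#' @return A list of class `concordance_table` with elements `table`
#'   (quadrant x category counts), `n`, and `unclassifiable_fraction`
#'   (`NA` for empty input).
#' @examples
#' th <- factor(rep("Q1_ACD", 4), levels = preopanemia:::thomas_quadrants)
#' na <- classify_nata(c(10, 150, 65, 40), c(15, 15, 25, 10))
#' concordance_table(th, na)
#' @export
concordance_table <- function(thomas, nata) {
  q <- if (is.data.frame(thomas)) thomas$quadrant else thomas
  k <- if (is.data.frame(nata)) nata$category else nata
  if (length(q) != length(k)) {
    stop("thomas and nata results must be patient-aligned (equal length)")
  }
  q <- factor(q, levels = thomas_quadrants)
  k <- factor(k, levels = nata_categories)
  tab <- table(quadrant = q, nata = k)
  unclass_cells <- c("UNCLASS_HIGH_FERR_LOW_TSAT", "UNCLASS_MID_FERR_HIGH_TSAT")
  n <- length(q)
  structure(
    list(table = tab, n = n,
         unclassifiable_fraction =
           if (n == 0) NA_real_ else sum(tab[, unclass_cells]) / n),
    class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Thomas-plot vs NATA-grid concordance (n = ", x$n, ")\n", sep = "")
  print(x$table)
  if (!is.na(x$unclassifiable_fraction)) {
    cat(sprintf("NATA-unclassifiable fraction: %.3f\n",
                x$unclassifiable_fraction))
  }
  invisible(x)
}
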