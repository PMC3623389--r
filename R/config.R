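#' Pipeline configuration with the published cut-offs as defaults
#'
#' Every threshold used anywhere in the package is read from this object, so a
#' single override propagates consistently through classification, therapy and
#' reporting. The defaults are the cut-offs of the management algorithm:
#'
#' * `hb_cutoff` (g/dL): therapeutic hemoglobin threshold, 13 for both sexes.
#' * `hb_who_female` (g/dL): WHO anemia threshold for women, 12.
#' * `chr_cutoff` (pg): reticulocyte hemoglobin content below which
#'   erythropoiesis is considered iron-restricted (functional iron
#'   deficiency), 28.
#' * `ratio_cutoff_low_crp`, `ratio_cutoff_high_crp`: cut-offs for the
#'   sTfR/log10(ferritin) index, 1.5 without and 0.8 with an acute-phase
#'   reaction.
#' * `crp_boundary` (mg/L): CRP value separating the two ratio cut-offs, 5.
#' * `ferritin_low`, `ferritin_high` (ng/mL): NATA-grid ferritin bands,
#'   30 and 100.
#' * `tsat_cutoff` (percent): NATA-grid transferrin-saturation band, 20.
#' * `mcv_low`, `mcv_high` (fL): normocytic reference range 80-99.
#' * `vitb12_low` (pg/mL), `folate_low` (ng/mL): deficiency thresholds 254
#'   and 3.1 (lower reference-range limits).
#' * `scheduled_day` (days before surgery): default therapy scheduling, 20.
#' * `therapy_window_days`: therapy given within this many days before
#'   surgery excludes a record from before/after evaluation, 7.
#' * `prices`: a [price_table()].
#'
#' @param ... named overrides of any default listed above. Unknown names are
#'   an error.
#' @return An object of class `pbm_config` (a named list).
#' @examples
#' cfg <- pbm_config()
#' cfg$hb_cutoff
#' strict <- pbm_config(chr_cutoff = 29)
#' @export
pbm_config <- function(...) {
  cfg <- list(
    hb_cutoff            = 13,
    hb_who_female        = 12,
    chr_cutoff           = 28,
    ratio_cutoff_low_crp = 1.5,
    ratio_cutoff_high_crp = 0.8,
    crp_boundary         = 5,
    ferritin_low         = 30,
    ferritin_high        = 100,
    tsat_cutoff          = 20,
    mcv_low              = 80,
    mcv_high             = 99,
    vitb12_low           = 254,
    folate_low           = 3.1,
    scheduled_day        = 20,
    therapy_window_days  = 7,
    prices               = price_table()
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "pbm_config")
}

#' @export
print.pbm_config <- function(x, ...) {
  cat("<pbm_config>\n")
  flat <- x[setdiff(names(x), "prices")]
  for (nm in names(flat)) cat(sprintf("  %-22s %s\n", nm, format(flat[[nm]])))
  cat("  prices:\n")
  p <- x$prices
  cat(sprintf("    RBC unit        %8.2f EUR\n", p$rbc_eur_per_unit))
  cat(sprintf("    iron / 100 mg   %8.2f EUR\n", p$iron_eur_per_100mg))
  cat(sprintf("    ESA / 1000 IU   %8.2f EUR  (40000 IU free: %s)\n",
              p$esa_eur_per_1000iu, p$esa_40000_free))
  invisible(x)
}

#' Unit prices for the therapy cost model
#'
#' Defaults are the purchase prices in effect during the study: EUR 135 per
#' RBC unit, EUR 27.32 per 100 mg i.v. ferric carboxymaltose, EUR 0.69 per
#' 1000 I.U. erythropoietin zeta, and 40000 I.U. ESA doses free of charge
#' under a hospital agreement.
#'
#' @param rbc_eur_per_unit price of one packed red-cell unit (EUR).
#' @param iron_eur_per_100mg price per 100 mg i.v. iron (EUR).
#' @param esa_eur_per_1000iu price per 1000 I.U. ESA (EUR).
#' @param esa_40000_free logical; if `TRUE`, doses of exactly 40000 I.U. are
#'   charged at zero.
#' @return An object of class `price_table`.
#' @examples
#' price_table()
#' @export
price_table <- function(rbc_eur_per_unit = 135,
                        iron_eur_per_100mg = 27.32,
                        esa_eur_per_1000iu = 0.69,
                        esa_40000_free = TRUE) {
  stopifnot(rbc_eur_per_unit >= 0, iron_eur_per_100mg >= 0,
            esa_eur_per_1000iu >= 0, is.logical(esa_40000_free))
  structure(
    list(rbc_eur_per_unit = rbc_eur_per_unit,
         iron_eur_per_100mg = iron_eur_per_100mg,
         esa_eur_per_1000iu = esa_eur_per_1000iu,
         esa_40000_free = isTRUE(esa_40000_free)),
    class = "price_table"
  )
}

#' Read a configuration from YAML or JSON
#'
#' The file may override any subset of [pbm_config()] fields; `prices` may be
#' given as a nested mapping with [price_table()] field names.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pbm_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$prices)) raw$prices <- do.call(price_table, raw$prices)
  do.call(pbm_config, raw)
}
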