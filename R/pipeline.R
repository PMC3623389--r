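cohort_numeric_cols <- c("hb", "hb1", "hb1_day", "hb2", "hb2_day", "hb3",
                         "hb3_day", "hb4", "hb4_day", "timepoint_day",
                         "stfr", "ferritin", "crp", "chr", "transferrin",
                         "iron", "mcv", "mch", "vitb12", "folate",
                         "iron_mg", "esa_iu", "scheduled_day", "therapy_day",
                         "rbc_units")
cohort_mandatory_cols <- c("group", "sex", "hb1", "hb2", "hb3", "hb4",
                           "rbc_units")

#' Read / write a patient-record cohort as CSV
#'
#' Strict schema validation: mandatory columns (`group`, `sex`,
#' `hb1`..`hb4`, `rbc_units`) must be present; unknown columns produce a
#' warning and are carried through; malformed numeric cells are an error
#' naming the row and column. Plain UTF-8 CSV, "." decimal, empty cell =
#' missing. `read_cohort(write_cohort(x))` round-trips all records.
#'
#' @param path file path.
#' @return `read_cohort()` returns a `pbm_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  stop_if_missing_cols(df, cohort_mandatory_cols, "cohort file")
  known <- c("id", "group", "sex", "surgery", "etiology", "esa_route",
             "arm", "surgery_cancelled", cohort_numeric_cols)
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("unknown column(s) carried through unparsed: ",
            paste(unknown, collapse = ", "))
  }
  for (cn in intersect(cohort_numeric_cols, names(df))) {
    raw <- df[[cn]]
    empty <- is.na(raw) | raw == ""
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(val))
    if (length(bad)) {
      stop("malformed numeric value '", raw[bad[1]], "' in column '", cn,
           "', row ", bad[1])
    }
    df[[cn]] <- val
  }
  if ("surgery_cancelled" %in% names(df)) {
    df$surgery_cancelled <- as.logical(df$surgery_cancelled)
  }
  class(df) <- c("pbm_cohort", class(df))
  df
}

#' @rdname read_cohort
#' @param x a cohort `data.frame`.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Run the full anemia-management analysis pipeline
#'
#' Executes, in order: eligibility filtering, anemia flags and prevalence
#' (on the full reviewed cohort), Thomas-plot and NATA classification of
#' anemic included records with complete iron panels, therapy
#' recommendation, and per-group transfusion, cost and Hb-course
#' summaries. If a paired POCT table is supplied the method-agreement
#' report is added.
#'
#' @param cohort a `pbm_cohort` data.frame or a path to a cohort CSV.
#' @param config a [pbm_config()].
#' @param paired optional `data.frame` with columns `reference` and `poct`
#'   (paired Hb measurements, g/dL).
#' @return A list of class `pbm_report` with sections `counts`,
#'   `eligibility`, `prevalence`, `thomas`, `nata`, `concordance`,
#'   `therapy`, `transfusion`, `reduction`, `costs`, `hb_course`, and
#'   optionally `agreement`.
#' @examples
#' coh <- generate_cohort(cohort_design(n_group1 = 30, n_group2 = 40, seed = 3))
#' rep <- run_pipeline(coh)
#' rep$counts
#' @export
run_pipeline <- function(cohort, config = pbm_config(), paired = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  elig <- check_eligibility(cohort, config)
  included <- cohort[elig$included, , drop = FALSE]

  report <- list(
    counts = list(reviewed = nrow(cohort), included = nrow(included),
                  excluded = nrow(cohort) - nrow(included)),
    eligibility = as.list(table(elig$reason)),
    prevalence = list(
      unified = prevalence(cohort, "UNIFIED", config),
      who = prevalence(cohort, "WHO", config))
  )

  anemic <- included[included$hb1 < config$hb_cutoff, , drop = FALSE]
  panel_cols <- c("stfr", "ferritin", "crp", "chr")
  complete <- anemic[stats::complete.cases(anemic[, intersect(panel_cols,
                                                    names(anemic))]), ,
                     drop = FALSE]
  if (nrow(complete) > 0 && all(panel_cols %in% names(complete))) {
    thomas <- classify_thomas(complete, config)
    report$thomas <- as.list(table(thomas$quadrant))
    if (all(c("iron", "transferrin") %in% names(complete)) &&
        !anyNA(complete$iron) && !anyNA(complete$transferrin)) {
      tsat <- compute_tsat(complete$iron, complete$transferrin)
      nata <- classify_nata(complete$ferritin, tsat, config)
      conc <- concordance_table(thomas, nata)
      report$nata <- as.list(table(nata$category))
      report$concordance <- list(
        n = conc$n, unclassifiable_fraction = conc$unclassifiable_fraction)
    }
    plans <- recommend_therapy(complete$hb1, as.character(thomas$quadrant),
                               config = config)
    report$therapy <- as.list(table(plans$arm))
  } else {
    report$thomas <- report$therapy <- list()
  }

  groups <- unique(included$group)
  report$transfusion <- lapply(stats::setNames(nm = groups), function(g) {
    sub <- included[included$group == g, , drop = FALSE]
    list(all = transfusion_summary(sub, "all", config),
         anemic = transfusion_summary(sub, "anemic", config))
  })
  if (all(c("I", "II") %in% groups)) {
    upp <- vapply(c("I", "II"), function(g) {
      report$transfusion[[g]]$all$units_per_patient
    }, numeric(1))
    if (upp["I"] > 0) report$reduction <- reduction_pct(upp["I"], upp["II"])
  }
  report$costs <- lapply(stats::setNames(nm = groups), function(g) {
    cost_report(included[included$group == g, , drop = FALSE], config$prices)
  })
  report$hb_course <- lapply(stats::setNames(nm = groups), function(g) {
    sub <- included[included$group == g, , drop = FALSE]
    list(all = hb_course(sub, "all", config = config),
         anemic = hb_course(sub, "anemic", config = config))
  })
  if (!is.null(paired)) {
    report$agreement <- agreement_report(paired$reference, paired$poct)
  }
  class(report) <- "pbm_report"
  report
}

#' Write a pipeline report to disk
#'
#' Writes `report.json` (machine-readable, full bundle) and `report.txt`
#' (human-readable summary) into `dir`.
#'
#' @param report a `pbm_report` from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  plain <- rapply(unclass(report), function(x) {
    if (inherits(x, "table")) as.list(x) else x
  }, how = "replace")
  jsonlite::write_json(plain, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null", na = "null")
  con <- file(file.path(dir, "report.txt"), "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(dir)
}

#' @export
print.pbm_report <- function(x, ...) {
  cat("Preoperative anemia management report\n")
  cat(sprintf("  reviewed %d, included %d, excluded %d\n",
              x$counts$reviewed, x$counts$included, x$counts$excluded))
  cat(sprintf("  prevalence: unified %.1f%%, WHO %.1f%%\n",
              x$prevalence$unified$percent, x$prevalence$who$percent))
  if (length(x$thomas)) {
    cat("  Thomas quadrants:",
        paste(names(x$thomas), unlist(x$thomas), sep = "=", collapse = ", "),
        "\n")
  }
  if (length(x$therapy)) {
    cat("  therapy arms:",
        paste(names(x$therapy), unlist(x$therapy), sep = "=", collapse = ", "),
        "\n")
  }
  for (g in names(x$transfusion)) {
    ts <- x$transfusion[[g]]$all
    cat(sprintf("  group %s: %d/%d transfused (%d%%), %d RBC units, cost %.2f EUR\n",
                g, ts$transfused_patients, ts$n, ts$rate_pct,
                ts$total_rbc_units, x$costs[[g]]$cost_total))
  }
  if (!is.null(x$reduction)) {
    cat(sprintf("  units/patient reduction (I -> II): %d%%\n",
                x$reduction$pct_rounded))
  }
  if (!is.null(x$agreement)) {
    cat(sprintf("  POCT agreement: bias %+.2f, LoA [%+.2f, %+.2f], r %.3f, alpha %.3f\n",
                x$agreement$bias, x$agreement$loa_low, x$agreement$loa_high,
                x$agreement$pearson_r, x$agreement$cronbach_alpha))
  }
  invisible(x)
}
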