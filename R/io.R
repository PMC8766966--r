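#' Read a measurement-record table
#'
#' Comma-separated, UTF-8, period decimal separator, mandatory header with
#' the [measurement_columns()] names. Rows are validated (known roles,
#' non-negative signals, nominal present exactly for the roles that carry
#' one) and errors name the offending data line.
#'
#' @param path path to a CSV file.
#' @param design optional [assay_design()]; when given, analyte codes are
#'   checked against it.
#' @return a tibble of measurement records.
#' @export
read_measurements <- function(path, design = NULL) {
  if (!file.exists(path))
    stop_tdm("tdm_parse_error", sprintf("measurement file not found: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(measurement_columns(), names(tab))
  if (length(missing))
    stop_tdm("tdm_parse_error",
             sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  line <- seq_len(nrow(tab)) + 1L   # header is line 1
  bad_role <- !(tab$role %in% measurement_roles())
  if (any(bad_role))
    stop_tdm("tdm_parse_error",
             sprintf("unknown role '%s' at line %d", tab$role[bad_role][1L],
                     line[bad_role][1L]))
  for (col in c("area_analyte", "area_is", "height_analyte")) {
    v <- tab[[col]]
    bad <- !is.numeric(v) | !is.finite(v) | v < 0
    if (any(bad, na.rm = FALSE))
      stop_tdm("tdm_parse_error",
               sprintf("non-numeric or negative %s at line %d", col,
                       line[which(bad)[1L]]))
  }
  needs_nominal <- tab$role %in% c("standard", "qc_pre_spiked",
                                   "qc_post_spiked", "neat", "dilution")
  bad_nom <- (needs_nominal & (is.na(tab$nominal) | tab$nominal <= 0)) |
    (tab$role == "blank" & !is.na(tab$nominal))
  if (any(bad_nom))
    stop_tdm("tdm_parse_error",
             sprintf("inconsistent role/nominal combination at line %d",
                     line[which(bad_nom)[1L]]))
  if (!is.null(design)) {
    unknown <- setdiff(unique(tab$analyte), names(design$analytes))
    if (length(unknown))
      stop_tdm("tdm_parse_error",
               sprintf("analyte code(s) not in the design: %s",
                       paste(unknown, collapse = ", ")))
  }
  tab
}

#' Write a measurement-record table
#'
#' @param records measurement records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  readr::write_csv(records[, measurement_columns()], path, progress = FALSE)
  invisible(path)
}

round_report <- function(x, dp) ifelse(is.na(x), NA_real_, round_half_up(x, dp))

#' Render a validation report to CSV and JSON
#'
#' The delimited output mirrors the validation-table layout (accuracy,
#' intra-/inter-day RSD, recovery, extraction efficiency, matrix effect and
#' IS-normalized matrix effect, each mean with RSD) with percentages at 1
#' decimal place and concentrations at 2; the JSON twin carries full
#' precision.
#'
#' @param report a `tdm_validation_report` from [validate_batch()].
#' @param dir output directory (created if missing).
#' @param stem file stem, default `"validation_report"`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_validation_report <- function(report, dir, stem = "validation_report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rounded <- report
  pct_cols <- c("accuracy", "intra_day_rsd", "inter_day_rsd",
                "recovery_mean", "recovery_rsd", "ee_mean", "ee_rsd",
                "me_mean", "me_rsd", "isnme_mean", "isnme_rsd")
  for (col in intersect(pct_cols, names(rounded)))
    rounded[[col]] <- round_report(rounded[[col]], 1L)
  if ("nominal" %in% names(rounded))
    rounded$nominal <- round_report(rounded$nominal, 2L)
  csv <- file.path(dir, paste0(stem, ".csv"))
  json <- file.path(dir, paste0(stem, ".json"))
  readr::write_csv(rounded, csv, progress = FALSE)
  jsonlite::write_json(as.data.frame(report), json, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(csv = csv, json = json))
}

#' Render a concordance result to CSV and JSON
#'
#' @param result a `tdm_concordance` from [concordance()].
#' @param dir output directory.
#' @param stem file stem, default `"concordance"`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_concordance <- function(result, dir, stem = "concordance") {
  stopifnot(inherits(result, "tdm_concordance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  row <- tibble::tibble(
    tp = result$tp, fp = result$fp, fn = result$fn, tn = result$tn,
    n_matches = result$n_matches,
    sensitivity = round_report(result$sensitivity, 1L),
    specificity = round_report(result$specificity, 1L),
    accuracy = round_report(result$accuracy, 1L))
  csv <- file.path(dir, paste0(stem, ".csv"))
  json <- file.path(dir, paste0(stem, ".json"))
  readr::write_csv(row, csv, progress = FALSE)
  jsonlite::write_json(unclass(result), json, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = json))
}

#' Quantify unknown samples against fitted calibration curves
#'
#' @param records measurement records with role `"patient"`.
#' @param curves named list of `tdm_curve` objects keyed by analyte.
#' @param response_mode `"is_ratio"` (default) or `"area"`.
#' @return the records with `conc` and `qualifier` columns appended.
#' @export
quantify_samples <- function(records, curves,
                             response_mode = c("is_ratio", "area")) {
  response_mode <- match.arg(response_mode)
  pts <- records[records$role == "patient", ]
  if (!nrow(pts))
    stop_tdm("tdm_no_matches", "no patient-role records to quantify")
  out <- dplyr::bind_rows(lapply(split(pts, pts$analyte), function(sub) {
    curve <- curves[[sub$analyte[[1L]]]]
    if (is.null(curve))
      stop_tdm("tdm_unmatched_design",
               sprintf("no calibration curve for analyte %s", sub$analyte[[1L]]))
    inv <- inverse_predict(curve, response_of(sub, response_mode))
    sub$conc <- inv$conc
    sub$qualifier <- inv$qualifier
    sub
  }))
  out[order(out$analyte, out$session, out$replicate), ]
}
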