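#' Measurement-record column contract
#'
#' Long-format per-injection table used throughout the pipeline. Columns:
#' `analyte`, `role` (one of `standard`, `qc_pre_spiked`, `qc_post_spiked`,
#' `neat`, `blank`, `dilution`, `patient`), `qc_level` (`H`/`M`/`L` or
#' `none`), `session`, `replicate`, `matrix_lot`, `nominal` (ng/ml, `NA` for
#' roles without one), `area_analyte`, `area_is`, `height_analyte`.
#'
#' @return character vector of required column names.
#' @export
measurement_columns <- function() {
  c("analyte", "role", "qc_level", "session", "replicate", "matrix_lot",
    "nominal", "area_analyte", "area_is", "height_analyte")
}

measurement_roles <- function() {
  c("standard", "qc_pre_spiked", "qc_post_spiked", "neat", "blank",
    "dilution", "patient")
}

response_of <- function(records, response_mode) {
  if (response_mode == "is_ratio") records$area_analyte / records$area_is
  else records$area_analyte
}

#' Fit per-session calibration curves for one analyte
#'
#' @param records measurement records (see [measurement_columns()]).
#' @param spec the [analyte_spec()] for the analyte.
#' @param response_mode `"is_ratio"` (analyte/IS area ratio, default) or
#'   `"area"` (raw analyte area).
#' @param weighting weighting scheme, default `"1/x"`.
#' @return named list of `tdm_curve` objects, one per session.
#' @export
fit_session_curves <- function(records, spec,
                               response_mode = c("is_ratio", "area"),
                               weighting = "1/x") {
  response_mode <- match.arg(response_mode)
  std <- records[records$analyte == spec$name & records$role == "standard", ]
  if (!nrow(std))
    stop_tdm("tdm_unmatched_design",
             sprintf("no calibration standards for analyte %s", spec$name))
  sessions <- sort(unique(std$session))
  curves <- lapply(sessions, function(s) {
    sub <- std[std$session == s, ]
    fit_calibration(
      calibration_points(sub$nominal, response_of(sub, response_mode)),
      weighting = weighting, analyte = spec$name, lod = spec$lod,
      range = c(spec$lloq, spec$std9)
    )
  })
  stats::setNames(curves, as.character(sessions))
}

#' Run the full validation battery on a measurement batch
#'
#' For each analyte: fits a through-origin weighted quadratic calibration per
#' session, back-calculates the pre-spiked QC samples with their session's
#' curve, and reports accuracy, intra-day and inter-day imprecision,
#' recovery, extraction efficiency, matrix effect and IS-normalized matrix
#' effect per QC level, with guideline pass flags.
#'
#' @param records measurement records (see [measurement_columns()]).
#' @param design an [assay_design()].
#' @param response_mode `"is_ratio"` (default) or `"area"` for calibration;
#'   recovery/extraction/matrix-effect metrics always use raw analyte areas.
#' @param weighting calibration weighting scheme, default `"1/x"`.
#' @param intra_session session used for intra-day imprecision (default:
#'   first session present).
#' @param inter_method `"pooled"` (default) or `"session_means"`.
#' @return a tibble of class `tdm_validation_report`, one row per
#'   (analyte, QC level).
#' @export
validate_batch <- function(records, design,
                           response_mode = c("is_ratio", "area"),
                           weighting = "1/x", intra_session = NULL,
                           inter_method = c("pooled", "session_means")) {
  response_mode <- match.arg(response_mode)
  inter_method <- match.arg(inter_method)
  stopifnot(inherits(design, "assay_design"))
  rows <- list()
  for (spec in design$analytes) {
    an <- records[records$analyte == spec$name, ]
    if (!nrow(an)) next
    curves <- fit_session_curves(an, spec, response_mode, weighting)
    qc_nominal <- build_qc_levels(spec$std9, spec$qc_fractions)
    pre_all <- an[an$role == "qc_pre_spiked", ]
    isession <- if (is.null(intra_session)) min(pre_all$session) else intra_session
    for (lvl in c("H", "M", "L")) {
      pre <- pre_all[pre_all$qc_level == lvl, ]
      post <- an[an$role == "qc_post_spiked" & an$qc_level == lvl, ]
      neat <- an[an$role == "neat" & an$qc_level == lvl, ]
      if (!nrow(pre)) next
      pre <- pre[order(pre$session, pre$replicate), ]
      back_tab <- dplyr::bind_rows(lapply(split(pre, pre$session), function(sub) {
        curve <- curves[[as.character(sub$session[[1L]])]]
        tibble::tibble(
          value = inverse_predict(curve, response_of(sub, response_mode))$conc,
          session = sub$session)
      }))
      rec <- recovery(data.frame(area = pre$area_analyte, session = pre$session),
                      data.frame(area = neat$area_analyte, session = neat$session))
      ee <- extraction_efficiency(
        data.frame(area = pre$area_analyte, session = pre$session),
        data.frame(area = post$area_analyte, session = post$session))
      me <- matrix_effect(data.frame(area = post$area_analyte, lot = post$matrix_lot),
                          data.frame(area = neat$area_analyte))
      isnme <- is_normalized_me(
        data.frame(area_analyte = post$area_analyte, area_is = post$area_is,
                   lot = post$matrix_lot),
        data.frame(area_analyte = neat$area_analyte, area_is = neat$area_is))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        analyte = spec$name, qc_level = lvl, nominal = qc_nominal[[lvl]],
        n = nrow(pre),
        accuracy = accuracy(back_tab$value, qc_nominal[[lvl]]),
        intra_day_rsd = imprecision(back_tab, "intra_day", session = isession),
        inter_day_rsd = imprecision(back_tab, "inter_day",
                                    inter_method = inter_method),
        recovery_mean = rec$mean, recovery_rsd = rec$rsd,
        ee_mean = ee$mean, ee_rsd = ee$rsd,
        me_mean = me$mean, me_rsd = me$rsd,
        isnme_mean = isnme$mean, isnme_rsd = isnme$rsd
      )
    }
  }
  if (!length(rows))
    stop_tdm("tdm_unmatched_design", "no QC records found for any design analyte")
  report <- evaluate_compliance(dplyr::bind_rows(rows))
  class(report) <- c("tdm_validation_report", class(report))
  report
}

#' Determine limits for every analyte of a batch
#'
#' Back-calculates the sub-LLOQ dilution-series records against the first
#' session's calibration curve, estimates blank baseline noise from the blank
#' records' heights, and applies [determine_limits()].
#'
#' @inheritParams validate_batch
#' @return a tibble with one row per analyte: `analyte`, `lloq`, `lod`.
#' @export
determine_limits_batch <- function(records, design,
                                   response_mode = c("is_ratio", "area"),
                                   weighting = "1/x") {
  response_mode <- match.arg(response_mode)
  rows <- list()
  for (spec in design$analytes) {
    an <- records[records$analyte == spec$name, ]
    dil <- an[an$role == "dilution", ]
    blank <- an[an$role == "blank", ]
    if (!nrow(dil) || !nrow(blank)) next
    curves <- fit_session_curves(an, spec, response_mode, weighting)
    curve <- curves[[1L]]
    measured <- inverse_predict(curve, response_of(dil, response_mode))$conc
    lim <- determine_limits(
      data.frame(conc = dil$nominal, measured = measured,
                 height = dil$height_analyte),
      noise = estimate_blank_noise(blank$height_analyte))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      analyte = spec$name, lloq = lim$lloq, lod = lim$lod)
  }
  if (!length(rows))
    stop_tdm("tdm_unmatched_design", "no dilution-series records found")
  dplyr::bind_rows(rows)
}

#' Run validation, limit determination and selectivity in one pass
#'
#' @inheritParams validate_batch
#' @return list with elements `report` (the [validate_batch()] table),
#'   `limits` ([determine_limits_batch()]) and `selectivity` (per-analyte,
#'   per-lot [selectivity_check()] results).
#' @export
run_validation <- function(records, design,
                           response_mode = c("is_ratio", "area"),
                           weighting = "1/x", intra_session = NULL,
                           inter_method = c("pooled", "session_means")) {
  response_mode <- match.arg(response_mode)
  inter_method <- match.arg(inter_method)
  report <- validate_batch(records, design, response_mode, weighting,
                           intra_session, inter_method)
  limits <- determine_limits_batch(records, design, response_mode, weighting)
  sel <- list()
  for (spec in design$analytes) {
    an <- records[records$analyte == spec$name, ]
    blanks <- an[an$role == "blank", ]
    lloq_rec <- an[an$role == "dilution" & an$nominal == spec$lloq, ]
    if (!nrow(lloq_rec))
      lloq_rec <- an[an$role == "standard" &
                       abs(an$nominal - spec$lloq) < 1e-9 * spec$lloq, ]
    if (!nrow(blanks) || !nrow(lloq_rec)) next
    tab <- selectivity_check(
      data.frame(lot = blanks$matrix_lot, area_analyte = blanks$area_analyte,
                 area_is = blanks$area_is),
      lloq_rec[, c("area_analyte", "area_is")])
    tab$analyte <- spec$name
    sel[[length(sel) + 1L]] <- tab[, c("analyte", "lot", "analyte_fraction",
                                       "is_fraction", "pass")]
  }
  list(report = report, limits = limits,
       selectivity = if (length(sel)) dplyr::bind_rows(sel) else NULL)
}
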