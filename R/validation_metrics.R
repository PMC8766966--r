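#' Accuracy as percent of nominal
#'
#' @param measured back-calculated concentrations (ng/ml).
#' @param nominal the nominal concentration (ng/ml), > 0.
#' @return `100 * mean(measured) / nominal`.
#' @export
accuracy <- function(measured, nominal) {
  if (length(nominal) != 1L || !is.finite(nominal) || nominal <= 0)
    stop_tdm("tdm_invalid_nominal", "nominal must be a single positive number")
  if (!length(measured))
    stop_tdm("tdm_insufficient_replicates", "at least one measured value is required")
  100 * mean(measured) / nominal
}

#' Relative standard deviation
#'
#' Imprecision measure: `100 * sd / mean`, sample standard deviation with the
#' n-1 denominator.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  if (length(values) < 2L)
    stop_tdm("tdm_insufficient_replicates", "RSD requires at least 2 values")
  m <- mean(values)
  if (m == 0)
    stop_tdm("tdm_undefined_rsd", "RSD is undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Intra- or inter-day imprecision
#'
#' Intra-day imprecision is the RSD over the replicates of one designated
#' session; inter-day imprecision pools the back-calculated values of all
#' sessions (the maximal-degrees-of-freedom reading of a multi-session
#' validation; set `inter_method = "session_means"` for the RSD of session
#' means instead).
#'
#' @param data data frame with columns `value` and `session`.
#' @param scope `"intra_day"` or `"inter_day"`.
#' @param session session used for intra-day imprecision (default: first).
#' @param inter_method `"pooled"` (default) or `"session_means"`.
#' @return RSD in percent.
#' @export
imprecision <- function(data, scope = c("intra_day", "inter_day"),
                        session = NULL, inter_method = c("pooled", "session_means")) {
  scope <- match.arg(scope)
  inter_method <- match.arg(inter_method)
  if (!all(c("value", "session") %in% names(data)))
    stop_tdm("tdm_invalid_points", "data must have columns 'value' and 'session'")
  if (scope == "intra_day") {
    if (is.null(session)) session <- min(data$session)
    v <- data$value[data$session == session]
    if (length(v) < 2L)
      stop_tdm("tdm_insufficient_replicates",
               sprintf("intra-day imprecision needs >= 2 replicates in session %s", session))
    rsd(v)
  } else {
    if (length(unique(data$session)) < 2L)
      stop_tdm("tdm_insufficient_replicates", "inter-day imprecision needs >= 2 sessions")
    if (inter_method == "pooled") rsd(data$value)
    else rsd(tapply(data$value, data$session, mean))
  }
}

# package per-group metric values as mean / across-group RSD. Signed effects
# (matrix effect, IS-nME) report the RSD of the underlying response ratio,
# 100 * sd / (100 + mean): a mean effect near zero is a ratio near 1, so the
# dispersion stays well defined on either side of zero.
summarize_groups <- function(groups, values, signed = FALSE) {
  spread <- if (length(values) < 2L) NA_real_
            else if (signed) 100 * stats::sd(values) / abs(100 + mean(values))
            else rsd(values)
  list(mean = mean(values), rsd = spread,
       by_group = tibble::tibble(group = groups, value = values))
}

#' Recovery: extracted versus directly injected signal
#'
#' Per validation session, `REC_s = 100 * mean(area pre-spiked) / mean(area
#' neat)`, where pre-spiked samples were spiked into blank saliva before
#' extraction and neat samples are the chemical mix injected directly. The
#' across-session mean and RSD are reported.
#'
#' @param pre_spiked data frame with columns `area` and `session`.
#' @param neat data frame with columns `area` and `session`.
#' @return list with `mean`, `rsd` and the per-session values (`by_group`).
#' @export
recovery <- function(pre_spiked, neat) {
  check_matched(pre_spiked, neat, "session")
  groups <- sort(unique(pre_spiked$session))
  per <- vapply(groups, function(s) {
    100 * mean(pre_spiked$area[pre_spiked$session == s]) /
      mean(neat$area[neat$session == s])
  }, numeric(1))
  summarize_groups(groups, per)
}

#' Extraction efficiency: pre-spiked versus post-spiked signal
#'
#' `EE_s = 100 * mean(area pre-spiked) / mean(area post-spiked)` per session;
#' post-spiked samples are blank saliva extracted first and spiked after, so
#' the ratio isolates the loss attributable to extraction.
#'
#' @param pre_spiked data frame with columns `area` and `session`.
#' @param post_spiked data frame with columns `area` and `session`.
#' @return list with `mean`, `rsd` and per-session values.
#' @export
extraction_efficiency <- function(pre_spiked, post_spiked) {
  check_matched(pre_spiked, post_spiked, "session")
  groups <- sort(unique(pre_spiked$session))
  per <- vapply(groups, function(s) {
    100 * mean(pre_spiked$area[pre_spiked$session == s]) /
      mean(post_spiked$area[post_spiked$session == s])
  }, numeric(1))
  summarize_groups(groups, per)
}

#' Matrix effect by post-extraction addition
#'
#' Per blank-matrix lot, `ME_l = 100 * (mean(area post-spiked in lot l) /
#' mean(area neat) - 1)`: negative values are ion suppression, positive ones
#' enhancement. Mean and RSD are taken across lots.
#'
#' @param post_spiked data frame with columns `area` and `lot`.
#' @param neat data frame with column `area` (direct injections; not
#'   lot-specific).
#' @return list with signed `mean`, `rsd` and per-lot values.
#' @export
matrix_effect <- function(post_spiked, neat) {
  if (!nrow(post_spiked) || !nrow(neat))
    stop_tdm("tdm_unmatched_design", "matrix effect needs post-spiked and neat records")
  lots <- sort(unique(post_spiked$lot))
  per <- vapply(lots, function(l) {
    100 * (mean(post_spiked$area[post_spiked$lot == l]) / mean(neat$area) - 1)
  }, numeric(1))
  summarize_groups(lots, per, signed = TRUE)
}

#' Internal-standard normalized matrix effect
#'
#' Ratio-of-ratios form: per lot, `IS-nME_l = 100 * ((analyte/IS area ratio,
#' post-spiked) / (analyte/IS area ratio, neat) - 1)`, with the per-injection
#' ratio averaged within each lot. An isotope-labelled IS co-suppressed with
#' its analyte cancels exactly, giving 0.
#'
#' @param post_spiked data frame with columns `area_analyte`, `area_is`, `lot`.
#' @param neat data frame with columns `area_analyte`, `area_is`.
#' @return list with signed `mean`, `rsd` and per-lot values.
#' @export
is_normalized_me <- function(post_spiked, neat) {
  if (any(post_spiked$area_is <= 0) || any(neat$area_is <= 0))
    stop_tdm("tdm_invalid_is", "internal standard areas must be positive")
  if (!nrow(post_spiked) || !nrow(neat))
    stop_tdm("tdm_unmatched_design", "IS-nME needs post-spiked and neat records")
  neat_ratio <- mean(neat$area_analyte / neat$area_is)
  post_ratio <- post_spiked$area_analyte / post_spiked$area_is
  lots <- sort(unique(post_spiked$lot))
  per <- vapply(lots, function(l) {
    100 * (mean(post_ratio[post_spiked$lot == l]) / neat_ratio - 1)
  }, numeric(1))
  summarize_groups(lots, per, signed = TRUE)
}

check_matched <- function(x, y, group) {
  if (!nrow(x) || !nrow(y))
    stop_tdm("tdm_unmatched_design", "both roles must contribute records")
  missing <- setdiff(unique(x[[group]]), unique(y[[group]]))
  if (length(missing))
    stop_tdm("tdm_unmatched_design",
             sprintf("no counterpart records for %s %s", group,
                     paste(missing, collapse = ", ")))
}

#' Determine the quantification and detection limits from a dilution series
#'
#' Walks a descending dilution series of the lowest standard. The LLOQ is the
#' lowest concentration whose replicates show absolute deviation from nominal
#' below 20%, RSD below 20% and signal-to-noise above 5; the LOD is the
#' lowest concentration with signal-to-noise of at least 3, the point at
#' which a peak is still clearly distinguishable from blank. S/N is peak
#' height divided by the blank baseline-noise estimate (standard deviation of
#' blank heights; supply your own estimator output via `noise`). LOD <= LLOQ
#' is enforced.
#'
#' @param series data frame with columns `conc` (nominal, ng/ml), `measured`
#'   (back-calculated, ng/ml) and `height` (peak height), replicate rows per
#'   level.
#' @param noise blank baseline-noise estimate, > 0 (same units as `height`).
#' @return list with `lloq`, `lod` and a per-level `levels` tibble
#'   (`conc`, `deviation_pct`, `rsd_pct`, `sn`).
#' @export
determine_limits <- function(series, noise) {
  if (!all(c("conc", "measured", "height") %in% names(series)))
    stop_tdm("tdm_invalid_points", "series must have columns conc, measured, height")
  if (length(noise) != 1L || !is.finite(noise) || noise <= 0)
    stop_tdm("tdm_invalid_points", "noise must be a single positive number")
  levels <- sort(unique(series$conc))
  stats_tab <- dplyr::bind_rows(lapply(levels, function(cc) {
    sub <- series[series$conc == cc, ]
    tibble::tibble(
      conc = cc,
      deviation_pct = 100 * (mean(sub$measured) - cc) / cc,
      rsd_pct = if (nrow(sub) >= 2L) rsd(sub$measured) else NA_real_,
      sn = mean(sub$height) / noise
    )
  }))
  ok_lloq <- abs(stats_tab$deviation_pct) < 20 &
    (is.na(stats_tab$rsd_pct) | stats_tab$rsd_pct < 20) &
    !is.na(stats_tab$rsd_pct) &
    stats_tab$sn > 5
  if (!any(ok_lloq))
    stop_tdm("tdm_method_insensitive",
             "no dilution level satisfies the LLOQ criteria (|bias| < 20%, RSD < 20%, S/N > 5)")
  lloq <- min(stats_tab$conc[ok_lloq])
  ok_lod <- stats_tab$sn >= 3
  lod <- min(c(stats_tab$conc[ok_lod], lloq))
  list(lloq = lloq, lod = min(lod, lloq), levels = stats_tab)
}

#' Blank baseline-noise estimate
#'
#' @param heights blank peak heights (>= 2 values).
#' @return their sample standard deviation.
#' @export
estimate_blank_noise <- function(heights) {
  if (length(heights) < 2L)
    stop_tdm("tdm_insufficient_replicates", "noise estimation needs >= 2 blank heights")
  stats::sd(heights)
}

#' Selectivity check against blank matrix lots
#'
#' A blank-matrix lot passes when its mean analyte response stays strictly
#' below 20% of the mean LLOQ-level analyte response and its mean IS response
#' stays strictly below 5% of the mean IS response of the LLOQ injections
#' (the customary interference thresholds of bioanalytical guidelines).
#'
#' @param blanks data frame with columns `lot`, `area_analyte`, `area_is`.
#' @param lloq_records data frame with columns `area_analyte`, `area_is` from
#'   LLOQ-level injections.
#' @return tibble with per-lot response fractions and a `pass` flag.
#' @export
selectivity_check <- function(blanks, lloq_records) {
  if (!nrow(lloq_records))
    stop_tdm("tdm_unmatched_design", "LLOQ reference records are required")
  ref_analyte <- mean(lloq_records$area_analyte)
  ref_is <- mean(lloq_records$area_is)
  lots <- sort(unique(blanks$lot))
  dplyr::bind_rows(lapply(lots, function(l) {
    sub <- blanks[blanks$lot == l, ]
    fa <- mean(sub$area_analyte) / ref_analyte
    fi <- mean(sub$area_is) / ref_is
    tibble::tibble(lot = l, analyte_fraction = fa, is_fraction = fi,
                   pass = fa < 0.20 & fi < 0.05)
  }))
}

#' Judge a validation report against guideline bounds
#'
#' Accuracy bias and both imprecision RSDs must stay strictly below 15% at
#' the QC levels (H, M, L) and strictly below 20% at the LLOQ level. Failing
#' cells are flagged, not dropped: a panel assay can be fit for purpose with
#' documented exceptions at the very low end.
#'
#' @param report a validation report tibble as produced by [validate_batch()]
#'   (columns `accuracy`, `intra_day_rsd`, `inter_day_rsd`, `qc_level`).
#' @param qc_bound percent bound at QC levels (default 15).
#' @param lloq_bound percent bound at the LLOQ level (default 20).
#' @return the report with `pass` and `flags` columns appended (or replaced).
#' @export
evaluate_compliance <- function(report, qc_bound = 15, lloq_bound = 20) {
  bound <- ifelse(report$qc_level == "LLOQ", lloq_bound, qc_bound)
  bias_ok <- abs(report$accuracy - 100) < bound
  intra_ok <- report$intra_day_rsd < bound
  inter_ok <- report$inter_day_rsd < bound
  flags <- mapply(function(b, i1, i2) {
    f <- c(if (!b) "bias", if (!i1) "intra_rsd", if (!i2) "inter_rsd")
    if (length(f)) paste(f, collapse = ",") else ""
  }, bias_ok, intra_ok, inter_ok)
  report$pass <- bias_ok & intra_ok & inter_ok
  report$flags <- unname(flags)
  report
}

#' Collection-device retention: loss and severity class
#'
#' Compares concentrations measured before and after passage through the
#' absorbent swab of the saliva collection device. Loss is
#' `100 * (post - pre) / pre` (negative = retained by the fiber). Classes:
#' `severe` (loss <= -50%), `moderate` (-50% < loss <= -20%), `negligible`
#' (|loss| < 20%, consistent with casual error), `increase` (loss >= +20%).
#'
#' @param pre concentrations before device contact (ng/ml), all > 0.
#' @param post paired concentrations after device contact (ng/ml).
#' @return list with `mean_loss_pct`, `class`, and the per-pair losses.
#' @export
salivette_retention <- function(pre, post) {
  if (length(pre) != length(post) || !length(pre))
    stop_tdm("tdm_invalid_pair", "pre and post must be non-empty and paired")
  if (any(!is.finite(pre)) || any(pre <= 0))
    stop_tdm("tdm_invalid_pair", "pre-device concentrations must be positive")
  losses <- 100 * (post - pre) / pre
  m <- mean(losses)
  list(mean_loss_pct = m, class = retention_class(m), losses = losses)
}

#' @rdname salivette_retention
#' @param loss_pct signed loss percentages.
#' @export
retention_class <- function(loss_pct) {
  cls <- character(length(loss_pct))
  cls[loss_pct <= -50] <- "severe"
  cls[loss_pct > -50 & loss_pct <= -20] <- "moderate"
  cls[abs(loss_pct) < 20] <- "negligible"
  cls[loss_pct >= 20] <- "increase"
  cls
}
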