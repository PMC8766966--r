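#' Classify a measured concentration against the detection limits
#'
#' Three-way call: `not_detected` below the LOD, `detected_sub_lloq` between
#' LOD and LLOQ (a reliable sign of drug intake, but with a quantification
#' error risk above 20%), `quantified` at or above the LLOQ. Boundaries are
#' half-open: exactly the LOD counts as detected, exactly the LLOQ as
#' quantified. For adherence purposes a sample is positive from the LOD
#' upward — sub-LLOQ saliva signals with a clean peak are treated as evidence
#' of intake.
#'
#' @param conc measured concentrations (ng/ml).
#' @param lod limit of detection (ng/ml).
#' @param lloq lower limit of quantification (ng/ml); must exceed `lod`.
#' @return tibble with columns `conc`, `call` and logical `positive`.
#' @export
classify_detection <- function(conc, lod, lloq) {
  if (length(lod) != 1L || length(lloq) != 1L || !is.finite(lod) ||
      !is.finite(lloq) || lod >= lloq)
    stop_tdm("tdm_invalid_limits", "lod must be a single value below lloq")
  call <- ifelse(conc < lod, "not_detected",
                 ifelse(conc < lloq, "detected_sub_lloq", "quantified"))
  tibble::tibble(conc = as.numeric(conc), call = call, positive = conc >= lod)
}

#' Concordance of adherence calls between two matrices
#'
#' Each "match" is one prescribed drug in one patient assayed in both the
#' test matrix (e.g. saliva) and the reference matrix (e.g. plasma).
#' Sensitivity is `100 * TP / (TP + FN)`, specificity `100 * TN / (TN + FP)`,
#' accuracy `100 * (TP + TN) / n`. A margin with no reference negatives (or
#' no reference positives) leaves the corresponding statistic not applicable
#' (`NA`) rather than inflating it to 100%.
#'
#' @param calls_test logical vector of positivity in the test matrix.
#' @param calls_ref paired logical vector of positivity in the reference
#'   matrix.
#' @return an object of class `tdm_concordance`: counts `tp`, `fp`, `fn`,
#'   `tn`, `n_matches`, and `sensitivity`, `specificity`, `accuracy` in
#'   percent.
#' @export
concordance <- function(calls_test, calls_ref) {
  if (length(calls_test) != length(calls_ref))
    stop_tdm("tdm_unmatched_design", "test and reference calls must be paired")
  keep <- !is.na(calls_test) & !is.na(calls_ref)
  calls_test <- calls_test[keep]; calls_ref <- calls_ref[keep]
  if (!length(calls_test))
    stop_tdm("tdm_no_matches", "no matched (patient, drug) pairs to compare")
  tp <- sum(calls_test & calls_ref)
  fp <- sum(calls_test & !calls_ref)
  fn <- sum(!calls_test & calls_ref)
  tn <- sum(!calls_test & !calls_ref)
  n <- tp + fp + fn + tn
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn, n_matches = n,
         sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
         accuracy = 100 * (tp + tn) / n),
    class = "tdm_concordance"
  )
}

#' @export
print.tdm_concordance <- function(x, ...) {
  cat(sprintf("<tdm_concordance> n = %d (TP %d, FP %d, FN %d, TN %d)\n",
              x$n_matches, x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "n.a." else sprintf("%.1f%%", v)
  cat(sprintf("  sensitivity %s, specificity %s, accuracy %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy)))
  invisible(x)
}

#' Agreement of adherence calls across three matrices
#'
#' For each match (one prescribed drug in one patient with calls in saliva,
#' plasma and urine), counts how many matrices agree with the majority call.
#' Full confirmation means all three agree; partial confirmation means at
#' least two of three.
#'
#' @param calls data frame with columns `patient`, `drug`, and logical
#'   `saliva`, `plasma`, `urine` positivity calls.
#' @return list with `n_matches`, `full` (3/3 agreement), `partial` (>= 2/3)
#'   and the per-match table.
#' @export
three_matrix_summary <- function(calls) {
  need <- c("patient", "drug", "saliva", "plasma", "urine")
  if (!all(need %in% names(calls)))
    stop_tdm("tdm_incomplete_match",
             "calls must have columns patient, drug, saliva, plasma, urine")
  m <- as.matrix(calls[, c("saliva", "plasma", "urine")])
  if (any(is.na(m)))
    stop_tdm("tdm_incomplete_match", "every match needs a call in all three matrices")
  pos <- rowSums(m)
  agree <- pmax(pos, 3 - pos)         # matrices agreeing with the majority call
  per_match <- tibble::tibble(patient = calls$patient, drug = calls$drug,
                              majority = pos >= 2, n_agree = agree)
  list(n_matches = nrow(calls),
       full = sum(agree == 3L),
       partial = sum(agree >= 2L),
       per_match = per_match)
}

#' Saliva/plasma ratio statistics per drug
#'
#' Per paired sample, `ratio = saliva / plasma`; reports the median and
#' interquartile range of the ratios and the saliva-plasma correlation on the
#' raw concentrations (Pearson by default). Pairs with zero plasma
#' concentration are excluded with a warning. Correlation needs at least 3
#' pairs, otherwise it is not applicable.
#'
#' @param saliva saliva concentrations (ng/ml).
#' @param plasma paired plasma concentrations (ng/ml).
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @return tibble with `n`, `median_ratio`, `iqr_lo`, `iqr_hi`, `r`,
#'   `p_value`.
#' @export
sp_ratio_stats <- function(saliva, plasma, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(saliva) != length(plasma) || !length(saliva))
    stop_tdm("tdm_unmatched_design", "saliva and plasma must be non-empty and paired")
  drop <- plasma == 0
  if (any(drop)) {
    warn_tdm("tdm_excluded_pair",
             sprintf("%d pair(s) with zero plasma concentration excluded", sum(drop)))
    saliva <- saliva[!drop]; plasma <- plasma[!drop]
  }
  if (!length(saliva))
    stop_tdm("tdm_no_matches", "no quantifiable pairs remain")
  ratio <- saliva / plasma
  q <- stats::quantile(ratio, c(0.25, 0.5, 0.75), names = FALSE)
  if (length(ratio) >= 3L && stats::sd(saliva) > 0 && stats::sd(plasma) > 0) {
    ct <- stats::cor.test(saliva, plasma, method = method, exact = FALSE)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_
  }
  tibble::tibble(n = length(ratio), median_ratio = q[[2L]],
                 iqr_lo = q[[1L]], iqr_hi = q[[3L]], r = r, p_value = p)
}

#' Adherence calls and concordance for a patient cohort table
#'
#' Applies [classify_detection()] per (drug, matrix) with the supplied limit
#' sets and computes saliva-versus-reference concordance plus per-drug
#' saliva/plasma ratio summaries.
#'
#' @param samples data frame with columns `patient`, `drug`, `matrix`
#'   (`saliva`/`plasma`/`urine`), `conc`.
#' @param limits data frame with columns `drug`, `matrix`, `lod`, `lloq`
#'   giving the per-matrix detection limits to classify against.
#' @param reference matrix used as the comparison standard (default
#'   `"plasma"`).
#' @return list with `calls` (wide per-match table), `concordance`
#'   (saliva vs reference), `sp_summary` (per-drug ratio statistics) and
#'   `three_matrix` (when all three matrices are present).
#' @export
cohort_concordance <- function(samples, limits, reference = "plasma") {
  need <- c("patient", "drug", "matrix", "conc")
  if (!all(need %in% names(samples)))
    stop_tdm("tdm_parse_error", "samples must have columns patient, drug, matrix, conc")
  labelled <- dplyr::left_join(samples, limits, by = c("drug", "matrix"))
  if (any(is.na(labelled$lod)))
    stop_tdm("tdm_invalid_limits", "missing detection limits for some (drug, matrix)")
  labelled$positive <- mapply(function(conc, lod, lloq) {
    classify_detection(conc, lod, lloq)$positive
  }, labelled$conc, labelled$lod, labelled$lloq)
  wide <- tidyr::pivot_wider(
    labelled[, c("patient", "drug", "matrix", "positive")],
    names_from = "matrix", values_from = "positive")
  if (!("saliva" %in% names(wide)) || !(reference %in% names(wide)))
    stop_tdm("tdm_no_matches",
             sprintf("cohort lacks saliva or reference (%s) samples", reference))
  paired <- wide[!is.na(wide$saliva) & !is.na(wide[[reference]]), ]
  conc_res <- concordance(paired$saliva, paired[[reference]])
  conc_tab <- tidyr::pivot_wider(
    labelled[, c("patient", "drug", "matrix", "conc")],
    names_from = "matrix", values_from = "conc")
  sp <- NULL
  if (all(c("saliva", "plasma") %in% names(conc_tab))) {
    both <- conc_tab[!is.na(conc_tab$saliva) & !is.na(conc_tab$plasma) &
                       conc_tab$plasma > 0, ]
    if (nrow(both)) {
      sp <- dplyr::bind_rows(lapply(split(both, both$drug), function(sub) {
        out <- sp_ratio_stats(sub$saliva, sub$plasma)
        out$drug <- sub$drug[[1L]]
        out[, c("drug", setdiff(names(out), "drug"))]
      }))
    }
  }
  three <- NULL
  if (all(c("saliva", "plasma", "urine") %in% names(wide))) {
    complete <- wide[stats::complete.cases(wide[, c("saliva", "plasma", "urine")]), ]
    if (nrow(complete)) three <- three_matrix_summary(complete)
  }
  list(calls = wide, concordance = conc_res, sp_summary = sp,
       three_matrix = three)
}
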