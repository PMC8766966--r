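#' Round half away from zero
#'
#' Reported concentrations use commercial rounding (half away from zero), not
#' banker's rounding: the lowest standard of a 3000 ng/ml series is
#' 11.71875 ng/ml and is reported as 11.72.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct an analyte assay specification
#'
#' One drug's assay design: the highest calibration standard (STD9 = the upper
#' limit of quantification), the number of serial 1:1 dilution levels, the
#' quality-control levels expressed as fractions of STD9, the empirically
#' determined limit of detection, and the assigned internal standard.
#'
#' The LOD is an empirical datum, not derived from the LLOQ: dilution of the
#' lowest standard stops at a signal-to-noise ratio of 3, which lands on a
#' different dyadic step for each analyte.
#'
#' @param name short analyte code, e.g. `"VAL"`.
#' @param std9 concentration of the highest standard (ng/ml); also the ULOQ.
#' @param lod empirical limit of detection (ng/ml); must be below the LLOQ.
#' @param is_name internal standard code.
#' @param n_std_levels number of calibration levels (default 9).
#' @param qc_fractions three strictly decreasing fractions of STD9 giving the
#'   high, medium and low QC concentrations (default 0.8, 0.1, 0.01).
#' @param polarity ionization mode, `"positive"` or `"negative"`; metadata
#'   only, it affects no computation.
#' @return an object of class `analyte_spec`.
#' @export
analyte_spec <- function(name, std9, lod, is_name,
                         n_std_levels = 9L,
                         qc_fractions = c(0.8, 0.1, 0.01),
                         polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_tdm("tdm_invalid_design", "analyte name must be a non-empty string")
  if (!is.numeric(std9) || length(std9) != 1L || !is.finite(std9) || std9 <= 0)
    stop_tdm("tdm_invalid_design", sprintf("std9 must be a positive number (analyte %s)", name))
  if (length(n_std_levels) != 1L || n_std_levels < 2L)
    stop_tdm("tdm_invalid_design", sprintf("n_std_levels must be >= 2 (analyte %s)", name))
  n_std_levels <- as.integer(n_std_levels)
  if (length(qc_fractions) != 3L || any(!is.finite(qc_fractions)) ||
      any(qc_fractions <= 0) || any(qc_fractions > 1) ||
      any(diff(qc_fractions) >= 0))
    stop_tdm("tdm_invalid_design",
             sprintf("qc_fractions must be three strictly decreasing values in (0, 1] (analyte %s)", name))
  lloq <- std9 / 2^(n_std_levels - 1L)
  if (!is.numeric(lod) || length(lod) != 1L || !is.finite(lod) || lod <= 0 || lod >= lloq)
    stop_tdm("tdm_invalid_design",
             sprintf("lod must be positive and below the LLOQ %.6g (analyte %s)", lloq, name))
  structure(
    list(name = name, std9 = std9, n_std_levels = n_std_levels,
         qc_fractions = qc_fractions, lod = lod, lloq = lloq,
         is_name = is_name, polarity = polarity),
    class = "analyte_spec"
  )
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat(sprintf("<analyte_spec> %s (%s ESI)\n", x$name, x$polarity))
  cat(sprintf("  range [LLOQ, ULOQ]: [%.4g, %.4g] ng/ml over %d levels; LOD %.4g ng/ml\n",
              x$lloq, x$std9, x$n_std_levels, x$lod))
  cat(sprintf("  QC (H, M, L): %s ng/ml; IS: %s\n",
              paste(signif(x$std9 * x$qc_fractions, 4), collapse = ", "), x$is_name))
  invisible(x)
}

#' Calibration level concentrations by serial 1:1 dilution
#'
#' Intermediate standards are produced by serial halving of the highest
#' standard down to the lowest (the LLOQ): level `k`, counted from the lowest,
#' is `std9 / 2^(n_levels - k)`. Computation keeps full precision; apply
#' [round_half_up()] only when reporting.
#'
#' @param std9 highest-standard concentration (ng/ml).
#' @param n_levels number of levels (>= 1).
#' @return increasing numeric vector of length `n_levels` (lowest first).
#' @examples
#' build_calibration_levels(3000, 9)[1]   # 11.71875, reported as 11.72
#' @export
build_calibration_levels <- function(std9, n_levels = 9L) {
  if (!is.numeric(std9) || length(std9) != 1L || !is.finite(std9) || std9 <= 0)
    stop_tdm("tdm_invalid_design", "std9 must be a positive number")
  if (length(n_levels) != 1L || !is.finite(n_levels) || n_levels < 1)
    stop_tdm("tdm_invalid_design", "n_levels must be >= 1")
  n_levels <- as.integer(n_levels)
  std9 / 2^(n_levels - seq_len(n_levels))
}

#' Quality-control concentrations as fractions of the highest standard
#'
#' @param std9 highest-standard concentration (ng/ml).
#' @param qc_fractions three strictly decreasing fractions in (0, 1] for the
#'   high, medium and low QC.
#' @return named numeric vector `c(H = , M = , L = )` (ng/ml).
#' @examples
#' build_qc_levels(100)  # H 80, M 10, L 1
#' @export
build_qc_levels <- function(std9, qc_fractions = c(0.8, 0.1, 0.01)) {
  if (!is.numeric(std9) || length(std9) != 1L || !is.finite(std9) || std9 <= 0)
    stop_tdm("tdm_invalid_design", "std9 must be a positive number")
  if (length(qc_fractions) != 3L || any(!is.finite(qc_fractions)) ||
      any(qc_fractions <= 0) || any(qc_fractions > 1) ||
      any(diff(qc_fractions) >= 0))
    stop_tdm("tdm_invalid_design",
             "qc_fractions must be three strictly decreasing values in (0, 1]")
  stats::setNames(std9 * qc_fractions, c("H", "M", "L"))
}

#' Construct an assay design
#'
#' Container for the per-analyte specifications plus internal-standard
#' metadata and the reporting precision.
#'
#' @param analytes list of [analyte_spec()] objects.
#' @param internal_standards named numeric vector of IS working concentrations
#'   (ng/ml); names are IS codes. Metadata only.
#' @param rounding decimal places used when reporting concentrations.
#' @return an object of class `assay_design`.
#' @export
assay_design <- function(analytes, internal_standards, rounding = 2L) {
  if (!length(analytes) || !all(vapply(analytes, inherits, logical(1), "analyte_spec")))
    stop_tdm("tdm_invalid_design", "analytes must be a non-empty list of analyte_spec objects")
  codes <- vapply(analytes, `[[`, character(1), "name")
  if (anyDuplicated(codes))
    stop_tdm("tdm_invalid_design", "analyte codes must be unique")
  names(analytes) <- codes
  is_used <- unique(vapply(analytes, `[[`, character(1), "is_name"))
  missing_is <- setdiff(is_used, names(internal_standards))
  if (length(missing_is))
    stop_tdm("tdm_invalid_design",
             sprintf("internal standard(s) not declared: %s", paste(missing_is, collapse = ", ")))
  structure(
    list(analytes = analytes, internal_standards = internal_standards,
         rounding = as.integer(rounding)),
    class = "assay_design"
  )
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("<assay_design> %d analytes, %d internal standards, %d-dp reporting\n",
              length(x$analytes), length(x$internal_standards), x$rounding))
  print(design_table(x))
  invisible(x)
}

#' Tabulate an assay design
#'
#' One row per analyte with the reported (rounded) design concentrations:
#' STD9/ULOQ, QC H/M/L, STD1/LLOQ and the empirical LOD.
#'
#' @param design an [assay_design()].
#' @return a tibble with one row per analyte.
#' @export
design_table <- function(design) {
  stopifnot(inherits(design, "assay_design"))
  dp <- design$rounding
  rows <- lapply(design$analytes, function(a) {
    qc <- build_qc_levels(a$std9, a$qc_fractions)
    tibble::tibble(
      analyte = a$name,
      std9 = round_half_up(a$std9, dp),
      qc_h = round_half_up(qc[["H"]], dp),
      qc_m = round_half_up(qc[["M"]], dp),
      qc_l = round_half_up(qc[["L"]], dp),
      std1 = round_half_up(a$lloq, dp),
      lod = round_half_up(a$lod, dp),
      is_name = a$is_name,
      polarity = a$polarity
    )
  })
  dplyr::bind_rows(rows)
}

#' Read an assay design from JSON
#'
#' Expected shape:
#' \preformatted{
#' {"rounding_dp": 2,
#'  "internal_standards": {"QX": 500, "ATE-d7": 250},
#'  "analytes": [{"name": "VAL", "std9_ng_ml": 3000, "lod_ng_ml": 0.73,
#'                "qc_fractions": [0.8, 0.1, 0.01], "is_name": "QX",
#'                "polarity": "positive"}]}
#' }
#'
#' @param path path to a JSON design file.
#' @return an [assay_design()].
#' @export
read_assay_design <- function(path) {
  if (!file.exists(path))
    stop_tdm("tdm_parse_error", sprintf("design file not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$analytes))
    stop_tdm("tdm_parse_error", "design JSON must contain an 'analytes' array")
  an <- cfg$analytes
  analytes <- lapply(seq_len(nrow(an)), function(i) {
    row <- an[i, ]
    qcf <- row$qc_fractions
    if (is.list(qcf)) qcf <- unlist(qcf)
    analyte_spec(
      name = row$name,
      std9 = row$std9_ng_ml,
      lod = row$lod_ng_ml,
      is_name = row$is_name,
      n_std_levels = if (!is.null(an$n_std_levels)) row$n_std_levels else 9L,
      qc_fractions = if (is.null(qcf) || all(is.na(qcf))) c(0.8, 0.1, 0.01) else qcf,
      polarity = row$polarity
    )
  })
  is_tab <- unlist(cfg$internal_standards)
  assay_design(analytes, is_tab,
               rounding = if (is.null(cfg$rounding_dp)) 2L else cfg$rounding_dp)
}

#' The bundled 16-analyte antihypertensive panel design
#'
#' Loads the assay design shipped with the package: 14 antihypertensive drugs
#' plus two active metabolites (ramiprilat, sacubitrilat), each with a 9-level
#' calibration series by serial 1:1 dilution, QC at 0.8/0.1/0.01 of the top
#' standard, and the empirically determined LOD.
#'
#' @return an [assay_design()].
#' @export
default_assay_design <- function() {
  read_assay_design(system.file("extdata", "assay_design_panel.json",
                                package = "salivatdm", mustWork = TRUE))
}
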