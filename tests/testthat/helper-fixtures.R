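# shared fixtures and independent oracles

is_table <- c("QX" = 500, "ATE-d7" = 250, "NFD-13C8" = 25, "AML-d4" = 25,
              "TEL-13C-d3" = 25)

# two-analyte design spanning the panel's concentration extremes
tiny_design <- function() {
  assay_design(
    list(analyte_spec("VAL", std9 = 3000, lod = 0.73, is_name = "QX"),
         analyte_spec("CLN", std9 = 10, lod = 0.02, is_name = "QX")),
    internal_standards = is_table
  )
}

one_analyte_design <- function() {
  assay_design(list(analyte_spec("VAL", std9 = 3000, lod = 0.73, is_name = "QX")),
               internal_standards = is_table)
}

# all stochastic components off; deterministic signal transformations stay on
noiseless_config <- function(design, seed = 1L, ee = 1, me_mean = 0, ...) {
  generator_config(design, seed = seed,
                   intra_day_cv = 0, inter_day_cv = 0, injection_cv = 0,
                   me_mean = me_mean, me_lot_sd = 0, ee = ee,
                   plasma_sd = 0, sp_sd = 0, urine_sd = 0,
                   blank_noise_scale = 1e-9, ...)
}

# independent oracle for the through-origin weighted quadratic fit
oracle_wls_fit <- function(nominal, response, w) {
  fit <- stats::lm(response ~ 0 + nominal + I(nominal^2), weights = w)
  unname(stats::coef(fit))
}

calib_weights_for_test <- function(nominal, w) {
  switch(w, "1/x" = 1 / nominal, "1/x2" = 1 / nominal^2,
         "none" = rep(1, length(nominal)))
}

# independent root finder for curve inversion
oracle_invert <- function(a, b, y, upper) {
  stats::uniroot(function(cc) a * cc + b * cc^2 - y, c(0, upper),
                 tol = 1e-12)$root
}

# per-(drug, matrix) detection limits sitting strictly below every positive
# simulated concentration (the regime of the noiseless concordance invariant)
limits_below_truth <- function(samples) {
  pos <- samples[samples$conc > 0, ]
  lim <- stats::aggregate(conc ~ drug + matrix, data = pos, FUN = min)
  grid <- expand.grid(drug = unique(samples$drug),
                      matrix = unique(samples$matrix),
                      stringsAsFactors = FALSE)
  grid$conc <- lim$conc[match(paste(grid$drug, grid$matrix),
                              paste(lim$drug, lim$matrix))]
  grid$conc[is.na(grid$conc)] <- min(pos$conc)   # drug never taken in cohort
  tibble::tibble(drug = grid$drug, matrix = grid$matrix,
                 lod = grid$conc / 2, lloq = grid$conc)
}
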