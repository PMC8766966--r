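# Run code under a temporary RNG state so simulation seeds do not disturb the
# caller's random stream.
with_seed_ <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configure the synthetic instrument-signal generator
#'
#' The generator emulates heteroscedastic LC-MS/MS peak-area response:
#' multiplicative lognormal session and replicate noise (proportional RSDs
#' are what a 256-fold dyadic concentration range shows in practice),
#' lot-specific matrix effects, extraction losses, collection-device
#' retention for saliva patient samples, and a blank baseline noise floor
#' anchored at each analyte's empirical LOD (so that S/N = 3 there).
#'
#' Per-analyte defaults come from the bundled reference tables: device
#' retention encodes the reported saliva-loss column, saliva/plasma ratio
#' medians and drug-typical plasma levels encode the reported cohort
#' medians; drugs without a reported plasma median default to the geometric
#' mid-range of their calibration interval, with a neutral S/P ratio of 1.
#'
#' @param design an [assay_design()].
#' @param seed integer seed; identical config implies identical datasets.
#' @param intra_day_cv,inter_day_cv replicate- and session-level
#'   coefficients of variation (lognormal sigma), defaults 0.05.
#' @param n_sessions,n_intra_replicates,n_lots validation layout: 6 sessions,
#'   5 intra-day replicates, 6 blank-matrix lots by default.
#' @param n_blank_replicates blank injections per lot (default 5).
#' @param n_dilution_steps length of the sub-LLOQ serial dilution used for
#'   limit determination (default 6: LLOQ down to LLOQ/32).
#' @param ee true extraction efficiency (fraction, default 0.9).
#' @param me_mean true mean matrix effect (signed fraction, default -0.05,
#'   i.e. 5% ion suppression).
#' @param me_lot_sd between-lot standard deviation of the matrix effect
#'   (default 0.03).
#' @param is_me_share fraction of the lot matrix effect shared by the
#'   internal standard (default 1: a co-eluting labelled IS is co-suppressed,
#'   so the IS-normalized matrix effect is centred on zero).
#' @param injection_cv CV of the per-injection instrumental factor (volume,
#'   source drift) shared by analyte and IS (default 0.03). It inflates raw
#'   areas but cancels in the analyte/IS ratio — the reason the ratio, not
#'   the raw area, is the default quantification response.
#' @param blank_noise_scale multiplier on the per-analyte LOD-anchored blank
#'   noise floor (default 1).
#' @param height_scale peak height per unit area (default 0.1).
#' @param is_area nominal IS peak area (default 1e5).
#' @param response_uloq nominal analyte peak area at the top standard
#'   (default 1e6); sets the slope `a = response_uloq / std9` per analyte.
#' @param curvature fractional deviation from linearity at the ULOQ (default
#'   -0.1, mild detector saturation); the quadratic coefficient is
#'   `b = curvature * a / uloq`.
#' @param plasma_sd,sp_sd,urine_sd lognormal sigmas of inter-patient plasma
#'   level, saliva/plasma partition and urine scaling (defaults 0.6, 0.5,
#'   0.8).
#' @param urine_scale global urine-to-plasma concentration factor (default
#'   25).
#' @param analyte_overrides optional data frame keyed by `analyte` whose
#'   remaining columns replace per-analyte parameters (`a`, `b`, `ee`,
#'   `me_mean`, `me_lot_sd`, `retention`, `sp_ratio`, `plasma_typical`).
#' @return an object of class `tdm_generator_config` with a per-analyte
#'   parameter table (`$analytes`) and the global settings.
#' @export
generator_config <- function(design, seed = 1L,
                             intra_day_cv = 0.05, inter_day_cv = 0.05,
                             n_sessions = 6L, n_intra_replicates = 5L,
                             n_lots = 6L, n_blank_replicates = 5L,
                             n_dilution_steps = 6L,
                             ee = 0.9, me_mean = -0.05, me_lot_sd = 0.03,
                             is_me_share = 1, injection_cv = 0.03,
                             blank_noise_scale = 1,
                             height_scale = 0.1, is_area = 1e5,
                             response_uloq = 1e6, curvature = -0.1,
                             plasma_sd = 0.6, sp_sd = 0.5, urine_sd = 0.8,
                             urine_scale = 25,
                             analyte_overrides = NULL) {
  stopifnot(inherits(design, "assay_design"))
  if (intra_day_cv < 0 || inter_day_cv < 0)
    stop_tdm("tdm_invalid_design", "CVs must be non-negative")
  if (ee < 0 || ee > 2)
    stop_tdm("tdm_invalid_design", "extraction efficiency must lie in [0, 2]")
  ret <- utils::read.csv(system.file("extdata", "reference_device_retention.csv",
                                     package = "salivatdm", mustWork = TRUE))
  coh <- utils::read.csv(system.file("extdata", "reference_cohort_summary.csv",
                                     package = "salivatdm", mustWork = TRUE))
  tab <- dplyr::bind_rows(lapply(design$analytes, function(spec) {
    a <- response_uloq / spec$std9
    saliva_loss <- ret$saliva_loss_pct[match(spec$name, ret$analyte)]
    retention <- if (is.na(saliva_loss)) 1 else max(1 + saliva_loss / 100, 0.01)
    i <- match(spec$name, coh$drug)
    tibble::tibble(
      analyte = spec$name, std9 = spec$std9, lloq = spec$lloq, lod = spec$lod,
      a = a, b = curvature * a / spec$std9,
      ee = ee, me_mean = me_mean, me_lot_sd = me_lot_sd,
      retention = retention,
      sp_ratio = if (is.na(i)) 1 else coh$sp_ratio_median[[i]],
      plasma_typical = if (is.na(i) || is.na(coh$plasma_median[[i]]))
        sqrt(spec$lloq * spec$std9) else coh$plasma_median[[i]],
      blank_noise_sd = blank_noise_scale * a * spec$lod * height_scale / 3
    )
  }))
  if (!is.null(analyte_overrides)) {
    ov <- as.data.frame(analyte_overrides)
    for (col in setdiff(names(ov), "analyte")) {
      i <- match(ov$analyte, tab$analyte)
      tab[[col]][i[!is.na(i)]] <- ov[[col]][!is.na(i)]
    }
  }
  structure(
    list(design = design, analytes = tab, seed = as.integer(seed),
         intra_day_cv = intra_day_cv, inter_day_cv = inter_day_cv,
         n_sessions = as.integer(n_sessions),
         n_intra_replicates = as.integer(n_intra_replicates),
         n_lots = as.integer(n_lots),
         n_blank_replicates = as.integer(n_blank_replicates),
         n_dilution_steps = as.integer(n_dilution_steps),
         is_me_share = is_me_share, injection_cv = injection_cv,
         height_scale = height_scale,
         is_area = is_area, plasma_sd = plasma_sd, sp_sd = sp_sd,
         urine_sd = urine_sd, urine_scale = urine_scale),
    class = "tdm_generator_config"
  )
}

#' @export
print.tdm_generator_config <- function(x, ...) {
  cat(sprintf("<tdm_generator_config> %d analytes; %d sessions x %d replicates, %d lots; seed %d\n",
              nrow(x$analytes), x$n_sessions, x$n_intra_replicates, x$n_lots, x$seed))
  cat(sprintf("  intra-CV %.3g, inter-CV %.3g; EE %.3g, ME %.3g +/- %.3g (lot sd)\n",
              x$intra_day_cv, x$inter_day_cv, x$analytes$ee[[1L]],
              x$analytes$me_mean[[1L]], x$analytes$me_lot_sd[[1L]]))
  invisible(x)
}

# role -> deterministic signal transformation; standards and dilution-series
# samples are matrix calibrators, spiked before extraction like pre-spiked QCs
role_factor <- function(role, ee, me_lot) {
  switch(role,
         neat = 1,
         qc_post_spiked = 1 + me_lot,
         qc_pre_spiked = ,
         standard = ,
         dilution = ,
         patient = ee * (1 + me_lot),
         stop_tdm("tdm_invalid_points", sprintf("role '%s' has no signal model", role)))
}

#' Simulate one injection's measurement record
#'
#' Deterministic core: base response `a*c + b*c^2`, multiplied by the role
#' transformation (neat: none; post-spiked: lot matrix effect; pre-spiked,
#' standards and dilution samples: extraction efficiency times lot matrix
#' effect), by `exp(session effect) * exp(replicate effect)` with the
#' configured inter- and intra-day CVs, and by a per-injection instrumental
#' factor shared with the internal standard. Blanks draw a folded-normal
#' baseline at the analyte's noise floor. Heights are proportional to areas.
#' Session effects and lot matrix effects are drawn once per batch by
#' [simulate_validation_batch()] and passed in; when omitted they are drawn
#' fresh from the configured distributions.
#'
#' @param conc nominal concentration (ng/ml), >= 0.
#' @param role one of the measurement roles (see [measurement_columns()]).
#' @param analyte analyte code (must exist in the config).
#' @param cfg a [generator_config()].
#' @param session,lot,replicate design labels stored on the record.
#' @param session_effect,me_lot,rep_effect,injection_effect optional
#'   pre-drawn effects (log-scale session, replicate and shared injection
#'   effects; signed lot matrix-effect fraction).
#' @return a one-row tibble in the [measurement_columns()] layout.
#' @export
simulate_response <- function(conc, role, analyte, cfg,
                              session = 1L, lot = 1L, replicate = 1L,
                              session_effect = NULL, me_lot = NULL,
                              rep_effect = NULL, injection_effect = NULL) {
  stopifnot(inherits(cfg, "tdm_generator_config"))
  pars <- cfg$analytes[cfg$analytes$analyte == analyte, ]
  if (!nrow(pars))
    stop_tdm("tdm_invalid_design", sprintf("analyte %s not in generator config", analyte))
  if (is.null(session_effect)) session_effect <- stats::rnorm(1, 0, cfg$inter_day_cv)
  if (is.null(me_lot)) me_lot <- stats::rnorm(1, pars$me_mean, pars$me_lot_sd)
  if (is.null(rep_effect)) rep_effect <- stats::rnorm(1, 0, cfg$intra_day_cv)
  if (is.null(injection_effect)) injection_effect <- stats::rnorm(1, 0, cfg$injection_cv)
  noise <- exp(session_effect) * exp(rep_effect) * exp(injection_effect)
  if (role == "blank") {
    # unspiked donor saliva: neither analyte nor IS, only baseline noise
    height <- abs(stats::rnorm(1, 0, pars$blank_noise_sd))
    area <- height / cfg$height_scale
    area_is <- abs(stats::rnorm(1, 0, pars$blank_noise_sd)) / cfg$height_scale
    nominal <- NA_real_
  } else {
    base <- pars$a * conc + pars$b * conc^2
    area <- base * role_factor(role, pars$ee, me_lot) * noise
    is_me <- if (role %in% c("neat")) 0 else me_lot * cfg$is_me_share
    area_is <- cfg$is_area * (1 + is_me) * exp(injection_effect)
    height <- area * cfg$height_scale
    nominal <- conc
  }
  tibble::tibble(analyte = analyte, role = role,
                 qc_level = "none", session = as.integer(session),
                 replicate = as.integer(replicate), matrix_lot = as.integer(lot),
                 nominal = nominal, area_analyte = area, area_is = area_is,
                 height_analyte = height)
}

# Vectorized record builder sharing simulate_response's signal model; one
# call per (analyte, role block) keeps batch generation fast.
simulate_records_ <- function(conc, role, qc_level, session, lot, replicate,
                              pars, cfg, session_effects, me_lots) {
  n <- length(conc)
  se <- session_effects[session]
  me <- me_lots[lot]
  rep_eff <- stats::rnorm(n, 0, cfg$intra_day_cv)
  inj_eff <- stats::rnorm(n, 0, cfg$injection_cv)
  base <- pars$a * conc + pars$b * conc^2
  factor <- vapply(seq_len(n), function(i) {
    if (role[[i]] == "blank") 0 else role_factor(role[[i]], pars$ee, me[[i]])
  }, numeric(1))
  area <- base * factor * exp(se) * exp(rep_eff) * exp(inj_eff)
  is_me <- ifelse(role == "neat", 0, me * cfg$is_me_share)
  area_is <- cfg$is_area * (1 + is_me) * exp(inj_eff)
  height <- area * cfg$height_scale
  nominal <- conc
  blank <- role == "blank"
  if (any(blank)) {
    bh <- abs(stats::rnorm(sum(blank), 0, pars$blank_noise_sd))
    height[blank] <- bh
    area[blank] <- bh / cfg$height_scale
    area_is[blank] <- abs(stats::rnorm(sum(blank), 0, pars$blank_noise_sd)) /
      cfg$height_scale
    nominal[blank] <- NA_real_
  }
  tibble::tibble(analyte = pars$analyte, role = role, qc_level = qc_level,
                 session = as.integer(session), replicate = as.integer(replicate),
                 matrix_lot = as.integer(lot), nominal = nominal,
                 area_analyte = area, area_is = area_is,
                 height_analyte = height)
}

#' Simulate a complete multi-session validation batch
#'
#' Emits, per analyte: calibration standards at every level for every
#' session; pre-spiked, post-spiked and neat QC samples at H/M/L; blank
#' injections for every matrix lot; and a descending sub-LLOQ dilution
#' series. Standards and the dilution series are matrix calibrators (lot 1);
#' pre-spiked QC replicates cycle through the lots; post-spiked QCs cover
#' every lot in every session. The record count follows the closed-form
#' layout formula `S*(n_std + 3*R) + 3*L*S + 3*S*R + L*B + D*R` per analyte.
#'
#' @param design an [assay_design()].
#' @param cfg a [generator_config()]; its seed fixes the dataset.
#' @return a tibble in the [measurement_columns()] layout.
#' @export
simulate_validation_batch <- function(design, cfg) {
  stopifnot(inherits(design, "assay_design"), inherits(cfg, "tdm_generator_config"))
  S <- cfg$n_sessions; R <- cfg$n_intra_replicates; L <- cfg$n_lots
  with_seed_(cfg$seed, {
    out <- lapply(design$analytes, function(spec) {
      pars <- cfg$analytes[cfg$analytes$analyte == spec$name, ]
      session_effects <- stats::rnorm(S, 0, cfg$inter_day_cv)
      me_lots <- stats::rnorm(L, pars$me_mean, pars$me_lot_sd)
      levels <- build_calibration_levels(spec$std9, spec$n_std_levels)
      qc <- build_qc_levels(spec$std9, spec$qc_fractions)

      std <- expand.grid(k = seq_along(levels), s = seq_len(S))
      qcg <- expand.grid(r = seq_len(R), lvl = c("H", "M", "L"), s = seq_len(S),
                         stringsAsFactors = FALSE)
      post <- expand.grid(l = seq_len(L), lvl = c("H", "M", "L"), s = seq_len(S),
                          stringsAsFactors = FALSE)
      blk <- expand.grid(r = seq_len(cfg$n_blank_replicates), l = seq_len(L))
      dil <- expand.grid(r = seq_len(R), d = seq_len(cfg$n_dilution_steps))

      blocks <- list(
        simulate_records_(levels[std$k], rep("standard", nrow(std)),
                          rep("none", nrow(std)), std$s, rep(1L, nrow(std)),
                          std$k, pars, cfg, session_effects, me_lots),
        simulate_records_(unname(qc[qcg$lvl]), rep("qc_pre_spiked", nrow(qcg)),
                          qcg$lvl, qcg$s, ((qcg$r - 1L) %% L) + 1L, qcg$r,
                          pars, cfg, session_effects, me_lots),
        simulate_records_(unname(qc[qcg$lvl]), rep("neat", nrow(qcg)),
                          qcg$lvl, qcg$s, rep(1L, nrow(qcg)), qcg$r,
                          pars, cfg, session_effects, me_lots),
        simulate_records_(unname(qc[post$lvl]), rep("qc_post_spiked", nrow(post)),
                          post$lvl, post$s, post$l, post$s,
                          pars, cfg, session_effects, me_lots),
        simulate_records_(rep(0, nrow(blk)), rep("blank", nrow(blk)),
                          rep("none", nrow(blk)), rep(1L, nrow(blk)), blk$l,
                          blk$r, pars, cfg, session_effects, me_lots),
        simulate_records_(spec$lloq / 2^(dil$d - 1L), rep("dilution", nrow(dil)),
                          rep("none", nrow(dil)), rep(1L, nrow(dil)),
                          rep(1L, nrow(dil)), dil$r,
                          pars, cfg, session_effects, me_lots)
      )
      dplyr::bind_rows(blocks)
    })
    dplyr::bind_rows(out)
  })
}

#' Expected record count of a validation batch
#'
#' @param cfg a [generator_config()].
#' @param n_std_levels calibration levels per analyte (default 9).
#' @return records per analyte (multiply by the number of analytes for the
#'   batch total).
#' @export
batch_record_count <- function(cfg, n_std_levels = 9L) {
  S <- cfg$n_sessions; R <- cfg$n_intra_replicates; L <- cfg$n_lots
  S * (n_std_levels + 3L * R) + 3L * L * S + 3L * S * R +
    L * cfg$n_blank_replicates + cfg$n_dilution_steps * R
}

#' Simulate a tri-matrix patient cohort with known adherence states
#'
#' Each patient is prescribed 1-3 drugs from the cohort panel. Adherent
#' drug-patient pairs draw a lognormal plasma level around the drug-typical
#' median; saliva is plasma times the saliva/plasma partition ratio, device
#' retention and lognormal inter-patient noise; urine is plasma times a
#' global scale and its own noise. Non-adherent pairs measure zero in every
#' matrix (blank-level signal stays below any positive detection limit).
#' Partially adherent patients take a random proper subset of their drugs.
#'
#' @param n_patients number of patients.
#' @param adherence_mix fractions `c(adherent, partial, non)` summing to 1
#'   (default `c(0.6, 0.2, 0.2)`).
#' @param cfg a [generator_config()]; its seed fixes the cohort.
#' @param drugs panel to prescribe from; defaults to the config analytes
#'   that have cohort reference data and a parent-drug role.
#' @return a tibble with columns `patient`, `drug`, `matrix`, `conc`,
#'   `prescribed`, `adherent` (truth), and an attribute `"truth"` holding the
#'   per-drug generator truth (including the expected measured saliva/plasma
#'   median `sp_measured = sp_ratio * retention`).
#' @export
simulate_cohort <- function(n_patients, adherence_mix = c(0.6, 0.2, 0.2),
                            cfg, drugs = NULL) {
  stopifnot(inherits(cfg, "tdm_generator_config"))
  if (length(adherence_mix) != 3L || abs(sum(adherence_mix) - 1) > 1e-8 ||
      any(adherence_mix < 0))
    stop_tdm("tdm_invalid_design", "adherence_mix must be 3 non-negative fractions summing to 1")
  if (is.null(drugs)) {
    coh <- utils::read.csv(system.file("extdata", "reference_cohort_summary.csv",
                                       package = "salivatdm", mustWork = TRUE))
    drugs <- intersect(cfg$analytes$analyte, setdiff(coh$drug, "RAM-M"))
  }
  with_seed_(cfg$seed, {
    states <- sample(c("adherent", "partial", "non"), n_patients,
                     replace = TRUE, prob = adherence_mix)
    rows <- vector("list", n_patients)
    for (p in seq_len(n_patients)) {
      k <- sample(1:3, 1L, prob = c(0.54, 0.30, 0.16))
      k <- min(k, length(drugs))
      pd <- sample(drugs, k)
      taken <- switch(states[[p]],
                      adherent = rep(TRUE, k),
                      non = rep(FALSE, k),
                      partial = {
                        t <- rep(TRUE, k)
                        t[sample(k, sample(k, 1L))] <- FALSE
                        t
                      })
      sub <- lapply(seq_len(k), function(i) {
        pars <- cfg$analytes[cfg$analytes$analyte == pd[[i]], ]
        if (taken[[i]]) {
          plasma <- pars$plasma_typical * exp(stats::rnorm(1, 0, cfg$plasma_sd))
          saliva <- plasma * pars$sp_ratio * pars$retention *
            exp(stats::rnorm(1, 0, cfg$sp_sd))
          urine <- plasma * cfg$urine_scale * exp(stats::rnorm(1, 0, cfg$urine_sd))
        } else {
          plasma <- 0; saliva <- 0; urine <- 0
        }
        tibble::tibble(patient = p, drug = pd[[i]],
                       matrix = c("saliva", "plasma", "urine"),
                       conc = c(saliva, plasma, urine),
                       prescribed = TRUE, adherent = taken[[i]])
      })
      rows[[p]] <- dplyr::bind_rows(sub)
    }
    out <- dplyr::bind_rows(rows)
    truth <- cfg$analytes[cfg$analytes$analyte %in% drugs,
                          c("analyte", "sp_ratio", "retention", "plasma_typical")]
    truth$sp_measured <- truth$sp_ratio * truth$retention
    attr(out, "truth") <- truth
    out
  })
}
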