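test_that("accuracy and RSD follow their definitions", {
  expect_equal(accuracy(c(10, 10, 10), 10), 100)
  expect_equal(accuracy(c(9, 10, 11), 10), 100)
  expect_equal(accuracy(rep(7.66, 3), 8), 95.75)
  expect_error(accuracy(c(1, 2), 0), class = "tdm_invalid_nominal")
  expect_equal(rsd(c(5, 5, 5)), 0)
  expect_equal(rsd(c(8, 10, 12)), 20)         # sd 2, mean 10
  expect_error(rsd(3), class = "tdm_insufficient_replicates")
  expect_error(rsd(c(-1, 1)), class = "tdm_undefined_rsd")
})

test_that("imprecision separates intra-day replicates from pooled sessions", {
  d <- data.frame(value = c(10, 10, 10, 9, 11), session = c(1, 1, 1, 2, 2))
  expect_equal(imprecision(d, "intra_day"), 0)
  one_each <- data.frame(value = c(9, 10, 11), session = 1:3)
  expect_equal(imprecision(one_each, "inter_day"), 10)
  expect_equal(imprecision(one_each, "inter_day", inter_method = "session_means"), 10)
  expect_error(imprecision(data.frame(value = 1, session = 1), "intra_day"),
               class = "tdm_insufficient_replicates")
  expect_error(imprecision(data.frame(value = c(1, 2), session = c(1, 1)), "inter_day"),
               class = "tdm_insufficient_replicates")
})

test_that("recovery, extraction efficiency and matrix effect follow the area-ratio definitions", {
  pre <- data.frame(area = c(90, 90), session = c(1, 1))
  neat <- data.frame(area = c(100, 100), session = c(1, 1))
  expect_equal(recovery(pre, neat)$mean, 90)
  expect_equal(recovery(neat, neat)$mean, 100)
  post <- data.frame(area = c(100, 100), session = c(1, 1))
  expect_equal(extraction_efficiency(data.frame(area = 80, session = 1), post)$mean, 80)
  expect_equal(matrix_effect(data.frame(area = 120, lot = 1),
                             data.frame(area = 100))$mean, 20)
  expect_equal(matrix_effect(data.frame(area = 80, lot = 1),
                             data.frame(area = 100))$mean, -20)
  expect_equal(matrix_effect(data.frame(area = c(100, 100), lot = c(1, 2)),
                             data.frame(area = 100))$mean, 0)
  expect_error(recovery(pre, data.frame(area = 100, session = 2)),
               class = "tdm_unmatched_design")
})

test_that("REC equals EE times (1 + ME/100) on any common triplet", {
  # hand triplet shaped like a typical high-QC row
  rec <- recovery(data.frame(area = 90, session = 1),
                  data.frame(area = 100, session = 1))$mean
  ee <- extraction_efficiency(data.frame(area = 90, session = 1),
                              data.frame(area = 95.5, session = 1))$mean
  me <- matrix_effect(data.frame(area = 95.5, lot = 1),
                      data.frame(area = 100))$mean
  expect_equal(rec, 90)
  expect_equal(ee, 100 * 90 / 95.5, tolerance = 1e-12)
  expect_equal(me, -4.5)
  expect_equal(rec, ee * (1 + me / 100), tolerance = 1e-12)
  # random triplets
  set.seed(31)
  for (i in 1:25) {
    areas <- runif(3, 10, 200)   # pre, post, neat
    rec <- recovery(data.frame(area = areas[1], session = 1),
                    data.frame(area = areas[3], session = 1))$mean
    ee <- extraction_efficiency(data.frame(area = areas[1], session = 1),
                                data.frame(area = areas[2], session = 1))$mean
    me <- matrix_effect(data.frame(area = areas[2], lot = 1),
                        data.frame(area = areas[3]))$mean
    expect_equal(rec, ee * (1 + me / 100), tolerance = 1e-12)
  }
})

test_that("IS normalization cancels shared suppression and exposes differential effects", {
  neat <- data.frame(area_analyte = 100, area_is = 50)
  co_sup <- data.frame(area_analyte = 100 * 0.7, area_is = 50 * 0.7, lot = 1)
  expect_equal(is_normalized_me(co_sup, neat)$mean, 0, tolerance = 1e-12)
  only_analyte <- data.frame(area_analyte = 120, area_is = 50, lot = 1)
  expect_equal(is_normalized_me(only_analyte, neat)$mean, 20, tolerance = 1e-12)
  only_is <- data.frame(area_analyte = 100, area_is = 50 * 1.25, lot = 1)
  expect_equal(is_normalized_me(only_is, neat)$mean, -20, tolerance = 1e-12)
  expect_error(is_normalized_me(data.frame(area_analyte = 1, area_is = 0, lot = 1), neat),
               class = "tdm_invalid_is")
})

test_that("noiseless generator parameters pass through the metrics unchanged", {
  design <- one_analyte_design()
  cfg <- noiseless_config(design, ee = 0.9, me_mean = -0.1)
  batch <- simulate_validation_batch(design, cfg)
  pre <- batch[batch$role == "qc_pre_spiked" & batch$qc_level == "H", ]
  post <- batch[batch$role == "qc_post_spiked" & batch$qc_level == "H", ]
  neat <- batch[batch$role == "neat" & batch$qc_level == "H", ]
  ee <- extraction_efficiency(data.frame(area = pre$area_analyte, session = pre$session),
                              data.frame(area = post$area_analyte, session = post$session))
  expect_equal(ee$mean, 90, tolerance = 1e-9)
  me <- matrix_effect(data.frame(area = post$area_analyte, lot = post$matrix_lot),
                      data.frame(area = neat$area_analyte))
  expect_equal(me$mean, -10, tolerance = 1e-9)
  rec <- recovery(data.frame(area = pre$area_analyte, session = pre$session),
                  data.frame(area = neat$area_analyte, session = neat$session))
  expect_equal(rec$mean, 90 * 0.9, tolerance = 1e-9)
})

test_that("identity holds exactly on generator triplets within one session and lot", {
  design <- one_analyte_design()
  cfg <- generator_config(design, seed = 5)
  batch <- simulate_validation_batch(design, cfg)
  s1 <- batch[batch$session == 1, ]
  pre <- s1[s1$role == "qc_pre_spiked" & s1$qc_level == "M" & s1$matrix_lot == 1, ]
  post <- s1[s1$role == "qc_post_spiked" & s1$qc_level == "M" & s1$matrix_lot == 1, ]
  neat <- s1[s1$role == "neat" & s1$qc_level == "M", ]
  rec <- recovery(data.frame(area = pre$area_analyte, session = 1),
                  data.frame(area = neat$area_analyte, session = 1))$mean
  ee <- extraction_efficiency(data.frame(area = pre$area_analyte, session = 1),
                              data.frame(area = post$area_analyte, session = 1))$mean
  me <- matrix_effect(data.frame(area = post$area_analyte, lot = 1),
                      data.frame(area = neat$area_analyte))$mean
  expect_equal(rec, ee * (1 + me / 100), tolerance = 1e-10)
})

test_that("pipeline recovers generator EE and ME truth across seeds", {
  design <- one_analyte_design()
  est <- sapply(1:40, function(s) {
    cfg <- generator_config(design, seed = s, intra_day_cv = 0.03,
                            n_intra_replicates = 3L, ee = 0.90, me_mean = -0.10)
    batch <- simulate_validation_batch(design, cfg)
    rep <- validate_batch(batch, design)
    h <- rep[rep$qc_level == "H", ]
    c(ee = h$ee_mean, me = h$me_mean)
  })
  expect_gte(mean(est["ee", ]), 88); expect_lte(mean(est["ee", ]), 92)
  expect_gte(mean(est["me", ]), -13); expect_lte(mean(est["me", ]), -7)
})

test_that("limit determination applies the S/N, bias and RSD rules jointly", {
  # S/N halves per dilution starting at 8; bias and RSD clean everywhere
  series <- data.frame(
    conc = rep(c(4, 2, 1), each = 2),
    measured = rep(c(4, 2, 1), each = 2) * c(1, 1.02),
    height = rep(c(8, 4, 2), each = 2))
  lim <- determine_limits(series, noise = 1)
  expect_equal(lim$lloq, 4)   # S/N 8 > 5 and criteria met
  expect_equal(lim$lod, 2)    # S/N 4 >= 3
  # a level with good S/N but bad RSD is not the LLOQ
  bad_rsd <- data.frame(conc = rep(c(4, 2), each = 3),
                        measured = c(4, 4, 4, 2 * c(0.7, 1.0, 1.3)),
                        height = rep(c(12, 6), each = 3))
  lim2 <- determine_limits(bad_rsd, noise = 1)
  expect_equal(lim2$lloq, 4)
  expect_equal(lim2$lod, 2)
  # nothing distinguishable from blank
  dead <- data.frame(conc = rep(c(4, 2), each = 2),
                     measured = rep(c(4, 2), each = 2),
                     height = rep(c(2.5, 1), each = 2))
  expect_error(determine_limits(dead, noise = 1), class = "tdm_method_insensitive")
})

test_that("raising all signals by a common factor never raises the limits", {
  set.seed(17)
  for (i in 1:100) {
    concs <- 2^(4:0)
    base_h <- 6 * concs / max(concs) * runif(1, 1, 4)
    series <- data.frame(
      conc = rep(concs, each = 3),
      measured = rep(concs, each = 3) * exp(rnorm(15, 0, 0.05)),
      height = rep(base_h, each = 3) * exp(rnorm(15, 0, 0.05)))
    lim <- determine_limits(series, noise = 1)
    k <- runif(1, 1, 10)
    scaled <- series; scaled$height <- scaled$height * k
    lim_k <- determine_limits(scaled, noise = 1)
    expect_lte(lim_k$lloq, lim$lloq)
    expect_lte(lim_k$lod, lim$lod)
    expect_lte(lim$lod, lim$lloq)
  }
})

test_that("selectivity fails a lot at or above the interference thresholds", {
  lloq_rec <- data.frame(area_analyte = rep(100, 4), area_is = rep(1000, 4))
  clean <- data.frame(lot = 1:6, area_analyte = 0, area_is = 0)
  expect_true(all(selectivity_check(clean, lloq_rec)$pass))
  dirty <- data.frame(lot = c(1, 2), area_analyte = c(30, 5), area_is = c(10, 10))
  res <- selectivity_check(dirty, lloq_rec)
  expect_equal(res$pass, c(FALSE, TRUE))
  boundary <- data.frame(lot = 1, area_analyte = 20, area_is = 0)
  expect_false(selectivity_check(boundary, lloq_rec)$pass)  # strict inequality
})

test_that("compliance bounds are strict, 15% at QC levels and 20% at the LLOQ", {
  report <- tibble::tibble(
    analyte = c("A", "B", "C", "D"),
    qc_level = c("H", "L", "H", "LLOQ"),
    accuracy = c(95.9, 51.7, 85.0, 82.0),
    intra_day_rsd = c(0.8, 4.2, 14.9, 19.0),
    inter_day_rsd = c(0.7, 10.0, 14.9, 19.0))
  out <- evaluate_compliance(report)
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out$flags[[2]], "bias")
  # 85.0 fails at a QC level (|bias| = 15 not < 15) but would pass at LLOQ
  out2 <- evaluate_compliance(dplyr::mutate(report[3, ], qc_level = "LLOQ"))
  expect_true(out2$pass)
})

test_that("device retention losses classify into the three severity tiers", {
  sev <- salivette_retention(pre = c(100, 100), post = c(6, 6))
  expect_equal(sev$mean_loss_pct, -94)
  expect_equal(sev$class, "severe")
  expect_equal(salivette_retention(100, 100)$class, "negligible")
  inc <- salivette_retention(100, 124)
  expect_equal(inc$mean_loss_pct, 24)
  expect_equal(inc$class, "increase")
  expect_equal(retention_class(c(-62, -33.5, -10, 33)),
               c("severe", "moderate", "negligible", "increase"))
  expect_equal(retention_class(-20), "moderate")   # boundary belongs to moderate
  expect_equal(retention_class(-50), "severe")
  expect_error(salivette_retention(0, 5), class = "tdm_invalid_pair")
})

test_that("the reported reference retention table classifies as published", {
  tab <- utils::read.csv(system.file("extdata", "reference_device_retention.csv",
                                     package = "salivatdm"))
  cls <- retention_class(tab$saliva_loss_pct)
  severe <- tab$analyte[cls == "severe"]
  expect_setequal(severe, c("AML", "TEL", "DOX", "NBV", "HCTZ"))
  expect_setequal(tab$analyte[cls == "increase"], c("CLN", "IDP"))
  expect_setequal(tab$analyte[retention_class(tab$solvent_loss_pct) == "severe"],
                  c("AML", "TEL", "DOX", "NBV"))
})
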