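ac <- radionuclide("Ac-225")
bi <- radionuclide("Bi-213")

test_that("dose coefficient: dimensional anchor and linearity", {
  expect_equal(dose_coefficient(0, ac, organ = "x")$coefficient, 0)
  # independently worked conversion: 1 %IA.h/g = 0.01 * 3600 Bq.s/g per Bq,
  # x 1000 Bq/kBq, x 1000 g/kg, x 1000 mGy/Gy
  liver <- dose_coefficient(4660, ac, organ = "liver")
  expect_equal(liver$coefficient,
               4660 * 0.01 * 3600 * 1000 * 1000 * 1000 * ac$delta_alpha)
  expect_equal(liver$coefficient, 738, tolerance = 0.01)

  doubled <- structure(list(label = "X", half_life_h = ac$half_life_h,
                            lambda_h = ac$lambda_h,
                            delta_alpha = 2 * ac$delta_alpha),
                       class = "radionuclide")
  expect_equal(dose_coefficient(100, doubled)$coefficient,
               2 * dose_coefficient(100, ac)$coefficient)
  expect_equal(dose_coefficient(200, ac)$coefficient,
               2 * dose_coefficient(100, ac)$coefficient)
  expect_equal(dose_coefficient(100, ac, phi = 0.5)$coefficient,
               0.5 * dose_coefficient(100, ac)$coefficient)
  expect_error(dose_coefficient(100, ac, phi = 0),
               class = "alphadose_validation_error")
})

test_that("dose coefficient accepts TIA objects and carries the organ", {
  r <- tia_fit(exp_model(10, log(2) / 24, "blood"))
  d <- dose_coefficient(r, ac)
  expect_equal(d$organ, "blood")
  expect_equal(d$coefficient,
               r$tia * alphadose:::PCT_TIA_TO_MGY_PER_KBQ * ac$delta_alpha)
})

test_that("kidney stripping recovers known components", {
  # zero free component
  s <- simulate_well_counter(0, 500, 0.3, 0.5, seed = 21)
  d <- decompose_kidney_counts(s)
  expect_lt(d$free_bi_conc, 0.02 * d$supported_conc)

  # seeded 70/30 split
  s <- simulate_well_counter(700, 300, 0.3, 0.5, seed = 22)
  expect_gt(sum(s$counts), 1e4)
  d <- decompose_kidney_counts(s)
  share <- 100 * d$free_bi_conc / (d$free_bi_conc + d$supported_conc)
  expect_lt(abs(share - 70), 5)

  # slow component alone decays < 2% over 4.5 h: amplitude ~ late count rate
  s <- simulate_well_counter(0, 2000, 0.5, 0.5, seed = 23)
  d <- decompose_kidney_counts(s)
  late <- s$counts[s$t_start_min >= 240]
  late_rate_bq <- mean(late) / (0.5 * 60)           # counts/min -> Bq
  expect_equal(unname(d$supported_conc * 0.5), late_rate_bq,
               tolerance = 0.05)
})

test_that("kidney stripping edge cases", {
  z <- list(t_start_min = 0:269, interval_min = 1,
            counts = rep(0L, 270), efficiency = 0.5, mass_g = 0.3)
  d <- decompose_kidney_counts(z)
  expect_equal(d$free_bi_conc, 0)
  expect_equal(d$supported_conc, 0)
  expect_equal(d$flag, "all_zero")

  short <- list(t_start_min = 0:29, interval_min = 1,
                counts = rep(10L, 30), efficiency = 0.5, mass_g = 0.3)
  expect_error(decompose_kidney_counts(short),
               class = "alphadose_numerical_error")
  bad <- list(t_start_min = 0:269, interval_min = 1,
              counts = c(-1L, rep(1L, 269)), efficiency = 0.5, mass_g = 0.3)
  expect_error(decompose_kidney_counts(bad),
               class = "alphadose_validation_error")
})

test_that("kidney dose: free-Bi component adds and conserves", {
  kid_tia <- tia_fit(exp_model(5, log(2) / 30, "kidneys"))
  parent_only <- dose_coefficient(kid_tia, ac)

  zero_free <- tac("kidneys", study_schedule, rep(0, 5))
  total <- kidney_dose_with_free_bi(kid_tia, zero_free)
  expect_equal(total$coefficient, parent_only$coefficient)
  expect_equal(unname(total$components["free_bi"]), 0)

  free <- tac("kidneys", study_schedule,
              3 * exp(-log(2) / 40 * study_schedule))
  total <- kidney_dose_with_free_bi(kid_tia, free)
  expect_equal(sum(total$components), total$coefficient)
  expect_gt(total$components[["free_bi"]], 0)
  expect_equal(total$components[["parent"]], parent_only$coefficient)
})

test_that("end-to-end synthetic truth recovers the free-Bi dose share", {
  # ground truth: free-Bi TIA and kidney TIA chosen for a ~60% free share
  kid_tia <- tia_fit(exp_model(5, log(2) / 30, "kidneys"))
  free_truth <- exp_model(4, log(2) / 35, "kidneys")
  free_curve <- tac("kidneys", study_schedule,
                    predict(free_truth, study_schedule))
  total <- kidney_dose_with_free_bi(kid_tia, free_curve)
  # analytic truth for the free component (closed-form TIA, Bi Delta)
  truth_free <- auc(free_truth) * alphadose:::BQ_TIA_TO_MGY_PER_KBQ *
    bi$delta_alpha
  expect_equal(unname(total$components["free_bi"]), truth_free,
               tolerance = 0.1)
})

test_that("marrow-from-blood rule", {
  m <- marrow_from_blood(80.4)
  expect_equal(m$organ, "red marrow")
  expect_equal(round(m$coefficient), 29)
  expect_equal(marrow_from_blood(0)$coefficient, 0)
  expect_equal(marrow_from_blood(100)$coefficient, 36)
  expect_error(marrow_from_blood(100, factor = 0),
               class = "alphadose_validation_error")
})

test_that("activity prescription under organ limits", {
  coeffs <- c(liver = 738, kidneys = 138, tumor = 141, blood = 80.4)
  p <- prescribe_activity(coeffs, c(liver = 28))
  expect_equal(p$limiting_organ, "liver")
  expect_equal(round(p$activity_kbq), 38)
  expect_equal(p$organ_doses_gy[["tumor"]], 5.3, tolerance = 0.02)

  p2 <- prescribe_activity(coeffs, c(kidneys = 18))
  expect_equal(signif(p2$activity_kbq, 2), 130)

  # the tighter constraint wins
  p3 <- prescribe_activity(coeffs, c(liver = 28, kidneys = 18))
  expect_equal(p3$limiting_organ, "liver")
  expect_error(prescribe_activity(coeffs, numeric()),
               class = "alphadose_validation_error")
  expect_error(prescribe_activity(coeffs, c(spleen = 10)),
               class = "alphadose_validation_error")
})

test_that("prescription safety: no organ exceeds its limit (randomized)", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    cf <- stats::setNames(stats::runif(n, 10, 900), paste0("o", seq_len(n)))
    lim <- stats::setNames(stats::runif(n, 1, 40), names(cf))
    keep <- sample(n, sample(n, 1))
    p <- prescribe_activity(cf, lim[keep])
    doses <- p$organ_doses_gy[names(p$limits_gy)]
    expect_true(all(doses <= p$limits_gy + 1e-9))
    expect_equal(p$organ_doses_gy[[p$limiting_organ]], p$limit_gy)
  }
})

test_that("organ doses are linear in administered activity", {
  coeffs <- c(liver = 738, tumor = 141)
  p1 <- prescribe_activity(coeffs, c(liver = 14))
  p2 <- prescribe_activity(coeffs, c(liver = 28))
  expect_equal(2 * p1$activity_kbq, p2$activity_kbq)
  expect_equal(2 * p1$organ_doses_gy[["tumor"]], p2$organ_doses_gy[["tumor"]])
})
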