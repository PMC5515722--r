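test_that("closed-form TIA of a fitted model", {
  r <- tia_fit(exp_model(10, log(2) / 24, "blood"))
  expect_equal(r$tia, 10 * 24 / log(2), tolerance = 1e-12)
  expect_equal(r$tia, 346.2, tolerance = 1e-3)

  m <- blood_model(blood_params$ac225_3mgkg)
  expect_equal(tia_fit(m)$tia, auc(m))

  set.seed(404)
  for (i in 1:100) {
    m <- random_stable_model()
    expect_equal(tia_fit(m)$tia, quad_tia(m), tolerance = 1e-4)
  }
})

test_that("tail fraction of the fit route shrinks as the window extends", {
  m <- blood_model(blood_params$ac225_3mgkg)
  fr <- vapply(c(24, 72, 144, 400), function(T) {
    tia_fit(m, last_time = T)$tail_fraction
  }, 0)
  expect_true(all(diff(fr) < 0))
  expect_lt(fr[4], 1e-4)
})

test_that("hybrid TIA converges to the closed form under dense sampling", {
  m <- exp_model(10, log(2) / 24, "x")
  tt <- seq(0.1, 5 * 24, by = 0.1)
  h <- tia_hybrid(tac("x", tt, predict(m, tt)))
  expect_equal(h$tia, tia_fit(m)$tia, tolerance = 0.01)
})

test_that("two-point hybrid follows the stated trapezoid-plus-tail rule", {
  h <- tia_hybrid(tac("x", c(72, 144), c(10, 5)))
  lam <- log(2) / 72
  tail <- 5 * 72 / log(2)             # c_k / lambda_tail = 519.4
  measured <- (10 + 5) / 2 * 72
  leading <- 10 * exp(lam * 72) * (1 - exp(-lam * 72)) / lam
  expect_equal(tail, 519.4, tolerance = 1e-4)
  expect_equal(h$tia, leading + measured + tail, tolerance = 1e-12)
  expect_equal(h$tail_fraction, tail / h$tia, tolerance = 1e-12)
})

test_that("flat tails use the physical-decay fallback and are flagged", {
  flat <- tac("liver", c(24, 72, 144), c(8, 9, 9))
  expect_error(tia_hybrid(flat), class = "alphadose_numerical_error")
  nuc <- radionuclide("Ac-225")
  h <- tia_hybrid(flat, lambda_phys = nuc$lambda_h)
  expect_equal(h$flag, "constant_tail")
  # tail is terminated by physical decay alone
  expect_equal(h$tail_fraction * h$tia,
               9 * exp(-nuc$lambda_h * 144) / nuc$lambda_h)
})

test_that("zero terminal concentration gives a zero, flagged tail", {
  h <- tia_hybrid(tac("x", c(1, 6, 24), c(10, 5, 0)))
  expect_equal(h$flag, "zero_tail")
  expect_equal(h$tail_fraction, 0)
  expect_error(tia_hybrid(tac("x", 1, 10)),
               class = "alphadose_validation_error")
})

test_that("radionuclide substitution: identity at lambda 0, closed forms", {
  m <- blood_model(blood_params$ac225_3mgkg)
  expect_equal(tia_fit(m, lambda_phys = 0)$tia, tia_fit(m)$tia)

  # constant biological level under pure physical decay
  at <- radionuclide("At-211")
  r <- tia_fit(exp_model(4, 0, "plateau"), lambda_phys = at$lambda_h)
  expect_equal(r$tia, 4 * 7.2 / log(2), tolerance = 1e-12)

  ac <- radionuclide("Ac-225")
  sub_ac <- substitute_radionuclide(m, ac)
  sub_at <- substitute_radionuclide(m, at)
  expect_lt(sub_at$tia, sub_ac$tia)
  expect_equal(sub_ac$tia, quad_tia(m, ac$lambda_h), tolerance = 1e-4)
  expect_equal(sub_at$tia, quad_tia(m, at$lambda_h), tolerance = 1e-4)
  expect_equal(sub_at$nuclide, "At-211")
})

test_that("TIA is monotonically non-increasing in physical decay", {
  set.seed(505)
  for (i in 1:50) {
    m <- random_stable_model()
    l <- sort(stats::runif(2, 0, 0.5))
    expect_gte(tia_fit(m, lambda_phys = l[1])$tia,
               tia_fit(m, lambda_phys = l[2])$tia)
  }
  # and along the candidate nuclides, on the hybrid route too
  curve <- noise_free_tac(blood_model(blood_params$ac225_3mgkg))
  tias <- vapply(c("Ac-225", "Pb-212", "At-211"), function(lab) {
    substitute_radionuclide(curve, radionuclide(lab))$tia
  }, 0)
  expect_true(all(diff(tias) < 0))  # 240 h > 10.6 h > 7.2 h
})

test_that("fit and hybrid routes agree on dense noise-free curves", {
  set.seed(606)
  for (i in 1:20) {
    m <- random_stable_model()
    t12_slow <- log(2) / min(m$terms$rate_h)
    tt <- seq(0.05, 8 * t12_slow, length.out = 2000)
    h <- tia_hybrid(tac("x", tt, predict(m, tt)))
    expect_equal(h$tia, tia_fit(m)$tia, tolerance = 0.02)
  }
})

test_that("TIA ratio tables", {
  df <- data.frame(organ = c("tumor", "blood", "spleen"),
                   tia_pia_h_g = c(200, 100, 200),
                   nuclide = "Ac-225")
  rt <- tia_ratio_table(df, "tumor", c("blood", "spleen", "tumor"))
  expect_equal(rt$ratio, c(2, 1, 1))
  df$tia_pia_h_g[2] <- 0
  expect_error(tia_ratio_table(df, "tumor", "blood"), "blood",
               class = "alphadose_validation_error")
})

test_that("longest-lived nuclide maximises tumor-to-blood TIA ratio", {
  # slowly accumulating tumor vs clearing blood, known truth
  tumor <- organ_model("tumor", c(12, -11), log(2) / c(300, 10), 0)
  blood <- organ_model("blood", 30 * c(0.63, 0.37), log(2) / c(6, 19), 0)
  ds <- simulate_biodistribution(list(tumor, blood), n_per_time = 1)
  rows <- do.call(rbind, lapply(c("Ac-225", "Pb-212", "At-211"), function(lab) {
    nuc <- radionuclide(lab)
    do.call(rbind, lapply(ds$curves, function(cv) {
      as.data.frame(substitute_radionuclide(cv, nuc))
    }))
  }))
  rt <- tia_ratio_table(rows, "tumor", "blood")
  ord <- rt$ratio[match(c("Ac-225", "Pb-212", "At-211"), rt$nuclide)]
  expect_true(all(diff(ord) < 0))
})
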