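test_that("noiseless data generated by each model is recovered exactly", {
  # model 1
  f1 <- fit_model(record_from_params(motional_params(1, S2 = 0.85), 6.6),
                  6.6, 1, fc800)
  expect_equal(f1$par[1], 0.85, tolerance = 1e-6)
  expect_lt(f1$chi2, 1e-6)
  # model-2 truth: model 1 fails badly, model 2 nails S2 and Rex
  rec2 <- record_from_params(motional_params(2, S2 = 0.85, R_ex = 5), 6.6)
  expect_gt(fit_model(rec2, 6.6, 1, fc800)$chi2, 10)
  f2 <- fit_model(rec2, 6.6, 2, fc800)
  expect_lt(f2$chi2, 1e-6)
  expect_equal(f2$par[1], 0.85, tolerance = 1e-4)
  expect_equal(f2$par[2], 5, tolerance = 1e-3)
  # model 3
  rec3 <- record_from_params(motional_params(3, S2 = 0.8, tau_e = 50e-12),
                             6.6)
  f3 <- fit_model(rec3, 6.6, 3, fc800)
  expect_equal(f3$par[1], 0.8, tolerance = 1e-3)
  expect_equal(f3$par[2], 0.05, tolerance = 1e-2)  # ns
  # model 5 recovers all three parameters within 1 percent
  rec5 <- record_from_params(
    motional_params(5, S2 = 0.6, S2_f = 0.9, tau_i = 2e-9), 6.6)
  f5 <- fit_model(rec5, 6.6, 5, fc800)
  expect_equal(f5$par[1], 0.9, tolerance = 0.01)             # S2f
  expect_equal(f5$par[1] * f5$par[2], 0.6, tolerance = 0.01) # S2
  expect_equal(f5$par[3], 2, tolerance = 0.01)               # tau_i, ns
  expect_error(fit_model(list(residue_id = 9, R1 = 1, R1_err = 0.1,
                              R2 = NA, R2_err = 0.1, NOE = 0.8,
                              NOE_err = 0.02), 6.6, 1, fc800),
               "must all be present")
})

test_that("nested F-test matches the closed-form F(1,1) distribution", {
  eq <- ftest_nested(3, 3, 3, 1, 2)
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  ft <- ftest_nested(10, 1, 3, 1, 2)
  expect_equal(ft$F, 9)
  # F(1,1) CDF is (2/pi) atan(sqrt(x)): independent analytic check
  expect_equal(ft$p, 1 - 2 / pi * atan(3), tolerance = 1e-12)
  # invariance under common chi2 rescaling
  ft2 <- ftest_nested(10 * 7.3, 1 * 7.3, 3, 1, 2)
  expect_equal(ft2$F, ft$F)
  expect_warning(z <- ftest_nested(5, 0, 3, 1, 2), "p = 0")
  expect_equal(z$p, 0)
})

test_that("Monte-Carlo critical chi-square behaves as a quantile and
           approaches the chi-square(2) limit for model 1", {
  rec <- record_from_params(motional_params(1, S2 = 0.85), 6.6,
                            frac_err = 0.01, noe_err = 0.01)
  f <- fit_model(rec, 6.6, 1, fc800)
  sig <- c(rec$R1_err, rec$R2_err, rec$NOE_err)
  c90 <- critical_chi2(sig, 1, f, 6.6, fc800, n_sim = 300,
                       confidence = 0.90, seed = 5)
  c95 <- critical_chi2(sig, 1, f, 6.6, fc800, n_sim = 300,
                       confidence = 0.95, seed = 5)
  expect_lte(c90$chi2_critical, c95$chi2_critical)
  c95b <- critical_chi2(sig, 1, f, 6.6, fc800, n_sim = 300,
                        confidence = 0.95, seed = 5)
  expect_identical(c95$chi2_sim, c95b$chi2_sim)  # same seed, same result
  big <- critical_chi2(sig, 1, f, 6.6, fc800, n_sim = 2000, seed = 11)
  expect_equal(big$chi2_critical, qchisq(0.95, 2), tolerance = 0.1)
})

test_that("model selection keeps model 1 on perfect rigid data", {
  rec <- record_from_params(motional_params(1, S2 = 0.85), 6.6)
  sel <- select_model(rec, 6.6, fc800, n_sim = 150, seed = 3)
  expect_equal(sel$model_id, 1L)
  expect_true(sel$satisfactory)
})

test_that("selected-model chi2 never exceeds the model-1 chi2", {
  for (s in 1:6) {
    truth <- switch(1 + s %% 3,
                    motional_params(1, S2 = 0.85),
                    motional_params(2, S2 = 0.8, R_ex = 6),
                    motional_params(3, S2 = 0.4, tau_e = 0.6e-9))
    rec <- noisy_record(record_from_params(truth, 6.6), seed = 100 + s)
    sel <- select_model(rec, 6.6, fc800, n_sim = 150, seed = s)
    f1 <- fit_model(rec, 6.6, 1, fc800)
    expect_lte(sel$chi2, f1$chi2 + 1e-9)
  }
})

test_that("halving the errors never simplifies the selection on
           noiseless data", {
  complexity <- c(1, 2, 2, 3, 3)  # parameter count per model id
  truths <- list(motional_params(1, S2 = 0.85),
                 motional_params(2, S2 = 0.8, R_ex = 6),
                 motional_params(3, S2 = 0.4, tau_e = 0.6e-9))
  for (truth in truths) {
    rec <- record_from_params(truth, 6.6)
    rec_half <- rec
    rec_half[c("R1_err", "R2_err", "NOE_err")] <-
      rec[c("R1_err", "R2_err", "NOE_err")] / 2
    m_full <- select_model(rec, 6.6, fc800, n_sim = 150, seed = 9)$model_id
    m_half <- select_model(rec_half, 6.6, fc800, n_sim = 150, seed = 9)$model_id
    expect_gte(complexity[m_half], complexity[m_full])
  }
})

test_that("a synthetic domain profile reproduces its generating structure", {
  # termini flexible, loop exchange-broadened, core rigid (one seed;
  # the large-sample selection statistics live in the acceptance suite)
  prof <- synthetic_profile()
  d <- gen_relaxation_dataset(prof, seed = 21)
  sub <- c(1:3, 73:75, 40:44)   # termini, loop, core
  out <- fit_modelfree_table(d$records[sub, ], prof$tau_c, fc800,
                             n_sim = 150, seed = 4)
  expect_true(all(out$S2[out$residue_id <= 3] < 0.5))
  loop <- out[out$residue_id %in% 73:75, ]
  expect_true(all(loop$model %in% c(2L, 4L)))
  expect_true(all(loop$Rex > 0))
  core <- out[out$residue_id %in% 40:44, ]
  expect_true(all(abs(core$S2 - d$truth$S2[40:44]) < 0.1))
  expect_true(all(c("decision_path", "chi2_crit") %in% names(out)))
})
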