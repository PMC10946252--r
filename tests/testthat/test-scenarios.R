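small_spec <- population_spec("caucasian", "patient", n_subjects = 2, seed = 21)

test_that("threshold specification validates its window", {
  th <- threshold_spec()
  expect_equal(th$ctrough_low, 328)
  expect_equal(th$ctrough_high, 677)
  expect_equal(th$min_inhibition, 80)
  expect_error(threshold_spec(ctrough_low = 700), "<")
  expect_error(threshold_spec(min_inhibition = 0), "min_inhibition")
})

test_that("a zero dose fails both thresholds with zero inhibition", {
  er <- evaluate_regimen(small_spec, regimens = list(dosing_regimen(0, 24, 3)))
  expect_equal(er$ctrough_gm, 0)
  expect_equal(er$min_inh_T790M, 0)
  expect_false(er$pk_pass)
  expect_false(er$pd_pass)
})

test_that("trough rises with dose and the standard dose clears the PD threshold", {
  er <- evaluate_regimen(small_spec,
                         regimens = lapply(c(20, 80), dosing_regimen,
                                           interval = 24, n_doses = 14))
  expect_lt(er$ctrough_gm[1], er$ctrough_gm[2])
  ## 80 mg once daily: pulmonary inhibition of both mutants stays above 80%
  expect_gt(er$min_inh_T790M[2], 80)
  expect_gt(er$min_inh_L858R[2], 80)
  expect_true(er$pd_pass[2])
})

test_that("evaluate_regimen is deterministic for a pinned seed", {
  reg <- list(dosing_regimen(80, 24, 5))
  expect_identical(evaluate_regimen(small_spec, regimens = reg),
                   evaluate_regimen(small_spec, regimens = reg))
})

test_that("a unit multiplier sweep reproduces the unswept baseline", {
  base <- evaluate_regimen(small_spec,
                           regimens = list(dosing_regimen(80, 24, 5)))
  sw <- factor_sweep("cyp3a4_clint_multiplier", 1.0, small_spec,
                     regimen = dosing_regimen(80, 24, 5))
  expect_equal(sw$ctrough_gm, base$ctrough_gm, tolerance = 1e-10)
})

test_that("trough decreases monotonically as the free fraction is swept upward", {
  one <- population_spec("caucasian", "patient", n_subjects = 1, seed = 1,
                         cv_map = c(albumin = 0))
  sw <- factor_sweep("fup", c(0.009, 0.019, 0.034), one,
                     regimen = dosing_regimen(80, 24, 7))
  expect_true(all(diff(sw$ctrough_gm) < 0))
  expect_warning(
    factor_sweep("fup", 0.2, one, regimen = dosing_regimen(80, 24, 2)),
    "documented range"
  )
})

test_that("disabling the CYP3A4 auto-effects raises the trough", {
  one <- population_spec("caucasian", "patient", n_subjects = 1, seed = 1,
                         cv_map = c(albumin = 0))
  sw <- factor_sweep("auto_inhibition_induction_on_off", c(TRUE, FALSE), one,
                     regimen = dosing_regimen(80, 24, 7))
  ## auto-induction dominates at these unbound liver concentrations, so
  ## removing the auto-effects lowers clearance and raises the trough
  expect_gt(sw$ctrough_gm[2], sw$ctrough_gm[1])
})

test_that("matched groups give a unit clearance ratio and outputs are structured", {
  g <- population_spec("japanese", "patient", n_subjects = 3, seed = 8)
  cc <- compare_clf(list(a = g, b = g), dosing_regimen(80),
                    phase = "single_dose", sd_duration = 240)
  expect_equal(cc$ratios$fold_ratio, 1.0, tolerance = 1e-10)
  expect_true(all(cc$groups$clf_geometric_mean > 0))
  expect_error(compare_clf(list(population_spec()), dosing_regimen(80)),
               "two groups")
})

test_that("output variability vanishes at zero input CV and grows with it", {
  va <- variability_attribution(list(albumin = c(0, 15, 30)),
                                population_spec("caucasian", "patient"),
                                regimen = dosing_regimen(80, 24, 14),
                                n_subjects = 120, seed = 31)
  expect_equal(va$auc_cv_percent[1], 0)
  expect_true(all(diff(va$auc_cv_percent) > 0))
  expect_true(all(diff(va$ctrough_cv_percent) > 0))
  expect_error(variability_attribution(list(bogus = 10)), "unsupported")
})

test_that("simulated troughs at the clinical 80 mg dose are within 2-fold of observed values", {
  obs <- observed_ctrough()
  obs80 <- obs[obs$dose_mg == 80, ]
  for (anc in unique(obs80$ancestry)) {
    spec <- population_spec(anc, "patient", n_subjects = 10, seed = 17)
    pop <- sample_population(spec)
    troughs <- vapply(pop, function(s) {
      r <- simulate_pbpk(s, osi, od80_14d, points_per_hour = 2)
      compute_pk_metrics(r, ss_window, 80)$ctrough
    }, numeric(1))
    pred <- geometric_stats(troughs)$geometric_mean
    for (o in obs80$observed_ctrough[obs80$ancestry == anc]) {
      expect_gt(pred / o, 0.5)
      expect_lt(pred / o, 2.0)
    }
  }
})
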