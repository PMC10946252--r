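test_that("competitive auto-inhibition scales intrinsic clearance", {
  expect_equal(effective_clint_cyp3a4(0.9, 0, 2.55), 0.9)
  expect_equal(effective_clint_cyp3a4(0.9, 2.55, 2.55), 0.45)
  expect_equal(effective_clint_cyp3a4(0.73, 1.0, 2.55), 0.5243,
               tolerance = 1e-3)
})

test_that("enzyme turnover has the analytic steady states", {
  ## baseline is a steady state without drug
  expect_equal(cyp3a4_turnover_rhs(1, 0, 10.8, 0.12, 0.0158), 0)
  ## steady-state level solves rhs = 0: level* = 1 + Emax*Cu/(EC50+Cu)
  expect_equal(cyp3a4_turnover_rhs(1 + 10.8 / 2, 0.12, 10.8, 0.12, 0.0158), 0,
               tolerance = 1e-12)
  ## saturating maximum 1 + Emax
  expect_equal(cyp3a4_turnover_rhs(11.8, 1e9, 10.8, 0.12, 0.0158), 0,
               tolerance = 1e-6)
})

test_that("hepatic metabolic rate is linear in enzyme levels with the right CYP3A4 share", {
  state <- c(A_liver = 1000, cyp3a4_level = 1)
  r1 <- hepatic_metabolic_rate(state, ref_healthy, osi)
  expect_gt(r1, 0)
  expect_equal(hepatic_metabolic_rate(c(A_liver = 0, cyp3a4_level = 1),
                                      ref_healthy, osi), 0)

  ## doubling every enzyme concentration doubles the rate
  s2 <- ref_healthy
  s2$physiology$enzyme_conc <- s2$physiology$enzyme_conc * 2
  expect_equal(hepatic_metabolic_rate(state, s2, osi), 2 * r1,
               tolerance = 1e-12)

  ## fraction metabolized by CYP3A4 in healthy liver ~0.44 (reported ~0.476)
  cl <- enzyme_clearances(ref_healthy, osi)
  fm <- cl[["CYP3A4"]] / sum(cl)
  expect_equal(fm, 0.476, tolerance = 0.1 / 0.476)  # within 10 points
})

test_that("mass balance holds to well below 0.1% throughout multiple dosing", {
  res <- simulate_pbpk(ref_patient, osi, od80_14d)
  expect_lt(res$mass_balance_error, 1e-3)
  expect_true(all(res$plasma_conc >= 0))
  expect_true(!is.unsorted(res$time))
})

test_that("a zero dose yields identically zero concentrations", {
  res <- simulate_pbpk(ref_patient, osi, dosing_regimen(0, 24, 3))
  expect_true(all(res$plasma_conc == 0))
  expect_true(all(res$tissue_conc == 0))
  expect_equal(res$enzyme_level, rep(1, length(res$time)), tolerance = 1e-10)
})

test_that("AUC is dose-proportional when the CYP3A4 auto-effects are disabled", {
  sim <- function(dose) {
    r <- simulate_pbpk(ref_patient, osi, dosing_regimen(dose, 24, 7),
                       auto_inhibition = FALSE, auto_induction = FALSE)
    compute_pk_metrics(r, window = c(144, 168), dose_mg = dose)$auc
  }
  a40 <- sim(40)
  a80 <- sim(80)
  expect_equal(a80 / a40, 2, tolerance = 1e-3)
})

test_that("oral AUC to infinity matches the closed-form unbound clearance identity", {
  ## with auto-effects off and renal clearance off, every absorbed molecule
  ## is cleared by the liver and plasma AUC(0-inf) = Dose / (fup * CLint,u)
  res <- simulate_pbpk(ref_patient, osi_linear, dosing_regimen(80, n_doses = 1),
                       duration = 2000, auto_inhibition = FALSE,
                       auto_induction = FALSE, points_per_hour = 2)
  auc <- compute_pk_metrics(res, dose_mg = 80, extrapolate = TRUE)$auc_inf
  analytic <- res$dose_nmol / (ref_patient$fup *
                                 sum(enzyme_clearances(ref_patient, osi_linear)))
  expect_equal(auc, analytic, tolerance = 0.01)
})

test_that("the lung partition override moves lung exposure but hardly plasma", {
  reg <- dosing_regimen(80, 24, 5)
  r_hi <- simulate_pbpk(ref_patient, osi, reg)
  r_lo <- simulate_pbpk(ref_patient, osi, reg,
                        partition = build_partition_set(osi, overrides = c(lung = 14.3)))
  w <- c(96, 120)
  sel <- r_hi$time >= w[1] & r_hi$time <= w[2]
  lung_ratio <- mean(r_hi$tissue_conc[sel, "lung"]) /
    mean(r_lo$tissue_conc[sel, "lung"])
  plasma_ratio <- compute_pk_metrics(r_hi, w, 80)$auc /
    compute_pk_metrics(r_lo, w, 80)$auc
  expect_equal(lung_ratio, 28.5 / 14.3, tolerance = 0.1)
  expect_lt(abs(plasma_ratio - 1), 0.1)
})

test_that("solutions are converged with respect to solver tolerances", {
  reg <- dosing_regimen(80, 24, 5)
  a1 <- compute_pk_metrics(simulate_pbpk(ref_patient, osi, reg),
                           c(96, 120), 80)$auc
  a2 <- compute_pk_metrics(simulate_pbpk(ref_patient, osi, reg,
                                         rtol = 1e-9, atol = 1e-7),
                           c(96, 120), 80)$auc
  expect_equal(a1, a2, tolerance = 1e-3)
})

test_that("simulation is deterministic and validates its inputs", {
  reg <- dosing_regimen(80, 24, 2)
  r1 <- simulate_pbpk(ref_patient, osi, reg)
  r2 <- simulate_pbpk(ref_patient, osi, reg)
  expect_identical(r1$plasma_conc, r2$plasma_conc)

  expect_error(simulate_pbpk(ref_patient, osi, reg, duration = 10),
               "cover the dosing regimen")
  expect_error(dosing_regimen(-5), "dose_amount")
  expect_error(dosing_regimen(80, interval = 0, n_doses = 3), "interval")
  expect_error(simulate_pbpk(ref_patient, osi, reg, rtol = -1), "positive")
})

test_that("dose conversion to nmol uses the molecular weight", {
  res <- simulate_pbpk(ref_patient, osi, dosing_regimen(80, n_doses = 1),
                       duration = 1)
  expect_equal(res$dose_nmol, 80e6 / 499.6)
  expect_equal(round(res$dose_nmol), 160128)
})
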