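test_that("the drug-free receptor pool is a steady state of the occupancy ODEs", {
  p <- occupancy_params()
  d <- occupancy_rhs(em_free = p$em0, oem = 0, clung = 0, p)
  expect_equal(unname(d), c(0, 0))
})

test_that("inhibition percent follows the occupancy fraction", {
  expect_equal(inhibition_percent(0, 5), 0)
  expect_equal(inhibition_percent(3, 3), 50)
  expect_equal(inhibition_percent(3, 1), 75)
  expect_error(inhibition_percent(0, 0), "both")
  expect_error(inhibition_percent(-1, 1), ">= 0")
})

test_that("constant-drug inhibition reaches the closed-form steady state", {
  p <- occupancy_params()
  ## kon*C = kturnover gives exactly 50% at steady state
  c50 <- p$kturnover / (p$kon[["T790M"]] * 3600)
  prof <- data.frame(time = seq(0, 600, by = 0.5), conc = c50)
  occ <- simulate_occupancy(prof, p, mutants = "T790M",
                            ss_window = c(550, 600))
  expect_equal(occ$summary$min_inhibition, 50, tolerance = 0.5 / 50)

  ## 0.01 uM on T790M: kon*C = 32.76/h >> kturnover -> ~99.9%
  prof2 <- data.frame(time = seq(0, 48, by = 0.1), conc = 0.01)
  occ2 <- simulate_occupancy(prof2, p, mutants = "T790M",
                             ss_window = c(40, 48))
  expect_equal(occ2$summary$min_inhibition,
               steady_state_inhibition(0.01, 0.91, 0.025),
               tolerance = 0.005)
  expect_equal(steady_state_inhibition(0.01, 0.91, 0.025), 99.92,
               tolerance = 1e-4)
})

test_that("the adaptive integrator agrees with a fixed-step Euler oracle", {
  p <- occupancy_params()
  ## square-wave free lung concentration: 0.002 uM for 12 h, 0 for 12 h
  tt <- seq(0, 72, by = 0.05)
  cc <- ifelse(tt %% 24 < 12, 0.002, 0)
  occ <- simulate_occupancy(data.frame(time = tt, conc = cc), p,
                            mutants = "T790M", ss_window = c(48, 72))

  ## independent brute-force Euler at dt = 1e-4 h on the same linearly
  ## interpolated profile the integrator consumes
  dt <- 1e-4
  grid_dt <- 0.05
  kon <- p$kon[["T790M"]] * 3600
  kt <- p$kturnover
  em <- p$em0; oe <- 0
  inh_euler <- numeric(length(tt))
  inh_euler[1] <- 0
  idx <- 2
  t <- 0
  for (i in seq_len(72 / dt)) {
    j <- floor(t / grid_dt)
    frac <- (t - j * grid_dt) / grid_dt
    cl <- if (j + 2 <= length(cc)) {
      cc[j + 1] * (1 - frac) + cc[j + 2] * frac
    } else cc[length(cc)]
    d_oe <- kon * cl * em - kt * oe
    d_em <- (p$em0 - em) * kt - kon * cl * em
    em <- em + dt * d_em
    oe <- oe + dt * d_oe
    t <- t + dt
    while (idx <= length(tt) && tt[idx] <= t + 1e-12) {
      inh_euler[idx] <- 100 * oe / (em + oe)
      idx <- idx + 1
    }
  }
  expect_lt(max(abs(occ$inhibition[, "T790M"] - inh_euler)), 0.1)
})

test_that("T790M inhibition dominates L858R for any common profile", {
  tt <- seq(0, 96, by = 0.2)
  cc <- 0.003 * (1 + sin(tt / 5)^2)
  occ <- simulate_occupancy(data.frame(time = tt, conc = cc))
  expect_true(all(occ$inhibition[, "T790M"] >= occ$inhibition[, "L858R"] - 1e-6))
})

test_that("steady-state inhibition is monotone in the lung concentration", {
  p <- occupancy_params()
  levels <- c(1e-6, 5e-6, 2e-5, 1e-4, 1e-3)
  mins <- vapply(levels, function(cl) {
    prof <- data.frame(time = seq(0, 400, by = 1), conc = cl)
    simulate_occupancy(prof, p, mutants = "L858R",
                       ss_window = c(350, 400))$summary$min_inhibition
  }, numeric(1))
  expect_true(all(diff(mins) > 0))
})

test_that("the receptor pool is conserved under complex degradation", {
  p <- occupancy_params(complex_degradation = TRUE)
  prof <- data.frame(time = seq(0, 500, by = 1), conc = 2e-5)
  occ <- simulate_occupancy(prof, p, mutants = "T790M")
  total <- occ$em_free[, 1] + occ$oem[, 1]
  n <- length(total)
  expect_equal(total[n], p$em0, tolerance = 0.005)
})

test_that("without complex degradation the covalent complex only accumulates", {
  p <- occupancy_params(complex_degradation = FALSE)
  tt <- seq(0, 72, by = 0.1)
  cc <- ifelse(tt %% 24 < 6, 0.001, 0)
  occ <- simulate_occupancy(data.frame(time = tt, conc = cc), p,
                            mutants = "T790M")
  expect_true(all(diff(occ$oem[, 1]) > -1e-9))
})

test_that("profile validation catches malformed input and zero profiles give zero inhibition", {
  p <- occupancy_params()
  zero <- data.frame(time = seq(0, 24, by = 0.5), conc = 0)
  occ <- simulate_occupancy(zero, p)
  expect_true(all(occ$inhibition == 0))

  expect_error(simulate_occupancy(data.frame(time = c(1, 0), conc = c(0, 0)), p),
               "sorted")
  expect_error(simulate_occupancy(data.frame(time = c(0, 1), conc = c(0, -1)), p),
               "non-negative")
  expect_error(occupancy_params(kon = c(T790M = -1)), "positive")
  expect_error(occupancy_params(em0 = 0), "positive")
})
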