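test_that("reference physiologies reproduce the published parameter table", {
  h <- reference_physiology("caucasian", "healthy")
  expect_equal(h$albumin, 0.45)
  expect_equal(h$hematocrit, 0.47)
  expect_equal(h$get, 15)
  expect_equal(h$liver_volume, 2.38)
  expect_equal(unname(h$enzyme_conc["CYP3A4"]), 4.32)
  expect_equal(unname(h$enzyme_conc["CYP1A2"]), 1.80)

  p <- reference_physiology("caucasian", "patient")
  expect_equal(p$albumin, 0.31)
  expect_equal(p$hematocrit, 0.33)
  expect_equal(p$get, 120)
  expect_equal(unname(p$enzyme_conc[c("CYP1A2", "CYP2A6", "CYP2C9",
                                      "CYP2E1", "CYP3A4", "CYP3A5")]),
               c(1.33, 1.90, 3.20, 1.37, 3.02, 0.028))

  j <- reference_physiology("japanese", "healthy")
  expect_equal(unname(j$enzyme_conc["CYP3A4"]), 4.32 * 112 / 137,
               tolerance = 1e-12)
  expect_equal(j$liver_volume, 1.91)
  expect_equal(reference_physiology("chinese", "healthy")$liver_volume, 2.16)

  expect_error(reference_physiology("martian", "healthy"), "valid options")
  expect_error(reference_physiology("caucasian", "zombie"), "valid options")
})

test_that("regional blood flows balance cardiac output", {
  for (e in c("caucasian", "japanese", "chinese")) {
    p <- reference_physiology(e, "patient")
    expect_equal(sum(p$organ_flows), cardiac_output(p), tolerance = 1e-12)
    expect_true(all(p$organ_flows > 0))
    expect_true(all(p$organ_volumes > 0))
  }
})

test_that("disease downregulation scales enzyme concentrations as printed", {
  expect_equal(apply_disease_downregulation(1.80, 0.74), 1.332)  # CYP1A2 -> 1.33
  expect_equal(apply_disease_downregulation(2.72, 0.70), 1.904)  # CYP2A6 -> 1.90
  expect_equal(apply_disease_downregulation(3.7, 1.0), 3.7)
  expect_error(apply_disease_downregulation(1, 1.2), "retained fraction")
  expect_error(apply_disease_downregulation(1, -0.1), "retained fraction")
})

test_that("disease translation composed with the binding equation gives printed patient binding", {
  s <- reference_subject("caucasian", "patient")
  expect_equal(round(s$fup, 3), 0.019)
  expect_equal(round(s$rbp, 1), 1.1)
})

test_that("ethnic abundance scaling is order-preserving", {
  enzymes <- names(reference_physiology("caucasian", "healthy")$enzyme_conc)
  concs <- sapply(c("caucasian", "japanese", "chinese"), function(e) {
    reference_physiology(e, "healthy")$enzyme_conc[enzymes]
  })
  abund <- sapply(c("caucasian", "japanese", "chinese"), function(e) {
    reference_physiology(e, "healthy")$enzyme_abundance[enzymes]
  })
  for (i in seq_along(enzymes)) {
    expect_equal(order(concs[i, ]), order(abund[i, ]))
  }
})

test_that("population sampling is seed-deterministic and respects zero CV", {
  spec0 <- population_spec("caucasian", "patient", n_subjects = 10, seed = 5,
                           cv_map = c(albumin = 0))
  pop0 <- sample_population(spec0)
  expect_length(pop0, 10)
  ref <- reference_subject("caucasian", "patient")
  for (s in pop0) {
    expect_equal(s$physiology$albumin, ref$physiology$albumin)
    expect_equal(s$fup, ref$fup)
    expect_equal(s$rbp, ref$rbp)
  }

  spec <- population_spec("japanese", "patient", n_subjects = 25, seed = 11)
  expect_identical(population_table(sample_population(spec)),
                   population_table(sample_population(spec)))
  ## different seed gives a different draw
  spec2 <- population_spec("japanese", "patient", n_subjects = 25, seed = 12)
  expect_false(identical(population_table(sample_population(spec)),
                         population_table(sample_population(spec2))))
})

test_that("sampling converges to the reference subject as CV -> 0", {
  spec <- population_spec("caucasian", "patient", n_subjects = 5, seed = 3,
                          cv_map = c(albumin = 1e-6))
  pop <- sample_population(spec)
  ref <- reference_subject("caucasian", "patient")
  for (s in pop) {
    expect_equal(s$physiology$albumin, ref$physiology$albumin,
                 tolerance = 1e-6)
    expect_equal(s$fup, ref$fup, tolerance = 1e-5)
  }
})

test_that("log-normal draws recover the requested geometric mean and CV", {
  spec <- population_spec("japanese", "patient", n_subjects = 10000, seed = 99,
                          cv_map = c(albumin = 30))
  alb <- population_table(sample_population(spec))$albumin
  gs <- geometric_stats(alb)
  expect_equal(gs$geometric_mean, 0.31, tolerance = 0.01)      # within 1%
  expect_equal(gs$geometric_cv_percent, 30, tolerance = 0.05)  # within 5%
})

test_that("population spec validates its inputs and round-trips through YAML", {
  expect_error(population_spec(n_subjects = 0), "n_subjects")
  expect_error(population_spec(cv_map = c(albumin = -5)), ">= 0")
  expect_error(population_spec(cv_map = c(bogus = 10)), "unsupported")
  spec <- population_spec("chinese", "patient", 7, seed = 2,
                          cv_map = c(albumin = 30, cyp3a4_clint = 10))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_population_config(spec, f)
  expect_equal(read_population_config(f), spec)
})
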