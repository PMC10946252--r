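## shared fixtures: the default compound and reference subjects, built once

osi <- osimertinib_parameters()
ref_patient <- reference_subject("caucasian", "patient", compound = osi)
ref_healthy <- reference_subject("caucasian", "healthy", compound = osi)
od80_14d <- dosing_regimen(80, 24, 14)
ss_window <- c(312, 336)

## compound with auto-effects structurally removed and no renal clearance,
## for closed-form clearance checks
osi_linear <- local({
  x <- osi
  x$fraction_gfr <- 0
  x
})

## random valid compound generator for property tests
random_compound <- function() {
  compound_parameters(
    molecular_weight = runif(1, 200, 700),
    pka_base = c(runif(1, 7.5, 10.5), runif(1, 3, 6)),
    logp = runif(1, 0.5, 6),
    peff = runif(1, 0.05, 3),
    fup = runif(1, 0.005, 0.5),
    rbp = runif(1, 0.8, 2),
    clint_u = c(CYP3A4 = runif(1, 0.1, 2)),
    ki_cyp3a4 = 2.55, ec50_cyp3a4 = 0.12, emax_cyp3a4 = 10.8,
    klu_p = NA_real_, kp_scale = 1
  )
}
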