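## Reference physiology tables and the virtual-population generator.
##
## Ethnic differences enter through two channels only: liver volume and
## hepatic enzyme abundance ratios (concentration scaled by the abundance
## ratio relative to the Caucasian reference). All other anthropometrics are
## held at a ~70-kg reference human; organ volumes (L) and blood flows (L/h)
## follow standard reference tables (Brown et al. 1997 compilation, ICRP-style
## cardiac-output fractions) and are config-overridable.

.eth_levels <- c("caucasian", "japanese", "chinese")
.state_levels <- c("healthy", "patient")
.enzymes <- c("CYP1A2", "CYP2A6", "CYP2C9", "CYP2E1", "CYP3A4", "CYP3A5")

## Hepatic enzyme concentration, umol/L liver tissue (Caucasian reference)
.enzyme_conc_healthy <- c(CYP1A2 = 1.80, CYP2A6 = 2.72, CYP2C9 = 3.84,
                          CYP2E1 = 1.96, CYP3A4 = 4.32, CYP3A5 = 0.04)
.enzyme_conc_patient <- c(CYP1A2 = 1.33, CYP2A6 = 1.90, CYP2C9 = 3.20,
                          CYP2E1 = 1.37, CYP3A4 = 3.02, CYP3A5 = 0.028)

## Hepatic enzyme abundance, pmol/mg microsomal protein, per ethnicity
.enzyme_abundance <- list(
  caucasian = c(CYP1A2 = 52,   CYP2A6 = 36,   CYP2C9 = 73,
                CYP2E1 = 61,   CYP3A4 = 137,  CYP3A5 = 116),
  japanese  = c(CYP1A2 = 31.8, CYP2A6 = 11.5, CYP2C9 = 59.2,
                CYP2E1 = 36,   CYP3A4 = 112,  CYP3A5 = 27.8),
  chinese   = c(CYP1A2 = 42,   CYP2A6 = 14,   CYP2C9 = 60,
                CYP2E1 = 70.5, CYP3A4 = 120,  CYP3A5 = 99)
)

.liver_volumes <- c(caucasian = 2.38, japanese = 1.91, chinese = 2.16)

## Organ volumes (L) and regional blood flows (L/h) for the lumped
## compartment set. "rest" lumps bone, brain, heart, spleen, pancreas and
## the remaining carcass. Flows sum exactly to cardiac output.
.organ_volumes <- c(gut = 1.10, lung = 0.53, kidney = 0.31, adipose = 15.0,
                    muscle = 29.0, skin = 3.40, rest = 11.0,
                    arterial_blood = 1.70, venous_blood = 3.50)
.organ_flows <- c(gut = 51, hepatic_artery = 22, kidney = 62, adipose = 17,
                  muscle = 57, skin = 19, rest = 108)

#' Reference physiology for an ethnicity and health state
#'
#' Builds the deterministic reference individual: organ volumes and flows,
#' liver volume, hematocrit, albumin, glomerular filtration rate, gastric
#' emptying time, and hepatic enzyme concentrations. Ethnic enzyme scaling
#' multiplies the Caucasian concentration by the abundance ratio
#' \code{abundance(ethnicity)/abundance(caucasian)} per enzyme. The patient
#' state applies the NSCLC adjustments: albumin 0.31 g/dL, hematocrit 0.33,
#' gastric emptying 120 min, and downregulated enzyme concentrations.
#'
#' @param ethnicity one of \code{"caucasian"}, \code{"japanese"},
#'   \code{"chinese"}.
#' @param health_state \code{"healthy"} or \code{"patient"}.
#' @param liver_volumes named vector of liver volumes (L) per ethnicity;
#'   override to swap the Japanese/Chinese assignment.
#' @param gfr glomerular filtration rate, mL/min.
#' @param organ_volumes,organ_flows optional named overrides (L, L/h).
#' @return An object of class \code{physiology}.
#' @examples
#' p <- reference_physiology("caucasian", "healthy")
#' p$albumin     # 0.45 g/dL
#' p$enzyme_conc[["CYP3A4"]]  # 4.32 uM
#' @export
reference_physiology <- function(ethnicity = c("caucasian", "japanese", "chinese"),
                                 health_state = c("healthy", "patient"),
                                 liver_volumes = .liver_volumes,
                                 gfr = 120,
                                 organ_volumes = NULL,
                                 organ_flows = NULL) {
  if (is.character(ethnicity) && length(ethnicity) == 1L &&
      !ethnicity %in% .eth_levels) {
    stop("unknown ethnicity '", ethnicity, "'; valid options: ",
         paste(.eth_levels, collapse = ", "))
  }
  ethnicity <- match.arg(ethnicity)
  if (is.character(health_state) && length(health_state) == 1L &&
      !health_state %in% .state_levels) {
    stop("unknown health_state '", health_state, "'; valid options: ",
         paste(.state_levels, collapse = ", "))
  }
  health_state <- match.arg(health_state)

  vols <- .organ_volumes
  if (!is.null(organ_volumes)) vols[names(organ_volumes)] <- organ_volumes
  flows <- .organ_flows
  if (!is.null(organ_flows)) flows[names(organ_flows)] <- organ_flows
  if (any(vols <= 0) || any(flows <= 0)) {
    stop("all organ volumes and flows must be positive")
  }

  conc_cauc <- if (health_state == "healthy") .enzyme_conc_healthy else .enzyme_conc_patient
  ratio <- .enzyme_abundance[[ethnicity]] / .enzyme_abundance$caucasian
  enzyme_conc <- conc_cauc * ratio[names(conc_cauc)]

  structure(
    list(
      ethnicity = ethnicity,
      health_state = health_state,
      liver_volume = unname(liver_volumes[[ethnicity]]),
      hematocrit = if (health_state == "healthy") 0.47 else 0.33,
      albumin = if (health_state == "healthy") 0.45 else 0.31,
      gfr = gfr,
      get = if (health_state == "healthy") 15 else 120,
      enzyme_conc = enzyme_conc,
      enzyme_abundance = .enzyme_abundance[[ethnicity]],
      organ_volumes = vols,
      organ_flows = flows,
      body_weight = 70
    ),
    class = "physiology"
  )
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s %s\n", x$ethnicity, x$health_state))
  cat(sprintf("  liver %.2f L, Hct %.2f, albumin %.2f g/dL, GET %g min, GFR %g mL/min\n",
              x$liver_volume, x$hematocrit, x$albumin, x$get, x$gfr))
  cat("  enzyme conc (uM):",
      paste(sprintf("%s=%.3g", names(x$enzyme_conc), x$enzyme_conc), collapse = " "), "\n")
  invisible(x)
}

#' Cardiac output of a physiology
#'
#' Sum of the regional blood flows; the venous-to-arterial (lung) flow
#' carries exactly this amount so that flows balance at every node.
#' @param phys a \code{physiology} object.
#' @return Cardiac output, L/h (blood).
#' @export
cardiac_output <- function(phys) sum(phys$organ_flows)

#' Disease downregulation of an enzyme concentration
#'
#' @param healthy_conc healthy enzyme concentration, umol/L liver tissue.
#' @param factor retained fraction in disease, in [0, 1]
#'   (e.g. 0.74 for a 26\% downregulation).
#' @return \code{healthy_conc * factor}.
#' @examples
#' apply_disease_downregulation(1.80, 0.74)  # 1.332, prints as 1.33 (CYP1A2)
#' @export
apply_disease_downregulation <- function(healthy_conc, factor) {
  if (any(healthy_conc < 0)) stop("`healthy_conc` must be >= 0")
  if (any(factor < 0 | factor > 1)) {
    stop("`factor` is a retained fraction and must lie in [0, 1], got ",
         paste(factor, collapse = ", "))
  }
  healthy_conc * factor
}

#' Population specification
#'
#' Describes a virtual population: ethnicity, health state, size, RNG seed,
#' and the log-normal inter-subject variability (as percent CV) per sampled
#' parameter. Supported \code{cv_map} names: \code{albumin}, \code{fup}, and
#' per-enzyme intrinsic-clearance multipliers such as \code{cyp3a4_clint}
#' (any of \code{cyp1a2_clint}, ..., \code{cyp3a5_clint}).
#'
#' Default albumin variability follows the population calibration: 20\% CV
#' for Caucasians, 30\% for Japanese and Chinese.
#'
#' @param ethnicity,health_state as in [reference_physiology()].
#' @param n_subjects number of virtual subjects (>= 1).
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   populations.
#' @param cv_map named numeric vector of percent CVs; \code{NULL} uses the
#'   ethnicity default for albumin and 0 elsewhere.
#' @param age_range,proportion_female demographic metadata (not used by the
#'   model; carried for reporting).
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(ethnicity = "caucasian",
                            health_state = "patient",
                            n_subjects = 10,
                            seed = 1L,
                            cv_map = NULL,
                            age_range = NULL,
                            proportion_female = NULL) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  if (is.null(cv_map)) {
    cv_map <- c(albumin = if (ethnicity == "caucasian") 20 else 30)
  }
  if (any(cv_map < 0)) stop("percent CVs must be >= 0")
  known <- c("albumin", "fup", paste0(tolower(.enzymes), "_clint"))
  bad <- setdiff(names(cv_map), known)
  if (length(bad)) {
    stop("unsupported cv_map parameter(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(known, collapse = ", "))
  }
  structure(
    list(ethnicity = ethnicity, health_state = health_state,
         n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         cv_map = cv_map, age_range = age_range,
         proportion_female = proportion_female),
    class = "population_spec"
  )
}

## log-normal multiplier with geometric mean 1 and the requested percent CV:
## sigma^2 = log(1 + CV^2)
.lognormal_multipliers <- function(n, cv_percent) {
  if (cv_percent <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + (cv_percent / 100)^2))
  exp(stats::rnorm(n, mean = 0, sd = sigma))
}

#' Build a virtual subject from a physiology and compound
#'
#' Derives the subject's fraction unbound from its albumin level via the
#' binding equation (anchored at the healthy reference albumin 0.45 g/dL and
#' the compound's healthy \code{fup}), then its blood-to-plasma ratio from its
#' hematocrit with the blood-cell affinity held at the healthy-derived value.
#'
#' @param physiology a \code{physiology} object (possibly with sampled
#'   albumin).
#' @param compound a \code{compound_parameters} object.
#' @param subject_id integer identifier.
#' @param clint_multipliers named multipliers on per-enzyme intrinsic
#'   clearance (default all 1).
#' @param fup_multiplier extra multiplier on the derived fraction unbound.
#' @param albumin_healthy healthy reference albumin, g/dL.
#' @param hct_healthy healthy reference hematocrit used to derive the
#'   blood-cell affinity.
#' @param rng_draws named multipliers actually drawn (bookkeeping).
#' @return An object of class \code{virtual_subject}.
#' @export
virtual_subject <- function(physiology, compound, subject_id = 1L,
                            clint_multipliers = NULL, fup_multiplier = 1,
                            albumin_healthy = 0.45, hct_healthy = 0.47,
                            rng_draws = NULL) {
  stopifnot(inherits(physiology, "physiology"),
            inherits(compound, "compound_parameters"))
  fup <- patient_fup(compound$fup, physiology$albumin, albumin_healthy) *
    fup_multiplier
  if (fup > 1) fup <- 1
  kbc <- kpu_bc(hct_healthy, compound$rbp, compound$fup)
  rbp <- patient_rbp(physiology$hematocrit, fup, kbc)
  mult <- stats::setNames(rep(1, length(.enzymes)), .enzymes)
  if (!is.null(clint_multipliers)) {
    mult[toupper(names(clint_multipliers))] <- clint_multipliers
  }
  structure(
    list(physiology = physiology, fup = fup, rbp = rbp,
         subject_id = as.integer(subject_id),
         clint_multipliers = mult,
         rng_draws = rng_draws %||% c(albumin = 1, fup = 1)),
    class = "virtual_subject"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference subject (no variability)
#'
#' Convenience wrapper: the deterministic reference individual of an
#' ethnicity/health state coupled to a compound.
#' @inheritParams virtual_subject
#' @param ethnicity,health_state passed to [reference_physiology()].
#' @param ... passed to [reference_physiology()].
#' @return A \code{virtual_subject}.
#' @export
reference_subject <- function(ethnicity = "caucasian",
                              health_state = "patient",
                              compound = osimertinib_parameters(), ...) {
  virtual_subject(reference_physiology(ethnicity, health_state, ...), compound)
}

#' Sample a seeded virtual population
#'
#' Draws \code{n_subjects} virtual subjects. Each parameter named in the
#' spec's \code{cv_map} is drawn log-normally with geometric mean equal to the
#' reference value and the requested percent CV
#' (\eqn{\sigma^2 = \ln(1 + CV^2)}). Albumin draws propagate to the fraction
#' unbound via the binding equation and to the blood-to-plasma ratio via the
#' blood-cell affinity relation; \code{fup} and per-enzyme \code{*_clint} CVs
#' act as independent multipliers.
#'
#' @param spec a \code{population_spec}.
#' @param compound a \code{compound_parameters} object.
#' @param ... passed to [reference_physiology()].
#' @return A list of \code{virtual_subject} objects, length
#'   \code{spec$n_subjects}.
#' @export
sample_population <- function(spec, compound = osimertinib_parameters(), ...) {
  stopifnot(inherits(spec, "population_spec"))
  ref <- reference_physiology(spec$ethnicity, spec$health_state, ...)
  n <- spec$n_subjects
  cv <- function(name) if (name %in% names(spec$cv_map)) spec$cv_map[[name]] else 0

  ## fixed draw order for seed reproducibility
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  alb_mult <- .lognormal_multipliers(n, cv("albumin"))
  fup_mult <- .lognormal_multipliers(n, cv("fup"))
  cl_mult <- vapply(.enzymes, function(e) {
    .lognormal_multipliers(n, cv(paste0(tolower(e), "_clint")))
  }, numeric(n))
  cl_mult <- matrix(cl_mult, nrow = n, dimnames = list(NULL, .enzymes))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  lapply(seq_len(n), function(i) {
    phys <- ref
    phys$albumin <- ref$albumin * alb_mult[i]
    virtual_subject(
      phys, compound, subject_id = i,
      clint_multipliers = stats::setNames(cl_mult[i, ], .enzymes),
      fup_multiplier = fup_mult[i],
      rng_draws = c(albumin = alb_mult[i], fup = fup_mult[i],
                    stats::setNames(cl_mult[i, ], paste0(tolower(.enzymes), "_clint")))
    )
  })
}

#' Tabulate a virtual population
#'
#' One row per subject with the sampled parameters; suitable for CSV export
#' via [utils::write.csv()].
#' @param population list of \code{virtual_subject} objects.
#' @return A data.frame.
#' @export
population_table <- function(population) {
  do.call(rbind, lapply(population, function(s) {
    data.frame(
      subject_id = s$subject_id,
      ethnicity = s$physiology$ethnicity,
      health_state = s$physiology$health_state,
      albumin = s$physiology$albumin,
      hematocrit = s$physiology$hematocrit,
      fup = s$fup,
      rbp = s$rbp,
      liver_volume = s$physiology$liver_volume,
      t(s$clint_multipliers)
    )
  }))
}

#' Write / read a population specification as YAML
#' @param spec a \code{population_spec}; \code{path} file path.
#' @param path file path.
#' @return \code{read_population_config} returns a \code{population_spec}.
#' @export
write_population_config <- function(spec, path) {
  stopifnot(inherits(spec, "population_spec"))
  lst <- unclass(spec)
  lst$cv_map <- as.list(lst$cv_map)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_population_config
#' @export
read_population_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$cv_map <- unlist(lst$cv_map)
  do.call(population_spec, lst)
}
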