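#' Compound parameter set
#'
#' Container for the drug-specific constants that drive the PBPK model:
#' physicochemistry (molecular weight, basic pKa values, logP, solubility,
#' effective intestinal permeability), plasma binding (healthy fraction
#' unbound \code{fup}, blood-to-plasma ratio \code{rbp}), per-enzyme unbound
#' intrinsic clearances, CYP3A4 auto-inhibition (\code{ki_cyp3a4}) and
#' auto-induction (\code{ec50_cyp3a4}, \code{emax_cyp3a4}) constants, the
#' experimental lung-to-plasma partition coefficient \code{klu_p}, the global
#' partition scale \code{kp_scale}, and the fraction of glomerular filtration
#' available for renal clearance.
#'
#' @param molecular_weight g/mol.
#' @param pka_base numeric vector of basic dissociation constants (strongest
#'   first); empty vector for a neutral compound.
#' @param logp octanol-water log partition coefficient.
#' @param solubility aqueous solubility, mg/mL.
#' @param peff effective intestinal permeability, 1e-4 cm/s units
#'   (i.e. \code{peff = 0.187} means 0.187e-4 cm/s).
#' @param fup healthy fraction unbound in plasma, in (0, 1].
#' @param rbp healthy blood-to-plasma concentration ratio, > 0.
#' @param clint_u named numeric vector, unbound intrinsic clearance per
#'   enzyme, uL/min/pmol.
#' @param ki_cyp3a4 competitive auto-inhibition constant for CYP3A4/5, umol/L.
#' @param ec50_cyp3a4 auto-induction half-maximal concentration, umol/L.
#' @param emax_cyp3a4 maximal fold induction effect (dimensionless, >= 0).
#' @param klu_p experimental lung-to-plasma partition coefficient used as the
#'   default lung override.
#' @param kp_scale multiplier applied to Rodgers-Rowland partition
#'   predictions for all non-overridden organs.
#' @param fraction_gfr fraction of GFR contributing to renal clearance.
#' @param kdeg_cyp3a4 hepatic CYP3A4 degradation rate constant, 1/h. This is
#'   an external literature constant (turnover half-life about 44 h), not a
#'   compound property; it is carried here because the induction ODE needs it.
#'
#' @return An object of class \code{compound_parameters}.
#' @seealso [osimertinib_parameters()] for the default osimertinib set.
#' @export
compound_parameters <- function(molecular_weight,
                                pka_base = numeric(0),
                                logp,
                                solubility = NA_real_,
                                peff,
                                fup,
                                rbp,
                                clint_u = c(CYP3A4 = 0),
                                ki_cyp3a4 = Inf,
                                ec50_cyp3a4 = Inf,
                                emax_cyp3a4 = 0,
                                klu_p = NA_real_,
                                kp_scale = 1,
                                fraction_gfr = 1,
                                kdeg_cyp3a4 = 0.0158) {
  stopifnot(is.numeric(molecular_weight), molecular_weight > 0)
  if (!(fup > 0 && fup <= 1)) {
    stop("`fup` must lie in (0, 1], got ", fup)
  }
  if (!(rbp > 0)) stop("`rbp` must be positive, got ", rbp)
  if (any(clint_u < 0)) stop("all `clint_u` entries must be >= 0")
  if (is.null(names(clint_u)) || any(!nzchar(names(clint_u)))) {
    stop("`clint_u` must be a named vector (enzyme -> uL/min/pmol)")
  }
  if (!(ki_cyp3a4 > 0)) stop("`ki_cyp3a4` must be positive")
  if (!(ec50_cyp3a4 > 0)) stop("`ec50_cyp3a4` must be positive")
  if (emax_cyp3a4 < 0) stop("`emax_cyp3a4` must be >= 0")
  if (kp_scale <= 0) stop("`kp_scale` must be positive")
  if (kdeg_cyp3a4 <= 0) stop("`kdeg_cyp3a4` must be positive")

  structure(
    list(
      molecular_weight = molecular_weight,
      pka_base = as.numeric(pka_base),
      logp = logp,
      solubility = solubility,
      peff = peff,
      fup = fup,
      rbp = rbp,
      clint_u = clint_u,
      ki_cyp3a4 = ki_cyp3a4,
      ec50_cyp3a4 = ec50_cyp3a4,
      emax_cyp3a4 = emax_cyp3a4,
      klu_p = klu_p,
      kp_scale = kp_scale,
      fraction_gfr = fraction_gfr,
      kdeg_cyp3a4 = kdeg_cyp3a4
    ),
    class = "compound_parameters"
  )
}

#' Default osimertinib parameter set
#'
#' The versioned constant set (\code{"table1"}) of osimertinib-specific
#' parameters: MW 499.6 g/mol, diprotic base (pKa 9.5, 4.4), logP 5.45,
#' solubility 3.1 mg/mL, Peff 0.187e-4 cm/s, healthy fup 0.013 and Rbp 1.0,
#' unbound intrinsic clearances for CYP1A2/2A6/2C9/2E1/3A4/3A5, CYP3A4/5
#' competitive auto-inhibition Ki 2.55 uM, CYP3A4 auto-induction EC50 0.12 uM
#' and Emax 10.8, experimental lung partition coefficient 28.5, and a global
#' Kp scale of 1.5.
#'
#' @param version character; currently only \code{"table1"}.
#' @return A \code{compound_parameters} object.
#' @export
osimertinib_parameters <- function(version = "table1") {
  version <- match.arg(version)
  compound_parameters(
    molecular_weight = 499.6,
    pka_base = c(9.5, 4.4),
    logp = 5.45,
    solubility = 3.1,
    peff = 0.187,
    fup = 0.013,
    rbp = 1.0,
    clint_u = c(
      CYP1A2 = 0.52, CYP2A6 = 0.37, CYP2C9 = 0.48,
      CYP2E1 = 0.11, CYP3A4 = 0.73, CYP3A5 = 0.21
    ),
    ki_cyp3a4 = 2.55,
    ec50_cyp3a4 = 0.12,
    emax_cyp3a4 = 10.8,
    klu_p = 28.5,
    kp_scale = 1.5,
    fraction_gfr = 1.0,
    kdeg_cyp3a4 = 0.0158
  )
}

#' @export
print.compound_parameters <- function(x, ...) {
  cat("<compound_parameters>\n")
  cat(sprintf("  MW %.1f g/mol, logP %.2f, pKa(base) %s\n",
              x$molecular_weight, x$logp,
              if (length(x$pka_base)) paste(x$pka_base, collapse = ", ") else "none"))
  cat(sprintf("  fup %.4g, Rbp %.3g, Klu,p %.3g, Kp scale %.2g\n",
              x$fup, x$rbp, x$klu_p, x$kp_scale))
  cat("  CLint,u (uL/min/pmol):",
      paste(sprintf("%s=%.3g", names(x$clint_u), x$clint_u), collapse = " "), "\n")
  cat(sprintf("  CYP3A4 auto-effects: Ki %.3g uM, EC50 %.3g uM, Emax %.3g\n",
              x$ki_cyp3a4, x$ec50_cyp3a4, x$emax_cyp3a4))
  invisible(x)
}

check_positive <- function(value, name) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0) {
    stop("`", name, "` must be a positive number, got ",
         paste(format(value), collapse = ", "), call. = FALSE)
  }
  invisible(value)
}

#' Disease translation of the plasma fraction unbound
#'
#' Scales the healthy fraction unbound to a patient albumin level assuming
#' linear binding to albumin with a fixed association constant: the bound:free
#' ratio is proportional to the albumin concentration, so
#' \deqn{fu_{pat} = \frac{1}{1 + \frac{(1 - fu_h)\,P_{pat}}{P_h\,fu_h}}}
#' Only the albumin ratio enters, so any consistent unit works; the reference
#' values are carried in g/dL (healthy 0.45, NSCLC patient 0.31).
#'
#' @param fup_healthy healthy fraction unbound, in (0, 1).
#' @param albumin_patient,albumin_healthy plasma albumin levels, g/dL.
#' @return Patient fraction unbound, in (0, 1). Strictly decreasing in
#'   \code{albumin_patient}, strictly increasing in \code{fup_healthy}.
#' @examples
#' patient_fup(0.013, 0.31, 0.45)  # ~0.0188, prints as 0.019
#' @export
patient_fup <- function(fup_healthy, albumin_patient, albumin_healthy) {
  check_positive(fup_healthy, "fup_healthy")
  check_positive(albumin_patient, "albumin_patient")
  check_positive(albumin_healthy, "albumin_healthy")
  if (fup_healthy >= 1) stop("`fup_healthy` must be < 1, got ", fup_healthy)
  1 / (1 + ((1 - fup_healthy) * albumin_patient) / (albumin_healthy * fup_healthy))
}

#' Blood-cell affinity constant of unbound drug
#'
#' Inverts the healthy blood-to-plasma ratio into the partition coefficient of
#' unbound drug into blood cells:
#' \deqn{K_{puBC} = \frac{Hct - 1 + R_{bp}}{Hct \cdot fu_p}}
#'
#' @param hct hematocrit, in (0, 1).
#' @param rbp blood-to-plasma concentration ratio; must satisfy
#'   \code{rbp >= 1 - hct} (otherwise cell partitioning would be negative).
#' @param fup fraction unbound in plasma, in (0, 1].
#' @return Non-negative blood-cell affinity (dimensionless).
#' @examples
#' kpu_bc(0.47, 1.0, 0.013)  # ~76.9 for healthy osimertinib values
#' @export
kpu_bc <- function(hct, rbp, fup) {
  if (!(hct > 0 && hct < 1)) stop("`hct` must lie in (0, 1), got ", hct)
  if (!(fup > 0 && fup <= 1)) stop("`fup` must lie in (0, 1], got ", fup)
  if (rbp < 1 - hct) {
    stop("`rbp` (", rbp, ") implies negative blood-cell partitioning; ",
         "requires rbp >= 1 - hct = ", 1 - hct)
  }
  (hct - 1 + rbp) / (hct * fup)
}

#' Patient blood-to-plasma ratio
#'
#' Rebuilds the blood-to-plasma ratio for a patient hematocrit and fraction
#' unbound, holding the blood-cell affinity fixed at the value derived from
#' healthy measurements:
#' \deqn{R_{bp} = 1 + Hct\,(fu_p \cdot K_{puBC} - 1)}
#'
#' @param hct_patient patient hematocrit, in (0, 1).
#' @param fup_patient patient fraction unbound, in (0, 1].
#' @param kpu_bc blood-cell affinity computed from healthy values via
#'   [kpu_bc()].
#' @return Patient blood-to-plasma ratio (> 0).
#' @examples
#' k <- kpu_bc(0.47, 1.0, 0.013)
#' patient_rbp(0.33, patient_fup(0.013, 0.31, 0.45), k)  # ~1.15, prints as 1.1
#' @export
patient_rbp <- function(hct_patient, fup_patient, kpu_bc) {
  if (!(hct_patient > 0 && hct_patient < 1)) {
    stop("`hct_patient` must lie in (0, 1), got ", hct_patient)
  }
  check_positive(fup_patient, "fup_patient")
  check_positive(kpu_bc, "kpu_bc")
  out <- 1 + hct_patient * (fup_patient * kpu_bc - 1)
  if (out <= 0) {
    stop("computed blood-to-plasma ratio is non-positive (", out, ")")
  }
  out
}

#' Write / read compound parameters as a YAML config
#'
#' @param x a \code{compound_parameters} object.
#' @param path file path.
#' @return \code{write_compound_config} returns \code{path} invisibly;
#'   \code{read_compound_config} returns a \code{compound_parameters} object.
#' @export
write_compound_config <- function(x, path) {
  stopifnot(inherits(x, "compound_parameters"))
  lst <- unclass(x)
  lst$clint_u <- as.list(lst$clint_u)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_compound_config
#' @export
read_compound_config <- function(path) {
  lst <- yaml::read_yaml(path)
  clint <- unlist(lst$clint_u)
  do.call(compound_parameters, c(
    lst[setdiff(names(lst), "clint_u")],
    list(clint_u = clint)
  ))
}
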