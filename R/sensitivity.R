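## Local sensitivity analysis by +/-20% parameter perturbation.

#' Normalized local sensitivity coefficient
#'
#' \deqn{SC = \frac{\Delta Y / Y}{\Delta P / P}}
#'
#' @param y_base unperturbed output (> 0).
#' @param y_perturbed output after perturbation.
#' @param delta_frac fractional parameter change (non-zero; e.g. 0.2 or -0.2).
#' @return Dimensionless signed coefficient.
#' @examples
#' sensitivity_coefficient(1, 1.44, 0.2)  # 2.2 for y = P^2 at +20%
#' @export
sensitivity_coefficient <- function(y_base, y_perturbed, delta_frac) {
  if (!(y_base > 0)) stop("`y_base` must be positive")
  if (delta_frac == 0) stop("`delta_frac` must be non-zero")
  ((y_perturbed - y_base) / y_base) / delta_frac
}

.sensitivity_parameters <- c(
  "fup", "rbp", "get", "albumin",
  paste0(tolower(.enzymes), "_clint"),
  paste0(tolower(.enzymes), "_conc"),
  "liver_volume", "auto_inhibition_induction"
)

## Apply a multiplicative perturbation of one named parameter and return the
## rebuilt (subject, compound) pair. Albumin propagates to fup and Rbp
## through the binding equations; fup and rbp act directly on the subject;
## the auto-effect perturbation scales Ki and Emax jointly.
.perturb <- function(subject, compound, parameter, factor,
                     albumin_healthy = 0.45) {
  s <- subject
  cp <- compound
  if (parameter == "fup") {
    s$fup <- s$fup * factor
  } else if (parameter == "rbp") {
    s$rbp <- s$rbp * factor
  } else if (parameter == "get") {
    s$physiology$get <- s$physiology$get * factor
  } else if (parameter == "albumin") {
    alb <- s$physiology$albumin * factor
    s$physiology$albumin <- alb
    s$fup <- patient_fup(cp$fup, alb, albumin_healthy)
    s$rbp <- patient_rbp(s$physiology$hematocrit, s$fup,
                         kpu_bc(0.47, cp$rbp, cp$fup))
  } else if (parameter == "liver_volume") {
    s$physiology$liver_volume <- s$physiology$liver_volume * factor
  } else if (parameter == "auto_inhibition_induction") {
    cp$ki_cyp3a4 <- cp$ki_cyp3a4 * factor
    cp$emax_cyp3a4 <- cp$emax_cyp3a4 * factor
  } else if (grepl("_clint$", parameter)) {
    enz <- toupper(sub("_clint$", "", parameter))
    if (!enz %in% names(cp$clint_u)) stop("unknown enzyme in '", parameter, "'")
    cp$clint_u[[enz]] <- cp$clint_u[[enz]] * factor
  } else if (grepl("_conc$", parameter)) {
    enz <- toupper(sub("_conc$", "", parameter))
    if (!enz %in% names(s$physiology$enzyme_conc)) {
      stop("unknown enzyme in '", parameter, "'")
    }
    s$physiology$enzyme_conc[[enz]] <- s$physiology$enzyme_conc[[enz]] * factor
  } else {
    stop("unknown sensitivity parameter '", parameter, "'; supported: ",
         paste(.sensitivity_parameters, collapse = ", "))
  }
  list(subject = s, compound = cp)
}

.ss_outputs <- function(subject, compound, regimen, partition = NULL) {
  if (is.null(partition)) partition <- build_partition_set(compound)
  duration <- regimen$start_time + regimen$interval * regimen$n_doses
  res <- simulate_pbpk(subject, compound, regimen, duration = duration,
                       partition = partition)
  win <- c(duration - regimen$interval, duration)
  m <- compute_pk_metrics(res, window = win, dose_mg = regimen$dose_amount)
  c(auc_ss = m$auc, css_max = m$cmax, ctrough = m$ctrough)
}

#' Local sensitivity analysis of steady-state PK metrics
#'
#' Runs the deterministic reference individual at the given regimen, perturbs
#' each parameter by \code{+delta_frac} and \code{-delta_frac}, and reports
#' the mean of the two one-sided coefficients for steady-state AUC, peak and
#' trough over the final dosing interval. The albumin perturbation is
#' propagated to the fraction unbound and the blood-to-plasma ratio through
#' the binding equations, which is why albumin and fup are distinct rows.
#'
#' @param subject a \code{virtual_subject} (typically a reference patient).
#' @param compound a \code{compound_parameters}.
#' @param regimen a \code{dosing_regimen} (default 80 mg once daily x 14 d).
#' @param parameter_list character vector of parameters to perturb; see
#'   Details. Supported names: \code{fup}, \code{rbp}, \code{get},
#'   \code{albumin}, \code{<enzyme>_clint}, \code{<enzyme>_conc},
#'   \code{liver_volume}, \code{auto_inhibition_induction}.
#' @param delta_frac perturbation fraction (default 0.20).
#' @param verbose logical; also return both one-sided coefficients.
#' @return data.frame with one row per parameter: \code{sc_auc_ss},
#'   \code{sc_css_max}, \code{sc_ctrough} (mean of the +/- coefficients) and,
#'   when \code{verbose}, the one-sided values.
#' @export
run_sensitivity <- function(subject = reference_subject("caucasian", "patient"),
                            compound = osimertinib_parameters(),
                            regimen = dosing_regimen(80, 24, 14),
                            parameter_list = .sensitivity_parameters,
                            delta_frac = 0.20,
                            verbose = FALSE) {
  base <- .ss_outputs(subject, compound, regimen)
  rows <- lapply(parameter_list, function(p) {
    up <- .perturb(subject, compound, p, 1 + delta_frac)
    dn <- .perturb(subject, compound, p, 1 - delta_frac)
    y_up <- .ss_outputs(up$subject, up$compound, regimen)
    y_dn <- .ss_outputs(dn$subject, dn$compound, regimen)
    sc_up <- (y_up / base - 1) / delta_frac
    sc_dn <- (y_dn / base - 1) / (-delta_frac)
    sc <- (sc_up + sc_dn) / 2
    out <- data.frame(parameter = p,
                      sc_auc_ss = sc[["auc_ss"]],
                      sc_css_max = sc[["css_max"]],
                      sc_ctrough = sc[["ctrough"]],
                      perturbation_fraction = delta_frac)
    if (verbose) {
      out$sc_auc_ss_up <- sc_up[["auc_ss"]]; out$sc_auc_ss_dn <- sc_dn[["auc_ss"]]
      out$sc_ctrough_up <- sc_up[["ctrough"]]; out$sc_ctrough_dn <- sc_dn[["ctrough"]]
    }
    out
  })
  do.call(rbind, rows)
}
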