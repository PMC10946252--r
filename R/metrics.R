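## Non-compartmental PK metrics and geometric population summaries.

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

## terminal log-linear slope: initial fit on the final 20% of the span after
## the peak, refit over the last three estimated half-lives
terminal_slope <- function(time, conc) {
  i_max <- which.max(conc)
  t_end <- max(time)
  sel <- time >= (t_end - 0.2 * (t_end - time[i_max])) & conc > 0
  if (sum(sel) < 3) stop("too few positive terminal points for extrapolation")
  fit <- stats::lm(log(conc[sel]) ~ time[sel])
  lambda <- -unname(stats::coef(fit)[2])
  if (lambda > 0) {
    span <- 3 * log(2) / lambda
    sel2 <- time >= max(time[i_max], t_end - span) & conc > 0
    if (sum(sel2) >= 3) {
      fit <- stats::lm(log(conc[sel2]) ~ time[sel2])
      lambda <- -unname(stats::coef(fit)[2])
    }
  }
  if (lambda <= 0) stop("non-positive terminal slope; profile not in decline")
  lambda
}

#' Non-compartmental PK metrics on a simulated profile
#'
#' AUC by the trapezoid rule on the dense output grid; \code{cmax}/\code{tmax}
#' within the window; \code{ctrough} is the concentration at the window end
#' (the pre-dose trough when the window is the final dosing interval at
#' steady state). Apparent clearance CL/F is dose/AUC over the window for
#' steady-state metrics (\code{extrapolate = FALSE}), or dose/AUC(0-inf) with
#' log-linear tail extrapolation (tail fitted over the final three estimated
#' half-lives) for single-dose profiles (\code{extrapolate = TRUE}).
#'
#' @param result a \code{pbpk_result} (or data.frame with \code{time} and
#'   \code{plasma_conc}).
#' @param window \code{c(start, end)} in h; must lie inside the simulated
#'   span. Defaults to the full span.
#' @param dose_mg dose per administration, mg, for CL/F. Taken from the
#'   result's regimen when omitted.
#' @param molecular_weight g/mol for mg -> nmol conversion.
#' @param extrapolate logical; log-linear AUC extrapolation to infinity
#'   (single-dose CL/F).
#' @return An object of class \code{pk_metrics}: \code{auc} (nmol*h/L),
#'   \code{cmax}, \code{ctrough} (nmol/L), \code{tmax} (h), \code{cl_f}
#'   (L/h), \code{auc_inf} (when extrapolated), \code{window}.
#' @examples
#' ## triangular profile 0 -> 100 -> 0 over 2 h has AUC 100
#' tri <- data.frame(time = c(0, 1, 2), plasma_conc = c(0, 100, 0))
#' compute_pk_metrics(tri, dose_mg = 0)$auc
#' @export
compute_pk_metrics <- function(result, window = NULL, dose_mg = NULL,
                               molecular_weight = 499.6,
                               extrapolate = FALSE) {
  time <- result$time
  conc <- if (inherits(result, "pbpk_result")) result$plasma_conc else result$plasma_conc
  if (is.null(window)) window <- range(time)
  if (window[1] < min(time) - 1e-9 || window[2] > max(time) + 1e-9) {
    stop("`window` [", window[1], ", ", window[2],
         "] lies outside the simulated span [", min(time), ", ", max(time), "]")
  }
  if (is.null(dose_mg)) {
    dose_mg <- if (!is.null(result$regimen)) result$regimen$dose_amount else NA_real_
  }
  sel <- time >= window[1] - 1e-9 & time <= window[2] + 1e-9
  tw <- time[sel]; cw <- conc[sel]

  auc <- trapz(tw, cw)
  i_max <- which.max(cw)
  cmax <- cw[i_max]
  tmax <- tw[i_max]
  ctrough <- cw[length(cw)]

  dose_nmol <- mg_to_nmol(dose_mg, molecular_weight)
  auc_inf <- NA_real_
  if (extrapolate) {
    lambda <- terminal_slope(tw, cw)
    auc_inf <- auc + ctrough / lambda
    cl_f <- dose_nmol / auc_inf
  } else {
    cl_f <- dose_nmol / auc
  }

  structure(
    list(auc = auc, auc_inf = auc_inf, cmax = cmax, ctrough = ctrough,
         tmax = tmax, cl_f = cl_f, window = window, dose_mg = dose_mg),
    class = "pk_metrics"
  )
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("<pk_metrics> window [%g, %g] h\n", x$window[1], x$window[2]))
  cat(sprintf("  AUC %.5g nmol*h/L%s, Cmax %.5g @ %.3g h, Ctrough %.5g nmol/L, CL/F %.4g L/h\n",
              x$auc,
              if (!is.na(x$auc_inf)) sprintf(" (AUCinf %.5g)", x$auc_inf) else "",
              x$cmax, x$tmax, x$ctrough, x$cl_f))
  invisible(x)
}

#' Geometric summary statistics
#'
#' Geometric mean \code{exp(mean(log x))}, geometric percent CV
#' \code{100 * sqrt(exp(var(log x)) - 1)}, and a 95\% t-interval for the
#' geometric mean on the log scale.
#'
#' @param values positive numeric vector, length >= 1.
#' @return An object of class \code{population_summary}: \code{geometric_mean},
#'   \code{geometric_cv_percent}, \code{ci95} (length 2), \code{n}.
#' @examples
#' geometric_stats(c(1, 10, 100))$geometric_mean  # 10
#' @export
geometric_stats <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all values must be positive and finite for geometric statistics")
  }
  lx <- log(values)
  n <- length(lx)
  m <- mean(lx)
  v <- if (n > 1) stats::var(lx) else 0
  half <- if (n > 1) stats::qt(0.975, n - 1) * sqrt(v / n) else 0
  structure(
    list(geometric_mean = exp(m),
         geometric_cv_percent = 100 * sqrt(exp(v) - 1),
         ci95 = exp(c(m - half, m + half)),
         n = n),
    class = "population_summary"
  )
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> n=%d  geo mean %.5g (%.1f%% CV), 95%% CI [%.5g, %.5g]\n",
              x$n, x$geometric_mean, x$geometric_cv_percent,
              x$ci95[1], x$ci95[2]))
  invisible(x)
}
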