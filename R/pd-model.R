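# Emax pharmacodynamics: drug efficacy as a saturating function of
# concentration, cohort-level estimation of the efficacy-to-death-rate
# conversion constant K, and inversion for patient-specific EC50.

#' Emax pharmacodynamic parameters
#'
#' @param emax maximum effect (> 0; dimensionless).
#' @param ec50 concentration of half-maximal effect (mg/L, > 0).
#' @param n Hill shape factor (> 0).
#' @return an object of class `pd_parameters`.
#' @export
pd_parameters <- function(emax = 1, ec50 = 0.123, n = 1) {
  check_positive(emax, "emax")
  check_positive(ec50, "ec50")
  check_positive(n, "n")
  structure(list(emax = emax, ec50 = ec50, n = n), class = "pd_parameters")
}

#' The benchmark average PD model
#'
#' The population-average Emax model used to calibrate the conversion
#' constant: `n = 1`, `EC50 = 0.123 mg/L`, `Emax = 1`.
#'
#' @return a [pd_parameters()] object.
#' @export
benchmark_pd <- function() pd_parameters(emax = 1, ec50 = 0.123, n = 1)

#' @export
print.pd_parameters <- function(x, ...) {
  cat(sprintf("Emax PD model: Emax = %g, EC50 = %g mg/L, n = %g\n",
              x$emax, x$ec50, x$n))
  invisible(x)
}

#' Drug efficacy at a concentration (Emax model)
#'
#' `E(c) = Emax * c^n / (EC50^n + c^n)`: zero at zero concentration,
#' strictly increasing, saturating at `Emax`.
#'
#' @param c concentration(s) in mg/L (>= 0; vectorized).
#' @param pd a [pd_parameters()] object.
#' @return dimensionless efficacy in \[0, Emax).
#' @export
efficacy <- function(c, pd = benchmark_pd()) {
  if (any(c < 0)) stop_invalid("concentration must be non-negative")
  cn <- c^pd$n
  pd$emax * cn / (pd$ec50^pd$n + cn)
}

#' Estimate the efficacy-to-death-rate conversion constant K
#'
#' Calibrates the linear relation `<d1> = K <E>` between the
#' population-average CSC death rate and the population-average drug
#' efficacy. For each patient the time-average concentration `C_bar` under a
#' reference regimen (default: 40 days of 400 mg/day) is computed from the
#' patient's PK model and converted to efficacy with the benchmark PD model;
#' then `K = mean(d1) / mean(E)`. The confidence half-width follows by
#' first-order error propagation from the patients' `d1` standard errors
#' (treated as independent): `k_ci = sqrt(sum(se^2)) / (N * mean(E))`.
#'
#' @param pk_models list of [pk_model()] objects, one per patient.
#' @param d1 CSC death rates (1/day), one per patient.
#' @param d1_se optional standard errors of `d1` (1/day).
#' @param benchmark a [pd_parameters()] benchmark PD model.
#' @param reference_schedule a [dose_schedule()]; default 40-day 400 mg/day.
#' @return an object of class `conversion_constant` with fields `k`, `k_ci`
#'   (half-width; `NA` without standard errors), `c_bar` and `efficacy`
#'   per-patient vectors.
#' @export
estimate_K <- function(pk_models, d1, d1_se = NULL,
                       benchmark = benchmark_pd(),
                       reference_schedule = standard_schedule(40)) {
  if (!length(pk_models) || length(pk_models) != length(d1))
    stop_invalid("need one PK model per d1 estimate")
  c_bar <- vapply(pk_models, function(pk)
    time_average_concentration(reference_schedule, pk), numeric(1))
  e_bar <- efficacy(c_bar, benchmark)
  if (mean(e_bar) <= 0) stop_invalid("zero mean efficacy: cannot estimate K")
  k <- mean(d1) / mean(e_bar)
  k_ci <- if (is.null(d1_se)) NA_real_
          else sqrt(sum(d1_se^2)) / (length(d1) * mean(e_bar))
  structure(list(k = k, k_ci = k_ci, c_bar = c_bar, efficacy = e_bar),
            class = "conversion_constant")
}

#' @export
print.conversion_constant <- function(x, ...) {
  cat(sprintf("Efficacy-to-death-rate conversion: K = %.4f %s 1/day (n = %d patients)\n",
              x$k,
              if (is.finite(x$k_ci)) sprintf("+/- %.4g", x$k_ci) else "",
              length(x$c_bar)))
  invisible(x)
}

#' Patient-specific EC50 from the estimated death rate
#'
#' Inverts `d1 = K * Emax * C_bar^n / (EC50^n + C_bar^n)` for EC50:
#' `EC50 = C_bar * (K * Emax / d1 - 1)^(1/n)`. Requires
#' `0 < d1 < K * Emax`, otherwise the implied efficacy would exceed the
#' maximum effect.
#'
#' @param c_bar patient time-average concentration under the reference
#'   regimen (mg/L).
#' @param k conversion constant (1/day), or a `conversion_constant` object.
#' @param d1 patient CSC death rate (1/day).
#' @param emax,n fixed PD parameters (defaults `Emax = 1`, `n = 1`).
#' @return EC50 in mg/L.
#' @export
estimate_ec50 <- function(c_bar, k, d1, emax = 1, n = 1) {
  if (inherits(k, "conversion_constant")) k <- k$k
  check_positive(c_bar, "c_bar")
  check_positive(k, "k")
  if (d1 <= 0 || d1 >= k * emax)
    stop_invalid("d1 = %g outside (0, K*Emax = %g): efficacy would exceed Emax",
                 d1, k * emax)
  c_bar * (k * emax / d1 - 1)^(1 / n)
}
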