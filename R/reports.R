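# Pipeline commands and human-readable comparison reports: optimized vs
# standard therapy at diagnosis, cohort burden fitting with PD estimation,
# therapy adjustment for burden minimization, and robustness studies. Each
# command is a plain function returning a report list; `out_dir` writes the
# JSON report, schedule CSVs and the resolved configuration next to each
# other so every run is reproducible from its own outputs.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

.schedule_summary <- function(schedule, pk, target, grid_minutes = 1) {
  list(times_h = schedule$times, doses_mg = schedule$doses,
       total_mg = sum(schedule$doses),
       auc_mg_h_L = auc(schedule, pk),
       mean_concentration_mg_L = time_average_concentration(schedule, pk),
       cumulative_distance_mg_h_L =
         if (!is.null(target)) cost_optimal_target(schedule, pk, target)
         else NULL,
       fraction_time_above =
         if (!is.null(target))
           fraction_time_above(schedule, target, pk = pk,
                               grid_minutes = grid_minutes)
         else NULL)
}

#' Diagnosis-time optimization report
#'
#' For each patient, optimizes 1-dose/day and 3-doses/day schedules for both
#' the lower-bound target (default 0.57 mg/L) and the optimal target
#' (default 1 mg/L), and reports dosage, concentration summaries, cumulative
#' distance to target, AUC and fraction of time above target, next to the
#' standard 400 mg/day comparator.
#'
#' @param patients a named list of [patient_record()] (or a CSV/JSON path
#'   readable by [read_patients()]).
#' @param coeffs a [pk_coefficients()] object.
#' @param days horizon in days.
#' @param lower_bound_target,optimal_target target concentrations in mg/L.
#' @param doses_per_day integer vector of dosing frequencies to optimize.
#' @param config an [optimizer_config()].
#' @param seed integer seed; runs are seeded deterministically from it.
#' @param out_dir optional output directory for JSON/CSV artifacts.
#' @return a list of per-patient reports.
#' @export
report_diagnosis <- function(patients, coeffs = default_pk_coefficients(),
                             days = 14, lower_bound_target = 0.57,
                             optimal_target = 1.0, doses_per_day = c(1, 3),
                             config = optimizer_config(), seed = 1,
                             out_dir = NULL) {
  if (is.character(patients)) patients <- read_patients(patients)
  reports <- list()
  run_idx <- 0L
  for (p in patients) {
    pk <- pk_model(p, coeffs)
    std <- standard_schedule(days)
    rep_p <- list(patient = list(id = p$id, age = p$age, sex = p$sex,
                                 body_weight = p$body_weight),
                  pk = list(ka = pk$ka, f = pk$f, clearance = pk$clearance,
                            volume = pk$volume),
                  runs = list())
    for (cost in c("lower_bound", "optimal_target")) {
      target <- if (cost == "lower_bound") lower_bound_target
                else optimal_target
      for (dpd in doses_per_day) {
        run_idx <- run_idx + 1L
        prob <- control_problem(pk, cost = cost, days = days,
                                doses_per_day = dpd, target = target)
        res <- optimize_schedule(prob, config, seed = seed + run_idx)
        rep_p$runs[[sprintf("%s_%ddose", cost, dpd)]] <- c(
          list(cost_kind = cost, target_mg_L = target,
               doses_per_day = dpd, best_cost = res$best_cost,
               cost_trace = res$cost_trace, seed = res$seed),
          optimized = list(.schedule_summary(res$schedule, pk, target,
                                             config$grid_minutes)),
          standard = list(.schedule_summary(std, pk, target,
                                            config$grid_minutes)))
      }
    }
    reports[[p$id]] <- rep_p
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_json(reports, file.path(out_dir, "diagnosis_report.json"))
    .write_json(list(command = "optimize-diagnosis", days = days,
                     lower_bound_target = lower_bound_target,
                     optimal_target = optimal_target,
                     doses_per_day = doses_per_day, seed = seed,
                     config = unclass(config)),
                file.path(out_dir, "resolved_config.json"))
  }
  reports
}

#' Cohort burden-fit and PD-estimation report
#'
#' Fits each patient's tumor-burden series with the biphasic log10 decay,
#' derives the cancer-stem-cell death rate from the rightmost slope,
#' calibrates the cohort conversion constant K against the benchmark PD
#' model under the reference regimen, and inverts for each patient's EC50.
#' Patients failing the inclusion filter (fewer than 3 points, or a fit
#' infeasibility) are listed with reasons.
#'
#' @param burden a named list of [burden_series()] (or a CSV path for
#'   [read_burden()]).
#' @param patients a named list of [patient_record()] matching the burden
#'   ids (or a CSV/JSON path).
#' @param coeffs a [pk_coefficients()] object.
#' @param a1,p1 leukemia model constants (defaults 0.87 and 0.45/day).
#' @param benchmark benchmark [pd_parameters()] for the K calibration.
#' @param reference_days length of the reference regimen window in days.
#' @param out_dir optional output directory.
#' @return a list with `patients` (per-patient fit + PD estimates), `K`
#'   (the [estimate_K()] result) and `excluded` (id -> reason).
#' @export
report_burden_fits <- function(burden, patients,
                               coeffs = default_pk_coefficients(),
                               a1 = 0.87, p1 = 0.45,
                               benchmark = benchmark_pd(),
                               reference_days = 40, out_dir = NULL) {
  if (is.character(burden)) burden <- read_burden(burden)
  if (is.character(patients)) patients <- read_patients(patients)
  excluded <- as.list(attr(burden, "excluded"))
  fits <- list(); pks <- list(); d1 <- c(); d1_se <- c()
  for (id in names(burden)) {
    if (!id %in% names(patients)) {
      excluded[[id]] <- "no matching patient record"
      next
    }
    f <- tryCatch(fit_biphasic(burden[[id]]), error = conditionMessage)
    if (!inherits(f, "biphasic_fit")) { excluded[[id]] <- f; next }
    d1i <- tryCatch(csc_death_rate(f$slope2, a1, p1),
                    error = conditionMessage)
    if (!is.numeric(d1i)) { excluded[[id]] <- d1i; next }
    fits[[id]] <- f
    pks[[id]] <- pk_model(patients[[id]], coeffs)
    d1 <- c(d1, d1i)
    d1_se <- c(d1_se, f$slope_se[2] / log10(exp(1)))
  }
  if (!length(fits))
    stop_invalid("no patient passed the burden-fit filter (%d excluded)",
                 length(excluded))
  K <- estimate_K(pks, d1, d1_se, benchmark,
                  standard_schedule(reference_days))
  out <- list(patients = list(), K = K, excluded = excluded)
  for (i in seq_along(fits)) {
    id <- names(fits)[i]
    ec50 <- tryCatch(estimate_ec50(K$c_bar[i], K$k, d1[i]),
                     error = function(e) NA_real_)
    out$patients[[id]] <- list(
      slope1 = fits[[id]]$slope1, slope2 = fits[[id]]$slope2,
      intercept1 = fits[[id]]$intercept1,
      intercept2 = fits[[id]]$intercept2,
      breakpoint_days = fits[[id]]$breakpoint,
      r_squared = fits[[id]]$r_squared,
      d1_per_day = d1[i], d1_se_per_day = d1_se[i],
      c_bar_mg_L = K$c_bar[i], ec50_mg_L = ec50, K_used = K$k)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_json(list(patients = out$patients,
                     K = list(k = K$k, k_ci = K$k_ci),
                     excluded = excluded),
                file.path(out_dir, "burden_fit_report.json"))
  }
  out
}

#' Therapy-adjustment report: burden minimization with estimated PD
#'
#' Runs the burden fit + PD estimation, then optimizes the burden/exposure
#' cost per patient (weight ratio phi chosen per sex), and reports the
#' predicted cancer-stem-cell decay rate under the optimized versus standard
#' schedule and their ratio (the decay speed-up factor).
#'
#' @inheritParams report_burden_fits
#' @param phi_male,phi_female burden/exposure weight ratios per sex
#'   (defaults 60 and 75).
#' @param days,doses_per_day optimization horizon and dosing frequency.
#' @param config an [optimizer_config()].
#' @param seed integer seed.
#' @return a list of per-patient adjustment reports (plus `K`).
#' @export
report_adjustment <- function(burden, patients,
                              coeffs = default_pk_coefficients(),
                              phi_male = 60, phi_female = 75,
                              a1 = 0.87, p1 = 0.45,
                              days = 14, doses_per_day = 1,
                              config = optimizer_config(), seed = 1,
                              out_dir = NULL) {
  if (phi_male <= 0 || phi_female <= 0)
    stop_invalid("phi must be positive: both cost terms must be meaningful")
  fits <- report_burden_fits(burden, patients, coeffs, a1, p1)
  if (is.character(patients)) patients <- read_patients(patients)
  lk <- leukemia_params(a1, p1)
  out <- list(K = fits$K, patients = list())
  run_idx <- 0L
  for (id in names(fits$patients)) {
    run_idx <- run_idx + 1L
    est <- fits$patients[[id]]
    if (!is.finite(est$ec50_mg_L)) next
    p <- patients[[id]]
    pk <- pk_model(p, coeffs)
    pd <- pd_parameters(emax = 1, ec50 = est$ec50_mg_L, n = 1)
    phi <- if (p$q == 1) phi_male else phi_female
    prob <- control_problem(pk, cost = "burden_auc", days = days,
                            doses_per_day = doses_per_day,
                            w1 = phi, w2 = 1, pd = pd, leukemia = lk,
                            k = fits$K)
    res <- optimize_schedule(prob, config, seed = seed + run_idx)
    std <- standard_schedule(days)
    decay <- function(s) {
      cb <- time_average_concentration(s, pk)
      (2 * a1 - 1) * p1 - fits$K$k * efficacy(cb, pd)
    }
    lam_opt <- decay(res$schedule)
    lam_std <- decay(std)
    out$patients[[id]] <- list(
      phi = phi, seed = res$seed, best_cost = res$best_cost,
      schedule = list(times_h = res$schedule$times,
                      doses_mg = res$schedule$doses),
      auc_optimized = auc(res$schedule, pk),
      auc_standard = auc(std, pk),
      csc_decay_rate_optimized = lam_opt,
      csc_decay_rate_standard = lam_std,
      decay_speed_ratio = lam_opt / lam_std,
      ec50_mg_L = est$ec50_mg_L, d1_per_day = est$d1_per_day)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_json(out, file.path(out_dir, "adjustment_report.json"))
  }
  out
}

#' Robustness study report
#'
#' Optimizes the lower-bound problem for the average patient, then runs the
#' intra-patient noise study on the requested PK parameters and the
#' systematic absorption-rate error sweep.
#'
#' @param sex sex of the average reference patient.
#' @param coeffs a [pk_coefficients()] object.
#' @param target lower-bound target in mg/L.
#' @param days,doses_per_day optimization horizon and dosing frequency.
#' @param parameters PK parameters for the noise study.
#' @param n_simulations simulations per noise level.
#' @param config an [optimizer_config()].
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @return a list with the optimization result, one `robustness_result` per
#'   parameter, and the systematic-error table.
#' @export
report_robustness <- function(sex = "M",
                              coeffs = default_pk_coefficients(),
                              target = 0.57, days = 14, doses_per_day = 1,
                              parameters = c("ka", "CL", "v"),
                              n_simulations = 700,
                              config = optimizer_config(), seed = 1,
                              out_dir = NULL) {
  pk <- pk_model(average_patient(sex, coeffs), coeffs)
  prob <- control_problem(pk, cost = "lower_bound", days = days,
                          doses_per_day = doses_per_day, target = target)
  res <- optimize_schedule(prob, config, seed = seed)
  noise <- lapply(parameters, function(par)
    intra_patient_noise_study(res, noise = noise_spec(
      parameter = par, n_simulations = n_simulations, seed = seed)))
  names(noise) <- parameters
  sys_err <- systematic_error_study(res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_json(list(
      best_cost = res$best_cost,
      schedule = list(times_h = res$schedule$times,
                      doses_mg = res$schedule$doses),
      noise = lapply(noise, function(r)
        list(table = r$table, quad_fit = as.list(r$quad_fit),
             r_squared = r$quad_r_squared)),
      systematic_error = sys_err,
      max_abs_delta_cost = max(abs(sys_err$delta_cost))),
      file.path(out_dir, "robustness_report.json"))
    utils::write.csv(sys_err, file.path(out_dir, "systematic_error.csv"),
                     row.names = FALSE)
  }
  list(optimization = res, noise = noise, systematic_error = sys_err)
}
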