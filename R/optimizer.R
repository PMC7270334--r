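# Open-loop optimal-control engine for discrete dose schedules: a chopped
# random Fourier-basis correction to the standard dosing rate, optimized one
# frequency at a time ("super-iterations") by Nelder-Mead direct search.
# Every candidate is scored as the *discretized* integer-mg schedule it
# would prescribe, through the closed-form concentration and one of three
# cost functionals (optimal target, lower-bound target, burden + AUC).

# ---- quadrature helpers -----------------------------------------------------

# integrate f over [a, b] with stats::integrate (adaptive quadrature)
.quad <- function(f, a, b) {
  if (b - a < 1e-12) return(0)
  stats::integrate(f, a, b, rel.tol = 1e-8, abs.tol = 1e-10,
                   subdivisions = 200L, stop.on.error = FALSE)$value
}

# locate the times in [a, b] where C(t) crosses `level` (sign changes of a
# 33-point scan, refined by uniroot); used to split cost integrals at the
# kinks of |C - target| and the jumps of the step penalty
.crossings <- function(cfun, level, a, b) {
  ts <- seq(a, b, length.out = 33)
  h <- cfun(ts) - level
  idx <- which(h[-1] * h[-length(h)] < 0)
  vapply(idx, function(i)
    stats::uniroot(function(t) cfun(t) - level,
                   lower = ts[i], upper = ts[i + 1],
                   tol = 1e-10)$root, numeric(1))
}

# pieces of [t_in, t_fin] on which the concentration is smooth and on one
# side of `level`: split at dose times and target crossings
.target_pieces <- function(schedule, pk, level) {
  cfun <- function(t) concentration(t, schedule, pk)
  brk <- sort(unique(c(schedule$t_in, schedule$times, schedule$t_fin)))
  brk <- brk[brk >= schedule$t_in & brk <= schedule$t_fin]
  pts <- schedule$t_in
  for (i in seq_len(length(brk) - 1)) {
    pts <- c(pts, .crossings(cfun, level, brk[i], brk[i + 1]), brk[i + 1])
  }
  sort(unique(pts))
}

# ---- cost functionals -------------------------------------------------------

#' Optimal-target cost: integrated distance to a target concentration
#'
#' `L = integral over the horizon of |C(t) - C_tg| dt` (mg h/L), computed by
#' adaptive quadrature on the closed-form concentration, with the integral
#' split at dose times and target crossings so every piece is smooth. No
#' preference between being above or below the target.
#'
#' @param schedule a [dose_schedule()].
#' @param pk a [pk_model()].
#' @param target target concentration `C_tg` in mg/L.
#' @return cost in mg h/L.
#' @export
cost_optimal_target <- function(schedule, pk, target) {
  check_positive(target, "target")
  cfun <- function(t) concentration(t, schedule, pk)
  pts <- .target_pieces(schedule, pk, target)
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    a <- pts[i]; b <- pts[i + 1]
    sgn <- sign(cfun((a + b) / 2) - target)
    total <- total + sgn * .quad(function(t) cfun(t) - target, a, b)
  }
  total
}

#' Lower-bound cost: step-penalized distance to a lower-bound target
#'
#' Integrates the step distance `S(C, C_tg)` over the horizon: `|C - C_tg|`
#' where `C >= C_tg`, and the constant penalty `G` where `C < C_tg`.
#' Solutions are driven to stay strictly above the target.
#'
#' @inheritParams cost_optimal_target
#' @param g_penalty the step-penalty constant `G` in mg/L (> 0); default
#'   `10 * target`, large enough to dominate any realistic overage distance.
#' @return cost in mg h/L.
#' @export
cost_lower_bound <- function(schedule, pk, target, g_penalty = 10 * target) {
  check_positive(target, "target")
  check_positive(g_penalty, "g_penalty")
  cfun <- function(t) concentration(t, schedule, pk)
  pts <- .target_pieces(schedule, pk, target)
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    a <- pts[i]; b <- pts[i + 1]
    if (cfun((a + b) / 2) >= target) {
      total <- total + .quad(function(t) cfun(t) - target, a, b)
    } else {
      total <- total + g_penalty * (b - a)
    }
  }
  total
}

#' Burden + exposure cost for therapy adjustment
#'
#' Integrates (in days) the instantaneous net log10 growth rate of the
#' cancer-stem-cell compartment under the drug effect, plus a toxicity term
#' proportional to the concentration:
#' `L = integral of [ W1 * log10(e) * ((2 a1 - 1) p1 - K * E(C(t))) +
#'  W2 * C(t) ] dtau`, with `E` the patient's Emax PD model and `K` the
#' efficacy-to-death-rate conversion constant. Minimizing the first term
#' maximizes the predicted CSC decay speed without needing the (unknowable)
#' initial CSC count; the second term penalizes cumulative exposure (AUC).
#' The ratio `phi = W1 / W2` sets the trade-off.
#'
#' @inheritParams cost_optimal_target
#' @param pd a [pd_parameters()] object (patient-specific).
#' @param leukemia a [leukemia_params()] object (supplies `a1`, `p1`).
#' @param k conversion constant (1/day) or `conversion_constant` object.
#' @param w1,w2 non-negative weights of the burden and exposure terms (not
#'   both zero).
#' @return cost (day-denominated mixed units).
#' @export
cost_burden_auc <- function(schedule, pk, pd, leukemia, k, w1, w2) {
  if (inherits(k, "conversion_constant")) k <- k$k
  if (w1 < 0 || w2 < 0 || (w1 == 0 && w2 == 0))
    stop_invalid("weights must be non-negative and not both zero")
  lam0 <- (2 * leukemia$a1 - 1) * leukemia$p1
  l10e <- log10(exp(1))
  cfun <- function(t) concentration(t, schedule, pk)
  brk <- sort(unique(c(schedule$t_in, schedule$times, schedule$t_fin)))
  total <- 0
  for (i in seq_len(length(brk) - 1)) {
    total <- total + .quad(function(t)
      w1 * l10e * (lam0 - k * efficacy(cfun(t), pd)) + w2 * cfun(t),
      brk[i], brk[i + 1])
  }
  total / HOURS_PER_DAY  # time measured in days
}

# ---- control problem and optimizer configuration ---------------------------

#' Define a dose-design control problem
#'
#' Bundles the PK (and, for the burden cost, PD and population-dynamics)
#' models with the horizon, dose count, cost functional and dose bounds.
#'
#' @param pk a [pk_model()].
#' @param cost one of `"lower_bound"`, `"optimal_target"`, `"burden_auc"`.
#' @param days horizon length in days.
#' @param doses_per_day doses per day (the schedule has
#'   `days * doses_per_day` doses at uniform times).
#' @param target target concentration `C_tg` in mg/L (target costs only).
#' @param g_penalty step-penalty constant `G` (lower-bound cost); default
#'   `10 * target`.
#' @param w1,w2 weights of the burden and exposure terms (`burden_auc`
#'   only); `phi = w1 / w2`.
#' @param pd,leukemia,k patient PD model, leukemia parameters and conversion
#'   constant (required for `burden_auc`).
#' @param daily_reference reference daily dose in mg (the standard regimen
#'   the correction is added to; default 400).
#' @param dose_max_daily maximum daily-equivalent dose in mg (default 800,
#'   the accepted dose-escalation ceiling); per-dose cap is
#'   `dose_max_daily / doses_per_day`.
#' @return an object of class `control_problem`.
#' @export
control_problem <- function(pk,
                            cost = c("lower_bound", "optimal_target",
                                     "burden_auc"),
                            days = 14, doses_per_day = 1,
                            target = 0.57, g_penalty = NULL,
                            w1 = NULL, w2 = NULL,
                            pd = NULL, leukemia = NULL, k = NULL,
                            daily_reference = 400, dose_max_daily = 800) {
  cost <- match.arg(cost)
  stopifnot(inherits(pk, "pk_model"))
  check_positive(days, "days")
  if (doses_per_day < 1) stop_invalid("doses_per_day must be >= 1")
  if (cost %in% c("lower_bound", "optimal_target")) {
    check_positive(target, "target")
    if (is.null(g_penalty)) g_penalty <- 10 * target
  }
  if (cost == "burden_auc") {
    if (is.null(pd) || is.null(leukemia) || is.null(k))
      stop_invalid("burden_auc cost requires pd, leukemia and k")
    if (is.null(w1) || is.null(w2) || w1 < 0 || w2 < 0 ||
        (w1 == 0 && w2 == 0))
      stop_invalid("burden_auc cost requires non-negative weights w1, w2, not both zero")
  }
  structure(list(pk = pk, cost = cost, days = days,
                 doses_per_day = doses_per_day,
                 n_doses = as.integer(days * doses_per_day),
                 horizon = c(0, days_to_hours(days)),
                 target = target, g_penalty = g_penalty,
                 w1 = w1, w2 = w2, pd = pd, leukemia = leukemia, k = k,
                 daily_reference = daily_reference,
                 dose_max_daily = dose_max_daily),
            class = "control_problem")
}

#' @export
print.control_problem <- function(x, ...) {
  cat(sprintf("Control problem: %s cost, %d doses over %g days (max %g mg/day)\n",
              x$cost, x$n_doses, x$days, x$dose_max_daily))
  if (x$cost != "burden_auc")
    cat(sprintf("  target %g mg/L%s\n", x$target,
                if (x$cost == "lower_bound")
                  sprintf(", step penalty G = %g", x$g_penalty) else ""))
  else
    cat(sprintf("  weights W1 = %g, W2 = %g (phi = %g)\n",
                x$w1, x$w2, x$w1 / x$w2))
  invisible(x)
}

#' Optimizer configuration
#'
#' Tunables of the random-Fourier-basis search. The defaults are the
#' package's reference budget: 8 super-iterations (one randomized frequency
#' each) of 200 Nelder-Mead evaluations, trapezoid boundary envelope with
#' 5% ramps, amplitudes initialized at zero with an initial simplex scale of
#' 10% of the reference dose rate, integer-mg rounding inside the scoring
#' loop, and a 1-minute concentration grid for coverage summaries.
#'
#' @param n_frequencies number of super-iterations / random frequencies.
#' @param evals_per_superiteration Nelder-Mead evaluation budget per
#'   frequency.
#' @param gamma_shape boundary envelope `Gamma(t)` keeping the correction
#'   zero at the horizon ends: `"trapezoid"` (flat with linear ramps) or
#'   `"half_sine"`.
#' @param gamma_ramp_frac ramp width of the trapezoid envelope as a fraction
#'   of the horizon.
#' @param simplex_scale_frac initial simplex scale as a fraction of the
#'   reference dose rate.
#' @param rounding_grain_mg dose rounding grain in mg (1 = integer mg).
#' @param grid_minutes grid resolution for coverage summaries.
#' @return an object of class `optimizer_config`.
#' @export
optimizer_config <- function(n_frequencies = 8,
                             evals_per_superiteration = 200,
                             gamma_shape = c("trapezoid", "half_sine"),
                             gamma_ramp_frac = 0.05,
                             simplex_scale_frac = 0.1,
                             rounding_grain_mg = 1,
                             grid_minutes = 1) {
  gamma_shape <- match.arg(gamma_shape)
  structure(list(n_frequencies = as.integer(n_frequencies),
                 evals_per_superiteration = as.integer(evals_per_superiteration),
                 gamma_shape = gamma_shape,
                 gamma_ramp_frac = gamma_ramp_frac,
                 simplex_scale_frac = simplex_scale_frac,
                 rounding_grain_mg = rounding_grain_mg,
                 grid_minutes = grid_minutes),
            class = "optimizer_config")
}

# boundary envelope Gamma(t) on [0, T]
.gamma_envelope <- function(config, T) {
  if (config$gamma_shape == "half_sine") {
    function(t) sin(pi * t / T)
  } else {
    ramp <- config$gamma_ramp_frac * T
    function(t) pmin(1, pmax(0, pmin(t, T - t) / ramp))
  }
}

#' Dose-rate function from a Fourier correction
#'
#' Builds `D(t) = max(0, D0(t) + Gamma(t) * sum_k [A_k sin(w_k t) +
#' B_k cos(w_k t)])`: the reference dose rate plus the enveloped truncated
#' random-Fourier correction, clamped at zero for physical feasibility.
#'
#' @param reference reference dose-rate function `D0(t)` (mg/h), or a single
#'   number for a constant rate.
#' @param amplitudes numeric matrix with columns `A`, `B` (one row per
#'   frequency); zero rows give the identity correction.
#' @param frequencies angular frequencies `w_k` (1/h), same number of rows.
#' @param envelope envelope function `Gamma(t)` (or a constant).
#' @return a vectorized dose-rate function of time (mg/h).
#' @export
build_dose_function <- function(reference, amplitudes, frequencies,
                                envelope) {
  if (is.numeric(reference)) {
    r0 <- reference
    reference <- function(t) rep(r0, length(t))
  }
  if (is.numeric(envelope)) {
    g0 <- envelope
    envelope <- function(t) rep(g0, length(t))
  }
  amplitudes <- rbind(amplitudes)
  function(t) {
    corr <- 0
    for (j in seq_len(nrow(amplitudes))) {
      corr <- corr + amplitudes[j, 1] * sin(frequencies[j] * t) +
        amplitudes[j, 2] * cos(frequencies[j] * t)
    }
    pmax(0, reference(t) + envelope(t) * corr)
  }
}

#' Discretize a dose-rate function into a schedule
#'
#' Places `n_doses` doses at the uniform times `t_i = i * T / (n + 1)`
#' (`i = 0, ..., n`, with `n + 1 = n_doses`) and assigns each dose the
#' integral of the dose-rate function over its interval,
#' `D_j = integral from t_j to t_(j+1) of D(s) ds`, rounded to the
#' configured grain (integer mg by default) and clamped to the per-dose cap.
#'
#' @param d_fn dose-rate function (mg/h).
#' @param n_doses number of doses.
#' @param t_fin horizon end in hours.
#' @param dose_max per-dose cap in mg (`Inf` for none).
#' @param grain rounding grain in mg (0 to skip rounding).
#' @return a list with `schedule` (a [dose_schedule()]) and `raw` (the
#'   unrounded dose masses, whose sum equals the integral of `d_fn`).
#' @export
discretize_doses <- function(d_fn, n_doses, t_fin, dose_max = Inf,
                             grain = 1) {
  if (n_doses < 1) stop_invalid("n_doses must be >= 1")
  edges <- seq(0, t_fin, length.out = n_doses + 1)
  raw <- vapply(seq_len(n_doses), function(j)
    .quad(d_fn, edges[j], edges[j + 1]), numeric(1))
  d <- if (grain > 0) round(raw / grain) * grain else raw
  d <- pmin(pmax(d, 0), dose_max)
  list(schedule = dose_schedule(times = edges[-length(edges)], doses = d,
                                t_in = 0, t_fin = t_fin),
       raw = raw)
}

# evaluate a problem's cost for a concrete schedule
.problem_cost <- function(problem, schedule) {
  switch(problem$cost,
    lower_bound = cost_lower_bound(schedule, problem$pk, problem$target,
                                   problem$g_penalty),
    optimal_target = cost_optimal_target(schedule, problem$pk,
                                         problem$target),
    burden_auc = cost_burden_auc(schedule, problem$pk, problem$pd,
                                 problem$leukemia, problem$k,
                                 problem$w1, problem$w2))
}

#' Optimize a dose schedule by chopped random-basis direct search
#'
#' Starting from the constant reference dose rate (the standard regimen
#' spread uniformly in time), the optimizer runs `n_frequencies`
#' super-iterations. Each super-iteration draws one randomized Fourier
#' frequency `w_k = 2 pi (k + r_k) / T` with `r_k ~ U(-0.5, 0.5)` and
#' optimizes its amplitude pair `(A_k, B_k)` by Nelder-Mead, with all
#' earlier frequencies frozen at their accepted optima. Every candidate is
#' scored as the schedule it would actually prescribe: the corrected rate is
#' discretized to integer-mg doses at uniform times, the closed-form
#' concentration is evaluated, and the problem's cost functional is
#' integrated. A super-iteration's amplitudes are accepted only if they
#' improve the best cost, so the cost trace is non-increasing. The result is
#' deterministic given `(problem, config, seed)`.
#'
#' @param problem a [control_problem()].
#' @param config an [optimizer_config()].
#' @param seed integer seed for the random frequencies.
#' @return an object of class `dose_optim` with components `schedule`
#'   (a [dose_schedule()]), `best_cost`, `cost_trace` (initial cost plus one
#'   entry per super-iteration), `amplitudes`, `frequencies`, `raw_doses`
#'   (unrounded dose masses of the final schedule), `seed`, `problem`,
#'   `config`.
#' @examples
#' \donttest{
#' pk <- pk_model(average_patient("M"))
#' prob <- control_problem(pk, cost = "lower_bound", target = 0.57, days = 14)
#' res <- optimize_schedule(prob, optimizer_config(n_frequencies = 2,
#'                                                 evals_per_superiteration = 50),
#'                          seed = 1)
#' res$best_cost
#' }
#' @export
optimize_schedule <- function(problem, config = optimizer_config(), seed = 1) {
  stopifnot(inherits(problem, "control_problem"),
            inherits(config, "optimizer_config"))
  T <- problem$horizon[2]
  n <- problem$n_doses
  d0_rate <- problem$daily_reference / HOURS_PER_DAY
  dose_cap <- problem$dose_max_daily / problem$doses_per_day
  env <- .gamma_envelope(config, T)
  nc <- config$n_frequencies

  score <- function(amps, freqs) {
    d_fn <- build_dose_function(d0_rate, amps, freqs, env)
    disc <- discretize_doses(d_fn, n, T, dose_max = dose_cap,
                             grain = config$rounding_grain_mg)
    cost <- .problem_cost(problem, disc$schedule)
    if (!is.finite(cost))
      stop_invalid("non-finite cost during search (amplitudes: %s)",
                   paste(signif(amps, 4), collapse = ", "))
    list(cost = cost, disc = disc)
  }

  amps <- matrix(0, nrow = nc, ncol = 2,
                 dimnames = list(NULL, c("A", "B")))
  freqs <- numeric(nc)
  init <- score(matrix(0, 1, 2), 1)  # reference schedule, zero correction
  best <- init$cost
  trace <- best

  if (best > 1e-12) {
    pscale <- rep(config$simplex_scale_frac * d0_rate, 2)
    with_seed(seed, {
      for (k in seq_len(nc)) {
        freqs[k] <- 2 * pi * (k + stats::runif(1, -0.5, 0.5)) / T
        obj <- function(p) {
          a <- amps[seq_len(k), , drop = FALSE]
          a[k, ] <- p
          score(a, freqs[seq_len(k)])$cost
        }
        res <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                            control = list(
                              maxit = config$evals_per_superiteration,
                              reltol = 1e-8, parscale = pscale))
        if (res$value < best) {
          best <- res$value
          amps[k, ] <- res$par
        }
        trace <- c(trace, best)
      }
    })
  }

  final <- score(amps, if (any(freqs > 0)) freqs else rep(1, nc))
  structure(list(schedule = final$disc$schedule,
                 best_cost = best,
                 cost_trace = trace,
                 amplitudes = amps, frequencies = freqs,
                 raw_doses = final$disc$raw,
                 seed = seed, problem = problem, config = config),
            class = "dose_optim")
}

#' @export
print.dose_optim <- function(x, ...) {
  cat(sprintf("Optimized dose schedule (%s cost, seed %d)\n",
              x$problem$cost, x$seed))
  cat(sprintf("  best cost %.4f (reference %.4f; %d super-iterations)\n",
              x$best_cost, x$cost_trace[1], length(x$cost_trace) - 1))
  print(x$schedule)
  invisible(x)
}

#' @export
plot.dose_optim <- function(x, what = c("concentration", "doses", "trace"),
                            ...) {
  what <- match.arg(what)
  if (what == "trace") {
    graphics::plot(seq_along(x$cost_trace) - 1, x$cost_trace, type = "b",
                   xlab = "super-iteration", ylab = "best cost", ...)
  } else if (what == "doses") {
    graphics::plot(x$schedule$times / HOURS_PER_DAY, x$schedule$doses,
                   type = "h", lwd = 3, xlab = "time [days]",
                   ylab = "dose [mg]", ...)
  } else {
    prof <- concentration_profile(x$schedule, x$problem$pk,
                                  grid_minutes = x$config$grid_minutes)
    plot(prof, threshold = if (x$problem$cost != "burden_auc")
      x$problem$target else NULL, ...)
  }
  invisible(x)
}

#' Scan the burden/exposure weight ratio phi
#'
#' Re-optimizes the burden + AUC problem for each value of
#' `phi = W1 / W2` (with `W2 = 1`) and each patient, recording the 14-day
#' AUC and the efficacy at the 14-day time-average concentration — the
#' quantities used to pick a sound phi per sex.
#'
#' @param pk_models named list of [pk_model()] objects.
#' @param pd_list list of [pd_parameters()], one per patient.
#' @param k conversion constant.
#' @param phi_values numeric vector of phi values to scan.
#' @param leukemia a [leukemia_params()] object.
#' @param days,doses_per_day horizon and dosing frequency.
#' @param config an [optimizer_config()].
#' @param seed integer seed (each run is seeded deterministically from it).
#' @return a data.frame with columns `patient`, `phi`, `auc`,
#'   `mean_concentration`, `efficacy_at_mean`, `best_cost`.
#' @export
phi_scan <- function(pk_models, pd_list, k, phi_values,
                     leukemia = leukemia_params(),
                     days = 14, doses_per_day = 1,
                     config = optimizer_config(), seed = 1) {
  if (!length(phi_values)) stop_invalid("phi_values must be non-empty")
  ids <- names(pk_models)
  if (is.null(ids)) ids <- paste0("patient", seq_along(pk_models))
  rows <- list()
  for (i in seq_along(pk_models)) {
    for (j in seq_along(phi_values)) {
      phi <- phi_values[j]
      prob <- control_problem(pk_models[[i]], cost = "burden_auc",
                              days = days, doses_per_day = doses_per_day,
                              w1 = phi, w2 = 1, pd = pd_list[[i]],
                              leukemia = leukemia, k = k)
      res <- optimize_schedule(prob, config,
                               seed = seed + 1000L * (i - 1L) + j - 1L)
      cbar <- time_average_concentration(res$schedule, pk_models[[i]])
      rows[[length(rows) + 1L]] <- data.frame(
        patient = ids[i], phi = phi,
        auc = auc(res$schedule, pk_models[[i]]),
        mean_concentration = cbar,
        efficacy_at_mean = efficacy(cbar, pd_list[[i]]),
        best_cost = res$best_cost)
    }
  }
  do.call(rbind, rows)
}
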