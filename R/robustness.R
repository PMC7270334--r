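# Robustness analyses for a fixed optimized schedule: intra-patient
# variability (independent uniform noise on one PK parameter at every
# evaluation time point) and systematic parameter errors (a constant offset
# in the absorption rate).

# grid-based evaluation of a problem's cost from precomputed concentrations;
# the noise studies use this consistently for the noisy and noise-free cases
# so the relative cost change is exactly zero at zero noise
.grid_cost <- function(problem, C, t_fin) {
  switch(problem$cost,
    lower_bound = mean(ifelse(C >= problem$target, C - problem$target,
                              problem$g_penalty)) * t_fin,
    optimal_target = mean(abs(C - problem$target)) * t_fin,
    burden_auc = {
      lam0 <- (2 * problem$leukemia$a1 - 1) * problem$leukemia$p1
      k <- if (inherits(problem$k, "conversion_constant")) problem$k$k
           else problem$k
      mean(problem$w1 * log10(exp(1)) *
             (lam0 - k * efficacy(C, problem$pd)) +
           problem$w2 * C) * t_fin / HOURS_PER_DAY
    })
}

# closed-form concentration where one PK parameter is multiplied by a
# per-grid-point factor (independent noise at every evaluation time)
.concentration_perturbed <- function(grid, schedule, pk, parameter, mult) {
  ka <- pk$ka; cl <- pk$clearance; v <- pk$volume
  kav <- rep(ka, length(grid)); clv <- rep(cl, length(grid))
  vv <- rep(v, length(grid))
  switch(parameter,
         ka = { kav <- ka * mult },
         CL = { clv <- cl * mult },
         v = { vv <- v * mult },
         stop_invalid("parameter must be one of ka, CL, v"))
  kev <- clv / vv
  out <- numeric(length(grid))
  for (i in seq_along(schedule$times)) {
    dt <- grid - schedule$times[i]
    m <- dt >= 0
    if (!any(m)) next
    out[m] <- out[m] + pk$f * schedule$doses[i] * kav[m] /
      (vv[m] * (kav[m] - kev[m])) *
      (exp(-kev[m] * dt[m]) - exp(-kav[m] * dt[m]))
  }
  out
}

#' Noise specification for the intra-patient variability study
#'
#' @param parameter PK parameter to perturb: `"ka"`, `"CL"` or `"v"`.
#' @param sigmas relative half-widths of the uniform noise (each in
#'   \[0, 1)); the perturbation at each evaluation time is an independent
#'   draw from `U(-sigma, sigma)` applied multiplicatively.
#' @param n_simulations simulations per sigma (the reference study uses
#'   700; tests scale down).
#' @param seed integer seed.
#' @param grid_minutes evaluation grid step in minutes.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(parameter = c("ka", "CL", "v"),
                       sigmas = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                       n_simulations = 700, seed = 1, grid_minutes = 5) {
  parameter <- match.arg(parameter)
  if (any(sigmas < 0) || any(sigmas >= 1))
    stop_invalid("sigmas must lie in [0, 1)")
  if (n_simulations < 1) stop_invalid("n_simulations must be >= 1")
  structure(list(parameter = parameter, sigmas = sigmas,
                 n_simulations = as.integer(n_simulations),
                 seed = seed, grid_minutes = grid_minutes),
            class = "noise_spec")
}

#' Intra-patient variability study on a fixed schedule
#'
#' For each noise level sigma, runs `n_simulations` evaluations of the
#' schedule's cost in which the chosen PK parameter is perturbed by an
#' independent multiplicative uniform draw `U(-sigma, sigma)` at every
#' evaluation time point, and summarizes the relative cost change
#' `Delta L / L0` (mean and SD) against the noise-free cost computed on the
#' same grid. The mean trend is then fitted with the quadratic law
#' `b + a sigma^2` by least squares.
#'
#' @param schedule a [dose_schedule()] (typically an optimized one) or a
#'   `dose_optim` result.
#' @param problem the [control_problem()] whose cost is evaluated; taken
#'   from the `dose_optim` object if omitted.
#' @param noise a [noise_spec()].
#' @return an object of class `robustness_result`: data.frame `table`
#'   (sigma, delta_mean, delta_sd), `quad_fit` (a, b), `quad_r_squared`,
#'   `L0`, plus the spec.
#' @export
intra_patient_noise_study <- function(schedule, problem = NULL,
                                      noise = noise_spec()) {
  if (inherits(schedule, "dose_optim")) {
    if (is.null(problem)) problem <- schedule$problem
    schedule <- schedule$schedule
  }
  stopifnot(inherits(schedule, "dose_schedule"),
            inherits(problem, "control_problem"),
            inherits(noise, "noise_spec"))
  pk <- problem$pk
  grid <- seq(schedule$t_in, schedule$t_fin, by = noise$grid_minutes / 60)
  t_fin <- schedule$t_fin - schedule$t_in
  L0 <- .grid_cost(problem, concentration(grid, schedule, pk), t_fin)

  rows <- with_seed(noise$seed, {
    lapply(noise$sigmas, function(sig) {
      if (sig == 0) return(data.frame(sigma = 0, delta_mean = 0,
                                      delta_sd = 0))
      dl <- vapply(seq_len(noise$n_simulations), function(s) {
        mult <- 1 + stats::runif(length(grid), -sig, sig)
        C <- .concentration_perturbed(grid, schedule, pk, noise$parameter,
                                      mult)
        .grid_cost(problem, C, t_fin) / L0 - 1
      }, numeric(1))
      data.frame(sigma = sig, delta_mean = mean(dl), delta_sd = stats::sd(dl))
    })
  })
  tab <- do.call(rbind, rows)

  if (nrow(tab) >= 2) {
    fit <- stats::lm(delta_mean ~ I(sigma^2), data = tab)
    co <- stats::coef(fit)
    v <- stats::var(tab$delta_mean)
    r2 <- if (is.finite(v) && v > 0) summary(fit)$r.squared else NA_real_
  } else {
    co <- c(NA_real_, NA_real_)
    r2 <- NA_real_
  }
  structure(list(table = tab,
                 quad_fit = c(a = unname(co[2]), b = unname(co[1])),
                 quad_r_squared = r2, L0 = L0,
                 parameter = noise$parameter, noise = noise),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("Intra-patient noise study on %s (%d simulations per sigma)\n",
              x$parameter, x$noise$n_simulations))
  print(x$table, row.names = FALSE)
  cat(sprintf("  quadratic fit dL/L0 = %.4g + %.4g sigma^2 (R^2 = %.3f)\n",
              x$quad_fit["b"], x$quad_fit["a"], x$quad_r_squared))
  invisible(x)
}

#' @export
plot.robustness_result <- function(x, ...) {
  graphics::plot(x$table$sigma, x$table$delta_mean, pch = 19,
                 xlab = "noise half-width sigma", ylab = "mean dL/L0", ...)
  ss <- seq(0, max(x$table$sigma), length.out = 100)
  graphics::lines(ss, x$quad_fit["b"] + x$quad_fit["a"] * ss^2, col = "red")
  invisible(x)
}

#' Systematic-error study on a fixed schedule
#'
#' Evaluates the cost of a schedule optimized at nominal PK parameters when
#' the absorption rate at evaluation time is `ka' = ka (1 + delta)`, over a
#' grid of relative errors, and reports the relative cost change
#' `Delta L / L0`. Deterministic given the schedule and grid.
#'
#' @param schedule a [dose_schedule()] or `dose_optim` result.
#' @param problem the [control_problem()]; taken from the `dose_optim`
#'   object if omitted.
#' @param deltas relative errors `delta_ka / ka` (default a 25-point grid on
#'   \[-0.3, 0.3\]).
#' @return a data.frame with columns `delta`, `cost`, `delta_cost`
#'   (relative), with attribute `L0`.
#' @export
systematic_error_study <- function(schedule, problem = NULL,
                                   deltas = seq(-0.3, 0.3,
                                                length.out = 25)) {
  if (inherits(schedule, "dose_optim")) {
    if (is.null(problem)) problem <- schedule$problem
    schedule <- schedule$schedule
  }
  stopifnot(inherits(schedule, "dose_schedule"),
            inherits(problem, "control_problem"))
  pk <- problem$pk
  L0 <- .problem_cost(problem, schedule)
  cost <- vapply(deltas, function(d) {
    pk2 <- pk
    pk2$ka <- pk$ka * (1 + d)
    pk2$ke <- pk2$clearance / pk2$volume
    prob2 <- problem
    prob2$pk <- pk2
    .problem_cost(prob2, schedule)
  }, numeric(1))
  out <- data.frame(delta = deltas, cost = cost,
                    delta_cost = cost / L0 - 1)
  attr(out, "L0") <- L0
  out
}
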