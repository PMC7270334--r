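test_that("clearance and volume follow the covariate relations", {
  co <- toy_coeffs()
  m <- patient_record("m", age = co$age_mean, sex = "M",
                      body_weight = co$bw_mean)
  f <- patient_record("f", age = co$age_mean, sex = "F",
                      body_weight = co$bw_mean)
  # at the population means the deviation terms vanish
  expect_equal(clearance_from_covariates(m, co), co$theta_a + co$theta_2)
  expect_equal(clearance_from_covariates(f, co), co$theta_a - co$theta_2)
  expect_equal(volume_from_covariates(m, co), co$theta_b + co$theta_4)
  expect_equal(volume_from_covariates(f, co), co$theta_b - co$theta_4)
  expect_equal(mean(c(volume_from_covariates(m, co),
                      volume_from_covariates(f, co))), co$theta_b)

  # arbitrary patient against direct arithmetic
  p <- patient_record("p", age = 61, sex = "F", body_weight = 58)
  expect_equal(
    clearance_from_covariates(p, co),
    co$theta_a + co$theta_1 * (58 - 72) / 72 - co$theta_2 +
      co$theta_3 * (61 - 48) / 48)

  # implausible covariates must error, naming the patient
  bad <- pk_coefficients(theta_a = 0.1, theta_b = 300, theta_1 = 50,
                         theta_2 = 0.1, theta_3 = 0, theta_4 = 50,
                         bw_mean = 72, age_mean = 48, ka = 0.5, f = 0.9)
  expect_error(clearance_from_covariates(p, bad), "non-positive clearance")
})

test_that("body-weight imputation is a piecewise-constant table lookup", {
  # two ages in the same bin give the same weight
  expect_identical(impute_body_weight(42, "M"), impute_body_weight(48, "M"))
  # male vs female differ at the same age
  expect_false(impute_body_weight(45, "M") == impute_body_weight(45, "F"))
  # out-of-range ages clamp with a warning
  expect_warning(bw <- impute_body_weight(10, "M"), "clamped")
  expect_identical(bw, impute_body_weight(18, "M"))
  # a record without weight imputes it
  p <- patient_record("x", age = 35, sex = "F")
  expect_identical(p$body_weight, impute_body_weight(35, "F"))
})

test_that("concentration is causal, superposed and dose-linear", {
  pk <- avg_pk()
  sch <- dose_schedule(c(0, 24, 48), c(400, 600, 200), t_fin = 96)
  empty <- dose_schedule(numeric(0), numeric(0), t_in = 0, t_fin = 96)
  tt <- seq(0, 96, by = 0.25)

  expect_identical(concentration(tt, empty, pk), rep(0, length(tt)))
  late <- dose_schedule(c(10, 24), c(400, 400), t_fin = 96)
  expect_identical(concentration(c(0, 5, 9.99), late, pk), rep(0, 3))

  # superposition: the multi-dose profile is the sum of single-dose profiles
  singles <- lapply(1:3, function(i)
    dose_schedule(sch$times[i], sch$doses[i], t_in = 0, t_fin = 96))
  summed <- Reduce(`+`, lapply(singles, concentration, t = tt, pk = pk))
  expect_equal(concentration(tt, sch, pk), summed, tolerance = 1e-12)

  # dose linearity: scaling all doses scales C and AUC
  sch2 <- dose_schedule(sch$times, 2 * sch$doses, t_fin = 96)
  expect_equal(concentration(tt, sch2, pk), 2 * concentration(tt, sch, pk),
               tolerance = 1e-12)
  expect_equal(auc(sch2, pk), 2 * auc(sch, pk), tolerance = 1e-12)

  # non-negativity over random schedules
  set.seed(42)
  for (i in 1:5) {
    times <- sort(runif(6, 0, 300))
    schr <- dose_schedule(times, runif(6, 0, 800), t_in = 0, t_fin = 336)
    expect_true(all(concentration(seq(0, 336, by = 0.5), schr, pk) >= 0))
  }
})

test_that("closed form matches the ODE oracle on a multi-dose profile", {
  pk <- avg_pk()
  sch <- standard_schedule(7, daily_dose = 400, doses_per_day = 3)
  grid <- seq(0, sch$t_fin, by = 0.25)
  cf <- concentration(grid, sch, pk)
  ode <- ode_concentration(grid, sch, pk)
  expect_lt(max(abs(cf - ode)) / max(cf), 1e-6)
})

test_that("degenerate ka == ke uses the continuous limit form", {
  co <- toy_coeffs()
  p <- average_patient("M", co)
  pk <- pk_model(p, co, clearance = co$ka * 100, volume = 100)  # ke == ka
  expect_true(abs(pk$ka - pk$ke) < 1e-15)
  sch <- dose_schedule(0, 400, t_fin = 48)
  tt <- seq(0.5, 48, by = 0.5)
  direct <- pk$f * 400 * pk$ka / pk$volume * tt * exp(-pk$ka * tt)
  expect_equal(concentration(tt, sch, pk), direct, tolerance = 1e-12)
  # and the nearby non-degenerate closed form is continuous in ka
  pk2 <- pk_model(p, co, clearance = co$ka * 100 * (1 + 1e-7),
                  volume = 100)
  expect_equal(concentration(tt, sch, pk2), direct, tolerance = 1e-5)
  # the exact AUC limit form integrates to f * D / CL
  expect_equal(auc(sch, pk, 0, Inf), pk$f * 400 / pk$clearance,
               tolerance = 1e-12)
})

test_that("AUC is exact: infinite-horizon limit, additivity, quadrature", {
  pk <- avg_pk()
  one <- dose_schedule(0, 400, t_fin = 24)
  # single-dose total exposure f * D / CL
  expect_equal(auc(one, pk, 0, Inf), pk$f * 400 / pk$clearance,
               tolerance = 1e-8)
  # multi-dose AUC against adaptive quadrature on the closed form
  sch <- dose_schedule(c(0, 24, 48), c(400, 600, 200), t_fin = 96)
  q <- integrate(function(t) concentration(t, sch, pk), 0, 96,
                 rel.tol = 1e-10, subdivisions = 500L)$value
  expect_equal(auc(sch, pk, 0, 96), q, tolerance = 1e-8)
  expect_error(auc(sch, pk, 50, 10), "t0 must be <")
  empty <- dose_schedule(numeric(0), numeric(0), t_in = 0, t_fin = 96)
  expect_identical(auc(empty, pk, 0, 96), 0)
})

test_that("time-average concentration is AUC over the window", {
  pk <- avg_pk()
  sch <- standard_schedule(40)
  expect_equal(time_average_concentration(sch, pk),
               auc(sch, pk, 0, 960) / 960, tolerance = 1e-12)
  # the 40-day standard-therapy average sits near 1 mg/L, the clinical
  # steady-state reference for 400 mg/day
  expect_gt(time_average_concentration(sch, pk), 0.8)
  expect_lt(time_average_concentration(sch, pk), 1.3)
})

test_that("fraction of time above target matches a root-finding oracle", {
  pk <- avg_pk()
  sch <- dose_schedule(0, 400, t_fin = 48)
  prof <- concentration_profile(sch, pk)
  expect_identical(fraction_time_above(prof, 0), 1)
  expect_identical(fraction_time_above(prof, max(prof$values) + 1), 0)

  # single-dose profile crosses a mid-level threshold exactly twice;
  # compare the measure with bisection roots of the closed form
  thr <- 0.5 * max(prof$values)
  f <- function(t) concentration(t, sch, pk) - thr
  tmax <- prof$grid[which.max(prof$values)]
  r1 <- uniroot(f, c(1e-9, tmax), tol = 1e-12)$root
  r2 <- uniroot(f, c(tmax, 48), tol = 1e-12)$root
  expect_equal(fraction_time_above(prof, thr), (r2 - r1) / 48,
               tolerance = 2 / (60 * 48))  # within grid resolution
})
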