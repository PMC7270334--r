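test_that("analytic leukemia trajectory solves the compartment ODEs", {
  # initial condition and decoupled-compartment special cases
  par <- leukemia_params(a1 = 0.87, p1 = 0.45, d1 = 0.4, d2 = 1)
  tr0 <- leukemia_trajectory(par, 100, 50, 0)
  expect_equal(c(tr0$l1, tr0$l2), c(100, 50))
  dec <- leukemia_params(a1 = 1, p1 = 0.45, d1 = 0.4, d2 = 1)  # gamma = 0
  expect_identical(leukemia_trajectory(dec, 10, 0, c(1, 5, 10))$l2,
                   rep(0, 3))

  # random parameter draws against the ODE oracle, including tau == lambda
  set.seed(7)
  for (i in 1:12) {
    a1 <- runif(1, 0.5, 1); p1 <- runif(1, 0.1, 1)
    d1 <- runif(1, 0.05, 1.2)
    par <- leukemia_params(a1, p1, d1, d2 = runif(1, 0.1, 2))
    if (i > 9) par <- leukemia_params(a1, p1, d1, d2 = -par$lambda)
    times <- seq(0, 30, by = 1)
    tr <- leukemia_trajectory(par, 1000, 500, times)
    ode <- ode_leukemia(par, 1000, 500, times)
    scale <- pmax(abs(ode[, "l1"]), 1e-9)
    expect_lt(max(abs(tr$l1 - ode[, "l1"]) / scale), 1e-6)
    scale2 <- pmax(abs(ode[, "l2"]), 1e-9)
    expect_lt(max(abs(tr$l2 - ode[, "l2"]) / scale2), 1e-6)
  }
})

test_that("biphasic fit recovers a noiseless two-line decay exactly", {
  spec <- burden_spec(slope1 = -0.01, slope2 = -0.001, breakpoint = 300,
                      noise_sd = 0, duration = 2700)
  s <- generate_burden_series(spec)
  fit <- fit_biphasic(s)
  expect_equal(fit$slope1, -0.01, tolerance = 1e-10)
  expect_equal(fit$slope2, -0.001, tolerance = 1e-10)
  expect_lt(abs(fit$breakpoint - 300), 1)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("single-line data yield near-equal slopes and scaling shifts only intercepts", {
  t <- seq(0, 900, by = 90)
  y <- 10^(-0.003 * t)                       # one line in log10 scale
  s <- burden_series("one-line", t, y)
  fit <- fit_biphasic(s)
  expect_equal(fit$slope1, fit$slope2, tolerance = 1e-8)
  expect_equal(fit$slope1, -0.003, tolerance = 1e-10)

  # vertical scaling of the burden moves intercepts, not slopes
  spec <- burden_spec(noise_sd = 0.1, seed = 11)
  s1 <- generate_burden_series(spec)
  s2 <- burden_series(s1$patient_id, s1$times, 7.3 * s1$burden)
  f1 <- fit_biphasic(s1); f2 <- fit_biphasic(s2)
  expect_equal(f1$slope1, f2$slope1, tolerance = 1e-10)
  expect_equal(f1$slope2, f2$slope2, tolerance = 1e-10)
  expect_equal(f2$intercept2 - f1$intercept2, log10(7.3),
               tolerance = 1e-10)
})

test_that("two-line fit is never worse than the single-line fit", {
  set.seed(3)
  for (i in 1:5) {
    s <- generate_burden_series(burden_spec(noise_sd = 0.2, seed = i))
    f1 <- fit_biphasic(s, segments = 1)
    f2 <- fit_biphasic(s, segments = 2)
    expect_gte(f2$r_squared, f1$r_squared - 1e-12)
  }
})

test_that("model selection and degenerate inputs behave", {
  s <- generate_burden_series(burden_spec(noise_sd = 0, seed = 1))
  auto <- fit_biphasic(s, segments = "auto")
  expect_s3_class(auto, "biphasic_fit")
  # exact two-line data: adjusted R^2 picks two segments
  expect_identical(auto$segments, 2L)
  # continuity-constrained variant reproduces the continuous generator
  fc <- fit_biphasic(s, continuous = TRUE)
  expect_equal(fc$slope2, -0.001, tolerance = 1e-8)
  # too few points for a two-line fit
  few <- burden_series("few", c(0, 90, 180), c(1, 0.1, 0.05))
  expect_error(fit_biphasic(few), "at least 4 points")
  expect_error(burden_series("two", c(0, 90), c(1, 0.1)),
               "at least 3 points")
})

test_that("CSC death rate inverts the log10 slope relation", {
  # zero slope: steady CSC pool, d1 = (2 a1 - 1) p1
  expect_equal(csc_death_rate(0), (2 * 0.87 - 1) * 0.45)
  # unit conversion: beta shifts by -log10(e) * x raise d1 by x
  expect_equal(csc_death_rate(-log10(exp(1)) * 0.1),
               (2 * 0.87 - 1) * 0.45 + 0.1)
  # algebraic round trip on random parameters
  set.seed(5)
  for (i in 1:20) {
    a1 <- runif(1, 0.5, 1); p1 <- runif(1, 0.1, 1)
    d1 <- runif(1, 0.01, 1) + (2 * a1 - 1) * p1
    beta <- log10(exp(1)) * ((2 * a1 - 1) * p1 - d1)
    expect_equal(csc_death_rate(beta, a1, p1), d1, tolerance = 1e-12)
  }
  # a growing CSC pool under therapy is flagged as implausible
  expect_error(csc_death_rate(0.2), "implausible slope")
})
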