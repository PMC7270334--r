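# Shared fixtures and independent oracles for the test suite.

avg_pk <- function(sex = "M") pk_model(average_patient(sex))

# a small optimizer budget for tests that exercise the search machinery
# without needing a converged schedule
small_config <- function(...) {
  optimizer_config(n_frequencies = 3, evals_per_superiteration = 60, ...)
}

# numerical ODE oracle for the one-compartment oral-absorption model:
# integrates dG/dt = -ka G, dB/dt = ka G - CL B / v with dose impulses
# f * D added to the gut compartment at the dose times; returns C = B / v
ode_concentration <- function(grid, schedule, pk) {
  rhs <- function(t, y, p) {
    list(c(-pk$ka * y[1], pk$ka * y[1] - pk$clearance * y[2] / pk$volume))
  }
  ev <- data.frame(var = "G", time = schedule$times,
                   value = pk$f * schedule$doses, method = "add")
  times <- sort(unique(c(grid, schedule$times)))
  out <- deSolve::lsoda(c(G = 0, B = 0), times, rhs, parms = NULL,
                        events = list(data = ev),
                        rtol = 1e-10, atol = 1e-12)
  approx(out[, "time"], out[, "B"] / pk$volume, xout = grid)$y
}

# numerical oracle for the two-compartment leukemia model
ode_leukemia <- function(params, l1_0, l2_0, times) {
  rhs <- function(t, y, p) {
    list(c(params$lambda * y[1],
           params$gamma * y[1] + params$tau * y[2]))
  }
  out <- deSolve::lsoda(c(l1 = l1_0, l2 = l2_0), times, rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-14, maxsteps = 50000)
  out
}

# dense-grid Riemann (midpoint) oracle for cost integrals
riemann <- function(f, a, b, n = 200000L) {
  h <- (b - a) / n
  mid <- a + (seq_len(n) - 0.5) * h
  sum(f(mid)) * h
}

# arbitrary covariate coefficient set for oracle arithmetic, distinct from
# the bundled defaults
toy_coeffs <- function() {
  pk_coefficients(theta_a = 12, theta_b = 300, theta_1 = 4, theta_2 = 1.5,
                  theta_3 = -2, theta_4 = 50, bw_mean = 72, age_mean = 48,
                  ka = 0.5, f = 0.9)
}
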