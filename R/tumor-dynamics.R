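# Two-compartment leukemia population dynamics and biphasic log-linear
# fitting of longitudinal tumor-burden (BCR-ABL ratio) series.
#
# The model tracks cancer stem cells (CSC, l1) feeding a differentiated
# compartment (l2):
#   dl1/dt = lambda l1,     lambda = (2 a1 - 1) p1 - d1
#   dl2/dt = gamma l1 + tau l2,  gamma = 2 (1 - a1) p1,  tau = -d2
# Under successful therapy the late log10-linear decay of the burden series
# reflects the CSC compartment alone, so its slope beta satisfies
# beta = log10(e) * lambda, which is inverted to estimate the CSC death
# rate d1.

#' Two-compartment leukemia model parameters
#'
#' @param a1 CSC self-renewal probability, in \[0, 1\].
#' @param p1 CSC division rate (1/day).
#' @param d1 CSC death rate (1/day).
#' @param d2 differentiated-cell death rate (1/day).
#' @return an object of class `leukemia_params` with derived rates
#'   `lambda = (2 a1 - 1) p1 - d1` (net CSC growth), `gamma = 2 (1 - a1) p1`
#'   (differentiation flux) and `tau = -d2`.
#' @export
leukemia_params <- function(a1 = 0.87, p1 = 0.45, d1 = 0.1, d2 = 1) {
  if (a1 < 0 || a1 > 1) stop_invalid("a1 must lie in [0, 1]")
  check_positive(p1, "p1")
  structure(list(a1 = a1, p1 = p1, d1 = d1, d2 = d2,
                 lambda = (2 * a1 - 1) * p1 - d1,
                 gamma = 2 * (1 - a1) * p1,
                 tau = -d2),
            class = "leukemia_params")
}

#' Analytic trajectory of the two-compartment leukemia model
#'
#' Closed-form solution of the linear system:
#' `l1(t) = l1_0 exp(lambda t)` and
#' `l2(t) = exp(tau t) l2_0 + gamma l1_0 (exp(tau t) - exp(lambda t)) /
#'  (tau - lambda)`, with the removable singularity at `tau == lambda`
#' replaced by its limit `l2(t) = exp(tau t) l2_0 + gamma l1_0 t
#' exp(lambda t)`.
#'
#' @param params a [leukemia_params()] object.
#' @param l1_0,l2_0 initial compartment sizes (>= 0).
#' @param t time(s) in days (vectorized).
#' @return a data.frame with columns `t`, `l1`, `l2`.
#' @export
leukemia_trajectory <- function(params, l1_0, l2_0, t) {
  stopifnot(inherits(params, "leukemia_params"), l1_0 >= 0, l2_0 >= 0)
  lam <- params$lambda; tau <- params$tau; gam <- params$gamma
  l1 <- l1_0 * exp(lam * t)
  if (abs(tau - lam) < 1e-12 * max(abs(tau), abs(lam), 1)) {
    l2 <- exp(tau * t) * l2_0 + gam * l1_0 * t * exp(lam * t)
  } else {
    l2 <- exp(tau * t) * l2_0 + gam * l1_0 * (exp(tau * t) - exp(lam * t)) /
      (tau - lam)
  }
  data.frame(t = t, l1 = l1, l2 = l2)
}

#' Create a tumor-burden series
#'
#' Longitudinal BCR-ABL ratio measurements for one patient. Ratios must be
#' strictly positive (the fit operates in log10 scale) and may exceed 1 on
#' the international scale.
#'
#' @param patient_id character identifier.
#' @param times measurement times in days, non-negative and increasing.
#' @param burden BCR-ABL ratios (> 0), same length as `times`.
#' @return an object of class `burden_series`.
#' @export
burden_series <- function(patient_id, times, burden) {
  if (length(times) != length(burden))
    stop_invalid("times and burden must have equal length")
  if (length(times) < 3)
    stop_invalid("burden series needs at least 3 points (got %d)", length(times))
  if (any(diff(times) <= 0)) stop_invalid("times must be increasing")
  if (any(times < 0)) stop_invalid("times must be non-negative")
  if (any(burden <= 0)) stop_invalid("burden must be positive (log10 scale)")
  structure(list(patient_id = as.character(patient_id),
                 times = as.numeric(times), burden = as.numeric(burden)),
            class = "burden_series")
}

# two-line least squares at a given split; returns pooled SSE and the fits
.split_fit <- function(t, y, left) {
  f1 <- stats::lm.fit(cbind(1, t[left]), y[left])
  f2 <- stats::lm.fit(cbind(1, t[!left]), y[!left])
  list(sse = sum(f1$residuals^2) + sum(f2$residuals^2),
       c1 = f1$coefficients, c2 = f2$coefficients)
}

#' Fit a biphasic (two-line) log10 decay to a tumor-burden series
#'
#' Fits `log10(burden)` with two straight lines with distinct slopes,
#' scanning every candidate split time on a 1-day grid and keeping the split
#' whose combined (pooled-residual) R-squared is best; ties are broken by
#' the earliest split. The two segments are fitted independently (four free
#' parameters) unless `continuous = TRUE`, which constrains them to meet at
#' the split. The reported `breakpoint` is the intersection time of the two
#' fitted lines (the natural estimate of where the decay changes phase);
#' `split_day` is the scanned split itself. `segments` may be 1, 2 or 3, or
#' `"auto"` to choose by adjusted R-squared; the canonical responder model
#' is 2, with the rightmost slope reflecting pure cancer-stem-cell decay.
#'
#' @param series a [burden_series()], or a data.frame with columns `day` (or
#'   `times`) and `bcr_abl_ratio` (or `burden`).
#' @param segments number of lines (1, 2 or 3) or `"auto"`.
#' @param continuous logical; constrain adjacent segments to meet at the
#'   split time.
#' @return an object of class `biphasic_fit` with components `slope1`,
#'   `slope2` (log10 units/day, leftmost and rightmost), `intercept1`,
#'   `intercept2`, `breakpoint` (days), `split_day`, `r_squared`,
#'   `slope_se` (per-segment slope standard errors), `segments`, `data`.
#' @examples
#' s <- generate_burden_series(burden_spec(noise_sd = 0, seed = 1))
#' fit <- fit_biphasic(s)
#' coef(fit)
#' @export
fit_biphasic <- function(series, segments = 2, continuous = FALSE) {
  if (is.data.frame(series)) {
    tcol <- intersect(c("day", "times", "time_d"), names(series))[1]
    bcol <- intersect(c("bcr_abl_ratio", "burden"), names(series))[1]
    if (is.na(tcol) || is.na(bcol))
      stop_invalid("data.frame must have day/times and bcr_abl_ratio/burden columns")
    id <- if ("patient_id" %in% names(series)) series$patient_id[1] else "patient"
    series <- burden_series(id, series[[tcol]], series[[bcol]])
  }
  stopifnot(inherits(series, "burden_series"))
  t <- series$times
  y <- log10(series$burden)
  n <- length(t)
  sst <- sum((y - mean(y))^2)

  if (identical(segments, "auto")) {
    cands <- lapply(c(1, 2, 3), function(k)
      tryCatch(fit_biphasic(series, segments = k, continuous = continuous),
               error = function(e) NULL))
    cands <- Filter(Negate(is.null), cands)
    adj <- vapply(cands, function(f) {
      p <- 2 * f$segments - if (continuous) (f$segments - 1) else 0
      1 - (1 - f$r_squared) * (n - 1) / max(n - p, 1)
    }, numeric(1))
    return(cands[[which.max(adj)]])
  }

  if (segments == 1) {
    fit <- stats::lm(y ~ t)
    sse <- sum(stats::residuals(fit)^2)
    co <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))[2]
    return(structure(list(
      slope1 = unname(co[2]), slope2 = unname(co[2]),
      intercept1 = unname(co[1]), intercept2 = unname(co[1]),
      breakpoint = NA_real_, split_day = NA_real_,
      r_squared = if (sst > 0) 1 - sse / sst else 1,
      slope_se = c(se, se), segments = 1L, continuous = continuous,
      data = series), class = "biphasic_fit"))
  }
  if (segments == 2) return(.fit_two_lines(series, t, y, sst, continuous))
  if (segments == 3) return(.fit_three_lines(series, t, y, sst, continuous))
  stop_invalid("segments must be 1, 2, 3 or 'auto'")
}

.fit_two_lines <- function(series, t, y, sst, continuous) {
  n <- length(t)
  if (n < 4)
    stop_invalid("two-line fit needs at least 4 points (got %d)", n)
  # candidate splits on a 1-day grid; each segment must keep >= 2 points
  lo <- ceiling(t[2])            # first split leaving 2 points on the left
  hi <- floor(t[n - 1])          # last split leaving 2 points on the right
  cands <- seq(lo, hi, by = 1)
  cands <- cands[vapply(cands, function(bp)
    sum(t <= bp) >= 2 && sum(t > bp) >= 2, logical(1))]
  if (!length(cands))
    stop_invalid("no candidate split leaves >= 2 points per segment: fit infeasible")

  best <- NULL
  for (bp in cands) {
    left <- t <= bp
    if (continuous) {
      # shared value at bp: y = a + b1*(t-bp) left, a + b2*(t-bp) right
      X <- cbind(1, ifelse(left, t - bp, 0), ifelse(left, 0, t - bp))
      f <- stats::lm.fit(X, y)
      sse <- sum(f$residuals^2)
      cf <- f$coefficients
      c1 <- c(cf[1] - cf[2] * bp, cf[2])
      c2 <- c(cf[1] - cf[3] * bp, cf[3])
      res <- list(sse = sse, c1 = c1, c2 = c2)
    } else {
      res <- .split_fit(t, y, left)
    }
    if (is.null(best) || res$sse < best$sse - 1e-12) {
      best <- res
      best$bp <- bp
      best$left <- left
    }
  }

  # slope standard errors from the two segment regressions
  se_seg <- function(mask, cf) {
    tt <- t[mask]; yy <- y[mask]
    k <- length(tt)
    if (k <= 2) return(NA_real_)
    res <- yy - (cf[1] + cf[2] * tt)
    sig2 <- sum(res^2) / (k - 2)
    sqrt(sig2 / sum((tt - mean(tt))^2))
  }
  slope1 <- unname(best$c1[2]); slope2 <- unname(best$c2[2])
  int1 <- unname(best$c1[1]); int2 <- unname(best$c2[1])
  # breakpoint = intersection of the two fitted lines; fall back to the
  # split day when the lines are (near-)parallel
  bp_x <- if (abs(slope1 - slope2) > 1e-12) (int2 - int1) / (slope1 - slope2)
          else best$bp
  if (!is.finite(bp_x) || bp_x < t[1] || bp_x > t[length(t)]) bp_x <- best$bp
  structure(list(
    slope1 = slope1, slope2 = slope2, intercept1 = int1, intercept2 = int2,
    breakpoint = bp_x, split_day = best$bp,
    r_squared = if (sst > 0) 1 - best$sse / sst else 1,
    slope_se = c(se_seg(best$left, best$c1), se_seg(!best$left, best$c2)),
    segments = 2L, continuous = continuous, data = series),
    class = "biphasic_fit")
}

.fit_three_lines <- function(series, t, y, sst, continuous) {
  n <- length(t)
  if (n < 6) stop_invalid("three-line fit needs at least 6 points")
  rng <- range(t)
  step <- max(1, round(diff(rng) / 80))
  cands <- seq(ceiling(rng[1]), floor(rng[2]), by = step)
  best <- NULL
  for (b1 in cands) for (b2 in cands[cands > b1]) {
    g <- cut(t, c(-Inf, b1, b2, Inf), labels = FALSE)
    if (any(tabulate(g, 3) < 2)) next
    sse <- 0; cfs <- vector("list", 3)
    for (k in 1:3) {
      f <- stats::lm.fit(cbind(1, t[g == k]), y[g == k])
      sse <- sse + sum(f$residuals^2)
      cfs[[k]] <- f$coefficients
    }
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(sse = sse, cfs = cfs, b1 = b1, b2 = b2)
  }
  if (is.null(best)) stop_invalid("three-line fit infeasible")
  structure(list(
    slope1 = unname(best$cfs[[1]][2]), slope2 = unname(best$cfs[[3]][2]),
    intercept1 = unname(best$cfs[[1]][1]), intercept2 = unname(best$cfs[[3]][1]),
    breakpoint = best$b2, split_day = best$b1,
    mid = list(slope = unname(best$cfs[[2]][2]),
               intercept = unname(best$cfs[[2]][1])),
    r_squared = if (sst > 0) 1 - best$sse / sst else 1,
    slope_se = c(NA_real_, NA_real_),
    segments = 3L, continuous = continuous, data = series),
    class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf("Biphasic log10 decay fit (%d segment%s) for patient %s\n",
              x$segments, if (x$segments > 1) "s" else "", x$data$patient_id))
  cat(sprintf("  slope1 = %.5g, slope2 = %.5g log10/day\n", x$slope1, x$slope2))
  if (x$segments >= 2)
    cat(sprintf("  breakpoint = %.1f days (split scanned at day %g)\n",
                x$breakpoint, x$split_day))
  cat(sprintf("  R^2 = %.4f (pooled residuals, n = %d)\n",
              x$r_squared, length(x$data$times)))
  invisible(x)
}

#' @export
coef.biphasic_fit <- function(object, ...) {
  c(slope1 = object$slope1, intercept1 = object$intercept1,
    slope2 = object$slope2, intercept2 = object$intercept2,
    breakpoint = object$breakpoint)
}

#' @export
summary.biphasic_fit <- function(object, ...) {
  out <- list(fit = object,
              beta = object$slope2,
              beta_se = object$slope_se[2],
              d1 = tryCatch(csc_death_rate(object$slope2),
                            error = function(e) NA_real_))
  class(out) <- "summary.biphasic_fit"
  out
}

#' @export
print.summary.biphasic_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  rightmost slope beta = %.5g +/- %.2g log10/day\n",
              x$beta, x$beta_se))
  if (is.finite(x$d1))
    cat(sprintf("  implied CSC death rate d1 = %.4f 1/day (a1 = 0.87, p1 = 0.45)\n",
                x$d1))
  invisible(x)
}

#' @export
predict.biphasic_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) newtimes <- object$data$times
  if (object$segments == 1)
    return(object$intercept1 + object$slope1 * newtimes)
  if (object$segments == 3) {
    b1 <- object$split_day; b2 <- object$breakpoint
    ifelse(newtimes <= b1, object$intercept1 + object$slope1 * newtimes,
      ifelse(newtimes <= b2,
             object$mid$intercept + object$mid$slope * newtimes,
             object$intercept2 + object$slope2 * newtimes))
  } else {
    ifelse(newtimes <= object$breakpoint,
           object$intercept1 + object$slope1 * newtimes,
           object$intercept2 + object$slope2 * newtimes)
  }
}

#' @export
residuals.biphasic_fit <- function(object, ...) {
  log10(object$data$burden) - predict(object)
}

#' @export
plot.biphasic_fit <- function(x, ...) {
  t <- x$data$times
  graphics::plot(t, log10(x$data$burden), pch = 19,
                 xlab = "time [days]", ylab = "log10 BCR-ABL ratio", ...)
  tt <- seq(min(t), max(t), length.out = 400)
  graphics::lines(tt, predict(x, tt), col = "red")
  if (x$segments >= 2)
    graphics::abline(v = x$breakpoint, lty = 3)
  invisible(x)
}

#' Cancer-stem-cell death rate from the rightmost decay slope
#'
#' Inverts `beta = log10(e) * ((2 a1 - 1) p1 - d1)`: the late log10-linear
#' slope of the burden series is the net CSC growth rate in log10 units, so
#' `d1 = (2 a1 - 1) p1 - beta / log10(e)`. A decaying CSC population under
#' therapy requires `d1 > (2 a1 - 1) p1`, i.e. `beta < 0`.
#'
#' @param beta rightmost slope in log10 units/day.
#' @param a1 CSC self-renewal probability (default 0.87).
#' @param p1 CSC division rate in 1/day (default 0.45).
#' @return CSC death rate `d1` in 1/day (error if non-positive).
#' @export
csc_death_rate <- function(beta, a1 = 0.87, p1 = 0.45) {
  if (a1 < 0 || a1 > 1) stop_invalid("a1 must lie in [0, 1]")
  check_positive(p1, "p1")
  d1 <- (2 * a1 - 1) * p1 - beta / log10(exp(1))
  if (any(!is.finite(d1)) || any(d1 <= 0))
    stop_invalid("implausible slope beta = %g: implied CSC death rate %g <= 0",
                 beta[1], d1[1])
  d1
}
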