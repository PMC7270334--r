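# Seeded generators for demographic cohorts and tumor-burden series with the
# statistical structure the pipeline assumes: truncated-normal demographics
# and biphasic log10 decay with additive measurement noise at a fixed
# blood-draw interval.

#' Specification of a synthetic demographic cohort
#'
#' Defaults loosely mirror the shape of the CML case-study cohort
#' (male-dominated, middle-aged, sex-specific body-weight means around the
#' population averages); all are configurable — the generator is a study
#' fixture, not a reconstruction of any real cohort.
#'
#' @param n_patients cohort size (>= 1).
#' @param male_fraction expected fraction of males, in \[0, 1\].
#' @param age_mean,age_sd,age_range age distribution (years), truncated to
#'   `age_range`.
#' @param bw_mean_m,bw_mean_f,bw_sd,bw_range body-weight distributions per
#'   sex (kg), truncated to `bw_range`.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 22, male_fraction = 18 / 22,
                        age_mean = 50, age_sd = 12, age_range = c(18, 85),
                        bw_mean_m = 78, bw_mean_f = 66, bw_sd = 10,
                        bw_range = c(40, 140), seed = 1) {
  if (n_patients < 1) stop_invalid("n_patients must be >= 1")
  if (male_fraction < 0 || male_fraction > 1)
    stop_invalid("male_fraction must lie in [0, 1]")
  if (diff(age_range) < 0 || diff(bw_range) < 0)
    stop_invalid("ranges must be non-decreasing")
  structure(as.list(environment()), class = "cohort_spec")
}

# truncated normal by resampling; degenerate sd = 0 returns the mean
.rtrunc_norm <- function(n, mean, sd, range) {
  if (sd == 0) {
    if (mean < range[1] || mean > range[2])
      stop_invalid("unsatisfiable bounds: mean %g outside [%g, %g]",
                   mean, range[1], range[2])
    return(rep(mean, n))
  }
  if (stats::pnorm(range[2], mean, sd) - stats::pnorm(range[1], mean, sd) <
      1e-6)
    stop_invalid("unsatisfiable bounds for truncated normal")
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic demographic cohort
#'
#' Seeded, reproducible sampling of patient records: sex by a Bernoulli
#' draw, age and body weight from truncated normals (out-of-bounds draws are
#' resampled).
#'
#' @param spec a [cohort_spec()].
#' @return a list of [patient_record()] objects, named by id.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    male <- stats::runif(spec$n_patients) < spec$male_fraction
    age <- .rtrunc_norm(spec$n_patients, spec$age_mean, spec$age_sd,
                        spec$age_range)
    bw <- numeric(spec$n_patients)
    if (any(male))
      bw[male] <- .rtrunc_norm(sum(male), spec$bw_mean_m, spec$bw_sd,
                               spec$bw_range)
    if (any(!male))
      bw[!male] <- .rtrunc_norm(sum(!male), spec$bw_mean_f, spec$bw_sd,
                                spec$bw_range)
    out <- lapply(seq_len(spec$n_patients), function(i)
      patient_record(sprintf("syn-%03d", i), age = age[i],
                     sex = if (male[i]) "M" else "F", body_weight = bw[i]))
    names(out) <- vapply(out, `[[`, character(1), "id")
    out
  })
}

#' Specification of a synthetic tumor-burden series
#'
#' The generator emulates a treatment responder: log10 burden follows two
#' intersecting lines (a steep early decay and a shallower late decay that
#' reflects the cancer-stem-cell compartment), sampled at a fixed blood-draw
#' interval (default 90 days) with additive Gaussian noise in log10 scale.
#'
#' @param slope1,slope2 early and late slopes in log10 units/day (both
#'   negative for a responder, `slope1 < slope2 < 0`).
#' @param breakpoint day at which the two lines intersect.
#' @param initial_burden BCR-ABL ratio at day 0.
#' @param noise_sd additive noise SD in log10 units (>= 0).
#' @param sampling_interval days between measurements (default 90).
#' @param duration follow-up length in days.
#' @param seed integer seed.
#' @return an object of class `burden_spec`.
#' @export
burden_spec <- function(slope1 = -0.01, slope2 = -0.001, breakpoint = 300,
                        initial_burden = 1, noise_sd = 0.15,
                        sampling_interval = 90, duration = 2700, seed = 1) {
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  check_positive(sampling_interval, "sampling_interval")
  check_positive(duration, "duration")
  check_positive(initial_burden, "initial_burden")
  if (breakpoint <= 0 || breakpoint >= duration)
    stop_invalid("breakpoint must lie strictly inside (0, duration)")
  structure(as.list(environment()), class = "burden_spec")
}

#' Generate a synthetic tumor-burden series
#'
#' Samples the two-line log10 decay (continuous at the breakpoint) at
#' multiples of the sampling interval, adds independent Gaussian noise in
#' log10 scale, and returns positive BCR-ABL ratios.
#'
#' @param spec a [burden_spec()].
#' @param patient_id identifier for the series.
#' @return a [burden_series()].
#' @export
generate_burden_series <- function(spec = burden_spec(),
                                   patient_id = "syn-001") {
  stopifnot(inherits(spec, "burden_spec"))
  times <- seq(0, spec$duration, by = spec$sampling_interval)
  b0 <- log10(spec$initial_burden)
  logb <- ifelse(times <= spec$breakpoint,
                 b0 + spec$slope1 * times,
                 b0 + spec$slope1 * spec$breakpoint +
                   spec$slope2 * (times - spec$breakpoint))
  if (spec$noise_sd > 0)
    logb <- logb + with_seed(spec$seed,
                             stats::rnorm(length(times), 0, spec$noise_sd))
  burden_series(patient_id, times, 10^logb)
}

# ---- CSV / JSON interchange ------------------------------------------------

#' Read patient records from CSV or JSON
#'
#' CSV columns: `id, age, sex, body_weight` with `sex` in `{M, F}`; JSON: an
#' array of objects with the same keys. A missing `body_weight` is imputed
#' from the bundled age-by-sex table.
#'
#' @param path file path (`.csv` or `.json`).
#' @return a named list of [patient_record()] objects.
#' @export
read_patients <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("id", "age", "sex")
  if (!all(need %in% names(df)))
    stop_invalid("patient file must have columns id, age, sex")
  if (!"body_weight" %in% names(df)) df$body_weight <- NA_real_
  out <- list()
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      patient_record(df$id[i], df$age[i], df$sex[i],
                     if (is.na(df$body_weight[i])) NULL
                     else df$body_weight[i]),
      error = function(e)
        stop_invalid("row %d (id '%s'): %s", i, df$id[i],
                     conditionMessage(e)))
    out[[rec$id]] <- rec
  }
  out
}

#' Write patient records to CSV
#'
#' @param patients a list of [patient_record()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(patients, path) {
  df <- do.call(rbind, lapply(patients, function(p)
    data.frame(id = p$id, age = p$age, sex = p$sex,
               body_weight = p$body_weight)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read tumor-burden series from CSV
#'
#' Expects columns `patient_id, day, bcr_abl_ratio`, one cohort per file.
#'
#' @param path CSV path.
#' @return a named list of [burden_series()] objects; patients whose series
#'   cannot be constructed (e.g. too few points) are returned in the
#'   `"excluded"` attribute with their reasons.
#' @export
read_burden <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "bcr_abl_ratio")
  if (!all(need %in% names(df)))
    stop_invalid("burden file must have columns patient_id, day, bcr_abl_ratio")
  if (!nrow(df)) stop_invalid("burden file '%s' is empty", path)
  out <- list(); excluded <- list()
  for (id in unique(df$patient_id)) {
    sub <- df[df$patient_id == id, ]
    sub <- sub[order(sub$day), ]
    res <- tryCatch(burden_series(id, sub$day, sub$bcr_abl_ratio),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "burden_series")) out[[id]] <- res
    else excluded[[id]] <- res
  }
  attr(out, "excluded") <- excluded
  out
}

#' Write a tumor-burden series (or list of them) to CSV
#'
#' @param series a [burden_series()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_burden <- function(series, path) {
  if (inherits(series, "burden_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(patient_id = s$patient_id, day = s$times,
               bcr_abl_ratio = s$burden)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
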