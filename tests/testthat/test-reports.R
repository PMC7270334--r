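# helpers shared by the report tests: a tiny synthetic cohort with burden
# series written to CSV
make_cohort_files <- function(dir, n = 3, noise_sd = 0.1,
                              slope2 = -0.001, duration = 2700,
                              breakpoint = 300, slope1 = -0.01) {
  cohort <- generate_cohort(cohort_spec(n_patients = n, seed = 8))
  pfile <- file.path(dir, "patients.csv")
  write_patients(cohort, pfile)
  series <- lapply(seq_along(cohort), function(i)
    generate_burden_series(burden_spec(slope1 = slope1, slope2 = slope2,
                                       breakpoint = breakpoint,
                                       duration = duration,
                                       noise_sd = noise_sd, seed = 100 + i),
                           patient_id = names(cohort)[i]))
  bfile <- file.path(dir, "burden.csv")
  write_burden(series, bfile)
  list(patients = pfile, burden = bfile, cohort = cohort)
}

test_that("burden-fit report fits the cohort, reports K and filters", {
  dir <- withr::local_tempdir()
  fx <- make_cohort_files(dir)
  # append a patient with too few points
  extra <- data.frame(patient_id = "short", day = c(0, 90),
                      bcr_abl_ratio = c(1, 0.1))
  df <- read.csv(fx$burden)
  write.csv(rbind(df, extra), fx$burden, row.names = FALSE)

  rep <- report_burden_fits(fx$burden, fx$patients, out_dir = dir)
  expect_length(rep$patients, 3)
  expect_s3_class(rep$K, "conversion_constant")
  expect_gt(rep$K$k, 0)
  expect_true("short" %in% names(rep$excluded))
  expect_match(rep$excluded[["short"]], "at least 3 points")
  for (p in rep$patients) {
    expect_true(is.finite(p$ec50_mg_L))
    expect_gt(p$d1_per_day, 0)
  }
  expect_true(file.exists(file.path(dir, "burden_fit_report.json")))

  # an empty burden file errors cleanly
  empty <- file.path(dir, "empty.csv")
  writeLines("patient_id,day,bcr_abl_ratio", empty)
  expect_error(read_burden(empty), "empty")
})

test_that("malformed patient rows are reported with their row", {
  dir <- withr::local_tempdir()
  pfile <- file.path(dir, "bad.csv")
  writeLines(c("id,age,sex,body_weight",
               "ok,50,M,70",
               "bad,-3,M,70"), pfile)
  expect_error(read_patients(pfile), "row 2.*bad")
})

test_that("diagnosis report is deterministic and carries comparators", {
  dir <- withr::local_tempdir()
  p <- list(a = patient_record("a", 50, "M", 70))
  cfg <- small_config()
  r1 <- report_diagnosis(p, days = 7, doses_per_day = 1, config = cfg,
                         seed = 3, out_dir = dir)
  r2 <- report_diagnosis(p, days = 7, doses_per_day = 1, config = cfg,
                         seed = 3)
  expect_identical(r1$a$runs, r2$a$runs)
  run <- r1$a$runs[["lower_bound_1dose"]]
  # standard-therapy comparator present with its AUC
  expect_true(is.finite(run$standard$auc_mg_h_L))
  expect_true(is.finite(run$optimized$auc_mg_h_L))
  expect_true(run$optimized$fraction_time_above <= 1)
  # both cost kinds reported
  expect_setequal(names(r1$a$runs),
                  c("lower_bound_1dose", "optimal_target_1dose"))
  expect_true(file.exists(file.path(dir, "diagnosis_report.json")))
  expect_true(file.exists(file.path(dir, "resolved_config.json")))
})

test_that("adjustment report rejects degenerate weights and predicts decay", {
  dir <- withr::local_tempdir()
  # a clear responder: steeper late decay than the generator default so the
  # predicted CSC pool keeps shrinking under therapy-average concentrations
  fx <- make_cohort_files(dir, n = 2, noise_sd = 0.05, slope1 = -0.02,
                          slope2 = -0.005, breakpoint = 400,
                          duration = 1800)
  expect_error(
    report_adjustment(fx$burden, fx$patients, phi_male = 0),
    "must be positive")

  rep <- report_adjustment(fx$burden, fx$patients, days = 7,
                           config = small_config(), seed = 2,
                           out_dir = dir)
  expect_true(file.exists(file.path(dir, "adjustment_report.json")))
  expect_gte(length(rep$patients), 1)
  for (p in rep$patients) {
    # a responder keeps decaying under both schedules; at the tuned phi the
    # optimized schedule decays at least as fast at comparable exposure
    expect_lt(p$csc_decay_rate_standard, 0)
    expect_lt(p$csc_decay_rate_optimized, 0)
    expect_gte(p$decay_speed_ratio, 1 - 1e-6)
    expect_lte(p$auc_optimized, 1.15 * p$auc_standard)
  }

  # seed determinism of the full command
  rep2 <- report_adjustment(fx$burden, fx$patients, days = 7,
                            config = small_config(), seed = 2)
  expect_identical(rep$patients, rep2$patients)
})
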