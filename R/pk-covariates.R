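# Covariate-based patient-specific PK parameters for oral imatinib:
# demographic records, covariate coefficients, clearance/volume relations,
# and body-weight imputation from an age-by-sex reference table.

#' Create a patient demographic record
#'
#' A patient record carries the demographic covariates that drive the
#' patient-specific pharmacokinetic model: age, sex and body weight.
#'
#' @param id character patient identifier.
#' @param age age in years (> 0).
#' @param sex `"M"`/`"F"` (or the binary indicator 1 = male, 0 = female).
#' @param body_weight body weight in kg (> 0), or `NULL` to impute it from
#'   the bundled age-by-sex reference table via [impute_body_weight()].
#' @return an object of class `patient_record` with fields `id`, `age`,
#'   `sex` (`"M"`/`"F"`), `q` (1 male, 0 female) and `body_weight`.
#' @examples
#' patient_record("p1", age = 50, sex = "M", body_weight = 70)
#' patient_record("p2", age = 45, sex = "F")  # weight imputed
#' @export
patient_record <- function(id, age, sex, body_weight = NULL) {
  check_positive(age, "age")
  q <- parse_sex(sex)
  if (is.null(body_weight) || (length(body_weight) == 1L && is.na(body_weight)))
    body_weight <- impute_body_weight(age, q)
  check_positive(body_weight, "body_weight")
  structure(
    list(id = as.character(id), age = as.numeric(age),
         sex = if (q == 1) "M" else "F", q = q,
         body_weight = as.numeric(body_weight)),
    class = "patient_record")
}

parse_sex <- function(sex) {
  if (is.character(sex)) {
    s <- toupper(substr(sex, 1, 1))
    if (!s %in% c("M", "F"))
      stop_invalid("sex must be 'M' or 'F' (got '%s')", sex)
    return(if (s == "M") 1 else 0)
  }
  if (is.numeric(sex) && sex %in% c(0, 1)) return(as.integer(sex))
  stop_invalid("sex must be 'M'/'F' or 0/1")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: %s, %.0f years, %.1f kg\n",
              x$id, if (x$q == 1) "male" else "female", x$age, x$body_weight))
  invisible(x)
}

#' Covariate coefficients of the population PK model
#'
#' Coefficients of the covariate relations for clearance and volume of
#' distribution, plus the absorption rate and bioavailability shared by all
#' patients. Clearance is an additive model in the relative body-weight
#' deviation, a sex contrast, and the relative age deviation; volume carries
#' a sex contrast only.
#'
#' @param theta_a typical clearance (L/h).
#' @param theta_b typical volume of distribution (L).
#' @param theta_1 clearance shift per unit relative body-weight deviation (L/h).
#' @param theta_2 clearance sex contrast, added for males and subtracted for
#'   females (L/h).
#' @param theta_3 clearance shift per unit relative age deviation (L/h).
#' @param theta_4 volume sex contrast (L).
#' @param bw_mean population-average body weight (kg).
#' @param age_mean population-average age (years).
#' @param ka first-order absorption rate (1/h).
#' @param f oral bioavailability, in (0, 1].
#' @return an object of class `pk_coefficients`.
#' @seealso [default_pk_coefficients()] for the bundled imatinib defaults.
#' @export
pk_coefficients <- function(theta_a, theta_b, theta_1, theta_2, theta_3,
                            theta_4, bw_mean, age_mean, ka, f) {
  check_positive(ka, "ka")
  check_positive(bw_mean, "bw_mean")
  check_positive(age_mean, "age_mean")
  if (!is.numeric(f) || f <= 0 || f > 1)
    stop_invalid("bioavailability f must lie in (0, 1]")
  structure(
    list(theta_a = theta_a, theta_b = theta_b, theta_1 = theta_1,
         theta_2 = theta_2, theta_3 = theta_3, theta_4 = theta_4,
         bw_mean = bw_mean, age_mean = age_mean, ka = ka, f = f),
    class = "pk_coefficients")
}

#' Load PK covariate coefficients from a constants file
#'
#' Reads a JSON constants file with keys `theta_a`..`theta_4`, `bw_mean`,
#' `age_mean`, `ka`, `f`. With no argument, loads the versioned imatinib
#' defaults bundled with the package (see the file's own provenance note).
#'
#' @param path path to a JSON constants file, or `NULL` for the bundled
#'   defaults.
#' @return a [pk_coefficients()] object.
#' @export
default_pk_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pk_constants_imatinib.json",
                        package = "dosedesign", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("theta_a", "theta_b", "theta_1", "theta_2", "theta_3", "theta_4",
            "bw_mean", "age_mean", "ka", "f")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop_invalid("constants file '%s' is missing keys: %s",
                 path, paste(miss, collapse = ", "))
  do.call(pk_coefficients, lapply(j[need], as.numeric))
}

#' Clearance from demographic covariates
#'
#' Computes patient-specific clearance
#' `CL = theta_a + theta_1 * (BW - BWbar)/BWbar + theta_2 * q -
#'  theta_2 * (1 - q) + theta_3 * (AGE - AGEbar)/AGEbar`,
#' where `q` is 1 for males and 0 for females.
#'
#' @param patient a [patient_record()].
#' @param coeffs a [pk_coefficients()] object.
#' @return clearance in L/h (error if the covariate combination gives a
#'   non-positive value).
#' @export
clearance_from_covariates <- function(patient,
                                      coeffs = default_pk_coefficients()) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(coeffs, "pk_coefficients"))
  cl <- coeffs$theta_a +
    coeffs$theta_1 * (patient$body_weight - coeffs$bw_mean) / coeffs$bw_mean +
    coeffs$theta_2 * patient$q - coeffs$theta_2 * (1 - patient$q) +
    coeffs$theta_3 * (patient$age - coeffs$age_mean) / coeffs$age_mean
  if (!is.finite(cl) || cl <= 0)
    stop_invalid(
      "non-positive clearance (%.3f L/h) for patient '%s' (age %.0f, sex %s, BW %.1f kg): invalid covariates",
      cl, patient$id, patient$age, patient$sex, patient$body_weight)
  cl
}

#' Volume of distribution from demographic covariates
#'
#' Computes `v = theta_b + theta_4 * q - theta_4 * (1 - q)`, i.e. the typical
#' volume shifted up for males and down for females.
#'
#' @inheritParams clearance_from_covariates
#' @return volume of distribution in L (error if non-positive).
#' @export
volume_from_covariates <- function(patient,
                                   coeffs = default_pk_coefficients()) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(coeffs, "pk_coefficients"))
  v <- coeffs$theta_b + coeffs$theta_4 * patient$q -
    coeffs$theta_4 * (1 - patient$q)
  if (!is.finite(v) || v <= 0)
    stop_invalid("non-positive volume (%.3f L) for patient '%s': invalid covariates",
                 v, patient$id)
  v
}

# cached body-weight reference table
bw_reference_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      path <- system.file("extdata", "bw_by_age_sex.csv",
                          package = "dosedesign", mustWork = TRUE)
      tab <<- utils::read.csv(path, comment.char = "#",
                              stringsAsFactors = FALSE)
    }
    tab
  }
})

#' Impute body weight from age and sex
#'
#' Looks up the population-average body weight for the patient's age bin and
#' sex in the bundled reference table (piecewise constant over age bins).
#' Ages outside the table range are clamped to the nearest bin with a
#' warning.
#'
#' @param age age in years (> 0).
#' @param sex `"M"`/`"F"` or 1/0.
#' @return body weight in kg.
#' @export
impute_body_weight <- function(age, sex) {
  check_positive(age, "age")
  q <- parse_sex(sex)
  tab <- bw_reference_table()
  tab <- tab[tab$sex == (if (q == 1) "M" else "F"), ]
  if (age < min(tab$age_min) || age > max(tab$age_max)) {
    warning(sprintf("age %.0f outside body-weight table range [%d, %d]; clamped",
                    age, min(tab$age_min), max(tab$age_max)), call. = FALSE)
    age <- min(max(age, min(tab$age_min)), max(tab$age_max))
  }
  hit <- tab$age_min <= age & age <= tab$age_max
  tab$bw_kg[which(hit)[1]]
}

#' Build a patient-specific PK model
#'
#' Combines a patient record with covariate coefficients into the
#' one-compartment oral-absorption PK parameter set: absorption rate `ka`,
#' bioavailability `f`, covariate-derived clearance `CL` and volume of
#' distribution `v` (and hence elimination rate `ke = CL/v`).
#'
#' @param patient a [patient_record()], or `NULL` when giving `clearance`
#'   and `volume` directly.
#' @param coeffs a [pk_coefficients()] object.
#' @param clearance,volume optional direct parameter values (L/h, L),
#'   bypassing the covariate relations.
#' @return an object of class `pk_model` with fields `ka`, `f`, `clearance`,
#'   `volume`, `ke` and `patient`.
#' @examples
#' pk <- pk_model(patient_record("avg-m", 50, "M", 70))
#' pk$clearance  # L/h
#' @export
pk_model <- function(patient = NULL, coeffs = default_pk_coefficients(),
                     clearance = NULL, volume = NULL) {
  if (is.null(clearance)) clearance <- clearance_from_covariates(patient, coeffs)
  if (is.null(volume)) volume <- volume_from_covariates(patient, coeffs)
  check_positive(clearance, "clearance")
  check_positive(volume, "volume")
  structure(
    list(ka = coeffs$ka, f = coeffs$f, clearance = clearance, volume = volume,
         ke = clearance / volume, patient = patient),
    class = "pk_model")
}

#' @export
print.pk_model <- function(x, ...) {
  cat("One-compartment oral-absorption PK model\n")
  if (!is.null(x$patient))
    cat(sprintf("  patient: %s (%s, %.0f y, %.1f kg)\n", x$patient$id,
                x$patient$sex, x$patient$age, x$patient$body_weight))
  cat(sprintf("  ka = %.3f 1/h, f = %.2f, CL = %.2f L/h, v = %.1f L (ke = %.4f 1/h)\n",
              x$ka, x$f, x$clearance, x$volume, x$ke))
  invisible(x)
}

#' The population-average reference patient
#'
#' Convenience constructor for the "average patient" used in the robustness
#' studies and examples: age and body weight equal to the population means of
#' the coefficient set, for a given sex.
#'
#' @param sex `"M"` or `"F"`.
#' @param coeffs a [pk_coefficients()] object.
#' @return a [patient_record()].
#' @export
average_patient <- function(sex = "M", coeffs = default_pk_coefficients()) {
  patient_record(paste0("average-", tolower(sex)), age = coeffs$age_mean,
                 sex = sex, body_weight = coeffs$bw_mean)
}
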