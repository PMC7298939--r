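#' Classify an ICD-10 main diagnosis into a severe-mental-disorder group
#'
#' Inclusion groups: any F2-prefixed code (schizophrenia, schizotypal and
#' delusional disorders) is `psychotic`; F30*, F31* and F603 (manic episode,
#' bipolar affective disorder, emotionally unstable personality disorder) are
#' `bipolar_personality`; the severe depressive episode codes F322, F323, F332,
#' F333 are `severe_depressive`. Codes are uppercased and dots stripped before
#' matching; prefix matching applies to F2/F30/F31 and exact matching to the
#' 4-character codes.
#'
#' @param icd10 character vector of ICD-10 codes.
#' @return character vector: `"psychotic"`, `"bipolar_personality"`,
#'   `"severe_depressive"` or `NA` when the code is outside the inclusion list.
#' @examples
#' classify_diagnosis(c("F200", "F603", "F321"))
#' @export
classify_diagnosis <- function(icd10) {
  code <- toupper(gsub(".", "", icd10, fixed = TRUE))
  bad <- !grepl("^[A-Z][0-9]{2,}$", code)
  if (any(bad)) {
    stop(sprintf("malformed ICD-10 code(s): %s",
                 paste(unique(icd10[bad]), collapse = ", ")), call. = FALSE)
  }
  out <- rep(NA_character_, length(code))
  out[grepl("^F2[0-9]", code)] <- "psychotic"
  out[grepl("^F3[01]", code) | code == "F603"] <- "bipolar_personality"
  out[code %in% c("F322", "F323", "F332", "F333")] <- "severe_depressive"
  out
}

#' Select index hospitalizations
#'
#' One index stay per retained patient: the earliest full-time psychiatric
#' inpatient stay with an included ICD-10 main diagnosis, admitted during the
#' index window at a sectorized, non-military hospital, for patients aged 18 to
#' 65 at admission. Selection is independent of input row order.
#'
#' @param stays inpatient-stay table (`patient_id`, `hospital_id`,
#'   `admit_date`, `discharge_date`, `icd10_main`, `care_type`).
#' @param patients patient table (needs `patient_id`, `birth_year`).
#' @param providers provider table (needs `provider_id`, `sectorized`,
#'   `military`).
#' @param index_years two calendar years delimiting eligible admissions.
#' @return data frame of index stays with `diagnosis_group` and
#'   `age_at_index`, one row per retained patient.
#' @export
select_index_stays <- function(stays, patients, providers,
                               index_years = c(2012, 2013)) {
  if (nrow(stays) == 0) {
    warning("empty stay table: no index stays selected")
    return(stays[0, ])
  }
  s <- stays
  s$admit_date <- as.Date(s$admit_date)
  s$discharge_date <- as.Date(s$discharge_date)
  s$diagnosis_group <- suppressWarnings(classify_diagnosis_safe(s$icd10_main))

  admit_year <- as.integer(format(s$admit_date, "%Y"))
  hosp <- providers[match(s$hospital_id, providers$provider_id), ]
  by <- patients$birth_year[match(s$patient_id, patients$patient_id)]
  if (anyNA(by)) {
    missing_ids <- unique(s$patient_id[is.na(by)])
    stop(sprintf("missing birth year for patient(s): %s",
                 paste(utils::head(missing_ids, 5), collapse = ", ")),
         call. = FALSE)
  }
  age <- admit_year - by

  military <- hosp$military %||% rep(FALSE, nrow(s))
  military[is.na(military)] <- FALSE
  eligible <- !is.na(s$diagnosis_group) &
    s$care_type == "full_time_psychiatric" &
    admit_year >= min(index_years) & admit_year <= max(index_years) &
    !is.na(hosp$sectorized) & hosp$sectorized &
    !military &
    age >= 18 & age <= 65

  s <- s[eligible, , drop = FALSE]
  s$age_at_index <- age[eligible]
  if (nrow(s) == 0) {
    warning("no eligible index stays")
    return(s)
  }
  ## earliest eligible stay per patient; deterministic tie-break on stay id
  s <- s[order(s$patient_id, s$admit_date, s$stay_id), ]
  s <- s[!duplicated(s$patient_id), ]
  names(s)[names(s) == "hospital_id"] <- "index_hospital_id"
  rownames(s) <- NULL
  s
}

## vectorized classification that maps malformed codes to NA instead of
## aborting (index selection should skip junk rows, not fail on them)
classify_diagnosis_safe <- function(icd10) {
  code <- toupper(gsub(".", "", icd10, fixed = TRUE))
  ok <- grepl("^[A-Z][0-9]{2,}$", code)
  out <- rep(NA_character_, length(code))
  if (any(ok)) out[ok] <- classify_diagnosis(code[ok])
  out
}

#' Derive patient-level covariates for the index cohort
#'
#' Adds the adjustor set used downstream: age at index admission, sex,
#' low-income scheme flag (CMU-C), somatic long-term-illness flag (ALD),
#' diagnosis group, and the precedence flag — `TRUE` iff the patient had any
#' hospital-based psychiatric contact in the 730 days before index admission.
#'
#' @param index_stays output of [select_index_stays()].
#' @param stays full stay table (history source for precedence).
#' @param patients patient table.
#' @return the cohort table: one row per patient, index stay plus covariates.
#' @export
derive_covariates <- function(index_stays, stays, patients) {
  idx <- index_stays
  p <- patients[match(idx$patient_id, patients$patient_id), ]
  if (anyNA(p$birth_year)) {
    stop(sprintf("missing birth year for patient(s): %s",
                 paste(unique(idx$patient_id[is.na(p$birth_year)]),
                       collapse = ", ")), call. = FALSE)
  }

  psy <- stays[grepl("psychiatric", stays$care_type), ]
  psy$admit_date <- as.Date(psy$admit_date)
  ## precedence: any psychiatric hospital contact in (admit-730, admit)
  key <- split(psy$admit_date, psy$patient_id)
  idx_admit <- as.Date(idx$admit_date)
  precedence <- vapply(seq_len(nrow(idx)), function(i) {
    dates <- key[[idx$patient_id[i]]]
    if (is.null(dates)) return(FALSE)
    d <- as.numeric(idx_admit[i] - dates)
    any(d >= 1 & d <= 730)
  }, logical(1))

  data.frame(
    patient_id = idx$patient_id,
    index_hospital_id = idx$index_hospital_id,
    admit_date = as.Date(idx$admit_date),
    discharge_date = as.Date(idx$discharge_date),
    icd10_main = idx$icd10_main,
    diagnosis_group = idx$diagnosis_group,
    age_at_index = idx$age_at_index,
    sex = p$sex,
    sex_male = p$sex == "male",
    low_income = p$low_income,
    somatic_ltd = p$somatic_ltd,
    precedence = precedence,
    stringsAsFactors = FALSE
  )
}

#' Build the study cohort from a claims bundle
#'
#' Convenience wrapper: [select_index_stays()] then [derive_covariates()].
#'
#' @param bundle a `claims_bundle`.
#' @param index_years index admission window.
#' @return the cohort table.
#' @export
build_cohort <- function(bundle, index_years = c(2012, 2013)) {
  idx <- select_index_stays(bundle$stays, bundle$patients, bundle$providers,
                            index_years = index_years)
  derive_covariates(idx, bundle$stays, bundle$patients)
}
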