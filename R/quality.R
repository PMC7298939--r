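#' Quality indicator 1: 15-day psychiatric readmission
#'
#' `TRUE` iff any full-time psychiatric inpatient admission (any hospital,
#' index hospital included) occurs within 15 days of the index discharge,
#' day 15 inclusive.
#'
#' @param discharge_date index discharge date.
#' @param patient_stays stay rows of the patient.
#' @return logical.
#' @export
indicator_readmission <- function(discharge_date, patient_stays) {
  st <- patient_stays[patient_stays$care_type == "full_time_psychiatric", ,
                      drop = FALSE]
  if (nrow(st) == 0) return(FALSE)
  d <- days_since(st$admit_date, discharge_date)
  any(d >= 1 & d <= 15)
}

#' Quality indicator 2: referring-physician contact within 2 months
#'
#' `TRUE` iff a contact with the patient's designated referring physician
#' ("medecin traitant") occurs within 60 days of the index discharge. Patients
#' with no designated physician score `FALSE` (the indicator measures the
#' realized hospital-community transition).
#'
#' @param discharge_date index discharge date.
#' @param patient_contacts contact rows of the patient.
#' @param referring_physician_id designated physician id (`NA` when none).
#' @return logical.
#' @export
indicator_referring_physician <- function(discharge_date, patient_contacts,
                                          referring_physician_id) {
  if (is.na(referring_physician_id)) return(FALSE)
  cc <- patient_contacts[patient_contacts$provider_id ==
                           referring_physician_id, , drop = FALSE]
  if (nrow(cc) == 0) return(FALSE)
  d <- days_since(cc$date, discharge_date)
  any(d >= 1 & d <= 60)
}

#' Quality indicator 3: three recommended prevention procedures within 2 years
#'
#' `TRUE` iff all three distinct configured procedure tags occur within 730
#' days of the index discharge. Unknown tags are ignored.
#'
#' @param discharge_date index discharge date.
#' @param patient_procedures procedure rows of the patient (`date`, `tag`).
#' @param tags the three recognized procedure tags.
#' @return logical.
#' @export
indicator_prevention <- function(discharge_date, patient_procedures,
                                 tags = c("P1", "P2", "P3")) {
  pr <- patient_procedures
  unknown <- setdiff(unique(pr$tag), tags)
  if (length(unknown)) {
    message(sprintf("ignoring unknown procedure tag(s): %s",
                    paste(unknown, collapse = ", ")))
  }
  pr <- pr[pr$tag %in% tags, , drop = FALSE]
  if (nrow(pr) == 0) return(FALSE)
  d <- days_since(pr$date, discharge_date)
  pr <- pr[d >= 1 & d <= 730, , drop = FALSE]
  length(unique(pr$tag)) == length(tags)
}

#' Quality indicator 4: at least nine antipsychotic deliveries within 12 months
#'
#' `TRUE` iff >= 9 antipsychotic delivery events occur within 365 days of the
#' index discharge; same-day deliveries count separately.
#'
#' @param discharge_date index discharge date.
#' @param patient_deliveries delivery rows of the patient (`date`,
#'   `antipsychotic`).
#' @return logical.
#' @export
indicator_antipsychotic <- function(discharge_date, patient_deliveries) {
  dl <- patient_deliveries[patient_deliveries$antipsychotic %||% TRUE, ,
                           drop = FALSE]
  if (nrow(dl) == 0) return(FALSE)
  d <- days_since(dl$date, discharge_date)
  sum(d >= 1 & d <= 365) >= 9
}

#' Compute the four quality indicators on the schizophrenia-spectrum subcohort
#'
#' Indicators are defined only for patients whose index diagnosis group is
#' `psychotic`; all windows are anchored at the index discharge.
#'
#' @param cohort cohort table from [build_cohort()].
#' @param bundle a `claims_bundle`.
#' @param referring_map optional data frame (`patient_id`,
#'   `referring_physician_id`); default: the designation column of the patient
#'   table.
#' @param tags the three prevention-procedure tags.
#' @return data frame of class `quality_rows`: one row per subcohort patient
#'   with `network_id` and the four indicator booleans.
#' @export
quality_table <- function(cohort, bundle, referring_map = NULL,
                          tags = c("P1", "P2", "P3")) {
  sub <- cohort[cohort$diagnosis_group == "psychotic", , drop = FALSE]
  if (is.null(referring_map)) {
    referring_map <- data.frame(
      patient_id = bundle$patients$patient_id,
      referring_physician_id = bundle$patients$referring_physician_id %||%
        rep(NA_character_, nrow(bundle$patients)),
      stringsAsFactors = FALSE
    )
  }
  ref_of <- stats::setNames(referring_map$referring_physician_id,
                            referring_map$patient_id)

  ## pre-split event tables once; per-patient lookups are then O(1)
  idx_keys <- stats::setNames(sub$patient_id, sub$patient_id)
  split_by_patient <- function(df) {
    df <- df[df$patient_id %in% sub$patient_id, , drop = FALSE]
    split(df, df$patient_id)
  }
  stays_by <- split_by_patient(bundle$stays)
  contacts_by <- split_by_patient(bundle$contacts)
  proc_by <- split_by_patient(bundle$procedures %||%
                                data.frame(patient_id = character(0),
                                           date = as.Date(character(0)),
                                           tag = character(0)))
  del_by <- split_by_patient(bundle$deliveries)
  empty <- function(cols) {
    out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    out
  }

  rows <- lapply(seq_len(nrow(sub)), function(i) {
    pid <- sub$patient_id[i]
    disc <- sub$discharge_date[i]
    ## the index stay itself must not count as its own readmission
    st <- stays_by[[pid]] %||% empty(c("admit_date", "care_type"))
    st <- st[days_since(st$admit_date, sub$admit_date[i]) != 0, ,
             drop = FALSE]
    data.frame(
      patient_id = pid,
      network_id = sub$index_hospital_id[i],
      readmit_15d = indicator_readmission(disc, st),
      referring_contact_2m = indicator_referring_physician(
        disc, contacts_by[[pid]] %||% empty(c("provider_id", "date")),
        ref_of[pid] %||% NA_character_
      ),
      prevention_3proc_2y = suppressMessages(indicator_prevention(
        disc, proc_by[[pid]] %||% empty(c("date", "tag")), tags
      )),
      antipsychotic_9plus_12m = indicator_antipsychotic(
        disc, del_by[[pid]] %||% empty(c("date", "antipsychotic"))
      ),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("quality_rows", "data.frame")
  out
}

#' Aggregate quality indicators by network and cluster
#'
#' Per network: the percentage of subcohort patients meeting each indicator.
#' Per cluster: mean and SD of those network-level percentages across member
#' networks, with a v-test flag against the overall mean.
#'
#' @param quality_rows output of [quality_table()].
#' @param solution a `cluster_solution` (may be `NULL` for network-level
#'   output only).
#' @return list with `by_network` and (when a solution is given) `by_cluster`.
#' @export
aggregate_quality <- function(quality_rows, solution = NULL) {
  nets <- sort(unique(quality_rows$network_id))
  by_network <- do.call(rbind, lapply(nets, function(h) {
    sub <- quality_rows[quality_rows$network_id == h, , drop = FALSE]
    vals <- vapply(QUALITY_INDICATORS, function(ind) 100 * mean(sub[[ind]]),
                   numeric(1))
    data.frame(network_id = h, n_patients = nrow(sub), t(vals),
               stringsAsFactors = FALSE)
  }))
  rownames(by_network) <- NULL
  if (is.null(solution)) return(list(by_network = by_network))

  labels <- solution$labels[by_network$network_id]
  crit <- stats::qnorm(0.975)
  rows <- list()
  for (ind in QUALITY_INDICATORS) {
    x <- by_network[[ind]]
    for (cl in sort(unique(labels))) {
      members <- which(labels == cl)
      vt <- v_test(x, members)
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = ind, cluster = cl, n_networks = length(members),
        mean_pct = mean(x[members]),
        sd_pct = stats::sd(x[members]),
        overall_mean_pct = mean(x),
        v_statistic = vt,
        significant = !is.na(vt) && abs(vt) >= crit,
        stringsAsFactors = FALSE
      )
    }
  }
  list(by_network = by_network, by_cluster = do.call(rbind, rows))
}
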