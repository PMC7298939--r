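#' Default archetype parameters of the synthetic claims generator
#'
#' Three planted network archetypes drive the generator:
#' * `A1` — hospital-centric, sectorized networks: a high share of specialized
#'   ambulatory care delivered inside the index hospital, high patient loyalty,
#'   concentrated provider pools (hence dense projections), few private
#'   hospitals, rural or resource-limited areas.
#' * `A2` — scattered urban networks: many and diverse providers, high contact
#'   intensity, low in-hospital ambulatory share, strong private supply, larger
#'   patient volumes.
#' * `A3` — medically-oriented networks: patient sharing directed mostly at
#'   physicians (GPs and psychiatrists), few nurses, the lowest contact
#'   intensity, mid-sized catchments.
#'
#' `contact_rates` are expected numbers of *distinct* providers of each type a
#' patient contacts during the one-year follow-up window (Poisson means);
#' `visits_per_provider` is the mean number of repeat visits to each contacted
#' community provider, so total contact volume is their product.
#'
#' @return named list of per-archetype parameter lists.
#' @export
default_archetype_params <- function() {
  list(
    A1 = list(
      volume_multiplier = 1.0,
      provider_pool_sizes = c(hospital = 8, psychiatrist = 24, gp = 44, nurse = 40),
      contact_rates = c(hospital = 0.40, psychiatrist = 1.20, gp = 2.20, nurse = 2.00),
      visits_per_provider = 10.6,
      in_hospital_ambulatory_share = 0.40,
      pathway_share = 0.45,
      loyalty_target = 0.92,
      private_hospital_share = 0.05,
      specialized_prob = 0.20,
      beds_mean = 150,
      catchment_population = 28000,
      area_typology_probs = c(0.2, 0, 0, 0.4, 0.4)
    ),
    A2 = list(
      volume_multiplier = 1.3,
      provider_pool_sizes = c(hospital = 24, psychiatrist = 44, gp = 49, nurse = 47),
      contact_rates = c(hospital = 1.02, psychiatrist = 1.86, gp = 2.08, nurse = 2.00),
      visits_per_provider = 12.8,
      in_hospital_ambulatory_share = 0.15,
      pathway_share = 0.30,
      loyalty_target = 0.72,
      private_hospital_share = 0.50,
      specialized_prob = 0.44,
      beds_mean = 159,
      catchment_population = 120000,
      area_typology_probs = c(0, 0, 0.556, 0.444, 0)
    ),
    A3 = list(
      volume_multiplier = 1.5,
      provider_pool_sizes = c(hospital = 16, psychiatrist = 16, gp = 37, nurse = 9),
      contact_rates = c(hospital = 0.64, psychiatrist = 0.64, gp = 1.48, nurse = 0.36),
      visits_per_provider = 17.5,
      in_hospital_ambulatory_share = 0.27,
      pathway_share = 0.02,
      loyalty_target = 0.82,
      private_hospital_share = 0.70,
      specialized_prob = 0.20,
      beds_mean = 104,
      catchment_population = 110000,
      area_typology_probs = c(0, 0, 0.8, 0.2, 0)
    )
  )
}

## ICD-10 codes sampled per diagnosis group
DIAG_CODES <- list(
  psychotic = c("F200", "F201", "F205", "F220", "F259"),
  bipolar_personality = c("F300", "F310", "F312", "F316", "F603"),
  severe_depressive = c("F322", "F323", "F332", "F333")
)

#' Scenario configuration for the synthetic claims generator
#'
#' Validates and assembles the generator configuration. Per-archetype settings
#' (`contact_rates`, `loyalty_target`, ...) can be overridden selectively; the
#' remaining values come from [default_archetype_params()].
#'
#' @param n_index_hospitals number of sectorized index hospitals.
#' @param archetype_assignment character vector of archetype labels
#'   (`"A1"`,`"A2"`,`"A3"`), one per index hospital. Default: 5 / 9 / 5.
#' @param n_patients_per_hospital baseline index cohort size per hospital,
#'   scaled by each archetype's `volume_multiplier`.
#' @param contact_rates,provider_pool_sizes,visits_per_provider,
#'   in_hospital_ambulatory_share,loyalty_target per-archetype overrides: a
#'   named list `list(A1 = ..., A2 = ..., A3 = ...)` (vectors merged into the
#'   defaults by name).
#' @param outcome_base_rates named vector of baseline probabilities for the
#'   four quality indicators.
#' @param outcome_coefficients list mapping each indicator to a named vector of
#'   log-relative-rates per patient covariate (`age_c` = age minus 40 in years,
#'   `sex_male`, `low_income`, `precedence`, `somatic_ltd`). Empty = null model.
#' @param cluster_correlation exchangeable within-archetype outcome correlation
#'   in `[0, 1)`, induced through a shared archetype-level latent intercept on
#'   the log scale.
#' @param referring_designation_rate share of patients with a designated
#'   referring physician ("medecin traitant").
#' @param prevention_tags the three recommended prevention-procedure tags.
#' @param index_years two calendar years of index admissions.
#' @param follow_up_days length of the post-discharge follow-up window (days).
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_index_hospitals = 19,
                            archetype_assignment = NULL,
                            n_patients_per_hospital = 200,
                            contact_rates = NULL,
                            provider_pool_sizes = NULL,
                            visits_per_provider = NULL,
                            in_hospital_ambulatory_share = NULL,
                            loyalty_target = NULL,
                            outcome_base_rates = c(
                              readmit_15d = 0.30,
                              referring_contact_2m = 0.33,
                              prevention_3proc_2y = 0.50,
                              antipsychotic_9plus_12m = 0.54
                            ),
                            outcome_coefficients = list(),
                            cluster_correlation = 0.05,
                            referring_designation_rate = 1.0,
                            prevention_tags = c("P1", "P2", "P3"),
                            index_years = c(2012, 2013),
                            follow_up_days = 365,
                            seed = 1L) {
  check_count(n_index_hospitals, "n_index_hospitals")
  check_count(n_patients_per_hospital, "n_patients_per_hospital")
  if (is.null(archetype_assignment)) {
    n <- n_index_hospitals
    n_side <- max(1, round(n * 5 / 19))
    archetype_assignment <- c(
      rep("A1", n_side),
      rep("A2", n - 2 * n_side),
      rep("A3", n_side)
    )
  }
  if (length(archetype_assignment) != n_index_hospitals) {
    stop_config("archetype_assignment",
                "must assign exactly one archetype per index hospital")
  }
  if (!all(archetype_assignment %in% c("A1", "A2", "A3"))) {
    stop_config("archetype_assignment", "labels must be A1, A2 or A3")
  }

  arch <- default_archetype_params()
  merge_field <- function(field, value, check = NULL) {
    if (is.null(value)) return()
    for (a in names(value)) {
      if (!a %in% names(arch)) stop_config(field, paste("unknown archetype", a))
      v <- value[[a]]
      if (!is.null(check)) check(v, field)
      if (is.null(names(v)) && length(v) > 1) {
        stop_config(field, "per-type vectors must be named")
      }
      if (length(v) == 1 && is.null(names(v))) {
        arch[[a]][[field]] <<- v
      } else {
        old <- arch[[a]][[field]]
        old[names(v)] <- v
        arch[[a]][[field]] <<- old
      }
    }
  }
  merge_field("contact_rates", contact_rates, function(v, f) {
    if (any(v < 0) || any(!is.finite(v))) stop_config(f, "rates must be >= 0")
  })
  merge_field("provider_pool_sizes", provider_pool_sizes, function(v, f) {
    if (any(v < 1)) stop_config(f, "provider pools must be non-empty")
    check_count(v, f)
  })
  merge_field("visits_per_provider", visits_per_provider, function(v, f) {
    if (any(v < 1)) stop_config(f, "mean visits must be >= 1")
  })
  merge_field("in_hospital_ambulatory_share", in_hospital_ambulatory_share,
              check_prob)
  merge_field("loyalty_target", loyalty_target, check_prob)

  check_prob(outcome_base_rates, "outcome_base_rates")
  if (!all(QUALITY_INDICATORS %in% names(outcome_base_rates))) {
    stop_config("outcome_base_rates",
                "must name all four quality indicators")
  }
  if (length(outcome_coefficients)) {
    if (!all(names(outcome_coefficients) %in% QUALITY_INDICATORS)) {
      stop_config("outcome_coefficients", "unknown outcome name")
    }
  }
  if (!is.finite(cluster_correlation) || cluster_correlation < 0 ||
      cluster_correlation >= 1) {
    stop_config("cluster_correlation", "must lie in [0, 1)")
  }
  check_prob(referring_designation_rate, "referring_designation_rate")
  if (length(prevention_tags) != 3 || anyDuplicated(prevention_tags)) {
    stop_config("prevention_tags", "exactly three distinct tags required")
  }
  if (length(index_years) != 2) {
    stop_config("index_years", "two consecutive index years expected")
  }
  check_count(follow_up_days, "follow_up_days")

  structure(
    list(
      n_index_hospitals = as.integer(n_index_hospitals),
      archetype_assignment = archetype_assignment,
      n_patients_per_hospital = as.integer(n_patients_per_hospital),
      archetypes = arch,
      outcome_base_rates = outcome_base_rates,
      outcome_coefficients = outcome_coefficients,
      cluster_correlation = cluster_correlation,
      referring_designation_rate = referring_designation_rate,
      prevention_tags = prevention_tags,
      index_years = as.integer(index_years),
      follow_up_days = as.integer(follow_up_days),
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [scenario_config()].
#'
#' @param path path to a YAML file.
#' @return a `scenario_config` object.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("outcome_base_rates")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  for (f in c("contact_rates", "provider_pool_sizes",
              "in_hospital_ambulatory_share", "loyalty_target",
              "visits_per_provider")) {
    if (!is.null(raw[[f]])) raw[[f]] <- lapply(raw[[f]], unlist)
  }
  if (!is.null(raw$outcome_coefficients)) {
    raw$outcome_coefficients <- lapply(raw$outcome_coefficients, unlist)
  }
  if (!is.null(raw$archetype_assignment)) {
    raw$archetype_assignment <- unlist(raw$archetype_assignment)
  }
  do.call(scenario_config, raw)
}

## latent-intercept variance on the log scale inducing approximately the
## requested exchangeable outcome correlation at baseline rate p
latent_sigma2 <- function(rho, p) {
  if (rho <= 0) return(0)
  log(1 + rho * (1 - p) / p)
}

#' Planted ground truth of a scenario
#'
#' Echoes the archetype label of each index hospital and the target relative
#' rates implied by the configured outcome coefficients, for parameter-recovery
#' experiments. Never consumed by the analysis stages.
#'
#' @param config a [scenario_config()].
#' @return list with `archetypes` (named by hospital id) and `target_rr`
#'   (per outcome, named vector of relative rates over the standard covariate
#'   set; 1.0 where no effect is planted).
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  hosp_ids <- sprintf("H%02d", seq_len(config$n_index_hospitals))
  covs <- c("age_c", "sex_male", "low_income", "precedence", "somatic_ltd")
  target_rr <- lapply(QUALITY_INDICATORS, function(o) {
    beta <- stats::setNames(numeric(length(covs)), covs)
    planted <- config$outcome_coefficients[[o]]
    if (!is.null(planted)) beta[names(planted)] <- planted
    exp(beta)
  })
  names(target_rr) <- QUALITY_INDICATORS
  list(
    archetypes = stats::setNames(config$archetype_assignment, hosp_ids),
    target_rr = target_rr
  )
}

#' Generate a synthetic claims bundle
#'
#' Produces the six delimited-table equivalents of a claims extract: providers,
#' patients, inpatient stays, community contacts, drug deliveries and
#' prevention procedures, with planted network archetypes and planted outcome
#' effects. Generation is bit-reproducible for a fixed seed.
#'
#' Outcome realization is exact: each patient's four indicator outcomes are
#' drawn from the configured log-linear model (with the shared archetype-level
#' latent intercept), and the events that the indicators read (early
#' readmissions, referring-physician contact timing, procedure tags, delivery
#' counts) are then generated consistent with the drawn outcome, so empirical
#' indicator rates match the planted probabilities up to binomial noise.
#'
#' @param config a [scenario_config()].
#' @return an object of class `claims_bundle`: a list of data frames
#'   `providers`, `patients`, `stays`, `contacts`, `deliveries`, `procedures`.
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)

  n_hosp <- config$n_index_hospitals
  hosp_ids <- sprintf("H%02d", seq_len(n_hosp))
  zones <- sprintf("Z%02d", seq_len(n_hosp))
  arch_of <- stats::setNames(config$archetype_assignment, hosp_ids)

  rho <- config$cluster_correlation
  base <- config$outcome_base_rates
  ## one shared latent intercept per archetype and outcome
  arch_levels <- c("A1", "A2", "A3")
  latent <- sapply(QUALITY_INDICATORS, function(o) {
    s2 <- latent_sigma2(rho, base[[o]])
    stats::rnorm(length(arch_levels), mean = -s2 / 2, sd = sqrt(s2))
  })
  rownames(latent) <- arch_levels

  providers <- list()
  patients <- list()
  stays <- list()
  contacts <- list()
  deliveries <- list()
  procedures <- list()

  index_start <- as.Date(sprintf("%d-01-01", config$index_years[1]))
  index_end <- as.Date(sprintf("%d-12-31", config$index_years[2]))
  index_span <- as.integer(index_end - index_start)
  fup <- config$follow_up_days

  pat_counter <- 0L
  stay_counter <- 0L

  for (hi in seq_len(n_hosp)) {
    h <- hosp_ids[hi]
    zone <- zones[hi]
    a <- arch_of[[h]]
    pars <- config$archetypes[[a]]

    ## per-hospital heterogeneity: hospitals of one archetype differ in the
    ## breadth of their provider neighbourhood (scale factor g inflates the
    ## local pool and the number of distinct providers each patient sees,
    ## leaving the per-provider shared-patient concentration unchanged), in
    ## repeat-visit intensity (compensated by 1/g so total contact volume
    ## remains an archetype trait), and in the in-house ambulatory share;
    ## real networks show large within-type spread on size and shares
    g <- exp(stats::rnorm(1, 0, 0.04))
    pools <- pmax(round(pars$provider_pool_sizes * g), 2)
    rates <- pars$contact_rates * g * exp(stats::rnorm(1, 0, 0.03))
    visits_mean <- max(1, pars$visits_per_provider *
                         exp(stats::rnorm(1, 0, 0.03)) / g)
    amb_share <- stats::plogis(
      stats::qlogis(min(max(pars$in_hospital_ambulatory_share, 1e-6),
                        1 - 1e-6)) + stats::rnorm(1, 0, 0.07)
    )
    pathway <- stats::plogis(
      stats::qlogis(min(max(pars$pathway_share, 1e-6), 1 - 1e-6)) +
        stats::rnorm(1, 0, 0.15)
    )

    n_p <- round(config$n_patients_per_hospital * pars$volume_multiplier *
                   exp(stats::rnorm(1, 0, 0.04)))

    ## ---- providers: the index hospital plus its local pools -------------
    ## bed counts track caseload (larger hospitals admit more index patients),
    ## as in real data where beds co-vary with network size measures
    idx_provider <- data.frame(
      provider_id = h, type = "hospital", zone = zone, in_region = TRUE,
      is_index = TRUE, sectorized = TRUE, military = FALSE,
      private = FALSE,
      specialized = stats::runif(1) < pars$specialized_prob,
      beds = max(20L, round(n_p * 1.25 * exp(stats::rnorm(1, 0, 0.1)))),
      catchment_population = pars$catchment_population,
      area_typology = sample(AREA_TYPOLOGY_LEVELS, 1,
                             prob = pars$area_typology_probs),
      stringsAsFactors = FALSE
    )
    pool_ids <- list(
      hospital = sprintf("%s_HO%02d", h, seq_len(pools[["hospital"]])),
      psychiatrist = sprintf("%s_PS%02d", h, seq_len(pools[["psychiatrist"]])),
      gp = sprintf("%s_GP%02d", h, seq_len(pools[["gp"]])),
      nurse = sprintf("%s_NU%02d", h, seq_len(pools[["nurse"]]))
    )
    pool_providers <- data.frame(
      provider_id = unlist(pool_ids, use.names = FALSE),
      type = rep(names(pool_ids), lengths(pool_ids)),
      zone = zone, in_region = TRUE, is_index = FALSE, sectorized = FALSE,
      military = FALSE, private = FALSE, specialized = NA, beds = NA_integer_,
      catchment_population = NA_integer_, area_typology = NA_character_,
      stringsAsFactors = FALSE
    )
    is_pool_hosp <- pool_providers$type == "hospital"
    pool_providers$private[is_pool_hosp] <-
      stats::runif(sum(is_pool_hosp)) < pars$private_hospital_share
    providers[[h]] <- rbind(idx_provider, pool_providers)

    ## ---- patients -------------------------------------------------------
    pid <- sprintf("P%06d", pat_counter + seq_len(n_p))
    pat_counter <- pat_counter + n_p

    age <- pmin(65, pmax(18, round(stats::rnorm(n_p, 41.7, 12.2))))
    sex_male <- stats::runif(n_p) < 0.571
    low_income <- stats::runif(n_p) < 0.206
    somatic <- stats::runif(n_p) < 0.152
    precedence <- stats::runif(n_p) < 0.562
    in_catchment <- stats::runif(n_p) < pars$loyalty_target
    res_zone <- ifelse(in_catchment, zone,
                       sprintf("Z%02d", 1 + (hi + sample(seq_len(n_hosp - 1),
                                                         n_p, replace = TRUE) - 1) %% n_hosp))

    grp <- sample(names(DIAG_CODES), n_p, replace = TRUE,
                  prob = c(0.664, 0.221, 0.115))
    icd <- vapply(grp, function(g) sample(DIAG_CODES[[g]], 1), character(1))

    admit <- index_start + sample.int(index_span + 1, n_p, replace = TRUE) - 1
    los <- pmax(3, round(stats::rgamma(n_p, shape = 2, scale = 15)))
    discharge <- admit + los
    birth_year <- as.integer(format(admit, "%Y")) - age

    idx_stays <- data.frame(
      stay_id = sprintf("S%07d", stay_counter + seq_len(n_p)),
      patient_id = pid, hospital_id = h,
      admit_date = admit, discharge_date = discharge,
      icd10_main = icd, care_type = "full_time_psychiatric",
      stringsAsFactors = FALSE
    )
    stay_counter <- stay_counter + n_p
    h_stays <- list(idx_stays)

    ## precedence: part-time psychiatric contact in the prior two years
    ## (counts as a hospital psychiatric contact but is not index-eligible)
    prec_idx <- which(precedence)
    if (length(prec_idx)) {
      d_back <- sample(30:730, length(prec_idx), replace = TRUE)
      h_stays$prior <- data.frame(
        stay_id = sprintf("S%07d", stay_counter + seq_along(prec_idx)),
        patient_id = pid[prec_idx], hospital_id = h,
        admit_date = admit[prec_idx] - d_back,
        discharge_date = admit[prec_idx] - d_back,
        icd10_main = icd[prec_idx], care_type = "part_time_psychiatric",
        stringsAsFactors = FALSE
      )
      stay_counter <- stay_counter + length(prec_idx)
    }

    ## ---- community contacts ---------------------------------------------
    ## referral-pathway sharing: with probability `pathway` a patient follows
    ## the provider set of an earlier patient of the same hospital instead of
    ## sampling fresh providers; this concentrates co-occurrence and so drives
    ## the density/transitivity of the one-mode projection independently of
    ## contact volumes
    h_contacts <- list()
    contacted_gps <- vector("list", n_p)
    follows <- stats::runif(n_p) < pathway
    follow_of <- ifelse(follows & seq_len(n_p) > 1,
                        sapply(seq_len(n_p), function(i)
                          if (i > 1) sample.int(i - 1, 1) else i),
                        seq_len(n_p))
    for (ty in c("psychiatrist", "gp", "nurse")) {
      k <- pmin(stats::rpois(n_p, rates[[ty]]), pools[[ty]])
      tot <- sum(k)
      if (tot == 0) next
      chosen <- vector("list", n_p)
      for (i in seq_len(n_p)) {
        chosen[[i]] <- if (follow_of[i] < i && k[i] > 0) {
          prior <- chosen[[follow_of[i]]]
          if (length(prior) >= k[i]) prior[seq_len(k[i])]
          else unique(c(prior, sample.int(pools[[ty]], k[i])))[seq_len(k[i])]
        } else if (k[i] > 0) {
          sample.int(pools[[ty]], k[i])
        } else integer(0)
      }
      k <- lengths(chosen)
      tot <- sum(k)
      if (tot == 0) next
      if (ty == "gp") contacted_gps <- chosen
      prov_idx <- unlist(chosen)
      pat_rep <- rep(seq_len(n_p), k)
      nv <- 1 + stats::rpois(tot, visits_mean - 1)
      pat_all <- rep(pat_rep, nv)
      prov_all <- rep(prov_idx, nv)
      offs <- sample.int(fup, length(pat_all), replace = TRUE)
      h_contacts[[ty]] <- data.frame(
        patient_id = pid[pat_all],
        provider_id = pool_ids[[ty]][prov_all],
        date = discharge[pat_all] + offs,
        stringsAsFactors = FALSE
      )
    }

    ## ---- follow-up hospital admissions (day >= 16 so that the planted
    ## readmission outcome alone decides the 15-day indicator) --------------
    kh <- pmin(stats::rpois(n_p, rates[["hospital"]]), pools[["hospital"]])
    if (sum(kh) > 0) {
      chosen <- lapply(seq_len(n_p), function(i) {
        if (kh[i] == 0) return(integer(0))
        sample.int(pools[["hospital"]], kh[i])
      })
      prov_idx <- unlist(chosen)
      pat_rep <- rep(seq_len(n_p), kh)
      offs <- sample(16:fup, length(pat_rep), replace = TRUE)
      ct <- sample(c("full_time_psychiatric", "suicide_attempt", "emergency"),
                   length(pat_rep), replace = TRUE, prob = c(0.7, 0.15, 0.15))
      fu_icd <- ifelse(ct == "full_time_psychiatric", icd[pat_rep],
                       ifelse(ct == "suicide_attempt", "X60", "R69"))
      h_stays$followup <- data.frame(
        stay_id = sprintf("S%07d", stay_counter + seq_along(pat_rep)),
        patient_id = pid[pat_rep],
        hospital_id = pool_ids[["hospital"]][prov_idx],
        admit_date = discharge[pat_rep] + offs,
        discharge_date = discharge[pat_rep] + offs +
          sample(0:10, length(pat_rep), replace = TRUE),
        icd10_main = fu_icd, care_type = ct,
        stringsAsFactors = FALSE
      )
      stay_counter <- stay_counter + length(pat_rep)
    }

    ## ---- in-index ambulatory psychiatric contacts ------------------------
    s <- amb_share
    mu_amb <- if (s >= 1) 0 else
      s / (1 - s) * rates[["psychiatrist"]] * visits_mean
    n_amb <- stats::rpois(n_p, mu_amb)
    if (sum(n_amb) > 0) {
      pat_rep <- rep(seq_len(n_p), n_amb)
      h_contacts$index_amb <- data.frame(
        patient_id = pid[pat_rep], provider_id = h,
        date = discharge[pat_rep] +
          sample.int(fup, length(pat_rep), replace = TRUE),
        stringsAsFactors = FALSE
      )
    }

    ## ---- planted outcomes ------------------------------------------------
    xmat <- cbind(age_c = age - 40, sex_male = as.numeric(sex_male),
                  low_income = as.numeric(low_income),
                  precedence = as.numeric(precedence),
                  somatic_ltd = as.numeric(somatic))
    y <- sapply(QUALITY_INDICATORS, function(o) {
      eta <- log(base[[o]]) + latent[a, o]
      beta <- config$outcome_coefficients[[o]]
      if (!is.null(beta)) {
        eta <- eta + drop(xmat[, names(beta), drop = FALSE] %*% beta)
      }
      stats::runif(n_p) < pmin(exp(eta), 0.98)
    })

    ## readmission within 15 days of discharge, at the index hospital
    re_idx <- which(y[, "readmit_15d"])
    if (length(re_idx)) {
      r_off <- sample(1:15, length(re_idx), replace = TRUE)
      h_stays$readmit <- data.frame(
        stay_id = sprintf("S%07d", stay_counter + seq_along(re_idx)),
        patient_id = pid[re_idx], hospital_id = h,
        admit_date = discharge[re_idx] + r_off,
        discharge_date = discharge[re_idx] + r_off +
          sample(1:10, length(re_idx), replace = TRUE),
        icd10_main = icd[re_idx], care_type = "full_time_psychiatric",
        stringsAsFactors = FALSE
      )
      stay_counter <- stay_counter + length(re_idx)
    }

    ## referring physician: designate, then place/displace the 60-day contact
    ## designate from contacted GPs where possible; patients who contacted no
    ## GP get a pool designation only if GP contacts occur at all under this
    ## archetype, so a zero GP contact rate yields no GP rows anywhere
    designated <- stats::runif(n_p) < config$referring_designation_rate
    ref_gp <- rep(NA_character_, n_p)
    for (i in which(designated)) {
      if (length(contacted_gps[[i]])) {
        ref_gp[i] <- pool_ids$gp[contacted_gps[[i]][1]]
      } else if (rates[["gp"]] > 0) {
        ref_gp[i] <- pool_ids$gp[sample.int(pools[["gp"]], 1)]
      }
    }
    designated <- designated & !is.na(ref_gp)
    y_ref <- y[, "referring_contact_2m"] & designated
    add_idx <- which(y_ref)
    if (length(add_idx)) {
      h_contacts$referring <- data.frame(
        patient_id = pid[add_idx], provider_id = ref_gp[add_idx],
        date = discharge[add_idx] +
          sample(1:60, length(add_idx), replace = TRUE),
        stringsAsFactors = FALSE
      )
    }
    ## negatives: push any accidental referring-GP contact past day 60
    neg <- which(designated & !y_ref)
    if (length(neg)) {
      cc <- do.call(rbind, h_contacts[setdiff(names(h_contacts), "referring")])
      if (!is.null(cc) && nrow(cc)) {
        key <- paste(cc$patient_id, cc$provider_id)
        neg_key <- paste(pid[neg], ref_gp[neg])
        hit <- which(key %in% neg_key)
        if (length(hit)) {
          pi_of <- match(cc$patient_id[hit], pid)
          early <- as.numeric(cc$date[hit] - discharge[pi_of]) <= 60
          if (any(early)) {
            sel <- hit[early]
            cc$date[sel] <- discharge[match(cc$patient_id[sel], pid)] +
              sample(61:fup, length(sel), replace = TRUE)
            nm <- setdiff(names(h_contacts), "referring")
            sizes <- vapply(h_contacts[nm], nrow, integer(1))
            h_contacts[nm] <- split(cc, rep(nm, sizes))[nm]
          }
        }
      }
    }

    ## prevention procedures within two years of discharge
    tags <- config$prevention_tags
    prev_pos <- which(y[, "prevention_3proc_2y"])
    pr <- list()
    if (length(prev_pos)) {
      pr$pos <- data.frame(
        patient_id = rep(pid[prev_pos], each = 3),
        date = rep(discharge[prev_pos], each = 3) +
          sample.int(730, 3 * length(prev_pos), replace = TRUE),
        tag = rep(tags, times = length(prev_pos)),
        stringsAsFactors = FALSE
      )
    }
    prev_neg <- which(!y[, "prevention_3proc_2y"])
    if (length(prev_neg)) {
      n_proc <- sample(0:2, length(prev_neg), replace = TRUE)
      keep <- n_proc > 0
      if (any(keep)) {
        pat_rep <- rep(prev_neg[keep], n_proc[keep])
        tag_pick <- unlist(lapply(n_proc[keep], function(k) sample(tags, k)))
        pr$neg <- data.frame(
          patient_id = pid[pat_rep],
          date = discharge[pat_rep] +
            sample.int(730, length(pat_rep), replace = TRUE),
          tag = tag_pick,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(pr)) procedures[[h]] <- do.call(rbind, pr)

    ## antipsychotic deliveries within twelve months of discharge
    n_del <- ifelse(y[, "antipsychotic_9plus_12m"],
                    9 + stats::rpois(n_p, 1.5),
                    sample(0:8, n_p, replace = TRUE))
    if (sum(n_del) > 0) {
      pat_rep <- rep(seq_len(n_p), n_del)
      deliveries[[h]] <- data.frame(
        patient_id = pid[pat_rep],
        date = discharge[pat_rep] +
          sample.int(fup, length(pat_rep), replace = TRUE),
        antipsychotic = TRUE,
        stringsAsFactors = FALSE
      )
    }

    patients[[h]] <- data.frame(
      patient_id = pid, birth_year = birth_year,
      sex = ifelse(sex_male, "male", "female"),
      low_income = low_income, somatic_ltd = somatic,
      residence_zone = res_zone,
      referring_physician_id = ref_gp,
      stringsAsFactors = FALSE
    )
    stays[[h]] <- do.call(rbind, h_stays)
    contacts[[h]] <- do.call(rbind, h_contacts)
  }

  bind <- function(l) {
    out <- do.call(rbind, l)
    rownames(out) <- NULL
    out
  }
  empty_contacts <- data.frame(patient_id = character(0),
                               provider_id = character(0),
                               date = as.Date(character(0)),
                               stringsAsFactors = FALSE)
  structure(
    list(
      providers = bind(providers),
      patients = bind(patients),
      stays = bind(stays),
      contacts = if (length(contacts)) bind(contacts) else empty_contacts,
      deliveries = if (length(deliveries)) bind(deliveries) else
        data.frame(patient_id = character(0), date = as.Date(character(0)),
                   antipsychotic = logical(0)),
      procedures = if (length(procedures)) bind(procedures) else
        data.frame(patient_id = character(0), date = as.Date(character(0)),
                   tag = character(0))
    ),
    class = "claims_bundle",
    config = config
  )
}

#' @exportS3Method base::print
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-10s %7d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write / read a claims bundle as headered CSV tables
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @return `write_bundle` returns the file paths invisibly; `read_bundle`
#'   returns a `claims_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(bundle), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  tables <- c("providers", "patients", "stays", "contacts", "deliveries",
              "procedures")
  out <- lapply(tables, function(nm) {
    df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                          stringsAsFactors = FALSE)
    for (col in intersect(c("date", "admit_date", "discharge_date"),
                          names(df))) {
      df[[col]] <- as.Date(df[[col]])
    }
    df
  })
  names(out) <- tables
  structure(out, class = "claims_bundle")
}

#' Simulate clustered binary outcomes from a log-linear model
#'
#' A lightweight outcome-only simulator for relative-rate recovery and
#' confidence-interval coverage experiments: one binary exposure, a shared
#' cluster-level latent intercept on the log scale (exchangeable correlation),
#' and a marginal log-linear effect.
#'
#' @param n number of observations.
#' @param n_clusters number of equally sized clusters.
#' @param base_rate baseline outcome probability at exposure 0.
#' @param log_rr log relative rate of the exposure.
#' @param cluster_correlation within-cluster outcome correlation in `[0, 1)`.
#' @param exposure_prob probability of exposure.
#' @return data frame with columns `y`, `x`, `cluster`.
#' @export
simulate_outcome_data <- function(n, n_clusters, base_rate, log_rr,
                                  cluster_correlation = 0.05,
                                  exposure_prob = 0.5) {
  check_prob(base_rate, "base_rate")
  cl <- rep_len(seq_len(n_clusters), n)
  s2 <- latent_sigma2(cluster_correlation, base_rate)
  b <- stats::rnorm(n_clusters, -s2 / 2, sqrt(s2))
  x <- stats::rbinom(n, 1, exposure_prob)
  p <- pmin(base_rate * exp(log_rr * x + b[cl]), 0.98)
  data.frame(y = stats::rbinom(n, 1, p), x = x, cluster = cl)
}
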