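disc <- as.Date("2013-02-01")

test_that("15-day readmission boundary battery", {
  mkstay <- function(day, type = "full_time_psychiatric") {
    data.frame(admit_date = disc + day, care_type = type)
  }
  expect_true(indicator_readmission(disc, mkstay(14)))
  expect_true(indicator_readmission(disc, mkstay(15)))   # day 15 inclusive
  expect_false(indicator_readmission(disc, mkstay(16)))
  expect_false(indicator_readmission(disc, mkstay(10, "emergency")))
  empty_history <- data.frame(admit_date = as.Date(character(0)),
                              care_type = character(0))
  expect_false(indicator_readmission(disc, empty_history))
})

test_that("referring-physician 60-day boundary battery", {
  mk <- function(day, who = "GP1") data.frame(provider_id = who,
                                              date = disc + day)
  expect_true(indicator_referring_physician(disc, mk(59), "GP1"))
  expect_true(indicator_referring_physician(disc, mk(60), "GP1"))
  expect_false(indicator_referring_physician(disc, mk(61), "GP1"))
  ## wrong physician, or no designation on file
  expect_false(indicator_referring_physician(disc, mk(10, "GP9"), "GP1"))
  expect_false(indicator_referring_physician(disc, mk(10), NA))
})

test_that("prevention procedures: three distinct tags within 730 days", {
  mk <- function(tags, days) data.frame(tag = tags, date = disc + days)
  expect_true(indicator_prevention(disc, mk(c("P1", "P2", "P3"),
                                            c(100, 400, 700))))
  expect_true(indicator_prevention(disc, mk(c("P1", "P2", "P3"),
                                            c(1, 1, 730))))
  ## distinctness required
  expect_false(indicator_prevention(disc, mk(c("P1", "P1", "P2"),
                                             c(10, 20, 30))))
  ## boundary outside
  expect_false(indicator_prevention(disc, mk(c("P1", "P2", "P3"),
                                             c(100, 400, 731))))
  ## unknown tags are ignored (with a log message)
  expect_message(
    out <- indicator_prevention(disc, mk(c("P1", "P2", "XX"),
                                         c(10, 20, 30))),
    "XX")
  expect_false(out)
})

test_that("antipsychotic deliveries: nine in twelve months, same-day counted", {
  mk <- function(days) data.frame(date = disc + days, antipsychotic = TRUE)
  expect_true(indicator_antipsychotic(disc, mk(seq(10, 250, length.out = 9))))
  expect_false(indicator_antipsychotic(disc, mk(seq(10, 250, length.out = 8))))
  ## 9 deliveries but 2 beyond day 365
  expect_false(indicator_antipsychotic(disc, mk(c(seq(10, 200, length.out = 7),
                                                  370, 380))))
  ## same-day deliveries count separately
  expect_true(indicator_antipsychotic(disc, mk(rep(100, 9))))
  ## non-antipsychotic rows are ignored
  d <- mk(seq(10, 250, length.out = 9))
  d$antipsychotic[1] <- FALSE
  expect_false(indicator_antipsychotic(disc, d))
})

test_that("indicators are invariant under a common date shift", {
  set.seed(13)
  for (i in 1:10) {
    offs <- sort(sample(1:400, 12))
    shift <- sample(-500:500, 1)
    del <- data.frame(date = disc + offs, antipsychotic = TRUE)
    del2 <- data.frame(date = disc + shift + offs, antipsychotic = TRUE)
    expect_equal(indicator_antipsychotic(disc, del),
                 indicator_antipsychotic(disc + shift, del2))
    st <- data.frame(admit_date = disc + offs[1],
                     care_type = "full_time_psychiatric")
    st2 <- data.frame(admit_date = disc + shift + offs[1],
                      care_type = "full_time_psychiatric")
    expect_equal(indicator_readmission(disc, st),
                 indicator_readmission(disc + shift, st2))
  }
})

test_that("quality table is restricted to the psychotic subcohort", {
  b <- generate_bundle(small_config(seed = 21))
  co <- build_cohort(b)
  q <- quality_table(co, b)
  expect_setequal(q$patient_id,
                  co$patient_id[co$diagnosis_group == "psychotic"])
  for (ind in c("readmit_15d", "referring_contact_2m", "prevention_3proc_2y",
                "antipsychotic_9plus_12m")) {
    expect_type(q[[ind]], "logical")
  }
})

test_that("aggregation arithmetic and v-flags on a scripted fixture", {
  q <- data.frame(
    patient_id = sprintf("P%d", 1:40),
    network_id = rep(c("H1", "H2", "H3", "H4"), each = 10),
    readmit_15d = rep(c(TRUE, FALSE), c(10, 30)),
    referring_contact_2m = c(rep(c(TRUE, FALSE), c(4, 6)),
                             rep(c(TRUE, FALSE), c(6, 4)),
                             rep(TRUE, 10), rep(FALSE, 10)),
    prevention_3proc_2y = TRUE,
    antipsychotic_9plus_12m = FALSE,
    stringsAsFactors = FALSE
  )
  sol <- structure(list(labels = c(H1 = 1, H2 = 1, H3 = 2, H4 = 2)),
                   class = "cluster_solution")
  agg <- aggregate_quality(q, sol)
  bn <- agg$by_network
  expect_equal(bn$readmit_15d, c(100, 0, 0, 0))
  expect_equal(bn$referring_contact_2m, c(40, 60, 100, 0))
  ## cluster of networks at 40% and 60% -> mean 50, SD over network values
  bc <- agg$by_cluster
  row <- bc[bc$indicator == "referring_contact_2m" & bc$cluster == 1, ]
  expect_equal(row$mean_pct, 50)
  expect_equal(row$sd_pct, sd(c(40, 60)))
  ## all-true indicator: 100% with zero spread, v = 0 vs overall mean
  rowp <- bc[bc$indicator == "prevention_3proc_2y" & bc$cluster == 1, ]
  expect_equal(rowp$mean_pct, 100)
  expect_equal(rowp$sd_pct, 0)
  expect_equal(rowp$v_statistic, 0)
  expect_false(rowp$significant)
})

test_that("planted indicator rates are recovered within binomial error", {
  cfg <- scenario_config(
    n_index_hospitals = 4,
    archetype_assignment = c("A1", "A2", "A2", "A3"),
    n_patients_per_hospital = 700,
    outcome_base_rates = c(readmit_15d = 0.5, referring_contact_2m = 0.5,
                           prevention_3proc_2y = 0.5,
                           antipsychotic_9plus_12m = 0.5),
    cluster_correlation = 0,
    seed = 99
  )
  b <- generate_bundle(cfg)
  co <- build_cohort(b)
  q <- quality_table(co, b)
  n <- nrow(q)
  expect_gt(n, 1500)
  tol <- 3 * sqrt(0.25 / n)
  for (ind in c("readmit_15d", "referring_contact_2m", "prevention_3proc_2y",
                "antipsychotic_9plus_12m")) {
    expect_lt(abs(mean(q[[ind]]) - 0.5), tol + 0.005)
  }
})
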