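`%||%` <- function(x, y) if (is.null(x)) y else x

## Independent brute-force oracles used across the suite. They deliberately
## avoid the package's own graph code paths (and igraph) so that agreement is
## a real cross-check.

## density by exhaustive pair enumeration
bf_density <- function(nodes, edges) {
  n <- length(nodes)
  if (n < 2) return(NA_real_)
  present <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      hit <- any((edges$from == nodes[i] & edges$to == nodes[j]) |
                   (edges$from == nodes[j] & edges$to == nodes[i]))
      present <- present + hit
    }
  }
  100 * present / (n * (n - 1) / 2)
}

## global clustering coefficient by exhaustive triple enumeration
bf_transitivity <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    adj[edges$from[r], edges$to[r]] <- TRUE
    adj[edges$to[r], edges$from[r]] <- TRUE
  }
  triangles <- 0
  triples <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (i < j && j < k) {
          e <- adj[i, j] + adj[j, k] + adj[i, k]
          if (e == 3) triangles <- triangles + 1
        }
        ## connected triple centered at j: i-j and j-k links, i < k
        if (i < k && j != i && j != k && adj[i, j] && adj[j, k]) {
          triples <- triples + 1
        }
      }
    }
  }
  if (triples == 0) return(NA_real_)
  100 * 3 * triangles / triples
}

## node strengths by direct summation
bf_strengths <- function(nodes, edges) {
  s <- stats::setNames(numeric(length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    s[edges$from[r]] <- s[edges$from[r]] + edges$weight[r]
    s[edges$to[r]] <- s[edges$to[r]] + edges$weight[r]
  }
  s
}

## random sharing_network fixture with n nodes and edge probability p
random_network <- function(n, p = 0.4, weighted = TRUE) {
  ids <- c("IDX", sprintf("N%02d", seq_len(n - 1)))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      weight = if (weighted) sample(1:9, sum(keep), TRUE)
                      else rep(1, sum(keep)),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(provider_id = ids,
                      type = sample(c("hospital", "gp", "psychiatrist",
                                      "nurse"), n, TRUE),
                      stringsAsFactors = FALSE)
  structure(list(index_hospital_id = "IDX", nodes = nodes, links = edges),
            class = "sharing_network")
}

## brute-force distinct shared patients between every provider pair, from raw
## patient-provider event lists (set intersection per pair)
bf_pair_weights <- function(events) {
  sets <- split(events$patient_id, events$provider_id)
  provs <- sort(names(sets))
  out <- list()
  if (length(provs) >= 2) {
    for (i in seq_len(length(provs) - 1)) {
      for (j in (i + 1):length(provs)) {
        w <- length(intersect(unique(sets[[provs[i]]]),
                              unique(sets[[provs[j]]])))
        if (w > 0) {
          out[[length(out) + 1L]] <- data.frame(
            a = provs[i], b = provs[j], weight = w,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(a = character(0), b = character(0), weight = numeric(0))
}

## a tiny hand-assembled claims bundle for boundary tests: one index hospital,
## a handful of providers, fully scripted events
tiny_bundle <- function() {
  providers <- data.frame(
    provider_id = c("HX", "HY", "GP1", "GP2", "PSY1", "NUR1"),
    type = c("hospital", "hospital", "gp", "gp", "psychiatrist", "nurse"),
    zone = "Z1", in_region = TRUE,
    is_index = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    sectorized = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    military = FALSE,
    private = c(FALSE, TRUE, NA, NA, NA, NA),
    specialized = c(TRUE, NA, NA, NA, NA, NA),
    beds = c(100L, NA, NA, NA, NA, NA),
    catchment_population = c(100000L, NA, NA, NA, NA, NA),
    area_typology = c("strong_resources", NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  patients <- data.frame(
    patient_id = c("P1", "P2"),
    birth_year = c(1980L, 1970L),
    sex = c("male", "female"),
    low_income = c(FALSE, TRUE),
    somatic_ltd = c(FALSE, FALSE),
    residence_zone = c("Z1", "Z9"),
    referring_physician_id = c("GP1", NA),
    stringsAsFactors = FALSE
  )
  stays <- data.frame(
    stay_id = c("S1", "S2"),
    patient_id = c("P1", "P2"),
    hospital_id = "HX",
    admit_date = as.Date(c("2012-03-01", "2012-06-01")),
    discharge_date = as.Date(c("2012-03-20", "2012-06-15")),
    icd10_main = c("F200", "F322"),
    care_type = "full_time_psychiatric",
    stringsAsFactors = FALSE
  )
  contacts <- data.frame(
    patient_id = c("P1", "P1", "P2"),
    provider_id = c("GP1", "PSY1", "GP2"),
    date = as.Date(c("2012-04-01", "2012-05-01", "2012-07-01")),
    stringsAsFactors = FALSE
  )
  structure(
    list(providers = providers, patients = patients, stays = stays,
         contacts = contacts,
         deliveries = data.frame(patient_id = character(0),
                                 date = as.Date(character(0)),
                                 antipsychotic = logical(0)),
         procedures = data.frame(patient_id = character(0),
                                 date = as.Date(character(0)),
                                 tag = character(0))),
    class = "claims_bundle"
  )
}

## small scenario for fast end-to-end tests
small_config <- function(seed = 1) {
  scenario_config(
    n_index_hospitals = 6,
    archetype_assignment = c("A1", "A1", "A2", "A2", "A3", "A3"),
    n_patients_per_hospital = 60,
    seed = seed
  )
}
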