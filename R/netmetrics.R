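#' Network density (percent)
#'
#' Share of all possible undirected links actually present, on the unweighted
#' skeleton, no self-loops: `100 * m / (n * (n - 1) / 2)`.
#'
#' @param network a `sharing_network`.
#' @return percent in `[0, 100]`, or `NA` for networks with fewer than 2 nodes.
#' @export
net_density <- function(network) {
  n <- nrow(network$nodes)
  if (n < 2) return(NA_real_)
  100 * nrow(network$links) / (n * (n - 1) / 2)
}

#' Network transitivity / global clustering coefficient (percent)
#'
#' Probability that two providers connected to the same provider are also
#' connected: `100 * 3 * triangles / connected triples`, unweighted.
#'
#' @param network a `sharing_network`.
#' @return percent, or `NA` when the network has no connected triple.
#' @export
net_transitivity <- function(network) {
  if (nrow(network$links) < 2) return(NA_real_)
  t <- igraph::transitivity(as_igraph(network), type = "global")
  if (is.nan(t)) return(NA_real_)
  100 * t
}

#' Median weighted degree (strength)
#'
#' Per node, the sum of incident link weights; summarized at the network level
#' by the median over all nodes (index hospital included by default; an even
#' node count yields the mean of the two central order statistics).
#'
#' @param network a `sharing_network`.
#' @param include_index include the index hospital node in the median.
#' @return median strength.
#' @export
median_weighted_degree <- function(network, include_index = TRUE) {
  ids <- network$nodes$provider_id
  if (!include_index) ids <- setdiff(ids, network$index_hospital_id)
  if (length(ids) == 0) return(NA_real_)
  s <- stats::setNames(numeric(length(ids)), ids)
  for (side in c("from", "to")) {
    agg <- tapply(network$links$weight, network$links[[side]], sum)
    hit <- intersect(names(agg), ids)
    s[hit] <- s[hit] + agg[hit]
  }
  stats::median(s)
}

#' Compositional characteristics of a network
#'
#' Counts and percentages per provider type (index hospital excluded from the
#' type breakdown), community-professional rates per 100,000 adult inhabitants
#' of the index hospital's catchment, specialist and physician shares among
#' community professionals, and the private share among hospital providers
#' (index hospital included in the hospital denominator).
#'
#' @param network a `sharing_network`.
#' @param catchment_population adult population served by the index hospital.
#' @return named list of compositional fields (`NA` where a denominator is
#'   empty).
#' @export
network_composition <- function(network, catchment_population) {
  if (is.na(catchment_population) || catchment_population <= 0) {
    stop("catchment_population must be positive", call. = FALSE)
  }
  others <- network$nodes[network$nodes$provider_id !=
                            network$index_hospital_id, , drop = FALSE]
  n_other <- nrow(others)
  cnt <- vapply(PROVIDER_TYPES, function(t) sum(others$type == t), numeric(1))
  pct <- if (n_other > 0) 100 * cnt / n_other else
    stats::setNames(rep(NA_real_, length(cnt)), names(cnt))

  per100k <- 1e5 * cnt[c("psychiatrist", "gp", "nurse")] / catchment_population

  n_comm <- sum(cnt[c("psychiatrist", "gp", "nurse")])
  pct_specialists_among_community <- if (n_comm > 0)
    100 * cnt[["psychiatrist"]] / n_comm else NA_real_
  pct_physicians_among_community <- if (n_comm > 0)
    100 * (cnt[["psychiatrist"]] + cnt[["gp"]]) / n_comm else NA_real_

  hosp_nodes <- network$nodes[network$nodes$type == "hospital", , drop = FALSE]
  pct_private_hospitals <- if (nrow(hosp_nodes) > 0) {
    priv <- hosp_nodes$private
    priv[is.na(priv)] <- FALSE
    100 * sum(priv) / nrow(hosp_nodes)
  } else NA_real_

  list(
    n_providers = n_other,
    n_psychiatrists = cnt[["psychiatrist"]],
    n_gps = cnt[["gp"]],
    n_nurses = cnt[["nurse"]],
    n_hospitals = cnt[["hospital"]],
    pct_psychiatrists = pct[["psychiatrist"]],
    pct_gps = pct[["gp"]],
    pct_nurses = pct[["nurse"]],
    pct_hospitals = pct[["hospital"]],
    per100k_psychiatrists = per100k[["psychiatrist"]],
    per100k_gps = per100k[["gp"]],
    per100k_nurses = per100k[["nurse"]],
    pct_specialists_among_community = pct_specialists_among_community,
    pct_physicians_among_community = pct_physicians_among_community,
    pct_private_hospitals = pct_private_hospitals
  )
}

#' Loyalty index of an index hospital
#'
#' Share of the hospital's index patients residing in its official catchment
#' area, with the banding used as an illustrative typology variable: `> 80%`,
#' `[60-80%]` (closed: 60 and 80 both belong to the middle band), `< 60%`.
#'
#' @param index_hospital_id hospital id.
#' @param cohort cohort table.
#' @param patients patient table (residence zones).
#' @param catchment_map named list or vector mapping hospital id to the
#'   zone(s) of its catchment area.
#' @return list with `loyalty_pct` and `loyalty_band`.
#' @export
loyalty_index <- function(index_hospital_id, cohort, patients, catchment_map) {
  if (!index_hospital_id %in% names(catchment_map)) {
    stop(sprintf("hospital %s absent from catchment map", index_hospital_id),
         call. = FALSE)
  }
  sub <- cohort[cohort$index_hospital_id == index_hospital_id, , drop = FALSE]
  zones <- patients$residence_zone[match(sub$patient_id, patients$patient_id)]
  if (anyNA(zones)) {
    stop("every index patient needs a residence zone", call. = FALSE)
  }
  pct <- 100 * mean(zones %in% catchment_map[[index_hospital_id]])
  band <- if (pct > 80) ">80%" else if (pct >= 60) "[60-80%]" else "<60%"
  list(loyalty_pct = pct, loyalty_band = band)
}

#' Contact-intensity context metrics of a network
#'
#' * `pct_ambulatory_index`: index-hospital ambulatory psychiatric contacts as
#'   a percentage of all specialized ambulatory contacts (index-hospital
#'   ambulatory + community psychiatrist visits) within follow-up windows.
#' * `avg_contacts_per_patient`: all in-window contacts (community visits,
#'   in-index ambulatory contacts and follow-up admissions) averaged over all
#'   cohort patients of the network, zero-contact patients included.
#'
#' @param index_hospital_id hospital id.
#' @param cohort cohort table.
#' @param contacts community-contact table.
#' @param stays stay table.
#' @param providers provider table.
#' @param follow_up_days follow-up window in days.
#' @return list with `pct_ambulatory_index` and `avg_contacts_per_patient`.
#' @export
context_metrics <- function(index_hospital_id, cohort, contacts, stays,
                            providers, follow_up_days = 365) {
  sub <- cohort[cohort$index_hospital_id == index_hospital_id, , drop = FALSE]
  n_pat <- nrow(sub)
  if (n_pat == 0) {
    return(list(pct_ambulatory_index = NA_real_,
                avg_contacts_per_patient = NA_real_))
  }
  discharge <- stats::setNames(as.Date(sub$discharge_date), sub$patient_id)

  cc <- contacts[contacts$patient_id %in% sub$patient_id, , drop = FALSE]
  d <- as.numeric(as.Date(cc$date) - discharge[cc$patient_id])
  cc <- cc[d >= 1 & d <= follow_up_days, , drop = FALSE]

  st <- stays[stays$patient_id %in% sub$patient_id &
                stays$hospital_id != index_hospital_id &
                stays$care_type %in% c("full_time_psychiatric",
                                       "part_time_psychiatric",
                                       "suicide_attempt", "emergency"), ,
              drop = FALSE]
  ds <- as.numeric(as.Date(st$admit_date) - discharge[st$patient_id])
  st <- st[ds >= 1 & ds <= follow_up_days, , drop = FALSE]

  ptype <- stats::setNames(providers$type, providers$provider_id)
  in_index_amb <- sum(cc$provider_id == index_hospital_id)
  psy_visits <- sum(ptype[cc$provider_id] == "psychiatrist", na.rm = TRUE)
  denom <- in_index_amb + psy_visits
  pct_amb <- if (denom > 0) 100 * in_index_amb / denom else NA_real_

  list(
    pct_ambulatory_index = pct_amb,
    avg_contacts_per_patient = (nrow(cc) + nrow(st)) / n_pat
  )
}

#' Assemble the profile matrix of a set of networks
#'
#' One row per network, combining structural, compositional and contextual
#' characteristics; the typology's input.
#'
#' @param networks named list of `sharing_network` objects.
#' @param cohort cohort table.
#' @param bundle a `claims_bundle`.
#' @param catchment_map hospital to catchment-zone map; default: each index
#'   hospital's own zone from the provider table.
#' @param follow_up_days follow-up window in days.
#' @return data frame of class `network_profiles`, one row per network.
#' @export
network_profiles <- function(networks, cohort, bundle, catchment_map = NULL,
                             follow_up_days = 365) {
  providers <- bundle$providers
  if (is.null(catchment_map)) {
    idx <- providers[providers$is_index %||% FALSE, , drop = FALSE]
    catchment_map <- stats::setNames(as.list(idx$zone), idx$provider_id)
  }
  rows <- lapply(networks, function(net) {
    h <- net$index_hospital_id
    hrow <- providers[providers$provider_id == h, , drop = FALSE]
    comp <- network_composition(net, hrow$catchment_population)
    loy <- loyalty_index(h, cohort, bundle$patients, catchment_map)
    ctx <- context_metrics(h, cohort, bundle$contacts, bundle$stays,
                           providers, follow_up_days)
    data.frame(
      network_id = h,
      density = net_density(net),
      transitivity = net_transitivity(net),
      median_weighted_degree = median_weighted_degree(net),
      n_links = nrow(net$links),
      index_specialized = isTRUE(hrow$specialized),
      index_beds = hrow$beds,
      area_typology = hrow$area_typology,
      comp,
      loyalty_pct = loy$loyalty_pct,
      loyalty_band = loy$loyalty_band,
      pct_ambulatory_index = ctx$pct_ambulatory_index,
      avg_contacts_per_patient = ctx$avg_contacts_per_patient,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("network_profiles", "data.frame")
  out
}
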