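#' Count shared patients between the index hospital and other providers
#'
#' For each index hospital, counts the number of *distinct* cohort patients
#' shared with every other provider, and between every pair of such providers,
#' within each patient's personal one-year post-discharge window. Eligible
#' events are community contacts (psychiatrists, GPs, nurses) with in-region
#' providers, and admissions to other hospitals for psychiatric care, suicide
#' attempts or emergency care. Contacts with the index hospital itself create
#' no links (they feed the ambulatory-share metric instead); contacts outside
#' the window are ignored and tallied in the returned log summary.
#'
#' @param cohort cohort table from [build_cohort()].
#' @param contacts community-contact table (`patient_id`, `provider_id`,
#'   `date`).
#' @param stays inpatient-stay table.
#' @param providers provider table.
#' @param follow_up_days window length in days after index discharge.
#' @return object of class `pair_counts`: list with `index_links`
#'   (index_hospital_id, provider_id, provider_type, n_shared),
#'   `incidence` (distinct patient-provider pairs, kept for secondary-link
#'   computation), and `log` (counts of ignored events).
#' @export
count_shared_patients <- function(cohort, contacts, stays, providers,
                                  follow_up_days = 365) {
  ptype <- stats::setNames(providers$type, providers$provider_id)
  in_region <- stats::setNames(providers$in_region, providers$provider_id)
  discharge <- stats::setNames(as.Date(cohort$discharge_date),
                               cohort$patient_id)
  index_of <- stats::setNames(cohort$index_hospital_id, cohort$patient_id)

  ## community contact events
  cc <- contacts[contacts$patient_id %in% cohort$patient_id, , drop = FALSE]
  ev_contact <- data.frame(
    patient_id = cc$patient_id,
    provider_id = cc$provider_id,
    date = as.Date(cc$date),
    stringsAsFactors = FALSE
  )

  ## eligible hospital admissions (any hospital except handled below)
  st <- stays[stays$patient_id %in% cohort$patient_id &
                stays$care_type %in% c("full_time_psychiatric",
                                       "part_time_psychiatric",
                                       "suicide_attempt", "emergency"), ,
              drop = FALSE]
  ev_stay <- data.frame(
    patient_id = st$patient_id,
    provider_id = st$hospital_id,
    date = as.Date(st$admit_date),
    stringsAsFactors = FALSE
  )

  ev <- rbind(ev_contact, ev_stay)

  ## events at the patient's own index hospital never create links (the
  ## index stay itself, readmissions there, in-index ambulatory contacts)
  self <- ev$provider_id == index_of[ev$patient_id]
  n_self <- sum(self)
  ev <- ev[!self, , drop = FALSE]

  d <- as.numeric(ev$date - discharge[ev$patient_id])
  in_window <- d >= 1 & d <= follow_up_days
  n_out_of_window <- sum(!in_window)
  ev <- ev[in_window, , drop = FALSE]

  region <- in_region[ev$provider_id]
  region[is.na(region)] <- FALSE
  n_out_of_region <- sum(!region)
  ev <- ev[region, , drop = FALSE]

  ## distinct patient-provider incidence
  inc <- unique(ev[, c("patient_id", "provider_id")])
  inc$index_hospital_id <- index_of[inc$patient_id]

  agg <- stats::aggregate(
    list(n_shared = inc$patient_id),
    by = list(index_hospital_id = inc$index_hospital_id,
              provider_id = inc$provider_id),
    FUN = length
  )
  agg$provider_type <- unname(ptype[agg$provider_id])
  agg <- agg[order(agg$index_hospital_id, agg$provider_id), ]
  rownames(agg) <- NULL

  structure(
    list(
      index_links = agg,
      incidence = inc,
      log = c(out_of_window = n_out_of_window,
              index_self_contacts = n_self,
              out_of_region = n_out_of_region)
    ),
    class = "pair_counts"
  )
}

#' Compute per-provider-type retention thresholds
#'
#' For each provider type, the threshold is the third quartile (linear
#' interpolation between order statistics) of the distribution of shared
#' patient counts between index hospitals and providers of that type, pooled
#' across all index hospitals. Retention downstream requires a count *strictly
#' greater* than the threshold. A per-network pooling variant is available.
#'
#' @param pair_counts a `pair_counts` object.
#' @param pooled if `TRUE` (default), one region-wide threshold per type; if
#'   `FALSE`, thresholds computed within each index hospital's own link
#'   distribution (returned as a matrix hospital x type).
#' @return named numeric vector of thresholds per provider type (class
#'   `threshold_set`), or a matrix when `pooled = FALSE`.
#' @export
compute_thresholds <- function(pair_counts, pooled = TRUE) {
  il <- pair_counts$index_links
  if (pooled) {
    q <- tapply(il$n_shared, il$provider_type, third_quartile)
    out <- stats::setNames(as.numeric(q), names(q))
    class(out) <- "threshold_set"
    return(out)
  }
  hosps <- unique(il$index_hospital_id)
  types <- unique(il$provider_type)
  m <- matrix(NA_real_, length(hosps), length(types),
              dimnames = list(hosps, types))
  for (h in hosps) {
    sub <- il[il$index_hospital_id == h, ]
    q <- tapply(sub$n_shared, sub$provider_type, third_quartile)
    m[h, names(q)] <- as.numeric(q)
  }
  m
}

#' Force all retention thresholds to zero
#'
#' Used by the no-threshold sensitivity analysis: every provider sharing at
#' least one patient is retained.
#'
#' @param pair_counts a `pair_counts` object (supplies the type set).
#' @return a zero `threshold_set`.
#' @export
zero_thresholds <- function(pair_counts) {
  types <- unique(pair_counts$index_links$provider_type)
  out <- stats::setNames(rep(0, length(types)), types)
  class(out) <- "threshold_set"
  out
}

#' Build the patient-sharing network of one index hospital
#'
#' Nodes are the index hospital plus every provider whose shared-patient count
#' with the index hospital strictly exceeds its type's threshold. Links are the
#' index-hospital links of retained providers plus all provider-provider links
#' (weight = distinct shared patients, at least 1) among retained providers;
#' secondary links are not thresholded.
#'
#' @param index_hospital_id the hospital the network is centered on.
#' @param pair_counts a `pair_counts` object.
#' @param thresholds a `threshold_set` (or a named numeric vector).
#' @param providers provider table (node attributes).
#' @return object of class `sharing_network`: list with `index_hospital_id`,
#'   `nodes` (id, type, attributes) and `links` (from, to, weight).
#' @export
build_network <- function(index_hospital_id, pair_counts, thresholds,
                          providers) {
  il <- pair_counts$index_links
  il <- il[il$index_hospital_id == index_hospital_id, , drop = FALSE]
  q <- thresholds[il$provider_type]
  q[is.na(q)] <- Inf  # type with no threshold: nothing retained
  retained <- il[il$n_shared > q, , drop = FALSE]

  if (nrow(retained) == 0) {
    message(sprintf("network %s: no provider passes its threshold",
                    index_hospital_id))
  }

  node_ids <- c(index_hospital_id, retained$provider_id)
  nodes <- providers[match(node_ids, providers$provider_id),
                     intersect(c("provider_id", "type", "zone", "in_region",
                                 "is_index", "private", "specialized", "beds",
                                 "catchment_population", "area_typology"),
                               names(providers)), drop = FALSE]
  rownames(nodes) <- NULL

  links <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (nrow(retained)) {
    links <- data.frame(from = index_hospital_id, to = retained$provider_id,
                        weight = retained$n_shared, stringsAsFactors = FALSE)
    ## secondary links among retained providers via sparse cross-product of
    ## the distinct patient-provider incidence
    inc <- pair_counts$incidence
    inc <- inc[inc$index_hospital_id == index_hospital_id &
                 inc$provider_id %in% retained$provider_id, , drop = FALSE]
    if (nrow(inc)) {
      pats <- unique(inc$patient_id)
      provs <- sort(unique(inc$provider_id))
      m <- Matrix::sparseMatrix(
        i = match(inc$patient_id, pats),
        j = match(inc$provider_id, provs),
        x = 1,
        dims = c(length(pats), length(provs))
      )
      w <- Matrix::crossprod(m)
      w <- Matrix::triu(w, k = 1)
      sm <- Matrix::summary(w)
      sm <- sm[sm$x > 0, , drop = FALSE]
      if (nrow(sm)) {
        links <- rbind(links, data.frame(
          from = provs[sm$i], to = provs[sm$j], weight = as.numeric(sm$x),
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  rownames(links) <- NULL
  structure(
    list(index_hospital_id = index_hospital_id, nodes = nodes, links = links),
    class = "sharing_network"
  )
}

#' Build all patient-sharing networks of a run
#'
#' @param cohort cohort table.
#' @param bundle a `claims_bundle` (or list with the same tables).
#' @param thresholds optional precomputed `threshold_set`; default: pooled
#'   third-quartile thresholds from the data.
#' @param follow_up_days follow-up window in days.
#' @return list with `networks` (named list of `sharing_network`),
#'   `pair_counts` and `thresholds`.
#' @export
build_networks <- function(cohort, bundle, thresholds = NULL,
                           follow_up_days = 365) {
  pc <- count_shared_patients(cohort, bundle$contacts, bundle$stays,
                              bundle$providers, follow_up_days)
  if (is.null(thresholds)) thresholds <- compute_thresholds(pc)
  hosps <- sort(unique(cohort$index_hospital_id))
  nets <- lapply(hosps, build_network, pair_counts = pc,
                 thresholds = thresholds, providers = bundle$providers)
  names(nets) <- hosps
  list(networks = nets, pair_counts = pc, thresholds = thresholds)
}

#' @exportS3Method base::print
print.sharing_network <- function(x, ...) {
  cat(sprintf("<sharing_network> index hospital %s: %d providers, %d links\n",
              x$index_hospital_id, nrow(x$nodes) - 1L, nrow(x$links)))
  invisible(x)
}

#' Convert a sharing network to an igraph graph
#'
#' @param network a `sharing_network`.
#' @return an undirected weighted [igraph::graph].
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$links,
    directed = FALSE,
    vertices = network$nodes
  )
}

#' Export a sharing network
#'
#' Writes the network as GraphML (node attributes preserved) and as a
#' three-column weighted edge list (`node_a`, `node_b`, `weight`).
#'
#' @param network a `sharing_network`.
#' @param graphml_path,edgelist_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
export_network <- function(network, graphml_path = NULL,
                           edgelist_path = NULL) {
  written <- character(0)
  if (!is.null(graphml_path)) {
    g <- as_igraph(network)
    ## GraphML cannot carry NA logicals/numbers: stringify attributes
    for (at in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, at)
      if (!is.character(v)) {
        igraph::vertex_attr(g, at) <- ifelse(is.na(v), "", as.character(v))
      }
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(edgelist_path)) {
    el <- network$links
    names(el) <- c("node_a", "node_b", "weight")
    utils::write.table(el, edgelist_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, edgelist_path)
  }
  invisible(written)
}
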