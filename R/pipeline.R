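#' Validate a claims bundle
#'
#' Report-only checks: schema (required columns), foreign keys (every
#' patient/provider referenced in stays, contacts, deliveries resolves),
#' date sanity (discharge >= admission, parseable dates), and enumerated
#' categories (provider types). Each violation is one row.
#'
#' @param bundle a `claims_bundle` or list with the same tables.
#' @return data frame with columns `table`, `row`, `problem` (zero rows when
#'   the bundle is clean).
#' @export
validate_tables <- function(bundle) {
  v <- list()
  note <- function(table, row, problem) {
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row,
                                       problem = problem,
                                       stringsAsFactors = FALSE)
  }

  schema <- list(
    providers = c("provider_id", "type", "in_region"),
    patients = c("patient_id", "birth_year", "sex", "residence_zone"),
    stays = c("patient_id", "hospital_id", "admit_date", "discharge_date",
              "icd10_main", "care_type"),
    contacts = c("patient_id", "provider_id", "date"),
    deliveries = c("patient_id", "date"),
    procedures = c("patient_id", "date", "tag")
  )
  for (tab in names(schema)) {
    df <- bundle[[tab]]
    if (is.null(df)) {
      note(tab, NA_integer_, "table missing")
      next
    }
    miss <- setdiff(schema[[tab]], names(df))
    if (length(miss)) {
      note(tab, NA_integer_, paste("missing column(s):",
                                   paste(miss, collapse = ", ")))
    }
  }
  if (nrow(do.call(rbind, v) %||% data.frame()) > 0) {
    return(do.call(rbind, v))
  }

  pid <- bundle$patients$patient_id
  prid <- bundle$providers$provider_id

  bad <- which(!bundle$providers$type %in% PROVIDER_TYPES)
  for (i in bad) note("providers", i,
                      paste("unknown provider type:",
                            bundle$providers$type[i]))

  fk <- function(tab, col, universe, what) {
    vals <- bundle[[tab]][[col]]
    bad <- which(!is.na(vals) & !vals %in% universe)
    for (i in bad) note(tab, i, sprintf("unknown %s: %s", what, vals[i]))
  }
  fk("stays", "patient_id", pid, "patient")
  fk("stays", "hospital_id", prid, "provider")
  fk("contacts", "patient_id", pid, "patient")
  fk("contacts", "provider_id", prid, "provider")
  fk("deliveries", "patient_id", pid, "patient")
  fk("procedures", "patient_id", pid, "patient")

  adm <- as.Date(bundle$stays$admit_date)
  dis <- as.Date(bundle$stays$discharge_date)
  bad <- which(!is.na(adm) & !is.na(dis) & dis < adm)
  for (i in bad) note("stays", i, "discharge before admission")
  bad <- which(is.na(adm) | is.na(dis))
  for (i in bad) note("stays", i, "unparseable date")

  out <- do.call(rbind, v) %||%
    data.frame(table = character(0), row = integer(0),
               problem = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Stage order: data (synthetic generation or a supplied bundle) -> validation
#' -> cohort -> networks (quartile-thresholded patient sharing) -> profiles ->
#' typology -> quality indicators -> relative-rate models, with an optional
#' no-threshold sensitivity replication. When `out_dir` is given every stage's
#' outputs are written (delimited tables, GraphML + edge lists, a JSON
#' manifest with checksums).
#'
#' @param config a [scenario_config()], or the path to a YAML file, used when
#'   no `bundle` is supplied.
#' @param bundle optionally, a pre-built `claims_bundle` (user-supplied
#'   tables); `config` is then only consulted for window settings if it is a
#'   `scenario_config`.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param thresholds optional fixed `threshold_set` (default: pooled
#'   third-quartile rule).
#' @param sensitivity also run the no-threshold sensitivity analysis.
#' @param cluster_on working-correlation unit for the models.
#' @param k_range candidate cluster counts for the typology.
#' @return object of class `pipeline_result` with every stage's output and a
#'   `manifest`.
#' @export
run_all <- function(config = scenario_config(), bundle = NULL, out_dir = NULL,
                    thresholds = NULL, sensitivity = FALSE,
                    cluster_on = "cluster", k_range = 2:6) {
  if (is.character(config)) config <- read_scenario_config(config)
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    now <- Sys.time()
    timings[stage] <<- round(as.numeric(now - t0, units = "secs"), 3)
    t0 <<- now
  }

  if (is.null(bundle)) {
    bundle <- generate_bundle(config)
    tick("simulate")
  }
  fup <- if (inherits(config, "scenario_config")) config$follow_up_days else 365
  idx_years <- if (inherits(config, "scenario_config")) config$index_years
               else c(2012, 2013)
  tags <- if (inherits(config, "scenario_config")) config$prevention_tags
          else c("P1", "P2", "P3")

  violations <- validate_tables(bundle)
  if (nrow(violations)) {
    stop(sprintf(
      "stage validate: %d schema violation(s); first: %s row %s: %s",
      nrow(violations), violations$table[1], violations$row[1],
      violations$problem[1]), call. = FALSE)
  }
  tick("validate")

  cohort <- build_cohort(bundle, index_years = idx_years)
  tick("cohort")

  nb <- build_networks(cohort, bundle, thresholds = thresholds,
                       follow_up_days = fup)
  tick("networks")

  profiles <- network_profiles(nb$networks, cohort, bundle,
                               follow_up_days = fup)
  tick("profiles")

  pruned <- prune_correlated(profiles)
  pca <- run_pca(profiles, pruned$kept)
  solution <- cluster_networks(pca, k_range = k_range)
  characterization <- characterize_clusters(profiles, solution)
  tick("typology")

  qrows <- quality_table(cohort, bundle, tags = tags)
  qagg <- aggregate_quality(qrows, solution)
  tick("quality")

  models <- fit_quality_models(qrows, cohort, profiles, solution,
                               cluster_on = cluster_on)
  tick("models")

  result <- structure(
    list(
      bundle = bundle, cohort = cohort,
      pair_counts = nb$pair_counts, thresholds = nb$thresholds,
      networks = nb$networks, profiles = profiles,
      pruned = pruned, pca = pca, solution = solution,
      characterization = characterization,
      quality = qrows, quality_summary = qagg,
      models = models,
      follow_up_days = fup, prevention_tags = tags,
      config = if (inherits(config, "scenario_config")) config else NULL
    ),
    class = "pipeline_result"
  )

  if (sensitivity) {
    result$sensitivity <- sensitivity_no_threshold(result)
    tick("sensitivity")
  }

  result$manifest <- list(
    seed = if (!is.null(result$config)) result$config$seed else NA,
    n_networks = length(nb$networks),
    selected_k = solution$k,
    stage_timings_s = as.list(timings),
    warnings = list()
  )

  if (!is.null(out_dir)) {
    result$manifest$outputs <- write_pipeline_outputs(result, out_dir)
  }
  result
}

#' @exportS3Method base::print
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d patients, %d networks, typology k = %d\n",
    nrow(x$cohort), length(x$networks), x$solution$k))
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)

  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(
    w(result$cohort, "cohort.csv"),
    w(result$pair_counts$index_links, "pair_counts.csv"),
    w(data.frame(provider_type = names(result$thresholds),
                 q3 = as.numeric(result$thresholds)), "thresholds.csv"),
    w(result$profiles, "network_profiles.csv"),
    w(data.frame(network_id = names(result$solution$labels),
                 cluster = as.integer(result$solution$labels)),
      "cluster_assignments.csv"),
    w(result$solution$ari_by_k, "ari_by_k.csv"),
    w(result$characterization$v_tests, "cluster_v_tests.csv"),
    w(data.frame(cluster = names(result$solution$parangons),
                 parangon = result$solution$parangons), "parangons.csv"),
    w(result$quality, "quality_rows.csv"),
    w(result$quality_summary$by_network, "quality_by_network.csv"),
    w(result$quality_summary$by_cluster, "quality_by_cluster.csv"),
    w(model_results_table(result$models), "model_results.csv")
  )
  dend <- file.path(out_dir, "dendrogram.nwk")
  export_dendrogram(result$solution, dend)
  paths <- c(paths, dend)

  for (net in result$networks) {
    gp <- file.path(net_dir, paste0(net$index_hospital_id, ".graphml"))
    ep <- file.path(net_dir, paste0(net$index_hospital_id, "_edges.tsv"))
    export_network(net, gp, ep)
    paths <- c(paths, gp, ep)
  }
  if (!is.null(result$sensitivity)) {
    paths <- c(paths,
               w(result$sensitivity$comparison, "sensitivity_comparison.csv"))
  }

  inventory <- data.frame(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE
  )
  manifest <- result$manifest
  manifest$outputs <- inventory
  manifest$config <- if (!is.null(result$config)) {
    cfg <- unclass(result$config)
    cfg$archetypes <- NULL  # summarized by assignment; full params in code
    cfg
  } else NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  inventory
}
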