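#' Default quantitative candidate variables for the typology
#'
#' `candidates` is the quantitative set submitted to correlation pruning
#' before the PCA (size and type-share measures echoing the candidates enter
#' the cluster description instead); `priority` orders the preferred
#' representatives of correlated groups, the least noisy first (density for
#' the size/cohesion group, then the contact-pattern shares); `description`
#' is the wider variable set used when characterizing clusters.
#'
#' @return list with `candidates`, `priority` and `description` vectors.
#' @export
typology_variables <- function() {
  list(
    candidates = c(
      "density", "median_weighted_degree",
      "per100k_psychiatrists", "per100k_gps", "pct_hospitals",
      "pct_physicians_among_community", "pct_private_hospitals",
      "pct_ambulatory_index", "avg_contacts_per_patient"
    ),
    priority = c(
      "pct_ambulatory_index", "avg_contacts_per_patient", "density",
      "median_weighted_degree", "per100k_psychiatrists", "per100k_gps",
      "pct_physicians_among_community", "pct_hospitals",
      "pct_private_hospitals"
    ),
    description = c(
      "density", "transitivity", "n_providers", "n_links", "index_beds",
      "median_weighted_degree",
      "per100k_psychiatrists", "per100k_gps", "per100k_nurses",
      "pct_psychiatrists", "pct_gps", "pct_nurses", "pct_hospitals",
      "pct_specialists_among_community", "pct_physicians_among_community",
      "pct_private_hospitals", "pct_ambulatory_index",
      "avg_contacts_per_patient"
    )
  )
}

## shared greedy correlation pruning; kept variables are scanned in priority
## order, a candidate is dropped when |r| with an already-kept variable
## exceeds the threshold
prune_by_correlation <- function(data, vars, r_threshold, priority = NULL) {
  vars <- intersect(vars, names(data))
  constant <- vars[vapply(vars, function(v) {
    all(is.na(data[[v]])) ||
      isTRUE(stats::sd(data[[v]], na.rm = TRUE) == 0)
  }, logical(1))]
  if (length(constant)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(constant, collapse = ", ")))
    vars <- setdiff(vars, constant)
  }
  ordered <- c(intersect(priority %||% character(0), vars),
               setdiff(vars, priority %||% character(0)))
  cm <- abs(stats::cor(as.matrix(data[ordered]), use = "pairwise.complete.obs"))
  kept <- character(0)
  dropped <- list()
  for (v in ordered) {
    conflict <- kept[cm[v, kept] > r_threshold]
    if (length(conflict)) {
      dropped[[v]] <- conflict[1]
    } else {
      kept <- c(kept, v)
    }
  }
  list(
    kept = kept,
    dropped = if (length(dropped))
      data.frame(dropped = names(dropped),
                 correlated_with = unlist(dropped),
                 row.names = NULL, stringsAsFactors = FALSE)
    else data.frame(dropped = character(0), correlated_with = character(0))
  )
}

#' Prune highly correlated profile variables before the PCA
#'
#' Greedily drops variables whose absolute pairwise correlation with an
#' already-kept variable exceeds `r_threshold`, keeping one representative per
#' correlated group (preference order from `priority`). Constant variables are
#' dropped with a warning.
#'
#' @param profiles `network_profiles` data frame.
#' @param vars candidate quantitative variables (default
#'   [typology_variables()]).
#' @param r_threshold absolute-correlation cutoff, default 0.7.
#' @param priority preferred representatives, scanned first.
#' @return list with `kept` (the active variable set) and `dropped` (a
#'   dropped-to-kept report).
#' @export
prune_correlated <- function(profiles, vars = NULL, r_threshold = 0.7,
                             priority = NULL) {
  tv <- typology_variables()
  prune_by_correlation(profiles, vars %||% tv$candidates, r_threshold,
                       priority %||% tv$priority)
}

#' Principal component analysis of network profiles
#'
#' Active quantitative variables are standardized (zero mean, unit variance)
#' and decomposed with [stats::prcomp()]; qualitative illustrative variables
#' are projected afterwards as per-category centroids in component space and
#' never influence the axes.
#'
#' @param profiles `network_profiles` data frame.
#' @param active_vars character vector of active variables.
#' @param illustrative_vars character vector of qualitative variables to
#'   project (default: `area_typology`, `loyalty_band`, `index_specialized`).
#' @return object of class `net_pca`: `scores` (networks x components),
#'   `loadings`, `eig` (component variances), `var_explained` (shares),
#'   `illustrative` (per-category centroid coordinates).
#' @export
run_pca <- function(profiles, active_vars,
                    illustrative_vars = c("area_typology", "loyalty_band",
                                          "index_specialized")) {
  if (nrow(profiles) < 3) {
    stop("at least 3 networks are required for the PCA", call. = FALSE)
  }
  x <- as.matrix(profiles[active_vars])
  if (anyNA(x)) {
    ## mean imputation keeps rare missing metrics (e.g. undefined transitivity
    ## in a degenerate network) from dropping the whole network
    for (j in seq_len(ncol(x))) {
      x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  if (length(active_vars) > nrow(profiles)) {
    warning("more active variables than networks: rank-limited decomposition")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x
  rownames(scores) <- profiles$network_id
  eig <- pc$sdev^2

  illustrative_vars <- intersect(illustrative_vars, names(profiles))
  illustrative <- lapply(illustrative_vars, function(v) {
    vals <- as.character(profiles[[v]])
    cats <- sort(unique(vals))
    cent <- t(vapply(cats, function(cat) {
      colMeans(scores[vals == cat, , drop = FALSE])
    }, numeric(ncol(scores))))
    rownames(cent) <- cats
    cent
  })
  names(illustrative) <- illustrative_vars

  structure(
    list(
      scores = scores,
      loadings = pc$rotation,
      eig = eig,
      var_explained = eig / sum(eig),
      center = pc$center,
      scale = pc$scale,
      active_vars = active_vars,
      illustrative = illustrative
    ),
    class = "net_pca"
  )
}

## mean silhouette width of a partition given a full distance matrix
mean_silhouette <- function(dm, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dm[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b cluster label vectors over the same objects.
#' @return the adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}

#' Cluster networks on principal components with a robustness check
#'
#' Ward hierarchical clustering (on Euclidean distances over the retained
#' components) provides the candidate partition at each `k`; average-link
#' clustering and k-means partitions are computed at the same `k`. A `k` is
#' admissible when its partition is method-robust (mean pairwise adjusted
#' Rand among the three methods at least `ari_floor`) and every cluster has
#' at least `min_cluster_size` members; among admissible `k` the best mean
#' silhouette width of the Ward partition is selected (ties toward the
#' smallest `k`). Final labels come
#' from the Ward partition. Components retained: all with eigenvalue >= 1
#' (Kaiser rule) unless `n_components` is given.
#'
#' @param pca a `net_pca` object.
#' @param k_range candidate cluster counts (subset of `2:(n-1)`).
#' @param n_components number of leading components to cluster on.
#' @param ari_floor method-robustness floor: a partition is admissible when
#'   the mean pairwise ARI among the three methods reaches this value.
#' @param min_cluster_size smallest admissible type: clusters below this size
#'   cannot be characterized (their v-tests and spreads are meaningless), so
#'   partitions containing one are skipped during selection.
#' @param kmeans_seed seed for the k-means starts (logged in the result).
#' @return object of class `cluster_solution`: `k`, `labels` (named by
#'   network), `method_agreement` (pairwise ARI at the selected k),
#'   `ari_by_k`, `parangons`, `dendrogram` (the Ward tree), `kmeans_seed`.
#' @export
cluster_networks <- function(pca, k_range = 2:6, n_components = NULL,
                             ari_floor = 0.8, min_cluster_size = 3,
                             kmeans_seed = 20121231) {
  scores <- pca$scores
  n <- nrow(scores)
  if (n < 4) stop("at least 4 networks are required for clustering",
                  call. = FALSE)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("empty k_range", call. = FALSE)

  if (is.null(n_components)) n_components <- max(1, sum(pca$eig >= 1))
  n_components <- min(n_components, ncol(scores))
  z <- scores[, seq_len(n_components), drop = FALSE]

  ## k-means uses its own fixed, logged seed; the caller's RNG stream is
  ## restored afterwards so pipeline reproducibility is unaffected
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })

  d <- stats::dist(z)
  hc_ward <- stats::hclust(d, method = "ward.D2")
  hc_avg <- stats::hclust(d, method = "average")

  ari_by_k <- data.frame(k = k_range, ward_avg = NA_real_,
                         ward_kmeans = NA_real_, avg_kmeans = NA_real_,
                         mean_ari = NA_real_, silhouette = NA_real_,
                         score = NA_real_)
  dm <- as.matrix(d)
  partitions <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    lw <- stats::cutree(hc_ward, k)
    la <- stats::cutree(hc_avg, k)
    set.seed(kmeans_seed)
    lk <- stats::kmeans(z, centers = k, nstart = 25)$cluster
    ari_by_k$ward_avg[i] <- adjusted_rand(lw, la)
    ari_by_k$ward_kmeans[i] <- adjusted_rand(lw, lk)
    ari_by_k$avg_kmeans[i] <- adjusted_rand(la, lk)
    ari_by_k$mean_ari[i] <- mean(unlist(ari_by_k[i, 2:4]))
    ari_by_k$silhouette[i] <- mean_silhouette(dm, lw)
    partitions[[as.character(k)]] <- lw
  }
  ## method agreement alone cannot identify k on cleanly nested structure
  ## (all three methods also agree at every coarser cut), so selection is
  ## two-stage: a partition is admissible when it is method-robust (mean
  ## pairwise ARI >= ari_floor) and all its clusters are large enough to be
  ## characterized; among admissible k the best Ward silhouette wins, ties
  ## toward the smallest k. If nothing clears the robustness floor, the
  ## combined agreement + silhouette score ranks instead.
  ari_by_k$score <- ari_by_k$mean_ari + ari_by_k$silhouette
  no_singleton <- vapply(as.character(k_range), function(kk) {
    min(table(partitions[[kk]])) >= min_cluster_size
  }, logical(1))
  if (!any(no_singleton)) no_singleton[] <- TRUE
  robust <- no_singleton & ari_by_k$mean_ari >= ari_floor
  ari_by_k$admissible <- robust
  if (any(robust)) {
    best <- which(robust &
                    ari_by_k$silhouette == max(ari_by_k$silhouette[robust]))[1]
  } else {
    best <- which(no_singleton &
                    ari_by_k$score == max(ari_by_k$score[no_singleton]))[1]
  }
  k_sel <- ari_by_k$k[best]
  labels <- partitions[[as.character(k_sel)]]
  names(labels) <- rownames(scores)

  ## parangon: member closest to its cluster centroid in component space
  cluster_ids <- sort(unique(labels))
  names(cluster_ids) <- as.character(cluster_ids)
  parangons <- vapply(cluster_ids, function(cl) {
    members <- which(labels == cl)
    cent <- colMeans(z[members, , drop = FALSE])
    dists <- sqrt(rowSums((z[members, , drop = FALSE] -
                             matrix(cent, length(members), ncol(z),
                                    byrow = TRUE))^2))
    names(members)[which.min(dists)]
  }, character(1))

  structure(
    list(
      k = k_sel,
      labels = labels,
      method_agreement = unlist(ari_by_k[best, c("ward_avg", "ward_kmeans",
                                                 "avg_kmeans")]),
      ari_by_k = ari_by_k,
      n_components = n_components,
      parangons = parangons,
      dendrogram = hc_ward,
      kmeans_seed = kmeans_seed
    ),
    class = "cluster_solution"
  )
}

#' @exportS3Method base::print
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d (mean pairwise ARI %.3f)\n",
              x$k, mean(x$method_agreement)))
  print(table(x$labels))
  invisible(x)
}

#' v-test statistic of a cluster mean against the overall mean
#'
#' `v = (mean_k - mean) / sqrt((s2 / n_k) * (N - n_k) / (N - 1))` with `s2` the
#' population variance (denominator `N`) of the variable over all networks —
#' the finite-population comparison conventional in PCA-based cluster
#' description.
#'
#' @param x numeric variable over all N objects.
#' @param members logical or integer index of the cluster's members.
#' @return the v statistic (`NA` for singleton-degenerate cases).
#' @export
v_test <- function(x, members) {
  N <- length(x)
  xk <- x[members]
  n_k <- length(xk)
  if (n_k == 0 || n_k == N || N < 2) return(NA_real_)
  s2 <- pop_var(x)
  if (s2 == 0) return(0)
  (mean(xk) - mean(x)) / sqrt((s2 / n_k) * (N - n_k) / (N - 1))
}

#' Characterize clusters: v-tests, qualitative breakdowns, parangons
#'
#' For every quantitative variable and cluster: cluster mean, overall mean,
#' v statistic and its 5% two-sided significance flag. Qualitative variables
#' are tabulated per cluster. Singleton clusters keep their parangon (the
#' singleton itself) but the v statistic uses the usual formula (defined for
#' `n_k = 1 < N`).
#'
#' @param profiles `network_profiles` data frame.
#' @param solution a `cluster_solution`.
#' @param quantitative_vars variables to test (default: the typology candidate
#'   set present in the profiles).
#' @param qualitative_vars variables to tabulate.
#' @return list with `v_tests` (data frame), `qualitative` (list of tables)
#'   and `parangons`.
#' @export
characterize_clusters <- function(profiles, solution,
                                  quantitative_vars = NULL,
                                  qualitative_vars = c("area_typology",
                                                       "loyalty_band",
                                                       "index_specialized")) {
  quantitative_vars <- quantitative_vars %||%
    intersect(typology_variables()$description, names(profiles))
  labels <- solution$labels[profiles$network_id]
  clusters <- sort(unique(labels))
  crit <- stats::qnorm(0.975)

  rows <- list()
  for (v in quantitative_vars) {
    x <- profiles[[v]]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    for (cl in clusters) {
      members <- which(labels == cl)
      vt <- v_test(x, members)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, cluster = cl, n_k = length(members),
        cluster_mean = mean(x[members]),
        cluster_sd = stats::sd(x[members]),
        overall_mean = mean(x),
        v_statistic = vt,
        significant = !is.na(vt) && abs(vt) >= crit,
        stringsAsFactors = FALSE
      )
    }
  }
  v_tests <- do.call(rbind, rows)

  qualitative_vars <- intersect(qualitative_vars, names(profiles))
  qualitative <- lapply(qualitative_vars, function(v) {
    table(cluster = labels, category = as.character(profiles[[v]]))
  })
  names(qualitative) <- qualitative_vars

  list(v_tests = v_tests, qualitative = qualitative,
       parangons = solution$parangons)
}

#' Export a Ward dendrogram as nested Newick-like text
#'
#' @param solution a `cluster_solution`.
#' @param path output file; when `NULL` the string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
export_dendrogram <- function(solution, path = NULL) {
  hc <- solution$dendrogram
  labs <- hc$labels %||% as.character(seq_along(hc$order))
  recurse <- function(i) {
    if (i < 0) return(labs[-i])
    pair <- hc$merge[i, ]
    sprintf("(%s,%s):%.4f", recurse(pair[1]), recurse(pair[2]), hc$height[i])
  }
  ## the root carries no branch length
  newick <- paste0(sub(":[0-9.eE+-]+$", "", recurse(nrow(hc$merge))), ";")
  if (is.null(path)) return(newick)
  writeLines(newick, path)
  invisible(newick)
}
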