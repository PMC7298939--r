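#' Screen covariates for collinearity before model fitting
#'
#' Drops one member of each covariate pair whose absolute correlation exceeds
#' `r_threshold`, reporting the dropped-to-kept mapping. Same greedy logic as
#' the typology's pruning, applied to the model design table.
#'
#' @param data design data frame.
#' @param vars candidate covariate names.
#' @param r_threshold absolute-correlation cutoff, default 0.7.
#' @param priority covariates scanned (and so preferentially kept) first.
#' @param protect covariates never dropped (e.g. the patient adjustors).
#' @return list with `kept` and `dropped`.
#' @export
screen_collinearity <- function(data, vars, r_threshold = 0.7,
                                priority = NULL, protect = NULL) {
  num <- data[intersect(vars, names(data))]
  num <- as.data.frame(lapply(num, function(x) {
    if (is.logical(x)) as.numeric(x) else x
  }))
  res <- prune_by_correlation(num, names(num), r_threshold,
                              priority = c(protect, priority))
  if (!is.null(protect)) {
    lost <- setdiff(intersect(protect, vars), res$kept)
    if (length(lost)) {
      res$kept <- c(res$kept, lost)
      res$dropped <- res$dropped[!res$dropped$dropped %in% lost, , drop = FALSE]
    }
  }
  network_vars <- setdiff(res$kept, protect)
  if (length(setdiff(vars, protect)) > 0 && length(network_vars) == 0) {
    stop("collinearity screen removed every network covariate; ",
         "raise r_threshold", call. = FALSE)
  }
  res
}

## exchangeable working-correlation inverse applied to a cluster block:
## R^{-1} = 1/(1-a) [I - a/(1 + (n-1)a) J]
solve_exchangeable <- function(x, alpha) {
  n <- NROW(x)
  if (n == 1 || alpha == 0) return(x)
  f <- alpha / (1 + (n - 1) * alpha)
  if (is.matrix(x)) {
    (x - f * matrix(colSums(x), n, ncol(x), byrow = TRUE)) / (1 - alpha)
  } else {
    (x - f * sum(x)) / (1 - alpha)
  }
}

#' Fit a log-binomial marginal model with generalized estimating equations
#'
#' Log link, binomial variance, exchangeable (or independence) working
#' correlation, robust sandwich standard errors; effects are reported as
#' relative rates with 95% confidence intervals. If the log-binomial fit fails
#' to converge (fitted probabilities escaping toward 1 are the classic cause),
#' the fit falls back to the Poisson variance function with the same log link
#' and robust variance — the standard robust-Poisson estimator of relative
#' rates — and flags the fallback.
#'
#' @param formula model formula with a binary (0/1 or logical) outcome.
#' @param data design data frame.
#' @param cluster cluster id vector, or the name of a column of `data`.
#' @param corstr working correlation structure.
#' @param std_err `"sandwich"` for the usual robust estimator, or
#'   `"small_sample"` to additionally apply the `K/(K-1) * (N-1)/(N-p)`
#'   degrees-of-freedom inflation (anti-conservativeness guard when clusters
#'   are few).
#' @param max_iter,tol Fisher-scoring control.
#' @return object of class `gee_fit` with elements `coefficients`,
#'   `robust_se`, `rr` (relative-rate table with CI bounds and significance
#'   flags), `alpha` (estimated working correlation), `convergence_status`
#'   (`"log-binomial"`, `"poisson-fallback"` or `"failed"`), `n_obs`,
#'   `n_clusters`.
#' @export
fit_log_binomial_gee <- function(formula, data,
                                 cluster,
                                 corstr = c("exchangeable", "independence"),
                                 std_err = c("sandwich", "small_sample"),
                                 max_iter = 100, tol = 1e-8) {
  corstr <- match.arg(corstr)
  std_err <- match.arg(std_err)
  if (is.character(cluster) && length(cluster) == 1) {
    cluster <- data[[cluster]]
  }
  data <- as.data.frame(data)
  rownames(data) <- NULL
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  keep <- as.integer(rownames(mf))
  cluster <- as.character(cluster[keep])
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient after screening", call. = FALSE)
  }
  cl_idx <- split(seq_along(y), cluster)
  K <- length(cl_idx)
  if (K < 2) stop("at least 2 clusters are required", call. = FALSE)

  run <- function(variance) {
    ## Fisher scoring on the GEE; for the log link D = diag(mu) X
    beta <- tryCatch(
      stats::glm.fit(X, y, family = stats::poisson(link = "log"))$coefficients,
      error = function(e) NULL
    )
    if (is.null(beta) || anyNA(beta)) return(NULL)
    alpha <- 0
    p <- ncol(X)
    N <- length(y)
    for (iter in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      if (variance == "binomial") eta <- pmin(eta, -1e-8)  # keep mu < 1
      mu <- exp(eta)
      v <- switch(variance, binomial = mu * (1 - mu), poisson = mu)
      v <- pmax(v, 1e-10)

      ## working correlation from standardized residuals
      r <- (y - mu) / sqrt(v)
      if (corstr == "exchangeable") {
        num <- 0; pairs <- 0
        for (ix in cl_idx) {
          ni <- length(ix)
          if (ni > 1) {
            s <- sum(r[ix])
            num <- num + (s^2 - sum(r[ix]^2)) / 2
            pairs <- pairs + ni * (ni - 1) / 2
          }
        }
        phi <- sum(r^2) / (N - p)
        alpha <- if (pairs > p) (num / (pairs - p)) / phi else 0
        alpha <- max(min(alpha, 0.95), 0)
      }

      U <- numeric(p)
      H <- matrix(0, p, p)
      for (ix in cl_idx) {
        Di <- X[ix, , drop = FALSE] * mu[ix]
        Ai <- sqrt(v[ix])
        ri <- (y[ix] - mu[ix]) / Ai
        DA <- Di / Ai
        U <- U + crossprod(DA, solve_exchangeable(ri, alpha))
        H <- H + crossprod(DA, solve_exchangeable(DA, alpha))
      }
      step <- tryCatch(solve(H, U), error = function(e) NULL)
      if (is.null(step) || anyNA(step)) return(NULL)
      ## log-binomial only: step-halve against overshoot into mu >= 1
      cand <- beta + step
      if (variance == "binomial") {
        for (half in 0:10) {
          cand <- beta + step / 2^half
          if (all(drop(X %*% cand) < 0)) break
        }
      }
      beta_new <- cand
      done <- max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))
      beta <- beta_new
      if (done) {
        ## sandwich covariance at the solution
        eta <- drop(X %*% beta)
        if (variance == "binomial") eta <- pmin(eta, -1e-8)
        mu <- exp(eta)
        v <- pmax(switch(variance, binomial = mu * (1 - mu), poisson = mu),
                  1e-10)
        B <- matrix(0, p, p)
        M <- matrix(0, p, p)
        for (ix in cl_idx) {
          Di <- X[ix, , drop = FALSE] * mu[ix]
          Ai <- sqrt(v[ix])
          DA <- Di / Ai
          ri <- (y[ix] - mu[ix]) / Ai
          B <- B + crossprod(DA, solve_exchangeable(DA, alpha))
          g <- crossprod(DA, solve_exchangeable(ri, alpha))
          M <- M + tcrossprod(g)
        }
        Binv <- tryCatch(solve(B), error = function(e) NULL)
        if (is.null(Binv)) return(NULL)
        V <- Binv %*% M %*% Binv
        if (std_err == "small_sample") {
          V <- V * (K / (K - 1)) * ((N - 1) / (N - p))
        }
        ## a valid binomial solution must keep fitted probabilities inside
        ## (0, 1); boundary-pinned fits are treated as non-convergent
        if (variance == "binomial" && any(eta > -1e-6)) return(NULL)
        return(list(beta = beta, vcov = V, alpha = alpha, iter = iter))
      }
    }
    NULL
  }

  fit <- run("binomial")
  status <- "log-binomial"
  if (is.null(fit)) {
    fit <- run("poisson")
    status <- if (is.null(fit)) "failed" else "poisson-fallback"
  }
  if (is.null(fit)) {
    return(structure(
      list(coefficients = NULL, robust_se = NULL, rr = NULL, alpha = NA,
           convergence_status = "failed", n_obs = length(y), n_clusters = K,
           corstr = corstr),
      class = "gee_fit"
    ))
  }

  se <- sqrt(diag(fit$vcov))
  names(fit$beta) <- colnames(X)
  names(se) <- colnames(X)
  zcrit <- stats::qnorm(0.975)
  rr <- data.frame(
    term = colnames(X),
    estimate = fit$beta,
    robust_se = se,
    rr = exp(fit$beta),
    ci_low = exp(fit$beta - zcrit * se),
    ci_high = exp(fit$beta + zcrit * se),
    row.names = NULL, stringsAsFactors = FALSE
  )
  rr$significant <- rr$ci_low > 1 | rr$ci_high < 1

  structure(
    list(coefficients = fit$beta, robust_se = se, vcov = fit$vcov, rr = rr,
         alpha = fit$alpha, convergence_status = status,
         n_obs = length(y), n_clusters = K, corstr = corstr,
         formula = formula, iterations = fit$iter),
    class = "gee_fit"
  )
}

#' @exportS3Method base::print
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "<gee_fit> %s GEE (%s working correlation), %d obs in %d clusters\n",
    x$convergence_status, x$corstr, x$n_obs, x$n_clusters))
  if (!is.null(x$rr)) {
    cat(sprintf("estimated working correlation alpha = %.4f\n", x$alpha))
    out <- x$rr
    out[, c("estimate", "robust_se", "rr", "ci_low", "ci_high")] <-
      round(out[, c("estimate", "robust_se", "rr", "ci_low", "ci_high")], 3)
    print(out)
  }
  invisible(x)
}

#' Default model specification for the quality models
#'
#' Patient adjustors plus the network covariates of the relative-rate models;
#' the network set is screened for collinearity before fitting.
#'
#' @return list with `patient_vars` and `network_vars`.
#' @export
model_variables <- function() {
  list(
    patient_vars = c("age_at_index", "sex_male", "low_income", "precedence",
                     "somatic_ltd"),
    network_vars = c("density", "median_weighted_degree", "index_specialized",
                     "pct_physicians_among_community", "pct_hospitals",
                     "pct_private_hospitals", "per100k_psychiatrists",
                     "per100k_gps", "pct_ambulatory_index",
                     "avg_contacts_per_patient")
  )
}

#' Fit the four quality-indicator relative-rate models
#'
#' Joins each subcohort patient's quality indicators with their own covariates
#' and their network's characteristics, screens the network covariates for
#' collinearity, and fits one cluster-correlated log-binomial GEE per
#' indicator. The working-correlation clusters are the network clusters of the
#' typology by default (`cluster_on = "cluster"`), or the networks themselves
#' (`cluster_on = "network"`).
#'
#' @param quality_rows output of [quality_table()].
#' @param cohort cohort table.
#' @param profiles `network_profiles`.
#' @param solution `cluster_solution` (needed for `cluster_on = "cluster"`).
#' @param cluster_on clustering unit for the working correlation.
#' @param r_threshold collinearity screen cutoff.
#' @param corstr,std_err passed to [fit_log_binomial_gee()].
#' @return object of class `quality_models`: list with `fits` (one `gee_fit`
#'   per indicator), `screen` (kept/dropped report), `data` (the assembled
#'   design table).
#' @export
fit_quality_models <- function(quality_rows, cohort, profiles,
                               solution = NULL,
                               cluster_on = c("cluster", "network"),
                               r_threshold = 0.7,
                               corstr = "exchangeable",
                               std_err = "sandwich") {
  cluster_on <- match.arg(cluster_on)
  mv <- model_variables()

  d <- merge(quality_rows, cohort[, c("patient_id", mv$patient_vars)],
             by = "patient_id")
  net_cols <- intersect(c("network_id", mv$network_vars), names(profiles))
  d <- merge(d, profiles[, net_cols], by = "network_id")
  if (cluster_on == "cluster") {
    if (is.null(solution)) {
      stop("a cluster_solution is required to cluster on the typology",
           call. = FALSE)
    }
    d$cluster_id <- solution$labels[d$network_id]
  } else {
    d$cluster_id <- d$network_id
  }

  net_in_data <- intersect(mv$network_vars, names(d))
  screen <- screen_collinearity(
    d, vars = c(mv$patient_vars, net_in_data),
    r_threshold = r_threshold, protect = mv$patient_vars,
    priority = net_in_data
  )
  covars <- screen$kept

  ## network covariates are constant within network: at most
  ## n_networks - 1 of them can be linearly independent. Drop the aliased
  ## tail so the patient-level design stays full rank.
  net_kept <- intersect(covars, net_in_data)
  if (length(net_kept)) {
    net_level <- unique(d[c("network_id", net_kept)])
    m <- cbind(1, as.matrix(as.data.frame(
      lapply(net_level[net_kept], as.numeric))))
    qr_m <- qr(m)
    if (qr_m$rank < ncol(m)) {
      keep_cols <- qr_m$pivot[seq_len(qr_m$rank)]
      aliased <- net_kept[setdiff(seq_along(net_kept) + 1L,
                                  keep_cols) - 1L]
      covars <- setdiff(covars, aliased)
      screen$dropped <- rbind(
        screen$dropped,
        data.frame(dropped = aliased, correlated_with = "aliased",
                   stringsAsFactors = FALSE))
    }
  }
  fits <- lapply(QUALITY_INDICATORS, function(ind) {
    f <- stats::reformulate(covars, response = ind)
    fit_log_binomial_gee(f, d, cluster = d$cluster_id, corstr = corstr,
                         std_err = std_err)
  })
  names(fits) <- QUALITY_INDICATORS

  structure(list(fits = fits, screen = screen, covariates = covars,
                 cluster_on = cluster_on, data = d),
            class = "quality_models")
}

#' Relative-rate table of the fitted quality models
#'
#' One row per covariate and outcome, shaped like a published relative-rate
#' table (RR, 95% CI bounds, significance flag).
#'
#' @param models a `quality_models` object.
#' @return data frame.
#' @export
model_results_table <- function(models) {
  out <- do.call(rbind, lapply(names(models$fits), function(ind) {
    f <- models$fits[[ind]]
    if (is.null(f$rr)) return(NULL)
    cbind(outcome = ind, f$rr,
          convergence = f$convergence_status)
  }))
  rownames(out) <- NULL
  out
}

#' No-threshold sensitivity analysis
#'
#' Rebuilds every network with all retention thresholds forced to zero,
#' recomputes profiles and quality indicators, refits the four models on the
#' same typology clusters, and reports side-by-side relative rates with the
#' maximum absolute difference per covariate.
#'
#' @param result a `pipeline_result` from [run_all()].
#' @return list with `models` (the no-threshold `quality_models`),
#'   `comparison` (main vs sensitivity RRs and differences) and
#'   `networks` (the unthresholded networks).
#' @export
sensitivity_no_threshold <- function(result) {
  bundle <- result$bundle
  cohort <- result$cohort
  zeroth <- zero_thresholds(result$pair_counts)
  nb <- build_networks(cohort, bundle, thresholds = zeroth,
                       follow_up_days = result$follow_up_days)
  profiles <- network_profiles(nb$networks, cohort, bundle,
                               follow_up_days = result$follow_up_days)
  qr <- quality_table(cohort, bundle, tags = result$prevention_tags)
  models <- fit_quality_models(qr, cohort, profiles,
                               solution = result$solution,
                               cluster_on = result$models$cluster_on,
                               corstr = result$models$fits[[1]]$corstr)

  main <- model_results_table(result$models)
  sens <- model_results_table(models)
  ## the intercept is the baseline at covariate zero and is not comparable
  ## across runs whose covariate scales differ; only effects are paired
  main <- main[main$term != "(Intercept)", ]
  sens <- sens[sens$term != "(Intercept)", ]
  comparison <- merge(
    main[, c("outcome", "term", "rr")],
    sens[, c("outcome", "term", "rr")],
    by = c("outcome", "term"), suffixes = c("_main", "_no_threshold")
  )
  comparison$abs_diff <- abs(comparison$rr_main - comparison$rr_no_threshold)

  list(models = models, comparison = comparison, networks = nb$networks,
       max_abs_diff = stats::aggregate(abs_diff ~ term, comparison, max))
}
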