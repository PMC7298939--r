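test_that("correlation pruning keeps one representative per collinear block", {
  set.seed(1)
  base <- rnorm(30)
  d <- data.frame(
    v1 = base,
    v2 = base + rnorm(30, sd = 0.05),           # r ~ 0.99 with v1
    v3 = base * 0.9 + rnorm(30, sd = 0.15),     # engineered r ~ 0.95 block
    v4 = rnorm(30),                              # independent
    v5 = rnorm(30)
  )
  expect_gt(abs(cor(d$v1, d$v3)), 0.9)
  res <- prune_correlated(d, vars = names(d), priority = "v1")
  expect_equal(res$kept[1], "v1")
  expect_true(all(c("v4", "v5") %in% res$kept))
  expect_setequal(res$dropped$dropped, c("v2", "v3"))
  expect_true(all(res$dropped$correlated_with == "v1"))

  ## identical columns: exactly one survives
  dd <- data.frame(a = base, b = base)
  expect_equal(prune_correlated(dd, vars = c("a", "b"))$kept, "a")
  ## orthogonal columns: all survive
  expect_equal(length(prune_correlated(d[, 4:5], vars = c("v4", "v5"))$kept),
               2)
  ## constant column dropped with warning
  d$cst <- 1
  expect_warning(res2 <- prune_correlated(d, vars = names(d)), "constant")
  expect_false("cst" %in% res2$kept)
})

test_that("PCA reproduces an independent eigendecomposition", {
  set.seed(2)
  p <- data.frame(network_id = sprintf("N%02d", 1:12),
                  a = rnorm(12), b = rnorm(12), c = rnorm(12), d = rnorm(12))
  pc <- run_pca(p, c("a", "b", "c", "d"), illustrative_vars = NULL)
  ev <- eigen(cor(p[, c("a", "b", "c", "d")]))$values
  expect_equal(pc$eig, ev, tolerance = 1e-10)
  expect_equal(sum(pc$var_explained), 1)

  ## rank-1 data: first component explains everything
  q <- data.frame(network_id = sprintf("N%d", 1:6),
                  x = 1:6, y = 2 * (1:6), z = -3 * (1:6))
  pcq <- run_pca(q, c("x", "y", "z"), illustrative_vars = NULL)
  expect_equal(pcq$var_explained[1], 1, tolerance = 1e-10)

  ## permutation invariance up to row order
  perm <- sample(nrow(p))
  pc2 <- run_pca(p[perm, ], c("a", "b", "c", "d"), illustrative_vars = NULL)
  expect_equal(abs(pc2$scores[p$network_id[perm], ]), abs(pc$scores[p$network_id[perm], ]),
               tolerance = 1e-8)
})

test_that("illustrative variables never influence the axes", {
  set.seed(3)
  p <- data.frame(network_id = sprintf("N%02d", 1:10),
                  a = rnorm(10), b = rnorm(10),
                  grp = rep(c("u", "v"), 5))
  pc1 <- run_pca(p, c("a", "b"), illustrative_vars = NULL)
  pc2 <- run_pca(p, c("a", "b"), illustrative_vars = "grp")
  expect_equal(pc1$scores, pc2$scores)
  expect_equal(rownames(pc2$illustrative$grp), c("u", "v"))
})

test_that("adjusted Rand index matches a hand-computed contingency value", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  ## contingency: n11=2 n12=1 n21=0 n22=3; sum nij C2 = 1+0+0+3 = 4
  ## rows C2: 3+3=6; cols C2: 1+6=7; expected = 6*7/15 = 2.8
  ## max = (6+7)/2 = 6.5 -> ARI = (4-2.8)/(6.5-2.8)
  expect_equal(adjusted_rand(a, b), (4 - 2.8) / (6.5 - 2.8))
  expect_equal(adjusted_rand(a, a), 1)
})

test_that("three well-separated clouds give k = 3 with full agreement", {
  set.seed(4)
  p <- data.frame(
    network_id = sprintf("N%02d", 1:18),
    x = rep(c(0, 10, 20), each = 6) + rnorm(18, sd = 0.5),
    y = rep(c(0, 5, 10), each = 6) + rnorm(18, sd = 0.5),
    z = rnorm(18, sd = 0.5)
  )
  pc <- run_pca(p, c("x", "y", "z"), illustrative_vars = NULL)
  sol <- cluster_networks(pc, k_range = 2:6)
  expect_equal(sol$k, 3)
  expect_equal(unname(sol$method_agreement), rep(1, 3))
  truth <- rep(1:3, each = 6)
  expect_equal(adjusted_rand(sol$labels[p$network_id], truth), 1)
})

test_that("clustering is invariant to row order and refuses tiny inputs", {
  set.seed(5)
  p <- data.frame(
    network_id = sprintf("N%02d", 1:12),
    x = rep(c(0, 8, 16), each = 4) + rnorm(12, 0.3),
    y = rep(c(0, 8, 0), each = 4) + rnorm(12, 0.3)
  )
  sol1 <- cluster_networks(run_pca(p, c("x", "y"), NULL))
  perm <- sample(nrow(p))
  sol2 <- cluster_networks(run_pca(p[perm, ], c("x", "y"), NULL))
  expect_equal(sol1$k, sol2$k)
  expect_equal(adjusted_rand(sol1$labels[p$network_id],
                             sol2$labels[p$network_id]), 1)
  expect_error(cluster_networks(run_pca(p[1:3, ], c("x", "y"), NULL)),
               "at least 4")
})

test_that("v statistic matches direct arithmetic on a 19-row fixture", {
  set.seed(6)
  x <- rnorm(19, mean = 10, sd = 3)
  members <- 1:5
  s2 <- mean((x - mean(x))^2)
  expected <- (mean(x[members]) - mean(x)) /
    sqrt((s2 / 5) * (19 - 5) / (19 - 1))
  expect_equal(v_test(x, members), expected, tolerance = 1e-9)
  ## cluster mean equal to overall mean -> v = 0
  y <- rep(c(1, 2), length.out = 18)
  expect_equal(v_test(y, c(1, 2)), 0)
})

test_that("cluster characterization flags significance and finds parangons", {
  set.seed(7)
  p <- data.frame(
    network_id = sprintf("N%02d", 1:12),
    density = c(rnorm(6, 80, 1), rnorm(6, 20, 1)),
    avg_contacts_per_patient = c(rnorm(6, 30, 1), rnorm(6, 70, 1)),
    area_typology = rep(c("rural_health_social", "strong_private_urban"),
                        each = 6),
    stringsAsFactors = FALSE
  )
  pc <- run_pca(p, c("density", "avg_contacts_per_patient"),
                illustrative_vars = "area_typology")
  sol <- cluster_networks(pc, k_range = 2:4)
  ch <- characterize_clusters(p, sol,
                              quantitative_vars = c("density",
                                                    "avg_contacts_per_patient"),
                              qualitative_vars = "area_typology")
  vt <- ch$v_tests
  expect_true(all(vt$significant[vt$variable == "density"]))
  ## v = 0 exactly when cluster mean equals overall mean is encoded in v_test
  ## parangon: closest member to its centroid in component space
  z <- pc$scores[, seq_len(sol$n_components), drop = FALSE]
  for (cl in sort(unique(sol$labels))) {
    members <- names(sol$labels)[sol$labels == cl]
    cent <- colMeans(z[members, , drop = FALSE])
    dists <- sqrt(rowSums((z[members, , drop = FALSE] -
                             matrix(cent, length(members), ncol(z),
                                    byrow = TRUE))^2))
    expect_equal(ch$parangons[[as.character(cl)]],
                 members[which.min(dists)])
  }
  ## qualitative breakdown counts categories per cluster
  expect_equal(sum(ch$qualitative$area_typology), 12)
})

test_that("dendrogram exports as parsable nested text", {
  set.seed(8)
  p <- data.frame(network_id = sprintf("N%d", 1:6),
                  x = rnorm(6), y = rnorm(6))
  sol <- cluster_networks(run_pca(p, c("x", "y"), NULL), k_range = 2:4)
  nwk <- export_dendrogram(sol)
  expect_match(nwk, "^\\(.*\\);$")
  for (id in p$network_id) expect_match(nwk, id, fixed = TRUE)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, p$network_id)
})
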