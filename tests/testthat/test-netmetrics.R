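mknet <- function(edges, nodes = NULL, index = "IDX") {
  ids <- nodes %||% unique(c(edges$from, edges$to, index))
  structure(list(
    index_hospital_id = index,
    nodes = data.frame(provider_id = ids, type = "gp",
                       stringsAsFactors = FALSE),
    links = edges
  ), class = "sharing_network")
}

test_that("density matches hand-worked star and complete graphs", {
  star <- mknet(data.frame(from = "IDX", to = c("a", "b", "c"), weight = 1))
  expect_equal(net_density(star), 50)
  cmpl <- mknet(data.frame(
    from = c("IDX", "IDX", "IDX", "a", "a", "b"),
    to = c("a", "b", "c", "b", "c", "c"), weight = 1))
  expect_equal(net_density(cmpl), 100)
  ## single node: undefined
  single <- mknet(data.frame(from = character(0), to = character(0),
                             weight = numeric(0)), nodes = "IDX")
  expect_true(is.na(net_density(single)))
})

test_that("transitivity matches hand-worked triads", {
  tri <- mknet(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                          weight = 1), index = "a")
  expect_equal(net_transitivity(tri), 100)
  star <- mknet(data.frame(from = "IDX", to = c("a", "b", "c"), weight = 1))
  expect_equal(net_transitivity(star), 0)
  ## edges {ab, bc, ca, cd}: 1 triangle, 5 connected triples -> 60%
  kite <- mknet(data.frame(from = c("a", "b", "c", "c"),
                           to = c("b", "c", "a", "d"), weight = 1),
                index = "a")
  expect_equal(net_transitivity(kite), 60)
})

test_that("median weighted degree sums incident weights", {
  net <- mknet(data.frame(from = c("IDX", "IDX", "a"),
                          to = c("a", "b", "b"),
                          weight = c(5, 2, 1)))
  ## strengths: IDX 7, a 6, b 3 -> median 6
  expect_equal(median_weighted_degree(net), 6)
  ## star with unit weights: leaves dominate the median
  star <- mknet(data.frame(from = "IDX", to = letters[1:5], weight = 1))
  expect_equal(median_weighted_degree(star), 1)
  ## even node count averages the central order statistics
  expect_equal(median_weighted_degree(net, include_index = FALSE), 4.5)
})

test_that("graph metrics agree with brute-force enumeration on random graphs", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    net <- random_network(n, p = runif(1, 0.2, 0.8))
    expect_equal(net_density(net), bf_density(net$nodes$provider_id,
                                              net$links))
    bt <- bf_transitivity(net$nodes$provider_id, net$links)
    expect_equal(net_transitivity(net), bt)
    s <- bf_strengths(net$nodes$provider_id, net$links)
    expect_equal(median_weighted_degree(net), median(s))
  }
})

test_that("metrics are invariant to relabeling and weights (where defined)", {
  set.seed(9)
  net <- random_network(8, 0.5)
  relab <- net
  map <- setNames(paste0("X", seq_len(nrow(net$nodes))),
                  net$nodes$provider_id)
  relab$nodes$provider_id <- unname(map[relab$nodes$provider_id])
  relab$links$from <- unname(map[relab$links$from])
  relab$links$to <- unname(map[relab$links$to])
  relab$index_hospital_id <- unname(map[net$index_hospital_id])
  expect_equal(net_density(relab), net_density(net))
  expect_equal(net_transitivity(relab), net_transitivity(net))
  reweight <- net
  reweight$links$weight <- reweight$links$weight * 10
  expect_equal(net_density(reweight), net_density(net))
  expect_equal(net_transitivity(reweight), net_transitivity(net))
})

test_that("composition fields match direct tabulation", {
  nodes <- data.frame(
    provider_id = c("IDX", "P1", "G1", "G2", "G3", "G4", "G5",
                    "N1", "N2", "N3", "N4"),
    type = c("hospital", "psychiatrist", rep("gp", 5), rep("nurse", 4)),
    private = NA,
    stringsAsFactors = FALSE
  )
  net <- structure(list(index_hospital_id = "IDX", nodes = nodes,
                        links = data.frame(from = "IDX",
                                           to = nodes$provider_id[-1],
                                           weight = 1)),
                   class = "sharing_network")
  comp <- network_composition(net, 100000)
  expect_equal(comp$per100k_psychiatrists, 1)
  expect_equal(comp$pct_physicians_among_community, 60)
  expect_equal(comp$pct_specialists_among_community, 10)
  expect_equal(comp$pct_private_hospitals, 0)  # index only, public
  expect_equal(comp$pct_psychiatrists + comp$pct_gps + comp$pct_nurses +
                 comp$pct_hospitals, 100)
  expect_error(network_composition(net, 0), "positive")
})

test_that("loyalty index and its bands follow the closed middle interval", {
  co <- data.frame(patient_id = sprintf("P%d", 1:10),
                   index_hospital_id = "HX")
  mk <- function(n_in) {
    pats <- data.frame(
      patient_id = sprintf("P%d", 1:10),
      residence_zone = c(rep("Z1", n_in), rep("Z9", 10 - n_in))
    )
    loyalty_index("HX", co, pats, list(HX = "Z1"))
  }
  expect_equal(mk(8), list(loyalty_pct = 80, loyalty_band = "[60-80%]"))
  expect_equal(mk(10), list(loyalty_pct = 100, loyalty_band = ">80%"))
  expect_equal(mk(0), list(loyalty_pct = 0, loyalty_band = "<60%"))
  expect_equal(mk(6)$loyalty_band, "[60-80%]")
  expect_equal(mk(5)$loyalty_band, "<60%")
  expect_error(loyalty_index("HZ", co, data.frame(), list(HX = "Z1")), "HZ")
})

test_that("context metrics: ambulatory share and average contacts", {
  b <- tiny_bundle()
  d1 <- as.Date("2012-03-20")
  ## P1: 3 in-index ambulatory + 7 community psychiatrist visits + 0 GP
  b$contacts <- data.frame(
    patient_id = "P1",
    provider_id = c(rep("HX", 3), rep("PSY1", 7)),
    date = d1 + 5 + seq_len(10),
    stringsAsFactors = FALSE
  )
  co <- build_cohort(b)
  ctx <- context_metrics("HX", co, b$contacts, b$stays, b$providers)
  expect_equal(ctx$pct_ambulatory_index, 30)
  ## P2 has zero contacts but still counts in the denominator
  expect_equal(ctx$avg_contacts_per_patient, 5)
})

test_that("profile rows are complete and internally consistent", {
  b <- generate_bundle(small_config(seed = 4))
  co <- build_cohort(b)
  nb <- build_networks(co, b)
  p <- network_profiles(nb$networks, co, b)
  expect_equal(nrow(p), 6)
  pctcols <- c("pct_psychiatrists", "pct_gps", "pct_nurses", "pct_hospitals")
  ok <- p$n_providers > 0
  expect_true(all(abs(rowSums(p[ok, pctcols]) - 100) < 0.01))
  expect_true(all(p$n_links >= p$n_providers))
  pct_all <- unlist(p[, c(pctcols, "pct_private_hospitals",
                          "pct_ambulatory_index", "loyalty_pct")])
  expect_true(all(pct_all >= 0 & pct_all <= 100, na.rm = TRUE))
})
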