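test_that("shared-patient counts are distinct patients within personal windows", {
  b <- tiny_bundle()
  ## P1 discharged 2012-03-20: GP1 on day 12, PSY1 on day 42; add repeat
  ## visit and boundary contacts
  b$contacts <- rbind(b$contacts, data.frame(
    patient_id = c("P1", "P1", "P1"),
    provider_id = c("GP1", "GP1", "NUR1"),
    date = as.Date("2012-03-20") + c(200, 30, 366),  # repeat + outside window
    stringsAsFactors = FALSE
  ))
  co <- build_cohort(b)
  pc <- count_shared_patients(co, b$contacts, b$stays, b$providers)
  il <- pc$index_links

  ## repeat visits count once
  expect_equal(il$n_shared[il$provider_id == "GP1"], 1)
  ## day-366 contact is outside the one-year window
  expect_false("NUR1" %in% il$provider_id)
  expect_equal(unname(pc$log["out_of_window"]), 1)
})

test_that("day-365 boundary is inside, day 366 outside, day 0 outside", {
  b <- tiny_bundle()
  d0 <- as.Date("2012-03-20")
  b$contacts <- data.frame(
    patient_id = "P1",
    provider_id = c("GP1", "GP2", "PSY1", "NUR1"),
    date = d0 + c(365, 366, 0, 1),
    stringsAsFactors = FALSE
  )
  co <- build_cohort(b)
  pc <- count_shared_patients(co, b$contacts, b$stays, b$providers)
  expect_setequal(pc$index_links$provider_id[
    pc$index_links$index_hospital_id == "HX"], c("GP1", "NUR1"))
})

test_that("pair weights equal brute-force set intersections on random bundles", {
  set.seed(11)
  for (rep in 1:3) {
    b <- generate_bundle(scenario_config(
      n_index_hospitals = 2, archetype_assignment = c("A1", "A2"),
      n_patients_per_hospital = 60, seed = rep
    ))
    co <- build_cohort(b)
    pc <- count_shared_patients(co, b$contacts, b$stays, b$providers)
    nets <- build_networks(co, b, thresholds = zero_thresholds(pc))
    for (h in names(nets$networks)) {
      net <- nets$networks[[h]]
      ## oracle: raw in-window incidence for this hospital
      sub <- co[co$index_hospital_id == h, ]
      disc <- stats::setNames(as.Date(sub$discharge_date), sub$patient_id)
      cc <- b$contacts[b$contacts$patient_id %in% sub$patient_id, ]
      d <- as.numeric(as.Date(cc$date) - disc[cc$patient_id])
      cc <- cc[d >= 1 & d <= 365 & cc$provider_id != h, ]
      st <- b$stays[b$stays$patient_id %in% sub$patient_id &
                      b$stays$hospital_id != h, ]
      ds <- as.numeric(as.Date(st$admit_date) - disc[st$patient_id])
      st <- st[ds >= 1 & ds <= 365, ]
      ev <- rbind(cc[, c("patient_id", "provider_id")],
                  data.frame(patient_id = st$patient_id,
                             provider_id = st$hospital_id))
      oracle <- bf_pair_weights(ev)
      got <- net$links[net$links$from != h, ]
      key_o <- paste(pmin(oracle$a, oracle$b), pmax(oracle$a, oracle$b))
      key_g <- paste(pmin(got$from, got$to), pmax(got$from, got$to))
      expect_setequal(key_g, key_o)
      expect_equal(got$weight[order(key_g)],
                   oracle$weight[order(key_o)])
      ## index links against per-provider distinct-patient counts
      idx_links <- net$links[net$links$from == h, ]
      cnt <- tapply(ev$patient_id, ev$provider_id,
                    function(x) length(unique(x)))
      expect_equal(idx_links$weight,
                   as.numeric(cnt[idx_links$to]))
    }
  }
})

test_that("third-quartile rule matches the hand-checked example", {
  counts <- c(1, 2, 2, 3, 4, 6, 8, 20)
  expect_equal(third_quartile(counts), 6.5)
  expect_equal(counts[counts > third_quartile(counts)], c(8, 20))
})

test_that("thresholds are computed per provider type and pooled region-wide", {
  pc <- list(index_links = data.frame(
    index_hospital_id = rep(c("H1", "H2"), each = 4),
    provider_id = sprintf("P%d", 1:8),
    provider_type = rep(c("gp", "gp", "nurse", "nurse"), 2),
    n_shared = c(1, 2, 5, 5, 3, 4, 5, 5)
  ))
  q <- compute_thresholds(pc)
  expect_equal(unname(q["gp"]), unname(quantile(c(1, 2, 3, 4), 0.75)))
  expect_equal(unname(q["nurse"]), 5)
  ## degenerate distribution + strict inequality retains nothing
  net <- build_network("H1", c(pc, list(incidence = data.frame(
    patient_id = character(0), provider_id = character(0),
    index_hospital_id = character(0)))), q,
    providers = data.frame(provider_id = c("H1", sprintf("P%d", 1:8)),
                           type = c("hospital", rep(c("gp", "gp", "nurse",
                                                      "nurse"), 2))))
  expect_false(any(grepl("P[34]", net$nodes$provider_id)))  # nurses at Q3
})

test_that("strictly-greater retention and secondary-link rules hold", {
  ## GP with 3 shared when q_gp = 2 retained; GP with 2 dropped
  il <- data.frame(
    index_hospital_id = "H1",
    provider_id = c("G1", "G2", "N1", "N2"),
    provider_type = c("gp", "gp", "nurse", "nurse"),
    n_shared = c(3, 2, 4, 3)
  )
  inc <- data.frame(
    patient_id = c("a", "b", "c", "a", "b", "a", "b", "c", "d", "a"),
    provider_id = c("G1", "G1", "G1", "G2", "G2", "N1", "N1", "N1", "N1",
                    "N2"),
    index_hospital_id = "H1"
  )
  providers <- data.frame(
    provider_id = c("H1", "G1", "G2", "N1", "N2"),
    type = c("hospital", "gp", "gp", "nurse", "nurse")
  )
  q <- structure(c(gp = 2, nurse = 3), class = "threshold_set")
  net <- build_network("H1", list(index_links = il, incidence = inc), q,
                       providers)
  expect_setequal(net$nodes$provider_id, c("H1", "G1", "N1"))
  ## secondary link G1-N1 has weight 3 (patients a, b, c) without any
  ## thresholding of its own
  sec <- net$links[net$links$from != "H1", ]
  expect_equal(nrow(sec), 1)
  expect_equal(sec$weight, 3)
})

test_that("zero thresholds give the full >=1-shared-patient supergraph", {
  b <- generate_bundle(small_config(seed = 3))
  co <- build_cohort(b)
  nb <- build_networks(co, b)
  nb0 <- build_networks(co, b, thresholds = zero_thresholds(nb$pair_counts))
  for (h in names(nb$networks)) {
    thr <- nb$networks[[h]]
    full <- nb0$networks[[h]]
    expect_true(all(thr$nodes$provider_id %in% full$nodes$provider_id))
    key <- function(l) paste(pmin(l$from, l$to), pmax(l$from, l$to))
    expect_true(all(key(thr$links) %in% key(full$links)))
    ## full graph holds every provider sharing >= 1 patient
    il <- nb$pair_counts$index_links
    expect_setequal(full$nodes$provider_id,
                    c(h, il$provider_id[il$index_hospital_id == h]))
  }
})

test_that("raising a threshold never adds nodes or links", {
  b <- generate_bundle(small_config(seed = 5))
  co <- build_cohort(b)
  nb <- build_networks(co, b)
  q <- nb$thresholds
  q2 <- q
  q2["gp"] <- q["gp"] + 2
  for (h in names(nb$networks)) {
    n1 <- build_network(h, nb$pair_counts, q, b$providers)
    n2 <- build_network(h, nb$pair_counts, q2, b$providers)
    expect_true(all(n2$nodes$provider_id %in% n1$nodes$provider_id))
    expect_lte(nrow(n2$links), nrow(n1$links))
  }
})

test_that("network export writes GraphML and a weighted edge list", {
  b <- generate_bundle(small_config(seed = 2))
  co <- build_cohort(b)
  nb <- build_networks(co, b)
  net <- nb$networks[[1]]
  gp <- tempfile(fileext = ".graphml")
  ep <- tempfile(fileext = ".tsv")
  export_network(net, gp, ep)
  expect_true(file.exists(gp))
  g2 <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(net$nodes))
  el <- read.delim(ep)
  expect_equal(names(el), c("node_a", "node_b", "weight"))
  expect_equal(nrow(el), nrow(net$links))
})
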