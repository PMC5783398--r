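test_that("degree summaries satisfy symmetry and handshake identities", {
  tri <- build_network(rec(
    origin = c("a", "b", "c"), destination = c("b", "c", "a")
  ))
  expect_true(all(degree_distribution_summary(tri, "in")$degrees == 1))
  expect_true(all(degree_distribution_summary(tri, "out")$degrees == 1))

  star <- build_network(rec(
    origin = c("s1", "s2", "s3", "s4", "s5"), destination = "hub"
  ))
  d_in <- degree_distribution_summary(star, "in")$degrees
  expect_equal(unname(d_in["hub"]), 5)
  expect_equal(sum(d_in), 5)

  for (seed in 1:4) {
    net <- build_network(random_movement_table(seed))
    expect_equal(
      sum(degree_distribution_summary(net, "in")$degrees),
      nrow(net$links)
    )
    expect_equal(
      sum(degree_distribution_summary(net, "out")$degrees),
      nrow(net$links)
    )
  }

  empty <- build_network(rec("a", "b")[0, ])
  expect_error(degree_distribution_summary(empty), "empty")
})

test_that("power-law fitting recovers a known exponent and flags bad fits", {
  set.seed(42)
  k <- 1:10000
  x <- sample(k, 5000, replace = TRUE, prob = k^-1.7)
  fit <- fit_power_law(x, kind = "degree")
  expect_lt(abs(fit$exponent - 1.7), 0.15)
  expect_false(fit$poor_fit)

  # scale invariance of the continuous fit
  set.seed(43)
  w <- exp(rexp(3000, rate = 0.9)) # continuous power-ish tail
  f1 <- fit_power_law(w, kind = "weight")
  f10 <- fit_power_law(w * 10, kind = "weight")
  expect_lt(abs(f1$exponent - f10$exponent), 0.02)

  # uniform values are a poor power-law fit, and measurably worse than a
  # genuine power-law sample
  u <- fit_power_law(seq(1, 100, length.out = 2000), kind = "weight")
  expect_true(u$poor_fit)
  expect_gt(u$ks_stat, fit$ks_stat)

  expect_error(fit_power_law(rep(3, 10)), "3 distinct")
  expect_error(fit_power_law(c(-1, 2, 3, 4)), "positive")
})

test_that("component summary matches hand-enumerated cases", {
  chain <- build_network(rec(origin = c("a", "b"), destination = c("b", "c")))
  cs <- component_summary(chain)
  expect_true(cs$is_connected)
  expect_equal(cs$largest_weak, 3)
  expect_equal(cs$largest_strong, 1)

  dyads <- build_network(rec(origin = c("a", "c"), destination = c("b", "d")))
  cs2 <- component_summary(dyads)
  expect_false(cs2$is_connected)
  expect_equal(cs2$largest_weak, 2)
  expect_equal(cs2$n_components, 2)

  cyc <- build_network(rec(
    origin = c("a", "b", "c", "d", "e", "f"),
    destination = c("b", "c", "d", "e", "f", "a")
  ))
  expect_equal(component_summary(cyc)$largest_strong, 6)
})

test_that("clustering and diameter match construction and brute force", {
  tri <- build_network(rec(
    origin = c("a", "b", "c"), destination = c("b", "c", "a")
  ))
  expect_equal(clustering_and_diameter(tri)$clustering, 1)

  path8 <- build_network(rec(
    origin = letters[1:7], destination = letters[2:8]
  ))
  expect_equal(clustering_and_diameter(path8)$diameter, 7)

  for (seed in 1:20) {
    m <- random_digraph_matrix(seed, n_max = 6)
    if (all(m == 0)) next
    net <- build_network(table_from_matrix(m))
    got <- clustering_and_diameter(net)
    keep <- rownames(m) %in% net$nodes
    m2 <- m[keep, keep, drop = FALSE]
    expect_equal(got$clustering, bf_transitivity(m2), tolerance = 1e-12)
    expect_equal(got$diameter, bf_diameter(m2))
  }
})

test_that("haversine distances match closed forms and validate input", {
  expect_equal(haversine_km(-12, 16, -12, 16), 0)
  expect_equal(haversine_km(0, 0, 0, 1), 2 * pi * 6371.0088 / 360,
    tolerance = 1e-6)
  expect_equal(haversine_km(0, 0, 180, 0), pi * 6371.0088, tolerance = 1e-6)
  expect_equal(
    haversine_km(-12, 16, -10, 18),
    haversine_km(-10, 18, -12, 16)
  )
  expect_error(haversine_km(-200, 0, 0, 0), "longitude")
  expect_error(haversine_km(0, 95, 0, 0), "latitude")
})

test_that("distance profiles bin movements consistently", {
  gaz <- toy_gazetteer()
  # all records between the same two endpoints fall in a single bin
  d_ab <- haversine_km(gaz$lon[1], gaz$lat[1], gaz$lon[2], gaz$lat[2])
  tbl <- rec(origin = rep("a", 4), destination = rep("b", 4), head = 10)
  prof <- distance_profile(tbl, gaz)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$bin_lo, floor(d_ab / 100) * 100)
  expect_equal(prof$n_movements, 4)
  expect_equal(prof$volume, 40)

  # conservation + brute-force per-record binning
  tbl2 <- random_movement_table(9)
  prof2 <- distance_profile(tbl2, gaz, bin_km = 50)
  expect_equal(sum(prof2$n_movements), nrow(tbl2))
  expect_equal(sum(prof2$volume), sum(tbl2$head_count))
  lon <- stats::setNames(gaz$lon, gaz$id)
  lat <- stats::setNames(gaz$lat, gaz$id)
  for (r in sample(nrow(tbl2), 10)) {
    d <- haversine_km(
      lon[tbl2$origin_id[r]], lat[tbl2$origin_id[r]],
      lon[tbl2$destination_id[r]], lat[tbl2$destination_id[r]]
    )
    hit <- prof2[
      prof2$destination_activity == tbl2$destination_activity[r] &
        prof2$bin_lo <= d & d < prof2$bin_hi,
    ]
    expect_equal(nrow(hit), 1)
  }

  expect_error(
    distance_profile(rec("zz", "b"), gaz),
    "zz"
  )
})

test_that("flow summaries report coherent percentages", {
  single <- rec("a", "b", head = 7)
  fs <- summarize_flows(single)
  expect_equal(fs$pct_movements, 100)
  expect_equal(fs$pct_volume, 100)

  tbl <- random_movement_table(13)
  fs2 <- summarize_flows(tbl, grouping = c("species", "transport"))
  expect_equal(sum(fs2$pct_movements), 100)
  expect_equal(sum(fs2$pct_volume), 100, tolerance = 1e-9)
  expect_equal(sum(fs2$n_movements), nrow(tbl))
  expect_equal(sum(fs2$volume), sum(tbl$head_count))

  expect_error(summarize_flows(tbl[0, ]), "empty")
  expect_error(summarize_flows(tbl, grouping = "colour"), "grouping")
})
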