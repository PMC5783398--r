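test_that("set Jaccard satisfies its defining identities", {
  expect_equal(jaccard_sets(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_sets(c("a"), c("b")), 0)
  expect_equal(jaccard_sets(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_sets(character(0), character(0)), 1)
  expect_equal(jaccard_sets(character(0), "a"), 0)
  # symmetry on random sets
  set.seed(5)
  for (i in 1:10) {
    a <- sample(letters, sample(0:10, 1))
    b <- sample(letters, sample(0:10, 1))
    j <- jaccard_sets(a, b)
    expect_equal(j, jaccard_sets(b, a))
    expect_gte(j, 0)
    expect_lte(j, 1)
  }
})

test_that("weighted Jaccard matches hand computations and reduces to the set form", {
  expect_equal(jaccard_weighted(c(e1 = 2, e2 = 4), c(e1 = 6, e3 = 1)), 2 / 11)
  expect_equal(jaccard_weighted(c(e1 = 2, e2 = 4), c(e1 = 2, e2 = 4)), 1)
  expect_equal(jaccard_weighted(numeric(0), c(e1 = 3)), 0)
  expect_equal(jaccard_weighted(numeric(0), numeric(0)), 1)
  expect_error(jaccard_weighted(c(e1 = -1), c(e1 = 2)), "positive")

  # equal weights: J' == J on random link sets; symmetry and bounds
  set.seed(6)
  for (i in 1:15) {
    a <- sample(letters, sample(1:12, 1))
    b <- sample(letters, sample(1:12, 1))
    wa <- stats::setNames(rep(3, length(a)), a)
    wb <- stats::setNames(rep(3, length(b)), b)
    expect_equal(jaccard_weighted(wa, wb), jaccard_sets(a, b))
    wa2 <- stats::setNames(runif(length(a), 1, 9), a)
    wb2 <- stats::setNames(runif(length(b), 1, 9), b)
    j <- jaccard_weighted(wa2, wb2)
    expect_equal(j, jaccard_weighted(wb2, wa2))
    expect_gte(j, 0)
    expect_lte(j, 1)
  }
})

test_that("the Jaccard series composes the base operations pairwise", {
  tbl <- random_movement_table(17)
  snaps <- monthly_snapshots(tbl)
  js <- jaccard_series(snaps)
  expect_equal(nrow(js), 11)
  for (i in sample(11, 4)) {
    a <- snaps[[i]]
    b <- snaps[[i + 1]]
    expect_equal(js$j_nodes[i], jaccard_sets(a$nodes, b$nodes))
    wa <- stats::setNames(a$links$volume,
      paste(a$links$origin, a$links$destination))
    wb <- stats::setNames(b$links$volume,
      paste(b$links$origin, b$links$destination))
    expect_equal(js$j_weights[i], jaccard_weighted(wa, wb))
  }
  expect_error(jaccard_series(snaps[1]), "2 snapshots")
})

test_that("identical snapshots give constant-1 series and a single period", {
  one_month <- rec(
    origin = c("a", "b"), destination = c("b", "c"), head = c(5, 9)
  )
  tbl <- dplyr::bind_rows(lapply(1:12, function(m) {
    x <- one_month
    x$month <- m
    x
  }))
  snaps <- monthly_snapshots(tbl)
  js <- jaccard_series(snaps)
  expect_true(all(js$j_nodes == 1 & js$j_links == 1 & js$j_weights == 1))
  pp <- detect_periods(snaps)
  expect_equal(pp$periods, list(1:12))

  forced <- detect_periods(snaps, n_periods = 12)
  expect_equal(length(forced$periods), 12)
  expect_error(detect_periods(snaps, n_periods = 13), "n_periods")
})

test_that("alternating disjoint link sets give a zero link series", {
  a <- rec(origin = "a", destination = "b")
  b <- rec(origin = "x", destination = "y")
  tbl <- dplyr::bind_rows(lapply(1:12, function(m) {
    x <- if (m %% 2 == 1) a else b
    x$month <- m
    x
  }))
  js <- jaccard_series(monthly_snapshots(tbl))
  expect_true(all(js$j_links == 0))
  expect_true(all(js$j_weights == 0))
})

test_that("period detection is destroyed by shuffling months", {
  hits <- 0
  for (s in 1:5) {
    cfg <- sim_config(seed = 100 + s)
    gaz <- generate_locations(cfg)
    gen <- generate_movements(gaz, cfg)
    tbl <- gen$movements
    set.seed(s)
    perm <- sample(1:12)
    tbl$month <- perm[tbl$month]
    pp <- detect_periods(monthly_snapshots(tbl))
    if (length(pp$periods) == 2 &&
        identical(sort(pp$periods[[1]]), 1:8)) {
      hits <- hits + 1
    }
  }
  expect_lte(hits, 1)
})

test_that("links are classified by their exact activity-month counts", {
  mk <- function(months) {
    dplyr::bind_rows(lapply(months, function(m) {
      rec(origin = "a", destination = "b", month = m)
    }))
  }
  all_year <- classify_links(build_network(mk(1:12)))
  expect_equal(as.character(all_year$class), "backbone")
  five <- classify_links(build_network(mk(c(2, 5, 9, 11, 12))))
  expect_equal(as.character(five$class), "intermediate")
  once <- classify_links(build_network(mk(10)))
  expect_equal(as.character(once$class), "occasional")
  seven <- classify_links(build_network(mk(1:7)))
  expect_equal(as.character(seven$class), "frequent")

  # snapshot-based classification agrees with the annual network
  tbl <- random_movement_table(23)
  net <- build_network(tbl)
  from_net <- classify_links(net)
  from_snaps <- classify_links(monthly_snapshots(tbl))
  ord <- function(x) {
    x <- as.data.frame(x)[order(x$origin, x$destination), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(from_net), ord(from_snaps))
})

test_that("class subnetworks partition the annual network", {
  tbl <- random_movement_table(29)
  net <- build_network(tbl)
  cm <- classify_links(net)
  subs <- lapply(levels(cm$class), function(cl) {
    class_subnetwork(net, cm, cl)
  })
  links_union <- dplyr::bind_rows(lapply(subs, function(s) s$links))
  links_union <- links_union[order(links_union$origin, links_union$destination), ]
  expect_equal(
    as.data.frame(links_union),
    as.data.frame(net$links),
    ignore_attr = TRUE
  )
  expect_equal(
    sum(vapply(subs, function(s) sum(s$links$volume), numeric(1))),
    sum(net$links$volume)
  )
  # link-disjoint classes
  keys <- unlist(lapply(subs, function(s) {
    paste(s$links$origin, s$links$destination)
  }))
  expect_false(any(duplicated(keys)))
})

test_that("the activity raster mirrors raw monthly activity", {
  tbl <- random_movement_table(37)
  net <- build_network(tbl)
  snaps <- monthly_snapshots(tbl)
  cm <- classify_links(net)
  ras <- activity_raster(cm, snaps)
  mat <- as.matrix(ras[paste0("month_", 1:12)])
  expect_equal(unname(rowSums(mat)), as.double(cm$n_months))
  backbone_rows <- ras$class == "backbone"
  if (any(backbone_rows)) {
    expect_true(all(mat[backbone_rows, ]))
  }
  # oracle: recompute from raw records
  for (r in sample(nrow(ras), 5)) {
    months <- sort(unique(tbl$month[
      tbl$origin_id == ras$origin[r] & tbl$destination_id == ras$destination[r]
    ]))
    expect_equal(which(mat[r, ]), months, ignore_attr = TRUE)
  }
})
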