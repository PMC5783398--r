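# Fixtures and independent brute-force oracles used across the suite.
# All oracles work on plain matrices/loops, independent of the package's
# (igraph/dplyr) implementation paths.

toy_gazetteer <- function() {
  tibble::tibble(
    id = c("a", "b", "c", "d", "e", "f", "g", "h"),
    name = paste("Place", c("a", "b", "c", "d", "e", "f", "g", "h")),
    country = c("MRT", "MRT", "MRT", "MRT", "MRT", "MRT", "SEN", "MLI"),
    lon = c(-12, -11, -10, -13, -14, -9, -13.5, -8.5),
    lat = c(16, 17, 16.5, 18, 15.5, 17.5, 14.8, 14.9),
    activities = c(
      "zone_elevage", "zone_elevage;market", "market",
      "zone_elevage;slaughterhouse", "zone_elevage", "resting_area",
      "market", "zone_elevage;market"
    )
  )
}

# quick movement-record constructor (vectorised over its arguments)
rec <- function(origin, destination, month = 1, species = "small_ruminants",
                head = 10, transport = "foot", oact = "zone_elevage",
                dact = "market", scope = "national") {
  tibble::tibble(
    origin_id = origin, destination_id = destination,
    month = as.integer(month), species = species,
    head_count = as.integer(head), transport = transport,
    origin_activity = oact, destination_activity = dact,
    scope = scope
  )
}

movement_cols <- function() {
  c(
    "origin_id", "destination_id", "month", "species", "head_count",
    "transport", "origin_activity", "destination_activity"
  )
}

random_movement_table <- function(seed, n = 80) {
  set.seed(seed)
  gaz <- toy_gazetteer()
  ids <- gaz$id
  country <- stats::setNames(gaz$country, gaz$id)
  o <- sample(ids, n, replace = TRUE)
  d <- vapply(o, function(x) sample(setdiff(ids, x), 1), character(1))
  d <- unname(d)
  rec(
    origin = o, destination = d,
    month = sample(1:12, n, replace = TRUE),
    species = sample(c("small_ruminants", "cattle", "dromedaries"), n,
      replace = TRUE),
    head = sample(1:500, n, replace = TRUE),
    transport = sample(c("foot", "truck"), n, replace = TRUE),
    oact = sample(c("zone_elevage", "market"), n, replace = TRUE),
    dact = sample(c("zone_elevage", "market", "slaughterhouse"), n,
      replace = TRUE),
    scope = unname(ifelse(country[o] == "MRT" & country[d] == "MRT",
      "national", "international"))
  )
}

# weighted directed adjacency matrix -> movement table (one record per link)
table_from_matrix <- function(mat) {
  ids <- rownames(mat)
  idx <- which(mat > 0, arr.ind = TRUE)
  rec(
    origin = ids[idx[, 1]], destination = ids[idx[, 2]],
    month = 1, head = mat[idx]
  )
}

random_digraph_matrix <- function(seed, n_max = 5, w_max = 3) {
  set.seed(seed)
  n <- sample(2:n_max, 1)
  ids <- letters[seq_len(n)]
  m <- matrix(
    sample(0:w_max, n * n, replace = TRUE, prob = c(0.5, rep(0.5 / w_max, w_max))),
    n, n, dimnames = list(ids, ids)
  )
  diag(m) <- 0
  m
}

# ---- brute-force nodal-region oracle (plain loops) ----
bf_nodal_regions <- function(mat, threshold = 0.20, prune = TRUE) {
  ids <- rownames(mat)
  if (prune) {
    for (i in ids) {
      out <- sum(mat[i, ])
      if (out > 0) {
        mat[i, mat[i, ] / out <= threshold] <- 0
      }
    }
  }
  in_vol <- colSums(mat)
  dominant <- list()
  for (i in ids) {
    if (sum(mat[i, ]) == 0) next
    mx <- max(mat[i, ])
    cand <- ids[mat[i, ] == mx]
    if (length(cand) > 1) {
      cand <- cand[in_vol[cand] == max(in_vol[cand])]
      cand <- sort(cand)[1]
    }
    if (in_vol[cand] > in_vol[i]) {
      dominant[[length(dominant) + 1]] <- c(i, cand)
    }
  }
  if (length(dominant) == 0) {
    return(list(
      assignments = data.frame(node = character(0), parent = character(0)),
      dominant_nodes = character(0)
    ))
  }
  asg <- data.frame(
    node = vapply(dominant, `[`, character(1), 1),
    parent = vapply(dominant, `[`, character(1), 2)
  )
  list(
    assignments = asg[order(asg$node), ],
    dominant_nodes = sort(setdiff(unique(asg$parent), asg$node))
  )
}

# ---- brute-force graph metrics on the undirected projection ----
bf_undirected <- function(mat) {
  a <- (mat > 0 | t(mat) > 0) * 1
  diag(a) <- 0
  a
}

bf_transitivity <- function(mat) {
  a <- bf_undirected(mat)
  deg <- rowSums(a)
  triples <- sum(deg * (deg - 1) / 2)
  triangles <- sum(diag(a %*% a %*% a)) / 6
  if (triples == 0) 0 else 3 * triangles / triples
}

bf_components_weak <- function(mat) {
  a <- bf_undirected(mat)
  n <- nrow(a)
  label <- rep(NA_integer_, n)
  comp <- 0
  for (s in seq_len(n)) {
    if (!is.na(label[s])) next
    comp <- comp + 1
    frontier <- s
    label[s] <- comp
    while (length(frontier) > 0) {
      nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & is.na(label))
      label[nxt] <- comp
      frontier <- nxt
    }
  }
  label
}

bf_largest_strong <- function(mat) {
  n <- nrow(mat)
  reach <- (mat > 0)
  diag(reach) <- TRUE
  for (k in seq_len(n)) {
    reach <- reach | (reach[, k] %*% t(reach[k, ]) > 0)
  }
  mutual <- reach & t(reach)
  max(vapply(seq_len(n), function(i) sum(mutual[i, ]), numeric(1)))
}

bf_diameter <- function(mat) {
  a <- bf_undirected(mat)
  label <- bf_components_weak(mat)
  giant <- which(label == which.max(tabulate(label)))
  a <- a[giant, giant, drop = FALSE]
  n <- nrow(a)
  if (n == 1) {
    return(0L)
  }
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  dist[a == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (dist[i, k] + dist[k, j] < dist[i, j]) {
          dist[i, j] <- dist[i, k] + dist[k, j]
        }
      }
    }
  }
  as.integer(max(dist[is.finite(dist)]))
}

# tiny network builder straight from an edge tibble (bypasses records)
net_from_edges <- function(origin, destination, volume) {
  network_from_edge_list(tibble::tibble(
    origin = origin, destination = destination, volume = volume,
    n_movements = 1L,
    months_active = replicate(length(origin), 1L, simplify = FALSE)
  ))
}

make_random_net <- function(seed, ids = sprintf("n%02d", 1:20), p = 0.25) {
  set.seed(seed)
  pairs <- expand.grid(origin = ids, destination = ids,
    stringsAsFactors = FALSE)
  pairs <- pairs[pairs$origin != pairs$destination, ]
  pairs <- pairs[runif(nrow(pairs)) < p, ]
  net_from_edges(pairs$origin, pairs$destination,
    volume = round(rlnorm(nrow(pairs), 4, 1)) + 1)
}
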