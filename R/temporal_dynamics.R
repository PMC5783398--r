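# Temporal dynamics: Jaccard similarity between monthly snapshots,
# contiguity-constrained segmentation of the year into mobility periods, and
# persistence-based link classification.

#' Jaccard index of two sets
#'
#' `|A n B| / |A u B|`; two empty sets are identical by convention (1),
#' since 0/0 is otherwise undefined.
#'
#' @param a,b Vectors treated as sets.
#' @return Value in \[0, 1\].
#' @export
#' @examples
#' jaccard_sets(c("a", "b", "c"), c("b", "c", "d")) # 0.5
jaccard_sets <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    return(1)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Weighted Jaccard index of two link-weight maps
#'
#' Sum of elementwise minimum weights over the link union divided by the sum
#' of elementwise maximum weights; a link absent from one map contributes
#' weight 0 there. Two empty maps return 1 (identical).
#'
#' @param a,b Named numeric vectors of positive link weights (names are link
#'   identifiers).
#' @return Value in \[0, 1\].
#' @export
#' @examples
#' jaccard_weighted(c(e1 = 2, e2 = 4), c(e1 = 6, e3 = 1)) # 2/11
jaccard_weighted <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    stop("link weights must be positive", call. = FALSE)
  }
  keys <- union(names(a), names(b))
  if (length(keys) == 0) {
    return(1)
  }
  wa <- setNames(numeric(length(keys)), keys)
  wb <- wa
  wa[names(a)] <- a
  wb[names(b)] <- b
  sum(pmin(wa, wb)) / sum(pmax(wa, wb))
}

link_weights <- function(network) {
  setNames(
    network$links$volume,
    link_key(network$links$origin, network$links$destination)
  )
}

snapshot_jaccards <- function(a, b) {
  c(
    j_nodes = jaccard_sets(a$nodes, b$nodes),
    j_links = jaccard_sets(names(link_weights(a)), names(link_weights(b))),
    j_weights = jaccard_weighted(link_weights(a), link_weights(b))
  )
}

#' Jaccard series over consecutive monthly snapshots
#'
#' For each consecutive snapshot pair, the plain Jaccard index of the node
#' sets and of the link sets, and the weighted Jaccard index of the
#' link-volume maps.
#'
#' @param snapshots Ordered list of `mobility_network` snapshots (length >= 2),
#'   e.g. from [monthly_snapshots()].
#' @return Tibble with `from`, `to`, `j_nodes`, `j_links`, `j_weights`
#'   (one row per consecutive pair; 11 rows for a 12-month year).
#' @export
jaccard_series <- function(snapshots) {
  if (length(snapshots) < 2) {
    stop("at least 2 snapshots are required", call. = FALSE)
  }
  n <- length(snapshots)
  rows <- lapply(seq_len(n - 1), function(i) {
    j <- snapshot_jaccards(snapshots[[i]], snapshots[[i + 1]])
    tibble::tibble(
      from = i, to = i + 1,
      j_nodes = j[["j_nodes"]],
      j_links = j[["j_links"]],
      j_weights = j[["j_weights"]]
    )
  })
  bind_rows(rows)
}

#' Segment the year into mobility periods
#'
#' Contiguity-constrained agglomerative clustering of the snapshots: the
#' dissimilarity between two snapshots is one minus the weighted mean of
#' their node, link and volume Jaccard indices; adjacent clusters are merged
#' greedily (average linkage) and the merge costs recorded. With
#' `n_periods = NULL` the number of periods is chosen among the partitions
#' the merge sequence generates by maximising the mean silhouette width
#' (singleton clusters contribute 0); if all snapshots are identical a
#' single period is returned. The default weights (0, 0, 1) segment on the
#' volume Jaccard alone, the index that carries the seasonal signal in
#' livestock systems where the link set is more stable than the traded
#' volumes.
#'
#' @param snapshots Ordered list of `mobility_network` snapshots.
#' @param weights Length-3 non-negative weights for (nodes, links, volume)
#'   Jaccard indices.
#' @param n_periods Fixed number of periods, or `NULL` for the automatic cut.
#' @return A `period_partition`: `periods` (list of contiguous month
#'   vectors), `merge_costs`, `boundaries` (first month of each period after
#'   the first), `weights`.
#' @export
detect_periods <- function(snapshots, weights = c(0, 0, 1),
                           n_periods = NULL) {
  n <- length(snapshots)
  if (n < 2) {
    stop("at least 2 snapshots are required", call. = FALSE)
  }
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0)
  if (!is.null(n_periods) && (n_periods < 1 || n_periods > n)) {
    stop("n_periods must lie in 1..", n, call. = FALSE)
  }
  weights <- weights / sum(weights)

  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      jac <- snapshot_jaccards(snapshots[[i]], snapshots[[j]])
      d[i, j] <- d[j, i] <- 1 - sum(weights * jac)
    }
  }

  clusters <- as.list(seq_len(n))
  merge_costs <- numeric(0)
  while (length(clusters) > 1) {
    costs <- vapply(seq_len(length(clusters) - 1), function(k) {
      mean(d[clusters[[k]], clusters[[k + 1]], drop = FALSE])
    }, numeric(1))
    k <- which.min(costs)
    merge_costs <- c(merge_costs, costs[k])
    clusters[[k]] <- c(clusters[[k]], clusters[[k + 1]])
    clusters[[k + 1]] <- NULL
  }

  if (is.null(n_periods)) {
    if (max(merge_costs) < 1e-12) {
      n_periods <- 1L
    } else {
      sil <- vapply(2:(n - 1), function(k) {
        mean_silhouette(d, replay_merges(n, d, k))
      }, numeric(1))
      n_periods <- if (max(sil) <= 0) 1L else (2:(n - 1))[which.max(sil)]
    }
  }
  periods <- replay_merges(n, d, n_periods)

  structure(
    list(
      periods = periods,
      merge_costs = merge_costs,
      boundaries = vapply(periods[-1], min, numeric(1)),
      weights = weights
    ),
    class = "period_partition"
  )
}

# mean silhouette width of a partition under dissimilarity matrix d;
# singleton clusters contribute 0
mean_silhouette <- function(d, partition) {
  labels <- integer(nrow(d))
  for (c in seq_along(partition)) labels[partition[[c]]] <- c
  s <- vapply(seq_len(nrow(d)), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1) {
      return(0)
    }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(c) mean(d[i, which(labels == c)]),
      numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# deterministic replay of the greedy contiguous merges down to n_periods
replay_merges <- function(n, d, n_periods) {
  clusters <- as.list(seq_len(n))
  while (length(clusters) > n_periods) {
    costs <- vapply(seq_len(length(clusters) - 1), function(k) {
      mean(d[clusters[[k]], clusters[[k + 1]], drop = FALSE])
    }, numeric(1))
    k <- which.min(costs)
    clusters[[k]] <- c(clusters[[k]], clusters[[k + 1]])
    clusters[[k + 1]] <- NULL
  }
  lapply(clusters, sort)
}

#' @export
print.period_partition <- function(x, ...) {
  cat("Mobility periods:\n")
  for (p in x$periods) {
    cat("  months", min(p), "-", max(p), "\n")
  }
  invisible(x)
}

persistence_class <- function(n_months) {
  stopifnot(all(n_months >= 1 & n_months <= 12))
  cls <- character(length(n_months))
  cls[n_months == 12] <- "backbone"
  cls[n_months >= 7 & n_months <= 11] <- "frequent"
  cls[n_months >= 3 & n_months <= 6] <- "intermediate"
  cls[n_months <= 2] <- "occasional"
  factor(cls, levels = hf_classes)
}

#' Classify links by activity persistence
#'
#' Counts each link's active months over the year and assigns the fixed
#' persistence classes: backbone (all 12 months), frequent (7-11),
#' intermediate (3-6), occasional (1-2). The four classes partition the
#' links of the annual network.
#'
#' @param x An annual `mobility_network` (window 1..12) or a list of 12
#'   monthly snapshots.
#' @return A `link_class_map` tibble: `origin`, `destination`, `n_months`,
#'   `class`.
#' @export
classify_links <- function(x) {
  if (inherits(x, "mobility_network")) {
    links <- x$links
    n_months <- lengths(links$months_active)
    out <- tibble::tibble(
      origin = links$origin,
      destination = links$destination,
      n_months = as.integer(n_months)
    )
  } else {
    stopifnot(is.list(x), length(x) == 12)
    keys <- lapply(x, function(s) {
      link_key(s$links$origin, s$links$destination)
    })
    all_keys <- sort(unique(unlist(keys)))
    counts <- setNames(integer(length(all_keys)), all_keys)
    for (k in keys) {
      counts[k] <- counts[k] + 1L
    }
    parts <- strsplit(all_keys, " -> ", fixed = TRUE)
    out <- tibble::tibble(
      origin = vapply(parts, `[`, character(1), 1),
      destination = vapply(parts, `[`, character(1), 2),
      n_months = as.integer(counts)
    )
  }
  out$class <- persistence_class(out$n_months)
  class(out) <- c("link_class_map", class(out))
  out
}

#' Subnetwork of one persistence class
#'
#' @param network Annual `mobility_network`.
#' @param class_map A `link_class_map` from [classify_links()].
#' @param class One of `backbone`, `frequent`, `intermediate`, `occasional`.
#' @return A `mobility_network` restricted to links of that class, volumes
#'   preserved.
#' @export
class_subnetwork <- function(network, class_map, class) {
  stopifnot(inherits(network, "mobility_network"))
  assert_tokens(class, hf_classes, "persistence class")
  sel <- class_map[class_map$class == class, ]
  keys <- link_key(sel$origin, sel$destination)
  links <- network$links[
    link_key(network$links$origin, network$links$destination) %in% keys,
  ]
  records <- network$records
  if (!is.null(records)) {
    records <- records[
      link_key(records$origin_id, records$destination_id) %in% keys,
    ]
  }
  net <- new_mobility_network(
    links = links,
    window = network$window,
    filter = network$filter,
    records = records
  )
  net$persistence_class <- class
  net
}

#' Per-link monthly activity raster
#'
#' Boolean links-by-months table (the data behind link-activity strip plots):
#' one row per link, TRUE where the link is active that month, annotated with
#' the persistence class.
#'
#' @param class_map A `link_class_map`.
#' @param snapshots List of 12 monthly snapshots.
#' @return Tibble with `origin`, `destination`, `class`, `month_1` ..
#'   `month_12`.
#' @export
activity_raster <- function(class_map, snapshots) {
  stopifnot(is.list(snapshots), length(snapshots) == 12)
  keys <- link_key(class_map$origin, class_map$destination)
  mat <- matrix(FALSE, nrow = length(keys), ncol = 12,
    dimnames = list(keys, paste0("month_", 1:12)))
  for (m in 1:12) {
    active <- link_key(
      snapshots[[m]]$links$origin, snapshots[[m]]$links$destination
    )
    mat[keys %in% active, m] <- TRUE
  }
  out <- tibble::tibble(
    origin = class_map$origin,
    destination = class_map$destination,
    class = class_map$class
  )
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}
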