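# Dominant-flow (nodal-region) decomposition.
#
# The method extracts the market hierarchy of a weighted directed network:
# a link i -> j is dominant when j receives the largest share of i's outgoing
# volume AND j's total in-volume exceeds i's. Dominant links form a forest of
# trees rooted at dominant (central) nodes; each tree is the influence area
# of its root. Minor outgoing links (at most `threshold` of their origin's
# out-volume) are pruned first.

#' Prune minor outgoing links
#'
#' Keeps link (i, j) iff its volume is strictly more than `threshold` of i's
#' total outgoing volume; nodes left without any incident link are dropped.
#'
#' @param network A `mobility_network`.
#' @param threshold Fraction in (0, 1); default 0.20.
#' @return A pruned `mobility_network`.
#' @export
prune_minor_links <- function(network, threshold = 0.20) {
  stopifnot(inherits(network, "mobility_network"))
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  links <- network$links
  if (nrow(links) == 0) {
    return(network)
  }
  out_vol <- tapply(links$volume, links$origin, sum)
  frac <- links$volume / as.numeric(out_vol[links$origin])
  kept <- links[frac > threshold, ]
  records <- network$records
  if (!is.null(records)) {
    keys <- link_key(kept$origin, kept$destination)
    records <- records[
      link_key(records$origin_id, records$destination_id) %in% keys,
    ]
  }
  net <- new_mobility_network(
    links = kept,
    window = network$window,
    filter = network$filter,
    records = records
  )
  net$pruned_at <- threshold
  net
}

#' Nodal-region decomposition by dominant flows
#'
#' For every node i with outgoing links, the candidate parent is the
#' destination receiving i's largest outgoing volume (ties broken towards the
#' destination with larger total in-volume, then lexicographically). The link
#' is dominant iff the candidate's in-volume strictly exceeds i's. Dominant
#' links define a forest; its roots — parents with no dominant outgoing link
#' of their own — are the dominant nodes and their trees the influence areas.
#'
#' @param network A `mobility_network`.
#' @param threshold Pruning threshold passed to [prune_minor_links()].
#' @param prune Apply the pruning step first (default TRUE). Set FALSE if the
#'   network has already been pruned.
#' @return A `nodal_region_forest`: `dominant_nodes`, `assignments` (tibble
#'   `node`, `parent`), `retained_links` (the dominant links), `regions`
#'   (named list: root -> member nodes), `coverage` (see
#'   [reduction_stats()]).
#' @export
nodal_regions <- function(network, threshold = 0.20, prune = TRUE) {
  stopifnot(inherits(network, "mobility_network"))
  net <- if (prune) prune_minor_links(network, threshold) else network
  links <- net$links

  in_vol <- setNames(numeric(length(net$nodes)), net$nodes)
  if (nrow(links) > 0) {
    agg <- tapply(links$volume, links$destination, sum)
    in_vol[names(agg)] <- as.numeric(agg)
  }

  dominant <- links[0, ]
  for (i in unique(links$origin)) {
    cand <- links[links$origin == i, ]
    cand <- cand[cand$volume == max(cand$volume), ]
    if (nrow(cand) > 1) {
      cand <- cand[in_vol[cand$destination] ==
        max(in_vol[cand$destination]), ]
      cand <- cand[order(cand$destination), ][1, ]
    }
    if (in_vol[[cand$destination]] > in_vol[[i]]) {
      dominant <- bind_rows(dominant, cand)
    }
  }

  assignments <- tibble::tibble(
    node = dominant$origin,
    parent = dominant$destination
  )
  parents <- unique(assignments$parent)
  dominant_nodes <- sort(setdiff(parents, assignments$node))

  regions <- lapply(dominant_nodes, function(root) {
    members <- character(0)
    frontier <- root
    while (length(frontier) > 0) {
      children <- assignments$node[assignments$parent %in% frontier]
      children <- setdiff(children, members)
      members <- c(members, children)
      frontier <- children
    }
    sort(members)
  })
  names(regions) <- dominant_nodes

  forest <- structure(
    list(
      dominant_nodes = dominant_nodes,
      assignments = assignments,
      retained_links = dominant,
      regions = regions,
      threshold = if (prune) threshold else net$pruned_at
    ),
    class = "nodal_region_forest"
  )
  forest$coverage <- reduction_stats(forest, network)
  forest
}

#' @export
print.nodal_region_forest <- function(x, ...) {
  cat("Nodal-region forest:", length(x$dominant_nodes), "dominant node(s),",
    nrow(x$retained_links), "dominant link(s)\n")
  cov <- x$coverage
  cat(sprintf(
    "  coverage: %d nodes, %d links, %.1f%% of original volume\n",
    cov$n_nodes, cov$n_links, 100 * cov$volume_fraction
  ))
  invisible(x)
}

#' Coverage of a nodal-region forest
#'
#' How much of the original network the dominant-link skeleton retains.
#'
#' @param forest A `nodal_region_forest`.
#' @param original_network The `mobility_network` the forest was derived
#'   from (pre-pruning).
#' @return List with `n_nodes`, `n_links` and `volume_fraction` (retained
#'   link volume over total original link volume).
#' @export
reduction_stats <- function(forest, original_network) {
  stopifnot(inherits(forest, "nodal_region_forest"),
    inherits(original_network, "mobility_network"))
  retained <- forest$retained_links
  missing <- setdiff(
    link_key(retained$origin, retained$destination),
    link_key(original_network$links$origin,
      original_network$links$destination)
  )
  if (length(missing) > 0) {
    stop("forest links not present in the supplied network: ",
      paste(missing, collapse = ", "), call. = FALSE)
  }
  total <- sum(original_network$links$volume)
  list(
    n_nodes = length(unique(c(retained$origin, retained$destination))),
    n_links = nrow(retained),
    volume_fraction = if (total > 0) sum(retained$volume) / total else 0
  )
}
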