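# Aggregation of movement records into directed weighted networks.
#
# A link is drawn between an origin-destination pair as soon as a single
# animal moved between them inside the chosen window; all matching records
# are aggregated onto it. "Volume" is always a head count and "frequency"
# (n_movements) a record count. The network object keeps the matching records
# so that any later filter re-derives attributes exactly instead of
# approximating them from aggregates.

#' Build a mobility network from movement records
#'
#' Aggregates all records falling in `window` (and matching the optional
#' filters) into a directed weighted network. Self-loops, which can appear
#' when distinct place names resolve to the same location id, are dropped
#' with a warning. Nodes are the endpoints of surviving links; endpoints of
#' filtered-out records do not appear.
#'
#' @param table Validated movement tibble (with `scope`), e.g. the
#'   `movements` element of [read_movements()] or [generate_movements()].
#' @param window Set of months (subset of 1..12) the network covers.
#' @param species,transport,scope Optional filters; vectors of allowed tokens.
#' @return A `mobility_network`: list with `links` (tibble: `origin`,
#'   `destination`, `volume`, `n_movements`, `months_active` list-column,
#'   per-species and per-transport volumes, `scope`), `nodes`, `window`,
#'   `filter` and the matching `records`.
#' @export
build_network <- function(table, window = 1:12, species = NULL,
                          transport = NULL, scope = NULL) {
  assert_columns(table, c(movement_columns, "scope"), "movement table")
  window <- sort(unique(as.integer(window)))
  if (length(window) == 0) {
    stop("window must contain at least one month", call. = FALSE)
  }
  if (!all(window %in% 1:12)) {
    stop("window must be a subset of 1..12", call. = FALSE)
  }
  if (!is.null(species)) assert_tokens(species, hf_species, "species")
  if (!is.null(transport)) assert_tokens(transport, hf_transport, "transport")
  if (!is.null(scope)) assert_tokens(scope, hf_scopes, "scope")

  recs <- tibble::as_tibble(table)
  recs <- recs[recs$month %in% window, ]
  if (!is.null(species)) recs <- recs[recs$species %in% species, ]
  if (!is.null(transport)) recs <- recs[recs$transport %in% transport, ]
  if (!is.null(scope)) recs <- recs[recs$scope %in% scope, ]

  self <- recs$origin_id == recs$destination_id
  if (any(self)) {
    warning(sum(self), " self-loop record(s) dropped", call. = FALSE)
    recs <- recs[!self, ]
  }

  links <- recs %>%
    group_by(origin = .data$origin_id, destination = .data$destination_id) %>%
    summarise(
      volume = sum(.data$head_count),
      n_movements = dplyr::n(),
      months_active = list(sort(unique(.data$month))),
      vol_small_ruminants =
        sum(.data$head_count[.data$species == "small_ruminants"]),
      vol_cattle = sum(.data$head_count[.data$species == "cattle"]),
      vol_dromedaries =
        sum(.data$head_count[.data$species == "dromedaries"]),
      vol_foot = sum(.data$head_count[.data$transport == "foot"]),
      vol_truck = sum(.data$head_count[.data$transport == "truck"]),
      scope = .data$scope[1],
      .groups = "drop"
    ) %>%
    arrange(.data$origin, .data$destination)

  new_mobility_network(
    links = links,
    window = window,
    filter = list(species = species, transport = transport, scope = scope),
    records = recs
  )
}

new_mobility_network <- function(links, window, filter, records = NULL) {
  nodes <- sort(unique(c(links$origin, links$destination)))
  structure(
    list(
      links = links,
      nodes = nodes,
      window = window,
      filter = filter,
      records = records
    ),
    class = "mobility_network"
  )
}

#' Rebuild a network object from an imported edge list
#'
#' Inverse of [write_edge_list()] for the CSV format: reconstructs a
#' `mobility_network` from aggregated links alone. The result carries no
#' record backing, so record-level filters ([filter_view()]) are unavailable
#' on it.
#'
#' @param links Links tibble from [read_edge_list()].
#' @param window Months the edge list covers.
#' @return A `mobility_network`.
#' @export
network_from_edge_list <- function(links, window = 1:12) {
  assert_columns(
    links,
    c("origin", "destination", "volume", "n_movements", "months_active"),
    "edge list"
  )
  links <- arrange(tibble::as_tibble(links), .data$origin, .data$destination)
  new_mobility_network(
    links = links,
    window = sort(unique(as.integer(window))),
    filter = list(species = NULL, transport = NULL, scope = NULL),
    records = NULL
  )
}

#' @export
print.mobility_network <- function(x, ...) {
  cat("Mobility network:", length(x$nodes), "nodes,",
    nrow(x$links), "links,", sum(x$links$volume), "heads\n")
  cat("  window:", paste(x$window, collapse = ","), "\n")
  applied <- Filter(Negate(is.null), x$filter)
  if (length(applied) > 0) {
    cat("  filter:", paste(names(applied),
      vapply(applied, paste, character(1), collapse = "|"),
      sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Monthly snapshots of the mobility network
#'
#' Builds the 12 month-restricted networks: snapshot m contains exactly the
#' links active in month m; months without records yield empty networks.
#'
#' @inheritParams build_network
#' @return A named list of 12 `mobility_network` objects (`"1"`..`"12"`).
#' @export
monthly_snapshots <- function(table, species = NULL, transport = NULL,
                              scope = NULL) {
  out <- lapply(1:12, function(m) {
    build_network(table, window = m, species = species,
      transport = transport, scope = scope)
  })
  names(out) <- as.character(1:12)
  out
}

#' Filter a movement table or network by attribute
#'
#' Restricts to records matching the given species/transport/scope tokens.
#' Applied to a `mobility_network`, the network is rebuilt from its backing
#' records with the combined filters, so link attribute maps are re-derived
#' exactly. Filters commute.
#'
#' @param x A movement tibble or a `mobility_network`.
#' @param species,transport,scope Optional token vectors.
#' @return Object of the same kind as `x`.
#' @export
filter_view <- function(x, species = NULL, transport = NULL, scope = NULL) {
  UseMethod("filter_view")
}

#' @export
filter_view.data.frame <- function(x, species = NULL, transport = NULL,
                                   scope = NULL) {
  assert_columns(x, c(movement_columns, "scope"), "movement table")
  if (!is.null(species)) {
    assert_tokens(species, hf_species, "species")
    x <- x[x$species %in% species, ]
  }
  if (!is.null(transport)) {
    assert_tokens(transport, hf_transport, "transport")
    x <- x[x$transport %in% transport, ]
  }
  if (!is.null(scope)) {
    assert_tokens(scope, hf_scopes, "scope")
    x <- x[x$scope %in% scope, ]
  }
  x
}

#' @export
filter_view.mobility_network <- function(x, species = NULL, transport = NULL,
                                         scope = NULL) {
  if (is.null(x$records)) {
    stop("this network carries no record backing (imported edge list); ",
      "filter the movement table instead", call. = FALSE)
  }
  build_network(
    x$records,
    window = x$window,
    species = species %||% x$filter$species,
    transport = transport %||% x$filter$transport,
    scope = scope %||% x$filter$scope
  )
}

#' Convert a mobility network to an igraph graph
#'
#' @param network A `mobility_network`.
#' @return A directed igraph object with `volume`, `n_movements`, `scope` and
#'   semicolon-joined `months_active` edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "mobility_network"))
  edges <- network$links
  edges$months_active <- vapply(
    edges$months_active,
    function(m) paste(m, collapse = ";"),
    character(1)
  )
  igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = data.frame(name = network$nodes)
  )
}
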