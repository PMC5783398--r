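# Descriptive topology and summary tables: degree/weight distributions with
# power-law fits, components, clustering and diameter, great-circle distance
# profiles and activity/species/transport flow breakdowns.

#' Degree distribution of a mobility network
#'
#' @param network Non-empty `mobility_network`.
#' @param direction `"total"`, `"in"` or `"out"`.
#' @return List with per-node `degrees`, histogram `hist` (degree -> node
#'   count), `min` and `max`.
#' @export
degree_distribution_summary <- function(network,
                                        direction = c("total", "in", "out")) {
  stopifnot(inherits(network, "mobility_network"))
  direction <- match.arg(direction)
  if (length(network$nodes) == 0) {
    stop("degree distribution of an empty network is undefined",
      call. = FALSE)
  }
  g <- as_igraph(network)
  mode <- c(total = "all", `in` = "in", out = "out")[[direction]]
  deg <- igraph::degree(g, mode = mode, loops = FALSE)
  hist <- base::table(deg)
  list(
    direction = direction,
    degrees = deg,
    hist = setNames(as.integer(hist), names(hist)),
    min = min(deg),
    max = max(deg)
  )
}

#' Fit a power law to degrees or link volumes
#'
#' Maximum-likelihood (Clauset-style, via igraph's plfit implementation) fit
#' of P(x) ~ x^-alpha, with `xmin` fixed at the minimum observed value by
#' default so the whole distribution is fitted, as is usual when exponents
#' are read off log-log degree plots. A log-log least-squares fit on the
#' histogram is available for comparability with such plots. Exponents are
#' reported as positive magnitudes.
#'
#' @param values Positive numeric values (degrees or link volumes).
#' @param kind `"degree"` (discrete) or `"weight"` (continuous).
#' @param method `"mle"` or `"ls"` (log-log least squares on the histogram).
#' @param xmin Lower cut-off; defaults to `min(values)`.
#' @return List of class `power_law_fit`: `exponent`, `se`, `xmin`, `method`,
#'   `n_tail`, `ks_stat`, `ks_p` (MLE only) and a `poor_fit` flag.
#' @export
fit_power_law <- function(values, kind = c("degree", "weight"),
                          method = c("mle", "ls"), xmin = NULL) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (any(values <= 0)) {
    stop("power-law fit requires strictly positive values", call. = FALSE)
  }
  if (length(unique(values)) < 3) {
    stop("power-law fit requires at least 3 distinct values", call. = FALSE)
  }
  xmin <- xmin %||% min(values)
  tail_vals <- values[values >= xmin]

  if (method == "mle") {
    fit <- igraph::fit_power_law(
      tail_vals,
      xmin = xmin,
      implementation = "plfit",
      force.continuous = (kind == "weight")
    )
    exponent <- fit$alpha
    # standard large-sample approximation for the MLE of the exponent
    se <- (exponent - 1) / sqrt(length(tail_vals))
    ks_stat <- fit$KS.stat
    # asymptotic Kolmogorov p-value (ignores the fitted parameter, so it is
    # approximate; with a fixed xmin plfit reports no p-value of its own)
    ks_p <- kolmogorov_pvalue(sqrt(length(tail_vals)) * ks_stat)
    poor <- is.finite(ks_p) && ks_p < 0.05
  } else {
    counts <- base::table(tail_vals)
    x <- as.numeric(names(counts))
    p <- as.numeric(counts) / sum(counts)
    ls <- stats::lm(log(p) ~ log(x))
    exponent <- -unname(stats::coef(ls)[2])
    se <- unname(summary(ls)$coefficients[2, 2])
    ks_stat <- NA_real_
    ks_p <- NA_real_
    poor <- summary(ls)$r.squared < 0.7
  }

  structure(
    list(
      kind = kind, method = method,
      exponent = exponent, se = se, xmin = xmin,
      n_tail = length(tail_vals),
      ks_stat = ks_stat, ks_p = ks_p,
      poor_fit = poor
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit (%s, %s): exponent %.3f (se %.3f), xmin %g, n %d\n",
    x$kind, x$method, x$exponent, x$se, x$xmin, x$n_tail
  ))
  if (x$poor_fit) cat("  warning: goodness-of-fit diagnostics are poor\n")
  invisible(x)
}

#' Connected-component summary
#'
#' Reports whether the network holds together as a single entity when edge
#' direction is ignored, together with the sizes of the largest strongly and
#' weakly connected components. These bound how far an epidemic introduced at
#' one node could travel along trade links.
#'
#' @param network A `mobility_network`.
#' @return List with `is_connected`, `largest_strong`, `largest_weak`,
#'   `n_components` (weak components).
#' @export
component_summary <- function(network) {
  stopifnot(inherits(network, "mobility_network"))
  if (length(network$nodes) == 0) {
    return(list(is_connected = FALSE, largest_strong = 0L,
      largest_weak = 0L, n_components = 0L))
  }
  g <- as_igraph(network)
  strong <- igraph::components(g, mode = "strong")
  weak <- igraph::components(g, mode = "weak")
  list(
    is_connected = max(weak$csize) == length(network$nodes),
    largest_strong = as.integer(max(strong$csize)),
    largest_weak = as.integer(max(weak$csize)),
    n_components = as.integer(weak$no)
  )
}

#' Global clustering coefficient and diameter
#'
#' Both metrics are computed on the undirected projection: the global
#' clustering coefficient (transitivity) over the whole network, and the
#' diameter as the longest shortest path within the largest weakly connected
#' component (unweighted hops).
#'
#' @param network Non-empty `mobility_network`.
#' @return List with `clustering` (fraction) and `diameter` (integer links).
#' @export
clustering_and_diameter <- function(network) {
  stopifnot(inherits(network, "mobility_network"))
  if (length(network$nodes) == 0) {
    stop("clustering and diameter of an empty network are undefined",
      call. = FALSE)
  }
  g <- igraph::as_undirected(as_igraph(network), mode = "collapse")
  clustering <- igraph::transitivity(g, type = "global")
  if (is.nan(clustering)) clustering <- 0
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  giant <- igraph::induced_subgraph(g, keep)
  diam <- igraph::diameter(giant, directed = FALSE, weights = NA)
  list(clustering = clustering, diameter = as.integer(diam))
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). Vectorised over coordinates.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees WGS84.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1) # ~111.19 km, one degree of latitude
haversine_km <- function(lon1, lat1, lon2, lat2) {
  check_coords <- function(lon, lat) {
    if (any(!is.finite(lon)) || any(lon < -180) || any(lon > 180)) {
      stop("longitude out of bounds [-180, 180]", call. = FALSE)
    }
    if (any(!is.finite(lat)) || any(lat < -90) || any(lat > 90)) {
      stop("latitude out of bounds [-90, 90]", call. = FALSE)
    }
  }
  check_coords(lon1, lat1)
  check_coords(lon2, lat2)
  geosphere::distHaversine(
    cbind(lon1, lat1), cbind(lon2, lat2),
    r = 6371008.8
  ) / 1000
}

#' Distance profile of movements by destination activity
#'
#' Bins every movement by the great-circle distance between its endpoints
#' (half-open bins `[lo, hi)`) and tabulates movement counts and head-count
#' volumes per bin and destination activity.
#'
#' @param table Validated movement tibble.
#' @param gazetteer Gazetteer resolving every endpoint.
#' @param bin_km Bin width in km (default 100, the granularity at which
#'   short-haul pastoral movements separate from long-haul trade).
#' @return Tibble with `destination_activity`, `bin_lo`, `bin_hi`,
#'   `n_movements`, `volume`.
#' @export
distance_profile <- function(table, gazetteer, bin_km = 100) {
  assert_columns(table, movement_columns, "movement table")
  gazetteer <- validate_gazetteer(gazetteer)
  stopifnot(bin_km > 0)
  missing_ids <- setdiff(
    unique(c(table$origin_id, table$destination_id)), gazetteer$id
  )
  if (length(missing_ids) > 0) {
    stop("no coordinates for location(s): ",
      paste(missing_ids, collapse = ", "),
      call. = FALSE
    )
  }
  lon <- setNames(gazetteer$lon, gazetteer$id)
  lat <- setNames(gazetteer$lat, gazetteer$id)
  d <- haversine_km(
    lon[table$origin_id], lat[table$origin_id],
    lon[table$destination_id], lat[table$destination_id]
  )
  tbl <- tibble::tibble(
    destination_activity = table$destination_activity,
    bin_lo = floor(d / bin_km) * bin_km,
    head_count = table$head_count
  )
  tbl %>%
    group_by(.data$destination_activity, .data$bin_lo) %>%
    summarise(
      n_movements = dplyr::n(),
      volume = sum(.data$head_count),
      .groups = "drop"
    ) %>%
    mutate(bin_hi = .data$bin_lo + bin_km) %>%
    select(
      "destination_activity", "bin_lo", "bin_hi", "n_movements", "volume"
    ) %>%
    arrange(.data$destination_activity, .data$bin_lo)
}

#' Flow summary table
#'
#' Counts, volumes and percentage shares of movements grouped by any
#' combination of origin/destination activity, species, transport, scope or
#' month — the layout used for activity-by-activity movement tables in
#' surveillance reports. Percentages are given at full precision and as
#' half-up-rounded integers.
#'
#' @param table Movement tibble (raw records, or an aggregated toy table —
#'   percentages are shares of whatever rows are supplied, weighted by
#'   `n_movements` when that column is present).
#' @param grouping Character vector of grouping columns among
#'   `origin_activity`, `destination_activity`, `species`, `transport`,
#'   `scope`, `month`.
#' @return Tibble with one row per occupied cell: grouping columns,
#'   `n_movements`, `volume`, `pct_movements`, `pct_volume`,
#'   `pct_movements_int`, `pct_volume_int`.
#' @export
summarize_flows <- function(table,
                            grouping = c("origin_activity",
                                         "destination_activity")) {
  if (nrow(table) == 0) {
    stop("cannot summarise an empty movement table", call. = FALSE)
  }
  allowed <- c("origin_activity", "destination_activity", "species",
    "transport", "scope", "month")
  bad <- setdiff(grouping, allowed)
  if (length(bad) > 0) {
    stop("unknown grouping field(s): ", paste(bad, collapse = ", "),
      "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  assert_columns(table, c(grouping, "head_count"), "movement table")
  weight <- if ("n_movements" %in% names(table)) {
    table$n_movements
  } else {
    rep(1L, nrow(table))
  }
  tbl <- tibble::as_tibble(table[grouping])
  tbl$..n <- weight
  tbl$..vol <- table$head_count
  out <- tbl %>%
    group_by(dplyr::across(dplyr::all_of(grouping))) %>%
    summarise(
      n_movements = sum(.data$..n),
      volume = sum(.data$..vol),
      .groups = "drop"
    ) %>%
    mutate(
      pct_movements = 100 * .data$n_movements / sum(.data$n_movements),
      pct_volume = 100 * .data$volume / sum(.data$volume),
      pct_movements_int = round_half_up(.data$pct_movements),
      pct_volume_int = round_half_up(.data$pct_volume)
    )
  out
}
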