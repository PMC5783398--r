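# Synthetic movement-data generator with ground truth.
#
# Emulates the statistical structure of a Sahelian national livestock
# movement database: a two-regime year (routine pastoral movements up to the
# regime change month, then a Tabaski-driven trading season with higher truck
# and market-destination shares and a small-ruminant surge), heavy-tailed
# destination attachment around a few market hubs, exponential distance
# decay, log-normal herd sizes and persistence-classed links. Every link's
# class, the period partition and the hub set are returned as ground truth so
# downstream methods can be validated against known labels.

#' Simulation configuration
#'
#' Returns the default study conditions, optionally overridden. Defaults:
#' 73 national + 14 international locations, 147 aggregated O-D links,
#' regime change at month 9, truck probability 0.07/0.50 and
#' market-destination probability 0.13/0.64 in the routine/Tabaski regimes,
#' species mix (small ruminants, cattle, dromedaries) 0.60/0.30/0.10 routine
#' and 0.81/0.12/0.07 Tabaski, link-class mix backbone 0.31, frequent 0.12,
#' intermediate 0.45, occasional 0.12.
#'
#' @param ... Named overrides of any default field.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(...) {
  config <- list(
    n_national = 73L,
    n_international = 14L,
    n_links_target = 147L,
    regime_change_month = 9L,
    species_mix_by_regime = list(
      routine = c(small_ruminants = 0.60, cattle = 0.30, dromedaries = 0.10),
      tabaski = c(small_ruminants = 0.81, cattle = 0.12, dromedaries = 0.07)
    ),
    truck_prob_by_regime = c(routine = 0.07, tabaski = 0.50),
    market_dest_prob_by_regime = c(routine = 0.13, tabaski = 0.64),
    herd_size_lognormal = list(
      small_ruminants = c(meanlog = 7.3, sdlog = 1.2),
      cattle = c(meanlog = 6.3, sdlog = 1.0),
      dromedaries = c(meanlog = 5.8, sdlog = 1.0)
    ),
    monthly_noise_sdlog = 0.35,
    # routine-period movements are composite transhumant herds; Tabaski-period
    # consignments are smaller market batches: monthly volume drops to ~0.57x
    # after the regime change while movement frequency rises ~1.5x, so the
    # per-record consignment size scales by ~0.4
    regime_volume_scale = c(routine = 1, tabaski = 0.4),
    persistence_class_mix = c(
      backbone = 0.31, frequent = 0.12, intermediate = 0.45, occasional = 0.12
    ),
    # seasonal frequency profile: dry-season export peak around April-June,
    # then a September-October Tabaski surge and a quiet year end
    month_multiplier = c(
      0.8, 0.8, 1.0, 1.5, 1.8, 1.5, 1.0, 0.8, 1.2, 1.0, 0.6, 0.5
    ),
    base_monthly_rate = 1.2,
    intermediate_regime1_prob = 0.85,
    occasional_regime2_prob = 0.85,
    spatial_extent = c(
      lon_min = -17, lon_max = -5, lat_min = 15, lat_max = 27
    ),
    market_frac = 0.25,
    n_hubs = 5L,
    hub_boost = 25,
    distance_decay_km = 200,
    focal_country = "MRT",
    international_countries = c("SEN", "MLI", "MAR", "GNB", "GIN"),
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE)
  }
  config[names(overrides)] <- overrides
  validate_sim_config(config)
}

validate_sim_config <- function(config) {
  check_prob <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be a probability vector summing to 1", call. = FALSE)
    }
  }
  for (r in names(config$species_mix_by_regime)) {
    check_prob(config$species_mix_by_regime[[r]],
      paste0("species_mix_by_regime$", r))
  }
  check_prob(config$persistence_class_mix, "persistence_class_mix")
  if (any(config$truck_prob_by_regime < 0 |
      config$truck_prob_by_regime > 1)) {
    stop("truck_prob_by_regime must lie in [0, 1]", call. = FALSE)
  }
  if (any(config$market_dest_prob_by_regime < 0 |
      config$market_dest_prob_by_regime > 1)) {
    stop("market_dest_prob_by_regime must lie in [0, 1]", call. = FALSE)
  }
  if (!(config$regime_change_month %in% 2:12)) {
    stop("regime_change_month must lie in 2..12", call. = FALSE)
  }
  if (config$n_national < 1 || config$n_international < 0 ||
      config$n_links_target < 1) {
    stop("location and link counts must be positive", call. = FALSE)
  }
  if (length(config$month_multiplier) != 12 ||
      any(config$month_multiplier <= 0)) {
    stop("month_multiplier must be 12 positive values", call. = FALSE)
  }
  structure(config, class = "sim_config")
}

#' Generate a synthetic gazetteer
#'
#' National locations are scattered inside the focal bounding box with a
#' southern concentration (where herds and people are); international
#' locations sit across the southern border edge. A configurable fraction of
#' locations are markets; a few national markets are designated hubs (stored
#' in the `"hubs"` attribute) that later attract a heavy-tailed share of
#' destinations.
#'
#' @param config A `sim_config`.
#' @return A gazetteer tibble with attribute `hubs` (hub location ids).
#' @export
generate_locations <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  ext <- config$spatial_extent
  n_nat <- config$n_national
  n_int <- config$n_international

  nat_ids <- sprintf("MR%03d", seq_len(n_nat))
  nat_lon <- runif(n_nat, ext[["lon_min"]], ext[["lon_max"]])
  nat_lat <- ext[["lat_min"]] +
    (ext[["lat_max"]] - ext[["lat_min"]]) * rbeta(n_nat, 1.5, 4)

  int_ids <- if (n_int > 0) sprintf("INT%02d", seq_len(n_int)) else character(0)
  int_lon <- runif(n_int, ext[["lon_min"]], ext[["lon_max"]])
  int_lat <- ext[["lat_min"]] - runif(n_int, 0.2, 1.5)
  int_country <- if (n_int > 0) {
    sample(config$international_countries, n_int, replace = TRUE)
  } else {
    character(0)
  }

  ids <- c(nat_ids, int_ids)
  n <- length(ids)
  is_market <- runif(n) < config$market_frac
  is_slaughter <- runif(n) < 0.05
  is_rest <- runif(n) < 0.05
  hubs <- sample(nat_ids, min(config$n_hubs, n_nat))
  is_market[match(hubs, ids)] <- TRUE

  activities <- vapply(seq_len(n), function(i) {
    paste(c(
      "zone_elevage",
      if (is_market[i]) "market",
      if (is_slaughter[i]) "slaughterhouse",
      if (is_rest[i]) "resting_area"
    ), collapse = ";")
  }, character(1))

  gaz <- tibble::tibble(
    id = ids,
    name = paste("Location", ids),
    country = c(rep(config$focal_country, n_nat), int_country),
    lon = c(nat_lon, int_lon),
    lat = c(nat_lat, int_lat),
    activities = activities,
    coord_source = sample(c("gps", "commune_centroid"), n,
      replace = TRUE, prob = c(0.9, 0.1))
  )
  gaz <- validate_gazetteer(gaz)
  attr(gaz, "hubs") <- hubs
  gaz
}

regime_of <- function(month, regime_change_month) {
  ifelse(month >= regime_change_month, 2L, 1L)
}

# Activity months form runs (seasonal campaigns, as on link activity strip
# plots): intermediate runs sit mostly inside the routine regime and
# occasional runs inside the Tabaski regime. Runs are placed circularly
# within their month pool — the calendar year is an arbitrary window on an
# ongoing process, so a campaign may wrap around the pool edge; this also
# gives every month of a regime the same coverage.
draw_link_months <- function(class, config) {
  rcm <- config$regime_change_month
  run_in_pool <- function(k, pool) {
    n <- length(pool)
    start <- sample.int(n, 1)
    sort(pool[((start - 1 + 0:(k - 1)) %% n) + 1])
  }
  run_within <- function(k, pool, prob) {
    if (length(pool) < k || runif(1) >= prob) {
      return(run_in_pool(k, 1:12))
    }
    run_in_pool(k, pool)
  }
  switch(class,
    backbone = 1:12,
    frequent = run_in_pool(sample(7:11, 1), 1:12),
    intermediate = run_within(sample(3:6, 1), seq_len(rcm - 1),
      config$intermediate_regime1_prob),
    occasional = run_within(sample(1:2, 1), rcm:12,
      config$occasional_regime2_prob)
  )
}

#' Generate a synthetic movement table with ground truth
#'
#' Links are created first (origin uniform; destination by preferential
#' attachment with hub boost and exponential distance decay), each link gets
#' a persistence class and a set of active months consistent with it, and
#' each active link-month emits one or more records whose species, transport
#' and destination activity are drawn from the regime of that month.
#' Identical `(gazetteer, config)` inputs give identical outputs.
#'
#' @param gazetteer Gazetteer from [generate_locations()].
#' @param config The same `sim_config`.
#' @return List with `movements` (validated tibble with `scope`) and `truth`
#'   (a `ground_truth`: `link_class` tibble, `period_partition`,
#'   `dominant_nodes`, realized per-regime `truck_share`,
#'   `market_dest_share` and `species_mix`).
#' @export
generate_movements <- function(gazetteer, config = sim_config()) {
  config <- validate_sim_config(config)
  gazetteer <- validate_gazetteer(gazetteer)
  set.seed(config$seed + 1L)

  ids <- gazetteer$id
  n_loc <- length(ids)
  if (config$n_links_target > n_loc * (n_loc - 1)) {
    stop("n_links_target exceeds the number of possible O-D pairs",
      call. = FALSE)
  }
  hubs <- attr(gazetteer, "hubs") %||% character(0)
  is_hub <- ids %in% hubs

  dist_km <- matrix(0, n_loc, n_loc, dimnames = list(ids, ids))
  for (i in seq_len(n_loc)) {
    dist_km[i, ] <- haversine_km(
      gazetteer$lon[i], gazetteer$lat[i], gazetteer$lon, gazetteer$lat
    )
  }

  # --- links: preferential attachment with hub boost and distance decay ---
  origin <- character(config$n_links_target)
  destination <- character(config$n_links_target)
  in_count <- setNames(numeric(n_loc), ids)
  taken <- character(0)
  for (l in seq_len(config$n_links_target)) {
    for (try in 1:1000) {
      o <- sample(ids, 1)
      w <- (in_count + 1 + config$hub_boost * is_hub) *
        exp(-dist_km[o, ] / config$distance_decay_km)
      w[o] <- 0
      existing <- taken[startsWith(taken, paste0(o, " "))]
      if (length(existing) > 0) {
        w[sub(paste0("^", o, " "), "", existing)] <- 0
      }
      if (sum(w) > 0) break
    }
    if (sum(w) == 0) {
      stop("could not place link ", l, ": destination choice infeasible",
        call. = FALSE)
    }
    d <- sample(ids, 1, prob = w)
    origin[l] <- o
    destination[l] <- d
    taken <- c(taken, paste(o, d))
    in_count[d] <- in_count[d] + 1
  }

  classes <- sample(hf_classes, config$n_links_target,
    replace = TRUE, prob = config$persistence_class_mix)
  months <- lapply(classes, draw_link_months, config = config)

  # --- records per active link-month ---
  # Each link carries a persistent base consignment size (a route moves
  # similarly sized herds all year); it is drawn from the mixture of
  # species-specific size distributions so the cross-route volume
  # distribution stays heavy-tailed. The seasonal multiplier drives how
  # often a link fires, and a modest lognormal factor jitters herd sizes
  # month to month.
  rcm <- config$regime_change_month
  mult <- config$month_multiplier
  base_herd <- vapply(seq_len(config$n_links_target), function(l) {
    s <- sample(hf_species, 1, prob = config$species_mix_by_regime[[1]])
    p <- config$herd_size_lognormal[[s]]
    rlnorm(1, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]])
  }, numeric(1))
  link_idx <- rep(seq_len(config$n_links_target), lengths(months))
  month_vec <- unlist(months)
  n_rec <- 1L + rpois(length(month_vec),
    config$base_monthly_rate * mult[month_vec])
  rec_link <- rep(link_idx, n_rec)
  rec_month <- rep(month_vec, n_rec)
  n_tot <- length(rec_link)
  rec_regime <- regime_of(rec_month, rcm)

  species <- character(n_tot)
  for (r in 1:2) {
    idx <- which(rec_regime == r)
    species[idx] <- sample(hf_species, length(idx), replace = TRUE,
      prob = config$species_mix_by_regime[[r]])
  }
  head_count <- pmax(1, round(
    base_herd[rec_link] * config$regime_volume_scale[rec_regime] *
      rlnorm(n_tot, 0, config$monthly_noise_sdlog)
  ))
  dest_act <- ifelse(
    runif(n_tot) < config$market_dest_prob_by_regime[rec_regime],
    "market",
    sample(c("zone_elevage", "slaughterhouse", "resting_area"),
      n_tot, replace = TRUE, prob = c(0.95, 0.04, 0.01))
  )
  movements <- tibble::tibble(
    origin_id = origin[rec_link],
    destination_id = destination[rec_link],
    month = as.integer(rec_month),
    species = species,
    head_count = as.integer(head_count),
    transport = ifelse(
      runif(n_tot) < config$truck_prob_by_regime[rec_regime],
      "truck", "foot"
    ),
    origin_activity = ifelse(runif(n_tot) < 0.98,
      "zone_elevage", "market"),
    destination_activity = dest_act
  )
  country <- setNames(gazetteer$country, gazetteer$id)
  movements$scope <- unname(ifelse(
    country[movements$origin_id] == config$focal_country &
      country[movements$destination_id] == config$focal_country,
    "national", "international"
  ))
  movements <- arrange(movements, .data$month, .data$origin_id,
    .data$destination_id, .data$species, .data$head_count)

  regime <- regime_of(movements$month, rcm)
  realized <- list(
    truck_share = vapply(1:2, function(r) {
      mean(movements$transport[regime == r] == "truck")
    }, numeric(1)),
    market_dest_share = vapply(1:2, function(r) {
      mean(movements$destination_activity[regime == r] == "market")
    }, numeric(1)),
    species_mix = vapply(1:2, function(r) {
      prop.table(base::table(
        factor(movements$species[regime == r], levels = hf_species)
      ))
    }, numeric(3))
  )

  truth <- structure(
    list(
      link_class = tibble::tibble(
        origin = origin,
        destination = destination,
        class = classes,
        months = months
      ),
      period_partition = list(seq_len(rcm - 1), rcm:12),
      dominant_nodes = sort(hubs),
      realized = realized
    ),
    class = "ground_truth"
  )
  list(movements = movements, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", nrow(x$link_class), "links;",
    "periods:", paste(vapply(x$period_partition, function(p) {
      paste0(min(p), "-", max(p))
    }, character(1)), collapse = ", "), "\n")
  cat("  class mix:", paste(names(base::table(x$link_class$class)),
    as.integer(base::table(x$link_class$class)),
    sep = "=", collapse = " "), "\n")
  invisible(x)
}
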