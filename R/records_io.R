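# Reading, validating and writing movement tables, gazetteers and edge lists.
#
# All files are UTF-8 CSV with a header row. A gazetteer row is one location
# (id, name, country, lon, lat, semicolon-separated activities, and optionally
# coord_source in {gps, commune_centroid} for villages whose position had to
# be taken from the commune centroid). A movement row is one recorded herd
# movement; the starting date is already reduced to a month 1-12 because all
# downstream analyses work on monthly snapshots.

gazetteer_columns <- c("id", "name", "country", "lon", "lat", "activities")

#' Read a location gazetteer
#'
#' @param path Path to a CSV file with columns `id`, `name`, `country`,
#'   `lon`, `lat`, `activities` (semicolon-separated tokens among
#'   `zone_elevage`, `market`, `slaughterhouse`, `resting_area`) and optionally
#'   `coord_source` (`gps` or `commune_centroid`).
#' @return A tibble with one row per location, `coord_source` filled with
#'   `"gps"` when absent.
#' @export
read_gazetteer <- function(path) {
  if (!file.exists(path)) {
    stop("gazetteer file not found: ", path, call. = FALSE)
  }
  gaz <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_gazetteer(gaz)
}

#' Validate an in-memory gazetteer
#'
#' Enforces the gazetteer contract: unique ids, coordinates inside WGS84
#' bounds, non-empty known activity sets.
#'
#' @param gaz A data frame of locations.
#' @return The validated gazetteer as a tibble.
#' @export
validate_gazetteer <- function(gaz) {
  assert_columns(gaz, gazetteer_columns, "gazetteer")
  gaz <- tibble::as_tibble(gaz)
  dup <- unique(gaz$id[duplicated(gaz$id)])
  if (length(dup) > 0) {
    stop("duplicate location id(s) in gazetteer: ",
      paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  bad_lon <- which(!is.finite(gaz$lon) | gaz$lon < -180 | gaz$lon > 180)
  if (length(bad_lon) > 0) {
    stop("longitude out of bounds [-180, 180] in gazetteer row(s): ",
      paste(bad_lon, collapse = ", "),
      call. = FALSE
    )
  }
  bad_lat <- which(!is.finite(gaz$lat) | gaz$lat < -90 | gaz$lat > 90)
  if (length(bad_lat) > 0) {
    stop("latitude out of bounds [-90, 90] in gazetteer row(s): ",
      paste(bad_lat, collapse = ", "),
      call. = FALSE
    )
  }
  acts <- strsplit(as.character(gaz$activities), ";", fixed = TRUE)
  empty <- which(lengths(acts) == 0 | is.na(gaz$activities))
  if (length(empty) > 0) {
    stop("empty activity set in gazetteer row(s): ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  assert_tokens(unlist(acts), hf_activities, "activity")
  if (!"coord_source" %in% names(gaz)) {
    gaz$coord_source <- "gps"
  }
  assert_tokens(gaz$coord_source, c("gps", "commune_centroid"), "coord_source")
  gaz
}

#' Write a gazetteer to CSV
#'
#' @param gaz A gazetteer tibble as returned by [read_gazetteer()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gazetteer <- function(gaz, path) {
  validate_gazetteer(gaz)
  readr::write_csv(gaz, path, progress = FALSE)
  invisible(path)
}

#' Read a movement table
#'
#' Reads one row per recorded movement, validates every field against the
#' controlled vocabularies, resolves both endpoints in the gazetteer, derives
#' the national/international scope flag and drops exact duplicate rows.
#' Records whose endpoints are not in the gazetteer are excluded and counted,
#' never silently dropped.
#'
#' @param path Path to a CSV file with columns `origin_id`, `destination_id`,
#'   `month` (1-12), `species` (`small_ruminants`, `cattle`, `dromedaries`),
#'   `head_count` (positive integer), `transport` (`foot`, `truck`),
#'   `origin_activity`, `destination_activity`.
#' @param gazetteer Gazetteer tibble used to resolve endpoints and countries.
#' @param focal_country Country code defining "national"; defaults to the most
#'   frequent country in the gazetteer. A movement is national iff both
#'   endpoints are in the focal country.
#' @return A list with `movements` (validated tibble, with derived `scope`)
#'   and `report` (a `validation_report`).
#' @export
read_movements <- function(path, gazetteer, focal_country = NULL) {
  if (!file.exists(path)) {
    stop("movement file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_movements(raw, gazetteer, focal_country = focal_country)
}

#' Validate an in-memory movement table
#'
#' Same contract as [read_movements()] starting from a data frame.
#'
#' @inheritParams read_movements
#' @param table Data frame of raw movement rows.
#' @return A list with `movements` and `report`.
#' @export
validate_movements <- function(table, gazetteer, focal_country = NULL) {
  gazetteer <- validate_gazetteer(gazetteer)
  assert_columns(table, movement_columns, "movement table")
  raw <- tibble::as_tibble(table)[movement_columns]
  n_input <- nrow(raw)

  assert_tokens(raw$species, hf_species, "species")
  assert_tokens(raw$transport, hf_transport, "transport")
  assert_tokens(raw$origin_activity, hf_activities, "origin_activity")
  assert_tokens(raw$destination_activity, hf_activities,
    "destination_activity")
  bad_month <- which(!(raw$month %in% 1:12))
  if (length(bad_month) > 0) {
    stop("month outside 1..12 in row(s): ",
      paste(bad_month, collapse = ", "),
      call. = FALSE
    )
  }
  bad_head <- which(!is.finite(raw$head_count) | raw$head_count < 1)
  if (length(bad_head) > 0) {
    stop("head_count must be >= 1; offending row(s): ",
      paste(bad_head, collapse = ", "),
      call. = FALSE
    )
  }

  warnings <- character(0)
  dup <- duplicated(raw)
  n_dup <- sum(dup)
  tbl <- raw[!dup, ]
  if (n_dup > 0) {
    warnings <- c(warnings, sprintf("%d exact duplicate row(s) dropped", n_dup))
  }

  known <- gazetteer$id
  unknown_ids <- setdiff(
    unique(c(tbl$origin_id, tbl$destination_id)), known
  )
  unresolved <- !(tbl$origin_id %in% known) |
    !(tbl$destination_id %in% known)
  n_unknown <- sum(unresolved)
  if (n_unknown > 0) {
    warnings <- c(warnings, sprintf(
      "%d record(s) dropped; unknown location id(s): %s",
      n_unknown, paste(unknown_ids, collapse = ", ")
    ))
  }
  tbl <- tbl[!unresolved, ]

  focal_country <- focal_country %||%
    names(sort(base::table(gazetteer$country), decreasing = TRUE))[1]
  country <- setNames(gazetteer$country, gazetteer$id)
  tbl$scope <- unname(ifelse(
    country[tbl$origin_id] == focal_country &
      country[tbl$destination_id] == focal_country,
    "national", "international"
  ))

  report <- structure(
    list(
      n_records = nrow(tbl),
      n_dropped_duplicates = n_dup,
      n_unknown_locations = n_unknown,
      warnings = warnings
    ),
    class = "validation_report"
  )
  list(movements = tbl, report = report)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Movement validation report\n")
  cat("  records kept:        ", x$n_records, "\n")
  cat("  duplicates dropped:  ", x$n_dropped_duplicates, "\n")
  cat("  unresolved endpoints:", x$n_unknown_locations, "\n")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Write a movement table to CSV
#'
#' @param movements Validated movement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_movements <- function(movements, path) {
  assert_columns(movements, movement_columns, "movement table")
  readr::write_csv(movements, path, progress = FALSE)
  invisible(path)
}

#' Export a network's aggregated edge list
#'
#' Writes one row (CSV) or one edge element (GraphML, via igraph) per
#' aggregated origin-destination link, carrying volume, movement count,
#' active months and the species/transport volume breakdown. The CSV form is
#' re-importable with [read_edge_list()].
#'
#' @param network A `mobility_network`.
#' @param path Output path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, format = c("csv", "graphml")) {
  stopifnot(inherits(network, "mobility_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
    return(invisible(path))
  }
  links <- network$links
  out <- links
  out$months_active <- vapply(
    links$months_active,
    function(m) paste(m, collapse = ";"),
    character(1)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a CSV edge list written by [write_edge_list()]
#'
#' @param path CSV path.
#' @return A links tibble in the same layout as `network$links`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) {
    stop("edge list file not found: ", path, call. = FALSE)
  }
  links <- readr::read_csv(
    path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      origin = readr::col_character(),
      destination = readr::col_character(),
      months_active = readr::col_character()
    )
  )
  links$months_active <- lapply(
    strsplit(links$months_active, ";", fixed = TRUE),
    function(m) sort(as.integer(m))
  )
  tibble::as_tibble(links)
}
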