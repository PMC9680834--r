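#' Default sample-type whitelist for in situ chlorophyll records
#'
#' Water Quality Portal sample-type designations that correspond to actual
#' field measurements; other designations mark laboratory quality-control
#' samples that are unsuitable for satellite validation.
#' @export
SAMPLE_TYPE_WHITELIST <- c("Sample-Routine", "Field Msr/Obs", "Sample")

# Filter rules in their canonical order. `unparseable` is a catch-all for
# records whose coordinates or chlorophyll cannot be interpreted; it is
# attributed before any scientific rule so that malformed rows are never
# silently dropped.
FILTER_RULES <- c("unparseable", "depth", "chl_range", "date_mismatch",
                  "sample_type", "duplicate", "shore_distance")

#' Filter in situ chlorophyll records for satellite validation
#'
#' Applies the near-surface validation screening rules to a table of
#' discrete-sample chlorophyll records and returns the survivors together
#' with a per-rule audit. The rules, in attribution order:
#'
#' 1. `depth` — samples collected deeper than 0.5 m, or lacking a reported
#'    depth, are discarded (only near-surface samples are comparable to the
#'    satellite signal). Depth exactly 0.5 m is retained.
#' 2. `chl_range` — negative chlorophyll and extreme values above
#'    2000 ug/L are discarded as outliers beyond meaningful satellite
#'    detection.
#' 3. `date_mismatch` — records whose start and end dates differ are
#'    removed (collection time cannot be established).
#' 4. `sample_type` — only whitelisted sample-type labels are retained
#'    (exact match after trimming surrounding whitespace; case-sensitive).
#' 5. `duplicate` — replicates with identical (date, time, latitude,
#'    longitude, depth) are removed, keeping the first occurrence in input
#'    order.
#' 6. `shore_distance` — only samples collected more than 300 m from shore
#'    are retained, to avoid mixed land-water pixels, adjacency
#'    contamination and optically shallow water. Exactly 300 m is
#'    discarded; a missing distance is discarded.
#'
#' Every rule's predicate is evaluated on the full input (duplicates are
#' identified among all input records), so the surviving *set* does not
#' depend on rule order; a record failing several rules is attributed to
#' the first failing rule in the order above. Records with malformed
#' coordinates or non-finite chlorophyll get their own `unparseable` audit
#' category.
#'
#' @param records Data frame with columns `latitude`, `longitude`, `depth`
#'   (m), `chl` (ug/L), `start_date`, `end_date`, `sample_type`, and
#'   optionally `station_id`, `time`, `distance_to_shore` (m). Missing
#'   optional columns are treated as all-`NA` (`time`) or fail their rule
#'   (`distance_to_shore`).
#' @param max_depth Maximum retained sampling depth in m (default 0.5).
#' @param max_chl Maximum retained chlorophyll in ug/L (default 2000).
#' @param min_shore_distance Minimum (exclusive) shore distance in m
#'   (default 300).
#' @param sample_types Character whitelist (default
#'   [SAMPLE_TYPE_WHITELIST]).
#' @return A list of class `filter_result` with `records` (surviving rows,
#'   as a tibble, in input order) and `audit` (a `filter_audit`: per-rule
#'   discard counts plus input and surviving totals).
#' @export
filter_records <- function(records,
                           max_depth = 0.5,
                           max_chl = 2000,
                           min_shore_distance = 300,
                           sample_types = SAMPLE_TYPE_WHITELIST) {
  records <- tibble::as_tibble(records)
  need <- c("latitude", "longitude", "depth", "chl", "start_date",
            "end_date", "sample_type")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("filter_records: missing column(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(records)
  time_col <- if ("time" %in% names(records)) records$time else rep(NA, n)
  dist_col <- if ("distance_to_shore" %in% names(records)) {
    records$distance_to_shore
  } else {
    rep(NA_real_, n)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  lat <- num(records$latitude); lon <- num(records$longitude)
  chl <- num(records$chl); depth <- num(records$depth)
  dist <- num(dist_col)

  fails <- list(
    unparseable = is.na(lat) | is.na(lon) |
      lat < -90 | lat > 90 | lon < -180 | lon > 180 |
      is.infinite(chl),
    depth = is.na(depth) | depth > max_depth,
    chl_range = is.na(chl) | chl < 0 | chl > max_chl,
    date_mismatch = is.na(records$start_date) | is.na(records$end_date) |
      as.character(records$start_date) != as.character(records$end_date),
    sample_type = !(trimws(as.character(records$sample_type)) %in%
                      sample_types),
    duplicate = duplicated(data.frame(
      date = as.character(records$start_date),
      time = as.character(time_col),
      latitude = lat, longitude = lon, depth = depth,
      stringsAsFactors = FALSE)),
    shore_distance = is.na(dist) | dist <= min_shore_distance
  )
  fail_mat <- do.call(cbind, fails)
  first_fail <- apply(fail_mat, 1L, function(z) {
    i <- which(z)
    if (length(i) == 0L) NA_character_ else FILTER_RULES[i[1L]]
  })
  surviving <- is.na(first_fail)

  counts <- vapply(FILTER_RULES,
                   function(r) sum(first_fail == r, na.rm = TRUE),
                   integer(1))
  audit <- structure(
    list(rules = tibble::tibble(rule = FILTER_RULES,
                                discarded = unname(counts)),
         n_input = n, n_surviving = sum(surviving)),
    class = "filter_audit")
  out <- records[surviving, , drop = FALSE]
  attr(out, "first_failing_rule") <- first_fail
  structure(list(records = out, audit = audit,
                 first_failing_rule = first_fail),
            class = "filter_result")
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("<filter_audit>", x$n_input, "records in,", x$n_surviving,
      "surviving (",
      sprintf("%.0f%%", 100 * (1 - x$n_surviving / max(x$n_input, 1L))),
      "discarded )\n")
  kept <- x$rules[x$rules$discarded > 0L, ]
  if (nrow(kept) > 0L) print(kept)
  invisible(x)
}

#' @export
print.filter_result <- function(x, ...) {
  print(x$audit)
  invisible(x)
}

# Squared distance from points (px, py) to segment (ax, ay)-(bx, by).
dist2_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx * vx + vy * vy
  t <- ifelse(len2 == 0, 0,
              pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2)))
  dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
  dx * dx + dy * dy
}

#' Distance from a station to the nearest lake shore
#'
#' Minimum Euclidean distance from a sampling location inside a lake to the
#' lake's boundary polygon, in meters. Coordinates may be supplied already
#' projected in meters, or as longitude/latitude in decimal degrees, in
#' which case a local equirectangular approximation is used: degrees are
#' scaled to meters with one meridian factor and one cos(latitude) parallel
#' factor evaluated at the polygon's mean latitude. For lake-sized polygons
#' this approximation is accurate to well under a meter.
#'
#' @param point Numeric length-2 `(x, y)` (or `(lon, lat)`), or a two-column
#'   matrix / data frame of points.
#' @param lake_boundary Two-column matrix or data frame of polygon vertices
#'   in the same coordinates (closed or open ring).
#' @param coords `"meters"` for projected input, `"lonlat"` for decimal
#'   degrees.
#' @return Numeric vector of distances in meters, one per point.
#'   A point outside (or exactly on) the boundary is an error: the station
#'   is not in this lake.
#' @examples
#' sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
#' distance_to_shore(c(500, 500), sq)  # 500
#' @export
distance_to_shore <- function(point, lake_boundary, coords = c("meters",
                                                               "lonlat")) {
  coords <- match.arg(coords)
  pts <- if (is.null(dim(point))) matrix(point, ncol = 2) else
    as.matrix(point)
  poly <- as.matrix(lake_boundary)
  stopifnot(ncol(pts) == 2L, ncol(poly) == 2L, nrow(poly) >= 3L)
  # drop an explicit closing vertex
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), ,
                                                         drop = FALSE]
  if (coords == "lonlat") {
    lat0 <- mean(poly[, 2]) * pi / 180
    mx <- 111319.4906 * cos(lat0)   # meters per degree longitude
    my <- 111132.95                 # meters per degree latitude
    scale_fun <- function(m) cbind(m[, 1] * mx, m[, 2] * my)
  } else {
    scale_fun <- identity
  }
  inside <- sp::point.in.polygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2])
  if (any(inside != 1L)) {
    stop("distance_to_shore: point(s) ",
         paste(which(inside != 1L), collapse = ", "),
         " not strictly inside the lake polygon")
  }
  pm <- scale_fun(pts)
  vm <- scale_fun(poly)
  ax <- vm[, 1]; ay <- vm[, 2]
  bx <- c(vm[-1, 1], vm[1, 1]); by <- c(vm[-1, 2], vm[1, 2])
  vapply(seq_len(nrow(pm)), function(i) {
    sqrt(min(dist2_point_segment(pm[i, 1], pm[i, 2], ax, ay, bx, by)))
  }, numeric(1))
}

#' Read lake boundary polygons from GeoJSON
#'
#' Minimal reader for a GeoJSON `FeatureCollection` of `Polygon` features
#' (outer rings only; holes and multipolygons are not supported). Feature
#' names are taken from a `name` or `id` property when present.
#'
#' @param path Path to a GeoJSON file.
#' @return Named list of two-column (lon, lat) matrices.
#' @export
read_lake_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else
    list(gj)
  out <- list()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    if (!identical(geom$type, "Polygon")) {
      stop("read_lake_geojson: feature ", i, " is not a Polygon")
    }
    ring <- geom$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    nm <- f$properties$name
    if (is.null(nm)) nm <- f$properties$id
    if (is.null(nm)) nm <- paste0("lake_", i)
    out[[as.character(nm)]] <- m
  }
  out
}

#' Build same-day satellite-to-in situ match-ups
#'
#' Pairs each filtered in situ chlorophyll record with the satellite
#' CI_cyano value for the same station on the same UTC calendar date. A
#' pair is formed only when the satellite pixel is valid — unmasked and
#' classified as a cyanobacteria detection — and the in situ chlorophyll is
#' strictly positive (log-domain validation metrics require positivity; the
#' rare chl = 0 record survives filtering but cannot be paired).
#'
#' @param ci_series Data frame with columns `station_id`, `date`,
#'   `detection` and `ci_cyano` (e.g. the output of [compute_ci()] on a
#'   table carrying station/date columns). At most one satellite value per
#'   (station, date) is allowed; duplicates are an error because daily
#'   compositing upstream should already have reduced them.
#' @param records Data frame of filtered in situ records with `station_id`,
#'   `start_date` (the sampling date) and `chl`.
#' @return A tibble of match-up pairs with columns `date`, `station_id`,
#'   `ci_cyano` (> 0) and `chl_insitu` (> 0, ug/L).
#' @export
match_same_day <- function(ci_series, records) {
  ci_series <- tibble::as_tibble(ci_series)
  records <- tibble::as_tibble(records)
  for (col in c("station_id", "date", "detection", "ci_cyano")) {
    if (!col %in% names(ci_series)) {
      stop("match_same_day: `ci_series` lacks column ", col)
    }
  }
  for (col in c("station_id", "start_date", "chl")) {
    if (!col %in% names(records)) {
      stop("match_same_day: `records` lacks column ", col)
    }
  }
  key_sat <- paste(ci_series$station_id, as.character(ci_series$date),
                   sep = "\r")
  if (anyDuplicated(key_sat)) {
    stop("match_same_day: multiple satellite values for one ",
         "(station, date); composite daily scenes first")
  }
  key_rec <- paste(records$station_id, as.character(records$start_date),
                   sep = "\r")
  idx <- match(key_rec, key_sat)
  ok <- !is.na(idx) &
    ci_series$detection[idx] == "cyano" &
    !is.na(ci_series$ci_cyano[idx]) &
    !is.na(records$chl) & records$chl > 0
  idx <- idx[ok]
  tibble::tibble(
    date = records$start_date[ok],
    station_id = records$station_id[ok],
    ci_cyano = ci_series$ci_cyano[idx],
    chl_insitu = records$chl[ok]
  )
}
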