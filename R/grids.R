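#' Gridded reflectance / CI scene
#'
#' A `grid_scene` holds one date's mapped product on a regular
#' latitude-longitude (Plate Carree) grid: one 2-D array per reflectance
#' band, the CI_cyano field, and a per-cell state. Grids are north-up,
#' row-major and cell-center registered: row 1 is the northernmost row and
#' `origin_lon`/`origin_lat` give the center of cell (1, 1).
#'
#' Cell states distinguish three outcomes: `"detected"` (a positive
#' CI_cyano value is present), `"nondetect"` (a valid observation with no
#' cyanobacteria detection) and `"masked"` (contaminated or unobserved;
#' carries no usable data). Keeping `nondetect` distinct from `masked`
#' matters for compositing: a non-detection is evidence of low CI, a masked
#' cell is no evidence at all.
#'
#' @param rho Named list of numeric matrices, names `rho_s_<nm>`; all the
#'   same dimension. May be empty.
#' @param ci Numeric matrix of CI_cyano values (`NA` where not detected).
#' @param state Character matrix over `"detected"`, `"nondetect"`,
#'   `"masked"`; must have a CI value exactly where `"detected"`.
#' @param grid List with `origin_lon`, `origin_lat` (degrees, cell
#'   centers), `cell_size` (degrees) — rows and columns are taken from the
#'   arrays.
#' @param timestamp A `Date` (or string coercible to one), UTC.
#' @param n_members Optional named list of member-count matrices (set by
#'   [temporal_composite()]).
#' @return An object of class `grid_scene`.
#' @export
grid_scene <- function(rho, ci, state, grid, timestamp,
                       n_members = NULL) {
  stopifnot(is.list(rho), is.matrix(ci), is.matrix(state))
  dims <- dim(ci)
  if (!identical(dim(state), dims)) stop("grid_scene: state/ci shape mismatch")
  for (nm in names(rho)) {
    if (!identical(dim(rho[[nm]]), dims)) {
      stop("grid_scene: band ", nm, " shape mismatch")
    }
  }
  if (!all(state %in% c("detected", "nondetect", "masked"))) {
    stop("grid_scene: invalid state value")
  }
  if (any(state == "detected" & is.na(ci))) {
    stop("grid_scene: detected cells must carry a CI value")
  }
  stopifnot(all(c("origin_lon", "origin_lat", "cell_size") %in% names(grid)))
  grid$nrow <- dims[1]; grid$ncol <- dims[2]
  structure(list(rho = rho, ci = ci, state = state, grid = grid,
                 timestamp = as.Date(timestamp), n_members = n_members),
            class = "grid_scene")
}

#' @export
print.grid_scene <- function(x, ...) {
  st <- table(factor(x$state, c("detected", "nondetect", "masked")))
  cat(sprintf("<grid_scene> %s, %d x %d cells, %d band(s)\n",
              format(x$timestamp), x$grid$nrow, x$grid$ncol,
              length(x$rho)))
  cat(sprintf("  detected %d | nondetect %d | masked %d\n",
              st[["detected"]], st[["nondetect"]], st[["masked"]]))
  invisible(x)
}

check_same_grid <- function(scenes) {
  g1 <- scenes[[1]]$grid
  for (s in scenes[-1]) {
    g <- s$grid
    if (!isTRUE(all.equal(g[c("origin_lon", "origin_lat", "cell_size",
                              "nrow", "ncol")],
                          g1[c("origin_lon", "origin_lat", "cell_size",
                               "nrow", "ncol")]))) {
      stop("scenes are not on the same grid")
    }
    if (!identical(sort(names(s$rho)), sort(names(scenes[[1]]$rho)))) {
      stop("scenes carry different band sets")
    }
  }
  invisible(TRUE)
}

#' Daily maximum-CI composite
#'
#' Merges same-day scenes into one daily grid by per-cell bin selection:
#' each cell takes the contributing scene where the maximum CI_cyano is
#' found, and that scene supplies *both* the cell's CI_cyano and all of its
#' reflectance bands (so the composited spectrum stays physically
#' consistent with its CI). For selection, a non-detection scores 0 and a
#' masked cell is excluded; a cell masked in every scene stays masked.
#' Ties keep the earliest scene in the list, which makes the operation
#' idempotent; CI and state are order-invariant whenever detected scores
#' are distinct (cells that are nondetect in every scene tie at score 0,
#' so their band content follows the earliest scene supplied).
#'
#' @param scenes List of [grid_scene]s on an identical grid (same UTC
#'   date).
#' @return A [grid_scene] with the composite fields.
#' @export
daily_composite <- function(scenes) {
  if (length(scenes) == 0L) stop("daily_composite: no scenes")
  stopifnot(all(vapply(scenes, inherits, logical(1), "grid_scene")))
  check_same_grid(scenes)
  if (length(scenes) == 1L) return(scenes[[1]])
  dims <- dim(scenes[[1]]$ci)
  ncell <- prod(dims)
  score <- matrix(vapply(scenes, function(s) {
    sc <- ifelse(s$state == "masked", -Inf,
                 ifelse(s$state == "detected", s$ci, 0))
    as.numeric(sc)
  }, numeric(ncell)), ncell, length(scenes))
  sel <- max.col(score, ties.method = "first")
  all_masked <- !is.finite(score[cbind(seq_len(ncell), sel)])

  pick <- function(get) {
    v <- matrix(vapply(scenes, function(s) as.vector(get(s)), vector(
      mode = mode(get(scenes[[1]])[1]), ncell)), ncell, length(scenes))
    out <- v[cbind(seq_len(ncell), sel)]
    matrix(out, dims[1], dims[2])
  }
  ci <- pick(function(s) s$ci)
  state <- pick(function(s) s$state)
  state[matrix(all_masked, dims[1], dims[2])] <- "masked"
  ci[state != "detected"] <- NA_real_
  rho <- lapply(stats::setNames(nm = names(scenes[[1]]$rho)), function(b) {
    m <- pick(function(s) s$rho[[b]])
    m[state == "masked"] <- NA_real_
    m
  })
  grid_scene(rho, ci, state, scenes[[1]]$grid, scenes[[1]]$timestamp)
}

season_of <- function(d) {
  m <- as.integer(format(d, "%m"))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

# Member dates of a compositing window anchored at `anchor`.
window_dates <- function(dates, window, anchor) {
  anchor <- as.Date(anchor)
  switch(window,
    "7day" = {
      # Sunday-Saturday week containing the anchor, centered on Wednesday
      dow <- as.integer(format(anchor, "%w"))  # 0 = Sunday
      start <- anchor - dow
      dates >= start & dates <= start + 6
    },
    "28day" = dates > anchor - 28 & dates <= anchor,
    "month" = format(dates, "%Y-%m") == format(anchor, "%Y-%m"),
    "season" = season_of(dates) == season_of(anchor) &
      # December belongs to the following winter
      (as.integer(format(dates, "%Y")) +
         (format(dates, "%m") == "12")) ==
      (as.integer(format(anchor, "%Y")) + (format(anchor, "%m") == "12")),
    stop("unknown window: ", window)
  )
}

#' Temporal mean composite
#'
#' Averages daily composites over a time window: a 7-day Sunday--Saturday
#' week centered on Wednesday, a rolling 28-day window ending at the
#' anchor date, a calendar month, or a meteorological season (DJF, MAM,
#' JJA, SON). Per cell, each reflectance band is the arithmetic mean over
#' unmasked member days. For CI_cyano the default mean is over *detected*
#' members only, summarizing bloom intensity when present; set
#' `include_nondetect = TRUE` to average non-detections in as zeros
#' instead, which summarizes mean bloom signal including bloom-free days
#' and yields systematically lower values. Per-cell member counts are kept
#' in `n_members` (`rho`: unmasked days; `ci`: days entering the CI mean).
#'
#' @param daily List of daily [grid_scene]s on one grid.
#' @param window One of `"7day"`, `"28day"`, `"month"`, `"season"`.
#' @param anchor Date selecting the window (default: latest scene date).
#' @param include_nondetect Logical; see above.
#' @return A [grid_scene] timestamped at the anchor date.
#' @export
temporal_composite <- function(daily, window = c("7day", "28day", "month",
                                                 "season"),
                               anchor = NULL, include_nondetect = FALSE) {
  window <- match.arg(window)
  if (length(daily) == 0L) stop("temporal_composite: no scenes")
  stopifnot(all(vapply(daily, inherits, logical(1), "grid_scene")))
  check_same_grid(daily)
  dates <- as.Date(vapply(daily, function(s) format(s$timestamp),
                          character(1)))
  if (is.null(anchor)) anchor <- max(dates)
  in_win <- window_dates(dates, window, anchor)
  if (!any(in_win)) {
    stop("temporal_composite: no scenes fall in the ", window,
         " window at ", format(as.Date(anchor)))
  }
  members <- daily[in_win]
  dims <- dim(members[[1]]$ci)

  ncell <- prod(dims)
  masked_stack <- matrix(vapply(members,
                                function(s) as.vector(s$state == "masked"),
                                logical(ncell)), ncell, length(members))
  ci_use <- matrix(vapply(members, function(s) {
    use <- s$state == "detected" | (include_nondetect &
                                      s$state == "nondetect")
    as.vector(use)
  }, logical(ncell)), ncell, length(members))
  ci_val <- matrix(vapply(members, function(s) {
    v <- ifelse(s$state == "detected", s$ci, 0)
    as.vector(v)
  }, numeric(ncell)), ncell, length(members))

  n_ci <- rowSums(ci_use)
  ci_mean <- ifelse(n_ci > 0, rowSums(ci_val * ci_use) / n_ci, NA_real_)
  n_rho <- rowSums(!masked_stack)

  state <- ifelse(n_ci > 0, "detected",
                  ifelse(n_rho > 0, "nondetect", "masked"))
  rho <- lapply(stats::setNames(nm = names(members[[1]]$rho)), function(b) {
    vals <- matrix(vapply(members, function(s) as.vector(s$rho[[b]]),
                          numeric(ncell)), ncell, length(members))
    vals[masked_stack] <- 0
    m <- ifelse(n_rho > 0, rowSums(vals) / n_rho, NA_real_)
    matrix(m, dims[1], dims[2])
  })
  grid_scene(rho,
             matrix(ci_mean, dims[1], dims[2]),
             matrix(state, dims[1], dims[2]),
             members[[1]]$grid, as.Date(anchor),
             n_members = list(ci = matrix(n_ci, dims[1], dims[2]),
                              rho = matrix(n_rho, dims[1], dims[2])))
}

#' Write / read a scene as netCDF
#'
#' Scenes are stored with one float variable per band (`rho_s_<nm>`), a
#' `CI_cyano` variable holding values for detected cells and a fill value
#' elsewhere, and a byte `ci_state` variable (0 = detected, 1 = nondetect,
#' 2 = masked) so that non-detections are distinguishable from masked
#' cells, plus CF-style `lat`/`lon` cell-center coordinate variables. The
#' scene date is kept in a `date` global attribute.
#'
#' @param scene A [grid_scene].
#' @param path Output netCDF path.
#' @return `write_scene_nc` returns `path` invisibly; `read_scene_nc`
#'   returns a [grid_scene].
#' @export
write_scene_nc <- function(scene, path) {
  stopifnot(inherits(scene, "grid_scene"))
  g <- scene$grid
  lon <- g$origin_lon + (seq_len(g$ncol) - 1) * g$cell_size
  lat <- g$origin_lat - (seq_len(g$nrow) - 1) * g$cell_size
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lon)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lat)
  fill <- -32767
  vars <- list()
  for (b in names(scene$rho)) {
    vars[[b]] <- ncdf4::ncvar_def(b, "1", list(dim_lon, dim_lat), fill,
                                  prec = "double")
  }
  vars$CI_cyano <- ncdf4::ncvar_def("CI_cyano", "1", list(dim_lon, dim_lat),
                                    fill, prec = "double")
  vars$ci_state <- ncdf4::ncvar_def("ci_state", "", list(dim_lon, dim_lat),
                                    prec = "byte")
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  # netCDF vars are (lon, lat): transpose the north-up row-major matrices
  put <- function(name, m, na_fill = TRUE) {
    v <- t(m)
    if (na_fill) v[is.na(v)] <- fill
    ncdf4::ncvar_put(nc, name, v)
  }
  for (b in names(scene$rho)) put(b, scene$rho[[b]])
  put("CI_cyano", scene$ci)
  state_code <- matrix(match(scene$state,
                             c("detected", "nondetect", "masked")) - 1L,
                       nrow(scene$state), ncol(scene$state))
  put("ci_state", state_code, na_fill = FALSE)
  ncdf4::ncatt_put(nc, 0, "date", format(scene$timestamp))
  invisible(path)
}

#' @rdname write_scene_nc
#' @export
read_scene_nc <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- ncdf4::ncvar_get(nc, "lon")
  lat <- ncdf4::ncvar_get(nc, "lat")
  get <- function(name) t(matrix(ncdf4::ncvar_get(nc, name),
                                 length(lon), length(lat)))
  band_names <- grep("^rho_s_", names(nc$var), value = TRUE)
  rho <- lapply(stats::setNames(nm = band_names), get)
  ci <- get("CI_cyano")
  state <- matrix(c("detected", "nondetect", "masked")[get("ci_state") + 1L],
                  length(lat), length(lon))
  ci[state != "detected"] <- NA_real_
  for (b in band_names) rho[[b]][state == "masked"] <- NA_real_
  date <- ncdf4::ncatt_get(nc, 0, "date")$value
  cell <- if (length(lon) > 1) lon[2] - lon[1] else
    if (length(lat) > 1) lat[1] - lat[2] else 1
  grid_scene(rho, ci, state,
             list(origin_lon = lon[1], origin_lat = lat[1],
                  cell_size = cell),
             as.Date(date))
}
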