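# Shared fixtures and independent oracles for the suite.

# Literal, standalone transcription of the line-height formula, coded
# independently of spectral_shape() (plain positional arithmetic on a named
# vector) so the two can serve as cross-checks.
ss_oracle <- function(rho, center, lower, upper) {
  unname(rho[as.character(center)] - rho[as.character(lower)] +
           (rho[as.character(lower)] - rho[as.character(upper)]) *
           (center - lower) / (upper - lower))
}

# A random fully-populated spectrum (positive reflectance).
random_spectrum <- function() {
  lake_spectrum(runif(11, 0.001, 0.05))
}

# Spectrum from the four red/NIR bands only.
red_nir_spectrum <- function(r620, r665, r681, r709, flags = NULL) {
  lake_spectrum(c(rho_s_620 = r620, rho_s_665 = r665,
                  rho_s_681 = r681, rho_s_709 = r709), flags = flags)
}

# One clean in situ record row; fields overridable.
clean_record <- function(...) {
  base <- list(station_id = "S1", latitude = 45, longitude = -93,
               start_date = as.Date("2011-08-01"),
               end_date = as.Date("2011-08-01"),
               time = "10:00", depth = 0.3, chl = 25,
               sample_type = "Sample-Routine", distance_to_shore = 500)
  over <- list(...)
  base[names(over)] <- over
  tibble::as_tibble(base)
}

# Minimal scene: supply a CI matrix (NA = nondetect) and optional masked
# cells; bands are two constant layers so band propagation is checkable.
toy_scene <- function(ci, masked = NULL, band_value = 0.02,
                      timestamp = as.Date("2011-09-10")) {
  state <- ifelse(is.na(ci), "nondetect", "detected")
  if (!is.null(masked)) state[masked] <- "masked"
  ci[state != "detected"] <- NA_real_
  rho <- list(rho_s_665 = matrix(band_value, nrow(ci), ncol(ci)),
              rho_s_681 = matrix(band_value * 0.9, nrow(ci), ncol(ci)))
  for (b in names(rho)) rho[[b]][state == "masked"] <- NA_real_
  grid_scene(rho, ci, state,
             list(origin_lon = 0, origin_lat = 50, cell_size = 0.01),
             timestamp)
}

# Independently coded per-record filter predicates; duplicate status is
# decided on the full input table (keep-first).
oracle_pass <- function(rec) {
  dup <- duplicated(paste(rec$start_date, rec$time, rec$latitude,
                          rec$longitude, rec$depth))
  ok_coord <- !is.na(rec$latitude) & !is.na(rec$longitude) &
    abs(rec$latitude) <= 90 & abs(rec$longitude) <= 180
  !is.na(rec$depth) & rec$depth <= 0.5 &
    !is.na(rec$chl) & rec$chl >= 0 & rec$chl <= 2000 &
    rec$start_date == rec$end_date &
    trimws(rec$sample_type) %in% SAMPLE_TYPE_WHITELIST &
    !dup &
    !is.na(rec$distance_to_shore) & rec$distance_to_shore > 300 &
    ok_coord
}

# Per-cell loop oracle for the daily max-CI selection rule: index of the
# winning scene, NA where every scene is masked.
brute_daily <- function(scenes) {
  dims <- dim(scenes[[1]]$ci)
  sel <- matrix(NA_integer_, dims[1], dims[2])
  for (r in seq_len(dims[1])) for (c_ in seq_len(dims[2])) {
    best <- -Inf; pick <- NA_integer_
    for (k in seq_along(scenes)) {
      st <- scenes[[k]]$state[r, c_]
      if (st == "masked") next
      score <- if (st == "detected") scenes[[k]]$ci[r, c_] else 0
      if (score > best) { best <- score; pick <- k }
    }
    sel[r, c_] <- pick
  }
  sel
}

# Random scene on a fixed grid for brute-force composite oracles.
random_scene <- function(nr, nc, p_detect = 0.4, p_masked = 0.2,
                         timestamp = as.Date("2011-09-10")) {
  state <- matrix(sample(c("detected", "nondetect", "masked"), nr * nc,
                         replace = TRUE,
                         prob = c(p_detect, 1 - p_detect - p_masked,
                                  p_masked)),
                  nr, nc)
  ci <- matrix(runif(nr * nc, 1e-4, 0.05), nr, nc)
  ci[state != "detected"] <- NA_real_
  rho <- list(rho_s_665 = matrix(runif(nr * nc, 0.005, 0.05), nr, nc),
              rho_s_709 = matrix(runif(nr * nc, 0.005, 0.05), nr, nc))
  for (b in names(rho)) rho[[b]][state == "masked"] <- NA_real_
  grid_scene(rho, ci, state,
             list(origin_lon = 0, origin_lat = 50, cell_size = 0.01),
             timestamp)
}
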