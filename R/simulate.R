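#' Simulation configuration
#'
#' Collects the parameters of the synthetic-data generator. Defaults mirror
#' the structure of the study match-up set the package is designed around:
#' 1738 pairs, a right-skewed log-normal chlorophyll distribution with
#' median 45 ug/L (log-sd 0.958, giving a mean near 71 ug/L) clipped to
#' [0.5, 832] ug/L, a generating linear model with slope 6620 and intercept
#' -3.1, and multiplicative log-domain noise with sigma = 0.2 (in log10
#' units) on chlorophyll.
#'
#' The noise is mean-one multiplicative log-normal: the log10 perturbation
#' is drawn as Normal(-sigma^2 ln(10) / 2, sigma), so the *expected*
#' chlorophyll equals the generating line. This makes the linear-scale
#' least-squares fit used in calibration an unbiased estimator of the
#' generating coefficients, which is the property parameter-recovery tests
#' rely on.
#'
#' @param n Number of match-ups (or records) to generate.
#' @param true_slope,true_intercept Generating linear model (ug/L per CI
#'   unit; ug/L).
#' @param log_noise_sigma Sigma of the log10-domain chlorophyll noise
#'   (dimensionless, >= 0).
#' @param chl_median Median of the log-normal chlorophyll distribution
#'   (ug/L).
#' @param chl_sdlog Standard deviation of log (natural) chlorophyll.
#' @param chl_range Length-2 clipping range (ug/L), both positive.
#' @param contamination_rates Named rates in [0, 1] of planted filter-rule
#'   violations for [simulate_insitu_records()]; names among `depth`,
#'   `chl_range`, `date_mismatch`, `sample_type`, `duplicate`,
#'   `shore_distance`. Their sum must be < 1.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n = 1738L,
                       true_slope = 6620,
                       true_intercept = -3.1,
                       log_noise_sigma = 0.2,
                       chl_median = 45,
                       chl_sdlog = 0.958,
                       chl_range = c(0.5, 832),
                       contamination_rates = c(depth = 0.08,
                                               chl_range = 0.02,
                                               date_mismatch = 0.05,
                                               sample_type = 0.08,
                                               duplicate = 0.05,
                                               shore_distance = 0.12),
                       seed = 1L) {
  stopifnot(n >= 1, true_slope > 0, log_noise_sigma >= 0,
            chl_median > 0, chl_sdlog >= 0,
            length(chl_range) == 2L, chl_range[1] > 0,
            chl_range[1] < chl_range[2])
  rates <- contamination_rates
  bad <- setdiff(names(rates), setdiff(FILTER_RULES, "unparseable"))
  if (length(bad) > 0L) {
    stop("sim_config: unknown contamination rate(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(rates < 0 | rates > 1) || sum(rates) >= 1 + 1e-12) {
    stop("sim_config: contamination rates must lie in [0, 1] and sum < 1",
         " (rate 1 for a single rule is allowed)")
  }
  structure(list(n = as.integer(n), true_slope = true_slope,
                 true_intercept = true_intercept,
                 log_noise_sigma = log_noise_sigma,
                 chl_median = chl_median, chl_sdlog = chl_sdlog,
                 chl_range = chl_range,
                 contamination_rates = rates, seed = seed),
            class = "sim_config")
}

# Baseline reflectance: linear, gently decreasing with wavelength so that
# any band triplet of the unperturbed spectrum is exactly collinear
# (spectral shape zero).
sim_baseline <- function(lambda, baseline) {
  baseline * (1 - 4e-4 * (lambda - 413))
}

# Fraction of the generated CI carried by the 681 nm depression; the rest
# is carried by the 709 nm peak (added, so it can never drive reflectance
# negative).
W681 <- 0.1

#' Generate a synthetic bloom spectrum
#'
#' Builds an 11-band reflectance spectrum whose line-height signature is
#' controlled analytically. Starting from a linear (hence
#' spectral-shape-free) baseline, the generator
#'
#' * depresses the 681 nm band and raises the 709 nm band in a fixed 1:9
#'   split of the target line height, both scaled by
#'   `cyano_fraction * (chl - intercept) / slope`;
#' * depresses the 620 nm band by `0.002 * cyano_fraction`, the phycocyanin
#'   absorption signature that makes SS(665) positive.
#'
#' The construction guarantees, in closed form, that [compute_ci()] on the
#' noiseless output returns exactly
#' `ci_cyano = (chl - intercept) / slope` when `cyano_fraction = 1`, so
#' chlorophyll round-trips through the index math and the generating
#' [chl_model]. With `cyano_fraction = 0` the spectrum is the bare
#' baseline: no curvature, CI = 0, non-detection. This is a declared
#' parametric form, not a radiative-transfer model; its only contract is
#' invertibility through the line-height algebra.
#'
#' @param chl Chlorophyll-a (ug/L), >= 0.
#' @param cyano_fraction Proportion in [0, 1] scaling the cyanobacteria
#'   signature.
#' @param baseline Baseline reflectance amplitude at 413 nm (unitless,
#'   default 0.03).
#' @param seed Integer seed, used only when `noise_sd > 0`.
#' @param noise_sd Optional sd of additive Gaussian reflectance noise.
#' @param model Generating [chl_model] (default [chl_bs()]).
#' @return A [lake_spectrum].
#' @examples
#' s <- make_spectrum(63.1)
#' compute_ci(s)$ci_cyano  # 0.01 under the default model
#' @export
make_spectrum <- function(chl, cyano_fraction = 1, baseline = 0.03,
                          seed = NULL, noise_sd = 0, model = chl_bs()) {
  stopifnot(chl >= 0, cyano_fraction >= 0, cyano_fraction <= 1,
            baseline > 0, noise_sd >= 0)
  ci_t <- (chl - model$intercept) / model$slope
  rho <- sim_baseline(MERIS_BANDS, baseline)
  names(rho) <- paste0("rho_s_", MERIS_BANDS)
  f <- cyano_fraction
  rho[["rho_s_681"]] <- rho[["rho_s_681"]] - W681 * f * ci_t
  rho[["rho_s_709"]] <- rho[["rho_s_709"]] +
    (1 - W681) * (44 / 16) * f * ci_t
  rho[["rho_s_620"]] <- rho[["rho_s_620"]] - 0.002 * f
  if (noise_sd > 0) {
    rho <- rho + with_seed(seed, stats::rnorm(length(rho), 0, noise_sd))
  }
  if (any(rho <= 0)) {
    stop("make_spectrum: parameters produce non-positive reflectance ",
         "(chl too high for this baseline)")
  }
  lake_spectrum(rho)
}

# Clipped log-normal chlorophyll draw shared by the generators.
draw_chl <- function(n, cfg) {
  pmin(pmax(stats::rlnorm(n, log(cfg$chl_median), cfg$chl_sdlog),
            cfg$chl_range[1]), cfg$chl_range[2])
}

#' Simulate a satellite-to-in situ match-up table
#'
#' Draws true chlorophyll from the configured clipped log-normal, places
#' the satellite CI_cyano exactly on the generating line
#' (`ci = (chl_true - intercept) / slope`; pairs with ci <= 0 are dropped),
#' and reports the in situ chlorophyll with mean-one multiplicative
#' log-normal noise of sigma `cfg$log_noise_sigma` (see [sim_config()] for
#' why the noise is mean-centered in the linear domain). Synthetic station
#' ids and summer/autumn dates are attached so the table can flow through
#' the same-day matching and calibration interfaces unchanged.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with columns `date`, `station_id`, `ci_cyano`,
#'   `chl_insitu` and `chl_true`; the generating parameters are attached
#'   as attribute `"truth"` for recovery tests.
#' @export
simulate_matchups <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    chl_true <- draw_chl(cfg$n, cfg)
    ci <- (chl_true - cfg$true_intercept) / cfg$true_slope
    keep <- ci > 0
    chl_true <- chl_true[keep]; ci <- ci[keep]
    n <- length(ci)
    mu <- -cfg$log_noise_sigma^2 * log(10) / 2
    eps <- stats::rnorm(n, mu, cfg$log_noise_sigma)
    out <- tibble::tibble(
      date = as.Date("2011-05-01") +
        sample.int(183L, n, replace = TRUE) - 1L,
      station_id = sprintf("S%05d", sample.int(99999L, n, replace = TRUE)),
      ci_cyano = ci,
      chl_insitu = 10^(log10(chl_true) + eps),
      chl_true = chl_true
    )
    attr(out, "truth") <- cfg[c("true_slope", "true_intercept",
                                "log_noise_sigma")]
    out
  })
}

non_whitelist_types <- c("Quality Control Sample-Field Blank",
                         "Quality Control Sample-Lab Duplicate",
                         "Not determined")

#' Simulate in situ records with planted filter violations
#'
#' Emits a record table in the layout [filter_records()] consumes, planting
#' violations of each screening rule at the configured rates and labeling
#' every record with its expected first-failing rule (or `"survives"`).
#' Planted violations break exactly one rule: deep or missing depth,
#' negative or > 2000 ug/L chlorophyll, mismatched start/end dates,
#' non-whitelisted sample types, exact replicates of an earlier clean
#' record, and shore distances of at most 300 m. The labels serve as an
#' independent oracle for the filter audit.
#'
#' @param cfg A [sim_config()]; `cfg$n` records are generated and
#'   `cfg$contamination_rates` gives the violation rates.
#' @return Tibble of records with an `expected_rule` column.
#' @export
simulate_insitu_records <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  rates <- cfg$contamination_rates
  with_seed(cfg$seed, {
    n <- cfg$n
    cats <- sample(c(names(rates), "survives"), n, replace = TRUE,
                   prob = c(rates, 1 - sum(rates)))
    # a duplicate needs an earlier clean record to replicate
    if (cats[1L] == "duplicate") cats[1L] <- "survives"
    rec <- tibble::tibble(
      station_id = sprintf("S%05d", seq_len(n)),
      latitude = stats::runif(n, 44, 46),
      longitude = stats::runif(n, -94, -92),
      start_date = as.Date("2010-05-01") +
        sample.int(183L, n, replace = TRUE) - 1L,
      time = sprintf("%02d:%02d", sample(6:18, n, TRUE),
                     sample(0:59, n, TRUE)),
      depth = stats::runif(n, 0, 0.5),
      chl = draw_chl(n, cfg),
      sample_type = sample(SAMPLE_TYPE_WHITELIST, n, replace = TRUE),
      distance_to_shore = stats::runif(n, 301, 5000)
    )
    rec$end_date <- rec$start_date
    for (i in which(cats == "depth")) {
      rec$depth[i] <- if (stats::runif(1) < 0.5) NA_real_ else
        stats::runif(1, 0.6, 10)
    }
    for (i in which(cats == "chl_range")) {
      rec$chl[i] <- if (stats::runif(1) < 0.5) -stats::runif(1, 0.1, 5) else
        stats::runif(1, 2001, 5000)
    }
    for (i in which(cats == "date_mismatch")) {
      rec$end_date[i] <- rec$start_date[i] + sample(1:3, 1)
    }
    for (i in which(cats == "sample_type")) {
      rec$sample_type[i] <- sample(non_whitelist_types, 1)
    }
    for (i in which(cats == "shore_distance")) {
      rec$distance_to_shore[i] <- stats::runif(1, 0, 300)
    }
    for (i in which(cats == "duplicate")) {
      src <- which(cats[seq_len(i - 1L)] == "survives")
      if (length(src) == 0L) { cats[i] <- "survives"; next }
      j <- src[sample.int(length(src), 1L)]
      rec[i, c("start_date", "end_date", "time", "latitude", "longitude",
               "depth")] <-
        rec[j, c("start_date", "end_date", "time", "latitude", "longitude",
                 "depth")]
    }
    rec$expected_rule <- cats
    rec
  })
}

#' Simulate a gridded bloom scene
#'
#' Builds a [grid_scene] of background (non-detect) water with circular
#' bloom patches. Each patch cell receives the analytic spectrum of
#' [make_spectrum()] at the patch's chlorophyll with `cyano_fraction = 1`,
#' so its CI_cyano equals `(chl - intercept) / slope` under the generating
#' model; overlapping patches resolve to the maximum chlorophyll. A
#' fraction of cells can be masked to exercise flag handling.
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param bloom_patches List of `list(center = c(row, col), radius, chl)`;
#'   radius in cells, chl in ug/L.
#' @param seed Integer seed (drives masking and optional noise).
#' @param baseline Baseline reflectance amplitude.
#' @param model Generating [chl_model].
#' @param masked_fraction Fraction of cells masked at random.
#' @param timestamp Scene date.
#' @param grid Grid spec (origin and cell size in degrees).
#' @return A [grid_scene] carrying all 11 bands.
#' @export
make_scene <- function(rows, cols, bloom_patches = list(), seed = 1L,
                       baseline = 0.03, model = chl_bs(),
                       masked_fraction = 0,
                       timestamp = as.Date("2011-09-10"),
                       grid = list(origin_lon = -93, origin_lat = 45,
                                   cell_size = 0.0027)) {
  stopifnot(rows >= 1, cols >= 1, masked_fraction >= 0, masked_fraction < 1)
  chl <- matrix(0, rows, cols)
  for (p in bloom_patches) {
    stopifnot(all(c("center", "radius", "chl") %in% names(p)))
    rr <- outer((seq_len(rows) - p$center[1])^2,
                (seq_len(cols) - p$center[2])^2, "+")
    inside <- rr <= p$radius^2
    chl[inside] <- pmax(chl[inside], p$chl)
  }
  f <- (chl > 0) * 1
  ci_t <- (chl - model$intercept) / model$slope
  rho <- lapply(stats::setNames(MERIS_BANDS, paste0("rho_s_", MERIS_BANDS)),
                function(lam) matrix(sim_baseline(lam, baseline), rows, cols))
  rho$rho_s_681 <- rho$rho_s_681 - W681 * f * ci_t
  rho$rho_s_709 <- rho$rho_s_709 + (1 - W681) * (44 / 16) * f * ci_t
  rho$rho_s_620 <- rho$rho_s_620 - 0.002 * f
  if (any(vapply(rho, function(m) any(m <= 0), logical(1)))) {
    stop("make_scene: parameters produce non-positive reflectance")
  }
  ss <- ss_pair(rho$rho_s_620, rho$rho_s_665, rho$rho_s_681, rho$rho_s_709)
  ci <- -ss$ss681
  state <- matrix(ci_detection(ci, ss$ss665), rows, cols)
  state[state == "cyano"] <- "detected"
  state[state %in% c("noncyano", "nondetect")] <- "nondetect"
  if (masked_fraction > 0) {
    idx <- with_seed(seed, sample.int(rows * cols,
                                      round(masked_fraction * rows * cols)))
    state[idx] <- "masked"
  }
  ci[state != "detected"] <- NA_real_
  for (b in names(rho)) rho[[b]][state == "masked"] <- NA_real_
  grid_scene(rho, ci, state, grid, timestamp)
}
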