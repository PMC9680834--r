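test_that("one record per rule violation yields one survivor and unit audit
           counts", {
  clean <- clean_record()
  toy <- rbind(
    clean,
    clean_record(station_id = "S2", depth = 1.0),
    clean_record(station_id = "S3", chl = 2500),
    clean_record(station_id = "S4",
                 end_date = as.Date("2011-08-02")),
    clean_record(station_id = "S5", sample_type = "QC blank"),
    clean_record(station_id = "S6"),   # exact duplicate tuple of `clean`
    clean_record(station_id = "S7", latitude = 45.5,
                 distance_to_shore = 100)
  )
  res <- filter_records(toy)
  expect_identical(res$audit$n_input, 7L)
  expect_identical(res$audit$n_surviving, 1L)
  expect_identical(res$records$station_id, "S1")
  counts <- setNames(res$audit$rules$discarded, res$audit$rules$rule)
  expect_identical(unname(counts[c("depth", "chl_range", "date_mismatch",
                                   "sample_type", "duplicate",
                                   "shore_distance")]),
                   rep(1L, 6))
  expect_identical(unname(counts["unparseable"]), 0L)
})

test_that("boundary conventions: depth 0.5 retained, shore 300 discarded,
           chl 0 retained", {
  toy <- rbind(clean_record(depth = 0.5, chl = 0, station_id = "A"),
               clean_record(distance_to_shore = 300, station_id = "B"))
  res <- filter_records(toy)
  expect_identical(res$records$station_id, "A")
  expect_identical(
    res$audit$rules$discarded[res$audit$rules$rule == "shore_distance"], 1L)
})

test_that("malformed records get their own audit category", {
  toy <- rbind(clean_record(), clean_record(latitude = 95, station_id = "X"))
  res <- filter_records(toy)
  expect_identical(
    res$audit$rules$discarded[res$audit$rules$rule == "unparseable"], 1L)
  expect_identical(res$audit$n_surviving, 1L)
})

test_that("audit counts balance and survivors match a brute-force oracle
           on random record sets; filtering is idempotent", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    rec <- simulate_insitu_records(sim_config(
      n = n, seed = i,
      contamination_rates = c(depth = 0.15, chl_range = 0.1,
                              date_mismatch = 0.1, sample_type = 0.15,
                              duplicate = 0.15, shore_distance = 0.15)))
    res <- filter_records(rec)
    # conservation: input = surviving + sum of per-rule discards
    expect_identical(res$audit$n_input,
                     res$audit$n_surviving +
                       sum(res$audit$rules$discarded))
    # order-robust surviving set: all-predicates brute force
    expect_identical(res$records$station_id,
                     rec$station_id[oracle_pass(rec)])
    # idempotence
    res2 <- filter_records(res$records)
    expect_identical(res2$audit$n_surviving, nrow(res$records))
    expect_identical(sum(res2$audit$rules$discarded), 0L)
  }
})

test_that("distance_to_shore matches square-lake geometry", {
  sq <- cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000))
  expect_equal(distance_to_shore(c(500, 500), sq), 500)
  expect_equal(distance_to_shore(c(100, 500), sq), 100)
  expect_error(distance_to_shore(c(1500, 500), sq), "not strictly inside")
  expect_error(distance_to_shore(c(0, 500), sq), "not strictly inside")
})

test_that("distance_to_shore matches a dense boundary-sampling oracle on an
           L-shaped lake", {
  L <- cbind(c(0, 2000, 2000, 1000, 1000, 0),
             c(0, 0, 1000, 1000, 2000, 2000))
  dense <- do.call(rbind, lapply(seq_len(nrow(L)), function(i) {
    a <- L[i, ]; b <- L[if (i == nrow(L)) 1 else i + 1, ]
    t <- seq(0, 1, length.out = 4000)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  pts <- rbind(c(500, 500), c(1100, 900), c(900, 1100), c(500, 1800))
  for (i in seq_len(nrow(pts))) {
    brute <- sqrt(min((dense[, 1] - pts[i, 1])^2 +
                        (dense[, 2] - pts[i, 2])^2))
    expect_equal(distance_to_shore(pts[i, ], L), brute, tolerance = 0.5)
  }
})

test_that("lon/lat distances agree with great-circle geometry", {
  # ~2.2 km x 1.1 km lake at 45 N
  poly <- cbind(c(-93.00, -92.972, -92.972, -93.00),
                c(45.000, 45.000, 45.010, 45.010))
  pt <- c(-92.986, 45.005)
  d <- distance_to_shore(pt, poly, coords = "lonlat")
  boundary_line <- rbind(poly, poly[1, ])
  ref <- unname(geosphere::dist2Line(pt, boundary_line)[1, "distance"])
  expect_equal(d, ref, tolerance = 0.005)
})

test_that("same-day matching pairs valid cyano pixels with surviving
           records only", {
  ci_series <- tibble::tibble(
    station_id = c("S1", "S1", "S2", "S3"),
    date = as.Date(c("2011-09-10", "2011-09-11", "2011-09-10",
                     "2011-09-10")),
    detection = c("cyano", "cyano", "masked", "noncyano"),
    ci_cyano = c(0.005, 0.004, NA, NA))
  records <- tibble::tibble(
    station_id = c("S1", "S1", "S2", "S3", "S4"),
    start_date = as.Date(c("2011-09-10", "2011-09-12", "2011-09-10",
                           "2011-09-10", "2011-09-10")),
    chl = c(30, 40, 25, 18, 12))
  pairs <- match_same_day(ci_series, records)
  # S1 same-day pairs; S1's 09-12 sample has no same-day pixel; S2 masked;
  # S3 non-cyano; S4 has no satellite value at all
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$station_id, "S1")
  expect_equal(pairs$ci_cyano, 0.005)
  expect_equal(pairs$chl_insitu, 30)

  dup <- rbind(ci_series, ci_series[1, ])
  expect_error(match_same_day(dup, records), "multiple satellite values")

  zero_chl <- tibble::tibble(station_id = "S1",
                             start_date = as.Date("2011-09-10"), chl = 0)
  expect_identical(nrow(match_same_day(ci_series, zero_chl)), 0L)
})
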