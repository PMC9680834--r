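test_that("daily composite of one scene is the identity", {
  s <- toy_scene(matrix(c(0.01, NA, 0.02, NA), 2, 2))
  out <- daily_composite(list(s))
  expect_identical(out$ci, s$ci)
  expect_identical(out$state, s$state)
})

test_that("daily composite selects the max-CI scene and carries its bands", {
  a <- toy_scene(matrix(0.001, 1, 1), band_value = 0.02)
  b <- toy_scene(matrix(0.003, 1, 1), band_value = 0.04)
  out <- daily_composite(list(a, b))
  expect_equal(out$ci[1, 1], 0.003)
  expect_equal(out$rho$rho_s_665[1, 1], 0.04)  # from scene b, not a

  # nondetect scores 0 for selection; masked is excluded
  nd <- toy_scene(matrix(NA_real_, 1, 1), band_value = 0.05)
  mk <- toy_scene(matrix(0.9, 1, 1), masked = matrix(TRUE, 1, 1))
  out2 <- daily_composite(list(mk, nd))
  expect_identical(out2$state[1, 1], "nondetect")
  expect_equal(out2$rho$rho_s_665[1, 1], 0.05)
  out3 <- daily_composite(list(mk, mk))
  expect_identical(out3$state[1, 1], "masked")
})

test_that("daily composite equals the brute-force per-cell argmax on random
           scene stacks and is idempotent and order-invariant", {
  set.seed(21)
  scenes <- lapply(1:5, function(i) random_scene(20, 20))
  out <- daily_composite(scenes)
  sel <- brute_daily(scenes)
  for (r in 1:20) for (c_ in 1:20) {
    k <- sel[r, c_]
    if (is.na(k)) {
      expect_identical(out$state[r, c_], "masked")
    } else {
      expect_identical(out$state[r, c_], scenes[[k]]$state[r, c_])
      if (out$state[r, c_] == "detected") {
        expect_identical(out$ci[r, c_], scenes[[k]]$ci[r, c_])
      }
      expect_identical(out$rho$rho_s_665[r, c_],
                       scenes[[k]]$rho$rho_s_665[r, c_])
    }
  }
  # idempotent
  again <- daily_composite(list(out, out))
  expect_identical(again$ci, out$ci)
  # order-invariant in CI and state (detected scores almost surely
  # distinct); at detected cells the winning scene's bands follow
  rev_ <- daily_composite(rev(scenes))
  expect_identical(rev_$ci, out$ci)
  expect_identical(rev_$state, out$state)
  det <- out$state == "detected"
  expect_identical(rev_$rho$rho_s_709[det], out$rho$rho_s_709[det])
})

test_that("grid mismatches are rejected", {
  a <- toy_scene(matrix(0.01, 2, 2))
  b <- toy_scene(matrix(0.01, 3, 3))
  expect_error(daily_composite(list(a, b)), "shape|same grid")
})

test_that("temporal means reproduce constants and simple averages", {
  d1 <- toy_scene(matrix(2e-3, 2, 2), timestamp = as.Date("2011-09-05"))
  d2 <- toy_scene(matrix(4e-3, 2, 2), timestamp = as.Date("2011-09-06"))
  out <- temporal_composite(list(d1, d2), "7day",
                            anchor = as.Date("2011-09-07"))
  expect_equal(out$ci, matrix(3e-3, 2, 2))
  expect_equal(out$n_members$ci, matrix(2, 2, 2))

  same <- temporal_composite(list(d1, d1), "28day",
                             anchor = as.Date("2011-09-06"))
  expect_equal(same$ci, d1$ci)
  expect_equal(same$rho$rho_s_665, d1$rho$rho_s_665)
})

test_that("temporal windows select the right member dates", {
  mk <- function(d) toy_scene(matrix(1e-3, 1, 1), timestamp = as.Date(d))
  days <- c("2011-08-28", "2011-09-03", "2011-09-04", "2011-09-30",
            "2011-10-01", "2011-12-15")
  scenes <- lapply(days, mk)
  # Sunday 2011-08-28 .. Saturday 2011-09-03 contains the Wed 08-31 anchor
  w <- temporal_composite(scenes, "7day", anchor = as.Date("2011-08-31"))
  expect_equal(w$n_members$ci[1, 1], 2)
  m <- temporal_composite(scenes, "month", anchor = as.Date("2011-09-15"))
  expect_equal(m$n_members$ci[1, 1], 3)
  r <- temporal_composite(scenes, "28day", anchor = as.Date("2011-09-30"))
  expect_equal(r$n_members$ci[1, 1], 3)
  # SON 2011 holds the four Sep/Oct scenes; Aug is JJA, December DJF
  s <- temporal_composite(scenes, "season", anchor = as.Date("2011-09-15"))
  expect_equal(s$n_members$ci[1, 1], 4)
  expect_error(temporal_composite(scenes, "7day",
                                  anchor = as.Date("2012-06-01")),
               "no scenes")
})

test_that("temporal composite matches a brute-force masked mean and the
           nondetect-zero switch behaves as documented", {
  set.seed(31)
  stack <- lapply(1:10, function(i) {
    random_scene(8, 8, timestamp = as.Date("2011-09-01") + i - 1)
  })
  out <- temporal_composite(stack, "28day", anchor = as.Date("2011-09-10"))
  out0 <- temporal_composite(stack, "28day", anchor = as.Date("2011-09-10"),
                             include_nondetect = TRUE)
  for (r in 1:8) for (c_ in 1:8) {
    st <- vapply(stack, function(s) s$state[r, c_], character(1))
    civ <- vapply(stack, function(s) s$ci[r, c_], numeric(1))
    det <- st == "detected"
    if (any(det)) {
      expect_equal(out$ci[r, c_], mean(civ[det]))
      # min/max bracketing of the mean
      expect_gte(out$ci[r, c_], min(civ[det]))
      expect_lte(out$ci[r, c_], max(civ[det]))
      # zeros pull the including-nondetect mean down (or equal)
      expect_lte(out0$ci[r, c_], out$ci[r, c_] + 1e-15)
    }
    unm <- st != "masked"
    b <- vapply(stack, function(s) s$rho$rho_s_665[r, c_], numeric(1))
    if (any(unm)) {
      expect_equal(out$rho$rho_s_665[r, c_], mean(b[unm]))
    } else {
      expect_identical(out$state[r, c_], "masked")
    }
  }
})

test_that("scenes round-trip through netCDF", {
  set.seed(17)
  sc <- make_scene(6, 7, list(list(center = c(3, 3), radius = 2,
                                   chl = 63.1)),
                   masked_fraction = 0.1, seed = 9)
  path <- tempfile(fileext = ".nc")
  write_scene_nc(sc, path)
  back <- read_scene_nc(path)
  expect_identical(back$state, sc$state)
  expect_equal(back$ci, sc$ci, tolerance = 1e-12)
  expect_equal(back$rho$rho_s_709, sc$rho$rho_s_709, tolerance = 1e-12)
  expect_equal(back$grid$origin_lon, sc$grid$origin_lon)
  expect_equal(back$grid$cell_size, sc$grid$cell_size, tolerance = 1e-9)
  expect_identical(back$timestamp, sc$timestamp)
  unlink(path)
})
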