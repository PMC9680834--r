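test_that("spectral_shape reproduces hand-computed line heights", {
  # 0.025 - 0.020 + (0.020 - 0.018) * 16/44
  s <- red_nir_spectrum(NA, 0.020, 0.025, 0.018)
  expect_equal(spectral_shape(s, 681, 665, 709), 0.0057273, tolerance = 1e-5)
  # 0.012 - 0.020 + (0.020 - 0.022) * 16/44
  s2 <- red_nir_spectrum(NA, 0.020, 0.012, 0.022)
  expect_equal(spectral_shape(s2, 681, 665, 709), -0.0087273,
               tolerance = 1e-5)
  # collinear bands sit exactly on their own baseline
  flat <- red_nir_spectrum(0.01, 0.01, 0.01, 0.01)
  expect_identical(spectral_shape(flat, 681, 665, 709), 0)
  sloped <- lake_spectrum(0.05 - 2e-4 * (MERIS_BANDS - 413))
  expect_equal(spectral_shape(sloped, 665, 620, 681), 0, tolerance = 1e-15)
})

test_that("spectral_shape validates bands and band order", {
  s <- red_nir_spectrum(0.01, 0.02, 0.015, 0.012)
  expect_error(spectral_shape(s, 680, 665, 709), "canonical")
  expect_error(spectral_shape(s, 665, 681, 709), "lower < center < upper")
  expect_error(spectral_shape(s, 681, 665, 665), "lower < center < upper")
  missing560 <- red_nir_spectrum(0.01, 0.02, 0.015, 0.012)
  expect_error(spectral_shape(missing560, 620, 560, 665), "560")
})

test_that("spectral_shape is offset-invariant and homogeneous", {
  set.seed(41)
  for (i in 1:50) {
    rho <- runif(11, 0.005, 0.05)
    s <- lake_spectrum(rho)
    base <- spectral_shape(s, 681, 665, 709)
    expect_equal(spectral_shape(lake_spectrum(rho + 0.013), 681, 665, 709),
                 base, tolerance = 1e-12)
    c_ <- runif(1, 0.1, 5)
    expect_equal(spectral_shape(lake_spectrum(c_ * rho), 681, 665, 709),
                 c_ * base, tolerance = 1e-12)
  }
})

test_that("compute_ci reproduces the worked decision-tree example", {
  r <- compute_ci(red_nir_spectrum(0.015, 0.020, 0.012, 0.022))
  expect_equal(r$ss665, 0.0072131, tolerance = 1e-5)
  expect_equal(r$ss681, -0.0087273, tolerance = 1e-5)
  expect_identical(r$ci, -r$ss681)
  expect_identical(r$detection, "cyano")
  expect_identical(r$ci_cyano, r$ci)
})

test_that("compute_ci decision tree covers all branches conservatively", {
  flat <- compute_ci(red_nir_spectrum(0.01, 0.01, 0.01, 0.01))
  expect_identical(flat$detection, "nondetect")
  expect_identical(flat$ci, 0)
  expect_true(is.na(flat$ci_cyano))

  # 681 depressed (bloom) but 620 high (no phycocyanin absorption)
  # -> ss665 < 0 -> some other bloom type
  noncy <- compute_ci(red_nir_spectrum(0.035, 0.020, 0.015, 0.022))
  expect_gt(noncy$ci, 0)
  expect_lte(noncy$ss665, 0)
  expect_identical(noncy$detection, "noncyano")
  expect_true(is.na(noncy$ci_cyano))

  masked <- compute_ci(red_nir_spectrum(0.015, 0.020, 0.012, 0.022,
                                        flags = c(cloud = TRUE)))
  expect_identical(masked$detection, "masked")
  expect_false(identical(masked$detection, "nondetect"))

  expect_error(compute_ci(red_nir_spectrum(NA, 0.02, 0.015, 0.012)),
               "620")
})

test_that("compute_ci matches an independent transcription on random spectra
           and maps every unmasked spectrum to exactly one class", {
  set.seed(42)
  for (i in 1:1000) {
    rho <- runif(11, 0.001, 0.08)
    names(rho) <- as.character(MERIS_BANDS)
    r <- compute_ci(lake_spectrum(unname(rho)))
    ss681 <- ss_oracle(rho, 681, 665, 709)
    ss665 <- ss_oracle(rho, 665, 620, 681)
    expect_equal(r$ss681, ss681, tolerance = 1e-12)
    expect_equal(r$ss665, ss665, tolerance = 1e-12)
    expect_equal(r$ci, -ss681, tolerance = 1e-12)
    expect_true(r$detection %in% c("cyano", "noncyano", "nondetect"))
    expected <- if (-ss681 > 0 && ss665 > 0) "cyano" else
      if (-ss681 > 0) "noncyano" else "nondetect"
    expect_identical(r$detection, expected)
    expect_identical(!is.na(r$ci_cyano), r$detection == "cyano")
  }
})

test_that("data-frame compute_ci agrees with the scalar method rowwise", {
  set.seed(7)
  df <- as.data.frame(matrix(runif(20 * 11, 0.001, 0.06), 20))
  names(df) <- paste0("rho_s_", MERIS_BANDS)
  df$cloud <- rep(c(FALSE, FALSE, FALSE, TRUE), 5)
  df$station_id <- sprintf("S%02d", 1:20)
  out <- compute_ci(df)
  expect_identical(nrow(out), 20L)
  expect_identical(out$station_id, df$station_id)
  for (i in seq_len(nrow(df))) {
    one <- compute_ci(lake_spectrum(
      as.numeric(df[i, paste0("rho_s_", MERIS_BANDS)]),
      flags = c(cloud = df$cloud[i])))
    expect_identical(out$detection[i], one$detection)
    if (one$detection != "masked") {
      expect_equal(out$ci[i], one$ci, tolerance = 1e-14)
    } else {
      expect_true(is.na(out$ci[i]))
    }
  }
})

test_that("chlorophyll models evaluate and remove negative retrievals", {
  expect_equal(as.numeric(apply_chl_model(0, chl_t16())), 20)
  expect_equal(as.numeric(apply_chl_model(0.01, chl_bs())), 63.1)
  res <- apply_chl_model(c(0.0001, 0.01), chl_bs())
  expect_true(is.na(res[1]))        # 6620 * 1e-4 - 3.1 < 0: removed
  expect_equal(attr(res, "n_negative_removed"), 1L)
  expect_error(chl_model(-5, 0), "positive")
  expect_error(apply_chl_model(Inf, chl_bs()), "finite")
})

test_that("normalization integrates to one and is scale invariant", {
  flat <- lake_spectrum(rep(0.02, 11))
  n1 <- normalize_spectrum(flat)
  in_window <- MERIS_BANDS <= 754
  expect_equal(unname(n1$rho_s[in_window]),
               rep(1 / 341, sum(in_window)), tolerance = 1e-12)

  set.seed(11)
  rho <- runif(11, 0.002, 0.05)
  a <- normalize_spectrum(lake_spectrum(rho))
  b <- normalize_spectrum(lake_spectrum(3.7 * rho))
  expect_equal(a$rho_s, b$rho_s, tolerance = 1e-12)
  reint <- pracma::trapz(as.numeric(MERIS_BANDS[in_window]),
                         as.numeric(a$rho_s[in_window]))
  expect_equal(reint, 1, tolerance = 1e-12)

  expect_error(normalize_spectrum(lake_spectrum(rep(0, 11))),
               "non-positive integral")
  expect_error(
    normalize_spectrum(lake_spectrum(c(rho_s_620 = 0.1, rho_s_665 = 0.1,
                                       rho_s_681 = 0.1, rho_s_709 = 0.1))),
    "required")
})
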