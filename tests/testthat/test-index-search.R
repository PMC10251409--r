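test_that("index arithmetic follows the three two-band formulations", {
  s <- spectrum_set(500:501, matrix(c(0.5, 0.6, 0.5, 0.2), 2, 2))
  expect_equal(compute_index(s, "RSI", 500, 501), c(1.0, 3.0))
  expect_equal(compute_index(s, "DSI", 500, 501), c(0.0, 0.4))
  expect_equal(compute_index(s, "NDSI", 500, 501), c(0.0, 0.5))
  # swapping bands negates DSI/NDSI and inverts RSI
  expect_equal(compute_index(s, "DSI", 501, 500), -compute_index(s, "DSI", 500, 501))
  expect_equal(compute_index(s, "NDSI", 501, 500), -compute_index(s, "NDSI", 500, 501))
  expect_equal(compute_index(s, "RSI", 501, 500), 1 / compute_index(s, "RSI", 500, 501))
})

test_that("near-zero denominators are reported with the offending sample", {
  refl <- matrix(c(0.4, 0, 0.3, 0), 2, 2)  # second sample is (0, 0)
  s <- spectrum_set(600:601, refl, meta = data.frame(id = c("ok", "zero")))
  expect_error(compute_index(s, "RSI", 600, 601), "zero")
  expect_error(compute_index(s, "NDSI", 601, 600), "numeric-degeneracy")
})

test_that("pairwise maps equal the brute-force per-pair regression oracle", {
  s <- tiny_spectra(n = 10, p = 8, seed = 21)
  for (it in c("RSI", "DSI", "NDSI")) {
    m <- pairwise_r2_map(s, it)
    expect_equal(unname(m$values), oracle_pair_r2(s, it), tolerance = 1e-10)
  }
})

test_that("DSI and NDSI maps are symmetric; diagonal undefined", {
  s <- tiny_spectra(n = 12, p = 10, seed = 4)
  for (it in c("DSI", "NDSI")) {
    v <- pairwise_r2_map(s, it)$values
    expect_equal(v, t(v), tolerance = 1e-12)
    expect_true(all(is.na(diag(v))))
  }
})

test_that("ratio-type maps are scale invariant, the difference map is not", {
  s <- tiny_spectra(n = 9, p = 7, seed = 6)
  s_scaled <- spectrum_set(s$wavelengths, pmin(s$reflectance * 1.4, 1), lpc = s$lpc)
  for (it in c("RSI", "NDSI")) {
    expect_equal(pairwise_r2_map(s, it)$values,
                 pairwise_r2_map(s_scaled, it)$values, tolerance = 1e-9)
  }
  # DSI R2 values are scale covariant as a map of the same data, but the
  # index itself is not scale free: check covariance of the index values
  expect_equal(compute_index(s_scaled, "DSI", 502, 504),
               1.4 * compute_index(s, "DSI", 502, 504), tolerance = 1e-12)
})

test_that("NDSI and RSI are linked by the value identity (RSI-1)/(RSI+1)", {
  s <- tiny_spectra(n = 8, p = 5, seed = 13)
  rsi <- compute_index(s, "RSI", 501, 503)
  ndsi <- compute_index(s, "NDSI", 501, 503)
  expect_equal(ndsi, (rsi - 1) / (rsi + 1), tolerance = 1e-12)
})

test_that("a perfectly linear index yields a map value of 1", {
  s <- tiny_spectra(n = 10, p = 6, seed = 3)
  s$lpc <- 2 * (s$reflectance[, 2] - s$reflectance[, 5]) + 3
  s$lpc <- s$lpc - min(s$lpc) + 0.5  # keep lpc positive
  m <- pairwise_r2_map(s, "DSI")
  expect_equal(m$values[2, 5], 1, tolerance = 1e-10)
})

test_that("selection ranks by R2 with the documented tie-breaks and separation rule", {
  # two exact ties: smaller lambda1 wins
  v <- matrix(NA_real_, 4, 4, dimnames = list(900:903, 900:903))
  v[1, 3] <- 0.8; v[2, 4] <- 0.8; v[1, 2] <- 0.5
  m <- phospec:::new_score_map(900:903, 900:903, v, "pairwise-index", "DSI")
  f <- suppressWarnings(select_top_index_features(list(m), k = 2, min_separation_nm = 1))
  expect_equal(f$lambda1_nm[1], 900)
  expect_equal(f$lambda2_nm[1], 902)

  # separation rule: near-duplicate hot-spot cells collapse to one feature
  v2 <- matrix(NA_real_, 4, 4, dimnames = list(900:903, 900:903))
  v2[1, 3] <- 0.9; v2[2, 3] <- 0.85; v2[1, 4] <- 0.84; v2[4, 1] <- 0.84
  m2 <- phospec:::new_score_map(900:903, 900:903, v2, "pairwise-index", "DSI")
  f2 <- suppressWarnings(select_top_index_features(list(m2), k = 3, min_separation_nm = 5))
  expect_equal(nrow(f2), 1)  # all cells within 5 nm of the first pick
  expect_warning(select_top_index_features(list(m2), k = 3, min_separation_nm = 5),
                 "admissible")
})

test_that("planted difference signal is the first selected feature without noise", {
  cfg <- synthetic_config(n_per_cell = 3, noise_sd = 0, seed = 17)
  s <- suppressMessages(generate_dataset(cfg))
  m <- pairwise_r2_map(s, "DSI")
  f <- select_top_index_features(list(m), k = 1)
  expect_setequal(c(f$lambda1_nm, f$lambda2_nm), cfg$planted_pair)
  expect_equal(f$r2_cal, 1, tolerance = 1e-9)
})

test_that("index model calibration matches hand-computed OLS", {
  # index values (0,1,2), LPC (1,2,4): slope 3/2, intercept 1/6, R2 27/28
  refl <- cbind(c(0.2, 0.3, 0.4), c(0.2, 0.2, 0.2))
  s <- spectrum_set(700:701, refl, lpc = c(1, 2, 4))
  feats <- data.frame(index_type = "DSI", lambda1_nm = 700, lambda2_nm = 701,
                      r2_cal = NA_real_, slope = NA_real_, intercept = NA_real_)
  # DSI = (0, 0.1, 0.2); rescaling the regressor rescales the slope only,
  # leaving intercept (5/6 = ybar - slope*xbar) and R2 unchanged
  out <- fit_index_model(feats, s)
  expect_equal(out$slope, 1.5 / 0.1, tolerance = 1e-9)
  expect_equal(out$intercept, 5 / 6, tolerance = 1e-9)
  expect_equal(out$r2_cal, 27 / 28, tolerance = 1e-12)

  # exact linear relation recovers slope/intercept/R2 = 1
  s2 <- tiny_spectra(n = 6, p = 4, seed = 2)
  z <- compute_index(s2, "DSI", 501, 503)
  s2$lpc <- 2 * z + 1 - min(2 * z) + 0.2
  f2 <- fit_index_model(data.frame(index_type = "DSI", lambda1_nm = 501,
                                   lambda2_nm = 503, r2_cal = NA, slope = NA,
                                   intercept = NA), s2)
  expect_equal(f2$slope, 2, tolerance = 1e-10)
  expect_equal(f2$r2_cal, 1, tolerance = 1e-12)

  # constant index errors
  s3 <- spectrum_set(700:701, cbind(c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1)),
                     lpc = c(1, 2, 3))
  expect_error(fit_index_model(feats, s3), "degeneracy")
})

test_that("strided scan equals the full map on the strided subgrid", {
  s <- tiny_spectra(n = 8, p = 12, seed = 30)
  full <- pairwise_r2_map(s, "NDSI")
  strided <- pairwise_r2_map(s, "NDSI", step = 3L)
  keep <- seq(1, 12, by = 3)
  expect_equal(strided$values, full$values[keep, keep])
})
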