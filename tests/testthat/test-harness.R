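test_that("split respects floor arithmetic, disjointness and the seed", {
  s <- suppressMessages(generate_dataset(synthetic_config(n_per_cell = 19, seed = 1)))
  sp <- split_dataset(s, 0.7, seed = 5)
  expect_equal(nsamples(sp$calibration), 319)
  expect_equal(nsamples(sp$validation), 137)
  expect_length(intersect(sp$calibration$meta$id, sp$validation$meta$id), 0)
  expect_setequal(c(sp$calibration$meta$id, sp$validation$meta$id), s$meta$id)
  sp2 <- split_dataset(s, 0.7, seed = 5)
  expect_identical(sp$calibration$meta$id, sp2$calibration$meta$id)
  # n = 10 -> 7/3
  s10 <- ss <- tiny_spectra(n = 10, p = 4, seed = 2)
  sp10 <- split_dataset(s10, 0.7, seed = 1)
  expect_equal(nsamples(sp10$calibration), 7)
  expect_error(split_dataset(tiny_spectra(n = 9, p = 4), 0.7, 1), "size error")
})

test_that("every algorithm is deterministic under a fixed seed", {
  set.seed(3)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 + X[, 1] - 0.5 * X[, 3]^2 + rnorm(60, 0, 0.3)
  tr <- feature_table(X[1:40, ], colnames(X), "SIs", y[1:40])
  te <- feature_table(X[41:60, ], colnames(X), "SIs", y[41:60])
  for (alg in c("PLSR", "LASSO", "RF", "SVM", "BPANN")) {
    p1 <- fit_predict(alg, tr, te, light_control(), seed = 9)$predictions
    p2 <- fit_predict(alg, tr, te, light_control(), seed = 9)$predictions
    expect_identical(p1, p2)
    expect_true(all(is.finite(p1)))
  }
  expect_error(fit_predict("GBM", tr, te), "configuration error")
})

test_that("a noiseless linear single feature is recovered exactly", {
  x <- seq(-1, 1, length.out = 30)
  tab_tr <- feature_table(matrix(x[1:20], 20, 1, dimnames = list(NULL, "f")),
                          "f", "SIs", 3 * x[1:20] + 1)
  tab_te <- feature_table(matrix(x[21:30], 10, 1, dimnames = list(NULL, "f")),
                          "f", "SIs", 3 * x[21:30] + 1)
  fp <- fit_predict("PLSR", tab_tr, tab_te, seed = 1)
  expect_equal(r2_metric(tab_te$lpc, fp$predictions), 1, tolerance = 1e-9)
  cv <- cross_validate("PLSR", tab_tr, folds = 10, seed = 4)
  expect_equal(cv$r2_cv, 1, tolerance = 1e-6)
})

test_that("cross-validation equals a hand-looped oracle at the same assignment", {
  set.seed(10)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- 1 + X %*% c(1, -1, 0.5) + rnorm(30, 0, 0.2)
  tab <- feature_table(X, colnames(X), "SIs", as.numeric(y))
  seed <- 6
  cv <- cross_validate("PLSR", tab, folds = 10, seed = seed)
  set.seed(seed)
  fid <- sample(rep(1:10, length.out = 30))
  r2s <- rms <- numeric(10)
  for (f in 1:10) {
    tr <- feature_table(X[fid != f, ], colnames(X), "SIs", tab$lpc[fid != f])
    te <- feature_table(X[fid == f, , drop = FALSE], colnames(X), "SIs", tab$lpc[fid == f])
    pr <- fit_predict("PLSR", tr, te, seed = seed + f)$predictions
    r2s[f] <- r2_metric(te$lpc, pr)
    rms[f] <- rmse_metric(te$lpc, pr)
  }
  expect_equal(cv$r2_cv, mean(r2s), tolerance = 1e-10)
  expect_equal(cv$rmse_cv, mean(rms), tolerance = 1e-10)
})

test_that("permuted trait labels give no cross-validated skill", {
  set.seed(20)
  meds <- sapply(c("PLSR", "LASSO", "RF", "SVM", "BPANN"), function(alg) {
    r2 <- sapply(1:9, function(seed) {
      set.seed(seed)
      X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, paste0("f", 1:3)))
      y <- sample(rnorm(60, 2, 0.7))  # independent of X by construction
      tr <- feature_table(X[1:40, ], colnames(X), "SIs", y[1:40])
      te <- feature_table(X[41:60, ], colnames(X), "SIs", y[41:60])
      r2_metric(te$lpc, fit_predict(alg, tr, te, light_control(), seed)$predictions)
    })
    median(r2)
  })
  expect_true(all(meds <= 0.1))
})

test_that("run_matrix fills the 4 x 5 report grid with consistent columns", {
  s <- suppressMessages(generate_dataset(synthetic_config(
    n_per_cell = 2, seed = 3, wavelengths = 950:1250)))
  sp <- split_dataset(s, 0.7, seed = 2)
  maps <- lapply(c("RSI", "DSI", "NDSI"), function(it)
    pairwise_r2_map(sp$calibration, it, step = 20L))
  si <- fit_index_model(select_top_index_features(maps, k = 3), sp$calibration)
  cw <- cwt_transform(sp$calibration, "mexh", 1:3)
  wf <- select_per_scale_features(scalogram_r2_map(cw, sp$calibration$lpc),
                                  cw, sp$calibration$lpc)
  rep <- run_matrix(sp$calibration, sp$validation, si, wf,
                    control = light_control(), seed = 1, cv = FALSE)
  expect_equal(nrow(rep), 20)
  expect_setequal(unique(rep$model), c("PLSR", "LASSO", "RF", "SVM", "BPANN"))
  expect_equal(rep$k[rep$source == "OR"][1], 301)
  expect_equal(rep$k[rep$source == "SIs+CWT"][1], nrow(si) + nrow(wf))
  expect_true(all(rep$rmse_val >= 0))
  expect_true(all(rep$n == nsamples(sp$validation)))
  # Taylor columns satisfy the law-of-cosines identity row-wise
  sd_o <- sqrt(mean((sp$validation$lpc - mean(sp$validation$lpc))^2))
  lhs <- rep$centered_rmsd^2
  rhs <- (rep$std_ratio * sd_o)^2 + sd_o^2 -
    2 * rep$std_ratio * sd_o^2 * rep$pearson_r
  expect_equal(lhs, rhs, tolerance = 1e-10)
  # RF importance is exported per source
  expect_setequal(names(attr(rep, "importance")), unique(rep$source))
})

test_that("feature selection never sees validation samples", {
  s <- suppressMessages(generate_dataset(synthetic_config(
    n_per_cell = 3, seed = 8, wavelengths = 950:1150)))
  sp <- split_dataset(s, 0.7, seed = 4)
  select_from <- function(cal) {
    maps <- lapply(c("RSI", "DSI", "NDSI"), function(it)
      pairwise_r2_map(cal, it, step = 10L))
    select_top_index_features(maps, k = 3)
  }
  f1 <- select_from(sp$calibration)
  # mutate the validation partition: selection must be unchanged
  sp$validation$reflectance[] <- 0.5
  f2 <- select_from(sp$calibration)
  expect_identical(f1, f2)
})
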