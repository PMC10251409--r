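#' Random calibration/validation split
#'
#' Uniform random partition without replacement; the calibration set gets
#' `floor(cal_fraction * n)` samples (the conventional 70/30 split of 456
#' samples gives 319/137). Reproducible under `seed`; the caller's RNG
#' state is untouched.
#'
#' @param s a [spectrum_set()] with `lpc`
#' @param cal_fraction calibration fraction in (0, 1)
#' @param seed integer seed
#' @return list with `calibration` and `validation` spectrum sets
#' @export
split_dataset <- function(s, cal_fraction = 0.7, seed = 1) {
  stopifnot(inherits(s, "spectrum_set"))
  if (is.null(s$lpc)) stop("precondition error: split_dataset requires lpc")
  if (cal_fraction <= 0 || cal_fraction >= 1) stop("precondition error: cal_fraction in (0,1)")
  n <- nsamples(s)
  if (n < 10) stop("size error: need at least 10 samples to split")
  idx <- with_seed(seed, sample.int(n, floor(cal_fraction * n)))
  list(calibration = ss_rows(s, sort(idx)),
       validation = ss_rows(s, setdiff(seq_len(n), idx)))
}

# run code under a seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

ss_rows <- function(s, idx) {
  spectrum_set(s$wavelengths, s$reflectance[idx, , drop = FALSE],
               if (is.null(s$lpc)) NULL else s$lpc[idx],
               s$meta[idx, , drop = FALSE])
}

#' Harness hyperparameter defaults
#'
#' Explicit, documented defaults for the five algorithms (there is no
#' appeal to any library's "default settings"):
#' \describe{
#'   \item{PLSR}{latent components `min(plsr_max_ncomp, k, n - 1)`;
#'     set `plsr_inner_cv = TRUE` to choose the component count by inner
#'     5-fold CV instead of the fixed rule.}
#'   \item{LASSO}{penalty chosen by inner 5-fold CV over a logarithmic
#'     grid `10^seq(1, -4)` on standardized features.}
#'   \item{RF}{`rf_ntree` trees, unlimited depth, square-root feature
#'     subsampling, seeded; consumes raw (unstandardized) features.}
#'   \item{SVM}{radial basis kernel, `cost = svm_cost`, kernel width
#'     `gamma = 1/(k * mean feature variance)` on standardized features.}
#'   \item{BPANN}{one hidden layer sized by a weight budget,
#'     `clamp(floor(ann_weight_budget / (k + 2)), 1, ann_max_hidden)`
#'     sigmoidal units, weight decay `ann_decay`, up to `ann_maxit`
#'     optimizer iterations, seeded initialization. The budget keeps the
#'     dense-Hessian optimizer tractable on the 2151-band source.}
#' }
#'
#' @param ... overrides of the named defaults
#' @return a named list of settings
#' @export
harness_control <- function(...) {
  ctl <- list(
    plsr_max_ncomp = 10, plsr_inner_cv = FALSE,
    lasso_lambda = 10^seq(1, -4, length.out = 50), lasso_nfolds = 5,
    rf_ntree = 500,
    svm_cost = 1,
    ann_weight_budget = 3000, ann_max_hidden = 10, ann_decay = 0.1, ann_maxit = 150,
    cv_folds = 10,
    aic_variant = "rss"
  )
  over <- list(...)
  bad <- setdiff(names(over), names(ctl))
  if (length(bad)) stop("configuration error: unknown control settings: ", paste(bad, collapse = ", "))
  ctl[names(over)] <- over
  ctl
}

#' Assemble a feature table
#'
#' @param values sample x feature numeric matrix (no missing values)
#' @param feature_names ordered labels
#' @param source one of `"OR"`, `"SIs"`, `"CWT"`, `"SIs+CWT"` (or any label)
#' @param lpc aligned trait values
#' @return a `feature_table` object
#' @export
feature_table <- function(values, feature_names, source, lpc) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(feature_names), nrow(values) == length(lpc))
  if (!all(is.finite(values))) stop("range error: feature table contains non-finite values")
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 source = source, lpc = lpc),
            class = "feature_table")
}

#' Build the four input-variable sets for both splits
#'
#' Constructs OR (every band), SIs (optimized two-band indices), CWT
#' (per-scale optimal wavelet coefficients) and SIs+CWT feature tables for
#' the calibration and validation sets. Features must have been selected
#' on the calibration set only; this function merely evaluates them.
#'
#' @param s_cal,s_val calibration and validation [spectrum_set()]s
#' @param si_features an `index_features` data.frame
#' @param wavelet_features a `wavelet_features` data.frame
#' @return nested list: `tables[[source]][[split]]` with splits `cal`/`val`
#' @export
build_feature_tables <- function(s_cal, s_val, si_features, wavelet_features) {
  si_names <- sprintf("%s_%d_%d", si_features$index_type,
                      si_features$lambda1_nm, si_features$lambda2_nm)
  wl_names <- sprintf("%s_%d_s%d", wavelet_features$wavelet,
                      wavelet_features$wavelength_nm, wavelet_features$scale_index)
  mk <- function(s) {
    or <- s$reflectance
    colnames(or) <- paste0("b", s$wavelengths)
    si <- vapply(seq_len(nrow(si_features)), function(i) {
      compute_index(s, si_features$index_type[i],
                    si_features$lambda1_nm[i], si_features$lambda2_nm[i])
    }, numeric(nsamples(s)))
    cw <- cwt_at(s, wavelet_features$wavelength_nm, wavelet_features$scale_index,
                 wavelet_features$wavelet[1])
    list(
      "OR" = feature_table(or, colnames(or), "OR", s$lpc),
      "SIs" = feature_table(si, si_names, "SIs", s$lpc),
      "CWT" = feature_table(cw, wl_names, "CWT", s$lpc),
      "SIs+CWT" = feature_table(cbind(si, cw), c(si_names, wl_names), "SIs+CWT", s$lpc)
    )
  }
  cal <- mk(s_cal)
  val <- mk(s_val)
  lapply(stats::setNames(names(cal), names(cal)),
         function(src) list(cal = cal[[src]], val = val[[src]]))
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(mu = mu, sd = sdv)
}
.standardize_apply <- function(X, st) sweep(sweep(X, 2, st$mu), 2, st$sd, "/")

#' Fit one algorithm and predict
#'
#' Fits a single regression algorithm on a training feature table and
#' predicts a test table. Features are standardized with training
#' means/sds for PLSR, LASSO, SVM and BPANN; RF consumes raw features and
#' additionally reports permutation importance scores. All stochastic
#' fits are seeded, so identical inputs give identical predictions.
#'
#' For a single-feature table, PLSR and LASSO reduce to ordinary least
#' squares on that feature (one latent component / no meaningful
#' selection), and are fitted as such.
#'
#' @param algorithm `"PLSR"`, `"LASSO"`, `"RF"`, `"SVM"` or `"BPANN"`
#' @param train,test `feature_table`s sharing feature names
#' @param control settings from [harness_control()]
#' @param seed integer seed
#' @return list with `predictions` (test), `train_predictions`,
#'   `importance` (RF only, else `NULL`) and `details`
#' @export
fit_predict <- function(algorithm = c("PLSR", "LASSO", "RF", "SVM", "BPANN"),
                        train, test, control = harness_control(), seed = 1) {
  algorithm <- tryCatch(match.arg(algorithm), error = function(e)
    stop("configuration error: unknown algorithm '", algorithm[1], "'"))
  stopifnot(inherits(train, "feature_table"), inherits(test, "feature_table"))
  if (!identical(train$feature_names, test$feature_names)) {
    stop("precondition error: train and test tables must share feature names")
  }
  X <- train$values; y <- train$lpc; Xt <- test$values
  k <- ncol(X); n <- nrow(X)
  importance <- NULL; details <- list()

  if (algorithm %in% c("PLSR", "LASSO") && k == 1) {
    fit <- stats::lm(y ~ x, data = data.frame(x = X[, 1]))
    pred <- unname(predict(fit, data.frame(x = Xt[, 1])))
    predtr <- unname(fitted(fit))
    details$note <- "single feature: ordinary least squares"
  } else if (algorithm == "PLSR") {
    st <- .standardize_fit(X)
    Xs <- .standardize_apply(X, st); Xts <- .standardize_apply(Xt, st)
    ncomp_max <- min(control$plsr_max_ncomp, k, n - 1)
    ncomp <- ncomp_max
    if (isTRUE(control$plsr_inner_cv) && ncomp_max > 1) {
      fid <- with_seed(seed, sample(rep(1:5, length.out = n)))
      press <- numeric(ncomp_max)
      used <- integer(ncomp_max)
      for (f in 1:5) {
        tr <- fid != f
        m <- mixOmics::pls(Xs[tr, , drop = FALSE], y[tr],
                           ncomp = min(ncomp_max, sum(tr) - 1),
                           mode = "regression", scale = FALSE)
        pr <- as.matrix(predict(m, Xs[!tr, , drop = FALSE])$predict[, 1, ])
        for (cc in seq_len(ncol(pr))) {
          press[cc] <- press[cc] + sum((pr[, cc] - y[!tr])^2)
          used[cc] <- used[cc] + 1L
        }
      }
      press[used < 5] <- Inf
      ncomp <- which.min(press)
    }
    # near-collinear tables can make the component system singular close
    # to the effective rank; retry with fewer components
    res <- NULL
    while (is.null(res) && ncomp >= 1) {
      res <- tryCatch({
        m <- mixOmics::pls(Xs, y, ncomp = ncomp, mode = "regression", scale = FALSE)
        list(pred = as.numeric(predict(m, Xts)$predict[, 1, ncomp]),
             predtr = as.numeric(predict(m, Xs)$predict[, 1, ncomp]))
      }, error = function(e) NULL)
      if (is.null(res)) ncomp <- if (ncomp > 2) ncomp %/% 2 else ncomp - 1
    }
    if (is.null(res)) stop("numeric error: PLSR failed at every component count")
    pred <- res$pred
    predtr <- res$predtr
    details$ncomp <- ncomp
  } else if (algorithm == "LASSO") {
    st <- .standardize_fit(X)
    Xs <- .standardize_apply(X, st); Xts <- .standardize_apply(Xt, st)
    fid <- with_seed(seed, sample(rep(seq_len(control$lasso_nfolds), length.out = n)))
    cvfit <- glmnet::cv.glmnet(Xs, y, alpha = 1, lambda = control$lasso_lambda,
                               foldid = fid, standardize = FALSE)
    pred <- as.numeric(predict(cvfit, Xts, s = "lambda.min"))
    predtr <- as.numeric(predict(cvfit, Xs, s = "lambda.min"))
    details$lambda <- cvfit$lambda.min
  } else if (algorithm == "RF") {
    m <- with_seed(seed, randomForest::randomForest(
      x = X, y = y, ntree = control$rf_ntree,
      mtry = max(1, floor(sqrt(k))), importance = TRUE))
    pred <- unname(predict(m, Xt))
    predtr <- unname(predict(m, X))
    imp <- randomForest::importance(m, type = 1, scale = FALSE)
    importance <- stats::setNames(as.numeric(imp), rownames(imp))
    details$ntree <- control$rf_ntree
  } else if (algorithm == "SVM") {
    st <- .standardize_fit(X)
    Xs <- .standardize_apply(X, st); Xts <- .standardize_apply(Xt, st)
    gamma <- 1 / (k * max(mean(apply(Xs, 2, stats::var)), 1e-12))
    m <- e1071::svm(x = Xs, y = y, kernel = "radial",
                    cost = control$svm_cost, gamma = gamma, scale = FALSE)
    pred <- unname(predict(m, Xts))
    predtr <- unname(predict(m, Xs))
    details$gamma <- gamma
  } else { # BPANN
    st <- .standardize_fit(X)
    Xs <- .standardize_apply(X, st); Xts <- .standardize_apply(Xt, st)
    ymu <- mean(y); ysd <- max(stats::sd(y), 1e-12)
    size <- max(1, min(control$ann_max_hidden,
                       floor(control$ann_weight_budget / (k + 2))))
    nw <- size * (k + 1) + size + 1
    m <- with_seed(seed, nnet::nnet(
      x = Xs, y = (y - ymu) / ysd, size = size, linout = TRUE,
      decay = control$ann_decay, maxit = control$ann_maxit,
      MaxNWts = nw + 10, trace = FALSE))
    pred <- as.numeric(predict(m, Xts)) * ysd + ymu
    predtr <- as.numeric(predict(m, Xs)) * ysd + ymu
    details$size <- size
  }
  if (!all(is.finite(pred)) || !all(is.finite(predtr))) {
    stop("numeric error: non-finite predictions from ", algorithm)
  }
  list(algorithm = algorithm, predictions = pred, train_predictions = predtr,
       importance = importance, details = details)
}

#' Seeded k-fold cross-validation of one algorithm
#'
#' Random (unstratified) fold assignment under `seed`; each fold is
#' predicted by a model fitted on the remaining folds, and the reported
#' `r2_cv`/`rmse_cv` are the means of the per-fold metrics. A fold whose
#' measured values are constant cannot yield an R-squared; it is excluded
#' from the R-squared mean with a warning (its RMSE still counts).
#'
#' @param algorithm algorithm label, see [fit_predict()]
#' @param table a `feature_table`
#' @param folds number of folds (default 10)
#' @param seed integer seed
#' @param control settings from [harness_control()]
#' @return list with `r2_cv`, `rmse_cv`, and per-fold vectors
#' @export
cross_validate <- function(algorithm, table, folds = 10, seed = 1,
                           control = harness_control()) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$values)
  if (n < folds) stop("precondition error: need at least `folds` samples")
  fid <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  r2f <- rmsef <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- fid != f
    tt <- feature_table(table$values[tr, , drop = FALSE], table$feature_names,
                        table$source, table$lpc[tr])
    te <- feature_table(table$values[!tr, , drop = FALSE], table$feature_names,
                        table$source, table$lpc[!tr])
    fp <- fit_predict(algorithm, tt, te, control, seed = seed + f)
    rmsef[f] <- rmse_metric(te$lpc, fp$predictions)
    if (stats::sd(te$lpc) > 0) {
      r2f[f] <- r2_metric(te$lpc, fp$predictions)
    } else {
      warning(sprintf("fold %d has constant measured values; excluded from R2 mean", f))
    }
  }
  list(r2_cv = mean(r2f, na.rm = TRUE), rmse_cv = mean(rmsef),
       r2_folds = r2f, rmse_folds = rmsef)
}

#' Run the full algorithm-by-feature-set matrix
#'
#' Builds the four feature tables (OR, SIs, CWT, SIs+CWT) for both splits
#' and runs all five algorithms on each, yielding 20 model reports. Each
#' report carries the training-set fit R-squared (`r2_cal_fit`; for
#' flexible learners such as RF this is optimistically high), the 10-fold
#' cross-validation means on the calibration set (`r2_cv`, `rmse_cv`),
#' held-out validation metrics, the residual-based AIC on validation
#' predictions, and Taylor-diagram statistics. Feature selection must
#' have been performed on the calibration set only (see
#' [run_pipeline()], which enforces this by construction).
#'
#' @param s_cal,s_val calibration and validation [spectrum_set()]s
#' @param si_features selected `index_features` (calibration-derived)
#' @param wavelet_features selected `wavelet_features` (calibration-derived)
#' @param control settings from [harness_control()]
#' @param seed integer seed driving every stochastic fit
#' @param cv run the 10-fold cross-validation (set `FALSE` to skip the
#'   CV columns when only validation metrics are needed)
#' @return data.frame of class `model_reports`, one row per
#'   algorithm x source, with RF importance vectors in
#'   `attr(, "importance")`
#' @export
run_matrix <- function(s_cal, s_val, si_features, wavelet_features,
                       control = harness_control(), seed = 1, cv = TRUE) {
  tables <- build_feature_tables(s_cal, s_val, si_features, wavelet_features)
  algorithms <- c("PLSR", "LASSO", "RF", "SVM", "BPANN")
  rows <- list()
  importance <- list()
  for (src in names(tables)) {
    tcal <- tables[[src]]$cal
    tval <- tables[[src]]$val
    for (alg in algorithms) {
      fp <- fit_predict(alg, tcal, tval, control, seed = seed)
      cvres <- if (cv) cross_validate(alg, tcal, control$cv_folds, seed, control)
               else list(r2_cv = NA_real_, rmse_cv = NA_real_)
      tp <- taylor_statistics(tval$lpc, fp$predictions, label = paste(alg, src, sep = "-"))
      k <- ncol(tcal$values)
      rows[[length(rows) + 1L]] <- data.frame(
        source = src, k = k, model = alg,
        r2_cal_fit = r2_metric(tcal$lpc, fp$train_predictions),
        r2_cv = cvres$r2_cv, rmse_cv = cvres$rmse_cv,
        r2_val = r2_metric(tval$lpc, fp$predictions),
        rmse_val = rmse_metric(tval$lpc, fp$predictions),
        aic = aic_metric(tval$lpc, fp$predictions, k, control$aic_variant),
        pearson_r = tp$pearson_r, std_ratio = tp$std_ratio,
        centered_rmsd = tp$centered_rmsd,
        n = nrow(tval$values)
      )
      if (alg == "RF") importance[[src]] <- fp$importance
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "importance") <- importance
  class(out) <- c("model_reports", "data.frame")
  out
}

#' Run the complete estimation pipeline on one dataset
#'
#' Orchestrates the full workflow: 70/30 split, all-pairs index scan and
#' top-k selection on the calibration set, full-grid CWT and per-scale
#' feature selection on the calibration set, then the 20-model harness.
#' Because every selection step sees only the calibration partition, the
#' validation metrics are leakage-free by construction.
#'
#' @param s a [spectrum_set()] with `lpc`
#' @param seed integer seed (split, folds and stochastic fits)
#' @param cal_fraction calibration fraction
#' @param k_si number of index features
#' @param min_separation_nm band-separation rule for index selection
#' @param si_step stride (nm) of the pair scan; 1 = full resolution
#' @param wavelet mother wavelet label
#' @param scales dyadic scale indices
#' @param control settings from [harness_control()]
#' @param cv run 10-fold CV inside the harness
#' @return list with `split`, `si_maps`, `si_features`,
#'   `wavelet_features`, `reports`
#' @export
run_pipeline <- function(s, seed = 1, cal_fraction = 0.7, k_si = 10,
                         min_separation_nm = 10, si_step = 1L,
                         wavelet = "mexh", scales = 1:10,
                         control = harness_control(), cv = TRUE) {
  sp <- split_dataset(s, cal_fraction, seed)
  maps <- lapply(c("RSI", "DSI", "NDSI"), function(it)
    pairwise_r2_map(sp$calibration, it, step = si_step))
  si <- select_top_index_features(maps, k = k_si, min_separation_nm = min_separation_nm)
  si <- fit_index_model(si, sp$calibration)
  cw <- cwt_transform(sp$calibration, wavelet, scales)
  sg <- scalogram_r2_map(cw, sp$calibration$lpc)
  wf <- select_per_scale_features(sg, cw, sp$calibration$lpc)
  reports <- run_matrix(sp$calibration, sp$validation, si, wf,
                        control = control, seed = seed, cv = cv)
  list(split = sp, si_maps = maps, si_features = si,
       wavelet_features = wf, scalogram = sg, reports = reports)
}

#' Write the model-report table as CSV
#'
#' @param reports a `model_reports` data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_model_report <- function(reports, path) {
  utils::write.csv(as.data.frame(reports), path, row.names = FALSE)
  invisible(path)
}
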