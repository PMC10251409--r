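#' Compute a two-band spectral index for every sample
#'
#' The three classical two-band formulations are supported:
#' \describe{
#'   \item{RSI}{ratio spectral index, `R_l1 / R_l2`}
#'   \item{DSI}{difference spectral index, `R_l1 - R_l2`}
#'   \item{NDSI}{normalized difference spectral index,
#'     `(R_l1 - R_l2) / (R_l1 + R_l2)`}
#' }
#'
#' @param s a [spectrum_set()]
#' @param index_type `"RSI"`, `"DSI"` or `"NDSI"`
#' @param lambda1_nm,lambda2_nm band wavelengths (nm), both on the grid
#' @return numeric vector, one index value per sample
#' @export
#' @examples
#' s <- spectrum_set(c(500:501), matrix(c(0.6, 0.2), 1, 2))
#' compute_index(s, "RSI", 500, 501)   # 3
#' compute_index(s, "NDSI", 500, 501)  # 0.5
compute_index <- function(s, index_type = c("RSI", "DSI", "NDSI"),
                          lambda1_nm, lambda2_nm) {
  stopifnot(inherits(s, "spectrum_set"))
  index_type <- match.arg(index_type)
  i1 <- match(as.integer(lambda1_nm), s$wavelengths)
  i2 <- match(as.integer(lambda2_nm), s$wavelengths)
  if (is.na(i1) || is.na(i2)) stop("bounds error: wavelengths must lie on the grid")
  r1 <- s$reflectance[, i1]
  r2 <- s$reflectance[, i2]
  if (index_type == "DSI") return(unname(r1 - r2))
  den <- if (index_type == "RSI") r2 else r1 + r2
  bad <- which(abs(den) < 1e-12)
  if (length(bad)) {
    stop(sprintf("numeric-degeneracy error: near-zero %s denominator for sample %s",
                 index_type, s$meta$id[bad[1]]))
  }
  if (index_type == "RSI") unname(r1 / r2) else unname((r1 - r2) / den)
}

new_score_map <- function(axis1, axis2, values, kind, label = NULL) {
  structure(list(axis1 = axis1, axis2 = axis2, values = values,
                 kind = kind, label = label),
            class = "score_map")
}

#' @export
print.score_map <- function(x, ...) {
  cat(sprintf("score_map [%s%s]: %d x %d, max R2 = %.4f (%d undefined cells)\n",
              x$kind, if (is.null(x$label)) "" else paste0(", ", x$label),
              nrow(x$values), ncol(x$values),
              suppressWarnings(max(x$values, na.rm = TRUE)), sum(is.na(x$values))))
  invisible(x)
}

#' All-pairs R-squared map for a two-band index
#'
#' For every ordered band pair (lambda1, lambda2), the squared Pearson
#' correlation between the index and LPC across samples -- identical to the
#' R-squared of the univariate OLS of LPC on the index. Diagonal cells and
#' cells where the index is constant (or has a near-zero denominator in any
#' sample) are undefined (`NA`) and rank last. Both triangles are retained:
#' the DSI and NDSI maps are symmetric, the RSI map is not (the reciprocal
#' index is a nonlinear transform).
#'
#' The DSI map is computed in closed form from centered cross-moments
#' (`cor(R1 - R2, y)` expands in the band covariance matrix); RSI and NDSI
#' have no such expansion and are scanned pairwise in compiled code.
#'
#' @param s a [spectrum_set()] with `lpc` and at least 3 samples
#' @param index_type `"RSI"`, `"DSI"` or `"NDSI"`
#' @param step optional stride (nm) over the grid for quick looks;
#'   1 scans the full grid.
#' @return a `score_map` with `kind = "pairwise-index"`; rows index
#'   lambda1, columns lambda2
#' @export
pairwise_r2_map <- function(s, index_type = c("RSI", "DSI", "NDSI"), step = 1L) {
  stopifnot(inherits(s, "spectrum_set"))
  index_type <- match.arg(index_type)
  if (is.null(s$lpc)) stop("precondition error: pairwise_r2_map requires lpc")
  if (nsamples(s) < 3) stop("precondition error: need at least 3 samples")
  keep <- seq(1L, length(s$wavelengths), by = as.integer(step))
  wl <- s$wavelengths[keep]
  X <- s$reflectance[, keep, drop = FALSE]
  y <- s$lpc
  n <- nrow(X)
  if (index_type == "DSI") {
    Xc <- sweep(X, 2, colMeans(X))
    yc <- y - mean(y)
    syy <- sum(yc^2)
    cvec <- as.numeric(crossprod(Xc, yc))       # n * cov(X_i, y)
    S <- crossprod(Xc)                           # n * cov(X_i, X_j)
    v <- diag(S)
    num <- outer(cvec, cvec, "-")^2
    den <- (outer(v, v, "+") - 2 * S) * syy
    vals <- num / den
    vals[!is.finite(vals)] <- NA_real_
    # constant-difference cells: variance of X_i - X_j numerically zero
    vv <- outer(v, v, "+") - 2 * S
    vals[vv <= 1e-12 * max(vv)] <- NA_real_
    vals[vals > 1] <- 1
    diag(vals) <- NA_real_
  } else {
    vals <- pair_r2_scan_cpp(X, y, if (index_type == "RSI") 0L else 1L)
  }
  dimnames(vals) <- list(as.character(wl), as.character(wl))
  new_score_map(wl, wl, vals, "pairwise-index", index_type)
}

#' Select the top band-pair index features across the three maps
#'
#' Pools every defined (index_type, lambda1, lambda2) cell across the
#' supplied maps, sorts by R-squared (descending; ties broken by smaller
#' lambda1, then smaller lambda2, then index order RSI < DSI < NDSI), and
#' greedily keeps a candidate only if, within the same index type, no
#' already-kept candidate has both bands (as an unordered pair) within
#' `min_separation_nm`. The separation rule prevents the selection from
#' returning k near-copies of one contour hot spot; mirrored duplicates of
#' the symmetric maps collapse onto one feature the same way.
#'
#' @param maps list of `score_map`s from [pairwise_r2_map()] (typically one
#'   per index type), computed on the calibration set
#' @param k number of features to return (default 10)
#' @param min_separation_nm minimum band separation within an index type
#' @return data.frame of class `index_features` with columns
#'   `index_type,lambda1_nm,lambda2_nm,r2_cal,slope,intercept` (model
#'   columns `NA` until [fit_index_model()])
#' @export
select_top_index_features <- function(maps, k = 10, min_separation_nm = 10) {
  if (inherits(maps, "score_map")) maps <- list(maps)
  stopifnot(k >= 1, all(vapply(maps, inherits, TRUE, "score_map")))
  type_order <- c(RSI = 1L, DSI = 2L, NDSI = 3L)
  cand <- do.call(rbind, lapply(maps, function(m) {
    v <- m$values
    ok <- which(!is.na(v), arr.ind = TRUE)
    if (!nrow(ok)) return(NULL)
    # keep a generous head per map; the greedy pass rarely digs deeper
    r2 <- v[ok]
    top <- order(-r2)[seq_len(min(length(r2), max(1000L, 200L * k)))]
    data.frame(index_type = m$label,
               lambda1_nm = m$axis1[ok[top, 1]],
               lambda2_nm = m$axis2[ok[top, 2]],
               r2_cal = r2[top])
  }))
  if (is.null(cand) || !nrow(cand)) stop("selection error: no defined cells in the maps")
  cand <- cand[order(-cand$r2_cal, cand$lambda1_nm, cand$lambda2_nm,
                     type_order[cand$index_type]), , drop = FALSE]
  lo <- pmin(cand$lambda1_nm, cand$lambda2_nm)
  hi <- pmax(cand$lambda1_nm, cand$lambda2_nm)
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    same <- kept[cand$index_type[kept] == cand$index_type[i]]
    if (length(same) &&
        any(abs(lo[same] - lo[i]) < min_separation_nm &
            abs(hi[same] - hi[i]) < min_separation_nm)) next
    kept <- c(kept, i)
    if (length(kept) == k) break
  }
  if (length(kept) < k) {
    warning(sprintf("only %d admissible index features (requested %d)", length(kept), k))
  }
  out <- cand[kept, , drop = FALSE]
  out$slope <- NA_real_
  out$intercept <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("index_features", "data.frame")
  out
}

#' Calibrate linear LPC models for index features
#'
#' Ordinary least squares of LPC on each index (`LPC = slope * index +
#' intercept`); `r2_cal` is the determination coefficient of the fitted
#' line's predictions on the calibration samples.
#'
#' @param features an `index_features` data.frame (or any data.frame with
#'   `index_type,lambda1_nm,lambda2_nm` columns)
#' @param s_cal calibration [spectrum_set()] with `lpc` (>= 3 samples)
#' @return `features` with `slope`, `intercept`, `r2_cal` filled
#' @export
fit_index_model <- function(features, s_cal) {
  stopifnot(inherits(s_cal, "spectrum_set"))
  if (is.null(s_cal$lpc)) stop("precondition error: fit_index_model requires lpc")
  if (nsamples(s_cal) < 3) stop("precondition error: need at least 3 calibration samples")
  for (i in seq_len(nrow(features))) {
    z <- compute_index(s_cal, features$index_type[i],
                       features$lambda1_nm[i], features$lambda2_nm[i])
    if (stats::sd(z) < 1e-12) {
      stop(sprintf("degeneracy error: constant %s(%d, %d) index",
                   features$index_type[i], features$lambda1_nm[i], features$lambda2_nm[i]))
    }
    fit <- stats::lm(s_cal$lpc ~ z)
    features$slope[i] <- unname(coef(fit)[2])
    features$intercept[i] <- unname(coef(fit)[1])
    features$r2_cal[i] <- r2_metric(s_cal$lpc, unname(fitted(fit)))
  }
  features
}

#' Export a score map as a CSV grid
#'
#' Rows are axis1 (lambda1 or scale), columns axis2; undefined cells are
#' written blank.
#'
#' @param map a `score_map`
#' @param path output path (a `.gz` suffix gzips the grid)
#' @return `path`, invisibly
#' @export
write_score_map <- function(map, path) {
  stopifnot(inherits(map, "score_map"))
  df <- as.data.frame(map$values)
  names(df) <- as.character(map$axis2)
  df <- cbind(axis1 = map$axis1, df)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}
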