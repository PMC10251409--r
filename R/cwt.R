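#' Mexican Hat mother wavelet
#'
#' The negative, normalized second derivative of a Gaussian,
#' `psi(u) = 2/(sqrt(3) * pi^(1/4)) * (1 - u^2) * exp(-u^2/2)`,
#' a zero-mean wavelet with two vanishing moments and unit L2 norm. It
#' acts on a spectrum as Gaussian smoothing followed by a second
#' derivative, which is what makes it effective at isolating absorption
#' features from broad continuum.
#'
#' @param u dimensionless offset (translation-centred, dilation-scaled)
#' @return wavelet amplitude at `u`
#' @export
#' @examples
#' mexh(0)            # 2/(sqrt(3) * pi^0.25)
#' mexh(c(-1, 1))     # roots at +-1
mexh <- function(u) {
  2 / (sqrt(3) * pi^0.25) * (1 - u^2) * exp(-u^2 / 2)
}

# probabilists' Hermite polynomial He_n(u), recurrence
.hermite <- function(u, n) {
  h0 <- rep(1, length(u))
  if (n == 0) return(h0)
  h1 <- u
  if (n == 1) return(h1)
  for (k in 2:n) {
    h2 <- u * h1 - (k - 1) * h0
    h0 <- h1; h1 <- h2
  }
  h1
}

#' Mother wavelet functions shipped with the package
#'
#' Returns the mother wavelet `psi(u)` by name. Available: `mexh` (Mexican
#' Hat, the default throughout), `gaus1`..`gaus4` (L2-normalized
#' derivatives of a Gaussian of order 1-4) and `morlet` (real part,
#' centre frequency 5). This configurable set supports screening several
#' wavelet bases with the same transform machinery.
#'
#' @param name wavelet label
#' @return a vectorized function of the dimensionless offset `u`
#' @export
wavelet_function <- function(name = c("mexh", "gaus1", "gaus2", "gaus3", "gaus4", "morlet")) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("configuration error: unknown wavelet '", name[1], "'"))
  if (name == "mexh") return(mexh)
  if (name == "morlet") {
    # real part of the Morlet wavelet, rescaled to unit L2 norm
    nrm <- sqrt((1 + exp(-25)) / 2)
    return(function(u) pi^(-0.25) * cos(5 * u) * exp(-u^2 / 2) / nrm)
  }
  ord <- as.integer(substring(name, 5))
  # d^n/du^n exp(-u^2/2) = (-1)^n He_n(u) exp(-u^2/2); L2-normalize numerically
  raw <- function(u) (-1)^ord * .hermite(u, ord) * exp(-u^2 / 2)
  nrm <- sqrt(stats::integrate(function(u) raw(u)^2, -Inf, Inf)$value)
  function(u) raw(u) / nrm
}

.sym_ext_idx <- function(p, P) {
  # symmetric (half-point, edge-repeating) extension indices for grid
  # positions 1-P .. p+P; period-2p reflection handles P > p
  pos <- (1L - P):(p + P)
  m <- (pos - 1L) %% (2L * p)
  ifelse(m < p, m + 1L, 2L * p - m)
}

#' Continuous wavelet transform of each spectrum
#'
#' Transforms every sample along the wavelength axis:
#' `C(a, b) = sum_l f(l) * psi((l - b) / s_a) / sqrt(s_a)` with dyadic
#' dilation `s_a = 2^a` nm (grid step 1 nm), evaluated at every grid
#' position `b`. Boundaries are handled by symmetric (reflect) padding of
#' length `8 * s_a` each side (periodic reflection when the pad exceeds
#' the signal), and the output is trimmed back to the original grid. All
#' samples and scales are batched through FFT convolution with a shared
#' pad, which matches the defining direct summation to machine precision.
#'
#' @param s a [spectrum_set()]
#' @param wavelet_name mother wavelet label, see [wavelet_function()]
#' @param scale_indices integer dyadic scale exponents (default 1:10,
#'   dilations 2..1024 nm)
#' @return an object of class `wavelet_coefficients`: list with
#'   `wavelengths`, `scale_indices`, `scale_dilations`, `wavelet` and
#'   `coefficients`, a sample x scale x wavelength array
#' @export
cwt_transform <- function(s, wavelet_name = "mexh", scale_indices = 1:10) {
  stopifnot(inherits(s, "spectrum_set"))
  scale_indices <- as.integer(scale_indices)
  if (any(scale_indices < 1)) stop("configuration error: scale indices must be >= 1")
  psi <- wavelet_function(wavelet_name)
  R <- s$reflectance
  n <- nrow(R); p <- ncol(R)
  dil <- 2L^scale_indices
  # pack pairs of real spectra into complex columns: the FFT pipeline is
  # linear and the kernel spectrum multiplies both, so Re/Im of the result
  # are the two samples' (real) coefficient tracks
  odd <- seq(1L, n, by = 2L)
  even <- if (n >= 2L) seq(2L, n, by = 2L) else integer(0)
  npair <- length(odd)

  out <- array(NA_real_, dim = c(n, length(scale_indices), p))
  for (si in seq_along(scale_indices)) {
    sc <- dil[si]
    Ps <- 8L * sc
    idx <- .sym_ext_idx(p, Ps)
    L <- p + 2L * Ps
    K <- 2L * Ps + 1L
    M <- stats::nextn(L + K - 1L, c(2L, 3L, 5L))
    Fp <- matrix(0i, M, npair)
    Fp[seq_len(L), ] <- t(R[odd, idx, drop = FALSE]) +
      (0+1i) * t(rbind(R[even, idx, drop = FALSE],
                       matrix(0, npair - length(even), L)))
    w <- psi(seq(-Ps, Ps) / sc) / sqrt(sc)
    kv <- numeric(M)
    kv[seq_len(K)] <- rev(w)
    G <- stats::mvfft(Fp) * stats::fft(kv)
    g <- stats::mvfft(G, inverse = TRUE) / M
    band <- g[2L * Ps + seq_len(p), , drop = FALSE]
    out[odd, si, ] <- t(Re(band))
    if (length(even)) out[even, si, ] <- t(Im(band[, seq_along(even), drop = FALSE]))
  }
  structure(list(wavelengths = s$wavelengths, scale_indices = scale_indices,
                 scale_dilations = dil, wavelet = wavelet_name,
                 coefficients = out),
            class = "wavelet_coefficients")
}

#' @export
print.wavelet_coefficients <- function(x, ...) {
  cat(sprintf("wavelet_coefficients [%s]: %d samples x %d scales (2^{%s}) x %d bands\n",
              x$wavelet, dim(x$coefficients)[1], length(x$scale_indices),
              paste(range(x$scale_indices), collapse = ".."),
              length(x$wavelengths)))
  invisible(x)
}

#' Wavelet coefficients at selected (wavelength, scale) locations
#'
#' Direct summation of the defining transform at arbitrary grid positions;
#' used to evaluate selected wavelet features on new spectra without a
#' full-grid transform. Identical (to machine precision) to the
#' corresponding cells of [cwt_transform()].
#'
#' @param s a [spectrum_set()]
#' @param wavelength_nm,scale_index equal-length vectors of feature
#'   locations
#' @param wavelet_name mother wavelet label
#' @return sample x feature matrix of coefficients
#' @export
cwt_at <- function(s, wavelength_nm, scale_index, wavelet_name = "mexh") {
  stopifnot(inherits(s, "spectrum_set"), length(wavelength_nm) == length(scale_index))
  psi <- wavelet_function(wavelet_name)
  p <- length(s$wavelengths)
  out <- matrix(NA_real_, nsamples(s), length(wavelength_nm))
  for (f in seq_along(wavelength_nm)) {
    b <- match(as.integer(wavelength_nm[f]), s$wavelengths)
    if (is.na(b)) stop("bounds error: feature wavelength off the grid")
    sc <- 2L^as.integer(scale_index[f])
    Ps <- 8L * sc
    w <- psi(seq(-Ps, Ps) / sc) / sqrt(sc)
    pos <- (b - Ps):(b + Ps)
    m <- (pos - 1L) %% (2L * p)
    idx <- ifelse(m < p, m + 1L, 2L * p - m)
    out[, f] <- s$reflectance[, idx, drop = FALSE] %*% w
  }
  out
}

#' Correlation scalogram between wavelet coefficients and LPC
#'
#' For each (scale, wavelength) cell, the squared Pearson correlation
#' between the coefficient across samples and LPC. Cells whose coefficient
#' is constant across samples are undefined (`NA`).
#'
#' @param coeffs a `wavelet_coefficients` object
#' @param lpc trait vector, one value per sample
#' @return a `score_map` with `kind = "scalogram"`; rows are scales,
#'   columns wavelengths
#' @export
scalogram_r2_map <- function(coeffs, lpc) {
  stopifnot(inherits(coeffs, "wavelet_coefficients"))
  n <- dim(coeffs$coefficients)[1]
  if (length(lpc) != n) stop("precondition error: sample counts differ")
  yc <- lpc - mean(lpc)
  syy <- sum(yc^2)
  ns <- length(coeffs$scale_indices)
  p <- length(coeffs$wavelengths)
  vals <- matrix(NA_real_, ns, p)
  for (si in seq_len(ns)) {
    Cm <- coeffs$coefficients[, si, ]
    Cc <- sweep(Cm, 2, colMeans(Cm))
    num <- as.numeric(crossprod(yc, Cc))^2
    den <- colSums(Cc^2) * syy
    r2 <- num / den
    r2[den <= 1e-300 | colSums(Cc^2) < 1e-24] <- NA_real_
    vals[si, ] <- pmin(r2, 1)
  }
  dimnames(vals) <- list(as.character(coeffs$scale_indices),
                         as.character(coeffs$wavelengths))
  new_score_map(coeffs$scale_indices, coeffs$wavelengths, vals, "scalogram",
                coeffs$wavelet)
}

#' Select the optimal wavelet feature on each scale
#'
#' Per scale, the wavelength with maximal scalogram R-squared (ties broken
#' by the smaller wavelength). With calibration data supplied, each
#' feature's linear LPC model (`LPC = slope * coefficient + intercept`) is
#' fitted by OLS.
#'
#' @param map a scalogram `score_map` from [scalogram_r2_map()]
#' @param coeffs optional `wavelet_coefficients` used to calibrate
#' @param lpc optional calibration trait values
#' @return data.frame of class `wavelet_features` with columns
#'   `wavelet,wavelength_nm,scale_index,scale_dilation,r2_cal,slope,intercept`
#' @export
select_per_scale_features <- function(map, coeffs = NULL, lpc = NULL) {
  stopifnot(inherits(map, "score_map"), map$kind == "scalogram")
  rows <- lapply(seq_along(map$axis1), function(si) {
    v <- map$values[si, ]
    if (all(is.na(v))) {
      warning(sprintf("scale %d has no defined scalogram cell; feature omitted", map$axis1[si]))
      return(NULL)
    }
    j <- which.max(v)  # first maximum = smallest wavelength on ties
    data.frame(wavelet = if (is.null(map$label)) "mexh" else map$label,
               wavelength_nm = map$axis2[j],
               scale_index = map$axis1[si],
               scale_dilation = 2^map$axis1[si],
               r2_cal = v[j], slope = NA_real_, intercept = NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(coeffs) && !is.null(lpc)) {
    for (i in seq_len(nrow(out))) {
      si <- match(out$scale_index[i], coeffs$scale_indices)
      z <- coeffs$coefficients[, si, match(out$wavelength_nm[i], coeffs$wavelengths)]
      fit <- stats::lm(lpc ~ z)
      out$slope[i] <- unname(coef(fit)[2])
      out$intercept[i] <- unname(coef(fit)[1])
      out$r2_cal[i] <- r2_metric(lpc, unname(fitted(fit)))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("wavelet_features", "data.frame")
  out
}
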