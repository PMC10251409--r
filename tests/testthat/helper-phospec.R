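# fixtures and independent oracles used across the suite

# small random spectrum set on an arbitrary contiguous grid
tiny_spectra <- function(n = 10, p = 8, wl_start = 500, seed = 1,
                         lpc = NULL, refl = NULL) {
  set.seed(seed)
  if (is.null(refl)) refl <- matrix(runif(n * p, 0.05, 0.65), n, p)
  if (is.null(lpc)) lpc <- runif(n, 0.5, 3.5)
  spectrum_set(wl_start + seq_len(p) - 1L, refl, lpc = lpc)
}

# brute-force all-pairs index R2: one univariate OLS per ordered pair
oracle_pair_r2 <- function(s, index_type) {
  p <- length(s$wavelengths)
  out <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    r1 <- s$reflectance[, i]; r2 <- s$reflectance[, j]
    z <- switch(index_type,
                RSI = r1 / r2, DSI = r1 - r2, NDSI = (r1 - r2) / (r1 + r2))
    if (sd(z) < 1e-12) next
    out[i, j] <- summary(lm(s$lpc ~ z))$r.squared
  }
  out
}

# direct-summation CWT with explicit symmetric (reflect) padding; the
# defining sum, no FFT
oracle_cwt <- function(f, scale_index, psi = mexh) {
  p <- length(f)
  sc <- 2^scale_index
  P <- 8L * sc
  pos <- (1L - P):(p + P)
  m <- (pos - 1L) %% (2L * p)
  fp <- f[ifelse(m < p, m + 1L, 2L * p - m)]
  w <- psi(seq(-P, P) / sc) / sqrt(sc)
  vapply(seq_len(p), function(b) sum(fp[b:(b + 2L * P)] * w), numeric(1))
}

# light harness settings for structural tests (not the scientific defaults)
light_control <- function() {
  harness_control(rf_ntree = 30, ann_maxit = 40, plsr_max_ncomp = 3,
                  lasso_lambda = 10^seq(0, -3, length.out = 20))
}

argmax_cell <- function(map) {
  am <- which(map$values == max(map$values, na.rm = TRUE), arr.ind = TRUE)[1, ]
  c(map$axis1[am[1]], map$axis2[am[2]])
}
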