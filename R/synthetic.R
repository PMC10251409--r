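#' Configuration for the synthetic leaf-spectra generator
#'
#' The generator emulates the statistical structure of greenhouse rice leaf
#' spectra under four phosphorus (P) supply levels: within-treatment LPC
#' means ordered P0 < P1 < P2 < P3, visible-region reflectance increasing
#' with P deficit (peak effect near 550 nm, the anthocyanin/pigment
#' signature), NIR reflectance increasing with LPC, no cultivar effect, and
#' a leaf-layer LPC effect only under the zero-P treatment. A planted,
#' exactly linear band-difference signal at `planted_pair` gives the
#' pipeline a known recoverable optimum.
#'
#' Two design points matter for recoverability. First, the visible and NIR
#' reflectance responses are multiplied by a per-sample lognormal amplitude
#' factor (`amp_jitter_sd`) emulating leaf-to-leaf structural variability;
#' without it the NIR response would be a deterministic function of LPC and
#' every band pair touching it would reach R-squared 1 in the noiseless
#' limit, making the planted optimum non-unique. Second, the planted signal
#' is applied antisymmetrically (+slope/2 at `planted_pair[1]`, -slope/2 at
#' `planted_pair[2]`) and the NIR plateau weight is symmetric about the
#' pair's midpoint, so the pair difference carries exactly
#' `planted_slope * lpc` while mirror pairs without the planted shift
#' cancel to a constant (flagged undefined by the scan) instead of tying.
#'
#' @param n_per_cell samples per (treatment x cultivar x layer) cell;
#'   19 gives the conventional 19 x 4 x 2 x 3 = 456 samples.
#' @param treatment_lpc_means four cell means (mg g-1), strictly increasing
#'   P0 < P1 < P2 < P3.
#' @param lpc_sd within-cell LPC standard deviation (mg g-1).
#' @param vis_gain visible-region reflectance increase per unit LPC deficit
#'   (fraction per mg g-1), Gaussian in wavelength around 550 nm.
#' @param nir_gain NIR reflectance increase per unit of the (saturating)
#'   phosphorus response (fraction per mg g-1) over the 750-1350 nm
#'   plateau. Reflectance responses to pigment/structure changes saturate,
#'   so both regions respond to `sat(x) = ref * (1 - exp(-x / ref))` of
#'   the spectrally active status rather than to it linearly
#'   (`ref` = the P3 mean).
#' @param planted_pair two distinct grid wavelengths (nm) whose reflectance
#'   difference carries the exact linear LPC signal.
#' @param planted_slope strength of the planted difference signal
#'   (reflectance fraction per mg g-1).
#' @param noise_sd additive i.i.d. Gaussian spectral noise (fraction).
#' @param layer_p0_drop LPC decrement per layer step (upper -> middle ->
#'   lower) applied under P0 only.
#' @param amp_jitter_sd lognormal sd of the per-sample amplitude factor on
#'   the visible and NIR responses (0 disables). One factor is shared by
#'   both responses.
#' @param trait_noise_sd sd (mg g-1) of the latent decoupling between
#'   assayed LPC and the spectrally active phosphorus status: the visible
#'   and NIR responses follow `lpc + N(0, trait_noise_sd)` rather than the
#'   assayed value itself. This bounds the trait correlation attainable
#'   from the pigment/structure responses, which is what keeps model
#'   skill on a realistic scale; the planted signal remains exact in the
#'   assayed LPC (0 disables).
#' @param seed integer seed; one global stream drives all draws.
#' @param wavelengths wavelength grid (nm).
#' @return a validated list of class `synthetic_config`
#' @export
synthetic_config <- function(n_per_cell = 19,
                             treatment_lpc_means = c(1.2, 1.9, 2.5, 3.0),
                             lpc_sd = 0.35,
                             vis_gain = 0.04,
                             nir_gain = 0.018,
                             planted_pair = c(1080, 1070),
                             planted_slope = 0.02,
                             noise_sd = 0.01,
                             layer_p0_drop = 0.15,
                             amp_jitter_sd = 0.25,
                             trait_noise_sd = 0.35,
                             seed = 42,
                             wavelengths = 350:2500) {
  cfg <- list(
    n_per_cell = as.integer(n_per_cell),
    treatment_lpc_means = as.numeric(treatment_lpc_means),
    lpc_sd = lpc_sd, vis_gain = vis_gain, nir_gain = nir_gain,
    planted_pair = as.integer(planted_pair), planted_slope = planted_slope,
    noise_sd = noise_sd, layer_p0_drop = layer_p0_drop,
    amp_jitter_sd = amp_jitter_sd, trait_noise_sd = trait_noise_sd,
    seed = as.integer(seed),
    wavelengths = as.integer(wavelengths)
  )
  if (cfg$n_per_cell < 1) stop("config error: n_per_cell must be >= 1")
  m <- cfg$treatment_lpc_means
  if (length(m) != 4 || any(diff(m) <= 0) || any(m <= 0)) {
    stop("config error: treatment_lpc_means must be four strictly increasing positive values")
  }
  if (cfg$noise_sd < 0) stop("config error: noise_sd must be >= 0")
  if (length(cfg$planted_pair) != 2 || cfg$planted_pair[1] == cfg$planted_pair[2] ||
      !all(cfg$planted_pair %in% cfg$wavelengths)) {
    stop("config error: planted_pair must be two distinct wavelengths on the grid")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Green-leaf baseline reflectance template
#'
#' Deterministic, piecewise-smooth template of a healthy green leaf
#' spectrum: a low visible plateau with a local maximum at 550 nm, a
#' monotone red-edge rise over 680-750 nm, a NIR plateau near 0.45-0.50
#' over 750-1350 nm, and water-absorption troughs centred at 1450 and
#' 1940 nm. Values lie strictly in (0, 1).
#'
#' @param wavelength_nm wavelengths in nm, each within \[350, 2500\]
#' @return reflectance fractions, same length as `wavelength_nm`
#' @export
#' @examples
#' baseline_reflectance(c(550, 680, 1000, 1450))
baseline_reflectance <- function(wavelength_nm) {
  w <- as.numeric(wavelength_nm)
  if (any(w < 350 | w > 2500)) stop("bounds error: wavelength outside [350, 2500] nm")
  logi <- function(x) 1 / (1 + exp(-x))
  0.05 +
    0.07 * exp(-((w - 550) / 35)^2) +         # green peak
    0.42 * logi((w - 715) / 15) -             # red edge up to the NIR plateau
    0.18 * exp(-((w - 1450) / 50)^2) -        # 1450 nm water trough
    0.28 * exp(-((w - 1940) / 60)^2) -        # 1940 nm water trough
    0.10 * logi((w - 1500) / 200) -           # gradual SWIR decline
    0.06 * logi((w - 2200) / 150)
}

#' Generate a synthetic leaf-spectra dataset
#'
#' Draws `n_per_cell` samples for every (treatment x cultivar x layer) cell
#' and assembles reflectance as baseline + visible deficit bump + NIR lift
#' + planted band-pair signal + i.i.d. Gaussian noise, clipped to
#' \[0.001, 0.999\]. LPC is drawn from the cell mean (treatment mean, minus
#' `layer_p0_drop` per layer step under P0 only) with sd `lpc_sd`,
#' truncated at 0.1 mg g-1. The visible bump amplitude is proportional to
#' `max(0, sat(P3_mean) - sat(lpc_eff))` (P3 is the sufficiency
#' reference), the NIR lift to `sat(lpc_eff)`, where `lpc_eff` is the
#' assayed LPC plus the latent trait-decoupling term and `sat()` the
#' saturating response of [synthetic_config()]; both are multiplied by
#' the shared per-sample amplitude factor. The planted band-pair signal
#' is exact in assayed LPC. The
#' same config and seed reproduce the dataset bitwise; the caller's RNG
#' state is left untouched.
#'
#' @param config a [synthetic_config()]
#' @return a [spectrum_set()] with `lpc` and metadata columns
#'   `cultivar` (C1/C2), `treatment` (P0-P3), `layer` (upper/middle/lower)
#' @export
#' @examples
#' s <- generate_dataset(synthetic_config(n_per_cell = 1))
#' nsamples(s)  # 24
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) config <- do.call(synthetic_config, config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  wl <- config$wavelengths
  p <- length(wl)
  cells <- expand.grid(
    rep = seq_len(config$n_per_cell),
    layer = c("upper", "middle", "lower"),
    cultivar = c("C1", "C2"),
    treatment = c("P0", "P1", "P2", "P3"),
    stringsAsFactors = FALSE
  )
  n <- nrow(cells)
  t_idx <- match(cells$treatment, c("P0", "P1", "P2", "P3"))
  l_idx <- match(cells$layer, c("upper", "middle", "lower")) - 1L
  mu <- config$treatment_lpc_means[t_idx] -
    ifelse(t_idx == 1L, config$layer_p0_drop * l_idx, 0)
  lpc <- pmax(0.1, stats::rnorm(n, mu, config$lpc_sd))

  # one structural amplitude factor per sample, shared by the visible and
  # NIR responses: a leaf's overall responsiveness varies, but a single
  # leaf does not respond strongly in one region and weakly in the other.
  # (Independent factors would let band-pair differences average the
  # jitter away and overtake the planted optimum.)
  jv <- if (config$amp_jitter_sd > 0) {
    exp(stats::rnorm(n, 0, config$amp_jitter_sd) - config$amp_jitter_sd^2 / 2)
  } else rep(1, n)
  jn <- jv
  # spectrally active P status: assayed LPC plus a latent decoupling term
  lpc_eff <- lpc + if (config$trait_noise_sd > 0) {
    stats::rnorm(n, 0, config$trait_noise_sd)
  } else 0

  base <- baseline_reflectance(wl)
  visprof <- exp(-0.5 * ((wl - 550) / 30)^2)
  mid <- mean(config$planted_pair)
  logi <- function(x) 1 / (1 + exp(-x))
  # plateau weight, exactly symmetric about the planted-pair midpoint
  wprof <- logi((wl - (mid - 290)) / 15) * logi(((mid + 290) - wl) / 15) *
    exp(-((wl - mid) / 600)^2)

  lpc_ref <- config$treatment_lpc_means[4]
  # saturating reflectance response to the spectrally active status
  sat <- function(x) lpc_ref * (1 - exp(-pmax(x, 0) / lpc_ref))
  s_eff <- sat(lpc_eff)
  deficit <- pmax(0, sat(lpc_ref) - s_eff)

  R <- rep(1, n) %o% base +
    (config$vis_gain * deficit * jv) %o% visprof +
    (config$nir_gain * s_eff * jn) %o% wprof
  i1 <- match(config$planted_pair[1], wl)
  i2 <- match(config$planted_pair[2], wl)
  R[, i1] <- R[, i1] + config$planted_slope / 2 * lpc
  R[, i2] <- R[, i2] - config$planted_slope / 2 * lpc
  if (config$noise_sd > 0) R <- R + matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)

  n_clip <- sum(R < 0.001 | R > 0.999)
  if (n_clip > 0) {
    message(sprintf("generate_dataset: clipped %d reflectance values to [0.001, 0.999]", n_clip))
    R <- pmin(pmax(R, 0.001), 0.999)
  }

  meta <- data.frame(
    id = sprintf("S%04d", seq_len(n)),
    cultivar = cells$cultivar, treatment = cells$treatment, layer = cells$layer,
    stringsAsFactors = FALSE
  )
  spectrum_set(wl, R, lpc = lpc, meta = meta)
}
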