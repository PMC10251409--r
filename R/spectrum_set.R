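#' Construct a spectrum set
#'
#' A `spectrum_set` bundles a sample-by-wavelength reflectance matrix with
#' its wavelength grid, an optional per-sample leaf phosphorus concentration
#' (LPC, mg g-1) and per-sample metadata. It is the exchange object passed
#' between every stage of the pipeline.
#'
#' Invariants enforced at construction: the wavelength grid is strictly
#' increasing with a uniform 1 nm step; reflectance values are finite
#' fractions in \[0, 1\] (a tolerance of 1e-6 is allowed on the bounds);
#' LPC values, when present, are finite and positive; all per-sample
#' components have one entry per reflectance row; sample ids are unique.
#'
#' @param wavelengths integer wavelengths in nm, strictly increasing, 1 nm
#'   step. The conventional full grid is 350:2500 (2151 bands).
#' @param reflectance numeric matrix, one row per sample, one column per
#'   wavelength, values in \[0, 1\]. Inputs on a percent scale (max > 1.5)
#'   are detected and divided by 100 with a warning.
#' @param lpc optional numeric vector of leaf phosphorus concentrations
#'   (mg g-1), one per sample; `NULL` for prediction-only sets.
#' @param meta optional data.frame of per-sample metadata. Recognised
#'   columns: `id`, `cultivar`, `treatment` (P0-P3), `layer`
#'   (upper/middle/lower). An `id` column is created when absent.
#' @return an object of class `spectrum_set` with elements `wavelengths`,
#'   `reflectance`, `lpc`, `meta`.
#' @export
#' @examples
#' s <- spectrum_set(400:409, matrix(0.3, 2, 10), lpc = c(1.5, 2.5))
#' nsamples(s)
spectrum_set <- function(wavelengths, reflectance, lpc = NULL, meta = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (anyNA(wavelengths) || any(wavelengths != round(wavelengths))) {
    stop("grid error: wavelengths must be integer nanometres (no resampling is performed)")
  }
  wavelengths <- as.integer(round(wavelengths))
  if (length(wavelengths) > 1) {
    d <- diff(wavelengths)
    if (any(d != 1L)) {
      stop("grid error: wavelengths must be strictly increasing with a uniform 1 nm step")
    }
  }
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (ncol(reflectance) != length(wavelengths)) {
    stop("shape error: ncol(reflectance) must equal length(wavelengths)")
  }
  if (!all(is.finite(reflectance))) stop("range error: reflectance contains non-finite values")
  if (max(reflectance) > 1.5) {
    warning("reflectance maximum exceeds 1.5; interpreting values as percent and dividing by 100")
    reflectance <- reflectance / 100
  }
  tol <- 1e-6
  if (min(reflectance) < -tol || max(reflectance) > 1 + tol) {
    stop("range error: reflectance outside [0, 1] beyond tolerance 1e-6")
  }
  n <- nrow(reflectance)
  if (!is.null(lpc)) {
    lpc <- as.numeric(lpc)
    if (length(lpc) != n) stop("shape error: length(lpc) must equal the number of samples")
    if (!all(is.finite(lpc)) || any(lpc <= 0)) {
      stop("range error: lpc values must be finite and > 0")
    }
  }
  if (is.null(meta)) meta <- data.frame(id = paste0("S", seq_len(n)))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop("shape error: nrow(meta) must equal the number of samples")
  if (is.null(meta$id)) meta$id <- paste0("S", seq_len(n))
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id)) stop("identity error: duplicate sample ids")
  dimnames(reflectance) <- list(meta$id, as.character(wavelengths))
  structure(
    list(wavelengths = wavelengths, reflectance = reflectance, lpc = lpc, meta = meta),
    class = "spectrum_set"
  )
}

#' Number of samples in a spectrum set
#' @param s a `spectrum_set`
#' @return integer sample count
#' @export
nsamples <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  nrow(s$reflectance)
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(
    "spectrum_set: %d samples x %d bands (%d-%d nm)%s\n",
    nrow(x$reflectance), length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths),
    if (is.null(x$lpc)) ", no LPC" else sprintf(", LPC %.2f-%.2f mg/g", min(x$lpc), max(x$lpc))
  ))
  extra <- setdiff(names(x$meta), "id")
  if (length(extra)) cat("metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a spectrum set to a wavelength window
#'
#' @param s a `spectrum_set`
#' @param lo_nm,hi_nm inclusive window bounds in nm; both must lie on the
#'   grid of `s`.
#' @return a `spectrum_set` restricted to wavelengths in `[lo_nm, hi_nm]`;
#'   LPC and metadata are carried over unchanged.
#' @export
#' @examples
#' s <- spectrum_set(350:2500, matrix(0.3, 1, 2151))
#' nir <- subset_bands(s, 750, 1350)  # 601 bands
subset_bands <- function(s, lo_nm, hi_nm) {
  stopifnot(inherits(s, "spectrum_set"))
  if (lo_nm > hi_nm) stop("bounds error: lo_nm must be <= hi_nm")
  if (!(lo_nm %in% s$wavelengths) || !(hi_nm %in% s$wavelengths)) {
    stop("bounds error: window bounds must lie on the wavelength grid")
  }
  keep <- s$wavelengths >= lo_nm & s$wavelengths <= hi_nm
  spectrum_set(s$wavelengths[keep], s$reflectance[, keep, drop = FALSE], s$lpc, s$meta)
}

.meta_cols <- c("id", "cultivar", "treatment", "layer")

#' Read a spectral dataset from CSV
#'
#' Two layouts are supported. `wide` (the primary exchange format): one row
#' per sample, wavelength columns headed by their nm value, plus any of the
#' trait/metadata columns `id`, `cultivar`, `treatment`, `layer`, `lpc`.
#' `long`: triples `id,wavelength_nm,reflectance`, optionally accompanied by
#' a trait table (`trait_path`) with columns `id` and any of
#' `cultivar,treatment,layer,lpc`.
#'
#' @param path CSV file path
#' @param layout `"wide"` or `"long"`
#' @param trait_path optional trait CSV for the long layout
#' @return a validated [spectrum_set()]
#' @export
read_spectra <- function(path, layout = c("wide", "long"), trait_path = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    is_wl <- grepl("^[0-9]+(\\.[0-9]+)?$", names(df))
    if (any(is_wl & grepl("\\.", names(df)))) {
      stop("grid error: fractional wavelength headers are rejected (no resampling)")
    }
    wl <- as.integer(names(df)[is_wl])
    ord <- order(wl)
    refl <- as.matrix(df[, which(is_wl)[ord], drop = FALSE])
    lpc <- if ("lpc" %in% names(df)) df$lpc else NULL
    meta <- df[, intersect(.meta_cols, names(df)), drop = FALSE]
    if (!ncol(meta)) meta <- NULL
    spectrum_set(wl[ord], refl, lpc = lpc, meta = meta)
  } else {
    need <- c("id", "wavelength_nm", "reflectance")
    if (!all(need %in% names(df))) {
      stop("layout error: long layout requires columns id, wavelength_nm, reflectance")
    }
    ids <- unique(df$id)
    wl <- sort(unique(as.integer(df$wavelength_nm)))
    m <- matrix(NA_real_, length(ids), length(wl),
                dimnames = list(ids, as.character(wl)))
    m[cbind(match(df$id, ids), match(as.integer(df$wavelength_nm), wl))] <- df$reflectance
    if (anyNA(m)) stop("layout error: long data do not form a complete sample x wavelength grid")
    lpc <- NULL
    meta <- data.frame(id = as.character(ids))
    if (!is.null(trait_path)) {
      tr <- utils::read.csv(trait_path, stringsAsFactors = FALSE)
      if (is.null(tr$id)) stop("layout error: trait table requires an id column")
      j <- match(ids, tr$id)
      if (anyNA(j)) stop("identity error: trait table is missing some sample ids")
      if ("lpc" %in% names(tr)) lpc <- tr$lpc[j]
      meta <- cbind(meta, tr[j, setdiff(intersect(.meta_cols, names(tr)), "id"), drop = FALSE])
    }
    spectrum_set(wl, m, lpc = lpc, meta = meta)
  }
}

#' Write a spectrum set to a wide CSV
#'
#' Column order is `id,cultivar,treatment,layer,lpc` (whichever are
#' present) followed by the wavelength columns in increasing nm. The file
#' round-trips through [read_spectra()] to within 1e-9 on reflectance and
#' exactly on metadata.
#'
#' @param s a `spectrum_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectrum_set"))
  meta <- s$meta[, intersect(.meta_cols, names(s$meta)), drop = FALSE]
  df <- meta
  if (!is.null(s$lpc)) df$lpc <- s$lpc
  refl <- as.data.frame(s$reflectance)
  names(refl) <- as.character(s$wavelengths)
  out <- cbind(df, refl)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  invisible(path)
}
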