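# Standard Raman preprocessing chain: iterative polynomial fluorescence
# baseline removal, threshold-gated median despiking, Savitzky-Golay
# smoothing, max normalization. Each step acts on one spectrum; cubes are
# processed pixel by pixel, independently.

#' Preprocessing configuration
#'
#' @param steps Ordered subset of `"baseline"`, `"despike"`, `"smooth"`,
#'   `"normalize"`; the default order follows the conventional chain.
#' @param poly_order Baseline polynomial degree (>= 1; default 5).
#' @param baseline_iters Clipped-refit iterations (default 20).
#' @param median_window Odd despiking window (default 5).
#' @param despike_k Robust threshold multiplier: a channel is a spike when it
#'   deviates from the running median by more than `k * MAD` (default 8).
#' @param sg_window,sg_order Savitzky-Golay window (odd, default 9) and
#'   polynomial order (default 3, must be < window).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(steps = c("baseline", "despike", "smooth", "normalize"),
                              poly_order = 5, baseline_iters = 20,
                              median_window = 5, despike_k = 8,
                              sg_window = 9, sg_order = 3) {
  if (length(steps) == 0) abort("`steps` must be nonempty")
  steps <- match.arg(steps, c("baseline", "despike", "smooth", "normalize"),
                     several.ok = TRUE)
  if (poly_order < 1) abort("`poly_order` must be >= 1")
  for (w in c(median_window, sg_window)) {
    if (w < 3 || w %% 2 == 0) abort("windows must be odd and >= 3")
  }
  if (sg_order >= sg_window) abort("`sg_order` must be < `sg_window`")
  structure(
    list(steps = steps, poly_order = poly_order, baseline_iters = baseline_iters,
         median_window = median_window, despike_k = despike_k,
         sg_window = sg_window, sg_order = sg_order),
    class = "preprocess_config"
  )
}

#' Iterative polynomial baseline removal
#'
#' Fits a degree-`poly_order` polynomial, then repeatedly clips the working
#' spectrum to the current fit (points above the fit are replaced by it) and
#' refits. Peaks are thereby excluded from the fit while the smooth
#' fluorescence background is tracked; the final fit is subtracted, so small
#' negatives may remain around noise.
#'
#' @param spectrum Numeric vector, length >= `poly_order + 2`.
#' @param poly_order Polynomial degree (>= 0; 0 removes a flat offset;
#'   default 5).
#' @param baseline_iters Clip-and-refit iterations (default 20).
#' @return Baseline-subtracted spectrum.
#' @export
remove_baseline <- function(spectrum, poly_order = 5, baseline_iters = 20) {
  n <- length(spectrum)
  if (n < poly_order + 2) abort("spectrum too short for the polynomial order")
  x <- seq(0, 1, length.out = n)
  X <- cbind(1, outer(x, seq_len(poly_order), "^"))
  work <- spectrum
  fit <- numeric(n)
  for (i in seq_len(max(1, baseline_iters))) {
    coef <- stats::lm.fit(X, work)$coefficients
    coef[is.na(coef)] <- 0
    fit <- drop(X %*% coef)
    work <- pmin(work, fit)
  }
  spectrum - fit
}

#' Threshold-gated median despiking
#'
#' Computes a running median and replaces only the channels whose deviation
#' from it exceeds `k * MAD` of the deviations; genuine (smooth) features pass
#' through untouched, single-channel cosmic-ray spikes are removed.
#'
#' @param spectrum Numeric vector.
#' @param median_window Odd window length, < spectrum length (default 5).
#' @param k Robust threshold multiplier (default 8).
#' @return Despiked spectrum.
#' @export
despike <- function(spectrum, median_window = 5, k = 8) {
  n <- length(spectrum)
  if (median_window %% 2 == 0 || median_window < 3) {
    abort("`median_window` must be odd and >= 3")
  }
  if (median_window >= n) abort("`median_window` must be smaller than the spectrum")
  med <- stats::runmed(spectrum, median_window, endrule = "median")
  dev <- spectrum - med
  # a running median reproduces many channels exactly (monotone stretches),
  # so the MAD over all deviations can degenerate to zero; fall back to the
  # MAD of the nonzero deviations before giving up
  scale <- stats::mad(dev)
  if (scale == 0 && any(dev != 0)) scale <- stats::mad(dev[dev != 0])
  if (scale == 0) scale <- .Machine$double.eps
  out <- spectrum
  spikes <- abs(dev) > k * scale
  out[spikes] <- med[spikes]
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing via [signal::sgolayfilt()]; a
#' polynomial of degree <= `sg_order` passes through unchanged, white noise is
#' contracted. Edges are handled by the filter's asymmetric polynomial fits
#' over the leading/trailing window.
#'
#' @param spectrum Numeric vector, longer than `sg_window`.
#' @param sg_window Odd window (default 9).
#' @param sg_order Polynomial order < window (default 3).
#' @return Smoothed spectrum.
#' @export
smooth_spectrum <- function(spectrum, sg_window = 9, sg_order = 3) {
  if (sg_window %% 2 == 0 || sg_window < 3) abort("`sg_window` must be odd and >= 3")
  if (sg_order >= sg_window) abort("`sg_order` must be < `sg_window`")
  if (length(spectrum) <= sg_window) abort("spectrum shorter than the window")
  as.numeric(signal::sgolayfilt(spectrum, p = sg_order, n = sg_window))
}

#' Max normalization
#'
#' Divides by the spectrum maximum so the highest channel equals exactly 1;
#' scale-invariant and idempotent. Rejects non-positive maxima.
#'
#' @param spectrum Numeric vector with `max(spectrum) > 0`.
#' @return Normalized spectrum.
#' @export
normalize_max <- function(spectrum) {
  m <- max(spectrum)
  if (!is.finite(m) || m <= 0) abort("spectrum maximum must be positive")
  spectrum / m
}

apply_steps <- function(spectrum, config) {
  for (s in config$steps) {
    spectrum <- switch(s,
      baseline = remove_baseline(spectrum, config$poly_order, config$baseline_iters),
      despike = despike(spectrum, config$median_window, config$despike_k),
      smooth = smooth_spectrum(spectrum, config$sg_window, config$sg_order),
      normalize = normalize_max(spectrum)
    )
  }
  spectrum
}

#' Preprocess every pixel spectrum of a cube
#'
#' Applies the configured steps, in order, independently per pixel, and
#' records the configuration in the cube metadata. Requires a fully observed
#' cube (complete first).
#'
#' @param cube A [hyper_cube()] without missing entries.
#' @param config A [preprocess_config()].
#' @return The preprocessed [hyper_cube()].
#' @export
preprocess_cube <- function(cube, config = preprocess_config()) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (!is.null(cube$observed) && !all(cube$observed)) {
    abort("cube has missing entries; run complete_cube() first")
  }
  out <- cube$intensities
  for (p in seq_len(nrow(out))) {
    res <- tryCatch(apply_steps(out[p, ], config), error = function(e) e)
    if (inherits(res, "error")) {
      abort(sprintf("preprocessing failed at pixel (row %d, col %d): %s",
                    pixel_rows(cube)[p], pixel_cols(cube)[p],
                    conditionMessage(res)))
    }
    out[p, ] <- res
  }
  hyper_cube(out, cube$axis, cube$dims,
             meta = c(cube$meta, list(preprocess_steps = paste(config$steps, collapse = ","))))
}

#' Preprocess a flat spectra matrix
#'
#' Convenience wrapper applying the same chain to each row of a matrix.
#'
#' @param spectra `n x L` matrix (rows are spectra).
#' @param config A [preprocess_config()].
#' @return Matrix of the same shape.
#' @export
preprocess_spectra <- function(spectra, config = preprocess_config()) {
  t(apply(spectra, 1, apply_steps, config = config))
}
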