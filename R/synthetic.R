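# Synthetic Raman scene generators.
#
# Every generator is seeded and deterministic: identical arguments (including
# the seed) give byte-identical output. Noiseless signal components are
# nonnegative by construction, and with noise and baseline switched off the
# pixels x wavenumbers matrix has numerical rank equal to the number of
# distinct endmembers present — the low-rank premise the completion engine
# relies on.

# Smooth fluorescence-like baseline: degree-3 polynomial in x in [0, 1],
# shifted to be nonnegative. `coefs` is a length-4 vector.
eval_baseline_poly <- function(coefs, L) {
  x <- seq(0, 1, length.out = L)
  b <- coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3
  m <- min(b)
  if (m < 0) b <- b - m
  b
}

random_baseline_coefs <- function() {
  c(runif(1, 0.5, 1), runif(3, -0.5, 0.5))
}

# Shared renderer: class map + endmembers -> noisy cube. Shot-like noise has
# standard deviation noise_sd * sqrt(total noiseless intensity), so spectra
# sitting on a large fluorescence background are proportionally noisier.
render_scene <- function(class_map, endmembers, axis, baseline_amplitude,
                         noise_sd, shot_noise, seed, meta = list()) {
  dims <- dim(class_map)
  labels <- as.vector(t(class_map)) # row-major pixel order
  L <- length(axis)
  pure <- t(vapply(endmembers, make_endmember_spectrum, numeric(L), axis = axis))
  signal <- pure[labels, , drop = FALSE]
  withr::with_seed(seed, {
    if (baseline_amplitude > 0) {
      base <- t(vapply(seq_along(labels), function(i) {
        baseline_amplitude * eval_baseline_poly(random_baseline_coefs(), L)
      }, numeric(L)))
      signal <- signal + base
    }
    noise <- matrix(rnorm(length(signal), sd = noise_sd), nrow = nrow(signal))
    if (shot_noise) {
      noise <- noise + matrix(rnorm(length(signal)), nrow = nrow(signal)) *
        noise_sd * sqrt(pmax(signal, 0))
    }
    intens <- signal + noise
  })
  hyper_cube(intens, axis, dims,
             meta = c(meta, list(
               classes = names(endmembers),
               baseline_amplitude = baseline_amplitude,
               noise_sd = noise_sd, shot_noise = shot_noise, seed = seed
             )))
}

#' Two-component concentration mixture series
#'
#' Emulates a hydration-phantom calibration set: replicate spectra of
#' water/solute mixtures at known water fractions (percent by weight).
#' Each spectrum is `f/100 * water + (1 - f/100) * solute`, plus an optional
#' smooth baseline of fixed shape with a random per-spectrum amplitude
#' (adding one to the chemical rank) and i.i.d. Gaussian noise. Replicates at
#' the same fraction differ only by their noise and baseline draw.
#'
#' @param fractions Water fractions in percent, each in (0, 100]. The default
#'   sweeps 60-80% in 2% steps, the physiological hydration range.
#' @param n_replicates Spectra per fraction (>= 2; default 10, enough for a
#'   per-concentration coefficient of variation).
#' @param axis A [wavenumber_axis()].
#' @param endmembers List with elements `water` and `solute`
#'   (see [default_mixture_endmembers()]).
#' @param noise_sd Additive Gaussian noise sd (intensity units where peak
#'   amplitudes are ~1).
#' @param baseline_amplitude Scale of the smooth baseline; 0 disables it.
#' @param seed Integer seed.
#' @return A `concentration_dataset`: list with `spectra`
#'   (`n x L` matrix), `fractions` (per spectrum), `axis`,
#'   `truth_endmembers`, `seed`.
#' @examples
#' ds <- make_mixture_series(fractions = c(60, 70, 80), n_replicates = 3,
#'                           noise_sd = 0, baseline_amplitude = 0, seed = 1)
#' dim(ds$spectra)
#' @export
make_mixture_series <- function(fractions = seq(60, 80, by = 2),
                                n_replicates = 10,
                                axis = wavenumber_axis(),
                                endmembers = default_mixture_endmembers(),
                                noise_sd = 0.01,
                                baseline_amplitude = 0.05,
                                seed = 1) {
  if (any(fractions <= 0 | fractions > 100)) {
    abort("all fractions must lie in (0, 100] percent")
  }
  if (length(unique(fractions)) < 2) {
    abort("need at least 2 distinct concentrations")
  }
  if (n_replicates < 2) {
    abort("need at least 2 replicates per concentration")
  }
  if (!all(c("water", "solute") %in% names(endmembers))) {
    abort("`endmembers` must contain `water` and `solute`")
  }
  L <- length(axis)
  water <- make_endmember_spectrum(endmembers$water, axis)
  solute <- make_endmember_spectrum(endmembers$solute, axis)
  # fixed baseline shape; only its amplitude varies per spectrum (rank + 1)
  bshape <- eval_baseline_poly(c(0.6, 0.4, -0.3, 0.4), L)
  f_all <- rep(fractions, each = n_replicates)
  spectra <- withr::with_seed(seed, {
    t(vapply(f_all, function(f) {
      s <- (f / 100) * water + (1 - f / 100) * solute
      if (baseline_amplitude > 0) {
        s <- s + baseline_amplitude * runif(1, 0.5, 1.5) * bshape
      }
      s + rnorm(L, sd = noise_sd)
    }, numeric(L)))
  })
  structure(
    list(spectra = spectra, fractions = f_all, axis = axis,
         truth_endmembers = endmembers, seed = seed),
    class = "concentration_dataset"
  )
}

#' @export
print.concentration_dataset <- function(x, ...) {
  cat(sprintf("<concentration_dataset> %d spectra, %d levels (%g-%g%% water), %d channels\n",
              nrow(x$spectra), length(unique(x$fractions)),
              min(x$fractions), max(x$fractions), ncol(x$spectra)))
  invisible(x)
}

# Elliptical cell body mask used by the cell scene
ellipse_mask <- function(dims, rx = 0.40, ry = 0.42) {
  r <- matrix(rep(seq_len(dims[1]), dims[2]), nrow = dims[1])
  c_ <- matrix(rep(seq_len(dims[2]), each = dims[1]), nrow = dims[1])
  cr <- (dims[1] + 1) / 2
  cc <- (dims[2] + 1) / 2
  ((r - cr) / (dims[1] * ry))^2 + ((c_ - cc) / (dims[2] * rx))^2 <= 1
}

# Grow `n_target` contiguous pixels from `n_blobs` random seeds inside the
# allowed region. Returns a logical matrix.
grow_blobs <- function(allowed, n_target, n_blobs) {
  dims <- dim(allowed)
  idx_allowed <- which(allowed)
  blob <- matrix(FALSE, dims[1], dims[2])
  seeds <- sample(idx_allowed, min(n_blobs, n_target))
  blob[seeds] <- TRUE
  neighbours <- function(i) {
    r <- ((i - 1) %% dims[1]) + 1
    c_ <- ((i - 1) %/% dims[1]) + 1
    cand <- c(
      if (r > 1) i - 1, if (r < dims[1]) i + 1,
      if (c_ > 1) i - dims[1], if (c_ < dims[2]) i + dims[1]
    )
    cand
  }
  while (sum(blob) < n_target) {
    frontier <- setdiff(unique(unlist(lapply(which(blob), neighbours))),
                        which(blob))
    frontier <- frontier[allowed[frontier]]
    if (length(frontier) == 0) { # region exhausted; spill anywhere allowed
      frontier <- setdiff(idx_allowed, which(blob))
    }
    take <- sample(frontier, 1)
    blob[take] <- TRUE
  }
  blob
}

#' Synthetic cell scene with a rare drug component
#'
#' A background / cytoplasm / drug scene: an elliptical cell body on a clean
#' background, with the drug confined to a few contiguous blobs inside the
#' cytoplasm covering `rare_fraction` percent of all pixels (within one pixel
#' of rounding). Only the drug endmember carries the diagnostic peak at
#' `drug_peak_center` (1168 cm^-1 by default), so peak-based detection has an
#' exact ground truth.
#'
#' @param dims Grid `c(rows, cols)`; default `c(32, 36)`.
#' @param rare_fraction Drug prevalence in percent of all pixels, in (0, 20].
#' @param drug_peak_center Diagnostic drug peak position (cm^-1).
#' @param axis,endmembers,noise_sd,baseline_amplitude,seed See
#'   [make_mixture_series()]; endmembers must be named `background`,
#'   `cytoplasm`, `drug`.
#' @param shot_noise Add signal-proportional noise on top of the additive term.
#' @param n_blobs Number of drug blob seeds (default 3).
#' @return List with `cube` (a [hyper_cube()]) and `labels` (integer matrix,
#'   1 = background, 2 = cytoplasm, 3 = drug).
#' @export
make_cell_scene <- function(dims = c(32, 36), rare_fraction = 3,
                            drug_peak_center = 1168,
                            axis = wavenumber_axis(),
                            endmembers = default_cell_endmembers(),
                            noise_sd = 0.04, baseline_amplitude = 1,
                            shot_noise = FALSE, n_blobs = 3, seed = 1) {
  if (rare_fraction <= 0 || rare_fraction > 20) {
    abort("`rare_fraction` must be in (0, 20] percent")
  }
  if (!all(c("background", "cytoplasm", "drug") %in% names(endmembers))) {
    abort("cell endmembers must be named background, cytoplasm, drug")
  }
  drug_peaks <- endmembers$drug$peaks$center
  if (min(abs(drug_peaks - drug_peak_center)) > 2) {
    abort(sprintf("drug endmember has no peak at %g cm^-1", drug_peak_center))
  }
  other_peaks <- c(endmembers$background$peaks$center,
                   endmembers$cytoplasm$peaks$center)
  if (any(abs(other_peaks - drug_peak_center) < 20)) {
    abort("non-drug endmembers must not have a peak near the drug marker")
  }
  dims <- as.integer(dims)
  n_total <- prod(dims)
  n_drug <- max(1L, round(rare_fraction / 100 * n_total))
  cell <- ellipse_mask(dims)
  if (n_drug > sum(cell)) {
    abort("requested drug pixels exceed the cytoplasm area")
  }
  labels <- withr::with_seed(seed, {
    lab <- matrix(1L, dims[1], dims[2])
    lab[cell] <- 2L
    drug <- grow_blobs(cell, n_drug, n_blobs)
    lab[drug] <- 3L
    lab
  })
  em <- endmembers[c("background", "cytoplasm", "drug")]
  cube <- render_scene(labels, em, axis, baseline_amplitude, noise_sd,
                       shot_noise, seed = seed + 1L,
                       meta = list(scene = "cell", rare_fraction = rare_fraction,
                                   drug_peak_center = drug_peak_center))
  list(cube = cube, labels = labels)
}

#' Synthetic layered tissue scene
#'
#' Three horizontal tissue layers (background, gray-matter-like,
#' white-matter-like) with wavy boundaries, sitting on a large smooth
#' per-pixel fluorescence baseline (random cubic polynomial, amplitude
#' `baseline_amplitude` — set it ~10x the peak scale to emulate raw
#' autofluorescence-dominated spectra) plus additive and shot-like noise.
#'
#' @param dims Grid `c(rows, cols)`; the default `c(16, 36)` is a scaled-down
#'   test geometry, `c(65, 145)` the full study geometry.
#' @param axis,endmembers,noise_sd,seed As elsewhere; endmembers must have
#'   exactly 3 components.
#' @param baseline_amplitude Fluorescence baseline scale; default 10.
#' @param shot_noise Default `TRUE`.
#' @return List with `cube` and `labels` (1..3 integer matrix).
#' @export
make_tissue_scene <- function(dims = c(16, 36),
                              axis = wavenumber_axis(),
                              endmembers = default_tissue_endmembers(),
                              noise_sd = 0.02, baseline_amplitude = 10,
                              shot_noise = TRUE, seed = 1) {
  if (length(endmembers) != 3) {
    abort("the tissue scene needs exactly 3 endmember classes")
  }
  dims <- as.integer(dims)
  labels <- withr::with_seed(seed, {
    phase <- runif(2, 0, 2 * pi)
    amp <- 0.08 * dims[1]
    cols <- seq_len(dims[2])
    b1 <- dims[1] / 3 + amp * sin(2 * pi * 1.5 * cols / dims[2] + phase[1])
    b2 <- 2 * dims[1] / 3 + amp * sin(2 * pi * 1.5 * cols / dims[2] + phase[2])
    lab <- matrix(1L, dims[1], dims[2])
    for (cc in cols) {
      lab[, cc] <- ifelse(seq_len(dims[1]) < b1[cc], 1L,
                          ifelse(seq_len(dims[1]) < b2[cc], 2L, 3L))
    }
    lab
  })
  cube <- render_scene(labels, endmembers, axis, baseline_amplitude, noise_sd,
                       shot_noise, seed = seed + 1L,
                       meta = list(scene = "tissue"))
  list(cube = cube, labels = labels)
}

#' Add single-channel cosmic-ray-like spikes
#'
#' Each pixel independently receives (with probability `spike_rate`) one
#' positive spike of height `amplitude` at a random single channel —
#' the artifact median despiking exists to remove.
#'
#' @param cube A [hyper_cube()].
#' @param spike_rate Per-pixel spike probability in `[0, 1]`.
#' @param amplitude Spike height (> 0).
#' @param seed Integer seed.
#' @return The cube with spikes added; `spike_rate = 0` returns it unchanged.
#' @export
add_spikes <- function(cube, spike_rate, amplitude, seed = 1) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (amplitude <= 0) abort("spike `amplitude` must be positive")
  if (spike_rate < 0 || spike_rate > 1) abort("`spike_rate` must be in [0, 1]")
  if (spike_rate == 0) return(cube)
  L <- length(cube$axis)
  withr::with_seed(seed, {
    hit <- runif(n_pixels(cube)) < spike_rate
    channels <- sample.int(L, n_pixels(cube), replace = TRUE)
    for (p in which(hit)) {
      cube$intensities[p, channels[p]] <- cube$intensities[p, channels[p]] + amplitude
    }
  })
  cube$meta$spike_rate <- spike_rate
  cube
}
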