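#' Wavenumber axis
#'
#' A strictly increasing grid of Raman shifts (cm^-1) shared by every spectrum
#' in a dataset. The default covers the biological fingerprint region.
#'
#' @param values Numeric vector of wavenumber positions in cm^-1, strictly
#'   increasing, length >= 16, all finite.
#' @return A numeric vector of class `wavenumber_axis`.
#' @examples
#' ax <- wavenumber_axis()
#' range(ax)
#' @export
wavenumber_axis <- function(values = seq(600, 1800, length.out = 300)) {
  values <- as.numeric(values)
  if (length(values) < 16) {
    abort("a wavenumber axis needs at least 16 channels")
  }
  if (any(!is.finite(values))) {
    abort("wavenumber axis values must all be finite")
  }
  if (any(diff(values) <= 0)) {
    abort("wavenumber axis must be strictly increasing")
  }
  structure(values, class = "wavenumber_axis")
}

#' Pure-component endmember spectrum description
#'
#' An endmember is a pure chemical component described as a sum of peaks
#' (Lorentzian by default, the natural Raman lineshape; Gaussian available).
#' Mixtures of a few endmembers are what makes a hyperspectral Raman matrix
#' low-rank.
#'
#' @param name Label for the component.
#' @param peaks Data frame (or tibble) with columns `center` (cm^-1),
#'   `width` (full width at half maximum, cm^-1, > 0) and `amplitude` (>= 0).
#'   At least one peak.
#' @param profile Peak shape, `"lorentzian"` (default) or `"gaussian"`.
#' @return An object of class `endmember`.
#' @examples
#' em <- endmember("phenylalanine-like",
#'                 peaks = data.frame(center = 1003, width = 12, amplitude = 1))
#' @export
endmember <- function(name, peaks, profile = c("lorentzian", "gaussian")) {
  profile <- match.arg(profile)
  peaks <- as_tibble(peaks)
  required <- c("center", "width", "amplitude")
  if (!all(required %in% names(peaks))) {
    abort("`peaks` needs columns center, width, amplitude")
  }
  if (nrow(peaks) < 1) {
    abort("an endmember needs at least one peak")
  }
  if (any(peaks$width <= 0)) {
    abort("peak widths must be positive")
  }
  if (any(peaks$amplitude < 0)) {
    abort("peak amplitudes must be nonnegative")
  }
  structure(
    list(name = name, peaks = peaks, profile = profile),
    class = "endmember"
  )
}

#' Evaluate an endmember on a wavenumber axis
#'
#' Sums the declared peak profiles over the axis. Deterministic and
#' nonnegative; every peak center must lie inside the axis range.
#'
#' @param em An [endmember()].
#' @param axis A [wavenumber_axis()].
#' @return Numeric vector of length `length(axis)`.
#' @examples
#' em <- endmember("demo", data.frame(center = 1000, width = 20, amplitude = 2))
#' s <- make_endmember_spectrum(em, wavenumber_axis())
#' max(s)
#' @export
make_endmember_spectrum <- function(em, axis) {
  stopifnot(inherits(em, "endmember"))
  axis <- as.numeric(axis)
  rng <- range(axis)
  if (any(em$peaks$center < rng[1] | em$peaks$center > rng[2])) {
    abort(sprintf("endmember '%s' has a peak center outside the axis range [%g, %g]",
                  em$name, rng[1], rng[2]))
  }
  out <- numeric(length(axis))
  for (i in seq_len(nrow(em$peaks))) {
    p <- em$peaks[i, ]
    if (em$profile == "lorentzian") {
      # FWHM parameterization: gamma is the half width at half maximum
      gam <- p$width / 2
      out <- out + p$amplitude * gam^2 / ((axis - p$center)^2 + gam^2)
    } else {
      sigma <- p$width / (2 * sqrt(2 * log(2)))
      out <- out + p$amplitude * exp(-((axis - p$center)^2) / (2 * sigma^2))
    }
  }
  out
}

# Built-in endmember libraries ------------------------------------------------

#' Default endmember sets used by the synthetic generators
#'
#' `default_mixture_endmembers()` returns a water-like and a protein-like
#' (BSA-style) component for the hydration mixture series.
#' `default_cell_endmembers()` returns background / cytoplasm / drug
#' components; only the drug carries the distinctive 1168 cm^-1 peak.
#' `default_tissue_endmembers()` returns background / gray-matter-like /
#' white-matter-like components with contrasting protein and lipid bands.
#'
#' Peak positions are placed at familiar Raman bands (1003 cm^-1 ring breathing,
#' 1440-1450 cm^-1 CH2 deformation, 1657 cm^-1 amide I, 1640 cm^-1 water
#' bending) but are generic stand-ins, not fits to any measured spectrum.
#'
#' @return A named list of [endmember()] objects.
#' @export
default_mixture_endmembers <- function() {
  list(
    water = endmember("water", tibble(
      center = c(1640),
      width = c(90),
      amplitude = c(1)
    )),
    solute = endmember("protein", tibble(
      center = c(1003, 1250, 1450, 1657),
      width = c(14, 60, 35, 45),
      amplitude = c(1, 0.45, 0.8, 0.9)
    ))
  )
}

#' @rdname default_mixture_endmembers
#' @export
default_cell_endmembers <- function() {
  list(
    background = endmember("background", tibble(
      center = c(950, 1600),
      width = c(160, 180),
      amplitude = c(0.3, 0.15)
    )),
    cytoplasm = endmember("cytoplasm", tibble(
      center = c(1003, 1093, 1300, 1450, 1657),
      width = c(14, 30, 40, 35, 45),
      amplitude = c(0.9, 0.4, 0.5, 0.8, 0.85)
    )),
    drug = endmember("drug", tibble(
      center = c(1168, 1410, 1003),
      width = c(16, 30, 14),
      amplitude = c(1.5, 0.5, 0.3)
    ))
  )
}

#' @rdname default_mixture_endmembers
#' @export
default_tissue_endmembers <- function() {
  list(
    background = endmember("background", tibble(
      center = c(1080, 1590),
      width = c(200, 160),
      amplitude = c(0.25, 0.12)
    )),
    gray_matter = endmember("gray_matter", tibble(
      center = c(1003, 1240, 1450, 1657),
      width = c(14, 55, 35, 45),
      amplitude = c(0.8, 0.5, 0.6, 1)
    )),
    white_matter = endmember("white_matter", tibble(
      center = c(1065, 1130, 1300, 1440, 1657),
      width = c(25, 25, 30, 30, 45),
      amplitude = c(0.5, 0.45, 0.8, 1, 0.55)
    ))
  )
}
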