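#' Hyperspectral Raman cube
#'
#' A spatial grid of spectra sharing one wavenumber axis. Internally the
#' intensities are a `(rows * cols) x L` matrix with pixels linearized
#' row-major over `(row, col)` — rows are pixels, columns are wavenumbers,
#' so chemically sparse scenes are low-rank in this orientation. Entries may
#' carry an observed/missing flag (see [apply_mask()]); missing intensities
#' are stored as `NA`.
#'
#' @param intensities Numeric matrix, `n_pixels x length(axis)`.
#' @param axis A [wavenumber_axis()].
#' @param dims Integer `c(rows, cols)` with `rows * cols == nrow(intensities)`.
#' @param observed Optional logical matrix of the same shape as `intensities`;
#'   `NULL` means fully observed.
#' @param meta Named list of free-form metadata.
#' @return An object of class `hyper_cube`.
#' @export
hyper_cube <- function(intensities, axis, dims, observed = NULL, meta = list()) {
  intensities <- as.matrix(intensities)
  dimnames(intensities) <- NULL
  axis <- wavenumber_axis(as.numeric(axis))
  dims <- as.integer(dims)
  if (length(dims) != 2 || any(dims < 1)) {
    abort("`dims` must be two positive integers (rows, cols)")
  }
  if (prod(dims) != nrow(intensities)) {
    abort(sprintf("grid %d x %d does not match %d pixel rows",
                  dims[1], dims[2], nrow(intensities)))
  }
  if (ncol(intensities) != length(axis)) {
    abort("intensity columns must match the axis length")
  }
  if (!is.null(observed)) {
    observed <- as.matrix(observed)
    dimnames(observed) <- NULL
    if (!identical(dim(observed), dim(intensities))) {
      abort("`observed` must have the same shape as `intensities`")
    }
    storage.mode(observed) <- "logical"
    if (any(!is.finite(intensities[observed]))) {
      abort("observed intensities must be finite")
    }
  } else if (any(!is.finite(intensities))) {
    abort("intensities must be finite (use `observed` to flag missing entries)")
  }
  structure(
    list(intensities = intensities, axis = axis, dims = dims,
         observed = observed, meta = meta),
    class = "hyper_cube"
  )
}

#' @export
print.hyper_cube <- function(x, ...) {
  cat(sprintf("<hyper_cube> %d x %d pixels, %d wavenumbers [%g, %g] cm^-1\n",
              x$dims[1], x$dims[2], length(x$axis),
              min(x$axis), max(x$axis)))
  if (!is.null(x$observed)) {
    cat(sprintf("  sparse: %.1f%% of entries missing\n",
                100 * mean(!x$observed)))
  }
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of pixels in a cube
#' @param cube A [hyper_cube()].
#' @return Integer pixel count.
#' @export
n_pixels <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  nrow(cube$intensities)
}

#' Spectra matrix of a cube
#' @param x A [hyper_cube()].
#' @param ... Unused.
#' @return The `n_pixels x L` intensity matrix.
#' @export
as.matrix.hyper_cube <- function(x, ...) x$intensities

#' Tidy view of a cube
#'
#' One row per (pixel, wavenumber) entry with grid coordinates, so cubes can
#' flow straight into dplyr/ggplot2.
#'
#' @param x A [hyper_cube()].
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `pixel`, `wavenumber`,
#'   `intensity`, `observed`.
#' @export
as_tibble.hyper_cube <- function(x, ...) {
  np <- n_pixels(x)
  L <- length(x$axis)
  obs <- if (is.null(x$observed)) rep(TRUE, np * L) else as.vector(x$observed)
  tibble(
    row = rep(pixel_rows(x), times = L),
    col = rep(pixel_cols(x), times = L),
    pixel = rep(seq_len(np), times = L),
    wavenumber = rep(as.numeric(x$axis), each = np),
    intensity = as.vector(x$intensities),
    observed = obs
  )
}

# row-major linearization: pixel index = (row - 1) * cols + col
pixel_rows <- function(cube) ((seq_len(n_pixels(cube)) - 1) %/% cube$dims[2]) + 1
pixel_cols <- function(cube) ((seq_len(n_pixels(cube)) - 1) %% cube$dims[2]) + 1

#' Fold a per-pixel vector back onto the cube grid
#' @param cube A [hyper_cube()].
#' @param values Vector with one value per pixel (row-major order).
#' @return A `rows x cols` matrix.
#' @export
pixel_grid <- function(cube, values) {
  stopifnot(length(values) == n_pixels(cube))
  matrix(values, nrow = cube$dims[1], ncol = cube$dims[2], byrow = TRUE)
}

#' Nearest axis channel for a wavenumber
#' @param axis A [wavenumber_axis()] (or plain numeric axis).
#' @param wavenumber Target position in cm^-1; must lie within the axis range.
#' @return Integer channel index.
#' @export
nearest_channel <- function(axis, wavenumber) {
  axis <- as.numeric(axis)
  if (wavenumber < min(axis) || wavenumber > max(axis)) {
    abort(sprintf("wavenumber %g cm^-1 is outside the axis range [%g, %g]",
                  wavenumber, min(axis), max(axis)))
  }
  which.min(abs(axis - wavenumber))
}

#' Plot one spectral channel of a cube as an image
#'
#' @param object A [hyper_cube()].
#' @param wavenumber Channel to display (cm^-1); defaults to the axis midpoint.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hyper_cube <- function(object, wavenumber = NULL, ...) {
  wavenumber <- wavenumber %||% stats::median(as.numeric(object$axis))
  ch <- nearest_channel(object$axis, wavenumber)
  df <- tibble(
    row = pixel_rows(object),
    col = pixel_cols(object),
    intensity = object$intensities[, ch]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("Intensity at %.0f cm^-1", as.numeric(object$axis)[ch]),
      x = "column", y = "row", fill = "I"
    )
}

#' Plot spectra from a cube or matrix
#'
#' Overlays a handful of pixel spectra; useful for eyeballing baselines,
#' noise and reconstruction quality.
#'
#' @param x A [hyper_cube()] or a spectra matrix (rows = spectra).
#' @param axis Wavenumber axis (taken from the cube when `x` is one).
#' @param pixels Which rows to draw (default: up to 6 spread evenly).
#' @return A ggplot object.
#' @export
plot_spectra <- function(x, axis = NULL, pixels = NULL) {
  if (inherits(x, "hyper_cube")) {
    axis <- x$axis
    x <- x$intensities
  }
  if (is.null(axis)) abort("`axis` is required when `x` is a plain matrix")
  pixels <- pixels %||% unique(round(seq(1, nrow(x), length.out = min(6, nrow(x)))))
  df <- purrr::map_dfr(pixels, function(p) {
    tibble(pixel = factor(p), wavenumber = as.numeric(axis), intensity = x[p, ])
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                   colour = .data$pixel)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "wavenumber (cm^-1)", y = "intensity")
}
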