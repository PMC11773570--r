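# Portable on-disk formats: delimited text tables for flat spectra, and a
# schema-versioned JSON document for cubes and masks (self-describing, text
# only, lossless: numbers are written at full precision).

CUBE_SCHEMA <- "ramancs-cube/1"
MASK_SCHEMA <- "ramancs-mask/1"

detect_delim <- function(line, dialect) {
  switch(dialect,
    comma = ",",
    tab = "\t",
    auto = if (grepl("\t", line)) "\t" else ","
  )
}

#' Read a flat spectra table
#'
#' Delimited text with the wavenumber axis in the first column and one
#' spectrum per remaining column; an optional header row names the spectra.
#' A descending axis is reversed (with a warning) so the returned axis is
#' strictly increasing; ragged rows and non-numeric cells are rejected with
#' their position.
#'
#' @param path File to read.
#' @param dialect `"auto"` (default: tab if the first line contains one,
#'   else comma), `"comma"` or `"tab"`.
#' @return List with `axis` (a [wavenumber_axis()]), `spectra`
#'   (`n_spectra x L` matrix, rows are spectra) and `labels`.
#' @export
read_spectra_table <- function(path, dialect = c("auto", "comma", "tab")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("empty spectra table")
  delim <- detect_delim(lines[1], dialect)
  cells <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1])) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf("ragged row %d: %d fields where %d expected",
                  bad, widths[bad], widths[1]))
  }
  if (widths[1] < 2) abort("need a wavenumber column plus at least one spectrum")
  first <- suppressWarnings(as.numeric(cells[[1]]))
  has_header <- any(is.na(first))
  labels <- if (has_header) {
    cells[[1]][-1]
  } else {
    paste0("spectrum_", seq_len(widths[1] - 1))
  }
  data_cells <- if (has_header) cells[-1] else cells
  if (length(data_cells) == 0) abort("no data rows")
  num <- matrix(NA_real_, nrow = length(data_cells), ncol = widths[1])
  for (i in seq_along(data_cells)) {
    v <- suppressWarnings(as.numeric(data_cells[[i]]))
    if (any(is.na(v) & data_cells[[i]] != "NA")) {
      j <- which(is.na(v) & data_cells[[i]] != "NA")[1]
      abort(sprintf("non-numeric cell at data row %d, column %d: '%s'",
                    i, j, data_cells[[i]][j]))
    }
    num[i, ] <- v
  }
  ax <- num[, 1]
  spectra <- t(num[, -1, drop = FALSE]) # rows = spectra, cols = wavenumbers
  if (all(diff(ax) < 0)) {
    warning("wavenumber axis is descending; reversing axis and spectra")
    ax <- rev(ax)
    spectra <- spectra[, rev(seq_along(ax)), drop = FALSE]
  }
  rownames(spectra) <- labels
  list(axis = wavenumber_axis(ax), spectra = spectra, labels = labels)
}

#' Write a flat spectra table
#'
#' Inverse of [read_spectra_table()]: wavenumber first column, one column per
#' spectrum, header row with labels.
#'
#' @param axis Wavenumber axis.
#' @param spectra `n_spectra x L` matrix (rows are spectra).
#' @param path Output file.
#' @param labels Column labels; default from rownames or generated.
#' @param dialect `"comma"` (default) or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(axis, spectra, path, labels = NULL,
                                dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  delim <- if (dialect == "tab") "\t" else ","
  spectra <- as.matrix(spectra)
  if (is.null(dim(spectra)) || ncol(spectra) != length(axis)) {
    abort("`spectra` must be an n x length(axis) matrix")
  }
  labels <- labels %||% rownames(spectra) %||%
    paste0("spectrum_", seq_len(nrow(spectra)))
  header <- paste(c("wavenumber", labels), collapse = delim)
  body <- apply(cbind(as.numeric(axis), t(spectra)), 1, function(r) {
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = delim)
  })
  writeLines(c(header, body), path)
  invisible(path)
}

cube_to_doc <- function(cube) {
  list(
    schema = CUBE_SCHEMA,
    pixel_order = "row-major",
    grid = cube$dims,
    axis = as.numeric(cube$axis),
    intensities = unname(cube$intensities),
    observed = if (is.null(cube$observed)) NULL else unname(cube$observed),
    meta = cube$meta
  )
}

#' Write / read a hyperspectral cube
#'
#' One self-describing JSON document per cube holding the schema version,
#' pixel linearization, grid, axis, intensities (missing entries as null),
#' observed flags and metadata. `read_cube()` refuses documents whose schema
#' version does not match.
#'
#' @param cube A [hyper_cube()].
#' @param path File path.
#' @return `write_cube()` returns `path` invisibly; `read_cube()` the cube.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "hyper_cube"))
  jsonlite::write_json(cube_to_doc(cube), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null")
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(doc$schema, CUBE_SCHEMA)) {
    abort(sprintf("unsupported cube schema '%s' (expected '%s')",
                  doc$schema %||% "<missing>", CUBE_SCHEMA))
  }
  intens <- doc$intensities
  observed <- doc$observed
  if (!is.null(observed)) storage.mode(observed) <- "logical"
  meta <- doc$meta
  if (length(meta) == 0) meta <- list()
  hyper_cube(intens, doc$axis, doc$grid, observed = observed, meta = meta)
}

#' Write / read an observation mask
#'
#' Lossless JSON round trip of the observed pattern together with the scheme,
#' seed and target sparsity that produced it. When a companion `cube` is given
#' at read time the mask shape is checked against it.
#'
#' @param mask An [observation_mask()].
#' @param path File path.
#' @param cube Optional companion [hyper_cube()] for a shape check on read.
#' @return `write_mask()` returns `path` invisibly; `read_mask()` the mask.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "observation_mask"))
  doc <- list(
    schema = MASK_SCHEMA,
    observed = unname(mask$observed),
    sparsity = mask$sparsity,
    target_sparsity = mask$target_sparsity,
    scheme = mask$scheme,
    seed = mask$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, cube = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(doc$schema, MASK_SCHEMA)) {
    abort(sprintf("unsupported mask schema '%s' (expected '%s')",
                  doc$schema %||% "<missing>", MASK_SCHEMA))
  }
  observed <- doc$observed
  storage.mode(observed) <- "logical"
  mask <- observation_mask(observed, scheme = doc$scheme, seed = doc$seed,
                           target_sparsity = doc$target_sparsity)
  if (!is.null(cube)) {
    if (!identical(dim(mask$observed), dim(cube$intensities))) {
      abort("mask shape does not match the companion cube")
    }
  }
  mask
}
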