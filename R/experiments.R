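# Orchestrated sparsity sweeps: the three evaluation studies
# (concentration regression, cell segmentation with a rare drug component,
# tissue clustering with raw-first vs processed-first ordering) run as seeded
# grids over sparsity levels, emitting tidy long-form records.

REPORT_SCHEMA <- "ramancs-report/1"

#' Sweep specification
#'
#' Everything a study run needs: which study, the sparsity grid, the seeds
#' (one synthetic dataset/scene and mask stream per seed), component
#' configurations, and (for the tissue study) whether masking happens on raw
#' or on preprocessed spectra.
#'
#' The default completion configuration for sweeps uses
#' `clamp_observed = FALSE`: downstream analysis consumes the low-rank
#' estimate at every channel, so the reconstruction also acts as a shrinkage
#' denoiser — the convention under which a large fluorescence background
#' can starve small Raman peaks of nuclear-norm budget.
#'
#' @param study `"concentration"`, `"cell"` or `"tissue"`.
#' @param sparsity_levels Nonempty numeric vector in `[0, 1)`; level 0 always
#'   bypasses completion (exact baseline).
#' @param seeds Nonempty integer vector.
#' @param ordering Tissue only: `"processed_first"` or `"raw_first"`.
#' @param data_args Named list of overrides for the study's generator
#'   ([make_mixture_series()], [make_cell_scene()], [make_tissue_scene()]).
#' @param completion A [completion_config()].
#' @param preprocess A [preprocess_config()].
#' @param n_components PLS components (concentration study).
#' @param pca_components PCA depth (tissue study; default 10).
#' @param cv_threshold LoQ threshold in percent.
#' @param kmeans_n_init Random k-means restarts.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(study = c("concentration", "cell", "tissue"),
                       sparsity_levels, seeds, ordering = NULL,
                       data_args = list(),
                       completion = completion_config(clamp_observed = FALSE),
                       preprocess = preprocess_config(),
                       n_components = 2, pca_components = 10,
                       cv_threshold = 2, kmeans_n_init = 10) {
  study <- match.arg(study)
  if (length(sparsity_levels) == 0 || any(sparsity_levels < 0 | sparsity_levels >= 1)) {
    abort("`sparsity_levels` must be nonempty, each in [0, 1)")
  }
  if (length(seeds) == 0) abort("`seeds` must be nonempty")
  if (study == "tissue") {
    ordering <- match.arg(ordering, c("processed_first", "raw_first"))
  } else if (!is.null(ordering)) {
    abort("`ordering` only applies to the tissue study")
  }
  structure(
    list(study = study, sparsity_levels = sparsity_levels,
         seeds = as.integer(seeds), ordering = ordering,
         data_args = data_args, completion = completion,
         preprocess = preprocess, n_components = n_components,
         pca_components = pca_components, cv_threshold = cv_threshold,
         kmeans_n_init = kmeans_n_init),
    class = "sweep_spec"
  )
}

# deterministic per-(seed, level) stream; stays far below .Machine$integer.max
derive_seed <- function(seed, level, salt = 0L) {
  as.integer(seed * 1000L + round(level * 100) + salt)
}

# mask + complete a flat spectra matrix at sparsity s; level 0 bypasses
# completion exactly
complete_matrix <- function(m, s, seed, config) {
  if (s == 0) {
    return(list(x = m, realized = 0))
  }
  mask <- make_random_mask(nrow(m), ncol(m), s, seed = seed)
  fit <- fista_complete(m, mask$observed, config)
  x <- fit$x_hat
  if (config$clamp_observed) x[mask$observed] <- m[mask$observed]
  list(x = x, realized = mask$sparsity)
}

new_sweep_result <- function(records, spec) {
  attr(records, "study") <- spec$study
  attr(records, "provenance") <- list(
    sparsity_levels = spec$sparsity_levels, seeds = spec$seeds,
    ordering = spec$ordering, created = format(Sys.time(), tz = "UTC")
  )
  class(records) <- c("sweep_result", class(records))
  records
}

#' Run the concentration-regression study
#'
#' Per (sparsity level, seed): generate a mixture series, mask its spectra in
#' the spectral domain, recover them by matrix completion (bypassed exactly
#' at level 0), preprocess, and run leave-one-concentration-out PLS
#' validation. Records `r2`, `max_cv_percent`, `loq` (an unquantifiable grid
#' is recorded as `Inf`) and `realized_sparsity`.
#'
#' @param spec A [sweep_spec()] with `study = "concentration"`.
#' @return A `sweep_result` tibble with columns `study`, `sparsity`, `seed`,
#'   `metric`, `value`.
#' @export
run_concentration_study <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"), spec$study == "concentration")
  records <- purrr::map_dfr(spec$seeds, function(seed) {
    ds <- do.call(make_mixture_series, c(list(seed = seed), spec$data_args))
    if (length(unique(ds$fractions)) < 3) {
      abort("the concentration study needs >= 3 concentration levels")
    }
    purrr::map_dfr(spec$sparsity_levels, function(s) {
      cm <- complete_matrix(ds$spectra, s, derive_seed(seed, s), spec$completion)
      proc <- preprocess_spectra(cm$x, spec$preprocess)
      rep_ <- locoo_validate(list(spectra = proc, fractions = ds$fractions),
                             n_components = spec$n_components,
                             cv_threshold = spec$cv_threshold,
                             sparsity_level = s, seed = seed)
      tibble(study = "concentration", sparsity = s, seed = seed,
             metric = c("r2", "max_cv_percent", "loq", "realized_sparsity"),
             value = c(rep_$r2, max(rep_$cv$cv_percent),
                       ifelse(is.na(rep_$loq), Inf, rep_$loq), cm$realized))
    })
  })
  new_sweep_result(records, spec)
}

#' Run the cell-imaging study
#'
#' Per (level, seed): generate a background/cytoplasm/drug scene, mask,
#' complete, preprocess, then (a) delineate the cell by k = 2 clustering of
#' the preprocessed spectra and score pixel agreement against the true
#' cell-vs-background map, and (b) detect drug pixels by the 1168 cm^-1
#' marker using a fixed threshold learned by Otsu on the full-sampling
#' reference, scoring drug-class recall. Records `cell_accuracy_percent`,
#' `drug_accuracy_percent`, `realized_sparsity`.
#'
#' @param spec A [sweep_spec()] with `study = "cell"`.
#' @return A `sweep_result` tibble.
#' @export
run_cell_study <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"), spec$study == "cell")
  records <- purrr::map_dfr(spec$seeds, function(seed) {
    scene <- do.call(make_cell_scene, c(list(seed = seed), spec$data_args))
    truth <- as.vector(t(scene$labels)) # row-major pixel order
    truth_cell <- ifelse(truth == 1L, 1L, 2L)
    truth_drug <- ifelse(truth == 3L, 2L, 1L)
    marker <- scene$cube$meta$drug_peak_center %||% 1168
    reference <- preprocess_cube(scene$cube, spec$preprocess)
    ref_det <- detect_drug_pixels(reference, marker, rule = "otsu")
    thr <- attr(ref_det, "threshold")
    purrr::map_dfr(spec$sparsity_levels, function(s) {
      cm <- complete_matrix(scene$cube$intensities, s, derive_seed(seed, s),
                            spec$completion)
      rec <- hyper_cube(cm$x, scene$cube$axis, scene$cube$dims)
      proc <- preprocess_cube(rec, spec$preprocess)
      km <- kmeans_lloyd(proc$intensities, k = 2,
                         seed = derive_seed(seed, s, 7L),
                         n_init = spec$kmeans_n_init)
      aligned <- align_labels(km$labels, truth_cell)
      cell_acc <- segmentation_accuracy(aligned, truth_cell)
      det <- detect_drug_pixels(proc, marker, rule = "fixed", threshold = thr)
      pred_drug <- ifelse(as.vector(t(det)), 2L, 1L)
      drug_acc <- segmentation_accuracy(pred_drug, truth_drug,
                                        class_of_interest = 2L)
      tibble(study = "cell", sparsity = s, seed = seed,
             metric = c("cell_accuracy_percent", "drug_accuracy_percent",
                        "realized_sparsity"),
             value = c(cell_acc, drug_acc, cm$realized))
    })
  })
  new_sweep_result(records, spec)
}

#' Run the tissue-clustering study
#'
#' Per (level, seed): generate a three-layer tissue scene with a large
#' fluorescence baseline. With `ordering = "raw_first"`, the raw cube is
#' masked and completed, then preprocessed; with `"processed_first"`, the
#' cube is preprocessed first and the clean spectra are masked and completed.
#' Either way the spectra are reduced to the top `pca_components` PC scores
#' and clustered with k = 3; the aligned pixel accuracy and the length of the
#' PC-loading prefix matching the full-sampling reference are recorded
#' (`accuracy_percent`, `pc_prefix`, `realized_sparsity`). Level 0 bypasses
#' completion, so both orderings agree exactly there.
#'
#' @param spec A [sweep_spec()] with `study = "tissue"` and `ordering` set.
#' @return A `sweep_result` tibble.
#' @export
run_tissue_study <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"), spec$study == "tissue")
  records <- purrr::map_dfr(spec$seeds, function(seed) {
    scene <- do.call(make_tissue_scene, c(list(seed = seed), spec$data_args))
    truth <- as.vector(t(scene$labels))
    ref_proc <- preprocess_cube(scene$cube, spec$preprocess)
    ref_pca <- pca_fit(ref_proc$intensities, spec$pca_components)
    purrr::map_dfr(spec$sparsity_levels, function(s) {
      cm <- if (spec$ordering == "raw_first") {
        raw_cm <- complete_matrix(scene$cube$intensities, s,
                                  derive_seed(seed, s), spec$completion)
        rec <- hyper_cube(raw_cm$x, scene$cube$axis, scene$cube$dims)
        list(x = preprocess_cube(rec, spec$preprocess)$intensities,
             realized = raw_cm$realized)
      } else {
        complete_matrix(ref_proc$intensities, s, derive_seed(seed, s),
                        spec$completion)
      }
      pca <- pca_fit(cm$x, spec$pca_components)
      km <- kmeans_lloyd(pca$scores, k = 3, seed = derive_seed(seed, s, 7L),
                         n_init = spec$kmeans_n_init)
      aligned <- align_labels(km$labels, truth)
      tibble(study = "tissue", sparsity = s, seed = seed,
             metric = c("accuracy_percent", "pc_prefix", "realized_sparsity"),
             value = c(segmentation_accuracy(aligned, truth),
                       compare_pc_loadings(ref_pca, pca)$prefix,
                       cm$realized))
    })
  })
  records$ordering <- spec$ordering
  new_sweep_result(records, spec)
}

#' Run the study named in a sweep spec
#' @param spec A [sweep_spec()].
#' @return A `sweep_result` tibble.
#' @export
run_sweep <- function(spec) {
  switch(spec$study,
    concentration = run_concentration_study(spec),
    cell = run_cell_study(spec),
    tissue = run_tissue_study(spec)
  )
}

#' Median of each metric by sparsity level
#'
#' @param result A `sweep_result`.
#' @return A tibble with one row per (sparsity, metric) and the across-seed
#'   median.
#' @export
summarize_sweep <- function(result) {
  grp <- intersect(c("study", "ordering", "sparsity", "metric"), names(result))
  result |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(median_value = median(.data$value), n_seeds = dplyr::n(),
                     .groups = "drop")
}

#' @export
autoplot.sweep_result <- function(object, ...) {
  sm <- summarize_sweep(object)
  ggplot2::ggplot(sm, ggplot2::aes(.data$sparsity, .data$median_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity", y = "median over seeds")
}

#' Write / load a sweep report
#'
#' A flat, line-oriented file: a `#`-prefixed header (schema version, study,
#' provenance, and a human-readable median summary) followed by
#' tab-separated long-form records. `load_report()` refuses files whose
#' schema line does not match and restores the records losslessly.
#'
#' @param result A `sweep_result`.
#' @param path Output file.
#' @return `write_report()` returns `path` invisibly; `load_report()` the
#'   `sweep_result` tibble.
#' @export
write_report <- function(result, path) {
  prov <- attr(result, "provenance")
  sm <- summarize_sweep(result)
  header <- c(
    paste0("#schema: ", REPORT_SCHEMA),
    paste0("#study: ", attr(result, "study")),
    paste0("#created: ", prov$created %||% ""),
    paste0("#seeds: ", paste(prov$seeds, collapse = ",")),
    "#summary (median over seeds):",
    paste0("#  ", apply(sm, 1, function(r) paste(trimws(r), collapse = " ")))
  )
  cols <- names(result)
  fmt <- lapply(result, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  body <- c(paste(cols, collapse = "\t"),
            do.call(paste, c(fmt, sep = "\t")))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_report
#' @export
load_report <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], paste0("#schema: ", REPORT_SCHEMA))) {
    abort(sprintf("unsupported report schema (expected '%s')", REPORT_SCHEMA))
  }
  study <- sub("^#study: ", "", lines[2])
  data_lines <- lines[!startsWith(lines, "#")]
  cols <- strsplit(data_lines[1], "\t", fixed = TRUE)[[1]]
  cells <- strsplit(data_lines[-1], "\t", fixed = TRUE)
  records <- as_tibble(setNames(
    lapply(seq_along(cols), function(j) {
      v <- vapply(cells, `[[`, character(1), j)
      if (cols[j] %in% c("study", "metric", "ordering")) v else as.numeric(v)
    }),
    cols
  ))
  records$seed <- as.integer(records$seed)
  attr(records, "study") <- study
  class(records) <- c("sweep_result", class(records))
  records
}
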