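# Imaging analytics: PCA, seeded Lloyd k-means with an inertia trace,
# peak-based rare-component detection, cluster-label alignment and the
# segmentation accuracy metrics.

#' Principal component analysis of spectra
#'
#' Thin wrapper over [stats::prcomp()] exposing mean-centered leading right
#' singular directions with a fixed sign convention (each loading's
#' largest-magnitude element is positive), per-pixel scores and explained
#' variance fractions.
#'
#' @param x Spectra matrix (`n x L`).
#' @param n_components Components to keep, `<= min(n, L)` (default 10, the
#'   conventional depth for tissue clustering).
#' @return A `pca_result`: `mean`, `loadings` (`n_components x L`, orthonormal
#'   rows), `scores` (`n x n_components`), `explained_variance`.
#' @export
pca_fit <- function(x, n_components = 10) {
  x <- as.matrix(x)
  if (n_components < 1 || n_components > min(dim(x))) {
    abort(sprintf("`n_components` must be in [1, %d]", min(dim(x))))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  loadings <- t(pc$rotation[, keep, drop = FALSE])
  scores <- pc$x[, keep, drop = FALSE]
  dimnames(loadings) <- dimnames(scores) <- NULL
  for (i in keep) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) {
      loadings[i, ] <- -loadings[i, ]
      scores[, i] <- -scores[, i]
    }
  }
  structure(
    list(mean = unname(pc$center), loadings = loadings, scores = scores,
         explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[keep]),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components, %.1f%% variance explained\n",
              nrow(x$loadings), 100 * sum(x$explained_variance)))
  invisible(x)
}

#' @export
tidy.pca_result <- function(x, ...) {
  nc <- nrow(x$loadings)
  tibble(component = rep(seq_len(nc), each = ncol(x$loadings)),
         channel = rep(seq_len(ncol(x$loadings)), times = nc),
         loading = as.vector(t(x$loadings)))
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_components = nrow(x$loadings),
         variance_explained = sum(x$explained_variance))
}

#' Seeded Lloyd k-means
#'
#' Classic Lloyd iterations (random data points as initial centroids,
#' nearest-centroid assignment, mean update, repeat until assignments are
#' stable) run from `n_init` seeded random starts, keeping the lowest-inertia
#' run. An emptied cluster is re-seeded to the point farthest from its
#' assigned centroid. The winning run's inertia trace (within-cluster sum of
#' squares after each update) is returned and is non-increasing.
#'
#' @param points Numeric matrix (`n x d`), one row per observation.
#' @param k Number of clusters (> 0, at most the number of distinct rows).
#' @param seed Integer seed (the `n_init` starts draw from one seeded stream).
#' @param n_init Random restarts (default 10).
#' @param max_iter Lloyd iteration cap per start (default 100).
#' @return A `cluster_map`: integer `labels` (1..k), `k`, `centers`,
#'   `inertia`, `inertia_trace`, `seed`.
#' @export
kmeans_lloyd <- function(points, k, seed = 1, n_init = 10, max_iter = 100) {
  points <- as.matrix(points)
  if (k <= 0) abort("`k` must be positive")
  n_distinct <- nrow(unique(points))
  if (k > n_distinct) abort("`k` exceeds the number of distinct points")
  sq <- rowSums(points^2)
  run_once <- function() {
    centers <- points[sample.int(nrow(points), k), , drop = FALSE]
    labels <- rep(0L, nrow(points))
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      d2 <- outer(sq, rowSums(centers^2), "+") - 2 * tcrossprod(points, centers)
      new_labels <- max.col(-d2, ties.method = "first")
      for (cl in seq_len(k)) {
        if (!any(new_labels == cl)) {
          far <- which.max(d2[cbind(seq_len(nrow(points)), new_labels)])
          new_labels[far] <- cl
        }
      }
      for (cl in seq_len(k)) {
        centers[cl, ] <- colMeans(points[new_labels == cl, , drop = FALSE])
      }
      d2 <- outer(sq, rowSums(centers^2), "+") - 2 * tcrossprod(points, centers)
      trace <- c(trace, sum(pmax(d2[cbind(seq_len(nrow(points)), new_labels)], 0)))
      if (identical(new_labels, labels)) break
      labels <- new_labels
    }
    list(labels = labels, centers = centers, trace = trace,
         inertia = tail(trace, 1))
  }
  best <- withr::with_seed(seed, {
    runs <- lapply(seq_len(n_init), function(i) run_once())
    runs[[which.min(vapply(runs, `[[`, numeric(1), "inertia"))]]
  })
  structure(
    list(labels = best$labels, k = as.integer(k), centers = best$centers,
         inertia = best$inertia, inertia_trace = best$trace, seed = seed),
    class = "cluster_map"
  )
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> k = %d over %d points, inertia %.4g\n",
              x$k, length(x$labels), x$inertia))
  invisible(x)
}

#' @export
tidy.cluster_map <- function(x, ...) {
  tibble(point = seq_along(x$labels), label = x$labels)
}

#' @export
glance.cluster_map <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, iterations = length(x$inertia_trace),
         seed = x$seed)
}

as_label_vector <- function(x) {
  if (inherits(x, "cluster_map")) x$labels else as.integer(as.vector(t(as.matrix(x))))
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  # lexicographic order so ties break deterministically
  out[order(vapply(out, paste, character(1), collapse = ","))]
}

#' Align arbitrary cluster labels to a reference
#'
#' k-means labels are arbitrary; this finds the label permutation maximizing
#' pixel agreement with the truth map (exhaustive search, `k <= 8`; ties go
#' to the lexicographically lowest permutation) and relabels the prediction.
#'
#' @param predicted A `cluster_map`, or an integer label matrix/vector.
#' @param truth Ground-truth integer labels of the same length/grid.
#' @return The relabeled prediction (same type as the input) with attributes
#'   `permutation` and `agreement` (fraction in `[0, 1]`).
#' @export
align_labels <- function(predicted, truth) {
  pred <- as_label_vector(predicted)
  tr <- as_label_vector(truth)
  if (length(pred) != length(tr)) abort("prediction and truth grids differ")
  k <- max(pred, tr)
  if (k > 8) abort("label alignment supports at most 8 classes")
  best <- NULL
  for (perm in all_permutations(k)) {
    agree <- mean(perm[pred] == tr)
    if (is.null(best) || agree > best$agree) {
      best <- list(perm = perm, agree = agree)
    }
  }
  relabeled <- best$perm[pred]
  out <- if (inherits(predicted, "cluster_map")) {
    predicted$labels <- relabeled
    predicted
  } else if (is.matrix(predicted)) {
    matrix(relabeled, nrow(predicted), ncol(predicted), byrow = TRUE)
  } else {
    relabeled
  }
  attr(out, "permutation") <- as.integer(best$perm)
  attr(out, "agreement") <- best$agree
  out
}

#' Segmentation accuracy (percent)
#'
#' With `class_of_interest = NULL`, the fraction of pixels whose (aligned)
#' label matches the truth. With a class given, the recall for that class:
#' the fraction of truth pixels of the class that carry the correct label —
#' so a present class that is never predicted scores exactly 0.
#'
#' @param predicted Aligned predicted labels (matrix, vector or
#'   `cluster_map`).
#' @param truth Ground-truth labels.
#' @param class_of_interest Optional class label; must be present in truth.
#' @return Accuracy in percent.
#' @export
segmentation_accuracy <- function(predicted, truth, class_of_interest = NULL) {
  pred <- as_label_vector(predicted)
  tr <- as_label_vector(truth)
  if (length(pred) != length(tr)) abort("prediction and truth grids differ")
  if (is.null(class_of_interest)) {
    return(100 * mean(pred == tr))
  }
  sel <- tr == class_of_interest
  if (!any(sel)) abort(sprintf("class %s is absent from the truth map",
                               format(class_of_interest)))
  100 * mean(pred[sel] == class_of_interest)
}

otsu_threshold <- function(v) {
  v <- sort(v)
  n <- length(v)
  csum <- cumsum(v)
  total <- csum[n]
  i <- seq_len(n - 1)
  w1 <- i / n
  w2 <- 1 - w1
  m1 <- csum[i] / i
  m2 <- (total - csum[i]) / (n - i)
  between <- w1 * w2 * (m1 - m2)^2
  j <- which.max(between)
  (v[j] + v[j + 1]) / 2
}

#' Detect rare-component (drug) pixels by marker-peak intensity
#'
#' Flags pixels whose intensity at the channel nearest `peak_wavenumber`
#' exceeds a threshold. Rules: `"otsu"` (default; maximizes between-class
#' variance of the channel values), `"fixed"` (explicit `threshold`, e.g. one
#' learned on a full-sampling reference), or `"mean_plus_ksd"`
#' (`mean + k * sd`, default `k = 3`).
#'
#' @param cube A [hyper_cube()] (typically preprocessed).
#' @param peak_wavenumber Marker position in cm^-1 (default 1168, the
#'   drug-nanoparticle marker); must lie within the axis.
#' @param rule Threshold rule.
#' @param threshold Threshold for `rule = "fixed"`.
#' @param k Multiplier for `rule = "mean_plus_ksd"`.
#' @return Logical `rows x cols` matrix with attributes `threshold` and
#'   `channel`.
#' @export
detect_drug_pixels <- function(cube, peak_wavenumber = 1168,
                               rule = c("otsu", "fixed", "mean_plus_ksd"),
                               threshold = NULL, k = 3) {
  rule <- match.arg(rule)
  stopifnot(inherits(cube, "hyper_cube"))
  ch <- nearest_channel(cube$axis, peak_wavenumber)
  v <- cube$intensities[, ch]
  thr <- switch(rule,
    otsu = otsu_threshold(v),
    fixed = {
      if (is.null(threshold)) abort("`threshold` required for rule = \"fixed\"")
      threshold
    },
    mean_plus_ksd = mean(v) + k * sd(v)
  )
  out <- pixel_grid(cube, v > thr)
  attr(out, "threshold") <- thr
  attr(out, "channel") <- ch
  out
}

#' Compare PCA loadings between two fits
#'
#' Declares component `i` preserved when the absolute cosine similarity of
#' the two loading vectors reaches the threshold, and reports the longest
#' all-preserved prefix — the depth to which a reconstruction retains the
#' reference's principal structure.
#'
#' @param a,b `pca_result` objects on the same wavenumber axis (same channel
#'   count).
#' @param similarity_threshold Cosine threshold (default 0.95).
#' @return List with `prefix` (integer) and `components` (tibble with
#'   `component`, `similarity`, `match`).
#' @export
compare_pc_loadings <- function(a, b, similarity_threshold = 0.95) {
  stopifnot(inherits(a, "pca_result"), inherits(b, "pca_result"))
  if (ncol(a$loadings) != ncol(b$loadings)) {
    abort("the two fits live on different wavenumber axes")
  }
  nc <- min(nrow(a$loadings), nrow(b$loadings))
  sim <- vapply(seq_len(nc), function(i) {
    la <- a$loadings[i, ]
    lb <- b$loadings[i, ]
    abs(sum(la * lb)) / sqrt(sum(la^2) * sum(lb^2))
  }, numeric(1))
  match_ <- sim >= similarity_threshold
  prefix <- if (all(match_)) nc else which(!match_)[1] - 1L
  list(prefix = as.integer(prefix),
       components = tibble(component = seq_len(nc), similarity = sim,
                           match = match_))
}
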