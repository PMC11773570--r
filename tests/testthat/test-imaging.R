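test_that("pca matches an eigendecomposition oracle and its invariants", {
  # collinear two-column data: one component carries all variance
  x <- cbind(1:6, 2 * (1:6))
  p1 <- pca_fit(x, 1)
  expect_equal(p1$explained_variance, 1, tolerance = 1e-12)
  # tiny case against eigen of the covariance matrix
  set.seed(1)
  y <- matrix(rnorm(6), 3, 2)
  p2 <- pca_fit(y, 2)
  eg <- eigen(stats::cov(y), symmetric = TRUE)
  for (i in 1:2) {
    expect_equal(abs(sum(p2$loadings[i, ] * eg$vectors[, i])), 1,
                 tolerance = 1e-8)
  }
  # orthonormal loadings, sign convention, exact reconstruction
  set.seed(2)
  z <- matrix(rnorm(80), 10, 8)
  pf <- pca_fit(z, 8)
  expect_equal(tcrossprod(pf$loadings), diag(8), tolerance = 1e-8)
  expect_true(all(apply(pf$loadings, 1, function(l) l[which.max(abs(l))]) > 0))
  recon <- pf$scores %*% pf$loadings
  expect_equal(recon, sweep(z, 2, pf$mean), tolerance = 1e-8)
  expect_error(pca_fit(z, 11), "n_components")
})

test_that("lloyd k-means separates blobs and finds small global optima", {
  set.seed(3)
  blobs <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
                 matrix(rnorm(40, 5, 0.1), 20, 2))
  truth <- rep(1:2, each = 20)
  km <- kmeans_lloyd(blobs, 2, seed = 1)
  expect_equal(attr(align_labels(km, truth), "agreement"), 1)
  # k = n gives zero inertia
  pts <- matrix(c(0, 1, 2, 5, 9, 11), 6, 1)
  expect_equal(kmeans_lloyd(pts, 6, seed = 1)$inertia, 0)
  expect_error(kmeans_lloyd(pts, 0, seed = 1), "positive")
  expect_error(kmeans_lloyd(pts, 7, seed = 1), "distinct")
  # 6-point 1-D case against exhaustive enumeration of all assignments
  wss_best <- Inf
  for (code in 0:(2^6 - 1)) {
    lab <- as.integer(intToBits(code))[1:6] + 1L
    if (length(unique(lab)) < 2) next
    wss <- sum(vapply(1:2, function(cl) {
      v <- pts[lab == cl, 1]
      sum((v - mean(v))^2)
    }, numeric(1)))
    wss_best <- min(wss_best, wss)
  }
  expect_equal(kmeans_lloyd(pts, 2, seed = 2)$inertia, wss_best)
})

test_that("k-means inertia traces never increase and runs are seeded", {
  set.seed(4)
  pts <- matrix(rnorm(200), 100, 2)
  km <- kmeans_lloyd(pts, 3, seed = 9)
  expect_true(all(diff(km$inertia_trace) <= 1e-10))
  expect_identical(kmeans_lloyd(pts, 3, seed = 9)$labels, km$labels)
  # cross-check against the stock implementation on a well-separated case
  blobs <- rbind(matrix(rnorm(60, 0, 0.05), 30, 2),
                 matrix(rnorm(60, 4, 0.05), 30, 2),
                 matrix(rnorm(60, 8, 0.05), 30, 2))
  ours <- kmeans_lloyd(blobs, 3, seed = 1)
  ref <- stats::kmeans(blobs, 3, nstart = 10, algorithm = "Lloyd")
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("label alignment finds the best permutation deterministically", {
  truth <- matrix(c(1, 1, 2, 2, 3, 3), 2, 3)
  expect_equal(attr(align_labels(truth, truth), "agreement"), 1)
  expect_identical(attr(align_labels(truth, truth), "permutation"), 1:3)
  swapped <- truth; swapped[truth == 1] <- 2; swapped[truth == 2] <- 1
  al <- align_labels(swapped, truth)
  expect_equal(attr(al, "agreement"), 1)
  expect_identical(unname(as.vector(al)), unname(as.vector(truth)))
  # random 4x4 map with k = 3 against exhaustive 3! search
  set.seed(5)
  pred <- matrix(sample(1:3, 16, TRUE), 4, 4)
  tr <- matrix(sample(1:3, 16, TRUE), 4, 4)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- max(vapply(perms, function(p) mean(p[pred] == tr), numeric(1)))
  expect_equal(attr(align_labels(pred, tr), "agreement"), best)
  # agreement is invariant to relabeling the prediction
  relab <- matrix(c(3, 1, 2)[pred], 4, 4)
  expect_equal(attr(align_labels(relab, tr), "agreement"), best)
  expect_error(align_labels(pred[1:2, ], tr), "differ")
})

test_that("segmentation accuracy counts pixels and class recall", {
  truth <- matrix(c(1, 1, 1, 2, 2, 2, 3, 3, 3), 3, 3)
  expect_identical(segmentation_accuracy(truth, truth), 100)
  expect_identical(segmentation_accuracy(truth, truth, class_of_interest = 2), 100)
  one_off <- truth; one_off[1, 1] <- 2
  expect_equal(segmentation_accuracy(one_off, truth), 100 * 8 / 9)
  # a present class never predicted scores zero recall
  no3 <- truth; no3[truth == 3] <- 1
  expect_identical(segmentation_accuracy(no3, truth, class_of_interest = 3), 0)
  expect_error(segmentation_accuracy(truth, truth, class_of_interest = 7),
               "absent")
})

test_that("drug detection recovers the exact truth on a noiseless scene", {
  sc <- make_cell_scene(dims = c(12, 14), rare_fraction = 4, axis = tiny_axis(128),
                        noise_sd = 0, baseline_amplitude = 0, seed = 6)
  det <- detect_drug_pixels(sc$cube)
  expect_identical(matrix(as.vector(det), nrow(det)), sc$labels == 3L)
  expect_error(detect_drug_pixels(sc$cube, peak_wavenumber = 200), "outside")
  expect_error(detect_drug_pixels(sc$cube, rule = "fixed"), "threshold")
  # all-background scene: mean + k*sd flags nothing when there is no outlier
  bg <- hyper_cube(matrix(rep(make_endmember_spectrum(default_cell_endmembers()$background,
                                                      tiny_axis(128)),
                              each = 20), 20, 128),
                   tiny_axis(128), c(4, 5))
  expect_false(any(detect_drug_pixels(bg, rule = "mean_plus_ksd")))
})

test_that("fixed-threshold sweeps yield a monotone detection rate", {
  sc <- make_cell_scene(dims = c(12, 14), rare_fraction = 4, axis = tiny_axis(128),
                        noise_sd = 0.05, baseline_amplitude = 0, seed = 7)
  truth_drug <- sc$labels == 3L
  thresholds <- seq(1.6, 0.1, by = -0.1)
  tpr <- vapply(thresholds, function(t) {
    det <- detect_drug_pixels(sc$cube, rule = "fixed", threshold = t)
    sum(det & truth_drug) / sum(truth_drug)
  }, numeric(1))
  expect_true(all(diff(tpr) >= 0)) # TPR non-decreasing as t decreases
})

test_that("pc loading comparison reports the longest matching prefix", {
  set.seed(8)
  x <- matrix(rnorm(300), 30, 10)
  a <- pca_fit(x, 5)
  expect_identical(compare_pc_loadings(a, a)$prefix, 5L)
  b <- a
  b$loadings[1, ] <- withr::with_seed(9, rnorm(10))
  expect_identical(compare_pc_loadings(a, b)$prefix, 0L)
  b2 <- a
  b2$loadings[3, ] <- withr::with_seed(10, rnorm(10))
  cmp <- compare_pc_loadings(a, b2)
  expect_identical(cmp$prefix, 2L)
  expect_identical(cmp$components$match[1:3], c(TRUE, TRUE, FALSE))
  wrong_axis <- pca_fit(matrix(rnorm(240), 30, 8), 5)
  expect_error(compare_pc_loadings(a, wrong_axis), "different wavenumber")
})
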