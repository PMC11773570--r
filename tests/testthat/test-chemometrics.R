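test_that("pls reproduces exact linear responses and closed-form weights", {
  set.seed(1)
  x <- matrix(rnorm(40), 10, 4)
  b <- c(1, -2, 0.5, 3)
  y <- drop(x %*% b)
  fit <- pls_fit(x, y, n_components = 4)
  expect_equal(pls_predict(fit, x), y, tolerance = 1e-8)
  expect_error(pls_fit(x, y, n_components = 0), "n_components")
  expect_error(pls_fit(x, rep(1, 10), 1), "zero variance")
  # orthonormal predictors: the first weight vector is proportional to X'y
  q_ <- qr.Q(qr(matrix(rnorm(36), 9, 4)))
  yq <- drop(q_ %*% c(2, 1, -1, 0.5)) + 5
  f1 <- pls_fit(q_, yq, n_components = 1)
  w_oracle <- drop(crossprod(sweep(q_, 2, colMeans(q_)), yq - mean(yq)))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(abs(sum(f1$weights[, 1] * w_oracle)), 1, tolerance = 1e-10)
})

test_that("pls prediction is an affine map through the centering point", {
  set.seed(2)
  x <- matrix(rnorm(60), 12, 5)
  y <- rnorm(12) + 70
  fit <- pls_fit(x, y, 3)
  expect_equal(pls_predict(fit, x[3, , drop = FALSE]),
               unname(pls_predict(fit, x)[3]))
  expect_equal(pls_predict(fit, matrix(fit$x_mean, 1)), fit$y_mean)
  # affine consistency on centered inputs
  xc <- sweep(x, 2, fit$x_mean)
  fitted <- pls_predict(fit, x)
  for (alpha in c(0.5, 2)) {
    expect_equal(pls_predict(fit, alpha * xc + rep(1, 12) %o% fit$x_mean),
                 alpha * (fitted - fit$y_mean) + fit$y_mean, tolerance = 1e-10)
  }
  expect_error(pls_predict(fit, x[, 1:3]), "columns")
})

test_that("full-component pls equals ordinary least squares on small cases", {
  set.seed(3)
  for (i in 1:3) {
    x <- matrix(rnorm(7 * 3), 7, 3)
    y <- rnorm(7)
    fit <- pls_fit(x, y, n_components = 3)
    # normal-equations oracle
    xc <- cbind(1, x)
    beta_ols <- solve(crossprod(xc), crossprod(xc, y))
    expect_equal(pls_predict(fit, x), drop(xc %*% beta_ols), tolerance = 1e-6)
  }
})

test_that("pls agrees with an independent reference implementation", {
  set.seed(4)
  x <- matrix(rnorm(20 * 8), 20, 8)
  colnames(x) <- paste0("w", 1:8)
  y <- drop(x %*% rnorm(8)) + rnorm(20, sd = 0.1)
  fit <- pls_fit(x, y, n_components = 2)
  ref <- mixOmics::pls(x, y, ncomp = 2, mode = "regression", scale = FALSE)
  pred_ref <- drop(predict(ref, x)$predict[, 1, 2])
  expect_equal(unname(pls_predict(fit, x)), unname(pred_ref), tolerance = 1e-6)
})

test_that("leave-one-concentration-out predicts every spectrum exactly once", {
  ds <- make_mixture_series(fractions = seq(60, 80, 5), n_replicates = 4,
                            axis = tiny_axis(), endmembers = tiny_endmembers(),
                            noise_sd = 0, baseline_amplitude = 0, seed = 1)
  rep_ <- locoo_validate(ds, n_components = 2)
  expect_identical(nrow(rep_$predictions), nrow(ds$spectra))
  expect_identical(sort(unique(rep_$predictions$fraction)),
                   sort(unique(ds$fractions)))
  expect_gt(rep_$r2, 0.999)
  expect_true(all(rep_$cv$cv_percent < 0.1))
  expect_identical(rep_$loq, 60)
  expect_error(locoo_validate(list(spectra = ds$spectra[ds$fractions < 70, ],
                                   fractions = ds$fractions[ds$fractions < 70])),
               "3 distinct")
})

test_that("contradictory duplicate spectra cap the achievable r-squared", {
  ds <- make_mixture_series(fractions = c(60, 70, 80), n_replicates = 3,
                            axis = tiny_axis(), endmembers = tiny_endmembers(),
                            noise_sd = 0.01, baseline_amplitude = 0, seed = 1)
  spectra <- ds$spectra
  # relabel an independent draw of 60% mixtures as 70%: irreducible ambiguity
  ds2 <- make_mixture_series(fractions = c(60, 70, 80), n_replicates = 3,
                             axis = tiny_axis(), endmembers = tiny_endmembers(),
                             noise_sd = 0.01, baseline_amplitude = 0, seed = 99)
  spectra[ds$fractions == 70, ] <- ds2$spectra[ds2$fractions == 60, ]
  rep_ <- locoo_validate(list(spectra = spectra, fractions = ds$fractions), 2)
  expect_lt(rep_$r2, 1)
})

test_that("coefficient of variation follows its textbook definition", {
  expect_identical(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(69, 70, 71)), 100 * 1 / 70)
  v <- c(3, 4, 5, 7)
  expect_equal(coefficient_of_variation(2.5 * v), coefficient_of_variation(v))
  expect_error(coefficient_of_variation(5), ">= 2")
  expect_error(coefficient_of_variation(c(-3, 1)), "positive")
})

test_that("the limit of quantification walks up from failing levels", {
  grid <- seq(60, 80, 2)
  all_pass <- data.frame(fraction = grid, cv_percent = rep(1, 11))
  expect_identical(limit_of_quantification(all_pass), 60)
  low_fail <- all_pass
  low_fail$cv_percent[1] <- 2.7
  expect_identical(limit_of_quantification(low_fail), 62)
  mid_fail <- all_pass
  mid_fail$cv_percent[6] <- 2.5 # 70% fails -> everything below is disqualified
  expect_identical(limit_of_quantification(mid_fail), 72)
  all_fail <- all_pass
  all_fail$cv_percent <- 3
  expect_identical(limit_of_quantification(all_fail), NA_real_)
  expect_error(limit_of_quantification(all_pass[0, ]), "empty")
})

test_that("r-squared matches its definition", {
  y <- c(60, 65, 70, 75)
  expect_identical(r_squared(y, y), 1)
  expect_identical(r_squared(y, rep(mean(y), 4)), 0)
  pred <- c(61, 64, 71, 73)
  expect_equal(r_squared(y, pred),
               1 - sum((y - pred)^2) / sum((y - mean(y))^2))
  expect_error(r_squared(rep(1, 3), 1:3), "zero variance")
})
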