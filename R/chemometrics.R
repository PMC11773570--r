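# PLS-1 calibration for concentration prediction, with
# leave-one-concentration-out validation, per-concentration coefficient of
# variation and a CV-based limit of quantification.

#' Fit a PLS regression model
#'
#' Univariate-response partial least squares by sequential deflation
#' (NIPALS): each latent component's score vector maximizes covariance with
#' the current response residual among unit-norm weight vectors; both the
#' spectra and the response are deflated before extracting the next
#' component. Deterministic. With as many components as the rank of the
#' (centered) spectra on noiseless linear data, PLS reproduces ordinary least
#' squares.
#'
#' @param x Spectra matrix (`n x L`, rows are spectra), no missing entries.
#' @param y Numeric response (e.g. water fraction in percent), nonzero
#'   variance.
#' @param n_components Latent variables, `1 <= A <= min(n - 1, L)`.
#' @return A `pls_model`: centering vectors, per-component `weights`,
#'   `x_loadings`, `y_loadings`, and the collapsed coefficient vector
#'   `beta` plus `intercept` such that `y_hat = x %*% beta + intercept`.
#' @export
pls_fit <- function(x, y, n_components = 2) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (anyNA(x)) abort("`x` must not contain missing entries; complete first")
  if (length(y) != nrow(x)) abort("`y` length must match rows of `x`")
  if (var(y) == 0) abort("`y` has zero variance")
  a_max <- min(nrow(x) - 1, ncol(x))
  if (n_components < 1 || n_components > a_max) {
    abort(sprintf("`n_components` must be in [1, %d]", a_max))
  }
  x_mean <- colMeans(x)
  y_mean <- mean(y)
  xc <- sweep(x, 2, x_mean)
  yc <- y - y_mean
  L <- ncol(x)
  W <- P <- matrix(0, L, n_components)
  q <- numeric(n_components)
  a_used <- 0
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break # response residual fully explained
    w <- w / nw
    t_ <- drop(xc %*% w)
    tt <- sum(t_^2)
    p <- drop(crossprod(xc, t_)) / tt
    qa <- sum(yc * t_) / tt
    xc <- xc - tcrossprod(t_, p)
    yc <- yc - qa * t_
    W[, a] <- w
    P[, a] <- p
    q[a] <- qa
    a_used <- a
  }
  if (a_used == 0) abort("no informative component could be extracted")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  beta <- drop(W %*% solve(crossprod(P, W), q))
  structure(
    list(n_components = a_used, x_mean = x_mean, y_mean = y_mean,
         weights = W, x_loadings = P, y_loadings = q,
         beta = beta, intercept = y_mean - sum(x_mean * beta)),
    class = "pls_model"
  )
}

#' Predict concentrations from a PLS model
#'
#' @param model A [pls_fit()] model.
#' @param x Spectra matrix with the training column count.
#' @return Numeric vector of predictions.
#' @export
pls_predict <- function(model, x) {
  stopifnot(inherits(model, "pls_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$x_mean)) {
    abort(sprintf("`x` has %d columns; the model was trained on %d",
                  ncol(x), length(model$x_mean)))
  }
  drop(x %*% model$beta) + model$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d wavenumbers\n",
              x$n_components, length(x$beta)))
  invisible(x)
}

#' @export
tidy.pls_model <- function(x, ...) {
  tibble(term = seq_along(x$beta), beta = x$beta)
}

#' @export
glance.pls_model <- function(x, ...) {
  tibble(n_components = x$n_components, intercept = x$intercept)
}

#' Coefficient of determination
#'
#' `1 - SSE/SST`; can be negative for predictions worse than the mean.
#'
#' @param y_true Observed values (>= 2, nonzero variance).
#' @param y_pred Predictions.
#' @return R-squared (<= 1).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) < 2 || length(y_true) != length(y_pred)) {
    abort("need >= 2 paired values")
  }
  if (var(y_true) == 0) abort("`y_true` has zero variance")
  1 - sum((y_true - y_pred)^2) / sum((y_true - mean(y_true))^2)
}

#' Coefficient of variation of predictions (percent)
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation, over the
#' predictions at a single true concentration.
#'
#' @param predictions Numeric vector (>= 2 values, positive mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(predictions) {
  if (length(predictions) < 2) abort("need >= 2 predictions")
  m <- mean(predictions)
  if (m <= 0) abort("mean prediction must be positive")
  100 * sd(predictions) / m
}

#' Limit of quantification from per-concentration CVs
#'
#' The smallest tested concentration `c*` such that every tested
#' concentration `>= c*` has CV below the threshold: a single failing low
#' level moves the LoQ up to the next level, while a failure at the top makes
#' the whole grid unquantifiable (`NA`, read as "none").
#'
#' @param report A `regression_report`, or a data frame with columns
#'   `fraction` and `cv_percent`.
#' @param cv_threshold CV threshold in percent (default 2).
#' @return The LoQ concentration, or `NA_real_` when even the largest tested
#'   concentration fails.
#' @export
limit_of_quantification <- function(report, cv_threshold = 2) {
  cv <- if (inherits(report, "regression_report")) report$cv else as_tibble(report)
  if (nrow(cv) == 0) abort("empty report")
  cv <- cv[order(cv$fraction), ]
  pass <- cv$cv_percent < cv_threshold
  # smallest level from which everything above also passes
  ok_from <- rev(cumprod(rev(pass))) == 1
  if (!any(ok_from)) return(NA_real_)
  cv$fraction[which(ok_from)[1]]
}

#' Leave-one-concentration-out PLS validation
#'
#' For each concentration level, trains a PLS model on every spectrum of the
#' other levels and blind-predicts all spectra of the held-out level, so each
#' spectrum is predicted exactly once by a model that never saw its level.
#' Aggregates held-out R-squared, per-concentration CV and the LoQ.
#'
#' @param dataset A `concentration_dataset` (see [make_mixture_series()]), or
#'   a list with `spectra` and `fractions`.
#' @param n_components PLS components (default 2, the chemical rank of a
#'   two-component mixture).
#' @param cv_threshold LoQ threshold in percent (default 2).
#' @param sparsity_level,seed Optional provenance stored in the report.
#' @return A `regression_report`: `predictions` tibble, `r2`, `cv` tibble,
#'   `loq`, plus provenance.
#' @export
locoo_validate <- function(dataset, n_components = 2, cv_threshold = 2,
                           sparsity_level = NA_real_, seed = NA_integer_) {
  spectra <- as.matrix(dataset$spectra)
  fractions <- dataset$fractions
  levels_ <- sort(unique(fractions))
  if (length(levels_) < 3) abort("need >= 3 distinct concentrations")
  preds <- purrr::map_dfr(levels_, function(lv) {
    hold <- fractions == lv
    if (!any(hold)) abort(sprintf("concentration %g has no replicates", lv))
    model <- pls_fit(spectra[!hold, , drop = FALSE], fractions[!hold],
                     n_components)
    tibble(fraction = lv,
           replicate = seq_len(sum(hold)),
           prediction = pls_predict(model, spectra[hold, , drop = FALSE]))
  })
  cv <- preds |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(cv_percent = coefficient_of_variation(.data$prediction),
                     .groups = "drop")
  report <- structure(
    list(predictions = preds,
         r2 = r_squared(preds$fraction, preds$prediction),
         cv = cv, cv_threshold = cv_threshold,
         n_components = n_components,
         sparsity_level = sparsity_level, seed = seed),
    class = "regression_report"
  )
  report$loq <- limit_of_quantification(report, cv_threshold)
  report
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> %d predictions over %d levels | R2 = %.4f, max CV = %.3f%%, LoQ = %s\n",
              nrow(x$predictions), nrow(x$cv), x$r2, max(x$cv$cv_percent),
              if (is.na(x$loq)) "none" else sprintf("%g%%", x$loq)))
  invisible(x)
}

#' @export
tidy.regression_report <- function(x, ...) x$predictions

#' @export
glance.regression_report <- function(x, ...) {
  tibble(r2 = x$r2, max_cv_percent = max(x$cv$cv_percent), loq = x$loq,
         n_components = x$n_components, sparsity_level = x$sparsity_level,
         seed = x$seed)
}

#' @export
autoplot.regression_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$fraction, .data$prediction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "true water fraction (%)", y = "predicted (%)",
                  title = sprintf("Held-out R2 = %.4f", object$r2))
}
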