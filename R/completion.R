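# Nuclear-norm matrix completion.
#
# A chemically sparse hyperspectral matrix (pixels x wavenumbers) is low-rank:
# it mixes a handful of endmember spectra. Missing entries are recovered by
# minimizing
#
#   F(X) = 1/2 * || P_Omega(X - M) ||_F^2 + lambda * || X ||_*
#
# with FISTA: proximal gradient steps (the proximal operator of the nuclear
# norm is singular value soft-thresholding) accelerated by Nesterov momentum,
# with an optional monotone restart so the reported objective trace never
# increases.

#' Completion solver configuration
#'
#' @param lam Nuclear-norm weight: a positive number, or `"auto"` to resolve
#'   it with [choose_lambda()] using `lambda_rule`.
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param step Gradient step size in (0, 1]; the sampling operator is a
#'   projection with unit Lipschitz constant, so the default 1 is safe.
#' @param restart Monotone restart: a momentum step that increases the
#'   objective is replaced by a plain proximal step (default `TRUE`).
#' @param clamp_observed Used by [complete_cube()]: restore observed entries
#'   exactly in the returned cube (default `TRUE`; the measurements are
#'   trusted).
#' @param lambda_rule,lambda_c,lambda_seed Passed to [choose_lambda()] when
#'   `lam = "auto"`.
#' @return A `completion_config` list.
#' @export
completion_config <- function(lam = "auto", max_iter = 500, tol = 1e-6,
                              step = 1, restart = TRUE, clamp_observed = TRUE,
                              lambda_rule = "fixed_fraction_of_sigma_max",
                              lambda_c = 0.01, lambda_seed = 1) {
  if (!identical(lam, "auto") && (!is.numeric(lam) || lam <= 0)) {
    abort("`lam` must be a positive number or \"auto\"")
  }
  if (tol <= 0) abort("`tol` must be positive")
  if (step <= 0 || step > 1) abort("`step` must be in (0, 1]")
  structure(
    list(lam = lam, max_iter = as.integer(max_iter), tol = tol, step = step,
         restart = isTRUE(restart), clamp_observed = isTRUE(clamp_observed),
         lambda_rule = lambda_rule, lambda_c = lambda_c,
         lambda_seed = lambda_seed),
    class = "completion_config"
  )
}

# svd with shrunk singular values; also reports the nuclear norm of the result
svt_impl <- function(m, tau) {
  sv <- svd(m)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  x <- if (!any(keep)) {
    matrix(0, nrow(m), ncol(m))
  } else {
    sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
  }
  list(x = x, nuclear = sum(d))
}

#' Singular value thresholding
#'
#' The proximal operator of the nuclear norm: soft-thresholds the singular
#' values of `m` at `tau`. Shrinks the nuclear norm, never grows it.
#'
#' @param m Finite numeric matrix.
#' @param tau Threshold, >= 0.
#' @return A matrix of the same shape.
#' @examples
#' svt(diag(c(3, 1)), 2) # diag(1, 0)
#' @export
svt <- function(m, tau) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) abort("`m` must be finite")
  if (tau < 0) abort("`tau` must be nonnegative")
  svt_impl(m, tau)$x
}

p_omega <- function(x, observed) {
  x[!observed] <- 0
  x
}

#' FISTA nuclear-norm matrix completion
#'
#' Approximately minimizes `1/2 ||P_Omega(X - M)||_F^2 + lam ||X||_*` starting
#' from `X0 = P_Omega(M)`. Momentum follows
#' `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2`; with `restart` on, any momentum
#' step that would increase the objective is replaced by a plain proximal step
#' from the previous iterate, so the objective trace is non-increasing. Stops
#' when the relative objective change drops below `tol`, or at `max_iter`
#' (returned with `converged = FALSE`, not an error).
#'
#' @param m Numeric matrix of observed values (entries outside `observed` are
#'   ignored; `NA` allowed there).
#' @param observed Logical matrix of the same shape; every row needs at least
#'   one observed entry.
#' @param config A [completion_config()]; `lam` must be numeric here or
#'   `"auto"` (resolved with the config's lambda rule).
#' @return A `completion_result`: list with `x_hat`, `objective_trace`,
#'   `iterations`, `converged`, `lam_used`.
#' @export
fista_complete <- function(m, observed, config = completion_config()) {
  m <- as.matrix(m)
  observed <- as.matrix(observed)
  storage.mode(observed) <- "logical"
  if (!identical(dim(m), dim(observed))) abort("`m` and `observed` shapes differ")
  if (!any(observed)) abort("empty observation mask")
  if (any(rowSums(observed) == 0)) {
    abort("every row needs at least one observed entry")
  }
  if (any(!is.finite(m[observed]))) abort("observed entries must be finite")
  lam <- if (identical(config$lam, "auto")) {
    choose_lambda(m, observed, rule = config$lambda_rule, c = config$lambda_c,
                  seed = config$lambda_seed)
  } else {
    config$lam
  }
  mm <- p_omega(m, observed)
  step <- config$step
  x <- mm
  x_nuc <- sum(svd(x)$d)
  y <- x
  tk <- 1
  objective <- function(xmat, nuc) {
    r <- p_omega(xmat - mm, observed)
    0.5 * sum(r^2) + lam * nuc
  }
  f_prev <- objective(x, x_nuc)
  trace <- f_prev
  converged <- FALSE
  iter <- 0
  while (iter < config$max_iter) {
    iter <- iter + 1
    grad <- p_omega(y - mm, observed)
    pr <- svt_impl(y - step * grad, step * lam)
    x_new <- pr$x
    f_new <- objective(x_new, pr$nuclear)
    if (config$restart && f_new > f_prev) {
      # momentum overshoot: restart from the last iterate with a plain step
      tk <- 1
      grad <- p_omega(x - mm, observed)
      pr <- svt_impl(x - step * grad, step * lam)
      x_new <- pr$x
      f_new <- objective(x_new, pr$nuclear)
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x_new + ((tk - 1) / t_new) * (x_new - x)
    x <- x_new
    tk <- t_new
    trace <- c(trace, f_new)
    if (abs(f_new - f_prev) / max(1, abs(f_prev)) < config$tol) {
      f_prev <- f_new
      converged <- TRUE
      break
    }
    f_prev <- f_new
  }
  structure(
    list(x_hat = x, objective_trace = trace, iterations = as.integer(iter),
         converged = converged, lam_used = lam),
    class = "completion_result"
  )
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf("<completion_result> %d iterations, %s, lambda = %.4g, objective %.6g\n",
              x$iterations, if (x$converged) "converged" else "not converged",
              x$lam_used, tail(x$objective_trace, 1)))
  invisible(x)
}

#' @export
tidy.completion_result <- function(x, ...) {
  tibble(iteration = seq_along(x$objective_trace) - 1L,
         objective = x$objective_trace)
}

#' @export
glance.completion_result <- function(x, ...) {
  tibble(iterations = x$iterations, converged = x$converged,
         lam_used = x$lam_used, objective = tail(x$objective_trace, 1))
}

#' Choose the nuclear-norm weight
#'
#' `fixed_fraction_of_sigma_max` (default) returns `c * sigma_max(P_Omega(M))`
#' with `c = 0.01` — scale-equivariant, cheap, and in practice strong enough
#' to suppress sampling noise while keeping dominant chemical components.
#' `cross_validate_holdout` hides a further 10% of the observed entries,
#' scans a log-spaced grid of fractions, and returns the weight minimizing
#' the held-out RMSE.
#'
#' @param m,observed As in [fista_complete()].
#' @param rule `"fixed_fraction_of_sigma_max"` or `"cross_validate_holdout"`.
#' @param c Fraction of the top singular value (> 0).
#' @param holdout_frac Fraction of observed entries to hide (holdout rule).
#' @param grid Candidate fractions of `sigma_max` to scan (holdout rule).
#' @param seed Seed for the holdout split.
#' @param inner_config [completion_config()] for the holdout fits.
#' @return A positive scalar lambda.
#' @export
choose_lambda <- function(m, observed,
                          rule = c("fixed_fraction_of_sigma_max",
                                   "cross_validate_holdout"),
                          c = 0.01, holdout_frac = 0.1,
                          grid = 10^seq(-5, -1, length.out = 9), seed = 1,
                          inner_config = completion_config(max_iter = 1500,
                                                           tol = 1e-9)) {
  rule <- match.arg(rule)
  m <- as.matrix(m)
  observed <- as.matrix(observed)
  storage.mode(observed) <- "logical"
  if (c <= 0) abort("`c` must be positive")
  mm <- p_omega(m, observed)
  if (all(mm == 0)) abort("all observed entries are zero; lambda is undefined")
  sig_max <- svd(mm)$d[1]
  if (rule == "fixed_fraction_of_sigma_max") {
    return(c * sig_max)
  }
  obs_idx <- which(observed)
  n_hold <- max(1L, round(holdout_frac * length(obs_idx)))
  hold <- withr::with_seed(seed, sample(obs_idx, n_hold))
  train_obs <- observed
  train_obs[hold] <- FALSE
  # every row must keep at least one training observation
  for (r in which(rowSums(train_obs) == 0)) {
    row_hold <- hold[((hold - 1) %% nrow(m)) + 1 == r]
    train_obs[row_hold[1]] <- TRUE
    hold <- setdiff(hold, row_hold[1])
  }
  best <- NULL
  for (ci in grid) {
    cfg <- inner_config
    cfg$lam <- ci * sig_max
    fit <- fista_complete(m, train_obs, cfg)
    err <- sqrt(mean((fit$x_hat[hold] - m[hold])^2))
    if (is.null(best) || err < best$err) best <- list(lam = cfg$lam, err = err)
  }
  best$lam
}

#' Complete a sparse cube
#'
#' Flattens the cube (pixels row-major), runs [fista_complete()], and returns
#' the recovered cube. With `clamp_observed = TRUE` (default) observed entries
#' are restored exactly; with `FALSE` the low-rank estimate is returned at
#' every entry, i.e. the reconstruction also acts as a denoiser on observed
#' channels.
#'
#' @param cube A [hyper_cube()] (its `observed` flags are used when `mask` is
#'   `NULL`).
#' @param mask Optional [observation_mask()].
#' @param config A [completion_config()].
#' @return List with `cube` (recovered, fully observed) and `result`
#'   (the `completion_result`).
#' @export
complete_cube <- function(cube, mask = NULL, config = completion_config()) {
  stopifnot(inherits(cube, "hyper_cube"))
  observed <- if (!is.null(mask)) {
    if (!identical(dim(mask$observed), dim(cube$intensities))) {
      abort("mask shape does not match the cube")
    }
    mask$observed
  } else if (!is.null(cube$observed)) {
    cube$observed
  } else {
    matrix(TRUE, n_pixels(cube), length(cube$axis))
  }
  result <- fista_complete(cube$intensities, observed, config)
  out <- result$x_hat
  if (config$clamp_observed) {
    out[observed] <- cube$intensities[observed]
  }
  rec <- hyper_cube(out, cube$axis, cube$dims,
                    meta = c(cube$meta, list(completed = TRUE,
                                             lam_used = result$lam_used)))
  list(cube = rec, result = result)
}
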