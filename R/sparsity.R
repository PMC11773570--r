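#' Observation mask
#'
#' A boolean observed/missing pattern over (pixel, wavenumber). The realized
#' sparsity is always recomputed from the pattern itself, so the invariant
#' `sparsity == 1 - mean(observed)` holds exactly.
#'
#' @param observed Logical `n_pixels x L` matrix.
#' @param scheme Generating scheme tag.
#' @param seed Seed used to generate the mask.
#' @param target_sparsity The requested sparsity, for provenance.
#' @return An object of class `observation_mask`.
#' @export
observation_mask <- function(observed, scheme = "manual", seed = NA_integer_,
                             target_sparsity = NA_real_) {
  observed <- as.matrix(observed)
  storage.mode(observed) <- "logical"
  if (any(is.na(observed))) abort("`observed` must not contain NA")
  structure(
    list(observed = observed,
         sparsity = 1 - sum(observed) / length(observed),
         target_sparsity = target_sparsity,
         scheme = scheme, seed = seed),
    class = "observation_mask"
  )
}

#' @export
print.observation_mask <- function(x, ...) {
  cat(sprintf("<observation_mask> %d x %d, realized sparsity %.4f (%s, seed %s)\n",
              nrow(x$observed), ncol(x$observed), x$sparsity, x$scheme,
              format(x$seed)))
  invisible(x)
}

#' Random spectral under-sampling mask
#'
#' Emulates compressive acquisition: each pixel's spectrum is observed only at
#' a random subset of wavenumber channels. The default scheme draws exactly
#' `round((1 - s) * L)` channels per pixel uniformly without replacement
#' (fresh channels per pixel, maximizing incoherence); `global_bernoulli`
#' observes every entry independently with probability `1 - s`.
#'
#' @param n_pixels Number of pixel rows.
#' @param L Number of wavenumber channels.
#' @param sparsity Fraction of entries to drop, `0 <= s < 1`. Rejected when
#'   the per-pixel observed count would round to zero.
#' @param seed Integer seed; same arguments give an identical mask.
#' @param scheme `"per_spectrum_exact"` (default) or `"global_bernoulli"`.
#' @return An [observation_mask()].
#' @examples
#' m <- make_random_mask(10, 100, sparsity = 0.9, seed = 1)
#' rowSums(m$observed) # exactly 10 observed channels per pixel
#' @export
make_random_mask <- function(n_pixels, L, sparsity, seed = 1,
                             scheme = c("per_spectrum_exact", "global_bernoulli")) {
  scheme <- match.arg(scheme)
  if (sparsity < 0 || sparsity >= 1) abort("`sparsity` must be in [0, 1)")
  observed <- withr::with_seed(seed, {
    if (scheme == "per_spectrum_exact") {
      n_obs <- round((1 - sparsity) * L)
      if (n_obs == 0) {
        abort("sparsity so high that no channels per spectrum would be observed")
      }
      m <- matrix(FALSE, n_pixels, L)
      for (p in seq_len(n_pixels)) {
        m[p, sample.int(L, n_obs)] <- TRUE
      }
      m
    } else {
      matrix(runif(n_pixels * L) < (1 - sparsity), n_pixels, L)
    }
  })
  observation_mask(observed, scheme = scheme, seed = seed,
                   target_sparsity = sparsity)
}

#' Apply an observation mask to a cube
#'
#' Flags masked entries as missing (`NA` intensities plus an `observed`
#' matrix) without touching any observed value; the input cube is unchanged.
#'
#' @param cube A [hyper_cube()].
#' @param mask An [observation_mask()] of matching shape.
#' @return A sparse [hyper_cube()].
#' @export
apply_mask <- function(cube, mask) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(mask, "observation_mask"))
  if (!identical(dim(mask$observed), dim(cube$intensities))) {
    abort("mask shape does not match the cube")
  }
  intens <- cube$intensities
  intens[!mask$observed] <- NA_real_
  hyper_cube(intens, cube$axis, cube$dims, observed = mask$observed,
             meta = c(cube$meta, list(mask_scheme = mask$scheme,
                                      mask_seed = mask$seed,
                                      realized_sparsity = mask$sparsity)))
}
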