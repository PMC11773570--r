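# Small shared fixtures; everything is generated in code.

tiny_axis <- function(L = 64) wavenumber_axis(seq(600, 1800, length.out = L))

# one broad + one narrow component pair on the tiny axis
tiny_endmembers <- function() {
  list(
    water = endmember("water", data.frame(center = 1640, width = 120, amplitude = 1)),
    solute = endmember("solute", data.frame(center = c(1003, 1450),
                                            width = c(60, 80),
                                            amplitude = c(1, 0.7)))
  )
}

# a deterministic low-rank test cube: two-class stripe scene, no noise
tiny_cube <- function(rows = 4, cols = 6, L = 64, noise_sd = 0, seed = 1) {
  em <- tiny_endmembers()
  ax <- tiny_axis(L)
  s1 <- make_endmember_spectrum(em$water, ax)
  s2 <- make_endmember_spectrum(em$solute, ax)
  labels <- matrix(rep(c(1L, 2L), length.out = rows * cols), rows, cols)
  intens <- rbind(s1, s2)[as.vector(t(labels)), , drop = FALSE]
  if (noise_sd > 0) {
    intens <- intens + withr::with_seed(seed, matrix(rnorm(length(intens), sd = noise_sd),
                                                     nrow(intens)))
  }
  hyper_cube(intens, ax, c(rows, cols))
}

# fast completion config for small exact problems
quick_config <- function(lam, max_iter = 5000) {
  completion_config(lam = lam, max_iter = max_iter, tol = 1e-14)
}

rel_err <- function(a, b) norm(a - b, "F") / norm(b, "F")
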