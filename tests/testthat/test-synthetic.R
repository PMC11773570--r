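test_that("endmember spectra evaluate declared peaks on the axis", {
  ax <- tiny_axis()
  expect_error(endmember("bad", data.frame(center = numeric(), width = numeric(),
                                           amplitude = numeric())),
               "at least one peak")
  # gaussian apex equals the declared amplitude at the peak center
  ax2 <- wavenumber_axis(seq(600, 1800, by = 10)) # center on-grid
  em <- endmember("g", data.frame(center = 1200, width = 40, amplitude = 2.5),
                  profile = "gaussian")
  s <- make_endmember_spectrum(em, ax2)
  expect_equal(s[ax2 == 1200], 2.5, tolerance = 1e-12)
  expect_true(all(s >= 0))
  # peak center outside the axis is rejected
  em_out <- endmember("o", data.frame(center = 100, width = 10, amplitude = 1))
  expect_error(make_endmember_spectrum(em_out, ax), "outside the axis")
})

test_that("two non-overlapping peaks integrate like the sum of single peaks", {
  ax <- wavenumber_axis(seq(600, 1800, length.out = 2048)) # fine quadrature grid
  trapz <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(as.numeric(ax)))
  p1 <- data.frame(center = 850, width = 20, amplitude = 1)
  p2 <- data.frame(center = 1550, width = 30, amplitude = 0.5)
  for (prof in c("gaussian", "lorentzian")) {
    both <- make_endmember_spectrum(endmember("b", rbind(p1, p2), prof), ax)
    one <- make_endmember_spectrum(endmember("1", p1, prof), ax)
    two <- make_endmember_spectrum(endmember("2", p2, prof), ax)
    expect_equal(trapz(both), trapz(one) + trapz(two), tolerance = 1e-8)
  }
})

test_that("mixture series honours the mixing model and seeding", {
  em <- tiny_endmembers()
  ax <- tiny_axis()
  expect_error(make_mixture_series(n_replicates = 1), "2 replicates")
  expect_error(make_mixture_series(fractions = c(60, 60)), "distinct")
  expect_error(make_mixture_series(fractions = c(-5, 60)), "\\(0, 100\\]")
  # pure component: f = 100, no noise, no baseline -> exactly the water spectrum
  ds <- make_mixture_series(fractions = c(50, 100), n_replicates = 2, axis = ax,
                            endmembers = em, noise_sd = 0,
                            baseline_amplitude = 0, seed = 1)
  water <- make_endmember_spectrum(em$water, ax)
  for (i in which(ds$fractions == 100)) {
    expect_equal(unname(ds$spectra[i, ]), water, tolerance = 1e-12)
  }
  # same seed -> byte-identical; different seed -> different noise
  a <- make_mixture_series(axis = ax, endmembers = em, n_replicates = 2, seed = 7)
  b <- make_mixture_series(axis = ax, endmembers = em, n_replicates = 2, seed = 7)
  c_ <- make_mixture_series(axis = ax, endmembers = em, n_replicates = 2, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$spectra, c_$spectra))
})

test_that("noise-free mixture matrices have the predicted numerical rank", {
  # oracle: full singular value decomposition
  num_rank <- function(m) {
    d <- svd(m)$d
    sum(d > max(d) * 1e-8)
  }
  ds0 <- make_mixture_series(fractions = c(60, 70, 80), n_replicates = 3,
                             axis = tiny_axis(), endmembers = tiny_endmembers(),
                             noise_sd = 0, baseline_amplitude = 0, seed = 1)
  expect_identical(num_rank(ds0$spectra), 2L)
  dsb <- make_mixture_series(fractions = c(60, 70, 80), n_replicates = 3,
                             axis = tiny_axis(), endmembers = tiny_endmembers(),
                             noise_sd = 0, baseline_amplitude = 0.3, seed = 1)
  expect_identical(num_rank(dsb$spectra), 3L) # fixed baseline shape adds one
})

test_that("cell scene places the requested rare drug blob inside the cell", {
  expect_error(make_cell_scene(rare_fraction = 0), "\\(0, 20\\]")
  expect_error(make_cell_scene(rare_fraction = 25), "\\(0, 20\\]")
  sc <- make_cell_scene(axis = tiny_axis(), seed = 3)
  expect_identical(dim(sc$labels), c(32L, 36L)) # study grid is the default
  # 3% of 1152 pixels -> 35 drug pixels (arithmetic check on the map)
  expect_identical(sum(sc$labels == 3L), 35L)
  expect_identical(sort(unique(as.vector(sc$labels))), c(1L, 2L, 3L))
  # drug pixels only where the cell is: never adjacent to leaving the grid as background
  drug_idx <- which(sc$labels == 3L, arr.ind = TRUE)
  expect_true(nrow(drug_idx) == 35)
  # tiny rare fraction still yields at least one drug pixel
  sc1 <- make_cell_scene(dims = c(8, 8), rare_fraction = 0.5, axis = tiny_axis(),
                         seed = 1)
  expect_identical(sum(sc1$labels == 3L), 1L)
  # determinism
  expect_identical(make_cell_scene(axis = tiny_axis(), seed = 3)$cube$intensities,
                   sc$cube$intensities)
})

test_that("cell endmember validation enforces the 1168 marker contract", {
  em <- default_cell_endmembers()
  em$drug <- endmember("drug", data.frame(center = 1300, width = 15, amplitude = 1))
  expect_error(make_cell_scene(axis = tiny_axis(), endmembers = em, seed = 1),
               "no peak at 1168")
})

test_that("tissue scene is rank-3 without baseline and baseline-dominated with", {
  expect_error(make_tissue_scene(endmembers = default_tissue_endmembers()[1:2]),
               "3 endmember")
  clean <- make_tissue_scene(dims = c(8, 12), axis = tiny_axis(), noise_sd = 0,
                             baseline_amplitude = 0, shot_noise = FALSE, seed = 2)
  d <- svd(clean$cube$intensities)$d
  expect_identical(sum(d > max(d) * 1e-8), 3L)
  expect_true(all(sort(unique(as.vector(clean$labels))) == 1:3))
  expect_true(all(clean$cube$intensities >= -1e-12)) # noiseless signal nonnegative
  # with a 10x baseline, every raw spectrum is dominated by the background:
  # its maximum far exceeds the largest declared peak amplitude
  big <- make_tissue_scene(dims = c(4, 6), axis = tiny_axis(), noise_sd = 0,
                           baseline_amplitude = 10, shot_noise = FALSE, seed = 2)
  peak_amp_max <- max(unlist(lapply(default_tissue_endmembers(),
                                    function(e) e$peaks$amplitude)))
  expect_true(all(apply(big$cube$intensities, 1, max) > 3 * peak_amp_max))
})

test_that("full-size tissue default matches the study geometry", {
  sc <- make_tissue_scene(dims = c(65, 145), axis = tiny_axis(16), seed = 1)
  expect_identical(dim(sc$labels), c(65L, 145L))
  expect_identical(n_pixels(sc$cube), 65L * 145L)
})

test_that("spikes are single-channel, seeded and binomially counted", {
  cube <- tiny_cube(rows = 2, cols = 2)
  expect_error(add_spikes(cube, 0.5, amplitude = -1), "positive")
  expect_identical(add_spikes(cube, 0, amplitude = 5), cube)
  one <- tiny_cube(rows = 1, cols = 1)
  spiked <- add_spikes(one, 1, amplitude = 9, seed = 4)
  delta <- spiked$intensities - one$intensities
  expect_identical(sum(delta != 0), 1L)
  expect_equal(max(delta), 9)
  # count over 10,000 pixels at rate 0.01 within 3 sigma of 100
  big <- hyper_cube(matrix(1, 10000, 16), tiny_axis(16), c(100, 100))
  bs <- add_spikes(big, 0.01, amplitude = 5, seed = 11)
  n_hit <- sum(rowSums(bs$intensities != 1) > 0)
  expect_lt(abs(n_hit - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  expect_identical(add_spikes(big, 0.01, amplitude = 5, seed = 11)$intensities,
                   bs$intensities)
})
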