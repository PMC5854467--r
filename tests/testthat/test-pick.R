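test_that("preprocess resamples to half the picking resolution and removes ramps", {
  set.seed(15)
  ph <- small_phantom(48, 3)
  mg <- simulate_micrograph(ph, 0, box = 512, snr = 1, seed = 2)
  pp <- pick_params(template_radius = 45, max_particle_radius = 60,
                    threshold_sd = 4, highest_resolution = 30)
  work <- cryopipe:::pick_preprocess(mg$micrograph, pp)
  expect_equal(work$pixel_size, 15, tolerance = 0.05 * 15)
  # linear ramp killed by more than 10x
  n <- 512
  ramp <- em_image(outer(seq(-1, 1, length.out = n), rep(1, n)) * 10 +
                     matrix(rnorm(n * n, 0, 0.1), n), 3)
  wr <- cryopipe:::pick_preprocess(ramp, pp)
  fitslope <- function(img) {
    m <- box_size(img)
    ax <- seq_len(m)
    abs(coef(lm(rowMeans(img$data) ~ ax))[2]) * m
  }
  expect_lt(fitslope(wr), fitslope(fourier_crop(ramp, 15)) / 10)
  # constant image -> ~zero
  cstm <- em_image(matrix(5, 512, 512), 3)
  expect_lt(max(abs(cryopipe:::pick_preprocess(cstm, pp)$data)), 1e-8)
})

test_that("local statistics find homogeneous variance and flag bright insertions", {
  set.seed(16)
  img <- em_image(matrix(rnorm(256 * 256), 256), 15)
  st <- local_stats(img, 60)
  expect_gt(mean(abs(st$variance_map - 1) < 0.5), 0.95)
  expect_equal(median(st$variance_map), 1, tolerance = 0.2)
  # a bright square lifts the mean map at its location
  img2 <- img
  img2$data[100:120, 100:120] <- img2$data[100:120, 100:120] + 5
  st2 <- local_stats(img2, 60)
  expect_gt(st2$mean_map[110, 110], st2$mo_mean + 2 * st2$fwhm_mean)
  # mode/FWHM of a known Gaussian map
  set.seed(17)
  gm <- mode_stats <- cryopipe:::mode_fwhm(matrix(rnorm(1e5, 3, 0.5)))
  expect_equal(gm$mode, 3, tolerance = 0.05 * 3)
  expect_equal(gm$fwhm, 2.355 * 0.5, tolerance = 0.06)
})

test_that("background whitening flattens a blank micrograph and honors area count", {
  set.seed(18)
  ph <- small_phantom(48, 3)
  mg <- simulate_micrograph(ph, 0, box = 512, snr = 1, seed = 3)
  pp <- pick_params(template_radius = 45, max_particle_radius = 60,
                    threshold_sd = 4, n_background_areas = 20)
  work <- cryopipe:::pick_preprocess(mg$micrograph, pp)
  st <- local_stats(work, 60)
  wh <- background_whitening_filter(work, st, pp)
  expect_equal(nrow(wh$areas), 20)
  n <- box_size(work)
  g <- cryopipe:::freq_magnitude(c(n, n), work$pixel_size)
  wf <- matrix(cryopipe:::profile_at(wh$filter, as.vector(g)), n, n)
  wf[1, 1] <- 0
  white <- Re(ifft2(fft2(work$data) * wf))
  prof <- radial_average(Mod(fft2(white))^2, work$pixel_size)
  # flat away from the high-pass transition band
  mid <- prof$values[18:(length(prof$values) - 2)]
  expect_lt(max(abs(mid - mean(mid))) / mean(mid), 0.45)
  # chosen areas avoid an inserted high-variance blob
  mg2 <- mg$micrograph
  mg2$data[201:260, 201:260] <- mg2$data[201:260, 201:260] * 8
  work2 <- cryopipe:::pick_preprocess(mg2, pp)
  st2 <- local_stats(work2, 60)
  wh2 <- background_whitening_filter(work2, st2, pp)
  blob_center_work <- c(230, 230) * 3 / work2$pixel_size
  d <- sqrt((wh2$areas[, 1] - blob_center_work[1])^2 +
            (wh2$areas[, 2] - blob_center_work[2])^2)
  expect_gt(min(d), 2)
})

test_that("null score map is standard normal and blank picking follows the Gaussian tail", {
  set.seed(19)
  ph <- small_phantom(48, 3)
  blank <- simulate_micrograph(ph, 0, box = 1024, snr = 0.4, seed = 5)
  pp <- pick_params(template_radius = 45, max_particle_radius = 60,
                    threshold_sd = 6)
  work <- cryopipe:::pick_preprocess(blank$micrograph, pp)
  st <- local_stats(work, 60)
  wh <- background_whitening_filter(work, st, pp)
  sc <- match_template(work, wh, NULL, pp)
  expect_equal(mean(sc$data), 0, tolerance = 0.05)
  expect_equal(sd(sc$data), 1, tolerance = 0.1)
  tail3 <- mean(sc$data > 3)
  p3 <- pnorm(3, lower.tail = FALSE)
  npix <- length(sc$data)
  expect_lt(abs(tail3 - p3), 3 * sqrt(p3 / npix) + 2 * p3)
  # threshold 6 on a blank: expected count << 1
  expect_equal(nrow(pick_particles(blank$micrograph, pp)), 0)
})

test_that("an inserted disk is located to within one working pixel", {
  set.seed(20)
  n <- 256
  blank <- em_image(matrix(rnorm(n * n), n), 15)
  r <- sqrt(outer(((0:(n - 1)) - 80)^2, ((0:(n - 1)) - 120)^2, `+`)) * 15
  img <- em_image(blank$data + 5 * cryopipe:::soft_edge(r, 45, 10), 15)
  pp <- pick_params(template_radius = 45, max_particle_radius = 60,
                    threshold_sd = 4, highest_resolution = 30)
  st <- local_stats(img, 60)
  wh <- background_whitening_filter(img, st, pp)
  sc <- match_template(img, wh, NULL, pp)
  k <- which.max(sc$data)
  expect_lte(max(abs(c((k - 1) %% n, (k - 1) %/% n) - c(80, 120))), 1)
})

test_that("exclusion thresholds follow the mode/FWHM rule and the phase-plate switch", {
  set.seed(21)
  st <- list(mean_map = matrix(rnorm(100 * 100), 100),
             variance_map = matrix(abs(rnorm(100 * 100, 10, 1)), 100),
             mo_mean = 0, fwhm_mean = 2.355, mo_var = 10, fwhm_var = 2.355)
  pp2 <- pick_params(45, 60, threshold_sd = 4)
  ex <- exclusion_mask(st, pp2)
  expect_lt(mean(ex), 0.01)
  # high-variance patch is excluded
  st$variance_map[40:50, 40:50] <- 30
  ex2 <- exclusion_mask(st, pp2)
  expect_true(all(ex2[40:50, 40:50]))
  # phase plate in (0.1 pi, 0.9 pi) switches k from 2 to 8: fewer exclusions
  st$variance_map[60:70, 60:70] <- 10 + 5 * 2.355  # between 2 and 8 FWHM
  pp_pp <- pick_params(45, 60, threshold_sd = 4,
                       phase_plate_phase = 0.5 * pi)
  expect_true(all(exclusion_mask(st, pp2)[60:70, 60:70]))
  expect_false(any(exclusion_mask(st, pp_pp)[60:70, 60:70]))
  # degenerate FWHM: nothing excluded, with a warning
  st$fwhm_var <- 0
  expect_warning(ex3 <- exclusion_mask(st, pp2))
  expect_false(any(ex3))
})

test_that("peak finding suppresses close picks and respects exclusions", {
  sc <- em_image(matrix(0, 64, 64), 15)
  sc$data[20, 20] <- 8
  sc$data[22, 21] <- 7       # closer than the minimum distance
  sc$data[40, 40] <- 6
  pp <- pick_params(template_radius = 30, max_particle_radius = 60,
                    threshold_sd = 4)
  picks <- find_peaks(sc, NULL, pp)
  expect_equal(nrow(picks), 2)
  expect_equal(picks$peak_sd[1], 8)
  # excluded pixels are never picked
  excl <- matrix(FALSE, 64, 64); excl[20, 20] <- TRUE
  picks2 <- find_peaks(sc, excl, pp)
  expect_false(any(picks2$peak_sd == 8))
})

test_that("picking on a synthetic micrograph reaches high precision and recall", {
  ph <- small_phantom(48, 3)
  ctf <- base_ctf(3)
  mg <- simulate_micrograph(ph, 20, box = 1024, snr = 0.75, ctf = ctf,
                            seed = 3)
  pp <- pick_params(template_radius = 40, max_particle_radius = 60,
                    threshold_sd = 4)
  picks <- pick_particles(mg$micrograph, pp, ctf = ctf)
  d2 <- outer(picks$x, mg$coords$x, `-`)^2 + outer(picks$y, mg$coords$y, `-`)^2
  precision <- mean(sqrt(apply(d2, 1, min)) < 65)
  recall <- sum(sqrt(apply(d2, 2, min)) < 65) / nrow(mg$coords)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
  # determinism and threshold monotonicity
  picks_b <- pick_particles(mg$micrograph, pp, ctf = ctf)
  expect_identical(picks, picks_b)
  pp6 <- pick_params(template_radius = 40, max_particle_radius = 60,
                     threshold_sd = 6)
  expect_lte(nrow(pick_particles(mg$micrograph, pp6, ctf = ctf)),
             nrow(picks))
})

test_that("high-variance artifact patches are excluded and never picked", {
  ph <- small_phantom(48, 3)
  ctf <- base_ctf(3)
  mg <- simulate_micrograph(ph, 20, box = 1024, snr = 0.75, ctf = ctf,
                            n_artifacts = 1, seed = 4)
  pp <- pick_params(template_radius = 40, max_particle_radius = 60,
                    threshold_sd = 4)
  # the artifact's local variance exceeds the exclusion threshold
  hp <- min(4 * pp$max_particle_radius, 1024 * 3 / 4)
  native <- cryopipe:::fourier_bandpass(mg$micrograph, highpass = hp,
                                        edge_shells = 2)
  st <- local_stats(native, pp$max_particle_radius)
  ex <- exclusion_mask(st, pp)
  ai <- round(mg$artifact_coords$x[1] / 3) + 1
  aj <- round(mg$artifact_coords$y[1] / 3) + 1
  expect_true(ex[ai, aj])
  # no pick lands on the artifact
  picks <- pick_particles(mg$micrograph, pp, ctf = ctf)
  da <- sqrt((picks$x - mg$artifact_coords$x[1])^2 +
             (picks$y - mg$artifact_coords$y[1])^2)
  expect_true(all(da > 60))
})
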