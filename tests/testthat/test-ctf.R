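# helper: forward-simulate a centered power spectrum for known parameters
simulate_spectrum <- function(params, n = 320, envelope_b = 120,
                              noise_sd = 0, background = TRUE,
                              seed = 1) {
  set.seed(seed)
  px <- params$pixel_size
  g <- cryopipe:::fftshift2(cryopipe:::freq_magnitude(c(n, n), px))
  ax <- cryopipe:::freq_axis(n, px)
  gx <- cryopipe:::fftshift2(matrix(ax, n, n))
  gy <- cryopipe:::fftshift2(matrix(ax, n, n, byrow = TRUE))
  az <- atan2(gy, gx)
  sp <- evaluate_ctf(params, g, az)^2 * exp(-envelope_b * g^2) * 1000
  if (background) sp <- sp + 500 * exp(-g * 30)
  if (noise_sd > 0) sp <- sp + matrix(rnorm(n * n, 0, noise_sd), n, n)
  em_image(sp, px)
}

test_that("evaluate_ctf is azimuth-free without astigmatism, bounded, with analytic zeros", {
  p <- ctf_params(defocus1 = 15000, defocus2 = 15000, pixel_size = 1)
  g <- seq(0, 0.4, length.out = 200)
  expect_equal(evaluate_ctf(p, g, 0), evaluate_ctf(p, g, 1.1), tolerance = 1e-12)
  pa <- ctf_params(defocus1 = 16000, defocus2 = 14000, astig_angle = 20,
                   pixel_size = 1)
  gr <- expand.grid(g = seq(0, 0.45, length.out = 100),
                    az = seq(0, pi, length.out = 24))
  v <- evaluate_ctf(pa, gr$g, gr$az)
  expect_true(all(v^2 <= 1 + 1e-12))
  # zero count up to g matches the aberration-phase crossing count
  w <- p$amplitude_contrast
  chi <- cryopipe:::ctf_phase(p, g) + atan2(w, sqrt(1 - w^2))
  analytic_zeros <- floor(max(chi) / pi) - floor(min(chi[g > 0]) / pi)
  sgn <- sign(evaluate_ctf(p, g))
  observed <- sum(diff(sgn[sgn != 0]) != 0)
  expect_lte(abs(observed - analytic_zeros), 1)
})

test_that("defocus1 >= defocus2 convention is enforced", {
  p <- ctf_params(defocus1 = 12000, defocus2 = 15000, astig_angle = 10)
  expect_gte(p$defocus1, p$defocus2)
  expect_equal(p$astig_angle, 100)
})

test_that("amplitude spectrum of white noise is flat and fine pixels are clipped to 1/2.8", {
  set.seed(10)
  img <- em_image(matrix(rnorm(512 * 512), 512), 3)
  ps <- amplitude_spectrum(img, tile = 64)
  prof <- cryopipe:::spectrum_radial(ps)
  mid <- prof$values[5:(length(prof$values) - 2)]
  expect_lt(max(abs(mid - mean(mid))) / mean(mid), 0.05)
  # pixel 1.0 input: spectrum edge at 1/2.8
  img1 <- em_image(matrix(rnorm(256 * 256), 256), 1)
  ps1 <- amplitude_spectrum(img1, tile = 128)
  expect_equal(1 / (2 * ps1$pixel_size), 1 / 2.8, tolerance = 0.03)
})

test_that("movie sub-sums give stronger Thon rings than the blurred full sum", {
  set.seed(11)
  ph <- small_phantom(48, 3)
  truep <- ctf_params(defocus1 = 18000, pixel_size = 3)
  mg <- simulate_micrograph(ph, 15, box = 384, snr = 0.4, ctf = truep,
                            seed = 7)
  mv <- simulate_movie(mg$micrograph, n_frames = 9, drift_amplitude = 18,
                       frame_snr = 1.5, seed = 8)
  # ring visibility: correlation of the background-subtracted radial
  # profile with the known CTF^2 model over the ring band
  ring_contrast <- function(spec) {
    bs <- subtract_background(spec)
    prof <- cryopipe:::spectrum_radial(bs)
    band <- prof$bin_centers > 0.02 & prof$bin_centers < 0.12
    model <- evaluate_ctf(truep, prof$bin_centers[band])^2
    cor(prof$values[band], model)
  }
  tr0 <- data.frame(frame = 1:9, x = 0, y = 0)  # unaligned sum
  full <- exposure_filtered_sum(mv$movie, tr0)
  ps_full <- amplitude_spectrum(full, tile = 192)
  ps_sub <- amplitude_spectrum(mv$movie, frames_to_sum = 3, tile = 192)
  expect_gt(ring_contrast(ps_sub), ring_contrast(ps_full))
})

test_that("background subtraction flattens smooth backgrounds and keeps ring positions", {
  p <- ctf_params(defocus1 = 15000, pixel_size = 2)
  sp <- simulate_spectrum(p, n = 256, background = TRUE)
  bs <- subtract_background(sp)
  # constant spectrum -> ~zero
  cst <- em_image(matrix(7, 128, 128), 2)
  expect_lt(max(abs(subtract_background(cst)$data)), 1e-6)
  # ring-free noise spectrum: residual RMS well below input RMS
  set.seed(12)
  noise_sp <- em_image(matrix(500, 128, 128) +
                         matrix(rnorm(128^2, 0, 5), 128), 2)
  bs_n <- subtract_background(noise_sp)
  expect_lt(sqrt(mean(bs_n$data^2)), 0.1 * sqrt(mean(noise_sp$data^2)))
  # ring peaks move by less than one shell
  prof <- cryopipe:::spectrum_radial(bs)
  raw <- cryopipe:::spectrum_radial(sp)
  band <- which(prof$bin_centers > 0.03 & prof$bin_centers < 0.15)
  # every raw local maximum keeps a subtracted local maximum nearby
  is_peak <- function(v) which(diff(sign(diff(v))) == -2) + 1
  pr <- band[is_peak(raw$values[band])]
  psub <- band[is_peak(prof$values[band])]
  for (pk in pr)
    expect_lte(min(abs(psub - pk)), 2)
})

test_that("1D exhaustive search recovers defocus and phase shift within a grid step", {
  base <- ctf_params(pixel_size = 2)
  p <- ctf_params(defocus1 = 15000, pixel_size = 2)
  sp <- simulate_spectrum(p, noise_sd = 10)
  prof <- cryopipe:::spectrum_radial(subtract_background(sp))
  r <- fit_ctf_1d(prof, base, c(8000, 25000), 250)
  expect_lte(abs(r$defocus - 15000), 250)
  # matching candidate wins between two
  r2 <- fit_ctf_1d(prof, base, c(15000, 20000), 5000)
  expect_equal(r2$defocus, 15000)
  # phase plate: 90 degree phase shift recovered
  pp <- ctf_params(defocus1 = 12000, phase_shift = pi / 2, pixel_size = 2)
  spp <- simulate_spectrum(pp, noise_sd = 10, seed = 2)
  profp <- cryopipe:::spectrum_radial(subtract_background(spp))
  rp <- fit_ctf_1d(profp, base, c(8000, 20000), 250,
                   phase_shift_range = c(0, pi), phase_shift_step = pi / 18)
  expect_lte(abs(rp$phase_shift - pi / 2), pi / 18 + 1e-9)
  expect_error(fit_ctf_1d(radial_profile(c(1e-12, 0.1), c(0, 0)), base,
                          c(1000, 2000), 500))
})

test_that("2D refinement recovers astigmatism and never degrades the objective", {
  truep <- ctf_params(defocus1 = 16000, defocus2 = 14000, astig_angle = 30,
                      pixel_size = 2)
  bs <- subtract_background(simulate_spectrum(truep, noise_sd = 15))
  init <- ctf_params(defocus1 = 15300, defocus2 = 14700, astig_angle = 0,
                     pixel_size = 2)
  best <- NULL
  for (a0 in c(0, 45, 90, 135)) {
    init$astig_angle <- a0
    r <- refine_ctf_2d(bs, init)
    expect_gte(r$cc, r$cc_initial - 1e-9)
    if (is.null(best) || r$cc > best$cc) best <- r
  }
  expect_lt(abs(best$params$defocus1 - 16000), 100)
  expect_lt(abs(best$params$defocus2 - 14000), 100)
  expect_lt(min(abs(best$params$astig_angle - 30),
                180 - abs(best$params$astig_angle - 30)), 3)
  # zero-astigmatism input from an astigmatic init converges to round
  bs0 <- subtract_background(simulate_spectrum(
    ctf_params(defocus1 = 15000, pixel_size = 2), noise_sd = 15, seed = 3))
  r0 <- refine_ctf_2d(bs0, ctf_params(defocus1 = 15800, defocus2 = 14200,
                                      astig_angle = 45, pixel_size = 2))
  expect_lt(abs(r0$params$defocus1 - r0$params$defocus2), 100)
})

test_that("moving-window fit quality tracks ring damping", {
  p <- ctf_params(defocus1 = 15000, pixel_size = 2)
  # perfect rings: ccfit ~ 1 through the spectrum
  perfect <- simulate_spectrum(p, envelope_b = 0, background = FALSE)
  gof <- goodness_of_fit(perfect, p)
  inner <- gof$ccfit$values[gof$ccfit$bin_centers > 1 / 30 &
                            gof$ccfit$bin_centers < 0.9 / (2 * 2)]
  expect_gt(median(inner), 0.9)
  expect_true(all(gof$ccfit$values >= -1 & gof$ccfit$values <= 1))
  # rings killed beyond 5 A: fit resolution lands near 5 A
  n <- 320
  g <- cryopipe:::fftshift2(cryopipe:::freq_magnitude(c(n, n), 2))
  damped <- simulate_spectrum(p, envelope_b = 0, background = FALSE)
  set.seed(13)
  damped$data <- damped$data * (g < 1 / 5) +
    matrix(rnorm(n * n, 0, 100), n, n) * (g >= 1 / 5)
  gof2 <- goodness_of_fit(damped, p, window = 5)
  dshell <- 1 / (n * 2)
  expect_lt(abs(1 / gof2$fit_resolution - 1 / 5), 4 * dshell)
  # pure noise: fit resolution stays at low resolution
  set.seed(14)
  noise <- em_image(matrix(rnorm(n * n), n, n), 2)
  gof3 <- goodness_of_fit(noise, p)
  expect_gt(gof3$fit_resolution, 10)
})

test_that("CTF aliasing warning follows the phase-derivative rule", {
  p_hi <- ctf_params(defocus1 = 30000, pixel_size = 1)
  expect_true(check_aliasing(128, p_hi))
  p_lo <- ctf_params(defocus1 = 5000, pixel_size = 1)
  expect_false(check_aliasing(1024, p_lo))
  p0 <- ctf_params(defocus1 = 0, defocus2 = 0, cs = 0, pixel_size = 1)
  expect_false(check_aliasing(128, p0))
})
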