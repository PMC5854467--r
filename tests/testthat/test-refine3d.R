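test_that("the projection operator matches the analytic Gaussian oracle", {
  blobs <- data.frame(x = 12, y = -6, z = 9, sigma = 6, amplitude = 1)
  ph <- make_phantom(blobs, 48, 2)
  p <- project_volume(ph, 25, 40, 70)
  R <- euler_matrix(25, 40, 70)
  c2 <- crossprod(R, c(12, -6, 9))[1:2]
  ax <- (0:47 - 24) * 2
  analytic <- exp(-outer((ax - c2[1])^2, (ax - c2[2])^2, `+`) / (2 * 36)) *
    (6 * sqrt(2 * pi) / 2)
  expect_gt(cor(as.vector(p$data), as.vector(analytic)), 0.995)
  # centered blob: projections from any angle identical
  ph0 <- make_phantom(data.frame(x = 0, y = 0, z = 0, sigma = 8,
                                 amplitude = 1), 32, 3)
  pa <- project_volume(ph0, 0, 0, 0)
  pb <- project_volume(ph0, 111, 67, 23)
  expect_gt(cor(as.vector(pa$data), as.vector(pb$data)), 0.999)
})

test_that("SNR curve is PSSNR x CTF^2 with exact zeros", {
  n <- 32; px <- 3
  pssnr <- radial_profile(pmax((0:16) / (n * px), 1e-12), rep(1, 17))
  ctf <- base_ctf(px)
  snr <- snr_curve(pssnr, ctf, n, px)
  expect_equal(snr, ctf_image(ctf, n, px)^2, tolerance = 1e-9)
  pss0 <- radial_profile(pmax((0:16) / (n * px), 1e-12), rep(0, 17))
  expect_true(all(snr_curve(pss0, ctf, n, px) == 0))
})

test_that("matched whitening and reference scaling behave in the SNR limits", {
  set.seed(28)
  img <- em_image(matrix(rnorm(32 * 32), 32), 3)
  # SNR = 0: reference scales to zero
  z <- scale_reference(img, matrix(0, 32, 32))
  expect_lt(max(abs(z$data)), 1e-10)
  # noise-only image whitened at SNR 0 has a flat unit-shape spectrum
  w <- whiten_image_matched(img, 0)
  prof <- radial_average(Mod(fft2(w$data))^2, 3)
  mid <- prof$values[3:14]
  expect_lt(max(abs(mid / mean(mid) - 1)), 0.35)
  # whitening gain is monotone in SNR
  s1 <- whiten_image_matched(img, 1)
  s9 <- whiten_image_matched(img, 9)
  r1 <- sum(Mod(fft2(s1$data))^2); r9 <- sum(Mod(fft2(s9$data))^2)
  expect_gt(r9, r1)
})

test_that("the objective honors Cauchy-Schwarz limits and the signed-band rule", {
  set.seed(29)
  img <- em_image(matrix(rnorm(32 * 32), 32), 3)
  cfg <- search_config(R1 = 300, R3 = 7)
  expect_equal(objective_cc(img, img, cfg), 1, tolerance = 1e-9)
  # disjoint Fourier support gives zero
  n <- 32
  f1 <- matrix(0 + 0i, n, n); f2 <- matrix(0 + 0i, n, n)
  f1[3, 1] <- 10; f1[n - 1, 1] <- Conj(f1[3, 1])
  f2[5, 1] <- 10; f2[n - 3, 1] <- Conj(f2[5, 1])
  i1 <- em_image(Re(ifft2(f1)), 3); i2 <- em_image(Re(ifft2(f2)), 3)
  expect_equal(objective_cc(i1, i2, cfg), 0, tolerance = 1e-10)
  # unsigned cross terms never reduce the objective; equality when the
  # signed band covers everything
  img2 <- em_image(matrix(rnorm(32 * 32), 32), 3)
  cfg_signed <- search_config(R1 = 300, R2 = 7, R3 = 7)
  cfg_unsig <- search_config(R1 = 300, R2 = 15, R3 = 7)
  for (k in 1:5) {
    a <- em_image(matrix(rnorm(32 * 32), 32), 3)
    b <- em_image(matrix(rnorm(32 * 32), 32), 3)
    expect_gte(objective_cc(a, b, cfg_unsig), objective_cc(a, b, cfg_signed))
  }
  expect_equal(objective_cc(img, img2, search_config(R1 = 300, R2 = 7, R3 = 7)),
               objective_cc(img, img2, cfg))
})

test_that("the shift restraint is quadratic, zero at the mean, and scores scale by 100", {
  rm <- restraint_model(mean_shift = c(1, -2), sd_shift = c(4, 5),
                        sigma = 1.3, mask_pixels = 900)
  expect_equal(shift_restraint(alignment_params(sx = 1, sy = -2), rm), 0)
  r1 <- shift_restraint(alignment_params(sx = 3, sy = -2), rm)
  r2 <- shift_restraint(alignment_params(sx = 5, sy = -2), rm)
  expect_lt(r1, 0)
  expect_equal(r2 / r1, 4, tolerance = 1e-9)
  expect_equal(particle_score(1, 0), 100)
  # perfect match at the restraint mean scores exactly 100
  set.seed(30)
  img <- em_image(matrix(rnorm(32 * 32), 32), 3)
  cc <- objective_cc(img, img, search_config(R1 = 300, R3 = 7))
  at_mean <- alignment_params(sx = 1, sy = -2)
  expect_equal(particle_score(cc, shift_restraint(at_mean, rm)),
               100, tolerance = 1e-6)
})

test_that("global search recovers a grid orientation exactly and degrades gracefully with noise", {
  ph <- small_phantom(32, 3)
  sim <- simulate_particles(ph, 1, snr = Inf,
                            angles = data.frame(phi = 30, theta = 60,
                                                psi = 45), seed = 3)
  img <- cryopipe:::stack_image(sim$stack, 1)
  cfg <- search_config(R1 = 300, R3 = 8, angular_step = 15,
                       translation_px = 1)
  res <- global_search(img, ph, config = cfg)
  expect_lt(abs(res$phi - 30) %% 360, 3)
  expect_lt(abs(res$theta - 60), 3)
  expect_lt(abs(res$psi - 45) %% 360, 3)
  expect_lt(sqrt(res$sx^2 + res$sy^2), 1.5)
  expect_gt(attr(res, "score"), 90)
  # deterministic: same result on re-run
  res2 <- global_search(img, ph, config = cfg)
  expect_equal(unclass(res)[1:5], unclass(res2)[1:5], tolerance = 1e-12)
})

test_that("noisy particles are aligned with small median angular error", {
  set.seed(31)
  ph <- small_phantom(48, 3)
  sim <- simulate_particles(ph, 25, snr = 0.2, seed = 10)
  cfg <- search_config(R1 = 300, R3 = 10, angular_step = 15,
                       translation_px = 1)
  errs <- numeric(25)
  machine <- NULL
  for (i in 1:25) {
    img <- whiten_background(cryopipe:::stack_image(sim$stack, i), 55)
    if (is.null(machine)) {
      prep0 <- cryopipe:::add_shell_info(cryopipe:::prepare_particle_mf(
        img, NULL, cryopipe:::flat_pssnr(img), cfg))
      machine <- cryopipe:::mf_machine(ph, cfg, prep0$fl)
    }
    res <- global_search(img, ph, config = cfg, machine = machine)
    R_est <- euler_matrix(res$phi, res$theta, res$psi)
    R_true <- euler_matrix(sim$truth$phi[i], sim$truth$theta[i],
                           sim$truth$psi[i])
    errs[i] <- acos(pmin((sum(diag(crossprod(R_est, R_true))) - 1) / 2, 1)) *
      180 / pi
  }
  expect_lt(median(errs), 5)
})

test_that("local refinement reduces a small angular offset and never degrades the objective", {
  ph <- small_phantom(32, 3)
  sim <- simulate_particles(ph, 1, snr = Inf,
                            angles = data.frame(phi = 40, theta = 70,
                                                psi = 10), seed = 4)
  img <- cryopipe:::stack_image(sim$stack, 1)
  cfg <- search_config(R1 = 300, R3 = 8)
  truth <- alignment_params(phi = 40, theta = 70, psi = 10)
  # init at truth stays put
  r0 <- local_refine(img, ph, truth, cfg)
  expect_lt(abs(r0$phi - 40) + abs(r0$theta - 70) + abs(r0$psi - 10), 1)
  # 3 degrees off: error reduced by 10x or more
  init <- alignment_params(phi = 43, theta = 70, psi = 10)
  r1 <- local_refine(img, ph, init, cfg, max_evals = 400)
  err0 <- 3
  err1 <- sqrt((r1$phi - 40)^2 + (r1$theta - 70)^2 + (r1$psi - 10)^2)
  expect_lt(err1, err0 / 10)
  o_init <- cryopipe:::objective_eval(
    cryopipe:::add_shell_info(cryopipe:::prepare_particle_mf(
      img, NULL, cryopipe:::flat_pssnr(img), cfg)),
    cryopipe:::prepare_reference_mf(ph), init, NULL)
  expect_gte(attr(r1, "objective"), o_init - 1e-9)
})

test_that("per-particle defocus refinement recovers an injected offset", {
  # fine sampling: the offset signal lives in the many Thon rings of the
  # high-resolution band
  ph <- small_phantom(96, 1.5)
  ctf_nominal <- base_ctf(1.5)
  ctf_true <- ctf_nominal
  ctf_true$defocus1 <- ctf_true$defocus1 + 200
  ctf_true$defocus2 <- ctf_true$defocus2 + 200
  sim <- simulate_particles(ph, 1, snr = 2,
                            ctfs = ctf_true,
                            angles = data.frame(phi = 10, theta = 50,
                                                psi = 0), seed = 5)
  img <- cryopipe:::stack_image(sim$stack, 1)
  par <- alignment_params(phi = 10, theta = 50, psi = 0)
  cfg <- search_config(R1 = 300, R3 = 4)
  off <- refine_defocus(img, ph, par, ctf_nominal, config = cfg)
  expect_lte(abs(off - 200), 50)
  # grid has 21 points for the defaults
  expect_equal(length(seq(-cfg$defocus_range, cfg$defocus_range,
                          by = cfg$defocus_step)), 21)
  # noiseless particle at nominal defocus: offset 0
  sim0 <- simulate_particles(ph, 1, snr = Inf, ctfs = ctf_nominal,
                             angles = data.frame(phi = 10, theta = 50,
                                                 psi = 0), seed = 6)
  off0 <- refine_defocus(cryopipe:::stack_image(sim0$stack, 1), ph, par,
                         ctf_nominal, config = cfg)
  expect_lte(abs(off0), 50)
})

test_that("3D reference masking implements binarize/soften/blend", {
  ph <- small_phantom(32, 3)
  # all-positive mask: output equals input
  mask_all <- em_volume(array(1, c(32, 32, 32)), 3)
  out <- mask_reference_3d(ph, mask_all, falloff_width = 9)
  expect_equal(out$data, ph$data, tolerance = 1e-9)
  # spherical mask with zero outside
  r <- sqrt(outer(outer(((0:31) - 16)^2, ((0:31) - 16)^2, `+`),
                  ((0:31) - 16)^2, `+`)) * 3
  mvol <- em_volume(array(ifelse(r < 30, 1, -1), c(32, 32, 32)), 3)
  out0 <- mask_reference_3d(ph, mvol, falloff_width = 9)
  expect_lt(sum(out0$data[r > 33]^2), 1e-12)
  expect_lte(sum(out0$data[r > 30]^2) + 1e-12, sum(ph$data[r > 30]^2) + 1e-9)
  # outside kept as a weighted low-pass filtered copy
  out1 <- mask_reference_3d(ph, mvol, falloff_width = 9, outside_lp = 30,
                            outside_weight = 1)
  lp <- cryopipe:::fourier_bandpass(ph$data, 3, lowpass = 30)
  deep_out <- r > 40
  expect_equal(out1$data[deep_out], lp[deep_out], tolerance = 1e-6)
  expect_error(mask_reference_3d(ph, em_volume(array(-1, c(32, 32, 32)), 3)))
})
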