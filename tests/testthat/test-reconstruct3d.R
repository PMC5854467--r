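test_that("background whitening yields unit pixel variance and flattens colored noise", {
  set.seed(32)
  img <- em_image(matrix(rnorm(48 * 48, 0, 2), 48), 3)
  w <- whiten_background(img, 55)
  expect_equal(sd(w$data), 1, tolerance = 0.02)
  # colored generator spectrum flattened
  n <- 48; px <- 3
  g <- cryopipe:::freq_magnitude(c(n, n), px)
  shape <- 1 / (1 + (g / 0.05)^2); shape[1, 1] <- shape[1, 2]
  col <- em_image(Re(ifft2(fft2(matrix(rnorm(n * n), n)) * sqrt(shape))), px)
  wc <- whiten_background(col, 55)
  prof <- radial_average(Mod(fft2(wc$data))^2, px)
  mid <- prof$values[3:14]
  expect_lt(max(abs(mid / mean(mid) - 1)), 0.4)
})

test_that("insertion respects occupancy and noise scaling; adjoint is faithful", {
  ph <- small_phantom(32, 3)
  sim <- simulate_particles(ph, 1, snr = Inf,
                            angles = data.frame(phi = 30, theta = 60,
                                                psi = 45), seed = 7)
  img <- cryopipe:::stack_image(sim$stack, 1)
  par <- alignment_params(phi = 30, theta = 60, psi = 45)
  acc <- recon_accumulator(32, 3)
  # q = 0 leaves the accumulator untouched
  acc0 <- insert_particle(acc, img, par, q = 0)
  expect_true(all(acc0$den == 0))
  # doubling sigma quarters the contributions
  a1 <- insert_particle(recon_accumulator(32, 3), img, par, sigma = 1)
  a2 <- insert_particle(recon_accumulator(32, 3), img, par, sigma = 2)
  expect_equal(a1$den, 4 * a2$den, tolerance = 1e-9)
  # adjoint: project the single-particle reconstruction back
  vol <- finalize_reconstruction(a1, 1e6)
  proj <- project_volume(vol, 30, 60, 45)
  expect_gt(cor(as.vector(proj$data), as.vector(img$data)), 0.985)
})

test_that("reconstruction accumulators merge linearly", {
  ph <- small_phantom(32, 3)
  sim <- simulate_particles(ph, 6, snr = 1, seed = 8)
  parts <- lapply(1:6, function(i) cryopipe:::stack_image(sim$stack, i))
  pars <- lapply(1:6, function(i)
    alignment_params(phi = sim$truth$phi[i], theta = sim$truth$theta[i],
                     psi = sim$truth$psi[i]))
  all_acc <- recon_accumulator(32, 3)
  for (i in 1:6) all_acc <- insert_particle(all_acc, parts[[i]], pars[[i]])
  a <- recon_accumulator(32, 3); b <- recon_accumulator(32, 3)
  for (i in 1:3) a <- insert_particle(a, parts[[i]], pars[[i]])
  for (i in 4:6) b <- insert_particle(b, parts[[i]], pars[[i]])
  merged <- merge_accumulators(a, b)
  expect_equal(merged$num_re, all_acc$num_re, tolerance = 1e-12)
  expect_equal(merged$den, all_acc$den, tolerance = 1e-12)
})

test_that("the Wiener term obeys its limits", {
  ph <- small_phantom(32, 3)
  sim <- simulate_particles(ph, 4, snr = Inf, seed = 9)
  acc <- recon_accumulator(32, 3)
  for (i in 1:4)
    acc <- insert_particle(acc, cryopipe:::stack_image(sim$stack, i),
                           alignment_params(phi = sim$truth$phi[i],
                                            theta = sim$truth$theta[i],
                                            psi = sim$truth$psi[i]))
  # PSSNR -> 0 gives the zero map
  v0 <- finalize_reconstruction(acc, 0)
  expect_lt(max(abs(v0$data)), 1e-10)
  v <- finalize_reconstruction(acc, 1e6)
  expect_true(all(is.finite(v$data)))
  expect_error(finalize_reconstruction(recon_accumulator(32, 3), 10))
})

test_that("score weights follow the exponential form with the printed B-factor span", {
  w0 <- score_weights(score = 37, score_mean = 20, bsc = 0)
  expect_true(all(w0(seq(0, 0.3, 0.05)) == 1))
  wm <- score_weights(score = 20, score_mean = 20, bsc = 10)
  expect_true(all(wm(seq(0, 0.3, 0.05)) == 1))
  # delta score 10 at BSC = 10 gives an effective B-factor difference of 100
  wa <- score_weights(30, 20, 10)
  wb <- score_weights(20, 20, 10)
  g <- seq(0.01, 0.3, 0.01)
  ratio <- wa(g) / wb(g)
  expect_equal(ratio, exp(-100 * g^2 / 4), tolerance = 1e-12)
  expect_equal(wa(0), 1)
})

test_that("FSC behaves at its limits and matches a constructed SNR", {
  set.seed(33)
  ph <- small_phantom(32, 3)
  f1 <- compute_fsc(ph, ph)
  expect_true(all(abs(f1$fsc_raw[f1$shells < 1 / 6.5] - 1) < 1e-9))
  n1 <- em_volume(array(rnorm(32^3), c(32, 32, 32)), 3)
  n2 <- em_volume(array(rnorm(32^3), c(32, 32, 32)), 3)
  f0 <- compute_fsc(n1, n2)
  expect_lt(max(abs(f0$fsc_raw[3:15])), 0.35)
  # signal + independent noise halves: FSC ~ SNR/(SNR+1) per shell
  snr_shell <- 1.5
  sig <- array(rnorm(32^3), c(32, 32, 32))
  h1 <- em_volume(sig + array(rnorm(32^3, 0, sqrt(1 / snr_shell)),
                              c(32, 32, 32)), 3)
  h2 <- em_volume(sig + array(rnorm(32^3, 0, sqrt(1 / snr_shell)),
                              c(32, 32, 32)), 3)
  fs <- compute_fsc(h1, h2)
  mid <- fs$fsc_raw[4:14]
  expect_equal(mean(mid), snr_shell / (snr_shell + 1), tolerance = 0.05)
})

test_that("solvent-corrected FSC follows the exact algebra", {
  shells <- c(1e-12, 0.05, 0.1)
  fsc <- structure(list(shells = shells, fsc = c(1, 0.5, 0.2),
                        fsc_raw = c(1, 0.5, 0.2), pixel_size = 3),
                   class = "fsc_curve")
  # f = 1 is the identity
  expect_equal(part_fsc(fsc, 1)$fsc, fsc$fsc)
  # FSC = 1 is a fixed point for any f
  expect_equal(part_fsc(fsc, 3)$fsc[1], 1)
  # worked value: f = 2, FSC = 0.5 -> 2/3
  expect_equal(part_fsc(fsc, 2)$fsc[2], 2 / 3, tolerance = 1e-12)
  # model-map variant squares the FSC
  expect_equal(part_fsc_model(fsc, 2)$fsc[2], 2 * 0.25 / 1.25,
               tolerance = 1e-12)
  expect_equal(part_fsc_model(fsc, 1)$fsc, fsc$fsc^2)
})

test_that("particle volume and solvent ratio follow the 0.81 Da rule", {
  expect_equal(particle_volume_from_mass(810), 1000)
  expect_equal(particle_volume_from_mass(2e5), 2 * particle_volume_from_mass(1e5))
  r <- 50; mw <- 3e5
  expect_equal(solvent_ratio(r, mw),
               (4 / 3) * pi * r^3 / (mw / 0.81), tolerance = 1e-12)
})

test_that("resolution estimation interpolates the first crossing", {
  shells <- pmax((0:16) / 96, 1e-12)
  ones <- structure(list(shells = shells, fsc = rep(1, 17),
                         fsc_raw = rep(1, 17), pixel_size = 3),
                    class = "fsc_curve")
  expect_equal(resolution_at_threshold(ones, 0.143), 6)  # Nyquist at 3 A/px
  vals <- rep(1, 17); vals[12:17] <- 0
  stepc <- ones; stepc$fsc <- vals
  expect_equal(1 / resolution_at_threshold(stepc, 0.143),
               shells[11] + (1 - 0.143) / 1 * (shells[12] - shells[11]),
               tolerance = 1e-9)
  # 0.5 crossing is never finer than the 0.143 crossing
  smooth <- ones; smooth$fsc <- seq(1, 0, length.out = 17)
  expect_lte(1 / resolution_at_threshold(smooth, 0.5),
             1 / resolution_at_threshold(smooth, 0.143))
})

test_that("PSSNR from FSC follows the half-to-full algebra", {
  shells <- pmax((0:4) / 96, 1e-12)
  f <- structure(list(shells = shells, fsc = c(0.9, 1 / 3, 0.1, 0, -0.1),
                      fsc_raw = c(0.9, 1 / 3, 0.1, 0, -0.1),
                      pixel_size = 3), class = "fsc_curve")
  p <- pssnr_from_fsc(f)
  # half-map SSNR 2 FSC/(1-FSC) = 1 at FSC = 1/3; full data doubles it
  expect_equal(p$values[2], 2, tolerance = 1e-9)
  expect_equal(p$values[4], 0)
  expect_equal(p$values[5], 0)
  # monotone FSC gives monotone PSSNR
  expect_true(all(diff(p$values) <= 1e-12))
})

test_that("likelihood-blurred insertion reduces to the standard one for a delta", {
  ph <- small_phantom(32, 3)
  sim <- simulate_particles(ph, 1, snr = 5,
                            angles = data.frame(phi = 10, theta = 40,
                                                psi = 5), seed = 11)
  img <- cryopipe:::stack_image(sim$stack, 1)
  par <- alignment_params(phi = 10, theta = 40, psi = 5)
  delta <- data.frame(dalpha = 0, dx = 0, dy = 0, weight = 1)
  a_blur <- insert_particle_blurred(recon_accumulator(32, 3), img, par,
                                    delta)
  a_std <- insert_particle(recon_accumulator(32, 3), img, par)
  expect_equal(a_blur$num_re, a_std$num_re, tolerance = 1e-9)
  expect_equal(a_blur$den, a_std$den, tolerance = 1e-9)
  # uniform blur over two shifts equals the average of the shifted maps
  two <- data.frame(dalpha = 0, dx = c(-3, 3), dy = 0, weight = c(1, 1))
  vb <- finalize_reconstruction(
    insert_particle_blurred(recon_accumulator(32, 3), img, par, two,
                            res_limit = 12), 1e4)
  pa <- par; pa$sx <- par$sx - 3
  pb <- par; pb$sx <- par$sx + 3
  va <- finalize_reconstruction(
    insert_particle(recon_accumulator(32, 3), img, pa, q = 0.5,
                    res_limit = 12), 1e4)
  expect_gt(cor(as.vector(vb$data),
                as.vector(va$data +
                            finalize_reconstruction(
                              insert_particle(recon_accumulator(32, 3), img,
                                              pb, q = 0.5, res_limit = 12),
                              1e4)$data)), 0.8)
  expect_error(insert_particle_blurred(recon_accumulator(32, 3), img, par,
                                       data.frame(dalpha = 0, dx = 0,
                                                  dy = 0, weight = 0)))
})

test_that("sharpening whitens, applies the B-factor exactly, and respects limits", {
  set.seed(34)
  ph <- small_phantom(32, 3)
  # B = 0, whitening off, no mask: identity
  cfg_id <- sharpen_config(bfactor = 0, whiten_beyond = NULL)
  expect_equal(sharpen_map(ph, cfg_id)$data, ph$data, tolerance = 1e-9)
  # whitening flattens shell power beyond the start
  cfg_w <- sharpen_config(bfactor = 0, whiten_beyond = 12)
  sw <- sharpen_map(ph, cfg_w)
  pw <- radial_average(Mod(fft3(sw$data))^2, 3)
  hi <- pw$bin_centers > 1 / 11 & pw$bin_centers < 1 / 6.5
  expect_lt(max(abs(pw$values[hi] / mean(pw$values[hi]) - 1)), 0.25)
  # negative B raises the 4 A / 8 A amplitude ratio by the closed form
  v <- em_volume(array(rnorm(32^3), c(32, 32, 32)), 1.6)
  cfg_b <- sharpen_config(bfactor = -100, whiten_beyond = NULL)
  sb <- sharpen_map(v, cfg_b)
  ftr <- fft3(sb$data) / fft3(v$data)
  g <- cryopipe:::freq_magnitude(c(32, 32, 32), 1.6)
  pick_g <- function(target) which(abs(g - target) < 0.004)[1]
  i4 <- pick_g(0.25); i8 <- pick_g(0.125)
  expect_equal(Mod(ftr[i4]) / Mod(ftr[i8]),
               exp(25 * (g[i4]^2 - g[i8]^2)), tolerance = 1e-6)
  expect_error(sharpen_map(ph, sharpen_config(resolution_cutoff = 3)))
})
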