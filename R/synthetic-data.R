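# Ground-truth generators: phantom volumes built from Gaussian blobs,
# simulated particle stacks with known orientations/shifts/defocus and
# calibrated SNR, synthetic micrographs with optional high-variance
# artifacts, and drifting movies. Every generator is deterministic under a
# fixed seed.

#' Build a phantom volume from Gaussian blobs
#'
#' The density is a sum of isotropic 3D Gaussians; optional point-group
#' symmetry replicates every blob under the group's rotations. All blobs
#' must fit inside 0.8 x the box.
#'
#' @param blobs data.frame(x, y, z, sigma, amplitude): centers in Angstrom
#'   relative to the box center, widths (sigma) in Angstrom
#' @param box box size in voxels
#' @param pixel_size voxel size in Angstrom
#' @param symmetry optional point-group label (e.g. "C4")
#' @return `em_volume` with attribute `blobs` (the replicated blob table)
#' @export
make_phantom <- function(blobs, box, pixel_size, symmetry = "C1") {
  stopifnot(nrow(blobs) >= 1, all(blobs$sigma > 0),
            all(blobs$amplitude >= 0))
  if (symmetry != "C1") {
    ops <- symmetry_ops(symmetry)
    rep_blobs <- do.call(rbind, lapply(ops, function(o) {
      xyz <- t(o %*% t(as.matrix(blobs[, c("x", "y", "z")])))
      data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 sigma = blobs$sigma, amplitude = blobs$amplitude)
    }))
    blobs <- rep_blobs
  }
  half <- box * pixel_size / 2
  if (any(sqrt(blobs$x^2 + blobs$y^2 + blobs$z^2) + 2 * blobs$sigma >
          0.8 * half))
    stop("blob outside 0.8 x box")
  ax <- (seq_len(box) - 1 - box / 2) * pixel_size
  v <- array(0, c(box, box, box))
  for (b in seq_len(nrow(blobs))) {
    gx <- exp(-(ax - blobs$x[b])^2 / (2 * blobs$sigma[b]^2))
    gy <- exp(-(ax - blobs$y[b])^2 / (2 * blobs$sigma[b]^2))
    gz <- exp(-(ax - blobs$z[b])^2 / (2 * blobs$sigma[b]^2))
    v <- v + blobs$amplitude[b] * outer(outer(gx, gy), gz)
  }
  out <- em_volume(v, pixel_size)
  attr(out, "blobs") <- blobs
  out
}

#' Default desk-scale phantom
#'
#' A pseudo-atomic cluster: a few broad Gaussians define the particle
#' envelope and a deterministic quasi-random cloud of sharp (sigma
#' ~2.5 A) Gaussians provides signal out to high resolution, mimicking
#' the roughly flat spectral behavior of real macromolecules. The design
#' spans ~110 Angstrom and is scaled down for smaller boxes.
#'
#' @param box box size in voxels
#' @param pixel_size voxel size in Angstrom
#' @param symmetry optional point group
#' @return `em_volume`
#' @export
default_phantom <- function(box = 48, pixel_size = 3, symmetry = "C1") {
  env <- data.frame(x = 0, y = 0, z = 0, sigma = 12, amplitude = 0.08)
  # asymmetric domain-scale blobs: orientation signal in the 15-40 A band
  med <- data.frame(
    x = c(0, 24, -20, 8, -8, 16, -24, 2),
    y = c(0, 10, 14, -24, 20, -14, -8, 28),
    z = c(0, 16, -14, 10, 22, 24, 12, -8),
    sigma = 5, amplitude = 0.8)
  # golden-ratio lattice of "atoms" inside a 32 A-radius ball
  i <- 1:60
  u1 <- (i * 0.6180339887) %% 1
  u2 <- (i * 0.7548776662) %% 1
  u3 <- (i * 0.5698402910) %% 1
  r <- 32 * u1^(1 / 3)
  th <- acos(2 * u2 - 1)
  phi <- 2 * pi * u3
  atoms <- data.frame(
    x = r * sin(th) * cos(phi), y = r * sin(th) * sin(phi),
    z = r * cos(th), sigma = 2.5, amplitude = 0.9)
  blobs <- rbind(env, med, atoms)
  extent <- max(sqrt(blobs$x^2 + blobs$y^2 + blobs$z^2) + 2 * blobs$sigma)
  s <- min(1, 0.38 * box * pixel_size / extent)
  blobs[c("x", "y", "z", "sigma")] <- blobs[c("x", "y", "z", "sigma")] * s
  make_phantom(blobs, box, pixel_size, symmetry)
}

#' Simulate a particle stack with known ground truth
#'
#' Projects the phantom at random uniform orientations (or supplied
#' angles), applies per-particle shifts and CTF, and adds white Gaussian
#' noise scaled so that SNR = signal variance / noise variance inside the
#' particle mask.
#'
#' @param phantom `em_volume`
#' @param n number of particles
#' @param snr target signal-to-noise ratio (Inf = noiseless)
#' @param ctfs per-particle `ctf_params` list, shared `ctf_params`, or
#'   NULL
#' @param mask_radius mask radius (A) for the SNR calibration (default
#'   0.4 x box)
#' @param shift_sd standard deviation of the true x/y shifts in Angstrom
#' @param angles optional data.frame(phi, theta, psi) of true orientations
#' @param seed RNG seed
#' @return list(stack = `em_stack`, truth = data.frame(index, phi, theta,
#'   psi, sx, sy, defocus1, defocus2, snr))
#' @export
simulate_particles <- function(phantom, n, snr = 0.1, ctfs = NULL,
                               mask_radius = NULL, shift_sd = 0,
                               angles = NULL, seed = 1) {
  set.seed(seed)
  stopifnot(n >= 1)
  box <- box_size(phantom)
  px <- phantom$pixel_size
  if (is.null(mask_radius)) mask_radius <- 0.4 * box * px
  if (is.null(angles))
    angles <- data.frame(phi = runif(n, 0, 360),
                         theta = acos(runif(n, -1, 1)) * 180 / pi,
                         psi = runif(n, 0, 360))
  sx <- rnorm(n, 0, shift_sd)
  sy <- rnorm(n, 0, shift_sd)
  mask <- make_soft_mask(box, px, mask_radius, 0, ndim = 2L) >= 0.5
  dat <- array(0, c(box, box, n))
  truth <- NULL
  vft <- volume_ft(phantom)
  fl <- freq_list(box, px, half = TRUE)
  for (i in seq_len(n)) {
    vals <- cp_slice_extract(vft$re, vft$im, vft$n,
                             euler_matrix(angles$phi[i], angles$theta[i],
                                          angles$psi[i]),
                             as.numeric(fl$hx), as.numeric(fl$hy)) *
      center_phase(fl)
    vals <- vals * shift_phase(fl, sx[i] / px, sy[i] / px)
    ctf_i <- ctf_of(ctfs, i)
    if (!is.null(ctf_i)) vals <- vals * ctf_at(ctf_i, fl)
    img <- freqlist_to_image(fl, vals)
    sig_var <- var(img[mask])
    noise_sd <- if (is.finite(snr)) sqrt(sig_var / snr) else 0
    dat[, , i] <- img + rnorm(box * box, 0, noise_sd)
    truth <- rbind(truth, data.frame(
      index = i, phi = angles$phi[i], theta = angles$theta[i],
      psi = angles$psi[i], sx = sx[i], sy = sy[i],
      defocus1 = if (is.null(ctf_i)) NA_real_ else ctf_i$defocus1,
      defocus2 = if (is.null(ctf_i)) NA_real_ else ctf_i$defocus2,
      snr = snr))
  }
  list(stack = em_stack(dat, px), truth = truth)
}

#' Simulate a micrograph with known particle positions
#'
#' Places CTF-filtered projections of the phantom at random positions with
#' a minimum-distance constraint, optionally inserts high-variance
#' "ice blob" artifact patches, and adds white noise calibrated against
#' the particle signal variance.
#'
#' @param phantom `em_volume`
#' @param n_particles number of particles to place (0 = blank)
#' @param box micrograph side in pixels
#' @param snr signal-to-noise ratio of the placed particles
#' @param ctf `ctf_params` or NULL
#' @param min_distance minimum center distance in Angstrom (default:
#'   particle box extent)
#' @param n_artifacts number of high-variance artifact patches
#' @param seed RNG seed
#' @return list(micrograph = `em_image`, coords = data.frame(x, y) in
#'   Angstrom, artifact_coords)
#' @export
simulate_micrograph <- function(phantom, n_particles, box = 1024,
                                snr = 0.1, ctf = NULL, min_distance = NULL,
                                n_artifacts = 0, seed = 1) {
  set.seed(seed)
  pbox <- box_size(phantom)
  px <- phantom$pixel_size
  if (is.null(min_distance)) min_distance <- pbox * px
  mg <- matrix(0, box, box)
  margin <- pbox %/% 2 + 2
  coords <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(coords) < n_particles) {
    tries <- tries + 1
    if (tries > 200 * max(n_particles, 1)) stop("impossible packing")
    cx <- sample(margin:(box - margin), 1)
    cy <- sample(margin:(box - margin), 1)
    if (nrow(coords) > 0 &&
        any(((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2) * px^2 <
            min_distance^2)) next
    proj <- project_volume(phantom, runif(1, 0, 360),
                           acos(runif(1, -1, 1)) * 180 / pi,
                           runif(1, 0, 360))
    xs <- (cx - pbox / 2):(cx + pbox / 2 - 1)
    ys <- (cy - pbox / 2):(cy + pbox / 2 - 1)
    mg[xs, ys] <- mg[xs, ys] + proj$data
    coords <- rbind(coords, c(cx, cy))
  }
  sig_var <- if (n_particles > 0) {
    proj0 <- project_volume(phantom, 0, 0, 0)
    var(as.vector(proj0$data))
  } else 1
  noise_sd <- sqrt(sig_var / snr)
  # ice-thickness variation: a smooth multiplicative field modulating the
  # noise power and a smooth additive background ramp, as on real
  # micrographs (and what the picker's high-pass / histogram statistics
  # are built to tolerate)
  smooth_field <- function() {
    f <- fourier_bandpass(matrix(rnorm(box * box), box, box), px,
                          lowpass = box * px / 6)
    f / sd(f)
  }
  fv <- smooth_field(); fm <- smooth_field()
  mg <- mg + matrix(rnorm(box * box, 0, noise_sd), box, box) *
    (1 + 0.15 * pmax(fv, -0.9))
  # solvent (structural) noise is imaged through the CTF like the
  # particles; detector noise and the background ramp are added after
  if (!is.null(ctf))
    mg <- Re(ifft2(fft2(mg) * ctf_image(ctf, box, px)))
  mg <- mg + matrix(rnorm(box * box, 0, 0.2 * noise_sd), box, box) +
    0.8 * noise_sd * fm
  art <- matrix(numeric(0), 0, 2)
  if (n_artifacts > 0) {
    aside <- 2 * pbox
    for (a in seq_len(n_artifacts)) {
      ax <- sample(aside:(box - aside), 1)
      ay <- sample(aside:(box - aside), 1)
      xs <- (ax - aside / 2):(ax + aside / 2 - 1)
      ys <- (ay - aside / 2):(ay + aside / 2 - 1)
      mg[xs, ys] <- mg[xs, ys] +
        matrix(rnorm(aside * aside, 5 * noise_sd, 4 * noise_sd),
               aside, aside)
      art <- rbind(art, c(ax, ay))
    }
  }
  list(micrograph = em_image(mg, px),
       coords = data.frame(x = (coords[, 1] - 1) * px,
                           y = (coords[, 2] - 1) * px),
       artifact_coords = if (nrow(art) > 0)
         data.frame(x = (art[, 1] - 1) * px, y = (art[, 2] - 1) * px)
       else NULL)
}

#' Simulate a drifting movie with known trajectory
#'
#' Frames are sub-pixel shifted (Fourier phase ramps), noisy copies of the
#' input image following a smooth drift; the returned true trajectory is
#' gauge-fixed to zero mean.
#'
#' @param image `em_image` underlying (noise-free) scene
#' @param n_frames number of frames (>= 3)
#' @param drift_amplitude total drift scale in Angstrom
#' @param frame_snr per-frame signal-to-noise ratio
#' @param exposure_per_frame e-/A^2 per frame (metadata for exposure
#'   weighting)
#' @param seed RNG seed
#' @return list(movie = `movie_stack`, trajectory = data.frame(frame, x,
#'   y) in Angstrom)
#' @export
simulate_movie <- function(image, n_frames = 10, drift_amplitude = 10,
                           frame_snr = 0.1, exposure_per_frame = 1,
                           seed = 1) {
  set.seed(seed)
  stopifnot(n_frames >= 3)
  n <- box_size(image)
  px <- image$pixel_size
  t <- seq(0, 1, length.out = n_frames)
  # smooth decelerating drift plus a gentle curve
  x <- drift_amplitude * (1 - exp(-2 * t)) / (1 - exp(-2))
  y <- drift_amplitude * 0.6 * t^1.5
  x <- x - mean(x); y <- y - mean(y)
  hx <- matrix(freq_index(n), n, n)
  hy <- matrix(freq_index(n), n, n, byrow = TRUE)
  ft0 <- fft2(image$data)
  sig_var <- var(as.vector(image$data))
  noise_sd <- if (is.finite(frame_snr)) sqrt(sig_var / frame_snr) else 0
  frames <- array(0, c(n, n, n_frames))
  for (i in seq_len(n_frames)) {
    ramp <- exp(-2i * pi * (hx * x[i] / px + hy * y[i] / px) / n)
    frames[, , i] <- Re(ifft2(ft0 * ramp)) +
      matrix(rnorm(n * n, 0, noise_sd), n, n)
  }
  list(movie = movie_stack(frames, px,
                           exposure_per_frame = exposure_per_frame),
       trajectory = data.frame(frame = seq_len(n_frames), x = x, y = y))
}
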