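# 3D refinement core: matched-filter objective (noise-whitened images vs
# SNR-scaled, CTF-multiplied reference projections), restrained by a
# quadratic shift prior; exhaustive global orientation search with local
# refinement of the top candidates; per-particle defocus refinement; and
# 3D reference masking.

#' Per-particle alignment parameters
#'
#' @param phi,theta,psi Euler angles (degrees, Z-Y-Z intrinsic)
#' @param sx,sy shifts in Angstrom
#' @param magnification scale factor (carried, not searched)
#' @param defocus_offset per-particle defocus offset in Angstrom
#' @return object of class `alignment_params`
#' @export
alignment_params <- function(phi = 0, theta = 0, psi = 0, sx = 0, sy = 0,
                             magnification = 1, defocus_offset = 0) {
  stopifnot(is.finite(phi), is.finite(theta), is.finite(psi),
            is.finite(sx), is.finite(sy))
  structure(list(phi = phi, theta = theta, psi = psi, sx = sx, sy = sy,
                 magnification = magnification,
                 defocus_offset = defocus_offset),
            class = "alignment_params")
}

#' Shift restraint model
#'
#' @param mean_shift length-2, average particle shift (x, y) in Angstrom
#' @param sd_shift length-2, standard deviations (sigma_x, sigma_y) > 0
#' @param sigma standard deviation of the noise in the particle image
#' @param mask_pixels number of pixels M in the alignment mask
#' @return object of class `restraint_model`
#' @export
restraint_model <- function(mean_shift = c(0, 0), sd_shift = c(5, 5),
                            sigma = 1, mask_pixels = 1000) {
  stopifnot(all(sd_shift > 0), mask_pixels > 0)
  structure(list(mean_shift = mean_shift, sd_shift = sd_shift,
                 sigma = sigma, mask_pixels = mask_pixels),
            class = "restraint_model")
}

#' Search configuration for 3D refinement
#'
#' @param R1,R2,R3 low, signed-CC and high resolution limits in Angstrom
#'   (R1 >= R2 >= R3); cross terms between R2 and R3 enter with their
#'   absolute value
#' @param top_h number of grid-search results refined locally (default 20)
#' @param angular_step global grid step in degrees
#' @param translation_px translation grid bound (working pixels)
#' @param defocus_range,defocus_step defocus-offset search (Angstrom)
#' @return object of class `search_config`
#' @export
search_config <- function(R1 = 300, R2 = NULL, R3 = 8, top_h = 20,
                          angular_step = 15, translation_px = 2,
                          defocus_range = 500, defocus_step = 50,
                          cross_shifts = FALSE) {
  if (is.null(R2)) R2 <- R3
  stopifnot(R1 >= R2, R2 >= R3, top_h >= 1)
  structure(list(R1 = R1, R2 = R2, R3 = R3, top_h = top_h,
                 angular_step = angular_step,
                 translation_px = translation_px,
                 defocus_range = defocus_range,
                 defocus_step = defocus_step,
                 cross_shifts = cross_shifts),
            class = "search_config")
}

#' Spectral SNR of a particle image on the 2D Fourier grid
#'
#' SNR(g) = PSSNR(g) x CTF^2(g), using the particle's anisotropic CTF.
#'
#' @param pssnr `radial_profile` of the particle SSNR before CTF
#' @param ctf `ctf_params`
#' @param n box size in pixels
#' @param pixel_size pixel size in Angstrom
#' @return matrix (unshifted Fourier convention)
#' @export
snr_curve <- function(pssnr, ctf, n, pixel_size) {
  stopifnot(all(pssnr$values >= 0))
  g <- freq_magnitude(c(n, n), pixel_size)
  matrix(profile_at(pssnr, as.vector(g)), n, n) *
    ctf_image(ctf, n, pixel_size)^2
}

#' Noise-whiten a particle image for matched filtering
#'
#' Divides the image transform by its radially averaged amplitude spectrum
#' (which contains signal + noise power) and multiplies by the gain
#' sqrt(1 + SNR(g)) that amplifies amplitudes according to the signal
#' strength.
#'
#' @param image `em_image`
#' @param snr SNR matrix from [snr_curve()] (0 for a plain whitening)
#' @return `em_image`
#' @export
whiten_image_matched <- function(image, snr = 0) {
  n <- box_size(image)
  ft <- fft2(image$data)
  amp <- radial_average(Mod(ft)^2, image$pixel_size)
  if (all(amp$values == 0)) stop("degenerate amplitude spectrum")
  g <- freq_magnitude(c(n, n), image$pixel_size)
  denom <- sqrt(matrix(profile_at(amp, as.vector(g)), n, n))
  out <- ft * sqrt(1 + snr)
  ok <- denom > 0
  out[ok] <- out[ok] / denom[ok]
  out[!ok] <- 0
  em_image(Re(ifft2(out)), image$pixel_size)
}

#' Scale a reference projection to the measured SNR
#'
#' Divides the projection transform by its radially averaged amplitude
#' spectrum and multiplies by sqrt(SNR(g)), so the variance of the signal
#' in the reference is proportional to the signal-to-noise ratio measured
#' in the whitened images. With SNR = 0 everywhere the reference scales
#' to zero.
#'
#' @param projection `em_image` (typically already CTF-multiplied)
#' @param snr SNR matrix from [snr_curve()]
#' @return `em_image`
#' @export
scale_reference <- function(projection, snr) {
  n <- box_size(projection)
  ft <- fft2(projection$data)
  amp <- radial_average(Mod(ft)^2, projection$pixel_size)
  g <- freq_magnitude(c(n, n), projection$pixel_size)
  denom <- sqrt(matrix(profile_at(amp, as.vector(g)), n, n))
  out <- ft * sqrt(pmax(snr, 0))
  ok <- denom > 0
  out[ok] <- out[ok] / denom[ok]
  out[!ok] <- 0
  em_image(Re(ifft2(out)), projection$pixel_size)
}

# band masks for the [R1, R3] objective on a freq list
objective_bands <- function(fl, config) {
  inb <- fl$g >= 1 / config$R1 - 1e-12 & fl$g <= 1 / config$R3 + 1e-12
  signed <- inb & fl$g <= 1 / config$R2 + 1e-12
  list(all = inb, signed = signed, unsigned = inb & !signed)
}

# Eq. 9a/9b on complex value vectors already restricted to [R1, R3]
cc_values <- function(avals, xvals, signed, unsigned) {
  na <- sqrt(sum(Mod(avals)^2))
  nx <- sqrt(sum(Mod(xvals)^2))
  if (na == 0 || nx == 0) stop("zero-norm input to objective")
  num <- sum(Re(Conj(avals[signed]) * xvals[signed]))
  if (any(unsigned))
    num <- num + abs(sum(Re(Conj(avals[unsigned]) * xvals[unsigned])))
  num / (na * nx)
}

#' Matched-filter cross-correlation objective
#'
#' Normalized real cross-correlation between a whitened particle image and
#' a scaled reference projection over the [R1, R3] band. If R2 < R1 a
#' signed band [R1, R2] and an unsigned band (R2, R3] are used: the
#' unsigned band contributes the absolute value of its cross-term sum,
#' which never decreases the objective. Denominator norms always use the
#' full [R1, R3] band.
#'
#' @param image whitened `em_image`
#' @param projection scaled `em_image` projection
#' @param config `search_config` carrying R1, R2, R3
#' @return value in [-1, 1]
#' @export
objective_cc <- function(image, projection, config) {
  n <- box_size(image)
  fl <- freq_list(n, image$pixel_size, half = FALSE, include_dc = FALSE)
  b <- objective_bands(fl, config)
  cc_values(fft2(projection$data)[fl$idx][b$all],
            fft2(image$data)[fl$idx][b$all],
            b$signed[b$all], b$unsigned[b$all])
}

#' Quadratic shift restraint
#'
#' R(phi | Theta) = -sigma^2 / (2 M) [ (x - xbar)^2 / sigma_x^2 +
#' (y - ybar)^2 / sigma_y^2 ]; zero at the mean shift, always <= 0.
#'
#' @param params `alignment_params`
#' @param restraint `restraint_model`
#' @return penalty (<= 0)
#' @export
shift_restraint <- function(params, restraint) {
  if (is.null(restraint)) return(0)
  dx <- params$sx - restraint$mean_shift[1]
  dy <- params$sy - restraint$mean_shift[2]
  -restraint$sigma^2 / (2 * restraint$mask_pixels) *
    (dx^2 / restraint$sd_shift[1]^2 + dy^2 / restraint$sd_shift[2]^2)
}

#' Particle score
#'
#' The complete objective O = CC + R converted to the reported score by
#' multiplication with 100 (perfect unshifted match = 100).
#'
#' @param cc cross-correlation objective value
#' @param penalty shift-restraint value
#' @return score
#' @export
particle_score <- function(cc, penalty = 0) 100 * (cc + penalty)

# ---- search engine ---------------------------------------------------------

# per-particle preparation: whitened values on the band freq list
prepare_particle_mf <- function(image, ctf, pssnr, config) {
  n <- box_size(image)
  px <- image$pixel_size
  # half-plane list: image and reference are Hermitian, so every cross
  # term and norm doubles identically and the normalized CC is unchanged
  # at half the cost
  fl <- freq_list(n, px, res_limit = config$R3, half = TRUE,
                  include_dc = FALSE)
  b <- objective_bands(fl, config)
  sel <- which(b$all)
  ft <- fft2(image$data)
  amp <- radial_average(Mod(ft)^2, px)
  cvec <- if (is.null(ctf)) rep(1, length(fl$idx)) else ctf_at(ctf, fl)
  snr <- if (is.null(pssnr)) rep(0, length(fl$idx)) else
    profile_at(pssnr, fl$g) * cvec^2
  denom <- sqrt(profile_at(amp, fl$g))
  xw <- ft[fl$idx] * sqrt(1 + snr)
  ok <- denom > 0
  xw[ok] <- xw[ok] / denom[ok]
  xw[!ok] <- 0
  list(fl = sub_freq_list(fl, sel), x = xw[sel], ctf = cvec[sel],
       snr = snr[sel], signed = b$signed[sel], unsigned = b$unsigned[sel],
       norm_x = sqrt(sum(Mod(xw[sel])^2)), pixel_size = px, n = n)
}

sub_freq_list <- function(fl, sel) {
  list(n = fl$n, pixel_size = fl$pixel_size, hx = fl$hx[sel],
       hy = fl$hy[sel], g = fl$g[sel], idx = fl$idx[sel])
}

# reference prepared for repeated slice extraction (zero-padded x pad for
# better trilinear accuracy; the padded transform samples the volume's
# continuous transform at pad-times finer spacing)
prepare_reference_mf <- function(volume, pad = 2L) {
  n <- box_size(volume)
  if (pad > 1L) {
    np <- n * pad
    big <- array(0, c(np, np, np))
    lo <- np / 2 - n / 2 + 1
    big[lo:(lo + n - 1), lo:(lo + n - 1), lo:(lo + n - 1)] <- volume$data
    vft <- volume_ft(em_volume(big, volume$pixel_size))
  } else vft <- volume_ft(volume)
  list(vft = vft, pad = pad, n = n, pixel_size = volume$pixel_size)
}

# complex slice values at the particle freq list for Euler angles
reference_slice <- function(ref, phi, theta, psi, fl) {
  sc <- ref$pad
  cp_slice_extract(ref$vft$re, ref$vft$im, ref$vft$n,
                   euler_matrix(phi, theta, psi),
                   as.numeric(fl$hx) * sc, as.numeric(fl$hy) * sc) *
    center_phase(fl)
}

# SNR-scaled, CTF-multiplied reference values (per-shell scaling keeps the
# CTF sign structure while matching shell power to sqrt(SNR))
scale_slice <- function(avals, prep) {
  a <- avals * prep$ctf
  pw <- as.numeric(crossprod(prep$shell_memb, Mod(a)^2))
  rad <- sqrt(pw / pmax(prep$shell_counts, 1))[prep$shell_index]
  out <- a * prep$snr_gain
  ok <- rad > 0
  out[ok] <- out[ok] / rad[ok]
  out[!ok] <- 0
  out
}

rowsum_vec <- function(v, idx, nbins) {
  out <- numeric(nbins)
  s <- rowsum(v, idx)
  out[as.integer(rownames(s))] <- s
  out
}

add_shell_info <- function(prep) {
  dg <- 1 / (prep$n * prep$pixel_size)
  shell <- pmin(floor(prep$fl$g / dg + 0.5), prep$n %/% 2) + 1L
  prep$shell_index <- shell
  prep$n_shells <- prep$n %/% 2 + 1L
  prep$shell_counts <- tabulate(shell, prep$n_shells)
  memb <- matrix(0, length(shell), prep$n_shells)
  memb[cbind(seq_along(shell), shell)] <- 1
  prep$shell_memb <- memb
  prep$snr_gain <- sqrt(pmax(prep$snr, 0))
  prep
}

# objective for prepared particle / reference at given parameters
objective_eval <- function(prep, ref, params, restraint = NULL) {
  avals <- reference_slice(ref, params$phi, params$theta, params$psi,
                           prep$fl)
  avals <- scale_slice(avals, prep)
  px <- prep$pixel_size
  avals <- avals * shift_phase(prep$fl, params$sx / px, params$sy / px)
  cc <- cc_values(avals, prep$x, prep$signed, prep$unsigned)
  cc + shift_restraint(params, restraint)
}

# quasi-uniform direction grid (phi, theta) plus psi ring, step in degrees
orientation_grid <- function(step) {
  out <- NULL
  thetas <- seq(0, 180, by = step)
  for (th in thetas) {
    nphi <- max(1L, ceiling(360 * sin(th * pi / 180) / step))
    phis <- seq(0, 360 - 360 / nphi, by = 360 / nphi)
    out <- rbind(out, cbind(phi = phis, theta = th))
  }
  psis <- seq(0, 360 - step, by = step)
  list(dirs = out, psis = psis)
}

#' Exhaustive global orientation search with local refinement
#'
#' Evaluates the matched-filter objective on an Euler grid (step
#' `config$angular_step`) with a translation grid per orientation, keeps
#' the `top_h` best candidates, refines each locally, and returns the best
#' refined result (ties broken by lowest grid index).
#'
#' @param particle `em_image`
#' @param reference `em_volume` (resolution-limited by the R3 band inside
#'   the objective)
#' @param ctf `ctf_params` or NULL
#' @param pssnr `radial_profile` or NULL (flat SNR = 1 assumed)
#' @param config `search_config`
#' @param restraint `restraint_model` or NULL
#' @param candidates return all grid candidates instead of refining
#'   (used by the ab-initio randomized selection)
#' @return `alignment_params` with attributes `score` and `cc`; or a
#'   data.frame of candidates when `candidates = TRUE`
#' @export
global_search <- function(particle, reference, ctf = NULL, pssnr = NULL,
                          config = search_config(), restraint = NULL,
                          candidates = FALSE, machine = NULL) {
  prep <- prepare_particle_mf(particle, ctf,
                              pssnr %||% flat_pssnr(particle), config)
  prep <- add_shell_info(prep)
  if (is.null(machine)) machine <- mf_machine(reference, config, prep$fl)
  orient <- machine$orient
  nor <- nrow(orient)
  tr <- config$translation_px
  shift_grid <- expand.grid(sx = (-tr:tr) * prep$pixel_size,
                            sy = (-tr:tr) * prep$pixel_size)
  if (isTRUE(config$cross_shifts))
    shift_grid <- shift_grid[abs(shift_grid$sx) < 1e-9 |
                               abs(shift_grid$sy) < 1e-9, , drop = FALSE]
  ns <- nrow(shift_grid)
  ramps <- vapply(seq_len(ns), function(s)
    shift_phase(prep$fl, shift_grid$sx[s] / prep$pixel_size,
                shift_grid$sy[s] / prep$pixel_size),
    complex(length(prep$fl$idx)))
  cc <- mf_cc_matrix(machine, prep, ramps)
  pen <- vapply(seq_len(ns), function(s)
    shift_restraint(alignment_params(sx = shift_grid$sx[s],
                                     sy = shift_grid$sy[s]), restraint),
    numeric(1))
  obj <- sweep(cc, 2, pen, `+`)
  if (candidates) {
    best_s <- max.col(obj, ties.method = "first")
    o <- obj[cbind(seq_len(nor), best_s)]
    return(data.frame(phi = orient[, 1], theta = orient[, 2],
                      psi = orient[, 3],
                      sx = shift_grid$sx[best_s],
                      sy = shift_grid$sy[best_s],
                      objective = o, score = 100 * o))
  }
  ord <- order(as.vector(obj), decreasing = TRUE)
  h <- min(config$top_h, length(ord))
  best <- NULL
  for (k in seq_len(h)) {
    idx <- ord[k]
    r <- (idx - 1) %% nor + 1
    s <- (idx - 1) %/% nor + 1
    init <- alignment_params(phi = orient[r, 1], theta = orient[r, 2],
                             psi = orient[r, 3], sx = shift_grid$sx[s],
                             sy = shift_grid$sy[s])
    cand <- local_refine_prepared(prep, machine$ref, init, restraint)
    if (is.null(best) || attr(cand, "objective") > attr(best, "objective"))
      best <- cand
  }
  attr(best, "score") <- 100 * attr(best, "objective")
  best
}

# Precompute the orientation grid and the matrix of reference slices for
# one reference + search configuration; reusable across the particles of
# an iteration (they share box, pixel size and resolution band).
mf_machine <- function(reference, config, fl) {
  ref <- prepare_reference_mf(reference)
  grid <- orientation_grid(config$angular_step)
  if (nrow(grid$dirs) == 0) stop("empty orientation grid")
  orient <- do.call(rbind, lapply(seq_len(nrow(grid$dirs)), function(d)
    cbind(phi = grid$dirs[d, 1], theta = grid$dirs[d, 2], psi = grid$psis)))
  rots <- vapply(seq_len(nrow(orient)), function(r)
    as.numeric(euler_matrix(orient[r, 1], orient[r, 2], orient[r, 3])),
    numeric(9))
  A <- cp_slice_extract_many(ref$vft$re, ref$vft$im, ref$vft$n, rots,
                             as.numeric(fl$hx) * ref$pad,
                             as.numeric(fl$hy) * ref$pad)
  A <- sweep(A, 2, center_phase(fl), `*`)
  dg <- 1 / (fl$n * fl$pixel_size)
  shell <- pmin(floor(fl$g / dg + 0.5), fl$n %/% 2) + 1L
  nsh <- fl$n %/% 2 + 1L
  memb <- matrix(0, length(shell), nsh)
  memb[cbind(seq_along(shell), shell)] <- 1
  list(ref = ref, orient = orient, A = A, A2 = Mod(A)^2,
       shell = shell, memb = memb,
       counts = tabulate(shell, nsh), fl = fl, cache = new.env())
}

# normalized CC of one prepared particle against every machine orientation
# (rows) and shift (columns); reference rows are CTF-multiplied and
# per-shell scaled to sqrt(SNR) before correlation
mf_cc_matrix <- function(machine, prep, ramps) {
  c2 <- prep$ctf^2
  gain <- sqrt(pmax(prep$snr, 0)) * prep$ctf
  env <- machine$cache
  if (!is.null(env$gain) && identical(env$gain, gain)) {
    # particles sharing CTF and SNR reuse the scaled reference matrix
    B <- env$B
    na <- env$na
  } else {
    shellpow <- sweep(machine$A2, 2, c2, `*`) %*% machine$memb
    rad <- sqrt(sweep(shellpow, 2, pmax(machine$counts, 1), `/`))
    denom <- rad[, machine$shell, drop = FALSE]
    scale <- sweep(1 / pmax(denom, 1e-300), 2, gain, `*`)
    scale[denom == 0] <- 0
    B <- machine$A * scale
    na <- sqrt(rowSums(Mod(B)^2))
    na[na == 0] <- Inf
    env$gain <- gain; env$B <- B; env$na <- na
  }
  Ys <- prep$x * Conj(ramps)
  num <- Re(Conj(B[, prep$signed, drop = FALSE]) %*%
              Ys[prep$signed, , drop = FALSE])
  if (any(prep$unsigned))
    num <- num + abs(Re(Conj(B[, prep$unsigned, drop = FALSE]) %*%
                          Ys[prep$unsigned, , drop = FALSE]))
  sweep(num / prep$norm_x, 1, na, `/`)
}

# local refinement on prepared particle/reference state
local_refine_prepared <- function(prep, ref, init, restraint = NULL,
                                  max_evals = 150) {
  v0 <- c(init$phi, init$theta, init$psi, init$sx, init$sy)
  obj <- function(v) {
    p <- alignment_params(phi = v[1], theta = v[2], psi = v[3],
                          sx = v[4], sy = v[5])
    objective_eval(prep, ref, p, restraint)
  }
  res <- optim(v0, obj, method = "Nelder-Mead",
               control = list(fnscale = -1, maxit = max_evals,
                              reltol = 1e-8))
  o0 <- obj(v0)
  v <- if (res$value >= o0) res$par else v0
  out <- alignment_params(phi = v[1], theta = v[2], psi = v[3],
                          sx = v[4], sy = v[5],
                          magnification = init$magnification,
                          defocus_offset = init$defocus_offset)
  attr(out, "objective") <- max(res$value, o0)
  out
}

#' Local refinement of alignment parameters
#'
#' Derivative-free (Nelder-Mead) maximization of the complete objective
#' O = CC + R over Euler angles and shifts. The returned objective is never
#' below the objective at the initial parameters.
#'
#' @param particle `em_image`
#' @param reference `em_volume`
#' @param init `alignment_params` starting point
#' @param config `search_config`
#' @param restraint `restraint_model` or NULL
#' @param ctf `ctf_params` or NULL
#' @param pssnr `radial_profile` or NULL
#' @return `alignment_params` with attributes `objective` and `score`
#' @export
local_refine <- function(particle, reference, init, config = search_config(),
                         restraint = NULL, ctf = NULL, pssnr = NULL,
                         max_evals = 150) {
  prep <- add_shell_info(prepare_particle_mf(
    particle, ctf, pssnr %||% flat_pssnr(particle), config))
  ref <- prepare_reference_mf(reference)
  out <- local_refine_prepared(prep, ref, init, restraint, max_evals)
  attr(out, "score") <- 100 * attr(out, "objective")
  out
}

#' Per-particle defocus refinement
#'
#' One-dimensional grid search of a defocus offset applied to both defocus
#' values (default: steps of 50 Angstrom over +/- 500 Angstrom), keeping
#' the offset that maximizes the objective at the particle's current
#' alignment parameters.
#'
#' @param particle `em_image`
#' @param reference `em_volume`
#' @param params `alignment_params` (orientation fixed during the search)
#' @param ctf `ctf_params` for the micrograph
#' @param pssnr `radial_profile` or NULL
#' @param config `search_config` (provides range, step and bands)
#' @return best defocus offset in Angstrom (attribute `objective`)
#' @export
refine_defocus <- function(particle, reference, params, ctf,
                           pssnr = NULL, config = search_config()) {
  offsets <- seq(-config$defocus_range, config$defocus_range,
                 by = config$defocus_step)
  ref <- prepare_reference_mf(reference)
  best <- NULL
  for (off in offsets) {
    ctf_i <- ctf
    ctf_i$defocus1 <- ctf$defocus1 + off
    ctf_i$defocus2 <- ctf$defocus2 + off
    prep <- add_shell_info(prepare_particle_mf(
      particle, ctf_i, pssnr %||% flat_pssnr(particle), config))
    o <- objective_eval(prep, ref, params, NULL)
    if (is.null(best) || o > best$o) best <- list(o = o, off = off)
  }
  out <- best$off
  attr(out, "objective") <- best$o
  out
}

#' Apply a 3D mask to a reference volume
#'
#' The mask volume is binarized (voxels > 0 become 1), given a soft
#' cosine-shaped falloff of the requested width, and applied so that the
#' region outside is set to zero or to a low-pass filtered version of the
#' original density, optionally down-weighted. At the mask edge the
#' outside density is blended with the unfiltered density inside.
#'
#' @param volume `em_volume` to mask
#' @param mask_volume `em_volume` with positive values inside the mask
#' @param falloff_width cosine falloff width in Angstrom (e.g. 10)
#' @param outside_lp low-pass resolution (A) for the outside density, or
#'   NULL for zero outside
#' @param outside_weight weight of the outside density in [0, 1]
#' @return masked `em_volume`
#' @export
mask_reference_3d <- function(volume, mask_volume, falloff_width = 10,
                              outside_lp = NULL, outside_weight = 0) {
  stopifnot(identical(dim(volume$data), dim(mask_volume$data)))
  bin <- mask_volume$data > 0
  if (!any(bin)) stop("empty mask (all voxels <= 0)")
  px <- volume$pixel_size
  soft <- soft_mask_from_binary(bin, falloff_width / px)
  outside <- 0
  if (!is.null(outside_lp) && outside_weight > 0)
    outside <- fourier_bandpass(volume$data, px, lowpass = outside_lp) *
      outside_weight
  em_volume(volume$data * soft + outside * (1 - soft), px)
}

# cosine falloff over `width` voxels measured inward from the binary edge
soft_mask_from_binary <- function(bin, width) {
  m <- array(as.numeric(bin), dim(bin))
  k <- ceiling(width)
  if (k < 1) return(m)
  er <- bin
  depth <- array(ifelse(bin, k + 1, 0), dim(bin))
  for (d in seq_len(k)) {
    er <- erode6(er)
    depth[bin & !er & depth == k + 1] <- d
    bin <- er  # erode progressively
  }
  soft <- array(0, dim(depth))
  inside <- depth > 0
  soft[inside] <- 0.5 * (1 - cos(pi * pmin(depth[inside], k + 1) / (k + 1)))
  soft
}

# 6-neighborhood binary erosion via shifts; outside the array counts as
# inside so an all-positive mask stays the identity
erode6 <- function(b) {
  n <- dim(b)
  sh <- function(a, d, k) {
    out <- array(TRUE, dim(a))
    src <- lapply(n, seq_len)
    dst <- src
    if (k > 0) { dst[[d]] <- (k + 1):n[d]; src[[d]] <- 1:(n[d] - k) }
    else { dst[[d]] <- 1:(n[d] + k); src[[d]] <- (1 - k):n[d] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  b & sh(b, 1, 1) & sh(b, 1, -1) & sh(b, 2, 1) & sh(b, 2, -1) &
    sh(b, 3, 1) & sh(b, 3, -1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flat_pssnr <- function(particle) {
  n <- box_size(particle)
  dg <- 1 / (n * particle$pixel_size)
  radial_profile(pmax((0:(n %/% 2)) * dg, 1e-12),
                 rep(1, n %/% 2 + 1))
}
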