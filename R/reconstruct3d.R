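# Fourier-insertion 3D reconstruction with per-particle weighting,
# likelihood-based blurring, FSC / PSSNR / resolution machinery and map
# sharpening.

#' Background-whiten a particle image for reconstruction
#'
#' The noise spectrum is measured on B(X), a copy of the particle with the
#' area inside the circular mask replaced by the average value at the mask
#' edge; the particle transform is divided by sqrt of the radially averaged
#' power of B(X) and the result is rescaled to unit average pixel variance.
#' The signal inside the mask is untouched by the replacement (it only
#' affects the spectrum estimate).
#'
#' @param particle `em_image`
#' @param mask_radius circular mask radius in Angstrom
#' @return `em_image` with attribute `sigma_scale` (the applied scale)
#' @export
whiten_background <- function(particle, mask_radius) {
  n <- box_size(particle)
  px <- particle$pixel_size
  r <- make_soft_mask(n, px, mask_radius, 0, ndim = 2L)
  inside <- r >= 0.5
  edge <- make_soft_mask(n, px, mask_radius + 2 * px, 0, ndim = 2L) >= 0.5 &
    !inside
  if (!any(!inside)) stop("mask leaves no background ring")
  bx <- particle$data
  bx[inside] <- mean(particle$data[edge])
  pw <- radial_average(Mod(fft2(bx - mean(bx)))^2, px)
  pw$values[pw$values <= 0] <- min(pw$values[pw$values > 0])
  g <- freq_magnitude(c(n, n), px)
  wfilt <- matrix(1 / sqrt(profile_at(pw, as.vector(g))), n, n)
  wfilt[1, 1] <- 0
  out <- Re(ifft2(fft2(particle$data) * wfilt))
  sc <- 1 / sd(out)
  em_image(out * sc, px) |> (\(im) { attr(im, "sigma_scale") <- sc; im })()
}

#' Create an empty reconstruction accumulator
#'
#' Holds the complex numerator and real (CTF^2) denominator grids of the
#' Fourier-insertion reconstruction. Accumulators are mergeable with
#' [merge_accumulators()], mirroring reconstruction parallelization by
#' merge of intermediate reconstructions.
#'
#' @param box box size in voxels
#' @param pixel_size voxel size in Angstrom
#' @return object of class `recon_accumulator`
#' @export
recon_accumulator <- function(box, pixel_size) {
  n3 <- as.double(box)^3
  structure(list(num_re = numeric(n3), num_im = numeric(n3),
                 den = numeric(n3), n = as.integer(box),
                 pixel_size = pixel_size, count = 0L),
            class = "recon_accumulator")
}

#' Insert one particle into a reconstruction accumulator
#'
#' Adds (q / sigma^2) x trilinear spreading of w CTF F(X) into the
#' numerator and of w CTF^2 into the denominator along the central slice
#' at the particle's orientation; the particle's shifts are removed by
#' phase ramps before insertion. Friedel mates are inserted so Hermitian
#' symmetry is kept.
#'
#' @param acc `recon_accumulator`
#' @param particle whitened `em_image` (see [whiten_background()])
#' @param params `alignment_params`
#' @param ctf `ctf_params` or NULL
#' @param q class occupancy in [0, 1]
#' @param sigma per-particle noise standard deviation
#' @param weight_g optional per-frequency weight function of g (score
#'   weighting, see [score_weights()]); NULL = 1
#' @param res_limit optional insertion resolution limit (A)
#' @return updated accumulator
#' @export
insert_particle <- function(acc, particle, params, ctf = NULL, q = 1,
                            sigma = 1, weight_g = NULL, res_limit = NULL) {
  if (q == 0) return(acc)
  n <- acc$n
  px <- acc$pixel_size
  if (any(!is.finite(particle$data))) stop("non-finite particle pixels")
  fl <- freq_list(n, px, res_limit = res_limit, half = TRUE)
  # undo the particle's shift and move to the origin-centered convention
  # of the insertion grid
  x <- fft2(particle$data)[fl$idx] * center_phase(fl)
  x <- x * shift_phase(fl, -params$sx / px, -params$sy / px)
  cvec <- if (is.null(ctf)) rep(1, length(x)) else ctf_at(ctf, fl)
  w <- if (is.null(weight_g)) 1 else weight_g(fl$g)
  fac <- q / sigma^2
  rot <- euler_matrix(params$phi, params$theta, params$psi)
  cp_insert_slice(acc$num_re, acc$num_im, acc$den, n, rot,
                  as.numeric(fl$hx), as.numeric(fl$hy),
                  as.complex(fac * w * cvec * x), fac * w * cvec^2)
  acc$count <- acc$count + 1L
  acc
}

#' Merge reconstruction accumulators
#'
#' Numerators and denominators add linearly, so reconstructing a
#' concatenated particle set equals merging per-set accumulators.
#'
#' @param a,b `recon_accumulator` objects on the same grid
#' @return merged accumulator
#' @export
merge_accumulators <- function(a, b) {
  stopifnot(a$n == b$n, a$pixel_size == b$pixel_size)
  a$num_re <- a$num_re + b$num_re
  a$num_im <- a$num_im + b$num_im
  a$den <- a$den + b$den
  a$count <- a$count + b$count
  a
}

#' Finalize a reconstruction
#'
#' V = IFFT( numerator / (denominator + 1/PSSNR) ). Shells with
#' PSSNR <= 0 are zeroed (infinite Wiener term); Friedel symmetry is
#' enforced by taking the real part.
#'
#' @param acc `recon_accumulator` with at least one insertion
#' @param pssnr `radial_profile` of the particle SSNR, or a single number
#'   used flat across shells
#' @return `em_volume`
#' @export
finalize_reconstruction <- function(acc, pssnr = 1000) {
  stopifnot(acc$count >= 1)
  n <- acc$n
  g <- freq_magnitude(c(n, n, n), acc$pixel_size)
  pvals <- if (inherits(pssnr, "radial_profile"))
    profile_at(pssnr, as.vector(g)) else rep(pssnr, length(g))
  wiener <- ifelse(pvals > 0, 1 / pvals, Inf)
  num <- array(complex(real = acc$num_re, imaginary = acc$num_im),
               c(n, n, n))
  den <- array(acc$den + wiener, c(n, n, n))
  vft <- num / den
  vft[!is.finite(Re(vft)) | !is.finite(Im(vft))] <- 0
  # the accumulation grid holds the object at the array origin; roll the
  # inverse transform back to the box-centered convention
  em_volume(fftshift3(Re(ifft3(vft))), acc$pixel_size)
}

#' Score-based particle weight function
#'
#' w(score, g) = exp( -(BSC / 4) (score - score_mean) g^2 ). BSC converts
#' score differences into B-factor differences; BSC = 0 disables the
#' weighting (w = 1).
#'
#' @param score particle score
#' @param score_mean dataset average score
#' @param bsc B-factor conversion constant (A^2)
#' @return function of g (1/A) returning the weight; w(0) = 1 always
#' @export
score_weights <- function(score, score_mean, bsc) {
  force(score); force(score_mean); force(bsc)
  function(g) exp(-(bsc / 4) * (score - score_mean) * g^2)
}

# ---- FSC machinery ---------------------------------------------------------

#' Fourier shell correlation between two maps
#'
#' Standard per-shell normalized cross-correlation of the two transforms,
#' optionally after applying a real-space mask; the reported curve is
#' smoothed with a Savitzky-Golay cubic polynomial.
#'
#' @param half1,half2 `em_volume` half-maps on the same grid
#' @param mask optional numeric array in [0, 1] applied to both maps
#' @param sg_window Savitzky-Golay window (odd; 7 by default)
#' @return object of class `fsc_curve`: list(shells (1/A), fsc (smoothed),
#'   fsc_raw, pixel_size)
#' @export
compute_fsc <- function(half1, half2, mask = NULL, sg_window = 7) {
  stopifnot(identical(dim(half1$data), dim(half2$data)))
  n <- dim(half1$data)[1]
  px <- half1$pixel_size
  a <- half1$data; b <- half2$data
  if (!is.null(mask)) { a <- a * mask; b <- b * mask }
  fa <- fft3(a); fb <- fft3(b)
  g <- freq_magnitude(c(n, n, n), px)
  dg <- 1 / (n * px)
  shell <- pmin(floor(g / dg + 0.5), n %/% 2) + 1L
  nsh <- n %/% 2 + 1L
  cross <- rowsum_vec(as.vector(Re(fa * Conj(fb))), as.vector(shell), nsh)
  p1 <- rowsum_vec(as.vector(Mod(fa)^2), as.vector(shell), nsh)
  p2 <- rowsum_vec(as.vector(Mod(fb)^2), as.vector(shell), nsh)
  fsc_raw <- ifelse(p1 > 0 & p2 > 0, cross / sqrt(p1 * p2), 0)
  fsc_raw <- pmin(fsc_raw, 1)
  sm <- fsc_raw
  if (nsh > sg_window && sg_window >= 5)
    sm <- pmin(signal::sgolayfilt(fsc_raw, p = 3, n = sg_window), 1)
  shells <- pmax((0:(nsh - 1)) * dg, 1e-12)
  structure(list(shells = shells, fsc = sm, fsc_raw = fsc_raw,
                 pixel_size = px), class = "fsc_curve")
}

#' Solvent-corrected FSC between half-maps
#'
#' Part_FSC = f FSC / (1 + (f - 1) FSC), where f is the ratio of mask
#' volume to estimated particle volume (f = 1 is the identity; FSC = 1 is
#' a fixed point for any f).
#'
#' @param fsc `fsc_curve`
#' @param f mask-to-particle volume ratio (>= 1)
#' @return `fsc_curve` with corrected values
#' @export
part_fsc <- function(fsc, f) {
  stopifnot(f >= 1)
  out <- fsc
  out$fsc <- f * fsc$fsc / (1 + (f - 1) * fsc$fsc)
  out$fsc_raw <- f * fsc$fsc_raw / (1 + (f - 1) * fsc$fsc_raw)
  out
}

#' Solvent-corrected FSC against a noise-free model map
#'
#' Part_FSC = f FSC^2 / (1 + (f - 1) FSC^2): the squared-FSC variant used
#' when one of the maps (e.g. derived from an atomic model) carries no
#' solvent noise.
#'
#' @param fsc `fsc_curve`
#' @param f mask-to-particle volume ratio (>= 1)
#' @return `fsc_curve`
#' @export
part_fsc_model <- function(fsc, f) {
  stopifnot(f >= 1)
  out <- fsc
  out$fsc <- f * fsc$fsc^2 / (1 + (f - 1) * fsc$fsc^2)
  out$fsc_raw <- f * fsc$fsc_raw^2 / (1 + (f - 1) * fsc$fsc_raw^2)
  out
}

#' Particle volume from molecular mass
#'
#' V = Mw / 0.81 Angstrom^3 per Dalton.
#'
#' @param mw molecular mass in Dalton (> 0)
#' @return volume in Angstrom^3
#' @export
particle_volume_from_mass <- function(mw) {
  stopifnot(mw > 0)
  mw / 0.81
}

#' Mask-to-particle volume ratio for a spherical mask
#'
#' @param mask_radius spherical mask radius in Angstrom
#' @param mw molecular mass in Dalton
#' @return f = (4/3) pi r^3 / (Mw / 0.81), floored at 1
#' @export
solvent_ratio <- function(mask_radius, mw) {
  max(1, (4 / 3) * pi * mask_radius^3 / particle_volume_from_mass(mw))
}

#' Resolution at an FSC threshold
#'
#' First crossing of the (smoothed) FSC below the threshold, by linear
#' interpolation between shells; returns the Nyquist resolution when the
#' curve never crosses.
#'
#' @param fsc `fsc_curve`
#' @param threshold 0.143 for reported resolution, 0.5 inside
#'   auto-refinement
#' @return resolution in Angstrom
#' @export
resolution_at_threshold <- function(fsc, threshold = 0.143) {
  v <- fsc$fsc
  s <- fsc$shells
  nyq <- 1 / (2 * fsc$pixel_size)
  for (i in 2:length(v)) {
    if (s[i] > nyq + 1e-12) break
    if (v[i] < threshold && v[i - 1] >= threshold) {
      gg <- s[i - 1] + (threshold - v[i - 1]) / (v[i] - v[i - 1]) *
        (s[i] - s[i - 1])
      return(1 / gg)
    }
  }
  1 / nyq
}

#' Particle SSNR from the solvent-corrected half-map FSC
#'
#' The half-dataset SSNR per shell is 2 FSC / (1 - FSC); the full-dataset
#' value is twice that. Values are clipped at a ceiling; FSC <= 0 gives 0.
#' No CTF^2-coverage factor is tracked.
#'
#' @param fsc `fsc_curve` (typically the solvent-corrected Part_FSC)
#' @param ceiling upper clip for near-unity FSC shells
#' @return `radial_profile`
#' @export
pssnr_from_fsc <- function(fsc, ceiling = 1000) {
  v <- pmax(pmin(fsc$fsc, 1), 0)
  half <- ifelse(v >= 1, Inf, 2 * v / (1 - v))
  full <- pmin(2 * half, ceiling)
  full[v <= 0] <- 0
  radial_profile(fsc$shells, full)
}

#' Likelihood-blurred reconstruction
#'
#' Each particle is inserted multiple times over a grid of in-plane
#' rotation and x,y shifts, weighted by its normalized likelihood values;
#' the denominator uses the single maximum-likelihood insertion as in the
#' unblurred reconstruction.
#'
#' @param acc `recon_accumulator` to fill
#' @param particle whitened `em_image`
#' @param params `alignment_params` (MAP estimate)
#' @param gamma data.frame(dalpha (deg), dx, dy (A), weight) of likelihood
#'   weights over the in-plane grid; weights are normalized internally
#' @param ctf,q,sigma,weight_g,res_limit as in [insert_particle()]
#' @return updated accumulator
#' @export
insert_particle_blurred <- function(acc, particle, params, gamma,
                                    ctf = NULL, q = 1, sigma = 1,
                                    weight_g = NULL, res_limit = NULL) {
  if (nrow(gamma) == 0 || sum(gamma$weight) <= 0)
    stop("degenerate (all-zero) likelihood weights")
  w <- gamma$weight / sum(gamma$weight)
  n0 <- acc$count
  den_keep <- acc$den + 0  # deep copy: insertions modify `den` in place
  for (j in seq_len(nrow(gamma))) {
    pj <- params
    pj$psi <- params$psi + gamma$dalpha[j]
    pj$sx <- params$sx + gamma$dx[j]
    pj$sy <- params$sy + gamma$dy[j]
    acc <- insert_particle(acc, particle, pj, ctf, q * w[j], sigma,
                           weight_g, res_limit)
  }
  # replace the blurred denominator contribution with a single insertion
  acc$den <- den_keep
  tmp <- recon_accumulator(acc$n, acc$pixel_size)
  tmp <- insert_particle(tmp, particle, params, ctf, q, sigma, weight_g,
                         res_limit)
  acc$den <- acc$den + tmp$den
  acc$count <- n0 + 1L
  acc
}

# ---- map sharpening --------------------------------------------------------

#' Sharpening configuration
#'
#' @param bfactor B-factor in A^2 applied as exp(-B g^2 / 4) (negative
#'   sharpens)
#' @param whiten_beyond resolution (A) beyond which the radial power
#'   spectrum is flattened (NULL disables; default 8)
#' @param mask_inner,mask_outer hollow spherical mask radii in Angstrom
#'   (NULL disables masking)
#' @param resolution_cutoff final low-pass limit (A; NULL = none)
#' @param fom_filter apply the figure-of-merit filter
#'   sqrt(2 FSC / (1 + FSC)) from the reconstruction's FSC
#' @return object of class `sharpen_config`
#' @export
sharpen_config <- function(bfactor = 0, whiten_beyond = 8,
                           mask_inner = 0, mask_outer = NULL,
                           resolution_cutoff = NULL, fom_filter = FALSE) {
  if (!is.null(mask_outer)) stopifnot(mask_outer > mask_inner)
  structure(list(bfactor = bfactor, whiten_beyond = whiten_beyond,
                 mask_inner = mask_inner, mask_outer = mask_outer,
                 resolution_cutoff = resolution_cutoff,
                 fom_filter = fom_filter),
            class = "sharpen_config")
}

#' Sharpen a map
#'
#' Pipeline: optional hollow-sphere (or custom) mask, per-shell whitening
#' of the power spectrum beyond `whiten_beyond`, B-factor
#' exp(-B g^2 / 4), optional figure-of-merit filtering from the FSC, and
#' an optional resolution cutoff.
#'
#' @param volume `em_volume`
#' @param config `sharpen_config`
#' @param fsc `fsc_curve` (required when `fom_filter = TRUE`)
#' @param custom_mask optional array in [0, 1] replacing the hollow sphere
#' @return sharpened `em_volume`
#' @export
sharpen_map <- function(volume, config, fsc = NULL, custom_mask = NULL) {
  n <- box_size(volume)
  px <- volume$pixel_size
  nyq <- 1 / (2 * px)
  if (!is.null(config$resolution_cutoff) &&
      1 / config$resolution_cutoff > nyq + 1e-12)
    stop("resolution cutoff beyond Nyquist")
  v <- volume$data
  if (!is.null(custom_mask)) {
    v <- v * custom_mask
  } else if (!is.null(config$mask_outer)) {
    outer_m <- make_soft_mask(n, px, config$mask_outer,
                              min(4 * px, config$mask_outer / 4), ndim = 3L)
    m <- outer_m
    if (config$mask_inner > 0) {
      inner_m <- make_soft_mask(n, px, config$mask_inner,
                                min(2 * px, config$mask_inner / 2), ndim = 3L)
      m <- outer_m * (1 - inner_m)
    }
    v <- v * m
  }
  ft <- fft3(v)
  g <- freq_magnitude(c(n, n, n), px)
  dg <- 1 / (n * px)
  shell <- pmin(floor(g / dg + 0.5), n %/% 2) + 1L
  filt <- array(1, c(n, n, n))
  if (!is.null(config$whiten_beyond)) {
    pw <- rowsum_vec(as.vector(Mod(ft)^2), as.vector(shell), n %/% 2 + 1L)
    cnt <- tabulate(as.vector(shell), n %/% 2 + 1L)
    pw <- pw / pmax(cnt, 1)
    gw <- 1 / config$whiten_beyond
    k0 <- min(max(1L, floor(gw / dg + 0.5) + 1L), n %/% 2 + 1L)
    target <- pw[k0]
    scale <- rep(1, n %/% 2 + 1L)
    hi <- seq_along(pw) > k0 & pw > 0
    scale[hi] <- sqrt(target / pw[hi])
    filt <- filt * array(scale[shell], c(n, n, n))
  }
  if (config$bfactor != 0)
    filt <- filt * exp(-config$bfactor * g^2 / 4)
  if (config$fom_filter) {
    stopifnot(!is.null(fsc))
    fv <- pmax(pmin(profile_at(
      radial_profile(fsc$shells, fsc$fsc), as.vector(g)), 1), 0)
    filt <- filt * array(sqrt(2 * fv / (1 + fv)), c(n, n, n))
  }
  if (!is.null(config$resolution_cutoff)) {
    gc <- 1 / config$resolution_cutoff
    filt <- filt * soft_edge(g, gc + 2 * dg, 2 * dg)
  }
  em_volume(Re(ifft3(ft * filt)), px)
}
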