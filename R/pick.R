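# Matched-filter particle picking with a soft-edged disk template.
# Micrographs are Fourier-cropped to a working pixel size of
# highest_resolution/2 (default 15 A), high-pass filtered, whitened using
# the average rotational power spectrum of areas devoid of particles, and
# scored against a CTF-convolved disk so that the score map is ~N(0,1)
# under a particle-free null.

#' Picking parameters
#'
#' @param template_radius radius of the soft-edged disk template, Angstrom
#' @param max_particle_radius maximum particle radius, Angstrom; sets the
#'   minimum distance between picks (>= template_radius)
#' @param threshold_sd detection threshold in standard deviations of the
#'   null score distribution (values 1-6 generally acceptable)
#' @param highest_resolution highest resolution used in picking, Angstrom
#'   (working pixel size is half this value)
#' @param n_background_areas number of particle-free areas used for the
#'   background noise spectrum
#' @param use_variance_mode_areas select background areas closest to the
#'   mode of the local-variance distribution instead of the lowest-variance
#'   areas
#' @param phase_plate_phase phase-plate phase shift in radians, or NULL
#' @return object of class `pick_params`
#' @export
pick_params <- function(template_radius, max_particle_radius,
                        threshold_sd = 4, highest_resolution = 30,
                        n_background_areas = 50,
                        use_variance_mode_areas = FALSE,
                        phase_plate_phase = NULL) {
  stopifnot(threshold_sd > 0, max_particle_radius >= template_radius,
            n_background_areas >= 1)
  structure(list(template_radius = template_radius,
                 max_particle_radius = max_particle_radius,
                 threshold_sd = threshold_sd,
                 highest_resolution = highest_resolution,
                 n_background_areas = n_background_areas,
                 use_variance_mode_areas = use_variance_mode_areas,
                 phase_plate_phase = phase_plate_phase),
            class = "pick_params")
}

#' Resample and high-pass filter a micrograph for picking
#'
#' Fourier-crops to a working pixel size of `highest_resolution / 2` and
#' removes very low-frequency density ramps with a cosine-edged high-pass
#' aperture.
#'
#' @param micrograph `em_image`
#' @param params `pick_params`
#' @return working-scale `em_image`
#' @export
pick_preprocess <- function(micrograph, params) {
  target_px <- params$highest_resolution / 2
  if (micrograph$pixel_size > target_px + 1e-9)
    stop("micrograph pixel size exceeds the working pixel size")
  work <- fourier_crop(micrograph, target_px)
  if (box_size(work) < 4 * params$max_particle_radius / work$pixel_size)
    stop("micrograph smaller than a few template diameters")
  # remove density ramps above a few particle diameters
  hp <- min(4 * params$max_particle_radius,
            box_size(work) * work$pixel_size / 4)
  out <- fourier_bandpass(work, highpass = hp, edge_shells = 2)
  out$data <- out$data - mean(out$data)
  out
}

#' Local mean and variance maps with histogram mode statistics
#'
#' Per-pixel mean and variance over a disk of the given radius (computed by
#' FFT convolution), plus the mode (Mo) and full width at half maximum
#' (FWHM) of the histogram of each map.
#'
#' @param image working-scale `em_image`
#' @param radius disk radius in Angstrom (>= 2 working pixels)
#' @return list(mean_map, variance_map, mo_mean, fwhm_mean, mo_var, fwhm_var)
#' @export
local_stats <- function(image, radius) {
  n <- box_size(image)
  px <- image$pixel_size
  r_px <- radius / px
  stopifnot(r_px >= 2)
  ax <- (seq_len(n) - 1 - n / 2) * 1
  disk <- outer(ax^2, ax^2, `+`) <= r_px^2
  kernel <- fftshift2(disk / sum(disk))
  kft <- fft2(kernel)
  mean_map <- Re(ifft2(fft2(image$data) * Conj(kft)))
  mean_sq <- Re(ifft2(fft2(image$data^2) * Conj(kft)))
  var_map <- pmax(mean_sq - mean_map^2, 0)
  sm <- mode_fwhm(mean_map)
  sv <- mode_fwhm(var_map)
  list(mean_map = mean_map, variance_map = var_map,
       mo_mean = sm$mode, fwhm_mean = sm$fwhm,
       mo_var = sv$mode, fwhm_var = sv$fwhm)
}

# histogram mode and FWHM of a map
mode_fwhm <- function(x) {
  v <- as.vector(x)
  d <- stats::density(v, n = 512)
  k <- which.max(d$y)
  half <- d$y[k] / 2
  above <- d$y >= half
  lo <- suppressWarnings(min(which(above)))
  hi <- suppressWarnings(max(which(above)))
  list(mode = d$x[k], fwhm = max(d$x[hi] - d$x[lo], 0))
}

#' Background-noise whitening filter from particle-free areas
#'
#' Averages the rotational power spectrum of `n_background_areas` square
#' tiles (side = 2 x max particle radius) chosen either with the lowest
#' local variance or closest to the variance mode, and returns the
#' whitening filter 1/sqrt(background power) per shell.
#'
#' @param image working-scale `em_image`
#' @param stats output of [local_stats()]
#' @param params `pick_params`
#' @return list(filter = `radial_profile`, areas = matrix of tile centers
#'   (pixels))
#' @export
background_whitening_filter <- function(image, stats, params) {
  n <- box_size(image)
  px <- image$pixel_size
  side <- max(2L * ceiling(params$max_particle_radius / px), 24L)
  if (side %% 2L == 1L) side <- side + 1L
  if (side > n) stop("micrograph too small for background tiles")
  step <- side %/% 2L
  x0 <- seq(1, n - side + 1, by = step)
  centers <- expand.grid(x = x0, y = x0)
  ci <- pmin(centers$x + step, n)
  v <- stats$variance_map[cbind(ci, pmin(centers$y + step, n))]
  k <- min(params$n_background_areas, length(v))
  if (k < params$n_background_areas)
    warning("fewer candidate areas than requested; using all ", k)
  ord <- if (params$use_variance_mode_areas)
    order(abs(v - stats$mo_var)) else order(v)
  sel <- ord[seq_len(k)]
  # Hann-windowed tile spectra: the window suppresses the spectral
  # leakage that would otherwise tilt the background estimate
  hw <- 0.5 - 0.5 * cos(2 * pi * (0:(side - 1)) / (side - 1))
  hann <- outer(hw, hw)
  hnorm <- mean(hann^2)
  acc <- NULL
  p <- NULL
  for (s in sel) {
    tile <- image$data[centers$x[s]:(centers$x[s] + side - 1),
                       centers$y[s]:(centers$y[s] + side - 1)]
    tile <- (tile - mean(tile)) * hann
    p <- radial_average(Mod(fft2(tile))^2 / hnorm, px)
    acc <- if (is.null(acc)) p$values else acc + p$values
  }
  pw <- acc / k
  pw[pw <= 0] <- min(pw[pw > 0])
  list(filter = radial_profile(p$bin_centers, 1 / sqrt(pw)),
       areas = cbind(x = centers$x[sel] + step, y = centers$y[sel] + step))
}

#' Matched-filter score map in SD units
#'
#' Whitens the micrograph with the background filter, correlates it with a
#' CTF-convolved soft-edged disk template, and normalizes so that under a
#' no-particle null the scores are ~N(0, 1).
#'
#' @param image working-scale `em_image`
#' @param whitening output of [background_whitening_filter()]
#' @param ctf `ctf_params` for the micrograph (NULL = no CTF convolution)
#' @param params `pick_params`
#' @return `em_image` score map (working scale, SD units)
#' @export
match_template <- function(image, whitening, ctf, params) {
  n <- box_size(image)
  px <- image$pixel_size
  g <- freq_magnitude(c(n, n), px)
  wfilt <- matrix(profile_at(whitening$filter, as.vector(g)), n, n)
  wfilt[1, 1] <- 0  # remove DC
  ft_w <- fft2(image$data) * wfilt
  white <- Re(ifft2(ft_w))
  sdw <- sd(white)
  if (sdw > 0) { white <- white / sdw; ft_w <- ft_w / sdw }
  # soft-edged disk template, centered at origin (wrapped)
  ax <- c(0:(n / 2 - 1), -(n / 2):-1) * px
  r <- sqrt(outer(ax^2, ax^2, `+`))
  edge <- min(2 * px, params$template_radius / 2)
  tmpl <- soft_edge(r, params$template_radius + edge, edge)
  tft <- fft2(tmpl)
  # signed CTF: particles carry phase-contrast sign (dark at underfocus);
  # the template is whitened like the image (matched filtering divides the
  # cross-spectrum by the noise power)
  if (!is.null(ctf)) tft <- tft * ctf_image(ctf, n, px)
  tft <- tft * wfilt
  tft[1, 1] <- 0
  # unit-norm template in real space => null scores have ~unit variance
  tnorm <- sqrt(sum(Mod(tft)^2) / (n * n))
  if (tnorm == 0) stop("degenerate template")
  score <- Re(ifft2(ft_w * Conj(tft))) / tnorm
  # residual spatial correlation after whitening biases the analytic
  # normalization; rescale by the null SD estimated from the negative
  # side of the score distribution (particles only add positive mass)
  neg <- score - median(score)
  msd <- -quantile(neg, pnorm(-1), names = FALSE)
  if (msd > 0) score <- (score - median(score)) / msd
  em_image(score, px)
}

#' Exclusion mask for abnormal local mean or variance
#'
#' Excludes pixels with local variance above Mo + k FWHM (k = 2, raised to
#' 8 for phase-plate phases in (0.1 pi, 0.9 pi)) or local mean outside
#' Mo +/- 2 FWHM.
#'
#' @param stats output of [local_stats()]
#' @param params `pick_params` (phase-plate phase read from here)
#' @return logical matrix, TRUE = excluded
#' @export
exclusion_mask <- function(stats, params) {
  if (stats$fwhm_var == 0 || stats$fwhm_mean == 0) {
    warning("degenerate histogram (FWHM = 0); excluding nothing")
    return(matrix(FALSE, nrow(stats$mean_map), ncol(stats$mean_map)))
  }
  k <- 2
  pp <- params$phase_plate_phase
  if (!is.null(pp) && pp > 0.1 * pi && pp < 0.9 * pi) k <- 8
  (stats$variance_map > stats$mo_var + k * stats$fwhm_var) |
    (stats$mean_map > stats$mo_mean + 2 * stats$fwhm_mean) |
    (stats$mean_map < stats$mo_mean - 2 * stats$fwhm_mean)
}

#' Greedy peak picking with minimum-distance suppression
#'
#' Selects peaks in descending score order, suppressing all pixels within
#' `max_particle_radius` of each accepted pick; excluded pixels are never
#' picked. Coordinates are mapped back to Angstrom on the original
#' micrograph. Ties are broken by scan order (deterministic).
#'
#' @param score_map `em_image` from [match_template()]
#' @param exclusion logical matrix from [exclusion_mask()] (or NULL)
#' @param params `pick_params`
#' @return data.frame(x, y, peak_sd) with coordinates in Angstrom; class
#'   `pick_list`
#' @export
find_peaks <- function(score_map, exclusion, params) {
  n <- box_size(score_map)
  px <- score_map$pixel_size
  s <- score_map$data
  if (!is.null(exclusion)) s[exclusion] <- -Inf
  border <- ceiling(params$template_radius / px)
  if (border > 0 && 2 * border < n) {
    s[c(seq_len(border), (n - border + 1):n), ] <- -Inf
    s[, c(seq_len(border), (n - border + 1):n)] <- -Inf
  }
  min_d_px <- params$max_particle_radius / px
  cand <- which(s >= params$threshold_sd)
  cand <- cand[order(s[cand], decreasing = TRUE)]
  picked <- matrix(numeric(0), 0, 3)
  for (k in cand) {
    i <- (k - 1) %% n + 1
    j <- (k - 1) %/% n + 1
    if (nrow(picked) > 0 &&
        any((picked[, 1] - i)^2 + (picked[, 2] - j)^2 < min_d_px^2)) next
    picked <- rbind(picked, c(i, j, s[k]))
  }
  out <- data.frame(x = (picked[, 1] - 1) * px, y = (picked[, 2] - 1) * px,
                    peak_sd = picked[, 3])
  class(out) <- c("pick_list", "data.frame")
  out
}

#' Pick particles from a micrograph
#'
#' Full matched-filter picking driver: preprocess, local statistics,
#' background whitening, template matching, exclusion and peak finding.
#'
#' @param micrograph `em_image` at its native pixel size
#' @param params `pick_params`
#' @param ctf optional `ctf_params`
#' @return `pick_list` data.frame(x, y, peak_sd), coordinates in Angstrom
#' @export
pick_particles <- function(micrograph, params, ctf = NULL) {
  work <- pick_preprocess(micrograph, params)
  # local statistics at the micrograph's native sampling: per-pixel
  # particle contrast is weak there, so ordinary particles stay inside
  # the bulk of the histograms while genuinely abnormal areas (ice,
  # carbon) stand out; the maps are then resampled to the working grid
  hp <- min(4 * params$max_particle_radius,
            box_size(micrograph) * micrograph$pixel_size / 4)
  native <- fourier_bandpass(micrograph, highpass = hp, edge_shells = 2)
  st <- local_stats(native, params$max_particle_radius)
  nw <- box_size(work)
  ratio <- box_size(micrograph) / nw
  idx <- pmin(pmax(round((seq_len(nw) - 0.5) * ratio + 0.5), 1),
              box_size(micrograph))
  st$mean_map <- st$mean_map[idx, idx]
  st$variance_map <- st$variance_map[idx, idx]
  wh <- background_whitening_filter(work, st, params)
  score <- match_template(work, wh, ctf, params)
  excl <- exclusion_mask(st, params)
  find_peaks(score, excl, params)
}
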