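# CTF determination: 1D exhaustive pre-search over a radial average,
# 2D local refinement against the masked spectrum, moving-window fit
# quality, and an aliasing check, plus CTF evaluation used everywhere else.

#' Microscope + per-micrograph CTF description
#'
#' `defocus1 >= defocus2` is enforced by convention (values swapped and the
#' astigmatism angle rotated by 90 degrees when violated). Underfocus is
#' positive.
#'
#' @param defocus1,defocus2 defocus along the astigmatism axes, Angstrom
#' @param astig_angle astigmatism angle, degrees
#' @param phase_shift additional phase-plate phase shift, radians
#' @param voltage acceleration voltage, kV
#' @param cs spherical aberration, mm
#' @param amplitude_contrast amplitude contrast fraction in [0, 1)
#' @param pixel_size detector pixel size, Angstrom
#' @return object of class `ctf_params`
#' @export
ctf_params <- function(defocus1 = 15000, defocus2 = defocus1,
                       astig_angle = 0, phase_shift = 0, voltage = 300,
                       cs = 2.7, amplitude_contrast = 0.07,
                       pixel_size = 1.0) {
  stopifnot(amplitude_contrast >= 0, amplitude_contrast < 1, voltage > 0,
            pixel_size > 0)
  if (defocus2 > defocus1) {
    tmp <- defocus1; defocus1 <- defocus2; defocus2 <- tmp
    astig_angle <- astig_angle + 90
  }
  structure(list(defocus1 = defocus1, defocus2 = defocus2,
                 astig_angle = astig_angle %% 180, phase_shift = phase_shift,
                 voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "ctf_params")
}

# relativistic electron wavelength in Angstrom, voltage in kV
electron_wavelength <- function(kv) {
  v <- kv * 1000
  12.2639 / sqrt(v * (1 + v * 0.97845e-6))
}

# aberration phase chi(g, azimuth) in radians (without the amplitude term)
ctf_phase <- function(params, g, azimuth = 0) {
  lambda <- electron_wavelength(params$voltage)
  ang <- params$astig_angle * pi / 180
  df <- 0.5 * (params$defocus1 + params$defocus2 +
               (params$defocus1 - params$defocus2) * cos(2 * (azimuth - ang)))
  pi * lambda * g^2 * (df - 0.5 * lambda^2 * g^2 * (params$cs * 1e7)) +
    params$phase_shift
}

#' Evaluate the CTF at spatial frequency g
#'
#' Standard phase-aberration CTF with astigmatic defocus, spherical
#' aberration, amplitude contrast and an additive phase shift:
#' CTF = -sin(chi + atan(w / sqrt(1 - w^2))). Values lie in [-1, 1].
#'
#' @param params `ctf_params`
#' @param g spatial frequency in 1/Angstrom (vectorized, >= 0)
#' @param azimuth azimuth angle(s) in radians
#' @return numeric vector of CTF values
#' @export
evaluate_ctf <- function(params, g, azimuth = 0) {
  stopifnot(all(g >= 0))
  w <- params$amplitude_contrast
  -sin(ctf_phase(params, g, azimuth) + atan2(w, sqrt(1 - w^2)))
}

# CTF evaluated on the unshifted n x n Fourier grid of an image
ctf_image <- function(params, n, pixel_size = params$pixel_size) {
  ax <- freq_axis(n, pixel_size)
  gx <- matrix(ax, n, n)
  gy <- matrix(ax, n, n, byrow = TRUE)
  g <- sqrt(gx^2 + gy^2)
  evaluate_ctf(params, g, atan2(gy, gx))
}

# CTF at the points of a freq list
ctf_at <- function(params, fl) {
  gx <- fl$hx / (fl$n * fl$pixel_size)
  gy <- fl$hy / (fl$n * fl$pixel_size)
  evaluate_ctf(params, fl$g, atan2(gy, gx))
}

#' Average power spectrum of an image or movie for CTF fitting
#'
#' Tiles the input into overlapping square boxes, averages the squared
#' Fourier amplitudes, and returns the centered power spectrum. For movies,
#' frames are first grouped into sub-sums of `frames_to_sum` frames, which
#' strengthens Thon rings relative to using the full drift-blurred average.
#' When the pixel size is below 1.4 Angstrom, the spectrum is clipped so its
#' edge corresponds to 1/2.8 1/Angstrom so the rings are not all compressed
#' near the origin.
#'
#' @param x `em_image` or `em_stack` (movie frames)
#' @param frames_to_sum frames per sub-sum when `x` is a movie
#' @param tile tile box size in pixels (reduced to fit small inputs)
#' @return `em_image` containing the centered power spectrum; its
#'   `pixel_size` encodes the spectrum edge (Nyquist = 1/(2 pixel_size))
#' @export
amplitude_spectrum <- function(x, frames_to_sum = 1, tile = 512) {
  stopifnot(frames_to_sum >= 1)
  imgs <- list()
  if (inherits(x, "em_stack") || inherits(x, "movie_stack")) {
    nf <- dim(x$data)[3]
    starts <- seq(1, nf, by = frames_to_sum)
    for (s in starts) {
      e <- min(s + frames_to_sum - 1, nf)
      imgs[[length(imgs) + 1L]] <-
        em_image(apply(x$data[, , s:e, drop = FALSE], c(1, 2), sum),
                 x$pixel_size)
    }
  } else imgs <- list(x)
  n <- box_size(imgs[[1]])
  tile <- min(tile, n)
  if (tile %% 2L == 1L) tile <- tile - 1L
  if (tile < 16) stop("input box smaller than a usable spectrum size")
  px <- imgs[[1]]$pixel_size
  acc <- matrix(0, tile, tile)
  count <- 0
  starts <- unique(pmin(seq(1, n - tile + 1, by = max(1, tile %/% 2)),
                        n - tile + 1))
  for (img in imgs) {
    for (sx in starts) for (sy in starts) {
      t0 <- img$data[sx:(sx + tile - 1), sy:(sy + tile - 1)]
      t0 <- t0 - mean(t0)
      acc <- acc + Mod(fft2(t0))^2
      count <- count + 1
    }
  }
  ps <- fftshift2(acc / count)
  out_px <- px
  if (px < 1.4) {
    m <- 2L * max(4L, round(tile * px / 1.4 / 2))
    m <- min(m, tile)
    lo <- tile / 2 - m / 2 + 1
    ps <- ps[lo:(lo + m - 1), lo:(lo + m - 1)]
    out_px <- tile * px / m
  }
  em_image(ps, out_px)
}

# radial profile of a centered spectrum (shift back to the unshifted
# convention expected by radial_average)
spectrum_radial <- function(spectrum) {
  radial_average(fftshift2(spectrum$data), spectrum$pixel_size)
}

#' Subtract the slowly varying radial background from a power spectrum
#'
#' The background is the radial average smoothed with a wide running median
#' plus Savitzky-Golay pass, interpolated back onto the 2D grid and
#' subtracted, leaving Thon-ring modulation around zero.
#'
#' @param spectrum centered power spectrum from [amplitude_spectrum()]
#' @return `em_image`, background-subtracted spectrum
#' @export
subtract_background <- function(spectrum) {
  prof <- spectrum_radial(spectrum)
  v <- prof$values
  k <- max(5L, 2L * (length(v) %/% 16L) + 1L)
  bg <- stats::runmed(v, k, endrule = "median")
  if (length(bg) > 9) {
    w <- min(2L * (length(bg) %/% 8L) + 1L, length(bg) - 2L)
    if (w %% 2L == 0L) w <- w - 1L
    if (w >= 5) bg <- signal::sgolayfilt(bg, p = 3, n = w)
  }
  n <- box_size(spectrum)
  g <- fftshift2(freq_magnitude(c(n, n), spectrum$pixel_size))
  bg2d <- matrix(approx(prof$bin_centers, bg, xout = as.vector(g),
                        rule = 2)$y, n, n)
  em_image(spectrum$data - bg2d, spectrum$pixel_size)
}

# radial sine-edged mask used during CTF search/refinement: 0.0 at the
# origin, 1.0 from 1/4 1/A outward
ctf_fit_mask <- function(n, pixel_size) {
  g <- fftshift2(freq_magnitude(c(n, n), pixel_size))
  sin(pi / 2 * pmin(g / 0.25, 1))
}

weighted_cor <- function(a, b, w) {
  sw <- sum(w)
  ma <- sum(w * a) / sw; mb <- sum(w * b) / sw
  va <- sum(w * (a - ma)^2); vb <- sum(w * (b - mb)^2)
  if (va <= 0 || vb <= 0) return(0)
  sum(w * (a - ma) * (b - mb)) / sqrt(va * vb)
}

#' Exhaustive 1D CTF pre-search over a radial spectrum
#'
#' Grid search over defocus (and optionally phase shift) using the
#' rotationally averaged, background-subtracted spectrum and a 1D CTF model
#' (no astigmatism). Returns the grid argmax of the masked normalized
#' cross-correlation between CTF^2 and the profile.
#'
#' @param profile `radial_profile` of the background-subtracted spectrum
#' @param base `ctf_params` carrying the microscope constants
#' @param defocus_range length-2 vector (min, max) in Angstrom
#' @param defocus_step grid step in Angstrom
#' @param phase_shift_range optional length-2 vector in radians (NULL = no
#'   phase-plate search)
#' @param phase_shift_step phase grid step in radians
#' @param res_range fitting band as (low, high) resolution in Angstrom
#' @return list(defocus, phase_shift, cc)
#' @export
fit_ctf_1d <- function(profile, base, defocus_range, defocus_step,
                       phase_shift_range = NULL,
                       phase_shift_step = pi / 18,
                       res_range = c(30, NULL)) {
  stopifnot(defocus_range[2] >= defocus_range[1], defocus_step > 0)
  if (all(profile$values == 0)) stop("degenerate (all-zero) profile")
  g <- profile$bin_centers
  band <- g >= 1 / res_range[1]
  if (length(res_range) > 1 && !is.na(res_range[2]))
    band <- band & g <= 1 / res_range[2]
  g <- g[band]
  y <- profile$values[band]
  w <- sin(pi / 2 * pmin(g / 0.25, 1))
  defs <- seq(defocus_range[1], defocus_range[2], by = defocus_step)
  phases <- if (is.null(phase_shift_range)) 0 else
    seq(phase_shift_range[1], phase_shift_range[2], by = phase_shift_step)
  best <- list(defocus = defs[1], phase_shift = phases[1], cc = -Inf)
  for (ph in phases) {
    for (df in defs) {
      p <- base
      p$defocus1 <- p$defocus2 <- df
      p$phase_shift <- ph
      model <- evaluate_ctf(p, g)^2
      cc <- weighted_cor(y, model, w)
      if (cc > best$cc) best <- list(defocus = df, phase_shift = ph, cc = cc)
    }
  }
  best
}

#' Local 2D refinement of CTF parameters against the masked spectrum
#'
#' Refines (defocus1, defocus2, astigmatism angle and, optionally, phase
#' shift) by derivative-free local maximization of the correlation between
#' the model CTF^2 and the background-subtracted spectrum under the radial
#' sine-edged mask. The returned objective is never worse than at the
#' initial parameters.
#'
#' @param spectrum background-subtracted centered spectrum
#' @param initial `ctf_params` starting point (e.g. from [fit_ctf_1d()])
#' @param refine_phase also refine the phase shift
#' @param res_range fitting band (low, high) resolution in Angstrom
#' @param max_evals evaluation budget; best-so-far returned with
#'   `converged = FALSE` if exceeded
#' @return list(params, cc, cc_initial, converged)
#' @export
refine_ctf_2d <- function(spectrum, initial, refine_phase = FALSE,
                          res_range = c(30, NULL), max_evals = 2000) {
  n <- box_size(spectrum)
  px <- spectrum$pixel_size
  g <- fftshift2(freq_magnitude(c(n, n), px))
  ax <- freq_axis(n, px)
  gx <- fftshift2(matrix(ax, n, n))
  gy <- fftshift2(matrix(ax, n, n, byrow = TRUE))
  az <- atan2(gy, gx)
  band <- g >= 1 / res_range[1]
  if (length(res_range) > 1 && !is.na(res_range[2]))
    band <- band & g <= 1 / res_range[2]
  band <- band & g <= 1 / (2 * px)
  wmask <- ctf_fit_mask(n, px)[band]
  gv <- g[band]; azv <- az[band]; sv <- spectrum$data[band]
  obj <- function(v) {
    p <- initial
    p$defocus1 <- v[1]; p$defocus2 <- v[2]; p$astig_angle <- v[3]
    if (refine_phase) p$phase_shift <- v[4]
    weighted_cor(sv, evaluate_ctf(p, gv, azv)^2, wmask)
  }
  v0 <- c(initial$defocus1, initial$defocus2, initial$astig_angle)
  if (refine_phase) v0 <- c(v0, initial$phase_shift)
  res <- optim(v0, obj, method = "Nelder-Mead",
               control = list(fnscale = -1, maxit = max_evals,
                              reltol = 1e-10))
  cc0 <- obj(v0)
  v <- if (res$value >= cc0) res$par else v0
  out <- ctf_params(defocus1 = v[1], defocus2 = v[2], astig_angle = v[3],
                    phase_shift = if (refine_phase) v[4] else
                      initial$phase_shift,
                    voltage = initial$voltage, cs = initial$cs,
                    amplitude_contrast = initial$amplitude_contrast,
                    pixel_size = initial$pixel_size)
  list(params = out, cc = max(res$value, cc0), cc_initial = cc0,
       converged = res$convergence == 0)
}

#' Moving-window quality of fit and fit resolution
#'
#' Per-shell correlation between the fitted CTF^2 and the rotationally
#' averaged background-subtracted spectrum, computed over a moving window
#' of shells (rather than between CTF nodes). The fit resolution is the
#' first shell at which the correlation drops below `threshold` and stays
#' below it for `persistence` consecutive shells.
#'
#' @param spectrum background-subtracted centered spectrum
#' @param params fitted `ctf_params`
#' @param window moving window width in shells (>= 3)
#' @param threshold ccfit threshold defining the fit resolution
#' @param persistence consecutive shells required below threshold
#' @return list(ccfit = `radial_profile` in [-1, 1], fit_resolution (A),
#'   aliasing_warning)
#' @export
goodness_of_fit <- function(spectrum, params, window = 9, threshold = 0.3,
                            persistence = 3, min_resolution = 30) {
  stopifnot(window >= 3)
  prof <- spectrum_radial(spectrum)
  g <- prof$bin_centers
  if (window > length(g)) stop("window larger than profile")
  model <- evaluate_ctf(params, g)^2
  half <- window %/% 2
  cc <- vapply(seq_along(g), function(i) {
    lo <- max(1, i - half); hi <- min(length(g), i + half)
    a <- prof$values[lo:hi]; b <- model[lo:hi]
    if (sd(a) == 0 || sd(b) == 0) return(0)
    stats::cor(a, b)
  }, numeric(1))
  cc <- pmax(-1, pmin(1, cc))
  # assess only inside the fitting band: shells before the first Thon ring
  # carry no fit information
  below <- cc < threshold & g > 1 / min_resolution
  fit_res <- NA_real_
  run <- 0
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1 else 0
    if (run >= persistence) { fit_res <- 1 / g[i - persistence + 1]; break }
  }
  if (is.na(fit_res)) fit_res <- 1 / g[length(g)]
  list(ccfit = radial_profile(g, cc), fit_resolution = fit_res,
       aliasing_warning = check_aliasing(box_size(spectrum), params,
                                         spectrum$pixel_size))
}

#' Warn when the spectrum box undersamples the CTF oscillations
#'
#' TRUE when the local CTF oscillation period (from the derivative of the
#' aberration phase) falls below two spectrum pixels anywhere inside the
#' fitting limit, i.e. when significant CTF aliasing is expected.
#'
#' @param box_size spectrum box side in pixels
#' @param params `ctf_params`
#' @param pixel_size spectrum pixel size in Angstrom
#' @param g_limit highest fitted frequency (default: spectrum edge)
#' @return logical
#' @export
check_aliasing <- function(box_size, params, pixel_size = params$pixel_size,
                           g_limit = NULL) {
  if (is.null(g_limit)) g_limit <- 1 / (2 * pixel_size)
  lambda <- electron_wavelength(params$voltage)
  df <- 0.5 * (params$defocus1 + params$defocus2)
  g <- seq(0, g_limit, length.out = 512)
  dchi <- abs(2 * pi * lambda * g * df -
              2 * pi * lambda^3 * g^3 * (params$cs * 1e7))
  period <- ifelse(dchi > 0, pi / dchi, Inf)  # zero spacing in 1/A
  dg_pix <- 1 / (box_size * pixel_size)
  any(period < 2 * dg_pix)
}

#' Full CTF determination for a micrograph or movie
#'
#' Convenience driver: average power spectrum, background subtraction, 1D
#' exhaustive pre-search, 2D local refinement, and diagnostics. The
#' diagnostics are computed on the background-subtracted but non-masked
#' spectrum.
#'
#' @param x `em_image` micrograph or `em_stack` movie
#' @param base `ctf_params` with the microscope constants
#' @param defocus_range,defocus_step 1D search grid in Angstrom
#' @param frames_to_sum movie sub-sum size for the power spectrum
#' @param tile spectrum tile size
#' @param phase_shift_range optional phase-plate search range (radians)
#' @param res_range fitting band (low, high resolution, A)
#' @param exhaustive_2d skip the 1D pre-search and search the astigmatic
#'   2D model exhaustively (slow; for very large astigmatism)
#' @return list(params, diagnostics, spectrum, cc)
#' @export
fit_ctf <- function(x, base, defocus_range = c(5000, 30000),
                    defocus_step = 500, frames_to_sum = 1, tile = 512,
                    phase_shift_range = NULL, res_range = c(30, NULL),
                    exhaustive_2d = FALSE) {
  ps <- amplitude_spectrum(x, frames_to_sum = frames_to_sum, tile = tile)
  bs <- subtract_background(ps)
  if (exhaustive_2d) {
    best <- NULL
    defs <- seq(defocus_range[1], defocus_range[2], by = defocus_step)
    for (d1 in defs) for (d2 in defs[defs <= d1]) for (ang in seq(0, 150, 30)) {
      init <- ctf_params(d1, d2, ang, voltage = base$voltage, cs = base$cs,
                         amplitude_contrast = base$amplitude_contrast,
                         pixel_size = base$pixel_size)
      r <- list(params = init,
                cc = weighted_cor_spectrum(bs, init, res_range))
      if (is.null(best) || r$cc > best$cc) best <- r
    }
    init <- best$params
  } else {
    prof <- spectrum_radial(bs)
    base_ps <- base
    base_ps$pixel_size <- bs$pixel_size
    r1 <- fit_ctf_1d(prof, base_ps, defocus_range, defocus_step,
                     phase_shift_range = phase_shift_range,
                     res_range = res_range)
    init <- ctf_params(r1$defocus, r1$defocus, 0, phase_shift = r1$phase_shift,
                       voltage = base$voltage, cs = base$cs,
                       amplitude_contrast = base$amplitude_contrast,
                       pixel_size = base$pixel_size)
  }
  # the astigmatism angle is multi-modal from a round starting point:
  # refine from four angle starts with a small defocus split and keep the
  # best local optimum
  ref <- NULL
  for (ang0 in c(0, 45, 90, 135)) {
    init_a <- init
    init_a$defocus1 <- init$defocus1 + 300
    init_a$defocus2 <- init$defocus2 - 300
    init_a$astig_angle <- ang0
    r <- refine_ctf_2d(bs, init_a,
                       refine_phase = !is.null(phase_shift_range),
                       res_range = res_range)
    if (is.null(ref) || r$cc > ref$cc) ref <- r
  }
  diag <- goodness_of_fit(bs, ref$params)
  list(params = ref$params, diagnostics = diag, spectrum = bs, cc = ref$cc)
}

# masked correlation of a parameter set against a subtracted spectrum
weighted_cor_spectrum <- function(bs, params, res_range = c(30, NULL)) {
  n <- box_size(bs); px <- bs$pixel_size
  g <- fftshift2(freq_magnitude(c(n, n), px))
  ax <- freq_axis(n, px)
  gx <- fftshift2(matrix(ax, n, n)); gy <- fftshift2(matrix(ax, n, n, TRUE))
  band <- g >= 1 / res_range[1] & g <= 1 / (2 * px)
  if (length(res_range) > 1 && !is.na(res_range[2]))
    band <- band & g <= 1 / res_range[2]
  weighted_cor(bs$data[band],
               evaluate_ctf(params, g[band], atan2(gy, gx)[band])^2,
               ctf_fit_mask(n, px)[band])
}
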