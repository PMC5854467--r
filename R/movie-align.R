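# Whole-frame movie motion correction: iterative leave-one-out alignment
# with Savitzky-Golay trajectory smoothing, and exposure-weighted frame
# summation using the published critical-exposure dose-weighting curve.

#' Construct a movie stack
#'
#' @param frames list of `em_image` frames (same box and pixel size) or a
#'   3D array
#' @param pixel_size pixel size in Angstrom (required for an array input)
#' @param exposure_per_frame electron exposure per frame, e-/A^2
#' @param pre_exposure exposure accumulated before the first frame, e-/A^2
#' @return object of class `movie_stack`
#' @export
movie_stack <- function(frames, pixel_size = NULL, exposure_per_frame = 1,
                        pre_exposure = 0) {
  if (is.list(frames)) {
    pixel_size <- frames[[1]]$pixel_size
    arr <- simplify2array(lapply(frames, function(f) f$data))
  } else arr <- frames
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] >= 3L,
            exposure_per_frame >= 0, pre_exposure >= 0)
  if (any(!is.finite(arr))) stop("non-finite pixels in movie frames")
  structure(list(data = arr, pixel_size = pixel_size,
                 exposure_per_frame = exposure_per_frame,
                 pre_exposure = pre_exposure),
            class = "movie_stack")
}

# apply SG smoothing to a trajectory column; window clamped to odd <= n
sg_smooth <- function(x, window, order) {
  n <- length(x)
  w <- min(window, n)
  if (w %% 2L == 0L) w <- w - 1L
  if (w <= order + 1) return(x)
  signal::sgolayfilt(x, p = order, n = w)
}

# parabolic sub-pixel peak around the argmax of a cross-correlation map
cc_peak_subpixel <- function(cc) {
  n <- nrow(cc)
  k <- which.max(cc)
  i <- (k - 1) %% n + 1
  j <- (k - 1) %/% n + 1
  wrap <- function(a) ((a - 1) %% n) + 1
  par1 <- function(m1, c0, p1) {
    den <- m1 - 2 * c0 + p1
    if (den >= 0) 0 else 0.5 * (m1 - p1) / den
  }
  dx <- par1(cc[wrap(i - 1), j], cc[i, j], cc[wrap(i + 1), j])
  dy <- par1(cc[i, wrap(j - 1)], cc[i, j], cc[i, wrap(j + 1)])
  sx <- i - 1 + dx; sy <- j - 1 + dy
  if (sx > n / 2) sx <- sx - n
  if (sy > n / 2) sy <- sy - n
  c(sx, sy)
}

#' Align movie frames by iterative leave-one-out correlation
#'
#' Each frame is aligned against the sum of all other (currently shifted)
#' frames; after each pass the x(t) and y(t) trajectories are smoothed with
#' a Savitzky-Golay filter, and the mean shift is removed (gauge fixing).
#' Iteration stops when the largest per-frame shift change falls below
#' `min_shift_change` or `max_iterations` is reached.
#'
#' @param movie `movie_stack`
#' @param max_iterations iteration cap
#' @param min_shift_change convergence threshold in Angstrom
#' @param smoothing_window Savitzky-Golay window (frames; clamped odd)
#' @param smoothing_order Savitzky-Golay polynomial order
#' @param bfactor B-factor (A^2) applied to the correlation to damp noise
#' @return object of class `movie_trajectory`: data.frame(frame, x, y) in
#'   Angstrom with attribute `iterations`
#' @export
align_movie <- function(movie, max_iterations = 20, min_shift_change = 0.1,
                        smoothing_window = 7, smoothing_order = 3,
                        bfactor = 1500) {
  nf <- dim(movie$data)[3]
  n <- dim(movie$data)[1]
  px <- movie$pixel_size
  fts <- lapply(seq_len(nf), function(i) fft2(movie$data[, , i]))
  g2 <- freq_magnitude(c(n, n), px)^2
  damp <- exp(-bfactor * g2 / 4)
  hx <- matrix(freq_index(n), n, n)
  hy <- matrix(freq_index(n), n, n, byrow = TRUE)
  ramp <- function(sx_px, sy_px) exp(-2i * pi * (hx * sx_px + hy * sy_px) / n)
  shifts <- matrix(0, nf, 2)  # in pixels
  iterations <- 0
  for (it in seq_len(max_iterations)) {
    iterations <- it
    shifted <- lapply(seq_len(nf), function(i)
      fts[[i]] * ramp(-shifts[i, 1], -shifts[i, 2]))
    total <- Reduce(`+`, shifted)
    new_shifts <- shifts
    for (i in seq_len(nf)) {
      ref <- total - shifted[[i]]
      cc <- Re(ifft2(Conj(ref) * fts[[i]] * damp))
      new_shifts[i, ] <- cc_peak_subpixel(cc)
    }
    new_shifts[, 1] <- sg_smooth(new_shifts[, 1], smoothing_window,
                                 smoothing_order)
    new_shifts[, 2] <- sg_smooth(new_shifts[, 2], smoothing_window,
                                 smoothing_order)
    new_shifts <- sweep(new_shifts, 2, colMeans(new_shifts))
    change <- max(sqrt(rowSums((new_shifts - shifts)^2))) * px
    shifts <- new_shifts
    if (change < min_shift_change) break
  }
  out <- data.frame(frame = seq_len(nf), x = shifts[, 1] * px,
                    y = shifts[, 2] * px)
  attr(out, "iterations") <- iterations
  class(out) <- c("movie_trajectory", "data.frame")
  out
}

# critical exposure (e-/A^2) at spatial frequency g (1/A); published
# dose-weighting curve constants, exposed for configuration
critical_exposure <- function(g, a = 0.245, b = -1.665, c = 2.81) {
  ifelse(g > 0, a * g^b + c, Inf)
}

#' Exposure-weighted aligned frame sum
#'
#' Shifts each frame by its trajectory entry (Fourier phase ramps) and sums.
#' With `apply_exposure_filter = TRUE` each frame's Fourier amplitudes are
#' attenuated by exp(-E_acc / (2 Nc(g))) where E_acc is the accumulated
#' exposure at the frame center and Nc the critical exposure curve; the sum
#' is re-normalized per frequency by sqrt(sum w^2) so filtered signal power
#' is restored.
#'
#' @param movie `movie_stack`
#' @param trajectory `movie_trajectory` from [align_movie()]
#' @param apply_exposure_filter logical
#' @param dose_constants length-3 numeric (a, b, c) of the critical-exposure
#'   curve Nc(g) = a g^b + c
#' @return `em_image` aligned (and optionally exposure-weighted) sum
#' @export
exposure_filtered_sum <- function(movie, trajectory,
                                  apply_exposure_filter = FALSE,
                                  dose_constants = c(0.245, -1.665, 2.81)) {
  nf <- dim(movie$data)[3]
  stopifnot(nrow(trajectory) == nf)
  if (apply_exposure_filter && movie$exposure_per_frame <= 0)
    stop("exposure filter requested with zero exposure per frame")
  n <- dim(movie$data)[1]
  px <- movie$pixel_size
  g <- freq_magnitude(c(n, n), px)
  hx <- matrix(freq_index(n), n, n)
  hy <- matrix(freq_index(n), n, n, byrow = TRUE)
  acc <- matrix(0 + 0i, n, n)
  wsq <- matrix(0, n, n)
  for (i in seq_len(nf)) {
    sx <- trajectory$x[i] / px; sy <- trajectory$y[i] / px
    ft <- fft2(movie$data[, , i]) *
      exp(-2i * pi * (hx * -sx + hy * -sy) / n)
    w <- 1
    if (apply_exposure_filter) {
      e_acc <- movie$pre_exposure + (i - 0.5) * movie$exposure_per_frame
      nc <- critical_exposure(g, dose_constants[1], dose_constants[2],
                              dose_constants[3])
      w <- exp(-e_acc / (2 * nc))
    }
    acc <- acc + w * ft
    wsq <- wsq + w^2
  }
  if (apply_exposure_filter) acc <- acc * sqrt(nf) / sqrt(wsq)
  em_image(Re(ifft2(acc)), px)
}

# per-frame, per-frequency exposure weights (exposed for tests/diagnostics)
exposure_weights <- function(movie, g, dose_constants = c(0.245, -1.665, 2.81)) {
  nf <- dim(movie$data)[3]
  t(vapply(seq_len(nf), function(i) {
    e_acc <- movie$pre_exposure + (i - 0.5) * movie$exposure_per_frame
    exp(-e_acc / (2 * critical_exposure(g, dose_constants[1],
                                        dose_constants[2], dose_constants[3])))
  }, numeric(length(g))))
}
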