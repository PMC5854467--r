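#' @useDynLib cryopipe, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim rnorm runif sd var approx median quantile setNames
#' @importFrom utils head read.table write.table tail
NULL

# ---- containers ------------------------------------------------------------

#' Create a 2D image with physical pixel size
#'
#' Images are square real-valued arrays with an even box side and a pixel
#' size in Angstrom per pixel. All frequency bookkeeping downstream is in
#' 1/Angstrom.
#'
#' @param pixels numeric matrix (square, even side)
#' @param pixel_size pixel size in Angstrom (> 0)
#' @return object of class `em_image` with fields `data` and `pixel_size`
#' @export
em_image <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  stopifnot(nrow(pixels) == ncol(pixels), nrow(pixels) %% 2L == 0L,
            is.numeric(pixel_size), pixel_size > 0)
  structure(list(data = pixels, pixel_size = as.numeric(pixel_size)),
            class = "em_image")
}

#' Create a 3D volume with physical pixel size
#'
#' @param voxels numeric 3D array (cubic, even side)
#' @param pixel_size voxel size in Angstrom (> 0)
#' @return object of class `em_volume`
#' @export
em_volume <- function(voxels, pixel_size) {
  d <- dim(voxels)
  stopifnot(length(d) == 3L, d[1] == d[2], d[2] == d[3], d[1] %% 2L == 0L,
            is.numeric(pixel_size), pixel_size > 0)
  structure(list(data = voxels, pixel_size = as.numeric(pixel_size)),
            class = "em_volume")
}

#' Create a stack of particle images
#'
#' @param data 3D array, third index enumerating particles
#' @param pixel_size pixel size in Angstrom
#' @return object of class `em_stack`
#' @export
em_stack <- function(data, pixel_size) {
  d <- dim(data)
  stopifnot(length(d) == 3L, d[1] == d[2], d[1] %% 2L == 0L, pixel_size > 0)
  structure(list(data = data, pixel_size = as.numeric(pixel_size)),
            class = "em_stack")
}

#' @export
print.em_image <- function(x, ...) {
  cat(sprintf("<em_image %d x %d, %.4g A/px>\n", nrow(x$data), ncol(x$data),
              x$pixel_size))
  invisible(x)
}

#' @export
print.em_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<em_volume %d^3, %.4g A/px>\n", d[1], x$pixel_size))
  invisible(x)
}

#' @export
print.em_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<em_stack %d images of %d x %d, %.4g A/px>\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

box_size <- function(x) dim(x$data)[1]

stack_image <- function(stack, i) em_image(stack$data[, , i], stack$pixel_size)

# ---- Fourier transforms ----------------------------------------------------
# Normalization convention (documented contract): forward transform is
# unscaled (as returned by stats::fft); the inverse carries the 1/N factor.
# Under this convention Parseval's relation reads
#   sum(x^2) = sum(|X|^2) / N.

#' 2D fast Fourier transform (forward unscaled)
#' @param x numeric or complex matrix with even sides
#' @return complex matrix
#' @export
fft2 <- function(x) {
  stopifnot(is.matrix(x), nrow(x) %% 2L == 0L, ncol(x) %% 2L == 0L)
  stats::fft(x)
}

#' Inverse 2D FFT (scaled by 1/N)
#' @param x complex matrix
#' @return complex matrix; take `Re()` for real images
#' @export
ifft2 <- function(x) {
  stopifnot(is.matrix(x), nrow(x) %% 2L == 0L, ncol(x) %% 2L == 0L)
  stats::fft(x, inverse = TRUE) / length(x)
}

#' 3D fast Fourier transform (forward unscaled)
#' @param x numeric or complex 3D array with even sides
#' @return complex array
#' @export
fft3 <- function(x) {
  stopifnot(length(dim(x)) == 3L, all(dim(x) %% 2L == 0L))
  stats::fft(x)
}

#' Inverse 3D FFT (scaled by 1/N)
#' @param x complex 3D array
#' @return complex array
#' @export
ifft3 <- function(x) {
  stopifnot(length(dim(x)) == 3L, all(dim(x) %% 2L == 0L))
  stats::fft(x, inverse = TRUE) / length(x)
}

# Wrapped integer frequency index along one axis: 0, 1, ..., n/2-1, -n/2, ..., -1
freq_index <- function(n) c(0:(n / 2 - 1), -(n / 2):-1)

# Spatial frequency axis in 1/A for an unshifted transform
freq_axis <- function(n, pixel_size) freq_index(n) / (n * pixel_size)

# |g| map (1/A) for an unshifted 2D or 3D transform
freq_magnitude <- function(dims, pixel_size) {
  ax <- lapply(dims, function(n) freq_axis(n, pixel_size))
  if (length(dims) == 2L) {
    sqrt(outer(ax[[1]]^2, ax[[2]]^2, `+`))
  } else {
    g2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
    sqrt(g2)
  }
}

fftshift2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  x[c((n / 2 + 1):n, 1:(n / 2)), c((m / 2 + 1):m, 1:(m / 2))]
}

# ---- Fourier cropping ------------------------------------------------------

#' Resample an image or volume to a coarser pixel size by Fourier cropping
#'
#' The output box is the even size whose pixel size is closest to
#' `target_pixel_size` (always within one Fourier pixel). The image mean is
#' preserved exactly; Fourier amplitudes below the new Nyquist are preserved.
#'
#' @param x `em_image` or `em_volume`
#' @param target_pixel_size requested pixel size in Angstrom (>= current)
#' @return object of the same class at the new sampling
#' @export
fourier_crop <- function(x, target_pixel_size) {
  n <- box_size(x)
  px <- x$pixel_size
  if (target_pixel_size < px - 1e-9)
    stop("fourier_crop cannot upsample: target pixel size below source")
  m <- best_crop_box(n, px, target_pixel_size)
  if (m == n) return(x)
  ndim <- length(dim(x$data))
  ft <- if (ndim == 2L) fft2(x$data) else fft3(x$data)
  keep <- c(1:(m / 2), (n - m / 2 + 1):n)
  ft <- if (ndim == 2L) ft[keep, keep] else ft[keep, keep, keep]
  # scaling by (m/n)^ndim preserves the mean and band-limited amplitudes
  ft <- ft * (m / n)^ndim
  out <- if (ndim == 2L) Re(ifft2(ft)) else Re(ifft3(ft))
  out_px <- n * px / m
  if (ndim == 2L) em_image(out, out_px) else em_volume(out, out_px)
}

# chosen even box minimizing |n*px/m - target|
best_crop_box <- function(n, px, target) {
  m0 <- n * px / target
  cand <- unique(pmin(n, pmax(2, 2 * c(floor(m0 / 2), ceiling(m0 / 2)))))
  cand[which.min(abs(n * px / cand - target))]
}

# ---- radial statistics -----------------------------------------------------

#' Construct a radial profile object
#' @param bin_centers spatial frequencies (1/A), strictly increasing
#' @param values one value per shell
#' @return object of class `radial_profile`
#' @export
radial_profile <- function(bin_centers, values) {
  stopifnot(length(bin_centers) == length(values),
            all(diff(bin_centers) > 0))
  structure(list(bin_centers = as.numeric(bin_centers),
                 values = as.numeric(values)),
            class = "radial_profile")
}

#' Radially average a 2D or 3D spectrum
#'
#' Input is an unshifted transform (Fourier origin at array element
#' \code{[1,1(,1)]}). Shells are half-open intervals of width
#' 1/(box * pixel_size); each value is the mean over pixels whose |g| falls
#' in the shell. Empty shells carry the previous shell's value.
#'
#' @param spectrum real or complex array (complex input is averaged as
#'   squared modulus is NOT implied -- pass |.|^2 yourself if wanted; complex
#'   values are averaged as their modulus)
#' @param pixel_size pixel size in Angstrom of the originating image
#' @return `radial_profile`
#' @export
radial_average <- function(spectrum, pixel_size) {
  vals <- if (is.complex(spectrum)) Mod(spectrum) else spectrum
  dims <- dim(vals)
  n <- dims[1]
  g <- freq_magnitude(dims, pixel_size)
  dg <- 1 / (n * pixel_size)
  shell <- pmin(floor(g / dg + 0.5), n %/% 2)  # bin k covers [k-.5, k+.5) dg
  nshell <- n %/% 2 + 1
  sums <- rep(NA_real_, nshell)
  tab <- tapply(as.vector(vals), as.vector(shell), mean)
  sums[as.integer(names(tab)) + 1L] <- tab
  for (i in seq_len(nshell)) if (is.na(sums[i]) && i > 1) sums[i] <- sums[i - 1]
  if (is.na(sums[1])) sums[1] <- 0
  centers <- (seq_len(nshell) - 1L) * dg
  centers[1] <- 1e-12  # first bin at/near zero frequency, strictly increasing
  radial_profile(centers, sums)
}

# interpolate a radial profile at arbitrary |g| (rule 2: clamp at the ends)
profile_at <- function(profile, g) {
  approx(profile$bin_centers, profile$values, xout = g, rule = 2)$y
}

# ---- soft masks ------------------------------------------------------------

#' Build a soft cosine-edged mask
#'
#' Values are exactly 1 strictly inside `radius - falloff_width`, exactly 0
#' strictly outside `radius`, with a cosine-shaped falloff in between (value
#' 0.5 at `radius - falloff_width/2`).
#'
#' @param box box side in pixels (even)
#' @param pixel_size pixel size in Angstrom
#' @param radius outer mask radius in Angstrom (> 0)
#' @param falloff_width width of the cosine edge in Angstrom (0 = binary)
#' @param ndim 2 for a circular mask, 3 for a spherical mask
#' @param center optional center in Angstrom relative to the box center
#' @return numeric array in [0, 1]
#' @export
make_soft_mask <- function(box, pixel_size, radius, falloff_width = 0,
                           ndim = 2L, center = NULL) {
  stopifnot(radius > 0, falloff_width >= 0)
  if (radius + 0 > box / 2 * pixel_size * sqrt(ndim))
    stop("mask radius does not fit in box")
  if (is.null(center)) center <- rep(0, ndim)
  ax <- (seq_len(box) - 1 - box / 2) * pixel_size
  r <- if (ndim == 2L) {
    sqrt(outer((ax - center[1])^2, (ax - center[2])^2, `+`))
  } else {
    sqrt(outer(outer((ax - center[1])^2, (ax - center[2])^2, `+`),
               (ax - center[3])^2, `+`))
  }
  soft_edge(r, radius, falloff_width)
}

# cosine edge helper on a radius map
soft_edge <- function(r, radius, falloff) {
  m <- array(0, dim = dim(r))
  m[r <= radius - falloff] <- 1
  if (falloff > 0) {
    band <- r > radius - falloff & r < radius
    m[band] <- 0.5 * (1 + cos(pi * (r[band] - (radius - falloff)) / falloff))
  }
  m
}

# apply a low-pass (and/or high-pass) cosine-edged filter in Fourier space;
# limits in Angstrom resolution, edge width in shells of 1/(n px)
fourier_bandpass <- function(x, pixel_size = NULL, lowpass = NULL,
                             highpass = NULL, edge_shells = 2) {
  obj <- NULL
  if (inherits(x, "em_image") || inherits(x, "em_volume")) {
    obj <- x; pixel_size <- x$pixel_size; x <- x$data
  }
  dims <- dim(x)
  g <- freq_magnitude(dims, pixel_size)
  dg <- 1 / (dims[1] * pixel_size)
  filt <- array(1, dims)
  if (!is.null(lowpass)) {
    gc <- 1 / lowpass
    filt <- filt * soft_edge(g, gc + edge_shells * dg, edge_shells * dg)
  }
  if (!is.null(highpass)) {
    gc <- 1 / highpass
    filt <- filt * (1 - soft_edge(g, gc, edge_shells * dg))
  }
  ft <- if (length(dims) == 2L) fft2(x) else fft3(x)
  out <- if (length(dims) == 2L) Re(ifft2(ft * filt)) else Re(ifft3(ft * filt))
  if (!is.null(obj)) { obj$data <- out; obj } else out
}
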