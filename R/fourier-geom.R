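# Projection geometry. Euler convention: Z-Y-Z intrinsic (phi about z,
# theta about the new y, psi about the final z), rotation matrix
# R = Rz(phi) %*% Ry(theta) %*% Rz(psi). The projection operator computes
# P(x, y) = integral of rho(R (x, y, z)') dz, i.e. the central Fourier
# slice through the plane spanned by the first two columns of R. Real-space
# origin is the box center (side/2, 0-based); Fourier origin is array
# element [1, 1] (unshifted).

rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}

rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}

#' Rotation matrix from Euler angles (Z-Y-Z intrinsic, degrees)
#'
#' @param phi,theta,psi Euler angles in degrees
#' @return 3x3 rotation matrix
#' @export
euler_matrix <- function(phi, theta, psi) {
  d <- pi / 180
  rot_z(phi * d) %*% rot_y(theta * d) %*% rot_z(psi * d)
}

# List of 2D Fourier sample points for an n x n transform.
# hx, hy: integer voxel-frequency indices; g: |g| in 1/A; idx: linear index
# into the unshifted transform matrix. res_limit (A) bounds |g|; half = TRUE
# keeps one member of each Friedel pair (hx > 0, or hx == 0 & hy >= 0).
freq_list <- function(n, pixel_size, res_limit = NULL, half = FALSE,
                      include_dc = TRUE) {
  h <- freq_index(n)
  hx <- rep(h, times = n)
  hy <- rep(h, each = n)
  g <- sqrt(hx^2 + hy^2) / (n * pixel_size)
  keep <- rep(TRUE, n * n)
  if (!is.null(res_limit)) keep <- keep & g <= 1 / res_limit + 1e-12
  # drop pure-Nyquist rows (unpaired under Friedel symmetry)
  keep <- keep & abs(hx) < n / 2 & abs(hy) < n / 2
  if (half) keep <- keep & (hx > 0 | (hx == 0 & hy >= 0))
  if (!include_dc) keep <- keep & (hx != 0 | hy != 0)
  i <- which(keep)
  hx <- hx[i]; hy <- hy[i]
  row <- (hx %% n) + 1L
  col <- (hy %% n) + 1L
  list(n = n, pixel_size = pixel_size, hx = hx, hy = hy, g = g[i],
       idx = row + (col - 1L) * n)
}

# Phase factors applying a real-space shift of (sx, sy) pixels:
# multiplying a transform by this moves the image by +s.
shift_phase <- function(fl, sx_px, sy_px) {
  exp(-2i * pi * (fl$hx * sx_px + fl$hy * sy_px) / fl$n)
}

# Extract a central slice (complex values at the freq-list points) from a
# volume transform; the centering phase re-expresses the slice in the
# box-centered real-space convention used for particle images.
slice_extract <- function(vft, rot, fl) {
  cp_slice_extract(vft$re, vft$im, vft$n, rot,
                   as.numeric(fl$hx), as.numeric(fl$hy)) * center_phase(fl)
}

# +/-1 phases converting between "object at array origin" (the rotation
# center of the Fourier-slice operators) and "object at box center" (the
# storage convention for all real-space images)
center_phase <- function(fl) {
  1 - 2 * ((fl$hx + fl$hy) %% 2)
}

fftshift3 <- function(a) {
  n <- dim(a)[1]
  idx <- c((n / 2 + 1):n, 1:(n / 2))
  a[idx, idx, idx]
}

# transform of the volume rolled so the box center sits at the array
# origin: rotations in Fourier space then rotate about the box center
volume_ft <- function(vol) {
  ft <- fft3(fftshift3(vol$data))
  list(re = as.numeric(Re(ft)), im = as.numeric(Im(ft)), n = dim(vol$data)[1],
       pixel_size = vol$pixel_size)
}

# Build a full complex n x n transform from values on a half-plane (or full)
# freq list, enforcing Friedel symmetry, then invert to a real image.
freqlist_to_image <- function(fl, values) {
  n <- fl$n
  ft <- matrix(0 + 0i, n, n)
  ft[fl$idx] <- values
  # Friedel completion
  row_m <- ((-fl$hx) %% n) + 1L
  col_m <- ((-fl$hy) %% n) + 1L
  ft[row_m + (col_m - 1L) * n] <- Conj(values)
  Re(ifft2(ft))
}

# Values of a full transform matrix at the freq-list points
ft_at <- function(ft, fl) ft[fl$idx]

#' Project a volume along a view given by Euler angles
#'
#' Central-slice projection: the volume is rotated by the transpose of
#' `euler_matrix(phi, theta, psi)` and integrated along z. Optionally shift
#' the projection by (sx, sy) Angstrom and band-limit it.
#'
#' @param vol `em_volume` (or a prepared transform from internal use)
#' @param phi,theta,psi Euler angles in degrees (Z-Y-Z intrinsic)
#' @param sx,sy shifts in Angstrom applied to the projection
#' @param res_limit optional resolution limit in Angstrom
#' @return `em_image` of the same box and pixel size
#' @export
project_volume <- function(vol, phi, theta, psi, sx = 0, sy = 0,
                           res_limit = NULL) {
  vft <- volume_ft(vol)
  n <- vft$n
  fl <- freq_list(n, vol$pixel_size, res_limit = res_limit, half = TRUE)
  vals <- slice_extract(vft, euler_matrix(phi, theta, psi), fl)
  if (sx != 0 || sy != 0)
    vals <- vals * shift_phase(fl, sx / vol$pixel_size, sy / vol$pixel_size)
  # slice values are exactly the 2D transform of the voxel-sum projection
  em_image(freqlist_to_image(fl, vals), vol$pixel_size)
}
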