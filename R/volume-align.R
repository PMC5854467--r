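# Rigid alignment of one map onto another (rotation grid + local
# refinement + translation), used to compare reconstructions against a
# ground-truth reference whose orientation (and handedness) the
# reconstruction cannot know.

# real-space correlation of a rotated copy of `vol` with `ref`
rot_correlation <- function(vol, ref, rot) {
  n <- dim(ref)[1]
  r <- cp_rotate3d(as.numeric(vol), n, rot, 0)
  stats::cor(r, as.numeric(ref))
}

#' Align a volume to a reference volume
#'
#' Coarse grid search over rotations (optionally including the mirrored
#' volume, since an ab-initio reconstruction can converge to either hand),
#' followed by derivative-free local refinement and a translation fit by
#' cross-correlation. Returns the aligned volume and the achieved
#' real-space correlation.
#'
#' @param volume `em_volume` to align
#' @param reference `em_volume` target (same grid)
#' @param step coarse rotation grid step in degrees
#' @param try_mirror also test the z-mirrored volume
#' @return list(volume = aligned `em_volume`, correlation, mirrored,
#'   rotation)
#' @export
align_volumes <- function(volume, reference, step = 24, try_mirror = TRUE) {
  stopifnot(identical(dim(volume$data), dim(reference$data)))
  n <- dim(volume$data)[1]
  refd <- reference$data - mean(reference$data)
  # the coarse grid search runs on Fourier-cropped copies: rigid
  # alignment only needs the low-resolution shape
  small <- function(v) {
    if (n <= 32) return(v)
    fourier_crop(em_volume(v, volume$pixel_size),
                 volume$pixel_size * n / 24)$data
  }
  ref_s <- small(refd)
  cands <- list(list(v = volume$data, mirrored = FALSE))
  if (try_mirror)
    cands <- c(cands, list(list(v = volume$data[, , n:1], mirrored = TRUE)))
  grid <- orientation_grid(step)
  best <- NULL
  for (cand in cands) {
    vd <- cand$v - mean(cand$v)
    vs <- small(vd)
    for (d in seq_len(nrow(grid$dirs))) {
      for (ps in grid$psis) {
        rot <- euler_matrix(grid$dirs[d, 1], grid$dirs[d, 2], ps)
        cc <- rot_correlation(vs, ref_s, rot)
        if (is.null(best) || cc > best$cc)
          best <- list(cc = cc, angles = c(grid$dirs[d, 1],
                                           grid$dirs[d, 2], ps),
                       mirrored = cand$mirrored, v = vd)
      }
    }
  }
  # local refinement of the three angles
  obj <- function(a) rot_correlation(best$v, refd,
                                     euler_matrix(a[1], a[2], a[3]))
  opt <- optim(best$angles, obj, method = "Nelder-Mead",
               control = list(fnscale = -1, maxit = 200))
  ang <- opt$par
  rot <- euler_matrix(ang[1], ang[2], ang[3])
  aligned <- array(cp_rotate3d(as.numeric(best$v), n, rot, 0), c(n, n, n))
  # translation by 3D cross-correlation (integer voxel, then phase ramp)
  ccv <- Re(ifft3(Conj(fft3(refd)) * fft3(aligned)))
  k <- which.max(ccv)
  ijk <- arrayInd(k, c(n, n, n)) - 1L
  sh <- ifelse(ijk > n / 2, ijk - n, ijk)
  if (any(sh != 0)) {
    h <- freq_index(n)
    ph <- exp(-2i * pi * (outer(outer(h * -sh[1], h * -sh[2], `+`),
                                h * -sh[3], `+`)) / n)
    aligned <- Re(ifft3(fft3(aligned) * ph))
  }
  cc_final <- stats::cor(as.numeric(aligned), as.numeric(refd))
  list(volume = em_volume(aligned, volume$pixel_size),
       correlation = cc_final, mirrored = best$mirrored, rotation = rot)
}
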