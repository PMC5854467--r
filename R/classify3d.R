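# Maximum-likelihood 3D classification with optional focused spherical
# masks. Images are assumed whitened to unit pixel noise variance (see
# whiten_background()); the per-class probability density is the Gaussian
# density of the masked residual image - CTF x projection, combined with
# the shift prior; occupancies and class priors follow the standard EM
# updates. No marginalization over alignment parameters is performed.

#' Focused classification mask
#'
#' A sphere with user-specified center (in the 3D map frame, Angstrom
#' relative to the box center) and radius; its projection at each
#' particle's orientation restricts the classification residual.
#'
#' @param center length-3 center (x, y, z) in Angstrom
#' @param radius sphere radius in Angstrom
#' @return object of class `focus_mask`
#' @export
focus_mask <- function(center = c(0, 0, 0), radius) {
  stopifnot(radius > 0, length(center) == 3)
  structure(list(center = center, radius = radius), class = "focus_mask")
}

# projected 2D mask of the focus sphere at a particle's orientation; the
# sphere center rotates with the reference, the shift follows the particle
project_focus_mask <- function(focus, params, n, pixel_size) {
  rot <- euler_matrix(params$phi, params$theta, params$psi)
  # reference frame -> image frame: object rotated by R^T before projection
  c2 <- crossprod(rot, focus$center)[1:2] + c(params$sx, params$sy)
  make_soft_mask(n, pixel_size, focus$radius, 2 * pixel_size, ndim = 2L,
                 center = c2)
}

#' Log probability density of a particle under a 3D class
#'
#' log Gamma(X | phi, V_k): Gaussian log-density of the masked residual
#' (X - CTF x projection) over the M pixels inside the mask (unit noise
#' variance), plus the hierarchical shift prior. With a focus mask, M and
#' the residual sum are restricted to the projected sphere.
#'
#' @param particle whitened `em_image`
#' @param params `alignment_params`
#' @param reference `em_volume` (or prepared reference, internal)
#' @param ctf `ctf_params` or NULL
#' @param mask_radius circular particle mask radius (A) used when no focus
#'   mask is given
#' @param focus `focus_mask` or NULL
#' @param restraint `restraint_model` or NULL
#' @return log probability density (up to the common (2 pi)^(-M/2) term
#'   which cancels in occupancy updates; included here explicitly)
#' @export
log_pdf <- function(particle, params, reference, ctf = NULL,
                    mask_radius = NULL, focus = NULL, restraint = NULL) {
  n <- box_size(particle)
  px <- particle$pixel_size
  proj <- project_volume(reference, params$phi, params$theta, params$psi,
                         sx = params$sx, sy = params$sy)
  if (!is.null(ctf)) {
    cimg <- ctf_image(ctf, n, px)
    proj$data <- Re(ifft2(fft2(proj$data) * cimg))
  }
  m <- if (!is.null(focus)) {
    project_focus_mask(focus, params, n, px)
  } else {
    if (is.null(mask_radius)) mask_radius <- n / 2 * px * 0.9
    make_soft_mask(n, px, mask_radius, 0, ndim = 2L)
  }
  mm <- sum(m)
  if (mm < 1) stop("empty projected mask")
  # the reference scale is a nuisance (reconstruction and whitening leave
  # it arbitrary); fit it by least squares inside the mask so the density
  # compares shapes, not units
  pnorm2 <- sum(m * proj$data^2)
  alpha <- if (pnorm2 > 0) sum(m * particle$data * proj$data) / pnorm2 else 0
  rss <- sum(m * (particle$data - alpha * proj$data)^2)
  -mm / 2 * log(2 * pi) - rss / 2 +
    log_gamma_prior(params, restraint)
}

log_gamma_prior <- function(params, restraint) {
  if (is.null(restraint)) return(0)
  # Gaussian shift prior matching the refinement restraint
  dx <- params$sx - restraint$mean_shift[1]
  dy <- params$sy - restraint$mean_shift[2]
  -0.5 * (dx^2 / restraint$sd_shift[1]^2 + dy^2 / restraint$sd_shift[2]^2) -
    log(2 * pi * restraint$sd_shift[1] * restraint$sd_shift[2])
}

#' Update class occupancies from log densities
#'
#' q_ik = Gamma_ik pi_k / sum_k Gamma_ik pi_k, evaluated in the log domain
#' with log-sum-exp for numerical stability.
#'
#' @param log_pdfs N x K matrix of log densities
#' @param priors length-K class priors (pi_k)
#' @return N x K occupancy matrix, rows summing to 1
#' @export
update_occupancies <- function(log_pdfs, priors) {
  stopifnot(ncol(log_pdfs) == length(priors), all(priors >= 0))
  lp <- sweep(log_pdfs, 2, log(pmax(priors, 1e-300)), `+`)
  lp[, priors == 0] <- -Inf
  mx <- apply(lp, 1, max)
  bad <- !is.finite(mx)
  if (any(bad)) stop("all-zero occupancy row")
  w <- exp(lp - mx)
  w / rowSums(w)
}

#' Update class priors from occupancies
#'
#' pi_k = (1/N) sum_i q_ik over the entire dataset.
#'
#' @param q N x K occupancy matrix
#' @return length-K prior vector summing to 1
#' @export
update_priors <- function(q) {
  colMeans(q)
}

#' Maximum-likelihood 3D classification
#'
#' Iterates occupancy and prior updates against K reference volumes at
#' fixed alignment parameters, then rebuilds each class reconstruction
#' from its occupancy-weighted particles.
#'
#' @param stack `em_stack` of particles (whitened internally)
#' @param param_list list of `alignment_params`, one per particle
#' @param references list of K `em_volume` starting references
#' @param ctfs per-particle `ctf_params` list, shared `ctf_params`, or NULL
#' @param mask_radius particle mask radius (A)
#' @param focus `focus_mask` or NULL
#' @param n_iterations EM iterations
#' @param reconstruct rebuild class volumes each iteration
#' @param pssnr `radial_profile` or scalar for the reconstruction Wiener
#'   term
#' @return list(q, priors, references, history)
#' @export
classify3d <- function(stack, param_list, references, ctfs = NULL,
                       mask_radius, focus = NULL, n_iterations = 5,
                       reconstruct = TRUE, pssnr = 100) {
  N <- dim(stack$data)[3]
  K <- length(references)
  px <- stack$pixel_size
  white <- vector("list", N)
  for (i in seq_len(N))
    white[[i]] <- whiten_background(stack_image(stack, i), mask_radius)
  priors <- rep(1 / K, K)
  q <- matrix(1 / K, N, K)
  hist <- NULL
  for (it in seq_len(n_iterations)) {
    lp <- matrix(0, N, K)
    for (k in seq_len(K)) {
      for (i in seq_len(N)) {
        ctf_i <- if (is.null(ctfs)) NULL else
          if (inherits(ctfs, "ctf_params")) ctfs else ctfs[[i]]
        lp[i, k] <- log_pdf(white[[i]], param_list[[i]], references[[k]],
                            ctf = ctf_i, mask_radius = mask_radius,
                            focus = focus)
      }
    }
    q_new <- update_occupancies(lp, priors)
    dq <- mean(abs(q_new - q)) * 100
    q <- q_new
    priors <- update_priors(q)
    if (reconstruct) {
      for (k in seq_len(K)) {
        acc <- recon_accumulator(dim(stack$data)[1], px)
        for (i in seq_len(N)) {
          ctf_i <- if (is.null(ctfs)) NULL else
            if (inherits(ctfs, "ctf_params")) ctfs else ctfs[[i]]
          acc <- insert_particle(acc, white[[i]], param_list[[i]], ctf_i,
                                 q = q[i, k])
        }
        if (acc$count > 0 && sum(q[, k]) > 0.5)
          references[[k]] <- finalize_reconstruction(acc, pssnr)
      }
    }
    hist <- rbind(hist, data.frame(iteration = it,
                                   occupancy_change_pct = dq,
                                   priors = I(list(priors))))
  }
  list(q = q, priors = priors, references = references, history = hist)
}
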