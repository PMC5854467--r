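# Maximum-likelihood 2D classification with a resolution ramp, random data
# subsets, noise whitening, CTF-corrected probability-weighted class sums
# and class-average thresholding. The per-iteration E-step marginalizes
# over class x in-plane rotation (step dalpha = R/D) x bounded translations,
# computed as band-limited Fourier matrix products.

#' 2D classification configuration
#'
#' @param K number of classes (>= 1)
#' @param n_iterations number of iterations (default 20)
#' @param R_start,R_finish resolution limits (A) at the first and last
#'   iteration (defaults 40 and 8)
#' @param mask_radius circular mask radius in Angstrom (particle diameter
#'   D = 2 x mask_radius enters the angular step R/D)
#' @param translation_px translation search bound in working pixels
#'   (default: mask_radius/4 converted at run time when NULL)
#' @param seed RNG seed used for subset selection and initialization
#' @return object of class `classify2d_config`
#' @export
classify2d_config <- function(K, n_iterations = 20, R_start = 40,
                              R_finish = 8, mask_radius,
                              translation_px = NULL, seed = 1) {
  stopifnot(K >= 1, R_start >= R_finish, n_iterations >= 1)
  structure(list(K = K, n_iterations = n_iterations, R_start = R_start,
                 R_finish = R_finish, mask_radius = mask_radius,
                 translation_px = translation_px, seed = seed),
            class = "classify2d_config")
}

#' Angular integration step
#'
#' dalpha = R / D where R is the resolution limit and D the particle
#' diameter (twice the mask radius).
#'
#' @param R resolution limit, Angstrom
#' @param D particle diameter, Angstrom
#' @return step in radians
#' @export
angular_step <- function(R, D) {
  stopifnot(R > 0, D > 0)
  R / D
}

#' Per-iteration resolution limit and subset fraction
#'
#' The resolution limit ramps linearly from `R_start` to `R_finish`. The
#' subset fraction follows the three-tier rule: iterations 0-9 use
#' min(300 K / N, 1); iterations 10-14 use 0.3 unless the early fraction
#' already exceeds 0.3 (then that); the final five iterations use all data.
#' Tier boundaries scale proportionally when `n_iterations != 20`.
#'
#' @param l iteration index, 0-based (0 <= l < n_iterations)
#' @param config `classify2d_config`
#' @param N number of particles in the dataset
#' @return list(R = resolution limit (A), p = subset fraction)
#' @export
class2d_schedule <- function(l, config, N) {
  n <- config$n_iterations
  stopifnot(l >= 0, l < n)
  R <- config$R_start + l * (config$R_finish - config$R_start) / (n - 1)
  p_early <- min(300 * config$K / N, 1)
  t1 <- round(n * 10 / 20); t2 <- round(n * 15 / 20)
  p <- if (l < t1) p_early
       else if (l < t2) max(0.3, p_early)
       else 1
  list(R = R, p = min(p, 1))
}

#' Estimate the noise power spectrum and whiten a particle stack
#'
#' The radially averaged noise power spectrum (NPS) is measured on the area
#' outside the circular particle mask, averaged across up to 2000 randomly
#' selected particles. Every particle transform is divided by sqrt(NPS),
#' and a constant is added per particle so the background average is zero.
#'
#' @param stack `em_stack`
#' @param mask_radius particle mask radius, Angstrom
#' @param n_sample particles used for the NPS estimate (default 2000)
#' @return list(stack = whitened `em_stack`, nps = `radial_profile`)
#' @export
estimate_noise_and_normalize <- function(stack, mask_radius,
                                         n_sample = 2000) {
  n <- dim(stack$data)[1]
  px <- stack$pixel_size
  np <- dim(stack$data)[3]
  mask <- make_soft_mask(n, px, mask_radius, 0, ndim = 2L)
  bg <- mask < 0.5
  frac_bg <- mean(bg)
  if (frac_bg < 0.2) stop("mask leaves less than 20% of the box as background")
  ids <- if (np > n_sample) sample.int(np, n_sample) else seq_len(np)
  acc <- NULL
  for (i in ids) {
    xi <- stack$data[, , i]
    xb <- (xi - mean(xi[bg])) * bg
    p <- radial_average(Mod(fft2(xb))^2 / frac_bg, px)
    acc <- if (is.null(acc)) p$values else acc + p$values
  }
  nps_vals <- acc / length(ids)
  nps_vals[nps_vals <= 0] <- min(nps_vals[nps_vals > 0])
  # the DC bin reflects the removed background mean, not noise power
  nps_vals[1] <- nps_vals[2]
  nps <- radial_profile(p$bin_centers, nps_vals)
  g <- freq_magnitude(c(n, n), px)
  # dividing the transform by sqrt(NPS) leaves unit noise variance per
  # Fourier coefficient, the scale the EM likelihood assumes
  wfilt <- matrix(1 / sqrt(profile_at(nps, as.vector(g))), n, n)
  wfilt[1, 1] <- 0  # the background-mean constant is re-set below
  out <- stack
  for (i in seq_len(np)) {
    w <- Re(ifft2(fft2(stack$data[, , i]) * wfilt))
    out$data[, , i] <- w - mean(w[bg])
  }
  list(stack = out, nps = nps)
}

# rotated, masked, band-limited reference matrix: (K * n_psi) x nfreq
build_reference_matrix <- function(averages, fl, mask, psis) {
  K <- dim(averages$data)[3]
  n <- dim(averages$data)[1]
  nrow_t <- K * length(psis)
  R <- matrix(0 + 0i, nrow_t, length(fl$idx))
  r <- 1L
  for (k in seq_len(K)) {
    for (ps in psis) {
      img <- cp_rotate2d(averages$data[, , k], ps, 0) * mask
      R[r, ] <- fft2(img)[fl$idx]
      r <- r + 1L
    }
  }
  R
}

#' One expectation-maximization iteration of 2D classification
#'
#' E-step: per-particle likelihood over classes x in-plane rotations (step
#' `dalpha`) x translations, under unit Gaussian noise in Fourier space
#' (images must be whitened). M-step: probability-weighted, fully
#' CTF-corrected class sums (CTF^2 accumulated in the denominator with a
#' Wiener regularizer). Fourier coefficients beyond the resolution limit
#' are exactly zero in the updated averages.
#'
#' @param stack whitened `em_stack` (all particles)
#' @param subset integer indices of the particles in this iteration
#' @param averages `em_stack` of K class averages
#' @param ctfs list of `ctf_params` (length N), a single `ctf_params`, or
#'   NULL for unit CTF
#' @param R_l resolution limit (A) for this iteration
#' @param dalpha in-plane angular step, radians
#' @param mask_radius mask radius (A)
#' @param translation_px translation bound in pixels
#' @param class_weights prior class weights (default uniform)
#' @return list(averages, q = subset x K occupancy matrix, loglik,
#'   assignments = max-q class per subset particle)
#' @export
em_iteration <- function(stack, subset, averages, ctfs, R_l, dalpha,
                         mask_radius, translation_px = 2,
                         class_weights = NULL, anneal = 0) {
  stopifnot(length(subset) >= 1)
  n <- dim(stack$data)[1]
  px <- stack$pixel_size
  K <- dim(averages$data)[3]
  if (2 * px > R_l) R_l <- 2 * px
  fl <- freq_list(n, px, res_limit = R_l, half = FALSE, include_dc = FALSE)
  nf <- length(fl$idx)
  mask <- make_soft_mask(n, px, mask_radius, min(4 * px, mask_radius / 2),
                         ndim = 2L)
  n_psi <- max(1L, ceiling(2 * pi / dalpha))
  psis <- (seq_len(n_psi) - 1L) * 2 * pi / n_psi
  R <- build_reference_matrix(averages, fl, mask, psis)
  # equalize band power across classes: otherwise the class with the
  # larger (or smaller) amplitude wins for every particle at once and the
  # classification collapses; shape differences should drive assignment
  kindex0 <- rep(seq_len(K), each = n_psi)
  pow_k <- vapply(seq_len(K), function(k)
    mean(Mod(R[kindex0 == k, , drop = FALSE])^2), numeric(1))
  target <- exp(mean(log(pmax(pow_k, 1e-300))))
  for (k in seq_len(K))
    if (pow_k[k] > 0)
      R[kindex0 == k, ] <- R[kindex0 == k, ] * sqrt(target / pow_k[k])
  Rn2 <- Mod(R)^2
  if (is.null(class_weights)) class_weights <- rep(1 / K, K)
  shift_grid <- expand.grid(sx = -translation_px:translation_px,
                            sy = -translation_px:translation_px)
  ns <- nrow(shift_grid)
  ramps <- vapply(seq_len(ns), function(s)
    shift_phase(fl, shift_grid$sx[s], shift_grid$sy[s]),
    complex(nf))
  num_acc <- vector("list", nrow(R))   # per (k, psi) Fourier accumulators
  den_acc <- vector("list", nrow(R))
  for (r in seq_len(nrow(R))) {
    num_acc[[r]] <- complex(nf)
    den_acc[[r]] <- numeric(nf)
  }
  qmat <- matrix(0, length(subset), K)
  loglik <- 0
  lw <- rep(log(pmax(class_weights, 1e-300)), each = n_psi)
  kindex <- rep(seq_len(K), each = n_psi)
  # ---- pass 1: E-step statistics per particle --------------------------
  cache <- vector("list", length(subset))
  margins <- numeric(length(subset))
  for (ii in seq_along(subset)) {
    i <- subset[ii]
    x <- fft2(stack$data[, , i])[fl$idx]
    cvec <- ctf_for_particle(ctfs, i, fl)
    cx <- cvec * x
    cross <- Re(Conj(R) %*% (ramps * cx))  # (K n_psi) x ns
    normA <- as.numeric(Rn2 %*% (cvec^2))
    normX <- sum(Mod(x)^2)
    # -residual/2 per (class, rotation, shift); the per-particle noise
    # variance is estimated from the best residual so the assignment
    # temperature adapts to the actual noise level (whitening leaves the
    # coefficients near, but not exactly at, unit variance)
    logL0 <- sweep(cross, 1, (normX + normA) / 2, `-`)
    sigma2 <- max(-2 * max(logL0) / nf, 1e-8)
    logL0 <- logL0 / sigma2
    if (K > 1) {
      lk <- vapply(seq_len(K), function(k) {
        v <- logL0[kindex == k, , drop = FALSE]
        m <- max(v); m + log(sum(exp(v - m)))
      }, numeric(1))
      s <- sort(lk, decreasing = TRUE)
      margins[ii] <- s[1] - s[2]
    }
    cache[[ii]] <- list(cx = cx, cvec = cvec, logL0 = logL0)
  }
  # deterministic annealing: early iterations soften the assignments so
  # small per-view preferences, not shared amplitude effects, drive the
  # separation of classes; anneal = 0 recovers the exact model
  temp <- 1 + anneal * max(0, median(margins) / 3 - 1)
  # ---- pass 2: soft assignment and accumulation ------------------------
  for (ii in seq_along(subset)) {
    ca <- cache[[ii]]
    logL <- ca$logL0 / temp + lw
    mx <- max(logL)
    w <- exp(logL - mx)
    Z <- sum(w)
    loglik <- loglik + (mx + log(Z))
    w <- w / Z
    qmat[ii, ] <- rowsum(rowSums(w), kindex)
    wr <- rowSums(w)
    active <- which(wr > 1e-8)
    for (r in active) {
      ws <- w[r, ]
      sel <- which(ws > 1e-8)
      if (length(sel) == 0) next
      xback <- Conj(ramps[, sel, drop = FALSE]) * ca$cx
      num_acc[[r]] <- num_acc[[r]] + as.vector(xback %*% ws[sel])
      den_acc[[r]] <- den_acc[[r]] + sum(ws[sel]) * ca$cvec^2
    }
  }
  # M-step: rotate accumulators back to the class frame and merge
  new_av <- averages
  occ <- colSums(qmat)
  for (k in seq_len(K)) {
    num_k <- matrix(0 + 0i, n, n)
    den_k <- matrix(0 + 0i, n, n)
    for (pi_ in seq_len(n_psi)) {
      r <- (k - 1L) * n_psi + pi_
      if (all(den_acc[[r]] == 0)) next
      fn <- matrix(0 + 0i, n, n); fn[fl$idx] <- num_acc[[r]]
      fd <- matrix(0 + 0i, n, n); fd[fl$idx] <- den_acc[[r]]
      rn <- cp_rotate2d(Re(ifft2(fn)), -psis[pi_], 0)
      rd <- cp_rotate2d(Re(ifft2(fd)), -psis[pi_], 0)
      num_k <- num_k + fft2(rn)
      den_k <- den_k + fft2(rd)
    }
    wiener <- 0.1 * max(occ[k], 1e-6)
    av_ft <- num_k / (Re(den_k) + wiener)
    keep <- matrix(FALSE, n, n); keep[fl$idx] <- TRUE
    av_ft[!keep] <- 0
    if (occ[k] < 1e-6) {
      warning("class ", k, " has no support; re-seeded from random particles")
      ids <- sample(dim(stack$data)[3], min(5, dim(stack$data)[3]))
      reseed <- apply(stack$data[, , ids, drop = FALSE], c(1, 2), mean)
      av_ft <- fft2(reseed * mask)
      av_ft[!keep] <- 0
    }
    new_av$data[, , k] <- Re(ifft2(av_ft))
  }
  list(averages = new_av, q = qmat, loglik = loglik,
       assignments = max.col(qmat))
}

ctf_for_particle <- function(ctfs, i, fl) {
  if (is.null(ctfs)) return(rep(1, length(fl$idx)))
  p <- if (inherits(ctfs, "ctf_params")) ctfs else ctfs[[i]]
  ctf_at(p, fl)
}

#' Suppress negative noise features in class averages
#'
#' For each class average the threshold t = -0.3 max is computed and all
#' values below t are reset to t.
#'
#' @param averages `em_stack` of class averages
#' @return `em_stack`
#' @export
threshold_averages <- function(averages) {
  out <- averages
  for (k in seq_len(dim(averages$data)[3])) {
    a <- averages$data[, , k]
    t <- -0.3 * max(a)
    a[a < t] <- t
    out$data[, , k] <- a
  }
  out
}

#' Run maximum-likelihood 2D classification
#'
#' Full driver: noise whitening and normalization, random class
#' initialization, then `n_iterations` EM iterations following the
#' resolution ramp and random-subset schedule, thresholding the class
#' averages at the start of each iteration.
#'
#' @param stack `em_stack` of particle images (raw; whitening is applied
#'   internally)
#' @param config `classify2d_config`
#' @param ctfs per-particle `ctf_params` list, one shared `ctf_params`, or
#'   NULL
#' @return list(averages = `em_stack`, q = N x K final occupancies,
#'   assignments, nps, history = per-iteration schedule log)
#' @export
classify2d <- function(stack, config, ctfs = NULL) {
  set.seed(config$seed)
  N <- dim(stack$data)[3]
  px <- stack$pixel_size
  wh <- estimate_noise_and_normalize(stack, config$mask_radius)
  wstack <- wh$stack
  K <- config$K
  n <- dim(stack$data)[1]
  tr_px <- config$translation_px
  if (is.null(tr_px))
    tr_px <- max(1L, min(4L, round(config$mask_radius / 4 / px)))
  # initialize from small random particle subsets: averages must differ
  # enough from each other to break the classification symmetry
  av <- array(0, c(n, n, K))
  init_size <- max(2, min(8, ceiling(N / K / 4)))
  for (k in seq_len(K)) {
    ids <- sample.int(N, init_size)
    av[, , k] <- apply(wstack$data[, , ids, drop = FALSE], c(1, 2), mean)
  }
  averages <- em_stack(av, px)
  qfull <- matrix(1 / K, N, K)
  hist <- NULL
  D <- 2 * config$mask_radius
  for (l in 0:(config$n_iterations - 1)) {
    sch <- class2d_schedule(l, config, N)
    subset <- sort(sample.int(N, max(K, round(sch$p * N))))
    averages <- threshold_averages(averages)
    res <- em_iteration(wstack, subset, averages, ctfs, sch$R,
                        angular_step(sch$R, D), config$mask_radius,
                        translation_px = tr_px,
                        class_weights = colMeans(qfull),
                        anneal = max(0, 1 - l / max(1, round(
                          0.75 * config$n_iterations))))
    averages <- res$averages
    qfull[subset, ] <- res$q
    hist <- rbind(hist, data.frame(iteration = l, R = sch$R, p = sch$p,
                                   subset_size = length(subset),
                                   loglik = res$loglik))
  }
  list(averages = averages, q = qfull, assignments = max.col(qfull),
       nps = wh$nps, history = hist)
}
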