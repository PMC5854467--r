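# Ab-initio 3D reconstruction (random start, resolution and subset ramps,
# randomized global-search result selection, automatic masking, symmetry
# handling) and the automatic refinement control loop with its
# resolution-driven schedule and stopping rules.

#' Ab-initio configuration
#'
#' @param n_iterations number of iterations (paper default 40; desk-scale
#'   runs use fewer)
#' @param R_start,R_finish resolution limits in Angstrom (defaults 20, 8)
#' @param K number of 3D classes
#' @param symmetry point group label ("C1", "C2", ..., "D2", ...)
#' @param apply_symmetry_mode "auto" (first 2/3 of iterations in C1, then
#'   align and apply), "always", or "never"
#' @param seed RNG seed
#' @return object of class `abinitio_config`
#' @export
abinitio_config <- function(n_iterations = 40, R_start = 20, R_finish = 8,
                            K = 1, symmetry = "C1",
                            apply_symmetry_mode = "auto", seed = 1) {
  stopifnot(n_iterations >= 2, K >= 1)
  structure(list(n_iterations = n_iterations, R_start = R_start,
                 R_finish = R_finish, K = K, symmetry = symmetry,
                 apply_symmetry_mode = match.arg(apply_symmetry_mode,
                                                 c("auto", "always",
                                                   "never")),
                 seed = seed),
            class = "abinitio_config")
}

# number of asymmetric units for a point-group label
symmetry_order <- function(group) {
  m <- regmatches(group, regexec("^([CD])([0-9]+)$", group))[[1]]
  if (length(m) == 0) stop("unsupported point group: ", group)
  k <- as.integer(m[3])
  if (m[2] == "C") k else 2L * k
}

# rotation matrices of a (C or D) point group
symmetry_ops <- function(group) {
  m <- regmatches(group, regexec("^([CD])([0-9]+)$", group))[[1]]
  if (length(m) == 0) stop("unsupported point group: ", group)
  k <- as.integer(m[3])
  ops <- lapply(0:(k - 1), function(j) rot_z(2 * pi * j / k))
  if (m[2] == "D")
    ops <- c(ops, lapply(ops, function(o) rot_x(pi) %*% o))
  ops
}

#' Per-iteration ab-initio schedule
#'
#' Resolution ramps linearly from `R_start` to `R_finish`; the included
#' fraction ramps from p_start = 2500 K / N_eff to p_finish =
#' 10000 K / N_eff (N_eff = N x number of asymmetric units), capped at 1.
#' The global search runs over three times the included fraction
#' (pool fraction = 3 p, capped at 1).
#'
#' @param l iteration, 0-based
#' @param config `abinitio_config`
#' @param N particle count
#' @return list(R, p, pool)
#' @export
abinitio_schedule <- function(l, config, N) {
  n <- config$n_iterations
  stopifnot(l >= 0, l < n)
  R <- config$R_start + l * (config$R_finish - config$R_start) / (n - 1)
  n_eff <- N * symmetry_order(config$symmetry)
  p_start <- min(2500 * config$K / n_eff, 1)
  p_finish <- min(10000 * config$K / n_eff, 1)
  p <- min(p_start + l * (p_finish - p_start) / (n - 1), 1)
  list(R = R, p = p, pool = min(3 * p, 1))
}

#' Keep the highest-scoring particles of a searched pool
#'
#' After a global search over the pool, the particles included in the
#' reconstruction are those with the highest scores; ties are broken by
#' particle index (deterministic).
#'
#' @param scores named or plain numeric vector of pool scores
#' @param pool_idx particle indices of the pool
#' @param n_keep how many to keep
#' @return kept particle indices
#' @export
select_pool_and_keep <- function(scores, pool_idx, n_keep) {
  stopifnot(length(scores) == length(pool_idx), n_keep >= 1)
  ord <- order(-scores, pool_idx)
  sort(pool_idx[ord[seq_len(min(n_keep, length(ord)))]])
}

#' Randomized selection among top global-search results
#'
#' Picks uniformly at random among all candidates whose score lies in the
#' top 15% of the (best - worst) score range; used instead of local
#' refinement of the top results during ab-initio reconstruction.
#'
#' @param candidates data.frame with a `score` column (one row per grid
#'   result)
#' @param top_fraction eligible score band as a fraction of the range
#' @return one row of `candidates`
#' @export
randomized_global_result <- function(candidates, top_fraction = 0.15) {
  stopifnot(nrow(candidates) >= 1)
  s <- candidates$score
  cutoff <- max(s) - top_fraction * (max(s) - min(s))
  eligible <- which(s >= cutoff - 1e-12)
  candidates[eligible[sample.int(length(eligible), 1)], , drop = FALSE]
}

#' Automatic masking of an intermediate reconstruction
#'
#' Pipeline: reset voxels below the density average rho_bar to rho_bar;
#' low-pass filter at 50 A; binarize at the threshold
#' t = rho_bar_filtered + 0.03 (rho_bar_max500 - rho_bar_filtered), where
#' rho_bar_max500 averages the 500 highest filtered values; keep the
#' largest 6-connected component (everything else reset to rho_bar);
#' finally apply a centered spherical mask (outside reset to zero).
#'
#' @param volume `em_volume`
#' @param mask_radius spherical mask radius in Angstrom (default 0.45 x
#'   box)
#' @param lp_resolution low-pass resolution for the mask (A)
#' @param n_top voxels averaged for the upper density reference
#' @return masked `em_volume`
#' @export
automask <- function(volume, mask_radius = NULL, lp_resolution = 50,
                     n_top = 500) {
  n <- box_size(volume)
  px <- volume$pixel_size
  if (is.null(mask_radius)) mask_radius <- 0.45 * n * px
  v <- volume$data
  rho_bar <- mean(v)
  v1 <- pmax(v, rho_bar)
  filt <- fourier_bandpass(v1, px, lowpass = lp_resolution)
  rf <- mean(filt)
  top <- mean(sort(as.vector(filt), decreasing = TRUE)[
    seq_len(min(n_top, length(filt)))])
  t <- rf + 0.03 * (top - rf)
  bin <- filt > t
  if (!any(bin)) {
    warning("degenerate automask (uniform map); returning input")
    return(volume)
  }
  lab <- array(cp_label3d(as.vector(bin), n, n, n), c(n, n, n))
  counts <- tabulate(lab[lab > 0])
  keep <- lab == which.max(counts)
  out <- v1
  out[!keep] <- rho_bar
  sphere <- make_soft_mask(n, px, mask_radius, min(4 * px, mask_radius / 4),
                           ndim = 3L)
  em_volume(out * sphere, px)
}

# projection of a volume along an arbitrary rotation matrix
project_matrix <- function(vol, rot, res_limit = NULL) {
  vft <- volume_ft(vol)
  fl <- freq_list(vft$n, vol$pixel_size, res_limit = res_limit, half = TRUE)
  em_image(freqlist_to_image(fl, cp_slice_extract(
    vft$re, vft$im, vft$n, rot, as.numeric(fl$hx),
    as.numeric(fl$hy)) * center_phase(fl)),
    vol$pixel_size)
}

#' Align a volume to its symmetry axes
#'
#' Brute-force grid search over rotations about x, y and z. At each grid
#' point the map is rotated, projected along the (0, 0, 0) view and two
#' additional views ((-45, -45, -45) and (15, 70, -15)); for every
#' symmetry-related view a cross-correlation map against the original
#' projection is computed and its peak found. The rotation with the
#' largest summed peak wins; shifts are estimated from the 2D peak offsets
#' (z shift fixed at 0 for C groups).
#'
#' @param volume `em_volume`
#' @param point_group symmetry label (C1 is refused: nothing to align)
#' @param step grid step in degrees
#' @return list(rotation = 3x3 matrix, angles (deg, about x/y/z),
#'   shift (A), peak_sum)
#' @export
align_to_symmetry <- function(volume, point_group, step = 15) {
  ops <- symmetry_ops(point_group)
  if (length(ops) < 2) stop("C1 has no symmetry axes to align to")
  test_angles <- list(c(0, 0, 0), c(-45, -45, -45), c(15, 70, -15))
  n <- box_size(volume)
  px <- volume$pixel_size
  half_range <- 180 / symmetry_order(point_group)
  grid <- seq(-half_range, half_range - step, by = step)
  gz <- seq(-half_range, half_range - step, by = step)
  best <- NULL
  for (ax in grid) for (ay in grid) for (az in gz) {
    rxyz <- rot_z(az * pi / 180) %*% rot_y(ay * pi / 180) %*%
      rot_x(ax * pi / 180)
    rotv <- em_volume(array(cp_rotate3d(as.numeric(volume$data), n, rxyz,
                                        mean(volume$data)), c(n, n, n)), px)
    peak_sum <- 0
    shifts <- NULL
    for (ta in test_angles) {
      re <- euler_matrix(ta[1], ta[2], ta[3])
      ref <- project_matrix(rotv, re)
      r0 <- ref$data - mean(ref$data)
      fref <- fft2(r0)
      for (k in 2:length(ops)) {
        # the symmetry operator acts on the map, i.e. left of the view
        mate <- project_matrix(rotv, ops[[k]] %*% re)
        m0 <- mate$data - mean(mate$data)
        # normalized correlation: unnormalized peaks reward rotations
        # that concentrate power, not symmetry agreement
        denom <- sqrt(sum(r0^2) * sum(m0^2))
        if (denom == 0) next
        cc <- Re(ifft2(Conj(fref) * fft2(m0))) / denom
        pk <- cc_peak_subpixel(cc)
        peak_sum <- peak_sum + max(cc)
        if (identical(ta, c(0, 0, 0)))
          shifts <- rbind(shifts, pk)
      }
    }
    if (is.null(best) || peak_sum > best$peak_sum)
      best <- list(rotation = rxyz, angles = c(ax, ay, az),
                   shift = colMeans(shifts) / 2 * px, peak_sum = peak_sum)
  }
  best
}

#' Symmetrize a volume
#'
#' Averages the volume over all rotations of the point group (real-space
#' trilinear resampling).
#'
#' @param volume `em_volume`
#' @param point_group symmetry label
#' @return symmetrized `em_volume`
#' @export
apply_symmetry <- function(volume, point_group) {
  ops <- symmetry_ops(point_group)
  if (length(ops) < 2) return(volume)
  n <- box_size(volume)
  acc <- volume$data
  for (k in 2:length(ops))
    acc <- acc + array(cp_rotate3d(as.numeric(volume$data), n, ops[[k]], 0),
                       c(n, n, n))
  em_volume(acc / length(ops), volume$pixel_size)
}

# flat default PSSNR based on molecular weight: particle-to-box volume
# fraction scaled to a conservative plateau (cap for the FSC-derived one)
default_pssnr <- function(mw, box, pixel_size, scale = 50) {
  fvol <- particle_volume_from_mass(mw) / (box * pixel_size)^3
  n_sh <- box %/% 2 + 1
  dg <- 1 / (box * pixel_size)
  radial_profile(pmax((0:(n_sh - 1)) * dg, 1e-12),
                 rep(max(scale * fvol, 0.1), n_sh))
}

cap_pssnr <- function(pssnr, cap, floor_frac = 0.1) {
  # the floor (a fraction of the molecular-weight default) keeps the
  # Wiener term moderate in high shells: zeroing them would both erase
  # the signal the next FSC needs to measure and strip the reference of
  # the detail the next refinement aligns against
  capv <- profile_at(cap, pssnr$bin_centers)
  radial_profile(pssnr$bin_centers,
                 pmax(pmin(pssnr$values, capv), floor_frac * capv))
}

#' Ab-initio 3D reconstruction from random angles
#'
#' Initializes particle orientations at random, then iterates: global
#' search over a random pool (3 p fraction) at the scheduled resolution
#' limit, randomized selection among the top-15%-range grid results,
#' reconstruction from the highest-scoring p fraction (sigma reset to 1,
#' score weighting disabled, PSSNR capped by the molecular-weight
#' default), and automatic masking. For symmetric particles in "auto"
#' mode the first 2/3 of iterations run in C1; the map is then aligned to
#' the symmetry axes and the remaining iterations apply the symmetry.
#'
#' @param stack `em_stack` of particles
#' @param config `abinitio_config`
#' @param mw molecular mass (Da) for the default PSSNR and solvent ratio
#' @param mask_radius particle mask radius (A)
#' @param ctfs per-particle `ctf_params`, shared, or NULL
#' @param verbose print per-iteration progress
#' @return list(volume, params = list of `alignment_params`, log =
#'   per-iteration data.frame)
#' @export
abinitio_run <- function(stack, config, mw, mask_radius, ctfs = NULL,
                         verbose = FALSE) {
  set.seed(config$seed)
  N <- dim(stack$data)[3]
  n <- dim(stack$data)[1]
  px <- stack$pixel_size
  D <- 2 * mask_radius
  white <- vector("list", N)
  for (i in seq_len(N))
    white[[i]] <- whiten_background(stack_image(stack, i), mask_radius)
  params <- lapply(seq_len(N), function(i)
    alignment_params(phi = runif(1, 0, 360),
                     theta = acos(runif(1, -1, 1)) * 180 / pi,
                     psi = runif(1, 0, 360)))
  pssnr_def <- default_pssnr(mw, n, px)
  pssnr <- pssnr_def
  scores <- rep(0, N)
  symmetrize_from <- ceiling(2 * config$n_iterations / 3)
  use_sym <- config$apply_symmetry_mode == "always"
  rec_all <- function(idx, res_lim) {
    acc <- recon_accumulator(n, px)
    acc_h <- list(recon_accumulator(n, px), recon_accumulator(n, px))
    for (i in idx) {
      ctf_i <- ctf_of(ctfs, i)
      acc <- insert_particle(acc, white[[i]], params[[i]], ctf_i,
                             sigma = 1, res_limit = res_lim)
      h <- i %% 2 + 1
      acc_h[[h]] <- insert_particle(acc_h[[h]], white[[i]], params[[i]],
                                    ctf_i, sigma = 1, res_limit = res_lim)
    }
    list(full = acc, halves = acc_h)
  }
  # starting map from the random angles
  r0 <- rec_all(seq_len(N), config$R_start)
  vol <- finalize_reconstruction(r0$full, pssnr)
  if (use_sym) vol <- apply_symmetry(vol, config$symmetry)
  vol <- automask(vol, mask_radius)
  log <- NULL
  for (l in 0:(config$n_iterations - 1)) {
    sch <- abinitio_schedule(l, config, N)
    pool_idx <- sort(sample.int(N, max(2, round(sch$pool * N))))
    step_deg <- max(angular_step(sch$R, D) * 180 / pi, 9)
    cfg <- search_config(R1 = 300, R3 = max(sch$R, 2.2 * px),
                         angular_step = step_deg, translation_px = 1,
                         cross_shifts = TRUE)
    machine <- NULL
    for (i in pool_idx) {
      if (is.null(machine)) {
        prep0 <- add_shell_info(prepare_particle_mf(
          white[[i]], ctf_of(ctfs, i), pssnr, cfg))
        machine <- mf_machine(vol, cfg, prep0$fl)
      }
      cand <- global_search(white[[i]], vol, ctf = ctf_of(ctfs, i),
                            pssnr = pssnr, config = cfg, candidates = TRUE,
                            machine = machine)
      pick <- randomized_global_result(cand)
      params[[i]] <- alignment_params(phi = pick$phi, theta = pick$theta,
                                      psi = pick$psi, sx = pick$sx,
                                      sy = pick$sy)
      scores[i] <- pick$score
    }
    keep <- select_pool_and_keep(scores[pool_idx], pool_idx,
                                 max(2, round(sch$p * N)))
    rec <- rec_all(keep, max(sch$R, 2.2 * px))
    # PSSNR: molecular-weight default for the first three iterations,
    # afterwards FSC-derived but never above the default
    if (l >= 3) {
      h1 <- finalize_reconstruction(rec$halves[[1]], pssnr)
      h2 <- finalize_reconstruction(rec$halves[[2]], pssnr)
      fsc <- compute_fsc(h1, h2)
      pssnr <- cap_pssnr(pssnr_from_fsc(part_fsc(
        fsc, solvent_ratio(mask_radius, mw))), pssnr_def)
    }
    vol <- finalize_reconstruction(rec$full, pssnr)
    if (config$apply_symmetry_mode == "auto" &&
        symmetry_order(config$symmetry) > 1 && l + 1 == symmetrize_from) {
      al <- align_to_symmetry(vol, config$symmetry)
      vol <- em_volume(array(cp_rotate3d(as.numeric(vol$data), n,
                                         al$rotation, mean(vol$data)),
                             c(n, n, n)), px)
      use_sym <- TRUE
    }
    if (use_sym) vol <- apply_symmetry(vol, config$symmetry)
    vol <- automask(vol, mask_radius)
    log <- rbind(log, data.frame(iteration = l, R = sch$R, p = sch$p,
                                 pool = sch$pool, kept = length(keep)))
    if (verbose)
      message(sprintf("ab-initio iter %d: R=%.1f A, p=%.2f", l, sch$R,
                      sch$p))
  }
  list(volume = vol, params = params, log = log)
}

ctf_of <- function(ctfs, i) {
  if (is.null(ctfs)) NULL
  else if (inherits(ctfs, "ctf_params")) ctfs
  else ctfs[[i]]
}

#' Auto-refinement schedule update
#'
#' When the estimated resolution improved in the previous iteration,
#' p_l = max(p_R, p_{l-1}) with p_R = 8000 K exp(75 / R_{l-1}^2) / N_eff;
#' otherwise p_l = 1.5 p_{l-1} (both capped at 1). The resolution estimate
#' is the frequency of the FSC = 0.5 crossing minus 2/D_mask (mask-induced
#' half-map correlation), and the refinement limit never goes finer than
#' this estimate. Refinement stops after at least five iterations once
#' p = 1 and the resolution has not improved for the last three
#' iterations; with multiple classes at least nine iterations are run,
#' the average occupancy change must be <= 1%, and the classification
#' resolution is capped at 8 A. Sigma and score weighting stay disabled
#' until the refinement resolution is better than 7 A.
#'
#' @param state list with `iteration`, `p`, `res_history` (A),
#'   `occ_history` (percent)
#' @param fsc `fsc_curve` of the current half maps (uncorrected for
#'   solvent)
#' @param Dmask mask diameter in Angstrom
#' @param K class count
#' @param N particle count
#' @param Osym asymmetric units per particle
#' @param occupancy_change average occupancy change (percent) of the last
#'   cycle (multi-class only)
#' @return updated state with fields `p`, `R_refine`, `R_class`, `stop`,
#'   `sigma_and_weighting_enabled`
#' @export
autorefine_update <- function(state, fsc, Dmask, K = 1, N, Osym = 1,
                              occupancy_change = 0) {
  g05 <- 1 / resolution_at_threshold(fsc, 0.5)
  g_est <- max(g05 - 2 / Dmask, 1e-4)
  res_est <- 1 / g_est
  # improvements below 0.2 A (a couple percent at desk scale) are
  # treated as noise by the stopping rules; slow creep otherwise defeats
  # the three-flat-iterations test
  improved <- length(state$res_history) == 0 ||
    res_est < min(state$res_history) - 0.2
  n_eff <- N * Osym
  r_prev <- if (length(state$res_history) > 0)
    tail(state$res_history, 1) else res_est
  if (improved) {
    p_r <- 8000 * K * exp(75 / r_prev^2) / n_eff
    p_new <- max(p_r, state$p)
  } else {
    p_new <- 1.5 * state$p
  }
  p_new <- min(p_new, 1)
  state$res_history <- c(state$res_history, res_est)
  state$occ_history <- c(state$occ_history, occupancy_change)
  state$iteration <- state$iteration + 1
  state$p <- p_new
  state$R_refine <- res_est
  state$R_class <- max(res_est, 8)
  state$sigma_and_weighting_enabled <- res_est < 7
  h <- state$res_history
  flat3 <- length(h) >= 4 &&
    min(tail(h, 3)) >= min(head(h, length(h) - 3)) - 0.2
  min_iter <- if (K > 1) 9 else 5
  occ_ok <- K == 1 || tail(state$occ_history, 1) <= 1
  state$stop <- state$iteration >= min_iter && p_new >= 1 && flat3 && occ_ok
  state
}

#' Initialize auto-refinement state
#'
#' @param p0 starting subset fraction
#' @return state list for [autorefine_update()]
#' @export
autorefine_state <- function(p0 = 0.1) {
  list(iteration = 0L, p = p0, res_history = numeric(0),
       occ_history = numeric(0), R_refine = Inf, R_class = Inf,
       stop = FALSE, sigma_and_weighting_enabled = FALSE)
}

#' Automatic refinement of a 3D reconstruction
#'
#' Iterates local refinement of a random particle subset against the
#' automasked current map, reconstruction of half maps, FSC-based
#' resolution estimation and the schedule of [autorefine_update()] until
#' the stopping rules fire.
#'
#' @param stack `em_stack`
#' @param init_params list of `alignment_params` (e.g. from
#'   [abinitio_run()])
#' @param reference starting `em_volume`
#' @param mw molecular mass in Dalton
#' @param mask_radius mask radius in Angstrom
#' @param ctfs per-particle `ctf_params`, shared, or NULL
#' @param max_iterations safety cap
#' @param seed RNG seed
#' @param verbose print progress
#' @return list(volume, params, fsc, state, log)
#' @export
autorefine_run <- function(stack, init_params, reference, mw, mask_radius,
                           ctfs = NULL, max_iterations = 12, seed = 1,
                           verbose = FALSE) {
  set.seed(seed)
  N <- dim(stack$data)[3]
  n <- dim(stack$data)[1]
  px <- stack$pixel_size
  white <- vector("list", N)
  for (i in seq_len(N))
    white[[i]] <- whiten_background(stack_image(stack, i), mask_radius)
  params <- init_params
  vol <- automask(reference, mask_radius)
  pssnr_def <- default_pssnr(mw, n, px)
  pssnr <- pssnr_def
  f <- solvent_ratio(mask_radius, mw)
  state <- autorefine_state(p0 = min(8000 / N, 1))
  Dmask <- 2 * mask_radius
  log <- NULL
  fsc <- NULL
  mask3 <- make_soft_mask(n, px, mask_radius, min(6 * px, mask_radius / 3),
                          ndim = 3L)
  # refinement-limit ladder: start at 4 pixels and follow the half-map
  # FSC 0.5 crossing downward, never coarsening; the solvent-corrected
  # estimate (with the mask-correlation term) is reported and drives the
  # subset schedule and the stopping rules
  R_lim <- max(4 * px, 2.2 * px)
  repeat {
    cfg <- search_config(R1 = 300, R3 = max(R_lim, 2.2 * px),
                         translation_px = 1)
    subset <- sort(sample.int(N, max(2, round(state$p * N))))
    for (i in subset) {
      params[[i]] <- local_refine(white[[i]], vol, params[[i]], cfg,
                                  ctf = ctf_of(ctfs, i), pssnr = pssnr,
                                  max_evals = 300)
    }
    acc_h <- list(recon_accumulator(n, px), recon_accumulator(n, px))
    acc <- recon_accumulator(n, px)
    for (i in subset) {
      sig <- 1
      acc <- insert_particle(acc, white[[i]], params[[i]], ctf_of(ctfs, i),
                             sigma = sig)
      h <- i %% 2 + 1
      acc_h[[h]] <- insert_particle(acc_h[[h]], white[[i]], params[[i]],
                                    ctf_of(ctfs, i), sigma = sig)
    }
    h1 <- finalize_reconstruction(acc_h[[1]], pssnr)
    h2 <- finalize_reconstruction(acc_h[[2]], pssnr)
    fsc <- compute_fsc(h1, h2, mask = mask3)
    pssnr <- cap_pssnr(pssnr_from_fsc(part_fsc(fsc, f)), pssnr_def)
    vol <- finalize_reconstruction(acc, pssnr)
    vol <- automask(vol, mask_radius)
    R_lim <- min(R_lim, resolution_at_threshold(fsc, 0.5))
    state <- autorefine_update(state, fsc, Dmask, K = 1, N = N)
    log <- rbind(log, data.frame(iteration = state$iteration,
                                 p = state$p,
                                 resolution = state$R_refine,
                                 subset = length(subset)))
    if (verbose)
      message(sprintf("auto-refine iter %d: res=%.1f A, p=%.2f",
                      state$iteration, state$R_refine, state$p))
    if (state$stop || state$iteration >= max_iterations) break
  }
  list(volume = vol, params = params, fsc = fsc, state = state, log = log)
}
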