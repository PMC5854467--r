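test_that("ab-initio schedule ramps and caps follow the rules", {
  cfg <- abinitio_config(n_iterations = 40, K = 1)
  expect_equal(abinitio_schedule(0, cfg, 1e5)$R, 20)
  expect_equal(abinitio_schedule(39, cfg, 1e5)$R, 8)
  s0 <- abinitio_schedule(0, cfg, 1e5)
  expect_equal(s0$p, 2500 / 1e5)
  expect_equal(s0$pool, 3 * 2500 / 1e5)
  expect_equal(abinitio_schedule(39, cfg, 1e5)$p, 10000 / 1e5)
  # p_start larger than one is reset to 1
  expect_equal(abinitio_schedule(0, cfg, 2000)$p, 1)
  # symmetry replaces N by N x O_sym
  cfg4 <- abinitio_config(n_iterations = 40, K = 1, symmetry = "C4")
  expect_equal(abinitio_schedule(0, cfg4, 1e5)$p, 2500 / 4e5)
  # ramps are monotone
  ps <- sapply(0:39, function(l) abinitio_schedule(l, cfg, 1e6)$p)
  expect_true(all(diff(ps) >= 0))
})

test_that("pool selection keeps the highest scores with index tie-break", {
  scores <- c(5, 9, 9, 1, 7)
  keep <- select_pool_and_keep(scores, pool_idx = 11:15, n_keep = 3)
  expect_equal(keep, c(12, 13, 15))
  # planted high-score subset recovered exactly
  sc2 <- rep(0, 20); sc2[c(3, 8, 17)] <- 10
  expect_equal(select_pool_and_keep(sc2, 1:20, 3), c(3, 8, 17))
  # equal scores: deterministic first indices
  expect_equal(select_pool_and_keep(rep(1, 5), 1:5, 2), c(1, 2))
})

test_that("randomized selection draws only from the top 15% score band", {
  cand <- data.frame(phi = 0, theta = 0, psi = 0, sx = 0, sy = 0,
                     score = 0:100)
  set.seed(38)
  draws <- replicate(200, randomized_global_result(cand)$score)
  expect_true(all(draws >= 85))
  expect_gt(length(unique(draws)), 3)
  # all-equal scores: everything eligible
  cand2 <- cand; cand2$score <- 5
  set.seed(39)
  d2 <- replicate(50, as.numeric(rownames(randomized_global_result(cand2))))
  expect_gt(length(unique(d2)), 10)
  # single candidate returned as-is
  expect_equal(randomized_global_result(cand[7, ])$score, cand$score[7])
})

test_that("automask keeps the largest component and applies the sphere", {
  # two disjoint blobs (the 50 A mask low-pass must not merge them):
  # the smaller one is erased
  blobs <- data.frame(x = c(0, 64), y = c(0, 0), z = c(0, 0),
                      sigma = c(8, 3), amplitude = c(1, 0.5))
  ph <- make_phantom(blobs, 64, 3)
  out <- automask(ph, mask_radius = 80)
  ax <- (0:63 - 32) * 3
  near_small <- which(abs(ax - 64) < 5)
  near_big <- which(abs(ax) < 5)
  expect_lt(max(out$data[near_small, near_big, near_big]),
            0.1 * max(out$data[near_big, near_big, near_big]))
  # the main blob survives with its volume roughly intact
  thr <- 0.5 * max(ph$data)
  expect_equal(sum(out$data > thr), sum(ph$data > thr), tolerance = 0.05)
  # uniform map degenerates with a warning
  expect_warning(automask(em_volume(array(1, c(32, 32, 32)), 3)))
})

test_that("symmetry alignment finds the rotation of an off-axis C4 phantom", {
  blobs <- data.frame(x = 22, y = 0, z = 8, sigma = 6, amplitude = 1)
  ph4 <- make_phantom(blobs, 48, 3, symmetry = "C4")
  # already aligned: the symmetry axis maps onto itself (rotations
  # about z are a degenerate direction for a C group)
  al0 <- align_to_symmetry(ph4, "C4", step = 10)
  expect_gt(abs((al0$rotation %*% c(0, 0, 1))[3]), cos(12 * pi / 180))
  # rotated off axis: recovered within the grid step
  rot <- cryopipe:::rot_x(20 * pi / 180)
  vr <- em_volume(array(cp_rotate3d(as.numeric(ph4$data), 48, rot, 0),
                        c(48, 48, 48)), 3)
  al <- align_to_symmetry(vr, "C4", step = 10)
  fixed <- em_volume(array(cp_rotate3d(as.numeric(vr$data), 48,
                                       al$rotation, 0), c(48, 48, 48)), 3)
  sym_cor <- function(v) {
    vs <- apply_symmetry(v, "C4")
    cor(as.vector(vs$data), as.vector(v$data))
  }
  expect_gt(sym_cor(fixed), 0.95)
  expect_error(align_to_symmetry(ph4, "C1"))
})

test_that("C4 phantoms are invariant under 90-degree rotation", {
  ph4 <- make_phantom(data.frame(x = 20, y = 6, z = -4, sigma = 6,
                                 amplitude = 1), 48, 3, symmetry = "C4")
  r90 <- cp_rotate3d(as.numeric(ph4$data), 48, cryopipe:::rot_z(pi / 2), 0)
  expect_gt(cor(r90, as.numeric(ph4$data)), 0.999)
})

test_that("auto-refinement updates follow the subset and stopping rules", {
  mk_fsc <- function(res) {
    shells <- pmax((0:24) / 144, 1e-12)
    v <- ifelse(shells < 1 / res, 1, 0)
    structure(list(shells = shells, fsc = v, fsc_raw = v, pixel_size = 3),
              class = "fsc_curve")
  }
  # improvement case: p_R = 8000 K exp(75/R^2) / N
  st <- autorefine_state(p0 = 0.05)
  st$res_history <- 10.001  # R_{l-1} = 10 -> exp(0.75)
  st$iteration <- 1L
  st2 <- autorefine_update(st, mk_fsc(8), Dmask = 150, K = 1, N = 1e5)
  expect_equal(st2$p, 8000 * exp(75 / 10.001^2) / 1e5, tolerance = 1e-3)
  # no improvement: p grows by 1.5x
  st3 <- autorefine_update(st2, mk_fsc(20), Dmask = 150, K = 1,
                           N = 1e5)
  expect_equal(st3$p, 1.5 * st2$p, tolerance = 1e-9)
  # p is capped at one
  st3$p <- 0.9
  st4 <- autorefine_update(st3, mk_fsc(30), Dmask = 150, K = 1, N = 1e5)
  expect_equal(st4$p, 1)
  # resolution estimate includes the mask-correlation term
  g_est <- 1 / resolution_at_threshold(mk_fsc(8), 0.5) - 2 / 150
  expect_equal(st2$R_refine, 1 / g_est, tolerance = 1e-9)
  # sigma/score weighting enabled only below 7 A
  expect_false(st2$sigma_and_weighting_enabled)
  stf <- autorefine_update(st, mk_fsc(5), Dmask = 300, K = 1, N = 1e5)
  expect_true(stf$sigma_and_weighting_enabled)
  # stopping needs >= 5 iterations, p = 1 and three flat resolutions
  s <- autorefine_state(p0 = 1)
  s$res_history <- c(12, 11, 10)
  s$iteration <- 3L
  s <- autorefine_update(s, mk_fsc(11), Dmask = 150, K = 1, N = 100)
  expect_false(s$stop)  # only 4 iterations
  s <- autorefine_update(s, mk_fsc(11.5), Dmask = 150, K = 1, N = 100)
  s <- autorefine_update(s, mk_fsc(11.5), Dmask = 150, K = 1, N = 100)
  expect_true(s$stop)
  # multi-class: classification resolution capped at 8 A, >= 9 iterations
  sm <- autorefine_state(p0 = 1)
  sm$res_history <- c(12, 11, 10.5)
  sm$iteration <- 3L
  sm <- autorefine_update(sm, mk_fsc(6), Dmask = 300, K = 2, N = 100,
                          occupancy_change = 0.5)
  expect_equal(sm$R_class, 8)
  expect_false(sm$stop)
})

test_that("the refinement limit never goes finer than the estimated resolution", {
  mk_fsc <- function(res) {
    shells <- pmax((0:24) / 144, 1e-12)
    v <- ifelse(shells < 1 / res, 1, 0)
    structure(list(shells = shells, fsc = v, fsc_raw = v, pixel_size = 3),
              class = "fsc_curve")
  }
  st <- autorefine_state()
  for (res in c(20, 15, 12, 10)) {
    st <- autorefine_update(st, mk_fsc(res), Dmask = 150, K = 1, N = 1e4)
    expect_gte(st$R_refine, res - 1e-9)
  }
})
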