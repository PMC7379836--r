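test_that("basal fluorescence estimation is smooth, mean-preserving, monotone", {
  const <- new_video(array(300, c(3, 40, 50)), 50)
  bf <- estimate_bf(const)
  expect_lt(max(abs(bf - 300)) / 300, 0.01)

  grad <- array(0, c(2, 40, 50))
  for (t in 1:2) grad[t, , ] <- outer(rep(1, 40), seq(100, 400, length.out = 50))
  bfg <- estimate_bf(new_video(grad, 50))
  expect_lt(abs(mean(bfg) - mean(grad)) / mean(grad), 0.01)
  mid <- bfg[20, ]
  expect_true(all(diff(mid[10:40]) > 0))  # gradient direction preserved
})

test_that("spheroid potential is antisymmetric with the spherical limit", {
  m <- ellipse_mask(81, 81, 30, 30)  # disk -> sphere limit
  fld <- spheroid_field(E = 4e4, a = 30, b = 30, um_per_px = 1)
  pk <- spheroid_potential(m, fld)
  ctr <- c(41, 41)
  expect_lt(abs(pk[ctr[1], ctr[2]]), 1e-9)
  ## mirror antisymmetry along the field axis
  expect_equal(pk[41, 41 + 20], -pk[41, 41 - 20], tolerance = 1e-9)
  ## polar deviation = 1.5 E a (classic sphere factor), E in V/m, a in um
  pole <- pk[41, 71]  # 30 px from center along the axis
  expect_equal(pole, 1.5 * 4e4 * 30 * 1e-3, tolerance = 1e-6)

  ## prolate case: outer-ROI means monotone in |cos(angle to field axis)|
  me <- ellipse_mask(61, 121, 25, 55)
  pe <- spheroid_potential(me, spheroid_field(E = 4e4))
  rs <- mess(me, 16, 16)
  cent <- t(sapply(1:16, function(k)
    colMeans(which(rs$labels == k, arr.ind = TRUE))))
  ctr2 <- colMeans(which(me$pixels, arr.ind = TRUE))
  cosang <- abs((cent[, 2] - ctr2[2])) /
    sqrt(rowSums((cent - rep(ctr2, each = 16))^2))
  roi_pk <- abs(sapply(1:16, function(k) mean(pe[rs$labels == k])))
  expect_gt(cor(cosang, roi_pk, method = "spearman"), 0.8)
})

test_that("pure signal videos have the stated structure", {
  m <- fix_ellipse(41, 81, 16, 36)
  bf <- matrix(400, 41, 81)
  ap <- pure_signal_video(bf, m, "AP", fps = 100)
  flat <- matrix(ap$video, nrow = 500)
  nz <- which(colSums(abs(flat)) > 0)
  ## rank-1 space-time structure: all pixel traces proportional
  sv <- svd(flat[, nz])
  expect_lt(sv$d[2] / sv$d[1], 1e-10)

  bf0 <- bf; bf0[21, 41] <- 0
  ep <- pure_signal_video(bf0, m, "electroporation", fps = 100,
                          field = spheroid_field(tau = 0.0167))
  expect_true(all(ep$video[, 21, 41] == 0))  # zero BF -> zero trace
  ## membrane potential within ~5 % of 0 mV 50 ms after the pulse:
  ## in the stored (baseline-subtracted) trace the approach to 0 mV is
  ## the approach to the persistent -V_rest plateau
  tr <- ep$video[, 21, 60]
  i_pulse <- 251
  plateau <- tr[500]
  expect_lt(abs(tr[i_pulse + 5] - plateau) / abs(tr[i_pulse] - plateau),
            0.06)
  ## silence before the pulse
  expect_true(all(ep$video[1:250, , ] == 0))
})

test_that("noise videos have per-pixel variance lambda and independence", {
  nv <- sim_noise_video(225, 2000, seed = 1, shape = c(6, 6))
  vs <- apply(nv, c(2, 3), var)
  expect_lt(max(abs(vs - 225)) / 225, 0.2)
  expect_lt(abs(mean(vs) - 225) / 225, 0.02)
  expect_lt(abs(cor(nv[, 1, 1], nv[, 3, 4])), 0.06)
  expect_identical(sim_noise_video(225, 50, seed = 2, shape = c(4, 4)),
                   sim_noise_video(225, 50, seed = 2, shape = c(4, 4)))
  expect_error(sim_noise_video(-1, 10, shape = c(2, 2)), "positive")
})

test_that("per-ROI gains hit their SNR targets and scale as power", {
  spec <- video_sim_spec(H = 41, W = 81, kind = "AP", target_db = -10,
                         seed = 3)
  sv <- compose_video(spec)
  nr <- metroidr:::roi_means_raw(sv$components$noise, sv$rois)
  snr_roi <- 10 * log10(rowMeans(sv$truth$traces^2) / rowMeans(nr^2))
  expect_true(all(abs(snr_roi - (-10)) < 0.5))
  ## +3 dB multiplies the gain by sqrt(2)
  pure <- pure_signal_video(spec$bf, spec$mask, "AP", spec$fps)
  g1 <- gain_for_snr(pure$video, sv$components$noise, sv$rois, -10)
  g2 <- gain_for_snr(pure$video, sv$components$noise, sv$rois, -7)
  nz <- g1 > 0
  expect_equal(g2[nz] / g1[nz], rep(10^(3 / 20), sum(nz)),
               tolerance = 0.01)
})

test_that("composed videos are additive and degenerate specs collapse to BF", {
  spec <- video_sim_spec(H = 41, W = 81, kind = "AP", target_db = -10,
                         seed = 4)
  sv <- compose_video(spec)
  T_ <- dim(sv$video$frames)[1]
  resum <- rep(sv$bf, each = T_) + sv$components$signal +
    sv$components$bleach + sv$components$noise
  expect_equal(pmax(resum, 0), sv$video$frames, tolerance = 1e-12)

  quiet <- video_sim_spec(H = 41, W = 81, kind = "AP", target_db = -300,
                          lam = 1e-6, bleach = NULL, seed = 5)
  sq <- compose_video(quiet)
  ## Poisson(1e-6) still yields a handful of unit counts; the mean
  ## deviation from BF must be negligible
  expect_lt(mean(abs(sq$video$frames - rep(sq$bf, each = T_))), 1e-3)
})

test_that("blank pairs carry the configured global-mean drift", {
  spec <- video_sim_spec(H = 41, W = 81, kind = "AP", target_db = -10,
                         seed = 6)
  pair <- gen_blank_pair(spec, drift_fraction = 0.003)
  pre <- (seq_len(500) - 1) / spec$fps < pair$stimulated$timing$t_onset
  ratio <- mean(pair$blank$frames) /
    mean(pair$stimulated$video$frames[pre, , ])
  expect_lt(abs(ratio - 1.003), 5e-4)

  pair0 <- gen_blank_pair(spec, drift_fraction = 0)
  ratio0 <- mean(pair0$blank$frames) /
    mean(pair0$stimulated$video$frames[pre, , ])
  expect_lt(abs(ratio0 - 1), 5e-4)
  ## the pair's noise realizations are independent draws, not copies
  d_stim <- pair$stimulated$video$frames[1, , ] - pair$stimulated$bf
  d_blank <- pair$blank$frames[1, , ] / ratio - pair$stimulated$bf
  expect_lt(abs(cor(as.vector(d_stim), as.vector(d_blank))), 0.05)
})
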