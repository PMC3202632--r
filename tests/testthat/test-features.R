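test_that("source projection applies the generalised lead-field inverse", {
  set.seed(1)
  epochs <- burst_epochs(3, noise_sd = 0.1)

  # identity lead field leaves the data unchanged
  same <- project_to_sources(epochs, diag(1))
  expect_equal(same$data, epochs$data)

  # orthogonal lead field: pseudo-inverse equals the transpose
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  src3 <- array(rnorm(2 * 3 * 193), c(2, 3, 193))
  fwd <- array(0, c(2, 3, 193))
  for (tr in 1:2) fwd[tr, , ] <- q %*% src3[tr, , ]
  rec <- project_to_sources(epoched_series(fwd, 128, c(-500, 1000)), q)
  expect_equal(rec$data, src3, tolerance = 1e-10)

  # forward then inverse round trip through a random tall lead field
  lf <- matrix(rnorm(50), 10, 5)
  src <- array(rnorm(2 * 5 * 193), c(2, 5, 193))
  chan <- array(0, c(2, 10, 193))
  for (tr in 1:2) chan[tr, , ] <- lf %*% src[tr, , ]
  rec2 <- project_to_sources(epoched_series(chan, 128, c(-500, 1000)), lf)
  expect_lt(max(abs(rec2$data - src)), 1e-8)

  # rank-deficient lead field is refused with a rank report
  lf_bad <- cbind(lf[, 1:4], lf[, 4])
  expect_error(project_to_sources(epoched_series(chan, 128, c(-500, 1000)), lf_bad),
               "rank")
})

test_that("Morlet transform localises tones and scales quadratically", {
  sfreq <- 128
  times <- seq(0, 2, by = 1 / sfreq)
  freqs <- seq(5, 40, by = 1)
  tone <- sin(2 * pi * 20 * times)
  coef <- morlet_transform(tone, sfreq, freqs, wavelet_number = 7)
  mid <- round(length(times) / 2)
  expect_equal(freqs[which.max(Mod(coef[, mid])^2)], 20)

  expect_equal(morlet_transform(numeric(100), sfreq, freqs),
               matrix(0i, length(freqs), 100), ignore_attr = TRUE)

  # power at the tone frequency scales as amplitude squared
  p <- vapply(c(1, 2, 4), function(a) {
    Mod(morlet_transform(a * tone, sfreq, freqs)[freqs == 20, mid])^2
  }, 0)
  expect_equal(p[2] / p[1], 4, tolerance = 1e-8)
  expect_equal(p[3] / p[1], 16, tolerance = 1e-8)

  expect_error(morlet_transform(tone, sfreq, c(10, 70)), "Nyquist")
})

test_that("white-noise Morlet power is flat across mid-band frequencies", {
  set.seed(7)
  sfreq <- 256
  freqs <- seq(10, 40, by = 5)
  p <- 0
  for (r in 1:20) {
    x <- rnorm(2 * sfreq)
    co <- morlet_transform(x, sfreq, freqs)
    p <- p + rowMeans(Mod(co[, 150:350])^2)
  }
  p <- p / 20
  expect_lt(diff(range(p)) / mean(p), 0.25)
})

test_that("evoked is the transform of the average; induced the average of transforms", {
  # identical trials: no trial variability, the two conditions coincide
  one <- burst_epochs(1, jitter_ms = 0, noise_sd = 0)
  ident <- epoched_series(array(rep(one$data[1, 1, ], each = 4), c(4, 1, dim(one$data)[3])),
                          128, c(-500, 1000))
  sp <- build_conditions(ident, freqs = seq(5, 30, by = 5))
  expect_equal(sp$power[1, , , ], sp$power[2, , , ], tolerance = 1e-10)

  # latency jitter destroys phase locking: induced exceeds evoked mid-band
  jit <- burst_epochs(40, jitter_ms = 100, noise_sd = 0, seed = 3)
  spj <- build_conditions(jit, freqs = seq(5, 30, by = 5))
  band <- which(seq(5, 30, by = 5) == 15)
  win <- jit$times > 100 & jit$times < 500
  expect_gt(mean(spj$power[2, 1, band, win]), 1.5 * mean(spj$power[1, 1, band, win]))

  expect_warning(build_conditions(burst_epochs(1), freqs = c(10, 20)), "single trial")
})

test_that("evoked and induced burst power converge with many noisy phase-locked trials", {
  ep <- burst_epochs(200, jitter_ms = 0, noise_sd = 0.5, seed = 11)
  sp <- build_conditions(ep, freqs = c(10, 15, 20))
  win <- ep$times > 100 & ep$times < 500
  ev <- mean(sp$power[1, 1, 2, win])
  ind <- mean(sp$power[2, 1, 2, win])
  # induced still carries a small noise floor; demand closeness, not equality
  expect_lt(abs(ind - ev) / ev, 0.35)
  # and in expectation induced >= evoked cell-wise (Jensen on magnitudes)
  expect_gt(mean(sp$power[2, 1, , ] - sp$power[1, 1, , ]), -1e-10)
})

test_that("baseline correction zeroes the first bin and is idempotent", {
  set.seed(2)
  p <- array(abs(rnorm(2 * 1 * 5 * 20)), c(2, 1, 5, 20))
  sp <- tf_spectra(p, freqs = 1:5, times = seq(0, 190, by = 10))
  bc <- baseline_correct(sp)
  expect_true(all(bc$power[, , , 1] == 0))
  expect_equal(baseline_correct(bc)$power, bc$power)

  const <- tf_spectra(array(3, c(2, 1, 5, 20)), 1:5, seq(0, 190, by = 10))
  expect_equal(baseline_correct(const)$power, array(0, c(2, 1, 5, 20)))
})

test_that("SVD mode extraction recovers rank and generating subspaces", {
  freqs <- 4:48
  times <- seq(0, 500, by = 10)
  profile <- exp(-(freqs - 20)^2 / 50)
  tc <- sin(2 * pi * times / 300)^2
  p <- array(0, c(2, 1, length(freqs), length(times)))
  for (ci in 1:2) p[ci, 1, , ] <- outer(profile, tc)
  sp <- tf_spectra(p, freqs, times)
  m1 <- extract_modes(sp, 1)
  expect_equal(m1$cumulative_variance[1], 1, tolerance = 1e-10)

  # complete basis explains everything
  modes <- demo_mode_profiles(freqs)
  g1 <- outer(1:2, tc)                      # 2 modes x time
  mix <- modes$profiles %*% g1
  p2 <- array(0, c(2, 1, length(freqs), length(times)))
  p2[1, 1, , ] <- mix
  p2[2, 1, , ] <- modes$profiles %*% (1.3 * g1 + 0.2)
  sp2 <- tf_spectra(p2, freqs, times)
  m2 <- extract_modes(sp2, 2)
  expect_gt(m2$cumulative_variance[2], 0.999)
  expect_lt(subspace_angle(m2$profiles, modes$profiles), 1e-6)
  # orthonormal profiles
  expect_equal(crossprod(m2$profiles), diag(2), tolerance = 1e-10)

  expect_error(extract_modes(sp2, 3), "rank")
  expect_error(extract_modes(sp, length(freqs) + 1), "exceeds")
})

test_that("mode projection is a least-squares reduction with exact back-projection on its range", {
  freqs <- 4:48
  times <- seq(0, 500, by = 10)
  modes <- demo_mode_profiles(freqs)
  g <- rbind(sin(2 * pi * times / 400), cos(2 * pi * times / 250))
  p <- array(0, c(2, 1, length(freqs), length(times)))
  p[1, 1, , ] <- modes$profiles %*% g
  p[2, 1, , ] <- modes$profiles %*% (0.5 * g)
  sp <- tf_spectra(p, freqs, times)
  feats <- project_to_modes(sp, modes)
  # back-projection reproduces rank-K data
  back <- modes$profiles %*% feats$values[, , 1]
  expect_lt(max(abs(back - p[1, 1, , ])), 1e-10)
  expect_equal(feats$values[, , 1], g, tolerance = 1e-10)

  # random spectra: residual orthogonal to the mode subspace, Bessel holds
  set.seed(4)
  pr <- array(abs(rnorm(2 * 1 * length(freqs) * 10)), c(2, 1, length(freqs), 10))
  spr <- tf_spectra(pr, freqs, times[1:10])
  fr <- project_to_modes(spr, modes)
  resid <- pr[1, 1, , ] - modes$profiles %*% fr$values[, , 1]
  expect_lt(max(abs(crossprod(modes$profiles, resid))), 1e-10)
  expect_lte(sum(fr$values[, , 1]^2), sum(pr[1, 1, , ]^2))

  bad <- demo_mode_profiles(5:40)
  expect_error(project_to_modes(spr, bad), "grids")
})

test_that("coupling blocks map to frequency space through the mode profiles", {
  modes <- demo_mode_profiles()
  P <- modes$profiles
  # identity block becomes the projector onto the mode subspace
  expect_equal(coupling_to_frequency(diag(2), modes), P %*% t(P))
  expect_equal(coupling_to_frequency(matrix(0, 2, 2), modes),
               matrix(0, nrow(P), nrow(P)))
  # closure: a matrix already in the subspace round-trips exactly
  M <- matrix(c(0.3, -0.1, 0.2, 0.5), 2, 2)
  Fq <- coupling_to_frequency(M, modes)
  expect_equal(t(P) %*% Fq %*% P, M, tolerance = 1e-10)
  expect_error(coupling_to_frequency(diag(3), modes), "mode space")
})

test_that("the spectra-level pipeline returns the generating mode trajectories", {
  truth <- two_area_truth("er+ir")
  times <- seq(-500, 1000, by = 1000 / 240)
  freqs <- 4:48
  modes <- demo_mode_profiles(freqs)
  p <- array(0, c(2, 2, length(freqs), length(times)))
  for (v in 0:1) {
    traj <- integrate_trajectory(truth$coupling, gamma_input(), v, times)
    for (s in 1:2) {
      p[v + 1, s, , ] <- modes$profiles %*% traj$g[(s - 1) * 2 + 1:2, ]
    }
  }
  sp <- tf_spectra(p, freqs, times, source_labels = c("area1", "area2"))
  est_modes <- extract_modes(sp, 2)
  feats <- project_to_modes(sp, est_modes)
  # recovered coefficients equal the generating ones after subspace alignment
  R <- crossprod(est_modes$profiles, modes$profiles)   # rotation between bases
  for (v in 0:1) {
    traj <- integrate_trajectory(truth$coupling, gamma_input(), v, times)
    for (s in 1:2) {
      aligned <- t(R) %*% feats$values[(s - 1) * 2 + 1:2, , v + 1]
      expect_lt(max(abs(aligned - traj$g[(s - 1) * 2 + 1:2, ])), 1e-6)
    }
  }
})
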