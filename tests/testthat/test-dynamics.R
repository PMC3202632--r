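test_that("coupling_flow evaluates the bilinear state equation", {
  A <- matrix(c(-1, 0.5, 0, -1), 2, 2, byrow = TRUE)
  B <- matrix(c(0, 0, 0.3, 0), 2, 2, byrow = TRUE)
  cs <- coupling_set(A, list(B), C = matrix(c(1, 0), 2, 1), tau = 2)

  # null state and input
  expect_equal(coupling_flow(c(0, 0), cs, v = 1, u = 0), c(0, 0))

  # evoked condition is independent of B
  g <- c(0.4, -0.2)
  cs_nob <- coupling_set(A, list(matrix(0, 2, 2)), cs$C, tau = 2)
  expect_equal(coupling_flow(g, cs, v = 0, u = 1),
               coupling_flow(g, cs_nob, v = 0, u = 1))
  expect_equal(coupling_flow(g, cs, v = 0, u = 1),
               as.vector(A %*% g + cs$C %*% 1) / 2)

  # hand-computed value: ((A + B) g + C u) / tau
  expect_equal(coupling_flow(c(1, 1), cs, v = 1, u = 2), c(0.75, -0.35))

  expect_error(coupling_flow(c(1, 1, 1), cs, v = 1, u = 0), "length")
  expect_error(coupling_flow(c(1, NA), cs, v = 1, u = 0), "non-finite")
})

test_that("coupling_set validates shape, diagonal and masks", {
  A <- diag(-1, 2)
  expect_error(coupling_set(matrix(0, 2, 2), C = matrix(1, 2, 1), tau = 1),
               "diagonal")
  expect_error(coupling_set(A, C = matrix(1, 2, 1), tau = -1), "positive")
  g <- model_graph(1, 2, a_mask = matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
  A2 <- A; A2[1, 2] <- 0.5   # outside the mask (only [2,1] is estimable)
  expect_error(coupling_set(A2, C = matrix(c(1, 0), 2, 1), tau = 1, graph = g),
               "a_mask")
})

test_that("gamma input integrates to its amplitude and respects the onset", {
  inp <- gamma_input(shape = 6, rate = 0.048, amplitude = 3, onset = 100)
  times <- seq(-500, 1500, by = 1)
  u <- evaluate_input(inp, times)
  expect_true(all(u[times < 100] == 0))
  expect_true(all(u >= 0))
  expect_equal(sum(u) * 1, 3, tolerance = 1e-6)   # quadrature vs amplitude

  expect_equal(evaluate_input(gamma_input(amplitude = 0), times),
               numeric(length(times)))

  # shape 1 is a decaying exponential from the onset
  u1 <- evaluate_input(gamma_input(shape = 1, rate = 0.01, amplitude = 1), 0:500)
  ratio <- u1[2:200] / u1[1:199]
  expect_equal(ratio, rep(exp(-0.01), 199), tolerance = 1e-10)

  expect_error(gamma_input(shape = -1), "positive")
  expect_error(gamma_input(rate = 0), "positive")
})

test_that("matrix-exponential integration matches a fine-step RK4 oracle", {
  truth <- two_area_truth("er+ir")
  times <- seq(-500, 1000, by = 1000 / 240)
  inp <- gamma_input()
  for (v in 0:1) {
    traj <- integrate_trajectory(truth$coupling, inp, v, times)
    oracle <- rk4_zoh_oracle(truth$coupling, inp, v, times)
    expect_lt(max(abs(traj$g - oracle)) / max(abs(oracle)), 1e-6)
  }
})

test_that("trajectories respect equilibrium, linearity and stability", {
  truth <- two_area_truth("er+ir")
  times <- seq(-500, 1000, by = 1000 / 240)

  # no input, zero start: identically zero
  z <- integrate_trajectory(truth$coupling, gamma_input(amplitude = 0), 1, times)
  expect_equal(z$g, matrix(0, 4, length(times)))

  # inert bilinear term: v = 0 vs v = 1 with B = 0
  er <- two_area_truth("er")
  t0 <- integrate_trajectory(er$coupling, gamma_input(), 0, times)
  t1 <- integrate_trajectory(er$coupling, gamma_input(), 1, times)
  expect_equal(t0$g, t1$g)

  # linear in the input amplitude
  a1 <- integrate_trajectory(truth$coupling, gamma_input(amplitude = 10), 1, times)
  a2 <- integrate_trajectory(truth$coupling, gamma_input(amplitude = 20), 1, times)
  expect_equal(2 * a1$g, a2$g, tolerance = 1e-12)

  # stable system decays once the input has vanished
  nrm <- sqrt(colSums(a1$g^2))
  late <- times > 600
  expect_true(all(diff(nrm[late]) < 0))

  # divergence is reported with the unstable eigenvalue
  Abad <- matrix(c(-1, 3, 3, -1), 2, 2)
  bad <- coupling_set(Abad, C = matrix(c(1, 0), 2, 1), tau = 100)
  expect_error(integrate_trajectory(bad, gamma_input(), 0, seq(0, 20000, by = 5)),
               "unstable eigenvalue")

  expect_error(integrate_trajectory(truth$coupling, gamma_input(), 0,
                                    c(0, 1, 3, 6)),
               "uniform")
})

test_that("coupling sets, graphs and trajectories survive a JSON round trip", {
  truth <- two_area_truth("er+ir")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_coupling(truth$coupling, tmp)
  back <- read_coupling(tmp)
  expect_equal(back$A, truth$coupling$A)
  expect_equal(back$B, truth$coupling$B)
  expect_equal(back$C, truth$coupling$C)
  expect_equal(back$tau, truth$coupling$tau)

  tmp2 <- withr::local_tempfile(fileext = ".json")
  write_model_graph(truth$graph, tmp2)
  g2 <- read_model_graph(tmp2)
  expect_equal(g2$a_mask, truth$graph$a_mask)
  expect_equal(g2$b_masks, truth$graph$b_masks)
  expect_equal(g2$c_mask, truth$graph$c_mask)

  times <- seq(-500, 1000, by = 1000 / 240)
  traj <- integrate_trajectory(truth$coupling, gamma_input(), 1, times)
  tmp3 <- withr::local_tempfile(fileext = ".json")
  write_trajectory(traj, tmp3)
  t2 <- read_trajectory(tmp3)
  expect_equal(t2$g, traj$g)
  expect_equal(t2$condition, "induced")
})
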