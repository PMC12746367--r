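test_that("single pool without RF relaxes with eigenvalues -1/T2, -1/T2, -1/T1", {
  sys <- single_pool_system(t1 = 1.4, t2 = 0.05)
  pc <- build_propagator(sys, b1_uT = 0, offset_ppm = 11)
  ev <- eigen(pc$A)$values
  expect_equal(sort(Re(ev)), sort(c(-1 / 0.05, -1 / 0.05, -1 / 1.4)),
               tolerance = 1e-12)
})

test_that("on-resonance RF produces the standard nutation skew pair", {
  w1 <- 2 * pi * 100
  b1 <- w1 / GAMMA_1H * 1e6
  sys <- single_pool_system(t1 = 1, t2 = 0.1)
  pc <- build_propagator(sys, b1_uT = b1, offset_ppm = 0)
  # hand-built 3x3 Bloch matrix, RF along x, on resonance
  A_ref <- matrix(c(-1 / 0.1, 0, 0,
                    0, -1 / 0.1, w1,
                    0, -w1, -1), 3, 3, byrow = TRUE)
  expect_equal(pc$A, A_ref, tolerance = 1e-12)
  expect_equal(pc$C, c(0, 0, 1))
})

test_that("Mz-exchange sub-block conserves magnetization (zero column sums)", {
  sys <- two_pool_system(fs = 2e-3, ksw = 400)
  pc <- build_propagator(sys, b1_uT = 0, offset_ppm = 3)
  # Mz rows are 3 (water) and 6 (solute); exchange contributions must cancel
  ex <- matrix(c(-2e-3 * 400, 400, 2e-3 * 400, -400), 2, 2, byrow = TRUE)
  blk <- pc$A[c(3, 6), c(3, 6)]
  relax <- diag(c(-1 / sys$t1[1], -1 / sys$t1[2]))
  expect_equal(blk - relax, ex, tolerance = 1e-12)
  expect_equal(colSums(blk - relax), c(0, 0), tolerance = 1e-12)
})

test_that("propagation fixed point is -A^-1 C and steady states are exact", {
  sys <- single_pool_system(t1 = 1, t2 = 0.1)
  pc <- build_propagator(sys, b1_uT = 1.3, offset_ppm = 0.7)
  fp <- as.numeric(solve(pc$A, -pc$C))
  expect_equal(propagate_interval(fp, pc, 0.37), fp, tolerance = 1e-12)
})

test_that("T1 recovery and CW saturation match their closed forms", {
  sys <- single_pool_system(t1 = 1, t2 = 0.1)
  pc0 <- build_propagator(sys, b1_uT = 0, offset_ppm = 0)
  M <- propagate_interval(c(0, 0, 0), pc0, dt = 1)
  expect_equal(M[3], 1 - exp(-1), tolerance = 1e-9)

  w1 <- 267.5
  pc1 <- build_propagator(sys, b1_uT = w1 / GAMMA_1H * 1e6, offset_ppm = 0)
  M <- propagate_interval(c(0, 0, 1), pc1, dt = 10)
  expect_equal(M[3], 1 / (1 + w1^2 * 1 * 0.1), tolerance = 1e-6)
})

test_that("step splitting is exact: one step of dt equals two of dt/2", {
  sys <- two_pool_system()
  pc <- build_propagator(sys, b1_uT = 3, offset_ppm = 3)
  M0 <- equilibrium_state(sys)
  M1 <- propagate_interval(M0, pc, 0.8)
  M2 <- propagate_interval(propagate_interval(M0, pc, 0.4), pc, 0.4)
  expect_equal(M1, M2, tolerance = 1e-10)
})

test_that("the matrix exponential agrees with an independent implementation", {
  skip_if_not_installed("Matrix")
  sys <- two_pool_system(fs = 5e-3, ksw = 900)
  pc <- build_propagator(sys, b1_uT = 4, offset_ppm = 3)
  M0 <- equilibrium_state(sys)
  dt <- 0.25
  f <- solve(pc$A, pc$C)
  ref <- as.numeric(as.matrix(Matrix::expm(pc$A * dt)) %*% (M0 + f) - f)
  expect_equal(propagate_interval(M0, pc, dt), ref, tolerance = 1e-10)
})

test_that("rate-model semisolid pool saturates at W = pi w1^2 g", {
  sys <- mt_pool_system(lineshape = "superlorentzian_rate", fs = 0.1, ksw = 40)
  pc <- build_propagator(sys, b1_uT = 2, offset_ppm = 20)
  # state: water (Mx, My, Mz) + semisolid Mz -> dimension 4
  expect_equal(nrow(pc$A), 4)
  w1 <- b1_to_rads(2)
  dw <- ppm_to_rads(20 - (-2.5), 3)
  W <- pi * w1^2 * lineshape_g("superlorentzian", 1e-5, dw)
  # diagonal of the semisolid row: -1/T1ss - ksw - W
  expect_equal(pc$A[4, 4], -1 / 1.0 - 40 - W, tolerance = 1e-10)
  expect_equal(pc$C[4], 0.1 / 1.0)
})

test_that("invalid inputs are rejected", {
  sys <- single_pool_system()
  pc <- build_propagator(sys, 1, 0)
  expect_error(propagate_interval(c(0, 0), pc, 0.1), "length")
  expect_error(propagate_interval(c(0, 0, 0), pc, -1), "dt")
  expect_error(pool("x", t1 = -1, t2 = 0.1), "t1")
  expect_error(pool("x", t1 = 1, t2 = 0), "t2")
})
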