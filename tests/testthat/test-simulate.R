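test_that("zero saturation gives sin(FA) and zero flip gives nothing", {
  sys <- two_pool_system()
  sch <- cw4(b1 = rep(0, 4))
  tr <- simulate_schedule(sys, sch)
  expect_equal(tr$signal, rep(sin(60 * pi / 180), 4), tolerance = 1e-9)

  sch0 <- cw_schedule(c(1, 2), flip_angle_deg = 0)
  expect_equal(simulate_schedule(sys, sch0)$signal, c(0, 0))
})

test_that("two-pool CW at the decoupled limit matches the closed form", {
  # f -> 0: water behaves as an isolated pool; off-resonance CW steady state
  sys <- larg_pool_system(b0 = 7, fs = 1e-9, ksw = 1)
  sch <- cw_schedule(2.2, offset_ppm = 3, t_sat_s = 60, t_rec_s = 0,
                     flip_angle_deg = 90)
  tr <- simulate_schedule(sys, sch)
  mz <- cw_steady_mz(t1 = 2.8, t2 = 0.6, w1 = b1_to_rads(2.2),
                     dw = ppm_to_rads(3, 7))
  expect_equal(tr$signal[1], mz, tolerance = 1e-6)
})

test_that("signals are bounded and monotone in saturation power", {
  sys <- single_pool_system(t1 = 1.2, t2 = 0.08)
  b1s <- seq(0, 5, by = 1)
  sig <- vapply(b1s, function(b) {
    simulate_schedule(sys, cw_schedule(b, offset_ppm = 0, t_sat_s = 2,
                                       t_rec_s = 0.5))$signal[1]
  }, numeric(1))
  expect_true(all(diff(sig) <= 1e-12))
  expect_true(all(sig >= 0 & sig <= 1 + 1e-6))
})

test_that("state returns to equilibrium after a long recovery", {
  sys <- two_pool_system()
  long_rec <- cw_schedule(c(5, 0), offset_ppm = 3, t_sat_s = 3,
                          t_rec_s = 10 * 2.8, flip_angle_deg = 60)
  tr <- simulate_schedule(sys, long_rec)
  # second image follows >= 10 T1 of recovery after heavy saturation
  expect_equal(tr$signal[2], sin(60 * pi / 180), tolerance = 1e-4)
})

test_that("relabeling solute pools leaves the signal unchanged", {
  p1 <- pool("a", t1 = 1.1, t2 = 0.02, f = 2e-3, k = 300, delta = 2)
  p2 <- pool("b", t1 = 0.9, t2 = 0.01, f = 5e-3, k = 50, delta = -1)
  w <- pool("water", t1 = 1.5, t2 = 0.1)
  s12 <- pool_system(w, list(p1, p2), b0 = 3)
  s21 <- pool_system(w, list(p2, p1), b0 = 3)
  sch <- cw_schedule(c(1.5, 3), offset_ppm = 2, t_sat_s = 1.5, t_rec_s = 0.5)
  expect_equal(simulate_schedule(s12, sch)$signal,
               simulate_schedule(s21, sch)$signal, tolerance = 1e-12)
})

test_that("pulsed trains differ from CW at matched average timing", {
  sys <- larg_pool_system(b0 = 3)
  pw <- pulsed_schedule(2, offset_ppm = 3)
  cw <- cw_schedule(2, offset_ppm = 3, t_sat_s = 2.6, t_rec_s = 1,
                    flip_angle_deg = 12)
  s_pw <- simulate_schedule(sys, pw)$signal
  s_cw <- simulate_schedule(sys, cw)$signal
  expect_gt(s_pw[1], s_cw[1]) # 50 % duty cycle saturates less
})

test_that("isochromat ensembles are deterministic, normalized and symmetric", {
  ens <- make_isochromats(33, t2 = 0.1, t2star = 0.05)
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_equal(ens$db0_offsets, -rev(ens$db0_offsets), tolerance = 1e-9)
  expect_equal(ens$lorentz_scale, 1 / 0.05 - 1 / 0.1)
  expect_identical(make_isochromats(33, 0.1, 0.05)$db0_offsets,
                   ens$db0_offsets)

  expect_equal(make_isochromats(1, t2 = 0.1)$db0_offsets, 0)
  same <- make_isochromats(9, t2 = 0.1, t2star = 0.1)
  expect_equal(same$db0_offsets, rep(0, 9))
  expect_equal(same$lorentz_scale, 0)
  expect_error(make_isochromats(10, 0.1, 0.05), "odd")
  expect_error(make_isochromats(9, 0.1, 0.2), "t2star")
})

test_that("the summed free decay reproduces the T2* envelope", {
  t2 <- 0.07
  t2star <- 0.045
  t <- seq(5e-4, t2star, length.out = 150)
  env_err <- function(n) {
    ens <- make_isochromats(n, t2 = t2, t2star = t2star)
    sig <- vapply(t, function(tt) {
      sum(ens$weights * cos(ens$db0_offsets * tt)) * exp(-tt / t2)
    }, numeric(1))
    max(abs(sig / exp(-t / t2star) - 1))
  }
  expect_lt(env_err(101), 0.01)
  expect_lt(env_err(33), 0.02)
})

test_that("T2* broadening attenuates the echoed signal", {
  sys <- single_pool_system(t1 = 1.3, t2 = 0.08)
  sch <- cw_schedule(c(1, 2), offset_ppm = 0, t_sat_s = 1, t_rec_s = 0.5)
  plain <- simulate_schedule(sys, sch)
  broad <- simulate_schedule(sys, sch, make_isochromats(33, 0.08, 0.05))
  expect_true(all(is.finite(broad$signal)))
  expect_false(isTRUE(all.equal(plain$signal, broad$signal)))
})

test_that("empty schedules are rejected", {
  sys <- single_pool_system()
  sch <- cw_schedule(1)[0, ]
  attr(sch, "t_rec_s") <- 1
  attr(sch, "flip_angle_deg") <- 60
  expect_error(simulate_schedule(sys, sch), "empty")
})
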