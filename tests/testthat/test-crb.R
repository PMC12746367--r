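test_that("finite differences are exact for signals linear in the parameters", {
  g <- tiny_grid()
  d <- fake_dictionary(g, function(fs, ksw) {
    c(3 * fs + 0.001 * ksw, -2 * fs, 5e-4 * ksw, 1)
  }, n_images = 4)
  J <- finite_diff_jacobian(d, 5) # interior node
  expect_equal(J[, "fs"], c(3, -2, 0, 0), tolerance = 1e-12)
  expect_equal(J[, "ksw"], c(0.001, 0, 5e-4, 0), tolerance = 1e-12)
  # boundary node: one-sided, still exact for a linear map
  Jb <- finite_diff_jacobian(d, 1)
  expect_equal(Jb[, "fs"], c(3, -2, 0, 0), tolerance = 1e-12)
  expect_true(all(attr(Jb, "one_sided")))

  dconst <- fake_dictionary(g, function(fs, ksw) rep(1, 3), n_images = 3)
  expect_equal(finite_diff_jacobian(dconst, 5),
               matrix(0, 3, 2, dimnames = list(NULL, c("fs", "ksw"))),
               ignore_attr = TRUE)
})

test_that("grid finite differences track a step-halving oracle on BM signals", {
  sys <- two_pool_system()
  sch <- cw4()
  fs0 <- 2e-3
  k0 <- 500
  make_d <- function(h_fs, h_k) {
    g <- param_grid(fs0 + h_fs * (-1:1), k0 + h_k * (-1:1))
    generate_dictionary(sys, g, sch)
  }
  J <- finite_diff_jacobian(make_d(2e-4, 50), 5)
  J_fine <- finite_diff_jacobian(make_d(5e-5, 12.5), 5)
  # Richardson-extrapolated oracle from quarter-spacing central differences
  expect_equal(J[, "fs"], J_fine[, "fs"], tolerance = 1e-2)
  expect_equal(J[, "ksw"], J_fine[, "ksw"], tolerance = 1e-2)
})

test_that("Fisher information matches the mono-exponential closed form", {
  # s(theta) = exp(-theta * t), t = (1, 2), theta = 1, sigma = 1:
  # I = sum t^2 exp(-2 theta t) = e^-2 + 4 e^-4
  t_n <- c(1, 2)
  theta <- 1
  J <- matrix(-t_n * exp(-theta * t_n), ncol = 1)
  I_closed <- exp(-2) + 4 * exp(-4)
  expect_equal(fisher_information(J, 1)[1, 1], I_closed, tolerance = 1e-12)
  expect_equal(fisher_information(J, 2), fisher_information(J, 1) / 4)
  expect_equal(fisher_information(matrix(0, 5, 2)), matrix(0, 2, 2))
  # scalar CRB is the reciprocal
  expect_equal(1 / fisher_information(J, 1)[1, 1], 1 / I_closed,
               tolerance = 1e-10)
})

test_that("normalized CRB applies the theta scaling to the diagonal", {
  cfgs <- list(theta = crb_config(normalization = "theta"),
               theta2 = crb_config(normalization = "theta_squared"))
  for (cfg in cfgs) {
    n <- normalized_crb(diag(2), c(1, 1), cfg)
    expect_equal(diag(n), c(1, 1))
    expect_equal(sum(diag(n)), 2)
  }
  n2 <- normalized_crb(diag(c(4, 1)), c(2, 1), cfgs$theta2)
  expect_equal(diag(n2), c(1 / 16, 1))
  expect_equal(sum(diag(n2)), 1.0625)
  n1 <- normalized_crb(diag(c(4, 1)), c(2, 1), cfgs$theta)
  expect_equal(diag(n1), c(1 / 8, 1))
  expect_error(normalized_crb(matrix(1, 2, 2), c(1, 1)), "unidentifiable")
})

test_that("loss aggregation, boundary handling and sigma scaling", {
  sys <- two_pool_system()
  d <- generate_dictionary(sys, tiny_grid(), cw4())
  res <- crb_loss(d)
  # 3x3 grid has a single interior node; the loss is that node's trace
  expect_equal(sum(res$node_results$included), 1)
  inc <- res$node_results[res$node_results$included, ]
  expect_equal(res$loss, inc$loss)
  expect_equal(inc$node, 5)
  expect_true(all(vapply(
    res$node_results$fisher[res$node_results$included],
    function(f) isTRUE(all.equal(f, t(f))) && all(eigen(f)$values > -1e-8),
    logical(1))))

  res2 <- crb_loss(d, crb_config(sigma = 2))
  expect_equal(res2$loss, 4 * res$loss, tolerance = 1e-12)

  res_all <- crb_loss(d, crb_config(include_boundary = TRUE))
  expect_equal(sum(res_all$node_results$included), 9)
  res_sum <- crb_loss(d, crb_config(include_boundary = TRUE,
                                    aggregation = "sum"))
  expect_equal(res_sum$loss,
               sum(res_all$node_results$loss), tolerance = 1e-12)
})

test_that("Fisher information is additive over concatenated trajectories", {
  g <- tiny_grid()
  sys <- two_pool_system()
  d1 <- generate_dictionary(sys, g, cw_schedule(c(1, 2), offset_ppm = 3))
  d2 <- generate_dictionary(sys, g, cw_schedule(c(3, 5), offset_ppm = 3))
  J1 <- finite_diff_jacobian(d1, 5)
  J2 <- finite_diff_jacobian(d2, 5)
  expect_equal(fisher_information(rbind(J1, J2), 1),
               fisher_information(J1, 1) + fisher_information(J2, 1),
               tolerance = 1e-12)
})

test_that("sigma rescales the loss uniformly without changing schedule ranking", {
  sys <- two_pool_system()
  g <- tiny_grid()
  set.seed(99)
  losses <- function(sigma) {
    vapply(1:5, function(i) {
      set.seed(i)
      sch <- cw_schedule(runif(4, 0, 6), offset_ppm = 3)
      crb_loss(generate_dictionary(sys, g, sch), crb_config(sigma = sigma))$loss
    }, numeric(1))
  }
  l1 <- losses(1)
  l3 <- losses(3)
  expect_equal(l3, 9 * l1, tolerance = 1e-10)
  expect_equal(order(l1), order(l3))
})
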