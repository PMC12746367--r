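test_that("vial phantoms map concentration to fs by the proton convention", {
  ph <- make_phantom("vial_grid", c(25, 50, 100), c(300, 500, 700), size = 32)
  expect_equal(ph$roi_fs, 3 * c(25, 50, 100) / 111e3)
  expect_equal(sort(unique(as.vector(ph$roi_labels))), 0:3)
  for (r in 1:3) {
    expect_equal(unique(ph$fs_truth[ph$roi_labels == r]), ph$roi_fs[r])
    expect_equal(unique(ph$ksw_truth[ph$roi_labels == r]), ph$roi_ksw[r])
  }
  expect_true(all(ph$fs_truth[ph$roi_labels == 0L] == 0))
  expect_error(make_phantom("vial_grid", c(0, 50), c(1, 2), size = 32),
               "positive")
  expect_error(make_phantom("vial_grid", c(25, 50), c(1, 2, 3), size = 32),
               "equal length")
  tw <- make_phantom("two_tissue", c(50, 100), c(30, 60), size = 32,
                     pools = mt_pool_system())
  expect_equal(sort(unique(as.vector(tw$roi_labels))), 1:2)
})

test_that("noiseless acquisition of on-grid truth is recovered exactly", {
  tpl <- protocol_template("cw7t_larg", n_images = 4)
  grid <- param_grid(3 * 25 / 111e3 * 1:8, seq(100, 800, by = 100))
  ph <- make_phantom("vial_grid", c(25, 50, 100), c(300, 500, 700),
                     size = 32, pools = tpl$pools)
  sch <- cw4(b1 = c(0.5, 2, 4, 6))
  img <- simulate_acquisition(ph, sch, sigma = 0)
  d <- generate_dictionary(tpl$pools, grid, sch)
  maps <- reconstruct_maps(img, d)
  rep <- metric_report(ph, maps)
  expect_equal(rep$mape_mean_pct, c(0, 0))
  expect_equal(rep$nrmse, c(0, 0), tolerance = 1e-12)
  expect_equal(rep$ssim, c(1, 1), tolerance = 1e-12)
  expect_equal(rep$pearson_r, c(1, 1), tolerance = 1e-12)
  mp <- mape(ph$ksw_truth, maps$ksw_map, ph$roi_labels)
  expect_equal(mp$mape_pct, rep(0, 3))
})

test_that("acquisition noise is seeded and has the requested spread", {
  ph <- make_phantom("vial_grid", c(50, 100), c(300, 700), size = 32)
  sch <- cw_schedule(c(1, 3), offset_ppm = 3)
  a <- simulate_acquisition(ph, sch, sigma = 0.02, seed = 9)
  b <- simulate_acquisition(ph, sch, sigma = 0.02, seed = 9)
  expect_identical(a$data, b$data)

  clean <- simulate_acquisition(ph, sch, sigma = 0)
  mask3 <- array(ph$roi_labels > 0L, dim(a$data))
  noise <- (a$data - clean$data)[mask3]
  # empirical SD over all masked samples
  expect_equal(sd(noise), 0.02, tolerance = 0.05)
  # background stays exactly zero
  expect_true(all(a$data[!mask3] == 0))
})

test_that("MAPE matches hand-computed values", {
  labels <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  truth <- matrix(c(100, 100, 200, 200), 2, 2)
  est <- matrix(c(110, 110, 180, 180), 2, 2)
  m <- mape(truth, est, labels)
  expect_equal(m$mape_pct, c(10, 10))
  expect_equal(mape(truth, truth, labels)$mape_pct, c(0, 0))
  expect_equal(mape(truth, 2 * truth, labels)$mape_pct, c(100, 100))
  bad <- truth
  bad[1, 1] <- 0
  expect_error(mape(bad, est, labels), "non-zero")
})

test_that("NRMSE matches hand-computed values and guards zero range", {
  ref <- matrix(c(0, 1, 0, 1), 2, 2)
  expect_equal(nrmse(ref, ref), 0)
  est0 <- matrix(0, 2, 2)
  expect_equal(nrmse(ref, est0), sqrt(0.5), tolerance = 1e-12)
  expect_error(nrmse(matrix(1, 2, 2), est0), "zero range")
})

test_that("SSIM and Pearson behave on identical, affine and anticorrelated maps", {
  set.seed(31)
  ref <- matrix(rnorm(100), 10, 10)
  same <- ssim_and_pearson(ref, ref)
  expect_equal(same$ssim, 1, tolerance = 1e-12)
  expect_equal(same$pearson_r, 1)
  aff <- ssim_and_pearson(ref, 2.5 * ref + 1)
  expect_equal(aff$pearson_r, 1)
  chk <- matrix(rep(c(1, -1), 50), 10, 10)
  anti <- ssim_and_pearson(chk, -chk)
  expect_equal(anti$pearson_r, -1)
  expect_error(ssim_and_pearson(matrix(1, 10, 10), ref), "zero")
})

test_that("SSIM reproduces the reference-implementation value on a fixture", {
  # oracle frozen from scikit-image structural_similarity (win 7, uniform
  # window, data_range = reference range) on this deterministic fixture
  n <- 12
  i <- matrix(rep(0:(n - 1), n), n, n)
  j <- matrix(rep(0:(n - 1), each = n), n, n)
  ref <- sin(i / 3) + 0.5 * cos(j / 2)
  est <- ref + 0.1 * sin(2 * i + 3 * j)
  expect_equal(ssim_and_pearson(ref, est)$ssim, 0.985588469548542,
               tolerance = 1e-9)
})

test_that("paired t-test matches the textbook formula and guards degeneracy", {
  before <- c(3, 4, 5, 7)
  after <- c(2, 3, 4, 5)
  d <- before - after
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * (1 - pt(t_oracle, length(d) - 1))
  r <- paired_ttest(before, after)
  expect_equal(r$t, t_oracle, tolerance = 1e-12)
  expect_equal(r$p, p_oracle, tolerance = 1e-12)

  same <- paired_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_ttest(1:3, 1:4), "equal length")

  stars <- paired_ttest(c(10, 11, 12, 13, 14), c(1, 2.1, 2.9, 4, 5.2))
  expect_equal(stars$stars, "***")
})

test_that("error metrics do not improve with noise on average", {
  tpl <- protocol_template("cw7t_larg", n_images = 4)
  grid <- param_grid(3 * 25 / 111e3 * 1:8, seq(100, 800, by = 100))
  ph <- make_phantom("vial_grid", c(25, 100), c(300, 700), size = 32,
                     pools = tpl$pools)
  sch <- cw4(b1 = c(0.5, 2, 4, 6))
  d <- generate_dictionary(tpl$pools, grid, sch)
  mean_mape <- function(sigma) {
    mean(vapply(1:20, function(s) {
      img <- simulate_acquisition(ph, sch, sigma = sigma, seed = 1000 + s)
      maps <- reconstruct_maps(img, d)
      mean(mape(ph$ksw_truth, maps$ksw_map, ph$roi_labels)$mape_pct)
    }, numeric(1)))
  }
  m <- vapply(c(0.01, 0.02, 0.05), mean_mape, numeric(1))
  expect_true(all(diff(m) >= 0))
})
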