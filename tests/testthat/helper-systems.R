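# shared fixtures: small pool systems, schedules and grids built in code

single_pool_system <- function(t1 = 1, t2 = 0.1, b0 = 3) {
  pool_system(pool("water", t1 = t1, t2 = t2), b0 = b0)
}

two_pool_system <- function(fs = 1.35e-3, ksw = 500, b0 = 7) {
  larg_pool_system(b0 = b0, fs = fs, ksw = ksw)
}

cw4 <- function(b1 = c(1, 2, 3, 4), ...) {
  cw_schedule(b1_uT = b1, offset_ppm = 3, t_sat_s = 3, t_rec_s = 1,
              flip_angle_deg = 60, ...)
}

tiny_grid <- function() {
  param_grid(fs_values = c(1e-3, 2e-3, 3e-3), ksw_values = c(300, 500, 700))
}

# single-pool off-resonance CW saturation steady state (closed form)
cw_steady_mz <- function(t1, t2, w1, dw) {
  (1 / t2^2 + dw^2) / (1 / t2^2 + dw^2 + w1^2 * t1 / t2)
}

# independent brute-force cosine matcher (plain loop, no shared code path)
brute_force_match <- function(e, dictionary) {
  best_score <- -Inf
  best <- NA_integer_
  for (r in seq_len(nrow(dictionary$signals))) {
    d <- dictionary$signals[r, ]
    sc <- sum(e * d) / sqrt(sum(e^2) * sum(d^2))
    if (sc > best_score) {
      best_score <- sc
      best <- r
    }
  }
  list(node = best, score = best_score)
}

# hand-assembled dictionary object with prescribed signals on a grid
fake_dictionary <- function(grid, signal_fun, n_images) {
  signals <- t(vapply(seq_len(nrow(grid$nodes)), function(i) {
    signal_fun(grid$nodes$fs[i], grid$nodes$ksw[i])
  }, numeric(n_images)))
  structure(list(
    grid = grid, signals = signals, norms = sqrt(rowSums(signals^2)),
    schedule = NULL, pools = NULL, solute = 1L
  ), class = "st_dictionary")
}
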