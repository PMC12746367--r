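#' Built-in protocol templates
#'
#' Bundles the timing, readout, bounds, default pool system and default
#' dictionary grid of the three imaging scenarios the pipeline targets:
#'
#' * `cw7t_larg` - preclinical 7T L-arginine phantom: CW rectangular
#'   saturation, Tsat = 3 s, Trec = 1 s, FA = 60 deg, offset fixed at 3 ppm,
#'   B1 in \[0, 6\] uT.
#' * `pw3t_larg` - clinical 3T L-arginine phantom: spin-lock train of
#'   13 x 100 ms at 50 % duty cycle, Trec = 1 s, FA = 12 deg, offset fixed at
#'   3 ppm, B1 in \[0, 4\] uT.
#' * `pw3t_mt` - clinical 3T semisolid MT brain imaging: same train timing,
#'   offsets free in \[10, 75\] ppm, B1 in \[0, 4\] uT.
#'
#' @param name Template name.
#' @param n_images Schedule length N (4, 8 and 30 in the source protocols;
#'   any N >= 1 works).
#' @param b1_uT Optional starting powers (defaults to mid-range).
#' @return List with `schedule` (an `st_schedule`), `bounds`, `pools`, `grid`
#'   and the template `name`.
#' @export
protocol_template <- function(name = c("cw7t_larg", "pw3t_larg", "pw3t_mt"),
                              n_images = 4, b1_uT = NULL) {
  name <- match.arg(name)
  if (n_images < 1) abort("n_images must be >= 1")
  spec <- switch(name,
    cw7t_larg = list(
      bounds = schedule_bounds(0, 6, offset_fixed = 3),
      pools = larg_pool_system(b0 = 7),
      grid = larg_grid(),
      make = function(b1) cw_schedule(b1, offset_ppm = 3, t_sat_s = 3,
                                      t_rec_s = 1, flip_angle_deg = 60)
    ),
    pw3t_larg = list(
      bounds = schedule_bounds(0, 4, offset_fixed = 3),
      pools = larg_pool_system(b0 = 3),
      grid = larg_grid(),
      make = function(b1) pulsed_schedule(b1, offset_ppm = 3, pulse_count = 13,
                                          pulse_duration_s = 0.1,
                                          duty_cycle = 0.5, t_rec_s = 1,
                                          flip_angle_deg = 12)
    ),
    pw3t_mt = list(
      bounds = schedule_bounds(0, 4, offset_min = 10, offset_max = 75,
                               optimize_offsets = TRUE),
      pools = mt_pool_system(b0 = 3),
      grid = mt_grid(),
      make = function(b1) pulsed_schedule(b1, offset_ppm = 42.5,
                                          pulse_count = 13,
                                          pulse_duration_s = 0.1,
                                          duty_cycle = 0.5, t_rec_s = 1,
                                          flip_angle_deg = 12)
    )
  )
  b1 <- b1_uT %||%
    rep((spec$bounds$b1_min + spec$bounds$b1_max) / 2, n_images)
  if (length(b1) != n_images) abort("b1_uT must have length n_images")
  list(name = name, schedule = spec$make(b1), bounds = spec$bounds,
       pools = spec$pools, grid = spec$grid)
}
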