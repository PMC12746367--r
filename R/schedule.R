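EVENT_COLS <- c("b1_uT", "offset_ppm", "t_sat_s", "pulse_count",
                "pulse_duration_s", "duty_cycle", "shape")

#' Define one saturation event
#'
#' An event is the saturation block preceding one raw MRF image: either a
#' continuous-wave (CW) rectangular pulse or a spin-lock pulse train. For a
#' train the timing convention is: each pulse of `pulse_duration_s` is
#' followed by a gap of `pulse_duration_s * (1 - duty_cycle) / duty_cycle`,
#' repeated `pulse_count` times, with the final gap included in the block, so
#' `t_sat_s = pulse_count * pulse_duration_s / duty_cycle`.
#'
#' @param b1_uT Saturation amplitude, microtesla (>= 0).
#' @param offset_ppm Saturation frequency offset, ppm.
#' @param t_sat_s Total saturation block duration, seconds. Defaults to the
#'   value implied by the train structure.
#' @param pulse_count Number of pulses (1 for CW).
#' @param pulse_duration_s Single-pulse duration, seconds (for CW defaults to
#'   `t_sat_s`).
#' @param duty_cycle RF-on fraction of the block, in (0, 1].
#' @param shape `"rect"` (CW) or `"spin_lock"`.
#' @return One-row tibble.
#' @export
sat_event <- function(b1_uT, offset_ppm, t_sat_s = NULL, pulse_count = 1L,
                      pulse_duration_s = NULL, duty_cycle = 1,
                      shape = c("rect", "spin_lock")) {
  shape <- match.arg(shape)
  if (!is.finite(b1_uT) || b1_uT < 0) abort("b1_uT must be >= 0")
  if (pulse_count < 1) abort("pulse_count must be >= 1")
  if (duty_cycle <= 0 || duty_cycle > 1) abort("duty_cycle must be in (0, 1]")
  if (is.null(pulse_duration_s)) {
    if (is.null(t_sat_s)) abort("give t_sat_s or pulse_duration_s")
    pulse_duration_s <- t_sat_s * duty_cycle / pulse_count
  }
  if (is.null(t_sat_s)) {
    t_sat_s <- pulse_count * pulse_duration_s / duty_cycle
  }
  if (pulse_count * pulse_duration_s / duty_cycle > t_sat_s + 1e-9)
    abort("pulse train does not fit into t_sat_s")
  tibble(
    b1_uT = b1_uT, offset_ppm = offset_ppm, t_sat_s = t_sat_s,
    pulse_count = as.integer(pulse_count),
    pulse_duration_s = pulse_duration_s, duty_cycle = duty_cycle,
    shape = shape
  )
}

#' Assemble an acquisition schedule
#'
#' An acquisition schedule is an ordered table of saturation events (one per
#' raw MRF image) plus the global readout parameters. The per-image power and
#' offset vectors B1\[n\], d-omega\[n\] are the columns `b1_uT`, `offset_ppm`.
#'
#' @param events Tibble of events ([sat_event()] rows bound together).
#' @param t_rec_s Recovery time after each readout, seconds (>= 0).
#' @param flip_angle_deg Readout excitation flip angle, degrees.
#' @param spoil_transverse Zero the transverse water magnetization after each
#'   readout (snapshot sequences crush residual transverse signal).
#' @return An `st_schedule` tibble (one row per image) with timing attributes.
#' @examples
#' cw_schedule(b1_uT = c(1, 2, 3, 4), offset_ppm = 3)
#' @export
acq_schedule <- function(events, t_rec_s = 1, flip_angle_deg = 60,
                         spoil_transverse = TRUE) {
  stopifnot(is.data.frame(events))
  missing <- setdiff(EVENT_COLS, names(events))
  if (length(missing) > 0)
    abort(paste("events table lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(events) < 1) abort("a schedule needs at least one event")
  if (t_rec_s < 0) abort("t_rec_s must be >= 0")
  structure(
    as_tibble(events[EVENT_COLS]),
    t_rec_s = t_rec_s,
    flip_angle_deg = flip_angle_deg,
    spoil_transverse = isTRUE(spoil_transverse),
    class = c("st_schedule", class(tibble()))
  )
}

#' @export
print.st_schedule <- function(x, ...) {
  cat(sprintf(
    "<st_schedule> %d image(s), t_rec = %g s, FA = %g deg, duration = %g s\n",
    nrow(x), attr(x, "t_rec_s"), attr(x, "flip_angle_deg"),
    schedule_duration(x)))
  NextMethod()
}

#' Convenience constructors for CW and pulsed protocols
#'
#' `cw_schedule()` builds a continuous-wave rectangular-saturation protocol
#' (one 3 s CW pulse, 1 s recovery and a 60 degree readout by default, as used
#' for preclinical L-arginine phantom imaging at 7T). `pulsed_schedule()`
#' builds a clinical spin-lock pulse-train protocol (13 x 100 ms pulses at
#' 50 % duty cycle, 1 s recovery, 12 degree readout by default).
#'
#' @param b1_uT Vector of per-image saturation powers, microtesla.
#' @param offset_ppm Per-image frequency offsets, ppm (recycled to length of
#'   `b1_uT`).
#' @param t_sat_s CW saturation time per image, seconds.
#' @param t_rec_s Recovery time, seconds.
#' @param flip_angle_deg Readout flip angle, degrees.
#' @param pulse_count,pulse_duration_s,duty_cycle Spin-lock train structure.
#' @param ... Passed to [acq_schedule()].
#' @return An `st_schedule`.
#' @export
cw_schedule <- function(b1_uT, offset_ppm = 3, t_sat_s = 3, t_rec_s = 1,
                        flip_angle_deg = 60, ...) {
  offset_ppm <- rep_len(offset_ppm, length(b1_uT))
  events <- purrr::map2(b1_uT, offset_ppm,
                        ~ sat_event(.x, .y, t_sat_s = t_sat_s, shape = "rect"))
  acq_schedule(dplyr::bind_rows(events), t_rec_s = t_rec_s,
               flip_angle_deg = flip_angle_deg, ...)
}

#' @rdname cw_schedule
#' @export
pulsed_schedule <- function(b1_uT, offset_ppm = 3, pulse_count = 13,
                            pulse_duration_s = 0.1, duty_cycle = 0.5,
                            t_rec_s = 1, flip_angle_deg = 12, ...) {
  offset_ppm <- rep_len(offset_ppm, length(b1_uT))
  events <- purrr::map2(
    b1_uT, offset_ppm,
    ~ sat_event(.x, .y, pulse_count = pulse_count,
                pulse_duration_s = pulse_duration_s,
                duty_cycle = duty_cycle, shape = "spin_lock"))
  acq_schedule(dplyr::bind_rows(events), t_rec_s = t_rec_s,
               flip_angle_deg = flip_angle_deg, ...)
}

t_rec_of <- function(schedule) attr(schedule, "t_rec_s")
flip_angle_of <- function(schedule) attr(schedule, "flip_angle_deg")
spoil_of <- function(schedule) attr(schedule, "spoil_transverse")

#' Total schedule duration
#'
#' Sum over images of saturation plus recovery time. The readout itself is
#' treated as instantaneous: for the CW phantom protocols this reproduces the
#' nominal 16 s (4 images) and 32 s (8 images) acquisition times exactly.
#'
#' @param schedule An `st_schedule` (an empty event table gives 0).
#' @return Duration in seconds.
#' @export
schedule_duration <- function(schedule) {
  if (nrow(schedule) == 0) return(0)
  sum(schedule$t_sat_s + t_rec_of(schedule))
}

#' Bounds of the schedule search space
#'
#' @param b1_min,b1_max Saturation power range, microtesla.
#' @param offset_min,offset_max Frequency-offset range, ppm (used only when
#'   `optimize_offsets` is `TRUE`).
#' @param offset_fixed Fixed offset in ppm (forces `optimize_offsets = FALSE`).
#' @param optimize_offsets Include the offsets in the optimization vector?
#' @return A `schedule_bounds` list.
#' @export
schedule_bounds <- function(b1_min = 0, b1_max = 4, offset_min = NULL,
                            offset_max = NULL, offset_fixed = NULL,
                            optimize_offsets = is.null(offset_fixed)) {
  if (b1_min < 0) abort("b1_min must be >= 0")
  if (b1_max <= b1_min) abort("b1_max must exceed b1_min")
  if (!is.null(offset_fixed) && optimize_offsets)
    abort("offset_fixed excludes optimize_offsets")
  if (optimize_offsets &&
      (is.null(offset_min) || is.null(offset_max) || offset_max <= offset_min))
    abort("optimize_offsets requires offset_min < offset_max")
  structure(list(
    b1_min = b1_min, b1_max = b1_max,
    offset_min = offset_min, offset_max = offset_max,
    offset_fixed = offset_fixed, optimize_offsets = optimize_offsets
  ), class = "schedule_bounds")
}

#' Map a schedule to the optimizer's flat parameter vector and back
#'
#' The optimization variable is the per-image power vector B1\[n\] (length N),
#' extended by the per-image offsets (length 2N) when the bounds declare the
#' offsets free. `unflatten_schedule()` is the exact inverse given the same
#' template schedule and bounds.
#'
#' @param schedule Template `st_schedule` (provides timing and fixed fields).
#' @param bounds A [schedule_bounds()].
#' @param x Flat parameter vector.
#' @return `flatten_schedule()`: numeric vector of length N or 2N;
#'   `unflatten_schedule()`: an `st_schedule`.
#' @export
flatten_schedule <- function(schedule, bounds) {
  x <- schedule$b1_uT
  if (bounds$optimize_offsets) x <- c(x, schedule$offset_ppm)
  x
}

#' @rdname flatten_schedule
#' @export
unflatten_schedule <- function(x, schedule, bounds) {
  n <- nrow(schedule)
  want <- if (bounds$optimize_offsets) 2L * n else n
  if (length(x) != want)
    abort(sprintf("parameter vector has length %d, expected %d",
                  length(x), want))
  schedule$b1_uT <- x[seq_len(n)]
  if (bounds$optimize_offsets) schedule$offset_ppm <- x[n + seq_len(n)]
  if (!is.null(bounds$offset_fixed)) schedule$offset_ppm <- bounds$offset_fixed
  schedule
}

#' Flat vector bounds matching [flatten_schedule()]
#' @inheritParams flatten_schedule
#' @return List with `lower` and `upper` numeric vectors.
#' @export
flat_bounds <- function(schedule, bounds) {
  n <- nrow(schedule)
  lower <- rep(bounds$b1_min, n)
  upper <- rep(bounds$b1_max, n)
  if (bounds$optimize_offsets) {
    lower <- c(lower, rep(bounds$offset_min, n))
    upper <- c(upper, rep(bounds$offset_max, n))
  }
  list(lower = lower, upper = upper)
}

#' Read and write schedules as YAML
#'
#' Serializes a schedule as a flat, versioned YAML document with one mapping
#' per event (`b1_uT`, `offset_ppm`, `t_sat_s`, `pulse_count`,
#' `pulse_duration_s`, `duty_cycle`, `shape`) plus the global timing fields.
#' Round-trips exactly on canonical form.
#'
#' @param schedule An `st_schedule`.
#' @param path File path.
#' @return `read_schedule_yaml()` returns an `st_schedule`;
#'   `write_schedule_yaml()` returns `path` invisibly.
#' @export
write_schedule_yaml <- function(schedule, path) {
  doc <- list(
    format = "stmrf-schedule",
    version = 1L,
    t_rec_s = t_rec_of(schedule),
    flip_angle_deg = flip_angle_of(schedule),
    spoil_transverse = spoil_of(schedule),
    events = purrr::pmap(schedule, function(...) list(...))
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$format, "stmrf-schedule"))
    abort("not an stmrf schedule file")
  events <- dplyr::bind_rows(lapply(doc$events, as_tibble))
  events$pulse_count <- as.integer(events$pulse_count)
  acq_schedule(events, t_rec_s = doc$t_rec_s,
               flip_angle_deg = doc$flip_angle_deg,
               spoil_transverse = doc$spoil_transverse)
}
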