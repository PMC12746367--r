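#' Optimizer configuration
#'
#' @param n_hops Number of basin-hopping perturbations after the initial local
#'   minimization (0 gives a pure local search).
#' @param hop_stepsize Perturbation half-width as a fraction of each bound
#'   range.
#' @param temperature Metropolis acceptance scale, loss units.
#' @param sqp_max_iter Iteration cap of the local minimizer.
#' @param sqp_ftol Loss-change convergence tolerance of the local minimizer.
#' @param seed RNG seed; a fixed seed makes the whole run reproducible.
#' @param n_restarts Independent repetitions in [optimize_schedule_restarts()].
#' @param retries Fresh perturbations attempted when the objective errors.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(n_hops = 20, hop_stepsize = 0.25,
                             temperature = 1.0, sqp_max_iter = 100,
                             sqp_ftol = 1e-6, seed = NULL, n_restarts = 4,
                             retries = 3) {
  stopifnot(n_hops >= 0, hop_stepsize > 0, temperature > 0,
            sqp_max_iter >= 1, sqp_ftol > 0, n_restarts >= 1)
  structure(list(
    n_hops = as.integer(n_hops), hop_stepsize = hop_stepsize,
    temperature = temperature, sqp_max_iter = as.integer(sqp_max_iter),
    sqp_ftol = sqp_ftol, seed = seed, n_restarts = as.integer(n_restarts),
    retries = as.integer(retries)
  ), class = "optimizer_config")
}

#' Randomly initialized acquisition schedule
#'
#' Draws per-image powers uniformly within the B1 bounds and, when the bounds
#' leave the offsets free, offsets uniformly within the offset range; the
#' timing (CW or pulse-train structure, recovery, flip angle) comes from the
#' template schedule.
#'
#' @param template An `st_schedule` providing the timing.
#' @param bounds A [schedule_bounds()].
#' @param seed Optional RNG seed.
#' @return An `st_schedule` with randomized saturation parameters.
#' @export
random_initial_schedule <- function(template, bounds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(template)
  template$b1_uT <- runif(n, bounds$b1_min, bounds$b1_max)
  if (bounds$optimize_offsets) {
    template$offset_ppm <- runif(n, bounds$offset_min, bounds$offset_max)
  } else if (!is.null(bounds$offset_fixed)) {
    template$offset_ppm <- bounds$offset_fixed
  }
  template
}

# forward finite-difference gradient on the scaled objective
fd_gradient <- function(fn, x, f0, h = 1e-8) {
  vapply(seq_along(x), function(i) {
    xi <- x
    xi[i] <- xi[i] + h
    (fn(xi) - f0) / h
  }, numeric(1))
}

#' Bound-constrained local minimization
#'
#' Gradient-based local search used as the inner step of the basin-hopping
#' optimizer: parameters are scaled to the unit box for conditioning and
#' minimized with a bound-constrained quasi-Newton method, with gradients
#' obtained by forward finite differences on the objective.
#'
#' @param fn Objective taking a numeric vector.
#' @param x0 Start point (must give a finite objective).
#' @param lower,upper Bounds.
#' @param max_iter Iteration cap.
#' @param ftol Relative loss-change tolerance.
#' @param fd_step Forward-difference step on the unit-scaled parameters.
#' @return List with `par`, `value`, `iterations`, `convergence`.
#' @export
sqp_minimize <- function(fn, x0, lower, upper, max_iter = 100, ftol = 1e-6,
                         fd_step = 1e-8) {
  stopifnot(length(x0) == length(lower), length(lower) == length(upper))
  range <- upper - lower
  if (any(range <= 0)) abort("upper bounds must exceed lower bounds")
  to_unit <- function(x) (x - lower) / range
  from_unit <- function(u) lower + u * range
  last <- new.env(parent = emptyenv()) # reuse f(u) between fn and gr calls
  fn_unit <- function(u) {
    v <- fn(from_unit(u))
    if (!is.finite(v))
      abort(sprintf("objective non-finite at x = (%s)",
                    paste(signif(from_unit(u), 6), collapse = ", ")))
    last$u <- u
    last$f <- v
    v
  }
  gr_unit <- function(u) {
    f0 <- if (!is.null(last$u) && identical(last$u, u)) last$f else fn_unit(u)
    fd_gradient(fn_unit, u, f0, h = fd_step)
  }
  res <- optim(
    par = pmin(pmax(to_unit(x0), 0), 1),
    fn = fn_unit, gr = gr_unit,
    method = "L-BFGS-B", lower = 0, upper = 1,
    control = list(maxit = max_iter,
                   factr = ftol / .Machine$double.eps)
  )
  list(par = from_unit(res$par), value = res$value,
       iterations = res$counts[["function"]], convergence = res$convergence)
}

#' Basin-hopping global search
#'
#' Local minimization from the start point, followed by `n_hops` rounds of a
#' random uniform perturbation (clipped to the bounds), local minimization and
#' Metropolis acceptance at the configured temperature. The best point ever
#' evaluated is returned; it is never worse than the start.
#'
#' @param fn Objective.
#' @param x0 Start point.
#' @param lower,upper Bounds.
#' @param config An [optimizer_config()].
#' @return An `st_opt_trace`: list with the per-iteration `trace` tibble
#'   (`iteration`, `loss`, `accepted`, list-column `par`), `best_par`,
#'   `best_loss`, `x0`, `initial_loss`.
#' @export
basin_hopping <- function(fn, x0, lower, upper, config = optimizer_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  range <- upper - lower
  f0 <- fn(x0)
  if (!is.finite(f0)) abort("objective non-finite at the start point")

  run_local <- function(x) {
    sqp_minimize(fn, x, lower, upper,
                 max_iter = config$sqp_max_iter, ftol = config$sqp_ftol)
  }
  rows <- list()
  note <- function(it, loss, par, accepted) {
    rows[[length(rows) + 1L]] <<- tibble(
      iteration = it, loss = loss, accepted = accepted, par = list(par))
  }

  loc <- run_local(x0)
  best_par <- if (loc$value <= f0) loc$par else x0
  best_loss <- min(loc$value, f0)
  cur_par <- best_par
  cur_loss <- best_loss
  note(0L, loc$value, loc$par, TRUE)

  for (hop in seq_len(config$n_hops)) {
    cand <- NULL
    for (try in seq_len(config$retries + 1L)) {
      x_try <- pmin(pmax(
        cur_par + runif(length(x0), -1, 1) * config$hop_stepsize * range,
        lower), upper)
      cand <- tryCatch(run_local(x_try), error = function(e) e)
      if (!inherits(cand, "error")) break
    }
    if (inherits(cand, "error")) {
      abort(paste("objective kept failing during basin hopping:",
                  conditionMessage(cand)))
    }
    accept <- cand$value <= cur_loss ||
      runif(1) < exp(-(cand$value - cur_loss) / config$temperature)
    if (accept) {
      cur_par <- cand$par
      cur_loss <- cand$value
    }
    if (cand$value < best_loss) {
      best_loss <- cand$value
      best_par <- cand$par
    }
    note(hop, cand$value, cand$par, accept)
  }

  structure(list(
    trace = dplyr::bind_rows(rows),
    best_par = best_par, best_loss = best_loss,
    x0 = x0, initial_loss = f0
  ), class = "st_opt_trace")
}

#' Optimize an acquisition schedule against the CRB loss
#'
#' The full design loop: a candidate flat parameter vector is unflattened into
#' a schedule, a fresh dictionary is generated for it (the de novo
#' regeneration is what makes the objective exact rather than interpolated),
#' and the aggregate normalized-CRB trace is returned as the loss. The search
#' runs basin-hopping around the bound-constrained local minimizer. The
#' deterministic isochromat ensemble keeps the objective smooth for the
#' finite-difference gradients.
#'
#' @param pools A [pool_system()] with the fixed tissue parameters.
#' @param grid The [param_grid()] the CRB is aggregated over.
#' @param schedule Template / initial `st_schedule`. Its saturation parameters
#'   are the start point.
#' @param bounds A [schedule_bounds()].
#' @param ensemble Optional isochromat ensemble.
#' @param crb A [crb_config()].
#' @param config An [optimizer_config()].
#' @param solute Solute pool receiving the grid (fs, ksw).
#' @details Candidate schedules whose Fisher matrix is unidentifiable at some
#'   grid node (e.g. all-zero powers) receive a large finite penalty loss
#'   instead of erroring, so the search is simply driven away from them.
#' @return An `st_optim`: the optimization trace plus `initial_schedule`,
#'   `best_schedule`, `initial_loss`, `best_loss`.
#' @export
optimize_schedule <- function(pools, grid, schedule, bounds, ensemble = NULL,
                              crb = crb_config(), config = optimizer_config(),
                              solute = 1L) {
  penalty <- 1e250
  objective <- function(x) {
    sch <- unflatten_schedule(x, schedule, bounds)
    d <- generate_dictionary(pools, grid, sch, ensemble, solute = solute)
    tryCatch(crb_loss(d, crb)$loss, error = function(e) {
      if (grepl("unidentifiable", conditionMessage(e))) penalty else stop(e)
    })
  }
  fb <- flat_bounds(schedule, bounds)
  x0 <- flatten_schedule(schedule, bounds)
  hop <- basin_hopping(objective, x0, fb$lower, fb$upper, config)
  structure(list(
    trace = hop$trace,
    initial_schedule = schedule,
    best_schedule = unflatten_schedule(hop$best_par, schedule, bounds),
    initial_loss = hop$initial_loss,
    best_loss = hop$best_loss,
    bounds = bounds, config = config
  ), class = "st_optim")
}

#' Repeated independently seeded schedule optimizations
#'
#' Mirrors the practice of repeating the optimization from several random
#' initializations and keeping every outcome for consistency assessment.
#'
#' @inheritParams optimize_schedule
#' @param template Timing template passed to [random_initial_schedule()].
#' @param seeds Integer seeds, one per restart (default `1:n_restarts`).
#' @return Tibble with one row per restart: `seed`, `initial_loss`,
#'   `best_loss`, list-columns `initial_schedule`, `best_schedule`.
#' @export
optimize_schedule_restarts <- function(pools, grid, template, bounds,
                                       ensemble = NULL, crb = crb_config(),
                                       config = optimizer_config(),
                                       seeds = NULL, solute = 1L) {
  seeds <- seeds %||% seq_len(config$n_restarts)
  purrr::map_dfr(seeds, function(s) {
    sch0 <- random_initial_schedule(template, bounds, seed = s)
    cfg <- config
    cfg$seed <- s + 10000L
    opt <- optimize_schedule(pools, grid, sch0, bounds, ensemble, crb, cfg,
                             solute = solute)
    tibble(
      seed = s, initial_loss = opt$initial_loss, best_loss = opt$best_loss,
      initial_schedule = list(opt$initial_schedule),
      best_schedule = list(opt$best_schedule)
    )
  })
}

#' @export
print.st_optim <- function(x, ...) {
  cat(sprintf("<st_optim> loss %g -> %g over %d candidate(s)\n",
              x$initial_loss, x$best_loss, nrow(x$trace)))
  invisible(x)
}

#' @export
tidy.st_optim <- function(x, ...) x$trace

#' @export
glance.st_optim <- function(x, ...) {
  tibble(
    initial_loss = x$initial_loss,
    best_loss = x$best_loss,
    improvement = x$initial_loss - x$best_loss,
    n_candidates = nrow(x$trace)
  )
}
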