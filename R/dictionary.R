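#' Parameter grid over (fs, ksw)
#'
#' The dictionary axes: solute proton volume fraction `fs` (dimensionless) and
#' solute-to-water exchange rate `ksw` (s^-1). Node order is row-major with
#' `fs` as the outer axis and `ksw` as the inner axis, fixed so that
#' dictionaries are portable.
#'
#' @param fs_values Strictly increasing fs values (>= 3 for central
#'   differences).
#' @param ksw_values Strictly increasing ksw values (>= 3).
#' @return A `param_grid` with a `nodes` tibble (`node`, `i_fs`, `i_ksw`,
#'   `fs`, `ksw`) and recorded axis spacing type.
#' @export
param_grid <- function(fs_values, ksw_values) {
  check_axis <- function(v, name) {
    if (length(v) < 3) abort(paste(name, "needs at least 3 values"))
    if (any(diff(v) <= 0)) abort(paste(name, "must be strictly increasing"))
  }
  check_axis(fs_values, "fs_values")
  check_axis(ksw_values, "ksw_values")
  spacing <- function(v) {
    if (isTRUE(all.equal(diff(v), rep(diff(v)[1], length(v) - 1))))
      "uniform"
    else if (all(v > 0) &&
             isTRUE(all.equal(diff(log(v)), rep(diff(log(v))[1], length(v) - 1))))
      "log-uniform"
    else "irregular"
  }
  nodes <- tidyr::expand_grid(
    i_fs = seq_along(fs_values),
    i_ksw = seq_along(ksw_values)
  )
  nodes$node <- seq_len(nrow(nodes))
  nodes$fs <- fs_values[nodes$i_fs]
  nodes$ksw <- ksw_values[nodes$i_ksw]
  structure(list(
    fs_values = fs_values, ksw_values = ksw_values,
    fs_spacing = spacing(fs_values), ksw_spacing = spacing(ksw_values),
    nodes = nodes[c("node", "i_fs", "i_ksw", "fs", "ksw")]
  ), class = "param_grid")
}

#' Default grids for the built-in imaging scenarios
#'
#' The phantom grid spans fs equivalent to 10-250 mM of a 3-labile-proton
#' solute (`fs = 3 conc / 111e3 mM`) and ksw 100-1200 s^-1; the semisolid MT
#' grid spans fss 0.02-0.30 and kssw 5-100 s^-1.
#'
#' @param n_fs,n_ksw Number of grid values per axis.
#' @return A [param_grid()].
#' @export
larg_grid <- function(n_fs = 11, n_ksw = 11) {
  param_grid(
    fs_values = 3 * seq(10, 250, length.out = n_fs) / 111e3,
    ksw_values = seq(100, 1200, length.out = n_ksw)
  )
}

#' @rdname larg_grid
#' @export
mt_grid <- function(n_fs = 11, n_ksw = 11) {
  param_grid(
    fs_values = seq(0.02, 0.30, length.out = n_fs),
    ksw_values = seq(5, 100, length.out = n_ksw)
  )
}

#' Generate the synthetic-signal dictionary
#'
#' Simulates one trajectory per (fs, ksw) grid node by substituting the node
#' parameters into the designated solute pool and running
#' [simulate_schedule()]. Regeneration with identical inputs is bit-exact, and
#' results do not depend on the worker count.
#'
#' @param pools A [pool_system()] providing all fixed tissue parameters.
#' @param grid A [param_grid()].
#' @param schedule An `st_schedule`.
#' @param ensemble Optional isochromat ensemble (see [simulate_schedule()]).
#' @param solute Which solute pool receives the node (fs, ksw); default the
#'   first non-water pool.
#' @param cores Parallel workers (forked; result identical for any count).
#' @return An `st_dictionary`: list with the `grid`, the `signals` matrix
#'   (nodes x N, row-major node order), per-row L2 `norms`, and references to
#'   schedule/pools.
#' @export
generate_dictionary <- function(pools, grid, schedule, ensemble = NULL,
                                solute = 1L, cores = 1L) {
  sim_node <- function(node) {
    p <- set_solute_params(pools, grid$nodes$fs[node], grid$nodes$ksw[node],
                           solute)
    tryCatch(
      simulate_schedule(p, schedule, ensemble)$signal,
      error = function(e) abort(sprintf(
        "simulation failed at node %d (fs = %g, ksw = %g): %s",
        node, grid$nodes$fs[node], grid$nodes$ksw[node], conditionMessage(e)))
    )
  }
  nodes <- grid$nodes$node
  rows <- if (cores > 1L) {
    parallel::mclapply(nodes, sim_node, mc.cores = cores)
  } else {
    lapply(nodes, sim_node)
  }
  signals <- do.call(rbind, rows)
  norms <- sqrt(rowSums(signals^2))
  if (any(norms <= 0)) abort("dictionary contains an all-zero trajectory")
  structure(list(
    grid = grid, signals = signals, norms = norms,
    schedule = schedule, pools = pools, solute = solute
  ), class = "st_dictionary")
}

#' @export
print.st_dictionary <- function(x, ...) {
  cat(sprintf("<st_dictionary> %d nodes (%d fs x %d ksw), %d images\n",
              nrow(x$signals), length(x$grid$fs_values),
              length(x$grid$ksw_values), ncol(x$signals)))
  invisible(x)
}

#' @export
tidy.st_dictionary <- function(x, ...) {
  sig <- as_tibble(x$signals, .name_repair = ~ paste0("s", seq_along(.x)))
  dplyr::bind_cols(x$grid$nodes, sig)
}

#' Grid neighbors of a dictionary node
#'
#' Returns the +/- 1 neighbors along each parameter axis, flagging boundary
#' (one-sided) axes; used for the finite-difference Jacobian.
#'
#' @param grid A [param_grid()].
#' @param node Node index (row-major).
#' @return Tibble with one row per axis: `axis`, `lower`, `upper` (node
#'   indices, `NA` at the grid edge) and `one_sided`.
#' @export
node_neighbors <- function(grid, node) {
  n_ksw <- length(grid$ksw_values)
  n_fs <- length(grid$fs_values)
  if (node < 1 || node > n_fs * n_ksw) abort("node index out of range")
  i_fs <- grid$nodes$i_fs[node]
  i_ksw <- grid$nodes$i_ksw[node]
  to_node <- function(i, j) (i - 1L) * n_ksw + j
  fs_lo <- if (i_fs > 1) to_node(i_fs - 1L, i_ksw) else NA_integer_
  fs_hi <- if (i_fs < n_fs) to_node(i_fs + 1L, i_ksw) else NA_integer_
  k_lo <- if (i_ksw > 1) to_node(i_fs, i_ksw - 1L) else NA_integer_
  k_hi <- if (i_ksw < n_ksw) to_node(i_fs, i_ksw + 1L) else NA_integer_
  tibble(
    axis = c("fs", "ksw"),
    lower = c(fs_lo, k_lo),
    upper = c(fs_hi, k_hi),
    one_sided = c(is.na(fs_lo) || is.na(fs_hi), is.na(k_lo) || is.na(k_hi))
  )
}

#' Write a dictionary to CSV (+ JSON sidecar of fixed parameters)
#' @param dictionary An `st_dictionary`.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_dictionary_csv <- function(dictionary, path) {
  write.csv(as.data.frame(tidy(dictionary)), path, row.names = FALSE)
  side <- list(
    pools = as.data.frame(dictionary$pools),
    b0 = b0_of(dictionary$pools),
    schedule = as.data.frame(dictionary$schedule),
    t_rec_s = t_rec_of(dictionary$schedule),
    flip_angle_deg = flip_angle_of(dictionary$schedule)
  )
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
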