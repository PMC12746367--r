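#' Configuration of the Cramer-Rao bound objective
#'
#' @param sigma Noise standard deviation of the Gaussian signal model, signal
#'   units. The argmin of the schedule loss is invariant to `sigma` (it only
#'   rescales the loss), so the default 1 is a pure convention.
#' @param weights Per-parameter weights applied to the normalized CRB
#'   diagonal; equal by default.
#' @param normalization `"theta_squared"` (default) divides diagonal element i
#'   of the inverse Fisher matrix by `theta_i^2`, giving a dimensionless
#'   relative variance that makes fs (~1e-3) and ksw (~1e3 s^-1) commensurate;
#'   `"theta"` divides by `theta_i`.
#' @param aggregation How node losses combine into the scalar loss:
#'   `"mean"` (grid-size invariant, default), `"sum"` or `"max"`.
#' @param include_boundary Include one-sided boundary nodes in the aggregate?
#' @param cond_cap Condition-number cap above which a node's Fisher matrix is
#'   declared unidentifiable.
#' @return A `crb_config` list.
#' @export
crb_config <- function(sigma = 1, weights = c(1, 1),
                       normalization = c("theta_squared", "theta"),
                       aggregation = c("mean", "sum", "max"),
                       include_boundary = FALSE, cond_cap = 1e12) {
  if (sigma <= 0) abort("sigma must be positive")
  if (any(weights <= 0)) abort("weights must be positive")
  structure(list(
    sigma = sigma, weights = weights,
    normalization = match.arg(normalization),
    aggregation = match.arg(aggregation),
    include_boundary = include_boundary, cond_cap = cond_cap
  ), class = "crb_config")
}

#' Finite-difference signal Jacobian at a dictionary node
#'
#' Two-point derivative of the trajectory with respect to theta = (fs, ksw) on
#' the dictionary grid: central differences at interior nodes (step = the grid
#' spacing around the node), one-sided differences at boundary nodes.
#'
#' @param dictionary An `st_dictionary`.
#' @param node Node index.
#' @return N x 2 matrix (columns fs, ksw) with attributes `steps` (the
#'   differencing steps used) and `one_sided`.
#' @export
finite_diff_jacobian <- function(dictionary, node) {
  grid <- dictionary$grid
  nb <- node_neighbors(grid, node)
  sig <- dictionary$signals
  theta_vals <- list(fs = grid$fs_values, ksw = grid$ksw_values)
  theta_idx <- c(grid$nodes$i_fs[node], grid$nodes$i_ksw[node])
  J <- matrix(NA_real_, ncol(sig), 2)
  steps <- numeric(2)
  colnames(J) <- c("fs", "ksw")
  for (a in 1:2) {
    vals <- theta_vals[[a]]
    if (length(vals) < 2) abort("degenerate parameter axis")
    lo <- nb$lower[a]; hi <- nb$upper[a]
    i <- theta_idx[a]
    if (!is.na(lo) && !is.na(hi)) {
      h <- vals[i + 1] - vals[i - 1]
      J[, a] <- (sig[hi, ] - sig[lo, ]) / h
      steps[a] <- h / 2
    } else if (is.na(lo)) {
      h <- vals[i + 1] - vals[i]
      J[, a] <- (sig[hi, ] - sig[node, ]) / h
      steps[a] <- h
    } else {
      h <- vals[i] - vals[i - 1]
      J[, a] <- (sig[node, ] - sig[lo, ]) / h
      steps[a] <- h
    }
  }
  attr(J, "steps") <- steps
  attr(J, "one_sided") <- nb$one_sided
  J
}

#' Fisher information of a Gaussian trajectory model
#'
#' For i.i.d. Gaussian noise of standard deviation `sigma` on the trajectory,
#' `I = (1/sigma^2) J^T J`, symmetric positive semidefinite by construction.
#'
#' @param jacobian N x p signal Jacobian.
#' @param sigma Noise standard deviation.
#' @return p x p Fisher information matrix.
#' @export
fisher_information <- function(jacobian, sigma = 1) {
  jacobian <- as.matrix(jacobian)
  if (any(!is.finite(jacobian))) abort("jacobian must be finite")
  crossprod(jacobian) / sigma^2
}

#' Normalized Cramer-Rao bound
#'
#' Inverts the Fisher matrix and normalizes diagonal element i by `theta_i`
#' (the literal reading of nCRB = I^-1 / theta) or by `theta_i^2`
#' (dimensionless relative variance, the default), then applies the
#' per-parameter weights multiplicatively to the diagonal.
#'
#' @param fisher p x p Fisher information matrix.
#' @param theta Parameter values at the node.
#' @param config A [crb_config()].
#' @return The normalized CRB matrix.
#' @export
normalized_crb <- function(fisher, theta, config = crb_config()) {
  p <- length(theta)
  stopifnot(nrow(fisher) == p)
  # conditioning is judged on the dimensionless theta-scaled matrix: the raw
  # Fisher matrix mixes fs (~1e-3) and ksw (~1e3 s^-1) units and its condition
  # number reflects scale, not identifiability
  scaled <- fisher * outer(theta, theta)
  if (!all(is.finite(scaled)) || kappa(scaled, exact = TRUE) > config$cond_cap)
    abort(sprintf(
      "unidentifiable at node: Fisher matrix singular for theta = (%s)",
      paste(signif(theta, 6), collapse = ", ")))
  inv_scaled <- solve(scaled)
  ncrb <- inv_scaled * outer(theta, theta) # = solve(fisher)
  pow <- if (config$normalization == "theta") 1 else 2
  for (i in seq_len(p)) {
    ncrb[i, i] <- config$weights[i] * ncrb[i, i] / theta[i]^pow
  }
  ncrb
}

#' Cramer-Rao bound loss of a dictionary
#'
#' Per node: finite-difference Jacobian, Fisher information, normalized CRB
#' and its trace; the scalar loss aggregates the node traces (mean over
#' interior nodes by default). This is the objective the schedule optimizer
#' minimizes.
#'
#' @param dictionary An `st_dictionary` (>= 3 values per grid axis).
#' @param config A [crb_config()].
#' @return A `crb_result`: list with `node_results` tibble (`node`, `fs`,
#'   `ksw`, `interior`, `included`, `loss`, list-columns `fisher` and `ncrb`),
#'   the aggregate `loss`, and the `config`.
#' @export
crb_loss <- function(dictionary, config = crb_config()) {
  grid <- dictionary$grid
  nodes <- grid$nodes
  interior <- nodes$i_fs > 1 & nodes$i_fs < length(grid$fs_values) &
    nodes$i_ksw > 1 & nodes$i_ksw < length(grid$ksw_values)
  included <- if (config$include_boundary) rep(TRUE, nrow(nodes)) else interior
  if (!any(included)) abort("no grid nodes available for aggregation")

  fishers <- vector("list", nrow(nodes))
  ncrbs <- vector("list", nrow(nodes))
  losses <- rep(NA_real_, nrow(nodes))
  for (n in nodes$node[included]) {
    J <- finite_diff_jacobian(dictionary, n)
    I_n <- fisher_information(J, config$sigma)
    ncrb <- normalized_crb(I_n, c(nodes$fs[n], nodes$ksw[n]), config)
    fishers[[n]] <- I_n
    ncrbs[[n]] <- ncrb
    losses[n] <- sum(diag(ncrb))
  }
  loss <- switch(config$aggregation,
    mean = mean(losses[included]),
    sum = sum(losses[included]),
    max = max(losses[included])
  )
  if (!is.finite(loss)) abort("CRB loss is not finite")
  structure(list(
    node_results = tibble(
      node = nodes$node, fs = nodes$fs, ksw = nodes$ksw,
      interior = interior, included = included, loss = losses,
      fisher = fishers, ncrb = ncrbs
    ),
    loss = loss, config = config
  ), class = "crb_result")
}

#' @export
print.crb_result <- function(x, ...) {
  cat(sprintf("<crb_result> loss = %g (%s over %d node(s))\n",
              x$loss, x$config$aggregation, sum(x$node_results$included)))
  invisible(x)
}

#' @export
tidy.crb_result <- function(x, ...) {
  dplyr::select(x$node_results, "node", "fs", "ksw", "interior",
                "included", "loss")
}

#' @export
glance.crb_result <- function(x, ...) {
  tibble(
    loss = x$loss,
    n_included = sum(x$node_results$included),
    sigma = x$config$sigma,
    normalization = x$config$normalization,
    aggregation = x$config$aggregation
  )
}

#' Export per-node CRB losses as JSON
#' @param result A `crb_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crb_json <- function(result, path) {
  jsonlite::write_json(
    list(loss = result$loss, nodes = tidy(result)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Finite-difference convergence check of the CRB loss
#'
#' Recomputes the loss on dictionaries regenerated at 1/2 and 1/4 of the grid
#' spacing around the same parameter ranges, reporting how the aggregate loss
#' moves as the differencing step shrinks.
#'
#' @param pools,schedule,ensemble Passed to [generate_dictionary()].
#' @param grid The reference [param_grid()].
#' @param config A [crb_config()].
#' @return Tibble with `spacing_factor` and `loss`.
#' @export
crb_step_check <- function(pools, grid, schedule, ensemble = NULL,
                           config = crb_config()) {
  refine <- function(v, f) {
    seq(min(v), max(v), by = (v[2] - v[1]) * f)
  }
  purrr::map_dfr(c(1, 0.5, 0.25), function(f) {
    g <- param_grid(refine(grid$fs_values, f), refine(grid$ksw_values, f))
    d <- generate_dictionary(pools, g, schedule, ensemble)
    tibble(spacing_factor = f, loss = crb_loss(d, config)$loss)
  })
}
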