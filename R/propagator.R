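# State layout: full Bloch-McConnell pools contribute (Mx, My, Mz) triples in
# pool order (water first); rate-model semisolid pools contribute a single Mz
# component each, appended after all triples. Water M0 is normalized to 1 and
# every other pool's equilibrium Mz is its volume fraction f.

state_layout <- function(pools) {
  full <- pools$lineshape == "full_bm_lorentzian"
  n_full <- sum(full)
  idx <- integer(nrow(pools)) # index of the pool's Mz component
  trip <- 0L
  rate_pos <- 3L * n_full
  for (p in seq_len(nrow(pools))) {
    if (full[p]) {
      idx[p] <- 3L * trip + 3L
      trip <- trip + 1L
    } else {
      rate_pos <- rate_pos + 1L
      idx[p] <- rate_pos
    }
  }
  list(full = full, n_full = n_full, dim = 3L * n_full + sum(!full),
       mz_index = idx)
}

#' Thermal-equilibrium magnetization state
#'
#' @param pools A [pool_system()].
#' @return Numeric state vector: transverse components zero, each pool's Mz at
#'   its volume fraction (water = 1).
#' @export
equilibrium_state <- function(pools) {
  lay <- state_layout(pools)
  M <- numeric(lay$dim)
  M[lay$mz_index] <- pools$f
  M
}

#' Build the Bloch-McConnell evolution matrix for one RF segment
#'
#' Constructs the pieces of the piecewise-constant evolution
#' `dM/dt = A M + C`: relaxation (1/T1, 1/T2), inter-pool exchange with
#' detailed-balance back-rates (`k` solute to water, `f k` water to solute),
#' off-resonance precession at `(offset - delta_pool)` plus the isochromat
#' shift `db0`, and RF nutation at `w1 = gamma b1`. Rate-model semisolid
#' pools carry no transverse components; their Mz row instead contains the
#' saturation rate `W = pi w1^2 g(offset - delta)` with a super-Lorentzian
#' lineshape.
#'
#' @param pools A [pool_system()].
#' @param b1_uT RF amplitude, microtesla.
#' @param offset_ppm RF frequency offset, ppm.
#' @param db0 Additional B0 shift of this isochromat, rad s^-1.
#' @return List with `A` (s^-1), `C` (s^-1) and the state layout.
#' @export
build_propagator <- function(pools, b1_uT, offset_ppm, db0 = 0) {
  if (any(pools$t1 <= 0) || any(pools$t2 <= 0))
    abort("relaxation times must be positive")
  lay <- state_layout(pools)
  b0 <- b0_of(pools)
  gamma <- gamma_of(pools)
  w1 <- b1_to_rads(b1_uT, gamma)
  A <- matrix(0, lay$dim, lay$dim)
  C <- numeric(lay$dim)

  trip <- 0L
  for (p in seq_len(nrow(pools))) {
    t1 <- pools$t1[p]; t2 <- pools$t2[p]; f <- pools$f[p]
    dw <- ppm_to_rads(offset_ppm - pools$delta[p], b0, gamma) + db0
    if (lay$full[p]) {
      ix <- 3L * trip + 1L; iy <- ix + 1L; iz <- ix + 2L
      trip <- trip + 1L
      A[ix, ix] <- A[ix, ix] - 1 / t2
      A[iy, iy] <- A[iy, iy] - 1 / t2
      A[iz, iz] <- A[iz, iz] - 1 / t1
      A[ix, iy] <- A[ix, iy] + dw
      A[iy, ix] <- A[iy, ix] - dw
      A[iy, iz] <- A[iy, iz] + w1
      A[iz, iy] <- A[iz, iy] - w1
      C[iz] <- f / t1
    } else {
      iz <- lay$mz_index[p]
      W <- pi * w1^2 * lineshape_g("superlorentzian", t2, dw)
      A[iz, iz] <- A[iz, iz] - 1 / t1 - W
      C[iz] <- f / t1
    }
  }

  # exchange with water (pool 1); component-wise for full-BM pools, Mz-only
  # for rate pools
  for (p in seq_len(nrow(pools))[-1]) {
    k <- pools$k[p]; f <- pools$f[p]
    if (k == 0) next
    comps <- if (lay$full[p]) 0:2 else 2L
    for (c in comps) {
      iw <- 1L + c
      is <- lay$mz_index[p] - (2L - c) * as.integer(lay$full[p])
      if (!lay$full[p]) is <- lay$mz_index[p]
      A[iw, iw] <- A[iw, iw] - f * k
      A[iw, is] <- A[iw, is] + k
      A[is, is] <- A[is, is] - k
      A[is, iw] <- A[is, iw] + f * k
    }
  }

  structure(list(A = A, C = C, layout = lay), class = "bm_propagator")
}

#' Propagate the magnetization over one constant-RF interval
#'
#' Exact one-step solution of `dM/dt = A M + C` over `dt`:
#' `M(t + dt) = expm(A dt) (M + A^-1 C) - A^-1 C`. The fixed point is
#' `-A^-1 C`.
#'
#' @param state Magnetization state vector.
#' @param pieces A [build_propagator()] result.
#' @param dt Interval length, seconds.
#' @return The propagated state vector.
#' @export
propagate_interval <- function(state, pieces, dt) {
  if (length(state) != nrow(pieces$A))
    abort("state length does not match the evolution matrix")
  if (dt < 0) abort("dt must be >= 0")
  if (dt == 0) return(state)
  as.numeric(bm_step_cpp(state, pieces$A, pieces$C, dt))
}
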