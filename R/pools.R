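LINESHAPES <- c("full_bm_lorentzian", "superlorentzian_rate")

#' Define a proton pool
#'
#' A pool is one exchanging proton environment: free water, a mobile solute
#' (e.g. the L-arginine guanidinium protons at 3 ppm) or the semisolid
#' macromolecular pool. Solute pools are characterized by their volume
#' fraction `f` (proton fraction relative to water) and exchange rate `k`
#' toward water; these two numbers, (fs, ksw), are the quantification targets
#' of the whole pipeline.
#'
#' @param name Pool label.
#' @param t1,t2 Longitudinal / transverse relaxation times, seconds.
#' @param f Volume fraction relative to water. Water has `f = 1`.
#' @param k Exchange rate toward water, s^-1. Must be 0 for water.
#' @param delta Chemical shift relative to water, ppm.
#' @param lineshape `"full_bm_lorentzian"` simulates the pool with full
#'   transverse dynamics (its absorption profile is then intrinsically
#'   Lorentzian); `"superlorentzian_rate"` models a semisolid pool by its
#'   longitudinal component only, saturated at the rate
#'   `W = pi * w1^2 * g(delta)` with a super-Lorentzian absorption lineshape.
#' @return One-row tibble describing the pool.
#' @seealso [pool_system()]
#' @export
pool <- function(name, t1, t2, f = 1, k = 0, delta = 0,
                 lineshape = "full_bm_lorentzian") {
  lineshape <- match.arg(lineshape, LINESHAPES)
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(t1) || t1 <= 0) abort("t1 must be a positive time in seconds")
  if (!is.finite(t2) || t2 <= 0) abort("t2 must be a positive time in seconds")
  if (!is.finite(f) || f <= 0 || f > 1) abort("f must lie in (0, 1]")
  if (!is.finite(k) || k < 0) abort("k must be a non-negative rate in s^-1")
  tibble(
    name = name, t1 = t1, t2 = t2, f = f, k = k,
    delta = delta, lineshape = lineshape
  )
}

#' Assemble a multi-pool system
#'
#' Binds a water pool and one or more solute/semisolid pools into the pool
#' table the Bloch-McConnell simulator consumes, together with the static
#' field strength used for all ppm conversions.
#'
#' @param water A water [pool()] (`f = 1`, `k = 0`).
#' @param solutes List of non-water [pool()] rows (at least one is required
#'   for Cramer-Rao computations over (fs, ksw)).
#' @param b0 Field strength, Tesla.
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1.
#' @return A `pool_system`: a tibble of pools (water first) with `b0` and
#'   `gamma` attributes.
#' @examples
#' sys <- pool_system(
#'   water = pool("water", t1 = 2.8, t2 = 0.6),
#'   solutes = list(pool("larg", t1 = 2.8, t2 = 0.04,
#'                       f = 1.35e-3, k = 500, delta = 3)),
#'   b0 = 7
#' )
#' @export
pool_system <- function(water, solutes = list(), b0, gamma = GAMMA_1H) {
  stopifnot(is.data.frame(water), nrow(water) == 1)
  if (water$k != 0) abort("the water pool must have k = 0")
  if (water$f != 1) abort("the water pool must have f = 1")
  if (water$lineshape != "full_bm_lorentzian")
    abort("the water pool must be a full Bloch-McConnell pool")
  if (is.data.frame(solutes)) solutes <- list(solutes)
  for (s in solutes) {
    if (s$f >= 1 || s$f <= 0) abort("non-water pools need 0 < f < 1")
    if (s$k <= 0) abort("non-water pools need k > 0")
  }
  if (!is.finite(b0) || b0 <= 0) abort("b0 must be a positive field in Tesla")
  pools <- dplyr::bind_rows(c(list(water), solutes))
  structure(pools,
    b0 = b0, gamma = gamma,
    class = c("pool_system", class(tibble())))
}

#' @export
print.pool_system <- function(x, ...) {
  cat(sprintf("<pool_system> %d pool(s) at B0 = %g T\n", nrow(x), attr(x, "b0")))
  NextMethod()
}

b0_of <- function(pools) attr(pools, "b0")
gamma_of <- function(pools) attr(pools, "gamma")

#' Replace the (fs, ksw) of a solute pool
#'
#' @param pools A [pool_system()].
#' @param fs,ksw New volume fraction and exchange rate.
#' @param solute Name or index (within the non-water pools) of the pool to
#'   modify; default the first non-water pool.
#' @return The modified `pool_system`.
#' @export
set_solute_params <- function(pools, fs, ksw, solute = 1L) {
  idx <- solute_index(pools, solute)
  if (!is.finite(fs) || fs <= 0 || fs >= 1) abort("fs must lie in (0, 1)")
  if (!is.finite(ksw) || ksw <= 0) abort("ksw must be positive")
  pools$f[idx] <- fs
  pools$k[idx] <- ksw
  pools
}

solute_index <- function(pools, solute = 1L) {
  if (is.character(solute)) {
    idx <- which(pools$name == solute)
    if (length(idx) != 1) abort(paste0("no unique pool named '", solute, "'"))
  } else {
    idx <- 1L + as.integer(solute)
    if (idx < 2 || idx > nrow(pools)) abort("solute index out of range")
  }
  if (idx == 1L) abort("cannot target the water pool")
  idx
}

#' Built-in pool systems
#'
#' `larg_pool_system()` describes an L-arginine-in-PBS phantom (guanidinium
#' amine protons at 3 ppm exchanging with water); `mt_pool_system()` a
#' two-pool brain tissue model with a semisolid macromolecular pool. Fixed
#' relaxation times are typical literature values for these preparations and
#' are freely overridable.
#'
#' @param b0 Field strength in Tesla.
#' @param fs,ksw Solute volume fraction and exchange rate (s^-1).
#' @param water_t1,water_t2,solute_t1,solute_t2 Relaxation times, seconds.
#' @param lineshape Semisolid pool representation (see [pool()]).
#' @param delta Semisolid pool chemical shift, ppm.
#' @return A [pool_system()].
#' @export
larg_pool_system <- function(b0 = 7, fs = 1.35e-3, ksw = 500,
                             water_t1 = 2.8, water_t2 = 0.6,
                             solute_t1 = 2.8, solute_t2 = 0.04) {
  pool_system(
    water = pool("water", t1 = water_t1, t2 = water_t2),
    solutes = list(pool("larg", t1 = solute_t1, t2 = solute_t2,
                        f = fs, k = ksw, delta = 3)),
    b0 = b0
  )
}

#' @rdname larg_pool_system
#' @export
mt_pool_system <- function(b0 = 3, fs = 0.1, ksw = 50,
                           water_t1 = 1.3, water_t2 = 0.08,
                           solute_t1 = 1.0, solute_t2 = 1e-5,
                           lineshape = "full_bm_lorentzian",
                           delta = -2.5) {
  pool_system(
    water = pool("water", t1 = water_t1, t2 = water_t2),
    solutes = list(pool("mt", t1 = solute_t1, t2 = solute_t2,
                        f = fs, k = ksw, delta = delta,
                        lineshape = lineshape)),
    b0 = b0
  )
}
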