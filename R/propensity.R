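#' Per-deme event rates and total propensity
#'
#' For a deme holding `x` wild-type and `y` mutant individuals the four event
#' rates are
#' wild-type division `r_w x b(x + y)`, mutant division `r_m y b(x + y)`,
#' wild-type death `d_w x delta(x + y)` and mutant death `d_m y delta(x + y)`,
#' with the shared density factor applied to the summed division rates.  The
#' total propensity is their sum,
#' \deqn{A = (r_w x + r_m y)\,b(x+y) + (d_w x + d_m y)\,\delta(x+y),}
#' which under the default shapes is
#' `(r_w x + r_m y) [1 - (x+y)/K]_+ + d_w x + d_m y`.
#'
#' @param x Wild-type count (non-negative integer; vectorized).
#' @param y Mutant count (non-negative integer; vectorized).
#' @param rates A [kinetic_rates()] object.
#' @param config A [deme_config()] object (supplies `K` and the density
#'   shapes).
#' @return `deme_propensity` returns the total event rate; `deme_event_rates`
#'   returns the four component rates for a single state as a named vector
#'   `(wt_division, wt_death, mut_division, mut_death)`.
#' @examples
#' r <- kinetic_rates(5, 0.5)
#' cfg <- deme_config(K = 20)
#' deme_propensity(10, 0, r, cfg)  # 30: 5*10*0.5 + 0.5*10
#' deme_event_rates(10, 5, r, cfg)
#' @export
deme_propensity <- function(x, y, rates, config) {
  stopifnot(inherits(rates, "kinetic_rates"), inherits(config, "deme_config"))
  if (any(x < 0) || any(y < 0) || any(x != round(x)) || any(y != round(y)))
    stop("x and y must be non-negative integers")
  occ <- x + y
  b <- config$density$b(occ, config$K)
  de <- config$density$delta(occ, config$K)
  (rates$r_w * x + rates$r_m * y) * b + (rates$d_w * x + rates$d_m * y) * de
}

#' @rdname deme_propensity
#' @export
deme_event_rates <- function(x, y, rates, config) {
  stopifnot(length(x) == 1L, length(y) == 1L)
  if (x < 0 || y < 0 || x != round(x) || y != round(y))
    stop("x and y must be non-negative integers")
  occ <- x + y
  b <- config$density$b(occ, config$K)
  de <- config$density$delta(occ, config$K)
  c(wt_division = rates$r_w * x * b,
    wt_death = rates$d_w * x * de,
    mut_division = rates$r_m * y * b,
    mut_death = rates$d_m * y * de)
}

#' Deterministic equilibrium occupancy of a single-type deme
#'
#' Fixed point of the per-deme logistic dynamics
#' \eqn{\dot x = r x (1 - x/K) - d x}, namely \eqn{K (1 - d/r)}.  This is the
#' default per-deme size `N` used by [effective_fitness()].
#'
#' @param r Per-capita division rate, `> 0`.
#' @param d Per-capita death rate, `>= 0`; must satisfy `d < r`.
#' @param K Carrying capacity.
#' @return The (generally non-integer) equilibrium occupancy.
#' @examples
#' deterministic_equilibrium(1, 0.1, 20)  # 18
#' @export
deterministic_equilibrium <- function(r, d, K) {
  stopifnot(is.numeric(r), is.numeric(d), is.numeric(K), K >= 2)
  if (r <= 0 || d < 0) stop("need r > 0 and d >= 0")
  if (d >= r) stop("no positive equilibrium: d >= r")
  K * (1 - d / r)
}
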