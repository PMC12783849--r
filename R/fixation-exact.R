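#' Two-type Markov chain of one isolated deme
#'
#' The exact competition chain on states `(x, y)` with `0 <= x + y <= K`:
#' `x` residents and `y` invaders, with transition rates
#' resident birth `r_res x b(x+y)`, invader birth `r_inv y b(x+y)`,
#' resident death `d_res x delta(x+y)`, invader death `d_inv y delta(x+y)`.
#' Absorption is classified at the first hitting of a zero coordinate:
#' `y = 0` is invader loss, `x = 0` (with `y >= 1`) is deme conversion.
#' Since every event changes one count by one, the state `(0, 0)` is never
#' reached before absorption.
#'
#' By default the resident is the wild type and the invader the mutant; set
#' `direction = "wt_into_mutant"` to swap the roles.
#'
#' @param rates A [kinetic_rates()] object.
#' @param K Carrying capacity.
#' @param density A [density_dependence()] object; the exact solver requires
#'   `b(K) = 0` so that no transition leaves the simplex.
#' @param direction Which type invades which: `"mutant_into_wt"` (default) or
#'   `"wt_into_mutant"`.
#' @return An object of class `"deme_chain"`.
#' @examples
#' ch <- deme_chain(kinetic_rates(1, 0.1, tau = 2), K = 20)
#' within_deme_fixation(18, 1, ch)
#' @export
deme_chain <- function(rates, K, density = density_dependence(),
                       direction = c("mutant_into_wt", "wt_into_mutant")) {
  direction <- match.arg(direction)
  stopifnot(inherits(rates, "kinetic_rates"), K >= 2)
  validate_density(density, K)
  if (density$b(K, K) > 0)
    stop("exact chain requires b(K) = 0: births must stop at carrying capacity")
  if (direction == "mutant_into_wt") {
    res <- c(r = rates$r_w, d = rates$d_w)
    inv <- c(r = rates$r_m, d = rates$d_m)
  } else {
    res <- c(r = rates$r_m, d = rates$d_m)
    inv <- c(r = rates$r_w, d = rates$d_w)
  }
  structure(
    list(rates = rates, K = as.integer(K), density = density,
         direction = direction, resident = res, invader = inv),
    class = "deme_chain"
  )
}

# enumerate transient states (x >= 1, y >= 1, x + y <= K) and solve the
# first-step system for the requested absorbing class; returns the full
# solution plus the state index
solve_first_step <- function(chain, outcome = c("conversion", "loss")) {
  outcome <- match.arg(outcome)
  K <- chain$K
  x <- rep(seq_len(K - 1), times = (K - 1):1)
  y <- sequence((K - 1):1)
  m <- length(x)
  id <- matrix(NA_integer_, K, K)
  id[cbind(x, y)] <- seq_len(m)
  occ <- x + y
  b <- chain$density$b(occ, K)
  de <- chain$density$delta(occ, K)
  bx <- chain$resident["r"] * x * b
  by <- chain$invader["r"] * y * b
  dx <- chain$resident["d"] * x * de
  dy <- chain$invader["d"] * y * de
  diag_rate <- bx + by + dx + dy
  if (any(diag_rate <= 0))
    stop("singular first-step system: a transient state has no outgoing rate")

  ii <- jj <- integer(0)
  vv <- numeric(0)
  add <- function(from, to, rate) {
    keep <- rate > 0 & !is.na(to)
    ii <<- c(ii, from[keep]); jj <<- c(jj, to[keep]); vv <<- c(vv, -rate[keep])
  }
  i_all <- seq_len(m)
  # resident birth (x+1, y); rate is 0 at x + y = K under b(K) = 0
  add(i_all, id[cbind(pmin(x + 1, K), y)], bx)
  # invader birth (x, y+1)
  add(i_all, id[cbind(x, pmin(y + 1, K))], by)
  # resident death to (x-1, y); x = 1 exits to the conversion class
  in_x <- x >= 2
  add(i_all[in_x], id[cbind(x[in_x] - 1, y[in_x])], dx[in_x])
  # invader death to (x, y-1); y = 1 exits to the loss class
  in_y <- y >= 2
  add(i_all[in_y], id[cbind(x[in_y], y[in_y] - 1)], dy[in_y])

  A <- Matrix::sparseMatrix(i = c(i_all, ii), j = c(i_all, jj),
                            x = c(diag_rate, vv), dims = c(m, m))
  rhs <- numeric(m)
  if (outcome == "conversion") {
    rhs[x == 1] <- dx[x == 1]
  } else {
    rhs[y == 1] <- dy[y == 1]
  }
  p <- as.numeric(Matrix::solve(A, rhs))
  list(p = p, x = x, y = y, id = id)
}

#' Exact within-deme invader fixation probability
#'
#' First-hitting probability of the conversion class (`x = 0`) from the state
#' with `x0` residents and `y0` invaders, obtained by solving the sparse
#' first-step linear system over all transient states.  With
#' `outcome = "loss"` the complementary absorption probability (invader lost,
#' resident retained) is solved independently; for every transient state the
#' two sum to one.
#'
#' @param x0 Resident count, `>= 1`.
#' @param y0 Invader count, `>= 1`, with `x0 + y0 <= K`.
#' @param chain A [deme_chain()] object.
#' @param outcome Which absorbing class to hit.
#' @return A probability in `[0, 1]`.
#' @export
within_deme_fixation <- function(x0, y0, chain,
                                 outcome = c("conversion", "loss")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(chain, "deme_chain"))
  K <- chain$K
  if (any(x0 < 1) || any(y0 < 1) || any(x0 + y0 > K))
    stop("need x0 >= 1, y0 >= 1 and x0 + y0 <= K")
  sol <- solve_first_step(chain, outcome)
  sol$p[sol$id[cbind(x0, y0)]]
}

#' Expected single-invader fixation probability at quasi-equilibrium
#'
#' Averages the exact within-deme fixation probability of a single invader
#' over the resident deme's quasi-stationary size distribution, restricted and
#' renormalized to sizes `n < K` — mirroring the simulation protocol, which
#' only seeds a mutant into a deme below carrying capacity:
#' \deqn{\bar\rho = \sum_{n < K} q(n \mid n < K)\; \rho(n \to n{+}1
#' \text{ invader}).}
#' `direction = "mutant_into_wt"` gives \eqn{\bar\rho_m} (one mutant invading
#' a wild-type deme); `"wt_into_mutant"` gives \eqn{\bar\rho_w}.
#'
#' @param rates A [kinetic_rates()] object.
#' @param config A [deme_config()] object (only `K` and the density shapes are
#'   used; invasion is computed for an isolated deme, the rare-migration
#'   assumption behind the coarse-grained reduction).
#' @param direction Which type invades which.
#' @param resident_law `"qsd"` (default) averages over the quasi-stationary
#'   distribution; `"deterministic"` uses a point mass at the rounded
#'   deterministic equilibrium.
#' @return The expected fixation probability.
#' @examples
#' cfg <- deme_config(K = 20)
#' rho_bar(kinetic_rates(1, 0.1, tau = 2), cfg)  # below the neutral 1/N
#' @export
rho_bar <- function(rates, config,
                    direction = c("mutant_into_wt", "wt_into_mutant"),
                    resident_law = c("qsd", "deterministic")) {
  direction <- match.arg(direction)
  resident_law <- match.arg(resident_law)
  stopifnot(inherits(rates, "kinetic_rates"), inherits(config, "deme_config"))
  K <- config$K
  res <- if (direction == "mutant_into_wt") c(rates$r_w, rates$d_w)
         else c(rates$r_m, rates$d_m)
  if (res[1] <= res[2])
    stop("resident type is not viable in isolation (r <= d)")
  chain <- deme_chain(rates, K, config$density, direction)
  sol <- solve_first_step(chain, "conversion")
  p_n <- sol$p[sol$id[cbind(seq_len(K - 1), 1L)]]  # invade n residents
  if (resident_law == "deterministic") {
    n_star <- round(deterministic_equilibrium(res[1], res[2], K))
    n_star <- min(max(n_star, 1L), K - 1L)
    return(p_n[n_star])
  }
  q <- single_type_qsd(res[1], res[2], K, config$density)
  w <- q$weights[seq_len(K - 1)]
  w <- w / sum(w)                                   # condition on size < K
  sum(w * p_n)
}

#' Single-mutant fixation probability in one unfragmented population
#'
#' The exact fixation probability of one mutant in a single logistic deme of
#' carrying capacity `K_total`, i.e. [rho_bar()] evaluated for an isolated
#' deme of that size.  Used as the non-fragmented reference when comparing a
#' fragmented and a non-fragmented system of equal total size.
#'
#' @param rates A [kinetic_rates()] object.
#' @param K_total Total carrying capacity; capped (default 600) because the
#'   chain has `O(K_total^2)` states.
#' @param max_K Size guard for the sparse solver.
#' @return The fixation probability.
#' @export
nonfragmented_pfix <- function(rates, K_total, max_K = 600) {
  stopifnot(K_total >= 2)
  if (K_total > max_K)
    stop("K_total exceeds the solver size guard (", max_K, ")")
  rho_bar(rates, deme_config(K = K_total, D = 1), "mutant_into_wt")
}
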