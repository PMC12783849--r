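#' Binomial proportion standard error
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `>= 1`.
#' @return `sqrt(p (1 - p) / n)` with `p = k / n`.
#' @examples
#' binomial_se(50, 100)  # 0.05
#' @export
binomial_se <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  p <- k / n
  sqrt(p * (1 - p) / n)
}

# shared result container for fixation experiments
experiment_result <- function(n_runs, n_fixed, n_lost, n_extinct, seed,
                              params, extra = list()) {
  structure(
    c(list(n_runs = n_runs, n_fixed = n_fixed, n_lost = n_lost,
           n_extinct = n_extinct, p_hat = n_fixed / n_runs,
           se = binomial_se(n_fixed, n_runs), seed = seed, params = params),
      extra),
    class = "experiment_result"
  )
}

#' @exportS3Method base::print
print.experiment_result <- function(x, ...) {
  cat(sprintf("Fixation experiment: %d runs, %d fixed (p_hat = %.5g, se = %.3g)\n",
              x$n_runs, x$n_fixed, x$p_hat, x$se))
  if (x$n_extinct > 0)
    cat(sprintf("  whole-population extinctions (counted as non-fixation): %d\n",
                x$n_extinct))
  if (!is.null(x$seed)) cat(sprintf("  seed: %s\n", format(x$seed)))
  invisible(x)
}

#' Initialize a deme-system state
#'
#' @param config A [deme_config()] object.
#' @param x,y Per-deme wild-type and mutant counts (recycled to `D`); default
#'   all demes at carrying capacity, no mutants.
#' @return An object of class `"system_state"`: list with integer vectors `x`,
#'   `y`, elapsed time `t` and an event counter.
#' @export
init_state <- function(config, x = config$K, y = 0L) {
  stopifnot(inherits(config, "deme_config"))
  x <- rep_len(as.integer(x), config$D)
  y <- rep_len(as.integer(y), config$D)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  structure(list(x = x, y = y, t = 0, events = 0L), class = "system_state")
}

#' One Gillespie update of the deme system
#'
#' Reference (pure R) implementation of a single event of the deme-structured
#' simulation: a deme is chosen with probability `A_i / A`; the event within
#' the deme is chosen among the four rates (wild-type/mutant division/death);
#' a division's offspring migrates with probability `epsilon` to a uniformly
#' chosen *other* deme and is discarded when the target is full (under
#' crowd-controlled migration); a wild-type division's offspring is mutant
#' with probability `mu`; the elapsed time is exponential with mean `1/A`.
#' One uniform variate is drawn per hierarchical choice.
#'
#' The compiled experiment drivers ([run_fixation_experiment()],
#' [run_mutation_experiment()]) implement the same kernel; this stepper
#' additionally supports generalized density shapes and exposes the chosen
#' event for inspection.
#'
#' @param state A [init_state()] object.
#' @param rates A [kinetic_rates()] object.
#' @param config A [deme_config()] object.
#' @return Invisibly, a list with the updated `state`, the elapsed `dt`, and
#'   `event` (list with `deme`, `type`, and for divisions `migrated`,
#'   `target`, `aborted`, `mutant_offspring`).
#' @export
gillespie_step <- function(state, rates, config) {
  stopifnot(inherits(state, "system_state"))
  D <- config$D
  Ai <- deme_propensity(state$x, state$y, rates, config)
  A <- sum(Ai)
  if (A <= 0) stop("total propensity is zero: population extinct")
  k <- findInterval(stats::runif(1) * A, cumsum(Ai)) + 1L
  k <- min(k, D)
  ev <- deme_event_rates(state$x[k], state$y[k], rates, config)
  u <- stats::runif(1) * sum(ev)
  type <- names(ev)[findInterval(u, cumsum(ev)) + 1L]
  event <- list(deme = k, type = type)
  if (type == "wt_death") {
    state$x[k] <- state$x[k] - 1L
  } else if (type == "mut_death") {
    state$y[k] <- state$y[k] - 1L
  } else {
    mutant <- type == "mut_division"
    if (!mutant && config$mu > 0 && stats::runif(1) < config$mu)
      mutant <- TRUE
    event$mutant_offspring <- mutant
    event$migrated <- config$epsilon > 0 && stats::runif(1) < config$epsilon
    event$aborted <- FALSE
    if (event$migrated) {
      if (D == 1) {
        event$aborted <- TRUE          # "another deme" excludes self
      } else {
        j <- sample.int(D - 1L, 1L)
        if (j >= k) j <- j + 1L
        event$target <- j
        full <- state$x[j] + state$y[j] >= config$K
        if (config$migration_model == "crowd_controlled_by_division" && full) {
          event$aborted <- TRUE
        } else if (mutant) {
          state$y[j] <- state$y[j] + 1L
        } else {
          state$x[j] <- state$x[j] + 1L
        }
      }
    } else if (mutant) {
      state$y[k] <- state$y[k] + 1L
    } else {
      state$x[k] <- state$x[k] + 1L
    }
  }
  dt <- stats::rexp(1, rate = A)
  state$t <- state$t + dt
  state$events <- state$events + 1L
  invisible(list(state = state, dt = dt, event = event))
}

check_simulator_config <- function(config) {
  if (!config$density$default)
    stop("the compiled simulator supports only the default density shapes; ",
         "use gillespie_step() or the exact solvers for custom b/delta")
}

#' Mutant fixation experiment in the deme system
#'
#' Full simulation protocol: every replicate starts with `K` wild-type
#' individuals in all `D` demes, runs `burn_in_events` update events to reach
#' quasi-equilibrium, adds a single mutant to a uniformly chosen deme with
#' occupancy below `K` (redrawing until placement succeeds; if every deme is
#' full the simulation advances one event and retries), and then continues
#' until either the mutant or the wild-type population is extinct.
#' Whole-population extinction during a run (possible but rare) is recorded
#' separately and counted as non-fixation.
#'
#' @param rates A [kinetic_rates()] object.
#' @param config A [deme_config()] object with the default density shapes.
#' @param n_runs Number of replicates.
#' @param burn_in_events Update events before seeding (default 10,000, the
#'   protocol's quasi-equilibration length; each Gillespie update is one
#'   "time-step" with exponential duration).  Set
#'   `scale_burn_in_with_demes = TRUE` to use `burn_in_events * D` instead.
#' @param seed Integer seed (recorded in the result); `NULL` leaves the RNG
#'   state untouched.
#' @param scale_burn_in_with_demes Scale the burn-in with the deme count.
#' @return An `"experiment_result"`: replicate counts, fixation counts,
#'   `p_hat`, binomial `se`, extinction diagnostics, seed and parameter echo.
#' @examples
#' r <- kinetic_rates(1, 0.1, tau = 1)
#' cfg <- deme_config(K = 20, D = 4, epsilon = 1e-4)
#' run_fixation_experiment(r, cfg, n_runs = 200, seed = 1)
#' @export
run_fixation_experiment <- function(rates, config, n_runs,
                                    burn_in_events = 10000, seed = NULL,
                                    scale_burn_in_with_demes = FALSE) {
  stopifnot(inherits(rates, "kinetic_rates"), inherits(config, "deme_config"),
            n_runs >= 1)
  check_simulator_config(config)
  if (!is.null(seed)) set.seed(seed)
  burn <- if (scale_burn_in_with_demes) burn_in_events * config$D
          else burn_in_events
  res <- cpp_deme_fixation(
    rates$r_w, rates$d_w, rates$r_m, rates$d_m,
    config$K, config$D, config$epsilon,
    config$migration_model == "crowd_controlled_by_division",
    as.integer(n_runs), burn
  )
  experiment_result(
    n_runs = as.integer(n_runs), n_fixed = as.integer(res$n_fixed),
    n_lost = as.integer(res$n_lost), n_extinct = as.integer(res$n_extinct),
    seed = seed,
    params = list(rates = rates, config = config, burn_in_events = burn),
    extra = list(n_burn_restarts = as.integer(res$n_burn_restarts))
  )
}

#' Monte Carlo invasion of one isolated deme from a fixed state
#'
#' Simulates the isolated-deme competition chain (no migration) from `x0`
#' residents (wild type) and `y0` invaders (mutants) to absorption, `n_runs`
#' times.  This is the stochastic counterpart of [within_deme_fixation()].
#'
#' @param rates A [kinetic_rates()] object.
#' @param K Carrying capacity.
#' @param x0,y0 Initial wild-type and mutant counts.
#' @param n_runs Number of replicates.
#' @param seed Integer seed or `NULL`.
#' @return An `"experiment_result"`.
#' @export
run_isolated_invasion <- function(rates, K, x0, y0, n_runs, seed = NULL) {
  stopifnot(inherits(rates, "kinetic_rates"), x0 >= 1, y0 >= 1, x0 + y0 <= K)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_isolated_invasion(rates$r_w, rates$d_w, rates$r_m, rates$d_m,
                               as.integer(K), as.integer(x0), as.integer(y0),
                               as.integer(n_runs))
  experiment_result(
    n_runs = as.integer(n_runs), n_fixed = as.integer(res$n_fixed),
    n_lost = as.integer(res$n_lost), n_extinct = 0L, seed = seed,
    params = list(rates = rates, K = K, x0 = x0, y0 = y0)
  )
}

#' De-novo mutation time series in the deme system
#'
#' Starts all demes at carrying capacity with wild types only and simulates
#' with recurrent mutation (each wild-type division's offspring is mutant with
#' probability `mu`) up to `t_max`, sampling the total wild-type and mutant
#' counts every `sample_dt` time units.
#'
#' @param rates A [kinetic_rates()] object.
#' @param config A [deme_config()] object with `mu > 0` (or `mu = 0` for a
#'   control run) and the default density shapes.
#' @param t_max Simulated time horizon.
#' @param sample_dt Sampling interval (default `t_max / 1000`).
#' @param seed Integer seed or `NULL`.
#' @return A `data.frame` of class `"deme_timeseries"` with columns `time`,
#'   `wildtype`, `mutant`; attributes carry the parameters and seed.
#' @export
run_mutation_experiment <- function(rates, config, t_max,
                                    sample_dt = t_max / 1000, seed = NULL) {
  stopifnot(inherits(rates, "kinetic_rates"), inherits(config, "deme_config"),
            t_max > 0, sample_dt > 0)
  check_simulator_config(config)
  if (!is.null(seed)) set.seed(seed)
  m <- cpp_deme_mutation(
    rates$r_w, rates$d_w, rates$r_m, rates$d_m,
    config$K, config$D, config$epsilon, config$mu,
    config$migration_model == "crowd_controlled_by_division",
    t_max, sample_dt
  )
  out <- data.frame(time = m[, 1], wildtype = m[, 2], mutant = m[, 3])
  attr(out, "params") <- list(rates = rates, config = config,
                              t_max = t_max, sample_dt = sample_dt)
  attr(out, "seed") <- seed
  class(out) <- c("deme_timeseries", "data.frame")
  out
}

#' Simulated occupancy distribution of an isolated single-type deme
#'
#' Long-run expected-holding-time weights of the occupancy of one deme with
#' wild types only and no migration, for comparison with the exact
#' quasi-stationary distribution of [single_type_qsd()].
#'
#' @param r,d Per-capita division and death rates.
#' @param K Carrying capacity.
#' @param n_events Events to accumulate after burn-in.
#' @param burn_in Burn-in events.
#' @param seed Integer seed or `NULL`.
#' @return Named numeric vector of normalized weights over occupancies
#'   `0..K` (weight at 0 is zero unless extinction occurred).
#' @export
simulated_occupancy <- function(r, d, K, n_events = 1e6, burn_in = 1e4,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- cpp_deme_occupancy_weights(r, d, as.integer(K), n_events, burn_in)
  w <- w / sum(w)
  names(w) <- 0:K
  w
}
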