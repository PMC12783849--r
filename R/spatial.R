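#' Configuration of the spatial agent-based model
#'
#' The spatial model lives on an `n x n` grid with periodic boundaries; each
#' spot is empty or holds one wild-type or mutant individual.  Per time step
#' and per hit, an individual dies with probability `D_w` (`D_m`) and, if it
#' survived the hit, attempts reproduction with probability `R_w` (`R_m`) into
#' a uniformly chosen one of its 8 nearest neighbours, succeeding only when
#' that spot is empty.  Mutant probabilities follow the same scaling as the
#' deme model: `R_m = tau (1 + s) R_w`, `D_m = tau D_w`; combinations pushing
#' any probability above 1 are rejected.
#'
#' @param n Grid side length.
#' @param R_w,D_w Wild-type per-hit reproduction and death probabilities.
#' @param tau Turnover factor.
#' @param s Selection coefficient.
#' @param mu Mutation probability per wild-type reproduction.
#' @return An object of class `"spatial_config"`.
#' @examples
#' spatial_config(n = 20, R_w = 0.1, D_w = 0.01, tau = 5)
#' @export
spatial_config <- function(n, R_w, D_w, tau = 1, s = 0, mu = 0) {
  stopifnot(n >= 3, n == round(n))
  R_m <- tau * (1 + s) * R_w
  D_m <- tau * D_w
  p <- c(R_w = R_w, D_w = D_w, R_m = R_m, D_m = D_m, mu = mu)
  if (any(p < 0) || any(p > 1))
    stop("all per-step probabilities must lie in [0, 1]; got ",
         paste(sprintf("%s = %g", names(p), p)[p < 0 | p > 1], collapse = ", "))
  if (tau <= 0) stop("tau must be > 0")
  if (s <= -1) stop("s must be > -1")
  structure(
    list(n = as.integer(n), R_w = R_w, D_w = D_w, R_m = R_m, D_m = D_m,
         tau = tau, s = s, mu = mu),
    class = "spatial_config"
  )
}

#' One time step of the spatial model
#'
#' Advances a grid by `n_steps` time steps (default one).  A step processes
#' `M` hits, where `M` is the occupied count at the step's start; each hit is
#' uniform over the spots occupied at that moment (the state is updated
#' continuously within a step).
#'
#' @param grid Integer matrix with entries 0 (empty), 1 (wild type),
#'   2 (mutant).
#' @param config A [spatial_config()] object.
#' @param n_steps Number of steps.
#' @return The updated grid.
#' @export
spatial_step <- function(grid, config, n_steps = 1) {
  stopifnot(inherits(config, "spatial_config"), is.matrix(grid),
            nrow(grid) == config$n, ncol(grid) == config$n,
            all(grid %in% 0:2))
  storage.mode(grid) <- "integer"
  cpp_spatial_step(grid, config$R_w, config$D_w, config$R_m, config$D_m,
                   config$mu, as.integer(n_steps))
}

#' Torus neighbourhood table
#'
#' 8-neighbour indices (column-major spot indices, 1-based) for every spot of
#' an `n x n` torus.
#'
#' @param n Grid side length.
#' @return An `n^2 x 8` integer matrix.
#' @export
spatial_neighborhood <- function(n) {
  t(vapply(seq_len(n * n), function(i) cpp_spatial_neighbors(n, i),
           integer(8)))
}

#' Mean steady-state occupancy of the wild type on the grid
#'
#' Seeds half the grid with wild types, runs `burn_in` steps, and averages the
#' occupied count over a further observation `window`, per replicate.
#'
#' @param config A [spatial_config()] object (only the wild-type
#'   probabilities are used).
#' @param burn_in Equilibration steps (default 500).
#' @param window Averaging window in steps.
#' @param replicates Independent replicates.
#' @param seed Integer seed or `NULL`.
#' @return A list with `M_star` (grand mean occupancy) and `per_replicate`.
#'   Extinction of a majority of replicates is an error (non-viable
#'   parameters).
#' @export
estimate_steady_state <- function(config, burn_in = 500, window = 100,
                                  replicates = 10, seed = NULL) {
  stopifnot(inherits(config, "spatial_config"))
  if (!is.null(seed)) set.seed(seed)
  init <- max(1L, as.integer(config$n^2 / 2))
  m <- cpp_spatial_steady(config$R_w, config$D_w, config$n,
                          as.integer(burn_in), as.integer(window),
                          as.integer(replicates), init)
  if (mean(m == 0) > 0.5)
    stop("wild type went extinct in a majority of replicates: ",
         "non-viable spatial parameters")
  list(M_star = mean(m), per_replicate = m)
}

#' Mutant fixation experiment on the grid
#'
#' Protocol per replicate: seed `M_star` (rounded) wild types at distinct
#' random spots, equilibrate `burn_in` steps, replace one uniformly chosen
#' wild type with a mutant, and run until one type is extinct.  Replicates in
#' which the wild type died out before seeding are excluded and reported.
#'
#' @param config A [spatial_config()] object.
#' @param n_runs Number of replicates.
#' @param M_star Seeding count; estimated via [estimate_steady_state()] when
#'   `NULL`.
#' @param burn_in Equilibration steps (default 500).
#' @param seed Integer seed or `NULL`.
#' @return An `"experiment_result"` with extra elements `M_star` and
#'   `mean_M_at_seeding`.
#' @export
spatial_fixation_experiment <- function(config, n_runs, M_star = NULL,
                                        burn_in = 500, seed = NULL) {
  stopifnot(inherits(config, "spatial_config"), n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(M_star))
    M_star <- estimate_steady_state(config)$M_star
  res <- cpp_spatial_fixation(config$R_w, config$D_w, config$R_m, config$D_m,
                              config$n, as.integer(round(M_star)),
                              as.integer(burn_in), as.integer(n_runs))
  n_eff <- as.integer(n_runs) - as.integer(res$n_pre_extinct)
  if (n_eff < 1) stop("all replicates went extinct before seeding")
  experiment_result(
    n_runs = n_eff, n_fixed = as.integer(res$n_fixed),
    n_lost = as.integer(res$n_lost), n_extinct = as.integer(res$n_extinct),
    seed = seed, params = list(config = config, burn_in = burn_in),
    extra = list(M_star = M_star,
                 mean_M_at_seeding = res$mean_M_at_seeding,
                 n_pre_extinct = as.integer(res$n_pre_extinct))
  )
}

#' De-novo mutation time series on the grid
#'
#' Seeds `M_star` wild types, then simulates with mutation for `t_steps` time
#' steps, sampling type counts every `sample_every` steps.
#'
#' @param config A [spatial_config()] object with `mu > 0` (or 0 for a
#'   control).
#' @param t_steps Time-step horizon.
#' @param sample_every Sampling stride in steps.
#' @param M_star Initial wild-type count; estimated when `NULL`.
#' @param seed Integer seed or `NULL`.
#' @return A `data.frame` with columns `step`, `wildtype`, `mutant`.
#' @export
spatial_mutation_experiment <- function(config, t_steps, sample_every = 10,
                                        M_star = NULL, seed = NULL) {
  stopifnot(inherits(config, "spatial_config"), t_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(M_star))
    M_star <- estimate_steady_state(config)$M_star
  m <- cpp_spatial_mutation(config$R_w, config$D_w, config$R_m, config$D_m,
                            config$mu, config$n, as.integer(round(M_star)),
                            as.integer(t_steps), as.integer(sample_every))
  out <- data.frame(step = m[, 1], wildtype = m[, 2], mutant = m[, 3])
  attr(out, "params") <- list(config = config, t_steps = t_steps,
                              sample_every = sample_every, M_star = M_star)
  attr(out, "seed") <- seed
  out
}
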