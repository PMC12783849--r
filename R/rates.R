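#' Wild-type and mutant kinetic rates
#'
#' Parameterizes the two competing types.  The wild type divides at per-capita
#' rate `r_w` and dies at rate `d_w`.  The mutant's rates are obtained by
#' scaling both with a turnover factor `tau` and changing the lifetime
#' reproductive output by a selection coefficient `s`:
#' \deqn{r_m = \tau (1 + s) r_w, \qquad d_m = \tau d_w.}
#' A mutant with `s = 0` is *quasi-neutral*: its maximum lifetime reproductive
#' output (`r_m / d_m = r_w / d_w`) equals the wild type's, but its turnover
#' differs by the factor `tau`.
#'
#' @param r_w Wild-type per-capita division rate (1/time), `> 0`.
#' @param d_w Wild-type per-capita death rate (1/time), `>= 0`.
#' @param tau Turnover factor (dimensionless), `> 0`.
#' @param s Selection coefficient (dimensionless), `> -1`.
#'
#' @return An object of class `"kinetic_rates"`: a list with elements `r_w`,
#'   `d_w`, `tau`, `s` and the derived mutant rates `r_m`, `d_m`.
#' @examples
#' kinetic_rates(r_w = 5, d_w = 0.5, tau = 5, s = 0.01)
#' @export
kinetic_rates <- function(r_w, d_w, tau = 1, s = 0) {
  stopifnot(is.numeric(r_w), length(r_w) == 1L, is.finite(r_w),
            is.numeric(d_w), length(d_w) == 1L, is.finite(d_w),
            is.numeric(tau), length(tau) == 1L, is.finite(tau),
            is.numeric(s), length(s) == 1L, is.finite(s))
  if (r_w <= 0) stop("r_w must be > 0")
  if (d_w < 0) stop("d_w must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  if (s <= -1) stop("s must be > -1")
  structure(
    list(r_w = r_w, d_w = d_w, tau = tau, s = s,
         r_m = tau * (1 + s) * r_w, d_m = tau * d_w),
    class = "kinetic_rates"
  )
}

#' @rdname kinetic_rates
#' @param x,... Object and further arguments for the print method.
#' @exportS3Method base::print
print.kinetic_rates <- function(x, ...) {
  cat("Kinetic rates\n")
  cat(sprintf("  wild type: r_w = %g, d_w = %g\n", x$r_w, x$d_w))
  cat(sprintf("  mutant:    r_m = %g, d_m = %g  (tau = %g, s = %g)\n",
              x$r_m, x$d_m, x$tau, x$s))
  invisible(x)
}

#' Is a mutant quasi-neutral?
#'
#' `TRUE` when the selection coefficient is zero, i.e. when mutant and
#' wild-type lifetime reproductive outputs coincide (`d_m/r_m == d_w/r_w`).
#'
#' @param rates A [kinetic_rates()] object.
#' @export
is_quasi_neutral <- function(rates) {
  stopifnot(inherits(rates, "kinetic_rates"))
  rates$s == 0
}

#' Density-dependence shapes
#'
#' The per-capita division rate in a deme of occupancy `x` is `r * b(x)` and
#' the death rate `d * delta(x)`.  Both modifiers are functions of the integer
#' occupancy and the carrying capacity `K`.  The defaults are the logistic
#' shapes `b(x) = max(1 - x/K, 0)` and `delta(x) = 1`, i.e. crowding slows
#' division and leaves death untouched.  Custom shapes must satisfy
#' `b(0) = 1` with `b` non-increasing and `delta(0) = 1` with `delta`
#' non-decreasing; these constraints are checked by sampling on `0..K` when a
#' configuration is built.
#'
#' @param b Function of `(x, K)` returning the division modifier.
#' @param delta Function of `(x, K)` returning the death modifier.
#' @return An object of class `"density_dependence"`.
#' @examples
#' density_dependence()  # logistic division, constant death
#' @export
density_dependence <- function(b = NULL, delta = NULL) {
  default_b <- is.null(b)
  default_delta <- is.null(delta)
  if (default_b) b <- function(x, K) pmax(1 - x / K, 0)
  if (default_delta) delta <- function(x, K) rep_len(1, length(x))
  stopifnot(is.function(b), is.function(delta))
  structure(
    list(b = b, delta = delta,
         default = default_b && default_delta),
    class = "density_dependence"
  )
}

validate_density <- function(density, K) {
  x <- 0:K
  bv <- density$b(x, K)
  dv <- density$delta(x, K)
  if (length(bv) != K + 1 || length(dv) != K + 1)
    stop("density shapes must be vectorized over occupancy")
  if (abs(bv[1] - 1) > 1e-12) stop("b(0) must equal 1")
  if (any(diff(bv) > 1e-12)) stop("b must be non-increasing in occupancy")
  if (any(bv < 0)) stop("b must be non-negative")
  if (abs(dv[1] - 1) > 1e-12) stop("delta(0) must equal 1")
  if (any(diff(dv) < -1e-12)) stop("delta must be non-decreasing in occupancy")
  invisible(TRUE)
}

#' Deme-system configuration
#'
#' Collects the structural parameters of the deme model: carrying capacity
#' `K`, deme count `D`, per-division migration probability `epsilon`,
#' per-division mutation probability `mu`, the migration variant, and the
#' density-dependence shapes.
#'
#' Under `"crowd_controlled_by_division"` (the default) a newborn that drew a
#' migration attempt is discarded when the target deme is at carrying
#' capacity, so no deme ever exceeds `K`.  Under
#' `"unconditional_by_division"` the migrant is always placed; a deme may
#' transiently exceed `K`, after which its division rate is zero until deaths
#' restore it.
#'
#' @param K Deme carrying capacity (`>= 2`).
#' @param D Number of demes (`>= 1`).
#' @param epsilon Migration probability per division, in `[0, 1]`.
#' @param mu Mutation probability per wild-type division, in `[0, 1]`.
#' @param migration_model Migration variant; see Details.
#' @param density A [density_dependence()] object.
#' @return An object of class `"deme_config"`.
#' @examples
#' deme_config(K = 20, D = 9, epsilon = 1e-4)
#' @export
deme_config <- function(K, D = 1, epsilon = 0, mu = 0,
                        migration_model = c("crowd_controlled_by_division",
                                            "unconditional_by_division"),
                        density = density_dependence()) {
  migration_model <- match.arg(migration_model)
  stopifnot(is.numeric(K), length(K) == 1L, K == round(K),
            is.numeric(D), length(D) == 1L, D == round(D))
  if (K < 2) stop("K must be >= 2")
  if (D < 1) stop("D must be >= 1")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0, 1]")
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  stopifnot(inherits(density, "density_dependence"))
  validate_density(density, K)
  structure(
    list(K = as.integer(K), D = as.integer(D), epsilon = epsilon, mu = mu,
         migration_model = migration_model, density = density),
    class = "deme_config"
  )
}

#' @rdname deme_config
#' @param x,... Object and further arguments for the print method.
#' @exportS3Method base::print
print.deme_config <- function(x, ...) {
  cat(sprintf("Deme system: D = %d demes, K = %d, epsilon = %g, mu = %g\n",
              x$D, x$K, x$epsilon, x$mu))
  cat(sprintf("  migration: %s; density shapes: %s\n", x$migration_model,
              if (x$density$default) "logistic division, constant death"
              else "custom"))
  invisible(x)
}

#' Serialize / restore a parameter set
#'
#' Writes the kinetic and structural parameters to a flat JSON key-value file
#' and reads them back.  Custom density shapes are not serializable; only
#' configurations with the default shapes round-trip.
#'
#' @param rates A [kinetic_rates()] object.
#' @param config A [deme_config()] object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   list with elements `rates` and `config`.
#' @export
write_params <- function(rates, config, path) {
  stopifnot(inherits(rates, "kinetic_rates"), inherits(config, "deme_config"))
  if (!config$density$default)
    stop("custom density shapes cannot be serialized to JSON")
  x <- list(r_w = rates$r_w, d_w = rates$d_w, tau = rates$tau, s = rates$s,
            K = config$K, D = config$D, epsilon = config$epsilon,
            mu = config$mu, migration_model = config$migration_model)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    rates = kinetic_rates(as.numeric(x$r_w), as.numeric(x$d_w),
                          as.numeric(x$tau), as.numeric(x$s)),
    config = deme_config(x$K, x$D, as.numeric(x$epsilon), as.numeric(x$mu),
                         x$migration_model)
  )
}
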