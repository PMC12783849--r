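#' Quasi-stationary occupancy distribution of a single-type deme
#'
#' An isolated deme with one type follows a logistic birth-death chain on
#' `{0, 1, ..., K}` with birth rate `r n b(n)` and death rate `d n delta(n)`;
#' state 0 is absorbing.  Conditioning on non-extinction yields the
#' quasi-stationary distribution (QSD) on `{1, ..., K}`: the normalized left
#' principal eigenvector of the generator restricted to the transient states.
#' It is computed by power iteration on the uniformized restricted generator,
#' which is guaranteed to converge for this tridiagonal chain.
#'
#' The QSD depends on the rates only through the embedded jump chain, so it is
#' invariant under a common rescaling of `r` and `d`: a quasi-neutral mutant
#' deme has the same QSD as a wild-type deme.
#'
#' @param r Per-capita division rate, `> 0`.
#' @param d Per-capita death rate, `>= 0`.  `d >= r` is allowed (with a
#'   warning): the QSD still exists but its interpretation as a long-lived
#'   metastable state does not.
#' @param K Carrying capacity, `>= 2`.
#' @param density A [density_dependence()] object.
#' @param tol Supremum-norm convergence tolerance of the iteration.
#' @param max_iter Iteration cap; exceeding it is an error (ill-conditioning).
#' @return An object of class `"qsd"`: list with `sizes` (`1:K`), `weights`
#'   (normalized), `mean`, and the inputs.
#' @examples
#' q <- single_type_qsd(1, 0.1, 20)
#' q$mean  # close to the deterministic equilibrium 18
#' @export
single_type_qsd <- function(r, d, K, density = density_dependence(),
                            tol = 1e-12, max_iter = 5e5) {
  stopifnot(r > 0, d >= 0, K >= 2)
  if (d >= r)
    warning("d >= r: extinction-dominated regime; QSD computed anyway")
  n <- seq_len(K)
  lam <- r * n * density$b(n, K)        # birth n -> n+1 (lam[K] = 0 by default)
  mu <- d * n * density$delta(n, K)     # death n -> n-1; mu[1] kills to 0
  if (lam[K] > 0)
    stop("density shape must satisfy b(K) = 0 so the chain stays within K")
  Lam <- max(lam + mu) * (1 + 1e-7)
  if (Lam <= 0) stop("all rates vanish; no dynamics")
  q <- rep(1 / K, K)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    inflow <- c(0, q[-K] * lam[-K]) + c(q[-1] * mu[-1], 0)
    qn <- q + (inflow - q * (lam + mu)) / Lam
    qn <- qn / sum(qn)
    step <- max(abs(qn - q))
    q <- qn
    iter <- it
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("QSD power iteration did not converge within max_iter")
  structure(
    list(sizes = n, weights = q, mean = sum(n * q),
         r = r, d = d, K = K, iterations = iter),
    class = "qsd"
  )
}

#' @rdname single_type_qsd
#' @param x,... Object and further arguments for the print method.
#' @exportS3Method base::print
print.qsd <- function(x, ...) {
  cat(sprintf("Quasi-stationary distribution on {1..%d} (r = %g, d = %g)\n",
              x$K, x$r, x$d))
  cat(sprintf("  mean occupancy %.4f; P(size = K) = %.4g\n",
              x$mean, x$weights[x$K]))
  invisible(x)
}

# QSD-expected total division flux r * n * b(n) of a pure deme
qsd_division_flux <- function(q, r, density) {
  sum(q$weights * r * q$sizes * density$b(q$sizes, q$K))
}

# QSD probability that the deme can accept a migrant (size < K)
qsd_acceptance <- function(q) {
  1 - q$weights[q$K]
}
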