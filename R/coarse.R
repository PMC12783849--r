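#' Relative fitness of a mutant deme
#'
#' In the rare-migration (coarse-grained) limit the multi-deme process reduces
#' to a one-dimensional walk over the number of mutant demes, driven by deme
#' conversions: a migrant of one type fixates in a deme of the other type.
#' The relative mutant deme fitness is the ratio of the two conversion rates,
#' \deqn{\mathcal{F} = \frac{E_m\, a_w\, \bar\rho_m}{E_w\, a_m\, \bar\rho_w},}
#' where for each type `E` is the quasi-stationary expected division flux of a
#' pure deme (the source of migrants; the per-division migration probability
#' `epsilon` multiplies both rates and cancels), `a` is the probability that a
#' deme of the *target* type is below carrying capacity and so accepts the
#' migrant, and \eqn{\bar\rho} is the within-deme fixation probability from
#' [rho_bar()].
#'
#' For quasi-neutral mutants (`s = 0`) the two QSDs coincide, the fluxes scale
#' exactly by `tau`, and the expression collapses to the closed form
#' \deqn{\mathcal{F} = \tau\, \bar\rho_m / \bar\rho_w,} which is what this
#' function returns in that case.
#'
#' @param rates A [kinetic_rates()] object.
#' @param config A [deme_config()] object.
#' @param include_acceptance Include the target-fullness acceptance factors
#'   `a_w`, `a_m` in the general-`s` conversion rates (default `TRUE`); both
#'   modes are provided because the exact treatment is a modeling choice.
#' @return The deme fitness `F > 0`.
#' @examples
#' cfg <- deme_config(K = 20)
#' deme_fitness(kinetic_rates(1, 0.1, tau = 2), cfg)  # < 1
#' @export
deme_fitness <- function(rates, config, include_acceptance = TRUE) {
  stopifnot(inherits(rates, "kinetic_rates"), inherits(config, "deme_config"))
  rm_ <- rho_bar(rates, config, "mutant_into_wt")
  rw_ <- rho_bar(rates, config, "wt_into_mutant")
  if (rates$s == 0)
    return(rates$tau * rm_ / rw_)
  qw <- single_type_qsd(rates$r_w, rates$d_w, config$K, config$density)
  qm <- single_type_qsd(rates$r_m, rates$d_m, config$K, config$density)
  E_w <- qsd_division_flux(qw, rates$r_w, config$density)
  E_m <- qsd_division_flux(qm, rates$r_m, config$density)
  a_w <- if (include_acceptance) qsd_acceptance(qw) else 1
  a_m <- if (include_acceptance) qsd_acceptance(qm) else 1
  (E_m * a_w * rm_) / (E_w * a_m * rw_)
}

#' System-level mutant fixation probability in a fragmented population
#'
#' Coarse-grained fixation probability of a lineage started from a single
#' mutant individual in a system of `D` demes:
#' \deqn{\Pi_1^{frag} \approx \bar\rho_m\,
#'   \frac{1 - 1/\mathcal{F}}{1 - 1/\mathcal{F}^D}.}
#' The deme-level factor is formally the fixation probability of a Moran
#' process with relative fitness `F`.  At `F = 1` the continuous limit
#' `rho_m / D` is returned; for `|F - 1| < 1e-8` a first-order expansion of
#' the geometric sum avoids 0/0.
#'
#' @param rho_m Within-deme single-mutant fixation probability, in `[0, 1]`.
#' @param F Relative mutant deme fitness, `> 0`.
#' @param D Number of demes, `>= 1`.
#' @return A probability.
#' @examples
#' fixation_prob_fragmented(0.1, F = 2, D = 3)  # 0.1 * 0.5 / 0.875
#' @export
fixation_prob_fragmented <- function(rho_m, F, D) {
  stopifnot(rho_m >= 0, rho_m <= 1, F > 0, D >= 1)
  if (D == 1) return(rho_m)
  u <- 1 - 1 / F
  if (abs(F - 1) < 1e-8)
    return(rho_m / D * (1 + (D - 1) * u / 2))
  rho_m * u / (1 - F^(-D))
}

#' Effective per-individual fitness in a fragmented population
#'
#' Converts the deme-level fitness into a per-individual effective fitness for
#' demes of equilibrium size `N`: \eqn{f_e = \mathcal{F}^{1/N}}.  Fragmentation
#' makes faster-turnover mutants genuinely disadvantageous (`f_e < 1` when
#' `F < 1`) and slower ones advantageous.
#'
#' @param F Deme fitness, `> 0`.
#' @param N Per-deme equilibrium size, `> 0` (default convention:
#'   [deterministic_equilibrium()]).
#' @return The effective fitness.
#' @examples
#' effective_fitness(0.25, 2)  # 0.5
#' @export
effective_fitness <- function(F, N) {
  stopifnot(F > 0, N > 0)
  F^(1 / N)
}

#' Well-mixed quasi-neutral fixation probability
#'
#' Diffusion-approximation fixation probability of a single quasi-neutral
#' mutant in a well-mixed, stochastically fluctuating (Verhulst-type)
#' population of mean size `N`:
#' \deqn{p_{fix} = \frac{1}{N}\,\frac{2}{\tau + 1}.}
#' Faster-turnover mutants (`tau > 1`) fix less often than neutral ones, but
#' only by a constant factor in `N` — hence *quasi*-neutral.
#'
#' @param N Mean population size, `>= 1`.
#' @param tau Turnover factor, `> 0`.
#' @return A probability.
#' @examples
#' wellmixed_quasineutral_pfix(10, 3)  # 0.05
#' @export
wellmixed_quasineutral_pfix <- function(N, tau) {
  stopifnot(N >= 1, tau > 0)
  2 / (N * (tau + 1))
}

#' Exact quasi-neutral fixation probability in a death-birth Moran process
#'
#' In a death-birth Moran process of constant size `N` an individual is chosen
#' to die proportionally to its death rate (weight `tau` for mutants, 1 for
#' wild types) and is replaced by the offspring of one of the remaining
#' `N - 1` individuals, chosen proportionally to birth rates (same weights).
#' With `j` mutants the backward/forward transition ratio is
#' \deqn{\gamma_j = \frac{j\tau + N - j - 1}{(N - j) + (j - 1)\tau},}
#' and the single-mutant fixation probability is the standard birth-death
#' product form \eqn{1 / (1 + \sum_{k=1}^{N-1} \prod_{j=1}^{k} \gamma_j)}.
#' Remarkably this equals the well-mixed diffusion value
#' `2 / (N (tau + 1))` exactly, for every `N` and `tau`.
#'
#' @param N Population size, `>= 2`.
#' @param tau Turnover factor, `> 0`.
#' @return A probability.
#' @examples
#' moran_db_exact_pfix(20, 2) - wellmixed_quasineutral_pfix(20, 2)  # ~0
#' @export
moran_db_exact_pfix <- function(N, tau) {
  stopifnot(N >= 2, N == round(N), tau > 0)
  j <- seq_len(N - 1)
  gam <- (j * tau + N - j - 1) / ((N - j) + (j - 1) * tau)
  1 / (1 + sum(cumprod(gam)))
}

#' Full coarse-grained theory for one parameter set
#'
#' Computes the within-deme invasion probabilities, the deme fitness, the
#' effective fitness, the system-level fixation probability and the
#' normalization constant `alpha` linking its two printed forms:
#' \deqn{\Pi_1^{frag} = \bar\rho_m \frac{1 - 1/\mathcal{F}}
#'   {1 - 1/\mathcal{F}^D} = \alpha\,
#'   \frac{1 - 1/f_e}{1 - 1/f_e^{N_{tot}}}.}
#' `alpha` is exposed purely as the consistency constant between the two
#' forms (it is independent of the deme number).
#'
#' @param rates A [kinetic_rates()] object.
#' @param config A [deme_config()] object.
#' @param size_measure Per-deme size `N` used in `f_e`:
#'   `"deterministic"` (default, `K (1 - d_w/r_w)`) or `"qsd_mean"` (mean of
#'   the wild-type quasi-stationary distribution).
#' @param include_acceptance Passed to [deme_fitness()].
#' @return An object of class `"coarse_grained"`: list with `rho_m`, `rho_w`,
#'   `F`, `f_e`, `Pi_frag`, `alpha`, `N`, `N_tot` and the inputs.
#' @examples
#' cg <- coarse_grained(kinetic_rates(1, 0.1, tau = 2), deme_config(20, D = 9))
#' cg$Pi_frag < 1 / cg$N_tot  # fragmentation penalizes fast turnover
#' @export
coarse_grained <- function(rates, config,
                           size_measure = c("deterministic", "qsd_mean"),
                           include_acceptance = TRUE) {
  size_measure <- match.arg(size_measure)
  rho_m <- rho_bar(rates, config, "mutant_into_wt")
  rho_w <- rho_bar(rates, config, "wt_into_mutant")
  F <- if (rates$s == 0) rates$tau * rho_m / rho_w
       else deme_fitness(rates, config, include_acceptance)
  N <- if (size_measure == "deterministic")
    deterministic_equilibrium(rates$r_w, rates$d_w, config$K)
  else
    single_type_qsd(rates$r_w, rates$d_w, config$K, config$density)$mean
  N_tot <- config$D * N
  f_e <- effective_fitness(F, N)
  Pi_frag <- fixation_prob_fragmented(rho_m, F, config$D)
  moran_factor <- if (abs(f_e - 1) < 1e-10) 1 / N_tot
                  else (1 - 1 / f_e) / (1 - f_e^(-N_tot))
  alpha <- Pi_frag / moran_factor
  structure(
    list(rho_m = rho_m, rho_w = rho_w, F = F, f_e = f_e, Pi_frag = Pi_frag,
         alpha = alpha, N = N, N_tot = N_tot, rates = rates, config = config),
    class = "coarse_grained"
  )
}

#' @rdname coarse_grained
#' @param x,... Object and further arguments for the print method.
#' @exportS3Method base::print
print.coarse_grained <- function(x, ...) {
  cat(sprintf("Coarse-grained theory (K = %d, D = %d, tau = %g, s = %g)\n",
              x$config$K, x$config$D, x$rates$tau, x$rates$s))
  cat(sprintf("  rho_m = %.6g  rho_w = %.6g\n", x$rho_m, x$rho_w))
  cat(sprintf("  deme fitness F = %.6g   effective fitness f_e = %.6g\n",
              x$F, x$f_e))
  cat(sprintf("  Pi_frag = %.6g   (neutral 1/N_tot = %.6g, N_tot = %.1f)\n",
              x$Pi_frag, 1 / x$N_tot, x$N_tot))
  invisible(x)
}
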