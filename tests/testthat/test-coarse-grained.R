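test_that("deme fitness of identical types is one and fast turnover lowers it", {
  cfg <- base_config(K = 20)
  expect_equal(deme_fitness(base_rates(tau = 1), cfg), 1, tolerance = 1e-10)
  expect_lt(deme_fitness(base_rates(tau = 2), cfg), 1)
  expect_gt(deme_fitness(base_rates(tau = 0.5), cfg), 1)
})

test_that("general-s deme fitness is continuous at s = 0 and sign-correct", {
  cfg <- base_config(K = 20)
  F0 <- deme_fitness(base_rates(tau = 2, s = 0), cfg)
  Feps <- deme_fitness(base_rates(tau = 2, s = 1e-6), cfg)
  expect_equal(Feps, F0, tolerance = 1e-3)
  # a reproductive advantage raises deme fitness, a disadvantage lowers it
  expect_gt(deme_fitness(base_rates(tau = 1, s = 0.01), cfg), 1)
  expect_lt(deme_fitness(base_rates(tau = 1, s = -0.01), cfg), 1)
  # acceptance factors are a small correction, not the effect itself
  Fa <- deme_fitness(base_rates(tau = 2, s = 0.01), cfg,
                     include_acceptance = TRUE)
  Fb <- deme_fitness(base_rates(tau = 2, s = 0.01), cfg,
                     include_acceptance = FALSE)
  expect_equal(Fa, Fb, tolerance = 0.05)
})

test_that("fragmentation into one huge deme washes the effect out", {
  # with the whole capacity in a single large deme the invasion ratio reaches
  # its diffusion value 1/tau and deme fitness returns to neutrality
  F480 <- deme_fitness(base_rates(tau = 2), base_config(K = 480))
  expect_lt(abs(F480 - 1), 0.01)
})

test_that("fragmented fixation probability follows the Moran-type form", {
  expect_equal(fixation_prob_fragmented(0.05, F = 1, D = 10), 0.005)
  expect_equal(fixation_prob_fragmented(0.37, F = 4.2, D = 1), 0.37)
  expect_equal(fixation_prob_fragmented(0.1, F = 2, D = 3), 0.1 * 0.5 / 0.875,
               tolerance = 1e-12)
  # the near-neutral series expansion joins the formula smoothly
  lim <- fixation_prob_fragmented(0.1, F = 1, D = 7)
  for (eps in c(1e-9, -1e-9, 5e-8)) {
    expect_equal(fixation_prob_fragmented(0.1, F = 1 + eps, D = 7), lim,
                 tolerance = 1e-6)
  }
  expect_equal(fixation_prob_fragmented(0.1, F = 1 + 1e-7, D = 7),
               fixation_prob_fragmented(0.1, F = 1 + 1.0000001e-7, D = 7),
               tolerance = 1e-6)
})

test_that("effective fitness is the per-individual root of deme fitness", {
  expect_equal(effective_fitness(1, 18), 1)
  expect_equal(effective_fitness(0.25, 2), 0.5)
  cfg9 <- base_config(K = 20, D = 9, epsilon = 1e-4)
  expect_lt(coarse_grained(base_rates(tau = 5), cfg9)$f_e, 1)
  expect_gt(coarse_grained(base_rates(tau = 0.2), cfg9)$f_e, 1)
})

test_that("well-mixed quasi-neutral closed form evaluates correctly", {
  expect_equal(wellmixed_quasineutral_pfix(100, 1), 0.01)
  expect_equal(wellmixed_quasineutral_pfix(10, 3), 0.05)
  # tau -> 0 limit is bounded by 2/N
  expect_equal(wellmixed_quasineutral_pfix(10, 1e-12), 0.2, tolerance = 1e-10)
})

test_that("death-birth Moran fixation matches brute-force absorption", {
  expect_equal(moran_db_exact_pfix(5, 1), 0.2, tolerance = 1e-12)
  for (N in 3:6) {
    for (tau in c(0.3, 1, 4)) {
      expect_equal(moran_db_exact_pfix(N, tau), moran_db_brute_force(N, tau),
                   tolerance = 1e-12)
    }
  }
})

test_that("coarse-grained bundle is internally consistent", {
  cg <- coarse_grained(base_rates(tau = 2), base_config(K = 20, D = 9,
                                                        epsilon = 1e-4))
  expect_gte(cg$Pi_frag, 0)
  expect_lte(cg$Pi_frag, 1)
  expect_gt(cg$F, 0)
  expect_equal(cg$f_e, cg$F^(1 / cg$N), tolerance = 1e-14)
  expect_equal(cg$N, 18)
  expect_equal(cg$N_tot, 162)
  # the deme-fitness form and the effective-fitness/alpha form agree
  expect_equal(cg$alpha * (1 - 1 / cg$f_e) / (1 - cg$f_e^(-cg$N_tot)),
               cg$Pi_frag, tolerance = 1e-12)
  # alpha is independent of the deme number
  cg2 <- coarse_grained(base_rates(tau = 2), base_config(K = 20, D = 25,
                                                         epsilon = 1e-4))
  expect_equal(cg2$alpha, cg$alpha, tolerance = 1e-6)
  # qsd-based deme size is close to, but distinct from, the deterministic one
  cgq <- coarse_grained(base_rates(tau = 2),
                        base_config(K = 20, D = 9, epsilon = 1e-4),
                        size_measure = "qsd_mean")
  expect_lt(abs(cgq$N - cg$N), 0.5)
})

test_that("unfragmented population: exact single-mutant fixation", {
  r <- base_rates(tau = 1)
  cfg <- base_config(K = 20)
  # a single deme is the D = 1 fragmented system by construction
  expect_equal(nonfragmented_pfix(r, 20), rho_bar(r, cfg), tolerance = 1e-12)
  # neutral fixation at quasi-equilibrium is close to 1/N = 1/18
  expect_lt(abs(nonfragmented_pfix(r, 20) - 1 / 18), 0.005)
  # the solver refuses sizes beyond its guard
  expect_error(nonfragmented_pfix(r, 1000), "guard")
})

test_that("advantageous mutants in large unfragmented populations fix at ~s", {
  p <- nonfragmented_pfix(base_rates(tau = 1, s = 0.01), 480)
  expect_lt(abs(p / 0.01 - 1), 0.1)
})
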