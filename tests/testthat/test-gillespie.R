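test_that("binomial proportion standard error", {
  expect_equal(binomial_se(0, 100), 0)
  expect_equal(binomial_se(50, 100), 0.05)
  expect_equal(binomial_se(1, 4), sqrt(0.25 * 0.75 / 4))
  expect_error(binomial_se(5, 4))
})

test_that("single step respects the event structure of the model", {
  r <- base_rates(tau = 2)
  cfg <- deme_config(K = 20, D = 1)
  # at carrying capacity the division propensity vanishes: only deaths
  set.seed(5)
  for (i in 1:25) {
    st <- init_state(cfg, x = 20, y = 0)
    out <- gillespie_step(st, r, cfg)
    expect_equal(out$event$type, "wt_death")
    expect_equal(out$state$x, 19L)
  }
})

test_that("counts stay within the simplex under crowd-controlled migration", {
  r <- base_rates(tau = 2, s = 0.01)
  cfg <- deme_config(K = 15, D = 3, epsilon = 0.2, mu = 0.01)
  set.seed(8)
  st <- init_state(cfg, x = c(7, 15, 2), y = c(3, 0, 1))
  for (i in 1:600) {
    if (sum(deme_propensity(st$x, st$y, r, cfg)) <= 0) break
    out <- gillespie_step(st, r, cfg)
    st <- out$state
    expect_true(all(st$x >= 0) && all(st$y >= 0))
    expect_true(all(st$x + st$y <= 15))
    expect_gt(out$dt, 0)
  }
  expect_gt(st$t, 0)
})

test_that("with one deme a migration draw aborts the birth", {
  r <- base_rates()
  cfg <- deme_config(K = 20, D = 1, epsilon = 1)  # every division migrates
  set.seed(11)
  st <- init_state(cfg, x = 10, y = 0)
  xmax <- 10L
  for (i in 1:300) {
    if (sum(deme_propensity(st$x, st$y, r, cfg)) <= 0) break
    st <- gillespie_step(st, r, cfg)$state
    xmax <- max(xmax, st$x)
  }
  expect_identical(xmax, 10L)  # births never land, the deme can only shrink
})

test_that("certain mutation turns the first wild-type division mutant", {
  r <- base_rates()
  cfg <- deme_config(K = 20, D = 1, mu = 1)
  set.seed(13)
  st <- init_state(cfg, x = 5, y = 0)
  repeat {
    out <- gillespie_step(st, r, cfg)
    st <- out$state
    if (out$event$type == "wt_division") {
      expect_true(out$event$mutant_offspring)
      expect_identical(st$y[1], 1L)
      break
    }
  }
})

test_that("fixation experiments are reproducible from their seed", {
  r <- base_rates(tau = 2)
  cfg <- deme_config(K = 20, D = 2, epsilon = 1e-4)
  a <- run_fixation_experiment(r, cfg, n_runs = 300, seed = 42)
  b <- run_fixation_experiment(r, cfg, n_runs = 300, seed = 42)
  d <- run_fixation_experiment(r, cfg, n_runs = 300, seed = 43)
  expect_identical(a$n_fixed, b$n_fixed)
  expect_identical(a$n_lost, b$n_lost)
  expect_equal(a$p_hat, a$n_fixed / a$n_runs)
  expect_equal(a$se, binomial_se(a$n_fixed, a$n_runs))
  # a different seed gives a different trajectory set (not a different law)
  expect_false(identical(c(a$n_fixed, a$n_lost), c(d$n_fixed, d$n_lost)))
})

test_that("the compiled simulator rejects custom density shapes", {
  cfg <- deme_config(K = 10, density = density_dependence(
    b = function(x, K) pmax(1 - (x / K)^2, 0) * as.numeric(x < K)
  ))
  expect_error(run_fixation_experiment(base_rates(), cfg, 10),
               "default density")
})

test_that("isolated-deme occupancy matches the quasi-stationary law", {
  w <- simulated_occupancy(1, 0.1, 20, n_events = 5e5, seed = 21)
  q <- single_type_qsd(1, 0.1, 20)
  tv <- 0.5 * sum(abs(w[-1] - q$weights))
  expect_lt(tv, 0.02)
})

test_that("single-deme protocol reproduces the exact invasion probability", {
  r <- base_rates(tau = 2)
  cfg <- base_config(K = 20, D = 1, epsilon = 0)
  ex <- run_fixation_experiment(r, cfg, n_runs = 4000, seed = 31)
  exact <- rho_bar(r, cfg)
  expect_lt(abs(ex$p_hat - exact), 4 * max(ex$se, sqrt(exact / 4000)))
})

test_that("mutation time series: no mutation means no mutants", {
  r <- mut_rates(tau = 1, s = 0.01)
  cfg0 <- deme_config(K = 20, D = 2, epsilon = 1e-4, mu = 0)
  ts0 <- run_mutation_experiment(r, cfg0, t_max = 300, sample_dt = 10,
                                 seed = 3)
  expect_true(all(ts0$mutant == 0))
  expect_true(all(diff(ts0$time) > 0))
  expect_true(all(ts0$wildtype >= 0))

  # with a high mutation rate mutants appear quickly
  cfg1 <- deme_config(K = 20, D = 2, epsilon = 1e-4, mu = 0.01)
  ts1 <- run_mutation_experiment(r, cfg1, t_max = 300, sample_dt = 10,
                                 seed = 3)
  expect_gt(max(ts1$mutant), 0)
})
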