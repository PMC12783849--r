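test_that("mutant rates follow the turnover/selection scaling", {
  r0 <- kinetic_rates(5, 0.5, tau = 1, s = 0)
  expect_equal(r0$r_m, 5)
  expect_equal(r0$d_m, 0.5)

  r1 <- kinetic_rates(5, 0.5, tau = 5, s = 0.01)
  expect_equal(r1$r_m, 25.25)
  expect_equal(r1$d_m, 2.5)

  r2 <- kinetic_rates(1, 0.1, tau = 0.2, s = -0.01)
  expect_equal(r2$r_m, 0.198)
  expect_equal(r2$d_m, 0.02)

  # quasi-neutral mutants preserve the lifetime reproductive output ratio
  r3 <- kinetic_rates(2, 0.3, tau = 3.7, s = 0)
  expect_true(is_quasi_neutral(r3))
  expect_equal(r3$d_m / r3$r_m, r3$d_w / r3$r_w)
  expect_false(is_quasi_neutral(r1))
})

test_that("invalid kinetic parameters are rejected", {
  expect_error(kinetic_rates(0, 0.1), "r_w")
  expect_error(kinetic_rates(-1, 0.1), "r_w")
  expect_error(kinetic_rates(1, -0.1), "d_w")
  expect_error(kinetic_rates(1, 0.1, tau = 0), "tau")
  expect_error(kinetic_rates(1, 0.1, tau = -2), "tau")
  expect_error(kinetic_rates(1, 0.1, s = -1), "s")
})

test_that("deme propensity matches the density-regulated rate sum", {
  r <- kinetic_rates(5, 0.5, tau = 1, s = 0)
  cfg <- deme_config(K = 20)
  # at carrying capacity only the death term survives
  expect_equal(deme_propensity(20, 0, r, cfg), 10)
  expect_equal(deme_propensity(10, 0, r, cfg), 30)  # 5*10*0.5 + 0.5*10
  expect_equal(deme_propensity(0, 0, r, cfg), 0)
  expect_error(deme_propensity(-1, 0, r, cfg), "non-negative")
  expect_error(deme_propensity(1.5, 0, r, cfg), "non-negative")
})

test_that("propensity equals the sum of the four event rates on every state", {
  r <- kinetic_rates(1.3, 0.2, tau = 2.5, s = 0.04)
  cfg <- deme_config(K = 10)
  for (x in 0:10) for (y in 0:(10 - x)) {
    expect_equal(deme_propensity(x, y, r, cfg),
                 sum(deme_event_rates(x, y, r, cfg)))
  }
})

test_that("common turnover rescaling scales pure-mutant propensities by tau", {
  cfg <- deme_config(K = 15)
  tau <- 3
  slow <- kinetic_rates(1, 0.1, tau = 1, s = 0)
  fast <- kinetic_rates(1, 0.1, tau = tau, s = 0)
  y <- 0:15
  expect_equal(deme_propensity(0, y, fast, cfg),
               tau * deme_propensity(0, y, slow, cfg))
})

test_that("deterministic equilibrium is the logistic fixed point", {
  expect_equal(deterministic_equilibrium(1, 0.1, 20), 18)
  expect_equal(deterministic_equilibrium(1, 0, 20), 20)
  expect_error(deterministic_equilibrium(1, 1, 20), "equilibrium")
  expect_error(deterministic_equilibrium(1, 1.5, 20), "equilibrium")
})

test_that("configuration and density-shape constraints are enforced", {
  expect_error(deme_config(K = 1), "K")
  expect_error(deme_config(K = 20, D = 0), "D")
  expect_error(deme_config(K = 20, epsilon = 1.2), "epsilon")
  expect_error(deme_config(K = 20, mu = -0.1), "mu")
  # b(0) must be 1
  expect_error(
    deme_config(K = 10, density = density_dependence(b = function(x, K) {
      0.5 * pmax(1 - x / K, 0)
    })),
    "b\\(0\\)"
  )
  # b must be non-increasing
  expect_error(
    deme_config(K = 10, density = density_dependence(b = function(x, K) {
      ifelse(x == 1, 1.5, pmax(1 - x / K, 0))
    })),
    "non-increasing"
  )
  # delta must be non-decreasing
  expect_error(
    deme_config(K = 10, density = density_dependence(delta = function(x, K) {
      1 - x / (2 * K)
    })),
    "non-decreasing"
  )
  # a valid custom pair passes
  cfg <- deme_config(K = 10, density = density_dependence(
    b = function(x, K) pmax(1 - (x / K)^2, 0) * as.numeric(x < K),
    delta = function(x, K) 1 + x / K
  ))
  expect_s3_class(cfg, "deme_config")
})

test_that("parameter sets round-trip through JSON", {
  r <- kinetic_rates(1, 0.1, tau = 2, s = 0.01)
  cfg <- deme_config(K = 20, D = 9, epsilon = 1e-4, mu = 1e-6)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(r, cfg, path)
  back <- read_params(path)
  expect_identical(back$rates, r)
  expect_equal(back$config$K, cfg$K)
  expect_equal(back$config$D, cfg$D)
  expect_equal(back$config$epsilon, cfg$epsilon)
  expect_equal(back$config$mu, cfg$mu)
  expect_equal(back$config$migration_model, cfg$migration_model)
})
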