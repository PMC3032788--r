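test_that("negative rate draws reverse the reaction direction", {
  sys <- ab_system()
  set.seed(1)  # first rnorm draw is negative
  k1 <- stats::rnorm(1)
  expect_lt(k1, 0)
  set.seed(1)
  out <- sample_rate_constants(sys, kinetics_config())
  expect_identical(out$reactions$substrates[[1]], "B")
  expect_identical(out$reactions$products[[1]], "A")
  expect_equal(out$reactions$rate[1], abs(k1))
  # direction change re-derives the flow boundary
  expect_identical(out$sources, "B")
  expect_identical(out$sinks, "A")

  zero <- sample_rate_constants(sys, kinetics_config(rate_sd = 0))
  expect_equal(zero$reactions$rate, 0)
})

test_that("initial states are clipped normal draws", {
  sys <- chain_system()
  exact <- sample_initial_state(sys, kinetics_config(init_mean = 1, init_sd = 0))
  expect_equal(as.numeric(exact), rep(1, 3))

  all_clipped <- sample_initial_state(
    sys, kinetics_config(init_mean = -5, init_sd = 0.1))
  expect_equal(as.numeric(all_clipped), rep(0, 3))

  set.seed(9)
  draws <- replicate(300, as.numeric(
    sample_initial_state(sys, kinetics_config(init_mean = 1, init_sd = 0.5))))
  expect_true(all(draws >= 0))
  expect_equal(mean(draws), 1, tolerance = 0.05)
})

test_that("the mass-action derivative matches hand evaluation", {
  sys <- ab_system(rate = 1)
  d <- time_derivative(state_of(sys, c(1, 0)), sys, closed_kinetics())
  expect_equal(d, c(A = -1, B = 1))

  # 2A -> B at c_A = 2: rate k c_A^2 = 4, A loses 2 per event
  dim <- dimer_system(rate = 1)
  d2 <- time_derivative(state_of(dim, c(2, 0)), dim, closed_kinetics())
  expect_equal(d2, c(A = -8, B = 4))

  # mass balance of the full derivative, flows included, on a random system
  sys3 <- prepared_system(13, generator_config(n_reactions = 80L))
  st <- sample_initial_state(sys3, kinetics_config())
  d3 <- time_derivative(st, sys3, kinetics_config())
  expect_equal(sum(d3 * sys3$molecules$mass), 0, tolerance = 1e-10)

  expect_error(time_derivative(
    concentration_state(c(X = 1, Y = 1)), sys, closed_kinetics()),
    "match the system")
})

test_that("euler steps advance, clip and preserve fixed points", {
  sys <- ab_system(rate = 1)
  s1 <- euler_step(state_of(sys, c(1, 0)), sys, dt = 0.01,
                   config = closed_kinetics())
  expect_equal(as.numeric(s1), c(0.99, 0.01))
  expect_equal(attr(s1, "time"), 0.01)

  # overshoot past zero is clipped
  fast <- ab_system(rate = 200)
  s2 <- euler_step(state_of(fast, c(0.1, 0)), fast, dt = 0.01,
                   config = closed_kinetics())
  expect_equal(as.numeric(s2), c(0, 0.2))

  # an exact fixed point does not move
  s3 <- euler_step(state_of(sys, c(0, 1)), sys, dt = 0.01,
                   config = closed_kinetics())
  expect_equal(as.numeric(s3), c(0, 1))
})

test_that("relaxation stops at the first step satisfying the criterion", {
  sys <- ab_system(rate = 1)
  cfg <- closed_kinetics(dt = 0.01, eps = 1e-8)
  at_eq <- relax(state_of(sys, c(0, 1)), sys, cfg)
  expect_true(at_eq$converged)
  expect_equal(at_eq$steps, 1L)
  expect_equal(at_eq$tau, 0.01)

  tr <- relax(state_of(sys, c(1, 0)), sys, cfg)
  expect_true(tr$converged)
  expect_equal(as.numeric(tr$final_state), c(0, 1), tolerance = 1e-5)

  # a tighter tolerance cannot converge earlier
  tr_loose <- relax(state_of(sys, c(1, 0)), sys, closed_kinetics(eps = 1e-4))
  expect_gte(tr$tau, tr_loose$tau)

  # hitting the cap flags non-convergence with tau undefined
  capped <- relax(state_of(sys, c(1, 0)), sys,
                  closed_kinetics(eps = 1e-12, max_steps = 10))
  expect_false(capped$converged)
  expect_equal(capped$steps, 10L)
  expect_true(is.na(capped$tau))
})

test_that("euler integration of A -> B shows first-order convergence", {
  sys <- ab_system(rate = 1)
  errs <- vapply(c(0.1, 0.01, 0.001), function(dt) {
    st <- state_of(sys, c(1, 0))
    tr <- relax(st, sys, closed_kinetics(dt = dt, eps = 1e-300,
                                         max_steps = round(1 / dt)))
    abs(as.numeric(tr$final_state)[1] - exp(-1))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  ratio <- errs[1:2] / errs[2:3]
  expect_true(all(ratio > 5 & ratio < 20))
})

test_that("the compiled integrator agrees with stepwise euler_step", {
  sys <- prepared_system(21, generator_config(n_reactions = 60L))
  cfg <- kinetics_config(dt = 0.01)
  set.seed(21)
  st <- sample_initial_state(sys, cfg)
  manual <- st
  for (i in 1:50) manual <- euler_step(manual, sys, cfg$dt, cfg)
  fast <- relax(st, sys, kinetics_config(dt = 0.01, eps = 1e-300,
                                         max_steps = 50))
  expect_equal(as.numeric(fast$final_state), as.numeric(manual),
               tolerance = 1e-12)
  # determinism of the compiled path
  again <- relax(st, sys, kinetics_config(dt = 0.01, eps = 1e-300,
                                          max_steps = 50))
  expect_identical(as.numeric(fast$final_state),
                   as.numeric(again$final_state))
})

test_that("total mass is the atom-weighted concentration sum", {
  water <- water_system()
  st <- state_of(water, c(0, 0, 2))  # only H2O at concentration 2
  expect_equal(total_mass(st, water), 6)
  expect_equal(total_mass(state_of(water, c(0, 0, 0)), water), 0)
})

test_that("closed and open systems conserve total mass while integrating", {
  # closed: stoichiometry alone (lambda = 0)
  sys <- prepared_system(31, generator_config(n_reactions = 60L))
  set.seed(31)
  st <- sample_initial_state(sys, kinetics_config())
  m0 <- total_mass(st, sys)
  tr <- relax(st, sys, closed_kinetics(eps = 1e-300, max_steps = 2000))
  expect_equal(total_mass(tr$final_state, sys) / m0, 1, tolerance = 1e-12)

  # open: inflow is tied to outflow mass per unit time
  tr2 <- relax(st, sys, kinetics_config(eps = 1e-300, max_steps = 2000))
  expect_equal(total_mass(tr2$final_state, sys) / m0, 1, tolerance = 1e-9)
})
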