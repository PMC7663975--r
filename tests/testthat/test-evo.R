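test_that("the CCC moves linearly from its onset", {
  expect_equal(ccc_position(environment_spec(c(0.2, 0)), 10), c(2, 0))
  expect_equal(ccc_position(environment_spec(c(0.2, 0), onset = 3), 3),
               c(0, 0))
  expect_equal(ccc_position(environment_spec(c(0, 0.05)), 32), c(0, 1.6))
  # before the onset the CCC stays put
  expect_equal(ccc_position(environment_spec(0.5, onset = 5), 2), 0)
})

test_that("an adaptive step moves a lagging species toward the CCC by dt N* S", {
  p <- model_params(D = 1)
  co <- ecological_equilibrium(community(-1, 1), 0, p)
  out <- adaptive_step(co, 0, p)
  expect_equal(out$phenotypes[1, 1] - co$phenotypes[1, 1],
               0.01 * exp(-1 / 4) * 1)
  expect_equal(out$time, co$time + p$dt)
  expect_equal(out$populations, co$populations)
  expect_equal(n_species(out), n_species(co))
  # at the CCC with symmetric competition nothing moves
  at0 <- ecological_equilibrium(community(0, 1), 0, p)
  expect_equal(adaptive_step(at0, 0, p)$phenotypes[1, 1], 0)
})

test_that("the simulated lag follows the reduced scalar lag ODE", {
  skip_if_not_installed("deSolve")
  # single species, B = 0, D = 1: d(lag)/dt = V_C - exp(-lag^4/4) lag^3
  p <- model_params(D = 1)
  V <- 0.6
  env <- environment_spec(V)
  tr <- run_epoch(community(0, 1), env, schedule(8, FALSE, 2), p)
  lag_sim <- ccc_position(env, tr$community$time) - tr$community$phenotypes[1, 1]
  ode <- deSolve::ode(0, c(0, 8), function(t, d, pp)
    list(V - exp(-d^4 / 4) * d^3), NULL, rtol = 1e-10, atol = 1e-12)
  expect_equal(lag_sim, unname(ode[2, 2]), tolerance = 5 * p$dt)
})

test_that("below u_max a single species settles at the stable steady lag", {
  p <- model_params(D = 1)
  for (V in c(0.2, 0.5, 0.8)) {
    env <- environment_spec(V)
    tr <- run_epoch(community(0, 1), env,
                    schedule(30, FALSE, 10), p)
    expect_equal(tr$outcome, "survived")
    lag <- ccc_position(env, tr$community$time) - tr$community$phenotypes[1, 1]
    expect_equal(lag, steady_lag(V), tolerance = 1e-3)
  }
})

test_that("above u_max a single species is dragged to extinction", {
  p <- model_params(D = 1)
  tr <- run_epoch(community(0, 1), environment_spec(2),
                  schedule(50, FALSE, 10), p)
  expect_equal(tr$outcome, "extinct")
  expect_true(is.finite(tr$t_ext))
  expect_equal(n_species(tr$community), 0L)
  expect_true(tr$t_ext < 50)
})

test_that("diversification events fire every split_interval time units", {
  set.seed(91)
  p <- model_params(D = 1, sigma = 0.5)
  co <- ecological_equilibrium(community(0, 1), 0, p)
  env <- environment_spec(0)
  tr <- run_epoch(co, env, schedule(35, TRUE, record_every = 5,
                                    keep_snapshots = TRUE), p)
  m_at <- vapply(tr$snapshots, n_species, integer(1))
  t_at <- tr$stats$t
  # splits occur at t = 10, 20, 30: m recorded just after each event
  # exceeds m recorded just before the first event
  expect_equal(m_at[t_at == 5], 1L)
  expect_gte(m_at[t_at == 15], 2L)
  expect_gte(m_at[t_at == 35], m_at[t_at == 15])
})

test_that("with diversification off the species count never increases", {
  set.seed(92)
  p <- model_params(D = 2, sigma = 0.5, B = matrix(rnorm(4), 2, 2))
  co <- random_community(2, 5)
  tr <- run_epoch(co, environment_spec(c(0.6, 0)),
                  schedule(20, FALSE, record_every = 1), p)
  expect_true(all(diff(tr$stats$m) <= 0))
})

test_that("a zero-velocity saturated run keeps its diversity", {
  set.seed(93)
  p <- model_params(D = 1, sigma = 0.5)
  rep1 <- burn_in_replica(93, p, t_star = 150, sample_B = FALSE)
  m0 <- rep1$community$m_sat
  tr <- run_epoch(rep1$community, environment_spec(0),
                  schedule(50, TRUE, record_every = 10), p)
  expect_gte(n_species(merge_close_species(tr$community,
                                           p$merge_distance, p)), m0 - 1L)
})
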