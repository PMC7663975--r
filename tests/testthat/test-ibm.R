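test_that("the CCC speed rescaling carries the sigma_mu^2 K0 / 2 factor", {
  ib <- ibm_params()
  expect_equal(rescale_velocity(0.2, ib), 9e-4)
  expect_equal(rescale_velocity(1, ib), 4.5e-3)
  expect_equal(rescale_velocity(0.2, ibm_params(sigma_mu = 0)), 0)
})

test_that("death rates equal the competitive load over K0 K", {
  # two individuals at the CCC and at distance 1: hand-computed rates,
  # self-competition included
  p <- model_params(D = 1, sigma = 0.5)
  ib <- ibm_params(K0 = 1000, sigma_mu = 0)
  X <- matrix(c(0, 1), ncol = 1)
  A <- ecoevosim:::alpha_matrix(X, 0, p)
  S <- colSums(A)
  K <- ecoevosim:::cc_K(X, 0, p)
  d <- S / (ib$K0 * K)
  expect_equal(d[1], (1 + exp(-2)) / 1000)
  expect_equal(d[2], (1 + exp(-2)) / (1000 * exp(-1 / 4)))
  # a lone individual at the CCC dies at rate 1/K0
  expect_equal(1 / (ib$K0 * 1), 0.001)
})

test_that("a monomorphic population fluctuates around K0 K", {
  # birth rate 1 vs death rate n/(K0 K) balance at n = K0 K
  set.seed(121)
  p <- model_params(D = 1, sigma = 0.5)
  ib <- ibm_params(K0 = 300, sigma_mu = 0)  # no mutation: strictly monomorphic
  env <- environment_spec(0)
  run <- run_ibm(matrix(0, 300, 1), p, ib, env, duration = 25,
                 record_every = 1)
  burn <- run$times >= 5
  expect_false(run$extinct)
  expect_equal(mean(run$counts[burn]), 300, tolerance = 0.05)
})

test_that("a displaced population equilibrates at the local carrying capacity", {
  set.seed(122)
  p <- model_params(D = 1, sigma = 0.5)
  ib <- ibm_params(K0 = 400, sigma_mu = 0)
  K <- carrying_capacity(0.9, 0, p)
  n0 <- round(400 * K)
  run <- run_ibm(matrix(0.9, n0, 1), p, ib, environment_spec(0),
                 duration = 20, record_every = 1)
  burn <- run$times >= 5
  expect_equal(mean(run$counts[burn]), 400 * K, tolerance = 0.08)
})

test_that("mutation offsets spread a clonal population", {
  set.seed(123)
  p <- model_params(D = 2, sigma = 0.5)
  ib <- ibm_params(K0 = 150, sigma_mu = 0.02)
  run <- run_ibm(matrix(0, 150, 2), p, ib, environment_spec(c(0, 0)),
                 duration = 10, record_every = 10)
  final <- run$state
  expect_gt(nrow(final), 0)
  expect_gt(stats::sd(final[, 1]), 0)
})

test_that("individuals cluster into species by transitive closure", {
  one <- matrix(0.3, 50, 2)
  co <- cluster_individuals(one, 0.1, K0 = 1000)
  expect_equal(n_species(co), 1L)
  expect_equal(co$populations, 0.05)
  expect_equal(co$phenotypes[1, ], c(0.3, 0.3))
  # two groups a unit apart stay separate at cutoff 0.1
  two <- rbind(matrix(0, 30, 2), matrix(1, 20, 2))
  co2 <- cluster_individuals(two, 0.1, K0 = 1000)
  expect_equal(n_species(co2), 2L)
  expect_equal(sort(co2$populations), c(0.02, 0.03))
  # a chain within the cutoff is one species
  chain <- matrix(c(0, 0.09, 0.18, 0, 0, 0), 3, 2)
  expect_equal(n_species(cluster_individuals(chain, 0.1)), 1L)
  # normalisation: 2000 individuals at K0 = 1000 is density 2
  big <- matrix(0, 2000, 1)
  expect_equal(cluster_individuals(big, 0.1, 1000)$populations, 2)
})

test_that("the individual-based and density models agree on branching", {
  # sigma < sigma_K is disruptive: a clonal population splits into clusters,
  # as the split/merge procedure does in the density model
  set.seed(124)
  p <- model_params(D = 1, sigma = 0.35)
  ib <- ibm_params(K0 = 150, sigma_mu = 0.015)
  run <- run_ibm(matrix(0, 150, 1), p, ib, environment_spec(0),
                 duration = 120, record_every = 60)
  final <- cluster_individuals(run$state, 0.15, ib$K0)
  expect_gt(n_species(final), 1L)
  # densities are comparable after the 1/K0 normalisation: the diversified
  # population exceeds the single-species carrying capacity
  expect_gt(sum(final$populations), 1)
})
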