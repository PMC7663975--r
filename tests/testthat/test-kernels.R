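test_that("carrying capacity matches direct evaluation and is maximal at the CCC", {
  p1 <- model_params(D = 1)
  expect_equal(carrying_capacity(0, 0, p1), 1)
  expect_equal(carrying_capacity(1, 0, p1), exp(-1 / 4))
  p2 <- model_params(D = 2)
  expect_equal(carrying_capacity(c(1, 1), c(0, 0), p2), exp(-1 / 2))
  expect_equal(carrying_capacity(c(0.3, -0.7), c(0.3, -0.7), p2), 1)
  expect_error(carrying_capacity(c(1, 2), 0, p1), "length D")
})

test_that("carrying capacity is translation invariant and in (0, 1]", {
  set.seed(11)
  p <- model_params(D = 3, sigma_K = 1.3)
  for (i in 1:20) {
    x <- rnorm(3); ccc <- rnorm(3); shift <- rnorm(3)
    k <- carrying_capacity(x, ccc, p)
    expect_gt(k, 0)
    expect_lte(k, 1)
    expect_equal(carrying_capacity(x + shift, ccc + shift, p), k)
  }
})

test_that("competition kernel matches direct evaluation, self-competition is 1", {
  p <- model_params(D = 1, sigma = 0.5)
  expect_equal(competition_kernel(1, 0, 0, p), exp(-2))
  expect_equal(competition_kernel(0.37, 0.37, -1.2, p), 1)
  pb <- model_params(D = 1, sigma = 0.5, B = matrix(1, 1, 1))
  expect_equal(competition_kernel(1, 0, 0, pb), exp(-1))
  # asymmetric deviation factor is taken from the effector argument
  expect_equal(competition_kernel(0, 1, 0, pb), exp(-2))
})

test_that("kernel is symmetric for B = 0 and agrees with the scalar oracle", {
  set.seed(21)
  for (i in 1:10) {
    D <- sample(1:3, 1)
    sig <- runif(D, 0.3, 0.9)
    B <- if (i %% 2) matrix(0, D, D) else matrix(rnorm(D * D), D, D)
    p <- model_params(D = D, sigma = sig, B = B)
    x <- rnorm(D); y <- rnorm(D); ccc <- 0.3 * rnorm(D)
    expect_equal(competition_kernel(x, y, ccc, p),
                 oracle_alpha(x, y, ccc, B, sig), tolerance = 1e-12)
    if (all(B == 0))
      expect_equal(competition_kernel(x, y, ccc, p),
                   competition_kernel(y, x, ccc, p))
  }
})

test_that("vectorised competition matrix agrees with pairwise kernel calls", {
  set.seed(31)
  p <- model_params(D = 2, sigma = c(0.4, 0.7), B = matrix(rnorm(4), 2, 2))
  X <- matrix(rnorm(10), 5, 2)
  ccc <- c(0.1, -0.2)
  A <- ecoevosim:::alpha_matrix(X, ccc, p)
  for (s in 1:5) for (r in 1:5)
    expect_equal(A[s, r], competition_kernel(X[s, ], X[r, ], ccc, p),
                 tolerance = 1e-12)
})

test_that("invasion fitness is zero for a resident and matches the formula", {
  p <- model_params(D = 1, sigma = 0.5)
  res <- ecological_equilibrium(community(0, 1), 0, p)
  expect_equal(invasion_fitness(res, 0, 0, p), 0)
  expect_equal(invasion_fitness(res, 1, 0, p), 1 - exp(-2) / exp(-1 / 4))
  expect_error(invasion_fitness(community(matrix(0, 0, 1), numeric(0)), 0.5,
                                0, p),
               "empty")
})

test_that("invasion fitness agrees with the oracle on an asymmetric community", {
  p <- model_params(D = 1, sigma = 0.5, B = matrix(0.5, 1, 1))
  co <- ecological_equilibrium(community(0.3, 0.5), 0, p)
  f <- invasion_fitness(co, 0.4, 0, p)
  expect_equal(f, oracle_fitness(co$phenotypes, co$populations, 0.4, 0, p),
               tolerance = 1e-12)
})

test_that("selection gradient is the finite-difference gradient of invasion fitness", {
  set.seed(41)
  for (i in 1:12) {
    D <- sample(1:3, 1)
    p <- model_params(D = D, sigma = runif(D, 0.3, 0.8),
                      B = matrix(rnorm(D * D), D, D))
    ccc <- 0.2 * rnorm(D)
    co <- ecological_equilibrium(random_community(D, sample(1:4, 1)), ccc, p)
    if (n_species(co) == 0L) next
    r <- sample(n_species(co), 1)
    S <- selection_gradient(co, r, ccc, p)
    fd <- fd_gradient(co, r, ccc, p)
    expect_equal(S, fd, tolerance = 1e-6)
  }
})

test_that("single-species gradient reduces to the cubic restoring force", {
  # with B = 0 and one species, N* S = -K(x) (x - x_c)^3 / sigma_K^4
  p <- model_params(D = 1)
  co <- ecological_equilibrium(community(-1, 0.5), 0, p)
  S <- selection_gradient(co, 1, 0, p)
  expect_equal(co$populations * S, exp(-1 / 4) * 1)
  expect_equal(S, 1)  # d^3 with lag d = 1
  # at the CCC the gradient vanishes
  co0 <- ecological_equilibrium(community(0, 1), 0, p)
  expect_equal(selection_gradient(co0, 1, 0, p), 0)
  expect_error(selection_gradient(co0, 2, 0, p), "index")
})
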