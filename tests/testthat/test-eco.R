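test_that("a lone species equilibrates at its carrying capacity", {
  p <- model_params(D = 1, sigma = 0.5)
  eq <- ecological_equilibrium(community(0.5, 0.02), 0, p)
  expect_equal(eq$populations, carrying_capacity(0.5, 0, p),
               tolerance = 1e-10)
  p2 <- model_params(D = 2)
  eq2 <- ecological_equilibrium(community(matrix(c(0.3, -0.4), 1), 1.7),
                                c(0, 0), p2)
  expect_equal(eq2$populations, carrying_capacity(c(0.3, -0.4), c(0, 0), p2),
               tolerance = 1e-10)
})

test_that("a symmetric pair equilibrates at K/(1 + alpha)", {
  p <- model_params(D = 1, sigma = 0.5)
  eq <- ecological_equilibrium(
    community(matrix(c(-0.5, 0.5), ncol = 1), c(0.3, 0.3)), 0, p)
  expected <- exp(-1 / 64) / (1 + exp(-2))
  expect_equal(eq$populations, rep(expected, 2), tolerance = 1e-8)
})

test_that("species with carrying capacity below the cutoff are pruned", {
  p <- model_params(D = 1, sigma = 0.5)
  # lone species at distance 3: K = exp(-81/4) ~ 1.6e-9 < 1e-6
  eq <- ecological_equilibrium(community(3, 0.5), 0, p)
  expect_equal(n_species(eq), 0L)
  # empty in, empty out
  eq0 <- ecological_equilibrium(community(matrix(0, 0, 1), numeric(0)), 0, p)
  expect_equal(n_species(eq0), 0L)
})

test_that("equilibration is idempotent and leaves the clock unchanged", {
  set.seed(52)
  p <- model_params(D = 2, sigma = 0.5, B = matrix(rnorm(4), 2, 2))
  co <- random_community(2, 4)
  co$time <- 7.25
  eq1 <- ecological_equilibrium(co, c(0.1, 0), p)
  eq2 <- ecological_equilibrium(eq1, c(0.1, 0), p)
  expect_equal(eq1$time, 7.25)
  expect_equal(eq2$populations, eq1$populations, tolerance = p$eco_tol)
  expect_true(all(eq1$populations > p$extinction_threshold))
})

test_that("equilibria agree with the linear-solve oracle for B = 0, m <= 4", {
  set.seed(61)
  for (i in 1:8) {
    D <- sample(1:2, 1)
    p <- model_params(D = D, sigma = 0.6)
    m <- sample(2:4, 1)
    # spread species out so all survive and no cluster degeneracy arises
    X <- matrix(stats::runif(m * D, -1, 1), m, D)
    X[, 1] <- seq(-0.9, 0.9, length.out = m)
    co <- ecological_equilibrium(community(X, rep(0.5, m)), rep(0, D), p)
    if (n_species(co) < m) next  # oracle applies to the full survivor set
    expect_equal(co$populations,
                 oracle_linear_equilibrium(co$phenotypes, rep(0, D), p),
                 tolerance = 1e-7)
    expect_lt(eco_residual(co, rep(0, D), p), p$eco_tol * 1.01)
  }
})

test_that("equilibration matches the logistic ODE flow integrated by deSolve", {
  skip_if_not_installed("deSolve")
  set.seed(71)
  p <- model_params(D = 1, sigma = 0.5)
  X <- matrix(c(-0.8, -0.1, 0.6), ncol = 1)
  N0 <- c(0.2, 0.9, 0.4)
  A <- outer(seq_len(3), seq_len(3), Vectorize(function(s, r)
    competition_kernel(X[s, ], X[r, ], 0, p)))
  K <- sapply(1:3, function(r) carrying_capacity(X[r, ], 0, p))
  out <- deSolve::ode(N0, c(0, 500), function(t, N, pp)
    list(N * (1 - colSums(A * N) / K)), NULL,
    rtol = 1e-10, atol = 1e-12)
  eq <- ecological_equilibrium(community(X, N0), 0, p)
  expect_equal(eq$populations, unname(out[2, -1]), tolerance = 1e-6)
})

test_that("fresh split halves survive equilibration as a quasi-equilibrated cluster", {
  # the intra-pair mode is slower than evolution; it must be left to the
  # evolutionary dynamics rather than resolved ecologically
  set.seed(81)
  p <- model_params(D = 2, sigma = 0.5, B = matrix(rnorm(4), 2, 2))
  co <- ecological_equilibrium(community(matrix(c(0.2, -0.1), 1), 0.5),
                               c(0, 0), p)
  cs <- split_random_species(co, p)
  eq <- ecological_equilibrium(cs, c(0, 0), p)
  expect_equal(n_species(eq), 2L)
  expect_equal(sum(eq$populations), sum(co$populations), tolerance = 1e-3)
})
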