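# Independent scalar-loop oracles for the kernel formulas and equilibria.
# Deliberately naive (explicit loops, no shared code with the package
# internals) so they can serve as a second route.

oracle_K <- function(x, ccc, sigma_K) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - ccc[i])^4
  exp(-s / (4 * sigma_K^4))
}

oracle_alpha <- function(x, y, ccc, B, sigma) {
  a <- 0
  for (i in seq_along(x)) for (j in seq_along(x))
    a <- a + B[i, j] * (x[i] - y[i]) * (x[j] - ccc[j])
  g <- 0
  for (i in seq_along(x)) g <- g + (x[i] - y[i])^2 / (2 * sigma[i]^2)
  exp(a - g)
}

oracle_fitness <- function(X, N, mutant, ccc, p) {
  s <- 0
  for (r in seq_len(nrow(X)))
    s <- s + oracle_alpha(X[r, ], mutant, ccc, p$B, p$sigma) * N[r]
  1 - s / oracle_K(mutant, ccc, p$sigma_K)
}

# equilibrium of the survivor linear system sum_s alpha_sr N_s = K_r
oracle_linear_equilibrium <- function(X, ccc, p) {
  m <- nrow(X)
  A <- matrix(0, m, m)
  for (s in seq_len(m)) for (r in seq_len(m))
    A[s, r] <- oracle_alpha(X[s, ], X[r, ], ccc, p$B, p$sigma)
  K <- vapply(seq_len(m), function(r) oracle_K(X[r, ], ccc, p$sigma_K),
              numeric(1))
  solve(t(A), K)
}

# central finite-difference gradient of the package's invasion fitness
fd_gradient <- function(co, r, ccc, p, h = 1e-6) {
  x0 <- co$phenotypes[r, ]
  vapply(seq_along(x0), function(i) {
    up <- x0; dn <- x0
    up[i] <- up[i] + h
    dn[i] <- dn[i] - h
    (invasion_fitness(co, up, ccc, p) - invasion_fitness(co, dn, ccc, p)) /
      (2 * h)
  }, numeric(1))
}

# residual of the logistic growth rates for every species of a community
eco_residual <- function(co, ccc, p) {
  m <- n_species(co)
  g <- vapply(seq_len(m), function(r) {
    s <- 0
    for (j in seq_len(m))
      s <- s + oracle_alpha(co$phenotypes[j, ], co$phenotypes[r, ], ccc,
                            p$B, p$sigma) * co$populations[j]
    1 - s / oracle_K(co$phenotypes[r, ], ccc, p$sigma_K)
  }, numeric(1))
  max(abs(g))
}

random_community <- function(D, m, spread = 0.6) {
  community(matrix(stats::rnorm(m * D, sd = spread), m, D),
            stats::runif(m, 0.2, 1))
}
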