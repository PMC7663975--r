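#' Carrying capacity of a phenotype
#'
#' The equilibrium population a monomorphic species with phenotype \code{x}
#' would reach on its own,
#' \deqn{K(x) = \exp\left(-\sum_i (x_i - x_{c,i})^4 / (4\sigma_K^4)\right),}
#' a quartic bell with its maximum 1 at the centre of the carrying capacity
#' (CCC) \code{ccc}. Environmental change is modelled by moving \code{ccc}
#' at a constant velocity (\code{\link{ccc_position}}).
#'
#' @param x phenotype, numeric vector of length D.
#' @param ccc position of the carrying-capacity centre, length D.
#' @param params an \code{\link{model_params}} object.
#' @return A single value in (0, 1].
#' @examples
#' p <- model_params(D = 1)
#' carrying_capacity(1, 0, p)   # exp(-1/4)
#' @export
carrying_capacity <- function(x, ccc, params) {
  x <- check_phenotype(x, params, "x")
  ccc <- check_phenotype(ccc, params, "ccc")
  exp(-sum((x - ccc)^4) / (4 * params$sigma_K^4))
}

#' Competition kernel
#'
#' Competitive effect of the species at \code{x} (the effector) on the species
#' at \code{y} (the focal species),
#' \deqn{\alpha(x, y) = \exp\left(\sum_{ij} b_{ij}(x_i - y_i)(x_j - x_{c,j})
#'   - \sum_i (x_i - y_i)^2 / (2\sigma_i^2)\right).}
#' The second term is the usual symmetric Gaussian kernel; the first is the
#' simplest asymmetric contribution, anchored to the instantaneous CCC through
#' the effector's deviation \eqn{x_j - x_{c,j}}.
#'
#' @param x effector phenotype (length D).
#' @param y focal phenotype (length D).
#' @param ccc current CCC position (length D).
#' @param params an \code{\link{model_params}} object.
#' @return A single positive value; \code{competition_kernel(x, x, ...) == 1}.
#' @examples
#' p <- model_params(D = 1, sigma = 0.5)
#' competition_kernel(1, 0, 0, p)  # exp(-2)
#' @export
competition_kernel <- function(x, y, ccc, params) {
  x <- check_phenotype(x, params, "x")
  y <- check_phenotype(y, params, "y")
  ccc <- check_phenotype(ccc, params, "ccc")
  d <- x - y
  exp(sum(d * (params$B %*% (x - ccc))) - sum(d^2 / (2 * params$sigma^2)))
}

# internal vectorised kernels ------------------------------------------------
# (hot path: no sweep()/outer()/t() - plain recycling arithmetic only)

# X with the vector v subtracted from every row
dev_rows <- function(X, v) X - rep(v, each = nrow(X))

# X with column i scaled by w[i]
col_scale <- function(X, w) X * rep(w, each = nrow(X))

# carrying capacity for each row of X
cc_K <- function(X, ccc, params) {
  dev <- dev_rows(X, ccc)
  exp(-rowSums(dev^4) / (4 * params$sigma_K^4))
}

# competition matrix A[s, r] = alpha(X[s, ], X[r, ]) (effect of s on r)
alpha_matrix <- function(X, ccc, params) {
  m <- nrow(X)
  Xs <- col_scale(X, 1 / params$sigma^2)
  sq <- rowSums(X * Xs)
  # sym[s, r] = sum_i (X[s,i]-X[r,i])^2 / (2 sigma_i^2)
  #           = (sq[s] + sq[r] - 2 Xs[s,] . X[r,]) / 2
  ex <- tcrossprod(Xs, X)
  ex <- ex - (sq + rep(sq, each = m)) / 2
  if (any(params$B != 0)) {
    g <- dev_rows(X, ccc) %*% t(params$B)  # g[s, i] = sum_j b_ij dev[s, j]
    # asym[s, r] = sum_i (X[s,i]-X[r,i]) g[s,i] = h[s] - (g X^T)[s, r]
    ex <- ex + (rowSums(X * g) - tcrossprod(g, X))
  }
  exp(ex)
}

# effect of each row of X on the single phenotype y: alpha(X[j, ], y)
alpha_from_rows <- function(X, y, ccc, params) {
  d <- dev_rows(X, y)                              # x_j - y
  ex <- -rowSums(col_scale(d^2, 1 / (2 * params$sigma^2)))
  if (any(params$B != 0))
    ex <- ex + rowSums(d * (dev_rows(X, ccc) %*% t(params$B)))
  exp(ex)
}

# effect of the single phenotype x on each row of X: alpha(x, X[j, ])
alpha_onto_rows <- function(x, X, ccc, params) {
  d <- dev_rows(-X, -x)                            # x - x_j
  ex <- -rowSums(col_scale(d^2, 1 / (2 * params$sigma^2)))
  if (any(params$B != 0))
    ex <- ex + drop(d %*% (params$B %*% (x - ccc)))
  exp(ex)
}

#' Invasion fitness of a mutant phenotype
#'
#' Per-capita growth rate of a rare mutant with phenotype \code{mutant} in
#' the environment set by the equilibrated resident community,
#' \deqn{f = 1 - \sum_s \alpha(x_s, y)\, N^*_s / K(y).}
#' It vanishes when the mutant coincides with a resident of an exactly
#' equilibrated community.
#'
#' @param community resident \code{\link{community}}, assumed at ecological
#'   equilibrium.
#' @param mutant mutant phenotype (length D).
#' @param ccc current CCC position.
#' @param params an \code{\link{model_params}} object.
#' @return A single value (positive: the mutant can invade).
#' @export
invasion_fitness <- function(community, mutant, ccc, params) {
  if (n_species(community) == 0L)
    stop("invasion fitness is undefined for an empty community",
         call. = FALSE)
  mutant <- check_phenotype(mutant, params, "mutant")
  ccc <- check_phenotype(ccc, params, "ccc")
  a <- alpha_from_rows(community$phenotypes, mutant, ccc, params)
  1 - sum(a * community$populations) /
    carrying_capacity(mutant, ccc, params)
}

# closed-form selection gradients for all species at once: m x D matrix.
# S[r, i] = (1/K_r) sum_s alpha_sr N_s [ sum_j b_ij dev_sj
#            - (X[s,i]-X[r,i])/sigma_i^2 - (X[r,i]-ccc_i)^3/sigma_K^4 ]
selection_gradient_all <- function(X, N, ccc, params, A = NULL, K = NULL) {
  if (is.null(A)) A <- alpha_matrix(X, ccc, params)
  if (is.null(K)) K <- cc_K(X, ccc, params)
  W <- A * N                                   # W[s, r] = alpha_sr N_s
  Csum <- colSums(W)                           # sum_s alpha_sr N_s
  dev <- dev_rows(X, ccc)
  Xs <- col_scale(X, 1 / params$sigma^2)
  term <- if (any(params$B != 0))
    crossprod(W, dev %*% t(params$B) - Xs) + Csum * Xs
  else
    Csum * Xs - crossprod(W, Xs)
  grad <- term - Csum * (dev^3 / params$sigma_K^4)
  grad / K
}

#' Selection gradient of a resident species
#'
#' The gradient of \code{\link{invasion_fitness}} with respect to the mutant
#' phenotype, evaluated at the phenotype of resident species \code{r}. It
#' points in the direction of the mutant with the highest growth rate and,
#' multiplied by the resident's equilibrium population, drives the adaptive
#' dynamics of the phenotype (\code{\link{adaptive_step}}). Computed in
#' closed form from the derivatives of the carrying capacity and the
#' competition kernel.
#'
#' @param community resident \code{\link{community}}, assumed at ecological
#'   equilibrium.
#' @param r index of the resident species.
#' @param ccc current CCC position.
#' @param params an \code{\link{model_params}} object.
#' @return Numeric vector of length D.
#' @export
selection_gradient <- function(community, r, ccc, params) {
  m <- n_species(community)
  if (length(r) != 1L || is.na(r) || r < 1L || r > m)
    stop("'r' must index a species in 1..", m, call. = FALSE)
  ccc <- check_phenotype(ccc, params, "ccc")
  S <- selection_gradient_all(community$phenotypes, community$populations,
                              ccc, params)
  S[r, ]
}
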