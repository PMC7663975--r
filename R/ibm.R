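#' Parameters of the individual-based model
#'
#' The individual-based counterpart scales the carrying capacity by
#' \code{K0}, so a monomorphic population at the CCC fluctuates around
#' \code{K0} individuals, and adds a mutation offset to every newborn.
#'
#' @param K0 carrying-capacity scale factor (expected individuals per unit
#'   density; default 1000).
#' @param sigma_mu standard deviation of the per-coordinate mutation offset
#'   (default 0.003).
#' @param cluster_cutoff distance below which individuals are grouped into
#'   one species by \code{\link{cluster_individuals}} (default 0.1).
#' @param mutation_kernel \code{"uniform"} (per-coordinate uniform offsets of
#'   standard deviation \code{sigma_mu}, i.e. half-width
#'   \eqn{\sqrt{3}\,\sigma_\mu}) or \code{"gaussian"}.
#' @param include_self logical; whether an individual's own contribution
#'   (kernel value 1) is counted in its competitive death rate, consistent
#'   with the density-regulated logistic dynamics whose \eqn{N_r} includes
#'   the focal individual (default \code{TRUE}).
#' @param refresh_interval time between full recomputations of all rates at
#'   the then-current CCC position; between refreshes the CCC is held fixed
#'   and rates are updated incrementally (exactly, for that frozen CCC).
#' @param hard_cap abort if the number of individuals exceeds this guard.
#' @return An object of class \code{"ibm_params"}.
#' @export
ibm_params <- function(K0 = 1000, sigma_mu = 0.003, cluster_cutoff = 0.1,
                       mutation_kernel = c("uniform", "gaussian"),
                       include_self = TRUE, refresh_interval = 0.05,
                       hard_cap = 1e5) {
  mutation_kernel <- match.arg(mutation_kernel)
  for (v in list(K0 = K0, cluster_cutoff = cluster_cutoff,
                 refresh_interval = refresh_interval, hard_cap = hard_cap)) {
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop("ibm parameters must be single positive numbers", call. = FALSE)
  }
  if (length(sigma_mu) != 1L || !is.finite(sigma_mu) || sigma_mu < 0)
    stop("'sigma_mu' must be a single nonnegative number", call. = FALSE)
  structure(list(K0 = K0, sigma_mu = sigma_mu,
                 cluster_cutoff = cluster_cutoff,
                 mutation_kernel = mutation_kernel,
                 include_self = isTRUE(include_self),
                 refresh_interval = refresh_interval, hard_cap = hard_cap),
            class = "ibm_params")
}

#' Rescale an adaptive-dynamics CCC speed to the individual-based model
#'
#' The deterministic trait dynamics emerging from the individual-based
#' process carries a mutational prefactor \eqn{\sigma_\mu^2 K_0 / 2} that the
#' density-scaled model absorbs into its time unit. To expose the
#' individual-based system to the environmental forcing corresponding to an
#' adaptive-dynamics rate \code{V_C}, the CCC speed must be rescaled by that
#' factor.
#'
#' @param V_C adaptive-dynamics rate of CCC motion.
#' @param ibm an \code{\link{ibm_params}} object.
#' @return The individual-based CCC speed \code{V_C * sigma_mu^2 * K0 / 2}.
#' @examples
#' rescale_velocity(0.2, ibm_params())  # 9e-4
#' @export
rescale_velocity <- function(V_C, ibm) {
  V_C * ibm$sigma_mu^2 * ibm$K0 / 2
}

#' Exact stochastic simulation of the individual-based model
#'
#' Gillespie simulation of an ensemble of individuals in trait space: every
#' individual has birth rate 1; its death rate is the logistic competition
#' load \eqn{\sum_j \alpha(x_j, x_i) / (K_0 K(x_i))} (the sum over the
#' population, including the individual itself unless
#' \code{ibm$include_self} is \code{FALSE}). A newborn inherits its parent's
#' phenotype plus an independent mutation offset per coordinate. The CCC
#' moves according to \code{env}; its position (and with it all rates) is
#' refreshed on a grid of spacing \code{ibm$refresh_interval} and held fixed
#' in between, where rates are maintained incrementally and exactly.
#'
#' @param phenotypes initial individuals: numeric matrix (one row per
#'   individual, D columns) or a single phenotype vector.
#' @param params an \code{\link{model_params}} object (kernel constants).
#' @param ibm an \code{\link{ibm_params}} object.
#' @param env an \code{\link{environment_spec}}.
#' @param duration simulated time span.
#' @param record_every spacing of population snapshots (default: 10
#'   snapshots over the run).
#' @param start_time initial time (default 0).
#' @return An object of class \code{"ibm_run"}: a list with \code{times},
#'   \code{snapshots} (list of phenotype matrices), \code{counts}
#'   (individuals per snapshot), \code{extinct}, \code{t_ext}, the final
#'   \code{state} matrix and final \code{time}.
#' @export
run_ibm <- function(phenotypes, params, ibm, env, duration,
                    record_every = duration / 10, start_time = 0) {
  if (is.null(dim(phenotypes)))
    phenotypes <- matrix(as.numeric(phenotypes), nrow = 1L)
  X0 <- as.matrix(phenotypes)
  if (ncol(X0) != params$D)
    stop("phenotypes must have D = ", params$D, " columns", call. = FALSE)
  n <- nrow(X0)
  if (n == 0L) stop("initial state must be nonempty", call. = FALSE)
  D <- params$D

  cap <- max(2L * n, 1024L)
  X <- matrix(0, cap, D)
  X[seq_len(n), ] <- X0
  S <- numeric(cap)   # competitive load incl. self term
  Kv <- numeric(cap)  # carrying capacity at the frozen CCC
  half_width <- sqrt(3) * ibm$sigma_mu
  excl <- if (ibm$include_self) 0 else 1

  t <- start_time
  t_end <- start_time + duration
  next_rec <- start_time
  next_ref <- start_time
  rec_times <- numeric(0)
  snaps <- list()
  counts <- integer(0)
  extinct <- FALSE
  t_ext <- NA_real_
  ccc <- ccc_position(env, t)

  refresh <- function() {
    A <- alpha_matrix(X[seq_len(n), , drop = FALSE], ccc, params)
    S[seq_len(n)] <<- colSums(A)
    Kv[seq_len(n)] <<- cc_K(X[seq_len(n), , drop = FALSE], ccc, params)
  }

  record <- function() {
    rec_times[length(rec_times) + 1L] <<- t
    snaps[[length(snaps) + 1L]] <<- X[seq_len(n), , drop = FALSE]
    counts[length(counts) + 1L] <<- n
  }

  repeat {
    if (t >= next_ref) {
      ccc <- ccc_position(env, t)
      refresh()
      next_ref <- next_ref + ibm$refresh_interval
    }
    if (t >= next_rec) {
      record()
      next_rec <- next_rec + record_every
    }
    if (t >= t_end) break

    idx <- seq_len(n)
    d <- (S[idx] - excl) / (ibm$K0 * Kv[idx])
    D_tot <- sum(d)
    total <- n + D_tot
    t_next <- t + stats::rexp(1L, total)

    bound <- min(t_end, next_ref, next_rec)
    if (t_next >= bound) {
      # no event before the next grid point; advance the clock only
      t <- bound
      next
    }
    t <- t_next

    if (stats::runif(1L) < n / total) {
      # birth: copy a uniformly chosen parent, add mutation offsets
      parent <- if (n == 1L) 1L else sample.int(n, 1L)
      offs <- if (ibm$mutation_kernel == "uniform")
        stats::runif(D, -half_width, half_width)
      else stats::rnorm(D, 0, ibm$sigma_mu)
      child <- X[parent, ] + offs
      if (n + 1L > cap) {
        cap2 <- 2L * cap
        X2 <- matrix(0, cap2, D); X2[idx, ] <- X[idx, , drop = FALSE]
        S2 <- numeric(cap2); S2[idx] <- S[idx]
        K2 <- numeric(cap2); K2[idx] <- Kv[idx]
        X <- X2; S <- S2; Kv <- K2; cap <- cap2
      }
      Xa <- X[idx, , drop = FALSE]
      S[idx] <- S[idx] + alpha_onto_rows(child, Xa, ccc, params)
      S[n + 1L] <- sum(alpha_from_rows(Xa, child, ccc, params)) + 1
      Kv[n + 1L] <- carrying_capacity(child, ccc, params)
      X[n + 1L, ] <- child
      n <- n + 1L
      if (n > ibm$hard_cap)
        stop("individual count exceeded the hard cap (", ibm$hard_cap,
             ") at t = ", signif(t, 6), call. = FALSE)
    } else {
      # death proportional to the competitive load
      i <- if (n == 1L) 1L else sample.int(n, 1L, prob = d)
      S[idx] <- S[idx] -
        alpha_onto_rows(X[i, ], X[idx, , drop = FALSE], ccc, params)
      if (i != n) {
        X[i, ] <- X[n, ]
        S[i] <- S[n]
        Kv[i] <- Kv[n]
      }
      n <- n - 1L
      if (n == 0L) {
        extinct <- TRUE
        t_ext <- t
        record()
        break
      }
    }
  }

  structure(list(times = rec_times, snapshots = snaps, counts = counts,
                 extinct = extinct, t_ext = t_ext,
                 state = X[seq_len(n), , drop = FALSE], time = t),
            class = "ibm_run")
}

#' @export
print.ibm_run <- function(x, ...) {
  cat("Individual-based run:", length(x$times), "snapshots, final n =",
      nrow(x$state), "at t =", signif(x$time, 6), "\n")
  if (x$extinct) cat("  population extinct at t =", signif(x$t_ext, 6), "\n")
  invisible(x)
}

#' Cluster individuals into phenotypic species
#'
#' Groups individuals by single-linkage transitive closure at Euclidean
#' cutoff \code{cutoff}; each cluster becomes one species with phenotype at
#' the cluster mean and population equal to the individual count divided by
#' \code{K0}, so densities are directly comparable with the
#' density-scaled adaptive-dynamics model.
#'
#' @param snapshot phenotype matrix (one row per individual) as stored in an
#'   \code{"ibm_run"}.
#' @param cutoff clustering distance.
#' @param K0 carrying-capacity scale of the run.
#' @param time time stamp for the resulting community (default 0).
#' @return A \code{\link{community}}.
#' @export
cluster_individuals <- function(snapshot, cutoff, K0 = 1000, time = 0) {
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0)
    stop("'cutoff' must be a single positive number", call. = FALSE)
  X <- as.matrix(snapshot)
  n <- nrow(X)
  if (n == 0L)
    return(community(matrix(numeric(0), 0, max(1L, ncol(X))), numeric(0),
                     time = time))
  grp <- single_linkage_clusters(X, cutoff)
  keys <- unique(grp)
  Xc <- matrix(0, length(keys), ncol(X))
  N <- numeric(length(keys))
  for (k in seq_along(keys)) {
    idx <- which(grp == keys[k])
    N[k] <- length(idx) / K0
    Xc[k, ] <- colMeans(X[idx, , drop = FALSE])
  }
  community(Xc, N, time = time)
}

# connected components of the graph "distance <= cutoff" (single linkage),
# found by vectorised frontier expansion on the adjacency matrix
single_linkage_clusters <- function(X, cutoff) {
  n <- nrow(X)
  if (n == 1L) return(1L)
  sq <- rowSums(X^2)
  d2 <- -2 * tcrossprod(X) + sq + rep(sq, each = n)
  adj <- d2 <= cutoff^2
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}
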