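#' Position of the carrying-capacity centre at a given time
#'
#' The centre of the carrying capacity (CCC) starts at the origin and moves
#' linearly, \eqn{x_c(t) = V_c \, \max(t - t_0, 0)}.
#'
#' @param env an \code{\link{environment_spec}}.
#' @param t evolutionary time.
#' @return Numeric vector of length D.
#' @examples
#' ccc_position(environment_spec(c(0.2, 0)), 10)  # (2, 0)
#' @export
ccc_position <- function(env, t) {
  env$velocity * max(t - env$onset, 0)
}

#' One explicit-Euler step of the adaptive dynamics
#'
#' Advances every phenotype by \eqn{\Delta t \, N^*_r S_r}, the product of the
#' evolutionary step, the species' (equilibrium) population density and its
#' selection gradient: abundant species generate more mutants and therefore
#' evolve faster. Populations are not modified by this operation (they are
#' re-equilibrated at the start of the next cycle); the evolutionary clock
#' advances by \code{params$dt}; the species count is unchanged.
#'
#' @param community an equilibrated \code{\link{community}}.
#' @param ccc current CCC position.
#' @param params an \code{\link{model_params}} object.
#' @return The community with updated phenotypes and clock.
#' @export
adaptive_step <- function(community, ccc, params) {
  m <- n_species(community)
  if (m > 0L) {
    ccc <- check_phenotype(ccc, params, "ccc")
    S <- selection_gradient_all(community$phenotypes, community$populations,
                                ccc, params)
    if (!all(is.finite(S))) {
      bad <- which(!stats::complete.cases(S))
      stop("non-finite selection gradient for species ",
           paste(bad, collapse = ", "), " at t = ", community$time,
           call. = FALSE)
    }
    community$phenotypes <- community$phenotypes +
      params$dt * (community$populations * S)
  }
  community$time <- community$time + params$dt
  community
}

#' Run an epoch of the eco-evolutionary simulation
#'
#' Iterates the simulation cycle: (i) relax the densities to ecological
#' equilibrium at the current CCC position, dropping species that fall below
#' the extinction threshold; (ii) advance all phenotypes by one adaptive-
#' dynamics Euler step. When diversification is active, every
#' \code{params$split_interval} time units the cycle first merges species
#' closer than the merging distance (collapsing failed branchings from the
#' previous round) and then splits one randomly chosen species into two
#' halves a distance \code{params$split_distance} apart - the speciation
#' attempt. The CCC is held fixed within each cycle, evaluated at the start
#' of the step.
#'
#' The epoch ends after \code{sched$duration} time units or as soon as the
#' community is empty, in which case the extinction time is recorded.
#'
#' Randomness (choice of the species to split and of the split direction) is
#' drawn from R's global RNG stream; seed it with \code{set.seed()} for
#' reproducible runs.
#'
#' @param community starting \code{\link{community}}.
#' @param env an \code{\link{environment_spec}}.
#' @param sched a \code{\link{schedule}}.
#' @param params an \code{\link{model_params}} object.
#' @return An object of class \code{"eco_trajectory"}: a list with
#'   \item{stats}{data frame of sampled community statistics (one row per
#'     sample time; see \code{\link{community_stats}}),}
#'   \item{snapshots}{list of sampled communities (if requested),}
#'   \item{outcome}{\code{"survived"} or \code{"extinct"},}
#'   \item{t_ext}{time at which the last species died, or \code{NA},}
#'   \item{community}{the final community.}
#' @export
run_epoch <- function(community, env, sched, params) {
  t0 <- community$time
  n_steps <- max(1L, round(sched$duration / params$dt))
  rec_steps <- max(1L, round(sched$record_every / params$dt))
  div_steps <- max(1L, round(params$split_interval / params$dt))

  stats_rows <- vector("list", n_steps %/% rec_steps + 2L)
  snaps <- if (sched$keep_snapshots) list() else NULL
  n_rec <- 0L
  outcome <- "survived"
  t_ext <- NA_real_

  for (step in seq_len(n_steps + 1L)) {
    # clock kept as a multiple of dt to avoid float drift
    t <- t0 + (step - 1L) * params$dt
    community$time <- t
    ccc <- ccc_position(env, t)
    core <- eco_core(community$phenotypes, community$populations, ccc,
                     params, t)
    community$phenotypes <- core$X
    community$populations <- core$N

    if (n_species(community) == 0L) {
      outcome <- "extinct"
      t_ext <- t
      n_rec <- n_rec + 1L
      stats_rows[[n_rec]] <- community_stats(community)
      if (sched$keep_snapshots) snaps[[n_rec]] <- community
      break
    }

    if ((step - 1L) %% rec_steps == 0L || step == n_steps + 1L) {
      n_rec <- n_rec + 1L
      stats_rows[[n_rec]] <- community_stats(community)
      if (sched$keep_snapshots) snaps[[n_rec]] <- community
    }

    if (step == n_steps + 1L) break

    # adaptive step, reusing the kernel matrix from the equilibration
    S <- selection_gradient_all(core$X, core$N, ccc, params,
                                A = core$A, K = core$K)
    if (!all(is.finite(S))) {
      bad <- which(!stats::complete.cases(S))
      stop("non-finite selection gradient for species ",
           paste(bad, collapse = ", "), " at t = ", t, call. = FALSE)
    }
    community$phenotypes <- core$X + params$dt * (core$N * S)
    community$time <- t + params$dt

    # diversification events every split_interval time units: merge failed
    # branchings from the previous round, then attempt a new speciation
    if (sched$diversification_on && step %% div_steps == 0L) {
      community <- merge_close_species(community, params$merge_distance,
                                       params)
      community <- split_random_species(community, params)
    }
  }

  stats <- do.call(rbind, stats_rows[seq_len(n_rec)])
  rownames(stats) <- NULL
  structure(list(stats = stats, snapshots = snaps, outcome = outcome,
                 t_ext = t_ext, community = community),
            class = "eco_trajectory")
}

#' @export
print.eco_trajectory <- function(x, ...) {
  cat("Eco-evolutionary trajectory:", nrow(x$stats), "samples, t in [",
      signif(x$stats$t[1], 6), ",", signif(x$stats$t[nrow(x$stats)], 6),
      "]\n")
  if (x$outcome == "extinct")
    cat("  outcome: total extinction at t_ext =", signif(x$t_ext, 6), "\n")
  else
    cat("  outcome: survived with m =", n_species(x$community),
        "species\n")
  invisible(x)
}
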