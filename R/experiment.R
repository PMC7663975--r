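#' Derive child seeds from a master seed
#'
#' The replicate protocol uses a seed hierarchy - master seed, per-replica
#' burn-in seeds, per-(replica, rate) direction seeds - so that every cell of
#' a sweep is independently reproducible. Child seeds are drawn from a stream
#' seeded by the parent.
#'
#' @param seed parent integer seed.
#' @param n number of child seeds.
#' @return Integer vector of \code{n} seeds.
#' @export
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' The default grid of environmental-change rates
#'
#' Rates of CCC motion covering 0.05 to 2 in steps of 0.05 (40 values).
#' @return Numeric vector of length 40.
#' @export
default_velocity_grid <- function() seq(0.05, 2, by = 0.05)

#' Prepare one saturated replica by burn-in under a constant environment
#'
#' Samples the asymmetric-competition coefficients \eqn{b_{ij}} i.i.d.
#' standard normal and a single founder phenotype from the D-dimensional
#' standard normal, then evolves the community with the CCC fixed at the
#' origin and diversification active until diversity saturates. Finally the
#' pre-change consolidation is applied: all species closer than
#' \code{merge_slack * merge_distance} are merged into integral species, the
#' saturation species count \code{m_sat} is frozen, and the evolutionary
#' clock is reset to 0, ready for the environmental change to start.
#'
#' If \code{t_star} is \code{NULL} the burn-in length is chosen by a
#' saturation detector: the run proceeds in windows of one split cycle and
#' stops when the species count sampled at the last 11 cycle boundaries
#' varies by at most 1 (diversity has plateaued), or at \code{max_t}.
#'
#' @param seed integer seed for this replica (coefficients, founder, and all
#'   burn-in randomness derive from it).
#' @param params an \code{\link{model_params}} object; its \code{B} is
#'   replaced by the sampled coefficients unless \code{sample_B = FALSE}.
#' @param t_star burn-in duration, or \code{NULL} for automatic detection.
#' @param max_t cap on the automatic burn-in length.
#' @param sample_B logical; set \code{FALSE} to keep \code{params$B} (used
#'   for symmetric-competition studies).
#' @return An object of class \code{"saturated_replica"}: a list with the
#'   consolidated \code{community} (clock 0, \code{m_sat} frozen), the
#'   \code{params} actually used (including the sampled \code{B}), the
#'   \code{seed}, the burn-in length \code{t_star} used, and the species
#'   counts \code{m_history} sampled at split-cycle boundaries.
#' @export
burn_in_replica <- function(seed, params, t_star = NULL, max_t = 1500,
                            sample_B = TRUE) {
  seeds <- derive_seeds(seed, 2L)
  set.seed(seeds[1])
  if (sample_B)
    params$B <- matrix(stats::rnorm(params$D^2), params$D, params$D)
  founder <- stats::rnorm(params$D)
  co <- community(matrix(founder, nrow = 1L),
                  carrying_capacity(founder, rep(0, params$D), params))
  env <- environment_spec(rep(0, params$D))

  set.seed(seeds[2])
  window <- 10L  # split cycles the detector requires to be flat
  cycle <- schedule(params$split_interval, diversification_on = TRUE,
                    record_every = params$split_interval)
  m_hist <- n_species(co)
  elapsed <- 0

  if (!is.null(t_star)) {
    n_cycles <- ceiling(t_star / params$split_interval)
    for (i in seq_len(n_cycles)) {
      traj <- run_epoch(co, env, cycle, params)
      co <- traj$community
      m_hist <- c(m_hist, n_species(co))
      elapsed <- elapsed + params$split_interval
      if (n_species(co) == 0L)
        stop("burn-in replica went extinct (founder outside the viable ",
             "range of the carrying capacity); seed = ", seed, call. = FALSE)
    }
  } else {
    repeat {
      traj <- run_epoch(co, env, cycle, params)
      co <- traj$community
      m_hist <- c(m_hist, n_species(co))
      elapsed <- elapsed + params$split_interval
      if (n_species(co) == 0L)
        stop("burn-in replica went extinct (founder outside the viable ",
             "range of the carrying capacity); seed = ", seed, call. = FALSE)
      if (length(m_hist) > window) {
        trail <- m_hist[(length(m_hist) - window):length(m_hist)]
        if (max(trail) - min(trail) <= 1L) break
      }
      if (elapsed >= max_t) break
    }
  }

  # pre-change consolidation: merge split "halves" into integral species at a
  # distance marginally larger than the routine merging distance
  co <- merge_close_species(co, params$merge_slack * params$merge_distance,
                            params)
  co <- ecological_equilibrium(co, rep(0, params$D), params)
  co$m_sat <- n_species(co)
  co$time <- 0

  structure(list(community = co, params = params, seed = seed,
                 t_star = elapsed, m_history = m_hist),
            class = "saturated_replica")
}

#' @export
print.saturated_replica <- function(x, ...) {
  cat("Saturated replica (seed ", x$seed, "): m_sat = ", x$community$m_sat,
      " after burn-in of t* = ", x$t_star, "\n", sep = "")
  invisible(x)
}

#' Subject a saturated replica to environmental change
#'
#' Starts from the consolidated community of a \code{\link{burn_in_replica}}
#' and moves the CCC at rate \code{V_C} in an isotropic random direction for
#' \code{t_star} time units or until total extinction, with the
#' diversification (speciation) procedure switched off. Evolution under a
#' changing environment is pure sorting: species adapt, fall behind, or die.
#'
#' @param replica a \code{"saturated_replica"}.
#' @param V_C nonnegative rate of CCC motion.
#' @param direction_seed integer seed from which the direction of change is
#'   drawn.
#' @param t_star duration of the change phase; defaults to the replica's
#'   burn-in length.
#' @param record_every sampling period of the statistics time series.
#' @param keep_snapshots store full community snapshots at sample times.
#' @return An object of class \code{"change_experiment"}: a list with
#'   \code{V_C}, the drawn \code{direction}, the \code{outcome}
#'   (\code{"survived"}/\code{"extinct"}), \code{t_ext}, the
#'   \code{trajectory} (an \code{"eco_trajectory"}), the \code{final_stats}
#'   row, and the seeds.
#' @export
run_change_experiment <- function(replica, V_C, direction_seed,
                                  t_star = replica$t_star, record_every = 1,
                                  keep_snapshots = FALSE) {
  if (!inherits(replica, "saturated_replica"))
    stop("'replica' must be a saturated_replica", call. = FALSE)
  if (length(V_C) != 1L || !is.finite(V_C) || V_C < 0)
    stop("'V_C' must be a single nonnegative number", call. = FALSE)
  params <- replica$params
  set.seed(direction_seed)
  u <- isotropic_unit(params$D)
  env <- environment_spec(V_C * u, onset = replica$community$time)
  sched <- schedule(t_star, diversification_on = FALSE,
                    record_every = record_every,
                    keep_snapshots = keep_snapshots)
  traj <- run_epoch(replica$community, env, sched, params)
  structure(list(V_C = V_C, direction = u, outcome = traj$outcome,
                 t_ext = traj$t_ext, trajectory = traj,
                 final_stats = traj$stats[nrow(traj$stats), , drop = FALSE],
                 replica_seed = replica$seed,
                 direction_seed = direction_seed),
            class = "change_experiment")
}

#' @export
print.change_experiment <- function(x, ...) {
  cat("Environmental-change run at V_C =", x$V_C, "->", x$outcome,
      if (x$outcome == "extinct") paste("at t_ext =", signif(x$t_ext, 5)),
      "\n")
  invisible(x)
}

#' Sweep a grid of environmental-change rates over replicate communities
#'
#' Runs every (replica, rate) pair with an independent direction seed derived
#' from \code{seed}, collects the per-run outcomes, and aggregates
#' survivor-averaged statistics per rate. Failures of individual cells are
#' recorded in the run table, not fatal to the sweep.
#'
#' @param replicas list of \code{"saturated_replica"} objects.
#' @param V_C_grid increasing rates of environmental change (default
#'   \code{\link{default_velocity_grid}}).
#' @param seed master seed for the direction draws.
#' @param t_star duration of each change phase; default: each replica's own
#'   burn-in length.
#' @param record_every sampling period passed to the runs.
#' @return An object of class \code{"vc_sweep"}: a list with \code{runs} (one
#'   row per cell), \code{summary} (per-rate survivor-averaged statistics,
#'   see \code{\link{summarize_sweep}}), and the extinction threshold
#'   \code{V_C_ext}.
#' @export
sweep_velocities <- function(replicas, V_C_grid = default_velocity_grid(),
                             seed = 1L, t_star = NULL, record_every = 1) {
  if (length(V_C_grid) == 0L)
    stop("'V_C_grid' must be nonempty", call. = FALSE)
  n_rep <- length(replicas)
  dseeds <- matrix(derive_seeds(seed, n_rep * length(V_C_grid)),
                   nrow = n_rep)
  rows <- vector("list", n_rep * length(V_C_grid))
  k <- 0L
  for (i in seq_len(n_rep)) {
    for (j in seq_along(V_C_grid)) {
      k <- k + 1L
      dur <- if (is.null(t_star)) replicas[[i]]$t_star else t_star
      res <- tryCatch(
        run_change_experiment(replicas[[i]], V_C_grid[j], dseeds[i, j],
                              t_star = dur, record_every = record_every),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[k]] <- data.frame(replica = i, V_C = V_C_grid[j],
                                outcome = "error", t_ext = NA_real_,
                                m = NA_integer_, N_tot = NA_real_,
                                N_av = NA_real_, sigma2_tot = NA_real_,
                                rho_surv = NA_real_,
                                error = conditionMessage(res))
      } else {
        fs <- res$final_stats
        rows[[k]] <- data.frame(replica = i, V_C = V_C_grid[j],
                                outcome = res$outcome, t_ext = res$t_ext,
                                m = fs$m, N_tot = fs$N_tot, N_av = fs$N_av,
                                sigma2_tot = fs$sigma2_tot,
                                rho_surv = fs$rho_surv,
                                error = NA_character_)
      }
    }
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  summ <- summarize_sweep(runs)
  structure(list(runs = runs, summary = summ,
                 V_C_ext = attr(summ, "V_C_ext"), grid = V_C_grid,
                 seed = seed),
            class = "vc_sweep")
}

#' Survivor-averaged summary of a velocity sweep
#'
#' For each rate of environmental change, averages the end-of-run statistics
#' only over the replicate communities that survived until the end of the
#' change phase; runs that went extinct earlier are completely excluded from
#' those averages (their extinction times are averaged separately). The
#' extinction threshold \code{V_C_ext} is the smallest rate in the grid at
#' which no replica survived.
#'
#' @param runs a per-run table as produced by \code{\link{sweep_velocities}}
#'   (columns \code{V_C}, \code{outcome}, \code{t_ext}, \code{m},
#'   \code{N_tot}, \code{N_av}, \code{sigma2_tot}, \code{rho_surv}).
#' @return A \code{data.frame} with one row per rate: replica counts,
#'   survivor count, survivor means and standard deviations of \code{m},
#'   \code{N_tot}, \code{N_av}, \code{sigma2_tot}, \code{rho_surv}, and the
#'   mean extinction time of the extinct runs. The extinction threshold is
#'   attached as attribute \code{"V_C_ext"} (\code{NA} if every rate had
#'   survivors).
#' @export
summarize_sweep <- function(runs) {
  grid <- sort(unique(runs$V_C))
  out <- lapply(grid, function(v) {
    cell <- runs[runs$V_C == v, , drop = FALSE]
    surv <- cell[cell$outcome == "survived", , drop = FALSE]
    ext <- cell[cell$outcome == "extinct", , drop = FALSE]
    msd <- function(x) if (nrow(surv) == 0L) c(NA_real_, NA_real_) else
      c(mean(x), if (nrow(surv) > 1L) stats::sd(x) else NA_real_)
    m_ <- msd(surv$m); nt <- msd(surv$N_tot); na <- msd(surv$N_av)
    s2 <- msd(surv$sigma2_tot); rs <- msd(surv$rho_surv)
    data.frame(V_C = v, n = nrow(cell), n_surv = nrow(surv),
               n_error = sum(cell$outcome == "error"),
               m_mean = m_[1], m_sd = m_[2],
               N_tot_mean = nt[1], N_tot_sd = nt[2],
               N_av_mean = na[1], N_av_sd = na[2],
               sigma2_tot_mean = s2[1], sigma2_tot_sd = s2[2],
               rho_surv_mean = rs[1], rho_surv_sd = rs[2],
               t_ext_mean = if (nrow(ext)) mean(ext$t_ext) else NA_real_)
  })
  summ <- do.call(rbind, out)
  rownames(summ) <- NULL
  dead <- summ$V_C[summ$n_surv == 0L & summ$n_error == 0L & summ$n > 0L]
  attr(summ, "V_C_ext") <- if (length(dead)) min(dead) else NA_real_
  summ
}

#' @export
print.vc_sweep <- function(x, ...) {
  cat("Velocity sweep:", length(x$grid), "rates x",
      length(unique(x$runs$replica)), "replicas\n")
  cat("  extinction threshold V_C_ext =",
      if (is.na(x$V_C_ext)) "not reached within the grid" else x$V_C_ext,
      "\n")
  invisible(x)
}
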