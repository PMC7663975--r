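#' Load a simulation configuration file
#'
#' Reads a YAML document with (all optional) sections \code{model},
#' \code{schedule}, \code{experiment} and \code{ibm}, validates every key and
#' returns the fully resolved parameter bundle. An empty or absent section
#' yields the package defaults (the reference parameterisation of the model).
#' Unknown keys are rejected with the offending name. Within \code{model},
#' \code{B} may be given explicitly as a row-major list of \code{D*D}
#' numbers; otherwise it is left to the replicate protocol to sample.
#'
#' @param path path to the YAML configuration file.
#' @return A list with elements \code{params} (\code{\link{model_params}}),
#'   \code{schedule} (named list of schedule settings), \code{experiment}
#'   (named list: \code{n_replicas}, \code{V_C_grid}, \code{t_star},
#'   \code{seed}) and \code{ibm} (\code{\link{ibm_params}}).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg))
    stop("config must be a mapping of sections", call. = FALSE)
  known_sections <- c("model", "schedule", "experiment", "ibm")
  bad <- setdiff(names(cfg), known_sections)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  take <- function(section, allowed) {
    x <- cfg[[section]]
    if (is.null(x)) x <- list()
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown key(s) in '", section, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    x
  }

  mo <- take("model", c("D", "sigma_K", "sigma", "B", "dt", "split_interval",
                        "split_distance", "merge_distance", "merge_slack",
                        "extinction_threshold", "eco_tol", "eco_max_time"))
  D <- if (is.null(mo$D)) 1L else as.integer(mo$D)
  if (!is.null(mo$B)) {
    Bv <- as.numeric(unlist(mo$B))
    if (length(Bv) != D * D)
      stop("'model$B' must have D*D = ", D * D, " entries (row-major), got ",
           length(Bv), call. = FALSE)
    mo$B <- matrix(Bv, D, D, byrow = TRUE)
  }
  mo$D <- D
  params <- do.call(model_params, mo)

  sc <- take("schedule", c("record_every", "keep_snapshots"))
  sched <- list(record_every = if (is.null(sc$record_every)) 1
                               else as.numeric(sc$record_every),
                keep_snapshots = isTRUE(sc$keep_snapshots))
  if (sched$record_every < params$dt)
    stop("'schedule$record_every' must be >= model$dt", call. = FALSE)

  ex <- take("experiment", c("n_replicas", "V_C_grid", "t_star", "seed"))
  experiment <- list(
    n_replicas = if (is.null(ex$n_replicas)) 30L else as.integer(ex$n_replicas),
    V_C_grid = if (is.null(ex$V_C_grid)) default_velocity_grid()
               else as.numeric(unlist(ex$V_C_grid)),
    t_star = if (is.null(ex$t_star)) NULL else as.numeric(ex$t_star),
    seed = if (is.null(ex$seed)) 1L else as.integer(ex$seed))
  if (experiment$n_replicas < 1L)
    stop("'experiment$n_replicas' must be >= 1", call. = FALSE)
  if (length(experiment$V_C_grid) < 1L || any(experiment$V_C_grid < 0))
    stop("'experiment$V_C_grid' must be nonnegative rates", call. = FALSE)

  ib <- take("ibm", c("K0", "sigma_mu", "cluster_cutoff", "mutation_kernel",
                      "include_self", "refresh_interval", "hard_cap"))
  ibm <- do.call(ibm_params, ib)

  list(params = params, schedule = sched, experiment = experiment, ibm = ibm)
}

# shortest round-trip decimal representation
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    format(v, digits = 17, scientific = NA, trim = TRUE)
  }, character(1))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer,
                                                      logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- fmt_num(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write the output files of a run
#'
#' Serialises a trajectory (or change experiment) into a deterministic set of
#' plain-text files in \code{out_dir}: \code{timeseries.tsv} (the sampled
#' statistics), \code{snapshots.tsv} (one row per species per sample, if
#' snapshots were kept) and \code{meta.json} (parameters, seeds and the
#' coefficient matrix \code{B} in row-major order - enough provenance to
#' re-run the computation exactly). Numeric fields are written in shortest
#' round-trip decimal form (17 significant digits).
#'
#' @param result an \code{"eco_trajectory"} or \code{"change_experiment"}.
#' @param out_dir output directory (created if needed).
#' @param params the \code{\link{model_params}} used (taken from a change
#'   experiment's metadata where available).
#' @param meta named list of extra provenance fields merged into
#'   \code{meta.json} (seeds, grid, ...).
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(result, out_dir, params = NULL, meta = list()) {
  traj <- if (inherits(result, "change_experiment")) result$trajectory
          else result
  if (!inherits(traj, "eco_trajectory"))
    stop("'result' must be an eco_trajectory or change_experiment",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  ts_path <- file.path(out_dir, "timeseries.tsv")
  write_tsv(traj$stats, ts_path)
  paths <- c(paths, ts_path)

  if (!is.null(traj$snapshots)) {
    rows <- lapply(traj$snapshots, function(co) {
      m <- n_species(co)
      if (m == 0L) return(NULL)
      X <- co$phenotypes
      colnames(X) <- paste0("x", seq_len(ncol(X)))
      data.frame(t = co$time, species_id = seq_len(m), N = co$populations, X)
    })
    snap_path <- file.path(out_dir, "snapshots.tsv")
    write_tsv(do.call(rbind, rows), snap_path)
    paths <- c(paths, snap_path)
  }

  info <- list(outcome = traj$outcome, t_ext = traj$t_ext)
  if (inherits(result, "change_experiment"))
    info <- c(info, list(V_C = result$V_C, direction = result$direction,
                         replica_seed = result$replica_seed,
                         direction_seed = result$direction_seed))
  if (!is.null(params))
    info$params <- c(params[setdiff(names(params), "B")],
                     list(B_row_major = as.numeric(t(params$B))))
  info <- c(info, meta,
            list(package_version =
                   as.character(utils::packageVersion("ecoevosim"))))
  meta_path <- file.path(out_dir, "meta.json")
  jsonlite::write_json(info, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, meta_path)
  invisible(paths)
}

#' Read back the time series written by \code{write_run_outputs}
#'
#' @param out_dir directory containing \code{timeseries.tsv}.
#' @return The statistics \code{data.frame}.
#' @export
read_run_timeseries <- function(out_dir) {
  utils::read.table(file.path(out_dir, "timeseries.tsv"), header = TRUE,
                    sep = "\t", colClasses = NA)
}

#' Write the per-rate summary of a velocity sweep
#'
#' One TSV row per rate of environmental change, plus the full per-run table
#' and a JSON metadata file with the master seed and grid.
#'
#' @param sweep a \code{"vc_sweep"}.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sweep_outputs <- function(sweep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- file.path(out_dir, "sweep_summary.tsv")
  rp <- file.path(out_dir, "sweep_runs.tsv")
  mp <- file.path(out_dir, "meta.json")
  write_tsv(sweep$summary, sp)
  write_tsv(sweep$runs, rp)
  jsonlite::write_json(list(seed = sweep$seed, grid = sweep$grid,
                            V_C_ext = sweep$V_C_ext,
                            package_version = as.character(
                              utils::packageVersion("ecoevosim"))),
                       mp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(c(sp, rp, mp))
}
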