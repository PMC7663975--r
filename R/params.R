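#' Model parameters for the eco-evolutionary community model
#'
#' Bundles every constant of the competition model and of the simulation
#' schedule: the carrying-capacity width \code{sigma_K}, the competition-kernel
#' widths \code{sigma} (one per trait), the asymmetric-competition coefficient
#' matrix \code{B}, the evolutionary time step, the split/merge schedule and
#' the extinction cutoff. Defaults are the reference parameterisation used
#' throughout the package: \code{sigma_K = 1}, \code{sigma_i = 1/2},
#' \code{dt = 1e-2}, a split of size \code{1e-3} every 10 time units, a
#' merging distance of \code{1e-1} and an extinction cutoff of \code{1e-6}.
#'
#' @param D integer dimension of trait space (>= 1).
#' @param sigma_K positive width of the carrying capacity.
#' @param sigma competition-kernel widths; a single positive number (recycled
#'   to length \code{D}) or a vector of \code{D} positive numbers.
#' @param B the \code{D x D} matrix of asymmetric-competition coefficients
#'   \eqn{b_{ij}}. The default \code{NULL} means "all zero" (purely symmetric
#'   competition); replicate preparation samples a random \code{B} itself
#'   (see \code{\link{burn_in_replica}}).
#' @param dt evolutionary (adaptive-dynamics) Euler step.
#' @param split_interval period, in evolutionary time units, of the
#'   diversification (merge-then-split) events.
#' @param split_distance separation \eqn{\Delta x} between the two halves of a
#'   split species.
#' @param merge_distance phenotypic distance below which species are merged.
#' @param merge_slack factor applied to \code{merge_distance} for the single
#'   consolidation merge performed right before environmental change starts
#'   ("marginally larger" than the routine merging distance).
#' @param extinction_threshold population below which a species is removed.
#' @param eco_tol residual tolerance defining ecological equilibrium.
#' @param eco_max_time pseudo-time budget for the ecological relaxation before
#'   it aborts with a diagnostic error.
#'
#' @return An object of class \code{"eco_params"} (a validated list).
#' @seealso \code{\link{carrying_capacity}}, \code{\link{competition_kernel}},
#'   \code{\link{ecological_equilibrium}}
#' @examples
#' p <- model_params(D = 2)
#' p$sigma
#' @export
model_params <- function(D = 1L,
                         sigma_K = 1,
                         sigma = 0.5,
                         B = NULL,
                         dt = 1e-2,
                         split_interval = 10,
                         split_distance = 1e-3,
                         merge_distance = 1e-1,
                         merge_slack = 1.05,
                         extinction_threshold = 1e-6,
                         eco_tol = 1e-8,
                         eco_max_time = 1e5) {
  D <- as.integer(D)
  if (length(D) != 1L || is.na(D) || D < 1L)
    stop("'D' must be a single integer >= 1", call. = FALSE)
  if (length(sigma) == 1L) sigma <- rep(sigma, D)
  if (length(sigma) != D)
    stop("'sigma' must have length 1 or D = ", D, call. = FALSE)
  if (is.null(B)) B <- matrix(0, D, D)
  B <- as.matrix(B)
  if (!all(dim(B) == c(D, D)))
    stop("'B' must be a ", D, "x", D, " matrix", call. = FALSE)
  if (!all(is.finite(B)))
    stop("'B' must be finite-valued", call. = FALSE)
  p <- list(D = D, sigma_K = sigma_K, sigma = as.numeric(sigma), B = B,
            dt = dt, split_interval = split_interval,
            split_distance = split_distance,
            merge_distance = merge_distance, merge_slack = merge_slack,
            extinction_threshold = extinction_threshold,
            eco_tol = eco_tol, eco_max_time = eco_max_time)
  for (nm in c("sigma_K", "dt", "split_interval", "split_distance",
               "merge_distance", "merge_slack", "extinction_threshold",
               "eco_tol", "eco_max_time")) {
    v <- p[[nm]]
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(p$sigma)) || any(p$sigma <= 0))
    stop("'sigma' components must be positive", call. = FALSE)
  if (p$dt >= p$split_interval)
    stop("'dt' must be smaller than 'split_interval'", call. = FALSE)
  class(p) <- "eco_params"
  p
}

#' @export
print.eco_params <- function(x, ...) {
  cat("Eco-evolutionary model parameters\n")
  cat("  D =", x$D, " sigma_K =", x$sigma_K,
      " sigma =", paste(signif(x$sigma, 4), collapse = ", "), "\n")
  cat("  asymmetric B:",
      if (all(x$B == 0)) "zero (symmetric competition)" else
        paste0(x$D, "x", x$D, " matrix, |b|_max = ",
               signif(max(abs(x$B)), 3)), "\n")
  cat("  dt =", x$dt, " split every", x$split_interval,
      "by", x$split_distance, " merge at", x$merge_distance, "\n")
  cat("  extinction threshold =", x$extinction_threshold,
      " eco tol =", x$eco_tol, "\n")
  invisible(x)
}

#' Environmental change: motion of the carrying-capacity optimum
#'
#' The environment is encoded by the trajectory of the centre of the carrying
#' capacity (CCC), which starts at the origin and moves at the constant
#' velocity vector \code{velocity} from time \code{onset} on.
#'
#' @param velocity numeric vector of length \code{D}; may be all zero for a
#'   constant environment.
#' @param onset time at which the motion starts (default 0).
#' @return An object of class \code{"eco_env"}.
#' @examples
#' env <- environment_spec(c(0.2, 0))
#' ccc_position(env, 10)
#' @export
environment_spec <- function(velocity, onset = 0) {
  velocity <- as.numeric(velocity)
  if (length(velocity) < 1L || any(!is.finite(velocity)))
    stop("'velocity' must be a finite numeric vector", call. = FALSE)
  if (length(onset) != 1L || !is.finite(onset))
    stop("'onset' must be a single finite number", call. = FALSE)
  structure(list(velocity = velocity, onset = onset), class = "eco_env")
}

#' @export
print.eco_env <- function(x, ...) {
  cat("Environment: CCC velocity (", paste(signif(x$velocity, 4),
      collapse = ", "), "), |V_C| = ", signif(sqrt(sum(x$velocity^2)), 4),
      ", onset t = ", x$onset, "\n", sep = "")
  invisible(x)
}

#' Construct a community of phenotypic species
#'
#' A community is an ordered set of species, each a point in D-dimensional
#' trait space with a population density, plus the evolutionary clock and
#' (once frozen at the onset of environmental change) the saturation species
#' count \code{m_sat} used for the survivor fraction.
#'
#' @param phenotypes numeric matrix with one row per species and D columns
#'   (a vector is taken as a single-species D-dimensional phenotype when
#'   \code{m = 1}, or as m one-dimensional species if \code{D = 1}; pass a
#'   matrix to disambiguate).
#' @param populations nonnegative numeric vector, one density per species.
#' @param time evolutionary clock (default 0).
#' @param m_sat species count at diversity saturation, or \code{NA} if not
#'   yet frozen.
#' @return An object of class \code{"eco_community"}.
#' @examples
#' community(matrix(c(-0.5, 0.5), ncol = 1), c(0.9, 0.9))
#' @export
community <- function(phenotypes, populations, time = 0, m_sat = NA_integer_) {
  if (is.null(dim(phenotypes))) {
    if (length(populations) == 1L)
      phenotypes <- matrix(as.numeric(phenotypes), nrow = 1L)
    else
      phenotypes <- matrix(as.numeric(phenotypes), ncol = 1L)
  }
  phenotypes <- as.matrix(phenotypes)
  storage.mode(phenotypes) <- "double"
  populations <- as.numeric(populations)
  if (nrow(phenotypes) != length(populations))
    stop("one population per species required: ", nrow(phenotypes),
         " phenotypes vs ", length(populations), " populations",
         call. = FALSE)
  if (any(!is.finite(populations)) || any(populations < 0))
    stop("populations must be finite and nonnegative", call. = FALSE)
  if (any(!is.finite(phenotypes)))
    stop("phenotypes must be finite", call. = FALSE)
  structure(list(phenotypes = phenotypes, populations = populations,
                 time = as.numeric(time),
                 m_sat = if (is.na(m_sat)) NA_integer_ else as.integer(m_sat)),
            class = "eco_community")
}

#' Number of species in a community
#' @param community an \code{eco_community}.
#' @return integer species count \code{m}.
#' @export
n_species <- function(community) nrow(community$phenotypes)

#' @export
print.eco_community <- function(x, ...) {
  m <- n_species(x)
  cat("Community of", m, "species in D =", ncol(x$phenotypes),
      "trait space at t =", signif(x$time, 6), "\n")
  if (m > 0)
    cat("  N_tot =", signif(sum(x$populations), 6),
        if (!is.na(x$m_sat)) paste(" m_sat =", x$m_sat) else "", "\n")
  invisible(x)
}

#' Simulation schedule for an epoch
#'
#' @param duration length of the epoch in evolutionary time units.
#' @param diversification_on logical; whether the periodic merge/split
#'   (speciation attempt) procedure is active. It is active during the
#'   burn-in to diversity saturation and switched off from the onset of
#'   environmental change.
#' @param record_every sampling period of the community statistics
#'   (must be >= the evolutionary step \code{dt}).
#' @param keep_snapshots logical; store full community snapshots at each
#'   sample time (memory-heavy for long runs).
#' @return An object of class \code{"eco_schedule"}.
#' @export
schedule <- function(duration, diversification_on = TRUE, record_every = 1,
                     keep_snapshots = FALSE) {
  if (length(duration) != 1L || !is.finite(duration) || duration <= 0)
    stop("'duration' must be a single positive number", call. = FALSE)
  if (length(record_every) != 1L || !is.finite(record_every) ||
      record_every <= 0)
    stop("'record_every' must be a single positive number", call. = FALSE)
  structure(list(duration = duration,
                 diversification_on = isTRUE(diversification_on),
                 record_every = record_every,
                 keep_snapshots = isTRUE(keep_snapshots)),
            class = "eco_schedule")
}

# internal: check a phenotype vector against the model dimension
check_phenotype <- function(x, params, what = "phenotype") {
  x <- as.numeric(x)
  if (length(x) != params$D)
    stop(what, " must have length D = ", params$D, ", got ", length(x),
         call. = FALSE)
  x
}
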