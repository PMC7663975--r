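#' Split a randomly chosen species into two halves
#'
#' The speciation attempt of the diversification procedure: one species,
#' chosen uniformly at random, is replaced by two species placed at
#' \eqn{x \pm (\Delta x / 2)\,\hat u}, where \eqn{\hat u} is an isotropic
#' random unit vector and \eqn{\Delta x} = \code{params$split_distance}, each
#' carrying half the parent's population. If disruptive selection favours
#' branching the halves drift apart; otherwise they are merged back at the
#' next diversification event. Total population is conserved exactly.
#'
#' Uses R's global RNG stream.
#'
#' @param community a \code{\link{community}}; an empty community is returned
#'   unchanged.
#' @param params an \code{\link{model_params}} object.
#' @return The community with one more species (same total population).
#' @export
split_random_species <- function(community, params) {
  m <- n_species(community)
  if (m == 0L) return(community)
  r <- if (m == 1L) 1L else sample.int(m, 1L)
  u <- isotropic_unit(ncol(community$phenotypes))
  parent_x <- community$phenotypes[r, ]
  parent_N <- community$populations[r]
  off <- (params$split_distance / 2) * u
  community$phenotypes <- rbind(
    community$phenotypes[-r, , drop = FALSE],
    parent_x - off,
    parent_x + off)
  community$populations <- c(community$populations[-r],
                             parent_N / 2, parent_N / 2)
  community
}

#' Merge phenotypically close species
#'
#' Groups species into clusters by single-linkage transitive closure of the
#' relation "Euclidean phenotypic distance <= \code{distance}" and replaces
#' each cluster by a single species carrying the summed population, placed at
#' the population-weighted mean phenotype. This collapses the failed
#' branchings created by \code{\link{split_random_species}} and, before the
#' onset of environmental change, consolidates meta-populations of split
#' halves into integral species so that the population factor driving the
#' adaptive dynamics is the species' full density. Total population and the
#' population-weighted phenotypic centre of mass are conserved.
#'
#' @param community a \code{\link{community}}.
#' @param distance merging distance (default \code{params$merge_distance}).
#' @param params an \code{\link{model_params}} object.
#' @return The community with \code{m_out <= m_in} species.
#' @examples
#' p <- model_params(D = 1)
#' co <- community(matrix(c(0, 0.08), ncol = 1), c(1, 3))
#' merge_close_species(co, 0.1, p)$phenotypes  # 0.06
#' @export
merge_close_species <- function(community, distance = params$merge_distance,
                                params) {
  if (length(distance) != 1L || !is.finite(distance) || distance <= 0)
    stop("'distance' must be a single positive number", call. = FALSE)
  m <- n_species(community)
  if (m <= 1L) return(community)

  grp <- single_linkage_clusters(community$phenotypes, distance)
  if (length(unique(grp)) == m) return(community)

  keys <- unique(grp)
  X <- matrix(0, length(keys), ncol(community$phenotypes))
  N <- numeric(length(keys))
  for (k in seq_along(keys)) {
    idx <- which(grp == keys[k])
    w <- community$populations[idx]
    N[k] <- sum(w)
    X[k, ] <- colSums(community$phenotypes[idx, , drop = FALSE] * w) / N[k]
  }
  community$phenotypes <- X
  community$populations <- N
  community
}

# isotropic random unit vector in d dimensions (normalised Gaussian draws)
isotropic_unit <- function(d) {
  repeat {
    u <- stats::rnorm(d)
    nu <- sqrt(sum(u^2))
    if (nu > 1e-12) return(u / nu)
  }
}
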