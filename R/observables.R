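#' Phenotypic centre of mass of a community
#'
#' The population-weighted mean phenotype,
#' \eqn{x^{mc}_i = \sum_r x_{r,i} N_r / N_{tot}}.
#'
#' @param community a non-empty \code{\link{community}} with positive total
#'   population.
#' @return Numeric vector of length D.
#' @export
phenotypic_center <- function(community) {
  if (n_species(community) == 0L)
    stop("the phenotypic centre of an empty community is undefined",
         call. = FALSE)
  N_tot <- sum(community$populations)
  if (N_tot <= 0)
    stop("the phenotypic centre requires a positive total population",
         call. = FALSE)
  colSums(community$phenotypes * community$populations) / N_tot
}

#' Phenotypic variance of a community
#'
#' The population-weighted mean squared distance of the species phenotypes
#' from the community's centre of mass,
#' \eqn{\sigma^2_{tot} = \sum_r (N_r/N_{tot}) \sum_i (x_{r,i} - x^{mc}_i)^2}.
#' A measure of phenotypic diversity: zero iff all species share one
#' phenotype, and invariant under rigid translations of the community.
#'
#' @param community a non-empty \code{\link{community}}.
#' @return A single nonnegative value.
#' @export
phenotypic_variance <- function(community) {
  if (n_species(community) == 0L)
    stop("the phenotypic variance of an empty community is undefined",
         call. = FALSE)
  if (n_species(community) == 1L) return(0)
  ctr <- phenotypic_center(community)
  dev <- sweep(community$phenotypes, 2L, ctr, `-`)
  sum(community$populations * rowSums(dev^2)) / sum(community$populations)
}

#' Summary statistics of a community
#'
#' One row of the per-run time series: species count \code{m}, total
#' population \code{N_tot}, mean per-species population \code{N_av},
#' phenotypic variance \code{sigma2_tot}, and - when the saturation count
#' \code{m_sat} is known - the fraction of surviving species
#' \code{rho_surv = m / m_sat}. For an empty (extinct) community,
#' \code{N_tot}, \code{sigma2_tot} and \code{rho_surv} are reported as 0 and
#' \code{N_av} as \code{NA}; the \code{extinct} flag lets survivor-only
#' aggregation exclude such rows.
#'
#' @param community a \code{\link{community}}.
#' @param m_sat species count at saturation; defaults to the value frozen in
#'   the community (\code{NA} until the burn-in consolidation).
#' @return A one-row \code{data.frame} with columns \code{t, m, N_tot, N_av,
#'   sigma2_tot, rho_surv, extinct}.
#' @examples
#' p <- model_params(D = 1)
#' co <- community(matrix(c(0, 1), ncol = 1), c(1, 3))
#' community_stats(co, m_sat = 4)
#' @export
community_stats <- function(community, m_sat = community$m_sat) {
  m <- n_species(community)
  if (!is.na(m_sat) && m_sat < 1L)
    stop("'m_sat' must be >= 1", call. = FALSE)
  if (m == 0L) {
    return(data.frame(t = community$time, m = 0L, N_tot = 0, N_av = NA_real_,
                      sigma2_tot = 0,
                      rho_surv = if (is.na(m_sat)) NA_real_ else 0,
                      extinct = TRUE))
  }
  N_tot <- sum(community$populations)
  data.frame(t = community$time, m = m, N_tot = N_tot, N_av = N_tot / m,
             sigma2_tot = phenotypic_variance(community),
             rho_surv = if (is.na(m_sat)) NA_real_ else m / m_sat,
             extinct = FALSE)
}
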