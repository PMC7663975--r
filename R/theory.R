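#' Single-species evolutionary speed at a given lag
#'
#' With the asymmetric part of the competition kernel ignored, a single
#' species trailing the moving CCC by a lag \eqn{d} along the direction of
#' motion evolves toward it at speed
#' \deqn{u(d) = K(d)\, d^3/\sigma_K^4 = \exp(-d^4/4\sigma_K^4)\, d^3/\sigma_K^4:}
#' a larger lag steepens the selection gradient, but it also shrinks the
#' population (and hence the mutant supply) through the carrying capacity.
#'
#' @param lag nonnegative distance behind the CCC.
#' @param sigma_K carrying-capacity width (default 1).
#' @return The speed, a nonnegative value.
#' @examples
#' single_species_speed(3^(1/4))  # (3/e)^(3/4), the maximum
#' @export
single_species_speed <- function(lag, sigma_K = 1) {
  if (any(!is.finite(lag)) || any(lag < 0))
    stop("'lag' must be nonnegative", call. = FALSE)
  exp(-lag^4 / (4 * sigma_K^4)) * lag^3 / sigma_K^4
}

#' Maximum sustainable speed of environmental change for a single species
#'
#' The speed-lag curve \code{\link{single_species_speed}} is unimodal: its
#' maximum, reached at lag \eqn{3^{1/4}\sigma_K}, is
#' \deqn{u_{max} = (3/e)^{3/4} / \sigma_K \approx 1.08 / \sigma_K,}
#' the fastest CCC motion a single species can track at a steady state. Above
#' it the lag grows without bound and the species goes extinct.
#'
#' @param sigma_K carrying-capacity width (default 1).
#' @return A list with elements \code{lag} (the optimal lag) and \code{u_max}.
#' @examples
#' max_sustainable_speed()  # lag 3^(1/4) ~ 1.316, u_max ~ 1.077
#' @export
max_sustainable_speed <- function(sigma_K = 1) {
  list(lag = 3^0.25 * sigma_K, u_max = (3 / exp(1))^0.75 / sigma_K)
}

#' Steady lag behind a CCC moving at a given rate
#'
#' For \eqn{V_C < u_{max}} the equation \eqn{u(d) = V_C} has two roots; the
#' smaller one (below the optimal lag) is the stable steady state at which
#' the species tracks the moving CCC. For \eqn{V_C > u_{max}} no steady
#' state exists - the species falls ever further behind and goes extinct -
#' and \code{NA} is returned.
#'
#' @param V_C nonnegative rate of CCC motion.
#' @param sigma_K carrying-capacity width (default 1).
#' @return The stable steady lag, 0 for \code{V_C = 0}, or \code{NA_real_} if
#'   \code{V_C > u_max}.
#' @examples
#' steady_lag(0.5)   # ~0.824
#' steady_lag(1.2)   # NA: faster than u_max
#' @export
steady_lag <- function(V_C, sigma_K = 1) {
  if (length(V_C) != 1L || !is.finite(V_C) || V_C < 0)
    stop("'V_C' must be a single nonnegative number", call. = FALSE)
  ms <- max_sustainable_speed(sigma_K)
  if (V_C == 0) return(0)
  if (V_C > ms$u_max) return(NA_real_)
  if (V_C == ms$u_max) return(ms$lag)
  # bracketed bisection on the rising (stable) branch [0, lag*]
  lo <- 0
  hi <- ms$lag
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (single_species_speed(mid, sigma_K) < V_C) lo <- mid else hi <- mid
    if (hi - lo < 1e-10 * sigma_K) break
  }
  (lo + hi) / 2
}
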