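#' Frame weights from a saved metadynamics bias potential
#'
#' Frames drawn from a simulation biased by a deposited hill potential
#' V(s,t) over-sample high-bias regions; their contribution to unbiased
#' averages is restored with w(t) proportional to exp(V(s,t)/kB T) (the
#' unbiased reference potential being zero). Weights are rescaled by a
#' common factor so the largest is 1; a common rescaling (equivalently,
#' adding any constant to all biases) changes no weighted average. A bias
#' saved in the opposite sign convention (as the running free-energy
#' estimate, -V) is handled with \code{sign = -1}.
#'
#' @param bias per-frame bias values, kJ/mol; all finite.
#' @param constants \code{\link{eemcc_constants}}.
#' @param sign +1 (default) when \code{bias} is the deposited hill sum, -1
#'   when it is its negative.
#' @return an \code{eemcc_weights} numeric vector (one positive weight per
#'   frame, max 1).
#' @export
frame_weights <- function(bias, constants = eemcc_constants(), sign = 1) {
  if (any(!is.finite(bias))) stop("non-finite bias value")
  v <- sign * bias / (constants$kB * constants$T)
  w <- exp(v - max(v))
  structure(w, class = "eemcc_weights")
}

#' Rolling weighted mean of a per-frame statistic
#'
#' After frame n the estimate is sum_{t<=n} A_t w_t / sum_{t<=n} w_t; the
#' final element equals the batch weighted mean.
#'
#' @param values per-frame statistic.
#' @param weights per-frame weights (positive, same length).
#' @return numeric vector of running weighted means.
#' @export
rolling_weighted_mean <- function(values, weights) {
  stopifnot(length(values) == length(weights))
  sw <- cumsum(as.numeric(weights))
  if (sum(weights) <= 0) stop("zero total weight")
  cumsum(values * as.numeric(weights)) / sw
}

#' Batch weighted mean
#'
#' @param values per-frame statistic.
#' @param weights per-frame weights.
#' @return the weighted mean.
#' @export
weighted_mean_batch <- function(values, weights) {
  sum(values * as.numeric(weights)) / sum(as.numeric(weights))
}
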