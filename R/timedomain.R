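## Time-domain noise statistics: time-weighted moments, coefficient of
## variation, frequency of change, and heat-map normalization.

#' Exact time-weighted moments of a trace window
#'
#' mean = integral of x dt / (t1 - t0) and sd = sqrt(integral of
#' (x - mean)^2 dt / (t1 - t0)), computed exactly from the plateau durations
#' of the piecewise-constant trace (no sampling involved). Under
#' stationarity these single-realization time averages estimate the ensemble
#' moments.
#'
#' @param trace an \linkS4class{EventTrace}.
#' @param species species name.
#' @param t0,t1 window (s), within the trace span, t1 > t0.
#' @return named numeric c(mean, sd) in molecule counts.
#' @export
timeWeightedMoments <- function(trace, species, t0 = trace@t0,
                                t1 = trace@tEnd) {
  m <- .trace_moments(trace, species, t0, t1)
  c(mean = m[["mean"]], sd = sqrt(m[["var"]]))
}

#' Coefficient of variation
#'
#' CV = sd / mean, the noise strength relative to the mean level. A zero
#' mean leaves the CV undefined; NA is returned (rendered gray in heat
#' maps downstream).
#'
#' @param mean,sd non-negative numerics (vectorized).
#' @return numeric CV, NA where mean is zero.
#' @export
coefficientOfVariation <- function(mean, sd) {
  if (any(mean < 0, na.rm = TRUE) || any(sd < 0, na.rm = TRUE))
    stop("mean and sd must be non-negative")
  ifelse(mean > 0, sd / mean, NA_real_)
}

#' Frequency of change of a species
#'
#' Number of events in (t0, t1] whose reaction changes the species' count
#' (non-zero stoichiometric entry). An elementary mass-action step never has
#' a net-zero entry for a species it touches, so this equals the number of
#' count changes.
#'
#' @param trace an \linkS4class{EventTrace}.
#' @param species species name.
#' @param t0,t1 window (s).
#' @return integer count.
#' @export
frequencyOfChange <- function(trace, species, t0 = trace@t0,
                              t1 = trace@tEnd) {
  S <- stoichiometricMatrix(trace@network)
  if (!species %in% rownames(S)) stop("unknown species: ", species)
  touches <- S[species, trace@eventReaction] != 0
  sum(touches & trace@eventTimes > t0 & trace@eventTimes <= t1)
}

#' Normalize a statistic matrix by its maximum
#'
#' Divides every defined entry by the global maximum of the defined entries,
#' mapping the matrix onto [0, 1] for heat-map display. NA entries (the
#' undefined / gray cells, e.g. CV at zero mean) are preserved.
#'
#' @param m numeric matrix with non-negative entries; NAs allowed.
#' @return matrix of the same shape.
#' @export
normalizeByMax <- function(m) {
  if (all(is.na(m))) stop("no defined entries to normalize")
  mx <- max(m, na.rm = TRUE)
  if (mx == 0) return(m)
  m / mx
}
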