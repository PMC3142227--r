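## Zero-order-hold sampling of piecewise-constant event traces, the
## captured-power criterion for choosing the sampling frequency, and
## anti-aliased decimation.

#' Sample an event trace at uniform instants
#'
#' Evaluates the piecewise-constant trace at T + n dt, n = 0..N-1, by
#' zero-order hold (at an exact event instant the post-event value applies).
#' Changes that happen between sample instants are deliberately neglected:
#' the captured-power criterion ([selectSamplingFrequency()]) decides whether
#' a sampling frequency retains enough of the signal's fluctuation.
#'
#' @param trace an \linkS4class{EventTrace}.
#' @param species species name.
#' @param T start of the sampling window (s).
#' @param N number of samples.
#' @param dt sampling step (s); sampling frequency F = 1/dt.
#' @return A \linkS4class{UniformSignal}.
#' @examples
#' id <- immigrationDeathNetwork(kOut = 1, targetMean = 20,
#'                               ctx = VolumeContext(1e-15))
#' tr <- simulateSSA(id$network, id$init, VolumeContext(1e-15), 5, seed = 1L)
#' sig <- sampleTrace(tr, "X", T = 0, N = 512, dt = 0.005)
#' @export
setMethod("sampleTrace", "EventTrace", function(trace, species, T, N, dt) {
  stopifnot(N >= 2, dt > 0)
  tN <- T + (N - 1) * dt
  if (T < trace@t0 || tN > trace@tEnd)
    stop("sampling window [", T, ", ", tN, "] exceeds trace span [",
         trace@t0, ", ", trace@tEnd, "]")
  vals <- traceValueAt(trace, species, T + (0:(N - 1)) * dt)
  UniformSignal(vals, dt = dt, tStart = T)
})

#' @rdname signal-accessors
#' @export
setMethod("samplingFrequency", "UniformSignal", function(x) 1 / x@dt)

#' Signal accessors
#'
#' \code{samplingFrequency} returns F = 1/dt; \code{signalValues} the sample
#' vector; \code{signalTimes} the sample instants.
#'
#' @param x a \linkS4class{UniformSignal}.
#' @name signal-accessors
NULL

#' @rdname signal-accessors
#' @export
signalValues <- function(x) x@values

#' @rdname signal-accessors
#' @export
signalTimes <- function(x) x@tStart + (seq_along(x@values) - 1) * x@dt

setMethod("show", "UniformSignal", function(object) {
  cat(sprintf("UniformSignal: N = %d, F = %g Hz, t in [%g, %g] s\n",
              length(object@values), 1 / object@dt, object@tStart,
              object@tStart + (length(object@values) - 1) * object@dt))
})

## exact time-weighted mean and variance of a trace over [t0, t1]
.trace_moments <- function(trace, species, t0, t1) {
  if (t1 <= t0) stop("empty window")
  if (t0 < trace@t0 || t1 > trace@tEnd) stop("window outside trace span")
  steps <- .species_steps(trace, species)
  bounds <- c(trace@t0, trace@eventTimes, trace@tEnd)
  lo <- pmax(bounds[-length(bounds)], t0)
  hi <- pmin(bounds[-1], t1)
  w <- pmax(hi - lo, 0)
  W <- t1 - t0
  m <- sum(steps * w) / W
  v <- sum((steps - m)^2 * w) / W
  c(mean = m, var = v)
}

#' Fraction of trace power captured by a sampled signal
#'
#' Ratio of the sample variance of the uniformly sampled signal to the exact
#' time-weighted variance of the piecewise-constant trace over the same
#' window. "Power" is taken as the variance about the mean, since the
#' analysis concerns fluctuations around a steady state. A trace with zero
#' variance over the window returns 1 (a constant is fully captured).
#'
#' @param trace an \linkS4class{EventTrace}.
#' @param species species name.
#' @param sig a \linkS4class{UniformSignal} sampled from the trace.
#' @return non-negative scalar; close to 1 when the sampling step resolves
#'   every plateau.
#' @export
capturedPowerFraction <- function(trace, species, sig) {
  N <- length(sig@values)
  t1 <- sig@tStart + (N - 1) * sig@dt
  tw <- .trace_moments(trace, species, sig@tStart, t1)
  if (tw[["var"]] <= 0) return(1)
  m <- mean(sig@values)
  sum((sig@values - m)^2) / N / tw[["var"]]
}

#' Choose a sampling frequency by the captured-power criterion
#'
#' Samples the trace at each candidate frequency (ascending) over the window
#' [T, T + window] and returns the smallest frequency whose
#' [capturedPowerFraction()] reaches the threshold. Defaults follow the
#' study design: candidates 10^3, 10^4, 10^5 Hz and a 95 percent threshold,
#' applied per species.
#'
#' @param trace an \linkS4class{EventTrace}.
#' @param species species name.
#' @param candidates ascending candidate frequencies (Hz).
#' @param threshold required captured-power fraction in (0, 1].
#' @param T window start (s).
#' @param window window length (s); defaults to the full trace span.
#' @return selected frequency (Hz), with attribute \code{"fraction"}.
#' @export
selectSamplingFrequency <- function(trace, species,
                                    candidates = c(1e3, 1e4, 1e5),
                                    threshold = 0.95, T = trace@t0,
                                    window = trace@tEnd - T) {
  stopifnot(!is.unsorted(candidates, strictly = TRUE),
            threshold > 0, threshold <= 1)
  fr <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    dt <- 1 / candidates[i]
    N <- floor(window / dt) + 1
    sig <- sampleTrace(trace, species, T, N, dt)
    fr[i] <- capturedPowerFraction(trace, species, sig)
    if (fr[i] >= threshold) {
      out <- candidates[i]
      attr(out, "fraction") <- fr[i]
      return(out)
    }
  }
  stop("no candidate sampling frequency reaches threshold ", threshold,
       "; achieved fractions: ", paste(signif(fr, 4), collapse = ", "))
}

## linear-phase windowed-sinc (Blackman) low-pass FIR
.design_lowpass <- function(fc_norm, ntaps) {
  # fc_norm: cutoff as a fraction of the sampling frequency
  m <- ntaps - 1
  n <- 0:m
  h <- 2 * fc_norm * sinc(2 * fc_norm * (n - m / 2))
  w <- 0.42 - 0.5 * cos(2 * pi * n / m) + 0.08 * cos(4 * pi * n / m)
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

## zero-phase FIR filtering with reflection padding (odd-length symmetric
## kernel applied centred, so no group delay remains)
.fir_filter <- function(x, h) {
  half <- (length(h) - 1) / 2
  n <- length(x)
  pad <- function(k) {
    idx <- seq_len(k)
    list(head = 2 * x[1] - x[pmin(1 + idx, n)][k:1],
         tail = 2 * x[n] - x[pmax(n - idx, 1)])
  }
  p <- pad(half)
  xx <- c(p$head, x, p$tail)
  y <- stats::filter(xx, h, method = "convolution", sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

#' Low-pass filter and down-sample a uniform signal
#'
#' Applies a zero-phase linear-phase FIR low-pass (windowed-sinc with a
#' Blackman window, passband edge at 0.4 of the new Nyquist frequency,
#' stopband attenuation >= 60 dB at and above the new Nyquist) and keeps
#' every \code{factor}-th sample. Required before down-sampling so that
#' fluctuations above the new Nyquist frequency do not alias into the
#' retained band.
#'
#' @param sig a \linkS4class{UniformSignal} with at least \code{8 * factor}
#'   samples.
#' @param factor integer down-sampling factor >= 2.
#' @return A \linkS4class{UniformSignal} with sampling frequency F / factor.
#' @export
decimate <- function(sig, factor) {
  if (length(factor) != 1 || factor != round(factor) || factor < 2)
    stop("factor must be an integer >= 2")
  factor <- as.integer(factor)
  x <- sig@values
  if (length(x) < 8 * factor)
    stop("need at least 8 * factor samples to decimate")
  # transition band 0.4..1.0 of the new Nyquist = 0.3/factor of F;
  # Blackman window reaches ~74 dB stopband with ~5.5/width taps
  width <- 0.3 / factor
  ntaps <- ceiling(5.5 / width)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  h <- .design_lowpass(0.35 / factor, ntaps)   # centre of the transition
  y <- .fir_filter(x, h)
  keep <- seq(1, length(y), by = factor)
  UniformSignal(y[keep], dt = sig@dt * factor, tStart = sig@tStart)
}
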