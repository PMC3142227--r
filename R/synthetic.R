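## Reference stochastic processes and toy networks with known analytic
## spectra and moments. These make every pipeline stage testable without
## external data: the generators are deterministic given (parameters, seed).

#' Random-walk reference signal
#'
#' Cumulative sum of i.i.d. Gaussian steps, mean-removed. Its PSD falls as
#' 1/f^2, i.e. a log-log slope of -2 - the comparison point for power-law
#' noise classification.
#'
#' @param n even number of samples (>= 256).
#' @param stepSD standard deviation of each step.
#' @param F sampling frequency (Hz).
#' @param seed integer seed.
#' @return A \linkS4class{UniformSignal}.
#' @export
randomWalkSignal <- function(n, stepSD = 1, F = 1, seed = 1L) {
  stopifnot(n %% 2 == 0, n >= 256)
  set.seed(seed)
  x <- cumsum(stats::rnorm(n, sd = stepSD))
  UniformSignal(x - mean(x), dt = 1 / F)
}

#' 1/f^alpha power-law reference signal
#'
#' Spectral synthesis: complex spectrum with amplitude proportional to
#' f^(-alpha/2) and i.i.d. uniform phases, conjugate symmetry enforced, DC
#' set to zero, inverse-transformed to a real signal and normalized to unit
#' variance. alpha = 0 gives white noise, alpha = 1 pure 1/f noise,
#' alpha = 2 the spectral shape of a random walk.
#'
#' @param alpha power-law exponent in (0, 3] (0 allowed for the white limit).
#' @param n even number of samples (>= 256).
#' @param F sampling frequency (Hz).
#' @param seed integer seed.
#' @return A \linkS4class{UniformSignal} with sample mean 0 and variance 1.
#' @export
oneOverFSignal <- function(alpha, n, F = 1, seed = 1L) {
  stopifnot(n %% 2 == 0, n >= 256, alpha >= 0, alpha <= 3)
  set.seed(seed)
  k <- 1:(n / 2)
  f <- F * k / n
  amp <- f^(-alpha / 2)
  phase <- stats::runif(n / 2, 0, 2 * pi)
  C <- complex(modulus = amp, argument = phase)
  C[n / 2] <- complex(real = amp[n / 2] * cos(phase[n / 2]))  # real Nyquist
  full <- complex(length.out = n)
  full[k + 1] <- C
  full[n + 1 - k[-(n / 2)]] <- Conj(C[-(n / 2)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  UniformSignal(x, dt = 1 / F)
}

#' Immigration-death birth-death network
#'
#' The linear oracle network: a constant source species SRC feeds X through
#' a pseudo-first-order reaction (SRC is clamped, so the reaction acts as a
#' constant-rate immigration) and X decays at rate kOut. The stationary law
#' of X is Poisson with mean (and variance) \code{targetMean}, the CV is
#' 1/sqrt(targetMean), and the one-sided PSD of the stationary fluctuations
#' is the Lorentzian of [analyticLorentzianPSD()] with tau = 1/kOut.
#'
#' @param kOut first-order decay rate of X (s^-1).
#' @param targetMean desired stationary mean count of X at \code{ctx}.
#' @param ctx a \linkS4class{VolumeContext}.
#' @param sourceConc concentration of the constant source species (M).
#' @return list with \code{network} (a \linkS4class{ReactionNetwork}) and
#'   \code{init} (counts at the rounded stationary mean).
#' @export
immigrationDeathNetwork <- function(kOut = 1, targetMean = 100, ctx,
                                    sourceConc = 1e-6) {
  stopifnot(targetMean > 0, kOut > 0)
  nav <- ctx@avogadro * ctx@volume
  xsrc <- .round_half_away(sourceConc * nav)
  stopifnot(xsrc >= 1)
  kin <- targetMean * kOut / xsrc   # per-molecule source rate, s^-1
  sp <- data.frame(name = c("SRC", "X"),
                   init_conc = c(sourceConc, targetMean / nav),
                   role = c("constant", "variable"))
  rx <- data.frame(id = c("immigration", "death"), k = c(kin, kOut),
                   tag = c("kf", "kf"))
  rx$reactants <- list("SRC", "X")
  rx$products <- list("X", character(0))
  rx <- rx[, c("id", "reactants", "products", "k", "tag")]
  net <- new("ReactionNetwork", species = sp, reactions = rx)
  list(network = net,
       init = stats::setNames(c(xsrc, .round_half_away(targetMean)),
                              c("SRC", "X")))
}

#' Analytic Lorentzian PSD of a linear birth-death process
#'
#' One-sided PSD of an exponentially correlated stationary process:
#' S(f) = 4 sigma^2 tau / (1 + (2 pi f tau)^2) with tau = 1/kOut, matching
#' the [periodogramPSD()] convention (integral over f > 0 equals sigma^2).
#'
#' @param f positive frequencies (Hz).
#' @param statVar stationary variance (counts^2).
#' @param kOut relaxation rate (s^-1).
#' @return numeric power vector (counts^2/Hz).
#' @export
analyticLorentzianPSD <- function(f, statVar, kOut) {
  stopifnot(all(f > 0), kOut > 0)
  tau <- 1 / kOut
  4 * statVar * tau / (1 + (2 * pi * f * tau)^2)
}

#' Closed two-state isomerization network
#'
#' A reversible A <-> B network with \code{nTotal} molecules, started all-A.
#' Detailed balance gives a Binomial(nTotal, kB/(kF+kB)) stationary law for
#' the count of A - the exactness oracle for the simulator.
#'
#' @param kF,kB forward/backward rates (s^-1).
#' @param nTotal total molecule count (conserved).
#' @param ctx a \linkS4class{VolumeContext} fixing the count/concentration
#'   mapping.
#' @return list with \code{network} and \code{init} (all molecules in A).
#' @export
isomerizationNetwork <- function(kF = 1, kB = 1, nTotal = 100,
                                 ctx = VolumeContext(1e-15)) {
  stopifnot(nTotal >= 1)
  nav <- ctx@avogadro * ctx@volume
  sp <- data.frame(name = c("A", "B"),
                   init_conc = c(nTotal / nav, 0),
                   role = "variable")
  rx <- data.frame(id = c("fwd", "bwd"), k = c(kF, kB), tag = c("kf", "kb"))
  rx$reactants <- list("A", "B")
  rx$products <- list("B", "A")
  rx <- rx[, c("id", "reactants", "products", "k", "tag")]
  net <- new("ReactionNetwork", species = sp, reactions = rx)
  list(network = net, init = stats::setNames(c(nTotal, 0), c("A", "B")))
}
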