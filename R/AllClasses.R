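#' @import methods
NULL

#' Mass-action reaction network
#'
#' Container for a chemical reaction network: an ordered species table
#' (name, initial concentration in molar, role \code{"variable"} or
#' \code{"constant"}) and an ordered list of elementary one-way mass-action
#' reactions of order 1 or 2. Constant species enter reaction propensities at
#' their fixed abundance but are never produced or consumed: their rows in the
#' stoichiometric matrix are forced to zero.
#'
#' @slot species data.frame with columns \code{name}, \code{init_conc} (M),
#'   \code{role}.
#' @slot reactions data.frame with columns \code{id}, \code{reactants} and
#'   \code{products} (list columns of species-name character vectors, with
#'   multiplicity), \code{k} (deterministic rate constant: s^-1 for order 1,
#'   M^-1 s^-1 for order 2) and \code{tag} (free label, e.g. kf/kb/kcat).
#'
#' @seealso [loadNetwork()], [stoichiometricMatrix()], [simulateSSA()]
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame", reactions = "data.frame"))

setValidity("ReactionNetwork", function(object) {
  sp <- object@species
  rx <- object@reactions
  msgs <- character()
  if (!all(c("name", "init_conc", "role") %in% names(sp)))
    return("species table must have columns name, init_conc, role")
  if (!all(c("id", "reactants", "products", "k", "tag") %in% names(rx)))
    return("reactions table must have columns id, reactants, products, k, tag")
  if (anyDuplicated(sp$name)) msgs <- c(msgs, "duplicate species names")
  if (any(sp$init_conc < 0)) msgs <- c(msgs, "negative initial concentration")
  if (!all(sp$role %in% c("variable", "constant")))
    msgs <- c(msgs, "species role must be 'variable' or 'constant'")
  if (nrow(rx) > 0) {
    ord <- lengths(rx$reactants)
    if (any(ord < 1 | ord > 2))
      msgs <- c(msgs, "reactant order must be 1 or 2")
    if (any(rx$k < 0)) msgs <- c(msgs, "negative rate constant")
    refd <- unique(c(unlist(rx$reactants), unlist(rx$products)))
    bad <- setdiff(refd, sp$name)
    if (length(bad))
      msgs <- c(msgs, paste0("unknown species referenced: ",
                             paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Volume context for deterministic/stochastic unit conversion
#'
#' Couples a system volume (liters) with Avogadro's number (fixed at the 2019
#' SI exact value). Concentration c (M) corresponds to round(c * N_A * V)
#' molecules; second-order deterministic rate constants k (M^-1 s^-1)
#' correspond to stochastic propensity constants k / (N_A * V).
#'
#' @slot volume numeric, system volume in liters (> 0).
#' @slot avogadro numeric, Avogadro constant in mol^-1.
#' @export
setClass("VolumeContext",
  representation(volume = "numeric", avogadro = "numeric"),
  prototype(avogadro = 6.02214076e23))

setValidity("VolumeContext", function(object) {
  if (length(object@volume) != 1 || !is.finite(object@volume) ||
      object@volume <= 0) return("volume must be a single positive number")
  TRUE
})

#' Construct a VolumeContext
#' @param volume system volume in liters.
#' @return A \linkS4class{VolumeContext}.
#' @examples
#' ctx <- VolumeContext(5e-16)
#' @export
VolumeContext <- function(volume) new("VolumeContext", volume = volume)

#' Event trace from a stochastic simulation
#'
#' Output of the Gillespie direct method: the initial molecule counts plus the
#' (event time, reaction index) sequence. Full state snapshots are
#' reconstructed on demand; between events the state is piecewise constant,
#' with the half-open plateau convention [t_i, t_{i+1}).
#'
#' @slot x0 named integer vector of initial counts, one per species.
#' @slot eventTimes numeric vector of event times (s), strictly increasing,
#'   all in (t0, tEnd].
#' @slot eventReaction integer vector of fired reaction indices (1-based,
#'   parallel to eventTimes).
#' @slot t0 numeric simulation start time (s).
#' @slot tEnd numeric simulation horizon (s).
#' @slot volume numeric system volume (l).
#' @slot seedPath integer vector (master_seed, volume_index, replicate_index)
#'   identifying the RNG substream, or integer(0) if seeded externally.
#' @slot network the \linkS4class{ReactionNetwork} that generated the trace.
#' @export
setClass("EventTrace",
  representation(x0 = "integer", eventTimes = "numeric",
                 eventReaction = "integer", t0 = "numeric", tEnd = "numeric",
                 volume = "numeric", seedPath = "integer",
                 network = "ReactionNetwork"))

setValidity("EventTrace", function(object) {
  if (length(object@eventTimes) != length(object@eventReaction))
    return("eventTimes and eventReaction lengths differ")
  if (is.unsorted(object@eventTimes, strictly = FALSE))
    return("event times must be non-decreasing")
  if (length(object@eventTimes) &&
      (object@eventTimes[1] < object@t0 ||
       object@eventTimes[length(object@eventTimes)] > object@tEnd))
    return("event times outside [t0, tEnd]")
  if (any(object@x0 < 0)) return("negative initial counts")
  TRUE
})

#' Uniformly sampled signal
#'
#' A discrete signal c[n], n = 0..N-1, obtained by zero-order-hold sampling of
#' a piecewise-constant event trace (or synthesized directly) at instants
#' t_start + n * dt. The sampling frequency is F = 1/dt.
#'
#' @slot values numeric vector of samples.
#' @slot dt numeric sampling step (s).
#' @slot tStart numeric time of the first sample (s).
#' @export
setClass("UniformSignal",
  representation(values = "numeric", dt = "numeric", tStart = "numeric"),
  prototype(tStart = 0))

setValidity("UniformSignal", function(object) {
  if (length(object@values) < 2) return("need at least 2 samples")
  if (!is.finite(object@dt) || object@dt <= 0) return("dt must be positive")
  if (any(!is.finite(object@values))) return("non-finite sample values")
  TRUE
})

#' Construct a UniformSignal
#' @param values numeric samples.
#' @param dt sampling step (s); the sampling frequency is 1/dt.
#' @param tStart time of the first sample (s).
#' @return A \linkS4class{UniformSignal}.
#' @export
UniformSignal <- function(values, dt, tStart = 0)
  new("UniformSignal", values = as.numeric(values), dt = dt, tStart = tStart)

#' One-sided power spectral density estimate
#'
#' Periodogram-type PSD on the positive-frequency grid f_k = F k / N,
#' k = 1..N/2 (DC excluded), in (signal units)^2 / Hz.
#'
#' @slot freqs numeric vector of frequencies (Hz), strictly increasing, > 0.
#' @slot power numeric vector of PSD values, >= 0.
#' @slot nAveraged integer, number of realizations averaged into the estimate.
#' @slot binWidth integer, number of raw periodogram bins aggregated per
#'   reported bin.
#' @export
setClass("PSDEstimate",
  representation(freqs = "numeric", power = "numeric",
                 nAveraged = "integer", binWidth = "integer"),
  prototype(nAveraged = 1L, binWidth = 1L))

setValidity("PSDEstimate", function(object) {
  if (length(object@freqs) != length(object@power))
    return("freqs and power lengths differ")
  if (any(object@freqs <= 0)) return("frequencies must be positive")
  if (is.unsorted(object@freqs, strictly = TRUE))
    return("frequencies must be strictly increasing")
  if (any(object@power < -1e-300)) return("negative power")
  TRUE
})

#' Configuration of a volume scan
#'
#' All tunable parameters of the full noise-characterization pipeline. The
#' defaults are desk-scale (4 volumes, few replicates); the published study
#' design (300 equidistant volumes between 5e-16 and 1e-13 l, 100 s
#' time-domain windows, 10 s spectral windows) is available via
#' \code{scanConfig(preset = "full")} and needs a multi-core machine.
#'
#' @slot networkPath character path of the reaction-table file.
#' @slot vMin,vMax numeric volume range (l).
#' @slot nVolumes integer number of equidistant volumes.
#' @slot tStats numeric time-domain window length (s) for CV/FC.
#' @slot tPSD numeric spectral window length (s).
#' @slot replicates integer SSA realizations per volume (PSDs are ensemble
#'   averaged over these; CV/FC use the first realization).
#' @slot candidateF numeric candidate sampling frequencies (Hz), ascending.
#' @slot powerThreshold numeric captured-power fraction required of the
#'   selected sampling frequency.
#' @slot smoothingM integer adjacent-bin smoothing width.
#' @slot slopeBand numeric length-2 multipliers (lo, hi): the log-log slope is
#'   fitted on [lo * f1, fmax / hi].
#' @slot psdSpecies character, species to carry through the spectral pipeline
#'   (character(0) = all variable species).
#' @slot masterSeed integer master RNG seed.
#' @slot nWorkers integer parallel workers (results are worker-invariant).
#' @export
setClass("ScanConfig",
  representation(networkPath = "character", vMin = "numeric", vMax = "numeric",
                 nVolumes = "integer", tStats = "numeric", tPSD = "numeric",
                 replicates = "integer", candidateF = "numeric",
                 powerThreshold = "numeric", smoothingM = "integer",
                 slopeBand = "numeric", psdSpecies = "character",
                 masterSeed = "integer", nWorkers = "integer"),
  prototype(vMin = 5e-16, vMax = 1e-13, nVolumes = 4L, tStats = 100,
            tPSD = 10, replicates = 2L, candidateF = c(1e3, 1e4, 1e5),
            powerThreshold = 0.95, smoothingM = 8L, slopeBand = c(10, 10),
            psdSpecies = character(0), masterSeed = 1L, nWorkers = 1L))

setValidity("ScanConfig", function(object) {
  if (object@vMin <= 0 || object@vMax < object@vMin)
    return("need 0 < vMin <= vMax")
  if (object@nVolumes < 1) return("nVolumes must be >= 1")
  if (object@powerThreshold <= 0 || object@powerThreshold > 1)
    return("powerThreshold must be in (0, 1]")
  if (is.unsorted(object@candidateF, strictly = TRUE))
    return("candidateF must be strictly ascending")
  if (object@tPSD > object@tStats)
    return("tPSD must not exceed tStats (one run covers both windows)")
  if (length(object@slopeBand) != 2 || any(object@slopeBand < 1))
    return("slopeBand must be two multipliers >= 1")
  TRUE
})

#' Result of a volume scan
#'
#' @slot config the \linkS4class{ScanConfig} that produced the result.
#' @slot volumes numeric volume grid (l).
#' @slot steadyState named numeric steady-state concentrations (M).
#' @slot cv matrix species x volume of coefficients of variation (NA where the
#'   time-weighted mean is zero: the undefined/gray case).
#' @slot fc matrix species x volume of frequency-of-change counts.
#' @slot meanCounts matrix species x volume of time-weighted mean counts.
#' @slot psd list (by species) of lists (by volume) of
#'   \linkS4class{PSDEstimate}s (smoothed, ensemble averaged).
#' @slot slopes data.frame with species, volume, slope, stderr, sampleF.
#' @slot provenance list: config echo, master seed, package version.
#' @export
setClass("ScanResult",
  representation(config = "ScanConfig", volumes = "numeric",
                 steadyState = "numeric", cv = "matrix", fc = "matrix",
                 meanCounts = "matrix", psd = "list", slopes = "data.frame",
                 provenance = "list"))
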