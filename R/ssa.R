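## R-side wrappers around the compiled Gillespie direct-method core.

## network arrays handed to the C++ loop
.net_arrays <- function(net, ctx) {
  sp <- net@species$name
  idx <- .reactant_index(net)
  homo <- !is.na(idx$r2) & idx$r1 == idx$r2
  list(r1 = idx$r1 - 1L,
       r2 = ifelse(is.na(idx$r2), -1L, idx$r2 - 1L),
       homo = homo,
       cj = unname(stochasticRateConstants(net, ctx)),
       S = stoichiometricMatrix(net))
}

#' Reaction propensities
#'
#' a_j = c_j x for order 1, c_j x_A x_B for a heterodimeric reaction and
#' c_j x_A (x_A - 1) / 2 for a homodimeric reaction, where c_j are the
#' stochastic rate constants at the given volume.
#'
#' @param counts integer molecule counts, one per species (named vectors are
#'   re-ordered by species name).
#' @param net a \linkS4class{ReactionNetwork}.
#' @param ctx a \linkS4class{VolumeContext}.
#' @return numeric vector of propensities (s^-1), one per reaction.
#' @export
propensities <- function(counts, net, ctx) {
  counts <- .align_conc(counts, net)
  if (any(counts < 0)) stop("negative counts")
  idx <- .reactant_index(net)
  cj <- unname(stochasticRateConstants(net, ctx))
  a <- cj * counts[idx$r1]
  two <- !is.na(idx$r2)
  homo <- two & idx$r1 == idx$r2
  het <- two & !homo
  a[het] <- a[het] * counts[idx$r2[het]]
  a[homo] <- cj[homo] * counts[idx$r1[homo]] * (counts[idx$r1[homo]] - 1) / 2
  stats::setNames(a, net@reactions$id)
}

#' Derive a reproducible RNG substream seed
#'
#' Maps (masterSeed, volumeIndex, replicateIndex) to a deterministic seed
#' below 2^31 by an integer LCG-style hash, so that every (volume, replicate)
#' task owns its own stream and results do not depend on how tasks are
#' scheduled across workers.
#'
#' @param masterSeed,volumeIndex,replicateIndex non-negative integers.
#' @return a single integer seed.
#' @export
deriveSeed <- function(masterSeed, volumeIndex = 0L, replicateIndex = 0L) {
  m <- 2147483629               # prime < 2^31
  h <- (as.numeric(masterSeed) %% m)
  for (v in c(volumeIndex, replicateIndex)) {
    h <- (h * 48271 + as.numeric(v) + 1) %% m
    h <- (h * 69621 + 7) %% m
  }
  as.integer(h)
}

#' Simulate a network with the exact Gillespie direct method
#'
#' Draws exponential waiting times from the total propensity and picks each
#' reaction with probability a_j / a0 (direct method; exact, no time-step
#' approximation). The trace terminates at the first event time beyond
#' \code{tEnd}; a state with zero total propensity is absorbing and persists
#' to \code{tEnd}.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param init integer initial counts per species (e.g. from
#'   [concentrationsToCounts()] of the ODE steady state). Named vectors are
#'   re-ordered by species name.
#' @param ctx a \linkS4class{VolumeContext}.
#' @param tEnd simulation horizon (s).
#' @param seed either \code{NULL} (use the current RNG state), a single
#'   integer, or an integer vector \code{c(masterSeed, volumeIndex,
#'   replicateIndex)} defining a reproducible substream via [deriveSeed()].
#' @param maxEvents safety cap on the number of events.
#' @return An \linkS4class{EventTrace}.
#' @examples
#' id <- immigrationDeathNetwork(kOut = 1, targetMean = 50,
#'                               ctx = VolumeContext(1e-15))
#' tr <- simulateSSA(id$network, id$init, VolumeContext(1e-15), tEnd = 10,
#'                   seed = 1L)
#' @export
simulateSSA <- function(net, init, ctx, tEnd, seed = NULL, maxEvents = 5e8) {
  stopifnot(tEnd > 0)
  arr <- .net_arrays(net, ctx)
  init <- as.integer(round(.align_conc(init, net)))
  if (any(init < 0)) stop("negative initial counts")
  path <- integer(0)
  if (!is.null(seed)) {
    path <- as.integer(seed)
    set.seed(if (length(path) == 1) path else
      deriveSeed(path[1], path[2], if (length(path) >= 3) path[3] else 0L))
  }
  res <- .ssa_simulate_cpp(arr$r1, arr$r2, arr$homo, arr$cj, arr$S,
                           as.numeric(init), tEnd, maxEvents)
  new("EventTrace", x0 = stats::setNames(init, net@species$name),
      eventTimes = res$times, eventReaction = as.integer(res$reactions),
      t0 = 0, tEnd = tEnd, volume = ctx@volume, seedPath = path,
      network = net)
}

setMethod("show", "EventTrace", function(object) {
  cat(sprintf(
    "EventTrace: %d events over [%g, %g] s, V = %g l, %d species\n",
    length(object@eventTimes), object@t0, object@tEnd, object@volume,
    length(object@x0)))
})

## per-species count as a step function: x0 + cumulative stoichiometry
.species_steps <- function(trace, species) {
  S <- stoichiometricMatrix(trace@network)
  if (!species %in% rownames(S)) stop("unknown species: ", species)
  d <- S[species, trace@eventReaction]
  c(trace@x0[[species]], trace@x0[[species]] + cumsum(as.numeric(d)))
}

#' Value of a trace at a time point
#'
#' Zero-order hold: the state set by the last event with time <= t. At an
#' exact event time the post-event value applies (plateaus are the half-open
#' intervals [t_i, t_{i+1})).
#'
#' @param trace an \linkS4class{EventTrace}.
#' @param species species name.
#' @param t time point(s), within \code{[t0, tEnd]}.
#' @return numeric molecule count(s).
#' @export
traceValueAt <- function(trace, species, t) {
  if (any(t < trace@t0 | t > trace@tEnd))
    stop("time outside trace span [", trace@t0, ", ", trace@tEnd, "]")
  steps <- .species_steps(trace, species)
  steps[findInterval(t, trace@eventTimes) + 1L]
}

#' Final state of a trace
#' @param trace an \linkS4class{EventTrace}.
#' @return named integer counts at \code{tEnd}.
#' @export
finalCounts <- function(trace) {
  S <- stoichiometricMatrix(trace@network)
  if (!length(trace@eventReaction)) return(trace@x0)
  delta <- rowSums(S[, trace@eventReaction, drop = FALSE])
  stats::setNames(as.integer(trace@x0 + delta), names(trace@x0))
}

#' Export / import an event trace as CSV
#'
#' Plain-text round-trippable representation: a commented header carrying
#' tEnd, volume and the initial counts, then one (time, reaction_index) row
#' per event.
#'
#' @param trace an \linkS4class{EventTrace}.
#' @param path file path.
#' @param net the network the trace belongs to (for [readTrace()]).
#' @return \code{path} (write) or an \linkS4class{EventTrace} (read).
#' @export
writeTrace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# t_end_s=%.17g volume_l=%.17g", trace@tEnd, trace@volume),
    sprintf("# seed_path=%s", paste(trace@seedPath, collapse = ",")),
    sprintf("# x0=%s", paste(trace@x0, collapse = ",")),
    "time_s,reaction_index"), con)
  if (length(trace@eventTimes))
    writeLines(sprintf("%.17g,%d", trace@eventTimes, trace@eventReaction), con)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path, net) {
  hdr <- readLines(path, n = 4)
  kv <- function(line, key) sub(paste0(".*", key, "="), "", line)
  meta <- strsplit(trimws(sub("^# ", "", hdr[1])), " ")[[1]]
  tEnd <- as.numeric(sub("t_end_s=", "", meta[1]))
  vol <- as.numeric(sub("volume_l=", "", meta[2]))
  sp <- strsplit(kv(hdr[2], "seed_path"), ",")[[1]]
  x0 <- as.integer(strsplit(kv(hdr[3], "x0"), ",")[[1]])
  ev <- utils::read.csv(path, comment.char = "#")
  new("EventTrace", x0 = stats::setNames(x0, net@species$name),
      eventTimes = as.numeric(ev$time_s),
      eventReaction = as.integer(ev$reaction_index),
      t0 = 0, tEnd = tEnd, volume = vol,
      seedPath = if (identical(sp, "")) integer(0) else as.integer(sp),
      network = net)
}
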