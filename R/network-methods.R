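#' Species accessors for a ReactionNetwork
#'
#' \code{speciesNames} returns all species names in declaration order;
#' \code{variableSpecies} and \code{constantSpecies} the names by role;
#' \code{initConc} the named vector of declared initial concentrations (M);
#' \code{species} and \code{reactions} the underlying tables.
#'
#' @param x,net a \linkS4class{ReactionNetwork}.
#' @return character vector, named numeric vector, or data.frame.
#' @name speciesNames
#' @aliases variableSpecies constantSpecies initConc species reactions
NULL

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species$name)

#' @rdname speciesNames
#' @export
setMethod("variableSpecies", "ReactionNetwork",
          function(x) x@species$name[x@species$role == "variable"])

#' @rdname speciesNames
#' @export
setMethod("constantSpecies", "ReactionNetwork",
          function(x) x@species$name[x@species$role == "constant"])

#' @rdname speciesNames
#' @export
setMethod("initConc", "ReactionNetwork", function(x) {
  stats::setNames(x@species$init_conc, x@species$name)
})

#' @rdname speciesNames
#' @export
species <- function(net) net@species

#' @rdname speciesNames
#' @export
reactions <- function(net) net@reactions

setMethod("show", "ReactionNetwork", function(object) {
  sp <- object@species
  cat("ReactionNetwork:", nrow(sp), "species (",
      sum(sp$role == "variable"), "variable,",
      sum(sp$role == "constant"), "constant ),",
      nrow(object@reactions), "one-way mass-action reactions\n")
})

setMethod("show", "VolumeContext", function(object) {
  cat(sprintf("VolumeContext: V = %g l (1 M = %.4g molecules)\n",
              object@volume, object@avogadro * object@volume))
})

#' Stoichiometric matrix
#'
#' One integer column per reaction: column j is the state-change vector
#' v_j = products - reactants (with multiplicity). Rows of constant species
#' are forced to zero: constant inputs enter propensities at their fixed
#' abundance but are never consumed or produced.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @return integer matrix, species x reactions, with dimnames.
#' @examples
#' net <- isomerizationNetwork(1, 1, 10)$network
#' stoichiometricMatrix(net)
#' @export
setMethod("stoichiometricMatrix", "ReactionNetwork", function(net) {
  sp <- net@species$name
  rx <- net@reactions
  S <- matrix(0L, nrow = length(sp), ncol = nrow(rx),
              dimnames = list(sp, rx$id))
  for (j in seq_len(nrow(rx))) {
    for (r in rx$reactants[[j]]) S[r, j] <- S[r, j] - 1L
    for (p in rx$products[[j]]) S[p, j] <- S[p, j] + 1L
  }
  S[net@species$role == "constant", ] <- 0L
  S
})

## round-half-away-from-zero (base round() rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert concentrations to molecule counts
#'
#' counts_i = round(conc_i * N_A * V), rounding half away from zero. This is
#' the discretization applied to the deterministic steady state before
#' stochastic simulation; note that species whose steady-state concentration
#' is below 0.5 / (N_A V) start with zero molecules, so the number of
#' zero-count species depends on the volume.
#'
#' @param conc numeric vector of concentrations (M), optionally named.
#' @param ctx a \linkS4class{VolumeContext}.
#' @return integer vector of molecule counts (names preserved).
#' @examples
#' concentrationsToCounts(2.5e-6, VolumeContext(5e-16))  # 753
#' @export
concentrationsToCounts <- function(conc, ctx) {
  stopifnot(is(ctx, "VolumeContext"))
  if (any(conc < 0)) stop("negative concentration")
  n <- .round_half_away(conc * ctx@avogadro * ctx@volume)
  if (any(n > .Machine$integer.max))
    stop("molecule count exceeds integer range at this volume")
  stats::setNames(as.integer(n), names(conc))
}

#' Convert molecule counts to concentrations
#'
#' @param counts numeric/integer vector of molecule counts.
#' @param ctx a \linkS4class{VolumeContext}.
#' @return numeric concentrations (M).
#' @export
countsToConcentrations <- function(counts, ctx) {
  stopifnot(is(ctx, "VolumeContext"))
  counts / (ctx@avogadro * ctx@volume)
}

#' Stochastic propensity constants
#'
#' Converts deterministic mass-action rate constants to the per-reaction
#' propensity constants c_j at a given volume: c_j = k_j for order 1;
#' c_j = k_j / (N_A V) for a heterodimeric order-2 reaction A + B; and
#' c_j = 2 k_j / (N_A V) for a homodimeric reaction A + A (whose propensity
#' is c_j x_A (x_A - 1) / 2).
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param ctx a \linkS4class{VolumeContext}.
#' @return numeric vector of propensity constants (s^-1 per reaction channel).
#' @export
stochasticRateConstants <- function(net, ctx) {
  stopifnot(is(ctx, "VolumeContext"))
  rx <- net@reactions
  ord <- lengths(rx$reactants)
  homo <- ord == 2 & vapply(rx$reactants,
                            function(r) r[1] == r[2], logical(1))
  c_j <- rx$k
  nav <- ctx@avogadro * ctx@volume
  c_j[ord == 2] <- c_j[ord == 2] / nav
  c_j[homo] <- 2 * c_j[homo]
  stats::setNames(c_j, rx$id)
}
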