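## Deterministic mass-action model dC/dt = S u(C) and its steady state.
## No ODE solver package is available in the target environment, so the
## integrator (adaptive implicit Euler with analytic Jacobian, L-stable,
## adequate for relaxation to a fixed point) is implemented here.

## per-reaction reactant indices (row 1 and 2; NA if order 1)
.reactant_index <- function(net) {
  sp <- net@species$name
  r1 <- vapply(net@reactions$reactants, function(r) match(r[1], sp), 0L)
  r2 <- vapply(net@reactions$reactants,
               function(r) if (length(r) == 2) match(r[2], sp) else NA_integer_,
               0L)
  list(r1 = r1, r2 = r2)
}

#' Deterministic mass-action reaction rates
#'
#' u_j = k_j times the product of reactant concentrations (with
#' multiplicity), in M/s.
#'
#' @param conc numeric concentrations (M), one per species in network order
#'   (a named vector is re-ordered by name if names are present).
#' @param net a \linkS4class{ReactionNetwork}.
#' @return numeric vector of reaction rates, one per reaction.
#' @export
reactionRates <- function(conc, net) {
  conc <- .align_conc(conc, net)
  if (any(conc < 0)) stop("negative concentration")
  idx <- .reactant_index(net)
  u <- net@reactions$k * conc[idx$r1]
  two <- !is.na(idx$r2)
  u[two] <- u[two] * conc[idx$r2[two]]
  unname(u)
}

.align_conc <- function(conc, net) {
  sp <- net@species$name
  if (!is.null(names(conc)) && all(sp %in% names(conc))) conc <- conc[sp]
  if (length(conc) != length(sp))
    stop("concentration vector length does not match species count")
  as.numeric(conc)
}

#' Right-hand side of the deterministic ODE model
#'
#' Returns S u(conc): the net production rate of each species in M/s.
#' Entries for constant species are exactly zero.
#'
#' @inheritParams reactionRates
#' @return named numeric derivative vector (M/s).
#' @export
odeRHS <- function(conc, net) {
  S <- stoichiometricMatrix(net)
  stats::setNames(drop(S %*% reactionRates(conc, net)), net@species$name)
}

## Jacobian of S_var u(c) w.r.t. variable-species concentrations
.ode_jacobian <- function(conc, net, S, idx, var_idx) {
  m <- nrow(net@reactions)
  n <- length(conc)
  k <- net@reactions$k
  dU <- matrix(0, m, n)
  for (j in seq_len(m)) {
    a <- idx$r1[j]; b <- idx$r2[j]
    if (is.na(b)) {
      dU[j, a] <- k[j]
    } else if (a == b) {
      dU[j, a] <- 2 * k[j] * conc[a]
    } else {
      dU[j, a] <- k[j] * conc[b]
      dU[j, b] <- k[j] * conc[a]
    }
  }
  (S %*% dU)[var_idx, var_idx, drop = FALSE]
}

#' Deterministic steady state of a reaction network
#'
#' Integrates the mass-action ODE model from the declared initial
#' concentrations with an adaptive implicit Euler scheme (analytic Jacobian)
#' up to \code{tMax}, then applies a damped Gauss-Newton polish to
#' S u(c) = 0 restricted to the variable species. Constant species stay at
#' their declared concentrations. The run starts from the declared initial
#' condition only: networks with conserved moieties have fixed points that
#' depend on the initial condition, and no search for alternative fixed
#' points is attempted.
#'
#' Convergence requires \code{max_i |f_i| / max(c_i, floor) <= relTol} over
#' variable species, with floor 1e-18 M.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param relTol relative residual tolerance.
#' @param tMax integration horizon (s).
#' @return named numeric vector of steady-state concentrations (M) with
#'   attribute \code{"residual"} (the scaled residual norm).
#' @examples
#' net <- isomerizationNetwork(1, 1, 100)$network
#' findSteadyState(net)  # both species at half the total
#' @export
findSteadyState <- function(net, relTol = 1e-9, tMax = 1e6) {
  sp <- net@species
  conc <- sp$init_conc
  var_idx <- which(sp$role == "variable")
  S <- stoichiometricMatrix(net)
  idx <- .reactant_index(net)
  nv <- length(var_idx)
  floor_ <- 1e-18

  rhs_var <- function(c_full) drop(S %*% {
    u <- net@reactions$k * c_full[idx$r1]
    two <- !is.na(idx$r2)
    u[two] <- u[two] * c_full[idx$r2[two]]
    u
  })[var_idx]

  scaled_resid <- function(c_full) {
    f <- rhs_var(c_full)
    max(abs(f) / pmax(c_full[var_idx], floor_))
  }

  ## adaptive implicit Euler on the variable species
  t <- 0
  f0 <- rhs_var(conc)
  fscale <- max(abs(f0), 1e-12)
  h <- min(1e-6 / fscale * 1e-6, 1e-3)  # gentle start for stiff transients
  h <- max(h, 1e-9)
  while (t < tMax) {
    h <- min(h, tMax - t)
    x <- conc[var_idx]
    cn <- x
    ok <- FALSE
    for (try in 1:60) {
      xk <- x
      conv <- FALSE
      for (it in 1:12) {
        c_full <- conc; c_full[var_idx] <- xk
        f <- rhs_var(c_full)
        g <- xk - cn - h * f
        J <- .ode_jacobian(c_full, net, S, idx, var_idx)
        A <- diag(nv) - h * J
        delta <- tryCatch(solve(A, g), error = function(e) NULL)
        if (is.null(delta)) break
        xk <- xk - delta
        xk[xk < 0 & xk > -1e-15] <- 0
        if (any(xk < 0)) break
        if (max(abs(delta) / pmax(abs(xk), floor_)) < 1e-10) { conv <- TRUE; break }
      }
      if (conv) { ok <- TRUE; break }
      h <- h / 4
      if (h < 1e-14) break
    }
    if (!ok) stop("implicit Euler step failed at t = ", t)
    conc[var_idx] <- xk
    t <- t + h
    h <- h * 1.6
  }

  ## damped Gauss-Newton / Levenberg polish on S_var u = 0
  lambda <- 1e-6
  f <- rhs_var(conc)
  best <- sqrt(sum(f^2))
  for (it in 1:60) {
    if (scaled_resid(conc) <= relTol) break
    J <- .ode_jacobian(conc, net, S, idx, var_idx)
    A <- crossprod(J) + lambda * diag(nv)
    delta <- tryCatch(solve(A, crossprod(J, f)), error = function(e) NULL)
    if (is.null(delta)) { lambda <- lambda * 10; next }
    cand <- conc
    cand[var_idx] <- pmax(conc[var_idx] - drop(delta), 0)
    fc <- rhs_var(cand)
    nc <- sqrt(sum(fc^2))
    if (nc < best) {
      conc <- cand; f <- fc; best <- nc; lambda <- max(lambda / 3, 1e-12)
    } else {
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
  }

  res <- scaled_resid(conc)
  if (res > relTol)
    stop(sprintf(
      "steady state did not converge: scaled residual %.3g > relTol %.3g",
      res, relTol))
  out <- stats::setNames(conc, sp$name)
  attr(out, "residual") <- res
  out
}

#' Export a steady state as CSV
#'
#' Writes a two-column CSV (species, conc_M).
#'
#' @param ss named concentration vector from [findSteadyState()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSteadyState <- function(ss, path) {
  utils::write.csv(data.frame(species = names(ss), conc_M = as.numeric(ss)),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
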