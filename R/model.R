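# Kinetics and forward simulation of the batch culture.
#
# State layout (13): GLC GLN GLU ASN ASP LAC ALA PRO MAb BM NH3 | X Xd.
# Species in mM (the antibody stored in mM, not the 1e-4 mM display scale),
# cells in 1e6 cells/mL.

.mabkin_env <- new.env(parent = emptyenv())
.mabkin_env$clip_count <- 0L

#' Count of negative-state clips applied by the rate functions
#'
#' Adaptive integrators may overshoot slightly below zero near substrate
#' depletion (glutamine reaches 0 within the batch).  Monod factors are
#' undefined for negative concentrations, so the rate functions clip
#' states at 0 and count the clips; this reports (and optionally resets)
#' the counter.
#'
#' @param reset if \code{TRUE}, zero the counter after reading it.
#' @return Integer count of clipped state evaluations.
#' @export
negative_clip_count <- function(reset = FALSE) {
  n <- .mabkin_env$clip_count
  if (reset) .mabkin_env$clip_count <- 0L
  n
}

# Monod factors for one reaction given a full 13-state vector.
# Returns phi (scalar), clipping negatives.
.rates_internal <- function(state, params) {
  if (any(state < 0)) {
    .mabkin_env$clip_count <- .mabkin_env$clip_count + 1L
    state <- pmax(state, 0)
  }
  X <- state[12L]
  phi <- params$phi_star * X
  if (params$kinetics_mode == "saturable") {
    ks <- params$ks
    for (i in seq_len(9L)) {
      subs <- RATE_SUBSTRATES[[i]]
      for (j in seq_along(subs)) {
        S <- state[[match(names(subs)[j], SPECIES)]]
        phi[i] <- phi[i] * S / (ks[[subs[j]]] + S)
      }
    }
  }
  phi
}

#' Macroreaction rates at a culture state
#'
#' Evaluates the nine macroreaction rates
#' \eqn{\phi_i = \phi_i^* X \prod_j S_j / (K_{Sj,i} + S_j)} (mM/h) at a
#' given state.  In \code{simplified} mode the Monod factors are dropped
#' and \eqn{\phi_i = \phi_i^* X}.  Biomass and antibody synthesis
#' (reactions 7 and 8) are rate-limited by glutamine only.
#'
#' @param state numeric length 13 (11 species, then \code{X}, \code{Xd});
#'   see [build_network()] for the species order.
#' @param params a [kinetic_parameters()] object.
#' @return Named numeric length 9 of reaction rates (mM/h).
#' @export
reaction_rates <- function(state, params) {
  state <- .check_state(state)
  if (any(params$phi_star < 0) ||
      (params$kinetics_mode == "saturable" && any(params$ks < 0)))
    stop("negative kinetic parameters are outside the rate-law domain")
  if (any(state < 0))
    stop("negative concentrations are outside the rate-law domain")
  phi <- .rates_internal(state, params)
  names(phi) <- REACTIONS
  phi
}

.check_state <- function(state) {
  if (length(state) != 13L)
    stop("`state` must have length 13 (11 species + X + Xd)")
  if (!is.null(names(state)) && all(STATES %in% names(state)))
    state <- state[STATES]
  unname(as.numeric(state))
}

#' Time derivative of the full 13-dimensional culture state
#'
#' Species balances are \eqn{d\xi/dt = K \phi(\xi)} with \eqn{K} from
#' [build_network()].  Viable cells grow exponentially until
#' \code{design$t_exp} and only die afterwards:
#' \eqn{dX/dt = \mu X - k_d X X_d} (growth phase) or
#' \eqn{-k_d X X_d} (decline), with \eqn{dX_d/dt = +k_d X X_d} always, so
#' dying cells are converted, not lost.
#'
#' @inheritParams reaction_rates
#' @param t time (h), used only for the phase switch.
#' @param design an [experiment_design()] object.
#' @return Named numeric length 13 of derivatives (mM/h; cell states in
#'   1e6 cells/mL/h).
#' @export
state_derivative <- function(t, state, params, design = experiment_design()) {
  state <- .check_state(state)
  phi <- reaction_rates(state, params)
  X <- state[12L]; Xd <- state[13L]
  death <- params$kd * X * Xd
  dX <- if (t < design$t_exp) params$mu * X - death else -death
  d <- c(as.numeric(.network_cache()$K %*% phi), dX, death)
  names(d) <- STATES
  d
}

# build_network() is pure; cache the matrix for the simulation hot path
.network_cache <- function() {
  if (is.null(.mabkin_env$network)) .mabkin_env$network <- build_network()
  .mabkin_env$network
}

.rhs_phase <- function(K, params, growth) {
  mu <- params$mu; kd <- params$kd
  function(t, y, p) {
    phi <- .rates_internal(y, params)
    X <- max(y[12L], 0); Xd <- max(y[13L], 0)
    death <- kd * X * Xd
    dX <- if (growth) mu * X - death else -death
    list(c(as.numeric(K %*% phi), dX, death))
  }
}

#' Simulate the batch culture
#'
#' Integrates the full model over \code{t_grid} with \code{deSolve}'s
#' \code{lsoda} (the state magnitudes span several orders of magnitude,
#' so a stiffness-switching method is used).  The growth/decline switch at
#' \code{design$t_exp} is handled by integrating the two phases
#' separately and restarting at the switch, so it is resolved exactly
#' rather than smeared across a step.
#'
#' For the simplified-kinetics comparison sets fitted per phase,
#' \code{params} may be a list \code{list(exponential = , decline = )} of
#' two \code{kinetic_params} objects; the decline-phase set takes over at
#' \code{t_exp}.
#'
#' @param initial numeric length 13, nonnegative initial state.
#' @param params a [kinetic_parameters()] object, or a two-element list
#'   for phase-split parameter sets.
#' @param design an [experiment_design()] object.
#' @param t_grid increasing times in \code{[0, design$t_final]} (h).
#' @param rtol,atol integrator tolerances.
#' @return Matrix \code{length(t_grid)} x 14: column \code{time} then the
#'   13 states.
#' @export
simulate_batch <- function(initial, params, design = experiment_design(),
                           t_grid = seq(0, design$t_final, by = design$Ts),
                           rtol = 1e-8, atol = 1e-10) {
  initial <- .check_state(initial)
  if (any(initial < 0)) stop("initial state must be nonnegative")
  if (any(diff(t_grid) <= 0)) stop("`t_grid` must be strictly increasing")
  if (min(t_grid) < 0 || max(t_grid) > design$t_final)
    stop("`t_grid` must lie within [0, t_final]")
  split <- is.list(params) && !inherits(params, "kinetic_params")
  if (split) {
    stopifnot(all(c("exponential", "decline") %in% names(params)))
    p_exp <- params$exponential; p_dec <- params$decline
  } else {
    p_exp <- params; p_dec <- params
  }
  K <- .network_cache()$K
  tx <- design$t_exp

  t1 <- t_grid[t_grid < tx]
  t2 <- t_grid[t_grid >= tx]
  y <- initial
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = 14L,
                dimnames = list(NULL, c("time", STATES)))

  run <- function(y0, times, rhs) {
    res <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                          rtol = rtol, atol = atol)
    if (anyNA(res) || any(!is.finite(res)))
      stop("integration failed: non-finite states near t = ",
           signif(res[which(!stats::complete.cases(res))[1L], 1L], 4L),
           " h; check parameter magnitudes")
    res
  }

  res1 <- run(y, unique(c(0, t1, tx)), .rhs_phase(K, p_exp, growth = TRUE))
  if (length(t1))
    out[seq_along(t1), ] <- res1[match(t1, res1[, 1L]), , drop = FALSE]
  y <- as.numeric(res1[nrow(res1), -1L])
  if (length(t2)) {
    res2 <- run(y, unique(c(tx, t2)), .rhs_phase(K, p_dec, growth = FALSE))
    keep <- match(t2, res2[, 1L])
    out[length(t1) + seq_along(t2), ] <- res2[keep, ]
  }
  out[, 1L] <- t_grid
  out
}
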