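# Particle swarm optimizer with the three coefficient regimes used for
# kinetic parameter estimation: linearly scheduled inertia weight,
# Clerc-style constriction factor, and time-varying acceleration
# coefficients (TVAC: cognitive weight decreasing, social increasing).

#' Swarm configuration
#'
#' @param n_particles swarm size.
#' @param max_iter iteration budget \eqn{k_{max}}.
#' @param tol stopping threshold on the objective: the run stops early
#'   once the swarm best drops to or below it.
#' @param variant coefficient regime: \code{"tvac"} (scheduled inertia +
#'   time-varying acceleration coefficients; the estimation default),
#'   \code{"inertia"} (scheduled inertia, fixed coefficients) or
#'   \code{"constriction"}.
#' @param omega_i,omega_f initial/final inertia weight of the linear
#'   schedule (0.9 down to 0.4).
#' @param c1i,c2i,c1f,c2f TVAC endpoints: the cognitive coefficient falls
#'   \code{c1i} to \code{c1f}, the social rises \code{c2i} to \code{c2f}.
#' @param c1,c2 fixed acceleration coefficients for the
#'   \code{inertia}/\code{constriction} variants (constriction requires
#'   \code{c1 + c2 > 4}).
#' @param bounds numeric matrix, one row per dimension, columns
#'   \code{low}, \code{high}.
#' @param v_max_fraction velocity clamp per dimension, as a fraction of
#'   the box width.
#' @param seed optional RNG seed for a reproducible run.
#' @param profile \code{"full"} keeps the supplied sizes;
#'   \code{"reduced"} overrides to a 50-particle, 100-iteration profile
#'   for quick runs.
#' @return An object of class \code{swarm_config}.
#' @export
swarm_config <- function(n_particles = 150, max_iter = 300, tol = 1e-6,
                         variant = c("tvac", "inertia", "constriction"),
                         omega_i = 0.9, omega_f = 0.4,
                         c1i = 2.5, c2i = 0.5, c1f = 0.5, c2f = 2.5,
                         c1 = 2.05, c2 = 2.05,
                         bounds = NULL, v_max_fraction = 0.2,
                         seed = NULL,
                         profile = c("full", "reduced")) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  if (profile == "reduced") { n_particles <- 50; max_iter <- 100 }
  stopifnot(omega_f > 0, omega_f <= omega_i, omega_i < 1,
            n_particles >= 2, max_iter >= 1, tol >= 0,
            v_max_fraction > 0)
  if (variant == "constriction" && c1 + c2 <= 4)
    stop("constriction variant requires c1 + c2 > 4")
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (ncol(bounds) != 2L || any(bounds[, 1L] >= bounds[, 2L]))
      stop("`bounds` must be a matrix with low < high in each row")
  }
  structure(list(n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter), tol = tol,
                 variant = variant,
                 omega_i = omega_i, omega_f = omega_f,
                 c1i = c1i, c2i = c2i, c1f = c1f, c2f = c2f,
                 c1 = c1, c2 = c2,
                 bounds = bounds, v_max_fraction = v_max_fraction,
                 seed = seed),
            class = "swarm_config")
}

#' Linearly scheduled inertia weight
#'
#' \eqn{\omega(k) = (\omega_i - \omega_f)(k_{max} - k)/k_{max} +
#' \omega_f}: decreases linearly from \code{omega_i} at \eqn{k = 0} to
#' \code{omega_f} at \eqn{k = k_{max}}, shifting the swarm from
#' exploration to exploitation.
#'
#' @param k current iteration, in \code{[0, max_iter]}.
#' @param cfg a [swarm_config()].
#' @return Scalar inertia weight.
#' @export
inertia_weight <- function(k, cfg) {
  if (k < 0 || k > cfg$max_iter)
    stop("iteration k must lie in [0, max_iter]")
  (cfg$omega_i - cfg$omega_f) * (cfg$max_iter - k) / cfg$max_iter +
    cfg$omega_f
}

#' Time-varying acceleration coefficients
#'
#' The cognitive coefficient decreases linearly from \code{c1i} to
#' \code{c1f} while the social coefficient increases from \code{c2i} to
#' \code{c2f}, so early iterations favour each particle's own memory and
#' late iterations favour the swarm consensus.
#'
#' @inheritParams inertia_weight
#' @return Numeric \code{c(c1, c2)}.
#' @export
tvac_coefficients <- function(k, cfg) {
  if (k < 0 || k > cfg$max_iter)
    stop("iteration k must lie in [0, max_iter]")
  sched <- function(ci, cf) (cf - ci) * k / cfg$max_iter + ci
  c(c1 = sched(cfg$c1i, cfg$c1f), c2 = sched(cfg$c2i, cfg$c2f))
}

#' Constriction (dampening) factor
#'
#' \eqn{h = 2 / |2 - \alpha - \sqrt{\alpha^2 - 4\alpha}|} with
#' \eqn{\alpha = c_1 + c_2 > 4}.  The absolute value in the denominator
#' makes \eqn{0 < h < 1}, the standard convergent dampening form.
#'
#' @param c1,c2 acceleration coefficients with \code{c1 + c2 > 4}.
#' @return Scalar in (0, 1).
#' @export
constriction_factor <- function(c1, c2) {
  alpha <- c1 + c2
  if (alpha <= 4)
    stop("constriction factor requires c1 + c2 > 4, got ", alpha)
  2 / abs(2 - alpha - sqrt(alpha^2 - 4 * alpha))
}

#' Swarm stability condition
#'
#' Checks the cited convergence conditions \eqn{\omega > (c_1 + c_2)/2 -
#' 1} and \eqn{0 < \omega < 1} at the start-of-run coefficients of the
#' configured variant.  A violation is reported with a warning (the
#' schedules may leave the region late in a run by design) but is not an
#' error.
#'
#' @param cfg a [swarm_config()].
#' @param quiet suppress the warning.
#' @return Logical: \code{TRUE} if the condition holds.
#' @export
pso_stable <- function(cfg, quiet = FALSE) {
  if (cfg$variant == "constriction") {
    # convergence is guaranteed by the dampening construction (c1+c2 > 4)
    return(TRUE)
  }
  w <- inertia_weight(0, cfg)
  cc <- if (cfg$variant == "tvac") cfg$c1i + cfg$c2i else cfg$c1 + cfg$c2
  ok <- (w > cc / 2 - 1) && w > 0 && w < 1
  if (!ok && !quiet)
    warning("swarm coefficients violate the convergence guideline ",
            "omega > (c1 + c2)/2 - 1 with 0 < omega < 1", call. = FALSE)
  ok
}

.coeffs_at <- function(k, cfg) {
  switch(cfg$variant,
    tvac = {
      cc <- tvac_coefficients(k, cfg)
      c(w = inertia_weight(k, cfg), cc[[1L]], cc[[2L]])
    },
    inertia = c(w = inertia_weight(k, cfg), cfg$c1, cfg$c2),
    constriction = c(w = constriction_factor(cfg$c1, cfg$c2),
                     cfg$c1, cfg$c2))
}

# Evaluate objective at an n x d position matrix; non-finite -> +Inf.
.eval_positions <- function(objective, X, vectorized) {
  v <- if (vectorized) objective(X)
       else apply(X, 1L, function(x) objective(x))
  v <- as.numeric(v)
  bad <- !is.finite(v)
  if (any(bad)) {
    .mabkin_env$nonfinite_evals <-
      (.mabkin_env$nonfinite_evals %||% 0L) + sum(bad)
    v[bad] <- Inf
  }
  v
}

#' Advance a swarm by one iteration
#'
#' Applies the velocity update of the configured variant with fresh
#' uniform \eqn{r_1, r_2} draws per particle and dimension, clamps each
#' velocity component to \code{v_max_fraction} of the box width, moves the
#' particles, reflects any position back into the bounds (zeroing the
#' offending velocity component), re-evaluates the objective and updates
#' the personal and swarm bests.
#'
#' @param state swarm state list as produced by [pso_init()].
#' @param objective objective function (see [pso_minimize()]).
#' @param k current iteration (1-based).
#' @param cfg a [swarm_config()].
#' @param vectorized does \code{objective} accept a position matrix?
#' @return Updated swarm state.
#' @export
pso_step <- function(state, objective, k, cfg, vectorized = FALSE) {
  co <- .coeffs_at(k, cfg)
  n <- cfg$n_particles
  d <- nrow(cfg$bounds)
  lo <- matrix(cfg$bounds[, 1L], n, d, byrow = TRUE)
  hi <- matrix(cfg$bounds[, 2L], n, d, byrow = TRUE)
  vmax <- cfg$v_max_fraction * (hi - lo)

  r1 <- matrix(stats::runif(n * d), n, d)
  r2 <- matrix(stats::runif(n * d), n, d)
  v <- co[[1L]] * state$v +
    co[[2L]] * r1 * (state$pbest - state$x) +
    co[[3L]] * r2 * sweep(-state$x, 2L, state$gbest, `+`)
  v <- pmin(pmax(v, -vmax), vmax)
  x <- state$x + v

  # reflect into the box; zero the velocity component that left it
  below <- x < lo; above <- x > hi
  x[below] <- (2 * lo - x)[below]
  x[above] <- (2 * hi - x)[above]
  x <- pmin(pmax(x, lo), hi)        # guard against double overshoot
  v[below | above] <- 0

  f <- .eval_positions(objective, x, vectorized)
  improved <- f < state$pbest_val
  state$pbest[improved, ] <- x[improved, , drop = FALSE]
  state$pbest_val[improved] <- f[improved]
  b <- which.min(state$pbest_val)
  state$gbest <- state$pbest[b, ]
  state$gbest_val <- state$pbest_val[b]
  state$x <- x
  state$v <- v
  state$iter <- k
  state
}

#' Initialize a swarm
#'
#' Positions are drawn uniformly inside the bounds, velocities uniformly
#' in the clamp range.
#'
#' @inheritParams pso_step
#' @return Swarm state list: \code{x}, \code{v}, \code{pbest},
#'   \code{pbest_val}, \code{gbest}, \code{gbest_val}, \code{iter}.
#' @export
pso_init <- function(objective, cfg, vectorized = FALSE) {
  if (is.null(cfg$bounds)) stop("`cfg$bounds` must be set")
  n <- cfg$n_particles
  d <- nrow(cfg$bounds)
  lo <- matrix(cfg$bounds[, 1L], n, d, byrow = TRUE)
  hi <- matrix(cfg$bounds[, 2L], n, d, byrow = TRUE)
  x <- lo + matrix(stats::runif(n * d), n, d) * (hi - lo)
  vmax <- cfg$v_max_fraction * (hi - lo)
  v <- matrix(stats::runif(n * d, -1, 1), n, d) * vmax
  f <- .eval_positions(objective, x, vectorized)
  b <- which.min(f)
  list(x = x, v = v, pbest = x, pbest_val = f,
       gbest = x[b, ], gbest_val = f[b], iter = 0L)
}

#' Minimize an objective with the particle swarm
#'
#' Runs [pso_step()] until the swarm best reaches \code{cfg$tol} or
#' \code{cfg$max_iter} iterations have been spent.  Deterministic given
#' \code{cfg$seed}.
#'
#' @param objective either a function of one position vector returning a
#'   scalar, or (with \code{vectorized = TRUE}) a function of an
#'   \code{n x d} position matrix returning \code{n} values.  Non-finite
#'   values are treated as \code{+Inf}.
#' @param cfg a [swarm_config()] with \code{bounds} set.
#' @param vectorized see \code{objective}.
#' @return List: \code{par} (best position), \code{value} (best
#'   objective), \code{history} (swarm-best value per iteration,
#'   non-increasing), \code{iterations}.
#' @export
pso_minimize <- function(objective, cfg, vectorized = FALSE) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pso_stable(cfg)
  state <- pso_init(objective, cfg, vectorized)
  history <- numeric(cfg$max_iter)
  k <- 0L
  while (k < cfg$max_iter && state$gbest_val > cfg$tol) {
    k <- k + 1L
    state <- pso_step(state, objective, k, cfg, vectorized)
    history[k] <- state$gbest_val
  }
  list(par = state$gbest, value = state$gbest_val,
       history = history[seq_len(k)], iterations = k)
}
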