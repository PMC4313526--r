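# Multistep estimation: nine sequential PSO subproblems (P1..P9) over
# one-step-ahead explicit-Euler prediction errors against the
# interpolated measurements, with forward freezing of estimated
# parameters.
#
# Each subproblem fits the balance equation of one target state.  In
# that equation every state other than the target is replaced by its
# interpolated measured trajectory (the viable-cell concentration X
# included); only the target is propagated by the Euler recursion
#   xhat(k+1) = xhat(k) + Ts * f(states at k), xhat(0) = interpolated(0),
# and the objective is the summed squared error between recursion and
# interpolant over the full Ts grid.

# Default search boxes.  Rate ceilings and half-saturation constants are
# searched on a log10 scale (published estimates span 13 orders of
# magnitude; a linear box of that width is unsearchable); mu and kd on a
# linear scale.
.LOG_BOUNDS <- c(-8, 7)
.LIN_BOUNDS <- c(1e-3, 1)

# Constant glutamate level substituted when GLU is not among the
# measured variables (it is unmeasured in the bundled data set).  See
# the methods vignette: the choice only rescales phi*/KS pairs that are
# not individually identifiable from GLU-free measurements.
GLU_SURROGATE_DEFAULT <- 0.3

.SUBPROBLEM_DEFS <- list(
  list(id = "P1", target = "BM",  free = c("phi7", "KS2_7")),
  list(id = "P2", target = "MAb", free = c("phi8", "KS2_8")),
  list(id = "P3", target = "PRO", free = c("phi4", "KS3_4")),
  list(id = "P4", target = "ALA", free = c("phi2", "KS1_2", "KS3_2")),
  list(id = "P5", target = "GLN",
       free = c("phi6", "KS2_6", "KS2_9", "phi9", "KS5_6")),
  list(id = "P6", target = "ASN", free = c("phi5", "KS4_5")),
  list(id = "P7", target = "ASP", free = c("phi3", "KS1_3", "KS3_3")),
  list(id = "P8", target = "GLC", free = c("phi1", "KS1_1")),
  list(id = "P9", target = c("X", "Xd"), free = c("mu", "kd"))
)

# Parameters entering the balance equation of a species target: the
# rate ceiling and half-saturation constants of every reaction with a
# nonzero stoichiometric entry in the target's row.
.equation_params <- function(target) {
  if (identical(sort(target), c("X", "Xd"))) return(c("mu", "kd"))
  K <- .network_cache()$K
  j <- which(K[target, ] != 0)
  unique(unlist(lapply(j, function(i)
    c(PHI_NAMES[i], unname(RATE_SUBSTRATES[[i]])))))
}

#' The nine estimation subproblems
#'
#' Returns the multistep decomposition of the 23-parameter estimation
#' problem: each subproblem fits the balance equation of one target
#' state and estimates only the parameters unique to it, the remaining
#' parameters of that equation having been frozen by earlier
#' subproblems.  The order (biomass, antibody, proline, alanine,
#' glutamine, asparagine, aspartate, glucose, cells) is the unique one in
#' which every equation's remaining parameters are already available.
#'
#' @param design an [experiment_design()] (kept for interface symmetry;
#'   the decomposition itself does not depend on it).
#' @return List of 9 \code{subproblem_spec} objects with fields
#'   \code{id}, \code{target}, \code{free}, \code{required},
#'   \code{bounds} (search-space box per free parameter) and
#'   \code{log_scale} (which free parameters are searched as log10).
#' @export
default_subproblems <- function(design = experiment_design()) {
  seen <- character()
  specs <- lapply(.SUBPROBLEM_DEFS, function(d) {
    eq <- .equation_params(d$target)
    required <- setdiff(eq, d$free)
    if (!all(required %in% seen))
      stop("internal: subproblem ", d$id, " needs parameters not yet ",
           "frozen: ", paste(setdiff(required, seen), collapse = ", "))
    seen <<- c(seen, d$free)
    log_scale <- !(d$free %in% c("mu", "kd"))
    bounds <- t(vapply(log_scale,
                       function(l) if (l) .LOG_BOUNDS else .LIN_BOUNDS,
                       numeric(2)))
    rownames(bounds) <- d$free
    colnames(bounds) <- c("low", "high")
    structure(list(id = d$id, target = d$target, free = d$free,
                   required = required, bounds = bounds,
                   log_scale = log_scale),
              class = "subproblem_spec")
  })
  names(specs) <- vapply(specs, `[[`, "", "id")
  specs
}

#' @export
print.subproblem_spec <- function(x, ...) {
  cat(x$id, ": fit ", paste(x$target, collapse = "+"),
      " balance; free {", paste(x$free, collapse = ", "),
      "}; frozen {", paste(x$required, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# State series needed by the objectives, with the glutamate surrogate
# substituted when GLU was not measured.
.series_lookup <- function(traj, glu_surrogate) {
  m <- length(traj$grid)
  function(sp) {
    if (sp %in% traj$variables) return(traj$values[, sp])
    if (sp == "GLU") return(rep(glu_surrogate, m))
    if (sp == "NH3") return(rep(0, m))
    stop("variable ", sp, " is neither measured nor substitutable")
  }
}

# Build a vectorized objective for one subproblem: a function taking an
# n x p matrix of NATURAL-scale candidates (columns ordered as
# spec$free) and returning n summed squared one-step-ahead errors.
.build_objective <- function(spec, traj, frozen, design,
                             glu_surrogate = GLU_SURROGATE_DEFAULT) {
  miss <- setdiff(spec$required, names(frozen))
  if (length(miss))
    stop("missing frozen parameter(s) for ", spec$id, ": ",
         paste(miss, collapse = ", "))
  lookup <- .series_lookup(traj, glu_surrogate)
  grid <- traj$grid
  Ts <- grid[2L] - grid[1L]
  m <- length(grid)

  if (identical(sort(spec$target), c("X", "Xd"))) {
    yX <- lookup("X"); yXd <- lookup("Xd")
    growth <- grid < design$t_exp
    return(function(theta) {
      theta <- rbind(theta)
      mu <- theta[, 1L]; kd <- theta[, 2L]
      n <- length(mu)
      X <- rep(yX[1L], n); Xd <- rep(yXd[1L], n)
      sse <- numeric(n)
      for (k in seq_len(m - 1L)) {
        death <- kd * X * Xd
        dX <- if (growth[k]) mu * X - death else -death
        X <- X + Ts * dX
        Xd <- Xd + Ts * death
        sse <- sse + (yX[k + 1L] - X)^2 + (yXd[k + 1L] - Xd)^2
      }
      sse[!is.finite(sse)] <- Inf
      sse
    })
  }

  target <- spec$target
  K <- .network_cache()$K
  jset <- which(K[target, ] != 0)
  Xs <- lookup("X")
  y <- lookup(target)

  # per-reaction plan: static part computable outside the recursion,
  # dynamic Monod factor in the target substrate (if any)
  plan <- lapply(jset, function(j) {
    subs <- RATE_SUBSTRATES[[j]]
    static <- list(); dyn_ks <- NULL
    for (i in seq_along(subs)) {
      sp <- names(subs)[i]; ksn <- subs[[i]]
      if (sp == target) dyn_ks <- ksn
      else static[[length(static) + 1L]] <- list(S = lookup(sp), ks = ksn)
    }
    list(coef = K[target, j], phi = PHI_NAMES[j], static = static,
         dyn_ks = dyn_ks)
  })
  dynamic <- any(!vapply(plan, function(p) is.null(p$dyn_ks), TRUE))

  function(theta) {
    theta <- rbind(theta)
    colnames(theta) <- spec$free
    n <- nrow(theta)
    getp <- function(name) {
      if (name %in% spec$free) theta[, name] else unname(frozen[[name]])
    }
    # static part of each reaction: m-vector (theta-independent) or
    # m x n matrix
    statics <- lapply(plan, function(p) {
      base <- p$coef * getp(p$phi)     # scalar or n-vector
      part <- if (length(base) == 1L) base * Xs
              else outer(Xs, base)      # m x n
      for (f in p$static) {
        ks <- getp(f$ks)
        fac <- if (length(ks) == 1L) f$S / (ks + f$S)
               else f$S / outer(f$S, ks, `+`)
        part <- if (is.matrix(part) || is.matrix(fac)) {
          if (!is.matrix(part)) part <- matrix(part, m, n)
          if (!is.matrix(fac)) fac <- matrix(fac, m, n)
          part * fac
        } else part * fac
      }
      part
    })

    if (!dynamic) {
      D <- NULL
      for (s in statics) {
        s <- if (is.matrix(s)) s else matrix(s, m, n)
        D <- if (is.null(D)) s else D + s
      }
      cum <- apply(D[-m, , drop = FALSE], 2L, cumsum)
      xhat <- rbind(rep(y[1L], n), y[1L] + Ts * cum)
      sse <- colSums((y - xhat)^2)
      sse[!is.finite(sse)] <- Inf
      return(sse)
    }

    dyn_ks_val <- lapply(plan, function(p)
      if (is.null(p$dyn_ks)) NULL else getp(p$dyn_ks))
    xhat <- rep(y[1L], n)
    sse <- numeric(n)
    for (k in seq_len(m - 1L)) {
      d <- 0
      for (i in seq_along(plan)) {
        s <- statics[[i]]
        sk <- if (is.matrix(s)) s[k, ] else s[k]
        ks <- dyn_ks_val[[i]]
        if (!is.null(ks)) sk <- sk * xhat / (ks + xhat)
        d <- d + sk
      }
      xhat <- pmax(xhat + Ts * d, 0)
      sse <- sse + (y[k + 1L] - xhat)^2
    }
    sse[!is.finite(sse)] <- Inf
    sse
  }
}

#' One-step-ahead prediction-error objective of a subproblem
#'
#' Computes the summed squared error between the interpolated
#' measurements of the subproblem's target state and its explicit-Euler
#' one-step-ahead reconstruction on the full \code{Ts} grid, with every
#' other state in the balance equation taken from the interpolated
#' measurements and the candidate/frozen parameters substituted into the
#' rate laws.  For the cell subproblem the coupled viable/dead pair is
#' propagated jointly and both errors are summed.
#'
#' @param spec one element of [default_subproblems()].
#' @param traj an interpolated trajectory from
#'   [interpolate_measurements()].
#' @param frozen named numeric of already-estimated parameters (must
#'   cover \code{spec$required}).
#' @param candidate numeric, natural-scale values of \code{spec$free}
#'   (in that order, or named).
#' @param design an [experiment_design()].
#' @param glu_surrogate constant glutamate concentration (mM) used when
#'   GLU is not among the measured variables.
#' @return Scalar summed squared error.
#' @export
subproblem_objective <- function(spec, traj, frozen, candidate,
                                 design = experiment_design(),
                                 glu_surrogate = GLU_SURROGATE_DEFAULT) {
  if (!is.null(names(candidate))) {
    if (!setequal(names(candidate), spec$free))
      stop("candidate names must be ", paste(spec$free, collapse = ", "))
    candidate <- candidate[spec$free]
  }
  if (length(candidate) != length(spec$free))
    stop("candidate must have ", length(spec$free), " values")
  obj <- .build_objective(spec, traj, frozen, design, glu_surrogate)
  as.numeric(obj(matrix(as.numeric(candidate), nrow = 1L)))
}

.decode <- function(theta_search, spec) {
  th <- theta_search
  th[spec$log_scale] <- 10^th[spec$log_scale]
  names(th) <- spec$free
  th
}

#' Estimate all 23 kinetic parameters by the multistep PSO scheme
#'
#' Interpolates the measurement table once, then solves the nine
#' subproblems of [default_subproblems()] in order with
#' [pso_minimize()], freezing each subproblem's estimates before the
#' next (frozen parameters are never revisited).  Rate ceilings and
#' half-saturation constants are searched on a log10 scale.
#'
#' @param table a [measurement_table()] covering the variables used by
#'   the subproblem equations (glutamate may be absent; see
#'   \code{glu_surrogate}).
#' @param cfg a [swarm_config()]; its \code{bounds} and \code{seed} are
#'   set per subproblem.
#' @param design an [experiment_design()].
#' @param seed integer; subproblem \code{i} runs PSO with seed
#'   \code{seed + i}, making the whole estimate reproducible.
#' @param glu_surrogate see [subproblem_objective()].
#' @param restarts number of PSO runs per subproblem (derived seeds);
#'   the best is kept.
#' @param verbose print per-subproblem progress.
#' @return An object of class \code{estimation_result}: list with
#'   \code{params} (the assembled [kinetic_parameters()]),
#'   \code{subproblems} (per-subproblem estimates, objective value,
#'   iterations, seed), \code{objective_total}, and \code{config}.
#' @export
multistep_estimate <- function(table, cfg = swarm_config(),
                               design = experiment_design(),
                               seed = 1L,
                               glu_surrogate = GLU_SURROGATE_DEFAULT,
                               restarts = 1L, verbose = FALSE) {
  traj <- interpolate_measurements(table, design)
  specs <- default_subproblems(design)
  frozen <- c()
  sub_results <- list()
  for (spec in specs) {
    obj_nat <- .build_objective(spec, traj, frozen, design, glu_surrogate)
    log_idx <- which(spec$log_scale)
    obj_search <- function(theta) {
      theta <- rbind(theta)
      theta[, log_idx] <- 10^theta[, log_idx]
      obj_nat(theta)
    }
    sub_cfg <- cfg
    sub_cfg$bounds <- spec$bounds
    best <- NULL
    for (r in seq_len(restarts)) {
      sub_cfg$seed <- seed + match(spec$id, names(specs)) +
        (r - 1L) * 1000L
      fit <- pso_minimize(obj_search, sub_cfg, vectorized = TRUE)
      if (is.null(best) || fit$value < best$value) {
        best <- fit; best$seed <- sub_cfg$seed
      }
    }
    est <- .decode(best$par, spec)
    frozen <- c(frozen, est)
    sub_results[[spec$id]] <- list(id = spec$id, estimate = est,
                                   objective = best$value,
                                   iterations = best$iterations,
                                   seed = best$seed,
                                   history = best$history)
    if (verbose)
      message(sprintf("%s: W = %.4g after %d iterations", spec$id,
                      best$value, best$iterations))
  }
  params <- params_from_vector(frozen[PARAM_NAMES])
  structure(list(params = params, subproblems = sub_results,
                 objective_total = sum(vapply(sub_results, `[[`,
                                              0, "objective")),
                 config = list(swarm = cfg, design = design, seed = seed,
                               glu_surrogate = glu_surrogate,
                               restarts = restarts)),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("Multistep PSO estimate: 23 parameters,",
      "total objective", signif(x$objective_total, 4), "\n")
  for (s in x$subproblems)
    cat(sprintf("  %s  W = %-11.4g  %s\n", s$id, s$objective,
                paste(sprintf("%s = %.4g", names(s$estimate),
                              s$estimate), collapse = ", ")))
  invisible(x)
}

#' Serialize an estimation result
#'
#' Writes the assembled parameter set as flat YAML and, optionally, the
#' per-subproblem swarm-best histories as CSV.
#'
#' @param result an \code{estimation_result}.
#' @param params_path YAML output path.
#' @param history_path optional CSV path for the per-iteration
#'   swarm-best objective of each subproblem.
#' @export
write_estimation <- function(result, params_path, history_path = NULL) {
  write_params(result$params, params_path)
  if (!is.null(history_path)) {
    h <- do.call(rbind, lapply(result$subproblems, function(s)
      data.frame(subproblem = s$id, iteration = seq_along(s$history),
                 gbest = s$history)))
    utils::write.csv(h, history_path, row.names = FALSE)
  }
  invisible(params_path)
}
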