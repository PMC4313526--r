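# Monte Carlo robustness analysis: perturb the measurements within
# their reported standard deviations, re-estimate, drop outlying
# replicates by the interquartile fence, and summarize per-parameter
# variability as SD percent of mean.

#' Perturb a measurement table with Gaussian noise
#'
#' Replaces every mean by an independent draw from
#' \eqn{N(\mathrm{mean}, \mathrm{sd}^2)}, truncated at 0 from below
#' (concentrations cannot be negative); the standard deviations are
#' copied unchanged.  Points with sd = 0 are left exactly as measured.
#'
#' @param table a [measurement_table()].
#' @return A new \code{measurement_table} with perturbed means.
#' @export
perturb_table <- function(table) {
  noisy <- table$mean +
    matrix(stats::rnorm(length(table$mean)), nrow(table$mean)) * table$sd
  measurement_table(table$times, pmax(noisy, 0), table$sd)
}

#' Quartile-fence outlier mask
#'
#' Computes the lower and upper quartiles as the medians of the two
#' exclusive halves of the ordered data (the overall median, when the
#' count is odd, belongs to neither half), and retains values inside the
#' closed fence
#' \eqn{[q_{low} - 1.5\,\mathrm{IQR},\; q_{up} + 1.5\,\mathrm{IQR}]}.
#'
#' @param objectives numeric vector of replicate objective values
#'   (length >= 4).
#' @return Logical mask of retained values, same length and order.
#' @export
quartile_filter <- function(objectives) {
  n <- length(objectives)
  if (n < 4L) stop("need at least 4 values for the quartile fence")
  s <- sort(objectives)
  half <- n %/% 2L
  lower <- s[seq_len(half)]
  upper <- s[seq.int(n - half + 1L, n)]
  q_low <- stats::median(lower)
  q_up <- stats::median(upper)
  iqr <- q_up - q_low
  objectives >= q_low - 1.5 * iqr & objectives <= q_up + 1.5 * iqr
}

#' Monte Carlo robustness analysis of the multistep estimator
#'
#' For each replicate: perturb the measurement table within its reported
#' standard deviations, re-interpolate, and rerun the full multistep
#' estimation; then exclude replicates whose total objective lies
#' outside the quartile fence and report, per parameter, the mean and
#' the standard deviation expressed as percent of that mean.
#'
#' Replicate \code{i} perturbs the data with seed \code{seed + i}; the
#' swarm seed is shared across replicates, so with zero measurement
#' noise every replicate reproduces the same estimate (and all SD
#' percentages are exactly 0).
#'
#' @param table a [measurement_table()] with standard deviations.
#' @param n_reps number of replicates (>= 4).
#' @param cfg,design,glu_surrogate passed to [multistep_estimate()].
#' @param seed base seed.
#' @param verbose print per-replicate progress.
#' @return An object of class \code{mc_summary}: list with
#'   \code{n_requested}, \code{n_retained}, \code{summary} (data frame:
#'   parameter, mean, sd_percent), \code{objectives} (per replicate),
#'   \code{retained} (mask), \code{estimates} (retained replicate
#'   parameter matrix).
#' @export
run_monte_carlo <- function(table, n_reps = 150, cfg = swarm_config(),
                            design = experiment_design(), seed = 1L,
                            glu_surrogate = GLU_SURROGATE_DEFAULT,
                            verbose = FALSE) {
  if (n_reps < 4L) stop("need at least 4 replicates")
  ests <- matrix(NA_real_, nrow = n_reps, ncol = length(PARAM_NAMES),
                 dimnames = list(NULL, PARAM_NAMES))
  objectives <- rep(NA_real_, n_reps)
  failed <- 0L
  for (i in seq_len(n_reps)) {
    set.seed(seed + i)
    rep_table <- perturb_table(table)
    res <- tryCatch(
      multistep_estimate(rep_table, cfg = cfg, design = design,
                         seed = seed, glu_surrogate = glu_surrogate),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("replicate ", i, " failed: ", conditionMessage(res),
              call. = FALSE)
      failed <- failed + 1L
      next
    }
    ests[i, ] <- param_vector(res$params)
    objectives[i] <- res$objective_total
    if (verbose)
      message(sprintf("replicate %d/%d: W_total = %.4g", i, n_reps,
                      res$objective_total))
  }
  ok <- !is.na(objectives)
  retained <- ok
  retained[ok] <- quartile_filter(objectives[ok])
  kept <- ests[retained, , drop = FALSE]
  mean_v <- colMeans(kept)
  sd_v <- apply(kept, 2L, stats::sd)
  sd_pct <- ifelse(mean_v == 0, 0, 100 * sd_v / abs(mean_v))
  structure(list(n_requested = n_reps,
                 n_retained = sum(retained),
                 n_failed = failed,
                 summary = data.frame(parameter = PARAM_NAMES,
                                      mean = unname(mean_v),
                                      sd_percent = unname(sd_pct)),
                 objectives = objectives, retained = retained,
                 estimates = kept),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat("Monte Carlo summary:", x$n_retained, "of", x$n_requested,
      "replicates retained\n")
  df <- x$summary
  df$mean <- signif(df$mean, 4)
  df$sd_percent <- round(df$sd_percent, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname run_monte_carlo
#' @param x an \code{mc_summary}.
#' @param path output CSV path (columns parameter, mean, sd_percent).
#' @export
write_mc_summary <- function(x, path) {
  utils::write.csv(x$summary, path, row.names = FALSE)
  invisible(path)
}
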