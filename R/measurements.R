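# Sparse measurement tables, shape-preserving interpolation, and the
# forward-difference derivative reconstruction used by the estimator.

MEASURED_DEFAULT <- c("GLC", "GLN", "ASN", "ASP", "LAC", "ALA", "PRO",
                      "MAb", "BM", "X", "Xd")

#' Construct a measurement table
#'
#' Holds sparse timed concentration measurements: means and standard
#' deviations per variable, in model units (mM; cells in 1e6 cells/mL).
#'
#' @param times strictly increasing sampling times (h).
#' @param mean,sd numeric matrices, \code{length(times)} rows, one column
#'   per measured variable (column names must be model state names).
#' @return An object of class \code{measurement_table}.
#' @export
measurement_table <- function(times, mean, sd) {
  mean <- as.matrix(mean); sd <- as.matrix(sd)
  if (is.null(colnames(mean))) stop("`mean` needs variable column names")
  vars <- colnames(mean)
  bad <- setdiff(vars, STATES)
  if (length(bad))
    stop("unknown measured variable(s): ", paste(bad, collapse = ", "))
  if (any(diff(times) <= 0))
    stop("measurement times must be strictly increasing")
  if (!identical(dim(mean), dim(sd)))
    stop("`sd` must have the same shape as `mean`")
  if (nrow(mean) != length(times))
    stop("`mean` must have one row per time point")
  if (any(mean < 0)) {
    i <- which(mean < 0, arr.ind = TRUE)[1L, ]
    stop("negative mean at time ", times[i[1L]], " h, variable ",
         vars[i[2L]])
  }
  if (any(sd < 0)) {
    i <- which(sd < 0, arr.ind = TRUE)[1L, ]
    stop("negative sd at time ", times[i[1L]], " h, variable ",
         vars[i[2L]])
  }
  colnames(sd) <- vars
  rownames(mean) <- rownames(sd) <- NULL
  structure(list(times = as.numeric(times), variables = vars,
                 mean = mean, sd = sd),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat("Measurement table:", length(x$times), "time points (",
      min(x$times), "-", max(x$times), "h ),",
      length(x$variables), "variables\n")
  print(round(cbind(time_h = x$times, x$mean), 4))
  invisible(x)
}

# The antibody is measured on a 1e-4 mM scale (its concentration is four
# orders of magnitude below the other metabolites); CSV files keep that
# display scale, the in-memory table uses plain mM.
MAB_CSV_SCALE <- 1e-4

#' Read a measurement table from CSV
#'
#' The CSV dialect is a header \code{time_h} followed by paired
#' \code{<var>, <var>_sd} columns.  \code{MAb} columns are stored on the
#' conventional 1e-4 mM display scale and converted to mM on load.
#' \code{source = "bundled"} loads the packaged 147-h hybridoma batch
#' data set: 11 measured variables at 7 sampling times, each point the
#' mean of three independent cultures with its standard deviation.
#'
#' @param source a CSV path, or \code{"bundled"}.
#' @return A [measurement_table()].
#' @export
load_measurements <- function(source = "bundled") {
  if (identical(source, "bundled"))
    source <- system.file("extdata", "measurements_hybridoma.csv",
                          package = "mabkin", mustWork = TRUE)
  df <- tryCatch(utils::read.csv(source, check.names = FALSE),
                 error = function(e)
                   stop("measurement CSV is empty or unreadable (",
                        conditionMessage(e), "): ", source,
                        call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 3L)
    stop("measurement CSV is empty or lacks <var>, <var>_sd columns: ",
         source)
  if (names(df)[1L] != "time_h")
    stop("first column must be `time_h`, got `", names(df)[1L], "`")
  cols <- names(df)[-1L]
  sd_cols <- grep("_sd$", cols, value = TRUE)
  vars <- setdiff(cols, sd_cols)
  if (!setequal(paste0(vars, "_sd"), sd_cols))
    stop("every variable column needs a matching `_sd` column")
  mean <- as.matrix(df[vars]); sd <- as.matrix(df[paste0(vars, "_sd")])
  colnames(sd) <- vars
  if ("MAb" %in% vars) {
    mean[, "MAb"] <- mean[, "MAb"] * MAB_CSV_SCALE
    sd[, "MAb"] <- sd[, "MAb"] * MAB_CSV_SCALE
  }
  measurement_table(df$time_h, mean, sd)
}

#' @rdname load_measurements
#' @param table a [measurement_table()].
#' @param path output CSV path.
#' @export
write_measurements <- function(table, path) {
  mean <- table$mean; sd <- table$sd
  if ("MAb" %in% table$variables) {
    mean[, "MAb"] <- mean[, "MAb"] / MAB_CSV_SCALE
    sd[, "MAb"] <- sd[, "MAb"] / MAB_CSV_SCALE
  }
  colnames(sd) <- paste0(table$variables, "_sd")
  df <- data.frame(time_h = table$times, mean, sd, check.names = FALSE)
  # interleave var, var_sd pairs
  ord <- c(1L, rbind(seq_along(table$variables) + 1L,
                     seq_along(table$variables) + 1L +
                       length(table$variables)))
  utils::write.csv(df[, ord], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dense shape-preserving interpolation of a measurement table
#'
#' Builds, per measured variable, a monotone piecewise-cubic Hermite
#' interpolant (Fritsch--Carlson slope limiting,
#' \code{stats::splinefun(method = "monoH.FC")}) through the measured
#' means, evaluated on the regular grid \code{0, Ts, 2 Ts, ...,
#' t_final}.  The shape-preserving derivative choice keeps the
#' interpolant within the data range on each interval, so depleted
#' substrates (glutamine reaches exactly 0) never swing negative — an
#' unconstrained cubic spline would, which is fatal inside Monod factors.
#' Values are additionally clamped at 0.
#'
#' @param table a [measurement_table()].
#' @param design an [experiment_design()]; the grid must not extend
#'   beyond the measured time range (no extrapolation).
#' @return An object of class \code{interp_trajectory}: list with
#'   \code{grid}, \code{values} (grid x variables), \code{variables},
#'   \code{source}.
#' @export
interpolate_measurements <- function(table, design = experiment_design()) {
  if (length(table$times) < 2L)
    stop("need at least 2 time points per variable to interpolate")
  grid <- seq(0, design$t_final, by = design$Ts)
  if (min(grid) < min(table$times) || max(grid) > max(table$times) + 1e-9)
    stop("interpolation grid [0, ", design$t_final,
         "] extends beyond the measured range [", min(table$times), ", ",
         max(table$times), "]; extrapolation is not supported")
  vals <- vapply(table$variables, function(v) {
    f <- stats::splinefun(table$times, table$mean[, v],
                          method = "monoH.FC")
    pmax(f(grid), 0)
  }, numeric(length(grid)))
  # exact value at the knots (clamping never moves them: means are >= 0)
  knot <- match(round(table$times, 9), round(grid, 9))
  ok <- !is.na(knot)
  vals[knot[ok], ] <- table$mean[ok, , drop = FALSE]
  structure(list(grid = grid, values = vals,
                 variables = table$variables, source = table),
            class = "interp_trajectory")
}

#' Forward-difference derivative reconstruction
#'
#' Approximates the time derivative of each interpolated variable by the
#' forward difference \eqn{(\xi(t_k + T_s) - \xi(t_k)) / T_s}; the last
#' grid point carries the backward difference.  The truncation error is
#' proportional to the grid step.
#'
#' @param traj an \code{interp_trajectory} from
#'   [interpolate_measurements()].
#' @return Matrix, same shape as \code{traj$values}, of derivative
#'   estimates (units/h).
#' @export
finite_difference <- function(traj) {
  v <- traj$values
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 grid points")
  h <- diff(traj$grid)
  d <- (v[-1L, , drop = FALSE] - v[-n, , drop = FALSE]) / h
  rbind(d, d[n - 1L, , drop = FALSE])
}
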