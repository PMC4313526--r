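#' Kinetic parameter set of the culture model
#'
#' Bundles the 23 kinetic parameters of the batch-culture model: nine
#' maximum reaction rates \eqn{\phi_i^*} (pmol/(cell h)), twelve Monod
#' half-saturation constants \eqn{K_{Sj,i}} (mM), the specific growth rate
#' \eqn{\mu} (1/h) and the death constant \eqn{k_d}
#' (per (1e6 cells/mL) per h).  With concentrations in mM and cells in
#' 1e6 cells/mL, \eqn{\phi_i^* X} is directly a volumetric rate in mM/h
#' (pmol/(cell h) x 1e6 cells/mL = nmol/(mL h) = mM/h), which keeps the
#' rate and measurement units mutually consistent.
#'
#' @param phi_star numeric length 9, maximum reaction rates, named or in
#'   reaction order.
#' @param ks named numeric length 12, half-saturation constants with names
#'   \code{KS1_1, KS1_2, KS3_2, KS1_3, KS3_3, KS3_4, KS4_5, KS2_6, KS5_6,
#'   KS2_7, KS2_8, KS2_9} (\code{KS<substrate>_<reaction>}).
#' @param mu,kd scalars, growth and decay constants.
#' @param kinetics_mode \code{"saturable"} (Monod products) or
#'   \code{"simplified"} (\eqn{\phi_i = \phi_i^* X}; the half-saturation
#'   constants are then ignored).
#' @param strict if \code{TRUE} (default) negative values are an error;
#'   some published comparison sets contain negative fitted rates and are
#'   loaded with \code{strict = FALSE}.
#' @return An object of class \code{kinetic_params}.
#' @seealso [load_params()], [bundled_params()]
#' @export
kinetic_parameters <- function(phi_star, ks, mu, kd,
                               kinetics_mode = c("saturable", "simplified"),
                               strict = TRUE) {
  kinetics_mode <- match.arg(kinetics_mode)
  phi_star <- as.numeric(phi_star)
  if (length(phi_star) != 9L)
    stop("`phi_star` must have length 9, got ", length(phi_star))
  names(phi_star) <- PHI_NAMES
  if (is.null(names(ks)) && length(ks) == 12L) names(ks) <- KS_NAMES
  if (!setequal(names(ks), KS_NAMES) || length(ks) != 12L)
    stop("`ks` must be the 12 half-saturation constants named ",
         paste(KS_NAMES, collapse = ", "))
  ks <- as.numeric(ks[KS_NAMES])
  names(ks) <- KS_NAMES
  stopifnot(length(mu) == 1L, length(kd) == 1L,
            is.finite(mu), is.finite(kd))
  if (strict && (any(phi_star < 0) || any(ks < 0) || mu < 0 || kd < 0))
    stop("kinetic parameters must be nonnegative")
  structure(list(phi_star = phi_star, ks = ks,
                 mu = as.numeric(mu), kd = as.numeric(kd),
                 kinetics_mode = kinetics_mode),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameter set (", x$kinetics_mode, " kinetics)\n", sep = "")
  v <- param_vector(x)
  print(signif(v, 4))
  invisible(x)
}

#' Flatten / rebuild the 23-parameter vector
#'
#' @param params a \code{kinetic_params} object.
#' @return \code{param_vector()}: named numeric of length 23 in the order
#'   \code{phi1..phi9}, the 12 \code{KS} constants, \code{mu}, \code{kd}.
#' @export
param_vector <- function(params) {
  c(params$phi_star, params$ks, mu = params$mu, kd = params$kd)
}

#' @rdname param_vector
#' @param x named numeric of length 23 (names as in [param_vector()]).
#' @param kinetics_mode passed to [kinetic_parameters()].
#' @param strict passed to [kinetic_parameters()].
#' @export
params_from_vector <- function(x, kinetics_mode = "saturable",
                               strict = TRUE) {
  if (!all(PARAM_NAMES %in% names(x)))
    stop("missing parameters: ",
         paste(setdiff(PARAM_NAMES, names(x)), collapse = ", "))
  kinetic_parameters(x[PHI_NAMES], x[KS_NAMES], x[["mu"]], x[["kd"]],
                     kinetics_mode = kinetics_mode, strict = strict)
}

#' Read / write a parameter set as flat key = value YAML
#'
#' @param path file path.
#' @param strict passed to [kinetic_parameters()].
#' @return \code{load_params()}: a \code{kinetic_params} object.
#' @export
load_params <- function(path, strict = TRUE) {
  y <- yaml::read_yaml(path)
  mode <- y$kinetics_mode %||% "saturable"
  y$kinetics_mode <- NULL
  v <- unlist(y)
  params_from_vector(v, kinetics_mode = mode, strict = strict)
}

#' @rdname load_params
#' @param params a \code{kinetic_params} object.
#' @export
write_params <- function(params, path) {
  v <- as.list(param_vector(params))
  v$kinetics_mode <- params$kinetics_mode
  yaml::write_yaml(v, path)
  invisible(path)
}

#' Bundled published parameter sets
#'
#' Parameter estimates for the hybridoma culture shipped with the package:
#' \describe{
#'   \item{\code{"pso"}}{the multistep PSO estimates (saturable kinetics).}
#'   \item{\code{"gao_exp"}, \code{"gao_decl"}}{the quadratic-programming
#'     estimates of Gao and co-workers for the exponential and decline
#'     phases; these assume the simplified kinetics
#'     \eqn{\phi_i = \phi_i^* X} and include negative fitted rates.}
#'   \item{\code{"baughman"}}{the interior-point estimates of Baughman and
#'     co-workers (saturable kinetics).}
#' }
#'
#' @param set one of \code{"pso"}, \code{"gao_exp"}, \code{"gao_decl"},
#'   \code{"baughman"}.
#' @return A \code{kinetic_params} object.
#' @export
bundled_params <- function(set = c("pso", "gao_exp", "gao_decl",
                                   "baughman")) {
  set <- match.arg(set)
  path <- system.file("extdata", paste0("params_", set, ".yaml"),
                      package = "mabkin", mustWork = TRUE)
  load_params(path, strict = !startsWith(set, "gao"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch experiment design
#'
#' @param t_exp end of the exponential growth phase (h); the viable-cell
#'   balance loses its growth term afterwards.
#' @param t_final batch duration (h).
#' @param Ts sampling period of discretized computations (h).
#' @return An object of class \code{experiment_design}.
#' @export
experiment_design <- function(t_exp = 54, t_final = 147, Ts = 0.1) {
  stopifnot(t_exp > 0, t_final > t_exp, Ts > 0)
  structure(list(t_exp = t_exp, t_final = t_final, Ts = Ts),
            class = "experiment_design")
}
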