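#' Parameters of the boosted-anticipation choice model
#'
#' Bundles the subject-level parameters of the savoring model. The reward
#' value \eqn{R^+} is fixed to 1 (value units are defined relative to it); the
#' no-reward value \eqn{R^-} is non-positive. The anticipation weight is
#' \eqn{\eta = \eta_0 + C|\delta_{aRPE}|}: \code{eta0} is the base weight and
#' \code{C} the boosting gain, which must lie strictly below the stability
#' bound (\code{\link{stability_bound}}) for the self-consistent
#' prediction-error equation to have a finite solution.
#'
#' @param R_minus value of the no-reward outcome (unitless, \eqn{\le 0}).
#' @param eta0 base anticipation weight (unitless, \eqn{\ge 0}).
#' @param C boosting gain (1/value units, \eqn{\ge 0}).
#' @param nu_plus rate of the positive anticipation kernel (1/s, \eqn{> 0}).
#' @param nu_minus rate of the negative anticipation kernel (1/s, \eqn{> 0}).
#' @param gamma temporal discounting rate, shared across valences (1/s,
#'   \eqn{\ge 0}).
#' @param sigma choice noise of the sigmoid (value units, \eqn{> 0}).
#' @param check_stability if \code{TRUE} (default), error when \code{C} is not
#'   strictly below \code{\link{stability_bound}}.
#'
#' @return An object of class \code{savor_params}: a named list with the seven
#'   free parameters plus \code{R_plus = 1}.
#' @examples
#' p <- savor_params(R_minus = -0.5, eta0 = 0.5, C = 0.1,
#'                   nu_plus = 0.2, nu_minus = 0.2, gamma = 0.05, sigma = 0.3)
#' choice_prob(p, q = 0.5, T = c(5, 10, 20, 40))
#' @export
savor_params <- function(R_minus = -0.5, eta0 = 0.5, C = 0, nu_plus = 0.2,
                         nu_minus = 0.2, gamma = 0.05, sigma = 0.5,
                         check_stability = TRUE) {
  x <- list(R_plus = 1, R_minus = R_minus, eta0 = eta0, C = C,
            nu_plus = nu_plus, nu_minus = nu_minus, gamma = gamma,
            sigma = sigma)
  vals <- unlist(x)
  if (!all(is.finite(vals)))
    stop("all model parameters must be finite numbers")
  if (R_minus > 0) stop("R_minus must be <= 0")
  if (eta0 < 0) stop("eta0 must be >= 0")
  if (C < 0) stop("C must be >= 0")
  if (nu_plus <= 0 || nu_minus <= 0) stop("nu_plus and nu_minus must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  class(x) <- "savor_params"
  if (check_stability && C > 0) {
    b <- stability_bound(x)
    if (C >= b)
      stop(sprintf("C = %g violates the stability bound C < %g", C, b))
  }
  x
}

#' @export
print.savor_params <- function(x, ...) {
  cat("Boosted-anticipation model parameters:\n")
  v <- unlist(x)
  print(round(v, 4))
  b <- stability_bound(x)
  cat(sprintf("Stability bound on C: %.4g (C/C_max = %.3f)\n", b, x$C / b))
  invisible(x)
}

.param_names <- c("R_minus", "eta0", "C", "nu_plus", "nu_minus", "gamma",
                  "sigma")

as_savor_params <- function(x, check_stability = FALSE) {
  if (inherits(x, "savor_params")) return(x)
  x <- as.list(x)
  do.call(savor_params, c(x[.param_names], list(check_stability = check_stability)))
}

# natural-scale parameter vector in canonical order (drops R_plus)
par_vector <- function(params) {
  unlist(params[.param_names], use.names = FALSE)
}

#' Stability bound on the boosting gain
#'
#' The self-consistent prediction-error equation has a finite, stable solution
#' only while the boosting gain keeps its denominator
#' \eqn{1 - C((1-q)A^+ - qA^-)} positive for every probability
#' \eqn{0 \le q \le 1} and delay \eqn{T \ge 0}. Because the anticipation
#' coefficient \eqn{A^+(T)} peaks at \eqn{T = \ln(\gamma/\nu)/(\gamma-\nu)},
#' the bound is
#' \deqn{C_{max} = \min\!\left(\frac{\gamma}{R^+}(\gamma/\nu^+)^{\nu^+/(\gamma-\nu^+)},
#'   \; \frac{-\gamma}{R^-}(\gamma/\nu^-)^{\nu^-/(\gamma-\nu^-)}\right).}
#' At \eqn{\gamma = 0} each branch reduces to \eqn{\nu/|R|}; at
#' \eqn{\nu = \gamma} to \eqn{\gamma e / |R|}; a branch with \eqn{R = 0} never
#' binds. Gains above the bound model runaway valuation (an addiction
#' analogy); all fitting routines reparameterize \code{C} to stay below it.
#'
#' @param params a \code{\link{savor_params}} object (only \code{R_minus},
#'   \code{nu_plus}, \code{nu_minus}, \code{gamma} are used).
#' @return The supremum of admissible \code{C} (a positive scalar, possibly
#'   \code{Inf} when both branches are degenerate).
#' @seealso \code{\link{solve_arpe}}
#' @export
stability_bound <- function(params) {
  stability_bound_cpp(params$R_minus, params$nu_plus, params$nu_minus,
                      params$gamma)
}

# clamps used where a boundary parameter value has no finite transform
.H_CLAMP <- 30

#' Map model parameters to and from unconstrained space
#'
#' The hierarchical fit works on a transformed vector \code{h} in which every
#' coordinate is unconstrained: \code{R_minus = -exp(h)},
#' \code{eta0 = softplus(h)}, \code{C = C_max * logistic(h)} (so every
#' candidate is automatically inside the stability region for its own rates),
#' and \code{log} for the two anticipation rates, the discount rate and the
#' choice noise. Boundary values (\code{R_minus = 0}, \code{eta0 = 0},
#' \code{C = 0}) are clamped to \code{h = -30}, the resolution limit of the
#' transform.
#'
#' @param params a \code{\link{savor_params}} object.
#' @param h a named numeric vector in transformed space (names
#'   \code{R_minus, eta0, C, nu_plus, nu_minus, gamma, sigma}).
#' @return \code{transform_params} returns the transformed vector;
#'   \code{untransform_params} the \code{savor_params} object.
#' @export
transform_params <- function(params) {
  p <- as_savor_params(params)
  hR <- if (-p$R_minus < exp(-.H_CLAMP)) -.H_CLAMP else log(-p$R_minus)
  he <- if (p$eta0 < 1e-12) -.H_CLAMP else log(expm1(p$eta0))
  b <- stability_bound(p)
  r <- p$C / b
  hC <- if (r < 1e-12) -.H_CLAMP else if (r > 1 - 1e-12) .H_CLAMP else qlogis(r)
  h <- c(hR, he, hC, log(p$nu_plus), log(p$nu_minus), log(p$gamma),
         log(p$sigma))
  names(h) <- .param_names
  h
}

#' @rdname transform_params
#' @export
untransform_params <- function(h) {
  h <- pmin(pmax(h, -40), 40)
  if (is.null(names(h))) names(h) <- .param_names
  p <- list(R_plus = 1,
            R_minus = -exp(h[["R_minus"]]),
            eta0 = log1p(exp(h[["eta0"]])),
            C = 0,
            nu_plus = exp(h[["nu_plus"]]),
            nu_minus = exp(h[["nu_minus"]]),
            gamma = exp(h[["gamma"]]),
            sigma = exp(h[["sigma"]]))
  class(p) <- "savor_params"
  b <- stability_bound(p)
  p$C <- b * plogis(h[["C"]])
  p
}

#' Model variants of the savoring model
#'
#' Defines which parameters are free in each model variant used for model
#' comparison: the \code{"full"} boosted model (7 free parameters), the
#' \code{"noboost"} model with anticipation but no boosting (\code{C = 0}, 6
#' free), and the \code{"noanticipation"} model with no anticipatory utility
#' at all (\code{eta0 = C = 0}, 5 free). The number of fitted group-prior
#' parameters is \code{n_prior = 2 *} (free-parameter count): one mean and one
#' variance per coordinate.
#'
#' @param name one of \code{"full"}, \code{"noboost"},
#'   \code{"noanticipation"}.
#' @return An object of class \code{savor_model_spec} with elements
#'   \code{name}, \code{free} (character vector of free parameter names),
#'   \code{fixed} (named numeric of fixed natural-scale values) and
#'   \code{n_prior}.
#' @export
savor_model_spec <- function(name = c("full", "noboost", "noanticipation")) {
  name <- match.arg(name)
  fixed <- switch(name,
                  full = numeric(0),
                  noboost = c(C = 0),
                  noanticipation = c(eta0 = 0, C = 0))
  free <- setdiff(.param_names, names(fixed))
  out <- list(name = name, free = free, fixed = fixed,
              n_prior = 2L * length(free))
  class(out) <- "savor_model_spec"
  out
}

#' @export
print.savor_model_spec <- function(x, ...) {
  cat(sprintf("savor model spec '%s': %d free parameters (%s), |M| = %d\n",
              x$name, length(x$free), paste(x$free, collapse = ", "),
              x$n_prior))
  invisible(x)
}
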