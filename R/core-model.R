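#' Anticipation and discounted-outcome coefficients
#'
#' \code{anticipation_coefficient} returns the per-unit-of-\eqn{\eta} value of
#' anticipating an outcome over a delay \code{T}: the discounted integral of
#' the anticipation kernel,
#' \eqn{A^{\pm} = R^{\pm}/(\nu^{\pm}-\gamma)\,(e^{-\gamma T}-e^{-\nu^{\pm}T})},
#' switching to the analytic limit \eqn{R^{\pm} T e^{-\gamma T}} when
#' \eqn{|\nu - \gamma| < 10^{-9}}. \code{discounted_outcome} returns the
#' conventionally discounted outcome value \eqn{B^{\pm} = R^{\pm}e^{-\gamma T}}.
#'
#' @param params a \code{\link{savor_params}} object.
#' @param T delay(s) in seconds, \eqn{\ge 0}; vectorized.
#' @param valence \code{"+"} (reward, \eqn{R^+ = 1}) or \code{"-"}
#'   (no reward, \eqn{R^-}).
#' @return Numeric vector the length of \code{T}.
#' @export
anticipation_coefficient <- function(params, T, valence = c("+", "-")) {
  valence <- match.arg(valence)
  p <- as_savor_params(params)
  if (any(!is.finite(T)) || any(T < 0)) stop("T must be finite and >= 0")
  R <- if (valence == "+") p$R_plus else p$R_minus
  nu <- if (valence == "+") p$nu_plus else p$nu_minus
  .acoef(R, nu, p$gamma, T)
}

.acoef <- function(R, nu, gamma, T) {
  if (abs(nu - gamma) < 1e-9) R * T * exp(-gamma * T)
  else R / (nu - gamma) * (exp(-gamma * T) - exp(-nu * T))
}

#' @rdname anticipation_coefficient
#' @export
discounted_outcome <- function(params, T, valence = c("+", "-")) {
  valence <- match.arg(valence)
  p <- as_savor_params(params)
  if (any(!is.finite(T)) || any(T < 0)) stop("T must be finite and >= 0")
  R <- if (valence == "+") p$R_plus else p$R_minus
  R * exp(-p$gamma * T)
}

# A+/A-/B+/B- for vectors of delays
.coefs <- function(p, T) {
  list(Ap = .acoef(p$R_plus, p$nu_plus, p$gamma, T),
       Am = .acoef(p$R_minus, p$nu_minus, p$gamma, T),
       Bp = p$R_plus * exp(-p$gamma * T),
       Bm = p$R_minus * exp(-p$gamma * T))
}

#' Self-consistent anticipation + reward prediction errors (aRPE)
#'
#' At an advance-information cue, the prediction error is computed over the
#' sum of anticipatory utility and discounted reward; because the boosted
#' anticipation weight itself depends on \eqn{|\delta|}, the prediction errors
#' obey a coupled self-consistency equation. Under the linear boosting ansatz
#' and \eqn{R^- \le 0 \le R^+}, it reduces to the closed form
#' \deqn{\delta^+ = \frac{(1-q)\,(\eta_0(A^+-A^-)+B^+-B^-)}{1 - C((1-q)A^+ - qA^-)},
#'   \quad \delta^- = \frac{-q\,(\eta_0(A^+-A^-)+B^+-B^-)}{1 - C((1-q)A^+ - qA^-)}.}
#' \code{arpe_fixed_point} iterates the unreduced coupled map from
#' \eqn{\delta = 0} instead and serves as an independent oracle: the two agree
#' to near machine precision for any admissible gain \code{C}.
#'
#' @param params a \code{\link{savor_params}} object; \code{C} must be below
#'   \code{\link{stability_bound}}.
#' @param q reward probability(ies) in \eqn{[0, 1]}; vectorized with \code{T}.
#' @param T delay(s) in seconds.
#' @param tol convergence tolerance for the fixed-point iteration.
#' @param max_iter iteration cap; exceeding it signals a stability violation
#'   (or a tolerance below attainable precision).
#' @return A list with components \code{delta_plus} (\eqn{\ge 0}) and
#'   \code{delta_minus} (\eqn{\le 0}), each the common length of \code{q} and
#'   \code{T}. They satisfy \eqn{q\delta^+ + (1-q)\delta^- = 0}.
#' @export
solve_arpe <- function(params, q, T) {
  p <- as_savor_params(params)
  .check_cond(q, T)
  k <- .coefs(p, T)
  numer <- p$eta0 * (k$Ap - k$Am) + k$Bp - k$Bm
  den <- 1 - p$C * ((1 - q) * k$Ap - q * k$Am)
  if (any(den <= 0))
    stop("stability violation: self-consistency denominator <= 0")
  list(delta_plus = (1 - q) * numer / den,
       delta_minus = -q * numer / den)
}

.check_cond <- function(q, T) {
  if (any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("q must lie in [0, 1]")
  if (any(!is.finite(T)) || any(T < 0)) stop("T must be finite and >= 0")
  invisible(TRUE)
}

#' @rdname solve_arpe
#' @export
arpe_fixed_point <- function(params, q, T, tol = 1e-12, max_iter = 10000L) {
  p <- as_savor_params(params)
  .check_cond(q, T)
  n <- max(length(q), length(T))
  q <- rep_len(q, n); T <- rep_len(T, n)
  k <- .coefs(p, T)
  dp <- dm <- numeric(n)
  for (i in seq_len(max_iter)) {
    gap <- (p$eta0 + p$C * abs(dp)) * k$Ap + k$Bp -
      ((p$eta0 + p$C * abs(dm)) * k$Am + k$Bm)
    dp_new <- (1 - q) * gap
    dm_new <- -q * gap
    if (max(abs(dp_new - dp), abs(dm_new - dm)) < tol) {
      return(list(delta_plus = dp_new, delta_minus = dm_new,
                  iterations = i))
    }
    dp <- dp_new; dm <- dm_new
    if (any(!is.finite(dp)) || any(!is.finite(dm)))
      stop("fixed-point iteration diverged: C violates the stability bound")
  }
  stop("fixed-point iteration did not converge in max_iter steps ",
       "(stability violation or tol below attainable precision)")
}

#' Cue values, target values and choice probability
#'
#' \code{cue_value} returns the total value of an outcome-predictive cue,
#' \eqn{Q_{S^\pm} = (\eta_0 + C|\delta^\pm|)A^\pm + B^\pm}: boosted
#' anticipatory utility plus the discounted outcome. \code{target_values}
#' returns the values of the two choice targets,
#' \eqn{V_{II} = qQ_{S^+} + (1-q)Q_{S^-}} for immediate information and
#' \eqn{V_{NI} = \eta_0(qA^+ + (1-q)A^-) + qB^+ + (1-q)B^-} for no
#' information (probability-weighted anticipation with no prediction error,
#' hence no boosting). \code{choice_prob} passes the value difference through
#' a sigmoid with noise \eqn{\sigma}:
#' \eqn{p(II) = 1/(1 + e^{-(V_{II}-V_{NI})/\sigma})}.
#'
#' With no boosting (\code{C = 0}) the information targets are exactly
#' equivalued (\eqn{V_{II} = V_{NI}}) whatever \code{eta0}, so conventional
#' discounting models — with or without unboosted anticipation — predict
#' indifference (\eqn{p = 0.5}) in every condition.
#'
#' @inheritParams solve_arpe
#' @param cue \code{"S+"} (reward-predictive) or \code{"S-"}
#'   (no-reward-predictive).
#' @return \code{cue_value}: numeric vector; \code{target_values}: list with
#'   \code{V_II} and \code{V_NI}; \code{choice_prob}: probability of choosing
#'   the immediate-information target.
#' @export
cue_value <- function(params, q, T, cue = c("S+", "S-")) {
  cue <- match.arg(cue)
  p <- as_savor_params(params)
  d <- solve_arpe(p, q, T)
  k <- .coefs(p, T)
  if (cue == "S+") (p$eta0 + p$C * abs(d$delta_plus)) * k$Ap + k$Bp
  else (p$eta0 + p$C * abs(d$delta_minus)) * k$Am + k$Bm
}

#' @rdname cue_value
#' @export
target_values <- function(params, q, T) {
  p <- as_savor_params(params)
  d <- solve_arpe(p, q, T)
  k <- .coefs(p, T)
  Qp <- (p$eta0 + p$C * abs(d$delta_plus)) * k$Ap + k$Bp
  Qm <- (p$eta0 + p$C * abs(d$delta_minus)) * k$Am + k$Bm
  list(V_II = q * Qp + (1 - q) * Qm,
       V_NI = p$eta0 * (q * k$Ap + (1 - q) * k$Am) + q * k$Bp +
         (1 - q) * k$Bm)
}

#' @rdname cue_value
#' @export
choice_prob <- function(params, q, T) {
  p <- as_savor_params(params)
  if (p$sigma <= 0) stop("sigma must be > 0")
  v <- target_values(p, q, T)
  plogis((v$V_II - v$V_NI) / p$sigma)
}
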